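question,S1,S2,S3,S4,S5,S6
1. AR in surgeries (general),5,4,5,5,3,5
2. AR in surgeon's operations (general),5,4,3,3,4,5
3. DEMO: surgeon understanding,5,4,5,5,4,5
4. DEMO: surgical planning,5,4,5,5,5,5
5. DEMO: patient communication,5,5,5,5,5,5
6. CLINIC: PLA bone fragment,5,4,4,5,4,5
7. CLINIC: practice with AR,5,3,4,5,5,5
8. CLINIC: patient communication,5,3,5,5,3,5
9. SURGERY: tumor location,5,5,4,5,4,5
10. SURGERY: increase of accuracy,5,4,4,5,5,5
11. SURGERY: phone case,5,4,5,5,5,5
12. GENERIC: easiness of interpretation,5,5,4,5,4,5
13. GENERIC: patient communication,5,5,5,5,5,5
14. GENERIC: surgeon's confidently,4,4,5,5,4,5
15. GENERIC: use this workflow,5,4,4,5,4,5
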