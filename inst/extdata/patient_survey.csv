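question,P1,P2
1. Pathology understanding before ARHealth,2,4
2. Pathology understanding after ARHealth,5,5
3. General opinion about AR,5,5
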