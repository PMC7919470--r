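test_that("phantom generation is deterministic and honors its spec", {
  spec <- phantom_spec("AR3DP0002", c(170, 150, 130), "ellipsoid",
                       n_guide_fiducials = 5L, seed = 1L)
  p1 <- generate_phantom(spec)
  p2 <- generate_phantom(spec)
  expect_identical(p1$bone$vertices, p2$bone$vertices)
  expect_identical(p1$fiducials$points, p2$fiducials$points)
  expect_identical(as.matrix(p1$guide$holder_pose),
                   as.matrix(p2$guide$holder_pose))
  # bounding box within the stated dimensions (Table-sized case)
  bb <- phantom_bbox(p1)
  expect_true(all(bb[2, ] - bb[1, ] <= c(170, 150, 130) + 1e-6))
  # 8 conical surface fiducials, each on the surface within 0.1 mm
  expect_equal(n_fiducials(p1$fiducials), 8L)
  expect_equal(length(p1$fiducial_cones), 8L)
  expect_lt(max(mesh_closest_points(p1$bone, p1$fiducials$points)$distance), 0.1)
  expect_true(all(vapply(p1$fiducial_cones, function(cn)
    cn$diameter == 4 && cn$depth == 3, TRUE)))
  # guide has 3-5 cones and a holder; meshes watertight; stable stand
  expect_true(length(p1$guide$fiducial_cones) >= 3 &&
              length(p1$guide$fiducial_cones) <= 5)
  expect_false(is.null(p1$guide$holder_pose))
  expect_true(is_watertight(p1$bone))
  expect_true(is_watertight(p1$tumor))
  expect_true(phantom_stable(p1))
  expect_error(phantom_spec("x", c(-1, 10, 10)), "impossible")
})

test_that("noiseless trials close the chain to numerical zero", {
  ph <- test_phantom(2L)
  pt <- placement_trial(ph, zero_noise(), user = 1, rep = 1, seed = 99)
  expect_lt(max(pt$error_mm), 1e-6)
  expect_true(nrow(pt) >= 3 && nrow(pt) <= 5)   # one row per guide cone
  expect_equal(nrow(pt), length(ph$guide$fiducial_cones))
  tt <- tracking_trial(ph, noise = zero_noise(), user = 1, rep = 1, seed = 99)
  expect_lt(max(tt$error_mm), 1e-6)
  expect_equal(nrow(tt), 14L)                   # 14 augmented spheres
  expect_equal(tt$kind, rep("tracking", 14))
})

test_that("trials are reproducible under a fixed seed", {
  ph <- test_phantom(2L)
  a <- tracking_trial(ph, noise = noise_model(), seed = 123)
  b <- tracking_trial(ph, noise = noise_model(), seed = 123)
  expect_identical(a$error_mm, b$error_mm)
  c_ <- tracking_trial(ph, noise = noise_model(), seed = 124)
  expect_false(identical(a$error_mm, c_$error_mm))
})

test_that("the experiment design is balanced and reproducible", {
  phs <- list(test_phantom(2L), test_phantom(5L, case = "AR3DP0005"))
  tr <- run_experiment(phs, users = 2, reps = 5, seed = 42,
                       kinds = "placement")
  trials <- unique(tr[c("case", "user", "rep")])
  expect_equal(nrow(trials), 2 * 2 * 5)
  expect_equal(as.vector(table(tr$user)), rep(nrow(tr) / 2, 2)) # balanced users
  tr2 <- run_experiment(phs, users = 2, reps = 5, seed = 42,
                        kinds = "placement")
  expect_identical(tr$error_mm, tr2$error_mm)
})

test_that("tracking error stochastically dominates placement-only error", {
  ph <- test_phantom(2L)
  n <- 300
  pl <- numeric(n); tk <- numeric(n)
  for (i in seq_len(n)) {
    pl[i] <- mean(placement_trial(ph, noise_model(), seed = 1e5 + i)$error_mm)
    tk[i] <- mean(tracking_trial(ph, noise = noise_model(),
                                 seed = 2e5 + i)$error_mm)
  }
  expect_gt(mean(tk), mean(pl))
})

test_that("placement error scales with the localization noise chain", {
  # sigma_loc only: compare the simulated mean per-point error against an
  # independent direct simulation of the same measurement chain
  ph <- test_phantom(2L)
  nm <- noise_model(fiducial_sigma = 0.5, pointer_sigma = 0,
                    seating_sigma_trans = 0, seating_sigma_rot = 0,
                    marker_sigma_trans = 0, marker_sigma_rot = 0)
  n <- 400
  sim <- numeric(n)
  for (i in seq_len(n))
    sim[i] <- mean(placement_trial(ph, nm, seed = 3e5 + i)$error_mm)
  # oracle: direct simulation with the quaternion registration oracle
  set.seed(777)
  G <- guide_fiducials(ph$guide)$points
  Fp <- ph$fiducials$points
  oracle <- replicate(n, {
    y <- G + matrix(rnorm(length(G), sd = 0.5), ncol = 3)
    z <- Fp + matrix(rnorm(length(Fp), sd = 0.5), ncol = 3)
    o <- horn_quaternion_oracle(z, Fp)           # registration from noisy set
    yhat <- sweep(y %*% t(o$R), 2, o$t, "+")
    mean(sqrt(rowSums((yhat - G)^2)))
  })
  expect_lt(abs(mean(sim) - mean(oracle)) / mean(oracle), 0.05)
})
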