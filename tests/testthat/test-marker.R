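test_that("cube corners sit at half the edge length on every axis", {
  corners <- cube_corners(marker_model(30))
  expect_equal(n_fiducials(corners), 8L)
  expect_true(all(abs(abs(corners$points) - 15) < 1e-12))
  # pairwise-distance enumeration: 12 edges of 30, 12 face diagonals 30*sqrt2,
  # 4 space diagonals 30*sqrt3
  d <- as.matrix(dist(corners$points))
  du <- sort(d[upper.tri(d)])
  expect_equal(du, c(rep(30, 12), rep(30 * sqrt(2), 12), rep(30 * sqrt(3), 4)),
               tolerance = 1e-12)
  expect_error(marker_model(0), "edge")
})

test_that("the corner set is symmetric under the cube rotation group", {
  corners <- cube_corners(marker_model())$points
  key <- function(m) sort(unname(apply(round(m, 9), 1, paste, collapse = ",")))
  for (ax in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) for (ang in c(90, 180)) {
    rot <- corners %*% t(rotation_axis_angle(ax, ang))
    expect_identical(key(rot), key(corners))
  }
})

test_that("face visibility follows the outward-normal test, at most 3 faces", {
  id <- transform_identity("camera", "marker")
  expect_equal(visible_faces(id, c(0, 0, -1)), 5L)   # looking down onto +z
  expect_error(visible_faces(id, c(0, 0, 0)), "non-zero")
  set.seed(51)
  for (i in 1:50) {
    pose <- rigid_transform(random_rotation(), rnorm(3), "camera", "marker")
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    vis <- visible_faces(pose, v)
    # brute force: count sign pattern of rotated normals against v
    n_vis <- sum((marker_model()$face_normals %*% t(pose$rotation)) %*% v < 0)
    expect_equal(length(vis), n_vis)
    expect_lte(length(vis), 3L)
    expect_gte(length(vis), 1L)
    # occluding one face leaves the pose recoverable from the rest
    occ <- visible_faces(pose, v, occluded = vis[1])
    expect_equal(length(occ), length(vis) - 1L)
  }
})

test_that("marker observations are exact at zero noise and seeded", {
  set.seed(52)
  pose <- rigid_transform(random_rotation(), rnorm(3, sd = 100),
                          "camera", "marker")
  obs0 <- simulate_marker_observation(pose, 0, 0)
  expect_equal(as.matrix(obs0$pose), as.matrix(pose))
  o1 <- simulate_marker_observation(pose, 0.5, 0.5, seed = 7)
  o2 <- simulate_marker_observation(pose, 0.5, 0.5, seed = 7)
  expect_identical(as.matrix(o1$pose), as.matrix(o2$pose))
  expect_error(simulate_marker_observation(pose, -1, 0), ">= 0")
})

test_that("mean translation error matches the chi-distribution expectation", {
  # E|N3(0, s^2 I)| = s * sqrt(2) * gamma(2) / gamma(1.5) ~= 1.5958 s
  set.seed(53)
  pose <- transform_identity("camera", "marker")
  n <- 10000
  errs <- vapply(seq_len(n), function(i) {
    o <- simulate_marker_observation(pose, 0.5, 0)
    sqrt(sum(o$pose$translation^2))
  }, 1)
  expected <- 0.5 * sqrt(2) * gamma(2) / gamma(1.5)
  expect_lt(abs(mean(errs) - expected) / expected, 0.03)
})

test_that("marker specs round-trip through JSON", {
  m <- marker_model(edge = 30, pattern_seed = 5L)
  f <- tempfile(fileext = ".json")
  write_marker_json(m, f)
  m2 <- read_marker_json(f)
  expect_equal(m2$edge, 30)
  expect_equal(m2$pattern_seed, 5L)
  expect_identical(marker_face_pattern(m2, 3), marker_face_pattern(m, 3))
})

test_that("face patterns are deterministic and distinct per face", {
  m <- marker_model()
  p1 <- marker_face_pattern(m, 1)
  expect_identical(p1, marker_face_pattern(m, 1))
  expect_true(all(p1 %in% 0:1))
  pats <- lapply(1:6, marker_face_pattern, model = m)
  expect_equal(length(unique(lapply(pats, paste, collapse = ""))), 6L)
})
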