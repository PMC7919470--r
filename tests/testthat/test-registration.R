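test_that("identical fiducial sets register to the identity with zero FRE", {
  set.seed(41)
  p <- matrix(rnorm(24, sd = 50), ncol = 3)
  a <- fiducial_set(p, frame = "x"); b <- fiducial_set(p, frame = "y")
  r <- horn_register(a, b)
  expect_lt(max(abs(as.matrix(r$transform) - diag(4))), 1e-10)
  expect_lt(r$fre, 1e-10)
})

test_that("known rigid motions are recovered to machine precision", {
  set.seed(42)
  for (i in 1:25) {
    R <- random_rotation(); tt <- rnorm(3, sd = 80)
    p <- matrix(rnorm(24, sd = 60), ncol = 3)
    q <- sweep(p %*% t(R), 2, tt, "+")
    r <- horn_register(fiducial_set(p, frame = "moving"),
                       fiducial_set(q, frame = "fixed"))
    expect_lt(max(abs(r$transform$rotation - R)), 1e-9)
    expect_lt(max(abs(r$transform$translation - tt)), 1e-9)
    expect_lt(r$fre, 1e-9)
  }
})

test_that("the SVD solution agrees with Horn's quaternion method", {
  set.seed(43)
  for (i in 1:10) {
    p <- matrix(rnorm(18, sd = 40), ncol = 3)
    q <- matrix(rnorm(18, sd = 40), ncol = 3)     # unrelated clouds
    r <- horn_register(fiducial_set(p, frame = "m"), fiducial_set(q, frame = "f"))
    o <- horn_quaternion_oracle(p, q)
    expect_lt(max(abs(r$transform$rotation - o$R)), 1e-8)
    expect_lt(max(abs(r$transform$translation - o$t)), 1e-7)
  }
})

test_that("FRE is invariant to a common rigid motion of both sets", {
  set.seed(44)
  p <- matrix(rnorm(24, sd = 50), ncol = 3)
  q <- p + matrix(rnorm(24, sd = 0.5), ncol = 3)
  base <- horn_register(fiducial_set(p, frame = "m"), fiducial_set(q, frame = "f"))
  for (i in 1:5) {
    g <- rigid_transform(random_rotation(), rnorm(3, sd = 100), "w", "f")
    moved <- horn_register(
      fiducial_set(transform_points(g, p), frame = "m"),
      fiducial_set(transform_points(g, q), frame = "f"))
    expect_equal(moved$fre, base$fre, tolerance = 1e-9)
  }
})

test_that("degenerate and mismatched inputs are rejected", {
  line <- fiducial_set(cbind(1:5, 2 * (1:5), 3 * (1:5)), frame = "m")
  line2 <- fiducial_set(cbind(1:5, 2 * (1:5), 3 * (1:5)) + 0, frame = "f")
  expect_error(horn_register(line, line2), "collinear")
  a <- fiducial_set(diag(3), labels = c("A", "B", "C"))
  b <- fiducial_set(diag(3), labels = c("A", "B", "D"))
  expect_error(horn_register(a, b), "label mismatch")
  expect_error(fiducial_set(matrix(1:3, 1)), NA)  # single point constructs...
  two <- fiducial_set(rbind(c(0, 0, 0), c(1, 0, 0)), labels = c("A", "B"))
  expect_error(horn_register(two, two), "at least 3")
})

test_that("target errors are per-label Euclidean distances", {
  t1 <- fiducial_set(rbind(c(0, 0, 0), c(1, 1, 1)), labels = c("A", "B"))
  e1 <- fiducial_set(rbind(c(3, 4, 0), c(1, 1, 1)), labels = c("A", "B"))
  d <- target_errors(e1, t1)
  expect_equal(unname(d), c(5, 0))                 # 3-4-5 triangle
  expect_equal(target_errors(t1, t1), c(A = 0, B = 0))
  set.seed(45)
  p <- matrix(rnorm(30), ncol = 3); q <- matrix(rnorm(30), ncol = 3)
  fp <- fiducial_set(p); fq <- fiducial_set(q)
  loop <- vapply(1:10, function(i) sqrt(sum((p[i, ] - q[i, ])^2)), 1)
  expect_equal(unname(target_errors(fp, fq)), loop)
  # label pairing, not order: permute estimated rows
  perm <- sample(10)
  fpp <- fiducial_set(p[perm, ], labels = paste0("F", perm))
  expect_equal(target_errors(fpp, fq), target_errors(fp, fq))
  expect_error(target_errors(fiducial_set(p, labels = paste0("X", 1:10)), fq),
               "label mismatch")
})

test_that("the marker-to-patient chain composes and round-trips", {
  set.seed(46)
  holder <- rigid_transform(random_rotation(), rnorm(3, sd = 20),
                            "guide", "marker")
  seating <- rigid_transform(random_rotation(), rnorm(3, sd = 20),
                             "anatomy", "guide")
  chain <- marker_to_patient(holder, seating)
  expect_identical(c(chain$parent, chain$child), c("anatomy", "marker"))
  expect_lt(max(abs(as.matrix(chain) -
                    as.matrix(seating) %*% as.matrix(holder))), 1e-12)
  # tumor centroid anatomy -> marker -> anatomy round trip
  centroid <- c(40, -25, 110)
  back <- transform_points(chain, transform_points(invert_transform(chain),
                                                   centroid))
  expect_lt(max(abs(back - centroid)), 1e-9)
  expect_lt(max(abs(as.matrix(marker_to_patient(
    transform_identity("guide", "marker"),
    transform_identity("anatomy", "guide"))) - diag(4))), 1e-15)
})

test_that("expected FRE follows the (1 - 2/N) localization-error law", {
  # closed form at sigma = 0.5, N = 8: sqrt(0.75 * 3 * 0.25) = 0.75 mm
  expect_equal(expected_fre(8, 0.5), sqrt((1 - 2 / 8) * 3 * 0.25))
  expect_equal(expected_fre(8, 0), 0)
})
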