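#' Closed-form rigid point-based registration
#'
#' Least-squares rigid alignment of two label-matched fiducial sets (the
#' classic absolute-orientation problem, solved in closed form via the SVD of
#' the cross-covariance with a reflection guard). Returns the transform that
#' maps `moving`-frame coordinates into the `fixed` frame, together with the
#' fiducial registration error (FRE), the root-mean-square residual distance
#' over the paired fiducials after alignment.
#'
#' At least 3 non-collinear pairs are required. Pairing is strictly by label.
#'
#' @param moving,fixed `fiducial_set` objects with identical label sets.
#' @return list with `transform` (a `rigid_transform`, fixed <- moving),
#'   `fre` (mm), and `residuals` (per-fiducial mm, named).
#' @export
horn_register <- function(moving, fixed) {
  stopifnot(inherits(moving, "fiducial_set"), inherits(fixed, "fiducial_set"))
  if (!setequal(moving$labels, fixed$labels))
    stop("label mismatch between moving and fixed fiducial sets")
  n <- n_fiducials(fixed)
  if (n < 3L) stop("at least 3 fiducials are required")
  P <- moving$points[fixed$labels, , drop = FALSE]  # moving, in fixed label order
  Q <- fixed$points
  pc <- colMeans(P); qc <- colMeans(Q)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  # collinearity check: second singular value of the centred cloud
  sv <- svd(Pc)$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("degenerate fiducial geometry: points are (nearly) collinear")
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  D <- diag(c(1, 1, sign(det(s$v %*% t(s$u)))))
  R <- s$v %*% D %*% t(s$u)
  t <- as.numeric(qc - R %*% pc)
  tr <- rigid_transform(R, t, parent = fixed$frame, child = moving$frame)
  res <- sqrt(rowSums((transform_points(tr, P) - Q)^2))
  names(res) <- fixed$labels
  list(transform = tr, fre = sqrt(mean(res^2)), residuals = res)
}

#' Expected FRE under isotropic fiducial localization error
#'
#' Closed-form expectation `E[FRE^2] = (1 - 2/N) * FLE^2` with
#' `FLE^2 = 3 sigma^2` for independent per-axis Gaussian localization noise of
#' standard deviation `sigma`; returns `sqrt(E[FRE^2])` in mm. Useful as an
#' analytic cross-check of registration simulations.
#'
#' @param n number of fiducials.
#' @param sigma per-axis localization sigma, mm.
#' @export
expected_fre <- function(n, sigma) {
  stopifnot(n >= 3, sigma >= 0)
  sqrt((1 - 2 / n) * 3 * sigma^2)
}

#' Marker-to-patient registration chain
#'
#' The automatic registration the AR display relies on: the guide's marker
#' holder fixes the marker relative to the guide (`holder_pose`,
#' guide <- marker), and the guide seats in a unique position on the bone
#' (`seating`, anatomy <- guide). Their composition re-expresses any model
#' stored in the anatomy frame in the marker frame and back.
#'
#' @param holder_pose `rigid_transform`, guide <- marker.
#' @param seating `rigid_transform`, anatomy <- guide.
#' @return `rigid_transform`, anatomy <- marker.
#' @export
marker_to_patient <- function(holder_pose, seating) {
  compose_transforms(seating, holder_pose)
}
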