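#' Rigid transform between two named frames
#'
#' A rigid (Euclidean) transform maps coordinates expressed in the `child`
#' frame into the `parent` frame: `p_parent = R p_child + t`. Every frame
#' relation in the workflow (anatomy, guide, marker, tracker, camera) is held
#' in one of these, and frame names are checked at composition time so that a
#' broken chain fails loudly instead of silently producing garbage poses.
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 numeric, mm.
#' @param parent,child frame names (single strings).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            parent = "parent", child = "child") {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > 1e-6) stop("rotation is not orthonormal (|R'R - I| = ", format(err), ")")
  if (det(rotation) < 0) stop("rotation has det < 0 (reflection, not a rigid motion)")
  structure(list(rotation = rotation, translation = translation,
                 parent = as.character(parent), child = as.character(child)),
            class = "rigid_transform")
}

#' Identity transform between two frames
#' @inheritParams rigid_transform
#' @export
transform_identity <- function(parent = "parent", child = parent)
  rigid_transform(diag(3), c(0, 0, 0), parent, child)

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform %s <- %s>\n", x$parent, x$child))
  m <- as.matrix(x)
  dimnames(m) <- NULL
  print(round(m, 6))
  invisible(x)
}

#' Homogeneous 4x4 matrix of a rigid transform
#' @param x a `rigid_transform`.
#' @param ... unused.
#' @export
as.matrix.rigid_transform <- function(x, ...) {
  m <- diag(4)
  m[1:3, 1:3] <- x$rotation
  m[1:3, 4] <- x$translation
  m
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` maps `b`'s child frame into `a`'s parent frame;
#' `a$child` must equal `b$parent`.
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform` from `b$child` to `a$parent`.
#' @export
compose_transforms <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  if (!identical(a$child, b$parent))
    stop(sprintf("frame chain mismatch: cannot compose (%s <- %s) with (%s <- %s)",
                 a$parent, a$child, b$parent, b$child))
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation,
                  a$parent, b$child)
}

#' Invert a rigid transform
#' @param x a `rigid_transform`.
#' @export
invert_transform <- function(x) {
  stopifnot(inherits(x, "rigid_transform"))
  rt <- t(x$rotation)
  rigid_transform(rt, as.numeric(-rt %*% x$translation), x$child, x$parent)
}

#' Apply a rigid transform to points
#' @param x a `rigid_transform`.
#' @param points n x 3 matrix (or length-3 vector) of child-frame coordinates, mm.
#' @return n x 3 matrix of parent-frame coordinates.
#' @export
transform_points <- function(x, points) {
  stopifnot(inherits(x, "rigid_transform"))
  p <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  stopifnot(ncol(p) == 3L)
  sweep(p %*% t(x$rotation), 2, x$translation, "+")
}

#' Rotation matrix from axis and angle
#' @param axis length-3 vector (need not be unit).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix (Rodrigues formula).
#' @export
rotation_axis_angle <- function(axis, angle_deg) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("axis must be non-zero")
  u <- axis / n
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Uniformly random rotation matrix
#'
#' Drawn from the Haar measure on SO(3) via QR of a Gaussian matrix.
#' @export
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  d <- diag(qr.R(qr_))
  q <- q %*% diag(sign(d))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Angle of a rotation matrix, degrees
#' @param r 3x3 rotation matrix.
#' @export
rotation_angle <- function(r) {
  ct <- (sum(diag(r)) - 1) / 2
  acos(max(-1, min(1, ct))) * 180 / pi
}

#' Perturb a rigid transform with small random motion
#'
#' Adds an independent Gaussian offset per translation axis and a rotation of
#' angle `|N(0, sigma_rot)|` about a uniformly random axis through the child
#' frame origin (right-multiplied, i.e. expressed in the child frame).
#'
#' @param x a `rigid_transform`.
#' @param sigma_trans per-axis translation sigma, mm.
#' @param sigma_rot rotation-angle sigma, degrees.
#' @export
perturb_transform <- function(x, sigma_trans = 0, sigma_rot = 0) {
  stopifnot(sigma_trans >= 0, sigma_rot >= 0)
  dR <- diag(3)
  if (sigma_rot > 0) {
    ax <- stats::rnorm(3)
    while (sum(ax^2) < 1e-12) ax <- stats::rnorm(3)
    dR <- rotation_axis_angle(ax, abs(stats::rnorm(1, sd = sigma_rot)))
  }
  dt <- if (sigma_trans > 0) stats::rnorm(3, sd = sigma_trans) else c(0, 0, 0)
  delta <- rigid_transform(dR, dt, x$child, x$child)
  compose_transforms(x, delta)
}

#' Write / read a rigid transform as a JSON sidecar
#'
#' The matrix is stored 4x4 row-major in mm together with the frame names,
#' with stable key order so files are diffable.
#'
#' @param x a `rigid_transform`.
#' @param path file path.
#' @export
write_transform_json <- function(x, path) {
  stopifnot(inherits(x, "rigid_transform"))
  obj <- list(parent = x$parent, child = x$child,
              matrix_row_major = as.numeric(t(as.matrix(x))), units = "mm")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- matrix(as.numeric(obj$matrix_row_major), 4, 4, byrow = TRUE)
  rigid_transform(m[1:3, 1:3], m[1:3, 4], obj$parent, obj$child)
}

# Run code under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. seed = NULL runs in the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
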