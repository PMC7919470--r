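#' Cubic AR marker model
#'
#' The tracked reference is a cube (default 30 x 30 x 30 mm) carrying a
#' unique black-and-white pattern on each face so a camera can identify its
#' pose from any exposed side. The marker frame has its origin at the cube
#' centre; face 6 (-z) is the face mounted on the holder adaptor, so +z
#' points towards the exposed faces. Faces are numbered 1..6 with outward
#' normals +x, -x, +y, -y, +z, -z.
#'
#' @param edge edge length, mm (> 0).
#' @param pattern_seed integer seed for the deterministic face patterns.
#' @export
marker_model <- function(edge = 30, pattern_seed = 1L) {
  if (edge <= 0) stop("edge must be > 0")
  normals <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  rownames(normals) <- paste0("face", 1:6)
  structure(list(edge = edge, face_normals = normals,
                 pattern_seed = as.integer(pattern_seed)),
            class = "marker_model")
}

#' @export
print.marker_model <- function(x, ...) {
  cat(sprintf("<marker_model: %g mm cube, holder face 6 (-z)>\n", x$edge))
  invisible(x)
}

#' Corner coordinates of the marker cube
#' @param model a `marker_model`.
#' @return `fiducial_set` of the 8 corners (labels C1..C8) in the marker frame.
#' @export
cube_corners <- function(model) {
  stopifnot(inherits(model, "marker_model"))
  h <- model$edge / 2
  g <- as.matrix(expand.grid(x = c(-h, h), y = c(-h, h), z = c(-h, h)))
  fiducial_set(g, paste0("C", 1:8), frame = "marker")
}

#' Faces of the marker visible from a viewing direction
#'
#' A face is visible when its outward normal (in the observer frame) makes an
#' obtuse angle with the viewing direction. Physically occluded faces (e.g.
#' covered by tissue) can be excluded; for generic directions at most 3 faces
#' are visible, and occluding one still leaves the pose recoverable from the
#' rest.
#'
#' @param pose `rigid_transform` observer <- marker.
#' @param view_direction length-3 viewing direction in the observer frame
#'   (from camera towards the marker; non-zero).
#' @param occluded integer face ids to exclude.
#' @return integer vector of visible face ids.
#' @export
visible_faces <- function(pose, view_direction, occluded = integer(0)) {
  stopifnot(inherits(pose, "rigid_transform"))
  v <- as.numeric(view_direction)
  n <- sqrt(sum(v^2))
  if (n == 0) stop("view direction must be non-zero")
  v <- v / n
  model <- marker_model()
  world_n <- model$face_normals %*% t(pose$rotation)
  vis <- which(as.numeric(world_n %*% v) < 0)
  setdiff(vis, as.integer(occluded))
}

#' Simulated noisy marker pose observation
#'
#' Stand-in for a camera-SDK pose estimate: the true pose is perturbed by an
#' independent Gaussian offset per translation axis and a rotation of angle
#' `|N(0, sigma_rot)|` about a uniformly random axis through the cube centre.
#' Seeded and reproducible.
#'
#' @param true_pose `rigid_transform` camera <- marker.
#' @param sigma_trans translation noise per axis, mm (>= 0).
#' @param sigma_rot rotation-angle noise, degrees (>= 0).
#' @param seed optional integer seed (NULL uses the ambient RNG stream).
#' @return list with `pose` (perturbed `rigid_transform`), `noise`
#'   (the sigmas used) and `timestamp`.
#' @export
simulate_marker_observation <- function(true_pose, sigma_trans = 0.5,
                                        sigma_rot = 0.5, seed = NULL) {
  stopifnot(inherits(true_pose, "rigid_transform"))
  if (sigma_trans < 0 || sigma_rot < 0) stop("noise sigmas must be >= 0")
  pose <- with_seed(seed, perturb_transform(true_pose, sigma_trans, sigma_rot))
  list(pose = pose, noise = c(sigma_trans = sigma_trans, sigma_rot = sigma_rot),
       timestamp = as.numeric(Sys.time()))
}

#' Write / read a marker spec as JSON
#'
#' Stores edge length, holder face id and the pattern seed with stable key
#' order.
#' @param model a `marker_model`.
#' @param path file path.
#' @export
write_marker_json <- function(model, path) {
  stopifnot(inherits(model, "marker_model"))
  jsonlite::write_json(list(edge_mm = model$edge, holder_face = 6L,
                            pattern_seed = model$pattern_seed),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_marker_json
#' @export
read_marker_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  marker_model(edge = obj$edge_mm, pattern_seed = obj$pattern_seed)
}

#' Deterministic black-and-white face pattern
#'
#' Each face carries a unique binary pattern; these bit matrices exist for
#' documentation and printing, image-based detection is not modelled.
#'
#' @param model a `marker_model`.
#' @param face face id 1..6.
#' @param n pattern grid size.
#' @return n x n 0/1 matrix.
#' @export
marker_face_pattern <- function(model, face, n = 8) {
  stopifnot(inherits(model, "marker_model"), face %in% 1:6)
  with_seed(model$pattern_seed * 1000L + as.integer(face),
            matrix(stats::rbinom(n * n, 1, 0.5), n, n))
}
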