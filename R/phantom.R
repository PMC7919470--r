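#' Noise model for the virtual validation experiments
#'
#' All sources of error in the simulated protocol, in the units used
#' throughout (mm, degrees): independent per-axis Gaussian localization error
#' for pointer and fiducial touches (FLE), a seating perturbation applied to
#' the guide before it is re-fitted (imperfect manual placement), and the
#' marker pose noise of the camera tracking stand-in. Defaults are the
#' simulation's stated operating point: 0.5 mm / 0.5 degrees everywhere.
#'
#' @param fiducial_sigma per-axis fiducial localization sigma, mm.
#' @param pointer_sigma per-axis pointer localization sigma, mm.
#' @param seating_sigma_trans,seating_sigma_rot guide seating perturbation
#'   (mm, degrees) applied before ICP refinement.
#' @param marker_sigma_trans,marker_sigma_rot marker pose observation noise
#'   (mm, degrees).
#' @export
noise_model <- function(fiducial_sigma = 0.5, pointer_sigma = 0.5,
                        seating_sigma_trans = 0.5, seating_sigma_rot = 0.5,
                        marker_sigma_trans = 0.5, marker_sigma_rot = 0.5) {
  vals <- c(fiducial_sigma, pointer_sigma, seating_sigma_trans,
            seating_sigma_rot, marker_sigma_trans, marker_sigma_rot)
  if (any(vals < 0)) stop("noise sigmas must be >= 0")
  structure(list(fiducial_sigma = fiducial_sigma, pointer_sigma = pointer_sigma,
                 seating_sigma_trans = seating_sigma_trans,
                 seating_sigma_rot = seating_sigma_rot,
                 marker_sigma_trans = marker_sigma_trans,
                 marker_sigma_rot = marker_sigma_rot), class = "noise_model")
}

#' @rdname noise_model
#' @export
zero_noise <- function() noise_model(0, 0, 0, 0, 0, 0)

#' Specification of a synthetic validation phantom
#'
#' Describes one case: a bone primitive (an asymmetric tapered tube or a
#' bumpy ellipsoid), a tumor, supports and a stand base, overall bounding
#' dimensions, and the fiducial counts of the validation protocol (8 conical
#' holes on the phantom surface, 3 to 5 on the guide).
#'
#' @param case_id case name (e.g. "AR3DP0002").
#' @param dims length-3 overall dimensions, mm (all > 0).
#' @param bone_type "tube" or "ellipsoid".
#' @param n_fiducials surface fiducials on the phantom (default 8).
#' @param n_guide_fiducials conical holes on the guide (3 to 5).
#' @param seed integer seed making the phantom deterministic.
#' @export
phantom_spec <- function(case_id, dims, bone_type = c("tube", "ellipsoid"),
                         n_fiducials = 8L, n_guide_fiducials = 4L, seed = 1L) {
  bone_type <- match.arg(bone_type)
  dims <- as.numeric(dims)
  if (length(dims) != 3L || any(dims <= 0)) stop("impossible dimensions")
  if (any(dims < 40)) stop("impossible dimensions: phantom smaller than 40 mm")
  stopifnot(n_fiducials >= 3L, n_guide_fiducials >= 3L, n_guide_fiducials <= 5L)
  structure(list(case_id = as.character(case_id), dims = dims,
                 bone_type = bone_type, n_fiducials = as.integer(n_fiducials),
                 n_guide_fiducials = as.integer(n_guide_fiducials),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' The six validation cases
#'
#' Case ids, overall printed-phantom dimensions (mm) and bone primitive per
#' case, mirroring a six-case protocol spanning thorax, femur, hip and tibia
#' regions; guide fiducial counts vary from 3 to 5 with guide size.
#'
#' @param seeds integer seeds, one per case.
#' @return data.frame with one row per case.
#' @export
phantom_case_table <- function(seeds = 1:6) {
  data.frame(
    case_id = paste0("AR3DP000", 2:7),
    dx = c(170, 120, 220, 160, 170, 220),
    dy = c(150, 110, 220, 100, 150, 120),
    dz = c(130,  90, 190,  50, 100, 110),
    bone_type = c("ellipsoid", "tube", "ellipsoid", "tube", "tube", "tube"),
    n_guide_fiducials = c(5L, 3L, 5L, 3L, 4L, 4L),
    seed = as.integer(seeds),
    stringsAsFactors = FALSE)
}

#' @rdname phantom_case_table
#' @param row one row of the case table.
#' @export
spec_from_case_row <- function(row) {
  phantom_spec(row$case_id, c(row$dx, row$dy, row$dz), row$bone_type,
               n_guide_fiducials = row$n_guide_fiducials, seed = row$seed)
}

# orthonormal basis whose third column is the unit vector n
basis_from_normal <- function(n) {
  n <- n / sqrt(sum(n^2))
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  cbind(u, v, n)  # right-handed with det +1 (v = n x u, so u x v = n)
}

# greedy farthest-point subset: returns row indices into p
farthest_points <- function(p, k, start = 1L) {
  sel <- start
  d <- sqrt(rowSums(sweep(p, 2, p[start, ])^2))
  while (length(sel) < k) {
    nxt <- which.max(d)
    sel <- c(sel, nxt)
    d <- pmin(d, sqrt(rowSums(sweep(p, 2, p[nxt, ])^2)))
  }
  sel
}

#' Generate a synthetic validation phantom
#'
#' Builds the case geometry deterministically from its spec: an asymmetric
#' bone (tapered, bumped tube or bumpy ellipsoid), an adjacent tumor, a stand
#' base with two supports joining it to the bone, 8 conical surface fiducials
#' (4 mm diameter, 3 mm deep; opening centres snapped to the surface), and a
#' seated surgical guide with its own 3-5 conical fiducials and the AR-marker
#' holder. The guide is designed in the anatomy frame, so its true seating is
#' the identity transform. The assembly fits inside `spec$dims` and its
#' centre of mass projects inside the base footprint.
#'
#' @param spec a `phantom_spec`.
#' @return an object of class `phantom`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    d <- spec$dims
    base_h <- 8
    if (spec$bone_type == "tube") {
      L <- 0.8 * d[1]
      r0 <- 0.22 * min(d[2], d[3])
      zb <- base_h + 0.45 * (d[3] - base_h)   # bone axis height
      bump_th <- pi - 0.45; bump_z <- 0.15 * L  # bump faces up after rotation
      prof <- function(z, theta) {
        dth <- atan2(sin(theta - bump_th), cos(theta - bump_th))
        r0 * (1 + 0.22 * z / L) *
          (1 + 0.25 * exp(-(dth^2 / 0.5 + ((z - bump_z) / (0.12 * L))^2)))
      }
      tube <- mesh_tube(prof, length = L, segments = 44, rings = 36)
      rot <- rigid_transform(rotation_axis_angle(c(0, 1, 0), 90),
                             c(0, 0, zb), "anatomy", "anatomy")
      bone <- transform_mesh(rot, tube)
      bone$label <- "bone"
      tumor_c <- c(-0.18 * L, 0.6 * r0, zb + 0.9 * r0)
      tumor_ax <- c(0.16 * L, 1.1 * r0, 0.9 * r0)
    } else {
      ax <- c(0.38 * d[1], 0.33 * d[2], 0.40 * (d[3] - base_h) / 1)
      zb <- base_h + 1.05 * ax[3]
      bump_dir <- c(0.5, 0.6, 0.62)
      bump_dir <- bump_dir / sqrt(sum(bump_dir^2))
      radfun <- function(dirs) {
        base_r <- 1 / sqrt((dirs[, 1] / ax[1])^2 + (dirs[, 2] / ax[2])^2 +
                           (dirs[, 3] / ax[3])^2)
        ang <- acos(pmin(1, pmax(-1, dirs %*% bump_dir)))
        as.numeric(base_r * (1 + 0.12 * exp(-(ang / 0.45)^2)))
      }
      bone <- mesh_icosphere(radfun, subdiv = 4, center = c(0, 0, zb))
      bone$label <- "bone"
      tumor_c <- c(0.35 * ax[1], -0.3 * ax[2], zb + 0.45 * ax[3])
      tumor_ax <- 0.45 * ax
    }
    tumor <- mesh_icosphere(function(dirs) {
      r <- 1 / sqrt((dirs[, 1] / tumor_ax[1])^2 + (dirs[, 2] / tumor_ax[2])^2 +
                    (dirs[, 3] / tumor_ax[3])^2)
      as.numeric(r * (1 + 0.05 * sin(5 * dirs[, 1]) * cos(4 * dirs[, 2])))
    }, subdiv = 3, center = tumor_c)
    tumor$label <- "tumor"
    base <- mesh_box(c(0.85 * d[1], 0.85 * d[2], base_h),
                     center = c(0, 0, base_h / 2))
    sup <- lapply(c(-0.25, 0.25), function(fx) {
      m <- mesh_tube(4, length = zb - base_h + 6, segments = 12, rings = 1,
                     center = c(0, 0, 0))
      transform_mesh(rigid_transform(diag(3),
                                     c(fx * 0.5 * d[1], 0, base_h + (zb - base_h + 6) / 2 - 3),
                                     "anatomy", "anatomy"), m)
    })
    support_base <- merge_meshes(c(list(base), sup), label = "base")

    # 8 well-spread conical fiducials on the bone surface
    cand <- sample_surface_points(bone, 400)
    cand <- cand[cand[, 3] > base_h + 5, , drop = FALSE]
    fpts <- cand[farthest_points(cand, spec$n_fiducials), , drop = FALSE]
    snap <- mesh_closest_points(bone, fpts)
    fn <- mesh_face_normals(bone)$normals
    fids <- fiducial_set(snap$points, paste0("F", seq_len(spec$n_fiducials)),
                         "anatomy")
    fid_cones <- lapply(seq_len(spec$n_fiducials), function(i)
      list(point = snap$points[i, ], normal = fn[snap$face[i], ],
           diameter = 4, depth = 3))

    # guide on the asymmetric (bumped) side of the bone
    seed_pt <- if (spec$bone_type == "tube") {
      # tube axis was rotated onto x (x -> -z, z -> x), so the surface point
      # at axial coordinate t, angle th maps to (t, r sin th, zb - r cos th)
      rb <- prof(bump_z, bump_th)
      c(bump_z, rb * sin(bump_th), zb - rb * cos(bump_th))
    } else {
      bone_c <- c(0, 0, zb)
      bone_c + bump_dir * radfun(matrix(bump_dir, 1))
    }
    seed_pt <- mesh_closest_points(bone, seed_pt)$points[1, ]
    g_radius <- max(15, min(25, 0.12 * min(d)))
    patch <- select_contact_region(bone, seed_pt, g_radius)
    guide <- build_guide(patch, thickness = 3)

    # guide fiducials on the outer (offset) surface
    pn <- mesh_vertex_normals(patch)
    gidx <- farthest_points(patch$vertices, spec$n_guide_fiducials)
    gpts <- patch$vertices[gidx, , drop = FALSE] + 3 * pn[gidx, , drop = FALSE]
    guide$fiducial_cones <- lapply(seq_len(nrow(gpts)), function(i)
      list(point = gpts[i, ], normal = pn[gidx[i], ], diameter = 4, depth = 3))

    # two screw axes through the patch interior
    ctr <- colMeans(patch$vertices)
    nbar <- colMeans(pn); nbar <- nbar / sqrt(sum(nbar^2))
    guide$screw_axes <- lapply(c(0.4, -0.4), function(s) {
      pt <- ctr + s * (patch$vertices[gidx[1], ] - ctr)
      list(point = mesh_closest_points(bone, pt)$points[1, ] + 5 * nbar,
           direction = -nbar, diameter = 5)
    })

    # marker holder above the patch, marker +z pointing away from the bone
    hold_c <- ctr + (3 + 3 + 15 + 4) * nbar
    holder <- rigid_transform(basis_from_normal(nbar), hold_c, "guide", "marker")
    guide <- add_marker_holder(guide, holder)

    ph <- structure(list(spec = spec, bone = bone, tumor = tumor,
                         base = support_base, fiducials = fids,
                         fiducial_cones = fid_cones, guide = guide,
                         seating = transform_identity("anatomy", "guide")),
                    class = "phantom")
    # stability + size contracts
    stopifnot(phantom_stable(ph))
    bb <- phantom_bbox(ph)
    if (any(bb[2, ] - bb[1, ] > d + 1e-6))
      stop("generated phantom exceeds its specified dimensions")
    ph
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom %s: %s bone, %d+%d fiducials, dims %s mm>\n",
              x$spec$case_id, x$spec$bone_type, n_fiducials(x$fiducials),
              length(x$guide$fiducial_cones),
              paste(x$spec$dims, collapse = " x ")))
  invisible(x)
}

#' Bounding box of the printed phantom body
#'
#' Covers bone, tumor, supports and base -- the piece that is printed as one
#' phantom and whose overall dimensions are specified. The resin guide (with
#' its marker holder) is a separate print seated on the phantom and is not
#' part of the size contract.
#' @param phantom a `phantom`.
#' @export
phantom_bbox <- function(phantom) {
  v <- rbind(phantom$bone$vertices, phantom$tumor$vertices,
             phantom$base$vertices)
  rbind(min = apply(v, 2, min), max = apply(v, 2, max))
}

#' Does the phantom stand on its base?
#'
#' True when the volume-weighted centre of mass of the solids projects
#' vertically inside the base footprint.
#' @param phantom a `phantom`.
#' @export
phantom_stable <- function(phantom) {
  com_part <- function(m) {
    v <- m$vertices; f <- m$faces
    a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
    cc <- v[f[, 3], , drop = FALSE]
    w <- (a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
          a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
          a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
    list(vol = sum(w), mom = colSums(w * (a + b + cc) / 4))
  }
  parts <- lapply(list(phantom$bone, phantom$tumor, phantom$base), com_part)
  vol <- sum(vapply(parts, `[[`, 1, "vol"))
  com <- colSums(do.call(rbind, lapply(parts, `[[`, "mom"))) / vol
  bb <- mesh_bbox(phantom$base)
  com[1] >= bb[1, 1] && com[1] <= bb[2, 1] && com[2] >= bb[1, 2] && com[2] <= bb[2, 2]
}

# seat the guide: perturb the designed pose, then refine by ICP
seat_guide <- function(phantom, noise) {
  init <- perturb_transform(phantom$seating, noise$seating_sigma_trans,
                            noise$seating_sigma_rot)
  fit_guide(phantom$guide, phantom$bone, init)
}

#' One virtual guide-placement trial
#'
#' Reproduces the placement-error measurement: the guide is removed and
#' re-seated (perturbed pose refined by [fit_guide()]), its conical fiducials
#' are touched with a tracked pointer (per-axis Gaussian localization error),
#' the phantom is registered to its virtual model through the 8 surface
#' fiducials ([horn_register()]), and the per-fiducial Euclidean distance to
#' the designed positions is the Surgical Guide Placement Error.
#'
#' @param phantom a `phantom`.
#' @param noise a `noise_model`.
#' @param user,rep user id and repetition index labels.
#' @param seed optional integer seed.
#' @return data.frame with one row per guide fiducial (class `trial_result`).
#' @export
placement_trial <- function(phantom, noise = noise_model(), user = 1L,
                            rep = 1L, seed = NULL) {
  stopifnot(inherits(phantom, "phantom"), inherits(noise, "noise_model"))
  with_seed(seed, {
    fit <- seat_guide(phantom, noise)
    t_seat <- fit$transform
    gf <- guide_fiducials(phantom$guide, frame = "guide")
    p_design <- gf$points                         # designed (= anatomy) coords
    p_phys <- transform_points(t_seat, p_design)  # where the cones really are
    # a random tracker frame; it must cancel through the registration
    t_track <- rigid_transform(random_rotation(), stats::runif(3, -100, 100),
                               "tracker", "anatomy")
    y <- transform_points(t_track, p_phys) +
      matrix(stats::rnorm(length(p_phys), sd = noise$fiducial_sigma),
             ncol = 3)
    z <- transform_points(t_track, phantom$fiducials$points) +
      matrix(stats::rnorm(3 * n_fiducials(phantom$fiducials),
                          sd = noise$fiducial_sigma), ncol = 3)
    reg <- horn_register(fiducial_set(z, phantom$fiducials$labels, "tracker"),
                         phantom$fiducials)
    p_hat <- transform_points(reg$transform, y)
    err <- sqrt(rowSums((p_hat - p_design)^2))
    mc <- marker_centre(phantom, t_seat)
    res <- data.frame(case = phantom$spec$case_id, user = as.integer(user),
                      rep = as.integer(rep), kind = "placement",
                      target = gf$labels, error_mm = err,
                      distance_to_marker_mm =
                        sqrt(rowSums(sweep(p_design, 2, mc)^2)),
                      fit_converged = fit$converged,
                      stringsAsFactors = FALSE)
    class(res) <- c("trial_result", "data.frame")
    res
  })
}

# true marker centre in the anatomy frame for a given physical seating
marker_centre <- function(phantom, seating = phantom$seating) {
  marker_to_patient(phantom$guide$holder_pose, seating)$translation
}

#' One virtual AR tracking trial
#'
#' Reproduces the end-to-end tracking-error measurement: targets (default 14
#' virtual spheres) are sampled uniformly by area on the phantom surface;
#' their displayed positions are computed through the chain camera <-
#' observed marker pose <- designed holder/seating, while their true
#' positions follow the physical chain with the actually seated guide; the
#' pointer touch adds localization noise, and the per-target Euclidean
#' distance is the Augmented Reality Tracking Error.
#'
#' @inheritParams placement_trial
#' @param marker a `marker_model`.
#' @param n_targets number of augmented targets (>= 1).
#' @export
tracking_trial <- function(phantom, marker = marker_model(),
                           noise = noise_model(), n_targets = 14L,
                           user = 1L, rep = 1L, seed = NULL) {
  stopifnot(inherits(phantom, "phantom"), n_targets >= 1L)
  with_seed(seed, {
    fit <- seat_guide(phantom, noise)
    t_seat <- fit$transform
    surf <- merge_meshes(phantom$bone, phantom$tumor, label = "phantom")
    p <- sample_surface_points(surf, n_targets)
    t_anat_marker_true <- marker_to_patient(phantom$guide$holder_pose, t_seat)
    t_anat_marker_model <- marker_to_patient(phantom$guide$holder_pose,
                                             phantom$seating)
    t_cam <- rigid_transform(random_rotation(), stats::runif(3, -200, 200),
                             "camera", "anatomy")
    true_marker_cam <- compose_transforms(t_cam, t_anat_marker_true)
    obs <- simulate_marker_observation(true_marker_cam,
                                       noise$marker_sigma_trans,
                                       noise$marker_sigma_rot)
    t_cam_anat_est <- compose_transforms(obs$pose,
                                         invert_transform(t_anat_marker_model))
    displayed <- transform_points(t_cam_anat_est, p)
    truth <- transform_points(t_cam, p)
    recorded <- displayed +
      matrix(stats::rnorm(3 * n_targets, sd = noise$pointer_sigma), ncol = 3)
    err <- sqrt(rowSums((recorded - truth)^2))
    mc <- marker_centre(phantom, t_seat)
    res <- data.frame(case = phantom$spec$case_id, user = as.integer(user),
                      rep = as.integer(rep), kind = "tracking",
                      target = paste0("T", seq_len(n_targets)), error_mm = err,
                      distance_to_marker_mm = sqrt(rowSums(sweep(p, 2, mc)^2)),
                      fit_converged = fit$converged,
                      stringsAsFactors = FALSE)
    class(res) <- c("trial_result", "data.frame")
    res
  })
}

#' Run the full validation experiment
#'
#' Full factorial case x user x repetition trial set (default 2 users x 5
#' repetitions, the validation protocol), seeded and reproducible. Users are
#' independent RNG streams with identical noise parameters.
#'
#' @param phantoms list of `phantom` objects.
#' @param users,reps protocol counts (>= 1).
#' @param noise a `noise_model`.
#' @param seed master integer seed.
#' @param kinds trial kinds to run.
#' @param n_targets targets per tracking trial.
#' @param marker a `marker_model`.
#' @return data.frame of all per-target rows (class `trial_result`).
#' @export
run_experiment <- function(phantoms, users = 2L, reps = 5L,
                           noise = noise_model(), seed = 1L,
                           kinds = c("placement", "tracking"),
                           n_targets = 14L, marker = marker_model()) {
  stopifnot(users >= 1L, reps >= 1L)
  kinds <- match.arg(kinds, c("placement", "tracking"), several.ok = TRUE)
  out <- list(); k <- 0L
  for (ci in seq_along(phantoms)) for (u in seq_len(users)) for (r in seq_len(reps)) {
    for (kind in kinds) {
      k <- k + 1L
      ts <- (as.numeric(seed) * 131071 + k * 2654435) %% 2147483647
      out[[length(out) + 1L]] <-
        if (kind == "placement")
          placement_trial(phantoms[[ci]], noise, u, r, seed = ts)
        else
          tracking_trial(phantoms[[ci]], marker, noise, n_targets, u, r, seed = ts)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("trial_result", "data.frame")
  res
}
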