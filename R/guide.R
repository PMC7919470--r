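#' Patient-specific surgical guide model
#'
#' The guide is a negative extrusion of a bone contact patch: a watertight
#' body whose inner surface reproduces the bone curvature so the guide seats
#' in a unique position, plus attachment screw axes (default diameter 5 mm),
#' conical validation fiducials (default 4 mm diameter, 3 mm deep) and the
#' pose of the holder for the cubic AR marker (`holder_pose`,
#' guide <- marker).
#'
#' @param body watertight `surface_mesh`.
#' @param contact_patch open `surface_mesh` coinciding with the bone patch.
#' @param screw_axes list of `list(point, direction, diameter)` entries.
#' @param fiducial_cones list of `list(point, normal, diameter, depth)`
#'   entries; `point` is the cone opening centre on the surface and `normal`
#'   the outward surface normal there.
#' @param holder_pose `rigid_transform` guide <- marker, or NULL.
#' @export
guide_model <- function(body, contact_patch, screw_axes = list(),
                        fiducial_cones = list(), holder_pose = NULL) {
  stopifnot(inherits(body, "surface_mesh"), inherits(contact_patch, "surface_mesh"))
  if (!is.null(holder_pose)) stopifnot(inherits(holder_pose, "rigid_transform"))
  structure(list(body = body, contact_patch = contact_patch,
                 screw_axes = screw_axes, fiducial_cones = fiducial_cones,
                 holder_pose = holder_pose),
            class = "guide_model")
}

#' @export
print.guide_model <- function(x, ...) {
  cat(sprintf("<guide_model: body %d faces (%.0f mm^3), patch %d faces, %d screws, %d cones, holder %s>\n",
              nrow(x$body$faces), mesh_volume(x$body), nrow(x$contact_patch$faces),
              length(x$screw_axes), length(x$fiducial_cones),
              if (is.null(x$holder_pose)) "unset" else "set"))
  invisible(x)
}

#' Fiducial set of a guide's cone openings
#' @param guide a `guide_model`.
#' @param frame frame name (the guide is designed in the anatomy frame).
#' @export
guide_fiducials <- function(guide, frame = "guide") {
  stopifnot(length(guide$fiducial_cones) >= 1L)
  p <- t(vapply(guide$fiducial_cones, function(cn) as.numeric(cn$point), numeric(3)))
  fiducial_set(p, paste0("G", seq_len(nrow(p))), frame)
}

# mesh edge graph with opposite-vertex shortcut edges; geodesic distances from
# a source vertex. Shortcuts across each interior edge cut the systematic
# overestimate of graph geodesics roughly from ~5% to ~1-2%.
geodesic_distances <- function(mesh, from_vertex) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  ek <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  opp <- c(f[, 3], f[, 1], f[, 2])
  # shortcut: the two opposite vertices of the faces sharing an edge
  sh <- split(opp, ek)
  sh <- sh[lengths(sh) == 2L]
  shm <- if (length(sh)) matrix(unlist(sh), ncol = 2, byrow = TRUE) else
    matrix(0L, 0, 2)
  edges <- rbind(unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))), shm)
  w <- sqrt(rowSums((mesh$vertices[edges[, 1], , drop = FALSE] -
                     mesh$vertices[edges[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(g) < nrow(mesh$vertices))
    g <- igraph::add_vertices(g, nrow(mesh$vertices) - igraph::vcount(g))
  as.numeric(igraph::distances(g, v = from_vertex, weights = w))
}

#' Select the bone contact region for a guide
#'
#' Returns the connected open sub-mesh of all faces within geodesic distance
#' `radius` of the surface point nearest `seed`. Geodesic (not Euclidean)
#' distance is used so the patch cannot jump across thin gaps in the anatomy.
#'
#' @param bone closed `surface_mesh` of the bone.
#' @param seed approximate patch centre, mm; must lie within 2 mm of the
#'   bone surface.
#' @param radius geodesic patch radius, mm.
#' @return open `surface_mesh` patch (faces whose centroidal geodesic
#'   distance is within `radius`).
#' @export
select_contact_region <- function(bone, seed, radius) {
  stopifnot(inherits(bone, "surface_mesh"), radius > 0)
  cp <- mesh_closest_points(bone, seed)
  if (cp$distance[1] > 2)
    stop(sprintf("seed is %.1f mm from the bone surface (limit 2 mm)", cp$distance[1]))
  # nearest vertex of the owning face
  fv <- bone$faces[cp$face[1], ]
  dv <- rowSums(sweep(bone$vertices[fv, , drop = FALSE], 2, as.numeric(seed))^2)
  src <- fv[which.min(dv)]
  gd <- geodesic_distances(bone, src)
  fd <- (gd[bone$faces[, 1]] + gd[bone$faces[, 2]] + gd[bone$faces[, 3]]) / 3
  keep <- which(fd <= radius)
  if (!length(keep)) stop("empty patch; increase radius")
  # connected component of faces containing the seed face
  patch_faces <- bone$faces[keep, , drop = FALSE]
  fg <- igraph::graph_from_edgelist(
    rbind(patch_faces[, 1:2], patch_faces[, 2:3], patch_faces[, c(3, 1)]),
    directed = FALSE)
  comp <- igraph::components(fg)$membership
  seed_face_row <- match(cp$face[1], keep)
  target <- if (is.na(seed_face_row)) comp[src] else comp[patch_faces[seed_face_row, 1]]
  keep <- keep[comp[patch_faces[, 1]] == target]
  submesh(bone, keep)
}

#' Build a surgical guide body from a contact patch
#'
#' Offsets the patch outward along its vertex normals by `thickness` and
#' stitches the rim, producing a watertight slab whose inner surface is the
#' patch itself, i.e. the negative of the bone surface. If the offset
#' self-intersects (non-watertight or non-positive volume), the body is
#' rebuilt by voxel remeshing at 0.5 mm with a warning.
#'
#' @param patch open connected `surface_mesh` (from [select_contact_region()]),
#'   oriented with normals pointing away from the bone.
#' @param thickness guide thickness, mm (> 0).
#' @return a `guide_model` (holder and screws unset).
#' @export
build_guide <- function(patch, thickness = 3) {
  stopifnot(inherits(patch, "surface_mesh"))
  if (thickness <= 0) stop("thickness must be > 0")
  be <- boundary_edges(patch)
  if (!nrow(be)) stop("patch is closed; expected an open patch")
  n <- mesh_vertex_normals(patch)
  nv <- nrow(patch$vertices)
  outer_v <- patch$vertices + thickness * n
  v <- rbind(patch$vertices, outer_v)
  inner_f <- patch$faces[, c(1, 3, 2), drop = FALSE]        # flipped: faces bone
  outer_f <- patch$faces + nv
  wall_f <- rbind(cbind(be[, 1], be[, 2], be[, 2] + nv),
                  cbind(be[, 1], be[, 2] + nv, be[, 1] + nv))
  body <- surface_mesh(v, rbind(inner_f, outer_f, wall_f), label = "guide")
  if (!is_watertight(body) || mesh_volume(body) <= 0) {
    warning("offset body self-intersects; falling back to 0.5 mm voxel remesh")
    body <- extract_surface(voxelize_mesh(body, voxel = 0.5), label = "guide")
  }
  guide_model(body, patch)
}

# voxel boolean: subtract an implicit solid (function of voxel-centre coords
# returning logical) from a closed mesh, re-extracting the surface.
subtract_implicit <- function(mesh, inside_fn, voxel = 0.5) {
  mk <- voxelize_mesh(mesh, voxel = voxel)
  d <- dim(mk$voxels)
  ctr <- cbind(rep(seq_len(d[1]) - 1L, times = d[2] * d[3]),
               rep(rep(seq_len(d[2]) - 1L, each = d[1]), times = d[3]),
               rep(seq_len(d[3]) - 1L, each = d[1] * d[2]))
  ctr <- sweep(sweep(ctr, 2, mk$spacing, "*"), 2, mk$origin, "+")
  rm_ <- inside_fn(ctr)
  vox <- mk$voxels
  vox[rm_] <- 0L
  out <- label_mask(vox, mk$spacing, mk$origin, mesh$label)
  extract_surface(out, label = mesh$label)
}

#' Drill screw holes through a guide body
#'
#' Boolean-subtracts a cylinder per axis by voxel remeshing (0.5 mm voxels).
#' An axis that misses the body leaves the volume unchanged. The result is
#' watertight by construction.
#'
#' @param guide a `guide_model`.
#' @param axes list of `list(point, direction)` entries (mm, unit direction
#'   not required to be normalized).
#' @param diameter hole diameter, mm (5 mm attachment screws by default).
#' @param voxel voxel size for the boolean remesh, mm.
#' @export
add_screw_holes <- function(guide, axes, diameter = 5, voxel = 0.5) {
  stopifnot(inherits(guide, "guide_model"))
  if (!length(axes)) return(guide)
  r <- diameter / 2
  axes <- lapply(axes, function(a) {
    dirn <- as.numeric(a$direction); dirn <- dirn / sqrt(sum(dirn^2))
    list(point = as.numeric(a$point), direction = dirn, diameter = diameter)
  })
  inside <- function(p) {
    hit <- rep(FALSE, nrow(p))
    for (a in axes) {
      rel <- sweep(p, 2, a$point)
      tpar <- as.numeric(rel %*% a$direction)
      perp2 <- rowSums(rel^2) - tpar^2
      hit <- hit | (perp2 <= r^2)
    }
    hit
  }
  body <- subtract_implicit(guide$body, inside, voxel)
  guide$body <- body
  guide$screw_axes <- c(guide$screw_axes, axes)
  guide
}

#' Bounded cutting plane
#'
#' Osteotomy planes designed during planning: a point, a unit normal and the
#' half-extents of the bounded rectangle, plus a thin-slab mesh for display
#' and export alongside the other case models.
#'
#' @param point length-3 point on the plane, mm.
#' @param normal length-3 normal (normalized internally, must be non-zero).
#' @param extents length-2 rectangle half-extents, mm.
#' @export
cutting_plane <- function(point, normal, extents = c(30, 30)) {
  normal <- as.numeric(normal)
  n <- sqrt(sum(normal^2))
  if (n == 0) stop("normal must be non-zero")
  structure(list(point = as.numeric(point), normal = normal / n,
                 extents = as.numeric(extents)), class = "cutting_plane")
}

#' @rdname cutting_plane
#' @param plane a `cutting_plane`.
#' @param thickness display-slab thickness, mm.
#' @export
cutting_plane_mesh <- function(plane, thickness = 0.4) {
  stopifnot(inherits(plane, "cutting_plane"))
  b <- basis_from_normal(plane$normal)
  tr <- rigid_transform(b, plane$point, "anatomy", "plane")
  m <- mesh_box(c(2 * plane$extents, thickness))
  m <- transform_mesh(tr, m)
  m$label <- "cutting_plane"
  m
}

#' Socket mesh for the cubic AR marker
#'
#' A square pocket that receives the lower half of the marker cube, expressed
#' in the marker frame (origin at the cube centre, +z towards the exposed
#' faces). The cavity is the cube cross-section grown by `clearance` on every
#' side; walls are `wall` mm thick.
#'
#' @param edge marker edge length, mm.
#' @param clearance fit clearance, mm.
#' @param wall wall/floor thickness, mm.
#' @export
socket_mesh <- function(edge = 30, clearance = 0.2, wall = 3) {
  h <- edge / 2 + clearance          # cavity half-width
  H <- h + wall                      # outer half-width
  zf <- -edge / 2 - clearance        # cavity floor
  zb <- zf - wall                    # outer bottom
  sq <- function(s, z) cbind(c(-s, s, s, -s), c(-s, -s, s, s), z)
  v <- rbind(sq(H, zb),   # 1-4  outer bottom
             sq(H, 0),    # 5-8  outer top
             sq(h, 0),    # 9-12 inner top
             sq(h, zf))   # 13-16 cavity floor
  quad <- function(a, b, c, d) rbind(c(a, b, c), c(a, c, d))
  f <- rbind(quad(1, 4, 3, 2),                     # bottom (-z)
             quad(1, 2, 6, 5), quad(2, 3, 7, 6),   # outer walls
             quad(3, 4, 8, 7), quad(4, 1, 5, 8),
             quad(5, 6, 10, 9), quad(6, 7, 11, 10),  # top ring (+z)
             quad(7, 8, 12, 11), quad(8, 5, 9, 12),
             quad(9, 10, 14, 13), quad(10, 11, 15, 14),  # cavity walls
             quad(11, 12, 16, 15), quad(12, 9, 13, 16),
             quad(13, 14, 15, 16))                 # cavity floor (+z)
  surface_mesh(v, f, label = "holder")
}

#' Attach the AR-marker holder to a guide
#'
#' Adds the socket geometry at `pose` (guide <- marker) and stores the pose
#' exactly; a marker cube placed at `pose` clears the socket walls by the
#' given clearance. Errors if the socket would collide with the bone contact
#' patch.
#'
#' @param guide a `guide_model`.
#' @param pose `rigid_transform`, guide <- marker.
#' @param edge marker edge, mm.
#' @param clearance socket clearance, mm.
#' @param wall socket wall thickness, mm.
#' @export
add_marker_holder <- function(guide, pose, edge = 30, clearance = 0.2, wall = 3) {
  stopifnot(inherits(guide, "guide_model"), inherits(pose, "rigid_transform"))
  sock <- transform_mesh(pose, socket_mesh(edge, clearance, wall))
  if (any(points_in_mesh(sock, guide$contact_patch$vertices)))
    stop("holder placement error: socket collides with the bone contact patch")
  guide$body <- merge_meshes(guide$body, sock, label = guide$body$label)
  guide$holder_pose <- pose
  guide
}

# split edge (a, b) at its midpoint: each adjacent face (x, y, z) with the
# edge as consecutive pair (x, y) becomes (x, m, z) + (m, y, z), preserving
# orientation and watertightness
split_edge <- function(v, f, a, b) {
  m <- nrow(v) + 1L
  v <- rbind(v, (v[a, ] + v[b, ]) / 2)
  hit <- which((f[, 1] == a | f[, 2] == a | f[, 3] == a) &
               (f[, 1] == b | f[, 2] == b | f[, 3] == b))
  new_faces <- NULL
  for (i in hit) {
    r <- f[i, ]
    for (s in 1:3) {
      x <- r[s]; y <- r[s %% 3L + 1L]; z <- r[(s + 1L) %% 3L + 1L]
      if ((x == a && y == b) || (x == b && y == a)) {
        f[i, ] <- c(x, m, z)
        new_faces <- rbind(new_faces, c(m, y, z))
        break
      }
    }
  }
  list(v = v, f = rbind(f, new_faces), mid = m)
}

#' Carve conical fiducial depressions into a mesh
#'
#' Adds conical holes (default 4 mm diameter, 3 mm depth) used for
#' point-based registration and error measurement. Each depression is carved
#' by local mesh surgery: the closest face is split at the fiducial point,
#' nearby edges are refined, and vertices inside the cone footprint are
#' displaced inward onto the cone surface, so the apex sits exactly at
#' `point - depth * normal` and the mesh stays watertight.
#'
#' @param mesh closed `surface_mesh`.
#' @param points n x 3 matrix of cone opening centres; each must lie within
#'   0.5 mm of the surface (they are snapped onto it).
#' @param diameter cone opening diameter, mm.
#' @param depth cone depth, mm.
#' @return list with `mesh` (carved `surface_mesh`) and `cones` (list of
#'   `list(point, normal, diameter, depth)`).
#' @export
add_cone_fiducials <- function(mesh, points, diameter = 4, depth = 3) {
  stopifnot(inherits(mesh, "surface_mesh"))
  p <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  if (!nrow(p)) return(list(mesh = mesh, cones = list()))
  cp <- mesh_closest_points(mesh, p)
  off <- which(cp$distance > 0.5)
  if (length(off))
    stop("points off the surface (> 0.5 mm): rows ",
         paste(off, collapse = ", "))
  r <- diameter / 2
  v <- mesh$vertices; f <- mesh$faces
  cones <- vector("list", nrow(p))
  fn <- mesh_face_normals(mesh)$normals
  for (i in seq_len(nrow(p))) {
    centre <- cp$points[i, ]
    nrm <- fn[cp$face[i], ]
    # insert the centre vertex by splitting its containing face into three
    tmp <- surface_mesh(v, f)
    face_id <- mesh_closest_points(tmp, centre)$face[1]
    tri <- f[face_id, ]
    vc <- nrow(v) + 1L
    v <- rbind(v, centre)
    f <- rbind(f[-face_id, , drop = FALSE],
               c(tri[1], tri[2], vc), c(tri[2], tri[3], vc), c(tri[3], tri[1], vc))
    # refine edges crossing the footprint until the cone is resolved
    for (pass in 1:12) {
      el <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
      a <- v[el[, 1], , drop = FALSE]; b <- v[el[, 2], , drop = FALSE]
      ab <- b - a
      len2 <- rowSums(ab^2)
      tt <- pmin(1, pmax(0, rowSums(sweep(a, 2, centre, "-") * -ab) /
                              pmax(len2, 1e-300)))
      seg_d2 <- rowSums((a + tt * ab - rep(centre, each = nrow(a)))^2)
      long <- el[seg_d2 <= (1.6 * r)^2 & len2 > (r / 2)^2, , drop = FALSE]
      if (!nrow(long)) break
      long <- unique(cbind(pmin(long[, 1], long[, 2]), pmax(long[, 1], long[, 2])))
      for (q in seq_len(nrow(long))) {
        sp <- split_edge(v, f, long[q, 1], long[q, 2])
        v <- sp$v; f <- sp$f
      }
    }
    # displace vertices in the footprint onto the cone surface
    rel <- sweep(v, 2, centre)
    tpar <- as.numeric(rel %*% nrm)
    rho <- sqrt(pmax(rowSums(rel^2) - tpar^2, 0))
    infoot <- rho < r & abs(tpar) < depth
    dd <- depth * (1 - rho[infoot] / r)
    v[infoot, ] <- v[infoot, ] - outer(dd, nrm)
    cones[[i]] <- list(point = as.numeric(centre), normal = as.numeric(nrm),
                       diameter = diameter, depth = depth)
  }
  list(mesh = surface_mesh(v, f, mesh$label), cones = cones)
}

#' Extract the bone fragment under a guide patch
#'
#' The printable sub-solid of the bone within `margin` mm of the contact
#' patch, used to rehearse guide placement. Computed by voxelizing the bone
#' and keeping voxels near the patch.
#'
#' @param bone closed `surface_mesh`.
#' @param patch open `surface_mesh` on the bone surface.
#' @param margin dilation margin, mm (>= 0).
#' @param voxel voxel size, mm.
#' @return watertight `surface_mesh`.
#' @export
extract_bone_fragment <- function(bone, patch, margin, voxel = 1) {
  stopifnot(inherits(bone, "surface_mesh"), inherits(patch, "surface_mesh"),
            margin >= 0)
  mk <- voxelize_mesh(bone, voxel = voxel)
  bb <- mesh_bbox(bone)
  if (margin >= max(bb[2, ] - bb[1, ])) {
    if (!sum(mk$voxels)) stop("empty intersection of bone and patch region")
    return(extract_surface(mk, label = "fragment"))
  }
  eff <- max(margin, 2 * voxel)
  d <- dim(mk$voxels)
  idx <- which(mk$voxels == 1L, arr.ind = TRUE) - 1L
  ctr <- sweep(sweep(idx, 2, mk$spacing, "*"), 2, mk$origin, "+")
  pb <- mesh_bbox(patch)
  cand <- ctr[, 1] >= pb[1, 1] - eff & ctr[, 1] <= pb[2, 1] + eff &
          ctr[, 2] >= pb[1, 2] - eff & ctr[, 2] <= pb[2, 2] + eff &
          ctr[, 3] >= pb[1, 3] - eff & ctr[, 3] <= pb[2, 3] + eff
  keepmask <- array(0L, d)
  if (any(cand)) {
    dist <- mesh_closest_points(patch, ctr[cand, , drop = FALSE])$distance
    sel <- which(cand)[dist <= eff]
    keepmask[idx[sel, , drop = FALSE] + 1L] <- 1L
  }
  if (!sum(keepmask)) stop("empty intersection of bone and patch region")
  out <- keep_largest_components(label_mask(keepmask, mk$spacing, mk$origin), 1L)
  extract_surface(out, label = "fragment")
}

#' Seat a guide on a bone by trimmed point-to-plane ICP
#'
#' Refines an initial seating pose by iterative closest point between the
#' guide's contact-patch vertices and the bone surface, with point-to-plane
#' correspondences and the worst 10 percent of pairs trimmed each iteration.
#' Convergence is declared when the RMS contact distance changes by less
#' than 1e-4 mm.
#'
#' @param guide a `guide_model` (designed in the anatomy frame, so the
#'   designed seating is the identity).
#' @param bone closed `surface_mesh`.
#' @param init initial `rigid_transform` (anatomy <- guide).
#' @param max_iter iteration cap; if reached, the best pose so far is
#'   returned with `converged = FALSE`.
#' @param trim fraction of worst correspondences dropped.
#' @return list with `transform`, `rms` (mm, trimmed RMS contact distance),
#'   `converged`, `iterations`.
#' @export
fit_guide <- function(guide, bone, init = transform_identity("anatomy", "guide"),
                      max_iter = 60, trim = 0.1) {
  stopifnot(inherits(guide, "guide_model"), inherits(bone, "surface_mesh"),
            inherits(init, "rigid_transform"))
  P0 <- guide$contact_patch$vertices
  # restrict the bone to faces near the initial patch position
  p_init <- transform_points(init, P0)
  lo <- apply(p_init, 2, min) - 15; hi <- apply(p_init, 2, max) + 15
  fc <- (bone$vertices[bone$faces[, 1], ] + bone$vertices[bone$faces[, 2], ] +
         bone$vertices[bone$faces[, 3], ]) / 3
  nearf <- which(fc[, 1] >= lo[1] & fc[, 1] <= hi[1] &
                 fc[, 2] >= lo[2] & fc[, 2] <= hi[2] &
                 fc[, 3] >= lo[3] & fc[, 3] <= hi[3])
  sub <- if (length(nearf) >= 1L) submesh(bone, nearf) else bone
  subn <- mesh_face_normals(sub)$normals
  Tcur <- init
  rms_prev <- Inf; rms <- Inf; converged <- FALSE; it <- 0L
  n_keep <- max(6L, ceiling((1 - trim) * nrow(P0)))
  while (it < max_iter) {
    it <- it + 1L
    P <- transform_points(Tcur, P0)
    cp <- mesh_closest_points(sub, P)
    keep <- order(cp$distance)[seq_len(n_keep)]
    q <- cp$points[keep, , drop = FALSE]
    nn <- subn[cp$face[keep], , drop = FALSE]
    pk <- P[keep, , drop = FALSE]
    rms <- sqrt(mean(cp$distance[keep]^2))
    if (abs(rms_prev - rms) < 1e-4) { converged <- TRUE; break }
    rms_prev <- rms
    r <- rowSums((pk - q) * nn)
    A <- cbind(pk[, 2] * nn[, 3] - pk[, 3] * nn[, 2],
               pk[, 3] * nn[, 1] - pk[, 1] * nn[, 3],
               pk[, 1] * nn[, 2] - pk[, 2] * nn[, 1], nn)
    x <- tryCatch(solve(crossprod(A) + 1e-9 * diag(6), -crossprod(A, r)),
                  error = function(e) rep(0, 6))
    w <- x[1:3]; tt <- x[4:6]
    ang <- sqrt(sum(w^2))
    dR <- if (ang > 1e-14) rotation_axis_angle(w, ang * 180 / pi) else diag(3)
    delta <- rigid_transform(dR, tt, Tcur$parent, Tcur$parent)
    Tcur <- compose_transforms(delta, Tcur)
  }
  list(transform = Tcur, rms = rms, converged = converged, iterations = it)
}

#' Write / read a guide as STL plus JSON sidecar
#'
#' The body and the open contact patch are written as binary STL
#' (`<base>.stl`, `<base>_patch.stl`); screw axes, fiducial cones and the
#' holder pose (4x4 row-major, mm) go to `<base>.json` with stable key order.
#'
#' @param guide a `guide_model`.
#' @param base path prefix (no extension).
#' @export
write_guide <- function(guide, base) {
  write_stl(guide$body, paste0(base, ".stl"))
  write_stl(guide$contact_patch, paste0(base, "_patch.stl"))
  side <- list(
    screw_axes = lapply(guide$screw_axes, function(a)
      list(point = a$point, direction = a$direction, diameter = a$diameter)),
    fiducial_cones = lapply(guide$fiducial_cones, function(cn)
      list(point = cn$point, normal = cn$normal,
           diameter = cn$diameter, depth = cn$depth)),
    holder_pose = if (is.null(guide$holder_pose)) NULL else
      list(parent = guide$holder_pose$parent, child = guide$holder_pose$child,
           matrix_row_major = as.numeric(t(as.matrix(guide$holder_pose)))),
    units = "mm")
  jsonlite::write_json(side, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(base)
}

#' @rdname write_guide
#' @export
read_guide <- function(base) {
  body <- read_stl(paste0(base, ".stl"))
  body$label <- "guide"
  patch <- read_stl(paste0(base, "_patch.stl"))
  side <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE,
                              simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  hp <- NULL
  if (!is.null(side$holder_pose)) {
    m <- matrix(as.numeric(unlist(side$holder_pose$matrix_row_major)), 4, 4,
                byrow = TRUE)
    hp <- rigid_transform(m[1:3, 1:3], m[1:3, 4],
                          side$holder_pose$parent, side$holder_pose$child)
  }
  as_num <- function(x) as.numeric(unlist(x))
  guide_model(body, patch,
              screw_axes = lapply(side$screw_axes, function(a)
                list(point = as_num(a$point), direction = as_num(a$direction),
                     diameter = as.numeric(a$diameter))),
              fiducial_cones = lapply(side$fiducial_cones, function(cn)
                list(point = as_num(cn$point), normal = as_num(cn$normal),
                     diameter = as.numeric(cn$diameter),
                     depth = as.numeric(cn$depth))),
              holder_pose = hp)
}
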