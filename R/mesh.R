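#' Triangle surface mesh in mm
#'
#' Vertices are mm coordinates (RAS when anatomical); faces are 1-based vertex
#' index triples, counter-clockwise seen from outside. Bones, tumors, guides
#' and phantom parts all use this container.
#'
#' @param vertices n x 3 numeric matrix.
#' @param faces m x 3 integer matrix, 1-based.
#' @param label optional label string ("bone", "tumor", ...).
#' @export
surface_mesh <- function(vertices, faces, label = NULL) {
  v <- as.matrix(vertices); storage.mode(v) <- "double"
  f <- as.matrix(faces); storage.mode(f) <- "integer"
  stopifnot(ncol(v) == 3L, ncol(f) == 3L)
  if (nrow(f) && (min(f) < 1L || max(f) > nrow(v)))
    stop("face indices out of range")
  structure(list(vertices = v, faces = f, label = label), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  bb <- mesh_bbox(x)
  cat(sprintf("<surface_mesh%s: %d vertices, %d faces, bbox %s mm>\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              nrow(x$vertices), nrow(x$faces),
              paste(sprintf("%.1f", bb[2, ] - bb[1, ]), collapse = " x ")))
  invisible(x)
}

#' Axis-aligned bounding box of a mesh
#' @param mesh a `surface_mesh`.
#' @return 2 x 3 matrix, rows min and max, mm.
#' @export
mesh_bbox <- function(mesh) {
  rbind(min = apply(mesh$vertices, 2, min), max = apply(mesh$vertices, 2, max))
}

#' Per-face unit normals and face areas
#' @param mesh a `surface_mesh`.
#' @export
mesh_face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  a2 <- sqrt(rowSums(n^2))
  list(normals = n / pmax(a2, 1e-300), areas = a2 / 2)
}

#' Area-weighted vertex normals
#' @param mesh a `surface_mesh`.
#' @return n x 3 matrix of unit normals (degenerate vertices fall back to the
#'   1-ring average direction).
#' @export
mesh_vertex_normals <- function(mesh) {
  fn <- mesh_face_normals(mesh)
  w <- fn$normals * fn$areas
  n <- matrix(0, nrow(mesh$vertices), 3)
  for (c in 1:3) {
    idx <- mesh$faces[, c]
    for (d in 1:3) n[, d] <- n[, d] + unname(tapply_add(idx, w[, d], nrow(n)))
  }
  len <- sqrt(rowSums(n^2))
  n / pmax(len, 1e-300)
}

# sum `val` into bins `idx` of length n (fast base R accumulation)
tapply_add <- function(idx, val, n) {
  out <- numeric(n)
  s <- rowsum(val, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Enclosed volume of a closed mesh (divergence theorem)
#' @param mesh a watertight `surface_mesh` with outward orientation.
#' @return volume in mm^3 (signed; positive for outward orientation).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]; c <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
      a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Total surface area of a mesh
#' @param mesh a `surface_mesh`.
#' @export
mesh_area <- function(mesh) sum(mesh_face_normals(mesh)$areas)

# directed edge table: one row per half-edge (a, b)
half_edges <- function(mesh) {
  f <- mesh$faces
  cbind(a = c(f[, 1], f[, 2], f[, 3]), b = c(f[, 2], f[, 3], f[, 1]))
}

#' Is a mesh watertight?
#'
#' True when every undirected edge is shared by exactly two faces with
#' opposite orientation (a closed, consistently oriented 2-manifold; disjoint
#' unions of closed components count as watertight).
#' @param mesh a `surface_mesh`.
#' @export
is_watertight <- function(mesh) {
  if (!nrow(mesh$faces)) return(FALSE)
  he <- half_edges(mesh)
  key <- paste(he[, 1], he[, 2])
  rkey <- paste(he[, 2], he[, 1])
  if (anyDuplicated(key)) return(FALSE)
  all(key %in% rkey)
}

#' Boundary edges of an open mesh
#' @param mesh a `surface_mesh`.
#' @return k x 2 matrix of directed vertex index pairs lying on the boundary
#'   (edges with no opposite half-edge), or a 0-row matrix if closed.
#' @export
boundary_edges <- function(mesh) {
  he <- half_edges(mesh)
  key <- paste(he[, 1], he[, 2])
  rkey <- paste(he[, 2], he[, 1])
  he[!(key %in% rkey), , drop = FALSE]
}

#' Apply a rigid transform to a mesh
#' @param x a `rigid_transform`.
#' @param mesh a `surface_mesh`.
#' @export
transform_mesh <- function(x, mesh) {
  surface_mesh(transform_points(x, mesh$vertices), mesh$faces, mesh$label)
}

#' Concatenate meshes (disjoint union)
#' @param ... `surface_mesh` objects.
#' @param label optional label for the result.
#' @export
merge_meshes <- function(..., label = NULL) {
  ms <- list(...)
  if (length(ms) == 1L && is.list(ms[[1]]) && !inherits(ms[[1]], "surface_mesh"))
    ms <- ms[[1]]
  vs <- lapply(ms, `[[`, "vertices")
  off <- cumsum(c(0L, vapply(vs, nrow, 1L)))
  fs <- mapply(function(m, o) m$faces + o, ms, off[-length(off)], SIMPLIFY = FALSE)
  surface_mesh(do.call(rbind, vs), do.call(rbind, fs), label)
}

#' Sub-mesh from a face subset
#' @param mesh a `surface_mesh`.
#' @param face_idx integer vector of face rows to keep.
#' @export
submesh <- function(mesh, face_idx) {
  f <- mesh$faces[face_idx, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  surface_mesh(mesh$vertices[used, , drop = FALSE],
               matrix(remap[f], ncol = 3), mesh$label)
}

#' Closest surface points on a mesh
#' @param mesh a `surface_mesh`.
#' @param points query points, n x 3 mm.
#' @return list with `points` (closest surface points), `distance` (mm) and
#'   `face` (1-based owning face index).
#' @export
mesh_closest_points <- function(mesh, points) {
  p <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  r <- .closest_point_on_mesh(mesh$vertices, mesh$faces - 1L, p)
  r$face <- r$face + 1L
  r
}

#' Inside test for closed meshes (ray parity)
#'
#' Query points are nudged by a fixed sub-micron offset before the parity ray
#' cast so that queries lying exactly on axis-aligned faces or edges do not
#' hit degenerate configurations.
#' @param mesh a closed `surface_mesh`.
#' @param points n x 3 query points, mm.
#' @export
points_in_mesh <- function(mesh, points) {
  p <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  eps <- matrix(rep(c(1.13e-6, 2.41e-6, 3.71e-6), each = nrow(p)), ncol = 3)
  as.logical(.points_in_mesh(mesh$vertices, mesh$faces - 1L, p + eps))
}

#' Voxelize a closed mesh
#'
#' Ray-parity voxelization on a grid anchored at the bounding-box minimum plus
#' half a voxel (so solids aligned with their bounding box rasterize exactly).
#' @param mesh a closed `surface_mesh`.
#' @param voxel voxel edge length, mm.
#' @param pad extra voxels of padding around the bounding box.
#' @return a `label_mask` (see [label_mask()]).
#' @export
voxelize_mesh <- function(mesh, voxel = 0.5, pad = 2L) {
  bb <- mesh_bbox(mesh)
  origin <- bb[1, ] + voxel / 2 - pad * voxel + voxel * 1e-4 * c(0, 0.37, 0.61)
  dims <- pmax(1L, as.integer(ceiling((bb[2, ] - origin) / voxel)) + pad + 1L)
  occ <- .voxelize_mesh(mesh$vertices, mesh$faces - 1L, origin, rep(voxel, 3), dims)
  label_mask(array(as.integer(occ), dim = dims), spacing = rep(voxel, 3),
             origin = origin, label = mesh$label)
}

# --- primitives -----------------------------------------------------------

#' Axis-aligned box mesh
#' @param dims length-3 extents, mm.
#' @param center length-3 centre, mm.
#' @export
mesh_box <- function(dims, center = c(0, 0, 0)) {
  h <- dims / 2
  v <- as.matrix(expand.grid(x = c(-h[1], h[1]), y = c(-h[2], h[2]), z = c(-h[3], h[3])))
  v <- sweep(v, 2, center, "+")
  # vertex order from expand.grid: x fastest; faces chosen outward
  f <- rbind(c(1, 3, 4), c(1, 4, 2),   # z-
             c(5, 6, 8), c(5, 8, 7),   # z+
             c(1, 2, 6), c(1, 6, 5),   # y-
             c(3, 7, 8), c(3, 8, 4),   # y+
             c(1, 5, 7), c(1, 7, 3),   # x-
             c(2, 4, 8), c(2, 8, 6))   # x+
  m <- surface_mesh(v, f)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Icosphere mesh, optionally with direction-dependent radius
#'
#' Subdivided icosahedron. `radius` may be a scalar or a function of an n x 3
#' matrix of unit directions returning per-vertex radii, which yields smooth
#' star-shaped solids (ellipsoid-like bones, bumpy tumors).
#' @param radius scalar mm, or `function(dirs)` -> radii.
#' @param subdiv subdivision level (0 = icosahedron; each level quadruples faces).
#' @param center length-3 centre, mm.
#' @export
mesh_icosphere <- function(radius = 1, subdiv = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdiv)) {
    mid_cache <- new.env(hash = TRUE)
    vlist <- asplit(v, 1)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- mid_cache[[key]]
      if (!is.null(id)) return(id)
      m <- vlist[[a]] + vlist[[b]]
      m <- m / sqrt(sum(m^2))
      vlist[[length(vlist) + 1]] <<- m
      id <- length(vlist)
      mid_cache[[key]] <- id
      id
    }
    nf <- matrix(0L, nrow(f) * 4, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[(i - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                       c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, vlist)
    f <- nf
  }
  r <- if (is.function(radius)) radius(v) else rep(radius, nrow(v))
  surface_mesh(sweep(v * r, 2, center, "+"), f)
}

#' Closed tube / cylinder mesh with a radius profile
#'
#' Surface of revolution about the z axis with end caps. `radius` may be a
#' scalar, or a `function(z, theta)` returning the local radius, which gives
#' tapered and bumped shafts (long-bone stand-ins with an asymmetric surface).
#' @param radius scalar mm or `function(z, theta)`.
#' @param length axial length, mm (z in \[-length/2, length/2\] before centring).
#' @param segments angular segments.
#' @param rings axial rings.
#' @param center length-3 centre, mm.
#' @export
mesh_tube <- function(radius = 10, length = 100, segments = 48, rings = 30,
                      center = c(0, 0, 0)) {
  zs <- seq(-length / 2, length / 2, length.out = rings + 1)
  th <- seq(0, 2 * pi, length.out = segments + 1)[-(segments + 1)]
  rf <- if (is.function(radius)) radius else function(z, theta) rep(radius, length(z))
  grid <- expand.grid(theta = th, z = zs)
  r <- rf(grid$z, grid$theta)
  v <- cbind(r * cos(grid$theta), r * sin(grid$theta), grid$z)
  id <- function(i, j) (i - 1) * segments + ((j - 1) %% segments) + 1  # ring i, seg j
  f <- vector("list", rings)
  for (i in seq_len(rings)) {
    j <- seq_len(segments)
    f[[i]] <- rbind(cbind(id(i, j), id(i, j + 1), id(i + 1, j + 1)),
                    cbind(id(i, j), id(i + 1, j + 1), id(i + 1, j)))
  }
  f <- do.call(rbind, f)
  nb <- nrow(v)
  v <- rbind(v, c(0, 0, -length / 2), c(0, 0, length / 2))
  j <- seq_len(segments)
  f <- rbind(f,
             cbind(nb + 1, id(1, j + 1), id(1, j)),                 # bottom cap
             cbind(nb + 2, id(rings + 1, j), id(rings + 1, j + 1))) # top cap
  m <- surface_mesh(sweep(v, 2, center, "+"), f)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# --- STL / PLY IO ---------------------------------------------------------

weld_vertices <- function(tri_verts) {
  key <- apply(tri_verts, 1, function(r) paste(sprintf("%.9g", r), collapse = "_"))
  uk <- !duplicated(key)
  map <- match(key, key[uk])
  list(vertices = tri_verts[uk, , drop = FALSE],
       faces = matrix(map, ncol = 3, byrow = TRUE))
}

#' Read a surface mesh (STL binary/ASCII or PLY)
#'
#' Format is inferred from content for STL (binary vs ASCII) and from the
#' extension. Units are taken to be mm. STL triangle soups are welded into
#' indexed meshes on read.
#' @param path file path.
#' @param label optional label.
#' @export
read_mesh <- function(path, label = NULL) {
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext, stl = read_stl(path), ply = read_ply(path),
              stop("unsupported mesh format: .", ext))
  m$label <- label
  m
}

#' @rdname read_mesh
#' @export
read_stl <- function(path) {
  size <- file.info(path)$size
  if (is.na(size) || size < 15) stop("malformed STL (file too short): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 80)
  is_ascii <- grepl("^solid", rawToChar(head[1:5]))
  if (!is_ascii && size < 84) stop("malformed binary STL (truncated header, ",
                                   size, " bytes): ", path)
  if (!is_ascii) {
    nt <- readBin(con, "integer", 1, size = 4, endian = "little")
    need <- 84 + 50 * as.numeric(nt)
    if (nt < 0 || size < need)
      stop("malformed binary STL: header declares ", nt, " triangles (needs ",
           need, " bytes) but file has ", size, " bytes: ", path)
    tv <- matrix(0, nt * 3, 3)
    for (i in seq_len(nt)) {
      rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
      readBin(con, "raw", 2)
      tv[(i - 1) * 3 + 1:3, ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    if (!length(vl) || length(vl) %% 3 != 0)
      stop("malformed ASCII STL (vertex count ", length(vl),
           " not a multiple of 3): ", path)
    tv <- t(vapply(strsplit(trimws(vl), "\\s+"),
                   function(f) as.numeric(f[2:4]), numeric(3)))
    if (anyNA(tv)) stop("malformed ASCII STL (non-numeric vertex): ", path)
  }
  w <- weld_vertices(tv)
  surface_mesh(w$vertices, w$faces)
}

#' Write a surface mesh
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @param format `"stl-binary"`, `"stl-ascii"`, or `"ply"` (ASCII PLY); the
#'   default picks binary STL or PLY from the extension.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  if (is.null(format))
    format <- switch(tolower(tools::file_ext(path)), stl = "stl-binary", ply = "ply",
                     stop("cannot infer mesh format for ", path))
  switch(format,
         "stl-binary" = write_stl(mesh, path, ascii = FALSE),
         "stl-ascii" = write_stl(mesh, path, ascii = TRUE),
         "ply" = write_ply(mesh, path),
         stop("unknown mesh format: ", format))
  invisible(path)
}

#' @rdname write_mesh
#' @param ascii write ASCII STL instead of binary.
#' @export
write_stl <- function(mesh, path, ascii = FALSE) {
  v <- mesh$vertices; f <- mesh$faces
  fn <- mesh_face_normals(mesh)$normals
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid arguide", con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g", fn[i, 1], fn[i, 2], fn[i, 3]), con)
      writeLines("    outer loop", con)
      for (c in 1:3)
        writeLines(sprintf("      vertex %.9g %.9g %.9g",
                           v[f[i, c], 1], v[f[i, c], 2], v[f[i, c], 3]), con)
      writeLines(c("    endloop", "  endfacet"), con)
    }
    writeLines("endsolid arguide", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0, 80)), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(c(fn[i, ], t(v[f[i, ], ])), con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  }
  invisible(path)
}

#' @rdname read_mesh
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    ln <- readLines(con, 1)
    if (!length(ln)) stop("malformed PLY (no end_header): ", path)
    hdr <- c(hdr, ln)
    if (trimws(ln) == "end_header") break
  }
  fmt <- grep("^format", hdr, value = TRUE)[1]
  nv <- as.integer(sub(".*vertex\\s+", "", grep("^element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*face\\s+", "", grep("^element face", hdr, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("malformed PLY header: ", path)
  if (grepl("ascii", fmt)) {
    rest <- readLines(con, warn = FALSE)
    if (length(rest) < nv + nf) stop("malformed PLY (truncated body): ", path)
    v <- t(vapply(strsplit(trimws(rest[seq_len(nv)]), "\\s+"),
                  function(x) as.numeric(x[1:3]), numeric(3)))
    f <- t(vapply(strsplit(trimws(rest[nv + seq_len(nf)]), "\\s+"),
                  function(x) as.integer(x[2:4]), integer(3))) + 1L
  } else if (grepl("binary_little_endian", fmt)) {
    nprop <- sum(grepl("^property (float|double)", hdr))
    v <- matrix(0, nv, 3)
    for (i in seq_len(nv)) {
      rec <- readBin(con, "numeric", nprop, size = 4, endian = "little")
      if (length(rec) < nprop) stop("malformed PLY (truncated vertices): ", path)
      v[i, ] <- rec[1:3]
    }
    f <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- readBin(con, "integer", 1, size = 1, signed = FALSE)
      if (!length(cnt) || cnt != 3) stop("malformed PLY (non-triangular face): ", path)
      f[i, ] <- readBin(con, "integer", 3, size = 4, endian = "little") + 1L
    }
  } else stop("unsupported PLY format: ", fmt)
  surface_mesh(v, f)
}

#' @rdname write_mesh
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices; f <- mesh$faces
  writeLines(c("ply", "format ascii 1.0", "comment units mm",
               paste("element vertex", nrow(v)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

#' Sample points uniformly by area on a mesh surface
#' @param mesh a `surface_mesh`.
#' @param n number of points.
#' @return n x 3 matrix of surface points, mm.
#' @export
sample_surface_points <- function(mesh, n) {
  fn <- mesh_face_normals(mesh)
  fi <- sample.int(nrow(mesh$faces), n, replace = TRUE, prob = fn$areas)
  u <- stats::runif(n); v <- stats::runif(n)
  flip <- u + v > 1
  u[flip] <- 1 - u[flip]; v[flip] <- 1 - v[flip]
  a <- mesh$vertices[mesh$faces[fi, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[fi, 2], , drop = FALSE]
  c <- mesh$vertices[mesh$faces[fi, 3], , drop = FALSE]
  a + u * (b - a) + v * (c - a)
}
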