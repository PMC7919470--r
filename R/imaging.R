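#' Scalar volume image
#'
#' A 3D intensity grid with physical geometry: voxel (i, j, k) (0-based) is
#' centred at `origin + (i, j, k) * spacing`, axes fixed RAS, mm.
#'
#' @param voxels 3D numeric array.
#' @param spacing length-3 positive mm per axis.
#' @param origin length-3 mm.
#' @export
volume_image <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  stopifnot(length(dim(voxels)) == 3L, all(dim(voxels) >= 1L))
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  stopifnot(length(spacing) == 3L, all(spacing > 0), length(origin) == 3L)
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "volume_image")
}

#' Binary label mask
#'
#' Same geometry contract as [volume_image()]; voxels are 0/1 integers.
#' @inheritParams volume_image
#' @param label label name ("bone", "tumor", ...).
#' @export
label_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       label = NULL) {
  voxels <- as.array(voxels)
  stopifnot(length(dim(voxels)) == 3L)
  if (!all(voxels %in% c(0L, 1L, TRUE, FALSE)))
    stop("mask voxels must be binary (0/1)")
  storage.mode(voxels) <- "integer"
  obj <- volume_image(array(voxels, dim(voxels)), spacing, origin)
  obj$label <- label
  class(obj) <- c("label_mask", "volume_image")
  obj
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<%s%s: %s voxels, spacing %s mm, %d foreground>\n",
              class(x)[1],
              if (!is.null(x$label)) paste0(" '", x$label, "'") else "",
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              if (inherits(x, "label_mask")) sum(x$voxels) else NA_integer_))
  invisible(x)
}

#' Threshold a volume into a binary mask
#'
#' The first segmentation step for bone on CT: voxels with intensity in
#' `[low, high]` become foreground. Geometry is copied from the volume.
#'
#' @param volume a `volume_image`.
#' @param low,high inclusive intensity bounds; `low <= high`.
#' @param label label for the resulting mask.
#' @return a `label_mask`.
#' @export
threshold_mask <- function(volume, low, high = Inf, label = "bone") {
  stopifnot(inherits(volume, "volume_image"))
  if (low > high) stop("invalid range: low > high")
  m <- array(as.integer(volume$voxels >= low & volume$voxels <= high),
             dim(volume$voxels))
  label_mask(m, volume$spacing, volume$origin, label)
}

#' Keep the largest connected components of a mask
#'
#' The "islands" cleanup step: connected components (26-neighborhood) are
#' ranked by voxel count and only the `n_keep` largest survive, removing
#' disconnected structures such as the scanner bed.
#'
#' @param mask a `label_mask`.
#' @param n_keep number of components to keep (>= 1).
#' @return a `label_mask`.
#' @export
keep_largest_components <- function(mask, n_keep = 1L) {
  stopifnot(inherits(mask, "label_mask"), n_keep >= 1L)
  if (sum(mask$voxels) == 0L) {
    warning("keep_largest_components: mask is empty")
    return(mask)
  }
  lab <- .cc_label26(as.logical(mask$voxels), dim(mask$voxels))
  counts <- tabulate(lab)
  keep <- order(counts, decreasing = TRUE)[seq_len(min(n_keep, length(counts)))]
  out <- array(as.integer(lab %in% keep), dim(mask$voxels))
  label_mask(out, mask$spacing, mask$origin, mask$label)
}

#' Morphological hole filling (binary closing)
#'
#' Binary closing with a rectangular structuring element in voxel units,
#' default 7 x 7 x 3 (in-plane x in-plane x slice), the post-processing used
#' to close small interior cavities before printing. The grid is padded by
#' the kernel radius before closing so the operation is extensive
#' (output is a superset of the input) and idempotent.
#'
#' @param mask a `label_mask`.
#' @param kernel length-3 odd voxel dimensions of the structuring element.
#' @return a `label_mask`.
#' @export
fill_holes <- function(mask, kernel = c(7, 7, 3)) {
  stopifnot(inherits(mask, "label_mask"))
  kernel <- as.integer(kernel)
  if (length(kernel) != 3L || any(kernel < 1L) || any(kernel %% 2L == 0L))
    stop("kernel dimensions must be odd and >= 1")
  r <- (kernel - 1L) %/% 2L
  d <- dim(mask$voxels)
  pd <- d + 2L * r
  padded <- array(FALSE, pd)
  padded[r[1] + seq_len(d[1]), r[2] + seq_len(d[2]), r[3] + seq_len(d[3])] <-
    as.logical(mask$voxels)
  dil <- .box_filter(as.logical(padded), pd, kernel, TRUE)
  clo <- array(.box_filter(dil, pd, kernel, FALSE), pd)
  out <- clo[r[1] + seq_len(d[1]), r[2] + seq_len(d[2]), r[3] + seq_len(d[3])]
  label_mask(array(as.integer(out), d), mask$spacing, mask$origin, mask$label)
}

#' Extract the surface mesh of a binary mask
#'
#' Meshes the 0.5 iso-level of the mask under nearest-neighbour
#' interpolation: every voxel face between foreground and background becomes
#' two triangles, with vertices on the half-spacing lattice in physical mm
#' (spacing and origin applied). The result is always watertight and its
#' enclosed volume equals the voxel count times the voxel volume, which
#' converges to the true volume as spacing shrinks.
#'
#' @param mask a non-empty `label_mask`.
#' @param label optional label for the mesh (defaults to the mask label).
#' @return a watertight `surface_mesh`.
#' @export
extract_surface <- function(mask, label = NULL) {
  stopifnot(inherits(mask, "label_mask"))
  if (sum(mask$voxels) == 0L) stop("cannot extract a surface from an empty mask")
  r <- .mask_to_mesh(as.logical(mask$voxels), dim(mask$voxels),
                     mask$spacing, mask$origin)
  surface_mesh(r$vertices, r$faces + 1L,
               label = if (is.null(label)) mask$label else label)
}

# --- volume IO ------------------------------------------------------------

#' Read / write volumes (NRRD or NIfTI-1)
#'
#' Format chosen by extension: `.nrrd` uses the package's NRRD reader/writer
#' (raw or ascii encodings, little endian), `.nii` / `.nii.gz` go through
#' RNifti. Spacing and origin are honoured; NRRD `left-posterior-superior`
#' space is converted to RAS on read with a warning.
#'
#' @param path file path.
#' @return `read_volume`: a `volume_image` (or `label_mask` if binary and
#'   `as_mask = TRUE`).
#' @param as_mask coerce a binary volume to a `label_mask`.
#' @export
read_volume <- function(path, as_mask = FALSE) {
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  v <- switch(ext, nrrd = read_nrrd(path), nii = read_nifti_volume(path),
              stop("unsupported volume format: ", path))
  if (as_mask) v <- label_mask(v$voxels != 0, v$spacing, v$origin)
  v
}

#' @rdname read_volume
#' @param volume a `volume_image` or `label_mask`.
#' @export
write_volume <- function(volume, path) {
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  switch(ext, nrrd = write_nrrd(volume, path),
         nii = write_nifti_volume(volume, path),
         stop("unsupported volume format: ", path))
  invisible(path)
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, 1)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    ln <- readLines(con, 1)
    if (!length(ln) || ln == "") break
    if (startsWith(ln, "#")) next
    kv <- strsplit(ln, ":\\s*")[[1]]
    fields[[tolower(kv[1])]] <- paste(kv[-1], collapse = ": ")
  }
  dims <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(dims) != 3L) stop("only 3D NRRD volumes are supported: ", path)
  type <- fields[["type"]]
  enc <- tolower(fields[["encoding"]])
  spacing <- c(1, 1, 1); origin <- c(0, 0, 0); flip <- c(FALSE, FALSE, FALSE)
  if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    dirm <- t(vapply(vecs, function(s)
      as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]]), numeric(3)))
    spacing <- sqrt(rowSums(dirm^2))
    ax <- dirm / spacing
    if (max(abs(abs(ax) - diag(3))) > 1e-6)
      warning("oblique NRRD space directions; treating axes as axis-aligned")
    flip <- diag(ax) < 0
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  }
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "",
                                       fields[["space origin"]]), ",")[[1]])
  lps <- !is.null(fields[["space"]]) &&
    grepl("left-posterior-superior|^LPS$", fields[["space"]], ignore.case = TRUE)
  n <- prod(dims)
  what <- switch(type,
                 "float" = list("numeric", 4L), "double" = list("numeric", 8L),
                 "short" = list("integer", 2L), "int" = list("integer", 4L),
                 "uchar" = , "unsigned char" = list("integer", 1L),
                 stop("unsupported NRRD type: ", type))
  if (enc == "raw") {
    vals <- readBin(con, what[[1]], n, size = what[[2]], endian = "little",
                    signed = what[[2]] > 1)
    if (length(vals) < n) stop("truncated NRRD data block: ", path)
  } else if (enc %in% c("ascii", "text", "txt")) {
    vals <- scan(con, what = double(), n = n, quiet = TRUE)
    if (length(vals) < n) stop("truncated NRRD data block: ", path)
  } else stop("unsupported NRRD encoding: ", enc)
  vox <- array(as.numeric(vals), dims)
  if (lps) {
    warning("LPS-space NRRD converted to RAS on read: ", path)
    origin[1:2] <- -origin[1:2]
    flip[1:2] <- !flip[1:2]
  }
  for (axq in 1:3) if (flip[axq]) {
    idx <- rev(seq_len(dims[axq]))
    vox <- switch(axq, vox[idx, , , drop = FALSE], vox[, idx, , drop = FALSE],
                  vox[, , idx, drop = FALSE])
    origin[axq] <- origin[axq] - (dims[axq] - 1) * spacing[axq]
  }
  volume_image(vox, spacing, origin)
}

write_nrrd <- function(volume, path, encoding = c("raw", "ascii")) {
  stopifnot(inherits(volume, "volume_image"))
  encoding <- match.arg(encoding)
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(volume$voxels); sp <- volume$spacing; o <- volume$origin
  hdr <- c("NRRD0004",
           "# generated by arguide",
           "type: float", "dimension: 3",
           "space: right-anterior-superior",
           paste("sizes:", paste(d, collapse = " ")),
           sprintf("space directions: (%g,0,0) (0,%g,0) (0,0,%g)", sp[1], sp[2], sp[3]),
           "kinds: domain domain domain", "endian: little",
           paste("encoding:", encoding),
           sprintf("space origin: (%g,%g,%g)", o[1], o[2], o[3]), "")
  writeLines(hdr, con, sep = "\n")
  if (encoding == "raw")
    writeBin(as.numeric(volume$voxels), con, size = 4, endian = "little")
  else
    writeLines(paste(as.numeric(volume$voxels), collapse = " "), con)
  invisible(path)
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- attr(img, "pixdim")[1:3]
  xf <- RNifti::xform(img)
  origin <- xf[1:3, 4]
  ax <- xf[1:3, 1:3] / rep(sp, each = 3)
  if (max(abs(ax - diag(3))) > 1e-4)
    warning("non-RAS NIfTI orientation; voxel axes assumed RAS-aligned: ", path)
  volume_image(array(as.numeric(img), dim(img)[1:3]), sp, origin)
}

write_nifti_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume_image"))
  img <- RNifti::asNifti(array(as.numeric(volume$voxels), dim(volume$voxels)))
  RNifti::pixdim(img) <- volume$spacing
  m <- diag(4)
  diag(m)[1:3] <- volume$spacing
  m[1:3, 4] <- volume$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
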