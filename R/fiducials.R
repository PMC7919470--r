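#' Labelled fiducial point set
#'
#' A set of named 3D landmarks (mm, RAS) expressed in a named frame. Used for
#' the conical registration holes on phantoms and guides and for target
#' points. Pairing between two sets is always by label, never by proximity.
#'
#' @param points n x 3 numeric matrix, mm.
#' @param labels character vector of unique labels (default F1..Fn).
#' @param frame frame name.
#' @export
fiducial_set <- function(points, labels = NULL, frame = "anatomy") {
  p <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  stopifnot(ncol(p) == 3L, nrow(p) >= 1L)
  if (is.null(labels)) labels <- paste0("F", seq_len(nrow(p)))
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(p), !anyDuplicated(labels))
  dimnames(p) <- list(labels, c("x", "y", "z"))
  structure(list(points = p, labels = labels, frame = as.character(frame)),
            class = "fiducial_set")
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat(sprintf("<fiducial_set: %d points, frame '%s'>\n", nrow(x$points), x$frame))
  print(round(x$points, 3))
  invisible(x)
}

#' Number of fiducials
#' @param x a `fiducial_set`.
#' @export
n_fiducials <- function(x) nrow(x$points)

#' Apply a rigid transform to a fiducial set
#' @param x a `rigid_transform` whose child frame matches `fids$frame`.
#' @param fids a `fiducial_set`.
#' @export
transform_fiducials <- function(x, fids) {
  stopifnot(inherits(fids, "fiducial_set"))
  if (!identical(x$child, fids$frame))
    stop(sprintf("transform child frame '%s' does not match fiducial frame '%s'",
                 x$child, fids$frame))
  fiducial_set(transform_points(x, fids$points), fids$labels, x$parent)
}

#' Per-label Euclidean distances between two fiducial sets
#'
#' The target / fiducial error measure: for each label present in both sets,
#' the Euclidean distance (mm) between the estimated and true position.
#'
#' @param estimated,truth `fiducial_set` objects with identical label sets.
#' @return Named numeric vector of distances, mm, in `truth` label order.
#' @export
target_errors <- function(estimated, truth) {
  stopifnot(inherits(estimated, "fiducial_set"), inherits(truth, "fiducial_set"))
  if (!setequal(estimated$labels, truth$labels))
    stop("label mismatch between estimated and truth fiducial sets")
  e <- estimated$points[truth$labels, , drop = FALSE]
  d <- sqrt(rowSums((e - truth$points)^2))
  names(d) <- truth$labels
  d
}

#' Read / write 3D Slicer fiducial files (FCSV)
#'
#' The FCSV dialect: comment header lines starting with `#`, one of which may
#' declare `CoordinateSystem`. Files flagged LPS (or coordinate system `0`)
#' are converted to RAS on read (x and y negated) with a warning. Writing
#' always produces RAS mm.
#'
#' @param path file path.
#' @param frame frame name to attach to the returned set.
#' @return `read_fcsv`: a `fiducial_set`.
#' @export
read_fcsv <- function(path, frame = "anatomy") {
  lines <- readLines(path, warn = FALSE)
  header <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body)) stop("no fiducial rows in ", path)
  cs <- "RAS"
  cs_line <- grep("CoordinateSystem", header, value = TRUE)
  if (length(cs_line)) {
    val <- trimws(sub(".*=", "", cs_line[1]))
    if (val %in% c("LPS", "0")) cs <- "LPS"
  }
  fields <- strsplit(body, ",")
  xyz <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
  labels <- vapply(fields, function(f)
    if (length(f) >= 12 && nzchar(f[12])) f[12] else f[1], character(1))
  if (cs == "LPS") {
    warning("LPS-flagged fiducial file converted to RAS (x, y negated): ", path)
    xyz[, 1:2] <- -xyz[, 1:2]
  }
  fiducial_set(xyz, labels, frame)
}

#' @rdname read_fcsv
#' @param fids a `fiducial_set` to write.
#' @export
write_fcsv <- function(fids, path) {
  stopifnot(inherits(fids, "fiducial_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# Markups fiducial file version = 4.11",
               "# CoordinateSystem = RAS",
               "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID"),
             con)
  p <- fids$points
  for (i in seq_len(nrow(p)))
    writeLines(sprintf("vtkMRMLMarkupsFiducialNode_%d,%.17g,%.17g,%.17g,0,0,0,1,1,1,0,%s,,",
                       i, p[i, 1], p[i, 2], p[i, 3], fids$labels[i]), con)
  invisible(path)
}
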