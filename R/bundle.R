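#' Case bundle: the per-patient file-system case
#'
#' One directory per case holding everything the AR display needs: the
#' virtual models (bone, tumor, guide, fragment, cutting planes) with display
#' hints, the rigid transforms of the registration chain, and fiducial sets.
#' All coordinates are RAS mm.
#'
#' @param case_id case name (non-empty).
#' @param models named list of `surface_mesh` objects; names are roles
#'   ("bone", "tumor", "guide", ...).
#' @param transforms named list of `rigid_transform` objects.
#' @param fiducials named list of `fiducial_set` objects.
#' @param display optional named list of `list(color, transparency)` hints
#'   per model role.
#' @param provenance character vector of log lines.
#' @export
case_bundle <- function(case_id, models = list(), transforms = list(),
                        fiducials = list(), display = list(),
                        provenance = character()) {
  if (!nzchar(case_id)) stop("case id must be non-empty")
  structure(list(case_id = case_id, models = models, transforms = transforms,
                 fiducials = fiducials, display = display,
                 provenance = provenance),
            class = "case_bundle")
}

#' @export
print.case_bundle <- function(x, ...) {
  cat(sprintf("<case_bundle %s: %d models, %d transforms, %d fiducial sets>\n",
              x$case_id, length(x$models), length(x$transforms),
              length(x$fiducials)))
  invisible(x)
}

#' Build a case bundle from a phantom
#' @param phantom a `phantom`.
#' @export
bundle_from_phantom <- function(phantom) {
  stopifnot(inherits(phantom, "phantom"))
  case_bundle(
    phantom$spec$case_id,
    models = list(bone = phantom$bone, tumor = phantom$tumor,
                  base = phantom$base, guide = phantom$guide$body),
    transforms = list(holder_pose = phantom$guide$holder_pose,
                      seating = phantom$seating),
    fiducials = list(phantom = phantom$fiducials,
                     guide = guide_fiducials(phantom$guide, "anatomy")),
    display = list(bone = list(color = "white", transparency = 0.3),
                   tumor = list(color = "red", transparency = 0),
                   guide = list(color = "green", transparency = 0),
                   base = list(color = "grey", transparency = 0)),
    provenance = sprintf("generated by arguide %s, phantom seed %d",
                         as.character(utils::packageVersion("arguide")),
                         phantom$spec$seed))
}

#' Save a case bundle to a directory
#'
#' Layout: `manifest.json` + `models/<role>.stl` + `fiducials/<name>.fcsv` +
#' `transforms/<name>.json`. The manifest is written with stable key order so
#' saved bundles diff cleanly.
#'
#' @param bundle a `case_bundle`.
#' @param dir output directory (created if needed).
#' @export
save_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "case_bundle"))
  for (d in file.path(dir, c("", "models", "fiducials", "transforms")))
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(bundle$models))
    write_stl(bundle$models[[nm]], file.path(dir, "models", paste0(nm, ".stl")))
  for (nm in names(bundle$fiducials))
    write_fcsv(bundle$fiducials[[nm]],
               file.path(dir, "fiducials", paste0(nm, ".fcsv")))
  for (nm in names(bundle$transforms))
    write_transform_json(bundle$transforms[[nm]],
                         file.path(dir, "transforms", paste0(nm, ".json")))
  manifest <- list(
    case_id = bundle$case_id,
    models = lapply(names(bundle$models), function(nm)
      list(role = nm, file = file.path("models", paste0(nm, ".stl")),
           color = bundle$display[[nm]]$color %||% "white",
           transparency = bundle$display[[nm]]$transparency %||% 0)),
    fiducials = lapply(names(bundle$fiducials), function(nm)
      list(name = nm, file = file.path("fiducials", paste0(nm, ".fcsv")),
           frame = bundle$fiducials[[nm]]$frame)),
    transforms = lapply(names(bundle$transforms), function(nm)
      list(name = nm, file = file.path("transforms", paste0(nm, ".json")),
           parent = bundle$transforms[[nm]]$parent,
           child = bundle$transforms[[nm]]$child)),
    frames = sort(unique(c("anatomy",
                           unlist(lapply(bundle$transforms,
                                         function(t) c(t$parent, t$child))),
                           vapply(bundle$fiducials, `[[`, "", "frame")))),
    provenance = as.list(bundle$provenance))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a bundle directory
#'
#' Checks that the manifest exists, every referenced file is present, and
#' every transform's frames resolve against the declared frame list. All
#' problems are collected and returned (empty character vector when valid).
#'
#' @param dir bundle directory.
#' @export
validate_bundle <- function(dir) {
  problems <- character()
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) return(paste("missing manifest.json in", dir))
  man <- jsonlite::read_json(mf, simplifyVector = FALSE)
  if (is.null(man$case_id) || !nzchar(man$case_id))
    problems <- c(problems, "empty case id")
  for (m in man$models)
    if (!file.exists(file.path(dir, m$file)))
      problems <- c(problems, paste("missing model file:", m$file))
  for (fd in man$fiducials)
    if (!file.exists(file.path(dir, fd$file)))
      problems <- c(problems, paste("missing fiducial file:", fd$file))
  frames <- unlist(man$frames)
  for (tr in man$transforms) {
    if (!file.exists(file.path(dir, tr$file)))
      problems <- c(problems, paste("missing transform file:", tr$file))
    for (fr in c(tr$parent, tr$child))
      if (!fr %in% frames)
        problems <- c(problems, paste0("dangling frame '", fr,
                                       "' in transform ", tr$name))
  }
  problems
}

#' Load a case bundle from a directory
#'
#' Validates first; on any problem, stops with a report listing all of them.
#' @param dir bundle directory.
#' @return a `case_bundle`.
#' @export
load_bundle <- function(dir) {
  problems <- validate_bundle(dir)
  if (length(problems))
    stop("invalid bundle ", dir, ":\n  - ", paste(problems, collapse = "\n  - "))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = FALSE)
  models <- list(); display <- list()
  for (m in man$models) {
    models[[m$role]] <- read_mesh(file.path(dir, m$file), label = m$role)
    display[[m$role]] <- list(color = m$color, transparency = m$transparency)
  }
  fids <- list()
  for (fd in man$fiducials)
    fids[[fd$name]] <- read_fcsv(file.path(dir, fd$file), frame = fd$frame)
  trs <- list()
  for (tr in man$transforms)
    trs[[tr$name]] <- read_transform_json(file.path(dir, tr$file))
  case_bundle(man$case_id, models, trs, fids, display,
              provenance = unlist(man$provenance))
}
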