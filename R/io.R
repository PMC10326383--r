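# Delimited-text readers/writers and the JSON dataset manifest.
#
# Time series: TSV/CSV with rows = regions, first column the region label,
# remaining columns timepoints.  Matrices: headerless R x R CSV.  Manifest:
# JSON array of subject records with per-modality paths and a brain volume.

#' Read a regional time-series table
#'
#' @param path TSV or CSV file; rows = regions, first column region labels.
#' @param subject_id Subject id (defaults to the file name).
#' @return A [time_series_set()].
#' @export
read_timeseries <- function(path, subject_id = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = FALSE,
                          stringsAsFactors = FALSE)
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]+$", "", basename(path))
  regions <- as.character(df[[1]])
  series <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(series) <- "double"
  message("read_timeseries: ", path, " (", nrow(series), " regions x ",
          ncol(series), " timepoints)")
  time_series_set(subject_id, regions, series)
}

#' Read a headerless square connectivity matrix
#'
#' @param path CSV file with R rows of R comma-separated values.
#' @return Numeric matrix.
#' @export
read_matrix_csv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  message("read_matrix_csv: ", path, " (", nrow(m), " x ", ncol(m), ")")
  m
}

#' Write a matrix as headerless CSV
#'
#' @param m Numeric matrix.
#' @param path Output file.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a dataset manifest
#'
#' A manifest is a JSON array of records
#' `{subject_id, label, brain_volume, paths: {functional: ..., structural:
#' ..., timeseries: ...}}`; paths are resolved relative to the manifest.
#'
#' @param path Manifest JSON file.
#' @return List of manifest records.
#' @export
read_manifest <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  message("read_manifest: ", path, " (", length(recs), " subjects)")
  base <- dirname(path)
  lapply(recs, function(r) {
    r$paths <- lapply(r$paths, function(p)
      if (file.exists(p)) p else file.path(base, p))
    r
  })
}

#' Write a dataset manifest
#'
#' @param records List of manifest records (see [read_manifest()]).
#' @param path Output JSON file.
#' @export
write_manifest <- function(records, path) {
  jsonlite::write_json(records, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a dataset of multi-channel samples from a manifest
#'
#' Per subject: the functional channel comes from a precomputed matrix
#' (`paths$functional`) or from a time-series table (`paths$timeseries`)
#' via [pearson_connectivity()]; the structural channel from
#' `paths$structural` streamline counts normalized by `brain_volume`.
#'
#' @param manifest Path to a manifest JSON or the list from
#'   [read_manifest()].
#' @return List of `multimodal_sample` objects.
#' @export
load_dataset <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  lapply(manifest, function(r) {
    chans <- list()
    regions <- NULL
    if (!is.null(r$paths$timeseries)) {
      ts <- read_timeseries(r$paths$timeseries, r$subject_id)
      chans[[length(chans) + 1L]] <- pearson_connectivity(ts)
      regions <- ts$regions
    } else if (!is.null(r$paths$functional)) {
      m <- read_matrix_csv(r$paths$functional)
      # files may hold scaled/augmented derivatives, so only structural
      # integrity (squareness, symmetry) is enforced here
      chans[[length(chans) + 1L]] <-
        connectivity_matrix(r$subject_id, "functional", m,
                            validate = FALSE)
    }
    if (!is.null(r$paths$structural)) {
      m <- read_matrix_csv(r$paths$structural)
      if (is.null(r$brain_volume))
        stop("subject ", r$subject_id,
             ": structural path given without brain_volume")
      chans[[length(chans) + 1L]] <-
        normalize_structural(m, r$brain_volume, r$subject_id,
                             regions = if (!is.null(regions) &&
                                           length(regions) == nrow(m))
                               regions)
    }
    if (!length(chans)) stop("subject ", r$subject_id, ": no channels")
    stack_modalities(chans, r$label, subject_id = r$subject_id)
  })
}

#' Write samples and a manifest to a directory
#'
#' One CSV per subject and channel; provenance (shift index for augmented
#' variants) stays in the file and subject names.
#'
#' @param samples List of `multimodal_sample` objects.
#' @param dir Output directory (created if needed).
#' @return Path of the written manifest.
#' @export
write_dataset <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  recs <- lapply(samples, function(s) {
    paths <- list()
    for (ch in seq_along(s$modalities)) {
      fn <- sprintf("%s_%s.csv", s$subject_id, s$modalities[ch])
      write_matrix_csv(s$tensor[, , ch], file.path(dir, fn))
      nm <- s$modalities[ch]
      # keep channels distinct if a modality repeats
      while (!is.null(paths[[nm]])) nm <- paste0(nm, "x")
      paths[[nm]] <- fn
    }
    list(subject_id = s$subject_id, label = s$label, brain_volume = 1,
         paths = paths)
  })
  mp <- file.path(dir, "manifest.json")
  write_manifest(recs, mp)
  mp
}

#' Write the resolved run configuration sidecar
#'
#' Every run directory carries the fully resolved configuration (defaults
#' included) plus the seed, so the run can be replayed exactly.
#'
#' @param config Named list of resolved settings (must include `seed`).
#' @param path Output JSON file.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a resolved run configuration sidecar
#'
#' @param path JSON file written by [write_run_config()].
#' @return Named list.
#' @export
read_run_config <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
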