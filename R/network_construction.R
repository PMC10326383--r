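# Construction of per-subject connectivity matrices and multi-channel
# samples.  Functional networks are Pearson-correlation matrices of regional
# time series; structural networks are streamline-count matrices normalized
# by brain volume.  Modalities are stacked as channels of one sample.

#' Regional time-series container
#'
#' @param subject_id Subject identifier.
#' @param regions Character vector of unique region labels (length R).
#' @param series Numeric R x T matrix, one row per region, T >= 3 timepoints.
#' @return A `time_series_set` object.
#' @export
time_series_set <- function(subject_id, regions, series) {
  series <- as.matrix(series)
  if (length(regions) != nrow(series))
    stop("regions (", length(regions), ") and series rows (", nrow(series),
         ") disagree")
  if (nrow(series) < 2) stop("need at least 2 regions")
  if (ncol(series) < 3) stop("need at least 3 timepoints")
  if (anyNA(series)) stop("series contains missing values")
  if (anyDuplicated(regions)) stop("region labels must be unique")
  structure(list(subject_id = subject_id, regions = as.character(regions),
                 series = series),
            class = "time_series_set")
}

#' Single-modality connectivity matrix
#'
#' Validates the modality conventions: functional matrices have unit
#' diagonal and entries in `[-1, 1]`; structural matrices are non-negative
#' with zero diagonal (self-connections are undefined for tractography).
#'
#' @param subject_id Subject identifier.
#' @param modality `"functional"` or `"structural"`.
#' @param matrix Square symmetric numeric matrix.
#' @param regions Optional region labels (defaults to rownames or `V1..VR`).
#' @param sym_tol Symmetry tolerance.
#' @param validate Enforce the modality value conventions?  Set `FALSE`
#'   for derived matrices (e.g. min-max scaled) that are no longer raw
#'   correlations or counts; squareness and symmetry are always checked.
#' @return A `connectivity_matrix` object.
#' @export
connectivity_matrix <- function(subject_id, modality, matrix,
                                regions = NULL, sym_tol = 1e-8,
                                validate = TRUE) {
  modality <- match.arg(modality, c("functional", "structural"))
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  if (max(abs(m - t(m))) > sym_tol)
    stop("matrix is asymmetric beyond tolerance ", sym_tol)
  if (is.null(regions))
    regions <- if (!is.null(rownames(m))) rownames(m)
               else paste0("V", seq_len(nrow(m)))
  if (length(regions) != nrow(m)) stop("regions length must match matrix")
  if (!validate) {
    dimnames(m) <- list(regions, regions)
    return(structure(list(subject_id = subject_id, modality = modality,
                          matrix = m, regions = as.character(regions)),
                     class = "connectivity_matrix"))
  }
  if (modality == "functional") {
    if (any(m < -1 - 1e-12) || any(m > 1 + 1e-12))
      stop("functional connectivity entries must lie in [-1, 1]")
    if (max(abs(diag(m) - 1)) > 1e-12)
      stop("functional connectivity must have unit diagonal")
  } else {
    if (any(m < 0)) stop("structural connectivity must be non-negative")
  }
  dimnames(m) <- list(regions, regions)
  structure(list(subject_id = subject_id, modality = modality, matrix = m,
                 regions = as.character(regions)),
            class = "connectivity_matrix")
}

#' Functional connectivity by Pearson correlation
#'
#' Computes the R x R matrix of Pearson correlation coefficients
#' `r(X, Y) = sum((X - mean(X)) (Y - mean(Y))) / sqrt(sum((X - mean(X))^2)
#' sum((Y - mean(Y))^2))` between all pairs of regional time series.  The
#' normalization constant cancels, so population and sample conventions give
#' the same coefficient.  Results are clamped to `[-1, 1]` to absorb
#' rounding and the diagonal is exactly 1.
#'
#' @param ts A [time_series_set()].
#' @return A [connectivity_matrix()] with `modality = "functional"`.
#' @export
pearson_connectivity <- function(ts) {
  stopifnot(inherits(ts, "time_series_set"))
  v <- apply(ts$series, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance time series for region(s): ",
         paste(ts$regions[v == 0], collapse = ", "))
  r <- stats::cor(t(ts$series))
  r <- pmin(pmax(r, -1), 1)
  diag(r) <- 1
  connectivity_matrix(ts$subject_id, "functional", r, ts$regions)
}

#' Structural connectivity from streamline counts
#'
#' Normalizes a symmetric non-negative streamline-count matrix by the
#' subject's brain volume: `entry(i, j) = counts(i, j) / brain_volume`.
#' The diagonal is set to 0.
#'
#' @param streamline_counts Square symmetric non-negative matrix.
#' @param brain_volume Positive scalar (mm^3).
#' @param subject_id Subject identifier.
#' @param regions Optional region labels.
#' @param sym_tol Symmetry tolerance for the counts.
#' @return A [connectivity_matrix()] with `modality = "structural"`.
#' @export
normalize_structural <- function(streamline_counts, brain_volume,
                                 subject_id = "", regions = NULL,
                                 sym_tol = 1e-8) {
  m <- as.matrix(streamline_counts)
  if (nrow(m) != ncol(m)) stop("streamline_counts must be square")
  if (!is.numeric(brain_volume) || length(brain_volume) != 1 ||
      !is.finite(brain_volume) || brain_volume <= 0)
    stop("brain_volume must be a positive scalar")
  if (any(m < 0)) stop("streamline counts must be non-negative")
  if (max(abs(m - t(m))) > sym_tol)
    stop("streamline counts are asymmetric beyond tolerance ", sym_tol)
  out <- m / brain_volume
  diag(out) <- 0
  connectivity_matrix(subject_id, "structural", out, regions,
                      sym_tol = sym_tol)
}

#' Stack modalities into a multi-channel sample
#'
#' Superimposes the connectivity matrices of one subject as channels of a
#' single R x R x n tensor.  All channels must share the region ordering;
#' no re-sorting is attempted.
#'
#' @param mats List of [connectivity_matrix()] objects (>= 1), one per
#'   modality, identical region order.
#' @param label Binary class label: 1 = abnormal (AB), 0 = healthy control.
#' @param subject_id Optional; defaults to the first matrix's subject.
#' @return A `multimodal_sample` with fields `subject_id`, `label`,
#'   `modalities`, `regions` and `tensor` (R x R x n array).
#' @export
stack_modalities <- function(mats, label, subject_id = NULL) {
  if (length(mats) < 1) stop("need at least one matrix")
  if (!all(vapply(mats, inherits, logical(1), "connectivity_matrix")))
    stop("all elements must be connectivity_matrix objects")
  if (!label %in% c(0, 1)) stop("label must be 0 (HC) or 1 (AB)")
  ref <- mats[[1]]$regions
  for (k in seq_along(mats)) {
    rk <- mats[[k]]$regions
    if (length(rk) != length(ref))
      stop("channel ", k, " has ", length(rk), " regions; expected ",
           length(ref))
    mm <- which(rk != ref)
    if (length(mm))
      stop("channel ", k, " region order mismatch at position ", mm[1],
           ": '", rk[mm[1]], "' vs '", ref[mm[1]], "'")
  }
  R <- length(ref); n <- length(mats)
  tensor <- array(0, c(R, R, n))
  for (k in seq_len(n)) tensor[, , k] <- mats[[k]]$matrix
  if (is.null(subject_id)) subject_id <- mats[[1]]$subject_id
  structure(list(subject_id = subject_id, label = as.integer(label),
                 modalities = vapply(mats, function(m) m$modality,
                                     character(1)),
                 regions = ref, tensor = tensor),
            class = "multimodal_sample")
}

#' @export
print.multimodal_sample <- function(x, ...) {
  cat("multimodal_sample:", x$subject_id,
      sprintf("(%s)", if (x$label == 1) "AB" else "HC"), "\n")
  cat("  ", length(x$regions), "regions x", dim(x$tensor)[3], "channel(s):",
      paste(x$modalities, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("connectivity_matrix:", x$subject_id, "|", x$modality, "|",
      nrow(x$matrix), "x", ncol(x$matrix), "\n")
  invisible(x)
}
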