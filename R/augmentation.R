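# Symmetry-preserving cyclic augmentation and min-max scaling.
#
# One augmentation step moves the first column of a matrix to the last
# column, then the first row to the last row; because rows and columns are
# relabeled simultaneously the symmetry of a connectivity matrix is
# preserved.  Repeating the step on each newly produced matrix yields R - 1
# additional matrices per original (the full cyclic orbit minus the source).

#' One cyclic shift of a square matrix
#'
#' `output(i, j) = input((i mod R) + 1, (j mod R) + 1)`: the first column
#' becomes the last, then the first row becomes the last — a simultaneous
#' cyclic relabeling of rows and columns.
#'
#' @param m Square matrix.
#' @return The shifted matrix.
#' @export
cyclic_shift <- function(m) {
  m <- as.matrix(m)
  R <- nrow(m)
  if (R != ncol(m)) stop("cyclic_shift requires a square matrix")
  ord <- c(seq_len(R)[-1], 1L)
  m[ord, ord, drop = FALSE]
}

#' Full augmentation orbit of a sample
#'
#' Applies [cyclic_shift()] repeatedly and simultaneously to every channel
#' of a multi-channel sample, producing exactly `R - 1` derived samples
#' (shift indices `1 .. R-1`).  Each variant carries the source's subject id
#' and label.
#'
#' @param sample A `multimodal_sample` (see [stack_modalities()]).
#' @return An `augmentation_orbit`: list with `source`, `variants` (list of
#'   R - 1 samples) and `shifts` (number of shifts applied per variant).
#' @export
augment <- function(sample) {
  stopifnot(inherits(sample, "multimodal_sample"))
  R <- dim(sample$tensor)[1]
  n <- dim(sample$tensor)[3]
  variants <- vector("list", R - 1L)
  cur <- sample$tensor
  for (k in seq_len(R - 1L)) {
    nxt <- cur
    for (ch in seq_len(n)) nxt[, , ch] <- cyclic_shift(cur[, , ch])
    cur <- nxt
    v <- sample
    v$tensor <- cur
    v$regions <- sample$regions[c(seq_len(R)[-seq_len(k)], seq_len(k))]
    v$shift <- k
    variants[[k]] <- v
  }
  structure(list(source = sample, variants = variants,
                 shifts = seq_len(R - 1L)),
            class = "augmentation_orbit")
}

#' @export
print.augmentation_orbit <- function(x, ...) {
  cat("augmentation_orbit:", x$source$subject_id, "->",
      length(x$variants), "variants\n")
  invisible(x)
}

#' Augment a whole dataset
#'
#' @param samples List of `multimodal_sample`.
#' @param include_original Keep the source matrices in the output (flagged
#'   `is_original`)?
#' @return Flat list of samples; each carries `$shift` (0 for originals) and
#'   `$is_original`.
#' @export
augment_dataset <- function(samples, include_original = TRUE) {
  out <- list()
  for (s in samples) {
    if (include_original) {
      s0 <- s; s0$shift <- 0L; s0$is_original <- TRUE
      out[[length(out) + 1L]] <- s0
    }
    orb <- augment(s)
    for (v in orb$variants) {
      v$is_original <- FALSE
      v$subject_id <- paste0(v$subject_id, "+", v$shift)
      out[[length(out) + 1L]] <- v
    }
  }
  out
}

#' Min-max scale a matrix to [0, 1]
#'
#' `output = (m - min) / (max - min)`.  A constant matrix has no defined
#' scaling and raises an error.
#'
#' @param m Numeric matrix or array.
#' @return The scaled object with minimum 0 and maximum 1.
#' @export
minmax_scale <- function(m) {
  lo <- min(m); hi <- max(m)
  if (!is.finite(lo) || !is.finite(hi)) stop("non-finite entries")
  if (hi == lo) stop("constant matrix: min-max scaling undefined")
  (m - lo) / (hi - lo)
}

#' Min-max scale a sample per channel
#'
#' Applies [minmax_scale()] to each channel independently; channel
#' statistics never mix across channels or subjects.
#'
#' @param sample A `multimodal_sample`.
#' @return The sample with every channel scaled to `[0, 1]`.
#' @export
scale_sample <- function(sample) {
  stopifnot(inherits(sample, "multimodal_sample"))
  for (ch in seq_len(dim(sample$tensor)[3]))
    sample$tensor[, , ch] <- minmax_scale(sample$tensor[, , ch])
  sample
}

#' Train/test split of a sample list
#'
#' `matrix_level` splits over individual (possibly augmented) matrices, as
#' in an 80/20 pool over all enhanced matrices; `subject_level` keeps every
#' variant of a subject on one side of the split (no augmented copy of a
#' test subject can leak into training).  Train size is
#' `floor(fraction * total)`; the shuffle is seeded.
#'
#' @param samples List of `multimodal_sample`.
#' @param fraction Training fraction, strictly in (0, 1).
#' @param mode `"matrix_level"` or `"subject_level"`.
#' @param seed Integer seed for the shuffle.
#' @return List with elements `train` and `test`.
#' @export
split_dataset <- function(samples, fraction = 0.8,
                          mode = c("matrix_level", "subject_level"),
                          seed = 1) {
  mode <- match.arg(mode)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly in (0, 1)")
  N <- length(samples)
  base_id <- function(s) sub("\\+[0-9]+$", "", s$subject_id)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (mode == "matrix_level") {
    ntr <- floor(fraction * N)
    if (ntr < 1 || ntr >= N) stop("split leaves an empty side")
    ord <- sample.int(N)
    list(train = samples[sort(ord[seq_len(ntr)])],
         test = samples[sort(ord[-seq_len(ntr)])])
  } else {
    subj <- vapply(samples, base_id, character(1))
    us <- unique(subj)
    ntr <- floor(fraction * length(us))
    if (ntr < 1 || ntr >= length(us))
      stop("too few subjects (", length(us),
           ") for a subject-level split at fraction ", fraction)
    tr_subj <- us[sample.int(length(us))[seq_len(ntr)]]
    list(train = samples[subj %in% tr_subj],
         test = samples[!subj %in% tr_subj])
  }
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
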