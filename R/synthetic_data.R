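# Synthetic two-class connectome generator.
#
# Emulates a balanced case/control cohort of symmetric connectivity
# matrices: one shared base connectome per modality, a class effect added on
# a configurable subset of edges, and symmetric Gaussian edge noise.  The
# complementary-signal structure across modalities (independent effect-edge
# masks per channel) mirrors why stacking modalities helps.  A latent-factor
# time-series generator feeds the Pearson pipeline.

#' Specification of a synthetic two-class connectome dataset
#'
#' Defaults describe the desk-scale study conditions used throughout the
#' package: 40 regions, 40 + 40 subjects, two modalities, a standardized
#' mean difference of 2 on 10% of edges, edge noise SD 0.5.
#'
#' @param n_regions Number of regions R (>= 4).
#' @param n_per_class Subjects per class (AB and HC are balanced).
#' @param n_modalities Number of channels (functional, structural, ...).
#' @param effect_edges Fraction of the `choose(R, 2)` edges whose mean
#'   differs between classes, in `[0, 1]`.
#' @param effect_size Standardized mean difference (in units of `noise_sd`)
#'   on the affected edges; >= 0.
#' @param noise_sd Edge-noise standard deviation.
#' @param seed Integer seed; all randomness derives from it.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_regions = 40, n_per_class = 40,
                           n_modalities = 2, effect_edges = 0.1,
                           effect_size = 2, noise_sd = 0.5, seed = 1) {
  if (n_regions < 4) stop("need n_regions >= 4")
  if (effect_edges < 0 || effect_edges > 1)
    stop("effect_edges must lie in [0, 1]")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  n_edges <- choose(n_regions, 2)
  if (effect_size > 0 && round(effect_edges * n_edges) < 1)
    stop("effect_edges * choose(R, 2) < 1: no edge can carry the effect")
  structure(list(n_regions = as.integer(n_regions),
                 n_per_class = as.integer(n_per_class),
                 n_modalities = as.integer(n_modalities),
                 effect_edges = effect_edges, effect_size = effect_size,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

symmetrize_upper <- function(v, R) {
  m <- matrix(0, R, R)
  m[upper.tri(m)] <- v
  m + t(m)
}

#' Generate a labeled synthetic connectome dataset
#'
#' Per subject and channel: `matrix = clamp(base + effect * mask + noise)`,
#' symmetrized, with the modality's diagonal convention (functional: unit
#' diagonal, entries clamped to `[-1, 1]`; structural: zero diagonal,
#' non-negative).  The base connectome is drawn once per dataset, so
#' within-class variability comes only from the edge noise; effect-edge
#' masks are drawn independently per channel.
#'
#' @param spec A [synthetic_spec()].
#' @return List of `2 * n_per_class` `multimodal_sample` objects (AB first),
#'   with attribute `"masks"` (list of logical effect masks per channel).
#' @export
generate_connectomes <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  R <- spec$n_regions; nmod <- spec$n_modalities
  n_edges <- choose(R, 2)
  modal <- rep(c("functional", "structural"), length.out = nmod)
  base <- masks <- vector("list", nmod)
  for (ch in seq_len(nmod)) {
    base[[ch]] <- if (modal[ch] == "functional")
      symmetrize_upper(stats::runif(n_edges, -0.6, 0.6), R)
    else
      symmetrize_upper(stats::runif(n_edges, 0, 1), R)
    mv <- logical(n_edges)
    n_eff <- round(spec$effect_edges * n_edges)
    if (n_eff > 0) mv[sample.int(n_edges, n_eff)] <- TRUE
    masks[[ch]] <- mv
  }
  shift <- spec$effect_size * spec$noise_sd
  regions <- sprintf("R%03d", seq_len(R))
  make_subject <- function(id, label) {
    chans <- vector("list", nmod)
    for (ch in seq_len(nmod)) {
      noise <- stats::rnorm(n_edges, 0, spec$noise_sd)
      v <- base[[ch]][upper.tri(base[[ch]])] + noise +
        if (label == 1) shift * masks[[ch]] else 0
      m <- symmetrize_upper(v, R)
      if (modal[ch] == "functional") {
        m <- pmin(pmax(m, -1), 1); diag(m) <- 1
      } else {
        m <- pmax(m, 0); diag(m) <- 0
      }
      chans[[ch]] <- connectivity_matrix(id, modal[ch], m, regions)
    }
    stack_modalities(chans, label, subject_id = id)
  }
  samples <- vector("list", 2L * spec$n_per_class)
  for (i in seq_len(spec$n_per_class)) {
    samples[[i]] <- make_subject(sprintf("AB%03d", i), 1L)
    samples[[spec$n_per_class + i]] <- make_subject(sprintf("HC%03d", i), 0L)
  }
  attr(samples, "masks") <- masks
  samples
}

#' Generate regional time series from a latent-factor model
#'
#' `series = L f + noise_sd * e`, where the loading matrix `L` encodes a
#' target correlation structure `cov2cor(L L' + noise_sd^2 I)` that differs
#' between classes on the effect edges.  The realized (positive-definite)
#' class targets are returned as an attribute for Monte-Carlo checks.
#'
#' @param spec A [synthetic_spec()].
#' @param n_timepoints Number of timepoints T.
#' @param n_factors Number of latent factors (default `max(2, round(R/5))`).
#' @return List of `2 * n_per_class` [time_series_set()] objects with
#'   attribute `"target"` = list(`hc`, `ab`) correlation matrices.
#' @export
generate_timeseries <- function(spec, n_timepoints = 200,
                                n_factors = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed + 1L)
  R <- spec$n_regions; TT <- as.integer(n_timepoints)
  if (is.null(n_factors)) n_factors <- max(2L, round(R / 5))
  q <- as.integer(n_factors)
  L0 <- matrix(stats::rnorm(R * q, 0, 0.7), R, q)
  S0 <- tcrossprod(L0) + spec$noise_sd^2 * diag(R)
  if (any(diag(S0) <= 0)) stop("degenerate covariance: zero-variance region")
  C0 <- stats::cov2cor(S0)
  n_edges <- choose(R, 2)
  mask <- logical(n_edges)
  n_eff <- round(spec$effect_edges * n_edges)
  if (n_eff > 0) mask[sample.int(n_edges, n_eff)] <- TRUE
  # class AB target: push affected correlations toward 0 by a fraction
  # proportional to the effect size, then restore positive definiteness
  C1 <- C0
  up <- upper.tri(C1)
  shrink <- min(0.9, 0.25 * spec$effect_size)
  C1[up][mask] <- C1[up][mask] * (1 - shrink)
  C1[lower.tri(C1)] <- t(C1)[lower.tri(C1)]
  fix_pd <- function(C) {
    e <- eigen(C, symmetric = TRUE)
    lam <- pmax(e$values, 1e-6)
    stats::cov2cor(e$vectors %*% (lam * t(e$vectors)))
  }
  if (shrink > 0 && n_eff > 0) C1 <- fix_pd(C1)
  targets <- list(hc = C0, ab = C1)
  # symmetric PSD square root (tolerates the singular zero-noise case)
  sqrt_of <- function(C) {
    e <- eigen(C, symmetric = TRUE)
    e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  }
  Ls <- list(hc = sqrt_of(C0), ab = sqrt_of(C1))
  regions <- sprintf("R%03d", seq_len(R))
  make_ts <- function(id, cls) {
    Z <- matrix(stats::rnorm(R * TT), R, TT)
    series <- Ls[[cls]] %*% Z
    time_series_set(id, regions, series)
  }
  out <- vector("list", 2L * spec$n_per_class)
  for (i in seq_len(spec$n_per_class)) {
    out[[i]] <- make_ts(sprintf("AB%03d", i), "ab")
    out[[spec$n_per_class + i]] <- make_ts(sprintf("HC%03d", i), "hc")
  }
  attr(out, "target") <- targets
  out
}
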