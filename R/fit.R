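# User-facing fitting interface in the classic R modelling idiom: one
# fitting function returning a classed object with print / summary /
# predict / plot / simulate methods.

#' Fit a loop-learning GAN classifier to connectivity samples
#'
#' Runs the full pipeline: (optional) per-channel min-max scaling,
#' conditional WGAN-GP pretraining ([pretrain_gan()]), then the
#' multiple-loop-learning algorithm ([run_multiloop()]) that trains the
#' convolutional classifier incrementally on critic-ranked batches.
#'
#' @param samples List of `multimodal_sample` objects (see
#'   [stack_modalities()] or [generate_connectomes()]).
#' @param val_samples Optional validation samples driving convergence; by
#'   default a fraction of `samples` is held aside.
#' @param gan A [gan_config()].
#' @param loop A [loop_config()].
#' @param scale Min-max scale every channel of every sample first?
#' @param seed Master seed; fanned out to the GAN, the loop draws and the
#'   split so components are independently reproducible.
#' @param verbose Print progress?
#' @return A `loopgan` object with components `gan`, `fit`
#'   (the `multiloop_fit`), `history`, and the resolved configs.
#' @seealso [predict.loopgan()], [simulate.loopgan()], [plot.loopgan()]
#' @examples
#' spec <- synthetic_spec(n_regions = 24, n_per_class = 10, seed = 7)
#' samples <- generate_connectomes(spec)
#' fit <- loopgan(samples,
#'                gan = gan_config(steps = 3, critic_steps = 1,
#'                                 batch_size = 4, width = 0.25,
#'                                 d_norm = "none"),
#'                loop = loop_config(batch_per_class = 4, max_loops = 2,
#'                                   classifier_epochs = 2),
#'                seed = 1)
#' print(fit)
#' head(predict(fit, samples[1:3]))
#' @export
loopgan <- function(samples, val_samples = NULL, gan = gan_config(),
                    loop = loop_config(), scale = TRUE, seed = 1,
                    verbose = FALSE) {
  cl <- match.call()
  seed <- as.integer(seed)
  gan$seed <- seed * 101L + 1L
  loop$seed <- seed * 101L + 2L
  if (scale) {
    samples <- lapply(samples, scale_sample)
    if (!is.null(val_samples)) val_samples <- lapply(val_samples,
                                                     scale_sample)
  }
  g <- pretrain_gan(samples, gan, verbose = verbose)
  fit <- run_multiloop(samples, g, loop, val_samples = val_samples,
                       verbose = verbose)
  structure(list(gan = g, fit = fit, history = fit$history,
                 gan_config = gan, loop_config = loop, scale = scale,
                 seed = seed, n_modalities = g$n_modalities,
                 image_size = g$image_size, call = cl),
            class = "loopgan")
}

#' @export
print.loopgan <- function(x, ...) {
  cat("Loop-learning GAN classifier\n")
  cat("  input:", x$image_size, "x", x$image_size, "x", x$n_modalities,
      "connectivity samples\n")
  cat("  GAN pretraining:", x$gan_config$steps, "generator steps",
      sprintf("(lambda_gp = %g)", x$gan_config$lambda_gp), "\n")
  cat("  loops:", nrow(x$history),
      if (x$fit$converged) "(converged)" else "(max_loops reached)", "\n")
  cat("  best validation accuracy:", round(x$fit$best_acc, 4), "\n")
  invisible(x)
}

#' @export
summary.loopgan <- function(object, ...) {
  structure(list(history = object$history,
                 converged = object$fit$converged,
                 best_acc = object$fit$best_acc,
                 gan_log = object$gan$log,
                 image_size = object$image_size,
                 n_modalities = object$n_modalities),
            class = "summary.loopgan")
}

#' @export
print.summary.loopgan <- function(x, ...) {
  cat("Loop-learning GAN classifier --", x$image_size, "x", x$image_size,
      "x", x$n_modalities, "\n\nPer-loop validation metrics:\n")
  print(x$history, row.names = FALSE)
  cat("\nConverged:", x$converged,
      " best accuracy:", round(x$best_acc, 4), "\n")
  invisible(x)
}

#' Predict class membership for new connectivity samples
#'
#' @param object A fitted [loopgan()] model.
#' @param newdata List of `multimodal_sample` objects.
#' @param type `"prob"` (AB probability), `"class"` (0/1), or `"score"`
#'   (raw logit).
#' @param ... Unused.
#' @return Numeric (or integer for `"class"`) vector, one value per sample,
#'   named by subject id.
#' @export
predict.loopgan <- function(object, newdata,
                            type = c("prob", "class", "score"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "multimodal_sample")) newdata <- list(newdata)
  if (object$scale) newdata <- lapply(newdata, scale_sample)
  X <- stack_batch(lapply(newdata, function(s) s$tensor))
  z <- clf_logits(object$fit$classifier, X)
  names(z) <- vapply(newdata, function(s) s$subject_id, character(1))
  switch(type,
         score = z,
         prob = stats::plogis(z),
         class = {
           out <- as.integer(z > 0); names(out) <- names(z); out
         })
}

#' Plot the per-loop validation accuracy
#'
#' @param x A fitted [loopgan()] model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.loopgan <- function(x, ...) {
  h <- x$history
  graphics::plot(h$loop, h$acc, type = "b", pch = 16,
                 xlab = "Loop", ylab = "Validation accuracy",
                 ylim = c(0, 1), ...)
  graphics::abline(h = 0.5, lty = 3, col = "grey50")
  invisible(x)
}

#' Simulate connectivity samples from the fitted generator
#'
#' Draws `nsim` class-conditioned samples per class from the trained
#' generator.
#'
#' @param object A fitted [loopgan()] model.
#' @param nsim Samples per class.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return List of `multimodal_sample` objects (generated, labels attached).
#' @export
simulate.loopgan <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  labels <- rep(c(1L, 0L), each = nsim)
  fakes <- generate_fakes(object$gan, labels)
  out <- vector("list", length(labels))
  R <- dim(fakes)[1]
  regions <- sprintf("R%03d", seq_len(R))
  for (i in seq_along(labels)) {
    out[[i]] <- structure(
      list(subject_id = sprintf("sim_%s%03d",
                                if (labels[i] == 1) "AB" else "HC",
                                ((i - 1) %% nsim) + 1),
           label = labels[i],
           modalities = rep("functional", dim(fakes)[3]),
           regions = regions,
           tensor = fakes[, , , i, drop = TRUE]),
      class = "multimodal_sample")
    if (length(dim(out[[i]]$tensor)) == 2)
      dim(out[[i]]$tensor) <- c(R, R, 1L)
  }
  out
}

#' Evaluate a fitted model on a test set
#'
#' @param object A fitted [loopgan()] model.
#' @param test_samples List of `multimodal_sample` objects.
#' @return List: `counts` ([confusion_counts()]), `metrics`
#'   (`ACC`, `SEN`, `SPE`), `auc`, `roc` (a [roc_curve()]), `n`.
#' @export
evaluate_model <- function(object, test_samples) {
  stopifnot(inherits(object, "loopgan"))
  y <- vapply(test_samples, function(s) s$label, integer(1))
  sc <- predict(object, test_samples, type = "score")
  pred <- as.integer(sc > 0)
  cc <- confusion_counts(y, pred)
  roc <- roc_curve(sc, y)
  list(counts = cc, metrics = acc_sen_spe(cc), auc = roc_auc(roc),
       roc = roc, n = length(y))
}
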