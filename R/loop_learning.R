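# Multiple-loop-learning: incremental classifier training driven by
# critic-space sample contribution ranking.
#
# Each loop: a class-balanced batch is assembled (carryover from the
# previous loop topped up by a seeded random draw from the database);
# class-conditioned fakes are generated; every real sample is scored by the
# Euclidean distance between its critic patch map and the centroid of the
# fake patch maps of its class; per class, the top-ranked (closest, i.e.
# easiest-to-learn) half trains the classifier, ranks 1/2..3/4 carry over
# to the next loop, and the bottom quarter returns to the database.  The
# loop stops when validation accuracy stops improving.

#' Configuration of the multiple-loop-learning algorithm
#'
#' @param batch_per_class Samples per class per loop (>= 4 so that ranked
#'   quarters are non-empty).
#' @param classifier_epochs Classifier training epochs per loop.
#' @param patience Loops without improvement before stopping.
#' @param max_loops Hard cap on the number of loops.
#' @param tol Minimum validation-accuracy improvement that counts.
#' @param lr Classifier Adam learning rate.
#' @param refresh_gan Fine-tune generator and critic each loop? (Default
#'   keeps them frozen after pretraining.)
#' @param refresh_steps Generator steps per loop when `refresh_gan`.
#' @param easy_first Rank direction: `TRUE` selects samples closest to the
#'   generator's learned distribution ("easier-to-learn"); `FALSE` inverts
#'   the direction for ablation.
#' @param val_fraction Held-aside validation fraction when no validation set
#'   is supplied.
#' @param seed Integer seed for batch draws and classifier training.
#' @return A `loop_config` list.
#' @export
loop_config <- function(batch_per_class = 8, classifier_epochs = 10,
                        patience = 3, max_loops = 10, tol = 1e-3,
                        lr = 1e-3, refresh_gan = FALSE, refresh_steps = 5,
                        easy_first = TRUE, val_fraction = 0.2, seed = 1) {
  if (batch_per_class < 4) stop("batch_per_class must be >= 4")
  if (patience < 1) stop("patience must be >= 1")
  structure(list(batch_per_class = as.integer(batch_per_class),
                 classifier_epochs = as.integer(classifier_epochs),
                 patience = as.integer(patience),
                 max_loops = as.integer(max_loops), tol = tol, lr = lr,
                 refresh_gan = refresh_gan,
                 refresh_steps = as.integer(refresh_steps),
                 easy_first = easy_first, val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "loop_config")
}

#' Sample contribution ranking
#'
#' Scores every real sample by the Euclidean distance between its flattened
#' critic patch map and the centroid of the fake patch maps of its class,
#' and ranks ascending within class (rank 1 = closest to the learned
#' distribution).  Ties are broken by sample id, so the order is stable.
#'
#' @param critic Runnable critic network.
#' @param reals List of `multimodal_sample` (the current loop's batch).
#' @param fakes `R x R x n x B` array of generated samples.
#' @param fake_labels 0/1 condition labels of the fakes.
#' @param conditional Append the condition channel before critic passes?
#' @return A `ranking_table` data frame: `sample_id`, `label`, `score`,
#'   `rank` (within class), sorted by class then rank.
#' @export
contribution_ranking <- function(critic, reals, fakes, fake_labels,
                                 conditional = TRUE) {
  stopifnot(length(reals) >= 1, dim(fakes)[4] == length(fake_labels))
  rl <- vapply(reals, function(s) s$label, integer(1))
  ids <- vapply(reals, function(s) s$subject_id, character(1))
  X <- stack_batch(lapply(reals, function(s) s$tensor))
  maps_of <- function(x, lb) {
    xin <- if (conditional) condition_inputs(x, lb, "discriminator") else x
    out <- nn_forward(critic, xin, train = FALSE)$out
    d <- dim(out); dim(out) <- c(prod(d[1:3]), d[4])
    out
  }
  real_maps <- maps_of(X, rl)
  fake_maps <- maps_of(fakes, fake_labels)
  rows <- list()
  for (cls in sort(unique(rl))) {
    fsel <- fake_labels == cls
    if (!any(fsel))
      stop("no fake samples for class ", cls, "; cannot rank it")
    centroid <- rowMeans(fake_maps[, fsel, drop = FALSE])
    rsel <- which(rl == cls)
    sc <- sqrt(colSums((real_maps[, rsel, drop = FALSE] - centroid)^2))
    ord <- order(sc, ids[rsel])
    rows[[length(rows) + 1L]] <-
      data.frame(sample_id = ids[rsel][ord], label = cls,
                 score = sc[ord], rank = seq_along(ord),
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("ranking_table", "data.frame"))
}

#' Partition a ranking table into train / carryover / returned pools
#'
#' Per class independently (so the training set stays class-balanced):
#' ranks `1..ceiling(m/2)` train the classifier, ranks
#' `ceiling(m/2)+1 .. ceiling(3m/4)` carry over to the next loop, and the
#' remainder returns to the database.
#'
#' @param table A [contribution_ranking()] result.
#' @return List of character vectors `train`, `carryover`, `returned`.
#' @export
partition_ranked <- function(table) {
  stopifnot(inherits(table, "ranking_table") || is.data.frame(table))
  out <- list(train = character(), carryover = character(),
              returned = character())
  for (cls in sort(unique(table$label))) {
    tc <- table[table$label == cls, ]
    tc <- tc[order(tc$rank), ]
    m <- nrow(tc)
    if (m < 4) stop("class ", cls, " has only ", m,
                    " ranked samples; need >= 4")
    htop <- ceiling(m / 2); q3 <- ceiling(3 * m / 4)
    out$train <- c(out$train, tc$sample_id[seq_len(htop)])
    out$carryover <- c(out$carryover,
                       if (q3 > htop) tc$sample_id[(htop + 1):q3]
                       else character())
    out$returned <- c(out$returned,
                      if (m > q3) tc$sample_id[(q3 + 1):m] else character())
  }
  out
}

#' Initialize loop-learning pool bookkeeping
#'
#' @param sample_ids Ids of all training samples (start in the database).
#' @return A `loop_state` with disjoint `database`, `carryover`, `selected`
#'   pools and an empty history.
#' @export
loop_state <- function(sample_ids) {
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  structure(list(loop_index = 0L, database = as.character(sample_ids),
                 carryover = character(), selected = character(),
                 history = NULL),
            class = "loop_state")
}

#' Assemble one loop's class-balanced batch
#'
#' Moves the carryover into the selected pool and tops it up to
#' `batch_per_class` per class with a uniform random draw from the
#' database (drawn samples leave the database).
#'
#' @param state A [loop_state()].
#' @param labels Named 0/1 vector giving each sample id's class.
#' @param config A [loop_config()].
#' @return The updated state (`selected` holds the new batch).
#' @export
assemble_loop_batch <- function(state, labels, config) {
  stopifnot(inherits(state, "loop_state"))
  if (length(state$selected))
    stop("selected pool not empty; finish the previous loop first")
  sel <- state$carryover
  for (cls in c(0L, 1L)) {
    have <- sum(labels[sel] == cls)
    need <- config$batch_per_class - have
    if (need < 0)
      stop("carryover exceeds batch_per_class for class ", cls)
    pool <- state$database[labels[state$database] == cls]
    if (length(pool) < need)
      stop("insufficient database samples for class ", cls, " (need ",
           need, ", have ", length(pool),
           "); use a smaller batch_per_class")
    draw <- if (need > 0) pool[sample.int(length(pool), need)]
            else character()
    sel <- c(sel, draw)
    state$database <- setdiff(state$database, draw)
  }
  state$carryover <- character()
  state$selected <- sel
  state$loop_index <- state$loop_index + 1L
  state
}

#' Run the multiple-loop-learning algorithm
#'
#' Per loop: assemble a balanced batch, generate class-conditioned fakes,
#' rank the batch by critic-space distance, train the classifier on the
#' top-ranked half per class, log validation accuracy, and recycle pools
#' (trained-on and bottom-quarter samples return to the database; ranks
#' 1/2..3/4 carry over).  Stops when validation accuracy has not improved
#' by more than `tol` for `patience` consecutive loops, or at `max_loops`
#' (then the best checkpoint is returned with `converged = FALSE` and a
#' warning flag, not an error).
#'
#' @param samples Training samples (list of `multimodal_sample`, unique
#'   ids, both classes present).
#' @param gan A pre-trained `loopgan_gan` (see [pretrain_gan()]).
#' @param config A [loop_config()].
#' @param val_samples Optional validation samples; when `NULL` a
#'   `val_fraction` matrix-level split is carved out of `samples`.
#' @param classifier Optional runnable classifier network to continue
#'   training; by default one is built to match the data geometry.
#' @param verbose Print one line per loop?
#' @return A `multiloop_fit`: `classifier` (best checkpoint), `history`
#'   data frame (`loop`, `n_selected`, `acc`, `sen`, `spe`), `converged`,
#'   `ledger` (one row per sample-pool assignment per loop), `state`,
#'   `config`.
#' @export
run_multiloop <- function(samples, gan, config = loop_config(),
                          val_samples = NULL, classifier = NULL,
                          verbose = FALSE) {
  stopifnot(inherits(gan, "loopgan_gan"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  if (is.null(val_samples)) {
    sp <- split_dataset(samples, 1 - config$val_fraction, "matrix_level",
                        seed = config$seed)
    val_samples <- sp$test; samples <- sp$train
  }
  ids <- vapply(samples, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids)) stop("sample ids must be unique")
  names(samples) <- ids
  labels <- vapply(samples, function(s) s$label, integer(1))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  R <- gan$image_size; n <- gan$n_modalities
  if (is.null(classifier)) {
    cspec <- build_classifier(n, image_size = R, width = gan$config$width,
                              normalization = "none")
    classifier <- nn_build(cspec)
  }
  c_state <- adam_state()
  Xval <- stack_batch(lapply(val_samples, function(s) s$tensor))
  yval <- vapply(val_samples, function(s) s$label, integer(1))
  state <- loop_state(ids)
  history <- data.frame(loop = integer(), n_selected = integer(),
                        acc = numeric(), sen = numeric(), spe = numeric())
  ledger <- list()
  best_acc <- -Inf; best_net <- classifier; stall <- 0L; converged <- FALSE
  genv <- NULL
  if (config$refresh_gan) {
    genv <- new.env(parent = emptyenv())
    genv$generator <- gan$generator; genv$critic <- gan$critic
    genv$g_state <- gan$g_state; genv$d_state <- gan$d_state
    genv$config <- gan$config; genv$n_modalities <- n
  }
  for (l in seq_len(config$max_loops)) {
    state <- assemble_loop_batch(state, labels, config)
    sel <- samples[state$selected]
    if (config$refresh_gan) {
      sd <- samples_to_tensor(sel)
      for (st in seq_len(config$refresh_steps)) {
        genv$step <- st
        gan_step(genv, sd$X, sd$labels, update_gen = TRUE)
      }
      gan$generator <- genv$generator; gan$critic <- genv$critic
    }
    nf <- config$batch_per_class
    fake_labels <- rep(c(0L, 1L), each = nf)
    fakes <- generate_fakes(gan, fake_labels)
    rk <- contribution_ranking(gan$critic, sel, fakes, fake_labels,
                               conditional = gan$config$conditional)
    if (!config$easy_first) {
      for (cls in unique(rk$label)) {
        i <- rk$label == cls
        rk$rank[i] <- rev(rk$rank[i])
      }
    }
    part <- partition_ranked(rk)
    tr <- samples[part$train]
    Xtr <- stack_batch(lapply(tr, function(s) s$tensor))
    ytr <- vapply(tr, function(s) s$label, integer(1))
    classifier <- train_classifier(classifier, Xtr, ytr, c_state,
                                   epochs = config$classifier_epochs,
                                   lr = config$lr)
    zv <- clf_logits(classifier, Xval)
    pv <- as.integer(zv > 0)
    cc <- confusion_counts(yval, pv)
    acc <- (cc["TP"] + cc["TN"]) / sum(cc)
    sen <- if (cc["TP"] + cc["FN"] > 0) cc["TP"] / (cc["TP"] + cc["FN"])
           else NA_real_
    spe <- if (cc["FP"] + cc["TN"] > 0) cc["TN"] / (cc["FP"] + cc["TN"])
           else NA_real_
    history <- rbind(history,
                     data.frame(loop = l, n_selected = length(part$train),
                                acc = unname(acc), sen = unname(sen),
                                spe = unname(spe)))
    for (pool in names(part))
      if (length(part[[pool]]))
        ledger[[length(ledger) + 1L]] <-
          data.frame(loop = l, sample_id = part[[pool]], pool = pool,
                     stringsAsFactors = FALSE)
    # trained-on and bottom-quarter samples return to the database;
    # carryover is held for the next loop
    state$database <- c(state$database, part$train, part$returned)
    state$carryover <- part$carryover
    state$selected <- character()
    stopifnot(length(state$database) + length(state$carryover) ==
                length(samples))
    if (verbose)
      message(sprintf("loop %d: trained on %d, val acc %.3f", l,
                      length(part$train), acc))
    if (acc > best_acc + config$tol) {
      best_acc <- acc; best_net <- classifier; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) { converged <- TRUE; break }
    }
  }
  structure(list(classifier = best_net, final_classifier = classifier,
                 history = history, converged = converged,
                 best_acc = unname(best_acc),
                 ledger = do.call(rbind, ledger), state = state,
                 config = config),
            class = "multiloop_fit")
}

#' @export
print.multiloop_fit <- function(x, ...) {
  cat("multiple-loop-learning fit:", nrow(x$history), "loop(s);",
      if (x$converged) "converged" else "max_loops reached (best kept)",
      "\n")
  cat("  best validation accuracy:", round(x$best_acc, 4), "\n")
  invisible(x)
}
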