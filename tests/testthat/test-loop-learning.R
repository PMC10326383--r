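# Contribution ranking, ranked partitioning, and pool bookkeeping of the
# multiple-loop-learning algorithm.

test_that("degenerate critics rank by stable id order with zero scores", {
  critic <- make_constant_critic(6, 1, value = 0)
  reals <- lapply(c("c", "a", "b"), function(id)
    make_sample(R = 6, id = id, label = 1L))
  fakes <- array(runif(6 * 6 * 2), c(6, 6, 1, 2))
  rk <- contribution_ranking(critic, reals, fakes, c(1L, 1L),
                             conditional = FALSE)
  expect_equal(rk$score, rep(0, 3))
  expect_identical(rk$sample_id, c("a", "b", "c"))
})

test_that("a real sample equal to the single fake gets distance zero, rank 1", {
  critic <- make_toy_critic(6, 1, seed = 61)
  set.seed(62)
  twin <- make_sample(R = 6, id = "twin", label = 1L)
  other <- make_sample(R = 6, id = "other", label = 1L)
  fakes <- array(twin$tensor, c(6, 6, 1, 1))
  rk <- contribution_ranking(critic, list(other, twin), fakes, 1L,
                             conditional = FALSE)
  expect_equal(rk$score[rk$sample_id == "twin"], 0, tolerance = 1e-12)
  expect_identical(rk$sample_id[rk$rank == 1], "twin")
})

test_that("scores match a hand-computed critic-space Euclidean oracle", {
  critic <- make_toy_critic(6, 1, seed = 63)
  set.seed(64)
  reals <- lapply(1:3, function(i)
    make_sample(R = 6, id = paste0("r", i), label = 0L))
  fakes <- array(runif(6 * 6 * 2), c(6, 6, 1, 2))
  rk <- contribution_ranking(critic, reals, fakes, c(0L, 0L),
                             conditional = FALSE)
  fmap <- function(x) as.vector(nn_forward(critic,
                                           array(x, c(6, 6, 1, 1)),
                                           train = FALSE)$out)
  centroid <- (fmap(fakes[, , , 1]) + fmap(fakes[, , , 2])) / 2
  for (i in 1:3) {
    want <- sqrt(sum((fmap(reals[[i]]$tensor[, , 1]) - centroid)^2))
    expect_equal(rk$score[rk$sample_id == paste0("r", i)], want,
                 tolerance = 1e-10)
  }
  expect_error(contribution_ranking(critic, reals, fakes, c(1L, 1L),
                                    conditional = FALSE),
               "no fake samples for class 0")
})

test_that("ranking is permutation-equivariant", {
  critic <- make_toy_critic(6, 1, seed = 65)
  set.seed(66)
  reals <- lapply(1:6, function(i)
    make_sample(R = 6, id = paste0("r", i), label = i %% 2L))
  fakes <- array(runif(6 * 6 * 4), c(6, 6, 1, 4))
  fl <- c(0L, 0L, 1L, 1L)
  r1 <- contribution_ranking(critic, reals, fakes, fl, conditional = FALSE)
  r2 <- contribution_ranking(critic, rev(reals), fakes, fl,
                             conditional = FALSE)
  expect_identical(r1$sample_id, r2$sample_id)
  expect_equal(r1$score, r2$score)
})

test_that("ranked partitioning follows the ceiling half/quarter rule", {
  mk <- function(m_per_class) {
    data.frame(sample_id = c(sprintf("a%02d", 1:m_per_class),
                             sprintf("h%02d", 1:m_per_class)),
               label = rep(c(1L, 0L), each = m_per_class),
               score = c(seq_len(m_per_class), seq_len(m_per_class)),
               rank = c(seq_len(m_per_class), seq_len(m_per_class)))
  }
  p8 <- partition_ranked(mk(8))
  expect_length(p8$train, 2 * 4)
  expect_length(p8$carryover, 2 * 2)
  expect_length(p8$returned, 2 * 2)
  expect_identical(sort(p8$train), sort(c(sprintf("a%02d", 1:4),
                                          sprintf("h%02d", 1:4))))
  p7 <- partition_ranked(mk(7))
  expect_length(p7$train, 2 * 4)     # ceiling(7/2) = 4
  expect_length(p7$carryover, 2 * 2) # ceiling(21/4) = 6 -> ranks 5..6
  expect_length(p7$returned, 2 * 1)
  for (m in 4:50) {
    p <- partition_ranked(mk(m))
    all_ids <- c(p$train, p$carryover, p$returned)
    expect_length(all_ids, 2 * m)
    expect_identical(anyDuplicated(all_ids), 0L)
    expect_length(p$train, 2 * ceiling(m / 2))
    expect_length(p$carryover, 2 * (ceiling(3 * m / 4) - ceiling(m / 2)))
  }
  expect_error(partition_ranked(mk(3)), ">= 4")
})

test_that("batch assembly tops carryover up with seeded balanced draws", {
  ids <- c(sprintf("a%02d", 1:20), sprintf("h%02d", 1:20))
  labels <- setNames(rep(c(1L, 0L), each = 20), ids)
  cfg <- loop_config(batch_per_class = 8)
  set.seed(71)
  st <- loop_state(ids)
  st1 <- assemble_loop_batch(st, labels, cfg)
  expect_length(st1$selected, 16)
  expect_equal(sum(labels[st1$selected] == 1), 8)
  expect_equal(sum(labels[st1$selected] == 0), 8)
  expect_length(st1$database, 40 - 16)

  # carryover of 2 per class -> 6 fresh draws per class
  st2 <- st1
  st2$selected <- character()
  st2$carryover <- c("a01", "a02", "h01", "h02")
  st2$database <- setdiff(ids, st2$carryover)
  st3 <- assemble_loop_batch(st2, labels, cfg)
  expect_length(st3$selected, 16)
  expect_true(all(c("a01", "a02", "h01", "h02") %in% st3$selected))
  expect_equal(sum(labels[st3$selected] == 1), 8)

  small <- loop_state(c("a01", "a02", "h01", "h02"))
  expect_error(assemble_loop_batch(small, labels, cfg), "insufficient")
})

test_that("a single loop trains once and the null effect stays near chance", {
  spec <- synthetic_spec(n_regions = 24, n_per_class = 12,
                         n_modalities = 1, effect_size = 0, seed = 72)
  samples <- lapply(generate_connectomes(spec), scale_sample)
  cfg <- gan_config(steps = 2, critic_steps = 1, batch_size = 4,
                    width = 0.25, d_norm = "none", seed = 73)
  gan <- pretrain_gan(samples, cfg)
  fit1 <- run_multiloop(samples, gan,
                        loop_config(batch_per_class = 4, max_loops = 1,
                                    classifier_epochs = 2, seed = 74))
  expect_identical(nrow(fit1$history), 1L)
  expect_false(fit1$converged)
})

test_that("pools stay disjoint, exhaustive, and class-balanced over loops", {
  spec <- synthetic_spec(n_regions = 24, n_per_class = 16,
                         n_modalities = 1, effect_size = 1, seed = 75)
  samples <- lapply(generate_connectomes(spec), scale_sample)
  cfg <- gan_config(steps = 2, critic_steps = 1, batch_size = 4,
                    width = 0.25, d_norm = "none", seed = 76)
  gan <- pretrain_gan(samples, cfg)
  lcfg <- loop_config(batch_per_class = 6, max_loops = 5,
                      classifier_epochs = 2, patience = 99, seed = 77)
  fit <- run_multiloop(samples, gan, lcfg)
  expect_identical(nrow(fit$history), 5L)
  # replay the ledger: every sample lands in exactly one pool per loop
  led <- fit$ledger
  for (l in unique(led$loop)) {
    sel <- led[led$loop == l, ]
    expect_identical(anyDuplicated(sel$sample_id), 0L)
    expect_length(sel$sample_id, 2 * lcfg$batch_per_class)
    # every ranked batch is class-balanced
    lab <- substr(sel$sample_id, 1, 2)
    expect_equal(sum(lab == "AB"), lcfg$batch_per_class)
    tr <- sel$sample_id[sel$pool == "train"]
    expect_equal(sum(substr(tr, 1, 2) == "AB"), length(tr) / 2)
  }
  # terminal conservation over the training pool (validation is held aside)
  expect_length(c(fit$state$database, fit$state$carryover,
                  fit$state$selected),
                floor((1 - lcfg$val_fraction) * length(samples)))
})
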