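# WGAN-GP objective: gradient penalty, critic and generator losses,
# classifier readout, and pretraining contracts.

test_that("unit-gradient linear critic gives exactly zero penalty", {
  set.seed(51)
  critic <- make_linear_critic(6, 1)
  real <- array(runif(6 * 6 * 1 * 4), c(6, 6, 1, 4))
  fake <- array(runif(6 * 6 * 1 * 4), c(6, 6, 1, 4))
  expect_equal(gradient_penalty(real, fake, critic), 0, tolerance = 1e-12)
})

test_that("constant critic gives penalty exactly one", {
  set.seed(52)
  critic <- make_constant_critic(6, 1, value = 2.5)
  real <- array(runif(6 * 6 * 4), c(6, 6, 1, 4))
  fake <- array(runif(6 * 6 * 4), c(6, 6, 1, 4))
  expect_equal(gradient_penalty(real, fake, critic), 1, tolerance = 1e-12)
})

test_that("penalty matches a finite-difference gradient-norm oracle", {
  critic <- make_toy_critic(6, 1, seed = 53)
  set.seed(54)
  real <- array(runif(6 * 6 * 3), c(6, 6, 1, 3))
  fake <- array(runif(6 * 6 * 3), c(6, 6, 1, 3))
  set.seed(99)
  got <- gradient_penalty(real, fake, critic)
  # replay the interpolation draw, then differentiate the critic's scalar
  # summary coordinate-by-coordinate
  set.seed(99)
  eps <- runif(3)
  xhat <- real
  for (b in 1:3)
    xhat[, , , b] <- eps[b] * real[, , , b] + (1 - eps[b]) * fake[, , , b]
  dscalar <- function(x1) {
    out <- nn_forward(critic, x1, train = FALSE)$out
    mean(out)
  }
  h <- 1e-5
  norms <- numeric(3)
  for (b in 1:3) {
    g <- numeric(36)
    for (i in 1:36) {
      xp <- xhat[, , , b, drop = FALSE]; xm <- xp
      xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
      g[i] <- (dscalar(xp) - dscalar(xm)) / (2 * h)
    }
    norms[b] <- sqrt(sum(g^2))
  }
  expect_equal(got, mean((norms - 1)^2), tolerance = 1e-4)
  expect_error(gradient_penalty(real, fake[, , , 1:2, drop = FALSE], critic),
               "identical shape")
})

test_that("penalty parameter gradient matches a finite-difference oracle", {
  # smooth critic so second derivatives exist everywhere
  spec <- network_spec("discriminator",
                       list(layer_spec("conv", 3, 1, 0, 2, "sigmoid"),
                            layer_spec("conv", 3, 2, 0, 1, "none")),
                       1, c(6, 6, 1))
  set.seed(55)
  critic <- nn_build(spec, init_sd = 0.5)
  xhat <- array(runif(6 * 6 * 3), c(6, 6, 1, 3))
  got <- loopgan:::gp_with_param_grads(critic, xhat, train = FALSE,
                                       fd_eps = 1e-4)
  pen_at <- function(net) loopgan:::gp_exact(net, xhat)$penalty
  h <- 1e-5
  for (li in seq_along(critic$layers)) {
    if (critic$layers[[li]]$type != "conv") next
    for (nm in c("W", "b")) {
      fd <- critic$layers[[li]][[nm]] * 0
      for (i in seq_along(fd)) {
        np <- critic; np$layers[[li]][[nm]][i] <-
          np$layers[[li]][[nm]][i] + h
        nm2 <- critic; nm2$layers[[li]][[nm]][i] <-
          nm2$layers[[li]][[nm]][i] - h
        fd[i] <- (pen_at(np) - pen_at(nm2)) / (2 * h)
      }
      expect_equal(as.vector(got$grads[[li]][[nm]]), as.vector(fd),
                   tolerance = 1e-3)
    }
  }
})

test_that("critic loss follows the penalized Wasserstein form", {
  expect_equal(discriminator_loss(c(1, 1), c(1, 1), gp = 0), 0)
  expect_equal(discriminator_loss(d_real = 1, d_fake = 2, gp = 0.5,
                                  lambda = 10), 2 - 1 + 5)
  expect_error(discriminator_loss(1, 2, 0, lambda = -1), "lambda")
  # with lambda = 0 the loss is the negated empirical score gap
  set.seed(56)
  dr <- rnorm(8); df <- rnorm(8)
  expect_equal(discriminator_loss(dr, df, gp = 7, lambda = 0),
               -(mean(dr) - mean(df)))
})

test_that("generator loss is the negated mean critic score", {
  expect_equal(generator_loss(c(3, 3)), -3)
  set.seed(57)
  df <- rnorm(6)
  expect_lt(generator_loss(df + 1), generator_loss(df))
  # L_G cancels the fake term of the unpenalized critic loss
  dr <- rnorm(6)
  expect_equal(generator_loss(df) +
                 discriminator_loss(dr, df, 0, lambda = 0),
               -mean(dr))
  expect_error(generator_loss(numeric(0)), "empty")
})

test_that("classifier readout averages the 2x2 map into a BCE logit", {
  expect_equal(classifier_logit(array(0, c(2, 2, 1))), 0)
  expect_equal(classifier_loss(0, 0), log(2))
  m1 <- array(1, c(2, 2, 1))
  expect_equal(classifier_loss(classifier_logit(m1), 1), log(1 + exp(-1)))
  # hand-computed three-sample batch
  z <- c(2, -1, 0.5); y <- c(1, 0, 0)
  want <- mean(c(log(1 + exp(-2)), log(1 + exp(-1)),
                 log(1 + exp(0.5))))
  expect_equal(classifier_loss(z, y), want, tolerance = 1e-12)
  expect_error(classifier_loss(z, c(1, 0, 2)), "labels")
  maps <- array(rnorm(2 * 2 * 1 * 5), c(2, 2, 1, 5))
  expect_equal(classifier_logit(maps),
               apply(maps, 4, mean))
})

test_that("pretraining runs, logs every step, and generates in [0, 1]", {
  set.seed(58)
  samples <- lapply(1:8, function(i)
    make_sample(R = 24, n = 1, id = paste0("s", i), label = i %% 2L))
  samples <- lapply(samples, scale_sample)
  cfg <- gan_config(steps = 3, critic_steps = 2, batch_size = 4,
                    width = 0.25, d_norm = "none", seed = 9)
  gan <- pretrain_gan(samples, cfg)
  expect_s3_class(gan, "loopgan_gan")
  expect_identical(nrow(gan$log), 3L)
  expect_true(all(is.finite(gan$log$L_D)))
  expect_true(all(is.finite(gan$log$L_G)))
  expect_true(all(gan$log$gp >= 0))
  fakes <- generate_fakes(gan, c(0L, 1L, 1L))
  expect_identical(dim(fakes), c(24L, 24L, 1L, 3L))
  expect_true(all(fakes >= 0 & fakes <= 1))
})

test_that("pretraining is reproducible given the seed", {
  samples <- lapply(1:6, function(i)
    make_sample(R = 24, n = 1, id = paste0("s", i), label = i %% 2L))
  samples <- lapply(samples, scale_sample)
  cfg <- gan_config(steps = 2, critic_steps = 1, batch_size = 4,
                    width = 0.25, d_norm = "none", seed = 17)
  g1 <- pretrain_gan(samples, cfg)
  g2 <- pretrain_gan(samples, cfg)
  expect_identical(g1$log, g2$log)
  expect_identical(g1$generator$layers, g2$generator$layers)
})
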