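# Architecture fidelity: shape arithmetic and the tabulated feature-map
# sizes of the three sub-networks.

test_that("output_shape implements conv and transposed-conv arithmetic", {
  # fifth generator layer: 32x32 -> 41x41 with kernel 12, stride 1, pad 1
  expect_identical(
    output_shape(layer_spec("transposed_conv", 12, 1, 1, 32), c(32, 32, 64)),
    c(41L, 41L, 32L))
  # third critic layer: 41x41 -> 32x32 with kernel 10, stride 1, pad 0
  expect_identical(
    output_shape(layer_spec("conv", 10, 1, 0, 128), c(41, 41, 64)),
    c(32L, 32L, 128L))
  # 1x1 kernel, stride 1, no padding leaves the spatial size unchanged
  expect_identical(
    output_shape(layer_spec("conv", 1, 1, 0, 7), c(13, 13, 3)),
    c(13L, 13L, 7L))
  expect_error(
    output_shape(layer_spec("conv", 9, 1, 0, 1), c(4, 4, 1)),
    "non-positive")
})

generator_cells <- rbind(
  c(4, 512), c(8, 256), c(16, 128), c(32, 64), c(41, 32), c(82, 16))
critic_cells <- rbind(c(82, 16), c(41, 64), c(32, 128), c(16, 256),
                      c(8, 512))
classifier_cells <- critic_cells

test_that("full shape traces reproduce every tabulated feature-map cell", {
  for (n in 1:2) {
    tg <- shape_trace(build_generator(n, conditional = FALSE))
    expect_identical(unname(tg[1:6, c(1, 3)]),
                     matrix(as.integer(generator_cells), 6, 2))
    expect_identical(unname(tg[7, ]), c(164L, 164L, n))

    td <- shape_trace(build_discriminator(n, conditional = FALSE))
    expect_identical(unname(td[1:5, c(1, 3)]),
                     matrix(as.integer(critic_cells), 5, 2))
    expect_identical(unname(td[6, ]), c(5L, 5L, n))

    tc <- shape_trace(build_classifier(n))
    expect_identical(unname(tc[1:5, c(1, 3)]),
                     matrix(as.integer(classifier_cells), 5, 2))
    expect_identical(unname(tc[6, ]), c(2L, 2L, 1L))
  }
  expect_error(build_generator(0), "n_modalities")
})

test_that("latent input is 100 n values plus the one-hot condition", {
  g1 <- build_generator(1, conditional = TRUE)
  g2 <- build_generator(2, conditional = TRUE)
  expect_identical(g1$input_shape[3], 102L)
  expect_identical(g2$input_shape[3], 202L)
  expect_identical(build_generator(2, conditional = FALSE)$input_shape[3],
                   200L)
  z <- loopgan:::sample_latent(2, 5)
  expect_identical(dim(z), c(200L, 5L))
  zc <- condition_inputs(z, c(0, 1, 1, 0, 1), "generator")
  expect_identical(dim(zc), c(202L, 5L))
  expect_identical(unname(zc[201:202, 1]), c(1, 0))  # HC one-hot
  expect_identical(unname(zc[201:202, 2]), c(0, 1))  # AB one-hot
})

test_that("conditioning adds one constant critic channel and can be disabled", {
  d_on <- build_discriminator(2, conditional = TRUE)
  d_off <- build_discriminator(2, conditional = FALSE)
  expect_identical(d_on$input_shape[3], 3L)
  expect_identical(d_off$input_shape[3], 2L)
  x <- array(runif(4 * 4 * 2 * 3), c(4, 4, 2, 3))
  xc <- condition_inputs(x, c(1, 0, 1), "discriminator")
  expect_identical(dim(xc), c(4L, 4L, 3L, 3L))
  expect_true(all(xc[, , 3, 1] == 1))
  expect_true(all(xc[, , 3, 2] == 0))
  expect_identical(xc[, , 1:2, ], x)
  expect_error(condition_inputs(x, c(1, 0, 2), "discriminator"), "labels")
})

test_that("conditioning breaks symmetry between the classes", {
  set.seed(7)
  spec <- build_generator(1, image_size = 24, conditional = TRUE,
                          width = 0.25, normalization = "none")
  net <- nn_build(spec)
  z <- loopgan:::sample_latent(1, 1)
  z2 <- cbind(z, z)
  zc <- condition_inputs(z2, c(0, 1), "generator")
  out <- nn_forward(net, loopgan:::latent_to_tensor(zc), train = FALSE)$out
  expect_gt(max(abs(out[, , , 1] - out[, , , 2])), 0)
})

test_that("runnable networks realize their traced shapes", {
  set.seed(8)
  for (n in 1:2) {
    gs <- build_generator(n, image_size = 40, conditional = FALSE,
                          width = 0.25, normalization = "batch")
    ds <- build_discriminator(n, image_size = 40, conditional = FALSE,
                              width = 0.25, normalization = "none")
    cs <- build_classifier(n, image_size = 40, width = 0.25,
                           normalization = "none")
    z <- array(rnorm(100 * n * 2), c(1, 1, 100 * n, 2))
    fake <- nn_forward(nn_build(gs), z)$out
    expect_identical(dim(fake), c(40L, 40L, n, 2L))
    expect_true(all(fake >= 0 & fake <= 1))
    pm <- nn_forward(nn_build(ds), fake)$out
    expect_identical(dim(pm), c(5L, 5L, n, 2L))
    cm <- nn_forward(nn_build(cs), fake)$out
    expect_identical(dim(cm), c(2L, 2L, 1L, 2L))
  }
})
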