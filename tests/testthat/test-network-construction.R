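# Pearson functional connectivity, structural normalization, and channel
# stacking.

test_that("pearson_connectivity matches direct formula evaluation", {
  # X = (1,2,3,4), Y = (2,1,4,3): centered products sum to 3, each sum of
  # squares is 5, so r = 3/5
  ts <- time_series_set("s", c("A", "B"),
                        rbind(c(1, 2, 3, 4), c(2, 1, 4, 3)))
  cm <- pearson_connectivity(ts)
  expect_equal(cm$matrix["A", "B"], 0.6, tolerance = 1e-12)

  # identical series and perfect anticorrelation
  x <- c(0.3, 1.7, 0.9, 2.4, 1.1)
  ts2 <- time_series_set("s2", c("A", "B", "C"), rbind(x, x, -x))
  cm2 <- pearson_connectivity(ts2)
  expect_equal(cm2$matrix["A", "B"], 1.0)
  expect_equal(cm2$matrix["A", "C"], -1.0)

  # textbook covariance / sigma oracle on random inputs
  set.seed(21)
  for (rep in 1:5) {
    R <- 6; TT <- 30
    s <- matrix(rnorm(R * TT), R, TT)
    ts3 <- time_series_set("r", paste0("V", 1:R), s)
    got <- pearson_connectivity(ts3)$matrix
    want <- matrix(0, R, R)
    for (i in 1:R) for (j in 1:R) {
      dx <- s[i, ] - mean(s[i, ]); dy <- s[j, ] - mean(s[j, ])
      want[i, j] <- sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
    }
    expect_equal(unname(got), want, tolerance = 1e-10)
  }
})

test_that("pearson correlation is invariant to positive affine rescaling", {
  set.seed(22)
  s <- matrix(rnorm(4 * 20), 4, 20)
  base <- pearson_connectivity(time_series_set("a", paste0("V", 1:4), s))
  s2 <- s
  s2[2, ] <- 3.7 * s[2, ] + 11
  s2[4, ] <- 0.01 * s[4, ] - 5
  resc <- pearson_connectivity(time_series_set("a", paste0("V", 1:4), s2))
  expect_equal(base$matrix, resc$matrix, tolerance = 1e-12)
})

test_that("zero-variance regions raise an error naming the region", {
  s <- rbind(rnorm(10), rep(2, 10), rnorm(10))
  ts <- time_series_set("s", c("good1", "flatline", "good2"), s)
  expect_error(pearson_connectivity(ts), "flatline")
})

test_that("structural normalization divides by brain volume with zero diagonal", {
  counts <- matrix(0, 4, 4)
  counts[1, 2] <- counts[2, 1] <- 10
  counts[3, 4] <- counts[4, 3] <- 7
  cm <- normalize_structural(counts, 2, "s")
  expect_equal(cm$matrix[1, 2], 5.0)
  expect_equal(cm$matrix[3, 4], 3.5)
  expect_equal(diag(cm$matrix), setNames(rep(0, 4), cm$regions))

  z <- normalize_structural(matrix(0, 3, 3), 5, "z")
  expect_true(all(z$matrix == 0))

  # elementwise oracle and linearity in 1/volume
  set.seed(23)
  m <- matrix(sample(0:50, 25, replace = TRUE), 5, 5)
  m <- m + t(m); diag(m) <- 0
  v <- 3.7
  a <- normalize_structural(m, v)$matrix
  expect_equal(unname(a), m / v)
  b <- normalize_structural(m, 2 * v)$matrix
  expect_equal(unname(b), unname(a) / 2)

  expect_error(normalize_structural(m, 0), "positive")
  expect_error(normalize_structural(m, -1), "positive")
  asym <- m; asym[1, 2] <- asym[1, 2] + 1
  expect_error(normalize_structural(asym, 1), "asymmetric")
})

test_that("stack_modalities preserves channels and rejects mismatched regions", {
  set.seed(24)
  R <- 6L
  reg <- sprintf("R%02d", 1:R)
  mf <- matrix(runif(R * R, -1, 1), R, R); mf <- (mf + t(mf)) / 2
  diag(mf) <- 1
  ms <- matrix(runif(R * R), R, R); ms <- (ms + t(ms)) / 2; diag(ms) <- 0
  f <- connectivity_matrix("s", "functional", mf, reg)
  s <- connectivity_matrix("s", "structural", ms, reg)

  one <- stack_modalities(list(f), 0)
  expect_identical(dim(one$tensor), c(R, R, 1L))
  expect_equal(one$tensor[, , 1], unname(mf))

  two <- stack_modalities(list(f, s), 1)
  expect_identical(dim(two$tensor), c(R, R, 2L))
  expect_equal(two$tensor[, , 1], unname(mf))
  expect_equal(two$tensor[, , 2], unname(ms))
  expect_identical(two$label, 1L)

  s_bad <- connectivity_matrix("s", "structural", ms, rev(reg))
  expect_error(stack_modalities(list(f, s_bad), 1), "position 1")
  expect_error(stack_modalities(list(f, s), 2), "label")
  expect_error(stack_modalities(list(), 1), "at least one")
})

test_that("a 164-region functional + structural pair stacks to 164 x 164 x 2", {
  set.seed(25)
  R <- 164
  reg <- sprintf("R%03d", 1:R)
  mf <- matrix(runif(R * R, -1, 1), R, R); mf <- (mf + t(mf)) / 2
  diag(mf) <- 1
  ms <- matrix(runif(R * R), R, R); ms <- (ms + t(ms)) / 2; diag(ms) <- 0
  sample <- stack_modalities(
    list(connectivity_matrix("s", "functional", mf, reg),
         connectivity_matrix("s", "structural", ms, reg)), 1)
  expect_identical(dim(sample$tensor), c(164L, 164L, 2L))
})

test_that("connectivity_matrix enforces the modality conventions", {
  bad <- matrix(2, 3, 3)
  expect_error(connectivity_matrix("s", "functional", bad), "\\[-1, 1\\]")
  neg <- -diag(3)
  expect_error(connectivity_matrix("s", "structural", neg), "non-negative")
  asym <- matrix(runif(9), 3, 3)
  expect_error(connectivity_matrix("s", "structural", asym), "asymmetric")
})
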