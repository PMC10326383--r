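# Shared fixtures: hand-constructed critics and small synthetic samples.

# Critic realizing D(x) = sum(x) / sqrt(d): a single full-image conv with
# constant weights, so every input-gradient norm is exactly 1.
make_linear_critic <- function(H, C) {
  spec <- network_spec("discriminator",
                       list(layer_spec("conv", H, 1, 0, 1, "none")),
                       n_modalities = C, input_shape = c(H, H, C))
  net <- nn_build(spec)
  d <- H * H * C
  net$layers[[1]]$W[] <- 1 / sqrt(d)
  net$layers[[1]]$b[] <- 0
  net
}

# Critic that ignores its input entirely: D(x) = const.
make_constant_critic <- function(H, C, value = 3) {
  net <- make_linear_critic(H, C)
  net$layers[[1]]$W[] <- 0
  net$layers[[1]]$b[] <- value
  net
}

# Small nonlinear critic with a 2x2 patch map, random (seeded) weights.
make_toy_critic <- function(H = 6, C = 1, seed = 42) {
  spec <- network_spec("discriminator",
                       list(layer_spec("conv", 3, 1, 0, 2, "leaky_relu"),
                            layer_spec("conv", H - 3, 2, 0, 1, "none")),
                       n_modalities = C, input_shape = c(H, H, C))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  set.seed(seed)
  net <- nn_build(spec, init_sd = 0.3)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  net
}

# Random symmetric multimodal sample in [0, 1].
make_sample <- function(R = 8, n = 1, id = "s1", label = 0L) {
  chans <- vector("list", n)
  modal <- rep(c("functional", "structural"), length.out = n)
  for (k in seq_len(n)) {
    m <- matrix(runif(R * R), R, R)
    m <- (m + t(m)) / 2
    if (modal[k] == "functional") diag(m) <- 1 else diag(m) <- 0
    chans[[k]] <- connectivity_matrix(id, modal[k], m,
                                      sprintf("R%03d", seq_len(R)))
  }
  stack_modalities(chans, label, subject_id = id)
}

# Mann-Whitney concordance AUC oracle (half-credit for ties).
auc_concordance <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# Nearest-centroid linear baseline on flattened upper triangles; returns
# held-out accuracy.  Independent of the package's networks.
centroid_baseline_acc <- function(train, test) {
  feat <- function(s) {
    n <- dim(s$tensor)[3]
    unlist(lapply(seq_len(n), function(ch) {
      m <- s$tensor[, , ch]; m[upper.tri(m)]
    }))
  }
  Xtr <- vapply(train, feat, numeric(length(feat(train[[1]]))))
  ytr <- vapply(train, function(s) s$label, integer(1))
  mu1 <- rowMeans(Xtr[, ytr == 1, drop = FALSE])
  mu0 <- rowMeans(Xtr[, ytr == 0, drop = FALSE])
  w <- mu1 - mu0
  thr <- sum(w * (mu1 + mu0)) / 2
  Xte <- vapply(test, feat, numeric(length(w)))
  yte <- vapply(test, function(s) s$label, integer(1))
  pred <- as.integer(colSums(Xte * w) > thr)
  mean(pred == yte)
}
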