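# Minimal convolutional-network engine on dense R arrays.
#
# Tensors are 4-d arrays dim = c(height, width, channels, batch).  Convolution
# and transposed convolution are realised as im2col / col2im plus one BLAS
# GEMM; gradients are hand-derived reverse-mode.  Only what the patch critic,
# generator and classifier need is implemented.

# ---- index machinery ------------------------------------------------------

# Linear gather index for im2col on a zero-padded (Hp x Wp x C) volume.
# Column r of the result indexes one k x k x C patch (row offset fastest,
# then column offset, then channel); patches ordered output-row fastest.
im2col_index <- function(Hp, Wp, C, k, s) {
  ho <- (Hp - k) %/% s + 1L
  wo <- (Wp - k) %/% s + 1L
  if (ho < 1L || wo < 1L)
    stop("im2col: non-positive output size (input ", Hp, "x", Wp,
         ", kernel ", k, ", stride ", s, ")")
  di <- rep.int(seq_len(k) - 1L, k)
  dj <- rep(seq_len(k) - 1L, each = k)
  off <- as.vector(outer(di + dj * Hp, (seq_len(C) - 1L) * (Hp * Wp), "+"))
  i0 <- (seq_len(ho) - 1L) * s + 1L
  j0 <- (seq_len(wo) - 1L) * s
  base <- as.vector(outer(i0, j0 * Hp, "+"))
  list(idx = outer(as.integer(off), as.integer(base), "+"), ho = ho, wo = wo)
}

pad2d <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  out
}

unpad2d <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  x[p + seq_len(d[1] - 2L * p), p + seq_len(d[2] - 2L * p), , , drop = FALSE]
}

# Scatter-add of columns back onto the padded volume (adjoint of the gather).
col2im_add <- function(cols_mat, idx, Hp, Wp, C, B) {
  g <- rowsum(cols_mat, group = rep_len(as.vector(idx), nrow(cols_mat)),
              reorder = FALSE)
  Z <- matrix(0, Hp * Wp * C, B)
  Z[as.integer(rownames(g)), ] <- g
  array(Z, c(Hp, Wp, C, B))
}

# ---- convolution ----------------------------------------------------------

conv2d_forward <- function(x, W, b, k, s, p) {
  d <- dim(x)
  xp <- pad2d(x, p)
  dp <- dim(xp)
  ix <- im2col_index(dp[1], dp[2], d[3], k, s)
  Xp <- xp; dim(Xp) <- c(dp[1] * dp[2] * d[3], d[4])
  P <- Xp[as.vector(ix$idx), , drop = FALSE]
  kkC <- k * k * d[3]
  dim(P) <- c(kkC, ix$ho * ix$wo * d[4])
  out_cols <- W %*% P + b
  Co <- nrow(W)
  A <- out_cols; dim(A) <- c(Co, ix$ho * ix$wo, d[4])
  out <- aperm(A, c(2, 1, 3))
  dim(out) <- c(ix$ho, ix$wo, Co, d[4])
  list(out = out, cache = list(P = P, ix = ix, in_dim = d, pad_dim = dp))
}

conv2d_backward <- function(dout, cache, W, k, s, p) {
  d <- cache$in_dim; dp <- cache$pad_dim; ix <- cache$ix
  od <- dim(dout)
  A <- dout; dim(A) <- c(od[1] * od[2], od[3], od[4])
  A <- aperm(A, c(2, 1, 3)); dim(A) <- c(od[3], od[1] * od[2] * od[4])
  dW <- A %*% t(cache$P)
  db <- rowSums(A)
  dP <- crossprod(W, A)
  dim(dP) <- c(nrow(dP) * ix$ho * ix$wo, d[4])
  dxp <- col2im_add(dP, ix$idx, dp[1], dp[2], d[3], d[4])
  list(dx = unpad2d(dxp, p), dW = dW, db = db)
}

# Transposed convolution: the adjoint map of a stride-s conv, so the forward
# pass is a col2im scatter and the backward data pass an im2col gather.
# Weight layout: C_in x (k*k*C_out).
convt2d_forward <- function(x, W, b, k, s, p) {
  d <- dim(x)
  o <- (d[1] - 1L) * s - 2L * p + k
  ow <- (d[2] - 1L) * s - 2L * p + k
  if (o < 1L || ow < 1L) stop("convt: non-positive output size")
  Co <- ncol(W) / (k * k)
  A <- x; dim(A) <- c(d[1] * d[2], d[3], d[4])
  x_cols <- aperm(A, c(2, 1, 3)); dim(x_cols) <- c(d[3], d[1] * d[2] * d[4])
  cols <- crossprod(W, x_cols)
  ix <- im2col_index(o + 2L * p, ow + 2L * p, Co, k, s)
  stopifnot(ix$ho == d[1], ix$wo == d[2])
  cm <- cols; dim(cm) <- c(k * k * Co * d[1] * d[2], d[4])
  outp <- col2im_add(cm, ix$idx, o + 2L * p, ow + 2L * p, Co, d[4])
  out <- unpad2d(outp, p)
  out <- out + rep(b, each = o * ow)
  list(out = out, cache = list(x_cols = x_cols, ix = ix, in_dim = d,
                               out_dim = c(o, ow, Co, d[4])))
}

convt2d_backward <- function(dout, cache, W, k, s, p) {
  d <- cache$in_dim; od <- cache$out_dim; ix <- cache$ix
  doutp <- pad2d(dout, p)
  Dp <- doutp; dim(Dp) <- c(prod(dim(doutp)[1:3]), od[4])
  G <- Dp[as.vector(ix$idx), , drop = FALSE]
  dim(G) <- c(k * k * od[3], d[1] * d[2] * od[4])
  dx_cols <- W %*% G
  dim(dx_cols) <- c(d[3], d[1] * d[2], d[4])
  dx <- aperm(dx_cols, c(2, 1, 3)); dim(dx) <- d
  dW <- tcrossprod(cache$x_cols, G)
  dm <- dout; dim(dm) <- c(od[1] * od[2], od[3] * od[4])
  db <- rowSums(matrix(colSums(dm), od[3], od[4]))
  list(dx = dx, dW = dW, db = db)
}

# ---- normalization --------------------------------------------------------

# Batch norm normalizes each channel over (H, W, batch); instance norm over
# (H, W) of each sample.  Running moments (batch mode) feed eval-mode passes.
norm_forward <- function(x, gamma, beta, stats, mode = c("batch", "instance"),
                         train = TRUE, eps = 1e-5, momentum = 0.1) {
  mode <- match.arg(mode)
  d <- dim(x)
  m <- x; dim(m) <- c(d[1] * d[2], d[3], d[4])
  if (mode == "batch") {
    if (train) {
      mu <- apply(m, 2, mean)
      v <- apply(m, 2, function(z) mean((z - mean(z))^2))
      stats$mu <- (1 - momentum) * stats$mu + momentum * mu
      stats$var <- (1 - momentum) * stats$var + momentum * v
    } else {
      mu <- stats$mu; v <- stats$var
    }
    invstd <- 1 / sqrt(v + eps)
    xhat <- sweep(sweep(m, 2, mu, "-"), 2, invstd, "*")
    out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  } else {
    mu <- colMeans(m)                      # d[3] x d[4]
    v <- matrix(apply(m, c(2, 3), function(z) mean((z - mean(z))^2)),
                d[3], d[4])
    invstd <- 1 / sqrt(v + eps)
    xhat <- array(0, dim(m))
    for (b in seq_len(d[4]))
      xhat[, , b] <- sweep(sweep(m[, , b, drop = FALSE][, , 1], 2, mu[, b], "-"),
                           2, invstd[, b], "*")
    out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  }
  dim(out) <- d
  list(out = out, cache = list(xhat = xhat, invstd = invstd, dim = d,
                               mode = mode))
}

norm_backward <- function(dout, cache, gamma) {
  d <- cache$dim
  dm <- dout; dim(dm) <- c(d[1] * d[2], d[3], d[4])
  xhat <- cache$xhat
  if (cache$mode == "batch") {
    n <- d[1] * d[2] * d[4]
    dgamma <- apply(dm * xhat, 2, sum)
    dbeta <- apply(dm, 2, sum)
    dx <- array(0, dim(dm))
    for (c in seq_len(d[3])) {
      dz <- dm[, c, ] * gamma[c]
      xh <- xhat[, c, ]
      dx[, c, ] <- cache$invstd[c] / n *
        (n * dz - sum(dz) - xh * sum(dz * xh))
    }
  } else {
    n <- d[1] * d[2]
    dgamma <- apply(dm * xhat, 2, sum)
    dbeta <- apply(dm, 2, sum)
    dx <- array(0, dim(dm))
    for (b in seq_len(d[4])) for (c in seq_len(d[3])) {
      dz <- dm[, c, b] * gamma[c]
      xh <- xhat[, c, b]
      dx[, c, b] <- cache$invstd[c, b] / n *
        (n * dz - sum(dz) - xh * sum(dz * xh))
    }
  }
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- activations ----------------------------------------------------------

act_forward <- function(x, type, slope = 0.2) {
  out <- switch(type,
    relu = pmax(x, 0),
    leaky_relu = ifelse(x > 0, x, slope * x),
    sigmoid = 1 / (1 + exp(-x)),
    none = x,
    stop("unknown activation: ", type))
  if (is.null(dim(out))) dim(out) <- dim(x)
  list(out = out, cache = if (type == "sigmoid") out else x)
}

act_backward <- function(dout, cache, type, slope = 0.2) {
  switch(type,
    relu = dout * (cache > 0),
    leaky_relu = dout * ifelse(cache > 0, 1, slope),
    sigmoid = dout * cache * (1 - cache),
    none = dout)
}

# ---- runnable networks ----------------------------------------------------

#' Instantiate a runnable network from a specification
#'
#' Expands a [network_spec()] into a list of primitive layers
#' (convolution, transposed convolution, normalization, activation) with
#' randomly initialized weights (`N(0, init_sd)`, drawn from the current
#' RNG stream).  Batch-norm running moments live in a per-layer
#' environment.
#'
#' @param spec A [network_spec()].
#' @param init_sd Weight initialization standard deviation.
#' @return A `loopgan_net` usable with [nn_forward()].
#' @export
nn_build <- function(spec, init_sd = 0.02) {
  in_shape <- spec$input_shape
  layers <- list()
  H <- in_shape[1]; C <- in_shape[3]
  nL <- length(spec$layers)
  for (i in seq_len(nL)) {
    ls <- spec$layers[[i]]
    k <- ls$kernel; Co <- ls$out_channels
    if (ls$kind == "conv") {
      W <- matrix(stats::rnorm(Co * k * k * C, 0, init_sd), Co, k * k * C)
    } else {
      W <- matrix(stats::rnorm(C * k * k * Co, 0, init_sd), C, k * k * Co)
    }
    layers[[length(layers) + 1L]] <- list(
      type = ls$kind, W = W, b = numeric(Co),
      k = k, s = ls$stride, p = ls$padding)
    if (identical(ls$normalization, "batch") ||
        identical(ls$normalization, "instance")) {
      st <- new.env(parent = emptyenv())
      st$mu <- numeric(Co); st$var <- rep(1, Co)
      layers[[length(layers) + 1L]] <- list(
        type = "norm", mode = ls$normalization,
        gamma = rep(1, Co), beta = numeric(Co), stats = st)
    }
    if (ls$activation != "none")
      layers[[length(layers) + 1L]] <- list(type = "act", act = ls$activation)
    sh <- output_shape(ls, c(H, H, C))
    H <- sh[1]; C <- sh[3]
  }
  structure(list(layers = layers, spec = spec, out_shape = c(H, H, C)),
            class = "loopgan_net")
}

#' Forward pass through a runnable network
#'
#' @param net A `loopgan_net` from [nn_build()].
#' @param x Input array `height x width x channels x batch`.
#' @param train Training mode (batch statistics, running-moment updates)?
#' @return List with `out` (the output tensor) and `caches` (intermediate
#'   values for the backward pass).
#' @export
nn_forward <- function(net, x, train = TRUE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    r <- switch(ly$type,
      conv = conv2d_forward(x, ly$W, ly$b, ly$k, ly$s, ly$p),
      convt = convt2d_forward(x, ly$W, ly$b, ly$k, ly$s, ly$p),
      norm = norm_forward(x, ly$gamma, ly$beta, ly$stats, ly$mode, train),
      act = act_forward(x, ly$act))
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

# Returns the input gradient and one grad entry per layer (NULL for
# parameter-free layers).
nn_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    if (ly$type == "conv") {
      r <- conv2d_backward(dout, caches[[i]], ly$W, ly$k, ly$s, ly$p)
      grads[[i]] <- list(W = r$dW, b = r$db); dout <- r$dx
    } else if (ly$type == "convt") {
      r <- convt2d_backward(dout, caches[[i]], ly$W, ly$k, ly$s, ly$p)
      grads[[i]] <- list(W = r$dW, b = r$db); dout <- r$dx
    } else if (ly$type == "norm") {
      r <- norm_backward(dout, caches[[i]], ly$gamma)
      grads[[i]] <- list(gamma = r$dgamma, beta = r$dbeta); dout <- r$dx
    } else {
      dout <- act_backward(dout, caches[[i]], ly$act)
    }
  }
  list(dx = dout, grads = grads)
}

# ---- optimizer ------------------------------------------------------------

adam_state <- function() {
  e <- new.env(parent = emptyenv()); e$t <- 0L; e$m <- list(); e$v <- list()
  e
}

adam_step <- function(net, grads, state, lr = 1e-4, beta1 = 0.5,
                      beta2 = 0.9, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      key <- paste0(i, ".", nm)
      if (is.null(state$m[[key]])) {
        state$m[[key]] <- g[[nm]] * 0
        state$v[[key]] <- g[[nm]] * 0
      }
      state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g[[nm]]
      state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g[[nm]]^2
      net$layers[[i]][[nm]] <- net$layers[[i]][[nm]] -
        lr * (state$m[[key]] / bc1) / (sqrt(state$v[[key]] / bc2) + eps)
    }
  }
  net
}

# Stack a list of H x W x C arrays into an H x W x C x B batch.
stack_batch <- function(xs) {
  d <- dim(xs[[1]])
  if (length(d) == 2L) d <- c(d, 1L)
  out <- array(0, c(d, length(xs)))
  for (i in seq_along(xs)) out[, , , i] <- xs[[i]]
  out
}
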