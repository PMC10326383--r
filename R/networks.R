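# Declarative network specifications and shape arithmetic.
#
# The three sub-networks (generator, patch critic, classifier) are described
# as ordered lists of layer specifications; a runnable net (nn.R) is
# instantiated from the spec.  The tabulated 164-region geometry is the
# default; a scaled-down family with the same topology (latent -> stack of
# stride-2 transposed convolutions; critic ending in a 5x5 patch map;
# classifier ending in a 2x2 map) is provided for desk-scale work and is not
# part of the reference architecture.

#' Describe one convolutional layer
#'
#' @param kind `"conv"` or `"transposed_conv"` (alias `"convt"`).
#' @param kernel,stride,padding Integer layer geometry.
#' @param out_channels Number of output channels.
#' @param activation One of `"relu"`, `"leaky_relu"`, `"sigmoid"`, `"none"`.
#' @param normalization `"batch"`, `"instance"` or `"none"`.
#' @return A `layer_spec` object.
#' @export
layer_spec <- function(kind, kernel, stride, padding, out_channels,
                       activation = "none", normalization = "none") {
  kind <- match.arg(kind, c("conv", "transposed_conv", "convt"))
  if (kind == "transposed_conv") kind <- "convt"
  stopifnot(kernel >= 1, stride >= 1, padding >= 0, out_channels >= 1)
  activation <- match.arg(activation,
                          c("relu", "leaky_relu", "sigmoid", "none"))
  normalization <- match.arg(normalization, c("batch", "instance", "none"))
  structure(list(kind = kind, kernel = as.integer(kernel),
                 stride = as.integer(stride), padding = as.integer(padding),
                 out_channels = as.integer(out_channels),
                 activation = activation, normalization = normalization),
            class = "layer_spec")
}

#' Spatial output shape of a convolutional layer
#'
#' Applies the standard output-size arithmetic: for a convolution
#' `out = floor((in + 2 pad - kernel)/stride) + 1`, for a transposed
#' convolution `out = (in - 1) stride - 2 pad + kernel`.
#'
#' @param layer A [layer_spec()].
#' @param in_shape Integer vector `c(height, width, channels)`.
#' @return Integer vector `c(height, width, channels)` of the output map.
#' @export
output_shape <- function(layer, in_shape) {
  stopifnot(inherits(layer, "layer_spec"), length(in_shape) == 3)
  f <- function(n) {
    if (layer$kind == "conv")
      (n + 2L * layer$padding - layer$kernel) %/% layer$stride + 1L
    else
      (n - 1L) * layer$stride - 2L * layer$padding + layer$kernel
  }
  h <- f(as.integer(in_shape[1])); w <- f(as.integer(in_shape[2]))
  if (h < 1L || w < 1L)
    stop("layer (kernel ", layer$kernel, ", stride ", layer$stride,
         ", padding ", layer$padding, ") yields non-positive output size ",
         h, "x", w, " from input ", in_shape[1], "x", in_shape[2])
  c(h, w, layer$out_channels)
}

#' Describe a full sub-network
#'
#' @param role `"generator"`, `"discriminator"` or `"classifier"`.
#' @param layers List of [layer_spec()] objects.
#' @param n_modalities Number of input/output data channels `n`.
#' @param input_shape `c(height, width, channels)` fed to the first layer.
#' @return A `network_spec` object.
#' @export
network_spec <- function(role, layers, n_modalities, input_shape) {
  role <- match.arg(role, c("generator", "discriminator", "classifier"))
  stopifnot(n_modalities >= 1, length(input_shape) == 3)
  structure(list(role = role, layers = layers,
                 n_modalities = as.integer(n_modalities),
                 input_shape = as.integer(input_shape)),
            class = "network_spec")
}

#' Layer-by-layer shape trace of a network
#'
#' @param spec A [network_spec()].
#' @return Integer matrix with one row per layer (`height`, `width`,
#'   `channels`), rownames `layer 1..L`.
#' @export
shape_trace <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  sh <- spec$input_shape
  out <- matrix(NA_integer_, length(spec$layers), 3,
                dimnames = list(paste0("layer", seq_along(spec$layers)),
                                c("height", "width", "channels")))
  for (i in seq_along(spec$layers)) {
    sh <- output_shape(spec$layers[[i]], sh)
    out[i, ] <- sh
  }
  out
}

scale_ch <- function(ch, width) max(1L, as.integer(round(ch * width)))

# Normalization placement: every layer except the first and the last of each
# sub-network carries normalization (the critic's may be switched to
# instance norm, which does not couple samples through batch statistics and
# so keeps per-sample gradient penalties exact).
place_norm <- function(layers, mode) {
  if (mode == "none" || length(layers) < 3) return(layers)
  for (i in seq(2, length(layers) - 1))
    layers[[i]]$normalization <- mode
  layers
}

#' Build the generator specification
#'
#' Maps a latent vector of `100 n` values (presented as a 1x1 spatial map;
#' plus a 2-value one-hot class condition when `conditional`) through a stack
#' of transposed convolutions to an `image_size` x `image_size` x `n` map in
#' `[0, 1]` (final Sigmoid).  `image_size = 164` reproduces the reference
#' seven-layer geometry (4, 8, 16, 32, 41, 82, 164); other sizes (multiples
#' of 8, at least 24) use a scaled four-layer variant.
#'
#' @param n_modalities Number of output channels `n`.
#' @param image_size Output height (= width); default 164.
#' @param conditional Append a one-hot class label to the latent input?
#' @param width Channel-width multiplier for desk-scale runs.
#' @param normalization Normalization for the interior layers.
#' @return A [network_spec()].
#' @export
build_generator <- function(n_modalities = 1, image_size = 164,
                            conditional = TRUE, width = 1,
                            normalization = "batch") {
  n <- as.integer(n_modalities)
  if (n < 1) stop("n_modalities must be >= 1")
  cin <- 100L * n + if (conditional) 2L else 0L
  if (image_size == 164) {
    ch <- vapply(c(512, 256, 128, 64, 32, 16), scale_ch, integer(1), width)
    layers <- list(
      layer_spec("convt", 4, 1, 0, ch[1], "relu"),
      layer_spec("convt", 4, 2, 1, ch[2], "relu"),
      layer_spec("convt", 4, 2, 1, ch[3], "relu"),
      layer_spec("convt", 4, 2, 1, ch[4], "relu"),
      layer_spec("convt", 12, 1, 1, ch[5], "relu"),
      layer_spec("convt", 4, 2, 1, ch[6], "relu"),
      layer_spec("convt", 4, 2, 1, n, "sigmoid"))
  } else {
    s <- as.integer(image_size)
    if (s %% 8L != 0L || s < 24L)
      stop("scaled generator needs image_size a multiple of 8, >= 24")
    ch <- vapply(c(64, 32, 16), scale_ch, integer(1), width)
    layers <- list(
      layer_spec("convt", s %/% 8L, 1, 0, ch[1], "relu"),
      layer_spec("convt", 4, 2, 1, ch[2], "relu"),
      layer_spec("convt", 4, 2, 1, ch[3], "relu"),
      layer_spec("convt", 4, 2, 1, n, "sigmoid"))
  }
  layers <- place_norm(layers, normalization)
  network_spec("generator", layers, n, c(1L, 1L, cin))
}

#' Build the patch-critic (discriminator) specification
#'
#' Maps an `image_size` x `image_size` x `n` input (plus one constant
#' condition channel when `conditional`) to an unbounded 5x5x`n` patch map
#' with no final activation.  `image_size = 164` reproduces the reference
#' six-layer geometry (82, 41, 32, 16, 8, 5).
#'
#' @inheritParams build_generator
#' @return A [network_spec()].
#' @export
build_discriminator <- function(n_modalities = 1, image_size = 164,
                                conditional = TRUE, width = 1,
                                normalization = "batch") {
  n <- as.integer(n_modalities)
  if (n < 1) stop("n_modalities must be >= 1")
  cin <- n + if (conditional) 1L else 0L
  if (image_size == 164) {
    ch <- vapply(c(16, 64, 128, 256, 512), scale_ch, integer(1), width)
    layers <- list(
      layer_spec("conv", 4, 2, 1, ch[1], "leaky_relu"),
      layer_spec("conv", 4, 2, 1, ch[2], "leaky_relu"),
      layer_spec("conv", 10, 1, 0, ch[3], "leaky_relu"),
      layer_spec("conv", 4, 2, 1, ch[4], "leaky_relu"),
      layer_spec("conv", 4, 2, 1, ch[5], "leaky_relu"),
      layer_spec("conv", 4, 1, 0, n, "none"))
  } else {
    s <- as.integer(image_size)
    if (s %% 8L != 0L || s < 24L)
      stop("scaled critic needs image_size a multiple of 8, >= 24")
    ch <- vapply(c(16, 32), scale_ch, integer(1), width)
    layers <- list(
      layer_spec("conv", 4, 2, 1, ch[1], "leaky_relu"),
      layer_spec("conv", 4, 2, 1, ch[2], "leaky_relu"),
      layer_spec("conv", s %/% 4L - 4L, 1, 0, n, "none"))
  }
  layers <- place_norm(layers, normalization)
  network_spec("discriminator", layers, n,
               c(as.integer(image_size), as.integer(image_size), cin))
}

#' Build the classifier specification
#'
#' Maps an `image_size` x `image_size` x `n` input to a 2x2x1 map with no
#' final activation; the class logit is the mean of the four map values
#' (see [classifier_logit()]).  `image_size = 164` reproduces the reference
#' six-layer geometry (82, 41, 32, 16, 8, 2).
#'
#' @inheritParams build_generator
#' @return A [network_spec()].
#' @export
build_classifier <- function(n_modalities = 1, image_size = 164, width = 1,
                             normalization = "batch") {
  n <- as.integer(n_modalities)
  if (n < 1) stop("n_modalities must be >= 1")
  if (image_size == 164) {
    ch <- vapply(c(16, 64, 128, 256, 512), scale_ch, integer(1), width)
    layers <- list(
      layer_spec("conv", 4, 2, 1, ch[1], "leaky_relu"),
      layer_spec("conv", 4, 2, 1, ch[2], "leaky_relu"),
      layer_spec("conv", 10, 1, 0, ch[3], "leaky_relu"),
      layer_spec("conv", 4, 2, 1, ch[4], "leaky_relu"),
      layer_spec("conv", 4, 2, 1, ch[5], "leaky_relu"),
      layer_spec("conv", 8, 2, 1, 1, "none"))
  } else {
    s <- as.integer(image_size)
    if (s %% 8L != 0L || s < 24L)
      stop("scaled classifier needs image_size a multiple of 8, >= 24")
    ch <- vapply(c(16, 32, 64), scale_ch, integer(1), width)
    layers <- list(
      layer_spec("conv", 4, 2, 1, ch[1], "leaky_relu"),
      layer_spec("conv", 4, 2, 1, ch[2], "leaky_relu"),
      layer_spec("conv", 4, 2, 1, ch[3], "leaky_relu"),
      layer_spec("conv", s %/% 8L - 1L, 2, 1, 1, "none"))
  }
  layers <- place_norm(layers, normalization)
  network_spec("classifier", layers, n,
               c(as.integer(image_size), as.integer(image_size), n))
}

#' Attach class-conditioning information to an input
#'
#' For the generator, the 2-value one-hot label (HC = `c(1, 0)`,
#' AB = `c(0, 1)`) is appended to each latent vector.  For the
#' discriminator, the label is broadcast as one constant-valued extra input
#' channel, so the critic sees `n + 1` channels.
#'
#' @param x For `role = "generator"` a `latent_dim x batch` matrix of noise;
#'   for `role = "discriminator"` an `H x W x C x batch` array.
#' @param labels Integer vector of 0/1 class labels, one per batch element.
#' @param role `"generator"` or `"discriminator"`.
#' @return The conditioned input (matrix or array with one extra channel).
#' @export
condition_inputs <- function(x, labels, role = c("generator",
                                                 "discriminator")) {
  role <- match.arg(role)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 (HC) or 1 (AB)")
  if (role == "generator") {
    stopifnot(is.matrix(x), ncol(x) == length(labels))
    onehot <- rbind(1 - labels, labels)
    rbind(x, onehot)
  } else {
    d <- dim(x)
    stopifnot(length(d) == 4, d[4] == length(labels))
    out <- array(0, c(d[1], d[2], d[3] + 1L, d[4]))
    out[, , seq_len(d[3]), ] <- x
    for (b in seq_len(d[4])) out[, , d[3] + 1L, b] <- labels[b]
    out
  }
}

# Latent prior: standard normal noise of length 100 * n per sample.
sample_latent <- function(n_modalities, batch) {
  matrix(stats::rnorm(100L * n_modalities * batch), 100L * n_modalities,
         batch)
}

# Present a latent matrix (possibly conditioned) as a 1 x 1 x C x B tensor.
latent_to_tensor <- function(z) {
  out <- z
  dim(out) <- c(1L, 1L, nrow(z), ncol(z))
  out
}
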