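# Network construction. Layers are environments so that batch-norm running
# moments can be updated in place during training; weights are stored as
# vol2col matrices (K x Cout, K = Cin * k^3).

new_conv_layer <- function(cin, cout, k, stride, pad, bias = TRUE,
                           norm = c("batch", "none"),
                           act = c("relu", "lrelu", "tanh", "none"),
                           slope = 0.2, name = "conv") {
  norm <- match.arg(norm); act <- match.arg(act)
  fan_in <- cin * k^3
  gain <- switch(act, relu = sqrt(2), lrelu = sqrt(2 / (1 + slope^2)), 1)
  l <- new.env(parent = emptyenv())
  l$name <- name
  l$cin <- cin; l$cout <- cout
  l$k <- k; l$stride <- stride; l$pad <- pad
  l$act <- act; l$slope <- slope; l$norm <- norm
  l$W <- matrix(rnorm(fan_in * cout, sd = gain / sqrt(fan_in)), fan_in, cout)
  l$b <- if (bias) numeric(cout) else NULL
  if (norm == "batch") {
    l$gamma <- rep(1, cout); l$beta <- numeric(cout)
    l$run_mean <- numeric(cout); l$run_var <- rep(1, cout)
  }
  class(l) <- "fd_layer"
  l
}

layer_param_names <- function(l) {
  nms <- c("W", if (!is.null(l$b)) "b",
           if (identical(l$norm, "batch")) c("gamma", "beta"))
  nms
}

# apply conv (+ optional BN + activation); pw gives wrapped parameter nodes
apply_layer <- function(tape, x, l, training = FALSE, pw = NULL) {
  W <- if (!is.null(pw)) pw$W else l$W
  b <- if (!is.null(pw) && !is.null(pw$b)) pw$b else l$b
  if (is.null(b)) b <- numeric(l$cout)
  y <- op_conv3d(tape, x, W, b, l$k, l$stride, l$pad)
  if (identical(l$norm, "batch")) {
    gamma <- if (!is.null(pw)) pw$gamma else l$gamma
    beta <- if (!is.null(pw)) pw$beta else l$beta
    y <- op_batchnorm(tape, y, gamma, beta, l, training)
  }
  switch(l$act,
    relu = op_relu(tape, y),
    lrelu = op_leaky_relu(tape, y, l$slope),
    tanh = op_tanh(tape, y),
    y
  )
}

#' Generator architecture specification
#'
#' Resolves the recorded full-scale fusion plan for a dataset scheme: a
#' three-convolution 32-map stem, strided-convolution encoder with widths
#' 64/128/256/512 (refinement-conv multiplicities per scale as recorded in
#' the package config), five scales, 32-channel skip branches from every
#' scale into every decoder step (5 x 32 = 160 fused maps), interpolation
#' upsampling, and a final hyperbolic-tangent convolution.
#'
#' @param scheme Dataset scheme `"A"`, `"B"` or `"C"` (7 / 2 / 1 input
#'   channels at inference).
#' @param width_mult Width multiplier for desk-scale runs; 1 reproduces the
#'   full architecture.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(scheme = c("A", "B", "C"), width_mult = 1) {
  scheme <- match.arg(scheme)
  cfg <- fd_config()$generator
  w <- function(x) pmax(1L, as.integer(round(x * width_mult)))
  scale_ch <- c(w(cfg$stem_width), w(cfg$encoder_widths))
  skip <- w(cfg$skip_width)
  structure(list(
    scheme = scheme,
    in_channels = cfg$in_channels[[scheme]],
    kernel = cfg$kernel,
    stem_convs = cfg$stem_convs,
    scale_channels = scale_ch,
    refine = as.integer(cfg$encoder_refine_convs),
    skip = skip,
    fused = 5L * skip,
    width_mult = width_mult
  ), class = "generator_spec")
}

#' Discriminator architecture specification
#'
#' Three stride-2 and two stride-1 4^3 convolutions with the recorded
#' channel ladder; every output element has a 70-voxel receptive field per
#' axis.
#'
#' @inheritParams generator_spec
#' @return A `discriminator_spec` list.
#' @export
discriminator_spec <- function(scheme = c("A", "B", "C"), width_mult = 1) {
  scheme <- match.arg(scheme)
  cfg <- fd_config()$discriminator
  w <- function(x) pmax(1L, as.integer(round(x * width_mult)))
  structure(list(
    scheme = scheme,
    in_channels = cfg$in_channels[[scheme]],
    kernel = cfg$kernel,
    strides = as.integer(cfg$strides),
    widths = w(cfg$widths),
    slope = cfg$leaky_slope,
    width_mult = width_mult
  ), class = "discriminator_spec")
}

#' Build the full-scale feature-fusion generator
#'
#' Encoder: a stem of three 3^3 convolutions producing the scale-1 features,
#' then one strided 3^3 convolution per scale (replacing max-pooling) with
#' the recorded number of refinement convolutions. Decoder: each step fuses
#' five same-size 32-channel branches drawn from all encoder scales and all
#' lower decoder scales (downsampled by average pooling or upsampled by
#' trilinear interpolation, then convolved), concatenated to 160 maps and
#' merged by a 3^3 fusion convolution. The output convolution ends in tanh,
#' so predictions live in (-1, 1).
#'
#' @param spec A [generator_spec()].
#' @param seed Seed for Kaiming-initialized weights.
#' @return An `fd_network` of kind `"generator"`.
#' @export
build_generator <- function(spec = generator_spec(), seed = 1L) {
  with_seed(seed, {
    k <- spec$kernel
    ch <- spec$scale_channels
    layers <- list()
    cin <- spec$in_channels
    for (i in seq_len(spec$stem_convs)) {
      nm <- paste0("stem_", i)
      layers[[nm]] <- new_conv_layer(cin, ch[1], k, 1, 1, name = nm)
      cin <- ch[1]
    }
    for (s in 2:5) {
      nm <- paste0("enc", s, "_down")
      layers[[nm]] <- new_conv_layer(ch[s - 1], ch[s], k, 2, 1, name = nm)
      nref <- spec$refine[s - 1]
      if (nref > 0) for (r in seq_len(nref)) {
        nm <- paste0("enc", s, "_ref", r)
        layers[[nm]] <- new_conv_layer(ch[s], ch[s], k, 1, 1, name = nm)
      }
    }
    for (s in 4:1) {
      srcs <- decoder_sources(s, ch, spec$fused)
      for (j in seq_along(srcs)) {
        nm <- sprintf("dec%d_br%d", s, j)
        layers[[nm]] <- new_conv_layer(srcs[[j]]$ch, spec$skip, k, 1, 1, name = nm)
      }
      nm <- sprintf("dec%d_fuse", s)
      layers[[nm]] <- new_conv_layer(spec$fused, spec$fused, k, 1, 1, name = nm)
    }
    layers$final <- new_conv_layer(spec$fused, 1L, k, 1, 1, norm = "none",
                                   act = "tanh", name = "final")
    structure(list(kind = "generator", spec = spec, layers = layers,
                   introspect = new.env(parent = emptyenv())),
              class = "fd_network")
  })
}

# sources feeding decoder step s: encoders 1..s, then decoders s+1..5
# (decoder 5 is the deepest encoder output itself)
decoder_sources <- function(s, ch, fused) {
  srcs <- lapply(seq_len(s), function(t) list(kind = "enc", scale = t, ch = ch[t]))
  if (s < 4) for (u in (s + 1):4)
    srcs <- c(srcs, list(list(kind = "dec", scale = u, ch = fused)))
  c(srcs, list(list(kind = "enc", scale = 5L, ch = ch[5])))
}

#' Build the 3D patch discriminator
#'
#' A fully convolutional classifier over overlapping 3D patches: 4^3
#' convolutions with strides (2,2,2,1,1), LeakyReLU activations, batch
#' normalization on the middle layers, and a final 1-channel logit map in
#' which each element has a 70^3-voxel receptive field.
#'
#' @param spec A [discriminator_spec()].
#' @param seed Seed for Kaiming-initialized weights.
#' @return An `fd_network` of kind `"discriminator"`.
#' @export
build_discriminator <- function(spec = discriminator_spec(), seed = 1L) {
  with_seed(seed, {
    k <- spec$kernel
    widths <- c(spec$widths, 1L)
    layers <- list()
    cin <- spec$in_channels
    for (i in seq_along(widths)) {
      nm <- paste0("d", i)
      last <- i == length(widths)
      nrm <- if (i > 1 && !last) "batch" else "none"
      layers[[nm]] <- new_conv_layer(
        cin, widths[i], k, spec$strides[i], 1,
        bias = nrm == "none",      # batch-normed convolutions carry no bias
        norm = nrm,
        act = if (last) "none" else "lrelu",
        slope = spec$slope, name = nm
      )
      cin <- widths[i]
    }
    structure(list(kind = "discriminator", spec = spec, layers = layers,
                   introspect = new.env(parent = emptyenv())),
              class = "fd_network")
  })
}

#' @export
print.fd_network <- function(x, ...) {
  cat(sprintf("<fd_network> %s (%s, width x%g): %d layers, %s trainable parameters\n",
              x$kind, x$spec$scheme, x$spec$width_mult, length(x$layers),
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' Sums every trainable scalar: convolution weights and biases and the
#' batch-norm affine parameters.
#'
#' @param network An `fd_network`, a single layer, or a list of layers.
#' @return Integer count.
#' @export
count_parameters <- function(network) {
  layers <- if (inherits(network, "fd_network")) network$layers
            else if (inherits(network, "fd_layer")) list(network)
            else network
  total <- 0
  for (l in layers)
    for (nm in layer_param_names(l)) total <- total + length(l[[nm]])
  as.integer(total)
}

#' Analytic receptive-field extent of a convolution stack
#'
#' For kernel sizes k_i and strides s_i, the receptive field of one output
#' element is `1 + sum_i (k_i - 1) * prod_{j<i} s_j` voxels per axis.
#'
#' @param kernels Integer vector of kernel edges.
#' @param strides Integer vector of strides (same length).
#' @return Integer extent per axis.
#' @export
receptive_field_extent <- function(kernels, strides) {
  stopifnot(length(kernels) == length(strides))
  jumps <- cumprod(c(1, utils::head(strides, -1)))
  as.integer(1 + sum((kernels - 1) * jumps))
}

#' Spatial shape of the discriminator logit map
#'
#' @param spec A [discriminator_spec()].
#' @param input_size Input spatial extent per axis (scalar or length 3).
#' @return Integer length-3 output extent.
#' @export
discriminator_output_shape <- function(spec, input_size) {
  n <- rep_len(as.integer(input_size), 3L)
  for (s in spec$strides) n <- (n + 2L - spec$kernel) %/% s + 1L
  n
}

# ---- forward passes --------------------------------------------------------

ensure_batch <- function(x) {
  if (length(dim(x)) == 4L) dim(x) <- c(dim(x), 1L)
  x
}

#' Run the generator
#'
#' @param net Generator built by [build_generator()].
#' @param x Input array (x, y, z, channels\[, batch\]) of normalized values;
#'   spatial extents must be divisible by 16 (four halvings).
#' @param tape Optional autograd tape (training); NULL for inference.
#' @param training Use batch statistics and update running moments.
#' @param wrapped Optional wrapped parameter nodes (internal, training).
#' @return Array or tape node of shape (x, y, z, 1, batch) in (-1, 1).
#' @export
generator_forward <- function(net, x, tape = NULL, training = FALSE,
                              wrapped = NULL) {
  x <- ensure_batch(ag_val(x))
  d <- dim(x)[1:3]
  if (any(d %% 16L != 0L))
    stop("generator input spatial size must be divisible by 16")
  if (dim(x)[4] != net$spec$in_channels)
    stop(sprintf("generator expects %d input channels, got %d",
                 net$spec$in_channels, dim(x)[4]))
  L <- net$layers
  pw <- function(nm) if (!is.null(wrapped)) wrapped[[nm]] else NULL
  h <- x
  for (i in seq_len(net$spec$stem_convs)) {
    nm <- paste0("stem_", i)
    h <- apply_layer(tape, h, L[[nm]], training, pw(nm))
  }
  enc <- list(h)                      # scale-1 features
  for (s in 2:5) {
    nm <- paste0("enc", s, "_down")
    h <- apply_layer(tape, h, L[[nm]], training, pw(nm))
    r <- 1
    while (!is.null(L[[paste0("enc", s, "_ref", r)]])) {
      nm <- paste0("enc", s, "_ref", r)
      h <- apply_layer(tape, h, L[[nm]], training, pw(nm))
      r <- r + 1
    }
    enc[[s]] <- h
  }
  dec <- list()                       # decoder outputs by scale (4..1)
  concat_channels <- integer(0)
  for (s in 4:1) {
    srcs <- decoder_sources(s, net$spec$scale_channels, net$spec$fused)
    target <- d %/% (2L^(s - 1L))
    branches <- vector("list", length(srcs))
    for (j in seq_along(srcs)) {
      src <- srcs[[j]]
      feat <- if (src$kind == "enc") enc[[src$scale]] else dec[[src$scale]]
      if (src$scale < s) {
        feat <- op_avgpool(tape, feat, 2L^(s - src$scale))
      } else if (src$scale > s) {
        feat <- op_resize(tape, feat, target)
      }
      nm <- sprintf("dec%d_br%d", s, j)
      branches[[j]] <- apply_layer(tape, feat, L[[nm]], training, pw(nm))
    }
    cat_in <- op_concat(tape, branches)
    concat_channels <- c(concat_channels, dim(ag_val(cat_in))[4])
    nm <- sprintf("dec%d_fuse", s)
    dec[[s]] <- apply_layer(tape, cat_in, L[[nm]], training, pw(nm))
  }
  net$introspect$concat_channels <- concat_channels
  apply_layer(tape, dec[[1]], L$final, training, pw("final"))
}

#' Run the discriminator
#'
#' @param net Discriminator built by [build_discriminator()].
#' @param x Input array (x, y, z, channels\[, batch\]) -- the conditioning
#'   stack concatenated with a dose channel. May be a tape node (so generator
#'   gradients can flow through).
#' @inheritParams generator_forward
#' @return The patch logit map, shape (px, py, pz, 1, batch).
#' @export
discriminator_forward <- function(net, x, tape = NULL, training = FALSE,
                                  wrapped = NULL) {
  if (!is_node(x)) x <- ensure_batch(x)
  h <- x
  for (nm in names(net$layers)) {
    l <- net$layers[[nm]]
    sz <- dim(ag_val(h))[1:3]
    if (any((sz + 2L - l$k) %/% l$stride + 1L < 1L))
      stop("discriminator input smaller than its receptive field stack")
    h <- apply_layer(tape, h, l, training,
                     if (!is.null(wrapped)) wrapped[[nm]] else NULL)
  }
  h
}

# ---- parameter plumbing for the optimizer ---------------------------------

# flat named list of parameter arrays ("layer/slot")
net_params <- function(net) {
  out <- list()
  for (nm in names(net$layers)) {
    l <- net$layers[[nm]]
    for (p in layer_param_names(l)) out[[paste(nm, p, sep = "/")]] <- l[[p]]
  }
  out
}

set_net_params <- function(net, params) {
  for (key in names(params)) {
    parts <- strsplit(key, "/", fixed = TRUE)[[1]]
    net$layers[[parts[1]]][[parts[2]]] <- params[[key]]
  }
  invisible(net)
}

# wrap every parameter as a tape leaf; returns per-layer node lists
wrap_network <- function(tape, net) {
  out <- list()
  for (nm in names(net$layers)) {
    l <- net$layers[[nm]]
    w <- list()
    for (p in layer_param_names(l)) w[[p]] <- ag_leaf(tape, l[[p]])
    out[[nm]] <- w
  }
  out
}

# extract gradient arrays for wrapped params (zero where never touched)
wrapped_grads <- function(wrapped, grads, net) {
  out <- list()
  for (nm in names(wrapped)) {
    for (p in names(wrapped[[nm]])) {
      g <- grads[[wrapped[[nm]][[p]]$id]]
      if (is.null(g)) g <- array(0, dim(as.array(net$layers[[nm]][[p]])))
      out[[paste(nm, p, sep = "/")]] <- g
    }
  }
  out
}

# serializable network state (weights + batch-norm running moments)
network_state <- function(net) {
  st <- list()
  for (nm in names(net$layers)) {
    l <- net$layers[[nm]]
    slots <- c(layer_param_names(l),
               if (identical(l$norm, "batch")) c("run_mean", "run_var"))
    st[[nm]] <- mget(slots, envir = l)
  }
  st
}

restore_network_state <- function(net, state) {
  for (nm in names(state))
    for (p in names(state[[nm]]))
      net$layers[[nm]][[p]] <- state[[nm]][[p]]
  invisible(net)
}
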