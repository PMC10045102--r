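# Compact trainable regularization network and its exact reverse-mode
# gradients. The network is a small encoder-decoder with skip connections
# ("U-Net" style): per scale one 3x3 convolution + ReLU, 2x2 average-pool
# downsampling, nearest-neighbor upsampling, channel concatenation with the
# skip, and a zero-initialized output convolution feeding a residual
# connection, so a freshly initialized network is the identity map.
#
# Complex images enter as two real channels (real, imaginary) and leave the
# same way; everything in between is real-valued. Convolutions are computed
# as im2col patch-matrix products in compiled code, and the backward pass is
# hand-derived and checked against finite differences in the test suite.

#' Denoiser architecture descriptor
#'
#' Size of the regularization network: number of resolution scales and base
#' channel count (channels double per scale). The default (2 scales, 8 base
#' channels) is a compact desk-scale network; both knobs scale the model up.
#'
#' @param n_scales number of resolution scales (>= 1).
#' @param base_channels channels at the finest scale.
#' @param kernel odd convolution kernel size (default 3).
#' @return object of class `denoiser_spec`.
#' @export
denoiser_spec <- function(n_scales = 2L, base_channels = 8L, kernel = 3L) {
  if (n_scales < 1L) stop("n_scales must be >= 1", call. = FALSE)
  if (kernel %% 2L != 1L) stop("kernel size must be odd", call. = FALSE)
  structure(list(n_scales = as.integer(n_scales),
                 base_channels = as.integer(base_channels),
                 kernel = as.integer(kernel)),
            class = "denoiser_spec")
}

# Layer plan: name, input channels, output channels.
denoiser_plan <- function(spec) {
  S <- spec$n_scales
  C <- as.integer(spec$base_channels * 2^(seq_len(S) - 1L))
  layers <- list(list(name = "enc1", cin = 2L, cout = C[1]))
  if (S > 1L) {
    for (s in 2:S) {
      layers <- c(layers, list(list(name = paste0("enc", s),
                                    cin = C[s - 1L], cout = C[s])))
    }
    for (s in (S - 1L):1L) {
      layers <- c(layers, list(list(name = paste0("dec", s),
                                    cin = C[s + 1L] + C[s], cout = C[s])))
    }
  }
  c(layers, list(list(name = "out", cin = C[1], cout = 2L)))
}

#' Initialize denoiser weights
#'
#' He-normal initialization for the hidden convolutions; the output
#' convolution is zero-initialized so the residual network starts as the
#' identity.
#'
#' @param spec a `denoiser_spec`.
#' @param seed integer seed.
#' @return a `model_weights` object: named list of parameter arrays
#'   (`<layer>.K` kernel matrices, `<layer>.b` biases).
#' @export
init_denoiser <- function(spec, seed = 1L) {
  k <- spec$kernel
  w <- list()
  with_seed(derive_seed(seed, 41L), {
    for (ly in denoiser_plan(spec)) {
      n_in <- k * k * ly$cin
      K <- if (ly$name == "out") {
        matrix(0, n_in, ly$cout)
      } else {
        matrix(stats::rnorm(n_in * ly$cout, 0, sqrt(2 / n_in)), n_in, ly$cout)
      }
      w[[paste0(ly$name, ".K")]] <- K
      w[[paste0(ly$name, ".b")]] <- numeric(ly$cout)
    }
  })
  structure(w, class = "model_weights")
}

#' Apply the regularization network to a complex image
#'
#' Splits the complex image into real/imaginary channels, runs the
#' encoder-decoder, and adds the network output back to the input (residual
#' connection). Spatial dimensions must be divisible by `2^(n_scales - 1)`.
#'
#' @param x complex `H x W` image.
#' @param weights a `model_weights` collection conformable with `spec`.
#' @param spec a `denoiser_spec`.
#' @return complex `H x W` image of the same shape.
#' @export
denoise <- function(x, weights, spec) {
  denoise_check(x, weights, spec)
  lw <- weights_as_lists(weights, spec)
  cpp_denoise_forward(x + 0i, lw$Ks, lw$bs, spec$n_scales, spec$kernel,
                      NULL, 0L, FALSE)
}

denoise_check <- function(x, weights, spec) {
  H <- nrow(x); W <- ncol(x)
  div <- 2L^(spec$n_scales - 1L)
  if (H %% div != 0L || W %% div != 0L) {
    stop("image size not divisible by the scale factor of the denoiser",
         call. = FALSE)
  }
  check_conformable(weights, spec)
  invisible(TRUE)
}

# Weights as layer-ordered kernel/bias lists for the compiled passes.
weights_as_lists <- function(weights, spec) {
  plan <- denoiser_plan(spec)
  list(Ks = lapply(plan, function(l) weights[[paste0(l$name, ".K")]]),
       bs = lapply(plan, function(l) weights[[paste0(l$name, ".b")]]),
       names = vapply(plan, function(l) l$name, character(1)))
}

# Training-path forward: stores per-layer activations in `cache` (an external
# pointer from den_cache_new) under the given slot.
den_cache_new <- function(n_slots) cpp_den_cache_new(as.integer(n_slots))

denoise_train <- function(x, lw, spec, cache, slot) {
  cpp_denoise_forward(x + 0i, lw$Ks, lw$bs, spec$n_scales, spec$kernel,
                      cache, as.integer(slot - 1L), TRUE)
}

# Backward pass: `g` carries (d/d Re, d/d Im) of a real scalar loss with
# respect to the complex output. Returns the input gradient in the same
# convention plus named per-parameter gradients (the residual connection
# contributes the identity term).
denoise_backward <- function(g, lw, spec, cache, slot) {
  bk <- cpp_denoise_backward(g + 0i, lw$Ks, spec$n_scales, spec$kernel,
                             cache, as.integer(slot - 1L))
  gw <- vector("list", 2L * length(lw$names))
  nms <- character(2L * length(lw$names))
  for (i in seq_along(lw$names)) {
    nms[2L * i - 1L] <- paste0(lw$names[i], ".K")
    nms[2L * i] <- paste0(lw$names[i], ".b")
    gw[[2L * i - 1L]] <- bk$gK[[i]]
    gw[[2L * i]] <- as.numeric(bk$gb[[i]])
  }
  names(gw) <- nms
  list(g_in = bk$g_in, gw = gw)
}

check_conformable <- function(weights, spec) {
  for (ly in denoiser_plan(spec)) {
    K <- weights[[paste0(ly$name, ".K")]]
    if (is.null(K) || nrow(K) != spec$kernel^2 * ly$cin || ncol(K) != ly$cout) {
      stop(sprintf("weights not conformable with denoiser_spec at layer %s",
                   ly$name), call. = FALSE)
    }
  }
  invisible(TRUE)
}
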