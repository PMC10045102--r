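# Unrolled model-based reconstruction: a fixed-depth alternation of
# conjugate-gradient data consistency and the learned regularization network,
# trained end to end with a negative-SSIM objective on coil-combined
# magnitude images. One weight collection is shared across all unrolls, so
# the parameter count is independent of the unroll depth.
#
# Gradients flow through the data-consistency solve via the implicit
# (adjoint linear-system) rule: for z = (A^H A + lam I)^{-1} (A^H y + lam x)
# the Jacobian with respect to x is lam (A^H A + lam I)^{-1}, itself applied
# with the same fixed-iteration CG routine.

#' Unrolled reconstruction configuration
#'
#' @param n_unrolls number of unrolls (data-consistency + denoiser
#'   repetitions); default 6.
#' @param n_cg CG iterations per data-consistency block; default 6.
#' @param lam positive coupling weight of the data-consistency solve;
#'   default 0.05.
#' @param denoiser a `denoiser_spec` describing the regularization network.
#' @return object of class `unroll_config`.
#' @export
unroll_config <- function(n_unrolls = 6L, n_cg = 6L, lam = 0.05,
                          denoiser = denoiser_spec()) {
  if (n_unrolls < 1L) stop("n_unrolls must be >= 1", call. = FALSE)
  if (n_cg < 1L) stop("n_cg must be >= 1", call. = FALSE)
  if (lam <= 0) stop("lam must be positive", call. = FALSE)
  structure(list(n_unrolls = as.integer(n_unrolls), n_cg = as.integer(n_cg),
                 lam = lam, denoiser = denoiser),
            class = "unroll_config")
}

# Forward pass, optionally caching denoiser activations for the backward
# pass (the cache lives behind an external pointer; one slot per unroll).
modl_forward <- function(sample, weights, cfg, keep_cache = FALSE,
                         keep_intermediates = !keep_cache) {
  sample <- normalize_sample(sample)
  op <- forward_operator(sample$sens_maps, sample$mask)
  y <- sample$kspace
  x <- apply_AH(y, op)
  denoise_check(x, weights, cfg$denoiser)
  lw <- weights_as_lists(weights, cfg$denoiser)
  cache <- if (keep_cache) den_cache_new(cfg$n_unrolls) else NULL
  inter <- if (keep_intermediates) vector("list", cfg$n_unrolls) else NULL
  for (n in seq_len(cfg$n_unrolls)) {
    z <- cg_data_consistency(x, y, op, cfg$lam, cfg$n_cg)
    x <- if (keep_cache) {
      denoise_train(z, lw, cfg$denoiser, cache, n)
    } else {
      cpp_denoise_forward(z, lw$Ks, lw$bs, cfg$denoiser$n_scales,
                          cfg$denoiser$kernel, NULL, 0L, FALSE)
    }
    if (keep_intermediates) inter[[n]] <- x
  }
  list(x = x, op = op, sample = sample, lw = lw, cache = cache,
       intermediates = inter)
}

#' Reconstruct a slice with the unrolled model
#'
#' Starting from the zero-filled adjoint image `x0 = A^H y`, alternates
#' `n_unrolls` times between the CG data-consistency solve and the learned
#' denoiser, sharing one weight collection across all unrolls.
#'
#' @param sample a `multicoil_sample` (normalized internally if needed).
#' @param weights a `model_weights` collection.
#' @param cfg an `unroll_config`.
#' @param intermediates if TRUE, also return the image after every unroll.
#' @return complex `H x W` reconstruction, or a list with `x` and
#'   `intermediates` when requested.
#' @export
modl_reconstruct <- function(sample, weights, cfg, intermediates = FALSE) {
  fw <- modl_forward(sample, weights, cfg, keep_cache = FALSE,
                     keep_intermediates = intermediates)
  if (intermediates) list(x = fw$x, intermediates = fw$intermediates) else fw$x
}

# Coil-combined magnitude image of a reconstruction: |x| weighted by the
# root-sum-of-squares of the sensitivity maps (identically 1 inside the
# normalized-map support).
rss_project <- function(x, sens_maps) {
  sos <- sqrt(rowSums(Mod(sens_maps)^2, dims = 2L))
  sos * Mod(x)
}

#' Training loss: negative SSIM
#'
#' `-SSIM` between the coil-combined magnitude of the reconstruction and the
#' reference root-sum-of-squares image, with the data range set by the
#' reference maximum. Bounded in `[-1, 1]`; equals -1 iff the magnitudes
#' match exactly.
#'
#' @param recon complex `H x W` reconstruction.
#' @param sample the (normalized) `multicoil_sample` it was computed from.
#' @return scalar loss.
#' @export
train_loss <- function(recon, sample) {
  sample <- normalize_sample(sample)
  m <- rss_project(recon, sample$sens_maps)
  -ssim(sample$target_rss, m)
}

# Loss + full end-to-end gradient with respect to the weights.
modl_loss_grad <- function(sample, weights, cfg) {
  fw <- modl_forward(sample, weights, cfg, keep_cache = TRUE,
                     keep_intermediates = FALSE)
  sample <- fw$sample
  sos <- sqrt(rowSums(Mod(sample$sens_maps)^2, dims = 2L))
  m <- sos * Mod(fw$x)
  tgt <- sample$target_rss
  sg <- ssim_value_grad(tgt, m)
  loss <- -sg$mssim
  g_m <- -sg$grad
  mod_x <- Mod(fw$x)
  scale <- ifelse(mod_x > 0, g_m * sos / mod_x, 0)
  g <- scale * fw$x  # complex carrier of (d/dRe, d/dIm)
  grad <- NULL
  for (n in cfg$n_unrolls:1L) {
    bk <- denoise_backward(g, fw$lw, cfg$denoiser, fw$cache, n)
    grad <- if (is.null(grad)) bk$gw else mapply(`+`, grad, bk$gw, SIMPLIFY = FALSE)
    g <- cfg$lam * cg_solve_gram(bk$g_in, fw$op, cfg$lam, cfg$n_cg)
  }
  grad <- grad[names(weights)]  # align parameter order with the weights
  list(loss = loss, grad = structure(grad, class = "model_weights"),
       recon = fw$x)
}

#' Train the model locally
#'
#' Runs `n_steps` single-sample gradient steps over a local dataset with the
#' adaptive-moment (Adam) or plain SGD optimizer. The sample order is a
#' seeded shuffle per epoch. A `grad_transform` hook is applied to the raw
#' gradient before it enters the optimizer (used for the Scaffold drift
#' correction).
#'
#' @param weights initial `model_weights`.
#' @param dataset non-empty list of `multicoil_sample` objects.
#' @param n_steps number of gradient steps (>= 1).
#' @param lr local learning rate (default 1e-4).
#' @param cfg an `unroll_config`.
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param opt_state optional optimizer state to resume from.
#' @param seed integer seed controlling the sample shuffle.
#' @param grad_transform optional function applied to each raw gradient.
#' @param record_loss if TRUE, keep the per-step loss trace.
#' @param return_mean_grad if TRUE, also return the mean of the raw
#'   per-step gradients (before `grad_transform`), as required by the
#'   Scaffold control-variate update under adaptive local optimizers.
#' @return list with `weights`, `opt_state`, `losses` (NULL unless recorded),
#'   `mean_grad` (NULL unless requested), and `n_steps`.
#' @export
local_train <- function(weights, dataset, n_steps, lr = 1e-4, cfg,
                        optimizer = c("adam", "sgd"), opt_state = NULL,
                        seed = 1L, grad_transform = NULL,
                        record_loss = FALSE, return_mean_grad = FALSE) {
  optimizer <- match.arg(optimizer)
  if (length(dataset) == 0L) stop("empty local dataset", call. = FALSE)
  if (n_steps < 1L) stop("n_steps must be >= 1", call. = FALSE)
  dataset <- lapply(dataset, normalize_sample)
  if (optimizer == "adam" && is.null(opt_state)) opt_state <- adam_init(weights)
  losses <- if (record_loss) numeric(n_steps) else NULL
  grad_sum <- if (return_mean_grad) weights_zero_like(weights) else NULL
  step <- 0L
  epoch <- 0L
  while (step < n_steps) {
    epoch <- epoch + 1L
    ord <- with_seed(derive_seed(seed, 53L, epoch), sample.int(length(dataset)))
    for (i in ord) {
      step <- step + 1L
      lg <- modl_loss_grad(dataset[[i]], weights, cfg)
      g <- lg$grad
      if (return_mean_grad) grad_sum <- weights_map(`+`, grad_sum, g)
      if (!is.null(grad_transform)) g <- grad_transform(g)
      if (optimizer == "adam") {
        st <- adam_step(weights, g, opt_state, lr)
        weights <- st$weights
        opt_state <- st$state
      } else {
        weights <- sgd_step(weights, g, lr)
      }
      if (record_loss) losses[step] <- lg$loss
      if (step >= n_steps) break
    }
  }
  list(weights = weights, opt_state = opt_state, losses = losses,
       mean_grad = if (return_mean_grad) weights_scale(1 / n_steps, grad_sum),
       n_steps = n_steps)
}
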