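# Image-quality metrics: mean structural similarity (SSIM) with its exact
# reverse-mode gradient (needed because the unrolled model trains on a
# negative-SSIM objective), normalized root mean squared error, and the
# half-away-from-zero percent-change formatting used in the summary tables.
#
# SSIM convention: 7x7 uniform windows fully contained in the image ("valid"
# windows), sample-covariance normalization (N/(N-1)), k1 = 0.01, k2 = 0.03,
# data range = maximum of the reference image. This is the convention used by
# the standard accelerated-MRI evaluation stack.

# Sliding-window sums over all w x w windows fully inside x (compiled
# summed-area table). Returns an (H-w+1) x (W-w+1) matrix.
box_sum_valid <- function(x, w) cpp_box_sum_valid(x, as.integer(w))

# Adjoint of the valid sliding-window sum: scatter each window value back
# over its w x w footprint (a "full" box convolution).
box_sum_adjoint <- function(g, w, H, W) {
  pad <- matrix(0, H + w - 1L, W + w - 1L)
  pad[w:(w + nrow(g) - 1L), w:(w + ncol(g) - 1L)] <- g
  box_sum_valid(pad, w)
}

#' Mean structural similarity index (SSIM)
#'
#' Mean local SSIM between a reference magnitude image `a` and a test image
#' `b`, computed over all `win x win` uniform windows fully contained in the
#' image, with sample-covariance normalization and luminance/contrast
#' constants `C1 = (k1 L)^2`, `C2 = (k2 L)^2` where `L` is the data range
#' (default: maximum of the reference).
#'
#' @param a reference magnitude image (nonnegative matrix).
#' @param b test magnitude image, same shape.
#' @param data_range dynamic range `L`; defaults to `max(a)`.
#' @param win odd window size (default 7).
#' @param k1,k2 stability constants (defaults 0.01 and 0.03).
#' @return scalar in `[-1, 1]`.
#' @export
ssim <- function(a, b, data_range = max(a), win = 7L, k1 = 0.01, k2 = 0.03) {
  ssim_stat(a, b, data_range, win, k1, k2)$mssim
}

ssim_stat <- function(a, b, data_range, win, k1, k2) {
  if (!all(dim(a) == dim(b))) stop("image shape mismatch", call. = FALSE)
  if (min(dim(a)) < win) stop("image smaller than SSIM window", call. = FALSE)
  np <- win^2
  cov_norm <- np / (np - 1)
  bx <- function(x) box_sum_valid(x, win) / np
  ux <- bx(a); uy <- bx(b)
  vx <- cov_norm * (bx(a * a) - ux^2)
  vy <- cov_norm * (bx(b * b) - uy^2)
  vxy <- cov_norm * (bx(a * b) - ux * uy)
  C1 <- (k1 * data_range)^2
  C2 <- (k2 * data_range)^2
  A1 <- 2 * ux * uy + C1
  A2 <- 2 * vxy + C2
  B1 <- ux^2 + uy^2 + C1
  B2 <- vx + vy + C2
  S <- (A1 * A2) / (B1 * B2)
  list(mssim = mean(S), S = S, ux = ux, uy = uy, A1 = A1, A2 = A2,
       B1 = B1, B2 = B2, cov_norm = cov_norm, win = win, np = np)
}

# Gradient of mean SSIM(a, b) with respect to the test image b.
ssim_grad <- function(a, b, data_range = max(a), win = 7L, k1 = 0.01, k2 = 0.03) {
  ssim_value_grad(a, b, data_range, win, k1, k2)$grad
}

# Value and gradient in one pass (the local statistics are shared).
ssim_value_grad <- function(a, b, data_range = max(a), win = 7L,
                            k1 = 0.01, k2 = 0.03) {
  st <- ssim_stat(a, b, data_range, win, k1, k2)
  n_pos <- length(st$S)
  dS <- 1 / n_pos
  den <- st$B1 * st$B2
  gA1 <- dS * st$A2 / den
  gA2 <- dS * st$A1 / den
  gB1 <- -dS * st$S / st$B1
  gB2 <- -dS * st$S / st$B2
  cn <- st$cov_norm
  # local-statistic gradients
  g_uy <- 2 * st$ux * gA1 + 2 * st$uy * gB1
  g_vy <- gB2
  g_vxy <- 2 * gA2
  # vy = cn (uyy - uy^2), vxy = cn (uxy - ux uy)
  g_uyy <- cn * g_vy
  g_uxy <- cn * g_vxy
  g_uy <- g_uy - 2 * st$uy * cn * g_vy - st$ux * cn * g_vxy
  H <- nrow(a); W <- ncol(a); np <- st$np
  adj <- function(g) box_sum_adjoint(g, win, H, W) / np
  list(mssim = st$mssim,
       grad = adj(g_uy) + 2 * b * adj(g_uyy) + a * adj(g_uxy))
}

#' Normalized root mean squared error
#'
#' `||x - x_hat||_2 / ||x||_2` over all pixels: the Euclidean norm of the
#' reconstruction error relative to the norm of the reference.
#'
#' @param x reference image (matrix or array).
#' @param x_hat reconstruction, same shape.
#' @return nonnegative scalar; 0 for a perfect reconstruction, 1 for an
#'   all-zero one.
#' @export
nrmse <- function(x, x_hat) {
  if (!all(dim(x) == dim(x_hat))) stop("image shape mismatch", call. = FALSE)
  nx <- sqrt(sum(Mod(x)^2))
  if (nx == 0) stop("reference image has zero norm", call. = FALSE)
  sqrt(sum(Mod(x - x_hat)^2)) / nx
}

# Round half away from zero at `digits` decimals (base round() rounds half to
# even, which does not reproduce the table formatting).
round_half_away <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Signed percent change
#'
#' `100 * (new - base) / base`, rounded half away from zero to `decimals`
#' decimal places — the convention used for the "Increase"/"Decrease" columns
#' of the federated-vs-centralized summary tables.
#'
#' @param base baseline value (nonzero).
#' @param new comparison value.
#' @param decimals decimal places to keep (default 2).
#' @return signed rounded percentage.
#' @export
percent_change <- function(base, new, decimals = 2L) {
  if (base == 0) stop("percent change undefined for zero baseline", call. = FALSE)
  round_half_away(100 * (new - base) / base, decimals)
}
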