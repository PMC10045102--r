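# Linear MRI operators: centered orthonormal 2-D Fourier transform, Cartesian
# phase-encode sampling masks with an auto-calibration (ACS) region, SENSE-type
# multi-coil forward/adjoint maps, ACS-based normalization, and the
# conjugate-gradient data-consistency solver used inside the unrolled model.
#
# Conventions (fixed across the package):
#   * images are complex H x W matrices; coil stacks are H x W x Nc arrays
#     with the coil axis last;
#   * the phase-encode (PE) direction is the column (last spatial) axis, so a
#     sampling mask is a binary vector over the W columns replicated down
#     each readout line;
#   * the Fourier transform is the centered (fftshifted) orthonormal 2-D
#     transform, so the adjoint equals the inverse under full sampling.

fftshift_idx <- function(n) c((floor(n / 2) + 1L):n, 1L:floor(n / 2))
ifftshift_idx <- function(n) c((ceiling(n / 2) + 1L):n, 1L:ceiling(n / 2))

# Memoized linear index maps for the centered transforms (the shift
# permutations dominate FFT cost at small image sizes otherwise).
.shift_cache <- new.env(parent = emptyenv())

shift_maps <- function(H, W) {
  key <- paste0(H, "x", W)
  hit <- .shift_cache[[key]]
  if (!is.null(hit)) return(hit)
  lin <- function(ri, ci) {
    outer(ri, (ci - 1L) * H, "+")
  }
  res <- list(fwd = lin(fftshift_idx(H), fftshift_idx(W)),
              inv = lin(ifftshift_idx(H), ifftshift_idx(W)))
  .shift_cache[[key]] <- res
  res
}

fftshift2 <- function(x) {
  m <- shift_maps(nrow(x), ncol(x))$fwd
  y <- x[m]
  dim(y) <- dim(x)
  y
}

ifftshift2 <- function(x) {
  m <- shift_maps(nrow(x), ncol(x))$inv
  y <- x[m]
  dim(y) <- dim(x)
  y
}

# Stacked centered orthonormal 2-D FFT over the first two dimensions of an
# H x W x Nc array, computed with two batched 1-D mvfft passes and cached
# shift gathers (one R-level call chain regardless of coil count).
.stack_cache <- new.env(parent = emptyenv())

stack_maps <- function(H, W, Nc) {
  key <- paste(H, W, Nc, sep = "x")
  hit <- .stack_cache[[key]]
  if (!is.null(hit)) return(hit)
  pre <- array(0L, dim = c(H, W, Nc))
  post <- array(0L, dim = c(H, W, Nc))
  ri_pre <- ifftshift_idx(H); ci_pre <- ifftshift_idx(W)
  ri_post <- fftshift_idx(H); ci_post <- fftshift_idx(W)
  plane <- outer(ri_pre, (ci_pre - 1L) * H, "+")
  plane_post <- outer(ri_post, (ci_post - 1L) * H, "+")
  for (c in seq_len(Nc)) {
    pre[, , c] <- plane + (c - 1L) * H * W
    post[, , c] <- plane_post + (c - 1L) * H * W
  }
  res <- list(pre = pre, post = post)
  .stack_cache[[key]] <- res
  res
}

fft2c_stack <- function(x, inverse = FALSE) {
  d <- dim(x); H <- d[1]; W <- d[2]; Nc <- if (length(d) == 3L) d[3] else 1L
  m <- stack_maps(H, W, Nc)
  y <- x[m$pre]
  dim(y) <- c(H, W * Nc)
  y <- stats::mvfft(y, inverse = inverse)          # along rows (dim 1)
  dim(y) <- c(H, W, Nc)
  y <- aperm(y, c(2L, 1L, 3L))
  dim(y) <- c(W, H * Nc)
  y <- stats::mvfft(y, inverse = inverse)          # along columns (dim 2)
  dim(y) <- c(W, H, Nc)
  y <- aperm(y, c(2L, 1L, 3L))
  y <- y[m$post]
  dim(y) <- d
  y / sqrt(H * W)
}

#' Centered orthonormal 2-D Fourier transform
#'
#' Forward (`fft2c`) and inverse (`ifft2c`) centered orthonormal 2-D discrete
#' Fourier transforms. The DC component sits at the matrix center and
#' `ifft2c(fft2c(x)) == x` up to round-off; both directions preserve the
#' Euclidean norm, so the adjoint of `fft2c` is `ifft2c`.
#'
#' @param x complex (or numeric) matrix.
#' @return complex matrix of the same dimension.
#' @export
fft2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(x))) / sqrt(length(x))
}

#' @rdname fft2c
#' @export
ifft2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(x), inverse = TRUE)) / sqrt(length(x))
}

#' Cartesian phase-encode under-sampling mask
#'
#' Draws a 1-D random under-sampling pattern over `n_pe` phase-encode lines
#' with a fully sampled, contiguous, centered auto-calibration (ACS) block of
#' `round(acs_frac * n_pe)` lines. The total number of sampled lines is
#' `round(n_pe / accel_R)`; lines beyond the ACS block are drawn uniformly
#' without replacement from the remaining positions.
#'
#' @param n_pe number of phase-encode lines (>= 8).
#' @param accel_R acceleration factor (ratio of total to acquired lines).
#' @param acs_frac fraction of lines in the fully sampled central region
#'   (default 0.08, i.e. 8\% of the PE lines).
#' @param seed integer seed controlling the random line selection.
#' @return an object of class `sampling_mask`: list with `pe_flags` (0/1
#'   integer vector of length `n_pe`), `acs_width`, `acs_lines`, `accel_R`.
#' @export
make_mask <- function(n_pe, accel_R, acs_frac = 0.08, seed = 1L) {
  if (n_pe < 8L) stop("n_pe must be at least 8", call. = FALSE)
  if (accel_R < 1) stop("accel_R must be >= 1", call. = FALSE)
  n_keep <- round(n_pe / accel_R)
  acs_width <- round(acs_frac * n_pe)
  if (acs_width < 1L) acs_width <- 1L
  if (n_keep < acs_width) {
    stop(sprintf(
      "infeasible mask: sampling budget %d smaller than ACS width %d",
      n_keep, acs_width
    ), call. = FALSE)
  }
  center <- floor(n_pe / 2) + 1L
  half_lo <- floor((acs_width - 1) / 2)
  acs_lines <- (center - half_lo):(center - half_lo + acs_width - 1L)
  flags <- integer(n_pe)
  flags[acs_lines] <- 1L
  n_rand <- n_keep - acs_width
  if (n_rand > 0L) {
    pool <- setdiff(seq_len(n_pe), acs_lines)
    picked <- with_seed(seed, sample(pool, n_rand, replace = FALSE))
    flags[picked] <- 1L
  }
  structure(
    list(pe_flags = flags, acs_width = as.integer(acs_width),
         acs_lines = as.integer(acs_lines), accel_R = accel_R),
    class = "sampling_mask"
  )
}

mask_flags <- function(mask) {
  if (inherits(mask, "sampling_mask")) mask$pe_flags else as.integer(mask != 0)
}

#' SENSE-type multi-coil forward operator
#'
#' Bundles coil sensitivity maps `S`, a phase-encode sampling mask `P` and the
#' centered orthonormal Fourier transform `F` into the linear acquisition
#' operator `A = P F S` of accelerated multi-coil MRI, applied per coil.
#'
#' @param sens_maps complex `H x W x Nc` array of coil sensitivities.
#' @param mask a `sampling_mask` or a 0/1 vector over the W phase-encode
#'   columns.
#' @return object of class `forward_operator`.
#' @export
forward_operator <- function(sens_maps, mask) {
  d <- dim(sens_maps)
  if (is.null(d) || length(d) != 3L) stop("sens_maps must be H x W x Nc", call. = FALSE)
  flags <- mask_flags(mask)
  if (length(flags) != d[2]) {
    stop("mask length must equal the number of phase-encode columns", call. = FALSE)
  }
  drop0 <- as.integer(which(flags == 0L) - 1L)  # 0-based, for C++
  structure(
    list(sens_maps = sens_maps, mask = mask, pe_flags = flags,
         drop0 = drop0, kmask = cpp_mask_kernel(d[2], drop0),
         H = d[1], W = d[2], Nc = d[3]),
    class = "forward_operator"
  )
}

#' Apply the forward operator A = P F S
#'
#' Per coil: multiply the image by the coil sensitivity, take the centered
#' orthonormal 2-D Fourier transform, and zero the unsampled phase-encode
#' lines.
#'
#' @param x complex `H x W` image.
#' @param op a `forward_operator`.
#' @return complex `H x W x Nc` masked multi-coil k-space.
#' @export
apply_A <- function(x, op) {
  if (!all(dim(x) == c(op$H, op$W))) stop("image shape mismatch", call. = FALSE)
  cpp_apply_A(x + 0i, op$sens_maps, op$drop0)
}

#' Apply the adjoint operator A^H = S^H F^H P
#'
#' @param y complex `H x W x Nc` multi-coil k-space.
#' @param op a `forward_operator`.
#' @return complex `H x W` coil-combined image.
#' @export
apply_AH <- function(y, op) {
  d <- dim(y)
  if (length(d) != 3L || !all(d == c(op$H, op$W, op$Nc))) {
    stop("k-space shape mismatch", call. = FALSE)
  }
  cpp_apply_AH(y + 0i, op$sens_maps, op$drop0)
}

# Normal operator A^H A x, used by the CG solver. Equivalent to
# apply_AH(apply_A(x, op), op) but skips one masking pass.
apply_gram <- function(x, op) {
  cpp_apply_gram(x + 0i, op$sens_maps, op$kmask)
}

#' Root-sum-of-squares coil combination
#'
#' Pixelwise Euclidean norm across the coil axis, producing a nonnegative
#' magnitude image from a stack of complex coil images.
#'
#' @param coil_images complex `H x W x Nc` array (a plain `H x W` matrix is
#'   treated as a single coil).
#' @return nonnegative `H x W` matrix.
#' @export
rss <- function(coil_images) {
  if (is.matrix(coil_images)) return(Mod(coil_images))
  d <- dim(coil_images)
  out <- sqrt(rowSums(Mod(coil_images)^2, dims = 2L))
  dim(out) <- d[1:2]
  out
}

#' ACS-based normalization constant
#'
#' Zero-fills all non-ACS phase-encode lines, inverse-transforms per coil,
#' combines by root-sum-of-squares and returns the maximum pixel value. Data
#' divided by this constant have a low-resolution RSS image with unit maximum,
#' making downstream metrics invariant to global k-space scaling.
#'
#' @param kspace complex `H x W x Nc` multi-coil k-space.
#' @param acs_lines integer indices of the ACS phase-encode columns, or a
#'   `sampling_mask` whose `acs_lines` are used.
#' @return positive scalar.
#' @export
acs_rss_norm <- function(kspace, acs_lines) {
  if (inherits(acs_lines, "sampling_mask")) acs_lines <- acs_lines$acs_lines
  d <- dim(kspace)
  if (length(d) != 3L) stop("kspace must be H x W x Nc", call. = FALSE)
  klow <- array(0i, dim = d)
  klow[, acs_lines, ] <- kspace[, acs_lines, ]
  imgs <- fft2c_stack(klow, inverse = TRUE)
  nc <- max(rss(imgs))
  if (nc <= 0) stop("degenerate normalization: ACS region is identically zero", call. = FALSE)
  nc
}

#' Conjugate-gradient data-consistency solve
#'
#' Runs a fixed number of conjugate-gradient iterations on the Hermitian
#' positive-definite system `(A^H A + lam I) z = A^H y + lam x_n`, warm-started
#' at `x_n`. This is the data-consistency half-step of the unrolled model: it
#' balances fidelity to the measured k-space against proximity to the current
#' denoised iterate. The iteration count is fixed (no residual tolerance) so
#' the solve is a deterministic fixed-depth computation.
#'
#' @param x_n complex `H x W` image, the current iterate (also the CG
#'   initialization).
#' @param y complex `H x W x Nc` measured (masked) k-space.
#' @param op a `forward_operator`.
#' @param lam positive regularization weight coupling the solve to `x_n`.
#' @param n_iter number of CG iterations (>= 1).
#' @return complex `H x W` image.
#' @export
cg_data_consistency <- function(x_n, y, op, lam, n_iter) {
  if (lam <= 0) stop("lam must be positive", call. = FALSE)
  if (n_iter < 1L) stop("n_iter must be >= 1", call. = FALSE)
  stopifnot_finite(x_n, "x_n"); stopifnot_finite(y, "y")
  rhs <- apply_AH(y, op) + lam * x_n
  cg_solve_gram(rhs, op, lam, n_iter, init = x_n)
}

# CG on (A^H A + lam I) z = rhs starting from `init` (0 if NULL).
cg_solve_gram <- function(rhs, op, lam, n_iter, init = NULL) {
  use_init <- !is.null(init)
  if (!use_init) init <- matrix(0i, nrow(rhs), ncol(rhs))
  cpp_cg_gram(rhs + 0i, op$sens_maps, op$kmask, lam, as.integer(n_iter),
              init + 0i, use_init)
}
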