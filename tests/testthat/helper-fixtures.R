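# Shared fixtures: tiny multi-coil samples, dense operator materialization,
# and an independent brute-force SSIM oracle. Everything is generated in
# code at test time.

tiny_sample <- function(seed = 1L, snr_db = 20, H = 32L, W = 32L,
                        n_coils = 4L, accel_R = 4, site = 1L) {
  prof <- default_profiles(10)[[site]]
  x <- gen_phantom(prof, subject_seed = seed, slice_index = 1L, H = H, W = W)
  maps <- gen_coil_maps(n_coils, H, W, seed = seed + 1L)
  msk <- make_mask(W, accel_R, 0.08, seed = seed + 2L)
  simulate_sample(x, maps, msk, snr_db = snr_db, seed = seed + 3L)
}

tiny_cfg <- function(n_unrolls = 2L, n_cg = 4L) {
  unroll_config(n_unrolls, n_cg, 0.05, denoiser_spec(2L, 8L))
}

# Materialize A^H A as a dense N x N complex matrix by probing with deltas.
dense_gram <- function(op) {
  N <- op$H * op$W
  M <- matrix(0i, N, N)
  for (j in seq_len(N)) {
    e <- matrix(0i, op$H, op$W)
    e[j] <- 1
    M[, j] <- as.vector(apply_AH(apply_A(e, op), op))
  }
  M
}

rand_cplx <- function(H, W = NULL) {
  if (is.null(W)) {
    complex(real = stats::rnorm(H), imaginary = stats::rnorm(H))
  } else {
    matrix(complex(real = stats::rnorm(H * W), imaginary = stats::rnorm(H * W)),
           H, W)
  }
}

# Independent SSIM oracle: explicit loop over every valid window, using
# stats::var / stats::cov for the (sample-normalized) local moments.
ref_ssim <- function(a, b, data_range = max(a), win = 7L,
                     k1 = 0.01, k2 = 0.03) {
  H <- nrow(a); W <- ncol(a)
  C1 <- (k1 * data_range)^2
  C2 <- (k2 * data_range)^2
  vals <- numeric(0)
  for (i in 1:(H - win + 1L)) {
    for (j in 1:(W - win + 1L)) {
      pa <- as.vector(a[i:(i + win - 1L), j:(j + win - 1L)])
      pb <- as.vector(b[i:(i + win - 1L), j:(j + win - 1L)])
      ma <- mean(pa); mb <- mean(pb)
      vals <- c(vals, ((2 * ma * mb + C1) * (2 * stats::cov(pa, pb) + C2)) /
                  ((ma^2 + mb^2 + C1) * (stats::var(pa) + stats::var(pb) + C2)))
    }
  }
  mean(vals)
}
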