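# Synthetic multi-site data: piecewise-smooth complex ellipse phantoms with
# per-site content/contrast/noise profiles, smooth coil sensitivity maps, the
# noisy under-sampled multi-coil acquisition model, and the federation
# builder that assembles heterogeneous client datasets with subject-disjoint
# train/validation splits.
#
# The site heterogeneity axes mirror a multi-institution MRI federation:
# image content family (standing in for anatomy), contrast parameters
# (region-intensity ranges and texture, standing in for pulse-sequence
# contrast) and SNR in dB (standing in for field strength).

#' Client site profile
#'
#' Describes one data site of the federation: which phantom content family it
#' images, its contrast statistics, its acquisition SNR, and how many
#' subjects/slices it holds locally.
#'
#' @param site_id integer site identifier.
#' @param content_family one of `names(phantom_families())` — the ellipse
#'   geometry family standing in for anatomy.
#' @param contrast_params list with `intensity` (length-2 range for region
#'   intensities) and `texture_sd` (within-region texture standard deviation,
#'   0 for piecewise-constant phantoms).
#' @param snr_db acquisition signal-to-noise ratio in decibels (`Inf` for a
#'   noiseless acquisition).
#' @param n_subjects number of local training subjects (default 5).
#' @param slices_per_subject slices per subject (default 10), so the local
#'   training set holds `n_subjects * slices_per_subject` slices.
#' @return object of class `client_profile`.
#' @export
client_profile <- function(site_id, content_family, contrast_params,
                           snr_db, n_subjects = 5L, slices_per_subject = 10L) {
  if (!content_family %in% names(phantom_families())) {
    stop(sprintf("unknown content_family '%s'", content_family), call. = FALSE)
  }
  if (!is.finite(snr_db) && !identical(snr_db, Inf)) {
    stop("snr_db must be finite or Inf", call. = FALSE)
  }
  if (is.null(contrast_params$intensity) || length(contrast_params$intensity) != 2L) {
    stop("contrast_params$intensity must be a length-2 range", call. = FALSE)
  }
  if (is.null(contrast_params$texture_sd)) contrast_params$texture_sd <- 0
  structure(
    list(site_id = as.integer(site_id), content_family = content_family,
         contrast_params = contrast_params, snr_db = snr_db,
         n_subjects = as.integer(n_subjects),
         slices_per_subject = as.integer(slices_per_subject)),
    class = "client_profile"
  )
}

#' Phantom content families
#'
#' Named ellipse-geometry presets standing in for anatomical content. Each
#' family fixes the support shape and the number/size distribution of the
#' internal ellipses; contrast and noise are controlled separately by the
#' site profile.
#'
#' @return named list of geometry parameter sets.
#' @export
phantom_families <- function() {
  list(
    # round support, several mid-sized internal regions (brain-like)
    compact = list(aspect = c(0.85, 0.85), n_ell = 4L,
                   ax_range = c(0.12, 0.35), center_sd = 0.30),
    # elongated support, fewer larger regions (knee-like, sagittal)
    oblong = list(aspect = c(0.95, 0.60), n_ell = 3L,
                  ax_range = c(0.15, 0.45), center_sd = 0.25),
    # ring of small structures inside a round support
    ring = list(aspect = c(0.80, 0.80), n_ell = 6L,
                ax_range = c(0.08, 0.20), center_sd = 0.45),
    # tall-narrow support (axial-extremity-like)
    tall = list(aspect = c(0.60, 0.90), n_ell = 3L,
                ax_range = c(0.12, 0.35), center_sd = 0.25)
  )
}

profile_key <- function(p) {
  paste(p$content_family,
        paste(signif(unlist(p$contrast_params), 8), collapse = ","),
        format(p$snr_db), sep = "|")
}

# Smooth random field: white noise low-pass filtered in k-space with a
# Gaussian kernel of bandwidth `bw` (cycles relative to FOV), unit variance.
smooth_field <- function(H, W, bw = 4) {
  z <- matrix(stats::rnorm(H * W), H, W)
  u <- seq(-floor(H / 2), ceiling(H / 2) - 1)
  v <- seq(-floor(W / 2), ceiling(W / 2) - 1)
  G <- exp(-(outer(u^2, rep(1, W)) / (2 * bw^2) +
               outer(rep(1, H), v^2) / (2 * bw^2)))
  f <- Re(ifft2c(fft2c(z) * G))
  s <- stats::sd(f)
  if (s > 0) f <- f / s
  f
}

#' Generate one phantom slice
#'
#' Renders a piecewise-smooth complex image for a given site profile: a
#' support ellipse containing randomized overlapping ellipses with intensities
#' drawn from the profile's contrast range, optional smooth within-region
#' texture, and a smooth spatial phase. Slices sharing `subject_seed` share
#' the underlying ellipse geometry (each slice applies a small deterministic
#' shift and scale), so subject-level data splits are meaningful.
#'
#' @param profile a `client_profile`.
#' @param subject_seed integer identifying the subject (fixes geometry).
#' @param slice_index integer slice number within the subject.
#' @param H,W image dimensions (both >= 16).
#' @return complex `H x W` matrix, zero outside a finite support.
#' @export
gen_phantom <- function(profile, subject_seed, slice_index, H = 32L, W = 32L) {
  if (H < 16L || W < 16L) stop("phantom dimensions must be at least 16 x 16", call. = FALSE)
  fam <- phantom_families()[[profile$content_family]]
  cp <- profile$contrast_params
  geo <- with_seed(derive_seed(subject_seed, 11L), {
    n <- fam$n_ell
    list(
      centers = cbind(stats::rnorm(n, 0, fam$center_sd),
                      stats::rnorm(n, 0, fam$center_sd)),
      axes = cbind(stats::runif(n, fam$ax_range[1], fam$ax_range[2]),
                   stats::runif(n, fam$ax_range[1], fam$ax_range[2])),
      angles = stats::runif(n, 0, pi),
      intens = stats::runif(n, cp$intensity[1], cp$intensity[2]),
      base = stats::runif(1, cp$intensity[1], cp$intensity[2]),
      phase_coef = stats::rnorm(3, 0, 0.6)
    )
  })
  mv <- with_seed(derive_seed(subject_seed, 13L, slice_index), {
    list(shift = stats::runif(2, -0.06, 0.06),
         scale = stats::runif(1, 0.92, 1.08))
  })
  xg <- matrix(seq(-1, 1, length.out = H), H, W)
  yg <- matrix(seq(-1, 1, length.out = W), H, W, byrow = TRUE)
  support <- (xg / fam$aspect[1])^2 + (yg / fam$aspect[2])^2 <= 1
  mag <- matrix(0, H, W)
  mag[support] <- geo$base
  for (e in seq_len(nrow(geo$centers))) {
    cx <- geo$centers[e, 1] * mv$scale + mv$shift[1]
    cy <- geo$centers[e, 2] * mv$scale + mv$shift[2]
    a <- geo$axes[e, 1] * mv$scale
    b <- geo$axes[e, 2] * mv$scale
    th <- geo$angles[e]
    xr <- (xg - cx) * cos(th) + (yg - cy) * sin(th)
    yr <- -(xg - cx) * sin(th) + (yg - cy) * cos(th)
    inside <- (xr / a)^2 + (yr / b)^2 <= 1
    mag[inside & support] <- mag[inside & support] + geo$intens[e]
  }
  if (cp$texture_sd > 0) {
    tex <- with_seed(derive_seed(subject_seed, 17L, slice_index),
                     smooth_field(H, W))
    mag <- mag + cp$texture_sd * tex
    mag[!support] <- 0
    mag <- pmax(mag, 0)
  }
  phase <- geo$phase_coef[1] * xg + geo$phase_coef[2] * yg +
    geo$phase_coef[3] * xg * yg
  x <- mag * exp(1i * phase)
  x[!support] <- 0i
  x
}

#' Generate smooth coil sensitivity maps
#'
#' Complex coil sensitivities as Gaussian magnitude lobes centered just
#' outside the field-of-view boundary at equispaced angles, with a smooth
#' per-coil linear phase, normalized so the coil-axis sum of squared
#' magnitudes is exactly 1 at every pixel.
#'
#' @param n_coils number of receive coils (>= 1).
#' @param H,W map dimensions.
#' @param seed integer seed (jitters lobe positions, widths and phases).
#' @return complex `H x W x n_coils` array.
#' @export
gen_coil_maps <- function(n_coils, H, W, seed = 1L) {
  if (n_coils < 1L) stop("n_coils must be at least 1", call. = FALSE)
  xg <- matrix(seq(-1, 1, length.out = H), H, W)
  yg <- matrix(seq(-1, 1, length.out = W), H, W, byrow = TRUE)
  pars <- with_seed(derive_seed(seed, 23L), {
    list(ang = 2 * pi * (seq_len(n_coils) - 1) / n_coils +
           stats::runif(n_coils, -0.2, 0.2),
         rad = stats::runif(n_coils, 1.05, 1.25),
         width = stats::runif(n_coils, 0.7, 1.0),
         ph = matrix(stats::rnorm(3 * n_coils, 0, 0.4), ncol = 3))
  })
  maps <- array(0i, dim = c(H, W, n_coils))
  for (c in seq_len(n_coils)) {
    cx <- pars$rad[c] * cos(pars$ang[c])
    cy <- pars$rad[c] * sin(pars$ang[c])
    m <- exp(-((xg - cx)^2 + (yg - cy)^2) / (2 * pars$width[c]^2))
    ph <- pars$ph[c, 1] + pars$ph[c, 2] * xg + pars$ph[c, 3] * yg
    maps[, , c] <- m * exp(1i * ph)
  }
  sos <- sqrt(rowSums(Mod(maps)^2, dims = 2L))
  maps / as.vector(sos)
}

#' Simulate one noisy under-sampled multi-coil acquisition
#'
#' Applies the multi-coil forward model: per-coil sensitivity weighting,
#' centered orthonormal Fourier transform, additive zero-mean complex white
#' Gaussian noise scaled to `snr_db`, then retrospective masking of the
#' phase-encode lines (noise is injected into the full k-space before
#' masking, so the ACS-based normalization sees noise). The reference image
#' is the root-sum-of-squares of the noiseless fully sampled coil images.
#'
#' @param x complex `H x W` image.
#' @param sens_maps complex `H x W x Nc` sensitivities.
#' @param mask a `sampling_mask` over the W phase-encode columns.
#' @param snr_db per-sample SNR in dB (`Inf` = noiseless); defined as
#'   `10 log10(P_signal / P_noise)` with powers averaged over full k-space.
#' @param seed integer seed for the noise draw.
#' @return object of class `multicoil_sample`: list with `kspace`
#'   (`H x W x Nc`, exactly zero on unsampled lines), `sens_maps`, `mask`,
#'   `target_rss`, `norm_const`, `snr_db`.
#' @export
simulate_sample <- function(x, sens_maps, mask, snr_db = Inf, seed = 1L) {
  d <- dim(sens_maps)
  if (length(d) != 3L || !all(dim(x) == d[1:2])) {
    stop("image / sensitivity map shape mismatch", call. = FALSE)
  }
  flags <- mask_flags(mask)
  if (length(flags) != d[2]) stop("mask / k-space width mismatch", call. = FALSE)
  coil_imgs <- sens_maps * as.vector(x)
  kfull <- fft2c_stack(coil_imgs)
  if (is.finite(snr_db)) {
    p_sig <- mean(Mod(kfull)^2)
    sigma2 <- p_sig / 10^(snr_db / 10)
    noise <- with_seed(derive_seed(seed, 29L), {
      array(complex(real = stats::rnorm(length(kfull), 0, sqrt(sigma2 / 2)),
                    imaginary = stats::rnorm(length(kfull), 0, sqrt(sigma2 / 2))),
            dim = d)
    })
    kfull <- kfull + noise
  }
  kfull[, flags == 0L, ] <- 0i
  target <- rss(coil_imgs)
  nrm <- acs_rss_norm(kfull, mask)
  structure(
    list(kspace = kfull, sens_maps = sens_maps, mask = mask,
         target_rss = target, norm_const = nrm, snr_db = snr_db,
         normalized = FALSE),
    class = "multicoil_sample"
  )
}

#' Apply the ACS normalization to a sample
#'
#' Divides the k-space and the reference image by the sample's normalization
#' constant so the low-resolution ACS reconstruction has unit maximum.
#'
#' @param sample a `multicoil_sample`.
#' @return the normalized sample (`norm_const` reset to 1).
#' @export
normalize_sample <- function(sample) {
  if (isTRUE(sample$normalized)) return(sample)
  sample$kspace <- sample$kspace / sample$norm_const
  sample$target_rss <- sample$target_rss / sample$norm_const
  sample$norm_const <- 1
  sample$normalized <- TRUE
  sample
}

#' Default heterogeneous site profiles
#'
#' A ten-site federation spanning the three heterogeneity axes: four content
#' families, five contrast presets (distinct intensity ranges and texture
#' levels) and two SNR levels. No two sites share the full
#' (family, contrast, SNR) triple.
#'
#' @param K number of sites (default 10).
#' @return list of `client_profile` objects.
#' @export
default_profiles <- function(K = 10L) {
  fams <- c("oblong", "oblong", "compact", "compact", "ring",
            "ring", "tall", "tall", "compact", "oblong")
  contrasts <- list(
    list(intensity = c(0.20, 0.45), texture_sd = 0.02),
    list(intensity = c(0.35, 0.65), texture_sd = 0.04),
    list(intensity = c(0.50, 0.85), texture_sd = 0.03),
    list(intensity = c(0.65, 1.00), texture_sd = 0.05),
    list(intensity = c(0.80, 1.20), texture_sd = 0.02)
  )
  snrs <- c(14, 20)  # lower/higher field strength surrogates
  lapply(seq_len(K), function(k) {
    client_profile(
      site_id = k,
      content_family = fams[((k - 1L) %% length(fams)) + 1L],
      contrast_params = contrasts[[((k - 1L) %% length(contrasts)) + 1L]],
      snr_db = snrs[((k - 1L) %% 2L) + 1L]
    )
  })
}

#' Build a federation of synthetic client datasets
#'
#' Generates `K` client datasets with subject-disjoint train/validation
#' splits. In i.i.d. mode every client draws from the first profile with
#' globally non-overlapping subject IDs; in non-i.i.d. mode each client uses
#' its own profile, and profiles must be pairwise distinct in the full
#' (content family, contrast, SNR) triple. Each subject gets its own coil
#' maps; each slice gets its own under-sampling mask, drawn once at creation.
#'
#' @param profiles list of `client_profile` objects (length K >= 1).
#' @param iid logical: homogeneous federation from `profiles[[1]]`?
#' @param seed master seed; all per-client/subject/slice randomness is
#'   derived from it by fixed offsets, so adding a client never perturbs the
#'   data of existing clients.
#' @param H,W image size (default 32 x 32).
#' @param n_coils receive coils (default 4).
#' @param accel_R acceleration factor (default 4).
#' @param acs_frac ACS fraction (default 0.08).
#' @param n_val_subjects held-out validation subjects per client (default 2).
#' @return object of class `federation`: list with `clients` (each holding
#'   `profile`, `train`, `val` sample lists and subject ID vectors) plus the
#'   generation settings.
#' @export
make_federation <- function(profiles, iid = FALSE, seed = 1L,
                            H = 32L, W = 32L, n_coils = 4L,
                            accel_R = 4, acs_frac = 0.08,
                            n_val_subjects = 2L) {
  K <- length(profiles)
  if (K < 1L) stop("need at least one client profile", call. = FALSE)
  if (!iid && K > 1L) {
    keys <- vapply(profiles, profile_key, character(1))
    if (anyDuplicated(keys)) {
      stop("non-i.i.d. federation requires pairwise distinct profiles", call. = FALSE)
    }
  }
  clients <- vector("list", K)
  for (k in seq_len(K)) {
    prof <- if (iid) profiles[[1]] else profiles[[k]]
    n_subj <- prof$n_subjects + n_val_subjects
    # globally unique subject IDs: block-disjoint across clients
    subj_ids <- (k - 1L) * 1000L + seq_len(n_subj)
    train_subj <- subj_ids[seq_len(prof$n_subjects)]
    val_subj <- setdiff(subj_ids, train_subj)
    gen_subject <- function(sid, n_slices) {
      maps <- gen_coil_maps(n_coils, H, W, seed = derive_seed(seed, 3L, sid))
      lapply(seq_len(n_slices), function(s) {
        x <- gen_phantom(prof, subject_seed = derive_seed(seed, 5L, sid),
                         slice_index = s, H = H, W = W)
        msk <- make_mask(W, accel_R, acs_frac,
                         seed = derive_seed(seed, 7L, sid, s))
        smp <- simulate_sample(x, maps, msk, snr_db = prof$snr_db,
                               seed = derive_seed(seed, 9L, sid, s))
        smp$subject_id <- sid
        smp$slice_index <- s
        smp
      })
    }
    train <- do.call(c, lapply(train_subj, gen_subject,
                               n_slices = prof$slices_per_subject))
    val <- do.call(c, lapply(val_subj, gen_subject,
                             n_slices = prof$slices_per_subject))
    clients[[k]] <- list(profile = prof, train = train, val = val,
                         train_subjects = train_subj, val_subjects = val_subj)
  }
  structure(
    list(clients = clients, iid = iid, seed = seed, H = H, W = W,
         n_coils = n_coils, accel_R = accel_R, acs_frac = acs_frac),
    class = "federation"
  )
}

#' Write / read a scan container
#'
#' Serializes the slices of one subject ("scan") in a layout mirroring the
#' standard raw-MRI per-file convention: datasets `kspace`
#' (slices x coils x H x W), `reconstruction_rss` (slices x H x W) and the
#' synthetic-only extension `sens_maps`, plus a profile-metadata attribute
#' list (also written as a plain-text JSON sidecar). The round trip is
#' bit-exact.
#'
#' @param samples list of `multicoil_sample` objects from one subject.
#' @param path output file path (an `.json` sidecar is written next to it).
#' @param attrs named list of metadata attributes.
#' @return `path`, invisibly (for `write_scan`); the scan list for
#'   `read_scan`.
#' @export
write_scan <- function(samples, path, attrs = list()) {
  ns <- length(samples)
  d <- dim(samples[[1]]$kspace)
  ks <- array(0i, dim = c(ns, d[3], d[1], d[2]))
  rssim <- array(0, dim = c(ns, d[1], d[2]))
  sm <- array(0i, dim = c(ns, d[3], d[1], d[2]))
  for (s in seq_len(ns)) {
    ks[s, , , ] <- aperm(samples[[s]]$kspace, c(3, 1, 2))
    rssim[s, , ] <- samples[[s]]$target_rss
    sm[s, , , ] <- aperm(samples[[s]]$sens_maps, c(3, 1, 2))
  }
  scan <- list(kspace = ks, reconstruction_rss = rssim, sens_maps = sm,
               attrs = attrs)
  saveRDS(scan, path)
  jsonlite::write_json(attrs, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) readRDS(path)
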