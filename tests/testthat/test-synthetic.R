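# Synthetic data: phantoms, coil maps, acquisition model, federation
# structure, and the scan container round trip.

test_that("phantom generation is deterministic and respects geometry contracts", {
  prof <- default_profiles(10)[[1]]
  x1 <- gen_phantom(prof, subject_seed = 7, slice_index = 3)
  x2 <- gen_phantom(prof, subject_seed = 7, slice_index = 3)
  expect_identical(x1, x2)
  expect_false(identical(x1, gen_phantom(prof, 7, 4)))
  expect_false(identical(x1, gen_phantom(prof, 8, 3)))
  expect_error(gen_phantom(prof, 1, 1, H = 8, W = 32), "at least 16")
  # bounded magnitude, nonzero finite support
  expect_true(all(is.finite(Mod(x1))))
  expect_gt(sum(Mod(x1) > 0), 100)
  expect_gt(sum(Mod(x1) == 0), 50)
  # slices of one subject share geometry: correlation between slice supports
  s1 <- Mod(gen_phantom(prof, 7, 1)) > 0
  s2 <- Mod(gen_phantom(prof, 7, 2)) > 0
  expect_gt(mean(s1 == s2), 0.9)
})

test_that("disjoint contrast ranges yield separated region intensities", {
  lo <- client_profile(1, "compact", list(intensity = c(0.1, 0.2), texture_sd = 0),
                       snr_db = Inf)
  hi <- client_profile(2, "compact", list(intensity = c(1.0, 1.3), texture_sd = 0),
                       snr_db = Inf)
  m_lo <- m_hi <- numeric(100)
  for (i in 1:100) {
    a <- Mod(gen_phantom(lo, i, 1)); b <- Mod(gen_phantom(hi, i, 1))
    m_lo[i] <- mean(a[a > 0]); m_hi[i] <- mean(b[b > 0])
  }
  expect_gt(min(m_hi), max(m_lo))
})

test_that("zero texture variance gives piecewise-constant phantoms", {
  prof <- client_profile(1, "oblong", list(intensity = c(0.4, 0.8), texture_sd = 0),
                         snr_db = Inf)
  x <- Mod(gen_phantom(prof, 3, 1))
  vals <- unique(round(x[x > 0], 10))
  expect_lt(length(vals), 2^4 + 2)  # at most one level per region overlap
})

test_that("coil maps are smooth, normalized, and reproducible", {
  m <- gen_coil_maps(4, 32, 32, seed = 9)
  sos <- sqrt(rowSums(Mod(m)^2, dims = 2))
  expect_lt(max(abs(sos - 1)), 1e-6)
  m1 <- gen_coil_maps(1, 16, 16, seed = 2)
  expect_lt(max(abs(Mod(m1[, , 1]) - 1)), 1e-12)
  expect_identical(m, gen_coil_maps(4, 32, 32, seed = 9))
  expect_error(gen_coil_maps(0, 16, 16), "at least 1")
})

test_that("noiseless fully sampled acquisition inverts to the coil images", {
  prof <- default_profiles(10)[[2]]
  x <- gen_phantom(prof, 5, 1)
  maps <- gen_coil_maps(4, 32, 32, seed = 5)
  s <- simulate_sample(x, maps, make_mask(32, 1, 0.08, seed = 1), snr_db = Inf)
  for (c in 1:4) {
    expect_lt(max(Mod(ifft2c(s$kspace[, , c]) - maps[, , c] * x)), 1e-12)
  }
  expect_equal(s$target_rss, rss(maps * as.vector(x)), tolerance = 1e-12)
})

test_that("unsampled phase-encode lines are exactly zero", {
  s <- tiny_sample(seed = 61, snr_db = 10)
  flags <- s$mask$pe_flags
  expect_true(all(Mod(s$kspace[, flags == 0, ]) == 0))
  expect_true(any(Mod(s$kspace[, flags == 1, ]) > 0))
})

test_that("k-space noise variance matches the SNR specification", {
  prof <- default_profiles(10)[[1]]
  x <- gen_phantom(prof, 2, 1, H = 64, W = 64)
  maps <- gen_coil_maps(4, 64, 64, seed = 3)
  msk <- make_mask(64, 4, 0.08, seed = 4)
  snr_db <- 10
  noiseless <- simulate_sample(x, maps, msk, snr_db = Inf)
  noisy <- simulate_sample(x, maps, msk, snr_db = snr_db, seed = 11)
  kfull <- array(0i, dim(noiseless$kspace))
  for (c in 1:4) kfull[, , c] <- fft2c(maps[, , c] * x)
  sigma2 <- mean(Mod(kfull)^2) / 10^(snr_db / 10)
  keep <- noisy$mask$pe_flags == 1
  diff <- (noisy$kspace - noiseless$kspace)[, keep, ]
  emp <- mean(c(Re(diff)^2 + Im(diff)^2))  # per-complex-entry variance
  expect_lt(abs(emp - sigma2) / sigma2, 0.05)
})

test_that("i.i.d. federations share one profile with disjoint subjects", {
  fedn <- make_federation(default_profiles(10), iid = TRUE, seed = 3,
                          n_val_subjects = 1)
  keys <- vapply(fedn$clients, function(cl) fedunroll:::profile_key(cl$profile),
                 character(1))
  expect_equal(length(unique(keys)), 1L)
  subj <- lapply(fedn$clients, function(cl) c(cl$train_subjects, cl$val_subjects))
  all_ids <- unlist(subj)
  expect_equal(anyDuplicated(all_ids), 0L)
  expect_equal(length(fedn$clients[[1]]$train), 50L)
})

test_that("non-i.i.d. federations have distinct profiles and reject duplicates", {
  profs <- default_profiles(10)
  keys <- vapply(profs, fedunroll:::profile_key, character(1))
  expect_equal(anyDuplicated(keys), 0L)
  fedn <- make_federation(profs[1:3], iid = FALSE, seed = 2, n_val_subjects = 1)
  expect_equal(length(fedn$clients), 3L)
  expect_error(make_federation(list(profs[[1]], profs[[1]]), iid = FALSE),
               "distinct")
  single <- make_federation(profs[1], iid = FALSE, seed = 2, n_val_subjects = 1)
  expect_equal(length(single$clients), 1L)
})

test_that("train and validation subjects never overlap within a client", {
  fedn <- make_federation(default_profiles(3), iid = FALSE, seed = 5,
                          n_val_subjects = 2)
  for (cl in fedn$clients) {
    expect_length(intersect(cl$train_subjects, cl$val_subjects), 0)
    tr_subj <- unique(vapply(cl$train, `[[`, numeric(1), "subject_id"))
    va_subj <- unique(vapply(cl$val, `[[`, numeric(1), "subject_id"))
    expect_length(intersect(tr_subj, va_subj), 0)
  }
})

test_that("federation generation is a pure function of (config, seed)", {
  f1 <- make_federation(default_profiles(2), iid = FALSE, seed = 7,
                        n_val_subjects = 1)
  f2 <- make_federation(default_profiles(2), iid = FALSE, seed = 7,
                        n_val_subjects = 1)
  expect_identical(f1$clients[[2]]$train[[13]]$kspace,
                   f2$clients[[2]]$train[[13]]$kspace)
  # adding a client leaves existing clients' data untouched
  f3 <- make_federation(default_profiles(3), iid = FALSE, seed = 7,
                        n_val_subjects = 1)
  expect_identical(f1$clients[[1]]$train[[1]]$kspace,
                   f3$clients[[1]]$train[[1]]$kspace)
})

test_that("heterogeneous clients are separable from intensity histograms", {
  profs <- default_profiles(10)
  n_tr <- 20L; n_te <- 10L
  breaks <- seq(0, 2, length.out = 13)
  hist_of <- function(p, sid) {
    x <- Mod(gen_phantom(p, sid, 1 + (sid %% 7)))
    h <- hist(pmin(x[x > 0], 2), breaks = breaks, plot = FALSE)$density
    h / sum(h)
  }
  centroids <- list(); test_feats <- list()
  for (k in seq_along(profs)) {
    feats <- t(vapply(1:(n_tr + n_te),
                      function(s) hist_of(profs[[k]], s + 1000 * k),
                      numeric(length(breaks) - 1)))
    centroids[[k]] <- colMeans(feats[1:n_tr, ])
    test_feats[[k]] <- feats[(n_tr + 1):(n_tr + n_te), ]
  }
  correct <- 0
  for (k in seq_along(profs)) {
    for (i in 1:n_te) {
      d <- vapply(centroids, function(ce) sum((test_feats[[k]][i, ] - ce)^2),
                  numeric(1))
      if (which.min(d) == k) correct <- correct + 1
    }
  }
  acc <- correct / (length(profs) * n_te)
  # chance is 0.1 with sd ~0.03 over 100 draws; 0.2 is >3 sigma above chance
  expect_gt(acc, 0.2)
})

test_that("scan container round trip is bit-exact", {
  fedn <- make_federation(default_profiles(1), iid = FALSE, seed = 13,
                          n_val_subjects = 1)
  cl <- fedn$clients[[1]]
  scan_slices <- cl$train[1:10]
  path <- tempfile(fileext = ".rds")
  write_scan(scan_slices, path, attrs = list(site_id = 1L, snr_db = 14))
  sc <- read_scan(path)
  expect_equal(dim(sc$kspace), c(10L, 4L, 32L, 32L))
  expect_equal(dim(sc$reconstruction_rss), c(10L, 32L, 32L))
  expect_identical(sc$kspace[3, 2, , ], scan_slices[[3]]$kspace[, , 2])
  expect_identical(sc$reconstruction_rss[5, , ], scan_slices[[5]]$target_rss)
  expect_identical(sc$attrs$snr_db, 14)
  expect_true(file.exists(paste0(path, ".json")))
})

test_that("sample normalization is idempotent and flags state", {
  s <- tiny_sample(seed = 71)
  n1 <- normalize_sample(s)
  n2 <- normalize_sample(n1)
  expect_identical(n1, n2)
  expect_equal(n1$norm_const, 1)
  expect_equal(acs_rss_norm(n1$kspace, n1$mask), 1, tolerance = 1e-12)
})
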