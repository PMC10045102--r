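# Study orchestration at desk scale: the low-data sweep (how many local
# slices does a site need before local-only training saturates?), the
# homogeneous vs heterogeneous federation comparison across the five
# federated optimizers, and the communication-budget x personalization
# study. Every experiment is a pure function of (configuration, seed) and
# returns plain data frames; tables are built from those records.

#' Desk-scale experiment preset
#'
#' The reduced problem size used throughout the experiments and tests:
#' 32 x 32 slices, 4 coils, 4 unrolls with 4 CG steps, a 2-scale/8-channel
#' denoiser, 10 clients with 50 training slices (5 subjects x 10 slices) and
#' 20 held-out validation slices (2 subjects) each, acceleration 4 with an
#' 8\% ACS region, and a 400-step local budget split over 20 rounds. The
#' full-scale configuration (6 unrolls, 6 CG steps, 24,000 local steps over
#' 240 rounds) is expressible through the same constructors.
#'
#' @return list with `ucfg` (an `unroll_config`), geometry fields, and the
#'   default federation schedule.
#' @export
desk_preset <- function() {
  list(
    ucfg = unroll_config(n_unrolls = 4L, n_cg = 4L, lam = 0.05,
                         denoiser = denoiser_spec(2L, 8L)),
    H = 32L, W = 32L, n_coils = 4L, accel_R = 4, acs_frac = 0.08,
    n_val_subjects = 2L,
    total_local_steps = 400L, n_rounds = 20L,
    local_lr = 1e-4, sweep_lr = 1e-3, sweep_steps = 600L
  )
}

#' Profiles for clients outside the training federation
#'
#' Two site profiles whose (content family, contrast, SNR) triples do not
#' occur in [default_profiles()]; used to probe generalization and
#' personalization on clients that never participated in federated training.
#'
#' @param n number of unseen profiles (1 or 2).
#' @return list of `client_profile` objects with site IDs 101, 102.
#' @export
unseen_profiles <- function(n = 2L) {
  all <- list(
    client_profile(101L, "tall",
                   list(intensity = c(0.90, 1.40), texture_sd = 0.06),
                   snr_db = 17),
    client_profile(102L, "ring",
                   list(intensity = c(0.10, 0.30), texture_sd = 0.01),
                   snr_db = 17)
  )
  all[seq_len(n)]
}

#' Low-data sweep: local-only training vs sample count
#'
#' Trains a separate centralized model per training-set size on a single
#' site's data (no federation involved) and evaluates each on the site's
#' held-out subjects, tracing how reconstruction quality grows with the
#' number of local slices.
#'
#' @param profile the site's `client_profile`.
#' @param grid strictly increasing vector of training sample counts.
#' @param seeds integer vector of seeds (results are averaged downstream).
#' @param preset experiment preset (see [desk_preset()]).
#' @param max_samples cap on the synthetic sample pool per seed; a grid
#'   exceeding it is a configuration error.
#' @return data frame with columns `n_samples`, `seed`, `ssim`, `nrmse`.
#' @export
run_low_data_sweep <- function(profile, grid = c(10L, 50L, 250L),
                               seeds = 1:3, preset = desk_preset(),
                               max_samples = 300L) {
  if (any(diff(grid) <= 0)) stop("sample grid must be strictly increasing", call. = FALSE)
  if (max(grid) > max_samples) {
    stop("sample grid exceeds the available synthetic slices", call. = FALSE)
  }
  rows <- list()
  for (seed in seeds) {
    n_subj <- ceiling(max(grid) / profile$slices_per_subject)
    prof <- profile
    prof$n_subjects <- as.integer(n_subj)
    fedn <- make_federation(list(prof), iid = FALSE, seed = seed,
                            H = preset$H, W = preset$W,
                            n_coils = preset$n_coils,
                            accel_R = preset$accel_R,
                            acs_frac = preset$acs_frac,
                            n_val_subjects = preset$n_val_subjects)
    client <- fedn$clients[[1]]
    for (n in grid) {
      if (n > length(client$train)) {
        stop("sample grid exceeds the available synthetic slices", call. = FALSE)
      }
      w0 <- init_denoiser(preset$ucfg$denoiser, seed = derive_seed(seed, 101L, n))
      tr <- local_train(w0, client$train[seq_len(n)], preset$sweep_steps,
                        lr = preset$sweep_lr, cfg = preset$ucfg,
                        seed = derive_seed(seed, 103L, n))
      ev <- evaluate_weights(tr$weights, client$val, preset$ucfg)
      rows[[length(rows) + 1L]] <- data.frame(
        n_samples = n, seed = seed, ssim = ev$ssim, nrmse = ev$nrmse)
    }
  }
  do.call(rbind, rows)
}

#' Federation experiment: one algorithm on one federation
#'
#' Builds the synthetic federation (homogeneous or heterogeneous) and runs
#' one federated algorithm (or the pooled centralized baseline) under the
#' preset schedule.
#'
#' @param algorithm passed to [fed_config()].
#' @param iid homogeneous federation?
#' @param seed master seed.
#' @param preset experiment preset.
#' @param profiles client profiles (default [default_profiles()]).
#' @param n_rounds,total_steps override the preset schedule.
#' @return a `fed_result`.
#' @export
run_federation_experiment <- function(algorithm, iid = FALSE, seed = 1L,
                                      preset = desk_preset(),
                                      profiles = default_profiles(),
                                      n_rounds = preset$n_rounds,
                                      total_steps = preset$total_local_steps) {
  fedn <- make_federation(profiles, iid = iid, seed = seed,
                          H = preset$H, W = preset$W,
                          n_coils = preset$n_coils, accel_R = preset$accel_R,
                          acs_frac = preset$acs_frac,
                          n_val_subjects = preset$n_val_subjects)
  run_federated(fedn, preset$ucfg,
                fed_config(algorithm, local_lr = preset$local_lr),
                make_schedule(total_steps, n_rounds), seed = seed)
}

#' Communication-budget sweep with personalization
#'
#' For every communication budget (number of rounds at a fixed total local
#' step count), trains one Scaffold federation, then personalizes designated
#' clients by cross-validated fine-tuning: one under-represented site that
#' participated in training ("seen") and one or more sites that never did
#' ("unseen", fresh profiles with their own local data). Reports validation
#' SSIM/NRMSE with and without personalization at every budget point.
#'
#' @param budgets vector of round counts; each must divide `total_steps`.
#' @param total_steps fixed local-step budget per client.
#' @param seed master seed.
#' @param preset experiment preset.
#' @param pcfg a `personalization_config` (desk default: 2-point learning
#'   rate grid, small epoch ceiling).
#' @param seen_site site ID of the designated seen client (default 2).
#' @param n_unseen number of unseen-profile clients (default 1).
#' @return list with `records` (data frame: `n_rounds`, `site_id`, `seen`,
#'   `personalized`, `ssim`, `nrmse`, `r_fine`, `n_fine`) and
#'   `global_weights` per budget.
#' @export
run_budget_sweep <- function(budgets = c(20L, 10L, 4L), total_steps = 400L,
                             seed = 1L, preset = desk_preset(),
                             pcfg = personalization_config(max_epochs = 4L),
                             seen_site = 2L, n_unseen = 1L) {
  if (any(total_steps %% budgets != 0)) {
    stop("every budget must divide the total step count", call. = FALSE)
  }
  fedn <- make_federation(default_profiles(), iid = FALSE, seed = seed,
                          H = preset$H, W = preset$W,
                          n_coils = preset$n_coils, accel_R = preset$accel_R,
                          acs_frac = preset$acs_frac,
                          n_val_subjects = preset$n_val_subjects)
  unseen <- make_federation(unseen_profiles(n_unseen), iid = FALSE,
                            seed = derive_seed(seed, 107L),
                            H = preset$H, W = preset$W,
                            n_coils = preset$n_coils,
                            accel_R = preset$accel_R,
                            acs_frac = preset$acs_frac,
                            n_val_subjects = preset$n_val_subjects)
  seen_idx <- which(vapply(fedn$clients,
                           function(cl) cl$profile$site_id == seen_site,
                           logical(1)))[1]
  targets <- c(
    list(list(client = fedn$clients[[seen_idx]], seen = TRUE)),
    lapply(unseen$clients, function(cl) list(client = cl, seen = FALSE))
  )
  rows <- list()
  weights_per_budget <- list()
  for (b in budgets) {
    res <- run_federated(fedn, preset$ucfg,
                         fed_config("scaffold", local_lr = preset$local_lr),
                         make_schedule(total_steps, b), seed = seed)
    weights_per_budget[[as.character(b)]] <- res$global_weights
    for (tg in targets) {
      ev0 <- evaluate_weights(res$global_weights, tg$client$val, preset$ucfg)
      pers <- personalize_client(res$global_weights, tg$client$train, pcfg,
                                 preset$ucfg, seed = derive_seed(seed, 109L, b))
      ev1 <- evaluate_weights(pers$weights, tg$client$val, preset$ucfg)
      sid <- tg$client$profile$site_id
      rows[[length(rows) + 1L]] <- data.frame(
        n_rounds = b, site_id = sid, seen = tg$seen,
        personalized = c(FALSE, TRUE),
        ssim = c(ev0$ssim, ev1$ssim), nrmse = c(ev0$nrmse, ev1$nrmse),
        r_fine = pers$r_fine, n_fine = pers$n_fine)
    }
  }
  list(records = do.call(rbind, rows), global_weights = weights_per_budget)
}
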