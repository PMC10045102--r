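# Synchronous full-participation federated optimization of the unrolled
# reconstruction model: round scheduling at a fixed local-step budget, client
# updates, and the five server aggregation rules (FedAvg, FedAdam, FedYogi,
# FedAdaGrad, Scaffold) plus a pooled-data centralized baseline. Only
# weight-shaped objects cross the client/server boundary; raw k-space and
# images never leave a client.

#' Round schedule at a fixed local-step budget
#'
#' Partition of a fixed total number of local optimization steps into
#' communication rounds: `n_rounds * steps_per_round = total_local_steps`
#' exactly (the study's communication-budget axis varies `n_rounds` while
#' holding the product fixed).
#'
#' @param total_local_steps total local steps per client across all rounds.
#' @param n_rounds number of communication rounds.
#' @return object of class `round_schedule`.
#' @export
make_schedule <- function(total_local_steps, n_rounds) {
  if (n_rounds < 1L || total_local_steps < 1L) {
    stop("schedule requires positive rounds and steps", call. = FALSE)
  }
  if (total_local_steps %% n_rounds != 0L) {
    stop(sprintf("total_local_steps (%d) not divisible by n_rounds (%d)",
                 total_local_steps, n_rounds), call. = FALSE)
  }
  structure(list(total_local_steps = as.integer(total_local_steps),
                 n_rounds = as.integer(n_rounds),
                 steps_per_round = as.integer(total_local_steps / n_rounds)),
            class = "round_schedule")
}

#' Federated optimization configuration
#'
#' Server and client hyper-parameters. The global step size defaults to 1
#' for FedAvg/Scaffold (plain averaging of client progress) and 1e-2 for the
#' adaptive server optimizers; `beta1`, `beta2`, `tau` follow the adaptive
#' federated optimization conventions. Clients train with Adam at `local_lr`
#' unless `local_optimizer = "sgd"`. For Scaffold, the drift correction
#' `-c_k + c_g` is applied to the raw gradient before it enters the local
#' optimizer, and the control-variate update uses option `"ii"` (the cheap
#' difference form) unless `"i"` (fresh gradient) is requested.
#'
#' @param algorithm one of `"fedavg"`, `"fedadam"`, `"fedyogi"`,
#'   `"fedadagrad"`, `"scaffold"`, `"centralized"`.
#' @param eta_g global (server) step size; algorithm-dependent default.
#' @param beta1,beta2 server moment decay rates (adaptive variants).
#' @param tau adaptivity floor added to the square-root second moment.
#' @param local_lr local learning rate.
#' @param local_optimizer `"adam"` or `"sgd"`.
#' @param scaffold_option control-variate update: `"ii"` (default) or `"i"`.
#' @return object of class `fed_config`.
#' @export
fed_config <- function(algorithm = c("fedavg", "fedadam", "fedyogi",
                                     "fedadagrad", "scaffold", "centralized"),
                       eta_g = NULL, beta1 = 0.9, beta2 = 0.99, tau = 1e-3,
                       local_lr = 1e-4, local_optimizer = c("adam", "sgd"),
                       scaffold_option = c("ii", "i")) {
  algorithm <- match.arg(algorithm)
  local_optimizer <- match.arg(local_optimizer)
  scaffold_option <- match.arg(scaffold_option)
  if (is.null(eta_g)) {
    eta_g <- if (algorithm %in% c("fedadam", "fedyogi", "fedadagrad")) 1e-2 else 1
  }
  structure(list(algorithm = algorithm, eta_g = eta_g, beta1 = beta1,
                 beta2 = beta2, tau = tau, local_lr = local_lr,
                 local_optimizer = local_optimizer,
                 scaffold_option = scaffold_option),
            class = "fed_config")
}

#' Federated averaging of client weights
#'
#' Elementwise arithmetic mean of conformable client weight collections.
#'
#' @param client_weights non-empty list of `model_weights`.
#' @return the averaged `model_weights`.
#' @export
fedavg_aggregate <- function(client_weights) {
  if (length(client_weights) == 0L) {
    stop("fedavg_aggregate needs at least one client", call. = FALSE)
  }
  nm <- names(client_weights[[1]])
  for (w in client_weights[-1]) {
    if (!identical(names(w), nm)) {
      stop("client weight collections are not conformable", call. = FALSE)
    }
  }
  weights_mean(client_weights)
}

#' Adaptive server aggregation round
#'
#' Server update of the adaptive federated optimizers. The pseudo-gradient is
#' `Delta = mean(client weights) - global weights`; the first moment is
#' `m <- beta1 m + (1 - beta1) Delta`; the second moment follows the variant
#' (`adagrad`: `v <- v + Delta^2`; `adam`: `v <- beta2 v + (1-beta2) Delta^2`;
#' `yogi`: `v <- v - (1-beta2) sign(v - Delta^2) Delta^2`); the global update
#' is `theta <- theta + eta_g * m / (sqrt(v) + tau)`.
#'
#' @param fed server state: list with `global_weights`, `server_aux`
#'   (`m`, `v` or NULL before the first round), `round_index`.
#' @param client_weights list of uploaded client weight collections.
#' @param variant `"adam"`, `"yogi"` or `"adagrad"`.
#' @param cfg a `fed_config` providing `eta_g`, `beta1`, `beta2`, `tau`.
#' @return the updated server state.
#' @export
fedopt_server_round <- function(fed, client_weights,
                                variant = c("adam", "yogi", "adagrad"), cfg) {
  variant <- match.arg(variant)
  delta <- weights_map(`-`, fedavg_aggregate(client_weights),
                       fed$global_weights)
  if (is.null(fed$server_aux)) {
    fed$server_aux <- list(m = weights_zero_like(delta),
                           v = weights_zero_like(delta))
  }
  b1 <- cfg$beta1; b2 <- cfg$beta2
  m <- weights_map(function(m, d) b1 * m + (1 - b1) * d, fed$server_aux$m, delta)
  v <- switch(variant,
    adagrad = weights_map(function(v, d) v + d^2, fed$server_aux$v, delta),
    adam = weights_map(function(v, d) b2 * v + (1 - b2) * d^2,
                       fed$server_aux$v, delta),
    yogi = weights_map(function(v, d) v - (1 - b2) * sign(v - d^2) * d^2,
                       fed$server_aux$v, delta)
  )
  fed$global_weights <- weights_map(function(th, m, v) th + cfg$eta_g * m / (sqrt(v) + cfg$tau),
                                    fed$global_weights, m, v)
  fed$server_aux <- list(m = m, v = v)
  fed$round_index <- fed$round_index + 1L
  fed
}

#' One Scaffold client round
#'
#' Starting from the broadcast global weights, performs `steps` local
#' optimization steps with the drift-corrected gradient `g - c_k + c_g`,
#' then updates the local control variate: option `"i"` re-evaluates the mean
#' local gradient at the final weights; option `"ii"` uses
#' `c_k - c_g + (theta_G - theta_k) / (S eta_l)`. Returns the weight and
#' control-variate increments uploaded to the server.
#'
#' @param state client state: list with `control_variate` (`c_k`).
#' @param fed server state: list with `global_weights`, `control_variate`
#'   (`c_g`).
#' @param dataset the client's local samples.
#' @param steps local steps `S` this round.
#' @param cfg a `fed_config` (uses `local_lr`, `local_optimizer`,
#'   `scaffold_option`).
#' @param ucfg an `unroll_config`.
#' @param seed integer seed for the local sample shuffle.
#' @return list with `delta_w`, `delta_c`, `c_new`, `weights`.
#' @export
scaffold_client_round <- function(state, fed, dataset, steps, cfg, ucfg,
                                  seed = 1L) {
  c_k <- state$control_variate
  c_g <- fed$control_variate
  if (!identical(names(c_k), names(fed$global_weights)) ||
      !identical(names(c_g), names(fed$global_weights))) {
    stop("control variates not conformable with the global weights", call. = FALSE)
  }
  corr <- weights_map(`-`, c_g, c_k)  # added to every raw gradient
  adaptive <- cfg$local_optimizer != "sgd"
  tr <- local_train(fed$global_weights, dataset, steps, lr = cfg$local_lr,
                    cfg = ucfg, optimizer = cfg$local_optimizer, seed = seed,
                    grad_transform = function(g) weights_map(`+`, g, corr),
                    return_mean_grad = cfg$scaffold_option == "ii" && adaptive)
  delta_w <- weights_map(`-`, tr$weights, fed$global_weights)
  c_new <- if (cfg$scaffold_option == "i") {
    gs <- lapply(dataset, function(s) modl_loss_grad(s, tr$weights, ucfg)$grad)
    weights_mean(gs)
  } else if (adaptive) {
    # option (ii) in gradient units: under SGD the displacement form
    # (theta_G - theta_k)/(S eta_l) equals the mean corrected gradient, so
    # c+ = c_k - c_g + mean(corrected g) = mean(raw g) at the visited
    # iterates; with an adaptive local optimizer the displacement is on the
    # optimizer's step scale, so the gradient-unit form is the consistent one
    tr$mean_grad
  } else {
    if (cfg$local_lr == 0) {
      stop("scaffold option (ii) undefined for a zero local step size", call. = FALSE)
    }
    weights_map(function(ck, cg, d) ck - cg - d / (steps * cfg$local_lr),
                c_k, c_g, delta_w)
  }
  delta_c <- weights_map(`-`, c_new, c_k)
  list(delta_w = delta_w, delta_c = delta_c, c_new = c_new,
       weights = tr$weights)
}

#' Scaffold server round
#'
#' Full-participation aggregation of Scaffold uploads: the global weights
#' move by `eta_g` times the mean weight increment and the global control
#' variate accumulates the mean control-variate increment.
#'
#' @param fed server state (`global_weights`, `control_variate`,
#'   `round_index`).
#' @param uploads list of client uploads (each with `delta_w`, `delta_c`).
#' @param cfg a `fed_config` (uses `eta_g`).
#' @param n_expected number of participating clients; fewer uploads raise a
#'   synchronicity-violation error.
#' @return the updated server state.
#' @export
scaffold_server_round <- function(fed, uploads, cfg, n_expected = length(uploads)) {
  if (length(uploads) < n_expected || length(uploads) == 0L) {
    stop("synchronicity violation: missing client uploads", call. = FALSE)
  }
  mean_dw <- weights_mean(lapply(uploads, `[[`, "delta_w"))
  mean_dc <- weights_mean(lapply(uploads, `[[`, "delta_c"))
  fed$global_weights <- weights_axpy(cfg$eta_g, mean_dw, fed$global_weights)
  fed$control_variate <- weights_map(`+`, fed$control_variate, mean_dc)
  fed$round_index <- fed$round_index + 1L
  fed
}

#' Run synchronous full-participation federated training
#'
#' Broadcasts the global weights each round, runs every client for
#' `steps_per_round` local steps, aggregates with the chosen algorithm, and
#' logs per-client validation SSIM/NRMSE. `algorithm = "centralized"` pools
#' all client training data into one dataset and trains it with the same
#' total step budget. Fully deterministic given `seed`.
#'
#' @param federation a `federation` (see [make_federation()]).
#' @param ucfg an `unroll_config`.
#' @param cfg a `fed_config`.
#' @param schedule a `round_schedule`.
#' @param seed master seed (weight init, shuffles).
#' @param eval_every evaluate validation metrics every this many rounds
#'   (default 0 = final round only; per-round logging costs one validation
#'   sweep per round).
#' @param val_max cap on validation slices per client during per-round
#'   logging (NULL = all).
#' @return object of class `fed_result`: `global_weights`, `server_aux`,
#'   `client_states`, `history` (per-evaluation data frame), `final_metrics`,
#'   `algorithm`, `schedule`.
#' @export
run_federated <- function(federation, ucfg, cfg, schedule, seed = 1L,
                          eval_every = 0L, val_max = NULL) {
  K <- length(federation$clients)
  if (K < 1L) stop("federation has no clients", call. = FALSE)
  w0 <- init_denoiser(ucfg$denoiser, seed = derive_seed(seed, 71L))
  history <- list()
  log_metrics <- function(weights, round_idx) {
    rows <- lapply(seq_len(K), function(k) {
      val <- federation$clients[[k]]$val
      if (!is.null(val_max) && length(val) > val_max) val <- val[seq_len(val_max)]
      ev <- evaluate_weights(weights, val, ucfg)
      data.frame(round = round_idx, site_id = federation$clients[[k]]$profile$site_id,
                 ssim = ev$ssim, nrmse = ev$nrmse)
    })
    do.call(rbind, rows)
  }
  if (cfg$algorithm == "centralized") {
    pooled <- do.call(c, lapply(federation$clients, `[[`, "train"))
    weights <- w0
    opt_state <- NULL
    for (r in seq_len(schedule$n_rounds)) {
      tr <- local_train(weights, pooled, schedule$steps_per_round,
                        lr = cfg$local_lr, cfg = ucfg,
                        optimizer = cfg$local_optimizer, opt_state = opt_state,
                        seed = derive_seed(seed, 73L, r))
      weights <- tr$weights
      opt_state <- tr$opt_state
      if (eval_every > 0L && (r %% eval_every == 0L)) {
        history[[length(history) + 1L]] <- log_metrics(weights, r)
      }
    }
    fed <- list(global_weights = weights, server_aux = NULL,
                round_index = schedule$n_rounds)
    client_states <- NULL
  } else {
    fed <- list(global_weights = w0, server_aux = NULL,
                control_variate = weights_zero_like(w0), round_index = 0L)
    client_states <- lapply(seq_len(K), function(k) {
      list(client_id = k, control_variate = weights_zero_like(w0))
    })
    for (r in seq_len(schedule$n_rounds)) {
      if (cfg$algorithm == "scaffold") {
        uploads <- vector("list", K)
        for (k in seq_len(K)) {
          up <- scaffold_client_round(client_states[[k]], fed,
                                      federation$clients[[k]]$train,
                                      schedule$steps_per_round, cfg, ucfg,
                                      seed = derive_seed(seed, 79L, r, k))
          client_states[[k]]$control_variate <- up$c_new
          uploads[[k]] <- up[c("delta_w", "delta_c")]
        }
        fed <- scaffold_server_round(fed, uploads, cfg, n_expected = K)
      } else {
        client_w <- vector("list", K)
        for (k in seq_len(K)) {
          tr <- local_train(fed$global_weights, federation$clients[[k]]$train,
                            schedule$steps_per_round, lr = cfg$local_lr,
                            cfg = ucfg, optimizer = cfg$local_optimizer,
                            seed = derive_seed(seed, 79L, r, k))
          client_w[[k]] <- tr$weights
        }
        if (cfg$algorithm == "fedavg") {
          fed$global_weights <- fedavg_aggregate(client_w)
          fed$round_index <- fed$round_index + 1L
        } else {
          variant <- sub("^fed", "", cfg$algorithm)
          fed <- fedopt_server_round(fed, client_w, variant, cfg)
        }
      }
      if (eval_every > 0L && (r %% eval_every == 0L)) {
        history[[length(history) + 1L]] <- log_metrics(fed$global_weights, r)
      }
    }
  }
  final <- log_metrics(fed$global_weights, schedule$n_rounds)
  structure(
    list(global_weights = fed$global_weights, server_aux = fed$server_aux,
         control_variate = fed$control_variate, client_states = client_states,
         history = if (length(history)) do.call(rbind, history) else final,
         final_metrics = final, algorithm = cfg$algorithm,
         schedule = schedule, seed = seed),
    class = "fed_result"
  )
}
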