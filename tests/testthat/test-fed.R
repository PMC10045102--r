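# Federated optimization: aggregation identities, Scaffold reductions,
# adaptive server recursions, scheduling, and the training loop contracts.

make_toy_weights <- function(vals) {
  structure(list(a = matrix(vals[1:4], 2, 2), b = vals[5:6]),
            class = "model_weights")
}

test_that("fedavg aggregation is the elementwise mean", {
  w0 <- make_toy_weights(c(0, 0, 0, 0, 0, 0))
  w2 <- make_toy_weights(c(2, 2, 2, 2, 2, 2))
  m <- fedavg_aggregate(list(w0, w2))
  expect_equal(m$a, matrix(1, 2, 2))
  expect_equal(m$b, c(1, 1))
  expect_equal(fedavg_aggregate(list(w2, w2, w2)), w2)
  expect_error(fedavg_aggregate(list()), "at least one")
  # brute-force elementwise mean oracle on random collections
  set.seed(31)
  ws <- lapply(1:5, function(i) make_toy_weights(stats::rnorm(6)))
  m <- fedavg_aggregate(ws)
  for (nm in c("a", "b")) {
    acc <- 0
    for (i in 1:5) acc <- acc + ws[[i]][[nm]]
    expect_equal(m[[nm]], acc / 5, tolerance = 1e-15)
  }
  # permutation invariance
  expect_equal(fedavg_aggregate(ws[c(3, 1, 5, 2, 4)]), m, tolerance = 1e-12)
  # commutes with elementwise affine reparameterization
  aff <- lapply(ws, function(w) weights_map(function(x) 2 * x + 1, w))
  expect_equal(fedavg_aggregate(aff),
               weights_map(function(x) 2 * x + 1, m), tolerance = 1e-12)
})

test_that("round schedules preserve the fixed local-step budget", {
  for (r in c(240L, 120L, 80L, 60L, 40L, 24L, 4L)) {
    sch <- make_schedule(24000L, r)
    expect_equal(sch$n_rounds * sch$steps_per_round, 24000L)
  }
  sch <- make_schedule(400L, 20L)
  expect_equal(sch$steps_per_round, 20L)
  expect_equal(make_schedule(400L, 4L)$steps_per_round, 100L)
  expect_error(make_schedule(400L, 7L), "divisible")
})

test_that("scalar FedAdam recursion matches a hand-computed two-round oracle", {
  cfg <- fed_config("fedadam", eta_g = 0.1, beta1 = 0.9, beta2 = 0.99,
                    tau = 1e-3)
  th0 <- 1.0
  fed <- list(global_weights = structure(list(w = th0), class = "model_weights"),
              server_aux = NULL, round_index = 0L)
  up1 <- 1.5; up2 <- 0.8   # client means per round (single client)
  fed <- fedopt_server_round(fed, list(structure(list(w = up1), class = "model_weights")),
                             "adam", cfg)
  # hand recursion, round 1
  d1 <- up1 - th0
  m1 <- 0.1 * d1
  v1 <- 0.01 * d1^2
  th1 <- th0 + 0.1 * m1 / (sqrt(v1) + 1e-3)
  expect_equal(fed$global_weights$w, th1, tolerance = 1e-12)
  fed <- fedopt_server_round(fed, list(structure(list(w = up2), class = "model_weights")),
                             "adam", cfg)
  d2 <- up2 - th1
  m2 <- 0.9 * m1 + 0.1 * d2
  v2 <- 0.99 * v1 + 0.01 * d2^2
  th2 <- th1 + 0.1 * m2 / (sqrt(v2) + 1e-3)
  expect_equal(fed$global_weights$w, th2, tolerance = 1e-12)
})

test_that("adaptive server updates are fixed points at zero pseudo-gradient", {
  for (variant in c("adam", "yogi", "adagrad")) {
    cfg <- fed_config(paste0("fed", variant))
    w <- make_toy_weights(stats::rnorm(6))
    fed <- list(global_weights = w, server_aux = NULL, round_index = 0L)
    fed2 <- fedopt_server_round(fed, list(w, w), variant, cfg)
    expect_equal(fed2$global_weights, w, tolerance = 1e-15)
  }
  expect_error(match.arg("nadam", c("adam", "yogi", "adagrad")))
})

test_that("adagrad with beta1 = 0 steps in the sign of the pseudo-gradient", {
  cfg <- fed_config("fedadagrad", beta1 = 0, eta_g = 0.5)
  w <- make_toy_weights(c(1, -1, 2, -2, 0.5, -0.5))
  up <- make_toy_weights(c(2, -3, 2.5, -1, 1, -2))
  fed <- list(global_weights = w, server_aux = NULL, round_index = 0L)
  fed2 <- fedopt_server_round(fed, list(up), "adagrad", cfg)
  for (nm in c("a", "b")) {
    delta <- up[[nm]] - w[[nm]]
    step <- fed2$global_weights[[nm]] - w[[nm]]
    expect_true(all(sign(step[delta != 0]) == sign(delta[delta != 0])))
  }
})

test_that("scaffold with zero control variates reduces to plain local descent", {
  cfg_u <- tiny_cfg()
  fcfg <- fed_config("scaffold", local_lr = 1e-3, local_optimizer = "sgd")
  s <- tiny_sample(seed = 41)
  w0 <- init_denoiser(cfg_u$denoiser, seed = 1)
  fed <- list(global_weights = w0, control_variate = weights_zero_like(w0))
  st <- list(client_id = 1, control_variate = weights_zero_like(w0))
  up <- scaffold_client_round(st, fed, list(s), steps = 3, fcfg, cfg_u, seed = 9)
  plain <- local_train(w0, list(s), 3, lr = 1e-3, cfg = cfg_u,
                       optimizer = "sgd", seed = 9)
  expect_equal(weights_axpy(1, up$delta_w, w0), plain$weights,
               tolerance = 1e-14)
})

test_that("scaffold option (ii) with one step recovers the raw gradient", {
  cfg_u <- tiny_cfg()
  eta <- 1e-3
  fcfg <- fed_config("scaffold", local_lr = eta, local_optimizer = "sgd")
  s <- tiny_sample(seed = 43)
  w0 <- init_denoiser(cfg_u$denoiser, seed = 2)
  fed <- list(global_weights = w0, control_variate = weights_zero_like(w0))
  st <- list(client_id = 1, control_variate = weights_zero_like(w0))
  up <- scaffold_client_round(st, fed, list(s), steps = 1, fcfg, cfg_u, seed = 5)
  g <- fedunroll:::modl_loss_grad(normalize_sample(s), w0, cfg_u)$grad
  # c+ = c - cg + (theta_G - theta)/ (S eta) = g for a single SGD step
  for (nm in names(g)) {
    expect_equal(up$c_new[[nm]], g[[nm]], tolerance = 1e-10)
  }
  # zero local step size triggers the option (ii) division guard
  fcfg0 <- fed_config("scaffold", local_lr = 0, local_optimizer = "sgd")
  expect_error(scaffold_client_round(st, fed, list(s), 1, fcfg0, cfg_u),
               "zero local step")
})

test_that("option (ii) displacement and gradient-unit forms agree under SGD", {
  # (theta_G - theta_k)/(S eta_l) equals the mean corrected gradient for
  # SGD clients, so the displacement form of the control-variate update and
  # the accumulated-raw-gradient form coincide (the latter is what adaptive
  # clients use)
  cfg_u <- tiny_cfg()
  fcfg <- fed_config("scaffold", local_lr = 1e-3, local_optimizer = "sgd")
  ds <- list(tiny_sample(seed = 44), tiny_sample(seed = 45))
  w0 <- init_denoiser(cfg_u$denoiser, seed = 6)
  c_k <- weights_scale(1e-3, init_denoiser(cfg_u$denoiser, seed = 7))
  c_g <- weights_scale(-5e-4, init_denoiser(cfg_u$denoiser, seed = 8))
  fed <- list(global_weights = w0, control_variate = c_g)
  st <- list(client_id = 1, control_variate = c_k)
  up <- scaffold_client_round(st, fed, ds, steps = 4, fcfg, cfg_u, seed = 12)
  corr <- weights_map(`-`, c_g, c_k)
  tr <- local_train(w0, ds, 4, lr = 1e-3, cfg = cfg_u, optimizer = "sgd",
                    seed = 12,
                    grad_transform = function(g) weights_map(`+`, g, corr),
                    return_mean_grad = TRUE)
  # the displacement form accumulates cancellation error (weight deltas are
  # ~1e-9 here), so agreement is to single-precision-like relative accuracy
  for (nm in names(w0)) {
    expect_equal(up$c_new[[nm]], tr$mean_grad[[nm]], tolerance = 1e-5)
  }
})

test_that("scaffold server aggregation accumulates means with eta_g scaling", {
  w <- make_toy_weights(c(1, 1, 1, 1, 1, 1))
  z <- weights_zero_like(w)
  fed <- list(global_weights = w, control_variate = z, round_index = 0L)
  cfg <- fed_config("scaffold", eta_g = 1)
  ups <- list(list(delta_w = z, delta_c = z), list(delta_w = z, delta_c = z))
  fed2 <- scaffold_server_round(fed, ups, cfg, n_expected = 2)
  expect_equal(fed2$global_weights, w, tolerance = 1e-15)
  dc1 <- make_toy_weights(c(2, 0, 0, 0, 0, 0))
  ups <- list(list(delta_w = z, delta_c = dc1), list(delta_w = z, delta_c = z))
  fed3 <- scaffold_server_round(fed2, ups, cfg, n_expected = 2)
  expect_equal(fed3$control_variate$a[1, 1], 1)  # running mean accumulates
  fed4 <- scaffold_server_round(fed3, ups, cfg, n_expected = 2)
  expect_equal(fed4$control_variate$a[1, 1], 2)
  expect_error(scaffold_server_round(fed, ups[1], cfg, n_expected = 2),
               "synchronicity")
})

test_that("scaffold with pinned-zero variates and eta_g = 1 reproduces FedAvg", {
  cfg_u <- tiny_cfg()
  fedn <- make_federation(default_profiles(2), iid = FALSE, seed = 11,
                          n_val_subjects = 1)
  w0 <- init_denoiser(cfg_u$denoiser, seed = 3)
  fcfg <- fed_config("scaffold", local_lr = 1e-3, local_optimizer = "sgd")
  global <- w0
  for (r in 1:2) {
    fed <- list(global_weights = global,
                control_variate = weights_zero_like(w0))
    ups <- lapply(1:2, function(k) {
      st <- list(client_id = k, control_variate = weights_zero_like(w0))
      scaffold_client_round(st, fed, fedn$clients[[k]]$train, 3, fcfg, cfg_u,
                            seed = 100 + 10 * r + k)
    })
    fed <- scaffold_server_round(fed, lapply(ups, `[`, c("delta_w", "delta_c")),
                                 fcfg, n_expected = 2)
    global <- fed$global_weights
    # FedAvg reference round with the same SGD clients
    avg_ref <- fedavg_aggregate(lapply(1:2, function(k) {
      local_train(if (r == 1) w0 else global_prev, fedn$clients[[k]]$train, 3,
                  lr = 1e-3, cfg = cfg_u, optimizer = "sgd",
                  seed = 100 + 10 * r + k)$weights
    }))
    # compare trajectories exactly
    for (nm in names(global)) expect_equal(global[[nm]], avg_ref[[nm]],
                                           tolerance = 1e-13)
    global_prev <- global
  }
})

test_that("single-client FedAvg equals centralized training with the same seed", {
  cfg_u <- tiny_cfg()
  fedn <- make_federation(default_profiles(1), iid = FALSE, seed = 13,
                          n_val_subjects = 1)
  sch <- make_schedule(20, 2)
  res <- run_federated(fedn, cfg_u, fed_config("fedavg", local_lr = 1e-3),
                       sch, seed = 21)
  # replicate: same init, same per-round local training (optimizer state
  # resets at each broadcast, as in the federated loop)
  w <- init_denoiser(cfg_u$denoiser, seed = fedunroll:::derive_seed(21, 71L))
  for (r in 1:2) {
    w <- local_train(w, fedn$clients[[1]]$train, 10, lr = 1e-3, cfg = cfg_u,
                     seed = fedunroll:::derive_seed(21, 79L, r, 1))$weights
  }
  expect_equal(res$global_weights, w, tolerance = 1e-14)
})

test_that("federated runs are deterministic and log per-round metrics", {
  cfg_u <- tiny_cfg()
  fedn <- make_federation(default_profiles(2), iid = FALSE, seed = 17,
                          n_val_subjects = 1)
  sch <- make_schedule(10, 2)
  r1 <- run_federated(fedn, cfg_u, fed_config("fedyogi"), sch, seed = 5,
                      eval_every = 1L, val_max = 3L)
  r2 <- run_federated(fedn, cfg_u, fed_config("fedyogi"), sch, seed = 5,
                      eval_every = 1L, val_max = 3L)
  expect_identical(r1$history, r2$history)
  expect_equal(nrow(r1$history), 2 * 2)  # rounds x clients
  expect_true(all(c("round", "site_id", "ssim", "nrmse") %in% names(r1$history)))
})

test_that("only weight-shaped payloads cross the client/server boundary", {
  cfg_u <- tiny_cfg()
  fcfg <- fed_config("scaffold", local_lr = 1e-3, local_optimizer = "sgd")
  s <- tiny_sample(seed = 55)
  w0 <- init_denoiser(cfg_u$denoiser, seed = 1)
  fed <- list(global_weights = w0, control_variate = weights_zero_like(w0))
  st <- list(client_id = 1, control_variate = weights_zero_like(w0))
  up <- scaffold_client_round(st, fed, list(s), 2, fcfg, cfg_u, seed = 1)
  upload <- up[c("delta_w", "delta_c")]       # what the client transmits
  for (part in upload) {
    expect_identical(names(part), names(w0))
    expect_true(all(vapply(part, is.numeric, logical(1))))
  }
  payload <- rawToChar(serialize(upload, NULL, ascii = TRUE))
  expect_false(grepl("kspace|sens_maps|target_rss", payload))
  # serialized payload is weight-sized, not data-sized
  expect_lt(length(serialize(upload, NULL)),
            4 * 8 * fedunroll:::n_params(w0) + 1e4)
})
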