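# Client-side personalization: after federated training concludes, a client
# fine-tunes the broadcast global model on its own local slices only. The
# fine-tuning learning rate and epoch count are selected by k-fold
# cross-validation on the local training data, with subject-stratified fold
# assignment and early stopping at the epoch maximizing mean held-out SSIM.

#' Personalization configuration
#'
#' @param lr_grid candidate fine-tuning learning rates (default
#'   `c(1e-5, 1e-4)`).
#' @param max_epochs epoch ceiling for the cross-validated early-stopping
#'   search (default 200; scale down for quick experiments).
#' @param n_folds number of cross-validation folds (default 5).
#' @return object of class `personalization_config`.
#' @export
personalization_config <- function(lr_grid = c(1e-5, 1e-4), max_epochs = 200L,
                                   n_folds = 5L) {
  if (length(lr_grid) == 0L) stop("lr_grid must be non-empty", call. = FALSE)
  if (n_folds < 2L) stop("need at least 2 folds", call. = FALSE)
  if (max_epochs < 1L) stop("max_epochs must be >= 1", call. = FALSE)
  structure(list(lr_grid = lr_grid, max_epochs = as.integer(max_epochs),
                 n_folds = as.integer(n_folds)),
            class = "personalization_config")
}

# Subject-stratified fold assignment: within each subject, slices are dealt
# round-robin (after a seeded shuffle) so every fold sees every subject.
assign_folds <- function(dataset, n_folds, seed) {
  subj <- vapply(dataset, function(s) {
    if (is.null(s$subject_id)) NA_integer_ else as.integer(s$subject_id)
  }, integer(1))
  if (anyNA(subj)) subj <- rep(1L, length(dataset))
  folds <- integer(length(dataset))
  for (sg in unique(subj)) {
    idx <- which(subj == sg)
    idx <- with_seed(derive_seed(seed, 83L, sg), sample(idx))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

#' Cross-validated selection of fine-tuning hyper-parameters
#'
#' For every candidate learning rate, runs `n_folds`-fold cross-validation on
#' the client's local data: fine-tune on the in-fold slices for up to
#' `max_epochs` epochs, tracking mean held-out SSIM after every epoch (epoch
#' 0 is the unmodified global model). Selects the (learning rate, epoch) pair
#' maximizing the fold-averaged held-out SSIM; ties break toward the smaller
#' learning rate, then the smaller epoch count (least perturbation of the
#' global model).
#'
#' @param global_weights the broadcast global `model_weights`.
#' @param dataset the client's local samples (length >= `n_folds`).
#' @param cfg a `personalization_config`.
#' @param ucfg an `unroll_config`.
#' @param seed integer seed (fold assignment and training shuffles).
#' @return list with `r_fine`, `n_fine`, and the `cv_curves` data frame
#'   (columns `lr`, `epoch`, `ssim`).
#' @export
crossval_select <- function(global_weights, dataset, cfg, ucfg, seed = 1L) {
  if (length(dataset) < cfg$n_folds) {
    stop("dataset smaller than the number of folds", call. = FALSE)
  }
  dataset <- lapply(dataset, normalize_sample)
  folds <- assign_folds(dataset, cfg$n_folds, seed)
  curves <- list()
  for (lr in cfg$lr_grid) {
    ssim_mat <- matrix(NA_real_, cfg$n_folds, cfg$max_epochs + 1L)
    for (f in seq_len(cfg$n_folds)) {
      train <- dataset[folds != f]
      held <- dataset[folds == f]
      if (length(held) == 0L || length(train) == 0L) next
      w <- global_weights
      opt_state <- NULL
      ssim_mat[f, 1L] <- evaluate_weights(w, held, ucfg)$ssim
      if (lr > 0) {
        for (e in seq_len(cfg$max_epochs)) {
          tr <- local_train(w, train, n_steps = length(train), lr = lr,
                            cfg = ucfg, opt_state = opt_state,
                            seed = derive_seed(seed, 89L, f, e))
          w <- tr$weights
          opt_state <- tr$opt_state
          ssim_mat[f, e + 1L] <- evaluate_weights(w, held, ucfg)$ssim
        }
      } else {
        ssim_mat[f, -1L] <- ssim_mat[f, 1L]
      }
    }
    curves[[as.character(lr)]] <- colMeans(ssim_mat, na.rm = TRUE)
  }
  cv <- do.call(rbind, lapply(names(curves), function(lrc) {
    data.frame(lr = as.numeric(lrc), epoch = 0:cfg$max_epochs,
               ssim = curves[[lrc]])
  }))
  # selection: max mean held-out SSIM; ties -> smaller lr, then smaller epoch
  ord <- order(-cv$ssim, cv$lr, cv$epoch)
  best <- cv[ord[1L], ]
  list(r_fine = best$lr, n_fine = as.integer(best$epoch), cv_curves = cv)
}

#' Fine-tune the global model on local data
#'
#' `n_fine` epochs of single-sample adaptive-moment training over all local
#' slices, starting from the broadcast global weights, with the same
#' negative-SSIM objective used in federated training. `n_fine = 0` returns
#' the global weights unchanged.
#'
#' @param global_weights the broadcast global `model_weights`.
#' @param dataset the client's full local dataset.
#' @param r_fine fine-tuning learning rate (>= 0).
#' @param n_fine number of fine-tuning epochs (>= 0).
#' @param ucfg an `unroll_config`.
#' @param seed integer seed for the sample shuffles.
#' @return the personalized `model_weights`.
#' @export
fine_tune <- function(global_weights, dataset, r_fine, n_fine, ucfg, seed = 1L) {
  if (r_fine < 0) stop("r_fine must be nonnegative", call. = FALSE)
  if (n_fine < 0) stop("n_fine must be nonnegative", call. = FALSE)
  if (n_fine == 0L || r_fine == 0) return(global_weights)
  tr <- local_train(global_weights, dataset,
                    n_steps = as.integer(n_fine) * length(dataset),
                    lr = r_fine, cfg = ucfg, seed = derive_seed(seed, 97L))
  tr$weights
}

#' Personalize a client: select hyper-parameters, then fine-tune
#'
#' Convenience wrapper: cross-validated selection of `(r_fine, n_fine)` on
#' the local training data, followed by fine-tuning on all local slices with
#' the selected values.
#'
#' @inheritParams crossval_select
#' @return list with `weights`, `r_fine`, `n_fine`, `cv_curves`.
#' @export
personalize_client <- function(global_weights, dataset, cfg, ucfg, seed = 1L) {
  sel <- crossval_select(global_weights, dataset, cfg, ucfg, seed = seed)
  w <- fine_tune(global_weights, dataset, sel$r_fine, sel$n_fine, ucfg,
                 seed = seed)
  list(weights = w, r_fine = sel$r_fine, n_fine = sel$n_fine,
       cv_curves = sel$cv_curves)
}
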