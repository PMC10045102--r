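# Algebra on model weight collections. A `model_weights` object is an ordered
# named list of real parameter arrays; two collections are conformable iff
# their names and shapes match. All federated update rules below reduce to
# elementwise operations on these collections.

#' Weight-collection arithmetic
#'
#' Elementwise helpers over `model_weights` collections: map a function over
#' one or more conformable collections, zero-like, a*x + y, scaling, and the
#' elementwise mean of a list of collections.
#'
#' @param f function applied elementwise.
#' @param ... one or more conformable `model_weights` collections.
#' @return a `model_weights` collection.
#' @export
weights_map <- function(f, ...) {
  ws <- list(...)
  out <- ws[[1]]
  nm <- names(out)
  for (j in seq_along(ws)[-1]) {
    if (!identical(names(ws[[j]]), nm)) {
      stop("weight collections are not conformable", call. = FALSE)
    }
  }
  for (n in nm) {
    out[[n]] <- do.call(f, lapply(ws, function(w) w[[n]]))
  }
  structure(out, class = "model_weights")
}

#' @rdname weights_map
#' @param w a `model_weights` collection.
#' @export
weights_zero_like <- function(w) weights_map(function(x) x * 0, w)

#' @rdname weights_map
#' @param a scalar.
#' @param x,y conformable collections.
#' @export
weights_axpy <- function(a, x, y) weights_map(function(u, v) a * u + v, x, y)

#' @rdname weights_map
#' @export
weights_scale <- function(a, x) weights_map(function(u) a * u, x)

#' @rdname weights_map
#' @param ws list of conformable collections.
#' @export
weights_mean <- function(ws) {
  if (length(ws) == 0L) stop("empty list of weight collections", call. = FALSE)
  out <- ws[[1]]
  for (n in names(out)) {
    acc <- ws[[1]][[n]]
    if (length(ws) > 1L) {
      for (j in 2:length(ws)) acc <- acc + ws[[j]][[n]]
    }
    out[[n]] <- acc / length(ws)
  }
  structure(out, class = "model_weights")
}

# Squared Euclidean norm across the whole collection.
weights_sqnorm <- function(w) sum(vapply(w, function(x) sum(x^2), numeric(1)))

n_params <- function(w) sum(vapply(w, length, integer(1)))

# --- local adaptive-moment optimizer (Adam) --------------------------------

adam_init <- function(w) {
  list(m = weights_zero_like(w), v = weights_zero_like(w), t = 0L)
}

adam_step <- function(w, g, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- weights_map(function(m, gg) beta1 * m + (1 - beta1) * gg, state$m, g)
  state$v <- weights_map(function(v, gg) beta2 * v + (1 - beta2) * gg^2, state$v, g)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  w <- weights_map(function(th, m, v) th - lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   w, state$m, state$v)
  list(weights = w, state = state)
}

sgd_step <- function(w, g, lr) weights_axpy(-lr, g, w)

# --- checkpointing ---------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Named-array archive with a configuration header; the reload round trip is
#' bit-exact.
#'
#' @param weights a `model_weights` collection.
#' @param spec the `denoiser_spec` the weights conform to.
#' @param path file path.
#' @param extra optional named list of additional header fields.
#' @return `path` invisibly for save; a list with `weights`, `spec`, `extra`
#'   for load.
#' @export
save_checkpoint <- function(weights, spec, path, extra = list()) {
  saveRDS(list(weights = weights, spec = spec, extra = extra,
               format = "fedunroll-checkpoint-1"), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "fedunroll-checkpoint-1")) {
    stop("not a fedunroll checkpoint", call. = FALSE)
  }
  ck[c("weights", "spec", "extra")]
}
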