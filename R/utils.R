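#' @keywords internal
#' @useDynLib fedunroll, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Derive a child seed from a master seed and integer offsets.
# Keeps results < 2^31 and decorrelates streams (client, subject, slice, ...)
# so that adding one stream never perturbs another.
derive_seed <- function(seed, ...) {
  offs <- c(...)
  s <- as.double(seed) %% 2147483629
  for (o in offs) {
    s <- (s * 69069 + as.double(o) * 2654435761 + 1013904223) %% 2147483629
  }
  as.integer(s)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

stopifnot_finite <- function(x, what = "input") {
  if (!all(is.finite(Re(x))) || (is.complex(x) && !all(is.finite(Im(x))))) {
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  }
  invisible(TRUE)
}
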