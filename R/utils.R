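# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. `seed = NULL` leaves the global stream in charge.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Monic polynomial coefficients (descending powers) from its roots.
poly_from_roots <- function(roots) {
  coefs <- 1
  for (r in roots) coefs <- c(coefs, 0) - c(0, r * coefs)
  coefs
}

stop_if_not_signal <- function(x, arg = deparse(substitute(x))) {
  if (!inherits(x, "sampled_signal"))
    stop(sprintf("`%s` must be a sampled_signal", arg))
  invisible(x)
}

stop_if_not_ibi <- function(x, arg = deparse(substitute(x))) {
  if (!inherits(x, "ibi_series"))
    stop(sprintf("`%s` must be an ibi_series", arg))
  invisible(x)
}
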