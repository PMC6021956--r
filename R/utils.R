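# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded simulation code never
#' disturbs the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_hbci <- function(msg, class) {
  stop(structure(class = c(class, "hbci_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop_hbci(sprintf("'%s' must be a finite number in [%s, %s]", name, lo, hi),
              "hbci_config_error")
  invisible(x)
}

# Stratified fold assignment: within each class, a seeded permutation of the
# class's trials is dealt round-robin into k folds. Returns an integer vector
# of fold ids (1..k) aligned with `labels`. Uses the caller's RNG stream.
stratified_folds <- function(labels, k) {
  labels <- as.character(labels)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Raised-cosine gate: 0 outside [on, off], 1 inside, half-cosine ramps of
# length `ramp` centred on the edges.
cosine_gate <- function(t, on, off, ramp) {
  g <- numeric(length(t))
  g[t >= on + ramp & t <= off - ramp] <- 1
  up <- t >= on & t < on + ramp
  g[up] <- 0.5 - 0.5 * cos(pi * (t[up] - on) / ramp)
  dn <- t > off - ramp & t <= off
  g[dn] <- 0.5 - 0.5 * cos(pi * (off - t[dn]) / ramp)
  g
}
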