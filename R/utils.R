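# Internal helpers shared across modules.

#' Stop with a formatted message
#' @noRd
abort <- function(...) stop(sprintf(...), call. = FALSE)

#' Check a scalar probability/proportion
#' @noRd
check_prop <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    abort("%s must be a single value in [0, 1], got %s", what, format(x))
  invisible(x)
}

#' Evaluate an expression under a local RNG seed, restoring the caller's state
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Geometric mean of positive values
#' @noRd
geo_mean <- function(x) exp(mean(log(x)))

#' log2 with pseudocount
#' @noRd
log2p <- function(x, pseudo) log2(x + pseudo)

#' Benjamini-Hochberg adjustment (thin wrapper kept for a single call site)
#' @noRd
bh_adjust <- function(p) p.adjust(p, method = "BH")

#' Type-stable sparse-to-dense column extraction
#' @noRd
dense_col <- function(m, j) as.numeric(m[, j])
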