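# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package operations do not
#' disturb the caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Row/column coordinates (1-based) of linear indices into an nrow x ncol grid.
idx_rows <- function(idx, nr) ((idx - 1L) %% nr) + 1L
idx_cols <- function(idx, nr) ((idx - 1L) %/% nr) + 1L
rc_to_idx <- function(row, col, nr) (col - 1L) * nr + row

# Truncated-normal draws by rejection; bounds may be +-Inf.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(0)
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    abort_if(guard > 10000L, "truncated-normal rejection sampling failed")
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}
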