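# Internal numeric helpers shared across modules.

INTENSITY_MAX <- 4095  # 12-bit camera scale

#' @noRd
clip01 <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Column-wise cumulative sums without apply(); used by the box filters.
#' @noRd
col_cumsum <- function(M) {
  h <- nrow(M); w <- ncol(M)
  cs <- matrix(cumsum(M), h, w)
  if (w > 1) cs <- cs - rep(c(0, cs[h, -w]), each = h)
  cs
}

# Sliding 5x5 box sum with replicate-padded borders. Output has the
# input's dimensions; entry (i,j) is the sum over the 5x5 window
# centred at (i,j) of the padded image.
#' @noRd
box5_sum <- function(m) {
  h <- nrow(m); w <- ncol(m)
  P <- m[c(1, 1, 1:h, h, h), c(1, 1, 1:w, w, w)]
  cs <- rbind(0, col_cumsum(P))
  A <- cs[6:(h + 5), , drop = FALSE] - cs[1:h, , drop = FALSE]
  B <- t(A)
  cs2 <- rbind(0, col_cumsum(B))
  t(cs2[6:(w + 5), , drop = FALSE] - cs2[1:w, , drop = FALSE])
}

# Run a block of code with a temporary RNG stream, restoring the caller's
# RNG state afterwards so lazily rendered frames do not perturb user code.
#' @noRd
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @noRd
is_single_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
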