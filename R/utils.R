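# internal helpers shared across modules

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
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
  })
  set.seed(seed)
  force(code)
}

# Derive child seeds (< 2^31) reproducibly from a master seed.
derive_seeds <- function(seed, n) {
  local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Expected mean of the folded allele fraction min(X, 1 - X) when the
# unfolded fraction X is approximately N(m, s). Folding pulls the mean of
# near-balanced segments below 0.5 by ~ s * sqrt(2/pi); ignoring this biases
# minor-allele-count inference at balanced states.
expected_folded_maf <- function(m, s) {
  mu <- abs(m - 0.5)
  out <- ifelse(
    s <= 0,
    pmin(m, 1 - m),
    0.5 - (s * sqrt(2 / pi) * exp(-mu^2 / (2 * s^2)) +
             mu * (1 - 2 * stats::pnorm(-mu / s)))
  )
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Invert the folding bias: given an observed mean folded minor fraction g
# at SNP depth `depth`, recover the underlying mean m with
# expected_folded_maf(m, binomial sd at depth) = g. Monotone interpolation
# on a fine m-grid; observations above the folded ceiling map to 0.5.
unfold_maf <- function(g, depth, grid = seq(0, 0.5, by = 0.0025)) {
  out <- numeric(length(g))
  for (k in seq_along(g)) {
    fv <- expected_folded_maf(grid, sqrt(grid * (1 - grid) / depth[k]))
    out[k] <- if (g[k] >= max(fv)) 0.5 else if (g[k] <= fv[1]) grid[1] else
      stats::approx(fv, grid, xout = g[k])$y
  }
  out
}
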