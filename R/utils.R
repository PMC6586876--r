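# Internal helpers shared across modules.

#' @importFrom stats rnorm runif rpois sd var quantile
#' @importFrom rlang abort warn .data
NULL

# Derive a reproducible sub-seed for a named stream from a master seed.
# Keeps results independent across streams (events / spikes / kinematics / cv)
# while remaining a deterministic function of the master seed. Always < 2^31.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) * 2654435 + h * 40503 + 12345) %% 2147483647)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

softplus <- function(x) {
  # numerically stable log(1 + exp(x)), branch-free for speed on big arrays
  log1p(exp(pmin(x, 50))) + pmax(x - 50, 0)
}

softplus_inv <- function(y) {
  stopifnot(all(y > 0))
  ifelse(y > 30, y, log(expm1(y)))
}

# C1 smooth ramp: 0 below t0, 1 above t0 + rise, smoothstep in between.
smoothstep <- function(t, t0, rise) {
  x <- pmin(pmax((t - t0) / rise, 0), 1)
  x * x * (3 - 2 * x)
}

# Orthonormal basis via QR with deterministic column signs.
orthonormalize <- function(m) {
  qr_m <- qr(m)
  q <- qr.Q(qr_m)
  signs <- sign(diag(qr.R(qr_m)))
  signs[signs == 0] <- 1
  sweep(q, 2, signs, `*`)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
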