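# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All exported stochastic entry points funnel through this.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Truncated-normal draws by inverse-CDF; support [lo, hi].
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Largest-remainder allocation of `total` into shares proportional to w.
allocate_counts <- function(total, w) {
  stopifnot(total >= 0, all(w >= 0), sum(w) > 0)
  raw <- total * w / sum(w)
  base <- floor(raw)
  short <- total - sum(base)
  if (short > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(fmt, ...) {
  stop(sprintf(paste0("configuration error: ", fmt), ...), call. = FALSE)
}
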