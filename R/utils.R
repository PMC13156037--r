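# Internal helpers shared across modules.

# Floor p-values away from 0 so signed -log10 / qnorm stay finite.
.P_FLOOR <- 1e-300

.check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

.check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  }
  x
}

# Local RNG scope: run `expr` under a given seed without disturbing the
# caller's RNG stream. Generators are pure functions of (config, seed).
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  seed <- .check_count(seed, "seed", min = 0L)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Two-sided normal p from a Z statistic.
.p_from_z <- function(z) 2 * stats::pnorm(-abs(z))

# Signed Z from a two-sided p-value and an effect direction.
.z_from_p <- function(p, sign) {
  p <- pmax(p, .P_FLOOR)
  sign * stats::qnorm(p / 2, lower.tail = FALSE)
}

.signed_log10p <- function(p, sign) sign * -log10(pmax(p, .P_FLOOR))
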