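# internal validators and seed plumbing

check_prob <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be a finite numeric vector.", name))
  }
  if (any(x < lo | x > hi)) {
    abort(sprintf("`%s` must lie in [%s, %s].", name, format(lo), format(hi)))
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

check_flag_choice <- function(x, name, choices) {
  x <- match.arg(x, choices)
  x
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Deterministic per-run seed from a base seed and a run index. Kept below
# 2^31 - 1 so it is always a valid R integer seed; distinct run indices give
# distinct seeds for any fixed base seed (indices stay far below 1e6).
derive_seed <- function(base_seed, index) {
  base <- as.numeric(base_seed) %% 1000003
  as.integer((base * 1000000 + as.numeric(index)) %% 2147483647)
}

# Uniform sample of k elements from a pool, safe for length-one pools
# (base::sample() would treat a scalar as 1:n).
sample_pool <- function(pool, k) {
  n <- length(pool)
  k <- min(k, n)
  if (k == 0L) return(pool[0])
  pool[sample.int(n, k)]
}
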