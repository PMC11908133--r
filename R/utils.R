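# Internal numerical helpers.

# log(sum(exp(x))) without overflow; -Inf for empty/all -Inf input
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Continuous binomial coefficient via lgamma: identical to lchoose at
# integer counts but silent for the non-integer expected counts that
# noiseless fixtures carry.
lchoose_cont <- function(n, k) lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)

# Binomial log-likelihood tolerant of non-integer counts (the normalizing
# term is constant in p, so continuity in k is harmless for optimization).
ll_binom <- function(k, n, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  lchoose_cont(n, k) + k * log(p) + (n - k) * log1p(-p)
}

condition_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "clonedyn_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
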