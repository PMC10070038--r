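# Internal numerical helpers.

.gh_cache <- new.env(parent = emptyenv())

# Gauss-Hermite rule (physicists' weight exp(-t^2)), cached by node count.
gh_rule <- function(nodes = 64L) {
  key <- as.character(nodes)
  if (is.null(.gh_cache[[key]])) .gh_cache[[key]] <- pracma::gaussHermite(nodes)
  .gh_cache[[key]]
}

# Largest-remainder (Hamilton) apportionment of `total` into integer counts
# proportional to `p`. Preserves sum(counts) == total exactly.
largest_remainder <- function(p, total) {
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-8)
  target <- total * p / sum(p)
  fl <- floor(target)
  k <- as.integer(round(total - sum(fl)))
  if (k > 0L) {
    idx <- order(target - fl, decreasing = TRUE)[seq_len(k)]
    fl[idx] <- fl[idx] + 1
  }
  as.integer(fl)
}

# mu(1-mu) for mu = plogis(eta): the logistic information weight
# w = exp(-eta) / (1 + exp(-eta))^2.
logis_weight <- function(eta) {
  mu <- stats::plogis(eta)
  mu * (1 - mu)
}

# Two-sided Wald power at level alpha given the true log-odds effect and the
# variance v of its estimator: Phi(-z + b/sqrt(v)) + Phi(-z - b/sqrt(v)).
wald_power <- function(beta_G, v, alpha) {
  z <- stats::qnorm(1 - alpha / 2)
  s <- beta_G / sqrt(v)
  stats::pnorm(-z + s) + stats::pnorm(-z - s)
}

# Extract [I^-1]_{G,G} (the 2nd diagonal element, order intercept, G, E...)
# via a linear solve rather than full inversion.
inv_gg <- function(info) {
  rc <- rcond(info)
  if (!is.finite(rc) || rc < 1e-12)
    warning("information matrix is ill-conditioned (rcond = ",
            format(rc, digits = 3), "); results may be unstable")
  e2 <- numeric(ncol(info))
  e2[2L] <- 1
  as.numeric(solve(info, e2)[2L])
}

# set.seed only when a seed is supplied; keeps functions usable inside an
# existing RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
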