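#' Simulate a complete association study
#'
#' Full-simulation benchmark data. Prospective: covariates from the
#' population law, then Y ~ Bernoulli(expit(eta)) at the population
#' intercept. Retrospective: exactly `round(case_fraction * n)` cases drawn
#' from P(x|Y=1) and the rest controls from P(x|Y=0) (exact cell sampling
#' for discrete designs, rejection sampling otherwise).
#'
#' @inheritParams power_ss
#' @param n Study size.
#' @param seed Optional integer seed.
#' @return `data.frame` with columns `G`, `E1`, ..., `Y`; attributes `design`
#'   and `seed`.
#' @export
simulate_study <- function(design_cov, trait, design, n, seed = NULL) {
  res <- resolve_inputs(design_cov, trait, design)
  out <- with_seed(seed, {
    if (res$design$mode == "prospective") {
      rows <- sample_covariates(res$design_cov, n)
      mu <- stats::plogis(eta_rows(rows, res$trait$beta0, res$design_cov,
                                   res$trait))
      rows$Y <- stats::rbinom(n, 1L, mu)
      rows
    } else {
      n1 <- as.integer(round(res$design$case_fraction * n))
      rows <- sample_case_control_rows(res, n1, n - n1)
      rows$Y <- rep(c(1L, 0L), c(n1, n - n1))
      rows[sample.int(n), , drop = FALSE]
    }
  })
  rownames(out) <- NULL
  attr(out, "design") <- res$design$mode
  attr(out, "seed") <- seed
  out
}

#' Logistic MLE and observed information for a simulated study
#'
#' Fits the logistic regression of Y on (1, G, E...) by IRLS
#' ([stats::glm.fit()]) and returns the MLE together with the observed
#' Fisher information \eqn{X^T W(\hat\beta) X}, where W is diagonal with
#' entries \eqn{\hat\mu_i(1-\hat\mu_i)}. Non-convergence or (quasi-)complete
#' separation is flagged rather than raised, so the caller can drop and
#' count failed replicates.
#'
#' @param study Output of [simulate_study()] (or any data frame with columns
#'   `G`, `E*`, `Y`).
#' @return List with `beta` (named: intercept, G, E...), `info`, `converged`.
#' @export
fit_logistic <- function(study) {
  X <- model_matrix_rows(study)
  colnames(X) <- c("(Intercept)", "G",
                   grep("^E[0-9]+$", names(study), value = TRUE))
  fit <- suppressWarnings(
    stats::glm.fit(X, study$Y, family = stats::binomial()))
  beta <- fit$coefficients
  mu <- fit$fitted.values
  info <- crossprod(X, X * (mu * (1 - mu)))
  ok <- fit$converged && all(is.finite(beta)) && max(abs(beta)) < 30 &&
    is.finite(rcond(info)) && rcond(info) > 1e-14
  list(beta = beta, info = info, converged = ok)
}

#' Wald test of the genetic effect
#'
#' \eqn{T = \hat\beta_G^2 / [I_X(\hat\beta)^{-1}]_{G,G}}, compared to the
#' \eqn{\chi^2_1} quantile at 1 - alpha (equivalently, two-sided normal test
#' of \eqn{\beta_G = 0}).
#'
#' @param fit Output of [fit_logistic()].
#' @param alpha Significance level.
#' @return List with `T`, `p_value`, `reject`.
#' @export
wald_test <- function(fit, alpha = 0.05) {
  v <- inv_gg(fit$info)
  T_stat <- unname(fit$beta[2L]^2 / v)
  p <- stats::pchisq(T_stat, df = 1L, lower.tail = FALSE)
  list(T = T_stat, p_value = p, reject = T_stat > stats::qchisq(1 - alpha, 1L))
}

#' Empirical power by full simulation
#'
#' The benchmark oracle: simulate `replicates` complete studies, fit each by
#' logistic regression, apply the Wald test, and report the rejection
#' fraction with its binomial standard error. Replicate r uses seed
#' `seed + r`, so individual replicates do not depend on the total count.
#'
#' @inheritParams power_ss
#' @param replicates Number of simulated studies (paper-scale default 1000).
#' @param seed Base seed.
#' @return `power_result` with extra fields `se` (binomial SE) and `failed`
#'   (replicates dropped for non-convergence/separation).
#' @export
empirical_power <- function(design_cov, trait, design, n, alpha = 0.05,
                            replicates = 1000L, seed = NULL) {
  stopifnot(replicates >= 10L)
  res <- resolve_inputs(design_cov, trait, design)
  rejects <- 0L
  failed <- 0L
  for (r in seq_len(replicates)) {
    study <- simulate_study(res$design_cov, res$trait, res$design, n,
                            seed = if (is.null(seed)) NULL else seed + r)
    fit <- fit_logistic(study)
    if (!fit$converged) { failed <- failed + 1L; next }
    if (wald_test(fit, alpha)$reject) rejects <- rejects + 1L
  }
  ok <- replicates - failed
  if (failed > 0.05 * replicates)
    warning(failed, " of ", replicates, " replicates failed to fit")
  p_hat <- rejects / ok
  out <- power_result(p_hat, NA_real_, n, alpha, "empirical", res)
  out$se <- sqrt(p_hat * (1 - p_hat) / ok)
  out$failed <- failed
  out
}

#' Accuracy benchmark of the SS and RD estimators against the oracle
#'
#' For each n on a grid, computes SS power (one shared covariate draw of
#' size b across the grid), RD power, and the full-simulation empirical
#' power; summarizes the absolute error AE = |computed - empirical| per
#' method by its average and maximum over the grid.
#'
#' @param scenario A scenario id (`"S1"`, `"S2"`, `"S3"`, see
#'   [scenario_fixture()]) or a list with elements `design_cov`, `trait`,
#'   `design`.
#' @param n_grid Sample sizes; default spans 600-10000.
#' @param replicates Oracle replicates per n.
#' @param b Covariate draws for the SS estimator.
#' @param alpha Significance level.
#' @param seed Base seed.
#' @return List with `table` (per-n powers and AEs) and `summary`
#'   (`data.frame` of method, avg_AE, max_AE).
#' @export
benchmark_accuracy <- function(scenario,
                               n_grid = c(600L, 1000L, 2000L, 3000L, 4000L,
                                          5000L, 6000L, 8000L, 10000L),
                               replicates = 1000L, b = 10000L, alpha = 0.05,
                               seed = 1L) {
  sc <- if (is.character(scenario)) scenario_fixture(scenario) else scenario
  res <- resolve_inputs(sc$design_cov, sc$trait, sc$design)
  info <- unit_information_ss(res$design_cov, res$trait, res$design, b = b,
                              seed = seed)
  rows <- lapply(seq_along(n_grid), function(k) {
    n <- n_grid[k]
    ss <- power_ss(res$design_cov, res$trait, res$design, n, alpha,
                   info = info)$power
    rd <- power_rd(res$design_cov, res$trait, res$design, n, alpha)$power
    emp <- empirical_power(res$design_cov, res$trait, res$design, n, alpha,
                           replicates = replicates,
                           seed = seed + 7919L * k)
    data.frame(n = n, ss = ss, rd = rd, empirical = emp$power,
               oracle_se = emp$se,
               ae_ss = abs(ss - emp$power), ae_rd = abs(rd - emp$power))
  })
  tab <- do.call(rbind, rows)
  summary <- data.frame(
    method = c("SS", "RD"),
    avg_AE = c(mean(tab$ae_ss), mean(tab$ae_rd)),
    max_AE = c(max(tab$ae_ss), max(tab$ae_rd)))
  list(table = tab, summary = summary)
}
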