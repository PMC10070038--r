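#' Integer representative counts for discrete covariate cells
#'
#' Apportions a sample of size n over the discrete covariate cells of the
#' design, targeting \eqn{n_{cell} = n P(cell)} under the study's sampling
#' law, with largest-remainder rounding so the integer counts sum to n
#' exactly.
#'
#' @inheritParams power_ss
#' @param n Representative sample size.
#' @return `data.frame` of cells (`G`, `E1`, ...) with integer column
#'   `count`; a cell whose expected count rounds to zero triggers a warning
#'   (that stratum contributes no information).
#' @export
representative_counts <- function(design_cov, trait, design, n) {
  cells <- cell_probs(design_cov, trait, design)
  cells$count <- largest_remainder(cells$prob, n)
  if (any(cells$count == 0L & cells$prob > 0))
    warning("some covariate cells have representative count 0 at n = ", n,
            "; their strata are lost from the information")
  cells
}

#' Quantile-spaced representative values for a continuous covariate
#'
#' For a genotype stratum G = g of size `n_i`, returns the conditional-normal
#' scores \eqn{E_j = \gamma_0 + \gamma_G g + \sigma_{E|G}
#' \Phi^{-1}[(j - 0.375)/(n_i + 0.25)]}, j = 1..n_i (Blom-type expected
#' normal order statistics), so the stratum's empirical distribution mirrors
#' the conditional law of E given G.
#'
#' @param gamma0 Second-stage intercept.
#' @param gamma_G Second-stage slope.
#' @param sigma_cond Conditional SD of E given G.
#' @param g Genotype value of the stratum.
#' @param n_i Stratum size.
#' @return Numeric vector of `n_i` values, symmetric about
#'   `gamma0 + gamma_G * g`.
#' @export
representative_continuous_values <- function(gamma0, gamma_G, sigma_cond, g,
                                             n_i) {
  stopifnot(n_i >= 1)
  j <- seq_len(n_i)
  gamma0 + gamma_G * g + sigma_cond * stats::qnorm((j - 0.375) / (n_i + 0.25))
}

# Representative covariate rows of size n. All-discrete designs replicate
# cells by their integer counts; with one continuous covariate, the discrete
# skeleton (G and binary covariates) is apportioned first and each stratum
# filled with quantile-spaced conditional-normal values.
representative_rows <- function(design_cov, trait, design, n) {
  res <- resolve_inputs(design_cov, trait, design)
  kinds <- vapply(res$design_cov$covariates, `[[`, character(1L), "kind")
  n_cont <- sum(kinds == "continuous")
  if (n_cont > 1L)
    stop("the representative-dataset method supports at most one continuous ",
         "covariate; use the semi-simulation method instead", call. = FALSE)
  if (n_cont == 0L) {
    cells <- suppressWarnings(
      representative_counts(res$design_cov, res$trait, res$design, n))
    keep <- cells$count > 0L
    idx <- rep(which(keep), cells$count[keep])
    rows <- cells[idx, setdiff(names(cells), c("prob", "count")), drop = FALSE]
    rownames(rows) <- NULL
    return(rows)
  }
  # Discrete skeleton: marginalize the continuous covariate out of the
  # (possibly retrospective) law via the quadrature grid, then apportion.
  grid <- quad_grid(res$design_cov)
  w <- grid$w
  if (res$design$mode == "retrospective") {
    mu <- stats::plogis(eta_rows(grid, res$trait$beta0, res$design_cov,
                                 res$trait))
    Ksum <- sum(w * mu)
    phi <- res$design$case_fraction
    w <- phi * w * mu / Ksum + (1 - phi) * w * (1 - mu) / (1 - Ksum)
  }
  cont_j <- which(kinds == "continuous")
  disc_cols <- c("G", paste0("E", setdiff(seq_along(kinds), cont_j),
                             recycle0 = TRUE))
  key <- interaction(grid[disc_cols], drop = TRUE)
  probs <- tapply(w, key, sum)
  skel <- grid[match(names(probs), as.character(key)), disc_cols, drop = FALSE]
  counts <- largest_remainder(as.numeric(probs), n)
  sp <- res$design_cov$covariates[[cont_j]]
  pieces <- lapply(seq_len(nrow(skel)), function(i) {
    if (counts[i] == 0L) return(NULL)
    out <- skel[rep(i, counts[i]), , drop = FALSE]
    out[[paste0("E", cont_j)]] <- representative_continuous_values(
      sp$gamma0, sp$gamma_G, sp$sigma_cond, skel$G[i], counts[i])
    out
  })
  rows <- do.call(rbind, pieces)
  rows <- rows[c("G", paste0("E", seq_along(kinds)))]
  rownames(rows) <- NULL
  rows
}

#' Expand covariate rows into the weighted representative dataset
#'
#' Each covariate row x splits into the two possible outcomes, (x, y = 0)
#' and (x, y = 1), weighted by the model probabilities
#' \eqn{\delta_{il} = P(Y = l | x_i)} evaluated at the effective intercept,
#' so \eqn{\delta_{i0} + \delta_{i1} = 1} and the 2n weighted rows carry
#' total weight n. Rows may come from the representative construction or
#' from a user-supplied observed covariate table (conditional power).
#'
#' @param covariate_rows `data.frame` with columns `G`, `E1`, ...
#' @param design_cov,trait,design As in [power_ss()].
#' @return Object of class `representative_dataset`: the 2n-row `data.frame`
#'   with columns `y` and `delta` appended, plus attribute `n`.
#' @export
expand_rd <- function(covariate_rows, design_cov, trait, design) {
  res <- resolve_inputs(design_cov, trait, design)
  mu <- stats::plogis(eta_rows(covariate_rows, res$beta0_eff, res$design_cov,
                               res$trait))
  n <- nrow(covariate_rows)
  out <- rbind(covariate_rows, covariate_rows)
  out$y <- rep(c(0L, 1L), each = n)
  out$delta <- c(1 - mu, mu)
  rownames(out) <- NULL
  structure(out, n = n, class = c("representative_dataset", "data.frame"))
}

#' Unconditional power via the expanded representative dataset (RD)
#'
#' Builds a deterministic representative covariate set of size n, expands it
#' to 2n outcome-weighted rows, and evaluates the Fisher information
#' \eqn{\sum_i \sum_l \delta_{il} w_i x_i^T x_i} at the true coefficients
#' (algebraically \eqn{\sum_i w_i x_i^T x_i}, since the outcome weights sum
#' to one per row; at these weights the weighted score is zero at the true
#' \eqn{\beta}, so the weighted MLE equals it and direct evaluation is
#' exact). \eqn{\hat V_{G,n}} is then plugged into the two-term Wald power
#' formula. Fully deterministic: no random draws.
#'
#' @inheritParams power_ss
#' @return A `power_result`.
#' @export
power_rd <- function(design_cov, trait, design, n, alpha = 0.05) {
  stopifnot(n >= 1, alpha > 0, alpha < 1)
  res <- resolve_inputs(design_cov, trait, design)
  if (n < 2L + length(res$design_cov$covariates))
    stop("n is below the number of model parameters", call. = FALSE)
  rows <- representative_rows(res$design_cov, res$trait, res$design, n)
  X <- model_matrix_rows(rows)
  wi <- logis_weight(eta_rows(rows, res$beta0_eff, res$design_cov, res$trait))
  info <- crossprod(X, X * wi)
  if (!is.finite(rcond(info)) || rcond(info) < 1e-14)
    stop("singular information from the representative dataset ",
         "(degenerate covariate strata at this n)", call. = FALSE)
  v <- inv_gg(info)
  power_result(wald_power(res$trait$beta_G, v, alpha), v, n, alpha, "RD", res)
}

#' Sample size by inverting the representative-dataset power function
#'
#' As [sample_size_ss()], but each candidate n rebuilds its representative
#' dataset (the RD construction depends on n). The integer-rounded counts
#' make the power curve very mildly non-monotone, so the bisection result is
#' polished by a local scan to the exact boundary: power(n*) >= target and
#' power(n* - 1) < target.
#'
#' @inheritParams sample_size_ss
#' @return Smallest integer n with RD power at least `target_power`.
#' @export
sample_size_rd <- function(design_cov, trait, design, target_power = 0.8,
                           alpha = 0.05) {
  stopifnot(target_power > alpha, target_power < 1)
  res <- resolve_inputs(design_cov, trait, design)
  if (res$trait$beta_G == 0)
    stop("beta_G = 0: power never exceeds alpha, no finite sample size",
         call. = FALSE)
  p_min <- 4L + length(res$design_cov$covariates)
  pw <- function(n) power_rd(res$design_cov, res$trait, res$design, n, alpha)$power
  igg <- inv_gg(unit_information_exact(res$design_cov, res$trait, res$design))
  n0 <- max(p_min, ceiling((stats::qnorm(1 - alpha / 2) +
                            stats::qnorm(target_power))^2 * igg /
                           res$trait$beta_G^2))
  lo <- p_min; hi <- max(lo + 1L, n0)
  while (pw(hi) < target_power) {
    hi <- hi * 2L
    if (hi > 1e7) stop("sample size exceeds 1e7; use sample_size_ss()",
                       call. = FALSE)
  }
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (pw(mid) >= target_power) hi <- mid else lo <- mid + 1L
  }
  n_star <- lo
  for (i in 1:1000) {  # polish against rounding wobble
    if (n_star > p_min && pw(n_star - 1L) >= target_power)
      n_star <- n_star - 1L
    else if (pw(n_star) < target_power)
      n_star <- n_star + 1L
    else break
  }
  as.integer(n_star)
}
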