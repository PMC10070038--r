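#' Non-genetic covariate specification
#'
#' Describes one non-genetic covariate E and its dependence on the genotype G
#' through a second-stage regression \eqn{g_2(E(E|G)) = \gamma_0 + \gamma_G
#' G}, with identity link for continuous E and logit link for binary E. The
#' second-stage intercept \eqn{\gamma_0} is never supplied by the user: it is
#' gleaned from the marginal information by [resolve_stage2()].
#'
#' Exactly one way of giving the marginal must be used:
#' \itemize{
#'   \item binary E: `exposure_rate`, the population rate P(E = 1);
#'   \item continuous E: `mean` together with either the marginal `sd` or the
#'     conditional standard deviation `conditional_sd` of E given G (not
#'     both; supplying both is rejected as contradictory).
#' }
#'
#' @param kind `"binary"` or `"continuous"`.
#' @param gamma_G Second-stage slope: log-odds of exposure per genotype unit
#'   (binary E) or mean shift per genotype unit (continuous E).
#' @param beta_E Effect of E on the trait, log odds per unit E.
#' @param exposure_rate Marginal P(E = 1), binary E only.
#' @param mean,sd Marginal mean and SD of a continuous E.
#' @param conditional_sd SD of E given G, continuous E only.
#' @return An object of class `covariate_spec`.
#' @examples
#' covariate_spec("binary", gamma_G = log(0.2), beta_E = log(2.5),
#'                exposure_rate = 0.3)
#' covariate_spec("continuous", gamma_G = log(0.5), beta_E = log(2.5),
#'                mean = 0, conditional_sd = 1)
#' @export
covariate_spec <- function(kind = c("binary", "continuous"), gamma_G, beta_E,
                           exposure_rate = NULL, mean = NULL, sd = NULL,
                           conditional_sd = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(gamma_G), length(gamma_G) == 1L,
            is.numeric(beta_E), length(beta_E) == 1L)
  if (kind == "binary") {
    if (!is.null(mean) || !is.null(sd) || !is.null(conditional_sd))
      stop("binary covariate takes `exposure_rate` only", call. = FALSE)
    if (is.null(exposure_rate) || exposure_rate <= 0 || exposure_rate >= 1)
      stop("binary covariate needs `exposure_rate` in (0, 1)", call. = FALSE)
  } else {
    if (!is.null(exposure_rate))
      stop("continuous covariate does not take `exposure_rate`", call. = FALSE)
    if (is.null(mean))
      stop("continuous covariate needs `mean` (to glean the stage-2 intercept)",
           call. = FALSE)
    if (!is.null(sd) && !is.null(conditional_sd))
      stop("supply either marginal `sd` or `conditional_sd`, not both: ",
           "the pair over-determines Var(E|G)", call. = FALSE)
    if (is.null(sd) && is.null(conditional_sd))
      stop("continuous covariate needs `sd` or `conditional_sd`", call. = FALSE)
    if (!is.null(sd) && sd <= 0) stop("`sd` must be > 0", call. = FALSE)
    if (!is.null(conditional_sd) && conditional_sd <= 0)
      stop("`conditional_sd` must be > 0", call. = FALSE)
  }
  structure(list(kind = kind, gamma_G = gamma_G, beta_E = beta_E,
                 exposure_rate = exposure_rate, mean = mean, sd = sd,
                 conditional_sd = conditional_sd,
                 gamma0 = NULL, sigma_cond = conditional_sd),
            class = "covariate_spec")
}

#' Glean the second-stage intercept (and conditional SD) of a covariate
#'
#' Resolves the free parameters of the E-given-G law from the user-supplied
#' marginal. For binary E, \eqn{\gamma_0} solves
#' \eqn{\sum_g P(g)\,\mathrm{expit}(\gamma_0 + \gamma_G g) = p_E}
#' by bracketed root finding on \[-50, 50\] (the map is strictly increasing in
#' \eqn{\gamma_0}), polished by Newton steps to ~1e-12. For continuous E,
#' \eqn{\gamma_0 = \mu_E - \gamma_G E[G]} and, when the marginal SD is given,
#' \eqn{\sigma_{E|G} = \sqrt{\sigma_E^2 - \gamma_G^2 Var(G)}}; an infeasible
#' marginal (\eqn{\sigma_E^2 \le \gamma_G^2 Var(G)}) is an error.
#'
#' @param spec A [covariate_spec()].
#' @param model The [genotype_model()] the covariate depends on.
#' @return The spec with `gamma0` (and `sigma_cond` if continuous) filled in.
#' @export
resolve_stage2 <- function(spec, model) {
  stopifnot(inherits(spec, "covariate_spec"), inherits(model, "genotype_model"))
  pr <- hwe_probs(model)
  g <- as.numeric(names(pr))
  if (spec$kind == "binary") {
    target <- spec$exposure_rate
    f <- function(g0) sum(pr * stats::plogis(g0 + spec$gamma_G * g)) - target
    root <- stats::uniroot(f, c(-50, 50), tol = 1e-12)$root
    for (i in 1:3) { # Newton polish; derivative is the summed Bernoulli variance
      d <- sum(pr * logis_weight(root + spec$gamma_G * g))
      root <- root - f(root) / d
    }
    spec$gamma0 <- root
  } else {
    mom <- genotype_moments(model)
    spec$gamma0 <- spec$mean - spec$gamma_G * mom[["mean"]]
    if (is.null(spec$sigma_cond)) {
      v <- spec$sd^2 - spec$gamma_G^2 * mom[["variance"]]
      if (v <= 0)
        stop("infeasible continuous marginal: sd^2 = ", format(spec$sd^2),
             " must exceed gamma_G^2 * Var(G) = ",
             format(spec$gamma_G^2 * mom[["variance"]]), call. = FALSE)
      spec$sigma_cond <- sqrt(v)
    }
  }
  spec
}

#' Joint covariate design: genotype plus covariates
#'
#' Bundles a genotype model with an ordered list of covariate specs into the
#' joint covariate law F_x of (G, E1, ..., EK). Covariates are mutually
#' conditionally independent given G.
#'
#' @param genotype A [genotype_model()].
#' @param covariates List of [covariate_spec()] objects (possibly empty).
#' @return An object of class `covariate_design`.
#' @export
covariate_design <- function(genotype, covariates = list()) {
  stopifnot(inherits(genotype, "genotype_model"))
  if (inherits(covariates, "covariate_spec")) covariates <- list(covariates)
  lapply(covariates, function(s) stopifnot(inherits(s, "covariate_spec")))
  structure(list(genotype = genotype, covariates = covariates),
            class = "covariate_design")
}

#' @export
print.covariate_design <- function(x, ...) {
  cat("Covariate design:", length(x$covariates), "covariate(s)\n")
  print(x$genotype)
  for (i in seq_along(x$covariates)) {
    s <- x$covariates[[i]]
    cat(sprintf("  E%d: %s, gamma_G = %.4g, beta_E = %.4g%s\n", i, s$kind,
                s$gamma_G, s$beta_E,
                if (!is.null(s$gamma0))
                  sprintf(", gamma0 = %.4g", s$gamma0) else " (unresolved)"))
  }
  invisible(x)
}

#' Resolve all second-stage parameters of a design
#'
#' @param design A [covariate_design()].
#' @return The design with every covariate resolved via [resolve_stage2()].
#' @export
resolve_design <- function(design) {
  stopifnot(inherits(design, "covariate_design"))
  design$covariates <- lapply(design$covariates, resolve_stage2,
                              model = design$genotype)
  design
}

design_resolved <- function(design) {
  all(vapply(design$covariates, function(s) !is.null(s$gamma0), logical(1L)))
}

#' Sample i.i.d. covariate rows from the population law
#'
#' Draws G from its Hardy-Weinberg probabilities, then each covariate
#' independently from its conditional law given G: Bernoulli with logit mean
#' \eqn{\gamma_0 + \gamma_G G} if binary, Normal with that mean and SD
#' \eqn{\sigma_{E|G}} if continuous.
#'
#' @param design A resolved [covariate_design()].
#' @param n Number of rows.
#' @param seed Optional integer seed for reproducibility.
#' @return `data.frame` with columns `G`, `E1`, ..., `EK`.
#' @export
sample_covariates <- function(design, n, seed = NULL) {
  stopifnot(inherits(design, "covariate_design"), n >= 1)
  if (!design_resolved(design))
    stop("design has unresolved covariates; call resolve_design() first",
         call. = FALSE)
  with_seed(seed, {
    pr <- hwe_probs(design$genotype)
    G <- sample(as.numeric(names(pr)), n, replace = TRUE, prob = pr)
    out <- data.frame(G = G)
    for (i in seq_along(design$covariates)) {
      s <- design$covariates[[i]]
      mu <- s$gamma0 + s$gamma_G * G
      out[[paste0("E", i)]] <- if (s$kind == "binary")
        stats::rbinom(n, 1L, stats::plogis(mu))
      else stats::rnorm(n, mu, s$sigma_cond)
    }
    out
  })
}

# Deterministic quadrature grid over the covariate space: rows of
# (G, E1..EK, w) such that sum(w * f(row)) ~= E_{F_x}[f]. Exact for discrete
# covariates; Gauss-Hermite (default 64 nodes) for continuous ones.
quad_grid <- function(design, nodes = 64L) {
  stopifnot(design_resolved(design))
  pr <- hwe_probs(design$genotype)
  grid <- data.frame(G = as.numeric(names(pr)), w = unname(pr))
  for (j in seq_along(design$covariates)) {
    s <- design$covariates[[j]]
    pieces <- lapply(seq_len(nrow(grid)), function(i) {
      mu <- s$gamma0 + s$gamma_G * grid$G[i]
      if (s$kind == "binary") {
        v <- c(0, 1); wt <- c(1 - stats::plogis(mu), stats::plogis(mu))
      } else {
        gh <- gh_rule(nodes)
        v <- mu + sqrt(2) * s$sigma_cond * gh$x
        wt <- gh$w / sqrt(pi)
      }
      out <- grid[rep(i, length(v)), , drop = FALSE]
      out[[paste0("E", j)]] <- v
      out$w <- out$w * wt
      out
    })
    grid <- do.call(rbind, pieces)
    rownames(grid) <- NULL
  }
  grid[c(setdiff(names(grid), "w"), "w")]
}

# Design matrix (1, G, E1..EK) from a covariate row table.
model_matrix_rows <- function(rows) {
  cols <- c("G", grep("^E[0-9]+$", names(rows), value = TRUE))
  cbind(1, as.matrix(rows[cols]))
}
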