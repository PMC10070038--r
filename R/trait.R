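#' Binary trait model
#'
#' Logistic regression of the binary trait Y on the coded genotype G and
#' covariates: \eqn{logit(P(Y=1|G,E)) = \beta_0 + \beta_G G + \sum_k
#' \beta_{E_k} E_k}. The intercept is usually not supplied: it is gleaned
#' from the disease prevalence K by [solve_beta0()]. Covariate effects
#' `beta_E` live on the covariate specs of the design; this object carries
#' the genetic effect, the prevalence, and optionally a user intercept.
#'
#' @param beta_G Log odds ratio per genotype unit (the tested effect).
#' @param prevalence Population probability K of Y = 1, in (0, 1). Required
#'   unless `beta0` is given and the design is prospective.
#' @param beta0 Optional log-odds intercept. Ignored for retrospective
#'   designs, where the prevalence alone governs the sampling law and the
#'   intercept is always gleaned from it (the intercept does not affect
#'   case-control power).
#' @return An object of class `trait_model`.
#' @export
trait_model <- function(beta_G, prevalence = NULL, beta0 = NULL) {
  stopifnot(is.numeric(beta_G), length(beta_G) == 1L)
  if (!is.null(prevalence) &&
      (prevalence <= 0 || prevalence >= 1))
    stop("`prevalence` must be in (0, 1)", call. = FALSE)
  if (is.null(prevalence) && is.null(beta0))
    stop("supply `prevalence` (for intercept gleaning) or `beta0`",
         call. = FALSE)
  structure(list(beta_G = beta_G, prevalence = prevalence, beta0 = beta0),
            class = "trait_model")
}

#' Study design: prospective or retrospective case-control
#'
#' @param mode `"prospective"` (random population sample, Y drawn given x) or
#'   `"retrospective"` (fixed numbers of cases and controls; the covariate
#'   law becomes the mixture \eqn{\phi P(x|Y=1) + (1-\phi) P(x|Y=0)}).
#' @param case_fraction Case fraction \eqn{\phi} of the sample
#'   (retrospective only); a 1:1 case-control ratio is \eqn{\phi = 0.5}.
#' @return An object of class `study_design`.
#' @export
study_design <- function(mode = c("prospective", "retrospective"),
                         case_fraction = 0.5) {
  mode <- match.arg(mode)
  if (mode == "retrospective" &&
      (case_fraction <= 0 || case_fraction >= 1))
    stop("`case_fraction` must be in (0, 1)", call. = FALSE)
  structure(list(mode = mode,
                 case_fraction = if (mode == "retrospective") case_fraction),
            class = "study_design")
}

# Linear predictor eta over covariate rows at a given intercept.
eta_rows <- function(rows, beta0, design, trait) {
  X <- model_matrix_rows(rows)
  betaE <- vapply(design$covariates, `[[`, numeric(1L), "beta_E")
  as.numeric(X %*% c(beta0, trait$beta_G, betaE))
}

#' Glean the trait-model intercept from the prevalence
#'
#' Solves \eqn{E_{F_x}[\mathrm{expit}(\beta_0 + \beta_G G + \sum \beta_E E)]
#' = K} for \eqn{\beta_0}. The expectation is exact enumeration over discrete
#' covariates and Gauss-Hermite quadrature (64 nodes) over each continuous
#' covariate; the root is bracketed on \[-50, 50\] (the map is strictly
#' increasing) and polished by Newton steps.
#'
#' @param trait A [trait_model()] with `prevalence` set.
#' @param design_cov A resolved [covariate_design()].
#' @return The gleaned intercept \eqn{\beta_0}.
#' @export
solve_beta0 <- function(trait, design_cov) {
  stopifnot(inherits(trait, "trait_model"))
  if (is.null(trait$prevalence))
    stop("`prevalence` is required to glean beta0", call. = FALSE)
  design_cov <- resolve_design(design_cov)
  grid <- quad_grid(design_cov)
  eta0 <- eta_rows(grid, 0, design_cov, trait)
  K <- trait$prevalence
  f <- function(b0) sum(grid$w * stats::plogis(b0 + eta0)) - K
  root <- stats::uniroot(f, c(-50, 50), tol = 1e-12)$root
  for (i in 1:3) {
    d <- sum(grid$w * logis_weight(root + eta0))
    root <- root - f(root) / d
  }
  root
}

# Resolve trait + design into the population intercept actually used.
# Prospective: user beta0 if supplied, else gleaned. Retrospective: always
# gleaned from the prevalence (user beta0 deliberately unused).
resolve_trait <- function(trait, design_cov, design) {
  if (design$mode == "retrospective") {
    if (is.null(trait$prevalence))
      stop("retrospective design requires `prevalence`", call. = FALSE)
    trait$beta0 <- solve_beta0(trait, design_cov)
  } else if (is.null(trait$beta0)) {
    trait$beta0 <- solve_beta0(trait, design_cov)
  }
  trait
}

#' Effective intercept under the sampling design
#'
#' Prospective sampling leaves the intercept unchanged. Under retrospective
#' case-control sampling with case fraction \eqn{\phi} and prevalence K, an
#' ordinary logistic fit to the sample targets the offset intercept
#' \eqn{\beta_0^* = \beta_0 + \log(\phi/(1-\phi)) - \log(K/(1-K))} while the
#' slopes are unchanged (the classical case-control intercept shift); power
#' computations evaluate the information weights at \eqn{\beta_0^*}.
#'
#' @param trait A resolved [trait_model()] (intercept set).
#' @param design A [study_design()].
#' @return The intercept at which the analysis model operates.
#' @export
effective_intercept <- function(trait, design) {
  stopifnot(inherits(design, "study_design"))
  if (is.null(trait$beta0))
    stop("trait intercept unresolved; glean beta0 first", call. = FALSE)
  if (design$mode == "prospective") return(trait$beta0)
  if (is.null(trait$prevalence))
    stop("retrospective design requires `prevalence`", call. = FALSE)
  phi <- design$case_fraction
  K <- trait$prevalence
  trait$beta0 + log(phi / (1 - phi)) - log(K / (1 - K))
}

# One-stop resolution used by every power routine.
resolve_inputs <- function(design_cov, trait, design) {
  stopifnot(inherits(design_cov, "covariate_design"),
            inherits(trait, "trait_model"),
            inherits(design, "study_design"))
  design_cov <- resolve_design(design_cov)
  trait <- resolve_trait(trait, design_cov, design)
  list(design_cov = design_cov, trait = trait, design = design,
       beta0_eff = effective_intercept(trait, design))
}

all_discrete <- function(design_cov) {
  all(vapply(design_cov$covariates, function(s) s$kind == "binary", logical(1L)))
}

#' Covariate cell probabilities under the study's sampling law
#'
#' For an all-discrete design (genotype plus binary covariates), enumerates
#' the covariate cells with their probabilities under the design: the
#' population law for prospective sampling, or the case-control mixture
#' \eqn{\phi P(x|Y=1) + (1-\phi) P(x|Y=0)} with
#' \eqn{P(x|Y=1) \propto \mathrm{expit}(\eta(x)) P(x)} for retrospective
#' sampling.
#'
#' @param design_cov A [covariate_design()] with only binary covariates.
#' @param trait A [trait_model()].
#' @param design A [study_design()].
#' @return `data.frame` of cells (`G`, `E1`, ...) with column `prob`.
#' @export
cell_probs <- function(design_cov, trait, design) {
  if (!all_discrete(design_cov))
    stop("cell_probs() requires an all-discrete covariate design",
         call. = FALSE)
  res <- resolve_inputs(design_cov, trait, design)
  grid <- quad_grid(res$design_cov)   # exact cells when all discrete
  names(grid)[names(grid) == "w"] <- "prob"
  if (res$design$mode == "retrospective") {
    mu <- stats::plogis(eta_rows(grid, res$trait$beta0, res$design_cov, res$trait))
    Ksum <- sum(grid$prob * mu)       # equals prevalence up to gleaning tol
    phi <- res$design$case_fraction
    grid$prob <- phi * grid$prob * mu / Ksum +
      (1 - phi) * grid$prob * (1 - mu) / (1 - Ksum)
  }
  grid
}

# Draw covariate rows under the study's sampling law (the semi-simulation
# covariate stream). Prospective: the population law. Retrospective: per-row
# case/control labels ~ Bernoulli(phi), then x | Y by exact cell sampling
# (discrete designs) or rejection from the population law with acceptance
# probability expit(eta) for cases and 1 - expit(eta) for controls.
sample_study_covariates <- function(design_cov, trait, design, n, seed = NULL) {
  res <- resolve_inputs(design_cov, trait, design)
  if (res$design$mode == "prospective")
    return(sample_covariates(res$design_cov, n, seed))
  with_seed(seed, {
    n1 <- stats::rbinom(1L, n, res$design$case_fraction)
    rows <- sample_case_control_rows(res, n1, n - n1)
    rows[sample.int(nrow(rows)), , drop = FALSE]
  })
}

# n1 case rows then n0 control rows from P(x | Y = 1), P(x | Y = 0);
# operates inside an established RNG stream.
sample_case_control_rows <- function(res, n1, n0) {
  if (all_discrete(res$design_cov)) {
    grid <- quad_grid(res$design_cov)
    mu <- stats::plogis(eta_rows(grid, res$trait$beta0, res$design_cov, res$trait))
    p1 <- grid$w * mu; p1 <- p1 / sum(p1)
    p0 <- grid$w * (1 - mu); p0 <- p0 / sum(p0)
    idx <- c(sample.int(nrow(grid), n1, replace = TRUE, prob = p1),
             sample.int(nrow(grid), n0, replace = TRUE, prob = p0))
    out <- grid[idx, setdiff(names(grid), "w"), drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  take <- function(m, as_case) {
    if (m == 0L) {
      out <- sample_covariates(res$design_cov, 1L)[0L, , drop = FALSE]
      return(out)
    }
    got <- NULL
    tries <- 0L
    while (is.null(got) || nrow(got) < m) {
      tries <- tries + 1L
      if (tries > 10000L)
        stop("rejection sampler efficiency too low for the case-control law",
             call. = FALSE)
      prop <- sample_covariates(res$design_cov, max(2L * m, 1000L))
      mu <- stats::plogis(eta_rows(prop, res$trait$beta0, res$design_cov,
                                   res$trait))
      acc <- stats::runif(nrow(prop)) < (if (as_case) mu else 1 - mu)
      got <- rbind(got, prop[acc, , drop = FALSE])
    }
    got[seq_len(m), , drop = FALSE]
  }
  out <- rbind(take(n1, TRUE), take(n0, FALSE))
  rownames(out) <- NULL
  out
}

# Unit Fisher information by deterministic enumeration/quadrature: exact for
# all-discrete designs, Gauss-Hermite-accurate otherwise. Used as the
# closed-form reference and to seed sample-size searches.
unit_information_exact <- function(design_cov, trait, design, nodes = 64L) {
  res <- resolve_inputs(design_cov, trait, design)
  grid <- quad_grid(res$design_cov, nodes)
  w_pop <- grid$w
  if (res$design$mode == "retrospective") {
    mu <- stats::plogis(eta_rows(grid, res$trait$beta0, res$design_cov, res$trait))
    Ksum <- sum(w_pop * mu)
    phi <- res$design$case_fraction
    w_pop <- phi * w_pop * mu / Ksum + (1 - phi) * w_pop * (1 - mu) / (1 - Ksum)
  }
  X <- model_matrix_rows(grid)
  wi <- logis_weight(eta_rows(grid, res$beta0_eff, res$design_cov, res$trait))
  crossprod(X, X * (w_pop * wi))
}
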