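#' Built-in benchmark scenarios
#'
#' Three canonical study-planning settings used throughout the package's
#' validation suite. All assume a MAF-0.1 variant with a dominant effect and
#' disease prevalence 0.20 at significance level 0.05:
#' \describe{
#'   \item{S1}{No covariate; retrospective case-control sampling with a 1:1
#'     case-to-control ratio; genetic effect \eqn{\beta_G = \log 1.5}.}
#'   \item{S2}{Prospective sampling; one binary covariate with population
#'     exposure rate 0.3, trait effect \eqn{\beta_E = \log 2.5}, and G-E
#'     dependence \eqn{\gamma_G = \log 0.2}; \eqn{\beta_G = \log 1.5}.}
#'   \item{S3}{Prospective sampling; one continuous covariate, standard
#'     normal given G (mean gleaned from \eqn{\mu_E = 0},
#'     \eqn{\sigma_{E|G} = 1}), \eqn{\beta_E = \log 2.5},
#'     \eqn{\gamma_G = \log 0.5}; smaller genetic effect
#'     \eqn{\beta_G = \log 1.3} to keep the power range comparable.}
#' }
#'
#' @param id `"S1"`, `"S2"`, or `"S3"`.
#' @return List with elements `design_cov`, `trait`, `design`, `label`.
#' @examples
#' sc <- scenario_fixture("S2")
#' power_rd(sc$design_cov, sc$trait, sc$design, n = 3000)
#' @export
scenario_fixture <- function(id = c("S1", "S2", "S3")) {
  id <- match.arg(id)
  geno <- genotype_model(0.1, "dominant")
  switch(id,
    S1 = list(
      design_cov = covariate_design(geno),
      trait = trait_model(beta_G = log(1.5), prevalence = 0.2),
      design = study_design("retrospective", case_fraction = 0.5),
      label = "S1: no covariate, 1:1 case-control"),
    S2 = list(
      design_cov = covariate_design(geno, list(
        covariate_spec("binary", gamma_G = log(0.2), beta_E = log(2.5),
                       exposure_rate = 0.3))),
      trait = trait_model(beta_G = log(1.5), prevalence = 0.2),
      design = study_design("prospective"),
      label = "S2: binary covariate, prospective"),
    S3 = list(
      design_cov = covariate_design(geno, list(
        covariate_spec("continuous", gamma_G = log(0.5), beta_E = log(2.5),
                       mean = 0, conditional_sd = 1))),
      trait = trait_model(beta_G = log(1.3), prevalence = 0.2),
      design = study_design("prospective"),
      label = "S3: continuous covariate, prospective"))
}
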