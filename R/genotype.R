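#' Genotype model under Hardy-Weinberg equilibrium
#'
#' Describes a single bi-allelic variant by its minor allele frequency (MAF)
#' and the genetic-effect coding used in the association model. Genotype
#' frequencies follow Hardy-Weinberg equilibrium: for MAF `p`, the genotypes
#' aa, Aa, AA occur with probabilities \eqn{(1-p)^2}, \eqn{2p(1-p)},
#' \eqn{p^2}. The coding maps genotypes to the numeric value G entering the
#' regression: additive \{0,1,2\}, dominant \{0,1,1\}, recessive \{0,0,1\}.
#'
#' @param maf Minor allele frequency, a single number in (0, 0.5].
#' @param coding One of `"additive"`, `"dominant"`, `"recessive"`.
#' @return An object of class `genotype_model`.
#' @examples
#' g <- genotype_model(0.1, "dominant")
#' hwe_probs(g)
#' genotype_moments(g)
#' @export
genotype_model <- function(maf, coding = c("additive", "dominant", "recessive")) {
  coding <- match.arg(coding)
  if (!is.numeric(maf) || length(maf) != 1L || is.na(maf) || maf <= 0 || maf > 0.5)
    stop("`maf` must be a single number in (0, 0.5], got ",
         deparse(substitute(maf)), " = ", format(maf), call. = FALSE)
  structure(list(maf = maf, coding = coding), class = "genotype_model")
}

#' @export
print.genotype_model <- function(x, ...) {
  cat("Genotype model: MAF =", x$maf, "| coding =", x$coding, "\n")
  print(hwe_probs(x))
  invisible(x)
}

#' Hardy-Weinberg probabilities on the coding's support
#'
#' @param model A [genotype_model()].
#' @return Named numeric vector of probabilities; names are the numeric
#'   genotype values of the coding's support.
#' @export
hwe_probs <- function(model) {
  stopifnot(inherits(model, "genotype_model"))
  p <- model$maf
  switch(model$coding,
    additive  = c("0" = (1 - p)^2, "1" = 2 * p * (1 - p), "2" = p^2),
    dominant  = c("0" = (1 - p)^2, "1" = 1 - (1 - p)^2),
    recessive = c("0" = 1 - p^2,   "1" = p^2))
}

#' Mean and variance of the coded genotype
#'
#' @param model A [genotype_model()].
#' @return Named numeric vector `c(mean, variance)`.
#' @export
genotype_moments <- function(model) {
  pr <- hwe_probs(model)
  g <- as.numeric(names(pr))
  m <- sum(g * pr)
  c(mean = m, variance = sum(g^2 * pr) - m^2)
}

genotype_support <- function(model) as.numeric(names(hwe_probs(model)))
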