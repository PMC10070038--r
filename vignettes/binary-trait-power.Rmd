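---
title: "Power and sample size for binary-trait association studies: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power and sample size for binary-trait association studies: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binpower)
```

## The problem

When a continuous trait is analysed by linear regression, the power of the
genetic association test depends on the covariates only through the residual
variance, so study planning can ignore them. Logistic regression of a binary
trait is not collapsible: the Fisher information for the genetic log odds
ratio $\beta_G$ depends explicitly on the covariate effects $\beta_E$ and on
the dependence between genotype and covariates, even without any
interaction. Planning a binary-trait study while ignoring its covariates
therefore overestimates power and underestimates the replication sample
size. `binpower` makes the covariates explicit.

## Models

The analysis model is the ordinary logistic regression

$$\operatorname{logit} P(Y=1 \mid G, E) = \beta_0 + \beta_G G + \textstyle\sum_k \beta_{E_k} E_k,$$

with the variant coded additively ($G \in \{0,1,2\}$), dominantly or
recessively, and genotype frequencies given by Hardy–Weinberg equilibrium
for a minor allele frequency $p$. Each covariate is tied to the genotype by
a second-stage regression

$$g_2\!\left(E(E \mid G)\right) = \gamma_0 + \gamma_G G,$$

with logit link for a binary $E$ and identity link (plus a conditional
normal law with variance $\sigma^2_{E|G}$) for a continuous $E$. Multiple
covariates are taken conditionally independent given $G$; correlated
covariates would need nested second-stage models and are out of scope.

Intercepts have no useful interpretation for the planner, so the package
*gleans* them from marginal information:

* $\gamma_0$ from the exposure rate $P(E=1)$ (binary; 1-D root finding on
  a strictly increasing map, bracketed on $[-50, 50]$ and polished by
  Newton steps to ~1e-12) or from $\mu_E$ (continuous, closed form
  $\gamma_0 = \mu_E - \gamma_G E[G]$);
* $\sigma_{E|G} = \sqrt{\sigma_E^2 - \gamma_G^2 \mathrm{Var}(G)}$ when the
  marginal SD is supplied — an infeasible combination
  ($\sigma_E^2 \le \gamma_G^2 \mathrm{Var}(G)$) is an error, and supplying
  both $\sigma_E$ and $\sigma_{E|G}$ is rejected as contradictory rather
  than silently resolved;
* $\beta_0$ from the disease prevalence $K$ by solving
  $E_{F_x}[\operatorname{expit}(\eta)] = K$, where the expectation is exact
  enumeration over discrete covariates and 64-node Gauss–Hermite quadrature
  over each continuous one. Quadrature rather than Monte Carlo keeps the
  resolution deterministic; a large Monte Carlo check appears only in the
  tests.

## Power of the Wald test

The association test is the two-sided Wald test of $\beta_G = 0$. With
$V_{G,n} = [(n I_1(\beta))^{-1}]_{G,G}$ the asymptotic power at level
$\alpha$ is

$$\Phi\!\left(-z_{1-\alpha/2} + \beta_G/\sqrt{V_{G,n}}\right) +
  \Phi\!\left(-z_{1-\alpha/2} - \beta_G/\sqrt{V_{G,n}}\right),$$

where $I_1(\beta) = E_{F_x}[w(\eta)\, x^\top x]$ is the unconditional unit
Fisher information, $w(\eta) = e^{-\eta}(1+e^{-\eta})^{-2}$, and
$x = (1, G, E_1, \dots)$. Columns are always ordered (intercept, $G$,
$E$s), so the "second diagonal element" is always the genetic coordinate;
the element is extracted by a linear solve against the $G$ basis vector
instead of a full matrix inversion, with a warning when the condition
number of $I_1$ exceeds about $10^{12}$. At $\beta_G = 0$ the formula
collapses to $\alpha$ identically, which the tests assert to machine
precision.

$I_1$ has no closed form for a general covariate space, so the package
offers two estimators.

**Semi-simulation (SS).** Draw $B$ covariate rows from the design's
sampling law — never simulating outcomes, never fitting a model — and
average $w_i x_i^\top x_i$. The cost depends on $B$ only, not on the target
$n$, so one draw serves a whole power curve or sample-size search (this
sharing trades a common Monte-Carlo offset across the grid for smoothness
and speed). The default $B = 10{,}000$ keeps the Monte-Carlo SD of the
power below 0.01 on the benchmark scenarios; the SE shrinks at the CLT
rate, i.e. log–log linearly in $B$ with slope $-1/2$, which
`power_se_curve()` exposes. Below $B = 10{,}000$ the package warns, below
1000 it refuses.

**Representative dataset (RD).** Build a deterministic covariate set of
size $n$ that mirrors $F_x$: discrete cells get integer counts
$n_{cell} \approx n P(cell)$, rounded by largest-remainder apportionment so
they sum to $n$ exactly (the scheme that minimizes the largest cell
distortion; cells whose count rounds to zero trigger a warning because
their stratum drops out of the information). A continuous covariate fills
each genotype stratum with the quantile-spaced conditional-normal scores
$\gamma_0 + \gamma_G g + \sigma_{E|G}\,\Phi^{-1}[(j-0.375)/(n_i+0.25)]$ —
Blom-type expected normal order statistics; the scale here is the
*conditional* SD. Each row is then expanded into both outcomes with
weights $\delta_{il} = P(Y=l \mid x_i)$, giving $2n$ weighted rows of total
weight $n$. Because $\delta_{i0} + \delta_{i1} = 1$, the weighted
information at the true $\beta$ is $\sum_i w_i x_i^\top x_i$; and because
the weighted score vanishes at $\beta$, the weighted MLE *is* $\beta$, so
the information is evaluated there directly instead of running IRLS (the
equivalence is asserted against a weighted `glm` fit in the tests). RD is
fully deterministic but its cost grows linearly with $n$; SS is the
default recommendation for large studies.

## Study designs

Prospective sampling uses the population covariate law and the population
intercept. Retrospective case–control sampling with case fraction $\phi$
changes two things, mirroring what an ordinary logistic fit to case–control
data estimates (the Prentice–Pyke result):

* the covariate law becomes the mixture
  $\phi P(x \mid Y=1) + (1-\phi) P(x \mid Y=0)$ with
  $P(x \mid Y=1) \propto \operatorname{expit}(\eta) P(x)$ — exact cell
  reweighting for discrete designs, rejection sampling (acceptance
  probability $\operatorname{expit}(\eta)$ for cases) otherwise;
* the intercept entering the information weights shifts to
  $\beta_0^* = \beta_0 + \log\frac{\phi}{1-\phi} - \log\frac{K}{1-K}$,
  slopes unchanged.

Since the intercept cannot affect case–control power, a user-supplied
$\beta_0$ is deliberately ignored in retrospective mode: the prevalence
alone governs the sampling law, and $\beta_0$ is always gleaned from it.
The tests assert that retrospective power is bit-identical across
user intercepts $-2$, $0$, $+3$ at fixed $K$ and $\phi$. When $\phi = K$
the mixture collapses to the population law.

Two retrospective corner cases are approximations by design: RD with a
continuous covariate under retrospective sampling uses the retrospective
genotype marginal but prospective conditional-normal quantile values (the
exact conditional law under case–control sampling is a non-normal
mixture); and RD refuses more than one continuous covariate, since the
quantile construction defines values for a single continuous axis per
stratum and any pairing of two sequences would impose an arbitrary rank
correlation — the SS estimator handles both situations exactly and is the
advised route.

## Sample-size inversion

Power is strictly increasing in $n$ for fixed $I_1$, so the required $n$
for a target power solves a monotone integer problem. The search is seeded
by the one-term closed form
$n_0 = (z_{1-\alpha/2} + z_{\rm power})^2 [I_1^{-1}]_{G,G} / \beta_G^2$
and finished by integer bisection on the full two-term formula, returning
the smallest $n$ whose power reaches the target. For SS the unit
information is estimated once and reused across the search (whether the
original method redraws per candidate $n$ is not documented; one shared
draw is this package's choice). For RD every candidate $n$ rebuilds its
representative dataset; integer count rounding makes the RD curve wobble
by $O(1/n)$, so the bisection result is polished by a bounded local scan
to the exact boundary.

## The empirical oracle and the benchmark scenarios

`empirical_power()` is the package's own full-simulation benchmark:
simulate complete studies (prospective: $x \sim F_x$,
$Y \sim \text{Bernoulli}(\operatorname{expit}(\eta))$; retrospective:
exactly $\mathrm{round}(\phi n)$ cases from $P(x|Y=1)$), fit each by IRLS
(`stats::glm.fit`), apply the Wald test, and report the rejection
fraction. Replicate $r$ uses seed $\texttt{seed} + r$, so individual
replicates do not depend on how many are run. Separated or non-converged
fits are dropped and counted (a warning fires above 5%); at the benchmark
sample sizes they are vanishingly rare. The default 1000 replicates give a
binomial SE of about 0.016 at power one half.

`scenario_fixture()` encodes the three validation scenarios used
throughout: all share MAF 0.1, a dominant effect, prevalence 0.20 and
$\alpha = 0.05$. S1 has no covariate and 1:1 retrospective sampling with
$\beta_G = \log 1.5$; S2 is prospective with a binary covariate (exposure
rate 0.3, $\beta_E = \log 2.5$, $\gamma_G = \log 0.2$); S3 is prospective
with a continuous covariate, standard normal given $G$
($\mu_E = 0$, $\sigma_{E|G} = 1$, $\gamma_G = \log 0.5$,
$\beta_E = \log 2.5$) and the smaller effect $\beta_G = \log 1.3$ so the
power range stays comparable. `benchmark_accuracy()` sweeps the grid
$\{600, 1000, 2000, 3000, 4000, 5000, 6000, 8000, 10000\}$ — the published
range states only its endpoints, so the interior points are this package's
choice — and summarizes $|{\rm computed} - {\rm empirical}|$ per method by
its average and maximum.

What the oracle validates, and what it does not: the simulated scenarios
exercise HWE genotypes, one binary or continuous covariate, and both
sampling designs, but real studies add covariate measurement error,
non-normal continuous covariates, correlated covariates, related
individuals, and effect-size estimates inflated by winner's curse. Accuracy
on the scenarios shows the estimators track the *model's* power, not that
the model matches any particular cohort. At the smallest benchmark sizes
($n \lesssim 1000$ with these effect sizes) the Wald test is slightly
anti-conservative in finite samples, so both asymptotic estimators sit a
couple of points below the empirical power there; this is a property of
the asymptotic target, visible equally in the published accuracy figures.

## Numerical choices, in one place

* Gauss–Hermite: 64 nodes per continuous covariate; the gleaned $\beta_0$
  is cross-checked in the tests against a $10^6$-draw Monte-Carlo forward
  evaluation of the prevalence.
* Root finding: `uniroot` on $[-50, 50]$, tolerance 1e-12, plus up to
  three Newton polish steps — intercepts are recovered to ~1e-10, which the
  property tests assert.
* Problem sizes in the test suite: the oracle-comparison tests run the
  full 1000-replicate benchmark on all three scenarios; stability tests
  use 200 seeds at $B = 10^4$ and a $B$-grid up to $2 \times 10^4$ with
  100 repeats; the enumeration-equivalence tests push SS to $B = 10^6$.
* Ties in largest-remainder apportionment break by cell order
  (deterministic).
* Degenerate inputs: MAF outside $(0, 0.5]$, prevalence outside $(0,1)$,
  $\beta_G = 0$ in a sample-size call, a singular information estimate
  (e.g. no minor alleles drawn at tiny MAF $\times$ small $B$), and
  rejection-sampler starvation all raise named errors rather than
  returning numbers.

## A worked example

```{r example, eval = FALSE}
design <- covariate_design(
  genotype_model(maf = 0.1, coding = "dominant"),
  list(covariate_spec("binary", gamma_G = log(0.2), beta_E = log(2.5),
                      exposure_rate = 0.3)))
trait  <- trait_model(beta_G = log(1.5), prevalence = 0.2)
study  <- study_design("prospective")

power_ss(design, trait, study, n = 3000, seed = 1)
sample_size_ss(design, trait, study, target_power = 0.8, seed = 1)
# Compare with the deterministic estimator and the simulation oracle:
power_rd(design, trait, study, n = 3000)
empirical_power(design, trait, study, n = 3000, replicates = 1000, seed = 1)
```
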