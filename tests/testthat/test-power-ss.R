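# Exact unit information of the S2 design by direct 6-cell enumeration,
# independent of the package internals.
s2_exact_info <- function() {
  s2 <- scenario_fixture("S2")
  g0 <- resolve_stage2(s2$design_cov$covariates[[1]],
                       s2$design_cov$genotype)$gamma0
  b0 <- solve_beta0(s2$trait, s2$design_cov)
  cells <- expand.grid(g = c(0, 1), e = c(0, 1))
  pg <- c(0.81, 0.19)[cells$g + 1]
  pe <- plogis(g0 + log(0.2) * cells$g)
  pcell <- pg * ifelse(cells$e == 1, pe, 1 - pe)
  eta <- b0 + log(1.5) * cells$g + log(2.5) * cells$e
  w <- exp(-eta) / (1 + exp(-eta))^2
  I1 <- matrix(0, 3, 3)
  for (i in seq_len(nrow(cells))) {
    x <- c(1, cells$g[i], cells$e[i])
    I1 <- I1 + pcell[i] * w[i] * tcrossprod(x)
  }
  I1
}

test_that("unit information with flat weights reduces to covariate moments", {
  # beta = 0 everywhere: every weight is exactly 1/4
  des <- covariate_design(genotype_model(0.3, "additive"))
  tr <- trait_model(beta_G = 0, beta0 = 0)
  info <- unit_information_ss(des, tr, study_design("prospective"),
                              b = 50000L, seed = 1)
  EG <- 0.6; EG2 <- 2 * 0.3 * 0.7 + 4 * 0.09   # Binomial(2, 0.3) moments
  expect_equal(info$matrix / 0.25,
               matrix(c(1, EG, EG, EG2), 2, 2,
                      dimnames = dimnames(info$matrix)),
               tolerance = 0.02)
  expect_equal(info$matrix[1, 1], 0.25)  # weight identically 1/4
})

test_that("semi-simulation information converges to the exact enumeration", {
  s2 <- scenario_fixture("S2")
  exact <- s2_exact_info()
  est <- unit_information_ss(s2$design_cov, s2$trait, s2$design,
                             b = 200000L, seed = 5)
  # every entry within 3 Monte-Carlo standard errors (entries are means of
  # bounded terms; crude SE bound 1/sqrt(b) per entry is generous enough)
  expect_lt(max(abs(est$matrix - exact)), 3 / sqrt(200000))
})

test_that("information estimate is reproducible and warns on small b", {
  s1 <- scenario_fixture("S1")
  a <- unit_information_ss(s1$design_cov, s1$trait, s1$design, seed = 9)
  b <- unit_information_ss(s1$design_cov, s1$trait, s1$design, seed = 9)
  expect_identical(a$matrix, b$matrix)
  expect_warning(
    unit_information_ss(s1$design_cov, s1$trait, s1$design, b = 2000L,
                        seed = 1), "noisy")
  expect_error(
    unit_information_ss(s1$design_cov, s1$trait, s1$design, b = 500L),
    "at least 1000")
})

test_that("power is exactly the level at beta_G = 0 and increases with n", {
  des <- covariate_design(genotype_model(0.2, "additive"))
  tr0 <- trait_model(beta_G = 0, prevalence = 0.3)
  pd <- study_design("prospective")
  expect_equal(power_ss(des, tr0, pd, n = 5000, alpha = 0.05, seed = 2)$power,
               0.05, tolerance = 1e-12)

  s2 <- scenario_fixture("S2")
  info <- unit_information_ss(s2$design_cov, s2$trait, s2$design, seed = 3)
  pw <- vapply(c(500, 1000, 2000, 4000, 8000, 16000), function(n)
    power_ss(s2$design_cov, s2$trait, s2$design, n, info = info)$power,
    numeric(1))
  expect_true(all(diff(pw) > 0))
  expect_gt(pw[6], 0.999)  # power tends to 1
})

test_that("sample-size inversion brackets the target power exactly", {
  s2 <- scenario_fixture("S2")
  info <- unit_information_ss(s2$design_cov, s2$trait, s2$design, seed = 4)
  n_star <- sample_size_ss(s2$design_cov, s2$trait, s2$design,
                           target_power = 0.8, info = info)
  pw <- function(n) power_ss(s2$design_cov, s2$trait, s2$design, n,
                             info = info)$power
  expect_gte(pw(n_star), 0.8)
  expect_lt(pw(n_star - 1), 0.8)

  # n scales roughly as 1 / beta_G^2 for small effects
  small <- scenario_fixture("S2"); small$trait$beta_G <- log(1.1)
  dbl <- scenario_fixture("S2"); dbl$trait$beta_G <- 2 * log(1.1)
  info_s <- unit_information_ss(small$design_cov, small$trait, small$design,
                                b = 100000L, seed = 6)
  info_d <- unit_information_ss(dbl$design_cov, dbl$trait, dbl$design,
                                b = 100000L, seed = 6)
  n_s <- sample_size_ss(small$design_cov, small$trait, small$design,
                        info = info_s)
  n_d <- sample_size_ss(dbl$design_cov, dbl$trait, dbl$design, info = info_d)
  expect_gt(n_s / n_d, 3.3)
  expect_lt(n_s / n_d, 4.7)

  expect_error(
    sample_size_ss(s2$design_cov, trait_model(beta_G = 0, prevalence = 0.2),
                   s2$design, info = info), "beta_G = 0")
})

test_that("Monte-Carlo SE of the power estimate shrinks with b", {
  s2 <- scenario_fixture("S2")
  curve <- power_se_curve(s2$design_cov, s2$trait, s2$design, n = 1000,
                          b_grid = c(1000L, 8000L), replicates = 40L,
                          seed = 21)
  expect_lt(curve$se[2], curve$se[1])
})
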