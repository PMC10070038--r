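# independent largest-remainder apportionment for the oracle comparisons
lr_oracle <- function(p, n) {
  tgt <- n * p
  fl <- floor(tgt)
  k <- round(n - sum(fl))
  idx <- order(tgt - fl, decreasing = TRUE)[seq_len(k)]
  fl[idx] <- fl[idx] + 1
  as.integer(fl)
}

test_that("representative counts apportion the cell law exactly", {
  # exact multiples need no rounding at all
  des <- covariate_design(genotype_model(0.5, "additive"))
  tr <- trait_model(beta_G = log(1.2), prevalence = 0.2)
  pd <- study_design("prospective")
  cnt <- representative_counts(des, tr, pd, 100)
  expect_identical(cnt$count, c(25L, 50L, 25L))

  # S2 cells against the independent largest-remainder oracle
  s2 <- scenario_fixture("S2")
  cells <- cell_probs(s2$design_cov, s2$trait, s2$design)
  cnt2 <- representative_counts(s2$design_cov, s2$trait, s2$design, 100)
  expect_identical(cnt2$count, lr_oracle(cells$prob, 100))
  expect_identical(sum(cnt2$count), 100L)
})

test_that("counts always sum to n over random parameter draws", {
  set.seed(31)
  for (i in 1:200) {
    des <- covariate_design(
      genotype_model(runif(1, 0.02, 0.5),
                     sample(c("additive", "dominant", "recessive"), 1)),
      list(covariate_spec("binary", gamma_G = runif(1, -1.5, 1.5),
                          beta_E = runif(1, -1, 1),
                          exposure_rate = runif(1, 0.1, 0.9))))
    tr <- trait_model(beta_G = runif(1, -0.5, 0.5),
                      prevalence = runif(1, 0.05, 0.5))
    n <- sample(50:5000, 1)
    cnt <- suppressWarnings(
      representative_counts(des, tr, study_design("prospective"), n))
    expect_identical(sum(cnt$count), n)
  }
})

test_that("continuous representative values are conditional-normal scores", {
  # a singleton stratum sits at its conditional mean
  expect_equal(representative_continuous_values(0.3, 0.5, 2, g = 2, n_i = 1),
               0.3 + 1.0)
  # j = 1 of 5 is the Blom score of the smallest of five
  v <- representative_continuous_values(0, 0, 1, g = 0, n_i = 5)
  expect_equal(v[1], qnorm(0.625 / 5.25), tolerance = 1e-10)
  # symmetry about the conditional mean for several stratum sizes
  for (m in c(2, 7, 40)) {
    v <- representative_continuous_values(1, 0.4, 1.3, g = 1, n_i = m)
    expect_equal(v + rev(v), rep(2 * 1.4, m))
  }
})

test_that("expansion produces 2n rows with complementary unit weights", {
  s2 <- scenario_fixture("S2")
  rows <- sample_covariates(resolve_design(s2$design_cov), 50, seed = 3)
  rd <- expand_rd(rows, s2$design_cov, s2$trait, s2$design)
  expect_identical(nrow(rd), 100L)
  expect_equal(rd$delta[1:50] + rd$delta[51:100], rep(1, 50))
  expect_equal(sum(rd$delta), 50)  # total weight n
  expect_true(all(rd$delta >= 0 & rd$delta <= 1))

  # eta = 0 row splits half and half
  des0 <- covariate_design(genotype_model(0.2, "additive"))
  tr0 <- trait_model(beta_G = 0, beta0 = 0)
  rd0 <- expand_rd(data.frame(G = 1), des0, tr0, study_design("prospective"))
  expect_equal(rd0$delta, c(0.5, 0.5))
})

test_that("RD power: level at the null, determinism, enumeration agreement", {
  s2 <- scenario_fixture("S2")
  null2 <- scenario_fixture("S2"); null2$trait$beta_G <- 0
  expect_equal(power_rd(null2$design_cov, null2$trait, null2$design,
                        n = 2000)$power, 0.05, tolerance = 1e-12)
  expect_identical(power_rd(s2$design_cov, s2$trait, s2$design, 3000)$power,
                   power_rd(s2$design_cov, s2$trait, s2$design, 3000)$power)

  # against closed-form power from the exact 6-cell information (in
  # test-power-ss.R helpers' spirit, recomputed here independently)
  g0 <- resolve_stage2(s2$design_cov$covariates[[1]],
                       s2$design_cov$genotype)$gamma0
  b0 <- solve_beta0(s2$trait, s2$design_cov)
  cells <- expand.grid(g = c(0, 1), e = c(0, 1))
  pg <- c(0.81, 0.19)[cells$g + 1]
  pe <- plogis(g0 + log(0.2) * cells$g)
  pcell <- pg * ifelse(cells$e == 1, pe, 1 - pe)
  eta <- b0 + log(1.5) * cells$g + log(2.5) * cells$e
  w <- plogis(eta) * (1 - plogis(eta))
  I1 <- Reduce(`+`, lapply(seq_len(4), function(i)
    pcell[i] * w[i] * tcrossprod(c(1, cells$g[i], cells$e[i]))))
  n <- 5000
  v <- solve(n * I1)[2, 2]
  z <- qnorm(0.975)
  exact_power <- pnorm(-z + log(1.5) / sqrt(v)) + pnorm(-z - log(1.5) / sqrt(v))
  expect_equal(power_rd(s2$design_cov, s2$trait, s2$design, n)$power,
               exact_power, tolerance = 0.003)
})

test_that("RD information equals an IRLS fit on the weighted expansion", {
  s3 <- scenario_fixture("S3")
  res <- binpower:::resolve_inputs(s3$design_cov, s3$trait, s3$design)
  rows <- binpower:::representative_rows(res$design_cov, res$trait,
                                         res$design, 400)
  rd <- expand_rd(rows, res$design_cov, res$trait, res$design)
  fit <- suppressWarnings(
    glm(y ~ G + E1, family = binomial(), data = rd, weights = rd$delta))
  # the weighted MLE recovers the true (effective) coefficients ...
  expect_equal(unname(coef(fit)),
               c(res$beta0_eff, res$trait$beta_G,
                 res$design_cov$covariates[[1]]$beta_E), tolerance = 1e-6)
  # ... and its information matches the direct evaluation at beta
  X <- cbind(1, rows$G, rows$E1)
  mu <- plogis(X %*% c(res$beta0_eff, res$trait$beta_G,
                       res$design_cov$covariates[[1]]$beta_E))
  direct <- crossprod(X, X * as.numeric(mu * (1 - mu)))
  irls <- solve(summary(fit)$cov.unscaled)
  expect_equal(unname(irls), unname(direct), tolerance = 1e-6)
})

test_that("RD sample-size inversion brackets the target and tracks SS", {
  s2 <- scenario_fixture("S2")
  n_star <- sample_size_rd(s2$design_cov, s2$trait, s2$design, 0.8)
  expect_gte(power_rd(s2$design_cov, s2$trait, s2$design, n_star)$power, 0.8)
  expect_lt(power_rd(s2$design_cov, s2$trait, s2$design, n_star - 1)$power,
            0.8)
  n_ss <- sample_size_ss(s2$design_cov, s2$trait, s2$design, 0.8,
                         b = 200000L, seed = 17)
  expect_lt(abs(n_star - n_ss) / n_ss, 0.02)

  # larger effects need no more samples
  big <- scenario_fixture("S2"); big$trait$beta_G <- log(2.5)
  expect_lte(sample_size_rd(big$design_cov, big$trait, big$design, 0.8),
             n_star)
})

test_that("two continuous covariates are rejected for the RD path", {
  sp <- function() covariate_spec("continuous", gamma_G = 0.1, beta_E = 0.2,
                                  mean = 0, conditional_sd = 1)
  des <- covariate_design(genotype_model(0.2, "additive"), list(sp(), sp()))
  tr <- trait_model(beta_G = 0.3, prevalence = 0.2)
  expect_error(power_rd(des, tr, study_design("prospective"), 1000),
               "one continuous")
})
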