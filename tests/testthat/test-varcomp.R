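test_that("Gibbs sampler recovers Gaussian variance components and agrees with moments", {
  sim <- sim_gaussian()   # truth: V_line 2, V_vial 0.5, V_r 1, 200x4x10
  vc <- fit_gaussian_nested(sim$pheno, config = mcmc_config(seed = 5))
  post <- setNames(vc$summary$mean, vc$summary$parameter)
  expect_lt(abs(post[["V_line"]] - 2) / 2, 0.15)
  expect_lt(abs(post[["V_vial"]] - 0.5) / 0.5, 0.15)
  expect_lt(abs(post[["V_r"]] - 1) / 1, 0.15)
  expect_true(all(vc$summary$rhat < 1.1, na.rm = TRUE))
  # V_g = V_line / 2 per draw, exactly
  expect_equal(vc$draws$V_g, vc$draws$V_line / 2)
  # posterior means vs expected-mean-squares oracle
  mom <- moments_nested_anova(sim$pheno)
  expect_lt(abs(post[["V_line"]] - mom$V_line) / mom$V_line, 0.10)
  expect_lt(abs(post[["V_vial"]] - mom$V_vial) / mom$V_vial, 0.10)
  expect_lt(abs(post[["V_r"]] - mom$V_r) / mom$V_r, 0.10)
})

test_that("degenerate Gaussian inputs are handled", {
  # identical observations: all variance posteriors collapse toward zero
  ph <- survival_table(rep(sprintf("L%02d", 1:40), each = 6),
                       rep(rep(c("v1", "v2"), each = 3), 40),
                       rep(4.2, 240))
  vc <- fit_gaussian_nested(ph, config = quick_mcmc())
  expect_lt(mean(vc$draws$V_line), 0.05)
  expect_lt(mean(vc$draws$V_vial), 0.05)
  expect_lt(mean(vc$draws$V_r), 0.05)
  # one vial per line everywhere: V_vial flagged inestimable, fixed at 0
  ph1 <- survival_table(rep(sprintf("L%02d", 1:20), each = 5),
                        rep("v1", 100), rnorm(100))
  expect_warning(vc1 <- fit_gaussian_nested(ph1, config = quick_mcmc()),
                 "inestimable")
  expect_true(all(vc1$draws$V_vial == 0))
})

test_that("moments estimator handles exact and degenerate designs", {
  # zero noise, distinct line means
  means <- c(1, 3, 8, 2, 6)
  ph <- survival_table(rep(sprintf("L%d", 1:5), each = 6),
                       rep(rep(c("a", "b"), each = 3), 5),
                       rep(means, each = 6))
  mom <- moments_nested_anova(ph)
  expect_equal(mom$V_r, 0)
  expect_equal(mom$V_vial, 0)
  expect_equal(mom$V_line, stats::var(means))
  # single line rejected
  ph1 <- survival_table(rep("L1", 10), rep(c("a", "b"), each = 5), rnorm(10))
  expect_error(moments_nested_anova(ph1), "2 lines")
})

test_that("binomial logit sampler recovers truth and flags degenerate designs", {
  set.seed(21)
  nl <- 200
  b <- rnorm(nl, 0, sqrt(1.94))
  lv <- rep(1:nl, each = 4)
  eta <- b[lv] + rnorm(nl * 4, 0, sqrt(1.5))
  ph <- phenotype_table(
    data.frame(line_id = sprintf("L%03d", lv), virus = "w",
               vial_id = rep(sprintf("v%d", 1:4), nl), n_flies = 15L,
               n_infected = rbinom(nl * 4, 15, plogis(eta))), "infection")
  vc <- fit_binomial_logit(ph, config = mcmc_config(n_iter = 10000,
                                                    burnin = 2500, thin = 5,
                                                    seed = 2))
  s <- vc$summary
  lo <- s$hpd_lower[s$parameter == "V_line"]
  hi <- s$hpd_upper[s$parameter == "V_line"]
  expect_lt(lo, 1.94); expect_gt(hi, 1.94)
  expect_lt(abs(s$mean[s$parameter == "V_r"] - 1.5) / 1.5, 0.35)

  expect_error(fit_binomial_logit(phenotype_table(
    data.frame(line_id = "L1", virus = "w", vial_id = sprintf("v%d", 1:8),
               n_flies = 15L, n_infected = rbinom(8, 15, 0.4)), "infection")),
    "2 lines")
})

test_that("null between-line variance concentrates near zero", {
  set.seed(31)
  nl <- 200
  lv <- rep(1:nl, each = 4)
  eta <- rnorm(nl * 4, 0, sqrt(1))   # vial noise only, no line effects
  ph <- phenotype_table(
    data.frame(line_id = sprintf("L%03d", lv), virus = "w",
               vial_id = rep(sprintf("v%d", 1:4), nl), n_flies = 15L,
               n_infected = rbinom(nl * 4, 15, plogis(eta))), "infection")
  vc <- fit_binomial_logit(ph, config = mcmc_config(n_iter = 10000,
                                                    burnin = 2500, thin = 5,
                                                    seed = 3))
  s <- vc$summary
  expect_lt(s$hpd_upper[s$parameter == "V_line"], 0.5)
})

test_that("heritability calculus matches the observed- and logit-scale formulas", {
  # logit scale: published DMelSV components give h2 = 0.29
  vc <- varcomp_components(V_g = 1.94, V_r = 4.79 - pi^2 / 3, scale = "logit")
  expect_equal(round(heritability(vc)$mean, 2), 0.29)
  # observed scale: published FHV components give h2 = 0.07
  vc2 <- varcomp_components(V_g = 0.17, V_vial = 0, V_r = 2.10,
                            scale = "observed")
  expect_equal(round(heritability(vc2)$mean, 2), 0.07)
  # limits
  expect_equal(heritability(varcomp_components(V_g = 0, V_r = 1,
                                               scale = "observed"))$mean, 0)
  expect_equal(heritability(varcomp_components(V_g = 3, V_vial = 0, V_r = 0,
                                               scale = "observed"))$mean, 1)
  # logit formula reduces to V_g/(V_g + pi^2/3) when V_r = 0
  vc3 <- varcomp_components(V_g = pi^2 / 3, V_r = 0, scale = "logit")
  expect_equal(vc3$draws$V_e, pi^2 / 3)
  expect_equal(heritability(vc3)$mean, 0.5)
  # h2 always within [0, 1] on real posterior draws
  vc4 <- fit_gaussian_nested(sim_gaussian(n_lines = 30)$pheno,
                             config = quick_mcmc())
  h <- heritability(vc4)
  expect_true(all(h$draws >= 0 & h$draws <= 1))
  expect_lte(h$hpd[["lower"]], h$hpd[["upper"]])
})

test_that("CVg follows 100*sqrt(Vg)/beta and is refused on the logit scale", {
  expect_equal(cvg(varcomp_components(V_g = 1, V_r = 1, beta = 10,
                                      scale = "observed"))$mean, 10)
  expect_equal(cvg(varcomp_components(V_g = 0, V_r = 1, beta = 10,
                                      scale = "observed"))$mean, 0)
  # inverting the published DCV CVg = 20 with V_g = 0.61 implies beta ~ 3.905
  expect_equal(round(cvg(varcomp_components(V_g = 0.61, V_r = 1,
                                            beta = 3.905,
                                            scale = "observed"))$mean), 20)
  expect_error(cvg(varcomp_components(V_g = 1, V_r = 1, scale = "logit")),
               "logit")
})

test_that("posterior summaries are invariant to line relabeling", {
  sim <- sim_gaussian(n_lines = 60)
  vc <- fit_gaussian_nested(sim$pheno, config = quick_mcmc(seed = 4))
  ph2 <- sim$pheno
  perm <- sample(unique(ph2$line_id))
  ph2$line_id <- setNames(perm, unique(ph2$line_id))[ph2$line_id]
  vc2 <- fit_gaussian_nested(phenotype_table(as.data.frame(ph2), "survival"),
                             config = quick_mcmc(seed = 4))
  expect_lt(abs(mean(vc$draws$V_line) - mean(vc2$draws$V_line)) /
              mean(vc$draws$V_line), 0.05)
})

test_that("hpd and ess behave on known inputs", {
  x <- c(rep(0, 90), seq(10, 19))   # shortest 95% window excludes the tail
  h <- hpd_interval(x, 0.90)
  expect_equal(unname(h), c(0, 0))
  expect_lt(ess(cumsum(rnorm(500))), 500)  # strong autocorrelation shrinks ESS
})
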