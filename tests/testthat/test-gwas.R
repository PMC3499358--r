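test_that("line values are fly-weighted survival means or pooled proportions", {
  # two vials with 10 flies at mean 4 and 30 flies at mean 8 -> 7.0
  ph <- survival_table(rep("L1", 40), rep(c("v1", "v2"), c(10, 30)),
                       c(rep(4, 10), rep(8, 30)))
  lv <- collapse_to_line_values(ph)
  expect_equal(lv$value, 7.0)
  expect_equal(lv$weight, 40)
  expect_equal(lv$n_vials, 2L)

  # pooled infection proportions, with and without the arcsin-sqrt transform
  ph2 <- phenotype_table(
    data.frame(line_id = c("L1", "L2", "L2", "L3"), virus = "w",
               vial_id = c("v1", "v1", "v2", "v1"),
               n_flies = c(10L, 10L, 10L, 10L),
               n_infected = c(0L, 5L, 5L, 10L)), "infection")
  lv2 <- collapse_to_line_values(ph2)
  expect_equal(lv2$value, c(0, 0.5, 1))
  lv3 <- collapse_to_line_values(ph2, transform = TRUE)
  expect_equal(lv3$value, c(0, pi / 4, pi / 2))

  # single vial: the line value is that vial's statistic
  ph3 <- survival_table(rep("L1", 5), rep("v1", 5), c(1, 2, 3, 4, 5))
  expect_equal(collapse_to_line_values(ph3)$value, 3)
})

test_that("site filter applies the 4-minor-line rule after masking segregating calls", {
  g <- matrix(0L, nrow = 20, ncol = 4)
  g[1:3, 1] <- 2L            # minor allele in 3 lines: dropped
  g[1:4, 2] <- 2L            # minor allele in 4 lines: kept
  # site 3 monomorphic: dropped
  g[1:4, 4] <- 2L            # would be kept, but the segregating call in one
  g[4, 4] <- 1L              # minor line drops it to 3 minor lines
  panel <- toy_panel(g)
  kept <- filter_sites(panel, min_minor_lines = 4)
  expect_identical(as.vector(kept), panel$sites$site_id[2])
  # and a site whose only minor line segregates becomes monomorphic
  g2 <- matrix(0L, nrow = 20, ncol = 1)
  g2[1, 1] <- 1L
  expect_length(filter_sites(toy_panel(g2), min_minor_lines = 1), 0)
})

test_that("scan matches a hand-solved least-squares fit on a 6-line toy", {
  g <- matrix(c(0L, 0L, 0L, 2L, 2L, 2L), ncol = 1)
  panel <- toy_panel(g)
  y <- c(1.2, 0.8, 1.1, 3.0, 3.4, 2.9)
  lv <- toy_line_values(y)
  scan <- scan_assoc(panel, lv, sites = panel$sites$site_id)
  # closed-form normal equations on the +/-1 coding
  x <- c(-1, -1, -1, 1, 1, 1)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  res <- y - mean(y) - slope * (x - mean(x))
  s2 <- sum(res^2) / 4
  se <- sqrt(s2 / sum((x - mean(x))^2))
  expect_equal(scan$a_hat, slope, tolerance = 1e-12)
  expect_equal(scan$se, se, tolerance = 1e-12)
  expect_equal(scan$F, (slope / se)^2, tolerance = 1e-10)
  expect_equal(scan$p, pf((slope / se)^2, 1, 4, lower.tail = FALSE))
  expect_equal(scan$n_lines, 6L)
})

test_that("a noiseless planted effect is recovered exactly and nulls are uniform", {
  set.seed(8)
  g <- matrix(2L * rbinom(200 * 50, 1, 0.3), nrow = 200)
  panel <- toy_panel(g)
  yv <- 5 + 1.5 * (g[, 7] - 1)
  scan <- scan_assoc(panel, toy_line_values(yv), sites = panel$sites$site_id)
  expect_equal(scan$a_hat[7], 1.5, tolerance = 1e-10)
  expect_lt(scan$p[7], 1e-200)

  # null calibration: p-values uniform under no association
  set.seed(9)
  gp <- matrix(2L * rbinom(200 * 100, 1, 0.4), nrow = 200)
  pnull <- unlist(lapply(1:50, function(i) {
    scan_assoc(toy_panel(gp), toy_line_values(rnorm(200)),
               sites = paste0("2L:", 100 * (1:100)))$p
  }))
  expect_gt(stats::ks.test(pnull, "punif")$p.value, 0.01)
})

test_that("scan is equivariant under line relabeling and allele swaps", {
  set.seed(10)
  g <- matrix(2L * rbinom(100 * 20, 1, 0.3), nrow = 100)
  g[sample(length(g), 50)] <- -1L
  panel <- toy_panel(g)
  y <- rnorm(100) + 0.8 * ifelse(g[, 3] == -1L, 0, g[, 3] - 1)
  scan <- scan_assoc(panel, toy_line_values(y), panel$sites$site_id)
  # permute lines (same pairing of genotype and phenotype)
  perm <- sample(100)
  panel_p <- toy_panel(g[perm, ])
  scan_p <- scan_assoc(panel_p, toy_line_values(y[perm]),
                       panel$sites$site_id)
  expect_equal(scan_p$p, scan$p)
  expect_equal(scan_p$a_hat, scan$a_hat)
  # swap allele labels: p unchanged, a_hat flips sign
  g_sw <- g
  g_sw[g == 0L] <- 2L; g_sw[g == 2L] <- 0L
  scan_s <- scan_assoc(toy_panel(g_sw), toy_line_values(y),
                       panel$sites$site_id)
  expect_equal(scan_s$p, scan$p)
  expect_equal(scan_s$a_hat, -scan$a_hat)
})

test_that("conditional scan reports collinear sites and keeps nulls calibrated", {
  set.seed(11)
  g <- matrix(2L * rbinom(150 * 30, 1, 0.4), nrow = 150)
  g[, 2] <- g[, 1]   # perfect copy
  panel <- toy_panel(g)
  y <- rnorm(150) + (g[, 1] - 1)
  scan <- scan_assoc(panel, toy_line_values(y), panel$sites$site_id,
                     covariates = panel$sites$site_id[1])
  expect_equal(scan$reason[scan$site_id == panel$sites$site_id[2]],
               "collinear_with_covariates")
  expect_true(is.na(scan$p[scan$site_id == panel$sites$site_id[2]]))
  # pure-noise covariate leaves null p-values uniform
  set.seed(12)
  pnull <- unlist(lapply(1:30, function(i) {
    gp <- matrix(2L * rbinom(150 * 40, 1, 0.4), nrow = 150)
    pa <- toy_panel(gp)
    scan_assoc(pa, toy_line_values(rnorm(150)), pa$sites$site_id[-1],
               covariates = pa$sites$site_id[1])$p
  }))
  expect_gt(stats::ks.test(pnull[!is.na(pnull)], "punif")$p.value, 0.01)
})

test_that("permutation thresholds behave like empirical quantiles of min p", {
  set.seed(13)
  # a single independent site: min over one test, threshold(alpha) ~ alpha
  g1 <- matrix(2L * rbinom(100, 1, 0.5), ncol = 1)
  panel1 <- toy_panel(g1)
  lv1 <- toy_line_values(rnorm(100))
  null1 <- permute_threshold(panel1, lv1, sites = panel1$sites$site_id,
                             n_perm = 400, seed = 14)
  expect_lt(abs(threshold_at(null1, 0.05) - 0.05), 0.025)
  expect_lte(threshold_at(null1, 0.05), threshold_at(null1, 0.2))
  # reproducible under the same seed
  null1b <- permute_threshold(panel1, lv1, sites = panel1$sites$site_id,
                              n_perm = 400, seed = 14)
  expect_identical(null1$min_p, null1b$min_p)
  expect_warning(permute_threshold(panel1, lv1,
                                   sites = panel1$sites$site_id, n_perm = 10,
                                   seed = 1), "unstable")
})

test_that("qq curves sit on the diagonal for null data and flag planted effects", {
  set.seed(15)
  g <- matrix(2L * rbinom(120 * 80, 1, 0.4), nrow = 120)
  panel <- toy_panel(g)
  lv <- toy_line_values(rnorm(120))
  null <- permute_threshold(panel, lv, panel$sites$site_id, n_perm = 50,
                            seed = 16, keep_scans = TRUE)
  # a null observed scan: curve close to the diagonal
  qq0 <- qq_curve(scan_assoc(panel, lv, panel$sites$site_id), null)
  expect_lt(mean(abs(qq0$observed - qq0$expected)), 0.35)
  expect_true(all(diff(qq0$observed) <= 1e-12))
  expect_true(all(diff(qq0$expected) <= 1e-12))
  # planted major effect: top of the curve rises above the diagonal
  y1 <- rnorm(120) + 1.5 * (g[, 5] - 1)
  qq1 <- qq_curve(scan_assoc(panel, toy_line_values(y1),
                             panel$sites$site_id), null)
  expect_gt(qq1$observed[1] - qq1$expected[1], 2)
})

test_that("joint and sequential fits disentangle linked sites", {
  set.seed(17)
  g <- matrix(2L * rbinom(120 * 3, 1, 0.5), nrow = 120)
  g[, 2] <- g[, 1]
  panel <- toy_panel(g)
  y <- rnorm(120, sd = 0.5) + (g[, 1] - 1)
  lv <- toy_line_values(y)
  # perfectly correlated pair: aliasing reported
  expect_warning(jf <- joint_fit(panel, lv, panel$sites$site_id[1:2]),
                 "aliased")
  expect_true(jf$aliased[2])
  expect_false(jf$aliased[1])
  # single site: marginal p equals the scan p
  jf1 <- joint_fit(panel, lv, panel$sites$site_id[1])
  sc <- scan_assoc(panel, lv, panel$sites$site_id[1])
  expect_equal(jf1$p, sc$p, tolerance = 1e-12)
  expect_equal(jf1$a_hat, sc$a_hat, tolerance = 1e-12)
  # sequential p of the first term matches its own single-site fit
  sf <- sequential_fit(panel, lv, panel$sites$site_id[c(1, 3)])
  an <- anova(lm(y ~ I(g[, 1] - 1) + I(g[, 3] - 1)))
  expect_equal(sf$F, an[1:2, "F value"], tolerance = 1e-10)
})

test_that("the causal site beats a correlated proxy in joint marginal tests", {
  set.seed(18)
  wins <- vapply(1:100, function(i) {
    n <- 200
    causal <- 2L * rbinom(n, 1, 0.5)
    flip <- rbinom(n, 1, (1 - sqrt(0.8)) / 2) == 1
    proxy <- ifelse(flip, 2L - causal, causal)
    panel <- toy_panel(cbind(causal, proxy))
    y <- (causal - 1) + rnorm(n, sd = 0.7)   # strong signal
    jf <- joint_fit(panel, toy_line_values(y), panel$sites$site_id)
    jf$p[1] < jf$p[2]
  }, logical(1))
  expect_gte(sum(wins), 90)
})
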