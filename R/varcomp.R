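#' Fit the Gaussian nested animal model by Gibbs sampling
#'
#' Model: per-fly survival `y = beta + b_line + c_vial + e`, with
#' `b ~ N(0, V_line)`, `c ~ N(0, V_vial)`, `e ~ N(0, V_r)`. All full
#' conditionals are conjugate (flat prior on `beta`, inverse-gamma priors on
#' the variances), so the sampler is a plain Gibbs scheme. The genetic
#' variance of the base population is half the between-line variance of the
#' homozygous panel, `V_g = V_line / 2`, computed per draw.
#'
#' @param pheno a survival-kind [phenotype_table()]
#' @param trait virus/trait id to fit (default: the only one present)
#' @param config an [mcmc_config()]
#' @return an object of class `varcomp`: posterior draws of
#'   `beta, V_line, V_vial, V_r, V_g` with a summary table (posterior mean,
#'   95% HPD, effective sample size, split-chain Rhat)
#' @export
fit_gaussian_nested <- function(pheno, trait = NULL, config = mcmc_config()) {
  stopifnot(pheno_kind(pheno) == "survival")
  d <- .subset_trait(pheno, trait)
  y <- d$value
  line <- factor(d$line_id)
  vial <- factor(paste(d$line_id, d$vial_id))
  nl <- nlevels(line); nv <- nlevels(vial); n <- length(y)
  if (nl < 2L) stop("need >= 2 lines to estimate between-line variance")
  vials_per_line <- tapply(as.integer(vial), line,
                           function(v) length(unique(v)))
  vial_estimable <- any(vials_per_line > 1L)
  if (!vial_estimable)
    warning("every line has a single vial: V_vial is inestimable, fixed at 0")
  li <- as.integer(line); vi <- as.integer(vial)
  line_of_vial <- as.integer(tapply(li, vi, `[`, 1L))
  n_per_line <- tabulate(li, nl); n_per_vial <- tabulate(vi, nv)
  # the model is nested, so the Gibbs sweep only needs per-vial sufficient
  # statistics: each iteration is O(n_vials), not O(n_flies)
  Sy_v <- rowsum(y, vi)[, 1L]
  Syy_v <- rowsum(y^2, vi)[, 1L]
  Sy_i <- rowsum(Sy_v, line_of_vial)[, 1L]
  ig <- .prior_ig(config)
  keep <- seq.int(config$burnin + config$thin, config$n_iter, by = config$thin)
  keep_it <- logical(config$n_iter); keep_it[keep] <- TRUE
  all_draws <- list()
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    beta <- mean(y); b <- numeric(nl); cc <- numeric(nv)
    Vl <- max(stats::var(tapply(y, li, mean)), 0.1)
    Vv <- if (vial_estimable) Vl / 2 else 0
    Vr <- max(stats::var(y) / 2, 0.1)
    out <- matrix(NA_real_, length(keep), 4L,
                  dimnames = list(NULL, c("beta", "V_line", "V_vial", "V_r")))
    k <- 0L
    for (it in seq_len(config$n_iter)) {
      nc_i <- rowsum(n_per_vial * cc, line_of_vial)[, 1L]
      beta <- stats::rnorm(1L, (sum(Sy_i) - sum(n_per_line * b) - sum(nc_i)) / n,
                           sqrt(Vr / n))
      # line effects
      sums <- Sy_i - beta * n_per_line - nc_i
      prec <- n_per_line / Vr + 1 / Vl
      b <- stats::rnorm(nl, (sums / Vr) / prec, sqrt(1 / prec))
      # vial effects
      if (vial_estimable) {
        sums_v <- Sy_v - (beta + b[line_of_vial]) * n_per_vial
        prec_v <- n_per_vial / Vr + 1 / Vv
        cc <- stats::rnorm(nv, (sums_v / Vr) / prec_v, sqrt(1 / prec_v))
      }
      # variances
      Vl <- .rinvgamma1(ig["a0"] + nl / 2, ig["b0"] + sum(b^2) / 2)
      if (vial_estimable)
        Vv <- .rinvgamma1(ig["a0"] + nv / 2, ig["b0"] + sum(cc^2) / 2)
      m_v <- beta + b[line_of_vial] + cc
      sse <- sum(Syy_v - 2 * m_v * Sy_v + n_per_vial * m_v^2)
      Vr <- .rinvgamma1(ig["a0"] + n / 2, ig["b0"] + max(sse, 0) / 2)
      if (keep_it[it]) {
        k <- k + 1L
        out[k, ] <- c(beta, Vl, Vv, Vr)
      }
    }
    all_draws[[ch]] <- out
  }
  .varcomp_object(all_draws, scale = "observed", trait = d$virus[1L],
                  config = config, n_lines = nl, n_vials = nv, n_obs = n)
}

#' Fit the binomial logit model with overdispersion by MCMC
#'
#' Model: per-vial infected counts `k ~ Binomial(n, p)` with
#' `logit(p) = beta + b_line + e_vial`, where `b ~ N(0, V_line)` and the
#' vial-level `e ~ N(0, V_od)` captures extra-binomial (overdispersion)
#' variation. Latent effects and `beta` are updated by adaptive random-walk
#' Metropolis steps (tuned to ~44% acceptance during burn-in); the variances
#' have conjugate inverse-gamma updates.
#'
#' @param pheno an infection-kind [phenotype_table()]
#' @inheritParams fit_gaussian_nested
#' @return a `varcomp` object on the logit scale (`V_r` is the
#'   overdispersion variance)
#' @export
fit_binomial_logit <- function(pheno, trait = NULL, config = mcmc_config()) {
  stopifnot(pheno_kind(pheno) == "infection")
  d <- .subset_trait(pheno, trait)
  vial <- factor(paste(d$line_id, d$vial_id))
  kk <- rowsum(d$n_infected, vial)[, 1L]
  nn <- rowsum(d$n_flies, vial)[, 1L]
  line_of_vial <- tapply(as.character(d$line_id), vial, `[`, 1L)
  line <- factor(line_of_vial)
  nl <- nlevels(line); nv <- length(kk)
  if (nl < 2L) stop("need >= 2 lines to estimate between-line variance")
  if (sum(kk) == 0L || sum(kk) == sum(nn))
    warning("all flies ", if (sum(kk) == 0L) "uninfected" else "infected",
            ": beta is poorly identified")
  li <- as.integer(line)
  ig <- .prior_ig(config)
  keep <- seq.int(config$burnin + config$thin, config$n_iter, by = config$thin)
  keep_it <- logical(config$n_iter); keep_it[keep] <- TRUE
  ll_binom <- function(eta) kk * eta - nn * (pmax(eta, 0) + log1p(exp(-abs(eta))))
  all_draws <- list()
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    p0 <- (sum(kk) + 0.5) / (sum(nn) + 1)
    beta <- stats::qlogis(p0)
    b <- numeric(nl); e <- numeric(nv)
    Vl <- 1; Vod <- 1
    step_b <- 0.5; step_e <- 0.8; step_beta <- 0.2
    acc <- c(b = 0, e = 0, beta = 0); batch <- 0L
    out <- matrix(NA_real_, length(keep), 3L,
                  dimnames = list(NULL, c("beta", "V_line", "V_r")))
    k <- 0L
    for (it in seq_len(config$n_iter)) {
      eta <- beta + b[li] + e
      ll <- ll_binom(eta)
      # vial-level overdispersion effects (vectorized MH)
      e_new <- e + step_e * stats::rnorm(nv)
      d_ll <- ll_binom(eta + (e_new - e)) - ll +
        (e^2 - e_new^2) / (2 * Vod)
      a_e <- log(stats::runif(nv)) < d_ll
      e[a_e] <- e_new[a_e]
      eta <- beta + b[li] + e
      ll <- ll_binom(eta)
      # line effects (vectorized MH; per-line likelihood sums)
      delta <- step_b * stats::rnorm(nl)
      d_ll_line <- rowsum(ll_binom(eta + delta[li]) - ll, li)[, 1L] +
        (b^2 - (b + delta)^2) / (2 * Vl)
      a_b <- log(stats::runif(nl)) < d_ll_line
      b[a_b] <- b[a_b] + delta[a_b]
      eta <- beta + b[li] + e
      # overall mean (scalar MH, flat prior)
      beta_new <- beta + step_beta * stats::rnorm(1L)
      d_beta <- sum(ll_binom(eta + (beta_new - beta))) - sum(ll_binom(eta))
      a_beta <- log(stats::runif(1L)) < d_beta
      if (a_beta) beta <- beta_new
      # conjugate variance updates
      Vl <- .rinvgamma1(ig["a0"] + nl / 2, ig["b0"] + sum(b^2) / 2)
      Vod <- .rinvgamma1(ig["a0"] + nv / 2, ig["b0"] + sum(e^2) / 2)
      # step-size adaptation during burn-in
      acc <- acc + c(mean(a_b), mean(a_e), a_beta)
      batch <- batch + 1L
      if (it <= config$burnin && batch == 50L) {
        step_b <- .adapt_step(step_b, acc[["b"]] / 50, it / 50)
        step_e <- .adapt_step(step_e, acc[["e"]] / 50, it / 50)
        step_beta <- .adapt_step(step_beta, acc[["beta"]] / 50, it / 50)
        acc[] <- 0; batch <- 0L
      }
      if (keep_it[it]) {
        k <- k + 1L
        out[k, ] <- c(beta, Vl, Vod)
      }
    }
    all_draws[[ch]] <- out
  }
  .varcomp_object(all_draws, scale = "logit", trait = d$virus[1L],
                  config = config, n_lines = nl, n_vials = nv, n_obs = sum(nn))
}

.subset_trait <- function(pheno, trait) {
  traits <- unique(pheno$virus)
  if (is.null(trait)) {
    if (length(traits) > 1L)
      stop("phenotype table has several traits; pick one: ",
           paste(traits, collapse = ", "))
    trait <- traits
  }
  d <- pheno[pheno$virus == trait, , drop = FALSE]
  if (nrow(d) == 0L) stop("no records for trait '", trait, "'")
  d
}

.varcomp_object <- function(all_draws, scale, trait, config, n_lines,
                            n_vials, n_obs) {
  draws <- as.data.frame(do.call(rbind, all_draws))
  chain <- rep(seq_along(all_draws), vapply(all_draws, nrow, integer(1)))
  draws$V_g <- draws$V_line / 2
  if (scale == "observed") {
    draws$V_e <- draws$V_vial + draws$V_r
  } else {
    draws$V_e <- draws$V_r + pi^2 / 3
  }
  obj <- list(draws = draws, chain = chain, scale = scale, trait = trait,
              summary = summarize_draws(as.matrix(draws), chain),
              config = config,
              sizes = c(n_lines = n_lines, n_vials = n_vials, n_obs = n_obs))
  class(obj) <- "varcomp"
  obj
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf("varcomp fit (%s scale), trait '%s': %d lines, %d vials, %d obs\n",
              x$scale, x$trait, x$sizes[["n_lines"]], x$sizes[["n_vials"]],
              x$sizes[["n_obs"]]))
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Posterior heritability
#'
#' Heritability is computed per posterior draw and then summarized
#' (posterior mean of the ratio, not ratio of posterior means). On the
#' observed scale `h2 = V_g / (V_g + V_vial + V_r)`; on the logit scale
#' `h2 = V_g / (V_g + V_r + pi^2/3)`, the `pi^2/3` term being the variance of
#' the standard logistic distribution implicit in the link.
#'
#' @param vc a [fit_gaussian_nested()] or [fit_binomial_logit()] result
#' @return a `posterior_summary`: posterior mean, 95% HPD and the draws
#' @export
heritability <- function(vc) {
  stopifnot(inherits(vc, "varcomp"))
  d <- vc$draws
  h2 <- if (vc$scale == "observed") {
    d$V_g / (d$V_g + d$V_vial + d$V_r)
  } else {
    d$V_g / (d$V_g + d$V_r + pi^2 / 3)
  }
  posterior_summary(h2, "h2")
}

#' Posterior coefficient of genetic variation
#'
#' `CV_g = 100 * sqrt(V_g) / beta`, a mean-standardized evolvability measure.
#' Only defined for traits on the observed scale with a positive mean;
#' refused for logit-scale fits (ratios of infected flies analysed on a logit
#' scale have no meaningful trait mean for standardization).
#'
#' @inheritParams heritability
#' @return a `posterior_summary`
#' @export
cvg <- function(vc) {
  stopifnot(inherits(vc, "varcomp"))
  if (vc$scale != "observed")
    stop("CVg is not defined for logit-scale fits")
  posterior_summary(100 * sqrt(vc$draws$V_g) / vc$draws$beta, "CVg")
}

#' Construct a posterior summary from draws
#' @param draws numeric vector of per-draw values
#' @param name quantity name
#' @return object of class `posterior_summary` with `mean`, `hpd`, `draws`
#' @export
posterior_summary <- function(draws, name = "quantity") {
  structure(list(name = name, mean = mean(draws), hpd = hpd_interval(draws),
                 draws = draws),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("%s: %.4g (95%% HPD %.4g - %.4g) [%d draws]\n", x$name, x$mean,
              x$hpd[["lower"]], x$hpd[["upper"]], length(x$draws)))
  invisible(x)
}

#' Build a variance-component object from point values
#'
#' Wraps known component values (e.g. published posterior summaries) in a
#' degenerate single-draw `varcomp` object so the derived-quantity calculus
#' ([heritability()], [cvg()]) can be applied to them. On the logit scale,
#' pass the residual (overdispersion) variance as `V_r`; if only the total
#' environmental variance `V_e = V_r + pi^2/3` is known, subtract `pi^2/3`
#' first.
#'
#' @param V_line between-line variance (`V_g` is half of it); give either
#'   this or `V_g`
#' @param V_g genetic variance (alternative to `V_line`)
#' @param V_vial between-vial variance (observed scale; default 0)
#' @param V_r residual (observed) or overdispersion (logit) variance
#' @param beta trait mean on the model scale
#' @param scale `"observed"` or `"logit"`
#' @param trait trait label
#' @return a `varcomp` object with a single draw
#' @export
varcomp_components <- function(V_line = NULL, V_g = NULL, V_vial = 0, V_r,
                               beta = NA_real_, scale = c("observed", "logit"),
                               trait = "trait") {
  scale <- match.arg(scale)
  if (is.null(V_line)) {
    if (is.null(V_g)) stop("give V_line or V_g")
    V_line <- 2 * V_g
  }
  draws <- data.frame(beta = beta, V_line = V_line, V_r = V_r)
  if (scale == "observed") draws$V_vial <- V_vial
  .varcomp_object(list(as.matrix(draws)), scale = scale, trait = trait,
                  config = NULL, n_lines = NA_integer_, n_vials = NA_integer_,
                  n_obs = NA_integer_)
}

#' Method-of-moments nested ANOVA estimates
#'
#' Expected-mean-squares estimator for the two-level nested design (flies in
#' vials in lines), valid for balanced and mildly unbalanced data; used as a
#' fast deterministic cross-check on the MCMC fit. Negative solutions are
#' truncated at zero and flagged.
#'
#' @param pheno a survival-kind [phenotype_table()]
#' @param trait trait id (default: the only one present)
#' @return list with `V_line`, `V_vial`, `V_r`, `truncated` (character vector
#'   of components truncated at 0) and the mean squares
#' @export
moments_nested_anova <- function(pheno, trait = NULL) {
  stopifnot(pheno_kind(pheno) == "survival")
  d <- .subset_trait(pheno, trait)
  y <- d$value
  line <- factor(d$line_id)
  vial <- factor(paste(d$line_id, d$vial_id))
  a <- nlevels(line)
  if (a < 2L) stop("need >= 2 lines")
  vial_counts <- tapply(as.integer(vial), line, function(v) length(unique(v)))
  if (all(vial_counts < 2L)) stop("V_vial inestimable: every line has one vial")
  N <- length(y)
  li <- as.integer(line); vi <- as.integer(vial)
  n_ij <- tabulate(vi)                      # flies per vial
  line_of_vial <- as.integer(tapply(li, vi, `[`, 1L))
  n_i <- tabulate(li, a)                    # flies per line
  btot <- nlevels(vial)
  ybar <- mean(y)
  line_means <- rowsum(y, li)[, 1L] / n_i
  vial_means <- rowsum(y, vi)[, 1L] / n_ij
  ss_a <- sum(n_i * (line_means - ybar)^2)
  ss_b <- sum(n_ij * (vial_means - line_means[line_of_vial])^2)
  ss_w <- sum((y - vial_means[vi])^2)
  ms_a <- ss_a / (a - 1)
  ms_b <- ss_b / (btot - a)
  ms_w <- ss_w / (N - btot)
  # Searle's unbalanced EMS coefficients
  sum_nij2_over_ni <- sum(rowsum(n_ij^2, line_of_vial)[, 1L] / n_i)
  c1 <- (N - sum_nij2_over_ni) / (btot - a)
  c2 <- (sum_nij2_over_ni - sum(n_ij^2) / N) / (a - 1)
  c3 <- (N - sum(n_i^2) / N) / (a - 1)
  V_r <- ms_w
  V_vial <- (ms_b - ms_w) / c1
  V_line <- (ms_a - ms_w - c2 * V_vial) / c3
  truncated <- character()
  if (V_vial < 0) { truncated <- c(truncated, "V_vial"); V_vial <- 0 }
  if (V_line < 0) { truncated <- c(truncated, "V_line"); V_line <- 0 }
  list(V_line = V_line, V_vial = V_vial, V_r = V_r, truncated = truncated,
       mean_squares = c(line = ms_a, vial = ms_b, within = ms_w))
}
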