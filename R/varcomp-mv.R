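#' Binarize a survival trait at a single observation day
#'
#' Converts a per-fly survival table into per-vial counts of dead (by the
#' given day) and alive flies, so survival traits can enter the multivariate
#' binomial model alongside infection traits. By default the day is chosen as
#' the observation day at which pooled mortality is nearest 50%, which
#' maximizes the binomial information.
#'
#' @param pheno a survival-kind [phenotype_table()]
#' @param day integer day; `NULL` picks the day with pooled mortality nearest 0.5
#' @return an infection-kind `phenotype_table` (`n_infected` = flies dead by `day`)
#'   with the chosen day in attribute `day`
#' @export
binarize_survival <- function(pheno, day = NULL) {
  stopifnot(pheno_kind(pheno) == "survival")
  if (is.null(day)) {
    cand <- seq(ceiling(min(pheno$value)), floor(max(pheno$value)))
    if (length(cand) == 0L) cand <- round(stats::median(pheno$value))
    mort <- vapply(cand, function(d) mean(pheno$value <= d), numeric(1))
    day <- cand[which.min(abs(mort - 0.5))]
  }
  key <- paste(pheno$line_id, pheno$vial_id)
  out <- data.frame(
    line_id = tapply(as.character(pheno$line_id), key, `[`, 1L),
    virus = tapply(as.character(pheno$virus), key, `[`, 1L),
    vial_id = tapply(as.character(pheno$vial_id), key, `[`, 1L),
    n_flies = as.integer(tapply(pheno$value, key, length)),
    n_infected = as.integer(tapply(pheno$value <= day, key, sum)),
    row.names = NULL, stringsAsFactors = FALSE)
  out <- phenotype_table(out, kind = "infection")
  attr(out, "day") <- day
  out
}

#' Fit the multivariate binary line-effect model by MCMC
#'
#' All traits are treated as vial-level binomial responses on the logit scale
#' (survival traits are first binarized at a single day with
#' [binarize_survival()]). Per-trait means are fixed effects; line effects are
#' multivariate normal across traits with an unstructured covariance matrix
#' (inverse-Wishart conjugate update); a vial-level normal residual with a
#' separate variance per trait captures overdispersion. Latent effects are
#' updated with adaptive random-walk Metropolis steps.
#'
#' @param phenos list of single-trait [phenotype_table()] objects (two or more
#'   traits; survival tables are binarized automatically)
#' @param day day at which to binarize survival traits (`NULL` = pooled
#'   mortality nearest 50%, chosen per trait)
#' @param config an [mcmc_config()]
#' @return an object of class `gencov`: posterior draws of the line-effect
#'   covariance matrix (`Sigma`, traits x traits x draws), per-trait means and
#'   overdispersion variances
#' @export
fit_multivariate_binary <- function(phenos, day = NULL,
                                    config = mcmc_config()) {
  if (inherits(phenos, "phenotype_table")) phenos <- list(phenos)
  phenos <- lapply(phenos, function(p) {
    if (pheno_kind(p) == "survival") binarize_survival(p, day) else p
  })
  tab <- do.call(rbind, lapply(phenos, function(p) {
    as.data.frame(p)[c("line_id", "virus", "n_flies", "n_infected")]
  }))
  traits <- unique(tab$virus)
  Tt <- length(traits)
  if (Tt < 2L) stop("need >= 2 traits for a covariance matrix")
  for (i in seq_len(Tt - 1L)) for (j in seq(i + 1L, Tt)) {
    shared <- intersect(tab$line_id[tab$virus == traits[i]],
                        tab$line_id[tab$virus == traits[j]])
    if (length(shared) == 0L)
      stop("traits '", traits[i], "' and '", traits[j],
           "' share no lines; covariance inestimable")
  }
  lines <- sort(unique(tab$line_id))
  nl <- length(lines)
  li <- match(tab$line_id, lines)
  ti <- match(tab$virus, traits)
  kk <- tab$n_infected; nn <- tab$n_flies
  nv <- nrow(tab)
  nv_t <- tabulate(ti, Tt)
  ig <- .prior_ig(config)
  nu0 <- config$prior$nu + Tt
  S0 <- diag(if (config$improper) 1e-8 else config$prior$V, Tt)
  if (config$improper) nu0 <- Tt + 1e-3
  keep <- seq.int(config$burnin + config$thin, config$n_iter, by = config$thin)
  keep_it <- logical(config$n_iter); keep_it[keep] <- TRUE
  ll_binom <- function(eta, idx = NULL) {
    if (is.null(idx)) {
      kk * eta - nn * (pmax(eta, 0) + log1p(exp(-abs(eta))))
    } else {
      kk[idx] * eta - nn[idx] * (pmax(eta, 0) + log1p(exp(-abs(eta))))
    }
  }
  vials_of_trait <- lapply(seq_len(Tt), function(j) which(ti == j))
  all_sig <- list(); all_beta <- list(); all_vr <- list()
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    beta <- vapply(seq_len(Tt), function(j) {
      idx <- vials_of_trait[[j]]
      stats::qlogis((sum(kk[idx]) + 0.5) / (sum(nn[idx]) + 1))
    }, numeric(1))
    B <- matrix(0, nl, Tt)
    e <- numeric(nv)
    Sigma <- diag(1, Tt)
    Vr <- rep(1, Tt)
    step_B <- rep(0.5, Tt); step_e <- 0.8; step_beta <- rep(0.2, Tt)
    accB <- numeric(Tt); acce <- 0; accbeta <- numeric(Tt); batch <- 0L
    sig_out <- array(NA_real_, c(Tt, Tt, length(keep)))
    beta_out <- matrix(NA_real_, length(keep), Tt)
    vr_out <- matrix(NA_real_, length(keep), Tt)
    k <- 0L
    eta <- beta[ti] + B[cbind(li, ti)] + e
    for (it in seq_len(config$n_iter)) {
      # vial-level overdispersion
      e_new <- e + step_e * stats::rnorm(nv)
      d_ll <- ll_binom(eta + (e_new - e)) - ll_binom(eta) +
        (e^2 - e_new^2) / (2 * Vr[ti])
      a_e <- log(stats::runif(nv)) < d_ll
      e[a_e] <- e_new[a_e]
      eta <- beta[ti] + B[cbind(li, ti)] + e
      # line effects, one trait column at a time, conditioning on the others
      for (j in seq_len(Tt)) {
        if (Tt == 2L) {
          jo <- 3L - j
          s22inv <- 1 / Sigma[jo, jo]
          cmean <- B[, jo] * Sigma[j, jo] * s22inv
          cvar <- Sigma[j, j] - Sigma[j, jo]^2 * s22inv
        } else {
          s22inv <- solve(Sigma[-j, -j])
          w <- s22inv %*% Sigma[-j, j]
          cmean <- as.vector(B[, -j, drop = FALSE] %*% w)
          cvar <- Sigma[j, j] - sum(Sigma[j, -j] * w)
        }
        cvar <- max(cvar, 1e-12)
        delta <- step_B[j] * stats::rnorm(nl)
        idx <- vials_of_trait[[j]]
        lsub <- li[idx]
        d_lik <- rowsum(
          ll_binom(eta[idx] + delta[lsub], idx) - ll_binom(eta[idx], idx),
          lsub)[, 1L]
        d_full <- numeric(nl)
        d_full[sort(unique(lsub))] <- d_lik
        bj <- B[, j]; bj_new <- bj + delta
        d_prior <- ((bj - cmean)^2 - (bj_new - cmean)^2) / (2 * cvar)
        a_b <- log(stats::runif(nl)) < d_full + d_prior
        B[a_b, j] <- bj_new[a_b]
        accB[j] <- accB[j] + mean(a_b)
        eta <- beta[ti] + B[cbind(li, ti)] + e
        # trait mean
        bn <- beta[j] + step_beta[j] * stats::rnorm(1L)
        d_beta <- sum(ll_binom(eta[idx] + (bn - beta[j]), idx) -
                        ll_binom(eta[idx], idx))
        if (log(stats::runif(1L)) < d_beta) {
          beta[j] <- bn
          eta <- beta[ti] + B[cbind(li, ti)] + e
          accbeta[j] <- accbeta[j] + 1
        }
      }
      # covariance matrix: conjugate inverse-Wishart
      Sc <- S0 + crossprod(B)
      W <- stats::rWishart(1L, df = nu0 + nl, Sigma = solve(Sc))[, , 1L]
      Sigma <- solve(W)
      Sigma <- (Sigma + t(Sigma)) / 2
      # overdispersion variances
      for (j in seq_len(Tt)) {
        idx <- vials_of_trait[[j]]
        Vr[j] <- .rinvgamma1(ig["a0"] + length(idx) / 2,
                             ig["b0"] + sum(e[idx]^2) / 2)
      }
      acce <- acce + mean(a_e); batch <- batch + 1L
      if (it <= config$burnin && batch == 50L) {
        step_e <- .adapt_step(step_e, acce / 50, it / 50)
        for (j in seq_len(Tt)) {
          step_B[j] <- .adapt_step(step_B[j], accB[j] / 50, it / 50)
          step_beta[j] <- .adapt_step(step_beta[j], accbeta[j] / 50, it / 50)
        }
        accB[] <- 0; acce <- 0; accbeta[] <- 0; batch <- 0L
      }
      if (keep_it[it]) {
        k <- k + 1L
        sig_out[, , k] <- Sigma
        beta_out[k, ] <- beta
        vr_out[k, ] <- Vr
      }
    }
    all_sig[[ch]] <- sig_out; all_beta[[ch]] <- beta_out; all_vr[[ch]] <- vr_out
  }
  nk <- length(keep)
  Sigma_draws <- array(NA_real_, c(Tt, Tt, nk * config$n_chains),
                       dimnames = list(traits, traits, NULL))
  for (ch in seq_len(config$n_chains))
    Sigma_draws[, , (ch - 1L) * nk + seq_len(nk)] <- all_sig[[ch]]
  obj <- list(traits = traits,
              Sigma = Sigma_draws,
              beta = do.call(rbind, all_beta),
              V_r = do.call(rbind, all_vr),
              chain = rep(seq_len(config$n_chains), each = nk),
              config = config, n_lines = nl)
  class(obj) <- "gencov"
  obj
}

#' @export
print.gencov <- function(x, ...) {
  cat(sprintf("gencov fit: %d traits (%s), %d lines, %d draws\n",
              length(x$traits), paste(x$traits, collapse = ", "),
              x$n_lines, dim(x$Sigma)[3L]))
  cat("posterior mean line-effect covariance:\n")
  print(apply(x$Sigma, c(1, 2), mean), digits = 3)
  invisible(x)
}

#' Posterior genetic correlation between two traits
#'
#' Per-draw correlation `r = cov_ij / sqrt(cov_ii * cov_jj)` from the
#' line-effect covariance draws (the factor relating line variance to genetic
#' variance cancels in the ratio). The MCMC p-value is
#' `2 * min(P(r > 0), P(r < 0))` over the draws, floored at `2/n_draws`.
#'
#' @param gc a [fit_multivariate_binary()] result
#' @param trait_i,trait_j trait ids or indices
#' @return a `posterior_summary` with extra fields `p_value` and
#'   `n_excluded` (draws with a zero variance, for which r is undefined)
#' @export
genetic_correlation <- function(gc, trait_i, trait_j) {
  stopifnot(inherits(gc, "gencov"))
  i <- if (is.character(trait_i)) match(trait_i, gc$traits) else trait_i
  j <- if (is.character(trait_j)) match(trait_j, gc$traits) else trait_j
  if (is.na(i) || is.na(j)) stop("trait not in the fitted covariance matrix")
  vii <- gc$Sigma[i, i, ]; vjj <- gc$Sigma[j, j, ]; vij <- gc$Sigma[i, j, ]
  ok <- vii > 0 & vjj > 0
  r <- vij[ok] / sqrt(vii[ok] * vjj[ok])
  out <- posterior_summary(r, sprintf("r_g(%s, %s)", gc$traits[i], gc$traits[j]))
  p <- 2 * min(mean(r > 0), mean(r < 0))
  out$p_value <- max(p, 2 / length(r))
  out$n_excluded <- sum(!ok)
  out
}

#' MCMC p-value from a vector of posterior draws
#'
#' `2 * min(fraction of draws > 0, fraction of draws < 0)`.
#' @param draws numeric draws
#' @param floor_at lower bound (default `2/length(draws)`); set 0 to disable
#' @return the two-sided MCMC p-value
#' @export
mcmc_p_value <- function(draws, floor_at = 2 / length(draws)) {
  max(2 * min(mean(draws > 0), mean(draws < 0)), floor_at)
}
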