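#' MCMC configuration
#'
#' Settings for the Gibbs / Metropolis-within-Gibbs samplers used by the
#' variance-component fitters. The defaults (20,000 iterations, 5,000 burn-in,
#' thinning interval 10, two chains) are a scaled-down configuration suitable
#' for panels of one to a few hundred lines; increase `n_iter` for final
#' analyses.
#'
#' @param n_iter total iterations per chain (including burn-in)
#' @param burnin iterations discarded from the start of each chain
#' @param thin thinning interval applied after burn-in
#' @param n_chains number of independent chains
#' @param seed integer seed; chain c uses `seed + c - 1`
#' @param prior list with `nu` (prior degrees of freedom) and `V` (prior scale)
#'   for every variance component, parameterised as an inverse-gamma with
#'   shape `nu/2` and rate `nu*V/2`. The default `nu = 1, V = 1` is a weakly
#'   informative proper prior.
#' @param improper if `TRUE`, use the improper flat prior on variances
#'   (`nu = 0`); the posterior can be improper when a component has very few
#'   levels, which is why the proper prior is the default.
#' @return an object of class `mcmc_config`
#' @export
mcmc_config <- function(n_iter = 20000L, burnin = 5000L, thin = 10L,
                        n_chains = 2L, seed = 1L,
                        prior = list(nu = 1, V = 1), improper = FALSE) {
  stopifnot(n_iter > burnin, thin >= 1L, n_chains >= 1L)
  cfg <- list(n_iter = as.integer(n_iter), burnin = as.integer(burnin),
              thin = as.integer(thin), n_chains = as.integer(n_chains),
              seed = as.integer(seed), prior = prior,
              improper = isTRUE(improper))
  class(cfg) <- "mcmc_config"
  cfg
}

# inverse-gamma hyperparameters (shape a0, rate b0) implied by a config
.prior_ig <- function(config) {
  if (config$improper) return(c(a0 = 0, b0 = 0))
  nu <- config$prior$nu
  V <- config$prior$V
  c(a0 = nu / 2, b0 = nu * V / 2)
}

# draw from inverse-gamma(shape, rate) given sufficient statistics
.rinvgamma1 <- function(shape, rate) {
  1 / stats::rgamma(1L, shape = shape, rate = rate)
}

#' Highest posterior density interval
#'
#' Shortest interval containing a given posterior probability, computed from
#' the empirical draws (the convention used for all credible intervals in this
#' package).
#'
#' @param x numeric vector of posterior draws
#' @param prob coverage probability
#' @return numeric vector `c(lower, upper)`
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(unname(x[is.finite(x)]))
  n <- length(x)
  if (n == 0L) return(c(lower = NA_real_, upper = NA_real_))
  k <- max(1L, ceiling(prob * n) - 1L)   # window of k+1 points covers >= prob
  if (k >= n) return(c(lower = x[1L], upper = x[n]))
  widths <- x[(k + 1L):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k])
}

#' Effective sample size of an MCMC trace
#'
#' Geyer's initial positive sequence estimator: the integrated autocorrelation
#' time is estimated by summing consecutive pairs of autocorrelations until a
#' pair sum turns negative.
#'
#' @param x numeric vector of draws from a single chain
#' @return estimated effective sample size
#' @export
ess <- function(x) {
  n <- length(x)
  v <- stats::var(x)
  if (n < 4L || !is.finite(v) || v == 0) return(n)
  lag_max <- min(n - 2L, 1000L)
  rho <- stats::acf(x, lag.max = lag_max, plot = FALSE)$acf[-1L]
  npair <- floor(length(rho) / 2)
  tau <- 1
  for (m in seq_len(npair)) {
    s <- rho[2L * m - 1L] + rho[2L * m]
    if (s < 0) break
    tau <- tau + 2 * s
  }
  n / max(tau, 1)
}

# split-chain potential scale reduction factor; draws is iterations x chains
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  sub <- cbind(draws[1:half, , drop = FALSE],
               draws[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2L, stats::var)
  w <- mean(vars)
  b <- half * stats::var(means)
  if (w == 0) return(1)
  sqrt(((half - 1) / half * w + b / half) / w)
}

# posterior summary table for a draws matrix (rows = draws, cols = params),
# with a chain index for diagnostics
summarize_draws <- function(draws, chain) {
  params <- colnames(draws)
  out <- lapply(params, function(p) {
    x <- draws[, p]
    hpd <- hpd_interval(x)
    es <- sum(vapply(split(x, chain), ess, numeric(1)))
    rh <- if (length(unique(chain)) > 1L) {
      split_rhat(do.call(cbind, split(x, chain)))
    } else {
      NA_real_
    }
    data.frame(parameter = p, mean = mean(x), hpd_lower = hpd[["lower"]],
               hpd_upper = hpd[["upper"]], ess = es, rhat = rh)
  })
  do.call(rbind, out)
}

# adaptive random-walk step-size update (Robbins-Monro on the log scale,
# targeting the given acceptance rate); used only during burn-in
.adapt_step <- function(step, acc_rate, batch, target = 0.44) {
  step * exp((acc_rate - target) / sqrt(batch))
}
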