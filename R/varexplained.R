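#' Bias-corrected squared effect size
#'
#' The squared estimated effect overstates the true squared effect by its
#' sampling variance, so the unbiased estimate of `a^2` is `a_hat^2 - se^2`,
#' floored at zero (with a flag) when the correction exceeds the estimate.
#'
#' @param a_hat estimated half homozygote difference
#' @param se its standard error
#' @return the corrected `a^2`, with attribute `floored = TRUE` when negative
#'   before flooring
#' @export
unbiased_a2 <- function(a_hat, se) {
  stopifnot(se >= 0)
  a2 <- a_hat^2 - se^2
  floored <- a2 < 0
  structure(pmax(a2, 0), floored = floored)
}

#' Additive genetic variance contributed by a biallelic locus
#'
#' Under random mating and additivity, a locus with allele frequencies `p`
#' and `q = 1 - p` and genotypic values `+a` / `-a` for the two homozygotes
#' contributes `2 p q a^2` to the additive genetic variance.
#'
#' @param p,q allele frequencies (must sum to 1)
#' @param a2 squared effect (use [unbiased_a2()] for estimates)
#' @return `2 * p * q * a2`
#' @export
locus_additive_variance <- function(p, q, a2) {
  if (abs(p + q - 1) > 1e-8) stop("p + q must equal 1")
  if (any(a2 < 0)) stop("a2 must be >= 0")
  2 * p * q * a2
}

#' Proportion of heritability explained by a set of loci
#'
#' The ratio of the summed locus additive variances to the genetic variance.
#' Because heritability shares a denominator with `V_g`, adjusting the
#' numerator of the heritability formula by the locus variances yields the
#' same ratio. Summing over loci assumes linkage equilibrium between them; if
#' a genotype matrix is supplied, pairwise genotype correlations above 0.2
#' trigger a warning.
#'
#' @param va_loci numeric vector of per-locus additive variances
#' @param vg genetic variance `V_g` (a number, or a `varcomp` fit whose
#'   posterior-mean `V_g` is used)
#' @param genotypes optional lines x loci dosage matrix for the LD check
#' @return the explained fraction `sum(va_loci) / V_g`
#' @export
proportion_heritability <- function(va_loci, vg, genotypes = NULL) {
  if (inherits(vg, "varcomp")) vg <- mean(vg$draws$V_g)
  if (vg <= 0) stop("V_g must be positive")
  if (!is.null(genotypes) && ncol(genotypes) > 1L) {
    cors <- stats::cor(genotypes, use = "pairwise.complete.obs")
    off <- abs(cors[upper.tri(cors)])
    if (any(off > 0.2, na.rm = TRUE))
      warning("loci are in linkage disequilibrium (max |r| = ",
              signif(max(off, na.rm = TRUE), 2),
              "); summed variances may overstate the joint contribution")
  }
  sum(va_loci) / vg
}

#' Dominance scenario for outbred-population projections
#'
#' `d_ratio` expresses the dominance deviation `d` as a multiple of `a`
#' (+1: the allele with genotypic value `+a` is fully dominant; -1: fully
#' recessive; 0: additive). `frac_remaining_additive` is the fraction of the
#' non-focal genetic variance assumed to remain additive in the outbred
#' population.
#'
#' @param d_ratio dominance deviation as a multiple of `a`, in \[-1, 1\]
#' @param frac_remaining_additive fraction in \[0, 1\]
#' @return a `dominance_scenario` list
#' @export
dominance_scenario <- function(d_ratio = 0, frac_remaining_additive = 1) {
  if (abs(d_ratio) > 1) stop("d_ratio must be in [-1, 1]")
  if (frac_remaining_additive < 0 || frac_remaining_additive > 1)
    stop("frac_remaining_additive must be in [0, 1]")
  structure(list(d_ratio = d_ratio,
                 frac_remaining_additive = frac_remaining_additive),
            class = "dominance_scenario")
}

#' Project a locus's share of additive variance into an outbred population
#'
#' In an inbred panel a locus's contribution is estimated assuming additivity
#' (`2pqa^2`). In a random-mating population with dominance deviation
#' `d = d_ratio * a`, the average effect of an allele substitution is
#' `alpha = a * (1 + d_ratio * (q - p))` and the locus contributes
#' `2 p q alpha^2` to the outbred additive variance. The remaining (non-focal)
#' genetic variance `Vg_total - 2pqa^2` contributes only the fraction of it
#' assumed additive. The returned value is the locus share
#' `locus Va / (locus Va + remaining additive)`.
#'
#' @param p frequency of the allele with genotypic value `+a` (`q = 1 - p`)
#' @param twopqa2 the locus additive variance under additivity (`2pqa^2`)
#' @param vg_total total genetic variance on the same scale
#' @param scenario a [dominance_scenario()]
#' @return fraction of outbred additive variance attributable to the locus
#' @export
outbred_va_projection <- function(p, twopqa2, vg_total, scenario) {
  stopifnot(inherits(scenario, "dominance_scenario"))
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  if (twopqa2 > vg_total + 1e-12)
    stop("locus variance exceeds total genetic variance")
  q <- 1 - p
  locus_va <- twopqa2 * (1 + scenario$d_ratio * (q - p))^2
  remaining <- scenario$frac_remaining_additive * (vg_total - twopqa2)
  locus_va / (locus_va + remaining)
}

#' Assemble a locus-effect report from an association record
#'
#' Collects, for one associated site: the frequency of the resistant allele
#' among the genotyped lines (`p`, with `q = 1 - p`), the estimated half
#' homozygote difference and its standard error, the bias-corrected `a^2` and
#' the locus additive variance `2pqa^2`. Which homozygote class is resistant
#' is decided by the sign of `a_hat` together with the trait direction:
#' higher values mean more resistant for survival traits, less resistant for
#' infection proportions.
#'
#' @param assoc one row of a [scan_assoc()] or [joint_fit()] result
#' @param panel the panel the association was fitted on
#' @param direction `"higher"` if larger phenotype values mean more resistant
#'   (survival), `"lower"` for infection proportions
#' @return an object of class `locus_effect`
#' @export
effect_summary <- function(assoc, panel, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  site <- assoc$site_id
  g <- panel$geno[, site]
  g[g == GENO_CODES[["seg"]]] <- GENO_CODES[["missing"]]
  n_ref <- sum(g == 0L); n_alt <- sum(g == 2L)
  n_typed <- n_ref + n_alt
  a_hat <- assoc$a_hat
  se <- assoc$se
  # +1 coding is the alt homozygote: alt raises the value iff a_hat > 0
  alt_is_resistant <- if (direction == "higher") a_hat > 0 else a_hat < 0
  tie <- is.na(a_hat) || a_hat == 0
  if (tie) alt_is_resistant <- TRUE
  p <- if (alt_is_resistant) n_alt / n_typed else n_ref / n_typed
  a2 <- unbiased_a2(abs(a_hat), se)
  structure(list(site_id = site, p = p, q = 1 - p,
                 n_resistant_lines = if (alt_is_resistant) n_alt else n_ref,
                 n_typed_lines = n_typed,
                 a_hat = abs(a_hat), se = se,
                 a2_unbiased = as.numeric(a2),
                 a2_floored = attr(a2, "floored"),
                 va_locus = locus_additive_variance(p, 1 - p, as.numeric(a2)),
                 orientation_tie = tie),
            class = "locus_effect")
}

#' @export
print.locus_effect <- function(x, ...) {
  cat(sprintf("locus_effect %s: resistant allele in %d of %d lines (p = %.3f)\n",
              x$site_id, x$n_resistant_lines, x$n_typed_lines, x$p))
  cat(sprintf("  a_hat = %.3g (se %.3g), a2_unbiased = %.3g, Va = %.3g%s\n",
              x$a_hat, x$se, x$a2_unbiased, x$va_locus,
              if (x$orientation_tie) " [orientation tie]" else ""))
  invisible(x)
}

#' Brute-force additive variance at a biallelic locus under HWE
#'
#' Enumerates the three genotypes at Hardy-Weinberg frequencies
#' `(p^2, 2pq, q^2)` with genotypic values `(a, d, -a)` and computes the
#' additive genetic variance as the variance of the least-squares fitted
#' values from regressing genotypic value on allele count. Closed form:
#' `2pq (a + d(q-p))^2`. Exposed for use as an independent check on
#' [outbred_va_projection()].
#'
#' @param p frequency of the allele whose homozygote has value `+a`
#' @param a half the homozygote difference
#' @param d dominance deviation (heterozygote value)
#' @return the additive variance from the enumeration regression
#' @export
hwe_additive_variance <- function(p, a, d = 0) {
  q <- 1 - p
  freq <- c(p^2, 2 * p * q, q^2)
  count <- c(2, 1, 0)     # copies of the +a allele
  value <- c(a, d, -a)
  mu_x <- sum(freq * count)
  mu_y <- sum(freq * value)
  beta <- sum(freq * (count - mu_x) * (value - mu_y)) /
    sum(freq * (count - mu_x)^2)
  fitted <- mu_y + beta * (count - mu_x)
  sum(freq * (fitted - mu_y)^2)
}
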