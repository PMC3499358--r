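#' Collapse vial-level phenotypes to per-line susceptibility values
#'
#' Survival traits: the line value is the mean survival time across vials with
#' vials weighted by the number of flies in each (equivalently, the plain mean
#' over all flies of the line). Infection traits: the pooled proportion of
#' infected flies, optionally arcsine-square-root transformed to remove the
#' dependence of the variance on the mean.
#'
#' @param pheno a [phenotype_table()]
#' @param trait trait id (default: the only one present)
#' @param transform apply `asin(sqrt(p))` to infection proportions
#' @return a `line_values` data frame: `line_id`, `virus`, `value`,
#'   `weight` (total flies) and `n_vials`; lines with zero flies are dropped
#'   and listed in attribute `dropped`
#' @export
collapse_to_line_values <- function(pheno, trait = NULL, transform = FALSE) {
  d <- .subset_trait(pheno, trait)
  kind <- pheno_kind(pheno)
  if (kind == "survival") {
    val <- tapply(d$value, d$line_id, mean)  # flies are rows: vial weighting
    wt <- tapply(d$value, d$line_id, length)
    nv <- tapply(paste(d$line_id, d$vial_id), d$line_id,
                 function(v) length(unique(v)))
  } else {
    wt <- tapply(d$n_flies, d$line_id, sum)
    inf <- tapply(d$n_infected, d$line_id, sum)
    val <- ifelse(wt > 0, inf / wt, NA_real_)
    if (transform) val <- asin(sqrt(val))
    nv <- tapply(d$vial_id, d$line_id, function(v) length(unique(v)))
  }
  lines <- names(val)
  keep <- wt > 0
  dropped <- lines[!keep]
  if (length(dropped))
    message("dropping ", length(dropped), " line(s) with zero flies: ",
            paste(dropped, collapse = ", "))
  out <- data.frame(line_id = lines[keep], virus = d$virus[1L],
                    value = as.numeric(val[keep]),
                    weight = as.numeric(wt[keep]),
                    n_vials = as.integer(nv[keep]),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  attr(out, "transform") <- isTRUE(transform) && kind == "infection"
  class(out) <- c("line_values", "data.frame")
  out
}

#' Filter panel sites for association testing
#'
#' Within-line segregating calls are set to missing; sites are retained if
#' they remain biallelic among the non-missing lines and the minor allele
#' occurs in at least `min_minor_lines` lines.
#'
#' @param panel a [generate_panel()] / [read_genotypes()] result
#' @param min_minor_lines minimum number of lines carrying the minor allele
#' @return character vector of retained site ids, with a `counts` attribute
#'   (data frame of per-site reference/alternate line counts)
#' @export
filter_sites <- function(panel, min_minor_lines = 4L) {
  g <- panel$geno
  g[g == GENO_CODES[["seg"]]] <- GENO_CODES[["missing"]]
  n_ref <- colSums(g == 0L)
  n_alt <- colSums(g == 2L)
  keep <- pmin(n_ref, n_alt) >= min_minor_lines
  out <- colnames(g)[keep]
  attr(out, "counts") <- data.frame(site_id = colnames(g), n_ref = n_ref,
                                    n_alt = n_alt, retained = keep,
                                    row.names = NULL)
  out
}

# lines x sites matrix on the +/-1 coding (ref hom = -1, alt hom = +1),
# segregating and missing calls as NA
panel_dosage <- function(panel, sites = NULL) {
  g <- panel$geno
  if (!is.null(sites)) g <- g[, sites, drop = FALSE]
  d <- matrix(NA_real_, nrow(g), ncol(g), dimnames = dimnames(g))
  d[g == 0L] <- -1
  d[g == 2L] <- 1
  d
}

#' Line-mean association scan
#'
#' For each retained site, fits the least-squares regression of the line
#' susceptibility value on the site genotype (homozygotes coded -1/+1, so the
#' slope estimates `a`, half the difference between the homozygote classes),
#' optionally with the genotypes of known major-effect loci as additional
#' covariates (a conditional scan). Missing genotypes are dropped per site
#' (casewise); the F test is the partial test of the focal site.
#'
#' @param panel a line panel
#' @param linevals a [collapse_to_line_values()] result
#' @param sites sites to test (default [filter_sites()] with its defaults)
#' @param covariates character vector of covariate site ids (or `NULL`)
#' @return a `scan_result` data frame: `site_id, chrom, pos, n_lines, a_hat,
#'   se, F, p` (NA with a reason when a site is collinear with the covariates)
#' @export
scan_assoc <- function(panel, linevals, sites = NULL, covariates = NULL) {
  if (is.null(sites)) sites <- filter_sites(panel)
  sites <- setdiff(sites, covariates)
  idx <- match(linevals$line_id, panel$lines)
  if (anyNA(idx)) stop("phenotyped lines missing from panel: ",
                       paste(linevals$line_id[is.na(idx)], collapse = ", "))
  G <- panel_dosage(panel, sites)[idx, , drop = FALSE]
  y <- linevals$value
  if (is.null(covariates)) {
    res <- .scan_simple(G, y)
  } else {
    X_cov <- panel_dosage(panel, covariates)[idx, , drop = FALSE]
    res <- .scan_conditional(G, y, X_cov)
  }
  info <- panel$sites[match(sites, panel$sites$site_id), c("chrom", "pos")]
  out <- data.frame(site_id = sites, chrom = info$chrom, pos = info$pos,
                    res, row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "trait") <- linevals$virus[1L]
  attr(out, "covariates") <- covariates
  class(out) <- c("scan_result", "data.frame")
  out
}

# vectorized single-SNP regressions with per-site casewise deletion;
# g in {-1, +1, NA} so g^2 = 1 and the cross-products simplify
.scan_simple <- function(G, y) {
  M <- !is.na(G)
  G0 <- G; G0[!M] <- 0
  ok <- !is.na(y)
  M <- M & ok; G0[!ok, ] <- 0
  y0 <- ifelse(ok, y, 0)
  n <- colSums(M)
  Sg <- colSums(G0)
  Sy <- as.vector(crossprod(M, y0))
  Sgy <- as.vector(crossprod(G0, y0))
  Syy <- as.vector(crossprod(M, y0^2))
  Sxx <- n - Sg^2 / n
  Sxy <- Sgy - Sg * Sy / n
  Syy_c <- Syy - Sy^2 / n
  slope <- Sxy / Sxx
  df <- n - 2
  SSE <- pmax(Syy_c - Sxy^2 / Sxx, 0)
  s2 <- SSE / df
  Fstat <- (Sxy^2 / Sxx) / s2
  p <- stats::pf(Fstat, 1, df, lower.tail = FALSE)
  bad <- !is.finite(Sxx) | Sxx < 1e-10 | df < 1
  slope[bad] <- NA; Fstat[bad] <- NA; p[bad] <- NA
  se <- sqrt(s2 / Sxx); se[bad] <- NA
  reason <- ifelse(bad, "monomorphic_or_underdetermined", NA_character_)
  data.frame(n_lines = n, a_hat = slope, se = se, F = Fstat, p = p,
             reason = reason)
}

# per-site least squares with covariates; partial F test for the focal site
.scan_conditional <- function(G, y, X_cov) {
  n_sites <- ncol(G)
  out <- data.frame(n_lines = integer(n_sites), a_hat = NA_real_,
                    se = NA_real_, F = NA_real_, p = NA_real_,
                    reason = NA_character_)
  cov_ok <- stats::complete.cases(X_cov) & !is.na(y)
  for (s in seq_len(n_sites)) {
    use <- cov_ok & !is.na(G[, s])
    nn <- sum(use)
    out$n_lines[s] <- nn
    X1 <- cbind(1, X_cov[use, , drop = FALSE], g = G[use, s])
    k <- ncol(X1)
    if (nn <= k) { out$reason[s] <- "underdetermined"; next }
    q1 <- qr(X1)
    if (q1$rank < k) { out$reason[s] <- "collinear_with_covariates"; next }
    fit <- qr.coef(q1, y[use])
    res1 <- y[use] - X1 %*% fit
    rss1 <- sum(res1^2)
    q0 <- qr(X1[, -k, drop = FALSE])
    res0 <- qr.resid(q0, y[use])
    rss0 <- sum(res0^2)
    df <- nn - k
    Fs <- (rss0 - rss1) / (rss1 / df)
    R <- qr.R(q1)
    xtx_inv_gg <- chol2inv(R)[k, k]
    out$a_hat[s] <- fit[k]
    out$se[s] <- sqrt(rss1 / df * xtx_inv_gg)
    out$F[s] <- Fs
    out$p[s] <- stats::pf(Fs, 1, df, lower.tail = FALSE)
  }
  out
}

#' Permutation null distribution of the genome-wide minimum p-value
#'
#' Phenotype values are permuted across lines, the full scan rerun, and the
#' genome-wide minimum p-value recorded; the empirical alpha-quantile of the
#' resulting null distribution is the genome-wide significance threshold
#' controlling family-wise error at alpha. Covariate genotypes (conditional
#' scans) stay attached to their lines; only the phenotype vector is shuffled.
#'
#' @inheritParams scan_assoc
#' @param n_perm number of permutations
#' @param alpha significance levels for which thresholds are reported
#' @param seed integer seed for the permutation stream
#' @param keep_scans keep every permutation's full vector of sorted
#'   -log10 p-values (needed by [qq_curve()])
#' @return an object of class `perm_null`: `min_p` (one per permutation),
#'   `thresholds` (named by alpha), and optionally `neglogp` (sites x perms)
#' @export
permute_threshold <- function(panel, linevals, sites = NULL,
                              covariates = NULL, n_perm = 400L,
                              alpha = c(0.05, 0.2), seed = 1L,
                              keep_scans = FALSE) {
  if (n_perm < 20L) warning("fewer than 20 permutations: thresholds unstable")
  if (is.null(sites)) sites <- filter_sites(panel)
  sites <- setdiff(sites, covariates)
  idx <- match(linevals$line_id, panel$lines)
  G <- panel_dosage(panel, sites)[idx, , drop = FALSE]
  X_cov <- if (is.null(covariates)) NULL else
    panel_dosage(panel, covariates)[idx, , drop = FALSE]
  y <- linevals$value
  nl <- length(y)
  set.seed(seed)
  min_p <- numeric(n_perm)
  neglogp <- if (keep_scans) matrix(NA_real_, ncol(G), n_perm) else NULL
  for (b in seq_len(n_perm)) {
    yp <- y[sample.int(nl)]
    p <- if (is.null(X_cov)) .scan_simple(G, yp)$p else
      .scan_conditional(G, yp, X_cov)$p
    min_p[b] <- min(p, na.rm = TRUE)
    if (keep_scans) neglogp[, b] <- sort(-log10(p), decreasing = TRUE,
                                         na.last = TRUE)
  }
  thresholds <- stats::quantile(min_p, alpha, type = 7, names = FALSE)
  obj <- list(min_p = min_p, n_perm = n_perm, seed = seed,
              alpha = alpha, thresholds = stats::setNames(thresholds,
                                                          paste0("alpha_", alpha)),
              neglogp = neglogp)
  class(obj) <- "perm_null"
  obj
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf("perm_null: %d permutations (seed %d)\n", x$n_perm, x$seed))
  for (i in seq_along(x$alpha))
    cat(sprintf("  threshold(alpha = %.3g) = %.3g\n", x$alpha[i],
                x$thresholds[i]))
  invisible(x)
}

#' Genome-wide significance threshold at a given level
#' @param null a [permute_threshold()] result
#' @param alpha significance level
#' @return the empirical alpha-quantile of the null minimum p-values
#' @export
threshold_at <- function(null, alpha) {
  stats::quantile(null$min_p, alpha, type = 7, names = FALSE)
}

#' Observed-vs-permutation QQ table
#'
#' Pairs the k-th order statistic of the observed -log10 p-values with the
#' mean k-th order statistic across the permutation scans, the permutation
#' analogue of the uniform QQ expectation.
#'
#' @param scan a [scan_assoc()] result
#' @param null a [permute_threshold()] result fitted with `keep_scans = TRUE`
#' @return data frame with `expected` and `observed` -log10 p columns,
#'   ordered from the most significant site down
#' @export
qq_curve <- function(scan, null) {
  if (is.null(null$neglogp))
    stop("permutation null was built without keep_scans = TRUE")
  obs <- sort(-log10(scan$p[!is.na(scan$p)]), decreasing = TRUE)
  expd <- rowMeans(null$neglogp, na.rm = TRUE)
  k <- min(length(obs), length(expd))
  data.frame(expected = expd[seq_len(k)], observed = obs[seq_len(k)])
}

#' Joint multi-SNP fit: marginal p-values
#'
#' Fits the line values on all listed sites simultaneously and reports each
#' site's marginal significance (its partial F test controlling for all the
#' others), used to disentangle associated sites in linkage disequilibrium.
#' Lines missing a genotype at any listed site are excluded listwise.
#' Collinear (perfectly correlated) sites are reported as aliased rather than
#' given p-values.
#'
#' @param panel a line panel
#' @param linevals a [collapse_to_line_values()] result
#' @param sites character vector of site ids to fit jointly
#' @return data frame `site_id, a_hat, se, F, df2, p, aliased`
#' @export
joint_fit <- function(panel, linevals, sites) {
  d <- .joint_data(panel, linevals, sites)
  if (length(sites) > nrow(d$X) - 2L)
    stop("more sites than lines - 2 after listwise deletion")
  fit <- stats::lm(d$y ~ ., data = as.data.frame(d$X))
  aliased <- is.na(stats::coef(fit))[-1L]
  if (any(aliased)) {
    warning("aliased (perfectly correlated) sites dropped from the joint fit: ",
            paste(sites[aliased], collapse = ", "))
    # marginal tests are only defined in the full-rank model
    fit <- stats::lm(d$y ~ ., data = as.data.frame(d$X[, !aliased,
                                                       drop = FALSE]))
  }
  dr <- stats::drop1(fit, test = "F")
  sm <- summary(fit)$coefficients
  out <- data.frame(site_id = sites, a_hat = NA_real_, se = NA_real_,
                    F = NA_real_, df2 = stats::df.residual(fit), p = NA_real_,
                    aliased = aliased, row.names = NULL)
  for (i in seq_along(sites)) {
    term <- colnames(d$X)[i]
    if (aliased[i]) next
    out$a_hat[i] <- sm[term, "Estimate"]
    out$se[i] <- sm[term, "Std. Error"]
    j <- match(term, rownames(dr))
    out$F[i] <- dr[j, "F value"]
    out$p[i] <- dr[j, "Pr(>F)"]
  }
  attr(out, "n_lines") <- nrow(d$X)
  out
}

#' Sequential (ANOVA-table) p-values for an ordered set of sites
#'
#' Adds sites to the model in the given order and reports the sequential
#' F tests from the ANOVA table, i.e. each site's significance controlling
#' only for the sites that precede it.
#'
#' @inheritParams joint_fit
#' @param sites sites in the order they should enter the model
#' @return data frame `site_id, F, df2, p, aliased`
#' @export
sequential_fit <- function(panel, linevals, sites) {
  d <- .joint_data(panel, linevals, sites)
  fit <- stats::lm(d$y ~ ., data = as.data.frame(d$X))
  aliased <- is.na(stats::coef(fit))[-1L]
  an <- stats::anova(fit)
  out <- data.frame(site_id = sites, F = NA_real_,
                    df2 = stats::df.residual(fit), p = NA_real_,
                    aliased = aliased, row.names = NULL)
  for (i in seq_along(sites)) {
    if (aliased[i]) next
    term <- colnames(d$X)[i]
    j <- match(term, rownames(an))
    out$F[i] <- an[j, "F value"]
    out$p[i] <- an[j, "Pr(>F)"]
  }
  out
}

.joint_data <- function(panel, linevals, sites) {
  idx <- match(linevals$line_id, panel$lines)
  G <- panel_dosage(panel, sites)[idx, , drop = FALSE]
  colnames(G) <- make.names(sites)
  use <- stats::complete.cases(G) & !is.na(linevals$value)
  if (sum(use) < length(sites) + 2L)
    stop("too few fully genotyped lines for a joint fit")
  list(X = G[use, , drop = FALSE], y = linevals$value[use])
}
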