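#' Specification of a synthetic inbred-line genotype panel
#'
#' Describes a DGRP-like panel of fully homozygous lines genotyped at biallelic
#' SNPs. Sites are laid out on named chromosome arms; minor-allele frequencies
#' are drawn from a beta law; linkage disequilibrium is generated by a
#' first-order Markov copying process in which each site copies the previous
#' site's line-assignment pattern with probability `ld_copy_prob`, giving
#' monotone LD decay with distance. A fraction of calls are masked as missing
#' and a fraction are flagged as segregating within a line (inbred lines are
#' not perfectly homozygous); segregating calls are treated as missing by all
#' downstream analyses.
#'
#' @param n_lines number of homozygous lines (>= 2)
#' @param n_sites total number of sites; ignored when `chrom_lengths` is given
#' @param chrom_lengths named integer vector, chromosome arm -> site count;
#'   default splits `n_sites` across arms 2L, 2R, 3L, 3R and X
#' @param maf_law two shape parameters of the beta law for minor-allele
#'   frequencies; the draw is folded onto (0, 0.5]
#' @param ld_copy_prob probability in \[0,1\] that a site copies the previous
#'   site's line-assignment pattern
#' @param missing_rate fraction of calls masked as missing, in \[0,1)
#' @param het_rate fraction of calls flagged as within-line segregating, in \[0,1)
#' @param seed integer seed making the panel reproducible
#' @return an object of class `panel_spec`
#' @export
panel_spec <- function(n_lines = 185L, n_sites = 2000L, chrom_lengths = NULL,
                       maf_law = c(1, 3), ld_copy_prob = 0.8,
                       missing_rate = 0.03, het_rate = 0.01, seed = 1L) {
  if (n_lines < 2L) stop("n_lines must be >= 2 (no between-line variance otherwise)")
  if (is.null(chrom_lengths)) {
    arms <- c("2L", "2R", "3L", "3R", "X")
    base <- n_sites %/% 5L
    chrom_lengths <- stats::setNames(rep(base, 5L), arms)
    chrom_lengths[1L] <- chrom_lengths[1L] + n_sites - 5L * base
  }
  chrom_lengths <- chrom_lengths[chrom_lengths > 0L]
  if (sum(chrom_lengths) < 1L) stop("need at least one site")
  rates <- c(missing_rate, het_rate)
  if (any(rates < 0 | rates >= 1)) stop("rates must be in [0, 1)")
  if (missing_rate + het_rate >= 1) stop("missing_rate + het_rate must be < 1")
  if (ld_copy_prob < 0 || ld_copy_prob > 1) stop("ld_copy_prob must be in [0, 1]")
  if (length(maf_law) != 2L || any(maf_law <= 0)) stop("maf_law must be two positive shapes")
  structure(list(n_lines = as.integer(n_lines),
                 chrom_lengths = as.integer(round(chrom_lengths)) |>
                   stats::setNames(names(chrom_lengths)),
                 maf_law = as.numeric(maf_law),
                 ld_copy_prob = as.numeric(ld_copy_prob),
                 missing_rate = as.numeric(missing_rate),
                 het_rate = as.numeric(het_rate),
                 seed = as.integer(seed)),
            class = "panel_spec")
}

# genotype codes used throughout: homozygous reference = 0, homozygous
# alternate = 2, missing = -1, within-line segregating = 1 (mapped to missing
# by every downstream analysis)
GENO_CODES <- c(ref = 0L, seg = 1L, alt = 2L, missing = -1L)

#' Generate a synthetic line-by-site genotype panel
#'
#' @param spec a [panel_spec()]
#' @return an object of class `line_panel`: a list with `geno` (integer matrix,
#'   lines x sites, codes 0/2/-1/1), `sites` (data frame with `site_id`,
#'   `chrom`, `pos`, `ref`, `alt`), `lines` (line ids), and the complete
#'   pre-masking truth matrix in `geno_true` (used by the trait simulators).
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  set.seed(spec$seed)
  n <- spec$n_lines
  arms <- names(spec$chrom_lengths)
  cols <- list(); site_rows <- list()
  for (arm in arms) {
    m <- spec$chrom_lengths[[arm]]
    pos <- cumsum(sample.int(2000L, m, replace = TRUE) + 50L)
    maf <- 0.5 * stats::rbeta(m, spec$maf_law[1L], spec$maf_law[2L])
    g <- matrix(0L, nrow = n, ncol = m)
    for (s in seq_len(m)) {
      if (s > 1L && stats::runif(1L) < spec$ld_copy_prob) {
        g[, s] <- g[, s - 1L]
      } else {
        g[, s] <- 2L * stats::rbinom(n, 1L, maf[s])
      }
    }
    alleles <- vapply(seq_len(m), function(s) {
      sample(c("A", "C", "G", "T"), 2L)
    }, character(2L))
    cols[[arm]] <- g
    site_rows[[arm]] <- data.frame(
      site_id = paste0(arm, ":", pos), chrom = arm, pos = pos,
      ref = alleles[1L, ], alt = alleles[2L, ], stringsAsFactors = FALSE)
  }
  geno_true <- do.call(cbind, cols)
  sites <- do.call(rbind, site_rows)
  rownames(sites) <- NULL
  # overlay the observation process: disjoint missing / segregating masks
  u <- matrix(stats::runif(length(geno_true)), nrow = nrow(geno_true))
  geno <- geno_true
  geno[u < spec$missing_rate] <- GENO_CODES[["missing"]]
  seg <- u >= spec$missing_rate & u < spec$missing_rate + spec$het_rate
  geno[seg] <- GENO_CODES[["seg"]]
  lines <- sprintf("line_%03d", seq_len(n))
  dimnames(geno) <- dimnames(geno_true) <- list(lines, sites$site_id)
  structure(list(geno = geno, sites = sites, lines = lines,
                 geno_true = geno_true, spec = spec),
            class = "line_panel")
}

#' @export
print.line_panel <- function(x, ...) {
  cat(sprintf("line_panel: %d lines x %d sites on %d chromosome arms\n",
              length(x$lines), nrow(x$sites), length(unique(x$sites$chrom))))
  frac <- function(code) mean(x$geno == code)
  cat(sprintf("  missing %.1f%%, within-line segregating %.1f%%\n",
              100 * frac(GENO_CODES[["missing"]]), 100 * frac(GENO_CODES[["seg"]])))
  invisible(x)
}

#' Define the generative genetic model for trait simulation
#'
#' A trait lives on one of two scales: `"survival"` (days after infection,
#' Gaussian with a nested line/vial/fly structure) or `"infection"` (logit of
#' the per-vial infection probability, with line effects and vial-level
#' overdispersion). Causal loci act additively on the trait scale: homozygous
#' alternate lines deviate by `+a` and homozygous reference lines by `-a`, so
#' `a` is half the difference between the two homozygotes. `d_ratio` (the
#' dominance deviation as a multiple of `a`) is carried along for
#' outbred-population projections only; homozygous lines never express it.
#'
#' @param traits named list, trait id -> list with `scale` ("survival" or
#'   "infection"), `beta` (trait mean on its scale), `V_line_poly` (polygenic
#'   between-line variance), and `V_vial`, `V_r` (survival) or `V_od`
#'   (infection overdispersion)
#' @param causal_loci data frame with columns `site_id`, `trait`, `a`, and
#'   optionally `d_ratio` (default 0)
#' @return an object of class `genetic_model`
#' @export
genetic_model <- function(traits, causal_loci = NULL) {
  if (is.null(causal_loci)) {
    causal_loci <- data.frame(site_id = character(), trait = character(),
                              a = numeric(), d_ratio = numeric())
  }
  if (is.null(causal_loci$d_ratio)) causal_loci$d_ratio <- 0
  for (id in names(traits)) {
    tr <- traits[[id]]
    if (!tr$scale %in% c("survival", "infection"))
      stop("trait scale must be 'survival' or 'infection'")
    vs <- unlist(tr[grep("^V_", names(tr))])
    if (any(vs < 0)) stop("variances must be >= 0")
  }
  structure(list(traits = traits, causal_loci = causal_loci),
            class = "genetic_model")
}

# per-line causal genetic value for one trait, from the true genotypes
.causal_values <- function(panel, model, trait) {
  loci <- model$causal_loci[model$causal_loci$trait == trait, , drop = FALSE]
  g <- numeric(length(panel$lines))
  for (r in seq_len(nrow(loci))) {
    sid <- loci$site_id[r]
    if (!sid %in% colnames(panel$geno_true))
      stop("causal site not in panel: ", sid)
    g <- g + loci$a[r] * (panel$geno_true[, sid] - 1L)  # 0 -> -a, 2 -> +a
  }
  g
}

#' Simulate a Gaussian survival trait on a line panel
#'
#' Per-fly survival is `beta` + causal genotypic value + polygenic line
#' deviation + vial deviation + residual, with all deviations Gaussian. By
#' default survival is continuous; `round_days = TRUE` reports nonnegative
#' whole days (observation every 24 h).
#'
#' @param panel a [generate_panel()] result
#' @param model a [genetic_model()] with a `"survival"`-scale trait
#' @param trait trait id within the model (default: the first survival trait)
#' @param n_vials vials per line
#' @param n_flies flies per vial (scalar, or vector recycled over vials)
#' @param seed integer seed
#' @param round_days report whole nonnegative days instead of continuous values
#' @return list with `pheno` (a per-fly `phenotype_table`) and `truth`
#'   (a `truth_manifest` recording the model, design, seed and realized
#'   per-line genetic values)
#' @export
simulate_gaussian_trait <- function(panel, model, trait = NULL, n_vials = 4L,
                                    n_flies = 15L, seed = 1L,
                                    round_days = FALSE) {
  trait <- .pick_trait(model, trait, "survival")
  tr <- model$traits[[trait]]
  set.seed(seed)
  nl <- length(panel$lines)
  causal <- .causal_values(panel, model, trait)
  b <- stats::rnorm(nl, 0, sqrt(tr$V_line_poly))
  gvals <- causal + b
  flies <- rep_len(as.integer(n_flies), nl * n_vials)
  line_of_vial <- rep(seq_len(nl), each = n_vials)
  c_vial <- stats::rnorm(nl * n_vials, 0, sqrt(tr$V_vial))
  rows <- lapply(seq_along(line_of_vial), function(v) {
    i <- line_of_vial[v]
    nf <- flies[v]
    y <- tr$beta + gvals[i] + c_vial[v] + stats::rnorm(nf, 0, sqrt(tr$V_r))
    data.frame(line_id = panel$lines[i], virus = trait,
               vial_id = sprintf("%s_v%02d", panel$lines[i],
                                 ((v - 1L) %% n_vials) + 1L),
               fly_id = seq_len(nf), value = y, stringsAsFactors = FALSE)
  })
  pheno <- do.call(rbind, rows)
  if (round_days) pheno$value <- pmax(round(pheno$value), 0)
  pheno <- phenotype_table(pheno, kind = "survival")
  truth <- truth_manifest(model, trait = trait, seed = seed,
                          design = list(n_vials = n_vials, n_flies = n_flies),
                          line_values = stats::setNames(gvals, panel$lines))
  list(pheno = pheno, truth = truth)
}

#' Simulate a binomial infection trait on a line panel
#'
#' Per-vial infected counts are binomial with a logit-linear probability:
#' `logit(p) = beta + causal + line deviation + vial overdispersion`.
#'
#' @inheritParams simulate_gaussian_trait
#' @return list with `pheno` (a per-vial count `phenotype_table`) and `truth`
#' @export
simulate_binomial_trait <- function(panel, model, trait = NULL, n_vials = 4L,
                                    n_flies = 15L, seed = 1L) {
  trait <- .pick_trait(model, trait, "infection")
  tr <- model$traits[[trait]]
  set.seed(seed)
  nl <- length(panel$lines)
  gvals <- .causal_values(panel, model, trait) +
    stats::rnorm(nl, 0, sqrt(tr$V_line_poly))
  flies <- rep_len(as.integer(n_flies), nl * n_vials)
  line_of_vial <- rep(seq_len(nl), each = n_vials)
  eta <- tr$beta + gvals[line_of_vial] +
    stats::rnorm(nl * n_vials, 0, sqrt(tr$V_od))
  n_inf <- stats::rbinom(nl * n_vials, flies, stats::plogis(eta))
  pheno <- data.frame(
    line_id = panel$lines[line_of_vial], virus = trait,
    vial_id = sprintf("%s_v%02d", panel$lines[line_of_vial],
                      rep(seq_len(n_vials), times = nl)),
    n_flies = flies, n_infected = n_inf, stringsAsFactors = FALSE)
  pheno <- phenotype_table(pheno, kind = "infection")
  truth <- truth_manifest(model, trait = trait, seed = seed,
                          design = list(n_vials = n_vials, n_flies = n_flies),
                          line_values = stats::setNames(gvals, panel$lines))
  list(pheno = pheno, truth = truth)
}

.pick_trait <- function(model, trait, scale) {
  if (is.null(trait)) {
    ids <- names(model$traits)[vapply(model$traits,
                                      function(t) t$scale == scale, logical(1))]
    if (length(ids) == 0L) stop("model has no ", scale, "-scale trait")
    trait <- ids[1L]
  }
  if (model$traits[[trait]]$scale != scale)
    stop("trait '", trait, "' is not on the ", scale, " scale")
  trait
}

#' Vial-structured phenotype table
#'
#' Validating constructor. Survival tables are per-fly
#' (`line_id, virus, vial_id, fly_id, value`); infection tables are per-vial
#' counts (`line_id, virus, vial_id, n_flies, n_infected`).
#'
#' @param df a data frame in one of the two schemas
#' @param kind `"survival"` or `"infection"`
#' @return `df` with class `phenotype_table` and attribute `kind`
#' @export
phenotype_table <- function(df, kind = c("survival", "infection")) {
  kind <- match.arg(kind)
  need <- if (kind == "survival") {
    c("line_id", "virus", "vial_id", "fly_id", "value")
  } else {
    c("line_id", "virus", "vial_id", "n_flies", "n_infected")
  }
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("phenotype table missing columns: ",
                         paste(miss, collapse = ", "))
  if (kind == "infection") {
    if (any(df$n_infected < 0) || any(df$n_flies < 0))
      stop("counts must be >= 0")
    if (any(df$n_infected > df$n_flies))
      stop("n_infected exceeds n_flies in some vial")
  }
  # vial ids are scoped within (line, trait): analyses key vials as
  # line_id x vial_id, so the same label may recur across lines
  structure(df, class = c("phenotype_table", "data.frame"), kind = kind)
}

pheno_kind <- function(pheno) attr(pheno, "kind")

#' Truth manifest for a simulated trait
#'
#' Records everything needed to score recovery: the generative model, the
#' design, the seed, and the realized per-line genetic values.
#' @param model a [genetic_model()]
#' @param trait simulated trait id
#' @param seed simulation seed
#' @param design list with `n_vials`, `n_flies`
#' @param line_values named numeric vector of realized line genetic values
#' @return object of class `truth_manifest`
#' @export
truth_manifest <- function(model, trait, seed, design, line_values) {
  structure(list(model = model, trait = trait, seed = seed, design = design,
                 line_values = line_values),
            class = "truth_manifest")
}
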