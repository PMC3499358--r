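#' Pipeline run configuration
#'
#' A flat, file-round-trippable configuration for the end-to-end driver
#' [run_pipeline()]: simulate (or load) a panel and phenotypes, estimate
#' variance components, run the permutation-thresholded association scan, and
#' convert the top locus into variance explained. When `genotype_tsv` /
#' `phenotype_csv` are set, those files are loaded instead of simulating.
#'
#' @param n_lines,n_sites panel dimensions (simulation)
#' @param ld_copy_prob,maf_shape1,maf_shape2,missing_rate,het_rate panel
#'   generation parameters, see [panel_spec()]
#' @param trait_name,trait_scale trait id and scale ("survival"/"infection")
#' @param beta,V_line_poly,V_vial,V_r,V_od generative trait parameters
#' @param causal_site_index site column index of the planted causal locus
#'   (0 = none); `causal_a` its effect size
#' @param n_vials,n_flies phenotyping design
#' @param transform arcsine-square-root transform for infection line values
#' @param min_minor_lines site filter threshold
#' @param n_perm,alpha permutation settings
#' @param mcmc_n_iter,mcmc_burnin,mcmc_thin,mcmc_chains MCMC settings
#' @param seed master seed (stage seeds are derived from it)
#' @param out_dir output directory
#' @param genotype_tsv,phenotype_csv optional input paths ("" = simulate)
#' @return an object of class `run_config`
#' @export
run_config <- function(n_lines = 100L, n_sites = 500L, ld_copy_prob = 0.8,
                       maf_shape1 = 1, maf_shape2 = 3, missing_rate = 0.03,
                       het_rate = 0.01, trait_name = "virus1",
                       trait_scale = "survival", beta = 10, V_line_poly = 1,
                       V_vial = 0.5, V_r = 2, V_od = 1,
                       causal_site_index = 0L, causal_a = 0, n_vials = 4L,
                       n_flies = 15L, transform = FALSE,
                       min_minor_lines = 4L, n_perm = 100L, alpha = 0.05,
                       mcmc_n_iter = 6000L, mcmc_burnin = 1000L,
                       mcmc_thin = 5L, mcmc_chains = 2L, seed = 1L,
                       out_dir = "viroquant_run", genotype_tsv = "",
                       phenotype_csv = "") {
  cfg <- as.list(environment())
  int_fields <- c("n_lines", "n_sites", "causal_site_index", "n_vials",
                  "n_flies", "min_minor_lines", "n_perm", "mcmc_n_iter",
                  "mcmc_burnin", "mcmc_thin", "mcmc_chains", "seed")
  for (f in int_fields) cfg[[f]] <- as.integer(cfg[[f]])
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration as flat `key = value` text
#' @param config a [run_config()]
#' @param path file path
#' @export
write_config <- function(config, path) {
  fmt <- function(v) {
    if (is.character(v)) v
    else if (is.logical(v)) as.character(v)
    else sprintf("%.17g", v)
  }
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, fmt, character(1))), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  if (any(!grepl("=", ln, fixed = TRUE)))
    stop("malformed config line: ", ln[!grepl("=", ln, fixed = TRUE)][1L])
  keys <- trimws(sub("=.*$", "", ln))
  vals <- trimws(sub("^[^=]*=", "", ln))
  proto <- run_config()
  cfg <- proto
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (!k %in% names(proto)) stop("unknown config key: ", k)
    v <- vals[i]
    cfg[[k]] <- if (is.character(proto[[k]])) v
    else if (is.logical(proto[[k]])) as.logical(v)
    else if (is.integer(proto[[k]])) as.integer(round(as.numeric(v)))
    else as.numeric(v)
  }
  class(cfg) <- "run_config"
  cfg
}

.stamp <- function(seed, hash) sprintf("# viroquant seed=%d config_md5=%s", seed, hash)

.write_stamped_tsv <- function(df, path, stamp) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(stamp, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full simulate/estimate/scan/explain pipeline
#'
#' Executes the stages in order, writing every intermediate artifact into
#' `config$out_dir` plus a machine-readable JSON run log with versions, stage
#' seeds, and line/site/vial counts at each stage. Any stage failure aborts
#' with the stage name; artifacts already written are preserved.
#'
#' @param config a [run_config()]
#' @return invisibly, a list with the in-memory results of each stage and the
#'   run log
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(config$out_dir, "config.txt")
  write_config(config, cfg_path)
  hash <- unname(tools::md5sum(cfg_path))
  log <- list(package = "viroquant",
              version = as.character(utils::packageVersion("viroquant")),
              r_version = R.version.string, seed = config$seed,
              config_md5 = hash, stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  stamp <- .stamp(config$seed, hash)
  out <- list(config = config)

  # ---- stage 1: data (simulate or load) -------------------------------
  gaussian <- config$trait_scale == "survival"
  out$data <- stage("data", {
    if (nzchar(config$genotype_tsv)) {
      panel <- read_genotypes(config$genotype_tsv, "tsv")
      pheno <- read_phenotype_csv(config$phenotype_csv)
      truth <- NULL
    } else {
      spec <- panel_spec(n_lines = config$n_lines, n_sites = config$n_sites,
                         maf_law = c(config$maf_shape1, config$maf_shape2),
                         ld_copy_prob = config$ld_copy_prob,
                         missing_rate = config$missing_rate,
                         het_rate = config$het_rate, seed = config$seed)
      panel <- generate_panel(spec)
      causal <- if (config$causal_site_index > 0L) {
        data.frame(site_id = colnames(panel$geno)[config$causal_site_index],
                   trait = config$trait_name, a = config$causal_a,
                   d_ratio = 0)
      } else NULL
      tr <- if (gaussian) {
        list(scale = "survival", beta = config$beta,
             V_line_poly = config$V_line_poly, V_vial = config$V_vial,
             V_r = config$V_r)
      } else {
        list(scale = "infection", beta = config$beta,
             V_line_poly = config$V_line_poly, V_od = config$V_od)
      }
      model <- genetic_model(stats::setNames(list(tr), config$trait_name),
                             causal)
      sim <- if (gaussian) {
        simulate_gaussian_trait(panel, model, n_vials = config$n_vials,
                                n_flies = config$n_flies,
                                seed = config$seed + 1L)
      } else {
        simulate_binomial_trait(panel, model, n_vials = config$n_vials,
                                n_flies = config$n_flies,
                                seed = config$seed + 1L)
      }
      write_genotype_tsv(panel, file.path(config$out_dir, "panel.tsv"))
      write_vcf(panel, file.path(config$out_dir, "panel.vcf"))
      con <- file(file.path(config$out_dir, "pheno.csv"), "w")
      writeLines(stamp, con)
      utils::write.table(as.data.frame(sim$pheno), con, sep = ",",
                         quote = FALSE, row.names = FALSE)
      close(con)
      write_truth(sim$truth, file.path(config$out_dir, "truth.txt"))
      pheno <- sim$pheno
      truth <- sim$truth
    }
    list(panel = panel, pheno = pheno, truth = truth)
  })
  panel <- out$data$panel; pheno <- out$data$pheno
  log$stages$data <- list(
    n_lines = length(panel$lines), n_sites = nrow(panel$sites),
    n_vials = length(unique(paste(pheno$line_id, pheno$vial_id))),
    n_records = nrow(pheno), seed = config$seed)

  # ---- stage 2: variance components -----------------------------------
  out$varcomp <- stage("varcomp", {
    mc <- mcmc_config(n_iter = config$mcmc_n_iter,
                      burnin = config$mcmc_burnin, thin = config$mcmc_thin,
                      n_chains = config$mcmc_chains, seed = config$seed + 2L)
    vc <- if (gaussian) fit_gaussian_nested(pheno, config = mc)
    else fit_binomial_logit(pheno, config = mc)
    h2 <- heritability(vc)
    extra <- data.frame(parameter = "h2", mean = h2$mean,
                        hpd_lower = h2$hpd[["lower"]],
                        hpd_upper = h2$hpd[["upper"]],
                        ess = NA_real_, rhat = NA_real_)
    .write_stamped_tsv(rbind(vc$summary, extra),
                       file.path(config$out_dir, "components.tsv"), stamp)
    vc
  })
  log$stages$varcomp <- list(scale = out$varcomp$scale,
                             seed = config$seed + 2L,
                             n_draws = nrow(out$varcomp$draws))

  # ---- stage 3: GWAS ---------------------------------------------------
  out$gwas <- stage("gwas", {
    lv <- collapse_to_line_values(pheno, transform = config$transform)
    sites <- filter_sites(panel, config$min_minor_lines)
    scan <- scan_assoc(panel, lv, sites)
    null <- permute_threshold(panel, lv, sites, n_perm = config$n_perm,
                              alpha = c(config$alpha, 0.2),
                              seed = config$seed + 3L, keep_scans = TRUE)
    qq <- qq_curve(scan, null)
    .write_stamped_tsv(as.data.frame(scan),
                       file.path(config$out_dir, "scan.tsv"), stamp)
    .write_stamped_tsv(data.frame(min_p = null$min_p),
                       file.path(config$out_dir, "perm_null.tsv"), stamp)
    .write_stamped_tsv(qq, file.path(config$out_dir, "qq.tsv"), stamp)
    list(linevals = lv, scan = scan, null = null, qq = qq)
  })
  log$stages$gwas <- list(
    sites_read = nrow(panel$sites),
    sites_retained = nrow(out$gwas$scan),
    lines_phenotyped = nrow(out$gwas$linevals),
    n_perm = config$n_perm, seed = config$seed + 3L,
    threshold = unname(out$gwas$null$thresholds[1L]))

  # ---- stage 4: variance explained ------------------------------------
  out$explain <- stage("explain", {
    scan <- out$gwas$scan
    top <- scan[which.min(scan$p), , drop = FALSE]
    dirn <- if (gaussian) "higher" else "lower"
    eff <- effect_summary(top, panel, direction = dirn)
    frac <- proportion_heritability(eff$va_locus, out$varcomp)
    rep <- data.frame(site_id = eff$site_id, p = eff$p, a_hat = eff$a_hat,
                      se = eff$se, a2_unbiased = eff$a2_unbiased,
                      va = eff$va_locus, frac_h2 = frac,
                      scan_p = top$p)
    .write_stamped_tsv(rep, file.path(config$out_dir, "locus_report.tsv"),
                       stamp)
    list(effect = eff, frac_h2 = frac, top_site = top$site_id)
  })
  log$stages$explain <- list(top_site = out$explain$top_site,
                             frac_h2 = out$explain$frac_h2)

  stopifnot(log$stages$gwas$sites_retained <= log$stages$gwas$sites_read,
            log$stages$gwas$lines_phenotyped <= log$stages$data$n_lines)
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out$log <- log
  invisible(out)
}
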