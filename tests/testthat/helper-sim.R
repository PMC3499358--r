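# shared fixture builders (everything is generated in code at test time)

# wrap a lines x sites matrix of codes {0,2,-1,1} as a line_panel
toy_panel <- function(geno, chrom = "2L") {
  nl <- nrow(geno); ns <- ncol(geno)
  lines <- sprintf("line_%03d", seq_len(nl))
  pos <- seq_len(ns) * 100L
  site_ids <- paste0(chrom, ":", pos)
  dimnames(geno) <- list(lines, site_ids)
  structure(list(geno = geno,
                 sites = data.frame(site_id = site_ids, chrom = chrom,
                                    pos = pos, ref = "A", alt = "T",
                                    stringsAsFactors = FALSE),
                 lines = lines, geno_true = geno, spec = NULL),
            class = "line_panel")
}

# line_values table straight from a per-line vector
toy_line_values <- function(values, trait = "v") {
  lines <- sprintf("line_%03d", seq_along(values))
  structure(data.frame(line_id = lines, virus = trait, value = values,
                       weight = 10, n_vials = 1L, stringsAsFactors = FALSE),
            class = c("line_values", "data.frame"))
}

# quick Gaussian survival table from explicit per-vial means
survival_table <- function(line_id, vial_id, values, trait = "v") {
  phenotype_table(data.frame(line_id = line_id, virus = trait,
                             vial_id = vial_id,
                             fly_id = stats::ave(seq_along(values),
                                                 paste(line_id, vial_id),
                                                 FUN = seq_along),
                             value = values, stringsAsFactors = FALSE),
                  kind = "survival")
}

# default small simulated Gaussian dataset used by several tests
sim_gaussian <- function(n_lines = 200, n_vials = 4, n_flies = 10,
                         V_line = 2, V_vial = 0.5, V_r = 1, beta = 10,
                         panel_seed = 3, sim_seed = 7) {
  panel <- generate_panel(panel_spec(n_lines = n_lines, n_sites = 10,
                                     seed = panel_seed))
  model <- genetic_model(list(v = list(scale = "survival", beta = beta,
                                       V_line_poly = V_line, V_vial = V_vial,
                                       V_r = V_r)))
  simulate_gaussian_trait(panel, model, n_vials = n_vials, n_flies = n_flies,
                          seed = sim_seed)
}

# short MCMC config for replicate-based tests
quick_mcmc <- function(seed = 1, n_iter = 4000, burnin = 1000, thin = 3,
                       n_chains = 1) {
  mcmc_config(n_iter = n_iter, burnin = burnin, thin = thin,
              n_chains = n_chains, seed = seed)
}

make_binomial_pair <- function(nl, r, v_line = 1.5, v_od = 1, n_vials = 4,
                               n_flies = 15, seed = 1,
                               traits = c("A", "B")) {
  set.seed(seed)
  Sig <- matrix(c(v_line, r * v_line, r * v_line, v_line), 2)
  B <- matrix(rnorm(nl * 2), nl, 2) %*% chol(Sig)
  lines <- sprintf("L%03d", seq_len(nl))
  mk <- function(j, trait) {
    lv <- rep(seq_len(nl), each = n_vials)
    eta <- B[lv, j] + rnorm(nl * n_vials, 0, sqrt(v_od))
    phenotype_table(
      data.frame(line_id = lines[lv], virus = trait,
                 vial_id = rep(sprintf("v%d", seq_len(n_vials)), nl),
                 n_flies = as.integer(n_flies),
                 n_infected = rbinom(nl * n_vials, n_flies, plogis(eta))),
      "infection")
  }
  list(a = mk(1, traits[1]), b = mk(2, traits[2]), B = B)
}

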