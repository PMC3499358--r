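#' Published reference values bundled with the package
#'
#' `virus_panel_summary()` returns the per-virus summary of a published
#' genome-wide screen of DGRP lines injected with four viruses (two natural
#' D. melanogaster pathogens, DCV and DMelSV, and two viruses isolated from
#' other insects, FHV and DAffSV): fly and line counts, environmental and
#' genetic variances (`v_e`, `v_g`), heritability and the coefficient of
#' genetic variation. Survival traits are on the observed scale (`v_e`
#' includes vial and residual variance); CO2-sensitivity traits are on the
#' logit scale (`v_e` includes the implicit logistic variance `pi^2/3`).
#' `major_locus_table()` returns the screen's major-effect loci with the
#' resistant-allele line counts and the fraction of heritability each
#' explains.
#'
#' @return a data frame
#' @export
virus_panel_summary <- function() {
  utils::read.delim(system.file("extdata", "virus_panel_summary.tsv",
                                package = "viroquant"),
                    stringsAsFactors = FALSE)
}

#' @rdname virus_panel_summary
#' @export
major_locus_table <- function() {
  utils::read.delim(system.file("extdata", "major_loci.tsv",
                                package = "viroquant"),
                    stringsAsFactors = FALSE)
}
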