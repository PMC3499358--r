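#' Parse and format site identifiers
#'
#' Sites are identified as `"chrom:pos"` with 1-based positions and
#' chromosome-arm names (e.g. `"3L:7350895"`).
#'
#' @param x character vector of site ids
#' @return data frame with `chrom` (character) and `pos` (integer)
#' @export
parse_site_id <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed site id: ", x[bad][1L])
  chrom <- vapply(parts, `[`, character(1), 1L)
  pos <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2L)))
  if (anyNA(pos) || any(pos < 1L))
    stop("site positions must be integers >= 1 (1-based)")
  data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

#' @rdname parse_site_id
#' @param chrom,pos chromosome names and 1-based positions
#' @export
format_site_id <- function(chrom, pos) paste0(chrom, ":", pos)

#' Write a line panel to the genotype TSV dialect
#'
#' Lines x sites table: first column `line_id`, remaining columns named by
#' site id (`chrom:pos`), genotype codes 0 (hom ref), 2 (hom alt),
#' 1 (within-line segregating), -1 (missing).
#'
#' @param panel a line panel
#' @param path output path
#' @export
write_genotype_tsv <- function(panel, path) {
  df <- data.frame(line_id = panel$lines, panel$geno, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype table (TSV or minimal VCF)
#'
#' @param path input path
#' @param format `"tsv"` (the dialect written by [write_genotype_tsv()]) or
#'   `"vcf"` (GT-only VCF 4.x subset: `0/0` -> 0, `1/1` -> 2, `0/1`/`1/0` ->
#'   within-line segregating, anything containing `.` -> missing)
#' @return a `line_panel` (without a simulation truth matrix)
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") .read_genotype_tsv(path) else .read_genotype_vcf(path)
}

.read_genotype_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1L] != "line_id")
    stop("malformed header: first column must be 'line_id' (", path, ")")
  site_ids <- names(df)[-1L]
  if (anyDuplicated(site_ids))
    stop("duplicate site ids: ", site_ids[duplicated(site_ids)][1L])
  geno <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(geno) <- "integer"
  bad <- !geno %in% unname(GENO_CODES)
  if (any(bad)) {
    row <- which(rowSums(matrix(bad, nrow(geno))) > 0)[1L]
    stop("invalid genotype code at data row ", row, " of ", path)
  }
  rownames(geno) <- df$line_id
  .panel_from_matrix(geno, site_ids)
}

.panel_from_matrix <- function(geno, site_ids) {
  loc <- parse_site_id(site_ids)
  sites <- data.frame(site_id = site_ids, chrom = loc$chrom, pos = loc$pos,
                      ref = NA_character_, alt = NA_character_,
                      stringsAsFactors = FALSE)
  structure(list(geno = geno, sites = sites, lines = rownames(geno),
                 geno_true = NULL, spec = NULL),
            class = "line_panel")
}

#' Write a line panel as a minimal VCF (GT fields only)
#'
#' @param panel a line panel
#' @param path output path
#' @export
write_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=viroquant",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$lines), collapse = "\t")), con)
  gt_map <- c(`0` = "0/0", `2` = "1/1", `1` = "0/1", `-1` = "./.")
  ref <- ifelse(is.na(panel$sites$ref), "A", panel$sites$ref)
  alt <- ifelse(is.na(panel$sites$alt), "T", panel$sites$alt)
  for (s in seq_len(nrow(panel$sites))) {
    gts <- gt_map[as.character(panel$geno[, s])]
    writeLines(paste(c(panel$sites$chrom[s], panel$sites$pos[s],
                       panel$sites$site_id[s], ref[s], alt[s], ".", "PASS",
                       ".", "GT", gts), collapse = "\t"), con)
  }
  invisible(path)
}

.read_genotype_vcf <- function(path) {
  ln <- readLines(path)
  hdr <- grep("^#CHROM", ln)
  if (length(hdr) != 1L) stop("malformed VCF: no #CHROM header line (", path, ")")
  cols <- strsplit(ln[hdr], "\t", fixed = TRUE)[[1L]]
  if (length(cols) < 10L) stop("VCF has no sample columns")
  samples <- cols[-(1:9)]
  body <- ln[-seq_len(hdr)]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(cols)))
    stop("malformed VCF row at line ", hdr + which(nf != length(cols))[1L])
  chrom <- vapply(fields, `[`, character(1), 1L)
  pos <- as.integer(vapply(fields, `[`, character(1), 2L))
  if (any(pos < 1L)) stop("VCF position < 1 (positions are 1-based)")
  ref <- vapply(fields, `[`, character(1), 4L)
  alt <- vapply(fields, `[`, character(1), 5L)
  site_ids <- format_site_id(chrom, pos)
  if (anyDuplicated(site_ids)) stop("duplicate site ids in VCF")
  code_gt <- function(gt) {
    gt <- sub(":.*", "", gt)
    gt <- gsub("|", "/", gt, fixed = TRUE)
    ifelse(grepl("\\.", gt), GENO_CODES[["missing"]],
           ifelse(gt == "0/0", 0L, ifelse(gt == "1/1", 2L,
                                          GENO_CODES[["seg"]])))
  }
  geno <- matrix(NA_integer_, length(samples), length(site_ids),
                 dimnames = list(samples, site_ids))
  for (s in seq_along(fields))
    geno[, s] <- code_gt(fields[[s]][-(1:9)])
  panel <- .panel_from_matrix(geno, site_ids)
  panel$sites$ref <- ref
  panel$sites$alt <- alt
  panel
}

#' Write / read phenotype CSV
#'
#' Survival schema: `line_id, virus, vial_id, fly_id, value`; infection
#' schema: `line_id, virus, vial_id, n_flies, n_infected`.
#'
#' @param pheno a [phenotype_table()]
#' @param path file path
#' @export
write_phenotype_csv <- function(pheno, path) {
  utils::write.csv(as.data.frame(pheno), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotype_csv
#' @export
read_phenotype_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  kind <- if ("value" %in% names(df)) "survival" else "infection"
  phenotype_table(df, kind = kind)
}

#' Write / read a truth manifest as flat key-value text
#'
#' @param truth a [truth_manifest()]
#' @param path file path
#' @export
write_truth <- function(truth, path) {
  num <- function(x) sprintf("%.17g", x)
  out <- c(sprintf("trait\t%s", truth$trait),
           sprintf("seed\t%d", truth$seed),
           sprintf("n_vials\t%d", truth$design$n_vials),
           sprintf("n_flies\t%s", paste(truth$design$n_flies, collapse = ",")))
  tr <- truth$model$traits[[truth$trait]]
  for (fld in names(tr))
    out <- c(out, sprintf("model.%s\t%s", fld,
                          if (is.character(tr[[fld]])) tr[[fld]] else num(tr[[fld]])))
  loci <- truth$model$causal_loci
  loci <- loci[loci$trait == truth$trait, , drop = FALSE]
  for (r in seq_len(nrow(loci)))
    out <- c(out, sprintf("causal\t%s\t%s\t%s", loci$site_id[r],
                          num(loci$a[r]), num(loci$d_ratio[r])))
  for (i in seq_along(truth$line_values))
    out <- c(out, sprintf("line_value\t%s\t%s", names(truth$line_values)[i],
                          num(truth$line_values[i])))
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  ln <- readLines(path)
  fields <- strsplit(ln, "\t", fixed = TRUE)
  key <- vapply(fields, `[`, character(1), 1L)
  get1 <- function(k) fields[[match(k, key)]][2L]
  tr <- list()
  for (f in fields[startsWith(key, "model.")]) {
    nm <- sub("^model\\.", "", f[1L])
    tr[[nm]] <- if (nm == "scale") f[2L] else as.numeric(f[2L])
  }
  loci <- fields[key == "causal"]
  causal <- if (length(loci)) {
    data.frame(site_id = vapply(loci, `[`, character(1), 2L),
               trait = get1("trait"),
               a = as.numeric(vapply(loci, `[`, character(1), 3L)),
               d_ratio = as.numeric(vapply(loci, `[`, character(1), 4L)),
               stringsAsFactors = FALSE)
  } else NULL
  lv <- fields[key == "line_value"]
  line_values <- stats::setNames(
    as.numeric(vapply(lv, `[`, character(1), 3L)),
    vapply(lv, `[`, character(1), 2L))
  model <- genetic_model(stats::setNames(list(tr), get1("trait")), causal)
  truth_manifest(model, trait = get1("trait"),
                 seed = as.integer(get1("seed")),
                 design = list(n_vials = as.integer(get1("n_vials")),
                               n_flies = as.integer(strsplit(get1("n_flies"),
                                                             ",")[[1L]])),
                 line_values = line_values)
}
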