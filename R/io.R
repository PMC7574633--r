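#' Read tag-SNP genotypes from a VCF
#'
#' Extracts unphased GT calls at the panel SNPs (matched by ID) and
#' converts them to tag-allele dosages. Phase separators are ignored
#' (dosage arithmetic needs no phase). Records at panel sites must be
#' biallelic and their REF/ALT must include the panel's tag base;
#' panel SNPs absent from the file produce a warning and all-missing
#' calls.
#'
#' @param path Path to a VCF (v4.x, plain text or gzipped).
#' @param panel An [abo_panel()].
#' @return Integer matrix (samples x panel SNPs) of tag dosages with
#'   `NA` for missing calls; row names are VCF sample names.
#' @export
read_abo_vcf <- function(path, panel = abo_panel()) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- tryCatch(
    suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE)),
    error = function(e) stop("malformed VCF: ", conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || ncol(gt) == 0) stop("malformed VCF: no genotype data")

  n <- ncol(gt)
  calls <- matrix(NA_integer_, n, nrow(panel),
                  dimnames = list(colnames(gt), panel$snp_id))
  for (i in seq_len(nrow(panel))) {
    snp <- panel$snp_id[i]
    j <- which(fix[, "ID"] == snp)
    if (length(j) == 0) {
      warning("panel SNP ", snp, " absent from VCF; calls set missing")
      next
    }
    if (length(j) > 1) stop("duplicate VCF records for ", snp)
    alt <- fix[j, "ALT"]
    if (grepl(",", alt))
      stop("multi-allelic record at panel site ", snp)
    alleles <- c(fix[j, "REF"], alt)
    tag_idx <- match(panel$tag_base[i], alleles) - 1L
    if (is.na(tag_idx))
      stop("tag base ", panel$tag_base[i], " not among REF/ALT at ", snp)
    g <- gt[j, ]
    a1 <- substr(g, 1, 1)
    a2 <- substr(g, 3, 3)
    d <- (a1 == as.character(tag_idx)) + (a2 == as.character(tag_idx))
    d[a1 == "." | a2 == "." | is.na(g) | nchar(g) < 3] <- NA
    calls[, snp] <- as.integer(d)
  }
  calls
}

#' Write a simulated cohort as VCF plus sample sheet
#'
#' Emits a VCFv4.2 file with one biallelic record per panel SNP (GT only,
#' unphased, position-sorted) in the panel's REF/ALT orientation, a TSV
#' sample sheet (`sample_id`, `status`, `sex`), and a TSV of the
#' ground-truth diplotypes. Output is byte-deterministic given the
#' simulation.
#'
#' @param sim An [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"cohort"`).
#' @return Invisibly, named paths of the three files written.
#' @export
write_cohort_vcf <- function(sim, dir, prefix = "cohort") {
  stopifnot(inherits(sim, "abo_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- sim$panel
  vcf_path <- file.path(dir, paste0(prefix, ".vcf"))
  sheet_path <- file.path(dir, paste0(prefix, "_samples.tsv"))
  truth_path <- file.path(dir, paste0(prefix, "_truth.tsv"))

  # dosage of the tag base -> GT in REF/ALT index space
  tag_is_alt <- panel$tag_base == panel$alt
  gt_for <- function(d, is_alt) {
    out <- rep("./.", length(d))
    alt_d <- if (is_alt) d else 2L - d
    out[!is.na(d)] <- c("0/0", "0/1", "1/1")[alt_d[!is.na(d)] + 1L]
    out
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=abotype",
    sprintf("##contig=<ID=%s>", unique(panel$chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", sim$samples$sample_id), collapse = "\t"))
  body <- vapply(seq_len(nrow(panel)), function(i) {
    g <- gt_for(sim$calls[, panel$snp_id[i]], tag_is_alt[i])
    paste(c(panel$chrom[i], panel$pos[i], panel$snp_id[i],
            panel$ref[i], panel$alt[i], ".", "PASS", ".", "GT", g),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), vcf_path)
  utils::write.table(sim$samples, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(vcf = vcf_path, samples = sheet_path, truth = truth_path))
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id`, `status` (`case`/`control`),
#'   `sex` (`M`/`F`/`U`).
#' @return Data frame with those columns.
#' @export
read_sample_sheet <- function(path) {
  s <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "status", "sex")
  if (!all(req %in% names(s)))
    stop("sample sheet must have columns: ", paste(req, collapse = ", "))
  if (!all(s$status %in% c("case", "control")))
    stop("status must be 'case' or 'control'")
  if (!all(s$sex %in% c("M", "F", "U")))
    stop("sex must be 'M', 'F' or 'U'")
  s[, req]
}

format_assoc_table <- function(x) {
  out <- data.frame(
    Item = x$item, Group = x$stratum, CN = x$cn,
    CF = sprintf("%.4f", x$cf), MN = x$mn, MF = sprintf("%.4f", x$mf),
    chi2 = sprintf("%.2f", x$chi2), OR = sprintf("%.2f", x$or),
    CI_low = sprintf("%.2f", x$ci_low),
    CI_high = sprintf("%.2f", x$ci_high),
    P = sprintf("%.2f", x$p), stringsAsFactors = FALSE)
  if (!is.na(attr(x, "m")))
    out$P_corr <- ifelse(is.na(x$p_corr), "NT", sprintf("%.2f", x$p_corr))
  out
}

#' Write pipeline results as TSV reports
#'
#' Writes the typed cohort, one association table per computed level
#' (frequencies to 4 decimals, chi-square/OR/CI to 2, corrected p as
#' "NT" where not tested), the per-SNP HWE table, meta-analysis and
#' forest tables when present, and a JSON sidecar of run metadata
#' (exclusion counts, configuration, package version).
#'
#' @param results A list as returned by [abo_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[name]] <<- p
  }
  if (!is.null(results$cohort)) {
    w(as.data.frame(results$cohort), "typed.tsv")
  }
  for (lv in names(results$association))
    w(format_assoc_table(results$association[[lv]]),
      paste0("association_", lv, ".tsv"))
  if (!is.null(results$hwe)) {
    h <- results$hwe
    h$p_hat <- sprintf("%.4f", h$p_hat)
    h$chi2 <- sprintf("%.2f", h$chi2)
    h$p <- sprintf("%.2f", h$p)
    w(h, "hwe.tsv")
  }
  if (!is.null(results$meta)) {
    w(summary(results$meta), "meta.tsv")
    w(forest_table(results$meta), "forest.tsv")
  }
  meta_info <- list(
    package = "abotype",
    version = as.character(utils::packageVersion("abotype")),
    exclusions = if (!is.null(results$cohort))
      as.list(attr(results$cohort, "exclusions")) else NULL,
    n_samples = if (!is.null(results$cohort)) nrow(results$cohort)
      else NULL,
    config = results$config)
  sidecar <- file.path(dir, "run_info.json")
  jsonlite::write_json(meta_info, sidecar, auto_unbox = TRUE, null = "null")
  paths[["run_info.json"]] <- sidecar
  invisible(paths)
}

#' End-to-end analysis: VCF to association tables (and meta-analysis)
#'
#' Reads genotypes and the sample sheet, types the cohort, runs per-SNP
#' HWE tests and the association analysis at all three levels (total and
#' sex-stratified), and, when per-study 2x2 tables are supplied, the
#' blood-type meta-analysis. Writes TSV reports if `out_dir` is given.
#'
#' @param vcf Path to the cohort VCF.
#' @param samples Path to the sample sheet TSV, or a data frame.
#' @param panel An [abo_panel()].
#' @param consensus Redundant-tag policy, see [allele_dosages()].
#' @param denominators `"full"` or `"typed"`, see [abo_association()].
#' @param studies Optional per-study 2x2 table for [abo_meta()]
#'   (e.g. [abo_longevity_studies()]).
#' @param out_dir Optional report directory for [write_report()].
#' @return List with `cohort`, `hwe`, `association` (named list over
#'   levels), `meta` (or `NULL`), `config`.
#' @export
abo_pipeline <- function(vcf, samples, panel = abo_panel(),
                         consensus = "unanimous",
                         denominators = "full",
                         studies = NULL, out_dir = NULL) {
  calls <- read_abo_vcf(vcf, panel)
  sheet <- if (is.character(samples)) read_sample_sheet(samples)
           else samples
  if (!all(rownames(calls) %in% sheet$sample_id))
    stop("VCF contains samples absent from the sample sheet")
  sheet <- sheet[match(rownames(calls), sheet$sample_id), ]
  cohort <- type_cohort(calls, sheet, panel, consensus = consensus)
  association <- list(
    allele = abo_association(cohort, "allele",
                             denominators = denominators),
    genotype = abo_association(cohort, "genotype",
                               denominators = denominators),
    phenotype = abo_association(cohort, "phenotype",
                                denominators = denominators))
  res <- list(cohort = cohort, hwe = abo_hwe(cohort),
              association = association,
              meta = if (!is.null(studies)) abo_meta(studies) else NULL,
              config = list(consensus = consensus,
                            denominators = denominators))
  if (!is.null(out_dir)) write_report(res, out_dir)
  res
}
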