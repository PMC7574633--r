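# Published statistics (chi-square, OR, 95% CI, P) for the reference
# cohort's association tables, row-aligned with abo_reference_counts():
# item-major, strata in the order total / male / female. Used to verify
# that recomputation from the published counts reproduces the published
# statistics.
printed_assoc_stats <- function(level) {
  v <- switch(level,
    allele = c(
      0.40, 0.97, 0.87, 1.07, 0.53,   3.30, 0.84, 0.70, 1.01, 0.07,
      0.26, 1.03, 0.91, 1.17, 0.61,
      2.59, 0.92, 0.83, 1.02, 0.11,   0.05, 0.98, 0.81, 1.18, 0.82,
      3.04, 0.90, 0.80, 1.01, 0.08,
      2.78, 0.92, 0.83, 1.02, 0.10,   0.05, 0.98, 0.81, 1.18, 0.83,
      3.43, 0.89, 0.79, 1.01, 0.06,
      2.40, 0.92, 0.84, 1.02, 0.12,   0.03, 0.98, 0.82, 1.18, 0.86,
      2.98, 0.90, 0.80, 1.01, 0.08,
      2.80, 1.07, 0.99, 1.17, 0.09,   2.66, 1.14, 0.97, 1.33, 0.10,
      0.81, 1.05, 0.96, 1.16, 0.37,
      0.08, 1.01, 0.46, 1.25, 0.78,   1.11, 1.10, 0.92, 1.31, 0.29,
      0.14, 0.98, 0.87, 1.10, 0.71,
      0.08, 1.01, 0.46, 1.25, 0.78,   1.03, 1.10, 0.92, 1.31, 0.31,
      0.12, 0.98, 0.87, 1.10, 0.73,
      0.08, 1.01, 0.46, 1.12, 0.78,   0.96, 1.09, 0.92, 1.30, 0.33,
      0.10, 0.98, 0.88, 1.10, 0.75),
    genotype = c(
      0.86, 0.87, 0.65, 1.17, 0.36,   2.99, 0.62, 0.36, 1.07, 0.08,
      0.01, 1.02, 0.72, 1.46, 0.92,
      0.07, 0.98, 0.82, 1.16, 0.80,   0.28, 0.92, 0.67, 1.25, 0.60,
      0.00, 1.00, 0.82, 1.23, 0.97,
      1.78, 1.13, 0.94, 1.38, 0.18,   0.00, 1.00, 0.71, 1.40, 1.00,
      2.72, 1.21, 0.96, 1.53, 0.10,
      0.36, 0.92, 0.69, 1.22, 0.55,   0.66, 0.81, 0.50, 1.33, 0.42,
      0.00, 1.00, 0.70, 1.41, 1.00,
      0.13, 1.03, 0.87, 1.22, 0.72,   1.18, 1.19, 0.87, 1.62, 0.28,
      0.11, 0.97, 0.79, 1.18, 0.74,
      4.36, 0.82, 0.68, 0.99, 0.04,   0.06, 0.96, 0.66, 1.38, 0.81,
      5.99, 0.76, 0.61, 0.95, 0.01,
      1.31, 1.12, 0.92, 1.34, 0.25,   0.23, 1.08, 0.78, 1.52, 0.63,
      1.41, 1.15, 0.91, 1.45, 0.23,
      0.91, 1.08, 0.92, 1.27, 0.34,   0.29, 1.09, 0.80, 1.47, 0.59,
      0.36, 1.06, 0.88, 1.28, 0.55,
      0.03, 1.02, 0.80, 1.30, 0.85,   1.09, 1.25, 0.82, 1.87, 0.30,
      0.12, 0.95, 0.70, 1.28, 0.73,
      0.37, 0.94, 0.76, 1.15, 0.54,   0.05, 0.96, 0.66, 1.39, 0.82,
      0.34, 0.93, 0.73, 1.18, 0.56),
    phenotype = c(
      0.09, 1.02, 0.90, 1.16, 0.76,   1.44, 0.86, 0.68, 1.10, 0.23,
      1.40, 1.10, 0.94, 1.28, 0.24,
      2.03, 0.91, 0.80, 1.04, 0.15,   0.07, 1.03, 0.82, 1.31, 0.79,
      3.79, 0.86, 0.74, 1.00, 0.05,
      2.52, 1.11, 0.98, 1.25, 0.11,   1.68, 1.16, 0.93, 1.46, 0.20,
      1.16, 1.09, 0.93, 1.26, 0.28,
      0.37, 0.94, 0.76, 1.15, 0.54,   0.05, 0.96, 0.66, 1.39, 0.82,
      0.34, 0.93, 0.73, 1.18, 0.56))
  m <- matrix(v, ncol = 5, byrow = TRUE)
  counts <- abo_reference_counts(level)
  data.frame(item = counts$item, stratum = counts$stratum,
             chi2 = m[, 1], or = m[, 2], ci_low = m[, 3],
             ci_high = m[, 4], p = m[, 5], stringsAsFactors = FALSE)
}

# Published CI bounds that do not reproduce from the published counts
# under the Woolf interval. "gross": typographical misprints, internally
# inconsistent with the same row's printed OR/chi-square/P (e.g. lower
# bound 0.46 against OR 1.01, chi2 = 0.08, P = 0.78). "near": bounds off
# by 0.011-0.016, consistent with a different CI method having been used
# for those small-count rows.
ci_bound_errata <- function() {
  data.frame(
    level = c(rep("allele", 6), rep("genotype", 5)),
    item = c("O02 (rs512770)", "O02 (rs512770)", "O02 (rs688976)",
             "O02 (rs688976)", "O02 (rs549446)", "O (rs687289)",
             "A/A", "A/O01", "A/O02", "B/B", "O02/O02"),
    stratum = c(rep("total", 5), "female",
                "female", "male", "male", "female", "male"),
    bound = c("ci_low", "ci_high", "ci_low", "ci_high", "ci_low",
              "ci_low",
              "ci_high", "ci_high", "ci_high", "ci_high", "ci_high"),
    kind = c(rep("gross", 5), rep("near", 6)),
    stringsAsFactors = FALSE)
}

# Tag-dosage calls matrix for explicit diplotypes, bypassing the
# simulator (independent of diplotype_to_tags): hand-coded per-haplotype
# contributions in abo_panel() column order.
calls_for_diplotypes <- function(hap1, hap2) {
  panel <- abo_panel()
  contrib <- function(h) {
    switch(h,
      A   = as.integer(panel$tagged_allele == "A"),
      B   = as.integer(panel$tagged_allele == "B"),
      O01 = as.integer(panel$tagged_allele == "O"),
      O02 = as.integer(panel$tagged_allele %in% c("O", "O02")))
  }
  m <- t(mapply(function(h1, h2) contrib(h1) + contrib(h2), hap1, hap2))
  colnames(m) <- panel$snp_id
  rownames(m) <- NULL
  m
}

sample_sheet_for <- function(n, status = "case", sex = "F") {
  data.frame(sample_id = sprintf("T%04d", seq_len(n)),
             status = rep_len(status, n), sex = rep_len(sex, n),
             stringsAsFactors = FALSE)
}

# All 10 diplotype classes as unordered haplotype pairs
all_diplotypes <- function() {
  data.frame(
    hap1 = c("A", "A", "A", "B", "B", "B", "O01", "O01", "O02", "A"),
    hap2 = c("A", "O01", "O02", "B", "O01", "O02", "O01", "O02", "O02",
             "B"),
    genotype = c("A/A", "A/O01", "A/O02", "B/B", "B/O01", "B/O02",
                 "O01/O01", "O01/O02", "O02/O02", "A/B"),
    blood_type = c("A", "A", "A", "B", "B", "B", "O", "O", "O", "AB"),
    stringsAsFactors = FALSE)
}
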