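#' Published ABO count tables from a large Chinese centenarian cohort
#'
#' Item counts published for the CLHLS centenarian case-control cohort
#' (2201 centenarians vs 2330 middle-aged controls, SNP-genotyped at the
#' eight-SNP ABO tag panel), at three levels: per-SNP allele counts
#' (chromosomes), the ten diplotype classes, and the four blood types,
#' each totalled and sex-stratified. These are the inputs from which the
#' package's association statistics can be recomputed and checked against
#' the published values; only the counts are stored -- every statistic is
#' derived at run time.
#'
#' @param level `"phenotype"`, `"genotype"` or `"allele"`.
#' @return Data frame with columns `item`, `stratum` (`total`/`male`/
#'   `female`), `cn` (case count), `mn` (control count).
#' @seealso [abo_reference_strata()] for the matching denominators,
#'   [association_from_counts()] to recompute the statistics.
#' @export
abo_reference_counts <- function(level = c("phenotype", "genotype",
                                           "allele")) {
  level <- match.arg(level)
  strat <- c("total", "male", "female")
  build <- function(items, cn, mn) {
    data.frame(item = rep(items, each = 3L),
               stratum = rep(strat, length(items)),
               cn = cn, mn = mn, stringsAsFactors = FALSE)
  }
  switch(level,
    allele = build(
      c("A (rs507666)", "B (rs8176743)", "B (rs8176746)", "B (rs8176749)",
        "O (rs687289)", "O02 (rs512770)", "O02 (rs688976)",
        "O02 (rs549446)"),
      cn = c(902, 223, 679,   899, 241, 658,   918, 244, 674,
             916, 244, 672,   2576, 674, 1902, 1103, 294, 809,
             1103, 294, 809,  1104, 294, 810),
      mn = c(980, 356, 624,   1016, 341, 675,  1039, 345, 694,
             1032, 344, 688,  2646, 888, 1758, 1156, 381, 775,
             1156, 382, 774,  1157, 383, 774)),
    genotype = build(
      GENOTYPE_CLASSES,
      cn = c(87, 19, 68,    290, 72, 218,  244, 61, 183,
             93, 26, 67,    319, 85, 234,  219, 56, 163,
             246, 68, 178,  360, 85, 275,  138, 45, 93,
             189, 49, 140),
      mn = c(105, 42, 63,   313, 108, 205, 230, 85, 145,
             107, 44, 63,   329, 102, 227, 277, 81, 196,
             236, 88, 148,  357, 110, 247, 143, 51, 92,
             212, 71, 141)),
    phenotype = build(
      BLOOD_TYPES,
      cn = c(621, 152, 469,  631, 167, 464,  744, 198, 546,
             189, 49, 140),
      mn = c(648, 235, 413,  713, 227, 486,  736, 249, 487,
             212, 71, 141))
  )
}

#' Stratum sizes for the reference cohort
#'
#' Individual counts per stratum in the reference case-control cohort:
#' 2201 centenarians (570 male, 1631 female) versus 2330 middle-aged
#' controls (793 male, 1537 female). Allele-level denominators are twice
#' these (chromosomes).
#'
#' @return Named list mapping stratum to `c(n_case, n_ctrl)`.
#' @export
abo_reference_strata <- function() {
  list(total = c(2201, 2330),
       male = c(570, 793),
       female = c(1631, 1537))
}

#' Per-study blood-type 2x2 tables for the longevity meta-analysis
#'
#' The published per-study counts pooled in the blood-type/longevity
#' meta-analysis: five case-control studies from the literature (one,
#' Coppola 2003, reports only the O contrast) plus the CLHLS
#' SNP-genotyped cohort, as cases/controls carrying vs not carrying each
#' blood type.
#'
#' @return Long-format data frame with columns `study`, `year`, `country`,
#'   `contrast`, `case_item`, `case_nonitem`, `ctrl_item`, `ctrl_nonitem`,
#'   suitable for [abo_meta()].
#' @export
abo_longevity_studies <- function() {
  rec <- function(study, year, country, contrast, ci, cni, mi, mni) {
    data.frame(study = study, year = year, country = country,
               contrast = contrast, case_item = ci, case_nonitem = cni,
               ctrl_item = mi, ctrl_nonitem = mni,
               stringsAsFactors = FALSE)
  }
  rbind(
    rec("Sturgeon 1969", 1969, "Turkey", "A", 22, 28, 47, 63),
    rec("Shimizu 2004", 2004, "Japan", "A", 92, 177, 2759, 4394),
    rec("Mengoli 2015", 2015, "Italy", "A", 108, 144, 2145, 2880),
    rec("Franchini 2016", 2016, "Italy", "A", 55, 110, 2086, 2977),
    rec("CLHLS 2020", 2020, "China", "A", 621, 1580, 648, 1682),

    rec("Sturgeon 1969", 1969, "Turkey", "B", 11, 39, 20, 90),
    rec("Shimizu 2004", 2004, "Japan", "B", 79, 190, 1570, 5583),
    rec("Mengoli 2015", 2015, "Italy", "B", 22, 230, 575, 4450),
    rec("Franchini 2016", 2016, "Italy", "B", 14, 151, 541, 4522),
    rec("CLHLS 2020", 2020, "China", "B", 631, 1570, 713, 1617),

    rec("Sturgeon 1969", 1969, "Turkey", "O", 11, 39, 37, 73),
    rec("Coppola 2003", 2003, "Italy", "O", 32, 42, 39, 71),
    rec("Shimizu 2004", 2004, "Japan", "O", 76, 193, 2153, 5000),
    rec("Mengoli 2015", 2015, "Italy", "O", 110, 142, 2087, 2938),
    rec("Franchini 2016", 2016, "Italy", "O", 93, 72, 2201, 2862),
    rec("CLHLS 2020", 2020, "China", "O", 744, 1457, 736, 1594),

    rec("Sturgeon 1969", 1969, "Turkey", "AB", 6, 44, 6, 104),
    rec("Shimizu 2004", 2004, "Japan", "AB", 22, 247, 671, 6482),
    rec("Mengoli 2015", 2015, "Italy", "AB", 12, 240, 218, 4807),
    rec("Franchini 2016", 2016, "Italy", "AB", 3, 162, 235, 4828),
    rec("CLHLS 2020", 2020, "China", "AB", 189, 2012, 212, 2118)
  )
}
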