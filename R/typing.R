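#' @name abotype-classes
#' @title ABO haplotype, genotype and blood-type label sets
#' @description Constant label sets used throughout the package: the four
#'   common ABO haplotypes, the ten diplotype (genotype) classes they form,
#'   and the four blood types. `A` and `B` are dominant over `O`; `O01` and
#'   `O02` are subtypes of the null allele distinguished only at the DNA
#'   level.
#' @keywords internal
NULL

ABO_HAPLOTYPES <- c("A", "B", "O01", "O02")

GENOTYPE_CLASSES <- c("A/A", "A/O01", "A/O02", "B/B", "B/O01", "B/O02",
                      "O01/O01", "O01/O02", "O02/O02", "A/B")

BLOOD_TYPES <- c("A", "B", "O", "AB")

# The 10 feasible dosage vectors (d_A, d_B, d_O, d_O02) with
# d_A + d_B + d_O = 2 and d_O02 <= d_O, keyed for O(1) lookup.
feasible_dosages <- function() {
  g <- expand.grid(d_A = 0:2, d_B = 0:2, d_O = 0:2, d_O02 = 0:2)
  g <- g[g$d_A + g$d_B + g$d_O == 2L & g$d_O02 <= g$d_O, , drop = FALSE]
  rownames(g) <- NULL
  g
}

dosage_key <- function(d_A, d_B, d_O, d_O02) {
  paste(d_A, d_B, d_O, d_O02, sep = "")
}

genotype_lookup <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      g <- feasible_dosages()
      lab <- character(nrow(g))
      for (i in seq_len(nrow(g))) {
        counts <- c(A = g$d_A[i], B = g$d_B[i],
                    O01 = g$d_O[i] - g$d_O02[i], O02 = g$d_O02[i])
        lab[i] <- paste(rep(names(counts), counts), collapse = "/")
      }
      tab <<- stats::setNames(lab, dosage_key(g$d_A, g$d_B, g$d_O, g$d_O02))
    }
    tab
  }
})

#' Resolve ABO diplotypes from allele dosages
#'
#' Given per-individual counts of the tagged alleles (`d_A`, `d_B`, `d_O`,
#' `d_O02`, each 0--2), resolves the unordered haplotype pair: the `O01`
#' dosage is `d_O - d_O02` (carriers of `O` with no `O02` tag are assigned
#' `O01`), and the size-2 multiset over \{A, B, O01, O02\} is the diplotype.
#' The blood type follows dominance: any `A` with any `B` is AB, otherwise
#' `A` present is A, `B` present is B, and two `O` haplotypes are O.
#'
#' @param d_A,d_B,d_O,d_O02 Integer vectors of equal length with values in
#'   0--2. `d_A + d_B + d_O` must equal 2 and `d_O02 <= d_O` wherever all
#'   four are non-missing; infeasible rows yield `NA`.
#' @return A data frame with columns `genotype` (one of the 10 classes, e.g.
#'   `"A/O02"`) and `blood_type` (`"A"`, `"B"`, `"O"`, `"AB"`). `genotype`
#'   is `NA` when any dosage is missing or the vector is infeasible;
#'   `blood_type` is additionally resolved when only `d_O02` is missing,
#'   since the phenotype does not depend on the O subtype.
#' @examples
#' resolve_diplotype(1, 0, 1, 1)   # A/O02, blood type A
#' resolve_diplotype(0, 0, 2, 0)   # O01/O01, blood type O
#' @export
resolve_diplotype <- function(d_A, d_B, d_O, d_O02) {
  n <- length(d_A)
  stopifnot(length(d_B) == n, length(d_O) == n, length(d_O02) == n)
  genotype <- unname(genotype_lookup()[dosage_key(d_A, d_B, d_O, d_O02)])

  # phenotype needs only d_A, d_B, d_O: resolvable with d_O02 missing
  blood <- rep(NA_character_, n)
  ok <- !is.na(d_A) & !is.na(d_B) & !is.na(d_O) & (d_A + d_B + d_O == 2L)
  ok[is.na(ok)] <- FALSE
  # a known d_O02 must be feasible
  ok <- ok & (is.na(d_O02) | d_O02 <= d_O)
  blood[ok & d_A > 0 & d_B > 0] <- "AB"
  blood[ok & d_A > 0 & d_B == 0] <- "A"
  blood[ok & d_A == 0 & d_B > 0] <- "B"
  blood[ok & d_A == 0 & d_B == 0] <- "O"
  data.frame(genotype = genotype, blood_type = blood,
             stringsAsFactors = FALSE)
}

# Align a calls matrix to the panel: add all-missing columns for absent
# SNPs and order columns as the panel lists them.
pad_calls <- function(calls, panel) {
  calls <- as.matrix(calls)
  missing_snps <- setdiff(panel$snp_id, colnames(calls))
  if (length(missing_snps)) {
    add <- matrix(NA_integer_, nrow(calls), length(missing_snps),
                  dimnames = list(rownames(calls), missing_snps))
    calls <- cbind(calls, add)
  }
  calls[, panel$snp_id, drop = FALSE]
}

# Reconcile redundant tag-SNP dosages (columns of `m`) into one dosage per
# row. Unanimity: all observed calls must agree, otherwise the row is
# discordant. Majority: the modal value wins; ties are discordant.
reconcile_group <- function(m, policy = c("unanimous", "majority")) {
  policy <- match.arg(policy)
  m <- as.matrix(m)
  n_obs <- rowSums(!is.na(m))
  if (policy == "unanimous") {
    args <- c(lapply(seq_len(ncol(m)), function(j) m[, j]), list(na.rm = TRUE))
    lo <- suppressWarnings(do.call(pmin, args))
    hi <- suppressWarnings(do.call(pmax, args))
    value <- ifelse(n_obs > 0 & lo == hi, lo, NA_integer_)
    discordant <- n_obs > 0 & lo != hi
  } else {
    cnt <- sapply(0:2, function(v) rowSums(m == v, na.rm = TRUE))
    if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = 1)
    top <- apply(cnt, 1, max)
    n_top <- rowSums(cnt == top)
    value <- max.col(cnt, ties.method = "first") - 1L
    value[n_obs == 0 | n_top > 1] <- NA_integer_
    discordant <- n_obs > 0 & n_top > 1
  }
  discordant[is.na(discordant)] <- FALSE
  list(value = as.integer(value), discordant = discordant)
}

#' Compute ABO allele dosages from tag-SNP calls
#'
#' Collapses per-SNP tag-allele dosages into one dosage per ABO allele.
#' The single `A` and `O` SNPs are read directly; the redundant `B` and
#' `O02` tag groups are reconciled under the chosen consensus policy
#' (default: unanimity -- any discordance among observed calls marks the
#' sample unresolvable; `"majority"` takes the modal call and treats ties
#' as discordant). A missing `A`, `B` or `O` dosage that is forced to a
#' unique in-range value by the constraint `d_A + d_B + d_O = 2` is imputed
#' and flagged, as is `d_O02 = 0` when `d_O = 0`.
#'
#' @param calls Integer matrix (samples x SNPs) of tag-allele dosages in
#'   0--2 with `NA` for missing calls; column names are panel `snp_id`s.
#' @param panel An [abo_panel()] data frame.
#' @param consensus `"unanimous"` (default) or `"majority"`.
#' @return A data frame with one row per sample: integer dosages `d_A`,
#'   `d_B`, `d_O`, `d_O02` (with `NA` where unresolvable), `discordant`
#'   (any redundant tag group in conflict) and `imputed` (any dosage filled
#'   from the sum constraint).
#' @examples
#' panel <- abo_panel()
#' calls <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0), nrow = 1,
#'                 dimnames = list("s1", panel$snp_id[order(match(
#'                   panel$tagged_allele, c("A", "B", "O", "O02")))]))
#' allele_dosages(calls, panel)   # d_A = 1, d_B = 1: an A/B individual
#' @export
allele_dosages <- function(calls, panel = abo_panel(),
                           consensus = c("unanimous", "majority")) {
  consensus <- match.arg(consensus)
  calls <- pad_calls(calls, panel)

  one <- function(allele) {
    cols <- panel_cols(panel, allele)
    reconcile_group(calls[, cols, drop = FALSE], consensus)
  }
  rA <- one("A"); rB <- one("B"); rO <- one("O"); rO2 <- one("O02")

  d <- data.frame(d_A = rA$value, d_B = rB$value,
                  d_O = rO$value, d_O02 = rO2$value)
  d$discordant <- rA$discordant | rB$discordant | rO$discordant |
    rO2$discordant
  d$imputed <- FALSE

  # impute missing A/B/O dosages forced by the diploid sum: either the
  # known dosages already account for both haplotypes (missing ones are 0),
  # or exactly one is missing and its value is determined
  abo <- cbind(d$d_A, d$d_B, d$d_O)
  n_miss <- rowSums(is.na(abo))
  known_sum <- as.integer(rowSums(abo, na.rm = TRUE))
  fix <- which(n_miss >= 1L & !d$discordant &
                 (known_sum == 2L | (n_miss == 1L & known_sum < 2L)))
  for (i in fix) {
    j <- which(is.na(abo[i, ]))
    v <- if (known_sum[i] == 2L) rep(0L, length(j)) else 2L - known_sum[i]
    d[i, c("d_A", "d_B", "d_O")[j]] <- v
    d$imputed[i] <- TRUE
  }
  # d_O = 0 forces d_O02 = 0
  f2 <- which(is.na(d$d_O02) & !is.na(d$d_O) & d$d_O == 0L & !d$discordant)
  if (length(f2)) {
    d$d_O02[f2] <- 0L
    d$imputed[f2] <- TRUE
  }
  rownames(d) <- rownames(calls)
  d
}

#' Type a cohort: tag-SNP calls to diplotypes and blood types
#'
#' Runs [allele_dosages()] and [resolve_diplotype()] over a cohort and
#' attaches per-sample exclusion reasons. Samples are excluded when a
#' redundant tag group is discordant (`"discordant_tags"`), when the
#' resolved dosages do not sum to two haplotypes (`"dosage_sum"`), when the
#' `O02` dosage exceeds the `O` dosage (`"o02_exceeds_o"`), or when missing
#' calls leave the dosages underdetermined (`"missing"`). Individuals whose
#' `A`/`B`/`O` dosages resolve but whose `O02` dosage does not are typed at
#' the blood-type level and kept (with `genotype` `NA`) when
#' `keep_partial = TRUE`, since the phenotype does not depend on the O
#' subtype; set `keep_partial = FALSE` to exclude them outright.
#'
#' @param calls Integer matrix of per-SNP tag dosages as in
#'   [allele_dosages()].
#' @param samples Data frame with columns `sample_id`, `status`
#'   (`"case"`/`"control"`) and `sex` (`"M"`/`"F"`/`"U"`), one row per row
#'   of `calls`.
#' @param panel An [abo_panel()].
#' @param consensus Consensus policy, see [allele_dosages()].
#' @param keep_partial Keep blood-type-only resolutions (default `TRUE`).
#' @return An object of class `abo_cohort`: a data frame with the sample
#'   sheet columns plus `d_A`, `d_B`, `d_O`, `d_O02`, `genotype`,
#'   `blood_type`, `imputed` and `exclusion` (`NA` for fully typed
#'   samples). Attributes `exclusions` (a named count table by reason) and
#'   `calls` (the input matrix) are attached.
#' @export
type_cohort <- function(calls, samples, panel = abo_panel(),
                        consensus = c("unanimous", "majority"),
                        keep_partial = TRUE) {
  consensus <- match.arg(consensus)
  if (nrow(samples) != nrow(calls))
    stop("`samples` and `calls` must have one row per individual")
  if (!all(c("sample_id", "status", "sex") %in% names(samples)))
    stop("`samples` must have columns sample_id, status, sex")
  if (!all(samples$status %in% c("case", "control")))
    stop("status must be 'case' or 'control'")

  d <- allele_dosages(calls, panel, consensus)
  excl <- rep(NA_character_, nrow(d))

  sum_abo <- d$d_A + d$d_B + d$d_O
  core_known <- !is.na(d$d_A) & !is.na(d$d_B) & !is.na(d$d_O)
  excl[d$discordant] <- "discordant_tags"
  bad_sum <- is.na(excl) & core_known & sum_abo != 2L
  excl[bad_sum] <- "dosage_sum"
  bad_o02 <- is.na(excl) & core_known & !is.na(d$d_O02) & d$d_O02 > d$d_O
  excl[bad_o02] <- "o02_exceeds_o"
  # a partial dosage set already exceeding two haplotypes is a sum violation
  over <- is.na(excl) & !core_known &
    rowSums(cbind(d$d_A, d$d_B, d$d_O), na.rm = TRUE) > 2L
  excl[over] <- "dosage_sum"
  excl[is.na(excl) & !core_known] <- "missing"
  partial <- is.na(excl) & core_known & is.na(d$d_O02)
  if (!keep_partial) excl[partial] <- "missing"

  res <- resolve_diplotype(d$d_A, d$d_B, d$d_O, d$d_O02)
  res$genotype[!is.na(excl)] <- NA_character_
  res$blood_type[!is.na(excl)] <- NA_character_

  out <- cbind(samples[, c("sample_id", "status", "sex")],
               d[, c("d_A", "d_B", "d_O", "d_O02")],
               res, imputed = d$imputed, exclusion = excl)
  # dosages of excluded samples contribute nothing downstream
  out[!is.na(excl), c("d_A", "d_B", "d_O", "d_O02")] <- NA_integer_
  rownames(out) <- NULL
  attr(out, "exclusions") <- table(excl[!is.na(excl)])
  attr(out, "calls") <- pad_calls(calls, panel)
  attr(out, "panel") <- panel
  class(out) <- c("abo_cohort", "data.frame")
  out
}

#' @export
print.abo_cohort <- function(x, ...) {
  n <- nrow(x)
  n_case <- sum(x$status == "case")
  typed <- sum(!is.na(x$blood_type))
  full <- sum(!is.na(x$genotype))
  cat("ABO-typed cohort: ", n, " individuals (",
      n_case, " cases, ", n - n_case, " controls)\n", sep = "")
  cat("  blood-typed: ", typed, "; full diplotype: ", full,
      "; excluded: ", n - typed, "\n", sep = "")
  ex <- attr(x, "exclusions")
  if (length(ex) && sum(ex) > 0) {
    cat("  exclusions by reason:\n")
    for (r in names(ex)) cat("    ", r, ": ", ex[[r]], "\n", sep = "")
  }
  if (typed > 0) {
    cat("  blood types:\n")
    print(table(factor(x$blood_type, levels = BLOOD_TYPES), x$status))
  }
  invisible(x)
}

#' @export
summary.abo_cohort <- function(object, ...) {
  list(
    n = nrow(object),
    by_status = table(object$status),
    exclusions = attr(object, "exclusions"),
    genotype = table(factor(object$genotype, levels = GENOTYPE_CLASSES),
                     object$status),
    blood_type = table(factor(object$blood_type, levels = BLOOD_TYPES),
                       object$status)
  )
}
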