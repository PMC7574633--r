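#' Build a case-control 2x2 table from item counts
#'
#' The complement cells are taken against the full group denominators
#' (`b = n_case - count_case`, `d = n_ctrl - count_ctrl`), so an
#' individual not carrying the item -- including one untyped at a finer
#' level -- counts as "non-item".
#'
#' @param count_case,count_ctrl Item counts among cases and controls.
#' @param n_case,n_ctrl Group denominators (individuals, or chromosomes
#'   for allele-level counts).
#' @return Named numeric vector `c(a, b, c, d)`.
#' @examples
#' make_2x2(744, 2201, 736, 2330)
#' @export
make_2x2 <- function(count_case, n_case, count_ctrl, n_ctrl) {
  if (any(count_case > n_case) || any(count_ctrl > n_ctrl))
    stop("item count exceeds its denominator")
  if (any(c(count_case, n_case, count_ctrl, n_ctrl) < 0))
    stop("counts must be non-negative")
  c(a = count_case, b = n_case - count_case,
    c = count_ctrl, d = n_ctrl - count_ctrl)
}

#' Pearson chi-square test for a 2x2 table
#'
#' The uncorrected (no continuity correction) Pearson statistic
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on 1 degree of freedom,
#' identical to the classical expected-count form.
#'
#' @param a,b,c,d Cell counts: cases item / non-item, controls item /
#'   non-item.
#' @return List with `chi2` and two-sided `p`; both `NA` when a margin is
#'   zero (the statistic is undefined).
#' @examples
#' pearson_chi2(744, 1457, 736, 1594)  # chi2 ~ 2.52
#' @export
pearson_chi2 <- function(a, b, c, d) {
  n <- a + b + c + d
  m1 <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- ifelse(m1 > 0, n * (a * d - b * c)^2 / m1, NA_real_)
  list(chi2 = chi2,
       p = ifelse(is.na(chi2), NA_real_,
                  stats::pchisq(chi2, df = 1, lower.tail = FALSE)))
}

#' Odds ratio with Woolf (log-normal) confidence interval
#'
#' `OR = ad/(bc)` with CI `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' Tables with a zero cell get the Haldane--Anscombe 0.5 continuity
#' correction applied to all four cells (for the OR and CI only) and are
#' flagged.
#'
#' @inheritParams pearson_chi2
#' @param conf_level Confidence level (default 0.95).
#' @return List with `or`, `ci_low`, `ci_high`, `log_or`, `se` and
#'   `corrected` (`TRUE` when the 0.5 correction was applied).
#' @examples
#' odds_ratio_woolf(744, 1457, 736, 1594)  # OR ~ 1.11, CI 0.98-1.25
#' @export
odds_ratio_woolf <- function(a, b, c, d, conf_level = 0.95) {
  corrected <- (a == 0 | b == 0 | c == 0 | d == 0)
  a <- a + 0.5 * corrected; b <- b + 0.5 * corrected
  c <- c + 0.5 * corrected; d <- d + 0.5 * corrected
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  log_or <- log(a) + log(d) - log(b) - log(c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = exp(log_or),
       ci_low = exp(log_or - z * se),
       ci_high = exp(log_or + z * se),
       log_or = log_or, se = se, corrected = corrected)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Estimates the tag-allele frequency from the genotype counts and tests
#' observed against expected Hardy-Weinberg proportions
#' (`p^2 n`, `2p(1-p) n`, `(1-p)^2 n`) with a 1-df chi-square.
#'
#' @param n_hom_tag,n_het,n_hom_other Genotype counts: homozygous for the
#'   tag allele, heterozygous, homozygous for the other allele.
#' @return List with `n`, `p_hat`, `observed`, `expected`, `chi2`, `p`.
#'   `chi2`/`p` are `NA` for a monomorphic SNP (`p_hat` 0 or 1).
#' @examples
#' hwe_chi2(25, 50, 25)   # exact HW proportions: chi2 = 0
#' @export
hwe_chi2 <- function(n_hom_tag, n_het, n_hom_other) {
  n <- n_hom_tag + n_het + n_hom_other
  if (n <= 0) stop("empty genotype table")
  p_hat <- (2 * n_hom_tag + n_het) / (2 * n)
  obs <- c(hom_tag = n_hom_tag, het = n_het, hom_other = n_hom_other)
  if (p_hat %in% c(0, 1)) {
    return(list(n = n, p_hat = p_hat, observed = obs,
                expected = obs, chi2 = NA_real_, p = NA_real_))
  }
  expd <- n * c(p_hat^2, 2 * p_hat * (1 - p_hat), (1 - p_hat)^2)
  chi2 <- sum((obs - expd)^2 / expd)
  list(n = n, p_hat = p_hat, observed = obs,
       expected = stats::setNames(expd, names(obs)),
       chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Bonferroni correction
#'
#' @param p Uncorrected p-value(s).
#' @param m Family size (number of comparisons), `>= 1`.
#' @return `min(1, m * p)`.
#' @export
bonferroni <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, m * p)
}

# ---------------------------------------------------------------------------

stratum_filter <- function(x, stratum) {
  switch(stratum,
         total = rep(TRUE, nrow(x)),
         male = x$sex == "M",
         female = x$sex == "F",
         stop("unknown stratum: ", stratum))
}

# item counts for one level within a (sub)cohort; returns named vectors
# over the item labels for cases and controls plus denominators
level_counts <- function(cohort, level, calls, panel, denominators) {
  is_case <- cohort$status == "case"
  count_both <- function(v) {
    # v: per-sample numeric contribution per item (matrix samples x items)
    list(case = colSums(v[is_case, , drop = FALSE], na.rm = TRUE),
         ctrl = colSums(v[!is_case, , drop = FALSE], na.rm = TRUE))
  }
  if (level == "allele") {
    # per tag SNP, counting chromosomes
    m <- calls
    items <- paste0(panel$tagged_allele, " (", panel$snp_id, ")")
    colnames(m) <- items
    cnt <- count_both(m)
    if (denominators == "full") {
      den <- c(case = 2 * sum(is_case), ctrl = 2 * sum(!is_case))
      den <- list(case = rep(den[["case"]], length(items)),
                  ctrl = rep(den[["ctrl"]], length(items)))
    } else {
      ok <- !is.na(m)
      den <- list(case = 2 * colSums(ok & is_case),
                  ctrl = 2 * colSums(ok & !is_case))
    }
  } else {
    lab <- if (level == "genotype") cohort$genotype else cohort$blood_type
    levels_ <- if (level == "genotype") GENOTYPE_CLASSES else BLOOD_TYPES
    ind <- matrix(0, nrow(cohort), length(levels_),
                  dimnames = list(NULL, levels_))
    ok <- !is.na(lab)
    ind[ok, ] <- outer(lab[ok], levels_, `==`) + 0
    cnt <- count_both(ind)
    items <- levels_
    if (denominators == "full") {
      den <- list(case = rep(sum(is_case), length(items)),
                  ctrl = rep(sum(!is_case), length(items)))
    } else {
      den <- list(case = rep(sum(ok & is_case), length(items)),
                  ctrl = rep(sum(ok & !is_case), length(items)))
    }
  }
  list(items = items,
       cn = as.numeric(cnt$case), mn = as.numeric(cnt$ctrl),
       n_case = as.numeric(den$case), n_ctrl = as.numeric(den$ctrl))
}

assoc_rows <- function(items, stratum, cn, n_case, mn, n_ctrl,
                       correct_m, alpha, conf_level) {
  cf <- cn / n_case
  mf <- mn / n_ctrl
  a <- cn; b <- n_case - cn; c <- mn; d <- n_ctrl - mn
  x2 <- pearson_chi2(a, b, c, d)
  or <- odds_ratio_woolf(a, b, c, d, conf_level)
  p_corr <- rep(NA_real_, length(items))
  if (!is.na(correct_m)) {
    gate <- !is.na(x2$p) & x2$p < alpha
    p_corr[gate] <- bonferroni(x2$p[gate], correct_m)
  }
  data.frame(item = items, stratum = stratum,
             cn = cn, cf = cf, mn = mn, mf = mf,
             chi2 = x2$chi2, or = or$or,
             ci_low = or$ci_low, ci_high = or$ci_high,
             p = x2$p, p_corr = p_corr,
             stringsAsFactors = FALSE)
}

#' Case-control association tables at allele, genotype or phenotype level
#'
#' Reproduces the classical frequency-table layout: for every item at the
#' chosen level (8 tag SNPs at allele level, 10 diplotype classes, or 4
#' blood types) and every stratum (total, male, female), case and control
#' counts and frequencies, the uncorrected Pearson chi-square, the Woolf
#' odds ratio with 95% CI, the p-value, and -- at genotype and phenotype
#' level -- the Bonferroni-corrected p-value for rows whose uncorrected p
#' falls below `alpha` (other rows are reported "NT", not tested; the
#' family size is the number of items at the level). Frequencies use the
#' full stratum denominators by default (untyped individuals count in the
#' denominator and as "non-item"); `denominators = "typed"` restricts to
#' resolved samples.
#'
#' @param cohort An [type_cohort()] result (class `abo_cohort`).
#' @param level `"phenotype"` (default), `"genotype"` or `"allele"`.
#' @param strata Subset of `c("total", "male", "female")`.
#' @param denominators `"full"` (default) or `"typed"`.
#' @param alpha Significance gate for applying the correction (0.05).
#' @param conf_level CI level for the odds ratio.
#' @return An object of class `abo_assoc`: a data frame with columns
#'   `item`, `stratum`, `cn`, `cf`, `mn`, `mf`, `chi2`, `or`, `ci_low`,
#'   `ci_high`, `p`, `p_corr` and attributes `level`, `m` (Bonferroni
#'   family size, `NA` at allele level) and `alpha`.
#' @export
abo_association <- function(cohort,
                            level = c("phenotype", "genotype", "allele"),
                            strata = c("total", "male", "female"),
                            denominators = c("full", "typed"),
                            alpha = 0.05, conf_level = 0.95) {
  level <- match.arg(level)
  denominators <- match.arg(denominators)
  strata <- match.arg(strata, c("total", "male", "female"),
                      several.ok = TRUE)
  if (!inherits(cohort, "abo_cohort")) stop("`cohort` must be an abo_cohort")
  if (nrow(cohort) == 0) stop("empty cohort")
  panel <- attr(cohort, "panel")
  calls <- attr(cohort, "calls")

  m_items <- switch(level, allele = NA_real_,
                    genotype = length(GENOTYPE_CLASSES),
                    phenotype = length(BLOOD_TYPES))
  out <- NULL
  for (s in strata) {
    keep <- stratum_filter(cohort, s)
    lc <- level_counts(cohort[keep, , drop = FALSE], level,
                       calls[keep, , drop = FALSE], panel, denominators)
    out <- rbind(out, assoc_rows(lc$items, s, lc$cn, lc$n_case,
                                 lc$mn, lc$n_ctrl,
                                 m_items, alpha, conf_level))
  }
  # order rows item-major as in the published layout
  out <- out[order(match(out$item, unique(out$item)),
                   match(out$stratum, c("total", "male", "female"))), ]
  rownames(out) <- NULL
  structure(out, level = level, m = m_items, alpha = alpha,
            denominators = denominators,
            class = c("abo_assoc", "data.frame"))
}

#' Association statistics recomputed from published count tables
#'
#' Rebuilds every case-control comparison from item counts and stratum
#' denominators alone -- the form in which cohort results are published --
#' rather than from individual-level data. Used to verify that the
#' statistics pipeline reproduces printed tables.
#'
#' @param counts Data frame with columns `item`, `stratum`, `cn`, `mn` and
#'   optionally `level` (single level assumed otherwise).
#' @param strata_sizes Named list mapping stratum to `c(n_case, n_ctrl)`
#'   individual counts, e.g. `list(total = c(2201, 2330))`.
#' @param level Analysis level; allele-level denominators are doubled
#'   (chromosomes).
#' @param m Bonferroni family size (`NA` to skip correction).
#' @inheritParams abo_association
#' @return An `abo_assoc` data frame as in [abo_association()].
#' @export
association_from_counts <- function(counts, strata_sizes,
                                    level = c("phenotype", "genotype",
                                              "allele"),
                                    m = NULL, alpha = 0.05,
                                    conf_level = 0.95) {
  level <- match.arg(level)
  mult <- if (level == "allele") 2 else 1
  if (is.null(m))
    m <- switch(level, allele = NA_real_,
                genotype = length(GENOTYPE_CLASSES),
                phenotype = length(BLOOD_TYPES))
  unknown <- setdiff(unique(counts$stratum), names(strata_sizes))
  if (length(unknown))
    stop("no sizes for stratum: ", paste(unknown, collapse = ", "))
  sz <- do.call(rbind, strata_sizes[counts$stratum])
  if (is.null(sz)) sz <- matrix(numeric(0), 0, 2)
  out <- assoc_rows(counts$item, counts$stratum, counts$cn,
                    mult * sz[, 1], counts$mn, mult * sz[, 2],
                    m, alpha, conf_level)
  rownames(out) <- NULL
  structure(out, level = level, m = m, alpha = alpha,
            denominators = "full",
            class = c("abo_assoc", "data.frame"))
}

#' @export
print.abo_assoc <- function(x, ...) {
  cat("ABO case-control association, level = ", attr(x, "level"), "\n",
      sep = "")
  fmt <- data.frame(
    Item = x$item, Group = x$stratum,
    CN = x$cn, CF = sprintf("%.4f", x$cf),
    MN = x$mn, MF = sprintf("%.4f", x$mf),
    chi2 = sprintf("%.2f", x$chi2),
    OR = sprintf("%.2f", x$or),
    `CI95` = sprintf("%.2f-%.2f", x$ci_low, x$ci_high),
    P = sprintf("%.2f", x$p),
    check.names = FALSE
  )
  if (!is.na(attr(x, "m")))
    fmt$P_corr <- ifelse(is.na(x$p_corr), "NT", sprintf("%.2f", x$p_corr))
  print(fmt, row.names = FALSE)
  invisible(x)
}

#' Hardy-Weinberg equilibrium tests per tag SNP
#'
#' Runs [hwe_chi2()] for every panel SNP within each arm of the cohort
#' (and optionally sex strata), using samples with a non-missing call at
#' that SNP.
#'
#' @param cohort An `abo_cohort`.
#' @param strata Strata to test within (default both arms of the total
#'   cohort).
#' @return Data frame with one row per SNP x arm: `snp_id`, `arm`, `n`,
#'   genotype counts, `p_hat`, `chi2`, `p`.
#' @export
abo_hwe <- function(cohort, strata = "total") {
  calls <- attr(cohort, "calls")
  panel <- attr(cohort, "panel")
  out <- NULL
  for (s in strata) {
    keep <- stratum_filter(cohort, s)
    for (arm in c("case", "control")) {
      sub <- calls[keep & cohort$status == arm, , drop = FALSE]
      for (snp in panel$snp_id) {
        g <- sub[, snp]
        g <- g[!is.na(g)]
        counts <- c(sum(g == 2L), sum(g == 1L), sum(g == 0L))
        if (sum(counts) == 0) next
        h <- hwe_chi2(counts[1], counts[2], counts[3])
        out <- rbind(out, data.frame(
          snp_id = snp, stratum = s, arm = arm, n = h$n,
          n_hom_tag = counts[1], n_het = counts[2], n_hom_other = counts[3],
          p_hat = h$p_hat, chi2 = h$chi2, p = h$p,
          stringsAsFactors = FALSE))
      }
    }
  }
  rownames(out) <- NULL
  out
}
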