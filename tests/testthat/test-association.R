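test_that("pearson chi-square matches the brute-force expected-count form", {
  set.seed(11)
  for (i in 1:50) {
    t <- rpois(4, lambda = sample(c(20, 200, 2000), 1)) + 1
    a <- t[1]; b <- t[2]; c <- t[3]; d <- t[4]
    n <- sum(t)
    # oracle: sum over cells of (obs - exp)^2 / exp
    obs <- matrix(c(a, b, c, d), 2, byrow = TRUE)
    expd <- outer(rowSums(obs), colSums(obs)) / n
    oracle <- sum((obs - expd)^2 / expd)
    got <- pearson_chi2(a, b, c, d)
    expect_equal(got$chi2, oracle, tolerance = 1e-12)
    # and against the standard uncorrected test
    ref <- suppressWarnings(stats::chisq.test(obs, correct = FALSE))
    expect_equal(got$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("chi-square anchors and degenerate tables behave as specified", {
  expect_equal(pearson_chi2(744, 1457, 736, 1594)$chi2, 2.52,
               tolerance = 0.01 / 2.52)
  expect_equal(pearson_chi2(189, 2012, 212, 2118)$chi2, 0.37,
               tolerance = 0.01 / 0.37)
  # independence: ad = bc
  x <- pearson_chi2(10, 20, 30, 60)
  expect_equal(x$chi2, 0)
  expect_equal(x$p, 1)
  # zero margin: undefined
  expect_true(is.na(pearson_chi2(0, 0, 5, 5)$chi2))
})

test_that("Woolf odds ratio and CI reproduce published anchors", {
  w <- odds_ratio_woolf(744, 1457, 736, 1594)
  expect_equal(w$or, 1.11, tolerance = 0.01)
  expect_equal(w$ci_low, 0.98, tolerance = 0.01)
  expect_equal(w$ci_high, 1.25, tolerance = 0.01)
  expect_equal(odds_ratio_woolf(223, 917, 356, 1230)$or, 0.84,
               tolerance = 0.01)
})

test_that("odds ratio obeys symmetry, inversion and monotonicity", {
  k <- 17
  w <- odds_ratio_woolf(k, k, k, k)
  expect_equal(w$or, 1)
  expect_equal(log(w$ci_high), -log(w$ci_low))  # symmetric on log scale
  set.seed(5)
  for (i in 1:20) {
    t <- rpois(4, 80) + 1
    o1 <- odds_ratio_woolf(t[1], t[2], t[3], t[4])$or
    o2 <- odds_ratio_woolf(t[3], t[4], t[1], t[2])$or
    expect_equal(o1 * o2, 1, tolerance = 1e-12)
  }
  # increasing a with all margins fixed increases the OR
  ors <- sapply(5:15, function(a)
    odds_ratio_woolf(a, 20 - a, 25 - a, 35 + a)$or)
  expect_true(all(diff(ors) > 0))
})

test_that("zero cells get the Haldane-Anscombe correction and a flag", {
  w <- odds_ratio_woolf(0, 10, 5, 5)
  expect_true(w$corrected)
  expect_equal(w$or, (0.5 * 5.5) / (10.5 * 5.5))
  expect_true(is.finite(w$ci_low) && is.finite(w$ci_high))
  expect_false(odds_ratio_woolf(1, 10, 5, 5)$corrected)
})

test_that("HWE chi-square is exact on perfect proportions and extremes", {
  expect_equal(hwe_chi2(25, 50, 25)$chi2, 0)
  # all-homozygote extreme: p = 0.5, expected het = n/2, chi2 = n
  expect_equal(hwe_chi2(50, 0, 50)$chi2, 100)
  # monomorphic: not applicable
  expect_true(is.na(hwe_chi2(0, 0, 120)$chi2))
  expect_true(is.na(hwe_chi2(120, 0, 0)$chi2))
  # observed and expected totals agree
  h <- hwe_chi2(30, 44, 26)
  expect_equal(sum(h$expected), sum(h$observed))
})

test_that("bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(0.04, 10), 0.40)
  expect_equal(bonferroni(0.5, 4), 1.0)
  expect_equal(bonferroni(0.123, 1), 0.123)
})

test_that("2x2 construction uses full-cohort complements", {
  expect_equal(make_2x2(744, 2201, 736, 2330),
               c(a = 744, b = 1457, c = 736, d = 1594))
  expect_equal(make_2x2(0, 10, 0, 10), c(a = 0, b = 10, c = 0, d = 10))
  expect_equal(unname(make_2x2(5, 5, 3, 3))[c(2, 4)], c(0, 0))
  expect_error(make_2x2(11, 10, 3, 5), "exceeds")
})

test_that("published Table 3 total odds ratios reproduce", {
  r <- association_from_counts(abo_reference_counts("phenotype"),
                               abo_reference_strata(), "phenotype")
  tot <- r[r$stratum == "total", ]
  expect_equal(round(tot$or[match(c("A", "B", "O", "AB"), tot$item)], 2),
               c(1.02, 0.91, 1.11, 0.94))
})

test_that("correction is gated on the uncorrected p and family size", {
  r <- association_from_counts(abo_reference_counts("genotype"),
                               abo_reference_strata(), "genotype")
  gate <- !is.na(r$p) & r$p < 0.05
  expect_equal(!is.na(r$p_corr), gate)
  expect_equal(r$p_corr[gate], pmin(1, 10 * r$p[gate]))
  expect_true(all(r$p_corr[gate] >= r$p[gate]))
  # the B/O02 rows are the only sub-0.05 genotype rows, and neither
  # survives correction
  expect_equal(r$item[gate], c("B/O02", "B/O02"))
  expect_true(all(r$p_corr[gate] > 0.05))
})

test_that("single-sex cohorts make the total stratum equal that sex", {
  set.seed(9)
  sim <- simulate_cohort(n_case = 150, n_ctrl = 150,
                         sex_ratio_case = 0, sex_ratio_ctrl = 0)
  co <- type_cohort(sim$calls, sim$samples)
  a <- abo_association(co, "phenotype", strata = c("total", "female"))
  tot <- a[a$stratum == "total", -2]
  fem <- a[a$stratum == "female", -2]
  rownames(tot) <- rownames(fem) <- NULL
  expect_equal(tot, fem, ignore_attr = TRUE)
})

test_that("typed-only denominators shrink with exclusions, full stay put", {
  dip <- all_diplotypes()
  calls <- calls_for_diplotypes(dip$hap1, dip$hap2)
  calls <- rbind(calls, calls)
  panel <- abo_panel()
  calls[1, panel$snp_id[panel$tagged_allele == "B"]] <- c(0L, 1L, 2L)
  sheet <- sample_sheet_for(20, status = rep(c("case", "control"), 10))
  co <- type_cohort(calls, sheet)
  full <- abo_association(co, "phenotype", strata = "total",
                          denominators = "full")
  typed <- abo_association(co, "phenotype", strata = "total",
                           denominators = "typed")
  # one of 10 cases is excluded: full denominators keep it as "non-item"
  expect_equal(sum(full$cf), 9 / 10)
  expect_equal(sum(full$mf), 1)
  # typed-only denominators renormalise over the 9 resolvable cases
  expect_equal(sum(typed$cf), 1)
  expect_equal(typed$cn, full$cn)
})

test_that("HWE over a simulated cohort is computed per SNP and arm", {
  set.seed(31)
  sim <- simulate_cohort(n_case = 500, n_ctrl = 500)
  co <- type_cohort(sim$calls, sim$samples)
  h <- abo_hwe(co)
  expect_equal(nrow(h), 16)   # 8 SNPs x 2 arms
  expect_true(all(h$n_hom_tag + h$n_het + h$n_hom_other == h$n))
  expect_true(all(h$chi2 >= 0, na.rm = TRUE))
  # large HW-sampled arms should rarely reject; sanity, not calibration
  expect_gt(min(h$p, na.rm = TRUE), 1e-4)
})
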