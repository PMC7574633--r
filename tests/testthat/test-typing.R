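test_that("feasible dosage vectors map bijectively onto the 10 genotype classes", {
  # brute force: every (d_A, d_B, d_O, d_O02) in 0..2^4
  g <- expand.grid(d_A = 0:2, d_B = 0:2, d_O = 0:2, d_O02 = 0:2)
  feas <- g$d_A + g$d_B + g$d_O == 2 & g$d_O02 <= g$d_O
  expect_equal(sum(feas), 10)

  res <- resolve_diplotype(g$d_A, g$d_B, g$d_O, g$d_O02)
  expect_true(all(is.na(res$genotype[!feas])))
  expect_setequal(res$genotype[feas], GENOTYPE_CLASSES)
  expect_equal(anyDuplicated(res$genotype[feas]), 0)

  # independent phenotype oracle from the class label itself
  label_type <- function(lab) {
    h <- strsplit(lab, "/", fixed = TRUE)[[1]]
    has_a <- "A" %in% h; has_b <- "B" %in% h
    if (has_a && has_b) "AB" else if (has_a) "A"
    else if (has_b) "B" else "O"
  }
  expect_equal(res$blood_type[feas],
               unname(vapply(res$genotype[feas], label_type,
                             character(1))))
})

test_that("documented dosage resolutions hold", {
  expect_equal(resolve_diplotype(1, 0, 1, 1),
               data.frame(genotype = "A/O02", blood_type = "A"))
  expect_equal(resolve_diplotype(0, 0, 2, 0),
               data.frame(genotype = "O01/O01", blood_type = "O"))
  expect_equal(resolve_diplotype(1, 1, 0, 0),
               data.frame(genotype = "A/B", blood_type = "AB"))
  expect_equal(resolve_diplotype(0, 0, 2, 1)$genotype, "O01/O02")
})

test_that("concordant full calls give the expected allele dosages", {
  panel <- abo_panel()
  # A-SNP het + one tag copy on each B SNP, O and O02 tag-free
  calls <- calls_for_diplotypes("A", "B")
  d <- allele_dosages(calls, panel)
  expect_equal(unname(unlist(d[1, c("d_A", "d_B", "d_O", "d_O02")])),
               c(1L, 1L, 0L, 0L))
  # O hom tag, O02 SNPs one tag copy each
  d2 <- allele_dosages(calls_for_diplotypes("O01", "O02"), panel)
  expect_equal(unname(unlist(d2[1, c("d_A", "d_B", "d_O", "d_O02")])),
               c(0L, 0L, 2L, 1L))
  expect_false(d$discordant[1] || d2$discordant[1])
})

test_that("unanimity rejects exactly the non-constant redundant tag patterns", {
  panel <- abo_panel()
  b_cols <- panel$snp_id[panel$tagged_allele == "B"]
  pats <- expand.grid(0:2, 0:2, 0:2)
  base <- calls_for_diplotypes(rep("O01", nrow(pats)),
                               rep("O01", nrow(pats)))
  base[, b_cols] <- as.matrix(pats)
  d <- allele_dosages(base, panel, consensus = "unanimous")
  constant <- pats[, 1] == pats[, 2] & pats[, 2] == pats[, 3]
  expect_equal(d$discordant, !constant)
  expect_equal(d$d_B[constant], pats[constant, 1])
  expect_true(all(is.na(d$d_B[!constant])))
})

test_that("majority policy takes the modal call and rejects ties", {
  panel <- abo_panel()
  b_cols <- panel$snp_id[panel$tagged_allele == "B"]
  base <- calls_for_diplotypes(rep("O01", 3), rep("O01", 3))
  base[1, b_cols] <- c(1L, 1L, 2L)   # majority 1
  base[2, b_cols] <- c(0L, 1L, 2L)   # three-way tie
  base[3, b_cols] <- c(2L, 2L, 2L)   # unanimous
  d <- allele_dosages(base, panel, consensus = "majority")
  expect_equal(d$d_B, c(1L, NA, 2L))
  expect_equal(d$discordant, c(FALSE, TRUE, FALSE))
  # unanimity rejects the first pattern
  du <- allele_dosages(base, panel, consensus = "unanimous")
  expect_true(du$discordant[1])
})

test_that("dosages forced by the diploid sum constraint are imputed and flagged", {
  panel <- abo_panel()
  a_col <- panel$snp_id[panel$tagged_allele == "A"]
  o_col <- panel$snp_id[panel$tagged_allele == "O"]
  b_cols <- panel$snp_id[panel$tagged_allele == "B"]
  o2_cols <- panel$snp_id[panel$tagged_allele == "O02"]

  # A call missing, B and O known: d_A = 2 - 1 - 1 = 0
  m <- calls_for_diplotypes("B", "O01")
  m[, a_col] <- NA
  d <- allele_dosages(m, panel)
  expect_equal(d$d_A, 0L)
  expect_true(d$imputed)

  # known dosages already sum to 2: both missing dosages forced to 0
  m2 <- calls_for_diplotypes("A", "A")
  m2[, c(b_cols, o_col)] <- NA
  d2 <- allele_dosages(m2, panel)
  expect_equal(unname(unlist(d2[1, c("d_A", "d_B", "d_O")])),
               c(2L, 0L, 0L))
  expect_true(d2$imputed)

  # d_O = 0 forces d_O02 = 0
  m3 <- calls_for_diplotypes("A", "B")
  m3[, o2_cols] <- NA
  d3 <- allele_dosages(m3, panel)
  expect_equal(d3$d_O02, 0L)

  # two missing among A/B/O with known sum < 2: underdetermined
  m4 <- calls_for_diplotypes("A", "O01")
  m4[, c(a_col, o_col)] <- NA
  d4 <- allele_dosages(m4, panel)
  expect_true(is.na(d4$d_A) && is.na(d4$d_O))
  expect_false(d4$imputed)
})

test_that("noise-free cohorts covering all 10 classes round-trip exactly", {
  dip <- all_diplotypes()
  calls <- calls_for_diplotypes(dip$hap1, dip$hap2)
  co <- type_cohort(calls, sample_sheet_for(nrow(dip)))
  expect_equal(co$genotype, dip$genotype)
  expect_equal(co$blood_type, dip$blood_type)
  expect_true(all(is.na(co$exclusion)))
  expect_equal(sum(attr(co, "exclusions")), 0)
})

test_that("exclusions are per-sample and counted by reason", {
  dip <- all_diplotypes()
  calls <- calls_for_diplotypes(dip$hap1, dip$hap2)
  panel <- abo_panel()
  b_cols <- panel$snp_id[panel$tagged_allele == "B"]
  calls[4, b_cols] <- c(1L, 1L, 2L)                 # discordant B tags
  co <- type_cohort(calls, sample_sheet_for(nrow(dip)))
  expect_equal(unname(attr(co, "exclusions")[["discordant_tags"]]), 1)
  expect_equal(co$exclusion[4], "discordant_tags")
  expect_true(all(is.na(co$genotype[4])))
  expect_equal(co$genotype[-4], dip$genotype[-4])

  # dosage-sum violation: an extra tag copy everywhere
  calls2 <- calls_for_diplotypes("A", "B")
  a_col <- panel$snp_id[panel$tagged_allele == "A"]
  calls2[, a_col] <- 2L
  co2 <- type_cohort(calls2, sample_sheet_for(1))
  expect_equal(co2$exclusion, "dosage_sum")

  # O02 dosage exceeding O dosage
  calls3 <- calls_for_diplotypes("A", "B")
  o2_cols <- panel$snp_id[panel$tagged_allele == "O02"]
  calls3[, o2_cols] <- 1L
  co3 <- type_cohort(calls3, sample_sheet_for(1))
  expect_equal(co3$exclusion, "o02_exceeds_o")
})

test_that("O-typed samples with unresolved O02 keep their blood type", {
  panel <- abo_panel()
  o2_cols <- panel$snp_id[panel$tagged_allele == "O02"]
  calls <- calls_for_diplotypes("O01", "O02")
  calls[, o2_cols] <- NA
  co <- type_cohort(calls, sample_sheet_for(1))
  expect_true(is.na(co$genotype))
  expect_equal(co$blood_type, "O")
  expect_true(is.na(co$exclusion))
  co2 <- type_cohort(calls, sample_sheet_for(1), keep_partial = FALSE)
  expect_equal(co2$exclusion, "missing")
  expect_true(is.na(co2$blood_type))
})

test_that("missingness without error never mistypes, only excludes", {
  set.seed(42)
  sim <- simulate_cohort(n_case = 400, n_ctrl = 400, missing_rate = 0.15)
  co <- type_cohort(sim$calls, sim$samples)
  typed <- !is.na(co$blood_type)
  expect_equal(co$blood_type[typed], sim$truth$blood_type[typed])
  full <- !is.na(co$genotype)
  expect_equal(co$genotype[full], sim$truth$genotype[full])
  # every exclusion must stem from a missing call
  excluded <- !is.na(co$exclusion)
  expect_true(all(co$exclusion[excluded] == "missing"))
  has_missing <- rowSums(is.na(sim$calls)) > 0
  expect_true(all(has_missing[excluded]))
  # phenotype partition: types + untyped account for everyone
  expect_equal(sum(table(co$blood_type)) + sum(!typed), nrow(co))
})
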