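#' Default ABO haplotype frequencies
#'
#' Haplotype frequencies estimated from the reference control arm
#' (middle-aged Chinese controls): the `O` frequency is split into `O01`
#' and `O02` using the per-SNP tag counts, and `B` absorbs the remainder
#' so the vector sums to one. Used as the generator's null (both arms)
#' default.
#'
#' @return Named numeric vector over `c("A", "B", "O01", "O02")` summing
#'   to 1.
#' @export
abo_default_freqs <- function() {
  c(A = 0.2103, B = 0.2219, O01 = 0.3197, O02 = 0.2481)
}

check_freqs <- function(p, arm) {
  if (!all(ABO_HAPLOTYPES %in% names(p)))
    stop(arm, " frequencies must be named over ",
         paste(ABO_HAPLOTYPES, collapse = ", "))
  p <- p[ABO_HAPLOTYPES]
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop(arm, " frequencies must be non-negative and sum to 1")
  p
}

# 0/1 matrix: does haplotype (row) carry the tag base at panel SNP (col)?
hap_contrib <- function(panel) {
  m <- rbind(
    A   = as.integer(panel$tagged_allele == "A"),
    B   = as.integer(panel$tagged_allele == "B"),
    O01 = as.integer(panel$tagged_allele == "O"),
    O02 = as.integer(panel$tagged_allele %in% c("O", "O02"))
  )
  colnames(m) <- panel$snp_id
  m
}

#' Expand ABO diplotypes to tag-SNP dosages
#'
#' The deterministic inverse of the typing map: an `A` haplotype carries
#' the tag base at the A SNP only, `B` at all B SNPs, `O01` at the O SNP
#' only, and `O02` at the O SNP and all O02 SNPs. Summing the two
#' haplotypes' contributions gives each individual's per-SNP tag dosage.
#'
#' @param hap1,hap2 Character vectors of haplotype labels from
#'   `c("A", "B", "O01", "O02")`.
#' @param panel An [abo_panel()].
#' @return Integer matrix (individuals x panel SNPs) of tag dosages.
#' @examples
#' diplotype_to_tags("A", "B")      # het tag at the A SNP and all B SNPs
#' diplotype_to_tags("O01", "O02")  # hom tag at the O SNP, het at O02 SNPs
#' @export
diplotype_to_tags <- function(hap1, hap2, panel = abo_panel()) {
  stopifnot(length(hap1) == length(hap2),
            all(hap1 %in% ABO_HAPLOTYPES), all(hap2 %in% ABO_HAPLOTYPES))
  H <- hap_contrib(panel)
  calls <- H[hap1, , drop = FALSE] + H[hap2, , drop = FALSE]
  rownames(calls) <- NULL
  storage.mode(calls) <- "integer"
  calls
}

#' Simulate a case-control cohort of ABO-typed individuals
#'
#' Draws each individual's two ABO haplotypes i.i.d. from the arm's
#' frequency vector (Hardy--Weinberg proportions), expands them to
#' tag-SNP dosages via [diplotype_to_tags()], then applies per-call
#' genotyping error (each of the two allele copies flips tag/non-tag
#' independently with probability `error_rate`) and per-call missingness.
#' With equal arm frequencies the generator is a null model for the
#' association stage; a case-arm effect is configured directly as a case
#' frequency vector (see [case_freqs_for_or()] to derive one from a
#' target blood-type odds ratio).
#'
#' @param n_case,n_ctrl Arm sizes (defaults mirror the reference cohort:
#'   2201 cases, 2330 controls).
#' @param freqs_control Named haplotype frequencies for controls.
#' @param freqs_case Case-arm frequencies; defaults to `freqs_control`.
#' @param sex_ratio_case,sex_ratio_ctrl Proportion of males per arm
#'   (defaults mirror the reference cohort); sex is independent of
#'   genotype.
#' @param missing_rate,error_rate Per-call probabilities in `[0, 1]`.
#' @param seed Optional integer; fixing it makes the cohort (and any VCF
#'   written from it) fully reproducible.
#' @param panel An [abo_panel()].
#' @return An object of class `abo_sim`: list with `samples` (sample
#'   sheet: `sample_id`, `status`, `sex`), `calls` (individuals x SNPs tag
#'   dosages, `NA` = missing), `truth` (per-individual `hap1`, `hap2`,
#'   `genotype`, `blood_type`), `panel` and `config`.
#' @examples
#' sim <- simulate_cohort(n_case = 100, n_ctrl = 100, seed = 1)
#' table(sim$truth$blood_type, sim$samples$status)
#' @export
simulate_cohort <- function(n_case = 2201, n_ctrl = 2330,
                            freqs_control = abo_default_freqs(),
                            freqs_case = freqs_control,
                            sex_ratio_case = 570 / 2201,
                            sex_ratio_ctrl = 793 / 2330,
                            missing_rate = 0, error_rate = 0,
                            seed = NULL, panel = abo_panel()) {
  freqs_control <- check_freqs(freqs_control, "control")
  freqs_case <- check_freqs(freqs_case, "case")
  stopifnot(n_case >= 0, n_ctrl >= 0,
            missing_rate >= 0, missing_rate <= 1,
            error_rate >= 0, error_rate <= 1,
            sex_ratio_case >= 0, sex_ratio_case <= 1,
            sex_ratio_ctrl >= 0, sex_ratio_ctrl <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- n_case + n_ctrl
  status <- rep(c("case", "control"), c(n_case, n_ctrl))

  draw <- function(k, p) ABO_HAPLOTYPES[sample.int(4L, k, replace = TRUE,
                                                   prob = p)]
  hap1 <- c(draw(n_case, freqs_case), draw(n_ctrl, freqs_control))
  hap2 <- c(draw(n_case, freqs_case), draw(n_ctrl, freqs_control))
  sex <- ifelse(stats::runif(n) < c(rep(sex_ratio_case, n_case),
                                    rep(sex_ratio_ctrl, n_ctrl)),
                "M", "F")

  calls <- diplotype_to_tags(hap1, hap2, panel)
  if (error_rate > 0) {
    g <- as.vector(calls)
    g <- g - stats::rbinom(length(g), g, error_rate) +
      stats::rbinom(length(g), 2L - g, error_rate)
    calls[] <- as.integer(g)
  }
  if (missing_rate > 0)
    calls[stats::runif(length(calls)) < missing_rate] <- NA_integer_

  # truth labels via the same pure resolution map
  dt <- resolve_diplotype(
    (hap1 == "A") + (hap2 == "A"),
    (hap1 == "B") + (hap2 == "B"),
    (hap1 %in% c("O01", "O02")) + (hap2 %in% c("O01", "O02")),
    (hap1 == "O02") + (hap2 == "O02"))

  samples <- data.frame(
    sample_id = sprintf("S%05d", seq_len(n)),
    status = status, sex = sex, stringsAsFactors = FALSE)
  rownames(calls) <- samples$sample_id
  truth <- data.frame(sample_id = samples$sample_id,
                      hap1 = hap1, hap2 = hap2,
                      genotype = dt$genotype, blood_type = dt$blood_type,
                      stringsAsFactors = FALSE)
  structure(list(samples = samples, calls = calls, truth = truth,
                 panel = panel,
                 config = list(n_case = n_case, n_ctrl = n_ctrl,
                               freqs_control = freqs_control,
                               freqs_case = freqs_case,
                               sex_ratio_case = sex_ratio_case,
                               sex_ratio_ctrl = sex_ratio_ctrl,
                               missing_rate = missing_rate,
                               error_rate = error_rate, seed = seed)),
            class = "abo_sim")
}

#' @export
print.abo_sim <- function(x, ...) {
  cfg <- x$config
  cat("Simulated ABO cohort: ", cfg$n_case, " cases + ", cfg$n_ctrl,
      " controls\n", sep = "")
  cat("  control freqs: ",
      paste(sprintf("%s=%.4f", names(cfg$freqs_control),
                    cfg$freqs_control), collapse = ", "), "\n", sep = "")
  if (!identical(cfg$freqs_case, cfg$freqs_control))
    cat("  case freqs:    ",
        paste(sprintf("%s=%.4f", names(cfg$freqs_case), cfg$freqs_case),
              collapse = ", "), "\n", sep = "")
  cat("  missing rate ", cfg$missing_rate, ", error rate ",
      cfg$error_rate, "\n", sep = "")
  invisible(x)
}

#' Blood-type probabilities under Hardy-Weinberg proportions
#'
#' @param freqs Named haplotype frequency vector.
#' @return Named probabilities of blood types A, B, O, AB.
#' @export
blood_type_probs <- function(freqs) {
  p <- check_freqs(freqs, "input")
  pO <- p[["O01"]] + p[["O02"]]
  c(A = p[["A"]]^2 + 2 * p[["A"]] * pO,
    B = p[["B"]]^2 + 2 * p[["B"]] * pO,
    O = pO^2,
    AB = 2 * p[["A"]] * p[["B"]])
}

#' Case-arm frequencies realising a target blood-type odds ratio
#'
#' Finds case haplotype frequencies whose Hardy--Weinberg blood-type
#' probability gives the requested population odds ratio for one blood
#' type versus the rest, relative to the control frequencies. The
#' frequency (or frequencies, for O and AB) of the alleles defining the
#' target type is scaled by a common factor, the remaining alleles are
#' renormalised proportionally, and the factor is solved by
#' [stats::uniroot()] -- the odds ratio is continuous and monotone in the
#' scale, so the root is unique.
#'
#' @param target_or Desired odds ratio (case vs control odds of carrying
#'   the blood type).
#' @param blood_type `"A"`, `"B"`, `"O"` or `"AB"`.
#' @param freqs_control Control haplotype frequencies.
#' @return Named case frequency vector summing to 1.
#' @examples
#' f <- case_freqs_for_or(1.5, "O")
#' p1 <- blood_type_probs(f)[["O"]]
#' p0 <- blood_type_probs(abo_default_freqs())[["O"]]
#' (p1 / (1 - p1)) / (p0 / (1 - p0))   # 1.5
#' @export
case_freqs_for_or <- function(target_or, blood_type = "O",
                              freqs_control = abo_default_freqs()) {
  stopifnot(target_or > 0, blood_type %in% BLOOD_TYPES)
  p0 <- check_freqs(freqs_control, "control")
  scale_alleles <- switch(blood_type,
                          A = "A", B = "B",
                          O = c("O01", "O02"), AB = c("A", "B"))
  scaled <- function(t) {
    p <- p0
    p[scale_alleles] <- p[scale_alleles] * t
    rest <- setdiff(ABO_HAPLOTYPES, scale_alleles)
    p[rest] <- p[rest] * (1 - sum(p[scale_alleles])) / sum(p0[rest])
    p
  }
  q0 <- blood_type_probs(p0)[[blood_type]]
  odds0 <- q0 / (1 - q0)
  f <- function(t) {
    q <- blood_type_probs(scaled(t))[[blood_type]]
    q / (1 - q) / odds0 - target_or
  }
  upper <- 0.999 / sum(p0[scale_alleles])
  t_star <- stats::uniroot(f, c(1e-6, upper), tol = 1e-12)$root
  scaled(t_star)
}
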