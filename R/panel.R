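#' Tag-SNP panel for ABO allele inference
#'
#' The ABO blood-group locus has four common haplotype classes -- `A`, `B`,
#' `O01` and `O02` -- each of which is marked deterministically by one or more
#' tag SNPs: rs507666 tags `A`; rs8176743, rs8176746 and rs8176749 redundantly
#' tag `B`; rs687289 tags `O` (either subtype); and rs688976, rs549446 and
#' rs512770 redundantly tag `O02`. Carriers of `O` without an `O02` tag are
#' assigned the `O01` subtype.
#'
#' `abo_panel()` returns the shipped default panel as a data frame with one
#' row per SNP. The `tag_base` column gives the nucleotide whose dosage
#' (0, 1 or 2 copies) counts the tagged allele; `ref`/`alt` give the VCF
#' orientation the simulator writes and the reader expects, and `chrom`/`pos`
#' place the records on chromosome 9 (positions are illustrative coordinates
#' within the ABO locus, used only to emit a sorted VCF).
#'
#' @param file Optional path to a TSV with columns `snp_id`, `tagged_allele`,
#'   `tag_base` (and optionally `chrom`, `pos`, `ref`, `alt`) overriding the
#'   default panel.
#' @return A data frame of class `abo_panel` with columns `snp_id`,
#'   `tagged_allele`, `chrom`, `pos`, `ref`, `alt`, `tag_base`.
#' @examples
#' abo_panel()
#' @export
abo_panel <- function(file = NULL) {
  if (is.null(file)) {
    panel <- data.frame(
      snp_id        = c("rs507666",
                        "rs8176743", "rs8176746", "rs8176749",
                        "rs687289",
                        "rs688976", "rs549446", "rs512770"),
      tagged_allele = c("A", "B", "B", "B", "O", "O02", "O02", "O02"),
      chrom         = "9",
      pos           = c(136149399L,
                        136131651L, 136131461L, 136131322L,
                        136137106L,
                        136133506L, 136133424L, 136133392L),
      ref           = c("G", "G", "C", "G", "A", "G", "G", "C"),
      alt           = c("A", "A", "A", "A", "G", "T", "A", "T"),
      tag_base      = c("A", "A", "A", "A", "G", "T", "A", "T"),
      stringsAsFactors = FALSE
    )
  } else {
    panel <- utils::read.delim(file, stringsAsFactors = FALSE)
    req <- c("snp_id", "tagged_allele", "tag_base")
    if (!all(req %in% names(panel)))
      stop("panel file must have columns: ", paste(req, collapse = ", "))
    if (is.null(panel$chrom)) panel$chrom <- "9"
    if (is.null(panel$pos))   panel$pos   <- seq_len(nrow(panel))
    if (is.null(panel$ref))   panel$ref   <- "N"
    if (is.null(panel$alt))   panel$alt   <- panel$tag_base
  }
  validate_panel(panel)
}

#' @keywords internal
validate_panel <- function(panel) {
  if (anyDuplicated(panel$snp_id))
    stop("panel snp_ids must be unique")
  bad <- setdiff(unique(panel$tagged_allele), c("A", "B", "O", "O02"))
  if (length(bad))
    stop("unknown tagged_allele: ", paste(bad, collapse = ", "))
  n <- table(factor(panel$tagged_allele, levels = c("A", "B", "O", "O02")))
  if (n[["A"]] != 1L) stop("panel must have exactly one SNP tagging allele A")
  if (n[["O"]] != 1L) stop("panel must have exactly one SNP tagging allele O")
  if (n[["B"]] < 1L)  stop("panel must have at least one SNP tagging allele B")
  if (n[["O02"]] < 1L) stop("panel must have at least one SNP tagging allele O02")
  panel <- panel[order(panel$chrom, panel$pos), , drop = FALSE]
  rownames(panel) <- NULL
  class(panel) <- c("abo_panel", "data.frame")
  panel
}

# column indices of the calls matrix for one tagged allele
panel_cols <- function(panel, allele) which(panel$tagged_allele == allele)
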