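#' Locus categories
#'
#' The four parental genotype categories used throughout: `AAAA` (both parents
#' homozygous), `AAAB` (mother homozygous, father heterozygous), `ABAA`
#' (mother heterozygous, father homozygous), `ABAB` (both heterozygous). The
#' labels are symbolic: a homozygous-alt parent plays the same role as a
#' homozygous-ref one (the category depends only on heterozygosity), so e.g. a
#' mother-AA / father-BB site falls in `AAAA`.
#'
#' @format A character vector of length 4.
#' @export
LOCUS_CATEGORIES <- c("AAAA", "AAAB", "ABAA", "ABAB")

#' Classify a locus by parental genotypes
#'
#' Genotypes are encoded as alt-allele dosage: 0 (hom ref), 1 (het), 2
#' (hom alt). The category is a pure function of parental heterozygosity,
#' which makes it invariant under simultaneous ref/alt relabelling
#' (dosage `g -> 2 - g` for both parents).
#'
#' @param maternal_gt,paternal_gt integer vectors of alt-allele dosages
#'   (0, 1 or 2), recycled to a common length.
#' @return character vector of categories (see [LOCUS_CATEGORIES]).
#' @examples
#' classify_locus(0, 1)  # "AAAB"
#' classify_locus(1, 0)  # "ABAA"
#' classify_locus(0, 2)  # "AAAA": both homozygous, obligate-het fetus
#' @export
classify_locus <- function(maternal_gt, paternal_gt) {
  if (!all(maternal_gt %in% 0:2, na.rm = FALSE) ||
      !all(paternal_gt %in% 0:2, na.rm = FALSE)) {
    stop("genotypes must be alt-allele dosages in {0, 1, 2}")
  }
  mat_het <- maternal_gt == 1L
  pat_het <- paternal_gt == 1L
  ifelse(mat_het,
         ifelse(pat_het, "ABAB", "ABAA"),
         ifelse(pat_het, "AAAB", "AAAA"))
}

#' Merge parental site tables into a locus table
#'
#' Joins the maternal and paternal per-site tables (as returned by
#' [read_parental_vcf()] or produced by [simulate_family()]) on
#' (chrom, pos, ref, alt), keeping only sites genotyped in both parents over
#' the same allele pair, and assigns the locus category. Sites present in only
#' one parent, or called over different alt alleles, are dropped; the number
#' dropped is reported via `attr(., "n_dropped")`.
#'
#' @param maternal,paternal tibbles with columns
#'   `chrom, pos, ref, alt, vclass, gt, h1, h2, block`.
#' @return tibble with columns `chrom, pos, ref, alt, vclass`,
#'   `mat_gt, mat_h1, mat_h2, mat_block`, `pat_gt, pat_h1, pat_h2, pat_block`
#'   and `category`.
#' @export
build_loci <- function(maternal, paternal) {
  need <- c("chrom", "pos", "ref", "alt", "vclass", "gt", "h1", "h2", "block")
  stopifnot(all(need %in% names(maternal)), all(need %in% names(paternal)))
  m <- dplyr::rename(maternal, mat_gt = "gt", mat_h1 = "h1", mat_h2 = "h2",
                     mat_block = "block")
  p <- dplyr::rename(paternal, pat_gt = "gt", pat_h1 = "h1", pat_h2 = "h2",
                     pat_block = "block")
  p$vclass <- NULL
  loci <- dplyr::inner_join(m, p, by = c("chrom", "pos", "ref", "alt"))
  loci$category <- classify_locus(loci$mat_gt, loci$pat_gt)
  loci <- dplyr::arrange(loci, .data$chrom, .data$pos)
  attr(loci, "n_dropped") <-
    (nrow(maternal) - nrow(loci)) + (nrow(paternal) - nrow(loci))
  loci
}

# genotype string like "C/T" from alt dosage; NA -> "./."
gt_string <- function(ref, alt, gt) {
  out <- rep("./.", length(gt))
  ok <- !is.na(gt)
  out[ok & gt == 0L] <- paste(ref, ref, sep = "/")[ok & gt == 0L]
  out[ok & gt == 1L] <- paste(ref, alt, sep = "/")[ok & gt == 1L]
  out[ok & gt == 2L] <- paste(alt, alt, sep = "/")[ok & gt == 2L]
  out
}

# variant class from allele strings
variant_class <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV", "InDel")
}

# chromosome-qualified block key (phase-set ids are only unique per chrom)
block_key <- function(chrom, block) {
  ifelse(is.na(block), NA_character_, paste(chrom, block, sep = ":"))
}
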