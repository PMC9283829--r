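#' Estimate fetal fraction from plasma allele counts
#'
#' The fetal fraction (FF) is estimated at maternal-homozygous,
#' paternal-informative sites as `FF = 2p / (p + q) * 100`, where `p` is the
#' summed read count of fetal-specific alleles and `q` the summed count of
#' alleles shared with the mother.
#'
#' Site selection uses parental genotypes only (fetal heterozygosity is not
#' knowable a priori). The primary site set is mother homozygous / father
#' homozygous for the other allele (every fetus is an obligate heterozygote,
#' so the paternal allele is fetal-specific with probability 1). When fewer
#' than `min_hom_sites` such sites exist, the estimator falls back to
#' mother-homozygous / father-heterozygous sites, where the fetus inherits the
#' non-maternal allele only half the time, and corrects by doubling `p`.
#'
#' @param loci locus table (see [build_loci()]).
#' @param counts plasma counts tibble (`chrom, pos, ref_count, alt_count`).
#' @param regions `NULL` for a single genome-wide estimate, or `"chrom"` for
#'   an additional per-chromosome breakdown.
#' @param min_hom_sites minimum number of primary (hom/hom-opposite) sites
#'   required to use the primary path (default 500).
#' @return an object of class `fetoscope_ff`: a list with `ff_percent`
#'   (fetal fraction, percent), `n_sites` (informative sites with non-zero
#'   depth), `site_set` (`"hom_hom"` or `"hom_het"`), and `per_region`
#'   (tibble or `NULL`).
#' @examples
#' # one site, fetal-specific reads p = 10, shared reads q = 190 -> 10 %
#' loci <- tibble::tibble(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
#'   vclass = "SNV", mat_gt = 0L, mat_h1 = 0L, mat_h2 = 0L, mat_block = NA,
#'   pat_gt = 2L, pat_h1 = 1L, pat_h2 = 1L, pat_block = NA, category = "AAAA")
#' cts <- tibble::tibble(chrom = "chr1", pos = 100L,
#'                       ref_count = 190L, alt_count = 10L)
#' estimate_ff(loci, cts, min_hom_sites = 1)$ff_percent
#' @export
estimate_ff <- function(loci, counts, regions = NULL, min_hom_sites = 500) {
  df <- dplyr::inner_join(loci, counts, by = c("chrom", "pos"))
  df <- df[(df$ref_count + df$alt_count) > 0, ]

  hom_hom <- (df$mat_gt == 0L & df$pat_gt == 2L) |
             (df$mat_gt == 2L & df$pat_gt == 0L)
  hom_het <- (df$mat_gt %in% c(0L, 2L)) & df$pat_gt == 1L

  # fetal-specific allele = the allele the mother lacks
  fs_is_alt <- df$mat_gt == 0L
  p_site <- ifelse(fs_is_alt, df$alt_count, df$ref_count)
  q_site <- ifelse(fs_is_alt, df$ref_count, df$alt_count)

  if (sum(hom_hom) >= min_hom_sites) {
    use <- hom_hom
    mult <- 1
    site_set <- "hom_hom"
  } else {
    use <- hom_hom | hom_het
    mult <- ifelse(hom_hom[use], 1, 2)
    site_set <- "hom_het"
  }
  if (!any(use)) {
    stop("no informative site for fetal-fraction estimation; ",
         "supply the fetal fraction explicitly (e.g. --ff <pct>)")
  }

  ff_of <- function(p, q) {
    if (p + q == 0) return(NA_real_)
    max(0, min(100, 2 * p / (p + q) * 100))
  }
  p <- sum(p_site[use] * mult)
  q <- sum(q_site[use])
  per_region <- NULL
  if (identical(regions, "chrom")) {
    sub <- tibble::tibble(region = df$chrom[use],
                          p = p_site[use] * mult, q = q_site[use])
    per_region <- dplyr::summarise(
      dplyr::group_by(sub, .data$region),
      ff_percent = ff_of(sum(.data$p), sum(.data$q)),
      n_sites = dplyr::n(), .groups = "drop")
  }
  structure(list(ff_percent = ff_of(p, q), n_sites = sum(use),
                 site_set = site_set, per_region = per_region),
            class = "fetoscope_ff")
}

#' @export
print.fetoscope_ff <- function(x, ...) {
  cat(sprintf("Fetal fraction estimate: %.2f%% (%d informative sites, %s set)\n",
              x$ff_percent, x$n_sites, x$site_set))
  if (!is.null(x$per_region)) {
    cat("Per-region estimates:\n")
    print(x$per_region)
  }
  invisible(x)
}
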