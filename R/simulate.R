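#' Simulation configuration
#'
#' Defaults emulate the study conditions the pipeline is designed for:
#' cfDNA sequenced to ~100x with a mean fetal fraction of 13% (observed
#' range 4--27%), per-read error typical of short-read platforms (1e-3),
#' parental phasing into long haplotype blocks with N50 of 18.72 Mb
#' (maternal) and 13.57 Mb (paternal), >99% of heterozygous sites phased,
#' human-like variant density (~1 SNV per 1.5 kb, ~1 InDel per 12 kb) and
#' recombination at ~1.2 cM/Mb. Chromosome count and length set the problem
#' size only.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param snv_rate,indel_rate expected variants per bp.
#' @param maf_range range of the per-locus alt-allele population frequency
#'   (drawn uniformly; parents are independent Hardy-Weinberg draws).
#' @param ff fetal fraction of plasma cfDNA, proportion in `[0, 1)` (0 is
#'   allowed for diagnostics: plasma then contains no fetal reads).
#' @param depth mean plasma depth per locus (Poisson).
#' @param err per-read allele error rate.
#' @param indel_err_mult multiplier on `err` for InDel loci, modelling their
#'   lower count fidelity (default 2).
#' @param mat_n50,pat_n50 target haplotype-block N50 in bp.
#' @param phased_frac fraction of heterozygous sites that are phased.
#' @param recomb_rate crossovers per Mb per meiosis.
#' @param seed RNG seed; fixes the whole output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 1, chrom_length = 5e7,
                       snv_rate = 1 / 1500, indel_rate = 1 / 12000,
                       maf_range = c(0.05, 0.5),
                       ff = 0.13, depth = 100, err = 1e-3,
                       indel_err_mult = 2,
                       mat_n50 = 18.72e6, pat_n50 = 13.57e6,
                       phased_frac = 0.995, recomb_rate = 0.012,
                       seed = 1L) {
  cfg <- list(n_chrom = as.integer(n_chrom), chrom_length = chrom_length,
              snv_rate = snv_rate, indel_rate = indel_rate,
              maf_range = maf_range, ff = ff, depth = depth, err = err,
              indel_err_mult = indel_err_mult, mat_n50 = mat_n50,
              pat_n50 = pat_n50, phased_frac = phased_frac,
              recomb_rate = recomb_rate, seed = as.integer(seed))
  stopifnot(cfg$n_chrom >= 1, cfg$chrom_length > 0,
            cfg$snv_rate >= 0, cfg$indel_rate >= 0,
            cfg$snv_rate + cfg$indel_rate > 0,
            cfg$ff >= 0, cfg$ff < 1, cfg$depth > 0, cfg$err >= 0,
            cfg$mat_n50 > 0, cfg$pat_n50 > 0,
            cfg$phased_frac >= 0, cfg$phased_frac <= 1,
            cfg$recomb_rate >= 0)
  structure(cfg, class = "sim_config")
}

# block boundaries as a Poisson process whose rate is tuned so the
# length-weighted median (N50) of the resulting exponential block lengths
# matches the target: for Exp(mean mu) blocks the length-biased length is
# Gamma(2, mu) with median ~1.6783 mu, so mu = n50 / 1.6783.
block_ids <- function(pos, chrom_length, n50, offset) {
  mu <- n50 / 1.6783
  brk <- cumsum(rexp(ceiling(chrom_length / mu * 4) + 10, rate = 1 / mu))
  brk <- brk[brk < chrom_length]
  findInterval(pos, c(0, brk)) + offset
}

# transmitted haplotype index (1/2) per position for one recombined gamete
gamete_hap <- function(pos, chrom_length, recomb_rate) {
  n_cx <- rpois(1, recomb_rate * chrom_length / 1e6)
  cx <- sort(runif(n_cx, 1, chrom_length))
  start <- sample(1:2, 1)
  (start - 1L + findInterval(pos, cx)) %% 2L + 1L
}

#' Simulate a parental trio and maternal-plasma allele counts
#'
#' Generates, per chromosome: biallelic SNV and InDel loci at genome-like
#' density; parental genotypes as independent Hardy-Weinberg draws from a
#' per-locus population allele frequency; true parental haplotypes fragmented
#' into phase blocks hitting the configured N50; a fetus formed from one
#' recombined gamete per parent (crossovers Poisson per Mb); and plasma
#' counts per locus (depth Poisson, each read fetal with probability `ff`,
#' allele drawn from the carrier's genotype and flipped with the per-read
#' error rate, doubled for InDels).
#'
#' The output is deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list of class `fetoscope_sim`: `loci` (locus table as from
#'   [build_loci()]), `counts` (plasma counts), `truth` (tibble
#'   `chrom, pos, ref, alt, fet_mat, fet_pat, fet_gt, mat_hap, pat_hap`),
#'   `crossovers` (per chrom/parent counts) and `cfg`.
#' @export
simulate_family <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  loci_l <- list()
  truth_l <- list()
  counts_l <- list()
  cx_l <- list()
  blk_off_m <- 0L
  blk_off_p <- 0L
  bases <- c("A", "C", "G", "T")
  for (ci in seq_len(cfg$n_chrom)) {
    chrom <- paste0("chr", ci)
    L <- cfg$chrom_length
    n_snv <- rpois(1, L * cfg$snv_rate)
    n_ind <- rpois(1, L * cfg$indel_rate)
    n <- n_snv + n_ind
    if (n == 0) stop("degenerate configuration: zero loci on ", chrom)
    pos <- sort(sample.int(L, n))
    vclass <- sample(rep(c("SNV", "InDel"), c(n_snv, n_ind)))

    ref_i <- sample.int(4, n, replace = TRUE)
    alt_i <- (ref_i - 1L + sample.int(3, n, replace = TRUE)) %% 4L + 1L
    ref <- bases[ref_i]
    alt <- bases[alt_i]
    is_ind <- vclass == "InDel"
    ins <- is_ind & runif(n) < 0.5
    del <- is_ind & !ins
    alt[ins] <- paste0(ref[ins], bases[alt_i[ins]])
    alt[del] <- ref[del]
    ref[del] <- paste0(alt[del], bases[alt_i[del]])

    f <- runif(n, cfg$maf_range[1], cfg$maf_range[2])
    m_a1 <- rbinom(n, 1, f)
    m_a2 <- rbinom(n, 1, f)
    p_a1 <- rbinom(n, 1, f)
    p_a2 <- rbinom(n, 1, f)
    mat_gt <- m_a1 + m_a2
    pat_gt <- p_a1 + p_a2
    poly <- mat_gt + pat_gt > 0          # drop sites invariant in both parents
    keep <- which(poly)

    m_blk <- block_ids(pos, L, cfg$mat_n50, blk_off_m)
    p_blk <- block_ids(pos, L, cfg$pat_n50, blk_off_p)
    blk_off_m <- max(m_blk) + 1L
    blk_off_p <- max(p_blk) + 1L

    m_phased <- runif(n) < cfg$phased_frac
    p_phased <- runif(n) < cfg$phased_frac

    mat_hap <- gamete_hap(pos, L, cfg$recomb_rate)
    pat_hap <- gamete_hap(pos, L, cfg$recomb_rate)
    fet_mat <- ifelse(mat_hap == 1L, m_a1, m_a2)
    fet_pat <- ifelse(pat_hap == 1L, p_a1, p_a2)
    fet_gt <- fet_mat + fet_pat

    d <- rpois(n, cfg$depth)
    fk <- rbinom(n, d, cfg$ff)
    mat_alt <- rbinom(n, d - fk, mat_gt / 2)
    fet_alt <- rbinom(n, fk, fet_gt / 2)
    e <- ifelse(is_ind, cfg$err * cfg$indel_err_mult, cfg$err)
    alt_true <- mat_alt + fet_alt
    ref_true <- d - alt_true
    alt_obs <- alt_true - rbinom(n, alt_true, e) + rbinom(n, ref_true, e)
    ref_obs <- d - alt_obs

    het_m <- mat_gt == 1L
    het_p <- pat_gt == 1L
    loci_l[[ci]] <- tibble::tibble(
      chrom = chrom, pos = pos, ref = ref, alt = alt, vclass = vclass,
      mat_gt = mat_gt,
      mat_h1 = ifelse(het_m & !m_phased, NA_integer_, m_a1),
      mat_h2 = ifelse(het_m & !m_phased, NA_integer_, m_a2),
      mat_block = ifelse(het_m & m_phased, m_blk, NA_integer_),
      pat_gt = pat_gt,
      pat_h1 = ifelse(het_p & !p_phased, NA_integer_, p_a1),
      pat_h2 = ifelse(het_p & !p_phased, NA_integer_, p_a2),
      pat_block = ifelse(het_p & p_phased, p_blk, NA_integer_),
      category = classify_locus(mat_gt, pat_gt)
    )[keep, ]
    truth_l[[ci]] <- tibble::tibble(
      chrom = chrom, pos = pos, ref = ref, alt = alt,
      fet_mat = fet_mat, fet_pat = fet_pat, fet_gt = fet_gt,
      mat_hap = mat_hap, pat_hap = pat_hap
    )[keep, ]
    counts_l[[ci]] <- tibble::tibble(
      chrom = chrom, pos = pos, ref = ref, alt = alt,
      ref_count = as.integer(ref_obs), alt_count = as.integer(alt_obs)
    )[keep, ]
    # crossovers observable at retained loci = haplotype-label switches
    cx_l[[ci]] <- tibble::tibble(
      chrom = chrom,
      parent = c("maternal", "paternal"),
      n_crossovers = c(sum(diff(mat_hap[keep]) != 0L),
                       sum(diff(pat_hap[keep]) != 0L))
    )
  }
  structure(list(loci = dplyr::bind_rows(loci_l),
                 counts = dplyr::bind_rows(counts_l),
                 truth = dplyr::bind_rows(truth_l),
                 crossovers = dplyr::bind_rows(cx_l),
                 cfg = cfg),
            class = "fetoscope_sim")
}

#' @export
print.fetoscope_sim <- function(x, ...) {
  cat(sprintf(paste0("Simulated trio: %d loci on %d chromosome(s); ",
                     "ff = %.3f, depth = %gx\n"),
              nrow(x$loci), x$cfg$n_chrom, x$cfg$ff, x$cfg$depth))
  print(table(x$loci$category, x$loci$vclass))
  invisible(x)
}

#' Write a simulated family to standard files
#'
#' Writes `maternal.vcf`, `paternal.vcf` (phased, with PS block ids),
#' `truth.vcf` (fetal genotypes from cord-blood-equivalent ground truth) and
#' `plasma_counts.tsv` into a directory.
#'
#' @param sim a [simulate_family()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "fetoscope_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  l <- sim$loci
  mk <- function(prefix) {
    tibble::tibble(chrom = l$chrom, pos = l$pos, ref = l$ref, alt = l$alt,
                   gt = l[[paste0(prefix, "_gt")]],
                   h1 = l[[paste0(prefix, "_h1")]],
                   h2 = l[[paste0(prefix, "_h2")]],
                   block = l[[paste0(prefix, "_block")]])
  }
  write_parental_vcf(mk("mat"), file.path(dir, "maternal.vcf"), "MOTHER")
  write_parental_vcf(mk("pat"), file.path(dir, "paternal.vcf"), "FATHER")
  tr <- sim$truth
  write_fetal_vcf(tibble::tibble(chrom = tr$chrom, pos = tr$pos,
                                 ref = tr$ref, alt = tr$alt,
                                 fet_gt = tr$fet_gt, method = "truth",
                                 conf = NA_real_),
                  file.path(dir, "truth.vcf"))
  write_plasma_counts(sim$counts, file.path(dir, "plasma_counts.tsv"))
  invisible(dir)
}
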