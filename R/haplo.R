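#' Orient loci for relative-haplotype-dosage SPRT
#'
#' At a maternally heterozygous, phased locus the plasma allele balance shifts
#' by half the fetal fraction depending on which maternal haplotype the fetus
#' inherited. Writing Hap I / Hap II for the two maternal haplotypes and `b`
#' for the plasma read count of the Hap I allele, the expected Hap-I-allele
#' fraction is:
#'
#' * paternal transmitted allele == Hap I allele: `0.5 + C/2` under
#'   "fetus carries Hap I" (H1) and `0.5` under H0;
#' * paternal transmitted allele == Hap II allele: `0.5` under H1 and
#'   `0.5 - C/2` under H0.
#'
#' Both give a positive log-likelihood-ratio drift under H1, so one SPRT per
#' block tests H1 against H0 across mixed orientations. Loci where the
#' orientation is undeterminable (unphased mother, unknown paternal
#' contribution) are flagged unusable.
#'
#' @param loci tibble with `mat_h1, mat_h2, ref_count, alt_count` and a
#'   `pat_allele` column (alt indicator of the paternally transmitted allele:
#'   the father's homozygous allele at ABAA loci, the closest-variant-
#'   resolved allele at ABAB loci; `NA` when unknown).
#' @param C fetal fraction (proportion), > 0.
#' @return tibble aligned with `loci`: `b` (Hap-I-allele count), `n` (depth),
#'   `p1`, `p0` (expected Hap-I fractions under H1/H0), `usable`.
#' @export
orient_loci <- function(loci, C) {
  stopifnot(C >= 0, C < 1)   # C = 0 gives p1 = p0: the SPRT can never decide
  usable <- !is.na(loci$mat_h1) & !is.na(loci$mat_h2) &
    loci$mat_h1 != loci$mat_h2 & !is.na(loci$pat_allele)
  b <- ifelse(loci$mat_h1 == 1L, loci$alt_count, loci$ref_count)
  n <- loci$ref_count + loci$alt_count
  pat_is_h1 <- loci$pat_allele == loci$mat_h1
  p1 <- ifelse(pat_is_h1, 0.5 + C / 2, 0.5)
  p0 <- ifelse(pat_is_h1, 0.5, 0.5 - C / 2)
  tibble::tibble(b = ifelse(usable, b, NA_integer_),
                 n = ifelse(usable, n, NA_integer_),
                 p1 = p1, p0 = p0, usable = usable)
}

# segment-wise SPRT over one block. pos sorted ascending; inc is the per-locus
# log-likelihood-ratio increment (0 for passenger loci that do not accumulate,
# e.g. InDels). Returns labels, segment ids and the deciding LLR.
sprt_run_segments <- function(inc, log_bound) {
  n <- length(inc)
  label <- rep(NA_character_, n)
  seg <- integer(n)
  llr <- rep(NA_real_, n)
  start <- 1L
  s <- 0L
  while (start <= n) {
    cs <- cumsum(inc[start:n])
    up <- which(cs >= log_bound)
    lo <- which(cs <= -log_bound)
    first_up <- if (length(up)) up[1L] else Inf
    first_lo <- if (length(lo)) lo[1L] else Inf
    s <- s + 1L
    if (!is.finite(first_up) && !is.finite(first_lo)) {
      seg[start:n] <- s
      break
    }
    j <- min(first_up, first_lo)
    idx <- start:(start + j - 1L)
    label[idx] <- if (first_up <= first_lo) "HapI" else "HapII"
    seg[idx] <- s
    llr[idx] <- cs[j]
    start <- start + j
  }
  list(label = label, segment = seg, llr = llr)
}

#' SPRT classification of maternal inheritance along a haplotype block
#'
#' Accumulates oriented allele counts locus by locus along one phased block
#' and emits a decision whenever the cumulative binomial likelihood ratio for
#' "fetus inherited maternal Hap I" (success probability `p1` per locus)
#' versus Hap II (`p0`) crosses the symmetric boundary `L` (decision when
#' LR >= L or <= 1/L). All loci of the decided accumulation segment --
#' including non-accumulating passenger loci such as InDels lying inside it --
#' receive the segment's label, and the accumulator resets, so a
#' recombination breakpoint can flip subsequent segments. Loci in segments
#' that never reach a boundary stay unclassified (`NA`).
#'
#' @param block tibble of one block's loci, positions ascending, with columns
#'   `pos`, `b`, `n`, `p1`, `p0` (see [orient_loci()]) and `accum` (logical:
#'   contributes counts to the accumulator).
#' @param L likelihood-ratio decision boundary (default 1200).
#' @return tibble aligned with `block`: `label` (`"HapI"`, `"HapII"` or `NA`),
#'   `segment`, `llr` (cumulative log-LR at the segment's decision).
#' @export
sprt_classify_block <- function(block, L = 1200) {
  if (nrow(block) == 0) {
    return(tibble::tibble(label = character(0), segment = integer(0),
                          llr = double(0)))
  }
  stopifnot(!is.unsorted(block$pos), L > 1)
  inc <- rep(0, nrow(block))
  acc <- block$accum & !is.na(block$b) & block$n > 0
  inc[acc] <- block$b[acc] * log(block$p1[acc] / block$p0[acc]) +
    (block$n[acc] - block$b[acc]) *
      log((1 - block$p1[acc]) / (1 - block$p0[acc]))
  res <- sprt_run_segments(inc, log(L))
  tibble::tibble(label = res$label, segment = res$segment, llr = res$llr)
}

#' SPRT classification across all maternal blocks
#'
#' Groups loci by (chromosome, maternal block), orients them (see
#' [orient_loci()]) and runs [sprt_classify_block()] per block.
#'
#' @param loci tibble with `chrom, pos, mat_h1, mat_h2, mat_block,
#'   ref_count, alt_count, pat_allele` and `accum`.
#' @param C fetal fraction (proportion).
#' @param L likelihood-ratio boundary.
#' @return tibble aligned with `loci`: `mat_hap` (`"HapI"`/`"HapII"`/`NA`),
#'   `segment`, `llr`.
#' @export
sprt_classify <- function(loci, C, L = 1200) {
  n <- nrow(loci)
  out <- tibble::tibble(mat_hap = rep(NA_character_, n),
                        segment = rep(NA_integer_, n),
                        llr = rep(NA_real_, n))
  if (n == 0) return(out)
  ori <- orient_loci(loci, C)
  key <- block_key(loci$chrom, loci$mat_block)
  usable_blk <- !is.na(key)
  ord <- order(key, loci$pos)
  ord <- ord[usable_blk[ord]]
  if (length(ord) == 0) return(out)
  grp <- split(ord, key[ord])
  for (ids in grp) {
    blk <- tibble::tibble(pos = loci$pos[ids], b = ori$b[ids], n = ori$n[ids],
                          p1 = ori$p1[ids], p0 = ori$p0[ids],
                          accum = ori$usable[ids])
    res <- sprt_classify_block(blk, L = L)
    out$mat_hap[ids] <- res$label
    out$segment[ids] <- res$segment
    out$llr[ids] <- res$llr
  }
  out
}

#' Closest-variant imputation of inheritance labels
#'
#' Each unclassified target takes the inheritance label of the nearest
#' classified anchor (by absolute position difference) lying within
#' `window_bp` in the same haplotype block. If the nearest upstream and
#' nearest downstream anchors inside the window carry different labels, the
#' target is left unclassified (conflict rule). A single in-window anchor on
#' one side suffices. Labels never cross block boundaries.
#'
#' @param targets tibble with `block` (chromosome-qualified block key) and
#'   `pos`.
#' @param anchors tibble with `block`, `pos`, `label`.
#' @param window_bp search window in bp: 200,000 for closest-variant
#'   algorithm 1, 500,000 for algorithm 2.
#' @return character vector of labels aligned with `targets` (`NA` when
#'   unclassified).
#' @export
closest_variant <- function(targets, anchors, window_bp = 200000) {
  stopifnot(window_bp > 0)
  n <- nrow(targets)
  out <- rep(NA_character_, n)
  if (n == 0 || nrow(anchors) == 0) return(out)
  anchors <- anchors[!is.na(anchors$block) & !is.na(anchors$label), ]
  a_split <- split(seq_len(nrow(anchors)), anchors$block)
  t_ok <- which(!is.na(targets$block))
  t_split <- split(t_ok, targets$block[t_ok])
  for (bk in names(t_split)) {
    ai <- a_split[[bk]]
    if (is.null(ai)) next
    apos <- anchors$pos[ai]
    alab <- anchors$label[ai]
    o <- order(apos)
    apos <- apos[o]
    alab <- alab[o]
    ti <- t_split[[bk]]
    tpos <- targets$pos[ti]
    iv <- findInterval(tpos, apos)
    up <- iv                   # index of nearest anchor at or before target
    dn <- iv + 1L              # nearest anchor after target
    d_up <- ifelse(up >= 1L, tpos - apos[pmax(up, 1L)], Inf)
    d_dn <- ifelse(dn <= length(apos), apos[pmin(dn, length(apos))] - tpos, Inf)
    d_up[d_up > window_bp] <- Inf
    d_dn[d_dn > window_bp] <- Inf
    lab_up <- ifelse(is.finite(d_up), alab[pmax(up, 1L)], NA_character_)
    lab_dn <- ifelse(is.finite(d_dn), alab[pmin(dn, length(apos))],
                     NA_character_)
    conflict <- is.finite(d_up) & is.finite(d_dn) & lab_up != lab_dn
    nearest <- ifelse(d_up <= d_dn, lab_up, lab_dn)
    nearest[conflict] <- NA_character_
    nearest[!is.finite(d_up) & !is.finite(d_dn)] <- NA_character_
    out[ti] <- nearest
  }
  out
}

#' Impute the paternally transmitted allele at InDel loci
#'
#' Applies closest-variant algorithm 2 (500 kb window, same paternal block)
#' to AAAB/ABAB InDels, transferring the transmitted paternal haplotype from
#' the nearest paternally informative classified locus and reading off the
#' InDel's allele on that haplotype.
#'
#' @param loci tibble of target InDels with `chrom, pos, pat_h1, pat_h2,
#'   pat_block`.
#' @param anchors tibble with `chrom, pos, pat_block` and `label`
#'   (`"I"`/`"II"`, the transmitted paternal haplotype).
#' @param window_bp window (default 500,000: algorithm 2).
#' @return integer vector: alt indicator of the paternal transmitted allele
#'   at each target (`NA` when unclassified).
#' @export
infer_paternal_indels <- function(loci, anchors, window_bp = 500000) {
  lab <- closest_variant(
    tibble::tibble(block = block_key(loci$chrom, loci$pat_block),
                   pos = loci$pos),
    tibble::tibble(block = block_key(anchors$chrom, anchors$pat_block),
                   pos = anchors$pos, label = anchors$label),
    window_bp = window_bp
  )
  as.integer(ifelse(is.na(lab), NA_integer_,
                    ifelse(lab == "I", loci$pat_h1, loci$pat_h2)))
}
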