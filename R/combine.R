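#' Configuration for the combined caller
#'
#' @param eps parental genotyping error rate (Bayesian prior).
#' @param err per-read sequencing error rate.
#' @param mode Bayesian likelihood mode (see [combo_likelihood()]).
#' @param sprt_L SPRT likelihood-ratio boundary.
#' @param window1_bp closest-variant algorithm 1 window (SNVs, 200 kb).
#' @param window2_bp closest-variant algorithm 2 window (InDels, 500 kb).
#' @param anchor_conf minimum Bayesian paternal-allele confidence for an AAAB
#'   locus to anchor closest-variant transfer along paternal blocks.
#' @return a list of class `combine_config`.
#' @export
combine_config <- function(eps = 1e-3, err = 1e-3,
                           mode = c("multinomial", "literal"),
                           sprt_L = 1200, window1_bp = 200000,
                           window2_bp = 500000, anchor_conf = 0.95) {
  mode <- match.arg(mode)
  stopifnot(eps >= 0, eps <= 0.1, err >= 0, err < 0.05, sprt_L > 1,
            window1_bp > 0, window2_bp > 0,
            anchor_conf >= 0, anchor_conf <= 1)
  structure(list(eps = eps, err = err, mode = mode, sprt_L = sprt_L,
                 window1_bp = window1_bp, window2_bp = window2_bp,
                 anchor_conf = anchor_conf),
            class = "combine_config")
}

#' Combined Bayesian + haplotype fetal genotype calls
#'
#' Per-category dispatch of the two engines, with Bayesian gap-filling:
#'
#' * **AAAA / AAAB SNVs**: Bayesian call (`method = "bayes"`).
#' * **ABAA SNVs**: paternal allele is the father's homozygous allele;
#'   maternal allele by SPRT along the maternal block (`"sprt"`), gaps by
#'   closest-variant algorithm 1 anchored on SPRT-classified loci
#'   (`"closest1"`), residual gaps by the Bayesian model (`"bayes"`).
#' * **ABAB SNVs**: paternal allele by closest-variant algorithm 1 anchored
#'   on high-confidence Bayesian AAAB calls within 200 kb in the same
#'   paternal block; maternal allele by SPRT (these loci join the block's
#'   accumulator once their paternal allele is resolved) or closest-variant 1;
#'   loci unresolved on either side fall back to the Bayesian call.
#' * **InDels**: excluded from SPRT accumulation; paternal allele at
#'   AAAB/ABAB InDels by closest-variant algorithm 2 (500 kb, paternal
#'   block); maternal allele from the containing decided SPRT segment or
#'   closest-variant 2 (maternal block); InDels unresolved on either side
#'   stay `"unclassified"` (no Bayesian gap-fill for InDels).
#'
#' Every locus receives exactly one provenance in
#' `{bayes, sprt, closest1, closest2, unclassified}` (ABAB loci resolved by a
#' mix record the maternal mechanism). When the haplotype and Bayesian paths
#' disagree at a locus resolved by both, the haplotype call wins. If no
#' parental phasing is available at all, the caller warns and falls back to
#' Bayesian-only calls.
#'
#' @param loci locus table (see [build_loci()] / [simulate_family()]).
#' @param counts plasma counts tibble (`chrom, pos, ref_count, alt_count`).
#' @param C fetal fraction (proportion); `NULL` to estimate it with
#'   [estimate_ff()].
#' @param config a [combine_config()].
#' @return tibble: locus columns plus `fet_gt, fet_mat, fet_pat, method,
#'   conf`, the engine-level detail columns `bayes_gt, bayes_conf, haplo_gt,
#'   haplo_note`, and `ff` (the fetal fraction used) as an attribute.
#' @export
combined_call <- function(loci, counts, C = NULL, config = combine_config()) {
  stopifnot(inherits(config, "combine_config"))
  df <- dplyr::left_join(loci, counts[, c("chrom", "pos", "ref_count",
                                          "alt_count")],
                         by = c("chrom", "pos"))
  df$ref_count[is.na(df$ref_count)] <- 0L
  df$alt_count[is.na(df$alt_count)] <- 0L
  if (is.null(C)) C <- estimate_ff(loci, counts)$ff_percent / 100
  stopifnot(C > 0, C < 1)

  n <- nrow(df)
  bb <- bayes_call(df, counts = NULL, C = C, eps = config$eps,
                   err = config$err, mode = config$mode)
  snv <- df$vclass == "SNV"
  cat_ <- df$category

  fet_mat <- rep(NA_integer_, n)
  fet_pat <- rep(NA_integer_, n)
  mat_src <- rep(NA_character_, n)
  pat_src <- rep(NA_character_, n)
  sprt_conf <- rep(NA_real_, n)

  has_phase <- any(!is.na(df$mat_block)) || any(!is.na(df$pat_block))
  if (!has_phase) {
    warning("no phased haplotype blocks in input; falling back to ",
            "Bayesian-only calls")
  } else {
    # Mendel-trivial alleles
    abaa <- cat_ == "ABAA"
    fet_pat[abaa] <- df$pat_gt[abaa] %/% 2L       # father homozygous
    pat_src[abaa] <- "mendel"
    aaab_ind <- cat_ == "AAAB" & !snv
    fet_mat[aaab_ind] <- df$mat_gt[aaab_ind] %/% 2L
    mat_src[aaab_ind] <- "mendel"

    # paternal anchors: high-confidence Bayesian AAAB SNV calls on phased
    # paternal blocks; label is the transmitted paternal haplotype
    anch <- which(cat_ == "AAAB" & snv & !is.na(df$pat_block) &
                    !is.na(df$pat_h1) & bb$ok &
                    bb$conf_pat >= config$anchor_conf)
    pat_anchors <- tibble::tibble(
      block = block_key(df$chrom[anch], df$pat_block[anch]),
      pos = df$pos[anch],
      label = ifelse(bb$fet_pat[anch] == df$pat_h1[anch], "I", "II")
    )

    # ABAB SNV paternal allele: closest-variant 1 along paternal blocks
    tgt1 <- which(cat_ == "ABAB" & snv & !is.na(df$pat_block) &
                    !is.na(df$pat_h1))
    if (length(tgt1)) {
      lab <- closest_variant(
        tibble::tibble(block = block_key(df$chrom[tgt1], df$pat_block[tgt1]),
                       pos = df$pos[tgt1]),
        pat_anchors, window_bp = config$window1_bp)
      fet_pat[tgt1] <- ifelse(lab == "I", df$pat_h1[tgt1], df$pat_h2[tgt1])
      pat_src[tgt1] <- ifelse(is.na(lab), NA_character_, "closest1")
    }
    # AAAB / ABAB InDel paternal allele: closest-variant 2
    tgt2 <- which(cat_ %in% c("AAAB", "ABAB") & !snv & !is.na(df$pat_block) &
                    !is.na(df$pat_h1))
    if (length(tgt2)) {
      pa <- infer_paternal_indels(df[tgt2, ],
                                  tibble::tibble(chrom = df$chrom[anch],
                                                 pos = df$pos[anch],
                                                 pat_block = df$pat_block[anch],
                                                 label = pat_anchors$label),
                                  window_bp = config$window2_bp)
      fet_pat[tgt2] <- pa
      pat_src[tgt2] <- ifelse(is.na(pa), NA_character_, "closest2")
    }

    # maternal SPRT along maternal blocks: ABAA SNVs and paternally resolved
    # ABAB SNVs accumulate; ABAA/ABAB InDels ride as passengers
    elig <- (cat_ %in% c("ABAA", "ABAB")) & !is.na(df$mat_block) &
      !is.na(df$mat_h1)
    sel <- which(elig)
    if (length(sel)) {
      sp_in <- tibble::tibble(
        chrom = df$chrom[sel], pos = df$pos[sel],
        mat_h1 = df$mat_h1[sel], mat_h2 = df$mat_h2[sel],
        mat_block = df$mat_block[sel],
        ref_count = df$ref_count[sel], alt_count = df$alt_count[sel],
        pat_allele = fet_pat[sel],
        accum = snv[sel]
      )
      sp <- sprt_classify(sp_in, C = C, L = config$sprt_L)
      decided <- !is.na(sp$mat_hap)
      fm <- ifelse(sp$mat_hap == "HapI", df$mat_h1[sel], df$mat_h2[sel])
      fet_mat[sel[decided]] <- fm[decided]
      mat_src[sel[decided]] <- "sprt"
      lr <- exp(pmin(abs(sp$llr), 700))
      sprt_conf[sel[decided]] <- (lr / (1 + lr))[decided]

      # closest-variant gap-fill of the maternal allele
      mat_anchors <- tibble::tibble(
        block = block_key(df$chrom[sel], df$mat_block[sel])[decided],
        pos = df$pos[sel][decided],
        label = sp$mat_hap[decided])
      fill <- function(idx, window) {
        if (!length(idx)) return()
        lab <- closest_variant(
          tibble::tibble(block = block_key(df$chrom[idx], df$mat_block[idx]),
                         pos = df$pos[idx]),
          mat_anchors, window_bp = window)
        got <- !is.na(lab)
        fet_mat[idx[got]] <<- ifelse(lab[got] == "HapI",
                                     df$mat_h1[idx[got]], df$mat_h2[idx[got]])
        mat_src[idx[got]] <<- if (window == config$window1_bp)
          "closest1" else "closest2"
      }
      undecided <- sel[!decided]
      fill(undecided[snv[undecided]], config$window1_bp)
      fill(undecided[!snv[undecided]], config$window2_bp)
    }
  }

  # assemble: Bayesian default, haplotype overrides where both alleles resolved
  fet_gt <- bb$fet_gt
  conf <- bb$conf
  method <- ifelse(bb$ok, "bayes", "unclassified")
  hap_ok <- cat_ %in% c("ABAA", "ABAB") & !is.na(fet_mat) & !is.na(fet_pat)
  fet_gt[hap_ok] <- fet_mat[hap_ok] + fet_pat[hap_ok]
  conf[hap_ok] <- sprt_conf[hap_ok]
  method[hap_ok] <- dplyr::case_when(
    !snv[hap_ok] & (mat_src[hap_ok] == "closest2" |
                      pat_src[hap_ok] == "closest2") ~ "closest2",
    mat_src[hap_ok] == "sprt" ~ "sprt",
    mat_src[hap_ok] == "closest1" ~ "closest1",
    TRUE ~ "sprt"
  )
  # AAAB InDels: resolved only via closest-variant 2, otherwise unclassified
  aaab_ind <- cat_ == "AAAB" & !snv
  res_ind <- aaab_ind & !is.na(fet_mat) & !is.na(fet_pat)
  fet_gt[res_ind] <- fet_mat[res_ind] + fet_pat[res_ind]
  conf[res_ind] <- NA_real_
  method[res_ind] <- "closest2"
  method[aaab_ind & !res_ind] <- "unclassified"
  fet_gt[aaab_ind & !res_ind] <- NA_integer_
  # ABAA/ABAB InDels without a haplotype resolution stay unclassified
  ind_unres <- cat_ %in% c("ABAA", "ABAB") & !snv & !hap_ok
  method[ind_unres] <- "unclassified"
  fet_gt[ind_unres] <- NA_integer_
  conf[ind_unres] <- NA_real_

  # engine-level detail (for dual-format target reports)
  haplo_gt <- rep(NA_integer_, n)
  haplo_gt[hap_ok | res_ind] <- fet_mat[hap_ok | res_ind] +
    fet_pat[hap_ok | res_ind]
  haplo_note <- rep(NA_character_, n)
  relevant <- cat_ %in% c("ABAA", "ABAB", "AAAB")
  haplo_note[relevant & is.na(haplo_gt)] <- "NA"
  mat_side <- cat_ %in% c("ABAA", "ABAB")
  haplo_note[mat_side & is.na(df$mat_block)] <- "not in block"

  out <- df
  out$fet_gt <- as.integer(fet_gt)
  out$fet_mat <- ifelse(method == "unclassified", NA_integer_, fet_mat)
  out$fet_pat <- ifelse(method == "unclassified", NA_integer_, fet_pat)
  out$method <- method
  out$conf <- conf
  out$bayes_gt <- bb$fet_gt
  out$bayes_conf <- bb$conf
  out$haplo_gt <- as.integer(haplo_gt)
  out$haplo_note <- haplo_note
  attr(out, "ff") <- C
  out
}

#' Report combined, Bayesian and haplotype calls at target variants
#'
#' Produces the dual-format diagnosis report used for pathogenic target
#' variants: the combined call plus each engine's individual call, with
#' `"NA"` when an engine produced no call and `"not in block"` when the locus
#' lies outside any phased haplotype block. Targets absent from the parental
#' loci are reported as `untyped`.
#'
#' @param targets tibble with `chrom, pos, ref, alt` (extra annotation
#'   columns are passed through).
#' @param calls output of [combined_call()].
#' @return tibble: target columns plus `combined`, `bayes`, `haplo` genotype
#'   strings (e.g. `"C/T"`), `method` and `status` (`"called"`/`"untyped"`).
#' @export
call_pathogenic <- function(targets, calls) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(targets)))
  m <- match(paste(targets$chrom, targets$pos, targets$ref, targets$alt),
             paste(calls$chrom, calls$pos, calls$ref, calls$alt))
  hit <- !is.na(m)
  res <- targets
  res$status <- ifelse(hit, "called", "untyped")
  res$combined <- NA_character_
  res$bayes <- NA_character_
  res$haplo <- NA_character_
  res$method <- NA_character_
  if (any(hit)) {
    cm <- calls[m[hit], ]
    res$combined[hit] <- gt_string(cm$ref, cm$alt, cm$fet_gt)
    res$bayes[hit] <- gt_string(cm$ref, cm$alt, cm$bayes_gt)
    hp <- gt_string(cm$ref, cm$alt, cm$haplo_gt)
    hp[is.na(cm$haplo_gt)] <- cm$haplo_note[is.na(cm$haplo_gt)]
    res$haplo[hit] <- hp
    res$method[hit] <- cm$method
  }
  res
}
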