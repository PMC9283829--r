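#' Read a single-sample (optionally phased) parental VCF
#'
#' Parses a plain or bgzipped VCF 4.x file with one sample column, keeping
#' biallelic SNV/InDel records. Phased heterozygotes (`0|1` / `1|0`) carry
#' their haplotype-block id from the `PS` (phase set) FORMAT field; unphased
#' heterozygotes are retained with phase absent (usable by the Bayesian engine
#' only). Multiallelic records, missing genotypes and records failing the
#' quality filters are dropped; the total dropped is reported with a message
#' and via `attr(., "n_dropped")`.
#'
#' The default quality filters are standard germline hygiene: `QUAL >= 30`
#' and, when a `DP` FORMAT field is present, `min_dp <= DP <= max_dp_mult *
#' mean(DP)`. Records with missing QUAL/DP pass the corresponding filter.
#'
#' @param path VCF file path.
#' @param min_qual minimum QUAL (default 30); `-Inf` disables.
#' @param min_dp,max_dp_mult depth filter bounds (defaults 10 and 3); applied
#'   only when the VCF has per-sample DP.
#' @return tibble with columns `chrom, pos, ref, alt, vclass, gt, h1, h2,
#'   block`: `gt` is alt-allele dosage; `h1`/`h2` are the alt indicators of
#'   haplotype I / II (equal to the allele for homozygotes, `NA` for unphased
#'   heterozygotes); `block` is the phase-set id (`NA` when unphased).
#' @export
read_parental_vcf <- function(path, min_qual = 30, min_dp = 10,
                              max_dp_mult = 3) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(v@gt) < 2L) stop("VCF has no sample column: ", path)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  n_in <- nrow(fix)
  gt_raw <- unname(vcfR::extract.gt(v, element = "GT")[, 1L])
  fmt <- strsplit(unname(v@gt[, "FORMAT"]), ":", fixed = TRUE)
  has_ps <- any(vapply(fmt, function(f) "PS" %in% f, logical(1)))
  has_dp <- any(vapply(fmt, function(f) "DP" %in% f, logical(1)))
  ps <- if (has_ps) unname(vcfR::extract.gt(v, element = "PS")[, 1L]) else
    rep(NA_character_, n_in)
  dp <- if (has_dp) {
    suppressWarnings(as.numeric(vcfR::extract.gt(v, element = "DP")[, 1L]))
  } else rep(NA_real_, n_in)
  qual <- suppressWarnings(as.numeric(fix$QUAL))

  keep <- !grepl(",", fix$ALT, fixed = TRUE) & !is.na(fix$ALT) &
    !is.na(gt_raw) & !grepl("\\.", gt_raw)
  keep <- keep & (is.na(qual) | qual >= min_qual)
  if (has_dp) {
    mean_dp <- mean(dp, na.rm = TRUE)
    keep <- keep & (is.na(dp) | (dp >= min_dp & dp <= max_dp_mult * mean_dp))
  }

  gt_raw <- gt_raw[keep]
  phased <- grepl("|", gt_raw, fixed = TRUE)
  parts <- strsplit(gt_raw, "[/|]")
  a1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
  a2 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  ok <- !is.na(a1) & !is.na(a2) & a1 %in% 0:1 & a2 %in% 0:1
  gt <- a1 + a2
  het <- gt == 1L
  h1 <- ifelse(het & !phased, NA_integer_, a1)
  h2 <- ifelse(het & !phased, NA_integer_, a2)
  blk <- ps[keep]
  blk[!(het & phased)] <- NA_character_
  blk[blk %in% "."] <- NA_character_

  out <- tibble::tibble(
    chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
    ref = fix$REF[keep], alt = fix$ALT[keep],
    vclass = variant_class(fix$REF[keep], fix$ALT[keep]),
    gt = gt, h1 = h1, h2 = h2, block = blk
  )[ok, ]
  n_dropped <- n_in - nrow(out)
  if (n_dropped > 0) {
    message(n_dropped, " of ", n_in, " records excluded (multiallelic, ",
            "missing genotype, or failed quality filters)")
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a parental site table as a phased single-sample VCF
#'
#' The inverse of [read_parental_vcf()]: phased heterozygotes are written as
#' `h1|h2` with their block id in the `PS` FORMAT field; unphased
#' heterozygotes as `0/1`; homozygotes as `0/0` / `1/1`.
#'
#' @param sites tibble with columns `chrom, pos, ref, alt, gt, h1, h2, block`.
#' @param path output path (plain-text `.vcf`).
#' @param sample_name sample column name.
#' @return `path`, invisibly.
#' @export
write_parental_vcf <- function(sites, path, sample_name = "SAMPLE") {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "gt", "h1", "h2", "block")
                %in% names(sites)))
  phased <- sites$gt == 1L & !is.na(sites$h1)
  gt_field <- ifelse(sites$gt == 1L,
                     ifelse(phased, paste0(sites$h1, "|", sites$h2), "0/1"),
                     ifelse(sites$gt == 2L, "1/1", "0/0"))
  ps_field <- ifelse(phased & !is.na(sites$block), sites$block, ".")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=fetoscope",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set (haplotype block id)\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_name)
  )
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, "60",
                "PASS", ".", "GT:PS", paste(gt_field, ps_field, sep = ":"),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write fetal genotype calls as a VCF
#'
#' Calls must be sorted by (chrom, pos). Each record carries INFO keys
#' `METHOD` (call provenance: bayes, sprt, closest1, closest2, unclassified),
#' `CONF` (posterior probability or SPRT-derived confidence, `.` when not
#' defined) and `CAT` (locus category). Unclassified loci are emitted with
#' genotype `./.`.
#'
#' @param calls tibble with columns `chrom, pos, ref, alt, fet_gt, method,
#'   conf` (and optionally `category`).
#' @param path output path (plain-text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_fetal_vcf <- function(calls, path) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "fet_gt", "method", "conf")
                %in% names(calls)))
  if (nrow(calls) > 0) {
    r <- rle(calls$chrom)
    if (anyDuplicated(r$values) > 0) stop("calls are not sorted by chromosome")
    for (ch in r$values) {
      if (is.unsorted(calls$pos[calls$chrom == ch])) {
        stop("calls are not sorted by position on ", ch)
      }
    }
  }
  gt_num <- rep("./.", nrow(calls))
  gt_num[!is.na(calls$fet_gt) & calls$fet_gt == 0L] <- "0/0"
  gt_num[!is.na(calls$fet_gt) & calls$fet_gt == 1L] <- "0/1"
  gt_num[!is.na(calls$fet_gt) & calls$fet_gt == 2L] <- "1/1"
  conf <- ifelse(is.na(calls$conf), ".", sprintf("%.6g", calls$conf))
  cat_ <- if ("category" %in% names(calls)) calls$category else "."
  info <- paste0("METHOD=", calls$method, ";CONF=", conf, ";CAT=", cat_)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=fetoscope",
    "##INFO=<ID=METHOD,Number=1,Type=String,Description=\"Inference engine that produced the call\">",
    "##INFO=<ID=CONF,Number=1,Type=Float,Description=\"Call confidence\">",
    "##INFO=<ID=CAT,Number=1,Type=String,Description=\"Parental locus category\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tFETUS"
  )
  body <- if (nrow(calls) > 0) {
    paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".", "PASS",
          info, "GT", gt_num, sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a fetal (or truth) VCF into a call table
#'
#' @param path VCF path; single-sample, genotypes over \{ref, alt\}.
#' @return tibble `chrom, pos, ref, alt, fet_gt, method, conf` (`method`/
#'   `conf` are `NA` when the INFO keys are absent, as in a cord-blood truth
#'   VCF).
#' @export
read_fetal_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          fet_gt = integer(), method = character(),
                          conf = double()))
  }
  gt_raw <- unname(vcfR::extract.gt(v, element = "GT")[, 1L])
  parts <- strsplit(gt_raw, "[/|]")
  a1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
  a2 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  method <- vcfR::extract.info(v, "METHOD")
  conf <- suppressWarnings(as.numeric(vcfR::extract.info(v, "CONF")))
  tibble::tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    fet_gt = a1 + a2,
    method = if (is.null(method)) NA_character_ else method,
    conf = if (is.null(conf)) NA_real_ else conf
  )
}

#' Read / write a plasma allele-count table
#'
#' Plain TSV with header `chrom pos ref alt ref_count alt_count`; one row per
#' candidate locus, counts are the per-allele cfDNA read counts.
#'
#' @param path TSV path.
#' @return tibble with those six columns.
#' @export
read_plasma_counts <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    ref = readr::col_character(), alt = readr::col_character(),
    ref_count = readr::col_integer(), alt_count = readr::col_integer()
  ))
}

#' @rdname read_plasma_counts
#' @param counts tibble to write.
#' @export
write_plasma_counts <- function(counts, path) {
  readr::write_tsv(counts[, c("chrom", "pos", "ref", "alt",
                              "ref_count", "alt_count")], path)
  invisible(path)
}
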