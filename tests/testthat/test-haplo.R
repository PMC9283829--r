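test_that("locus orientation gives the shifted allele fractions", {
  C <- 0.2
  # ABAA, maternal phase ref|alt (Hap I = ref), father hom-ref:
  # paternal allele equals the Hap I allele
  loci <- tibble::tibble(mat_h1 = 0L, mat_h2 = 1L, pat_allele = 0L,
                         ref_count = 60L, alt_count = 40L)
  o <- orient_loci(loci, C)
  expect_true(o$usable)
  expect_equal(o$b, 60L)            # Hap-I (ref) reads
  expect_equal(o$p1, 0.5 + C / 2)   # fetus = Hap I elevates them
  expect_equal(o$p0, 0.5)           # fetus = Hap II leaves them balanced
  # father hom-alt: paternal allele equals the Hap II allele
  o2 <- orient_loci(dplyr::mutate(loci, pat_allele = 1L), C)
  expect_equal(o2$p1, 0.5)
  expect_equal(o2$p0, 0.5 - C / 2)
  # unphased mother or unresolved paternal allele -> skipped
  expect_false(orient_loci(dplyr::mutate(loci, mat_h1 = NA), C)$usable)
  expect_false(orient_loci(dplyr::mutate(loci, pat_allele = NA), C)$usable)
})

test_that("SPRT decides only when the likelihood ratio crosses the boundary", {
  mk <- function(b, n) tibble::tibble(pos = 1L, b = b, n = n,
                                      p1 = 0.6, p0 = 0.5, accum = TRUE)
  # (120, 200) at q1 = 0.6: LLR = 4.03 < log(1200) = 7.09 -> unclassified
  expect_true(is.na(sprt_classify_block(mk(120L, 200L), L = 1200)$label))
  # doubling the segment crosses: LLR = 8.05 -> Hap I
  expect_equal(sprt_classify_block(mk(240L, 400L), L = 1200)$label, "HapI")
  # balanced counts never decide
  expect_true(is.na(sprt_classify_block(mk(50L, 100L), L = 1200)$label))
  # strong deficit of Hap-I reads -> Hap II
  expect_equal(sprt_classify_block(mk(160L, 400L), L = 1200)$label, "HapII")
})

test_that("segment accumulator resets after each decision", {
  # 6 loci pushing up, then 6 pushing down: two decided segments
  blk <- tibble::tibble(
    pos = seq_len(12) * 1000L,
    b = c(rep(80L, 6), rep(20L, 6)),
    n = rep(100L, 12),
    p1 = 0.6, p0 = 0.5, accum = TRUE)
  res <- sprt_classify_block(blk, L = 1200)
  expect_equal(unique(res$label[res$segment == 1]), "HapI")
  expect_true("HapII" %in% res$label)
  expect_true(max(res$segment) >= 2)
  # labels flip at most once here (one simulated breakpoint)
  runs <- rle(res$label[!is.na(res$label)])$values
  expect_lte(length(runs), 2)
})

test_that("passenger loci inherit the segment label without accumulating", {
  blk <- tibble::tibble(
    pos = c(1000L, 1500L, 2000L, 3000L),
    b = c(80L, NA, 80L, 80L),
    n = c(100L, NA, 100L, 100L),
    p1 = 0.6, p0 = 0.5,
    accum = c(TRUE, FALSE, TRUE, TRUE))
  res <- sprt_classify_block(blk, L = 1200)
  dec <- which(!is.na(res$label))
  if (length(dec)) {
    # the passenger at 1500 is labelled iff its segment decided
    expect_equal(res$label[2], res$label[1])
  }
  # an all-passenger block stays unclassified
  blk2 <- dplyr::mutate(blk, accum = FALSE)
  expect_true(all(is.na(sprt_classify_block(blk2, L = 1200)$label)))
})

test_that("decisions are invariant to within-segment count ordering", {
  # per-locus increments all positive, boundary set so the crossing can only
  # happen at the final locus: the one decision depends on the totals alone
  b <- c(60L, 65L, 70L, 75L, 72L, 68L)
  blk <- function(bv) tibble::tibble(pos = seq_along(bv) * 100L, b = bv,
                                     n = 100L, p1 = 0.6, p0 = 0.5,
                                     accum = TRUE)
  inc_tot <- sum(b * log(0.6 / 0.5) + (100 - b) * log(0.4 / 0.5))
  L <- exp(inc_tot - 0.5)
  for (bv in list(b, rev(b), sample(b))) {
    r <- sprt_classify_block(blk(bv), L = L)
    expect_equal(r$label, rep("HapI", 6))
    expect_equal(r$segment, rep(1L, 6))
  }
})

test_that("SPRT never decides at fetal fraction zero", {
  loci <- tibble::tibble(chrom = "chr1", pos = seq_len(200) * 100L,
                         mat_h1 = 0L, mat_h2 = 1L, mat_block = 1L,
                         ref_count = rbinom(200, 150, 0.55),
                         alt_count = rbinom(200, 150, 0.45),
                         pat_allele = 0L, accum = TRUE)
  res <- sprt_classify(loci, C = 0, L = 1200)
  expect_true(all(is.na(res$mat_hap)))
})

test_that("closest-variant transfers the nearest in-window in-block label", {
  anchors <- tibble::tibble(block = c("chr1:1", "chr1:1"),
                            pos = c(900000L, 1150000L),
                            label = c("HapI", "HapI"))
  tgt <- tibble::tibble(block = "chr1:1", pos = 1000000L)
  expect_equal(closest_variant(tgt, anchors, 200000), "HapI")
  # flanking disagreement inside the window vetoes the call
  anchors2 <- tibble::tibble(block = c("chr1:1", "chr1:1"),
                             pos = c(900000L, 1100000L),
                             label = c("HapI", "HapII"))
  expect_true(is.na(closest_variant(tgt, anchors2, 200000)))
  # nearest anchor outside the window -> unclassified
  far <- tibble::tibble(block = "chr1:1", pos = 1250000L, label = "HapI")
  expect_true(is.na(closest_variant(tgt, far, 200000)))
  # but within the 500 kb window of algorithm 2 it is reachable
  expect_equal(closest_variant(tgt, far, 500000), "HapI")
  # labels never cross block boundaries
  other <- tibble::tibble(block = "chr1:2", pos = 1010000L, label = "HapII")
  expect_true(is.na(closest_variant(tgt, other, 200000)))
})

test_that("closest-variant is symmetric under coordinate reflection", {
  set.seed(31)
  anchors <- tibble::tibble(block = "chr1:1",
                            pos = sort(sample.int(2e6, 30)),
                            label = sample(c("HapI", "HapII"), 30, TRUE))
  tgt <- tibble::tibble(block = "chr1:1", pos = sort(sample.int(2e6, 50)))
  lab <- closest_variant(tgt, anchors, 200000)
  refl <- function(p) 3e6L - p
  lab_r <- closest_variant(dplyr::mutate(tgt, pos = refl(pos)),
                           dplyr::mutate(anchors, pos = refl(pos)), 200000)
  expect_equal(lab, lab_r)
})

test_that("paternal InDel imputation respects window and block", {
  anchors <- tibble::tibble(chrom = "chr1", pos = 900000L,
                            pat_block = 7L, label = "I")
  tgt <- tibble::tibble(chrom = "chr1", pos = 1000000L,
                        pat_h1 = 1L, pat_h2 = 0L, pat_block = 7L)
  # 100 kb from a paternal Hap-I anchor in-block: InDel takes the Hap I allele
  expect_equal(infer_paternal_indels(tgt, anchors), 1L)
  # conflicting flanking anchors -> unclassified
  a2 <- tibble::tibble(chrom = "chr1", pos = c(900000L, 1100000L),
                       pat_block = 7L, label = c("I", "II"))
  expect_true(is.na(infer_paternal_indels(tgt, a2)))
  # anchor in a different paternal block -> unclassified
  a3 <- dplyr::mutate(anchors, pat_block = 8L)
  expect_true(is.na(infer_paternal_indels(tgt, a3)))
})

test_that("block classification recovers simulated maternal inheritance", {
  sim <- small_sim(seed = 4, chrom_length = 2e7)
  df <- dplyr::left_join(sim$loci, sim$counts[, c("chrom", "pos", "ref_count",
                                                  "alt_count")],
                         by = c("chrom", "pos"))
  abaa <- df[df$category == "ABAA" & df$vclass == "SNV" &
               !is.na(df$mat_block), ]
  abaa$pat_allele <- abaa$pat_gt %/% 2L
  abaa$accum <- TRUE
  res <- sprt_classify(abaa, C = 0.13, L = 1200)
  tr <- dplyr::inner_join(abaa, sim$truth[, c("chrom", "pos", "fet_mat")],
                          by = c("chrom", "pos"))
  called <- !is.na(res$mat_hap)
  expect_gt(mean(called), 0.9)
  got <- ifelse(res$mat_hap[called] == "HapI", abaa$mat_h1[called],
                abaa$mat_h2[called])
  expect_gt(mean(got == tr$fet_mat[called]), 0.97)
})
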