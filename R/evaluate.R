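#' Accuracy percentage in the standard report format
#'
#' `100 * n_true / n_total`, rounded half-up to one decimal -- the precision
#' used by the per-category accuracy tables this package emits.
#'
#' @param n_true number of true predictions (0 <= n_true <= n_total).
#' @param n_total number of loci (> 0).
#' @return numeric vector of percentages with one-decimal precision.
#' @examples
#' table1_accuracy(631788, 652391)  # 96.8
#' @export
table1_accuracy <- function(n_true, n_total) {
  if (any(n_total <= 0)) stop("n_total must be positive")
  if (any(n_true < 0 | n_true > n_total)) {
    stop("n_true must lie in [0, n_total]")
  }
  x <- 100 * n_true / n_total
  floor(x * 10 + 0.5 + 1e-9) / 10
}

#' Score fetal calls against truth, per category and variant class
#'
#' Joins calls to a truth table and tabulates true predictions per (category,
#' variant class). The denominator convention differs by engine, matching the
#' standard report format: haplotype-method rows count classified loci only
#' (`denominator = "classified"`), Bayesian and combined rows count all
#' addressable loci, with unclassified calls scored as misses
#' (`denominator = "all"`). Calls absent from the truth table are excluded
#' and counted in `attr(., "n_excluded")`.
#'
#' @param calls tibble with `chrom, pos, category, vclass, fet_gt` (and
#'   `method` when `denominator = "classified"`).
#' @param truth tibble with `chrom, pos, fet_gt` (e.g. `sim$truth` or
#'   [read_fetal_vcf()] output).
#' @param engine label recorded in the output.
#' @param denominator `"all"` or `"classified"`.
#' @return tibble `engine, category, vclass, n_true, n_total, accuracy`.
#' @export
score_calls <- function(calls, truth, engine = "combined",
                        denominator = c("all", "classified")) {
  denominator <- match.arg(denominator)
  tr <- truth[, c("chrom", "pos", "fet_gt")]
  names(tr)[3] <- "true_gt"
  df <- dplyr::inner_join(calls, tr, by = c("chrom", "pos"))
  n_excluded <- nrow(calls) - nrow(df)
  if (denominator == "classified") {
    df <- df[!is.na(df$fet_gt), ]
    if ("method" %in% names(df)) df <- df[df$method != "unclassified", ]
  }
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$category, .data$vclass),
    n_true = sum(!is.na(.data$fet_gt) & .data$fet_gt == .data$true_gt),
    n_total = dplyr::n(), .groups = "drop")
  out$accuracy <- table1_accuracy(out$n_true, out$n_total)
  out <- dplyr::bind_cols(tibble::tibble(engine = rep(engine, nrow(out))), out)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Diagnostic accuracy from a per-variant diagnosis table
#'
#' Tallies a dual-format diagnosis report (one row per inferred target
#' variant, with a logical `correct` column validated against ground truth)
#' into the overall diagnostic accuracy percentage.
#'
#' @param diagnoses tibble with a logical `correct` column.
#' @return list `n_correct, n_total, accuracy` (percent, one decimal).
#' @export
score_diagnoses <- function(diagnoses) {
  stopifnot("correct" %in% names(diagnoses), nrow(diagnoses) > 0)
  n_correct <- sum(diagnoses$correct)
  list(n_correct = n_correct, n_total = nrow(diagnoses),
       accuracy = table1_accuracy(n_correct, nrow(diagnoses)))
}
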