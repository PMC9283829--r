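#' The ten maternal x fetal genotype combinations
#'
#' The Bayesian engine scores a fixed set of n = 10 combinations of the true
#' maternal genotype and the ordered fetal genotype (F1 the maternally
#' transmitted allele, F2 the paternally transmitted allele), alleles drawn
#' from the locus's \{ref (A), alt (B)\} pair:
#'
#' * mother AA: fetus AA, AB (2)
#' * mother AB: fetus AA, AB, BA, BB (4)
#' * mother BB: fetus BA, BB (2)
#' * maternal-error pairs (AA, BB) and (BB, AA), reachable only through the
#'   genotyping/transmission error rate `eps` (2)
#'
#' Internally genotypes are alt-allele dosages; `enumerate_combos()` renders
#' the set with allele strings for a given locus.
#'
#' @return data.frame with columns `mat` (maternal alt dosage), `f1`, `f2`
#'   (alt indicators of the maternally / paternally transmitted allele) and
#'   `mendelian`.
#' @keywords internal
combo_def <- function() {
  data.frame(
    mat = c(0L, 0L, 1L, 1L, 1L, 1L, 2L, 2L, 0L, 2L),
    f1  = c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L, 1L, 0L),
    f2  = c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 1L, 0L),
    mendelian = c(rep(TRUE, 8), FALSE, FALSE)
  )
}

#' Enumerate the genotype combinations for a locus
#'
#' @param ref,alt the locus's reference and alternate allele strings.
#' @return tibble with the maternal genotype, ordered fetal genotype
#'   (maternal allele first), dosage encodings and Mendelian-consistency flag;
#'   always 10 rows (see [combo_def()]).
#' @examples
#' enumerate_combos("A", "B")
#' @export
enumerate_combos <- function(ref = "A", alt = "B") {
  cmb <- combo_def()
  al <- function(x) ifelse(x == 0L, ref, alt)
  gt <- function(d) c(paste0(ref, ref), paste0(ref, alt), paste0(alt, alt))[d + 1L]
  tibble::tibble(
    combo = seq_len(nrow(cmb)),
    maternal = gt(cmb$mat),
    fetal = paste0(al(cmb$f1), al(cmb$f2)),
    mat = cmb$mat, f1 = cmb$f1, f2 = cmb$f2,
    mendelian = cmb$mendelian
  )
}

# prior lookup: 3 x 3 x 10 array indexed by (called maternal gt + 1,
# called paternal gt + 1, combo). eps enters three ways: probability the
# called parental genotype is wrong (mass eps, split over the two other
# genotypes), and a transmission slip for homozygous mothers (P(F1 != the
# hom allele) = eps) which is what gives the two non-Mendelian combos mass.
prior_table <- function(eps) {
  cmb <- combo_def()
  p_called <- function(g, called) ifelse(g == called, 1 - eps, eps / 2)
  p_f1 <- function(f1, m) {
    ifelse(m == 1L, 0.5, ifelse(f1 == m / 2L, 1 - eps, eps))
  }
  arr <- array(0, dim = c(3, 3, nrow(cmb)))
  for (mc in 0:2) {
    for (pc in 0:2) {
      pg <- p_called(0:2, pc)
      t_alt <- pg[2] * 0.5 + pg[3]          # P(paternal transmitted = alt)
      pr <- p_called(cmb$mat, mc) * p_f1(cmb$f1, cmb$mat) *
        ifelse(cmb$f2 == 1L, t_alt, 1 - t_alt)
      arr[mc + 1L, pc + 1L, ] <- pr / sum(pr)
    }
  }
  arr
}

#' Prior over the genotype combinations
#'
#' `P(Ai) = P(true maternal gt | called; eps) * P(F1 | maternal gt) *
#' P(F2 | called paternal gt; Mendel, eps)`, normalised over the 10
#' combinations. With `eps = 0` this reduces to pure Mendelian inheritance
#' from the called parental genotypes.
#'
#' @param maternal_gt,paternal_gt called parental alt-allele dosages (scalars).
#' @param eps genotyping/transmission error rate, in `[0, 0.1]`.
#' @return numeric vector of length 10, summing to 1, in [combo_def()] order.
#' @examples
#' combo_prior(0, 1, eps = 0)  # mother AA, father AB: 0.5 / 0.5 on (AA,AA),(AA,AB)
#' @export
combo_prior <- function(maternal_gt, paternal_gt, eps = 1e-3) {
  stopifnot(length(maternal_gt) == 1L, length(paternal_gt) == 1L,
            maternal_gt %in% 0:2, paternal_gt %in% 0:2,
            eps >= 0, eps <= 0.1)
  prior_table(eps)[maternal_gt + 1L, paternal_gt + 1L, ]
}

#' Per-allele plasma probabilities under a genotype combination
#'
#' The probability of drawing allele j from plasma under combination i is
#' `P_j = B_jF / 2 * C + B_jM / 2 * (1 - C)`, where `B_jF` / `B_jM` count
#' allele j in the fetal / maternal genotype and `C` is the fetal fraction.
#' Sequencing error is then folded in: a read from allele i is misread as a
#' specific other allele with probability `err`, giving
#' `P'_j = P_j (1 - k err) + err (1 - P_j)` with `k` the number of
#' alternative alleles (k = 1 for the biallelic ref/alt pair used here),
#' which sums to 1 by construction. Set `err = 0` (or `smooth = FALSE`) for
#' the unsmoothed value.
#'
#' @param mat maternal alt dosage (0/1/2) of the combination.
#' @param f1,f2 fetal transmitted-allele alt indicators (0/1).
#' @param C fetal fraction as a proportion in (0, 1).
#' @param err per-read sequencing error rate in `[0, 0.05)`.
#' @param smooth apply the error smoothing (default `TRUE`).
#' @return named numeric vector `c(ref = P'_ref, alt = P'_alt)`.
#' @examples
#' allele_probs(0, 0, 1, C = 0.2, err = 0)  # mother AA, fetus AB: 0.9 / 0.1
#' @export
allele_probs <- function(mat, f1, f2, C, err = 1e-3, smooth = TRUE) {
  stopifnot(C > 0, C < 1, err >= 0, err < 0.05)
  p_alt <- (f1 + f2) / 2 * C + mat / 2 * (1 - C)
  if (smooth && err > 0) p_alt <- p_alt * (1 - 2 * err) + err
  c(ref = 1 - p_alt, alt = p_alt)
}

#' Likelihood score of plasma counts under a combination
#'
#' Two parameterisations are provided. `"literal"` is the flat weighted mean
#' `sum(P_j A_j) / sum(A_j)`; `"multinomial"` is the standard log-likelihood
#' `sum(A_j log P_j)`. The multinomial form is the package default throughout
#' because the weighted mean does not rank genotype combinations by fit (it
#' is maximised by whichever combination puts most mass on the majority
#' allele); see the methods vignette.
#'
#' @param ref_count,alt_count plasma read counts for the two alleles.
#' @param probs allele probability vector from [allele_probs()].
#' @param mode `"literal"` or `"multinomial"`.
#' @return scalar score (a probability-scale mean for `"literal"`, a
#'   log-likelihood for `"multinomial"`).
#' @examples
#' combo_likelihood(90, 10, c(ref = 0.9, alt = 0.1), mode = "literal")  # 0.82
#' @export
combo_likelihood <- function(ref_count, alt_count, probs,
                             mode = c("multinomial", "literal")) {
  mode <- match.arg(mode)
  depth <- ref_count + alt_count
  if (depth == 0) stop("zero depth: locus should be flagged no-call upstream")
  if (mode == "literal") {
    (probs[["ref"]] * ref_count + probs[["alt"]] * alt_count) / depth
  } else {
    ref_count * log(probs[["ref"]]) + alt_count * log(probs[["alt"]])
  }
}

#' Vectorised Bayesian fetal genotype calls
#'
#' For each locus, computes the posterior over the 10 maternal x fetal
#' genotype combinations (prior from the called parental genotypes, data
#' model from the fetal fraction and plasma counts), and calls the fetal
#' genotype of the maximum-posterior combination. The reported confidence is
#' the summed posterior of all combinations sharing that (unordered) fetal
#' genotype; `conf_pat` analogously for the paternally transmitted allele,
#' used when Bayesian calls anchor the haplotype engine.
#'
#' Ties are broken deterministically by combination order (Mendelian
#' combinations first, fetal genotypes with fewer alt alleles first).
#' Zero-depth loci are returned with `ok = FALSE` (no call).
#'
#' @param loci locus table (needs `mat_gt`, `pat_gt`); may already contain
#'   count columns, otherwise supply `counts`.
#' @param counts plasma counts tibble joined on (chrom, pos), or `NULL` if
#'   `loci` already has `ref_count`/`alt_count`.
#' @param C fetal fraction (proportion).
#' @param eps parental genotyping error rate.
#' @param err per-read sequencing error rate.
#' @param mode likelihood mode, see [combo_likelihood()].
#' @return tibble aligned with `loci`: `fet_gt, fet_mat, fet_pat, conf,
#'   conf_pat, ok`.
#' @export
bayes_call <- function(loci, counts = NULL, C, eps = 1e-3, err = 1e-3,
                       mode = c("multinomial", "literal")) {
  mode <- match.arg(mode)
  stopifnot(C > 0, C < 1)
  df <- if (is.null(counts)) loci else
    dplyr::left_join(loci, counts, by = c("chrom", "pos"))
  rc <- df$ref_count
  ac <- df$alt_count
  rc[is.na(rc)] <- 0L
  ac[is.na(ac)] <- 0L
  n <- nrow(df)
  cmb <- combo_def()
  p_alt <- (cmb$f1 + cmb$f2) / 2 * C + cmb$mat / 2 * (1 - C)
  if (err > 0) p_alt <- p_alt * (1 - 2 * err) + err
  p_ref <- 1 - p_alt

  pt <- prior_table(eps)
  prior <- matrix(0, n, nrow(cmb))
  idx <- cbind(df$mat_gt + 1L, df$pat_gt + 1L)
  for (k in seq_len(nrow(cmb))) prior[, k] <- pt[cbind(idx, k)]

  if (mode == "multinomial") {
    t_ref <- outer(rc, log(p_ref))
    t_ref[is.nan(t_ref)] <- 0      # 0 * log(0): no reads of an impossible allele
    t_alt <- outer(ac, log(p_alt))
    t_alt[is.nan(t_alt)] <- 0
    ll <- t_ref + t_alt
    mx <- do.call(pmax, as.data.frame(ll))
    w <- prior * exp(ll - mx)
  } else {
    depth <- pmax(rc + ac, 1L)
    lik <- (outer(rc, p_ref) + outer(ac, p_alt)) / depth
    w <- prior * lik
  }
  s <- rowSums(w)
  ok <- (rc + ac) > 0 & s > 0 & is.finite(s)
  post <- w / ifelse(s > 0, s, 1)

  k_star <- max.col(post, ties.method = "first")
  fsum <- cmb$f1 + cmb$f2
  fet_gt <- fsum[k_star]
  fet_mat <- cmb$f1[k_star]
  fet_pat <- cmb$f2[k_star]
  ind_gt <- outer(fsum, 0:2, `==`) * 1
  post_gt <- post %*% ind_gt
  conf <- post_gt[cbind(seq_len(n), fet_gt + 1L)]
  ind_pat <- cbind(1 - cmb$f2, cmb$f2)
  post_pat <- post %*% ind_pat
  conf_pat <- post_pat[cbind(seq_len(n), fet_pat + 1L)]

  fet_gt[!ok] <- NA_integer_
  fet_mat[!ok] <- NA_integer_
  fet_pat[!ok] <- NA_integer_
  conf[!ok] <- NA_real_
  conf_pat[!ok] <- NA_real_
  tibble::tibble(fet_gt = as.integer(fet_gt), fet_mat = as.integer(fet_mat),
                 fet_pat = as.integer(fet_pat), conf = conf,
                 conf_pat = conf_pat, ok = ok)
}

#' Posterior fetal genotype call at a single locus
#'
#' Single-locus interface to the Bayesian engine, returning the full
#' prior/likelihood/posterior vector over the 10 genotype combinations
#' alongside the call.
#'
#' @param locus one-row locus table (or list) with `mat_gt`, `pat_gt` and
#'   optionally `ref`/`alt`.
#' @param counts list or one-row tibble with `ref_count`, `alt_count`.
#' @inheritParams bayes_call
#' @return list of class `fetoscope_posterior` with elements `call` (tibble:
#'   `fet_gt, fet_mat, fet_pat, method, conf`) and `posterior` (tibble over
#'   the 10 combinations with `prior`, `lik`, `post`).
#' @export
posterior_call <- function(locus, counts, C, eps = 1e-3, err = 1e-3,
                           mode = c("multinomial", "literal")) {
  mode <- match.arg(mode)
  rc <- counts$ref_count
  ac <- counts$alt_count
  loci1 <- tibble::tibble(chrom = "x", pos = 1L,
                          mat_gt = locus$mat_gt, pat_gt = locus$pat_gt,
                          ref_count = rc, alt_count = ac)
  res <- bayes_call(loci1, counts = NULL, C = C, eps = eps, err = err,
                    mode = mode)
  cmb <- combo_def()
  prior <- combo_prior(locus$mat_gt, locus$pat_gt, eps)
  p_alt <- (cmb$f1 + cmb$f2) / 2 * C + cmb$mat / 2 * (1 - C)
  if (err > 0) p_alt <- p_alt * (1 - 2 * err) + err
  if (rc + ac > 0) {
    lik <- if (mode == "literal") {
      ((1 - p_alt) * rc + p_alt * ac) / (rc + ac)
    } else {
      t1 <- rc * log(1 - p_alt)
      t1[is.nan(t1)] <- 0
      t2 <- ac * log(p_alt)
      t2[is.nan(t2)] <- 0
      exp(t1 + t2 - max(t1 + t2))
    }
    post <- prior * lik
    post <- if (sum(post) > 0) post / sum(post) else rep(NA_real_, length(post))
  } else {
    lik <- rep(NA_real_, nrow(cmb))
    post <- lik
  }
  ref <- if (!is.null(locus$ref)) locus$ref else "A"
  alt <- if (!is.null(locus$alt)) locus$alt else "B"
  pv <- enumerate_combos(ref, alt)
  pv$prior <- prior
  pv$lik <- lik
  pv$post <- post
  call <- tibble::tibble(
    fet_gt = res$fet_gt, fet_mat = res$fet_mat, fet_pat = res$fet_pat,
    method = ifelse(res$ok, "bayes", "unclassified"), conf = res$conf
  )
  structure(list(call = call, posterior = pv), class = "fetoscope_posterior")
}

#' @export
print.fetoscope_posterior <- function(x, ...) {
  cat("Bayesian fetal genotype call\n")
  print(x$call)
  cat("\nPosterior over genotype combinations:\n")
  print(x$posterior[, c("combo", "maternal", "fetal", "prior", "lik", "post")])
  invisible(x)
}
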