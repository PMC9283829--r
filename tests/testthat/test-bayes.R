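test_that("combo enumeration has the documented 10 members", {
  cmb <- enumerate_combos("A", "B")
  expect_equal(nrow(cmb), 10L)
  key <- paste(cmb$maternal, cmb$fetal)
  # Mendelian-consistent ordered pairs present
  expect_true(all(c("AA AA", "AA AB", "AB AA", "AB AB", "AB BA", "AB BB",
                    "BB BA", "BB BB") %in% key))
  # mother AA cannot transmit B: (AA, BA)/(AA, BB) only as error combos
  expect_false("AA BA" %in% key)
  expect_true(all(!cmb$mendelian[key %in% c("AA BB", "BB AA")]))
  expect_equal(sum(cmb$mendelian), 8L)
})

test_that("priors reduce to Mendelian inheritance at eps = 0", {
  cmb <- enumerate_combos("A", "B")
  pr <- combo_prior(0, 0, eps = 0)
  expect_equal(pr[cmb$maternal == "AA" & cmb$fetal == "AA"], 1)
  pr <- combo_prior(0, 1, eps = 0)
  expect_equal(pr[cmb$maternal == "AA" & cmb$fetal == "AA"], 0.5)
  expect_equal(pr[cmb$maternal == "AA" & cmb$fetal == "AB"], 0.5)
  pr <- combo_prior(1, 1, eps = 0)
  expect_equal(pr[cmb$maternal == "AB" & cmb$fetal == "AA"], 0.25)
  expect_equal(sum(pr[cmb$maternal == "AB" & cmb$fetal %in% c("AB", "BA")]),
               0.5)
  expect_equal(pr[cmb$maternal == "AB" & cmb$fetal == "BB"], 0.25)
  # priors always sum to 1, with and without eps
  for (m in 0:2) for (p in 0:2) {
    expect_equal(sum(combo_prior(m, p, eps = 0)), 1)
    expect_equal(sum(combo_prior(m, p, eps = 1e-3)), 1)
  }
})

test_that("error combos carry prior mass only through eps", {
  cmb <- enumerate_combos("A", "B")
  err_rows <- !cmb$mendelian
  expect_equal(sum(combo_prior(0, 0, eps = 0)[err_rows]), 0)
  expect_gt(sum(combo_prior(0, 0, eps = 1e-2)[err_rows]), 0)
})

test_that("allele probabilities follow the mixture formula", {
  # mother AA, fetus AB at C = 0.2: alt from fetal half-dose only
  expect_equal(allele_probs(0, 0, 1, C = 0.2, err = 0),
               c(ref = 0.9, alt = 0.1))
  # mother AB, fetus AB: balanced at any C
  expect_equal(allele_probs(1, 0, 1, C = 0.37, err = 0),
               c(ref = 0.5, alt = 0.5))
  # C -> 0 limit: probabilities depend on the maternal genotype only
  p <- allele_probs(1, 1, 1, C = 1e-9, err = 0)
  expect_equal(unname(p["alt"]), 0.5, tolerance = 1e-6)
  p <- allele_probs(0, 1, 1, C = 1e-9, err = 0)
  expect_equal(unname(p["alt"]), 0, tolerance = 1e-6)
  # error smoothing keeps a proper distribution
  p <- allele_probs(0, 0, 1, C = 0.2, err = 1e-3)
  expect_equal(sum(p), 1)
  expect_true(all(p > 0))
})

test_that("literal likelihood reproduces the printed weighted mean", {
  expect_equal(combo_likelihood(90, 10, c(ref = 0.9, alt = 0.1),
                                mode = "literal"), 0.82)
  expect_equal(combo_likelihood(100, 0, c(ref = 1, alt = 0),
                                mode = "literal"), 1.0)
  expect_error(combo_likelihood(0, 0, c(ref = 1, alt = 0), "literal"),
               "zero depth")
})

test_that("literal-mode combo ranking matches an exhaustive recomputation", {
  cases <- random_locus_cases(40, seed = 301)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    pv <- posterior_call(list(mat_gt = cs$mat_gt, pat_gt = cs$pat_gt),
                         list(ref_count = cs$ref_count,
                              alt_count = cs$alt_count),
                         C = cs$C, eps = 1e-3, err = 1e-3,
                         mode = "literal")$posterior
    oracle <- oracle_posterior(cs$mat_gt, cs$pat_gt, cs$ref_count,
                               cs$alt_count, cs$C, 1e-3, 1e-3, "literal")
    expect_equal(pv$post, oracle, tolerance = 1e-12)
    expect_equal(which.max(pv$post), which.max(oracle))
  }
})

test_that("posterior calls follow the plasma allele balance", {
  # mother AA / father AA, eps 0: prior pins the call regardless of counts
  p <- posterior_call(list(mat_gt = 0L, pat_gt = 0L),
                      list(ref_count = 37L, alt_count = 63L),
                      C = 0.2, eps = 0, err = 1e-3)
  expect_equal(p$call$fet_gt, 0L)
  expect_equal(p$call$conf, 1)
  # mother AA / father AB at C = 0.2: 10% alt reads fit a het fetus
  p <- posterior_call(list(mat_gt = 0L, pat_gt = 1L),
                      list(ref_count = 90L, alt_count = 10L), C = 0.2)
  expect_equal(p$call$fet_gt, 1L)
  expect_equal(p$call$fet_gt,
               oracle_call_gt(0, 1, 90, 10, 0.2, 1e-3, 1e-3, "multinomial"))
  # mother AB / father AA: argmax agrees with the brute force
  p <- posterior_call(list(mat_gt = 1L, pat_gt = 0L),
                      list(ref_count = 55L, alt_count = 45L), C = 0.2)
  expect_equal(p$call$fet_gt,
               oracle_call_gt(1, 0, 55, 45, 0.2, 1e-3, 1e-3, "multinomial"))
  # zero depth -> unclassified
  p <- posterior_call(list(mat_gt = 0L, pat_gt = 1L),
                      list(ref_count = 0L, alt_count = 0L), C = 0.2)
  expect_equal(p$call$method, "unclassified")
  expect_true(is.na(p$call$fet_gt))
})

test_that("posterior vectors are normalised", {
  cases <- random_locus_cases(50, seed = 77)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    pv <- posterior_call(list(mat_gt = cs$mat_gt, pat_gt = cs$pat_gt),
                         list(ref_count = cs$ref_count,
                              alt_count = cs$alt_count), C = cs$C)
    expect_equal(sum(pv$posterior$prior), 1, tolerance = 1e-9)
    expect_equal(sum(pv$posterior$post), 1, tolerance = 1e-9)
  }
})

test_that("vectorised and single-locus engines agree", {
  cases <- random_locus_cases(60, seed = 88)
  loci <- tibble::tibble(chrom = "chr1", pos = seq_len(nrow(cases)) * 10L,
                         mat_gt = cases$mat_gt, pat_gt = cases$pat_gt,
                         ref_count = cases$ref_count,
                         alt_count = cases$alt_count)
  bb <- bayes_call(loci, C = 0.1)
  for (i in seq_len(nrow(cases))) {
    p <- posterior_call(list(mat_gt = cases$mat_gt[i],
                             pat_gt = cases$pat_gt[i]),
                        list(ref_count = cases$ref_count[i],
                             alt_count = cases$alt_count[i]), C = 0.1)
    expect_equal(bb$fet_gt[i], p$call$fet_gt)
  }
})
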