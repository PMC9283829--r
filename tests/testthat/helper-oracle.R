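# Independent brute-force of the Bayesian posterior (plain loops, coded from
# the model definition, sharing no internals with the package implementation).
# Genotypes as alt dosage; combos as (true maternal gt, F1 alt, F2 alt).

oracle_combos <- list(
  c(0, 0, 0), c(0, 0, 1),
  c(1, 0, 0), c(1, 0, 1), c(1, 1, 0), c(1, 1, 1),
  c(2, 1, 0), c(2, 1, 1),
  c(0, 1, 1), c(2, 0, 0)
)

oracle_prior <- function(mat_called, pat_called, eps) {
  p_g <- function(g, called) if (g == called) 1 - eps else eps / 2
  p_transmit_alt <- p_g(1, pat_called) * 0.5 + p_g(2, pat_called)
  pr <- numeric(10)
  for (i in 1:10) {
    cb <- oracle_combos[[i]]
    m <- cb[1]; f1 <- cb[2]; f2 <- cb[3]
    pf1 <- if (m == 1) 0.5 else if (f1 == m / 2) 1 - eps else eps
    pf2 <- if (f2 == 1) p_transmit_alt else 1 - p_transmit_alt
    pr[i] <- p_g(m, mat_called) * pf1 * pf2
  }
  pr / sum(pr)
}

oracle_posterior <- function(mat_called, pat_called, rc, ac, C, eps, err,
                             mode) {
  pr <- oracle_prior(mat_called, pat_called, eps)
  score <- numeric(10)
  for (i in 1:10) {
    cb <- oracle_combos[[i]]
    p_alt <- (cb[2] + cb[3]) / 2 * C + cb[1] / 2 * (1 - C)
    if (err > 0) p_alt <- p_alt * (1 - 2 * err) + err
    p_ref <- 1 - p_alt
    if (mode == "literal") {
      score[i] <- (p_ref * rc + p_alt * ac) / (rc + ac)
    } else {
      lt <- 0
      if (rc > 0) lt <- lt + rc * log(p_ref)
      if (ac > 0) lt <- lt + ac * log(p_alt)
      score[i] <- lt
    }
  }
  if (mode == "multinomial") score <- exp(score - max(score))
  post <- pr * score
  post / sum(post)
}

# oracle argmax over unordered fetal genotypes (sum posterior per genotype,
# matching the confidence definition; the called genotype is that of the
# maximum-posterior combination, first-max tie-break like the package)
oracle_call_gt <- function(mat_called, pat_called, rc, ac, C, eps, err,
                           mode) {
  post <- oracle_posterior(mat_called, pat_called, rc, ac, C, eps, err, mode)
  fsum <- vapply(oracle_combos, function(cb) cb[2] + cb[3], numeric(1))
  fsum[which.max(post)]
}
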