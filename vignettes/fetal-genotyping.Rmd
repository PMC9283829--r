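---
title: "Non-invasive fetal genotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-invasive fetal genotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetoscope)
```

## The problem

During pregnancy, maternal plasma carries a mixture of maternal and placental
(fetal) cell-free DNA fragments. The fetal fraction (FF, written `C` as a
proportion) is typically 4–27%. At any biallelic variant site the plasma
allele counts are therefore a mixture: a fraction `1 - C` of reads drawn from
the maternal genotype and `C` drawn from the fetal genotype. Given deep
plasma sequencing and the parents' genotypes — with the parental heterozygous
sites phased into long haplotype blocks — the fetal genotype can be inferred
genome-wide without invasive sampling.

Loci are grouped by parental genotype configuration: `AAAB` (mother
homozygous, father heterozygous), `ABAA` (mother heterozygous, father
homozygous), `ABAB` (both heterozygous), `AAAA` (both homozygous). The labels
are symbolic — a homozygous-alt parent plays the `AA` role after relabelling —
so the category depends only on parental heterozygosity. Each category gets
the inference strategy that suits its information content.

## Fetal fraction

At sites where the mother is homozygous and the father carries the other
allele, reads showing the non-maternal allele are fetal-specific. With `p`
the summed fetal-specific reads and `q` the summed shared (maternal-allele)
reads over such sites,

$$\mathrm{FF} = \frac{2p}{p+q} \times 100.$$

Site selection must be operationalised from parental genotypes alone, since
fetal heterozygosity is unknown a priori. The primary set is
mother-hom / father-hom-for-the-other-allele sites, where the fetus is an
obligate heterozygote and the estimator is unbiased. When fewer than 500 such
sites exist we fall back to mother-hom / father-het sites, where the fetus
inherits the paternal non-maternal allele only half the time; `p` is doubled
to compensate. The fallback carries a small second-order bias (relative size
about `C/4`), which is why the obligate-het set is preferred whenever
available. Zero-depth sites are skipped; the estimator is invariant to site
order and to uniform count scaling.

## The Bayesian engine

At each locus the engine scores `n = 10` combinations of the true maternal
genotype and the *ordered* fetal genotype `F1F2` (`F1` maternally
transmitted, `F2` paternally transmitted): 2 for mother `AA`, 4 for mother
`AB`, 2 for mother `BB`, plus the two maternal-error pairs `(AA, BB)` and
`(BB, AA)` which are reachable only through the error rate `eps` (a
genotyping/transmission slip; at `eps = 0` their prior is exactly zero and
the prior reduces to Mendelian inheritance from the called parental
genotypes).

The data model: under combination `i` the probability of drawing allele `j`
from plasma is

$$P_j = \frac{B_{jF}}{2} C + \frac{B_{jM}}{2} (1 - C),$$

with `B_jF`, `B_jM` the allele-j counts in the fetal and maternal genotypes.
Sequencing error is folded in by
`P'_j = P_j (1 - k\,err) + err (1 - P_j)` with `k = 1` alternative allele,
which keeps the vector normalised. The posterior is
`P(A_i | B) ∝ P(A_i) · P(B | A_i)`, normalised over the 10 combinations; the
call is the fetal genotype of the maximum-posterior combination and the
confidence is the posterior mass summed over combinations sharing that
(unordered) fetal genotype.

### Likelihood parameterisation

Two forms of `P(B | A_i)` are provided. The `literal` form is the flat
weighted mean `\sum_j P_j A_j / \sum_j A_j`. The `multinomial` form is the
standard count log-likelihood `\sum_j A_j \log P'_j`. The package default —
everywhere, including the combined caller — is `multinomial`, for a
structural reason: the weighted mean is maximised by whichever combination
puts the most mass on the majority allele, so it cannot rank combinations by
fit. Concretely, at a mother-AA/father-AB locus with `C = 0.2` and counts
(ref 90, alt 10) the observed alt fraction 0.10 exactly matches the
het-fetus expectation `C/2`, yet the weighted mean prefers the hom-ref
fetus; the multinomial likelihood calls the heterozygote. Only the
multinomial form yields per-category accuracies in the range this method is
expected to deliver. The literal form is retained as a documented,
unit-tested alternative (`mode = "literal"`).

Tie-breaking is deterministic: combinations are enumerated Mendelian-first
with fewer-alt fetal genotypes first, and the first maximum wins. Zero-depth
loci are no-calls. Defaults `eps = 1e-3`, `err = 1e-3` are typical
short-read germline error magnitudes.

## The haplotype engine (relative haplotype dosage)

At a maternally heterozygous phased locus, write Hap I / Hap II for the two
maternal haplotypes and let `b` be the plasma count of the Hap I allele out
of `n` total. The paternal contribution at the locus is known (father's
homozygous allele at `ABAA`; the closest-variant-resolved allele at `ABAB`).
A little bookkeeping on the mixture gives the expected Hap-I-allele
fraction:

| paternal allele | fetus = Hap I | fetus = Hap II |
|---|---|---|
| equals Hap I allele  | `0.5 + C/2` | `0.5` |
| equals Hap II allele | `0.5` | `0.5 - C/2` |

Both rows give a positive log-likelihood-ratio drift under "fetus carries
Hap I", so a single sequential probability ratio test (SPRT) per block can
accumulate loci of mixed orientation. The cumulative binomial log-LR is
compared with a symmetric boundary `log L`; we use `L = 1200` by default, a
conservative bound giving a nominal per-decision error near `1/L`. When a
boundary is crossed, *all* loci of the current accumulation segment
(including non-accumulating passengers, see below) take the decision's
label, and the accumulator resets — so a recombination breakpoint mid-block
simply flips subsequent segments. Segments that never reach a boundary stay
unclassified.

Unclassified loci are then imputed by the closest-variant rule: take the
label of the nearest classified locus within a window **in the same block**
(200 kb for algorithm 1, used for SNVs; 500 kb for algorithm 2, used for
InDels), unless the nearest upstream and downstream anchors inside the
window disagree, in which case the locus is left unclassified. A single
in-window anchor on one side suffices; flanking disagreement vetoes. Labels
never cross block boundaries.

InDel counts are excluded from SPRT accumulation: their plasma counts are
noisier than SNV counts (alignment around the event inflates miscounts), and
feeding them to the accumulator would degrade decisions at neighbouring
SNVs. InDels instead ride as passengers — labelled by the decided segment
that contains them — or are imputed by closest-variant algorithm 2.

## The combined caller

Per-category dispatch, with Bayesian gap-filling:

* `AAAA`, `AAAB` SNVs → Bayesian call.
* `ABAA` SNVs → paternal allele is the father's homozygous allele; maternal
  allele by SPRT, then closest-variant 1, then Bayesian fallback.
* `ABAB` SNVs → paternal allele by closest-variant 1 anchored on
  high-confidence Bayesian `AAAB` calls (paternal-allele posterior ≥ 0.95 by
  default) within 200 kb in the same paternal block; maternal allele by SPRT
  (such loci join the block accumulator once the paternal side is resolved)
  or closest-variant 1; loci unresolved on either side fall back to the
  Bayesian call.
* InDels → paternal allele at `AAAB`/`ABAB` by closest-variant 2 on the
  paternal blocks; maternal allele from the containing SPRT segment or
  closest-variant 2; unresolved InDels stay unclassified (no Bayesian
  gap-fill — the Bayesian model's InDel counts are the noisy ones the
  haplotype path exists to avoid).

When both paths resolve a locus, the haplotype call wins (it is the more
accurate engine at maternal-het categories). Every locus ends with exactly
one provenance among `bayes`, `sprt`, `closest1`, `closest2`,
`unclassified`. The anchor-confidence floor exists because an anchor error
propagates along a block: a misassigned paternal haplotype at one `AAAB`
locus would mislabel every `ABAB` locus that imputes from it.

## The simulator

`simulate_family()` provides ground truth for every engine. Its defaults
*are* the study conditions the pipeline targets: FF 13% (range used in
validation 4–27%), plasma depth 100x Poisson, per-read error `1e-3` (doubled
for InDels to model their lower count fidelity), ~1 SNV per 1.5 kb and ~1
InDel per 12 kb with population alt-frequency uniform on 0.05–0.5 and
parents as independent Hardy–Weinberg draws, maternal/paternal block N50 of
18.72 / 13.57 Mb, 99.5% of heterozygous sites phased, and recombination at
0.012 crossovers per Mb. Blocks are generated by fragmenting the true
haplotypes at Poisson-process breakpoints whose rate is tuned so the
length-weighted median block length (N50) matches the target (for
exponential lengths the length-biased median is ~1.678 times the mean). The
fetus is one recombined gamete per parent; plasma counts are drawn
read-by-read in distribution (depth Poisson, fetal origin Bernoulli(`C`),
allele from the carrier genotype, error flip).

What the simulator does **not** emulate: GC and mappability bias, duplicated
or low-complexity regions, maternal mosaicism, variant-calling errors in the
parents (beyond the `eps` the Bayesian prior absorbs), phasing switch
errors, and the long-tailed InDel alignment artefacts of real pipelines.
Passing tests on simulation therefore demonstrate correctness of the
inference machinery under the stated mixture model, not performance on real
plasma data; simulated accuracies run a few points above published
real-data figures for exactly this reason.

## Numerical choices and degenerate inputs

* Coordinates are 1-based as in VCF; the 200/500 kb windows are inclusive.
* Accuracy percentages round half-up to one decimal, matching the
  conventional report format.
* Posterior normalisation is exact to 1e-9 at every called locus (tested);
  the multinomial likelihood is computed in log space with the `0·log 0 = 0`
  convention so `err = 0` is safe.
* Zero-depth loci: Bayesian no-call; they can still be labelled by the
  haplotype path (the label derives from neighbours, not from the locus's
  own counts).
* `C = 0` makes the SPRT hypotheses coincide; it then never decides
  (tested). The Bayesian engine requires `C > 0`.
* Parental VCF quality filters default to `QUAL >= 30` and
  `10 <= DP <= 3 x mean(DP)` when DP is present — ordinary germline hygiene,
  configurable.
* X-chromosome loci are handled by the same machinery when the father's
  hemizygous genotype is encoded as homozygous for his single allele;
  no X-specific dosage model is applied.

## Problem sizes used in the shipped tests

The test suite and acceptance script run the full pipeline on single
chromosomes of 2–50 Mb (10k–35k loci) and the fetal-fraction recovery checks
on a 1 Gb chromosome (~500k loci, ≥50k informative sites), ten seeds per FF
level — sizes chosen so each check exercises thousands of loci per category
while the whole suite completes in a coffee break. All simulations are
seeded and byte-reproducible.

## Known limitations

* The SPRT boundary `L = 1200` and the anchor-confidence floor 0.95 are
  sensible defaults, not fitted constants; real-data tuning may move them.
* The closest-variant conflict rule discards targets with disagreeing
  flanks; no attempt is made to weigh flank distances or confidences.
* The fallback FF estimator (father-het sites) carries the small `C/4`
  relative bias noted above.
* Multiallelic sites are excluded upstream; de-novo mutations are scored by
  the Bayesian model only through the `eps`-weighted error combinations and
  are not separately validated.
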