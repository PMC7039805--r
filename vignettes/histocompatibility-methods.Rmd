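---
title: "Mother-child histocompatibility: models, scoring and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mother-child histocompatibility: models, scoring and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histocompat)
```

This vignette is the package's own account of the methods it implements:
the compatibility model and its edge cases, the SSM similarity score, the
HLA-restricted mHag layer, the association statistics, what the synthetic
cohort generator does and does not emulate, and the numerical conventions
fixed where the underlying method left them open.

## The compatibility model

The unit of analysis is a mother. The exposure of interest is whether she
has at least one child who is *histocompatible from her perspective* at a
locus: the child's paternally inherited allele is indistinguishable (at
two-field, i.e. protein-level, resolution) from one of her own two
alleles. The immunological intuition is graft-like: a fetus whose
paternal HLA looks like self to the mother is less likely to be rejected,
so fetal cells may persist (microchimerism) and interact with
autoimmunity.

Genotypes are unphased, so the paternal allele must be inferred from the
mother-child pair. Writing the mother as the multiset $\{m_1, m_2\}$ and
the child as $\{c_1, c_2\}$:

* if exactly one child allele lies in the mother's set, the assignment is
  forced: that allele was transmitted, the other is paternal, and the
  mother's other copy is the noninherited maternal allele (NIMA);
* if both child alleles are maternal and distinct, phase cannot be
  resolved (`ambiguous_both_maternal`) — but every consistent assignment
  leaves the paternal allele inside the mother's set, so the verdict is
  still determined: compatible;
* if neither child allele is maternal, the pair is flagged
  `mendelian_error`;
* a homozygous child $\{m_1, m_1\}$ of a heterozygous mother has the
  unique assignment transmitted $= m_1$, paternal $= m_1$, NIMA $= m_2$.

Matching consumes multiplicity — a homozygous mother $\{m, m\}$ can only
transmit $m$ — which prevents spurious Mendelian errors. These cases
collapse to a single set rule, *compatible $\iff \{c_1, c_2\} \subseteq
\{m_1, m_2\}$*, and the test suite verifies the classifier against an
oracle that enumerates every Mendelian phase assignment over all genotype
combinations on alphabets of up to six alleles.

**Eligibility.** For case mothers only children born before diagnosis
count (exposure must precede disease); all children of control mothers
are eligible — the data carry no diagnosis date for controls, and
restricting them would discard exposure information without a
corresponding index date. A child with a missing verdict is excluded from
the any-child OR but tallied; a mother's exposure is missing only when no
eligible child has a usable verdict. Mothers are retained in the HLA
analyses only with complete exposure data at all seven loci
(complete-case analysis), and a chi-square test per locus probes whether
missingness differs by case-control status, since differential
missingness under complete-case filtering is the main selection-bias
risk.

## SSM: graded similarity for non-identical pairs

Binary compatibility ignores how *far* a mismatch is. The sequence
similarity matching (SSM) score of two alleles with pre-aligned protein
sequences is

$$\mathrm{SSM}(a, b) \;=\; \sum_{p\,:\,a[p] \neq b[p]} w(p)\, d(a[p], b[p]),$$

a positional sum of amino-acid dissimilarities $d$ weighted by
functional-position weights $w \ge 0$. Lower scores mean greater
similarity; identical alleles score 0. For a mother-child pair the
relevant comparison is NIMA versus paternal allele — the two alleles not
shared by descent. Pairs with set-identical genotypes score exactly 0 by
convention. When the transmission assignment is not unique the
assignment minimising the score is used: this is deterministic,
conservative (it biases toward similarity), and coincides with the zero
rule on identical genotypes; it is checked against exhaustive assignment
enumeration in the tests.

Per mother and locus, pair scores of eligible children are averaged, and
the averages are cut into quartiles at the control group's 25/50/75th
percentiles. Quartile 1 (smallest scores) is the *most* histocompatible
group, quartile 4 the *least*; association models compare Q1 against Q4
as reference and test for linear trend across Q1-Q4.

Because the exact dissimilarity values and position weights of the
original web-tool scorer are not public, the scorer is fully
parameterised by an `ssm_resources()` object. The packaged default uses
uniform weights and a generic 20×20 dissimilarity derived from BLOSUM62
as $d(a,b) = s(a,a) + s(b,b) - 2s(a,b)$, which is symmetric,
non-negative and zero-diagonal by construction. Absolute score values
therefore depend on the chosen resources; ranking-based quantities
(quartiles, compatible-vs-incompatible score ordering) are the meaningful
outputs. Sequences must be pre-aligned to equal length within a locus —
no internal alignment is attempted, and unequal lengths are an error
rather than a silent trim.

## HLA-restricted mHags

Minor histocompatibility antigens are polymorphic peptides encoded
outside the HLA region, presented only by a specific HLA restriction
allele. Six are analysed, each tagged by a biallelic SNP:
SLC19A1 (rs1051266, DRB1\*15:01), LB-WNK1 (rs12828016, A\*02:01),
HA-3 (rs2061821, A\*01:01), ZAPHIR (rs2074071, B\*07:02),
HEATR1 (rs2275687, B\*08:01) and C19orf48 (rs3745526, A\*02:01).
Compatibility at the SNP uses the same mother-perspective rule on a
two-letter alphabet (so every Mendelian child of a heterozygous mother is
compatible), not predicted peptide immunogenicity — the SNP is treated as
the antigen's proxy. Because the antigen is only visible to the maternal
immune system when the mother can present it, each mHag's analysis set is
the mothers carrying at least one copy of the restriction allele
(carriage, not dosage).

The combined HLA+mHag exposure asks for a child compatible at the
restriction HLA locus *and* at the mHag; the conjunction is evaluated per
child and then OR-ed across children. A mother with one HLA-compatible
child and a different mHag-compatible child is *not* combined-compatible
— the hypothesis concerns a single persistent fetal cell population, so
both properties must hold for the same child. Combined-compatible
therefore nests inside mHag-compatible, which the tests assert.

## Association statistics and numerical conventions

* **Adjusted ORs** come from maximum-likelihood logistic regression with
  the number of live births as a continuous linear covariate; the OR is
  the exponentiated exposure coefficient with a Wald 95% interval and
  Wald p. Wald (rather than profile-likelihood) intervals are the
  standard epidemiological presentation and are exactly the
  cross-product OR in the covariate-free saturated case, which the tests
  check to high precision. Live births is the one adjustment variable
  because it confounds by construction: parity raises the number of
  chances to have a compatible child and is associated with case status.
* **Separation** is screened explicitly (non-convergence or |log-OR| >
  15 or a non-finite standard error) and flagged instead of reporting a
  spuriously enormous estimate.
* **Crude ORs** use Woolf's log-scale interval; a zero cell leaves the
  estimate undefined and flagged — no continuity correction is applied.
* **Fisher's exact test** is two-sided by the minimum-likelihood
  convention: conditional on both margins, sum the hypergeometric
  probabilities of all tables whose probability is at most that of the
  observed table, with a $1 + 10^{-7}$ relative tolerance on the
  comparison (the dominant software convention). A zero margin gives
  p = 1. The implementation is a vectorised hypergeometric sum, verified
  in the tests against full enumeration over every 2×2 table with total
  at most 60 and against `stats::fisher.test()`.
* **Multiplicity**: Bonferroni, $\min(1, 7p)$ over the seven classical
  loci.
* **Trend tests** enter the quartile as a single ordinal numeric term
  (1-4); the reported p is the Wald p of that term, invariant to affine
  recoding of the labels (quartile medians would not be).
* **Quartile cutpoints** use the linear-interpolation percentile
  definition (`quantile()` type 7) for cross-implementation
  reproducibility; assignment intervals are left-closed, right-open,
  last interval closed. An all-ties control distribution is an error
  advising manual bins rather than a silent 1-bin collapse.
* **Missingness tests** are Pearson chi-square without continuity
  correction; expected cells below 1 trigger advice to use the exact
  test.

## The synthetic cohort generator

`simulate_cohort()` draws mothers under Hardy-Weinberg equilibrium at
each locus, transmits one maternal allele per child uniformly at random,
draws the paternal allele from the population frequencies, ties the
number of children to a zero-truncated Poisson live-birth count (every
enrolled mother has at least one child), assigns disease by a logistic
model on the mother's true exposure and live births, and applies
missingness after capturing ground truth. Defaults, chosen once as
desk-scale but realistic study conditions:

* allele frequencies: a handful of common two-field alleles per locus
  with European-ancestry-like relative frequencies (synthetic vectors,
  not population estimates), and plausible SNP frequencies for the six
  mHag tags;
* live births: zero-truncated Poisson with truncated mean 2 (the study
  populations report means near 1.9-2.4), with at most 2 genotyped
  children per family (the study genotyped ~1.3 children per mother);
* disease model: intercept `qlogis(0.18)` (yielding roughly the one-in-
  five case fraction of the motivating case-control sample), exposure
  log-OR `log(1.8)` at HLA-B by default, live-birth log-OR `log(1.1)`;
* missingness: none unless configured; group-specific rates reproduce
  differential-missingness scenarios.

Truth (per-mother exposures, per-child paternal alleles, model
parameters) is emitted beside the cohort for recovery tests and never
read by the pipeline; with zero missingness the classified exposures
reproduce the truth exactly (pipeline closure, asserted in the tests).

What the generator does **not** emulate: linkage disequilibrium between
HLA loci and between SNPs and their restriction alleles (loci are
independent), assortative mating, allele-specific disease effects
(e.g. DRB1 shared-epitope risk), imputation-induced structured
missingness, genotyping error (so the zero Mendelian-error rate on
simulator output is a property of the generator, not of real data), and
multiple fathers per family. Passing tests therefore demonstrate the
correctness of the classification, scoring and inference machinery under
the stated generative model — not robustness to the correlated structure
of real cohorts.

## Problem sizes and statistical checks

The simulation-based checks use sizes chosen to make their asymptotic
claims hold at the resolution the checks can detect: parameter recovery
and CI coverage use 200 cohorts of 1000 mothers with a true exposure OR
of 1.8 (mean recovered OR within 5%, coverage within three binomial
standard errors of 95%); null rejection rates use 500 replicates; the
trend-test uniformity check uses 500 replicates of n = 2000, large
enough that the finite-sample distortion of the Wald p is below the
resolution of a Kolmogorov-Smirnov test at that replicate count.
Familywise error control over the seven locus tests is checked on
smaller cohorts (30 replicates of 250 mothers).

## Known limitations

* Two-field resolution cannot distinguish alleles identical at the
  protein level but regulated differently; higher-resolution names are
  truncated, not rejected, matching the analysis level.
* The default dissimilarity is a generic substitution-derived matrix;
  analyses sensitive to absolute SSM values should supply scorer
  resources calibrated for their question.
* Control children have no analogue of the born-before-diagnosis filter
  (no index date exists); if late-born children of controls differ
  systematically, control exposure prevalence is measured over a wider
  window than case exposure.
* The adjusted published ORs are not reproducible from printed counts
  (they require individual-level covariate data); only crude statistics
  from the embedded tables are, and the adjusted layer is validated by
  simulation instead.
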