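# histocompat

Mother–child histocompatibility classification and case–control
association analysis for autoimmune-disease epidemiology.

## The scientific problem

Rheumatoid arthritis (RA) and systemic lupus erythematosus (SLE)
predominantly affect women, and pregnancy modulates both diseases. One
hypothesis is that fetal cells acquired during pregnancy persist more
easily when mother and child are *histocompatible*, and that this
microchimerism contributes to disease risk. Testing the hypothesis in a
case–control design needs three ingredients, all provided here:

1. **Compatibility classification.** At a locus, a child is
   *histocompatible from the mother's perspective* when the paternally
   inherited allele is indistinguishable from one of the mother's two
   alleles. With unphased genotypes the paternal allele must be inferred:
   writing the mother's genotype as {m₁, m₂} and the child's as {c₁, c₂},
   the transmitted maternal allele must be a child allele that is also a
   maternal allele; the other child allele is paternal. The verdict
   collapses to a set rule — compatible ⟺ {c₁, c₂} ⊆ {m₁, m₂} — which the
   test suite proves equivalent to exhaustive phase enumeration. Per
   mother, the exposure is the binary "any histocompatible child" over
   eligible children (for case mothers, only children born before
   diagnosis).
2. **Graded similarity.** For non-identical pairs, a sequence similarity
   matching (SSM) score quantifies how far the noninherited maternal
   allele is from the paternal allele: SSM(a, b) = Σₚ w(p) · d(a[p], b[p])
   over mismatched aligned positions p, with an amino-acid dissimilarity
   matrix d and functional-position weights w. Lower = more similar.
   Per-mother locus averages are cut into quartiles at the control-group
   25/50/75th percentiles.
3. **Association layer.** Logistic regression ORs with Wald 95% CIs,
   adjusted for the number of live births; Bonferroni correction over the
   seven classical HLA loci (A, B, C, DPB1, DQA1, DQB1, DRB1); crude ORs
   with Woolf intervals; two-sided Fisher's exact tests; ordinal trend
   tests over SSM quartiles; and case–control missingness chi-square
   tests. Minor histocompatibility antigen (mHag) analyses apply the same
   compatibility rule to six tag SNPs, restricted to mothers carrying the
   presenting HLA allele (e.g. B\*07:02 for ZAPHIR).

A synthetic cohort generator (Hardy–Weinberg mating, Mendelian
transmission, parity-linked family size, logistic disease model,
group-specific missingness) makes every stage testable without access to
individual-level study data, and the published contingency tables ship as
a fixture for reproducing the crude statistics.

## Worked example

```r
library(histocompat)

classify_compatibility(c("B*07:02", "B*08:01"), c("B*07:02", "B*44:02"))$verdict
#> [1] "incompatible"
infer_paternal(c("B*07:02", "B*08:01"), c("B*07:02", "B*44:02"))
#> <paternal_inference> status: resolved
#>   paternal candidate(s): B*44:02
#>   maternal transmitted: B*07:02 | noninherited maternal: B*08:01
```

The child's paternal allele is forced to be B\*44:02 (B\*07:02 can have
come from the mother); it is absent from the mother's genotype, so the
child is incompatible, and the NIMA/paternal pair scored by SSM would be
(B\*08:01, B\*44:02).

A full synthetic analysis — simulate a cohort in which any-compatible
exposure at HLA-B carries a true OR of 1.8, then run the whole pipeline:

```r
sim <- simulate_cohort(sim_config(n_mothers = 600, seed = 42))
report <- run_full_analysis(sim$cohort)
report
#> <histocompat_report>
#>   mothers: RA=128, SLE=0, control=472 | complete-case: 600
#>
#> Any-compatible associations (adjusted for live births):
#>  disease locus n_any_case n_any_control            or p_bonferroni
#>       RA     A         41           166 0.8 (0.5-1.2)         1.00
#>       RA     B         42           103 1.6 (1.1-2.5)         0.19
#>       RA     C         34           126 1.0 (0.6-1.5)         1.00
#>       RA  DPB1         75           212 1.6 (1.1-2.4)         0.16
#>       ...
```

The OR column is the live-birth-adjusted logistic estimate with its Wald
interval; at the effect locus B the point estimate (1.6) brackets the
simulated truth of 1.8, while null loci sit near 1. `write_report()`
dumps the tables as TSV plus a JSON summary; each OR row carries the cell
counts it came from.

The published crude statistics are reproducible from the embedded tables:

```r
crude_or(published_tables()[["T6-ZAPHIR"]])
#> <assoc_result:crude> exposure
#>   OR 0.38 (95% CI 0.18-0.82)
#>   p = 0.01336
fisher_exact_two_sided(published_tables()[["T7-ZAPHIR"]])
#> [1] 0.05153178
```

i.e. the reduced SLE risk for mothers with ZAPHIR-compatible children
(OR 0.4; 0.2–0.8 among B\*07:02 carriers) and the borderline Fisher p of
0.05 for combined HLA+mHag compatibility.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/histocompat-cli.R` (subcommands `simulate`, `associate`,
`fixtures --verify`).

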