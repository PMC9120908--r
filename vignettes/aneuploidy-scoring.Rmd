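---
title: "Genome-wide aneuploidy scoring of cell-free DNA: model, calibration and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide aneuploidy scoring of cell-free DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfastseqr)
```

## The assay and the statistic

mFast-SeqS is a low-cost, low-resolution assay for tumor-derived aneuploidy
in plasma cell-free DNA (cfDNA). A single LINE-1 primer pair amplifies
thousands of dispersed loci across the genome from sub-nanogram cfDNA
input; sequencing those amplicons yields read counts whose distribution
over chromosome arms reflects the copy-number state of the DNA in
circulation. A tumor shedding DNA with arm-level gains and losses shifts
read mass between arms in proportion to the circulating tumor DNA (ctDNA)
fraction.

The statistic is built in three steps:

1. **Arm fractions.** Reads are binned by leftmost mapped position into
   chromosome arms (hg19 arm model). Per sample, counts over the scoring
   arms are normalized to fractions $x_a = c_a / \sum_b c_b$, which makes
   everything downstream invariant to sequencing depth.
2. **Arm Z-scores.** Against a reference panel of healthy controls with
   per-arm mean $\mu_a$ and SD $\sigma_a$ (sample SD, $n-1$):
   $z_a = (x_a - \mu_a)/\sigma_a$.
3. **Genome-wide score.** The squared Z-scores are summed,
   $S_\text{raw} = \sum_a z_a^2$, and — in the default `restandardized`
   mode — standardized a second time against the control panel's own
   distribution of $S_\text{raw}$:
   $S = (S_\text{raw} - \bar S_\text{ctrl}) / \mathrm{sd}(S_\text{ctrl})$.
   Samples with $S \ge 5$ are called aneuploidy **high**, otherwise
   **low** (the boundary is inclusive).

The two score modes exist because a literal sum of ~39 squared Z-scores
has null expectation near 39 (one per arm), which cannot be compared
against a cutoff of 5, nor can it produce the sub-1 scores observed in
diploid-like patients. The restandardized score is approximately
null-centered at 0 with unit spread, so the conventional cutoff of 5 is a
five-panel-SD exceedance. `sum_sq` mode is exported so the two conventions
can be inspected side by side.

### Scoring arms

By default 39 autosomal arms are scored. The acrocentric p-arms (13p, 14p,
15p, 21p, 22p) are excluded because they carry essentially no uniquely
mappable sequence; the sex chromosomes are excluded because a mixed-sex
reference panel would turn X/Y dosage into spurious aneuploidy. The set is
configurable (`default_arm_exclusions()`).

### Leave-one-out control scores

The control distribution of $S_\text{raw}$ is computed **leave-one-out**:
each control is standardized against the panel rebuilt without it. This is
a deliberate calibration choice. A control standardized against a panel
that contains it has shrunken Z-scores — across the panel,
$\sum_i z_i^2 = (n-1)$ exactly per arm, so $E[z_i^2] = (n-1)/n \approx
0.95$ at $n = 20$ — whereas a fresh sample scored against the same panel
has $E[z^2] = (1 + 1/n)\,\frac{n-1}{n-3} \approx 1.17$. Summed over 39
arms the gap is ~8-9 raw units, about one panel SD: with leave-one-in
control scores, fresh diploid samples would average a restandardized score
near +1 instead of 0. Leave-one-out control scores match the fresh-sample
distribution (simulated null mean ≈ 0); `leave_one_out = FALSE` restores
the simpler convention for comparison.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_mapq` | 1 | drop multimapping reads (MAPQ 0), which carry no arm information for LINE-1 amplicons; duplicates are kept because amplicon libraries are intentionally duplicated |
| `min_reads` | 90,000 | sample QC floor on retained reads, the assay's sequencing depth guarantee |
| `min_n` (panel) | 10 | smallest control panel accepted |
| `cutoff` | 5 | high/low boundary on the restandardized score, inclusive |
| coverage / variant reads / LOD | 100 / 3 / per-amplicon | plasma variant true-call rule: molecular coverage ≥ 100, ≥ 3 variant reads, VAF ≥ LOD (boundary passes) |
| `min_covered_frac` | 0.5 | fraction of an arm that segments must cover before an arm-level copy number is reported |
| CN `floor` | 0.1 | floor before `log2(CN/2)` so homozygous deletions do not map to −∞ |

Arm-level tissue copy number is the segment-length-weighted mean over the
arm, and the deviation $d_a = \log_2(\mathrm{CN}_a / 2)$ uses a fixed
diploid expectation — no ploidy or purity adjustment is attempted.
Tissue–plasma concordance correlates $d_a$ with the plasma $z_a$ over
shared arms (Spearman, pairwise deletion, ≥ 10 arms).

## Statistical conventions

- **Spearman correlation**: Pearson on average ranks; p-value from the
  exact permutation distribution when $n \le 10$ without ties, otherwise
  the $t$ approximation. The square-root transform applied to VAF–score
  scatter plots is strictly monotone and provably leaves rho unchanged; it
  is offered only for plotting parity.
- **Chi-square**: Pearson with Yates continuity correction on by default
  for 2×2 tables, matching common statistical-package defaults; expected
  counts are reported and small expected counts trigger a warning.
- **Kaplan–Meier**: product-limit estimates via the survival package;
  median survival is the first time the estimate drops to 0.5 or below;
  groups compared by the two-sample log-rank test.
- **Logistic regression**: plain maximum likelihood (`glm`), odds ratios
  with Wald 95% CIs and p-values. Complete/quasi-complete separation is
  detected and flagged rather than silently reported; a hand-implemented
  Firth (Jeffreys-prior) penalized fit is available via
  `method = "firth"` because near-separated cohort tables produce
  explosive ML estimates. The multivariate model can auto-select
  covariates with univariate Wald $p < 0.05$.
- **Cross-validation**: stratified k-fold (default 10-fold × 3 repeats),
  reporting per-fold and mean accuracy and AUC (the rank/Mann–Whitney
  form). Which single metric the original analyses monitored is not
  knowable, so both are reported. Fold assignment deals a seeded shuffle
  round-robin within each outcome class, making CV results bit-reproducible
  from `(seed, k, repeats)`.

## What the synthetic generator emulates

Cohort-scale re-analysis of the real patient data is impossible — the
underlying whole-genome and per-patient clinical data are access-restricted
— so the package ships a generator that reproduces the *statistical
structure* the pipeline assumes, and the packaged per-subject mutation
overview table is the one piece of real data included.

- **Counts**: Dirichlet-multinomial around baseline arm weights
  proportional to arm lengths. The single precision parameter
  (`dispersion`, default $5 \times 10^5$) adds ~0.9% per-arm
  inter-individual CV on top of the ~2% multinomial sampling CV at the
  default depth of 100,000 reads (just above the 90,000-read QC floor).
  `dispersion = Inf` recovers a pure multinomial. With these defaults the
  restandardized score crosses the cutoff of 5 at a tumor fraction near
  0.10, consistent with the published reading of the cutoff as 5–10%
  ctDNA.
- **Mixtures**: at tumor fraction $f$, arm $a$'s expected fraction is
  $w_a\,((1-f) + f\,\mathrm{CN}_a/2)$, renormalized. The default tumor
  profile alters eight arms typical of urothelial cancer (gains of 1q, 5p,
  8q, 20q; losses of 8p, 9p, 9q, 10q).
- **Sampling is inverse-CDF** (`qgamma`/sequential `qbinom`): with equal
  seeds, draws at different tumor fractions are coupled (common random
  numbers), so dose-response comparisons are not drowned in independent
  sampling noise.
- **Variants**: clonal heterozygous model — expected plasma VAF is
  $f \times$ tissue VAF, observed through negative-binomial molecular
  coverage (mean 2500, occasionally below the 100-read floor) and binomial
  variant reads, so the true-call rule is exercised on both sides of each
  threshold. Subclonal structure is deliberately out of scope.
- **Cohorts**: response drawn from a logistic model on the score-high and
  short-TFI flags (generating odds ratios 0.11 and 0.12, the magnitudes of
  the published multivariate estimates); baseline rates chosen to
  reproduce the published cohort proportions (28.4% score-high, ~45%
  benefit among score-low). Time on treatment runs in 21-day cycles,
  Poisson-distributed with response-dependent means, administratively
  censored at 735 days.

What passing simulation-based tests does **not** show: robustness to GC
and amplification bias, fragmentomic structure, locus-specific LINE-1
density, subclonal copy-number heterogeneity, or mixed-ancestry panel
composition. Real-data behavior on those axes is untested by construction.

## Numerical and design choices

- Coordinates are 0-based half-open internally; SAM's 1-based positions
  and 1-based segment tables are converted on ingest. "chr" prefixes are
  tolerated and stripped on both sides.
- Reads in the centromeric gap, on excluded arms, or on reference
  sequences absent from the arm table are counted as discarded, so
  retained + discarded always equals the number of input records.
- Score exactly at the cutoff is called high (the cutoff is "≥ 5").
- A patient's maximal plasma VAF includes zeros (assayed but undetected)
  and is undefined only when every assay failed.
- The simulation sizes used by the test suite and the acceptance script —
  500 null draws, 200 replicates per tumor fraction, 200 simulated cohorts
  of n = 500 — were chosen so that each property check resolves its effect
  at several standard errors while the whole suite runs in well under a
  minute of simulation time.
- The score dose-response in tumor fraction is evaluated with a fresh
  20-control panel per replicate rather than one shared panel. With one
  panel, the smallest step (f = 0 to 0.02, raw effect
  $\sum_a \delta_a^2 \approx 2$) can be exactly cancelled or doubled by
  the panel's own estimation error through the cross term
  $2\sum_a \delta_a b_a$ (where $b_a$ is the panel mean error, with SD
  around 1.3 across panels): conditional on a single panel the property
  is decided by the panel draw, not the method. Marginalizing over panel
  realizations measures the dose-response the claim is actually about.

## Worked example

```{r, eval = FALSE}
arms <- arm_table_hg19()
w <- arm_weights(arms)

# reference panel of 20 healthy controls
controls <- simulate_panel(20, w, seed = 1)
panel <- build_panel(lapply(controls, normalize_counts, arm_table = arms))

# a cfDNA sample with 15% ctDNA from a typical urothelial tumor profile
m <- tumor_model(w, uc_cn_profile(arms), f = 0.15)
sample_counts <- simulate_cfdna_sample(m, seed = 2)
score_sample(sample_counts, panel, arms)

# packaged mutation overview: detection rate and VAF-score correlation
fx <- load_table1_fixture()
detection_rate(fx$variants)
vaf_score_correlation(max_vaf_per_patient(fx$variants), fx$scores)
```

## Known limitations

- The arm model ships for hg19 only (the build the assay's reference
  pipeline uses); other builds require a user-supplied cytoBand file.
- Expected copy number is fixed at 2: whole-genome-doubled tumors will
  show compressed log2 deviations.
- The restandardized score's null calibration depends on panel size;
  below ~10 controls the second standardization is too noisy to support
  the cutoff, hence the `min_n` floor.
- `run_pipeline()` orchestrates the packaged stages; it is an R-level
  interface, not a shell tool.
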