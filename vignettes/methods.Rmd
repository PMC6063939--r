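---
title: "Benchmarking EHR phenotyping channels with polygenic scores: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking EHR phenotyping channels with polygenic scores: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genome-wide association studies and the polygenic risk scores (PRS) built
from them are only as good as their phenotypes. Electronic health records
offer several ways to decide who counts as a case — administrative billing
codes, the clinician-curated problem list, or a curated phenotyping
algorithm combining codes, labs, medications and note text — and these
differ sharply in sensitivity and specificity. `phenoscore` treats the
discriminative performance of a PRS trained *on a label set* as a
quantitative read-out of that label set's quality: cleaner labels give the
per-variant association scan more power, the resulting score separates that
channel's cases from controls better, and the channel ranks higher. The
package provides the whole loop — cohort simulation, genotype QC,
association, thresholded scoring under cross-validation, and evaluation — so
the design can be studied end to end without access to any protected cohort.

## The generative model

Because real biobank genotypes and EHR labels are access-restricted, the
package ships a first-class simulator whose outputs feed the identical
pipeline code that PLINK-format data would.

**Genotypes.** Each variant receives a coded-allele frequency drawn
uniformly on `[maf_low, maf_high]` (default 0.05–0.5: common variants, as on
a genotyping array after QC) and genotypes are `Binomial(2, f)` — exact
Hardy–Weinberg equilibrium. With `n_subpops = 2` the two subpopulation
frequencies come from the Balding–Nichols construction
`Beta(f(1-F)/F, (1-f)(1-F)/F)` with differentiation parameter `F = fst`,
the standard way to plant population structure that principal components can
recover. Missing calls are injected at a configurable rate (default 2%) so
call-rate filtering has something to do. The panel is a single
pseudo-chromosome with positions `1..m` and alleles coded A/B; there is no
linkage disequilibrium between neighbouring variants by construction, so the
LD pruner's interesting behaviour is exercised by planted collinear blocks
in the tests rather than by the default generator.

**Disease.** A liability-threshold model: `n_causal` variants (default 50)
get i.i.d. normal effects; the genetic score is standardized to variance
`h2_liability` and an independent `Normal(0, 1 - h2)` residual is added;
disease status is liability above the `1 - prevalence` standard-normal
quantile. Heritability is therefore a single interpretable knob, and the
realized genetic variance share matches `h2` by construction (the tests
check recovery within 0.02 at n = 20,000). Defaults `h2 = 0.5`,
`prevalence = 0.05` describe a moderately heritable, reasonably common
complex disease.

**Labeling channels.** Each channel labels a true case positive with
probability `sensitivity` and a true non-case positive with probability
`1 - specificity`, independently per sample. The defaults are

| channel      | sensitivity | specificity | emulates                      |
|--------------|------------:|------------:|-------------------------------|
| billing      | 0.95        | 0.90        | administrative billing codes  |
| problem_list | 0.60        | 0.995       | curated clinical problem list |
| algorithm    | 0.80        | 0.995       | curated phenotyping algorithm |

No published study states numeric operating points for these three sources;
these values are package defaults chosen once to reproduce the qualitative
character reported for them (billing finds nearly everyone but is heavily
contaminated; the problem list misses many true cases but is clean; the
algorithm is both reasonably sensitive and clean). Every value is
overridable per analysis via `channel_spec()`.

**Billing counts.** Billed samples receive `1 + Poisson(mean_extra)` repeat
occurrences, with a larger mean for labeled true cases (2.0) than for
labeled false positives (0.3). This encodes the observation that patients
billed repeatedly for a disease are more likely to truly have it, and makes
"billed at least *t* times" a family of sub-phenotypes whose specificity
rises with *t*.

## The pipeline

**Marker QC.** Sequential filters, each counted against its stage:
non-autosomal codes dropped, call rate ≥ 90%, minor allele frequency
strictly > 1%, exact Hardy–Weinberg test p ≥ `hwe_alpha`. The HWE test is
the plain exact conditional test (the sum of probabilities of heterozygote
counts no more probable than the observed one, given the allele counts) —
not the mid-p variant; monomorphic variants return p = 1 by convention. No
published threshold exists for the HWE cut in this design, so the field
convention 1e-6 is the default. Sample-level QC (per-individual
missingness) is available behind an optional `sample_callrate_min` flag but
is off by default: the simulated cohorts have no per-sample pathologies, and
for real data it is usually a cohort-preparation step done before this
pipeline.

**LD pruning.** A window of 50 variants sliding in steps of 5, removing
within each window the variant with the largest variance inflation factor
(`VIF_j = 1/(1 - R²_j)` against the other surviving window members, the
j-th diagonal of the inverse window correlation matrix) until all VIFs are
below 10, with three full passes; removals are global. Ties on the maximal
VIF are broken by removing the lower-MAF variant, then the lower index —
a deterministic rule chosen because the reference tool's tie behaviour is
undocumented. Missing dosages are mean-imputed for correlation purposes
only. Rank-deficient windows (duplicated variants) fall back to a
pseudoinverse R², reporting infinite VIF for exact collinearity. Each round
uses identical parameters.

**Association.** Per-variant logistic regression of the channel label on
coded-allele dosage plus covariates, fit by iteratively reweighted least
squares warm-started at the covariate-only fit, with a 25-iteration budget
and tolerance 1e-8 on the log-likelihood change (assessed by the Newton
decrement, the second-order estimate of the remaining improvement, so no
extra likelihood evaluation is needed per step); a coefficient exceeding 25
in magnitude is treated as divergence/complete separation and the variant is
flagged non-converged (such variants never enter weight sets). The Wald
test is reported, matching the default of standard GWAS tooling, rather
than the likelihood-ratio test. The genomic inflation factor
λ = median(χ²)/0.4549 and Q-Q points accompany every scan.

**Population structure.** PCA runs on the standardized
(`(d - 2f)/sqrt(2f(1-f))`, mean-imputed, column-centred) panel — an exact
SVD for small panels, a randomized subspace SVD with a fixed internal
projection seed for large ones, signs fixed by the largest-magnitude
loading. PCs are computed once on the full QC'd panel and reused across
folds: a deliberate simplification (per-fold PCA would multiply cost for no
change in the structure axes, which are properties of the genotypes, not
the labels). Unstructured simulated cohorts are analysed unadjusted
(`k = 0`); two PCs are the default whenever structure is plausible, and the
structured-simulation tests confirm that adjustment pulls an inflated λ
back toward 1.

**Scores.** Candidate weight sets are all converged variants with Wald
p ≤ cutoff, for 12 cutoffs log-spaced from 5e-5 to 0.1 (endpoints and count
fixed; log spacing chosen since subset sizes grow roughly geometrically
across that range). The score of a person is the *mean* over scored
variants of dosage × log-OR — the PLINK `--score` convention, which keeps
scores comparable across cutoffs with different variant counts. A
"risk-allele frequency times log OR" reading that used cohort-level
frequencies would give every individual the same number and cannot score
anyone; per-individual dosage is the only interpretation that yields
individual scores, and matches the stated use of `--score`. Missing
dosages are imputed at twice the training-set effect-allele frequency.
External (published) weight tables go through the same machinery: weights
are log odds ratios, harmonized so that a weight whose effect allele is the
panel's other allele contributes `w(2 - d)` — scores are then exactly
invariant to the panel's arbitrary allele coding — and unmatched or
allele-inconsistent rows are dropped and counted.

**Cross-validation.** Stratified 5-fold, stratifying on the
union-of-channels case indicator so that one fold plan serves every channel
and their results are directly comparable on identical train/test splits.
Per fold, association runs on the training 80% only and the held-out 20% is
scored at every cutoff; the reported cutoff maximizes fold-mean test AUC.
That selection-on-test mirrors the conventional procedure but is
optimistically biased, so the result object carries an explicit
`selected-on-test` flag and `selection = "nested"` switches to an inner-CV
selection per fold. Fold-mean selection (rather than per-fold winners) is
used because a single operating cutoff is what a practitioner would deploy.

**Evaluation.** Three statistics per channel, each computed on test folds
against the channel's own labels (cases = labeled positive, controls =
everyone else — no cross-channel exclusions, since none are part of the
published design): case-minus-control mean PRS difference, AUC
(Mann–Whitney formulation, ties half-credited), and the odds ratio per
standard deviation of score (exponentiated slope of label on z-scored PRS;
complete separation is reported as non-estimable rather than a huge
number). Fold aggregation uses the mean and *sample* (n−1) SD. In
simulated cohorts every channel is additionally evaluated against the true
status — the quantity the misclassification story actually explains — and
the overlap report partitions positively labeled samples into exact
one-/two-/three-channel regions. The billing-count sweep redefines billing
cases at count ≥ 1, 2, 3 and reruns the whole cross-validated pipeline at
the same fixed cutoff grid.

## Numerical and engineering choices

- The per-variant scans and the VIF pruner are compiled (RcppArmadillo):
  a scan touches `n × m × folds × channels` likelihood evaluations and is
  the pipeline's hot loop. The logistic fits agree with `glm()` to 1e-6,
  and tests verify this against direct numerical likelihood maximization.
- The exact HWE test computes all heterozygote-count probabilities from a
  shared log-factorial table; a tolerance of one part in 1e12 decides
  which tables count as "no more probable than observed", protecting the
  tie at the modal table from floating-point jitter.
- Fold subsets and imputed training matrices are built once per fold plan
  and shared across channels; results are identical to the uncached path.
- All randomness flows from explicit seeds through `withr::with_seed`, so
  no call disturbs the caller's RNG state; the pipeline derives per-stage
  seeds from the run seed by fixed offsets (genotypes +0, disease +1,
  channel *i* +10+i, billing counts +100, folds +200), letting any stage be
  reproduced in isolation.
- PLINK bed/bim/fam I/O is implemented bit-compatibly in the package (the
  installed R stack has no PLINK reader), and the test suite checks the
  encoding against an independent bit-level decoder.

## What the simulations do and do not show

The generator reproduces the *design* of an EHR-phenotyping PRS comparison:
misclassification with channel-specific operating points, count-graded
billing evidence, liability-scale polygenicity, optional two-population
structure, missing genotype calls. It deliberately omits realistic LD
(haplotype blocks), rare variants, sex chromosomes, covariate-linked
ascertainment and longitudinal event streams. Passing tests therefore
demonstrate that the pipeline's inferences behave correctly under the
stated model — e.g. that cleaner labels yield higher AUC, that repeat
billing raises PPV and AUC, that PC adjustment deflates λ — not that any
particular clinical cohort will show effects of a particular size.

The test suite and acceptance script run at deliberately modest problem
sizes chosen as the package's own benchmark conditions: the main
channel-ranking study uses n = 4000 samples × m = 5000 variants with 50
causal variants over 20 seeded replicates; the billing-count and
label-noise studies use n = 2500–3000 × m ≈ 1200 cohorts with a higher
prevalence (0.10) so that count-thresholded case sets stay large enough to
cross-validate; the null-calibration and structure studies use n = 2000.
At these sizes the qualitative phenomena of interest are comfortably
detectable while a full study remains a desk-scale computation.

## Known limitations

- Threshold selection on test AUC is optimistic; the nested option is
  honest but noisier and slower, and is not the default.
- With channels of similar specificity (problem list vs algorithm at
  0.995), their expected AUC difference is modest and single-replicate
  inversions occur; ranking claims are therefore made over replicate
  ensembles, never from one seed.
- OR-per-SD standardizes within each evaluated set, so its scale is not
  transferable across cohorts with different score variances.
- The simulator's independent-variant panel makes the LD pruner nearly a
  no-op on default synthetic data; its correctness is established on
  constructed collinear panels instead.
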