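---
title: "GWAS-ranked incremental feature selection for genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GWAS-ranked incremental feature selection for genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifsgp)
```

## The problem

Genomic prediction models map genome-wide SNP dosages to a quantitative
phenotype. Marker panels routinely carry tens or hundreds of thousands of
SNPs while populations number in the hundreds or low thousands, so a model
fed every marker spends most of its capacity on noise. Filtering markers
can help — but whether it helps, and how many markers to keep, depends on
the dataset. `ifsgp` answers both questions empirically with an
*incremental* sweep: rank the markers, train models on growing top-ranked
subsets, and look at where held-out accuracy peaks.

## The procedure and its assumptions

**Ranking.** Each SNP is scored by the simple linear regression
`phenotype ~ intercept + dosage` on training individuals, and SNPs are
ordered by the slope's two-sided t-test p-value (df = n_train − 2). This is
the standard quantitative-trait single-marker test without covariates; it
assumes an additive marginal signal is a usable proxy for a marker's value
to the predictor. Markers whose contribution is purely epistatic rank
poorly — which is one reason nothing is ever discarded: a marker that
enters late (or whose first addition even hurts accuracy) can still
contribute through interactions once the forest sees it together with its
partners. The p-values are used only as an ordering, so no multiple-testing
correction applies. Monomorphic SNPs get p = 1 and sort last; ties break by
(chromosome, position) so rankings are reproducible across platforms.

**Leakage.** Inside every cross-validation fold the ranking is recomputed
from that fold's training individuals only. Ranking on all data first and
cross-validating afterwards inflates accuracy estimates, because the test
individuals have already voted on which markers look good. The sweep in
`run_ifs()` enforces this structurally, and the test suite audits every
single model fit for train/test disjointness via the `fit_callback` hook.

**Prediction model.** A bootstrap regression forest (via `ranger`):
`n_trees = 500`, `min_node_size = 5`, and `mtry = floor(sqrt(p_used))`
recomputed from the number of SNPs actually supplied at each sweep step —
`mtry` refers to the model's current input dimension, not the panel size.
Forests are robust in the p ≫ n regime and can exploit dominance and
marker–marker interactions that purely additive predictors miss. Fits are
bit-reproducible for a fixed seed and thread count; across thread counts
only statistical equivalence should be expected. Per-fit seeds derive from
the master seed through a counter, so no two fits share a random stream.

**Accuracy.** R² = 1 − SS_res/SS_tot on observed/predicted pairs. Unlike a
squared correlation this measures calibrated agreement and is negative
whenever the model predicts worse than the phenotype mean — a real outcome
on near-zero-heritability traits, and one the pipeline propagates
unclipped end to end. Within each repetition, out-of-fold predictions from
all five folds are pooled and scored once (one R² per repetition; the
curve reports mean ± SE over the ten repetitions). A per-fold variant
(`per_fold = TRUE`) averages five per-fold R² values per repetition
instead; pooling is the default because each individual then contributes
exactly one prediction to the score. Pearson's r is available as an
alternative metric, and R² = r² exactly only for unconstrained linear
fits — a property the tests verify.

**Step schedule.** Training a forest at every marker count is wasteful at
the high end, so counts advance in regimes: step 1 until 100, 5 until 500,
10 until 1000, 50 until 5000, 100 until 10,000, 500 until 50,000, 1000
until 100,000, 5000 beyond; the sweep always ends at the full panel, which
doubles as the all-SNP baseline. Regimes are fully configurable
(`build_schedule(p, regimes)`), including offset variants.

**Smoothing and selection.** The raw accuracy curve is noisy; picking its
raw argmax would reward lucky spikes. `select_optimum()` smooths mean R²
against log₁₀(marker count) — log because the schedule is geometrically
spaced at the high end — with the variable-span super smoother and takes
the smoothed maximum. Ties within floating-point noise of the maximum go to
the smallest count (parsimony). When the maximum lands on the final point
the recommendation is "use all SNPs" and the selected-model column of the
report is `NA`: it would duplicate the baseline. On curves that rise
monotonically toward the full-model asymptote this rule is deliberately
conservative — it recommends the full panel even when a fraction of it
gets within noise of the same accuracy; manual inspection of the curve can
then justify a smaller panel.

## The super smoother

`supersmooth()` implements the variable-span smoother in full: running
local-linear fits at spans 0.05, 0.2 and 0.5 of the data with symmetric
nearest-neighbour windows (truncated at the boundaries); leave-one-out
absolute residuals per span obtained from in-window leverages;
those residual curves smoothed at the midrange span; a per-point best span,
itself smoothed at the midrange span and clamped to [0.05, 0.5]; final
values interpolated between the two bracketing span fits and polished with
a tweeter-span pass. The `bass` parameter (0–10, default 0) pulls the span
choice toward the woofer by the factor `(e_best/e_woofer)^(10 − bass)` for
users who prefer smoother trends. Numerical choices: local fits fall back
to window means when the in-window x-variance vanishes; leverage
denominators are floored at 1e−8; inputs shorter than 5 points use a
single running-line smooth whose half-width is chosen by leave-one-out
cross-validation, and 1–2 point inputs pass through. Local-linear windows
reproduce affine data exactly, which the tests assert to 1e−8, and the
output is equivariant under affine transforms of y because every stage is
either linear in y or selects among spans using residual magnitudes only.

## PLINK 1.x input

`read_plink()`/`write_plink()` are a bit-exact codec for the binary
`.bed`/`.bim`/`.fam` triplet (magic `0x6C 0x1B`, SNP-major mode, 2-bit
codes packed lowest-bits-first, rows padded to whole bytes). Dosages count
the `.bim` A1 allele by default — an individual homozygous for A2 has
dosage 0 — with `count_allele = "a2"` to flip; ranking is orientation-
invariant, so the choice only matters for round-trip fidelity and effect
signs. Phenotypes come from `.fam` column 6 (−9 and 0 are missing
sentinels) unless a separate `FID IID VALUE` file is supplied, which takes
precedence. `filter_missing()` removes individuals with missing phenotypes
first, then SNPs with any remaining missing genotype — strict removal, no
imputation, no MAF or HWE filtering — and reports the counts so the order
can be audited.

## The synthetic generator

`simulate_dataset()` exists so every stage is testable without external
downloads. It draws per-SNP allele frequencies uniformly on `maf_range`
(default 0.05–0.5), dosages as Binomial(2, f) independently across SNPs,
additive effects for `n_causal` SNPs from a Gaussian (or Laplace)
distribution, optional epistatic terms as products of centered dosages for
causal pairs, and Gaussian noise scaled so the genetic variance fraction
equals the target heritability in expectation — the realized ratio is
recorded in `realized_h2`, never assumed. An optional block mode
(`ld_block_size`, `ld_rho`) correlates latent allele draws within blocks,
AR(1)-style, to probe ranking behaviour under LD-like marker correlation
while keeping Binomial(2, f) marginals.

What it does *not* emulate: coalescent-realistic haplotype structure,
population stratification and kinship confounding, genotyping-platform
artefacts, and non-Gaussian phenotype noise. Tests passing on these
simulations therefore validate the machinery — leakage-safety, metric
definitions, selection logic — not robustness to structured real-world
confounding; on real data with strong family structure the single-marker
scan will rank confounded markers optimistically.

## Hold-out protocol

`evaluate_ifs()` splits individuals 80%/20% (Φ/Ψ; Φ size is
round-half-up of 0.8·n — the convention is arbitrary but must be fixed for
reproducibility). The whole sweep-and-select machinery runs on Φ; the final
marker set comes from a fresh GWAS ranking on all of Φ (using the most data
available without touching Ψ); one forest with the selected markers and one
with all markers are trained on Φ and each predicts Ψ once. The report
carries both R² values and their difference (the *advantage*), plus every
seed used. By default a single seeded split is evaluated; repeated-split
averaging is a matter of calling `evaluate_ifs()` over seeds.

## Problem sizes in the tests and acceptance script

The bundled studies use scaled-down but structurally faithful sizes chosen
so the full protocol — not a shortcut — runs in each check: the recovery
study uses 400 individuals × 2000 SNPs with 20 causal SNPs at h² = 0.7
under the `"test"` profile (coarser step regimes, 100 trees, 3
repetitions); the null study uses 200 × 500 at h² = 0. At these sizes the
phenomena of interest — a sharp interior accuracy peak for sparse
architectures, a flat near-zero curve for heritability zero, negative
out-of-fold R² — all manifest clearly. The `"full"` profile reproduces the
complete schedule and 500-tree/10-repetition settings for real analyses.

## Known limitations

- The single-marker ranking ignores population structure; on stratified
  data, rankings (and hence selections) inherit the confounding.
- Binary traits and covariate adjustment are out of scope; the association
  model is a quantitative-trait linear test only.
- The selection rule is conservative on monotone curves (see above).
- PLINK 2 formats, VCF import and dosage data are not supported; convert
  to PLINK 1.x binary first.
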