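---
title: "vulnscreen: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vulnscreen: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vulnscreen)
library(data.table)
```

## The problem

Genome-scale siRNA viability screens nominate genes whose knockdown kills a
cell line, but two artifact classes dominate naive hit lists: multiplicative
plate-to-plate signal variation, and miRNA-like off-target silencing driven
by the guide strand's seed region, which makes unrelated siRNAs that share a
seed phenocopy each other. vulnscreen implements a deconvolution pipeline
that addresses both, ranks genes by the joint behavior of all their siRNAs,
and pairs the RNAi arm with a quantitative small-molecule dose–response arm
scored on the same viability readout.

## RNAi arm

### Plate normalization and robust Z

Each library well is divided by the median signal of its own plate's
non-transfected reference wells (`plate_normalize()`). Medians rather than
means keep a few dead or contaminated control wells from biasing the
reference. The resulting viability ratios are scored as robust Z-scores,
`z = (x − median(x)) / (1.4826 · MAD(x))`, computed **per screen / cell
line**, not per plate: plate effects have already been removed, and
per-plate scoring would let a plate's own hit content distort its scale.

`run_discovery()` scores `log(plate_normalized)` by default
(`log_transform = TRUE`). Knockdown phenotypes and plate gains act
multiplicatively on luminescence, so the log is the scale on which they are
additive; on the raw ratio scale a lethal phenotype saturates near zero and
a −3 SD log effect would surface as only ≈ −0.9 robust Z, crippling tail
statistics. The raw-ratio mode is retained for comparison.

### Common-seed correction

siRNAs are grouped by the exact string of guide positions 2–7 — the
standard miRNA-like seed hexamer; a 7-nt variant is a config option
(`seed_length = 7`). Each activity is corrected by **subtracting** the
self-inclusive median activity of its seed group; subtraction (not
division) is the meaningful operator on a Z-score scale, and the
self-inclusive median matches classical common-seed analysis
(leave-one-out is available via `leave_one_out = TRUE`).

Small groups need a guard: a singleton group would subtract itself and
silence every unique-seed siRNA. Groups below `min_group_size = 3` are
corrected by the library-wide median instead — three members is the
smallest set whose median is not dominated by the siRNA being corrected.

### The activity tail model and the significance cutoff

Corrected activity distributions are symmetric-ish but heavier-tailed than
normal. `fit_tail_model()` fits the symmetric exponential-power
(generalized Gaussian) family, density ∝ exp(−|(x−μ)/α|^β): β = 2 is
normal, β = 1 Laplace (excess kurtosis 3), and β ≈ 0.75 reaches the excess
kurtosis of ≈ 6 that motivates an exponential-tail reference (an
exponential distribution has skewness 2 and excess kurtosis 6). Location is
the sample median; α has a closed-form MLE given β, and the profile
likelihood in β is optimized over a grid plus 1-D refinement. Sample
skewness and excess kurtosis are attached as *descriptive* diagnostics: a
symmetric family cannot express skewness, so a skewed screen will show its
skewness in the diagnostics while the fit captures only the tail weight —
the two statistics are deliberately reported side by side rather than
reconciled.

`estimate_cutoff()` returns the lower-tail p-quantile of the fitted model
(default p = 0.05). Because the exponential-power quantile runs through the
Gamma quantile of |X−μ|^β, it is accurate far into the tails (verified to
recover the normal −1.6449 and Laplace ln(0.1) quantiles exactly). An
`exponential_tail` mode instead fits a one-sided exponential to the
negative deviations from the location and solves
`0.5·exp(−λ·d) = p`; both modes are exposed because tail-model wording in
screen reports is often ambiguous between them. Cutoff values are
data-dependent outputs — on the default synthetic world they land around
−1.6 to −1.8.

### RSA gene ranking and hit calling

All N scored siRNAs are ranked ascending (rank 1 = most lethal; ties broken
by `sirna_id` for determinism). For a gene with n siRNAs at sorted ranks
r₁ < … < rₙ, `rsa_rank()` assigns

p = min over i of P(X ≥ i), X ~ Hypergeometric(N, n, rᵢ),

the probability that at least i of its n siRNAs would land in the top rᵢ by
chance. Tails come from `phyper(log.p = TRUE)`, so screens up to N = 1e5
are numerically safe; a brute-force binomial-coefficient oracle confirms
exact agreement on hundreds of small screens. A gene is a hit when
log₁₀p < −1.301 (p < 0.05) **and** its best corrected activity is below the
cutoff; no additional multiple-testing correction is applied, reproducing
the screen's fixed-threshold rule as-is.

That fixed threshold matters for interpretation: with 2 siRNAs per gene a
single cell line carries an intrinsic ≈ 2% null false-positive rate, so
per-line hit lists are deliberately permissive. Screen-level candidates are
declared by `combine_across_lines()` — a hit in both lines of a genetic
subgroup, or in ≥ 3 lines — which is where precision is recovered (≥ 0.95
on the default synthetic world).

### Verification and expression filtering

Verification plates are normalized per plate as
`v = (x − median(pos)) / median(neg)` — the literal reading of
"subtract the positive control, divide by the negative control" — with the
span-normalized alternative `(x − med(pos)) / (med(neg) − med(pos))`
available as `formula = "span"`; both are common and they agree when the
positive-control median is zero. RSA on the relative viabilities (rank 1 =
lowest viability) declares a gene verified at log₁₀p < −1.301, per line;
"verified overall" means verified in ≥ 1 line.

`expression_filter()` computes log₂(FPKM + 0.01) — the 0.01 smoothing
constant pins an unexpressed gene at log₂(0.01) ≈ −6.64 — and keeps genes
whose maximum across cell lines reaches a configurable threshold. The
threshold defaults to 0 (≈ FPKM 1, a conventional "expressed" floor); the
original analysis did not state its numeric value, so it is a parameter,
not a constant.

### Haystack off-target regression

`build_match_matrix()` counts, for every (siRNA, gene) pair, occurrences of
the seed's reverse-complement DNA site in the gene's 3′-UTR (overlapping
occurrences counted; N never matches). `haystack_regress()` fits, per gene,
OLS of activity on the binary site indicator — for a binary predictor the
slope is exactly the matched-vs-unmatched mean difference — with a
two-sided t-test, BH adjustment across tested genes, and candidacy =
negative estimate with q < 0.05. The count predictor is an option. Genes
need ≥ 5 matching and ≥ 5 non-matching siRNAs to be testable. A "most
active seeds" pre-filter is intentionally **off** by default: testing all
seeds is a conservative superset, and restricting to active seeds is a
power optimization that changes the multiple-testing universe.

## Drug arm

### Normalization and the 4PL fit

Library wells are mapped to percent viability with the plate's DMSO median
at 100% and bortezomib median at 0%. Curves use the four-parameter
logistic `v(c) = bottom + (top − bottom)/(1 + (c/ac50)^hill)`; the sign of
the Hill slope carries orientation (positive = viability falls with dose,
negative = activation readouts), with |hill| constrained to [0.3, 5] and
top/bottom to [−20, 120]%.

The fitter (`fit_4pl_grid()`) is built for plates with occasional bad
wells: a coarse grid over log₁₀(ac50) (tested range ± 1 decade, 0.125
steps) and Hill slopes (12 log-spaced values, both signs), with top/bottom
solved at each node by linear least squares (the model is linear in them)
and the node scored by the **sum of absolute residuals**; Nelder-Mead
refinement of the best node (with a restart, since the LAD surface is
kinked); then one pass masking points with |residual| > 3 × MAD and a
refit. The MAD gate has a 1e-6 floor so exact-model data — where MAD is
numerically zero — is never masked. A fit that cannot beat the best
flat-line model is reported `converged = FALSE` (inactive compound), and
downstream IC50/EC50 are NA rather than fabricated.

### Summaries

- **Normalized AUC**: trapezoidal integral of the *fitted* curve over
  log₁₀ concentration across the tested range, as a percentage of a flat
  100% response (floored at 0; values > 100 mean growth stimulation).
  Integrating the fit rather than raw points de-noises the summary; a
  raw-point mode is provided and labeled since either convention appears in
  practice.
- **Absolute IC50**: the 50%-of-control crossing, solved in closed form;
  undefined when the curve never crosses 50% — the convention for
  viability screens, where "IC50 = 38 µM at the top dose" really means
  "resistant". The relative **EC50** (= AC50, the inflection) is always
  reported alongside and is the right summary for activation readouts.
- **Class summaries**: mean normalized AUC and median of *defined* IC50s
  per genotype class, with the count of undefined IC50s reported, so one
  resistant line cannot silently vanish from the average.
- `tumor_volume()` implements the caliper formula long × short² / 2 with
  axis canonicalization.

## The synthetic world

The generators state one fixed world rather than tunable difficulty:

- Library: random 21-nt guides, 2 siRNAs/gene, default 2000 genes
  (structure of a druggable-genome library at desk scale; large enough for
  stable tail fits, small enough for CI).
- Truth: 50 hit genes at −3 and 10 toxic seeds at −2, in units of the
  log-scale well noise SD (default noise SD = 1, so these are robust-Z
  units); strong-lethality phenotypes against unit assay noise. Toxic seeds
  are drawn from seed groups with ≥ 4 members that touch no hit gene, so
  on- and off-target signal stay separable.
- Plates: 384-well geometry, 368 library + 16 reference wells, log-normal
  plate effects (SD 0.25 on the log scale — a realistic 25-30% plate CV);
  per-well log-normal noise; reference/control wells carry plate effect and
  noise but no phenotype.
- UTRs: uniform random DNA (default 800 nt) with reverse-complement seed
  sites planted at recorded positions; background matches follow the
  (L−5)/4⁶ expectation.
- Dose plates: 4PL viability + Gaussian percent-scale noise, uniform(0,120)
  outlier contamination, controls generated at their defining levels.

Not emulated: spatial/edge effects, transfection-efficiency gradients,
carry-over, compound degradation, or correlated noise. A green end-to-end
test therefore establishes that the *statistical machinery* recovers known
truth under the stated noise model — not that any particular wet-lab
screen would reach the same operating characteristics.

## Numerical choices

- Hypergeometric tails in log space; RSA p clamped to ≤ 1; rank ties broken
  by identifier.
- Exponential-power shape searched on a 25-point log grid over [0.3, 4]
  then refined; location fixed at the median (profile MLE).
- Seed groups below size 3 fall back to global-median correction.
- 4PL node least-squares solutions clamped to the [−20, 120]% box; penalty
  terms keep the refinement inside the grid span and Hill bounds.
- `write_results()` fixes numeric output at 10 significant digits so result
  files are byte-deterministic and round-trip to 1e-9.
- All simulators restore the caller's RNG state; identical (config, seed)
  inputs give byte-identical outputs.

## Known limitations

- The symmetric tail model cannot represent skewed activity distributions;
  skewness is reported but not modelled.
- The CSA operator (subtraction) and small-group policy are principled
  choices, not reconstructions of any specific historical implementation.
- Haystack uses exact seed-string matching only — no thermodynamics,
  conservation or context scoring.
- The per-line cutoffs and headline hit counts of any real screen depend on
  its raw plate data; this package reproduces the *method*, and its tests
  assert recovery on synthetic truth plus exact agreement with analytic
  oracles, not historical counts.
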