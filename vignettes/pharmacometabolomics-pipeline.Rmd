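---
title: "Methods: pharmacometabolomic association networks"
author: "pharmetanet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pharmacometabolomic association networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmetanet)
```

This vignette is the package's account of its methods: the models and
procedures each stage implements, the assumptions behind them, the tunable
parameters and why their defaults are what they are, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
made where the design was genuinely open. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## 1. Study design the pipeline assumes

A cohort of healthy adults each receives a single oral dose of a drug.
Plasma drug concentrations are sampled on a fixed time grid, and untargeted
LC-MS profiles are acquired at two timepoints per subject: baseline
(pre-dose) and at the time of maximum drug concentration (post-dose). A
pooled QC sample — an aliquot mixture of all study samples — is injected at
regular intervals through the randomized injection sequence to monitor
instrument drift. Subject-level covariates (sex, age, BMI, a crossover
period label) and clinical/laboratory traits are available per subject.

The pipeline answers three questions in sequence: which features differ
between pre- and post-dose; which metabolite sets (pathways) those features
over-represent; and which metabolites' abundances co-vary with the
pharmacokinetic parameters or traits, organized as a tripartite association
network with community structure.

## 2. Non-compartmental pharmacokinetics

`compute_pk_table()` makes no compartmental assumption. Per subject:

* **AUC~0–t~**: trapezoidal integration from dose time to the last observed
  time. The default is the linear trapezoid; `method = "linlog"` uses the
  log-trapezoid on strictly decreasing positive segments, which is exact for
  exponential decay. Both are exposed because neither is canonical across
  NCA software; the linear rule is the simpler default. `NA` concentrations
  are the missing-value (below-quantification) code and are dropped;
  recorded zeros are data and are integrated.
* **C~max~, T~max~**: the observed maximum and its time. Note that with
  multiplicative assay noise the observed maximum is an upward-biased
  estimate of the true curve maximum; this is a property of the estimand,
  not a bug, and it is visible in the simulation results.
* **k~el~**: minus the slope of an ordinary least-squares fit of
  log-concentration on time over a terminal window. Windows are anchored at
  the last positive observation and grown backwards (last 3 points, last 4,
  ...), never crossing T~max~ or an interior zero; the window with the best
  adjusted R² wins, ties going to the larger window. We deliberately do
  *not* search all contiguous interior windows: at 10% assay noise the
  interior search selects short, spuriously perfect fits and inflated the
  cohort-mean k~el~ error to several percent in our simulations, while the
  anchored search (the rule standard NCA software applies) kept it well
  under 2%. A best slope that is not negative leaves k~el~ and T~1/2~
  undefined (`NA`), flagged but not fatal; cohort summaries exclude such
  subjects pairwise.
* **T~1/2~** = ln 2 / k~el~, exactly, per subject.

## 3. Feature-table preprocessing

`preprocess()` runs a fixed chain; each step is also exported on its own.

1. **Drift correction** (`drift_correct`). Per feature, a smooth curve is
   fitted to the pooled-QC intensities as a function of injection order and
   every injection is divided by it. The curve is normalized to mean one
   over the QC injections, so per-feature QC levels are preserved and a
   drift-free feature passes through unchanged. The default smoother is
   local linear regression (`stats::lowess`) with the span chosen by
   leave-one-out cross-validation on a subsample of features (one shared
   span; per-feature cross-validation would multiply the cost for no
   measurable gain at the QC densities involved). `"median-ratio"`
   (interpolated QC/median ratios) and `"rf"` (random-forest regression on
   injection order) are selectable alternatives; all three honour the same
   QC-anchored multiplicative-drift contract. At least 5 QC injections are
   required; constant-QC and all-zero features pass through unchanged.
2. **Zero imputation** (`impute_zeros`). Every zero is replaced by half the
   smallest positive value of the full matrix — matrix-global and before
   any filtering, which is the literal reading of the half-minimum rule.
3. **IQR filter** (`iqr_filter`). Features are ranked by their
   interquartile range across *study* injections (QC injections are pooled
   means and would mask biological spread) and the `floor(0.10 * n)` lowest
   are removed, ties broken by row order. On raw intensities this is in
   practice close to a low-abundance filter — a point that matters for the
   generator design, see section 7.
4. **QC-RSD filter** (`rsd_filter`). RSD = 100·sd/mean over QC injections
   (sample SD); features above 20% are removed, zero-mean features are
   removed and flagged.
5. **Transform and scale** (`transform_scale`). log10 (the base is a
   convention; it only rescales every downstream linear statistic), then
   per-feature Pareto scaling over study injections: centre and divide by
   the square root of the standard deviation of the logged values. Zero-
   spread features are set to zero and flagged. The result carries a
   `scaled` attribute and the chain refuses to run twice — the transform is
   not idempotent and re-running it is always an error in the analysis.

The report returned alongside the matrix reconciles counts at every step
(asserted, not just documented) and carries the per-feature QC RSD before
and after correction so that correction quality is measurable.

## 4. Differential abundance

The design is paired with exactly two timepoints, so blocking on subject is
realized *exactly* by within-subject differencing: per feature, the
(post − pre) difference on the analysis scale is regressed on an intercept
plus subject-level covariates (sex, age, BMI, period by default). This is
equivalent to, and simpler than, a mixed model with a subject random effect,
which is only an approximation in unbalanced designs but exact here. The
covariate columns are centred, so the intercept *is* the covariate-adjusted
mean paired difference and its unit variance is 1/n. A rank-deficient
covariate design is an error naming the collinear columns; subjects missing
a timepoint are dropped with a warning.

`eb_moderate()` shrinks the per-feature residual variances toward a common
prior estimated by the closed-form method of moments on log sample
variances: with \(e_g = \log s_g^2 - \psi(d/2) + \log(d/2)\), the prior
degrees of freedom solve \(\psi'(d_0/2) = \mathrm{var}(e) - \psi'(d/2)\)
(trigamma inversion by Newton's method) and
\(s_0^2 = \exp(\bar e + \psi(d_0/2) - \log(d_0/2))\). Posterior variances
are \((d_0 s_0^2 + d s_g^2)/(d_0 + d)\) and moderated t-statistics carry
\(d_0 + d\) degrees of freedom. Two limits are worth noting: `prior_df = 0`
forces ordinary t-statistics, and a non-positive moment estimate gives
\(d_0 = \infty\) — complete shrinkage to \(s_0^2 = \exp(\bar e)\), which is
the common \(s^2\) *times* a log-chi-square bias correction of order
\(1 + 1/d\), not the raw common \(s^2\); the reference empirical-Bayes
implementation behaves identically and the tests cross-check both against
it and against an independently coded brute-force version of the formulas.

Selection is Benjamini–Hochberg at FDR ≤ 0.05 (`bh_adjust`, a thin wrapper
over `stats::p.adjust` that excludes `NA` p-values from the ranking). Where
a study has two ionization modes, the two matrices are preprocessed and
tested independently and selections are unioned; the package operates on
one matrix at a time and never merges modes.

## 5. Over-representation analysis

`enrich()` tests the selected metabolite set against each pathway with a
one-sided hypergeometric test (upper tail, `stats::phyper`), restricted to
pathways with 5–150 members and at least one hit, BH-adjusted over the
tested pathways only. The background universe defaults to the union of all
pathway members; in the pipeline it is the preprocessed features present in
the database, and it is an explicit argument because the "right" background
(all database metabolites vs. all measured metabolites) is a genuinely open
convention — results for strongly enriched sets are robust to the choice,
marginal calls are not. Sources (KEGG-, Reactome-, WikiPathways-style
labels) ride along as a column; cross-source duplicate pathways are *not*
deduplicated, matching how merged databases report them.

## 6. The association network

For every selected metabolite and every PK parameter and trait, the
dependence measure is the sample distance correlation: pairwise Euclidean
distance matrices are double-centred, the squared distance covariance is
the mean elementwise product, and \(d \in [0,1]\) normalizes by the
distance variances. \(d = 0\) characterizes independence (in the
population), and \(d\) responds to non-linear, non-monotone dependence that
Pearson correlation misses. Direction is taken from the sign of the Pearson
correlation on the same values; \(|r| < 10^{-10}\) flags the sign as
ambiguous (e.g. a symmetric quadratic) rather than guessing.

Significance is by permutation: subjects of the parameter vector are
permuted B times and \(p = (1 + \#\{d_\text{perm} \ge d_\text{obs}\})/(1+B)\),
which is assumption-free, exactly reproducible under a seed, and valid for
a statistic with no usable finite-sample null distribution at n = 37.
Implementation note: permuting subjects permutes rows and columns of the
centred distance matrix simultaneously, and double-centring commutes with
simultaneous permutation, so each permutation reduces to an indexed
elementwise product — all pairs share one seeded permutation set and the
full screen is a few seconds, not hours.

**Choice of B.** BH adjustment is applied globally across the full
metabolite × parameter pair set (the conservative reading of "FDR-adjusted"
when no scope is stated). The smallest attainable permutation p-value is
\(1/(B+1)\), so with ~1000 pairs and B = 999 even a perfect association
cannot reach q < 0.05 unless there are ≥ 20 discoveries — a structural
floor, not a power issue. The default is therefore B = 4999
(min p = 2·10⁻⁴), which lets a handful of true edges survive global BH at
the study's scale; users testing many more pairs should scale B
accordingly.

Edges with \(d > 0.5\) and \(q < 0.05\) (both strict) form an undirected
graph whose vertices carry a class label — metabolite, PK, trait — and
whose edges always join a metabolite to a non-metabolite: the tripartite
constraint is asserted structurally on every emitted graph, never assumed.
Edge weight is the unsigned \(d\) (modularity is ill-defined with negative
weights); the sign is an edge attribute. The network is built separately at
pre-dose (baseline abundances vs. traits *and* PK parameters — the PK
comparison at baseline is computed precisely so that its emptiness is a
result, not an omission) and post-dose (T~max~ abundances vs. both).

Communities are found with the Leiden algorithm (modularity objective,
resolution 1, `igraph::cluster_leiden`), which guarantees internally
connected communities. Because the algorithm is stochastic and can land in
a local optimum on small graphs, `leiden_partition()` runs a small number
of seeded restarts (default 5) and keeps the best-modularity partition —
deterministic under the seed, and verified in the tests against exhaustive
enumeration of all partitions on benchmark graphs. Module ids are
renumbered by decreasing size; isolated nodes never enter the graph (only
retained edges do), so module counts refer to connected structure.

`integrate_results()` finally left-joins the retained edges with the
enriched pathways containing each edge metabolite: one record per edge,
keeping metabolites with no enriched pathway (flagged `pathway_less`), so
the integrated table faithfully reflects the network rather than only its
pathway-annotated part.

## 7. The synthetic-study generator

`simulate_study()` generates the full bundle — concentration profiles, true
PK parameters, traits, feature matrix with injection metadata, pathway
database — plus the ground truth needed to score recovery. All randomness
flows from one seed with fixed per-stage sub-streams, so identical
configurations reproduce byte-identical outputs and re-running one stage
reproduces it exactly.

* **PK**: a one-compartment oral absorption model,
  \(C(t) = F D k_a / (V(k_a - k_e)) (e^{-k_e t} - e^{-k_a t})\), the
  simplest model consistent with a single-peak oral profile; the pipeline
  itself never assumes it. Population means default to k~a~ 1.3 h⁻¹,
  k~e~ 0.09 h⁻¹, V 11.5 L, F 1 — chosen so the cohort sits at C~max~ ≈ 35
  µg/mL, T~max~ ≈ 2.2 h and T~1/2~ ≈ 8 h for a 500 mg dose, a regime
  typical of a rapidly absorbed NSAID — with lognormal between-subject
  variability (CVs 35/22/20/5%). The AUC follows from the model
  (≈ 500 h·µg/mL at these defaults); a one-compartment curve cannot be
  bent to an arbitrary AUC once C~max~ and k~e~ are fixed. Subjects with
  \(k_a = k_e\) (where the curve is singular) are resampled. Multiplicative
  lognormal assay noise (mean-one, CV 10% by default) is applied to the
  sampled curve; the exported true parameters are computed analytically,
  noise-free.
* **Features**: lognormal baselines (natural-log abundance uniform over
  log 10⁴–10⁶), per-feature biological between-subject variability
  (median CV 30%, heterogeneous across features), a planted pre/post
  log-fold change on `n_differential` features (|LFC| drawn from
  {0.5, 0.8, 1.2}, random sign — several residual SDs at the default noise,
  i.e. planted effects are meant to be *found*), planted linear or
  rank-monotone (exponential) associations between edge features and a PK
  parameter or trait, a feature-specific multiplicative injection-order
  drift (monotone trend + low-frequency sinusoid, magnitude 0.15) shared by
  QC and study samples, and mean-one lognormal measurement noise. QC
  injections measure the per-feature mean of all study samples *before*
  drift and noise, so drift-correction quality is directly measurable
  against truth. The injection sequence randomizes study samples with a QC
  injection every 10 (bracketing the run).
* **Ground-truth placement.** Planted features are drawn from features
  above the 15th abundance percentile, because the raw-scale IQR filter
  removes the lowest-abundance decile by design and ground truth that the
  preprocessing chain is *specified* to delete would make recovery
  ill-defined; in practice identified metabolites are not at the detection
  floor. The planted association term is centred across subjects so that
  differential status (the planted LFC) and association strength are
  independent properties of a feature, and its default strength is set so
  planted edges sit clearly above the d > 0.5 retention threshold at
  n = 37 and 10% noise — recovery tests exercise the pipeline, not
  threshold luck. Planted edges attach to AUC~0–t~, C~max~, k~el~,
  T~1/2~ and the laboratory traits; T~max~ is excluded from the *planted*
  pool (it remains a network node) because its NCA estimate is quantized
  to the sampling grid, which degrades any planted continuous association
  by construction.
* **Traits**: independent normals around clinically plausible centres
  (blood pressure, cholesterol, creatinine, glucose, transaminases,
  bilirubin, hemoglobin, hematocrit), stored in the configuration; sex,
  age, BMI and a crossover period label serve as covariates.
* **Pathways**: 20 random sets with sizes uniform in 5–150, plus one
  planted pathway (12 members, 10 of them differential features) as the
  positive control for enrichment.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: spectral structure (m/z, retention time,
adducts, isotopes) and the peak-picking that produces a feature table;
correlated metabolite blocks (features are independent given the planted
structure, so the generator cannot probe how module detection behaves under
dense biological correlation); heavy-tailed or missing-not-at-random
intensity distributions; multi-compartment or enterohepatic PK; trait–trait
correlation; batch effects beyond smooth injection-order drift. Recovery on
this generator validates the pipeline's statistical machinery and its
bookkeeping, not the chemistry upstream of it.

## 8. Numerical choices and degenerate inputs

* Distance correlations are clamped to [0, 1] against floating-point
  undershoot; a constant vector has distance variance 0 and yields d = 0,
  p = 1, ambiguous sign, rather than an error.
* Permutation comparisons use `d2_perm >= d2_obs - 1e-15` so that exact
  ties (e.g. a perfectly dependent pair, where every permutation of an
  affine image ties at most) count toward the p-value, keeping it valid.
* Adjusted-R² ties in the terminal fit break toward more points within
  1e-12; trigamma inversion iterates Newton steps to relative 1e-10.
* `iqr_filter` tie-breaks by row order (stable sort); `floor()` semantics
  mean fewer than 10 features lose nothing at the default fraction.
* All-zero features pass drift correction unchanged; an all-zero matrix is
  an imputation error; a non-positive cell at the transform step is an
  error naming the offending feature and injection.
* Leiden restarts compare modularity with a 1e-15 margin so the first of
  exactly tied partitions is kept deterministically.

## 9. Problem sizes used by the tests

The test suite and acceptance script run entirely on generated data at the
study's natural scale where the property demands it, and smaller where it
does not: 37 subjects × 2000 features for type-I calibration and the
default end-to-end run; 37 × 1000 with 50 planted effects and 10 planted
linear edges for recovery; 100 random pairs at n ≤ 12 against the
brute-force distance-correlation oracle; exhaustive hypergeometric checks
at margins ≤ 50; exhaustive modularity enumeration on 8-node benchmark
graphs; 20 repeated seeds for null edge screens. These sizes are the
package's own choices balancing statistical resolution against a test run
measured in seconds per file.

## 10. Known limitations

* The paired design is hard-wired to two timepoints; longitudinal designs
  with three or more would need a genuine mixed model, not differencing.
* Permutation p-values are granular at 1/(B+1); global BH across very
  large pair sets requires B beyond the default (section 6).
* The drift model assumes drift is smooth in injection order and
  multiplicative; step changes (e.g. a mid-run recalibration) violate it
  and would be better served by batch covariates.
* Pathway inference is over-representation only: no topology, no effect
  direction, and identifiers must match between the feature table and the
  database — the integration step errors loudly on fully disjoint id
  spaces rather than silently reporting an empty join.
* Distance correlation at n = 37 has limited resolution; the d > 0.5
  threshold is a screen, not an effect-size estimate, and retained-edge
  d values are upward-selected.
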