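---
title: "Methods: metabolic trajectories, subtypes and biomarkers of LUAD progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolic trajectories, subtypes and biomarkers of LUAD progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(luadmet)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the design choices made where the
design was genuinely open, and what the synthetic-cohort tests do and do
not demonstrate about real data.

## The data model

The raw substrate is a wide peak-area matrix (metabolites × samples, `NA`
for undetected transitions) plus a sample table annotating each injection
with patient, cohort (tissue or plasma), role (tumor, NAT, plasma, QC),
histological stage (AAH, AIS, MIA, IAC for tissue; benign, AIS, MIA, IAC
for plasma), analytical batch, and injection order. Pooled-QC injections —
aliquots of a pool of all study samples injected at intervals — carry no
patient and anchor the batch correction. A clinical table carries
disease-free and overall survival (months, event flags) and covariates.
Both orientations of supplementary matrices occur in practice, so
`read_peak_matrix()` takes an orientation flag and a configurable
missing-value sentinel list (empty, `NA`, `NaN`; literal zero opt-in),
because export conventions vary between peak-integration tools.

## Preprocessing

The chain is fixed: detection filter → baseline fill → QC normalization →
total-signal scaling → tumor/NAT ratios. Order matters: the fill value
(default 1000) is a *detection baseline on the raw peak-area scale*, so it
must precede any rescaling.

**Detection filter.** A metabolite is kept when detected in at least 80%
of the samples of at least one group (boundary inclusive — exactly 8/10
counts). The grouping for "one group" is not canonical; the default
crosses role with stage (tumor-AAH, NAT-AAH, …) so that a metabolite
confined to one compartment or one stage survives, and is configurable.
The published wording of the rule leaves metabolites detected in 20–80% of
every group formally unaddressed; the default reading drops them (they
fail every group's 80% bar), and a `strict` mode that only drops
metabolites under the 20% fill margin everywhere is provided without
asserting either as the original intent.

**QC normalization.** For each metabolite, QC_all is the mean peak area
over all QC injections and QC_adj the mean over the QC injections
anchoring a group of test samples; each test value is multiplied by
QC_all/QC_adj. "Most adjacent" is not operationalized in the field's
descriptions; the reproducible default takes the group to be an analytical
batch (QC_adj = that batch's QC mean), and a sliding-window mode (the k
nearest QC injections by injection order, default k = 2) is available when
within-batch drift matters. The formula's fixed point is the property the
tests assert: after normalization, per-batch QC means agree across batches
to floating precision. A subtlety worth recording: injecting an extra
multiplicative constant into one batch does *not* leave the normalized
matrix bit-identical, because QC_all itself moves; it changes the matrix
by an exactly per-metabolite global factor, and paired tumor/NAT ratios
are exactly invariant. The tests assert those exact forms.

**Scaling and ratios.** Total-signal scaling divides each sample by its
summed signal (columns sum to 1), absorbing biomass differences. The
per-patient tumor/NAT ratio — positive by construction after filling — is
the unit of every stage comparison; patients lacking either pair member
are excluded and reported, never silently dropped.

## Differential statistics

All group comparisons are rank-based: Wilcoxon signed-rank for paired
tumor/NAT (exact null for ≤ 25 untied differences, otherwise normal
approximation with tie and continuity correction; all-zero differences are
flagged and reported as p = 1), rank-sum for unpaired contrasts, and
Kruskal–Wallis with tie correction for ≥ 3 groups. p-values are adjusted by
Benjamini–Hochberg, and calls are gated with strict inequalities:
FDR < 0.05 and fold change > 1.25 or < 0.8. The fold-change estimator is
deliberately explicit because thresholds alone do not define it: paired
designs use the geometric mean of per-pair ratios (the natural estimator
on a multiplicative scale), unpaired stage contrasts use the ratio of
group means; both are configurable. The plasma stage screen gates on raw
p < 0.1 rather than FDR — with 92 patients and 140 metabolites the
adjusted screen would be nearly empty, and the raw-p reading matches how
such plasma screens are reported. Exact-path cutovers (n = 25 signed-rank,
min group 10 rank-sum) are the conventional exact-computation limits and
are configurable; the dual paths are cross-checked against each other and
against enumeration oracles in the tests.

## Trajectory clustering

Stage trajectories are summarized as the per-stage mean of log2 tumor/NAT
relative abundance for metabolites passing a Kruskal–Wallis FDR < 0.1
screen, in fixed progression order. Whether to cluster per-patient
profiles or per-stage means is an interpretation point; per-stage means
are used here, matching how such trajectories are plotted and read.
Rows are standardized (mean 0, SD 1) so that Euclidean fuzzy c-means
groups by trajectory *shape* — standardization makes squared Euclidean
distance affinely equivalent to correlation distance; constant rows are
dropped and reported. Fuzzy c-means uses the standard alternating updates
with fuzzifier m = 2 (the common default; the value used originally is
unstated) and c = 4 clusters by default (the observed archetype count); a
silhouette-over-c diagnostic is emitted but never auto-selects c, since no
selection criterion was specified originally. Initialization draws c
distinct rows with a recorded seed and keeps the best of 10 seeded starts
by final objective — fuzzy c-means on standardized 4-point profiles has
genuine local optima, and multi-start is the standard remedy. Membership
rows sum to 1 and the objective trace is non-increasing by construction;
both are asserted, and the converged optimum is cross-checked against an
independent implementation.

## Consensus subtyping

Invasive patients are clustered on z-scored log2 tumor/NAT profiles
(input scaling was unstated originally; z-scoring per metabolite is the
documented, configurable choice). "k-means with Pearson distance" is
realized as Euclidean k-means on row-centered, unit-norm profiles, for
which squared Euclidean distance equals 2(1 − r); classical k-means does
not accept arbitrary metrics and this is the standard equivalence. For
each of 1000 repetitions, 80% of patients are subsampled without
replacement (the item fraction is the common default, exposed in config)
and partitioned for every k in 2..6; consensus is co-clustering count over
co-sampling count, with never-co-sampled pairs set to 0 under a warning
(vanishingly rare at these settings).

Model selection follows the two factors such analyses actually use. The
delta-area of the consensus CDF (Δ(2) = A(2), Δ(k) = (A(k) −
A(k−1))/A(k−1)) proposes candidate ks (threshold 0.1), and the mean
within-cluster consensus decides among them (bar 0.9): the largest
candidate meeting the bar is chosen. The stability bar is not decorative —
the delta-area alone keeps exceeding 0.1 one step past the true k, because
force-splitting a real cluster still adds CDF area while its within-
cluster consensus collapses; for clean three-cluster data with the subtype
proportions seen here, Δ(4) ≈ 0.14. With no candidate meeting the bar the
delta-only choice is returned flagged `stable = FALSE`, which is what a
homogeneous (null) cohort produces. Final assignment — unstated in the
original description — cuts an average-linkage tree on 1 − consensus at k
and renumbers subtypes by descending size. At small cohort sizes (a few
dozen patients) a true cluster of ~15 can split stably, so the chosen-k
recovery claim is made, and tested, at the study scale of 128 invasive
patients.

## Enrichment, panels, survival

**Enrichment** is a one-sided hypergeometric over-representation test per
metabolite set, BH-adjusted across sets, with fold enrichment
(overlap/differential)/(set/background) and the mean log2 fold change of
the overlapping metabolites. The background universe is the detected
metabolites mapping to at least one set (configurable to all detected) —
the original universe is unstated. Sets with fewer than 2 background
members are skipped and reported.

**Panels** are unpenalized binary logistic regressions on log10
abundances, the scale on which such markers are plotted; the headline
metric is in-sample (resubstitution) AUC, matching how such panels are
conventionally reported, with an optional stratified k-fold
cross-validated AUC computed alongside and never silently substituted.
Separation is detected and flagged rather than masked. ROC curves sweep
all distinct thresholds; the AUC is computed both by trapezoid and by
tie-aware pair counting and the two must agree to 1e-12. `screen_panels()`
makes the panel-selection step explicit (exhaustive subsets up to size 4,
ranked by AUC) without claiming equivalence to the original, unstated,
selection mechanism.

**Survival** uses the product-limit estimator and the log-rank test, with
the standard conventions: censored subjects at an event time remain at
risk through the event; quantile dichotomization uses type-7
(linear-interpolation) quantiles so thresholds are bit-reproducible; the
maximally selected cutpoint scans every cutoff leaving ≥ 10% of subjects
per side and reports the uncorrected maximal standardized log-rank
statistic (the cutoff, not its p, is the object of interest; a Bonferroni-
over-the-scan p is reported alongside). The histoscore is percent positive
cells (0–100) times mean staining intensity (0–3); its formula gives 0–300
even though such scores are conventionally quoted as 1–300 — the product
is implemented as stated and the discrepancy surfaced, not resolved.

## The synthetic cohorts

The generator defines the study conditions under which everything above is
exercised, with abundances lognormal and all effects additive on the log2
scale — multiplicative noise is the standard model for LC-MS peak areas
and makes ratio-based analysis exact.

* Cohort shape: 181 tissue patients (AAH/AIS/MIA/IAC = 12/22/19/128), one
  tumor and one NAT sample each, randomized into 14 batches with paired
  samples kept together and 5 QC injections per batch at evenly spaced
  positions; 92 plasma patients (benign/AIS/MIA/IAC = 10/32/22/28) in 2
  batches.
* Noise and nuisance: analytical noise SD 0.25 log2 units (~18% CV,
  typical of targeted assays); per-(batch, metabolite) effects
  N(0, 0.5²) log2, shared by the QC channel; linear injection-order drift
  0.002 log2/injection; plasma per-sample SD 0.6 log2 units (biological
  plus analytical).
* Trajectories: four archetypes × 20 metabolites — an AIS peak, an MIA
  peak, a stepwise increase already present in preneoplasia, and a
  stepwise decrease emerging with invasion (peak |log2| 1.0–1.2) — so
  tumor-vs-NAT differential counts grow along the progression, as
  observed in resected-lesion cohorts.
* Subtypes: three latent IAC subtypes at the 33/63/30 reference
  proportions, rescaled to the 128 invasive patients by largest remainder
  (34/64/30); the smallest subtype carries a 9-metabolite bile-acid block
  at +1.5 log2 in tumors, the other two carry 15-metabolite signatures at
  +1.0 log2. DFS hazards are 0.010/0.022/0.028 per month by subtype
  (hazard ratios 2.2–2.8), with independent Uniform(0, 120 months)
  censoring giving roughly 40% censored.
* Detection: detectable baselines span log2 13–20 with the threshold at
  peak area 2000, about three log2 units below the lowest baseline, so
  the designed panel of 158 tissue and 140 plasma metabolites is what the
  filter recovers; deliberately low-abundance metabolites (baselines log2
  8–10.5) exercise the dropped path.
* Plasma markers: stage shifts in within-class SD units, set by inverting
  the binormal AUC relation AUC = Φ(d/√2) at the diagnostic performance
  this study design targets (four markers at d = 0.9 for benign vs any
  malignant stage; cystine/valine strongest pre-invasively; asparagine/
  cystine strongest in AIS), plus nine further truly altered metabolites
  at d = 0.8 in assorted monotone/peak patterns.
* Seeding: a single master seed fans out to independent tissue and plasma
  substreams, so regenerating one cohort never perturbs the other, and
  identical configurations are bit-identical.

**What passing these tests shows — and does not.** The generator emulates
the *structure* of such a study (pairing, batches with QC anchoring,
left-censored detection, archetypal trajectories, blocky subtypes,
binormal marker separations, proportional-hazards survival). It does not
emulate correlated metabolite modules beyond the planted blocks, nonlinear
or retention-time-dependent drift, heavy-tailed or sample-specific
contamination, missingness that is informative beyond left-censoring, or
cohort confounding (age, smoking) of the metabolome. Recovery results
(ARI = 1 at the defaults) therefore validate the implementations under
their intended generative model; they are not performance claims for real
cohorts. On the real supplementary matrices the five reproduction tests
in `test-acceptance.R` run the identical code paths end to end.

## Numerical conventions and degenerate inputs

Fuzzy c-means stops when the objective changes by < 1e-8 (cap 500
iterations); zero distances receive full membership on the coincident
center; membership ties in hard assignment break toward the lowest cluster
index and are reported. Logistic fits use IRLS at tolerance 1e-8, cap 100
iterations. All-zero signed-rank differences flag the test degenerate
(p = 1); identical values across Kruskal–Wallis groups give H = 0, p = 1;
constant biomarkers make `quantile_split()` warn (single group) and
`optimal_cutpoint()` error (no admissible cutoff); a batch without QC
injections, a zero QC mean, and a zero-total sample are errors naming the
offending batch, metabolite, or sample. Problem sizes in the test suite
are scaled-down versions of the defaults (documented in the test helpers)
chosen so the structural checks run quickly; study-scale recovery claims
use the full 181/92-patient defaults.
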