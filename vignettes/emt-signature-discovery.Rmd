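---
title: "Discovering pan-cancer EMT signatures with emtscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering pan-cancer EMT signatures with emtscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emtscreen)
options(emtscreen.verbose = FALSE)
```

## The problem

Carcinoma cells can shift between an adhesive epithelial state and a
migratory mesenchymal state (the epithelial–mesenchymal transition, EMT), a
program implicated in invasion and metastasis. Genes whose expression tracks
this state *in cancer cells themselves* are candidate regulators and
prognostic markers. Finding them from public expression compendia is harder
than it looks, for two reasons this package is built around:

1. **Entity-specific confounding.** A gene separating epithelial-like from
   mesenchymal-like samples in one cancer entity may simply mark that
   entity's subtypes. Screening *each entity separately* and keeping only
   genes that pass in *every* entity removes such hitchhikers and doubles as
   de facto multiplicity control.
2. **Stromal contamination.** Bulk tumor profiles mix cancer cells with
   stroma. Fibroblasts and other stromal cells express the canonical
   mesenchymal program — vimentin above all — at one to two orders of
   magnitude above carcinoma cells, so a bulk "mesenchymal" readout largely
   measures stromal content, not the cancer cells' state. Cell lines have no
   stroma. The two data types therefore disagree systematically about
   mesenchymal genes, and agree about epithelial ones.

The package implements the resulting dual-screen design and every
downstream statistic, and ships a synthetic-data generator with planted
ground truth so that the whole flow is testable end to end.

## The dual screen

**Cell-line arm.** Lines are classified by the anchor ratio on linear-scale
expression: epithelial-like if CDH1 > 10 × VIM, mesenchymal-like if
VIM > 10 × CDH1, ambiguous otherwise (strict inequalities; ambiguous lines
are dropped, since the two printed definitions are not exhaustive). Within
each entity, every gene is compared between the two groups by a two-sided
pooled-variance Student's t-test on log2 values; genes with p < 0.05 are
flagged toward the side of their fold change. No per-gene multiplicity
correction is applied — the all-entity intersection is the filter (a
Benjamini–Hochberg option exists behind `screen_config(p_adjust=)`, and
Welch's t behind `welch = TRUE`).

**Tumor arm.** Within each entity, every gene is Spearman-correlated with
the two anchors. Epithelial-state genes satisfy r(CDH1) > 0.1 **and**
r(VIM) < −0.1; mesenchymal-state genes the mirror image; thresholds are
strict, no p-value is attached, and genes constant within an entity are
unclassifiable there (hence excluded by the intersection). Anchors are not
excluded from their own screen; their self-correlation of 1 simply places
each anchor in its own class whenever the two anchors are anti-correlated.

**Shared signature.** The class-wise intersection of the two arms. On real
compendia this is the step that collapses the mesenchymal side — the point
of the stromal argument — and the synthetic generator reproduces exactly
that behaviour.

## What the generator emulates

`simulate_cell_lines()` builds per-entity compendia with equal epithelial
and mesenchymal line counts. Each gene draws a log2 baseline on [4, 10]
once; planted epithelial (mesenchymal) markers gain `effect_size` (default
2.0 log2) in their state; entity-specific genes gain it in one designated
entity only; 900 nulls gain nothing; i.i.d. Gaussian noise (`noise_sd`,
default 0.5 log2) is added per cell. The anchors share one baseline and are
shifted by `log2(10) + 8 * noise_sd`, which puts the anchor log-ratio at
least eight noise standard deviations past the 10-fold threshold, so the
ratio rule classifies essentially every simulated line correctly — the
screen's entry condition, not its conclusion.

`simulate_bulk_tumors()` gives each tumor a latent EMT score `e ~ U(0, 1)`
and a purity `rho ~ U(0.5, 0.95)`. Cancer-cell expression responds as
`2^(effect_size * w * e)` (mesenchymal side) or `* (1 - e)` (epithelial
side). The stromal profile is where the asymmetry lives:

* **VIM** at baseline × the geometric mean of `stroma_factor_range`
  (≈ 32-fold; the "one to two orders of magnitude");
* **planted mesenchymal markers at baseline** — they are cancer-cell
  intrinsic markers, the kind the cell-line arm discovers, not fibroblast
  genes;
* epithelial-class genes nearly silent in stroma (per-gene floor from
  `stroma_epi_range`);
* nulls at baseline, so mixing leaves them flat and uncorrelated with
  everything — the tumor screen stays well-calibrated for them.

Bulk = `rho · cancer + (1 − rho) · stroma`, then multiplicative log-normal
noise. Because bulk VIM is dominated by `(1 − rho) × 32`, its ranking
across tumors reflects stromal content rather than the cancer cells' EMT
state. Epithelial genes still anti-correlate with it (they fall with
stromal content *and* with `e`), but a cancer-intrinsic mesenchymal marker
*rises* with purity while VIM falls with it — its required positive VIM
correlation is destroyed. Setting `purity_range = c(1, 1)` removes the
stromal term and restores perfect symmetry between the classes, which is
how the package demonstrates the mechanism rather than asserting it.

Two deliberate departures from a minimal mixture model:

* **Per-gene responsiveness** `w ~ U(0.3, 1.5)` (anchors at `w = 1`). Real
  markers differ widely in dynamic range. Beyond realism this matters
  mechanically: with one common effect size, z-scored signature profiles
  are rank-one, and the Pearson-correlation distance — which centers every
  profile — would see pure noise, making any correlation-based clustering
  of patients impossible *by construction of the data, not by any failure
  of the method*. The upper end stays at 1.5 because a much stronger
  responder's own variance shrinks its anchor correlations below the 0.1
  threshold under contamination (an attenuation effect worth knowing about
  in real data too).
* **Outcome links.** OS and RFS are independent exponentials with hazard
  `baseline_hazard * hazard_ratio_mes^e` and censoring tuned to
  `censor_rate` (default 0.2, keeping ≈ 720 events among 900 tumors — at
  0.3 censoring even a perfect median split of `e` detects the default
  hazard ratio in barely 90% of cohorts, which would say more about event
  counts than about stratification). M1 and N+ status follow a logistic
  link in `e` (base −2, slope 3: ≈ 12% M1 in fully epithelial, ≈ 73% in
  fully mesenchymal tumors). Pseudo-subtypes CMS1–CMS4 are EMT-score
  quartiles with CMS4 the most mesenchymal, mirroring how the mesenchymal
  consensus subtype behaves; the IHC score is a noisy 0–3 discretization
  of `1 − e`.

What the generator does **not** emulate: real marginal distributions,
library-size or batch effects, gene–gene co-expression beyond the planted
EMT axis, correlated censoring, or any coupling between OS and RFS. Passing
recovery tests here demonstrates that the procedures do what they claim
under their stated assumptions — not that real compendia satisfy those
assumptions.

## A complete run

```{r pipeline}
report <- run_pipeline(screen_config(seed = 1), sim_params(seed = 1))
str(report$counts$shared)
str(report$recovery)
report$survival$os$logrank
```

At the reference conditions the shared epithelial list recovers ≥ 90% of
the planted epithelial markers with no entity-specific and no null genes;
the shared mesenchymal list collapses to the anchor — the synthetic
counterpart of a 16-versus-4 style concordance gap.

## Scoring and stratification

`score_signature()` z-scores each signature gene's log2 expression across
the cohort and averages; with nothing dropped, scores are exactly centered.
`kmeans_stratify()` partitions samples by Lloyd's algorithm under the
distance `1 − Pearson(x, centroid)` with k = 2, at most 50 iterations, and
10 seeded restarts. Profiles are standardized per sample first; the
centroid update is then the plain mean of member profiles, which for this
distance is exactly the within-cluster optimum, so the logged objective is
non-increasing and convergence is an assignment fixpoint. Ties in distance
go to the lower-indexed centroid; an emptied cluster is re-seeded at the
sample farthest from its centroid; group polarity (`epi_group` vs
`mes_group`) comes from the signature scores, never from initialization.
Whether to cluster on the epithelial genes, the mesenchymal genes, or both
is genuinely ambiguous in the design this follows; the default is `"both"`
with the class exposed as an argument.

```{r strat}
strat <- report$stratification
table(strat$cluster)
emt <- report$truth$tumors$emt_score[strat$sample_id]
tapply(emt, strat$cluster, mean)
```

## Clinical statistics

Kaplan–Meier curves and the two-group log-rank test wrap the survival
package (`survfit`/`survdiff`); the test suite checks both against
hand-written product-limit and O/E/variance oracles to 1e-10, and checks
the log-rank's type-I error on 2000 null replicates. `roc_cutoff()` sweeps
all midpoints of the sorted values and maximizes Youden's J, breaking ties
toward balanced sensitivity/specificity and then the lower cutoff; a
log-rank-minimizing alternative was considered and rejected to keep the
dichotomizer outcome-agnostic (J against a stated binary outcome, e.g.
metastasis, is reproducible without access to follow-up). Fold-change
associations always carry an explicit numerator/denominator because a
printed ratio without orientation is uninterpretable — one published value
in this area appears to have exactly that problem. The chi-square is
Pearson's without continuity correction; subtype summaries use
Kruskal–Wallis, chosen (and documented) as this package's choice since the
original comparison shows distributions without naming a test.

```{r clin}
cli <- as.data.frame(simulate_bulk_tumors(sim_params(seed = 1))$clinical)
km <- km_estimate(cli$os_time, cli$os_event)
head(km, 3)
chisq_association(table(cli$ihc_score, cli$m_status))
```

## Numerical and degenerate-input policy

* Ratio of anchors with VIM = 0 and CDH1 > 0 is +Inf → epithelial-like;
  0/0 is ambiguous.
* Pooled t with both groups constant: p = 1 if means are equal, otherwise
  t = ±Inf, p = 0.
* Spearman of a constant vector is NA and the gene is unclassifiable.
* Scoring drops sd-0 genes with a warning; an all-constant signature is
  fatal.
* Clustering on identical profiles or constant profiles is fatal (the
  distance is undefined), as is a signature with fewer than two usable
  genes.
* Seeds: one user-facing seed; cell-line simulation, tumor simulation and
  k-means initialization each use a deterministically derived sub-stream,
  so regenerating one stage never perturbs another.

## Problem sizes used in the test suite

Unit and property tests run on reduced simulations (2–3 entities, ≈ 120
tumors) chosen to keep each property comfortably identifiable; the
acceptance suite re-runs everything at the reference conditions (5 × 40
lines, 3 × 300 tumors, 1022 genes, 20-seed grids, 2000 null replicates for
the log-rank calibration). These sizes are the package's reference
conditions, stated here so results are interpreted at the scale they were
established.

## Known limitations

* The all-entity intersection is brittle by design: one failing entity
  vetoes a gene. `require_all_entities = FALSE` only controls how
  unscreenable entities are handled, not a relaxation to majority voting.
* The generator's stromal model contaminates the mesenchymal anchor and
  silences epithelial genes in stroma; it does not model stromal expression
  heterogeneity across entities, immune fractions, or purity estimated
  with error.
* `roc_cutoff()` assumes the positive class sits at higher values; it does
  not auto-orient.
* k-means with k > 2 runs, but group naming logic is designed for the
  two-group epithelial/mesenchymal use.
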