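# emtscreen

Pan-cancer discovery of epithelial–mesenchymal transition (EMT) gene
signatures from expression compendia, as a tested R pipeline.

Carcinoma cells shift between an adhesive **epithelial** state and a
migratory **mesenchymal** state; genes tracking this state in the cancer
cells themselves are candidate drivers and prognostic markers. `emtscreen`
implements a dual-screen strategy for finding them, together with all the
downstream statistics a typical study needs, and a synthetic-data generator
with planted ground truth so every step can be validated end to end:

* **Cell-line screen.** Lines are classified by the anchor ratio
  (epithelial-like if CDH1 > 10 × VIM, mesenchymal-like if VIM > 10 × CDH1,
  on linear-scale values); per entity, every gene is tested between the two
  groups by a two-sided pooled-variance Student's t (p < 0.05, log2 fold
  change sign gives the side); only genes flagged in **every** entity
  survive.
* **Tumor screen.** Per entity, every gene's Spearman correlation with the
  anchors; epithelial-state if r(CDH1) > 0.1 and r(VIM) < −0.1,
  mesenchymal-state for the mirror image, kept only if classified in
  **every** entity.
* **Shared signature** = class-wise intersection of the two screens.
* **Downstream:** per-sample signature scores (mean of per-gene z-scores),
  patient stratification by k-means with Pearson-correlation distance
  (k = 2, ≤ 50 iterations), Kaplan–Meier/log-rank survival comparison,
  ROC/Youden optimal cutoffs, fold-change + t-test and chi-square clinical
  associations, subtype summaries with Kruskal–Wallis.

Bulk tumors are modeled as purity-weighted cancer/stroma mixtures in which
stromal cells express the mesenchymal anchor at 10–100 × cancer-cell
levels. This reproduces a key real-world effect: the two screens agree
about epithelial genes and disagree about mesenchymal ones, because bulk
VIM measures stromal content rather than cancer-cell state. See the
vignette (`vignettes/emt-signature-discovery.Rmd`) for the model and every
design decision.

## Worked example

```r
library(emtscreen)
report <- run_pipeline(screen_config(seed = 1), sim_params(seed = 1))

str(report$counts$shared)
#> List of 2
#>  $ epithelial : int 49
#>  $ mesenchymal: int 1

str(report$recovery)
#> List of 4
#>  $ epi_sensitivity             : num 0.96
#>  $ mes_sensitivity             : num 0
#>  $ entity_specific_in_signature: int 0
#>  $ null_in_signature           : int 0
```

The shared epithelial list recovered 48 of the 50 planted epithelial
markers plus the CDH1 anchor (49 genes), with zero entity-specific and zero
null genes; the shared mesenchymal list collapsed to the VIM anchor — the
stromal-contamination concordance gap, reproduced from mechanism rather
than asserted. Rerunning with `sim_params(seed = 1, purity_range = c(1, 1))`
(no stroma) restores full mesenchymal recovery.

```r
strat <- report$stratification
tapply(report$truth$tumors$emt_score[strat$sample_id], strat$cluster, mean)
#> epi_group mes_group
#>     0.270     0.722

report$survival$os$logrank
#> log-rank: statistic = 6.279, df = 1, p = 0.01222
```

k-means on the shared signature splits the 900 simulated tumors into an
epithelial-like group (439 samples, mean latent EMT score 0.27) and a
mesenchymal-like group (461 samples, 0.72), and the mesenchymal group has
significantly worse overall survival — the planted hazard link
(hazard ∝ 2^EMT score) recovered from expression alone.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/emtscreen.R simulate --seed 1 --out-dir out/   # data only
Rscript inst/scripts/emtscreen.R run      --seed 1 --out-dir out/   # full pipeline
```

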