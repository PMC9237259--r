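---
title: "Methods: c-Fos functional connectivity networks from small cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: c-Fos functional connectivity networks from small cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fosnet)
```

## The analysis in one paragraph

c-Fos is an immediate-early gene whose protein marks recently active neurons,
so counts of c-Fos-positive cells per region are a proxy for regional neural
activity. When such counts are available for the same set of regions in every
animal of a group, the cross-animal Pearson correlation between two regions'
counts can be read as functional co-activation, and the full region-by-region
correlation matrix as a functional connectivity network for that group.
`fosnet` builds these networks per experimental group (here: untreated
controls, an MPTP mouse model of Parkinson's disease, MPTP plus acupuncture,
and MPTP plus sham acupuncture), thresholds them into graphs, ranks regions
by degree and betweenness centrality to call hubs, extracts a seven-region
motor-circuit subnetwork and a seed-centered (ego) network around primary
motor cortex, and finally asks which hub-region activities and tyrosine
hydroxylase (TH) measures best predict motor behavior, using five regression
algorithms.

## Input data and the synthetic-cohort generator

The per-animal counts behind the published group summaries are not deposited
anywhere we can reach; what is available is the printed summary table: mean
± SEM of c-Fos-positive cells per counting frame for 30 regions × 4 groups
at n = 6 animals per group, packaged here as `fosnet_table1()`. The pipeline
therefore runs either on a user-supplied cohort table (wide CSV/TSV:
`animal_id, group, <region abbreviations>` plus optional `rotarod_s`,
`cylinder_rearings`, `th_st`, `th_sn` columns) or on synthetic cohorts
calibrated to that summary.

`generate_cohort()` draws each group from a Gaussian copula: marginal mean
equal to the table mean, marginal SD reconstructed as SEM × √n (n = 6 from
the table), and a user-specified within-group correlation matrix, with
unspecified pairs independent. Choices worth knowing:

* **Gaussian marginals truncated at zero**, rather than count distributions.
  Counts per frame are large enough for most regions that the normal
  approximation is harmless, and Pearson correlation — the analysis target —
  only needs second moments. Truncation is accounted for: the truncated
  fraction per region is attached to the cohort and a warning fires when it
  exceeds 1% (this happens for substantia nigra pars compacta, whose control
  mean of 1.3 ± 0.3 sits ~1.8 SD above zero; users simulating SNpc-heavy
  designs should know its marginal is mildly right-shifted and its
  correlations slightly attenuated).
* **Nearest-PSD repair** for user-written correlation matrices: eigenvalue
  clipping at zero followed by rescaling to unit diagonal. Hand-specified
  matrices are often slightly non-positive-definite; matrices with an
  eigenvalue below −1e−4 are treated as specification errors and rejected
  rather than silently repaired.
* **Determinism**: one RNG substream per group is derived from the master
  seed up front, so generating a subset of groups reproduces exactly the
  rows the full run would produce for those groups.

Behavior and TH columns are linked to regional activity with a
linear-Gaussian model (`generate_behavior()`): target = mean + weighted sum
of centred driver activities + noise, clipped to the assay range (the
rotarod test stops at 480 s). Because the link is linear-Gaussian, the noise
SD achieving a requested driver–target correlation r has the closed form
`sd_signal * sqrt(1/r^2 - 1)` (`calibrate_noise_sd()`), verified by
simulation in the test-suite.

### Recovery scenarios

`make_recovery_scenario()` returns explicit "planted truth" correlation
matrices over the seven motor-circuit regions (M1, DLS, DMS, Gp, Sm, SNpc,
SNr) with exactly 9, 3 or 7 pairs above the 0.5 detection threshold,
mirroring the supra-threshold edge counts reported for the control,
MPTP and acupuncture groups. The published analysis names only its strongest
pairs (DLS–DMS r = 0.986, SNr–M1 0.783, M1–DMS 0.742 in controls; M1–DLS
0.727 in MPTP; Sm–DMS 0.904, SNr–Sm and SNr–DMS 0.719 after acupuncture), so
the full matrices are constructions, not estimates: the named pairs carry the
published values, unnamed supra-threshold pairs sit at 0.62–0.74 and
sub-threshold pairs at ≤ 0.35. Every pair is thus at least 0.1 away from the
0.5 threshold, which makes exact edge-set recovery at n = 1,000 a
near-certain event (pairwise SE ≤ 0.032) — the basis of the recovery
acceptance checks. All three matrices are positive definite as written;
transitivity is why some sub-threshold pairs cannot be 0 (with DLS–DMS at
0.986 the two striatal regions are near-duplicates, so anything correlated
with one must correlate almost equally with the other).

`whole_brain_null` keeps all 30 regions with zero off-diagonal correlation.
Note that it retains the published group means, which genuinely differ
between groups — it is a null for *connectivity*, not for *group effects*.

## Group statistics

`oneway_anova()` and `tukey_hsd()` wrap the classical fixed-effects one-way
ANOVA and Tukey's honestly-significant-difference test. `anova_from_summary()`
reconstructs the same F statistic from printed mean/SEM/n alone:

* SS_between = Σ n_g (m_g − grand mean)², df = G − 1;
* MS_within pools per-group variances (SEM² × n) weighted by df:
  Σ (n_g − 1) sem_g² n_g / Σ (n_g − 1), df = N − G.

With equal n this is algebraically identical to the raw-data ANOVA (the
test-suite checks agreement to 1e−10). Reconstructing the primary motor
cortex row of the packaged table gives F(3, 20) = 12.73, matching the
published value of 12.7 — a useful integrity check connecting the fixture to
the published analysis. Degenerate summaries are handled explicitly: equal
means give F = 0, p = 1; all-zero SEMs with unequal means return an
infinite-F flag rather than an overflow.

Correlation reports (`pearson_matrix()`) use pairwise — not global —
listwise deletion, so a missing TH value in one animal does not shrink n for
region–region pairs. Zero-variance columns yield missing correlations, never
zero. Significance stars default to α = 0.001 (the convention of the
published correlation heatmap); the ANOVA/Tukey stage uses α = 0.05. No
multiple-testing correction is applied across the 30-region ANOVA family by
default, matching the published analysis; `region_group_stats(adjust_bh =
TRUE)` adds Benjamini–Hochberg adjusted p values for users who want them.

## Networks, thresholds, centralities, hubs

`interregional_correlation()` correlates region pairs across the animals of
one group (Pearson by default, Spearman as an option). Thresholding
(`threshold_network()`) keeps edges with *signed* r strictly greater than
tau by default — the published networks describe positive supra-threshold
correlations — with an absolute-value mode as a flag. All regions remain
nodes even when isolated: a disconnected region is a finding, not a display
artifact. The whole-brain analysis uses tau = 0.6, the motor subnetwork
tau = 0.5; both are configuration values, not constants.

Centralities follow the graph-theoretic textbook definitions on the
binarized graph: degree is the integer count of incident supra-threshold
edges (the hub criterion "score of 5 or greater" implies integer counts; a
strength variant summing |r| is a flag), and betweenness is unnormalized
shortest-path betweenness with fractional credit when several shortest
paths tie (a 1 − r edge-length variant is a flag). Both are delegated to
igraph and verified in the test-suite against brute-force path-enumeration
oracles on small graphs.

Hubs (`identify_hubs()`) must satisfy both criteria: degree ≥ 5 and
betweenness rank ≤ 10 of 30 (the top third). Ranks are descending with ties
sharing the minimum rank, and ties at the rank boundary are all included —
with 30 regions and many zero-betweenness ties this is the only
non-arbitrary choice, and it is deliberately inclusive: degree gating keeps
tie inflation from minting spurious hubs. `hub_overlap()` is the Venn
intersection of the two qualified lists; applied to the published MPTP lists
it returns exactly {AcbSh}, and to the published acupuncture lists the eight
hub regions {M1, DG, CA3, Cg1, PHA, VL, VTA, LC}.

`motor_subnetwork()` restricts the correlation network to the seven motor
regions before thresholding; `ego_network()` induces the subgraph on a seed
region (default M1) and its neighbors, with node and edge betweenness
computed on the *full* graph before induction, so the annotations describe
each element's role in the whole network.

### The PLS backend

The published networks were built from a partial least squares (PLS)
analysis whose description is too thin to reimplement uniquely ("correlations
between the LVs were abstracted"). `fosnet` therefore makes plain
within-group Pearson correlation the default backend — it reproduces the
r-valued edges the results quote — and provides a clearly-labeled
mean-centered task-PLS backend (`pls_lv_correlation()`) alongside it: SVD of
the group-mean deviation matrix, permutation p values per latent variable by
group-label shuffling, bootstrap ratios by within-group animal resampling
with sign alignment (defaults 1,000/1,000, seeded; the counts are our
choice — the published analysis states the tests but not the iteration
counts).

The network derived from the PLS stage required a design decision. Literally
correlating rank-(G − 1) LV projections collapses every pair to a near-±1
value whose sign reflects group-mean contrasts, not co-activation — under
that construction the PLS and Pearson backends disagree in sign even on
strongly planted structure, which would make the dual-backend comparison
useless. We instead correlate each region's *LV-adjusted* activity: the
group-mean component reconstructed from the retained LVs is removed and the
residual standardized within group (groups differ several-fold in
dispersion), giving approximately the n-weighted average of within-group
correlations. On scenario data with strong planted structure this agrees in
sign with the Pearson backend on every supra-threshold edge, which the
test-suite asserts.

## Behavior prediction

`fit_predictors()` implements the five-regressor stage: GLM, extra trees
(ET), random forest (RF), gradient boosting (GBM) and extreme gradient
boosting (XGB), fitted on one seeded 0.75:0.25 train/test split with 5-fold
cross-validation inside the training portion (a flag moves CV to the full
set; the published protocol is ambiguous on this point). Held-out R² is the
accuracy metric and held-out RMSE the overfitting guard; `rank_models()`
orders by descending R² with ascending-RMSE tie-breaks, which is exactly the
rule that puts GLM ahead of RF when both reach R² = 0.727 but GLM has the
smaller RMSE.

Model choices, all fixed and seeded rather than tuned:

* GLM is ordinary least squares on standardized features — the published
  "generalized linear modeling" names no family, the target (rotarod
  seconds) is continuous, and the Gaussian-identity GLM is the minimal
  faithful reading. Importance = |standardized coefficient|.
* ET is `ranger` with the extra-trees split rule, no bagging
  (`replace = FALSE`, full sample fraction), impurity importance.
* RF is `randomForest` with 500 trees, node-impurity importance.
* GBM is classic gradient boosting: shallow trees (depth 3), shrinkage 0.05,
  no subsampling, no L1/L2 penalties, exact greedy splits.
* XGB is the regularised, subsampled variant (depth 6, shrinkage 0.1,
  row/column subsampling 0.8, L2 = 1), gain importance. GBM and XGB share
  the xgboost engine but are deliberately distinct algorithm configurations.

Importances are reported raw and on two normalised scales, because published
importance tables conflate them: **proportions** (L1-normalised, summing
to 1, the "21.3%, 15.7%, 13.5%" scale) and **relative** importances
(max-normalised, maximum 1, the "1, 0.740, 0.635" scale). The two are
consistent by construction — relative = proportion / max(proportion) — and
max-normalising the published proportions reproduces the published relative
values to printing precision, which is how we know which convention each
printed number used. Per-model RMSEs get the same L1 treatment for
visualisation (`normalize_rmse()`).

The published metrics themselves (R² = 0.727, RMSE = 60.99 at roughly 24
animals) are *not* reproduction targets: the raw data are unavailable and at
that sample size a single 6-animal test split makes the metrics dominated by
split luck. The testable claims are structural, and the test-suite asserts
them on planted-signal cohorts: with the target driven by th_sn > th_st > M1
at decreasing weights (n = 500), the GLM recovers that importance ordering
in ≥ 95% of 100 seeded runs, and every model ranks the strongest driver
first on a low-noise cohort.

## Pipeline, determinism, and what passing tests show

`run_pipeline()` chains the stages from one configuration (YAML or
`pipeline_config()`), writes per-group artifacts (ANOVA/Tukey tables,
correlation matrices, GraphML networks, hub reports, motor TSV, ego
GraphML, ML reports) plus a MANIFEST with an md5 checksum per file, and is
byte-identical under a fixed seed and config — reruns are verifiable by
checksum. Failures abort with the stage name and leave a partial MANIFEST
marked incomplete. `summary_report()` reads every number it prints back from
the bundle files.

Problem sizes used by the shipped checks, chosen to make each claim sharp:
marginal and correlation recovery at n = 10,000 (Monte-Carlo error ~1% of
an SD); exact motor edge-set recovery at n = 1,000 over 100 seeds;
permutation-null calibration at n = 6 per group over 50 replicates with 500
permutations; importance-ordering recovery at n = 500 over 100 seeds.

Two honesty notes. First, at the study's actual size (n = 6 per group) the
same planted structures are recovered far less reliably — the test-suite
measures this directly, and with 435 region pairs the null probability of a
spurious r > 0.6 at n = 6 (~0.1 per pair) implies dozens of spurious edges
and occasionally a spurious hub in a null cohort. Small-n correlation
networks are noisy instruments; the package quantifies this rather than
hiding it. Second, the generator reproduces the *statistical* structure the
analysis assumes — Gaussian-copula marginals and planted correlations — not
the biology: no MPTP mechanism, no spatial autocorrelation between adjacent
regions, no count over-dispersion, no litter or batch effects. Passing
recovery tests show the pipeline's inference machinery is correct, not that
real cohorts of six animals would support the same conclusions.

## Known limitations

* The PLS backend is one defensible reading of an underdocumented method;
  its derived network is labeled `pls_lv` and should not be conflated with
  the default Pearson edges.
* Correlation networks from n = 6 animals have wide sampling error on every
  edge; all edge-level conclusions at that size are fragile (see above).
* Behavior/TH columns are optional and never imputed; downstream stages
  skip or error explicitly when they are absent.
* The exported GEXF writer covers the static undirected subset of the
  format that the pipeline itself produces.
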