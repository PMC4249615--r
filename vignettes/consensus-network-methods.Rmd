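---
title: "Seed-anchored consensus MI networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-anchored consensus MI networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`aplnet` reconstructs a disease-specific transcriptional subnetwork from two
independent acute myeloid leukemia (AML) expression cohorts. The anchor of
the analysis is a *seed list* — for the motivating application, direct
transcriptional targets of the hypoxia-inducible factor HIF-1 — and the
disease of interest is acute promyelocytic leukemia (APL), the FAB M3
subtype. This vignette documents the statistical model behind each stage,
the tunable parameters and their defaults, the synthetic-data generator used
to validate the pipeline, and the numerical choices and limitations a user
should know about.

## Pipeline overview

```{r}
library(aplnet)

cfg <- generator_config(seed = 1)
sim <- generate_cohorts(cfg)
res <- run_consensus_pipeline(sim$cohort_a, sim$cohort_b,
                              sim$annotation, sim$seed_genes)
```

The stages, each available as a standalone function:

1. **Harmonization and normalization** (`intersect_and_normalize`): both
   cohorts are restricted to the probes measured on both platforms; each
   probe row is log2-transformed and mean-centered per cohort.
2. **Entropy filter** (`entropy_filter`): probes whose histogram entropy
   falls strictly below the 10th percentile of the entropy distribution are
   discarded as uninformative.
3. **Null calibration** (`calibrate_null`): a permutation null for the MI
   estimator, fitted with an exponential tail so that extreme significance
   thresholds can be applied by extrapolation.
4. **Network inference** (`infer_relevance_network`): adaptive-partitioning
   MI for every (seed probe, other probe) pair; edges kept when the
   calibrated p-value clears the per-cohort threshold.
5. **DPI pruning** (`apply_dpi`): the weakest edge of each triangle is
   removed as likely indirect (data-processing inequality).
6. **Consensus** (`consensus_edges`): only edges significant in both
   cohorts survive.
7. **Differential pruning** (`differential_expression`,
   `extract_apl_subnetwork`): nodes must be significant (BH-FDR `q < 0.05`)
   with concordant direction in both cohorts; connected components with at
   most 10 distinct genes are discarded.
8. **Profiling** (`subtype_coloring`, `promyelocyte_separation`,
   `atra_reversal`, `hub_table`, `detect_modules`) and **integration**
   (`select_upregulated_mirnas`, `anticorrelation_ranking`,
   `predicted_target_fraction`, `ora_enrichment`).

## Normalization order

Mean-centering before a log transform is undefined for the non-positive
values centering creates, so the only well-defined order — and the standard
microarray practice — is log2 first, then centering. Each normalized value
is therefore the log2 ratio of a probe's intensity to its geometric mean
across the cohort's samples. Missing values are a hard error: imputation
would silently distort both the entropy filter and the MI estimates.

## The mutual-information estimator

Dependence between transcripts is measured by mutual information (MI), in
nats, estimated by recursive adaptive partitioning of the rank-transformed
sample (average ranks for ties, so the estimator is invariant under
monotone transforms of either variable):

* a cell holding $n_c$ points is split at the midpoints of its rank bounds
  into four quadrants when $n_c \ge$ `min_split` (default 8) and the
  quadrant-count statistic $\sum_q (n_q - n_c/4)^2 / (n_c/4)$ exceeds the
  $\chi^2_3$ critical value at `alpha_split` (default 0.05);
* a leaf cell of rank-widths $(w_x, w_y)$ contributes
  $\frac{n_c}{n}\,\ln\!\frac{n_c/n}{(w_x/n)(w_y/n)}$;
* the estimate is the sum over leaves, floored at zero.

For bivariate Gaussian data with correlation $\rho$ the population MI is
$-\tfrac12\ln(1-\rho^2)$, which the test suite uses as the closed-form
reference at $\rho \in \{0, 0.5, 0.9\}$.

**Initialization.** The root cell is always split once; the chi-square rule
governs every deeper cell. This choice matters: after rank transformation
the quadrant counts have fixed margins (each half-plane holds exactly half
the ranks), which leaves the nominal-0.05 three-degree-of-freedom test far
below its level — under independence the root would split with probability
of roughly $5 \times 10^{-3}$, so almost every null MI would be exactly
zero and the permutation null would be too discrete to calibrate. The
forced initial split leaves estimates for dependent pairs unchanged (their
root split fires anyway) and gives the null a continuous right tail.

**Termination.** A cell whose points all share one rank location can never
be separated by midpoint splits (heavily tied data); such cells are leaves
regardless of the chi-square rule, and recursion depth is capped at 64.
With at most a few distinct values per variable the estimator then
coincides with the plug-in discrete MI on the induced categories, which the
suite checks against an independent table-based implementation.

## Edge significance

The null distribution of the estimator depends on sample size, so each
cohort gets its own calibration: `n_pairs` (default 1000, minimum 200)
random probe pairs are drawn, one member of each pair is permuted, and MI
is estimated for each. The log empirical survival function is fitted by
least squares over the top `tail_fraction` (default 10%) of the sample:

$$\ln \Pr(\mathrm{MI} > m) \approx a + b\,m, \qquad b < 0,$$

giving `mi_pvalue(calib, mi) = min(1, exp(a + b mi))` and its inverse
`mi_threshold(calib, p)`. The exponential-tail form deliberately supports
extrapolation far beyond permutation resolution: the full-cohort analyses
this package follows used thresholds of $10^{-15}$ and $10^{-10}$ on two
cohorts of roughly 290 and 200 samples over 22,215 shared probes, values no
feasible permutation count can reach directly. At the desk scale of the
synthetic study (about 2,300 probes, 130–150 samples, ~200 seed probes,
hence ~4×10⁵ tested pairs per cohort) the pipeline default is $10^{-5}$ per
cohort — the Bonferroni magnitude for that pair count; it is a parameter,
chosen once, and should be re-scaled the same way for other data sizes. A
degenerate fit ($b \ge 0$) raises an error advising more permutation
pairs rather than returning unusable thresholds.

## DPI pruning and consensus

For a dependence chain $X\!-\!Y\!-\!Z$ the data-processing inequality bounds
$\mathrm{MI}(X,Z) \le \min(\mathrm{MI}(X,Y), \mathrm{MI}(Y,Z))$, so within a
triangle the weakest edge is the indirect-edge candidate. `apply_dpi`
removes edge $(i,j)$ when
$\mathrm{mi}(i,j) < (1-\theta)\min(\mathrm{mi}(i,k), \mathrm{mi}(j,k))$ for
some common neighbor $k$, with all marks evaluated on the input graph and
applied simultaneously (the result is independent of edge order, a subgraph
of the input, and idempotent at $\theta = 0$). The tolerance default
$\theta = 0.1$ follows the convention of the information-theoretic network
tools this stage mirrors; the setting is recorded in the network metadata.

The consensus network keeps the unordered edges present in both cohort
networks, with both cohorts' MI and p-value attributes retained. Because a
false edge must replicate to survive, consensus precision is expected to be
at least each single-cohort precision — a property the acceptance suite
measures over 20 seeded replicates rather than assumes.

## Differential pruning, modules, hubs

Differential expression is the Welch (unequal-variance) two-sample t-test,
case subtype versus all other samples, with Benjamini–Hochberg FDR across
all tested probes. Subnetwork membership requires `q < alpha` (default
0.05) in **both** cohorts. Direction concordance is additionally required by
default (`concordant = TRUE`): dual significance alone permits a node that
is up in one cohort and down in the other, which has no single color on a
map of the subnetwork; the flag can be turned off to reproduce the laxer
reading. Connected components with at most `min_component_genes` (default
10) distinct genes — counted at gene level through the probe annotation,
not at probe level — are discarded as isolated circuits.

"Modules" are connected components throughout; community detection within
components is deliberately out of scope. Component labels are
deterministic: largest first, ties by smallest member id. The hub table
pairs each node's consensus degree with the *worst* (largest) of its two
raw cohort p-values — the view in which highly connected genes usually show
weak disease specificity, so jointly high-degree, strongly differential
genes stand out as exceptional.

## Subtype, separation and reversal profiling

`subtype_coloring` repeats the one-vs-rest contrast for every subtype
(M0–M5), restricted to subnetwork nodes, with BH correction *within that
node set* — the correction scope matches the displayed set rather than the
whole array. Subtypes with fewer than two samples yield an all-`ns` column
with a warning instead of an error, so one small group does not abort a
profile.

`promyelocyte_separation` addresses whether the signature separates
leukemic from normal promyelocytes: hierarchical clustering with
correlation distance ($1 - r$ between sample profiles over the signature)
and average linkage, cut at `k = 2`, plus a PCA embedding of the same
submatrix; agreement with known labels is summarized as the adjusted Rand
index (ARI), a quantitative stand-in for the visual segregation the
original comparison reported. Correlation distance makes the result
invariant to per-sample scaling but also blind to uniform profile shifts —
a signature whose disease effect is a constant offset across all its genes
would not separate; the planted signature has gene-specific directions, as
real ones do.

`atra_reversal` scores a differentiation-treatment time course (log2 fold
change versus the 0 h reference) by the fraction of subnetwork genes moving
against their disease direction at the final time point: down-regulated
genes with strictly positive fold change plus up-regulated genes with
strictly negative fold change, over all non-`ns` subnetwork genes present.
Strict inequalities mean the reference time point scores exactly zero.

## miRNA integration and enrichment

Candidate regulators are miRNAs up-regulated in the case subtype (Welch
t-test, Bonferroni-corrected over *all* tested miRNAs, adjusted p < 0.05,
positive mean difference). Each candidate is ranked by the number of
down-regulated subnetwork transcripts with Pearson $r$ strictly below
`r_threshold` (default −0.4, strict at the boundary), ties broken by miRNA
id. Correlation is computed at probe level and collapsed to genes (a gene
counts once if any of its probes passes) for the predicted-target fraction,
which consumes an externally produced (miRNA, gene) binding-site table; an
empty anti-correlated list yields `NA`, never 0. Sequence-based target
prediction itself is out of scope.

`ora_enrichment` is a generic hypergeometric over-representation test
(upper tail, $P(X \ge k)$, identical to the one-sided Fisher exact test)
against GMT gene-set collections. The default background is the genes that
survived preprocessing — the universe the query was actually drawn from —
not the whole genome; BH is the default correction. The test suite verifies
the p-values against both exhaustive enumeration and `fisher.test`.

## The synthetic-data generator

`generate_cohorts` draws two cohorts from one linear-Gaussian truth:

* **anchors** (the seed genes, default 100) are standard normal; the
  designated down-module anchors (default 3) share a latent factor giving
  them pairwise correlation `anchor_latent_cor` (default 0.6), which ties
  the down-module stars into one community, as disease modules centered on
  a few interacting hubs look in practice;
* **members** follow $g_m = \beta g_a + \varepsilon$,
  $\varepsilon \sim N(0, \sigma_{\text{gene}}^2)$ with $\beta = 1$,
  $\sigma_{\text{gene}} = 0.5$, so the planted gene-level correlation is
  $\rho = \beta / \sqrt{\beta^2 + \sigma_{\text{gene}}^2} \approx 0.894$
  and the planted MI has the Gaussian closed form — the generator's
  self-consistency check;
* **APL modules**: a small up-module (30 genes including its anchor) and a
  larger down-module (100 genes including 3 anchors) receive a mean shift
  of $\pm\Delta$ (default 1.5 log2 units) in M3 samples only — the
  asymmetric two-module architecture the disease subnetwork is expected to
  show, at an effect size typical of strong microarray signatures;
* **probes**: 1–3 probes per gene (deterministic multiplicity, so seeds
  change values but never dimensions), probe noise
  $\sigma_{\text{probe}} = 0.3$, raw intensities $2^{x+8}$; the cohorts
  share `shared_probe_fraction` (default 0.8) of the probe universe with
  every gene keeping at least one shared probe, emulating two array
  platforms with a common core;
* **uninformative probes** (default 300 genes): near-flat expression
  (sd 0.15) with sparse artifact spikes (rate 0.02, 3–6 log2 units).
  These exist because histogram entropy over a probe's own range is
  scale-free: in an all-Gaussian universe the bottom entropy decile would
  be arbitrary signal probes and the entropy filter would remove planted
  structure at random. Real arrays carry a large population of
  low-information probes whose occasional artifacts compress their
  histograms; planting that population lets the filter remove what it is
  designed to remove;
* **sample sizes**: 150 and 130 samples across M0–M5 with 20 and 19 M3
  samples — the two real cohorts' M3 counts at roughly half their total
  size, keeping the full pipeline a few seconds per run;
* **miRNAs** (`generate_mirnas`): each regulator tracks the standardized
  mean of its down-module targets with loading −0.8 plus an M3 up-shift of
  0.5 and unit-variance noise; decoys (default 30) are independent noise;
* **time courses** (`generate_timecourse`): module genes relax
  exponentially toward baseline,
  $\mathrm{FC}(t) = s(e^{-t/\tau} - 1)$ for planted shift $s$, default
  $\tau = 12$ h with 0.05 noise — the reversal dynamics expected under a
  differentiation-inducing drug.

Everything is bit-reproducible under (config, seed); changing only the seed
changes values but neither dimensions nor truth-structure sizes.

What the generator does **not** emulate: batch and scanner effects,
probe-sequence (GC, cross-hybridization) biases, intensity-dependent
variance, count-based RNA-Seq noise, copy-number confounding, and
non-linear regulation. Passing recovery tests on these cohorts therefore
demonstrates correctness of the algorithms under the stated model, not
robustness to every artifact of real arrays.

## Pipeline composition choices

`run_consensus_pipeline` applies harmonization, normalization and the
entropy filter before inference, but leaves the disease-differential
prefilter (`prefilter_transcripts`) **off by default**. That prefilter
reduces the probe universe to case-differential transcripts — appropriate
when only the disease subnetwork is of interest, and available via
`prefilter_alpha` — but it removes every probe of the broader seed-anchored
network, making network-level recovery evaluation meaningless. The two
cohort calibrations use consecutive RNG seeds derived from the pipeline's
`rng_seed`, and all thresholds and DPI settings are recorded in the network
metadata.

## Numerical and degenerate-input conventions

* Ranks use average ties with stable order, so all MI results are exactly
  reproducible and symmetric in their arguments.
* Entropy uses $\lceil\sqrt{n}\rceil$ equal-width bins over the probe's
  observed range, natural log; a constant probe has entropy 0. The
  percentile cut is strict (ties at the cutoff survive), and the realized
  cutoff is recorded so a second pass removes nothing.
* Welch statistics with zero pooled variance are defined as $t = 0$
  (identical groups are never "significant").
* Empty networks and empty subnetworks are warnings, not errors; degenerate
  calibration fits, empty probe intersections, non-positive intensities
  under a log transform, missing labels, and sub-minimal group sizes are
  errors that name the offending probe or sample where possible.
* Edge keys are canonical unordered pairs; all orderings (hub table,
  component labels, miRNA ranking) have explicit deterministic tie-breaks
  by id.

## Problem sizes used in the checks

The test and acceptance suites run the estimator checks at $n = 5000$
(closed-form accuracy) and $n = 1000$ (monotonicity, 50 replicates), the
calibration check on 1000 permuted and 1000 fresh independent pairs, DPI on
100 planted chains of length 3 at $n = 200$, the end-to-end recovery on the
default generator configuration above, and the replicate comparison of
consensus versus single-cohort precision on 20 scaled-down cohorts (20
anchors, ~470 probes, 75/68 samples, thresholds re-scaled to $10^{-4}$ and
`min_component_genes = 5` accordingly). Full-cohort sizes (tens of
thousands of probes, hundreds of samples) are outside what a unit-test
suite should run but inside what the implementation supports; the batch MI
kernel evaluates roughly $10^5$ pairs per second per core at $n = 150$.

## Known limitations

* Seed-restricted inference cannot produce modules centered on non-seed
  genes unless those genes connect to many seed probes; `all_pairs` mode
  exists for that purpose at quadratic cost.
* The exponential null tail is an approximation; p-values at extreme
  thresholds inherit its extrapolation error, which is why thresholds
  should be read as sparsity controls rather than literal error rates.
* BH-FDR decisions depend on the tested set, so filter compositions and
  restricted-set colorings are set-dependent by construction.
* The component-size rule counts genes, so annotation completeness directly
  affects which small components survive.
* ARI of a k-cut dendrogram is a coarse summary of separation; inspect the
  PCA scores for structure a 2-cut misses.
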