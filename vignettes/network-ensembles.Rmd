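---
title: "Cross-kingdom association-network ensembles over occurrence-filter grids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-kingdom association-network ensembles over occurrence-filter grids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Marker-gene surveys of soils deliver paired fungal (ITS) and bacterial (16S)
ASV count tables over the same samples. A recurring question is which fungi
and bacteria co-occur — and whether those associations shift with an
environmental condition such as seasonal snow cover. Two obstacles stand in
the way:

1. **A single inferred network cannot be compared statistically** with
   another single network: there is no replication.
2. **Network inference is sensitive to the rare-ASV filter** applied before
   it; any single occurrence threshold is arbitrary.

`fbnet` addresses both at once, following the multi-threshold design of
snow-cover studies in (sub-)alpine *Pinus cembra* forest soils: each
kingdom's table is filtered at several occurrence thresholds (ASVs kept when
detected in at least *t* samples), every combination of a fungal and a
bacterial threshold yields one filtered table pair, and one network per
condition (snow-free, snow covered) is inferred from each pair. The default
5 × 5 grid gives 25 paired networks per condition — replicates over the
filtering choice that support paired tests of network properties and a
consensus notion of *frequent* associations (present in more than five of a
condition's networks).

# The inference model

For one filtered pair and one condition the samples are transformed and a
sparse conditional-dependence graph is estimated:

1. **Joint CLR.** Counts of both kingdoms are concatenated per sample and
   centred-log-ratio transformed with a single mean over the combined
   feature vector, after a pseudocount of 1 and normalisation of each
   kingdom to relative abundances. The normalisation matters: fungal and
   bacterial libraries are sequenced to very different and independently
   varying depths, and without it the per-sample depth *ratio* becomes a
   shared component of every fungal–bacterial pair — a pure sequencing
   artifact that inflates cross-kingdom correlations. The raw-count variant
   (`normalize = FALSE`) and a per-kingdom-centred variant
   (`per_kingdom = TRUE`) are available for comparison.
2. **Neighborhood selection.** Each feature is regressed on all others with
   an L1 penalty (Meinshausen–Bühlmann); an edge exists when either
   direction's coefficient is nonzero (OR rule). The lasso path is computed
   by coordinate descent on the Gram matrix (compiled code, warm starts,
   active sets); a unit test verifies coefficient agreement with `glmnet`
   on the identical objective.
3. **StARS penalty selection.** The penalty is chosen by stability: graphs
   are refit on random subsamples, per-pair selection frequencies
   $\hat\theta$ give the instability $2\hat\theta(1-\hat\theta)$ averaged
   over all pairs, the curve is monotonised by a running supremum from the
   sparse end, and the smallest penalty keeping it below $\beta = 0.05$ is
   selected. Since no penalty below the first crossing can ever be
   selected, the path is evaluated on doubling prefixes with an early stop
   — an exact shortcut, not an approximation.
4. **Weighted refit.** At the selected penalty the directed coefficients
   are symmetrised (larger-magnitude member by default, mean optionally)
   and multiplied onto the refitted structure; the sign of the weight is
   the association's sign, and orphan nodes are removed. These weights are
   penalised estimators: they order and sign associations but are not
   correlation coefficients.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `t_fungal` | 5, 7, 9, 11, 19 | fungal occurrence thresholds (samples) |
| `t_bacterial` | 10, 20, 31, 39, 46 | bacterial occurrence thresholds |
| `n_lambda`, `lambda_min_ratio` | 20, 0.01 | log-spaced penalty path from $\lambda_{max}$ |
| `n_subsamples` | 20 | StARS subsamples |
| `subsample_ratio` | 0.8 | subsample size $b = \min(\lfloor 10\sqrt n\rfloor, \lfloor 0.8n\rfloor)$ |
| `beta_threshold` | 0.05 | StARS instability bound |
| `null_replicates` | 999 | random networks per inferred network |
| `min_networks` | 6 | frequency rule: "more than 5 of 25 networks" |
| `min_pair_support` | 2 | genus summaries need at least two ASV-level associations |

The classic StARS prescription $b = \lfloor 10\sqrt n\rfloor$ targets
studies with hundreds of samples; at the study sizes here (34–45 samples
per condition) it would exceed $n$, and subsampling at $n-1$ collapses the
instability estimate to zero, which always selects the densest graph. The
$0.8n$ cap is the convention of the stability-selection tooling this
follows for small $n$.

# Null models

Two uniform random-graph references are attached to every network, each
with 999 replicates by default:

* **edge-type null** — random networks with the same edge count drawn on
  the *full filtered dataset's* node set give reference distributions for
  the fungal–fungal, fungal–bacterial and bacterial–bacterial edge
  fractions;
* **shared-association null** — per replicate one random network per
  condition, counting edges shared by chance; the fb-restricted variant
  draws only fungal–bacterial pairs among each network's connected nodes,
  which has fewer candidate pairs and therefore yields stochastically
  *larger* shared counts.

Empirical p-values use the add-one rule $(1+k)/(1+R)$ in both directions,
so they are never zero. The paper-level comparison is distributional; the
p-values are a convenience.

# GLMs of sign and frequency

The odds of a positive association per network are modelled by a binomial
GLM (logit link, response = per-network positive/negative counts,
predictor = condition), fitted across all networks of the grid. Complete
separation is flagged and handled by a Haldane–Anscombe 0.5-count refit.
Fungal-phylum association frequency is modelled per filter pair by a
Poisson GLM with candidate terms phylum, condition and their interaction;
the final model is chosen by bidirectional stepwise AIC from the
main-effects model within the hierarchical scope (intercept-only up to the
full interaction). Phyla with zero fb edges in both conditions of a pair
are dropped beforehand (log-link degeneracy). Rate-ratio contrasts with
Wald intervals are available for any phylum.

# The synthetic generator

`simulate_communities()` emulates the study design the pipeline targets:
79 samples in three locations split snow-free/snow covered (13/12, 19/14,
13/8), per-sample depths of about 6,500 ± 2,320 fungal and 60,000 ± 16,000
bacterial reads (truncated below at 100 to avoid degenerate CLR samples),
and 150 fungal / 600 bacterial ASVs — a desk-scale rendition of the
reference dataset's 1,654 / 27,213 preserving the fungi ≪ bacteria
asymmetry.

Counts arise from a latent Gaussian copula: per sample a multivariate
normal over all ASVs (unit marginals; correlation ρ on planted edges
active in that sample's condition) is pushed through per-ASV log-normal
abundance profiles, masked by Bernoulli occupancy, and multinomially
sampled at the drawn depth. The copula was chosen over
Dirichlet-multinomial mixing because the downstream inference operates on
CLR-space dependence, so planted edges keep a controllable magnitude and
sign there.

Two calibration choices deserve emphasis, both anchored to the reference
dataset's published summaries rather than to any test outcome:

* **Occupancy** is Beta(0.3, 4): the median ASV is detected in ~2 of 79
  samples and roughly a tenth of bacterial ASVs survive an occurrence-10
  filter. This matches the prevalence structure implied by the study's
  core statistics (even *core* ASVs — those detected in every location —
  have median detection 8–9/79; cores are 5.6% of fungal and 11.9% of
  bacterial ASVs, mirrored here as 8/150 and 72/600 forced-core ASVs).
* **Planted endpoints** get occupancy 1 and a log-abundance floor of 1.5.
  Planted edges emulate the associations a real analysis could actually
  report as frequent — links among consistently detected, reasonably
  abundant taxa. An association planted on a rare endpoint is drowned by
  count noise and is not a meaningful recovery target; the generator flags
  any planted edge with fewer than four co-occurrences in an active
  condition as weakly identifiable.

What the generator deliberately does **not** emulate: phylogenetically
structured abundances, environmental gradients shared across many taxa,
within-kingdom planted structure, and read-level error. Passing recovery
tests therefore show that the pipeline finds strong, well-sampled planted
dependence against realistic sparsity and compositional noise — not that
every edge in a real soil network is trustworthy.

# What recovery tests can and cannot show

With the study's sample sizes (45 + 34), planted latent correlations of
0.7 appear in CLR space at about 0.62 ± 0.10 after compositional
attenuation and sampling noise. Recall of planted edges by the
frequent-association consensus is essentially complete, sign accuracy is
perfect, and condition-specific planted edges land in their own partition
in >90% of runs. Precision against the planted truth, however, plateaus
around 0.15–0.3: at $n = 34$ the sample-correlation noise over thousands
of candidate cross-kingdom pairs puts dozens of null pairs above any
threshold that still catches the planted edges, and because all 25 grid
networks reuse the same samples, those null pairs recur across the grid —
a handful even in all 25 networks. The filter grid replicates the
*filtering* choice, not the *sampling*: consensus over it cannot average
away dataset-level noise. This is a property of single-dataset network
consensus at these sample sizes, not of the implementation; it is worth
keeping in mind when interpreting frequent associations from comparable
real datasets.

# Numerical choices and degenerate inputs

* Lasso coordinate descent converges on a coefficient-change tolerance of
  1e-5 with active-set/KKT sweeps; columns with zero variance are left
  unstandardised and attract no coefficients.
* $\lambda_{max}$ is the largest absolute off-diagonal entry of the
  standardised Gram matrix; the path is 20 log-spaced values down to
  0.01 $\lambda_{max}$.
* When even the sparsest graph exceeds the instability bound,
  $\lambda_{max}$ is selected with a warning; on an always-empty graph the
  instability is identically zero and the densest (smallest) penalty is
  returned, which is inconsequential since every penalty gives the same
  empty graph.
* Zero-depth samples are an error where proportions are needed; zero-count
  ASV columns are dropped with a warning on load; ASVs absent from a
  condition's samples are dropped from that condition's network input with
  a message.
* "Longest path" is reported as the unweighted diameter of the largest
  connected component (a true longest simple path is NP-hard and is not
  what standard graph libraries compute); the properties table labels it
  accordingly.
* The paired condition comparison is a Wilcoxon signed-rank test on the
  per-filter-pair differences (the paired analogue of a rank test;
  matching the reported `p_Wilcox` convention), with a pooled
  Kruskal–Wallis variant behind a flag. Fewer than three nonzero paired
  differences are an error, not a p-value.
* Dunn's post-hoc z-tests (tie-corrected, Holm-adjusted) run only when the
  omnibus Kruskal–Wallis test is significant; they are implemented in the
  package because no installed package provides them.
* PERMANOVA is delegated to `vegan::adonis2`, one factor at a time, with
  free permutations; a zero total sum of squares returns $R^2 = 0$, $p=1$.
* All randomness flows from one master seed through a string-hashed
  per-purpose derivation (`derive_seed`), so every stage is a pure
  function of inputs, configuration and seed, and grid runs are
  reproducible bit for bit.

# Problem sizes used in the test-suite

Routine unit tests run a reduced design (40 samples, 40 + 80 ASVs, 2 × 2
grids, 8–10 StARS subsamples) chosen to exercise every code path in
seconds. The end-to-end checks run the full default design: one complete
25-pair grid per seed (about 3 s each after compilation), 20 seeds for the
specificity check, 999-replicate null calibrations, and 50-seed GLM
recovery simulations.

# Known limitations

* Association weights are penalised regression coefficients; their
  magnitudes are not comparable across networks with different penalties.
* The consensus counts an association once per network regardless of
  weight; a strict sign-agreement mode exists for shared-edge counting.
* No degree-preserving rewiring nulls (the reference design uses uniform
  edge sampling), no latent-variable or glasso variants, no bootstrap
  intervals on weights, no mixed-effects or negative-binomial GLM
  extensions.
* Taxonomy handling assumes ASV ids are stable across conditions and
  filters (one denoising run); there is no sequence-level matching.
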