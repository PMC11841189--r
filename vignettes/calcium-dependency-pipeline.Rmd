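---
title: "Classifying calcium-dependent H2O2-responsive genes and extracting their regulatory paths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying calcium-dependent H2O2-responsive genes and extracting their regulatory paths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caldep)
```

## The problem

Hydrogen peroxide (H2O2) acts as a second messenger that reprograms plant
transcription under stress, and it also triggers transient elevations of
cytosolic free calcium. Blocking the calcium transient pharmacologically
(with the plasma-membrane channel blocker LaCl3) while applying H2O2 lets
one ask, gene by gene, whether the transcriptional response *requires* the
calcium signal, is merely *modulated* by it, or is *independent* of it.
`caldep` implements that comparative inference as a reusable pipeline over
three differential-expression contrasts per tissue:

* H2O2 vs. water control,
* H2O2 + LaCl3 vs. control (the "combined" treatment), and
* LaCl3 alone vs. control.

## The dependency classifier

A gene is a DEG in a contrast when `fdr < 0.01` **and** `|log2FC| >= 0.5`;
everything else is "unchanged" (UC). The FDR gate is strict and the
magnitude gate inclusive, matching the conventional reading of the
thresholds. Three decisions then classify each H2O2-DEG:

1. **LaCl3 exclusion.** Combined-treatment DEGs that are also LaCl3-alone
   DEGs are channel-blocker artifacts rather than calcium-signalling
   readouts; they are removed before classification. The default mode
   (`identity`) removes any overlap, which mirrors Venn-style exclusion of
   shared DEGs; a `same_direction` mode removing only same-sign overlaps is
   exposed because the looser prose reading ("similar differential
   expression") admits it.
2. **Strict dependency.** An H2O2-DEG whose combined status is UC lost its
   response entirely without the calcium transient. Note that combined
   UC is the complement of the full two-part DEG gate: a gene significant
   at FDR but with `|log2FC|` just below 0.5 counts as UC (and hence
   strict). The alternative reading is not implementable without a second,
   unstated threshold, so the complement rule is used and flagged here.
3. **Delta log2FC.** A gene that responds in both contrasts is
   calcium-modulated when `|lfc_h2o2 - lfc_combined| >= 1`, i.e. a twofold
   change in fold change. The unsigned form is applied to both up- and
   down-regulated genes. Same sign with reduced magnitude is
   `PARTIAL_ADDITIVE`, same sign with increased magnitude is `ENHANCED`,
   and a sign flip is `ANTAGONISTIC`. Equal magnitudes with the same sign
   cannot co-occur with a delta of 1 or more (equal values give delta 0),
   and the code asserts that branch unreachable. Everything else is
   `INDEPENDENT`.

Genes that are DEGs under the combined treatment but UC under H2O2 alone
are outside the classification domain (only previously H2O2-responsive
genes are classified); `classify_genes()` reports them in the
`combined_only` attribute instead of forcing a class.

```{r classify-example}
sim <- simulate_de_tables(sim_params(n_genes = 500, seed = 1))
cl <- classify_genes(sim$tables$h2o2, sim$tables$combined, sim$tables$lacl3)
tabulate_classes(cl)$per_class
```

`tabulate_classes()` reports exact sums only: the dependent total is always
strict + partial/additive + enhanced + antagonistic, and the dependent
fraction divides by all H2O2-DEGs considered. Published per-tissue counts
of this kind are internally inconsistent at the margin (a dependent total
quoted once as the sum of its parts and once as one less); this package
never adjusts counts to match a quoted total.

## Clustering response profiles

Dependent genes are clustered on the unscaled pair
`(lfc_h2o2, lfc_combined)`. Two raw log2FC coordinates per gene are what
per-cluster mean bar summaries display, so clustering is done in that space
by default; z-scaling would distort the strict/partial boundary and is left
to the caller. `kmeans_fit()` uses k-means++ initialisation with 25
restarts and Lloyd iterations (via the base k-means engine), with empty
clusters repaired by reseeding at the farthest point.

The number of clusters comes from the gap statistic
(`Gap(k) = E*[log W_k] - log W_k`) with `B = 100` uniform reference
datasets drawn over each feature's observed range, squared-distance
dispersion, simulation error `s_k = sd * sqrt(1 + 1/B)`, and the
one-standard-error selection rule (smallest k with
`Gap(k) >= Gap(k+1) - s_{k+1}`, argmax fallback). Only "the gap statistic
method" is fixed by convention; the canonical uniform reference and
one-SE rule are adopted and stated here. The default seed of 123 echoes
common practice of seeding before the gap computation. With `B = 1` the
simulation SE is undefined; it is reported as 0 with a flag rather than
NA so downstream tables stay numeric, and `k_max = 1` short-circuits to a
degenerate single-point curve.

On elongated, adjacent planted patterns the one-SE rule is deliberately
conservative and may merge neighbouring down-regulated patterns; the
recovery guarantees below therefore use five well-separated planted
patterns.

## Constrained regulatory paths

The knowledge network is a ranked, typed, mixed-direction multigraph
(edge types `TF_REGULATION`, `PTM`, `BINDING`, `OTHER`; reliability ranks
0-2 retained by default). Sources are selected by hierarchical annotation
terms with dot-boundary prefix matching ("30.3" matches "30.3.1" but not
"30.31"), the calcium-signalling bins being "30.3", "34.21" and "34.22"
(redox bins "21.1", "21.2", "21.4", "21.5" work identically for the
independent-gene variant). A valid path from a source to a target gene:

* has at most 3 edges and visits no node twice,
* contains exactly **one** transcription-regulation edge, which is the
  **final** edge (the two predicates are enforced jointly: either alone
  admits paths the constraint excludes),
* traverses directed edges (TF and PTM, actor to substrate) forwards only;
  binding edges are undirected and usable either way,
* and survives the closest-source reduction: per target, only paths of the
  minimal realised length are retained. This also makes per-pair and
  joint-source-set searches equivalent, so no separate mode is needed.

Sources may appear as intermediates of other targets' paths, and targets
may appear in other targets' paths; a node that is both source and target
cannot self-regulate in one step because self-loops are rejected on read.
Duplicate edge records produce indistinguishable paths and are collapsed
to one representative per signature. `merge_paths()` unions the retained
paths, tags roles, and scores hubs by the number of distinct targets and
path occurrences; `extract_hub_subnetwork()` restricts the merged network
to one hub's paths. Exports (SIF + GraphML) are sorted and byte-stable.

Ortholog mapping (`map_orthologs()`) keeps hits with E-value at most
1e-30 and picks the minimum E-value, breaking ties by bitscore and then
lexicographically, so the mapping is deterministic; unmapped queries stay
`NA` and are simply absent from the target set.

## qPCR validation and traces

`delta_delta_ct()` implements relative quantification with efficiency 2:
per replicate, the target Ct is normalised against the **arithmetic mean**
of the reference-gene Ct values (two references by default). Averaging at
the Ct scale equals the geometric mean of the linear quantities, and under
condition-invariant references it is algebraically identical to single-
reference normalisation (tested numerically); whether the original
normalisation averaged at Ct or linear scale is unstated, and the two
coincide under equal efficiencies. `concordance()` is ordinary least
squares plus Pearson correlation. `delta_peak()` subtracts the mean of the
10 s of baseline immediately before the injection from the post-injection
maximum; luminescence-to-concentration calibration is out of scope, so it
operates on calibrated traces only.

## What the synthetic generators emulate

The generators plant a known truth so every stage is testable by recovery:

* **Design:** 4 conditions (control, H2O2, LaCl3, H2O2 + LaCl3), 3
  biological replicates, negative-binomial counts with a log-normal
  baseline (`log mean = log 200`, `log sd = 1`) and one shared dispersion
  (0.05; variance `mu + 0.05 mu^2`).
* **Classes:** default proportions 30% null, 15% independent, 20% strict,
  15% partial, 5% enhanced-down, 10% antagonistic and 5% LaCl3 artifacts
  (whose effect is planted identically in the LaCl3-alone and combined
  contrasts, so the exclusion filter must remove them). Planted magnitudes
  are drawn so classes stay at least one delta-cutoff apart: partial and
  enhanced genes get planted deltas of 1.7-2.1, which is more than three
  delta standard errors above the cutoff at the default contrast noise.
* **DE noise:** observed log2FC = planted + `Normal(0, 0.15)`; the 0.15
  default is small against the 0.5 DEG gate so acceptance runs are
  well-separated, and it is a plain parameter for harder settings.
* **Networks:** planted valid paths of length 1-3 plus constraint-violating
  near-paths (two TF edges, non-terminal TF, length-4 routes, rank-3
  parallels) and background decoys. Decoys attach only through reserved
  nodes, so after rank filtering they can never form an additional valid
  source-to-target path: planted paths are provably the complete
  extraction result at any decoy density. Oracle-equivalence testing
  therefore uses a separate, fully unconstrained random-graph generator.
* **Ct tables:** Ct = base - planted lfc (+ Gaussian noise), two constant
  reference genes, so the noiseless 2^-ddCt ratio equals `2^lfc` exactly.

What they do **not** emulate: library-size or batch effects, per-gene
dispersion trends, read-level artefacts, correlated genes, annotation
errors, or the realistic topology of curated interaction networks. Passing
recovery tests shows the inference machinery is correct under its stated
model, not that real tissue data meet that model.

## Numerical and scale choices

Tests and the acceptance script use sizes chosen to exercise each claim
while staying desk-sized: 2,000 genes x 10 seeds for classifier recovery
(plus a noiseless run that must be exact), 20,000 genes for the full-null
FDR check, 200 random graphs of at most 12 nodes against the brute-force
path enumerator, 20 seeds x `B = 100` for each gap-statistic scenario, and
20 planted networks for hub recovery. The surrogate count-based DE test
(median-of-ratios size factors, Welch t on log counts, 0.5 pseudo-count in
the fold change) is intentionally minimal: it exists so that end-to-end
synthetic runs can start from counts, it is underpowered at three
replicates, and it is not a recommended analysis for real data, for which
dedicated count-model packages should produce the input tables.

## Known limitations

* The classifier consumes per-contrast summary statistics; it inherits
  whatever shrinkage or filtering produced them.
* The dependency taxonomy is threshold-based; genes near the
  `delta = 1` boundary flip classes under resampling (the planted
  separations in the generator avoid that region by design).
* Hub scores count retained paths only; they are not centrality measures
  on the full knowledge network.
* The 2^-ddCt method assumes amplification efficiency 2 for all assays;
  no efficiency correction is implemented.
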