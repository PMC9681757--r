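---
title: "Beta-series brain networks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta-series brain networks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betanet)
```

## The analysis

betanet implements a whole-brain network analysis of task fMRI that starts
from *beta series*: for each region of interest (ROI), the sequence of
trial-wise activation estimates produced by a trial-level GLM. Correlating two
regions' beta series across trials measures their task-state functional
connectivity. The pipeline then treats the brain as a graph and asks two
questions: how is the network organized globally (integration, segregation,
modularity), and what role does a designated *target node* — in the motivating
application, the left ventral occipito-temporal cortex, a high-level visual
region engaged during spoken-language processing — play as an interface
between regions and sub-networks, and how does that role change across task
conditions?

The stages, in order:

1. **Construction.** For every participant and condition, the Fisher-z
   transformed Spearman correlation of the beta series between each pair of
   ROIs gives a weighted, undirected connectivity matrix
   (`beta_correlation()`). Spearman is used because only the monotone
   relationship between trial-wise responses is trusted; the Fisher transform
   variance-stabilizes the coefficients. Rank correlations of magnitude 1 are
   clipped to `1 - 1e-12` so the transform stays finite.
2. **Thresholding.** Each weighted matrix is binarized at a proportional
   density d% by keeping the `round(d/100 * n(n-1)/2)` strongest edges
   (`proportional_threshold()`). The analysis density range is selected from
   largest-connected-component behavior (`select_density_range()`): the lower
   bound is the sparsest density at which 90% of all networks are fully
   connected, the upper bound the sparsest at which all of them are. Nodal
   results are reported at the lower bound, where noisy connections are
   fewest; a cross-density sweep with FDR correction (`fdr_correct()`)
   confirms that conclusions do not hinge on one density.
3. **Graph measures** (`nodal_metrics()`), all on the binary graphs:
   global efficiency (mean inverse shortest-path length; integration), mean
   clustering coefficient (segregation), and three nodal interface measures —
   flow coefficient (fraction of a node's neighbor pairs connected only
   through it: "local bridge"), betweenness centrality (share of shortest
   paths through the node: "global bridge"), and participation coefficient
   (evenness of a node's edges across communities: "connector").
4. **Communities.** Louvain modularity optimization (resolution γ = 1) is run
   1000 times per network with randomized node order; the runs are reduced to
   a single partition by consensus partitioning (`network_consensus()`):
   entries of the co-assignment (agreement) matrix below τ = 0.5 are zeroed
   and Louvain is re-run on the thresholded agreement graph until all runs
   agree. Participation coefficients use each participant's own consensus
   partition; the per-participant partitions are consensus-partitioned again
   into one representative partition per condition
   (`group_representative()`), which is labeled against a reference
   parcellation by maximal Jaccard overlap (`label_subnetworks()`) and used
   to report which sub-network the target node joins in each condition.
5. **Hubs and roles.** Nodal values are averaged across participants and
   ranked; nodes in the top 5% (rank ≤ `floor(0.05 n)`, i.e. 13 of 263) are
   hubs (`identify_hubs()`). The target node's roles follow its hub flags:
   flow hub → local bridge, betweenness hub → global bridge, participation
   hub → connector (`classify_roles()`). Node-vs-node paired sign-flip
   permutation tests (`target_vs_nodes_permutation()`) compare every other
   node against the target, uncorrected and one-sided, mirroring how such
   rank plots are annotated.
6. **Statistics.** Condition effects are tested with permutation tests that
   respect the repeated-measures design: the omnibus statistic is the
   between-condition sum of squares of condition means after
   within-participant centering, with the null built by permuting condition
   labels independently within each participant (`rm_permutation_test()`);
   post-hoc pairs use sign-flip permutation of within-participant differences
   (`pairwise_permutation()`), exhaustively enumerated when `2^n` fits the
   permutation budget. p-values use the add-one convention and never report
   zero. The published analysis used an asymptotic general-independence test;
   we substitute the exact/Monte-Carlo permutation analogue of the same null
   deliberately — it tests the same exchangeability with no asymptotic
   machinery. Brain-behavior coupling is the Pearson correlation between the
   target's participation coefficient and reaction time per condition
   (`behavior_correlation()`).

## The synthetic cohort generator

Real trial-wise fMRI betas for such a study are rarely public, so the
generator (`ground_truth()`, `sample_cohort()`) plants exactly the structure
the analysis is meant to detect, making every stage testable by recovery:

* **Modular block correlation.** 263 nodes in four modules (66/66/66/65 by
  default, labeled after the four large-scale networks such an analysis
  typically finds: visual, fronto-parietal, default-mode,
  sensorimotor-auditory), with beta-series correlation `rho_in = 0.4` within
  and `rho_out = 0.05` between modules. These defaults were chosen once as a
  realistic contrast for task-state connectivity — strong enough that 80
  trials support recovery, weak enough that thresholded graphs retain
  sampling noise.
* **A target node with a condition-dependent layout.** Per condition, the
  target's row follows a role profile: a budget of strong (rho_in-level)
  entries equal to its module size minus one, distributed over modules in the
  profile's proportions. The defaults plant the story the pipeline should
  find: member of the fronto-parietal module at baseline, connector anchored
  in the visual module during perception, connector anchored in the
  sensorimotor-auditory module in quiet comprehension, concentrated in the
  visual module (participation reduced) in noisy comprehension.
* **Behavior.** Reaction times are drawn with a planted Pearson correlation
  (default −0.47 in the noisy-comprehension condition, 0 elsewhere) against
  the target's realized participation coefficient, computed with the planted
  partition at the primary density; means (1296/1413/2389/2575 ms) and
  accuracies (96/92/88/63%) follow the emulated behavioral profile, with a
  free SD of 200 ms.
* **Trials and cohort.** 80 trials per condition, 24 participants,
  zero-mean Gaussian beta series. The mean level is irrelevant by design:
  the pipeline only uses rank correlations across trials, so simulating
  activation amplitudes, HRFs, or noise spectra would add realism the
  analysis cannot see.

### What the generator does and does not emulate

Passing recovery tests shows the pipeline detects planted modular structure,
interface roles, and behavioral coupling at realistic sample sizes. It does
*not* show robustness to properties of real data the generator omits: no
hemodynamic model, no motion or physiological confounds, no inter-individual
anatomical variability, no Go/NoGo trial-type structure (only the trial count
matters downstream), and Gaussian rather than heavy-tailed betas.

Two structural facts about the block model are worth knowing:

* **The override row needs a PSD repair.** A row correlated at `rho_in` with
  nodes of several mutually weakly-correlated modules is jointly
  inconsistent, so the raw block matrix with a connector override is
  indefinite. `build_block_correlation()` repairs it by clipping negative
  eigenvalues at zero and re-normalizing the diagonal — the simplest repair
  that preserves the structure. The repair attenuates the target row (strong
  entries land near 0.23 rather than 0.40 against a 0.06 background) while
  moving other entries by at most ~0.01; the planted contrast, and hence
  recovery, is unaffected. The plain block matrix without an override is
  positive semidefinite and is returned untouched.
* **A planted connector is never a connector-only hub.** In a strongly
  modular graph, a node whose strong edges span modules necessarily also has
  a high flow coefficient (its neighbors are mutually unconnected) and high
  betweenness (it supplies the short inter-module paths). The generator can
  therefore plant "connector among its roles", not "connector and nothing
  else" — which matches how such interface regions present empirically.
  Similarly, the concentrated noisy-comprehension profile lowers the target's
  participation enough for the condition contrast and post-hoc tests to
  detect, but its group-level rank may remain high: with 30% of its strong
  edges still leaving its module it out-participates ordinary nodes. Planted
  effect magnitudes are free parameters, not calibrated to any particular
  dataset.

## Numerical and procedural choices

* **Edge ranking.** "Strongest" edges are ranked by signed Fisher-z weight
  (most positive first), the common practice for correlation networks; set
  `absolute = TRUE` in `proportional_threshold()` to rank by magnitude. Ties
  are broken by lexicographic (row, column) order so thresholding is
  deterministic; edge counts round half up.
* **Degenerate degrees.** Clustering and flow coefficients are 0 for nodes of
  degree < 2, participation is 0 for isolated nodes: conventions chosen so
  hub rankings stay well-defined.
* **Betweenness convention.** Unordered pairs, each counted once; rankings
  are invariant to the ×2 convention, and an optional normalization by
  `(n-1)(n-2)/2` is provided.
* **Hub cutoff.** `floor(0.05 n)` (13.15 → 13 at n = 263). Ties straddling
  the cutoff are flagged with a warning, never silently resolved.
* **Seeds.** All randomness flows from one seed; stages draw from streams
  salted with the stage name and index, so adding a stage never perturbs
  another stage's draws. The 1000 Louvain runs use seeds
  `seed + 0 … seed + 999`.
* **Consensus convergence.** The iteration cap defaults to 50 (the
  literature's procedure states no cap); an all-zero thresholded agreement
  matrix returns the all-singleton partition with a warning, and
  non-convergence fails loudly with the residual agreement level.
* **Community ids** are contiguous integers starting at 1 (R convention),
  relabeled by first appearance so partitions compare with `identical()`.
* **NMI** is computed from the community contingency table with explicit
  degenerate conventions: identical partitions give 1 (including two
  single-community partitions), and a single-community partition against
  anything else gives 0.
* **Sub-network labeling** is automated (maximal Jaccard against the
  reference, ties by overlap count then label order) where a human would
  inspect visually; the full overlap table is emitted for review.

## Problem sizes used in the validation suite

The test suite validates metrics against brute-force path-enumeration oracles
on 200 random graphs of ≤ 7 nodes, runs the planted-structure recovery
experiments at the full design size (263 nodes, 24 participants, 80 trials)
over 20 seeds with Louvain runs reduced to 100 — community-count recovery on
the baseline condition, connector recovery in the perception condition, since
the planted modular structure is identical across conditions up to the target
node's row — and calibrates the omnibus test's type-I error over 1000 null
cohorts at 199 permutations each. These sizes are the package's chosen
compromise between statistical resolution and a suite that runs in minutes.

## Limitations

* All downstream measures are on binary undirected graphs; no weighted or
  directed variants, no other centralities, no overlapping or hierarchical
  communities, no γ sweeps.
* The density-selection rule requires some candidate density to fully connect
  the ensemble; very sparse or fragmented data fail with the per-density
  connectivity table rather than proceeding on fragments.
* Whether negative correlations should be excluded before ranking edges is
  genuinely open in the field; the signed default is explicit and switchable.
* The generator's block model cannot produce a connector-only hub, and its
  planted magnitudes are not calibrated to any empirical dataset (see above).
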