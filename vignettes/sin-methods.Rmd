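---
title: "Quantifying social behaviour in fly groups with interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying social behaviour in fly groups with interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flysin)
```

## The problem

Groups of walking *Drosophila* in a flat circular arena interact through
brief pairwise proximity episodes. `flysin` turns per-frame tracker output
(one centroid per fly per frame) into a **social interaction network
(SIN)**: an undirected weighted graph with one node per fly and one edge
per interacting pair, and then measures that network at three scales —
per fly (local), per community (middle) and per network (global) — so
that populations recorded under different conditions (for example
untreated versus drug-fed groups) can be compared statistically.

## The interaction criterion

Two flies interact while their centroids stay within **two body lengths**
of each other, with a body length of 2 mm, i.e. a metric threshold of
4 mm; an episode counts only if it lasts at least **0.5 s** (12 frames at
24 fps). Each pair's episodes are collapsed onto a single edge carrying
two weights: the number of episodes (`w_count`) and their summed duration
in seconds (`w_duration`).

Decisions where the criterion under-determines an implementation:

* *Distance reference.* Centroid-to-centroid distance; centroids are what
  trackers report, and the choice is reproducible.
* *"At least" versus "longer than" 0.5 s.* The duration test is inclusive
  (`>=`), so exactly 12 frames at 24 fps qualify. Configurable via
  `interaction_criteria(min_duration_s =)`.
* *Per-episode, not cumulative.* The 0.5 s minimum applies to each
  continuous episode, matching the notion of "an interaction".
* *Missing detections.* Frames where either fly is missing break an
  episode; nothing is imputed by default. An optional linear
  interpolation for gaps of at most 3 frames (`interpolate_gaps()`) is
  provided but off by default.
* *Boundary jitter.* Real tracking jitters across the 4 mm line.
  `gap_tolerance_frames` (default 0) optionally bridges brief
  above-threshold excursions; missing frames are never bridged.
* *Per-fly body size.* When the input carries a `body_length` column the
  threshold for a pair uses the mean of the two flies' body lengths.

## Network measures

**Local (per fly).** Degree centrality $k_i/(N-1)$; node strength (sum of
incident `w_count` or `w_duration`); closeness $(N-1)/\sum_j d_{ij}$;
betweenness (fraction of shortest paths through the fly, normalised by
$(N-1)(N-2)/2$); eigenvector centrality (principal adjacency eigenvector);
information centrality (current-flow closeness,
$1/\sum_j r_{ij}$ over effective resistances from the Laplacian
pseudoinverse — the convention of the NetworkX function of the same
name); and the local clustering coefficient, with count- and
duration-weighted variants using geometric-mean triangle intensities.

**Global (per network).** Node and link counts, average degree, average
strengths, density $2K/N(N-1)$, average shortest path length, diameter,
global efficiency, average clustering, transitivity, degree heterogeneity
(population SD of degrees over mean degree) and degree assortativity.

**Middle (communities).** Louvain partitions (duration-weighted by
default), modularity $Q = \sum_i (e_{ii} - a_i^2)$, connected components,
and the community-size summary (singleton communities correspond to
isolated, non-interacting flies).

Numerical conventions:

* *Disconnected networks.* All distance-type measures (closeness,
  betweenness, eigenvector, information centrality, path length,
  diameter, efficiency) are computed on the **largest connected
  component**, with the component size as the normalising $N$; nodes
  outside it score 0 in per-node tables. Degree, strength and clustering
  are defined on the full roster.
* *Undefined values* (diameter of an edgeless network, assortativity of a
  regular network) are returned as `NA`, never as 0, so that population
  averages are not silently biased.
* *Eigenvector centrality* is computed by power iteration on $A + I$ (the
  shift makes the Perron eigenvalue strictly dominant even on bipartite
  components), tolerance $10^{-10}$, at most 1000 iterations, returned
  with unit Euclidean norm.
* *Weighted shortest paths* use edge length $1/w$: a stronger social tie
  is a shorter distance. Unweighted variants are the default, weighted
  ones are opt-in.
* *Louvain* is order-dependent, so the partition seed (default 0) and
  resolution (default 1) are explicit arguments and are recorded in the
  returned partition.
* *Percentage of singleton communities* uses the number of communities as
  its denominator by default; `pct_single_denominator = "nodes"` switches
  to the roster size.

## Comparing populations

`compare_measures()` runs one Welch-corrected independent-samples t-test
per measure (the appropriate default when group sizes differ), with the
**network as the unit of analysis**: at the local level each network is
first reduced to its per-node median (mean optional) of each measure.
Significance is $p < 0.05$ per measure with no multiple-testing
correction by default, mirroring common practice for these panels; a
Benjamini–Hochberg option exists. `measure_correlations()` pools per-fly
rows across networks for a Pearson matrix of the local measures, and
`occupancy_heatmap()` bins fly-frames over the arena disc.

## The synthetic arena

`simulate_arena()` provides trajectories with known ground truth so the
entire pipeline is testable without video. It emulates the standard
recording design — 30 flies, 120 mm circular arena, 24 fps, 10 minutes —
with a correlated random walk per fly plus the behavioural ingredients
that shape real recordings:

* **Intermittent locomotion.** Flies alternate walking and standing bouts
  (two-state Markov kinetics; mean bout 2 s, walking fraction `activity`,
  default 0.25). Continuous walkers would meet each other essentially
  constantly in a 60 mm-radius disc, producing contact statistics orders
  of magnitude above anything a tracker reports; intermittency is what
  makes realistic sparse networks reachable.
* **Thigmotaxis.** A constant outward heading bias concentrates flies
  near the wall, as in real arenas.
* **Social spacing and engagement.** A walking fly with a neighbour
  within its personal space (5 mm) either stops to interact — with a
  per-frame probability scaled by `pause_prob`, closing in to body
  contact (~2.5 mm) — or turns away and disengages. A standing fly with a
  close neighbour is aroused to walk off after a short dwell unless
  `pause_prob` holds it longer. Interactions therefore end behaviourally,
  not kinematically, which is what keeps episodes in the observed
  ~1–3 s range.
* **Attraction.** A bounded heading bias (not a force) towards perceived
  neighbours within 8 mm; bounded so speeds stay stationary.
* **Immobile flies.** A fraction of flies that never move, emulating
  inactive, largely isolated individuals.

`preset("ctrl_like")` and `preset("coc_like")` encode an
untreated-versus-psychostimulant contrast: the coc-like population has
stronger attraction, a higher social-dwell probability, more immobile
flies and higher activity (drug-induced locomotion). The ctrl-like
parameters were calibrated so that one simulated group lands near the
published control-group global summary (density ≈ 0.10–0.12, mean
duration strength ≈ 8 s, 40–60 edges among 30 flies); the coc-like
parameters then follow the documented directions. With these settings
the simulated populations reproduce the qualitative contrast pattern:
higher density, much higher duration strength, shorter average paths,
lower modularity and more singleton communities in the coc-like group.

What the simulator does **not** emulate: body orientation and
touch-modality of interactions, courtship/aggression structure,
identity-swap artefacts, and the long-time drift of real groups. Passing
pipeline tests on simulated data therefore validates the measurement
machinery and the direction of population contrasts, not any biological
claim about real flies.

## Problem sizes used in the test-suite

The oracle-equivalence suites run every measure against brute-force
implementations (Floyd–Warshall distances, explicit path counting,
direct triangle counting, grounded-Laplacian resistances, a frame-scan
event detector) on all canonical fixtures, 200 random graphs of up to 8
nodes, and 100 random 5-fly trajectories of 200 frames under 6 criteria
settings. The population-contrast check simulates 5 independent
replications of a full 9-versus-11-group experiment at full scale
(30 flies, 600 s); the null-calibration check uses 200 replicate
experiments of reduced size (8 flies, 45 s, 4 networks per arm), which
keeps the t-test's unit of analysis intact while staying cheap.

## Known limitations

* Interaction typing (head-to-head, head-to-tail, head-to-body) is out of
  scope; edges are orientation-blind by design.
* The simulator's contact process is phenomenological; its parameters are
  calibrated to first-order network statistics, not fitted to
  trajectories.
* Louvain is a greedy heuristic: partitions (and hence modularity and
  community counts) are seed-dependent on ambiguous graphs; the seed is
  fixed and recorded for reproducibility.
* Dynamic (time-sliced) networks are not modelled; each recording yields
  one static SIN.
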