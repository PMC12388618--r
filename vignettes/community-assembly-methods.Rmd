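---
title: "Inferring assembly processes and network stability of AM fungal communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring assembly processes and network stability of AM fungal communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amfassembly)
```

`amfassembly` implements a complete inference chain for community ecology of
arbuscular mycorrhizal (AM) fungi surveyed along a soil-salinity gradient:
habitat generalist/specialist classification, null-model partitioning of
community assembly processes, the Sloan neutral community model, and
salinity-stratified co-occurrence network stability. This vignette explains
the models, their assumptions, the tunable parameters, and the design
decisions taken where the methodological literature leaves choices open.

## The data model

The central object is a samples x OTUs abundance matrix (counts or relative
abundances) with unique identifiers, accompanied by per-sample metadata
(site, soil salinity in mS/cm, optional covariates) and a rooted phylogeny of
the OTUs with branch lengths. Patristic (tip-to-tip) distances are taken
from the tree as stored; ultrametricity is not required. Samples are
stratified into salinity levels by left-closed, right-open bins (the last
bin closed), with default edges 0, 1, 2, 4, 7, 11 mS/cm giving five levels.
Those edges are a declared assumption: analyses of this kind typically name
only a few of their level boundaries, so the edges are fully overridable and
are recorded in every pipeline manifest.

## Habitat generalists and specialists

Levins niche breadth for OTU $j$ is $B_j = 1 / \sum_i P_{ij}^2$ with
$P_{ij}$ the fraction of OTU $j$'s total abundance found in sample $i$: the
effective number of samples occupied, from 1 (point niche) to the number of
samples (perfectly even). Breadth is scale-invariant per OTU, so counts and
relative abundances give the same value.

Observed breadth alone confounds niche with abundance: an abundant OTU is
detected in more samples by sampling effort only. The classification
therefore compares each observed breadth with a null distribution over 1000
randomized matrices that preserve every per-sample total and per-OTU total
(and matrix fill) exactly — vegan's `quasiswap_count` algorithm, the
standard fixed-margin null for occupancy tests. An OTU whose breadth
exceeds the null's 97.5th percentile is a generalist; below the 2.5th
percentile, a specialist; otherwise neutral. Ties on a bound are neutral:
the labels require strict exceedance. Because fixing both margins requires
integer counts, a second null ("shuffle": each sample's abundances permuted
across OTUs, preserving sample totals) is available for non-integer data.
A null that instead permuted each OTU's abundances across samples would be
inert here — Levins breadth depends only on the multiset of an OTU's
abundances, not on which samples hold them — so it is deliberately not
offered.

Under uniform multinomial communities (no occupancy structure) the
classifier labels about 5% of OTUs non-neutral, as a 95% interval should;
this calibration, and recovery of planted extreme OTUs, is part of the test
suite. One property of abundance-based margin-preserving nulls worth
knowing: the test is sensitive to within-occupancy *evenness* as well as to
occupancy itself, so a rare taxon sampled very evenly across the few
samples it occupies can exceed the null's upper bound without occupying
many habitats. Interpreting generalists should therefore always consider
the observed breadth value alongside the label.

## Assembly-process partitioning

For a sample pair, the between-community mean nearest taxon distance is

$$\beta MNTD = \tfrac12\Big[\sum_{i\in A} f_{iA}\min_{j\in B} d_{ij} +
\sum_{j\in B} f_{jB}\min_{i\in A} d_{ij}\Big],$$

abundance-weighted by default ($f$ = within-sample relative abundances over
present OTUs); a presence/absence switch is provided. The beta nearest
taxon index ($\beta$NTI) is the z-score of the observed $\beta$MNTD against
a null in which tip identities are shuffled across the entire OTU pool of
the table ("taxa labels" randomization, the standard scheme for this
index), with abundances held fixed; 999 draws by default. On degenerate
phylogenies (e.g. a star tree) the null has zero spread; the pair is
flagged `NaN` and excluded from process counts rather than silently
dropped.

The Raup-Crick metric on Bray-Curtis (RC-Bray) compares the observed
Bray-Curtis dissimilarity with nulls in which both communities are
probabilistically reassembled: each null community draws its observed
richness worth of OTUs with probability proportional to occupancy frequency,
then allocates its observed read total with probability proportional to pool
mean relative abundance. This is the probabilistic-assembly variant of
Raup-Crick (distinct from the classical permutation form), which is the
variant defined by the framework that combines it with $\beta$NTI. The rank
of the observation among nulls is rescaled to $[-1, 1]$, counting ties at
half weight.

Pairs are partitioned as: $\beta$NTI > 2 variable selection; < -2
homogeneous selection; otherwise RC > 0.95 dispersal limitation; RC < -0.95
homogenizing dispersal; else undominated. Boundary values fall on the
stochastic/undominated side, following the strict inequalities with which
these thresholds are conventionally stated. The stochastic fraction is the
sum of the last three categories.

Phylogenetic signal in niche space — the prerequisite for reading
$\beta$NTI as selection — is checked with a Mantel correlogram: patristic
distances cut into equal-frequency classes, per-class Mantel correlation
between class membership and pairwise niche differences, permutation
p-values with progressive Holm correction (via `vegan::mantel.correlog`).
The default niche variable is each OTU's abundance-weighted mean salinity,
a pragmatic proxy used because studies rarely print which niche axis their
signal test used.

## Sloan neutral community model

With metacommunity relative abundance $p$ and local community size $N$
(mean reads per sample), the neutral model predicts the local relative
abundance of a taxon to follow Beta$(Nmp,\; Nm(1-p))$, where $m$ is the
migration rate. The predicted occurrence frequency is the Beta mass above a
detection limit (default $1/N$, at which detection coincides with presence:
a single read counts as an occurrence). $m$ is fitted by bounded
least squares of predicted against observed frequencies ($m \in
(10^{-6}, 1]$; a single-parameter fit with $N$ fixed from the data keeps the
model identifiable), with $R^2 = 1 - SSE/SST$ and a 95% Wilson binomial
band around the predicted frequency at $n$ = number of samples classifying
OTUs as above/within/below the neutral expectation. The fit involves no
randomness. $N$ is the mean (not median) of per-sample totals, matching the
model's common implementation; both the limit and $N$ are configurable.

## Co-occurrence networks and stability

Per salinity level, OTUs with mean relative abundance strictly greater than
0.1% enter the network; edges are Spearman correlations with $|\rho| \ge
0.6$ and Benjamini-Hochberg adjusted $p < 0.05$ (p-values from the
t approximation on midranks, or exact for very small groups). "Strong and
significant" is all the precision most studies give for these cuts, so both
thresholds are explicit parameters recorded in the network object.
Isolated OTUs are not nodes.

Stability metrics:

* **Robustness** — remove a fraction (default 50%) of nodes at random, 100
  repetitions; a surviving node *remains* if it keeps at least one edge
  (i.e. remains in the network, not merely in its largest component);
  robustness is the remaining fraction of original nodes, reported as mean
  and standard deviation. Targeted removal deletes the highest-degree nodes
  (ties by node id) and is deterministic.
* **Vulnerability** — global efficiency $E$ is the mean inverse unweighted
  shortest-path length over node pairs (disconnected pairs contribute 0);
  node vulnerability is $(E - E_i)/E$ after deleting node $i$, and the
  network's vulnerability is the maximum over nodes. Unweighted paths are
  used because no weighting rule is standard for these networks.
* **Cohesion and complexity** — pairwise Pearson correlations of relative
  abundances corrected by a taxa-shuffle null (each OTU independently
  permuted across samples, 200 shuffles); an OTU's positive connectedness is
  the sum of its positive corrected correlations divided by the number of
  other OTUs (negative analogously), and a sample's positive (negative)
  cohesion is the abundance-weighted sum of connectedness. Dividing by all
  other OTUs (rather than only the positively correlated ones) keeps
  cohesion in $[-1, 1]$ and makes it vanish under independence. Complexity
  is positive + |negative| cohesion.

One property worth knowing: in closed compositions (rows summing to 1) the
covariances of each OTU with all others must sum to a negative number, so
"all OTUs positively correlated" is impossible after normalization —
positive and negative cohesion rise together when a dominant block of taxa
covaries. Complexity, which adds both magnitudes, is the robust summary.

## The synthetic-data generator

Real surveys of this design (tens of quadrats over ~10 sites, hundreds of
OTUs, amplicon read depths in the thousands) cannot be regenerated from a
paper's summary statistics, so the package ships generators whose defaults
mirror such a design — 54 samples in 11 sites, 428 OTUs in 12 genera,
10,000 reads per sample, salinity 0-11 mS/cm — and whose ground truth is
known:

* **neutral** — log-series metacommunity (Fisher's alpha 60, giving a
  realistic rank-abundance tail); each sample is a Dirichlet draw with
  concentrations $Nmp_i$ (the stationary Sloan distribution; $m = 0.1$)
  multinomially thinned to the read depth.
* **selection** — niche optima evolve by Brownian motion on a simulated
  birth-death phylogeny and are rescaled to span the salinity range;
  expected abundances follow a Gaussian kernel (width 1.5 mS/cm) around
  each OTU's optimum. Conserved optima make selection detectable both as
  $\beta$NTI > 2 between salinity extremes and as phylogenetic signal.
* **dispersal_limited** — per-site endemic OTU pools (overlap fraction
  configurable, 0 = fully endemic) with site-specific lognormal abundance
  ranks and salinity decoupled from site identity.
* **planted_generalist / planted_specialist** — a background of OTUs each
  occupying an uneven 20-60% of samples, plus one planted OTU holding 5%
  of each sample's reads,
  spread perfectly evenly over all samples or evenly over one site's
  samples. The planted profiles are deliberately exact so the expected
  label is unambiguous.
* **mid_salinity_coupling** — bin-specific co-occurrence architecture: the
  middle salinity level carries a shared latent factor (strength 0.6 on
  half the abundant OTUs) plus many near-duplicate OTU pairs, the extreme
  levels one tight 6-OTU clique each, intermediate levels a mixture. Pairs
  form fragile 2-node network components (a pair member survives random
  removal only if its partner does), cliques robust ones; the latent factor
  raises cohesion without crossing the edge-significance threshold. The
  scenario therefore produces hump-shaped complexity and U-shaped
  robustness across levels by construction. Effect sizes (loadings ~0.997-
  0.999 within modules, module read boosts) are chosen so the planted
  correlations survive multinomial read noise and Benjamini-Hochberg
  correction at roughly 11 samples per level; weaker settings would make
  the planted structure statistically invisible at this design's size,
  which would test the survey design rather than the method.

What the generators do *not* emulate: chimeras and sequencing error,
variable read depth (available as an option but off by default so method
behaviour is not confounded with depth artifacts), taxonomic mis-annotation,
and spatial autocorrelation beyond the site structure. Passing tests
therefore demonstrate correctness of the inference machinery on data whose
generating process matches the models' assumptions, not performance on any
particular real survey.

## Numerical and reproducibility choices

* Every randomized routine takes an explicit seed and restores the caller's
  RNG state; identical seeds give bit-identical results. The null loops for
  $\beta$NTI and RC-Bray are implemented in C++ (via Rcpp) with
  permutations and multinomial draws from R's RNG, so they are seeded the
  same way.
* $\beta$NTI supports an exhaustive mode enumerating all tip permutations
  (pools of up to 8 OTUs), used to validate the sampled null.
* RC-Bray tie counting uses an absolute tolerance of $10^{-10}$ on
  Bray-Curtis values, which are ratios of integers at count scale.
* The pipeline caps the number of sample pairs evaluated per run (default
  300, configurable) by uniform subsampling; a full pairwise analysis of 54
  samples at 999 nulls is available but disproportionate for routine runs.
  Test and acceptance runs use 99-999 nulls and problem sizes from toy
  fixtures up to the full 54 x 428 design, chosen per check so each
  quantity is measured at the scale that makes it meaningful.
* Degenerate inputs fail loudly and early: empty samples, all-zero OTUs,
  non-integer counts offered to integer-only nulls, salinities outside the
  binning range, singleton PERMANOVA groups, and edgeless networks all
  raise errors naming the offending objects (or produce flagged `NaN`s
  where a pair-level metric can be legitimately undefined).

## Limitations

Spearman co-occurrence networks on compositional data are descriptive, not
causal; no compositionally-aware correlation (SparCC-style) is attempted.
The per-clade refinement of the $\beta$NTI framework (phylogenetic-bin
partitioning) and indicator-species analyses are out of scope. The
generalist/specialist labels depend on the chosen null family, and the
salinity-bin edges are an assumption wherever a study does not print its
own.
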