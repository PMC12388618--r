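# amfassembly

Community-assembly inference and co-occurrence network stability analysis
for arbuscular mycorrhizal (AM) fungal communities sampled along a soil
salinity gradient.

Amplicon surveys of AM fungi — obligate root symbionts profiled as OTUs —
routinely ask three questions this package answers end to end:

1. **Which taxa are habitat generalists or specialists?** Levins niche
   breadth `B = 1/Σp²` per OTU, classified against the 95% interval of a
   1000-fold fixed-margin permutation null (vegan quasiswap): breadth above
   the interval → generalist, below → specialist.
2. **Which ecological processes assemble the community?** Per sample pair,
   the abundance-weighted beta mean nearest taxon distance (βMNTD) is
   z-scored against a tip-shuffling null to give βNTI, and Bray-Curtis
   dissimilarity is ranked against a probabilistic reassembly null to give
   RC<sub>Bray</sub> ∈ [−1, 1]. Pairs partition into five processes:
   βNTI > 2 variable selection, βNTI < −2 homogeneous selection, otherwise
   RC > 0.95 dispersal limitation, RC < −0.95 homogenizing dispersal, else
   undominated; the stochastic fraction sums the last three. The Sloan
   neutral community model (occurrence frequency ~ Beta tail with
   parameters `Nmp, Nm(1−p)`) is fitted by bounded least squares for the
   migration rate `m`.
3. **How stable and complex are the co-occurrence networks along the
   gradient?** Per salinity level (default bins 0–1, 1–2, 2–4, 4–7,
   7–11 mS/cm), Spearman networks over OTUs with mean relative abundance
   > 0.1% (|ρ| ≥ 0.6, BH-adjusted p < 0.05); robustness = proportion of
   taxa retaining an edge after removing 50% of nodes (mean ± sd of 100
   repetitions), vulnerability = maximal relative drop in global
   efficiency from deleting one node, and complexity = positive + |negative|
   cohesion (abundance-weighted, null-corrected correlations).

A synthetic-data module generates studies of matching design (54 samples,
11 sites, 428 OTUs, 10k reads, salinity 0–11 mS/cm) with known ground truth
— neutral, selection-driven, dispersal-limited, planted
generalist/specialist, and salinity-coupled network scenarios — so every
stage is testable without any sequence download.

## Worked example

```r
library(amfassembly)

# a selection-structured community with conserved niche optima
sim <- simulate_scenario(scenario_config("selection", seed = 1))

# niche classification
cls <- classify_generalists_specialists(sim$table, n_permutations = 1000,
                                        seed = 2)
table(cls$label)
#> generalist    neutral specialist
#>         64        266         98

# assembly processes between the salinity extremes
sal  <- setNames(sim$metadata$salinity, sim$metadata$sample_id)
pair <- c(names(which.min(sal)), names(which.max(sal)))
z  <- bnti(sim$table, sim$distances, pair, n_null = 999, seed = 3)
rc <- rc_bray(sim$table, pair, n_null = 999, seed = 3)
c(bnti = as.numeric(z), rc_bray = as.numeric(rc))
#>     bnti  rc_bray
#> 8.269902 1.000000
partition_processes(as.numeric(z), as.numeric(rc))
#> [1] "variable_selection"
```

A βNTI of 8.3 (≫ 2) says the phylogenetic turnover between the freshest and
saltiest sample far exceeds the tip-shuffling null — deterministic variable
selection, exactly what this scenario plants. On a neutral scenario the same
machinery returns a stochastic fraction near 1 and a Sloan fit with R² > 0.95:

```r
neu <- simulate_scenario(scenario_config("neutral", seed = 1))
fit <- fit_ncm(neu$table)
fit
#> Sloan neutral community model fit
#>   m = 0.1224  (Nm = 1224)
#>   R^2 = 0.981
#>   detection limit = 0.0001, N = 1e+04, 54 samples, 418 OTUs
```

The whole chain — niche, assembly (overall and per salinity level), neutral
model, per-level networks with robustness/vulnerability/cohesion, Mantel and
PERMANOVA — runs from one config:

```r
run_pipeline(list(output_dir = "results/run1", seed = 11,
                  input = list(scenario = "neutral")))
```

which writes TSV/JSON result tables, GraphML networks and a manifest
recording every parameter and seed. A thin command-line wrapper lives at
`inst/cli/amf-assembly.R` (`Rscript amf-assembly.R run --config config.yaml`).

See `vignettes/community-assembly-methods.Rmd` for the models, their
assumptions, parameter defaults and design decisions.

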