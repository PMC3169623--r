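# marbeta

Beta-diversity analysis of marine bacterial OTU tables across the pelagic
(water-column) and benthic (sediment) realms of the global ocean, packaged
as a tested, reusable R pipeline — plus a synthetic community generator
that emulates the statistical structure of global 16S pyrotag surveys so
every stage is verifiable without any external download.

**Who it is for.** Microbial ecologists comparing community composition
across ocean ecosystems (coastal, open-ocean surface and deep water, deep
seafloor, vents, anoxic habitats), and anyone needing a self-contained,
oracle-tested implementation of the classic beta-diversity toolkit.

**What is inside.** For an OTU count table *N* (samples × OTUs), metadata
and a taxonomy:

- Hellinger standardization `y = sqrt(n_ij / n_i.)` and Bray-Curtis
  dissimilarity `d(x,y) = Σ|x_k − y_k| / Σ(x_k + y_k)`;
- NMDS minimizing Kruskal stress-1 `S = sqrt(Σ(d − d̂)² / Σd²)` with
  20 random starts + one PCoA-seeded start (weak-tie monotone regression,
  guaranteed non-increasing stress within a start);
- ANOSIM `R = (r̄_B − r̄_W)/(M/2)` with label permutations, pairwise ANOSIM
  with Bonferroni correction;
- multivariate dispersion (distance to group centroid in the signed PCoA
  embedding) with exact/approximate Mann-Whitney contrasts;
- Procrustes superimposition (`m² = 1 − (Σσ)²`, correlation `√(1−m²)`) and
  the PROTEST permutation test; cross-rank consistency of ordinations;
- shared-OTU resampling, balanced-group ANOSIM simulation, cell-density
  weight sensitivity, singleton / presence-absence robustness;
- PCoA (negative eigenvalues reported; Lingoes correction optional),
  RDA/db-RDA with adjusted `R² = 1 − (1−R²)(n−1)/(n−m−1)`, and 2–4-set
  variation partitioning whose Venn fractions solve the
  inclusion–exclusion system exactly, with Freedman–Lane permutation tests
  of every pure effect;
- a fully seeded simulator: two realms with 7% shared OTU pool
  (cosmopolitan = abundant), singleton-rich lognormal/log-series abundance,
  evenness contrast between realms, exponential-covariance spatial fields
  with realm-specific ranges, ecosystem/productivity/time effects, nested
  taxonomy with realistic unassigned fractions.

## Worked example

```r
library(marbeta)

# a full synthetic survey: 201 samples, 8 realm:ecosystem groups,
# 100k-OTU pool, ~15k observed OTUs, ~46% dataset-wide singletons
sim <- generate_community(sim_params(seed = 7))
d   <- bray_curtis(hellinger(sim$table))

anosim(d, sim$metadata$realm, n_perm = 1000, seed = 1)
#> anosim_result: R = 0.999, p = 0.000999 (1000 permutations; groups: benthic=60, pelagic=141)

ord <- nmds(d, n_starts = 20, seed = 2)
ord$stress
#> [1] 0.073964

rob <- robustness_procrustes(sim$table, seed = 4)
rob[, c("comparison", "correlation", "p_value")]
#>                      comparison correlation      p_value
#> 1    with_vs_without_singletons   0.9990181 0.000999001
#> 2 abundance_vs_presence_absence   0.9835731 0.000999001
```

The realm separation (R near 1, p at the permutation floor), the low-stress
2-D ordination (stress 0.074), and ordinations essentially unchanged by
singleton removal (Procrustes correlation 0.999) or by presence/absence
coding (0.984) mirror the qualitative findings of published global surveys, where
pelagic and benthic communities separate strongly (R ≈ 0.56 on real data),
singleton removal leaves the ordination intact (correlation 0.997) and
presence/absence agrees with abundance-based patterns (0.909).

The whole pipeline, end to end:

```sh
Rscript inst/scripts/marbeta-cli.R run-all --out demo_run --seed 7
```

writes the per-ecosystem summary table, the Bray-Curtis matrix, NMDS
coordinates + run log, realm and pairwise ANOSIM, dispersion tests,
shared-OTU resampling, robustness Procrustes, per-realm variation
partitioning and cross-rank consistency, plus `manifest.json` with the seed
of every stage (any stage can be replayed in isolation). The default run
takes ~7 minutes on one CPU. Individual stages and parameters are
configurable through a YAML config (see `?read_run_config`).

Example fractions from the demo run (`varpart_pelagic.tsv`): pure ecosystem
0.025 (p = 0.001), pure space 0.0067 (p = 0.005), pure productivity 0.0052
(p = 0.003), pure time 0.00085 (p = 0.17) — ecosystem dominating space,
productivity small and time negligible, the same ordering the generator
injected.

## Documentation

The methods vignette (`vignettes/marine-beta-diversity.Rmd`) documents the
model, every tunable parameter with its default and rationale, what the
synthetic generator does and does not emulate, numerical edge cases, and
known limitations.
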