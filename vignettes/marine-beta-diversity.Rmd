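---
title: "Beta-diversity of marine bacterial communities: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta-diversity of marine bacterial communities: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Global surveys of marine bacterial 16S amplicons cluster reads into OTUs
(operational taxonomic units at 3% sequence dissimilarity) across hundreds
of samples spanning the pelagic (water-column) and benthic (sediment)
realms and several ecosystem types: coastal, open-ocean surface and deep
water, deep seafloor, hydrothermal vents and anoxic habitats. The analysis
questions are about *beta-diversity* — how community composition varies
among samples — and about what share of that variation is attributable to
ecosystem type, geographic location, sampling time and upper-water
productivity. `marbeta` implements that analysis chain as a tested,
reusable pipeline, together with a synthetic community generator that
reproduces the statistical structure such surveys exhibit, so that every
stage can be validated without access to any external dataset.

## The analysis model

Counts are standardized by the **Hellinger transformation**
($y_{ij} = \sqrt{n_{ij} / n_{i\cdot}}$), which makes downstream geometry
insensitive to per-sample sequencing depth, and pairwise **Bray-Curtis
dissimilarities** $d(x, y) = \sum_k |x_k - y_k| / \sum_k (x_k + y_k)$ form
the beta-diversity matrix. On top of this matrix the package provides:

* **NMDS** (`nmds()`): Kruskal stress-1 minimization,
  $S = \sqrt{\sum (d - \hat d)^2 / \sum d^2}$, alternating
  pool-adjacent-violators monotone regression with a Guttman-transform
  update and a backtracking line search. Ties are *weak* (primary): tied
  dissimilarities may receive unequal fitted values, the common choice for
  count data where ties are frequent and strong ties produce degenerate
  solutions. Twenty random starts (the survey's convention) plus one
  PCoA-seeded start; the line search makes the per-iteration stress
  sequence provably non-increasing, and the returned solution is the
  lowest-stress start, centred and rotated to principal axes. Convergence:
  relative stress change below `1e-7` or 500 iterations — the source survey
  does not state its criteria, so these are implementation-defined and
  exposed as arguments.
* **ANOSIM** (`anosim()`): $R = (\bar r_B - \bar r_W) / (M/2)$ on mid-ranked
  dissimilarities, $M = n(n-1)/2$, with label-permutation p-values using the
  $(b + 1)/(m + 1)$ convention throughout (p can never be 0). Pairwise
  ANOSIMs use Bonferroni correction (the survey's explicit choice, not
  Holm).
* **Multivariate dispersion** (`beta_dispersion()`): distance to group
  centroid in the PCoA embedding with positive- and negative-eigenvalue
  axes kept separately, $z = \sqrt{\max(0, d^2_+ - d^2_-)}$ (Anderson's
  PERMDISP construction; the centroid, not the spatial median, because the
  analysis being reproduced says "centroid"). Group contrasts use the
  Mann-Whitney rank-sum test: exact by enumeration when the smaller group
  has at most 8 observations, otherwise the normal approximation with tie
  and continuity corrections.
* **Procrustes / PROTEST** (`procrustes()`, `protest()`): symmetric
  superimposition, $m^2 = 1 - (\sum \sigma_i)^2$ after centring and unit
  sum-of-squares scaling; correlation $\sqrt{1 - m^2}$; PROTEST permutes
  rows of one configuration.
* **PCoA / RDA / db-RDA / variation partitioning** (`pcoa()`, `rda_r2()`,
  `db_rda_r2()`, `variation_partition()`): Gower double-centring with
  negative eigenvalues reported (default `keep_positive`, Lingoes
  correction optional — db-RDA downstream only needs a Euclidean
  representation); adjusted $R^2 = 1 - (1 - R^2)(n - 1)/(n - m - 1)$;
  Venn fractions recovered by solving the inclusion-exclusion system
  exactly, so fractions always sum to the full-model adjusted $R^2$ to
  machine precision. Negative fractions are a known adjusted-$R^2$
  artefact and are reported as-is, never clipped. Pure effects are tested
  by partial RDA with Freedman-Lane residual permutation (the survey names
  only "Monte Carlo permutation tests"; raw permutation is available for
  comparison); shared fractions are deduced numerically and therefore
  untested.

### Ecosystem classification

Water samples: *coastal* when within 200 nautical miles of the littoral and
above 200 m; *surface open ocean* offshore above 200 m; *deep open ocean*
offshore at or below 200 m. Sediment samples: *coastal* above 200 m water
depth, otherwise *deep seafloor*. Vent and anoxic habitats are taken from
sample descriptions and override the geometric rules. Two boundary choices
the published rules leave open: thresholds use strict `<` for
coastal/surface and `>=` for deep (so the partition is total), and
nearshore *water* samples deeper than 200 m — a combination the published
rules never mention — are classified `deep_open_ocean` (depth dominates).

### Order of operations

Hellinger-then-Bray-Curtis is applied literally as the source analysis
describes, although Bray-Curtis is more often used on raw relative
abundances; `weight_sensitivity(mode = "raw")` provides the unstandardized
route, which is also the only route on which cell-density weighting can act
— the composition pipeline is exactly invariant to per-sample scaling, a
property the test suite asserts.

## The synthetic data generator

`sim_params()` / `generate_community()` describe a *stated world* whose
defaults emulate what the global surveys report, and they were chosen once:

* **Two realms with low OTU overlap.** The OTU pool (100,000) is split so
  that 7% is shared. Shared OTUs use the *same abundance quantile* in both
  realms and draw that quantile from the upper half
  (`shared_quantile_min = 0.5`): the abundance-occupancy relationship —
  cosmopolitan taxa tend to be abundant, endemic taxa dominate the rare
  tail. Without this, a 7% pool overlap is observed as well under 1%
  shared OTUs at finite sequencing depth, because independently-rare taxa
  are almost never co-detected.
* **Singleton-rich tables.** Roughly half of all observed OTUs should occur
  exactly once in the whole dataset. Plain multinomial sampling from any
  unimodal lognormal abundance distribution saturates near 30% singletons;
  the missing ingredient is across-sample heterogeneity (the real data pool
  dozens of independent projects), modelled here as per-(sample, OTU)
  lognormal noise (`sample_noise_sd = 2`). With lognormal shape 3 and a
  mean depth of 1,000 reads/sample the realized fraction is ~0.46, within
  the ±5-point calibration band. `calibrate_singletons()` implements the
  prescribed bisection on the shape parameter (≤20 evaluations; a 5-point
  grid probe first, because the realized fraction is unimodal in the
  shape), returning the best achieved value with a warning when a target is
  unreachable.
* **Depth scaled down.** The survey averages ~19,000 reads/sample; the
  default world uses 1,000 so that a full pipeline run takes minutes, and
  the OTU pool is scaled with it (singleton structure depends on the
  reads-per-pool-OTU ratio). Consequence: the default world observes ~16k
  OTUs rather than the survey's 120k, and singletons are ~3.5% of reads
  rather than 0.6%.
* **Evenness contrast.** Pelagic communities are markedly less even than
  benthic ones. `evenness_contrast = c` multiplies the pelagic lognormal
  shape by $\sqrt c$ and divides the benthic one by it (for the log-series
  model the contrast acts as a power, `x^(1/c)` vs `x^c`, to stay in
  (0, 1)). At defaults the realized inverse Simpson means are ~20 (pelagic)
  vs ~54 (benthic); the published contrast is 20.2 vs 143.2 at 19 times the
  sequencing depth.
* **Spatial structure.** A latent Gaussian field per realm: five factors
  with exponential covariance on great-circle distance, range 8,000 km
  (pelagic) vs 2,000 km (benthic), exponentiated into multiplicative
  abundance effects — the shorter benthic range produces the stronger
  benthic distance decay the surveys describe. The published work gives no
  quantitative decay rates; these ranges are order-of-magnitude choices and
  labelled as such.
* **Ecosystem, productivity and time effects** are per-OTU Gaussian
  loadings (sd 1.0, 0.3, 0.15) on ecosystem identity, the standardized
  productivity class and days-since-first-sampling. Productivity classes
  are generated from a coast-distance/latitude proxy so that the
  *class* covariate used by the analysis is exactly the covariate that
  modulated abundances.
* **Taxonomy.** A nested random partition into 6 ranks; per-rank assigned
  fractions decline monotonically from 23% (phylum) to 16% (genus). The
  published per-rank assignment rates are non-monotone (order-level dip to
  8.5%), which cannot be represented under the prefix-annotation invariant
  this package enforces; the monotone profile covers the reported range.

**What a green test does not establish.** The generator draws independent
multinomial counts given smooth latent effects; it has no sequencing error,
no chimeras, no compositional interactions between taxa, no project-level
batch structure beyond the idiosyncratic noise term, and its taxonomy is a
random nesting with no phylogenetic signal in abundances. Tests against it
validate the *statistical machinery*, not biological conclusions.

## Ground-truth recovery

The parameter-recovery test defines the injected share of each explanatory
set as the pure adjusted-$R^2$ fraction computed on the *noise-free
expected relative abundances* (recorded in the generator's `GroundTruth`),
and compares it with the same partition computed on the sampled counts.
This isolates exactly the multinomial sampling error. The recovery world
uses three spatial PCoA axes (`spatial_axes = "first_k"`, `k_spatial = 3`:
great-circle geometry embeds in three dimensions; higher axes are curvature
residue) — retaining *all* positive axes, the package default elsewhere,
costs tens of residual degrees of freedom at $n \approx 200$ and drives
every adjusted $R^2$ down mechanically, which is also why the pipeline's
varpart stage defaults to `first_k`.

## Numerical choices and degenerate inputs

* Permutation p-values are always $(b+1)/(m+1)$; all permutation tests
  accept a `seed`, and composite procedures derive per-stage sub-seeds from
  it with a Lehmer congruence, so any stage can be replayed in isolation.
* Bray-Curtis between two all-zero samples is undefined and raises an
  error; a single all-zero row never arises because OTU-table validation
  requires positive sample totals.
* An all-equal (including all-zero) dissimilarity matrix is a degenerate
  NMDS input: under weak ties every configuration fits perfectly, so the
  solution has stress 0 and a warning is emitted.
* A focal design set numerically absorbed by its conditioning set (residual
  sum of squares below `1e-10` of its centred norm) is treated as rank
  zero: pure fraction 0, p = 1, with a warning.
* `mean_composition()` reports sd = 0 for single-sample groups.
* Singletons are defined dataset-wide (total count exactly 1). Published
  per-ecosystem summary tables turn out to use a within-group definition —
  their per-group singleton counts sum to more than the grand total — so
  `summarize_dataset()` defaults to the dataset-wide attribution and offers
  `singleton_scope = "within_group"` for parity with such tables.

## Known limitations

* NMDS is pure R; ~200 samples with 21 starts takes a few minutes. The
  structure (vectorized Guttman updates, `isoreg` for the monotone fit)
  keeps it acceptable at desk scale but it is not intended for thousands of
  samples.
* `read_otu_table()` accepts TSV and *dense* BIOM-style JSON only; no HDF5.
* No phylogenetic (UniFrac-style) dissimilarities: no tree is in scope.
* Forward selection of spatial eigenfunctions (MEM/PCNM) is deliberately
  out of scope; the space set is the geodesic PCoA axes plus water depth.
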