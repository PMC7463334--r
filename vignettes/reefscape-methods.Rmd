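---
title: "Methods: seascape genomics and connectivity indices in reefscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seascape genomics and connectivity indices in reefscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(reefscape)
```

## The two axes of the analysis

`reefscape` evaluates the adaptive potential of a reef system along two
independent axes that are combined at the end:

1. **Seascape genomics.** Genotypes of georeferenced coral colonies are
   associated with local environmental conditions through per-genotype
   logistic models. Significant associations (SGEAs) give, for any value of
   the environmental variable, the probability that a colony carries the
   putatively adaptive genotype; averaged over the SGEAs tied to one
   pressure this is the probability of carrying adapted genotypes, PA.
2. **Connectivity.** Daily current fields are turned into a directed
   conductance graph over sea pixels; least-cost path costs between reefs
   are asymmetric "sea distances". A linear model of pairwise FST on sea
   distance (the connectivity model) translates any distance into a
   predicted directional genetic separation, dFST.

Per reef cell the axes combine into three indices in km²: OCI (total area
of reefs reachable from the cell within a dFST threshold), ICI (total area
of reefs that can reach it), and API (ICI with each contributing reef's
area weighted by its PA).

## Environmental descriptors

Each *daily* variable contributes six statistics per pixel: the overall
mean (`AVG`), the highest and lowest calendar-month climatological means
(`HM`, `LM`), the SD of all daily values (`SD.AVG`), and the SDs of the
daily values inside the highest- and lowest-mean months (`SD.HM`,
`SD.LM`). Each *monthly* variable contributes `AVG`, `HM`, `LM` only.
With five daily variables (SST, salinity, chlorophyll, current speed, and
alkalinity derived from SST and salinity), two monthly ones (suspended
particulate matter, photosynthetically available radiation) and the three
singleton descriptors (BAF, depth, population density in a 50-km buffer)
the scheme has exactly 39 columns. Treating derived alkalinity as a full
daily variable is what makes the total come out at 39; that is the reading
implemented.

Two readings of the scheme were genuinely open and are resolved as
follows, with the alternatives reachable through arguments:

* *Which SDs?* `SD.HM`/`SD.LM` are the SDs of daily values within the
  extreme calendar months (pooled across years), not SDs of monthly means.
* *Month definition.* Calendar months, with partial months at the series
  edges included in their month's climatology.

**Bleaching alert frequency (BAF).** The daily hotspot is
`max(0, SST − MMM)` where MMM is the per-pixel maximum of the monthly
climatological means (computed from the supplied series unless an external
climatology is given). A day is under alert when the hotspot accumulated
over the trailing 14 days, divided by 7 (units of °C-weeks, the
degree-heating-week convention), reaches 4. BAF is the fraction of alerted
days among days with a full window. The accumulation window, threshold,
and a minimum-hotspot floor (default 0; the operational NOAA product uses
1 °C) are arguments, because the convention admits variants.

**Alkalinity.** A pointwise polynomial in centered salinity and
temperature; the default coefficients are the published subtropical-zone
fit of Lee et al. (2006), shipped as a plain-text config
(`inst/extdata/alkalinity_coeffs.csv`) and clearly marked as external
reference values.

**Spatial assignment.** Sample sites take the nearest-pixel value (an
error names any site on land); reef cells take the mean of their member
pixels; population density is averaged inside a 50-km buffer
(great-circle on geographic grids, Euclidean km on planar ones). All
spatial means are plain averages over enumerated pixels and are tested
against brute-force enumeration.

## Genotype handling and FST

Input genotypes are biallelic SNP dosages 0/1/2 with missing values,
read from VCF (via `vcfR`) plus a sites table. Filtering drops
individuals with ≥ 10% missing first, then SNPs with MAF ≤ 0.05, major
genotype class frequency ≥ 0.95, or missing rate ≥ 0.1; LD pruning is
greedy first-kept-wins on squared Pearson correlation (pairwise-complete)
within a trailing window. The filters are idempotent and report per-step
counts.

Pairwise FST uses the Weir–Cockerham (1984) variance components with the
multi-locus **ratio of sums** `Σa / Σ(a+b+c)` (the alternative, a mean of
per-locus ratios, is biased at low-information loci). Sites with ten or
fewer genotyped individuals are excluded — the strict `> 10` reading of
the sample-size rule, configurable. Missing genotypes are excluded per
locus; negative estimates are preserved (an estimator property) unless a
clamp is requested. A windowed per-scaffold FST scan flags candidate
high-FST islands before association analysis.

**Structure covariate.** The analytical role of a DAPC's first
discriminant function — a scalar proxy for neutral structure used as a
model covariate — is filled by the leading principal axis of the centered
dosage matrix (missing imputed to locus means), or by any externally
computed covariate loaded from CSV. A full DAPC re-implementation was
deliberately avoided: cluster-number selection is under-determined here,
and only the axis enters the models.

## Genotype–environment association

For each SNP, each of the three genotype classes becomes a binary
presence response; each environmental variable is one predictor; the
structure covariate is always retained. The logistic model
`logit P(y=1) = α + β·env + γ·cov` is fitted by IRLS (tolerance 1e-8 on
the deviance, max 100 iterations) on internally standardized predictors,
with coefficients reported on the original scale. Two statistics are
computed per model: the likelihood-ratio `G = 2(llfull − llnull)` where
the null keeps the covariates but drops the environment, and the scalar
Wald `W = (β/se(β))²`; both referred to χ²(1). Degenerate responses
(one class), degenerate predictors, singular systems and separation
(standardized coefficient beyond 50) are reported as statuses and yield
no p-values.

Multiple testing uses Storey q-values with π₀ estimated on a λ grid
(0.05–0.95 by 0.05) with a df-3 smoothing spline evaluated at λ = 0.95,
clamped to (0, 1]; with π₀ fixed at 1 the result is exactly
Benjamini–Hochberg. Correction batches are **per environmental variable**
across all genotype models (a global batch is available for sensitivity
analysis); this makes a variable's q-values invariant to which other
variables were scanned. The SGEA rule keeps models with both q-values
below 0.01 and, per SNP, the best model by G, with deterministic ties
(lower Wald p, then variable name). The batched and single-model fitting
paths are tested to agree, and the single path is cross-checked against
`glm` and a direct likelihood optimizer.

## Currents, transition graph, sea distances

Daily current vectors are decomposed by **positive scalar projection**
onto the eight neighbor unit vectors, accumulated over days. Projection
(rather than nearest-direction binning) is smooth and rotation-consistent
and reduces to the obvious answer for axis-aligned flow. The conductance
toward a direction is its cumulative speed divided by the pixel's total
over all eight physical directions; edges into land or off-grid are
removed *after* normalization (without re-normalizing), which keeps a
coastal pixel's outgoing conductance sum below one rather than inflating
its remaining directions. The cost of an edge is the inverse of its
squared conductance; a direction with zero cumulative speed has no edge.
Dijkstra (via `igraph`) gives directed least-cost distances; unreachable
pairs are `+Inf` with a warning. No geometric correction of diagonal
edges is applied by default (an optional √2 scaling exists); the
asymmetry of the resulting matrix is the point of the construction.

The connectivity model is OLS of pairwise FST on distance. FST is
undirected while distances are directed: the default collapses a pair to
the **minimum** of its two directed distances, on the rationale that gene
flow along the easier direction dominates homogenization; the mean is
available. AIC uses the full Gaussian log-likelihood with the variance
counted as a parameter (the `stats::AIC` convention), so least-cost and
Euclidean models are compared on the standard scale. dFST predictions
floor negative values at zero and zero the diagonal.

## Indices

With threshold T (default 0.02, strict `<` comparison, both
configurable):

* `OCI(i) = Σ_{j≠i} area_j · [dFST(i→j) < T]`
* `ICI(i) = Σ_{j≠i} area_j · [dFST(j→i) < T]`
* `API(i) = Σ_{j≠i} area_j · PA_j · [dFST(j→i) < T]`

The focal cell's own area is excluded (the indices describe
*neighboring* reefs; inclusion is an option). API ≤ ICI whenever PA ∈
[0, 1], all three are monotone in T, and reefs outside threshold reach of
a cell cannot affect it — which is why buffer reefs beyond the region of
interest should be included in the grid to avoid border effects.

At prediction time the structure covariate in an SGEA model is held at a
constant (default: its sample mean, 0 after centering) because covariate
values are undefined for unsampled reefs.

## The synthetic study system

The generator exists to give every stage a ground truth; its defaults are
the study conditions under which the package's claims are tested.

* **Domain.** A 24×40 grid of 10-km pixels, an island chain plus a
  western landmass, and a dominant north-eastward current (0.5 m/s) with
  spatially smooth daily noise (sd 0.25 m/s) — an idealized archipelago on
  a boundary current.
* **SST.** Four years of daily values: baseline 26 °C, seasonal
  amplitude 3 °C peaking in late summer, a north–south gradient, and two
  circular heatwave events (+4 and +3.5 °C, 40–45 days) each confined to
  one summer. Confining events to single years keeps the multi-year
  climatology only mildly contaminated so the degree-heating signal
  remains detectable, as it is for real satellite records spanning
  decades.
* **Sites and loci.** 12 sites × 15 colonies; 2,000 neutral loci; 5
  adaptive loci with logistic intercept −4 and slope 8 on the 0–1
  rescaled site BAF (presence probability rising from ≈0.02 to ≈0.98
  across the gradient), interleaved across scaffolds so LD pruning cannot
  collapse them onto one representative; 2% missing genotypes.
* **Neutral structure.** A Gaussian drift field: sites are embedded in
  Euclidean space by classical MDS so that squared embedding distances
  track the planted sea distances, and per-locus site frequencies are
  `p0 + e` with `E[(e_i − e_j)²] = 2 β p0(1−p0) d_ij`, giving expected
  pairwise FST `β·d` by construction. Least-cost matrices are generally
  not exactly embeddable; the embedding is rescaled so the with-intercept
  least-squares slope of achieved on planted distances is one, which
  pushes any distortion into a nonnegative offset (it surfaces as the
  intercept of the FST–distance relation, not as a slope bias). The
  realized-vs-planted slope is *tested*, not assumed: it comes out within
  about 10% of β at 2,000 loci. Frequencies are clamped to
  [0.005, 0.995]; genotypes are Hardy–Weinberg draws within sites.
* **FST scale.** The default target is FST ≈ 0.05 at the widest site
  pair (`fst_max`), chosen so the simulated FST range is comparable to
  published regional coral values and the conventional dFST threshold of
  0.02 falls inside the observed dFST distribution rather than below it.
* **Determinism.** All randomness derives from one root seed through
  named substreams (`currents`, `sst`, `genotypes`, …), so a stage can be
  regenerated independently and identical configurations are
  byte-identical. A truth table (locus type and planted coefficients) is
  written alongside the genotypes so downstream checks never
  reverse-engineer the simulation.

What the generator does **not** emulate: larval biology (the dispersal
model is phenomenological FST-on-distance, as in the analysis itself),
coalescent noise and linkage (loci are independent given site
frequencies), measurement error in the rasters, and fine-scale (<1 pixel)
environmental variation. Passing tests therefore validate the
statistical machinery and the workflow's internal consistency, not the
ecological realism of any particular reef system.

## Numerical choices and degenerate inputs

* IRLS: deviance tolerance 1e-8, max 100 iterations; separation declared
  at |standardized coefficient| > 50; singular systems reported.
* Storey π₀ clamped to [1e-8, 1]; empty p-vectors return empty.
* The MDS embedding keeps eigenvalues above 1e-10 of the largest;
  degenerate (all-zero-distance) site sets fall back to identical
  frequencies.
* Zero-variance predictors, one-class responses, empty SGEA sets, empty
  reef buffers, land sample points, sub-minimum site samples and
  unreachable reef pairs all raise errors or flagged statuses rather than
  silent numbers.
* Grid conventions: row 1 is the northernmost row; pixel index is
  `(col−1)·nrow + row`; u is eastward, v northward.

## Problem sizes used by the tests

The default test-and-validation scales were chosen to make every
stochastic claim measurable in minutes on one CPU: null calibration runs
50 neutral seeds of 12 sites × 15 colonies × 2,000 loci; power runs 50
seeds with one planted locus among 300 neutral; slope recovery runs 100
linear-model seeds; the least-cost versus Euclidean comparison runs 20
full seascape seeds at 800 loci; the demo pipeline runs the full default
configuration. The acceptance script re-runs the same computations at 10
seeds per stochastic block.

## Known limitations

* The structure covariate is a principal axis, not a full DAPC; with
  strong hierarchical structure several axes (`k > 1`) may be needed.
* SamBada's exact missing-data treatment and Wald construction are not
  published in detail; listwise deletion and the scalar df-1 Wald on the
  environmental coefficient are implemented and documented.
* Whether the published analyses excluded the focal cell's own area from
  the indices, and whether conductance was normalized before or after
  coastal edge removal, are not stated in the source material; the
  choices here are documented above and reversible by argument.
* Raster I/O is plain-text CSV; the container is deliberately minimal
  (regular grids, constant mask) rather than a full geospatial stack.
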