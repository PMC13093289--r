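---
title: "Methods: coalescent ABC inference of island colonisation with sea-ice comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coalescent ABC inference of island colonisation with sea-ice comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coalice)
```

## What the package does

`coalice` implements a complete inference pipeline for the phylogeography
of Arctic island ungulates (reindeer/caribou, *Rangifer*) from short
mitochondrial control-region alignments:

1. **Sequence data preparation** — trimming to a gap-free common region,
   haplotype collapsing, gene diversity, rarefied haplotypic richness,
   and pairwise differentiation (Nei's Gst, Hedrick's G'st, Jost's D).
2. **Exploratory population structure** — Euclidean indicator distances
   between individuals, Edwards angular distances between populations,
   UPGMA dendrograms with data-driven agglomeration-method selection,
   principal coordinates analysis, and K-means with elbow and
   average-silhouette selection of K.
3. **Demographic scenarios** — explicit hypothesis objects: populations
   with priors on haploid effective sizes, backward-in-time divergence /
   pulse-admixture / founder-bottleneck events with priors on times and
   rates, serial sampling ages, and automatic derivation of the order
   constraints a topology implies.
4. **Coalescent simulation** — a serial-sampling structured coalescent
   plus HKY+Γ+I sequence evolution, feeding a fixed-order
   summary-statistic vector shared bit-for-bit with the observed data.
5. **ABC with random forests** — reference tables, prior-predictive PCA
   checks, classification-forest model choice with out-of-bag posterior
   probabilities, and quantile-regression-forest parameter estimation
   with 95% credible intervals, converted to calendar years at a
   7-year generation time.
6. **Paleo sea-ice comparison** — extraction of monthly/annual sea-ice
   concentration series from gridded 1 ka snapshots around inferred
   event locations, and a 70% crossing-threshold analysis.
7. **Synthetic data** — generators for sequence datasets with known
   truth, herd coordinate tables, and seasonal gridded ice fields, so
   the full pipeline is testable without any external downloads.

## The coalescent model

Time runs backward in generations before present. Within a population of
haploid effective size $N$ (mtDNA copy number), $k$ active lineages
coalesce at rate $k(k-1)/(2N)$ per generation; the simulator is an
event-driven exact algorithm (exponential waiting times between
coalescences, interrupted by scheduled demographic events). We use the
continuous-time approximation rather than generation-by-generation
simulation because it is orders of magnitude faster; the test suite
validates it against a discrete-generation Wright–Fisher oracle at
$N = 100$ (Kolmogorov–Smirnov test on the TMRCA distribution) and
against the closed forms $E[T_2] = N$ and
$E[\mathrm{TMRCA}_{n=10}] = 2N(1 - 1/10)$.

Demographic events are interpreted as follows (all backward in time):

* **Divergence** at time $t$: the daughter population's lineages move
  into the parent (forward in time, the founding of the daughter).
* **Admixture** at time $t$ with rate $r \in [0,1]$: each lineage of the
  recipient moves to the donor independently with probability $r$ — an
  instantaneous unidirectional introgression pulse. Continuous gene flow
  is deliberately not modelled; the hypotheses concern discrete contact
  episodes over sea ice.
* **Founder bottleneck** $(N_b, d_b)$: the population founded at time
  $t$ has size $N_b$ for the $d_b$ generations following its founding,
  i.e. over backward ages $[t - d_b, t]$, then its ordinary $N_e$. The
  duration $d_b$ is rarely identifiable from single-locus data, so it
  carries its own prior (default U(1, 50) generations) rather than a
  fixed value.

Serial sampling: each population has one sampling age, and its lineages
enter the coalescent only at that age. The package enforces a single
sampling age per population because the simulator's reference tables
assume exchangeable samples within a population; the canonical use is an
ancient subfossil population, e.g. one sampled 502 generations before
present. Divergence times of serially sampled populations are
automatically constrained to be older than the sampling age.

Order constraints implied by the topology (a parent must outlive its
daughter's divergence; an admixture pulse must predate the extinction of
both partners) are derived automatically and enforced, together with any
explicit constraints, by rejection resampling from the priors. Priors
are uniform on the natural scale unless declared log-uniform — the
convention of the standard ABC scenario software this mirrors, whose
published analyses state ranges, not shapes.

## Sequence evolution

Sequences evolve under HKY with unequal base frequencies $\pi$ and
transition/transversion parameter $\kappa$, with continuous
gamma(\(\alpha\), mean 1) rate multipliers across sites and a proportion
$p_\mathrm{inv}$ of invariable (rate-0) sites. The rate matrix is
normalised to one expected substitution per unit of $\mu t$, so the
per-site per-generation mutation rate $\mu$ has its usual meaning.
Child states are drawn from the *exact* closed-form HKY transition
matrix $P(\mu t \cdot \mathrm{rate})$ along each branch, not from
Poisson event placement, so multiple hits at a site are handled exactly
at any branch length; the closed form is verified in the tests against
an independent eigendecomposition matrix exponential to $10^{-12}$.
Gamma rates are continuous rather than discretised into categories —
there is no computational reason to discretise when transition
probabilities are evaluated per site.

Realistic defaults in the example scenarios (a transition-heavy
$\kappa = 10$, AT-rich $\pi$, $\alpha = 0.5$, $p_\mathrm{inv} = 0.2$,
$\mu$ log-uniform over $10^{-6}$–$10^{-4}$ per site per generation)
reflect mammalian mitochondrial control-region behaviour: strong
transition bias, strongly heterogeneous site rates, and a fast overall
clock. They are illustrative settings for synthetic experiments, not
estimates.

## Summary statistics

One fixed-order vector serves observed and simulated data through the
same code path. Per population: number of distinct haplotypes,
segregating sites, mean and variance of pairwise nucleotide differences,
private segregating sites (segregating in that population and in no
other), and Tajima's D. Per population pair: mean between-population
differences ($d_{xy}$), Hudson-type
$F_\mathrm{ST} = 1 - \bar\pi_\mathrm{within}/\bar\pi_\mathrm{between}$,
and the number of shared haplotypes. The exact statistic set of the
reference ABC software is not published; this set was chosen to span
within- and between-population diversity and is what the forests
consume. Undefined statistics (Tajima's D at $S = 0$ or $n < 4$;
$F_\mathrm{ST}$ with a single sample or zero between-population
divergence) are encoded as 0 with a companion mask column set to 1 —
identically for training and observed vectors, so the forests can learn
from missingness without NA handling.

## Diversity and differentiation estimators

Gene diversity uses the small-sample correction
$H = \frac{n}{n-1}(1 - \sum_i p_i^2)$. Haplotypic richness is rarefied
by hypergeometric expectation to a common size (default: the smallest
population). Pairwise differentiation offers both the plug-in estimators
and the Nei–Chesser sample-size-corrected ones (harmonic-mean $\tilde n$;
$H_S' = \frac{\tilde n}{\tilde n - 1} H_S$,
$H_T' = H_T + H_S'/(\tilde n k)$, the haploid analogue of the diploid
correction), with the corrected variant as the default since that is the
default of the standard population-genetics packages whose outputs these
reproduce. Corrected estimators can be slightly negative in weakly
differentiated data; values are reported as computed and never clipped.
When both populations are monomorphic for the same haplotype
($H_T = 0$), all three statistics are defined as 0 and flagged.

## Population structure choices

* UPGMA agglomeration-method selection maximises the cophenetic
  correlation with the original distances over candidate `hclust`
  methods; ties are broken toward `"average"` (UPGMA proper).
* PCoA variance explained is computed over positive eigenvalues only;
  negative eigenvalues (non-Euclidean inputs) are reported separately
  rather than folded into the denominator.
* K-means uses k-means++ seeding with 25 restarts per K under a recorded
  seed. The elbow K is automated as the largest second difference of the
  within-group variance curve, but the full curve is always returned for
  the visual inspection the elbow heuristic really calls for. The
  silhouette-optimal and elbow K can disagree (they measure different
  things); both are reported and no reconciliation is attempted.

## ABC with random forests

The reference table holds, per simulation, the scenario id, the
parameter draw and the summary vector. Every row is seeded from the
master seed plus its (scenario, row) identity, so tables are
reproducible independently of chunking.

*Model choice* follows the ABC-RF algorithm: a classification forest
(500 trees by convention) on the summary statistics augmented with
linear-discriminant axes; the selected scenario is the majority vote at
the observed vector; the *global* (prior) error is the out-of-bag
misclassification rate; the *posterior probability* of the selected
scenario is an out-of-bag regression of the correct-classification
indicator evaluated at the observed point; the *local* error is one
minus that posterior. Prior-predictive PCA checks (1000 displayed
simulations per scenario by default) report whether the observation
falls inside each scenario's convex hull and 1st–99th percentile box on
the first two axes.

*Parameter estimation* uses quantile regression forests: posterior
median and 2.5%/97.5% quantiles at the observed vector; global accuracy
as out-of-bag normalised mean absolute error
($\mathrm{mean}\,|{\hat\theta - \theta}|/\theta$); local accuracy as the
posterior expected absolute deviation from the median (from a fine
quantile grid at the observation), relative to the median. Time
estimates convert to calendar years by multiplying the point estimate
and both interval bounds by the generation time (7 years by default),
reported in ka rounded to one decimal.

The published posterior-probability (>65%) and local-error (~20%)
model-acceptance heuristics are reporting conventions, not algorithmic
inputs; they can be applied to the returned numbers by the analyst.

## Sea-ice extraction

Ice fields are monthly concentration grids (fraction of cell covered,
in [0, 1]) on a Lambert azimuthal equal-area plane at a nominal 30 km
cell size, one snapshot per 1 ka. Because no NetCDF reader is assumed,
fields serialise to an equivalent plain-text form (JSON header +
long-format TSV with `time_ka, month, y, x, sic, land`). The spherical
LAEA forward projection is implemented directly (authalic radius
6371.0088 km) with a configurable central meridian: the polar-Arctic
EPSG convention is used with region-specific meridians, and the
meridian actually used is recorded with the results.

Population centroids are means of member-herd projected coordinates; an
event's location is the midpoint of its two population centroids; 100
points are sampled uniformly over a 100 km disc around it
($r = R\sqrt{u}$), and concentration is averaged over non-land cells
whose *centers* fall within the extraction radius of each point — the
cell-inclusion rule is applied identically in the brute-force oracle the
tests compare against. Land cells are excluded from both mean and sd
(concentration is undefined over land); a neighbourhood with no eligible
cell yields NA with a flag. Crossing windows classify months as open at
or above a 70% concentration threshold, the minimum cover associated
with *Rangifer* sea-ice crossings. Event medians and interval bounds map
to the nearest 1 ka slice with exact half-ka ties resolved toward the
*older* slice — conservative toward the pre-event ice state.

## What the synthetic generators emulate — and what they do not

`synth_sequence_dataset` produces alignments simulated under a known
scenario at known parameter values, with truth files as first-class
outputs. `synth_ice_field` builds
$\mathrm{clip}(\mathrm{base} + \mathrm{trend}\cdot t +
A\cos(2\pi(m - m_0)/12) + g\,x + \varepsilon,\,0,\,1)$ — a linear
glacial trend, a seasonal cycle peaking in late winter, a spatial
gradient and iid noise, with a land mask. These emulate the *structure*
of the real inputs (GenBank-derived alignments; climate-model snapshot
climatologies), not their content: no selection, no recombination (a
safe assumption for mtDNA), no sequencing error, perfectly known
population labels, and ice fields without coastline geometry, drift or
interannual variability. Green tests therefore demonstrate correctness
of the algorithms under the stated models, not that the published
biological estimates are recoverable from scratch — those depend on the
archived accession lists and climate-model grids, which the package
consumes but does not ship.

## Numerical choices and degenerate inputs

* Trimming keeps the longest contiguous block of columns free of `-`,
  `N` and `?` in every sequence (first such block on ties); sequences
  with IUPAC ambiguity codes inside the block are dropped with a
  warning, never imputed.
* Segregating sites are columns with ≥ 2 distinct states among retained
  samples.
* Constant statistic columns are dropped (with a warning) before PCA /
  LDA; forests tolerate them.
* A parameter constant across the reference table returns a degenerate
  interval equal to the constant.
* Rejection sampling reports an unsatisfiable constraint set after a
  bounded number of rounds instead of looping forever; satisfiability on
  prior bounds is also checked statically during validation.
* Seeds: every stochastic entry point takes or derives from an explicit
  integer seed; per-row seeds are mixed through a 32-bit LCG-style hash
  kept below $2^{31}$.

## Problem sizes used by the test suite

The full-scale study design (100,000 simulations per model set) is the
field convention, not a package requirement. The shipped tests run the
same algorithms at reduced, fixed sizes chosen to keep the whole suite
comfortably interactive while leaving Monte Carlo error well inside the
asserted tolerances: 20,000 replicates for coalescent expectations,
5,000 for the Wright–Fisher comparison, 5,000 simulations per scenario
(500 trees, 50 pseudo-observed datasets) for the model-choice
self-consistency experiment, and a shared 2,000-row reference table with
100 replicate observations for credible-interval coverage. The
acceptance script repeats the same computations at moderately smaller
sizes under a caller-supplied seed.

## Known limitations

* Single non-recombining locus: parameter posteriors are wide, and
  bottleneck durations are near-unidentifiable (by design they stay as
  priors).
* Pulse admixture only; continuous migration is out of scope.
* The summary-statistic list is fixed but deliberately configurable in
  code; statistic-for-statistic equality with any particular external
  ABC software is not a goal.
* The equal-area projection is spherical; at the 30 km nominal cell
  size the ellipsoidal correction is negligible relative to the
  1000-km-scale extraction radii.
* Reported posterior probabilities inherit the usual ABC-RF behaviour:
  they are calibrated by out-of-bag regression, not exact Bayesian
  posteriors.
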