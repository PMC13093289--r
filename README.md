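# coalice

Coalescent ABC inference of Arctic island colonisation histories from
mitochondrial control-region sequences, with paleo sea-ice comparison.

## The problem

When did island populations of ice-associated ungulates (*Rangifer* —
reindeer/caribou) colonise Arctic archipelagos, and do the inferred
divergence and admixture times line up with periods when sea ice was
extensive enough (≥ 70% cover) to walk across? Answering this from short
mitochondrial control-region alignments requires: summarising diversity
and differentiation, proposing explicit demographic scenarios
(divergence, pulse admixture, founder bottlenecks, serially sampled
ancient populations), simulating large reference tables under those
scenarios, choosing among scenarios and estimating event times with
random-forest ABC, and finally overlaying the dated events on gridded
paleoclimate sea-ice reconstructions.

`coalice` packages that whole pipeline for R, tidyverse-style: data
frames in, tibbles out, `autoplot()` for every result type, and
broom-style `tidy()`/`glance()` for fitted objects. A synthetic-data
module generates sequence datasets with known truth, herd coordinate
tables and seasonal gridded ice fields, so every stage is testable
end-to-end without downloads.

## The model in brief

* **Coalescent**: backward in time, k lineages in a population of haploid
  size N coalesce at rate k(k−1)/(2N) per generation; lineages of
  ancient samples enter at their sampling age (e.g. 502 generations for
  subfossils). Divergence merges a daughter into its parent; admixture
  moves each recipient lineage to the donor with probability r; a
  founder bottleneck holds the daughter at size N_b for d_b generations
  after founding.
* **Mutation**: HKY with transition/transversion parameter κ and base
  frequencies π, continuous gamma(α) site rates, proportion p_inv of
  invariable sites; exact transition probabilities per branch (multiple
  hits handled exactly).
* **ABC-RF**: classification forest (500 trees) over a fixed-order
  summary-statistic vector augmented with LDA axes; posterior
  probability of the selected scenario by out-of-bag regression of the
  correct-classification indicator; parameter posteriors by quantile
  regression forests (median and 95% CI), converted to calendar years at
  7 years/generation.
* **Sea ice**: event locations as centroids of herd centroids, 100
  random points in a 100 km buffer, concentration extracted from
  non-land cells within a set radius on a 30 km Lambert azimuthal
  equal-area grid, per month and 1 ka slice; months with mean cover
  ≥ 70% count as open for crossing; events map to the nearest slice
  (half-ka ties toward the older slice).

See `vignettes/coalice-methods.Rmd` for assumptions, parameter meanings,
defaults, and numerical conventions.

## Worked example

Two competing hypotheses for an island population — postglacial
colonisation (divergence prior U(100, 1500) generations) versus an older
glacial-refugium split (U(3000, 12000)) — tested against a synthetic
"observed" dataset whose true history is a postglacial split at 800
generations:

```r
library(coalice)

recent <- scenario("postglacial",
  populations = list(pop_spec("Mainland", ne = 1000, sample_size = 10),
                     pop_spec("Island",   ne = 1000, sample_size = 10)),
  events = list(event_divergence("split", daughter = "Island",
                                 parent = "Mainland",
                                 time = prior_uniform(100, 1500))),
  mutation = hky_model(mu = 1e-5, kappa = 2, pi = c(0.3, 0.2, 0.2, 0.3),
                       alpha = 0.5),
  L = 300)
glacial <- recent
glacial$id <- "glacial_refugium"
glacial$events[[1]]$time <- prior_uniform(3000, 12000)

truth <- sample_parameters(recent, 1, seed = 1)
truth$t_split <- 800
obs <- summarize_alignment(
  synth_sequence_dataset(recent, truth = truth, seed = 42)$alignment)

rt <- build_reference_table(list(recent, glacial), n_per_scenario = 1000,
                            seed = 7)
mc <- abc_model_choice(rt, obs, n_trees = 500, seed = 7)
glance(mc)
#> # A tibble: 1 × 5
#>   selected    posterior global_error local_error n_trees
#>   <chr>           <dbl>        <dbl>       <dbl>   <dbl>
#> 1 postglacial         1        0.038           0     500

est <- abc_estimate_parameter(rt[rt$scenario == "postglacial", ], obs,
                              "t_split", n_trees = 500, seed = 7)
generations_to_years(est)[, c("median", "ci_lower", "ci_upper",
                              "ka", "ka_rounded")]
#> # A tibble: 1 × 5
#>   median ci_lower ci_upper    ka ka_rounded
#>    <dbl>    <dbl>    <dbl> <dbl>      <dbl>
#> 1   662.     228.    1455.  4.63        4.6
```

Reading the output: the classification forest selects the postglacial
scenario with posterior probability ≈ 1 (out-of-bag prior error 3.8%),
and the quantile regression forest dates the split at a posterior median
of 662 generations (95% CI 228–1455), i.e. 4.6 ka at 7
years/generation — the interval covers the true value of 800 generations
(5.6 ka). With a single short locus and a 1000-row table the interval is
wide; full-scale analyses use 100,000-row tables.

Sea-ice overlay on a synthetic field:

```r
fld <- synth_ice_field(times_ka = 24:0)  # pole-centred 1200 km grid
pts <- event_buffer_points(
  synth_herd_locations(tibble::tibble(population = c("Mainland", "Island"),
                                      lon = c(60, 64), lat = c(86, 88.5))),
  populations = c("Mainland", "Island"), buffer_km = 100, n_points = 100,
  proj = list(lon0 = 62, lat0 = 90))
ser <- extract_ice_series(fld, pts$points, radius_km = 300)
crossing_window(ser, threshold = 0.70)
autoplot(ser, events = data.frame(event = "split", kind = "divergence",
                                  median_ka = 4.6, ci_lower_ka = 1.6,
                                  ci_upper_ka = 10.2))
```

Example scenario documents (illustrative priors) for a four-population
archipelago model set and a three-population stepwise-colonisation model
set ship under `inst/extdata/model_sets/` and load with
`read_scenario()`.

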