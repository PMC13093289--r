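small_pair <- function(n_per_pop = 6, L = 120) {
  list(split_scenario(100, n_per_pop = n_per_pop, L = L, mu = 2e-5,
                      id = "recent"),
       split_scenario(8000, n_per_pop = n_per_pop, L = L, mu = 2e-5,
                      id = "old"))
}

test_that("reference tables are balanced and deterministic", {
  scns <- small_pair()
  rt <- build_reference_table(scns, n_per_scenario = 25, seed = 7)
  expect_equal(nrow(rt), 50L)
  expect_equal(as.vector(table(rt$scenario)), c(25L, 25L))
  expect_true(all(c("param_t_split", "param_Ne_A") %in% names(rt)))
  # per-row seeding: rebuilding gives the identical table
  rt2 <- build_reference_table(scns, n_per_scenario = 25, seed = 7)
  expect_equal(as.data.frame(rt), as.data.frame(rt2))
  # and a subset-sized build reproduces its rows (chunking independence)
  rt3 <- build_reference_table(scns, n_per_scenario = 10, seed = 7)
  expect_equal(as.data.frame(rt3[rt3$scenario == "recent", ]),
               as.data.frame(rt[rt$scenario == "recent", ][1:10, ]))
})

test_that("reference tables round-trip through TSV + JSON sidecar", {
  rt <- build_reference_table(small_pair(), n_per_scenario = 10, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_reference_table(rt, path)
  back <- read_reference_table(path)
  expect_equal(as.data.frame(back), as.data.frame(rt), tolerance = 1e-12)
  expect_equal(attr(back, "stat_names"), attr(rt, "stat_names"))
})

test_that("prior predictive check flags far-away observations", {
  rt <- build_reference_table(small_pair(), n_per_scenario = 60, seed = 11)
  obs_in <- rt[5, ]
  suppressWarnings({
    pp <- prior_predictive_check(rt, obs_in, n_display = 60, seed = 1)
  })
  expect_true(pp$report$inside_hull[pp$report$scenario == "recent"])
  # shift the observation 10 SD along every statistic
  stats <- attr(rt, "stat_names")
  obs_out <- obs_in
  for (s in stats) {
    obs_out[[s]] <- obs_out[[s]] + 10 * max(sd(rt[[s]]), 1)
  }
  suppressWarnings({
    pp2 <- prior_predictive_check(rt, obs_out, n_display = 60, seed = 1)
  })
  expect_false(any(pp2$report$inside_hull))
  expect_false(any(pp2$report$inside_box))
})

test_that("model choice separates well-separated scenarios and reports votes", {
  scns <- small_pair()
  rt <- build_reference_table(scns, n_per_scenario = 150, seed = 5)
  obs <- dplyr::bind_rows(lapply(1:4, function(i)
    summarize_alignment(simulate_dataset(scns[[2]],
                                         seed = 9000 + i)$alignment)))
  mc <- abc_model_choice(rt, obs, n_trees = 200, seed = 2)
  expect_true(all(mc$selected == "old"))
  votes <- tidyr::pivot_wider(mc$votes, names_from = "scenario",
                              values_from = "vote_fraction")
  expect_equal(votes$old + votes$recent, rep(1, 4), tolerance = 1e-12)
  expect_true(all(mc$posterior >= 0 & mc$posterior <= 1))
  expect_lt(mc$global_error, 0.2)
  expect_equal(mc$local_error, 1 - mc$posterior)
})

test_that("indistinguishable scenarios give symmetric votes and chance-level error", {
  base <- split_scenario(500, n_per_pop = 6, L = 120, mu = 2e-5, id = "s1")
  twin <- base
  twin$id <- "s2"
  rt <- build_reference_table(list(base, twin), n_per_scenario = 200,
                              seed = 19)
  obs <- dplyr::bind_rows(lapply(1:10, function(i)
    summarize_alignment(simulate_dataset(base, seed = 7000 + i)$alignment)))
  mc <- abc_model_choice(rt, obs, n_trees = 300, seed = 3)
  mean_vote <- mean(mc$votes$vote_fraction[mc$votes$scenario == "s1"])
  expect_lt(abs(mean_vote - 0.5), 0.12)
  # global error approximately (K-1)/K for K = 2
  expect_lt(abs(mc$global_error - 0.5), 0.1)
})

test_that("a parameter fixed across the table returns a degenerate interval", {
  scns <- small_pair()
  rt <- build_reference_table(scns[1], n_per_scenario = 30, seed = 2)
  obs <- summarize_alignment(simulate_dataset(scns[[1]], seed = 1)$alignment)
  est <- abc_estimate_parameter(rt, obs, "t_split", n_trees = 50, seed = 1)
  expect_true(est$degenerate)
  expect_equal(est$estimates$median, 100)
  expect_equal(est$estimates$ci_lower, 100)
  expect_equal(est$estimates$ci_upper, 100)
})

test_that("quantile forests bracket the truth on an informative parameter", {
  scn <- split_scenario(prior_uniform(100, 5000), n_per_pop = 8, L = 200,
                        mu = 2e-5, id = "free")
  rt <- build_reference_table(scn, n_per_scenario = 400, seed = 23)
  truth <- sample_parameters(scn, 1, seed = 6)
  truth$t_split <- 1500
  obs <- summarize_alignment(simulate_dataset(scn, draw = truth,
                                              seed = 55)$alignment)
  est <- abc_estimate_parameter(rt, obs, "t_split", n_trees = 200, seed = 4)
  e <- est$estimates
  expect_true(e$ci_lower <= e$median & e$median <= e$ci_upper)
  expect_gt(est$global_nmae, 0)
  # the 95% interval is informative: narrower than the prior range
  expect_lt(e$ci_upper - e$ci_lower, 4900)
})

test_that("time conversion applies the generation time exactly", {
  expect_equal(generations_to_years(0)$years, 0)
  expect_equal(generations_to_years(502)$years, 3514)
  out <- generations_to_years(1529)
  expect_equal(out$ka, 10.703)
  expect_equal(out$ka_rounded, 10.7)
  est <- tibble::tibble(median = 1000, ci_lower = 500, ci_upper = 2000)
  yr <- generations_to_years(est, generation_time = 7)
  expect_equal(yr$years_lower, 3500)
  expect_equal(yr$years_upper, 14000)
  expect_error(generations_to_years(100, generation_time = 0), "positive")
})

test_that("tidy and glance methods return well-formed tibbles", {
  scns <- small_pair()
  rt <- build_reference_table(scns, n_per_scenario = 40, seed = 9)
  obs <- summarize_alignment(simulate_dataset(scns[[1]], seed = 3)$alignment)
  mc <- abc_model_choice(rt, obs, n_trees = 100, seed = 1)
  expect_s3_class(tidy(mc), "tbl_df")
  expect_named(glance(mc), c("selected", "posterior", "global_error",
                             "local_error", "n_trees"))
  est <- abc_estimate_parameter(rt[rt$scenario == "recent", ], obs, "Ne_A",
                                n_trees = 50, seed = 1)
  expect_s3_class(tidy(est), "tbl_df")
  p <- autoplot(mc)
  expect_s3_class(p, "ggplot")
})
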