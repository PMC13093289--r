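test_that("pairwise coalescence time averages N in a haploid population", {
  scn <- one_pop_scenario(2, ne = 1000)
  set.seed(21)
  t2 <- replicate(5000, max(simulate_genealogy(scn,
                                               list(Ne_A = 1000))$node_times))
  se <- sd(t2) / sqrt(length(t2))
  expect_lt(abs(mean(t2) - 1000), 3 * se)
})

test_that("no cross-population coalescence predates the divergence", {
  scn <- split_scenario(500, n_per_pop = 5, L = 10)
  draw <- sample_parameters(scn, 1, seed = 4)
  set.seed(8)
  for (i in 1:200) {
    gen <- simulate_genealogy(scn, draw)
    spans <- node_spans_populations(gen)
    internal_times <- gen$node_times[gen$merges[, 3]]
    expect_true(all(internal_times[spans > 1] >= 500))
  }
})

test_that("a serially sampled lineage never coalesces before its age", {
  scn <- split_scenario(1500, n_per_pop = 4, L = 10, age_B = 502)
  draw <- sample_parameters(scn, 1, seed = 4)
  set.seed(31)
  for (i in 1:300) {
    gen <- simulate_genealogy(scn, draw)
    ages <- first_coalescence_ages(gen)
    expect_true(all(ages[gen$leaf_age == 502] >= 502))
  }
})

test_that("the continuous coalescent matches a Wright-Fisher oracle (KS)", {
  N <- 100; n <- 10
  scn <- one_pop_scenario(n, ne = N)
  set.seed(13)
  cont <- replicate(2000, max(simulate_genealogy(scn,
                                                 list(Ne_A = N))$node_times))
  wf <- replicate(2000, wf_tmrca(n, N))
  ks <- suppressWarnings(stats::ks.test(cont, wf))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(cont) - 2 * N * (1 - 1 / n)), 4 * sd(cont) / sqrt(2000))
})

test_that("closed-form HKY transition probabilities match a matrix exponential", {
  pi <- c(A = 0.32, C = 0.25, G = 0.13, T = 0.30)
  kappa <- 10
  # independent oracle: eigendecomposition of the normalised rate matrix
  Q <- matrix(0, 4, 4, dimnames = list(names(pi), names(pi)))
  for (i in 1:4) for (j in 1:4) if (i != j) {
    both_purine <- all(names(pi)[c(i, j)] %in% c("A", "G"))
    both_pyrim <- all(names(pi)[c(i, j)] %in% c("C", "T"))
    Q[i, j] <- ifelse(both_purine || both_pyrim, kappa, 1) * pi[j]
  }
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(-pi * diag(Q))
  ee <- eigen(Q)
  P_oracle <- function(d) Re(ee$vectors %*% diag(exp(ee$values * d)) %*%
                               solve(ee$vectors))
  for (d in c(0.001, 0.1, 1, 10, 100)) {
    Pe <- P_oracle(d)
    Pc <- t(sapply(names(pi), function(s)
      coalice:::hky_prob_row(s, d, pi, kappa)[1, ]))
    expect_lt(max(abs(Pe - Pc)), 1e-12)
    expect_equal(rowSums(Pc), rep(1, 4), ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
})

test_that("zero mutation rate yields monomorphic sequences", {
  scn <- one_pop_scenario(6, ne = 500, L = 40, mu = 0)
  sim <- simulate_dataset(scn, seed = 5)
  expect_equal(collapse_haplotypes(sim$alignment)$n_haplotypes, 1L)
})

test_that("segregating sites track the expected mutation count at low theta", {
  mu <- 2e-6; L <- 200; p_inv <- 0.3
  scn <- scenario("s", list(pop_spec("A", 1000, 8)), list(),
                  hky_model(mu = mu, alpha = 1, p_inv = p_inv), L = L)
  set.seed(17)
  S <- numeric(400); TL <- numeric(400)
  for (i in 1:400) {
    gen <- simulate_genealogy(scn, list(Ne_A = 1000, mu = mu))
    aln <- simulate_sequences(gen, scn$mutation, L)
    S[i] <- collapse_haplotypes(aln)$n_segregating_sites
    TL[i] <- gen$tree_length
  }
  expected <- mu * L * mean(TL) * (1 - p_inv)
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - expected), 4 * se)
})

test_that("base composition converges to the stationary frequencies", {
  pi <- c(A = 0.32, C = 0.25, G = 0.13, T = 0.30)
  model <- hky_model(mu = 1, kappa = 10, pi = pi, alpha = 1e9)
  # two leaves hanging off a root at a huge distance
  gen <- structure(list(
    n_leaves = 2L, leaf_ids = c("x", "y"), leaf_pop = c("P", "P"),
    leaf_age = c(0, 0), merges = matrix(c(1L, 2L, 3L), 1, 3),
    node_times = c(0, 0, 50), tree_length = 100), class = "coal_genealogy")
  set.seed(23)
  aln <- simulate_sequences(gen, model, L = 20000)
  freqs <- table(factor(aln$seqs[1, ], levels = c("A", "C", "G", "T")))
  chi <- suppressWarnings(stats::chisq.test(freqs, p = pi))
  expect_gt(chi$p.value, 0.01)
})

test_that("gamma rate heterogeneity collapses when alpha is huge", {
  model <- hky_model(mu = 0.01, alpha = 1e9, p_inv = 0)
  gen <- structure(list(
    n_leaves = 2L, leaf_ids = c("x", "y"), leaf_pop = c("P", "P"),
    leaf_age = c(0, 0), merges = matrix(c(1L, 2L, 3L), 1, 3),
    node_times = c(0, 0, 10), tree_length = 20), class = "coal_genealogy")
  set.seed(2)
  aln <- simulate_sequences(gen, model, L = 500)
  rates <- attr(aln, "site_rates")
  expect_lt(var(rates), 1e-6)
})

test_that("genealogies export to valid phylo / Newick", {
  scn <- split_scenario(800, n_per_pop = 4, L = 10)
  sim <- simulate_dataset(scn, seed = 9)
  phy <- genealogy_to_phylo(sim$genealogy)
  expect_s3_class(phy, "phylo")
  expect_equal(ape::Ntip(phy), 8L)
  expect_true(ape::is.rooted(phy))
  expect_true(ape::is.ultrametric(phy, tol = 1e-6))
  nwk <- ape::write.tree(phy)
  expect_match(nwk, "^\\(")
  # branch lengths reconstruct node depths
  depths <- ape::node.depth.edgelength(phy)
  expect_equal(max(depths), max(sim$genealogy$node_times), tolerance = 1e-9)
})
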