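# in-code fixtures shared across test files

`%||%` <- function(x, y) if (is.null(x)) y else x

# tiny alignment: n sequences over given strings, two populations
toy_alignment <- function(strings, pops = NULL, ages = NULL, ids = NULL) {
  n <- length(strings)
  ids <- ids %||% paste0("s", seq_len(n))
  pops <- pops %||% rep("P1", n)
  ages <- ages %||% rep(0, n)
  # one age per population
  seqs <- do.call(rbind, strsplit(toupper(strings), ""))
  rownames(seqs) <- ids
  coal_alignment(seqs, tibble::tibble(
    id = ids, population = pops, lon = 0, lat = 70, age_generations = ages))
}

# haplotype table straight from a count matrix (haplotype x population)
toy_haplotypes <- function(counts, L = 10) {
  k <- nrow(counts)
  # distinct dummy sequences, one variant column per haplotype
  haps <- vapply(seq_len(k), function(i) {
    s <- rep("A", L)
    s[seq_len(min(i, L))] <- "C"
    paste0(s, collapse = "")
  }, character(1))
  names(haps) <- paste0("H", seq_len(k))
  rownames(counts) <- names(haps)
  structure(list(haplotype_seqs = haps, counts = counts,
                 n_haplotypes = k, n_segregating_sites = NA_integer_,
                 L = L, pop_ages = setNames(rep(0, ncol(counts)),
                                            colnames(counts))),
            class = "coal_haplotypes")
}

# single-population scenario for coalescent checks
one_pop_scenario <- function(n, ne = 1000, L = 10, mu = 1e-5) {
  scenario("one", list(pop_spec("A", ne, n)), list(),
           hky_model(mu = mu), L = L)
}

# two populations diverging at a fixed time
split_scenario <- function(t_div, n_per_pop = 10, ne = 1000, L = 300,
                           mu = 1e-5, id = "split", age_B = 0) {
  scenario(id,
           list(pop_spec("A", ne, n_per_pop),
                pop_spec("B", ne, n_per_pop, sampling_age = age_B)),
           list(event_divergence("split", "B", "A", t_div)),
           hky_model(mu = mu, kappa = 2, pi = c(0.3, 0.2, 0.2, 0.3),
                     alpha = 0.5),
           L = L)
}

# ages (backward times) at which each leaf's lineage first coalesces
first_coalescence_ages <- function(gen) {
  n <- gen$n_leaves
  parent <- integer(2L * n - 1L)
  parent[gen$merges[, 1L]] <- gen$merges[, 3L]
  parent[gen$merges[, 2L]] <- gen$merges[, 3L]
  gen$node_times[parent[seq_len(n)]]
}

# populations spanned by each internal node's descendant leaves
node_spans_populations <- function(gen) {
  n <- gen$n_leaves
  desc <- c(as.list(seq_len(n)), vector("list", n - 1L))
  for (j in seq_len(n - 1L)) {
    node <- gen$merges[j, 3L]
    desc[[node]] <- c(desc[[gen$merges[j, 1L]]], desc[[gen$merges[j, 2L]]])
  }
  vapply(seq_len(n - 1L), function(j) {
    leaves <- desc[[gen$merges[j, 3L]]]
    length(unique(gen$leaf_pop[leaves]))
  }, integer(1))
}

# discrete-generation Wright-Fisher TMRCA oracle (haploid size N)
wf_tmrca <- function(n, N) {
  lineages <- seq_len(n)
  g <- 0L
  while (length(unique(lineages)) > 1L) {
    g <- g + 1L
    parents <- sample.int(N, N, replace = TRUE)
    lineages <- parents[lineages]
  }
  g
}
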