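#' Simulate a genealogy under a demographic scenario (structured coalescent)
#'
#' Continuous-time structured coalescent with serial sampling. Within a
#' population of haploid size N, k active lineages coalesce at rate
#' k(k-1)/(2N) per generation. Lineages enter the process at their
#' population's sampling age; backward in time, divergence events move the
#' daughter's lineages into the parent, admixture pulses reassign each
#' recipient lineage to the donor with probability r, and founder
#' bottlenecks set the population size to Nb over backward ages
#' `[t - db, t]`.
#'
#' @param scn a validated `coal_scenario`.
#' @param draw a 1-row tibble / named numeric of parameter values (from
#'   [sample_parameters()]).
#' @return A `coal_genealogy`: list with `n_leaves`, `leaf_ids`,
#'   `leaf_pop`, `leaf_age`, `merges` (matrix (n-1) x 3: child1, child2,
#'   internal node id), `node_times` (length 2n-1; leaves first), and
#'   `tree_length` (sum of branch lengths in generations).
#' @export
simulate_genealogy <- function(scn, draw) {
  draw <- as.list(draw)
  labels <- vapply(scn$populations, `[[`, character(1), "label")
  npop <- length(labels)
  ne <- vapply(labels, function(l) draw[[paste0("Ne_", l)]], numeric(1))
  if (any(ne <= 0)) abort("effective sizes must be positive")

  # leaves
  sizes <- vapply(scn$populations, `[[`, integer(1), "sample_size")
  ages <- vapply(scn$populations, `[[`, numeric(1), "sampling_age")
  n <- sum(sizes)
  leaf_pop <- rep(seq_len(npop), sizes)
  leaf_age <- rep(ages, sizes)
  leaf_ids <- paste0(rep(labels, sizes), "_",
                     unlist(lapply(sizes, seq_len)))

  # breakpoint schedule (backward time, ascending)
  ev <- list()
  push <- function(time, type, ...) ev[[length(ev) + 1L]] <<-
    list(time = time, type = type, ...)
  for (j in seq_len(npop)) {
    if (ages[j] > 0) push(ages[j], "activate", pop = j)
  }
  for (e in scn$events) {
    t_e <- draw[[paste0("t_", e$name)]]
    if (e$kind == "divergence") {
      push(t_e, "divergence", from = match(e$daughter, labels),
           to = match(e$parent, labels))
    } else if (e$kind == "admixture") {
      push(t_e, "admixture", from = match(e$recipient, labels),
           to = match(e$donor, labels), rate = draw[[paste0("r_", e$name)]])
    } else if (e$kind == "bottleneck") {
      j <- match(e$population, labels)
      nb <- draw[[paste0("Nb_", e$name)]]
      db <- draw[[paste0("db_", e$name)]]
      push(max(0, t_e - db), "size", pop = j, size = nb)
      push(t_e, "size", pop = j, size = ne[j])
    }
  }
  ord <- order(vapply(ev, `[[`, numeric(1), "time"))
  ev <- ev[ord]
  ev_times <- vapply(ev, `[[`, numeric(1), "time")

  # state
  node_times <- c(leaf_age, rep(NA_real_, n - 1L))
  merges <- matrix(NA_integer_, n - 1L, 3L)
  active_id <- which(leaf_age == 0)
  active_pop <- leaf_pop[active_id]
  pending <- sum(leaf_age > 0)
  n_cur <- ne
  alive <- rep(TRUE, npop)
  t <- 0
  ev_i <- 1L
  m <- 0L
  next_node <- n

  while (length(active_id) + pending > 1L) {
    k <- tabulate(active_pop, npop)
    rates <- ifelse(k >= 2L, k * (k - 1) / (2 * n_cur), 0)
    total <- sum(rates)
    t_ev <- if (ev_i <= length(ev)) ev_times[ev_i] else Inf
    t_c <- if (total > 0) t + rexp(1L, total) else Inf
    if (t_c < t_ev) {
      # coalescence
      j <- sample.int(npop, 1L, prob = rates)
      in_pop <- which(active_pop == j)
      pair <- in_pop[sample.int(length(in_pop), 2L)]
      m <- m + 1L
      next_node <- next_node + 1L
      node_times[next_node] <- t_c
      merges[m, ] <- c(active_id[pair[1L]], active_id[pair[2L]], next_node)
      active_id <- c(active_id[-pair], next_node)
      active_pop <- c(active_pop[-pair], j)
      t <- t_c
    } else if (is.infinite(t_ev)) {
      abort("scenario never coalesces: lineages remain in isolated populations")
    } else {
      e <- ev[[ev_i]]
      t <- t_ev
      if (e$type == "activate") {
        ids <- which(leaf_age > 0 & leaf_pop == e$pop &
                       leaf_age == t)
        if (!alive[e$pop]) abort("samples activate in an already-merged population")
        active_id <- c(active_id, ids)
        active_pop <- c(active_pop, rep(e$pop, length(ids)))
        pending <- pending - length(ids)
      } else if (e$type == "divergence") {
        active_pop[active_pop == e$from] <- e$to
        alive[e$from] <- FALSE
      } else if (e$type == "admixture") {
        idx <- which(active_pop == e$from)
        move <- idx[runif(length(idx)) < e$rate]
        active_pop[move] <- e$to
      } else if (e$type == "size") {
        n_cur[e$pop] <- e$size
      }
      ev_i <- ev_i + 1L
    }
  }

  # tree length: every non-root node contributes (t_parent - t_node)
  parent <- integer(2L * n - 1L)
  parent[merges[, 1L]] <- merges[, 3L]
  parent[merges[, 2L]] <- merges[, 3L]
  nonroot <- seq_len(2L * n - 2L)
  tree_length <- sum(node_times[parent[nonroot]] - node_times[nonroot])

  structure(list(n_leaves = n, leaf_ids = leaf_ids,
                 leaf_pop = labels[leaf_pop], leaf_age = leaf_age,
                 merges = merges, node_times = node_times,
                 tree_length = tree_length),
            class = "coal_genealogy")
}

#' @export
print.coal_genealogy <- function(x, ...) {
  cat("<coal_genealogy> ", x$n_leaves, " leaves; TMRCA = ",
      format(max(x$node_times), digits = 5), " generations\n", sep = "")
  invisible(x)
}

#' Convert a genealogy to an ape `phylo` (and Newick)
#'
#' @param gen a `coal_genealogy`.
#' @return An `ape::phylo` with branch lengths in generations.
#' @export
genealogy_to_phylo <- function(gen) {
  n <- gen$n_leaves
  # ape numbering: tips 1..n, root n+1; our internal nodes n+1..2n-1 are in
  # merge order (root last), so internal node j maps to 2n - (j - n)
  remap <- function(v) ifelse(v <= n, v, 2L * n - (v - n))
  edge <- rbind(cbind(remap(gen$merges[, 3L]), remap(gen$merges[, 1L])),
                cbind(remap(gen$merges[, 3L]), remap(gen$merges[, 2L])))
  child_orig <- c(gen$merges[, 1L], gen$merges[, 2L])
  parent_orig <- c(gen$merges[, 3L], gen$merges[, 3L])
  len <- gen$node_times[parent_orig] - gen$node_times[child_orig]
  phy <- structure(list(edge = edge, edge.length = len,
                        tip.label = gen$leaf_ids, Nnode = n - 1L),
                   class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

# ---- HKY transition probabilities -----------------------------------------

# closed-form HKY P(d) as a function of expected substitutions d (the rate
# matrix is normalised to mean substitution rate 1 at stationarity), for a
# given parent state; vectorised over d. Returns an length(d) x 4 matrix.
hky_prob_row <- function(parent, d, pi, kappa) {
  piR <- pi["A"] + pi["G"]
  piY <- pi["C"] + pi["T"]
  beta <- 1 / (2 * (kappa * (pi["A"] * pi["G"] + pi["C"] * pi["T"]) + piR * piY))
  e1 <- exp(-beta * d)
  grp <- c(A = "R", C = "Y", G = "R", T = "Y")
  out <- matrix(0, length(d), 4L, dimnames = list(NULL, nucleotides))
  gi <- grp[parent]
  Pi <- if (gi == "R") piR else piY
  e2 <- exp(-d * beta * (Pi * kappa + (1 - Pi)))
  for (j in nucleotides) {
    pj <- pi[j]
    if (grp[j] != gi) {
      out[, j] <- pj * (1 - e1)
    } else if (j == parent) {
      out[, j] <- pj + pj * (1 / Pi - 1) * e1 + ((Pi - pj) / Pi) * e2
    } else {
      out[, j] <- pj + pj * (1 / Pi - 1) * e1 - (pj / Pi) * e2
    }
  }
  out
}

# sample child states given parent states (integer 1..4) and per-site
# expected substitution counts d (vector)
hky_evolve <- function(parent_states, d, pi, kappa) {
  child <- parent_states
  for (s in 1:4) {
    idx <- which(parent_states == s & d > 0)
    if (!length(idx)) next
    pr <- hky_prob_row(nucleotides[s], d[idx], pi, kappa)
    u <- runif(length(idx))
    cs <- 1L + (u > pr[, 1L]) + (u > pr[, 1L] + pr[, 2L]) +
      (u > pr[, 1L] + pr[, 2L] + pr[, 3L])
    child[idx] <- cs
  }
  child
}

#' Evolve sequences along a genealogy under HKY+Gamma+I
#'
#' Root states are drawn from the stationary base frequencies. Each site
#' is invariable with probability `p_inv` (rate 0) and otherwise carries a
#' continuous gamma(alpha, mean 1) rate multiplier. Child states are
#' sampled from the exact HKY transition-probability matrix at distance
#' `mu * branch_length * rate`, so multiple substitutions at a site are
#' modelled exactly rather than by event placement.
#'
#' @param gen a `coal_genealogy`.
#' @param model a [hky_model()]; `mu` must be fixed or supplied via `mu`.
#' @param L sequence length in bp.
#' @param mu optional numeric override of the mutation rate (per site per
#'   generation), e.g. a drawn value.
#' @return A [coal_alignment()] of the leaf sequences (population labels
#'   and sampling ages from the genealogy; coordinates NA).
#' @export
simulate_sequences <- function(gen, model, L, mu = NULL) {
  if (L < 1) abort("parameter error: L must be >= 1")
  mu <- mu %||% (if (model$mu$dist == "fixed") model$mu$value else
    abort("mu has a prior; supply the drawn value via `mu`"))
  if (mu < 0) abort("parameter error: mu must be non-negative")
  pi <- model$pi
  n <- gen$n_leaves
  L <- as.integer(L)
  rate <- rgamma(L, shape = model$alpha, rate = model$alpha)
  if (model$p_inv > 0) rate[runif(L) < model$p_inv] <- 0
  states <- matrix(NA_integer_, 2L * n - 1L, L)
  root <- 2L * n - 1L
  states[root, ] <- sample.int(4L, L, replace = TRUE, prob = pi)
  # parents are assigned before children when walking merges in reverse
  for (j in rev(seq_len(n - 1L))) {
    node <- gen$merges[j, 3L]
    for (child in gen$merges[j, 1:2]) {
      bl <- gen$node_times[node] - gen$node_times[child]
      d <- mu * bl * rate
      states[child, ] <- hky_evolve(states[node, ], d, pi, model$kappa)
    }
  }
  seqs <- decode_nuc(states[seq_len(n), , drop = FALSE])
  rownames(seqs) <- gen$leaf_ids
  meta <- tibble(id = gen$leaf_ids, population = gen$leaf_pop,
                 lon = NA_real_, lat = NA_real_,
                 age_generations = gen$leaf_age)
  out <- coal_alignment(seqs, meta, validated = TRUE)
  attr(out, "site_rates") <- rate
  out
}

#' Simulate one dataset under a scenario
#'
#' Convenience wrapper: draw (or accept) parameters, simulate a genealogy
#' and sequences, and return the alignment.
#'
#' @param scn a `coal_scenario`.
#' @param draw optional 1-row parameter draw; sampled from the priors when
#'   omitted.
#' @param seed optional integer seed.
#' @return A list with `alignment` (a [coal_alignment()]), `draw`, and
#'   `genealogy`.
#' @export
simulate_dataset <- function(scn, draw = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(draw)) draw <- sample_parameters(scn, 1L)
  gen <- simulate_genealogy(scn, draw)
  aln <- simulate_sequences(gen, scn$mutation, scn$L, mu = draw[["mu"]])
  list(alignment = aln, draw = draw, genealogy = gen)
}
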