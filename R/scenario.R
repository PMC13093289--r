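#' Prior specifications for scenario parameters
#'
#' Parameters of a demographic scenario (event times in generations,
#' haploid effective sizes, admixture rates, bottleneck sizes/durations,
#' mutation parameters) each carry a prior: uniform on the natural scale
#' (the default convention of ABC scenario software), log-uniform, a fixed
#' value, or a reference tying the parameter to another parameter's drawn
#' value (used e.g. to pin a founder bottleneck to its divergence time).
#'
#' @param min,max prior bounds (`min <= max`).
#' @param value fixed value.
#' @param name name of the referenced parameter.
#' @return A `coal_prior` list.
#' @export
prior_uniform <- function(min, max) {
  stopifnot(is.finite(min), is.finite(max), min <= max)
  structure(list(dist = "uniform", min = min, max = max), class = "coal_prior")
}

#' @rdname prior_uniform
#' @export
prior_loguniform <- function(min, max) {
  stopifnot(min > 0, min <= max)
  structure(list(dist = "loguniform", min = min, max = max), class = "coal_prior")
}

#' @rdname prior_uniform
#' @export
prior_fixed <- function(value) {
  structure(list(dist = "fixed", value = value), class = "coal_prior")
}

#' @rdname prior_uniform
#' @export
prior_ref <- function(name) {
  structure(list(dist = "ref", ref = name), class = "coal_prior")
}

as_prior <- function(x) {
  if (inherits(x, "coal_prior")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(prior_fixed(x))
  abort("expected a coal_prior or a single number")
}

prior_bounds <- function(p) {
  switch(p$dist,
         uniform = , loguniform = c(p$min, p$max),
         fixed = c(p$value, p$value),
         ref = c(NA_real_, NA_real_))
}

#' Population specification
#'
#' @param label population label.
#' @param ne haploid effective size (mtDNA copies): prior or fixed number.
#' @param sample_size number of sampled sequences.
#' @param sampling_age sampling time in generations before present
#'   (0 = modern; e.g. 502 for a subfossil population). All samples of a
#'   population share one age.
#' @return A list consumed by [scenario()].
#' @export
pop_spec <- function(label, ne, sample_size, sampling_age = 0) {
  stopifnot(sampling_age >= 0, sample_size >= 1)
  list(label = label, ne = as_prior(ne), sample_size = as.integer(sample_size),
       sampling_age = as.numeric(sampling_age))
}

#' Demographic events (backward in time)
#'
#' * `event_divergence`: at `time`, the daughter population's lineages
#'   merge into the parent population (the forward-time founding of the
#'   daughter from the parent).
#' * `event_admixture`: an instantaneous unidirectional introgression
#'   pulse; backward in time, each lineage of `recipient` moves to `donor`
#'   with probability `rate`.
#' * `event_bottleneck`: a founder bottleneck; the population has reduced
#'   size `nb` for the `db` generations following its founding, i.e. over
#'   backward ages `[time - db, time]` (`time` is usually tied to the
#'   founding divergence via [prior_ref()]).
#'
#' @param name event name; its parameters are registered as
#'   `t_<name>`, `r_<name>`, `Nb_<name>`, `db_<name>`.
#' @param daughter,parent,recipient,donor,population population labels.
#' @param time event time in generations before present (prior or number).
#' @param rate admixture rate prior/number in `[0, 1]`.
#' @param nb bottleneck (founder) size prior/number, > 0.
#' @param db bottleneck duration prior/number in generations, >= 1;
#'   default prior U(1, 50).
#' @return An event list consumed by [scenario()].
#' @export
event_divergence <- function(name, daughter, parent, time) {
  list(kind = "divergence", name = name, daughter = daughter, parent = parent,
       time = as_prior(time))
}

#' @rdname event_divergence
#' @export
event_admixture <- function(name, recipient, donor, time, rate) {
  list(kind = "admixture", name = name, recipient = recipient, donor = donor,
       time = as_prior(time), rate = as_prior(rate))
}

#' @rdname event_divergence
#' @export
event_bottleneck <- function(name, population, time, nb,
                             db = prior_uniform(1, 50)) {
  list(kind = "bottleneck", name = name, population = population,
       time = as_prior(time), nb = as_prior(nb), db = as_prior(db))
}

#' HKY+Gamma+I mutation model
#'
#' @param mu per-site per-generation mutation rate (prior or number).
#' @param kappa transition/transversion rate parameter.
#' @param pi base frequencies (A, C, G, T), summing to 1.
#' @param alpha gamma shape for among-site rate variation (mean-1 rates).
#' @param p_inv proportion of invariable sites in `[0, 1)`.
#' @return A `coal_mutmodel` list.
#' @export
hky_model <- function(mu, kappa = 2, pi = c(0.25, 0.25, 0.25, 0.25),
                      alpha = 0.5, p_inv = 0) {
  stopifnot(abs(sum(pi) - 1) < 1e-8, all(pi > 0), kappa > 0,
            alpha > 0, p_inv >= 0, p_inv < 1)
  structure(list(mu = as_prior(mu), kappa = kappa,
                 pi = setNames(as.numeric(pi), nucleotides),
                 alpha = alpha, p_inv = p_inv),
            class = "coal_mutmodel")
}

#' Define a demographic scenario
#'
#' A scenario is the hypothesis object of the ABC analysis: a set of
#' populations with priors on their haploid effective sizes, an ordered
#' (backward-in-time) list of divergence / admixture / bottleneck events
#' with priors on their times and rates, a mutation model, and the
#' sequence length. Order constraints between event-time parameters
#' (`t_a > t_b`) may be supplied explicitly; the constraints implied by
#' the topology (a parent population must outlive its daughter's
#' divergence, admixture must predate the extinction of both partners,
#' divergence must predate a population's own sampling age) are derived
#' automatically.
#'
#' @param id scenario identifier.
#' @param populations list of [pop_spec()].
#' @param events list of events ([event_divergence()] etc.).
#' @param mutation a [hky_model()].
#' @param L sequence length in bp.
#' @param constraints optional list of 2-vectors `c(larger, smaller)` of
#'   parameter names meaning `larger > smaller`.
#' @return A `coal_scenario` object.
#' @export
scenario <- function(id, populations, events, mutation, L,
                     constraints = list()) {
  stopifnot(L >= 1)
  labels <- vapply(populations, `[[`, character(1), "label")
  if (anyDuplicated(labels)) abort("duplicate population labels")
  structure(list(id = id, populations = populations, events = events,
                 mutation = mutation, L = as.integer(L),
                 constraints = constraints),
            class = "coal_scenario")
}

#' @export
print.coal_scenario <- function(x, ...) {
  cat("<coal_scenario> '", x$id, "': ", length(x$populations),
      " populations, ", length(x$events), " events, L = ", x$L, " bp\n",
      sep = "")
  invisible(x)
}

# parameter registry: name, prior, role
scenario_params <- function(scn) {
  out <- list()
  for (p in scn$populations) out[[paste0("Ne_", p$label)]] <- p$ne
  for (e in scn$events) {
    out[[paste0("t_", e$name)]] <- e$time
    if (e$kind == "admixture") out[[paste0("r_", e$name)]] <- e$rate
    if (e$kind == "bottleneck") {
      out[[paste0("Nb_", e$name)]] <- e$nb
      out[[paste0("db_", e$name)]] <- e$db
    }
  }
  for (m in c("mu", "kappa", "alpha", "p_inv")) {
    pr <- scn$mutation[[m]]
    out[[m]] <- if (inherits(pr, "coal_prior")) pr else prior_fixed(pr)
  }
  out
}

# constraints implied by the topology, as list(larger=, smaller=) where
# smaller may be a parameter name or a number
implied_constraints <- function(scn) {
  labels <- vapply(scn$populations, `[[`, character(1), "label")
  div_of <- list()  # population -> its divergence time parameter
  for (e in scn$events) {
    if (e$kind == "divergence") div_of[[e$daughter]] <- paste0("t_", e$name)
  }
  cons <- list()
  add <- function(larger, smaller) cons[[length(cons) + 1L]] <<-
    list(larger = larger, smaller = smaller)
  for (e in scn$events) {
    tname <- paste0("t_", e$name)
    if (e$kind == "divergence") {
      # parent must still exist: parent's own divergence is older
      if (!is.null(div_of[[e$parent]])) add(div_of[[e$parent]], tname)
      # daughter's samples must activate before it merges
      age <- scn$populations[[match(e$daughter, labels)]]$sampling_age
      if (age > 0) add(tname, age)
    }
    if (e$kind == "admixture") {
      for (pp in c(e$recipient, e$donor)) {
        if (!is.null(div_of[[pp]])) add(div_of[[pp]], tname)
      }
    }
  }
  for (cc in scn$constraints) add(cc[[1L]], cc[[2L]])
  cons
}

#' Validate a demographic scenario
#'
#' Checks structural invariants: every event references defined
#' populations, each population diverges at most once, the divergence
#' graph coalesces to a single ancestral root, admixture rates lie in
#' `[0, 1]`, bottleneck sizes/durations are positive, and the implied plus
#' explicit order constraints are jointly satisfiable on the prior bounds.
#'
#' @param scn a `coal_scenario`.
#' @return A list with `valid` (logical) and `errors` (character vector,
#'   machine-readable one-per-problem).
#' @export
validate_scenario <- function(scn) {
  errors <- character()
  labels <- vapply(scn$populations, `[[`, character(1), "label")
  refs <- function(e) switch(e$kind,
    divergence = c(e$daughter, e$parent),
    admixture = c(e$recipient, e$donor),
    bottleneck = e$population)
  for (e in scn$events) {
    bad <- setdiff(refs(e), labels)
    if (length(bad)) {
      errors <- c(errors, paste0("event '", e$name,
                                 "' references undefined population(s): ",
                                 paste(bad, collapse = ", ")))
    }
  }
  divs <- Filter(function(e) e$kind == "divergence", scn$events)
  daughters <- vapply(divs, `[[`, character(1), "daughter")
  if (anyDuplicated(daughters)) {
    errors <- c(errors, paste0("population(s) diverging more than once: ",
                               paste(unique(daughters[duplicated(daughters)]),
                                     collapse = ", ")))
  }
  # coalescence to a single root: follow daughter -> parent links
  if (!length(errors)) {
    parent_of <- setNames(vapply(divs, `[[`, character(1), "parent"),
                          daughters)
    roots <- setdiff(labels, daughters)
    if (length(roots) != 1L) {
      errors <- c(errors, paste0("scenario does not coalesce to one root; ",
                                 "root candidates: ",
                                 paste(roots, collapse = ", ")))
    } else {
      for (l in labels) {
        seen <- character()
        cur <- l
        while (cur %in% names(parent_of)) {
          if (cur %in% seen) {
            errors <- c(errors, "divergence cycle detected")
            break
          }
          seen <- c(seen, cur)
          cur <- parent_of[[cur]]
        }
      }
    }
  }
  for (e in scn$events) {
    if (e$kind == "admixture") {
      b <- prior_bounds(e$rate)
      if (!anyNA(b) && (b[1] < 0 || b[2] > 1)) {
        errors <- c(errors, paste0("admixture rate prior of '", e$name,
                                   "' outside [0, 1]"))
      }
    }
    if (e$kind == "bottleneck") {
      if (!anyNA(prior_bounds(e$nb)) && prior_bounds(e$nb)[1] <= 0) {
        errors <- c(errors, paste0("bottleneck size of '", e$name,
                                   "' must be positive"))
      }
      if (!anyNA(prior_bounds(e$db)) && prior_bounds(e$db)[1] < 1) {
        errors <- c(errors, paste0("bottleneck duration of '", e$name,
                                   "' must be >= 1 generation"))
      }
    }
    b <- prior_bounds(e$time)
    if (!anyNA(b) && b[1] < 0) {
      errors <- c(errors, paste0("event time of '", e$name,
                                 "' must be positive"))
    }
  }
  # constraint satisfiability on prior bounds
  params <- scenario_params(scn)
  for (cc in implied_constraints(scn)) {
    lb <- prior_bounds(params[[cc$larger]])
    sb <- if (is.numeric(cc$smaller)) c(cc$smaller, cc$smaller) else
      prior_bounds(params[[cc$smaller]])
    if (!anyNA(lb) && !anyNA(sb) && lb[2] <= sb[1]) {
      errors <- c(errors, paste0("constraint unsatisfiable: ", cc$larger,
                                 " > ", if (is.numeric(cc$smaller))
                                   cc$smaller else cc$smaller))
    }
  }
  list(valid = length(errors) == 0L, errors = errors)
}

#' Draw parameter values from a scenario's priors
#'
#' Independent draws from each parameter's prior; order constraints
#' (explicit and topology-implied) are enforced by rejection resampling.
#' Deterministic under a fixed seed (set `set.seed()` before calling, or
#' pass `seed`).
#'
#' @param scn a validated `coal_scenario`.
#' @param n number of draws.
#' @param seed optional integer seed.
#' @param max_tries bound on rejection rounds before an unsatisfiable
#'   constraint set is reported.
#' @return A tibble of `n` rows, one column per parameter.
#' @export
sample_parameters <- function(scn, n = 1, seed = NULL, max_tries = 1000) {
  if (!is.null(seed)) set.seed(seed)
  v <- validate_scenario(scn)
  if (!v$valid) abort(paste0("invalid scenario: ",
                             paste(v$errors, collapse = "; ")))
  params <- scenario_params(scn)
  cons <- implied_constraints(scn)
  draw_block <- function(m) {
    cols <- lapply(params, function(p) switch(p$dist,
      uniform = runif(m, p$min, p$max),
      loguniform = exp(runif(m, log(p$min), log(p$max))),
      fixed = rep(p$value, m),
      ref = rep(NA_real_, m)))
    df <- as_tibble(cols)
    for (nm in names(params)) {
      if (params[[nm]]$dist == "ref") df[[nm]] <- df[[params[[nm]]$ref]]
    }
    df
  }
  keep <- NULL
  tries <- 0L
  while (is.null(keep) || nrow(keep) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      abort("order constraints appear unsatisfiable (rejection bound reached)")
    }
    blk <- draw_block(max(n, 100L))
    ok <- rep(TRUE, nrow(blk))
    for (cc in cons) {
      smaller <- if (is.numeric(cc$smaller)) cc$smaller else blk[[cc$smaller]]
      ok <- ok & (blk[[cc$larger]] > smaller)
    }
    keep <- dplyr::bind_rows(keep, blk[ok, , drop = FALSE])
  }
  keep[seq_len(n), , drop = FALSE]
}

# ---- serialization ---------------------------------------------------------

prior_to_list <- function(p) unclass(p)
list_to_prior <- function(l) structure(l, class = "coal_prior")

#' Read / write scenario documents (JSON)
#'
#' Scenarios serialise to a JSON document (populations, events, priors,
#' mutation model, L, constraints) and re-parse to an identical object, so
#' model sets can be shipped and versioned as plain text.
#'
#' @param scn a `coal_scenario`.
#' @param path file path.
#' @return `read_scenario` returns a `coal_scenario`; `write_scenario`
#'   returns `scn` invisibly.
#' @export
write_scenario <- function(scn, path) {
  doc <- list(
    id = scn$id, L = scn$L,
    populations = lapply(scn$populations, function(p)
      list(label = p$label, ne = prior_to_list(p$ne),
           sample_size = p$sample_size, sampling_age = p$sampling_age)),
    events = lapply(scn$events, function(e) {
      e[["time"]] <- prior_to_list(e$time)
      if (!is.null(e$rate)) e$rate <- prior_to_list(e$rate)
      if (!is.null(e$nb)) e$nb <- prior_to_list(e$nb)
      if (!is.null(e$db)) e$db <- prior_to_list(e$db)
      e
    }),
    mutation = list(mu = prior_to_list(scn$mutation$mu),
                    kappa = scn$mutation$kappa,
                    pi = as.list(scn$mutation$pi),
                    alpha = scn$mutation$alpha, p_inv = scn$mutation$p_inv),
    constraints = scn$constraints
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(scn)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  pops <- lapply(doc$populations, function(p)
    pop_spec(p$label, list_to_prior(p$ne), p$sample_size, p$sampling_age))
  evs <- lapply(doc$events, function(e) {
    switch(e$kind,
      divergence = event_divergence(e$name, e$daughter, e$parent,
                                    list_to_prior(e$time)),
      admixture = event_admixture(e$name, e$recipient, e$donor,
                                  list_to_prior(e$time), list_to_prior(e$rate)),
      bottleneck = event_bottleneck(e$name, e$population,
                                    list_to_prior(e$time),
                                    list_to_prior(e$nb), list_to_prior(e$db)))
  })
  mut <- hky_model(mu = list_to_prior(doc$mutation$mu),
                   kappa = doc$mutation$kappa,
                   pi = unlist(doc$mutation$pi),
                   alpha = doc$mutation$alpha, p_inv = doc$mutation$p_inv)
  scenario(doc$id, pops, evs, mut, L = doc$L,
           constraints = lapply(doc$constraints, unlist))
}
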