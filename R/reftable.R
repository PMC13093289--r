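#' Build an ABC reference table
#'
#' Simulates `n_per_scenario` datasets per scenario by drawing parameters
#' from the priors, running the structured coalescent + HKY simulator, and
#' summarising each dataset with [summarize_alignment()]. Every row is
#' seeded from the master seed and its (scenario, row) identity, so the
#' table is identical regardless of chunking or worker count.
#'
#' @param scenarios a `coal_scenario` or list of them; all must share the
#'   same population labels, sample sizes, ages and L so their summary
#'   vectors are comparable.
#' @param n_per_scenario simulations per scenario (the field-standard full
#'   scale is 100,000 per model set; tests use far fewer).
#' @param seed master integer seed.
#' @param progress print a dot every 1000 rows.
#' @return A `coal_reftable` tibble: `scenario`, `sim`, `param_*` columns,
#'   then the summary-statistic columns; attributes `stat_names`,
#'   `param_names`, `seed`.
#' @export
build_reference_table <- function(scenarios, n_per_scenario, seed = 1,
                                  progress = FALSE) {
  if (inherits(scenarios, "coal_scenario")) scenarios <- list(scenarios)
  ids <- vapply(scenarios, `[[`, character(1), "id")
  if (anyDuplicated(ids)) abort("duplicate scenario ids")
  if (n_per_scenario < 1) abort("scenario with zero rows requested")
  sig <- lapply(scenarios, function(s)
    lapply(s$populations, function(p)
      list(p$label, p$sample_size, p$sampling_age)))
  if (length(unique(sig)) != 1L) {
    abort("scenarios must share population labels, sample sizes and ages")
  }
  rows <- vector("list", length(scenarios) * n_per_scenario)
  r <- 0L
  for (si in seq_along(scenarios)) {
    scn <- scenarios[[si]]
    v <- validate_scenario(scn)
    if (!v$valid) abort(paste0("scenario '", scn$id, "' invalid: ",
                               paste(v$errors, collapse = "; ")))
    for (i in seq_len(n_per_scenario)) {
      set.seed(derive_seed(seed, si, i))
      sim <- simulate_dataset(scn)
      stats <- summarize_alignment(sim$alignment)
      pr <- setNames(sim$draw, paste0("param_", names(sim$draw)))
      r <- r + 1L
      rows[[r]] <- dplyr::bind_cols(
        tibble(scenario = scn$id, sim = i), pr, stats)
      if (progress && r %% 1000L == 0L) cat(".")
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "stat_names") <-
    summary_stat_names(unique(vapply(scenarios[[1L]]$populations, `[[`,
                                     character(1), "label")))
  attr(out, "param_names") <- sub("^param_", "",
                                  grep("^param_", names(out), value = TRUE))
  attr(out, "seed") <- seed
  class(out) <- c("coal_reftable", class(out))
  out
}

reftable_stats <- function(rt) {
  attr(rt, "stat_names") %||%
    setdiff(names(rt), c("scenario", "sim",
                         grep("^param_", names(rt), value = TRUE)))
}

#' Write / read a reference table (TSV + JSON sidecar)
#'
#' @param rt a `coal_reftable`.
#' @param path TSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `read_reference_table` returns the `coal_reftable`.
#' @export
write_reference_table <- function(rt, path) {
  utils::write.table(as.data.frame(rt), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(seed = attr(rt, "seed"), stat_names = reftable_stats(rt),
         param_names = attr(rt, "param_names"),
         n_rows = nrow(rt)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(rt)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) {
  out <- as_tibble(utils::read.delim(path, sep = "\t",
                                     stringsAsFactors = FALSE))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  attr(out, "stat_names") <- side$stat_names
  attr(out, "param_names") <- side$param_names
  attr(out, "seed") <- side$seed
  class(out) <- c("coal_reftable", class(out))
  out
}
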