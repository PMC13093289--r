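#' Collapse an alignment into a haplotype frequency table
#'
#' Identical sequences are collapsed into haplotypes; segregating sites are
#' alignment columns at which at least two distinct states occur among the
#' retained samples.
#'
#' @param x a trimmed [coal_alignment()] (states A/C/G/T only).
#' @return An object of class `coal_haplotypes`: list with
#'   `haplotype_seqs` (named character vector of distinct sequences),
#'   `counts` (haplotype x population integer matrix),
#'   `n_haplotypes`, `n_segregating_sites`, `L`, and `pop_ages`
#'   (named sampling ages carried through from the alignment).
#' @export
collapse_haplotypes <- function(x) {
  stopifnot(inherits(x, "coal_alignment"))
  seq_str <- apply(x$seqs, 1L, paste0, collapse = "")
  # order of first appearance after sorting, so the table is
  # permutation-invariant in sample order
  hap_seqs <- sort(unique(seq_str))
  names(hap_seqs) <- paste0("H", seq_along(hap_seqs))
  pops <- sort(unique(x$meta$population))
  counts <- table(factor(match(seq_str, hap_seqs), levels = seq_along(hap_seqs)),
                  factor(x$meta$population, levels = pops))
  counts <- matrix(as.integer(counts), nrow = length(hap_seqs),
                   dimnames = list(names(hap_seqs), pops))
  n_states <- apply(x$seqs, 2L, function(col) length(unique(col)))
  pop_ages <- vapply(pops, function(p)
    x$meta$age_generations[match(p, x$meta$population)], numeric(1))
  structure(list(
    haplotype_seqs = hap_seqs,
    counts = counts,
    n_haplotypes = length(hap_seqs),
    n_segregating_sites = sum(n_states >= 2L),
    L = ncol(x$seqs),
    pop_ages = pop_ages
  ), class = "coal_haplotypes")
}

#' @export
print.coal_haplotypes <- function(x, ...) {
  cat("<coal_haplotypes> ", x$n_haplotypes, " haplotypes, ",
      x$n_segregating_sites, " segregating sites, L = ", x$L, " bp, ",
      ncol(x$counts), " population(s)\n", sep = "")
  invisible(x)
}

#' Tidy a haplotype table into long format
#' @param x a `coal_haplotypes` object.
#' @param ... unused.
#' @return A tibble with columns `haplotype`, `population`, `count`.
#' @export
tidy.coal_haplotypes <- function(x, ...) {
  as_tibble(as.data.frame.table(x$counts, stringsAsFactors = FALSE)) |>
    setNames(c("haplotype", "population", "count")) |>
    dplyr::mutate(count = as.integer(.data$count))
}

#' Per-population haplotype diversity summaries
#'
#' Gene diversity is the small-sample-corrected probability that two
#' randomly drawn haplotypes differ, `H = n/(n-1) * (1 - sum p_i^2)`.
#' Haplotypic (allelic) richness is rarefied to a common sample size by
#' hypergeometric expectation, `E[A] = sum_a (1 - C(n - N_a, g)/C(n, g))`.
#'
#' @param hap a `coal_haplotypes` table.
#' @param rarefaction_size rarefaction sample size `g`; defaults to the
#'   smallest population sample size.
#' @return A tibble with one row per population: `population`, `n`,
#'   `n_haplotypes`, `gene_diversity`, `allelic_richness`, and a logical
#'   `flag_small_n` marking populations of size 1 (H undefined, `NA`).
#' @export
diversity_stats <- function(hap, rarefaction_size = NULL) {
  counts <- hap$counts
  n <- colSums(counts)
  g <- rarefaction_size %||% min(n)
  if (any(n < g)) {
    abort(paste0("rarefaction size ", g,
                 " exceeds smallest population size ", min(n)))
  }
  purrr::map_dfr(colnames(counts), function(p) {
    ck <- counts[, p]
    nk <- sum(ck)
    pk <- ck / nk
    H <- if (nk >= 2L) (nk / (nk - 1)) * (1 - sum(pk^2)) else NA_real_
    ar <- sum(1 - exp(lchoose(nk - ck, g) - lchoose(nk, g)))
    tibble(population = p, n = nk, n_haplotypes = sum(ck > 0L),
           gene_diversity = H, allelic_richness = ar,
           flag_small_n = nk < 2L)
  })
}

# Hs/Ht for a set of populations (haploid data).
# plug-in: Hs = mean_k (1 - sum_i p_ki^2); Ht = 1 - sum_i pbar_i^2 with
# unweighted mean frequencies. Nei & Chesser sample-size correction uses the
# harmonic mean sample size n~: Hs' = n~/(n~-1) Hs; Ht' = Ht + Hs'/(n~ k)
# (haploid analogue of the diploid 2*n~*k denominator).
hs_ht <- function(counts, variant = c("nei_chesser", "plug_in")) {
  variant <- match.arg(variant)
  n <- colSums(counts)
  k <- ncol(counts)
  p <- sweep(counts, 2L, n, "/")
  hs_plug <- mean(1 - colSums(p^2))
  pbar <- rowMeans(p)
  ht_plug <- 1 - sum(pbar^2)
  if (variant == "plug_in") return(list(hs = hs_plug, ht = ht_plug))
  nt <- k / sum(1 / n)
  hs <- nt / (nt - 1) * hs_plug
  ht <- ht_plug + hs / (nt * k)
  list(hs = hs, ht = ht)
}

# Gst, Hedrick's G'st and Jost's D from (Hs, Ht) for k populations.
gst_family <- function(hs, ht, k) {
  if (ht <= 0) {
    return(list(gst = 0, gst_hedrick = 0, jost_d = 0, flag_monomorphic = TRUE))
  }
  gst <- (ht - hs) / ht
  denom <- (k - 1) * (1 - hs)
  gph <- if (denom > 0) gst * (k - 1 + hs) / denom else NA_real_
  d <- if ((1 - hs) > 0) (k / (k - 1)) * (ht - hs) / (1 - hs) else NA_real_
  list(gst = gst, gst_hedrick = gph, jost_d = d, flag_monomorphic = FALSE)
}

#' Pairwise population differentiation: Gst, Hedrick's G'st, Jost's D
#'
#' For each population pair (k = 2), computes Nei's
#' `Gst = (Ht - Hs)/Ht`, Hedrick's standardised
#' `G'st = Gst (k - 1 + Hs) / ((k - 1)(1 - Hs))` and Jost's
#' `D = k/(k-1) (Ht - Hs)/(1 - Hs)` from within- and total-diversity
#' components of the haplotype frequencies. Both the plug-in estimator and
#' the Nei-Chesser sample-size-corrected estimator are available; the
#' corrected variant (the default, and the default of the standard
#' population-genetic packages) may be slightly negative in weakly
#' differentiated data — values are reported as computed, never clipped.
#'
#' @param hap a `coal_haplotypes` table with >= 2 populations, each with
#'   n >= 2.
#' @param variant `"nei_chesser"` (default) or `"plug_in"`.
#' @return A tibble with one row per unordered population pair: `pop1`,
#'   `pop2`, `hs`, `ht`, `gst`, `gst_hedrick`, `jost_d`, `variant`, and
#'   `flag_monomorphic` (TRUE when Ht = 0 and the statistics are defined
#'   as 0).
#' @export
differentiation_stats <- function(hap, variant = c("nei_chesser", "plug_in")) {
  variant <- match.arg(variant)
  counts <- hap$counts
  if (ncol(counts) < 2L) abort("need >= 2 populations")
  if (any(colSums(counts) < 2L)) abort("every population needs n >= 2")
  pairs <- combn(colnames(counts), 2L)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    pp <- pairs[, j]
    cc <- counts[, pp, drop = FALSE]
    cc <- cc[rowSums(cc) > 0L, , drop = FALSE]
    hh <- hs_ht(cc, variant)
    g <- gst_family(hh$hs, hh$ht, k = 2L)
    tibble(pop1 = pp[1L], pop2 = pp[2L], hs = hh$hs, ht = hh$ht,
           gst = g$gst, gst_hedrick = g$gst_hedrick, jost_d = g$jost_d,
           variant = variant, flag_monomorphic = g$flag_monomorphic)
  })
}
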