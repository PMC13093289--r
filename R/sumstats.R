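# Tajima's D from S, mean pairwise differences and n. Returns c(value, mask):
# undefined cases (S = 0, n < 4, zero variance denominator) are encoded as
# 0 with mask = 1, identically for observed and simulated data.
tajimas_d <- function(S, pi_mean, n) {
  if (n < 4L || S == 0L) return(c(0, 1))
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  denom <- sqrt(e1 * S + e2 * S * (S - 1))
  if (denom <= 0) return(c(0, 1))
  c((pi_mean - S / a1) / denom, 0)
}

#' Names and order of the ABC summary-statistic vector
#'
#' @param pops sorted population labels.
#' @return Character vector of statistic names in their fixed order.
#' @export
summary_stat_names <- function(pops) {
  pops <- sort(pops)
  per_pop <- c("nhap", "segsites", "pi_mean", "pi_var", "private", "tajd",
               "tajd_mask")
  nm <- as.vector(t(outer(pops, per_pop, function(p, s) paste0(s, "_", p))))
  if (length(pops) >= 2L) {
    prs <- combn(pops, 2L)
    for (j in seq_len(ncol(prs))) {
      tag <- paste0(prs[1L, j], "_", prs[2L, j])
      nm <- c(nm, paste0(c("dxy", "fst", "fst_mask", "sharedhap"), "_", tag))
    }
  }
  nm
}

#' Summary-statistic vector for ABC
#'
#' Computes the fixed-order vector of summary statistics used both for the
#' observed data and inside the simulator (one shared code path). Per
#' population: number of distinct haplotypes, segregating sites, mean and
#' variance of pairwise differences, private segregating sites (sites
#' segregating within the population but in no other population), and
#' Tajima's D. Per population pair: mean between-population pairwise
#' differences (dxy), Hudson-type
#' `FST = 1 - mean(within) / mean(between)`, and the number of shared
#' haplotypes. Undefined statistics are encoded as 0 with a companion
#' `*_mask` column set to 1.
#'
#' @param x a trimmed [coal_alignment()].
#' @return A 1-row tibble whose columns follow [summary_stat_names()].
#' @export
summarize_alignment <- function(x) {
  stopifnot(inherits(x, "coal_alignment"))
  ints <- encode_nuc(x$seqs)
  n <- nrow(ints)
  L <- ncol(ints)
  pops <- sort(unique(x$meta$population))
  pop_of <- x$meta$population[match(rownames(ints), x$meta$id)]

  # pairwise difference matrix via per-state indicator cross-products
  matches <- matrix(0, n, n)
  for (s in 1:4) {
    xs <- (ints == s) * 1
    matches <- matches + tcrossprod(xs)
  }
  diffs <- L - matches

  hap_str <- apply(x$seqs, 1L, paste0, collapse = "")
  seg_in <- function(rows) {
    if (length(rows) < 2L) return(logical(L))
    sub <- ints[rows, , drop = FALSE]
    apply(sub, 2L, function(col) length(unique(col)) > 1L)
  }
  seg_by_pop <- lapply(pops, function(p) seg_in(which(pop_of == p)))
  names(seg_by_pop) <- pops

  out <- list()
  for (p in pops) {
    rows <- which(pop_of == p)
    np <- length(rows)
    seg <- seg_by_pop[[p]]
    others <- setdiff(pops, p)
    seg_other <- if (length(others)) Reduce(`|`, seg_by_pop[others]) else
      logical(L)
    if (np >= 2L) {
      dd <- diffs[rows, rows][upper.tri(matrix(0, np, np))]
      pim <- mean(dd)
      piv <- if (length(dd) > 1L) var(dd) else 0
    } else {
      pim <- 0
      piv <- 0
    }
    td <- tajimas_d(sum(seg), pim, np)
    out[[paste0("nhap_", p)]] <- length(unique(hap_str[rows]))
    out[[paste0("segsites_", p)]] <- sum(seg)
    out[[paste0("pi_mean_", p)]] <- pim
    out[[paste0("pi_var_", p)]] <- piv
    out[[paste0("private_", p)]] <- sum(seg & !seg_other)
    out[[paste0("tajd_", p)]] <- td[1L]
    out[[paste0("tajd_mask_", p)]] <- td[2L]
  }
  if (length(pops) >= 2L) {
    prs <- combn(pops, 2L)
    for (j in seq_len(ncol(prs))) {
      p1 <- prs[1L, j]; p2 <- prs[2L, j]
      r1 <- which(pop_of == p1); r2 <- which(pop_of == p2)
      tag <- paste0(p1, "_", p2)
      dxy <- mean(diffs[r1, r2, drop = FALSE])
      within_mean <- function(rows) {
        np <- length(rows)
        if (np < 2L) return(NA_real_)
        mean(diffs[rows, rows][upper.tri(matrix(0, np, np))])
      }
      w1 <- within_mean(r1); w2 <- within_mean(r2)
      if (is.na(w1) || is.na(w2) || dxy <= 0) {
        fst <- 0; mask <- 1
      } else {
        fst <- 1 - mean(c(w1, w2)) / dxy; mask <- 0
      }
      out[[paste0("dxy_", tag)]] <- dxy
      out[[paste0("fst_", tag)]] <- fst
      out[[paste0("fst_mask_", tag)]] <- mask
      out[[paste0("sharedhap_", tag)]] <-
        length(intersect(hap_str[r1], hap_str[r2]))
    }
  }
  as_tibble(out)[, summary_stat_names(pops), drop = FALSE]
}
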