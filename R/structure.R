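#' Genetic distance matrices
#'
#' Individual-level distances are plain (non-evolutionary) Euclidean
#' distances on per-site one-hot indicator vectors of the alignment.
#' Population-level distances are Edwards' angular (chord) distances on
#' haplotype frequencies, `D = sqrt(1 - sum_i sqrt(p1_i * p2_i))`.
#'
#' @param x a [coal_alignment()] (individual level) or a
#'   `coal_haplotypes` table (population level).
#' @param level `"individual"` or `"population"`; defaults to the natural
#'   level for the input type.
#' @return A `dist` object with attributes `level` and `method`.
#' @export
genetic_distances <- function(x, level = NULL) {
  if (inherits(x, "coal_alignment")) {
    level <- level %||% "individual"
    if (level != "individual") abort("alignment input gives individual-level distances")
    ints <- encode_nuc(x$seqs)
    onehot <- matrix(0L, nrow(ints), ncol(ints) * 4L,
                     dimnames = list(rownames(ints), NULL))
    for (s in 1:4) {
      onehot[, seq(s, by = 4L, length.out = ncol(ints))] <- (ints == s) * 1L
    }
    d <- dist(onehot)
    attr(d, "level") <- "individual"
    attr(d, "method") <- "euclidean-indicator"
    return(d)
  }
  if (inherits(x, "coal_haplotypes")) {
    level <- level %||% "population"
    if (level != "population") abort("haplotype-table input gives population-level distances")
    n <- colSums(x$counts)
    if (any(n == 0L)) abort("empty population in haplotype table")
    p <- sweep(x$counts, 2L, n, "/")
    k <- ncol(p)
    m <- matrix(0, k, k, dimnames = list(colnames(p), colnames(p)))
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      bc <- sum(sqrt(p[, i] * p[, j]))
      m[i, j] <- m[j, i] <- sqrt(max(0, 1 - bc))
    }
    d <- stats::as.dist(m)
    attr(d, "level") <- "population"
    attr(d, "method") <- "edwards-angular"
    return(d)
  }
  abort("x must be a coal_alignment or coal_haplotypes")
}

#' UPGMA-style hierarchical clustering with agglomeration-method selection
#'
#' Builds hierarchical trees under each candidate agglomeration rule and
#' retains the one whose cophenetic (tree-based) distances correlate best
#' with the original distances. Ties are broken toward `"average"`
#' (UPGMA proper).
#'
#' @param d a `dist` object.
#' @param methods candidate `stats::hclust` agglomeration methods.
#' @return An object of class `coal_dendro`: list with `hclust` (the
#'   selected tree), `method`, `cophenetic_cor` (named vector over all
#'   candidates), `newick` (the selected tree with heights), and
#'   `flag_constant` when the correlation is undefined because the input
#'   distances are constant.
#' @export
upgma_select <- function(d, methods = c("average", "single", "complete",
                                        "mcquitty", "ward.D2")) {
  if (attr(d, "Size") < 3L) abort("need >= 3 items")
  fits <- lapply(methods, function(m) hclust(d, method = m))
  names(fits) <- methods
  dv <- as.vector(d)
  constant <- sd(dv) == 0
  cors <- vapply(fits, function(h) {
    cv <- as.vector(cophenetic(h))
    if (constant || sd(cv) == 0) NA_real_ else cor(dv, cv)
  }, numeric(1))
  if (all(is.na(cors))) {
    sel <- "average"
  } else {
    best <- max(cors, na.rm = TRUE)
    top <- names(cors)[!is.na(cors) & cors >= best - 1e-12]
    sel <- if ("average" %in% top) "average" else top[1L]
  }
  h <- fits[[sel]]
  structure(list(
    hclust = h, method = sel, cophenetic_cor = cors,
    newick = ape::write.tree(ape::as.phylo(h)),
    flag_constant = constant
  ), class = "coal_dendro")
}

#' @export
print.coal_dendro <- function(x, ...) {
  cat("<coal_dendro> method = ", x$method, "; cophenetic r = ",
      format(x$cophenetic_cor[x$method], digits = 4), "\n", sep = "")
  invisible(x)
}

#' Principal coordinates analysis (classical metric MDS)
#'
#' Double-centred eigendecomposition of squared distances via
#' `stats::cmdscale`. Variance explained is computed over positive
#' eigenvalues only; negative eigenvalues (non-Euclidean distances) are
#' reported separately, not folded into the denominator.
#'
#' @param d a `dist` object with n >= 3 items.
#' @param n_axes number of axes to return.
#' @return An object of class `coal_ordination`: `coordinates` tibble
#'   (item + axis columns), `eigenvalues`, `variance_explained` (percent
#'   per returned axis), `negative_eigenvalues`, `flag_degenerate`.
#' @export
pcoa_ord <- function(d, n_axes = 2) {
  n <- attr(d, "Size")
  if (n < 3L) abort("need >= 3 items")
  n_axes <- min(n_axes, n - 1L)
  fit <- cmdscale(d, k = n_axes, eig = TRUE)
  ev <- fit$eig
  pos <- ev[ev > 1e-9]
  degenerate <- length(pos) == 0L
  ve <- if (degenerate) rep(NA_real_, n_axes) else
    100 * pmax(ev[seq_len(n_axes)], 0) / sum(pos)
  coords <- fit$points
  if (is.null(coords) || ncol(coords) < n_axes) {
    coords <- cbind(coords, matrix(0, n, n_axes - ncol(coords)))
  }
  colnames(coords) <- paste0("axis", seq_len(ncol(coords)))
  structure(list(
    coordinates = dplyr::bind_cols(tibble(item = labels(d) %||%
                                            as.character(seq_len(n))),
                                   as_tibble(coords)),
    eigenvalues = ev,
    variance_explained = ve,
    negative_eigenvalues = ev[ev < -1e-9],
    flag_degenerate = degenerate
  ), class = "coal_ordination")
}

#' @export
print.coal_ordination <- function(x, ...) {
  cat("<coal_ordination> ", nrow(x$coordinates), " items; axis variance: ",
      paste(format(x$variance_explained, digits = 3), collapse = "%, "),
      "%\n", sep = "")
  invisible(x)
}

#' @export
tidy.coal_ordination <- function(x, ...) x$coordinates

#' @export
glance.coal_ordination <- function(x, ...) {
  tibble(n_axes = length(x$variance_explained),
         var_axis1 = x$variance_explained[1L],
         var_axis2 = if (length(x$variance_explained) > 1L)
           x$variance_explained[2L] else NA_real_,
         n_negative_eig = length(x$negative_eigenvalues),
         flag_degenerate = x$flag_degenerate)
}

#' @export
autoplot.coal_ordination <- function(object, colour = NULL, ...) {
  dat <- object$coordinates
  ve <- object$variance_explained
  if (!is.null(colour)) dat$.colour <- colour
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$axis1, y = .data$axis2))
  p <- if (is.null(colour)) p + ggplot2::geom_point() else
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$.colour)) +
      ggplot2::labs(colour = NULL)
  p + ggplot2::labs(x = sprintf("PCo 1 (%.1f%%)", ve[1L]),
                    y = sprintf("PCo 2 (%.1f%%)", ve[2L])) +
    ggplot2::theme_minimal()
}

# k-means++ seeding: spread initial centers by squared-distance sampling
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- x[sample.int(n, 1L, prob = probs), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
  }
  centers
}

#' K-means clustering with elbow and average-silhouette K selection
#'
#' Runs K-means (k-means++ initialisation, `n_restarts` restarts per K)
#' over a range of candidate K and reports two data-driven choices: the K
#' maximising the average silhouette width, and the elbow K (largest
#' second difference of the within-group variance curve). Assignments are
#' returned at the silhouette-optimal K; the full diagnostic curves are
#' kept for visual confirmation.
#'
#' @param x a numeric matrix / data frame of coordinates, or a `dist`
#'   (embedded via PCoA on all positive axes before clustering).
#' @param k_range candidate K values, within `[2, n - 1]`.
#' @param n_restarts random restarts per K.
#' @param seed integer seed recorded in the output.
#' @return An object of class `coal_kselect` with fields `curve` (tibble:
#'   k, within_ss, avg_silhouette), `k_silhouette`, `k_elbow`,
#'   `assignments` (tibble: item, cluster), `seed`.
#' @export
select_k <- function(x, k_range = 2:8, n_restarts = 25, seed = 1) {
  if (inherits(x, "dist")) {
    dd <- x
    fit <- cmdscale(dd, k = attr(dd, "Size") - 1L, eig = TRUE)
    keep <- fit$eig > 1e-9
    pts <- fit$points[, keep[seq_len(ncol(fit$points))], drop = FALSE]
    items <- labels(dd) %||% as.character(seq_len(nrow(pts)))
  } else {
    pts <- as.matrix(x)
    items <- rownames(pts) %||% as.character(seq_len(nrow(pts)))
    dd <- dist(pts)
  }
  n <- nrow(pts)
  n_distinct_pts <- nrow(unique(pts))
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2L) || any(k_range > n - 1L)) {
    abort("k_range must lie within [2, n - 1]")
  }
  if (n_distinct_pts <= max(k_range)) {
    abort(paste0("fewer distinct points (", n_distinct_pts,
                 ") than largest candidate K (", max(k_range), ")"))
  }
  set.seed(seed)
  fits <- lapply(k_range, function(k) {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      km <- suppressWarnings(
        kmeans(pts, centers = kmeanspp_centers(pts, k), iter.max = 50L))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best
  })
  wss <- vapply(fits, function(f) f$tot.withinss, numeric(1))
  sil <- vapply(seq_along(fits), function(i) {
    s <- cluster::silhouette(fits[[i]]$cluster, dd)
    mean(s[, "sil_width"])
  }, numeric(1))
  k_sil <- k_range[which.max(sil)]
  # elbow: largest second difference of within-group variance
  k_elbow <- if (length(k_range) >= 3L) {
    d2 <- wss[seq_len(length(wss) - 2L)] - 2 * wss[seq_len(length(wss) - 2L) + 1L] +
      wss[seq_len(length(wss) - 2L) + 2L]
    k_range[which.max(d2) + 1L]
  } else NA_integer_
  structure(list(
    curve = tibble(k = k_range, within_ss = wss, avg_silhouette = sil),
    k_silhouette = k_sil,
    k_elbow = k_elbow,
    assignments = tibble(item = items,
                         cluster = fits[[match(k_sil, k_range)]]$cluster),
    seed = seed
  ), class = "coal_kselect")
}

#' @export
print.coal_kselect <- function(x, ...) {
  cat("<coal_kselect> silhouette-optimal K = ", x$k_silhouette,
      "; elbow K = ", x$k_elbow, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.coal_kselect <- function(x, ...) x$curve

#' @export
glance.coal_kselect <- function(x, ...) {
  tibble(k_silhouette = x$k_silhouette, k_elbow = x$k_elbow, seed = x$seed)
}

#' @export
autoplot.coal_kselect <- function(object, ...) {
  long <- tidyr::pivot_longer(object$curve, c("within_ss", "avg_silhouette"),
                              names_to = "criterion", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~criterion, scales = "free_y") +
    ggplot2::geom_vline(xintercept = object$k_silhouette, linetype = "dashed") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "K", y = NULL)
}
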