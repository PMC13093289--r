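# ray-casting point-in-polygon (polygon given as x/y vertex vectors)
point_in_polygon <- function(px, py, vx, vy) {
  nv <- length(vx)
  inside <- FALSE
  j <- nv
  for (i in seq_len(nv)) {
    if (((vy[i] > py) != (vy[j] > py)) &&
        (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

#' Prior predictive check on PCA axes
#'
#' Fits a PCA to the simulated summary-statistic vectors (a random display
#' subset per scenario, 1000 by default), projects the observed vector,
#' and reports whether the observation lies inside each scenario's cloud
#' on the first two axes — both inside the convex hull and inside the
#' axis-aligned 1st–99th percentile box. A scenario whose cloud does not
#' cover the observation is poorly specified (priors or topology) and
#' should be revised before model choice.
#'
#' @param rt a `coal_reftable`.
#' @param observed 1-row tibble of observed summary statistics (same
#'   columns).
#' @param n_display random datasets displayed per scenario.
#' @param seed seed for the display subsample.
#' @return A `coal_ppcheck`: `report` tibble (scenario, inside_hull,
#'   inside_box), `scores` (PC1/PC2 per displayed simulation),
#'   `observed_scores`, `var_explained`, `dropped` (constant columns).
#' @export
prior_predictive_check <- function(rt, observed, n_display = 1000, seed = 1) {
  stats <- reftable_stats(rt)
  X <- as.matrix(rt[, stats, drop = FALSE])
  keep <- apply(X, 2L, function(v) sd(v) > 0)
  if (!all(keep)) {
    warn(paste0("dropping constant statistic column(s): ",
                paste(stats[!keep], collapse = ", ")))
  }
  X <- X[, keep, drop = FALSE]
  obs <- as.matrix(observed[, stats[keep], drop = FALSE])
  set.seed(seed)
  idx <- unlist(lapply(split(seq_len(nrow(rt)), rt$scenario), function(ii)
    if (length(ii) > n_display) sample(ii, n_display) else ii))
  pca <- prcomp(X[idx, , drop = FALSE], center = TRUE, scale. = TRUE)
  sc <- pca$x[, 1:2, drop = FALSE]
  ob <- predict(pca, obs)[, 1:2, drop = FALSE]
  scen <- rt$scenario[idx]
  report <- purrr::map_dfr(unique(scen), function(s) {
    ss <- sc[scen == s, , drop = FALSE]
    hull <- grDevices::chull(ss[, 1L], ss[, 2L])
    in_hull <- point_in_polygon(ob[1L], ob[2L], ss[hull, 1L], ss[hull, 2L])
    q1 <- quantile(ss[, 1L], c(0.01, 0.99))
    q2 <- quantile(ss[, 2L], c(0.01, 0.99))
    tibble(scenario = s,
           inside_hull = in_hull,
           inside_box = ob[1L] >= q1[1L] && ob[1L] <= q1[2L] &&
             ob[2L] >= q2[1L] && ob[2L] <= q2[2L])
  })
  structure(list(
    report = report,
    scores = tibble(scenario = scen, pc1 = sc[, 1L], pc2 = sc[, 2L]),
    observed_scores = tibble(pc1 = ob[1L], pc2 = ob[2L]),
    var_explained = 100 * pca$sdev[1:2]^2 / sum(pca$sdev^2),
    dropped = stats[!keep]
  ), class = "coal_ppcheck")
}

#' @export
print.coal_ppcheck <- function(x, ...) {
  cat("<coal_ppcheck>\n")
  print(x$report)
  invisible(x)
}

#' @export
autoplot.coal_ppcheck <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$pc1, y = .data$pc2,
                               colour = .data$scenario)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_point(data = object$observed_scores,
                        ggplot2::aes(x = .data$pc1, y = .data$pc2),
                        inherit.aes = FALSE, shape = 8, size = 3) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", object$var_explained[1L]),
                  y = sprintf("PC2 (%.1f%%)", object$var_explained[2L]),
                  colour = "scenario") +
    ggplot2::theme_minimal()
}

# features for the forests: statistics (masks included) with constant
# columns dropped, optionally augmented with LDA axes fitted on the
# scenario labels (the convention of ABC-RF model choice)
rf_features <- function(rt, observed, lda = TRUE) {
  stats <- reftable_stats(rt)
  X <- as.matrix(rt[, stats, drop = FALSE])
  keep <- apply(X, 2L, function(v) sd(v) > 0)
  X <- X[, keep, drop = FALSE]
  O <- as.matrix(observed[, stats[keep], drop = FALSE])
  lda_proj <- NULL
  if (lda && length(unique(rt$scenario)) >= 2L) {
    fit <- suppressWarnings(MASS::lda(X, grouping = factor(rt$scenario)))
    ld_ref <- X %*% fit$scaling
    ld_obs <- O %*% fit$scaling
    colnames(ld_ref) <- colnames(ld_obs) <- paste0("LD", seq_len(ncol(ld_ref)))
    lda_proj <- list(ref = ld_ref, obs = ld_obs)
    X <- cbind(X, ld_ref)
    O <- cbind(O, ld_obs)
  }
  list(X = as.data.frame(X), O = as.data.frame(O), lda = lda_proj)
}

#' Random-forest ABC model choice
#'
#' Implements the ABC-RF model-choice algorithm: a classification forest
#' is trained on the reference table's summary statistics (augmented with
#' linear-discriminant axes), the selected scenario is the majority vote
#' among trees at the observed vector, the posterior probability of the
#' selected scenario is estimated by an out-of-bag regression of the
#' correct-classification indicator evaluated at the observed point, the
#' global (prior) error is the out-of-bag misclassification rate, and the
#' local error is one minus the posterior probability.
#'
#' @param rt a `coal_reftable` with >= 2 scenarios.
#' @param observed tibble of observed summary vectors (1 row, or several
#'   pseudo-observed rows — one forest is trained and reused).
#' @param n_trees number of trees (field convention: 500).
#' @param seed integer seed.
#' @param lda augment features with LDA axes (default TRUE).
#' @return A `coal_model_choice`: `selected` (per observed row),
#'   `votes` (tibble: row, scenario, vote fraction), `posterior`
#'   (per row), `global_error`, `local_error`, `lda_proj` for plotting.
#' @export
abc_model_choice <- function(rt, observed, n_trees = 500, seed = 1,
                             lda = TRUE) {
  scen <- factor(rt$scenario)
  if (nlevels(scen) < 2L) abort("need >= 2 scenarios in the reference table")
  if (any(table(scen) == 0L)) abort("scenario with zero rows")
  fe <- rf_features(rt, observed, lda = lda)
  dat <- cbind(fe$X, .scenario = scen)
  set.seed(seed)
  fit <- ranger::ranger(dependent.variable.name = ".scenario", data = dat,
                        num.trees = n_trees, seed = seed)
  oob <- fit$predictions
  global_error <- mean(oob != scen, na.rm = TRUE)
  pred_all <- predict(fit, fe$O, predict.all = TRUE)$predictions
  if (is.null(dim(pred_all))) pred_all <- matrix(pred_all, nrow = 1L)
  lev <- levels(scen)
  votes <- t(apply(pred_all, 1L, function(v)
    tabulate(v, nbins = length(lev)) / length(v)))
  colnames(votes) <- lev
  selected <- lev[max.col(votes, ties.method = "first")]
  # posterior: OOB regression of the correct-classification indicator
  correct <- as.numeric(oob == scen)
  datr <- cbind(fe$X, .correct = correct)
  keepr <- !is.na(correct)
  set.seed(seed + 1L)
  rfit <- ranger::ranger(dependent.variable.name = ".correct",
                         data = datr[keepr, , drop = FALSE],
                         num.trees = n_trees, seed = seed + 1L)
  posterior <- pmin(1, pmax(0, predict(rfit, fe$O)$predictions))
  vt <- as_tibble(as.data.frame(votes)) |>
    dplyr::mutate(row = dplyr::row_number(), .before = 1L) |>
    tidyr::pivot_longer(-"row", names_to = "scenario",
                        values_to = "vote_fraction")
  structure(list(
    selected = selected, votes = vt, posterior = posterior,
    global_error = global_error, local_error = 1 - posterior,
    n_trees = n_trees, seed = seed,
    lda_proj = if (!is.null(fe$lda)) list(
      ref = tibble(scenario = rt$scenario,
                   ld1 = fe$lda$ref[, 1L],
                   ld2 = if (ncol(fe$lda$ref) > 1L) fe$lda$ref[, 2L] else 0),
      obs = tibble(ld1 = fe$lda$obs[, 1L],
                   ld2 = if (ncol(fe$lda$obs) > 1L) fe$lda$obs[, 2L] else 0))
  ), class = "coal_model_choice")
}

#' @export
print.coal_model_choice <- function(x, ...) {
  cat("<coal_model_choice> selected: ",
      paste(unique(x$selected), collapse = ", "),
      "; posterior = ", paste(format(x$posterior, digits = 3),
                              collapse = ", "),
      "; global error = ", format(x$global_error, digits = 3), "\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.coal_model_choice <- function(x, ...) x$votes

#' @export
glance.coal_model_choice <- function(x, ...) {
  tibble(selected = x$selected[1L], posterior = x$posterior[1L],
         global_error = x$global_error, local_error = x$local_error[1L],
         n_trees = x$n_trees)
}

#' @export
autoplot.coal_model_choice <- function(object, type = c("votes", "lda"),
                                       ...) {
  type <- match.arg(type)
  if (type == "votes") {
    dat <- dplyr::filter(object$votes, .data$row == 1L)
    return(ggplot2::ggplot(dat, ggplot2::aes(x = .data$scenario,
                                             y = .data$vote_fraction)) +
             ggplot2::geom_col() +
             ggplot2::labs(y = "vote fraction") +
             ggplot2::theme_minimal())
  }
  if (is.null(object$lda_proj)) abort("model was fitted with lda = FALSE")
  ggplot2::ggplot(object$lda_proj$ref,
                  ggplot2::aes(x = .data$ld1, y = .data$ld2,
                               colour = .data$scenario)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_point(data = object$lda_proj$obs,
                        ggplot2::aes(x = .data$ld1, y = .data$ld2),
                        inherit.aes = FALSE, shape = 8, size = 3) +
    ggplot2::labs(x = "LD1", y = "LD2", colour = "scenario") +
    ggplot2::theme_minimal()
}

#' Quantile-regression-forest parameter estimation
#'
#' Trains a quantile regression forest for one parameter on a
#' single-scenario reference table and reads the posterior median and 95%
#' credible interval off the predicted quantiles at the observed vector.
#' Global accuracy is the out-of-bag normalised mean absolute error
#' (mean |pred - true| / true); local accuracy is the posterior expected
#' absolute deviation from the median, relative to the median, computed
#' from a fine quantile grid at the observed point.
#'
#' @param rt a `coal_reftable` restricted to one scenario.
#' @param observed tibble of observed summary vectors (>= 1 row).
#' @param parameter parameter name (without the `param_` prefix).
#' @param n_trees number of trees (default 500).
#' @param seed integer seed.
#' @return A `coal_param_estimate`: `estimates` tibble (row, median,
#'   ci_lower, ci_upper), `global_nmae`, `local_error` (per row),
#'   `parameter`, `degenerate` flag.
#' @export
abc_estimate_parameter <- function(rt, observed, parameter, n_trees = 500,
                                   seed = 1) {
  pcol <- paste0("param_", parameter)
  if (!pcol %in% names(rt)) abort(paste0("unknown parameter: ", parameter))
  if (length(unique(rt$scenario)) != 1L) {
    abort("restrict the reference table to the selected scenario first")
  }
  y <- rt[[pcol]]
  n_obs <- nrow(observed)
  if (sd(y) == 0) {
    est <- tibble(row = seq_len(n_obs), median = y[1L],
                  ci_lower = y[1L], ci_upper = y[1L])
    return(structure(list(estimates = est, global_nmae = 0,
                          local_error = rep(0, n_obs),
                          parameter = parameter, degenerate = TRUE,
                          n_trees = n_trees, seed = seed),
                     class = "coal_param_estimate"))
  }
  fe <- rf_features(rt, observed, lda = FALSE)
  dat <- cbind(fe$X, .y = y)
  set.seed(seed)
  fit <- ranger::ranger(dependent.variable.name = ".y", data = dat,
                        num.trees = n_trees, seed = seed, quantreg = TRUE)
  qs <- predict(fit, fe$O, type = "quantiles",
                quantiles = c(0.025, 0.5, 0.975))$predictions
  if (is.null(dim(qs))) qs <- matrix(qs, nrow = 1L)
  est <- tibble(row = seq_len(n_obs), median = qs[, 2L],
                ci_lower = qs[, 1L], ci_upper = qs[, 3L])
  oob <- fit$predictions
  ok <- !is.na(oob) & abs(y) > .Machine$double.eps
  global_nmae <- mean(abs(oob[ok] - y[ok]) / abs(y[ok]))
  grid <- predict(fit, fe$O, type = "quantiles",
                  quantiles = seq(0.005, 0.995, by = 0.005))$predictions
  if (is.null(dim(grid))) grid <- matrix(grid, nrow = 1L)
  local_error <- vapply(seq_len(n_obs), function(i) {
    med <- est$median[i]
    if (abs(med) < .Machine$double.eps) return(NA_real_)
    mean(abs(grid[i, ] - med)) / abs(med)
  }, numeric(1))
  structure(list(estimates = est, global_nmae = global_nmae,
                 local_error = local_error, parameter = parameter,
                 degenerate = FALSE, n_trees = n_trees, seed = seed),
            class = "coal_param_estimate")
}

#' @export
print.coal_param_estimate <- function(x, ...) {
  e <- x$estimates[1L, ]
  cat("<coal_param_estimate> ", x$parameter, ": median = ",
      format(e$median, digits = 4), " [", format(e$ci_lower, digits = 4),
      ", ", format(e$ci_upper, digits = 4), "]; OOB NMAE = ",
      format(x$global_nmae, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.coal_param_estimate <- function(x, ...) {
  dplyr::mutate(x$estimates, parameter = x$parameter,
                local_error = x$local_error)
}

#' @export
glance.coal_param_estimate <- function(x, ...) {
  tibble(parameter = x$parameter, global_nmae = x$global_nmae,
         degenerate = x$degenerate, n_trees = x$n_trees)
}

#' Convert generation-scale time estimates to calendar years
#'
#' Multiplies point estimates and credible-interval bounds by the
#' generation time (default 7 years) and reports thousands of years (ka)
#' rounded to one decimal, the conventional presentation scale.
#'
#' @param x a `coal_param_estimate`, or a numeric vector / tibble with
#'   columns `median`, `ci_lower`, `ci_upper` in generations.
#' @param generation_time years per generation (> 0), default 7.
#' @return A tibble with generations, years, and `ka` columns
#'   (`ka_rounded` at one decimal).
#' @export
generations_to_years <- function(x, generation_time = 7) {
  if (generation_time <= 0) abort("generation_time must be positive")
  if (inherits(x, "coal_param_estimate")) x <- x$estimates
  if (is.numeric(x)) x <- tibble(median = x, ci_lower = x, ci_upper = x)
  dplyr::mutate(as_tibble(x),
                years = .data$median * generation_time,
                years_lower = .data$ci_lower * generation_time,
                years_upper = .data$ci_upper * generation_time,
                ka = .data$years / 1000,
                ka_lower = .data$years_lower / 1000,
                ka_upper = .data$years_upper / 1000,
                ka_rounded = round(.data$ka, 1L))
}
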