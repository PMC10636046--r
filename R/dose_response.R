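#' Aggregate per-field metrics into per-condition dose-response series
#'
#' Averages the chosen response over all fields of view of all replicate
#' wells of each (compound, concentration) condition, with the standard
#' error of the mean. The vehicle condition is carried into every
#' compound's series as its concentration-0 baseline row. Fields flagged
#' invalid (zero nuclei) are dropped.
#'
#' @param fov_metrics Data frame of per-field metrics (needs `well_id` plus
#'   the response column; `n_nuclei` is summarized when present).
#' @param layout Plate layout data frame (see [read_layout()]).
#' @param response Name of the response column, e.g. `"wrapping_index"` or
#'   `"mbp_area_um2"`.
#' @return Data frame with one row per compound x concentration:
#'   `compound`, `concentration_nM`, `role`, `mean_response`, `sem`,
#'   `n_fov`, `nuclei_mean`, `included`.
#' @export
aggregate_conditions <- function(fov_metrics, layout,
                                 response = "wrapping_index") {
  layout <- validate_layout(layout, require_reference = FALSE)
  if (!response %in% names(fov_metrics))
    abort_validation(sprintf("response column '%s' not in fov_metrics", response))
  miss <- setdiff(unique(fov_metrics$well_id), layout$well_id)
  if (length(miss))
    abort_validation(paste("fields with no layout row for well(s):",
                           paste(miss, collapse = ", ")))
  if ("valid" %in% names(fov_metrics))
    fov_metrics <- fov_metrics[fov_metrics$valid, , drop = FALSE]
  m <- merge(fov_metrics, layout, by = "well_id")
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  agg <- do.call(rbind, lapply(
    split(m, list(m$compound, m$concentration_nM), drop = TRUE),
    function(g) data.frame(
      compound = g$compound[1],
      concentration_nM = g$concentration_nM[1],
      role = g$role[1],
      mean_response = mean(g[[response]]),
      sem = sem(g[[response]]),
      n_fov = nrow(g),
      nuclei_mean = if ("n_nuclei" %in% names(g)) mean(g$n_nuclei) else NA_real_
    )))
  veh <- agg[agg$role == "vehicle", , drop = FALSE]
  out <- list()
  for (cp in unique(agg$compound[agg$role != "vehicle"])) {
    s <- agg[agg$compound == cp, , drop = FALSE]
    s <- s[order(-s$concentration_nM), , drop = FALSE]
    if (nrow(veh)) {
      base <- veh[1, ]
      base$compound <- cp
      base$concentration_nM <- 0
      s <- rbind(s, base)
    }
    out[[cp]] <- s
  }
  res <- do.call(rbind, out)
  res$included <- TRUE
  rownames(res) <- NULL
  res
}

#' Mark cytotoxic concentrations as excluded
#'
#' A concentration is cytotoxic when its mean nuclei count falls below
#' `viability_fraction` of the vehicle's mean nuclei count; that
#' concentration and every higher one of the same compound are excluded
#' from fitting (cell loss at high dose invalidates the response there).
#'
#' @param series Output of [aggregate_conditions()] (needs `nuclei_mean`).
#' @param viability_fraction Fraction of the vehicle nuclei mean below
#'   which a condition counts as cytotoxic (default 0.5).
#' @param vehicle_nuclei Override for the vehicle nuclei mean; by default
#'   it is read from the concentration-0 baseline rows.
#' @return `series` with an updated `included` mask.
#' @export
exclude_cytotoxic <- function(series, viability_fraction = 0.5,
                              vehicle_nuclei = NULL) {
  if (is.null(vehicle_nuclei)) {
    veh <- series$nuclei_mean[series$concentration_nM == 0]
    if (!length(veh) || all(is.na(veh)))
      abort_validation("no vehicle nuclei mean available")
    vehicle_nuclei <- mean(veh, na.rm = TRUE)
  }
  cutoff <- viability_fraction * vehicle_nuclei
  for (cp in unique(series$compound)) {
    idx <- which(series$compound == cp & series$concentration_nM > 0)
    conc <- series$concentration_nM[idx]
    toxic <- idx[!is.na(series$nuclei_mean[idx]) &
                   series$nuclei_mean[idx] < cutoff]
    if (length(toxic)) {
      first_toxic <- min(series$concentration_nM[toxic])
      series$included[idx[conc >= first_toxic]] <- FALSE
    }
  }
  series
}

#' Fit a four-parameter logistic to one compound's series
#'
#' Least squares on the included, nonzero-concentration condition means:
#' `R(c) = bottom + (top - bottom) / (1 + (ec50/c)^hill)`, fitted in
#' log-EC50 space with EC50 constrained to `[c_min/100, c_max * 100]` and
#' the Hill slope to `[0.1, 10]`. Initialization: bottom = min mean,
#' top = max mean, ec50 = geometric mean of the tested concentrations,
#' hill = 1. A flat series or optimizer failure yields a non-converged fit.
#'
#' @param series One compound's rows from [aggregate_conditions()].
#' @return List: `bottom`, `top`, `ec50`, `hill`, `converged`, `n_points`,
#'   `rss`.
#' @export
fit_4pl <- function(series) {
  use <- series$included & series$concentration_nM > 0 &
    is.finite(series$mean_response)
  d <- series[use, , drop = FALSE]
  if (nrow(d) < 4L)
    abort_validation("need >= 4 included concentrations to fit a 4PL")
  y <- d$mean_response
  lc <- log(d$concentration_nM)
  failed <- list(bottom = NA_real_, top = NA_real_, ec50 = NA_real_,
                 hill = NA_real_, converged = FALSE, n_points = nrow(d),
                 rss = NA_real_)
  if (diff(range(y)) < 1e-10) return(failed)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + exp(hill * (lec50 - lc))),
      start = list(bottom = min(y), top = max(y), lec50 = mean(lc), hill = 1),
      lower = c(-Inf, -Inf, min(lc) - log(100), 0.1),
      upper = c(Inf, Inf, max(lc) + log(100), 10),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed)
  p <- stats::coef(fit)
  list(bottom = unname(p["bottom"]), top = unname(p["top"]),
       ec50 = exp(unname(p["lec50"])), hill = unname(p["hill"]),
       converged = TRUE, n_points = nrow(d),
       rss = sum(stats::resid(fit)^2))
}

#' EC50 with a response-plateau check
#'
#' The fitted EC50 is only reported when the response plateaus within the
#' tested range. It is undetermined when (a) the fit failed, (b) the
#' maximum included mean sits at the highest included concentration while
#' the fitted top exceeds it by more than 20% (still-rising series), or
#' (c) the fitted EC50 is at or beyond the highest included concentration.
#'
#' @param series One compound's rows from [aggregate_conditions()].
#' @param fit Output of [fit_4pl()].
#' @return List: `ec50` (`NA` when undetermined), `plateau_reached`.
#' @export
ec50_with_plateau_check <- function(series, fit) {
  undet <- list(ec50 = NA_real_, plateau_reached = FALSE)
  if (!isTRUE(fit$converged)) return(undet)
  use <- series$included & series$concentration_nM > 0 &
    is.finite(series$mean_response)
  d <- series[use, , drop = FALSE]
  top_conc <- max(d$concentration_nM)
  peak_at_top <- d$concentration_nM[which.max(d$mean_response)] == top_conc
  top_mean <- max(d$mean_response)
  if (peak_at_top && fit$top > 1.2 * top_mean) return(undet)
  if (fit$ec50 >= top_conc) return(undet)
  list(ec50 = fit$ec50, plateau_reached = TRUE)
}

#' Efficacy, relative efficacy and EC50 per compound
#'
#' Efficacy is the maximum included mean response over the dosed
#' concentrations — read from the data points, never from the fitted top.
#' Relative efficacy divides by the reference compound's efficacy (exactly
#' 1 for the reference itself); its SEM uses first-order ratio propagation.
#'
#' @param series Output of [aggregate_conditions()] /
#'   [exclude_cytotoxic()].
#' @param reference Reference compound name (must be present).
#' @param fits Optional named list of [fit_4pl()] results per compound;
#'   fitted and EC50-checked here when omitted.
#' @return Data frame, one row per compound: `compound`, `efficacy`,
#'   `efficacy_sem`, `peak_concentration_nM`, `relative_efficacy`,
#'   `relative_efficacy_sem`, `ec50_nM`, `hill`, `plateau_reached`,
#'   `fit_converged`.
#' @export
efficacy_and_relative <- function(series, reference = "T3", fits = NULL) {
  compounds <- unique(series$compound)
  if (!reference %in% compounds)
    abort_validation(sprintf("reference compound '%s' absent from series", reference))
  one <- function(cp) {
    s <- series[series$compound == cp, , drop = FALSE]
    dosed <- s[s$included & s$concentration_nM > 0, , drop = FALSE]
    i <- which.max(dosed$mean_response)
    fit <- if (!is.null(fits)) fits[[cp]] else
      tryCatch(fit_4pl(s), error = function(e)
        list(converged = FALSE, ec50 = NA_real_, hill = NA_real_))
    chk <- ec50_with_plateau_check(s, fit)
    data.frame(compound = cp,
               efficacy = dosed$mean_response[i],
               efficacy_sem = dosed$sem[i],
               peak_concentration_nM = dosed$concentration_nM[i],
               ec50_nM = chk$ec50,
               hill = if (isTRUE(fit$converged)) fit$hill else NA_real_,
               plateau_reached = chk$plateau_reached,
               fit_converged = isTRUE(fit$converged))
  }
  res <- do.call(rbind, lapply(compounds, one))
  ref <- res[res$compound == reference, ]
  rel_cv2 <- (res$efficacy_sem / res$efficacy)^2 +
    (ref$efficacy_sem / ref$efficacy)^2
  res$relative_efficacy <- res$efficacy / ref$efficacy
  res$relative_efficacy[res$compound == reference] <- 1
  res$relative_efficacy_sem <- res$relative_efficacy * sqrt(rel_cv2)
  rownames(res) <- NULL
  res
}

#' Two-group one-way ANOVA p-value
#'
#' @param y1,y2 Response vectors of the two groups.
#' @return The ANOVA F-test p-value (identical to the pooled-variance
#'   two-sided t-test, since F = t^2 with two groups), or `NA` when there
#'   are no residual degrees of freedom (fewer than 3 observations).
#' @export
anova_pairwise_p <- function(y1, y2) {
  if (length(y1) + length(y2) < 3L) return(NA_real_)
  d <- data.frame(y = c(y1, y2),
                  g = factor(rep(c("a", "b"), c(length(y1), length(y2)))))
  p <- summary(stats::aov(y ~ g, data = d))[[1]][["Pr(>F)"]][1]
  if (is.null(p)) NA_real_ else p
}

#' Rank compounds by efficacy with statistical ties
#'
#' Compounds are sorted by efficacy (descending); each adjacent pair is
#' compared by a two-group one-way ANOVA on the field-of-view level
#' responses at each compound's peak concentration, and pairs that cannot
#' be distinguished (p >= alpha) share a rank. Rank numbers follow
#' competition ranking over the tie groups.
#'
#' @param results Output of [efficacy_and_relative()].
#' @param fov_responses Data frame of field-level responses: `compound`,
#'   `concentration_nM`, `response`.
#' @param alpha Significance level for distinguishing adjacent compounds.
#' @param p_adjust Multiplicity correction passed to [stats::p.adjust()]
#'   over the adjacent-pair tests (default `"none"`, mirroring unadjusted
#'   pairwise ANOVA).
#' @return `results` with `rank` and, per adjacent pair, the p-values as
#'   attribute `pairwise_p`.
#' @export
rank_compounds <- function(results, fov_responses, alpha = 0.05,
                           p_adjust = "none") {
  if (nrow(results) < 2L)
    abort_validation("ranking needs >= 2 compounds")
  ord <- order(-results$efficacy)
  res <- results[ord, , drop = FALSE]
  peak_values <- function(cp) {
    pk <- res$peak_concentration_nM[res$compound == cp]
    fov_responses$response[fov_responses$compound == cp &
      abs(fov_responses$concentration_nM - pk) < 1e-9 * max(pk, 1)]
  }
  k <- nrow(res)
  p <- vapply(seq_len(k - 1L), function(i)
    anova_pairwise_p(peak_values(res$compound[i]),
                     peak_values(res$compound[i + 1L])), numeric(1))
  p <- stats::p.adjust(p, method = p_adjust)
  # a pair that cannot be tested (no replication) cannot be distinguished
  tied <- is.na(p) | p >= alpha
  grp_start <- 1L
  rank <- integer(k)
  rank[1] <- 1L
  for (i in 2:k) {
    if (!tied[i - 1L]) grp_start <- i
    rank[i] <- grp_start
  }
  res$rank <- rank
  attr(res, "pairwise_p") <- p
  res[order(match(res$compound, results$compound)), , drop = FALSE]
}
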