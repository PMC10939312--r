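# Model comparison: normalisation, sign matching, weighted MSE, ranking.

metric_names <- c("mam", "wc", "bc", "cp", "ama", "ams", "ip")

#' Normalise metric slopes by unmodulated reference responses
#'
#' Amplitude-type metrics (`mam`, `ama`, `ams`, `ip`) are divided by the mean
#' unexpected-trial response amplitude; correlation-type metrics (`wc`, `bc`,
#' `cp`) by the absolute mean unexpected-condition value of that metric.
#' Reference means are taken across participants, so normalisation is a
#' positive per-metric rescaling: it never flips a slope's sign and is
#' invariant to a common rescaling of all responses.
#'
#' @param slopes participants x 7 matrix (columns `mam`, `wc`, `bc`, `cp`,
#'   `ama`, `ams`, `ip`).
#' @param refs participants x 4 matrix of unexpected references (`amp_u`,
#'   `wc_u`, `bc_u`, `cp_u`), as attached by [metric_slopes()].
#' @return normalised slopes matrix of the same shape.
#' @export
normalize_metrics <- function(slopes, refs) {
  slopes <- rbind(slopes)
  refs <- rbind(refs)
  denom <- c(amp = mean(refs[, "amp_u"]),
             wc = abs(mean(refs[, "wc_u"])),
             bc = abs(mean(refs[, "bc_u"])),
             cp = abs(mean(refs[, "cp_u"])))
  if (any(denom == 0)) stop("zero normalisation reference")
  out <- slopes
  for (m in c("mam", "ama", "ams", "ip")) out[, m] <- slopes[, m] / denom["amp"]
  for (m in c("wc", "bc", "cp")) out[, m] <- slopes[, m] / denom[m]
  out
}

#' Empirical (or pseudo-empirical) result summary
#'
#' Reduces per-participant datasets, or a ready matrix of normalised slopes,
#' to the summary the model comparison needs: per-metric mean, SD, sign, and
#' reliability weights proportional to the inverse normalised SD
#' (`|mean| / SD`), normalised to sum one.
#'
#' @param x a list of [trial_dataset()] objects, or a participants x 7 matrix
#'   of normalised slopes.
#' @return An object of class `esfm_summary`.
#' @export
esfm_summary <- function(x) {
  if (is.list(x) && all(vapply(x, inherits, logical(1), "trial_dataset"))) {
    sl <- lapply(x, metric_slopes)
    slopes <- do.call(rbind, lapply(sl, as.vector))
    colnames(slopes) <- metric_names
    refs <- do.call(rbind, lapply(sl, attr, "refs"))
    norm <- normalize_metrics(slopes, refs)
  } else {
    norm <- rbind(x)
    if (is.null(colnames(norm))) colnames(norm) <- metric_names
  }
  if (nrow(norm) < 2L) stop("need at least 2 participants")
  mn <- colMeans(norm)
  sdv <- apply(norm, 2, sd)
  w <- abs(mn) / sdv
  w[!is.finite(w)] <- 0
  structure(list(norm_slopes = norm, mean = mn, sd = sdv,
                 signs = sign(mn), weights = w / sum(w),
                 n = nrow(norm)),
            class = "esfm_summary")
}

#' @export
print.esfm_summary <- function(x, ...) {
  cat(sprintf("<esfm_summary> %d participants\n", x$n))
  print(round(rbind(mean = x$mean, sd = x$sd, weight = x$weights), 4))
  invisible(x)
}

#' Sign matching of simulated against empirical outcome metrics
#'
#' A simulated metric matches the empirical result when its cross-participant
#' slope distribution differs significantly from zero (two-sided one-sample
#' t-test at `alpha`) and its mean has the empirical sign. Metrics with
#' empirical sign zero are excluded with a warning.
#'
#' @param sim_slopes simulated participants x 7 slope matrix for one
#'   parameterisation.
#' @param emp_signs named length-7 vector of empirical signs (-1, 0, 1).
#' @param alpha significance level.
#' @return A list with `matches` (named logical), `count` and `n_usable`.
#' @export
sign_match <- function(sim_slopes, emp_signs, alpha = 0.05) {
  sim_slopes <- rbind(sim_slopes)
  if (nrow(sim_slopes) < 2L) stop("need at least 2 simulated participants")
  usable <- emp_signs != 0
  if (any(!usable))
    warning("metrics with empirical sign 0 excluded: ",
            paste(names(emp_signs)[!usable], collapse = ", "))
  matches <- vapply(seq_along(emp_signs), function(m) {
    if (!usable[m]) return(FALSE)
    v <- sim_slopes[, m]
    if (sd(v) == 0) return(FALSE)  # degenerate: no test possible
    p <- t.test(v)$p.value
    p < alpha && sign(mean(v)) == emp_signs[m]
  }, logical(1))
  names(matches) <- names(emp_signs)
  list(matches = matches, count = sum(matches), n_usable = sum(usable))
}

#' Weighted mean squared error of one parameterisation
#'
#' Per metric, the squared difference between simulated and empirical
#' normalised slopes is averaged across simulated participants and scaled by
#' the grand median of that metric's squared errors (computed across all
#' model types and plausible parameterisations); the weighted mean across
#' metrics, with weights summing to one, is the parameterisation's MSE.
#'
#' @param sim_norm simulated participants x 7 normalised slope matrix.
#' @param emp_mean empirical per-metric mean normalised slopes (length 7).
#' @param grand_medians per-metric grand medians of squared errors; zero
#'   medians drop the metric with a warning.
#' @param weights per-metric weights (renormalised over retained metrics).
#' @return scalar MSE.
#' @export
weighted_mse <- function(sim_norm, emp_mean, grand_medians, weights) {
  sim_norm <- rbind(sim_norm)
  err <- colMeans((sim_norm - rep(emp_mean, each = nrow(sim_norm)))^2)
  keep <- grand_medians > 0
  if (any(!keep))
    warning("metrics with zero grand median dropped: ",
            paste(names(grand_medians)[!keep], collapse = ", "))
  w <- weights[keep] / sum(weights[keep])
  sum(w * err[keep] / grand_medians[keep])
}

#' Rank model families by MSE
#'
#' Per family: the minimum MSE over plausible parameterisations, the sorted
#' MSEs of the best `top_fraction` of the family's full grid, the mean over
#' that top set, and (when per-participant errors are available) bootstrap
#' confidence intervals obtained by resampling simulated participants. The
#' winner is the family with the smallest best MSE; ties break by family name
#' then lexicographic parameters.
#'
#' @param fit_table data.frame with columns `family`, `sigma`, `a`, `b`,
#'   `plausible`, `mse` (as produced by [esfm()]).
#' @param top_fraction fraction of the grid kept in the top set.
#' @param n_boot bootstrap resamples.
#' @param err_array optional grid-points x participants x metrics array of
#'   scaled squared errors aligned with `fit_table` rows, for the bootstrap.
#' @param weights per-metric weights (needed with `err_array`).
#' @param seed integer seed for the bootstrap.
#' @param grid_sizes named full-grid sizes per family used for the top-set
#'   size (`floor(top_fraction * size)`); defaults to the per-family row
#'   counts of `fit_table`. Useful when `fit_table` holds plausible rows only.
#' @return An object of class `esfm_ranking`: per-family data.frame `summary`
#'   (`best_mse`, `top_k`, `mean_top`, CI bounds), list `top_curves`, the
#'   `winner`, and `robust` (whether the winner's entire top set beats every
#'   competitor's).
#' @export
rank_models <- function(fit_table, top_fraction = 0.02, n_boot = 10000L,
                        err_array = NULL, weights = NULL, seed = 1L,
                        grid_sizes = NULL) {
  fams <- unique(fit_table$family)
  if (is.null(grid_sizes)) grid_sizes <- table(fit_table$family)
  rows <- list(); curves <- list()
  for (f in fams) {
    sel <- fit_table$family == f
    k <- max(1L, as.integer(floor(top_fraction * grid_sizes[[f]])))
    ok <- sel & fit_table$plausible & !is.na(fit_table$mse)
    if (!any(ok)) {
      rows[[f]] <- data.frame(family = f, n_plausible = 0L, top_k = k,
                              best_mse = NA_real_, mean_top = NA_real_,
                              ci_lo = NA_real_, ci_hi = NA_real_)
      curves[[f]] <- numeric(0)
      next
    }
    mse <- sort(fit_table$mse[ok])
    top <- head(mse, k)
    ci <- c(NA_real_, NA_real_)
    if (!is.null(err_array)) {
      ix <- which(ok)[order(fit_table$mse[ok])][seq_len(min(k, sum(ok)))]
      npr <- dim(err_array)[2]
      set.seed(derive_seed(seed, 13L))
      boot <- vapply(seq_len(n_boot), function(i) {
        pr <- sample.int(npr, npr, replace = TRUE)
        e <- apply(err_array[ix, pr, , drop = FALSE], c(1, 3), mean)
        min(e %*% weights)
      }, numeric(1))
      ci <- quantile(boot, c(0.025, 0.975), names = FALSE)
    }
    rows[[f]] <- data.frame(family = f, n_plausible = sum(ok), top_k = k,
                            best_mse = mse[1], mean_top = mean(top),
                            ci_lo = ci[1], ci_hi = ci[2])
    curves[[f]] <- top
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  fit_order <- order(summary$best_mse, summary$family)
  winner <- summary$family[fit_order[1]]
  others <- setdiff(fams, winner)
  robust <- length(others) > 0 && length(curves[[winner]]) > 0 &&
    all(vapply(others, function(f)
      length(curves[[f]]) == 0 ||
        max(curves[[winner]]) < min(curves[[f]]), logical(1)))
  structure(list(summary = summary, top_curves = curves, winner = winner,
                 robust = robust),
            class = "esfm_ranking")
}

#' @export
print.esfm_ranking <- function(x, ...) {
  cat("<esfm_ranking> winner:", x$winner,
      if (isTRUE(x$robust)) "(robust across the top set)" else "", "\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Parameter distribution among the best fits
#'
#' Summarises the parameter values (`a`, `b`, `sigma`) of the best
#' `top_fraction` parameterisations per family; `b` is reported as
#' not applicable for global families.
#'
#' @inheritParams rank_models
#' @return A data.frame per family x parameter with quantiles and the modal
#'   value (the most frequent grid value).
#' @export
best_parameter_summary <- function(fit_table, top_fraction = 0.02) {
  fams <- unique(fit_table$family)
  out <- list()
  for (f in fams) {
    sel <- fit_table$family == f & fit_table$plausible &
      !is.na(fit_table$mse)
    if (!any(sel)) next
    k <- max(1L, floor(top_fraction * sum(fit_table$family == f)))
    top <- fit_table[sel, ][order(fit_table$mse[sel]), ][seq_len(
      min(k, sum(sel))), ]
    for (par in c("a", "b", "sigma")) {
      v <- top[[par]]
      if (all(is.na(v))) {
        out[[length(out) + 1L]] <- data.frame(
          family = f, parameter = par, applicable = FALSE, mode = NA_real_,
          q25 = NA_real_, median = NA_real_, q75 = NA_real_)
      } else {
        tab <- table(v)
        out[[length(out) + 1L]] <- data.frame(
          family = f, parameter = par, applicable = TRUE,
          mode = as.numeric(names(tab)[which.max(tab)]),
          q25 = quantile(v, 0.25, names = FALSE),
          median = median(v), q75 = quantile(v, 0.75, names = FALSE))
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
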