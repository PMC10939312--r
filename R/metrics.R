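# The seven voxel-level outcome metrics. All of them reduce a trial-level
# dataset to per-participant summaries via two sufficient statistics: the
# per-(stimulus, condition) mean response pattern and the per-condition trial
# counts. The exported metric functions operate on a `trial_dataset`; the
# grid-search engine reuses the same core on precomputed statistics.

# Localizer-derived, condition-free structure: mean pattern per stimulus,
# voxel responsiveness ranking, voxel selectivity (slope of the localizer
# response over the within-voxel amplitude-ranked images), and the
# within-voxel image preference ranks (1 = most preferred).
localizer_profile <- function(localizer, info, n_bins = 10L) {
  stim <- info$stimulus_id
  Lmean <- rowsum(localizer, stim) / as.vector(table(stim))
  S <- nrow(Lmean)
  amp <- colMeans(Lmean)
  w <- ols_slope_weights(S)
  selectivity <- colSums(apply(Lmean, 2, sort) * w)
  pref_rank <- apply(Lmean, 2, function(col) rank(-col, ties.method = "first"))
  binnable <- length(amp) >= n_bins  # the binned metrics need >= 10 voxels
  list(Lmean = Lmean, amp = amp,
       amp_bin = if (binnable) equal_count_bins(amp, n_bins),
       selectivity = selectivity,
       sel_bin = if (binnable) equal_count_bins(selectivity, n_bins),
       pref_rank = pref_rank, n_bins = n_bins)
}

# Per-(stimulus, condition) mean patterns and trial counts.
task_suffstats <- function(task, trials, n_stim) {
  sum_for <- function(cond) {
    sel <- trials$expected == cond
    M <- matrix(0, n_stim, ncol(task))
    n <- integer(n_stim)
    if (any(sel)) {
      sums <- rowsum(task[sel, , drop = FALSE], trials$trailing_id[sel])
      ids <- as.integer(rownames(sums))
      M[ids, ] <- sums
      n <- as.vector(table(factor(trials$trailing_id[sel],
                                  levels = seq_len(n_stim))))
    }
    M <- M / ifelse(n == 0, NA, n)
    list(M = M, n = n)
  }
  e <- sum_for(TRUE); u <- sum_for(FALSE)
  list(M_e = e$M, n_e = e$n, M_u = u$M, n_u = u$n)
}

check_patterns <- function(M, what) {
  v <- apply(M, 1, stats::var)
  bad <- which(!is.na(v) & v == 0)
  if (length(bad))
    stop("zero-variance ", what, " pattern for stimulus ",
         paste(bad, collapse = ", "))
}

# Shared metric core. Returns the seven per-participant slopes, the
# unmodulated (unexpected-condition) reference values used for
# normalisation, and the per-metric detail (bin/rank profiles).
metrics_core <- function(stats, loc) {
  S <- nrow(stats$M_e)
  pe <- stats$n_e > 0
  pu <- stats$n_u > 0
  if (!any(pe) || !any(pu))
    stop("both expectation conditions must be present")
  both <- pe & pu

  # condition amplitudes are stimulus-balanced (mean of per-stimulus
  # condition means), so differing stimulus composition across conditions
  # cannot masquerade as an expectation effect
  amp_e <- mean(rowMeans(stats$M_e[pe, , drop = FALSE]))
  amp_u <- mean(rowMeans(stats$M_u[pu, , drop = FALSE]))
  mam <- mean(rowMeans(stats$M_u[both, , drop = FALSE]) -
                rowMeans(stats$M_e[both, , drop = FALSE]))

  check_patterns(stats$M_e[pe, , drop = FALSE], "expected task")
  check_patterns(stats$M_u[pu, , drop = FALSE], "unexpected task")
  check_patterns(loc$Lmean, "localizer")
  corr_with_loc <- function(M, present) {
    r <- cor(t(M[present, , drop = FALSE]),
             t(loc$Lmean[present, , drop = FALSE]))
    c(wc = mean(diag(r)), bc = offdiag_mean(r))
  }
  ce <- corr_with_loc(stats$M_e, pe)
  cu <- corr_with_loc(stats$M_u, pu)
  cp_e <- ce[["bc"]] - ce[["wc"]]
  cp_u <- cu[["bc"]] - cu[["wc"]]

  Dv <- colMeans(stats$M_u[both, , drop = FALSE]) -
    colMeans(stats$M_e[both, , drop = FALSE])
  if (!is.null(loc$amp_bin)) {
    w10 <- ols_slope_weights(loc$n_bins)
    ama_bins <- as.vector(rowsum(Dv, loc$amp_bin)) /
      as.vector(table(loc$amp_bin))
    ams_bins <- as.vector(rowsum(Dv, loc$sel_bin)) /
      as.vector(table(loc$sel_bin))
    ama <- sum(w10 * ama_bins)
    ams <- sum(w10 * ams_bins)
  } else {
    ama_bins <- ams_bins <- NULL
    ama <- ams <- NA_real_
  }

  d <- stats$M_u[both, , drop = FALSE] - stats$M_e[both, , drop = FALSE]
  rk <- loc$pref_rank[both, , drop = FALSE]
  ip_by_rank <- as.vector(rowsum(as.vector(d), as.vector(rk))) /
    as.vector(table(as.vector(rk)))
  # rank 1 = most preferred; positive slope = more suppression when preferred
  ip <- -sum(ols_slope_weights(length(ip_by_rank)) * ip_by_rank)

  list(slopes = c(mam = mam,
                  wc = ce[["wc"]] - cu[["wc"]],
                  bc = ce[["bc"]] - cu[["bc"]],
                  cp = cp_e - cp_u,
                  ama = ama, ams = ams, ip = ip),
       refs = c(amp_u = amp_u, wc_u = cu[["wc"]], bc_u = cu[["bc"]],
                cp_u = cp_u),
       detail = list(wc = c(expected = ce[["wc"]], unexpected = cu[["wc"]]),
                     bc = c(expected = ce[["bc"]], unexpected = cu[["bc"]]),
                     cp = c(expected = cp_e, unexpected = cp_u),
                     ama_bins = ama_bins, ams_bins = ams_bins,
                     ip_by_rank = ip_by_rank, suppression = Dv))
}

dataset_core <- function(dataset) {
  n_stim <- max(dataset$localizer_info$stimulus_id)
  loc <- localizer_profile(dataset$localizer, dataset$localizer_info)
  stats <- task_suffstats(dataset$task, dataset$trials, n_stim)
  metrics_core(stats, loc)
}

#' Mean amplitude modulation (expectation suppression)
#'
#' Mean response over voxels and trials to unexpected minus expected stimuli;
#' positive values indicate expectation suppression.
#'
#' @param dataset a [trial_dataset()].
#' @return scalar.
#' @export
mean_amplitude_modulation <- function(dataset) {
  dataset_core(dataset)$slopes[["mam"]]
}

#' Within- and between-class correlations
#'
#' Correlations between each stimulus's expectation-free localizer pattern
#' and the condition-mean task patterns (z-scored per pattern across voxels):
#' the same stimulus (within-class, WC) or the other stimuli (between-class,
#' BC), averaged over stimuli, per expectation condition.
#'
#' @param dataset a [trial_dataset()].
#' @return A list with `wc` and `bc`, each `c(expected=, unexpected=)`.
#' @export
class_correlations <- function(dataset) {
  d <- dataset_core(dataset)$detail
  list(wc = d$wc, bc = d$bc)
}

#' Classification performance
#'
#' Literally `BC - WC` per condition (the analysis convention this package
#' mirrors prints it this way, opposite to the usual Haxby-style `WC - BC`);
#' set `flip = TRUE` for the conventional sign.
#'
#' @param wc,bc outputs of [class_correlations()] (per-condition vectors).
#' @param flip return `WC - BC` instead.
#' @return per-condition vector.
#' @export
classification_performance <- function(wc, bc, flip = FALSE) {
  if (flip) wc - bc else bc - wc
}

#' Amplitude modulation by voxel amplitude
#'
#' Voxels are ranked by their mean localizer amplitude into 10 equal-count
#' bins (remainders to the lower bins); per bin the mean suppression
#' (unexpected - expected) is computed and the slope over the bin index 1..10
#' is returned. A positive slope means more responsive voxels are suppressed
#' more.
#'
#' @param dataset a [trial_dataset()]; needs at least 10 voxels.
#' @return A list with `bins` (10 values) and `slope`.
#' @export
amplitude_mod_by_amplitude <- function(dataset) {
  if (ncol(dataset$task) < 10L)
    stop("binned amplitude metrics need at least 10 voxels")
  core <- dataset_core(dataset)
  list(bins = core$detail$ama_bins, slope = core$slopes[["ama"]])
}

#' Amplitude modulation by voxel selectivity
#'
#' As [amplitude_mod_by_amplitude()], but voxels are binned by selectivity:
#' the regression slope of a voxel's localizer response over its within-voxel
#' amplitude-ranked images (a flat voxel has selectivity 0 and is retained).
#'
#' @param dataset a [trial_dataset()].
#' @return A list with `bins` and `slope`.
#' @export
amplitude_mod_by_selectivity <- function(dataset) {
  if (ncol(dataset$task) < 10L)
    stop("binned amplitude metrics need at least 10 voxels")
  core <- dataset_core(dataset)
  list(bins = core$detail$ams_bins, slope = core$slopes[["ams"]])
}

#' Image-preference suppression profile
#'
#' Within each voxel, trailing images are ranked by localizer amplitude
#' (rank 1 = most preferred); suppression (unexpected - expected) per image is
#' assigned to its rank and averaged over voxels. The slope is oriented so
#' that positive values mean more suppression for more preferred images.
#' Images missing either condition are skipped.
#'
#' @param dataset a [trial_dataset()].
#' @return A list with `by_rank` and `slope`.
#' @export
image_preference <- function(dataset) {
  core <- dataset_core(dataset)
  list(by_rank = core$detail$ip_by_rank, slope = core$slopes[["ip"]])
}

#' All seven outcome metrics of a dataset
#'
#' @param dataset a [trial_dataset()].
#' @return A list with `slopes` (named length-7 vector: `mam`, `wc`, `bc`,
#'   `cp`, `ama`, `ams`, `ip`), `refs` (unexpected-condition reference values
#'   used for normalisation) and `detail` (per-condition values, bin and rank
#'   profiles). Two-condition slopes are expected-minus-unexpected values
#'   (suppression difference for `mam`), so that the sign of each slope is
#'   well defined for sign matching.
#' @export
compute_metrics <- function(dataset) {
  dataset_core(dataset)
}

#' @rdname compute_metrics
#' @export
metric_slopes <- function(dataset) {
  core <- dataset_core(dataset)
  structure(core$slopes, refs = core$refs)
}
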