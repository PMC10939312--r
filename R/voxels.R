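#' Simulated voxels by biased sampling of tuned populations
#'
#' Each voxel pools a small random sample of neural populations (eight draws
#' with replacement from the eight tuning banks), mirroring biased-sampling /
#' macroscale-map accounts of voxel selectivity. A voxel's response to a
#' stimulus is the mean of its sampled populations' activities at the
#' stimulus's feature position, so the response scale is independent of the
#' per-voxel sample size.
#'
#' @param n_voxels number of voxels.
#' @param seed integer seed.
#' @param n_pop number of populations to draw from.
#' @param draws_per_voxel sampled populations per voxel.
#' @return An object of class `voxel_set`: `composition` (n_voxels x
#'   draws_per_voxel population indices) and `counts` (n_voxels x n_pop tally
#'   matrix used for fast response computation).
#' @export
sample_voxels <- function(n_voxels, seed = 1L, n_pop = 8L,
                          draws_per_voxel = 8L) {
  if (n_voxels < 1L) stop("`n_voxels` must be at least 1")
  set.seed(derive_seed(seed, 4L))
  comp <- matrix(sample.int(n_pop, n_voxels * draws_per_voxel, replace = TRUE),
                 nrow = n_voxels)
  counts <- matrix(0L, n_voxels, n_pop)
  for (k in seq_len(draws_per_voxel))
    counts[cbind(seq_len(n_voxels), comp[, k])] <-
      counts[cbind(seq_len(n_voxels), comp[, k])] + 1L
  structure(list(composition = comp, counts = counts,
                 n_voxels = as.integer(n_voxels), n_pop = as.integer(n_pop)),
            class = "voxel_set")
}

#' @export
print.voxel_set <- function(x, ...) {
  cat(sprintf("<voxel_set> %d voxels x %d sampled populations\n",
              x$n_voxels, ncol(x$composition)))
  invisible(x)
}

# Deterministic voxel responses (voxels x stimuli) from a population activity
# matrix (populations x stimuli): mean over sampled populations, gain-scaled.
voxel_responses <- function(voxels, pop_activity, gain = 100) {
  gain * (voxels$counts %*% pop_activity) / ncol(voxels$composition)
}

# Population activities at the stimulus positions: unmodulated, and (for
# expected trials) modulated with the expected position equal to the
# stimulus's own position, i.e. column s is the response to stimulus s when s
# was expected.
population_activities <- function(bank, model, x) {
  A_un <- bank_activity(bank, x)
  A_ex <- A_un
  for (s in seq_along(x)) {
    d <- feature_distance(bank$space, x[s], bank$mu)
    cf <- suppression_factor(model, d)
    A_ex[, s] <- if (model$op_class == "gain") {
      A_un[, s] * cf
    } else {
      bank_activity(bank, x[s], widths = cf * bank$sigma)[, 1]
    }
  }
  list(unexpected = A_un, expected = A_ex)
}

#' Trial-level dataset container
#'
#' Bundles a task response matrix (trials x voxels), its trial metadata, and
#' the matching localizer run ((stimulus x repetition) x voxels).
#'
#' @param task trials x voxels response matrix.
#' @param trials data.frame from [sample_trial_sequence()].
#' @param localizer list with `responses` and `info` as returned by
#'   [simulate_localizer()].
#' @param noise_sd,gain bookkeeping fields.
#' @return An object of class `trial_dataset`.
#' @export
trial_dataset <- function(task, trials, localizer, noise_sd = NA_real_,
                          gain = NA_real_) {
  stopifnot(nrow(task) == nrow(trials))
  structure(list(task = task, trials = trials,
                 localizer = localizer$responses,
                 localizer_info = localizer$info,
                 noise_sd = noise_sd, gain = gain),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf(paste0("<trial_dataset> %d trials x %d voxels, ",
                     "%d localizer rows, noise sd %.3g\n"),
              nrow(x$task), ncol(x$task), nrow(x$localizer), x$noise_sd))
  invisible(x)
}

#' Simulate task responses for a trial sequence
#'
#' Per trial, the trailing stimulus's voxel responses are computed from the
#' modulated response space if the trial is expected and from the unmodulated
#' one otherwise; iid Gaussian noise of SD `noise_sd` is added per trial x
#' voxel.
#'
#' @param voxels a [sample_voxels()] result.
#' @param bank a [build_bank()] result.
#' @param model a [modulation_model()].
#' @param sequence a [sample_trial_sequence()] data.frame.
#' @param x stimulus positions in feature units (inside the clipped region
#'   for linear spaces).
#' @param noise_sd Gaussian noise SD (gain-scaled response units).
#' @param seed integer seed for the noise draws.
#' @param gain response scale (see [ground_truth_spec()]).
#' @param clip optional precomputed [clip_space()].
#' @param on_implausible what to do when the model fails
#'   [plausibility_check()] for this bank: `"ignore"` (default; the screen is
#'   usually applied upstream), `"warn"`, or `"error"`.
#' @return trials x voxels response matrix.
#' @export
simulate_responses <- function(voxels, bank, model, sequence, x, noise_sd,
                               seed = 1L, gain = 100, clip = NULL,
                               on_implausible = c("ignore", "warn", "error")) {
  on_implausible <- match.arg(on_implausible)
  if (on_implausible != "ignore") {
    pc <- plausibility_check(bank, model)
    if (!pc$pass) {
      msg <- paste("model fails plausibility criterion", pc$criterion)
      if (on_implausible == "error") stop(msg) else warning(msg)
    }
  }
  if (bank$space$kind == "linear") {
    clip <- if (is.null(clip)) clip_space(bank) else clip
    if (any(x < clip$bounds[1] | x > clip$bounds[2]))
      stop("stimulus positions outside the clipped feature space")
  }
  A <- population_activities(bank, model, x)
  R_un <- voxel_responses(voxels, A$unexpected, gain)
  R_ex <- voxel_responses(voxels, A$expected, gain)
  det <- ifelse(sequence$expected, 1, 0)
  resp <- matrix(0, nrow(sequence), voxels$n_voxels)
  for (t in seq_len(nrow(sequence))) {
    s <- sequence$trailing_id[t]
    resp[t, ] <- if (sequence$expected[t]) R_ex[, s] else R_un[, s]
  }
  set.seed(derive_seed(seed, 5L))
  if (noise_sd > 0)
    resp <- resp + matrix(rnorm(length(resp), sd = noise_sd), nrow(resp))
  resp
}

#' Simulate an expectation-free localizer run
#'
#' Unmodulated responses per stimulus and repetition, with Gaussian noise of
#' half the task SD (the localizer design affords a higher SNR).
#'
#' @inheritParams simulate_responses
#' @param reps repetitions per stimulus.
#' @return A list with `responses` ((stimulus x repetition) x voxels) and
#'   `info` (data.frame `stimulus_id`, `repetition`).
#' @export
simulate_localizer <- function(voxels, bank, x, noise_sd, reps = 12L,
                               seed = 1L, gain = 100) {
  if (reps < 1L) stop("`reps` must be at least 1")
  R_un <- voxel_responses(voxels, bank_activity(bank, x), gain)
  info <- expand.grid(stimulus_id = seq_along(x), repetition = seq_len(reps),
                      KEEP.OUT.ATTRS = FALSE)
  resp <- t(R_un)[info$stimulus_id, , drop = FALSE]
  set.seed(derive_seed(seed, 6L))
  if (noise_sd > 0)
    resp <- resp + matrix(rnorm(length(resp), sd = noise_sd / 2), nrow(resp))
  list(responses = resp, info = info)
}

# Stratified k-fold cross-validated decoding accuracy of stimulus identity.
decode_accuracy <- function(responses, labels, folds = 4L,
                            decoder = c("svm", "nearest"), seed = 1L) {
  decoder <- match.arg(decoder)
  labels <- factor(labels)
  set.seed(derive_seed(seed, 7L))
  fold <- unlist(lapply(split(seq_along(labels), labels), function(ix)
    setNames(sample(rep_len(seq_len(folds), length(ix))), ix)))
  fold <- fold[order(as.integer(names(fold)))]
  correct <- 0L
  for (f in seq_len(folds)) {
    tr <- fold != f
    pred <- if (decoder == "svm") {
      fit <- e1071::svm(responses[tr, , drop = FALSE], labels[tr],
                        kernel = "linear", scale = FALSE)
      predict(fit, responses[!tr, , drop = FALSE])
    } else {
      # correlation with class-mean patterns
      mu <- t(vapply(levels(labels), function(l)
        colMeans(responses[tr & labels == l, , drop = FALSE]),
        numeric(ncol(responses))))
      r <- cor(t(responses[!tr, , drop = FALSE]), t(mu))
      factor(levels(labels)[max.col(r, ties.method = "first")],
             levels = levels(labels))
    }
    correct <- correct + sum(pred == labels[!tr])
  }
  correct / length(labels)
}

#' Calibrate voxel noise against a target decoding accuracy
#'
#' Starting at SD 0, localizer-style data are simulated from the unmodulated
#' bank and a cross-validated linear decoder of stimulus identity is run; the
#' SD is raised in steps of `step` until the simulated accuracy drops below
#' the target, and the visited SD whose accuracy is closest to the target is
#' returned. One calibration is intended per (ROI, sigma) combination; the
#' modulation parameters do not enter.
#'
#' @param bank a [build_bank()] result.
#' @param voxels a [sample_voxels()] result.
#' @param x stimulus positions in feature units.
#' @param target_accuracy empirical decoding accuracy to match; must exceed
#'   chance (1 / number of stimuli).
#' @param seed integer seed (noise draws and fold assignment).
#' @param reps localizer repetitions per stimulus used for the decode.
#' @param step SD increment (in gain-scaled response units).
#' @param gain response scale.
#' @param decoder `"svm"` (linear support-vector machine, default) or
#'   `"nearest"` (correlation-based nearest class mean).
#' @param folds cross-validation folds (stratified).
#' @param max_steps safety cap on the number of SD increments.
#' @return An object of class `noise_level`: `sd`, `achieved_accuracy`,
#'   `target_accuracy`, `trace` (data.frame of visited SDs).
#' @export
calibrate_noise <- function(bank, voxels, x, target_accuracy, seed = 1L,
                            reps = 12L, step = 1, gain = 100,
                            decoder = c("svm", "nearest"), folds = 4L,
                            max_steps = 400L) {
  decoder <- match.arg(decoder)
  chance <- 1 / length(x)
  if (target_accuracy <= chance || target_accuracy > 1)
    stop("`target_accuracy` must lie in (chance, 1]")
  R_un <- voxel_responses(voxels, bank_activity(bank, x), gain)
  labels <- rep(seq_along(x), times = reps)
  base <- t(R_un)[labels, , drop = FALSE]
  sds <- accs <- numeric(0)
  sd <- 0
  for (k in seq_len(max_steps)) {
    set.seed(derive_seed(seed, 8L, k))
    resp <- base
    if (sd > 0)
      resp <- resp + matrix(rnorm(length(resp), sd = sd), nrow(resp))
    acc <- decode_accuracy(resp, labels, folds = folds,
                           decoder = decoder, seed = derive_seed(seed, 9L, k))
    sds <- c(sds, sd); accs <- c(accs, acc)
    if (acc < target_accuracy) break
    sd <- sd + step
  }
  if (accs[1] < target_accuracy && length(accs) == 1L)
    warning("decoding accuracy already below target at sd = 0")
  best <- which.min(abs(accs - target_accuracy))
  structure(list(sd = sds[best], achieved_accuracy = accs[best],
                 target_accuracy = target_accuracy,
                 trace = data.frame(sd = sds, accuracy = accs)),
            class = "noise_level")
}

#' @export
print.noise_level <- function(x, ...) {
  cat(sprintf("<noise_level> sd = %g (accuracy %.3f, target %.3f)\n",
              x$sd, x$achieved_accuracy, x$target_accuracy))
  invisible(x)
}
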