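#' Probabilistic image-transition matrix
#'
#' Builds the leading-to-trailing transition matrix of a statistical-learning
#' design: each leading image predicts one trailing image with probability
#' `reliability`, and the remaining probability mass is spread evenly over the
#' other trailing images. The expected pairing is the identity mapping
#' (relabeling is free).
#'
#' @param n number of leading (= trailing) images, at least 2.
#' @param reliability probability of the expected trailing image; must be at
#'   least `1/n` so that the expected image is the most likely one.
#' @return An object of class `transition_matrix`: `probs` (n x n row
#'   stochastic matrix) and `expected_pairs` (trailing id expected after each
#'   leading id).
#' @export
make_transition_matrix <- function(n, reliability) {
  if (n < 2L) stop("`n` must be at least 2")
  if (reliability > 1 || reliability < 1 / n)
    stop("invalid design: `reliability` must lie in [1/n, 1] so the ",
         "expected image is the most likely one")
  off <- (1 - reliability) / (n - 1)
  probs <- matrix(off, n, n)
  diag(probs) <- reliability
  structure(list(probs = probs, expected_pairs = seq_len(n), n = as.integer(n),
                 reliability = reliability),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d x %d, reliability %.4g\n",
              x$n, x$n, x$reliability))
  invisible(x)
}

#' Experimental design description
#'
#' The two emulated statistical-learning studies: a 6 x 6 image matrix at 50%
#' reliability with 240 trials, and an 8 x 8 matrix at 56.25% (9/16)
#' reliability with 456 analysed (non-oddball) trials. Oddball trials are not
#' simulated; the analysed trial count is generated directly.
#'
#' @param n_leading,n_trailing image counts (equal in both emulated designs).
#' @param reliability probability of the expected trailing image.
#' @param n_trials number of (analysed) trials.
#' @param n_localizer_reps expectation-free localizer repetitions per stimulus.
#' @param label free-form study tag.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(n_leading, n_trailing, reliability, n_trials,
                              n_localizer_reps = 12L, label = "") {
  if (n_trials <= 0) stop("`n_trials` must be positive")
  if (reliability <= 0 || reliability > 1)
    stop("`reliability` must lie in (0, 1]")
  structure(list(n_leading = as.integer(n_leading),
                 n_trailing = as.integer(n_trailing),
                 reliability = reliability, n_trials = as.integer(n_trials),
                 n_localizer_reps = as.integer(n_localizer_reps),
                 label = label),
            class = "experiment_design")
}

#' @rdname experiment_design
#' @export
design_6x6 <- function() experiment_design(6, 6, 0.5, 240, label = "6x6")

#' @rdname experiment_design
#' @export
design_8x8 <- function() experiment_design(8, 8, 0.5625, 456, label = "8x8")

#' Sample a trial sequence from a design
#'
#' Leading images are balanced exactly (round-robin counts, any remainder
#' assigned to the lowest ids) and shuffled; trailing images are drawn from
#' the transition matrix row of the leading image. The expectation flag is
#' true exactly when the trailing image equals the leading image's expected
#' pair.
#'
#' @param design an [experiment_design()].
#' @param tm a [make_transition_matrix()] whose size matches the design.
#' @param seed integer seed; the sequence is reproducible given the seed.
#' @return A data.frame with columns `trial`, `leading_id`, `trailing_id`,
#'   `expected` (logical).
#' @export
sample_trial_sequence <- function(design, tm, seed) {
  if (tm$n != design$n_leading)
    stop("transition matrix size does not match the design")
  n <- design$n_leading
  nt <- design$n_trials
  base <- nt %/% n
  rem <- nt %% n
  leading <- rep(seq_len(n), times = base + (seq_len(n) <= rem))
  set.seed(derive_seed(seed, 1L))
  leading <- sample(leading)
  trailing <- integer(nt)
  for (l in seq_len(n)) {
    idx <- which(leading == l)
    trailing[idx] <- sample.int(n, length(idx), replace = TRUE,
                                prob = tm$probs[l, ])
  }
  data.frame(trial = seq_len(nt), leading_id = leading,
             trailing_id = trailing,
             expected = trailing == tm$expected_pairs[leading])
}

#' Synthetic stimulus set
#'
#' Samples `n` stimulus positions covering the feature axis (stratified
#' uniform on the unit interval: one draw per equal-width stratum), optionally
#' with matching toy images: oriented gratings for circular (orientation)
#' spaces, blob silhouettes with a graded number of protrusions for linear
#' (complexity-like) spaces.
#'
#' Positions are stored normalised on \[0, 1\]; [stimulus_feature_positions()]
#' maps them into feature units (times pi for circular spaces; affinely into
#' the clipped interval for linear spaces, where only relative positions are
#' meaningful).
#'
#' @param n number of stimuli (>= 2).
#' @param space a [feature_space()].
#' @param seed integer seed.
#' @param with_images also generate matching toy images.
#' @param image_size image side length in pixels.
#' @return An object of class `stimulus_set`: `id`, `position` (normalised),
#'   `space` kind, and optionally `images` (list of matrices).
#' @export
make_synthetic_stimuli <- function(n, space, seed = 1L, with_images = FALSE,
                                   image_size = 64L) {
  if (n < 2L) stop("`n` must be at least 2")
  set.seed(derive_seed(seed, 2L))
  pos <- (seq_len(n) - 1 + runif(n)) / n
  out <- structure(list(id = seq_len(n), position = pos, kind = space$kind),
                   class = "stimulus_set")
  if (with_images) {
    out$images <- if (space$kind == "circular") {
      lapply(pos * pi, grating_image, size = image_size)
    } else {
      lapply(seq_len(n), function(i)
        blob_silhouette(n_protrusions = i + 1L, size = image_size,
                        seed = derive_seed(seed, 3L, i)))
    }
  }
  out
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus_set> %d stimuli on a %s axis%s\n", length(x$id),
              x$kind, if (is.null(x$images)) "" else " (with images)"))
  invisible(x)
}

#' Map normalised stimulus positions into feature units
#'
#' @param positions normalised positions in \[0, 1\] (or a `stimulus_set`).
#' @param bank a [build_bank()] result; linear spaces place stimuli inside the
#'   bank's clipped region.
#' @param clip optional precomputed [clip_space()].
#' @return positions in feature units (radians for circular spaces).
#' @export
stimulus_feature_positions <- function(positions, bank, clip = NULL) {
  if (inherits(positions, "stimulus_set")) positions <- positions$position
  if (bank$space$kind == "circular") return(positions * pi)
  clip <- if (is.null(clip)) clip_space(bank) else clip
  clip$bounds[1] + positions * diff(clip$bounds)
}

#' Ground-truth generating specification
#'
#' Describes a known modulation model plus noise and cohort sizes, for
#' generating pseudo-empirical voxel datasets used in recovery experiments.
#'
#' @param model a [modulation_model()]; must pass [plausibility_check()] for
#'   the bank implied by `sigma` at generation time.
#' @param sigma response-function width of the generating bank.
#' @param noise_sd task noise SD in (gain-scaled) response units; the
#'   localizer receives half this SD.
#' @param n_participants,n_repetitions cohort sizes; each repetition redraws
#'   voxels and noise while the participant's trial sequence is kept.
#' @param n_voxels voxels per simulated ROI.
#' @param gain response scale: voxel responses are `gain` times the mean
#'   activity of the sampled populations (peak population activity is 1).
#' @param master_seed integer master seed; all sub-streams derive from it.
#' @return An object of class `ground_truth_spec`.
#' @export
ground_truth_spec <- function(model, sigma, noise_sd, n_participants = 20L,
                              n_repetitions = 1L, n_voxels = 200L,
                              gain = 100, master_seed = 1L) {
  stopifnot(inherits(model, "modulation_model"))
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  structure(list(model = model, sigma = sigma, noise_sd = noise_sd,
                 n_participants = as.integer(n_participants),
                 n_repetitions = as.integer(n_repetitions),
                 n_voxels = as.integer(n_voxels), gain = gain,
                 master_seed = as.integer(master_seed)),
            class = "ground_truth_spec")
}

#' Generate ground-truth voxel datasets
#'
#' Produces one trial-level dataset per simulated participant x repetition
#' under a known modulation model: voxels are sampled, a trial sequence drawn,
#' responses computed from the modulated (expected trials) or unmodulated
#' (unexpected trials) response space, Gaussian noise added per trial x voxel,
#' and an expectation-free localizer (half the task noise) attached. Fully
#' reproducible from the master seed; any participant can be regenerated in
#' isolation.
#'
#' @param spec a [ground_truth_spec()]; the model must pass the plausibility
#'   screen, otherwise generation refuses with the failing criterion.
#' @param design an [experiment_design()].
#' @param space a [feature_space()].
#' @param positions normalised stimulus positions (defaults to a stratified
#'   sample via [make_synthetic_stimuli()]).
#' @return A list of `trial_dataset` objects with attributes `participant` and
#'   `repetition`.
#' @export
generate_ground_truth_dataset <- function(spec, design, space,
                                          positions = NULL) {
  bank <- build_bank(space, spec$sigma)
  pc <- plausibility_check(bank, spec$model)
  if (!pc$pass)
    stop("ground-truth model fails plausibility criterion ", pc$criterion)
  if (is.null(positions))
    positions <- make_synthetic_stimuli(design$n_trailing, space,
                                        seed = spec$master_seed)$position
  tm <- make_transition_matrix(design$n_leading, design$reliability)
  clip <- clip_space(bank)
  x <- stimulus_feature_positions(positions, bank, clip)
  out <- list()
  for (p in seq_len(spec$n_participants)) {
    seq_p <- sample_trial_sequence(design, tm,
                                   seed = derive_seed(spec$master_seed, p))
    for (r in seq_len(spec$n_repetitions)) {
      sr <- derive_seed(spec$master_seed, p, r)
      vox <- sample_voxels(spec$n_voxels, seed = derive_seed(sr, 10L))
      task <- simulate_responses(vox, bank, spec$model, seq_p, x,
                                 noise_sd = spec$noise_sd,
                                 seed = derive_seed(sr, 11L),
                                 gain = spec$gain, clip = clip)
      loc <- simulate_localizer(vox, bank, x, noise_sd = spec$noise_sd,
                                reps = design$n_localizer_reps,
                                seed = derive_seed(sr, 12L),
                                gain = spec$gain)
      ds <- trial_dataset(task, seq_p, loc, noise_sd = spec$noise_sd,
                          gain = spec$gain)
      attr(ds, "participant") <- p
      attr(ds, "repetition") <- r
      out[[length(out) + 1L]] <- ds
    }
  }
  out
}
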