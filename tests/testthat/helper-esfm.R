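# Shared fixtures, all generated in code.

# A small trial-level dataset built directly from per-stimulus patterns:
# `expected_pat` and `unexpected_pat` are stimulus x voxel matrices presented
# on `reps_per_cell` trials per (stimulus, condition); the localizer shows
# `loc_pat` (defaults to the unexpected patterns) noise-free.
manual_dataset <- function(expected_pat, unexpected_pat,
                           loc_pat = unexpected_pat, reps_per_cell = 2L,
                           loc_reps = 2L) {
  S <- nrow(expected_pat)
  cells <- expand.grid(s = seq_len(S), cond = c(TRUE, FALSE),
                       rep = seq_len(reps_per_cell))
  task <- t(vapply(seq_len(nrow(cells)), function(i) {
    if (cells$cond[i]) expected_pat[cells$s[i], ]
    else unexpected_pat[cells$s[i], ]
  }, numeric(ncol(expected_pat))))
  trials <- data.frame(trial = seq_len(nrow(cells)),
                       leading_id = cells$s, trailing_id = cells$s,
                       expected = cells$cond)
  info <- expand.grid(stimulus_id = seq_len(S), repetition = seq_len(loc_reps))
  loc <- loc_pat[info$stimulus_id, , drop = FALSE]
  trial_dataset(task, trials, list(responses = loc, info = info),
                noise_sd = 0, gain = 1)
}

# Ground-truth datasets under a named modulation at zero noise.
noise_free_datasets <- function(op_class = "gain", distance = "global",
                                a = 0.5, b = 0.5, sigma = 0.5,
                                n_participants = 1L, seed = 42L,
                                space_kind = "circular", n_voxels = 40L) {
  sp <- feature_space(space_kind)
  model <- modulation_model(op_class, distance, a = a,
                            b = if (distance == "global") NA else b)
  spec <- ground_truth_spec(model, sigma = sigma, noise_sd = 0,
                            n_participants = n_participants,
                            n_voxels = n_voxels, master_seed = seed)
  generate_ground_truth_dataset(spec, design_6x6(), sp)
}

reduced_grid <- function() {
  build_grid(sigma = c(0.3, 0.5, 0.8), a = seq(0.2, 0.9, by = 0.1),
             b = c(0.1, 0.3, 0.5, 0.8, 1.2, 1.7, 2.3))
}
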