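make_patterns <- function(S = 3, V = 12, seed = 1) {
  set.seed(seed)
  matrix(rnorm(S * V), S, V)
}

test_that("mean amplitude modulation measures the condition difference", {
  U <- make_patterns()
  ds0 <- manual_dataset(U, U)
  expect_identical(mean_amplitude_modulation(ds0), 0)
  ds1 <- manual_dataset(U, U + 1)
  expect_equal(mean_amplitude_modulation(ds1), 1, tolerance = 1e-12)
  # condition missing
  broken <- ds1
  broken$trials$expected <- TRUE
  expect_error(compute_metrics(broken), "condition")
})

test_that("class correlations behave on constructed patterns", {
  # task patterns equal orthogonal localizer patterns: WC = 1, BC = 0
  P <- rbind(c(1, -1, 1, -1, 1, -1), c(1, -1, -1, 1, 0, 0))
  expect_equal(cor(P[1, ], P[2, ]), 0)
  ds <- manual_dataset(P, P, loc_pat = P)
  cc <- class_correlations(ds)
  expect_equal(unname(cc$wc), c(1, 1))
  expect_equal(unname(cc$bc), c(0, 0), tolerance = 1e-12)
  # a pattern and its negation: WC = 1, BC = -1
  Q <- rbind(c(1, 2, 0, -1, 3, 1), -c(1, 2, 0, -1, 3, 1))
  ds2 <- manual_dataset(Q, Q, loc_pat = Q)
  cc2 <- class_correlations(ds2)
  expect_equal(unname(cc2$wc), c(1, 1))
  expect_equal(unname(cc2$bc), c(-1, -1))
  # z-scoring: per-pattern affine transforms leave WC/BC unchanged
  Qa <- Q * 3.7 + 11
  cc3 <- class_correlations(manual_dataset(Qa, Qa, loc_pat = Q))
  expect_equal(cc3, cc2, tolerance = 1e-12)
})

test_that("classification performance is the printed BC - WC", {
  expect_equal(classification_performance(c(e = 0.5, u = 0.5),
                                          c(e = 0.5, u = 0.5)),
               c(e = 0, u = 0))
  expect_equal(classification_performance(1, -1), -2)
  expect_equal(classification_performance(1, -1, flip = TRUE), 2)
})

test_that("label swap flips the sign of two-condition slopes", {
  set.seed(3)
  U <- make_patterns(4, 16, seed = 4)
  E <- U * 0.6 + matrix(rnorm(64, sd = 0.1), 4)
  ds <- manual_dataset(E, U)
  swapped <- ds
  swapped$trials$expected <- !ds$trials$expected
  a <- metric_slopes(ds); b <- metric_slopes(swapped)
  for (m in c("mam", "wc", "bc", "cp"))
    expect_equal(a[[m]], -b[[m]], tolerance = 1e-12)
})

test_that("amplitude-by-amplitude bins match a hand-binned oracle", {
  S <- 3; V <- 20
  set.seed(5)
  loc <- matrix(rnorm(S * V, mean = 10), S, V)
  U <- loc
  supp <- matrix(rep(seq(0, 1.9, length.out = V), each = S), S, V)
  E <- U - supp
  ds <- manual_dataset(E, U, loc_pat = loc)
  res <- amplitude_mod_by_amplitude(ds)
  # oracle: order voxels by localizer amplitude, bins of 2, mean suppression
  amp <- colMeans(loc)
  ord <- order(amp)
  oracle <- vapply(1:10, function(b)
    mean(colMeans(supp)[ord[(2 * b - 1):(2 * b)]]), numeric(1))
  expect_equal(res$bins, oracle, tolerance = 1e-12)
  # suppression identical everywhere: slope 0
  flat <- manual_dataset(U - 1, U, loc_pat = loc)
  expect_equal(amplitude_mod_by_amplitude(flat)$slope, 0, tolerance = 1e-12)
  # suppression proportional to localizer amplitude: positive slope
  prop <- manual_dataset(U - rep(amp / 10, each = S), U, loc_pat = loc)
  expect_gt(amplitude_mod_by_amplitude(prop)$slope, 0)
  expect_error(amplitude_mod_by_amplitude(manual_dataset(E[, 1:8], U[, 1:8],
                                                         loc_pat = loc[, 1:8])),
               "at least 10")
})

test_that("voxel selectivity is the exact regression slope over ranked images", {
  # voxel responding (1, 2, 3) to its ranked images: one unit per rank step
  loc <- cbind(c(1, 2, 3), c(5, 5, 5), c(10, 30, 20))
  prof <- esfm:::localizer_profile(loc, data.frame(stimulus_id = 1:3,
                                                   repetition = 1))
  expect_equal(prof$selectivity, c(1, 0, 10))
  # flat voxels are retained with selectivity 0
  expect_equal(prof$selectivity[2], 0)
})

test_that("image preference orients suppression by within-voxel preference", {
  S <- 4; V <- 20
  set.seed(6)
  loc <- matrix(rnorm(S * V, 10), S, V)
  U <- loc
  # suppression largest for each voxel's most preferred image
  pref <- apply(loc, 2, function(col) rank(-col, ties.method = "first"))
  supp <- (S + 1 - pref) / S
  dsp <- manual_dataset(U - supp, U, loc_pat = loc)
  ipp <- image_preference(dsp)
  expect_gt(ipp$slope, 0)
  expect_equal(ipp$by_rank, sort(ipp$by_rank, decreasing = TRUE))
  # suppression independent of preference: slope 0
  ds0 <- manual_dataset(U - 0.5, U, loc_pat = loc)
  expect_equal(image_preference(ds0)$slope, 0, tolerance = 1e-12)
  # an image missing one condition is skipped, not fatal
  miss <- dsp
  drop <- miss$trials$trailing_id == 1 & !miss$trials$expected
  miss$task <- miss$task[!drop, ]
  miss$trials <- miss$trials[!drop, ]
  expect_silent(ip2 <- image_preference(miss))
  expect_length(ip2$by_rank, S)
})

test_that("metrics are invariant to voxel and trial order", {
  ds <- noise_free_datasets("gain", "local", a = 0.4, b = 0.6,
                            n_voxels = 30)[[1]]
  base <- metric_slopes(ds)
  set.seed(7)
  vperm <- sample(30); tperm <- sample(nrow(ds$task))
  shuf <- ds
  shuf$task <- ds$task[tperm, vperm]
  shuf$trials <- ds$trials[tperm, ]
  shuf$localizer <- ds$localizer[, vperm]
  expect_equal(metric_slopes(shuf), base, tolerance = 1e-12)
})

test_that("all seven metrics are exactly null for a = 1 at zero noise", {
  for (fam in list(c("gain", "local"), c("tuning", "remote"))) {
    ds <- noise_free_datasets(fam[1], fam[2], a = 1, b = 0.5,
                              n_voxels = 25)[[1]]
    sl <- metric_slopes(ds)
    expect_equal(as.numeric(sl), rep(0, 7), tolerance = 1e-11)
  }
})

test_that("the grid engine reproduces the trial-level metrics path", {
  sp <- feature_space("circular")
  des <- design_6x6()
  seed <- 31L
  grid1 <- build_grid(sigma = 0.5, a = 0.4, b = 0.6)
  fam <- esfm_families()[esfm_families()$family == "local gain", ]
  stim <- make_synthetic_stimuli(6, sp, seed = 2)
  emp <- esfm_summary(rbind(rep(0.3, 7), rep(0.5, 7)))
  fit <- esfm(emp, sp, des, stim$position, grid = grid1, families = fam,
              n_voxels = 25, n_participants = 2, n_repetitions = 1,
              noise = 0, seed = seed)
  # rebuild the engine's two simulated participants at trial level
  bank <- build_bank(sp, 0.5)
  x <- stim$position * pi
  model <- modulation_model("gain", "local", a = 0.4, b = 0.6)
  tm <- make_transition_matrix(6, 0.5)
  sl <- lapply(1:2, function(p) {
    sq <- sample_trial_sequence(des, tm, seed = esfm:::derive_seed(seed, 30L, p))
    vox <- sample_voxels(25, seed = esfm:::derive_seed(seed, 31L, p, 1L))
    task <- simulate_responses(vox, bank, model, sq, x, noise_sd = 0)
    loc <- simulate_localizer(vox, bank, x, noise_sd = 0,
                              reps = des$n_localizer_reps)
    metric_slopes(trial_dataset(task, sq, loc, noise_sd = 0, gain = 100))
  })
  slopes <- do.call(rbind, lapply(sl, as.vector))
  colnames(slopes) <- colnames(fit$fit_table)[
    match("mam", colnames(fit$fit_table)) + 0:6]
  refs <- do.call(rbind, lapply(sl, attr, "refs"))
  norm <- colMeans(normalize_metrics(slopes, refs))
  row <- fit$fit_table[1, c("mam", "wc", "bc", "cp", "ama", "ams", "ip")]
  expect_equal(unlist(row), norm, tolerance = 1e-10,
               ignore_attr = TRUE)
})
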