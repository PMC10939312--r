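test_that("response banks are peak-normalised and behave in the limits", {
  spc <- feature_space("circular")
  spl <- feature_space("linear")
  for (sigma in c(0.1, 0.5, 2, 5)) {
    bc <- build_bank(spc, sigma)
    bl <- build_bank(spl, sigma)
    # peak-normalisation holds exactly at the population means
    expect_equal(diag(esfm:::bank_activity(bc, bc$mu)), rep(1, 8),
                 tolerance = 1e-12)
    expect_equal(diag(esfm:::bank_activity(bl, bl$mu)), rep(1, 8),
                 tolerance = 1e-12)
    # and the grid evaluation never exceeds it
    expect_lte(max(bc$activity), 1)
    expect_lte(max(bl$activity), 1)
  }
  # very broad circular tuning: summed response uniform
  b <- build_bank(spc, 500)
  expect_lt(diff(range(b$summed)) / max(b$summed), 1e-6)
  # linear: summed response decays at the range ends
  b2 <- build_bank(spl, 0.5)
  expect_lt(b2$summed[1], b2$summed[round(length(b2$summed) / 2)])
  expect_error(build_bank(spc, 0), "positive")
})

test_that("clip bounds are symmetric and match a brute-force scan", {
  spl <- feature_space("linear")
  bank <- build_bank(spl, 0.5)
  cl <- clip_space(bank)
  expect_equal(cl$bounds[1] - 0, pi - cl$bounds[2], tolerance = 1e-9)
  # independent scan oracle on freshly evaluated Gaussians
  x <- spl$grid
  mu <- seq(0, pi, length.out = 8)
  S <- rowSums(vapply(mu, function(m) exp(-(x - m)^2 / (2 * 0.25)),
                      numeric(length(x))))
  ok <- which(S >= 0.95 * max(S))
  expect_equal(cl$bounds, x[range(ok)])
  # sigma -> large: bounds approach the full range
  cl_wide <- clip_space(build_bank(spl, 50))
  expect_lt(cl_wide$bounds[1], 0.05)
  # circular: no-op
  clc <- clip_space(build_bank(feature_space("circular"), 0.5))
  expect_equal(length(clc$idx), round(180 * pi))
})

test_that("suppression factors match the printed formulas and endpoints", {
  glob <- modulation_model("gain", "global", a = 0.3)
  expect_equal(suppression_factor(glob, c(0, 0.4, pi / 2)), rep(0.3, 3))
  loc <- modulation_model("gain", "local", a = 0.5, b = 0.2)
  rem <- modulation_model("gain", "remote", a = 0.5, b = 0.2)
  expect_equal(suppression_factor(loc, 0), 0.5)
  expect_equal(suppression_factor(rem, 0), 1)
  # no suppression at distances >= b scaled by (1 - a)
  loc2 <- modulation_model("gain", "local", a = 0.5, b = 0.1)
  expect_equal(suppression_factor(loc2, 0.1), 1)
  # mirror property on 0 <= d <= b
  d <- seq(0, 0.2, length.out = 21)
  expect_equal(suppression_factor(loc, d) + suppression_factor(rem, d),
               rep(1 + 0.5, 21), tolerance = 1e-12)
  # factors always within [a, 1]
  for (dist in c("local", "remote")) {
    m <- modulation_model("gain", dist, a = 0.2, b = 0.7)
    cf <- suppression_factor(m, seq(0, pi / 2, length.out = 50))
    expect_true(all(cf >= 0.2 - 1e-15 & cf <= 1 + 1e-15))
  }
})

test_that("local suppression approaches the global factor as b grows", {
  d <- seq(0, pi / 2, length.out = 101)
  for (a in c(0.05, 0.4, 0.95)) {
    loc <- modulation_model("gain", "local", a = a, b = 1e6)
    bound <- (pi / 2) / 1e6 * (1 - a)
    expect_lte(max(abs(suppression_factor(loc, d) - a)), bound + 1e-15)
  }
})

test_that("modulation respects gain and tuning contracts", {
  spc <- feature_space("circular")
  bank <- build_bank(spc, 0.5)
  fams <- esfm_families()
  # a = 1: all six models leave the response space untouched
  for (f in seq_len(nrow(fams))) {
    m1 <- modulation_model(fams$op_class[f], fams$distance[f], a = 1,
                           b = if (fams$distance[f] == "global") NA else 0.5)
    mod <- modulate(bank, m1, x_j = 1)
    expect_equal(mod$activity, bank$activity, tolerance = 1e-12)
  }
  # global gain a = 0.05: summed response is 5% of unmodulated everywhere
  mod5 <- modulate(bank, modulation_model("gain", "global", a = 0.05), 1)
  expect_equal(mod5$summed, 0.05 * bank$summed, tolerance = 1e-12)
  # gain models never amplify; equality only where the factor is 1
  loc <- modulation_model("gain", "local", a = 0.3, b = 1)
  modl <- modulate(bank, loc, 1)
  expect_true(all(modl$activity <= bank$activity + 1e-15))
  # tuning models keep every population's peak (evaluated at the means)
  for (dist in c("local", "remote", "global")) {
    mt <- modulation_model("tuning", dist, a = 0.3,
                           b = if (dist == "global") NA else 0.5)
    cf <- suppression_factor(mt, feature_distance(spc, 1, bank$mu))
    at_mu <- diag(esfm:::bank_activity(bank, bank$mu, widths = cf * 0.5))
    expect_equal(at_mu, rep(1, 8), tolerance = 1e-12)
    expect_lte(max(modulate(bank, mt, 1)$activity), 1)
  }
  # linear spaces refuse expected positions outside the clip
  bl <- build_bank(feature_space("linear"), 0.5)
  expect_error(modulate(bl, loc, x_j = 0.01), "clipped")
})

test_that("plausibility criteria fire on the documented cases", {
  spc <- feature_space("circular")
  bank <- build_bank(spc, 0.5)
  # heavy global gain starves the modulated response
  expect_equal(plausibility_check(bank,
                                  modulation_model("gain", "global", a = 0.05))$criterion, 2L)
  # no modulation with moderate tuning passes
  expect_true(plausibility_check(bank,
                                 modulation_model("gain", "global", a = 1))$pass)
  # flat Gaussian tuning fails the selectivity criterion
  expect_equal(exp(-(pi / 2)^2 / (2 * 36)), 0.966, tolerance = 1e-3)
  bl6 <- build_bank(feature_space("linear"), 6)
  expect_equal(plausibility_check(bl6,
                                  modulation_model("gain", "global", a = 1))$criterion, 3L)
})

test_that("scalar plausibility check agrees with the compiled grid scan", {
  grid <- build_grid(sigma = c(0.2, 0.5), a = c(0.05, 0.3, 1),
                     b = c(0.3, 2.3))
  for (kind in c("circular", "linear")) {
    sp <- feature_space(kind)
    tab <- plausibility_table(sp, grid)
    pick <- tab[tab$family %in% c("local gain", "remote tuning", "global tuning"), ]
    pick <- pick[seq(1, nrow(pick), by = 7), ]  # subsample for runtime
    for (i in seq_len(nrow(pick))) {
      bank <- build_bank(sp, pick$sigma[i])
      m <- modulation_model(pick$op_class[i], pick$distance[i], pick$a[i],
                            pick$b[i])
      ref <- plausibility_check(bank, m)
      expect_identical(ref$pass, pick$plausible[i],
                       info = paste(pick$family[i], pick$sigma[i], pick$a[i],
                                    pick$b[i], kind))
      if (!ref$pass)
        expect_identical(ref$criterion, pick$fail_criterion[i])
    }
  }
})

test_that("the default grid reproduces the printed bookkeeping", {
  g <- build_grid()
  expect_length(g$sigma, 17)
  expect_length(g$a, 20)
  expect_length(g$b, 23)
  expect_identical(grid_size(g), 7820L)
  fam_g <- esfm_families()[esfm_families()$distance == "global", ][1, ]
  expect_identical(grid_size(g, fam_g), 340L)
  expect_identical(floor(0.02 * grid_size(g)), 156)
  expect_error(build_grid(sigma = numeric(0)), "non-empty")
})
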