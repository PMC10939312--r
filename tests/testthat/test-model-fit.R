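fake_slopes <- function(n = 6, base = c(mam = 2, wc = -0.1, bc = 0.05,
                                        cp = 0.15, ama = 0.3, ams = 0.2,
                                        ip = 0.1), sd = 0.02, seed = 1) {
  set.seed(seed)
  out <- t(replicate(n, base + rnorm(7, sd = sd)))
  colnames(out) <- names(base)
  out
}

fake_refs <- function(n = 6, amp = 30, wc = 0.8, bc = -0.1, cp = -0.9) {
  matrix(rep(c(amp, wc, bc, cp), each = n), n, 4,
         dimnames = list(NULL, c("amp_u", "wc_u", "bc_u", "cp_u")))
}

test_that("normalisation is scale-invariant and sign-preserving", {
  sl <- fake_slopes()
  rf <- fake_refs()
  norm <- normalize_metrics(sl, rf)
  # a common rescaling of responses rescales amplitude slopes and their
  # reference alike
  sl10 <- sl
  sl10[, c("mam", "ama", "ams", "ip")] <-
    sl10[, c("mam", "ama", "ams", "ip")] * 10
  norm10 <- normalize_metrics(sl10, fake_refs(amp = 300))
  expect_equal(norm10, norm, tolerance = 1e-12)
  expect_identical(sign(norm), sign(sl))
  # negative correlation references normalise by magnitude, not sign
  expect_equal(norm[, "cp"], sl[, "cp"] / 0.9, tolerance = 1e-12)
  expect_error(normalize_metrics(sl, fake_refs(amp = 0)), "zero")
})

test_that("sign matching counts significant same-sign metrics", {
  emp <- sign(c(mam = 1, wc = -1, bc = 1, cp = 1, ama = 1, ams = 1, ip = 1))
  strong <- fake_slopes(base = c(mam = 1, wc = -0.5, bc = 0.4, cp = 0.9,
                                 ama = 0.5, ams = 0.4, ip = 0.3))
  expect_identical(sign_match(strong, emp)$count, 7L)
  # all-nonsignificant slopes match nothing
  flat <- fake_slopes(base = rep(0, 7), sd = 1, seed = 8)
  colnames(flat) <- names(emp)
  expect_identical(sign_match(flat, emp)$count, 0L)
  # flipping the empirical signs complements the count over significant metrics
  mixed <- fake_slopes(base = c(mam = 1, wc = 0.5, bc = -0.4, cp = 0.2,
                                ama = -0.5, ams = 0.4, ip = 0.3), seed = 3)
  n_sig <- sum(vapply(seq_len(7), function(m)
    t.test(mixed[, m])$p.value < 0.05, logical(1)))
  k <- sign_match(mixed, emp)$count
  k_flip <- sign_match(mixed, -emp)$count
  expect_identical(k + k_flip, n_sig)
  # empirical sign zero excludes the metric with a warning
  expect_warning(res <- sign_match(strong, replace(emp, "ip", 0)), "excluded")
  expect_identical(res$n_usable, 6L)
})

test_that("weighted MSE matches hand computation", {
  emp_mean <- c(a = 1, b = -2)
  sim <- rbind(c(1.5, -2), c(0.5, -2))   # errors: a: 0.25, b: 0
  gm <- c(a = 0.5, b = 1)
  w <- c(a = 0.5, b = 0.5)
  expect_equal(weighted_mse(sim, emp_mean, gm, w), 0.5 * 0.25 / 0.5)
  # identical slopes: zero error
  expect_equal(weighted_mse(rbind(emp_mean, emp_mean), emp_mean, gm, w), 0)
  # linearity: doubling one metric's squared error doubles its contribution
  sim2 <- rbind(c(1 + sqrt(2) * 0.5, -2), c(1 - sqrt(2) * 0.5, -2))
  expect_equal(weighted_mse(sim2, emp_mean, gm, w),
               2 * weighted_mse(sim, emp_mean, gm, w))
  expect_warning(weighted_mse(sim, emp_mean, c(a = 0.5, b = 0), w), "dropped")
})

test_that("ranking rewards dominance and sizes the top set from the grid", {
  g <- expand.grid(sigma = c(0.3, 0.5), a = seq(0.1, 1, by = 0.1),
                   b = seq(0.1, 2.3, by = 0.1))
  tab <- rbind(
    data.frame(family = "winner", sigma = g$sigma, a = g$a, b = g$b,
               plausible = TRUE, mse = 0.1 + 0.001 * seq_len(nrow(g))),
    data.frame(family = "loser", sigma = g$sigma, a = g$a, b = g$b,
               plausible = TRUE, mse = 5 + 0.001 * seq_len(nrow(g))))
  rk <- rank_models(tab, top_fraction = 0.02, n_boot = 10)
  expect_identical(rk$winner, "winner")
  expect_true(rk$robust)
  expect_identical(rk$summary$top_k, rep(as.integer(0.02 * nrow(g)), 2L))
  # bootstrap CI of constant errors has zero width
  err <- array(0.2, c(nrow(tab), 4, 2))
  rk2 <- rank_models(tab, n_boot = 50, err_array = err,
                     weights = c(0.5, 0.5))
  expect_equal(rk2$summary$ci_lo, rk2$summary$ci_hi, tolerance = 1e-12)
  # an empty plausible set reports the family as unfit
  tab$plausible[tab$family == "loser"] <- FALSE
  rk3 <- rank_models(tab, n_boot = 10)
  expect_true(is.na(rk3$summary$best_mse[rk3$summary$family == "loser"]))
})

test_that("parameter summaries report the top set, with b not applicable for global", {
  tab <- data.frame(family = c(rep("local gain", 50), rep("global gain", 50)),
                    sigma = rep(c(0.3, 0.5), 50),
                    a = rep(seq(0.1, 1, length.out = 10), 10),
                    b = c(rep(0.5, 50), rep(NA, 50)),
                    plausible = TRUE,
                    mse = c(seq(1, 2, length.out = 50),
                            seq(1, 2, length.out = 50)))
  ps <- best_parameter_summary(tab, top_fraction = 0.02)
  expect_false(ps$applicable[ps$family == "global gain" &
                               ps$parameter == "b"])
  # top set of size 1: the summary is that single parameterisation
  one <- ps[ps$family == "local gain" & ps$parameter == "a", ]
  expect_equal(one$mode, tab$a[1])
  expect_equal(one$median, tab$a[1])
})

test_that("MSE ordering is invariant to metric and participant order", {
  emp_mean <- c(m1 = 0.5, m2 = -1, m3 = 2)
  sim <- matrix(rnorm(12, 0.3), 4, 3, dimnames = list(NULL, names(emp_mean)))
  gm <- c(m1 = 0.2, m2 = 0.4, m3 = 1)
  w <- c(m1 = 0.2, m2 = 0.5, m3 = 0.3)
  base <- weighted_mse(sim, emp_mean, gm, w)
  perm <- c(3, 1, 2)
  expect_equal(weighted_mse(sim[c(4, 2, 1, 3), perm], emp_mean[perm],
                            gm[perm], w[perm]), base, tolerance = 1e-12)
})
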