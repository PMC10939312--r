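test_that("gabor energy recovers grating orientations", {
  for (deg in c(0, 40, 60, 120, 160)) {
    g <- grating_image(deg * pi / 180, size = 64)
    est <- gabor_orientation_energy(g)
    d <- abs(est - deg * pi / 180) %% pi
    expect_lt(min(d, pi - d), 20 * pi / 180 + 1e-9)
  }
  # intensity scaling invariance of the argmax (and of relative energies)
  g <- grating_image(0.7)
  expect_equal(gabor_orientation_energy(g),
               gabor_orientation_energy(4 * g + 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  # rotating by one orientation step shifts the dominant orientation one step
  step <- 20 * pi / 180
  e1 <- gabor_orientation_energy(grating_image(2 * step))
  e2 <- gabor_orientation_energy(grating_image(3 * step))
  expect_equal(as.numeric(e2) - as.numeric(e1), step, tolerance = 1e-9)
  # exact ties break toward the smallest orientation
  tie <- grating_image(0) + grating_image(pi / 2)
  expect_equal(as.numeric(gabor_orientation_energy(tie)), 0)
  expect_error(gabor_orientation_energy(matrix(1, 8, 8)), "degenerate")
})

test_that("shape metrics match constructed silhouettes", {
  disc <- blob_silhouette(0, size = 64)
  m <- shape_complexity(disc)
  expect_equal(m[["n_concavities"]], 0)
  expect_gt(m[["silhouette_to_circle_ratio"]], 0.9)
  for (k in 3:6) {
    star <- blob_silhouette(k, size = 96, depth = 0.4, seed = k)
    expect_equal(shape_complexity(star)[["n_concavities"]], k)
  }
  expect_error(shape_complexity(matrix(0, 8, 8)), "empty")
})

test_that("the complexity axis orders shapes by protrusion count", {
  shapes <- lapply(c(0, 3, 5, 7, 9), blob_silhouette, size = 96, depth = 0.4)
  M <- do.call(rbind, lapply(shapes, shape_complexity))
  scores <- pca_first_component(M)
  expect_identical(order(scores), 1:5)  # more protrusions, more complex
  # identical silhouettes get identical scores
  M2 <- rbind(M, M[3, ])
  s2 <- pca_first_component(M2)
  expect_equal(s2[3], s2[6], tolerance = 1e-12)
  expect_error(pca_first_component(M[1, , drop = FALSE]), "at least 2")
})

test_that("1-D MDS recovers collinear geometry", {
  rdm <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3)
  pos <- mds_1d(rdm)
  expect_equal(sort(pos), c(-1, 0, 1), tolerance = 1e-9)
  expect_equal(mds_1d(matrix(0, 4, 4)), rep(0, 4))
  expect_error(mds_1d(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  # adding a constant to all dissimilarities preserves the gap order
  # (embeddings are aligned to the generating axis first: MDS sign is free)
  set.seed(2)
  for (rep in 1:5) {
    x <- sort(runif(5, 0, 10))
    rdm <- as.matrix(dist(x))
    shifted <- rdm + 0.8
    diag(shifted) <- 0
    align <- function(p) if (cor(p, x) < 0) -p else p
    g1 <- diff(align(mds_1d(rdm)))
    g2 <- diff(align(mds_1d(shifted)))
    expect_identical(order(g1), order(g2))
  }
})

test_that("model RDMs use the right metric per space kind", {
  spc <- feature_space("circular")
  spl <- feature_space("linear")
  expect_equal(model_rdm(c(0.1, pi - 0.1), spc)[1, 2], 0.2)
  expect_equal(model_rdm(c(0.4, 0.4), spc)[1, 2], 0)
  set.seed(3)
  pos <- runif(4, 0, pi)
  for (sp in list(spc, spl)) {
    rdm <- model_rdm(pos, sp)
    oracle <- matrix(0, 4, 4)
    for (i in 1:4) for (j in 1:4)
      oracle[i, j] <- feature_distance(sp, pos[i], pos[j])
    expect_equal(rdm, oracle)
    expect_equal(rdm, t(rdm))
    expect_true(all(diag(rdm) == 0) && all(rdm >= 0))
  }
  expect_lte(max(model_rdm(pos, spc)), pi / 2)
})

test_that("neural RDMs are one minus pattern correlations", {
  set.seed(4)
  pat <- matrix(rnorm(50), 5, 10)
  rdm <- neural_rdm(pat)
  oracle <- 1 - cor(t(pat))  # z-scoring leaves Pearson correlation unchanged
  diag(oracle) <- 0
  expect_equal(rdm, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  same <- rbind(pat[1, ], pat[1, ], pat[2, ])
  expect_equal(neural_rdm(same)[1, 2], 0)
  flip <- rbind(pat[1, ], -pat[1, ])
  expect_equal(neural_rdm(flip)[1, 2], 2)
  expect_error(neural_rdm(rbind(rep(1, 10), pat[1, ])), "zero-variance")
})

test_that("RSA validation recovers known structure", {
  set.seed(5)
  sp <- feature_space("circular")
  pos <- runif(8, 0, pi)
  model <- model_rdm(pos, sp)
  controls <- list(neural_rdm(matrix(rnorm(80), 8, 10)))
  # neural RDM identical to the model: perfect partial correlation
  res <- rsa_validate(model, list(model, model, model), controls)
  expect_equal(res$rho, rep(1, 3), tolerance = 1e-9)
  # label-permuted neural RDMs: correlation near zero on average
  rhos <- vapply(1:200, function(i) {
    ix <- sample(8)
    rsa_validate(model, list(model[ix, ix], model[ix, ix]), list())$rho[1]
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.05)
  # with no controls this is a plain Spearman correlation
  nr <- neural_rdm(matrix(rnorm(80), 8, 10))
  plain <- rsa_validate(model, list(nr, nr), list())$rho[1]
  oracle <- cor(model[lower.tri(model)], nr[lower.tri(nr)],
                method = "spearman")
  expect_equal(plain, oracle, tolerance = 1e-12)
  # end-to-end: noise-free localizer patterns from a generating space
  bank <- build_bank(sp, 0.8)
  vox <- sample_voxels(60, seed = 6)
  loc <- simulate_localizer(vox, bank, pos, noise_sd = 0, reps = 2)
  nrdm <- neural_rdm(rowsum(loc$responses, loc$info$stimulus_id) / 2)
  expect_gt(rsa_validate(model, list(nrdm, nrdm), list())$rho[1], 0.3)
})

test_that("feature-space comparison is a rank statistic with calibrated Mantel p", {
  set.seed(7)
  sp <- feature_space("linear")
  r1 <- model_rdm(runif(10, 0, pi), sp)
  r2 <- model_rdm(runif(10, 0, pi), sp)
  self <- compare_feature_spaces(list(a = r1, b = r1), n_boot = 100,
                                 n_perm = 200, seed = 1)
  expect_equal(self$rho, 1)
  expect_equal(self$mantel_p, 1 / 201)
  # invariant under monotone transforms of one RDM's entries
  r1m <- r1^2
  res <- compare_feature_spaces(list(a = r1, b = r2), n_boot = 50,
                                n_perm = 100, seed = 2)
  resm <- compare_feature_spaces(list(a = r1m, b = r2), n_boot = 50,
                                 n_perm = 100, seed = 2)
  expect_equal(res$rho, resm$rho)
  skip_if_not_installed("vegan")
  # independent oracle for statistic and p-value
  vg <- vegan::mantel(as.dist(r1), as.dist(r2), method = "spearman",
                      permutations = 999)
  expect_equal(res$rho, unname(vg$statistic), tolerance = 1e-12)
  expect_lt(abs(res$mantel_p - vg$signif), 0.15)
})
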