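# Representational dissimilarity matrices and RSA validation of the
# one-dimensional feature spaces.

check_rdm <- function(rdm) {
  rdm <- as.matrix(rdm)
  if (nrow(rdm) != ncol(rdm) || !isTRUE(all.equal(rdm, t(rdm),
                                                  check.attributes = FALSE)))
    stop("RDM must be a symmetric matrix")
  if (any(diag(rdm) != 0)) stop("RDM must have a zero diagonal")
  if (any(rdm < 0)) stop("RDM entries must be non-negative")
  rdm
}

lower_vec <- function(rdm) rdm[lower.tri(rdm)]

#' Model RDM from feature-space positions
#'
#' Pairwise feature distances between stimuli: wrap-around distance
#' `min(|dx|, pi - |dx|)` on circular spaces (never exceeding pi/2), `|dx|`
#' on linear ones.
#'
#' @param positions stimulus positions in feature units.
#' @param space a [feature_space()].
#' @return symmetric, zero-diagonal dissimilarity matrix.
#' @export
model_rdm <- function(positions, space) {
  n <- length(positions)
  out <- matrix(0, n, n)
  for (i in seq_len(n))
    out[i, ] <- feature_distance(space, positions[i], positions)
  diag(out) <- 0
  out
}

#' Neural RDM from localizer patterns
#'
#' Patterns are z-scored per stimulus across voxels and the RDM entry is
#' `1 - Pearson correlation`.
#'
#' @param patterns stimulus x voxel matrix (>= 2 stimuli, >= 3 voxels).
#' @return dissimilarity matrix in \[0, 2\].
#' @export
neural_rdm <- function(patterns) {
  if (nrow(patterns) < 2L || ncol(patterns) < 3L)
    stop("need at least 2 stimuli and 3 voxels")
  z <- zscore_rows(patterns)
  rdm <- 1 - stats::cor(t(z))
  diag(rdm) <- 0
  rdm[abs(rdm) < 1e-14] <- 0
  rdm
}

#' One-dimensional embedding of an RDM
#'
#' Classical (metric) multidimensional scaling, first coordinate. The
#' returned positions are centred; orientation and origin are arbitrary.
#'
#' @param rdm a valid RDM.
#' @return numeric vector of per-stimulus positions on a linear axis.
#' @export
mds_1d <- function(rdm) {
  rdm <- check_rdm(rdm)
  if (all(rdm == 0)) return(rep(0, nrow(rdm)))
  out <- cmdscale(rdm, k = 1)[, 1]
  out - mean(out)
}

# Partial Spearman correlation: Pearson on ranked vectors after residualising
# both on the ranked controls.
partial_spearman <- function(x, y, controls = NULL) {
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("constant lower triangle: correlation undefined")
  if (is.null(controls) || length(controls) == 0L)
    return(cor(rx, ry))
  cm <- vapply(controls, rank, numeric(length(x)))
  rx <- residuals(lm(rx ~ cm))
  ry <- residuals(lm(ry ~ cm))
  cor(rx, ry)
}

#' RSA validation of a feature space against neural RDMs
#'
#' For each participant, the rank-based partial correlation between the model
#' RDM and the neural RDM (lower triangles), controlling for the other
#' feature-space RDMs; correlations are Fisher z-transformed and tested
#' against zero with a two-sided one-sample t-test.
#'
#' @param model an RDM of the candidate feature space.
#' @param neural list of per-participant neural RDMs (>= 2 for the t-test).
#' @param controls list of control RDMs (may be empty, giving a plain
#'   Spearman correlation).
#' @return A list with `rho` (per participant), `z` (Fisher z), `t`, `df`,
#'   `p`.
#' @export
rsa_validate <- function(model, neural, controls = list()) {
  model <- check_rdm(model)
  mv <- lower_vec(model)
  cvs <- lapply(controls, function(r) lower_vec(check_rdm(r)))
  rho <- vapply(neural, function(r) {
    r <- check_rdm(r)
    if (any(dim(r) != dim(model))) stop("RDM sizes differ")
    partial_spearman(mv, lower_vec(r), cvs)
  }, numeric(1))
  z <- atanh(pmin(pmax(rho, -1 + 1e-12), 1 - 1e-12))
  if (length(z) < 2L) stop("need at least 2 participants for the t-test")
  if (sd(z) == 0) {
    # degenerate cohort (identical correlations): the t statistic diverges
    t_stat <- if (mean(z) == 0) NaN else sign(mean(z)) * Inf
    return(list(rho = rho, z = z, t = t_stat, df = length(z) - 1L,
                p = if (is.nan(t_stat)) NA_real_ else 0))
  }
  tt <- t.test(z)
  list(rho = rho, z = z, t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value)
}

#' Compare feature-space RDMs
#'
#' Pairwise Spearman correlations between RDM lower triangles, with bootstrap
#' confidence intervals (joint resampling of stimuli) and Mantel permutation
#' p-values (row/column permutation of one RDM).
#'
#' @param rdms named list of RDMs over the same stimulus set.
#' @param n_boot bootstrap resamples for the CI.
#' @param n_perm Mantel permutations.
#' @param seed integer seed.
#' @return data.frame with one row per RDM pair: `rho`, `ci_lo`, `ci_hi`,
#'   `mantel_p`.
#' @export
compare_feature_spaces <- function(rdms, n_boot = 10000L, n_perm = 10000L,
                                   seed = 1L) {
  rdms <- lapply(rdms, check_rdm)
  n <- nrow(rdms[[1]])
  if (any(vapply(rdms, nrow, integer(1)) != n)) stop("RDM sizes differ")
  if (is.null(names(rdms))) names(rdms) <- paste0("rdm", seq_along(rdms))
  pairs <- utils::combn(length(rdms), 2)
  out <- list()
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    a <- rdms[[i]]; b <- rdms[[j]]
    rho <- cor(lower_vec(a), lower_vec(b), method = "spearman")
    set.seed(derive_seed(seed, 60L, k))
    boot <- vapply(seq_len(n_boot), function(q) {
      ix <- sample.int(n, n, replace = TRUE)
      av <- lower_vec(a[ix, ix]); bv <- lower_vec(b[ix, ix])
      if (sd(av) == 0 || sd(bv) == 0) return(NA_real_)
      cor(av, bv, method = "spearman")
    }, numeric(1))
    ci <- quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    perm <- vapply(seq_len(n_perm), function(q) {
      ix <- sample.int(n)
      cor(lower_vec(a), lower_vec(b[ix, ix]), method = "spearman")
    }, numeric(1))
    p <- (1 + sum(perm >= rho)) / (n_perm + 1)
    out[[k]] <- data.frame(pair = paste(names(rdms)[i], names(rdms)[j],
                                        sep = " vs "),
                           rho = rho, ci_lo = ci[1], ci_hi = ci[2],
                           mantel_p = p)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
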