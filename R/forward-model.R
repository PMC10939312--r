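#' One-dimensional stimulus feature space
#'
#' Constructs the discretised 1-D feature axis on which neural response
#' functions and stimulus positions live. Orientation-like spaces are
#' circular with period pi; complexity/similarity-like spaces are linear on
#' \[0, pi\] and are later clipped to their well-covered central region (see
#' [clip_space()]).
#'
#' @param kind `"circular"` or `"linear"`.
#' @param resolution number of grid points; the default, `round(180 * pi)`,
#'   gives a grid step of about a third of a degree of orientation.
#' @return An object of class `feature_space` with elements `kind`, `range`,
#'   `resolution` and `grid` (the evaluation grid; for circular spaces the
#'   endpoint pi is excluded as it aliases 0).
#' @export
feature_space <- function(kind = c("circular", "linear"),
                          resolution = round(180 * pi)) {
  kind <- match.arg(kind)
  resolution <- as.integer(resolution)
  if (resolution < 2L) stop("`resolution` must be at least 2")
  grid <- if (kind == "circular") {
    seq(0, pi, length.out = resolution + 1L)[-(resolution + 1L)]
  } else {
    seq(0, pi, length.out = resolution)
  }
  structure(list(kind = kind, range = c(0, pi), resolution = resolution,
                 grid = grid),
            class = "feature_space")
}

#' @export
print.feature_space <- function(x, ...) {
  cat(sprintf("<feature_space> %s on [0, pi%s, %d grid points\n",
              x$kind, if (x$kind == "circular") ")" else "]", x$resolution))
  invisible(x)
}

#' Distance in feature space
#'
#' Circular spaces use the wrap-around distance `min(|dx|, pi - |dx|)` (so the
#' maximal distance is pi/2, i.e. the orthogonal orientation); linear spaces
#' use `|dx|`.
#'
#' @param space a [feature_space()].
#' @param x,y positions (recycled).
#' @return numeric vector of distances.
#' @export
feature_distance <- function(space, x, y) {
  if (space$kind == "circular") {
    d <- abs(x - y) %% pi
    pmin(d, pi - d)
  } else {
    abs(x - y)
  }
}

# Width-free curve shape on the grid: activity = exp(shape * rate(width)).
# Circular: shape = cos(2 * (x - mu)) - 1 (period pi via angle doubling);
# linear:   shape = -(x - mu)^2 / 2.
curve_shape <- function(space, mu, x) {
  if (space$kind == "circular") {
    cos(2 * outer(mu, x, "-")) - 1
  } else {
    -outer(mu, x, "-")^2 / 2
  }
}

# Exponent power p such that rate = 1 / width^p. For linear (Gaussian)
# curves p = 2 always. For circular curves the width-to-concentration mapping
# is a package choice (see build_bank).
curve_power <- function(space, kappa_map) {
  if (space$kind == "linear") 2 else if (kappa_map == "inverse") 1 else 2
}

#' Bank of feature-tuned neural response functions
#'
#' Builds the eight evenly spaced population response functions covering the
#' feature space, each peak-normalised to one, plus their summed response over
#' the discrete grid. Circular spaces use a circular-normal (von Mises) curve
#' on the doubled angle; linear spaces use a Gaussian with standard deviation
#' `sigma`.
#'
#' For the circular family the free width parameter `sigma` must be mapped to
#' a von Mises concentration. The package default is `kappa = 1/sigma`
#' (`kappa_map = "inverse"`): under the selectivity criterion of
#' [plausibility_check()] this mapping keeps every grid width in the default
#' parameter grid feature-selective (response at the orthogonal orientation
#' below 75% of peak up to sigma of about 6.9), which reproduces the behaviour
#' of the analysis this package implements, where circular response spaces are
#' rejected far more rarely than linear ones. The small-angle Gaussian match
#' `kappa = 1/sigma^2` is available as `"inverse_square"`.
#'
#' @param space a [feature_space()].
#' @param sigma response-function width in feature-space units; must be > 0.
#' @param n_pop number of populations (8, matching the modelled banks).
#' @param kappa_map circular width-to-concentration mapping, `"inverse"`
#'   (default) or `"inverse_square"`; ignored for linear spaces.
#' @return An object of class `response_bank`: `space`, `sigma`, `mu`
#'   (population means), `activity` (`n_pop` x `resolution` matrix, each row
#'   peaking at 1), `summed` (column sums) and bookkeeping fields.
#' @export
build_bank <- function(space, sigma, n_pop = 8L,
                       kappa_map = c("inverse", "inverse_square")) {
  kappa_map <- match.arg(kappa_map)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("`sigma` must be a single positive number")
  mu <- if (space$kind == "circular") {
    seq(0, pi, length.out = n_pop + 1L)[-(n_pop + 1L)]
  } else {
    seq(0, pi, length.out = n_pop)
  }
  shape <- curve_shape(space, mu, space$grid)
  power <- curve_power(space, kappa_map)
  activity <- exp(shape / sigma^power)
  structure(list(space = space, sigma = sigma, mu = mu, n_pop = n_pop,
                 kappa_map = kappa_map, power = power, shape = shape,
                 activity = activity, summed = colSums(activity)),
            class = "response_bank")
}

#' @export
print.response_bank <- function(x, ...) {
  cat(sprintf("<response_bank> %d populations, %s space, sigma = %g\n",
              x$n_pop, x$space$kind, x$sigma))
  invisible(x)
}

# Population activity at arbitrary positions (not necessarily on the grid),
# optionally with per-population widths. Returns n_pop x length(x).
bank_activity <- function(bank, x, widths = NULL) {
  widths <- if (is.null(widths)) rep(bank$sigma, bank$n_pop) else widths
  shape <- curve_shape(bank$space, bank$mu, x)
  exp(shape / widths^bank$power)
}

#' Clip a linear feature space to its well-covered centre
#'
#' Near the ends of a linear feature space the summed response falls off
#' because no populations are tuned beyond the boundary. Stimuli are therefore
#' restricted to the region in which the summed unmodulated response reaches
#' at least `threshold` of its maximum. The clip is the smallest interval
#' containing every admissible grid position; interior coverage dips (which
#' arise for very narrow tuning) are left to the coverage criterion of
#' [plausibility_check()] rather than excluded here.
#'
#' @param bank a [build_bank()] result.
#' @param threshold minimal summed response relative to its maximum.
#' @return A list with `bounds` (length-2 numeric) and `idx` (grid indices of
#'   the clipped region). For circular spaces the full grid is returned.
#' @export
clip_space <- function(bank, threshold = 0.95) {
  grid <- bank$space$grid
  if (bank$space$kind == "circular")
    return(list(bounds = bank$space$range, idx = seq_along(grid)))
  ok <- which(bank$summed >= threshold * max(bank$summed))
  if (length(ok) == 0L) stop("empty clip region: sigma is pathological")
  idx <- seq(min(ok), max(ok))
  list(bounds = grid[range(ok)], idx = idx)
}

#' Expectation modulation model
#'
#' One of the six candidate neural modulations: an operation class (`gain`
#' rescales response amplitude; `tuning` narrows response width, leaving the
#' peak untouched) crossed with a distance profile (`local` suppresses
#' populations tuned toward the expected feature — dampening; `remote`
#' suppresses populations tuned away from it — sharpening; `global`
#' suppresses all populations equally).
#'
#' @param op_class `"gain"` or `"tuning"`.
#' @param distance `"local"`, `"remote"` or `"global"`.
#' @param a suppression magnitude in (0, 1]; `a = 1` means no modulation.
#' @param b distance scale (> 0) over which the modulation falls off; not used
#'   (and may be `NA`) for global models.
#' @return An object of class `modulation_model`.
#' @export
modulation_model <- function(op_class = c("gain", "tuning"),
                             distance = c("local", "remote", "global"),
                             a, b = NA_real_) {
  op_class <- match.arg(op_class)
  distance <- match.arg(distance)
  if (!is.numeric(a) || length(a) != 1L || a <= 0 || a > 1)
    stop("`a` must be a single number in (0, 1]")
  if (distance != "global" && (!is.numeric(b) || length(b) != 1L ||
                               is.na(b) || b <= 0))
    stop("`b` must be a single positive number for local/remote models")
  structure(list(op_class = op_class, distance = distance,
                 a = a, b = if (distance == "global") NA_real_ else b),
            class = "modulation_model")
}

#' @export
print.modulation_model <- function(x, ...) {
  cat(sprintf("<modulation_model> %s %s: a = %g%s\n", x$distance, x$op_class,
              x$a, if (is.na(x$b)) "" else sprintf(", b = %g", x$b)))
  invisible(x)
}

#' Suppression factor as a function of feature distance
#'
#' The multiplicative factor c applied to a population tuned a feature
#' distance `d` away from the expected stimulus:
#' local `c = min(1, a + |d/b| (1 - a))`,
#' remote `c = max(a, 1 - |d/b| (1 - a))`,
#' global `c = a`.
#' The factor always lies in `[a, 1]`.
#'
#' @param model a [modulation_model()].
#' @param d non-negative feature distance(s); circular distances are capped at
#'   pi/2 by construction ([feature_distance()]).
#' @return numeric vector of factors.
#' @export
suppression_factor <- function(model, d) {
  a <- model$a
  switch(model$distance,
         global = rep(a, length(d)),
         local  = pmin(1, a + abs(d / model$b) * (1 - a)),
         remote = pmax(a, 1 - abs(d / model$b) * (1 - a)))
}

#' Modulate a response bank for an expected stimulus
#'
#' Applies an expectation model to a bank, conditional on the expected
#' stimulus sitting at feature position `x_j`. Gain models multiply each
#' population's curve by its suppression factor; tuning models re-evaluate
#' each curve with width `c * sigma` (peak unchanged).
#'
#' @param bank a [build_bank()] result.
#' @param model a [modulation_model()].
#' @param x_j expected stimulus position; must lie inside the clipped region
#'   for linear spaces.
#' @param clip optional [clip_space()] result (computed if missing).
#' @param check_clip refuse positions outside the clipped region (default).
#'   The plausibility screen disables the check to probe worst-case expected
#'   positions anywhere on the feature axis.
#' @return A list of class `modulated_nrs`: `activity` (populations x grid),
#'   `summed`, plus the inputs.
#' @export
modulate <- function(bank, model, x_j, clip = NULL, check_clip = TRUE) {
  if (bank$space$kind == "linear" && check_clip) {
    clip <- if (is.null(clip)) clip_space(bank) else clip
    if (x_j < clip$bounds[1] || x_j > clip$bounds[2])
      stop("expected position lies outside the clipped feature space")
  }
  d <- feature_distance(bank$space, x_j, bank$mu)
  cf <- suppression_factor(model, d)
  activity <- if (model$op_class == "gain") {
    bank$activity * cf
  } else {
    exp(bank$shape / (cf * bank$sigma)^bank$power)
  }
  structure(list(activity = activity, summed = colSums(activity),
                 factors = cf, bank = bank, model = model, x_j = x_j),
            class = "modulated_nrs")
}

# Population response at distance pi/2 from its mean, relative to peak.
selectivity_at_orthogonal <- function(space, sigma, kappa_map = "inverse") {
  if (space$kind == "circular") {
    # doubled angle: cos(2 * pi/2) - 1 = -2
    exp(-2 / sigma^curve_power(space, kappa_map))
  } else {
    exp(-(pi / 2)^2 / (2 * sigma^2))
  }
}

#' Biological plausibility of a modulated neural response space
#'
#' Applies the three response requirements that every parameter combination
#' must satisfy before entering the simulation:
#' \enumerate{
#'   \item \emph{Coverage}: the unmodulated summed response over the clipped
#'     grid must nowhere fall below 75% of its maximum (no quasi-blind
#'     feature values).
#'   \item \emph{Minimal modulated response}: for the worst-case expected
#'     position in the clipped grid, the modulated summed response must stay
#'     at or above 10% of the maximal unmodulated summed response everywhere
#'     (no outright blindness to expected features).
#'   \item \emph{Selectivity}: no population may respond above 75% of its
#'     peak at a feature distance of pi/2 from its mean (tuning must not be
#'     implausibly flat).
#' }
#'
#' @param bank a [build_bank()] result.
#' @param model a [modulation_model()].
#' @param candidates candidate expected positions for criterion 2; defaults to
#'   every grid point of the full feature range (the minimal modulated
#'   response itself is always evaluated over the clipped grid). A coarser set
#'   can be supplied for quick checks.
#' @param thresholds named list overriding the default thresholds
#'   (`coverage = 0.75`, `modulated = 0.10`, `selectivity = 0.75`,
#'   `clip = 0.95`).
#' @return A list with `pass` (logical) and `criterion` (`NA` or 1, 2, 3 — the
#'   first failing criterion).
#' @export
plausibility_check <- function(bank, model, candidates = NULL,
                               thresholds = list()) {
  th <- utils::modifyList(list(coverage = 0.75, modulated = 0.10,
                               selectivity = 0.75, clip = 0.95), thresholds)
  clip <- clip_space(bank, th$clip)
  s <- bank$summed[clip$idx]
  if (min(s) < th$coverage * max(s))
    return(list(pass = FALSE, criterion = 1L))
  if (is.null(candidates)) candidates <- bank$space$grid
  thr <- th$modulated * max(s)
  for (x_j in candidates) {
    m <- modulate(bank, model, x_j, clip = clip, check_clip = FALSE)
    if (min(m$summed[clip$idx]) < thr)
      return(list(pass = FALSE, criterion = 2L))
  }
  if (selectivity_at_orthogonal(bank$space, bank$sigma, bank$kappa_map) >
      th$selectivity)
    return(list(pass = FALSE, criterion = 3L))
  list(pass = TRUE, criterion = NA_integer_)
}

#' Default parameter grid
#'
#' The default grid crosses 17 response widths, 20 suppression magnitudes and
#' 23 distance scales: sigma in 0.1-1.0 (step 0.1), 1.5-4.0 (step 0.5) and
#' 5.0; a from 0.05 to 1.00 in steps of 0.05; b from 0.1 to 2.3 in steps of
#' 0.1 (about three quarters of pi). This yields 17 x 20 x 23 = 7820
#' combinations for each local/remote family; global families have no b and
#' use the 340 sigma x a combinations.
#'
#' @param sigma,a,b value lists; all must be non-empty, a in (0, 1], b > 0.
#' @return An object of class `esfm_grid` (list of the three value vectors).
#' @export
build_grid <- function(sigma = c(seq(0.1, 1, by = 0.1), seq(1.5, 4, by = 0.5), 5),
                       a = seq(0.05, 1, by = 0.05),
                       b = seq(0.1, 2.3, by = 0.1)) {
  if (length(sigma) == 0L || length(a) == 0L || length(b) == 0L)
    stop("grid value lists must be non-empty")
  if (any(a <= 0 | a > 1)) stop("`a` values must lie in (0, 1]")
  if (any(b <= 0)) stop("`b` values must be positive")
  if (any(sigma <= 0)) stop("`sigma` values must be positive")
  structure(list(sigma = round(sigma, 10), a = round(a, 10), b = round(b, 10)),
            class = "esfm_grid")
}

#' @export
print.esfm_grid <- function(x, ...) {
  cat(sprintf(paste0("<esfm_grid> %d sigma x %d a x %d b = %d combinations ",
                     "(local/remote), %d (global)\n"),
              length(x$sigma), length(x$a), length(x$b), grid_size(x),
              length(x$sigma) * length(x$a)))
  invisible(x)
}

#' @rdname build_grid
#' @param grid an `esfm_grid`.
#' @param family optional family (row of [esfm_families()]); global families
#'   drop b.
#' @export
grid_size <- function(grid, family = NULL) {
  n <- length(grid$sigma) * length(grid$a)
  if (!is.null(family) && family$distance == "global") n
  else n * length(grid$b)
}

#' The six candidate model families
#'
#' @return A data.frame with columns `op_class` and `distance` and a `family`
#'   label, one row per candidate modulation family.
#' @export
esfm_families <- function() {
  fam <- expand.grid(distance = c("local", "remote", "global"),
                     op_class = c("gain", "tuning"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  fam <- fam[, c("op_class", "distance")]
  fam$family <- paste(fam$distance, fam$op_class)
  fam[order(fam$op_class, fam$distance), ]
}

#' Plausibility screen over a full parameter grid
#'
#' Runs [plausibility_check()] for every family and grid combination, using an
#' exact compiled scan with analytic pruning (the global model at the same
#' `a` is a pointwise lower bound for local/remote modulated responses, so
#' most combinations never need the expensive worst-case scan). Criterion 2
#' treats every grid position on the feature axis as a candidate expected
#' position and takes the minimum of the modulated summed response over the
#' clipped grid.
#'
#' @param space a [feature_space()].
#' @param grid an [build_grid()] grid.
#' @param families subset of [esfm_families()] rows.
#' @param kappa_map see [build_bank()].
#' @param thresholds see [plausibility_check()].
#' @return A data.frame: `family`, `op_class`, `distance`, `sigma`, `a`, `b`
#'   (`NA` for global), `plausible`, `fail_criterion` (`NA` or 1/2/3, first
#'   failing criterion).
#' @export
plausibility_table <- function(space, grid = build_grid(),
                               families = esfm_families(),
                               kappa_map = c("inverse", "inverse_square"),
                               thresholds = list()) {
  kappa_map <- match.arg(kappa_map)
  th <- utils::modifyList(list(coverage = 0.75, modulated = 0.10,
                               selectivity = 0.75, clip = 0.95), thresholds)
  dist_code <- c(local = 0L, remote = 1L)
  out <- vector("list", 0L)
  for (sigma in grid$sigma) {
    bank <- build_bank(space, sigma, kappa_map = kappa_map)
    clip <- clip_space(bank, th$clip)
    s <- bank$summed[clip$idx]
    fail1 <- min(s) < th$coverage * max(s)
    fail3 <- selectivity_at_orthogonal(space, sigma, kappa_map) >
      th$selectivity
    thr <- th$modulated * max(s)
    min_s <- min(s)
    # candidate expected positions span the full feature axis; the minimal
    # modulated response is evaluated over the clipped grid only
    Dxj <- vapply(space$grid, function(p) feature_distance(space, p, bank$mu),
                  numeric(bank$n_pop))
    for (f in seq_len(nrow(families))) {
      fam <- families[f, ]
      is_global <- fam$distance == "global"
      bvals <- if (is_global) NA_real_ else grid$b
      combos <- expand.grid(a = grid$a, b = bvals, KEEP.OUT.ATTRS = FALSE)
      if (fail1) {
        fail2 <- rep(NA, nrow(combos))
      } else if (fam$op_class == "gain") {
        if (is_global) {
          fail2 <- combos$a * min_s < thr
        } else {
          fail2 <- rep(FALSE, nrow(combos))
          scan <- combos$a * min_s < thr  # lower bound: c >= a everywhere
          if (any(scan))
            fail2[scan] <- crit2_scan_gain(bank$activity, Dxj,
                                           combos$a[scan], combos$b[scan],
                                           dist_code[[fam$distance]], thr,
                                           clip$idx)
        }
      } else {
        glob_min <- vapply(grid$a, function(a)
          min_summed_tuning(bank$shape, a * sigma, bank$power, clip$idx),
          numeric(1))
        names(glob_min) <- as.character(grid$a)
        if (is_global) {
          fail2 <- glob_min[as.character(combos$a)] < thr
        } else {
          fail2 <- rep(FALSE, nrow(combos))
          scan <- glob_min[as.character(combos$a)] < thr
          if (any(scan))
            fail2[scan] <- crit2_scan_tuning(bank$shape, Dxj,
                                             combos$a[scan], combos$b[scan],
                                             dist_code[[fam$distance]],
                                             sigma, bank$power, thr,
                                             clip$idx)
        }
      }
      n <- nrow(combos)
      crit <- ifelse(rep(fail1, n), 1L,
                     ifelse(!is.na(fail2) & fail2, 2L,
                            ifelse(rep(fail3, n), 3L, NA_integer_)))
      out[[length(out) + 1L]] <- data.frame(
        family = fam$family, op_class = fam$op_class,
        distance = fam$distance, sigma = sigma,
        a = combos$a, b = combos$b,
        plausible = is.na(crit), fail_criterion = crit,
        row.names = NULL)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rejection rates of the plausibility screen
#'
#' Summarises a [plausibility_table()] into the percentage of rejected
#' parameter combinations per model family, plus the pooled percentage.
#' Families are pooled by averaging their percentages, so that global
#' families (which have no distance-scale parameter) carry the same weight as
#' local/remote ones.
#'
#' @param tab a [plausibility_table()] result.
#' @return A list with `per_family` (named percentages) and `overall`
#'   (percentage).
#' @export
rejection_rates <- function(tab) {
  per <- tapply(!tab$plausible, tab$family, mean) * 100
  list(per_family = per, overall = mean(per))
}
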