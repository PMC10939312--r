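# Shape-complexity feature space: six silhouette metrics reduced to a single
# complexity axis by PCA.

# Convex hull of foreground pixel centres, as polygon vertex coordinates
# (rows = vertices, columns = x, y).
hull_polygon <- function(xy) {
  h <- grDevices::chull(xy)
  xy[h, , drop = FALSE]
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

polygon_perimeter <- function(poly) {
  d <- poly - poly[c(2:nrow(poly), 1), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

# Rasterise a convex polygon onto the pixel grid of a mask: scanline fill.
rasterize_convex <- function(poly, nr, nc) {
  out <- matrix(FALSE, nr, nc)
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  for (i in seq_len(nr)) {
    y <- i
    xs <- numeric(0)
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1L else k + 1L
      y1 <- py[k]; y2 <- py[k2]
      if ((y1 <= y && y2 >= y) || (y2 <= y && y1 >= y)) {
        if (y1 == y2) xs <- c(xs, px[k], px[k2])
        else xs <- c(xs, px[k] + (y - y1) / (y2 - y1) * (px[k2] - px[k]))
      }
    }
    if (length(xs) >= 2) {
      j <- seq(max(1L, ceiling(min(xs))), min(nc, floor(max(xs))))
      out[i, j] <- TRUE
    }
  }
  out
}

# Minimal enclosing circle of a point set (exact, via hull vertices: the
# optimal circle is determined by 2 or 3 hull points).
min_enclosing_circle <- function(xy) {
  hull <- hull_polygon(xy)
  n <- nrow(hull)
  if (n == 1L) return(list(center = hull[1, ], radius = 0))
  best <- NULL
  covers <- function(c, r) all(sqrt(rowSums((xy - rep(c, each = nrow(xy)))^2))
                               <= r + 1e-9)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    c <- (hull[i, ] + hull[j, ]) / 2
    r <- sqrt(sum((hull[i, ] - c)^2))
    if (covers(c, r) && (is.null(best) || r < best$radius))
      best <- list(center = c, radius = r)
  }
  if (!is.null(best)) return(best)
  for (i in seq_len(n - 2L)) for (j in (i + 1L):(n - 1L)) for (k in (j + 1L):n) {
    p1 <- hull[i, ]; p2 <- hull[j, ]; p3 <- hull[k, ]
    d <- 2 * (p1[1] * (p2[2] - p3[2]) + p2[1] * (p3[2] - p1[2]) +
                p3[1] * (p1[2] - p2[2]))
    if (abs(d) < 1e-12) next
    ux <- (sum(p1^2) * (p2[2] - p3[2]) + sum(p2^2) * (p3[2] - p1[2]) +
             sum(p3^2) * (p1[2] - p2[2])) / d
    uy <- (sum(p1^2) * (p3[1] - p2[1]) + sum(p2^2) * (p1[1] - p3[1]) +
             sum(p3^2) * (p2[1] - p1[1])) / d
    c <- c(ux, uy)
    r <- sqrt(sum((p1 - c)^2))
    if (covers(c, r) && (is.null(best) || r < best$radius))
      best <- list(center = c, radius = r)
  }
  best
}

#' Shape-complexity metrics of a silhouette
#'
#' Six complexity descriptors of a binary silhouette: the number and total
#' area of concavities (connected components of convex hull minus silhouette,
#' above a small area floor that suppresses rasterisation specks), the area
#' and perimeter of the convex hull, the area of the minimal enclosing
#' circle, and the silhouette-to-circle area ratio (compactness).
#'
#' @param silhouette binary (logical or 0/1) matrix with a single connected
#'   foreground component.
#' @param min_concavity_area area floor (pixels) below which a concavity is
#'   ignored.
#' @return A named numeric vector: `n_concavities`, `concavity_area`,
#'   `hull_area`, `hull_perimeter`, `min_circle_area`,
#'   `silhouette_to_circle_ratio`.
#' @export
shape_complexity <- function(silhouette, min_concavity_area = 5) {
  mask <- silhouette > 0
  if (!any(mask)) stop("empty silhouette")
  idx <- which(mask, arr.ind = TRUE)
  xy <- cbind(x = idx[, 2], y = idx[, 1])
  poly <- hull_polygon(xy)
  hull_mask <- rasterize_convex(poly, nrow(mask), ncol(mask))
  conc <- hull_mask & !mask
  lab <- label_components(conc)
  sizes <- tabulate(lab[lab > 0])
  keep <- sizes >= min_concavity_area
  circ <- min_enclosing_circle(xy)
  circle_area <- pi * circ$radius^2
  c(n_concavities = sum(keep),
    concavity_area = sum(sizes[keep]),
    hull_area = polygon_area(poly),
    hull_perimeter = polygon_perimeter(poly),
    min_circle_area = circle_area,
    silhouette_to_circle_ratio = if (circle_area > 0)
      min(sum(mask) / circle_area, 1) else 1)
}

#' First principal component of shape metrics
#'
#' Column-standardises a stimulus x metric table and returns the first
#' principal-component scores, with the sign fixed so that higher scores mean
#' more complex shapes (positive loading on the number of concavities).
#'
#' @param metrics stimulus x metric matrix (rows >= 2), e.g. rbind-ed
#'   [shape_complexity()] vectors.
#' @return per-stimulus complexity scores.
#' @export
pca_first_component <- function(metrics) {
  metrics <- as.matrix(metrics)
  if (nrow(metrics) < 2L) stop("PCA needs at least 2 stimuli")
  keep <- apply(metrics, 2, sd) > 0
  p <- prcomp(metrics[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  scores <- p$x[, 1]
  load <- p$rotation[, 1]
  if ("n_concavities" %in% names(load) && load[["n_concavities"]] < 0)
    scores <- -scores
  unname(scores)
}

#' Synthetic blob silhouette with protrusions
#'
#' A star-like blob whose boundary radius is modulated by `n_protrusions`
#' sinusoidal lobes; more protrusions produce more concavities and a more
#' complex shape. Used as ground truth for [shape_complexity()].
#'
#' @param n_protrusions number of lobes (0 gives a disc).
#' @param size image side length in pixels.
#' @param depth lobe depth as a fraction of the base radius.
#' @param seed rotation seed (a random phase decorrelates raster artefacts).
#' @return logical `size` x `size` silhouette matrix.
#' @export
blob_silhouette <- function(n_protrusions, size = 64L, depth = 0.35,
                            seed = 1L) {
  set.seed(derive_seed(seed, 70L))
  phase <- runif(1, 0, 2 * pi)
  ctr <- (size + 1) / 2
  base_r <- size * 0.32
  X <- matrix(seq_len(size), size, size, byrow = TRUE) - ctr
  Y <- matrix(seq_len(size), size, size) - ctr
  theta <- atan2(Y, X)
  r <- sqrt(X^2 + Y^2)
  boundary <- base_r * (1 + if (n_protrusions > 0)
    depth * cos(n_protrusions * (theta + phase)) else 0)
  r <= boundary
}
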