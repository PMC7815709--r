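#' Traced outline of an epithelial cell
#'
#' Holds the hand-traced apical and basal surfaces (open polylines) and
#' the cell region polygon of one choroid plexus epithelial cell, in
#' micrometres. Pixel-unit inputs are converted once at construction via
#' `pixel_size`.
#'
#' @param apical,basal Two-column matrices (x, y) with >= 2 vertices each;
#'   open polylines, no closing segment is added.
#' @param region Two-column matrix, vertices of a simple polygon bounding
#'   the cell (closed implicitly).
#' @param id Cell label.
#' @param pixel_size Optional um/px scale applied to all coordinates.
#' @return An object of class `"cell_outline"`.
#' @export
cell_outline <- function(apical, basal, region, id = "cell",
                         pixel_size = NULL) {
  apical <- as_xy(apical, "apical"); basal <- as_xy(basal, "basal")
  region <- as_xy(region, "region")
  if (nrow(apical) < 2L || nrow(basal) < 2L)
    stop("apical and basal polylines need >= 2 vertices")
  if (nrow(region) < 3L) stop("cell region needs >= 3 vertices")
  if (!is.null(pixel_size)) {
    if (pixel_size <= 0) stop("pixel_size must be > 0")
    apical <- apical * pixel_size; basal <- basal * pixel_size
    region <- region * pixel_size
  }
  structure(list(apical = apical, basal = basal, region = region, id = id),
            class = "cell_outline")
}

as_xy <- function(m, what) {
  m <- as.matrix(m)
  if (ncol(m) != 2L || !is.numeric(m) || any(!is.finite(m)))
    stop(sprintf("%s must be a finite numeric 2-column matrix", what))
  unname(m)
}

#' Shortest distance from a point to an open polyline
#'
#' Exact Euclidean distance from `p` to the nearest point on any segment
#' of the polyline, including projections onto segment interiors. This is
#' the distance-transform primitive behind the apical:basal proximity
#' ratio.
#'
#' @param p Numeric length-2 point (x, y) or an n x 2 matrix of points.
#' @param line Two-column matrix of polyline vertices (>= 2).
#' @return Distance(s), um; `>= 0`.
#' @examples
#' point_to_polyline_distance(c(0, 1), rbind(c(-1, 0), c(1, 0))) # 1
#' @export
point_to_polyline_distance <- function(p, line) {
  line <- as_xy(line, "polyline")
  if (nrow(line) < 2L) stop("polyline needs >= 2 vertices")
  pts <- if (is.null(dim(p))) matrix(p, ncol = 2L) else as_xy(p, "p")
  a <- line[-nrow(line), , drop = FALSE]
  b <- line[-1L, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  out <- vapply(seq_len(nrow(pts)), function(k) {
    ap <- sweep(a, 2L, pts[k, ], "-") * -1
    tpar <- rowSums(ap * ab) / pmax(len2, .Machine$double.eps)
    tpar <- pmin(pmax(tpar, 0), 1)
    near <- a + ab * tpar
    sqrt(min(rowSums(sweep(near, 2L, pts[k, ], "-")^2)))
  }, numeric(1L))
  if (is.null(dim(p))) out[1L] else out
}

#' Apical:basal proximity ratio of an organelle
#'
#' Polarity score of an organelle centroid within its cell: 1 means the
#' centroid lies on the apical surface, 0 on the basal surface. Interior
#' points are scored by `d_basal / (d_apical + d_basal)`, the simplest
#' continuous interpolant honouring both boundary anchors; the score is
#' invariant to rigid motion and uniform scaling of the geometry.
#'
#' @param centroid Length-2 numeric (x, y), um.
#' @param cell A [cell_outline()].
#' @return A list with `ratio` (in \[0, 1\]), `d_apical`, `d_basal` (um).
#' @export
proximity_ratio <- function(centroid, cell) {
  stopifnot(inherits(cell, "cell_outline"))
  da <- point_to_polyline_distance(centroid, cell$apical)
  db <- point_to_polyline_distance(centroid, cell$basal)
  if (da == 0 && db == 0)
    stop("degenerate geometry: centroid on both apical and basal surfaces")
  list(ratio = db / (da + db), d_apical = da, d_basal = db)
}

#' Polarity scores for a table of organelles
#'
#' Vectorised [proximity_ratio()] over a mitochondrion table.
#'
#' @param mitos Data frame with columns `cell_id`, `x`, `y`, `area` and
#'   optionally `group`.
#' @param cells Named list of [cell_outline()] objects (names = cell ids).
#' @return `mitos` with `d_apical`, `d_basal`, and `ratio` columns added.
#' @export
polarity_table <- function(mitos, cells) {
  need <- c("cell_id", "x", "y")
  if (!all(need %in% names(mitos)))
    stop("mitos must have columns cell_id, x, y")
  missing_cells <- setdiff(unique(mitos$cell_id), names(cells))
  if (length(missing_cells))
    stop("organelles reference unknown cells: ",
         paste(missing_cells, collapse = ", "))
  res <- lapply(seq_len(nrow(mitos)), function(k) {
    proximity_ratio(c(mitos$x[k], mitos$y[k]), cells[[mitos$cell_id[k]]])
  })
  mitos$d_apical <- vapply(res, `[[`, numeric(1L), "d_apical")
  mitos$d_basal <- vapply(res, `[[`, numeric(1L), "d_basal")
  mitos$ratio <- vapply(res, `[[`, numeric(1L), "ratio")
  mitos
}

#' Mitochondrial morphometrics for a field of view
#'
#' Count, mean organelle area, and percent area occupancy over the
#' epithelial area in the field of view (total organelle area divided by
#' total cell-region area, times 100).
#'
#' @param cells Named list of [cell_outline()] objects.
#' @param areas Numeric vector of organelle areas (um^2); may be empty.
#' @return A list with `count`, `mean_area` (um^2; `NA` when empty), and
#'   `occupancy` (percent).
#' @export
morphometrics <- function(cells, areas = numeric(0)) {
  if (any(areas <= 0)) stop("organelle areas must be > 0")
  cell_area <- sum(vapply(cells, function(cl) polygon_area(cl$region),
                          numeric(1L)))
  if (cell_area <= 0) stop("zero total cell area")
  list(count = length(areas),
       mean_area = if (length(areas)) mean(areas) else NA_real_,
       occupancy = 100 * sum(areas) / cell_area)
}

# shoelace formula, absolute area of a simple polygon
polygon_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# even-odd ray-casting point-in-polygon test (boundary counts as inside)
point_in_polygon <- function(p, v) {
  x <- v[, 1L]; y <- v[, 2L]; n <- length(x)
  j <- c(n, seq_len(n - 1L))
  inside <- FALSE
  for (k in seq_len(n)) {
    if (((y[k] > p[2L]) != (y[j[k]] > p[2L])) &&
        (p[1L] < (x[j[k]] - x[k]) * (p[2L] - y[k]) /
           (y[j[k]] - y[k]) + x[k]))
      inside <- !inside
  }
  if (!inside) {
    # accept boundary points
    inside <- point_to_polyline_distance(p, rbind(v, v[1L, ])) < 1e-9
  }
  inside
}

#' Empirical cumulative distribution of polarity scores
#'
#' Thin wrapper over [stats::ecdf()]: right-continuous, non-decreasing,
#' reaching 1 at the sample maximum. Used for cumulative polarity plots.
#'
#' @param values Non-empty numeric sample.
#' @return A function of class `"ecdf"`.
#' @export
polarity_ecdf <- function(values) {
  if (!length(values) || any(!is.finite(values)))
    stop("values must be a non-empty finite sample")
  stats::ecdf(values)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' D is the supremum over all observed points of the absolute difference
#' between the two empirical CDFs; the p-value uses the asymptotic
#' two-sided KS distribution at effective sample size
#' `n_a * n_b / (n_a + n_b)`. Suitable for the ~10^3-scale organelle
#' samples compared here; no exact small-sample table is used.
#'
#' @param a,b Non-empty numeric samples.
#' @return A list with `statistic` (D), `p_value`, `n_a`, `n_b`.
#' @export
ks_two_sample <- function(a, b) {
  if (!length(a) || !length(b) || any(!is.finite(c(a, b))))
    stop("both samples must be non-empty and finite")
  pooled <- sort(unique(c(a, b)))
  fa <- stats::ecdf(a)(pooled)
  fb <- stats::ecdf(b)(pooled)
  d <- max(abs(fa - fb))
  n_eff <- length(a) * length(b) / (length(a) + length(b))
  lambda <- sqrt(n_eff) * d
  p <- if (lambda < 1e-8) 1 else {
    k <- seq_len(101)
    min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))))
  }
  list(statistic = d, p_value = p, n_a = length(a), n_b = length(b))
}
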