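#' Percent volume increase of a cell timecourse
#'
#' dV/V0 expressed in percent for each timepoint after a challenge:
#' `100 * (v_t - v0) / v0`. Unit-free: voxel counts and um^3 give the
#' same series.
#'
#' @param v0 Initial (pre-challenge) volume; `> 0`.
#' @param v_t Volumes at subsequent timepoints.
#' @return Percent increase, same length as `v_t`.
#' @examples
#' percent_volume_increase(4000, c(4200, 4600)) # 5, 15
#' @export
percent_volume_increase <- function(v0, v_t) {
  if (!is.numeric(v0) || length(v0) != 1L || !is.finite(v0) || v0 <= 0)
    stop("v0 must be a positive scalar")
  if (any(!is.finite(v_t))) stop("non-finite volumes in v_t")
  100 * (v_t - v0) / v0
}

#' Per-animal swelling series under high-K+ challenge
#'
#' Averages per-cell percent-swelling series within each animal at every
#' timepoint, so one series represents one animal. Animals contributing
#' fewer than `min_cells` cells are excluded with a warning (the assay
#' design calls for at least five cells per explant).
#'
#' @param tc Data frame with columns `animal_id`, `cell_id`, `time_min`,
#'   `volume`. Within each cell, the earliest timepoint is V0.
#' @param min_cells Minimum cells per animal (default 5).
#' @param time_tol Timepoint alignment tolerance in minutes (default 0.5):
#'   cells are aligned by timepoint index and their nominal times must
#'   agree within this tolerance.
#' @return A list with `per_cell` (long data frame: animal_id, cell_id,
#'   time_min, pct_increase), `per_animal` (animal_id, time_min,
#'   mean_pct), and `excluded` (animal ids dropped).
#' @export
per_animal_swelling <- function(tc, min_cells = 5L, time_tol = 0.5) {
  need <- c("animal_id", "cell_id", "time_min", "volume")
  if (!all(need %in% names(tc)))
    stop("timecourse needs columns ", paste(need, collapse = ", "))
  key <- interaction(tc$animal_id, tc$cell_id, drop = TRUE)
  per_cell <- do.call(rbind, lapply(split(tc, key), function(d) {
    d <- d[order(d$time_min), ]
    data.frame(animal_id = d$animal_id[1L], cell_id = d$cell_id[1L],
               tp = seq_len(nrow(d) - 1L),
               time_min = d$time_min[-1L],
               pct_increase = percent_volume_increase(d$volume[1L],
                                                      d$volume[-1L]))
  }))
  rownames(per_cell) <- NULL
  # alignment check: same index => same nominal time across cells
  rng <- tapply(per_cell$time_min, per_cell$tp, function(x) diff(range(x)))
  if (any(rng > time_tol))
    stop("timepoints misaligned across cells (> ", time_tol, " min)")
  counts <- tapply(per_cell$cell_id, per_cell$animal_id,
                   function(x) length(unique(x)))
  drop <- names(counts)[counts < min_cells]
  if (length(drop))
    warning("excluding animals with < ", min_cells, " cells: ",
            paste(drop, collapse = ", "))
  keep <- !(per_cell$animal_id %in% drop)
  if (any(keep)) {
    pa <- stats::aggregate(pct_increase ~ animal_id + tp,
                           data = per_cell[keep, ], FUN = mean)
    tmean <- tapply(per_cell$time_min, per_cell$tp, mean)
    pa$time_min <- as.numeric(tmean[as.character(pa$tp)])
    pa <- pa[order(pa$animal_id, pa$tp),
             c("animal_id", "time_min", "pct_increase")]
    names(pa)[3L] <- "mean_pct"
    rownames(pa) <- NULL
  } else {
    pa <- data.frame(animal_id = character(0), time_min = numeric(0),
                     mean_pct = numeric(0))
  }
  list(per_cell = per_cell[keep, setdiff(names(per_cell), "tp")],
       per_animal = pa, excluded = drop)
}

#' Volume from a segmentation voxel count
#'
#' @param voxel_count Number of voxels in the mask.
#' @param voxel_dims Length-3 numeric, voxel edge lengths (mm per axis),
#'   e.g. in-plane resolution twice plus the 0.6 mm slice thickness.
#' @return Volume in mm^3.
#' @examples
#' volume_from_mask(1000, c(0.1, 0.1, 0.6)) # 6 mm^3
#' @export
volume_from_mask <- function(voxel_count, voxel_dims) {
  if (voxel_count < 0) stop("voxel_count must be >= 0")
  if (length(voxel_dims) != 3L || any(voxel_dims <= 0))
    stop("voxel_dims must be 3 positive lengths (mm)")
  voxel_count * prod(voxel_dims)
}

#' Group volume summaries with pairwise Welch comparisons
#'
#' Mean, SD, and n per group (e.g. lateral ventricle volumes by
#' treatment), plus Welch's two-tailed unpaired t-test for every pair of
#' groups via [welch_t()].
#'
#' @param volumes Data frame with columns `group` and `volume`.
#' @return A list with `summary` (group, n, mean, sd) and `tests`
#'   (group_a, group_b, t, df, p_value, ratio_of_means = mean_a/mean_b).
#' @export
group_volume_summary <- function(volumes) {
  if (!all(c("group", "volume") %in% names(volumes)))
    stop("volumes needs columns group, volume")
  if (any(volumes$volume <= 0)) stop("volumes must be > 0")
  sp <- split(volumes$volume, volumes$group)
  if (any(lengths(sp) < 2L))
    stop("each group needs >= 2 values")
  smry <- data.frame(group = names(sp), n = lengths(sp),
                     mean = vapply(sp, mean, numeric(1L)),
                     sd = vapply(sp, stats::sd, numeric(1L)),
                     row.names = NULL)
  pairs <- utils::combn(names(sp), 2L)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    ga <- pairs[1L, k]; gb <- pairs[2L, k]
    wt <- welch_t(sp[[ga]], sp[[gb]])
    data.frame(group_a = ga, group_b = gb, t = wt$t, df = wt$df,
               p_value = wt$p_value,
               ratio_of_means = mean(sp[[ga]]) / mean(sp[[gb]]))
  }))
  list(summary = smry, tests = tests)
}

#' Brain-size proxy from serial coronal sections
#'
#' The arithmetic mean of per-slice cross-sectional areas over the
#' designated slices; ventricle regions are included, not subtracted.
#'
#' @param slice_areas Per-slice areas (mm^2).
#' @return Mean area (mm^2).
#' @export
brain_size_proxy <- function(slice_areas) {
  if (!length(slice_areas) || any(slice_areas <= 0))
    stop("slice_areas must be positive and non-empty")
  mean(slice_areas)
}
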