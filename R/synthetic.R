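#' Developmental reference table of printed summary statistics
#'
#' Group means and SDs that parameterize the synthetic generators:
#' developmental CSF \[K+\] (mM), P50 lateral-ventricle volumes (mm^3)
#' under control vs. choroid plexus NKCC1 overexpression, and CSF total
#' protein (mg/ml). CSF values are study summaries; the serum \[K+\] rows
#' are synthetic assumptions at textbook murine levels (flagged in the
#' `provenance` column) supplied only so CSF/serum ratios can be
#' exercised.
#'
#' @return Data frame: `quantity`, `group`, `mean`, `sd`, `n`, `unit`,
#'   `provenance`.
#' @export
dev_reference_table <- function() {
  data.frame(
    quantity = c(rep("csf_k", 3L), rep("serum_k", 3L),
                 rep("ventricle_volume_p50", 2L), rep("csf_protein", 2L)),
    group = c("P0", "P7", "adult", "P0", "P7", "adult",
              "control", "NKCC1_OE", "control", "NKCC1_OE"),
    mean = c(9.6, 4.4, 3.1, 5.2, 5.0, 4.8, 3.12, 1.28, 2.50, 2.71),
    sd   = c(3.5, 0.9, 0.6, 0.6, 0.6, 0.5, 0.59, 0.28, 0.20, 0.46),
    n    = c(6L, 6L, 6L, 6L, 6L, 6L, 6L, 6L, 6L, 6L),
    unit = c(rep("mM", 6L), rep("mm3", 2L), rep("mg/ml", 2L)),
    provenance = c(rep("study summary", 3L), rep("synthetic assumption", 3L),
                   rep("study summary", 4L)),
    stringsAsFactors = FALSE)
}

# seeded draws without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Generate ion-concentration samples for one age group
#'
#' Draws i.i.d. normal samples (truncated at zero by resampling) with the
#' mean and SD of the requested reference row, in tidy ion-table form.
#'
#' @param age Group label present in [dev_reference_table()] for the
#'   chosen quantity (`"P0"`, `"P7"`, `"adult"`).
#' @param n Number of samples (>= 1).
#' @param seed Integer seed.
#' @param ion Ion label written into the table (default `"K"`).
#' @param compartment `"CSF"` (quantity `csf_k`) or `"serum"`
#'   (`serum_k`).
#' @return Data frame with columns `age`, `ion`, `compartment`,
#'   `value_mM`.
#' @export
gen_ion_samples <- function(age, n, seed, ion = "K",
                            compartment = c("CSF", "serum")) {
  compartment <- match.arg(compartment)
  ref <- dev_reference_table()
  q <- if (compartment == "CSF") "csf_k" else "serum_k"
  row <- ref[ref$quantity == q & ref$group == age, ]
  if (nrow(row) != 1L) stop("unknown age group: ", age)
  if (n < 1L) stop("n must be >= 1")
  vals <- with_seed(seed, rnorm_trunc0(n, row$mean, row$sd))
  data.frame(age = age, ion = ion, compartment = compartment,
             value_mM = vals, stringsAsFactors = FALSE)
}

# normal draws truncated at 0 by resampling (negligible mass at 0 for
# all reference rows except P0 CSF K+, where ~0.3% is redrawn)
rnorm_trunc0 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x <= 0)
  }
  x
}

#' Generate group volume samples from the reference table
#'
#' @param quantity `"ventricle_volume_p50"` or `"csf_protein"`.
#' @param group Group label (`"control"` or `"NKCC1_OE"`).
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return Data frame with columns `group`, `volume` (reference units).
#' @export
gen_group_values <- function(quantity, group, n, seed) {
  ref <- dev_reference_table()
  row <- ref[ref$quantity == quantity & ref$group == group, ]
  if (nrow(row) != 1L) stop("unknown quantity/group: ", quantity, "/", group)
  data.frame(group = group,
             volume = with_seed(seed, rnorm_trunc0(n, row$mean, row$sd)),
             stringsAsFactors = FALSE)
}

#' Specification of a synthetic epithelial field of view
#'
#' @param width,height Cell dimensions (um); apical edge on top
#'   (`y = height`), basal on the bottom (`y = 0`).
#' @param waviness Amplitude of the sinusoidal perturbation of both
#'   surfaces (um); kept well under `height / 2`.
#' @param n_mito Organelles per cell (>= 0).
#' @param depth_alpha,depth_beta Beta-distribution parameters of the
#'   normalized apical depth u (u = 1 at the apical surface): Beta(1, 1)
#'   is unpolarized; Beta(5, 1) is strongly apical, Beta(1, 5) strongly
#'   basal.
#' @param area_meanlog,area_sdlog Lognormal parameters of organelle area
#'   (um^2); defaults give ~0.3 um^2 median, typical of mitochondrial
#'   cross-sections in micrographs.
#' @return An object of class `"geometry_spec"`.
#' @export
geometry_spec <- function(width = 20, height = 15, waviness = 0.8,
                          n_mito = 50L, depth_alpha = 1, depth_beta = 1,
                          area_meanlog = log(0.3), area_sdlog = 0.4) {
  if (width <= 0 || height <= 0) stop("degenerate cell dimensions")
  if (waviness < 0 || waviness >= height / 4)
    stop("waviness must be in [0, height/4)")
  if (n_mito < 0) stop("n_mito must be >= 0")
  if (depth_alpha <= 0 || depth_beta <= 0)
    stop("depth Beta parameters must be > 0")
  structure(list(width = width, height = height, waviness = waviness,
                 n_mito = as.integer(n_mito), depth_alpha = depth_alpha,
                 depth_beta = depth_beta, area_meanlog = area_meanlog,
                 area_sdlog = area_sdlog),
            class = "geometry_spec")
}

#' Generate polarized epithelial geometry with organelles
#'
#' Builds `n_cells` rectangular cells with sinusoidally perturbed apical
#' (top) and basal (bottom) surfaces and scatters organelle centroids at
#' Beta-distributed normalized depths, guaranteed inside the cell
#' region. A depth bias toward 1 (apical) reproduces the adult-like
#' apically polarized distribution; Beta(1, 1) gives the unpolarized
#' control.
#'
#' @param spec A [geometry_spec()].
#' @param n_cells Number of cells (laid out side by side).
#' @param seed Integer seed.
#' @return A list with `cells` (named list of [cell_outline()]) and
#'   `mitos` (data frame: `cell_id`, `x`, `y`, `area`).
#' @export
gen_polarized_geometry <- function(spec, n_cells = 3L, seed = 1L) {
  stopifnot(inherits(spec, "geometry_spec"))
  if (n_cells < 1L) stop("n_cells must be >= 1")
  with_seed(seed, {
    cells <- list()
    mitos <- vector("list", n_cells)
    for (ci in seq_len(n_cells)) {
      x0 <- (ci - 1L) * spec$width
      xs <- seq(x0, x0 + spec$width, length.out = 21L)
      phase_a <- stats::runif(1L, 0, 2 * pi)
      phase_b <- stats::runif(1L, 0, 2 * pi)
      wig_a <- spec$waviness * sin(2 * pi * (xs - x0) / spec$width + phase_a)
      wig_b <- spec$waviness * sin(2 * pi * (xs - x0) / spec$width + phase_b)
      apical <- cbind(xs, spec$height + wig_a)
      basal <- cbind(xs, wig_b)
      region <- rbind(apical, basal[rev(seq_len(nrow(basal))), ])
      id <- sprintf("cell%02d", ci)
      cells[[id]] <- cell_outline(apical, basal, region, id = id)
      if (spec$n_mito > 0L) {
        u <- stats::rbeta(spec$n_mito, spec$depth_alpha, spec$depth_beta)
        mx <- stats::runif(spec$n_mito, x0 + 0.02 * spec$width,
                           x0 + 0.98 * spec$width)
        # interpolate both surfaces at mx, then place at depth u between
        # them with a small margin so centroids stay strictly inside
        ya <- stats::approx(xs, apical[, 2L], xout = mx)$y
        yb <- stats::approx(xs, basal[, 2L], xout = mx)$y
        eps <- 1e-3 * spec$height
        my <- yb + eps + (u * (1 - 2e-3)) * (ya - yb - 2 * eps)
        area <- stats::rlnorm(spec$n_mito, spec$area_meanlog,
                              spec$area_sdlog)
        mitos[[ci]] <- data.frame(cell_id = id, x = mx, y = my,
                                  area = area, stringsAsFactors = FALSE)
      }
    }
    mitos <- if (spec$n_mito > 0L) do.call(rbind, mitos)
             else data.frame(cell_id = character(0), x = numeric(0),
                             y = numeric(0), area = numeric(0))
    rownames(mitos) <- NULL
    list(cells = cells, mitos = mitos)
  })
}

#' Generate a collection of infusion-test recordings with ground truth
#'
#' Runs [simulate_infusion()] for each parameter set and replicate,
#' deriving one sub-seed per trace from the master seed, and records the
#' true parameters in a sidecar table for recovery studies.
#'
#' @param true_params A [marmarou_params()] object or list of them.
#' @param protocol An [infusion_protocol()].
#' @param waveform A [waveform_spec()].
#' @param n_replicates Replicates per parameter set.
#' @param seed Master integer seed.
#' @return A list with `traces` (list of [icp_trace()]) and `truth`
#'   (data frame: trace index, seed, and the five true parameters).
#' @export
gen_icp_dataset <- function(true_params, protocol = infusion_protocol(),
                            waveform = waveform_spec(), n_replicates = 1L,
                            seed = 1L) {
  if (inherits(true_params, "marmarou_params"))
    true_params <- list(true_params)
  stopifnot(all(vapply(true_params, inherits, logical(1L),
                       "marmarou_params")))
  sub_seeds <- with_seed(seed,
    sample.int(.Machine$integer.max,
               length(true_params) * n_replicates))
  traces <- list(); truth <- list(); k <- 0L
  for (pi in seq_along(true_params)) {
    for (r in seq_len(n_replicates)) {
      k <- k + 1L
      p <- true_params[[pi]]
      traces[[k]] <- simulate_infusion(p, protocol, waveform,
                                       seed = sub_seeds[k])
      truth[[k]] <- data.frame(trace = k, seed = sub_seeds[k],
                               icp_baseline = p$icp_baseline, p0 = p$p0,
                               r_csf = p$r_csf, c_i = p$c_i,
                               i_infusion = p$i_infusion)
    }
  }
  list(traces = traces, truth = do.call(rbind, truth))
}

#' Generate saturating cell-swelling timecourses
#'
#' Percent volume increase follows the saturating form
#' `plateau_pct * (1 - exp(-rate * t))` plus Gaussian noise; a higher
#' rate constant (more cotransporter activity) gives uniformly higher
#' early-time swelling. Volumes are emitted in voxels around a typical
#' initial cell volume so the series exercises the volumetrics readers.
#'
#' @param rate_constant Swelling rate (1/min).
#' @param plateau_pct Asymptotic percent volume increase (>= 0).
#' @param timepoints Post-challenge acquisition times (min), positive
#'   increasing; default 5 stacks over 10 min.
#' @param n_cells Cells per animal (default 5).
#' @param n_animals Animals (default 4).
#' @param noise_sd SD of the per-measurement noise in percent points.
#' @param v0 Initial volume (voxels).
#' @param seed Integer seed.
#' @return Data frame `animal_id`, `cell_id`, `time_min`, `volume`
#'   including the t = 0 baseline row per cell.
#' @export
gen_swelling <- function(rate_constant, plateau_pct, timepoints = (1:5) * 2,
                         n_cells = 5L, n_animals = 4L, noise_sd = 1,
                         v0 = 4000, seed = 1L) {
  if (plateau_pct < 0) stop("plateau_pct must be >= 0")
  if (any(timepoints <= 0)) stop("timepoints must be positive")
  if (rate_constant < 0) stop("rate_constant must be >= 0")
  with_seed(seed, {
    rows <- list(); k <- 0L
    for (a in seq_len(n_animals)) {
      for (cc in seq_len(n_cells)) {
        pct <- plateau_pct * (1 - exp(-rate_constant * timepoints))
        if (noise_sd > 0)
          pct <- pct + stats::rnorm(length(timepoints), 0, noise_sd)
        k <- k + 1L
        rows[[k]] <- data.frame(
          animal_id = sprintf("animal%02d", a),
          cell_id = sprintf("a%02d_cell%02d", a, cc),
          time_min = c(0, timepoints),
          volume = v0 * (1 + c(0, pct) / 100))
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
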