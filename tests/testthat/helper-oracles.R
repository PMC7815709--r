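# Shared fixtures and independent oracles for the test suite.

default_truth <- function() marmarou_params(icp_baseline = 5, p0 = 2,
                                            r_csf = 4, c_i = 10,
                                            i_infusion = 2)

quiet_waveform <- function() waveform_spec(cardiac_amp0 = 0, resp_amp0 = 0,
                                           noise_sd = 0)

# Fixed-step RK4 integration of the governing pressure ODE
#   dP/dt = ((P - p0)/ci) * (i - (P - icpb)/r),  P(0) = icpb,
# vectorised over parameter sets. Returns a matrix [time x set] of P at
# the requested times (which must be multiples of h).
rk4_icp <- function(icpb, p0, r, ci, i, times, h = 1e-3) {
  f <- function(P) ((P - p0) / ci) * (i - (P - icpb) / r)
  P <- icpb
  out <- matrix(NA_real_, length(times), length(icpb))
  ti <- 1L
  for (s in seq_len(round(max(times) / h))) {
    k1 <- f(P); k2 <- f(P + h / 2 * k1)
    k3 <- f(P + h / 2 * k2); k4 <- f(P + h * k3)
    P <- P + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    while (ti <= length(times) && abs(s * h - times[ti]) < h / 2) {
      out[ti, ] <- P
      ti <- ti + 1L
    }
  }
  out
}

# Brute-force two-sample KS statistic: evaluate both ECDFs at every
# pooled observed point and take the largest absolute difference.
ks_d_bruteforce <- function(a, b) {
  pts <- sort(c(a, b))
  max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x),
                 numeric(1L))))
}

# Dense-sampling oracle for point-to-polyline distance: sample many
# points along every segment and take the nearest.
polyline_distance_dense <- function(p, line, n_per_segment = 5000L) {
  d2 <- Inf
  for (k in seq_len(nrow(line) - 1L)) {
    tt <- seq(0, 1, length.out = n_per_segment)
    px <- line[k, 1L] + tt * (line[k + 1L, 1L] - line[k, 1L])
    py <- line[k, 2L] + tt * (line[k + 1L, 2L] - line[k, 2L])
    d2 <- min(d2, min((px - p[1L])^2 + (py - p[2L])^2))
  }
  sqrt(d2)
}

# One straight-sided cell for geometry unit tests: apical edge at
# y = height, basal at y = 0, spanning x in [0, width].
straight_cell <- function(width = 10, height = 8, id = "c1") {
  cell_outline(apical = rbind(c(0, height), c(width, height)),
               basal = rbind(c(0, 0), c(width, 0)),
               region = rbind(c(0, 0), c(width, 0), c(width, height),
                              c(0, height)),
               id = id)
}
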