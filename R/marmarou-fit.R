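#' Fit the Marmarou model to a constant-rate infusion recording
#'
#' Estimates baseline ICP, the storage-arm reference pressure p0, the
#' resistance to CSF outflow R_CSF, and the compliance coefficient C_i by
#' bounded nonlinear least squares (Levenberg-Marquardt,
#' [minpack.lm::nlsLM()]) on the full trace: baseline samples are
#' modelled as a constant at baseline ICP and post-infusion samples by
#' [icp_model()]. To keep p0 below the baseline the optimizer works in
#' the reparameterisation `x0 = icp_baseline - p0 > 0`.
#'
#' Starting values follow the physiology of the curve: baseline ICP from
#' the mean of the pre-infusion segment (excluding a 5 s guard band
#' before the infusion starts), R_CSF from (plateau - baseline) / rate
#' with the plateau taken as the mean of the last tenth of the trace,
#' C_i from the initial rise slope, and p0 at baseline - 1 mmHg. If the
#' optimizer fails from those values a coarse grid over (R_CSF, C_i)
#' supplies a fallback start.
#'
#' @param trace An [icp_trace()]; filter first with
#'   [lowpass_waveform_removal()] when pulsation is present.
#' @param guard_s Guard band (seconds) excluded from the end of the
#'   baseline segment. Default 5.
#' @param max_points Traces longer than this are thinned evenly before
#'   fitting (the information content of the low-passed rise is far below
#'   the raw sampling rate). Default 2000.
#' @param max_iter Iteration cap (default 500).
#'
#' @return An object of class `"marmarou_fit"`: list with `params`
#'   ([marmarou_params()] estimates), `stderr` (named per-parameter
#'   standard errors), `residual_rms` (mmHg), `converged`, and `n_used`.
#' @examples
#' truth <- marmarou_params(5, 2, 4, 10, 2)
#' quiet <- waveform_spec(cardiac_amp0 = 0, resp_amp0 = 0, noise_sd = 0)
#' tr <- simulate_infusion(truth, infusion_protocol(sample_rate = 10), quiet)
#' fit <- fit_marmarou(tr)
#' fit$params$r_csf # ~4
#' @export
fit_marmarou <- function(trace, guard_s = 5, max_points = 2000L,
                         max_iter = 500L) {
  stopifnot(inherits(trace, "icp_trace"))
  if (any(!is.finite(trace$pressure))) stop("non-finite pressures in trace")
  i <- trace$infusion_rate
  if (i <= 0) stop("unidentifiable model: infusion rate is zero")
  t0 <- trace$infusion_start
  post <- trace$time > t0
  if (sum(post) < 10L)
    stop("unidentifiable model: no post-infusion samples")

  # thin long traces evenly; the fit is on the slow component only
  n <- length(trace$time)
  keep <- if (n > max_points)
    unique(round(seq(1L, n, length.out = max_points))) else seq_len(n)
  tt <- trace$time[keep]
  pp <- trace$pressure[keep]

  base_idx <- tt < (t0 - guard_s / 60)
  base0 <- if (any(base_idx)) mean(pp[base_idx]) else pp[1L]
  plateau0 <- mean(pp[tt >= stats::quantile(tt, 0.9)])
  rise <- plateau0 - base0
  if (!is.finite(rise) || rise < 0.05)
    stop("unidentifiable model: no discernible pressure rise above baseline")
  r0 <- max(rise / i, 1e-3)
  # initial slope over the first ~10% of the rise; C_i = x0 * i / slope
  early <- which(tt > t0 & tt <= t0 + 0.1 * (max(tt) - t0))
  slope0 <- if (length(early) >= 3L)
    stats::coef(stats::lm(pp[early] ~ tt[early]))[2L] else NA_real_
  x0_start <- 1
  c0 <- if (is.finite(slope0) && slope0 > 0) max(x0_start * i / slope0, 1e-3)
        else 10

  pred <- function(icpb, x0, r, ci) {
    pm <- marmarou_params(icpb, icpb - x0, r, ci, i)
    ifelse(tt < t0, icpb, icp_model(pmax(tt - t0, 0), pm))
  }
  dat <- data.frame(tt = tt, pp = pp)
  lower <- c(icpb = min(pp) - 5, x0 = 1e-3, r = 1e-6, ci = 1e-6)
  upper <- c(icpb = max(pp) + 5, x0 = Inf, r = Inf, ci = Inf)
  run_fit <- function(start) {
    minpack.lm::nlsLM(
      pp ~ pred(icpb, x0, r, ci), data = dat, start = start,
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(
        maxiter = max_iter, ftol = 1e-10, ptol = 1e-12))
  }
  start <- list(icpb = base0, x0 = x0_start, r = r0, ci = c0)
  fit <- tryCatch(run_fit(start), error = function(e) NULL)
  if (is.null(fit)) {
    # coarse grid fallback over (r, ci)
    grid <- expand.grid(r = r0 * c(0.25, 1, 4), ci = c(1, 5, 20, 80))
    rss <- apply(grid, 1L, function(g)
      sum((pp - pred(base0, x0_start, g[["r"]], g[["ci"]]))^2))
    g <- grid[which.min(rss), ]
    fit <- run_fit(list(icpb = base0, x0 = x0_start,
                        r = g$r, ci = g$ci))
  }
  cf <- stats::coef(fit)
  est <- marmarou_params(cf[["icpb"]], cf[["icpb"]] - cf[["x0"]],
                         cf[["r"]], cf[["ci"]], i)
  vc <- tryCatch(stats::vcov(fit), error = function(e)
    matrix(NA_real_, 4, 4, dimnames = list(names(cf), names(cf))))
  se_p0 <- sqrt(pmax(vc["icpb", "icpb"] + vc["x0", "x0"] -
                       2 * vc["icpb", "x0"], 0))
  stderr <- c(icp_baseline = sqrt(pmax(vc["icpb", "icpb"], 0)),
              p0 = se_p0,
              r_csf = sqrt(pmax(vc["r", "r"], 0)),
              c_i = sqrt(pmax(vc["ci", "ci"], 0)))
  at_bound <- any(abs(cf - lower[names(cf)]) < 1e-8)
  conv <- isTRUE(fit$convInfo$isConv) &&
    fit$convInfo$finIter < max_iter && !at_bound
  structure(list(params = est, stderr = stderr,
                 residual_rms = sqrt(mean(stats::residuals(fit)^2)),
                 converged = conv, n_used = length(tt)),
            class = "marmarou_fit")
}

#' @export
print.marmarou_fit <- function(x, ...) {
  cat(sprintf("Marmarou model fit (%d samples, residual RMS %.3f mmHg, %s)\n",
              x$n_used, x$residual_rms,
              if (x$converged) "converged" else "NOT converged"))
  est <- unlist(x$params[c("icp_baseline", "p0", "r_csf", "c_i")])
  out <- data.frame(estimate = est, stderr = x$stderr[names(est)])
  print(round(out, 4))
  invisible(x)
}
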