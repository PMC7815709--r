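#' Infusion test protocol
#'
#' @param baseline_duration Minutes of resting ICP recorded before the
#'   infusion starts. Default 2 min.
#' @param infusion_duration Minutes of constant-rate infusion. Default 10.
#' @param sample_rate Sampling rate of the pressure sensor (samples/s).
#'   Default 50 Hz, enough to resolve the murine cardiac waveform.
#' @return An object of class `"infusion_protocol"`.
#' @export
infusion_protocol <- function(baseline_duration = 2, infusion_duration = 10,
                              sample_rate = 50) {
  if (baseline_duration < 0) stop("baseline_duration must be >= 0")
  if (infusion_duration <= 0) stop("infusion_duration must be > 0")
  if (sample_rate <= 0) stop("sample_rate must be > 0")
  structure(list(baseline_duration = baseline_duration,
                 infusion_duration = infusion_duration,
                 sample_rate = sample_rate),
            class = "infusion_protocol")
}

#' Physiological waveform specification for simulated ICP
#'
#' Describes the cardiac and respiratory pulsations superimposed on the
#' mean ICP, and how their amplitude grows with the volume load. In an
#' adult mouse the cardiac frequency is near 10 Hz (~600 bpm) and the
#' respiratory frequency near 2.5 Hz (~150 breaths/min); both pulsations
#' are visible in a well-placed intraventricular catheter and their
#' amplitude increases as the infusion raises mean ICP, which is the
#' basis of the placement quality control in [pulse_amplitude_qc()].
#'
#' @param cardiac_freq,resp_freq Pulsation frequencies (Hz);
#'   `cardiac_freq > resp_freq > 0`.
#' @param cardiac_amp0,resp_amp0 Pulsation amplitudes at baseline pressure
#'   (mmHg).
#' @param amp_pressure_coupling Dimensionless gain: instantaneous amplitude
#'   is `amp0 * (1 + amp_pressure_coupling * (P - icp_baseline))` with P in
#'   mmHg. 0 disables the coupling.
#' @param noise_sd Standard deviation of i.i.d. Gaussian sensor noise
#'   (mmHg).
#' @return An object of class `"waveform_spec"`.
#' @export
waveform_spec <- function(cardiac_freq = 10, resp_freq = 2.5,
                          cardiac_amp0 = 0.5, resp_amp0 = 0.3,
                          amp_pressure_coupling = 0.1, noise_sd = 0.3) {
  if (cardiac_freq <= 0 || resp_freq <= 0) stop("frequencies must be > 0")
  if (cardiac_freq <= resp_freq)
    stop("cardiac_freq must exceed resp_freq")
  if (cardiac_amp0 < 0 || resp_amp0 < 0) stop("amplitudes must be >= 0")
  if (amp_pressure_coupling < 0) stop("amp_pressure_coupling must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(cardiac_freq = cardiac_freq, resp_freq = resp_freq,
                 cardiac_amp0 = cardiac_amp0, resp_amp0 = resp_amp0,
                 amp_pressure_coupling = amp_pressure_coupling,
                 noise_sd = noise_sd),
            class = "waveform_spec")
}

#' Sampled ICP trace
#'
#' @param time Sample times (minutes), strictly increasing.
#' @param pressure Pressure samples (mmHg), same length as `time`.
#' @param infusion_start Time at which the infusion begins (minutes); must
#'   lie within the sampled range.
#' @param infusion_rate Infusion rate (uL/min).
#' @return An object of class `"icp_trace"`.
#' @export
icp_trace <- function(time, pressure, infusion_start, infusion_rate) {
  if (length(time) != length(pressure))
    stop("time and pressure must have equal length")
  if (length(time) < 2L) stop("trace needs at least 2 samples")
  if (any(!is.finite(time)) || any(!is.finite(pressure)))
    stop("non-finite values in trace")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (infusion_start < time[1L] || infusion_start > time[length(time)])
    stop("infusion_start outside sampled time range")
  if (infusion_rate < 0) stop("infusion_rate must be >= 0")
  structure(list(time = as.numeric(time), pressure = as.numeric(pressure),
                 infusion_start = infusion_start,
                 infusion_rate = infusion_rate),
            class = "icp_trace")
}

#' @export
print.icp_trace <- function(x, ...) {
  cat(sprintf(
    "ICP trace: %d samples, %.2f-%.2f min, infusion %.2g uL/min at t = %.2f min\n",
    length(x$time), x$time[1L], x$time[length(x$time)],
    x$infusion_rate, x$infusion_start))
  invisible(x)
}

# sample rate (Hz) of a uniformly sampled trace; errors if non-uniform
trace_fs <- function(trace, tol = 1e-6) {
  dt <- diff(trace$time)
  if (diff(range(dt)) > tol * stats::median(dt))
    stop("trace is not uniformly sampled")
  1 / (stats::median(dt) * 60)
}

#' Simulate a constant-rate infusion test recording
#'
#' Produces a full ICP recording: a resting baseline segment, the
#' Marmarou-model pressure rise after the infusion starts, superimposed
#' cardiac and respiratory sinusoids whose instantaneous amplitude grows
#' with the mean pressure above baseline, and i.i.d. Gaussian sensor
#' noise. The same seed always reproduces the same trace.
#'
#' @param params A [marmarou_params()] object (ground truth).
#' @param protocol An [infusion_protocol()].
#' @param waveform A [waveform_spec()]; use zero amplitudes and
#'   `noise_sd = 0` for a noise-free model curve.
#' @param seed Integer seed for the noise draws.
#' @return An [icp_trace()] with `infusion_start = baseline_duration`.
#' @examples
#' tr <- simulate_infusion(marmarou_params(5, 2, 4, 10, 2),
#'                         infusion_protocol(), waveform_spec(), seed = 1)
#' @export
simulate_infusion <- function(params, protocol = infusion_protocol(),
                              waveform = waveform_spec(), seed = 1L) {
  stopifnot(inherits(params, "marmarou_params"),
            inherits(protocol, "infusion_protocol"),
            inherits(waveform, "waveform_spec"))
  dt_min <- 1 / (protocol$sample_rate * 60)
  total <- protocol$baseline_duration + protocol$infusion_duration
  time <- seq(0, total, by = dt_min)
  t_inf <- pmax(time - protocol$baseline_duration, 0)
  p_model <- ifelse(time < protocol$baseline_duration,
                    params$icp_baseline, icp_model(t_inf, params))
  amp_gain <- 1 + waveform$amp_pressure_coupling *
    (p_model - params$icp_baseline)
  t_sec <- time * 60
  pulsation <- amp_gain *
    (waveform$cardiac_amp0 * sin(2 * pi * waveform$cardiac_freq * t_sec) +
     waveform$resp_amp0 * sin(2 * pi * waveform$resp_freq * t_sec))
  noise <- if (waveform$noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    stats::rnorm(length(time), 0, waveform$noise_sd)
  } else 0
  icp_trace(time, p_model + pulsation + noise,
            infusion_start = protocol$baseline_duration,
            infusion_rate = params$i_infusion)
}

# save/restore the global RNG state so seeded simulations do not disturb
# the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
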