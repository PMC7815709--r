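#' Parameters of the Marmarou model for a constant-rate infusion
#'
#' Bundles the four physiological parameters of the lumped-parameter
#' (Marmarou) model of CSF dynamics together with the infusion rate used
#' in a constant-rate infusion test.
#'
#' @param icp_baseline Resting intracranial pressure before infusion (mmHg).
#' @param p0 Reference pressure of the storage arm of the model (mmHg);
#'   must lie strictly below `icp_baseline`.
#' @param r_csf Resistance to CSF outflow (mmHg.min/uL).
#' @param c_i Pressure-independent compliance coefficient (uL); the rate of
#'   the pressure rise is inversely proportional to `c_i`.
#' @param i_infusion Infusion rate (uL/min); zero means no infusion.
#'
#' @return An object of class `"marmarou_params"`: a named list with the
#'   five fields above.
#' @examples
#' p <- marmarou_params(icp_baseline = 5, p0 = 2, r_csf = 4, c_i = 10,
#'                      i_infusion = 2)
#' plateau_pressure(p) # 5 + 2 * 4 = 13 mmHg
#' @export
marmarou_params <- function(icp_baseline, p0, r_csf, c_i, i_infusion) {
  for (v in c(icp_baseline, p0, r_csf, c_i, i_infusion)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("all Marmarou parameters must be finite numeric scalars")
  }
  if (r_csf <= 0) stop("r_csf must be > 0")
  if (c_i <= 0) stop("c_i must be > 0")
  if (icp_baseline <= p0) stop("icp_baseline must exceed p0")
  if (i_infusion < 0) stop("i_infusion must be >= 0")
  structure(list(icp_baseline = icp_baseline, p0 = p0, r_csf = r_csf,
                 c_i = c_i, i_infusion = i_infusion),
            class = "marmarou_params")
}

#' @export
print.marmarou_params <- function(x, ...) {
  cat("Marmarou model parameters:\n")
  cat(sprintf("  ICP baseline : %.3f mmHg\n", x$icp_baseline))
  cat(sprintf("  p0           : %.3f mmHg\n", x$p0))
  cat(sprintf("  R_CSF        : %.4f mmHg.min/uL\n", x$r_csf))
  cat(sprintf("  C_i          : %.4f uL\n", x$c_i))
  cat(sprintf("  infusion     : %.3f uL/min (plateau %.3f mmHg)\n",
              x$i_infusion, plateau_pressure(x)))
  invisible(x)
}

#' Closed-form ICP during a constant-rate infusion
#'
#' Evaluates the solution of the Marmarou model for intracranial pressure
#' under a constant ventricular infusion, in the offset form
#' \deqn{ICP(t) = p_0 + \frac{[i + (ICP_b - p_0)/R] (ICP_b - p_0)}
#'   {(ICP_b - p_0)/R + i\, e^{-(i + (ICP_b - p_0)/R) t / C_i}}}
#' which satisfies `ICP(0) = icp_baseline` and rises monotonically to the
#' plateau `icp_baseline + i_infusion * r_csf`. This closed form solves the
#' governing ODE
#' `dP/dt = ((P - p0)/c_i) * (i - (P - icp_baseline)/r_csf)`.
#'
#' @param t Time since start of infusion (minutes); vectorised, `t >= 0`.
#' @param params A [marmarou_params()] object.
#'
#' @return Pressure (mmHg), same length as `t`.
#' @examples
#' p <- marmarou_params(5, 2, 4, 10, 2)
#' icp_model(c(0, 1, 5, 60), p)
#' @export
icp_model <- function(t, params) {
  stopifnot(inherits(params, "marmarou_params"))
  if (any(t < 0)) stop("t must be >= 0")
  if (params$i_infusion == 0) return(rep(params$icp_baseline, length(t)))
  x0 <- params$icp_baseline - params$p0
  k  <- x0 / params$r_csf          # baseline outflow, uL/min
  i  <- params$i_infusion
  # guard the exponential against underflow for very large t
  ex <- exp(pmax(-(i + k) * t / params$c_i, -745))
  params$p0 + (i + k) * x0 / (k + i * ex)
}

#' Steady-state plateau pressure of the infusion test
#'
#' The t -> Inf limit of [icp_model()]:
#' `icp_baseline + i_infusion * r_csf`. During an infusion test the ICP
#' rises and plateaus at this level; the height of the plateau above
#' baseline identifies the outflow resistance.
#'
#' @param params A [marmarou_params()] object.
#' @return Pressure (mmHg).
#' @export
plateau_pressure <- function(params) {
  stopifnot(inherits(params, "marmarou_params"))
  params$icp_baseline + params$i_infusion * params$r_csf
}
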