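#' Developmental ion summaries
#'
#' Mean, sample SD, and n of ion concentrations per age group for one ion
#' and compartment (CSF or serum), as used for developmental CSF
#' electrolyte profiles.
#'
#' @param table Data frame with columns `age`, `ion`, `compartment`,
#'   `value_mM`.
#' @param ion Ion label (e.g. `"K"`).
#' @param compartment `"CSF"` or `"serum"`.
#' @return Data frame: `age`, `n`, `mean`, `sd` (NA when n = 1).
#' @export
ion_summary <- function(table, ion, compartment = "CSF") {
  need <- c("age", "ion", "compartment", "value_mM")
  if (!all(need %in% names(table)))
    stop("ion table needs columns ", paste(need, collapse = ", "))
  d <- table[table$ion == ion & table$compartment == compartment, ]
  if (!nrow(d))
    warning("no rows for ion ", ion, " in compartment ", compartment)
  if (any(d$value_mM <= 0)) stop("concentrations must be > 0")
  sp <- split(d$value_mM, d$age)
  out <- data.frame(age = names(sp), n = lengths(sp),
                    mean = vapply(sp, mean, numeric(1L)),
                    sd = vapply(sp, function(x)
                      if (length(x) > 1L) stats::sd(x) else NA_real_,
                      numeric(1L)),
                    row.names = NULL)
  out[order(out$age), , drop = FALSE]
}

#' CSF-to-serum concentration ratios
#'
#' Each CSF value divided by the mean serum concentration of the same
#' group, the standard way of expressing the CSF/serum K+ gradient.
#'
#' @param csf CSF concentrations (mM).
#' @param serum Serum concentrations (mM) of the matching group.
#' @return One ratio per CSF value.
#' @export
csf_serum_ratio <- function(csf, serum) {
  if (!length(serum)) stop("serum sample is empty")
  sm <- mean(serum)
  if (!is.finite(sm) || sm == 0) stop("serum mean is zero or non-finite")
  csf / sm
}

#' ATP-linked respiration from an OCR trace
#'
#' Extracts ATP production from a mitochondrial stress test: the drop in
#' oxygen consumption rate when ATP synthase is blocked by oligomycin.
#' Per well, ATP = (mean OCR of the last pre-oligomycin cycle) minus
#' (mean OCR of the post-oligomycin nadir cycle), divided by the well's
#' calcein fluorescence (tissue-amount normalizer). Each plate is then
#' normalized to the mean of its own adult-group wells, so adult wells
#' average 1.0 on every plate and plates are comparable.
#'
#' @param ocr Data frame with columns `plate`, `well`, `group`,
#'   `time_min`, `cycle`, `ocr`, `calcein` (calcein constant per well).
#' @param injections Data frame with columns `plate`, `label`,
#'   `time_min`; a row with label `"oligomycin"` is required per plate.
#' @param adult_group Group label used for same-plate normalization
#'   (default `"adult"`).
#' @param post_window `"nadir"` (default): post-injection cycle with the
#'   lowest mean OCR; `"first"`: the cycle immediately after injection.
#' @return Data frame: `plate`, `well`, `group`, `atp_raw` (OCR units per
#'   calcein unit), `atp_norm` (unitless, adult = 1).
#' @export
atp_production <- function(ocr, injections, adult_group = "adult",
                           post_window = c("nadir", "first")) {
  post_window <- match.arg(post_window)
  need <- c("plate", "well", "group", "time_min", "cycle", "ocr", "calcein")
  if (!all(need %in% names(ocr)))
    stop("ocr needs columns ", paste(need, collapse = ", "))
  if (any(ocr$ocr < 0)) stop("OCR values must be >= 0")
  if (any(ocr$calcein <= 0)) stop("calcein must be > 0")
  out <- do.call(rbind, lapply(split(ocr, ocr$plate), function(dp) {
    inj <- injections[injections$plate == dp$plate[1L] &
                        injections$label == "oligomycin", ]
    if (nrow(inj) != 1L)
      stop("plate ", dp$plate[1L],
           " needs exactly one oligomycin injection annotation")
    t_inj <- inj$time_min
    per_well <- do.call(rbind, lapply(split(dp, dp$well), function(dw) {
      cyc <- stats::aggregate(ocr ~ cycle, data = dw, FUN = mean)
      tmid <- tapply(dw$time_min, dw$cycle, mean)
      cyc$t <- as.numeric(tmid[as.character(cyc$cycle)])
      pre <- cyc[cyc$t < t_inj, ]
      post <- cyc[cyc$t > t_inj, ]
      if (!nrow(pre) || !nrow(post))
        stop("well ", dw$well[1L],
             " lacks cycles before and after oligomycin")
      pre_ocr <- pre$ocr[which.max(pre$t)]
      post_ocr <- if (post_window == "nadir") min(post$ocr)
                  else post$ocr[which.min(post$t)]
      data.frame(plate = dw$plate[1L], well = dw$well[1L],
                 group = dw$group[1L],
                 atp_raw = (pre_ocr - post_ocr) / dw$calcein[1L])
    }))
    adult <- per_well$atp_raw[per_well$group == adult_group]
    if (!length(adult))
      stop("plate ", dp$plate[1L], " has no '", adult_group,
           "' wells for normalization")
    per_well$atp_norm <- per_well$atp_raw / mean(adult)
    per_well
  }))
  rownames(out) <- NULL
  out
}

#' Welch's (or Student's) two-tailed unpaired t-test
#'
#' Works from raw samples or from (mean, sd, n) summary statistics, as
#' printed results often provide only the latter. The default is Welch's
#' test with the Welch-Satterthwaite degrees of freedom; `var_equal =
#' TRUE` gives the pooled-variance Student test.
#'
#' @param a,b Either numeric samples (length >= 2) or lists/vectors with
#'   named elements `mean`, `sd`, `n`.
#' @param var_equal Pool the variances (Student's t)? Default `FALSE`.
#' @return A list with `t`, `df`, `p_value`, and the two summaries.
#' @examples
#' welch_t(list(mean = 2.50, sd = 0.20, n = 6),
#'         list(mean = 2.71, sd = 0.46, n = 6))$p_value # ~0.34
#' @export
welch_t <- function(a, b, var_equal = FALSE) {
  sa <- as_summary(a); sb <- as_summary(b)
  if (sa$n < 2L || sb$n < 2L) stop("each group needs n >= 2")
  if (var_equal) {
    sp2 <- ((sa$n - 1) * sa$sd^2 + (sb$n - 1) * sb$sd^2) /
      (sa$n + sb$n - 2)
    se <- sqrt(sp2 * (1 / sa$n + 1 / sb$n))
    df <- sa$n + sb$n - 2
  } else {
    va <- sa$sd^2 / sa$n; vb <- sb$sd^2 / sb$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (sa$n - 1) + vb^2 / (sb$n - 1))
  }
  tval <- (sa$mean - sb$mean) / se
  list(t = tval, df = df, p_value = 2 * stats::pt(-abs(tval), df),
       a = sa, b = sb)
}

as_summary <- function(x) {
  if (is.list(x) || (!is.null(names(x)) && all(c("mean", "sd", "n") %in%
                                                 names(x)))) {
    x <- as.list(x)
    if (!all(c("mean", "sd", "n") %in% names(x)))
      stop("summary input needs mean, sd, n")
    if (x$sd < 0 || x$n < 1L) stop("invalid summary statistics")
    list(mean = x$mean, sd = x$sd, n = x$n)
  } else {
    if (any(!is.finite(x))) stop("non-finite values in sample")
    list(mean = mean(x), sd = stats::sd(x), n = length(x))
  }
}

#' Sidak multiple-comparison adjustment
#'
#' `1 - (1 - p)^m`, clipped to \[0, 1\]: the familywise-corrected p-value
#' for `m` independent comparisons.
#'
#' @param p Raw p-value(s) in \[0, 1\].
#' @param m Number of comparisons (>= 1).
#' @return Adjusted p-value(s).
#' @examples
#' sidak_adjust(0.01, 5) # 0.04901
#' @export
sidak_adjust <- function(p, m) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (any(m < 1)) stop("m must be >= 1")
  pmin(pmax(1 - (1 - p)^m, 0), 1)
}

#' MAD-based outlier flags
#'
#' A documented robust outlier rule of comparable stringency to common
#' robust-regression outlier screens: flag values with
#' `|x - median| > k * MAD` (scaled MAD, k = 4.45 by default). Off by
#' default in all pipelines; callers opt in and the flags are reported,
#' never silently dropped.
#'
#' @param x Numeric sample.
#' @param k Threshold multiplier (default 4.45).
#' @return Logical vector, `TRUE` = outlier.
#' @export
mad_outliers <- function(x, k = 4.45) {
  m <- stats::mad(x)
  if (m == 0) return(rep(FALSE, length(x)))
  abs(x - stats::median(x)) > k * m
}
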