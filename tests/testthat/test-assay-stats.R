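test_that("ion summaries report mean, sample SD, and n per age", {
  tab <- data.frame(age = c("P0", "P0", "P0", "P7"),
                    ion = "K", compartment = "CSF",
                    value_mM = c(4, 5, 6, 4.4))
  s <- ion_summary(tab, "K")
  p0 <- s[s$age == "P0", ]
  expect_equal(p0$mean, 5)
  expect_equal(p0$sd, 1)
  expect_equal(p0$n, 3L)
  p7 <- s[s$age == "P7", ]
  expect_equal(p7$n, 1L)
  expect_true(is.na(p7$sd))
  expect_warning(ion_summary(tab, "Na"), "no rows")
})

test_that("CSF/serum ratios divide by the group's serum mean", {
  expect_equal(csf_serum_ratio(4.5, c(4, 5)), 1)
  expect_equal(csf_serum_ratio(9, c(4, 5)), 2)
  # homogeneity: scaling both compartments cancels
  expect_equal(csf_serum_ratio(9 * 3, c(4, 5) * 3),
               csf_serum_ratio(9, c(4, 5)))
  expect_error(csf_serum_ratio(9, numeric(0)), "empty")
  expect_error(csf_serum_ratio(9, c(-1, 1)), "zero")
})

make_ocr <- function(groups = c(w1 = "adult", w2 = "adult", w3 = "P0"),
                     pre = c(100, 100, 100), post = c(40, 40, 40),
                     calcein = c(1, 1, 1), plate = "p1") {
  wells <- names(groups)
  d <- expand.grid(well = wells, cycle = 1:6, rep = 1:3,
                   stringsAsFactors = FALSE)
  d$plate <- plate
  d$group <- groups[d$well]
  d$time_min <- d$cycle * 6 + d$rep
  k <- match(d$well, wells)
  d$ocr <- ifelse(d$cycle <= 3, pre[k], post[k])
  d$calcein <- calcein[k]
  d
}
oligo <- function(plate = "p1") data.frame(plate = plate,
                                           label = "oligomycin",
                                           time_min = 20)

test_that("ATP extraction is the pre/post oligomycin OCR drop, adult-normalized", {
  d <- make_ocr(groups = c(w1 = "adult", w2 = "P0"),
                pre = c(60, 100), post = c(0, 40))
  res <- atp_production(d, oligo())
  expect_equal(res$atp_raw[res$group == "adult"], 60)
  expect_equal(res$atp_norm[res$group == "P0"], 1) # (100-40)/1/60
  # pre = post gives zero
  d0 <- make_ocr(pre = c(50, 50, 80), post = c(50, 50, 40))
  res0 <- atp_production(d0, oligo())
  expect_equal(res0$atp_raw[res0$well %in% c("w1", "w2")], c(0, 0))
})

test_that("adult wells self-normalize to mean 1 on every plate", {
  d1 <- make_ocr(pre = c(90, 110, 120), post = c(30, 40, 50))
  d2 <- make_ocr(pre = c(200, 180, 150), post = c(80, 60, 50), plate = "p2")
  res <- atp_production(rbind(d1, d2), rbind(oligo("p1"), oligo("p2")))
  for (pl in c("p1", "p2")) {
    adult <- res$atp_norm[res$plate == pl & res$group == "adult"]
    expect_equal(mean(adult), 1)
  }
})

test_that("ATP is invariant to uniform rescaling of OCR on a plate", {
  d <- make_ocr(pre = c(90, 110, 120), post = c(30, 40, 50))
  d_scaled <- d; d_scaled$ocr <- d$ocr * 7.3
  expect_equal(atp_production(d_scaled, oligo())$atp_norm,
               atp_production(d, oligo())$atp_norm)
})

test_that("missing annotations or adult wells are hard errors", {
  d <- make_ocr()
  expect_error(atp_production(d, data.frame(plate = "p1", label = "fccp",
                                            time_min = 20)),
               "oligomycin")
  d_no_adult <- make_ocr(groups = c(w1 = "P0", w2 = "P7", w3 = "P0"))
  expect_error(atp_production(d_no_adult, oligo()), "normalization")
})

test_that("Welch t from raw data and summaries; identical groups give t=0, p=1", {
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  # summary input and raw input agree
  a <- c(2.3, 2.5, 2.7, 2.4, 2.6, 2.5); b <- c(2.1, 3.0, 2.4, 3.2, 2.7, 2.9)
  raw <- welch_t(a, b)
  smry <- welch_t(list(mean = mean(a), sd = sd(a), n = 6),
                  list(mean = mean(b), sd = sd(b), n = 6))
  expect_equal(raw$t, smry$t)
  expect_equal(raw$p_value, smry$p_value)
  # agreement with the reference implementation
  ref <- t.test(a, b)
  expect_equal(raw$t, unname(ref$statistic))
  expect_equal(raw$df, unname(ref$parameter))
  expect_equal(raw$p_value, ref$p.value)
  expect_error(welch_t(c(1), c(1, 2)), "n >= 2")
})

test_that("the CSF-protein comparison reproduces the printed p of about 0.34", {
  gfp <- list(mean = 2.50, sd = 0.20, n = 6)
  oe <- list(mean = 2.71, sd = 0.46, n = 6)
  welch <- welch_t(gfp, oe)
  student <- welch_t(gfp, oe, var_equal = TRUE)
  expect_gt(welch$p_value, 0.33); expect_lt(welch$p_value, 0.35)
  expect_gt(student$p_value, 0.32); expect_lt(student$p_value, 0.34)
  # Welch df never exceeds the pooled df
  expect_lte(welch$df, student$df)
})

test_that("Welch reduces to Student when variances and sizes are equal", {
  smry <- list(mean = 5, sd = 1.2, n = 8)
  smry2 <- list(mean = 6, sd = 1.2, n = 8)
  expect_equal(welch_t(smry, smry2)$t,
               welch_t(smry, smry2, var_equal = TRUE)$t)
  expect_equal(welch_t(smry, smry2)$df, 14)
})

test_that("Welch p matches a permutation test within Monte-Carlo error", {
  set.seed(91)
  a <- rnorm(7, 0, 1); b <- rnorm(8, 0.8, 1)
  p_welch <- welch_t(a, b)$p_value
  pooled <- c(a, b); na <- length(a)
  nperm <- 10000
  tobs <- abs(welch_t(a, b)$t)
  exceed <- replicate(nperm, {
    idx <- sample(length(pooled), na)
    abs(welch_t(pooled[idx], pooled[-idx])$t) >= tobs
  })
  p_perm <- mean(exceed)
  mc_se <- sqrt(p_perm * (1 - p_perm) / nperm)
  expect_lt(abs(p_welch - p_perm), max(4 * mc_se, 0.02))
})

test_that("Sidak adjustment follows 1-(1-p)^m and is monotone", {
  expect_equal(sidak_adjust(0.2, 1), 0.2)
  expect_equal(sidak_adjust(0, 5), 0)
  expect_equal(sidak_adjust(1, 5), 1)
  expect_equal(sidak_adjust(0.01, 5), 1 - 0.99^5)
  p <- seq(0, 1, by = 0.05)
  expect_true(all(sidak_adjust(p, 4) >= p))
  expect_true(all(diff(sidak_adjust(p, 4)) >= 0))
  expect_true(all(sidak_adjust(0.3, 1:10) ==
                    cummax(sidak_adjust(0.3, 1:10))))
  expect_error(sidak_adjust(1.2, 2), "0, 1")
})

test_that("MAD outlier rule flags gross outliers only and can be disabled by data", {
  set.seed(101)
  flags <- mad_outliers(c(rnorm(20), 50))
  expect_true(flags[21])
  expect_true(sum(flags) <= 2)
  expect_false(any(mad_outliers(rep(3, 10))))
})
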