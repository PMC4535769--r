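melt_params <- function(Tm, dHm = 120) {
  list(Tm = Tm, dHm = dHm, a_n = 100, b_n = -0.12, a_u = 35, b_u = -0.05)
}
temps <- seq(283, 363, by = 1)

test_that("unfolded fraction is exactly one half at the midpoint", {
  expect_equal(two_state_fraction(328.85, Tm = 328.85, dHm = 100), 0.5)
  expect_equal(two_state_fraction(306.15, Tm = 306.15, dHm = 73, dCp = 1.2), 0.5)
  # monotone increasing through the transition
  th <- two_state_fraction(seq(300, 360, 5), Tm = 330, dHm = 100)
  expect_true(all(diff(th) > 0))
})

test_that("noiseless melting curves recover Tm to 0.1 K and dHm", {
  for (Tm_true in c(328.85, 306.15)) {
    cv <- gen_curve("melting", melt_params(Tm_true), x = temps,
                    noise_sd = 0, seed = 1)
    fit <- fit_melting_curve(cv)
    expect_lt(abs(fit$Tm - Tm_true), 0.1)
    expect_equal(fit$dHm, 120, tolerance = 0.05)
    expect_equal(fit$Tm_C, fit$Tm - 273.15)
  }
})

test_that("Celsius input converts at parse and fits identically", {
  cv_k <- gen_curve("melting", melt_params(328.85), x = temps,
                    noise_sd = 0, seed = 1)
  cv_c <- curve_table(temps - 273.15, cv_k$y, x_unit = "C")
  expect_equal(fit_melting_curve(cv_c)$Tm, fit_melting_curve(cv_k)$Tm,
               tolerance = 1e-6)
})

test_that("melting fit tolerates realistic noise with small Tm bias", {
  Tm_true <- 306.15
  tms <- vapply(1:20, function(s) {
    cv <- gen_curve("melting", melt_params(Tm_true), x = temps,
                    noise_sd = 0.02 * 65, seed = s)  # 2% of signal range
    fit_melting_curve(cv)$Tm
  }, numeric(1))
  expect_lt(abs(mean(tms) - Tm_true), 0.5)
})

test_that("melting fit is invariant to affine rescaling of the fluorescence axis", {
  cv <- gen_curve("melting", melt_params(320), x = temps, noise_sd = 0.5,
                  seed = 5)
  f1 <- fit_melting_curve(cv)
  cv2 <- curve_table(cv$x, 3.7 * cv$y + 210, x_unit = "K")
  f2 <- fit_melting_curve(cv2)
  expect_lt(abs(f2$Tm - f1$Tm), 0.01)
})

test_that("melting fit rejects flat curves and short series", {
  flat <- curve_table(temps, rep(80, length(temps)) + rnorm(length(temps), 0, 0.3),
                      x_unit = "K")
  set.seed(7)
  expect_error(fit_melting_curve(flat), "flat curve")
  short <- curve_table(seq(300, 340, by = 5), rnorm(9, 50), x_unit = "K")
  expect_error(fit_melting_curve(short), ">= 12 points")
})

test_that("ddG from Tm shift follows the two-state arithmetic", {
  ref <- list(Tm = 328.85, dHm = 100)
  expect_equal(ddg_from_tm(list(Tm = 328.85), ref)$ddG, 0)
  # the full-length vs empty contrast: 55.7 C vs 33 C midpoints
  d <- ddg_from_tm(list(Tm = 306.15), ref)
  expect_equal(d$dTm, -22.7, tolerance = 1e-9)
  expect_equal(d$ddG, 100 * (-22.7) / 328.85, tolerance = 1e-9)
  expect_equal(round(d$ddG, 2), -6.90)
  # linear in the reference enthalpy
  d2 <- ddg_from_tm(list(Tm = 306.15), list(Tm = 328.85, dHm = 200))
  expect_equal(d2$ddG, 2 * d$ddG)
  expect_error(ddg_from_tm(list(Tm = -10), ref), "unit error")
  expect_warning(ddg_from_tm(list(Tm = 33), list(Tm = 55.7, dHm = 100)),
                 "Celsius")
})

conc <- 10^seq(-9, -3.5, by = 0.25)
ic_params <- function(ic50, h = 1) list(ic50 = ic50, h = h, a_lo = 0.05,
                                        a_hi = 0.21)

test_that("noiseless 4PL competition curves recover IC50 within 1%", {
  for (ic in c(0.19e-6, 7.7e-6, 18.0e-6)) {
    cv <- gen_curve("competition", ic_params(ic), x = conc, noise_sd = 0,
                    seed = 1)
    fit <- fit_ic50(cv)
    expect_lt(abs(fit$ic50 - ic) / ic, 0.01)
    expect_equal(fit$hill, 1, tolerance = 0.01)
  }
})

test_that("the response at c = IC50 sits midway between the plateaus", {
  cv <- gen_curve("competition", ic_params(1e-6), x = conc, noise_sd = 0,
                  seed = 1)
  fit <- fit_ic50(cv)
  mid <- (fit$a_hi + fit$a_lo) / 2
  pred <- fit$a_lo + (fit$a_hi - fit$a_lo) / (1 + (fit$ic50 / fit$ic50)^fit$hill)
  expect_equal(pred, mid)
})

test_that("IC50 rescales exactly with the concentration scale", {
  cv <- gen_curve("competition", ic_params(0.5e-6), x = conc, noise_sd = 0.002,
                  seed = 3)
  f1 <- fit_ic50(cv)
  cv2 <- curve_table(cv$x * 1e6, cv$y, x_unit = "M")  # same data in micromolar
  f2 <- fit_ic50(cv2)
  expect_equal(f2$ic50, f1$ic50 * 1e6, tolerance = 1e-6)
})

test_that("noisy IC50 replicates recover the truth within 15% (geometric mean)", {
  ic_true <- 18.0e-6
  est <- vapply(1:15, function(s) {
    cv <- gen_curve("competition", ic_params(ic_true), x = conc,
                    noise_sd = 0.03 * 0.16, seed = s)
    fit_ic50(cv)$ic50
  }, numeric(1))
  gm <- exp(mean(log(est)))
  expect_lt(abs(gm - ic_true) / ic_true, 0.15)
})

test_that("degenerate competition inputs are caught", {
  flat <- curve_table(conc, rep(0.1, length(conc)), x_unit = "M")
  expect_error(fit_ic50(flat), "plateau")
  narrow <- curve_table(c(1, 1.5, 2, 2.5, 3, 3.5) * 1e-6, c(6:1) / 10,
                        x_unit = "M")
  expect_error(fit_ic50(narrow), "orders of magnitude")
  set.seed(8)
  bumpy <- gen_curve("competition", ic_params(1e-6), x = conc, noise_sd = 0,
                     seed = 2)
  bumpy$y[10] <- bumpy$y[10] + 0.08
  expect_warning(fit_ic50(bumpy), "monotone")
})

times_min <- seq(0, 240, by = 15)

test_that("decay fits recover half-time and plateau from clean data", {
  cv <- gen_curve("decay", list(k = log(2) / 50, n_inf = 0), x = times_min,
                  noise_sd = 0, seed = 1)
  fit <- fit_decay(cv, t_query = c(50, 240))
  expect_lt(abs(fit$t50 - 50), 1)
  expect_equal(unname(fit$at_query[1]), 50, tolerance = 0.5)

  # high plateau: surface level never falls to 50%
  cv2 <- gen_curve("decay", list(k = 0.03, n_inf = 80), x = times_min,
                   noise_sd = 0, seed = 1)
  fit2 <- fit_decay(cv2, t_query = 240)
  expect_true(is.na(fit2$t50))
  expect_gt(unname(fit2$at_query), 80)
})

test_that("a constant 100% series yields no decay and no half-time", {
  cv <- curve_table(times_min, rep(100, length(times_min)), x_unit = "min")
  fit <- fit_decay(cv, t_query = 240)
  expect_lt(fit$k, 1e-4)
  expect_equal(unname(fit$at_query), 100, tolerance = 0.5)
  expect_true(is.na(fit$t50))
})

test_that("increasing series warn but still return a fit", {
  cv <- curve_table(times_min, 100 + 0.1 * times_min, x_unit = "min")
  expect_warning(fit <- fit_decay(cv), "increasing")
  expect_s3_class(fit, "decay_fit")
  cv2 <- curve_table(times_min[-1], 100 * exp(-0.01 * times_min[-1]),
                     x_unit = "min")
  expect_error(fit_decay(cv2), "t = 0")
})

test_that("curve tables round trip through TSV in each unit", {
  cv <- gen_curve("melting", melt_params(320), x = temps, noise_sd = 0.3,
                  seed = 4)
  back <- read_curve_table(write_curve_table(cv, y_name = "fluorescence"))
  expect_equal(back$x, cv$x, tolerance = 1e-8)
  expect_equal(back$y, cv$y, tolerance = 1e-8)
  cvc <- read_curve_table(c("temperature_C\tfluorescence",
                            "25\t100", "30\t90"))
  expect_equal(cvc$x, c(298.15, 303.15))
  cvm <- read_curve_table(c("time_min\tpercent_mfi", "0\t100", "60\t70"))
  expect_equal(attr(cvm, "x_unit"), "min")
})
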