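# Experimental-side fits: two-state thermal denaturation (tryptophan
# fluorescence melting curves), competitive-anisotropy IC50 (four-parameter
# logistic), and cell-surface decay kinetics. All fitters are deterministic:
# initialization is data-derived (no random restarts).

#' Gas constant in kcal/mol/K
#' @export
R_KCAL <- 0.0019872041

#' Construct a measurement curve table
#'
#' Generic (x, y) series for melting, competition and decay fits.
#' Temperatures may be declared in degrees Celsius and are converted to
#' Kelvin at construction (`T_K = T_C + 273.15`); all fitting is done in K.
#'
#' @param x ordered finite numbers (K, degrees C, molar concentration, or
#'   minutes).
#' @param y measured response (fluorescence a.u., anisotropy, or percent MFI).
#' @param x_unit one of `"K"`, `"C"`, `"M"`, `"min"`.
#' @param replicate optional replicate id per point.
#' @return data frame of class `curve_table` with attribute `x_unit` (the
#'   internal unit: `"K"` for temperatures).
#' @export
curve_table <- function(x, y, x_unit = c("K", "C", "M", "min"),
                        replicate = NULL) {
  x_unit <- match.arg(x_unit)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("curve x and y must be finite")
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (x_unit == "C") { x <- x + 273.15; x_unit <- "K" }
  out <- data.frame(x = x, y = y)
  if (!is.null(replicate)) out$replicate <- replicate
  attr(out, "x_unit") <- x_unit
  class(out) <- c("curve_table", "data.frame")
  out
}

#' Read a curve table from TSV
#'
#' Header columns recognized: `temperature_C`/`temperature_K` +
#' `fluorescence`, `concentration_M` + `anisotropy`, or `time_min` +
#' `percent_mfi` (an optional `replicate` column is carried through).
#'
#' @param file path or text.
#' @return a [curve_table()].
#' @export
read_curve_table <- function(file) {
  lines <- .as_lines(file)
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t")
  dict <- list(temperature_C = "C", temperature_K = "K",
               concentration_M = "M", time_min = "min")
  xcol <- intersect(names(dict), names(tab))
  if (length(xcol) != 1L)
    stop("curve TSV needs exactly one of: ", paste(names(dict), collapse = ", "))
  ycol <- setdiff(names(tab), c(xcol, "replicate"))[1L]
  curve_table(tab[[xcol]], tab[[ycol]], x_unit = dict[[xcol]],
              replicate = tab$replicate)
}

#' Write a curve table as TSV
#' @param curve a [curve_table()].
#' @param y_name response column name for the header.
#' @param file optional path.
#' @param params named list echoed into the comment header.
#' @export
write_curve_table <- function(curve, y_name = "y", file = NULL,
                              params = list()) {
  unit <- attr(curve, "x_unit")
  xcol <- c(K = "temperature_K", M = "concentration_M", min = "time_min")[unit]
  hdr <- .header_comment("curve table", params)
  lines <- c(hdr, paste(xcol, y_name, sep = "\t"),
             sprintf("%.10g\t%.10g", curve$x, curve$y))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

# ---- two-state melting ------------------------------------------------------

#' Unfolded fraction of a two-state denaturation at temperature T
#'
#' `theta(T) = 1 / (1 + exp(dG_u(T) / (R T)))` with the Gibbs-Helmholtz
#' unfolding free energy
#' `dG_u(T) = dHm (1 - T/Tm) + dCp (T - Tm - T ln(T/Tm))`. At `T = Tm` the
#' fraction is exactly 0.5.
#'
#' @param T temperature in K.
#' @param Tm melting midpoint in K.
#' @param dHm van't Hoff enthalpy at Tm, kcal/mol.
#' @param dCp heat-capacity change, kcal/mol/K (default 0).
#' @return unfolded fraction in (0, 1).
#' @export
two_state_fraction <- function(T, Tm, dHm, dCp = 0) {
  dG <- dHm * (1 - T / Tm) + dCp * (T - Tm - T * log(T / Tm))
  1 / (1 + exp(dG / (R_KCAL * T)))
}

.melting_model <- function(T, Tm, dHm, a_n, b_n, a_u, b_u, dCp = 0) {
  th <- two_state_fraction(T, Tm, dHm, dCp)
  (a_n + b_n * T) * (1 - th) + (a_u + b_u * T) * th
}

#' Fit a two-state thermal denaturation curve
#'
#' Least-squares fit of
#' `F(T) = (a_n + b_n T)(1 - theta(T)) + (a_u + b_u T) theta(T)` with
#' [two_state_fraction()] as the transition, `Tm` and `dHm` free and `dCp`
#' fixed (default 0, the Schellman linear approximation). Initialization is
#' deterministic: `Tm` at the steepest descent of the smoothed signal,
#' baselines from the first/last deciles; a coarse `Tm`/`dHm` grid is retried
#' if the first attempt fails.
#'
#' @param curve a [curve_table()] with temperatures (K or C at construction)
#'   and fluorescence; at least 12 points spanning the transition.
#' @param dCp fixed heat-capacity change, kcal/mol/K.
#' @return object of class `melting_fit`: `Tm` (K), `Tm_C`, `dHm`
#'   (kcal/mol), baseline coefficients, `residual_norm`, `fitted`.
#' @export
fit_melting_curve <- function(curve, dCp = 0) {
  stopifnot(inherits(curve, "curve_table"))
  if (attr(curve, "x_unit") != "K")
    stop("melting fit needs temperatures (construct the curve with x_unit 'K' or 'C')")
  Tx <- curve$x; y <- curve$y
  if (length(Tx) < 12L) stop("need >= 12 points for a melting fit")
  rng <- range(Tx)
  noise_sd <- stats::sd(stats::residuals(stats::lm(y ~ Tx + I(Tx^2))))
  span <- abs(mean(y[Tx <= stats::quantile(Tx, 0.1)]) -
                mean(y[Tx >= stats::quantile(Tx, 0.9)]))
  if (span <= 5 * noise_sd)
    stop("flat curve: no unfolding transition detected")
  # deterministic initialization
  sm <- stats::lowess(Tx, y, f = 1 / 4)
  dy <- diff(sm$y) / diff(sm$x)
  Tm0 <- sm$x[which.max(abs(dy))]
  lo_i <- Tx <= stats::quantile(Tx, 0.1); hi_i <- Tx >= stats::quantile(Tx, 0.9)
  fit_base <- function(i) {
    if (sum(i) >= 2L && stats::sd(Tx[i]) > 0) stats::coef(stats::lm(y[i] ~ Tx[i]))
    else c(mean(y[i]), 0)
  }
  cn <- fit_base(lo_i); cu <- fit_base(hi_i)
  data <- data.frame(T = Tx, y = y)
  try_fit <- function(Tm0, dHm0) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ .melting_model(T, Tm, dHm, a_n, b_n, a_u, b_u, dCp = dCp),
        data = data,
        start = list(Tm = Tm0, dHm = dHm0, a_n = cn[[1]], b_n = cn[[2]],
                     a_u = cu[[1]], b_u = cu[[2]]),
        lower = c(Tm = rng[1], dHm = 1, a_n = -Inf, b_n = -Inf,
                  a_u = -Inf, b_u = -Inf),
        upper = c(Tm = rng[2], dHm = 2000, a_n = Inf, b_n = Inf,
                  a_u = Inf, b_u = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
  }
  fit <- try_fit(Tm0, 100)
  if (is.null(fit)) {
    for (Tm_try in stats::quantile(Tx, c(0.25, 0.5, 0.75))) {
      for (dH_try in c(30, 100, 300)) {
        fit <- try_fit(Tm_try, dH_try)
        if (!is.null(fit)) break
      }
      if (!is.null(fit)) break
    }
  }
  if (is.null(fit)) stop("melting fit failed to initialize (grid retry exhausted)")
  p <- as.list(stats::coef(fit))
  structure(list(Tm = p$Tm, Tm_C = p$Tm - 273.15, dHm = p$dHm, dCp = dCp,
                 native_baseline = c(intercept = p$a_n, slope = p$b_n),
                 unfolded_baseline = c(intercept = p$a_u, slope = p$b_u),
                 residual_norm = sqrt(sum(stats::residuals(fit)^2)),
                 fitted = stats::fitted(fit), converged = TRUE),
            class = "melting_fit")
}

#' @export
print.melting_fit <- function(x, ...) {
  cat(sprintf("melting_fit: Tm = %.2f K (%.2f C), dHm = %.1f kcal/mol\n",
              x$Tm, x$Tm_C, x$dHm))
  invisible(x)
}

#' Stability change from melting-temperature shift (two-state model)
#'
#' `ddG_TDTF = -dG_u,ref(Tm_variant)` evaluated with the reference fit's
#' enthalpy: `ddG = dHm_ref * dTm / Tm_ref` when `dCp = 0` (Schellman linear
#' approximation), with the Gibbs-Helmholtz `dCp` correction
#' `-dCp (Tv - Tref - Tv ln(Tv/Tref))` otherwise. Negative values mean the
#' variant complex is less stable than the reference.
#'
#' @param variant,reference [fit_melting_curve()] results, or plain lists
#'   with elements `Tm` (K) and (for the reference) `dHm`.
#' @param dCp heat-capacity change in kcal/mol/K (default 0).
#' @return object of class `ddg_tdtf`: `ddG` (kcal/mol), `dTm` (K),
#'   `Tm_ref`, `dHm_ref`, `dCp`.
#' @export
ddg_from_tm <- function(variant, reference, dCp = 0) {
  Tv <- variant$Tm; Tr <- reference$Tm; dH <- reference$dHm
  if (is.null(Tv) || is.null(Tr) || is.null(dH))
    stop("variant needs $Tm; reference needs $Tm and $dHm")
  if (Tr <= 0 || Tv <= 0)
    stop("unit error: non-positive Tm in Kelvin (was a Celsius value passed?)")
  if (Tr < 150 || Tv < 150)
    warning("Tm below 150 K: looks like a Celsius value passed as Kelvin")
  dTm <- Tv - Tr
  ddG <- dH * dTm / Tr - dCp * (Tv - Tr - Tv * log(Tv / Tr))
  structure(list(ddG = ddG, dTm = dTm, Tm_ref = Tr, dHm_ref = dH, dCp = dCp),
            class = "ddg_tdtf")
}

#' @export
print.ddg_tdtf <- function(x, ...) {
  cat(sprintf("ddg_tdtf: ddG = %.2f kcal/mol (dTm = %.2f K vs Tm_ref = %.2f K)\n",
              x$ddG, x$dTm, x$Tm_ref))
  invisible(x)
}

# ---- IC50 (four-parameter logistic) -----------------------------------------

.logistic4 <- function(c, ic50, h, a_lo, a_hi) {
  a_lo + (a_hi - a_lo) / (1 + (c / ic50)^h)
}

#' Fit a competitive-binding IC50 curve (four-parameter logistic)
#'
#' `A(c) = A_lo + (A_hi - A_lo) / (1 + (c / IC50)^h)`: a descending
#' anisotropy competition curve with Hill slope `h` and plateaus `A_hi`
#' (no competitor) and `A_lo` (full inhibition). The response at
#' `c = IC50` is exactly midway between the plateaus. Fitted on log
#' concentration; initialization is deterministic (plateaus from the extreme
#' deciles of the response, IC50 at the concentration nearest the half-range
#' response, `h = 1`).
#'
#' @param curve a [curve_table()] with molar concentrations and anisotropy;
#'   at least 6 points spanning at least two orders of magnitude.
#' @return object of class `ic50_fit`: `ic50` (molar), `hill`, `a_lo`,
#'   `a_hi`, `residual_norm`, `fitted`.
#' @export
fit_ic50 <- function(curve) {
  stopifnot(inherits(curve, "curve_table"))
  cc <- curve$x; y <- curve$y
  if (length(cc) < 6L) stop("need >= 6 points for an IC50 fit")
  if (any(cc <= 0)) stop("concentrations must be positive")
  if (diff(range(log10(cc))) < 2)
    stop("concentrations must span at least two orders of magnitude")
  ord <- order(cc)
  span <- diff(range(y))
  noise_sd <- stats::sd(diff(y[ord])) / sqrt(2)
  if (span < 3 * noise_sd || span == 0)
    stop("no inhibition detected: response is all plateau")
  run <- y[ord]
  if (any(diff(run) > 3 * noise_sd))
    warning("non-monotone competition curve beyond noise level")
  a_hi0 <- mean(run[seq_len(max(1L, floor(length(run) / 10)))])
  a_lo0 <- mean(run[seq(length(run) - max(0L, floor(length(run) / 10) - 1L), length(run))])
  half <- (a_hi0 + a_lo0) / 2
  ic0 <- cc[which.min(abs(y - half))]
  data <- data.frame(lc = log(cc), y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a_lo + (a_hi - a_lo) / (1 + exp(h * (lc - lic))),
      data = data,
      start = list(lic = log(ic0), h = 1, a_lo = a_lo0, a_hi = a_hi0),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("IC50 fit failed: ", conditionMessage(e)))
  p <- as.list(stats::coef(fit))
  structure(list(ic50 = exp(p$lic), hill = p$h, a_lo = p$a_lo, a_hi = p$a_hi,
                 residual_norm = sqrt(sum(stats::residuals(fit)^2)),
                 fitted = stats::fitted(fit)),
            class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat(sprintf("ic50_fit: IC50 = %.3g M, Hill slope = %.2f, plateaus %.3g / %.3g\n",
              x$ic50, x$hill, x$a_hi, x$a_lo))
  invisible(x)
}

# ---- surface decay ----------------------------------------------------------

.decay_model <- function(t, k, n_inf) n_inf + (100 - n_inf) * exp(-k * t)

#' Fit a cell-surface decay curve
#'
#' `N(t) = N_inf + (100 - N_inf) exp(-k t)` for percent-of-initial mean
#' fluorescence intensity over time. Reports the half-time `t50`, the time
#' at which `N(t)` first reaches 50 percent of the initial signal
#' (`NA` when the plateau `N_inf >= 50`, i.e. the curve never falls that
#' far), and optionally the fitted percentage at query times.
#'
#' @param curve a [curve_table()] with time in minutes (a `t = 0` point must
#'   be present) and percent MFI.
#' @param t_query optional times (min) at which to evaluate the fitted curve.
#' @return object of class `decay_fit`: `k` (1/min), `n_inf` (percent),
#'   `t50` (min or `NA`), `at_query` (named by time), `residual_norm`.
#' @export
fit_decay <- function(curve, t_query = NULL) {
  stopifnot(inherits(curve, "curve_table"))
  t <- curve$x; y <- curve$y
  if (!any(t == 0)) stop("decay curve must include a t = 0 point")
  trend <- if (stats::sd(y) > 0) stats::cor(t, y) else 0
  if (trend > 0.5 && y[which.max(t)] > mean(y[t == 0]))
    warning("increasing trend: data do not look like a decay")
  n_inf0 <- max(0, min(y))
  pos <- y > n_inf0 + 1e-9 & t > 0
  k0 <- if (any(pos)) {
    max(1e-4, stats::median(-log((y[pos] - n_inf0) / (100 - n_inf0 + 1e-9)) / t[pos]))
  } else 1e-3
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ .decay_model(t, k, n_inf),
                      data = data.frame(t = t, y = y),
                      start = list(k = k0, n_inf = n_inf0),
                      lower = c(k = 0, n_inf = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # flat series: slope indistinguishable from zero
    k <- 0; n_inf <- mean(y); resid <- y - n_inf
  } else {
    p <- as.list(stats::coef(fit)); k <- p$k; n_inf <- p$n_inf
    resid <- stats::residuals(fit)
  }
  t50 <- if (k > 1e-12 && n_inf < 50) log((100 - n_inf) / (50 - n_inf)) / k
         else NA_real_
  at_query <- if (is.null(t_query)) NULL else
    stats::setNames(.decay_model(t_query, k, n_inf), t_query)
  structure(list(k = k, n_inf = n_inf, t50 = t50, at_query = at_query,
                 residual_norm = sqrt(sum(resid^2))),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("decay_fit: k = %.4g /min, plateau = %.1f%%, t50 = %s min\n",
              x$k, x$n_inf, if (is.na(x$t50)) "NA" else sprintf("%.1f", x$t50)))
  invisible(x)
}
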