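# Thermal-stability descriptors and Michaelis-Menten kinetics. Both thermal
# curves are modelled as minimal two-state logistics, which gives analytic
# expressions for the descriptors of interest: midpoint (T0.5 of a
# thermal-shift melting curve, T50 of a residual-activity curve), maximum
# slope of the percentage curve (25/k %/degC for steepness k), and the onset
# ("initial unfolding") temperature at 5% unfolded fraction,
# onset = Tm - k*ln(19).

logistic_rise <- function(T, Tm, k) 1 / (1 + exp((Tm - T) / k))

#' Normalize a raw melting curve to unfolded fraction
#'
#' Baseline = mean of the lowest-temperature 10% of points; plateau = maximum
#' of a 3-point moving average (robust to the post-peak quenching typical of
#' hydrophobic-dye fluorimetry). The result is
#' \code{(y - baseline)/(plateau - baseline)} clipped to [0, 1.05], so a value
#' of 1 corresponds to completely unfolded protein.
#'
#' @param curve a melting \code{curve_table}.
#' @return normalized melting \code{curve_table} (procedure-defined units).
#' @export
normalize_melting <- function(curve) {
  stopifnot(curve_kind(curve) == "melting")
  n <- nrow(curve)
  nb <- max(1L, ceiling(0.1 * n))
  baseline <- mean(curve$y[seq_len(nb)])
  ma3 <- stats::filter(curve$y, rep(1 / 3, 3L), sides = 2L)
  plateau <- max(ma3, na.rm = TRUE)
  span <- plateau - baseline
  if (!is.finite(span) || span <= 1e-8 * max(abs(plateau), 1))
    stop("no transition: plateau and baseline coincide")
  y <- pmin(1.05, pmax(0, (curve$y - baseline) / span))
  curve_table(curve$x, y, kind = "melting",
              metadata = c(attr(curve, "metadata"),
                           list(baseline = baseline, plateau = plateau,
                                normalized = TRUE)))
}

new_stability_fit <- function(midpoint, k, max_slope, onset, residual_rms,
                              direction, onset_threshold = 0.05) {
  structure(list(midpoint = midpoint, k = k, max_slope = max_slope,
                 onset = onset, residual_rms = residual_rms,
                 direction = direction, onset_threshold = onset_threshold,
                 model = "two-state logistic"),
            class = "stability_fit")
}

#' @export
print.stability_fit <- function(x, ...) {
  cat(sprintf(
    "%s fit (%s): midpoint %.2f degC, k %.2f degC, max slope %.1f %%/degC, onset %.1f degC\n",
    x$model, x$direction, x$midpoint, x$k, x$max_slope, x$onset))
  invisible(x)
}

# rough logistic starts: midpoint from the 0.5 crossing by interpolation,
# steepness from the quartile-crossing spread
logistic_starts <- function(T, y, rising = TRUE) {
  yy <- if (rising) y else 1 - y
  cross <- function(level) {
    i <- which(yy >= level)[1L]
    if (is.na(i) || i == 1L) return(NA_real_)
    stats::approx(yy[(i - 1L):i], T[(i - 1L):i], xout = level)$y
  }
  Tm <- cross(0.5)
  if (is.na(Tm)) Tm <- T[which.min(abs(yy - 0.5))]
  k <- (cross(0.75) - cross(0.25)) / (2 * log(3))
  if (!is.finite(k) || k <= 0) k <- diff(range(T)) / 10
  c(Tm = Tm, k = k)
}

#' Fit a two-state unfolding logistic to a normalized melting curve
#'
#' Least-squares fit of \code{f(T) = 1/(1 + exp((Tm - T)/k))}. Reports the
#' midpoint (T0.5), the steepness \code{k}, the maximum slope of the
#' percentage curve (25/k, the analytic maximum derivative of 100 f), and the
#' onset temperature where the fitted unfolded fraction crosses
#' \code{onset_threshold} (default 0.05): \code{onset = Tm - k log(1/thr - 1)}.
#' If the nonlinear fit fails to converge, the midpoint falls back to
#' monotone linear interpolation of the 0.5 crossing.
#'
#' @param curve normalized melting \code{curve_table} spanning the transition.
#' @param onset_threshold unfolded fraction defining the onset.
#' @return object of class \code{stability_fit}.
#' @export
fit_unfolding <- function(curve, onset_threshold = 0.05) {
  stopifnot(curve_kind(curve) == "melting")
  T <- curve$x; y <- curve$y
  st <- logistic_starts(T, y, rising = TRUE)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 1 / (1 + exp((Tm - T) / k)),
                      start = list(Tm = st[["Tm"]], k = st[["k"]]),
                      lower = c(-Inf, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    if (is.na(st[["Tm"]]))
      stop("unfolding fit did not converge and the curve never crosses 0.5")
    return(new_stability_fit(st[["Tm"]], st[["k"]], 25 / st[["k"]],
                             st[["Tm"]] - st[["k"]] * log(1 / onset_threshold - 1),
                             NA_real_, "unfolding rises", onset_threshold))
  }
  p <- stats::coef(fit)
  new_stability_fit(
    midpoint = p[["Tm"]], k = p[["k"]], max_slope = 25 / p[["k"]],
    onset = p[["Tm"]] - p[["k"]] * log(1 / onset_threshold - 1),
    residual_rms = sqrt(mean(stats::residuals(fit)^2)),
    direction = "unfolding rises", onset_threshold = onset_threshold)
}

#' Fit a decreasing logistic to a residual-activity curve (T50)
#'
#' \code{A(T) = 100/(1 + exp((T - T50)/k))}, for residual activity expressed
#' as percent of the untreated control. The midpoint is the T50 (half the
#' activity survives the heat treatment).
#'
#' @param curve activity \code{curve_table} (percent scale).
#' @return object of class \code{stability_fit}.
#' @export
fit_t50 <- function(curve) {
  stopifnot(curve_kind(curve) == "activity")
  T <- curve$x; y <- curve$y
  if (max(y) > 150 || all(y < 1))
    stop("activity must be expressed as percent of the untreated control")
  st <- logistic_starts(T, y / 100, rising = FALSE)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 100 / (1 + exp((T - T50) / k)),
                      start = list(T50 = st[["Tm"]], k = st[["k"]]),
                      lower = c(-Inf, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) stop("T50 fit did not converge")
  p <- stats::coef(fit)
  new_stability_fit(
    midpoint = p[["T50"]], k = p[["k"]], max_slope = 25 / p[["k"]],
    onset = p[["T50"]] - p[["k"]] * log(19),
    residual_rms = sqrt(mean(stats::residuals(fit)^2)) / 100,
    direction = "activity falls")
}

#' Fit Michaelis-Menten kinetics and derive catalytic constants
#'
#' Nonlinear least squares on \code{v = Vmax S/(Km + S)} (rates in umol/min,
#' substrate in mM), with starts \code{Vmax = 1.05 max(v)} and Km at the
#' interpolated half-maximal substrate concentration. Derived quantities:
#' \code{kcat = Vmax/(E0_nmol * 60/1000)} (per second),
#' \code{specific_activity = Vmax/E0_mg} (U/mg, 1 U = 1 umol/min), and
#' \code{efficiency = kcat/Km} (per mM per second). Standard errors for Km
#' and Vmax come from the fit; kcat and efficiency errors by the delta
#' method using the parameter covariance.
#'
#' @param data kinetics \code{curve_table} (>= 5 substrate points spanning
#'   below and above Km).
#' @param E0_mg enzyme amount in the assay, mg.
#' @param E0_nmol enzyme amount, nmol.
#' @return object of class \code{kinetics_fit} with elements \code{Km},
#'   \code{Vmax}, \code{kcat}, \code{specific_activity}, \code{efficiency}
#'   and a \code{se} list.
#' @export
fit_michaelis_menten <- function(data, E0_mg, E0_nmol) {
  stopifnot(curve_kind(data) == "kinetics", E0_mg > 0, E0_nmol > 0)
  S <- data$x; v <- data$y
  if (length(S) < 5L) stop("need at least 5 substrate points")
  vmax0 <- 1.05 * max(v)
  half <- vmax0 / 2.1
  i <- which(v >= half)[1L]
  km0 <- if (!is.na(i) && i > 1L)
    stats::approx(v[(i - 1L):i], S[(i - 1L):i], xout = half)$y
  else stats::median(S)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ Vmax * S / (Km + S),
                      start = list(Vmax = vmax0, Km = km0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("Michaelis-Menten fit did not converge (starts: Vmax=",
           signif(vmax0, 4), ", Km=", signif(km0, 4), ")", call. = FALSE))
  p <- stats::coef(fit)
  if (any(p <= 0)) stop("negative parameter estimate: Vmax=",
                        signif(p[["Vmax"]], 4), ", Km=", signif(p[["Km"]], 4))
  V <- stats::vcov(fit)
  Vmax <- p[["Vmax"]]; Km <- p[["Km"]]
  conv <- E0_nmol * 60 / 1000          # umol/min per (1/s) of kcat
  kcat <- Vmax / conv
  eff <- kcat / Km
  se_Vmax <- sqrt(V["Vmax", "Vmax"]); se_Km <- sqrt(V["Km", "Km"])
  se_kcat <- se_Vmax / conv
  # delta method for eff = Vmax/(conv*Km): gradient (1/(conv*Km), -Vmax/(conv*Km^2))
  g <- c(1 / (conv * Km), -Vmax / (conv * Km^2))
  se_eff <- sqrt(drop(t(g) %*% V %*% g))
  structure(list(Km = Km, Vmax = Vmax, kcat = kcat,
                 specific_activity = Vmax / E0_mg, efficiency = eff,
                 se = list(Km = se_Km, Vmax = se_Vmax, kcat = se_kcat,
                           specific_activity = se_Vmax / E0_mg,
                           efficiency = se_eff),
                 E0_mg = E0_mg, E0_nmol = E0_nmol),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf(
    "Michaelis-Menten fit: Km %.2f +/- %.2f mM, kcat %.2f +/- %.2f 1/s,\n  specific activity %.1f U/mg, efficiency (kcat/Km) %.2f 1/(mM s)\n",
    x$Km, x$se$Km, x$kcat, x$se$kcat, x$specific_activity, x$efficiency))
  invisible(x)
}
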