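# Non-compartmental analysis: Cmax/Tmax, trapezoidal AUC, moments, MRT,
# moment-based V_SS, bioavailability ratios and two-fold prediction checks.

# coerce series-like input to list(times, conc)
as_tc <- function(series) {
  if (inherits(series, "pbpk_sim")) {
    list(times = series$time_min, conc = series$plasma_conc_ng_ml)
  } else if (inherits(series, "conc_time_series")) {
    list(times = series$times_min, conc = series$conc_ng_ml)
  } else if (is.list(series) && all(c("times", "conc") %in% names(series))) {
    list(times = as.numeric(series$times), conc = as.numeric(series$conc))
  } else {
    stop("expected a pbpk_sim, conc_time_series or list(times, conc)",
         call. = FALSE)
  }
}

# linear interpolation of the curve at time t (t inside the observed range)
interp_conc <- function(tc, t) {
  stats::approx(tc$times, tc$conc, xout = t, rule = 1)$y
}

#' Linear trapezoidal AUC over a window
#'
#' Applies the linear trapezoidal rule to the points inside
#' `[t0, t_last]`; when a window edge falls between sampling points the
#' curve is interpolated linearly at the edge, so the rule stays exact
#' for piecewise-linear profiles and additive over adjacent windows.
#'
#' @param series a `pbpk_sim`, `conc_time_series` or `list(times, conc)`.
#' @param t0,t_last window bounds (min); defaults cover the whole series.
#' @return AUC in ng*min/mL.
#' @export
auc_trapezoid <- function(series, t0 = NULL, t_last = NULL) {
  tc <- as_tc(series)
  if (is.null(t0)) t0 <- min(tc$times)
  if (is.null(t_last)) t_last <- max(tc$times)
  if (t_last <= t0) stop("empty AUC window", call. = FALSE)
  if (t0 < min(tc$times) || t_last > max(tc$times))
    stop("AUC window extends beyond the observed curve", call. = FALSE)
  inside <- tc$times > t0 & tc$times < t_last
  t <- c(t0, tc$times[inside], t_last)
  y <- c(interp_conc(tc, t0), tc$conc[inside], interp_conc(tc, t_last))
  if (length(t) < 2L) stop("need at least 2 points in window",
                           call. = FALSE)
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# linear-trapezoid first moment integral of t*C(t); exact for curves that
# are piecewise linear in C (t*C is then piecewise quadratic; integrate
# each panel of the linear-in-C interpolant exactly)
aumc_trapezoid <- function(tc, t0, t_last) {
  inside <- tc$times > t0 & tc$times < t_last
  t <- c(t0, tc$times[inside], t_last)
  y <- c(interp_conc(tc, t0), tc$conc[inside], interp_conc(tc, t_last))
  t1 <- utils::head(t, -1); t2 <- utils::tail(t, -1)
  y1 <- utils::head(y, -1); y2 <- utils::tail(y, -1)
  # integral of t*C over [t1,t2] with C linear between (t1,y1),(t2,y2)
  sum((t2 - t1) * (y1 * (2 * t1 + t2) + y2 * (t1 + 2 * t2)) / 6)
}

#' Peak concentration and its time
#'
#' @inheritParams auc_trapezoid
#' @param t0,t_last optional window (min) restricting the search.
#' @return List with `cmax` (ng/mL) and `tmax` (min; earliest attainment
#'   on ties).
#' @export
cmax_tmax <- function(series, t0 = -Inf, t_last = Inf) {
  tc <- as_tc(series)
  keep <- tc$times >= t0 & tc$times <= t_last
  if (!any(keep)) stop("no points in window", call. = FALSE)
  t <- tc$times[keep]; y <- tc$conc[keep]
  i <- which.max(y)
  list(cmax = y[i], tmax = t[i])
}

#' Moment analysis of an intravenous profile
#'
#' Standard moment analysis: the terminal slope `lambda_z` comes from a
#' log-linear regression on the tail points (the last `n_tail` points
#' with positive concentration by default), the observed AUC/AUMC are
#' extrapolated to infinity, and
#' `MRT = AUMC/AUC`, `V_SS = Dose * AUMC / AUC^2`.
#'
#' @inheritParams auc_trapezoid
#' @param dose_ng administered intravenous dose (ng).
#' @param n_tail number of terminal points for the log-linear regression
#'   (>= 3).
#' @return An `nca_result`: list with `cmax`, `tmax`, `auc_last`,
#'   `auc_inf`, `aumc_inf`, `mrt`, `lambda_z`, `vss_moment_ml` and the
#'   window used.
#' @export
moment_analysis <- function(series, dose_ng, n_tail = 3L) {
  tc <- as_tc(series)
  if (n_tail < 3L) stop("need at least 3 tail points", call. = FALSE)
  pos <- which(tc$conc > 0)
  if (length(pos) < n_tail)
    stop("fewer than ", n_tail, " positive concentrations", call. = FALSE)
  tail_idx <- utils::tail(pos, n_tail)
  fit <- stats::lm(log(tc$conc[tail_idx]) ~ tc$times[tail_idx])
  lambda_z <- -unname(stats::coef(fit)[2])
  if (!is.finite(lambda_z) || lambda_z <= 0)
    stop("terminal slope is not positive; cannot extrapolate",
         call. = FALSE)

  t0 <- min(tc$times); t_last <- max(tc$times)
  c_last <- tc$conc[length(tc$conc)]
  auc_last <- auc_trapezoid(tc, t0, t_last)
  aumc_last <- aumc_trapezoid(tc, t0, t_last)
  auc_inf <- auc_last + c_last / lambda_z
  aumc_inf <- aumc_last + c_last * t_last / lambda_z +
    c_last / lambda_z^2
  pk <- cmax_tmax(tc)
  structure(
    list(cmax = pk$cmax, tmax = pk$tmax,
         auc_last = auc_last, auc_inf = auc_inf, aumc_inf = aumc_inf,
         mrt = aumc_inf / auc_inf, lambda_z = lambda_z,
         vss_moment_ml = dose_ng * aumc_inf / auc_inf^2,
         window = c(t0, t_last)),
    class = "nca_result")
}

#' Dose-normalised oral/intravenous AUC ratio (absolute bioavailability)
#'
#' `F = (AUC_PO / dose_PO) / (AUC_IV / dose_IV)` over a common horizon.
#'
#' @param po_series,iv_series oral and intravenous curves (any input
#'   accepted by [auc_trapezoid()]); must cover the same time window.
#' @param dose_po_ng,dose_iv_ng the administered doses (ng).
#' @return F as a fraction.
#' @export
bioavailability_ratio <- function(po_series, iv_series, dose_po_ng,
                                  dose_iv_ng) {
  po <- as_tc(po_series); iv <- as_tc(iv_series)
  if (abs(min(po$times) - min(iv$times)) > 1e-9 ||
      abs(max(po$times) - max(iv$times)) > 1e-9)
    stop("oral and intravenous curves must cover the same horizon",
         call. = FALSE)
  (auc_trapezoid(po) / dose_po_ng) / (auc_trapezoid(iv) / dose_iv_ng)
}

#' Prediction-to-observation ratios with the two-fold criterion
#'
#' @param obs,pred observed and predicted values (scalars or equal-length
#'   vectors, e.g. AUC and Cmax).
#' @return List with `ratio` (pred/obs) and `within_twofold` (`TRUE` iff
#'   every ratio lies in `[0.5, 2]`).
#' @export
prediction_ratios <- function(obs, pred) {
  if (any(obs == 0)) stop("observed value is zero", call. = FALSE)
  ratio <- pred / obs
  list(ratio = ratio,
       within_twofold = all(ratio >= 0.5 & ratio <= 2))
}

#' @export
print.nca_result <- function(x, ...) {
  cat("<nca_result> Cmax", signif(x$cmax, 4), "ng/mL at", x$tmax,
      "min; AUC_last", signif(x$auc_last, 5), "AUC_inf",
      signif(x$auc_inf, 5), "ng*min/mL\n")
  cat("  MRT", signif(x$mrt, 4), "min; lambda_z", signif(x$lambda_z, 4),
      "/min; Vss(moment)", signif(x$vss_moment_ml / 1000, 4), "L\n")
  invisible(x)
}
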