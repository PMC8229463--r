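# 13-compartment perfusion-limited whole-body ODE model with fixed-step
# fourth-order Runge-Kutta integration and dose-event handling.
#
# State vector (amounts, ng):
#   absorption | 11 tissues | venous | arterial | eliminated
# The trailing "eliminated" slot accumulates hepatic elimination so that
# total mass is conserved exactly by construction.

pbpk_state_names <- function() {
  c("absorption", pbpk_tissues(), "venous", "arterial", "eliminated")
}

#' Right-hand side of the whole-body PBPK ODE system
#'
#' Pure derivative function, amounts in ng, time in min:
#' * absorption compartment: first-order loss `-Ka * Xa`, feeding the
#'   liver (the absorbed drug enters via the portal vein);
#' * each non-liver, non-lung tissue: `Q_T * (C_art - C_T * R / Kp_T)`,
#'   with outflow routed to the venous pool (adipose, adrenal gland,
#'   brain, heart, kidney) or into the liver (stomach, spleen, small and
#'   large intestine);
#' * liver: hepatic-arterial inflow `(Q_LI - sum(Q_portal)) * C_art`,
#'   portal inflows, absorption input `Ka * Xa`, venous outflow
#'   `Q_LI * C_LI * R / Kp_LI`, and elimination
#'   `CLu_int * fup * C_LI / Kp_LI` (clearance acts on the unbound liver
#'   concentration);
#' * venous pool: systemic tissue outflows plus the residual
#'   arteriovenous shunt `Q_RE * C_art`, minus `Q_CO * C_ven`;
#' * lung: in series, `Q_CO * (C_ven - C_LU * R / Kp_LU)`;
#' * arterial pool: `Q_CO * (C_LU * R / Kp_LU - C_art)`;
#' * eliminated: `+ CLu_int * fup * C_LI / Kp_LI`.
#'
#' @param state named numeric vector over `absorption`, the 11 tissues,
#'   `venous`, `arterial`, `eliminated` (ng). Unnamed vectors of length
#'   15 are accepted in that order.
#' @param phys a `physiology_set`.
#' @param drug a `drug_parameters` object.
#' @param clearance a `clearance_model`; built from `drug` when `NULL`.
#' @return Named derivative vector d(amount)/dt (ng/min).
#' @export
pbpk_rhs <- function(state, phys, drug, clearance = NULL) {
  if (is.null(clearance)) clearance <- build_clu_int(drug)
  nms <- pbpk_state_names()
  if (is.null(names(state))) {
    stopifnot(length(state) == length(nms))
    names(state) <- nms
  }
  r <- drug$blood_plasma_ratio
  kp <- drug$kp
  ts <- phys$tissues
  q <- stats::setNames(ts$blood_flow_ml_min, ts$name)
  v <- stats::setNames(ts$volume_ml, ts$name)

  c_art <- state[["arterial"]] / phys$arterial_blood_volume
  c_ven <- state[["venous"]] / phys$venous_blood_volume
  conc <- state[pbpk_tissues()] / v[pbpk_tissues()]
  # venous outflow concentration of tissue T on the blood scale
  out_blood <- conc * r / kp[pbpk_tissues()]

  d <- stats::setNames(numeric(length(nms)), nms)
  d[["absorption"]] <- -drug$ka * state[["absorption"]]

  for (t in setdiff(pbpk_tissues(), c("liver", "lung"))) {
    d[[t]] <- q[[t]] * (c_art - out_blood[[t]])
  }

  q_portal <- sum(q[portal_tissues()])
  elim <- clearance$clu_int_total * drug$fup * conc[["liver"]] /
    kp[["liver"]]
  d[["liver"]] <- drug$ka * state[["absorption"]] +
    (q[["liver"]] - q_portal) * c_art +
    sum(q[portal_tissues()] * out_blood[portal_tissues()]) -
    q[["liver"]] * out_blood[["liver"]] - elim

  d[["venous"]] <- sum(q[systemic_tissues()] *
                         out_blood[systemic_tissues()]) +
    phys$q_residual * c_art - phys$cardiac_output * c_ven

  d[["lung"]] <- phys$cardiac_output * (c_ven - out_blood[["lung"]])
  d[["arterial"]] <- phys$cardiac_output *
    (out_blood[["lung"]] - c_art)
  d[["eliminated"]] <- elim
  d
}

#' System matrix of the (linear) PBPK model
#'
#' The model is linear and time-invariant, so the right-hand side is
#' `A %*% state`. The matrix is assembled by applying [pbpk_rhs()] to
#' unit basis vectors, which keeps the two representations identical by
#' construction.
#'
#' @inheritParams pbpk_rhs
#' @return The 15 x 15 system matrix (1/min).
#' @export
pbpk_matrix <- function(phys, drug, clearance = NULL) {
  if (is.null(clearance)) clearance <- build_clu_int(drug)
  nms <- pbpk_state_names()
  n <- length(nms)
  A <- matrix(0, n, n, dimnames = list(nms, nms))
  for (j in seq_len(n)) {
    e <- stats::setNames(numeric(n), nms)
    e[j] <- 1
    A[, j] <- pbpk_rhs(e, phys, drug, clearance)
  }
  A
}

# one-step RK4 propagator for x' = A x at step h:
# P = I + hA + (hA)^2/2 + (hA)^3/6 + (hA)^4/24
rk4_propagator <- function(A, h) {
  hA <- h * A
  n <- nrow(A)
  P <- diag(n) + hA
  term <- hA
  for (k in 2:4) {
    term <- term %*% hA / k
    P <- P + term
  }
  P
}

# binary (repeated-squaring) matrix power, k >= 0
mat_pow <- function(P, k) {
  n <- nrow(P)
  out <- diag(n)
  base <- P
  while (k > 0) {
    if (k %% 2 == 1) out <- out %*% base
    base <- base %*% base
    k <- k %/% 2
  }
  out
}

# snap event/sample times to integration-grid indices
snap_to_grid <- function(time_min, dt) {
  idx <- round(time_min / dt)
  off <- abs(time_min - idx * dt)
  if (any(off > dt / 2 + 1e-9))
    stop("time cannot be snapped to the integration grid", call. = FALSE)
  as.integer(idx)
}

# apply a dose event to a state vector; PO doses enter the absorption
# compartment scaled by Fa, IV doses enter the venous pool
apply_dose <- function(state, route, amount_ng, fa) {
  if (route == "po") {
    state[["absorption"]] <- state[["absorption"]] + fa * amount_ng
  } else {
    state[["venous"]] <- state[["venous"]] + amount_ng
  }
  state
}

#' Simulate a dosing regimen with fixed-step RK4
#'
#' Integrates the whole-body model on a uniform grid. Because the system
#' is linear and time-invariant, the classical RK4 update equals a
#' constant one-step propagator matrix, which is applied per step: the
#' trajectory is bit-for-bit the fixed-step RK4 solution. Dose events are
#' instantaneous state increments at grid-snapped times (snap tolerance
#' dt/2): oral doses add `Fa * dose` to the absorption compartment,
#' intravenous doses add the full dose to the venous pool.
#'
#' @param regimen a `dose_regimen`.
#' @param phys a `physiology_set`.
#' @param drug a `drug_parameters` object.
#' @param clearance optional precomputed `clearance_model`.
#' @param t_end_min simulation horizon (min); must not precede the last
#'   dose.
#' @param dt integration step (min); default 0.5.
#' @return A `pbpk_sim`: list with `time_min`, `amounts` (matrix, one
#'   named column per compartment incl. `eliminated`),
#'   `plasma_conc_ng_ml` (venous amount / venous volume / R),
#'   `input_ng` (cumulative amount entered into the system) and
#'   `absorbed_ng` (cumulative absorption-compartment outflow).
#' @export
pbpk_simulate <- function(regimen, phys = default_physiology(),
                          drug = default_drug_parameters(),
                          clearance = NULL, t_end_min, dt = 0.5) {
  stopifnot(inherits(regimen, "dose_regimen"))
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  if (t_end_min < max(regimen$time_min))
    stop("t_end_min precedes the last dose", call. = FALSE)
  if (is.null(clearance)) clearance <- build_clu_int(drug)

  nms <- pbpk_state_names()
  n_steps <- ceiling(t_end_min / dt - 1e-9)
  A <- pbpk_matrix(phys, drug, clearance)
  P <- rk4_propagator(A, dt)

  ev_idx <- snap_to_grid(regimen$time_min, dt)
  traj <- matrix(0, n_steps + 1L, length(nms),
                 dimnames = list(NULL, nms))
  input <- numeric(n_steps + 1L)
  x <- stats::setNames(numeric(length(nms)), nms)
  dosed <- 0
  for (i in 0:n_steps) {
    hit <- which(ev_idx == i)
    for (j in hit) {
      amt <- regimen$amount_ng[j]
      eff <- if (regimen$route[j] == "po") drug$fa * amt else amt
      x <- apply_dose(x, regimen$route[j], amt, drug$fa)
      dosed <- dosed + eff
    }
    traj[i + 1L, ] <- x
    input[i + 1L] <- dosed
    if (i < n_steps) x <- drop(P %*% x)
  }

  total_in <- max(input)
  if (any(!is.finite(traj))) {
    warning("non-finite amounts encountered; dt = ", dt,
            " min exceeds the stability limit of the explicit ",
            "integrator (reduce dt)")
    traj[!is.finite(traj)] <- 0
  }
  undershoot <- -min(0, min(traj))
  if (isTRUE(undershoot > 1e-9 * total_in)) {
    warning("negative amounts of up to ", signif(undershoot, 3),
            " ng were floored to zero (reduce dt)")
  }
  traj[traj < 0] <- 0

  structure(
    list(time_min = (0:n_steps) * dt,
         amounts = traj,
         plasma_conc_ng_ml = traj[, "venous"] / phys$venous_blood_volume /
           drug$blood_plasma_ratio,
         input_ng = input,
         absorbed_ng = input - traj[, "absorption"],
         dt = dt,
         regimen = regimen),
    class = "pbpk_sim")
}

#' Plasma concentrations at selected times (fast path)
#'
#' Identical to sampling [pbpk_simulate()] on its grid, but advances the
#' state between dose events and sampling times with binary powers of the
#' one-step RK4 propagator instead of storing the full trajectory. Used
#' by the fitting and cohort modules, where only a handful of sampling
#' times per simulation are needed.
#'
#' @inheritParams pbpk_simulate
#' @param times_min sampling times (min), snapped to the integration
#'   grid.
#' @return Numeric vector of plasma concentrations (ng/mL) at
#'   `times_min`.
#' @export
pbpk_plasma_at <- function(times_min, regimen, phys = default_physiology(),
                           drug = default_drug_parameters(),
                           clearance = NULL, dt = 0.5) {
  stopifnot(inherits(regimen, "dose_regimen"))
  if (is.null(clearance)) clearance <- build_clu_int(drug)
  A <- pbpk_matrix(phys, drug, clearance)
  P <- rk4_propagator(A, dt)
  nms <- pbpk_state_names()

  s_idx <- snap_to_grid(times_min, dt)
  e_idx <- snap_to_grid(regimen$time_min, dt)
  nodes <- sort(unique(c(0L, s_idx, e_idx)))

  x <- stats::setNames(numeric(length(nms)), nms)
  out <- stats::setNames(numeric(length(nodes)), as.character(nodes))
  cur <- 0L
  for (nd in nodes) {
    if (nd > cur) {
      x <- stats::setNames(drop(mat_pow(P, nd - cur) %*% x), nms)
      cur <- nd
    }
    hit <- which(e_idx == nd)
    for (j in hit) x <- apply_dose(x, regimen$route[j],
                                   regimen$amount_ng[j], drug$fa)
    out[as.character(nd)] <- x[["venous"]]
  }
  pmax(out[as.character(s_idx)], 0) / phys$venous_blood_volume /
    drug$blood_plasma_ratio
}

#' Step-size convergence check
#'
#' Repeats a simulation at half the step size and reports the maximum
#' deviation of the plasma curve on the coarse grid, relative to the peak
#' concentration of the fine solution. Flags the run when the deviation
#' exceeds 0.1%.
#'
#' @inheritParams pbpk_simulate
#' @return List with `dt`, `max_rel_dev` and `flagged`.
#' @export
convergence_check <- function(regimen, phys = default_physiology(),
                              drug = default_drug_parameters(),
                              clearance = NULL, t_end_min, dt = 0.5) {
  coarse <- pbpk_simulate(regimen, phys, drug, clearance, t_end_min, dt)
  fine <- pbpk_simulate(regimen, phys, drug, clearance, t_end_min, dt / 2)
  n <- length(coarse$time_min)
  fine_on_coarse <- fine$plasma_conc_ng_ml[seq(1L, by = 2L,
                                               length.out = n)]
  cmax <- max(fine$plasma_conc_ng_ml)
  dev <- if (cmax > 0) {
    max(abs(coarse$plasma_conc_ng_ml - fine_on_coarse)) / cmax
  } else 0
  list(dt = dt, max_rel_dev = dev, flagged = dev > 1e-3)
}

#' Convert a simulation to a concentration-time series
#'
#' @param sim a `pbpk_sim`.
#' @param subject_id,dose_mg metadata for the resulting series.
#' @param times_min optional subset of grid times to keep.
#' @return A `conc_time_series` of the simulated plasma curve.
#' @export
as_conc_series <- function(sim, subject_id = "sim",
                           dose_mg = sim$regimen$amount_ng[1] / 1e6,
                           times_min = NULL) {
  stopifnot(inherits(sim, "pbpk_sim"))
  t <- sim$time_min
  c <- sim$plasma_conc_ng_ml
  if (!is.null(times_min)) {
    keep <- match(times_min, t)
    if (anyNA(keep)) stop("requested times not on the simulation grid",
                          call. = FALSE)
    t <- t[keep]; c <- c[keep]
  }
  conc_time_series(subject_id, dose_mg, t, c)
}

#' @export
print.pbpk_sim <- function(x, ...) {
  cat("<pbpk_sim>", length(x$time_min), "grid points, dt =", x$dt,
      "min, horizon", max(x$time_min) / 60, "h\n")
  cat("  Cmax", signif(max(x$plasma_conc_ng_ml), 4), "ng/mL\n")
  invisible(x)
}
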