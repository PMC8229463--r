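# Synthetic clinical cohort generator: lognormal inter-individual
# variability on Fa and CLu,add, proportional-plus-additive residual
# error, and LLOQ censoring, over a Phase-1-style sampling design.

#' Specify a synthetic cohort design
#'
#' Defaults mirror a multiple-ascending-dose Phase-1 design: 8 subjects
#' per dose at 20/40/80 mg once daily, a standard rich sampling schedule,
#' lognormal inter-individual variability on Fa (CV 35%) and CLu,add
#' (CV 50%) echoing the dispersion of the per-subject estimates, 10%
#' proportional residual error and an LLOQ of 0.1 ng/mL.
#'
#' @param doses_mg dose groups (mg).
#' @param n_per_dose subjects per dose group.
#' @param days number of once-daily doses.
#' @param tau_h dosing interval (h).
#' @param sampling_h sampling times (h post dose); applied after the
#'   first dose and, for multi-day designs, also after the last dose.
#' @param iiv_cv named vector `c(fa = ..., clu_add = ...)` of lognormal
#'   coefficients of variation.
#' @param prop_cv proportional residual error CV.
#' @param add_sd additive residual error SD (ng/mL).
#' @param lloq lower limit of quantification (ng/mL); censored samples
#'   are dropped.
#' @return A validated `cohort_spec`.
#' @export
cohort_spec <- function(doses_mg = c(20, 40, 80), n_per_dose = 8L,
                        days = 1L, tau_h = 24,
                        sampling_h = c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8,
                                       12, 24),
                        iiv_cv = c(fa = 0.35, clu_add = 0.5),
                        prop_cv = 0.1, add_sd = 0, lloq = 0.1) {
  if (any(doses_mg <= 0)) stop("doses must be positive", call. = FALSE)
  if (n_per_dose < 1L) stop("n_per_dose must be >= 1", call. = FALSE)
  if (days < 1L) stop("days must be >= 1", call. = FALSE)
  if (!all(c("fa", "clu_add") %in% names(iiv_cv)))
    stop("iiv_cv needs elements 'fa' and 'clu_add'", call. = FALSE)
  if (any(iiv_cv < 0) || prop_cv < 0 || add_sd < 0)
    stop("variability magnitudes must be non-negative", call. = FALSE)
  if (any(sampling_h <= 0) || any(sampling_h > tau_h * days))
    stop("sampling times must lie in (0, tau_h * days]", call. = FALSE)
  if (lloq < 0) stop("lloq must be non-negative", call. = FALSE)
  structure(
    list(doses_mg = doses_mg, n_per_dose = as.integer(n_per_dose),
         days = as.integer(days), tau_h = tau_h, sampling_h = sampling_h,
         iiv_cv = iiv_cv, prop_cv = prop_cv, add_sd = add_sd,
         lloq = lloq),
    class = "cohort_spec")
}

# lognormal draws with a given arithmetic mean and CV
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a virtual clinical dataset
#'
#' For each virtual subject, draws Fa and CLu,add from lognormal
#' distributions around the nominal means, simulates the dosing regimen
#' with the whole-body model, samples the plasma curve at the scheduled
#' times, applies residual error
#' `C_obs = C * (1 + e_prop) + e_add` with
#' `e_prop ~ N(0, prop_cv^2)`, `e_add ~ N(0, add_sd^2)`, and drops
#' samples below the LLOQ (so no negative concentration survives).
#'
#' @param spec a `cohort_spec`.
#' @param phys a `physiology_set`.
#' @param drug_template a `drug_parameters` object supplying everything
#'   except the two varied parameters.
#' @param true_params list with nominal means `fa` and `clu_add`
#'   (mL/min); defaults to the pooled reference values (0.761 and
#'   12,900 mL/min).
#' @param seed integer seed; the generator is deterministic given the
#'   seed. The caller's RNG state is restored on exit.
#' @param dt integration step (min).
#' @return List with `series` (list of `conc_time_series`) and `truth`
#'   (data frame of the drawn per-subject parameters).
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            phys = default_physiology(),
                            drug_template = default_drug_parameters(),
                            true_params = list(fa = 0.761,
                                               clu_add = 12900),
                            seed = 1L, dt = 0.5) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }

  sample_min <- spec$sampling_h * 60
  if (spec$days > 1L) {
    sample_min <- sort(unique(c(sample_min,
                                (spec$days - 1L) * spec$tau_h * 60 +
                                  spec$sampling_h * 60)))
  }

  series <- list()
  truth <- NULL
  for (dose in spec$doses_mg) {
    fa_i <- rlnorm_mean_cv(spec$n_per_dose, true_params$fa,
                           spec$iiv_cv[["fa"]])
    cl_i <- rlnorm_mean_cv(spec$n_per_dose, true_params$clu_add,
                           spec$iiv_cv[["clu_add"]])
    regimen <- dose_regimen(dose, n_doses = spec$days,
                            tau_h = spec$tau_h)
    for (s in seq_len(spec$n_per_dose)) {
      id <- sprintf("D%g_S%02d", dose, s)
      d <- drug_template
      d$fa <- fa_i[s]
      d$clu_add <- cl_i[s]
      conc <- pbpk_plasma_at(sample_min, regimen, phys, d,
                             clearance = build_clu_int(d), dt = dt)
      e_prop <- stats::rnorm(length(conc), 0, spec$prop_cv)
      e_add <- stats::rnorm(length(conc), 0, spec$add_sd)
      obs <- conc * (1 + e_prop) + e_add
      keep <- obs >= spec$lloq
      if (sum(keep) > 0L) {
        series[[id]] <- conc_time_series(id, dose, sample_min[keep],
                                         obs[keep])
      }
      truth <- rbind(truth,
                     data.frame(subject_id = id, dose_mg = dose,
                                fa = fa_i[s], clu_add_ml_min = cl_i[s],
                                stringsAsFactors = FALSE))
    }
  }
  list(series = unname(series), truth = truth)
}
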