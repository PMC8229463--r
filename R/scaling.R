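# Interspecies and in-vitro-to-in-vivo scaling: absorption rate from
# permeability, allometric V_SS, Oie-Tozer volume arithmetic, the Kp scalar,
# extraction-ratio correction of eliminating-organ Kp, and IVIVE of
# recombinant-CYP kinetics to whole-liver Vmax.

#' Effective intestinal permeability from Caco-2 permeability
#'
#' Log-linear empirical correlation between in vitro Caco-2 apparent
#' permeability (nm/s) and in vivo human jejunal effective permeability
#' (um/s): `log10(Peff) = 0.4926 * log10(Papp) - 0.1454`.
#'
#' @param papp_nm_s apparent Caco-2 permeability in nm/s.
#' @return Effective permeability Peff in um/s.
#' @export
peff_from_papp <- function(papp_nm_s) {
  if (any(!is.finite(papp_nm_s) | papp_nm_s <= 0))
    stop("papp must be positive", call. = FALSE)
  10^(0.4926 * log10(papp_nm_s) - 0.1454)
}

#' Absorption rate constant from effective permeability
#'
#' Treats the human small intestine as a cylindrical tube: the first-order
#' absorption rate constant is `Ka = 2 * Peff / radius`, converted to
#' 1/min.
#'
#' @param peff_um_s effective permeability (um/s).
#' @param radius_cm intestinal radius (cm); default 1.75 cm.
#' @return Ka in 1/min.
#' @export
ka_from_peff <- function(peff_um_s, radius_cm = 1.75) {
  if (any(!is.finite(peff_um_s) | peff_um_s <= 0))
    stop("peff must be positive", call. = FALSE)
  if (any(!is.finite(radius_cm) | radius_cm <= 0))
    stop("radius must be positive", call. = FALSE)
  peff_cm_s <- peff_um_s * 1e-4
  2 * peff_cm_s / radius_cm * 60
}

#' Fit an allometric power law to preclinical V_SS data
#'
#' Fits `Vss_total(L) = a * BW^b` by ordinary least squares on the
#' log-log scale.
#'
#' @param points data frame with columns `bw_kg` and either `vss_l`
#'   (total litres) or `vss_l_per_kg` (per-kg values, multiplied by body
#'   weight internally); at least two distinct body weights.
#' @return An `allometric_fit` with elements `a` (L), `b`
#'   (dimensionless) and the input `points`.
#' @export
fit_allometric <- function(points = preclinical_vss()) {
  stopifnot(is.data.frame(points), "bw_kg" %in% names(points))
  vss <- points[["vss_l"]]
  if (is.null(vss)) {
    if (!"vss_l_per_kg" %in% names(points))
      stop("points need 'vss_l' or 'vss_l_per_kg'", call. = FALSE)
    vss <- points$vss_l_per_kg * points$bw_kg
  }
  if (any(points$bw_kg <= 0) || any(vss <= 0))
    stop("body weights and volumes must be positive", call. = FALSE)
  if (length(unique(points$bw_kg)) < 2L)
    stop("need at least 2 distinct body weights", call. = FALSE)
  fit <- stats::lm(log(vss) ~ log(points$bw_kg))
  structure(
    list(a = exp(unname(stats::coef(fit)[1])),
         b = unname(stats::coef(fit)[2]),
         points = data.frame(bw_kg = points$bw_kg, vss_l = vss)),
    class = "allometric_fit")
}

#' Predict total V_SS at a body weight from an allometric fit
#'
#' @param fit an `allometric_fit`, or a list with elements `a` and `b`
#'   (so the published coefficients can be used directly).
#' @param bw_kg body weight (kg).
#' @return Total steady-state volume of distribution in litres.
#' @export
predict_vss <- function(fit, bw_kg) {
  if (any(!is.finite(bw_kg) | bw_kg <= 0))
    stop("body weight must be positive", call. = FALSE)
  fit$a * bw_kg^fit$b
}

#' Erythrocyte-to-plasma partition coefficient
#'
#' `EP = 1 + (R - 1) / Hct`, from the blood-to-plasma concentration ratio
#' and hematocrit. EP below 1 (drug excluded from erythrocytes) is valid.
#'
#' @param r blood-to-plasma concentration ratio (> 0).
#' @param hct hematocrit, in (0, 1).
#' @return EP (dimensionless).
#' @export
erythrocyte_partition <- function(r, hct) {
  if (any(!is.finite(r) | r <= 0)) stop("R must be positive", call. = FALSE)
  if (any(!is.finite(hct) | hct <= 0 | hct >= 1))
    stop("hematocrit must lie in (0, 1)", call. = FALSE)
  1 + (r - 1) / hct
}

# blood-pool contribution Vp + Vrbc * EP, in mL
blood_vss_ml <- function(phys, r) {
  v_blood <- phys$venous_blood_volume + phys$arterial_blood_volume
  vp <- (1 - phys$hematocrit) * v_blood
  vrbc <- phys$hematocrit * v_blood
  ep <- erythrocyte_partition(r, phys$hematocrit)
  vp + vrbc * ep
}

#' Oie-Tozer steady-state volume of distribution
#'
#' `Vss = Vp + Vrbc * EP + sum(V_T * Kp_T)`. The plasma and erythrocyte
#' volumes are split from total blood volume (venous + arterial) by
#' hematocrit.
#'
#' @param phys a `physiology_set`.
#' @param kp_map named Kp vector covering all tissues.
#' @param r blood-to-plasma concentration ratio.
#' @return Total V_SS in litres.
#' @export
oie_tozer_vss <- function(phys, kp_map, r) {
  names(kp_map) <- canonical_tissue(names(kp_map))
  miss <- setdiff(pbpk_tissues(), names(kp_map))
  if (length(miss) > 0L)
    stop("kp_map lacks tissue(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tissue_ml <- sum(phys$tissues$volume_ml * kp_map[phys$tissues$name])
  (blood_vss_ml(phys, r) + tissue_ml) / 1000
}

#' Solve for the Kp scalar matching a target V_SS
#'
#' Closed form: `s = (Vss_target - Vp - Vrbc * EP) / sum(V_T * Kp_SS)`.
#' Scaling the rat Kp values by `s` makes [oie_tozer_vss()] reproduce the
#' target exactly.
#'
#' @param phys a `physiology_set`.
#' @param rat_kp named rat steady-state Kp vector.
#' @param r blood-to-plasma concentration ratio.
#' @param target_vss_l target total V_SS (L), at least the blood
#'   contribution.
#' @return The Kp scalar (dimensionless).
#' @export
solve_kp_scalar <- function(phys, rat_kp, r, target_vss_l) {
  names(rat_kp) <- canonical_tissue(names(rat_kp))
  blood_l <- blood_vss_ml(phys, r) / 1000
  if (target_vss_l < blood_l)
    stop("target V_SS (", target_vss_l, " L) is below the blood ",
         "contribution (", signif(blood_l, 6), " L)", call. = FALSE)
  tissue_l <- sum(phys$tissues$volume_ml * rat_kp[phys$tissues$name]) / 1000
  (target_vss_l - blood_l) / tissue_l
}

#' Scale a Kp map by a common scalar
#'
#' @param rat_kp named Kp vector.
#' @param scalar positive Kp scalar.
#' @return Element-wise `rat_kp * scalar` (full precision; round only for
#'   display).
#' @export
scale_kp <- function(rat_kp, scalar) {
  if (!is.finite(scalar) || scalar <= 0)
    stop("scalar must be positive", call. = FALSE)
  rat_kp * scalar
}

#' Correct the apparent Kp of an eliminating organ
#'
#' A steady-state AUC-ratio Kp measured in an eliminating organ
#' understates the equilibrium partition coefficient by the organ's
#' availability: `Kp_corrected = Kp_apparent / (1 - ER)`.
#'
#' @param kp_scaled apparent (scaled) Kp value(s).
#' @param er extraction ratio, in `[0, 1)`.
#' @return Corrected Kp.
#' @export
correct_eliminating_kp <- function(kp_scaled, er) {
  if (any(!is.finite(er) | er < 0 | er >= 1))
    stop("extraction ratio must lie in [0, 1)", call. = FALSE)
  kp_scaled / (1 - er)
}

#' Derive the human Kp map from rat steady-state values
#'
#' Runs the full distribution-scaling chain: scale every rat Kp by the Kp
#' scalar, then divide the Kp of each eliminating organ (by default the
#' liver only) by `1 - ER`.
#'
#' @param rat_kp named rat Kp vector (default [rat_kp_ss()]).
#' @param scalar Kp scalar.
#' @param er hepatic extraction ratio.
#' @param eliminating character vector of eliminating organs; default
#'   `"liver"`.
#' @return A `kp_derivation`: list with `kp_scaled`, `final_kp`,
#'   `scalar`, `er`.
#' @export
derive_human_kp <- function(rat_kp = rat_kp_ss(), scalar, er,
                            eliminating = "liver") {
  names(rat_kp) <- canonical_tissue(names(rat_kp))
  eliminating <- canonical_tissue(eliminating)
  kp_scaled <- scale_kp(rat_kp, scalar)
  final_kp <- kp_scaled
  final_kp[eliminating] <- correct_eliminating_kp(kp_scaled[eliminating], er)
  structure(list(rat_kp_ss = rat_kp, kp_scalar = scalar, er = er,
                 kp_scaled = kp_scaled, final_kp = final_kp,
                 eliminating = eliminating),
            class = "kp_derivation")
}

#' Inter-system extrapolation factor (ISEF)
#'
#' Ratio of a marker activity measured in pooled human liver microsomes to
#' the same activity reconstructed from the recombinant enzyme and the
#' microsomal CYP abundance:
#' `ISEF = HLM activity / (rCYP activity * abundance)`.
#'
#' @param hlm_activity marker activity in microsomes (pmol/min/mg protein).
#' @param rcyp_activity marker activity in the recombinant system
#'   (pmol/min/pmol P450).
#' @param cyp_abundance_pmol_mg CYP abundance (pmol P450/mg microsomal
#'   protein); note 0.079 nmol/mg = 79 pmol/mg.
#' @return ISEF (dimensionless), full precision.
#' @export
isef <- function(hlm_activity, rcyp_activity, cyp_abundance_pmol_mg) {
  vals <- c(hlm_activity, rcyp_activity, cyp_abundance_pmol_mg)
  if (any(!is.finite(vals) | vals <= 0))
    stop("all ISEF inputs must be positive", call. = FALSE)
  hlm_activity / (rcyp_activity * cyp_abundance_pmol_mg)
}

#' Scale recombinant-enzyme Vmax to the whole liver
#'
#' `Vmax(liver) = Vmax_per_pmol * ISEF * abundance * MPPGL * liver mass`,
#' with the result in nmol/min
#' (pmol/min/pmol x pmol/mg x mg/g x g = pmol/min; divided by 1000).
#'
#' @param vmax_pmol_min_pmol recombinant-system Vmax (pmol/min/pmol P450).
#' @param isef inter-system extrapolation factor.
#' @param cyp_abundance_pmol_mg CYP abundance (pmol/mg microsomal protein).
#' @param mppgl mg microsomal protein per g liver; default 39.79.
#' @param liver_mass_g liver mass in g (volume at unit density).
#' @return Whole-liver Vmax in nmol/min.
#' @export
liver_vmax <- function(vmax_pmol_min_pmol, isef, cyp_abundance_pmol_mg,
                       mppgl = 39.79, liver_mass_g = 1800) {
  vals <- c(isef, cyp_abundance_pmol_mg, mppgl, liver_mass_g)
  if (any(!is.finite(vals) | vals <= 0) || !is.finite(vmax_pmol_min_pmol) ||
      vmax_pmol_min_pmol < 0)
    stop("liver_vmax inputs must be positive (Vmax may be zero)",
         call. = FALSE)
  vmax_pmol_min_pmol * isef * cyp_abundance_pmol_mg * mppgl *
    liver_mass_g / 1000
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat("<allometric_fit> Vss(L) =", signif(x$a, 4), "* BW^",
      signif(x$b, 4), "\n")
  invisible(x)
}
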