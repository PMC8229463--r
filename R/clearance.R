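# Hepatic intrinsic clearance assembly, metabolic-pathway fractions, and
# well-stirred hepatic availability / oral bioavailability.

#' Assemble the unbound hepatic intrinsic clearance
#'
#' Each identified metabolic pathway contributes
#' `Vmax / (Km * fu_mic)` (mL/min; Km in uM equals nmol/mL, so no
#' molecular weight enters), and the additional clearance CLu,add covers
#' biliary excretion and miscellaneous pathways. The total is the sum of
#' all pathway clearances plus CLu,add; fractional contributions (%fm)
#' are each component divided by the total. The unbound liver fraction
#' `fu_li = fup / Kp_liver` is computed and retained for reporting.
#'
#' @param drug a `drug_parameters` object.
#' @return A `clearance_model`: list with `pathway_clints` (named,
#'   mL/min), `clu_add`, `clu_int_total` (mL/min), `fm` (named fractions
#'   incl. `clu_add`), `fu_li`.
#' @export
build_clu_int <- function(drug) {
  stopifnot(inherits(drug, "drug_parameters"))
  ep <- drug$enzyme_pathways
  if (drug$fu_mic <= 0) stop("fu_mic must be positive", call. = FALSE)
  if (any(ep$km_um <= 0)) stop("Km must be positive", call. = FALSE)
  clints <- ep$vmax_nmol_min / (ep$km_um * drug$fu_mic)
  names(clints) <- ep$label
  total <- sum(clints) + drug$clu_add
  if (total <= 0) stop("total intrinsic clearance is zero", call. = FALSE)
  fm <- c(clints, clu_add = drug$clu_add) / total
  structure(
    list(pathway_clints = clints,
         clu_add = drug$clu_add,
         clu_int_total = total,
         fm = fm,
         fu_li = drug$fup / drug$kp[["liver"]]),
    class = "clearance_model")
}

#' Well-stirred hepatic availability and extraction ratio
#'
#' `Fh = Q_LI * R / (Q_LI * R + fup * CLu_int)`, with the hepatic blood
#' flow expressed on the blood-concentration scale via the blood-to-plasma
#' ratio R; `ER = 1 - Fh`.
#'
#' @param clu_int total unbound intrinsic clearance (mL/min).
#' @param fup unbound fraction in plasma.
#' @param q_liver hepatic blood flow (mL/min).
#' @param r blood-to-plasma concentration ratio.
#' @return List with `fh` and `er`.
#' @export
hepatic_availability <- function(clu_int, fup, q_liver, r) {
  vals <- c(fup, q_liver, r)
  if (any(!is.finite(vals) | vals <= 0) || !is.finite(clu_int) ||
      clu_int < 0)
    stop("inputs must be positive (clu_int may be zero)", call. = FALSE)
  fh <- (q_liver * r) / (q_liver * r + fup * clu_int)
  list(fh = fh, er = 1 - fh)
}

#' Absolute oral bioavailability
#'
#' `F = Fa * Fg * Fh`. An `fa` above 1 (apparent fraction absorbed from
#' fitting) is allowed with a warning.
#'
#' @param fa fraction absorbed.
#' @param fg fraction escaping gut-wall extraction.
#' @param fh hepatic availability.
#' @return Total oral bioavailability (fraction).
#' @export
oral_bioavailability <- function(fa, fg, fh) {
  if (any(!is.finite(c(fa, fg, fh)) | c(fa, fg, fh) <= 0))
    stop("all factors must be positive", call. = FALSE)
  if (fa > 1) warning("fa = ", fa, " exceeds 1 (apparent fraction absorbed)")
  if (fg > 1 || fh > 1)
    stop("fg and fh must not exceed 1", call. = FALSE)
  fa * fg * fh
}

#' Full bioavailability decomposition for a parameter set
#'
#' Convenience wrapper: assembles the intrinsic clearance, evaluates the
#' well-stirred liver model against a physiology, and multiplies the three
#' availability factors.
#'
#' @param drug a `drug_parameters` object.
#' @param phys a `physiology_set`.
#' @return A `bioavailability_result`: list with `fa`, `fg`, `fh`, `er`,
#'   `f_total` and the underlying `clearance_model`.
#' @export
bioavailability <- function(drug = default_drug_parameters(),
                            phys = default_physiology()) {
  cl <- build_clu_int(drug)
  ha <- hepatic_availability(cl$clu_int_total, drug$fup,
                             tissue_flow(phys, "liver"),
                             drug$blood_plasma_ratio)
  f <- drug$fa * drug$fg * ha$fh
  structure(list(fa = drug$fa, fg = drug$fg, fh = ha$fh, er = ha$er,
                 f_total = f, clearance = cl),
            class = "bioavailability_result")
}

#' @export
print.clearance_model <- function(x, ...) {
  cat("<clearance_model> CLu,int total", signif(x$clu_int_total, 6),
      "mL/min\n")
  comp <- c(x$pathway_clints, clu_add = x$clu_add)
  for (nm in names(comp)) {
    cat(sprintf("  %-8s %10.1f mL/min  (%%fm %.3g%%)\n", nm, comp[[nm]],
                100 * x$fm[[nm]]))
  }
  cat("  fu,liver", signif(x$fu_li, 4), "\n")
  invisible(x)
}

#' @export
print.bioavailability_result <- function(x, ...) {
  cat(sprintf("<bioavailability> Fa %.3f x Fg %.3f x Fh %.3f = F %.3f (ER %.3f)\n",
              x$fa, x$fg, x$fh, x$f_total, x$er))
  invisible(x)
}
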