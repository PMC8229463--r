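# Drug-specific parameters: binding, absorption, distribution (Kp) and
# hepatic enzyme kinetics.

#' Construct and validate a drug parameter set
#'
#' @param fup unbound fraction in plasma, in (0, 1].
#' @param blood_plasma_ratio blood-to-plasma concentration ratio R (> 0).
#' @param ka first-order absorption rate constant (1/min).
#' @param fa fraction absorbed. Values above 1 are permitted (apparent Fa
#'   from fitting can exceed 1) but flagged with a warning.
#' @param fg fraction escaping gut-wall extraction; default 1.
#' @param fu_mic unbound fraction in the microsomal incubation, in (0, 1].
#' @param clu_add additional unbound hepatic intrinsic clearance (mL/min):
#'   biliary excretion plus miscellaneous pathways beyond the two
#'   identified oxidative ones.
#' @param enzyme_pathways data frame with columns `label`,
#'   `vmax_nmol_min`, `km_um` describing hepatic metabolite-formation
#'   kinetics (whole-liver Vmax in nmol/min; Km in uM).
#' @param kp named numeric vector of tissue-to-plasma partition
#'   coefficients covering all tissues of [pbpk_tissues()].
#' @param pka,logp physicochemical metadata (not used in the kinetics).
#'
#' @details Km in uM equals nmol/mL, so `vmax_nmol_min / km_um` is a
#'   clearance in mL/min without any molecular-weight conversion; this is
#'   what keeps the intrinsic-clearance assembly dimensionally closed.
#'
#' @return A validated `drug_parameters` object.
#' @export
drug_parameters <- function(fup, blood_plasma_ratio, ka, fa, fg = 1,
                            fu_mic, clu_add, enzyme_pathways, kp,
                            pka = NA_real_, logp = NA_real_) {
  chk_frac <- function(x, nm) {
    if (!is.finite(x) || x <= 0 || x > 1)
      stop(nm, " must lie in (0, 1], got ", x, call. = FALSE)
  }
  chk_pos <- function(x, nm) {
    if (!is.finite(x) || x <= 0)
      stop(nm, " must be positive, got ", x, call. = FALSE)
  }
  chk_frac(fup, "fup")
  chk_frac(fu_mic, "fu_mic")
  chk_pos(blood_plasma_ratio, "blood_plasma_ratio")
  chk_pos(ka, "ka")
  chk_pos(fa, "fa")
  if (fa > 1) warning("fa = ", fa, " exceeds 1 (apparent fraction absorbed)")
  chk_frac(fg, "fg")
  if (!is.finite(clu_add) || clu_add < 0)
    stop("clu_add must be non-negative (mL/min)", call. = FALSE)

  stopifnot(is.data.frame(enzyme_pathways))
  req <- c("label", "vmax_nmol_min", "km_um")
  if (!all(req %in% names(enzyme_pathways)))
    stop("enzyme_pathways needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (any(enzyme_pathways$km_um <= 0))
    stop("Km must be positive", call. = FALSE)
  if (any(enzyme_pathways$vmax_nmol_min < 0))
    stop("Vmax must be non-negative", call. = FALSE)

  names(kp) <- canonical_tissue(names(kp))
  miss <- setdiff(pbpk_tissues(), names(kp))
  if (length(miss) > 0L)
    stop("kp lacks tissue(s): ", paste(miss, collapse = ", "), call. = FALSE)
  kp <- kp[pbpk_tissues()]
  if (any(!is.finite(kp) | kp <= 0))
    stop("all Kp values must be positive", call. = FALSE)

  structure(
    list(fup = fup, blood_plasma_ratio = blood_plasma_ratio, ka = ka,
         fa = fa, fg = fg, fu_mic = fu_mic, clu_add = clu_add,
         enzyme_pathways = enzyme_pathways, kp = kp, pka = pka,
         logp = logp),
    class = "drug_parameters")
}

#' Built-in fexuprazan parameter set
#'
#' The reference human parameter set for fexuprazan: plasma unbound
#' fraction 0.0645, blood/plasma ratio 0.8, permeability-predicted
#' Ka 0.0606 per min, pooled fraction absorbed 0.761, microsomal unbound
#' fraction 0.904, pooled additional unbound intrinsic clearance
#' 12.9 L/min, CYP3A4-mediated M14 formation (Vmax 248 nmol/min,
#' Km 0.093 uM) and M11 formation (Vmax 800 nmol/min, Km 15.95 uM), and
#' the 11 human tissue partition coefficients obtained by scaling rat
#' steady-state values (with extraction-ratio correction for the liver).
#'
#' @return A `drug_parameters` object.
#' @export
default_drug_parameters <- function() {
  drug_parameters(
    fup = 0.0645,
    blood_plasma_ratio = 0.8,
    ka = 0.0606,
    fa = 0.761,
    fg = 1,
    fu_mic = 0.904,
    clu_add = 12900,   # 12.9 L/min
    enzyme_pathways = data.frame(
      label = c("M14", "M11"),
      vmax_nmol_min = c(248, 800),
      km_um = c(0.093, 15.95),
      stringsAsFactors = FALSE
    ),
    kp = c(adipose = 4.32, adrenal_gland = 20.8, brain = 1.32,
           heart = 4.60, kidney = 16.4, large_intestine = 40.8,
           liver = 303, lung = 87.6, small_intestine = 124,
           spleen = 17.8, stomach = 193),
    pka = 9.04, logp = 2.38
  )
}

#' Rat steady-state tissue-to-plasma partition coefficients
#'
#' Steady-state Kp values (AUC_tissue / AUC_plasma) for fexuprazan
#' measured in 11 major rat tissues; the starting point of the human Kp
#' scaling chain.
#'
#' @return Named numeric vector over [pbpk_tissues()].
#' @export
rat_kp_ss <- function() {
  c(adipose = 11.7, adrenal_gland = 56.1, brain = 3.55, heart = 12.4,
    kidney = 44.2, large_intestine = 110, liver = 417, lung = 236,
    small_intestine = 637, spleen = 47.9, stomach = 519)
}

#' Preclinical steady-state volumes of distribution
#'
#' Moment-analysis V_SS estimates from rat, monkey and dog used to fit the
#' allometric body-weight relationship.
#'
#' @return Data frame with columns `species`, `bw_kg`, `vss_l_per_kg`.
#' @export
preclinical_vss <- function() {
  data.frame(
    species = c("rat", "monkey", "dog"),
    bw_kg = c(0.25, 4, 10),
    vss_l_per_kg = c(20.2, 9.17, 12.6),
    stringsAsFactors = FALSE
  )
}

#' Read drug parameters from a YAML config (or build from a list)
#'
#' Clearances may be given as `clu_add` (mL/min) or `clu_add_l_min`
#' (L/min); everything is held in mL/min internally.
#'
#' @param source `NULL` for the built-in fexuprazan defaults, a YAML file
#'   path, or a list of fields as in [drug_parameters()].
#' @return A validated `drug_parameters` object.
#' @export
load_drug_parameters <- function(source = NULL) {
  if (is.null(source)) return(default_drug_parameters())
  if (is.character(source) && length(source) == 1L) {
    source <- yaml::read_yaml(source)
  }
  if (inherits(source, "drug_parameters")) return(source)
  stopifnot(is.list(source))
  # [[ with exact = TRUE semantics: partial matching of e.g. clu_add
  # against clu_add_l_min must not occur
  clu_add <- source[["clu_add"]]
  if (is.null(clu_add) && !is.null(source[["clu_add_l_min"]])) {
    clu_add <- 1000 * as.numeric(source[["clu_add_l_min"]])
  }
  ep <- source[["enzyme_pathways"]]
  if (!is.data.frame(ep)) {
    ep <- do.call(rbind, lapply(ep, function(p) {
      data.frame(label = p$label,
                 vmax_nmol_min = as.numeric(p$vmax_nmol_min),
                 km_um = as.numeric(p$km_um), stringsAsFactors = FALSE)
    }))
  }
  kp <- unlist(source[["kp"]])
  drug_parameters(
    fup = as.numeric(source[["fup"]]),
    blood_plasma_ratio = as.numeric(source[["blood_plasma_ratio"]]),
    ka = as.numeric(source[["ka"]]),
    fa = as.numeric(source[["fa"]]),
    fg = if (is.null(source[["fg"]])) 1 else as.numeric(source[["fg"]]),
    fu_mic = as.numeric(source[["fu_mic"]]),
    clu_add = as.numeric(clu_add),
    enzyme_pathways = ep,
    kp = kp,
    pka = if (is.null(source[["pka"]])) NA_real_
          else as.numeric(source[["pka"]]),
    logp = if (is.null(source[["logp"]])) NA_real_
           else as.numeric(source[["logp"]])
  )
}

#' Write drug parameters to a YAML config
#'
#' Round-trips losslessly through [load_drug_parameters()].
#'
#' @param drug a `drug_parameters` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_drug_parameters <- function(drug, path) {
  stopifnot(inherits(drug, "drug_parameters"))
  ep <- lapply(seq_len(nrow(drug$enzyme_pathways)), function(i) {
    list(label = drug$enzyme_pathways$label[i],
         vmax_nmol_min = drug$enzyme_pathways$vmax_nmol_min[i],
         km_um = drug$enzyme_pathways$km_um[i])
  })
  yaml::write_yaml(
    list(schema = "fexupbpk/drug/v1",
         fup = drug$fup,
         blood_plasma_ratio = drug$blood_plasma_ratio,
         ka = drug$ka, fa = drug$fa, fg = drug$fg,
         fu_mic = drug$fu_mic, clu_add = drug$clu_add,
         enzyme_pathways = ep,
         kp = as.list(drug$kp),
         pka = drug$pka, logp = drug$logp),
    path, precision = 15)
  invisible(path)
}

#' @export
print.drug_parameters <- function(x, ...) {
  cat("<drug_parameters> fup", x$fup, "R", x$blood_plasma_ratio,
      "Ka", x$ka, "/min Fa", x$fa, "\n")
  cat("  fu_mic", x$fu_mic, " CLu,add", x$clu_add, "mL/min\n")
  print(x$enzyme_pathways, ...)
  cat("  Kp:", paste(names(x$kp), signif(x$kp, 3), sep = "=",
                     collapse = ", "), "\n")
  invisible(x)
}
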