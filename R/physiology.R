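# Physiology container: tissue volumes and blood flows for the whole-body model.
#
# Internal unit system: volumes mL, flows mL/min, time min, amounts ng,
# concentrations ng/mL.

#' Canonical tissue labels of the whole-body model
#'
#' The 13-compartment model carries 11 tissue compartments plus venous and
#' arterial blood. Tissue labels are normalised to lower-case snake case.
#'
#' @return Character vector of the 11 tissue labels, in fixed order.
#' @export
pbpk_tissues <- function() {
  c("adipose", "adrenal_gland", "brain", "heart", "kidney",
    "large_intestine", "liver", "lung", "small_intestine", "spleen",
    "stomach")
}

# tissues whose venous outflow enters the portal vein and hence the liver
portal_tissues <- function() {
  c("stomach", "spleen", "small_intestine", "large_intestine")
}

# tissues draining directly into the venous pool (liver included: it drains
# via the hepatic vein)
systemic_tissues <- function() {
  c("adipose", "adrenal_gland", "brain", "heart", "kidney", "liver")
}

#' Normalise a tissue label
#'
#' Accepts labels such as "Adrenal gland" or "Small Intestine" and maps them
#' onto the canonical snake-case labels of [pbpk_tissues()].
#'
#' @param x character vector of tissue labels.
#' @return Canonical labels; errors on anything unrecognised.
#' @export
canonical_tissue <- function(x) {
  out <- gsub("[ -]+", "_", tolower(trimws(x)))
  bad <- setdiff(out, pbpk_tissues())
  if (length(bad) > 0L) {
    stop("unknown tissue label(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Reference human physiology
#'
#' Tissue volumes and blood flows for a representative 70-kg human with a
#' cardiac output of 5200 mL/min and a hematocrit of 0.45. Lung blood flow
#' equals cardiac output (the lung sits in series between the venous and
#' arterial pools). These defaults are the built-in physiological parameter
#' set of the model.
#'
#' @return A `physiology_set` object.
#' @export
default_physiology <- function() {
  tissues <- data.frame(
    name = pbpk_tissues(),
    volume_ml = c(15000, 14, 1400, 329, 308, 371, 1800, 532, 520, 182, 147),
    blood_flow_ml_min = c(270, 15.6, 593, 208, 910, 208, 1326, 5200, 520,
                          104, 52),
    stringsAsFactors = FALSE
  )
  tissues$drainage <- ifelse(
    tissues$name %in% portal_tissues(), "portal-to-liver",
    ifelse(tissues$name == "lung", "lung-series", "systemic-venous"))
  physiology_set(
    tissues = tissues,
    venous_blood_volume = 3470,
    arterial_blood_volume = 1730,
    cardiac_output = 5200,
    hematocrit = 0.45,
    body_weight = 70
  )
}

#' Construct and validate a physiology set
#'
#' @param tissues data frame with columns `name`, `volume_ml`,
#'   `blood_flow_ml_min` and optionally `drainage`; must contain all 11
#'   tissues of [pbpk_tissues()].
#' @param venous_blood_volume,arterial_blood_volume blood pool volumes (mL).
#' @param cardiac_output total cardiac output (mL/min).
#' @param hematocrit erythrocyte volume fraction of blood, in (0, 1).
#' @param body_weight body weight (kg); metadata used for per-kg reporting.
#'
#' @details The residual (rest-of-body) blood flow is computed as
#'   `Q_RE = Q_CO - sum(systemic tissue flows incl. liver)` and must be
#'   non-negative; it is modelled as a pure arterial-to-venous shunt. Portal
#'   flows (stomach, spleen, small and large intestine) must not exceed the
#'   total hepatic blood flow, and lung flow must equal cardiac output.
#'
#' @return A validated `physiology_set` with `q_residual` stored.
#' @export
physiology_set <- function(tissues, venous_blood_volume,
                           arterial_blood_volume, cardiac_output,
                           hematocrit, body_weight = 70) {
  stopifnot(is.data.frame(tissues))
  req <- c("name", "volume_ml", "blood_flow_ml_min")
  miss <- setdiff(req, names(tissues))
  if (length(miss) > 0L) {
    stop("tissue table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tissues$name <- canonical_tissue(tissues$name)
  missing_t <- setdiff(pbpk_tissues(), tissues$name)
  if (length(missing_t) > 0L) {
    stop("missing tissue(s): ", paste(missing_t, collapse = ", "),
         call. = FALSE)
  }
  tissues <- tissues[match(pbpk_tissues(), tissues$name), , drop = FALSE]
  rownames(tissues) <- NULL
  if (is.null(tissues$drainage)) {
    tissues$drainage <- ifelse(
      tissues$name %in% portal_tissues(), "portal-to-liver",
      ifelse(tissues$name == "lung", "lung-series", "systemic-venous"))
  }

  for (i in seq_len(nrow(tissues))) {
    if (!is.finite(tissues$volume_ml[i]) || tissues$volume_ml[i] <= 0) {
      stop("volume must be positive for tissue '", tissues$name[i], "'",
           call. = FALSE)
    }
    if (!is.finite(tissues$blood_flow_ml_min[i]) ||
        tissues$blood_flow_ml_min[i] < 0) {
      stop("blood flow must be non-negative for tissue '", tissues$name[i],
           "'", call. = FALSE)
    }
  }
  if (!is.finite(venous_blood_volume) || venous_blood_volume <= 0)
    stop("venous_blood_volume must be positive", call. = FALSE)
  if (!is.finite(arterial_blood_volume) || arterial_blood_volume <= 0)
    stop("arterial_blood_volume must be positive", call. = FALSE)
  if (!is.finite(cardiac_output) || cardiac_output <= 0)
    stop("cardiac_output must be positive", call. = FALSE)
  if (!is.finite(hematocrit) || hematocrit <= 0 || hematocrit >= 1)
    stop("hematocrit must lie in (0, 1)", call. = FALSE)
  if (!is.finite(body_weight) || body_weight <= 0)
    stop("body_weight must be positive", call. = FALSE)

  flow <- function(nm) tissues$blood_flow_ml_min[tissues$name == nm]
  q_sys <- sum(vapply(systemic_tissues(), flow, numeric(1)))
  q_re <- cardiac_output - q_sys
  if (q_re < 0) {
    stop("residual flow q_residual = Q_CO - systemic tissue flows is ",
         "negative (", signif(q_re, 6), " mL/min)", call. = FALSE)
  }
  q_portal <- sum(vapply(portal_tissues(), flow, numeric(1)))
  if (q_portal > flow("liver") + 1e-9) {
    stop("portal inflows (", q_portal, " mL/min) exceed liver blood flow (",
         flow("liver"), " mL/min)", call. = FALSE)
  }
  if (abs(flow("lung") - cardiac_output) > 1e-6 * cardiac_output) {
    stop("lung blood flow (", flow("lung"), ") must equal cardiac output (",
         cardiac_output, ")", call. = FALSE)
  }

  structure(
    list(tissues = tissues,
         venous_blood_volume = venous_blood_volume,
         arterial_blood_volume = arterial_blood_volume,
         cardiac_output = cardiac_output,
         hematocrit = hematocrit,
         body_weight = body_weight,
         q_residual = q_re),
    class = "physiology_set")
}

#' Read a physiology set from a YAML config (or build from a list)
#'
#' @param source `NULL` for the built-in default, a path to a YAML file, or
#'   a list with elements `tissues` (a list of `name`/`volume_ml`/
#'   `blood_flow_ml_min` entries or a data frame), `venous_blood_volume`,
#'   `arterial_blood_volume`, `cardiac_output`, `hematocrit`,
#'   `body_weight`.
#' @return A validated `physiology_set`.
#' @export
load_physiology <- function(source = NULL) {
  if (is.null(source)) return(default_physiology())
  if (is.character(source) && length(source) == 1L) {
    source <- yaml::read_yaml(source)
  }
  if (inherits(source, "physiology_set")) return(source)
  stopifnot(is.list(source))
  tissues <- source$tissues
  if (is.null(tissues)) stop("config lacks 'tissues'", call. = FALSE)
  if (!is.data.frame(tissues)) {
    tissues <- do.call(rbind, lapply(tissues, function(t) {
      data.frame(name = t$name,
                 volume_ml = as.numeric(t$volume_ml),
                 blood_flow_ml_min = as.numeric(t$blood_flow_ml_min),
                 stringsAsFactors = FALSE)
    }))
  }
  physiology_set(
    tissues = tissues,
    venous_blood_volume = as.numeric(source$venous_blood_volume),
    arterial_blood_volume = as.numeric(source$arterial_blood_volume),
    cardiac_output = as.numeric(source$cardiac_output),
    hematocrit = as.numeric(source$hematocrit),
    body_weight = if (is.null(source$body_weight)) 70
                  else as.numeric(source$body_weight)
  )
}

#' Write a physiology set to a YAML config
#'
#' Round-trips losslessly through [load_physiology()].
#'
#' @param phys a `physiology_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_physiology <- function(phys, path) {
  stopifnot(inherits(phys, "physiology_set"))
  tl <- lapply(seq_len(nrow(phys$tissues)), function(i) {
    list(name = phys$tissues$name[i],
         volume_ml = phys$tissues$volume_ml[i],
         blood_flow_ml_min = phys$tissues$blood_flow_ml_min[i])
  })
  yaml::write_yaml(
    list(schema = "fexupbpk/physiology/v1",
         tissues = tl,
         venous_blood_volume = phys$venous_blood_volume,
         arterial_blood_volume = phys$arterial_blood_volume,
         cardiac_output = phys$cardiac_output,
         hematocrit = phys$hematocrit,
         body_weight = phys$body_weight),
    path, precision = 15)
  invisible(path)
}

# internal accessors -------------------------------------------------------

tissue_volume <- function(phys, name) {
  phys$tissues$volume_ml[phys$tissues$name == name]
}

tissue_flow <- function(phys, name) {
  phys$tissues$blood_flow_ml_min[phys$tissues$name == name]
}

#' @export
print.physiology_set <- function(x, ...) {
  cat("<physiology_set> body weight", x$body_weight, "kg, cardiac output",
      x$cardiac_output, "mL/min, Hct", x$hematocrit, "\n")
  cat("  residual (shunt) flow:", signif(x$q_residual, 6), "mL/min\n")
  print(x$tissues, ...)
  invisible(x)
}
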