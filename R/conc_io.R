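# Subject-level concentration-time records and their delimited-text I/O.

#' Construct a concentration-time series for one subject
#'
#' @param subject_id subject identifier (coerced to character).
#' @param dose_mg administered dose (mg).
#' @param times_min sampling times (min), sorted ascending.
#' @param conc_ng_ml plasma concentrations (ng/mL), non-negative.
#' @param day occasion metadata (dosing day index); default 1.
#' @return A `conc_time_series` object.
#' @export
conc_time_series <- function(subject_id, dose_mg, times_min, conc_ng_ml,
                             day = 1L) {
  stopifnot(length(times_min) == length(conc_ng_ml))
  if (length(times_min) > 0L) {
    if (any(!is.finite(times_min)) || any(!is.finite(conc_ng_ml)))
      stop("times and concentrations must be finite", call. = FALSE)
    if (is.unsorted(times_min, strictly = TRUE))
      stop("times must be strictly increasing", call. = FALSE)
    if (any(conc_ng_ml < 0))
      stop("concentrations must be non-negative", call. = FALSE)
  }
  if (!is.finite(dose_mg) || dose_mg <= 0)
    stop("dose_mg must be positive", call. = FALSE)
  structure(
    list(subject_id = as.character(subject_id), dose_mg = dose_mg,
         times_min = as.numeric(times_min),
         conc_ng_ml = as.numeric(conc_ng_ml), day = as.integer(day)),
    class = "conc_time_series")
}

#' Read subject concentration-time data from CSV
#'
#' Expects a comma-delimited file with header
#' `subject_id,dose_mg,time_min,conc_ng_per_ml`. Rows are grouped by
#' subject (in order of first appearance); times within a subject must be
#' strictly increasing.
#'
#' @param path input CSV path.
#' @return A list of `conc_time_series`, one per subject.
#' @export
read_conc_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  req <- c("subject_id", "dose_mg", "time_min", "conc_ng_per_ml")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L)
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in c("dose_mg", "time_min", "conc_ng_per_ml")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L)
      stop("unparseable number in column '", col, "' at data row ", bad[1],
           call. = FALSE)
    df[[col]] <- v
  }
  ids <- unique(df$subject_id)
  lapply(ids, function(id) {
    sub <- df[df$subject_id == id, , drop = FALSE]
    if (is.unsorted(sub$time_min, strictly = TRUE)) {
      i <- which(diff(sub$time_min) <= 0)[1]
      row <- which(df$subject_id == id)[i + 1L]
      stop("times not strictly increasing for subject '", id,
           "' at data row ", row, call. = FALSE)
    }
    conc_time_series(id, sub$dose_mg[1], sub$time_min, sub$conc_ng_per_ml)
  })
}

#' Write subject concentration-time data to CSV
#'
#' Inverse of [read_conc_table()]: writing then reading reproduces the
#' numeric values to full precision.
#'
#' @param series a `conc_time_series` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_conc_table <- function(series, path) {
  if (inherits(series, "conc_time_series")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(s) {
    data.frame(subject_id = s$subject_id, dose_mg = s$dose_mg,
               time_min = s$times_min, conc_ng_per_ml = s$conc_ng_ml,
               stringsAsFactors = FALSE)
  }))
  old <- options(digits = 15)
  on.exit(options(old))
  utils::write.csv(format(rows, digits = 15, scientific = FALSE,
                          trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.conc_time_series <- function(x, ...) {
  cat("<conc_time_series> subject", x$subject_id, "dose", x$dose_mg,
      "mg,", length(x$times_min), "points\n")
  invisible(x)
}

#' Ordered dosing schedule
#'
#' @param dose_mg dose per administration (mg).
#' @param n_doses number of doses.
#' @param tau_h dosing interval (h) for repeated dosing.
#' @param route `"po"` (oral) or `"iv"` (venous bolus).
#' @param start_h time of the first dose (h).
#' @return A `dose_regimen`: data frame of events with columns `time_min`,
#'   `route`, `amount_ng` (1 mg = 1e6 ng).
#' @export
dose_regimen <- function(dose_mg, n_doses = 1L, tau_h = 24, route = "po",
                         start_h = 0) {
  route <- match.arg(tolower(route), c("po", "iv"))
  if (!is.finite(dose_mg) || dose_mg <= 0)
    stop("dose_mg must be positive", call. = FALSE)
  if (n_doses < 1L) stop("n_doses must be >= 1", call. = FALSE)
  if (n_doses > 1L && tau_h <= 0)
    stop("tau_h must be positive for repeated dosing", call. = FALSE)
  times_min <- (start_h + (seq_len(n_doses) - 1L) * tau_h) * 60
  regimen_events(data.frame(time_min = times_min, route = route,
                            amount_ng = dose_mg * 1e6,
                            stringsAsFactors = FALSE))
}

#' Build a dose regimen from explicit events
#'
#' @param events data frame with columns `time_min`, `route`
#'   (`"po"`/`"iv"`) and `amount_ng`.
#' @return A validated `dose_regimen`.
#' @export
regimen_events <- function(events) {
  stopifnot(is.data.frame(events),
            all(c("time_min", "route", "amount_ng") %in% names(events)))
  events <- events[order(events$time_min), , drop = FALSE]
  rownames(events) <- NULL
  if (any(events$time_min < 0))
    stop("dose times must be non-negative", call. = FALSE)
  if (any(duplicated(events$time_min)))
    stop("dose times must be strictly increasing", call. = FALSE)
  if (any(events$amount_ng <= 0))
    stop("dose amounts must be positive", call. = FALSE)
  if (!all(events$route %in% c("po", "iv")))
    stop("route must be 'po' or 'iv'", call. = FALSE)
  structure(events, class = c("dose_regimen", "data.frame"))
}
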