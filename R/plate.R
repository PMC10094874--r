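#' Assemble a serial-dilution dose-response plate
#'
#' One plate holds the raw readout of a dilution series: a concentration, a
#' response and a replicate identifier per well. Concentrations are converted
#' to g/L at the boundary. The response axis is the percent of the untreated
#' signal remaining (100 near zero dose, falling toward 0 at full
#' inhibition), which is the axis the four-parameter logistic in
#' [fit_dose_response()] is parameterized on.
#'
#' @param concentration numeric vector of well concentrations, in `unit`.
#' @param response numeric vector of responses (percent scale).
#' @param replicate replicate identifiers, recycled to the number of wells.
#' @param unit concentration unit; see [parse_concentration()].
#' @param max_tested_concentration highest concentration tested, in `unit`;
#'   defaults to the largest well concentration. Used to right-censor fitted
#'   potencies that extrapolate beyond the tested range.
#' @param dilution_note free text describing the dilution scheme.
#' @return an object of class `dose_response_plate`: `points` (data.frame
#'   `concentration` g/L, `response`, `replicate`), `max_tested_concentration`
#'   (g/L), `dilution_note`.
#' @export
dose_response_plate <- function(concentration, response, replicate = 1L,
                                unit = "g/L", max_tested_concentration = NULL,
                                dilution_note = NA_character_) {
  conc <- parse_concentration(concentration, unit)
  if (!is.numeric(response) || length(response) != length(conc)) {
    abort_input("response must be numeric and match concentration in length")
  }
  if (any(!is.finite(response))) abort_input("responses must be finite")
  replicate <- rep_len(replicate, length(conc))
  max_c <- if (is.null(max_tested_concentration)) {
    max(conc)
  } else {
    parse_concentration(max_tested_concentration, unit)
  }
  if (max_c < max(conc)) {
    abort_domain("max_tested_concentration is below a well concentration")
  }
  structure(
    list(
      points = data.frame(
        concentration = conc,
        response = response,
        replicate = as.character(replicate),
        stringsAsFactors = FALSE
      ),
      max_tested_concentration = max_c,
      dilution_note = dilution_note
    ),
    class = "dose_response_plate"
  )
}

#' @export
print.dose_response_plate <- function(x, ...) {
  cat(sprintf(
    "<dose_response_plate> %d wells, %d distinct concentrations (max tested %.4g g/L)\n",
    nrow(x$points), length(unique(x$points$concentration)), x$max_tested_concentration
  ))
  invisible(x)
}

#' Read a plate CSV
#'
#' Expects a UTF-8, comma-separated file with header
#' `concentration,unit,response_pct,replicate`, one row per well; units may
#' differ between rows and are canonicalized to g/L.
#'
#' @param path path to the CSV file.
#' @return a [dose_response_plate()].
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("plate file not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  needed <- c("concentration", "unit", "response_pct", "replicate")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    abort_format(sprintf("plate CSV is missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  if (nrow(raw) == 0L) abort_input("plate CSV contains no wells")
  conc <- mapply(function(v, u, i) {
    val <- suppressWarnings(as.numeric(v))
    if (is.na(val)) abort_format(sprintf("row %d: unparseable concentration '%s'", i, v))
    parse_concentration(val, u)
  }, raw$concentration, raw$unit, seq_len(nrow(raw)))
  resp <- suppressWarnings(as.numeric(raw$response_pct))
  if (any(is.na(resp))) {
    abort_format(sprintf("row %d: unparseable response", which(is.na(resp))[1]))
  }
  dose_response_plate(conc, resp, replicate = raw$replicate, unit = "g/L")
}
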