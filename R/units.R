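#' Convert a mass concentration to the canonical g/L
#'
#' All potency arithmetic inside the package runs on concentrations in grams
#' per liter; every other unit is converted once, at the boundary. Unit tokens
#' are matched case- and whitespace-insensitively and the micro sign may be
#' written as `u` (so `"ug/ml"`, `"µg/mL"` and `" Ug / mL "` are all the
#' microgram-per-milliliter unit).
#'
#' @param value numeric vector of strictly positive concentrations.
#' @param unit a single unit token, one of `"µg/mL"`, `"mg/L"`, `"mg/mL"`,
#'   `"g/L"` (aliases as described above). `µg/mL` and `mg/L` are the same
#'   scale (x 1e-3); `mg/mL` and `g/L` are the same scale (x 1).
#' @return numeric vector of concentrations in g/L.
#' @examples
#' parse_concentration(1, "µg/mL") # 0.001 g/L
#' parse_concentration(10.02, "ug/ml") # 0.01002 g/L
#' @export
parse_concentration <- function(value, unit) {
  if (!is.numeric(value) || length(value) == 0L) {
    abort_domain("concentration value must be numeric")
  }
  if (any(!is.finite(value)) || any(value <= 0)) {
    abort_domain("concentration values must be finite and > 0")
  }
  value * concentration_factor(unit)
}

concentration_factor <- function(unit) {
  u <- normalize_unit_token(unit)
  factor <- c("ug/ml" = 1e-3, "mg/l" = 1e-3, "mg/ml" = 1, "g/l" = 1)[u]
  if (is.na(factor)) {
    abort_format(sprintf(
      "unknown concentration unit '%s' (expected one of ug/mL, mg/L, mg/mL, g/L)",
      as.character(unit)
    ))
  }
  unname(factor)
}

#' Convert a solid mass to the canonical grams
#'
#' @param value numeric vector of non-negative masses.
#' @param unit `"g"` or `"mg"` (case/whitespace tolerant).
#' @return numeric vector of masses in g.
#' @export
parse_mass <- function(value, unit) {
  if (!is.numeric(value) || length(value) == 0L) {
    abort_domain("mass value must be numeric")
  }
  if (any(!is.finite(value)) || any(value < 0)) {
    abort_domain("mass values must be finite and >= 0")
  }
  u <- normalize_unit_token(unit)
  factor <- c(g = 1, mg = 1e-3)[u]
  if (is.na(factor)) {
    abort_format(sprintf("unknown mass unit '%s' (expected g or mg)", as.character(unit)))
  }
  value * unname(factor)
}

normalize_unit_token <- function(unit) {
  if (length(unit) != 1L || is.na(unit)) abort_format("unit token must be a single string")
  u <- tolower(gsub("[[:space:]]+", "", enc2utf8(as.character(unit))))
  # micro sign U+00B5 and Greek mu U+03BC both collapse to "u"
  gsub("µ|μ", "u", u)
}
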