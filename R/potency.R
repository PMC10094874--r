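#' Convert an IC50 to the half-maximal effective dilution volume (EDV50)
#'
#' The EDV50 is the reciprocal of the half-maximal (inhibitory or effective)
#' concentration: the number of liters into which one gram of material can be
#' diluted while still eliciting half-maximal activity. Unlike IC50 it
#' *increases* with potency, which makes it the natural axis for
#' bioactivity-guided fractionation: an extract with an IC50 of 1 ug/mL
#' (1e-3 g/L) has an EDV50 of 1000 L/g.
#'
#' @param ic50 numeric vector of IC50 values in g/L, strictly positive.
#' @return numeric vector of EDV50 values in L/g.
#' @seealso [edv50_to_ic50()] for the exact inverse, [parse_concentration()]
#'   for unit conversion into g/L.
#' @examples
#' ic50_to_edv50(parse_concentration(1, "ug/mL")) # 1000 L/g
#' ic50_to_edv50(parse_concentration(10.02, "ug/mL")) # 99.80 L/g
#' @export
ic50_to_edv50 <- function(ic50) {
  if (!is.numeric(ic50) || length(ic50) == 0L) abort_domain("ic50 must be numeric")
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) abort_domain("ic50 must be finite and > 0")
  1 / ic50
}

#' Convert an EDV50 back to an IC50
#'
#' Exact inverse of [ic50_to_edv50()]; the round trip is an identity up to
#' floating-point reciprocal error.
#'
#' @param edv50 numeric vector of dilution volumes in L/g, strictly positive.
#' @return numeric vector of IC50 values in g/L.
#' @export
edv50_to_ic50 <- function(edv50) {
  if (!is.numeric(edv50) || length(edv50) == 0L) abort_domain("edv50 must be numeric")
  if (any(!is.finite(edv50)) || any(edv50 <= 0)) abort_domain("edv50 must be finite and > 0")
  1 / edv50
}

#' Construct a potency estimate
#'
#' A `potency_estimate` stores one assayed potency in canonical units (IC50 in
#' g/L) together with its uncertainty, replicate count, censoring status and a
#' free-text assay label. The EDV50 view (L/g) is derived on construction and
#' is always the exact reciprocal of the stored IC50.
#'
#' @param ic50 the half-maximal concentration, in `unit`.
#' @param unit concentration unit of `ic50` (and `ic50_sd`); see
#'   [parse_concentration()]. Default `"g/L"`.
#' @param ic50_sd standard deviation of `ic50`, same unit; `NA` when unknown.
#' @param n_replicates number of assay replicates behind the estimate, or `NA`.
#' @param censored `"none"`, or `"right"` when the IC50 exceeds the highest
#'   concentration tested so only a lower bound on IC50 (upper bound on EDV50)
#'   is known.
#' @param assay_label free text describing the readout (e.g.
#'   `"NO inhibition, LPS+IFN-g RAW264.7"`).
#' @param sd_source free text recording how `ic50_sd` was obtained
#'   (replicate spread vs. fit standard error); kept because published tables
#'   rarely say.
#' @return an object of class `potency_estimate` with elements `ic50`
#'   (g/L), `ic50_sd` (g/L or `NA`), `edv50` (L/g), `n_replicates`,
#'   `censored`, `assay_label`, `sd_source`.
#' @examples
#' p <- potency_estimate(10.02, "ug/mL", ic50_sd = 3.13)
#' p$edv50 # 99.80... L/g
#' @export
potency_estimate <- function(ic50, unit = "g/L", ic50_sd = NA_real_,
                             n_replicates = NA_integer_,
                             censored = c("none", "right"),
                             assay_label = NA_character_,
                             sd_source = NA_character_) {
  censored <- match.arg(censored)
  ic50_gl <- parse_concentration(ic50, unit)
  if (length(ic50_gl) != 1L) abort_domain("a potency estimate holds a single ic50")
  sd_gl <- NA_real_
  if (!is_blank(ic50_sd)) {
    if (!is.numeric(ic50_sd) || ic50_sd < 0) abort_domain("ic50_sd must be >= 0")
    sd_gl <- ic50_sd * concentration_factor(unit)
  }
  structure(
    list(
      ic50 = ic50_gl,
      ic50_sd = sd_gl,
      edv50 = 1 / ic50_gl,
      n_replicates = if (is_blank(n_replicates)) NA_integer_ else as.integer(n_replicates),
      censored = censored,
      assay_label = if (is_blank(assay_label)) NA_character_ else as.character(assay_label),
      sd_source = if (is_blank(sd_source)) NA_character_ else as.character(sd_source)
    ),
    class = "potency_estimate"
  )
}

#' @export
print.potency_estimate <- function(x, ...) {
  cat(sprintf(
    "<potency_estimate> IC50 %.6g g/L (EDV50 %.6g L/g)%s%s\n",
    x$ic50, x$edv50,
    if (!is.na(x$ic50_sd)) sprintf(" +/- %.3g g/L", x$ic50_sd) else "",
    if (x$censored == "right") " [right-censored: above highest tested concentration]" else ""
  ))
  if (!is.na(x$assay_label)) cat("  assay:", x$assay_label, "\n")
  invisible(x)
}

is_censored <- function(p) inherits(p, "potency_estimate") && identical(p$censored, "right")

#' Propagate IC50 uncertainty onto the EDV50 scale
#'
#' The EDV50 is a reciprocal, so its standard deviation is obtained from the
#' IC50 standard deviation by the delta method, `sd(EDV50) = sd(IC50) /
#' IC50^2`. A Monte-Carlo alternative resamples the IC50 from a
#' moment-matched lognormal (IC50 is a positive, typically right-skewed
#' quantity) and takes the empirical standard deviation of the reciprocal
#' draws. For small coefficients of variation the two agree; the reciprocal
#' is convex, so as the CV grows the Monte-Carlo spread exceeds the
#' linearized one and the result is flagged divergent.
#'
#' @param p a [potency_estimate()] carrying `ic50_sd`.
#' @param method `"delta"` (default, deterministic) or `"both"` to also run
#'   the Monte-Carlo check.
#' @param n_draws number of lognormal draws for `method = "both"`.
#' @param seed RNG seed, required when `method = "both"`.
#' @param divergence_tol relative disagreement between Monte-Carlo and delta
#'   beyond which the estimate is flagged divergent; default 0.15.
#' @return an object of class `edv50_uncertainty`: `available` (FALSE with a
#'   `reason` when `p` carries no `ic50_sd` -- explicitly not zero),
#'   `edv50_sd` (delta-method value, L/g), `cv` of the IC50, and when
#'   Monte-Carlo was run `mc_edv50_sd`, `n_draws`, `seed`, `divergent`.
#' @examples
#' p <- potency_estimate(10.02, "ug/mL", ic50_sd = 3.13)
#' potency_uncertainty_to_edv50(p)$edv50_sd # ~31.18 L/g
#' @export
potency_uncertainty_to_edv50 <- function(p, method = c("delta", "both"),
                                         n_draws = 10000L, seed = NULL,
                                         divergence_tol = 0.15) {
  method <- match.arg(method)
  if (!inherits(p, "potency_estimate")) abort_input("p must be a potency_estimate")
  if (is.na(p$ic50_sd)) {
    return(structure(
      list(available = FALSE,
           reason = "no ic50_sd recorded on this potency estimate",
           edv50_sd = NA_real_),
      class = "edv50_uncertainty"
    ))
  }
  delta_sd <- p$ic50_sd / p$ic50^2
  cv <- p$ic50_sd / p$ic50
  out <- list(available = TRUE, edv50_sd = delta_sd, cv = cv, method = method)
  if (method == "both") {
    if (is.null(seed)) abort_domain("Monte-Carlo propagation requires a caller-supplied seed")
    sdlog <- sqrt(log1p(cv^2))
    meanlog <- log(p$ic50) - sdlog^2 / 2
    draws <- with_seed(seed, stats::rlnorm(n_draws, meanlog = meanlog, sdlog = sdlog))
    mc_sd <- stats::sd(1 / draws)
    out$mc_edv50_sd <- mc_sd
    out$n_draws <- as.integer(n_draws)
    out$seed <- as.integer(seed)
    out$divergent <- abs(mc_sd - delta_sd) / delta_sd > divergence_tol
  }
  structure(out, class = "edv50_uncertainty")
}

#' @export
print.edv50_uncertainty <- function(x, ...) {
  if (!x$available) {
    cat("<edv50_uncertainty> not available:", x$reason, "\n")
  } else {
    cat(sprintf("<edv50_uncertainty> delta-method sd %.4g L/g (cv %.3g)", x$edv50_sd, x$cv))
    if (!is.null(x$mc_edv50_sd)) {
      cat(sprintf("; Monte-Carlo sd %.4g L/g over %d draws%s",
                  x$mc_edv50_sd, x$n_draws,
                  if (isTRUE(x$divergent)) " [DIVERGENT from delta method]" else ""))
    }
    cat("\n")
  }
  invisible(x)
}
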