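#' Define a ground-truth compound for simulation
#'
#' @param id unique token.
#' @param true_ic50 the compound's true IC50 in g/L.
#' @param mass solid mass present, g.
#' @return an object of class `true_compound`.
#' @export
true_compound <- function(id, true_ic50, mass) {
  if (is_blank(id)) abort_input("true_compound requires an id")
  if (!is.numeric(true_ic50) || true_ic50 <= 0) abort_domain("true_ic50 must be > 0")
  if (!is.numeric(mass) || mass < 0) abort_domain("mass must be >= 0")
  structure(list(id = as.character(id), true_ic50 = true_ic50, mass = mass),
            class = "true_compound")
}

#' Specify a mixture of compounds with an optional synergy factor
#'
#' @param compounds list of [true_compound()]s.
#' @param mass_fractions optional numeric vector summing to 1; defaults to
#'   the compounds' masses normalized.
#' @param synergy_factor dimensionless `s >= -1`; 0 is exact dose
#'   additivity, positive values make the mixture more potent than additive
#'   (synergy), negative values less (antagonism).
#' @param loss_fraction fraction of material lost per split step (used by
#'   [simulate_fractionation()]), in `[0, 1)`.
#' @return an object of class `mixture_spec`.
#' @export
mixture_spec <- function(compounds, mass_fractions = NULL, synergy_factor = 0,
                         loss_fraction = 0) {
  if (!is.list(compounds) || !length(compounds) ||
      !all(vapply(compounds, inherits, TRUE, "true_compound"))) {
    abort_input("compounds must be a non-empty list of true_compound objects")
  }
  if (is.null(mass_fractions)) {
    masses <- vapply(compounds, `[[`, 0, "mass")
    if (sum(masses) <= 0) abort_domain("total compound mass must be > 0 to derive mass fractions")
    mass_fractions <- masses / sum(masses)
  }
  if (length(mass_fractions) != length(compounds)) {
    abort_input("mass_fractions must match compounds in length")
  }
  if (abs(sum(mass_fractions) - 1) > 1e-9) {
    abort_domain("mass fractions must sum to 1 (tolerance 1e-9)")
  }
  if (!is.numeric(synergy_factor) || synergy_factor < -1) {
    abort_domain("synergy_factor must be >= -1")
  }
  if (!is.numeric(loss_fraction) || loss_fraction < 0 || loss_fraction >= 1) {
    abort_domain("loss_fraction must be in [0, 1)")
  }
  structure(
    list(compounds = compounds, mass_fractions = as.numeric(mass_fractions),
         synergy_factor = synergy_factor, loss_fraction = loss_fraction),
    class = "mixture_spec"
  )
}

#' Potency of a mixture under dose additivity
#'
#' Mass-fraction-weighted EDV50 (Loewe-style dose addition), scaled by the
#' synergy factor: `EDV50(mix) = (1 + s) * sum_i w_i * EDV50(i)`. Dose
#' addition is the unique mixture rule under which total bioactivity is
#' exactly conserved when a mixture is split into parts -- which is what
#' makes "the components are merely additive" an operationally testable
#' statement in this framework.
#'
#' @param spec a [mixture_spec()].
#' @return a [potency_estimate()] for the mixture.
#' @examples
#' a <- true_compound("a", true_ic50 = 0.01, mass = 1) # EDV50 100 L/g
#' b <- true_compound("b", true_ic50 = 1e9, mass = 1) # inert diluent
#' mixture_potency(mixture_spec(list(a, b)))$edv50 # 50 L/g
#' @export
mixture_potency <- function(spec) {
  if (!inherits(spec, "mixture_spec")) abort_input("spec must be a mixture_spec")
  edv <- vapply(spec$compounds, function(cp) 1 / cp$true_ic50, 0)
  mix_edv <- (1 + spec$synergy_factor) * sum(spec$mass_fractions * edv)
  if (mix_edv <= 0) abort_domain("mixture EDV50 collapsed to <= 0 (full antagonism)")
  potency_estimate(1 / mix_edv, "g/L", assay_label = "simulated (dose-additive mixture)")
}

#' Simulate a fractionation campaign with known ground truth
#'
#' Emulates one chromatographic split of a parent mixture into fractions:
#' the parent carries the dose-additive mixture potency of all compounds
#' (inflated by `synergy_factor` -- synergy lives in the intact mixture and
#' is lost on separation); each compound is assigned to exactly one fraction;
#' every fraction's mass is scaled by `1 - loss_fraction`; fraction
#' potencies are dose-additive (`s = 0`) over their own compounds. Under
#' this model the expected bioactivity recovery is the closed form
#' `100 * (1 - loss_fraction) / (1 + synergy_factor)`.
#'
#' @param compounds list of [true_compound()]s with positive total mass.
#' @param n_fractions number of fractions (>= 1).
#' @param loss_fraction material loss per fraction, `[0, 1)`.
#' @param synergy_factor synergy of the intact parent mixture (`s >= -1`).
#' @param assignment_rule `"random"` (default; seeded) or `"round_robin"`.
#' @param seed RNG seed (mandatory; recorded in the output).
#' @return a [purification_tree()] (extract root `"mix"` + fraction nodes)
#'   with attribute `"truth"`: the seed, parameters and the
#'   compound-to-fraction assignment.
#' @export
simulate_fractionation <- function(compounds, n_fractions, loss_fraction = 0,
                                   synergy_factor = 0,
                                   assignment_rule = c("random", "round_robin"),
                                   seed) {
  assignment_rule <- match.arg(assignment_rule)
  if (!is.numeric(n_fractions) || n_fractions < 1) abort_domain("n_fractions must be >= 1")
  n_fractions <- as.integer(n_fractions)
  parent_spec <- mixture_spec(compounds, synergy_factor = synergy_factor,
                              loss_fraction = loss_fraction)
  masses <- vapply(compounds, `[[`, 0, "mass")
  total_mass <- sum(masses)

  assignment <- if (assignment_rule == "round_robin") {
    rep_len(seq_len(n_fractions), length(compounds))
  } else {
    with_seed(seed, sample.int(n_fractions, length(compounds), replace = TRUE))
  }

  parent <- material_node(
    "mix", label = "simulated parent mixture", role = "extract",
    weight = total_mass, potency = mixture_potency(parent_spec)
  )
  fractions <- lapply(seq_len(n_fractions), function(f) {
    members <- which(assignment == f)
    fid <- sprintf("frac_%02d", f)
    if (!length(members) || sum(masses[members]) <= 0) {
      return(material_node(fid, label = sprintf("fraction %d (empty)", f),
                           role = "fraction", weight = 0, parent_id = "mix"))
    }
    frac_spec <- mixture_spec(compounds[members], synergy_factor = 0)
    material_node(
      fid, label = sprintf("fraction %d", f), role = "fraction",
      weight = (1 - loss_fraction) * sum(masses[members]),
      potency = mixture_potency(frac_spec),
      parent_id = "mix"
    )
  })
  tree <- purification_tree(c(list(parent), fractions))
  attr(tree, "truth") <- list(
    seed = as.integer(seed), loss_fraction = loss_fraction,
    synergy_factor = synergy_factor, assignment_rule = assignment_rule,
    assignment = assignment,
    compound_ids = vapply(compounds, `[[`, "", "id")
  )
  tree
}

#' Simulate a serial-dilution inhibition plate
#'
#' Draws responses from the four-parameter logistic mean ([hill_response()]
#' with `top = 100`, `bottom = 0`) plus Gaussian noise, clipped to
#' `[-10, 110]` percent as a plate reader would deliver them.
#'
#' @param true_ic50 true IC50 in g/L.
#' @param hill_slope true Hill slope.
#' @param dilution_start highest tested concentration, g/L.
#' @param dilution_factor fold-dilution between neighbouring wells (> 1).
#' @param n_dilutions number of concentrations.
#' @param noise_sd Gaussian response noise, percentage points.
#' @param n_replicates replicates per concentration.
#' @param seed RNG seed (mandatory; recorded in `dilution_note`).
#' @return a [dose_response_plate()].
#' @export
simulate_plate <- function(true_ic50, hill_slope = 1, dilution_start,
                           dilution_factor = 2, n_dilutions = 8,
                           noise_sd = 0, n_replicates = 1, seed) {
  for (v in list(true_ic50, hill_slope, dilution_start)) {
    if (!is.numeric(v) || v <= 0) abort_domain("true_ic50, hill_slope and dilution_start must be > 0")
  }
  if (dilution_factor <= 1) abort_domain("dilution_factor must be > 1")
  if (n_dilutions < 1 || n_replicates < 1) abort_domain("n_dilutions and n_replicates must be >= 1")
  if (noise_sd < 0) abort_domain("noise_sd must be >= 0")

  conc <- dilution_start / dilution_factor^(seq_len(n_dilutions) - 1)
  conc_all <- rep(conc, each = n_replicates)
  mean_resp <- hill_response(conc_all, true_ic50, hill_slope, top = 100, bottom = 0)
  resp <- with_seed(seed, mean_resp + stats::rnorm(length(conc_all), sd = noise_sd))
  resp <- pmin(pmax(resp, -10), 110)
  dose_response_plate(
    conc_all, resp,
    replicate = rep(seq_len(n_replicates), times = n_dilutions),
    unit = "g/L",
    max_tested_concentration = dilution_start,
    dilution_note = sprintf(
      "simulated: %d x %g-fold dilutions from %g g/L, noise sd %g, seed %d",
      n_dilutions, dilution_factor, dilution_start, noise_sd, as.integer(seed)
    )
  )
}
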