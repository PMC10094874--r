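# Independent oracles and fixture builders shared across the suite.
# The oracles use only plain arithmetic, never the package's ledger path.

# Published campaign for the Grey Myrtle worked example: IC50 in ug/mL,
# weights in g, dry starting plant mass in g.
extract_table <- data.frame(
  id = c("etoh_single", "hexane", "dcm", "etoac", "etoh_seq", "meoh", "water"),
  ic50_ug_ml = c(10.02, 39.11, 14.09, 18.25, 69.25, 49.93, 80.25),
  ic50_sd = c(3.13, 6.82, 0.81, 7.60, 13.33, 8.76, 17.18),
  weight_g = c(3.0, 1.5, 6.0, 2.9, 6.9, 3.2, 5.6),
  dry_plant_g = c(75, 230, 230, 230, 230, 230, 230),
  stringsAsFactors = FALSE
)
sequential_ids <- c("hexane", "dcm", "etoac", "etoh_seq", "meoh", "water")

# HPLC fraction campaign: weights in mg, IC50 in ug/mL.
fraction_table <- data.frame(
  id = sprintf("f%02d", 1:17),
  weight_mg = c(1.8, 9.4, 9.2, 6.6, 6.9, 7, 3.5, 4.5, 4, 6.6, 10.8, 12, 4.9,
                3.5, 2.1, 5.7, 6),
  ic50_ug_ml = c(68.8, 57.0, 62.2, 44.1, 35.8, 36.0, 25.6, 15.9, 16.2, 16.3,
                 17.1, 14.5, 8.6, 10.3, 8.3, 11.5, 6.7),
  stringsAsFactors = FALSE
)

# brute-force TBA in L from raw table units, bypassing every package class
oracle_tba <- function(ic50_ug_ml, weight_g) weight_g / (ic50_ug_ml * 1e-3)

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "tbakit")
  if (!nzchar(p)) stop("fixture not installed: ", name)
  p
}

make_extract_node <- function(row, parent_id = NA_character_) {
  material_node(
    row$id, role = "extract", weight = row$weight_g,
    dry_source_mass = row$dry_plant_g,
    potency = potency_estimate(row$ic50_ug_ml, "ug/mL", ic50_sd = row$ic50_sd),
    parent_id = parent_id
  )
}

# random synthetic campaign tree (parent + children) with plain-arithmetic truth
random_campaign <- function(n_children, seed) {
  set.seed(seed)
  ic50 <- stats::rlnorm(n_children + 1, meanlog = log(0.02), sdlog = 0.8)
  w <- stats::runif(n_children + 1, 0.001, 5)
  parent <- material_node("p", role = "extract", weight = w[1],
                          potency = potency_estimate(ic50[1], "g/L"))
  children <- lapply(seq_len(n_children), function(i) {
    material_node(sprintf("c%02d", i), role = "fraction", weight = w[i + 1],
                  potency = potency_estimate(ic50[i + 1], "g/L"),
                  parent_id = "p")
  })
  list(
    tree = purification_tree(c(list(parent), children)),
    truth = list(
      parent_tba = w[1] / ic50[1],
      children_tba = w[-1] / ic50[-1],
      children_weight = sum(w[-1]),
      parent_weight = w[1]
    )
  )
}
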