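#' Construct a material node
#'
#' One physical material in a purification campaign: the starting plant, a
#' solvent extract, a chromatographic fraction or a purified compound. Solid
#' weight is stored in grams (mg accepted at the boundary); the dry mass of
#' the starting plant material, when known, enables per-gram normalization of
#' total bioactivity.
#'
#' @param id unique token identifying the node within its tree.
#' @param label human-readable label; defaults to `id`.
#' @param role one of `"plant"`, `"extract"`, `"fraction"`, `"compound"`.
#' @param solvent extraction solvent, free text or `NA`.
#' @param weight solid mass, in `weight_unit`; `NA` when unknown (a plant
#'   node, for instance, often has no meaningful solid weight).
#' @param weight_unit `"g"` (default) or `"mg"`.
#' @param dry_source_mass grams of dry starting plant material this node
#'   derives from, or `NA`.
#' @param potency a [potency_estimate()] or `NULL`; required for any node
#'   that is to enter a total-bioactivity computation.
#' @param retention_time HPLC retention time in minutes, or `NA`.
#' @param parent_id id of the node this material was derived from, or `NA`
#'   for the root.
#' @return an object of class `material_node`.
#' @export
material_node <- function(id, label = id,
                          role = c("plant", "extract", "fraction", "compound"),
                          solvent = NA_character_,
                          weight = NA_real_, weight_unit = "g",
                          dry_source_mass = NA_real_,
                          potency = NULL,
                          retention_time = NA_real_,
                          parent_id = NA_character_) {
  role <- match.arg(role)
  if (is_blank(id)) abort_input("material node requires a non-empty id")
  w <- if (is_blank(weight)) NA_real_ else parse_mass(weight, weight_unit)
  if (!is_blank(dry_source_mass)) {
    if (!is.numeric(dry_source_mass) || dry_source_mass <= 0) {
      abort_domain("dry_source_mass must be > 0 when present")
    }
  } else {
    dry_source_mass <- NA_real_
  }
  if (!is.null(potency) && !inherits(potency, "potency_estimate")) {
    abort_input("potency must be a potency_estimate or NULL")
  }
  if (!is_blank(retention_time) && retention_time <= 0) {
    abort_domain("retention_time must be > 0 minutes when present")
  }
  structure(
    list(
      id = as.character(id),
      label = as.character(label),
      role = role,
      solvent = if (is_blank(solvent)) NA_character_ else as.character(solvent),
      weight = w,
      dry_source_mass = as.numeric(dry_source_mass),
      potency = potency,
      retention_time = if (is_blank(retention_time)) NA_real_ else as.numeric(retention_time),
      parent_id = if (is_blank(parent_id)) NA_character_ else as.character(parent_id)
    ),
    class = "material_node"
  )
}

#' @export
print.material_node <- function(x, ...) {
  cat(sprintf("<material_node %s> %s (%s)%s\n", x$id, x$label, x$role,
              if (!is.na(x$weight)) sprintf(", %.4g g", x$weight) else ""))
  invisible(x)
}

#' Assemble a purification tree
#'
#' Validates a set of [material_node()]s into a tree: unique ids, every
#' `parent_id` resolving, no cycles, exactly one root. An empty tree is
#' permitted (with a warning) so that header-only campaign files load.
#'
#' @param nodes a list of [material_node()] objects.
#' @return an object of class `purification_tree` with element `nodes`, a
#'   list named by node id preserving input order.
#' @export
purification_tree <- function(nodes = list()) {
  if (!is.list(nodes) || (length(nodes) && !all(vapply(nodes, inherits, TRUE, "material_node")))) {
    abort_input("nodes must be a list of material_node objects")
  }
  ids <- vapply(nodes, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    abort_structure(sprintf("duplicate node id(s): %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  names(nodes) <- ids
  if (length(nodes)) {
    parents <- vapply(nodes, function(n) n$parent_id %||% NA_character_, "")
    unresolved <- setdiff(parents[!is.na(parents)], ids)
    if (length(unresolved)) {
      abort_structure(sprintf("parent_id(s) do not resolve: %s",
                              paste(unresolved, collapse = ", ")))
    }
    roots <- ids[is.na(parents)]
    if (length(roots) != 1L) {
      abort_structure(sprintf("tree must have exactly one root, found %d (%s)",
                              length(roots), paste(roots, collapse = ", ")))
    }
    # cycle check: walk up from every node; a walk longer than the node count
    # can only mean a loop (unreachable when a single root exists, but cheap)
    for (id in ids) {
      seen <- character()
      cur <- id
      while (!is.na(cur)) {
        if (cur %in% seen) abort_structure(sprintf("cycle detected at node '%s'", cur))
        seen <- c(seen, cur)
        cur <- nodes[[cur]]$parent_id
      }
    }
  } else {
    warning("constructing an empty purification tree")
  }
  structure(list(nodes = nodes), class = "purification_tree")
}

#' @export
print.purification_tree <- function(x, ...) {
  cat(sprintf("<purification_tree> %d node(s)\n", length(x$nodes)))
  invisible(x)
}

#' @export
length.purification_tree <- function(x) length(x$nodes)

tree_root_id <- function(tree) {
  parents <- vapply(tree$nodes, function(n) n$parent_id %||% NA_character_, "")
  names(tree$nodes)[is.na(parents)]
}

tree_children_ids <- function(tree, id) {
  parents <- vapply(tree$nodes, function(n) n$parent_id %||% NA_character_, "")
  names(tree$nodes)[!is.na(parents) & parents == id]
}

#' Compute the total bioactivity (TBA) of a material
#'
#' The core bookkeeping quantity: `TBA = EDV50 x weight`, in liters -- the
#' volume of medium that the material's entire solid mass could bring to
#' half-maximal activity. One gram of an extract with an EDV50 of 1000 L/g
#' (IC50 1 ug/mL) carries a TBA of 1000 L.
#'
#' Materials whose potency is missing, or right-censored (IC50 beyond the
#' tested range), yield an explicit "not computable" result rather than a
#' guessed number; `allow_censored = TRUE` treats the censoring bound as a
#' conservative upper EDV50 estimate instead.
#'
#' @param node a [material_node()] with `potency` and `weight`.
#' @param round_edv50 optional number of decimals to which the EDV50 is
#'   rounded *before* multiplication. This printed-table mode exists to
#'   reproduce published tables computed from rounded intermediates;
#'   analytic work should leave it `NULL`.
#' @param allow_censored include right-censored potencies as bound estimates.
#' @return an object of class `tba_result`: `node_id`, `computable`,
#'   `reason` (when not computable), `tba` (L), `tba_sd` (L, delta-method,
#'   `NA` without `ic50_sd`), `tba_per_gram_source` (L/g, `NA` without
#'   `dry_source_mass`), and a `provenance` record of the ic50, EDV50,
#'   weight and rounding used.
#' @examples
#' n <- material_node("etoh", role = "extract", weight = 3,
#'                    potency = potency_estimate(10.02, "ug/mL"),
#'                    dry_source_mass = 75)
#' compute_tba(n)$tba # 299.40...
#' @export
compute_tba <- function(node, round_edv50 = NULL, allow_censored = FALSE) {
  if (!inherits(node, "material_node")) abort_input("node must be a material_node")
  not_computable <- function(reason) {
    structure(
      list(node_id = node$id, computable = FALSE, reason = reason,
           tba = NA_real_, tba_sd = NA_real_, tba_per_gram_source = NA_real_,
           provenance = NULL),
      class = "tba_result"
    )
  }
  if (is.null(node$potency)) return(not_computable("no potency recorded"))
  if (is_censored(node$potency) && !allow_censored) {
    return(not_computable("potency is right-censored (IC50 above highest tested concentration)"))
  }
  if (is.na(node$weight)) return(not_computable("no solid weight recorded"))

  edv <- node$potency$edv50
  if (!is.null(round_edv50)) edv <- round(edv, round_edv50)
  tba <- edv * node$weight
  tba_sd <- if (!is.na(node$potency$ic50_sd)) {
    (node$potency$ic50_sd / node$potency$ic50^2) * node$weight
  } else {
    NA_real_
  }
  structure(
    list(
      node_id = node$id,
      computable = TRUE,
      reason = NA_character_,
      tba = tba,
      tba_sd = tba_sd,
      tba_per_gram_source = if (!is.na(node$dry_source_mass)) tba / node$dry_source_mass else NA_real_,
      provenance = list(
        ic50_g_l = node$potency$ic50,
        edv50_l_g = node$potency$edv50,
        edv50_used = edv,
        round_edv50 = round_edv50 %||% NA_integer_,
        weight_g = node$weight,
        censored = node$potency$censored
      )
    ),
    class = "tba_result"
  )
}

#' @export
print.tba_result <- function(x, ...) {
  if (!x$computable) {
    cat(sprintf("<tba_result %s> not computable: %s\n", x$node_id, x$reason))
  } else {
    cat(sprintf("<tba_result %s> TBA %.4g L%s%s\n", x$node_id, x$tba,
                if (!is.na(x$tba_sd)) sprintf(" +/- %.3g", x$tba_sd) else "",
                if (!is.na(x$tba_per_gram_source)) {
                  sprintf(" (%.4g L/g dry plant)", x$tba_per_gram_source)
                } else ""))
  }
  invisible(x)
}

#' Normalize a TBA to the dry starting plant mass
#'
#' Dividing by the dry mass of plant material makes campaigns that started
#' from different batch sizes comparable: L of bioactivity recovered per gram
#' of plant processed.
#'
#' @param result a computable [compute_tba()] result, or a plain TBA in L.
#' @param dry_source_mass grams of dry starting material, > 0.
#' @return TBA per gram of dry source, L/g.
#' @export
tba_per_gram <- function(result, dry_source_mass) {
  tba <- if (inherits(result, "tba_result")) {
    if (!result$computable) abort_input("cannot normalize a non-computable TBA result")
    result$tba
  } else {
    if (!is.numeric(result) || length(result) != 1L) abort_input("result must be a tba_result or a single number")
    result
  }
  if (!is.numeric(dry_source_mass) || length(dry_source_mass) != 1L ||
      !is.finite(dry_source_mass) || dry_source_mass <= 0) {
    abort_domain("dry_source_mass must be a single value > 0")
  }
  tba / dry_source_mass
}

#' Sum total bioactivities across materials
#'
#' Plain arithmetic sum over computable results. `rounding = d` rounds each
#' addend to `d` decimals before summing -- the mode needed to reproduce
#' published table totals that were computed from printed (rounded) per-row
#' values; analytic work should leave it `NULL`. Non-computable results
#' (missing or censored potency) contribute zero and their ids are attached
#' as the `"skipped_ids"` attribute.
#'
#' @param results a list of [compute_tba()] results (possibly empty) or a
#'   numeric vector of TBAs in L.
#' @param rounding optional decimals applied to each addend before the sum.
#' @return the summed TBA in L (0 for an empty list).
#' @export
sum_tba <- function(results, rounding = NULL) {
  if (is.numeric(results)) {
    vals <- results
    skipped <- character()
  } else {
    if (!is.list(results)) abort_input("results must be a list of tba_result or numeric")
    if (length(results) && !all(vapply(results, inherits, TRUE, "tba_result"))) {
      abort_input("all elements must be tba_result objects")
    }
    computable <- vapply(results, `[[`, TRUE, "computable")
    skipped <- vapply(results[!computable], `[[`, "", "node_id")
    vals <- vapply(results[computable], `[[`, 0, "tba")
  }
  if (!is.null(rounding)) vals <- round(vals, rounding)
  total <- if (length(vals)) sum(vals) else 0
  if (length(skipped)) attr(total, "skipped_ids") <- skipped
  total
}

#' Classify an additive-vs-interaction comparison of two bioactivity totals
#'
#' Compares a bioactivity quantity measured after some processing (`b`)
#' against its reference before processing (`a`) -- per-gram TBA of
#' sequential vs. single extraction, or TBA recovery vs. mass recovery --
#' and classifies the outcome within a relative tolerance band. The method
#' deliberately reports *both* standard interpretations for each departure,
#' because mass/bioactivity accounting alone cannot distinguish them.
#'
#' * `equivalent` -- |b - a| / a within the band: additive behaviour, or the
#'   reference process already captured all active compounds.
#' * `reduced` -- b below the band: degradation of an active component
#'   during processing, and/or loss of synergistic interaction between
#'   separated components.
#' * `increased` -- b above the band: antagonistic interaction in the
#'   original mixture, and/or the reference process failed to capture all
#'   active compounds.
#'
#' @param a reference value (> 0).
#' @param b comparison value (>= 0).
#' @param tolerance_pct relative equivalence band, percent; default 10.
#' @return an object of class `interaction_classification`: `class`,
#'   `ratio_pct` (100 b/a), `rel_diff_pct`, `tolerance_pct`,
#'   `interpretations` (character vector of the two candidate readings).
#' @examples
#' classify_interaction(3.99, 3.72, tolerance_pct = 10)$class # "equivalent"
#' @export
classify_interaction <- function(a, b, tolerance_pct = 10) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1L || length(b) != 1L) {
    abort_input("a and b must be single numbers")
  }
  if (a < 0 || b < 0) abort_domain("bioactivity totals must be >= 0")
  if (a == 0) abort_domain("reference value a is zero: comparison undefined")
  if (tolerance_pct < 0) abort_domain("tolerance_pct must be >= 0")
  rel <- (b - a) / a
  cls <- if (abs(rel) <= tolerance_pct / 100) {
    "equivalent"
  } else if (rel < 0) {
    "reduced"
  } else {
    "increased"
  }
  interpretations <- switch(cls,
    equivalent = c(
      "additive interaction among the components",
      "the reference process captures all compounds responsible for the overall bioactivity"
    ),
    reduced = c(
      "loss of bioactivity by degradation of an active component during processing",
      "loss of synergistic interaction between components that were separated"
    ),
    increased = c(
      "antagonistic interaction present in the original mixture",
      "the reference process does not capture all compounds responsible for the overall bioactivity"
    )
  )
  structure(
    list(class = cls, ratio_pct = 100 * b / a, rel_diff_pct = 100 * rel,
         tolerance_pct = tolerance_pct, interpretations = interpretations),
    class = "interaction_classification"
  )
}

#' @export
print.interaction_classification <- function(x, ...) {
  cat(sprintf("<interaction> %s (ratio %.1f%%, band +/-%g%%)\n",
              x$class, x$ratio_pct, x$tolerance_pct))
  cat(paste0("  - ", x$interpretations, collapse = "\n"), "\n")
  invisible(x)
}

#' Mass and bioactivity recovery of a purification step
#'
#' Balances one parent material against the fractions derived from it:
#' percent of the parent's solid mass recovered in the children, percent of
#' its total bioactivity recovered, and the interaction classification of
#' bioactivity recovery against mass recovery. When bioactivity tracks mass
#' (equivalent), the components behave additively; bioactivity falling
#' behind mass suggests degradation or lost synergy; bioactivity exceeding
#' mass suggests antagonism relieved by separation.
#'
#' Children whose TBA is not computable (missing or censored potency)
#' contribute zero bioactivity and are listed in `excluded_child_ids`; a
#' child with positive weight but no potency is an accounting gap the caller
#' should resolve, and is reported, not guessed.
#'
#' @param parent a [material_node()] with weight and potency.
#' @param children list of [material_node()]s derived from the parent.
#' @param tolerance_band_pct equivalence band for the classification,
#'   percent; default 25 (recovery comparisons across a chromatography step
#'   are noisier than extract-level per-gram comparisons).
#' @param round_child_tba optional decimals for each child TBA before the
#'   sum (printed-table mode; see [sum_tba()]).
#' @param round_edv50 optional decimals for EDV50 values before
#'   multiplication (printed-table mode; applied to parent and children).
#' @return an object of class `recovery_report`: `parent_id`, `child_ids`,
#'   `mass_recovery_pct`, `tba_recovery_pct`, `interaction_class`,
#'   `tolerance_band_pct`, `parent_tba`, `children_tba_total`,
#'   `parent_weight_g`, `children_weight_g`, `excluded_child_ids`,
#'   `classification` (full [classify_interaction()] result).
#' @export
recovery <- function(parent, children, tolerance_band_pct = 25,
                     round_child_tba = NULL, round_edv50 = NULL) {
  if (!inherits(parent, "material_node")) abort_input("parent must be a material_node")
  if (!is.list(children) || !length(children) ||
      !all(vapply(children, inherits, TRUE, "material_node"))) {
    abort_input("children must be a non-empty list of material_node objects")
  }
  parent_res <- compute_tba(parent, round_edv50 = round_edv50)
  if (!parent_res$computable) {
    abort_domain(sprintf("parent TBA not computable: %s", parent_res$reason))
  }
  if (is.na(parent$weight) || parent$weight <= 0) {
    abort_domain("parent weight must be > 0 for recovery")
  }
  if (parent_res$tba <= 0) abort_domain("parent TBA is zero: recovery undefined")

  child_w <- vapply(children, function(n) {
    if (is.na(n$weight)) abort_input(sprintf("child '%s' has no weight", n$id))
    n$weight
  }, 0)
  child_res <- lapply(children, compute_tba, round_edv50 = round_edv50)
  children_tba <- sum_tba(child_res, rounding = round_child_tba)
  excluded <- attr(children_tba, "skipped_ids") %||% character()

  mass_pct <- 100 * sum(child_w) / parent$weight
  tba_pct <- 100 * as.numeric(children_tba) / parent_res$tba
  cls <- classify_interaction(mass_pct, tba_pct, tolerance_pct = tolerance_band_pct)

  structure(
    list(
      parent_id = parent$id,
      child_ids = vapply(children, `[[`, "", "id"),
      mass_recovery_pct = mass_pct,
      tba_recovery_pct = tba_pct,
      interaction_class = cls$class,
      tolerance_band_pct = tolerance_band_pct,
      parent_tba = parent_res$tba,
      children_tba_total = as.numeric(children_tba),
      parent_weight_g = parent$weight,
      children_weight_g = sum(child_w),
      excluded_child_ids = excluded,
      classification = cls
    ),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "<recovery_report %s -> %d children> mass %.2f%%, TBA %.1f%% (%s)\n",
    x$parent_id, length(x$child_ids), x$mass_recovery_pct, x$tba_recovery_pct,
    x$interaction_class
  ))
  if (length(x$excluded_child_ids)) {
    cat("  excluded from TBA sum:", paste(x$excluded_child_ids, collapse = ", "), "\n")
  }
  invisible(x)
}
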