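#' Full bioactivity ledger for a purification campaign
#'
#' Walks a [purification_tree()] depth-first (siblings in input order),
#' computes each node's TBA and per-gram normalization, and balances every
#' parent against its children with a [recovery()] report. Nodes whose TBA
#' cannot be computed (no potency, censored potency, no weight) appear in the
#' table with the reason instead of a number.
#'
#' @param tree a [purification_tree()].
#' @param round_edv50,round_tba optional decimals for the printed-table
#'   rounding mode (see [compute_tba()] and [sum_tba()]); `NULL` (default)
#'   keeps full precision. `round_tba` affects the recovery sums and the
#'   totals, not the stored per-node values.
#' @param recovery_tolerance_pct equivalence band for the per-step
#'   interaction classification; default 25.
#' @param allow_censored treat right-censored potencies as bound estimates.
#' @return an object of class `campaign_report`: `table` (one data.frame row
#'   per node: id, label, role, depth, parent_id, ic50_ug_ml, ic50_g_l,
#'   edv50_l_g, weight_g, tba_l, tba_sd_l, dry_source_mass_g, tba_per_g,
#'   retention_time_min, status, reason), `recoveries` (list of
#'   [recovery()] reports keyed by parent id), `totals` (per sibling group:
#'   parent id, summed weight and TBA), `policy` (the rounding/tolerance
#'   settings used).
#' @examples
#' tree <- read_campaign_csv(system.file("extdata", "grey_myrtle_fractions.csv",
#'                                       package = "tbakit"))
#' rep <- campaign_report(tree, round_tba = 3)
#' rep$recoveries[["dcm"]]$mass_recovery_pct # 2.6125
#' @export
campaign_report <- function(tree, round_edv50 = NULL, round_tba = NULL,
                            recovery_tolerance_pct = 25, allow_censored = FALSE) {
  if (!inherits(tree, "purification_tree")) abort_input("tree must be a purification_tree")
  if (!length(tree$nodes)) {
    return(structure(
      list(table = empty_report_table(), recoveries = list(), totals = list(),
           policy = report_policy(round_edv50, round_tba, recovery_tolerance_pct)),
      class = "campaign_report"
    ))
  }

  # depth-first node order, siblings kept in input order
  order_ids <- character()
  depths <- integer()
  visit <- function(id, depth) {
    order_ids[[length(order_ids) + 1L]] <<- id
    depths[[length(depths) + 1L]] <<- depth
    for (cid in tree_children_ids(tree, id)) visit(cid, depth + 1L)
  }
  visit(tree_root_id(tree), 0L)

  rows <- lapply(seq_along(order_ids), function(i) {
    node <- tree$nodes[[order_ids[[i]]]]
    res <- compute_tba(node, round_edv50 = round_edv50, allow_censored = allow_censored)
    data.frame(
      id = node$id, label = node$label, role = node$role, depth = depths[[i]],
      parent_id = node$parent_id %||% NA_character_,
      ic50_ug_ml = if (!is.null(node$potency)) node$potency$ic50 * 1e3 else NA_real_,
      ic50_g_l = if (!is.null(node$potency)) node$potency$ic50 else NA_real_,
      edv50_l_g = if (!is.null(node$potency)) node$potency$edv50 else NA_real_,
      weight_g = node$weight,
      tba_l = res$tba,
      tba_sd_l = res$tba_sd,
      dry_source_mass_g = node$dry_source_mass,
      tba_per_g = res$tba_per_gram_source,
      retention_time_min = node$retention_time,
      status = if (res$computable) "ok" else "not_computable",
      reason = res$reason,
      stringsAsFactors = FALSE
    )
  })
  table <- do.call(rbind, rows)

  recoveries <- list()
  totals <- list()
  for (pid in order_ids) {
    cids <- tree_children_ids(tree, pid)
    if (!length(cids)) next
    children <- tree$nodes[cids]
    child_res <- lapply(children, compute_tba, round_edv50 = round_edv50,
                        allow_censored = allow_censored)
    child_w <- vapply(children, `[[`, NA_real_, "weight")
    totals[[pid]] <- list(
      parent_id = pid,
      child_ids = cids,
      weight_g = sum(child_w, na.rm = TRUE),
      tba_l = as.numeric(sum_tba(child_res, rounding = round_tba))
    )
    parent <- tree$nodes[[pid]]
    can_balance <- !is.null(parent$potency) && !is.na(parent$weight) &&
      parent$weight > 0 && (!is_censored(parent$potency) || allow_censored)
    if (can_balance) {
      recoveries[[pid]] <- recovery(
        parent, unname(children),
        tolerance_band_pct = recovery_tolerance_pct,
        round_child_tba = round_tba, round_edv50 = round_edv50
      )
    }
  }

  structure(
    list(table = table, recoveries = recoveries, totals = totals,
         policy = report_policy(round_edv50, round_tba, recovery_tolerance_pct)),
    class = "campaign_report"
  )
}

report_policy <- function(round_edv50, round_tba, recovery_tolerance_pct) {
  list(round_edv50 = round_edv50, round_tba = round_tba,
       recovery_tolerance_pct = recovery_tolerance_pct)
}

empty_report_table <- function() {
  data.frame(
    id = character(), label = character(), role = character(), depth = integer(),
    parent_id = character(), ic50_ug_ml = numeric(), ic50_g_l = numeric(),
    edv50_l_g = numeric(), weight_g = numeric(), tba_l = numeric(),
    tba_sd_l = numeric(), dry_source_mass_g = numeric(), tba_per_g = numeric(),
    retention_time_min = numeric(), status = character(), reason = character(),
    stringsAsFactors = FALSE
  )
}

#' @export
print.campaign_report <- function(x, ...) {
  cat(sprintf("<campaign_report> %d node(s), %d recovery step(s)\n",
              nrow(x$table), length(x$recoveries)))
  if (nrow(x$table)) {
    show <- x$table[, c("id", "role", "edv50_l_g", "weight_g", "tba_l", "tba_per_g", "status")]
    show$edv50_l_g <- round(show$edv50_l_g, 2)
    show$tba_l <- round(show$tba_l, 3)
    show$tba_per_g <- round(show$tba_per_g, 3)
    print(show, row.names = FALSE)
  }
  for (r in x$recoveries) print(r)
  invisible(x)
}
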