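campaign_csv_columns <- c(
  "id", "label", "role", "solvent", "ic50_value", "ic50_unit", "ic50_sd",
  "weight_value", "weight_unit", "dry_source_mass_g", "parent_id",
  "retention_time_min"
)

#' Read a campaign table CSV into a purification tree
#'
#' The campaign table is the flat, spreadsheet-friendly exchange format: one
#' row per material with its potency (value + unit + optional SD), solid
#' weight (value + unit), optional dry starting-plant mass, optional HPLC
#' retention time, and a `parent_id` column encoding the tree. Dialect is
#' fixed (UTF-8, comma separator, `.` decimal mark, mandatory header) to
#' avoid locale drift; the micro sign may be written `u`. Units are
#' converted to the canonical g / g/L at the boundary.
#'
#' @param path path to the CSV file.
#' @return a [purification_tree()]; empty (with a warning) for a header-only
#'   file.
#' @examples
#' tree <- read_campaign_csv(system.file("extdata", "grey_myrtle_extracts.csv",
#'                                       package = "tbakit"))
#' length(tree) # 8 nodes: plant root, single EtOH extract, 6 sequential extracts
#' @export
read_campaign_csv <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("campaign file not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(campaign_csv_columns, names(raw))
  if (length(missing_cols)) {
    abort_format(sprintf("campaign CSV is missing required column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  if (nrow(raw) == 0L) {
    warning(sprintf("campaign file '%s' has a header but no rows; returning an empty tree",
                    basename(path)))
    return(suppressWarnings(purification_tree(list())))
  }
  nodes <- lapply(seq_len(nrow(raw)), function(i) {
    row <- raw[i, ]
    num <- function(field) {
      v <- trimws(row[[field]])
      if (!nzchar(v)) return(NA_real_)
      out <- suppressWarnings(as.numeric(v))
      if (is.na(out)) {
        abort_format(sprintf("row %d: unparseable number '%s' in column '%s'", i, v, field))
      }
      out
    }
    chr <- function(field) {
      v <- trimws(row[[field]])
      if (nzchar(v)) v else NA_character_
    }
    ic50 <- num("ic50_value")
    potency <- NULL
    if (!is.na(ic50)) {
      unit <- chr("ic50_unit")
      if (is.na(unit)) abort_format(sprintf("row %d: ic50_value without ic50_unit", i))
      potency <- potency_estimate(ic50, unit, ic50_sd = num("ic50_sd"))
    }
    weight <- num("weight_value")
    material_node(
      id = chr("id") %||% abort_format(sprintf("row %d: missing id", i)),
      label = chr("label") %||% chr("id"),
      role = chr("role"),
      solvent = chr("solvent"),
      weight = if (is.na(weight)) NA_real_ else weight,
      weight_unit = if (is.na(weight)) "g" else (chr("weight_unit") %||% "g"),
      dry_source_mass = num("dry_source_mass_g"),
      potency = potency,
      retention_time = num("retention_time_min"),
      parent_id = chr("parent_id")
    )
  })
  purification_tree(nodes)
}

#' Write a purification tree to a campaign table CSV
#'
#' Inverse of [read_campaign_csv()] up to unit canonicalization: potencies
#' are written in g/L and weights in g, so a read/write/read cycle is
#' lossless.
#'
#' @param tree a [purification_tree()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_campaign_csv <- function(tree, path) {
  if (!inherits(tree, "purification_tree")) abort_input("tree must be a purification_tree")
  lines <- paste(campaign_csv_columns, collapse = ",")
  cell <- function(x) if (is_blank(x)) "" else as.character(x)
  numcell <- function(x) if (is_blank(x)) "" else format(x, digits = 17, scientific = FALSE, trim = TRUE)
  for (node in tree$nodes) {
    p <- node$potency
    lines <- c(lines, paste(c(
      cell(node$id), cell(node$label), cell(node$role), cell(node$solvent),
      if (is.null(p)) "" else numcell(p$ic50),
      if (is.null(p)) "" else "g/L",
      if (is.null(p)) "" else numcell(p$ic50_sd),
      numcell(node$weight),
      if (is_blank(node$weight)) "" else "g",
      numcell(node$dry_source_mass),
      cell(node$parent_id),
      numcell(node$retention_time)
    ), collapse = ","))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

tree_json_schema <- "tba-tree v1"

#' Serialize / deserialize a purification tree as JSON
#'
#' The JSON schema (`"tba-tree v1"`) attaches an explicit unit to every
#' quantity -- the bookkeeping this package automates is unit-bug-prone, so
#' no bare numbers cross the file boundary. The round trip
#' write/read is lossless for all fields including potency uncertainty,
#' censoring and assay labels.
#'
#' @param tree a [purification_tree()].
#' @param path file path.
#' @return `read_tree_json` returns a [purification_tree()];
#'   `write_tree_json` returns `path` invisibly.
#' @export
write_tree_json <- function(tree, path) {
  if (!inherits(tree, "purification_tree")) abort_input("tree must be a purification_tree")
  qty <- function(value, unit) {
    if (is_blank(value)) NULL else list(value = value, unit = unit)
  }
  nodes <- lapply(unname(tree$nodes), function(n) {
    out <- list(
      id = n$id, label = n$label, role = n$role,
      solvent = if (is_blank(n$solvent)) NULL else n$solvent,
      weight = qty(n$weight, "g"),
      dry_source_mass = qty(n$dry_source_mass, "g"),
      retention_time = qty(n$retention_time, "min"),
      parent_id = if (is_blank(n$parent_id)) NULL else n$parent_id
    )
    if (!is.null(n$potency)) {
      p <- n$potency
      out$potency <- list(
        ic50 = list(value = p$ic50, unit = "g/L"),
        ic50_sd = qty(p$ic50_sd, "g/L"),
        edv50 = list(value = p$edv50, unit = "L/g"),
        n_replicates = if (is.na(p$n_replicates)) NULL else p$n_replicates,
        censored = p$censored,
        assay_label = if (is.na(p$assay_label)) NULL else p$assay_label,
        sd_source = if (is.na(p$sd_source)) NULL else p$sd_source
      )
    }
    out
  })
  jsonlite::write_json(list(schema = tree_json_schema, nodes = nodes), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_tree_json
#' @export
read_tree_json <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("tree file not found: %s", path))
  obj <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) abort_format(sprintf("malformed JSON in '%s': %s",
                                             basename(path), conditionMessage(e)))
  )
  if (!identical(obj$schema, tree_json_schema)) {
    abort_format(sprintf("unknown tree schema '%s' (expected '%s')",
                         obj$schema %||% "<missing>", tree_json_schema))
  }
  qty <- function(q, expected_unit) {
    if (is.null(q)) return(NA_real_)
    if (!identical(q$unit, expected_unit)) {
      abort_format(sprintf("expected unit '%s', found '%s'", expected_unit, q$unit %||% "<none>"))
    }
    as.numeric(q$value)
  }
  nodes <- lapply(obj$nodes, function(n) {
    potency <- NULL
    if (!is.null(n$potency)) {
      p <- n$potency
      potency <- potency_estimate(
        qty(p$ic50, "g/L"), "g/L",
        ic50_sd = qty(p$ic50_sd, "g/L"),
        n_replicates = p$n_replicates %||% NA_integer_,
        censored = p$censored %||% "none",
        assay_label = p$assay_label %||% NA_character_,
        sd_source = p$sd_source %||% NA_character_
      )
    }
    material_node(
      id = n$id, label = n$label %||% n$id, role = n$role,
      solvent = n$solvent %||% NA_character_,
      weight = qty(n$weight, "g"), weight_unit = "g",
      dry_source_mass = qty(n$dry_source_mass, "g"),
      potency = potency,
      retention_time = qty(n$retention_time, "min"),
      parent_id = n$parent_id %||% NA_character_
    )
  })
  purification_tree(nodes)
}

#' Render a campaign report to disk
#'
#' Deterministic, byte-stable rendering of a [campaign_report()]:
#' `"csv"` and `"markdown"` print rounded presentation values (EDV50 and
#' gram-scale TBA to 2 decimals by default; pass `digits_tba = 3` for
#' mg-scale fraction tables), with a totals row per sibling group and a
#' recovery row per balanced step; `"json"` keeps full precision.
#'
#' @param report a [campaign_report()].
#' @param path output file path.
#' @param format `"csv"`, `"json"` or `"markdown"`.
#' @param digits_edv50,digits_tba,digits_per_gram presentation decimals.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json", "markdown"),
                         digits_edv50 = 2, digits_tba = 2, digits_per_gram = 2) {
  format <- match.arg(format)
  if (!inherits(report, "campaign_report")) abort_input("report must be a campaign_report")
  fmt <- function(x, d) {
    ifelse(is.na(x), "", formatC(round(x, d), format = "f", digits = d))
  }
  tab <- report$table
  if (format == "json") {
    jsonlite::write_json(
      list(table = tab,
           totals = unname(report$totals),
           recoveries = lapply(unname(report$recoveries), function(r) {
             r$classification <- unclass(r$classification)
             unclass(r)
           }),
           policy = report$policy),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null", na = "null"
    )
    return(invisible(path))
  }

  # shared presentation rows: per-node, then per-group total + recovery
  header <- c("id", "label", "ic50_ug_ml", "edv50_l_g", "weight_g", "tba_l",
              "dry_plant_g", "tba_per_g")
  node_row <- function(i) {
    c(tab$id[i], tab$label[i],
      fmt(tab$ic50_ug_ml[i], 2), fmt(tab$edv50_l_g[i], digits_edv50),
      fmt(tab$weight_g[i], 4), fmt(tab$tba_l[i], digits_tba),
      fmt(tab$dry_source_mass_g[i], 0), fmt(tab$tba_per_g[i], digits_per_gram))
  }
  rows <- lapply(seq_len(nrow(tab)), node_row)
  for (pid in names(report$totals)) {
    tot <- report$totals[[pid]]
    rows[[length(rows) + 1L]] <- c(
      paste0("total:", pid), sprintf("sum of %d children", length(tot$child_ids)),
      "", "", fmt(tot$weight_g, 4), fmt(tot$tba_l, digits_tba), "", ""
    )
    rec <- report$recoveries[[pid]]
    if (!is.null(rec)) {
      rows[[length(rows) + 1L]] <- c(
        paste0("recovery:", pid),
        sprintf("mass %s%% / TBA %s%% (%s)",
                fmt(rec$mass_recovery_pct, 2), fmt(rec$tba_recovery_pct, 1),
                rec$interaction_class),
        "", "", "", "", "", ""
      )
    }
  }

  lines <- if (format == "csv") {
    c(paste(header, collapse = ","),
      vapply(rows, paste, "", collapse = ","))
  } else {
    md_row <- function(cells) paste0("| ", paste(cells, collapse = " | "), " |")
    c(md_row(header),
      md_row(rep("---", length(header))),
      vapply(rows, md_row, ""))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Export a chromatogram/potency overlay table
#'
#' Pairs each fraction's HPLC retention time with its EDV50 so the potency
#' profile can be overlaid on a chromatogram and the most potent fractions
#' spotted at a glance. Nodes lacking a retention time or a potency are
#' skipped with a warning.
#'
#' @param tree a [purification_tree()].
#' @param path optional CSV output path (header
#'   `fraction_id,retention_time_min,edv50_l_per_g`).
#' @return a data.frame (`fraction_id`, `retention_time_min`,
#'   `edv50_l_per_g`), sorted by retention time.
#' @export
export_overlay <- function(tree, path = NULL) {
  if (!inherits(tree, "purification_tree")) abort_input("tree must be a purification_tree")
  eligible <- Filter(function(n) !is.na(n$retention_time) && !is.null(n$potency), tree$nodes)
  skipped <- length(tree$nodes) - length(eligible)
  if (skipped > 0) {
    warning(sprintf("%d node(s) without retention time and potency skipped from overlay", skipped))
  }
  out <- if (length(eligible)) {
    df <- data.frame(
      fraction_id = vapply(eligible, `[[`, "", "id"),
      retention_time_min = vapply(eligible, `[[`, 0, "retention_time"),
      edv50_l_per_g = vapply(eligible, function(n) n$potency$edv50, 0),
      stringsAsFactors = FALSE
    )
    df[order(df$retention_time_min), , drop = FALSE]
  } else {
    data.frame(fraction_id = character(), retention_time_min = numeric(),
               edv50_l_per_g = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  if (!is.null(path)) {
    lines <- c("fraction_id,retention_time_min,edv50_l_per_g",
               if (nrow(out)) paste(out$fraction_id,
                                    format(out$retention_time_min, digits = 15, trim = TRUE),
                                    format(out$edv50_l_per_g, digits = 15, trim = TRUE),
                                    sep = ","))
    writeLines(lines, path, useBytes = TRUE)
  }
  out
}
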