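test_that("compute_tba reproduces the published worked examples", {
  # 1 g at EDV50 1 L/mg (= IC50 1 mg/L) -> 1000 L
  n <- material_node("x", role = "extract", weight = 1,
                     potency = potency_estimate(1, "mg/L"))
  expect_equal(compute_tba(n)$tba, 1000)

  # single ethanolic extract: IC50 10.02 ug/mL, 3.0 g -> 299.40 L
  etoh <- make_extract_node(extract_table[extract_table$id == "etoh_single", ])
  res <- compute_tba(etoh)
  expect_equal(round(res$tba, 2), 299.40)
  expect_equal(res$tba, res$provenance$edv50_used * res$provenance$weight_g,
               tolerance = 1e-12)

  # HPLC fraction F-17: IC50 6.7 ug/mL, 6 mg -> 0.896 L
  f17 <- material_node("f17", role = "fraction", weight = 6, weight_unit = "mg",
                       potency = potency_estimate(6.7, "ug/mL"))
  expect_equal(round(compute_tba(f17)$tba, 3), 0.896)

  # zero weight is a zero TBA, not an error
  z <- material_node("z", role = "fraction", weight = 0,
                     potency = potency_estimate(1, "g/L"))
  expect_identical(compute_tba(z)$tba, 0)
})

test_that("TBA is linear in weight and invariant to input units", {
  p <- potency_estimate(14.09, "ug/mL")
  base <- compute_tba(material_node("a", role = "extract", weight = 2, potency = p))$tba
  for (k in c(0.25, 1, 3, 117.5)) {
    scaled <- compute_tba(material_node("a", role = "extract", weight = 2 * k,
                                        potency = p))$tba
    expect_equal(scaled, k * base, tolerance = 1e-12)
  }
  # ug/mL + g  ==  g/L + mg pathways
  a <- material_node("a", role = "extract", weight = 6,
                     potency = potency_estimate(14.09, "ug/mL"))
  b <- material_node("b", role = "extract", weight = 6000, weight_unit = "mg",
                     potency = potency_estimate(0.01409, "g/L"))
  expect_equal(compute_tba(a)$tba, compute_tba(b)$tba, tolerance = 1e-12)
})

test_that("missing and censored potencies give explicit non-results", {
  bare <- material_node("bare", role = "fraction", weight = 1)
  res <- compute_tba(bare)
  expect_false(res$computable)
  expect_match(res$reason, "no potency")

  cens <- material_node("cens", role = "fraction", weight = 1,
                        potency = potency_estimate(2, "g/L", censored = "right"))
  res2 <- compute_tba(cens)
  expect_false(res2$computable)
  expect_match(res2$reason, "censored")
  # override treats the bound as a conservative estimate
  res3 <- compute_tba(cens, allow_censored = TRUE)
  expect_true(res3$computable)
  expect_equal(res3$tba, 0.5)
})

test_that("per-gram normalization reproduces Table 2 and rejects bad masses", {
  etoh <- compute_tba(make_extract_node(extract_table[1, ]))
  expect_equal(round(tba_per_gram(etoh, 75), 2), 3.99)
  expect_equal(round(tba_per_gram(856.60, 230), 2), 3.72)
  expect_identical(tba_per_gram(42.5, 1), 42.5)
  expect_error(tba_per_gram(etoh, 0), class = "tbakit_domain_error")
  expect_error(tba_per_gram(etoh, -3), class = "tbakit_domain_error")
})

test_that("sum_tba matches the published totals in both rounding modes", {
  seqs <- extract_table[extract_table$id %in% sequential_ids, ]
  results <- lapply(seq_len(nrow(seqs)), function(i) {
    compute_tba(make_extract_node(seqs[i, ]))
  })
  expect_equal(round(sum_tba(results), 2), 856.60)

  fr <- lapply(seq_len(nrow(fraction_table)), function(i) {
    compute_tba(material_node(fraction_table$id[i], role = "fraction",
                              weight = fraction_table$weight_mg[i], weight_unit = "mg",
                              potency = potency_estimate(fraction_table$ic50_ug_ml[i], "ug/mL")))
  })
  expect_equal(sum_tba(fr, rounding = 3), 5.963) # printed-table mode
  expect_equal(round(sum_tba(fr), 3), 5.960) # analytic mode differs by design
  expect_identical(sum_tba(list()), 0)
})

test_that("sum_tba is order-invariant and skips non-computable results visibly", {
  set.seed(21)
  vals <- stats::runif(40, 0.01, 500)
  results <- lapply(seq_along(vals), function(i) {
    compute_tba(material_node(paste0("n", i), role = "fraction", weight = vals[i],
                              potency = potency_estimate(1, "g/L")))
  })
  for (perm in replicate(5, sample(seq_along(results)), simplify = FALSE)) {
    expect_equal(sum_tba(results[perm]), sum_tba(results), tolerance = 1e-12)
  }
  mixed <- c(results[1:3], list(compute_tba(material_node("gap", role = "fraction",
                                                          weight = 1))))
  total <- sum_tba(mixed)
  expect_equal(as.numeric(total), as.numeric(sum_tba(results[1:3])))
  expect_identical(attr(total, "skipped_ids"), "gap")
})

test_that("recovery balances the HPLC campaign to the published percentages", {
  parent <- material_node("dcm", role = "extract", weight = 4000, weight_unit = "mg",
                          potency = potency_estimate(14.09, "ug/mL"))
  children <- lapply(seq_len(nrow(fraction_table)), function(i) {
    material_node(fraction_table$id[i], role = "fraction",
                  weight = fraction_table$weight_mg[i], weight_unit = "mg",
                  potency = potency_estimate(fraction_table$ic50_ug_ml[i], "ug/mL"),
                  parent_id = "dcm")
  })
  rep <- recovery(parent, children, round_child_tba = 3, round_edv50 = 2)
  expect_equal(round(rep$mass_recovery_pct, 2), 2.61)
  expect_equal(round(rep$tba_recovery_pct, 1), 2.1)
  expect_equal(round(rep$parent_tba, 2), 283.88) # printed-table mode
  expect_equal(rep$children_tba_total, 5.963)
})

test_that("recovery is exactly 100% for a lossless partition at parent potency", {
  p <- potency_estimate(0.02, "g/L")
  parent <- material_node("p", role = "extract", weight = 10, potency = p)
  # identical single child
  one <- recovery(parent, list(material_node("c", role = "fraction", weight = 10,
                                             potency = p, parent_id = "p")))
  expect_equal(one$mass_recovery_pct, 100, tolerance = 1e-9)
  expect_equal(one$tba_recovery_pct, 100, tolerance = 1e-9)
  # arbitrary partitions
  set.seed(31)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    parts <- as.numeric(stats::rmultinom(1, 1000, stats::runif(k))) / 100
    children <- lapply(seq_len(k), function(j) {
      material_node(paste0("c", j), role = "fraction", weight = parts[j],
                    potency = p, parent_id = "p")
    })
    rep <- recovery(parent, children)
    expect_equal(rep$tba_recovery_pct, 100, tolerance = 1e-9)
    expect_identical(rep$interaction_class, "equivalent")
  }
})

test_that("recovery refuses undefined balances and flags unaccountable children", {
  p <- potency_estimate(1, "g/L")
  no_weight <- material_node("p", role = "extract", potency = p)
  child <- material_node("c", role = "fraction", weight = 1, potency = p, parent_id = "p")
  expect_error(recovery(no_weight, list(child)), class = "tbakit_domain_error")

  parent <- material_node("p", role = "extract", weight = 2, potency = p)
  cens <- material_node("cens", role = "fraction", weight = 0.5,
                        potency = potency_estimate(1, "g/L", censored = "right"),
                        parent_id = "p")
  rep <- recovery(parent, list(child, cens))
  expect_identical(rep$excluded_child_ids, "cens")
  expect_equal(rep$mass_recovery_pct, 75) # censored mass still counts
  expect_equal(rep$tba_recovery_pct, 50) # censored bioactivity does not
})

test_that("interaction classification follows the tolerance band", {
  # the published single-vs-sequential comparison: 6.8% deficit, "nearly the same"
  cls <- classify_interaction(3.99, 3.72, tolerance_pct = 10)
  expect_identical(cls$class, "equivalent")
  expect_equal(round(cls$ratio_pct, 1), 93.2)
  # the same comparison at a 5% band flips to a real reduction
  expect_identical(classify_interaction(3.99, 3.72, tolerance_pct = 5)$class, "reduced")

  expect_identical(classify_interaction(100, 50)$class, "reduced")
  expect_identical(classify_interaction(50, 100)$class, "increased")
  expect_error(classify_interaction(0, 1), class = "tbakit_domain_error")
  expect_error(classify_interaction(1, -1), class = "tbakit_domain_error")

  # both candidate interpretations are always reported: the balance alone
  # cannot distinguish degradation from lost synergy
  expect_length(classify_interaction(100, 50)$interpretations, 2)
  expect_match(paste(classify_interaction(100, 50)$interpretations, collapse = "; "),
               "degradation")
  expect_match(paste(classify_interaction(100, 50)$interpretations, collapse = "; "),
               "synergistic")
})

test_that("purification trees validate topology", {
  p <- potency_estimate(1, "g/L")
  mk <- function(id, parent = NA) material_node(id, role = "fraction", weight = 1,
                                                potency = p, parent_id = parent)
  expect_error(purification_tree(list(mk("a"), mk("a"))),
               class = "tbakit_structure_error")
  expect_error(purification_tree(list(mk("a", "ghost"))),
               class = "tbakit_structure_error")
  expect_error(purification_tree(list(mk("a"), mk("b"))),
               class = "tbakit_structure_error") # two roots
  expect_error(purification_tree(list(mk("a", "b"), mk("b", "a"))),
               class = "tbakit_structure_error") # cycle
  expect_warning(purification_tree(list()), "empty")
})

test_that("campaign_report orders depth-first and matches the brute-force oracle", {
  rc <- random_campaign(5, seed = 42)
  rep <- campaign_report(rc$tree)
  expect_identical(rep$table$id, c("p", sprintf("c%02d", 1:5)))
  expect_identical(rep$table$depth, c(0L, rep(1L, 5)))
  expect_equal(rep$totals[["p"]]$tba_l, sum(rc$truth$children_tba), tolerance = 1e-12)

  # oracle equality over 100 random synthetic campaigns
  for (seed in 1:100) {
    rc <- random_campaign(sample(2:8, 1), seed = seed)
    rep <- campaign_report(rc$tree)
    expect_equal(rep$table$tba_l[1], rc$truth$parent_tba, tolerance = 1e-12)
    expect_equal(rep$totals[["p"]]$tba_l, sum(rc$truth$children_tba), tolerance = 1e-12)
    expect_equal(rep$recoveries[["p"]]$tba_recovery_pct,
                 100 * sum(rc$truth$children_tba) / rc$truth$parent_tba,
                 tolerance = 1e-9)
  }
})

test_that("campaign_report lists unaccountable nodes with reasons", {
  p <- potency_estimate(1, "g/L")
  tree <- purification_tree(list(
    material_node("root", role = "plant"),
    material_node("e1", role = "extract", weight = 2, potency = p, parent_id = "root")
  ))
  rep <- campaign_report(tree)
  expect_identical(rep$table$status, c("not_computable", "ok"))
  expect_match(rep$table$reason[1], "no potency")
  # single-node tree: one row, no recovery section
  single <- purification_tree(list(material_node("only", role = "extract",
                                                 weight = 1, potency = p)))
  srep <- campaign_report(single)
  expect_identical(nrow(srep$table), 1L)
  expect_length(srep$recoveries, 0)
})
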