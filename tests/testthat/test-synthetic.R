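test_that("mixture potency follows mass-fraction-weighted dose addition", {
  a <- true_compound("a", true_ic50 = 0.01, mass = 1) # EDV50 100 L/g
  # single component, no synergy: the mixture is the compound
  expect_equal(mixture_potency(mixture_spec(list(a)))$edv50, 100, tolerance = 1e-12)

  # 50:50 with an (almost) inert diluent halves the EDV50
  inert <- true_compound("d", true_ic50 = 1e9, mass = 1)
  mix <- mixture_potency(mixture_spec(list(a, inert)))
  expect_equal(mix$edv50, 50, tolerance = 1e-6)

  # synergy scales the mixture EDV50 multiplicatively
  syn <- mixture_potency(mixture_spec(list(a, inert), synergy_factor = 0.5))
  expect_equal(syn$edv50, 75, tolerance = 1e-6)

  expect_error(mixture_spec(list()), class = "tbakit_input_error")
  expect_error(mixture_spec(list(a), mass_fractions = c(0.7)),
               class = "tbakit_domain_error")
  expect_error(mixture_spec(list(a), synergy_factor = -2),
               class = "tbakit_domain_error")
})

test_that("dose addition conserves TBA exactly for additive mixtures", {
  # brute-force conservation over 1000 random 5-component draws
  set.seed(1234)
  for (i in 1:1000) {
    ic50 <- stats::rlnorm(5, log(0.05), 1)
    mass <- stats::runif(5, 0.1, 3)
    spec <- mixture_spec(lapply(1:5, function(j) {
      true_compound(paste0("c", j), ic50[j], mass[j])
    }))
    mix_tba <- mixture_potency(spec)$edv50 * sum(mass)
    component_tba <- sum(mass / ic50)
    expect_equal(mix_tba, component_tba, tolerance = 1e-9)
  }
})

test_that("simulated fractionation obeys the recovery law 100(1-loss)/(1+s)", {
  compounds <- lapply(1:12, function(i) {
    true_compound(sprintf("c%02d", i), true_ic50 = 0.005 * i, mass = 0.1 * i)
  })
  for (loss in c(0, 0.3, 0.9)) {
    for (s in c(0, 0.5, 1)) {
      tree <- simulate_fractionation(compounds, n_fractions = 5,
                                     loss_fraction = loss, synergy_factor = s,
                                     seed = 77)
      rep <- campaign_report(tree)
      expect_equal(rep$recoveries[["mix"]]$tba_recovery_pct,
                   100 * (1 - loss) / (1 + s), tolerance = 1e-6)
      expect_equal(rep$recoveries[["mix"]]$mass_recovery_pct,
                   100 * (1 - loss), tolerance = 1e-6)
    }
  }
  # both assignment rules conserve TBA when loss = 0 and s = 0
  for (rule in c("random", "round_robin")) {
    tree <- simulate_fractionation(compounds, n_fractions = 4, seed = 5,
                                   assignment_rule = rule)
    rep <- campaign_report(tree)
    expect_equal(rep$recoveries[["mix"]]$tba_recovery_pct, 100, tolerance = 1e-9)
  }
})

test_that("the published HPLC loss regime reproduces the published recovery", {
  compounds <- lapply(1:17, function(i) {
    true_compound(sprintf("c%02d", i), true_ic50 = 0.01 + 0.003 * i, mass = 0.23)
  })
  tree <- simulate_fractionation(compounds, n_fractions = 17,
                                 loss_fraction = 0.9739, synergy_factor = 0,
                                 assignment_rule = "round_robin", seed = 3)
  rep <- campaign_report(tree)
  expect_equal(rep$recoveries[["mix"]]$tba_recovery_pct, 2.61, tolerance = 0.01)
})

test_that("fractionation trees are deterministic for a fixed seed", {
  compounds <- lapply(1:6, function(i) {
    true_compound(sprintf("c%02d", i), true_ic50 = 0.01 * i, mass = 0.5)
  })
  t1 <- simulate_fractionation(compounds, n_fractions = 3, seed = 11)
  t2 <- simulate_fractionation(compounds, n_fractions = 3, seed = 11)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_tree_json(t1, f1)
  write_tree_json(t2, f2)
  expect_identical(readLines(f1), readLines(f2)) # byte-identical serialization
  t3 <- simulate_fractionation(compounds, n_fractions = 3, seed = 12)
  expect_false(identical(attr(t1, "truth")$assignment, attr(t3, "truth")$assignment))
  expect_identical(attr(t1, "truth")$seed, 11L)
  expect_error(simulate_fractionation(compounds, 3, loss_fraction = 1, seed = 1),
               class = "tbakit_domain_error")
})

test_that("simulated plates sit on the logistic curve and are seed-stable", {
  pl <- simulate_plate(true_ic50 = 0.02, hill_slope = 1.5, dilution_start = 1,
                       dilution_factor = 2, n_dilutions = 8, noise_sd = 0,
                       n_replicates = 2, seed = 9)
  expected <- hill_response(pl$points$concentration, 0.02, 1.5)
  expect_equal(pl$points$response, expected, tolerance = 1e-12)

  a <- simulate_plate(0.02, 1, 1, 2, 8, noise_sd = 5, n_replicates = 3, seed = 4)
  b <- simulate_plate(0.02, 1, 1, 2, 8, noise_sd = 5, n_replicates = 3, seed = 4)
  expect_identical(a$points, b$points)
  expect_true(all(a$points$response >= -10 & a$points$response <= 110))
})

test_that("simulated campaigns flow through the real CSV pipeline unchanged", {
  compounds <- lapply(1:5, function(i) {
    true_compound(sprintf("c%02d", i), true_ic50 = 0.02 * i, mass = 0.3)
  })
  tree <- simulate_fractionation(compounds, n_fractions = 3, loss_fraction = 0.4,
                                 seed = 8)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_campaign_csv(tree, tmp)
  reread <- read_campaign_csv(tmp)
  rep_direct <- campaign_report(tree)
  rep_io <- campaign_report(reread)
  expect_equal(rep_io$recoveries[["mix"]]$tba_recovery_pct,
               rep_direct$recoveries[["mix"]]$tba_recovery_pct, tolerance = 1e-9)
})
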