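test_that("exchange rate arithmetic, sign convention and antisymmetry", {
  expect_equal(exchange_rate(2.0, 1.5, 0.002, 0.25, 24), 4)
  expect_equal(exchange_rate(1.5, 1.5, 0.002, 0.25, 24), 0)
  expect_lt(exchange_rate(0.05, 0.75, 0.001, 0.4, 24), 0) # accumulation
  # antisymmetric under swapping blank and harvest
  set.seed(2)
  for (i in 1:10) {
    b <- runif(1, 0, 3); h <- runif(1, 0, 3)
    expect_equal(exchange_rate(b, h, 0.001, 0.3, 24),
                 -exchange_rate(h, b, 0.001, 0.3, 24))
  }
  # 12-h incubation doubles the per-day rate
  expect_equal(exchange_rate(2, 1.5, 0.001, 0.2, 12),
               2 * exchange_rate(2, 1.5, 0.001, 0.2, 24))
  expect_error(exchange_rate(2, 1, 0.001, 0, 24), "protein")
  expect_error(exchange_rate(2, 1, 0.001, 0.2, 0), "time")
})

test_that("tidy media tables gain rates and directions", {
  med <- tibble::tibble(metabolite = c("glutamine", "glutamate"),
                        blank_mM = c(2, 0.054), harvest_mM = c(1.5, 0.754),
                        volume_l = 0.001, protein_mg = 0.4, hours = 24)
  r <- exchange_rates(med)
  expect_equal(r$rate_umol_per_mg_day, c(1.25, -1.75))
  expect_equal(r$direction, c("uptake", "secretion"))
  expect_error(exchange_rates(med[, -2]), "lacks columns")
})

test_that("source apportionment mirrors the labeled shares of each experiment", {
  gln_mid <- c(0.14, 0.15, 0, 0, 0, 0.21, 0.50)  # M5+M6 = 0.71, M1 is 15N
  glc_mid <- c(0.85, 0, 0.09, 0.06, 0, 0)        # M2+M3 = 0.15
  ap <- source_apportionment(2.0, gln_mid, glc_mid, 2.0, 2.0)
  expect_equal(ap$fraction_glutamine, 0.71)
  expect_equal(ap$fraction_glucose, 0.15)
  expect_equal(ap$fraction_other, 0.14)
  expect_equal(ap$fraction_glutamine + ap$fraction_glucose +
                 ap$fraction_other, 1)
  # fully glutamine-derived
  full <- source_apportionment(1, c(0, 0, 0, 0, 0, 0, 1),
                               c(1, 0, 0, 0, 0, 0), 1, 1)
  expect_equal(unlist(full[1, 1:3]), c(fraction_glutamine = 1,
                                       fraction_glucose = 0,
                                       fraction_other = 0))
  # glutamate M1 (15N-only) never counts toward the glutamine share
  m1_heavy <- c(0.2, 0.6, 0, 0, 0, 0.1, 0.1)
  ap2 <- source_apportionment(1, m1_heavy, glc_mid, 1, 1)
  expect_equal(ap2$fraction_glutamine, 0.2)
  # inconsistent experiments
  expect_warning(source_apportionment(1, gln_mid, glc_mid, 1, 1.5),
                 "assumes")
  expect_error(source_apportionment(1, c(0, 0, 0, 0, 0, 0.5, 0.5),
                                    c(0.2, 0, 0.5, 0.3, 0, 0), 1, 1),
               "inconsistent")
  expect_error(source_apportionment(1, gln_mid, glc_mid, 0, 1), "> 0")
  # uncorrected tidy input is refused
  tidy_mid <- tibble::tibble(shift = 0:6, abundance = gln_mid,
                             corrected = FALSE)
  expect_error(source_apportionment(1, tidy_mid, glc_mid, 1, 1), "corrected")
})

test_that("utilization split reproduces the uptake/secretion bookkeeping", {
  u <- utilization_split(3.26, 1.89)
  expect_equal(u$utilized, 1.37)
  expect_equal(u$utilized_fraction, 0.42, tolerance = 0.002)
  expect_equal(utilization_split(2, 0)$utilized_fraction, 1)
  expect_equal(utilization_split(2, 2)$utilized_fraction, 0)
  expect_error(utilization_split(1, 1.2), "mass-balance")
  expect_error(utilization_split(0, 0), "> 0")
})

test_that("biomass enrichment is the baseline-subtracted atom percent", {
  expect_equal(cirms_enrichment(1.25, 1.0799), 0.1701)
  expect_equal(cirms_enrichment(1.0799), 0)
  expect_warning(out <- cirms_enrichment(1.0, 1.0799), "negative")
  expect_lt(out, 0)
  expect_error(cirms_enrichment(120), "\\[0, 100\\]")
  # no tracer -> no incorporation -> baseline-only simulated biomass
  d <- experiment_design("HDF", tracer_none(), n_replicates = 3, bio_cv = 0,
                         seed = 1)
  s <- simulate_experiment(d)
  expect_equal(cirms_enrichment(s$biomass$atom_pct), rep(0, 3),
               tolerance = 1e-12)
})

test_that("intracellular concentration scales with the cell-volume estimate", {
  expect_equal(intracellular_concentration(1e-9, 1e6, 1e-12), 1e-3) # 1 mM
  c1 <- intracellular_concentration(5e-9, 2e6, 1e-12)
  expect_equal(intracellular_concentration(5e-9, 2e6, 2e-12), c1 / 2)
  # equal amounts, 3.8-fold bigger cells -> 1/3.8 the concentration
  expect_equal(intracellular_concentration(1e-9, 1e6, 3.8e-12),
               intracellular_concentration(1e-9, 1e6, 1e-12) / 3.8)
  expect_error(intracellular_concentration(1, 0, 1), "> 0")
})

test_that("de novo secreted MID strips the pre-existing unlabeled pool", {
  secreted <- c(0.1, 0.05, 0, 0, 0, 0.25, 0.6)
  blank <- 0.054; added <- 1.05
  harvest_mid <- normalize_mid(blank * c(1, rep(0, 6)) + added * secreted)
  got <- denovo_secreted_mid(blank, blank + added, harvest_mid)
  expect_equal(got, secreted, tolerance = 1e-10)
  expect_error(denovo_secreted_mid(0.5, 0.3, harvest_mid), "net producer")
})
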