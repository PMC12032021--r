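test_that("all sixteen scenarios construct with the expected override shapes", {
  for (s in scenario_names()) {
    cfg <- build_scenario(s)
    expect_s3_class(cfg, "msim_scenario")
    expect_equal(cfg$effective_date, as.Date("2023-01-01"))
  }
  sq <- build_scenario("SQ")
  expect_identical(sq$overrides, maternalsim:::default_overrides())
  ipc <- build_scenario("IP CEmONC")$overrides
  expect_equal(unname(ipc$delivery_prob[c("prophylactic", "bemonc", "cemonc")]),
               c(0.9, 0.9, 0.9))
  expect_true(all(c("delivery_bemonc", "delivery_cemonc") %in%
                    ipc$delay3_disabled))
  ipm <- build_scenario("IP min.")$overrides
  expect_equal(unname(ipm$delivery_prob), c(0, 0, 0))
  expect_false(ipm$facility_all)   # attendance behaviour unchanged
  expect_error(build_scenario("not a scenario"), "unknown scenario")
})

test_that("composite scenarios equal the union of their components", {
  all_max <- build_scenario("All services max.")$overrides
  comp <- Reduce(maternalsim:::merge_overrides,
                 lapply(c("AN max.", "IP max.", "PN max."),
                        maternalsim:::scenario_overrides))
  expect_identical(all_max, comp)
  all_cov <- build_scenario("All services coverage")$overrides
  expect_equal(all_cov$anc4_target, 0.90)
  expect_equal(all_cov$pnc_target, 0.90)
  expect_equal(unname(all_cov$delivery_prob[c("prophylactic", "bemonc")]),
               c(0.9, 0.9))
  expect_true(is.na(all_cov$delivery_prob[["cemonc"]]))
})

test_that("scenarios only take effect from the intervention date", {
  cfg <- build_scenario("All services max.")
  before <- apply_scenario(cfg, PS, month_index(2022, 12))
  expect_null(before$overrides)
  expect_identical(before, PS)
  after <- apply_scenario(cfg, PS, month_index(2023, 1))
  expect_false(is.null(after$overrides))
})

test_that("AN min. shuts down routine and emergency antenatal care", {
  cfg <- build_scenario("AN min.")
  eff <- apply_scenario(cfg, PS, month_index(2023, 1))
  preg <- make_preg(200, seed = 31L)
  s <- plan_anc_schedule(preg, eff, seed = 31L)
  expect_false(any(s$initiates))
  expect_false(any(emergency_careseeking(1:200, 1L, eff, 1L, "antenatal")))
})

test_that("coverage targets are met by intercept recalibration", {
  women <- make_fixture_population(4000, seed = 33L, ps = PS)
  women <- women[women$sex == "F" & women$age_years >= 15 &
                   women$age_years < 50, ]
  eff <- apply_scenario(build_scenario("PN coverage"), PS,
                        month_index(2023, 1), women = women)
  p <- careseeking_probability("pnc_maternal", women, eff)
  expect_equal(mean(p), 0.90, tolerance = 0.005)
  # simulated early-PNC coverage ~ 0.90, quality untouched
  cov <- coverage_statistics(eff, n = 3000, seed = 34L)
  expect_equal(unname(cov[["pnc_maternal"]]), 0.90, tolerance = 0.02)
  expect_equal(unname(cov[["pnc_neonatal"]]), 0.90, tolerance = 0.02)
  expect_length(eff$overrides$quality_max, 0)
  # ANC4+ target rescales initiation and the transition odds together
  eff_an <- apply_scenario(build_scenario("AN coverage"), PS,
                           month_index(2023, 1), women = women)
  cov_an <- coverage_statistics(eff_an, n = 4000, seed = 35L)
  expect_equal(unname(cov_an[["anc4"]]), 0.90, tolerance = 0.03)
  # facility delivery is untouched by antenatal coverage scenarios
  expect_equal(eff_an$overrides$intercept_shift[["facility_delivery"]], 0)
})

test_that("min. scenarios zero out the service's contacts after 2023", {
  run <- simulate_run("AN min.", PS, n_pop = 2000, ratio = 2000,
                      start_year = 2022, end_year = 2025, seed = 5L)
  a <- run$annual
  expect_gt(a$anc_contacts[a$year == 2022], 0)
  expect_equal(sum(a$anc_contacts[a$year >= 2023]), 0)
  expect_equal(sum(a$inpatient_antenatal_hsi[a$year >= 2023]), 0)
  run_pn <- simulate_run("PN min.", PS, n_pop = 2000, ratio = 2000,
                         start_year = 2022, end_year = 2025, seed = 5L)
  b <- run_pn$annual
  expect_gt(b$pnc_maternal_contacts[b$year == 2022], 0)
  expect_equal(sum(b$pnc_maternal_contacts[b$year >= 2023]), 0)
  expect_equal(sum(b$pnc_neonatal_contacts[b$year >= 2023]), 0)
})

test_that("All services max. delivers every indicated intervention in facility", {
  eff <- apply_scenario(build_scenario("All services max."), PS,
                        month_index(2023, 1))
  ids <- 1:500
  for (nm in PS$interventions$name[PS$interventions$hsi_type != "post_abortion_care"]) {
    lvl <- if (maternalsim:::intervention_row(PS, nm)$hsi_type %in%
               c("delivery_cemonc", "cemonc_postnatal")) "hospital"
           else "health_centre"
    expect_true(all(attempt_intervention_delivery(nm, ids, 1L, eff, 1L,
                                                  level = lvl)),
                info = nm)
  }
  # and all births are facility births
  women <- make_preg(500, seed = 36L, gm = 9L)
  p <- careseeking_probability("facility_delivery", women, eff)
  expect_true(all(p > 0.999))
})
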