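test_that("care-seeking probability is the inverse-logit of the linear predictor", {
  person <- data.frame(wealth = 3, edu = 1, urban = FALSE, parity = 2,
                       age_years = 25)
  ps <- PS
  ps$careseeking[, -1] <- 0
  expect_equal(careseeking_probability("anc", person, ps), 0.5)
  ps$careseeking$intercept <- 1.2
  expect_equal(careseeking_probability("facility_delivery", person, ps),
               1 / (1 + exp(-1.2)))
  expect_error(careseeking_probability("anc", person[, -1], PS), "missing")
  expect_error(careseeking_probability("dental", person, PS), "unknown")
  # gradients: richer, urban, educated women seek more care
  rich <- person; rich$wealth <- 5; rich$urban <- TRUE; rich$edu <- 2
  expect_gt(careseeking_probability("anc", rich, PS),
            careseeking_probability("anc", person, PS))
})

test_that("ANC schedules follow the first-visit distribution and transition chain", {
  preg <- make_preg(4000, seed = 21L)
  ps0 <- PS
  ps0$scalars$anc_transition_prob <- 0
  s0 <- plan_anc_schedule(preg, ps0, seed = 21L)
  expect_true(all(s0$planned_visits <= 1))
  ps1 <- PS
  ps1$scalars$anc_transition_prob <- 1
  ps1$careseeking$intercept[ps1$careseeking$service == "anc"] <- 30
  s1 <- plan_anc_schedule(preg, ps1, seed = 21L)
  expect_true(all(s1$planned_visits == 8))
  expect_true(all(s1$first_gm %in% PS$anc_first_visit$gestational_month))
  # visit-count distribution equals the truncated geometric chain (oracle)
  p <- PS$scalars$anc_transition_prob
  s <- plan_anc_schedule(preg, ps1_init <- {
    x <- PS; x$careseeking$intercept[x$careseeking$service == "anc"] <- 30; x
  }, seed = 22L)
  counts <- tabulate(s$planned_visits, 8)
  chain <- c(p^(0:6) * (1 - p), p^7)   # P(exactly k+1 visits)
  for (k in 1:8) {
    b <- binom_bounds(nrow(preg), chain[k], conf = 0.999)
    expect_gte(counts[k], b[["lo"]])
    expect_lte(counts[k], b[["hi"]])
  }
})

test_that("emergency care seeking honours pins and its probability", {
  ids <- 1:10000
  ps1 <- with_overrides(PS, emergency_seek = c(antenatal = 1, postnatal = NA))
  expect_true(all(emergency_careseeking(ids, 1L, ps1, 1L, "antenatal")))
  ps0 <- with_overrides(PS, emergency_seek = c(antenatal = 0, postnatal = NA))
  expect_false(any(emergency_careseeking(ids, 1L, ps0, 1L, "antenatal")))
  got <- sum(emergency_careseeking(ids, 1L, PS, 1L, "antenatal"))
  expect_within_binom(got, length(ids), PS$scalars$emergency_careseek_prob)
})

test_that("squeeze factor is required over available minus one", {
  expect_equal(compute_squeeze_factor(60, 60), 0)
  expect_equal(compute_squeeze_factor(240, 60), 3)
  expect_equal(compute_squeeze_factor(30, 60), -0.5)
  expect_error(compute_squeeze_factor(10, 0), "positive")
  # randomized inputs against the formula
  req <- runif(200, 1, 500); av <- runif(200, 1, 500)
  expect_equal(compute_squeeze_factor(req, av), req / av - 1)
})

test_that("delay three triggers strictly above the squeeze threshold", {
  d <- assess_delays(1:5, 1L, c(-0.5, 0, 3, 3.01, 100), PS, 1L)
  expect_equal(d$d3, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  ps0 <- PS
  ps0$scalars$delay1_prob <- 0
  ps0$scalars$delay2_prob <- 0
  d0 <- assess_delays(1:3, 1L, rep(0, 3), ps0, 1L)
  expect_false(any(unlist(d0)))
  # delay-one frequency matches its probability
  d1 <- assess_delays(1:10000, 1L, rep(0, 10000), PS, 1L)
  expect_within_binom(sum(d1$d1), 10000, PS$scalars$delay1_prob)
  # scenario disabling of delay three
  ps3 <- with_overrides(PS, delay3_disabled = "delivery_bemonc")
  d3 <- assess_delays(1:3, 1L, rep(10, 3), ps3, 1L,
                      hsi_type = "delivery_bemonc")
  expect_false(any(d3$d3))
})

test_that("intervention delivery is the product of quality factors", {
  ids <- 1:10000
  # competence zero blocks delivery entirely
  ps0 <- PS
  ps0$interventions$competence_prob[ps0$interventions$name == "iptp"] <- 0
  expect_false(any(attempt_intervention_delivery("iptp", ids, 1L, ps0, 1L,
                                                 level = "health_centre")))
  # quality pinned to one delivers always
  psq <- with_overrides(PS, quality_max = "anc_contact")
  expect_true(all(attempt_intervention_delivery("iptp", ids, 1L, psq, 1L,
                                                level = "health_centre")))
  # one consumable at 0.8 and competence 0.9: frequency ~ 0.72
  ps1 <- PS
  ps1$consumables$availability[ps1$consumables$intervention == "iptp"] <- 0.8
  ps1$interventions$competence_prob[ps1$interventions$name == "iptp"] <- 0.9
  got <- sum(attempt_intervention_delivery("iptp", ids, 2L, ps1, 1L,
                                           level = "health_centre"))
  expect_within_binom(got, length(ids), 0.72)
  # comprehensive EmONC surgery cannot happen outside a hospital
  expect_false(any(attempt_intervention_delivery("caesarean_section", 1:50, 1L,
                                                 PS, 1L,
                                                 level = "health_centre")))
  # a scenario delivery-probability override replaces the whole product
  ps9 <- with_overrides(PS, delivery_prob = c(prophylactic = NA, bemonc = 0.9,
                                              cemonc = NA))
  got9 <- sum(attempt_intervention_delivery("uterotonics", ids, 3L, ps9, 1L,
                                            level = "health_centre"))
  expect_within_binom(got9, length(ids), 0.9)
  # a disabled service never delivers
  psoff <- with_overrides(PS, service_off = "pnc_neonatal")
  expect_false(any(attempt_intervention_delivery("neonatal_antibiotics", ids,
                                                 1L, psoff, 1L)))
})

test_that("execute_hsi accounts minutes, squeeze and delays per event", {
  ev <- data.frame(id = c(1, 2), hsi_type = "anc_contact",
                   level = "health_centre", day = 1,
                   stringsAsFactors = FALSE)
  ev$interventions <- list(c("iron_folic_acid", "iptp"), character(0))
  psq <- with_overrides(PS, quality_max = "anc_contact")
  out <- execute_hsi(ev, psq, seed = 1L, m = 1L,
                     avail_per_day = c(health_centre = 480, hospital = 480))
  # a routine ANC contact takes 12 minutes of nursing time; the preventative
  # bundle is delivered in full under pinned quality
  expect_equal(out$nursing_minutes, c(12, 12))
  expect_equal(out$delivered[[1]], c("iron_folic_acid", "iptp"))
  expect_equal(out$delivered[[2]], character(0))
  expect_false(any(out$d3))
  # an exhausted ledger still executes the event but flags delay three
  out2 <- execute_hsi(ev, psq, seed = 1L, m = 1L,
                      avail_per_day = c(health_centre = 1e-5, hospital = 480))
  expect_true(all(out2$squeeze > PS$scalars$squeeze_threshold))
  ev_bad <- ev; ev_bad$hsi_type <- "dentistry"
  expect_error(execute_hsi(ev_bad, PS, 1L, 1L,
                           c(health_centre = 480, hospital = 480)), "unknown")
})

test_that("sequential ledger depletion raises squeeze for later events", {
  sq <- maternalsim:::ledger_squeeze(rep(60, 4), rep("health_centre", 4),
                                     rep(1, 4),
                                     c(health_centre = 120, hospital = 480))
  # 120 available: events see 120, 60, ~0 remaining
  expect_equal(sq[1], 60 / 120 - 1)
  expect_equal(sq[2], 60 / 60 - 1)
  expect_gt(sq[3], PS$scalars$squeeze_threshold)
  expect_gte(sq[4], sq[3])
})
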