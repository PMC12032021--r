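test_that("onset probability composes relative risks multiplicatively with clipping", {
  expect_equal(onset_probability(0.01, 2.0), 0.02)
  expect_equal(onset_probability(0.6, 2.0), 1.0)
  expect_equal(onset_probability(0.37), 0.37)
  expect_equal(onset_probability(0.01, c(2, 3)), 0.06)
  expect_error(onset_probability(0.01, 0), "strictly positive")
  expect_error(onset_probability(1.2), "\\[0,1\\]")
})

test_that("labour is classified by standard gestational cut-points", {
  expect_equal(determine_labour_category(34 * 7), "preterm")
  expect_equal(determine_labour_category(39 * 7), "term")
  expect_equal(determine_labour_category(42 * 7), "post-term")
  # boundaries: 37 completed weeks is term, one day less is preterm
  expect_equal(determine_labour_category(259), "term")
  expect_equal(determine_labour_category(258), "preterm")
  expect_equal(determine_labour_category(293), "term")
})

test_that("antenatal cycle advances gestation and only fires configured risks", {
  ps0 <- PS
  ps0$conditions$baseline_risk <- 0
  ps0$conditions$birth_risk <- 0
  preg <- make_preg(50, seed = 5L, gm = 3L)
  res <- apply_antenatal_cycle(preg, ps0, seed = 5L, m = 10L)
  expect_equal(res$preg$gm, preg$gm + 1L)
  expect_equal(nrow(res$events), 0)
  expect_false(any(res$preg$ended))
  expect_false(any(res$preg$anaemia))
  # a certain antenatal stillbirth ends the pregnancy (and only that)
  ps1 <- ps0
  ps1$conditions$baseline_risk[ps1$conditions$name == "stillbirth_antenatal"] <- 1
  preg5 <- make_preg(20, seed = 6L, gm = 5L)
  res1 <- apply_antenatal_cycle(preg5, ps1, seed = 6L, m = 10L)
  expect_true(all(res1$preg$ended))
  expect_true(all(res1$preg$end_type == "stillbirth_antenatal"))
  expect_error(apply_antenatal_cycle(res1$preg, ps1, 6L, 11L), "ended")
})

test_that("monthly onset draws converge to the configured risk (binomial oracle)", {
  preg <- make_preg(10000, seed = 9L, gm = 2L)
  hits <- maternalsim:::draw_onset(preg, "maternal_anaemia", PS, seed = 9L,
                                   t = 4L)
  p <- PS$conditions$baseline_risk[PS$conditions$name == "maternal_anaemia"]
  expect_within_binom(sum(hits), nrow(preg), p)
  # a relative-risk modifier scales the realised frequency
  preg$malaria_preg <- TRUE
  hits_rr <- maternalsim:::draw_onset(preg, "maternal_anaemia", PS, seed = 9L,
                                      t = 5L)
  rr <- PS$modifiers$rr[PS$modifiers$condition == "maternal_anaemia" &
                          PS$modifiers$flag == "malaria_preg"]
  expect_within_binom(sum(hits_rr), nrow(preg), min(1, p * rr))
})

test_that("hypertensive disease progresses monotonically through severity", {
  ps1 <- PS
  ps1$conditions$progression_prob[!is.na(ps1$conditions$progression_to)] <- 1
  preg <- make_preg(10, seed = 7L, gm = 6L)
  preg$pe <- 1L
  r1 <- apply_progression(preg, ps1, seed = 7L, m = 20L)
  expect_true(all(r1$preg$pe == 2L))
  r2 <- apply_progression(r1$preg, ps1, seed = 7L, m = 21L)
  expect_true(all(r2$preg$pe == 3L))          # mild -> severe -> eclampsia
  expect_equal(unique(r2$events$condition), "eclampsia")
  # zero progression probability leaves everyone unchanged
  ps0 <- PS
  ps0$conditions$progression_prob[] <- 0
  r0 <- apply_progression(preg, ps0, seed = 7L, m = 20L)
  expect_equal(r0$preg$pe, preg$pe)
  # progression frequency matches its probability
  pregN <- make_preg(5000, seed = 8L, gm = 6L)
  pregN$gh <- 1L
  pN <- 0.3
  psN <- PS
  psN$conditions$progression_prob[psN$conditions$name == "gestational_htn_mild"] <- pN
  rN <- apply_progression(pregN, psN, seed = 8L, m = 22L)
  expect_within_binom(sum(rN$preg$gh == 2L), nrow(pregN), pN)
})

test_that("intrapartum complications respect stage structure and modifiers", {
  del <- make_preg(200, seed = 11L, gm = 9L)
  del$clean_birth <- FALSE
  ps0 <- PS
  ps0$conditions$birth_risk <- 0
  d0 <- apply_intrapartum_complications(del, ps0, seed = 11L, m = 30L, stage = 1)
  expect_false(any(d0$obstructed | d0$sepsis_ip | d0$eclampsia_ip | d0$aph_ip))
  d0$obstruction_relieved <- FALSE
  d0$sb_treatment_rr <- 1
  d0 <- apply_intrapartum_complications(d0, ps0, seed = 11L, m = 30L, stage = 2)
  expect_false(any(d0$uterine_rupture | d0$stillbirth_ip))
  # untreated obstructed labour raises the uterine rupture risk
  delN <- make_preg(10000, seed = 12L, gm = 9L)
  delN$clean_birth <- FALSE
  delN$obstructed <- TRUE
  delN$obstruction_relieved <- FALSE
  delN$sb_treatment_rr <- 1
  d2 <- apply_intrapartum_complications(delN, PS, seed = 12L, m = 30L,
                                        stage = 2)
  base <- PS$conditions$birth_risk[PS$conditions$name == "uterine_rupture"]
  rr <- PS$modifiers$rr[PS$modifiers$condition == "uterine_rupture"]
  expect_within_binom(sum(d2$uterine_rupture), nrow(delN), min(1, base * rr))
})

test_that("postnatal and neonatal cycles are phase- and window-gated", {
  rec <- make_preg(300, seed = 13L, gm = 9L)
  rec$amtsl_rr <- 1
  expect_error(apply_postnatal_neonatal_cycle(rec, 7, "mother", PS, 13L, 40L),
               "window")
  wk0 <- apply_postnatal_neonatal_cycle(rec, 0, "mother", PS, 13L, 40L)
  expect_true(!is.null(wk0$pph_primary))
  expect_null(wk0$pph_secondary)    # secondary haemorrhage never at birth
  wk2 <- apply_postnatal_neonatal_cycle(rec, 2, "mother", PS, 13L, 40L)
  expect_null(wk2$pph_primary)
  # term newborns carry no respiratory-distress risk
  nb <- data.frame(id = seq_len(400) + 1e6, preterm = FALSE,
                   low_birth_weight = FALSE, home_birth = FALSE,
                   steroid_rr = 1, enc_rr = 1)
  expect_error(apply_postnatal_neonatal_cycle(nb, 4, "newborn", PS, 13L, 40L),
               "window")
  n0 <- apply_postnatal_neonatal_cycle(nb, 0, "newborn", PS, 13L, 40L)
  expect_false(any(n0$preterm_rds))
  nb$preterm <- TRUE
  n1 <- apply_postnatal_neonatal_cycle(nb, 0, "newborn", PS, 13L, 41L)
  p_rds <- PS$conditions$birth_risk[PS$conditions$name == "preterm_rds"]
  expect_within_binom(sum(n1$preterm_rds), nrow(nb), p_rds)
})
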