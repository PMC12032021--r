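test_that("period means require every reporting year", {
  v <- stats::setNames(1:8, 2023:2030)
  expect_equal(per_run_period_mean(v), 4.5)
  expect_equal(per_run_period_mean(stats::setNames(rep(7, 8), 2023:2030)), 7)
  expect_error(per_run_period_mean(v[-3]), "missing year")
  set.seed(1)
  x <- stats::setNames(rnorm(8), 2023:2030)
  expect_equal(per_run_period_mean(x), mean(x))
})

test_that("across-run summaries behave like t intervals", {
  s <- across_run_summary(rep(5, 10))
  expect_equal(c(s$mean, s$lo, s$hi), c(5, 5, 5))
  set.seed(2)
  x <- rnorm(20, 10, 2)
  s2 <- across_run_summary(x)
  expect_equal(s2$hi - s2$mean, s2$mean - s2$lo) # symmetric about the mean
  tt <- stats::t.test(x)
  expect_equal(c(s2$lo, s2$hi), as.numeric(tt$conf.int))
  s3 <- across_run_summary(x, method = "normal")
  expect_lt(s3$hi - s3$lo, s2$hi - s2$lo)  # normal interval is narrower
  expect_error(across_run_summary(1), "at least 2")
})

test_that("paired differences subtract run-wise before summarising", {
  sq <- c(10, 11, 12, 13)
  expect_equal(paired_difference_summary(sq, sq)$mean, 0)
  expect_equal(paired_difference_summary(sq, sq)$lo, 0)
  d <- paired_difference_summary(sq, sq + 2.5)
  expect_equal(d$mean, 2.5)
  expect_equal(d$lo, 2.5)
  set.seed(3)
  a <- rnorm(20); b <- rnorm(20)
  d2 <- paired_difference_summary(a, b)
  expect_equal(d2$mean, mean(b - a))
  expect_equal(c(d2$lo, d2$hi), as.numeric(stats::t.test(b - a)$conf.int))
  expect_error(paired_difference_summary(1:3, 1:4), "differ")
})

test_that("percentage differences are withheld when the CI contains zero", {
  # printed-scale worked rows: withheld when the interval straddles zero
  g1 <- gated_percentage_difference(list(mean = -10.5, lo = -22.1, hi = 1.0),
                                    330.5)
  expect_true(g1$withheld)
  g2 <- gated_percentage_difference(list(mean = -16.1, lo = -28.2, hi = -4.0),
                                    330.5)
  expect_false(g2$withheld)
  expect_equal(g2$percentage, -4.9, tolerance = 0.01)
  g3 <- gated_percentage_difference(list(mean = 0, lo = -1, hi = 1), 100)
  expect_true(g3$withheld)
  expect_error(gated_percentage_difference(list(mean = 1, lo = 1, hi = 1), 0),
               "zero")
})

test_that("contact tallies convert to hours at the stated minutes per contact", {
  anc <- tally_contacts_and_hours(8110000, 12)
  expect_equal(anc$hours, 1622000)
  expect_equal(tally_contacts_and_hours(0, 12)$hours, 0)
  pnc <- tally_contacts_and_hours(c(1834000, 1658000), 15)
  expect_equal(pnc$hours, 873000)
  expect_equal(pnc$hours_per_year, 109125)
  expect_error(tally_contacts_and_hours(-1, 12), "non-negative")
})

test_that("maximum ability to pay multiplies significant DALY components by the CET", {
  expect_equal(max_ability_to_pay(3633832, TRUE, 62.3) / 1e6, 226.4,
               tolerance = 0.001)
  expect_equal(max_ability_to_pay(0, TRUE, 62.3), 0)
  # a non-significant maternal component contributes nothing
  expect_equal(max_ability_to_pay(c(24095, 424940), c(FALSE, TRUE), 62.3) / 1e6,
               26.5, tolerance = 0.002)
  expect_error(max_ability_to_pay(1, TRUE, 0), "positive")
})

test_that("health-spending projection compounds per-capita growth from 2015", {
  one <- data.frame(year = 2015, population = 1e6)
  expect_equal(project_total_health_spending(one, 40), 4e7)
  flat <- data.frame(year = 2023:2030, population = 1e6)
  expect_equal(project_total_health_spending(flat, 40, growth = 0),
               8 * 4e7)
  # arithmetic oracle over a growing population
  pop <- data.frame(year = 2023:2030,
                    population = round(2e7 * 1.025^(0:7)))
  got <- project_total_health_spending(pop, 40, 0.009)
  oracle <- sum(pop$population * 40 * 1.009^(pop$year - 2015))
  expect_equal(got, oracle)
  expect_error(project_total_health_spending(one, -1), "positive")
})

test_that("run summaries are invariant to ordering and rescale linearly", {
  mk_run <- function(scen, idx, shift = 0, ratio = 1) {
    a <- data.frame(year = 2023:2030,
                    mmr = 300 + shift + idx,
                    maternal_deaths = (100 + shift + idx),
                    live_births = 1000)
    a$nmr <- 15; a$sbr <- 16
    a$neonatal_deaths <- 50; a$stillbirths <- 20
    a$maternal_dalys <- 10 * (100 + shift + idx); a$neonatal_dalys <- 500
    structure(list(scenario = scen, run_index = idx, seed = idx,
                   ratio = ratio, annual = a), class = "msim_run")
  }
  runs <- c(lapply(1:4, function(i) mk_run("SQ", i)),
            lapply(1:4, function(i) mk_run("X", i, shift = -30)))
  s1 <- summarise_runs(runs, outcomes = c("mmr", "maternal_deaths"))
  s2 <- summarise_runs(rev(runs), outcomes = c("mmr", "maternal_deaths"))
  expect_equal(s1, s2)
  x <- s1[s1$scenario == "X" & s1$outcome == "mmr", ]
  expect_equal(x$diff, -30)
  expect_false(x$withheld)
  expect_equal(x$pct_diff, 100 * -30 / (300 + 2.5), tolerance = 1e-10)
  # linear outcomes scale with the model-to-real ratio; rates do not
  runs58 <- c(lapply(1:4, function(i) mk_run("SQ", i, ratio = 58)),
              lapply(1:4, function(i) mk_run("X", i, -30, ratio = 58)))
  s58 <- summarise_runs(runs58, outcomes = c("mmr", "maternal_deaths"))
  expect_equal(s58$mean[s58$outcome == "maternal_deaths"],
               58 * s1$mean[s1$outcome == "maternal_deaths"])
  expect_equal(s58$mean[s58$outcome == "mmr"], s1$mean[s1$outcome == "mmr"])
  expect_error(summarise_runs(runs, comparator = "Y"), "comparator")
})

test_that("economics report gates non-significant components to zero", {
  mk <- function(scen, idx, md, nd, jitter) {
    a <- data.frame(year = 2023:2030, mmr = 300, nmr = 15, sbr = 16,
                    live_births = 1000, maternal_deaths = 10,
                    neonatal_deaths = 20, stillbirths = 5,
                    maternal_dalys = md + jitter[idx],
                    neonatal_dalys = nd + jitter[idx])
    structure(list(scenario = scen, run_index = idx, seed = idx, ratio = 1,
                   annual = a), class = "msim_run")
  }
  j <- c(-30, -10, 10, 30)
  runs <- c(lapply(1:4, function(i) mk("SQ", i, 1000, 2000, j)),
            # maternal difference straddles zero; neonatal clearly averts
            lapply(1:4, function(i) mk("X", i, 1000, 1500, j * 2)))
  s <- summarise_runs(runs, outcomes = c("maternal_dalys", "neonatal_dalys"))
  e <- economics_report(s, cet = 62.3)
  expect_equal(e$dalys_averted, 500 * 8)
  expect_equal(e$max_ability_to_pay_usd, 500 * 8 * 62.3)
})
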