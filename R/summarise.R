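# Run aggregation: the mean-of-annual-means statistic, across-run confidence
# intervals, paired run differences against the comparator, CI-gated
# percentage differences, healthcare-worker time accounting and
# maximum-ability-to-pay economics.

#' Mean of annual values over a reporting period
#'
#' @param annual_values named numeric vector (names = years) or data frame
#'   with columns `year` and `value`.
#' @param years integer vector of required years (default 2023-2030).
#' @return arithmetic mean over the period; error if a year is missing.
#' @export
per_run_period_mean <- function(annual_values, years = 2023:2030) {
  if (is.data.frame(annual_values))
    annual_values <- stats::setNames(annual_values$value, annual_values$year)
  miss <- setdiff(as.character(years), names(annual_values))
  if (length(miss))
    stop("missing year(s) in annual series: ", paste(miss, collapse = ", "))
  mean(annual_values[as.character(years)])
}

#' Across-run mean and 95% confidence interval
#'
#' @param per_run_values numeric vector of per-run statistics (n >= 2).
#' @param level confidence level.
#' @param method `"t"` (default; t quantile on n-1 df) or `"normal"`.
#' @return list `mean`, `lo`, `hi`, `n`.
#' @export
across_run_summary <- function(per_run_values, level = 0.95, method = "t") {
  n <- length(per_run_values)
  if (n < 2) stop("need at least 2 runs")
  mu <- mean(per_run_values)
  se <- stats::sd(per_run_values) / sqrt(n)
  q <- switch(method,
              t = stats::qt(1 - (1 - level) / 2, df = n - 1),
              normal = stats::qnorm(1 - (1 - level) / 2),
              stop("method must be 't' or 'normal'"))
  list(mean = mu, lo = mu - q * se, hi = mu + q * se, n = n)
}

#' Paired difference between scenario and comparator runs
#'
#' Differences are taken per matched run index, then summarised across runs.
#'
#' @param sq_runs,scenario_runs numeric vectors of per-run period means,
#'   matched by run index (equal length).
#' @param level,method passed to [across_run_summary()].
#' @return list `mean`, `lo`, `hi`, `n`.
#' @export
paired_difference_summary <- function(sq_runs, scenario_runs, level = 0.95,
                                      method = "t") {
  if (length(sq_runs) != length(scenario_runs))
    stop("run counts differ between scenario and comparator")
  across_run_summary(scenario_runs - sq_runs, level = level, method = method)
}

#' CI-gated percentage difference from the comparator
#'
#' The percentage difference is only reported when the difference's 95%
#' confidence interval excludes 0; otherwise it is withheld (`NA`).
#'
#' @param diff list with `mean`, `lo`, `hi` (from
#'   [paired_difference_summary()]).
#' @param sq_mean comparator period mean (nonzero).
#' @return list `percentage` (NA if withheld), `withheld` (logical).
#' @export
gated_percentage_difference <- function(diff, sq_mean) {
  if (sq_mean == 0) stop("comparator mean is zero; percentage undefined")
  excludes0 <- diff$lo > 0 || diff$hi < 0
  if (!excludes0) return(list(percentage = NA_real_, withheld = TRUE))
  list(percentage = 100 * diff$mean / sq_mean, withheld = FALSE)
}

#' Contact counts to healthcare-worker hours
#'
#' @param contacts number of contacts over the period.
#' @param minutes_per_contact minutes of nursing/midwifery time per contact
#'   (12 for ANC, 15 for PNC by default).
#' @param period_years length of the reporting period in years (default 8).
#' @return list `contacts`, `hours`, `hours_per_year`.
#' @export
tally_contacts_and_hours <- function(contacts, minutes_per_contact,
                                     period_years = 8) {
  if (any(contacts < 0)) stop("contact counts must be non-negative")
  hours <- sum(contacts * minutes_per_contact) / 60
  list(contacts = sum(contacts), hours = hours,
       hours_per_year = hours / period_years)
}

#' Maximum ability to pay for a scenario's health gains
#'
#' The product of incremental DALYs averted (relative to the comparator) and
#' the cost-effectiveness threshold. Components whose difference CI contains 0
#' contribute nothing.
#'
#' @param dalys_averted numeric vector of DALYs-averted components (e.g.
#'   maternal, neonatal).
#' @param significant logical vector: does the component's CI exclude 0?
#' @param cet cost-effectiveness threshold in USD per DALY (> 0).
#' @return USD value.
#' @export
max_ability_to_pay <- function(dalys_averted, significant, cet = 62.3) {
  if (cet <= 0) stop("cet must be positive")
  if (length(dalys_averted) != length(significant))
    stop("components and significance flags differ in length")
  sum(dalys_averted[significant]) * cet
}

#' Projected total national health spending over a period
#'
#' Per-capita spending grows from its 2015 value at a fixed annual rate;
#' yearly totals are population times projected per-capita spending.
#'
#' @param population_by_year data frame with `year` and `population`.
#' @param per_capita_2015 health spending per capita in 2015 USD.
#' @param growth annualised growth rate (default 0.009).
#' @return total USD over the supplied years.
#' @export
project_total_health_spending <- function(population_by_year, per_capita_2015,
                                          growth = 0.009) {
  if (per_capita_2015 <= 0 || any(population_by_year$population <= 0))
    stop("inputs must be positive")
  sum(population_by_year$population * per_capita_2015 *
        (1 + growth)^(population_by_year$year - 2015))
}

run_outcome_series <- function(run, outcome) {
  a <- run$annual
  v <- switch(outcome,
    mmr = a$mmr, nmr = a$nmr, sbr = a$sbr,
    maternal_deaths = a$maternal_deaths * run$ratio,
    neonatal_deaths = a$neonatal_deaths * run$ratio,
    stillbirths = a$stillbirths * run$ratio,
    maternal_dalys = a$maternal_dalys * run$ratio,
    neonatal_dalys = a$neonatal_dalys * run$ratio,
    anc_contacts = a$anc_contacts * run$ratio,
    pnc_maternal_contacts = a$pnc_maternal_contacts * run$ratio,
    pnc_neonatal_contacts = a$pnc_neonatal_contacts * run$ratio,
    live_births = a$live_births * run$ratio,
    population = a$population * run$ratio,
    stop("unknown outcome: ", outcome))
  stats::setNames(v, a$year)
}

#' Summarise a set of runs across scenarios
#'
#' For each scenario and outcome: the across-run mean and 95% CI of the
#' period mean (2023-2030 by default), the paired difference from the
#' comparator with its CI, and the CI-gated percentage difference. Totals
#' (deaths, DALYs, contacts) are summed over the period rather than averaged;
#' rates are period means of annual rates. Counts are rescaled to the real
#' population.
#'
#' @param runs list of `msim_run` objects (several runs per scenario, matched
#'   run indices across scenarios).
#' @param outcomes character vector of outcome names.
#' @param years reporting period.
#' @param comparator comparator scenario short name (default `"SQ"`).
#' @param method CI method.
#' @return data frame of class `msim_summary`.
#' @export
summarise_runs <- function(runs, outcomes = c("mmr", "nmr", "sbr",
                                              "maternal_deaths",
                                              "neonatal_deaths",
                                              "maternal_dalys",
                                              "neonatal_dalys"),
                           years = 2023:2030, comparator = "SQ",
                           method = "t") {
  scen <- vapply(runs, function(r) r$scenario, character(1))
  if (!comparator %in% scen) stop("comparator scenario missing: ", comparator)
  totals <- c("maternal_deaths", "neonatal_deaths", "stillbirths",
              "maternal_dalys", "neonatal_dalys", "anc_contacts",
              "pnc_maternal_contacts", "pnc_neonatal_contacts", "live_births")
  per_run_stat <- function(r, outcome) {
    v <- per_run_period_mean(run_outcome_series(r, outcome), years)
    if (outcome %in% totals) v * length(years) else v
  }
  rows <- list()
  for (outcome in outcomes) {
    by_scen <- lapply(split(runs, scen), function(rs) {
      rs <- rs[order(vapply(rs, function(r) r$run_index, numeric(1)))]
      vapply(rs, per_run_stat, numeric(1), outcome = outcome)
    })
    sq <- by_scen[[comparator]]
    sq_sum <- across_run_summary(sq, method = method)
    for (s in names(by_scen)) {
      v <- by_scen[[s]]
      smry <- across_run_summary(v, method = method)
      if (s == comparator) {
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = s, outcome = outcome, mean = smry$mean, lo = smry$lo,
          hi = smry$hi, diff = NA_real_, diff_lo = NA_real_,
          diff_hi = NA_real_, pct_diff = NA_real_, withheld = NA)
        next
      }
      d <- paired_difference_summary(sq, v, method = method)
      g <- gated_percentage_difference(d, sq_sum$mean)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = s, outcome = outcome, mean = smry$mean, lo = smry$lo,
        hi = smry$hi, diff = d$mean, diff_lo = d$lo, diff_hi = d$hi,
        pct_diff = g$percentage, withheld = g$withheld)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("msim_summary", "data.frame")
  out
}

#' @export
print.msim_summary <- function(x, digits = 1, ...) {
  y <- as.data.frame(x)
  for (f in c("mean", "lo", "hi", "diff", "diff_lo", "diff_hi", "pct_diff"))
    y[[f]] <- round(y[[f]], digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Economics report: maximum ability to pay per scenario
#'
#' Uses the DALYs-averted components (maternal, neonatal) from a run summary;
#' non-significant components (difference CI containing 0) contribute 0.
#'
#' @param summary an `msim_summary` containing `maternal_dalys` and
#'   `neonatal_dalys` outcomes.
#' @param cet cost-effectiveness threshold (USD per DALY).
#' @param spending optional projected total health spending (USD) to express
#'   the result as a percentage.
#' @return data frame: scenario, dalys_averted, max_ability_to_pay_usd, and
#'   optionally pct_of_spending.
#' @export
economics_report <- function(summary, cet = 62.3, spending = NULL) {
  scen <- setdiff(unique(summary$scenario),
                  summary$scenario[is.na(summary$diff)])
  rows <- lapply(scen, function(s) {
    comp <- summary[summary$scenario == s &
                      summary$outcome %in% c("maternal_dalys",
                                             "neonatal_dalys"), ]
    averted <- -comp$diff   # DALYs averted = negative difference
    sig <- !comp$withheld & averted > 0
    matp <- max_ability_to_pay(averted, sig, cet)
    data.frame(scenario = s, dalys_averted = sum(averted[sig]),
               max_ability_to_pay_usd = matp,
               pct_of_spending = if (!is.null(spending))
                 100 * matp / spending else NA_real_)
  })
  do.call(rbind, rows)
}
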