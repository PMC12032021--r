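# Outcomes: death probabilities under treatment and delays, death application,
# DALY accrual (YLD + YLL) and the headline period rates (MMR, NMR, SBR).

#' Combine disability weights under multimorbidity
#'
#' Weights are combined additively and capped at 1.0.
#'
#' @param weights numeric vector, each in \[0,1\].
#' @return combined weight in \[0,1\].
#' @export
combine_disability_weights <- function(weights) {
  if (length(weights) && any(weights < 0 | weights > 1))
    stop("disability weights must be in [0,1]")
  min(1, sum(weights))
}

#' Case-fatality probability adjusted for treatment and delays
#'
#' Each delivered treatment multiplies the case-fatality risk by an effective
#' relative risk. Delays shrink the treatment effect towards no effect: with
#' `k` delays experienced, the effective relative risk is
#' `1 - (1 - rr) * (1 - attenuation)^k`. An untreated case keeps the raw CFR.
#'
#' @param cfr untreated case-fatality risk in \[0,1\].
#' @param treatment_rrs relative risks of the delivered treatments, each in
#'   (0,1\].
#' @param delays logical vector (or count) of delays experienced.
#' @param attenuation per-delay attenuation fraction in \[0,1).
#' @return adjusted probability of death.
#' @export
adjusted_death_probability <- function(cfr, treatment_rrs = numeric(0),
                                       delays = c(FALSE, FALSE, FALSE),
                                       attenuation = 0.25) {
  if (any(cfr < 0 | cfr > 1)) stop("cfr must be in [0,1]")
  if (length(treatment_rrs) &&
      any(treatment_rrs <= 0 | treatment_rrs > 1))
    stop("treatment relative risks must be in (0,1]")
  if (attenuation < 0 || attenuation >= 1)
    stop("attenuation must be in [0,1)")
  k <- if (is.logical(delays)) sum(delays) else sum(delays)
  eff <- 1 - (1 - treatment_rrs) * (1 - attenuation)^k
  cfr * prod(eff)
}

#' Apply a death draw for a fatal condition episode
#'
#' Bernoulli draw at the adjusted probability via the keyed RNG; on death the
#' record is marked dead with the cause and category taken from the condition
#' registry. Vectorised over episodes.
#'
#' @param ids unit ids; `t` time index; `seed` run seed.
#' @param p adjusted death probability per episode.
#' @param condition condition name (for the RNG channel and the category).
#' @param ps parameter set.
#' @return logical vector: died.
#' @export
apply_death <- function(ids, t, p, condition, ps, seed) {
  ci <- condition_index(ps, condition)
  if (is.na(ci)) stop("unknown condition: ", condition)
  u <- hash_unif(seed, ids, t, rng_channels$death + ci)
  u < p
}

#' Remaining life expectancy from the reference life table
#'
#' Step lookup at the greatest tabulated age not exceeding the age at death.
#'
#' @param age age at death, years.
#' @param life_table data frame with `age` and `expectancy`.
#' @return years of life lost per death.
#' @export
life_expectancy_at <- function(age, life_table) {
  life_table$expectancy[pmax(1L, findInterval(age, life_table$age))]
}

#' Accrue DALYs into a yearly ledger
#'
#' YLD: for every person, the monthly disability weights of their active
#' conditions are combined additively with the 1.0 cap and summed over months
#' affected, divided by 12. YLL: each death contributes the remaining life
#' expectancy at the age of death from the reference table. Categories are
#' `"maternal"` and `"neonatal"`; stillbirths accrue no YLD or YLL.
#'
#' @param episodes data frame of condition episodes: `person`, `condition`,
#'   `category`, `months` (duration in months, fractional allowed), `year`.
#' @param deaths data frame of deaths: `person`, `category`, `age_years`,
#'   `year`.
#' @param ps parameter set.
#' @return data frame (year, category, yld, yll, dalys).
#' @export
accrue_dalys <- function(episodes, deaths, ps) {
  cn <- ps$conditions
  out <- list()
  if (nrow(episodes)) {
    episodes$dw <- cn$disability_weight[match(episodes$condition, cn$name)]
    # Additive-capped combination applied per person-month: expand each
    # episode into whole and fractional months, cap the per-month sum at 1.
    key <- paste(episodes$person, episodes$year, episodes$category)
    yld <- vapply(split(episodes, key), function(e) {
      mlen <- max(1L, ceiling(max(e$months)))
      grid <- matrix(0, nrow = nrow(e), ncol = mlen)
      for (i in seq_len(nrow(e))) {
        full <- floor(e$months[i]); frac <- e$months[i] - full
        if (full > 0) grid[i, seq_len(full)] <- e$dw[i]
        if (frac > 0) grid[i, full + 1L] <- e$dw[i] * frac
      }
      sum(pmin(ps$scalars$disability_cap, colSums(grid))) / 12
    }, numeric(1))
    first <- !duplicated(key)
    out$yld <- data.frame(year = episodes$year[first],
                          category = episodes$category[first],
                          yld = unname(yld[match(key[first], names(yld))]))
  }
  yll <- NULL
  if (nrow(deaths)) {
    deaths$yll <- life_expectancy_at(deaths$age_years, ps$life_table)
    yll <- stats::aggregate(yll ~ year + category, deaths, sum)
  }
  yrs <- sort(unique(c(if (!is.null(out$yld)) out$yld$year, yll$year)))
  res <- expand.grid(year = yrs, category = c("maternal", "neonatal"),
                     stringsAsFactors = FALSE)
  res$yld <- rep(0, nrow(res)); res$yll <- rep(0, nrow(res))
  if (!is.null(out$yld)) {
    agg <- stats::aggregate(yld ~ year + category, out$yld, sum)
    i <- match(paste(res$year, res$category), paste(agg$year, agg$category))
    res$yld[!is.na(i)] <- agg$yld[i[!is.na(i)]]
  }
  if (!is.null(yll)) {
    i <- match(paste(res$year, res$category), paste(yll$year, yll$category))
    res$yll[!is.na(i)] <- yll$yll[i[!is.na(i)]]
  }
  res$dalys <- res$yld + res$yll
  res
}

#' Headline period rates from counts
#'
#' MMR: maternal deaths per 100,000 live births. NMR: neonatal deaths per
#' 1,000 live births. SBR: stillbirths per 1,000 births, where the denominator
#' is total births (live + still) by default, or live births only.
#'
#' @param live_births,maternal_deaths,neonatal_deaths,stillbirths counts.
#' @param sbr_denominator `"total"` (default) or `"live"`.
#' @return named list `mmr`, `nmr`, `sbr`.
#' @export
compute_period_rates <- function(live_births, maternal_deaths, neonatal_deaths,
                                 stillbirths, sbr_denominator = "total") {
  if (any(live_births <= 0)) stop("live births must be positive for rates")
  denom_sb <- switch(sbr_denominator,
                     total = live_births + stillbirths,
                     live = live_births,
                     stop("sbr_denominator must be 'total' or 'live'"))
  list(mmr = maternal_deaths / live_births * 1e5,
       nmr = neonatal_deaths / live_births * 1e3,
       sbr = stillbirths / denom_sb * 1e3)
}
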