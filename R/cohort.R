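# Population bookkeeping: initialisation, ageing, background (non-obstetric)
# mortality, and monthly conception. Time runs on a monthly master clock; month
# indices count from January 2010 = month 0 by convention (see month_index).

#' Convert a calendar year (and month) to the simulation month index
#' @param year calendar year.
#' @param month month of year, 1-12.
#' @return integer month index with January 2010 = 0.
#' @export
month_index <- function(year, month = 1) (year - 2010L) * 12L + (month - 1L)

#' Calendar year of a simulation month index
#' @param m month index.
#' @return integer year.
#' @export
index_year <- function(m) 2010L + m %/% 12L

#' Initialise a simulated population
#'
#' Wraps [make_fixture_population()] and records the model-to-real population
#' ratio used later to rescale counts to the real population.
#'
#' @param n number of simulated persons (>= 1).
#' @param ratio model-to-real ratio; `n * ratio` is the represented real
#'   population.
#' @param seed integer seed.
#' @param ps parameter set.
#' @return a population data frame with attributes `ratio` and
#'   `real_population`.
#' @export
initialise_population <- function(n, ratio = 58, seed = 1L,
                                  ps = generate_default_parameters()) {
  if (n < 1) stop("n must be at least 1")
  if (ratio <= 0) stop("ratio must be positive")
  pop <- make_fixture_population(n, seed = seed, ps = ps)
  attr(pop, "ratio") <- ratio
  attr(pop, "real_population") <- n * ratio
  pop
}

background_rate_for_age <- function(age, rates) {
  out <- numeric(length(age))
  out[age < 5] <- rates[["under5"]]
  out[age >= 5 & age < 15] <- rates[["age5_14"]]
  out[age >= 15 & age < 50] <- rates[["age15_49"]]
  out[age >= 50 & age < 70] <- rates[["age50_69"]]
  out[age >= 70] <- rates[["age70plus"]]
  out
}

#' Monthly demographic update: ageing and background mortality
#'
#' Ages every living person by one month and applies configured age-specific
#' background (non-obstetric, non-neonatal) death rates. Pregnancy fields are
#' not touched here; a woman who dies of a background cause while pregnant has
#' her pregnancy closed by the engine. Dead persons are never mutated.
#'
#' @param pop population data frame.
#' @param m simulation month index.
#' @param ps parameter set.
#' @param seed run seed.
#' @param rates optional override of the age-band monthly rates.
#' @return updated population.
#' @export
monthly_demographic_update <- function(pop, m, ps, seed,
                                       rates = ps$scalars$background_mortality_monthly) {
  alive <- which(pop$alive)
  if (!length(alive)) return(pop)
  pop$age_years[alive] <- pop$age_years[alive] + 1 / 12
  p <- background_rate_for_age(pop$age_years[alive], rates)
  u <- hash_unif(seed, pop$id[alive], m, rng_channels$bg_death)
  dies <- u < p
  if (any(dies)) {
    idx <- alive[dies]
    pop$alive[idx] <- FALSE
    pop$death_m[idx] <- m
    pop$cause_of_death[idx] <- "background"
  }
  pop
}

#' Initiate pregnancies for a simulation month
#'
#' Every living, non-pregnant woman of reproductive age (15-49) who is not in
#' the postnatal window conceives with her age-band monthly probability.
#' Conception clears any postnatal state and registers a new pregnancy record.
#'
#' @param pop population data frame.
#' @param m month index.
#' @param ps parameter set.
#' @param seed run seed.
#' @param prob_override optional single probability overriding the age bands
#'   (used in tests).
#' @return list with updated `pop` and a data frame `new` of conceptions
#'   (columns `mother`, `preg_id`).
#' @export
initiate_pregnancies <- function(pop, m, ps, seed, prob_override = NULL) {
  elig <- which(pop$alive & pop$sex == "F" & !pop$is_pregnant &
                  pop$age_years >= 15 & pop$age_years < 50 &
                  (is.na(pop$postnatal_until_m) | pop$postnatal_until_m <= m))
  if (!length(elig))
    return(list(pop = pop, new = data.frame(mother = numeric(0),
                                            preg_id = numeric(0))))
  if (is.null(prob_override)) {
    cb <- ps$conception
    band <- findInterval(pop$age_years[elig], cb$age_low)
    p <- cb$monthly_prob[pmax(1L, pmin(nrow(cb), band))]
  } else p <- prob_override
  u <- hash_unif(seed, pop$id[elig], m, rng_channels$conception)
  conc <- u < p
  idx <- elig[conc]
  if (!length(idx))
    return(list(pop = pop, new = data.frame(mother = numeric(0),
                                            preg_id = numeric(0))))
  preg_id <- pop$id[idx] * 1e4 + (m %% 1e4)
  pop$is_pregnant[idx] <- TRUE
  pop$preg_id[idx] <- preg_id
  pop$postnatal_until_m[idx] <- NA_real_
  list(pop = pop, new = data.frame(mother = pop$id[idx], preg_id = preg_id))
}
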