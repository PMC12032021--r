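# Simulation engine: monthly master clock over the population, with the
# intrapartum and postnatal/neonatal phases run as nested weekly sub-steps in
# the month of delivery (telescoped to the delivery month for accounting).

MATERNAL_CAUSES <- c("ectopic_pregnancy", "abortion_complications", "eclampsia",
                     "antepartum_haemorrhage", "sepsis_antenatal",
                     "obstructed_labour", "uterine_rupture",
                     "sepsis_intrapartum", "pph_primary", "pph_secondary",
                     "sepsis_postnatal")
NEONATAL_CAUSES <- c("preterm_rds", "prematurity_other",
                     "neonatal_encephalopathy", "neonatal_sepsis")

new_preg_rows <- function(pop, new, m) {
  i <- match(new$mother, pop$id)
  k <- nrow(new)
  f <- rep(FALSE, k)
  data.frame(
    id = new$preg_id, mother = new$mother, conc_m = rep(m, k),
    gm = rep(0L, k),
    age_years = pop$age_years[i], wealth = pop$wealth[i], edu = pop$edu[i],
    urban = pop$urban[i], parity = pop$parity[i],
    malaria_flag = pop$malaria_flag[i], hiv = pop$hiv[i],
    depression = pop$depression[i],
    anaemia = f, gdm = f, syphilis_active = f,
    malaria_preg = f, aph = f, sepsis_ante = f,
    gh = rep(0L, k), pe = rep(0L, k),
    on_ifa = f, on_iptp = f, on_calcium = f, on_antihtn = f,
    htn_detected = f, gdm_detected = f,
    steroids = f, ended = f, end_type = rep(NA_character_, k),
    anc_init = f, anc_first_gm = rep(NA_real_, k), anc_planned = rep(0L, k),
    anc_visits = rep(0L, k),
    stringsAsFactors = FALSE)
}

# Effective relative-risk product per episode given per-treatment delivery
# flags (a named list of logical vectors) and the per-episode delay count.
treatment_factor <- function(delivered, k_delays, ps) {
  n <- length(k_delays)
  f <- rep(1, n)
  att <- ps$scalars$delay_attenuation
  for (nm in names(delivered)) {
    rr <- intervention_row(ps, nm)$treatment_rr
    eff <- 1 - (1 - rr) * (1 - att)^k_delays
    f <- f * ifelse(delivered[[nm]], eff, 1)
  }
  f
}

#' Simulate one model run under one scenario
#'
#' Runs the monthly engine from `start_year` to `end_year` (exclusive) for a
#' population of `n_pop` persons and returns per-year counts, rates, DALYs,
#' health-system-interaction counts and healthcare-worker minutes.
#'
#' All randomness flows through the keyed counter-based RNG, so two runs with
#' the same seed are identical and runs of different scenarios with a shared
#' seed are event-wise paired (common random numbers).
#'
#' @param scenario an `msim_scenario` (or a short name).
#' @param ps base parameter set.
#' @param n_pop model population size.
#' @param ratio model-to-real population ratio.
#' @param start_year,end_year simulation window (calendar years).
#' @param seed integer run seed.
#' @param run_index index recorded in the result (for pairing).
#' @return an object of class `msim_run`.
#' @export
simulate_run <- function(scenario, ps = generate_default_parameters(),
                         n_pop = 7000, ratio = 2000,
                         start_year = 2018, end_year = 2031,
                         seed = 1L, run_index = 1L) {
  if (is.character(scenario)) scenario <- build_scenario(scenario)
  ps_base <- ps
  ps_base$overrides <- NULL
  pop <- initialise_population(n_pop, ratio = ratio, seed = seed, ps = ps)
  preg <- new_preg_rows(pop, data.frame(mother = numeric(0),
                                        preg_id = numeric(0)), 0L)
  years <- start_year:(end_year - 1L)
  nyr <- length(years)
  cnt_fields <- c("live_births", "total_births", "stillbirths",
                  "stillbirth_antenatal", "stillbirth_intrapartum",
                  "maternal_deaths", "neonatal_deaths",
                  "anc_contacts", "pnc_maternal_contacts",
                  "pnc_neonatal_contacts", "inpatient_antenatal_hsi",
                  "facility_deliveries", "home_deliveries",
                  "nursing_minutes", "clinician_minutes", "population")
  cnt <- matrix(0, nyr, length(cnt_fields), dimnames = list(years, cnt_fields))
  mat_cause <- matrix(0, nyr, length(MATERNAL_CAUSES),
                      dimnames = list(years, MATERNAL_CAUSES))
  neo_cause <- matrix(0, nyr, length(NEONATAL_CAUSES),
                      dimnames = list(years, NEONATAL_CAUSES))
  episodes <- list(); deaths <- list()
  yi <- function(m) as.character(index_year(m))
  bump <- function(m, field, x = 1) {
    y <- yi(m)
    if (y %in% rownames(cnt)) cnt[y, field] <<- cnt[y, field] + x
  }
  log_episode <- function(person, condition, category, m) {
    if (!length(person)) return(invisible(NULL))
    dm <- ps$conditions$dw_duration_months[match(condition, ps$conditions$name)]
    episodes[[length(episodes) + 1L]] <<-
      data.frame(person = person, condition = condition, category = category,
                 months = dm, year = index_year(m))
  }
  log_death <- function(person, cause, category, age, m, treated, k_delays) {
    if (!length(person)) return(invisible(NULL))
    deaths[[length(deaths) + 1L]] <<-
      data.frame(person = person, cause = cause, category = category,
                 age_years = age, year = index_year(m), treated = treated,
                 delays = k_delays)
    y <- yi(m)
    if (!y %in% rownames(cnt)) return(invisible(NULL))
    if (category %in% c("maternal-direct", "maternal-indirect")) {
      cnt[y, "maternal_deaths"] <<- cnt[y, "maternal_deaths"] + length(person)
      if (cause[1] %in% colnames(mat_cause))
        mat_cause[y, cause[1]] <<- mat_cause[y, cause[1]] + length(person)
    } else if (category == "neonatal") {
      cnt[y, "neonatal_deaths"] <<- cnt[y, "neonatal_deaths"] + length(person)
      if (cause[1] %in% colnames(neo_cause))
        neo_cause[y, cause[1]] <<- neo_cause[y, cause[1]] + length(person)
    }
  }
  kill_mothers <- function(idx_pop, cause, m) {
    pop$alive[idx_pop] <<- FALSE
    pop$death_m[idx_pop] <<- m
    pop$cause_of_death[idx_pop] <<- cause
    pop$is_pregnant[idx_pop] <<- FALSE
  }
  avail_per_day <- c(
    health_centre = ps$scalars$hcw_daily_minutes_per_1000[["health_centre_nursing"]] *
      n_pop / 1000,
    hospital = ps$scalars$hcw_daily_minutes_per_1000[["hospital_nursing"]] *
      n_pop / 1000)

  ps_eff <- ps
  applied <- FALSE
  eff_m <- scenario$effective_month
  m0 <- month_index(start_year); m1 <- month_index(end_year) - 1L

  for (m in m0:m1) {
    if (!applied && m >= eff_m) {
      women <- pop[pop$alive & pop$sex == "F" & pop$age_years >= 15 &
                     pop$age_years < 50, ]
      ps_eff <- apply_scenario(scenario, ps, m, women = women)
      applied <- TRUE
    }
    ov <- get_overrides(ps_eff)

    # -- demography ---------------------------------------------------------
    pre_alive <- pop$alive
    pop <- monthly_demographic_update(pop, m, ps, seed)
    died_bg <- which(pre_alive & !pop$alive)
    if (length(died_bg) && nrow(preg)) {
      gone <- preg$mother %in% pop$id[died_bg]
      if (any(gone)) {
        preg$ended[gone] <- TRUE
        preg$end_type[gone] <- "background_death"
      }
    }
    conc <- initiate_pregnancies(pop, m, ps, seed)
    pop <- conc$pop
    if (nrow(conc$new)) {
      np <- new_preg_rows(pop, conc$new, m)
      sched <- plan_anc_schedule(np, ps_eff, seed)
      np$anc_init <- sched$initiates
      np$anc_first_gm <- sched$first_gm
      np$anc_planned <- sched$planned_visits
      preg <- rbind(preg, np)
    }
    if (!nrow(preg)) { cnt[yi(m), "population"] <- sum(pop$alive); next }
    preg <- preg[!preg$ended, , drop = FALSE]
    if (!nrow(preg)) { cnt[yi(m), "population"] <- sum(pop$alive); next }

    # -- antenatal monthly cycle -------------------------------------------
    res <- apply_antenatal_cycle(preg, ps_eff, seed, m)
    preg <- res$preg
    events <- res$events

    # antenatal stillbirths / terminations tallied
    for (tt in c("ectopic_pregnancy", "abortion_complications")) {
      idx <- which(preg$ended & preg$end_type == tt)
      if (!length(idx)) next
      # post-abortion / ectopic care: never modified by scenarios
      seeks <- emergency_careseeking(preg$id[idx], m, ps_base, seed)
      delivered <- rep(FALSE, length(idx))
      if (any(seeks))
        delivered[seeks] <- attempt_intervention_delivery(
          "abortion_ectopic_care", preg$id[idx][seeks], m, ps_base, seed,
          level = "hospital")
      cfr <- condition_row(ps, tt)$untreated_cfr
      k <- rep(0L, length(idx))
      p <- cfr * treatment_factor(list(abortion_ectopic_care = delivered), k, ps)
      dies <- apply_death(preg$id[idx], m, p, tt, ps, seed)
      mpos <- match(preg$mother[idx], pop$id)
      log_episode(preg$mother[idx], tt, "maternal", m)
      if (any(dies)) {
        kill_mothers(mpos[dies], tt, m)
        log_death(preg$mother[idx][dies], tt, "maternal-direct",
                  pop$age_years[mpos][dies], m, delivered[dies], k[dies])
      }
      pop$is_pregnant[mpos] <- FALSE
      pop$preg_id[mpos] <- NA_real_
    }
    sb_a <- which(preg$ended & preg$end_type == "stillbirth_antenatal")
    if (length(sb_a)) {
      bump(m, "stillbirth_antenatal", length(sb_a))
      bump(m, "stillbirths", length(sb_a))
      bump(m, "total_births", length(sb_a))
      mpos <- match(preg$mother[sb_a], pop$id)
      pop$is_pregnant[mpos] <- FALSE
      pop$preg_id[mpos] <- NA_real_
      pop$postnatal_until_m[mpos] <- m + 2
    }
    preg <- preg[!preg$ended, , drop = FALSE]

    # -- routine ANC contacts ----------------------------------------------
    if (nrow(preg) && !ov$anc_off && !"anc_contact" %in% ov$service_off) {
      due <- which(preg$anc_init & !is.na(preg$anc_first_gm) &
                     preg$gm >= preg$anc_first_gm &
                     preg$anc_visits < pmin(preg$anc_planned, 8L))
      if (length(due)) {
        preg$anc_visits[due] <- preg$anc_visits[due] + 1L
        bump(m, "anc_contacts", length(due))
        bump(m, "nursing_minutes", length(due) * ps$scalars$anc_minutes)
        ids <- preg$id[due]
        # screening -> detection flags
        bp <- attempt_intervention_delivery("bp_screening", ids, m, ps_eff,
                                            seed, level = "health_centre")
        preg$htn_detected[due] <- preg$htn_detected[due] |
          (bp & (preg$gh[due] > 0 | preg$pe[due] > 0))
        gd <- attempt_intervention_delivery("gdm_screening", ids, m, ps_eff,
                                            seed, level = "health_centre")
        preg$gdm_detected[due] <- preg$gdm_detected[due] | (gd & preg$gdm[due])
        # preventative bundle (state flags drive onset relative risks)
        preg$on_ifa[due] <- preg$on_ifa[due] |
          attempt_intervention_delivery("iron_folic_acid", ids, m, ps_eff,
                                        seed, level = "health_centre")
        preg$on_iptp[due] <- preg$on_iptp[due] |
          attempt_intervention_delivery("iptp", ids, m, ps_eff, seed,
                                        level = "health_centre")
        at_risk <- preg$parity[due] == 0 | preg$pe[due] > 0
        calc <- attempt_intervention_delivery("calcium_supplementation", ids,
                                              m, ps_eff, seed,
                                              level = "health_centre")
        preg$on_calcium[due] <- preg$on_calcium[due] | (calc & at_risk)
        syp <- which(preg$syphilis_active[due])
        if (length(syp)) {
          cured <- attempt_intervention_delivery("syphilis_treatment",
                                                 ids[syp], m, ps_eff, seed,
                                                 level = "health_centre")
          preg$syphilis_active[due[syp][cured]] <- FALSE
        }
        # detected hypertensive disease -> inpatient antenatal management
        if (!"inpatient_antenatal" %in% ov$service_off) {
          inp <- due[preg$htn_detected[due] & (preg$gh[due] >= 2 |
                                                 preg$pe[due] >= 2)]
          inp <- c(inp, due[preg$gdm_detected[due]])
          inp <- unique(inp)
          if (length(inp)) {
            bump(m, "inpatient_antenatal_hsi", length(inp))
            bump(m, "nursing_minutes", length(inp) * 30)
            preg$on_antihtn[inp] <- preg$on_antihtn[inp] |
              attempt_intervention_delivery("antihypertensives", preg$id[inp],
                                            m, ps_eff, seed,
                                            level = "health_centre")
          }
        }
      }
    }

    # -- antenatal emergencies (eclampsia, APH, antenatal sepsis) ----------
    if (nrow(events)) {
      for (cond in c("eclampsia", "antepartum_haemorrhage", "sepsis_antenatal")) {
        er <- unique(events$id[events$condition == cond])
        er <- er[er %in% preg$id]
        if (!length(er)) next
        rows <- match(er, preg$id)
        log_episode(preg$mother[rows], cond, "maternal", m)
        seeks <- emergency_careseeking(er, m, ps_eff, seed,
                                       period = "antenatal")
        off <- "inpatient_antenatal" %in% ov$service_off
        seeks <- seeks & !off
        treats <- strsplit(condition_row(ps, cond)$treatments, ",")[[1]]
        delivered <- stats::setNames(
          rep(list(rep(FALSE, length(er))), length(treats)), treats)
        d1 <- rep(FALSE, length(er)); d2 <- d1; d3 <- d1
        if (any(seeks)) {
          u_day <- hash_unif(seed, er[seeks], m, rng_channels$delivery_day)
          day <- 1L + floor(28 * u_day)
          sq <- ledger_squeeze(rep(30, sum(seeks)),
                               rep("hospital", sum(seeks)), day, avail_per_day)
          dl <- assess_delays(er[seeks], m, sq, ps_eff, seed,
                              hsi_type = "inpatient_antenatal")
          d1[seeks] <- dl$d1; d2[seeks] <- dl$d2; d3[seeks] <- dl$d3
          bump(m, "inpatient_antenatal_hsi", sum(seeks))
          bump(m, "nursing_minutes", sum(seeks) * 30)
          for (tr in treats)
            delivered[[tr]][seeks] <- attempt_intervention_delivery(
              tr, er[seeks], m, ps_eff, seed, level = "hospital")
        }
        k <- as.integer(d1) + as.integer(d2) + as.integer(d3)
        cfr <- condition_row(ps, cond)$untreated_cfr
        p <- cfr * treatment_factor(delivered, k, ps)
        dies <- apply_death(er, m, p, cond, ps, seed)
        if (any(dies)) {
          mpos <- match(preg$mother[rows][dies], pop$id)
          kill_mothers(mpos, cond, m)
          log_death(preg$mother[rows][dies], cond, "maternal-direct",
                    pop$age_years[mpos], m,
                    Reduce(`|`, delivered)[dies], k[dies])
          preg$ended[rows[dies]] <- TRUE
          preg$end_type[rows[dies]] <- "maternal_death"
        }
      }
      preg <- preg[!preg$ended, , drop = FALSE]
    }

    # -- labour onset -------------------------------------------------------
    lab <- integer(0); lab_cat <- character(0)
    if (nrow(preg)) {
      pt_rows <- which(preg$gm %in% 7:8)
      is_pt <- logical(nrow(preg))
      if (length(pt_rows))
        is_pt[pt_rows] <- draw_onset(preg[pt_rows, , drop = FALSE],
                                     "preterm_labour", ps_eff, seed, m)
      term_rows <- which(preg$gm == 9L)
      goes_post <- logical(nrow(preg))
      if (length(term_rows)) {
        u <- hash_unif(seed, preg$id[term_rows], m, rng_channels$postterm)
        goes_post[term_rows] <- u < condition_row(ps, "post_term_pregnancy")$baseline_risk
      }
      lab <- c(which(is_pt), term_rows[!goes_post[term_rows]],
               which(preg$gm >= 10L))
      lab <- unique(lab)
      if (length(lab)) {
        uj <- hash_unif(seed, preg$id[lab], m, rng_channels$gest_jitter)
        gd <- numeric(length(lab))
        pt <- lab %in% which(is_pt)
        po <- preg$gm[lab] >= 10L
        gd[pt] <- 196 + uj[pt] * 62
        gd[po] <- 294 + uj[po] * 13
        gd[!pt & !po] <- 259 + uj[!pt & !po] * 34
        lab_cat <- determine_labour_category(gd)
      }
    }

    # -- delivery, postnatal and neonatal phases ---------------------------
    if (length(lab)) {
      del <- preg[lab, , drop = FALSE]
      del$labour_cat <- lab_cat
      preg <- preg[-lab, , drop = FALSE]
      out <- run_delivery_phase(del, pop, ps_eff, ps_base, seed, m,
                                avail_per_day, ov,
                                bump, log_episode, log_death)
      pop <- out$pop
    }
    cnt[yi(m), "population"] <- sum(pop$alive)
  }

  episodes <- if (length(episodes)) do.call(rbind, episodes) else
    data.frame(person = numeric(0), condition = character(0),
               category = character(0), months = numeric(0),
               year = integer(0))
  deaths <- if (length(deaths)) do.call(rbind, deaths) else
    data.frame(person = numeric(0), cause = character(0),
               category = character(0), age_years = numeric(0),
               year = integer(0), treated = logical(0), delays = integer(0))
  dal <- accrue_dalys(
    episodes,
    data.frame(person = deaths$person,
               category = ifelse(deaths$category == "neonatal", "neonatal",
                                 "maternal"),
               age_years = deaths$age_years, year = deaths$year),
    ps)
  annual <- data.frame(year = years, cnt[as.character(years), , drop = FALSE])
  for (cat in c("maternal", "neonatal")) {
    v <- numeric(nyr)
    sub <- dal[dal$category == cat, ]
    v[match(sub$year, years)] <- sub$dalys
    annual[[paste0(cat, "_dalys")]] <- v
  }
  lb <- pmax(annual$live_births, 1)
  annual$mmr <- annual$maternal_deaths / lb * 1e5
  annual$nmr <- annual$neonatal_deaths / lb * 1e3
  annual$sbr <- annual$stillbirths / pmax(annual$total_births, 1) * 1e3
  structure(list(scenario = scenario$short_name, run_index = run_index,
                 seed = seed, ratio = ratio, n_pop = n_pop,
                 annual = annual,
                 maternal_deaths_by_cause = mat_cause,
                 neonatal_deaths_by_cause = neo_cause,
                 deaths = deaths),
            class = "msim_run")
}

#' @export
print.msim_run <- function(x, ...) {
  cat("<msim_run>", x$scenario, "| run", x$run_index, "| seed", x$seed, "\n")
  yrs <- x$annual$year
  cat("  years", min(yrs), "-", max(yrs),
      "| live births", sum(x$annual$live_births),
      "| maternal deaths", sum(x$annual$maternal_deaths),
      "| neonatal deaths", sum(x$annual$neonatal_deaths), "\n")
  invisible(x)
}

# Intrapartum + postnatal + neonatal sub-simulation for one month's labours.
# Mutates tallies through the passed closures; returns the updated population.
run_delivery_phase <- function(del, pop, ps_eff, ps_base, seed, m,
                               avail_per_day, ov,
                               bump, log_episode, log_death) {
  n <- nrow(del)
  del$preterm <- del$labour_cat == "preterm"
  # local death bookkeeping: this function owns its copy of `pop` (it appends
  # newborns), so maternal deaths must mutate the local copy, not the outer one
  kill_local <- function(idx_pop, cause) {
    pop$alive[idx_pop] <<- FALSE
    pop$death_m[idx_pop] <<- m
    pop$cause_of_death[idx_pop] <<- cause
    pop$is_pregnant[idx_pop] <<- FALSE
  }
  # place of delivery
  p_fac <- careseeking_probability("facility_delivery", del, ps_eff)
  facility <- hash_unif(seed, del$id, m, rng_channels$facility) < p_fac
  u_lvl <- hash_unif(seed, del$id, m, rng_channels$facility_level)
  level <- ifelse(u_lvl < ps_eff$scalars$prop_hospital_delivery,
                  "hospital", "health_centre")
  level[!facility] <- "health_centre" # level used only if care is reached
  del$home_birth <- !facility
  day <- 1L + floor(28 * hash_unif(seed, del$id, m, rng_channels$delivery_day))

  bump(m, "facility_deliveries", sum(facility))
  bump(m, "home_deliveries", sum(!facility))

  # prophylactic bundle at facility
  deliv <- function(nm, who) {
    out <- rep(FALSE, n)
    if (any(who))
      out[who] <- attempt_intervention_delivery(nm, del$id[who], m, ps_eff,
                                                seed, level = level[who])
    out
  }
  clean <- deliv("clean_birth_practices", facility)
  amtsl <- deliv("amtsl", facility)
  sterd <- deliv("corticosteroids_preterm", facility & del$preterm)
  del$clean_birth <- clean
  del$steroids <- sterd

  # stage-1 intrapartum complications
  del <- apply_intrapartum_complications(del, ps_eff, seed, m, stage = 1)

  complicated <- del$obstructed | del$sepsis_ip | del$eclampsia_ip | del$aph_ip
  # home births with complications: emergency care seeking (delays 1 and 2
  # reflect deciding to seek and reaching care)
  seeks <- rep(FALSE, n)
  hb <- which(!facility & complicated)
  if (length(hb))
    seeks[hb] <- emergency_careseeking(del$id[hb], m, ps_eff, seed,
                                       period = "postnatal")
  care <- facility | seeks
  lvl_care <- level
  lvl_care[seeks & !facility] <-
    ifelse(hash_unif(seed, del$id[seeks & !facility], m + 5000L,
                     rng_channels$facility_level) <
             ps_eff$scalars$prop_hospital_delivery, "hospital", "health_centre")

  # squeeze over the day's remaining nursing budget; delays
  sq <- rep(-1, n)
  if (any(care))
    sq[care] <- ledger_squeeze(rep(60, sum(care)), lvl_care[care], day[care],
                               avail_per_day)
  dl <- assess_delays(del$id, m, sq, ps_eff, seed, hsi_type = "delivery_bemonc")
  dl$d3 <- dl$d3 & care
  k_del <- as.integer(dl$d1) + as.integer(dl$d2) + as.integer(dl$d3)
  if (any(care)) {
    bump(m, "nursing_minutes", sum(care) * 60)
  }

  # curative interventions, indication-gated
  deliv2 <- function(nm, who) {
    out <- rep(FALSE, n)
    w <- which(who & care)
    if (length(w))
      out[w] <- attempt_intervention_delivery(nm, del$id[w], m, ps_eff, seed,
                                              level = lvl_care[w])
    out
  }
  avd_d <- deliv2("avd", del$obstructed)
  cs_d <- deliv2("caesarean_section", del$obstructed & !avd_d)
  del$caesarean <- cs_d
  del$obstruction_relieved <- avd_d | cs_d
  abx_d <- deliv2("iv_antibiotics", del$sepsis_ip)
  mgso4_d <- deliv2("mgso4", del$eclampsia_ip | del$pe == 3)
  bt_aph <- deliv2("blood_transfusion", del$aph_ip)
  # stillbirth averting effect of operative delivery for complicated labours
  cr_avd <- intervention_row(ps_eff, "avd")$treatment_rr
  cr_cs <- intervention_row(ps_eff, "caesarean_section")$treatment_rr
  del$sb_treatment_rr <- ifelse(cs_d, cr_cs, ifelse(avd_d, cr_avd, 1))

  # stage-2: uterine rupture and intrapartum stillbirth
  del <- apply_intrapartum_complications(del, ps_eff, seed, m, stage = 2)
  rup <- del$uterine_rupture
  rup_surg <- deliv2("rupture_surgery", rup)
  bt_rup <- deliv2("blood_transfusion", rup) # shared channel with APH use
  if (any(cs_d)) bump(m, "clinician_minutes", sum(cs_d) * 60)

  # intrapartum maternal deaths
  mdead <- rep(FALSE, n)
  ip_fatal <- list(
    obstructed_labour = list(ind = del$obstructed,
                             tx = list(avd = avd_d, caesarean_section = cs_d)),
    uterine_rupture = list(ind = rup,
                           tx = list(rupture_surgery = rup_surg,
                                     blood_transfusion = bt_rup)),
    sepsis_intrapartum = list(ind = del$sepsis_ip,
                              tx = list(iv_antibiotics = abx_d)),
    eclampsia = list(ind = del$eclampsia_ip, tx = list(mgso4 = mgso4_d)),
    antepartum_haemorrhage = list(ind = del$aph_ip,
                                  tx = list(blood_transfusion = bt_aph)))
  for (cond in names(ip_fatal)) {
    ind <- which(ip_fatal[[cond]]$ind & !mdead)
    if (!length(ind)) next
    log_episode(del$mother[ind], cond, "maternal", m)
    tx <- lapply(ip_fatal[[cond]]$tx, function(v) v[ind])
    cfr <- condition_row(ps_eff, cond)$untreated_cfr
    p <- cfr * treatment_factor(tx, k_del[ind], ps_eff)
    dies <- apply_death(del$id[ind], m, p, cond, ps_eff, seed)
    if (any(dies)) {
      mp2 <- match(del$mother[ind][dies], pop$id)
      kill_local(mp2, cond)
      log_death(del$mother[ind][dies], cond, "maternal-direct",
                pop$age_years[mp2], m, Reduce(`|`, tx)[dies], k_del[ind][dies])
      mdead[ind[dies]] <- TRUE
    }
  }

  # birth outcome
  sb <- del$stillbirth_ip
  bump(m, "total_births", n)
  bump(m, "stillbirth_intrapartum", sum(sb))
  bump(m, "stillbirths", sum(sb))
  live <- !sb
  bump(m, "live_births", sum(live))

  # mother postnatal bookkeeping
  mpos <- match(del$mother, pop$id)
  pop$is_pregnant[mpos] <- FALSE
  pop$preg_id[mpos] <- NA_real_
  pop$parity[mpos] <- pop$parity[mpos] + ifelse(live, 1L, 0L)
  pop$postnatal_until_m[mpos] <- m + 2

  # newborns join the population
  nb_id <- del$id * 10 + 1
  if (any(live)) {
    u_sex <- hash_unif(seed, nb_id[live], m, rng_channels$sex)
    nb <- data.frame(
      id = nb_id[live], sex = ifelse(u_sex < 0.5, "F", "M"),
      age_years = 0, alive = TRUE, wealth = del$wealth[live],
      edu = del$edu[live], urban = del$urban[live], parity = 0L,
      is_pregnant = FALSE, preg_id = NA_real_,
      malaria_flag = FALSE, hiv = FALSE, depression = FALSE,
      postnatal_until_m = NA_real_, death_m = NA_real_,
      cause_of_death = NA_character_, stringsAsFactors = FALSE)
    pop <- rbind(pop, nb)
  }

  # ---- postnatal (mother) and neonatal weekly phases ----------------------
  # PNC coverage decisions
  pnc_m_ok <- !ov$pnc_off & !"pnc_maternal" %in% ov$service_off
  pnc_n_ok <- !ov$pnc_off & !"pnc_neonatal" %in% ov$service_off
  p_pnc_m <- if (pnc_m_ok) careseeking_probability("pnc_maternal", del, ps_eff)
             else rep(0, n)
  p_pnc_n <- if (pnc_n_ok) careseeking_probability("pnc_neonatal", del, ps_eff)
             else rep(0, n)
  pnc_m <- hash_unif(seed, del$id, m, rng_channels$pnc_maternal) < p_pnc_m
  pnc_n <- hash_unif(seed, nb_id, m, rng_channels$pnc_neonatal) < p_pnc_n
  pnc_m <- pnc_m & !mdead
  pnc_n <- pnc_n & live
  bump(m, "pnc_maternal_contacts", sum(pnc_m))
  bump(m, "pnc_neonatal_contacts", sum(pnc_n))
  bump(m, "nursing_minutes", (sum(pnc_m) + sum(pnc_n)) * ps_eff$scalars$pnc_minutes)

  del$amtsl_rr <- ifelse(amtsl,
                         intervention_row(ps_eff, "amtsl")$treatment_rr, 1)
  enc_rr_val <- intervention_row(ps_eff, "essential_newborn_care")$treatment_rr
  del$enc_rr <- 1 # maternal table placeholder (modifier column unused)

  # helper to resolve a maternal postnatal fatal episode
  maternal_pn_episode <- function(cond, ind, week, extra_tx_level = NULL) {
    ind <- which(ind & !mdead)
    if (!length(ind)) return(invisible(NULL))
    log_episode(del$mother[ind], cond, "maternal", m)
    treats <- strsplit(condition_row(ps_eff, cond)$treatments, ",")[[1]]
    # care reached: facility birth women are on site in week 0; otherwise
    # emergency care seeking; routine PNC (if attended) also detects
    reached <- (week == 0 & facility[ind]) |
      emergency_careseeking(del$id[ind], m * 100L + week, ps_eff, seed,
                            period = "postnatal") |
      (week <= 1 & pnc_m[ind])
    lvl <- lvl_care[ind]
    tx <- list()
    for (tr in treats) {
      got <- rep(FALSE, length(ind))
      w <- which(reached)
      if (length(w))
        got[w] <- attempt_intervention_delivery(tr, del$id[ind][w],
                                                m * 100L + week, ps_eff, seed,
                                                level = lvl[w])
      tx[[tr]] <- got
    }
    kk <- k_del[ind]
    cfr <- condition_row(ps_eff, cond)$untreated_cfr
    p <- cfr * treatment_factor(tx, kk, ps_eff)
    dies <- apply_death(del$id[ind], m * 100L + week, p, cond, ps_eff, seed)
    if (any(dies)) {
      mp <- match(del$mother[ind][dies], pop$id)
      kill_local(mp, cond)
      log_death(del$mother[ind][dies], cond, "maternal-direct",
                pop$age_years[mp], m, Reduce(`|`, tx)[dies], kk[dies])
      mdead[ind[dies]] <<- TRUE
    }
    invisible(NULL)
  }

  # neonatal episode resolver
  ndead <- rep(FALSE, n)
  neonatal_episode <- function(cond, ind, week) {
    ind <- which(ind & live & !ndead)
    if (!length(ind)) return(invisible(NULL))
    log_episode(nb_id[ind], cond, "neonatal", m)
    treats <- strsplit(condition_row(ps_eff, cond)$treatments, ",")[[1]]
    reached <- (week == 0 & facility[ind]) |
      emergency_careseeking(nb_id[ind], m * 100L + week, ps_eff, seed,
                            period = "postnatal") |
      (week <= 1 & pnc_n[ind])
    tx <- list()
    for (tr in treats) {
      got <- rep(FALSE, length(ind))
      w <- which(reached)
      if (length(w))
        got[w] <- attempt_intervention_delivery(tr, nb_id[ind][w],
                                                m * 100L + week, ps_eff, seed,
                                                level = lvl_care[ind][w])
      tx[[tr]] <- got
    }
    kk <- k_del[ind]
    cfr <- condition_row(ps_eff, cond)$untreated_cfr
    p <- cfr * treatment_factor(tx, kk, ps_eff)
    dies <- apply_death(nb_id[ind], m * 100L + week, p, cond, ps_eff, seed)
    if (any(dies)) {
      np <- match(nb_id[ind][dies], pop$id)
      pop$alive[np] <<- FALSE
      pop$death_m[np] <<- m
      pop$cause_of_death[np] <<- cond
      log_death(nb_id[ind][dies], cond, "neonatal", rep(0, sum(dies)), m,
                Reduce(`|`, tx)[dies], kk[dies])
      ndead[ind[dies]] <<- TRUE
    }
    invisible(NULL)
  }

  del$steroid_rr <- ifelse(del$steroids,
                           intervention_row(ps_eff, "corticosteroids_preterm")$treatment_rr,
                           1)
  nbrec <- data.frame(id = nb_id, preterm = del$preterm,
                      low_birth_weight = FALSE, home_birth = del$home_birth,
                      steroid_rr = del$steroid_rr, enc_rr = 1)
  lbw <- draw_onset(nbrec, "low_birth_weight", ps_eff, seed, m,
                    baseline = condition_row(ps_eff, "low_birth_weight")$birth_risk)
  nbrec$low_birth_weight <- lbw & live
  nbrec$enc_rr <- ifelse(pnc_n, enc_rr_val, 1)

  for (week in 0:6) {
    pn <- apply_postnatal_neonatal_cycle(del, week, "mother", ps_eff, seed, m)
    if (!is.null(pn$pph_primary))
      maternal_pn_episode("pph_primary", pn$pph_primary, week)
    if (!is.null(pn$pph_secondary))
      maternal_pn_episode("pph_secondary", pn$pph_secondary, week)
    maternal_pn_episode("sepsis_postnatal", pn$sepsis_postnatal, week)
    if (week <= 3) {
      nn <- apply_postnatal_neonatal_cycle(nbrec, week, "newborn", ps_eff,
                                           seed, m)
      if (week == 0) {
        neonatal_episode("preterm_rds", nn$preterm_rds, 0)
        neonatal_episode("neonatal_encephalopathy",
                         nn$neonatal_encephalopathy, 0)
        neonatal_episode("prematurity_other", nn$prematurity_other, 0)
      }
      neonatal_episode("neonatal_sepsis", nn$neonatal_sepsis, week)
    }
  }
  list(pop = pop)
}
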