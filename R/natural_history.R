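# Natural history: onset, progression, labour-onset and stillbirth risks in
# the absence of treatment. Modifier composition is multiplicative on the
# probability scale with clipping at 1; risk profiles are piecewise-constant
# by gestational month (antenatal), per labour (intrapartum) and per week
# (postnatal/neonatal).

#' Onset probability under multiplicative relative-risk modifiers
#'
#' @param baseline baseline per-timestep probability in \[0,1\].
#' @param modifiers numeric vector of relative risks, all strictly positive.
#' @return `min(1, baseline * prod(modifiers))`.
#' @export
onset_probability <- function(baseline, modifiers = numeric(0)) {
  if (any(baseline < 0 | baseline > 1)) stop("baseline must be in [0,1]")
  if (length(modifiers) && any(modifiers <= 0))
    stop("relative risks must be strictly positive")
  pmin(1, baseline * prod(modifiers))
}

condition_index <- function(ps, name) match(name, ps$conditions$name)

condition_row <- function(ps, name) {
  i <- condition_index(ps, name)
  if (is.na(i)) stop("unknown condition: ", name)
  ps$conditions[i, ]
}

# Per-row multiplicative relative risk for `condition` from the modifier link
# table: each link whose `flag` column exists in `df` contributes rr where the
# flag is TRUE. Derived flags (pe_severe etc.) must be materialised by the
# caller. Returns a numeric vector aligned with rows of df.
modifier_product <- function(df, condition, ps) {
  rr <- rep(1, nrow(df))
  links <- ps$modifiers[ps$modifiers$condition == condition, ]
  if (!nrow(links)) return(rr)
  for (k in seq_len(nrow(links))) {
    fl <- links$flag[k]
    if (fl %in% names(df)) {
      on <- !is.na(df[[fl]]) & df[[fl]]
      rr[on] <- rr[on] * links$rr[k]
    }
  }
  rr
}

# Vectorised onset draw for one condition over the rows of `df` (which must
# carry an `id` column used as the RNG unit key). `extra_rr` multiplies the
# baseline (prevention effects); `baseline` defaults to the condition's
# per-timestep risk.
draw_onset <- function(df, condition, ps, seed, t, baseline = NULL,
                       extra_rr = 1) {
  if (!nrow(df)) return(logical(0))
  ci <- condition_index(ps, condition)
  if (is.null(baseline)) baseline <- ps$conditions$baseline_risk[ci]
  p <- pmin(1, baseline * modifier_product(df, condition, ps) * extra_rr)
  u <- hash_unif(seed, df$id, t, rng_channels$onset + ci)
  u < p
}

#' Antenatal monthly cycle
#'
#' Applies, for every ongoing pregnancy, the gestational-month-specific onset
#' draws of the antenatal-phase conditions (with relative-risk modifiers and
#' any prevention effects already attached to the rows), progression of
#' hypertensive disease, and the pregnancy-terminating draws (ectopic
#' pregnancy, abortion complications, antenatal stillbirth). Gestational age
#' advances by one month.
#'
#' @param preg pregnancy table (rows = ongoing pregnancies; requires the state
#'   columns created by the engine and an `id` column equal to the pregnancy
#'   id).
#' @param ps parameter set.
#' @param seed run seed.
#' @param m simulation month index.
#' @return list: updated `preg`, and `events` - data frame (id, condition) of
#'   this month's new potentially-fatal or terminating onsets.
#' @export
apply_antenatal_cycle <- function(preg, ps, seed, m) {
  if (!nrow(preg)) return(list(preg = preg, events = empty_events()))
  if (any(preg$ended)) stop("apply_antenatal_cycle called on ended pregnancy")
  preg$gm <- preg$gm + 1L
  ev <- list()
  gm <- preg$gm
  cn <- ps$conditions

  window <- function(name) {
    i <- condition_index(ps, name)
    which(gm >= cn$gm_start[i] & gm <= cn$gm_end[i])
  }
  # prevention relative risks attached per pregnancy
  prev_rr <- function(rows, name) {
    rr <- rep(1, length(rows))
    iv <- ps$interventions
    if (name == "maternal_anaemia") rr[preg$on_ifa[rows]] <-
        iv$treatment_rr[iv$name == "iron_folic_acid"]
    if (name == "malaria_in_pregnancy") rr[preg$on_iptp[rows]] <-
        iv$treatment_rr[iv$name == "iptp"]
    if (name == "pre_eclampsia_mild") rr[preg$on_calcium[rows]] <-
        iv$treatment_rr[iv$name == "calcium_supplementation"]
    rr
  }

  # Terminating draws first: a pregnancy that ends this month is not exposed
  # to the remaining antenatal risks.
  for (name in c("ectopic_pregnancy", "abortion_complications",
                 "stillbirth_antenatal")) {
    rows <- window(name)
    rows <- rows[!preg$ended[rows]]
    if (!length(rows)) next
    sub <- preg[rows, , drop = FALSE]
    sub$pe_severe <- sub$pe >= 2
    hit <- draw_onset(sub, name, ps, seed, m)
    if (any(hit)) {
      idx <- rows[hit]
      preg$ended[idx] <- TRUE
      preg$end_type[idx] <- name
      ev[[name]] <- data.frame(id = preg$id[idx], condition = name)
    }
  }

  live <- !preg$ended
  # Simple (non-terminating) onsets.
  simple <- list(
    maternal_anaemia = "anaemia", gestational_diabetes = "gdm",
    syphilis = "syphilis_active", malaria_in_pregnancy = "malaria_preg")
  for (name in names(simple)) {
    col <- simple[[name]]
    rows <- window(name)
    rows <- rows[live[rows] & !preg[[col]][rows]]
    if (!length(rows)) next
    hit <- draw_onset(preg[rows, , drop = FALSE], name, ps, seed, m,
                      extra_rr = prev_rr(rows, name))
    preg[[col]][rows[hit]] <- TRUE
  }
  # Hypertensive disease onsets: mild gestational hypertension and mild
  # pre-eclampsia onset into disease-free women; severe states mostly arise by
  # progression but carry a small direct onset risk.
  hyp_free <- function(rows) rows[live[rows] & preg$gh[rows] == 0 &
                                    preg$pe[rows] == 0]
  rows <- hyp_free(window("gestational_htn_mild"))
  if (length(rows)) {
    hit <- draw_onset(preg[rows, , drop = FALSE], "gestational_htn_mild",
                      ps, seed, m)
    preg$gh[rows[hit]] <- 1L
  }
  rows <- hyp_free(window("pre_eclampsia_mild"))
  if (length(rows)) {
    hit <- draw_onset(preg[rows, , drop = FALSE], "pre_eclampsia_mild",
                      ps, seed, m, extra_rr = prev_rr(rows, "pre_eclampsia_mild"))
    preg$pe[rows[hit]] <- 1L
  }
  rows <- window("pre_eclampsia_severe")
  rows <- rows[live[rows] & preg$pe[rows] == 1]
  if (length(rows)) {
    hit <- draw_onset(preg[rows, , drop = FALSE], "pre_eclampsia_severe",
                      ps, seed, m)
    preg$pe[rows[hit]] <- 2L
  }
  # Potentially fatal antenatal emergencies.
  emergencies <- list(
    eclampsia = function(rows) preg$pe[rows] >= 2,
    antepartum_haemorrhage = function(rows) rep(TRUE, length(rows)),
    sepsis_antenatal = function(rows) rep(TRUE, length(rows)))
  for (name in names(emergencies)) {
    rows <- window(name)
    keep <- live[rows]
    if (name == "eclampsia") keep <- keep & preg$pe[rows] < 3
    if (name == "antepartum_haemorrhage") keep <- keep & !preg$aph[rows]
    if (name == "sepsis_antenatal") keep <- keep & !preg$sepsis_ante[rows]
    rows <- rows[keep]
    if (!length(rows)) next
    # eclampsia risk is strongly concentrated in severe pre-eclampsia; women
    # with pe >= 2 get the progression route below, others the small baseline.
    hit <- draw_onset(preg[rows, , drop = FALSE], name, ps, seed, m)
    if (any(hit)) {
      idx <- rows[hit]
      if (name == "eclampsia") preg$pe[idx] <- 3L
      if (name == "antepartum_haemorrhage") preg$aph[idx] <- TRUE
      if (name == "sepsis_antenatal") preg$sepsis_ante[idx] <- TRUE
      ev[[name]] <- data.frame(id = preg$id[idx], condition = name)
    }
  }
  res <- apply_progression(preg, ps, seed, m)
  preg <- res$preg
  if (nrow(res$events)) ev[["progression"]] <- res$events
  events <- if (length(ev)) do.call(rbind, ev) else empty_events()
  rownames(events) <- NULL
  list(preg = preg, events = events)
}

empty_events <- function()
  data.frame(id = numeric(0), condition = character(0))

#' Progression of hypertensive disorders
#'
#' With the configured per-month probabilities (halved under delivered
#' antihypertensive therapy), mild gestational hypertension progresses to
#' severe, mild pre-eclampsia to severe, and severe pre-eclampsia to
#' eclampsia. Severity is monotone non-decreasing absent treatment.
#'
#' @param preg pregnancy table.
#' @param ps parameter set.
#' @param seed run seed.
#' @param m month index.
#' @return list: updated `preg`; `events` rows for new eclampsia.
#' @export
apply_progression <- function(preg, ps, seed, m) {
  ev <- empty_events()
  if (!nrow(preg)) return(list(preg = preg, events = ev))
  iv <- ps$interventions
  anti_rr <- iv$treatment_rr[iv$name == "antihypertensives"]
  step <- function(rows, ci, state_col, to) {
    if (!length(rows)) return(invisible(NULL))
    p <- ps$conditions$progression_prob[ci]
    p <- p * ifelse(preg$on_antihtn[rows], anti_rr, 1)
    u <- hash_unif(seed, preg$id[rows], m, rng_channels$progression + ci)
    rows[u < p]
  }
  live <- which(!preg$ended)
  gh0 <- preg$gh; pe0 <- preg$pe  # snapshot: one severity step per month
  r <- step(live[gh0[live] == 1],
            condition_index(ps, "gestational_htn_mild"))
  if (length(r)) preg$gh[r] <- 2L
  r <- step(live[pe0[live] == 1],
            condition_index(ps, "pre_eclampsia_mild"))
  if (length(r)) preg$pe[r] <- 2L
  r <- step(live[pe0[live] == 2],
            condition_index(ps, "pre_eclampsia_severe"))
  if (length(r)) {
    preg$pe[r] <- 3L
    ev <- data.frame(id = preg$id[r], condition = "eclampsia")
  }
  list(preg = preg, events = ev)
}

#' Classify labour by gestational age
#'
#' Standard obstetric cut-points: preterm below 37 completed weeks (259 days),
#' post-term at or beyond 42 weeks (294 days), term otherwise.
#'
#' @param gestational_days days since conception.
#' @return character vector in `{"preterm","term","post-term"}`.
#' @export
determine_labour_category <- function(gestational_days) {
  ifelse(gestational_days < 259, "preterm",
         ifelse(gestational_days >= 294, "post-term", "term"))
}

#' Intrapartum complication draws
#'
#' Stage 1 draws obstructed labour, intrapartum sepsis, eclampsia and
#' antepartum haemorrhage for the month's labours. Stage 2 - run after the
#' engine has resolved which intrapartum interventions were delivered - draws
#' uterine rupture and intrapartum stillbirth, whose risks are modified by
#' untreated obstructed labour and the other complications.
#'
#' @param del delivery table (requires `id` and the complication flag columns).
#' @param ps parameter set.
#' @param seed run seed.
#' @param m month index.
#' @param stage 1 or 2.
#' @return updated `del`.
#' @export
apply_intrapartum_complications <- function(del, ps, seed, m, stage = 1) {
  if (!nrow(del)) return(del)
  if (stage == 1) {
    del$obstructed <- draw_onset(del, "obstructed_labour", ps, seed, m,
                                 baseline = condition_row(ps, "obstructed_labour")$birth_risk)
    del$sepsis_ip <- draw_onset(del, "sepsis_intrapartum", ps, seed, m,
                                baseline = condition_row(ps, "sepsis_intrapartum")$birth_risk,
                                extra_rr = ifelse(del$clean_birth,
                                  ps$interventions$treatment_rr[
                                    ps$interventions$name == "clean_birth_practices"], 1))
    rows <- which(del$pe < 3)
    ecl <- logical(nrow(del))
    if (length(rows)) {
      base <- condition_row(ps, "eclampsia")$birth_risk
      sub <- del[rows, , drop = FALSE]
      p <- pmin(1, base * ifelse(sub$pe == 2, 8, 1)) # concentrated in severe PE
      u <- hash_unif(seed, sub$id, m, rng_channels$onset +
                       condition_index(ps, "eclampsia") + 50L)
      ecl[rows] <- u < p
    }
    del$pe[ecl] <- 3L
    del$eclampsia_ip <- ecl
    rows <- which(!del$aph)
    if (length(rows)) {
      hit <- draw_onset(del[rows, , drop = FALSE], "antepartum_haemorrhage",
                        ps, seed, m + 12000L,
                        baseline = condition_row(ps, "antepartum_haemorrhage")$birth_risk)
      del$aph[rows[hit]] <- TRUE
      del$aph_ip <- FALSE
      del$aph_ip[rows[hit]] <- TRUE
    } else del$aph_ip <- FALSE
  } else {
    del$obstructed_untreated <- del$obstructed & !del$obstruction_relieved
    del$uterine_rupture <- draw_onset(del, "uterine_rupture", ps, seed, m,
                                      baseline = condition_row(ps, "uterine_rupture")$birth_risk)
    del$eclampsia <- del$pe == 3
    sb <- draw_onset(del, "stillbirth_intrapartum", ps, seed, m,
                     baseline = condition_row(ps, "stillbirth_intrapartum")$birth_risk,
                     extra_rr = del$sb_treatment_rr)
    del$stillbirth_ip <- sb
  }
  del
}

#' Postnatal / neonatal weekly cycle draws
#'
#' Week-specific draws for one record set. For mothers: primary postpartum
#' haemorrhage at week 0 only, secondary haemorrhage in weeks 1-6, postnatal
#' sepsis with an elevated immediate (week 0) risk. For newborns: preterm
#' respiratory distress syndrome and neonatal encephalopathy at birth only
#' (week 0), neonatal sepsis weekly through week 3. Callers outside the
#' 6-week postnatal / 4-week neonatal window get an error.
#'
#' @param rec record table with `id` and the flag columns used by the modifier
#'   links (`preterm`, `low_birth_weight`, `home_birth`, `caesarean`).
#' @param week completed weeks since delivery (0-6 mothers, 0-3 newborns).
#' @param who `"mother"` or `"newborn"`.
#' @param ps,seed,m parameter set, run seed, month index.
#' @return data frame of logical columns, one per condition drawn this week.
#' @export
apply_postnatal_neonatal_cycle <- function(rec, week, who, ps, seed, m) {
  if (who == "mother" && (week < 0 || week > 6))
    stop("postnatal week outside the 42-day window")
  if (who == "newborn" && (week < 0 || week > 3))
    stop("neonatal week outside the 28-day window")
  t <- m * 100L + week
  n <- nrow(rec)
  out <- data.frame(row.names = seq_len(n))
  risk <- function(name, use_birth) {
    r <- condition_row(ps, name)
    if (use_birth) r$birth_risk else r$baseline_risk
  }
  if (who == "mother") {
    if (week == 0) {
      out$pph_primary <- draw_onset(rec, "pph_primary", ps, seed, t,
                                    baseline = risk("pph_primary", TRUE),
                                    extra_rr = rec$amtsl_rr)
    }
    if (week >= 1)
      out$pph_secondary <- draw_onset(rec, "pph_secondary", ps, seed, t,
                                      baseline = risk("pph_secondary", FALSE))
    out$sepsis_postnatal <- draw_onset(rec, "sepsis_postnatal", ps, seed, t,
                                       baseline = risk("sepsis_postnatal", week == 0))
  } else {
    if (week == 0) {
      pt <- !is.na(rec$preterm) & rec$preterm
      rds <- logical(n)
      if (any(pt))
        rds[pt] <- draw_onset(rec[pt, , drop = FALSE], "preterm_rds", ps, seed,
                              t, baseline = risk("preterm_rds", TRUE),
                              extra_rr = rec$steroid_rr[pt])
      out$preterm_rds <- rds
      out$neonatal_encephalopathy <-
        draw_onset(rec, "neonatal_encephalopathy", ps, seed, t,
                   baseline = risk("neonatal_encephalopathy", TRUE))
      other <- logical(n)
      if (any(pt))
        other[pt] <- draw_onset(rec[pt, , drop = FALSE], "prematurity_other",
                                ps, seed, t,
                                baseline = risk("prematurity_other", TRUE))
      out$prematurity_other <- other
    }
    out$neonatal_sepsis <- draw_onset(rec, "neonatal_sepsis", ps, seed, t,
                                      baseline = risk("neonatal_sepsis", week == 0),
                                      extra_rr = rec$enc_rr)
  }
  out
}
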