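# Parameter registry: the synthetic parameter set that stands in for a full
# country calibration. Values are order-of-magnitude plausible for Malawi-like
# epidemiology (chosen from the arithmetic in the methods vignette) and are the
# declared tuning surface of the calibration module; none are claimed to equal
# any externally calibrated value.

CONDITION_PHASES <- c("antenatal-monthly", "intrapartum", "postnatal-weekly",
                      "neonatal")
FATAL_CATEGORIES <- c("none", "maternal-direct", "maternal-indirect",
                      "stillbirth-antenatal", "stillbirth-intrapartum",
                      "neonatal")

#' Generate the default synthetic parameter set
#'
#' Builds the complete parameter registry used by the simulation engine:
#' per-condition per-timestep onset risks with relative-risk modifiers,
#' untreated case-fatality risks, treatment-effect relative risks, disability
#' weights, care-seeking regression coefficients, consumable-availability and
#' competence probabilities, healthcare-worker time budgets, delay
#' probabilities, the squeeze threshold, and the economic constants
#' (cost-effectiveness threshold, spending growth).
#'
#' Construction is deterministic: the `seed` is recorded (and used as the
#' default base seed for simulations run from this set) but the default values
#' themselves are fixed constants.
#'
#' @param seed integer, recorded in the set and used as default simulation seed.
#' @return an object of class `msim_parameters` (a named list; see Details).
#' @export
generate_default_parameters <- function(seed = 0L) {
  conditions <- do.call(rbind, lapply(list(
    # name, phase, monthly/weekly risk, at-birth risk, gm window, untreated CFR,
    # disability weight, dw duration (months), progression, fatal category,
    # terminates pregnancy, preterm gated, treatments (comma separated)
    c("ectopic_pregnancy",      "antenatal-monthly", .0010, 0,    1, 2, .100, .324, 1.0, "", 0,    "maternal-direct", 1, 0, "abortion_ectopic_care"),
    c("abortion_complications", "antenatal-monthly", .0060, 0,    2, 6, .012, .114, 0.5, "", 0,    "maternal-direct", 1, 0, "abortion_ectopic_care"),
    c("maternal_anaemia",       "antenatal-monthly", .0350, 0,    1, 9, .000, .052, 3.0, "", 0,    "none",            0, 0, ""),
    c("gestational_diabetes",   "antenatal-monthly", .0040, 0,    4, 9, .000, .049, 4.0, "", 0,    "none",            0, 0, "gdm_management"),
    c("gestational_htn_mild",   "antenatal-monthly", .0100, 0,    5, 9, .000, .000, 3.0, "gestational_htn_severe", .05, "none", 0, 0, ""),
    c("gestational_htn_severe", "antenatal-monthly", .0008, 0,    5, 9, .000, .020, 2.0, "", 0,    "none",            0, 0, "antihypertensives"),
    c("pre_eclampsia_mild",     "antenatal-monthly", .0090, 0,    5, 9, .000, .000, 3.0, "pre_eclampsia_severe", .08, "none", 0, 0, ""),
    c("pre_eclampsia_severe",   "antenatal-monthly", .0010, 0,    5, 9, .010, .049, 2.0, "eclampsia", .06, "maternal-direct", 0, 0, "antihypertensives,mgso4"),
    c("eclampsia",              "antenatal-monthly", .0004, .0020, 6, 9, .100, .324, 1.0, "", 0,   "maternal-direct", 0, 0, "mgso4"),
    c("antepartum_haemorrhage", "antenatal-monthly", .0022, .0060, 6, 9, .030, .324, 1.0, "", 0,   "maternal-direct", 0, 0, "blood_transfusion"),
    c("syphilis",               "antenatal-monthly", .0020, 0,    1, 9, .000, .011, 6.0, "", 0,    "none",            0, 0, "syphilis_treatment"),
    c("malaria_in_pregnancy",   "antenatal-monthly", .0150, 0,    1, 9, .000, .051, 1.5, "", 0,    "maternal-indirect", 0, 0, ""),
    c("sepsis_antenatal",       "antenatal-monthly", .0006, 0,    3, 9, .070, .133, 1.0, "", 0,    "maternal-direct", 0, 0, "iv_antibiotics"),
    c("preterm_labour",         "antenatal-monthly", .0670, 0,    7, 8, .000, .000, 0.0, "", 0,    "none",            0, 0, ""),
    c("post_term_pregnancy",    "antenatal-monthly", .0500, 0,    9, 9, .000, .000, 0.0, "", 0,    "none",            0, 0, ""),
    c("stillbirth_antenatal",   "antenatal-monthly", .0026, 0,    5, 9, .000, .000, 0.0, "", 0,    "stillbirth-antenatal", 1, 0, ""),
    c("obstructed_labour",      "intrapartum",       0, .0550,    0, 0, .010, .324, 1.0, "", 0,    "maternal-direct", 0, 0, "avd,caesarean_section"),
    c("uterine_rupture",        "intrapartum",       0, .0040,    0, 0, .120, .324, 1.0, "", 0,    "maternal-direct", 0, 0, "rupture_surgery,blood_transfusion"),
    c("sepsis_intrapartum",     "intrapartum",       0, .0120,    0, 0, .060, .133, 1.0, "", 0,    "maternal-direct", 0, 0, "iv_antibiotics"),
    c("stillbirth_intrapartum", "intrapartum",       0, .0085,    0, 0, .000, .000, 0.0, "", 0,    "stillbirth-intrapartum", 0, 0, "avd,caesarean_section"),
    c("pph_primary",            "postnatal-weekly",  0, .0700,    0, 0, .050, .324, 0.5, "", 0,    "maternal-direct", 0, 0, "uterotonics,pph_surgery,blood_transfusion"),
    c("pph_secondary",          "postnatal-weekly", .0020, 0,     0, 0, .020, .114, 0.5, "", 0,    "maternal-direct", 0, 0, "pph_case_management"),
    c("sepsis_postnatal",       "postnatal-weekly", .0015, .0060, 0, 0, .050, .133, 1.0, "", 0,    "maternal-direct", 0, 0, "iv_antibiotics"),
    c("low_birth_weight",       "neonatal",          0, .0500,    0, 0, .000, .000, 0.0, "", 0,    "none",            0, 0, ""),
    c("preterm_rds",            "neonatal",          0, .2000,    0, 0, .350, .133, 1.0, "", 0,    "neonatal",        0, 1, "neonatal_resuscitation,full_supportive_care"),
    c("prematurity_other",      "neonatal",          0, .1200,    0, 0, .180, .133, 2.0, "", 0,    "neonatal",        0, 1, "kangaroo_mother_care"),
    c("neonatal_encephalopathy","neonatal",          0, .0160,    0, 0, .300, .133, 2.0, "", 0,    "neonatal",        0, 0, "neonatal_resuscitation"),
    c("neonatal_sepsis",        "neonatal",         .0040, .0100, 0, 0, .120, .133, 1.0, "", 0,    "neonatal",        0, 0, "neonatal_antibiotics,full_supportive_care")
  ), function(r) {
    data.frame(name = r[1], phase = r[2],
               baseline_risk = as.numeric(r[3]), birth_risk = as.numeric(r[4]),
               gm_start = as.integer(r[5]), gm_end = as.integer(r[6]),
               untreated_cfr = as.numeric(r[7]),
               disability_weight = as.numeric(r[8]),
               dw_duration_months = as.numeric(r[9]),
               progression_to = ifelse(r[10] == "", NA_character_, r[10]),
               progression_prob = as.numeric(r[11]),
               fatal_category = r[12],
               terminates_pregnancy = as.logical(as.integer(r[13])),
               preterm_only = as.logical(as.integer(r[14])),
               treatments = r[15],
               stringsAsFactors = FALSE)
  }))
  rownames(conditions) <- NULL

  # Inter-condition / risk-flag relative-risk links (data-driven; the default
  # list covers the links documented for this model class: malaria -> preterm
  # labour and anaemia, obstructed labour -> uterine rupture, caesarean ->
  # postnatal sepsis, hypertensive disease and haemorrhage -> stillbirth).
  modifiers <- data.frame(
    condition = c("preterm_labour", "maternal_anaemia", "uterine_rupture",
                  "sepsis_postnatal", "stillbirth_antenatal",
                  "stillbirth_antenatal", "stillbirth_intrapartum",
                  "stillbirth_intrapartum", "stillbirth_intrapartum",
                  "stillbirth_intrapartum", "neonatal_sepsis",
                  "neonatal_sepsis", "malaria_in_pregnancy",
                  "sepsis_antenatal", "low_birth_weight"),
    flag      = c("malaria_preg", "malaria_preg", "obstructed_untreated",
                  "caesarean", "syphilis_active",
                  "pe_severe", "obstructed_untreated",
                  "uterine_rupture", "aph",
                  "eclampsia", "low_birth_weight",
                  "home_birth", "malaria_flag",
                  "hiv", "preterm"),
    rr        = c(1.65, 2.0, 4.0,
                  2.5, 2.0,
                  2.5, 3.0,
                  6.0, 4.0,
                  3.0, 2.0,
                  1.4, 3.0,
                  1.5, 6.0),
    stringsAsFactors = FALSE)

  interventions <- do.call(rbind, lapply(list(
    # name, class, hsi_type, emonc, competence, treatment RR, target condition,
    # effect (cfr | onset | incidence | progression | cure), nursing min, clinician min
    c("bp_screening",          "screening",    "anc_contact",        "none",   .90, 1.00, "",                     "screen", 2, 0),
    c("urine_dipstick",        "screening",    "anc_contact",        "none",   .90, 1.00, "",                     "screen", 1, 0),
    c("hb_testing",            "screening",    "anc_contact",        "none",   .85, 1.00, "",                     "screen", 2, 0),
    c("gdm_screening",         "screening",    "anc_contact",        "none",   .80, 1.00, "",                     "screen", 2, 0),
    c("syphilis_treatment",    "preventative", "anc_contact",        "none",   .85, 1.00, "syphilis",             "cure",   2, 0),
    c("iron_folic_acid",       "preventative", "anc_contact",        "none",   .90, 0.45, "maternal_anaemia",     "onset",  1, 0),
    c("iptp",                  "preventative", "anc_contact",        "none",   .90, 0.55, "malaria_in_pregnancy", "onset",  1, 0),
    c("calcium_supplementation","preventative","anc_contact",        "none",   .80, 0.45, "pre_eclampsia_mild",   "onset",  1, 0),
    c("gdm_management",        "curative",     "inpatient_antenatal","none",   .80, 0.80, "stillbirth_antenatal", "cfr",    8, 4),
    c("antihypertensives",     "curative",     "inpatient_antenatal","none",   .80, 0.50, "pre_eclampsia_severe", "progression", 5, 3),
    c("mgso4",                 "curative",     "inpatient_antenatal","BEmONC", .75, 0.41, "eclampsia",            "cfr",    8, 5),
    c("iv_antibiotics",        "curative",     "inpatient_antenatal","BEmONC", .80, 0.30, "sepsis_antenatal",     "cfr",   10, 5),
    c("abortion_ectopic_care", "curative",     "post_abortion_care", "CEmONC", .80, 0.18, "ectopic_pregnancy",    "cfr",   20, 30),
    c("clean_birth_practices", "preventative", "delivery_bemonc",    "none",   .90, 0.60, "sepsis_intrapartum",   "incidence", 2, 0),
    c("amtsl",                 "preventative", "delivery_bemonc",    "none",   .85, 0.35, "pph_primary",          "incidence", 4, 0),
    c("corticosteroids_preterm","preventative","delivery_bemonc",    "none",   .70, 0.55, "preterm_rds",          "incidence", 3, 1),
    c("avd",                   "curative",     "delivery_bemonc",    "BEmONC", .70, 0.30, "obstructed_labour",    "cfr",   20, 10),
    c("uterotonics",           "curative",     "delivery_bemonc",    "BEmONC", .85, 0.30, "pph_primary",          "cfr",    8, 2),
    c("neonatal_resuscitation","curative",     "delivery_bemonc",    "BEmONC", .75, 0.50, "neonatal_encephalopathy","cfr", 10, 2),
    c("caesarean_section",     "curative",     "delivery_cemonc",    "CEmONC", .85, 0.20, "obstructed_labour",    "cfr",   30, 60),
    c("rupture_surgery",       "curative",     "delivery_cemonc",    "CEmONC", .85, 0.25, "uterine_rupture",      "cfr",   30, 75),
    c("blood_transfusion",     "curative",     "delivery_cemonc",    "CEmONC", .85, 0.35, "antepartum_haemorrhage","cfr",  15, 10),
    c("pph_case_management",   "curative",     "pnc_maternal",       "none",   .80, 0.30, "pph_secondary",        "cfr",   12, 4),
    c("pph_surgery",           "curative",     "cemonc_postnatal",   "CEmONC", .85, 0.20, "pph_primary",          "cfr",   30, 60),
    c("essential_newborn_care","preventative", "pnc_neonatal",       "none",   .90, 0.80, "neonatal_sepsis",      "onset",  4, 0),
    c("neonatal_antibiotics",  "curative",     "pnc_neonatal",       "none",   .80, 0.35, "neonatal_sepsis",      "cfr",   10, 3),
    c("full_supportive_care",  "curative",     "pnc_neonatal",       "CEmONC", .70, 0.55, "neonatal_sepsis",      "cfr",   30, 15),
    c("kangaroo_mother_care",  "curative",     "pnc_neonatal",       "none",   .85, 0.60, "prematurity_other",    "cfr",   10, 0)
  ), function(r) {
    data.frame(name = r[1], class = r[2], hsi_type = r[3], emonc = r[4],
               competence_prob = as.numeric(r[5]),
               treatment_rr = as.numeric(r[6]),
               target = ifelse(r[7] == "", NA_character_, r[7]),
               effect = r[8],
               nursing_minutes = as.numeric(r[9]),
               clinician_minutes = as.numeric(r[10]),
               stringsAsFactors = FALSE)
  }))
  rownames(interventions) <- NULL

  consumables <- data.frame(
    intervention = c("urine_dipstick", "hb_testing", "gdm_screening",
                     "syphilis_treatment", "iron_folic_acid", "iptp",
                     "calcium_supplementation", "gdm_management",
                     "antihypertensives", "mgso4", "iv_antibiotics",
                     "abortion_ectopic_care",
                     "amtsl", "corticosteroids_preterm", "avd", "uterotonics",
                     "neonatal_resuscitation", "caesarean_section",
                     "rupture_surgery", "blood_transfusion",
                     "pph_case_management", "pph_surgery",
                     "essential_newborn_care", "neonatal_antibiotics",
                     "full_supportive_care"),
    item = c("dipstick", "hb_cartridge", "glucose_test",
             "benzathine_penicillin", "ifa_tablets", "sp_tablets",
             "calcium_tablets", "insulin_oral_agents",
             "antihypertensive_drugs", "mgso4_vials", "iv_antibiotic_vials",
             "surgical_kit",
             "uterotonic_drugs", "dexamethasone", "vacuum_extractor",
             "uterotonic_drugs", "resuscitation_kit", "surgical_kit",
             "surgical_kit", "whole_blood",
             "uterotonic_drugs", "surgical_kit",
             "newborn_kit", "injectable_antibiotics",
             "supportive_care_kit"),
    availability = c(.65, .70, .60,
                     .70, .75, .70,
                     .60, .55,
                     .70, .65, .70,
                     .75,
                     .80, .60, .70, .80,
                     .75, .80,
                     .80, .50,
                     .75, .80,
                     .80, .70,
                     .55),
    stringsAsFactors = FALSE)

  # Care-seeking: multivariable logistic models. Covariates are centred so the
  # intercept is approximately the population logit of coverage; intercepts are
  # the calibration knobs for the coverage targets.
  careseeking <- data.frame(
    service  = c("anc", "facility_delivery", "pnc_maternal", "pnc_neonatal"),
    intercept = c(2.95, 2.40, -0.33, 0.42),
    b_wealth  = c(0.12, 0.15, 0.12, 0.12),   # per quintile above the 3rd
    b_edu     = c(0.25, 0.30, 0.25, 0.25),   # per level above primary
    b_urban   = c(0.35, 0.45, 0.35, 0.35),
    b_parity  = c(-0.05, -0.08, -0.04, -0.04), # per birth above 2
    b_age     = c(0.02, 0.01, 0.01, 0.01),   # per year above 25
    stringsAsFactors = FALSE)

  scalars <- list(
    emergency_careseek_prob = 0.65,
    delay1_prob = 0.35,
    delay2_prob = 0.30,
    squeeze_threshold = 3,
    delay_attenuation = 0.25,
    anc_minutes = 12,
    pnc_minutes = 15,
    cet_usd = 62.3,
    spending_growth = 0.009,
    model_to_real_ratio = 58,
    disability_cap = 1.0,
    anc_transition_prob = 0.82,
    prop_hospital_delivery = 0.45,
    bemonc_staffing_prob = 0.80,
    cemonc_staffing_prob = 0.85,
    female_fraction = 0.505,
    urban_fraction = 0.16,
    crude_birth_rate_target = 0.034,
    background_mortality_monthly = c(under5 = 8e-4, age5_14 = 1.2e-4,
                                     age15_49 = 2.5e-4, age50_69 = 1.2e-3,
                                     age70plus = 6e-3),
    risk_flag_prevalence = c(malaria_flag = 0.25, hiv = 0.08,
                             depression = 0.10),
    hcw_daily_minutes_per_1000 = c(health_centre_nursing = 8,
                                   hospital_nursing = 12,
                                   hospital_clinician = 6),
    seed = as.integer(seed)
  )

  # Monthly conception probability by maternal age band (15-49), set so the
  # crude birth rate lands near the configured target in a stable pyramid.
  conception <- data.frame(
    age_low  = c(15, 20, 25, 30, 35, 40, 45),
    age_high = c(19, 24, 29, 34, 39, 44, 49),
    monthly_prob = c(0.012, 0.019, 0.018, 0.014, 0.010, 0.005, 0.001))

  # First ANC visit timing: distribution over gestational month of initiation.
  anc_first_visit <- data.frame(gestational_month = 2:6,
                                prob = c(0.08, 0.25, 0.32, 0.22, 0.13))

  # Reference life table: remaining life expectancy by age (synthetic,
  # GBD-standard-shaped; expectancy at birth 62.7 years).
  life_table <- data.frame(
    age = c(0, 1, 5, 10, 15, 20, 25, 30, 35, 40, 45, 50, 55, 60, 65, 70, 75,
            80, 85),
    expectancy = c(62.7, 64.2, 61.3, 56.5, 51.6, 46.9, 42.3, 37.8, 33.4, 29.0,
                   24.8, 20.8, 17.0, 13.5, 10.4, 7.8, 5.7, 4.1, 2.9))

  ps <- structure(list(conditions = conditions, modifiers = modifiers,
                       interventions = interventions, consumables = consumables,
                       careseeking = careseeking, scalars = scalars,
                       conception = conception,
                       anc_first_visit = anc_first_visit,
                       life_table = life_table),
                  class = "msim_parameters")
  validate_parameters(ps)
  ps
}

#' Validate a parameter set
#'
#' Checks the full invariant suite: probabilities in \[0,1\], relative risks
#' strictly positive, treatment relative risks in (0,1\], known phases and
#' fatal categories, every treatment named by a condition present in the
#' intervention table, and positive time budgets. Errors name the offending
#' field and entity.
#'
#' @param ps an `msim_parameters` object.
#' @return `ps`, invisibly, if valid.
#' @export
validate_parameters <- function(ps) {
  stopifnot(inherits(ps, "msim_parameters"))
  cn <- ps$conditions
  need <- c("name", "phase", "baseline_risk", "birth_risk", "untreated_cfr",
            "disability_weight", "progression_prob", "fatal_category",
            "treatments")
  miss <- setdiff(need, names(cn))
  if (length(miss))
    stop("conditions table missing field(s): ", paste(miss, collapse = ", "))
  chk01 <- function(x, field, who) {
    bad <- which(is.na(x) | x < 0 | x > 1)
    if (length(bad))
      stop(field, " outside [0,1] for: ", paste(who[bad], collapse = ", "))
  }
  chk01(cn$baseline_risk, "baseline_risk", cn$name)
  chk01(cn$birth_risk, "birth_risk", cn$name)
  chk01(cn$untreated_cfr, "untreated_cfr", cn$name)
  chk01(cn$disability_weight, "disability_weight", cn$name)
  chk01(cn$progression_prob, "progression_prob", cn$name)
  if (any(!cn$phase %in% CONDITION_PHASES))
    stop("unknown phase for: ",
         paste(cn$name[!cn$phase %in% CONDITION_PHASES], collapse = ", "))
  if (any(!cn$fatal_category %in% FATAL_CATEGORIES))
    stop("unknown fatal_category for: ",
         paste(cn$name[!cn$fatal_category %in% FATAL_CATEGORIES], collapse = ", "))
  bad_prog <- !is.na(cn$progression_to) & !cn$progression_to %in% cn$name
  if (any(bad_prog))
    stop("progression_to names unknown condition for: ",
         paste(cn$name[bad_prog], collapse = ", "))

  iv <- ps$interventions
  chk01(iv$competence_prob, "competence_prob", iv$name)
  if (any(iv$treatment_rr <= 0 | iv$treatment_rr > 1))
    stop("treatment_rr outside (0,1] for: ",
         paste(iv$name[iv$treatment_rr <= 0 | iv$treatment_rr > 1],
               collapse = ", "))
  if (any(iv$nursing_minutes < 0) || any(iv$clinician_minutes < 0))
    stop("negative HCW minutes in interventions table")

  treats <- unlist(strsplit(cn$treatments[cn$treatments != ""], ","))
  unknown <- setdiff(treats, iv$name)
  if (length(unknown))
    stop("conditions reference unknown treatment(s): ",
         paste(unknown, collapse = ", "))

  chk01(ps$consumables$availability, "availability", ps$consumables$item)
  orphan <- setdiff(ps$consumables$intervention, iv$name)
  if (length(orphan))
    stop("consumables reference unknown intervention(s): ",
         paste(orphan, collapse = ", "))

  if (any(ps$modifiers$rr <= 0))
    stop("modifier relative risks must be strictly positive: ",
         paste(ps$modifiers$condition[ps$modifiers$rr <= 0], collapse = ", "))

  sc <- ps$scalars
  for (f in c("emergency_careseek_prob", "delay1_prob", "delay2_prob",
              "delay_attenuation", "anc_transition_prob",
              "prop_hospital_delivery", "bemonc_staffing_prob",
              "cemonc_staffing_prob", "female_fraction", "urban_fraction")) {
    v <- sc[[f]]
    if (is.null(v) || is.na(v) || v < 0 || v > 1)
      stop("scalar ", f, " missing or outside [0,1]")
  }
  if (sc$squeeze_threshold <= 0) stop("squeeze_threshold must be positive")
  if (sc$model_to_real_ratio <= 0) stop("model_to_real_ratio must be positive")
  if (any(sc$hcw_daily_minutes_per_1000 <= 0))
    stop("hcw_daily_minutes_per_1000 must be positive")
  if (abs(sum(ps$anc_first_visit$prob) - 1) > 1e-8)
    stop("anc_first_visit probabilities must sum to 1")
  if (any(diff(ps$life_table$age) <= 0))
    stop("life_table ages must be strictly increasing")
  if (any(ps$life_table$expectancy < 0))
    stop("life_table expectancy must be non-negative")
  invisible(ps)
}

#' @export
print.msim_parameters <- function(x, ...) {
  cat("<msim_parameters>\n")
  cat("  conditions:   ", nrow(x$conditions), "\n")
  cat("  interventions:", nrow(x$interventions), "\n")
  cat("  modifier links:", nrow(x$modifiers), "\n")
  cat("  squeeze threshold:", x$scalars$squeeze_threshold,
      "| CET: $", x$scalars$cet_usd, "\n")
  invisible(x)
}

#' Write a parameter set to a directory
#'
#' One flat CSV per entity type plus a YAML manifest carrying the scalar
#' parameters and the first-ANC-visit distribution. Probabilities are stored
#' unrounded (15 significant digits).
#'
#' @param ps an `msim_parameters` object.
#' @param path directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_parameters <- function(ps, path) {
  validate_parameters(ps)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, f)
    utils::write.csv(format(df, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     file.path(path, f), row.names = FALSE, quote = TRUE)
  wr(ps$conditions, "conditions.csv")
  wr(ps$modifiers, "modifiers.csv")
  wr(ps$interventions, "interventions.csv")
  wr(ps$consumables, "consumables.csv")
  wr(ps$careseeking, "careseeking.csv")
  wr(ps$conception, "conception.csv")
  wr(ps$life_table, "life_table.csv")
  manifest <- list(scalars = lapply(ps$scalars, function(v)
                     if (is.numeric(v) && !is.null(names(v))) as.list(v) else v),
                   anc_first_visit = list(
                     gestational_month = ps$anc_first_visit$gestational_month,
                     prob = ps$anc_first_visit$prob))
  yaml::write_yaml(manifest, file.path(path, "manifest.yaml"),
                   precision = 15)
  invisible(path)
}

#' Read a parameter set from a directory written by [write_parameters()]
#'
#' @param path directory containing the CSV tables and `manifest.yaml`.
#' @return a validated `msim_parameters` object.
#' @export
read_parameters <- function(path) {
  rd <- function(f) {
    fp <- file.path(path, f)
    if (!file.exists(fp)) stop("missing parameter file: ", f)
    utils::read.csv(fp, stringsAsFactors = FALSE)
  }
  conditions <- rd("conditions.csv")
  conditions$progression_to[conditions$progression_to %in% c("", "NA")] <- NA
  conditions$treatments[is.na(conditions$treatments)] <- ""
  for (f in c("baseline_risk", "birth_risk", "untreated_cfr",
              "disability_weight", "dw_duration_months", "progression_prob"))
    conditions[[f]] <- as.numeric(conditions[[f]])
  conditions$terminates_pregnancy <- as.logical(conditions$terminates_pregnancy)
  conditions$preterm_only <- as.logical(conditions$preterm_only)
  manifest <- yaml::read_yaml(file.path(path, "manifest.yaml"))
  scalars <- lapply(manifest$scalars, function(v)
    if (is.list(v)) unlist(v) else v)
  scalars$seed <- as.integer(scalars$seed)
  ps <- structure(list(
    conditions = conditions,
    modifiers = rd("modifiers.csv"),
    interventions = rd("interventions.csv"),
    consumables = rd("consumables.csv"),
    careseeking = rd("careseeking.csv"),
    scalars = scalars,
    conception = rd("conception.csv"),
    anc_first_visit = data.frame(
      gestational_month = manifest$anc_first_visit$gestational_month,
      prob = manifest$anc_first_visit$prob),
    life_table = rd("life_table.csv")),
    class = "msim_parameters")
  validate_parameters(ps)
  ps
}

#' Export the merged parameter set as JSON text
#'
#' @param ps an `msim_parameters` object.
#' @return a JSON string.
#' @export
parameters_json <- function(ps) {
  validate_parameters(ps)
  jsonlite::toJSON(unclass(ps), dataframe = "columns", auto_unbox = TRUE,
                   digits = NA)
}

#' Generate a synthetic fixture population
#'
#' Draws `n` individuals with demographic fields from the configured marginals
#' (sex ratio, an age pyramid with geometric decay, wealth quintile, education,
#' urban residence, parity rising with age, and the boolean comorbidity risk
#' flags). Reproducible for a given seed via the keyed RNG.
#'
#' @param n number of persons, at least 1.
#' @param seed integer seed.
#' @param ps parameter set (for marginal probabilities).
#' @return a data frame, one row per person.
#' @export
make_fixture_population <- function(n, seed = 1L, ps = generate_default_parameters()) {
  if (n < 1) stop("n must be at least 1")
  sc <- ps$scalars
  id <- seq_len(n)
  u_sex <- hash_unif(seed, id, 0, rng_channels$sex)
  sex <- ifelse(u_sex < sc$female_fraction, "F", "M")
  # Age pyramid: P(age = a) proportional to (1 - d)^a, d ~ 3%/yr, capped at 85.
  ages <- 0:85
  w <- (1 - 0.03)^ages
  cw <- cumsum(w) / sum(w)
  u_age <- hash_unif(seed, id, 1, rng_channels$demography)
  age <- findInterval(u_age, cw) # 0..85
  u2 <- hash_unif(seed, id, 2, rng_channels$demography)
  wealth <- 1L + as.integer(floor(u2 * 5)) # uniform quintiles by construction
  u3 <- hash_unif(seed, id, 3, rng_channels$demography)
  edu <- findInterval(u3, cumsum(c(0.35, 0.50))) # 0 none,1 primary,2 secondary+
  u4 <- hash_unif(seed, id, 4, rng_channels$demography)
  urban <- u4 < sc$urban_fraction
  u5 <- hash_unif(seed, id, 5, rng_channels$demography)
  parity <- ifelse(sex == "F" & age >= 15,
                   pmin(8L, as.integer(floor(u5 * pmax(0, (age - 15)) / 5))), 0L)
  fl <- sc$risk_flag_prevalence
  pop <- data.frame(
    id = as.numeric(id), sex = sex, age_years = age, alive = TRUE,
    wealth = wealth, edu = edu, urban = urban, parity = parity,
    is_pregnant = FALSE, preg_id = NA_real_,
    malaria_flag = hash_unif(seed, id, 6, rng_channels$risk_flag) < fl[["malaria_flag"]],
    hiv = hash_unif(seed, id, 7, rng_channels$risk_flag) < fl[["hiv"]],
    depression = hash_unif(seed, id, 8, rng_channels$risk_flag) < fl[["depression"]],
    postnatal_until_m = NA_real_,
    death_m = NA_real_, cause_of_death = NA_character_,
    stringsAsFactors = FALSE)
  pop
}
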