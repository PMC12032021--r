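# Scenario configurations: named bundles of coverage/quality overrides that
# take effect at the intervention date (1 January 2023 by default). Composite
# "All services" scenarios are the union of their component bundles.

#' Short names of all sixteen scenarios
#' @export
scenario_names <- function() c(
  "SQ",
  "AN coverage", "AN coverage and qual.", "AN max.", "AN min.",
  "IP BEmONC", "IP CEmONC", "IP max.", "IP min.",
  "PN coverage", "PN coverage and qual.", "PN max.", "PN min.",
  "All services coverage", "All services coverage and qual.",
  "All services max.", "All services min.")

merge_overrides <- function(a, b) {
  out <- a
  for (f in c("quality_max", "delay3_disabled", "delays12_off", "service_off"))
    out[[f]] <- unique(c(a[[f]], b[[f]]))
  for (f in c("delivery_prob", "emergency_seek")) {
    v <- a[[f]]
    v[!is.na(b[[f]])] <- b[[f]][!is.na(b[[f]])]
    out[[f]] <- v
  }
  for (f in c("facility_all", "anc_off", "anc_first_trimester", "pnc_max",
              "pnc_off"))
    out[[f]] <- a[[f]] || b[[f]]
  for (f in c("anc_transition", "anc4_target", "pnc_target"))
    if (!is.na(b[[f]])) out[[f]] <- b[[f]]
  out$intercept_shift <- a$intercept_shift + b$intercept_shift
  out
}

scenario_overrides <- function(short_name) {
  ov <- default_overrides()
  an_quality <- c("anc_contact", "inpatient_antenatal")
  pn_quality <- c("pnc_maternal", "pnc_neonatal", "cemonc_postnatal")
  switch(short_name,
    "SQ" = ov,
    "AN coverage" = { ov$anc4_target <- 0.90; ov },
    "AN coverage and qual." = {
      ov$anc4_target <- 0.90
      ov$quality_max <- an_quality
      ov$delay3_disabled <- "inpatient_antenatal"
      ov },
    "AN max." = {
      ov$anc_first_trimester <- TRUE
      ov$anc_transition <- 1.0
      ov$emergency_seek[["antenatal"]] <- 1
      ov$quality_max <- an_quality
      ov$delay3_disabled <- "inpatient_antenatal"
      ov$delays12_off <- "inpatient_antenatal"
      ov },
    "AN min." = {
      ov$anc_off <- TRUE
      ov$emergency_seek[["antenatal"]] <- 0
      ov$service_off <- an_quality
      ov },
    "IP BEmONC" = {
      ov$delivery_prob[c("prophylactic", "bemonc")] <- 0.90
      ov$delay3_disabled <- c("delivery_bemonc", "delivery_cemonc")
      ov },
    "IP CEmONC" = {
      ov$delivery_prob[c("prophylactic", "bemonc", "cemonc")] <- 0.90
      ov$delay3_disabled <- c("delivery_bemonc", "delivery_cemonc")
      ov },
    "IP max." = {
      ov$facility_all <- TRUE
      ov$delivery_prob[c("prophylactic", "bemonc", "cemonc")] <- 1.0
      ov$delay3_disabled <- c("delivery_bemonc", "delivery_cemonc")
      ov$delays12_off <- c("delivery_bemonc", "delivery_cemonc")
      ov },
    "IP min." = {
      ov$delivery_prob[c("prophylactic", "bemonc", "cemonc")] <- 0
      ov },
    "PN coverage" = { ov$pnc_target <- 0.90; ov },
    "PN coverage and qual." = {
      ov$pnc_target <- 0.90
      ov$quality_max <- pn_quality
      ov$delay3_disabled <- "cemonc_postnatal"
      ov },
    "PN max." = {
      ov$pnc_max <- TRUE
      ov$emergency_seek[["postnatal"]] <- 1
      ov$quality_max <- pn_quality
      ov$delay3_disabled <- pn_quality
      ov$delays12_off <- pn_quality
      ov },
    "PN min." = {
      ov$pnc_off <- TRUE
      ov$emergency_seek[["postnatal"]] <- 0
      ov$service_off <- pn_quality
      ov },
    "All services coverage" = Reduce(merge_overrides, lapply(
      c("AN coverage", "IP BEmONC", "PN coverage"), scenario_overrides)),
    "All services coverage and qual." = Reduce(merge_overrides, lapply(
      c("AN coverage and qual.", "IP CEmONC", "PN coverage and qual."),
      scenario_overrides)),
    "All services max." = Reduce(merge_overrides, lapply(
      c("AN max.", "IP max.", "PN max."), scenario_overrides)),
    "All services min." = Reduce(merge_overrides, lapply(
      c("AN min.", "IP min.", "PN min."), scenario_overrides)),
    stop("unknown scenario short name: ", short_name))
}

#' Build a scenario configuration
#'
#' @param short_name one of [scenario_names()].
#' @param effective_date date the overrides take effect (default 2023-01-01).
#' @return an object of class `msim_scenario`.
#' @export
build_scenario <- function(short_name, effective_date = as.Date("2023-01-01")) {
  ov <- scenario_overrides(short_name)
  structure(list(short_name = short_name, effective_date = effective_date,
                 effective_month = month_index(as.integer(format(effective_date, "%Y")),
                                               as.integer(format(effective_date, "%m"))),
                 overrides = ov),
            class = "msim_scenario")
}

#' @export
print.msim_scenario <- function(x, ...) {
  cat("<msim_scenario>", x$short_name, "| effective",
      format(x$effective_date), "\n")
  ov <- x$overrides
  act <- c(
    if (length(ov$quality_max)) paste("quality max:", paste(ov$quality_max, collapse = ", ")),
    if (length(ov$service_off)) paste("disabled:", paste(ov$service_off, collapse = ", ")),
    if (any(!is.na(ov$delivery_prob)))
      paste("delivery prob:", paste(names(ov$delivery_prob)[!is.na(ov$delivery_prob)],
                                    ov$delivery_prob[!is.na(ov$delivery_prob)],
                                    collapse = ", ")),
    if (!is.na(ov$anc4_target)) paste("ANC4+ target:", ov$anc4_target),
    if (!is.na(ov$pnc_target)) paste("PNC target:", ov$pnc_target))
  if (length(act)) cat(" ", paste(act, collapse = "\n  "), "\n")
  else cat("  (no overrides)\n")
  invisible(x)
}

# Solve the intercept shift delta so that the population mean of
# inv_logit(lp + delta) equals the target over the supplied covariate rows.
solve_intercept_shift <- function(lp, target) {
  f <- function(d) mean(inv_logit(lp + d)) - target
  stats::uniroot(f, c(-20, 20), tol = 1e-10)$root
}

#' Apply a scenario to a parameter set at a given simulation month
#'
#' Before the effective date the base parameters are returned unchanged. From
#' the effective date the override bundle is attached; population coverage
#' targets (ANC4+, PNC) are met by recalibrating the care-seeking intercepts
#' (and, for ANC4+, the visit-transition odds by the same shift) against the
#' covariate distribution of the supplied women, so sociodemographic gradients
#' in care seeking persist.
#'
#' @param config an `msim_scenario`.
#' @param ps base parameter set.
#' @param m simulation month index.
#' @param women data frame of care-seeking covariates used to solve coverage
#'   targets (defaults to a synthetic fixture cohort).
#' @return the scenario-effective `msim_parameters`.
#' @export
apply_scenario <- function(config, ps, m, women = NULL) {
  stopifnot(inherits(config, "msim_scenario"))
  if (m < config$effective_month) return(ps)
  ov <- config$overrides
  if (is.null(women)) {
    women <- make_fixture_population(2000, seed = 99L, ps = ps)
    women <- women[women$sex == "F" & women$age_years >= 15 &
                     women$age_years < 50, ]
  }
  if (!is.na(ov$anc4_target)) {
    base <- ps
    base$overrides <- NULL
    p_first6 <- sum(ps$anc_first_visit$prob[ps$anc_first_visit$gestational_month <= 6])
    lp <- stats::qlogis(careseeking_probability("anc", women, base))
    pt <- ps$scalars$anc_transition_prob
    f <- function(d) {
      mean(inv_logit(lp + d)) * p_first6 *
        inv_logit(stats::qlogis(pt) + d)^3 - ov$anc4_target
    }
    d <- stats::uniroot(f, c(-20, 20), tol = 1e-10)$root
    ov$intercept_shift[["anc"]] <- d
    ov$anc_transition <- inv_logit(stats::qlogis(pt) + d)
  }
  if (!is.na(ov$pnc_target)) {
    base <- ps; base$overrides <- NULL
    for (svc in c("pnc_maternal", "pnc_neonatal")) {
      lp <- stats::qlogis(careseeking_probability(svc, women, base))
      ov$intercept_shift[[svc]] <- solve_intercept_shift(lp, ov$pnc_target)
    }
  }
  if (ov$pnc_max)
    ov$intercept_shift[c("pnc_maternal", "pnc_neonatal")] <- 20
  if (ov$pnc_off)
    ov$intercept_shift[c("pnc_maternal", "pnc_neonatal")] <- -Inf
  if (ov$facility_all) ov$intercept_shift[["facility_delivery"]] <- 30
  ps$overrides <- ov
  ps
}
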