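#' Counter-based uniform draws
#'
#' Returns uniforms in (0,1) addressed by a key `(seed, id, t, channel)` rather
#' than by position in a stream. The same key always yields the same uniform,
#' which gives exact common random numbers across paired counterfactual runs:
#' the decision "does person i die of condition c at time t" consumes the same
#' uniform under every scenario, so scenarios that only shift the probability
#' produce nested (pointwise monotone) event sets.
#'
#' @param seed integer run seed.
#' @param id unit identifiers (person or pregnancy ids); numeric.
#' @param t time index (simulation month, or month*100 + week).
#' @param channel integer event-channel code, see [rng_channels].
#' @return numeric vector of uniforms, length `max(length(id), length(t), length(channel))`.
#' @export
hash_unif <- function(seed, id, t, channel) {
  hash_unif_cpp(as.numeric(seed), as.numeric(id), as.numeric(t),
                as.numeric(channel))
}

#' Event-channel codes for the keyed RNG
#'
#' Each distinct class of stochastic decision owns a channel so that draws for
#' different purposes at the same person-time never collide. Condition-specific
#' draws add the condition's row index to the listed base.
#' @export
rng_channels <- list(
  bg_death        = 1L,
  conception      = 2L,
  sex             = 3L,
  demography      = 4L,
  risk_flag       = 5L,
  anc_init        = 10L,
  anc_first_month = 11L,
  anc_transition  = 12L,
  facility        = 13L,
  facility_level  = 14L,
  pnc_maternal    = 15L,
  pnc_neonatal    = 16L,
  emergency_seek  = 17L,
  delay1          = 18L,
  delay2          = 19L,
  delivery_day    = 20L,
  postterm        = 21L,
  gest_jitter     = 22L,
  onset           = 100L,  # + condition index
  progression     = 200L,  # + condition index
  death           = 300L,  # + condition index
  treatment       = 400L,  # + intervention index
  consumable      = 600L,  # + intervention index
  competence      = 800L,  # + intervention index
  staffing        = 900L   # + intervention index
)
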