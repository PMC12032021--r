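# Shared fixtures: one default parameter set reused across tests (construction
# is deterministic), plus small helpers for binomial bounds.

PS <- generate_default_parameters()

# Exact two-sided binomial bounds at the given confidence level.
binom_bounds <- function(n, p, conf = 0.99) {
  a <- (1 - conf) / 2
  c(lo = stats::qbinom(a, n, p), hi = stats::qbinom(1 - a, n, p))
}

expect_within_binom <- function(successes, n, p, conf = 0.99) {
  b <- binom_bounds(n, p, conf)
  expect_gte(successes, b[["lo"]])
  expect_lte(successes, b[["hi"]])
}

# A small table of ongoing pregnancies in the engine's internal layout.
make_preg <- function(n, seed = 1L, gm = 0L) {
  pop <- initialise_population(max(20, n * 6), seed = seed, ps = PS)
  conc <- initiate_pregnancies(pop, 0L, PS, seed = seed, prob_override = 1)
  preg <- maternalsim:::new_preg_rows(conc$pop, conc$new, 0L)
  preg <- preg[seq_len(min(n, nrow(preg))), ]
  preg$gm <- gm
  preg
}

# A parameter set with one scenario-style override bundle attached directly.
with_overrides <- function(ps, ...) {
  ov <- maternalsim:::default_overrides()
  dots <- list(...)
  for (f in names(dots)) ov[[f]] <- dots[[f]]
  ps$overrides <- ov
  ps
}
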