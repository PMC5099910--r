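# Shared fixtures for calibration tests: a compact, fast design (short
# horizon) and restricted-fit helpers.

compact_design <- function(cv = 0, replicates = 1L,
                           postnatal_days = seq(0, 30, by = 3)) {
  study_design(prenatal_dpc = c(14.5, 16.5, 17.5, 18.5, 19.5),
               postnatal_days = postnatal_days,
               replicates = replicates, cv = cv)
}

fit_control <- function() {
  step_control(rtol = 1e-6, atol = 1e-10, grid_pre = 0.02, grid_post = 0.1)
}

# Clamp every free parameter of (class, variant) at the ground truth except
# `free`; returns the named list handed to fit_model(fixed = ...).
clamp_except <- function(spec, free) {
  flat <- thymodyn:::spec_to_flat(spec)
  as.list(flat[setdiff(names(flat), free)])
}

# Search box centred on the truth for a restricted fit.
box_around <- function(spec, free, factor = 4) {
  flat <- thymodyn:::spec_to_flat(spec)
  list(lower = flat[free] / factor, upper = flat[free] * factor)
}
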