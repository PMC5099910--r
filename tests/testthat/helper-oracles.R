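# Independent oracles: a second, hand-coded transcription of the model
# equations and a brute-force fixed-step Euler integrator with an explicit
# history buffer. Nothing here touches the package's solver path.

# Hand-coded derivative of the five-equation system (independent of rhs()).
oracle_deriv <- function(t, y, Nlag, sp, t_ref, spec, influx_mode) {
  pN <- sp$c_N * sp$b_N * exp(-sp$b_N * (t - t_ref))
  pP <- sp$c_P * sp$b_P * exp(-sp$b_P * (t - t_ref))
  p4 <- sp$c_48 * sp$b_4 * exp(-sp$b_4 * (t - t_ref))
  p8 <- sp$c_48 * sp$b_8 * exp(-sp$b_8 * (t - t_ref))
  if (spec$model_class == "M2") {
    pN <- pN * (1 - y[1] / sp$K_N)
    fac <- 1 - (y[2] + y[3] + y[4]) / sp$K
    pP <- pP * fac; p4 <- p4 * fac; p8 <- p8 * fac
  }
  b <- if (influx_mode == "zero") 0 else if (influx_mode == "constant_b0") {
    spec$b0
  } else {
    spec$b0 / (1 + exp(-spec$beta * (t - spec$tau_b)))
  }
  outN <- if (spec$delay_convention == "both_delayed") Nlag else y[1]
  c(pN * y[1] - sp$d_N * y[1] - sp$s_N * outN + b,
    pP * y[2] - sp$d_P * y[2] - (sp$s_4 + sp$s_8) * y[2] + sp$s_N * Nlag,
    p4 * y[3] - sp$d_4 * y[3] - sp$s_04 * y[3] + sp$s_4 * y[2],
    p8 * y[4] - sp$d_8 * y[4] - sp$s_08 * y[4] + sp$s_8 * y[2],
    sp$d_N * y[1] + sp$d_P * y[2] + sp$d_4 * y[3] + sp$d_8 * y[4] -
      sp$delta * y[5])
}

# Fixed-step Euler with an explicit DN history buffer (linear interpolation
# between buffer nodes for the lagged value).
euler_dde <- function(spec, t_end, h = 1e-3,
                      influx_mode_postnatal = "constant_b0") {
  t0 <- spec$t0
  birth <- spec$birth_time
  n <- ceiling((t_end - t0) / h)
  times <- t0 + h * (0:n)
  Y <- matrix(0, n + 1, 5)
  for (k in 1:n) {
    t <- times[k]
    prenatal <- t < birth
    sp <- if (prenatal) spec$prenatal else spec$postnatal
    t_ref <- if (prenatal) t0 else {
      if (spec$postnatal_decay_clock == "restart") birth else t0
    }
    imode <- if (prenatal) "logistic" else influx_mode_postnatal
    tl <- t - sp$tau_N
    Nlag <- if (tl <= t0) 0 else {
      idx <- (tl - t0) / h
      i0 <- floor(idx)
      w <- idx - i0
      (1 - w) * Y[i0 + 1, 1] + w * Y[min(i0 + 2, k), 1]
    }
    Y[k + 1, ] <- Y[k, ] + h * oracle_deriv(t, Y[k, ], Nlag, sp, t_ref,
                                            spec, imode)
  }
  list(times = times, states = Y)
}

# Mixed absolute/relative discrepancy between a trajectory and the Euler
# reference at the reference's grid times: per component, the error is
# scaled by max(|reference|, 0.05 * max_t |reference|). The floor reflects
# the oracle's own accuracy: Euler self-convergence (h = 1e-3 vs 2.5e-4)
# shows its truncation error reaches ~2e-3 in the sub-percent growth tail
# of these trajectories, so pointwise relative comparison is only
# meaningful where a component is within a factor ~20 of its maximum;
# below that the error is measured against that 5% scale.
max_rel_discrepancy <- function(traj, euler) {
  at <- trajectory_at(traj, euler$times)
  worst <- 0
  for (j in 1:5) {
    ref <- euler$states[, j]
    sc <- pmax(abs(ref), 0.05 * max(abs(ref), 1e-12))
    worst <- max(worst, max(abs(at[, j] - ref) / sc))
  }
  worst
}

# Random admissible parameter set with gentle rates: per-capita rates are
# kept near or below ~0.2/day and the influx logistic near ~1/day so that
# the first-order Euler reference at h = 1e-3 stays accurate to well under
# 1e-3 over a 40-day horizon (its global error scales with the squared
# Jacobian magnitude times the horizon).
random_spec <- function(seed, model_class = "M1",
                        delay_convention = "arrival_delayed") {
  set.seed(seed)
  r <- function(lo, hi) stats::runif(1, lo, hi)
  mk_stage <- function() {
    stage_parameters(
      b_N = r(0.03, 0.08), b_P = r(0.03, 0.08),
      b_4 = r(0.03, 0.08), b_8 = r(0.03, 0.08),
      c_N = r(0.4, 1.0), c_P = r(0.4, 1.0), c_48 = r(0.3, 0.8),
      s_N = r(0.03, 0.08), s_4 = r(0.01, 0.05), s_8 = r(0.01, 0.05),
      s_04 = r(0.01, 0.06), s_08 = r(0.01, 0.06),
      d_N = r(0.01, 0.04), d_P = r(0.01, 0.04),
      d_4 = r(0.01, 0.04), d_8 = r(0.01, 0.04),
      delta = r(0.05, 0.15), tau_N = r(0.8, 2.5),
      K_N = if (model_class == "M2") r(0.5, 3) else NA_real_,
      K = if (model_class == "M2") r(1, 6) else NA_real_
    )
  }
  model_spec(model_class, "V1", mk_stage(), mk_stage(),
             t0 = r(9.8, 10.2), b0 = r(2e-4, 6e-4), tau_b = r(16.5, 18),
             delay_convention = delay_convention)
}

# Minimal hand-built trajectory object for milestone unit tests.
fake_trajectory <- function(times, states, t0 = times[1], birth = 19.5) {
  colnames(states) <- c("N", "P", "SP4", "SP8", "D")
  structure(list(times = times, states = states,
                 spec = list(t0 = t0, birth_time = birth),
                 influx_mode_postnatal = "constant_b0",
                 raw_min = min(states),
                 segments = c(t0 = t0, birth = birth,
                              horizon = times[length(times)])),
            class = "thymus_trajectory")
}
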