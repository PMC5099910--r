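# Rate functions of the delayed compartmental thymocyte model.

ONE_CELL <- 1e-7  # one cell on the 1e7-cell scale

#' Solve the logistic steepness so that influx at t0 equals one cell
#'
#' The progenitor influx is the three-parameter logistic
#' `b(t) = b0 / (1 + exp(-beta * (t - tau_b)))`. `beta` is never estimated:
#' it is pinned by the requirement that the influx at thymopoiesis onset
#' equals a single progenitor cell, `b(t0) = 1e-7` (in 1e7-cell units).
#' The closed-form solution is
#' `beta = log(b0/1e-7 - 1) / (tau_b - t0)`.
#'
#' @param b0 Influx plateau, 1e7 cells/day; must exceed `2e-7` so that a
#'   non-negative steepness exists.
#' @param tau_b Logistic midpoint, days post-conception; must exceed `t0`.
#' @param t0 Thymopoiesis onset, days post-conception.
#' @return The steepness `beta` (1/day).
#' @export
solve_beta <- function(b0, tau_b, t0) {
  if (!is.finite(b0) || b0 <= ONE_CELL) {
    stop("infeasible influx: plateau b0 must exceed one cell (1e-7 units)")
  }
  if (tau_b <= t0) {
    stop("infeasible influx: logistic midpoint tau_b must exceed t0")
  }
  ratio <- b0 / ONE_CELL - 1
  if (ratio < 1) {
    # would require a decreasing logistic (beta < 0)
    stop("infeasible influx: no non-negative steepness reaches 1e-7 at t0")
  }
  log(ratio) / (tau_b - t0)
}

#' Progenitor influx into the DN compartment
#'
#' Prenatally the influx follows the logistic
#' `b(t) = b0 / (1 + exp(-beta * (t - tau_b)))`; the ablation scenarios
#' replace the postnatal influx by a constant at the birth plateau
#' (`constant_b0`) or by zero (`zero`).
#'
#' @param spec A [model_spec()] (supplies `b0`, `tau_b` and the derived
#'   `beta`).
#' @param t Time(s), days post-conception. Vectorized.
#' @param mode `"logistic"`, `"constant_b0"` or `"zero"`.
#' @return Influx in 1e7 cells/day, same length as `t`.
#' @export
progenitor_influx <- function(spec, t,
                              mode = c("logistic", "constant_b0", "zero")) {
  mode <- match.arg(mode)
  switch(mode,
    logistic = {
      if (is.null(spec$beta) || !is.finite(spec$beta)) {
        stop("beta is unset; call solve_beta()/model_spec() first")
      }
      spec$b0 / (1 + exp(-spec$beta * (t - spec$tau_b)))
    },
    constant_b0 = rep(spec$b0, length(t)),
    zero = rep(0, length(t))
  )
}

# Reference time of the proliferation-decay clock. A stage tagged by
# model_spec() uses its own clock (prenatal: t0; postnatal: birth under the
# "restart" convention); untagged stages fall back to inferring the phase
# from t.
decay_reference <- function(stage, spec, t) {
  phase <- attr(stage, "phase")
  if (is.null(phase)) {
    phase <- ifelse(t < spec$birth_time, "prenatal", "postnatal")
  }
  ifelse(phase == "prenatal" | spec$postnatal_decay_clock == "absolute",
         spec$t0, spec$birth_time)
}

#' Per-capita proliferation rate of a thymocyte population
#'
#' Model class `"M1"` uses the exponentially decreasing law
#' `p(t) = c * b * exp(-b * (t - t_ref))` where `t_ref` is `t0` prenatally
#' and (by default) the birth time postnatally, so that the decay clock
#' restarts at birth. Class `"M2"` multiplies this by a logistic density
#' factor: `(1 - N/K_N)` for the DN population and
#' `(1 - (P + SP4 + SP8)/K)` for DP, SP4 and SP8.
#'
#' @param stage [stage_parameters()] of the stage that `t` falls in.
#' @param spec The enclosing [model_spec()].
#' @param population One of `"DN"`, `"DP"`, `"SP4"`, `"SP8"`.
#' @param t Time, days post-conception; must be `>= t0`.
#' @param state Numeric state vector `c(N, P, SP4, SP8, D)`; required under
#'   `"M2"` for the density factor, ignored under `"M1"`.
#' @return Per-capita proliferation rate, 1/day.
#' @export
proliferation_rate <- function(stage, spec,
                               population = c("DN", "DP", "SP4", "SP8"),
                               t, state = NULL) {
  population <- match.arg(population)
  if (any(t < spec$t0)) {
    stop("proliferation rate is undefined before thymopoiesis onset t0")
  }
  t_ref <- decay_reference(stage, spec, t)
  par <- switch(population,
    DN = c(stage$c_N, stage$b_N),
    DP = c(stage$c_P, stage$b_P),
    SP4 = c(stage$c_48, stage$b_4),
    SP8 = c(stage$c_48, stage$b_8)
  )
  rate <- par[1] * par[2] * exp(-par[2] * (t - t_ref))
  if (spec$model_class == "M2") {
    if (is.null(state)) stop("state is required under model class M2")
    dens <- if (population == "DN") {
      1 - state[1] / stage$K_N
    } else {
      1 - (state[2] + state[3] + state[4]) / stage$K
    }
    rate <- rate * dens
  }
  rate
}

#' Right-hand side of the five-compartment delayed system
#'
#' State ordering is `c(N, P, SP4, SP8, D)` (DN, DP, SP4, SP8, apoptotic),
#' in 1e7-cell units. The derivative implements, per compartment:
#' proliferation minus death minus transfer-out, plus the upstream input —
#' the progenitor influx `b(t)` for DN, the lagged DN outflow
#' `s_N * N(t - tau_N)` for DP, and `s_4 * P` / `s_8 * P` for SP4/SP8.
#' Exported SP4/SP8 cells (`s_04`, `s_08` terms) leave the system; the
#' apoptotic compartment collects all death terms and degrades at `delta`.
#'
#' This R implementation is the reference form; the integrator uses an
#' equivalent compiled version for speed.
#'
#' @param t Time, days post-conception.
#' @param state Numeric vector `c(N, P, SP4, SP8, D)`; negative components
#'   are rejected.
#' @param delayed_N The lagged DN count `N(t - tau_N)` supplied by the
#'   solver's history (0 before thymopoiesis onset).
#' @param spec A [model_spec()].
#' @param stage [stage_parameters()] in force at `t`.
#' @param influx_mode Passed to [progenitor_influx()].
#' @return Named derivative vector, 1e7 cells/day.
#' @export
rhs <- function(t, state, delayed_N, spec, stage,
                influx_mode = c("logistic", "constant_b0", "zero")) {
  influx_mode <- match.arg(influx_mode)
  if (any(state < 0)) stop("negative state components are not admissible")
  N <- state[1]; P <- state[2]; S4 <- state[3]; S8 <- state[4]; D <- state[5]
  p_N <- proliferation_rate(stage, spec, "DN", t, state)
  p_P <- proliferation_rate(stage, spec, "DP", t, state)
  p_4 <- proliferation_rate(stage, spec, "SP4", t, state)
  p_8 <- proliferation_rate(stage, spec, "SP8", t, state)
  b_t <- progenitor_influx(spec, t, influx_mode)
  out_N <- if (spec$delay_convention == "both_delayed") delayed_N else N
  c(
    N = p_N * N - stage$d_N * N - stage$s_N * out_N + b_t,
    P = p_P * P - stage$d_P * P - (stage$s_4 + stage$s_8) * P +
      stage$s_N * delayed_N,
    SP4 = p_4 * S4 - stage$d_4 * S4 - stage$s_04 * S4 + stage$s_4 * P,
    SP8 = p_8 * S8 - stage$d_8 * S8 - stage$s_08 * S8 + stage$s_8 * P,
    D = stage$d_N * N + stage$d_P * P + stage$d_4 * S4 + stage$d_8 * S8 -
      stage$delta * D
  )
}
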