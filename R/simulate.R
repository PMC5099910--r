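# Method-of-steps integration of the delayed five-compartment system.
#
# The delay only enters through the lagged DN count N(t - tau_N). Advancing
# in windows no longer than tau_N makes the lagged term a *known* function of
# the stored solution, so each window is an ordinary ODE solve (deSolve). The
# lagged DN history is handed to the compiled right-hand side as a deSolve
# forcing. Birth is a hard window boundary: integration restarts there with
# the postnatal parameter set (rates may jump, the state is continuous).

CLAMP_TOL <- 1e-9  # components in (-CLAMP_TOL, 0) are clamped to 0

#' Solver settings for [simulate_thymus()]
#'
#' @param rtol,atol Relative/absolute tolerances handed to the ODE solver.
#' @param grid_pre,grid_post Output/history grid step (days) before and
#'   after birth. The stored grid doubles as the interpolation table for the
#'   lagged DN term, so it should stay well below the delay `tau_N`.
#' @param method deSolve integration method (default `"lsoda"`).
#' @return A list of class `step_control`.
#' @export
step_control <- function(rtol = 1e-8, atol = 1e-12,
                         grid_pre = 0.01, grid_post = 0.05,
                         method = "lsoda") {
  structure(list(rtol = rtol, atol = atol, grid_pre = grid_pre,
                 grid_post = grid_post, method = method),
            class = "step_control")
}

blowup_stop <- function(t, msg) {
  stop(structure(
    class = c("thymodyn_blowup", "error", "condition"),
    list(message = sprintf("simulation failed at t = %.4f dpc: %s", t, msg),
         call = NULL, time = t)
  ))
}

# Flat parameter vector for the compiled right-hand side.
rhs_parms <- function(spec, stage, t_ref, influx_mode, lag_is_current) {
  mode_flag <- switch(influx_mode, zero = 0, logistic = 1, constant_b0 = 2)
  c(stage$b_N, stage$b_P, stage$b_4, stage$b_8,
    stage$c_N, stage$c_P, stage$c_48,
    stage$s_N, stage$s_4, stage$s_8, stage$s_04, stage$s_08,
    stage$d_N, stage$d_P, stage$d_4, stage$d_8,
    stage$delta, t_ref,
    if (spec$model_class == "M2") 2 else 1,
    if (is.na(stage$K_N)) 1 else stage$K_N,
    if (is.na(stage$K)) 1 else stage$K,
    mode_flag, spec$b0, spec$beta, spec$tau_b,
    if (spec$delay_convention == "both_delayed") 1 else 0,
    if (lag_is_current) 1 else 0)
}

# rhs without the user-facing negativity guard (solver trial steps may dip
# marginally below zero); mirrors the compiled code.
rhs_core <- function(t, state, delayed_N, spec, stage, t_ref, influx_mode) {
  N <- state[1]; P <- state[2]; S4 <- state[3]; S8 <- state[4]; D <- state[5]
  e <- exp(-c(stage$b_N, stage$b_P, stage$b_4, stage$b_8) * (t - t_ref))
  p <- c(stage$c_N * stage$b_N, stage$c_P * stage$b_P,
         stage$c_48 * stage$b_4, stage$c_48 * stage$b_8) * e
  if (spec$model_class == "M2") {
    p <- p * c(1 - N / stage$K_N, rep(1 - (P + S4 + S8) / stage$K, 3))
  }
  b_t <- switch(influx_mode,
    zero = 0,
    logistic = spec$b0 / (1 + exp(-spec$beta * (t - spec$tau_b))),
    constant_b0 = spec$b0)
  out_N <- if (spec$delay_convention == "both_delayed") delayed_N else N
  c(p[1] * N - stage$d_N * N - stage$s_N * out_N + b_t,
    p[2] * P - stage$d_P * P - (stage$s_4 + stage$s_8) * P +
      stage$s_N * delayed_N,
    p[3] * S4 - stage$d_4 * S4 - stage$s_04 * S4 + stage$s_4 * P,
    p[4] * S8 - stage$d_8 * S8 - stage$s_08 * S8 + stage$s_8 * P,
    stage$d_N * N + stage$d_P * P + stage$d_4 * S4 + stage$d_8 * S8 -
      stage$delta * D)
}

# Advance one stage segment [t_from, t_to] in method-of-steps windows.
# env holds the growing storage (times, states, and the DN history used for
# lag lookups) shared across segments.
advance_segment <- function(env, spec, stage, t_from, t_to, t_ref,
                            influx_mode, grid, ctrl, use_compiled) {
  tau <- stage$tau_N
  lag_is_current <- tau <= 1e-10
  window <- if (lag_is_current) (t_to - t_from) else tau
  lag_lookup <- function(s) {
    out <- numeric(length(s))
    pos <- s >= spec$t0
    if (any(pos) && length(env$times) >= 2) {
      out[pos] <- stats::approx(env$times, env$N_hist, xout = s[pos],
                                rule = 2)$y
    } else if (any(pos)) {
      out[pos] <- env$N_hist[1]
    }
    out
  }
  cur <- t_from
  state <- env$state
  while (cur < t_to - 1e-12) {
    wend <- min(cur + window, t_to)
    tout <- seq(cur, wend, by = grid)
    if (tout[length(tout)] < wend - 1e-12) tout <- c(tout, wend)
    tout[length(tout)] <- wend
    if (use_compiled) {
      ft <- env$times[env$times >= cur - tau - 1e-12 &
                        env$times <= wend - tau + 1e-12] + tau
      ft <- sort(unique(c(cur, ft[ft > cur & ft < wend], wend)))
      forc <- cbind(ft, lag_lookup(ft - tau))
      sol <- deSolve::ode(
        y = state, times = tout, func = "thymodyn_derivs",
        parms = rhs_parms(spec, stage, t_ref, influx_mode, lag_is_current),
        dllname = "thymodyn", initfunc = "thymodyn_initmod",
        initforc = "thymodyn_initforc", forcings = forc,
        method = ctrl$method, rtol = ctrl$rtol, atol = ctrl$atol)
    } else {
      hist_t <- env$times
      hist_N <- env$N_hist
      lag_fun <- if (lag_is_current) {
        NULL
      } else if (length(hist_t) < 2) {
        function(s) 0
      } else {
        f <- stats::approxfun(hist_t, hist_N, rule = 2)
        function(s) if (s < spec$t0) 0 else f(s)
      }
      func <- function(t, y, p) {
        dN <- if (lag_is_current) y[1] else lag_fun(t - tau)
        list(rhs_core(t, y, dN, spec, stage, t_ref, influx_mode))
      }
      sol <- deSolve::ode(y = state, times = tout, func = func, parms = NULL,
                          method = ctrl$method, rtol = ctrl$rtol,
                          atol = ctrl$atol)
    }
    ys <- unname(as.matrix(sol[, 2:6, drop = FALSE]))
    if (anyNA(ys) || any(!is.finite(ys))) {
      bad <- which(!stats::complete.cases(ys) | rowSums(!is.finite(ys)) > 0)[1]
      blowup_stop(tout[bad], "non-finite state (blow-up)")
    }
    mn <- min(ys)
    if (mn < env$raw_min) env$raw_min <- mn
    if (mn < -CLAMP_TOL) {
      blowup_stop(tout[which(ys < -CLAMP_TOL, arr.ind = TRUE)[1, 1]],
                  sprintf("state component below -%g", CLAMP_TOL))
    }
    ys[ys < 0] <- 0
    keep <- -1L  # drop duplicated window start
    env$times <- c(env$times, tout[keep])
    env$states <- rbind(env$states, ys[keep, , drop = FALSE])
    env$N_hist <- c(env$N_hist, ys[keep, 1])
    state <- ys[nrow(ys), ]
    cur <- wend
  }
  env$state <- state
  invisible(env)
}

new_trajectory <- function(env, spec, influx_mode_postnatal, ctrl, horizon) {
  colnames(env$states) <- c("N", "P", "SP4", "SP8", "D")
  structure(list(
    times = env$times,
    states = env$states,
    spec = spec,
    influx_mode_postnatal = influx_mode_postnatal,
    raw_min = env$raw_min,
    control = ctrl,
    segments = c(t0 = spec$t0, birth = spec$birth_time, horizon = horizon)
  ), class = "thymus_trajectory")
}

#' Simulate the thymocyte system over the lifespan
#'
#' Integrates the delayed five-compartment system from thymopoiesis onset
#' `t0` (all compartments empty, history identically zero) to the horizon,
#' by the method of steps: windows no longer than the stage delay `tau_N`,
#' the lagged DN count interpolated from the stored solution. Integration is
#' restarted at birth with the postnatal parameter set; the prenatal influx
#' is always the logistic, the postnatal influx is selected by
#' `influx_mode_postnatal` (`"constant_b0"` keeps the birth-level inflow,
#' `"zero"` ablates the progenitor supply).
#'
#' @param spec A [model_spec()].
#' @param influx_mode_postnatal `"constant_b0"` or `"zero"`.
#' @param control A [step_control()].
#' @param horizon End of integration, days post-conception (defaults to
#'   `spec$horizon`). May be at or before birth, in which case only the
#'   prenatal segment is run.
#' @param use_compiled Use the compiled right-hand side (default) or the
#'   plain-R reference implementation.
#' @param prenatal_cache Internal: a previously computed prenatal segment
#'   (from [simulate_thymus()] with `horizon = spec$birth_time`) to be
#'   reused so that comparison scenarios share a bit-identical prenatal
#'   trajectory.
#' @return A `thymus_trajectory`: dense time grid, state matrix with columns
#'   `N`, `P`, `SP4`, `SP8`, `D` (units 1e7 cells), segment boundaries, and
#'   the minimum raw (pre-clamping) state value as a non-negativity
#'   diagnostic.
#' @export
simulate_thymus <- function(spec,
                            influx_mode_postnatal = c("constant_b0", "zero"),
                            control = step_control(),
                            horizon = spec$horizon,
                            use_compiled = TRUE,
                            prenatal_cache = NULL) {
  influx_mode_postnatal <- match.arg(influx_mode_postnatal)
  if (horizon <= spec$t0) stop("horizon must exceed t0")
  env <- new.env(parent = emptyenv())
  if (is.null(prenatal_cache)) {
    env$times <- spec$t0
    env$states <- matrix(0, nrow = 1, ncol = 5)
    env$N_hist <- 0
    env$state <- rep(0, 5)
    env$raw_min <- 0
    pre_end <- min(spec$birth_time, horizon)
    advance_segment(env, spec, spec$prenatal, spec$t0, pre_end,
                    t_ref = spec$t0, influx_mode = "logistic",
                    grid = control$grid_pre, ctrl = control,
                    use_compiled = use_compiled)
  } else {
    env$times <- prenatal_cache$times
    env$states <- prenatal_cache$states
    env$N_hist <- prenatal_cache$states[, 1]
    env$state <- prenatal_cache$states[nrow(prenatal_cache$states), ]
    env$raw_min <- prenatal_cache$raw_min
  }
  if (horizon > spec$birth_time) {
    t_ref_post <- if (spec$postnatal_decay_clock == "restart") {
      spec$birth_time
    } else {
      spec$t0
    }
    advance_segment(env, spec, spec$postnatal, spec$birth_time, horizon,
                    t_ref = t_ref_post, influx_mode = influx_mode_postnatal,
                    grid = control$grid_post, ctrl = control,
                    use_compiled = use_compiled)
  }
  new_trajectory(env, spec, influx_mode_postnatal, control, horizon)
}

#' @export
print.thymus_trajectory <- function(x, ...) {
  cat(sprintf("Thymocyte trajectory %s.%s: %d points, t in [%.3f, %.3f] dpc\n",
              x$spec$model_class, x$spec$variant, length(x$times),
              x$times[1], x$times[length(x$times)]))
  cat(sprintf("  postnatal influx: %s; min raw state: %.3g\n",
              x$influx_mode_postnatal, x$raw_min))
  invisible(x)
}

#' Evaluate a trajectory at arbitrary times
#'
#' Linear interpolation on the stored grid; exact at grid nodes. Times
#' before `t0` return the empty thymus (all zeros).
#'
#' @param traj A `thymus_trajectory`.
#' @param t Times, days post-conception; must not exceed the solved horizon.
#' @return Matrix `length(t) x 5` with columns `N`, `P`, `SP4`, `SP8`, `D`.
#' @export
trajectory_at <- function(traj, t) {
  if (any(t > traj$times[length(traj$times)] + 1e-9)) {
    stop("requested time beyond the solved horizon")
  }
  out <- matrix(0, nrow = length(t), ncol = 5,
                dimnames = list(NULL, colnames(traj$states)))
  ok <- t >= traj$spec$t0
  if (any(ok)) {
    for (j in seq_len(5)) {
      out[ok, j] <- stats::approx(traj$times, traj$states[, j],
                                  xout = t[ok], rule = 2)$y
    }
  }
  out
}

#' Export a trajectory as tidy CSV (plus a JSON metadata sidecar)
#'
#' Columns: `time_dpc`, `time_postnatal`, `N`, `P`, `SP4`, `SP8`, `D`
#' (units 1e7 cells). The sidecar `<path>.meta.json` records the model
#' configuration hash, solver settings and postnatal influx mode.
#'
#' @param traj A `thymus_trajectory`.
#' @param path Output CSV path.
#' @param thin Keep every `thin`-th grid point (default 1 = all).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, thin = 1L) {
  idx <- seq(1, length(traj$times), by = thin)
  if (idx[length(idx)] != length(traj$times)) idx <- c(idx, length(traj$times))
  df <- data.frame(
    time_dpc = traj$times[idx],
    time_postnatal = traj$times[idx] - traj$spec$birth_time,
    traj$states[idx, , drop = FALSE]
  )
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(
    spec_hash = spec_hash(traj$spec),
    model_class = traj$spec$model_class,
    variant = traj$spec$variant,
    influx_mode_postnatal = traj$influx_mode_postnatal,
    solver = traj$control[c("rtol", "atol", "grid_pre", "grid_post", "method")],
    units = traj$spec$units
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Stable content hash of a model specification (md5 of its canonical YAML).
spec_hash <- function(spec) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  write_model_spec(spec, tf)
  unname(tools::md5sum(tf))
}
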