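# Closed-form limits and oracle checks for the method-of-steps integrator.

zero_stage <- function() {
  stage_parameters(b_N = 0, b_P = 0, b_4 = 0, b_8 = 0,
                   c_N = 0, c_P = 0, c_48 = 0,
                   s_N = 0, s_4 = 0, s_8 = 0, s_04 = 0, s_08 = 0,
                   d_N = 0, d_P = 0, d_4 = 0, d_8 = 0,
                   delta = 0, tau_N = 1)
}

# stable log(1 + exp(x))
log1pexp <- function(x) ifelse(x > 30, x, log1p(exp(x)))

test_that("with all rates zero the system reduces to the influx integral", {
  spec <- model_spec("M1", "V1", zero_stage(), zero_stage(),
                     t0 = 10.2, b0 = 0.004, tau_b = 15)
  ctrl <- step_control(rtol = 1e-10, atol = 1e-14)
  horizon <- spec$birth_time + 30
  # logistic influx has the exact integral (b0/beta) * log(1 + e^(beta(t-tau)))
  cumulative_influx <- function(t) {
    spec$b0 / spec$beta * (log1pexp(spec$beta * (t - spec$tau_b)) -
                             log1pexp(spec$beta * (spec$t0 - spec$tau_b)))
  }
  traj <- simulate_thymus(spec, "constant_b0", control = ctrl,
                          horizon = horizon)
  n_birth <- cumulative_influx(spec$birth_time)
  for (t in c(12, 15, 18, 19.5)) {
    expect_equal(unname(trajectory_at(traj, t)[1, "N"]), cumulative_influx(t),
                 tolerance = 1e-8)
  }
  # postnatal constant influx: exact linear growth
  for (t in c(25, 40, 49.5)) {
    expect_equal(unname(trajectory_at(traj, t)[1, "N"]),
                 n_birth + spec$b0 * (t - spec$birth_time),
                 tolerance = 1e-8)
  }
  # all other compartments stay identically zero
  expect_true(all(traj$states[, 2:5] == 0))
  # ablated influx: DN frozen at its birth level
  traj0 <- simulate_thymus(spec, "zero", control = ctrl, horizon = horizon)
  expect_equal(unname(trajectory_at(traj0, horizon)[1, "N"]), n_birth,
               tolerance = 1e-8)
})

test_that("the DP compartment stays empty until the delayed inflow arrives", {
  spec <- default_ground_truth()
  traj <- simulate_thymus(spec, horizon = spec$t0 + 8)
  tau <- spec$prenatal$tau_N
  before <- traj$times <= spec$t0 + tau - 1e-9
  expect_true(all(traj$states[before, "P"] <= 1e-12))
  expect_gt(trajectory_at(traj, spec$t0 + tau + 1)[1, "P"], 0)
})

test_that("trajectories agree with the brute-force Euler oracle", {
  for (seed in 1:3) {
    cls <- if (seed %% 2 == 0) "M2" else "M1"
    spec <- random_spec(seed, model_class = cls)
    traj <- simulate_thymus(spec, horizon = spec$t0 + 40)
    eul <- euler_dde(spec, spec$t0 + 40, h = 1e-3)
    expect_lt(max_rel_discrepancy(traj, eul), 1e-3)
  }
})

test_that("compiled and plain-R solver paths coincide", {
  for (spec in list(default_ground_truth(), random_spec(5, "M2"))) {
    a <- simulate_thymus(spec, horizon = spec$t0 + 40)
    b <- simulate_thymus(spec, horizon = spec$t0 + 40, use_compiled = FALSE)
    expect_identical(a$times, b$times)
    sc <- pmax(abs(a$states), 1e-3 * max(abs(a$states)))
    expect_lt(max(abs(a$states - b$states) / sc), 5e-5)
  }
})

test_that("states remain non-negative across random admissible models", {
  worst <- 0
  for (seed in 1:20) {
    spec <- random_spec(seed, model_class = if (seed %% 3) "M1" else "M2")
    traj <- simulate_thymus(spec, horizon = spec$t0 + 60)
    worst <- min(worst, traj$raw_min)
    expect_true(all(traj$states >= 0))
  }
  expect_gte(worst, -1e-9)
})

test_that("emergence times are stable under solver-grid refinement", {
  spec <- default_ground_truth()
  coarse <- simulate_thymus(spec, horizon = 19.5,
                            control = step_control(grid_pre = 0.02))
  fine <- simulate_thymus(spec, horizon = 19.5,
                          control = step_control(grid_pre = 0.01))
  d <- abs(emergence_times(coarse) - emergence_times(fine))
  expect_true(all(d < 1e-3))
})

test_that("the dense evaluator reproduces grid nodes exactly", {
  spec <- default_ground_truth()
  traj <- simulate_thymus(spec, horizon = 30)
  idx <- seq(1, length(traj$times), by = 37)
  expect_equal(unname(trajectory_at(traj, traj$times[idx])),
               unname(traj$states[idx, ]), tolerance = 1e-14)
  expect_error(trajectory_at(traj, 31), "horizon")
})

test_that("delayed negative feedback that drives a state negative is diagnosed", {
  st <- zero_stage()
  st$s_N <- 2; st$tau_N <- 1.5
  spec <- model_spec("M1", "V1", st, st, t0 = 10.2, b0 = 0.004, tau_b = 15,
                     delay_convention = "both_delayed")
  err <- tryCatch(
    suppressWarnings(simulate_thymus(spec, horizon = 19.5)),
    thymodyn_blowup = function(e) e)
  expect_s3_class(err, "thymodyn_blowup")
  expect_true(is.finite(err$time))
})

test_that("trajectory CSV export round-trips the stored grid", {
  tf <- withr::local_tempfile(fileext = ".csv")
  spec <- default_ground_truth()
  traj <- simulate_thymus(spec, horizon = 25)
  write_trajectory(traj, tf)
  back <- utils::read.csv(tf)
  expect_identical(names(back),
                   c("time_dpc", "time_postnatal", "N", "P", "SP4", "SP8", "D"))
  expect_equal(back$time_dpc, traj$times, tolerance = 1e-12)
  expect_equal(back$N, unname(traj$states[, "N"]), tolerance = 1e-12)
  expect_equal(back$time_postnatal, back$time_dpc - 19.5, tolerance = 1e-12)
  expect_true(file.exists(paste0(tf, ".meta.json")))
})
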