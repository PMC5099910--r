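test_that("the MSE objective vanishes on model-generated data", {
  spec <- default_ground_truth()
  obs <- simulate_observations(spec, compact_design(cv = 0), seed = 1)
  for (scale in c("log10", "linear", "relative")) {
    expect_lt(mse_objective(spec, obs, scale), 1e-10)
  }
})

test_that("the MSE objective reproduces hand arithmetic and is symmetric", {
  spec <- default_ground_truth()
  traj <- simulate_thymus(spec, horizon = 25)
  p1 <- trajectory_at(traj, 18)[1, "N"]
  p2 <- trajectory_at(traj, 22)[1, "P"]
  obs <- observation_set(c(18, 22), c("DN", "DP"), c("a", "a"),
                         c(3e6, 5e6))
  expected <- mean(c((log10(3e6 / 1e7) - log10(p1))^2,
                     (log10(5e6 / 1e7) - log10(p2))^2))
  expect_equal(mse_objective(spec, obs, "log10", horizon = 25), expected,
               tolerance = 1e-10)
  # record order is irrelevant
  obs_rev <- observation_set(c(22, 18), c("DP", "DN"), c("a", "a"),
                             c(5e6, 3e6))
  expect_identical(mse_objective(spec, obs, "log10"),
                   mse_objective(spec, obs_rev, "log10"))
})

test_that("simulation failure is penalized with an infinite objective", {
  spec <- default_ground_truth()
  st <- spec$prenatal
  st$s_N <- 6; st$tau_N <- 1.5
  st$c_N <- 0; st$c_P <- 0; st$c_48 <- 0
  bad <- model_spec("M1", "V1", st, spec$postnatal, t0 = spec$t0,
                    b0 = spec$b0, tau_b = spec$tau_b,
                    delay_convention = "both_delayed")
  obs <- observation_set(19.4, "DN", "a", 1e6)
  expect_identical(suppressWarnings(mse_objective(bad, obs)), Inf)
})

test_that("AIC takes the Gaussian least-squares form", {
  expect_equal(aic_score(1, 10, 50), 20)
  expect_equal(aic_score(1, 7, 3), 14)
  # one added parameter costs exactly 2
  expect_equal(aic_score(0.3, 11, 120) - aic_score(0.3, 10, 120), 2)
  expect_equal(aic_score(0.0149, 39, 299), 299 * log(0.0149) + 78)
  expect_lt(abs(aic_score(0.0149, 39, 299) - (-1179.8)), 0.1)
  # AIC ranks like MSE at fixed (k, n)
  mses <- c(0.5, 0.1, 0.9, 0.2)
  expect_identical(order(vapply(mses, aic_score, numeric(1), k = 5, n = 40)),
                   order(mses))
  expect_error(aic_score(0, 5, 10), "mse")
  expect_error(aic_score(-1, 5, 10), "mse")
})

test_that("a restricted fit recovers death rates from noiseless data", {
  spec <- default_ground_truth()
  # observations generated at the same solver control used during fitting,
  # so the noiseless objective floor is numerically zero
  obs <- simulate_observations(spec, compact_design(cv = 0), seed = 7,
                               control = fit_control())
  free <- c("post_d_N", "post_d_P", "post_d_4", "post_d_8")
  fit <- fit_model(
    obs, "M1", "V1",
    ranges = box_around(spec, free),
    seed = 11,
    budget = fit_budget(pop = 10, generations = 25, nm_every = 10,
                        nm_maxit = 150),
    fixed = clamp_except(spec, free),
    control = fit_control())
  truth <- thymodyn:::spec_to_flat(spec)[free]
  expect_true(all(abs(fit$par[free] - truth) / truth < 0.01))
  # feasibility contract
  rng <- box_around(spec, free)
  expect_true(all(fit$par >= rng$lower & fit$par <= rng$upper))
  expect_true(postnatal_constraint_ok(fit$spec$postnatal))
  # elitism: best objective never worsens across generations
  expect_true(all(diff(fit$trace) <= 0))
  expect_identical(fit$k, length(free))
})

test_that("fits are deterministic given the seed", {
  spec <- default_ground_truth()
  obs <- simulate_observations(spec, compact_design(cv = 0.05), seed = 3)
  free <- c("post_d_P", "post_s_N")
  args <- list(obs = obs, model_class = "M1", variant = "V1",
               ranges = box_around(spec, free), seed = 42,
               budget = fit_budget(pop = 8, generations = 6, nm_every = 3,
                                   nm_maxit = 30),
               fixed = clamp_except(spec, free), control = fit_control())
  f1 <- do.call(fit_model, args)
  f2 <- do.call(fit_model, args)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$mse, f2$mse)
})

test_that("V2 fits never expose the derived postnatal amplitudes", {
  spec <- default_ground_truth("M1", "V2")
  obs <- simulate_observations(spec, compact_design(cv = 0), seed = 5)
  fit <- fit_model(obs, "M1", "V2", seed = 2,
                   budget = fit_budget(pop = 5, generations = 1,
                                       nm_every = 5, nm_maxit = 4),
                   control = fit_control())
  expect_identical(length(fit$par), count_free_parameters("M1", "V2"))
  expect_false(any(c("post_c_N", "post_c_P", "post_c_48") %in%
                     names(fit$par)))
  expect_identical(fit$k, 36L)
})

test_that("perturbing a free parameter strictly increases the objective", {
  spec <- default_ground_truth()
  obs <- simulate_observations(spec, compact_design(cv = 0), seed = 9)
  base <- mse_objective(spec, obs, control = fit_control())
  flat <- thymodyn:::spec_to_flat(spec)
  probe <- c("pre_s_N", "pre_tau_N", "post_c_P", "post_b_P", "post_d_N",
             "post_s_4", "b0", "t0")
  for (nm in probe) {
    pert <- flat
    pert[nm] <- pert[nm] * 1.2
    spec_p <- thymodyn:::spec_from_flat(pert, "M1", "V1")
    expect_gt(mse_objective(spec_p, obs, control = fit_control()),
              base + 1e-8)
  }
})

test_that("bootstrap re-estimation is reproducible and well-formed", {
  spec <- default_ground_truth()
  obs <- simulate_observations(
    spec, compact_design(cv = 0.05, replicates = 3,
                         postnatal_days = seq(0, 20, by = 5)), seed = 21)
  free <- c("post_d_P", "post_s_N")
  budget <- fit_budget(pop = 8, generations = 5, nm_every = 3, nm_maxit = 25)
  run <- function() {
    bootstrap_fit(obs, "M1", "V1", ranges = box_around(spec, free),
                  n_boot = 3, master_seed = 99, n_prelim = 2,
                  prelim_budget = budget,
                  fixed = clamp_except(spec, free),
                  control = fit_control())
  }
  b1 <- run()
  expect_identical(b1$n_boot, 3L)
  expect_identical(nrow(b1$parameters), 3L)
  expect_false(b1$partial)
  # percentile interval brackets the bootstrap average, per parameter
  expect_true(all(b1$ci[1, ] <= b1$average & b1$average <= b1$ci[2, ]))
  b2 <- run()
  expect_identical(b1$parameters, b2$parameters)
  # default bootstrap size is 100 re-estimations
  expect_identical(eval(formals(bootstrap_fit)$n_boot), 100L)
})

test_that("degenerate replicate structure triggers a warning", {
  spec <- default_ground_truth()
  obs <- observation_set(c(18, 19), c("DN", "DN"), c("a", "a"), c(1e6, 2e6))
  expect_warning(
    tryCatch(
      bootstrap_fit(obs, "M1", "V1",
                    ranges = box_around(spec, "post_d_P"),
                    n_boot = 1, master_seed = 1, n_prelim = 1,
                    prelim_budget = fit_budget(pop = 5, generations = 1,
                                               nm_every = 5, nm_maxit = 2),
                    fixed = clamp_except(spec, "post_d_P"),
                    control = fit_control()),
      error = function(e) NULL),
    "replicates")
})
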