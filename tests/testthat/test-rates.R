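test_that("solve_beta pins the influx at one cell at thymopoiesis onset", {
  # defining property across random feasible triples
  set.seed(42)
  for (i in 1:100) {
    b0 <- stats::runif(1, 3e-7, 0.05)
    t0 <- stats::runif(1, 9, 11)
    tau_b <- t0 + stats::runif(1, 1, 8)
    beta <- solve_beta(b0, tau_b, t0)
    infl <- b0 / (1 + exp(-beta * (t0 - tau_b)))
    expect_lt(abs(infl - 1e-7) / 1e-7, 1e-8)
  }
})

test_that("solve_beta agrees with an independent bisection root-finder", {
  b0 <- 0.01; tau_b <- 15; t0 <- 10.3
  target <- function(beta) b0 / (1 + exp(-beta * (t0 - tau_b))) - 1e-7
  lo <- 0; hi <- 50
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (target(mid) > 0) lo <- mid else hi <- mid
  }
  expect_equal(solve_beta(b0, tau_b, t0), (lo + hi) / 2, tolerance = 1e-8)
})

test_that("solve_beta signals infeasible influx configurations", {
  expect_error(solve_beta(1e-8, 15, 10.3), "infeasible")
  # plateau above one cell but below the level a non-negative steepness needs
  expect_error(solve_beta(1.5e-7, 15, 10.3), "infeasible")
  expect_error(solve_beta(0.01, 10.3, 15), "infeasible")
})

test_that("progenitor influx modes follow their defining shapes", {
  spec <- default_ground_truth()
  # half plateau at the logistic midpoint
  expect_equal(progenitor_influx(spec, spec$tau_b, "logistic"),
               spec$b0 / 2, tolerance = 1e-12)
  tt <- seq(spec$t0, spec$birth_time, length.out = 200)
  b <- progenitor_influx(spec, tt, "logistic")
  expect_true(all(diff(b) >= 0))
  expect_true(all(b <= spec$b0))
  expect_identical(progenitor_influx(spec, tt, "zero"), rep(0, 200))
  expect_identical(progenitor_influx(spec, tt, "constant_b0"),
                   rep(spec$b0, 200))
  nob <- spec; nob$beta <- NA_real_
  expect_error(progenitor_influx(nob, 12, "logistic"), "beta")
})

test_that("M1 proliferation is the decreasing exponential law", {
  spec <- default_ground_truth()
  st <- spec$prenatal
  st$b_N <- 0.1; st$c_N <- 5
  sp <- spec; sp$t0 <- 10.3; sp$prenatal <- st
  # direct symbolic evaluation of the law: c * b * exp(-b (t - t0))
  expect_equal(proliferation_rate(st, sp, "DN", 10.3), 5 * 0.1,
               tolerance = 1e-12)
  expect_equal(proliferation_rate(st, sp, "DN", 20.3),
               5 * 0.1 * exp(-0.1 * 10), tolerance = 1e-12)
  # strict decrease and vanishing tail
  expect_gt(proliferation_rate(st, sp, "DN", 12),
            proliferation_rate(st, sp, "DN", 19))
  expect_lt(proliferation_rate(st, sp, "DN", sp$t0 + 1e4),
            1e-6 * proliferation_rate(st, sp, "DN", sp$t0))
  expect_error(proliferation_rate(st, sp, "DN", 9.0), "t0")
  expect_error(proliferation_rate(st, sp, "DX", 12))
})

test_that("M1 proliferation is positive and strictly decreasing on a grid", {
  for (seed in 1:5) {
    spec <- random_spec(seed)
    tt <- seq(spec$t0, spec$birth_time, length.out = 100)
    for (pop in c("DN", "DP", "SP4", "SP8")) {
      r <- vapply(tt, function(t) {
        proliferation_rate(spec$prenatal, spec, pop, t)
      }, numeric(1))
      expect_true(all(r > 0))
      expect_true(all(diff(r) < 0))
    }
  }
})

test_that("the M2 density factor brakes growth relative to M1", {
  m2 <- random_spec(7, model_class = "M2")
  m1 <- m2; m1$model_class <- "M1"
  at_cap <- c(m2$prenatal$K_N, m2$prenatal$K, 0, 0, 0.1)
  for (pop in c("DN", "DP", "SP4", "SP8")) {
    r2 <- proliferation_rate(m2$prenatal, m2, pop, 12, at_cap)
    r1 <- proliferation_rate(m1$prenatal, m1, pop, 12, at_cap)
    expect_lt(r2, r1)
  }
  # at carrying capacity the DN density factor nullifies proliferation
  expect_equal(proliferation_rate(m2$prenatal, m2, "DN", 12, at_cap), 0)
  expect_error(proliferation_rate(m2$prenatal, m2, "DN", 12, NULL), "state")
})

test_that("the empty thymus only feels the influx source term", {
  spec <- default_ground_truth()
  d <- rhs(15, rep(0, 5), 0, spec, spec$prenatal, "logistic")
  expect_equal(unname(d),
               c(progenitor_influx(spec, 15, "logistic"), 0, 0, 0, 0),
               tolerance = 1e-15)
  expect_error(rhs(15, c(-1, 0, 0, 0, 0), 0, spec, spec$prenatal), "negative")
})

test_that("rhs satisfies the mass-balance identity on random states", {
  set.seed(11)
  for (i in 1:20) {
    spec <- random_spec(i, model_class = sample(c("M1", "M2"), 1))
    st <- spec$prenatal
    y <- stats::runif(5, 0, 2)
    dl <- stats::runif(1, 0, 2)
    t <- stats::runif(1, spec$t0, spec$birth_time)
    d <- rhs(t, y, dl, spec, st, "logistic")
    prol <- sum(vapply(c("DN", "DP", "SP4", "SP8"), function(p) {
      proliferation_rate(st, spec, p, t, y)
    }, numeric(1)) * y[1:4])
    expected <- prol + progenitor_influx(spec, t, "logistic") -
      st$delta * y[5] - st$s_04 * y[3] - st$s_08 * y[4] +
      st$s_N * dl - st$s_N * y[1]
    expect_equal(sum(d), expected, tolerance = 1e-12)
  }
})

test_that("rhs matches an independent transcription of the equations", {
  for (seed in c(3, 17)) {
    for (cls in c("M1", "M2")) {
      for (conv in c("arrival_delayed", "both_delayed")) {
        spec <- random_spec(seed, model_class = cls,
                            delay_convention = conv)
        y <- c(1, 2, 0.5, 0.4, 0.1)
        d <- rhs(12.5, y, 0.8, spec, spec$prenatal, "logistic")
        o <- oracle_deriv(12.5, y, 0.8, spec$prenatal, spec$t0, spec,
                          "logistic")
        expect_equal(unname(d), o, tolerance = 1e-12)
        # postnatal stage with restarted decay clock
        d2 <- rhs(25, y, 0.8, spec, spec$postnatal, "constant_b0")
        o2 <- oracle_deriv(25, y, 0.8, spec$postnatal, spec$birth_time,
                           spec, "constant_b0")
        expect_equal(unname(d2), o2, tolerance = 1e-12)
      }
    }
  }
})
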