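# Model calibration: MSE objective, AIC scoring, differential-evolution +
# Nelder-Mead hybrid optimization, and bootstrap re-estimation.

LOG10_FLOOR <- 1e-8  # floor (1e7-cell units) for log10 residuals

# Deterministic seed-splitting: every source of randomness below a master
# seed is derived through this map (kept within 32-bit integer range).
derive_seed <- function(master, k) {
  as.integer((as.double(master) %% 2147483563) * 40014 %% 2147483563 +
               k * 10007) %% 2147483562L + 1L
}

# Model predictions (1e7-cell units) for each observation record.
predict_observations <- function(traj, obs) {
  st <- trajectory_at(traj, obs$time_dpc)
  pred <- numeric(nrow(obs))
  for (pop in unique(obs$population)) {
    i <- obs$population == pop
    pred[i] <- switch(pop,
      DN = st[i, "N"], DP = st[i, "P"],
      SP4 = st[i, "SP4"], SP8 = st[i, "SP8"],
      total = rowSums(st[i, 1:4, drop = FALSE]),
      apoptotic = st[i, "D"])
  }
  pred
}

#' Mean squared error of a model against an observation set
#'
#' The mean over all observation records of the squared residual between the
#' transformed observed count and the transformed model prediction at the
#' record's time and population. The default transformation is `log10` of
#' counts in 1e7-cell units, floored at `1e-8`; `"linear"` uses raw 1e7-cell
#' units and `"relative"` divides residuals by the (floored) observation.
#'
#' @param spec A [model_spec()].
#' @param obs An [observation_set()].
#' @param residual_scale `"log10"`, `"linear"` or `"relative"`.
#' @param control A [step_control()] for the underlying simulation.
#' @param horizon Simulation horizon; defaults to just past the last
#'   observation.
#' @param use_compiled Passed to [simulate_thymus()].
#' @return The MSE (dimensionless). Simulation failure yields `Inf`.
#' @export
mse_objective <- function(spec, obs,
                          residual_scale = c("log10", "linear", "relative"),
                          control = step_control(), horizon = NULL,
                          use_compiled = TRUE) {
  residual_scale <- match.arg(residual_scale)
  if (is.null(horizon)) horizon <- max(obs$time_dpc) + 1e-6
  traj <- tryCatch(
    simulate_thymus(spec, "constant_b0", control = control,
                    horizon = horizon, use_compiled = use_compiled),
    error = function(e) NULL)
  if (is.null(traj)) return(Inf)
  pred <- predict_observations(traj, obs)
  y <- obs$count_cells / 1e7
  r <- switch(residual_scale,
    log10 = log10(pmax(y, LOG10_FLOOR)) - log10(pmax(pred, LOG10_FLOOR)),
    linear = y - pred,
    relative = (y - pred) / pmax(y, LOG10_FLOOR))
  mean(r^2)
}

#' Akaike information criterion for a least-squares fit
#'
#' Gaussian least-squares form: `AIC = n * ln(MSE) + 2k`.
#'
#' @param mse Mean squared error (> 0).
#' @param k Number of estimated parameters.
#' @param n Number of residuals.
#' @return The AIC (dimensionless).
#' @export
aic_score <- function(mse, k, n) {
  stopifnot(n > 0)
  if (!is.finite(mse) || mse <= 0) stop("aic_score requires mse > 0")
  n * log(mse) + 2 * k
}

#' Default box search ranges for calibration
#'
#' Wide, non-negativity-respecting boxes for every free parameter of the
#' requested model configuration.
#'
#' @inheritParams count_free_parameters
#' @return List with named numeric vectors `lower` and `upper` over
#'   [free_parameter_names()].
#' @export
default_search_ranges <- function(model_class = c("M1", "M2"),
                                  variant = c("V1", "V2")) {
  model_class <- match.arg(model_class)
  variant <- match.arg(variant)
  base <- list(
    b_N = c(0.001, 0.8), b_P = c(0.001, 0.8),
    b_4 = c(0.001, 0.8), b_8 = c(0.001, 0.8),
    c_N = c(0.1, 60), c_P = c(0.1, 60), c_48 = c(0.1, 60),
    s_N = c(1e-4, 0.8), s_4 = c(1e-4, 0.5), s_8 = c(1e-4, 0.5),
    s_04 = c(1e-4, 0.8), s_08 = c(1e-4, 0.8),
    d_N = c(1e-4, 0.5), d_P = c(1e-4, 0.5),
    d_4 = c(1e-4, 0.5), d_8 = c(1e-4, 0.5),
    delta = c(0.01, 3), tau_N = c(0.5, 4.5),
    K_N = c(0.05, 20), K = c(0.5, 60)
  )
  nm <- free_parameter_names(model_class, variant)
  lower <- upper <- stats::setNames(numeric(length(nm)), nm)
  for (key in nm) {
    raw <- sub("^(pre|post)_", "", key)
    rng <- switch(raw,
      t0 = c(9.5, 12), b0 = c(5e-4, 0.05), tau_b = c(12.5, 19),
      base[[raw]])
    lower[key] <- rng[1]; upper[key] <- rng[2]
  }
  list(lower = lower, upper = upper)
}

#' Optimizer budget for [fit_model()]
#'
#' @param pop Population size of the differential-evolution stage (default
#'   `min(15 * dimension, 600)`, resolved at fit time when `NULL`).
#' @param generations Maximum number of generations.
#' @param nm_every Run a Nelder-Mead refinement of the incumbent every this
#'   many generations (and always at termination).
#' @param nm_maxit Nelder-Mead iteration cap per refinement.
#' @param tol,patience Stop early when the best objective improves by less
#'   than `tol` over `patience` consecutive generations.
#' @param de_f,de_cr Differential-evolution scale factor and crossover rate.
#' @return A list of class `fit_budget`.
#' @export
fit_budget <- function(pop = NULL, generations = 200, nm_every = 20,
                       nm_maxit = 200, tol = 1e-8, patience = 30,
                       de_f = 0.7, de_cr = 0.9) {
  structure(list(pop = pop, generations = generations, nm_every = nm_every,
                 nm_maxit = nm_maxit, tol = tol, patience = patience,
                 de_f = de_f, de_cr = de_cr), class = "fit_budget")
}

# Decode a free-parameter vector (plus clamped values) into a model_spec.
# Returns NULL on any infeasibility (used as a death penalty).
decode_spec <- function(x, free, fixed, model_class, variant,
                        birth_time = 19.5, horizon = NULL) {
  values <- c(stats::setNames(as.numeric(x), free), unlist(fixed))
  spec <- tryCatch(
    spec_from_flat(values, model_class, variant, birth_time = birth_time,
                   horizon = if (is.null(horizon)) birth_time + 730 else horizon),
    error = function(e) NULL)
  if (is.null(spec)) return(NULL)
  if (!postnatal_constraint_ok(spec$postnatal)) return(NULL)
  spec
}

#' Calibrate the model to an observation set
#'
#' Hybrid global/local minimization of [mse_objective()]: a box-constrained
#' differential-evolution search (rand/1/bin with reflection at the bounds)
#' with periodic Nelder-Mead refinement of the incumbent, which is also run
#' once at termination. The logistic steepness `beta` is re-derived from
#' `(b0, tau_b, t0)` at every evaluation; under variant `"V2"` the postnatal
#' amplitudes are recomputed from the prenatal values at every evaluation;
#' candidates violating the postnatal DP constraint
#' `s_N > d_P + s_4 + s_8` receive an infinite objective (death penalty).
#' Deterministic given `seed`.
#'
#' @param obs An [observation_set()].
#' @param model_class,variant Model configuration.
#' @param ranges Search box (see [default_search_ranges()]); must cover all
#'   free, non-clamped parameters.
#' @param seed Integer master seed.
#' @param budget A [fit_budget()].
#' @param fixed Named list of parameters clamped to known values (removed
#'   from the search dimensions); useful for restricted refits.
#' @param residual_scale Passed to [mse_objective()].
#' @param control [step_control()] used during fitting (a slightly coarser
#'   default than for final simulations).
#' @param horizon Simulation horizon during fitting; defaults to just past
#'   the last observation.
#' @param init Optional named vector of starting values; the initial
#'   population is jittered around it instead of sampled uniformly.
#' @param use_compiled Passed to [simulate_thymus()].
#' @return An object of class `thymus_fit`: fitted `spec`, named parameter
#'   vector `par`, `mse`, `aic`, free-parameter count `k`, residual count
#'   `n`, best-per-generation `trace`, evaluation count and `seed`.
#' @export
fit_model <- function(obs, model_class = c("M1", "M2"),
                      variant = c("V1", "V2"),
                      ranges = default_search_ranges(model_class, variant),
                      seed = 1L,
                      budget = fit_budget(),
                      fixed = list(),
                      residual_scale = "log10",
                      control = step_control(rtol = 1e-6, atol = 1e-10,
                                             grid_pre = 0.02,
                                             grid_post = 0.1),
                      horizon = NULL,
                      init = NULL,
                      use_compiled = TRUE) {
  model_class <- match.arg(model_class)
  variant <- match.arg(variant)
  all_free <- free_parameter_names(model_class, variant)
  bad_fixed <- setdiff(names(fixed), all_free)
  if (length(bad_fixed)) {
    stop(sprintf("fixed parameter(s) not in this configuration: %s",
                 paste(bad_fixed, collapse = ", ")))
  }
  free <- setdiff(all_free, names(fixed))
  if (!length(free)) stop("no free parameters left to fit")
  miss <- setdiff(free, intersect(names(ranges$lower), names(ranges$upper)))
  if (length(miss)) {
    stop(sprintf("search ranges missing for: %s", paste(miss, collapse = ", ")))
  }
  lo <- ranges$lower[free]; hi <- ranges$upper[free]
  if (any(lo >= hi)) stop("infeasible search ranges (lower >= upper)")
  if (is.null(horizon)) horizon <- max(obs$time_dpc) + 1e-6
  d <- length(free)
  np <- if (is.null(budget$pop)) min(15L * d, 600L) else budget$pop
  np <- max(np, 5L)

  n_eval <- 0L
  objective <- function(x) {
    n_eval <<- n_eval + 1L
    x <- pmin(pmax(x, lo), hi)
    spec <- decode_spec(x, free, fixed, model_class, variant,
                        horizon = horizon)
    if (is.null(spec)) return(Inf)
    # solver accuracy warnings on doomed candidates are routine during the
    # global search; failures still surface as an infinite objective
    suppressWarnings(
      mse_objective(spec, obs, residual_scale, control = control,
                    horizon = horizon, use_compiled = use_compiled))
  }

  set.seed(seed)
  X <- if (is.null(init)) {
    # log-uniform initial sampling: rate parameters span orders of
    # magnitude, so a log prior seeds far more dynamically tame candidates
    # than a uniform one (the DE moves themselves stay on the linear scale)
    exp(matrix(stats::runif(np * d, rep(log(lo), each = np),
                            rep(log(hi), each = np)),
               nrow = np, ncol = d))
  } else {
    ctr <- pmin(pmax(init[free], lo), hi)
    jit <- matrix(stats::runif(np * d, -0.1, 0.1), np, d) *
      rep(hi - lo, each = np)
    sweep(jit, 2, ctr, "+")
  }
  X <- pmin(pmax(X, rep(lo, each = np)), rep(hi, each = np))
  if (!is.null(init)) X[1, ] <- pmin(pmax(init[free], lo), hi)
  fx <- apply(X, 1, objective)
  trace <- numeric(0)
  stall <- 0L
  best_prev <- min(fx)

  refine <- function() {
    ib <- which.min(fx)
    if (!is.finite(fx[ib])) return(invisible())
    # optim warns when it meets the infinite death penalty; that is the
    # intended constraint mechanism, not a numerical problem
    nm <- suppressWarnings(if (d == 1) {
      stats::optim(X[ib, ], objective, method = "Brent",
                   lower = lo, upper = hi)
    } else {
      stats::optim(X[ib, ], objective, method = "Nelder-Mead",
                   control = list(maxit = budget$nm_maxit))
    })
    if (is.finite(nm$value) && nm$value < fx[ib]) {
      X[ib, ] <<- pmin(pmax(nm$par, lo), hi)
      fx[ib] <<- nm$value
    }
  }

  for (gen in seq_len(budget$generations)) {
    # dithered scale factor: drawing F per generation improves robustness
    # on multimodal landscapes without extra evaluations
    f_gen <- stats::runif(1, 0.5, 1) * budget$de_f / 0.7
    for (i in seq_len(np)) {
      r <- sample(setdiff(seq_len(np), i), 3)
      v <- X[r[1], ] + f_gen * (X[r[2], ] - X[r[3], ])
      # reflect into the box
      v <- ifelse(v < lo, pmin(2 * lo - v, hi), v)
      v <- ifelse(v > hi, pmax(2 * hi - v, lo), v)
      jrand <- sample.int(d, 1)
      cross <- stats::runif(d) < budget$de_cr
      cross[jrand] <- TRUE
      u <- ifelse(cross, v, X[i, ])
      fu <- objective(u)
      if (fu <= fx[i]) {
        X[i, ] <- u
        fx[i] <- fu
      }
    }
    if (gen %% budget$nm_every == 0) refine()
    best <- min(fx)
    trace <- c(trace, best)
    stall <- if (isTRUE(best_prev - best >= budget$tol)) 0L else stall + 1L
    best_prev <- best
    if (stall >= budget$patience) break
  }
  # terminal polish: restarted Nelder-Mead (a fresh simplex around the
  # incumbent) until it stops improving, up to three rounds
  for (round in 1:3) {
    before <- min(fx)
    refine()
    if (!is.finite(before) || before - min(fx) <= budget$tol) break
  }
  ib <- which.min(fx)
  if (!is.finite(fx[ib])) {
    stop("optimization budget exhausted without a finite objective")
  }
  par <- stats::setNames(X[ib, ], free)
  spec <- decode_spec(par, free, fixed, model_class, variant)
  k <- if (length(fixed)) length(free) else
    count_free_parameters(model_class, variant)
  n <- nrow(obs)
  structure(list(
    spec = spec, par = par, fixed = fixed,
    mse = fx[ib], aic = aic_score(fx[ib], k, n),
    k = k, n = n, trace = trace, evaluations = n_eval,
    residual_scale = residual_scale, seed = seed
  ), class = "thymus_fit")
}

#' @export
print.thymus_fit <- function(x, ...) {
  cat(sprintf("Calibrated thymocyte model %s.%s\n",
              x$spec$model_class, x$spec$variant))
  cat(sprintf("  MSE = %.6g (%s scale), AIC = %.4f, k = %d, n = %d\n",
              x$mse, x$residual_scale, x$aic, x$k, x$n))
  cat(sprintf("  %d objective evaluations, %d generations, seed %d\n",
              x$evaluations, length(x$trace), x$seed))
  invisible(x)
}

# Case-resample replicates with replacement within each (time, population)
# cell of the observation set.
resample_observations <- function(obs) {
  key <- interaction(obs$time_dpc, obs$population, drop = TRUE)
  idx <- unlist(lapply(split(seq_len(nrow(obs)), key), function(i) {
    sample(i, length(i), replace = TRUE)
  }), use.names = FALSE)
  out <- obs[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("observation_set", "data.frame")
  out
}

#' Bootstrap re-estimation of model parameters
#'
#' Case-resampling bootstrap: replicates are resampled with replacement
#' within each (time, population) cell, and the model is refit on each
#' resample. Refits start from the incumbent of a preliminary stage
#' (`n_prelim` independent fits on the original data, best kept), with the
#' initial population jittered around it. Per-parameter percentile
#' confidence intervals (2.5/97.5%) and bootstrap averages are reported;
#' the averages define the central ("black curve") model used in downstream
#' scenario analyses.
#'
#' @inheritParams fit_model
#' @param n_boot Number of bootstrap re-estimations (default 100).
#' @param master_seed Master seed; all preliminary, resampling and refit
#'   seeds are derived from it.
#' @param n_prelim Number of preliminary runs used to pick the incumbent.
#' @param prelim_budget,boot_budget [fit_budget()]s for the preliminary and
#'   bootstrap stages.
#' @param max_retries Retries (with derived seeds) for a failed refit before
#'   flagging the result as partial.
#' @param ... Passed through to [fit_model()] (e.g. `fixed`, `control`,
#'   `residual_scale`, `horizon`).
#' @return An object of class `thymus_bootstrap`: list of `n_boot` fits,
#'   parameter matrix, percentile `ci` (2 x p), per-parameter `average`,
#'   the incumbent fit, and the `master_seed`.
#' @export
bootstrap_fit <- function(obs, model_class = c("M1", "M2"),
                          variant = c("V1", "V2"),
                          ranges = default_search_ranges(model_class, variant),
                          n_boot = 100L, master_seed = 1L,
                          n_prelim = 10L,
                          prelim_budget = fit_budget(),
                          boot_budget = prelim_budget,
                          max_retries = 3L, ...) {
  model_class <- match.arg(model_class)
  variant <- match.arg(variant)
  n_rep <- max(table(interaction(obs$time_dpc, obs$population, drop = TRUE)))
  if (n_rep < 2) {
    warning("fewer than 2 replicates per cell: bootstrap resampling degenerates")
  }
  prelim <- vector("list", n_prelim)
  for (j in seq_len(n_prelim)) {
    prelim[[j]] <- fit_model(obs, model_class, variant, ranges,
                             seed = derive_seed(master_seed, j),
                             budget = prelim_budget, ...)
  }
  incumbent <- prelim[[which.min(vapply(prelim, function(f) f$mse,
                                        numeric(1)))]]
  fits <- vector("list", n_boot)
  failed <- integer(0)
  for (b in seq_len(n_boot)) {
    fitted <- NULL
    for (r in 0:max_retries) {
      sd_b <- derive_seed(master_seed, 1000L + b * (max_retries + 1L) + r)
      set.seed(sd_b)
      obs_b <- resample_observations(obs)
      fitted <- tryCatch(
        fit_model(obs_b, model_class, variant, ranges, seed = sd_b,
                  budget = boot_budget, init = incumbent$par, ...),
        error = function(e) NULL)
      if (!is.null(fitted) && is.finite(fitted$mse)) break
    }
    if (is.null(fitted)) {
      failed <- c(failed, b)
    } else {
      fits[[b]] <- fitted
    }
  }
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (!length(fits)) stop("all bootstrap refits failed")
  par_mat <- do.call(rbind, lapply(fits, function(f) f$par))
  ci <- apply(par_mat, 2, stats::quantile, probs = c(0.025, 0.975))
  structure(list(
    fits = fits, parameters = par_mat,
    ci = ci, average = colMeans(par_mat),
    incumbent = incumbent,
    model_class = model_class, variant = variant,
    n_boot = length(fits), requested_n_boot = n_boot,
    failed = failed, partial = length(failed) > 0,
    master_seed = master_seed
  ), class = "thymus_bootstrap")
}

#' @export
print.thymus_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap re-estimation, %s.%s: %d/%d fits (master seed %d)\n",
              x$model_class, x$variant, x$n_boot, x$requested_n_boot,
              x$master_seed))
  if (x$partial) {
    cat(sprintf("  PARTIAL: %d refits failed\n", length(x$failed)))
  }
  invisible(x)
}
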