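# Parameter containers for the five-compartment thymocyte model.
#
# All cell quantities are expressed in units of 1e7 cells, so "one cell"
# corresponds to 1e-7 units. Time is a single absolute clock in days
# post-conception (dpc); birth defaults to 19.5 dpc and postnatal ages are
# derived views (t - birth_time).

#' Names of the per-stage rate parameters
#'
#' @param model_class `"M1"` (exponentially decreasing proliferation) or
#'   `"M2"` (decreasing proliferation with a density brake, which adds the
#'   carrying capacities `K_N` and `K`).
#' @return Character vector of parameter names for one developmental stage
#'   (prenatal or postnatal).
#' @export
stage_parameter_names <- function(model_class = c("M1", "M2")) {
  model_class <- match.arg(model_class)
  nm <- c(
    "b_N", "b_P", "b_4", "b_8",      # proliferation decay rates, 1/day
    "c_N", "c_P", "c_48",            # proliferation amplitudes, dimensionless
    "s_N", "s_4", "s_8",             # transfer rates DN->DP, DP->SP4, DP->SP8
    "s_04", "s_08",                  # SP4/SP8 export rates, 1/day
    "d_N", "d_P", "d_4", "d_8",      # death rates, 1/day
    "delta",                         # apoptotic degradation rate, 1/day
    "tau_N"                          # DN->DP differentiation delay, days
  )
  if (model_class == "M2") nm <- c(nm, "K_N", "K")
  nm
}

#' Stage-specific rate parameters
#'
#' Bundles every rate constant governing one developmental stage (prenatal
#' or postnatal): proliferation decay rates `b_*` (1/day), proliferation
#' amplitudes `c_*` (dimensionless; `c_48` is shared by SP4 and SP8),
#' transfer/export rates `s_*` (1/day), death rates `d_*` (1/day), the
#' apoptotic degradation rate `delta` (1/day), the DN-to-DP differentiation
#' delay `tau_N` (days) and, for density-controlled models, the carrying
#' capacities `K_N` (DN compartment) and `K` (aggregate of DP, SP4 and SP8),
#' both in units of 1e7 cells.
#'
#' @param b_N,b_P,b_4,b_8 Proliferation decay rates, 1/day.
#' @param c_N,c_P,c_48 Proliferation amplitude coefficients.
#' @param s_N DN to DP transfer rate, 1/day.
#' @param s_4,s_8 DP to SP4 / SP8 transfer rates, 1/day.
#' @param s_04,s_08 SP4 / SP8 export rates, 1/day.
#' @param d_N,d_P,d_4,d_8 Death rates, 1/day.
#' @param delta Apoptotic-cell degradation rate, 1/day.
#' @param tau_N DN to DP differentiation delay, days.
#' @param K_N,K Carrying capacities (1e7 cells); required for `"M2"` models.
#' @return An object of class `stage_parameters`.
#' @export
stage_parameters <- function(b_N, b_P, b_4, b_8, c_N, c_P, c_48,
                             s_N, s_4, s_8, s_04, s_08,
                             d_N, d_P, d_4, d_8,
                             delta, tau_N, K_N = NA_real_, K = NA_real_) {
  sp <- list(
    b_N = b_N, b_P = b_P, b_4 = b_4, b_8 = b_8,
    c_N = c_N, c_P = c_P, c_48 = c_48,
    s_N = s_N, s_4 = s_4, s_8 = s_8, s_04 = s_04, s_08 = s_08,
    d_N = d_N, d_P = d_P, d_4 = d_4, d_8 = d_8,
    delta = delta, tau_N = tau_N, K_N = K_N, K = K
  )
  sp <- lapply(sp, as.numeric)
  class(sp) <- "stage_parameters"
  sp
}

validate_stage_parameters <- function(sp, model_class = "M1",
                                      label = "stage") {
  stopifnot(inherits(sp, "stage_parameters"))
  rates <- unlist(sp[setdiff(names(sp), c("K_N", "K"))])
  if (anyNA(rates) || any(!is.finite(rates))) {
    stop(sprintf("%s parameters contain NA/non-finite values", label))
  }
  if (any(rates < 0)) {
    bad <- names(rates)[rates < 0]
    stop(sprintf("%s parameters must be non-negative; offending: %s",
                 label, paste(bad, collapse = ", ")))
  }
  if (model_class == "M2") {
    if (anyNA(c(sp$K_N, sp$K)) || sp$K_N <= 0 || sp$K <= 0) {
      stop(sprintf("%s: carrying capacities K_N and K must be > 0 under M2",
                   label))
    }
  }
  invisible(sp)
}

#' Check the postnatal DP throughput constraint
#'
#' Calibrated postnatal parameter sets must satisfy
#' `s_N > d_P + s_4 + s_8`, which keeps the DP population from dropping
#' below the DN population late in life.
#'
#' @param postnatal A [stage_parameters()] object.
#' @return `TRUE` if the constraint holds.
#' @export
postnatal_constraint_ok <- function(postnatal) {
  isTRUE(postnatal$s_N > postnatal$d_P + postnatal$s_4 + postnatal$s_8)
}

#' Full model specification
#'
#' Assembles a complete specification of the delayed compartmental model: the
#' model class (`"M1"` = decreasing proliferation only, `"M2"` = with density
#' brake), the stage-parameter variant (`"V1"` = independent prenatal and
#' postnatal parameters, `"V2"` = postnatal proliferation amplitudes tied to
#' the prenatal ones through the birth-continuity formula), the two stage
#' parameter sets, and the global quantities: thymopoiesis onset `t0` (dpc),
#' progenitor-influx plateau `b0` (1e7 cells/day), logistic midpoint `tau_b`
#' (dpc) and the derived steepness `beta` (1/day), which is never a free
#' parameter: it is solved so that the influx at `t0` equals one cell
#' (1e-7 units), see [solve_beta()].
#'
#' Under `"V2"` the postnatal `c_N`, `c_P`, `c_48` supplied in `postnatal`
#' are overwritten by [apply_continuity_constraint()].
#'
#' @param model_class `"M1"` or `"M2"`.
#' @param variant `"V1"` or `"V2"`.
#' @param prenatal,postnatal [stage_parameters()] for the two stages.
#' @param t0 Thymopoiesis onset, days post-conception.
#' @param b0 Progenitor-influx plateau, 1e7 cells/day.
#' @param tau_b Logistic midpoint of the influx, days post-conception.
#' @param birth_time Birth, days post-conception (default 19.5).
#' @param horizon End of the simulated lifespan, days post-conception
#'   (default `birth_time + 730`, i.e. two years of postnatal life).
#' @param postnatal_decay_clock `"restart"` (default) restarts the
#'   proliferation-decay clock at birth; `"absolute"` keeps measuring decay
#'   from `t0`.
#' @param delay_convention `"arrival_delayed"` (default): transfer out of DN
#'   is instantaneous while arrival into DP lags by `tau_N`;
#'   `"both_delayed"`: the DN outflow term also uses the lagged DN count.
#' @return An object of class `model_spec` with the derived `beta` attached.
#' @export
model_spec <- function(model_class = c("M1", "M2"),
                       variant = c("V1", "V2"),
                       prenatal, postnatal,
                       t0, b0, tau_b,
                       birth_time = 19.5,
                       horizon = birth_time + 730,
                       postnatal_decay_clock = c("restart", "absolute"),
                       delay_convention = c("arrival_delayed", "both_delayed")) {
  model_class <- match.arg(model_class)
  variant <- match.arg(variant)
  postnatal_decay_clock <- match.arg(postnatal_decay_clock)
  delay_convention <- match.arg(delay_convention)
  validate_stage_parameters(prenatal, model_class, "prenatal")
  if (!(t0 > 0 && t0 < birth_time)) {
    stop("t0 must satisfy 0 < t0 < birth_time")
  }
  if (variant == "V2") {
    cc <- apply_continuity_constraint(prenatal, t0)
    postnatal$c_N <- cc[["c_N"]]
    postnatal$c_P <- cc[["c_P"]]
    postnatal$c_48 <- cc[["c_48"]]
  }
  validate_stage_parameters(postnatal, model_class, "postnatal")
  attr(prenatal, "phase") <- "prenatal"
  attr(postnatal, "phase") <- "postnatal"
  beta <- solve_beta(b0, tau_b, t0)
  spec <- list(
    model_class = model_class, variant = variant,
    prenatal = prenatal, postnatal = postnatal,
    t0 = t0, b0 = b0, tau_b = tau_b, beta = beta,
    birth_time = birth_time, horizon = horizon,
    postnatal_decay_clock = postnatal_decay_clock,
    delay_convention = delay_convention,
    units = "1e7 cells"
  )
  class(spec) <- "model_spec"
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Thymocyte model %s.%s (units: %s)\n",
              x$model_class, x$variant, x$units))
  cat(sprintf("  t0 = %.4g dpc, birth = %.4g dpc, horizon = %.4g dpc\n",
              x$t0, x$birth_time, x$horizon))
  cat(sprintf("  influx: b0 = %.4g, tau_b = %.4g, beta = %.4g (derived)\n",
              x$b0, x$tau_b, x$beta))
  cat(sprintf("  decay clock: %s; delay convention: %s\n",
              x$postnatal_decay_clock, x$delay_convention))
  invisible(x)
}

#' Postnatal amplitudes under the birth-continuity constraint
#'
#' Computes the three postnatal proliferation amplitudes from the prenatal
#' values as `c_post = b_pre * c_pre * exp(b_pre * t0)` (applied to `c_N`,
#' `c_P`, `c_48`). Variant `"V2"` uses these derived values instead of
#' estimating the postnatal amplitudes, which removes three free parameters.
#'
#' @param prenatal Prenatal [stage_parameters()].
#' @param t0 Thymopoiesis onset, days post-conception.
#' @return Named numeric vector `c(c_N, c_P, c_48)`.
#' @export
apply_continuity_constraint <- function(prenatal, t0) {
  c(
    c_N = prenatal$b_N * prenatal$c_N * exp(prenatal$b_N * t0),
    c_P = prenatal$b_P * prenatal$c_P * exp(prenatal$b_P * t0),
    c_48 = prenatal$b_4 * prenatal$c_48 * exp(prenatal$b_4 * t0)
  )
}

#' Number of independently estimated parameters
#'
#' Per stage (prenatal and postnatal each): 7 proliferation parameters,
#' 5 transfer/export rates, 4 death rates, 1 degradation rate and 1 delay
#' (plus 2 carrying capacities under `"M2"`); plus the global `t0`, `b0` and
#' `tau_b`. The steepness `beta` is derived and never counted. Under `"V2"`
#' the three postnatal amplitudes are derived from prenatal values and are
#' excluded.
#'
#' @param model_class `"M1"` or `"M2"`.
#' @param variant `"V1"` or `"V2"`.
#' @return Integer count of free parameters.
#' @export
count_free_parameters <- function(model_class = c("M1", "M2"),
                                  variant = c("V1", "V2")) {
  model_class <- match.arg(model_class)
  variant <- match.arg(variant)
  per_stage <- 7L + 5L + 4L + 1L + 1L
  if (model_class == "M2") per_stage <- per_stage + 2L
  n <- 2L * per_stage + 3L
  if (variant == "V2") n <- n - 3L
  n
}

#' Names of the free parameters of a model configuration
#'
#' Flat key-value naming: stage-specific parameters carry a `pre_`/`post_`
#' prefix; global parameters are `t0`, `b0`, `tau_b`. Under `"V2"` the
#' postnatal amplitudes (`post_c_N`, `post_c_P`, `post_c_48`) are absent
#' because they are derived.
#'
#' @inheritParams count_free_parameters
#' @return Character vector whose length equals [count_free_parameters()].
#' @export
free_parameter_names <- function(model_class = c("M1", "M2"),
                                 variant = c("V1", "V2")) {
  model_class <- match.arg(model_class)
  variant <- match.arg(variant)
  snames <- stage_parameter_names(model_class)
  post <- snames
  if (variant == "V2") post <- setdiff(post, c("c_N", "c_P", "c_48"))
  c(paste0("pre_", snames), paste0("post_", post), "t0", "b0", "tau_b")
}

# Build a model_spec from a flat named vector/list of parameter values.
# Missing postnatal amplitudes are allowed under V2 (they are derived).
spec_from_flat <- function(values, model_class, variant,
                           birth_time = 19.5, horizon = birth_time + 730,
                           postnatal_decay_clock = "restart",
                           delay_convention = "arrival_delayed") {
  values <- unlist(values)
  snames <- stage_parameter_names(model_class)
  get_stage <- function(prefix, allow_missing = character(0)) {
    vals <- stats::setNames(rep(NA_real_, length(snames)), snames)
    for (nm in snames) {
      key <- paste0(prefix, nm)
      if (key %in% names(values)) {
        vals[nm] <- values[[key]]
      } else if (!(nm %in% allow_missing)) {
        stop(sprintf("missing parameter '%s'", key))
      }
    }
    do.call(stage_parameters, as.list(vals))
  }
  pre <- get_stage("pre_")
  allow <- if (variant == "V2") c("c_N", "c_P", "c_48") else character(0)
  post <- get_stage("post_", allow_missing = allow)
  if (variant == "V2") {
    # placeholder values; model_spec() overwrites them via the constraint
    post$c_N <- 0; post$c_P <- 0; post$c_48 <- 0
  }
  model_spec(model_class, variant, pre, post,
             t0 = values[["t0"]], b0 = values[["b0"]],
             tau_b = values[["tau_b"]],
             birth_time = birth_time, horizon = horizon,
             postnatal_decay_clock = postnatal_decay_clock,
             delay_convention = delay_convention)
}

# Flatten a model_spec into the flat named vector used by the optimizer and
# the on-disk config format.
spec_to_flat <- function(spec) {
  snames <- stage_parameter_names(spec$model_class)
  post <- snames
  if (spec$variant == "V2") post <- setdiff(post, c("c_N", "c_P", "c_48"))
  v <- c(
    stats::setNames(unlist(spec$prenatal[snames]), paste0("pre_", snames)),
    stats::setNames(unlist(spec$postnatal[post]), paste0("post_", post)),
    t0 = spec$t0, b0 = spec$b0, tau_b = spec$tau_b
  )
  v
}

#' Write a model specification to a YAML config file
#'
#' Flat key-value serialization with `pre_`/`post_` stage prefixes and a
#' header recording model class, variant and units. The derived `beta` is
#' stored for reference but is recomputed on read.
#'
#' @param spec A [model_spec()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(spec, path) {
  obj <- list(
    model_class = spec$model_class,
    variant = spec$variant,
    units = spec$units,
    birth_time = spec$birth_time,
    horizon = spec$horizon,
    postnatal_decay_clock = spec$postnatal_decay_clock,
    delay_convention = spec$delay_convention,
    beta_derived = spec$beta,
    parameters = as.list(spec_to_flat(spec))
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a model specification from a YAML config file
#'
#' @param path File written by [write_model_spec()].
#' @return A [model_spec()] with `beta` re-derived from `b0`, `tau_b`, `t0`.
#' @export
read_model_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  spec_from_flat(obj$parameters,
                 model_class = obj$model_class, variant = obj$variant,
                 birth_time = obj$birth_time, horizon = obj$horizon,
                 postnatal_decay_clock = obj$postnatal_decay_clock,
                 delay_convention = obj$delay_convention)
}
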