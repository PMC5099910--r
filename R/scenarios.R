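# In-silico progenitor-ablation scenarios: postnatal dynamics with the
# progenitor inflow held at its birth level versus cut to zero.

#' Default scenario checkpoints (days after birth)
#'
#' Six weeks, 3/6 months, 1 year, 18 months and 2 years.
#' @export
default_checkpoints <- function() {
  c(`6 weeks` = 42, `3 months` = 91, `6 months` = 182,
    `1 year` = 365, `18 months` = 548, `2 years` = 730)
}

#' Run one progenitor-supply scenario
#'
#' The prenatal segment always uses the logistic influx; after birth the
#' inflow is either held constant at the plateau `b0` (`"constant_b0"`) or
#' set to zero (`"zero"`, the ablation scenario).
#'
#' @param spec A [model_spec()].
#' @param mode `"constant_b0"` or `"zero"`.
#' @inheritParams simulate_thymus
#' @return A `thymus_trajectory`.
#' @export
run_progenitor_scenario <- function(spec, mode = c("constant_b0", "zero"),
                                    control = step_control(),
                                    horizon = spec$horizon,
                                    use_compiled = TRUE) {
  mode <- match.arg(mode)
  simulate_thymus(spec, influx_mode_postnatal = mode, control = control,
                  horizon = horizon, use_compiled = use_compiled)
}

#' Compare postnatal dynamics with and without progenitor inflow
#'
#' Solves the prenatal segment once and continues it twice — with the
#' postnatal inflow at the birth plateau and with it ablated — so the two
#' trajectories share a bit-identical prenatal history.
#'
#' @param spec A [model_spec()].
#' @param checkpoints Days after birth at which populations are compared
#'   (default [default_checkpoints()]).
#' @inheritParams simulate_thymus
#' @return An object of class `scenario_comparison` with fields `with`
#'   (constant inflow trajectory), `without` (ablated trajectory) and
#'   `checkpoints`.
#' @export
scenario_comparison <- function(spec, checkpoints = default_checkpoints(),
                                control = step_control(),
                                horizon = spec$horizon,
                                use_compiled = TRUE) {
  if (horizon <= spec$birth_time) {
    stop("scenario comparison requires a postnatal horizon")
  }
  pre <- simulate_thymus(spec, "constant_b0", control = control,
                         horizon = spec$birth_time,
                         use_compiled = use_compiled)
  cache <- list(times = pre$times, states = pre$states,
                raw_min = pre$raw_min)
  with_traj <- simulate_thymus(spec, "constant_b0", control = control,
                               horizon = horizon,
                               use_compiled = use_compiled,
                               prenatal_cache = cache)
  without_traj <- simulate_thymus(spec, "zero", control = control,
                                  horizon = horizon,
                                  use_compiled = use_compiled,
                                  prenatal_cache = cache)
  structure(list(with = with_traj, without = without_traj,
                 checkpoints = checkpoints, spec = spec),
            class = "scenario_comparison")
}

#' Percentage impact of progenitor ablation
#'
#' For each population and checkpoint computes
#' `(size with progenitors - size without progenitors) /
#'  (size with progenitors) * 100` (percent).
#'
#' @param cmp A [scenario_comparison()].
#' @param include_apoptotic_in_total Include the apoptotic compartment in
#'   the "Total thymocytes" row (default `FALSE`: live populations only).
#' @return A data.frame with rows `DN`, `DP`, `SP4`, `SP8`,
#'   `Total thymocytes` and one column per checkpoint. Checkpoints where the
#'   with-progenitor population is zero yield `NA` and are listed in the
#'   `flagged` attribute.
#' @export
percentage_difference_table <- function(cmp,
                                        include_apoptotic_in_total = FALSE) {
  stopifnot(inherits(cmp, "scenario_comparison"))
  t_abs <- cmp$spec$birth_time + cmp$checkpoints
  w <- trajectory_at(cmp$with, t_abs)
  wo <- trajectory_at(cmp$without, t_abs)
  tot_cols <- if (include_apoptotic_in_total) 1:5 else 1:4
  w_tab <- cbind(w[, 1:4, drop = FALSE],
                 Total = rowSums(w[, tot_cols, drop = FALSE]))
  wo_tab <- cbind(wo[, 1:4, drop = FALSE],
                  Total = rowSums(wo[, tot_cols, drop = FALSE]))
  pct <- (w_tab - wo_tab) / w_tab * 100
  pct[w_tab == 0] <- NA_real_
  out <- as.data.frame(t(pct))
  rownames(out) <- c("DN", "DP", "SP4", "SP8", "Total thymocytes")
  colnames(out) <- if (!is.null(names(cmp$checkpoints))) {
    names(cmp$checkpoints)
  } else {
    paste0("day ", cmp$checkpoints)
  }
  flagged <- which(is.na(as.matrix(out)), arr.ind = TRUE)
  attr(out, "flagged") <- flagged
  out
}

#' Export a percentage-difference table as CSV (plus JSON metadata)
#'
#' @param tab Output of [percentage_difference_table()].
#' @param cmp The [scenario_comparison()] the table came from.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_difference_table <- function(tab, cmp, path) {
  utils::write.csv(cbind(population = rownames(tab), tab), path,
                   row.names = FALSE)
  meta <- list(
    spec_hash = spec_hash(cmp$spec),
    checkpoints_postnatal_days = unname(cmp$checkpoints),
    formula = "(with - without) / with * 100",
    units = "percent"
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
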