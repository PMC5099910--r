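# Observation containers and file I/O.

OBS_POPULATIONS <- c("DN", "DP", "SP4", "SP8", "total", "apoptotic")

#' Construct an observation set
#'
#' The calibration target: replicate-structured cell counts per population
#' and time point. Times are days post-conception (one convention on disk);
#' counts are raw cells (not 1e7 units).
#'
#' @param time_dpc Numeric, days post-conception.
#' @param population Character, one of `r paste(OBS_POPULATIONS, collapse=", ")`.
#' @param replicate Replicate (animal) identifier within a time point.
#' @param count_cells Non-negative cell counts.
#' @return A data.frame of class `observation_set`.
#' @export
observation_set <- function(time_dpc, population, replicate, count_cells) {
  df <- data.frame(time_dpc = as.numeric(time_dpc),
                   population = as.character(population),
                   replicate = as.character(replicate),
                   count_cells = as.numeric(count_cells),
                   stringsAsFactors = FALSE)
  bad <- which(!df$population %in% OBS_POPULATIONS)
  if (length(bad)) {
    stop(sprintf("unknown population label(s) '%s' (row %s); accepted: %s",
                 paste(unique(df$population[bad]), collapse = "', '"),
                 paste(bad, collapse = ", "),
                 paste(OBS_POPULATIONS, collapse = ", ")))
  }
  bad <- which(!is.finite(df$count_cells) | df$count_cells < 0)
  if (length(bad)) {
    stop(sprintf("negative or non-finite count_cells at row %s",
                 paste(bad, collapse = ", ")))
  }
  if (anyNA(df$time_dpc)) stop("time_dpc contains missing values")
  class(df) <- c("observation_set", "data.frame")
  df
}

#' Read an observation set from CSV
#'
#' Expects the header `time_dpc, population, replicate, count_cells`.
#' Embryonic stage labels (e.g. `"E17.5"`) in `time_dpc` are accepted and
#' converted to days post-conception.
#'
#' @param path CSV path.
#' @return An [observation_set()].
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_dpc", "population", "replicate", "count_cells")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  tt <- df$time_dpc
  if (is.character(tt)) {
    e <- grepl("^[Ee]", tt)
    tt[e] <- sub("^[Ee]", "", tt[e])
    tt <- suppressWarnings(as.numeric(tt))
  }
  if (anyNA(tt)) {
    stop(sprintf("malformed time_dpc at row %s",
                 paste(which(is.na(tt)), collapse = ", ")))
  }
  observation_set(tt, df$population, df$replicate, df$count_cells)
}

#' Write an observation set to CSV
#'
#' @param obs An [observation_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(as.data.frame(obs)[, c("time_dpc", "population",
                                          "replicate", "count_cells")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a fit result to JSON
#'
#' @param fit A `thymus_fit` from [fit_model()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  obj <- list(
    model_class = fit$spec$model_class,
    variant = fit$spec$variant,
    parameters = as.list(fit$par),
    fixed = as.list(fit$fixed),
    mse = fit$mse, aic = fit$aic, k = fit$k, n = fit$n,
    residual_scale = fit$residual_scale,
    seed = fit$seed,
    spec_hash = spec_hash(fit$spec),
    evaluations = fit$evaluations,
    generations_run = length(fit$trace)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a bootstrap result to JSON
#'
#' @param boot A `thymus_bootstrap` from [bootstrap_fit()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_bootstrap <- function(boot, path) {
  obj <- list(
    model_class = boot$model_class,
    variant = boot$variant,
    n_boot = boot$n_boot,
    master_seed = boot$master_seed,
    average = as.list(boot$average),
    ci_lower = as.list(boot$ci[1, ]),
    ci_upper = as.list(boot$ci[2, ]),
    mse = vapply(boot$fits, function(f) f$mse, numeric(1)),
    partial = boot$partial
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write search ranges to YAML
#'
#' @param ranges A list with named numeric vectors `lower` and `upper`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_search_ranges <- function(ranges, path) {
  yaml::write_yaml(list(lower = as.list(ranges$lower),
                        upper = as.list(ranges$upper)), path)
  invisible(path)
}

#' Read search ranges from YAML
#'
#' @param path YAML path written by [write_search_ranges()].
#' @return A list with named numeric vectors `lower` and `upper`.
#' @export
read_search_ranges <- function(path) {
  obj <- yaml::read_yaml(path)
  list(lower = unlist(obj$lower), upper = unlist(obj$upper))
}
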