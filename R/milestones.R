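# Developmental milestones extracted from a simulated trajectory.

LIVE_POPS <- c(DN = "N", DP = "P", SP4 = "SP4", SP8 = "SP8")

#' Population emergence times
#'
#' The emergence time of a population is the earliest time at which it
#' reaches the threshold (default one cell, 1e-7 in 1e7-cell units), located
#' by linear interpolation between the bracketing grid points. A population
#' that never reaches the threshold gets `NA` ("absent").
#'
#' @param traj A `thymus_trajectory`.
#' @param threshold Emergence threshold in 1e7-cell units (default `1e-7`,
#'   i.e. a single cell).
#' @return Named numeric vector (days post-conception) for `DN`, `DP`,
#'   `SP4`, `SP8`; `NA` where the population never emerges.
#' @export
emergence_times <- function(traj, threshold = 1e-7) {
  stopifnot(threshold > 0)
  vapply(LIVE_POPS, function(col) {
    y <- traj$states[, col]
    i <- which(y >= threshold)
    if (!length(i)) return(NA_real_)
    i <- i[1]
    if (i == 1) return(traj$times[1])
    t1 <- traj$times[i - 1]; t2 <- traj$times[i]
    y1 <- y[i - 1]; y2 <- y[i]
    t1 + (threshold - y1) / (y2 - y1) * (t2 - t1)
  }, numeric(1))
}

#' Thymocyte composition fractions
#'
#' Fractions of DN, DP, SP4 and SP8 among live thymocytes (the apoptotic
#' compartment is excluded from the denominator).
#'
#' @param traj A `thymus_trajectory`.
#' @param t Time(s), days post-conception.
#' @return Matrix `length(t) x 4` with columns `DN`, `DP`, `SP4`, `SP8`;
#'   rows sum to 1. Errors if the live total is zero at any requested time.
#' @export
composition_fractions <- function(traj, t) {
  st <- trajectory_at(traj, t)
  live <- st[, 1:4, drop = FALSE]
  tot <- rowSums(live)
  if (any(tot <= 0)) {
    stop("composition undefined: zero live thymocytes at a requested time")
  }
  fr <- live / tot
  colnames(fr) <- names(LIVE_POPS)
  fr
}

#' First crossing time of two composition fractions
#'
#' Finds the earliest sign change of `fraction(a) - fraction(b)` along the
#' trajectory grid (restricted to times where the live total is positive),
#' refined by linear interpolation. Curves that are everywhere equal return
#' the first usable grid time with attribute `degenerate = TRUE`; curves
#' that never cross return `NA`.
#'
#' @param traj A `thymus_trajectory`.
#' @param a,b Population labels (`"DN"`, `"DP"`, `"SP4"`, `"SP8"`).
#' @param min_total Minimum live total (1e7 cells) for fractions to be
#'   considered defined (default one cell).
#' @return Crossing time in days post-conception, or `NA` if none.
#' @export
crossing_time <- function(traj, a = "DN", b = "DP", min_total = 1e-7) {
  a <- match.arg(a, names(LIVE_POPS))
  b <- match.arg(b, names(LIVE_POPS))
  live <- traj$states[, 1:4, drop = FALSE]
  tot <- rowSums(live)
  use <- tot >= min_total
  if (!any(use)) return(NA_real_)
  tt <- traj$times[use]
  d <- live[use, LIVE_POPS[[a]]] / tot[use] -
    live[use, LIVE_POPS[[b]]] / tot[use]
  if (all(abs(d) < 1e-12)) {
    return(structure(tt[1], degenerate = TRUE))
  }
  s <- sign(d)
  idx <- which(s[-1] != s[-length(s)])
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  if (d[i] == 0) return(tt[i])
  tt[i] + (0 - d[i]) / (d[i + 1] - d[i]) * (tt[i + 1] - tt[i])
}

#' Milestone report of a trajectory
#'
#' Bundles the population emergence times, the pairwise emergence delays
#' (DN to DP, DP to SP4, DP to SP8), the DN/DP composition crossing and the
#' peak of the total live population.
#'
#' @param traj A `thymus_trajectory`.
#' @param threshold Emergence threshold, 1e7-cell units.
#' @return A list of class `milestone_report`: `emergence` (named vector,
#'   dpc), `delays` (named vector, days; `NA` when an endpoint is absent),
#'   `dn_dp_crossing` (dpc or `NA`), `peak_time` (dpc) and `peak_total`
#'   (1e7 cells) of the live population.
#' @export
milestone_report <- function(traj, threshold = 1e-7) {
  em <- emergence_times(traj, threshold)
  delays <- c(
    DN_to_DP = unname(em["DP"] - em["DN"]),
    DP_to_SP4 = unname(em["SP4"] - em["DP"]),
    DP_to_SP8 = unname(em["SP8"] - em["DP"])
  )
  tot <- rowSums(traj$states[, 1:4, drop = FALSE])
  ipk <- which.max(tot)
  structure(list(
    emergence = em,
    delays = delays,
    dn_dp_crossing = crossing_time(traj, "DN", "DP"),
    peak_time = traj$times[ipk],
    peak_total = tot[ipk]
  ), class = "milestone_report")
}

#' @export
print.milestone_report <- function(x, ...) {
  cat("Developmental milestones (days post-conception):\n")
  cat("  emergence:",
      paste(sprintf("%s = %.3f", names(x$emergence), x$emergence),
            collapse = ", "), "\n")
  cat("  delays:",
      paste(sprintf("%s = %.3f", names(x$delays), x$delays),
            collapse = ", "), "\n")
  cat(sprintf("  DN%%=DP%% crossing: %.3f\n", x$dn_dp_crossing))
  cat(sprintf("  total live peak: %.3f (1e7 cells) at t = %.2f\n",
              x$peak_total, x$peak_time))
  invisible(x)
}
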