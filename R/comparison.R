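#' Trapezoidal area under a concentration-time curve
#'
#' @param series Nonnegative concentration vector.
#' @param times Time vector (h), same length, strictly increasing.
#' @return The trapezoidal integral.
#' @export
auc <- function(series, times) {
  n <- length(series)
  if (length(times) != n) stop("auc: series and times must have equal length")
  if (n < 2) stop("auc: need at least two points")
  if (any(diff(times) <= 0)) stop("auc: times must be strictly increasing")
  sum(diff(times) * (series[-1] + series[-n]) / 2)
}

extract_load <- function(traj, component, bacterial_as = "U+I") {
  switch(component,
         bacterial = if (identical(bacterial_as, "U")) traj$U else traj$U + traj$I,
         viral = traj$P,
         stop("unknown component: ", component))
}

#' Normalised area-between-curves error
#'
#' The percent difference between two simulated profiles:
#' `100 * 2 * int |X_A - X_B| dt / (int X_A dt + int X_B dt)`,
#' a symmetric, scale-invariant metric ranging from 0 (identical curves) to
#' 200 (disjoint support). Used both to compare model structures and as the
#' step-halving convergence criterion.
#'
#' @param traj_A,traj_B `phage_trajectory` objects on the same grid and
#'   horizon (see [compare_trajectories()] for automatic alignment).
#' @param component `"bacterial"` or `"viral"` load.
#' @param bacterial_as `"U+I"` (total live bacteria, default: the
#'   colony-forming count an experiment observes) or `"U"` (uninfected only),
#'   a sensitivity switch.
#' @return Error in percent. If both curves are identically zero the error is
#'   defined as 0.
#' @export
curve_error <- function(traj_A, traj_B, component = c("bacterial", "viral"),
                        bacterial_as = "U+I") {
  component <- match.arg(component)
  tA <- traj_A$times; tB <- traj_B$times
  if (length(tA) != length(tB) || max(abs(tA - tB)) > 1e-9 * max(tA[length(tA)], 1)) {
    stop("curve_error: trajectories must share the grid; see compare_trajectories()")
  }
  xA <- extract_load(traj_A, component, bacterial_as)
  xB <- extract_load(traj_B, component, bacterial_as)
  denom <- auc(xA, tA) + auc(xB, tA)
  if (denom == 0) return(0)
  100 * 2 * auc(abs(xA - xB), tA) / denom
}

#' Compare two trajectories on a common grid and horizon
#'
#' Truncates both trajectories to the shorter horizon and linearly
#' interpolates the second onto the grid of the first (the finer of the two
#' is used as the reference grid), then evaluates the area-between-curves
#' error for both loads.
#'
#' @param traj_A,traj_B `phage_trajectory` objects.
#' @param bacterial_as See [curve_error()].
#' @return A list of class `curve_error_pair`: `bacterial_error_pct`,
#'   `viral_error_pct`, `horizon`.
#' @export
compare_trajectories <- function(traj_A, traj_B, bacterial_as = "U+I") {
  if (traj_B$dt < traj_A$dt) { tmp <- traj_A; traj_A <- traj_B; traj_B <- tmp }
  horizon <- min(max(traj_A$times), max(traj_B$times))
  keep <- traj_A$times <= horizon + 1e-12
  tt <- traj_A$times[keep]
  A <- new_trajectory(tt, traj_A$U[keep], traj_A$I[keep], traj_A$P[keep],
                      traj_A$model, traj_A$dt)
  B <- new_trajectory(tt,
                      stats::approx(traj_B$times, traj_B$U, tt, rule = 2)$y,
                      stats::approx(traj_B$times, traj_B$I, tt, rule = 2)$y,
                      stats::approx(traj_B$times, traj_B$P, tt, rule = 2)$y,
                      traj_B$model, traj_A$dt)
  structure(list(
    bacterial_error_pct = curve_error(A, B, "bacterial", bacterial_as),
    viral_error_pct = curve_error(A, B, "viral", bacterial_as),
    horizon = horizon
  ), class = "curve_error_pair")
}

#' @export
print.curve_error_pair <- function(x, ...) {
  cat(sprintf("Curve error over [0, %g] h: bacterial %.2f%%, viral %.2f%%\n",
              x$horizon, x$bacterial_error_pct, x$viral_error_pct))
  invisible(x)
}
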