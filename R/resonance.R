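# Preferred-frequency analysis: power functions and their maximisers.
#
# The power function is P(Omega) = |Ghat(Omega)|^2 with the Laplace argument
# evaluated on the real axis.  For these kernels every segment formula is a
# monotone function of the decay rate gamma alone, so on networks of
# identical cells the maximiser Omega0 = argmin_omega gamma(omega) is exactly
# the same on every segment and independent of the gap-junction resistance;
# with heterogeneous cells or lumped somata the maximiser becomes cell- and
# coupling-dependent.  Passive membrane has monotone gamma, hence a low-pass
# power function maximised at the lower end of the search interval.

#' Power function of a frequency-domain response
#'
#' @param ghat function of a complex vector: Laplace-domain response.
#' @param Omega real grid of angular frequencies (rad/ms, >= 0).
#' @param normalise divide by the grid maximum so that max(P) = 1.
#' @return A data frame of class `power_spectrum` with columns `Omega` and `P`.
#' @export
power_function <- function(ghat, Omega = seq(1e-3, 5, by = 5e-3),
                           normalise = TRUE) {
  stopifnot(is.numeric(Omega), all(Omega >= 0))
  P <- Mod(ghat(as.complex(Omega)))^2
  if (normalise) P <- P / max(P)
  structure(data.frame(Omega = Omega, P = P),
            normalised = normalise, class = c("power_spectrum", "data.frame"))
}

#' Preferred (resonant) frequency Omega0
#'
#' Locates the maximiser of the power function `|ghat(Omega)|^2` on a real
#' interval by coarse grid search followed by golden-section/parabolic
#' refinement ([stats::optimize()]).  Ties are broken toward the smallest
#' maximiser; a maximum on the interval boundary (the passive, low-pass case)
#' triggers a warning and returns the boundary value.
#'
#' @param ghat function of a complex vector.
#' @param interval search interval (rad/ms).
#' @param coarse_step grid step of the bracketing stage (rad/ms).
#' @param tol refinement tolerance (rad/ms).
#' @return `Omega0` (rad/ms).
#' @examples
#' mp <- membrane_params(a_um = 2, tau_ms = 2, r_Ohm_cm2 = 100, L_H_cm2 = 5)
#' cfg <- two_cell_config(mp, R_GJ = 100)
#' find_omega0(function(w) two_cell_ghat(cfg, "m-", 10, 100, w)) # ~0.4272
#' @export
find_omega0 <- function(ghat, interval = c(1e-3, 5), coarse_step = 5e-3,
                        tol = 1e-5) {
  stopifnot(length(interval) == 2, interval[1] < interval[2])
  Om <- seq(interval[1], interval[2], by = coarse_step)
  P <- Mod(ghat(as.complex(Om)))^2
  i <- which.max(P)
  if (i == 1L || i == length(Om)) {
    warning(sprintf("power function maximal at the interval boundary (Omega = %g rad/ms); no interior resonance",
                    Om[i]), call. = FALSE)
    return(Om[i])
  }
  obj <- function(o) Mod(ghat(complex(real = o, imaginary = 0)))^2
  stats::optimize(obj, lower = Om[i - 1L], upper = Om[i + 1L],
                  maximum = TRUE, tol = tol)$maximum
}

#' Sweep of the somatic preferred frequency over gap-junction locations
#'
#' For each combination of gap-junction distance `L_GJ` and resistance
#' `R_GJ`, rebuilds the two-soma configuration with the stimulus at
#' `y0 = L_GJ + y0_offset`, evaluates the somatic word-series response of
#' each cell and locates its preferred frequency.
#'
#' @param base a [two_soma_config()] providing membrane, soma and `N`.
#' @param L_GJ vector of gap-junction distances (um).
#' @param R_GJ vector of gap-junction resistances (MOhm); defaults to the
#'   base configuration's value.
#' @param y0_offset stimulus distance beyond the gap junction (um).
#' @param n_max word-series truncation order.
#' @param interval,coarse_step passed to [find_omega0()].
#' @return A data frame of class `gj_sweep` with columns `cell`, `L_GJ_um`,
#'   `R_GJ_MOhm`, `omega0_rad_per_ms`.
#' @export
sweep_gj_location <- function(base, L_GJ = seq(50, 500, by = 50),
                              R_GJ = base$R_GJ, y0_offset = 10, n_max = 20,
                              interval = c(1e-3, 5), coarse_step = 5e-3) {
  stopifnot(inherits(base, "two_soma_config"))
  if (!length(L_GJ)) stop("empty L_GJ list", call. = FALSE)
  rows <- list()
  for (r in R_GJ) {
    for (l in L_GJ) {
      cfg <- two_soma_config(base$params, base$soma, N = base$N,
                             L_GJ = l, R_GJ = r, y0 = l + y0_offset)
      for (cell in 1:2) {
        gh <- function(w) word_series_ghat(cfg, cell, w, n_max = n_max)
        om0 <- find_omega0(gh, interval = interval, coarse_step = coarse_step)
        rows[[length(rows) + 1L]] <-
          data.frame(cell = cell, L_GJ_um = l, R_GJ_MOhm = r,
                     omega0_rad_per_ms = om0)
      }
    }
  }
  structure(do.call(rbind, rows), class = c("gj_sweep", "data.frame"))
}

#' Direction of the Omega0 trend of a sweep
#'
#' @param sweep a `gj_sweep` data frame.
#' @return A data frame with one row per (cell, R_GJ) giving the trend
#'   (`"increasing"`, `"decreasing"` or `"non-monotone"`) of Omega0 in L_GJ.
#' @export
sweep_trend <- function(sweep) {
  stopifnot(inherits(sweep, "gj_sweep"))
  out <- list()
  for (key in split(sweep, list(sweep$cell, sweep$R_GJ_MOhm), drop = TRUE)) {
    key <- key[order(key$L_GJ_um), ]
    d <- diff(key$omega0_rad_per_ms)
    trend <- if (all(d >= -1e-9)) "increasing"
             else if (all(d <= 1e-9)) "decreasing"
             else "non-monotone"
    out[[length(out) + 1L]] <- data.frame(cell = key$cell[1],
                                          R_GJ_MOhm = key$R_GJ_MOhm[1],
                                          trend = trend)
  }
  do.call(rbind, out)
}
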