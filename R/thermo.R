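#' Entropic component of the free energy by central finite difference
#'
#' `-T dS(r) = T dG/dT ~ (T / 2 dT) * (G(T + dT) - G(T - dT))`, evaluated on
#' matched r-grids from free-energy profiles at two bracketing temperatures.
#' The central difference is exact (zero truncation error) whenever `G` is
#' affine in `T`. Bins undefined in either input stay undefined.
#'
#' @param fep_lo,fep_hi `free_energy_profile`s at `central_T - dT` and
#'   `central_T + dT`, on an identical r-grid.
#' @param central_T Central temperature in K; must lie midway between the two
#'   profile temperatures (within 1e-6 K).
#' @return A tibble (`r`, `minus_TdS` in kJ/mol, `defined`).
#' @export
entropic_component <- function(fep_lo, fep_hi, central_T = 298) {
  check_matched_grid(fep_lo, fep_hi)
  T_lo <- attr(fep_lo, "temperature")
  T_hi <- attr(fep_hi, "temperature")
  if (T_hi <= T_lo) abort("fep_hi must be at the higher temperature",
                          class = "memlens_value_error")
  if (abs((T_lo + T_hi) / 2 - central_T) > 1e-6) {
    abort(sprintf("central_T = %g K is not midway between %g and %g K",
                  central_T, T_lo, T_hi), class = "memlens_value_error")
  }
  dT <- (T_hi - T_lo) / 2
  defined <- fep_lo$defined & fep_hi$defined
  minus_TdS <- ifelse(defined, (central_T / (2 * dT)) * (fep_hi$dG - fep_lo$dG),
                      NA_real_)
  tibble(r = fep_lo$r, minus_TdS = minus_TdS, defined = defined)
}

#' Enthalpic component
#'
#' `dH = dG + T dS = dG - (-T dS)` bin-wise: together with
#' [entropic_component()] the decomposition closes exactly,
#' `minus_TdS + dH = dG` wherever defined.
#'
#' @param fep_central `free_energy_profile` at the central temperature.
#' @param minus_TdS Output of [entropic_component()] (or a numeric vector on
#'   the same grid).
#' @return A tibble (`r`, `dH` in kJ/mol, `defined`).
#' @export
enthalpic_component <- function(fep_central, minus_TdS) {
  if (is.data.frame(minus_TdS)) {
    check_matched_grid(fep_central, minus_TdS)
    ts <- minus_TdS$minus_TdS
  } else {
    if (length(minus_TdS) != nrow(fep_central)) {
      abort("grid mismatch", class = "memlens_value_error")
    }
    ts <- minus_TdS
  }
  defined <- fep_central$defined & !is.na(ts)
  tibble(r = fep_central$r, dH = ifelse(defined, fep_central$dG - ts, NA_real_),
         defined = defined)
}

check_matched_grid <- function(a, b) {
  if (nrow(a) != nrow(b) || any(abs(a$r - b$r) > 1e-9)) {
    abort("r-grids do not match", class = "memlens_value_error")
  }
  invisible(TRUE)
}

#' Entropy/enthalpy decomposition from three trajectories
#'
#' Runs [com_rdf()] and [free_energy_profile()] at three temperatures on a
#' shared grid (same bin width, range, normalization mode and plateau
#' window — mixing conventions would inject spurious temperature
#' dependence), then forms the finite-difference entropic component at the
#' central temperature and the enthalpic remainder. Values at the two minima
#' located on the central profile are reported alongside the full curves.
#'
#' @param traj_lo,traj_central,traj_hi Trajectories of identical composition
#'   simulated at `temperatures[1:3]`.
#' @param temperatures Length-3 increasing vector in K (default
#'   `c(283, 298, 313)`).
#' @param bin_width,r_max,mode,plateau,window_frac Passed to [com_rdf()].
#' @param window1,window2 Minima search windows for the report.
#' @return A `thermo_decomposition` tibble (`r`, `dG`, `minus_TdS`, `dH`,
#'   `defined`) with attributes `temperature`, `delta_T` and `minima` (a
#'   one-row tibble with `dG`, `minus_TdS`, `dH` at each minimum).
#' @export
decompose_thermo <- function(traj_lo, traj_central, traj_hi,
                             temperatures = c(283, 298, 313),
                             bin_width = 0.02, r_max = NULL,
                             mode = "plateau_normalized", plateau = c(2.5, 3.2),
                             window_frac = 1, window1 = c(0.85, 1.25),
                             window2 = c(1.30, 1.75)) {
  stopifnot(length(temperatures) == 3, all(diff(temperatures) > 0))
  trajs <- list(traj_lo, traj_central, traj_hi)
  np <- vapply(trajs, function(t) n_molecules_of(t$topology, "fullerene"), numeric(1))
  if (length(unique(np)) != 1) {
    abort("trajectories have different particle compositions", class = "memlens_value_error")
  }
  r_max <- r_max %||% min(vapply(trajs, function(t) min(t$boxes) / 2, numeric(1)), 3.5)
  feps <- purrr::map2(trajs, temperatures, function(t, temp) {
    free_energy_profile(
      com_rdf(t, bin_width = bin_width, r_max = r_max, mode = mode,
              plateau = plateau, window_frac = window_frac),
      temperature = temp)
  })
  ts <- entropic_component(feps[[1]], feps[[3]], central_T = temperatures[2])
  dh <- enthalpic_component(feps[[2]], ts)
  defined <- feps[[2]]$defined & ts$defined
  out <- tibble(r = feps[[2]]$r, dG = feps[[2]]$dG, minus_TdS = ts$minus_TdS,
                dH = dh$dH, defined = defined)
  minima <- locate_minima(feps[[2]], window1, window2)
  at_r <- function(col, r0) {
    i <- which.min(abs(out$r - r0))
    out[[col]][i]
  }
  attr(out, "minima") <- dplyr::bind_cols(
    minima,
    tibble(minus_TdS_min1 = at_r("minus_TdS", minima$r_min1),
           dH_min1 = at_r("dH", minima$r_min1),
           minus_TdS_min2 = at_r("minus_TdS", minima$r_min2),
           dH_min2 = at_r("dH", minima$r_min2)))
  structure(out, class = c("thermo_decomposition", class(out)),
            temperature = temperatures[2],
            delta_T = (temperatures[3] - temperatures[1]) / 2)
}
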