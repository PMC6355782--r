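#' Unwrap periodic-boundary jumps
#'
#' Rebuilds continuous particle paths by accumulating minimum-image
#' displacements between consecutive frames (the first frame is unchanged).
#' Valid only while no particle moves half a box edge or more between
#' frames; such a displacement is reported as an error naming the frame and
#' bead.
#'
#' @param traj A wrapped [cg_trajectory()].
#' @return A [cg_trajectory()] with `wrapped = FALSE`.
#' @export
unwrap_trajectory <- function(traj) {
  nf <- n_frames(traj)
  out <- traj$coords
  if (nf > 1) {
    for (f in 2:nf) {
      box <- traj$boxes[f, ]
      d <- matrix(traj$coords[, , f] - traj$coords[, , f - 1], ncol = 3)
      w <- min_image_disp(d, box)
      half <- matrix(box / 2, nrow(w), 3, byrow = TRUE)
      bad <- which(abs(w) >= half - 1e-12, arr.ind = TRUE)
      if (length(bad) > 0) {
        abort(sprintf("displacement >= half box at frame %d, bead %d (axis %d)",
                      f, bad[1, 1], bad[1, 2]), class = "memlens_value_error")
      }
      out[, , f] <- out[, , f - 1] + w
    }
  }
  res <- cg_trajectory(traj$topology, out, traj$boxes, traj$times, wrapped = FALSE)
  res
}

#' Re-wrap an unwrapped trajectory into the primary box
#'
#' @param traj A [cg_trajectory()].
#' @return A wrapped [cg_trajectory()].
#' @export
wrap_trajectory <- function(traj) {
  out <- traj$coords
  for (f in seq_len(n_frames(traj))) {
    out[, , f] <- pbc_wrap(matrix(out[, , f], ncol = 3), traj$boxes[f, ])
  }
  cg_trajectory(traj$topology, out, traj$boxes, traj$times, wrapped = TRUE)
}

#' Mean-squared displacement
#'
#' All-time-origin MSD at origin stride 1, averaged over the selected
#' particles, restricted to lag times up to half the trajectory length. The
#' per-lag standard error is taken across particles (they are the
#' independent units). Computed per particle with the FFT
#' (Wiener-Khinchin) algorithm, which is exactly the all-origin average.
#'
#' @param traj An unwrapped [cg_trajectory()] (see [unwrap_trajectory()]),
#'   uniformly spaced in time.
#' @param axes Subset of `c("x", "y", "z")`; `c("x", "y")` is the lateral
#'   MSD, `"z"` the membrane-normal one.
#' @param group Bead group of the particles (default `"fullerene"`).
#' @return An `msd_curve` tibble (`lag`, `tau`, `msd`, `se`) with attributes
#'   `axes` and `dt`.
#' @export
msd <- function(traj, axes = c("x", "y"), group = "fullerene") {
  if (isTRUE(traj$wrapped) && n_frames(traj) > 1) {
    warn("trajectory looks wrapped; MSD expects unwrapped coordinates")
  }
  nf <- n_frames(traj)
  if (nf < 2) abort("need at least 2 frames", class = "memlens_value_error")
  dts <- diff(traj$times)
  if (max(dts) - min(dts) > 1e-9 * max(dts)) {
    abort("non-uniform frame spacing", class = "memlens_value_error")
  }
  ax_idx <- match(axes, c("x", "y", "z"))
  stopifnot(!any(is.na(ax_idx)))
  mc <- molecule_coms(traj, group = group, pbc = FALSE)
  n <- dim(mc$coms)[1]
  max_lag <- nf %/% 2
  per_particle <- matrix(0, max_lag, n)
  for (i in seq_len(n)) {
    m <- numeric(max_lag)
    for (a in ax_idx) m <- m + msd_fft_1d(mc$coms[i, a, ])[seq_len(max_lag) + 1]
    per_particle[, i] <- m
  }
  curve <- rowMeans(per_particle)
  se <- if (n > 1) apply(per_particle, 1, sd) / sqrt(n) else rep(NA_real_, max_lag)
  out <- tibble(lag = seq_len(max_lag), tau = seq_len(max_lag) * dts[1],
                msd = curve, se = se)
  structure(out, class = c("msd_curve", class(out)), axes = axes, dt = dts[1],
            n_particles = n)
}

# all-origin MSD of a 1-d series via FFT autocorrelation; returns lags 0..N-1
msd_fft_1d <- function(x) {
  n <- length(x)
  # S2: autocorrelation sum_t x_t x_{t+tau} via zero-padded FFT
  nfft <- 2^ceiling(log2(2 * n))
  fx <- fft(c(x, rep(0, nfft - n)))
  s2_raw <- Re(fft(fx * Conj(fx), inverse = TRUE))[1:n] / nfft
  counts <- n - (0:(n - 1))
  s2 <- s2_raw / counts
  # S1: sum of x_t^2 + x_{t+tau}^2 over valid origins, computed recursively
  x2 <- x^2
  ss <- 2 * sum(x2)
  s1 <- numeric(n)
  s1[1] <- ss / n
  for (tau in 1:(n - 1)) {
    ss <- ss - x2[tau] - x2[n - tau + 1]
    s1[tau + 1] <- ss / (n - tau)
  }
  s1 - 2 * s2
}

#' Diffusion coefficient from an MSD curve
#'
#' Least-squares slope of `MSD(tau)` over a window of lag times, with
#' `D = slope / (2 d)` for dimensionality `d` (2 for lateral, 1 for normal).
#' A fit with `r^2 < 0.9` triggers a warning: in a membrane the
#' normal-direction MSD saturates (confined regime) and the fitted number
#' must be read as an effective short-time coefficient.
#'
#' @param msd_curve An `msd_curve` tibble from [msd()].
#' @param dimensionality 1, 2 or 3 (count of summed axes).
#' @param fit_window Fractions of the maximum lag to fit over (default
#'   `c(0.1, 0.5)`).
#' @return A `diffusion_fit` object; [tidy()] gives the fit coefficients,
#'   [glance()] the one-row summary (`D` in nm^2/ns, `D_cm2_s`, `r2`,
#'   window, dimensionality).
#' @export
diffusion_coefficient <- function(msd_curve, dimensionality = 2,
                                  fit_window = c(0.1, 0.5)) {
  stopifnot(dimensionality %in% 1:3, length(fit_window) == 2,
            fit_window[1] < fit_window[2])
  tau_max <- max(msd_curve$tau)
  sel <- msd_curve$tau >= fit_window[1] * tau_max &
    msd_curve$tau <= fit_window[2] * tau_max
  if (sum(sel) < 3) abort("fit window contains fewer than 3 points",
                          class = "memlens_value_error")
  fit <- lm(msd ~ tau, data = msd_curve[sel, ])
  r2 <- summary(fit)$r.squared
  D <- unname(coef(fit)[2]) / (2 * dimensionality)
  if (is.finite(r2) && r2 < 0.9) {
    warn(sprintf("MSD fit r^2 = %.3f < 0.9: sub-diffusive or confined regime", r2))
  }
  structure(list(fit = fit, D = D, r2 = r2, dimensionality = dimensionality,
                 fit_window = fit_window, axes = attr(msd_curve, "axes")),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> D = %.4g nm^2/ns (%.3g cm^2/s), d = %d, r^2 = %.4f\n",
              x$D, x$D * CM2_S_PER_NM2_NS, x$dimensionality, x$r2))
  invisible(x)
}

#' @export
tidy.diffusion_fit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble(term = rownames(co), estimate = co[, 1], std.error = co[, 2],
         statistic = co[, 3], p.value = co[, 4])
}

#' @export
glance.diffusion_fit <- function(x, ...) {
  slope_se <- summary(x$fit)$coefficients["tau", 2]
  tibble(D = x$D, D_cm2_s = x$D * CM2_S_PER_NM2_NS,
         D_se = slope_se / (2 * x$dimensionality), r2 = x$r2,
         dimensionality = x$dimensionality,
         fit_lo = x$fit_window[1], fit_hi = x$fit_window[2])
}
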