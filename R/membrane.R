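#' Area per lipid
#'
#' Per-frame area per lipid `APL = Lx*Ly / (n_lipids/2)`: the projected box
#' area divided by the number of lipids per leaflet.
#'
#' @param traj A [cg_trajectory()] whose topology contains lipid beads.
#' @return A tibble with one row per frame (`frame`, `time`, `apl` in nm^2)
#'   carrying `mean` and `sd` attributes; [glance()] on it returns the
#'   summary row.
#' @export
area_per_lipid <- function(traj) {
  n_lip <- n_molecules_of(traj$topology, LIPID_GROUPS)
  if (n_lip == 0) abort("trajectory contains no lipids", class = "memlens_selection_error")
  out <- frame_info(traj) |>
    mutate(apl = .data$Lx * .data$Ly / (n_lip / 2)) |>
    select("frame", "time", "apl")
  as_series(out, "apl", n_lipids = n_lip)
}

#' Volume per lipid
#'
#' `VPL = (V_box - N_water * water_bead_volume - n_particles * particle_volume)
#' / n_lipids`. The water bead volume is a calibration constant (a water-only
#' reference system pins it down); `particle_volume` defaults to 0, in which
#' case the reported value is the lipid+particle composite volume.
#'
#' @param traj A [cg_trajectory()].
#' @param water_bead_volume Volume of one water bead, nm^3, > 0 (ignored if
#'   there are no waters).
#' @param particle_volume Volume attributed to one nanoparticle molecule,
#'   nm^3 (default 0).
#' @return A tibble with one row per frame (`frame`, `time`, `vpl` in nm^3)
#'   with `mean`/`sd` attributes.
#' @export
volume_per_lipid <- function(traj, water_bead_volume = 0.12, particle_volume = 0) {
  topo <- traj$topology
  n_lip <- n_molecules_of(topo, LIPID_GROUPS)
  if (n_lip == 0) abort("trajectory contains no lipids", class = "memlens_selection_error")
  n_wat <- sum(topo$group == "water")
  n_np <- n_molecules_of(topo, "fullerene")
  if (n_wat > 0) stopifnot(water_bead_volume > 0)
  out <- frame_info(traj) |>
    mutate(vpl = (.data$Lx * .data$Ly * .data$Lz - n_wat * water_bead_volume -
                    n_np * particle_volume) / n_lip) |>
    select("frame", "time", "vpl")
  if (any(out$vpl <= 0)) {
    abort("negative volume per lipid: water_bead_volume is miscalibrated",
          class = "memlens_value_error")
  }
  as_series(out, "vpl", n_lipids = n_lip, n_waters = n_wat)
}

as_series <- function(tbl, column, ...) {
  attr(tbl, "mean") <- mean(tbl[[column]])
  attr(tbl, "sd") <- sd(tbl[[column]])
  extra <- list(...)
  for (nm in names(extra)) attr(tbl, nm) <- extra[[nm]]
  class(tbl) <- c("memlens_series", class(tbl))
  attr(tbl, "value_column") <- column
  tbl
}

#' @export
glance.memlens_series <- function(x, ...) {
  col <- attr(x, "value_column")
  tibble(quantity = col, mean = attr(x, "mean"), sd = attr(x, "sd"),
         n_frames = nrow(x))
}

#' Mass density profile along the bilayer normal
#'
#' Per frame, each bead's z coordinate is taken relative to the circular-mean
#' center of mass of all lipid beads (so a drifting slab stays centred),
#' wrapped to `[-Lz/2, Lz/2)`, and the group's mass is histogrammed; the
#' histogram is divided by the bin volume `Lx*Ly*bin_width` and averaged over
#' frames. The integral of a group's profile times the box area recovers the
#' group's total mass.
#'
#' @param traj A [cg_trajectory()].
#' @param groups Character vector of group labels to profile (default: every
#'   group present).
#' @param bin_width Bin width in nm (default 0.1, fine enough to resolve the
#'   layering maxima of nanoparticles in unsaturated bilayers).
#' @param center_on Group set used for the per-frame centring (default: all
#'   lipid groups; falls back to all beads if no lipids).
#' @return A `membrane_profile` tibble (`z`, `group`, `density` in amu/nm^3)
#'   with attributes `bin_width`, `n_frames`, `box_area`.
#' @export
density_profile <- function(traj, groups = NULL, bin_width = 0.1,
                            center_on = LIPID_GROUPS) {
  stopifnot(bin_width > 0)
  topo <- traj$topology
  groups <- groups %||% intersect(GROUP_LEVELS, unique(topo$group))
  sel_rows <- lapply(groups, function(g) which(topo$group == g))
  if (any(lengths(sel_rows) == 0)) {
    abort(paste0("empty group selection: ",
                 paste(groups[lengths(sel_rows) == 0], collapse = ", ")),
          class = "memlens_selection_error")
  }
  center_rows <- which(topo$group %in% center_on)
  if (length(center_rows) == 0) center_rows <- seq_len(nrow(topo))
  Lz <- max(traj$boxes[, 3])
  half <- Lz / 2
  breaks <- seq(-half, half, by = bin_width)
  if (max(breaks) < half) breaks <- c(breaks, max(breaks) + bin_width)
  centers <- (head(breaks, -1) + tail(breaks, -1)) / 2
  nb <- length(centers)
  nf <- n_frames(traj)
  acc <- matrix(0, nb, length(groups))
  area_sum <- 0
  for (f in seq_len(nf)) {
    box <- traj$boxes[f, ]
    z <- traj$coords[, 3, f]
    zc <- center_of_mass(matrix(traj$coords[center_rows, , f], ncol = 3),
                         topo$mass[center_rows], box, pbc = TRUE)[3]
    zrel <- min_image_disp(z - zc, box[3])
    area_sum <- area_sum + box[1] * box[2]
    for (gi in seq_along(groups)) {
      rows <- sel_rows[[gi]]
      idx <- findInterval(zrel[rows], breaks, rightmost.closed = TRUE)
      idx[idx < 1] <- 1; idx[idx > nb] <- nb
      acc[, gi] <- acc[, gi] + tabulate_weighted(idx, topo$mass[rows], nb)
    }
  }
  mean_area <- area_sum / nf
  dens <- acc / (nf * mean_area * bin_width)
  out <- tibble(z = rep(centers, times = length(groups)),
                group = rep(groups, each = nb),
                density = as.numeric(dens))
  structure(out, class = c("membrane_profile", class(out)),
            bin_width = bin_width, n_frames = nf, box_area = mean_area)
}

tabulate_weighted <- function(idx, w, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Bilayer thickness from a density profile
#'
#' Distance between the head-group density maxima of the two leaflets, each
#' peak refined by quadratic interpolation through the maximum bin and its
#' neighbours. This peak-to-peak convention matches the phosphate peaks of a
#' mass density profile; other thickness conventions (e.g. Luzzati) are out
#' of scope.
#'
#' @param profile A `membrane_profile` from [density_profile()] containing a
#'   `lipid_head` group.
#' @param group Group used for the peaks (default `"lipid_head"`).
#' @return Thickness in nm, with attribute `peaks` (the two peak positions).
#' @export
bilayer_thickness <- function(profile, group = "lipid_head") {
  p <- profile[profile$group == group, ]
  if (nrow(p) == 0) abort("profile has no head-group rows", class = "memlens_selection_error")
  lower <- p[p$z < 0, ]; upper <- p[p$z >= 0, ]
  if (nrow(lower) == 0 || nrow(upper) == 0 || max(lower$density) == 0 ||
      max(upper$density) == 0) {
    abort("no bilayer structure: need one head-density maximum per side",
          class = "memlens_value_error")
  }
  peak_of <- function(side) {
    i <- which.max(side$density)
    refine_quadratic(side$z, side$density, i)
  }
  z1 <- peak_of(lower); z2 <- peak_of(upper)
  structure(z2 - z1, peaks = c(z1, z2))
}

# vertex of the parabola through (x[i-1..i+1], y[i-1..i+1]); falls back to
# the bin center at grid edges or degenerate curvature
refine_quadratic <- function(x, y, i) {
  if (i <= 1 || i >= length(x)) return(x[i])
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (!is.finite(denom) || denom >= 0 || abs(denom) < 1e-300) return(x[i])
  x[i] + 0.5 * (x[i + 1] - x[i]) * (y[i - 1] - y[i + 1]) / denom
}

#' Isothermal area compressibility from box-area fluctuations
#'
#' `K_A = kB * T * <A> / Var(A)` with `A` the total box area. The
#' uncertainty comes from block averaging: the series is cut into
#' `n_blocks` contiguous blocks, `K_A` is computed per block, and the
#' standard error across blocks is reported (area fluctuations are
#' correlated in time, so a naive SE would be too small).
#'
#' @param area_series Numeric vector of per-frame box areas (nm^2), or a
#'   [cg_trajectory()] (areas are taken from its boxes).
#' @param temperature Temperature in K.
#' @param n_blocks Number of blocks for the error estimate (default 5).
#' @return A one-row tibble: `ka` (kJ/(mol nm^2)), `ka_mN_per_m`, `se`,
#'   `mean_area`, `var_area`, `n_frames`.
#' @export
area_compressibility <- function(area_series, temperature = 298, n_blocks = 5) {
  if (inherits(area_series, "cg_trajectory")) {
    area_series <- area_series$boxes[, 1] * area_series$boxes[, 2]
  }
  n <- length(area_series)
  if (n < 100) abort("need at least 100 frames for a fluctuation estimate",
                     class = "memlens_value_error")
  v <- var(area_series)
  if (v == 0) abort("rigid area (Var(A) = 0) - barostat off?",
                    class = "memlens_value_error")
  ka <- kB * temperature * mean(area_series) / v
  blocks <- split(area_series, cut(seq_len(n), n_blocks, labels = FALSE))
  ka_blocks <- vapply(blocks, function(b) kB * temperature * mean(b) / var(b),
                      numeric(1))
  tibble(ka = ka, ka_mN_per_m = ka * MN_PER_M_PER_KJ_MOL_NM2,
         se = sd(ka_blocks) / sqrt(n_blocks), mean_area = mean(area_series),
         var_area = v, n_frames = n)
}

#' Membrane dimension summary
#'
#' Convenience wrapper returning mean and SD of APL, VPL and thickness (plus
#' `K_A` when the box area fluctuates) in a single row.
#'
#' @param traj A [cg_trajectory()].
#' @param water_bead_volume Passed to [volume_per_lipid()].
#' @param bin_width Passed to [density_profile()].
#' @param temperature Passed to [area_compressibility()].
#' @return A one-row tibble.
#' @export
membrane_dimensions <- function(traj, water_bead_volume = 0.12, bin_width = 0.1,
                                temperature = 298) {
  apl <- area_per_lipid(traj)
  vpl <- volume_per_lipid(traj, water_bead_volume)
  prof <- density_profile(traj, groups = "lipid_head", bin_width = bin_width)
  th <- bilayer_thickness(prof)
  area <- traj$boxes[, 1] * traj$boxes[, 2]
  ka <- if (length(area) >= 100 && var(area) > 0) {
    area_compressibility(area, temperature)$ka
  } else NA_real_
  apl_sd <- attr(apl, "sd")
  vpl_sd <- attr(vpl, "sd")
  tibble(apl = attr(apl, "mean"), apl_sd = apl_sd,
         vpl = attr(vpl, "mean"), vpl_sd = vpl_sd,
         thickness = as.numeric(th), ka = ka, n_frames = n_frames(traj))
}
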