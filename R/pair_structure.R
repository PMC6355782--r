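#' Center-of-mass radial distribution function
#'
#' Accumulates minimum-image nanoparticle center-of-mass pair distances into
#' uniform bins. Three normalization modes are exposed, because in thin-film
#' geometry the textbook shell normalization has no flat plateau and the
#' additive constant of the Boltzmann-inverted free energy must be fixed by
#' an explicit convention:
#'
#' * `raw_histogram` — plain pair counts per bin;
#' * `shell_normalized` — counts divided by the ideal-gas shell expectation
#'   `n_pairs * 4 pi r^2 dr / V` per frame (g -> 1 in bulk 3D);
#' * `plateau_normalized` (default) — counts divided by their mean over the
#'   plateau window (default 2.5-3.2 nm), so `mean(g) = 1` there.
#'
#' @param traj A [cg_trajectory()] with at least 2 fullerene-group molecules.
#' @param bin_width Bin width in nm (default 0.02).
#' @param r_max Histogram range (default `min(half smallest box edge, 3.5)`).
#' @param mode Normalization mode (see above).
#' @param plateau Plateau window in nm for `plateau_normalized`.
#' @param window_frac Trailing fraction of frames to accumulate (default 1:
#'   generator output is already post-burn-in).
#' @param group Bead group of the particles.
#' @return A `pair_distribution` tibble (`r`, `g`, `count`) with attributes
#'   `mode`, `bin_width`, `n_frames`, `pair_count`, `plateau`, `temperature`
#'   hints for downstream steps.
#' @export
com_rdf <- function(traj, bin_width = 0.02, r_max = NULL,
                    mode = c("plateau_normalized", "shell_normalized", "raw_histogram"),
                    plateau = c(2.5, 3.2), window_frac = 1, group = "fullerene") {
  mode <- match.arg(mode)
  stopifnot(bin_width > 0)
  frames <- window_frames(traj, window_frac)
  half_min_box <- min(traj$boxes[frames, ]) / 2
  r_max <- r_max %||% min(half_min_box, 3.5)
  if (r_max > half_min_box + 1e-9) {
    abort("r_max must not exceed half the smallest box edge", class = "memlens_value_error")
  }
  mc <- molecule_coms(traj, group = group)
  m <- dim(mc$coms)[1]
  if (m < 2) abort("need at least two particles for an RDF", class = "memlens_selection_error")
  breaks <- seq(0, r_max, by = bin_width)
  nb <- length(breaks) - 1
  centers <- breaks[-1] - bin_width / 2
  counts <- numeric(nb)
  pair_idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  n_pairs <- nrow(pair_idx)
  nf <- length(frames)
  boxes <- traj$boxes[frames, , drop = FALSE]
  if (n_pairs <= nf) {
    # few particles, many frames: vectorize across frames per pair
    for (k in seq_len(n_pairs)) {
      a <- t(mc$coms[pair_idx[k, 1], , frames])
      b <- t(mc$coms[pair_idx[k, 2], , frames])
      d <- a - b
      d <- d - round(d / boxes) * boxes
      r <- sqrt(rowSums(d * d))
      counts <- counts + tabulate(findInterval(r[r < r_max], breaks,
                                               left.open = TRUE), nb)
    }
  } else {
    for (fi in seq_len(nf)) {
      xyz <- mc$coms[, , frames[fi], drop = TRUE]
      r <- minimum_image_distance(xyz[pair_idx[, 1], , drop = FALSE],
                                  xyz[pair_idx[, 2], , drop = FALSE],
                                  boxes[fi, ])
      counts <- counts + tabulate(findInterval(r[r < r_max], breaks,
                                               left.open = TRUE), nb)
    }
  }
  vols <- boxes[, 1] * boxes[, 2] * boxes[, 3]
  shell <- counts / (n_pairs * 4 * pi * centers^2 * bin_width * mean(1 / vols) * nf)
  g <- switch(mode,
    raw_histogram = counts,
    shell_normalized = shell,
    plateau_normalized = {
      # divide out the ideal shell volume first, then pin the additive
      # constant by the plateau: in thin-film geometry the effective bulk
      # density is ambiguous, but the plateau rescale absorbs it while the
      # shell factor still removes the trivial r^2 geometry
      in_plat <- centers >= plateau[1] & centers <= plateau[2]
      if (!any(in_plat)) {
        abort("plateau window contains no bins", class = "memlens_value_error")
      }
      norm <- mean(shell[in_plat])
      if (norm == 0) abort("no pairs in the plateau window", class = "memlens_value_error")
      shell / norm
    })
  out <- tibble(r = centers, g = as.numeric(g), count = counts)
  structure(out, class = c("pair_distribution", class(out)),
            mode = mode, bin_width = bin_width, n_frames = nf,
            pair_count = sum(counts), plateau = plateau, n_particles = m)
}

#' Boltzmann-inversion free-energy profile
#'
#' `dG(r) = -kB * T * log(g(r))`. Bins with `g = 0` are masked as undefined
#' (`NA`, `defined = FALSE`) rather than clamped: clamping would fabricate
#' free-energy values. Raw-histogram input is rejected because its additive
#' constant is undefined.
#'
#' @param pd A `pair_distribution` in `plateau_normalized` or
#'   `shell_normalized` mode.
#' @param temperature Temperature in K.
#' @return A `free_energy_profile` tibble (`r`, `dG` in kJ/mol, `defined`)
#'   with attributes `temperature`, `mode` and `reference` (the
#'   additive-constant convention in words).
#' @export
free_energy_profile <- function(pd, temperature = 298) {
  mode <- attr(pd, "mode")
  if (is.null(mode) || mode == "raw_histogram") {
    abort(paste0("free energy needs a normalized g(r): raw counts leave the ",
                 "additive constant undefined"), class = "memlens_value_error")
  }
  stopifnot(temperature > 0)
  dG <- ifelse(pd$g > 0, -kB * temperature * log(pd$g), NA_real_)
  out <- tibble(r = pd$r, dG = dG, defined = pd$g > 0)
  reference <- if (mode == "plateau_normalized") {
    sprintf("dG = 0 where g equals its mean over the plateau window [%g, %g] nm",
            attr(pd, "plateau")[1], attr(pd, "plateau")[2])
  } else {
    "dG = 0 at the ideal-gas bulk density"
  }
  structure(out, class = c("free_energy_profile", class(out)),
            temperature = temperature, mode = mode, reference = reference,
            bin_width = attr(pd, "bin_width"))
}

#' Locate the contact and solvent-separated free-energy minima
#'
#' Finds the lowest defined bin in each search window and refines it by
#' quadratic interpolation through the bin and its neighbours. The default
#' windows bracket the two classes of minima of nanoparticle pair PMFs in
#' membranes: a contact pair near 1.0 nm and a lipid-bead-separated pair
#' near 1.5 nm. `ddG = dG_min1 - dG_min2` is negative when the contact pair
#' is favoured; it is independent of the additive-constant convention.
#'
#' @param fep A `free_energy_profile`.
#' @param window1,window2 Disjoint search windows in nm (defaults
#'   `c(0.85, 1.25)` and `c(1.30, 1.75)`).
#' @return A one-row tibble: `r_min1`, `dG_min1`, `r_min2`, `dG_min2`, `ddG`.
#' @export
locate_minima <- function(fep, window1 = c(0.85, 1.25), window2 = c(1.30, 1.75)) {
  if (max(window1) > min(window2)) {
    abort("search windows must be disjoint with window1 below window2",
          class = "memlens_value_error")
  }
  min_in <- function(w) {
    rows <- which(fep$r >= w[1] & fep$r <= w[2] & fep$defined)
    if (length(rows) == 0) {
      abort(sprintf("no defined bins in window [%g, %g] nm", w[1], w[2]),
            class = "memlens_value_error")
    }
    i <- rows[which.min(fep$dG[rows])]
    ok <- i > 1 && i < nrow(fep) && fep$defined[i - 1] && fep$defined[i + 1]
    r_ref <- if (ok) refine_quadratic(fep$r, -fep$dG, i) else fep$r[i]
    list(r = r_ref, dG = fep$dG[i])
  }
  m1 <- min_in(window1); m2 <- min_in(window2)
  tibble(r_min1 = m1$r, dG_min1 = m1$dG, r_min2 = m2$r, dG_min2 = m2$dG,
         ddG = m1$dG - m2$dG)
}

#' Detect splitting of the second RDF peak
#'
#' The bifurcation of the second coordination shell into two sub-peaks is a
#' signature of emerging short-range order (familiar from metallic glasses).
#' The detector reports `split = TRUE` when the window contains at least two
#' local maxima, each with topographic prominence at least
#' `prominence_frac` times the maximum of `g` in the window, separated by a
#' local minimum. Sub-peak positions are refined by quadratic interpolation.
#'
#' @param pd A `pair_distribution`.
#' @param window Search window in nm (default `c(1.30, 2.20)`, the second
#'   shell).
#' @param prominence_frac Minimum prominence as a fraction of the window
#'   maximum (default 0.02).
#' @return A list: `split` (flag), `subpeak_positions` (nm),
#'   `prominences`.
#' @export
detect_second_peak_split <- function(pd, window = c(1.30, 2.20),
                                     prominence_frac = 0.02) {
  rows <- which(pd$r >= window[1] & pd$r <= window[2])
  if (length(rows) < 3) {
    abort("window lies outside the RDF grid", class = "memlens_value_error")
  }
  r <- pd$r[rows]; g <- pd$g[rows]
  n <- length(g)
  is_peak <- which(diff(sign(diff(g))) == -2) + 1
  if (length(is_peak) < 2) {
    return(list(split = FALSE,
                subpeak_positions = if (length(is_peak) == 1)
                  refine_quadratic(r, g, is_peak) else numeric(0),
                prominences = numeric(0)))
  }
  prominence <- vapply(is_peak, function(i) {
    h <- g[i]
    left <- g[seq_len(i - 1)]
    right <- g[seq((i + 1), n)]
    higher_l <- which(left >= h)
    higher_r <- which(right >= h)
    saddle_l <- if (length(higher_l) > 0) min(left[(max(higher_l)):(i - 1)]) else min(left)
    saddle_r <- if (length(higher_r) > 0) min(right[seq_len(min(higher_r))]) else min(right)
    h - max(saddle_l, saddle_r)
  }, numeric(1))
  keep <- prominence >= prominence_frac * max(g)
  peaks <- is_peak[keep]
  split <- length(peaks) >= 2
  list(split = split,
       subpeak_positions = vapply(peaks, function(i) refine_quadratic(r, g, i),
                                  numeric(1)),
       prominences = prominence[keep])
}

#' Density along the axis connecting a particle pair
#'
#' For every frame, each nanoparticle center-of-mass pair whose separation
#' lies within `separation +/- tolerance` defines a local axis with origin at
#' the pair midpoint. Beads within `cylinder_radius` of the axis are
#' histogrammed by their axial coordinate, accumulated over qualifying pairs
#' and frames, and divided by the number of pair instances and the bin width
#' (a linear density per pair, 1/nm). This is the observable that shows
#' whether a lipid bead sits between the two particles of a
#' solvent-separated pair.
#'
#' @param traj A [cg_trajectory()].
#' @param separation Pair separation selecting the pairs, nm.
#' @param tolerance Half-width of the separation window (default 0.05 nm).
#' @param cylinder_radius Radius of the sampling cylinder (default 0.5 nm).
#' @param bin_width Axial bin width (default 0.05 nm).
#' @param half_length Axial half-range of the histogram (default 1.5 nm).
#' @param window_frac Trailing fraction of frames to analyse (default 1).
#' @return A tibble (`s`, `group`, `density`) where `group` is `fullerene`
#'   or `lipid`, with attribute `n_pair_instances`.
#' @export
pair_axis_density <- function(traj, separation, tolerance = 0.05,
                              cylinder_radius = 0.5, bin_width = 0.05,
                              half_length = 1.5, window_frac = 1) {
  mc <- molecule_coms(traj, group = "fullerene")
  m <- dim(mc$coms)[1]
  if (m < 2) abort("need at least two particles", class = "memlens_selection_error")
  topo <- traj$topology
  lipid_rows <- which(topo$group %in% LIPID_GROUPS)
  ful_rows <- which(topo$group == "fullerene")
  breaks <- seq(-half_length, half_length, by = bin_width)
  nb <- length(breaks) - 1
  centers <- breaks[-1] - bin_width / 2
  acc <- matrix(0, nb, 2, dimnames = list(NULL, c("fullerene", "lipid")))
  pair_idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  n_inst <- 0L
  frames <- window_frames(traj, window_frac)
  for (f in frames) {
    box <- traj$boxes[f, ]
    coms <- mc$coms[, , f, drop = TRUE]
    d <- minimum_image_distance(coms[pair_idx[, 1], , drop = FALSE],
                                coms[pair_idx[, 2], , drop = FALSE], box)
    hits <- which(abs(d - separation) <= tolerance)
    if (length(hits) == 0) next
    xyz <- traj$coords[, , f, drop = TRUE]
    for (k in hits) {
      i <- pair_idx[k, 1]; j <- pair_idx[k, 2]
      axis <- min_image_disp(coms[j, ] - coms[i, ], box)
      e <- axis / sqrt(sum(axis^2))
      mid <- pbc_wrap(coms[i, ] + axis / 2, box)
      n_inst <- n_inst + 1L
      for (grp in c("fullerene", "lipid")) {
        rows <- if (grp == "fullerene") ful_rows else lipid_rows
        if (length(rows) == 0) next
        disp <- min_image_disp(sweep(xyz[rows, , drop = FALSE], 2, mid, "-"), box)
        ax <- as.numeric(disp %*% e)
        rad2 <- rowSums(disp^2) - ax^2
        sel <- rad2 <= cylinder_radius^2 & abs(ax) < half_length
        if (any(sel)) {
          idx <- findInterval(ax[sel], breaks, rightmost.closed = TRUE)
          acc[, grp] <- acc[, grp] + tabulate(idx, nb)
        }
      }
    }
  }
  if (n_inst == 0L) {
    abort(sprintf("no pairs found at separation %g +/- %g nm in %d frames",
                  separation, tolerance, length(frames)),
          class = "memlens_value_error")
  }
  out <- tibble(s = rep(centers, 2),
                group = rep(c("fullerene", "lipid"), each = nb),
                density = c(acc[, "fullerene"], acc[, "lipid"]) / (n_inst * bin_width))
  structure(out, n_pair_instances = n_inst, separation = separation,
            class = c("pair_axis_density", class(out)))
}
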