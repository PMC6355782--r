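test_that("raw histogram puts a fixed pair in exactly one bin, matching brute force", {
  traj <- particle_traj(rbind(c(2, 5, 5), c(3, 5, 5)), c(12, 12, 12), n_frames = 3)
  pd <- com_rdf(traj, bin_width = 0.02, r_max = 4, mode = "raw_histogram")
  expect_equal(sum(pd$count > 0), 1)
  expect_equal(pd$r[pd$count > 0], 0.99)  # bin (0.98, 1.00]
  expect_equal(pd$count[pd$count > 0], 3)  # one pair, three frames

  # random frames: bin counts equal the all-pairs brute-force histogram
  set.seed(12)
  n <- 9; nf <- 40; box <- c(8, 8, 8)
  arr <- array(runif(n * 3 * nf) * 8, c(n, 3, nf))
  topo <- bead_topology(tibble::tibble(bead_name = "CNP",
                                       molecule_id = 0:(n - 1), species = "NP1",
                                       group = "fullerene", mass = 720))
  traj2 <- cg_trajectory(topo, arr, matrix(box, nf, 3, byrow = TRUE))
  pd2 <- com_rdf(traj2, bin_width = 0.05, r_max = 3.9, mode = "raw_histogram")
  breaks <- seq(0, 3.9, by = 0.05)
  ref <- numeric(length(breaks) - 1)
  for (f in seq_len(nf)) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- brute_min_image(arr[i, , f], arr[j, , f], box)
    if (d < 3.9) {
      b <- findInterval(d, breaks, left.open = TRUE)
      ref[b] <- ref[b] + 1
    }
  }
  expect_equal(pd2$count, ref)
})

test_that("plateau normalization pins the plateau mean at one and r_max is guarded", {
  set.seed(3)
  n <- 16
  arr <- array(runif(n * 3 * 200) * 9, c(n, 3, 200))
  topo <- bead_topology(tibble::tibble(bead_name = "CNP", molecule_id = 0:(n - 1),
                                       species = "NP1", group = "fullerene", mass = 720))
  traj <- cg_trajectory(topo, arr, matrix(9, 200, 3, byrow = TRUE))
  pd <- com_rdf(traj, bin_width = 0.02, r_max = 4.4, mode = "plateau_normalized",
                plateau = c(2.5, 3.2))
  in_plat <- pd$r >= 2.5 & pd$r <= 3.2
  expect_equal(mean(pd$g[in_plat]), 1, tolerance = 1e-6)
  expect_true(all(pd$g >= 0))
  expect_error(com_rdf(traj, r_max = 5), "half the smallest",
               class = "memlens_value_error")
  expect_error(com_rdf(traj, r_max = 4, plateau = c(4.5, 4.8)),
               "plateau", class = "memlens_value_error")
})

test_that("Boltzmann inversion is exact on closed-form g and masks zeros", {
  r <- seq(0.21, 3.99, by = 0.02)
  expect_equal(free_energy_profile(fake_pd(r, rep(1, length(r))), 298)$dG,
               rep(0, length(r)))

  g <- rep(1, length(r)); g[50] <- exp(1)
  fep <- free_energy_profile(fake_pd(r, g), temperature = 298)
  expect_equal(fep$dG[50], -kB * 298, tolerance = 1e-9)
  expect_equal(round(fep$dG[50], 3), -2.478)

  g0 <- g; g0[1:10] <- 0
  fep0 <- free_energy_profile(fake_pd(r, g0), 298)
  expect_true(all(is.na(fep0$dG[1:10])) && !any(fep0$defined[1:10]))
  expect_false(any(is.infinite(fep0$dG), na.rm = TRUE))

  expect_error(free_energy_profile(fake_pd(r, g, mode = "raw_histogram")),
               "additive constant|constant", class = "memlens_value_error")

  # round trip: g = exp(-u/kBT) recovers u exactly where g underflow leaves
  # it defined (the hard core has g = 0 and stays masked)
  u <- pair_potential_u(r, list(epsilon = 2, sigma = 0.9, cutoff = 1.2))
  fep_u <- free_energy_profile(fake_pd(r, exp(-u / (kB * 298))), 298)
  ok <- fep_u$defined
  expect_true(all(ok[r >= 0.8]))
  expect_equal(fep_u$dG[ok], u[ok], tolerance = 1e-9)
})

test_that("minima location refines sub-bin and ddG is convention-free", {
  r <- seq(0.5, 2.5, by = 0.02)
  # parabola with vertex at exactly 1.00 (off the bin grid: centers at 0.50, 0.52, ...)
  fep <- fake_fep(r, (r - 1.0)^2)
  m <- locate_minima(fep)
  expect_equal(m$r_min1, 1.00, tolerance = 1e-9)

  # symmetric double well, equal depths -> ddG = 0
  dwell <- function(d1, d2) -d1 * exp(-(r - 1.0)^2 / 0.005) - d2 * exp(-(r - 1.5)^2 / 0.005)
  expect_equal(locate_minima(fake_fep(r, dwell(3, 3)))$ddG, 0, tolerance = 1e-9)

  m2 <- locate_minima(fake_fep(r, dwell(6.76, 5.0)))
  expect_equal(m2$ddG, -1.76, tolerance = 1e-6)
  expect_equal(m2$r_min1, 1.0, tolerance = 0.01)
  expect_equal(m2$r_min2, 1.5, tolerance = 0.01)

  # additive constants cancel in positions and ddG
  m3 <- locate_minima(fake_fep(r, dwell(6.76, 5.0) + 11.3))
  expect_equal(m3$ddG, m2$ddG, tolerance = 1e-12)
  expect_equal(m3$r_min1, m2$r_min1, tolerance = 1e-12)

  expect_error(locate_minima(fake_fep(r, rep(NA_real_, length(r)))),
               "no defined bins", class = "memlens_value_error")
  expect_error(locate_minima(fep, window1 = c(0.9, 1.5), window2 = c(1.4, 1.8)),
               "disjoint", class = "memlens_value_error")
})

test_that("dG differences between bins do not depend on the plateau window", {
  set.seed(30)
  n <- 12
  arr <- array(runif(n * 3 * 400) * 9, c(n, 3, 400))
  topo <- bead_topology(tibble::tibble(bead_name = "CNP", molecule_id = 0:(n - 1),
                                       species = "NP1", group = "fullerene", mass = 720))
  traj <- cg_trajectory(topo, arr, matrix(9, 400, 3, byrow = TRUE))
  f1 <- free_energy_profile(com_rdf(traj, r_max = 4.4, plateau = c(2.5, 3.2)), 298)
  f2 <- free_energy_profile(com_rdf(traj, r_max = 4.4, plateau = c(3.3, 4.2)), 298)
  ok <- f1$defined & f2$defined
  diffs <- (f1$dG - f2$dG)[ok]
  expect_lt(max(diffs) - min(diffs), 1e-9)  # constant offset only
})

test_that("second-peak split detection flips at the analytic merge separation", {
  r <- seq(1.0, 2.5, by = 0.02)
  two_gauss <- function(d, s = 0.12, center = 1.7) {
    exp(-(r - (center - d / 2))^2 / (2 * s^2)) +
      exp(-(r - (center + d / 2))^2 / (2 * s^2))
  }
  # single bump
  single <- fake_pd(r, 0.05 + exp(-(r - 1.7)^2 / 0.02))
  expect_false(detect_second_peak_split(single, window = c(1.3, 2.2))$split)

  # well-separated sub-peaks at 1.55 and 1.85
  sp <- detect_second_peak_split(fake_pd(r, 0.05 + two_gauss(0.30)),
                                 window = c(1.3, 2.2))
  expect_true(sp$split)
  expect_equal(sort(sp$subpeak_positions), c(1.55, 1.85), tolerance = 0.02)

  # analytic oracle: equal Gaussians merge when separation d <= 2s; with the
  # 2% prominence threshold the flip moves to the d* where the saddle depth
  # reaches 2% of the peak, computed here directly from the closed form
  s <- 0.12
  prom_frac <- function(d) {
    f <- function(x) exp(-(x - d / 2)^2 / (2 * s^2)) + exp(-(x + d / 2)^2 / (2 * s^2))
    if (d <= 2 * s) return(0)
    xpk <- stats::optimize(function(x) -f(x), c(0, d))$minimum
    (f(xpk) - f(0)) / f(xpk)
  }
  d_star <- stats::uniroot(function(d) prom_frac(d) - 0.02,
                           c(2 * s + 1e-6, 6 * s))$root
  flips <- vapply(seq(0.20, 0.45, by = 0.01), function(d) {
    detect_second_peak_split(fake_pd(r, two_gauss(d)), window = c(1.3, 2.2))$split
  }, logical(1))
  d_grid <- seq(0.20, 0.45, by = 0.01)
  d_flip <- d_grid[which(flips)[1]]
  expect_lt(abs(d_flip - d_star), 0.02 + 1e-9)  # within one scan step + bin
  expect_true(all(flips[d_grid >= d_flip]))     # monotone beyond the flip

  expect_error(detect_second_peak_split(single, window = c(3, 4)),
               class = "memlens_value_error")
})

test_that("pair-axis density reproduces constructed geometries", {
  # two isolated particles at separation 1.5: symmetric peaks at +/- 0.75
  traj <- particle_traj(rbind(c(4, 5, 5), c(5.5, 5, 5)), c(12, 12, 12), n_frames = 2)
  pad <- pair_axis_density(traj, separation = 1.5, bin_width = 0.05)
  ful <- pad[pad$group == "fullerene", ]
  peaks <- ful$s[ful$density > 0]
  expect_equal(sort(peaks), c(-0.75, 0.75), tolerance = 0.05)
  expect_equal(ful$density[abs(ful$s) < 0.1], c(0, 0, 0, 0))

  # a lipid bead at the midpoint shows up at axial coordinate 0
  topo <- bead_topology(tibble::tibble(
    bead_name = c("CNP", "CNP", "C1B"), molecule_id = c(0L, 1L, 2L),
    species = c("NP1", "NP1", "DPPC"),
    group = c("fullerene", "fullerene", "lipid_tail"), mass = c(720, 720, 72)))
  coords <- rbind(c(4, 5, 5), c(5.5, 5, 5), c(4.75, 5, 5))
  traj2 <- cg_trajectory(topo, array(coords, c(3, 3, 1)), c(12, 12, 12))
  pad2 <- pair_axis_density(traj2, separation = 1.5)
  lip <- pad2[pad2$group == "lipid", ]
  expect_gt(max(lip$density[abs(lip$s) < 0.06]), 0)
  expect_equal(sum(lip$density > 0), 1)

  # the histogram is normalized per qualifying pair instance
  expect_equal(attr(pad, "n_pair_instances"), 2)
  expect_error(pair_axis_density(traj, separation = 3.0), "no pairs",
               class = "memlens_value_error")
})
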