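test_that("unwrapping continues paths across the boundary and round-trips", {
  # particle walking +0.4/frame through x = L
  n_f <- 10
  topo <- bead_topology(tibble::tibble(bead_name = "CNP", molecule_id = 0L,
                                       species = "NP1", group = "fullerene", mass = 720))
  x_true <- 9.0 + 0.4 * (0:(n_f - 1))
  arr <- array(0, c(1, 3, n_f))
  arr[1, 1, ] <- x_true %% 10; arr[1, 2, ] <- 5; arr[1, 3, ] <- 5
  traj <- cg_trajectory(topo, arr, matrix(10, n_f, 3, byrow = TRUE))
  un <- unwrap_trajectory(traj)
  expect_equal(un$coords[1, 1, ], x_true, tolerance = 1e-12)
  expect_true(all(diff(un$coords[1, 1, ]) > 0))

  rewrapped <- wrap_trajectory(un)
  expect_equal(rewrapped$coords, traj$coords, tolerance = 1e-12)

  # a half-box jump is rejected with frame and bead named
  arr2 <- arr; arr2[1, 1, 5] <- arr2[1, 1, 4] + 5
  bad <- cg_trajectory(topo, arr2, matrix(10, n_f, 3, byrow = TRUE))
  expect_error(unwrap_trajectory(bad), "frame 5", class = "memlens_value_error")
})

test_that("unwrap matches the Brownian generator's bookkept true path exactly", {
  spec <- synthetic_spec(n_particles = 16, box = c(7, 7, 7), seed = 9,
                         diffusion_constant = 0.05, dt = 1,
                         sampler = list(mode = "brownian", n_frames = 500))
  traj <- simulate_brownian(spec)
  un <- unwrap_trajectory(traj)
  truth <- attr(traj, "unwrapped")
  # exact up to a per-particle constant image offset fixed by frame 1
  expect_lt(max(abs(un$coords - truth)), 1e-9)
})

test_that("MSD closed forms: static, ballistic drift, and exhaustive enumeration", {
  topo3 <- bead_topology(tibble::tibble(bead_name = "CNP", molecule_id = 0:2,
                                        species = "NP1", group = "fullerene", mass = 720))
  # static
  arr <- array(rep(c(1, 2, 3), 3 * 6), c(3, 3, 6))
  static <- cg_trajectory(topo3, arr, matrix(50, 6, 3, byrow = TRUE), wrapped = FALSE)
  m0 <- msd(static, axes = c("x", "y", "z"))
  expect_lt(max(abs(m0$msd)), 1e-10)

  # drift x = v t -> MSD(tau) = v^2 tau^2 exactly, for every origin
  v <- 0.3; nf <- 21
  arr2 <- array(0, c(3, 3, nf))
  for (p in 1:3) arr2[p, 1, ] <- p + v * (0:(nf - 1))
  drift <- cg_trajectory(topo3, arr2, matrix(100, nf, 3, byrow = TRUE), wrapped = FALSE)
  md <- msd(drift, axes = "x")
  expect_equal(md$msd, v^2 * md$tau^2, tolerance = 1e-9)

  # 3 particles x 5 frames vs hand enumeration over all origins
  set.seed(2)
  arr3 <- array(rnorm(3 * 3 * 5), c(3, 3, 5))
  small <- cg_trajectory(topo3, arr3, matrix(100, 5, 3, byrow = TRUE),
                         times = 0:4, wrapped = FALSE)
  ms <- msd(small, axes = c("x", "y"))
  for (lag in 1:2) {
    per_part <- vapply(1:3, function(p) {
      origins <- 1:(5 - lag)
      mean(vapply(origins, function(t0) {
        sum((arr3[p, 1:2, t0 + lag] - arr3[p, 1:2, t0])^2)
      }, numeric(1)))
    }, numeric(1))
    expect_equal(ms$msd[lag], mean(per_part), tolerance = 1e-9)
    expect_equal(ms$se[lag], sd(per_part) / sqrt(3), tolerance = 1e-9)
  }

  # invariance under rigid translation and relabeling
  arr4 <- arr3 + 5
  shifted <- cg_trajectory(topo3, arr4, matrix(100, 5, 3, byrow = TRUE),
                           times = 0:4, wrapped = FALSE)
  expect_equal(msd(shifted, axes = c("x", "y"))$msd, ms$msd, tolerance = 1e-9)
  perm <- cg_trajectory(topo3, arr3[c(3, 1, 2), , ], matrix(100, 5, 3, byrow = TRUE),
                        times = 0:4, wrapped = FALSE)
  expect_equal(msd(perm, axes = c("x", "y"))$msd, ms$msd, tolerance = 1e-9)

  uneven <- cg_trajectory(topo3, arr3, matrix(100, 5, 3, byrow = TRUE),
                          times = c(0, 1, 2, 4, 8), wrapped = FALSE)
  expect_error(msd(uneven), "non-uniform", class = "memlens_value_error")
})

test_that("diffusion fit recovers closed-form and generated coefficients", {
  # exact line MSD = 4 D tau
  curve <- structure(tibble::tibble(lag = 1:100, tau = 1:100,
                                    msd = 4 * 0.01 * (1:100), se = 1),
                     class = c("msd_curve", "tbl_df", "tbl", "data.frame"),
                     axes = c("x", "y"), dt = 1)
  fit <- suppressWarnings(diffusion_coefficient(curve, dimensionality = 2))
  expect_equal(fit$D, 0.01, tolerance = 1e-12)
  expect_equal(fit$r2, 1)
  expect_equal(suppressWarnings(glance(fit))$D_cm2_s, 1e-7, tolerance = 1e-12)
  expect_equal(suppressWarnings(tidy(fit))$term, c("(Intercept)", "tau"))

  # generated Brownian motion, lateral
  spec <- synthetic_spec(n_particles = 48, box = c(20, 20, 20), seed = 13,
                         diffusion_constant = 0.02, dt = 1,
                         sampler = list(mode = "brownian", n_frames = 3000))
  un <- unwrap_trajectory(simulate_brownian(spec))
  fit2 <- diffusion_coefficient(msd(un, axes = c("x", "y")), 2,
                                fit_window = c(0.002, 0.1))
  expect_equal(fit2$D, 0.02, tolerance = 0.05)

  # z-MSD of a lateral-only walker fits to D = 0
  lat <- synthetic_spec(n_particles = 8, box = c(10, 10, 10), seed = 2,
                        diffusion_constant = 0.02, lateral_only = TRUE,
                        sampler = list(mode = "brownian", n_frames = 400))
  unl <- unwrap_trajectory(simulate_brownian(lat))
  fitz <- suppressWarnings(diffusion_coefficient(msd(unl, axes = "z"), 1))
  expect_equal(fitz$D, 0, tolerance = 1e-12)

  expect_error(diffusion_coefficient(curve, 2, fit_window = c(0.50, 0.51)),
               "fewer than 3", class = "memlens_value_error")
})

test_that("D estimates scale linearly across a decade of inputs", {
  ds <- c(0.002, 0.02)
  est <- vapply(seq_along(ds), function(i) {
    spec <- synthetic_spec(n_particles = 32, box = c(30, 30, 30), seed = 20 + i,
                           diffusion_constant = ds[i], dt = 1,
                           sampler = list(mode = "brownian", n_frames = 2000))
    un <- unwrap_trajectory(simulate_brownian(spec))
    diffusion_coefficient(msd(un, axes = c("x", "y")), 2,
                          fit_window = c(0.002, 0.1))$D
  }, numeric(1))
  slope <- diff(log(est)) / diff(log(ds))
  expect_equal(slope, 1, tolerance = 0.05)
})
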