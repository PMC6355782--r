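#' Synthetic system specification
#'
#' Describes a synthetic coarse-grained slab system: a (frozen) two-leaflet
#' lipid scaffold, nanoparticles sampled either from a Boltzmann distribution
#' (Metropolis) under a truncated-shifted 12-6 pair potential plus an
#' optional layering field `w(z)`, or as non-interacting Brownian walkers
#' with a known diffusion constant. Every generated observable has a
#' closed-form or brute-force ground truth, which is what makes the analysis
#' pipeline testable without a molecular-dynamics engine.
#'
#' @param n_lipids Even lipid count, split into two leaflets (0 = no membrane).
#' @param n_particles Nanoparticle count.
#' @param box Length-3 box `(Lx, Ly, Lz)` in nm.
#' @param target_apl Area per lipid in nm^2; must satisfy
#'   `target_apl * n_lipids/2 == Lx*Ly` within 1%.
#' @param head_separation Distance between the two head-bead planes (nm),
#'   `< Lz`.
#' @param unsaturated Label the second tail bead `double_bond` (DOPC-like)?
#' @param n_waters Water beads placed uniformly outside the slab.
#' @param area_sd Per-frame Gaussian SD of the total box area (nm^2, membrane
#'   generator only; 0 = rigid box).
#' @param pair_potential `list(epsilon, sigma, cutoff)` in kJ/mol and nm;
#'   truncated-and-shifted 12-6 form, default cutoff 1.2 nm (the simulation
#'   cutoff the trajectories this pipeline targets were produced with).
#' @param layering_field `NULL`, `list(form = "harmonic", k = )` (kJ/mol/nm^2)
#'   or `list(form = "cosine", A = , h = )`: `A*cos(3*pi*z'/h)` for
#'   `|z'| < h/2`, a three-well potential mimicking the three-region
#'   compartmentalization seen in unsaturated bilayers. `z'` is measured from
#'   the box midplane.
#' @param temperature Temperature in K for the Metropolis sampler.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @param sampler `list(mode, n_steps, step_size, frame_stride, n_frames)`;
#'   `mode` is `"metropolis"` or `"brownian"`. For Metropolis, `n_steps` is
#'   the number of sweeps (one attempted move per particle each), the first
#'   half is discarded as burn-in, and frames are recorded every
#'   `frame_stride` sweeps. For Brownian, `n_frames` frames are produced at
#'   spacing `dt`.
#' @param diffusion_constant Brownian diffusion constant in nm^2/ns.
#' @param dt Frame spacing in ns (Brownian and membrane generators).
#' @param lateral_only Brownian updates only in x/y (normal-direction MSD is
#'   then identically zero).
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_lipids = 0, n_particles = 0, box = c(10, 10, 10),
                           target_apl = 0.64, head_separation = 4.0,
                           unsaturated = FALSE, n_waters = 0, area_sd = 0,
                           pair_potential = list(epsilon = 2, sigma = 0.9,
                                                 cutoff = 1.2),
                           layering_field = NULL, temperature = 298,
                           seed = 1L,
                           sampler = list(mode = "metropolis", n_steps = 2e4,
                                          step_size = 0.45, frame_stride = 10,
                                          n_frames = 100),
                           diffusion_constant = 0.01, dt = 1,
                           lateral_only = FALSE) {
  spec <- list(n_lipids = as.integer(n_lipids), n_particles = as.integer(n_particles),
               box = as.numeric(box), target_apl = target_apl,
               head_separation = head_separation, unsaturated = isTRUE(unsaturated),
               n_waters = as.integer(n_waters), area_sd = area_sd,
               pair_potential = modifyList(list(epsilon = 2, sigma = 0.9, cutoff = 1.2),
                                           pair_potential),
               layering_field = layering_field, temperature = temperature,
               seed = as.integer(seed),
               sampler = modifyList(list(mode = "metropolis", n_steps = 2e4,
                                         step_size = 0.45, frame_stride = 10,
                                         n_frames = 100), sampler),
               diffusion_constant = diffusion_constant, dt = dt,
               lateral_only = isTRUE(lateral_only))
  validate_synthetic_spec(spec)
  structure(spec, class = "synthetic_spec")
}

validate_synthetic_spec <- function(spec) {
  stopifnot(length(spec$box) == 3, all(spec$box > 0), spec$temperature > 0,
            spec$pair_potential$epsilon >= 0, spec$pair_potential$sigma > 0,
            spec$n_particles >= 0, spec$n_lipids >= 0, spec$n_waters >= 0)
  if (spec$n_lipids > 0) {
    if (spec$n_lipids %% 2 != 0) {
      abort("n_lipids must be even (two leaflets)", class = "memlens_spec_error")
    }
    implied <- spec$target_apl * spec$n_lipids / 2
    area <- spec$box[1] * spec$box[2]
    if (abs(implied - area) / area > 0.01) {
      abort(sprintf("target_apl * n_lipids/2 = %.3f nm^2 differs from Lx*Ly = %.3f nm^2 by more than 1%%",
                    implied, area), class = "memlens_spec_error")
    }
    if (spec$head_separation >= spec$box[3]) {
      abort("head_separation must be smaller than Lz", class = "memlens_spec_error")
    }
  }
  if (!is.null(spec$layering_field) &&
      !spec$layering_field$form %in% c("harmonic", "cosine")) {
    abort("layering_field$form must be 'harmonic' or 'cosine'",
          class = "memlens_spec_error")
  }
  invisible(spec)
}

# Frozen slab scaffold: bead positions + topology rows for one configuration.
# Lipids: head bead (PO4) at +/- head_separation/2 from the midplane, three
# tail beads inward at 0.47-nm spacing; second tail bead labelled double_bond
# when unsaturated. Heads sit on a jittered square lattice (sigma = 0.05 nm).
slab_scaffold <- function(spec) {
  box <- spec$box
  n_leaf <- spec$n_lipids / 2
  n_side <- ceiling(sqrt(n_leaf))
  if (n_side^2 * (box[1] / n_side) * (box[2] / n_side) / n_leaf <
      spec$target_apl * 0.5) {
    abort("lattice cannot host n_lipids/2 at target_apl in the given box",
          class = "memlens_spec_error")
  }
  ax <- box[1] / n_side
  ay <- box[2] / n_side
  grid <- expand.grid(ix = seq_len(n_side) - 0.5, iy = seq_len(n_side) - 0.5)
  grid <- grid[seq_len(n_leaf), ]
  species <- if (spec$unsaturated) "DOPC" else "DPPC"
  bead_names <- c("PO4", "C1B", if (spec$unsaturated) "D2B" else "C2B", "C3B")
  groups <- c("lipid_head", "lipid_tail",
              if (spec$unsaturated) "double_bond" else "lipid_tail", "lipid_tail")
  zmid <- box[3] / 2
  tail_spacing <- 0.47
  coords <- list(); rows <- list()
  mol <- 0L
  for (leaf in c(1, -1)) {
    hx <- grid$ix * ax + rnorm(n_leaf, 0, 0.05)
    hy <- grid$iy * ay + rnorm(n_leaf, 0, 0.05)
    hz <- zmid + leaf * spec$head_separation / 2
    for (l in seq_len(n_leaf)) {
      z4 <- hz - leaf * tail_spacing * (0:3)
      coords[[length(coords) + 1]] <-
        cbind(rep(hx[l], 4), rep(hy[l], 4), z4)
      rows[[length(rows) + 1]] <- tibble(
        bead_name = bead_names, molecule_id = mol, species = species,
        group = groups, mass = 72)
      mol <- mol + 1L
    }
  }
  list(coords = do.call(rbind, coords), rows = bind_rows(rows), n_mol = mol)
}

water_scaffold <- function(spec, mol_offset) {
  box <- spec$box
  zmid <- box[3] / 2
  half_slab <- spec$head_separation / 2 + 0.3
  z <- numeric(spec$n_waters)
  for (i in seq_len(spec$n_waters)) {
    repeat {
      zi <- runif(1, 0, box[3])
      if (spec$n_lipids == 0 || abs(zi - zmid) > half_slab) break
    }
    z[i] <- zi
  }
  list(coords = cbind(runif(spec$n_waters, 0, box[1]),
                      runif(spec$n_waters, 0, box[2]), z),
       rows = tibble(bead_name = "W",
                     molecule_id = mol_offset + seq_len(spec$n_waters) - 1L,
                     species = "W", group = "water", mass = 72))
}

particle_rows <- function(n, mol_offset) {
  tibble(bead_name = "CNP", molecule_id = mol_offset + seq_len(n) - 1L,
         species = "NP1", group = "fullerene", mass = 720)
}

# random initial particle positions avoiding hard core overlap
init_particles <- function(spec) {
  n <- spec$n_particles
  box <- spec$box
  sig <- spec$pair_potential$sigma
  pos <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    for (try in 1:200) {
      p <- runif(3) * box
      if (i == 1 ||
          all(minimum_image_distance(matrix(p, nrow = i - 1, ncol = 3, byrow = TRUE),
                                     pos[seq_len(i - 1), , drop = FALSE],
                                     box) > 0.85 * sig)) break
    }
    pos[i, ] <- p
  }
  pos
}

#' Generate a frozen slab-membrane trajectory
#'
#' Two leaflets of four-bead lipids on a jittered square lattice, head beads
#' at `+/- head_separation/2` about the box midplane, plus optional water
#' beads outside the slab. When `area_sd > 0`, each frame's box area
#' fluctuates as an independent Gaussian and the in-plane coordinates are
#' scaled affinely with the box, which gives the area-compressibility
#' estimator a known ground truth.
#'
#' @param spec A [synthetic_spec()] with `n_lipids > 0`.
#' @param n_frames Number of frames (default `spec$sampler$n_frames`).
#' @return A [cg_trajectory()].
#' @export
generate_slab_membrane <- function(spec, n_frames = NULL) {
  validate_synthetic_spec(spec)
  stopifnot(spec$n_lipids > 0)
  n_frames <- n_frames %||% spec$sampler$n_frames
  set.seed(spec$seed)
  sc <- slab_scaffold(spec)
  rows <- sc$rows
  coords1 <- sc$coords
  if (spec$n_waters > 0) {
    wt <- water_scaffold(spec, sc$n_mol)
    coords1 <- rbind(coords1, wt$coords)
    rows <- bind_rows(rows, wt$rows)
  }
  topo <- bead_topology(rows)
  box0 <- spec$box
  A0 <- box0[1] * box0[2]
  coords <- array(NA_real_, c(nrow(coords1), 3, n_frames))
  boxes <- matrix(NA_real_, n_frames, 3)
  for (f in seq_len(n_frames)) {
    s <- if (spec$area_sd > 0) sqrt(max(0.5, 1 + rnorm(1, 0, spec$area_sd / A0))) else 1
    coords[, 1, f] <- coords1[, 1] * s
    coords[, 2, f] <- coords1[, 2] * s
    coords[, 3, f] <- coords1[, 3]
    boxes[f, ] <- c(box0[1] * s, box0[2] * s, box0[3])
  }
  cg_trajectory(topo, coords, boxes, times = (seq_len(n_frames) - 1) * spec$dt)
}

#' Sample nanoparticle configurations by Metropolis Monte Carlo
#'
#' Single-particle Metropolis moves under the sum of a truncated-shifted 12-6
#' pair potential and the optional layering field `w(z)`, with minimum-image
#' distances. The lipid scaffold (if any) is frozen: it provides labels and
#' geometry for the analyses, not dynamics. The first half of the sweeps is
#' discarded as burn-in; frames are recorded every `frame_stride` sweeps.
#' In the dilute limit the recorded configurations obey
#' `g(r) = exp(-u(r)/kB T)`, the closed-form ground truth for the
#' Boltzmann-inversion free-energy profile.
#'
#' The acceptance rate is reported via a message; a rate outside
#' `[0.1, 0.9]` raises a warning (dilute systems accept nearly every move,
#' which is expected and harmless).
#'
#' @param spec A [synthetic_spec()] with `sampler$mode = "metropolis"` and
#'   `n_particles >= 1`.
#' @param quiet Suppress the acceptance-rate message.
#' @return A [cg_trajectory()] whose recorded frames are the post-burn-in
#'   Metropolis samples; the acceptance rate is attached as attribute
#'   `acceptance_rate`.
#' @export
sample_particles_mc <- function(spec, quiet = FALSE) {
  validate_synthetic_spec(spec)
  stopifnot(spec$sampler$mode == "metropolis", spec$n_particles >= 1)
  set.seed(spec$seed)
  scaffold_coords <- NULL
  rows <- particle_rows(spec$n_particles, 0L)
  if (spec$n_lipids > 0) {
    sc <- slab_scaffold(spec)
    scaffold_coords <- sc$coords
    sc$rows$molecule_id <- sc$rows$molecule_id + spec$n_particles
    rows <- bind_rows(rows, sc$rows)
  }
  pos0 <- init_particles(spec)
  lf <- spec$layering_field
  field_type <- 0L; fp1 <- 0; fp2 <- 0
  if (!is.null(lf)) {
    if (lf$form == "harmonic") { field_type <- 1L; fp1 <- lf$k }
    else { field_type <- 2L; fp1 <- lf$A; fp2 <- lf$h %||% spec$box[3] }
  }
  n_sweeps <- as.integer(spec$sampler$n_steps)
  burnin <- n_sweeps %/% 2L
  res <- mc_kernel(pos0, spec$box, spec$pair_potential$epsilon,
                   spec$pair_potential$sigma, spec$pair_potential$cutoff,
                   field_type, fp1, fp2, kB * spec$temperature, n_sweeps,
                   spec$sampler$step_size, burnin,
                   as.integer(spec$sampler$frame_stride))
  if (res$n_recorded < 1) {
    abort("no frames recorded; increase n_steps or decrease frame_stride",
          class = "memlens_spec_error")
  }
  acc <- res$accepted / res$attempted
  if (!quiet) inform(sprintf("Metropolis acceptance rate: %.3f (%d sweeps, %d frames)",
                             acc, n_sweeps, res$n_recorded))
  if (acc < 0.1 || acc > 0.9) {
    warn(sprintf("Metropolis acceptance rate %.3f outside [0.1, 0.9]", acc))
  }
  part <- array(res$frames, c(spec$n_particles, 3, res$n_recorded))
  if (!is.null(scaffold_coords)) {
    nb <- spec$n_particles + nrow(scaffold_coords)
    coords <- array(NA_real_, c(nb, 3, res$n_recorded))
    coords[seq_len(spec$n_particles), , ] <- part
    coords[(spec$n_particles + 1):nb, , ] <- scaffold_coords
  } else {
    coords <- part
  }
  traj <- cg_trajectory(bead_topology(rows), coords,
                        matrix(spec$box, res$n_recorded, 3, byrow = TRUE),
                        times = res$rec_sweeps[seq_len(res$n_recorded)] * spec$dt)
  attr(traj, "acceptance_rate") <- acc
  traj
}

#' Simulate non-interacting Brownian particles
#'
#' Overdamped updates `x <- x + sqrt(2 D dt) eta` per axis (Gaussian `eta`),
#' wrapped into the box. The true unwrapped path is kept as attribute
#' `unwrapped` (array `n x 3 x frames`), the exact ground truth for
#' [unwrap_trajectory()] and the MSD estimators.
#'
#' @param spec A [synthetic_spec()] with `diffusion_constant > 0` (or 0 for a
#'   static system) and `sampler$n_frames` frames at spacing `dt`.
#' @return A [cg_trajectory()] with attribute `unwrapped`.
#' @export
simulate_brownian <- function(spec) {
  validate_synthetic_spec(spec)
  stopifnot(spec$n_particles >= 1, spec$diffusion_constant >= 0)
  set.seed(spec$seed)
  n <- spec$n_particles
  nf <- as.integer(spec$sampler$n_frames)
  box <- spec$box
  sd_step <- sqrt(2 * spec$diffusion_constant * spec$dt)
  if (sd_step > min(box) / 20) {
    # guard well below the half-box unwrapping bound: a 6-sigma step must
    # stay under box/4
    if (6 * sd_step > min(box) / 4) {
      abort("per-step displacement can exceed box/4; reduce dt or D",
            class = "memlens_spec_error")
    }
  }
  axes <- if (spec$lateral_only) 1:2 else 1:3
  unwrapped <- array(0, c(n, 3, nf))
  unwrapped[, 1, 1] <- runif(n, 0, box[1])
  unwrapped[, 2, 1] <- runif(n, 0, box[2])
  unwrapped[, 3, 1] <- runif(n, 0, box[3])
  for (f in seq_len(nf)[-1]) {
    step <- matrix(0, n, 3)
    step[, axes] <- rnorm(n * length(axes), 0, sd_step)
    unwrapped[, , f] <- unwrapped[, , f - 1] + step
  }
  coords <- unwrapped
  for (f in seq_len(nf)) coords[, , f] <- pbc_wrap(coords[, , f], box)
  traj <- cg_trajectory(particle_rows(n, 0L) |> bead_topology(), coords,
                        matrix(box, nf, 3, byrow = TRUE),
                        times = (seq_len(nf) - 1) * spec$dt)
  attr(traj, "unwrapped") <- unwrapped
  traj
}

#' Evaluate the generator's pair potential
#'
#' Truncated-and-shifted 12-6: `4*eps*((sigma/r)^12 - (sigma/r)^6) - u(cutoff)`
#' for `r < cutoff`, 0 beyond. This is the closed-form dilute-limit ground
#' truth for the Boltzmann-inversion free-energy profile.
#'
#' @param r Distances in nm.
#' @param pair_potential `list(epsilon, sigma, cutoff)`.
#' @return Potential values in kJ/mol.
#' @export
pair_potential_u <- function(r, pair_potential) {
  eps <- pair_potential$epsilon; sig <- pair_potential$sigma
  rc <- pair_potential$cutoff
  u <- function(x) 4 * eps * ((sig / x)^12 - (sig / x)^6)
  ifelse(r < rc, u(r) - u(rc), 0)
}
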