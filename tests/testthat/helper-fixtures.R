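# Fixtures are built in code at test time; nothing binary is stored.

# minimal topology map covering the bead names used in tests
test_map <- function() {
  list(
    PO4 = list(group = "lipid_head", mass = 72),
    GL1 = list(group = "lipid_glycerol", mass = 54),
    C1B = list(group = "lipid_tail", mass = 72),
    C2B = list(group = "lipid_tail", mass = 72),
    C3B = list(group = "lipid_tail", mass = 72),
    D2B = list(group = "double_bond", mass = 72),
    CNP = list(group = "fullerene", mass = 720),
    CF  = list(group = "fullerene", mass = 45),
    W   = list(group = "water", mass = 72)
  )
}

write_test_map <- function(map = test_map()) {
  path <- withr::local_tempfile(fileext = ".yaml", .local_envir = parent.frame())
  yaml::write_yaml(list(beads = map), path)
  path
}

# hand-written single-frame GRO text
gro_lines <- function(rows, box = c(10, 10, 10), title = "fixture t= 0.0") {
  c(title, sprintf("%5d", nrow(rows)),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", rows$resid, rows$resname,
            rows$atom, seq_len(nrow(rows)), rows$x, rows$y, rows$z),
    sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
}

# a tiny 3-bead fixture trajectory on disk
write_tiny_gro <- function(box = c(10, 10, 10)) {
  rows <- data.frame(resid = c(1, 2, 3), resname = c("W", "W", "NP1"),
                     atom = c("W", "W", "CNP"),
                     x = c(1.0, 2.5, 7.25), y = c(1.0, 2.0, 3.0),
                     z = c(5.0, 5.5, 6.0))
  path <- withr::local_tempfile(fileext = ".gro", .local_envir = parent.frame())
  writeLines(gro_lines(rows, box), path)
  path
}

# in-memory trajectory of free particles at given positions (single frame)
particle_traj <- function(coords, box, n_frames = 1, times = NULL) {
  n <- nrow(coords)
  topo <- bead_topology(tibble::tibble(
    bead_name = "CNP", molecule_id = seq_len(n) - 1L, species = "NP1",
    group = "fullerene", mass = 720))
  arr <- array(rep(as.numeric(coords), n_frames), c(n, 3, n_frames))
  cg_trajectory(topo, arr, matrix(box, n_frames, 3, byrow = TRUE), times)
}

# 16-bead cage on a unit sphere scaled to radius r (deterministic layout)
cage_coords <- function(center = c(0, 0, 0), radius = 0.35) {
  i <- seq_len(16)
  phi <- acos(1 - 2 * (i - 0.5) / 16)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(center[1] + radius * sin(phi) * cos(theta),
        center[2] + radius * sin(phi) * sin(theta),
        center[3] + radius * cos(phi))
}

# pair_distribution object built from an explicit g(r) curve
fake_pd <- function(r, g, mode = "plateau_normalized", plateau = c(2.5, 3.2)) {
  structure(tibble::tibble(r = r, g = g, count = round(g * 1000)),
            class = c("pair_distribution", "tbl_df", "tbl", "data.frame"),
            mode = mode, bin_width = r[2] - r[1], n_frames = 1,
            pair_count = sum(round(g * 1000)), plateau = plateau)
}

# free_energy_profile object from an explicit dG curve
fake_fep <- function(r, dG, temperature = 298) {
  structure(tibble::tibble(r = r, dG = dG, defined = !is.na(dG)),
            class = c("free_energy_profile", "tbl_df", "tbl", "data.frame"),
            temperature = temperature, mode = "plateau_normalized",
            reference = "synthetic", bin_width = r[2] - r[1])
}

# brute-force minimum distance over all 27 periodic images
brute_min_image <- function(a, b, box) {
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    d <- a - (b + c(ix, iy, iz) * box)
    best <- min(best, sqrt(sum(d^2)))
  }
  best
}

# O(N^2) reference clustering via adjacency + graph traversal (independent
# of the union-find implementation)
brute_cluster_membership <- function(coms, box, cutoff) {
  n <- nrow(coms)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    adj[i, j] <- adj[j, i] <-
      brute_min_image(coms[i, ], coms[j, ], box) < cutoff
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# canonical form of a partition (labels by first appearance)
canon_partition <- function(m) match(m, unique(m))

# rigid translation followed by wrapping into the box
pbc_shift <- function(x, shift, box) {
  y <- sweep(x, 2, shift, "+")
  y - floor(sweep(y, 2, box, "/")) * box
}

# head-density profile with peaks on one side only (no bilayer structure)
fake_profile_single_sided <- function() {
  structure(tibble::tibble(z = seq(-2, 2, 0.1), group = "lipid_head",
                           density = ifelse(seq(-2, 2, 0.1) > 0, 1, 0)),
            class = c("membrane_profile", "tbl_df", "tbl", "data.frame"),
            bin_width = 0.1, n_frames = 1, box_area = 1)
}
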