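#' Trajectory objects
#'
#' A `cg_trajectory` bundles a [bead_topology()] with an ordered set of
#' frames. Coordinates are held in a numeric array of dimension
#' `c(n_beads, 3, n_frames)` (nm), box dimensions in an `n_frames x 3`
#' matrix (orthorhombic, nm) and times in ns (strictly increasing).
#'
#' @param topology A [bead_topology()].
#' @param coords Numeric array `c(N, 3, F)` of positions in nm.
#' @param boxes Numeric `F x 3` matrix of box edges in nm (all > 0).
#' @param times Numeric vector of length `F`, strictly increasing, ns.
#' @param wrapped Logical flag: are coordinates wrapped into the primary box?
#' @return A `cg_trajectory` object.
#' @export
cg_trajectory <- function(topology, coords, boxes, times = NULL, wrapped = TRUE) {
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  n_frames <- dim(coords)[3]
  if (is.null(dim(boxes))) boxes <- matrix(boxes, nrow = n_frames, ncol = 3, byrow = TRUE)
  if (is.null(times)) times <- seq_len(n_frames) - 1
  if (dim(coords)[1] != nrow(topology)) {
    abort(sprintf("coordinate count (%d) does not match topology (%d beads)",
                  dim(coords)[1], nrow(topology)),
          class = "memlens_parse_error")
  }
  if (nrow(boxes) != n_frames || length(times) != n_frames) {
    abort("boxes/times length must equal the number of frames",
          class = "memlens_parse_error")
  }
  if (any(!is.finite(boxes)) || any(boxes <= 0)) {
    abort("box components must be finite and strictly positive",
          class = "memlens_parse_error")
  }
  if (n_frames > 1 && any(diff(times) <= 0)) {
    abort("frame times must be strictly increasing", class = "memlens_parse_error")
  }
  structure(list(topology = topology, coords = coords, boxes = boxes,
                 times = as.numeric(times), wrapped = isTRUE(wrapped)),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("<cg_trajectory> %d beads, %d frames, t = [%g, %g] ns\n",
              n_beads(x), n_frames(x), x$times[1], x$times[n_frames(x)]))
  comp <- topology_composition(x$topology)
  for (i in seq_len(nrow(comp))) {
    cat(sprintf("  %-6s %-14s %5d molecules x %g beads\n", comp$species[i],
                paste0("(", comp$group[i], ")"), comp$n_molecules[i],
                comp$beads_per_molecule[i]))
  }
  invisible(x)
}

#' @rdname cg_trajectory
#' @param traj A `cg_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname cg_trajectory
#' @export
n_beads <- function(traj) dim(traj$coords)[1]

#' @rdname cg_trajectory
#' @param i Frame index (1-based).
#' @export
frame_coords <- function(traj, i) traj$coords[, , i, drop = TRUE]

# trailing analysis window: keep the last `window_frac` of frames
window_frames <- function(traj, window_frac) {
  stopifnot(window_frac > 0, window_frac <= 1)
  nf <- n_frames(traj)
  from <- nf - floor(nf * window_frac) + 1L
  max(1L, from):nf
}

#' Tidy per-frame metadata
#'
#' @param traj A [cg_trajectory()].
#' @return A tibble with one row per frame: `frame`, `time`, `Lx`, `Ly`, `Lz`.
#' @export
frame_info <- function(traj) {
  tibble(frame = seq_len(n_frames(traj)), time = traj$times,
         Lx = traj$boxes[, 1], Ly = traj$boxes[, 2], Lz = traj$boxes[, 3])
}

#' Read a (multi-frame) GRO trajectory
#'
#' Parses the fixed-column GRO dialect: a title line (a `t=` tag, when
#' present, is read as the frame time in ns), an atom count, one line per
#' atom (`resid resname atomname atomid x y z` in columns 1-5, 6-10, 11-15,
#' 16-20 and three 8.3f fields) and a box line. Frames are concatenated.
#' Only orthorhombic boxes are accepted: a box line with nonzero
#' off-diagonal components is rejected.
#'
#' @param path Path to the GRO file.
#' @param topology_map Path to a YAML topology map (see
#'   [read_topology_map()]), or an already-parsed map list.
#' @param wrapped Are the coordinates wrapped (default `TRUE`)?
#' @return A [cg_trajectory()].
#' @export
read_trajectory <- function(path, topology_map, wrapped = TRUE) {
  map <- if (is.character(topology_map)) read_topology_map(topology_map) else topology_map
  lines <- readLines(path)
  i <- 1L
  n_total <- length(lines)
  frames <- list()
  boxes <- list()
  times <- c()
  topology <- NULL
  fidx <- 0L
  while (i <= n_total) {
    if (!nzchar(trimws(lines[i])) && i == n_total) break
    fidx <- fidx + 1L
    title <- lines[i]
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n) || n <= 0 || i + 1L + n + 1L > n_total) {
      abort(sprintf("malformed GRO frame %d (bad atom count line)", fidx),
            class = "memlens_parse_error")
    }
    atom_lines <- lines[(i + 2L):(i + 1L + n)]
    if (any(nchar(atom_lines) < 44)) {
      abort(sprintf("malformed GRO frame %d (short atom line)", fidx),
            class = "memlens_parse_error")
    }
    box_fields <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + 2L + n]),
                                                       "\\s+")[[1]]))
    if (length(box_fields) < 3 || any(is.na(box_fields[1:3])) ||
        any(box_fields[1:3] <= 0)) {
      abort(sprintf("malformed GRO frame %d (non-positive or missing box)", fidx),
            class = "memlens_parse_error")
    }
    if (length(box_fields) > 3 && any(abs(box_fields[-(1:3)]) > 1e-9)) {
      abort(sprintf("frame %d has a triclinic box; only orthorhombic boxes are supported",
                    fidx), class = "memlens_parse_error")
    }
    if (is.null(topology)) {
      resids <- as.integer(substr(atom_lines, 1, 5))
      resnames <- trimws(substr(atom_lines, 6, 10))
      atomnames <- trimws(substr(atom_lines, 11, 15))
      topology <- build_topology(resids, resnames, atomnames, map)
    } else if (n != nrow(topology)) {
      abort(sprintf("frame %d bead count (%d) differs from frame 1 (%d)",
                    fidx, n, nrow(topology)), class = "memlens_parse_error")
    }
    xyz <- cbind(as.numeric(substr(atom_lines, 21, 28)),
                 as.numeric(substr(atom_lines, 29, 36)),
                 as.numeric(substr(atom_lines, 37, 44)))
    if (any(!is.finite(xyz))) {
      abort(sprintf("malformed GRO frame %d (unparseable coordinates)", fidx),
            class = "memlens_parse_error")
    }
    tmatch <- regmatches(title, regexec("t=\\s*([-+0-9.eE]+)", title))[[1]]
    times <- c(times, if (length(tmatch) == 2) as.numeric(tmatch[2]) else NA_real_)
    frames[[fidx]] <- xyz
    boxes[[fidx]] <- box_fields[1:3]
    i <- i + n + 3L
    while (i <= n_total && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  if (fidx == 0L) abort("empty trajectory file", class = "memlens_parse_error")
  if (any(is.na(times)) || (fidx > 1 && any(diff(times) <= 0))) {
    times <- seq_len(fidx) - 1
  }
  coords <- array(unlist(frames), c(nrow(frames[[1]]), 3, fidx))
  cg_trajectory(topology, coords, do.call(rbind, boxes), times, wrapped = wrapped)
}

#' Write a trajectory in GRO format
#'
#' Coordinates are printed at the format's 0.001-nm precision; frames are
#' concatenated with `t=` tags on the title lines.
#'
#' @param traj A [cg_trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  topo <- traj$topology
  resid <- (topo$molecule_id + 1L) %% 100000L
  atomid <- (topo$bead_id + 1L) %% 100000L
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$coords[, , f, drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    writeLines(sprintf("memlens frame t= %.6f", traj$times[f]), con)
    writeLines(sprintf("%5d", n_beads(traj)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       resid, topo$species, topo$bead_name, atomid,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", traj$boxes[f, 1], traj$boxes[f, 2],
                       traj$boxes[f, 3]), con)
  }
  invisible(path)
}

#' Write the topology map matching a synthetic trajectory
#'
#' @param topology A [bead_topology()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_topology_map <- function(topology, path) {
  key <- paste0(topology$species, ":", topology$bead_name)
  first <- !duplicated(key)
  beads <- purrr::map2(topology$group[first], topology$mass[first],
                       function(g, m) list(group = g, mass = m))
  names(beads) <- key[first]
  yaml::write_yaml(list(beads = beads), path)
  invisible(path)
}
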