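#' Minimum-image displacement and distance
#'
#' Distances under periodic boundaries are measured to the nearest periodic
#' image (orthorhombic boxes only). `minimum_image_distance()` accepts single
#' positions or matrices of positions (row-wise pairing).
#'
#' @param a,b Numeric length-3 positions, or `n x 3` matrices, in nm.
#' @param box Numeric length-3 box edges in nm, all > 0.
#' @return Distance(s) in nm, each no larger than half the box diagonal.
#' @export
minimum_image_distance <- function(a, b, box) {
  stopifnot(all(box > 0), length(box) == 3)
  if (is.null(dim(a))) a <- matrix(a, ncol = 3)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3)
  d <- a - b
  d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
  sqrt(rowSums(d * d))
}

# displacement wrapped to [-L/2, L/2) per axis; d can be a matrix (cols = xyz)
min_image_disp <- function(d, box) {
  if (is.null(dim(d))) return(d - round(d / box) * box)
  d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
}

# wrap positions into [0, L)
pbc_wrap <- function(x, box) {
  if (is.null(dim(x))) return(x - floor(x / box) * box)
  x - sweep(floor(sweep(x, 2, box, "/")), 2, box, "*")
}

#' Center of mass, optionally under periodic boundaries
#'
#' With `pbc = TRUE` the center of mass is computed per axis by the circular
#' (angular) mean: each coordinate is mapped to an angle on a circle of
#' circumference equal to the box edge, the mass-weighted mean direction is
#' taken, and mapped back. Molecules split across the boundary therefore get
#' the physically correct center.
#'
#' @param coords `n x 3` matrix of bead positions (nm).
#' @param masses Length-n masses in amu, all > 0.
#' @param box Length-3 box (nm); required when `pbc = TRUE`.
#' @param pbc Use the circular-mean construction (default `FALSE`: plain
#'   mass-weighted mean).
#' @return Length-3 position in nm (wrapped into `[0, L)` when `pbc = TRUE`).
#' @export
center_of_mass <- function(coords, masses, box = NULL, pbc = FALSE) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3)
  if (nrow(coords) == 0) abort("empty selection", class = "memlens_selection_error")
  stopifnot(length(masses) == nrow(coords), all(masses > 0))
  if (!pbc) {
    return(colSums(coords * masses) / sum(masses))
  }
  stopifnot(!is.null(box), all(box > 0))
  theta <- sweep(coords, 2, 2 * pi / box, "*")
  cbar <- colSums(cos(theta) * masses)
  sbar <- colSums(sin(theta) * masses)
  ang <- atan2(sbar, cbar) %% (2 * pi)
  (ang / (2 * pi)) * box
}

#' Per-frame molecule centers of mass for a bead group
#'
#' Computes the mass-weighted center of each molecule that has at least one
#' bead in `group`, for every frame. Single-bead molecules take a fast path.
#'
#' @param traj A [cg_trajectory()].
#' @param group Bead group label (default `"fullerene"`).
#' @param pbc Use the circular-mean construction per molecule (default
#'   `TRUE`; correct for molecules split across the boundary).
#' @return A list with `coms` (array `n_molecules x 3 x n_frames`, nm) and
#'   `molecule_ids`.
#' @export
molecule_coms <- function(traj, group = "fullerene", pbc = TRUE) {
  topo <- traj$topology
  sel <- topo$group == group
  if (!any(sel)) {
    abort(paste0("no beads in group '", group, "'"), class = "memlens_selection_error")
  }
  mol_ids <- sort(unique(topo$molecule_id[sel]))
  bead_rows <- which(topo$molecule_id %in% mol_ids)
  mol_of <- match(topo$molecule_id[bead_rows], mol_ids)
  masses <- topo$mass[bead_rows]
  nf <- n_frames(traj)
  nm <- length(mol_ids)
  out <- array(NA_real_, c(nm, 3, nf))
  if (length(bead_rows) == nm) {
    # one bead per molecule: centers are the bead positions
    out <- traj$coords[bead_rows[order(mol_of)], , , drop = FALSE]
  } else {
    msum <- as.numeric(rowsum(masses, mol_of))
    for (f in seq_len(nf)) {
      xyz <- traj$coords[bead_rows, , f, drop = TRUE]
      box <- traj$boxes[f, ]
      if (pbc) {
        theta <- sweep(xyz, 2, 2 * pi / box, "*")
        cbar <- rowsum(cos(theta) * masses, mol_of)
        sbar <- rowsum(sin(theta) * masses, mol_of)
        ang <- atan2(sbar, cbar) %% (2 * pi)
        out[, , f] <- sweep(ang / (2 * pi), 2, box, "*")
      } else {
        out[, , f] <- rowsum(xyz * masses, mol_of) / msum
      }
    }
  }
  list(coms = out, molecule_ids = mol_ids)
}
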