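#' Bead topologies
#'
#' A bead topology maps every bead of a coarse-grained system to its molecule,
#' group label and mass. It is stored as a tibble with one row per bead and
#' columns:
#'
#' * `bead_id` — 0-based bead index (1-based only at file boundaries),
#' * `bead_name` — bead name as written in the coordinate file (e.g. `PO4`),
#' * `molecule_id` — 0-based molecule index, contiguous per species,
#' * `species` — molecule name (e.g. `DPPC`, `DOPC`, `F16`, `W`),
#' * `group` — one of `lipid_head`, `lipid_glycerol`, `lipid_tail`,
#'   `double_bond`, `fullerene`, `water`, `other`,
#' * `mass` — bead mass in amu, strictly positive.
#'
#' Groups are never inferred from bead names: an explicit topology map (see
#' [read_topology_map()]) assigns them, which keeps Martini-style naming
#' variations auditable.
#'
#' @param beads A data frame with the columns above (`bead_id` optional; it is
#'   regenerated as `0:(n-1)`).
#' @return A validated `bead_topology` tibble.
#' @export
bead_topology <- function(beads) {
  beads <- as_tibble(beads)
  required <- c("bead_name", "molecule_id", "species", "group", "mass")
  missing <- setdiff(required, names(beads))
  if (length(missing) > 0) {
    abort(paste0("topology is missing column(s): ", paste(missing, collapse = ", ")),
          class = "memlens_topology_error")
  }
  beads$bead_id <- seq_len(nrow(beads)) - 1L
  beads <- beads[, c("bead_id", "bead_name", "molecule_id", "species", "group", "mass")]
  validate_topology(beads)
  class(beads) <- c("bead_topology", class(beads))
  beads
}

validate_topology <- function(beads) {
  bad_group <- setdiff(unique(beads$group), GROUP_LEVELS)
  if (length(bad_group) > 0) {
    abort(paste0("unknown bead group(s): ", paste(bad_group, collapse = ", ")),
          class = "memlens_topology_error")
  }
  if (any(!is.finite(beads$mass)) || any(beads$mass <= 0)) {
    abort("bead masses must be finite and > 0", class = "memlens_topology_error")
  }
  # each molecule belongs to exactly one species
  sp_per_mol <- tapply(beads$species, beads$molecule_id, function(x) length(unique(x)))
  if (any(sp_per_mol != 1)) {
    abort("a molecule spans more than one species", class = "memlens_topology_error")
  }
  # molecule ids contiguous per species
  for (sp in unique(beads$species)) {
    ids <- sort(unique(beads$molecule_id[beads$species == sp]))
    if (length(ids) > 1 && any(diff(ids) != 1L)) {
      abort(paste0("molecule_ids of species ", sp, " are not contiguous"),
            class = "memlens_topology_error")
    }
  }
  # fullerene-group species must have a constant bead count per molecule;
  # the F16 model specifically has 16 beads per cage
  ful <- beads[beads$group == "fullerene", ]
  if (nrow(ful) > 0) {
    for (sp in unique(ful$species)) {
      counts <- table(beads$molecule_id[beads$species == sp])
      if (length(unique(as.integer(counts))) != 1) {
        abort(paste0("fullerene species ", sp, " has inconsistent bead counts"),
              class = "memlens_topology_error")
      }
      if (identical(sp, "F16") && as.integer(counts[1]) != 16L) {
        abort(paste0("species F16 must have 16 beads per molecule, found ",
                     counts[1]), class = "memlens_topology_error")
      }
    }
  }
  invisible(beads)
}

#' Read a topology map
#'
#' The map is a YAML file assigning each bead name a group and a mass
#' (species is taken from the residue name in the coordinate file):
#'
#' ```yaml
#' beads:
#'   PO4: {group: lipid_head, mass: 72}
#'   C1B: {group: lipid_tail, mass: 72}
#'   W:   {group: water, mass: 72}
#' ```
#'
#' An entry keyed `SPECIES:BEAD` (e.g. `DOPC:D2B`) takes precedence over a
#' plain bead-name entry, for bead names whose role differs between lipids.
#'
#' @param path Path to the YAML map.
#' @return A named list of `list(group =, mass =)` entries.
#' @export
read_topology_map <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$beads)) {
    abort("topology map must contain a top-level 'beads' mapping",
          class = "memlens_topology_error")
  }
  cfg$beads
}

# Build a bead_topology from parsed GRO columns + a topology map.
build_topology <- function(resids, resnames, atomnames, map) {
  n <- length(resids)
  group <- character(n)
  mass <- numeric(n)
  keys_specific <- paste0(resnames, ":", atomnames)
  for (i in seq_len(n)) {
    entry <- map[[keys_specific[i]]] %||% map[[atomnames[i]]]
    if (is.null(entry)) {
      abort(paste0("bead name '", atomnames[i], "' (residue ", resnames[i],
                   ") is not in the topology map; map it explicitly ",
                   "(group 'other' is allowed)"),
            class = "memlens_topology_error")
    }
    group[i] <- entry$group
    mass[i] <- entry$mass
  }
  # contiguous molecule ids from residue-id change points (GRO resids wrap at
  # 100000, so change points, not raw values, define molecules)
  changed <- c(TRUE, resids[-1] != resids[-n] | resnames[-1] != resnames[-n])
  molecule_id <- cumsum(changed) - 1L
  bead_topology(tibble(
    bead_name = atomnames, molecule_id = molecule_id,
    species = resnames, group = group, mass = mass
  ))
}

#' Count molecules per group or species
#'
#' @param topology A [bead_topology()] tibble.
#' @return A tibble with one row per species: species, group of its first
#'   bead, number of molecules and beads per molecule.
#' @export
topology_composition <- function(topology) {
  topology |>
    group_by(.data$species) |>
    summarise(
      group = .data$group[1],
      n_molecules = length(unique(.data$molecule_id)),
      beads_per_molecule = dplyr::n() / length(unique(.data$molecule_id)),
      .groups = "drop"
    )
}

n_molecules_of <- function(topology, groups) {
  length(unique(topology$molecule_id[topology$group %in% groups]))
}
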