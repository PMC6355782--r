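#' Cluster detection under a center-of-mass distance criterion
#'
#' Two particles belong to the same cluster when their minimum-image distance
#' is strictly below `cutoff` (default 1.30 nm, the standard fullerene
#' center-of-mass criterion); clusters are the connected components of the
#' resulting graph. Neighbour search uses a cell-list decomposition with cell
#' edge at least `cutoff` for larger systems and plain all-pairs for
#' `n < 64`; both give identical partitions.
#'
#' @param coms `n x 3` matrix of particle centers (nm).
#' @param box Length-3 box (nm).
#' @param cutoff Clustering distance in nm (default 1.30); must be below half
#'   the smallest box edge (minimum-image unambiguity).
#' @param method `"auto"` (cell list for `n >= 64`), `"cell"` or `"brute"`.
#' @return A `cluster_state` list: `membership` (integer cluster id per
#'   particle), `sizes`, `n_clusters`, `largest_size`, `fraction_in_largest`.
#' @export
find_clusters <- function(coms, box, cutoff = 1.30, method = c("auto", "cell", "brute")) {
  method <- match.arg(method)
  if (is.null(dim(coms))) coms <- matrix(coms, ncol = 3)
  n <- nrow(coms)
  if (n == 0) abort("no particles", class = "memlens_selection_error")
  stopifnot(cutoff > 0)
  if (cutoff >= min(box) / 2) {
    abort("cutoff must be below half the smallest box edge (minimum-image ambiguity)",
          class = "memlens_value_error")
  }
  pairs <- if (method == "brute" || (method == "auto" && n < 64)) {
    brute_pairs(coms, box, cutoff)
  } else {
    cell_list_pairs(coms, box, cutoff)
  }
  membership <- union_find(n, pairs)
  sizes <- as.integer(table(membership))
  largest <- max(sizes)
  structure(list(membership = membership, sizes = sizes,
                 n_clusters = length(sizes), largest_size = largest,
                 fraction_in_largest = largest / n, cutoff = cutoff),
            class = "cluster_state")
}

brute_pairs <- function(coms, box, cutoff) {
  n <- nrow(coms)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- minimum_image_distance(coms[idx[, 1], , drop = FALSE],
                              coms[idx[, 2], , drop = FALSE], box)
  idx[d < cutoff, , drop = FALSE]
}

cell_list_pairs <- function(coms, box, cutoff) {
  n <- nrow(coms)
  ncell <- pmax(1L, as.integer(floor(box / cutoff)))   # cell edge >= cutoff
  wrapped <- pbc_wrap(coms, box)
  ci <- sweep(wrapped, 2, box / ncell, "/")
  ci <- pmin(floor(ci), matrix(ncell - 1L, n, 3, byrow = TRUE))
  cell_id <- ci[, 1] + ncell[1] * (ci[, 2] + ncell[2] * ci[, 3])
  by_cell <- split(seq_len(n), cell_id)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  out_i <- integer(0); out_j <- integer(0)
  for (cell in names(by_cell)) {
    id <- as.numeric(cell)
    cx <- id %% ncell[1]
    cy <- (id %/% ncell[1]) %% ncell[2]
    cz <- id %/% (ncell[1] * ncell[2])
    members <- by_cell[[cell]]
    neigh_ids <- unique(((cx + offsets[, 1]) %% ncell[1]) +
                        ncell[1] * (((cy + offsets[, 2]) %% ncell[2]) +
                                    ncell[2] * ((cz + offsets[, 3]) %% ncell[3])))
    cand <- unlist(by_cell[as.character(neigh_ids)], use.names = FALSE)
    cand <- cand[cand > min(members) | cand %in% members]
    for (i in members) {
      js <- cand[cand > i]
      if (length(js) == 0) next
      d <- minimum_image_distance(matrix(wrapped[i, ], length(js), 3, byrow = TRUE),
                                  wrapped[js, , drop = FALSE], box)
      hit <- js[d < cutoff]
      out_i <- c(out_i, rep.int(i, length(hit))); out_j <- c(out_j, hit)
    }
  }
  cbind(out_i, out_j)
}

union_find <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Largest-cluster statistics over a trajectory
#'
#' Computes nanoparticle centers of mass per frame, clusters each frame under
#' the distance criterion, and reports the largest-cluster series. The
#' analysis window is a trailing fraction of the trajectory (default the last
#' half), the usual practice of analysing only the equilibrated tail.
#'
#' @param traj A [cg_trajectory()] containing fullerene-group molecules.
#' @param cutoff Clustering cutoff in nm (default 1.30).
#' @param window_frac Trailing fraction of frames to analyse (default 0.5).
#' @param group Bead group of the particles (default `"fullerene"`).
#' @return A tibble (`frame`, `time`, `largest_size`, `n_clusters`,
#'   `fraction_in_largest`) with `mean`/`sd` attributes on the largest size
#'   and a `mean_fraction` attribute; [glance()] summarises it.
#' @export
largest_cluster_series <- function(traj, cutoff = 1.30, window_frac = 0.5,
                                   group = "fullerene") {
  mc <- molecule_coms(traj, group = group)
  frames <- window_frames(traj, window_frac)
  res <- purrr::map(frames, function(f) {
    cs <- find_clusters(mc$coms[, , f, drop = TRUE], traj$boxes[f, ], cutoff)
    tibble(frame = f, time = traj$times[f], largest_size = cs$largest_size,
           n_clusters = cs$n_clusters,
           fraction_in_largest = cs$fraction_in_largest)
  }) |> bind_rows()
  out <- as_series(res, "largest_size", cutoff = cutoff)
  attr(out, "mean_fraction") <- mean(res$fraction_in_largest)
  out
}
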