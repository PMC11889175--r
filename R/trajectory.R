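#' Construct a trajectory ensemble
#'
#' A lightweight container for per-frame coordinates of a fixed atom
#' roster, plus named atom groups used by the analyses (cofactor markers,
#' gating residues, ion-pair atoms, Na+ ions). This is the reader contract
#' of the trajectory analyses: any source that can produce a
#' frames x atoms x 3 array can feed them.
#'
#' @param coords Numeric array of dimension `c(n_frames, n_atoms, 3)`.
#' @param atom_ids Character vector of atom identifiers (length n_atoms).
#' @param atom_groups Named list; each element is a vector of atom ids or
#'   indices defining a selection.
#' @param frame_interval Time per frame in arbitrary units (default 1).
#' @return An object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(coords, atom_ids, atom_groups = list(),
                                frame_interval = 1) {
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (dim(coords)[1] < 1L) stop("need at least one frame", call. = FALSE)
  if (length(atom_ids) != dim(coords)[2]) {
    stop("atom_ids length must match the atom dimension of coords",
         call. = FALSE)
  }
  groups <- lapply(atom_groups, function(g) {
    if (is.character(g)) {
      idx <- match(g, atom_ids)
      if (anyNA(idx)) stop("unknown atom id(s) in group: ",
                           paste(g[is.na(idx)], collapse = ", "),
                           call. = FALSE)
      idx
    } else as.integer(g)
  })
  structure(
    list(coords = coords, atom_ids = atom_ids, atom_groups = groups,
         frame_interval = frame_interval,
         n_frames = dim(coords)[1], n_atoms = dim(coords)[2]),
    class = "trajectory_ensemble"
  )
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("<trajectory_ensemble> %d frames x %d atoms; groups: %s\n",
              x$n_frames, x$n_atoms,
              paste(names(x$atom_groups), collapse = ", ")))
  invisible(x)
}

#' Read a columnar plain-text trajectory
#'
#' Reads the generator's columnar fixture format: a CSV with columns
#' `frame`, `atom_id`, `x`, `y`, `z` (frames numbered from 1, every atom
#' present in every frame).
#'
#' @param path CSV file path.
#' @param atom_groups Optional named group selections (see
#'   [trajectory_ensemble()]).
#' @param frame_interval Time per frame.
#' @return A `trajectory_ensemble`.
#' @export
read_trajectory_csv <- function(path, atom_groups = list(),
                                frame_interval = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "atom_id", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("trajectory CSV must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  frames <- sort(unique(df$frame))
  ids <- unique(df$atom_id[df$frame == frames[1]])
  n_f <- length(frames); n_a <- length(ids)
  coords <- array(NA_real_, c(n_f, n_a, 3))
  df <- df[order(match(df$frame, frames), match(df$atom_id, ids)), ]
  if (nrow(df) != n_f * n_a) {
    stop("atom roster is not constant across frames", call. = FALSE)
  }
  coords[, , 1] <- matrix(df$x, n_f, n_a, byrow = TRUE)
  coords[, , 2] <- matrix(df$y, n_f, n_a, byrow = TRUE)
  coords[, , 3] <- matrix(df$z, n_f, n_a, byrow = TRUE)
  trajectory_ensemble(coords, ids, atom_groups, frame_interval)
}

.resolve_group <- function(traj, group) {
  if (is.character(group) && length(group) == 1L &&
      group %in% names(traj$atom_groups)) {
    idx <- traj$atom_groups[[group]]
  } else if (is.character(group)) {
    idx <- match(group, traj$atom_ids)
  } else {
    idx <- as.integer(group)
  }
  if (length(idx) == 0L || anyNA(idx)) {
    stop("selection error: group '",
         paste(as.character(group), collapse = ","),
         "' resolves to no atoms", call. = FALSE)
  }
  idx
}

#' Per-frame distance between two atom groups
#'
#' @param traj A [trajectory_ensemble()].
#' @param group_a,group_b Group names (from the ensemble) or atom id /
#'   index vectors.
#' @param mode `"min"` (minimum pairwise distance) or `"centroid"`.
#' @return Numeric vector of per-frame distances (Angstrom).
#' @export
distance_series <- function(traj, group_a, group_b,
                            mode = c("min", "centroid")) {
  mode <- match.arg(mode)
  ia <- .resolve_group(traj, group_a)
  ib <- .resolve_group(traj, group_b)
  co <- traj$coords
  vapply(seq_len(traj$n_frames), function(f) {
    pa <- co[f, ia, , drop = FALSE][1, , , drop = TRUE]
    pb <- co[f, ib, , drop = FALSE][1, , , drop = TRUE]
    if (length(ia) == 1L) pa <- matrix(pa, 1L, 3L)
    if (length(ib) == 1L) pb <- matrix(pb, 1L, 3L)
    if (mode == "centroid") {
      sqrt(sum((colMeans(pa) - colMeans(pb))^2))
    } else {
      min(sqrt(outer(pa[, 1], pb[, 1], "-")^2 +
                 outer(pa[, 2], pb[, 2], "-")^2 +
                 outer(pa[, 3], pb[, 3], "-")^2))
    }
  }, numeric(1))
}

#' Centered rolling average with shrinking edge windows
#'
#' Centered moving mean of width `window`; near the edges the window
#' shrinks symmetrically so the output has the same length as the input.
#'
#' @param series Numeric vector.
#' @param window Window width in frames (>= 1, <= length of series).
#' @return Smoothed numeric vector, same length as `series`.
#' @examples
#' rolling_average(c(1, 2, 3, 4, 5), 3)  # 1.5 2 3 4 4.5
#' @export
rolling_average <- function(series, window) {
  n <- length(series)
  if (window < 1 || window > n) {
    stop("window must be between 1 and the series length", call. = FALSE)
  }
  half <- (window - 1) %/% 2
  hi_half <- window - 1 - half
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + hi_half)
    mean(series[lo:hi])
  }, numeric(1))
}

#' Define the gating pairs of the alternating-access classifier
#'
#' The complex gates access to the buried Na+ site with hydrophobic
#' residue pairs: an intracellular gate (open in the inward conformation)
#' and an extracellular gate (open in the outward conformation); both are
#' never open simultaneously, which prevents ion leaks.
#'
#' @param inward_pair,outward_pair Each a list/character vector of two
#'   group names (or selections) forming the intracellular and
#'   extracellular gate pairs.
#' @param open_A Distance at or above which a gate counts as open
#'   (default 9 Angstrom, side-chain heavy-atom minimum distance).
#' @param closed_A Distance at or below which a gate counts as closed
#'   (default 6 Angstrom). Must be < `open_A`; the band in between is
#'   assigned to the nearer threshold.
#' @return An object of class `gating_definition`.
#' @export
gating_definition <- function(inward_pair, outward_pair,
                              open_A = 9, closed_A = 6) {
  if (open_A <= closed_A) stop("open_A must exceed closed_A", call. = FALSE)
  structure(list(inward_pair = inward_pair, outward_pair = outward_pair,
                 open_A = open_A, closed_A = closed_A),
            class = "gating_definition")
}

#' Classify frames as inward, outward, or occluded
#'
#' Applies the alternating-access logic per frame: intracellular gate open
#' with extracellular gate closed is `inward`; the converse is `outward`;
#' both closed is `occluded`. Both gates open simultaneously would permit
#' a transmembrane leak and is flagged as `leak`, with a count attached as
#' an attribute. Classification is per-frame and therefore invariant to
#' frame order.
#'
#' @param traj A [trajectory_ensemble()].
#' @param gates A [gating_definition()].
#' @return Character vector of per-frame labels with attributes
#'   `leak_count` and `gate_distances` (2-column matrix).
#' @export
classify_conformations <- function(traj, gates) {
  stopifnot(inherits(gates, "gating_definition"))
  d_in <- distance_series(traj, gates$inward_pair[[1]],
                          gates$inward_pair[[2]], mode = "min")
  d_out <- distance_series(traj, gates$outward_pair[[1]],
                           gates$outward_pair[[2]], mode = "min")
  mid <- (gates$open_A + gates$closed_A) / 2
  open_in <- d_in >= mid
  open_out <- d_out >= mid
  labels <- ifelse(open_in & !open_out, "inward",
                   ifelse(!open_in & open_out, "outward",
                          ifelse(!open_in & !open_out, "occluded", "leak")))
  attr(labels, "leak_count") <- sum(labels == "leak")
  attr(labels, "gate_distances") <- cbind(inward_gate = d_in,
                                          outward_gate = d_out)
  labels
}

#' Ion-pair closed fraction per conformational class
#'
#' Fraction of frames in which the salt bridge is formed (minimum
#' cation-N to carboxylate-O distance at or below the cutoff), reported
#' separately per conformational class when labels are supplied.
#'
#' @param traj A [trajectory_ensemble()].
#' @param group_n,group_o Selections for the guanidinium nitrogens and the
#'   carboxylate oxygens.
#' @param cutoff_A Salt-bridge cutoff (default 4 Angstrom).
#' @param labels Optional per-frame class labels (e.g. from
#'   [classify_conformations()]); defaults to a single class `"all"`.
#' @return Named numeric vector of closed fractions per class. Classes
#'   with no frames are omitted (with a message).
#' @export
ion_pair_fraction <- function(traj, group_n, group_o, cutoff_A = 4.0,
                              labels = NULL) {
  d <- distance_series(traj, group_n, group_o, mode = "min")
  if (is.null(labels)) labels <- rep("all", traj$n_frames)
  stopifnot(length(labels) == traj$n_frames)
  classes <- unique(labels)
  out <- vapply(classes, function(cl) {
    mean(d[labels == cl] <= cutoff_A)
  }, numeric(1))
  names(out) <- classes
  out
}

#' Axial probability density of Na+ ions
#'
#' Histogram of ion z-offsets from a reference group centroid (the AE1
#' cluster for the RnfA/E axis), normalized so the density integrates to
#' one over the binned range. When per-frame class labels are given, a
#' profile is computed per class.
#'
#' @param traj A [trajectory_ensemble()].
#' @param ions Selection of ion atoms.
#' @param reference_group Selection whose per-frame centroid defines z = 0.
#' @param breaks Histogram breaks (vector) or bin count (scalar).
#' @param labels Optional per-frame class labels.
#' @param frames Optional frame subset.
#' @return A data frame of class `density_profile` with `z_mid`,
#'   `density`, and (when labels are given) `class`.
#' @export
sodium_axial_density <- function(traj, ions, reference_group, breaks = 30,
                                 labels = NULL, frames = NULL) {
  ii <- .resolve_group(traj, ions)
  ir <- .resolve_group(traj, reference_group)
  if (is.null(frames)) frames <- seq_len(traj$n_frames)
  ref_z <- vapply(frames, function(f) mean(traj$coords[f, ir, 3]),
                  numeric(1))
  offs <- lapply(seq_along(frames), function(k) {
    traj$coords[frames[k], ii, 3] - ref_z[k]
  })
  zmat <- do.call(rbind, offs)  # frames x ions

  one_profile <- function(z, cl = NA_character_) {
    if (length(z) == 0L) {
      warning("no ions in range; returning all-zero profile",
              call. = FALSE)
      z <- numeric(0)
    }
    h <- if (length(z) > 0L) {
      graphics::hist(z, breaks = breaks, plot = FALSE)
    } else {
      list(mids = seq(-1, 1, length.out = 10), density = rep(0, 10))
    }
    data.frame(z_mid = h$mids, density = h$density, class = cl,
               stringsAsFactors = FALSE)
  }
  if (is.null(labels)) {
    out <- one_profile(as.vector(zmat))
    out$class <- NULL
  } else {
    stopifnot(length(labels) == traj$n_frames)
    lab_sub <- labels[frames]
    out <- do.call(rbind, lapply(unique(lab_sub), function(cl) {
      one_profile(as.vector(zmat[lab_sub == cl, , drop = FALSE]), cl)
    }))
  }
  class(out) <- c("density_profile", "data.frame")
  out
}

#' 2D potential of mean force by Boltzmann inversion
#'
#' Bins sampled reaction-coordinate pairs into a 2D histogram, converts
#' the normalized probabilities to free energies
#' \eqn{F = -k_B T \ln p}, and shifts the minimum to zero. Empty bins are
#' reported as `NA` (undefined), never zero. For samples drawn from an
#' isotropic Gaussian of standard deviation sigma the recovered surface is
#' quadratic with curvature \eqn{k_B T / \sigma^2}.
#'
#' @param rc1,rc2 Numeric vectors of the two reaction coordinates (e.g.
#'   the TM4 inter-helix distance and the Na+ z-displacement).
#' @param temperature_K Temperature (default 310 K).
#' @param bins Number of bins per axis (default 25).
#' @return A list of class `pmf2d` with `x_mid`, `y_mid`, and matrix `F_kcal`.
#' @export
pmf_2d <- function(rc1, rc2, temperature_K = .DEFAULT_T_K, bins = 25) {
  stopifnot(length(rc1) == length(rc2), length(rc1) > 0)
  if (length(rc1) < bins * 10) {
    warning("fewer than bins*10 samples; PMF will be noisy", call. = FALSE)
  }
  bx <- seq(min(rc1), max(rc1), length.out = bins + 1)
  by <- seq(min(rc2), max(rc2), length.out = bins + 1)
  if (bx[1] == bx[length(bx)] || by[1] == by[length(by)]) {
    stop("degenerate surface: all samples fall in a single bin",
         call. = FALSE)
  }
  ix <- findInterval(rc1, bx, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(rc2, by, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0, bins, bins)
  for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1
  if (sum(counts > 0) == 1L) {
    stop("degenerate surface: all samples fall in a single bin",
         call. = FALSE)
  }
  p <- counts / sum(counts)
  rt <- .rt_kcal(temperature_K)
  F_mat <- -rt * log(p)
  F_mat[counts == 0] <- NA_real_
  F_mat <- F_mat - min(F_mat, na.rm = TRUE)
  structure(list(x_mid = (bx[-1] + bx[-length(bx)]) / 2,
                 y_mid = (by[-1] + by[-length(by)]) / 2,
                 F_kcal = F_mat, temperature_K = temperature_K),
            class = "pmf2d")
}

# vdW radii (Angstrom) for pathway voxelization
.VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, FE = 1.40, P = 1.80,
          "NA" = 2.27, H = 1.10)

#' Test ion-pathway continuity across a membrane slab
#'
#' Voxelizes the free space of a frame (voxels farther than
#' `probe + vdW` from every atom), flood-fills from the cytoplasmic face
#' of the declared slab, and reports whether the periplasmic face is
#' reached — i.e. whether a probe-sized ion can traverse the structure
#' continuously.
#'
#' @param atoms Data frame with `x`, `y`, `z` and optionally `elesy`
#'   (element; unknown elements use a carbon radius).
#' @param z_bounds Length-2 numeric: the membrane slab's cytoplasmic and
#'   periplasmic z limits.
#' @param probe_radius_A Probe radius (default 1.4 Angstrom).
#' @param grid_A Voxel edge (default 0.8; must not exceed the probe
#'   radius).
#' @param xy_pad_A Padding beyond the atom extent in x/y.
#' @return A list with `continuous` (logical), `path_voxels` (data frame
#'   of reachable free-voxel centers), and `n_free`.
#' @export
pathway_continuity <- function(atoms, z_bounds, probe_radius_A = 1.4,
                               grid_A = 0.8, xy_pad_A = 2) {
  if (grid_A > probe_radius_A) {
    stop("grid_A must not exceed probe_radius_A (pathway would be missed ",
         "between voxels)", call. = FALSE)
  }
  stopifnot(length(z_bounds) == 2L, z_bounds[1] < z_bounds[2])
  el <- if ("elesy" %in% names(atoms)) toupper(atoms$elesy)
        else rep("C", nrow(atoms))
  rad <- unname(.VDW[el])
  rad[is.na(rad)] <- .VDW[["C"]]
  r_occ <- rad + probe_radius_A

  xs <- seq(min(atoms$x) - xy_pad_A, max(atoms$x) + xy_pad_A, by = grid_A)
  ys <- seq(min(atoms$y) - xy_pad_A, max(atoms$y) + xy_pad_A, by = grid_A)
  zs <- seq(z_bounds[1], z_bounds[2], by = grid_A)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  occupied <- array(FALSE, c(nx, ny, nz))
  for (a in seq_len(nrow(atoms))) {
    r <- r_occ[a]
    xi <- which(abs(xs - atoms$x[a]) <= r)
    yi <- which(abs(ys - atoms$y[a]) <= r)
    zi <- which(abs(zs - atoms$z[a]) <= r)
    if (!length(xi) || !length(yi) || !length(zi)) next
    dx2 <- (xs[xi] - atoms$x[a])^2
    dy2 <- (ys[yi] - atoms$y[a])^2
    dz2 <- (zs[zi] - atoms$z[a])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    hit <- d2 <= r^2
    occupied[xi, yi, zi] <- occupied[xi, yi, zi] | hit
  }
  free <- !occupied
  # flood fill (6-connected BFS) from the cytoplasmic face (lowest z layer)
  reached <- array(FALSE, c(nx, ny, nz))
  seeds <- which(free[, , 1])
  if (length(seeds) == 0L) {
    return(list(continuous = FALSE,
                path_voxels = data.frame(x = numeric(), y = numeric(),
                                         z = numeric()),
                n_free = sum(free)))
  }
  idx <- arrayInd(seeds, c(nx, ny))
  queue <- cbind(idx, 1L)
  reached[cbind(queue[, 1], queue[, 2], queue[, 3])] <- TRUE
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  cur <- queue
  while (nrow(cur) > 0L) {
    nxt <- NULL
    for (s in seq_len(6L)) {
      cand <- cbind(cur[, 1] + shifts[s, 1], cur[, 2] + shifts[s, 2],
                    cur[, 3] + shifts[s, 3])
      ok <- cand[, 1] >= 1 & cand[, 1] <= nx &
        cand[, 2] >= 1 & cand[, 2] <= ny &
        cand[, 3] >= 1 & cand[, 3] <= nz
      cand <- cand[ok, , drop = FALSE]
      if (nrow(cand) == 0L) next
      keep <- free[cand] & !reached[cand]
      cand <- cand[keep, , drop = FALSE]
      if (nrow(cand) == 0L) next
      cand <- unique(cand)
      reached[cand] <- TRUE
      nxt <- rbind(nxt, cand)
    }
    cur <- if (is.null(nxt)) matrix(integer(), 0, 3) else nxt
  }
  continuous <- any(reached[, , nz])
  ri <- which(reached)
  vi <- arrayInd(ri, c(nx, ny, nz))
  list(continuous = continuous,
       path_voxels = data.frame(x = xs[vi[, 1]], y = ys[vi[, 2]],
                                z = zs[vi[, 3]]),
       n_free = sum(free))
}
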