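#' Configuration for the synthetic two-state trajectory generator
#'
#' Defines the statistical structure the trajectory analyses assume: a
#' two-conformation (inward/outward) Markov chain with state-dependent
#' B8-AE1 marker distances, state- and redox-conditional Na+ occupancy of
#' the buried site, an openable ion pair, and Gaussian positional noise.
#'
#' @param seed Integer seed; recorded in all outputs.
#' @param n_frames Number of frames (default 4000).
#' @param state_means_A Named means of the B8-AE1 distance per
#'   conformation (default inward 17, outward 24 Angstrom).
#' @param state_noise_A Gaussian sigma of the distance (default 0.8).
#' @param dwell_p Named per-frame persistence probabilities of the two
#'   conformations. Defaults c(inward = 0.97, outward = 0.955), giving a
#'   stationary inward fraction of 0.6.
#' @param ion_count Number of Na+ ions (>= 1; ion 1 is the tracked
#'   buried-site ion).
#' @param buried_site_occupancy 2x2 matrix of occupancy probabilities,
#'   rows = conformation (inward, outward), cols = AE1 redox state
#'   (reduced, oxidized). Default strongly favours the reduced state,
#'   emulating a binding site accessible only upon cluster reduction.
#' @param redox_reduced_p Per-frame probability that AE1 is reduced.
#' @param ion_pair_open_p Named per-conformation probability that the
#'   R67-E115 ion pair is open.
#' @param box_A Cubic solvent box edge for unbound ions (Angstrom).
#' @return A list of class `synthetic_traj_config`.
#' @export
synthetic_traj_config <- function(
    seed = 1L, n_frames = 4000L,
    state_means_A = c(inward = 17, outward = 24),
    state_noise_A = 0.8,
    dwell_p = c(inward = 0.97, outward = 0.955),
    ion_count = 4L,
    buried_site_occupancy = matrix(c(0.8, 0.2, 0.6, 0.15), 2, 2,
                                   byrow = TRUE,
                                   dimnames = list(c("inward", "outward"),
                                                   c("reduced",
                                                     "oxidized"))),
    redox_reduced_p = 0.5,
    ion_pair_open_p = c(inward = 0.1, outward = 0.8),
    box_A = 40) {
  stopifnot(all(dwell_p >= 0 & dwell_p <= 1),
            all(buried_site_occupancy >= 0 & buried_site_occupancy <= 1),
            all(ion_pair_open_p >= 0 & ion_pair_open_p <= 1),
            all(state_means_A > 0), n_frames >= 1, ion_count >= 1)
  structure(as.list(environment()), class = "synthetic_traj_config")
}

#' Generate a synthetic two-state trajectory with ground truth
#'
#' Produces a [trajectory_ensemble()] whose statistics follow the
#' configuration exactly: the conformation follows a two-state Markov
#' chain; B8 and AE1 marker atoms are placed so their distance is Gaussian
#' around the state mean; gating-residue pairs are open/closed according
#' to the conformation; the tracked Na+ occupies the buried site next to
#' AE1 with the configured conformation- and redox-conditional
#' probability, and is otherwise uniform in the solvent box; the ion-pair
#' atoms toggle between salt-bridge (3.0 Angstrom) and open (6.5
#' Angstrom) geometry. Per-frame ground-truth labels are returned and, if
#' requested, written to a manifest.
#'
#' @param config A [synthetic_traj_config()].
#' @param out_dir Optional directory; if given, writes `trajectory.csv`
#'   (columnar frame/atom_id/x/y/z), `topology.pdb`, and `manifest.json`.
#' @return A list with `ensemble` (a `trajectory_ensemble` with named
#'   groups), `truth` (per-frame data frame: `conformation`, `reduced`,
#'   `buried_occupied`, `ion_pair_open`, `b8_ae1_distance`), and `config`.
#' @export
make_two_state_trajectory <- function(config = synthetic_traj_config(),
                                      out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_traj_config"))
  cf <- config
  if (all(cf$dwell_p == 1) && cf$n_frames > 1L) {
    stop("dwell_p = 1 cannot produce a mixed-state trajectory",
         call. = FALSE)
  }
  set.seed(cf$seed)
  n <- cf$n_frames
  states <- c("inward", "outward")
  # stationary initial state: pi_in/pi_out = (1-p_out)/(1-p_in)
  w <- c(1 - cf$dwell_p[["outward"]], 1 - cf$dwell_p[["inward"]])
  conf <- character(n)
  conf[1] <- sample(states, 1, prob = w)
  if (n > 1) for (f in 2:n) {
    stay <- stats::runif(1) < cf$dwell_p[[conf[f - 1]]]
    conf[f] <- if (stay) conf[f - 1] else setdiff(states, conf[f - 1])
  }
  reduced <- stats::runif(n) < cf$redox_reduced_p
  occ_p <- cf$buried_site_occupancy[cbind(conf,
                                          ifelse(reduced, "reduced",
                                                 "oxidized"))]
  occupied <- stats::runif(n) < occ_p
  pair_open <- stats::runif(n) < cf$ion_pair_open_p[conf]
  d_b8 <- stats::rnorm(n, cf$state_means_A[conf], cf$state_noise_A)

  ids <- c("AE1_FE1", "B8_FE1",
           "GATE_IN_A", "GATE_IN_B", "GATE_OUT_A", "GATE_OUT_B",
           "ARG_NH1", "GLU_OE1",
           paste0("NA_", seq_len(cf$ion_count)))
  n_at <- length(ids)
  coords <- array(0, c(n, n_at, 3))
  half <- cf$box_A / 2
  gate_open_d <- 11; gate_closed_d <- 4; gate_sd <- 0.5
  buried_site <- c(0.5, 0.5, 0)
  for (f in seq_len(n)) {
    xyz <- matrix(0, n_at, 3)
    xyz[1, ] <- c(0, 0, 0)                      # AE1 reference
    xyz[2, ] <- c(0, 0, d_b8[f])                # B8 marker
    din <- stats::rnorm(1, if (conf[f] == "inward") gate_open_d
                           else gate_closed_d, gate_sd)
    dout <- stats::rnorm(1, if (conf[f] == "outward") gate_open_d
                            else gate_closed_d, gate_sd)
    xyz[3, ] <- c(5, 5, 8);  xyz[4, ] <- c(5 + din, 5, 8)
    xyz[5, ] <- c(5, 5, -8); xyz[6, ] <- c(5 + dout, 5, -8)
    dpair <- if (pair_open[f]) 6.5 else 3.0
    xyz[7, ] <- c(-8, 8, 0); xyz[8, ] <- c(-8 + dpair, 8, 0)
    for (k in seq_len(cf$ion_count)) {
      if (k == 1L && occupied[f]) {
        xyz[8 + k, ] <- buried_site + stats::rnorm(3, 0, 0.3)
      } else {
        # bulk ions stay clear of the buried site so site occupancy can be
        # read back from the coordinates alone
        repeat {
          pos <- stats::runif(3, -half, half)
          if (sqrt(sum((pos - buried_site)^2)) > 3) break
        }
        xyz[8 + k, ] <- pos
      }
    }
    coords[f, , ] <- xyz
  }
  groups <- list(
    AE1 = "AE1_FE1", B8 = "B8_FE1",
    gate_in_a = "GATE_IN_A", gate_in_b = "GATE_IN_B",
    gate_out_a = "GATE_OUT_A", gate_out_b = "GATE_OUT_B",
    ion_pair_N = "ARG_NH1", ion_pair_O = "GLU_OE1",
    na_ions = paste0("NA_", seq_len(cf$ion_count)),
    na_tracked = "NA_1"
  )
  ens <- trajectory_ensemble(coords, ids, groups)
  truth <- data.frame(frame = seq_len(n), conformation = conf,
                      reduced = reduced, buried_occupied = occupied,
                      ion_pair_open = pair_open, b8_ae1_distance = d_b8,
                      stringsAsFactors = FALSE)
  res <- list(ensemble = ens, truth = truth, config = cf)
  if (!is.null(out_dir)) .write_trajectory_fixture(res, out_dir)
  res
}

.write_trajectory_fixture <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ens <- res$ensemble
  n <- ens$n_frames; na <- ens$n_atoms
  df <- data.frame(
    frame = rep(seq_len(n), each = na),
    atom_id = rep(ens$atom_ids, times = n),
    x = sprintf("%.4f", as.vector(t(ens$coords[, , 1]))),
    y = sprintf("%.4f", as.vector(t(ens$coords[, , 2]))),
    z = sprintf("%.4f", as.vector(t(ens$coords[, , 3]))),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, file.path(out_dir, "trajectory.csv"),
                   row.names = FALSE, quote = FALSE)
  # minimal topology: first frame as a PDB
  at <- data.frame(record = "HETATM", chain = "X",
                   resid = substr(ens$atom_ids, 1, 3),
                   resno = seq_len(na), elety = ens$atom_ids,
                   elesy = ifelse(grepl("^NA_", ens$atom_ids), "NA",
                                  ifelse(grepl("FE", ens$atom_ids), "FE",
                                         "C")),
                   x = ens$coords[1, , 1], y = ens$coords[1, , 2],
                   z = ens$coords[1, , 3], stringsAsFactors = FALSE)
  .write_pdb_table(at, file.path(out_dir, "topology.pdb"))
  manifest <- list(
    generator = "make_two_state_trajectory",
    seed = res$config$seed,
    config = res$config[setdiff(names(res$config),
                                "buried_site_occupancy")],
    buried_site_occupancy = as.data.frame(res$config$buried_site_occupancy),
    atom_ids = ens$atom_ids,
    groups = lapply(ens$atom_groups, function(i) ens$atom_ids[i]),
    truth = res$truth
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# fixed-width PDB writer for generated fixtures
.write_pdb_table <- function(at, path) {
  lines <- sprintf(
    "%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    at$record, seq_len(nrow(at)), substr(at$elety, 1, 4), at$resid,
    at$chain, at$resno, at$x, at$y, at$z, 1.00, 0.00, at$elesy
  )
  writeLines(c(lines, "END"), path)
}

#' Configuration for the toy-complex writer
#'
#' @param seed Integer seed (recorded in the manifest; placement itself is
#'   deterministic).
#' @param bore Logical: drill an open channel through the membrane slab.
#' @param bore_radius_A Channel radius (default 5; a 2.5 Angstrom bore is
#'   narrower than a hydrated-ion probe and reads as sealed).
#' @param slab_spacing_A Grid spacing of the membrane-slab atoms.
#' @param slab_half_xy_A,slab_half_z_A Slab half-extents.
#' @param chain_spacing_A Center-to-center spacing of the cofactor chain.
#' @param ion_pair_closed Logical: write the R67-E115 pair salt-bridged
#'   (3 Angstrom) or open (6.5 Angstrom).
#' @return A list of class `toy_complex_config`.
#' @export
toy_complex_config <- function(seed = 1L, bore = TRUE, bore_radius_A = 5,
                               slab_spacing_A = 2, slab_half_xy_A = 12,
                               slab_half_z_A = 9, chain_spacing_A = 12,
                               ion_pair_closed = TRUE) {
  structure(as.list(environment()), class = "toy_complex_config")
}

# local geometry of one [4Fe4S] cubane, centered at the origin
.sf4_atoms <- function() {
  a <- 1.91
  fe <- rbind(c(0, 0, 0), c(a, a, 0), c(a, 0, a), c(0, a, a))
  s <- rbind(c(a, 0, 0), c(0, a, 0), c(0, 0, a), c(a, a, a))
  xyz <- rbind(fe, s)
  xyz <- sweep(xyz, 2, c(a / 2, a / 2, a / 2))
  data.frame(elety = c(paste0("FE", 1:4), paste0("S", 1:4)),
             elesy = c(rep("FE", 4), rep("S", 4)),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

.fes_atoms <- function() {
  data.frame(elety = c("FE1", "FE2", "S1", "S2"),
             elesy = c("FE", "FE", "S", "S"),
             x = c(-1.35, 1.35, 0, 0), y = c(0, 0, 1.1, -1.1),
             z = c(0, 0, 0, 0), stringsAsFactors = FALSE)
}

# simplified flavin: isoalloxazine-core names plus two ribityl atoms so the
# all-heavy and conjugated-only conventions differ
.flavin_atoms <- function() {
  ring <- data.frame(
    elety = c("N1", "C2", "O2", "N3", "C4", "O4", "C4A", "N5", "N10",
              "C10"),
    elesy = c("N", "C", "O", "N", "C", "O", "C", "N", "N", "C"),
    x = c(0, 1.2, 2.4, 1.2, 0, 0, -1.2, -2.4, -1.2, 0),
    y = c(1.4, 0.7, 1.4, -0.7, -1.4, -2.8, -0.7, -1.4, 0.7, 0),
    z = 0, stringsAsFactors = FALSE)
  tail <- data.frame(elety = c("C1'", "O2'"), elesy = c("C", "O"),
                     x = c(-1.2, -2.4), y = c(2.1, 2.8), z = c(0.5, 1.0),
                     stringsAsFactors = FALSE)
  rbind(ring, tail)
}

#' Write a toy Rnf-like complex as a PDB fixture
#'
#' Builds a minimal complex carrying the full cofactor inventory — eight
#' [4Fe4S] clusters in chain B, two in chain C, the AE1 [2Fe2S] at the
#' A/E interface, three FMN and one riboflavin — arranged as a linear
#' chain at a configurable center spacing, with four cysteines ligating
#' the [2Fe2S] at 2.3 Angstrom, the R67-E115 ion pair, the four gating
#' leucines, and a membrane-spanning atom slab with an optional bore. A
#' JSON manifest of ground-truth counts and positions is written
#' alongside.
#'
#' @param config A [toy_complex_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `pdb_path`, `manifest_path`, and the
#'   manifest itself.
#' @export
make_toy_complex <- function(config = toy_complex_config(),
                             out_dir = tempfile("toycomplex")) {
  stopifnot(inherits(config, "toy_complex_config"))
  cf <- config
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # cofactor chain along +x, well clear of the membrane slab in y
  sp <- cf$chain_spacing_A
  origin <- c(0, 60, 0)
  chain_def <- list(
    list(chain = "B", resid = "SF4", resno = 201), # B1..B8
    list(chain = "B", resid = "SF4", resno = 202),
    list(chain = "B", resid = "SF4", resno = 203),
    list(chain = "B", resid = "SF4", resno = 204),
    list(chain = "B", resid = "SF4", resno = 205),
    list(chain = "B", resid = "SF4", resno = 206),
    list(chain = "B", resid = "SF4", resno = 207),
    list(chain = "B", resid = "SF4", resno = 208), # B8
    list(chain = "A", resid = "FES", resno = 150), # AE1
    list(chain = "G", resid = "FMN", resno = 510),
    list(chain = "D", resid = "RBF", resno = 420),
    list(chain = "D", resid = "FMN", resno = 410),
    list(chain = "C", resid = "SF4", resno = 301), # C1
    list(chain = "C", resid = "SF4", resno = 302), # C2
    list(chain = "C", resid = "FMN", resno = 310)
  )
  rows <- list()
  centers <- list()
  for (i in seq_along(chain_def)) {
    cd <- chain_def[[i]]
    center <- origin + c((i - 1) * sp, 0, 0)
    local <- switch(cd$resid, SF4 = .sf4_atoms(), FES = .fes_atoms(),
                    .flavin_atoms())
    local$x <- local$x + center[1]
    local$y <- local$y + center[2]
    local$z <- local$z + center[3]
    local$record <- "HETATM"; local$chain <- cd$chain
    local$resid <- cd$resid; local$resno <- cd$resno
    rows[[length(rows) + 1]] <- local
    centers[[paste(cd$chain, cd$resid, cd$resno, sep = "_")]] <- center
  }

  # four cysteines ligating AE1 (SG at 2.3 A from an Fe, CB further out)
  ae1_center <- centers[["A_FES_150"]]
  fe1 <- ae1_center + c(-1.35, 0, 0)
  fe2 <- ae1_center + c(1.35, 0, 0)
  cys_def <- list(list(chain = "A", resno = 25, fe = fe1, dirn = c(0, 0, 1)),
                  list(chain = "A", resno = 113, fe = fe1,
                       dirn = c(0, 0, -1)),
                  list(chain = "E", resno = 25, fe = fe2, dirn = c(0, 0, 1)),
                  list(chain = "E", resno = 108, fe = fe2,
                       dirn = c(0, 0, -1)))
  for (cd in cys_def) {
    sg <- cd$fe + 2.3 * cd$dirn
    cb <- cd$fe + 4.1 * cd$dirn
    rows[[length(rows) + 1]] <- data.frame(
      elety = c("SG", "CB"), elesy = c("S", "C"),
      x = c(sg[1], cb[1]), y = c(sg[2], cb[2]), z = c(sg[3], cb[3]),
      record = "ATOM", chain = cd$chain, resid = "CYS", resno = cd$resno,
      stringsAsFactors = FALSE)
  }

  # R67-E115 ion pair (chain E), off to the side
  dpair <- if (cf$ion_pair_closed) 3.0 else 6.5
  rows[[length(rows) + 1]] <- data.frame(
    elety = c("NH1", "NH2", "NE"), elesy = "N",
    x = c(-30, -30.8, -29.2), y = c(-20, -20.8, -20.8), z = c(0, 0.4, 0.4),
    record = "ATOM", chain = "E", resid = "ARG", resno = 67,
    stringsAsFactors = FALSE)
  rows[[length(rows) + 1]] <- data.frame(
    elety = c("OE1", "OE2"), elesy = "O",
    x = c(-30 + dpair, -30 + dpair + 0.8), y = c(-20, -20.6),
    z = c(0, 0.3),
    record = "ATOM", chain = "E", resid = "GLU", resno = 115,
    stringsAsFactors = FALSE)

  # gating leucines (CD1 atoms): intracellular pair near z = +10,
  # extracellular pair near z = -10, beside the slab
  gate_def <- list(
    list(chain = "A", resno = 108, pos = c(20, -20, 10)),
    list(chain = "E", resno = 22, pos = c(24, -20, 10)),
    list(chain = "E", resno = 103, pos = c(20, -20, -10)),
    list(chain = "A", resno = 22, pos = c(24, -20, -10)))
  for (gd in gate_def) {
    rows[[length(rows) + 1]] <- data.frame(
      elety = "CD1", elesy = "C",
      x = gd$pos[1], y = gd$pos[2], z = gd$pos[3],
      record = "ATOM", chain = gd$chain, resid = "LEU", resno = gd$resno,
      stringsAsFactors = FALSE)
  }

  # membrane slab (chain M) with optional axial bore at x = y = 0
  gxy <- seq(-cf$slab_half_xy_A, cf$slab_half_xy_A, by = cf$slab_spacing_A)
  gz <- seq(-cf$slab_half_z_A, cf$slab_half_z_A, by = cf$slab_spacing_A)
  slab <- expand.grid(x = gxy, y = gxy, z = gz)
  if (cf$bore) {
    slab <- slab[sqrt(slab$x^2 + slab$y^2) >= cf$bore_radius_A, ,
                 drop = FALSE]
  }
  rows[[length(rows) + 1]] <- data.frame(
    elety = "C", elesy = "C", x = slab$x, y = slab$y, z = slab$z,
    record = "HETATM", chain = "M", resid = "MEM",
    resno = 900, stringsAsFactors = FALSE)

  at <- do.call(rbind, lapply(rows, function(r) {
    r[, c("record", "chain", "resid", "resno", "elety", "elesy",
          "x", "y", "z")]
  }))
  if (min(dist(at[at$record == "ATOM", c("x", "y", "z")])) < 0.5) {
    stop("generation error: overlapping atom placements", call. = FALSE)
  }
  pdb_path <- file.path(out_dir, "toy_complex.pdb")
  .write_pdb_table(at, pdb_path)

  manifest <- list(
    generator = "make_toy_complex", seed = cf$seed,
    config = unclass(cf),
    counts = list(SF4 = 10, FES = 1, FMN = 3, RBF = 1,
                  cofactors = 15, iron_total = 42,
                  n_atoms = nrow(at), n_slab_atoms = nrow(slab)),
    chain_order = names(centers),
    cofactor_centers = centers,
    ligating_residues = c("A 25", "A 113", "E 25", "E 108"),
    slab_z_bounds = c(-cf$slab_half_z_A, cf$slab_half_z_A),
    bore = cf$bore, bore_radius_A = cf$bore_radius_A,
    ion_pair_closed = cf$ion_pair_closed
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(pdb_path = pdb_path, manifest_path = manifest_path,
                 manifest = manifest))
}

#' Pump-cycle parameter presets
#'
#' Emits a complete, closure-consistent parameter set for
#' [build_canonical_cycle()]. The `"default"` preset uses the
#' printed midpoint potentials (Fd -450 mV, NAD+ -320 mV), barriers
#' (+4/+10 kcal/mol), and Na+ binding free energies (-1/-3 kcal/mol); the
#' `"fd-low"` preset moves the ferredoxin potential to the low end of its
#' physiological range (-500 mV), which raises the break-even SMF to
#' 180 mV; `"custom"` passes overrides through [cycle_params()].
#'
#' @param preset `"default"`, `"fd-low"`, or `"custom"`.
#' @param ... Overrides forwarded to [cycle_params()] (used by
#'   `"custom"`).
#' @param file Optional path; if given, the parameter set is written as
#'   JSON.
#' @return A [cycle_params()] object (invisibly also written to `file`).
#' @export
make_cycle_params <- function(preset = c("default", "fd-low",
                                         "custom"),
                              ..., file = NULL) {
  preset <- match.arg(preset)
  params <- switch(preset,
    "default" = cycle_params(),
    "fd-low" = cycle_params(fd_mV = -500),
    "custom" = cycle_params(...)
  )
  # validate closure by constructing the model
  model <- build_canonical_cycle(params)
  resid <- cycle_closure_check(model)
  if (!is.null(file)) {
    out <- unclass(params)
    out$preset <- preset
    out$closure_residual_kcal <- resid
    jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  params
}
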