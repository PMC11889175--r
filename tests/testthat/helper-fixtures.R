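# shared fixtures, built in code once per test run

the <- new.env()

toy_complex_cached <- function() {
  if (is.null(the$toy)) {
    dir <- file.path(tempdir(), "rnfpump-toy")
    the$toy <- make_toy_complex(out_dir = dir)
    the$toy_atoms <- load_structure(the$toy$pdb_path)
    the$toy_net <- cofactor_network(the$toy_atoms)
  }
  list(gen = the$toy, atoms = the$toy_atoms, net = the$toy_net)
}

traj_cached <- function() {
  if (is.null(the$traj)) {
    the$traj <- make_two_state_trajectory(
      synthetic_traj_config(seed = 7, n_frames = 5000))
  }
  the$traj
}

# a cofactor_network stub around a given distance matrix, for path tests
fake_network <- function(D) {
  ids <- rownames(D)
  cofs <- lapply(ids, function(id) {
    structure(list(id = id, kind = "SF4",
                   atoms = data.frame(elety = "FE1", elesy = "FE",
                                      x = 0, y = 0, z = 0),
                   iron_atoms = 4L),
              class = "cofactor_record")
  })
  structure(list(cofactors = cofs, edges = D, ligands = list(),
                 atoms = data.frame(), edge_convention = "all-heavy"),
            class = "cofactor_network")
}

# exhaustive minimal-distance simple-path oracle (<= 8 nodes)
enumerate_best_path <- function(D, start, end, ceiling_A) {
  ids <- rownames(D)
  others <- setdiff(ids, c(start, end))
  best <- NULL
  consider <- function(path) {
    v <- c(start, path, end)
    steps <- cbind(v[-length(v)], v[-1])
    if (any(D[steps] >= ceiling_A)) return()
    tot <- sum(D[steps])
    key <- paste(v, collapse = "|")
    cand <- list(ids = v, dist = tot, hops = length(v) - 1L, key = key)
    if (is.null(best) ||
        tot < best$dist - 1e-12 ||
        (abs(tot - best$dist) <= 1e-12 && (cand$hops < best$hops ||
          (cand$hops == best$hops && key < best$key)))) {
      best <<- cand
    }
  }
  consider(character())
  for (k in seq_along(others)) {
    combos <- utils::combn(others, k, simplify = FALSE)
    for (cmb in combos) {
      perms <- permutations_of(cmb)
      for (pp in perms) consider(pp)
    }
  }
  best
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}
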