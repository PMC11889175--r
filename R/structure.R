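#' Load a macromolecular structure as an atom table
#'
#' Reads a PDB or mmCIF coordinate file (via bio3d) into a plain atom data
#' frame with one row per atom. Author residue numbering and insertion
#' codes are retained as-is; coordinates are in Angstrom.
#'
#' @param path Path to the coordinate file.
#' @param format `"PDB"`, `"mmCIF"`, or `"auto"` (by file extension).
#' @return A data frame with columns `record` (ATOM/HETATM), `chain`,
#'   `resid` (residue name), `resno`, `insert`, `elety` (atom name),
#'   `elesy` (element symbol), `x`, `y`, `z`.
#' @export
load_structure <- function(path, format = c("auto", "PDB", "mmCIF")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmCIF"
              else "PDB"
  }
  obj <- tryCatch(
    if (format == "PDB") bio3d::read.pdb(path, verbose = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) {
      stop("failed to parse ", format, " file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  a <- obj$atom
  if (is.null(a) || nrow(a) == 0L) {
    stop("no atoms parsed from '", path, "'", call. = FALSE)
  }
  elesy <- a$elesy
  if (is.null(elesy) || all(is.na(elesy)) || all(elesy == "")) {
    elesy <- .element_from_name(a$elety)
  } else {
    miss <- is.na(elesy) | elesy == ""
    elesy[miss] <- .element_from_name(a$elety[miss])
  }
  data.frame(record = a$type, chain = a$chain, resid = a$resid,
             resno = a$resno,
             insert = if (is.null(a$insert)) NA_character_ else a$insert,
             elety = a$elety, elesy = toupper(elesy),
             x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
}

# crude element inference from the atom name (fallback when the element
# column is absent): two-letter metals first, else the first letter.
.element_from_name <- function(elety) {
  nm <- toupper(trimws(elety))
  two <- substr(nm, 1, 2)
  el <- substr(gsub("[^A-Z]", "", nm), 1, 1)
  el[two == "FE"] <- "FE"
  el[two == "NA" & nchar(nm) == 2] <- "NA"
  el[two == "MG"] <- "MG"
  el[two == "ZN"] <- "ZN"
  el
}

.COFACTOR_KINDS <- c("SF4", "FES", "FMN", "RBF", "NAD")
.IRON_PER_KIND <- c(SF4 = 4L, FES = 2L, FMN = 0L, RBF = 0L, NAD = 0L)

#' Detect redox cofactors in an atom table
#'
#' Groups HETATM residues with recognised cofactor codes — SF4 ([4Fe4S]
#' cluster), FES ([2Fe2S] cluster), FMN (flavin mononucleotide), RBF
#' (riboflavin), NAD — into cofactor records, counting iron atoms per
#' record. Unrecognised iron-containing HETATM residues are kept with kind
#' `"unknown"` and a warning.
#'
#' @param atoms Atom table from [load_structure()].
#' @return A list of `cofactor_record` objects, each with `id`
#'   (chain_resid_resno), `kind`, `atoms` (data frame), `iron_atoms`.
#' @export
detect_cofactors <- function(atoms) {
  het <- atoms[atoms$record == "HETATM", , drop = FALSE]
  if (nrow(het) == 0L) return(list())
  key <- paste(het$chain, het$resid, het$resno, sep = "_")
  out <- list()
  for (k in unique(key)) {
    sub <- het[key == k, , drop = FALSE]
    kind <- sub$resid[1]
    n_fe <- sum(sub$elesy == "FE")
    if (!(kind %in% .COFACTOR_KINDS)) {
      if (n_fe > 0L) {
        warning("unknown Fe-containing residue code '", kind,
                "' at ", k, "; kept with kind 'unknown'", call. = FALSE)
        kind <- "unknown"
      } else {
        next
      }
    }
    out[[k]] <- structure(
      list(id = k, kind = kind, atoms = sub, iron_atoms = n_fe),
      class = "cofactor_record"
    )
  }
  unname(out)
}

#' Build the cofactor network of a structure
#'
#' Detects cofactors, computes all pairwise edge-to-edge distances, and
#' records the coordinating residues of each FeS cluster.
#'
#' @param atoms Atom table from [load_structure()].
#' @param edge_convention `"all-heavy"` (default; the common
#'   tunneling-distance convention) or `"conjugated-only"` (isoalloxazine
#'   ring for flavins, Fe+S core for clusters).
#' @param ligand_cutoff_A Fe-to-donor-atom cutoff for ligand detection
#'   (Angstrom, default 2.6).
#' @return An object of class `cofactor_network` with `cofactors`, `edges`
#'   (symmetric distance matrix, Angstrom), `ligands` (per FeS cluster),
#'   and the source `atoms`.
#' @export
cofactor_network <- function(atoms,
                             edge_convention = c("all-heavy",
                                                 "conjugated-only"),
                             ligand_cutoff_A = 2.6) {
  edge_convention <- match.arg(edge_convention)
  cofs <- detect_cofactors(atoms)
  n <- length(cofs)
  ids <- vapply(cofs, `[[`, "", "id")
  edges <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d <- edge_to_edge_distance(cofs[[i]], cofs[[j]], edge_convention)
      edges[i, j] <- edges[j, i] <- d
    }
  }
  net <- structure(
    list(cofactors = cofs, edges = edges, ligands = list(), atoms = atoms,
         edge_convention = edge_convention),
    class = "cofactor_network"
  )
  fes_ids <- ids[vapply(cofs, function(co) co$iron_atoms > 0L, TRUE)]
  net$ligands <- stats::setNames(
    lapply(fes_ids, function(id) cluster_ligands(net, id, ligand_cutoff_A)),
    fes_ids
  )
  net
}

#' @export
print.cofactor_network <- function(x, ...) {
  kinds <- table(vapply(x$cofactors, `[[`, "", "kind"))
  cat(sprintf("<cofactor_network> %d cofactors (%s), %d Fe total\n",
              length(x$cofactors),
              paste(names(kinds), kinds, sep = ":", collapse = ", "),
              iron_inventory(x)))
  invisible(x)
}

#' Coordinating residues of an FeS cluster
#'
#' Returns the protein residues offering a sulfur (or O/N) donor atom
#' within `cutoff_A` of any iron atom of the named cluster, sorted by
#' chain then residue number. More than four coordinating residues
#' triggers an over-ligation warning.
#'
#' @param network A [cofactor_network()].
#' @param cluster_id Cofactor id (e.g. `"A_FES_200"`).
#' @param cutoff_A Distance cutoff in Angstrom (default 2.6, a typical
#'   Fe-S(cysteinate) bond plus slack).
#' @return Data frame with `chain`, `resid`, `resno`, `atom`,
#'   `distance_A` (one row per coordinating residue, closest donor atom).
#' @export
cluster_ligands <- function(network, cluster_id, cutoff_A = 2.6) {
  stopifnot(inherits(network, "cofactor_network"))
  ids <- vapply(network$cofactors, `[[`, "", "id")
  hit <- match(cluster_id, ids)
  if (is.na(hit)) stop("no cofactor with id '", cluster_id, "'",
                       call. = FALSE)
  co <- network$cofactors[[hit]]
  fe <- co$atoms[co$atoms$elesy == "FE", , drop = FALSE]
  if (nrow(fe) == 0L) stop("cofactor '", cluster_id, "' has no iron atoms",
                           call. = FALSE)
  prot <- network$atoms[network$atoms$record == "ATOM" &
                          network$atoms$elesy %in% c("S", "O", "N"), ,
                        drop = FALSE]
  if (nrow(prot) == 0L) return(.empty_ligands())
  dmin <- apply(as.matrix(prot[, c("x", "y", "z")]), 1L, function(v) {
    min(sqrt((fe$x - v[1])^2 + (fe$y - v[2])^2 + (fe$z - v[3])^2))
  })
  prot <- prot[dmin <= cutoff_A, , drop = FALSE]
  dmin <- dmin[dmin <= cutoff_A]
  if (nrow(prot) == 0L) return(.empty_ligands())
  key <- paste(prot$chain, prot$resno)
  best <- tapply(seq_along(key), key, function(ii) ii[which.min(dmin[ii])])
  res <- data.frame(chain = prot$chain[best], resid = prot$resid[best],
                    resno = prot$resno[best], atom = prot$elety[best],
                    distance_A = dmin[best], stringsAsFactors = FALSE)
  res <- res[order(res$chain, res$resno), , drop = FALSE]
  rownames(res) <- NULL
  if (nrow(res) > 4L) {
    warning("over-ligation: ", nrow(res), " residues within ", cutoff_A,
            " A of cluster '", cluster_id, "'", call. = FALSE)
  }
  res
}

.empty_ligands <- function() {
  data.frame(chain = character(), resid = character(), resno = integer(),
             atom = character(), distance_A = numeric(),
             stringsAsFactors = FALSE)
}

# conjugated-core atom names for the edge-to-edge convention
.FLAVIN_RING <- c("N1", "C2", "O2", "N3", "C4", "O4", "C4A", "C4X", "N5",
                  "C5A", "C5X", "C6", "C7", "C8", "C9", "C9A", "N10", "C10",
                  "C10A", "C7M", "C8M")

#' Edge-to-edge distance between two cofactors
#'
#' The minimum inter-atomic distance between the two cofactors' atom
#' subsets, hydrogens excluded. The `"all-heavy"` convention uses every
#' non-hydrogen atom; `"conjugated-only"` restricts flavins to the
#' isoalloxazine ring and FeS clusters to the Fe+S core.
#'
#' @param a,b `cofactor_record` objects.
#' @param convention `"all-heavy"` or `"conjugated-only"`.
#' @return Distance in Angstrom.
#' @export
edge_to_edge_distance <- function(a, b,
                                  convention = c("all-heavy",
                                                 "conjugated-only")) {
  convention <- match.arg(convention)
  pa <- .edge_atoms(a, convention)
  pb <- .edge_atoms(b, convention)
  if (nrow(pa) == 0L || nrow(pb) == 0L) {
    stop("empty atom subset after filtering (convention '", convention,
         "')", call. = FALSE)
  }
  dx <- outer(pa$x, pb$x, "-")
  dy <- outer(pa$y, pb$y, "-")
  dz <- outer(pa$z, pb$z, "-")
  min(sqrt(dx^2 + dy^2 + dz^2))
}

.edge_atoms <- function(rec, convention) {
  stopifnot(inherits(rec, "cofactor_record"))
  at <- rec$atoms[rec$atoms$elesy != "H", , drop = FALSE]
  if (convention == "conjugated-only") {
    if (rec$kind %in% c("SF4", "FES")) {
      at <- at[at$elesy %in% c("FE", "S"), , drop = FALSE]
    } else if (rec$kind %in% c("FMN", "RBF")) {
      at <- at[toupper(at$elety) %in% .FLAVIN_RING, , drop = FALSE]
    }
  }
  at
}

#' Minimal electron-transfer chain between two cofactors
#'
#' Finds the simple path from `start` to `end` with the smallest total
#' edge-to-edge distance over the cofactor graph, considering only edges
#' below `ceiling_A` (beyond which tunneling is negligible). Ties are
#' broken by fewer hops, then lexicographically on the id sequence. If no
#' path exists under the ceiling, a disconnected result reports the
#' bottleneck distance that would have to be admitted.
#'
#' @param network A [cofactor_network()].
#' @param start,end Cofactor ids.
#' @param ceiling_A Maximum usable edge length (Angstrom, default 25).
#' @return A list with `connected` (logical), `path` (ordered ids, or
#'   NULL), `total_distance_A`, and for disconnected results
#'   `bottleneck_gap_A` (the largest edge on the minimax path).
#' @export
build_et_chain <- function(network, start, end, ceiling_A = 25) {
  stopifnot(inherits(network, "cofactor_network"))
  ids <- vapply(network$cofactors, `[[`, "", "id")
  if (!(start %in% ids) || !(end %in% ids)) {
    stop("start/end must be cofactor ids of the network", call. = FALSE)
  }
  D <- network$edges
  adj <- D < ceiling_A
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  paths <- tryCatch(
    igraph::all_simple_paths(g, from = start, to = end),
    error = function(e) list()
  )
  if (length(paths) == 0L) {
    # minimax bottleneck: smallest ceiling that would connect start to end
    gap <- .bottleneck_gap(D, start, end)
    return(list(connected = FALSE, path = NULL, total_distance_A = NA_real_,
                bottleneck_gap_A = gap))
  }
  score <- lapply(paths, function(pp) {
    v <- names(pp)
    dd <- sum(D[cbind(v[-length(v)], v[-1])])
    list(ids = v, dist = dd, hops = length(v) - 1L)
  })
  dists <- vapply(score, `[[`, 0, "dist")
  hops <- vapply(score, `[[`, 0L, "hops")
  keys <- vapply(score, function(s) paste(s$ids, collapse = "|"), "")
  ord <- order(dists, hops, keys)
  best <- score[[ord[1]]]
  list(connected = TRUE, path = best$ids, total_distance_A = best$dist)
}

.bottleneck_gap <- function(D, start, end) {
  thr <- sort(unique(D[upper.tri(D)]))
  for (t in thr) {
    adj <- D <= t
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    if (igraph::distances(g, v = start, to = end) < Inf) return(t)
  }
  NA_real_
}

#' Total iron content of a cofactor network
#'
#' Sums the iron atoms over all cofactor records: 4 per [4Fe4S] (SF4) and
#' 2 per [2Fe2S] (FES). For the full Rnf inventory — eight [4Fe4S] in RnfB,
#' two in RnfC, and the AE1 [2Fe2S] — this gives 42 mol Fe/mol complex,
#' matching the colorimetrically measured 41.8 +/- 1.5.
#'
#' @param network A [cofactor_network()] (an empty network gives 0).
#' @return Total iron atom count.
#' @export
iron_inventory <- function(network) {
  stopifnot(inherits(network, "cofactor_network"))
  if (length(network$cofactors) == 0L) return(0L)
  sum(vapply(network$cofactors, `[[`, 0L, "iron_atoms"))
}

#' Define a cofactor-deletion variant
#'
#' @param name Variant label, e.g. `"dAE1"` or `"R67A"`.
#' @param removed_cofactors Character vector of cofactor ids removed by the
#'   mutation (may be empty for point substitutions).
#' @param substituted_residues Optional character vector of substituted
#'   residues.
#' @return An object of class `variant_spec`.
#' @export
variant_spec <- function(name, removed_cofactors = character(),
                         substituted_residues = character()) {
  structure(list(name = name, removed_cofactors = removed_cofactors,
                 substituted_residues = substituted_residues),
            class = "variant_spec")
}

#' Iron-content change of a cofactor-deletion variant
#'
#' The signed change in iron atoms when the variant's cofactors are
#' removed: -2 for loss of the AE1 [2Fe2S], -4 for loss of the B8 [4Fe4S],
#' 0 for flavin-only deletions.
#'
#' @param network Reference [cofactor_network()].
#' @param variant A [variant_spec()]; its removed cofactors must exist in
#'   the network.
#' @return Signed iron change (<= 0).
#' @export
variant_fe_delta <- function(network, variant) {
  stopifnot(inherits(network, "cofactor_network"),
            inherits(variant, "variant_spec"))
  ids <- vapply(network$cofactors, `[[`, "", "id")
  bad <- setdiff(variant$removed_cofactors, ids)
  if (length(bad) > 0L) {
    stop("unknown cofactor id(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(variant$removed_cofactors, ids)
  -sum(vapply(network$cofactors[idx], `[[`, 0L, "iron_atoms"))
}

#' Relative oxidoreductase activity of a variant
#'
#' Percent of wild-type specific activity, e.g. 0.7 of 7.1 U/mg is 9.9%,
#' reported as 10%.
#'
#' @param variant_U_per_mg Variant specific activity (U/mg).
#' @param wildtype_U_per_mg Wild-type specific activity (U/mg, > 0).
#' @return A list with `percent` (unrounded) and `percent_rounded`
#'   (nearest integer).
#' @export
relative_activity <- function(variant_U_per_mg, wildtype_U_per_mg) {
  if (!is.numeric(wildtype_U_per_mg) || wildtype_U_per_mg <= 0) {
    stop("wildtype activity must be > 0", call. = FALSE)
  }
  pct <- 100 * variant_U_per_mg / wildtype_U_per_mg
  list(percent = pct, percent_rounded = round(pct))
}
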