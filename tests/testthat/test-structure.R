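test_that("the toy complex round-trips through the PDB parser", {
  fx <- toy_complex_cached()
  expect_equal(nrow(fx$atoms), fx$gen$manifest$counts$n_atoms)
  # both cluster types present among HETATM records
  expect_true(all(c("SF4", "FES") %in%
                    fx$atoms$resid[fx$atoms$record == "HETATM"]))
  # an unparseable file is a parse error with context
  empty <- tempfile(fileext = ".pdb")
  writeLines(character(), empty)
  expect_error(load_structure(empty), "parse|atoms")
  expect_error(load_structure(tempfile(fileext = ".pdb")), "not found")
})

test_that("cofactor detection recovers the generator inventory", {
  fx <- toy_complex_cached()
  cofs <- fx$net$cofactors
  kinds <- table(vapply(cofs, `[[`, "", "kind"))
  expect_equal(unname(kinds[["SF4"]]), 10L)
  expect_equal(unname(kinds[["FES"]]), 1L)
  expect_equal(unname(kinds[["FMN"]]), 3L)
  expect_equal(unname(kinds[["RBF"]]), 1L)
  expect_equal(length(cofs), 15L)
  # per-kind iron counts
  for (co in cofs) {
    expect_equal(co$iron_atoms,
                 c(SF4 = 4L, FES = 2L, FMN = 0L, RBF = 0L)[[co$kind]])
  }
  # no HETATM -> no cofactors
  expect_length(detect_cofactors(fx$atoms[fx$atoms$record == "ATOM", ]), 0)
  # unknown Fe-containing code is kept with a warning
  odd <- data.frame(record = "HETATM", chain = "Z", resid = "FEX",
                    resno = 1, insert = NA, elety = "FE1", elesy = "FE",
                    x = 0, y = 0, z = 0)
  expect_warning(rec <- detect_cofactors(odd), "unknown")
  expect_equal(rec[[1]]$kind, "unknown")
})

test_that("ligating cysteines are found at the 2Fe2S cluster", {
  fx <- toy_complex_cached()
  lig <- cluster_ligands(fx$net, "A_FES_150")
  expect_equal(nrow(lig), 4L)
  expect_equal(paste(lig$chain, lig$resno),
               c("A 25", "A 113", "E 25", "E 108"))
  expect_true(all(lig$resid == "CYS"))
  expect_true(all(abs(lig$distance_A - 2.3) < 1e-6))
  # cutoff below bonding distance finds nothing
  expect_equal(nrow(cluster_ligands(fx$net, "A_FES_150", 0.1)), 0L)
  expect_error(cluster_ligands(fx$net, "Z_FES_1"), "no cofactor")
})

test_that("ligand detection is invariant to atom order and flags over-ligation", {
  fx <- toy_complex_cached()
  set.seed(1)
  shuffled <- fx$atoms[sample(nrow(fx$atoms)), ]
  net2 <- cofactor_network(shuffled)
  expect_equal(cluster_ligands(net2, "A_FES_150"),
               cluster_ligands(fx$net, "A_FES_150"))
  # five donors in range -> all five returned, with a warning
  atoms <- rbind(
    data.frame(record = "HETATM", chain = "A", resid = "FES", resno = 1,
               insert = NA, elety = c("FE1", "FE2", "S1", "S2"),
               elesy = c("FE", "FE", "S", "S"),
               x = c(-1.35, 1.35, 0, 0), y = c(0, 0, 1.1, -1.1), z = 0),
    data.frame(record = "ATOM", chain = "A", resid = "CYS",
               resno = 10 + 1:5, insert = NA, elety = "SG", elesy = "S",
               x = c(-1.35, -1.35, 1.35, 1.35, 0),
               y = c(0, 0, 0, 0, 2.2),
               z = c(2.3, -2.3, 2.3, -2.3, 0))
  )
  expect_warning(net5 <- cofactor_network(atoms), "over-ligation")
  lig5 <- suppressWarnings(cluster_ligands(net5, "A_FES_1"))
  expect_equal(nrow(lig5), 5L)
})

test_that("edge-to-edge distances equal the brute-force pairwise minimum", {
  # two single-atom records 10 A apart
  mk <- function(id, kind, df) {
    structure(list(id = id, kind = kind, atoms = df,
                   iron_atoms = sum(df$elesy == "FE")),
              class = "cofactor_record")
  }
  a <- mk("a", "SF4", data.frame(elety = "FE1", elesy = "FE",
                                 x = 0, y = 0, z = 0))
  b <- mk("b", "SF4", data.frame(elety = "FE1", elesy = "FE",
                                 x = 10, y = 0, z = 0))
  expect_equal(edge_to_edge_distance(a, b), 10)
  expect_equal(edge_to_edge_distance(a, a), 0)

  # random multi-atom records vs O(n^2) oracle
  set.seed(3)
  for (rep in 1:5) {
    pa <- matrix(rnorm(15, 0, 2), ncol = 3)
    pb <- matrix(rnorm(12, 8, 2), ncol = 3)
    ra <- mk("a", "SF4", data.frame(elety = "S1", elesy = "S",
                                    x = pa[, 1], y = pa[, 2], z = pa[, 3]))
    rb <- mk("b", "FES", data.frame(elety = "S1", elesy = "S",
                                    x = pb[, 1], y = pb[, 2], z = pb[, 3]))
    brute <- min(apply(pa, 1, function(u)
      apply(pb, 1, function(v) sqrt(sum((u - v)^2)))))
    expect_equal(edge_to_edge_distance(ra, rb), brute, tolerance = 1e-12)
    expect_equal(edge_to_edge_distance(rb, ra),
                 edge_to_edge_distance(ra, rb))
  }
})

test_that("the two edge conventions differ for flavins and agree on clusters", {
  fx <- toy_complex_cached()
  cofs <- fx$net$cofactors
  ids <- vapply(cofs, `[[`, "", "id")
  fes <- cofs[[match("A_FES_150", ids)]]
  fmn <- cofs[[match("G_FMN_510", ids)]]
  d_all <- edge_to_edge_distance(fes, fmn, "all-heavy")
  d_conj <- edge_to_edge_distance(fes, fmn, "conjugated-only")
  expect_gte(d_conj, d_all)  # subsetting can only increase the minimum
})

test_that("the ET chain is the minimal-distance simple path", {
  fx <- toy_complex_cached()
  ch <- build_et_chain(fx$net, "B_SF4_201", "C_FMN_310")
  expect_true(ch$connected)
  expect_equal(ch$path, fx$gen$manifest$chain_order)

  # exhaustive-enumeration oracle on small synthetic graphs with a decoy
  # shortcut edge
  set.seed(9)
  for (rep in 1:5) {
    n <- 6
    pts <- matrix(runif(n * 2, 0, 30), ncol = 2)
    D <- as.matrix(dist(pts))
    dimnames(D) <- list(letters[1:n], letters[1:n])
    got <- build_et_chain(fake_network(D), "a", "f", ceiling_A = 20)
    want <- enumerate_best_path(D, "a", "f", ceiling_A = 20)
    if (is.null(want)) {
      expect_false(got$connected)
    } else {
      expect_true(got$connected)
      expect_equal(got$path, want$ids)
      expect_equal(got$total_distance_A, want$dist, tolerance = 1e-12)
    }
  }

  # ceiling below every edge: disconnected, reporting the bottleneck
  ch_dis <- build_et_chain(fx$net, "B_SF4_201", "C_FMN_310",
                           ceiling_A = 5)
  expect_false(ch_dis$connected)
  expect_true(is.finite(ch_dis$bottleneck_gap_A))
  expect_gt(ch_dis$bottleneck_gap_A, 5)
})

test_that("iron accounting matches the cofactor stoichiometry", {
  fx <- toy_complex_cached()
  expect_equal(iron_inventory(fx$net), 42L)  # 4*10 + 2*1
  # conservation identity: 4 #SF4 + 2 #FES
  kinds <- vapply(fx$net$cofactors, `[[`, "", "kind")
  expect_equal(iron_inventory(fx$net),
               4L * sum(kinds == "SF4") + 2L * sum(kinds == "FES"))

  expect_equal(variant_fe_delta(fx$net, variant_spec("dAE1", "A_FES_150")),
               -2L)
  expect_equal(variant_fe_delta(fx$net, variant_spec("dB8", "B_SF4_208")),
               -4L)
  expect_equal(variant_fe_delta(fx$net, variant_spec("dFMNG", "G_FMN_510")),
               0L)
  expect_error(variant_fe_delta(fx$net, variant_spec("x", "Q_SF4_1")),
               "unknown cofactor")
})

test_that("relative activities reproduce the assay arithmetic", {
  r <- relative_activity(0.7, 7.1)
  expect_equal(r$percent, 100 * 0.7 / 7.1)
  expect_equal(r$percent_rounded, 10)
  expect_equal(relative_activity(0.8, 7.1)$percent_rounded, 11)
  expect_equal(relative_activity(3.4, 7.1)$percent_rounded, 48)
  expect_equal(relative_activity(7.1, 7.1)$percent, 100)
  expect_error(relative_activity(1, 0), "> 0")
})
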