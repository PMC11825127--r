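# small hand-built protomer: only the atoms a given descriptor needs
bare_protomer <- function(rows) {
  do.call(rbind, lapply(rows, function(r) data.frame(
    atom_name = r$atom, element = r$el, res_name = r$res,
    res_num = r$num, chain = "A", alt = "", x = r$xyz[1], y = r$xyz[2],
    z = r$xyz[3], occ = 1, hetero = FALSE, stringsAsFactors = FALSE)))
}

test_that("alpha-C distance is the Ile582 to helix-centroid distance", {
  p <- bare_protomer(list(
    list(atom = "CA", el = "C", res = "ILE", num = 582L, xyz = c(0, 0, 0)),
    list(atom = "CA", el = "C", res = "ASN", num = 500L, xyz = c(18, 0, 0)),
    list(atom = "CA", el = "C", res = "GLU", num = 501L, xyz = c(20, 0, 0)),
    list(atom = "CA", el = "C", res = "VAL", num = 502L, xyz = c(22, 0, 0))))
  expect_equal(alpha_c_distance(p), 20.0)
  # reference point at the centroid itself
  p$x[1] <- 20
  expect_equal(alpha_c_distance(p), 0)
  expect_error(alpha_c_distance(p[-2, ]), "nearest residue")
})

test_that("alpha-C state boundary is strict at 19.6 A", {
  expect_identical(classify_alpha_c(19.1), "in")
  expect_identical(classify_alpha_c(23.2), "out")
  expect_identical(classify_alpha_c(19.6), "out")
  expect_identical(classify_alpha_c(19.5999), "in")
  expect_error(classify_alpha_c(-1), "non-negative")
})

test_that("pseudo-dihedral handles planar arrangements and degeneracy", {
  o <- c(0, 0, 0)
  expect_equal(pseudo_dihedral(c(-1, 1, 0), o, c(1, 0, 0), c(2, 1, 0)), 0)
  expect_equal(pseudo_dihedral(c(-1, 1, 0), o, c(1, 0, 0), c(2, -1, 0)), 180)
  expect_error(pseudo_dihedral(c(-1, 0, 0), o, c(1, 0, 0), c(2, 0, 0)),
               "collinear")
})

test_that("pseudo-dihedral matches independent torsion oracles", {
  set.seed(42)
  wrap360 <- function(a) ifelse(a < 0, a + 360, a)
  for (i in 1:100) {
    p <- matrix(rnorm(12, sd = 4), 4, 3)
    mine <- pseudo_dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
    expect_lt(abs(mine - oracle_torsion(p[1, ], p[2, ], p[3, ], p[4, ])),
              1e-6)
    expect_gte(mine, 0)
    expect_lt(mine, 360)
  }
  # third-party cross-check (opposite sign convention: 360 - angle)
  p <- matrix(rnorm(12, sd = 4), 4, 3)
  mine <- pseudo_dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
  b3d <- wrap360(bio3d::torsion.xyz(as.vector(t(p)), atm.inc = 4))
  expect_equal((mine + b3d) %% 360, 0, tolerance = 1e-6)
})

test_that("DFG state boundary is closed at 140 degrees", {
  expect_identical(classify_dfg(210), "out")
  expect_identical(classify_dfg(290), "out")
  expect_identical(classify_dfg(100), "in")
  expect_identical(classify_dfg(140), "out")
  expect_error(classify_dfg(-5), "\\[0, 360\\)")
  expect_error(classify_dfg(380), "\\[0, 360\\)")
})

test_that("K-E distances take the pairwise minima", {
  p <- bare_protomer(list(
    list(atom = "NZ", el = "N", res = "LYS", num = 483L, xyz = c(0, 0, 0)),
    list(atom = "CE", el = "C", res = "LYS", num = 483L, xyz = c(0, 0, 2)),
    list(atom = "OE1", el = "O", res = "GLU", num = 501L, xyz = c(3, 0, 0)),
    list(atom = "OE2", el = "O", res = "GLU", num = 501L, xyz = c(5, 0, 0)),
    list(atom = "CD", el = "C", res = "GLU", num = 501L, xyz = c(4, 0, 0))))
  ke <- ke_distances(p)
  expect_equal(unname(ke["ke_no"]), 3.0)
  expect_lte(ke[["ke_min_sidechain"]], 3.0)

  # randomised rotamer sets: min-sidechain equals the brute-force pairwise
  # minimum and never exceeds the NZ-carboxylate distance
  set.seed(7)
  for (i in 1:20) {
    k_xyz <- matrix(rnorm(15, sd = 3), 5, 3)
    e_xyz <- matrix(rnorm(12, sd = 3) + 4, 4, 3)
    rows <- c(
      lapply(seq_len(5), function(j) list(
        atom = c("CB", "CG", "CD", "CE", "NZ")[j], el = c("C", "C", "C", "C", "N")[j],
        res = "LYS", num = 483L, xyz = k_xyz[j, ])),
      lapply(seq_len(4), function(j) list(
        atom = c("CG", "CD", "OE1", "OE2")[j], el = c("C", "C", "O", "O")[j],
        res = "GLU", num = 501L, xyz = e_xyz[j, ])))
    p <- bare_protomer(rows)
    ke <- ke_distances(p)
    expect_equal(ke[["ke_min_sidechain"]], oracle_min_pair(k_xyz, e_xyz),
                 tolerance = 1e-9)
    expect_lte(ke[["ke_min_sidechain"]], ke[["ke_no"]] + 1e-12)
  }
})

test_that("compute_descriptors reproduces generator targets exactly", {
  s <- make_structure(synthetic_spec(n_protomers = 1, alpha_c = 22.0,
                                     dfg = 210, ke = 3.5, ligand = NA))
  g <- compute_descriptors(protomer_atoms(s, "A"))
  expect_equal(g$alpha_c_distance, 22.0, tolerance = 1e-6)
  expect_equal(g$dfg_pseudo_dihedral, 210, tolerance = 1e-6)
  expect_equal(g$ke_no_distance, 3.5, tolerance = 1e-6)
  expect_identical(g$alpha_c_state, "out")
  expect_identical(g$dfg_state, "out")
  expect_true(g$salt_bridge_4A)
  expect_true(g$salt_bridge_45A)
  # stored states agree with the classifier functions
  expect_identical(g$alpha_c_state, classify_alpha_c(g$alpha_c_distance))
  expect_identical(g$dfg_state, classify_dfg(g$dfg_pseudo_dihedral))
})

test_that("missing activation-loop residues degrade per-descriptor only", {
  s <- make_structure(synthetic_spec(n_protomers = 1, alpha_c = 20,
                                     dfg = 200, ke = 3.0, ligand = NA))
  p <- protomer_atoms(s, "A")
  p <- p[!(p$res_num == 595L & p$atom_name == "CA"), ]
  g <- compute_descriptors(p)
  expect_true(is.na(g$dfg_pseudo_dihedral))
  expect_true(is.na(g$dfg_state))
  expect_true("dfg_pseudo_dihedral" %in% g$unavailable)
  expect_equal(g$alpha_c_distance, 20, tolerance = 1e-6)
  expect_equal(g$ke_no_distance, 3.0, tolerance = 1e-6)
})

test_that("all descriptors are rigid-motion invariant", {
  set.seed(11)
  s <- make_structure(synthetic_spec(n_protomers = 1, alpha_c = 19.3,
                                     dfg = 250, ke = 4.2, ligand = NA))
  p0 <- protomer_atoms(s, "A")
  g0 <- compute_descriptors(p0)
  for (i in 1:10) {
    p1 <- transform_atoms(p0, random_rigid_transform())
    g1 <- compute_descriptors(p1)
    expect_equal(g1$alpha_c_distance, g0$alpha_c_distance, tolerance = 1e-6)
    expect_equal(g1$dfg_pseudo_dihedral, g0$dfg_pseudo_dihedral,
                 tolerance = 1e-6)
    expect_equal(g1$ke_no_distance, g0$ke_no_distance, tolerance = 1e-6)
    expect_equal(g1$ke_min_sidechain_distance, g0$ke_min_sidechain_distance,
                 tolerance = 1e-6)
  }
})

test_that("descriptor_table emits one row per structure and chain", {
  s <- make_structure(synthetic_spec(n_protomers = 2, alpha_c = c(19.1, 19.0),
                                     dfg = 210, ke = 2.8, ligand = "PHI"))
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- descriptor_table(s, file = path)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$chain, c("A", "B"))
  expect_equal(tab$alpha_c_distance, c(19.1, 19.0), tolerance = 1e-6)
  reread <- read.delim(path, comment.char = "#")
  expect_equal(nrow(reread), 2L)
})
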