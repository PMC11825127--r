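mini_complex <- function(da_dist, protein_atom = "O", protein_res = "GLY",
                         lig_atom = "N1", lig_el = "N") {
  prot <- data.frame(
    atom_name = protein_atom, element = substr(protein_atom, 1, 1),
    res_name = protein_res, res_num = 10L, chain = "A", alt = "",
    x = 0, y = 0, z = 0, occ = 1, hetero = FALSE, stringsAsFactors = FALSE)
  lig_atoms <- data.frame(
    atom_name = lig_atom, element = lig_el, res_name = "XYZ", res_num = 900L,
    chain = "A", alt = "", x = da_dist, y = 0, z = 0, occ = 1, hetero = TRUE,
    stringsAsFactors = FALSE)
  lig <- ligand_record(lig_atoms, annotations = list(
    XYZ = list(donors = "N1", acceptors = "O9", aromatics = character())))
  list(prot = prot, lig = lig)
}

test_that("h-bond contacts respect the 3.5 A donor-acceptor cutoff", {
  close <- mini_complex(3.4)
  hb <- hbond_contacts(close$prot, close$lig)
  expect_equal(nrow(hb), 1L)
  expect_identical(hb$direction, "ligand_donates")
  far <- mini_complex(3.6)
  expect_equal(nrow(hbond_contacts(far$prot, far$lig)), 0L)
})

test_that("h-bond enumeration equals a brute-force pair scan", {
  set.seed(5)
  for (rep in 1:10) {
    n_d <- sample(2:5, 1); n_a <- sample(2:5, 1)
    d_xyz <- matrix(rnorm(3 * n_d, sd = 2.5), n_d, 3)
    a_xyz <- matrix(rnorm(3 * n_a, sd = 2.5), n_a, 3)
    prot <- data.frame(
      atom_name = "O", element = "O", res_name = "GLY",
      res_num = seq_len(n_a) + 10L, chain = "A", alt = "",
      x = a_xyz[, 1], y = a_xyz[, 2], z = a_xyz[, 3], occ = 1,
      hetero = FALSE, stringsAsFactors = FALSE)
    lig_atoms <- data.frame(
      atom_name = paste0("N", seq_len(n_d)), element = "N", res_name = "XYZ",
      res_num = 900L, chain = "A", alt = "", x = d_xyz[, 1], y = d_xyz[, 2],
      z = d_xyz[, 3], occ = 1, hetero = TRUE, stringsAsFactors = FALSE)
    lig <- ligand_record(lig_atoms, annotations = list(
      XYZ = list(donors = paste0("N", seq_len(n_d)), acceptors = character(),
                 aromatics = character())))
    hb <- hbond_contacts(prot, lig, cutoff = 3.5)
    expect_equal(nrow(hb), oracle_hbond_pairs(d_xyz, a_xyz, 3.5))
  }
})

test_that("hydrophobic cutoffs differ for aromatic and aliphatic pairs", {
  mk <- function(aromatic) {
    prot <- data.frame(
      atom_name = if (aromatic) "CZ" else "CB",
      element = "C", res_name = if (aromatic) "PHE" else "ALA",
      res_num = 20L, chain = "A", alt = "", x = 0, y = 0, z = 0, occ = 1,
      hetero = FALSE, stringsAsFactors = FALSE)
    # add the ring context so PHE CZ is recognised as aromatic
    lig_atoms <- data.frame(
      atom_name = "C1", element = "C", res_name = "XYZ", res_num = 900L,
      chain = "A", alt = "", x = 4.2, y = 0, z = 0, occ = 1, hetero = TRUE,
      stringsAsFactors = FALSE)
    lig <- ligand_record(lig_atoms, annotations = list(
      XYZ = list(donors = character(), acceptors = character(),
                 aromatics = if (aromatic) "C1" else character())))
    hydrophobic_contacts(prot, lig)
  }
  expect_length(mk(aromatic = TRUE), 0L)   # 4.2 A > 4.0 A aromatic cutoff
  expect_length(mk(aromatic = FALSE), 1L)  # 4.2 A < 4.5 A aliphatic cutoff
})

test_that("hydrophobic residue set equals exhaustive enumeration", {
  set.seed(9)
  n_res <- 6
  prot <- do.call(rbind, lapply(seq_len(n_res), function(i) data.frame(
    atom_name = "CB", element = "C", res_name = "ALA", res_num = 10L + i,
    chain = "A", alt = "", x = rnorm(1, sd = 4), y = rnorm(1, sd = 4),
    z = rnorm(1, sd = 4), occ = 1, hetero = FALSE, stringsAsFactors = FALSE)))
  lig_atoms <- data.frame(
    atom_name = c("C1", "C2"), element = "C", res_name = "XYZ",
    res_num = 900L, chain = "A", alt = "", x = rnorm(2, sd = 2),
    y = rnorm(2, sd = 2), z = rnorm(2, sd = 2), occ = 1, hetero = TRUE,
    stringsAsFactors = FALSE)
  lig <- ligand_record(lig_atoms, annotations = list(
    XYZ = list(donors = character(), acceptors = character(),
               aromatics = character())))
  got <- hydrophobic_contacts(prot, lig)
  want <- prot$res_num[vapply(seq_len(nrow(prot)), function(i) {
    any(sqrt((lig_atoms$x - prot$x[i])^2 + (lig_atoms$y - prot$y[i])^2 +
               (lig_atoms$z - prot$z[i])^2) <= 4.5)
  }, logical(1))]
  expect_setequal(unname(got), want)
})

test_that("shrinking a cutoff never adds contacts (monotonicity)", {
  s <- make_structure(synthetic_spec(n_protomers = 1, alpha_c = 19.1,
                                     dfg = 210, ke = 2.8, ligand = "PHI",
                                     leu505_contact = TRUE))
  p <- protomer_atoms(s, "A")
  l <- chain_ligands(s, "A")[[1]]
  hb_tight <- hbond_contacts(p, l, cutoff = 3.0)
  hb_loose <- hbond_contacts(p, l, cutoff = 3.5)
  key <- function(df) paste(df$res_num, df$protein_atom, df$ligand_atom,
                            df$direction)
  expect_true(all(key(hb_tight) %in% key(hb_loose)))
  hp_tight <- hydrophobic_contacts(p, l, 3.0, 3.5)
  hp_loose <- hydrophobic_contacts(p, l, 4.0, 4.5)
  expect_true(all(hp_tight %in% hp_loose))
})

test_that("fingerprint flags for a PHI1-like type-II pose", {
  s <- make_structure(synthetic_spec(n_protomers = 2, alpha_c = 19.1,
                                     dfg = 210, ke = 2.8, ligand = "PHI",
                                     glu501_hbond = TRUE,
                                     asp594_mode = "ligand_accepts",
                                     his574_hbond = TRUE))
  fp <- build_fingerprint(protomer_atoms(s, "A"), chain_ligands(s, "A")[[1]])
  expect_true(fp$glu501_hbond)
  expect_identical(fp$asp594_backbone_hbond, "ligand_accepts")
  expect_true(fp$his574_backbone_hbond)
  # every flagged special h-bond also appears as a per-residue entry
  expect_true(all(c(501L, 594L, 574L) %in% fp$entries$res_num))
  e501 <- fp$entries$categories[fp$entries$res_num == 501L]
  expect_match(e501, "h_donor")
})

test_that("fingerprint flags for a VEM-like monomer-selective pose", {
  s <- make_structure(synthetic_spec(n_protomers = 2, alpha_c = 22.0,
                                     dfg = 100, ke = 5.0, ligand = "VEM",
                                     glu501_hbond = FALSE,
                                     leu505_contact = TRUE))
  p <- protomer_atoms(s, "A")
  l <- chain_ligands(s, "A")[[1]]
  fp <- build_fingerprint(p, l)
  expect_false(fp$glu501_hbond)
  expect_identical(fp$asp594_backbone_hbond, "ligand_donates")
  expect_true(505L %in% unname(hydrophobic_contacts(p, l)))
})

test_that("a distant ligand yields an empty fingerprint", {
  s <- make_structure(synthetic_spec(n_protomers = 1, alpha_c = 20,
                                     dfg = 200, ke = 3.0, ligand = NA))
  lig_atoms <- data.frame(
    atom_name = c("N4", "O1"), element = c("N", "O"), res_name = "PHI",
    res_num = 901L, chain = "A", alt = "", x = 500, y = 500, z = c(500, 502),
    occ = 1, hetero = TRUE, stringsAsFactors = FALSE)
  lig <- ligand_record(lig_atoms)
  fp <- build_fingerprint(protomer_atoms(s, "A"), lig)
  expect_equal(nrow(fp$entries), 0L)
  expect_false(fp$glu501_hbond)
  expect_identical(fp$asp594_backbone_hbond, "none")
  expect_false(fp$his574_backbone_hbond)
})

test_that("back-pocket occupancy separates type-II and type-I poses", {
  pm <- backpocket_map()
  expect_setequal(names(pm$pockets), c("BP-I", "BP-II", "BP-III", "BP-IV"))
  s <- make_structure(synthetic_spec(n_protomers = 1, alpha_c = 19.1,
                                     dfg = 210, ke = 2.8, ligand = "PHI"))
  occ <- pocket_occupancy(chain_ligands(s, "A")[[1]], pm,
                          protomer_atoms(s, "A"))
  expect_true("BP-III" %in% occ)
  sv <- make_structure(synthetic_spec(n_protomers = 1, alpha_c = 22,
                                      dfg = 100, ke = 5.0, ligand = "VEM",
                                      glu501_hbond = FALSE))
  occ_v <- pocket_occupancy(chain_ligands(sv, "A")[[1]], pm,
                            protomer_atoms(sv, "A"))
  expect_false("BP-III" %in% occ_v)
  # far ligand occupies nothing
  far <- ligand_record(data.frame(
    atom_name = "C1", element = "C", res_name = "PHI", res_num = 901L,
    chain = "A", alt = "", x = 900, y = 900, z = 900, occ = 1, hetero = TRUE,
    stringsAsFactors = FALSE))
  expect_length(pocket_occupancy(far, pm, protomer_atoms(s, "A")), 0L)
})

test_that("fingerprint TSV/JSON writers mirror the entry matrix", {
  s <- make_structure(synthetic_spec(n_protomers = 1, alpha_c = 19.1,
                                     dfg = 210, ke = 2.8, ligand = "PHI"))
  fp <- build_fingerprint(protomer_atoms(s, "A"), chain_ligands(s, "A")[[1]])
  tsv <- withr::local_tempfile(fileext = ".tsv")
  json <- withr::local_tempfile(fileext = ".json")
  write_fingerprint(fp, tsv, json = json)
  mat <- read.delim(tsv, comment.char = "#")
  expect_equal(nrow(mat), nrow(fp$entries))
  flags <- jsonlite::read_json(json)
  expect_true(flags$glu501_hbond)
})
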