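# Synthetic structure and trajectory generator.
#
# Builds minimal kinase protomers containing exactly the atoms the
# descriptors need, placed so that computed descriptors equal their targets
# to machine precision.  The three descriptor regions are geometrically
# independent: the alpha-C centroid sits on a fixed axis from the Ile582
# C-alpha, the Phe595 C-alpha rotates about the Gly593-Asp594 axis to set
# the pseudo-dihedral, and the Glu501 carboxylate slides along the Lys483 NZ
# direction to set the K-E distance.  Geometry is deliberately not
# physically realistic (no force field, no covalent continuity); it is a
# controlled test bed for the analysis pipeline.

.rowvec <- function(name, el, resn, resnum, chain, xyz, het = FALSE) {
  data.frame(atom_name = name, element = el, res_name = resn,
             res_num = as.integer(resnum), chain = chain, alt = "",
             x = xyz[1], y = xyz[2], z = xyz[3], occ = 1, hetero = het,
             stringsAsFactors = FALSE)
}

# Rotate points about a unit axis through the origin (Rodrigues).
.rotate <- function(p, axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  ct <- cos(theta); st <- sin(theta)
  p * ct + .cross(axis, p) * st + axis * sum(axis * p) * (1 - ct)
}
.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Phe595 C-alpha position giving the requested pseudo-dihedral. p4 is found
# by rotating a reference position about the p2->p3 axis; the rotation sign
# is fixed by checking the resulting torsion.
.place_p4 <- function(p1, p2, p3, target_deg, r = 3.8) {
  bc <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  ref <- p1 - p2
  perp <- ref - sum(ref * bc) * bc
  perp <- perp / sqrt(sum(perp^2))
  p4_cis <- p3 + r * (0.5 * bc + 0.866 * perp)  # planar, same side as p1
  phi <- target_deg * pi / 180
  cand <- p3 + .rotate(p4_cis - p3, bc, phi)
  got <- pseudo_dihedral(p1, p2, p3, cand)
  if (min(abs(got - target_deg), 360 - abs(got - target_deg)) > 1e-6)
    cand <- p3 + .rotate(p4_cis - p3, bc, -phi)
  cand
}

#' Synthetic generation spec
#'
#' Bundles the controllable targets for the generator.  Scalars are point
#' targets (static structures); for trajectories, `alpha_c` takes
#' `c(mean, sd)` (Angstrom), `dfg` a data frame of wrapped-normal mixture
#' components (`mean`, `sd` in degrees, `weight`), `ke_occupancy` and
#' `glu501_hbond_prob` Bernoulli probabilities.  Defaults emulate the apo
#' BRAF dimer ensemble: a broad alpha-C-out distribution around 22 A, a
#' broad DFG-out dihedral around 210 deg and a ~25 percent Lys483-Glu501
#' salt-bridge occupancy, with three replicas.
#'
#' @param n_protomers 1 (monomer) or 2 (side-by-side dimer).
#' @param alpha_c Point target (A) or `c(mean, sd)`.
#' @param dfg Point target (deg) or mixture data frame.
#' @param ke Point K-E target (A) used when `ke_occupancy` is `NA`.
#' @param ke_occupancy Bernoulli salt-bridge occupancy probability (frames
#'   toggle between a bridged and an open K-E distance).
#' @param ligand Het-code per protomer (`NA` for apo), recycled.
#' @param glu501_hbond Logical per protomer: place the ligand donor within
#'   h-bond range of the Glu501 carboxylate (static generation).
#' @param glu501_hbond_prob Per-frame probability of that h-bond
#'   (trajectories).
#' @param asp594_mode `"ligand_accepts"`, `"ligand_donates"` or `"none"`.
#' @param his574_hbond Place a ligand donor at the His574 backbone carbonyl.
#' @param leu505_contact Place ligand ring carbons in hydrophobic contact
#'   with Leu505.
#' @param n_frames Frames per replica.
#' @param n_replicas Number of replicas.
#' @param seed Base random seed (replica r uses `seed + r`).
#' @param contact_scenario Named inter-lobe contact probabilities for
#'   [make_contact_scenario()].
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_protomers = 2, alpha_c = c(22.0, 0.6),
                           dfg = data.frame(mean = 210, sd = 15, weight = 1),
                           ke = 2.8, ke_occupancy = 0.25,
                           ligand = NA_character_, glu501_hbond = TRUE,
                           glu501_hbond_prob = 0.9,
                           asp594_mode = "ligand_accepts",
                           his574_hbond = TRUE, leu505_contact = FALSE,
                           n_frames = 10000, n_replicas = 3, seed = 1L,
                           contact_scenario = NULL) {
  stopifnot(n_protomers %in% 1:2, n_frames >= 1, n_replicas >= 1)
  probs <- c(ke_occupancy, glu501_hbond_prob)
  if (any(!is.na(probs) & (probs < 0 | probs > 1)))
    stop("generation error: probabilities must lie in [0, 1]")
  out <- list(n_protomers = n_protomers, alpha_c = alpha_c, dfg = dfg,
              ke = ke, ke_occupancy = ke_occupancy, ligand = ligand,
              glu501_hbond = glu501_hbond,
              glu501_hbond_prob = glu501_hbond_prob,
              asp594_mode = asp594_mode, his574_hbond = his574_hbond,
              leu505_contact = leu505_contact, n_frames = n_frames,
              n_replicas = n_replicas, seed = as.integer(seed),
              contact_scenario = contact_scenario)
  class(out) <- "synthetic_spec"
  out
}

# One protomer's atom table in local coordinates.
.protomer_atoms_local <- function(chain, alpha_c, dfg, ke, ligand = NA,
                                  glu501_hbond = TRUE, hbond_dist = 2.9,
                                  no_hbond_dist = 6.0,
                                  asp594_mode = "ligand_accepts",
                                  his574_hbond = TRUE,
                                  leu505_contact = FALSE) {
  if (alpha_c <= 0 || ke <= 0)
    stop("generation error: distance targets must be positive")
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- .rowvec(...)

  ## alpha-C region: Ile582 CA at origin, helix-centre C-alphas at x = target
  add("CA", "C", "ILE", .braf$ref, chain, c(0, 0, 0))
  add("CA", "C", "ASN", .braf$asn, chain, c(alpha_c, 1.0, 0))
  add("CA", "C", "GLU", .braf$glu, chain, c(alpha_c, -0.5, 0.8660254))
  add("CA", "C", "VAL", .braf$val, chain, c(alpha_c, -0.5, -0.8660254))

  ## DFG region: quadruple with the requested pseudo-dihedral
  o2 <- c(0, 30, 0)
  p1 <- o2 + c(-1.3, 3.571, 0)
  p2 <- o2
  p3 <- o2 + c(3.8, 0, 0)
  p4 <- .place_p4(p1, p2, p3, dfg)
  add("CA", "C", "ILE", 592, chain, p1)
  add("CA", "C", "GLY", 593, chain, p2)
  add("CA", "C", "ASP", 594, chain, p3)
  add("CA", "C", "PHE", 595, chain, p4)
  # Asp594 backbone amide/carbonyl for the ligand h-bond checks
  asp_n <- p3 + c(0.5, 1.35, 0)
  asp_o <- p3 + c(1.2, -1.25, 0)
  add("N", "N", "ASP", 594, chain, asp_n)
  add("O", "O", "ASP", 594, chain, asp_o)

  ## K-E region: Lys483 sidechain along +z from NZ; Glu501 carboxylate on +x
  o3 <- c(0, -30, 0)
  add("NZ", "N", "LYS", .braf$lys, chain, o3)
  add("CE", "C", "LYS", .braf$lys, chain, o3 + c(0, 0, 1.5))
  add("CD", "C", "LYS", .braf$lys, chain, o3 + c(0, 0, 3.0))
  add("CG", "C", "LYS", .braf$lys, chain, o3 + c(0, 0, 4.5))
  add("CB", "C", "LYS", .braf$lys, chain, o3 + c(0, 0, 6.0))
  add("CA", "C", "LYS", .braf$lys, chain, o3 + c(0, 0, 7.5))
  oe1 <- o3 + c(ke, 0, 0)
  add("OE1", "O", "GLU", .braf$glu, chain, oe1)
  add("OE2", "O", "GLU", .braf$glu, chain, oe1 + c(1.2, 0.5, 0))
  add("CD", "C", "GLU", .braf$glu, chain, oe1 + c(0.6, -0.6, 0))
  add("CG", "C", "GLU", .braf$glu, chain, oe1 + c(1.5, -1.5, 0))
  add("CB", "C", "GLU", .braf$glu, chain, oe1 + c(2.4, -2.4, 0))

  ## HRD His574 backbone (carbonyl O is the h-bond acceptor of interest)
  o4 <- c(30, 0, 0)
  add("N", "N", "HIS", .braf$his, chain, o4 + c(-1.4, 0.5, 0))
  add("CA", "C", "HIS", .braf$his, chain, o4 + c(0, 1.2, 0))
  add("C", "C", "HIS", .braf$his, chain, o4 + c(0.8, 0, 0))
  add("O", "O", "HIS", .braf$his, chain, o4)

  ## Leu505 sidechain (hydrophobic-contact partner)
  o5 <- c(-30, 0, 0)
  add("CA", "C", "LEU", .braf$leu, chain, o5 + c(0, 3.0, 0))
  add("CB", "C", "LEU", .braf$leu, chain, o5 + c(0, 1.5, 0))
  add("CG", "C", "LEU", .braf$leu, chain, o5)
  add("CD1", "C", "LEU", .braf$leu, chain, o5 + c(1.2, -0.8, 0))

  ## optional ligand (het-codes truncated to the 3 characters the PDB
  ## format's residue-name column can hold, e.g. PHI1 -> PHI)
  if (!is.na(ligand)) {
    ligand <- substr(ligand, 1, 3)
    d_glu <- if (isTRUE(glu501_hbond)) hbond_dist else no_hbond_dist
    if (ligand == "VEM") {
      # sulfonamide N1 donates to the Asp594 backbone; nothing near Glu501
      add("N1", "N", "VEM", 901, chain, asp_o + c(0, -2.9, 0), het = TRUE)
      add("O1", "O", "VEM", 901, chain, asp_o + c(2.5, -4.0, 0), het = TRUE)
      add("O2", "O", "VEM", 901, chain, asp_o + c(3.5, -4.0, 0), het = TRUE)
    } else {
      # PHI1/LY-like: amide N4 donates to the Glu501 carboxylate
      add("N4", "N", ligand, 901, chain, oe1 + c(0, 0, d_glu), het = TRUE)
      if (asp594_mode == "ligand_accepts")
        add("O1", "O", ligand, 901, chain, asp_n + c(0, 2.9, 0), het = TRUE)
      else if (asp594_mode == "ligand_donates")
        add("N4B", "N", ligand, 901, chain, asp_o + c(0, -2.9, 0), het = TRUE)
      else
        add("O1", "O", ligand, 901, chain, asp_n + c(0, 20, 0), het = TRUE)
      if (ligand == "PHI") {
        d_his <- if (isTRUE(his574_hbond)) 2.9 else 8.0
        add("N6", "N", ligand, 901, chain, o4 + c(0, -d_his, 0), het = TRUE)
      }
      # type-II pose: a carbon in the DFG-out subpocket next to Phe595
      add("C7", "C", ligand, 901, chain, p4 + c(0, 0, 3.0), het = TRUE)
    }
    if (isTRUE(leu505_contact)) {
      ring <- o5 + c(0, -3.8, 0)
      for (i in 1:6) {
        ang <- (i - 1) * pi / 3
        add(paste0("C", i), "C", ligand, 901, chain,
            ring + 1.4 * c(cos(ang), 0, sin(ang)), het = TRUE)
      }
    } else {
      add("C1", "C", ligand, 901, chain, c(0, 0, 60), het = TRUE)
    }
  }
  do.call(rbind, rows)
}

# Fixed rigid placement of protomer B relative to A.
.protomer_b_transform <- function() {
  ax <- c(1, 2, 3) / sqrt(14)
  list(axis = ax, theta = 0.7, shift = c(80, 5, -40))
}
.rotation_matrix <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  ct <- cos(theta); st <- sin(theta)
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) * ct + st * K + (1 - ct) * tcrossprod(axis)
}
.apply_transform <- function(xyz, tr) {
  R <- .rotation_matrix(tr$axis, tr$theta)
  sweep(xyz %*% t(R), 2, tr$shift, "+")
}

#' Generate a synthetic kinase structure with exact descriptor targets
#'
#' @param spec A [synthetic_spec()] with point targets (`alpha_c`, `dfg`,
#'   `ke` scalars; per-protomer vectors recycled).
#' @return A `kinase_structure` whose computed descriptors equal the
#'   targets to numerical precision.
#' @export
make_structure <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_protomers
  chains <- c("A", "B")[seq_len(n)]
  alpha_c <- rep(if (length(spec$alpha_c) > 1 && is.null(dim(spec$alpha_c)))
    spec$alpha_c else spec$alpha_c[1], length.out = n)
  if (length(spec$alpha_c) == 2 && n == 1) alpha_c <- spec$alpha_c[1]
  dfg <- rep(if (is.data.frame(spec$dfg)) spec$dfg$mean[1] else spec$dfg,
             length.out = n)
  ke <- rep(spec$ke, length.out = n)
  lig <- rep(spec$ligand, length.out = n)
  ghb <- rep(spec$glu501_hbond, length.out = n)
  parts <- lapply(seq_len(n), function(i) {
    at <- .protomer_atoms_local(chains[i], alpha_c[i], dfg[i], ke[i],
                                ligand = lig[i], glu501_hbond = ghb[i],
                                asp594_mode = spec$asp594_mode,
                                his574_hbond = spec$his574_hbond,
                                leu505_contact = spec$leu505_contact)
    if (i == 2L) {
      tr <- .protomer_b_transform()
      at[, c("x", "y", "z")] <- .apply_transform(
        as.matrix(at[, c("x", "y", "z")]), tr)
    }
    at
  })
  structure_from_atoms(do.call(rbind, parts),
                       source_id = sprintf("synthetic_%dmer", n),
                       resolution_note = "synthetic generator")
}

# Per-protomer vectorised target draws for one replica.
.draw_targets <- function(spec, n_frames) {
  ac <- if (length(spec$alpha_c) == 2)
    stats::rnorm(n_frames, spec$alpha_c[1], spec$alpha_c[2])
  else rep(spec$alpha_c[1], n_frames)
  ac <- pmax(ac, 1e-3)
  mix <- spec$dfg
  if (!is.data.frame(mix)) mix <- data.frame(mean = mix, sd = 0, weight = 1)
  comp <- sample.int(nrow(mix), n_frames, replace = TRUE,
                     prob = mix$weight / sum(mix$weight))
  dfg <- stats::rnorm(n_frames, mix$mean[comp], mix$sd[comp]) %% 360
  ke <- if (!is.na(spec$ke_occupancy)) {
    on <- stats::runif(n_frames) < spec$ke_occupancy
    ifelse(on, 3.0, 6.5)
  } else rep(spec$ke, n_frames)
  hb <- if (!is.na(spec$glu501_hbond_prob)) {
    on <- stats::runif(n_frames) < spec$glu501_hbond_prob
    ifelse(on, 2.9, 6.5)
  } else rep(2.9, n_frames)
  list(alpha_c = ac, dfg = dfg, ke = ke, hb = hb)
}

#' Generate synthetic trajectories (one per replica)
#'
#' Frame-wise geometry is realised so that each frame's descriptors are
#' draws from the spec's distributions; replicas differ only by sub-seed
#' (`seed + replica`).  Identical seeds give bit-identical output.
#'
#' @param spec A [synthetic_spec()] with distributional targets.
#' @return List of `kinase_trajectory` objects of length `n_replicas`.
#' @export
make_trajectory <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  topo <- make_structure(.static_spec(spec))
  a <- topo$atoms
  base <- as.matrix(a[, c("x", "y", "z")])
  n <- spec$n_protomers
  chains <- c("A", "B")[seq_len(n)]
  tr_b <- .protomer_b_transform()

  # The moving atoms depend affinely on the per-frame draws, so frames are
  # realised by vectorised linear updates in the protomer's global frame:
  # global = R %*% local + shift (R = I for protomer A).
  lapply(seq_len(spec$n_replicas), function(rep_i) {
    set.seed(spec$seed + rep_i)
    coords <- array(rep(base, spec$n_frames),
                    dim = c(nrow(a), 3, spec$n_frames))
    for (ci in seq_len(n)) {
      ch <- chains[ci]
      tg <- .draw_targets(spec, spec$n_frames)
      R <- if (ci == 2L) .rotation_matrix(tr_b$axis, tr_b$theta) else diag(3)
      sh <- if (ci == 2L) tr_b$shift else c(0, 0, 0)
      glob <- function(p) as.numeric(R %*% p + sh)
      e1 <- as.numeric(R %*% c(1, 0, 0))
      e2 <- as.numeric(R %*% c(0, 1, 0))
      e3 <- as.numeric(R %*% c(0, 0, 1))
      row_of <- function(resnum, atom, het = FALSE)
        which(a$chain == ch & a$hetero == het & a$res_num == resnum &
                a$atom_name == atom)[1]
      set_affine <- function(row, origin, dir, scalars) {
        if (is.na(row)) return(invisible())
        for (d in 1:3) coords[row, d, ] <<- origin[d] + dir[d] * scalars
      }
      ## alpha-C helix C-alphas slide along the reference axis
      ac_local <- rbind(c(0, 1.0, 0), c(0, -0.5, 0.8660254),
                        c(0, -0.5, -0.8660254))
      ac_res <- c(.braf$asn, .braf$glu, .braf$val)
      for (j in 1:3)
        set_affine(row_of(ac_res[j], "CA"), glob(ac_local[j, ]), e1,
                   tg$alpha_c)
      ## Phe595 C-alpha rotates about the Gly593->Asp594 (+x) axis
      o2 <- c(0, 30, 0)
      p1 <- o2 + c(-1.3, 3.571, 0); p2 <- o2; p3 <- o2 + c(3.8, 0, 0)
      amp <- 3.8 * 0.866
      p4_test <- p3 + c(1.9, amp * cos(pi / 6), amp * sin(pi / 6))
      sgn <- if (abs(pseudo_dihedral(p1, p2, p3, p4_test) - 30) < 1e-6) 1 else -1
      th <- sgn * tg$dfg * pi / 180
      r595 <- row_of(595L, "CA")
      origin <- glob(p3 + c(1.9, 0, 0))
      for (d in 1:3)
        coords[r595, d, ] <- origin[d] + amp * (cos(th) * e2[d] +
                                                  sin(th) * e3[d])
      ## Glu501 carboxylate slides along +x from the Lys483 NZ
      o3 <- c(0, -30, 0)
      set_affine(row_of(.braf$glu, "OE1"), glob(o3), e1, tg$ke)
      set_affine(row_of(.braf$glu, "OE2"),
                 glob(o3 + c(1.2, 0.5, 0)), e1, tg$ke)
      ## ligand donor rides above OE1 at the per-frame h-bond distance
      r_n4 <- row_of(901L, "N4", het = TRUE)
      if (!is.na(r_n4)) {
        oe1_g <- glob(o3)
        for (d in 1:3)
          coords[r_n4, d, ] <- oe1_g[d] + e1[d] * tg$ke + e3[d] * tg$hb
      }
    }
    kinase_trajectory(topo, coords)
  })
}

# point-target version of a distributional spec (for the topology)
.static_spec <- function(spec) {
  s <- spec
  s$alpha_c <- if (length(spec$alpha_c) == 2) spec$alpha_c[1] else spec$alpha_c
  s$dfg <- if (is.data.frame(spec$dfg)) spec$dfg$mean[1] else spec$dfg
  if (!is.na(spec$ke_occupancy)) s$ke <- 3.0
  s
}

#' Default inter-lobe contact scenario
#'
#' Planted apo/holo inter-lobe contact probabilities whose holo-minus-apo
#' inter-protomer deltas sum to +0.3: the increase is carried by the
#' N-lobe:A to C-lobe:B pair and partially offset by a decrease in the
#' C-lobe:A to C-lobe:B pair, mirroring the stabilisation pattern seen for
#' dimer-compatible inhibitors.
#'
#' @return List with `apo` and `holo` named probability vectors (names
#'   `"N_A-N_B"`, `"N_A-C_B"`, `"C_A-N_B"`, `"C_A-C_B"`).
#' @export
default_contact_scenario <- function() {
  list(apo = c("N_A-N_B" = 0.20, "N_A-C_B" = 0.20,
               "C_A-N_B" = 0.10, "C_A-C_B" = 0.50),
       holo = c("N_A-N_B" = 0.20, "N_A-C_B" = 0.70,
                "C_A-N_B" = 0.10, "C_A-C_B" = 0.30))
}

# four 6-residue blocks (N/C lobe x protomer) on small circles
.block_layout <- function() {
  list(N_A = list(chain = "A", res0 = 100L, center = c(0, 0, 0)),
       C_A = list(chain = "A", res0 = 200L, center = c(0, 60, 0)),
       N_B = list(chain = "B", res0 = 100L, center = c(60, 0, 0)),
       C_B = list(chain = "B", res0 = 200L, center = c(60, 60, 0)))
}

.block_atoms <- function() {
  lay <- .block_layout()
  rows <- list()
  for (b in names(lay)) {
    l <- lay[[b]]
    for (i in 1:6) {
      ang <- (i - 1) * pi / 3
      pos <- l$center + 2.2 * c(cos(ang), sin(ang), 0)
      rows[[length(rows) + 1L]] <-
        .rowvec("CA", "C", "GLY", l$res0 + i, l$chain, pos)
    }
  }
  do.call(rbind, rows)
}

#' Generate an apo-like / holo-like contact-scenario trajectory pair
#'
#' Four planted residue blocks (N/C lobes of protomers A and B) have stable
#' internal contacts; each inter-lobe pair carries a dedicated toggling atom
#' realising the planted Bernoulli contact probability.
#'
#' @param spec A [synthetic_spec()]; `contact_scenario` defaults to
#'   [default_contact_scenario()], `n_frames` frames per condition.
#' @return List with `apo` and `holo` `kinase_trajectory` objects, plus
#'   `blocks` (residue membership) and `protomer_of` (lobe to protomer map).
#' @export
make_contact_scenario <- function(spec = synthetic_spec()) {
  scen <- spec$contact_scenario
  if (is.null(scen)) scen <- default_contact_scenario()
  stopifnot(all(c("apo", "holo") %in% names(scen)))
  lay <- .block_layout()
  for (cond in c("apo", "holo"))
    if (any(scen[[cond]] < 0 | scen[[cond]] > 1))
      stop("generation error: contact probabilities must lie in [0, 1]")

  base_atoms <- .block_atoms()
  pairs <- names(scen$apo)
  stopifnot(identical(sort(pairs), sort(names(scen$holo))))
  # one toggle atom per pair, owned by residue 1 of the second-named block
  toggle_rows <- list()
  for (k in seq_along(pairs)) {
    ij <- strsplit(pairs[k], "-", fixed = TRUE)[[1]]
    owner <- lay[[ij[2]]]
    toggle_rows[[k]] <- .rowvec(paste0("C", k), "C", "GLY",
                                owner$res0 + 1L, owner$chain, owner$center)
  }
  atoms <- rbind(base_atoms, do.call(rbind, toggle_rows))
  topo <- structure_from_atoms(atoms, source_id = "synthetic_contact_blocks",
                               resolution_note = "synthetic generator")
  base <- as.matrix(topo$atoms[, c("x", "y", "z")])
  # row index of each toggle atom in the (re-ordered) structure atom table
  ta <- topo$atoms
  toggle_idx <- vapply(seq_along(pairs), function(k) {
    ij <- strsplit(pairs[k], "-", fixed = TRUE)[[1]]
    owner <- lay[[ij[2]]]
    which(ta$chain == owner$chain & ta$res_num == owner$res0 + 1L &
            ta$atom_name == paste0("C", k))
  }, integer(1))
  # 4 A out of the target block's plane (alternating sides so that two
  # toggles aimed at the same block never collide with each other)
  on_pos <- t(vapply(seq_along(pairs), function(k) {
    ij <- strsplit(pairs[k], "-", fixed = TRUE)[[1]]
    target <- lay[[ij[1]]]
    target$center + c(2.2, 0, 0) + c(0, 0, 4.0 * (-1)^k)
  }, numeric(3)))
  off_pos <- t(vapply(seq_along(pairs), function(k) {
    ij <- strsplit(pairs[k], "-", fixed = TRUE)[[1]]
    lay[[ij[2]]]$center
  }, numeric(3)))

  mk <- function(probs, sub_seed) {
    set.seed(spec$seed + sub_seed)
    coords <- array(rep(base, spec$n_frames),
                    dim = c(nrow(ta), 3, spec$n_frames))
    for (k in seq_along(pairs)) {
      on <- stats::runif(spec$n_frames) < probs[[pairs[k]]]
      for (d in 1:3)
        coords[toggle_idx[k], d, ] <- ifelse(on, on_pos[k, d], off_pos[k, d])
    }
    kinase_trajectory(topo, coords)
  }
  blocks <- lapply(lay, function(l)
    paste0(l$chain, ":", l$res0 + 1:6))
  list(apo = mk(scen$apo, 101L), holo = mk(scen$holo, 202L),
       blocks = blocks,
       protomer_of = vapply(lay, `[[`, "", "chain"))
}
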