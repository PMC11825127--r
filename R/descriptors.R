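# Conformational descriptors of one kinase protomer.
#
# alpha-C position: distance from the Ile582 C-alpha (a stable beta-7
# reference point) to the unweighted centroid of the C-alpha atoms of
# Asn500, Glu501 and Val502 (the centre of the alpha-C helix); < 19.6 A is
# alpha-C-in.  DFG state: C-alpha pseudo-dihedral of Ile592-Gly593-Asp594-
# Phe595 on [0, 360); >= 140 deg is DFG-out.  Salt bridge: Lys483 NZ to the
# nearest Glu501 carboxylate oxygen (4 A cutoff), with the 4.5 A
# minimum-sidechain-distance definition computed alongside.

#' alpha-C helix position of a protomer
#'
#' Euclidean distance (Angstrom) between the Ile582 C-alpha and the
#' unweighted centroid of the C-alpha atoms of Asn500, Glu501 and Val502.
#'
#' @param protomer Protomer atom data frame (see [protomer_atoms()]).
#' @return Distance in Angstrom.
#' @export
alpha_c_distance <- function(protomer) {
  chain <- protomer$chain[1L]
  ref <- get_atom(protomer, chain, .braf$ref, "CA")
  cas <- vapply(c(.braf$asn, .braf$glu, .braf$val),
                function(r) get_atom(protomer, chain, r, "CA"), numeric(3))
  centroid <- rowMeans(cas)
  sqrt(sum((ref - centroid)^2))
}

#' Classify the alpha-C helix state
#'
#' @param distance alpha-C position in Angstrom.
#' @param boundary State boundary (default 19.6 A); `in` is strict
#'   (`distance < boundary`), the boundary itself is `out`.
#' @return `"in"` or `"out"`.
#' @export
classify_alpha_c <- function(distance, boundary = 19.6) {
  if (any(!is.finite(distance)) || any(distance < 0))
    stop("alpha-C distance must be finite and non-negative")
  ifelse(distance < boundary, "in", "out")
}

#' Torsion angle of four points on [0, 360)
#'
#' Standard right-hand (IUPAC) torsion of p1-p2-p3-p4, mapped from
#' (-180, 180] to [0, 360) by adding 360 to negative values.  Invariant under
#' common rigid rotation and translation.
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors.
#' @return Angle in degrees in [0, 360).
#' @export
pseudo_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12)
    stop("undefined dihedral: three consecutive points are collinear")
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang < 0) ang <- ang + 360
  if (ang >= 360) ang <- ang - 360
  ang
}

#' DFG C-alpha pseudo-dihedral of a protomer
#'
#' Torsion of the C-alpha atoms of Ile592, Gly593, Asp594 and Phe595.
#'
#' @inheritParams alpha_c_distance
#' @return Angle in degrees in [0, 360).
#' @export
dfg_pseudo_dihedral <- function(protomer) {
  chain <- protomer$chain[1L]
  ca <- lapply(.braf$dfg, function(r) get_atom(protomer, chain, r, "CA"))
  pseudo_dihedral(ca[[1]], ca[[2]], ca[[3]], ca[[4]])
}

#' Classify the DFG state from the pseudo-dihedral
#'
#' @param angle Degrees in [0, 360).
#' @param cutoff State boundary (default 140 deg); `out` is closed
#'   (`angle >= cutoff`).
#' @return `"in"` or `"out"`.
#' @export
classify_dfg <- function(angle, cutoff = 140) {
  if (any(!is.finite(angle)) || any(angle < 0) || any(angle >= 360))
    stop("DFG pseudo-dihedral must lie in [0, 360)")
  ifelse(angle >= cutoff, "out", "in")
}

# Sidechain heavy atoms = everything beyond C-alpha (Cbeta onward); the
# backbone set and whether Cbeta counts is configurable via `from`.
.sidechain_atoms <- function(protomer, resnum, from = "CB") {
  bb <- c("N", "CA", "C", "O", "OXT")
  a <- protomer[protomer$res_num == resnum & !(protomer$atom_name %in% bb), ,
                drop = FALSE]
  if (from != "CB") a  # reserved for alternative conventions
  a
}

#' Lys483-Glu501 distances
#'
#' Two salt-bridge metrics: the distance from the Lys483 NZ nitrogen to the
#' nearest Glu501 carboxylate oxygen (OE1/OE2), and the minimum distance over
#' all sidechain heavy-atom pairs of the two residues (sidechain = heavy
#' atoms beyond the C-alpha).
#'
#' @inheritParams alpha_c_distance
#' @return Named numeric vector `c(ke_no, ke_min_sidechain)` in Angstrom.
#' @export
ke_distances <- function(protomer) {
  chain <- protomer$chain[1L]
  nz <- get_atom(protomer, chain, .braf$lys, "NZ")
  oe <- protomer[protomer$res_num == .braf$glu &
                   protomer$atom_name %in% c("OE1", "OE2"), , drop = FALSE]
  if (nrow(oe) == 0L)
    stop("descriptor unavailable: Glu", .braf$glu,
         " carboxylate oxygens missing in chain ", chain)
  d_no <- min(sqrt((oe$x - nz[1])^2 + (oe$y - nz[2])^2 + (oe$z - nz[3])^2))
  k_sc <- .sidechain_atoms(protomer, .braf$lys)
  e_sc <- .sidechain_atoms(protomer, .braf$glu)
  if (nrow(k_sc) == 0L || nrow(e_sc) == 0L)
    stop("descriptor unavailable: sidechain atoms of Lys", .braf$lys,
         " or Glu", .braf$glu, " missing in chain ", chain)
  dm <- .min_pair_distance(k_sc, e_sc)
  c(ke_no = d_no, ke_min_sidechain = dm)
}

# min over all heavy-atom pairs of two atom tables
.min_pair_distance <- function(a, b) {
  ax <- as.matrix(a[, c("x", "y", "z")])
  bx <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(ax^2), rowSums(bx^2), "+") - 2 * (ax %*% t(bx))
  sqrt(max(0, min(d2)))
}

#' All conformational descriptors of one protomer
#'
#' Computes the alpha-C position and state, both salt-bridge metrics with
#' their 4.0/4.5 A flags, and the DFG pseudo-dihedral and state.  Individual
#' descriptor failures (e.g. residues in an unresolved activation loop) are
#' recorded as `NA` rather than aborting the whole record.
#'
#' @inheritParams alpha_c_distance
#' @param alpha_c_boundary alpha-C in/out boundary (A).
#' @param dfg_cutoff DFG in/out boundary (degrees).
#' @param sb_cutoff NZ-carboxylate salt-bridge cutoff (A).
#' @param sb_sidechain_cutoff minimum-sidechain salt-bridge cutoff (A).
#' @return A `protomer_geometry` object (list of descriptor fields plus
#'   `unavailable`, the names of descriptors that could not be computed).
#' @export
compute_descriptors <- function(protomer, alpha_c_boundary = 19.6,
                                dfg_cutoff = 140, sb_cutoff = 4.0,
                                sb_sidechain_cutoff = 4.5) {
  unavailable <- character()
  grab <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unavailable <<- c(unavailable, name)
      NA_real_
    })
  }
  d_ac <- grab("alpha_c_distance", alpha_c_distance(protomer))
  ke <- grab("ke_distances", ke_distances(protomer))
  dih <- grab("dfg_pseudo_dihedral", dfg_pseudo_dihedral(protomer))
  if (length(ke) == 1L) ke <- c(ke_no = NA_real_, ke_min_sidechain = NA_real_)
  out <- list(
    chain = protomer$chain[1L],
    alpha_c_distance = d_ac,
    alpha_c_state = if (is.na(d_ac)) NA_character_
                    else classify_alpha_c(d_ac, alpha_c_boundary),
    ke_no_distance = unname(ke["ke_no"]),
    ke_min_sidechain_distance = unname(ke["ke_min_sidechain"]),
    salt_bridge_4A = if (is.na(ke["ke_no"])) NA else unname(ke["ke_no"]) <= sb_cutoff,
    salt_bridge_45A = if (is.na(ke["ke_min_sidechain"])) NA
                      else unname(ke["ke_min_sidechain"]) <= sb_sidechain_cutoff,
    dfg_pseudo_dihedral = dih,
    dfg_state = if (is.na(dih)) NA_character_ else classify_dfg(dih, dfg_cutoff),
    unavailable = unavailable)
  class(out) <- "protomer_geometry"
  out
}

#' @export
print.protomer_geometry <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "unavailable" else sprintf("%.2f", v)
  cat("protomer_geometry (chain ", x$chain, ")\n", sep = "")
  cat("  alpha-C position: ", fmt(x$alpha_c_distance), " A  [",
      ifelse(is.na(x$alpha_c_state), "?", x$alpha_c_state), "]\n", sep = "")
  cat("  K-E (NZ..OE):     ", fmt(x$ke_no_distance), " A  salt bridge (4 A): ",
      x$salt_bridge_4A, "\n", sep = "")
  cat("  K-E min sidechain:", fmt(x$ke_min_sidechain_distance),
      " A  salt bridge (4.5 A): ", x$salt_bridge_45A, "\n", sep = "")
  cat("  DFG pseudo-dihedral: ",
      if (is.na(x$dfg_pseudo_dihedral)) "unavailable"
      else sprintf("%.1f deg", x$dfg_pseudo_dihedral),
      "  [", ifelse(is.na(x$dfg_state), "?", x$dfg_state), "]\n", sep = "")
  if (length(x$unavailable))
    cat("  unavailable:", paste(x$unavailable, collapse = ", "), "\n")
  invisible(x)
}

#' Descriptor table for every protomer of one or more structures
#'
#' @param structures A `kinase_structure` or list of them.
#' @param file Optional TSV output path (one row per structure/chain).
#' @param ... Passed to [compute_descriptors()].
#' @return Data frame of descriptors, invisibly written to `file` if given.
#' @export
descriptor_table <- function(structures, file = NULL, ...) {
  if (inherits(structures, "kinase_structure")) structures <- list(structures)
  rows <- list()
  for (s in structures) {
    for (ch in s$protomer_chains) {
      g <- compute_descriptors(protomer_atoms(s, ch), ...)
      rows[[length(rows) + 1L]] <- data.frame(
        structure = s$source_id, chain = ch,
        alpha_c_distance = g$alpha_c_distance,
        alpha_c_state = g$alpha_c_state,
        ke_no_distance = g$ke_no_distance,
        ke_min_sidechain_distance = g$ke_min_sidechain_distance,
        salt_bridge_4A = g$salt_bridge_4A,
        salt_bridge_45A = g$salt_bridge_45A,
        dfg_pseudo_dihedral = g$dfg_pseudo_dihedral,
        dfg_state = g$dfg_state, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (!is.null(file)) .write_tsv(tab, file)
  tab
}
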