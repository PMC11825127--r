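# Protein-ligand interaction fingerprints.
#
# Categories follow the ligand's perspective, as in KLIFS-style fingerprint
# matrices: `h_donor` means the ligand donates a hydrogen bond to the
# residue, `h_acceptor` means the ligand accepts one, `hydrophobic` is a
# carbon-carbon contact.  H-bonds use a heavy-atom donor-acceptor cutoff of
# 3.5 A; hydrophobic contacts use 4.0 A when both carbons are aromatic and
# 4.5 A otherwise (aromatic face-to-face contacts are reported as
# hydrophobic, with no separate pi-stacking category).

# Fixed protein donor/acceptor typing.  Backbone N donates (except proline),
# backbone O (and OXT) accepts.  His ring nitrogens are treated as both
# donor and acceptor because the protonation state is unknown in a crystal.
.protein_polar <- list(
  donors = list(
    SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG", ASN = "ND2",
    GLN = "NE2", LYS = "NZ", ARG = c("NE", "NH1", "NH2"), TRP = "NE1",
    HIS = c("ND1", "NE2")),
  acceptors = list(
    SER = "OG", THR = "OG1", TYR = "OH", ASN = "OD1", GLN = "OE1",
    ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"),
    MET = "SD"))

# Aromatic sidechain carbons per residue.
.protein_aromatic <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))

.match_residue_atoms <- function(protomer, table) {
  hit <- rep(FALSE, nrow(protomer))
  for (res in names(table))
    hit <- hit | (protomer$res_name == res & protomer$atom_name %in% table[[res]])
  hit
}

.protein_donor_atoms <- function(protomer) {
  bbN <- protomer$atom_name == "N" & protomer$res_name != "PRO"
  protomer[bbN | .match_residue_atoms(protomer, .protein_polar$donors), ,
           drop = FALSE]
}

.protein_acceptor_atoms <- function(protomer) {
  bbO <- protomer$atom_name %in% c("O", "OXT")
  protomer[bbO | .match_residue_atoms(protomer, .protein_polar$acceptors), ,
           drop = FALSE]
}

.pair_distances <- function(a, b) {
  ax <- as.matrix(a[, c("x", "y", "z")])
  bx <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(ax^2), rowSums(bx^2), "+") - 2 * (ax %*% t(bx))
  sqrt(pmax(d2, 0))
}

#' Hydrogen-bond contacts between a protomer and a ligand
#'
#' Heavy-atom donor-acceptor pairs within the cutoff.  Each row records the
#' protein atom, the ligand atom, the distance and the direction
#' (`"ligand_donates"` or `"protein_donates"`); a pair where both sides can
#' both donate and accept yields one row per admissible direction.
#'
#' @param protomer Protomer atom data frame.
#' @param ligand A `ligand_record` with donor/acceptor annotations.
#' @param cutoff Donor-acceptor heavy-atom distance cutoff in A (default 3.5).
#' @return Data frame with columns `res_num`, `res_name`, `protein_atom`,
#'   `ligand_atom`, `distance`, `direction`.
#' @export
hbond_contacts <- function(protomer, ligand, cutoff = 3.5) {
  stopifnot(inherits(ligand, "ligand_record"))
  lig <- ligand$atoms
  out <- list()
  scan <- function(prot_side, lig_names, direction) {
    la <- lig[lig$atom_name %in% lig_names, , drop = FALSE]
    if (nrow(prot_side) == 0L || nrow(la) == 0L) return(NULL)
    d <- .pair_distances(prot_side, la)
    hit <- which(d <= cutoff, arr.ind = TRUE)
    if (nrow(hit) == 0L) return(NULL)
    data.frame(res_num = prot_side$res_num[hit[, 1]],
               res_name = prot_side$res_name[hit[, 1]],
               protein_atom = prot_side$atom_name[hit[, 1]],
               ligand_atom = la$atom_name[hit[, 2]],
               distance = d[hit], direction = direction,
               stringsAsFactors = FALSE)
  }
  out$ld <- scan(.protein_acceptor_atoms(protomer), ligand$donor_atoms,
                 "ligand_donates")
  out$pd <- scan(.protein_donor_atoms(protomer), ligand$acceptor_atoms,
                 "protein_donates")
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(res_num = integer(), res_name = character(),
                      protein_atom = character(), ligand_atom = character(),
                      distance = numeric(), direction = character(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res[order(res$res_num, res$distance), , drop = FALSE]
}

#' Hydrophobic contacts between a protomer and a ligand
#'
#' Residues with at least one carbon-carbon pair within the applicable
#' cutoff: the aromatic cutoff when both atoms are aromatic, the
#' non-aromatic cutoff otherwise.
#'
#' @inheritParams hbond_contacts
#' @param aromatic_cutoff Cutoff for aromatic-aromatic carbon pairs (A).
#' @param nonaromatic_cutoff Cutoff for all other carbon pairs (A).
#' @return Integer vector of residue numbers in contact (named by residue
#'   name).
#' @export
hydrophobic_contacts <- function(protomer, ligand, aromatic_cutoff = 4.0,
                                 nonaromatic_cutoff = 4.5) {
  pc <- protomer[protomer$element == "C", , drop = FALSE]
  lc <- ligand$atoms[ligand$atoms$element == "C", , drop = FALSE]
  if (nrow(pc) == 0L || nrow(lc) == 0L)
    return(stats::setNames(integer(), character()))
  d <- .pair_distances(pc, lc)
  p_arom <- .match_residue_atoms(pc, .protein_aromatic)
  l_arom <- lc$atom_name %in% ligand$aromatic_atoms
  cut <- ifelse(outer(p_arom, l_arom, "&"), aromatic_cutoff, nonaromatic_cutoff)
  hit_rows <- which(apply(d <= cut, 1, any))
  res <- unique(data.frame(n = pc$res_num[hit_rows],
                           nm = pc$res_name[hit_rows]))
  res <- res[order(res$n), , drop = FALSE]
  stats::setNames(res$n, res$nm)
}

#' Full protein-ligand interaction fingerprint
#'
#' Merges hydrogen-bond and hydrophobic contacts into a per-residue category
#' map and sets the three special h-bond flags the selectivity analysis
#' uses: the ligand-to-Glu501 carboxylate h-bond, the Asp594 backbone h-bond
#' (and its direction), and the ligand-to-His574 backbone-carbonyl h-bond.
#'
#' @inheritParams hydrophobic_contacts
#' @param hbond_cutoff Donor-acceptor cutoff in A.
#' @return An `interaction_fingerprint`: list with `entries` (data frame of
#'   residue/category rows), `ligand_id`, `glu501_hbond`,
#'   `asp594_backbone_hbond` (`"ligand_accepts"`, `"ligand_donates"` or
#'   `"none"`) and `his574_backbone_hbond`.
#' @export
build_fingerprint <- function(protomer, ligand, hbond_cutoff = 3.5,
                              aromatic_cutoff = 4.0, nonaromatic_cutoff = 4.5) {
  hb <- hbond_contacts(protomer, ligand, cutoff = hbond_cutoff)
  hp <- hydrophobic_contacts(protomer, ligand, aromatic_cutoff,
                             nonaromatic_cutoff)
  cats <- list()
  add <- function(resnum, resname, cat) {
    k <- as.character(resnum)
    cur <- cats[[k]]
    cats[[k]] <<- list(res_name = resname,
                       set = union(if (is.null(cur)) character() else cur$set, cat))
  }
  if (nrow(hb)) {
    for (i in seq_len(nrow(hb)))
      add(hb$res_num[i], hb$res_name[i],
          if (hb$direction[i] == "ligand_donates") "h_donor" else "h_acceptor")
  }
  if (length(hp))
    for (i in seq_along(hp)) add(hp[i], names(hp)[i], "hydrophobic")
  entries <- if (length(cats)) {
    data.frame(
      chain = protomer$chain[1L],
      res_num = as.integer(names(cats)),
      res_name = vapply(cats, function(e) e$res_name, ""),
      categories = vapply(cats, function(e)
        paste(sort(e$set), collapse = ","), ""),
      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(chain = character(), res_num = integer(),
               res_name = character(), categories = character(),
               stringsAsFactors = FALSE)
  }
  entries <- entries[order(entries$res_num), , drop = FALSE]

  glu_hb <- any(hb$direction == "ligand_donates" & hb$res_num == .braf$glu &
                  hb$protein_atom %in% c("OE1", "OE2"))
  asp_rows <- hb[hb$res_num == 594L, , drop = FALSE]
  asp <- if (any(asp_rows$direction == "protein_donates" &
                 asp_rows$protein_atom == "N")) "ligand_accepts"
         else if (any(asp_rows$direction == "ligand_donates" &
                      asp_rows$protein_atom %in% c("O", "OXT", "N")))
           "ligand_donates"
         else "none"
  his_hb <- any(hb$direction == "ligand_donates" & hb$res_num == .braf$his &
                  hb$protein_atom == "O")
  out <- list(entries = entries, ligand_id = ligand$res_name,
              chain = protomer$chain[1L],
              glu501_hbond = glu_hb, asp594_backbone_hbond = asp,
              his574_backbone_hbond = his_hb, hbonds = hb)
  class(out) <- "interaction_fingerprint"
  out
}

#' @export
print.interaction_fingerprint <- function(x, ...) {
  cat("interaction_fingerprint:", x$ligand_id, "vs chain", x$chain, "\n")
  cat("  residues in contact:", nrow(x$entries), "\n")
  cat("  Glu501 h-bond (ligand donates):", x$glu501_hbond, "\n")
  cat("  Asp594 backbone h-bond:", x$asp594_backbone_hbond, "\n")
  cat("  His574 backbone-carbonyl h-bond:", x$his574_backbone_hbond, "\n")
  invisible(x)
}

#' Default KLIFS-style back-pocket residue map (BRAF numbering)
#'
#' The four back pockets behind the ATP site.  Exact residue membership is
#' configuration, not code: the shipped map is read from
#' `inst/extdata/backpockets.tsv` and can be replaced by any TSV with
#' columns `pocket` and `res_num`.  BP-III is the subpocket occupied by the
#' Phe595 sidechain in the DFG-in state, so it is only open to ligands in
#' DFG-out structures.
#'
#' @param tsv Optional path to an alternative pocket definition TSV.
#' @param contact_cutoff Heavy-atom cutoff (A) used for occupancy.
#' @return A `backpocket_map`: list with `pockets` (named list of integer
#'   residue vectors) and `contact_cutoff`.
#' @export
backpocket_map <- function(tsv = NULL, contact_cutoff = 4.5) {
  if (is.null(tsv))
    tsv <- system.file("extdata", "backpockets.tsv", package = "braftools",
                       mustWork = TRUE)
  tab <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  stopifnot(all(c("pocket", "res_num") %in% names(tab)))
  pockets <- split(as.integer(tab$res_num), tab$pocket)
  out <- list(pockets = pockets, contact_cutoff = contact_cutoff)
  class(out) <- "backpocket_map"
  out
}

#' Back-pocket occupancy of a ligand
#'
#' A pocket is occupied when any ligand heavy atom lies within the map's
#' contact cutoff of any heavy atom of the pocket's residues.
#'
#' @inheritParams hbond_contacts
#' @param pocket_map A `backpocket_map`.
#' @return Character vector of occupied pocket labels (possibly empty).
#' @export
pocket_occupancy <- function(ligand, pocket_map, protomer) {
  stopifnot(inherits(pocket_map, "backpocket_map"))
  occupied <- character()
  for (p in names(pocket_map$pockets)) {
    res <- protomer[protomer$res_num %in% pocket_map$pockets[[p]], ,
                    drop = FALSE]
    if (nrow(res) == 0L) next
    if (.min_pair_distance(res, ligand$atoms) <= pocket_map$contact_cutoff)
      occupied <- c(occupied, p)
  }
  occupied
}

#' Write a fingerprint matrix as TSV
#'
#' One row per residue, one column per category (0/1), mirroring a
#' fingerprint heat-map; special flags go to a JSON side-car when `json`
#' is given.
#'
#' @param fp An `interaction_fingerprint`.
#' @param file TSV output path.
#' @param json Optional JSON path for the special h-bond flags.
#' @return `file`, invisibly.
#' @export
write_fingerprint <- function(fp, file, json = NULL) {
  e <- fp$entries
  mat <- data.frame(
    chain = e$chain, res_num = e$res_num, res_name = e$res_name,
    hydrophobic = as.integer(grepl("hydrophobic", e$categories)),
    h_donor = as.integer(grepl("h_donor", e$categories)),
    h_acceptor = as.integer(grepl("h_acceptor", e$categories)))
  .write_tsv(mat, file)
  if (!is.null(json)) {
    .write_json(list(ligand_id = fp$ligand_id, chain = fp$chain,
                     glu501_hbond = fp$glu501_hbond,
                     asp594_backbone_hbond = fp$asp594_backbone_hbond,
                     his574_backbone_hbond = fp$his574_backbone_hbond), json)
  }
  invisible(file)
}
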