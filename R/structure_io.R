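# Residues with special roles in BRAF numbering, used across modules.
.braf <- list(
  lys   = 483L,   # catalytic lysine (NZ)
  glu   = 501L,   # alpha-C glutamate (OE1/OE2 carboxylate)
  asn   = 500L,
  val   = 502L,
  leu   = 505L,
  his   = 574L,   # HRD histidine (backbone carbonyl h-bond acceptor)
  ref   = 582L,   # Ile on beta-7, stable reference for the alpha-C distance
  dfg   = 592:595 # Ile-Gly-Asp-Phe C-alpha pseudo-dihedral quadruple
)

.water_names <- c("HOH", "WAT", "DOD", "H2O")
.ion_names <- c("NA", "CL", "K", "MG", "CA", "ZN", "MN", "FE", "BR", "IOD",
                "CS", "LI", "NI", "CD", "CO", "CU", "SO4", "PO4")

#' Read a kinase structure from PDB or mmCIF
#'
#' Parses a crystal structure (or trajectory topology) and resolves it into
#' protomers (protein chains) and ligand records.  Waters and ions are
#' discarded; alternate locations are collapsed to the highest-occupancy
#' conformer (ties broken by alt-loc identifier order); hydrogens are dropped
#' because every distance criterion downstream is heavy-atom.
#'
#' @param path Path to a PDB or mmCIF file.
#' @param format File format, `"pdb"` or `"mmcif"`; guessed from the file
#'   extension when missing.
#' @param ligand_annotations Named list of ligand donor/acceptor/aromatic
#'   annotations as produced by [ligand_annotation_table()]; annotations for
#'   het-codes found in the file are attached to the ligand records.
#' @param heuristic_typing Fall back to element-based donor/acceptor typing
#'   (N/O atoms) for het-codes absent from the annotation table.
#' @return A `kinase_structure` object: a list with `atoms` (data frame of
#'   heavy atoms), `protomer_chains` (character vector), `ligands` (list of
#'   `ligand_record`), and `source_id`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           ligand_annotations = ligand_annotation_table(),
                           heuristic_typing = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("structure file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "mmcif") suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    else bio3d::read.pdb(path, verbose = FALSE, multi = FALSE),
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  atoms <- .atoms_from_bio3d(pdb)
  structure_from_atoms(atoms, source_id = basename(path),
                       ligand_annotations = ligand_annotations,
                       heuristic_typing = heuristic_typing)
}

# bio3d atom table -> the package's atom data frame
.atoms_from_bio3d <- function(pdb) {
  a <- pdb$atom
  data.frame(
    atom_name = trimws(a$elety),
    element = .infer_element(a),
    res_name = trimws(a$resid),
    res_num = as.integer(a$resno),
    chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
    alt = ifelse(is.na(a$alt), "", a$alt),
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o),
    hetero = a$type == "HETATM",
    stringsAsFactors = FALSE)
}

.infer_element <- function(a) {
  el <- if (!is.null(a$elesy)) trimws(a$elesy) else rep("", nrow(a))
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    # fall back on the atom-name convention: strip digits, first letter(s)
    nm <- gsub("[0-9']", "", trimws(a$elety[miss]))
    two <- toupper(substr(nm, 1, 2))
    el1 <- ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE"),
                  two, toupper(substr(nm, 1, 1)))
    el[miss] <- el1
  }
  # normalise case: "Cl" style
  paste0(substr(el, 1, 1), tolower(substr(el, 2, nchar(el))))
}

#' Build a kinase structure from an atom table
#'
#' Lower-level constructor used by [read_structure()] and the synthetic
#' generator.  Applies the alt-loc, water/ion and hydrogen policies, then
#' partitions atoms into protomers and ligand records.
#'
#' @param atoms Data frame with columns `atom_name`, `element`, `res_name`,
#'   `res_num`, `chain`, `alt`, `x`, `y`, `z`, `occ`, `hetero`.
#' @param source_id Identifier stored on the object (e.g. a file name).
#' @inheritParams read_structure
#' @param resolution_note Free-text provenance note.
#' @return A `kinase_structure`.
#' @export
structure_from_atoms <- function(atoms, source_id = "unknown",
                                 ligand_annotations = ligand_annotation_table(),
                                 heuristic_typing = TRUE,
                                 resolution_note = "") {
  stopifnot(is.data.frame(atoms))
  atoms <- atoms[atoms$element != "H" & atoms$element != "D", , drop = FALSE]
  atoms <- .resolve_altlocs(atoms)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in atom table")
  is_water <- atoms$res_name %in% .water_names
  is_ion <- atoms$hetero & atoms$res_name %in% .ion_names
  atoms <- atoms[!(is_water | is_ion), , drop = FALSE]

  prot <- atoms[!atoms$hetero, , drop = FALSE]
  het <- atoms[atoms$hetero, , drop = FALSE]
  if (nrow(prot) == 0L)
    stop("no protein chain found in ", source_id)
  chains <- sort(unique(prot$chain))

  ligands <- list()
  if (nrow(het) > 0L) {
    key <- paste(het$chain, het$res_name, het$res_num)
    for (k in unique(key)) {
      la <- het[key == k, , drop = FALSE]
      ligands[[length(ligands) + 1L]] <-
        ligand_record(la, annotations = ligand_annotations,
                      heuristic = heuristic_typing)
    }
  }
  out <- list(atoms = rbind(prot, het), protomer_chains = chains,
              ligands = ligands, source_id = source_id,
              resolution_note = resolution_note)
  class(out) <- "kinase_structure"
  out
}

# Highest-occupancy alt-loc wins; ties broken by alt identifier order.
.resolve_altlocs <- function(atoms) {
  alt <- atoms$alt
  if (all(alt == "" | is.na(alt))) return(atoms)
  key <- paste(atoms$chain, atoms$res_num, atoms$res_name, atoms$atom_name)
  ord <- order(key, -atoms$occ, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms[!duplicated(paste(atoms$chain, atoms$res_num, atoms$res_name,
                          atoms$atom_name)), , drop = FALSE]
}

#' Construct a ligand record
#'
#' @param atoms Atom data frame rows belonging to one HETATM residue.
#' @param annotations Named list of annotation entries (see
#'   [ligand_annotation_table()]).
#' @param heuristic Use element-based fallback typing when the het-code is
#'   not annotated.
#' @return A `ligand_record` list with `res_name`, `chain`, `atoms`,
#'   `donor_atoms`, `acceptor_atoms`, `aromatic_atoms`.
#' @export
ligand_record <- function(atoms, annotations = ligand_annotation_table(),
                          heuristic = TRUE) {
  stopifnot(nrow(atoms) > 0L)
  code <- atoms$res_name[1L]
  ann <- annotations[[code]]
  if (is.null(ann)) {
    if (!heuristic)
      stop("no donor/acceptor annotation for ligand het-code ", code,
           " and heuristic typing is disabled")
    no <- atoms$atom_name[atoms$element %in% c("N", "O")]
    ann <- list(donors = atoms$atom_name[atoms$element == "N"],
                acceptors = no, aromatics = character())
  }
  present <- atoms$atom_name
  out <- list(res_name = code, chain = atoms$chain[1L],
              res_num = atoms$res_num[1L], atoms = atoms,
              donor_atoms = intersect(ann$donors, present),
              acceptor_atoms = intersect(ann$acceptors, present),
              aromatic_atoms = intersect(ann$aromatics, present))
  class(out) <- "ligand_record"
  out
}

#' Shipped ligand donor/acceptor/aromatic annotations
#'
#' Hand-curated atom typing for the three exemplar inhibitors used throughout
#' the package: the dimer-selective PHI1, the equipotent LY3009120 (LY) and
#' the monomer-selective vemurafenib (VEM), keyed by the het-codes the
#' synthetic generator writes.  Users may extend the table from a TSV file
#' with columns `code`, `atom`, `role` (`donor`, `acceptor`, `aromatic`;
#' repeated rows per atom allowed).
#'
#' @param tsv Optional path to a TSV extending/overriding the shipped table.
#' @return Named list keyed by het-code; each entry has `donors`, `acceptors`
#'   and `aromatics` character vectors of atom names.
#' @export
ligand_annotation_table <- function(tsv = NULL) {
  tab <- list(
    # amide N-H donor (h-bond to Glu501), amide carbonyl acceptor (from the
    # Asp594 backbone amide), amino N next to the morpholine donating to the
    # His574 backbone carbonyl; aromatic core carbons
    PHI = list(donors = c("N4", "N6"), acceptors = c("O1", "O2", "N5"),
               aromatics = c("C1", "C2", "C3", "C4", "C5", "C6")),
    LY = list(donors = c("N4"), acceptors = c("O1", "N5"),
              aromatics = c("C1", "C2", "C3", "C4", "C5", "C6")),
    # sulfonamide N-H donor; no donor reaches Glu501
    VEM = list(donors = c("N1"), acceptors = c("O1", "O2"),
               aromatics = c("C1", "C2", "C3", "C4", "C5", "C6")))
  tab$PHI1 <- tab$PHI  # full inhibitor name as an alias
  if (!is.null(tsv)) {
    ext <- utils::read.delim(tsv, stringsAsFactors = FALSE)
    stopifnot(all(c("code", "atom", "role") %in% names(ext)))
    for (code in unique(ext$code)) {
      e <- ext[ext$code == code, ]
      tab[[code]] <- list(
        donors = unique(e$atom[e$role == "donor"]),
        acceptors = unique(e$atom[e$role == "acceptor"]),
        aromatics = unique(e$atom[e$role == "aromatic"]))
    }
  }
  tab
}

#' Extract one protomer's atoms
#'
#' @param structure A `kinase_structure`.
#' @param chain Chain identifier of the protomer.
#' @return Data frame of the protomer's protein atoms.
#' @export
protomer_atoms <- function(structure, chain) {
  stopifnot(inherits(structure, "kinase_structure"))
  if (!chain %in% structure$protomer_chains)
    stop("no protomer with chain id '", chain, "' (have: ",
         paste(structure$protomer_chains, collapse = ", "), ")")
  a <- structure$atoms
  a[!a$hetero & a$chain == chain, , drop = FALSE]
}

#' Look up one atom's coordinates
#'
#' @param structure A `kinase_structure` (or a protomer atom data frame).
#' @param chain Chain id.
#' @param resnum Author residue number.
#' @param atom Atom name (e.g. `"CA"`, `"NZ"`).
#' @return Numeric length-3 coordinate vector (Angstrom).
#' @export
get_atom <- function(structure, chain, resnum, atom) {
  a <- if (inherits(structure, "kinase_structure")) structure$atoms else structure
  hit <- a$chain == chain & a$res_num == resnum & a$atom_name == atom
  if (!any(hit)) {
    res_here <- unique(a$res_num[a$chain == chain])
    nearest <- if (length(res_here)) res_here[which.min(abs(res_here - resnum))] else NA
    stop("atom ", atom, " of residue ", resnum, " chain ", chain,
         " not found; nearest residue present in that chain: ", nearest)
  }
  as.numeric(a[which(hit)[1L], c("x", "y", "z")])
}

#' Write a structure (or one frame) as PDB
#'
#' Used for fixture round-trips and by the synthetic generator so the rest of
#' the pipeline only ever consumes standard formats.
#'
#' @param structure A `kinase_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  bio3d::write.pdb(file = path,
                   type = ifelse(a$hetero, "HETATM", "ATOM"),
                   eleno = seq_len(nrow(a)), elety = a$atom_name,
                   resid = a$res_name, chain = a$chain, resno = a$res_num,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   o = a$occ, b = rep(0, nrow(a)), elesy = a$element)
  invisible(path)
}

#' @export
print.kinase_structure <- function(x, ...) {
  cat("kinase_structure:", x$source_id, "\n")
  cat("  protomers:", length(x$protomer_chains),
      paste0("(", paste(x$protomer_chains, collapse = ", "), ")"), "\n")
  cat("  ligands:  ", length(x$ligands),
      if (length(x$ligands))
        paste0("(", paste(vapply(x$ligands, function(l)
          paste0(l$res_name, ":", l$chain), ""), collapse = ", "), ")")
      else "", "\n")
  cat("  atoms:    ", nrow(x$atoms), "(heavy)\n")
  invisible(x)
}

#' @export
print.ligand_record <- function(x, ...) {
  cat("ligand_record:", x$res_name, "chain", x$chain, "-", nrow(x$atoms),
      "atoms;", length(x$donor_atoms), "donors,",
      length(x$acceptor_atoms), "acceptors,",
      length(x$aromatic_atoms), "aromatic\n")
  invisible(x)
}

#' Ligands assigned to one chain
#' @param structure A `kinase_structure`.
#' @param chain Chain id.
#' @param het Optional het-code filter.
#' @return List of `ligand_record`s.
#' @export
chain_ligands <- function(structure, chain, het = NULL) {
  keep <- vapply(structure$ligands, function(l) {
    l$chain == chain && (is.null(het) || l$res_name == het)
  }, logical(1))
  structure$ligands[keep]
}
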