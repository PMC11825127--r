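# Empirical co-crystal-based dimer-selectivity assessment.
#
# The decision rule, applied to a dimeric co-crystal structure:
#   (1) no ligand h-bond to the Glu501 carboxylate        -> monomer_selective
#   (2) h-bond present but the alpha-C position and/or the K-E distance
#       differ between the two protomers by >= threshold  -> equipotent
#   (3) h-bond present and both metrics (nearly) identical
#                                                 -> likely_dimer_selective
# Deviations are rounded to 0.1 A before comparison, matching the precision
# at which such deviations are read off crystal structures; raw values are
# retained in the returned record.

#' Inter-protomer descriptor deviations of a dimer
#'
#' Absolute differences of the alpha-C position and of the Lys483
#' NZ-to-Glu501-carboxylate distance between the two protomers.
#'
#' @param structure A `kinase_structure` with exactly two protomers.
#' @return Named numeric vector `c(delta_alpha_c, delta_ke)` in Angstrom
#'   (full precision, unrounded).
#' @export
protomer_deviations <- function(structure) {
  stopifnot(inherits(structure, "kinase_structure"))
  if (length(structure$protomer_chains) != 2L)
    stop("protomer deviations need exactly 2 protomers, found ",
         length(structure$protomer_chains))
  g <- lapply(structure$protomer_chains, function(ch)
    compute_descriptors(protomer_atoms(structure, ch)))
  vals <- vapply(g, function(x) c(x$alpha_c_distance, x$ke_no_distance),
                 numeric(2))
  if (any(is.na(vals)))
    stop("descriptor unavailable in at least one protomer: ",
         paste(unique(unlist(lapply(g, `[[`, "unavailable"))), collapse = ", "))
  c(delta_alpha_c = abs(vals[1, 1] - vals[1, 2]),
    delta_ke = abs(vals[2, 1] - vals[2, 2]))
}

#' Classify inhibitor selectivity from the co-crystal evidence
#'
#' @param glu501_hbond Does the ligand h-bond the Glu501 carboxylate in at
#'   least one protomer?
#' @param delta_alpha_c Inter-protomer alpha-C position deviation (A).
#' @param delta_ke Inter-protomer K-E distance deviation (A).
#' @param threshold Deviation threshold in A (default 0.3).
#' @return A `selectivity_call`: list with `label` (one of
#'   `"monomer_selective"`, `"equipotent"`, `"likely_dimer_selective"`), the
#'   evidence fields, and `evidence_notes` naming the branch that fired.
#' @export
classify_selectivity <- function(glu501_hbond, delta_alpha_c, delta_ke,
                                 threshold = 0.3) {
  stopifnot(is.logical(glu501_hbond), length(glu501_hbond) == 1L)
  if (!is.finite(delta_alpha_c) || !is.finite(delta_ke) ||
      delta_alpha_c < 0 || delta_ke < 0)
    stop("protomer deviations must be finite and non-negative")
  r_ac <- round(delta_alpha_c, 1)
  r_ke <- round(delta_ke, 1)
  if (!glu501_hbond) {
    label <- "monomer_selective"
    note <- "no ligand h-bond to the Glu501 carboxylate"
  } else if (r_ac >= threshold || r_ke >= threshold) {
    label <- "equipotent"
    note <- sprintf(paste0("Glu501 h-bond present but protomer descriptors",
                           " inconsistent (delta alpha-C %.1f A, delta K-E",
                           " %.1f A, threshold %.1f A)"), r_ac, r_ke, threshold)
  } else {
    label <- "likely_dimer_selective"
    note <- sprintf(paste0("Glu501 h-bond present and protomer descriptors",
                           " identical within %.1f A (delta alpha-C %.1f A,",
                           " delta K-E %.1f A)"), threshold, r_ac, r_ke)
  }
  out <- list(label = label, glu501_hbond = glu501_hbond,
              delta_alpha_c = delta_alpha_c, delta_ke = delta_ke,
              delta_alpha_c_rounded = r_ac, delta_ke_rounded = r_ke,
              threshold = threshold, evidence_notes = note)
  class(out) <- "selectivity_call"
  out
}

#' End-to-end selectivity call on a dimeric co-crystal structure
#'
#' Computes the fingerprint of the named ligand against its protomer (the
#' Glu501 h-bond counts if present in at least one protomer), the
#' inter-protomer deviations, and applies the decision rule.
#'
#' @param structure A dimeric `kinase_structure`.
#' @param ligand_id Het-code of the inhibitor.
#' @param threshold Deviation threshold (A).
#' @return A `selectivity_call`.
#' @export
classify_structure <- function(structure, ligand_id, threshold = 0.3) {
  ligs <- Filter(function(l) l$res_name == ligand_id, structure$ligands)
  if (length(ligs) == 0L)
    stop("no ligand with het-code ", ligand_id, " in ", structure$source_id)
  hb <- any(vapply(ligs, function(l) {
    build_fingerprint(protomer_atoms(structure, l$chain), l)$glu501_hbond
  }, logical(1)))
  dev <- protomer_deviations(structure)
  classify_selectivity(hb, dev[["delta_alpha_c"]], dev[["delta_ke"]],
                       threshold = threshold)
}

#' @export
print.selectivity_call <- function(x, ...) {
  cat("selectivity_call:", x$label, "\n")
  cat("  Glu501 h-bond:", x$glu501_hbond, "\n")
  cat(sprintf("  delta alpha-C: %.2f A (rounded %.1f)\n",
              x$delta_alpha_c, x$delta_alpha_c_rounded))
  cat(sprintf("  delta K-E:     %.2f A (rounded %.1f)\n",
              x$delta_ke, x$delta_ke_rounded))
  cat("  threshold:", x$threshold, "A\n")
  cat("  evidence:", x$evidence_notes, "\n")
  invisible(x)
}
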