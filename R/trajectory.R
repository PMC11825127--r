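# Per-frame descriptor series and distribution summaries for MD
# trajectories.  A trajectory is carried as a `kinase_trajectory`: the
# topology (a kinase_structure) plus an n_atoms x 3 x n_frames coordinate
# array, read from multi-model PDB or DCD, or built by the synthetic
# generator.

#' Read a trajectory (multi-model PDB or DCD)
#'
#' @param path Trajectory file: a multi-model PDB, or a DCD with `topology`
#'   supplying the atom metadata.
#' @param topology A `kinase_structure` giving atom identities; required for
#'   DCD, optional for multi-model PDB (the first model is used when
#'   missing).
#' @param format `"auto"`, `"pdb"` or `"dcd"`.
#' @return A `kinase_trajectory`: list with `topology`, `coords`
#'   (`n_atoms x 3 x n_frames`), `n_frames`.
#' @export
read_trajectory <- function(path, topology = NULL,
                            format = c("auto", "pdb", "dcd")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "dcd") "dcd" else "pdb"
  }
  if (format == "dcd") {
    if (is.null(topology))
      stop("a topology structure is required to read a DCD trajectory")
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (is.null(topology)) {
      topo_atoms <- .atoms_from_bio3d(pdb)
      topology <- structure_from_atoms(topo_atoms, source_id = basename(path))
    }
  }
  xyz <- as.matrix(xyz)
  n_at <- ncol(xyz) / 3L
  if (n_at != nrow(topology$atoms))
    stop("topology/frame atom mismatch: topology has ", nrow(topology$atoms),
         " heavy atoms, frames have ", n_at)
  coords <- aperm(array(t(xyz), dim = c(3L, n_at, nrow(xyz))), c(2L, 1L, 3L))
  kinase_trajectory(topology, coords)
}

#' Construct a trajectory object from a topology and coordinate array
#'
#' @param topology A `kinase_structure`.
#' @param coords Numeric array `n_atoms x 3 x n_frames` matching the
#'   topology atom order.
#' @return A `kinase_trajectory`.
#' @export
kinase_trajectory <- function(topology, coords) {
  stopifnot(inherits(topology, "kinase_structure"),
            length(dim(coords)) == 3L, dim(coords)[2] == 3L,
            dim(coords)[1] == nrow(topology$atoms))
  if (dim(coords)[3] < 1L) stop("empty trajectory: no frames")
  out <- list(topology = topology, coords = coords,
              n_frames = dim(coords)[3])
  class(out) <- "kinase_trajectory"
  out
}

#' @export
print.kinase_trajectory <- function(x, ...) {
  cat("kinase_trajectory:", x$n_frames, "frames x",
      dim(x$coords)[1], "atoms (topology:", x$topology$source_id, ")\n")
  invisible(x)
}

#' Write a trajectory as multi-model PDB
#'
#' @param traj A `kinase_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  a <- traj$topology$atoms
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in seq_len(traj$n_frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj$coords[, , f]
    lines <- sprintf(
      "%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      ifelse(a$hetero, "HETATM", "ATOM"), seq_len(nrow(a)),
      ifelse(nchar(a$atom_name) < 4, paste0(" ", a$atom_name), a$atom_name),
      a$res_name, a$chain, a$res_num, xyz[, 1], xyz[, 2], xyz[, 3],
      a$occ, 0, toupper(a$element))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# Resolve atom row indices once so per-frame descriptor extraction is a
# plain array lookup.
.descriptor_indices <- function(topology, chain) {
  a <- topology$atoms
  idx <- function(resnum, atom) {
    i <- which(!a$hetero & a$chain == chain & a$res_num == resnum &
                 a$atom_name == atom)
    if (length(i)) i[1L] else NA_integer_
  }
  list(
    ref_ca = idx(.braf$ref, "CA"),
    ac_ca = vapply(c(.braf$asn, .braf$glu, .braf$val),
                   function(r) idx(r, "CA"), integer(1)),
    dfg_ca = vapply(.braf$dfg, function(r) idx(r, "CA"), integer(1)),
    nz = idx(.braf$lys, "NZ"),
    oe = which(!a$hetero & a$chain == chain & a$res_num == .braf$glu &
                 a$atom_name %in% c("OE1", "OE2")))
}

#' Extract per-frame descriptor series from a trajectory
#'
#' Computes, for every protomer and frame, the alpha-C position, DFG
#' pseudo-dihedral, Lys483-Glu501 NZ-carboxylate distance, and (when a
#' ligand with annotated donor atoms is bound to the protomer) the minimum
#' distance from the ligand's donor group to the Glu501 carboxylate oxygens.
#' The first `trim_fraction` of frames is discarded (equilibration trim).
#'
#' @param traj A `kinase_trajectory`.
#' @param trim_fraction Fraction of initial frames to drop (default 0.4,
#'   i.e. analyse the final 60 percent).
#' @param replica_id Integer tag stored on the series.
#' @param glu501_donor_atoms Optional named list (het-code to atom-name
#'   vector) overriding the donor-group atoms used for the ligand-Glu501
#'   distance; defaults to each ligand's annotated donors.
#' @return A list of `descriptor_series` objects, one per protomer, each a
#'   data frame-bearing list with `frames` (columns `frame`,
#'   `alpha_c_distance`, `dfg_dihedral`, `ke_no_distance`,
#'   `ligand_glu501_min_distance`).
#' @export
extract_series <- function(traj, trim_fraction = 0.4, replica_id = 1L,
                           glu501_donor_atoms = NULL) {
  stopifnot(inherits(traj, "kinase_trajectory"),
            trim_fraction >= 0, trim_fraction < 1)
  n <- traj$n_frames
  first <- floor(n * trim_fraction) + 1L
  keep <- first:n
  topo <- traj$topology
  a <- topo$atoms
  out <- list()
  for (ch in topo$protomer_chains) {
    ix <- .descriptor_indices(topo, ch)
    lig <- chain_ligands(topo, ch)
    lig_idx <- NULL
    if (length(lig)) {
      l <- lig[[1L]]
      donors <- if (!is.null(glu501_donor_atoms) &&
                    !is.null(glu501_donor_atoms[[l$res_name]]))
        glu501_donor_atoms[[l$res_name]] else l$donor_atoms
      lig_idx <- which(a$hetero & a$chain == ch & a$res_name == l$res_name &
                         a$atom_name %in% donors)
      if (length(lig_idx) == 0L) lig_idx <- NULL
    }
    have_ac <- !is.na(ix$ref_ca) && !any(is.na(ix$ac_ca))
    have_dfg <- !any(is.na(ix$dfg_ca))
    have_ke <- !is.na(ix$nz) && length(ix$oe) > 0
    m <- length(keep)
    ac <- dih <- ke <- lg <- rep(NA_real_, m)
    for (j in seq_len(m)) {
      xyz <- traj$coords[, , keep[j]]
      if (have_ac) {
        centroid <- colMeans(xyz[ix$ac_ca, , drop = FALSE])
        ac[j] <- sqrt(sum((xyz[ix$ref_ca, ] - centroid)^2))
      }
      if (have_dfg)
        dih[j] <- pseudo_dihedral(xyz[ix$dfg_ca[1], ], xyz[ix$dfg_ca[2], ],
                                  xyz[ix$dfg_ca[3], ], xyz[ix$dfg_ca[4], ])
      if (have_ke) {
        d <- sweep(xyz[ix$oe, , drop = FALSE], 2, xyz[ix$nz, ])
        ke[j] <- sqrt(min(rowSums(d^2)))
      }
      if (!is.null(lig_idx) && length(ix$oe)) {
        oe <- xyz[ix$oe, , drop = FALSE]
        ld <- xyz[lig_idx, , drop = FALSE]
        d2 <- outer(rowSums(oe^2), rowSums(ld^2), "+") - 2 * (oe %*% t(ld))
        lg[j] <- sqrt(max(0, min(d2)))
      }
    }
    s <- list(replica_id = replica_id, protomer_id = ch,
              trim_policy = sprintf("dropped first %.0f%% (%d of %d frames)",
                                    100 * trim_fraction, first - 1L, n),
              frames = data.frame(frame = keep, alpha_c_distance = ac,
                                  dfg_dihedral = dih, ke_no_distance = ke,
                                  ligand_glu501_min_distance = lg))
    class(s) <- "descriptor_series"
    out[[ch]] <- s
  }
  out
}

#' @export
print.descriptor_series <- function(x, ...) {
  cat("descriptor_series: replica", x$replica_id, "protomer", x$protomer_id,
      "-", nrow(x$frames), "frames (", x$trim_policy, ")\n")
  invisible(x)
}

#' Density-normalised histogram of a descriptor
#'
#' 50 equal-width bins spanning the pooled data range by default (supply
#' `edges` to share binning across conditions).  Densities integrate to one.
#'
#' @param values Numeric vector (pooled over replicas and, for dimers, both
#'   protomers); `NA`s dropped.
#' @param n_bins Number of bins (default 50).
#' @param edges Optional explicit bin edges (length `n_bins + 1`).
#' @return A `histogram_summary`: list with `bin_edges`, `densities`,
#'   `counts`, `n_frames`.
#' @export
descriptor_histogram <- function(values, n_bins = 50, edges = NULL) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("empty data: no finite values to bin")
  if (is.null(edges)) {
    rng <- range(values)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  }
  h <- graphics::hist(values, breaks = edges, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  out <- list(bin_edges = h$breaks, densities = h$density, counts = h$counts,
              n_frames = length(values))
  class(out) <- "histogram_summary"
  out
}

#' Replica-wise state probability with n-replica spread
#'
#' Fraction of frames satisfying a predicate, per replica, with the mean and
#' the sample standard deviation across replicas (the error bars used for
#' salt-bridge occupancy).
#'
#' @param series_list List of `descriptor_series` (one or more per replica;
#'   several series sharing a `replica_id` - e.g. both protomers of a dimer -
#'   are pooled within that replica).
#' @param predicate Function mapping the series `frames` data frame to a
#'   logical vector (e.g. `function(f) f$ke_no_distance <= 4`).
#' @return A `probability_estimate`: list with `per_replica`, `mean`, `sd`,
#'   `n_replicas`.
#' @export
state_probability <- function(series_list, predicate) {
  if (inherits(series_list, "descriptor_series"))
    series_list <- list(series_list)
  stopifnot(length(series_list) >= 1L)
  reps <- vapply(series_list, function(s) s$replica_id, numeric(1))
  per <- vapply(split(series_list, reps), function(group) {
    hits <- unlist(lapply(group, function(s) {
      v <- predicate(s$frames)
      if (length(v) == 0L)
        stop("zero frames in replica ", group[[1]]$replica_id)
      v
    }))
    mean(hits)
  }, numeric(1))
  out <- list(per_replica = unname(per), mean = mean(per),
              sd = if (length(per) > 1L) stats::sd(per) else 0,
              n_replicas = length(per))
  class(out) <- "probability_estimate"
  out
}

#' @export
print.probability_estimate <- function(x, ...) {
  cat(sprintf("probability_estimate: mean %.3f, sd %.3f (n=%d replicas: %s)\n",
              x$mean, x$sd, x$n_replicas,
              paste(sprintf("%.3f", x$per_replica), collapse = ", ")))
  invisible(x)
}

#' Two-dimensional binned density
#'
#' Normalised 2-D histogram of paired descriptor series (e.g. alpha-C
#' position against the ligand-Glu501 donor distance).  With shared edges
#' the x-marginal equals the 1-D histogram exactly.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param n_bins Bins per axis (default 50).
#' @param x_edges,y_edges Optional explicit edges.
#' @return A `density2d`: list with `x_edges`, `y_edges`, `density` (matrix,
#'   integrates to 1), `counts`, `n`.
#' @export
density2d <- function(x, y, n_bins = 50, x_edges = NULL, y_edges = NULL) {
  if (length(x) != length(y))
    stop("pairing error: x and y series have different lengths")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) == 0L) stop("empty data: no finite pairs to bin")
  mk <- function(v, edges) {
    if (!is.null(edges)) return(edges)
    rng <- range(v)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    seq(rng[1], rng[2], length.out = n_bins + 1L)
  }
  x_edges <- mk(x, x_edges); y_edges <- mk(y, y_edges)
  xi <- findInterval(x, x_edges, rightmost.closed = TRUE, left.open = TRUE)
  yi <- findInterval(y, y_edges, rightmost.closed = TRUE, left.open = TRUE)
  xi[xi == 0L] <- 1L; yi[yi == 0L] <- 1L  # values exactly at the left edge
  nx <- length(x_edges) - 1L; ny <- length(y_edges) - 1L
  counts <- matrix(0, nx, ny)
  for (k in seq_along(xi)) counts[xi[k], yi[k]] <- counts[xi[k], yi[k]] + 1
  wx <- diff(x_edges); wy <- diff(y_edges)
  area <- outer(wx, wy)
  dens <- counts / (sum(counts) * area)
  out <- list(x_edges = x_edges, y_edges = y_edges, density = dens,
              counts = counts, n = length(x))
  class(out) <- "density2d"
  out
}

#' Marginal of a 2-D density
#' @param d2 A `density2d`.
#' @param margin 1 for x, 2 for y.
#' @return A `histogram_summary` over the corresponding axis.
#' @export
density2d_marginal <- function(d2, margin = 1) {
  counts <- apply(d2$counts, margin, sum)
  edges <- if (margin == 1) d2$x_edges else d2$y_edges
  w <- diff(edges)
  out <- list(bin_edges = edges, densities = counts / (sum(counts) * w),
              counts = counts, n_frames = d2$n)
  class(out) <- "histogram_summary"
  out
}
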