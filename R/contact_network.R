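# Difference contact-network analysis of apo vs holo ensembles.
#
# Residue-pair contact probabilities (any heavy-atom pair within 4.5 A,
# sequence neighbours excluded), a stable-contact graph at threshold 0.7,
# deterministic divisive (Girvan-Newman) partitioning into k communities,
# community-level average contacts, and the holo-minus-apo difference
# network with its inter-protomer contact-change sum.

#' Residue-pair contact probabilities from a trajectory
#'
#' For each residue pair, the fraction of frames in which any heavy-atom
#' pair of the two residues lies within the cutoff.  Self pairs and
#' sequence-adjacent pairs (|delta resnum| <= `exclude_within` on the same
#' chain) are excluded.
#'
#' @param traj A `kinase_trajectory`.
#' @param cutoff Contact distance cutoff in A (default 4.5, closed).
#' @param exclude_within Exclude same-chain pairs this close in sequence
#'   (default 2; set 0 to keep all pairs).
#' @param protein_only Ignore HETATM residues (default TRUE).
#' @return A `contact_map`: list with `pairs` (data frame `chain_a`,
#'   `res_a`, `chain_b`, `res_b`, `probability`), `residues`, `n_frames`,
#'   `cutoff`.
#' @export
contact_probabilities <- function(traj, cutoff = 4.5, exclude_within = 2,
                                  protein_only = TRUE) {
  stopifnot(inherits(traj, "kinase_trajectory"))
  a <- traj$topology$atoms
  keep <- if (protein_only) !a$hetero else rep(TRUE, nrow(a))
  rows <- which(keep)
  if (length(rows) == 0L) stop("empty data: no atoms to analyse")
  rid <- paste(a$chain[rows], a$res_num[rows])
  res_tab <- unique(data.frame(chain = a$chain[rows], res_num = a$res_num[rows],
                               stringsAsFactors = FALSE))
  res_tab <- res_tab[order(res_tab$chain, res_tab$res_num), , drop = FALSE]
  res_key <- paste(res_tab$chain, res_tab$res_num)
  n_res <- nrow(res_tab)
  res_of_atom <- match(rid, res_key)
  n_frames <- traj$n_frames
  counts <- matrix(0L, n_res, n_res)
  cut2 <- cutoff^2
  for (f in seq_len(n_frames)) {
    xyz <- traj$coords[rows, , f, drop = FALSE][, , 1]
    d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
    hit <- d2 <= cut2
    # reduce atom-pair hits to residue-pair hits
    pairs <- which(hit, arr.ind = TRUE)
    pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) {
      ra <- res_of_atom[pairs[, 1]]; rb <- res_of_atom[pairs[, 2]]
      ok <- ra != rb
      u <- unique(cbind(pmin(ra, rb), pmax(ra, rb))[ok, , drop = FALSE])
      if (nrow(u))
        counts[u] <- counts[u] + 1L
    }
  }
  idx <- which(counts > 0L, arr.ind = TRUE)
  pairs <- data.frame(
    chain_a = res_tab$chain[idx[, 1]], res_a = res_tab$res_num[idx[, 1]],
    chain_b = res_tab$chain[idx[, 2]], res_b = res_tab$res_num[idx[, 2]],
    probability = counts[idx] / n_frames, stringsAsFactors = FALSE)
  adj <- pairs$chain_a == pairs$chain_b &
    abs(pairs$res_a - pairs$res_b) <= exclude_within
  pairs <- pairs[!adj, , drop = FALSE]
  ord <- order(pairs$chain_a, pairs$res_a, pairs$chain_b, pairs$res_b)
  out <- list(pairs = pairs[ord, , drop = FALSE], residues = res_tab,
              n_frames = n_frames, cutoff = cutoff)
  class(out) <- "contact_map"
  out
}

#' @export
print.contact_map <- function(x, ...) {
  cat("contact_map:", nrow(x$pairs), "residue pairs over", x$n_frames,
      "frames (cutoff", x$cutoff, "A)\n")
  invisible(x)
}

#' Stable-contact graph
#'
#' Keeps residue pairs whose contact probability is at least the threshold
#' (closed boundary) and returns them as an igraph graph whose vertices are
#' `chain:resnum` labels.
#'
#' @param map A `contact_map`.
#' @param threshold Stability threshold (default 0.7).
#' @return An igraph undirected graph with a `probability` edge attribute.
#' @export
stable_contact_graph <- function(map, threshold = 0.7) {
  stopifnot(inherits(map, "contact_map"))
  p <- map$pairs[map$pairs$probability >= threshold, , drop = FALSE]
  verts <- paste0(map$residues$chain, ":", map$residues$res_num)
  g <- igraph::make_empty_graph(n = length(verts), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = verts)
  if (nrow(p)) {
    el <- rbind(paste0(p$chain_a, ":", p$res_a), paste0(p$chain_b, ":", p$res_b))
    g <- igraph::add_edges(g, as.vector(el))
    g <- igraph::set_edge_attr(g, "probability", value = p$probability)
  }
  g
}

#' Deterministic divisive community detection
#'
#' Girvan-Newman partitioning: repeatedly remove the edge of highest
#' betweenness until the graph splits into `k` connected components.  Among
#' equal-betweenness edges the lexicographically smallest endpoint-name pair
#' is removed, making the partition deterministic.  Isolated residues are
#' assigned to the community of the nearest-in-sequence assigned residue on
#' the same chain.
#'
#' @param graph An igraph graph with `chain:resnum` vertex names.
#' @param k Number of communities (default 4).
#' @return A `community_partition`: list with `assignment` (named integer
#'   vector, vertex name to community id), `n_communities`.
#' @export
detect_communities <- function(graph, k = 4) {
  stopifnot(igraph::vcount(graph) > 0)
  deg <- igraph::degree(graph)
  g <- igraph::delete_vertices(graph, which(deg == 0))
  if (igraph::vcount(g) == 0L) stop("partition error: graph has no edges")
  comp <- igraph::components(g)
  if (comp$no > k)
    stop("partition error: graph already has ", comp$no,
         " components, more than k = ", k)
  while (igraph::components(g)$no < k) {
    if (igraph::ecount(g) == 0L)
      stop("partition error: ran out of edges before reaching k = ", k,
           " components")
    eb <- igraph::edge_betweenness(g)
    cand <- which(eb >= max(eb) - 1e-9)
    if (length(cand) > 1L) {
      ends <- igraph::ends(g, cand)
      key <- apply(ends, 1, function(r) paste(sort(r), collapse = "|"))
      cand <- cand[order(key)][1L]
    }
    g <- igraph::delete_edges(g, cand)
  }
  memb <- igraph::components(g)$membership
  assignment <- stats::setNames(memb, igraph::V(g)$name)
  # attach isolated residues to the nearest assigned residue in sequence
  all_names <- igraph::V(graph)$name
  iso <- setdiff(all_names, names(assignment))
  if (length(iso)) {
    parse <- function(v) {
      parts <- strsplit(v, ":", fixed = TRUE)
      data.frame(chain = vapply(parts, `[`, "", 1),
                 res = as.integer(vapply(parts, `[`, "", 2)))
    }
    ai <- parse(names(assignment))
    for (v in iso) {
      pv <- parse(v)
      same <- which(ai$chain == pv$chain)
      cand <- if (length(same)) same else seq_len(nrow(ai))
      j <- cand[which.min(abs(ai$res[cand] - pv$res))]
      assignment[v] <- assignment[[j]]
    }
  }
  assignment <- stats::setNames(as.integer(assignment), names(assignment))
  out <- list(assignment = assignment[all_names],
              n_communities = length(unique(assignment)))
  class(out) <- "community_partition"
  out
}

#' @export
print.community_partition <- function(x, ...) {
  cat("community_partition:", x$n_communities, "communities over",
      length(x$assignment), "residues\n")
  print(table(x$assignment))
  invisible(x)
}

#' Map communities to protomers by majority chain
#'
#' @param partition A `community_partition` whose vertex names are
#'   `chain:resnum` labels.
#' @return Named character vector: community id (as character) to the chain
#'   id contributing most of its residues.
#' @export
community_protomers <- function(partition) {
  chain_of <- vapply(strsplit(names(partition$assignment), ":", fixed = TRUE),
                     `[`, "", 1)
  vapply(split(chain_of, partition$assignment), function(ch)
    names(sort(table(ch), decreasing = TRUE))[1], "")
}

#' Community-level average contacts
#'
#' For each unordered community pair, the sum of residue-pair contact
#' probabilities between the two communities - the expected number of
#' simultaneous inter-community contacts.  Supply a list of contact maps
#' (replicas) to average across them.
#'
#' @param map A `contact_map` or list of them (replicas).
#' @param partition A `community_partition` covering the map's residues.
#' @return Data frame with `community_a`, `community_b` (a <= b),
#'   `avg_contacts`.
#' @export
community_average_contacts <- function(map, partition) {
  maps <- if (inherits(map, "contact_map")) list(map) else map
  ids <- sort(unique(partition$assignment))
  acc <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (m in maps) {
    p <- m$pairs
    ka <- paste0(p$chain_a, ":", p$res_a)
    kb <- paste0(p$chain_b, ":", p$res_b)
    ca <- partition$assignment[ka]
    cb <- partition$assignment[kb]
    if (any(is.na(ca)) || any(is.na(cb)))
      stop("consistency error: contact-map residue missing from partition")
    lo <- pmin(ca, cb); hi <- pmax(ca, cb)
    for (i in seq_along(lo)) {
      acc[as.character(lo[i]), as.character(hi[i])] <-
        acc[as.character(lo[i]), as.character(hi[i])] + p$probability[i]
    }
  }
  acc <- acc / length(maps)
  idx <- which(upper.tri(acc, diag = TRUE), arr.ind = TRUE)
  data.frame(community_a = ids[idx[, 1]], community_b = ids[idx[, 2]],
             avg_contacts = acc[idx])
}

#' Difference contact network (holo minus apo)
#'
#' Edge deltas between two community-level average-contact tables and the
#' signed sum of deltas over community pairs whose members lie in different
#' protomers (each unordered pair counted once).
#'
#' @param holo_avgs,apo_avgs Data frames from
#'   [community_average_contacts()] over the same community universe.
#' @param protomer_of Named vector mapping community id (as character) to a
#'   protomer label (e.g. `c("1" = "A", "2" = "A", "3" = "B", "4" = "B")`).
#' @return A `diff_network`: list with `edges` (data frame with `delta`),
#'   `interprotomer_sum`.
#' @export
diff_network <- function(holo_avgs, apo_avgs, protomer_of) {
  key <- function(d) paste(d$community_a, d$community_b)
  if (!identical(sort(key(holo_avgs)), sort(key(apo_avgs))))
    stop("consistency error: holo and apo community universes differ")
  m <- merge(holo_avgs, apo_avgs, by = c("community_a", "community_b"),
             suffixes = c("_holo", "_apo"))
  m$delta <- m$avg_contacts_holo - m$avg_contacts_apo
  pa <- protomer_of[as.character(m$community_a)]
  pb <- protomer_of[as.character(m$community_b)]
  if (any(is.na(pa)) || any(is.na(pb)))
    stop("consistency error: community missing from protomer_of")
  inter <- pa != pb
  out <- list(edges = m[, c("community_a", "community_b", "avg_contacts_holo",
                            "avg_contacts_apo", "delta")],
              interprotomer_sum = sum(m$delta[inter]),
              interprotomer_pairs = m[inter, c("community_a", "community_b",
                                               "delta")])
  class(out) <- "diff_network"
  out
}

#' @export
print.diff_network <- function(x, ...) {
  cat("diff_network (holo - apo):\n")
  for (i in seq_len(nrow(x$edges))) {
    e <- x$edges[i, ]
    if (abs(e$delta) > 1e-12)
      cat(sprintf("  %s -- %s : %+0.3f\n", e$community_a, e$community_b,
                  e$delta))
  }
  cat(sprintf("  inter-protomer contact-change sum: %+0.3f\n",
              x$interprotomer_sum))
  invisible(x)
}

#' Write a contact map as a TSV edge list
#' @param map A `contact_map`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_contact_map <- function(map, file) {
  .write_tsv(map$pairs, file)
  invisible(file)
}

#' Export a difference network as JSON and optionally GraphML
#'
#' @param dn A `diff_network`.
#' @param json JSON output path.
#' @param graphml Optional GraphML path (via igraph) for visualisation.
#' @return `json`, invisibly.
#' @export
write_diff_network <- function(dn, json, graphml = NULL) {
  .write_json(list(edges = dn$edges,
                   interprotomer_sum = dn$interprotomer_sum), json)
  if (!is.null(graphml)) {
    e <- dn$edges[abs(dn$edges$delta) > 1e-12, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(e$community_a),
                 to = as.character(e$community_b), delta = e$delta),
      directed = FALSE)
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(json)
}
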