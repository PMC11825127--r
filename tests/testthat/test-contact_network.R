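# hand-built trajectory: residues as single C-alpha atoms with scripted
# per-frame positions
scripted_traj <- function(positions_by_frame, chain = "A",
                          res_nums = NULL) {
  n_res <- nrow(positions_by_frame[[1]])
  if (is.null(res_nums)) res_nums <- seq_len(n_res) * 10L
  atoms <- data.frame(
    atom_name = "CA", element = "C", res_name = "GLY", res_num = res_nums,
    chain = chain, alt = "", x = positions_by_frame[[1]][, 1],
    y = positions_by_frame[[1]][, 2], z = positions_by_frame[[1]][, 3],
    occ = 1, hetero = FALSE, stringsAsFactors = FALSE)
  topo <- structure_from_atoms(atoms, source_id = "scripted")
  coords <- array(0, dim = c(n_res, 3, length(positions_by_frame)))
  for (f in seq_along(positions_by_frame))
    coords[, , f] <- positions_by_frame[[f]]
  kinase_trajectory(topo, coords)
}

test_that("contact probabilities count frames with any close heavy-atom pair", {
  near <- rbind(c(0, 0, 0), c(3, 0, 0))
  far <- rbind(c(0, 0, 0), c(20, 0, 0))
  tr_const <- scripted_traj(rep(list(near), 5))
  cm <- contact_probabilities(tr_const)
  expect_equal(nrow(cm$pairs), 1L)
  expect_equal(cm$pairs$probability, 1.0)

  tr_toggle <- scripted_traj(c(rep(list(near), 7), rep(list(far), 3)))
  cm2 <- contact_probabilities(tr_toggle)
  expect_equal(cm2$pairs$probability, 0.7)

  tr_far <- scripted_traj(rep(list(far), 4))
  cm3 <- contact_probabilities(tr_far)
  expect_equal(nrow(cm3$pairs), 0L)
})

test_that("sequence-adjacent pairs are excluded from the contact map", {
  near <- rbind(c(0, 0, 0), c(3, 0, 0))
  tr <- scripted_traj(rep(list(near), 3), res_nums = c(100L, 101L))
  expect_equal(nrow(contact_probabilities(tr)$pairs), 0L)
  expect_equal(nrow(contact_probabilities(tr, exclude_within = 0)$pairs), 1L)
})

test_that("concatenated trajectories give frame-weighted probabilities", {
  near <- rbind(c(0, 0, 0), c(3, 0, 0))
  far <- rbind(c(0, 0, 0), c(20, 0, 0))
  t1 <- scripted_traj(rep(list(near), 6))               # p = 1
  t2 <- scripted_traj(c(rep(list(near), 1), rep(list(far), 3)))  # p = 0.25
  cat12 <- scripted_traj(c(rep(list(near), 6), rep(list(near), 1),
                           rep(list(far), 3)))
  p1 <- contact_probabilities(t1)$pairs$probability
  p2 <- contact_probabilities(t2)$pairs$probability
  pc <- contact_probabilities(cat12)$pairs$probability
  expect_equal(pc, (6 * p1 + 4 * p2) / 10)
})

test_that("stable-contact threshold is closed at 0.7", {
  mk_map <- function(probs) {
    n <- length(probs)
    res <- data.frame(chain = "A", res_num = seq_len(n + 1) * 10L)
    out <- list(pairs = data.frame(
      chain_a = "A", res_a = seq_len(n) * 10L,
      chain_b = "A", res_b = (seq_len(n) + 1) * 10L,
      probability = probs, stringsAsFactors = FALSE),
      residues = res, n_frames = 100L, cutoff = 4.5)
    class(out) <- "contact_map"
    out
  }
  g <- stable_contact_graph(mk_map(c(0.7, 0.69, 0.71)))
  expect_equal(igraph::ecount(g), 2L)
  # random maps match a brute-force filter
  set.seed(17)
  probs <- runif(20)
  g2 <- stable_contact_graph(mk_map(probs), threshold = 0.5)
  expect_equal(igraph::ecount(g2), sum(probs >= 0.5))
})

test_that("divisive partitioning splits obvious block structures", {
  # two 10-node cliques joined by one edge
  g <- igraph::disjoint_union(igraph::make_full_graph(10),
                              igraph::make_full_graph(10))
  g <- igraph::set_vertex_attr(g, "name",
                               value = c(paste0("A:", 1:10 * 10),
                                         paste0("B:", 1:10 * 10)))
  g <- igraph::add_edges(g, c("A:100", "B:10"))
  part <- detect_communities(g, k = 2)
  expect_equal(part$n_communities, 2L)
  a_ids <- part$assignment[paste0("A:", 1:10 * 10)]
  b_ids <- part$assignment[paste0("B:", 1:10 * 10)]
  expect_length(unique(a_ids), 1L)
  expect_length(unique(b_ids), 1L)
  expect_false(unique(a_ids) == unique(b_ids))

  # four cliques in a ring; independent check via igraph's own algorithm
  ring4 <- Reduce(igraph::disjoint_union,
                  replicate(4, igraph::make_full_graph(5), simplify = FALSE))
  ring4 <- igraph::set_vertex_attr(ring4, "name",
                                   value = paste0("A:", seq_len(20) * 10))
  bridges <- c("A:50", "A:60", "A:100", "A:110", "A:150", "A:160",
               "A:200", "A:10")
  ring4 <- igraph::add_edges(ring4, bridges)
  part4 <- detect_communities(ring4, k = 4)
  expect_equal(part4$n_communities, 4L)
  want <- rep(1:4, each = 5)
  got <- part4$assignment[paste0("A:", seq_len(20) * 10)]
  expect_equal(length(unique(paste(want, got))), 4L)  # same partition
  ceb <- igraph::cluster_edge_betweenness(ring4)
  memb <- igraph::cut_at(ceb, no = 4)
  expect_equal(length(unique(paste(memb, got))), 4L)
})

test_that("partition errors are raised for unreachable k", {
  g <- igraph::make_full_graph(3)
  g <- igraph::set_vertex_attr(g, "name", value = paste0("A:", 1:3 * 10))
  expect_error(detect_communities(g, k = 5), "partition error")
})

test_that("community average contacts match a hand-summed oracle", {
  res <- data.frame(chain = "A", res_num = c(10L, 20L, 30L, 40L))
  map <- list(pairs = data.frame(
    chain_a = "A", res_a = c(10L, 10L, 20L, 30L),
    chain_b = "A", res_b = c(20L, 30L, 40L, 40L),
    probability = c(1.0, 0.5, 0.25, 0.8), stringsAsFactors = FALSE),
    residues = res, n_frames = 10L, cutoff = 4.5)
  class(map) <- "contact_map"
  part <- list(assignment = c("A:10" = 1L, "A:20" = 1L,
                              "A:30" = 2L, "A:40" = 2L),
               n_communities = 2L)
  class(part) <- "community_partition"
  avg <- community_average_contacts(map, part)
  val <- function(a, b) avg$avg_contacts[avg$community_a == a &
                                           avg$community_b == b]
  expect_equal(val(1, 1), 1.0)          # 10-20
  expect_equal(val(1, 2), 0.5 + 0.25)   # 10-30, 20-40
  expect_equal(val(2, 2), 0.8)          # 30-40
  # replica averaging
  avg2 <- community_average_contacts(list(map, map), part)
  expect_equal(avg2$avg_contacts, avg$avg_contacts)
  # residue missing from the partition is a consistency error
  bad_part <- part
  bad_part$assignment <- part$assignment[-1]
  expect_error(community_average_contacts(map, bad_part), "consistency")
})

test_that("difference networks are antisymmetric with a correct sum", {
  avg <- function(vals) data.frame(
    community_a = c(1, 1, 1, 2, 2, 3, 1, 2, 3, 4),
    community_b = c(2, 3, 4, 3, 4, 4, 1, 2, 3, 4),
    avg_contacts = vals)
  protomer_of <- c("1" = "A", "2" = "A", "3" = "B", "4" = "B")
  apo <- avg(c(5, 1.0, 0.2, 0.3, 0.6, 4, 9, 9, 9, 9))
  holo <- avg(c(5, 1.0, 0.7, 0.3, 0.4, 4, 9, 9, 9, 9))
  dn <- diff_network(holo, apo, protomer_of)
  # inter-protomer pairs: 1-3 (0), 1-4 (+0.5), 2-3 (0), 2-4 (-0.2)
  expect_equal(dn$interprotomer_sum, 0.3)
  expect_equal(dn$interprotomer_sum,
               sum(dn$interprotomer_pairs$delta))   # internal consistency
  dn_same <- diff_network(apo, apo, protomer_of)
  expect_true(all(dn_same$edges$delta == 0))
  expect_equal(dn_same$interprotomer_sum, 0)
  dn_swapped <- diff_network(apo, holo, protomer_of)
  expect_equal(dn_swapped$interprotomer_sum, -dn$interprotomer_sum)
  expect_equal(dn_swapped$edges$delta, -dn$edges$delta)
  expect_error(diff_network(holo[-1, ], apo, protomer_of), "consistency")
})
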