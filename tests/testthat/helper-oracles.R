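# Independent oracles, deliberately coded differently from the package
# internals they cross-check.

# Torsion via projection of the outer bonds onto the plane perpendicular to
# the central bond (praxeolitic formulation), wrapped to [0, 360).
oracle_torsion <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  b2 <- p4 - p3
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum(c(b1[2] * v[3] - b1[3] * v[2],
             b1[3] * v[1] - b1[1] * v[3],
             b1[1] * v[2] - b1[2] * v[1]) * w)
  ang <- atan2(y, x) * 180 / pi
  # the projection formula yields the opposite sign convention
  ang <- -ang
  if (ang < 0) ang + 360 else ang
}

# Brute-force minimum distance over all atom pairs of two coordinate sets.
oracle_min_pair <- function(xyz_a, xyz_b) {
  best <- Inf
  for (i in seq_len(nrow(xyz_a))) {
    for (j in seq_len(nrow(xyz_b))) {
      d <- sqrt(sum((xyz_a[i, ] - xyz_b[j, ])^2))
      if (d < best) best <- d
    }
  }
  best
}

# Brute-force donor-acceptor contact enumeration.
oracle_hbond_pairs <- function(donors_xyz, acceptors_xyz, cutoff) {
  hits <- 0L
  for (i in seq_len(nrow(donors_xyz))) {
    for (j in seq_len(nrow(acceptors_xyz))) {
      if (sqrt(sum((donors_xyz[i, ] - acceptors_xyz[j, ])^2)) <= cutoff)
        hits <- hits + 1L
    }
  }
  hits
}

# Random rigid-body transform (uniform rotation via QR + random shift).
random_rigid_transform <- function() {
  m <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(m)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, shift = rnorm(3, sd = 20))
}

apply_rigid <- function(xyz, tr) {
  sweep(as.matrix(xyz) %*% t(tr$R), 2, tr$shift, "+")
}

# Apply a rigid transform to a protomer atom data frame.
transform_atoms <- function(atoms, tr) {
  atoms[, c("x", "y", "z")] <- apply_rigid(atoms[, c("x", "y", "z")], tr)
  atoms
}
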