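# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (double loops, grid searches) so they cannot share a
# defect with the vectorised implementation paths.

# Plain double-loop hydrogen-bond count: every (donor N with H, acceptor
# O/OXT) pair, inclusive cutoffs, angle measured at the hydrogen.
oracle_count_backbone_hbonds <- function(struct, d_max = 3.5, a_max = 30) {
  a <- struct$atoms; X <- struct$xyz
  count <- 0
  for (i in seq_len(nrow(a))) {
    if (a$elety[i] != "N" || a$resid[i] == "PRO") next
    hi <- which(a$elety == "H" & a$chain == a$chain[i] &
                  a$resno == a$resno[i])
    if (length(hi) != 1) next
    for (j in seq_len(nrow(a))) {
      if (!(a$elety[j] %in% c("O", "OXT"))) next
      if (a$chain[j] == a$chain[i] && a$resno[j] == a$resno[i]) next
      d <- sqrt(sum((X[i, ] - X[j, ])^2))
      if (d > d_max) next
      v1 <- X[i, ] - X[hi, ]; v2 <- X[j, ] - X[hi, ]
      ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      if (180 - ang <= a_max) count <- count + 1
    }
  }
  count
}

# Double-loop intermonomer hydrophobic contact count over side-chain
# centers of mass (SCM pseudo-atoms).
oracle_count_hydrophobic <- function(struct, hydrophobic_set, d_max = 7.0) {
  a <- struct$atoms; X <- struct$xyz
  idx <- which(a$elety == "SCM")
  one <- setNames(names(coilstab::kyte_doolittle),
                  names(coilstab::kyte_doolittle))
  count <- 0
  for (p in seq_along(idx)) {
    for (q in seq_along(idx)) {
      if (q <= p) next
      i <- idx[p]; j <- idx[q]
      ri <- bio3d::aa321(a$resid[i]); rj <- bio3d::aa321(a$resid[j])
      if (!(ri %in% hydrophobic_set) || !(rj %in% hydrophobic_set)) next
      if (a$chain[i] == a$chain[j]) next
      if (sqrt(sum((X[i, ] - X[j, ])^2)) <= d_max) count <- count + 1
    }
  }
  count
}

# Double-loop intermonomer salt-bridge count at neutral pH over the full
# charged-group catalog of pseudo-atom structures: SCQ of K/R (plus the
# protonated N-terminal amine N) against SCQ of D/E (plus the C-terminal
# carbonyl O); one record per residue pair.
oracle_count_salt_bridges <- function(struct, d_max = 4.0) {
  a <- struct$atoms; X <- struct$xyz
  first_res <- tapply(a$resno, a$chain, min)
  last_res <- tapply(a$resno, a$chain, max)
  basic <- which((a$elety == "SCQ" & a$resid %in% c("LYS", "ARG")) |
                   (a$elety == "N" & a$resno == first_res[a$chain]))
  acidic <- which((a$elety == "SCQ" & a$resid %in% c("ASP", "GLU")) |
                    (a$elety == "O" & a$resno == last_res[a$chain]))
  pairs <- character(0)
  for (i in basic) {
    for (j in acidic) {
      if (a$chain[i] == a$chain[j]) next
      if (sqrt(sum((X[i, ] - X[j, ])^2)) <= d_max)
        pairs <- c(pairs, paste(a$chain[i], a$resno[i],
                                a$chain[j], a$resno[j]))
    }
  }
  length(unique(pairs))
}

# Brute-force rigid superposition by quaternion grid search plus local
# refinement; returns the minimal RMSD.
oracle_superpose_rmsd <- function(P, Q, n_grid = 12) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  quat_rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  obj <- function(q) {
    R <- quat_rot(q)
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  best <- Inf; bestq <- c(1, 0, 0, 0)
  gr <- seq(-1, 1, length.out = n_grid)
  for (w in gr) for (x in gr) for (y in gr) for (z in gr) {
    q <- c(w, x, y, z)
    if (sum(q^2) < 1e-6) next
    v <- obj(q)
    if (v < best) { best <- v; bestq <- q }
  }
  o <- optim(bestq, obj, control = list(reltol = 1e-14, maxit = 5000))
  o$value
}

# Exhaustive neighbor-count clustering oracle mirroring the quoted
# algorithm, with a plain RMSD matrix supplied by the caller.
oracle_cluster <- function(D, energies, cutoff) {
  n <- nrow(D)
  unassigned <- rep(TRUE, n)
  clusters <- list()
  while (any(unassigned)) {
    counts <- rep(-1L, n)
    for (i in which(unassigned)) {
      counts[i] <- 0L
      for (j in which(unassigned)) {
        if (j != i && D[i, j] <= cutoff) counts[i] <- counts[i] + 1L
      }
    }
    mx <- max(counts)
    best <- which(counts == mx)
    if (length(best) > 1) best <- best[which.min(energies[best])]
    members <- sort(c(best, which(unassigned & D[best, ] <= cutoff &
                                    seq_len(n) != best)))
    clusters[[length(clusters) + 1]] <- list(center = best,
                                             members = members)
    unassigned[members] <- FALSE
  }
  clusters
}

# A compact trimer fixture shared across files.
fixture_trimer <- function(sequence = strrep("IAAEKQL", 3), r0 = 6.1) {
  build_ideal_coiled_coil(sequence,
                          crick_parameters(supercoil_radius_R0 = r0))
}

# Random pseudo-atom frames (200-500 atoms) for oracle-equivalence tests:
# a jittered, partially displaced trimer so interactions genuinely vary.
fixture_random_frame <- function(seed) {
  set.seed(seed)
  len <- sample(12:24, 1)
  alphabet <- c("A", "V", "L", "I", "E", "K", "Q", "S", "G", "D", "R")
  seqv <- paste(sample(alphabet, len, replace = TRUE), collapse = "")
  st <- build_ideal_coiled_coil(seqv, crick_parameters())
  st$xyz <- st$xyz + matrix(rnorm(length(st$xyz), 0, 0.35),
                            nrow(st$xyz), 3)
  st <- place_amide_hydrogens(st)
  st
}
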