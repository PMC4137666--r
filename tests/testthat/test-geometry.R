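random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

test_that("superposition is exact for rigid copies and proper", {
  cc <- fixture_trimer()
  fit0 <- superpose(cc, cc)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  R <- random_rotation(4)
  moved <- cc
  moved$xyz <- cc$xyz %*% t(R) + matrix(c(5, -3, 11), nrow(cc$xyz), 3,
                                        byrow = TRUE)
  fit <- superpose(moved, cc)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  short <- cc; short$atoms <- cc$atoms[1:9, ]; short$xyz <- cc$xyz[1:9, ]
  expect_error(superpose(short, cc), "differ")
})

test_that("superposition matches a brute-force quaternion search on a
           5-atom toy", {
  set.seed(17)
  P <- matrix(rnorm(15, 0, 2), 5, 3)
  Q <- matrix(rnorm(15, 0, 2), 5, 3)
  fit <- superpose(P, Q)
  expect_equal(fit$rmsd, oracle_superpose_rmsd(P, Q), tolerance = 1e-4)
  expect_lte(fit$rmsd, oracle_superpose_rmsd(P, Q) + 1e-8)
  # and agrees with bio3d's independent fitting
  b <- suppressWarnings(bio3d::fit.xyz(as.vector(t(Q)), as.vector(t(P))))
  expect_equal(fit$rmsd,
               sqrt(mean(colSums((matrix(b, 3) - t(Q))^2))),
               tolerance = 1e-6)
})

test_that("rmsd_series starts at zero, is rigid-invariant, and matches the
           single-displaced-atom closed form", {
  cc <- fixture_trimer()
  const <- as_ensemble(list(cc, cc, cc))
  expect_equal(rmsd_series(const)$rmsd, c(0, 0, 0))
  # move one CA by d without superposition freedom: displacement spread
  # over a superposed fit must be <= d/sqrt(N) (Kabsch only improves it)
  ica <- which(cc$atoms$elety == "CA")
  moved <- cc
  d <- 3
  moved$xyz[ica[10], ] <- moved$xyz[ica[10], ] + c(d, 0, 0)
  rs <- rmsd_series(as_ensemble(list(cc, moved)))
  expect_equal(rs$rmsd[1], 0)
  expect_lte(rs$rmsd[2], d / sqrt(length(ica)) + 1e-9)
  expect_gt(rs$rmsd[2], 0)
  # rigid transform of every frame leaves the series unchanged
  R <- random_rotation(8)
  ens <- as_ensemble(list(cc, moved))
  ens2 <- ens
  ens2$xyz <- lapply(ens2$xyz, function(m)
    m %*% t(R) + matrix(c(1, 2, 3), nrow(m), 3, byrow = TRUE))
  expect_equal(rmsd_series(ens2)$rmsd, rs$rmsd, tolerance = 1e-9)
})

test_that("rmsf recovers isotropic jitter amplitude and commutes with
           monomer averaging", {
  cc <- fixture_trimer(strrep("IAALAAK", 2))
  sigma <- 0.3
  set.seed(99)
  frames <- lapply(1:800, function(i) {
    f <- cc
    f$xyz <- f$xyz + matrix(rnorm(length(f$xyz), 0, sigma), nrow(f$xyz), 3)
    f
  })
  ens <- as_ensemble(frames)
  rf <- rmsf_per_residue(ens)
  # isotropic Gaussian jitter: RMSF ~ sigma * sqrt(3)
  expect_equal(mean(rf$rmsf), sigma * sqrt(3), tolerance = 0.05)
  per_chain <- rmsf_per_residue(ens, monomer_average = FALSE)
  avg <- tapply(per_chain$rmsf^2, per_chain$resno, mean)
  expect_equal(rf$rmsf, sqrt(as.numeric(avg))[match(rf$resno,
                                                    sort(unique(per_chain$resno)))],
               tolerance = 1e-9)
  expect_error(rmsf_per_residue(as_ensemble(list(cc))), "2 frames")
  static <- rmsf_per_residue(as_ensemble(list(cc, cc)))
  expect_true(all(static$rmsf < 1e-10))
})

test_that("supercoil radius recovers parallel-helix spacing", {
  # three straight ideal helices (no supercoil twist) at axial distance d
  d_ax <- 5.5
  p <- crick_parameters(supercoil_radius_R0 = d_ax,
                        supercoil_frequency_w0 = 0)
  cc <- build_ideal_coiled_coil(strrep("A", 24), p)
  expect_lt(abs(estimate_supercoil_radius(cc) - d_ax), 0.1)
  expect_error(estimate_supercoil_radius(
    build_ideal_coiled_coil(strrep("A", 7), crick_parameters())), "short")
})

test_that("neighbor clustering matches exhaustive enumeration and its
           edge cases", {
  # two rigid groups: 5 decoys near the folded trimer, 3 far away
  cc <- fixture_trimer(strrep("IAALAAK", 2))
  set.seed(31)
  mk <- function(shift, jit) {
    f <- cc
    f$xyz <- f$xyz + matrix(rnorm(length(f$xyz), 0, jit), nrow(f$xyz), 3)
    # internal deformation (one chain pulled away) so the two groups stay
    # apart even after superposition
    ia <- which(f$atoms$chain == "A")
    f$xyz[ia, 1] <- f$xyz[ia, 1] + shift
    # random rigid placement so superposition matters
    R <- random_rotation(sample.int(1e6, 1))
    f$xyz <- f$xyz %*% t(R)
    f
  }
  frames <- c(lapply(1:5, function(i) mk(0, 0.3)),
              lapply(1:3, function(i) mk(40, 0.3)))
  ens <- as_ensemble(frames)
  energies <- c(3, 1, 4, 5, 6, 0.5, 2, 7)
  res <- cluster_by_neighbors(ens, energies, top_n = 8, rms_cutoff = 3.0)
  expect_length(res$clusters, 2)
  expect_true(res$clusters[[1]]$center %in% 1:5)
  expect_setequal(res$clusters[[1]]$members, 1:5)
  expect_setequal(res$clusters[[2]]$members, 6:8)
  expect_equal(res$final_model, res$clusters[[1]]$center)
  # exhaustive oracle on the same RMSD matrix
  ica <- which(cc$atoms$elety == "CA")
  D <- matrix(0, 8, 8)
  for (i in 1:7) for (j in (i + 1):8) {
    D[i, j] <- D[j, i] <- superpose(frames[[j]]$xyz[ica, ],
                                    frames[[i]]$xyz[ica, ])$rmsd
  }
  oc <- oracle_cluster(D, energies, 3.0)
  expect_equal(length(oc), length(res$clusters))
  for (k in seq_along(oc)) {
    expect_equal(res$clusters[[k]]$center, oc[[k]]$center)
    expect_setequal(res$clusters[[k]]$members, oc[[k]]$members)
  }
  # degenerate cases
  same <- as_ensemble(lapply(1:4, function(i) cc))
  r1 <- cluster_by_neighbors(same, c(2, 1, 3, 4), top_n = 4)
  expect_length(r1$clusters, 1)
  expect_equal(r1$clusters[[1]]$center, 2)  # tie broken by lowest energy
  r0 <- cluster_by_neighbors(ens, energies, top_n = 8, rms_cutoff = 0)
  expect_length(r0$clusters, 8)
  expect_warning(cluster_by_neighbors(ens, energies, top_n = 50),
                 "exceeds")
})
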