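test_that("ideal coiled-coil builder round-trips the supercoil radius", {
  for (r0 in c(4, 5.1, 6.1, 7, 8)) {
    cc <- build_ideal_coiled_coil(strrep("A", 28),
                                  crick_parameters(supercoil_radius_R0 = r0))
    expect_equal(estimate_supercoil_radius(cc), r0, tolerance = 0.1 / r0)
    expect_lt(abs(estimate_supercoil_radius(cc) - r0), 0.1)
  }
})

test_that("built bundles have exact C3 symmetry about the supercoil axis", {
  cc <- build_ideal_coiled_coil(strrep("IAAEKQL", 3), crick_parameters())
  ia <- which(cc$atoms$chain == "A")
  ib <- which(cc$atoms$chain == "B")
  ic <- which(cc$atoms$chain == "C")
  r <- -120 * pi / 180
  Rz <- matrix(c(cos(r), sin(r), 0, -sin(r), cos(r), 0, 0, 0, 1), 3, 3)
  rmsd_ab <- sqrt(mean(rowSums((cc$xyz[ia, ] %*% Rz - cc$xyz[ib, ])^2)))
  rmsd_bc <- sqrt(mean(rowSums((cc$xyz[ib, ] %*% Rz - cc$xyz[ic, ])^2)))
  expect_lt(rmsd_ab, 1e-6)
  expect_lt(rmsd_bc, 1e-6)
})

test_that("builder rejects invalid sequences", {
  expect_error(build_ideal_coiled_coil("", crick_parameters()), "at least")
  expect_error(build_ideal_coiled_coil("AAA", crick_parameters()),
               "at least 7")
  expect_error(build_ideal_coiled_coil("AAAAAAAZ", crick_parameters()),
               "non-standard")
})

test_that("ideal build is fully helical by an independent dihedral check", {
  cc <- build_ideal_coiled_coil(strrep("A", 21), crick_parameters())
  expect_equal(assign_helix(cc)$content, 100)
  # independent oracle: bio3d torsion on a written PDB
  f <- tempfile(fileext = ".pdb")
  write_structure_ensemble(cc, f)
  tor <- bio3d::torsion.pdb(bio3d::read.pdb(f, verbose = FALSE))
  phi <- tor$phi[is.finite(tor$phi)]
  psi <- tor$psi[is.finite(tor$psi)]
  expect_true(all(phi >= -100 & phi <= -30))
  expect_true(all(psi >= -67 & psi <= -7))
  unlink(f)
})

test_that("amide hydrogens sit 1 A from N, in-plane, skipping Pro and
           chain-initial residues", {
  cc <- build_ideal_coiled_coil(strrep("APAGKDL", 3), crick_parameters())
  cc <- place_amide_hydrogens(cc)
  a <- cc$atoms
  # no H on residue 1 or on prolines
  expect_false(any(a$elety == "H" & a$resno == 1))
  expect_false(any(a$elety == "H" & a$resid == "PRO"))
  for (ch in chain_ids(cc)) {
    hs <- which(a$elety == "H" & a$chain == ch)
    for (i in hs) {
      rn <- a$resno[i]
      N <- cc$xyz[which(a$chain == ch & a$resno == rn & a$elety == "N"), ]
      CA <- cc$xyz[which(a$chain == ch & a$resno == rn & a$elety == "CA"), ]
      Cp <- cc$xyz[which(a$chain == ch & a$resno == rn - 1 &
                           a$elety == "C"), ]
      H <- cc$xyz[i, ]
      expect_equal(sqrt(sum((H - N)^2)), 1.00, tolerance = 1e-3)
      # near-equal angles to C(i-1) and CA (independent vector check)
      ang <- function(p) {
        v1 <- H - N; v2 <- p - N
        acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      }
      expect_equal(ang(Cp), ang(CA), tolerance = 1e-6)
      # in the C(i-1)-N-CA plane
      nrm <- c(
        (Cp - N)[2] * (CA - N)[3] - (Cp - N)[3] * (CA - N)[2],
        (Cp - N)[3] * (CA - N)[1] - (Cp - N)[1] * (CA - N)[3],
        (Cp - N)[1] * (CA - N)[2] - (Cp - N)[2] * (CA - N)[1])
      expect_lt(abs(sum((H - N) * nrm / sqrt(sum(nrm^2)))), 1e-6)
    }
  }
  expect_error(place_amide_hydrogens(
    structure(list(atoms = data.frame(eleno = 1, elety = "CA",
                                      resid = "ALA", chain = "A", resno = 1),
                   xyz = matrix(0, 1, 3)), class = "cc_structure")),
    "backbone")
})

test_that("replica generator respects the logistic limits and is
           deterministic under a fixed seed", {
  cc <- fixture_trimer(strrep("IAALAAK", 2))
  mm <- melting_model(tm_association = 400, tm_helix = 500,
                      width_association = 10, width_helix = 10,
                      frames_per_temperature = 25, seed = 42)
  ladder <- c(400 - 10 * 10, 450, 500 + 10 * 10) # tm_helix +- 10 widths
  s1 <- generate_replica_ensembles(cc, ladder, mm)
  s2 <- generate_replica_ensembles(cc, ladder, mm)
  expect_identical(s1$frames, s2$frames)
  lowT <- s1$frames[s1$frames$temperature == ladder[1], ]
  highT <- s1$frames[s1$frames$temperature == ladder[3], ]
  expect_gte(mean(lowT$helix_content) / 100, 0.99)
  expect_lte(mean(highT$helix_content) / 100, 0.01)
  # coordinates are also reproducible
  s3 <- generate_replica_ensembles(cc, ladder, mm, store_coords = TRUE)
  s4 <- generate_replica_ensembles(cc, ladder, mm, store_coords = TRUE)
  expect_identical(s3$ensembles[[1]]$xyz, s4$ensembles[[1]]$xyz)
  expect_error(generate_replica_ensembles(cc, c(400, 300), mm),
               "strictly increasing")
})

test_that("mean helix content and contacts are non-increasing in T", {
  cc <- fixture_trimer(strrep("IAALAAK", 2))
  mm <- melting_model(tm_association = 420, tm_helix = 520,
                      width_association = 25, width_helix = 25,
                      frames_per_temperature = 60, seed = 9)
  ladder <- make_ladder(303.15, 809.57, 10)
  ser <- generate_replica_ensembles(cc, ladder, mm)
  cur <- ensemble_averages(ser, c("helix_content", "hydrophobic_contacts"),
                           window_fraction = 1)
  for (cu in cur) {
    se <- cu$sd / sqrt(cu$n)
    slack <- 3 * sqrt(se[-1]^2 + se[-length(se)]^2)
    expect_true(all(diff(cu$mean) <= slack + 1e-9))
  }
})

test_that("generator helix flags round-trip through the geometric
           helix assignment", {
  cc <- fixture_trimer(strrep("IAALAAK", 2))
  mm <- melting_model(tm_association = 450, tm_helix = 500,
                      width_association = 10, width_helix = 40,
                      frames_per_temperature = 6, seed = 5)
  ser <- generate_replica_ensembles(cc, c(420, 500, 580), mm,
                                    store_coords = TRUE)
  for (ti in 1:3) {
    ens <- ser$ensembles[[ti]]
    sub <- ser$frames[ser$frames$temperature == ser$temperatures[ti], ]
    for (f in seq_len(n_frames(ens))) {
      geom <- assign_helix(get_frame(ens, f))
      expect_equal(geom$content, sub$helix_content[sub$frame == f])
    }
  }
})

test_that("toy thermodynamic samplers match their closed forms", {
  # harmonic: symmetric mean and variance kB*T/k within 5 percent
  hs <- generate_toy_thermo_samples(list(type = "harmonic", k = 1),
                                    300, 1e5, seed = 21)
  x <- hs$frames$coord
  expect_lt(abs(mean(x)), 4 * sd(x) / sqrt(length(x)))
  expect_equal(var(x), kB_kJmol * 300 / 1, tolerance = 0.05)
  expect_equal(hs$frames$energy, 0.5 * x^2)
  # two-state at delta_e = kB*T*ln 2: excited fraction 1/3
  de <- kB_kJmol * 300 * log(2)
  ts <- generate_toy_thermo_samples(list(type = "two_state", delta_e = de),
                                    300, 2e5, seed = 22)
  expect_equal(mean(ts$frames$coord), 1 / 3, tolerance = 0.02)
  expect_error(generate_toy_thermo_samples(list(type = "harmonic", k = -1),
                                           300, 10), "k > 0")
  expect_error(generate_toy_thermo_samples(list(type = "nope"), 300, 10),
               "harmonic")
})
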