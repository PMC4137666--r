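# Helper: a minimal two-chain structure with hand-placed atoms so that
# distances and angles are exact by construction.
make_pair_structure <- function(rows, xyz) {
  atoms <- data.frame(eleno = seq_len(nrow(xyz)),
                      elety = rows$elety, resid = rows$resid,
                      chain = rows$chain, resno = rows$resno,
                      stringsAsFactors = FALSE)
  structure(list(atoms = atoms, xyz = xyz), class = "cc_structure")
}

test_that("hydrogen-bond cutoffs are inclusive and flip at the boundary", {
  # donor N-H on chain A pointing at an acceptor O on chain B
  geom <- function(d, dev_deg) {
    # place O at distance d from N, with the H displaced so the
    # D-H-A deviation from linearity equals dev_deg
    N <- c(0, 0, 0); H <- c(1, 0, 0)
    # acceptor along a direction making deviation dev_deg at H; solve
    # |N - O| = d exactly with O = H + t*dir
    dir <- c(cos(dev_deg * pi / 180), sin(dev_deg * pi / 180), 0)
    tq <- -sum(H * dir) + sqrt(sum(H * dir)^2 - sum(H^2) + d^2)
    O <- H + tq * dir
    # extra residue 1 so the donor is not chain-initial
    rows <- data.frame(elety = c("CA", "N", "H", "CA", "O"),
                       resid = "ALA",
                       chain = c("A", "A", "A", "A", "B"),
                       resno = c(1L, 2L, 2L, 2L, 5L))
    make_pair_structure(rows, rbind(c(9, 9, 9), N, H, c(0, -1, 0), O))
  }
  expect_equal(nrow(detect_hbonds(geom(3.40, 25))), 1L)
  expect_equal(nrow(detect_hbonds(geom(3.60, 5))), 0L)   # distance fails
  expect_equal(nrow(detect_hbonds(geom(3.0, 35))), 0L)   # angle fails
  # boundary inclusivity: at the cutoffs the record is kept, just beyond
  # it is dropped
  expect_equal(nrow(detect_hbonds(geom(3.5 - 1e-9, 10))), 1L)
  expect_equal(nrow(detect_hbonds(geom(3.5 + 1e-3, 10))), 0L)
  expect_equal(nrow(detect_hbonds(geom(3.0, 30 - 1e-6))), 1L)
  expect_equal(nrow(detect_hbonds(geom(3.0, 30 + 1e-3))), 0L)
})

test_that("an ideal helix has exactly L-4 backbone i->i-4 hydrogen bonds
           per chain", {
  for (L in c(12, 21, 35)) {
    cc <- build_ideal_coiled_coil(strrep("A", L), crick_parameters())
    hb <- detect_hbonds(cc)
    counts <- classify_and_count(hb)
    expect_equal(counts$n[counts$class == "mainchain"], 3L * (L - 4L))
    # every bond is i -> i-4 within a chain
    expect_true(all(hb$resno1 - hb$resno2 == 4))
    expect_true(all(hb$chain1 == hb$chain2))
  }
})

test_that("salt bridges are intermonomer-only and respect protonation", {
  base_rows <- data.frame(elety = c("SCQ", "SCQ"),
                          resid = c("LYS", "GLU"),
                          chain = c("A", "B"), resno = c(3L, 9L))
  xyz <- rbind(c(0, 0, 0), c(3.9, 0, 0))
  st <- make_pair_structure(base_rows, xyz)
  neutral <- assign_protonation(c("A", "A", "K", "A", "A", "A", "A", "A",
                                  "E", "A"), 7.4)
  acid <- assign_protonation(c("A", "A", "K", "A", "A", "A", "A", "A",
                               "E", "A"), 1.6)
  expect_equal(nrow(detect_salt_bridges(st, neutral)), 1L)
  # same pair on the same chain: not counted
  same <- base_rows; same$chain <- c("A", "A")
  expect_equal(nrow(detect_salt_bridges(make_pair_structure(same, xyz),
                                        neutral)), 0L)
  # protonated Glu at acidic pH is no acceptor
  expect_equal(nrow(detect_salt_bridges(st, acid)), 0L)
  # boundary: 4.0 inclusive, beyond excluded
  xyz2 <- rbind(c(0, 0, 0), c(4.0, 0, 0))
  expect_equal(nrow(detect_salt_bridges(make_pair_structure(base_rows, xyz2),
                                        neutral)), 1L)
  xyz3 <- rbind(c(0, 0, 0), c(4.0 + 1e-3, 0, 0))
  expect_equal(nrow(detect_salt_bridges(make_pair_structure(base_rows, xyz3),
                                        neutral)), 0L)
})

test_that("hydrophobic contacts use side-chain centers of mass with an
           inclusive 7 A cutoff, across chains only", {
  rows <- data.frame(elety = c("SCM", "SCM", "SCM"),
                     resid = c("ALA", "ALA", "LEU"),
                     chain = c("A", "B", "A"), resno = c(1L, 1L, 5L))
  st <- make_pair_structure(rows, rbind(c(0, 0, 0), c(6.9, 0, 0),
                                        c(0, 1, 0)))
  hits <- detect_hydrophobic_contacts(st)
  expect_equal(nrow(hits), 2L)  # A1-B1 (6.9) and A5-B1 (sqrt(6.9^2+1)<7.0)
  st2 <- make_pair_structure(rows, rbind(c(0, 0, 0), c(7.1, 0, 0),
                                         c(0, 30, 0)))
  expect_equal(nrow(detect_hydrophobic_contacts(st2)), 0L)
  # non-hydrophobic residues never pair
  rows$resid <- c("ASP", "ALA", "LEU")
  st3 <- make_pair_structure(rows, rbind(c(0, 0, 0), c(6.9, 0, 0),
                                         c(0, 30, 0)))
  expect_equal(nrow(detect_hydrophobic_contacts(st3)), 0L)
})

test_that("interaction counts match brute-force double loops on random
           frames", {
  for (seed in 1:6) {
    st <- fixture_random_frame(seed)
    expect_gte(nrow(st$atoms), 200)
    expect_lte(nrow(st$atoms), 520)
    hb <- detect_hbonds(st)
    expect_equal(nrow(hb), oracle_count_backbone_hbonds(st))
    hc <- detect_hydrophobic_contacts(st)
    expect_equal(nrow(hc), oracle_count_hydrophobic(st,
                                                    hydrophobic_residues))
    sb <- detect_salt_bridges(st)
    expect_equal(nrow(sb), oracle_count_salt_bridges(st))
  }
})

test_that("classification partitions records and symmetry gives equal
           per-chain-pair counts", {
  cc <- fixture_trimer()
  hb <- detect_hbonds(cc)
  counts <- classify_and_count(hb)
  expect_equal(sum(counts$n[counts$kind == "hbond"]), nrow(hb))
  expect_true(all(counts$n >= 0))
  # C3 frame: hydrophobic contacts equal across the three chain pairs
  hc <- detect_hydrophobic_contacts(cc)
  pair <- paste(pmin(hc$chain1, hc$chain2), pmax(hc$chain1, hc$chain2))
  expect_equal(length(unique(table(pair))), 1L)
})

test_that("helix content is bounded, flips with single-residue dihedral
           changes, and errors on tiny chains", {
  cc <- build_ideal_coiled_coil(strrep("A", 10), crick_parameters())
  res <- assign_helix(cc)
  expect_equal(res$content, 100)
  expect_true(all(res$flags$helical))
  # fully extended chain: 0 percent
  ext <- asNamespace("coilstab")$backbone_from_dihedrals(rep(180, 8),
                                                         rep(180, 8))
  atoms <- data.frame(eleno = 1:24, elety = rep(c("N", "CA", "C"), 8),
                      resid = "ALA", chain = "A",
                      resno = rep(1:8, each = 3))
  st <- structure(list(atoms = atoms, xyz = ext), class = "cc_structure")
  expect_equal(assign_helix(st)$content, 0)
  short <- structure(list(atoms = atoms[1:6, ], xyz = ext[1:6, ]),
                     class = "cc_structure")
  expect_error(assign_helix(short), "shorter than 3")
})
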