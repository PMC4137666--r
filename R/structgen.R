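# Ideal coiled-coil construction from Crick parameters.
#
# A straight alpha-helix is first built from ideal backbone internal
# coordinates, its exact screw axis extracted, and the chain then wound onto
# the supercoil by mapping transverse offsets through the moving radial
# frame of the supercoil centerline. Because the radial frame itself rotates
# with the supercoil, the straight-helix twist plays the role of the Crick
# local frequency w1 (phase measured relative to the radially outward
# direction), which is what makes heptad positions face the core
# consistently along the bundle.

#' Crick parameters of an ideal coiled coil
#'
#' Bundle of geometric parameters consumed by [build_ideal_coiled_coil()].
#' Defaults describe a canonical left-handed trimeric coiled coil with a
#' 7/2 sequence repeat: local helix frequency `w1 = 720/7` degrees per
#' residue so that one heptad closes exactly two local turns, and the
#' supercoil frequency derived from the pitch when not given explicitly.
#'
#' @param supercoil_radius_R0 distance (Angstrom) from each helix axis to
#'   the bundle axis.
#' @param helix_radius_R1 alpha-carbon helix radius (Angstrom).
#' @param supercoil_frequency_w0 supercoil phase advance in degrees per
#'   residue (negative = left-handed). When `NULL`, computed as
#'   `-360 * rise_per_residue / pitch`.
#' @param helix_frequency_w1 local helix phase advance, degrees per residue.
#' @param rise_per_residue axial rise (Angstrom) per residue along the
#'   local helix axis.
#' @param symmetry_order number of chains (3 for a C3 trimer).
#' @param registry_offset heptad register offset, an integer 0-6 rotating
#'   which face of the helix points at the core.
#' @param pitch supercoil pitch (Angstrom), used only to derive `w0`.
#' @return an object of class `crick_parameters`.
#' @export
crick_parameters <- function(supercoil_radius_R0 = 6.1,
                             helix_radius_R1 = 2.26,
                             supercoil_frequency_w0 = NULL,
                             helix_frequency_w1 = 720 / 7,
                             rise_per_residue = 1.51,
                             symmetry_order = 3,
                             registry_offset = 0,
                             pitch = 190) {
  if (supercoil_radius_R0 <= 0) stop("supercoil_radius_R0 must be > 0")
  if (helix_radius_R1 <= 0) stop("helix_radius_R1 must be > 0")
  if (symmetry_order < 2) stop("symmetry_order must be >= 2")
  if (!(registry_offset %in% 0:6)) stop("registry_offset must be in 0..6")
  if (is.null(supercoil_frequency_w0))
    supercoil_frequency_w0 <- -360 * rise_per_residue / pitch
  structure(list(supercoil_radius_R0 = supercoil_radius_R0,
                 helix_radius_R1 = helix_radius_R1,
                 supercoil_frequency_w0 = supercoil_frequency_w0,
                 helix_frequency_w1 = helix_frequency_w1,
                 rise_per_residue = rise_per_residue,
                 symmetry_order = as.integer(symmetry_order),
                 registry_offset = as.integer(registry_offset)),
            class = "crick_parameters")
}

# Backbone N/CA/C coordinates (3L x 3 matrix) from per-residue dihedrals.
backbone_from_dihedrals <- function(phi, psi) {
  g <- backbone_geometry
  build_backbone_cpp(phi, psi, g$omega, g$b_n_ca, g$b_ca_c, g$b_c_n,
                     g$a_c_n_ca, g$a_n_ca_c, g$a_ca_c_n)
}

# Exact screw transform of a periodic helix: least-squares transform mapping
# residues 1..L-1 onto residues 2..L of a backbone matrix, decomposed into
# twist per residue (degrees), rise per residue and the screw axis (unit
# direction u, point p with u.p = 0).
screw_parameters <- function(bb) {
  L <- nrow(bb) / 3
  P <- bb[1:(3 * (L - 1)), , drop = FALSE]
  Q <- bb[(3 + 1):(3 * L), , drop = FALSE]
  fit <- kabsch(P, Q)
  tvec <- fit$translation
  R <- t(fit$rotation)           # column-vector convention for axis/angle
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  sin2 <- vnorm(ax) / 2
  cos2 <- (sum(diag(R)) - 1) / 2
  angle <- atan2(sin2, cos2)
  u <- unit(ax)
  rise <- sum(tvec * u)
  if (rise < 0) { u <- -u; rise <- -rise; angle <- -angle }
  # point on axis: solve (I - R^T) p = perpendicular part of translation,
  # in the row-vector convention x_new = x %*% R + t
  A <- diag(3) - R
  t_perp <- tvec - rise * u
  p <- solve(A + outer(u, u), t_perp)
  list(twist = angle * 180 / pi, rise = rise, axis = u, point = p)
}

# Rigidly move a backbone so its screw axis is +z through the origin with
# residue index increasing along +z.
align_helix_to_z <- function(bb, scr) {
  u <- scr$axis
  a <- unit(if (abs(u[1]) < 0.9) pracma_cross(u, c(1, 0, 0)) else
              pracma_cross(u, c(0, 1, 0)))
  b <- pracma_cross(u, a)
  G <- rbind(a, b, u)            # rows form an orthonormal frame, u -> z
  sweep(bb, 2, scr$point) %*% t(G)
}

pracma_cross <- function(x, y) {
  c(x[2] * y[3] - x[3] * y[2],
    x[3] * y[1] - x[1] * y[3],
    x[1] * y[2] - x[2] * y[1])
}

rot_z <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), sin(r), 0, -sin(r), cos(r), 0, 0, 0, 1), 3, 3)
}

# Build a straight ideal helix for `sequence`, aligned to the z axis, with
# per-residue twist and rise adjusted exactly to w1 (deg/res) and rise (A),
# and CA radius scaled to R1.
straight_reference_helix <- function(sequence, w1, rise, R1) {
  L <- length(sequence)
  bb <- backbone_from_dihedrals(rep(helix_dihedrals[["phi"]], L),
                                rep(helix_dihedrals[["psi"]], L))
  scr <- screw_parameters(bb)
  bb <- align_helix_to_z(bb, scr)
  # per-residue corrections: twist to w1, axial scale to the requested rise
  dtw <- w1 - scr$twist
  for (i in seq_len(L)) {
    rows <- (3 * i - 2):(3 * i)
    bb[rows, ] <- bb[rows, , drop = FALSE] %*% rot_z(dtw * (i - 1))
  }
  bb[, 3] <- bb[, 3] * rise / scr$rise
  ca <- bb[seq(2, 3 * L, by = 3), , drop = FALSE]
  r_act <- mean(sqrt(ca[, 1]^2 + ca[, 2]^2))
  bb[, 1:2] <- bb[, 1:2] * R1 / r_act
  bb
}

# Map points expressed in the straight-helix frame (helix axis = z, rise d
# per residue) onto the supercoil: transverse (x, y) offsets are carried by
# the radial frame of the supercoil centerline at arc parameter t = z / d.
supercoil_map <- function(xyz, R0, w0_deg, d, phase_deg = 0) {
  w0 <- w0_deg * pi / 180
  if (abs(R0 * w0) >= d)
    stop("supercoil too tight: |R0 * w0| must be < rise per residue")
  dz <- sqrt(d^2 - (R0 * w0)^2)
  t <- xyz[, 3] / d
  th <- w0 * t + phase_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  # tangent of the centerline (unit), radial direction u = (ct, st, 0)
  tn <- cbind(-R0 * w0 * st, R0 * w0 * ct, rep(dz, length(t))) / d
  e2 <- cbind(tn[, 2] * 0 - tn[, 3] * st,
              tn[, 3] * ct - tn[, 1] * 0,
              tn[, 1] * st - tn[, 2] * ct)   # t x u
  cbind(R0 * ct, R0 * st, dz * t) + xyz[, 1] * cbind(ct, st, 0) + xyz[, 2] * e2
}

# Given backbone N/CA/C coordinates and the sequence, assemble a full chain
# atom table: N, H, CA, C, O plus side-chain pseudo-atoms SCM (side-chain
# center of mass) and SCQ (charged-group center for K/R/H/D/E).
decorate_chain <- function(bb, sequence, chain_id = "A", start_resno = 1) {
  L <- length(sequence)
  iN <- seq(1, 3 * L, 3); iCA <- iN + 1; iC <- iN + 2
  N <- bb[iN, , drop = FALSE]; CA <- bb[iCA, , drop = FALSE]
  C <- bb[iC, , drop = FALSE]
  g <- backbone_geometry
  # carbonyl O: opposite the bisector of CA-C-N(i+1); terminal O by
  # continuing the final psi plane
  O <- matrix(NA_real_, L, 3)
  if (L > 1) {
    dir <- -(t(apply(CA[-L, , drop = FALSE] - C[-L, , drop = FALSE], 1, unit)) +
             t(apply(N[-1, , drop = FALSE] - C[-L, , drop = FALSE], 1, unit)))
    dir <- dir / sqrt(rowSums(dir^2))
    O[-L, ] <- C[-L, , drop = FALSE] + g$b_c_o * dir
  }
  O[L, ] <- nerf_place_r(N[L, ], CA[L, ], C[L, ], g$b_c_o, g$a_ca_c_o, 133)
  # amide H: 1.00 A from N, in the C(i-1)/N/CA plane, opposite the bisector;
  # none for residue 1 or proline
  H <- matrix(NA_real_, L, 3)
  for (i in 2:L) {
    if (sequence[i] == "P") next
    H[i, ] <- amide_h_position(C[i - 1, ], N[i, ], CA[i, ])
  }
  # side-chain pseudo-atoms along the canonical CB direction
  SCM <- matrix(NA_real_, L, 3); SCQ <- matrix(NA_real_, L, 3)
  for (i in seq_len(L)) {
    d_com <- sidechain_com_distance[[sequence[i]]]
    if (is.na(d_com)) next
    dir <- cb_direction(N[i, ], CA[i, ], C[i, ])
    SCM[i, ] <- CA[i, ] + d_com * dir
    if (sequence[i] %in% charged_residues)
      SCQ[i, ] <- CA[i, ] + (d_com + 2.5) * dir
  }
  rows <- list(); xyz <- list()
  for (i in seq_len(L)) {
    resno <- start_resno + i - 1
    res3 <- aa_three[[sequence[i]]]
    add <- function(ety, coord) {
      rows[[length(rows) + 1]] <<- c(ety, res3, chain_id, resno)
      xyz[[length(xyz) + 1]] <<- coord
    }
    add("N", N[i, ])
    if (!is.na(H[i, 1])) add("H", H[i, ])
    add("CA", CA[i, ]); add("C", C[i, ]); add("O", O[i, ])
    if (!is.na(SCM[i, 1])) add("SCM", SCM[i, ])
    if (!is.na(SCQ[i, 1])) add("SCQ", SCQ[i, ])
  }
  m <- do.call(rbind, rows)
  atoms <- data.frame(eleno = seq_len(nrow(m)), elety = m[, 1],
                      resid = m[, 2], chain = m[, 3],
                      resno = as.integer(m[, 4]), stringsAsFactors = FALSE)
  new_structure(atoms, do.call(rbind, xyz))
}

# Unit vector from CA toward the side chain (canonical CB direction for an
# L-amino acid), from the backbone N, CA, C positions.
cb_direction <- function(N, CA, C) {
  u1 <- unit(N - CA); u2 <- unit(C - CA)
  b <- unit(u1 + u2)
  n <- unit(pracma_cross(u1, u2))
  gamma <- 51.75 * pi / 180
  unit(-b * cos(gamma) + n * sin(gamma))
}

amide_h_position <- function(C_prev, N, CA) {
  N - unit(unit(C_prev - N) + unit(CA - N)) * backbone_geometry$b_n_h
}

# Single-atom NeRF placement in R (used for terminal atoms).
nerf_place_r <- function(A, B, C, bond, angle, dihedral) {
  ar <- angle * pi / 180; dr <- dihedral * pi / 180
  bc <- unit(C - B); ab <- unit(B - A)
  n <- unit(pracma_cross(ab, bc)); m <- pracma_cross(n, bc)
  C + bond * (-cos(ar) * bc + sin(ar) * cos(dr) * m + sin(ar) * sin(dr) * n)
}

#' Build an ideal symmetric coiled coil
#'
#' Constructs an idealised parallel coiled-coil bundle of identical chains
#' from a sequence and a set of Crick parameters. Each chain carries backbone
#' N, H, CA, C, O atoms plus one side-chain center-of-mass pseudo-atom (SCM)
#' per non-glycine residue and an additional charged-group pseudo-atom (SCQ)
#' for K/R/H/D/E. Chains are labelled A, B, C, ... and are related by exact
#' rotations of `360 / symmetry_order` degrees about the bundle (z) axis.
#'
#' @param sequence amino-acid sequence (one-letter string or character
#'   vector), at least 7 residues of the standard 20-letter alphabet.
#' @param params a [crick_parameters()] object.
#' @return a `cc_structure`.
#' @examples
#' cc <- build_ideal_coiled_coil(strrep("A", 21), crick_parameters())
#' estimate_supercoil_radius(cc)
#' @export
build_ideal_coiled_coil <- function(sequence, params = crick_parameters()) {
  sequence <- check_sequence(sequence, min_length = 7)
  stopifnot(inherits(params, "crick_parameters"))
  bb <- straight_reference_helix(sequence, params$helix_frequency_w1,
                                 params$rise_per_residue,
                                 params$helix_radius_R1)
  bb <- bb %*% rot_z(params$registry_offset * params$helix_frequency_w1)
  chains <- lapply(seq_len(params$symmetry_order) - 1, function(k) {
    mapped <- supercoil_map(bb, params$supercoil_radius_R0,
                            params$supercoil_frequency_w0,
                            params$rise_per_residue,
                            phase_deg = 360 * k / params$symmetry_order)
    decorate_chain(mapped, sequence, chain_id = LETTERS[k + 1])
  })
  atoms <- do.call(rbind, lapply(chains, `[[`, "atoms"))
  atoms$eleno <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  new_structure(atoms, do.call(rbind, lapply(chains, `[[`, "xyz")))
}

#' Place or rebuild backbone amide hydrogens
#'
#' Positions each amide hydrogen 1.00 Angstrom from the backbone nitrogen,
#' in the plane of C(i-1), N(i), CA(i), opposite the bisector of the
#' C(i-1)-N-CA angle. Chain-initial residues and prolines receive no amide
#' hydrogen; existing H atoms are re-positioned.
#'
#' @param struct a `cc_structure` with complete backbone N, CA, C atoms.
#' @return the structure with H atoms placed.
#' @export
place_amide_hydrogens <- function(struct) {
  stopifnot(inherits(struct, "cc_structure"))
  a <- struct$atoms
  keep <- a$elety != "H"
  a2 <- a[keep, , drop = FALSE]
  xyz2 <- struct$xyz[keep, , drop = FALSE]
  new_rows <- list(); new_xyz <- list()
  for (ch in unique(a2$chain)) {
    idx_for <- function(ety) {
      s <- which(a2$chain == ch & a2$elety == ety)
      s[order(a2$resno[s])]
    }
    iN <- idx_for("N"); iCA <- idx_for("CA"); iC <- idx_for("C")
    if (length(iN) < 2 || length(iN) != length(iCA) ||
        length(iN) != length(iC))
      stop("missing backbone atoms in chain ", ch, call. = FALSE)
    for (j in 2:length(iN)) {
      if (a2$resid[iN[j]] == "PRO") next
      h <- amide_h_position(xyz2[iC[j - 1], ], xyz2[iN[j], ], xyz2[iCA[j], ])
      new_rows[[length(new_rows) + 1]] <-
        data.frame(eleno = NA_integer_, elety = "H",
                   resid = a2$resid[iN[j]], chain = ch,
                   resno = a2$resno[iN[j]], stringsAsFactors = FALSE)
      new_xyz[[length(new_xyz) + 1]] <- h
    }
  }
  atoms <- rbind(a2, do.call(rbind, new_rows))
  xyz <- rbind(xyz2, do.call(rbind, new_xyz))
  # keep a stable atom order: chain, residue, then canonical atom rank
  rank <- match(atoms$elety, c("N", "H", "CA", "C", "O", "OXT", "SCM", "SCQ"))
  rank[is.na(rank)] <- 99
  o <- order(atoms$chain, atoms$resno, rank)
  atoms <- atoms[o, , drop = FALSE]
  atoms$eleno <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  new_structure(atoms, xyz[o, , drop = FALSE])
}
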