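# Geometric interaction census: hydrogen bonds, salt bridges, hydrophobic
# contacts and helix-content assignment. All distance/angle cutoffs are
# inclusive (<=).

backbone_atom_names <- c("N", "H", "CA", "C", "O", "OXT")

# Side-chain donor heavy atoms and acceptor atoms by residue, using
# standard PDB atom names (full-atom structures). Pseudo-atom structures
# built by this package carry no side-chain donors/acceptors for H-bonds.
sidechain_donor_atoms <- list(
  SER = "OG", THR = "OG1", ASN = "ND2", GLN = "NE2", LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"), TYR = "OH",
  TRP = "NE1"
)
sidechain_acceptor_atoms <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2")
)

new_interaction_set <- function(df) {
  cols <- c("kind", "chain1", "resno1", "resid1", "atom1",
            "chain2", "resno2", "resid2", "atom2", "distance", "angle",
            "class")
  if (is.null(df) || nrow(df) == 0) {
    df <- tibble::tibble(kind = character(0), chain1 = character(0),
                         resno1 = integer(0), resid1 = character(0),
                         atom1 = character(0), chain2 = character(0),
                         resno2 = integer(0), resid2 = character(0),
                         atom2 = character(0), distance = numeric(0),
                         angle = numeric(0), class = character(0))
  }
  structure(tibble::as_tibble(df[, cols]), class = c("cc_interaction_set",
                                                     class(tibble::tibble())))
}

interaction_class <- function(kind, chain1, chain2, atom1, atom2) {
  ifelse(chain1 != chain2, "intermonomer",
         ifelse(kind == "hbond" & atom1 %in% backbone_atom_names &
                  atom2 %in% backbone_atom_names, "mainchain",
                "intramonomer"))
}

# protonation = NULL means a default neutral-pH (7.4) assignment derived
# from the first chain's sequence (structures are assumed homomeric).
resolve_protonation <- function(frame, protonation, pH = 7.4) {
  if (!is.null(protonation)) {
    stopifnot(inherits(protonation, "cc_protonation"))
    return(protonation)
  }
  assign_protonation(structure_sequence(frame)[[1]], pH = pH)
}

protonated_resnos <- function(protonation, resids) {
  sc <- protonation$sidechains
  sc$resno[sc$resid %in% resids & sc$protonated]
}

#' Detect hydrogen bonds
#'
#' Geometric hydrogen-bond detection with inclusive cutoffs on the
#' donor-acceptor heavy-atom distance and on the deviation of the
#' donor-H-acceptor angle from linearity. One record is produced per
#' (donor hydrogen, acceptor) pair. The donor/acceptor catalog covers the
#' backbone amide N-H and carbonyl O plus the standard side-chain
#' donors/acceptors (S/T/N/Q/K/R/H/Y/W and unprotonated D/E) when their
#' full-atom names are present. Donors whose hydrogen is missing are
#' skipped with a warning, except chain-initial residues and prolines,
#' which have no amide hydrogen by construction.
#'
#' @param frame a `cc_structure` with donor hydrogens placed (see
#'   [place_amide_hydrogens()]).
#' @param d_max maximum donor-acceptor distance (Angstrom).
#' @param a_max maximum deviation from donor-H-acceptor linearity (degrees).
#' @param protonation optional [assign_protonation()] result for one chain
#'   (applied to all chains); protonated carboxyls are not acceptors.
#' @return a `cc_interaction_set` tibble; `angle` holds the deviation from
#'   linearity in degrees.
#' @export
detect_hbonds <- function(frame, d_max = 3.5, a_max = 30,
                          protonation = NULL) {
  stopifnot(inherits(frame, "cc_structure"))
  a <- frame$atoms
  X <- frame$xyz
  prot <- resolve_protonation(frame, protonation)
  rkey <- paste(a$chain, a$resno)

  # hydrogen attached to a donor heavy atom: same residue, name starting
  # with H, within 1.25 A
  donors <- list()
  cand <- which((a$elety == "N" & a$resid != "PRO") |
                  mapply(function(res, ety) ety %in%
                           (sidechain_donor_atoms[[res]] %||% character(0)),
                         a$resid, a$elety))
  first_res <- tapply(a$resno, a$chain, min)
  h_idx_all <- which(substr(a$elety, 1, 1) == "H")
  for (i in cand) {
    if (a$elety[i] == "N" && a$resno[i] == first_res[[a$chain[i]]]) next
    hs <- h_idx_all[rkey[h_idx_all] == rkey[i]]
    if (length(hs)) {
      d2 <- rowSums((X[hs, , drop = FALSE] -
                       matrix(X[i, ], length(hs), 3, byrow = TRUE))^2)
      hs <- hs[d2 <= 1.25^2]
    }
    if (!length(hs)) {
      warning("donor ", a$elety[i], " of ", a$resid[i], a$resno[i],
              " chain ", a$chain[i], " has no hydrogen; skipped",
              call. = FALSE)
      next
    }
    donors[[length(donors) + 1]] <- cbind(i, hs)
  }
  donors <- if (length(donors)) do.call(rbind, donors) else
    matrix(integer(0), 0, 2)

  excl_d <- protonated_resnos(prot, c("D", "E"))
  acc <- which(
    a$elety %in% c("O", "OXT") |
      mapply(function(res, ety, rn) {
        ety %in% (sidechain_acceptor_atoms[[res]] %||% character(0)) &&
          !(res %in% c("ASP", "GLU") && rn %in% excl_d)
      }, a$resid, a$elety, a$resno))

  if (nrow(donors) == 0 || length(acc) == 0) return(new_interaction_set(NULL))
  Dm <- X[donors[, 1], , drop = FALSE]
  Am <- X[acc, , drop = FALSE]
  d2 <- outer(rowSums(Dm^2), rowSums(Am^2), "+") - 2 * Dm %*% t(Am)
  pairs <- which(d2 <= d_max^2, arr.ind = TRUE)
  if (nrow(pairs)) {   # drop same-residue pairs
    keep <- rkey[donors[pairs[, 1], 1]] != rkey[acc[pairs[, 2]]]
    pairs <- pairs[keep, , drop = FALSE]
  }
  if (nrow(pairs) == 0) return(new_interaction_set(NULL))
  di <- donors[pairs[, 1], 1]; hi <- donors[pairs[, 1], 2]
  ai <- acc[pairs[, 2]]
  dev <- 180 - vertex_angle(X[di, , drop = FALSE], X[hi, , drop = FALSE],
                            X[ai, , drop = FALSE])
  keep <- dev <= a_max
  di <- di[keep]; hi <- hi[keep]; ai <- ai[keep]; dev <- dev[keep]
  if (!length(di)) return(new_interaction_set(NULL))
  dist <- sqrt(rowSums((X[di, , drop = FALSE] - X[ai, , drop = FALSE])^2))
  new_interaction_set(tibble::tibble(
    kind = "hbond",
    chain1 = a$chain[di], resno1 = a$resno[di], resid1 = a$resid[di],
    atom1 = a$elety[di],
    chain2 = a$chain[ai], resno2 = a$resno[ai], resid2 = a$resid[ai],
    atom2 = a$elety[ai],
    distance = dist, angle = dev,
    class = interaction_class("hbond", a$chain[di], a$chain[ai],
                              a$elety[di], a$elety[ai])
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Charged-atom catalog for salt bridges. Basic groups participate when
# protonated (charged); acidic groups when deprotonated (charged). On
# pseudo-atom structures the SCQ charged-group pseudo-atom substitutes.
salt_bridge_atoms <- function(frame, protonation) {
  a <- frame$atoms
  prot <- protonation
  his_prot <- protonated_resnos(prot, "H")
  de_prot <- protonated_resnos(prot, c("D", "E"))
  last_res <- tapply(a$resno, a$chain, max)
  first_res <- tapply(a$resno, a$chain, min)
  is_cterm <- a$resno == unname(last_res[a$chain])
  is_nterm <- a$resno == unname(first_res[a$chain])

  basic <- (a$resid == "LYS" & a$elety %in% c("NZ", "SCQ")) |
    (a$resid == "ARG" & a$elety %in% c("NE", "NH1", "NH2", "SCQ")) |
    (a$resid == "HIS" & a$elety %in% c("ND1", "NE2", "SCQ") &
       a$resno %in% his_prot) |
    (is_nterm & a$elety == "N" & prot$nterm_protonated)
  acidic <- (a$resid == "ASP" & a$elety %in% c("OD1", "OD2", "SCQ") &
               !(a$resno %in% de_prot)) |
    (a$resid == "GLU" & a$elety %in% c("OE1", "OE2", "SCQ") &
       !(a$resno %in% de_prot)) |
    (is_cterm & a$elety %in% c("O", "OXT") & !prot$cterm_protonated)
  list(basic = which(basic), acidic = which(acidic))
}

#' Detect salt bridges
#'
#' Records a salt bridge for every pair of oppositely charged groups on
#' different chains whose closest charged-atom distance is at or below
#' `d_max`; no angular test is applied. Only intermonomer pairs are
#' reported. Protonated carboxyls (acidic pH) carry no charge and are
#' excluded; basic groups participate only while protonated.
#' Records are per residue pair, with the closest atom pair and its
#' distance.
#'
#' @param frame a `cc_structure`.
#' @param protonation optional [assign_protonation()] result for one chain
#'   (applied to all chains); defaults to neutral pH 7.4.
#' @param d_max maximum donor-acceptor atom distance (Angstrom).
#' @return a `cc_interaction_set`.
#' @export
detect_salt_bridges <- function(frame, protonation = NULL, d_max = 4.0) {
  stopifnot(inherits(frame, "cc_structure"))
  a <- frame$atoms; X <- frame$xyz
  prot <- resolve_protonation(frame, protonation)
  grp <- salt_bridge_atoms(frame, prot)
  if (!length(grp$basic) || !length(grp$acidic))
    return(new_interaction_set(NULL))
  B <- X[grp$basic, , drop = FALSE]; A2 <- X[grp$acidic, , drop = FALSE]
  d2 <- outer(rowSums(B^2), rowSums(A2^2), "+") - 2 * B %*% t(A2)
  pairs <- which(d2 <= d_max^2, arr.ind = TRUE)
  if (nrow(pairs) == 0) return(new_interaction_set(NULL))
  bi <- grp$basic[pairs[, 1]]; ai <- grp$acidic[pairs[, 2]]
  keep <- a$chain[bi] != a$chain[ai]
  bi <- bi[keep]; ai <- ai[keep]
  if (!length(bi)) return(new_interaction_set(NULL))
  dist <- sqrt(rowSums((X[bi, , drop = FALSE] - X[ai, , drop = FALSE])^2))
  df <- tibble::tibble(
    kind = "saltbridge",
    chain1 = a$chain[bi], resno1 = a$resno[bi], resid1 = a$resid[bi],
    atom1 = a$elety[bi],
    chain2 = a$chain[ai], resno2 = a$resno[ai], resid2 = a$resid[ai],
    atom2 = a$elety[ai],
    distance = dist, angle = NA_real_, class = "intermonomer")
  # one record per residue pair: keep the closest atom pair
  key <- paste(df$chain1, df$resno1, df$chain2, df$resno2)
  df <- df[order(key, df$distance), ]
  df <- df[!duplicated(paste(df$chain1, df$resno1, df$chain2, df$resno2)), ]
  new_interaction_set(df)
}

# Side-chain center of mass per residue: the SCM pseudo-atom when present,
# otherwise the mean of side-chain heavy atoms. Residues without side-chain
# heavy atoms (Gly) are excluded.
sidechain_coms <- function(frame) {
  a <- frame$atoms; X <- frame$xyz
  sc <- !(a$elety %in% backbone_atom_names) &
    substr(a$elety, 1, 1) != "H" & a$elety != "SCQ"
  if (!any(sc)) return(NULL)
  key <- paste(a$chain[sc], a$resno[sc], sep = "_")
  sums <- rowsum(X[sc, , drop = FALSE], key)   # rows ordered by sorted key
  ord_key <- rownames(sums)
  counts <- as.vector(table(key)[ord_key])
  coms <- sums / counts
  meta <- a[sc, ][match(ord_key, key), c("chain", "resno", "resid")]
  list(com = coms, chain = meta$chain, resno = meta$resno,
       resid = meta$resid)
}

#' Detect intermonomer hydrophobic contacts
#'
#' Records one contact per unordered pair of hydrophobic residues on
#' different chains whose side-chain centers of mass are at or below
#' `d_max` apart. On pseudo-atom structures the SCM atom is the center of
#' mass; on full-atom structures it is computed from the side-chain heavy
#' atoms. Glycine never participates.
#'
#' @param frame a `cc_structure`.
#' @param hydrophobic_set one-letter codes counted as hydrophobic.
#' @param d_max maximum center-of-mass distance (Angstrom).
#' @return a `cc_interaction_set` (atom fields are "SCM").
#' @export
detect_hydrophobic_contacts <- function(frame,
                                        hydrophobic_set = hydrophobic_residues,
                                        d_max = 7.0) {
  stopifnot(inherits(frame, "cc_structure"))
  cs <- sidechain_coms(frame)
  if (is.null(cs)) return(new_interaction_set(NULL))
  keep <- aa_one[cs$resid] %in% hydrophobic_set
  com <- cs$com[keep, , drop = FALSE]
  chain <- cs$chain[keep]; resno <- cs$resno[keep]; resid <- cs$resid[keep]
  n <- nrow(com)
  if (n < 2) return(new_interaction_set(NULL))
  d2 <- outer(rowSums(com^2), rowSums(com^2), "+") - 2 * com %*% t(com)
  pairs <- which(upper.tri(d2) & d2 <= d_max^2, arr.ind = TRUE)
  if (nrow(pairs)) {
    keep2 <- chain[pairs[, 1]] != chain[pairs[, 2]]
    pairs <- pairs[keep2, , drop = FALSE]
  }
  if (nrow(pairs) == 0) return(new_interaction_set(NULL))
  i <- pairs[, 1]; j <- pairs[, 2]
  new_interaction_set(tibble::tibble(
    kind = "hydrophobic",
    chain1 = chain[i], resno1 = resno[i], resid1 = resid[i], atom1 = "SCM",
    chain2 = chain[j], resno2 = resno[j], resid2 = resid[j], atom2 = "SCM",
    distance = sqrt(pmax(0, d2[cbind(i, j)])), angle = NA_real_,
    class = "intermonomer"))
}

#' Count interactions per kind and class
#'
#' Partitions an interaction set into mainchain (hydrogen bonds with both
#' partners backbone atoms of the same chain), intermonomer (partners on
#' different chains) and intramonomer records, and tabulates counts. The
#' counts sum to the record count of each kind.
#'
#' @param iset a `cc_interaction_set`.
#' @return a tibble with columns `kind`, `class`, `n`.
#' @export
classify_and_count <- function(iset) {
  stopifnot(inherits(iset, "cc_interaction_set"))
  if (nrow(iset) == 0)
    return(tibble::tibble(kind = character(0), class = character(0),
                          n = integer(0)))
  tb <- as.data.frame(table(kind = iset$kind, class = iset$class),
                      stringsAsFactors = FALSE)
  tb <- tb[tb$Freq > 0, ]
  tibble::tibble(kind = tb$kind, class = tb$class, n = as.integer(tb$Freq))
}

#' Assign per-residue helicity from backbone dihedrals
#'
#' A residue is helical when all of its available backbone dihedrals fall
#' inside the alpha-helical window phi in [-100, -30] and psi in [-67, -7]
#' degrees (chain-terminal residues have only one dihedral). Helix content
#' is the percentage of helical residues, averaged over chains.
#'
#' @param frame a `cc_structure` with complete backbone N, CA, C atoms and
#'   chains of at least 3 residues.
#' @return list with `flags` (data.frame chain, resno, phi, psi, helical)
#'   and `content` (percent, 0-100).
#' @export
assign_helix <- function(frame) {
  stopifnot(inherits(frame, "cc_structure"))
  lens <- table(frame$atoms$chain[frame$atoms$elety == "CA"])
  if (any(lens < 3))
    stop("helix content undefined for chains shorter than 3 residues",
         call. = FALSE)
  dh <- backbone_dihedrals(frame)
  win <- helix_window
  phi_ok <- is.na(dh$phi) |
    (dh$phi >= win$phi[1] & dh$phi <= win$phi[2])
  psi_ok <- is.na(dh$psi) |
    (dh$psi >= win$psi[1] & dh$psi <= win$psi[2])
  dh$helical <- phi_ok & psi_ok & !(is.na(dh$phi) & is.na(dh$psi))
  content <- mean(tapply(dh$helical, dh$chain, mean)) * 100
  list(flags = dh, content = content)
}
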