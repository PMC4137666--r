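# The atom-level structure container consumed by all geometric operations.
# A `cc_structure` keeps atom metadata (a plain data.frame) separate from the
# coordinate matrix so that ensembles can share one topology; a
# `cc_ensemble` is the same topology with a list of coordinate matrices.

new_structure <- function(atoms, xyz) {
  stopifnot(is.data.frame(atoms), nrow(atoms) == nrow(xyz), ncol(xyz) == 3)
  structure(list(atoms = atoms, xyz = unname(as.matrix(xyz))),
            class = "cc_structure")
}

new_ensemble <- function(atoms, xyz_list) {
  stopifnot(is.data.frame(atoms), is.list(xyz_list))
  structure(list(atoms = atoms, xyz = xyz_list), class = "cc_ensemble")
}

#' @export
print.cc_structure <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  cat("<cc_structure> ", nrow(x$atoms), " atoms, ",
      length(ch), " chain(s) [", paste(ch, collapse = ","), "], ",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), " residues\n",
      sep = "")
  invisible(x)
}

#' @export
print.cc_ensemble <- function(x, ...) {
  cat("<cc_ensemble> ", length(x$xyz), " frame(s) of ",
      nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param x a `cc_ensemble`
#' @export
n_frames <- function(x) length(x$xyz)

#' Extract one frame of an ensemble as a structure
#' @param x a `cc_ensemble`
#' @param i frame index (1-based)
#' @export
get_frame <- function(x, i) {
  stopifnot(inherits(x, "cc_ensemble"), i >= 1, i <= length(x$xyz))
  new_structure(x$atoms, x$xyz[[i]])
}

#' Combine structures sharing a topology into an ensemble
#' @param frames list of `cc_structure` objects with identical atom tables
#' @export
as_ensemble <- function(frames) {
  stopifnot(length(frames) >= 1)
  a0 <- frames[[1]]$atoms
  for (f in frames[-1])
    if (!identical(f$atoms[c("elety", "chain", "resno")],
                   a0[c("elety", "chain", "resno")]))
      stop("frames do not share a topology", call. = FALSE)
  new_ensemble(a0, lapply(frames, `[[`, "xyz"))
}

atom_index <- function(struct, elety = NULL, chain = NULL) {
  keep <- rep(TRUE, nrow(struct$atoms))
  if (!is.null(elety)) keep <- keep & struct$atoms$elety %in% elety
  if (!is.null(chain)) keep <- keep & struct$atoms$chain %in% chain
  which(keep)
}

#' Chain identifiers of a structure
#' @param struct a `cc_structure` or `cc_ensemble`
#' @export
chain_ids <- function(struct) unique(struct$atoms$chain)

#' One-letter sequence of each chain
#' @param struct a `cc_structure` or `cc_ensemble`
#' @return named list of one-letter residue vectors, one per chain
#' @export
structure_sequence <- function(struct) {
  a <- struct$atoms
  out <- lapply(chain_ids(struct), function(ch) {
    sub <- a[a$chain == ch & a$elety == "CA", , drop = FALSE]
    sub <- sub[order(sub$resno), ]
    unname(aa_one[sub$resid])
  })
  setNames(out, chain_ids(struct))
}

# Vector geometry ------------------------------------------------------------

vnorm <- function(v) sqrt(sum(v * v))
unit <- function(v) v / vnorm(v)

# Dihedral angle (degrees, in (-180, 180]) for rows of four coordinate
# matrices; vectorised over rows.
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cbind(b1[, 2] * b2[, 3] - b1[, 3] * b2[, 2],
              b1[, 3] * b2[, 1] - b1[, 1] * b2[, 3],
              b1[, 1] * b2[, 2] - b1[, 2] * b2[, 1])
  n2 <- cbind(b2[, 2] * b3[, 3] - b2[, 3] * b3[, 2],
              b2[, 3] * b3[, 1] - b2[, 1] * b3[, 3],
              b2[, 1] * b3[, 2] - b2[, 2] * b3[, 1])
  m1 <- cbind(n1[, 2] * b2[, 3] - n1[, 3] * b2[, 2],
              n1[, 3] * b2[, 1] - n1[, 1] * b2[, 3],
              n1[, 1] * b2[, 2] - n1[, 2] * b2[, 1])
  b2n <- sqrt(rowSums(b2 * b2))
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2) / b2n
  -atan2(y, x) * 180 / pi   # IUPAC sign convention
}

# Angle (degrees) at vertex b for rows of three coordinate matrices.
vertex_angle <- function(a, b, c) {
  v1 <- a - b; v2 <- c - b
  cosang <- rowSums(v1 * v2) /
    (sqrt(rowSums(v1 * v1)) * sqrt(rowSums(v2 * v2)))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Backbone phi/psi dihedrals of a structure
#'
#' Computes per-residue backbone dihedral angles chain by chain. The first
#' residue of a chain has no phi and the last no psi (returned as `NA`).
#'
#' @param struct a `cc_structure` with backbone N, CA, C atoms
#' @return a data.frame with columns chain, resno, resid, phi, psi
#' @export
backbone_dihedrals <- function(struct) {
  a <- struct$atoms
  out <- lapply(chain_ids(struct), function(ch) {
    idx <- function(ety) {
      sub <- which(a$chain == ch & a$elety == ety)
      sub[order(a$resno[sub])]
    }
    iN <- idx("N"); iCA <- idx("CA"); iC <- idx("C")
    L <- length(iCA)
    if (L < 2 || length(iN) != L || length(iC) != L)
      stop("incomplete backbone in chain ", ch, call. = FALSE)
    X <- struct$xyz
    phi <- rep(NA_real_, L); psi <- rep(NA_real_, L)
    if (L >= 2) {
      phi[2:L] <- dihedral_angle(X[iC[1:(L - 1)], , drop = FALSE],
                                 X[iN[2:L], , drop = FALSE],
                                 X[iCA[2:L], , drop = FALSE],
                                 X[iC[2:L], , drop = FALSE])
      psi[1:(L - 1)] <- dihedral_angle(X[iN[1:(L - 1)], , drop = FALSE],
                                       X[iCA[1:(L - 1)], , drop = FALSE],
                                       X[iC[1:(L - 1)], , drop = FALSE],
                                       X[iN[2:L], , drop = FALSE])
    }
    data.frame(chain = ch, resno = a$resno[iCA], resid = a$resid[iCA],
               phi = phi, psi = psi, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
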