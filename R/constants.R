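# Physical constants and residue-level lookup tables shared across modules.
# Units: lengths in Angstrom, angles in degrees, energies in kJ/mol,
# temperatures in K.

#' Boltzmann constant in kJ/mol/K
#'
#' The value used throughout the package for all Boltzmann factors and
#' free-energy conversions (the GROMACS/kJ convention).
#'
#' @export
kB_kJmol <- 0.0083144621

#' Default hydrophobic residue set
#'
#' One-letter codes of the apolar side chains used for heptad-register
#' scoring and hydrophobic-contact detection. Gly, Pro and Tyr are excluded;
#' the set is a single configurable constant, not a hard-coded rule.
#'
#' @export
hydrophobic_residues <- c("A", "V", "L", "I", "M", "F", "W")

#' Kyte-Doolittle hydropathy scale
#'
#' Named numeric vector of per-residue hydropathy values (positive =
#' hydrophobic) used by [hydrophobicity_profile()].
#'
#' @export
kyte_doolittle <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

#' Default side-chain pKa table
#'
#' Model pKa values for the titratable groups handled by
#' [assign_protonation()]. \code{NTERM}/\code{CTERM} are the backbone termini.
#'
#' @export
default_pka_table <- c(
  D = 3.65, E = 4.25, H = 6.0, K = 10.4, R = 12.0,
  CTERM = 3.6, NTERM = 8.0
)

# Approximate distance (Angstrom) from CA to the side-chain center of mass
# along the canonical CB direction; used to place the single side-chain
# pseudo-atom of built structures. Gly carries no side chain.
sidechain_com_distance <- c(
  A = 1.55, R = 4.10, N = 2.50, D = 2.45, C = 2.05,
  Q = 3.10, E = 3.05, G = NA,   H = 3.15, I = 2.30,
  L = 2.60, K = 3.50, M = 3.20, F = 3.40, P = 1.90,
  S = 1.90, T = 1.95, W = 3.90, Y = 3.80, V = 2.00
)

# Residues whose side chain carries a charged group pseudo-atom (placed
# 2.5 A beyond the side-chain center of mass along the CB direction).
charged_residues <- c("K", "R", "H", "D", "E")

# Backbone internal coordinates of the ideal peptide unit (lengths in A,
# angles in degrees) used by the chain builder.
backbone_geometry <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231, b_n_h = 1.00,
  a_c_n_ca = 121.7, a_n_ca_c = 111.2, a_ca_c_n = 116.6, a_ca_c_o = 120.5,
  omega = 180
)

# Ideal alpha-helical backbone dihedrals (degrees) used when a residue is
# built in the helical state.
helix_dihedrals <- c(phi = -57.8, psi = -47.0)

# Dihedral windows (degrees): a residue is called helical when its available
# backbone dihedrals fall inside these closed intervals.
helix_window <- list(phi = c(-100, -30), psi = c(-67, -7))

# Coil-state dihedral ranges for the synthetic generator; psi is disjoint
# from the helical psi window so a coil residue can never be called helical.
coil_dihedral_range <- list(phi = c(-180, -30), psi = c(60, 180))

#' Published 64-temperature replica ladder
#'
#' The 64 replica temperatures (K) of the reference replica-exchange
#' protocol for the lipoprotein coiled-coil systems, spanning 303.15 K to
#' 809.57 K. [make_ladder()] reproduces this ladder to within 0.5 K with a
#' constant-ratio (geometric) spacing.
#'
#' @export
remd_ladder_published <- c(
  303.15, 307.90, 312.72, 317.61, 322.59, 327.64, 332.77, 337.99,
  343.29, 348.68, 354.15, 359.70, 365.35, 371.08, 376.92, 382.83,
  388.86, 394.97, 401.18, 407.48, 413.91, 420.41, 427.03, 433.73,
  440.55, 447.48, 454.52, 461.68, 468.95, 476.33, 483.83, 491.44,
  499.18, 507.03, 515.01, 523.11, 531.35, 539.71, 547.96, 556.59,
  565.34, 574.24, 583.28, 592.47, 601.81, 611.28, 620.84, 630.62,
  640.54, 650.63, 660.87, 671.28, 681.85, 692.57, 703.47, 714.55,
  725.79, 737.21, 748.80, 760.60, 772.55, 784.71, 797.04, 809.57
)

# Amino-acid code conversion -------------------------------------------------

aa_three <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)
aa_one <- setNames(names(aa_three), unname(aa_three))

check_sequence <- function(sequence, min_length = 1) {
  if (length(sequence) == 1 && nchar(sequence) > 1)
    sequence <- strsplit(sequence, "")[[1]]
  sequence <- toupper(as.character(sequence))
  if (length(sequence) < min_length)
    stop("sequence must have at least ", min_length, " residues", call. = FALSE)
  bad <- setdiff(unique(sequence), names(aa_three))
  if (length(bad))
    stop("non-standard residue code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  sequence
}
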