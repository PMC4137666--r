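# Sequence-level analyses: heptad register, lipobox motif, hydropathy
# profile and pH-dependent protonation.

#' Assign the heptad register of a coiled-coil sequence
#'
#' Scores all seven register offsets and keeps the one that maximises the
#' hydrophobic occupancy of the core positions a and d (ties broken by the
#' smallest offset). With offset `o`, residue `i` receives heptad letter
#' `letters[((i - 1 + o) %% 7) + 1]` from a-g.
#'
#' @param sequence amino-acid sequence (string or character vector), at
#'   least 7 residues.
#' @param hydrophobic_set one-letter codes counted as hydrophobic.
#' @return an object of class `heptad_assignment`: list with `offset`,
#'   `positions` (per-residue letters a-g), `n_complete_heptads`, `score`
#'   (fraction of a/d positions occupied by hydrophobic residues) and the
#'   per-offset score table.
#' @examples
#' assign_heptad_register(strrep("LAALAAA", 4), hydrophobic_set = "L")
#' @export
assign_heptad_register <- function(sequence,
                                   hydrophobic_set = hydrophobic_residues) {
  s <- check_sequence(sequence, min_length = 7)
  L <- length(s)
  hydro <- s %in% hydrophobic_set
  scores <- vapply(0:6, function(o) {
    lett <- letters[((seq_len(L) - 1 + o) %% 7) + 1]
    core <- lett %in% c("a", "d")
    sum(hydro & core) / sum(core)
  }, numeric(1))
  offset <- which.max(scores) - 1L   # which.max takes the first maximum
  structure(list(
    offset = offset,
    positions = letters[((seq_len(L) - 1 + offset) %% 7) + 1],
    n_complete_heptads = L %/% 7L,
    score = scores[offset + 1],
    offset_scores = setNames(scores, 0:6)
  ), class = "heptad_assignment")
}

#' @export
print.heptad_assignment <- function(x, ...) {
  cat("<heptad_assignment> offset ", x$offset, ", ",
      x$n_complete_heptads, " complete heptads, a/d hydrophobic occupancy ",
      round(x$score, 3), "\n", sep = "")
  invisible(x)
}

#' Scan a sequence for the lipobox motif
#'
#' Finds every occurrence of the bacterial lipoprotein lipobox
#' L-(A/S)-(G/A)-C. The lipidated cysteine is the fourth position of the
#' motif and signal-peptide cleavage occurs immediately before it.
#'
#' @param sequence amino-acid sequence (string or character vector).
#' @return a tibble with one row per match: `start` (motif start, 1-based),
#'   `cys_position`, and `cleavage_site` formatted as "20|21" for cleavage
#'   between residues cys-1 and cys. Zero rows when there is no match.
#' @export
scan_lipobox <- function(sequence) {
  s <- if (length(sequence) == 1 && nchar(sequence) > 1)
    strsplit(toupper(sequence), "")[[1]] else toupper(as.character(sequence))
  L <- length(s)
  hits <- integer(0)
  if (L >= 4) {
    for (i in seq_len(L - 3)) {
      if (s[i] == "L" && s[i + 1] %in% c("A", "S") &&
          s[i + 2] %in% c("G", "A") && s[i + 3] == "C")
        hits <- c(hits, i)
    }
  }
  tibble::tibble(
    start = hits,
    cys_position = hits + 3L,
    cleavage_site = if (length(hits)) sprintf("%d|%d", hits + 2L, hits + 3L)
                    else character(0)
  )
}

#' Sliding-window hydrophobicity profile
#'
#' Mean Kyte-Doolittle hydropathy in a centered window of odd width; the
#' window is truncated at the sequence ends.
#'
#' @param sequence amino-acid sequence (string or character vector).
#' @param window odd window width, at most the sequence length.
#' @param scale named hydropathy scale (defaults to [kyte_doolittle]).
#' @return a tibble with `position`, `residue` and `hydropathy`.
#' @export
hydrophobicity_profile <- function(sequence, window = 7,
                                   scale = kyte_doolittle) {
  s <- check_sequence(sequence)
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  if (window > length(s)) stop("window exceeds sequence length", call. = FALSE)
  vals <- unname(scale[s])
  half <- (window - 1) / 2
  prof <- vapply(seq_along(s), function(i) {
    mean(vals[max(1, i - half):min(length(s), i + half)])
  }, numeric(1))
  tibble::tibble(position = seq_along(s), residue = s, hydropathy = prof)
}

#' Assign pH-dependent protonation states
#'
#' Applies a threshold pKa model: a titratable group is protonated if and
#' only if `pH < pKa` (strict inequality, so a group at its pKa is counted
#' deprotonated). For carboxyl groups (Asp, Glu, C-terminus) protonation
#' neutralises the charge; for amines and the imidazole (Lys, Arg, His,
#' N-terminus) protonation creates the charge. Lowering the pH can never
#' deprotonate a group, so protonation is monotone in pH.
#'
#' @param residues one chain's amino-acid sequence (string or character
#'   vector of one-letter codes).
#' @param pH solution pH in `[0, 14]`.
#' @param pka_table named pKa values; see [default_pka_table].
#' @return an object of class `cc_protonation`: list with `pH`,
#'   `pka_table`, a tibble `sidechains` (resno, resid, group, pka,
#'   protonated) covering D/E/H/K/R residues, and logical flags
#'   `cterm_protonated`, `nterm_protonated`.
#' @export
assign_protonation <- function(residues, pH, pka_table = default_pka_table) {
  s <- check_sequence(residues)
  if (pH < 0 || pH > 14) stop("pH must be in [0, 14]", call. = FALSE)
  idx <- which(s %in% c("D", "E", "H", "K", "R"))
  grp <- ifelse(s[idx] %in% c("D", "E"), "carboxyl",
                ifelse(s[idx] == "H", "imidazole", "amine"))
  pka <- unname(pka_table[s[idx]])
  structure(list(
    pH = pH,
    pka_table = pka_table,
    sidechains = tibble::tibble(
      resno = idx, resid = s[idx], group = grp, pka = pka,
      protonated = pH < pka
    ),
    cterm_protonated = pH < pka_table[["CTERM"]],
    nterm_protonated = pH < pka_table[["NTERM"]]
  ), class = "cc_protonation")
}

#' @export
print.cc_protonation <- function(x, ...) {
  np <- sum(x$sidechains$protonated)
  cat("<cc_protonation> pH ", x$pH, ": ", np, "/", nrow(x$sidechains),
      " titratable side chains protonated; C-term ",
      ifelse(x$cterm_protonated, "protonated", "deprotonated"), "\n", sep = "")
  invisible(x)
}
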