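# Synthetic replica-temperature ensembles with a two-state melting model,
# plus exact toy thermodynamic samplers used to validate the reweighting
# stage.
#
# Each frame is drawn independently: every residue is helical with a
# logistic probability in temperature (midpoint tm_helix), and the whole
# trimer is associated with a logistic probability (midpoint
# tm_association), so the expected radial chain separation grows with the
# inverted association order parameter. Chains are rebuilt from dihedrals
# (helical residues get ideal helical dihedrals, coil residues random coil
# dihedrals), superposed onto the folded reference, and dissociated frames
# have their chains displaced radially outward far beyond the contact
# cutoff. The per-frame pseudo-energy rewards helical residues and
# intermonomer hydrophobic contacts, with additive Gaussian noise.

run_with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Two-state melting model for the replica generator
#'
#' Parameters of the synthetic melting process: trimer association is lost
#' with a logistic midpoint `tm_association`, per-residue helicity with
#' midpoint `tm_helix`. `tm_association < tm_helix` is required, encoding
#' the unfolding order in which intermonomer contacts are lost before
#' secondary structure.
#'
#' @param tm_association midpoint (K) for loss of chain association.
#' @param tm_helix midpoint (K) for per-residue helix loss.
#' @param width_association,width_helix logistic widths (K), > 0.
#' @param frames_per_temperature frames generated at each ladder rung.
#' @param seed integer seed; the same seed reproduces the series exactly.
#' @param energy_scale_helix pseudo-energy reward (kJ/mol) per helical
#'   residue.
#' @param energy_scale_contact pseudo-energy reward (kJ/mol) per
#'   intermonomer hydrophobic contact.
#' @param noise_sd Gaussian noise on the per-frame energy (kJ/mol).
#' @param separation_scale radial displacement (Angstrom) of each chain in
#'   a dissociated frame; the default is far beyond the 7 A contact cutoff.
#' @param coil_jitter coordinate noise (Angstrom, per coordinate) applied
#'   to non-backbone atoms of coil residues.
#' @return an object of class `cc_melting_model`.
#' @export
melting_model <- function(tm_association = 450, tm_helix = 550,
                          width_association = 20, width_helix = 20,
                          frames_per_temperature = 100, seed = 1,
                          energy_scale_helix = 2,
                          energy_scale_contact = 1,
                          noise_sd = 5,
                          separation_scale = 15,
                          coil_jitter = 0.5) {
  if (width_association <= 0 || width_helix <= 0)
    stop("logistic widths must be > 0", call. = FALSE)
  if (frames_per_temperature < 1)
    stop("frames_per_temperature must be >= 1", call. = FALSE)
  if (!(tm_association < tm_helix))
    stop("tm_association must be < tm_helix (contacts are lost before ",
         "secondary structure)", call. = FALSE)
  structure(as.list(environment()), class = "cc_melting_model")
}

logistic_order_parameter <- function(temp, tm, width) {
  1 / (1 + exp((temp - tm) / width))
}

# Vectorised side-chain center-of-mass placement from backbone N/CA/C
# matrices (one row per residue); returns NA rows for Gly.
scm_from_backbone <- function(N, CA, C, sequence) {
  u1 <- (N - CA) / sqrt(rowSums((N - CA)^2))
  u2 <- (C - CA) / sqrt(rowSums((C - CA)^2))
  b <- u1 + u2; b <- b / sqrt(rowSums(b^2))
  n <- cbind(u1[, 2] * u2[, 3] - u1[, 3] * u2[, 2],
             u1[, 3] * u2[, 1] - u1[, 1] * u2[, 3],
             u1[, 1] * u2[, 2] - u1[, 2] * u2[, 1])
  n <- n / sqrt(rowSums(n^2))
  gamma <- 51.75 * pi / 180
  dir <- -b * cos(gamma) + n * sin(gamma)
  d <- sidechain_com_distance[sequence]
  CA + dir * d
}

# Count unordered cross-chain pairs of points within an inclusive cutoff.
count_cross_chain_contacts <- function(P, chains, cutoff) {
  n <- nrow(P)
  if (is.null(n) || n < 2) return(0L)
  d2 <- outer(rowSums(P^2), rowSums(P^2), "+") - 2 * P %*% t(P)
  as.integer(sum(upper.tri(d2) & d2 <= cutoff^2 &
                   outer(chains, chains, "!=")))
}

#' Generate synthetic replica-temperature ensembles
#'
#' Draws `frames_per_temperature` independent frames at every rung of a
#' strictly increasing temperature ladder from the two-state melting model
#' (see [melting_model()]), computing per-frame helix content, intermonomer
#' hydrophobic contact count and pseudo-energy. The same model seed yields
#' a bit-identical series.
#'
#' @param folded a folded reference trimer from
#'   [build_ideal_coiled_coil()].
#' @param ladder strictly increasing replica temperatures (K).
#' @param model a [melting_model()].
#' @param store_coords keep full coordinates of every frame (as one
#'   `cc_ensemble` per temperature); off by default to keep large ladders
#'   light.
#' @param hydrophobic_set residues counted for contacts.
#' @param contact_cutoff center-of-mass contact cutoff (Angstrom).
#' @return an object of class `cc_replica_series`: list with `frames`
#'   (tibble: temperature, frame, energy, n_helical, helix_content,
#'   associated, hydrophobic_contacts), `temperatures`, `folded_contacts`
#'   (contact count of the noise-free folded frame), `model`, and
#'   `ensembles` when `store_coords = TRUE`.
#' @export
generate_replica_ensembles <- function(folded, ladder, model,
                                       store_coords = FALSE,
                                       hydrophobic_set = hydrophobic_residues,
                                       contact_cutoff = 7.0) {
  stopifnot(inherits(folded, "cc_structure"),
            inherits(model, "cc_melting_model"))
  if (length(ladder) < 1 || any(diff(ladder) <= 0))
    stop("temperature ladder must be strictly increasing", call. = FALSE)
  seqs <- structure_sequence(folded)
  chains <- chain_ids(folded)
  nch <- length(chains)
  L <- length(seqs[[1]])
  # reference CA coordinates and outward radial directions per chain
  ref_ca <- lapply(chains, function(ch) {
    idx <- atom_index(folded, elety = "CA", chain = ch)
    folded$xyz[idx[order(folded$atoms$resno[idx])], , drop = FALSE]
  })
  axis_ctr <- colMeans(do.call(rbind, ref_ca))
  radial <- lapply(ref_ca, function(ca) {
    v <- colMeans(ca) - axis_ctr; v[3] <- 0
    if (vnorm(v) < 1e-8) c(1, 0, 0) else unit(v)
  })
  hydro <- lapply(seqs, function(s) which(s %in% hydrophobic_set &
                                            !is.na(sidechain_com_distance[s])))
  chain_lab <- rep(chains, lengths(hydro))
  ica <- seq(2, 3 * L, 3)
  # amide H is excluded from jitter so it stays bonded to its donor N
  jitter_ety <- c("O", "SCM", "SCQ")

  # one chain backbone from helicity flags, fitted onto the reference chain
  chain_backbone <- function(hf, k, dissociated) {
    coil_phi <- runif(L, coil_dihedral_range$phi[1],
                      coil_dihedral_range$phi[2])
    coil_psi <- runif(L, coil_dihedral_range$psi[1],
                      coil_dihedral_range$psi[2])
    phi <- ifelse(hf, helix_dihedrals[["phi"]], coil_phi)
    psi <- ifelse(hf, helix_dihedrals[["psi"]], coil_psi)
    # the chain-final residue has no psi, so its coil state must be
    # rejected by phi alone: draw it outside the helical phi window
    if (!hf[L]) phi[L] <- runif(1, -180, helix_window$phi[1] - 1)
    bb <- backbone_from_dihedrals(phi, psi)
    fit <- kabsch(bb[ica, , drop = FALSE], ref_ca[[k]])
    bb <- bb %*% fit$rotation +
      matrix(fit$translation, nrow(bb), 3, byrow = TRUE)
    if (dissociated)
      bb <- bb + matrix(model$separation_scale * radial[[k]],
                        nrow(bb), 3, byrow = TRUE)
    bb
  }

  # fast path: contacts from jittered side-chain centers of mass only
  frame_contacts <- function(flags, dissociated, jitter = TRUE) {
    scm <- vector("list", nch)
    for (k in seq_len(nch)) {
      bb <- chain_backbone(flags[, k], k, dissociated)
      s <- scm_from_backbone(bb[seq(1, 3 * L, 3), , drop = FALSE],
                             bb[ica, , drop = FALSE],
                             bb[seq(3, 3 * L, 3), , drop = FALSE],
                             seqs[[k]])
      if (jitter) {
        coil <- !flags[, k] & !is.na(s[, 1])
        if (any(coil))
          s[coil, ] <- s[coil, ] +
            matrix(rnorm(3 * sum(coil), 0, model$coil_jitter), sum(coil), 3)
      }
      scm[[k]] <- s[hydro[[k]], , drop = FALSE]
    }
    count_cross_chain_contacts(do.call(rbind, scm), chain_lab,
                               contact_cutoff)
  }

  # full path: decorated structure with jitter on non-backbone atoms of
  # coil residues; contacts counted from the stored coordinates
  frame_structure <- function(flags, dissociated) {
    parts <- lapply(seq_len(nch), function(k) {
      st <- decorate_chain(chain_backbone(flags[, k], k, dissociated),
                           seqs[[k]], chain_id = chains[k])
      coil_res <- which(!flags[, k])
      jrows <- which(st$atoms$resno %in% coil_res &
                       st$atoms$elety %in% jitter_ety)
      if (length(jrows))
        st$xyz[jrows, ] <- st$xyz[jrows, , drop = FALSE] +
          matrix(rnorm(3 * length(jrows), 0, model$coil_jitter),
                 length(jrows), 3)
      st
    })
    atoms <- do.call(rbind, lapply(parts, `[[`, "atoms"))
    atoms$eleno <- seq_len(nrow(atoms))
    rownames(atoms) <- NULL
    st <- new_structure(atoms, do.call(rbind, lapply(parts, `[[`, "xyz")))
    iset <- detect_hydrophobic_contacts(st, hydrophobic_set, contact_cutoff)
    list(structure = st, contacts = nrow(iset))
  }

  all_folded <- matrix(TRUE, L, nch)
  folded_contacts <- frame_contacts(all_folded, FALSE, jitter = FALSE)

  out <- run_with_seed(model$seed, {
    rows <- vector("list", length(ladder))
    ens <- if (store_coords) vector("list", length(ladder)) else NULL
    for (ti in seq_along(ladder)) {
      temp <- ladder[ti]
      p_h <- logistic_order_parameter(temp, model$tm_helix,
                                      model$width_helix)
      p_a <- logistic_order_parameter(temp, model$tm_association,
                                      model$width_association)
      nf <- model$frames_per_temperature
      frames <- matrix(0, nf, 7)
      structs <- if (store_coords) vector("list", nf) else NULL
      for (f in seq_len(nf)) {
        flags <- matrix(rbinom(L * nch, 1, p_h) == 1, L, nch)
        dissoc <- rbinom(1, 1, 1 - p_a) == 1
        if (store_coords) {
          fr <- frame_structure(flags, dissoc)
          structs[[f]] <- fr$structure$xyz
          if (ti == 1 && f == 1) atom_template <- fr$structure$atoms
          contacts <- fr$contacts
        } else {
          contacts <- frame_contacts(flags, dissoc)
        }
        n_hel <- sum(flags)
        energy <- -model$energy_scale_helix * n_hel -
          model$energy_scale_contact * contacts +
          rnorm(1, 0, model$noise_sd)
        frames[f, ] <- c(temp, f, energy, n_hel,
                         100 * n_hel / (L * nch), as.integer(!dissoc),
                         contacts)
      }
      rows[[ti]] <- frames
      if (store_coords) ens[[ti]] <- new_ensemble(atom_template, structs)
    }
    m <- do.call(rbind, rows)
    list(frames = tibble::tibble(
      temperature = m[, 1], frame = as.integer(m[, 2]), energy = m[, 3],
      n_helical = as.integer(m[, 4]), helix_content = m[, 5],
      associated = m[, 6] == 1, hydrophobic_contacts = as.integer(m[, 7])),
      ensembles = ens)
  })
  structure(list(frames = out$frames, temperatures = ladder,
                 ensembles = out$ensembles, model = model,
                 folded = folded, folded_contacts = folded_contacts,
                 seed = model$seed),
            class = "cc_replica_series")
}

#' @export
print.cc_replica_series <- function(x, ...) {
  cat("<cc_replica_series> ", length(x$temperatures), " temperature(s), ",
      nrow(x$frames), " frames",
      if (!is.null(x$ensembles)) " (with coordinates)", "\n", sep = "")
  invisible(x)
}

#' Exact Boltzmann toy samples for reweighting validation
#'
#' Draws exact equilibrium samples with exact energies from one of two
#' analytically solvable systems: a 1-D harmonic oscillator (`x` Gaussian
#' with variance kB*T/k, energy k*x^2/2) or a two-level system (excited
#' state occupied with probability exp(-dE/kB T) / (1 + exp(-dE/kB T)),
#' energy 0 or dE).
#'
#' @param system list: either `list(type = "harmonic", k = <kJ/mol/A^2>)`
#'   or `list(type = "two_state", delta_e = <kJ/mol>)`.
#' @param temperatures temperatures (K) to sample at.
#' @param n samples per temperature.
#' @param seed integer seed.
#' @return a `cc_replica_series` whose `frames` tibble has columns
#'   temperature, frame, coord, energy.
#' @export
generate_toy_thermo_samples <- function(system, temperatures, n, seed = 1) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (is.null(system$type) ||
      !system$type %in% c("harmonic", "two_state"))
    stop("system$type must be 'harmonic' or 'two_state'", call. = FALSE)
  if (system$type == "harmonic" &&
      (is.null(system$k) || system$k <= 0))
    stop("harmonic system needs force constant k > 0", call. = FALSE)
  if (system$type == "two_state" &&
      (is.null(system$delta_e) || !is.finite(system$delta_e)))
    stop("two-state system needs finite delta_e", call. = FALSE)
  frames <- run_with_seed(seed, {
    do.call(rbind, lapply(temperatures, function(temp) {
      if (system$type == "harmonic") {
        x <- rnorm(n, 0, sqrt(kB_kJmol * temp / system$k))
        data.frame(temperature = temp, frame = seq_len(n), coord = x,
                   energy = 0.5 * system$k * x^2)
      } else {
        p_exc <- 1 / (1 + exp(system$delta_e / (kB_kJmol * temp)))
        st <- rbinom(n, 1, p_exc)
        data.frame(temperature = temp, frame = seq_len(n), coord = st,
                   energy = st * system$delta_e)
      }
    }))
  })
  structure(list(frames = tibble::as_tibble(frames),
                 temperatures = temperatures, system = system, seed = seed),
            class = "cc_replica_series")
}
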