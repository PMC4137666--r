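# Superposition-based descriptors and decoy clustering.

# Kabsch least-squares superposition of P (mobile, n x 3) onto Q (fixed).
# Row-vector convention: fitted = P %*% rotation + translation; the rotation
# is proper (determinant +1).
kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), nrow(P) >= 3)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  s <- svd(t(Pc) %*% Qc)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  tvec <- cq - as.vector(cp %*% R)
  fitted <- P %*% R + matrix(tvec, nrow(P), 3, byrow = TRUE)
  list(rotation = R, translation = tvec,
       rmsd = sqrt(mean(rowSums((fitted - Q)^2))), fitted = fitted)
}

#' Least-squares rigid superposition
#'
#' Superposes a mobile structure onto a reference over a named atom
#' selection, returning the optimal proper rotation, translation and the
#' resulting RMSD (Angstrom). The transform acts on row-vector coordinates:
#' `fitted = xyz %*% rotation + translation`.
#'
#' @param mobile,reference `cc_structure` objects (or plain n x 3 coordinate
#'   matrices) with matching selected-atom counts in matching order.
#' @param selection atom names used for the fit (default alpha-carbons).
#' @return list with `rotation`, `translation`, `rmsd` and the fitted
#'   mobile coordinates (all atoms transformed).
#' @export
superpose <- function(mobile, reference, selection = "CA") {
  if (is.matrix(mobile) && is.matrix(reference)) {
    if (nrow(mobile) != nrow(reference))
      stop("selected atom counts differ", call. = FALSE)
    if (nrow(mobile) < 3) stop("need at least 3 atoms", call. = FALSE)
    return(kabsch(mobile, reference))
  }
  im <- atom_index(mobile, elety = selection)
  ir <- atom_index(reference, elety = selection)
  if (length(im) != length(ir))
    stop("selected atom counts differ (", length(im), " vs ", length(ir), ")",
         call. = FALSE)
  if (length(im) < 3) stop("need at least 3 atoms in selection", call. = FALSE)
  fit <- kabsch(mobile$xyz[im, , drop = FALSE],
                reference$xyz[ir, , drop = FALSE])
  all_fitted <- mobile$xyz %*% fit$rotation +
    matrix(fit$translation, nrow(mobile$xyz), 3, byrow = TRUE)
  list(rotation = fit$rotation, translation = fit$translation,
       rmsd = fit$rmsd, fitted = all_fitted)
}

#' Frame-wise RMSD of an ensemble against its first frame
#'
#' Each frame is superposed on the first frame over the selection before the
#' RMSD is taken, so the first value is exactly zero.
#'
#' @param ensemble a `cc_ensemble`.
#' @param selection atom names entering both the fit and the RMSD.
#' @return a tibble with columns `frame` and `rmsd` (Angstrom).
#' @export
rmsd_series <- function(ensemble, selection = "CA") {
  stopifnot(inherits(ensemble, "cc_ensemble"), n_frames(ensemble) >= 1)
  sel <- atom_index(ensemble, elety = selection)
  ref <- ensemble$xyz[[1]][sel, , drop = FALSE]
  vals <- vapply(ensemble$xyz, function(x) {
    kabsch(x[sel, , drop = FALSE], ref)$rmsd
  }, numeric(1))
  tibble::tibble(frame = seq_along(vals), rmsd = vals)
}

#' Per-residue RMSF of an ensemble
#'
#' Root-mean-square fluctuation of the selected atoms about the mean
#' structure. Frames are superposed iteratively against a running mean (two
#' passes: first against frame 1, then against the resulting mean). With
#' `monomer_average = TRUE` equivalent residue positions across chains are
#' averaged, giving one profile per monomer.
#'
#' @param ensemble a `cc_ensemble` with at least two frames.
#' @param selection atom names (default alpha-carbons, one per residue).
#' @param monomer_average average equivalent residues across chains.
#' @return a tibble with `resno` and `rmsf` (plus `chain` when not averaged).
#' @export
rmsf_per_residue <- function(ensemble, selection = "CA",
                             monomer_average = TRUE) {
  stopifnot(inherits(ensemble, "cc_ensemble"))
  if (n_frames(ensemble) < 2)
    stop("RMSF needs at least 2 frames", call. = FALSE)
  sel <- atom_index(ensemble, elety = selection)
  coords <- lapply(ensemble$xyz, function(x) x[sel, , drop = FALSE])
  ref <- coords[[1]]
  for (pass in 1:2) {
    fitted <- lapply(coords, function(x) kabsch(x, ref)$fitted)
    ref <- Reduce(`+`, fitted) / length(fitted)
  }
  dev2 <- Reduce(`+`, lapply(fitted, function(x) rowSums((x - ref)^2))) /
    length(fitted)
  a <- ensemble$atoms[sel, , drop = FALSE]
  if (!monomer_average)
    return(tibble::tibble(chain = a$chain, resno = a$resno,
                          rmsf = sqrt(dev2)))
  agg <- tapply(dev2, a$resno, mean)
  tibble::tibble(resno = as.integer(names(agg)),
                 rmsf = sqrt(as.numeric(agg)))
}

#' Estimate the supercoil radius of a helical bundle
#'
#' The bundle axis is taken as the first principal axis of all alpha-carbons.
#' Each chain's local helical axis is traced by window-5 running centroids of
#' its CA atoms (which cancel most of the helical excursion), and the mean
#' distance from these axis points to the bundle axis is returned.
#'
#' @param struct a `cc_structure` with at least 2 chains of >= 8 residues.
#' @return estimated supercoil radius R0 (Angstrom).
#' @export
estimate_supercoil_radius <- function(struct) {
  stopifnot(inherits(struct, "cc_structure"))
  chains <- chain_ids(struct)
  if (length(chains) < 2) stop("need at least 2 chains", call. = FALSE)
  ca_all <- struct$xyz[atom_index(struct, elety = "CA"), , drop = FALSE]
  ctr <- colMeans(ca_all)
  axis <- prcomp(ca_all, center = TRUE)$rotation[, 1]
  dists <- unlist(lapply(chains, function(ch) {
    idx <- atom_index(struct, elety = "CA", chain = ch)
    idx <- idx[order(struct$atoms$resno[idx])]
    if (length(idx) < 8) stop("chain ", ch, " too short", call. = FALSE)
    ca <- struct$xyz[idx, , drop = FALSE]
    n <- nrow(ca) - 4
    sm <- vapply(1:3, function(k) {
      (ca[1:n, k] + ca[2:(n + 1), k] + ca[3:(n + 2), k] +
         ca[4:(n + 3), k] + ca[5:(n + 4), k]) / 5
    }, numeric(n))
    rel <- sweep(matrix(sm, ncol = 3), 2, ctr)
    proj <- rel %*% axis
    sqrt(rowSums((rel - proj %*% t(axis))^2))
  }))
  mean(dists)
}

#' Neighbor-count clustering of structural decoys
#'
#' Selects the `top_n` lowest-energy models, then iteratively: among
#' still-unassigned models, the one with the largest number of unassigned
#' neighbors (pairwise superposed CA RMSD at or below `rms_cutoff`) becomes a
#' cluster center and forms a cluster with those neighbors; the procedure
#' repeats until every selected model is assigned. The neighbor count
#' excludes the model itself; ties are broken by lower energy. The final
#' representative model is the center of the most populated cluster.
#'
#' @param models a `cc_ensemble` of decoy structures.
#' @param energies numeric score per model (lower = better), aligned with
#'   the ensemble frames.
#' @param top_n number of lowest-energy models to cluster.
#' @param rms_cutoff neighbor radius as CA RMSD (Angstrom).
#' @return an object of class `cc_cluster_result`: list with `clusters`
#'   (each holding `center` and `members` as model indices into the original
#'   ensemble), `final_model`, `selected`, and the parameters used.
#' @export
cluster_by_neighbors <- function(models, energies, top_n = 400,
                                 rms_cutoff = 3.0) {
  stopifnot(inherits(models, "cc_ensemble"))
  nm <- n_frames(models)
  if (length(energies) != nm)
    stop("energies must align with models", call. = FALSE)
  if (top_n < 1) stop("top_n must be >= 1", call. = FALSE)
  if (top_n > nm) {
    warning("top_n (", top_n, ") exceeds model count (", nm, "); using all")
    top_n <- nm
  }
  selected <- order(energies)[seq_len(top_n)]
  sel_idx <- atom_index(models, elety = "CA")
  coords <- lapply(selected, function(i)
    models$xyz[[i]][sel_idx, , drop = FALSE])
  n <- length(selected)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- kabsch(coords[[j]], coords[[i]])$rmsd
    }
  }
  neighbor <- D <= rms_cutoff
  diag(neighbor) <- FALSE
  unassigned <- rep(TRUE, n)
  clusters <- list()
  while (any(unassigned)) {
    counts <- as.integer(neighbor %*% unassigned)
    counts[!unassigned] <- -1L
    best <- which(counts == max(counts[unassigned]) & unassigned)
    if (length(best) > 1)
      best <- best[which.min(energies[selected[best]])]
    members <- which(unassigned & (neighbor[best, ] | seq_len(n) == best))
    clusters[[length(clusters) + 1]] <-
      list(center = selected[best], members = selected[members])
    unassigned[members] <- FALSE
  }
  sizes <- vapply(clusters, function(cl) length(cl$members), integer(1))
  final <- clusters[[which.max(sizes)]]$center
  structure(list(clusters = clusters, final_model = final,
                 selected = selected,
                 parameters = list(top_n = top_n, rms_cutoff = rms_cutoff)),
            class = "cc_cluster_result")
}

#' @export
print.cc_cluster_result <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) length(cl$members), integer(1))
  cat("<cc_cluster_result> ", length(x$clusters), " cluster(s) over ",
      length(x$selected), " selected models; sizes: ",
      paste(sizes, collapse = ", "), "; final model: ", x$final_model,
      "\n", sep = "")
  invisible(x)
}
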