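# Multiple-histogram reweighting (Ferrenberg-Swendsen WHAM) over a
# temperature ladder, projecting the estimated density of states onto two
# structural reaction coordinates, and basin detection on the resulting
# probability surface.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

bin_index <- function(x, edges) {
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  idx[idx < 1 | idx > length(edges) - 1] <- NA_integer_
  idx
}

#' Reconstruct a 2-D probability surface at a target temperature by WHAM
#'
#' Ferrenberg-Swendsen multiple-histogram reweighting: per-frame energies
#' are histogrammed on a discretised energy axis jointly with two reaction
#' coordinates, the dimensionless per-replica free energies `f_i` are
#' iterated to self-consistency, and the density of states is projected to
#' the probability of each coordinate bin at temperature `t0`. With a
#' single replica and `t0` equal to its temperature the result reduces
#' exactly to the empirical 2-D histogram.
#'
#' @param series a `cc_replica_series` whose frames carry an `energy`
#'   column.
#' @param coords names of the two frame columns used as reaction
#'   coordinates (for one coordinate, give one name).
#' @param t0 target temperature (K).
#' @param e_bins number of energy-axis bins.
#' @param xy_bins bin counts for the coordinate axes (length 1 or 2).
#' @param tol convergence threshold on `max |delta f_i|`.
#' @param max_iter maximum self-consistency iterations.
#' @param window_fraction trailing fraction of frames per replica entering
#'   the histograms.
#' @param xlim,ylim coordinate ranges (default: data range).
#' @return an object of class `cc_fes`: list with bin edges/centers,
#'   `prob` (matrix, coordinate 1 by coordinate 2), `free_energy`
#'   (-kB*t0*ln P, kJ/mol, minimum at 0, empty bins NA), per-replica free
#'   energies `f`, and a `convergence` report (iterations, residual trace,
#'   converged flag).
#' @export
wham_reweight <- function(series, coords, t0, e_bins = 200,
                          xy_bins = c(50, 50), tol = 1e-7,
                          max_iter = 10000, window_fraction = 0.5,
                          xlim = NULL, ylim = NULL) {
  frames <- if (is.data.frame(series)) series else series$frames
  if (!("energy" %in% names(frames)) || all(is.na(frames$energy)))
    stop("WHAM needs per-frame energies; the series has no energy column",
         call. = FALSE)
  stopifnot(length(coords) %in% 1:2, all(coords %in% names(frames)))
  two_d <- length(coords) == 2
  if (length(xy_bins) == 1) xy_bins <- rep(xy_bins, 2)

  # trailing window per replica
  keep_rows <- unlist(lapply(split(seq_len(nrow(frames)),
                                   frames$temperature), function(idx) {
    idx <- idx[order(frames$frame[idx])]
    k <- max(1, ceiling(window_fraction * length(idx)))
    idx[(length(idx) - k + 1):length(idx)]
  }))
  fr <- frames[keep_rows, ]
  temps <- sort(unique(fr$temperature))
  nrep <- length(temps)
  beta <- 1 / (kB_kJmol * temps)
  beta0 <- 1 / (kB_kJmol * t0)
  n_i <- as.vector(table(factor(fr$temperature, levels = temps)))

  # energy axis
  erange <- range(fr$energy)
  if (diff(erange) == 0) erange <- erange + c(-0.5, 0.5)
  e_edges <- seq(erange[1], erange[2], length.out = e_bins + 1)
  e_mid <- (e_edges[-1] + e_edges[-(e_bins + 1)]) / 2
  ei <- bin_index(fr$energy, e_edges)

  # coordinate axes
  x <- fr[[coords[1]]]
  if (is.null(xlim)) xlim <- range(x)
  if (diff(xlim) == 0) xlim <- xlim + c(-0.5, 0.5)
  x_edges <- seq(xlim[1], xlim[2], length.out = xy_bins[1] + 1)
  xi <- bin_index(x, x_edges)
  if (two_d) {
    y <- fr[[coords[2]]]
    if (is.null(ylim)) ylim <- range(y)
    if (diff(ylim) == 0) ylim <- ylim + c(-0.5, 0.5)
    y_edges <- seq(ylim[1], ylim[2], length.out = xy_bins[2] + 1)
    yi <- bin_index(y, y_edges)
  } else {
    y_edges <- c(0, 1); yi <- rep(1L, nrow(fr)); xy_bins[2] <- 1L
  }
  evals <- fr$energy
  ok <- !is.na(ei) & !is.na(xi) & !is.na(yi)
  if (!all(ok)) {
    warning(sum(!ok), " frame(s) outside the histogram ranges dropped")
    ei <- ei[ok]; xi <- xi[ok]; yi <- yi[ok]; evals <- evals[ok]
  }

  # histograms: total per energy bin and joint (energy, x, y)
  H_e <- tabulate(ei, nbins = e_bins)
  joint <- tabulate(ei + e_bins * ((xi - 1) + xy_bins[1] * (yi - 1)),
                    nbins = e_bins * xy_bins[1] * xy_bins[2])
  dim(joint) <- c(e_bins, xy_bins[1], xy_bins[2])

  # representative energy per bin: the observed mean energy of the bin's
  # samples (exact for discrete-energy systems; the bin center is only a
  # fallback for the unoccupied bins, which never enter the iteration)
  agg <- tapply(evals, ei, mean)
  e_mid[as.integer(names(agg))] <- as.numeric(agg)

  occ <- which(H_e > 0)
  logH <- log(H_e[occ])
  # beta_i * E_m on occupied bins: nrep x n_occ
  bE <- outer(beta, e_mid[occ])
  logn <- log(n_i)

  f <- rep(0, nrep)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # denominator per occupied energy bin: logsumexp_i (log n_i + f_i - b_i E)
    A <- logn + f - bE            # column-recycled over replicas
    amax <- apply(A, 2, max)
    den <- amax + log(colSums(exp(sweep(A, 2, amax))))
    lomega <- logH - den
    B <- -bE + matrix(lomega, nrep, length(occ), byrow = TRUE)
    bmax <- apply(B, 1, max)
    f_new <- -(bmax + log(rowSums(exp(B - bmax))))
    f_new <- f_new - f_new[1]
    res <- max(abs(f_new - f))
    trace <- c(trace, res)
    f <- f_new
    if (res < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("WHAM did not converge after ", max_iter,
            " iterations (residual ", signif(res, 3), ")")

  # density of states on occupied bins, then project at t0
  A <- logn + f - bE
  amax <- apply(A, 2, max)
  den <- amax + log(colSums(exp(sweep(A, 2, amax))))
  # log weight per occupied energy bin at t0 per histogram count
  logw_bin <- -beta0 * e_mid[occ] - den
  logw_full <- rep(-Inf, e_bins)
  logw_full[occ] <- logw_bin
  w_full <- exp(logw_full - max(logw_bin))
  P <- apply(joint, c(2, 3), function(cnt) sum(cnt * w_full))
  P <- P / sum(P)

  G <- matrix(NA_real_, xy_bins[1], xy_bins[2])
  pos <- P > 0
  G[pos] <- -kB_kJmol * t0 * log(P[pos])
  G <- G - min(G, na.rm = TRUE)

  structure(list(
    coords = coords, t0 = t0,
    x_edges = x_edges, y_edges = y_edges,
    x_centers = (x_edges[-1] + x_edges[-length(x_edges)]) / 2,
    y_centers = (y_edges[-1] + y_edges[-length(y_edges)]) / 2,
    prob = P, free_energy = G,
    f = setNames(f, temps),
    convergence = list(iterations = length(trace),
                       residual = if (length(trace)) tail(trace, 1) else 0,
                       trace = trace, converged = converged)
  ), class = "cc_fes")
}

#' @export
print.cc_fes <- function(x, ...) {
  cat("<cc_fes> ", length(x$x_centers), "x", length(x$y_centers),
      " surface over (", paste(x$coords, collapse = ", "), ") at ",
      x$t0, " K; ", x$convergence$iterations, " WHAM iterations",
      if (!x$convergence$converged) " (NOT converged)", "\n", sep = "")
  invisible(x)
}

#' Locate probability basins on a free-energy surface
#'
#' Finds local maxima of the probability surface (strictly greater than at
#' least one and at least as large as all of their 3x3 neighbors), merges
#' maxima closer than `min_separation` bins (Chebyshev distance, keeping
#' the most probable), then assigns every occupied bin to a basin by
#' steepest ascent and orders basins by attached probability mass. A flat
#' or empty surface yields no basins.
#'
#' @param surface a `cc_fes`.
#' @param min_separation minimum bin separation between distinct basins.
#' @return tibble with `x`, `y` (bin centers), `xbin`, `ybin`, `prob`
#'   (peak bin probability) and `mass` (attached probability), ordered by
#'   decreasing mass.
#' @export
find_basins <- function(surface, min_separation = 2) {
  stopifnot(inherits(surface, "cc_fes"))
  P <- surface$prob
  nx <- nrow(P); ny <- ncol(P)
  pad <- matrix(NA_real_, nx + 2, ny + 2)   # out-of-grid bins are ignored
  pad[2:(nx + 1), 2:(ny + 1)] <- P
  is_max <- matrix(TRUE, nx, ny); has_less <- matrix(FALSE, nx, ny)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    nb <- pad[2:(nx + 1) + dx, 2:(ny + 1) + dy]
    is_max <- is_max & (is.na(nb) | P >= nb)
    has_less <- has_less | (!is.na(nb) & nb < P)
  }
  cand <- which(is_max & has_less & P > 0, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(tibble::tibble(x = numeric(0), y = numeric(0),
                          xbin = integer(0), ybin = integer(0),
                          prob = numeric(0), mass = numeric(0)))
  cand <- cand[order(-P[cand]), , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) for (j in (i + 1):nrow(cand)) {
      if (keep[j] &&
          max(abs(cand[i, ] - cand[j, ])) < min_separation)
        keep[j] <- FALSE
    }
  }
  peaks <- cand[keep, , drop = FALSE]

  # steepest-ascent basin assignment for every occupied bin
  peak_id <- matrix(0L, nx, ny)
  peak_id[peaks] <- seq_len(nrow(peaks))
  assign_of <- matrix(NA_integer_, nx, ny)
  climb <- function(i, j) {
    path_i <- integer(0); path_j <- integer(0)
    repeat {
      if (!is.na(assign_of[i, j])) break
      if (peak_id[i, j] > 0) { assign_of[i, j] <<- peak_id[i, j]; break }
      path_i <- c(path_i, i); path_j <- c(path_j, j)
      best <- c(i, j); bestp <- P[i, j]
      for (dx in -1:1) for (dy in -1:1) {
        ii <- i + dx; jj <- j + dy
        if (ii < 1 || ii > nx || jj < 1 || jj > ny) next
        if (P[ii, jj] > bestp) { bestp <- P[ii, jj]; best <- c(ii, jj) }
      }
      if (best[1] == i && best[2] == j) {
        # plateau not registered as a peak: attach to nearest peak
        d <- abs(peaks[, 1] - i) + abs(peaks[, 2] - j)
        assign_of[i, j] <<- which.min(d)
        break
      }
      i <- best[1]; j <- best[2]
    }
    tgt <- assign_of[i, j]
    if (length(path_i)) assign_of[cbind(path_i, path_j)] <<- tgt
    tgt
  }
  occ <- which(P > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(occ))) climb(occ[r, 1], occ[r, 2])
  mass <- vapply(seq_len(nrow(peaks)), function(id)
    sum(P[!is.na(assign_of) & assign_of == id]), numeric(1))
  out <- tibble::tibble(
    x = surface$x_centers[peaks[, 1]],
    y = surface$y_centers[peaks[, 2]],
    xbin = as.integer(peaks[, 1]), ybin = as.integer(peaks[, 2]),
    prob = P[peaks], mass = mass)
  out[order(-out$mass), ]
}
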