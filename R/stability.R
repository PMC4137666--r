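# Temperature-resolved averaging and melting-temperature extraction.

#' Construct a constant-ratio replica temperature ladder
#'
#' Geometric ladder `T_i = t_min * r^(i-1)` with
#' `r = (t_max / t_min)^(1 / (n - 1))`; both endpoints are exact. This is
#' the constant-exchange-probability spacing conventionally used for
#' replica-exchange simulations.
#'
#' @param t_min,t_max ladder endpoints (K), `t_min < t_max`.
#' @param n number of rungs, at least 2.
#' @return numeric vector of `n` strictly increasing temperatures.
#' @examples
#' make_ladder(303.15, 809.57, 64)
#' @export
make_ladder <- function(t_min, t_max, n) {
  if (!(t_min < t_max)) stop("t_min must be < t_max", call. = FALSE)
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  out <- t_min * (t_max / t_min)^((seq_len(n) - 1) / (n - 1))
  out[n] <- t_max
  out
}

#' Per-temperature means and standard deviations of observables
#'
#' Averages each requested per-frame observable over the final
#' `window_fraction` of frames at every ladder temperature (frames ordered
#' by frame index), mirroring the convention of analysing only the
#' equilibrated tail of each replica.
#'
#' @param series a `cc_replica_series` (or any list with a `frames` tibble
#'   containing `temperature` and `frame` columns).
#' @param observables character vector of frame columns to average.
#' @param window_fraction fraction (0, 1] of trailing frames entering the
#'   averages.
#' @return a named list of `cc_stability_curve` tibbles (columns
#'   `temperature`, `mean`, `sd`, `n`), one per observable, each carrying
#'   the observable name and window fraction as attributes.
#' @export
ensemble_averages <- function(series, observables, window_fraction = 0.5) {
  frames <- if (is.data.frame(series)) series else series$frames
  if (window_fraction <= 0 || window_fraction > 1)
    stop("window_fraction must be in (0, 1]", call. = FALSE)
  missing_cols <- setdiff(observables, names(frames))
  if (length(missing_cols))
    stop("unknown observable column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  temps <- sort(unique(frames$temperature))
  out <- lapply(observables, function(obs) {
    rows <- lapply(temps, function(tt) {
      sub <- frames[frames$temperature == tt, ]
      sub <- sub[order(sub$frame), ]
      keep <- ceiling(window_fraction * nrow(sub))
      if (keep < 2)
        stop("analysis window at T = ", tt, " has fewer than 2 frames",
             call. = FALSE)
      vals <- sub[[obs]][(nrow(sub) - keep + 1):nrow(sub)]
      c(tt, mean(vals), sd(vals), keep)
    })
    m <- do.call(rbind, rows)
    curve <- tibble::tibble(temperature = m[, 1], mean = m[, 2],
                            sd = m[, 3], n = as.integer(m[, 4]))
    attr(curve, "observable") <- obs
    attr(curve, "window_fraction") <- window_fraction
    class(curve) <- c("cc_stability_curve", class(curve))
    curve
  })
  setNames(out, observables)
}

# Centered moving average with truncated endpoints.
moving_average <- function(x, width) {
  if (width <= 1) return(x)
  half <- (width - 1) %/% 2
  vapply(seq_along(x), function(i) {
    mean(x[max(1, i - half):min(length(x), i + half)])
  }, numeric(1))
}

#' Extract the unfolding temperature from a stability curve
#'
#' Tm is the ladder rung at which the first derivative of the
#' (moving-average smoothed) mean observable with respect to temperature is
#' most negative (central differences on the non-uniform ladder, one-sided
#' at the ends). The curve is flagged `non_sigmoidal` -- signalling that
#' the midpoint fallback [extract_midpoint()] should be used instead --
#' when the steepest rung lies within 2 rungs of either ladder end or when
#' the total drop of the curve is smaller than 4 times the median
#' per-rung noise of the means (sd / sqrt(n)).
#'
#' @param curve a `cc_stability_curve` with at least 5 rungs.
#' @param smooth_window width (rungs) of the centered moving average
#'   applied before differentiation.
#' @return list with `tm` (K, a ladder rung), `diagnostic` ("sigmoidal" or
#'   "non_sigmoidal"), `index` of the rung, and the `derivative` vector.
#' @export
extract_tm <- function(curve, smooth_window = 3) {
  stopifnot(inherits(curve, "cc_stability_curve") || is.data.frame(curve))
  tt <- curve$temperature; y <- curve$mean
  n <- length(tt)
  if (n < 5) stop("need at least 5 ladder rungs", call. = FALSE)
  ys <- moving_average(y, smooth_window)
  deriv <- numeric(n)
  deriv[1] <- (ys[2] - ys[1]) / (tt[2] - tt[1])
  deriv[n] <- (ys[n] - ys[n - 1]) / (tt[n] - tt[n - 1])
  deriv[2:(n - 1)] <- (ys[3:n] - ys[1:(n - 2)]) / (tt[3:n] - tt[1:(n - 2)])
  idx <- which.min(deriv)
  near_edge <- min(idx - 1, n - idx) <= 2
  noise <- if (!is.null(curve$sd) && !is.null(curve$n) &&
               all(is.finite(curve$sd)))
    median(curve$sd / sqrt(curve$n)) else 0
  small_drop <- (max(y) - min(y)) < 4 * noise
  list(tm = tt[idx],
       diagnostic = if (near_edge || small_drop) "non_sigmoidal"
                    else "sigmoidal",
       index = idx, derivative = deriv)
}

#' Midpoint temperature of a stability curve
#'
#' Fallback for curves without sigmoidal shape: the temperature at which
#' the mean observable first crosses halfway between its extreme values
#' (linear interpolation between rungs, scanning from low temperature).
#' The result is invariant under affine rescaling of the observable.
#'
#' @param curve a `cc_stability_curve`.
#' @return midpoint temperature (K).
#' @export
extract_midpoint <- function(curve) {
  tt <- curve$temperature; y <- curve$mean
  if (max(y) - min(y) <= 0)
    stop("curve is constant; midpoint undefined", call. = FALSE)
  h <- (max(y) + min(y)) / 2
  s <- y - h
  if (abs(s[1]) < .Machine$double.eps^0.5) return(tt[1])
  for (i in seq_len(length(tt) - 1)) {
    if (s[i] == 0) return(tt[i])
    if (s[i] * s[i + 1] <= 0) {
      return(tt[i] + (tt[i + 1] - tt[i]) * s[i] / (s[i] - s[i + 1]))
    }
  }
  tt[length(tt)]
}
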