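test_that("single-replica WHAM reduces to the empirical histogram", {
  ts <- generate_toy_thermo_samples(list(type = "harmonic", k = 2),
                                    300, 4000, seed = 12)
  s <- wham_reweight(ts, coords = "coord", t0 = 300, e_bins = 60,
                     xy_bins = 30, window_fraction = 1)
  emp <- table(cut(ts$frames$coord, breaks = s$x_edges,
                   include.lowest = TRUE))
  emp <- as.numeric(emp) / sum(emp)
  expect_lt(max(abs(s$prob[, 1] - emp)), 1e-10)
  expect_true(s$convergence$converged)
})

test_that("two-state occupancy reweights to the Boltzmann closed form", {
  de <- 5
  ts <- generate_toy_thermo_samples(list(type = "two_state", delta_e = de),
                                    c(250, 300, 350), 2e4, seed = 3)
  t0 <- 300
  s <- wham_reweight(ts, coords = "coord", t0 = t0, e_bins = 8,
                     xy_bins = 2, window_fraction = 1)
  exact <- 1 / (1 + exp(de / (kB_kJmol * t0)))
  expect_equal(s$prob[2, 1], exact, tolerance = 0.02)
  # reweighting to an off-ladder temperature also matches the closed form
  s2 <- wham_reweight(ts, coords = "coord", t0 = 275, e_bins = 8,
                      xy_bins = 2, window_fraction = 1)
  exact2 <- 1 / (1 + exp(de / (kB_kJmol * 275)))
  expect_equal(s2$prob[2, 1], exact2, tolerance = 0.03)
})

test_that("harmonic variance at the target temperature matches kB*T0/k", {
  k <- 1
  hs <- generate_toy_thermo_samples(list(type = "harmonic", k = k),
                                    c(250, 300, 360), 3e4, seed = 8)
  s <- wham_reweight(hs, coords = "coord", t0 = 300, e_bins = 150,
                     xy_bins = 100, window_fraction = 1)
  m1 <- sum(s$prob[, 1] * s$x_centers)
  v <- sum(s$prob[, 1] * s$x_centers^2) - m1^2
  expect_equal(v, kB_kJmol * 300 / k, tolerance = 0.05)
})

test_that("reweighting to a ladder temperature reproduces that replica's
           empirical mean within 3 SE", {
  hs <- generate_toy_thermo_samples(list(type = "harmonic", k = 1.5),
                                    c(260, 320, 380), 2e4, seed = 5)
  for (tt in c(260, 380)) {
    s <- wham_reweight(hs, coords = "coord", t0 = tt, e_bins = 120,
                       xy_bins = 80, window_fraction = 1)
    # compare second moments (the mean is ~0 by symmetry)
    rep_frames <- hs$frames[hs$frames$temperature == tt, ]
    emp <- mean(rep_frames$coord^2)
    se <- sd(rep_frames$coord^2) / sqrt(nrow(rep_frames))
    m2 <- sum(s$prob[, 1] * s$x_centers^2)
    # allow for binning discretisation on top of sampling error
    bin_w <- diff(s$x_edges[1:2])
    expect_lt(abs(m2 - emp), 3 * se + bin_w^2 / 12 + 1e-6)
  }
})

test_that("free-energy offsets are defined up to a constant and the
           residual trace is non-increasing", {
  ts <- generate_toy_thermo_samples(list(type = "two_state", delta_e = 4),
                                    c(260, 300, 340), 5000, seed = 6)
  s <- wham_reweight(ts, coords = "coord", t0 = 300, e_bins = 6,
                     xy_bins = 2, window_fraction = 1)
  expect_equal(s$f[[1]], 0)
  tr <- s$convergence$trace
  if (length(tr) > 1) expect_true(all(diff(tr) <= 1e-9))
  # surface probabilities normalise and the free-energy minimum is zero
  expect_equal(sum(s$prob), 1)
  expect_equal(min(s$free_energy, na.rm = TRUE), 0)
  expect_true(all(s$prob >= 0))
})

test_that("WHAM refuses series without energies and flags empty input", {
  frames <- tibble::tibble(temperature = rep(300, 10), frame = 1:10,
                           coord = rnorm(10))
  expect_error(wham_reweight(frames, "coord", 300), "energy")
})

test_that("basin detection finds modes, orders by mass and returns empty
           for flat surfaces", {
  mk_surface <- function(P) {
    P <- P / sum(P)
    nx <- nrow(P); ny <- ncol(P)
    structure(list(coords = c("x", "y"), t0 = 300,
                   x_edges = seq(0, 1, length.out = nx + 1),
                   y_edges = seq(0, 1, length.out = ny + 1),
                   x_centers = (seq_len(nx) - 0.5) / nx,
                   y_centers = (seq_len(ny) - 0.5) / ny,
                   prob = P,
                   free_energy = -log(pmax(P, 1e-300)),
                   f = 0, convergence = list(iterations = 1, residual = 0,
                                             trace = 0, converged = TRUE)),
              class = "cc_fes")
  }
  gauss <- function(n, cx, cy, s) {
    outer(seq_len(n), seq_len(n), function(i, j)
      exp(-((i - cx)^2 + (j - cy)^2) / (2 * s^2)))
  }
  # single Gaussian: one basin at its mode bin
  b1 <- find_basins(mk_surface(gauss(30, 10, 12, 3)))
  expect_equal(nrow(b1), 1L)
  expect_equal(c(b1$xbin, b1$ybin), c(10, 12))
  # two well-separated Gaussians, weights 0.7 / 0.3: heavier first;
  # masses recovered by the watershed within a few percent
  P2 <- 0.7 * gauss(40, 10, 10, 3) / sum(gauss(40, 10, 10, 3)) +
    0.3 * gauss(40, 30, 32, 3) / sum(gauss(40, 30, 32, 3))
  b2 <- find_basins(mk_surface(P2))
  expect_equal(nrow(b2), 2L)
  expect_equal(c(b2$xbin[1], b2$ybin[1]), c(10, 10))
  expect_equal(b2$mass[1], 0.7, tolerance = 0.02)
  expect_equal(b2$mass[2], 0.3, tolerance = 0.02)
  # uniform surface: no strict local maximum, no basins
  b0 <- find_basins(mk_surface(matrix(1, 20, 20)))
  expect_equal(nrow(b0), 0L)
})
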