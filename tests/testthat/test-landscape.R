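test_that("density estimation is a proper histogram", {
  ## all points in one bin
  d1 <- estimate_density(rep(0.5, 100), rep(-1, 100), bins = 8)
  expect_equal(max(d1$P), 1)
  expect_equal(sum(d1$P), 1)

  ## uniform points: multinomial deviation bound at T = 1e5
  n <- 1e5
  set.seed(61)
  d2 <- estimate_density(runif(n), runif(n), bins = 16, margin = 0)
  B <- 16 * 16
  expect_lt(max(abs(d2$P - 1 / B)), 4 * sqrt(1 / (n * B)))
  expect_equal(sum(d2$P), 1)

  expect_error(estimate_density(numeric(0), numeric(0)), "no points")
})

test_that("free-energy transform is Boltzmann-consistent and masks empty bins", {
  ## uniform occupied grid: G identically 0
  set.seed(62)
  d <- estimate_density(runif(4000), runif(4000), bins = 2)
  land <- to_free_energy(d)
  expect_true(all(abs(land$G) < 0.2)) # sampling noise only
  exact <- d
  exact$P <- matrix(0.25, 2, 2)
  exact$counts <- matrix(25, 2, 2)
  expect_true(all(to_free_energy(exact)$G == 0))

  ## a bin with P = Pmax / e sits exactly 1 kT up
  g <- d
  g$counts <- matrix(c(272, 100, 0, 0), 2, 2)
  g$P <- g$counts / sum(g$counts)
  land2 <- to_free_energy(g)
  expect_equal(land2$G[1, 1], 0)
  expect_equal(land2$G[2, 1], -log(100 / 272))
  expect_true(all(is.na(land2$G[, 2]))) # empty bins masked, never 0

  ## invariance under count rescaling
  g10 <- g
  g10$counts <- g$counts * 10
  g10$P <- g10$counts / sum(g10$counts)
  expect_equal(to_free_energy(g10)$G, land2$G)

  ## kJ/mol conversion at 300 K
  kj <- to_free_energy(g, units = "kJ/mol")
  expect_equal(kj$G[2, 1], -log(100 / 272) * 0.0083144626 * 300)
})

test_that("minima and barriers match the brute-force level-connectivity oracle", {
  ## two well-separated equal Gaussians along x
  set.seed(63)
  n <- 3e4
  x <- c(rnorm(n / 2, -1.5, 0.6), rnorm(n / 2, 1.5, 0.6))
  y <- rnorm(n, 0, 0.6)
  land <- to_free_energy(estimate_density(x, y, bins = 24))
  mm <- find_minima(land, min_separation = 2, depth_threshold = 0.5)
  expect_equal(nrow(mm$minima), 2)
  expect_true(all(mm$barriers[upper.tri(mm$barriers)] > 0))
  ## barrier symmetry
  expect_equal(mm$barriers, t(mm$barriers))

  ## oracle: minimax saddle level by flood fill over sorted levels
  lin <- function(ix, iy) (iy - 1) * nrow(land$G) + ix
  a <- lin(mm$minima$ix[1], mm$minima$iy[1])
  b <- lin(mm$minima$ix[2], mm$minima$iy[2])
  saddle <- saddle_oracle(land$G, a, b)
  expect_equal(
    mm$barriers[1, 2],
    saddle - max(mm$minima$G),
    tolerance = 1e-12
  )

  ## single Gaussian: exactly one minimum at the mode bin (+/- 1 bin)
  g1 <- to_free_energy(estimate_density(rnorm(n, 1, 0.4), rnorm(n, -1, 0.4),
    bins = 24
  ))
  m1 <- find_minima(g1, min_separation = 2, depth_threshold = 0.5)
  expect_equal(nrow(m1$minima), 1)
  expect_lt(abs(m1$minima$x - 1), 2 * diff(g1$x_centers[1:2]))
  expect_lt(abs(m1$minima$y + 1), 2 * diff(g1$y_centers[1:2]))

  ## mixture collapsed to one component: one minimum
  xc <- rnorm(n, -2, 0.5)
  mc <- find_minima(
    to_free_energy(estimate_density(xc, rnorm(n, 0, 0.5), bins = 24)),
    min_separation = 2, depth_threshold = 0.5
  )
  expect_equal(nrow(mc$minima), 1)

  expect_error(
    find_minima(structure(list(G = matrix(NA_real_, 2, 2)),
      class = "energy_landscape"
    )),
    "masked"
  )
})

test_that("candidate minima agree with exhaustive neighbour search on small grids", {
  set.seed(64)
  for (trial in 1:5) {
    G <- matrix(round(runif(12 * 12), 2), 12, 12)
    G[sample(144, 30)] <- NA
    if (all(is.na(G))) next
    land <- structure(
      list(
        G = G, counts = ifelse(is.na(G), 0, 1),
        x_centers = 1:12, y_centers = 1:12, n = sum(!is.na(G)),
        units = "kT", temperature = 300
      ),
      class = "energy_landscape"
    )
    mm <- find_minima(land,
      min_separation = 0, depth_threshold = 0,
      min_basin_fraction = 0, min_count = 0
    )
    ## exhaustive double loop
    expected <- c()
    for (ix in 1:12) {
      for (iy in 1:12) {
        if (is.na(G[ix, iy])) next
        nb <- c()
        for (dx in -1:1) {
          for (dy in -1:1) {
            if (dx == 0 && dy == 0) next
            jx <- ix + dx
            jy <- iy + dy
            if (jx < 1 || jx > 12 || jy < 1 || jy > 12) next
            if (!is.na(G[jx, jy])) nb <- c(nb, G[jx, jy])
          }
        }
        if (length(nb) == 0 || all(G[ix, iy] < nb)) {
          expected <- c(expected, (iy - 1) * 12 + ix)
        }
      }
    }
    got <- sort((mm$minima$iy - 1) * 12 + mm$minima$ix)
    expect_identical(got, sort(expected))
  }
})

test_that("marginal densities normalise and resolve bimodality", {
  set.seed(65)
  uni <- marginal_density(rnorm(2e4), bins = 32)
  expect_equal(sum(uni$P), 1)
  ## unimodal: single strong peak region
  peaks <- function(P) {
    which(P > dplyr::lag(P, default = 0) & P > dplyr::lead(P, default = 0) &
      P > max(P) / 4)
  }
  expect_equal(length(peaks(uni$P)), 1)

  bi <- marginal_density(c(rnorm(1e4, -3), rnorm(1e4, 3)), bins = 32)
  expect_equal(sum(bi$P), 1)
  expect_equal(length(peaks(bi$P)), 2)
})
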