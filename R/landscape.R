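#' Two-dimensional histogram density of two principal coordinates
#'
#' Bins the joint distribution of two projection series on a regular
#' grid spanning the data range of each axis plus a margin. Bin
#' probabilities are counts over the total number of frames.
#'
#' @param p1,p2 numeric vectors of equal length (projection values), or
#'   a single [project_trajectory()] result holding two modes.
#' @param bins number of bins per axis (length 1 or 2; default 64).
#' @param margin fractional range padding per side (default 0.05).
#' @return An object of class `density_grid`: list with `counts`,
#'   `P`, `x_centers`, `y_centers`, `n`.
#' @export
estimate_density <- function(p1, p2 = NULL, bins = 64, margin = 0.05) {
  if (inherits(p1, "projection_series")) {
    stopifnot(ncol(p1$values) >= 2)
    p2 <- p1$values[, 2]
    p1 <- p1$values[, 1]
  }
  if (length(p1) != length(p2)) abort("p1 and p2 must have equal length")
  if (length(p1) == 0) abort("no points to bin")
  bins <- rep_len(bins, 2)
  brk <- function(v, b) {
    r <- range(v)
    pad <- max(diff(r), 1e-12) * margin
    seq(r[1] - pad, r[2] + pad, length.out = b + 1)
  }
  bx <- brk(p1, bins[1])
  by <- brk(p2, bins[2])
  ix <- findInterval(p1, bx, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(p2, by, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, bins[1], bins[2])
  tab <- table(factor(ix, levels = seq_len(bins[1])),
    factor(iy, levels = seq_len(bins[2]))
  )
  counts[] <- as.integer(tab)
  structure(
    list(
      counts = counts, P = counts / length(p1),
      x_centers = (bx[-1] + bx[-length(bx)]) / 2,
      y_centers = (by[-1] + by[-length(by)]) / 2,
      n = length(p1)
    ),
    class = "density_grid"
  )
}

#' Transform a density grid into a Gibbs free-energy landscape
#'
#' Treats the binned ensemble as a Boltzmann ensemble:
#' \eqn{G_b = -\ln(P_b / P_{max})} in kT units, so the most populated
#' bin has G = 0 and every occupied bin has G >= 0. Empty bins are
#' masked (`NA`), never assigned a pseudo-count: they are unexplored,
#' not infinitely high, and barrier paths may not cross them.
#'
#' @param grid a [estimate_density()] result.
#' @param temperature reference temperature in kelvin (default 300, a
#'   typical simulation thermostat); used only for the kJ/mol
#'   conversion.
#' @param units `"kT"` (default) or `"kJ/mol"`.
#' @return An object of class `energy_landscape`: list with `G` (matrix,
#'   `NA` on empty bins), `counts`, `x_centers`, `y_centers`,
#'   `temperature`, `units`, `n`.
#' @export
to_free_energy <- function(grid, temperature = 300, units = c("kT", "kJ/mol")) {
  units <- match.arg(units)
  P <- grid$P
  if (all(P == 0)) abort("empty density grid")
  G <- matrix(NA_real_, nrow(P), ncol(P))
  occ <- P > 0
  G[occ] <- -log(P[occ] / max(P))
  if (units == "kJ/mol") G <- G * 0.0083144626 * temperature
  structure(
    list(
      G = G, counts = grid$counts, x_centers = grid$x_centers,
      y_centers = grid$y_centers, temperature = temperature,
      units = units, n = grid$n
    ),
    class = "energy_landscape"
  )
}

#' Local minima and barriers of a free-energy landscape
#'
#' Finds occupied bins lying strictly below all of their (up to 8)
#' occupied neighbours, merges minima closer than `min_separation` bins
#' (Chebyshev distance, keeping the deeper), and discards shallow minima
#' whose depth (barrier to a deeper minimum) is below
#' `depth_threshold`. The barrier between two minima is the minimax path
#' level on the occupied-bin graph minus the higher of the two minimum
#' energies, computed exactly by a watershed (union-find) sweep in order
#' of increasing G.
#'
#' Minima in occupied regions disconnected from any substantial basin
#' (connected components holding fewer than `min_basin_fraction` of the
#' occupied bins) are discarded as unsampled specks: a bin visited by a
#' stray frame at the landscape periphery has no neighbours and would
#' otherwise always count as a minimum. Genuinely separate,
#' well-sampled basins are kept, with `NA` barriers between
#' disconnected pairs.
#'
#' @param land a [to_free_energy()] result.
#' @param min_separation merge radius in bins (default 2).
#' @param depth_threshold minimum depth in energy units (default 1 kT,
#'   the thermal fluctuation scale: shallower dips are not distinct
#'   conformational states).
#' @param min_basin_fraction smallest occupied-bin fraction of a
#'   component that counts as a sampled basin (default 0.01).
#' @param min_count smallest bin count for a bin to qualify as a
#'   minimum (default 16): the shot-noise uncertainty of a bin's free
#'   energy is about `1/sqrt(count)` kT, so 16 counts bound it by a
#'   quarter of the default depth threshold; sparser bins are
#'   indistinguishable from Poisson fluctuations of the histogram rim.
#' @return List with `minima` (tibble: ix, iy, x, y, G) and `barriers`
#'   (symmetric matrix of barrier heights; `NA` between disconnected
#'   minima).
#' @export
find_minima <- function(land, min_separation = 2, depth_threshold = 1,
                        min_basin_fraction = 0.01, min_count = 16) {
  G <- land$G
  if (all(is.na(G))) abort("fully masked landscape")
  nx <- nrow(G)
  ny <- ncol(G)
  occ <- which(!is.na(G))
  ## candidate minima: strictly below all occupied neighbours
  is_min <- vapply(occ, function(b) {
    ix <- (b - 1) %% nx + 1
    iy <- (b - 1) %/% nx + 1
    for (dx in -1:1) {
      for (dy in -1:1) {
        if (dx == 0 && dy == 0) next
        jx <- ix + dx
        jy <- iy + dy
        if (jx < 1 || jx > nx || jy < 1 || jy > ny) next
        gn <- G[jx, jy]
        if (!is.na(gn) && gn <= G[ix, iy]) {
          return(FALSE)
        }
      }
    }
    TRUE
  }, logical(1))
  cand <- occ[is_min]
  cand <- cand[land$counts[cand] >= min_count]
  if (length(cand) == 0) {
    ## flat landscape: treat global minimum bin as the single minimum
    cand <- occ[which.min(G[occ])]
  }
  ## merge candidates within min_separation (keep deeper)
  cand <- cand[order(G[cand])]
  keep <- logical(length(cand))
  cx <- (cand - 1) %% nx + 1
  cy <- (cand - 1) %/% nx + 1
  for (i in seq_along(cand)) {
    ok <- TRUE
    for (j in seq_len(i - 1)) {
      if (keep[j] &&
        max(abs(cx[i] - cx[j]), abs(cy[i] - cy[j])) <= min_separation) {
        ok <- FALSE
        break
      }
    }
    keep[i] <- ok
  }
  cand <- cand[keep]
  ws_full <- watershed_saddles(G, cand)
  ## drop minima sitting in unsampled specks of the occupied region
  min_bins <- max(1, ceiling(min_basin_fraction * length(occ)))
  sampled <- ws_full$comp_size >= min_bins
  if (!any(sampled)) sampled <- ws_full$comp_size == max(ws_full$comp_size)
  cand <- cand[sampled]
  ws <- ws_full$saddle[sampled, sampled, drop = FALSE]
  ## depth filter: iteratively drop the shallowest minimum whose
  ## prominence (saddle to a deeper minimum) is below threshold
  minima <- cand
  saddle <- ws
  repeat {
    if (length(minima) <= 1) break
    gvals <- G[minima]
    prom <- vapply(seq_along(minima), function(i) {
      deeper <- which(gvals < gvals[i])
      if (!length(deeper)) {
        return(Inf)
      }
      min(saddle[i, deeper], na.rm = TRUE) - gvals[i]
    }, numeric(1))
    prom[is.na(prom)] <- Inf
    worst <- which(prom < depth_threshold)
    if (!length(worst)) break
    drop <- worst[which.max(gvals[worst])]
    minima <- minima[-drop]
    saddle <- saddle[-drop, -drop, drop = FALSE]
  }
  ix <- (minima - 1) %% nx + 1
  iy <- (minima - 1) %/% nx + 1
  gm <- G[minima]
  barriers <- matrix(NA_real_, length(minima), length(minima))
  for (i in seq_along(minima)) {
    for (j in seq_along(minima)) {
      if (i != j && is.finite(saddle[i, j])) {
        barriers[i, j] <- saddle[i, j] - max(gm[i], gm[j])
      }
    }
  }
  diag(barriers) <- 0
  list(
    minima = tibble(
      ix = ix, iy = iy,
      x = land$x_centers[ix], y = land$y_centers[iy], G = gm
    ),
    barriers = barriers
  )
}

## exact minimax saddle levels between marked bins: union-find sweep over
## occupied bins in increasing G; when two components holding marked bins
## merge, the current level is their saddle. Also reports the size of
## each marked bin's final connected component.
watershed_saddles <- function(G, marked) {
  nx <- nrow(G)
  ny <- ncol(G)
  occ <- which(!is.na(G))
  ord <- occ[order(G[occ])]
  parent <- integer(nx * ny)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  mark_id <- integer(nx * ny)
  mark_id[marked] <- seq_along(marked)
  comp_marks <- list() # root -> integer vector of marked ids
  saddle <- matrix(NA_real_, length(marked), length(marked))
  active <- logical(nx * ny)
  for (b in ord) {
    parent[b] <- b
    active[b] <- TRUE
    comp_marks[[b]] <- if (mark_id[b] > 0) mark_id[b] else integer(0)
    ix <- (b - 1) %% nx + 1
    iy <- (b - 1) %/% nx + 1
    for (dx in -1:1) {
      for (dy in -1:1) {
        if (dx == 0 && dy == 0) next
        jx <- ix + dx
        jy <- iy + dy
        if (jx < 1 || jx > nx || jy < 1 || jy > ny) next
        nb <- (jy - 1) * nx + jx
        if (!active[nb]) next
        ra <- find(b)
        rb <- find(nb)
        if (ra == rb) next
        ma <- comp_marks[[ra]]
        mb <- comp_marks[[rb]]
        if (length(ma) && length(mb)) {
          for (i in ma) {
            for (j in mb) {
              if (is.na(saddle[i, j])) {
                saddle[i, j] <- G[b]
                saddle[j, i] <- G[b]
              }
            }
          }
        }
        parent[rb] <- ra
        comp_marks[[ra]] <- c(ma, mb)
        comp_marks[[rb]] <- integer(0)
      }
    }
  }
  roots <- vapply(ord, find, integer(1))
  sizes <- table(roots)
  comp_size <- as.integer(sizes[as.character(vapply(marked, find, integer(1)))])
  list(saddle = saddle, comp_size = comp_size)
}

#' One-dimensional marginal density of a principal coordinate
#'
#' @param p numeric vector of projection values, or a
#'   [project_trajectory()] result (first mode used).
#' @param bins number of bins (default 64).
#' @param margin fractional range padding per side (default 0.05).
#' @return A tibble with columns `center` and `P` (probabilities summing
#'   to 1).
#' @export
marginal_density <- function(p, bins = 64, margin = 0.05) {
  if (inherits(p, "projection_series")) p <- p$values[, 1]
  if (length(p) == 0) abort("no points to bin")
  r <- range(p)
  pad <- max(diff(r), 1e-12) * margin
  brk <- seq(r[1] - pad, r[2] + pad, length.out = bins + 1)
  ix <- findInterval(p, brk, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(ix, nbins = bins)
  tibble(
    center = (brk[-1] + brk[-length(brk)]) / 2,
    P = counts / length(p)
  )
}
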