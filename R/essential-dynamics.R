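#' Remove rigid-body motion by least-squares superposition
#'
#' Fits every frame onto a reference by a mass-weighted least-squares
#' rotation and translation (Kabsch algorithm) over a common atom
#' subset. With `reference = "mean"` the fit is iterated: frames are
#' fitted to the ensemble mean, the mean is recomputed from the fitted
#' frames, and the fit repeated - without this step overall rotation
#' would dominate the first principal mode.
#'
#' @param traj a [trajectory_ensemble()].
#' @param reference `"mean"` (default), a frame index, or an N x 3
#'   coordinate matrix (nm).
#' @param selection integer atom indices used for the fit (default all).
#' @param iterations number of fit/re-mean rounds when fitting to the
#'   mean (default 2).
#' @return The superposed [trajectory_ensemble()].
#' @export
superpose <- function(traj, reference = "mean", selection = NULL,
                      iterations = 2) {
  sel <- selection %||% seq_len(n_atoms(traj))
  w <- traj$atoms$mass[sel]
  if (identical(reference, "mean")) {
    ref <- matrix(colMeans(traj$xyz), ncol = 3, byrow = TRUE)
    for (it in seq_len(iterations)) {
      traj <- fit_all(traj, ref, sel, w)
      ref <- matrix(colMeans(traj$xyz), ncol = 3, byrow = TRUE)
    }
    return(traj)
  }
  ref <- if (is.matrix(reference)) reference else frame_coords(traj, reference)
  fit_all(traj, ref, sel, w)
}

fit_all <- function(traj, ref, sel, w) {
  refsel <- ref[sel, , drop = FALSE]
  if (qr(sweep(refsel, 2, colMeans(refsel)))$rank < 2) {
    abort("degenerate (collinear) reference: superposition undefined")
  }
  out <- traj$xyz
  for (t in seq_len(n_frames(traj))) {
    xt <- frame_coords(traj, t)
    out[t, ] <- flatten_coords(kabsch_fit(xt, ref, sel, w))
  }
  trajectory_ensemble(out, traj$atoms, dt = traj$dt, labels = traj$labels)
}

## weighted Kabsch: rigid transform of x (N x 3) minimising weighted RMSD
## of x[sel,] onto ref[sel,]; applied to all atoms
kabsch_fit <- function(x, ref, sel, w) {
  ws <- w / sum(w)
  xc <- colSums(x[sel, , drop = FALSE] * ws)
  rc <- colSums(ref[sel, , drop = FALSE] * ws)
  xs <- sweep(x[sel, , drop = FALSE], 2, xc)
  rs <- sweep(ref[sel, , drop = FALSE], 2, rc)
  h <- t(xs * ws) %*% rs
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(sweep(x, 2, xc) %*% t(rot), 2, rc, `+`)
}

## mass-weighted RMSD between a frame and reference over a selection
rmsd_to <- function(x, ref, sel, w) {
  d <- x[sel, , drop = FALSE] - ref[sel, , drop = FALSE]
  sqrt(sum(w * rowSums(d^2)) / sum(w))
}

#' Mass-weighted covariance of atomic fluctuations
#'
#' Builds the 3N x 3N mass-weighted variance-covariance matrix of the
#' selected atoms over a (superposed) trajectory:
#' \deqn{C_{ab} = \sqrt{m_a m_b}\,(\langle x_a x_b\rangle -
#'   \langle x_a\rangle\langle x_b\rangle)}
#' with ensemble averages over frames (denominator T). Atom pairs moving
#' together give positive entries, pairs moving oppositely negative
#' ones; per-coordinate variances sit on the diagonal.
#'
#' @param traj a superposed [trajectory_ensemble()] with at least 2
#'   frames.
#' @param selection integer atom indices (default all).
#' @return An object of class `covariance_model`: list with `C`
#'   (nm^2 amu), `mean_coords` (N x 3 nm, unweighted), `masses`,
#'   `selection`.
#' @export
build_covariance <- function(traj, selection = NULL) {
  sel <- selection %||% seq_len(n_atoms(traj))
  if (length(sel) == 0) abort("empty atom selection")
  if (n_frames(traj) < 2) abort("at least 2 frames required")
  cols <- as.vector(rbind(3 * sel - 2, 3 * sel - 1, 3 * sel))
  x <- traj$xyz[, cols, drop = FALSE]
  m <- rep(traj$atoms$mass[sel], each = 3)
  xc <- sweep(x, 2, colMeans(x))
  y <- sweep(xc, 2, sqrt(m), `*`)
  C <- crossprod(y) / nrow(y)
  C <- (C + t(C)) / 2
  structure(
    list(
      C = C,
      mean_coords = matrix(colMeans(x), ncol = 3, byrow = TRUE),
      masses = traj$atoms$mass[sel],
      selection = sel
    ),
    class = "covariance_model"
  )
}

#' Eigendecomposition of a covariance model into principal modes
#'
#' Symmetric eigendecomposition \eqn{C = P D P^T}; eigenvectors (the
#' principal modes) are sorted by descending eigenvalue and sign-fixed so
#' each mode's largest-magnitude component is positive, making exported
#' mode vectors reproducible. Exactly degenerate eigenvalues are ordered
#' by first-differing vector component and flagged.
#'
#' @param cov a [build_covariance()] result (`C` must be symmetric).
#' @return An object of class `mode_set`: list with `vectors` (3N x 3N,
#'   orthonormal columns), `values` (descending, nm^2 amu),
#'   `mean_coords`, `masses`, `selection`, `total_variance`,
#'   `degenerate` flag.
#' @export
eigendecompose <- function(cov) {
  C <- cov$C
  if (max(abs(C - t(C))) > 1e-10 * max(1, max(abs(C)))) {
    abort("covariance matrix is not symmetric")
  }
  e <- eigen(C, symmetric = TRUE)
  vals <- e$values
  vecs <- e$vectors
  degenerate <- any(abs(diff(vals)) < 1e-12 * max(abs(vals), 1))
  if (degenerate) {
    ## stable order for ties: by first-differing vector component
    grp <- cumsum(c(TRUE, abs(diff(vals)) >= 1e-12 * max(abs(vals), 1)))
    for (g in unique(grp)) {
      idx <- which(grp == g)
      if (length(idx) > 1) {
        ord <- do.call(order, as.data.frame(t(round(vecs[, idx], 12))))
        vecs[, idx] <- vecs[, idx[ord]]
      }
    }
  }
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  structure(
    list(
      vectors = vecs, values = vals, mean_coords = cov$mean_coords,
      masses = cov$masses, selection = cov$selection,
      total_variance = sum(vals), degenerate = degenerate
    ),
    class = "mode_set"
  )
}

#' Project a trajectory onto principal modes
#'
#' Computes the principal components as functions of the trajectory,
#' \eqn{p_i(t) = \mu_i^T (x(t) - \langle x\rangle)} in mass-weighted
#' coordinates. The variance of each projection equals the mode's
#' eigenvalue when the projecting trajectory is the one the modes were
#' built from.
#'
#' @param traj a superposed [trajectory_ensemble()].
#' @param modes a [eigendecompose()] result. The trajectory must cover
#'   the same atom selection the modes were built on.
#' @param which_modes mode indices (default `1:2`).
#' @return An object of class `projection_series`: list with `values`
#'   (frames x modes matrix, nm amu^0.5), `modes` (indices), `dt`.
#' @export
project_trajectory <- function(traj, modes, which_modes = 1:2) {
  sel <- modes$selection
  if (length(modes$masses) != length(sel)) {
    abort("mode set carries inconsistent selection metadata")
  }
  cols <- as.vector(rbind(3 * sel - 2, 3 * sel - 1, 3 * sel))
  x <- traj$xyz[, cols, drop = FALSE]
  m3 <- rep(modes$masses, each = 3)
  mean3 <- flatten_coords(modes$mean_coords)
  y <- sweep(x, 2, mean3) * rep(sqrt(m3), each = nrow(x))
  p <- y %*% modes$vectors[, which_modes, drop = FALSE]
  structure(
    list(values = p, modes = which_modes, dt = traj$dt),
    class = "projection_series"
  )
}

#' Reconstruct Cartesian coordinates from mode projections
#'
#' Inverts the projection: \eqn{x'(t) = \langle x\rangle + \sum_i
#' p_i(t) \mu_i / \sqrt{m}} over the chosen mode subset. With all 3N
#' modes this is the identity; with a subset it is the motion filtered
#' onto those modes.
#'
#' @param proj a [project_trajectory()] result.
#' @param modes the matching [eigendecompose()] result.
#' @return A [trajectory_ensemble()] over the mode selection's atoms.
#' @export
reconstruct <- function(proj, modes) {
  m3 <- rep(modes$masses, each = 3)
  mean3 <- flatten_coords(modes$mean_coords)
  y <- proj$values %*% t(modes$vectors[, proj$modes, drop = FALSE])
  xyz <- sweep(y / rep(sqrt(m3), each = nrow(y)), 2, mean3, `+`)
  atoms <- tibble(
    resno = seq_along(modes$masses), resid = "XXX", elety = "CA",
    mass = modes$masses
  )
  trajectory_ensemble(xyz, atoms, dt = proj$dt %||% 1)
}

#' Cumulative variance fraction of the leading modes
#'
#' @param modes a [eigendecompose()] result.
#' @param k number of leading modes.
#' @return Fraction of total variance in the first `k` modes, in `[0, 1]`.
#' @export
cumulative_variance <- function(modes, k) {
  if (k < 0 || k > length(modes$values)) abort("k out of range")
  if (k == 0) {
    return(0)
  }
  sum(modes$values[seq_len(k)]) / sum(modes$values)
}

#' Structures at the extremes of a principal mode
#'
#' Reconstructs the conformations at the minimum and maximum observed
#' projection along one mode, together with the per-atom displacement
#' vectors between them - the data underlying porcupine-style renderings
#' of a mode's direction and amplitude. Displacements are reported both
#' raw (mass-weighted) and in Cartesian nm.
#'
#' @param proj a [project_trajectory()] result including mode `i`.
#' @param modes the matching [eigendecompose()] result.
#' @param i mode index.
#' @return List with `min_coords`, `max_coords` (N x 3 nm),
#'   `displacement` (tibble: atom, dx, dy, dz, length_nm,
#'   length_weighted).
#' @export
mode_extremes <- function(proj, modes, i) {
  col <- match(i, proj$modes)
  if (is.na(col)) abort(sprintf("mode %d not present in projection", i))
  p <- proj$values[, col]
  lo <- min(p)
  hi <- max(p)
  one <- function(val) {
    pr <- structure(
      list(values = matrix(val, 1, 1), modes = i, dt = proj$dt),
      class = "projection_series"
    )
    frame_coords(reconstruct(pr, modes), 1)
  }
  cmin <- one(lo)
  cmax <- one(hi)
  d <- cmax - cmin
  mu <- matrix(modes$vectors[, i], ncol = 3, byrow = TRUE)
  disp <- tibble(
    atom = seq_len(nrow(d)),
    dx = d[, 1], dy = d[, 2], dz = d[, 3],
    length_nm = sqrt(rowSums(d^2)),
    length_weighted = (hi - lo) * sqrt(rowSums(mu^2))
  )
  list(min_coords = cmin, max_coords = cmax, displacement = disp)
}

#' Per-block root-mean-square fluctuation
#'
#' Splits the trajectory into consecutive time blocks and computes, per
#' block and atom, \eqn{RMSF_a = \sqrt{\langle |x_a - \langle
#' x_a\rangle_{block}|^2\rangle}}. A stationary, well-behaved simulation
#' shows similar RMSF profiles across blocks; drifting blocks flag
#' unequilibrated or unstable stretches.
#'
#' @param traj a [trajectory_ensemble()].
#' @param block_ps block length in picoseconds; use `Inf` (default) for
#'   a single whole-trajectory block.
#' @return A tibble with columns `block`, `atom`, `resno`, `rmsf` (nm).
#' @export
block_rmsf <- function(traj, block_ps = Inf) {
  T_ <- n_frames(traj)
  n_block <- if (is.infinite(block_ps)) T_ else max(1, floor(block_ps / traj$dt))
  starts <- seq(1, T_, by = n_block)
  out <- purrr::map_dfr(seq_along(starts), function(b) {
    idx <- starts[b]:min(starts[b] + n_block - 1, T_)
    x <- traj$xyz[idx, , drop = FALSE]
    xc <- sweep(x, 2, colMeans(x))
    msf3 <- colMeans(xc^2)
    msf <- msf3[c(TRUE, FALSE, FALSE)] + msf3[c(FALSE, TRUE, FALSE)] +
      msf3[c(FALSE, FALSE, TRUE)]
    tibble(
      block = b, atom = seq_len(n_atoms(traj)),
      resno = traj$atoms$resno, rmsf = sqrt(msf)
    )
  })
  out
}
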