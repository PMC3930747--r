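# shared fixtures and independent oracles

## trajectory of identical frames from an N x 3 coordinate matrix
static_traj <- function(coords, atoms = NULL, n = 3, dt = 1) {
  xyz <- matrix(rep(as.numeric(t(coords)), n), n, byrow = TRUE)
  if (is.null(atoms)) {
    atoms <- data.frame(
      resno = seq_len(nrow(coords)), resid = "GLY", elety = "CA", mass = 1
    )
  }
  trajectory_ensemble(xyz, atoms, dt = dt)
}

## independent four-atom dihedral: praxeolitic formula, scalar inputs
dihedral_oracle <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- p3 - p2
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- p4 - p3
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum(c(
    b1[2] * v[3] - b1[3] * v[2],
    b1[3] * v[1] - b1[1] * v[3],
    b1[1] * v[2] - b1[2] * v[1]
  ) * w)
  atan2(y, x) * 180 / pi
}

## circular SD by direct unit-vector mean (independent of circular_sd)
circ_sd_oracle <- function(deg) {
  th <- deg * pi / 180
  r <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  sqrt(-2 * log(min(r, 1))) * 180 / pi
}

## brute-force symmetric eigendecomposition: power iteration + deflation
eigen_oracle <- function(C, tol = 1e-12, max_iter = 1e5) {
  n <- nrow(C)
  ## shift to make positive definite so power iteration tracks extremes
  shift <- sum(abs(C)) + 1
  A <- C + shift * diag(n)
  vals <- numeric(n)
  vecs <- matrix(0, n, n)
  for (k in seq_len(n)) {
    v <- seq_len(n) / n # deterministic start
    for (j in seq_len(k - 1)) v <- v - sum(v * vecs[, j]) * vecs[, j]
    v <- v / sqrt(sum(v^2))
    lam_old <- Inf
    for (it in seq_len(max_iter)) {
      u <- A %*% v
      for (j in seq_len(k - 1)) u <- u - sum(u * vecs[, j]) * vecs[, j]
      lam <- sqrt(sum(u^2))
      v <- as.numeric(u) / lam
      if (abs(lam - lam_old) < tol * max(1, lam)) break
      lam_old <- lam
    }
    vals[k] <- sum(v * (A %*% v)) - shift
    vecs[, k] <- v
  }
  ord <- order(vals, decreasing = TRUE)
  list(values = vals[ord], vectors = vecs[, ord, drop = FALSE])
}

## brute-force minimax saddle level between two bins of a grid with NA
## masking: smallest level L such that both bins are connected within
## {occupied bins with G <= L}
saddle_oracle <- function(G, a, b) {
  nx <- nrow(G)
  ny <- ncol(G)
  levels <- sort(unique(G[!is.na(G)]))
  for (L in levels) {
    ok <- !is.na(G) & G <= L
    if (!ok[a] || !ok[b]) next
    ## flood fill from a
    seen <- matrix(FALSE, nx, ny)
    ai <- c((a - 1) %% nx + 1, (a - 1) %/% nx + 1)
    queue <- list(ai)
    seen[ai[1], ai[2]] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      for (dx in -1:1) {
        for (dy in -1:1) {
          jx <- cur[1] + dx
          jy <- cur[2] + dy
          if (jx < 1 || jx > nx || jy < 1 || jy > ny) next
          if (seen[jx, jy] || !ok[jx, jy]) next
          seen[jx, jy] <- TRUE
          queue[[length(queue) + 1]] <- c(jx, jy)
        }
      }
    }
    bi <- c((b - 1) %% nx + 1, (b - 1) %/% nx + 1)
    if (seen[bi[1], bi[2]]) {
      return(L)
    }
  }
  NA_real_
}

## planted-sector alignment recipes used across SCA tests
planted_positions <- function() seq(5, 95, 10)

planted_recipe <- function(seed = 11, coupling = 0.8) {
  msa_recipe(
    n_seqs = 500, n_positions = 100,
    sector_positions = planted_positions(),
    sector_coupling = coupling, seed = seed
  )
}

## frame t of a trajectory as an N x 3 matrix (test-side copy)
frame_coords_oracle <- function(traj, t) {
  matrix(traj$xyz[t, ], ncol = 3, byrow = TRUE)
}

## plain (unweighted) RMSD between two N x 3 coordinate sets
rmsd_to_oracle <- function(x, ref) {
  sqrt(mean(rowSums((x - ref)^2)))
}
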