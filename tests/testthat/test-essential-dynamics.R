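test_that("superposition removes planted rigid-body motion exactly", {
  bb <- backbone_reference(5)
  ref <- bb$coords
  rot_z <- function(deg) {
    th <- deg * pi / 180
    matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  }
  ## frames are the same structure under random rigid motions
  set.seed(77)
  frames <- lapply(1:6, function(i) {
    r <- rot_z(runif(1, -180, 180))
    sweep(ref %*% r, 2, runif(3, -2, 2), `+`)
  })
  traj <- trajectory_ensemble(
    do.call(rbind, lapply(frames, function(m) as.numeric(t(m)))),
    bb$atoms
  )
  fit <- superpose(traj, reference = ref)
  for (t in 1:6) {
    expect_lt(rmsd_to_oracle(frame_coords_oracle(fit, t), ref), 1e-8)
  }

  ## 90-degree rotation: RMSD after fit < 1e-6 nm
  one <- trajectory_ensemble(
    rbind(as.numeric(t(ref %*% rot_z(90))), as.numeric(t(ref))), bb$atoms
  )
  fitted <- superpose(one, reference = ref)
  expect_lt(rmsd_to_oracle(frame_coords_oracle(fitted, 1), ref), 1e-6)

  ## already-superposed data unchanged
  again <- superpose(fitted, reference = ref)
  expect_equal(again$xyz, fitted$xyz, tolerance = 1e-8)

  ## degenerate collinear reference rejected
  line <- cbind(1:5, 0, 0)
  ltraj <- trajectory_ensemble(matrix(rnorm(30), 2), bb$atoms[1:5, ][
    ,
    c("resno", "resid", "elety", "mass")
  ])
  expect_error(superpose(ltraj, reference = line), "degenerate")
})

test_that("superposition agrees with bio3d's least-squares fit at unit masses", {
  bb <- backbone_reference(6)
  traj <- generate_trajectory(trajectory_recipe(
    bb$coords, orthonormal_modes(54, 2, 3), c(0.1, 0.05),
    noise_sd = 0.02, n_frames = 10, seed = 5
  ))
  ours <- superpose(traj, reference = bb$coords)
  ref_flat <- as.numeric(t(bb$coords))
  theirs <- suppressWarnings(bio3d::fit.xyz(ref_flat, traj$xyz))
  expect_lt(max(abs(ours$xyz - theirs)), 1e-8)
})

test_that("covariance matches hand-computed ensemble averages", {
  atoms <- data.frame(resno = 1, resid = "GLY", elety = "CA", mass = 1)
  ## one unit-mass atom at (0,0,0) then (2,0,0): C_xx = <x^2> - <x>^2 = 1
  tr <- trajectory_ensemble(rbind(c(0, 0, 0), c(2, 0, 0)), atoms)
  C <- build_covariance(tr)$C
  expect_equal(C[1, 1], 1)
  expect_equal(sum(abs(C)) - abs(C[1, 1]), 0)

  ## static trajectory: zero matrix
  expect_equal(max(abs(build_covariance(static_traj(matrix(1, 2, 3)))$C)), 0)

  ## anti-correlated pair: negative off-diagonal x-x element
  two <- data.frame(
    resno = 1:2, resid = "GLY", elety = "CA", mass = c(1, 1)
  )
  anti <- trajectory_ensemble(
    rbind(c(1, 0, 0, -1, 0, 0), c(-1, 0, 0, 1, 0, 0)), two
  )
  Ca <- build_covariance(anti)$C
  expect_lt(Ca[1, 4], 0)

  expect_error(build_covariance(tr, selection = integer(0)), "empty")
  expect_error(build_covariance(static_traj(matrix(1, 2, 3), n = 1)), "2 frames")
})

test_that("mass weighting scales covariance by sqrt(m_a m_b) and unit masses reduce to plain covariance", {
  atoms <- data.frame(
    resno = 1:2, resid = "GLY", elety = "CA", mass = c(4, 9)
  )
  xyz <- matrix(rnorm(20 * 6), 20, 6)
  heavy <- trajectory_ensemble(xyz, atoms)
  unit <- trajectory_ensemble(xyz, transform(atoms, mass = 1))
  Ch <- build_covariance(heavy)$C
  Cu <- build_covariance(unit)$C
  scale <- sqrt(rep(c(4, 9), each = 3))
  expect_equal(Ch, Cu * outer(scale, scale), tolerance = 1e-12)
})

test_that("eigendecomposition matches a brute-force oracle on small matrices", {
  set.seed(55)
  for (n in c(2, 4, 6)) {
    A <- crossprod(matrix(rnorm(n * n), n))
    cov <- structure(
      list(
        C = A, mean_coords = matrix(0, n / ifelse(n %% 3 == 0, 3, n), 3),
        masses = rep(1, max(1, n / 3)), selection = seq_len(max(1, n / 3))
      ),
      class = "covariance_model"
    )
    ours <- eigendecompose(cov)
    oracle <- eigen_oracle(A)
    expect_equal(ours$values, oracle$values, tolerance = 1e-6)
    for (k in seq_len(n)) {
      expect_gt(abs(sum(ours$vectors[, k] * oracle$vectors[, k])), 1 - 1e-5)
    }
    ## reconstruction P D P' = C
    expect_lt(
      max(abs(ours$vectors %*% diag(ours$values) %*% t(ours$vectors) - A)),
      1e-8 * max(abs(A))
    )
    ## trace conservation
    expect_equal(sum(ours$values), sum(diag(A)), tolerance = 1e-8)
  }
  ## non-symmetric input rejected
  bad <- structure(
    list(
      C = matrix(c(1, 2, 0, 1), 2), mean_coords = matrix(0, 1, 3),
      masses = 1, selection = 1
    ),
    class = "covariance_model"
  )
  expect_error(eigendecompose(bad), "symmetric")
})

test_that("planted modes are recovered within 5 degrees and 10% in eigenvalue", {
  ref <- matrix(rnorm(30), 10, 3)
  modes <- orthonormal_modes(30, 2, seed = 9)
  s <- c(0.3, 0.1)
  noise <- 0.02 # s/noise >= 5
  traj <- generate_trajectory(trajectory_recipe(ref, modes, s,
    noise_sd = noise, n_frames = 1e4, seed = 23
  ))
  ms <- eigendecompose(build_covariance(traj))
  for (i in 1:2) {
    ang <- acos(min(1, abs(sum(ms$vectors[, i] * modes[, i])))) * 180 / pi
    expect_lt(ang, 5)
    expect_equal(ms$values[i], s[i]^2 + noise^2, tolerance = 0.1)
  }
})

test_that("projection variance equals the eigenvalue and modes are uncorrelated", {
  bb <- backbone_reference(6)
  traj <- generate_trajectory(trajectory_recipe(
    bb$coords, orthonormal_modes(54, 3, 2), c(0.2, 0.1, 0.05),
    noise_sd = 0.01, n_frames = 500, seed = 3, atoms = bb$atoms
  ))
  traj <- superpose(traj)
  ms <- eigendecompose(build_covariance(traj))
  proj <- project_trajectory(traj, ms, 1:4)
  T_ <- n_frames(traj)
  for (k in 1:4) {
    v <- mean(proj$values[, k]^2) - mean(proj$values[, k])^2
    expect_equal(v, ms$values[k], tolerance = 1e-8)
  }
  ## mean projection ~ 0 and pairwise covariance ~ 0 in the eigenbasis
  expect_lt(max(abs(colMeans(proj$values))), 1e-10)
  cc <- crossprod(sweep(proj$values, 2, colMeans(proj$values))) / T_
  expect_lt(max(abs(cc - diag(diag(cc)))), 1e-8 * max(diag(cc)))
})

test_that("reconstruction inverts projection: all modes identity, zero gives the mean", {
  atoms <- data.frame(
    resno = 1:3, resid = "GLY", elety = "CA", mass = c(1, 12, 16)
  )
  xyz <- matrix(rnorm(40 * 9, sd = 0.1), 40, 9)
  traj <- trajectory_ensemble(xyz, atoms)
  ms <- eigendecompose(build_covariance(traj))
  all_modes <- project_trajectory(traj, ms, 1:9)
  back <- reconstruct(all_modes, ms)
  expect_lt(max(abs(back$xyz - traj$xyz)), 1e-6)

  zero <- structure(
    list(values = matrix(0, 1, 9), modes = 1:9, dt = 1),
    class = "projection_series"
  )
  mean_back <- reconstruct(zero, ms)
  expect_equal(
    frame_coords_oracle(mean_back, 1), ms$mean_coords,
    tolerance = 1e-10
  )

  ## one-mode reconstruction variance equals eigenvalue_1 (mass-weighted)
  one <- project_trajectory(traj, ms, 1)
  rec1 <- reconstruct(one, ms)
  m3 <- rep(atoms$mass, each = 3)
  y <- sweep(rec1$xyz, 2, colMeans(rec1$xyz)) *
    rep(sqrt(m3), each = nrow(rec1$xyz))
  expect_equal(sum(colMeans(y^2)), ms$values[1], tolerance = 1e-8)
})

test_that("cumulative variance fractions behave as stated", {
  vals <- c(3, 1)
  ms <- structure(
    list(
      values = vals, vectors = diag(2), mean_coords = matrix(0, 1, 3),
      masses = 1, selection = 1, total_variance = 4, degenerate = FALSE
    ),
    class = "mode_set"
  )
  expect_equal(cumulative_variance(ms, 0), 0)
  expect_equal(cumulative_variance(ms, 1), 0.75)
  expect_equal(cumulative_variance(ms, 2), 1)
  fracs <- vapply(0:2, cumulative_variance, numeric(1), modes = ms)
  expect_true(all(diff(fracs) >= 0))
})

test_that("mode extremes lie along the planted mode", {
  ref <- matrix(0, 5, 3)
  mu <- orthonormal_modes(15, 1, seed = 6)
  traj <- generate_trajectory(trajectory_recipe(ref, mu, 0.25,
    noise_sd = 0.01, n_frames = 2000, seed = 31
  ))
  ms <- eigendecompose(build_covariance(traj))
  proj <- project_trajectory(traj, ms, 1:2)
  ext <- mode_extremes(proj, ms, 1)
  d <- as.numeric(t(ext$max_coords - ext$min_coords))
  cosine <- abs(sum(d * mu[, 1])) / sqrt(sum(d^2))
  expect_gt(cosine, 0.99)
  ## symmetric projections give extremes roughly symmetric about the mean
  mid <- (ext$max_coords + ext$min_coords) / 2
  expect_lt(max(abs(mid - ms$mean_coords)), 0.05)
})

test_that("block RMSF is zero for static data and stable for stationary data", {
  tr <- static_traj(matrix(rnorm(9), 3, 3), n = 40)
  r <- block_rmsf(tr, block_ps = 10)
  expect_true(all(r$rmsf == 0))

  bb <- backbone_reference(4)
  stat <- generate_trajectory(trajectory_recipe(
    bb$coords, orthonormal_modes(36, 1, 4), 0.1,
    noise_sd = 0.02, n_frames = 4000, seed = 8
  ))
  blocks <- block_rmsf(stat, block_ps = 1000) # 4 blocks of 1e3 frames
  spread <- dplyr::summarise(
    dplyr::group_by(blocks, atom),
    rel = (max(rmsf) - min(rmsf)) / mean(rmsf)
  )
  expect_lt(max(spread$rel), 0.1)

  whole <- block_rmsf(stat)
  expect_equal(length(unique(whole$block)), 1)
  one_block <- block_rmsf(stat, block_ps = n_frames(stat) * stat$dt)
  expect_equal(whole$rmsf, one_block$rmsf)
})

test_that("essential dynamics agrees with bio3d's PCA at unit masses", {
  bb <- backbone_reference(5)
  traj <- generate_trajectory(trajectory_recipe(
    bb$coords, orthonormal_modes(45, 2, 11), c(0.15, 0.07),
    noise_sd = 0.02, n_frames = 300, seed = 19
  ))
  traj <- superpose(traj)
  ms <- eigendecompose(build_covariance(traj))
  b3 <- bio3d::pca.xyz(traj$xyz)
  ## bio3d's covariance uses denominator T - 1; ours is the ensemble
  ## average (denominator T)
  T_ <- n_frames(traj)
  expect_equal(ms$values * T_ / (T_ - 1), b3$L, tolerance = 1e-6)
  for (k in 1:3) {
    expect_gt(abs(sum(ms$vectors[, k] * b3$U[, k])), 1 - 1e-6)
  }
})
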