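#' Recipe for a synthetic trajectory with planted collective modes
#'
#' Describes an ensemble whose frames fluctuate about a reference
#' structure along a few prescribed orthonormal collective modes with
#' given amplitudes, plus isotropic per-coordinate noise:
#' \deqn{x_t = x_{ref} + \sum_i z_{t,i} s_i \mu_i + \epsilon_t}
#' with independent standard-normal `z` and `eps`. This is the
#' statistical structure essential-dynamics analysis assumes, so planted
#' recipes give exact expectations for covariance and mode recovery.
#'
#' @param reference N x 3 matrix of reference coordinates (nm).
#' @param modes 3N x k matrix of mutually orthonormal mode vectors
#'   (orthonormal to 1e-8).
#' @param mode_sd k non-negative mode amplitudes (nm).
#' @param noise_sd isotropic per-coordinate noise SD (nm).
#' @param n_frames number of frames.
#' @param dt frame spacing (ps).
#' @param seed integer seed; generation is a pure function of the recipe.
#' @param atoms optional atom metadata (defaults to unit-mass CA atoms,
#'   one per reference row, so mass weighting is exercised only where a
#'   test plants masses deliberately).
#' @return An object of class `trajectory_recipe`.
#' @export
trajectory_recipe <- function(reference, modes, mode_sd, noise_sd = 0,
                              n_frames = 1000, dt = 1, seed = 1,
                              atoms = NULL) {
  reference <- as.matrix(reference)
  modes <- as.matrix(modes)
  n3 <- 3 * nrow(reference)
  if (nrow(modes) != n3) abort("modes must be 3N-vectors")
  if (ncol(modes) > n3) abort("at most 3N modes allowed")
  if (length(mode_sd) != ncol(modes)) abort("one amplitude per mode required")
  if (any(mode_sd < 0) || noise_sd < 0) abort("amplitudes must be non-negative")
  gram <- crossprod(modes)
  if (max(abs(gram - diag(ncol(modes)))) > 1e-8) {
    abort("modes must be mutually orthonormal (tolerance 1e-8)")
  }
  if (is.null(atoms)) {
    atoms <- tibble(
      resno = seq_len(nrow(reference)), resid = "GLY",
      elety = "CA", mass = 1
    )
  }
  structure(
    list(
      reference = reference, modes = modes, mode_sd = mode_sd,
      noise_sd = noise_sd, n_frames = n_frames, dt = dt, seed = seed,
      atoms = as_tibble(atoms)
    ),
    class = "trajectory_recipe"
  )
}

#' Generate a synthetic trajectory from a recipe
#'
#' @param recipe a [trajectory_recipe()].
#' @return A [trajectory_ensemble()]; deterministic for a fixed recipe.
#' @examples
#' ref <- matrix(rnorm(9), 3, 3)
#' m <- qr.Q(qr(matrix(rnorm(18), 9, 2)))
#' tr <- generate_trajectory(trajectory_recipe(ref, m, c(0.3, 0.1),
#'   noise_sd = 0.02, n_frames = 100, seed = 7))
#' n_frames(tr)
#' @export
generate_trajectory <- function(recipe) {
  stopifnot(inherits(recipe, "trajectory_recipe"))
  n3 <- 3 * nrow(recipe$reference)
  k <- ncol(recipe$modes)
  xyz <- with_seed(recipe$seed, {
    z <- matrix(rnorm(recipe$n_frames * k), recipe$n_frames, k)
    eps <- if (recipe$noise_sd > 0) {
      matrix(rnorm(recipe$n_frames * n3, sd = recipe$noise_sd),
        recipe$n_frames, n3
      )
    } else {
      0
    }
    base <- matrix(flatten_coords(recipe$reference), recipe$n_frames, n3,
      byrow = TRUE
    )
    base + z %*% (diag(recipe$mode_sd, k) %*% t(recipe$modes)) + eps
  })
  trajectory_ensemble(xyz, recipe$atoms, dt = recipe$dt, labels = 1L)
}

#' Generate a wrapped-normal dihedral-angle series
#'
#' Draws angles from a wrapped normal distribution, reported in degrees
#' in (-180, 180]. The circular standard deviation of a wrapped normal
#' equals the SD of the underlying (unwrapped) normal, which makes the
#' generator directly comparable with [circular_sd()].
#'
#' @param n_frames number of draws.
#' @param mean_deg circular mean (degrees).
#' @param circ_sd_deg circular standard deviation (degrees).
#' @param seed integer seed.
#' @return Numeric vector of angles in (-180, 180].
#' @export
generate_dihedral_series <- function(n_frames, mean_deg, circ_sd_deg, seed = 1) {
  if (circ_sd_deg < 0) abort("circular SD must be non-negative")
  with_seed(seed, wrap_angle(mean_deg + rnorm(n_frames, sd = circ_sd_deg)))
}

#' Ideal backbone reference coordinates
#'
#' Builds N-CA-C backbone coordinates for a chain of `n_res` residues
#' from ideal bond lengths and angles and the supplied phi/psi torsions
#' (omega fixed trans at 180 degrees), using sequential internal-to-
#' Cartesian placement. Useful as a geometric fixture whose dihedrals are
#' known by construction.
#'
#' @param n_res number of residues.
#' @param phi,psi backbone torsions in degrees, recycled to `n_res`.
#'   `phi[1]` is undefined for a chain and ignored.
#' @param resid three-letter residue name, recycled.
#' @return List with `coords` (3*n_res x 3 matrix, nm) and `atoms`
#'   metadata suitable for [trajectory_recipe()].
#' @examples
#' bb <- backbone_reference(5, phi = -57, psi = -47) # alpha-helical
#' @export
backbone_reference <- function(n_res, phi = -57, psi = -47, resid = "ALA") {
  stopifnot(n_res >= 2)
  phi <- rep_len(phi, n_res)
  psi <- rep_len(psi, n_res)
  resid <- rep_len(resid, n_res)
  ## ideal geometry (angstrom, degrees)
  b_n_ca <- 1.458
  b_ca_c <- 1.525
  b_c_n <- 1.329
  a_n_ca_c <- 111.2
  a_ca_c_n <- 116.2
  a_c_n_ca <- 121.7
  omega <- 180
  coords <- matrix(NA_real_, 3 * n_res, 3)
  ## first residue: N at origin, CA on x, C in xy-plane
  coords[1, ] <- c(0, 0, 0)
  coords[2, ] <- c(b_n_ca, 0, 0)
  th <- a_n_ca_c * pi / 180
  coords[3, ] <- coords[2, ] + b_ca_c * c(-cos(th), sin(th), 0)
  for (i in 2:n_res) {
    r <- 3 * (i - 1)
    ## N(i): torsion psi(i-1) about N(i-1)-CA(i-1)-C(i-1)
    coords[r + 1, ] <- place_atom(
      coords[r - 2, ], coords[r - 1, ], coords[r, ],
      b_c_n, a_ca_c_n, psi[i - 1]
    )
    ## CA(i): torsion omega about CA(i-1)-C(i-1)-N(i)
    coords[r + 2, ] <- place_atom(
      coords[r - 1, ], coords[r, ], coords[r + 1, ],
      b_n_ca, a_c_n_ca, omega
    )
    ## C(i): torsion phi(i) about C(i-1)-N(i)-CA(i)
    coords[r + 3, ] <- place_atom(
      coords[r, ], coords[r + 1, ], coords[r + 2, ],
      b_ca_c, a_n_ca_c, phi[i]
    )
  }
  atoms <- tibble(
    resno = rep(seq_len(n_res), each = 3),
    resid = rep(resid, each = 3),
    elety = rep(c("N", "CA", "C"), n_res),
    mass = rep(c(14.007, 12.011, 12.011), n_res)
  )
  list(coords = coords / 10, atoms = atoms) # angstrom -> nm
}

## place atom D given A-B-C, bond length |CD|, angle B-C-D and torsion
## A-B-C-D (degrees); standard internal-coordinate (NeRF) construction
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180
  chi <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(
    ab[2] * bc[3] - ab[3] * bc[2],
    ab[3] * bc[1] - ab[1] * bc[3],
    ab[1] * bc[2] - ab[2] * bc[1]
  )
  n <- n / sqrt(sum(n^2))
  m <- c(
    n[2] * bc[3] - n[3] * bc[2],
    n[3] * bc[1] - n[1] * bc[3],
    n[1] * bc[2] - n[2] * bc[1]
  )
  d_local <- bond * c(-cos(th), sin(th) * cos(chi), sin(th) * sin(chi))
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}
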