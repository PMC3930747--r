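#' Backbone phi dihedral series from a trajectory
#'
#' Computes, for every residue and frame, the backbone phi torsion about
#' the N-CA bond, defined by atoms C(i-1), N(i), CA(i), C(i) with the
#' IUPAC sign convention. The first residue of the chain has no phi and
#' is reported as missing, as is any residue lacking one of the four
#' defining atoms (with a warning, not an error).
#'
#' @param traj a [trajectory_ensemble()] whose atom metadata contains
#'   backbone atoms named `N`, `CA` and `C`.
#' @param state_label optional label (e.g. "peptide-bound") carried into
#'   reports.
#' @return An object of class `dihedral_series`: list with `residues`
#'   (positions), `angles` (frames x residues matrix, degrees in
#'   (-180, 180]), `glycine` (logical per residue) and `state_label`.
#' @export
compute_phi_series <- function(traj, state_label = NULL) {
  at <- traj$atoms
  residues <- sort(unique(at$resno))
  T_ <- n_frames(traj)
  angles <- matrix(NA_real_, T_, length(residues))
  glycine <- logical(length(residues))
  idx_of <- function(resno, name) {
    i <- which(at$resno == resno & trimws(at$elety) == name)
    if (length(i) == 1) i else NA_integer_
  }
  col3 <- function(i) traj$xyz[, c(3 * i - 2, 3 * i - 1, 3 * i), drop = FALSE]
  missing_res <- integer(0)
  for (k in seq_along(residues)) {
    r <- residues[k]
    glycine[k] <- any(at$resno == r & at$resid == "GLY")
    if (k == 1) next # chain start: no preceding carbonyl carbon
    ic <- idx_of(residues[k - 1], "C")
    i_n <- idx_of(r, "N")
    ica <- idx_of(r, "CA")
    ic2 <- idx_of(r, "C")
    if (anyNA(c(ic, i_n, ica, ic2))) {
      missing_res <- c(missing_res, r)
      next
    }
    angles[, k] <- dihedral_deg(col3(ic), col3(i_n), col3(ica), col3(ic2))
  }
  if (length(missing_res)) {
    warn(sprintf(
      "phi undefined for residue(s) %s: missing backbone atoms",
      paste(missing_res, collapse = ", ")
    ))
  }
  structure(
    list(
      residues = residues, angles = angles, glycine = glycine,
      state_label = state_label
    ),
    class = "dihedral_series"
  )
}

## torsion angle (degrees, IUPAC sign) for four atom positions given as
## T x 3 matrices; vectorised over frames
dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  cross <- function(u, v) {
    cbind(
      u[, 2] * v[, 3] - u[, 3] * v[, 2],
      u[, 3] * v[, 1] - u[, 1] * v[, 3],
      u[, 1] * v[, 2] - u[, 2] * v[, 1]
    )
  }
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  m1 <- cross(n1, b2n)
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  wrap_angle(atan2(-y, x) * 180 / pi)
}

#' Circular standard deviation of an angle series
#'
#' Computes \eqn{\sqrt{-2 \ln \bar R} \cdot 180/\pi} where \eqn{\bar R}
#' is the mean resultant length of the angles on the unit circle. Unlike
#' the naive linear SD, this statistic is invariant to a constant
#' rotation of all angles and is correct across the +/-180-degree wrap -
#' exactly where highly flexible residues live.
#'
#' @param angles numeric vector of angles in degrees; `NA`s are dropped.
#' @return Circular SD in degrees, or `NA` if fewer than 2 angles remain.
#' @examples
#' circular_sd(rep(c(179, -179), 50)) # ~1 degree, not ~179
#' @export
circular_sd <- function(angles) {
  angles <- angles[!is.na(angles)]
  if (length(angles) < 2) {
    return(NA_real_)
  }
  th <- angles * pi / 180
  rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  rbar <- min(rbar, 1)
  sqrt(-2 * log(rbar)) * 180 / pi
}

## naive linear SD (population of sample? sample SD, as conventional)
linear_sd <- function(angles) {
  angles <- angles[!is.na(angles)]
  if (length(angles) < 2) {
    return(NA_real_)
  }
  stats::sd(angles)
}

#' Per-residue flexibility from a dihedral series
#'
#' Summarises the phi series as a per-residue dispersion (circular SD by
#' default) and flags flexible sites, i.e. residues whose SD strictly
#' exceeds the threshold. Glycines are included in the statistics but
#' flagged, mirroring how they are usually presented separately.
#'
#' @param series a `dihedral_series` from [compute_phi_series()], or a
#'   numeric matrix of angles (frames x residues).
#' @param threshold flexibility threshold in degrees (default 25).
#' @param method `"circular"` (default) or `"linear"` dispersion.
#' @return An object of class `flexibility_report`: a tibble with
#'   columns `residue`, `sd_phi`, `flexible`, `glycine`, plus attributes
#'   `threshold`, `method` and `state_label`.
#' @export
flexible_sites <- function(series, threshold = 25, method = c("circular", "linear")) {
  method <- match.arg(method)
  if (threshold <= 0) abort("threshold must be positive")
  if (is.matrix(series)) {
    series <- structure(
      list(
        residues = seq_len(ncol(series)), angles = series,
        glycine = rep(FALSE, ncol(series)), state_label = NULL
      ),
      class = "dihedral_series"
    )
  }
  f <- if (method == "circular") circular_sd else linear_sd
  sds <- apply(series$angles, 2, f)
  out <- tibble(
    residue = series$residues,
    sd_phi = sds,
    flexible = !is.na(sds) & sds > threshold,
    glycine = series$glycine
  )
  structure(out,
    threshold = threshold, method = method,
    state_label = series$state_label,
    class = c("flexibility_report", class(out))
  )
}

#' Compare per-residue flexibility between two states
#'
#' Aligns two flexibility reports by residue and reports the change in
#' phi dispersion together with the flexible-site counts of each state
#' (e.g. peptide-bound vs peptide-free).
#'
#' @param bound,free `flexibility_report` objects from [flexible_sites()].
#' @return A tibble with columns `residue`, `sd_bound`, `sd_free`,
#'   `delta_sd`, `flexible_bound`, `flexible_free`; the two flexible-site
#'   counts and their difference are in the `"site_counts"` attribute.
#' @export
compare_states <- function(bound, free) {
  b <- tibble(
    residue = bound$residue, sd_bound = bound$sd_phi,
    flexible_bound = bound$flexible
  )
  f <- tibble(
    residue = free$residue, sd_free = free$sd_phi,
    flexible_free = free$flexible
  )
  out <- dplyr::full_join(b, f, by = "residue")
  out <- dplyr::mutate(out, delta_sd = .data$sd_free - .data$sd_bound)
  out <- dplyr::arrange(out, .data$residue)
  counts <- c(
    bound = sum(bound$flexible, na.rm = TRUE),
    free = sum(free$flexible, na.rm = TRUE)
  )
  structure(out,
    site_counts = c(counts, delta = unname(counts["free"] - counts["bound"])),
    class = c("flexibility_comparison", class(out))
  )
}
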