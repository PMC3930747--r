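## integer-code the mapped columns of an alignment: M x K matrix with
## values 1..20 (alphabet index) or 0 for gap; columns named by
## reference position
code_alignment <- function(aln) {
  mapped <- which(!is.na(aln$column_map))
  if (length(mapped) < 1) abort("alignment has no mapped columns")
  sub <- aln$seqs[, mapped, drop = FALSE]
  code <- match(sub, aa_alphabet())
  code[is.na(code)] <- 0L
  code <- matrix(as.integer(code), nrow = nrow(sub))
  colnames(code) <- aln$column_map[mapped]
  code
}

#' Positional conservation as Kullback-Leibler relative entropy
#'
#' For each mapped reference position i, measures how far the observed
#' amino-acid frequencies are from a background composition:
#' \deqn{D_i = \sum_a f_i^a \ln(f_i^a / q^a)}
#' over the 20 amino acids, with gaps excluded from the frequencies.
#' D = 0 when a column matches the background exactly; a fully conserved
#' residue a gives D = ln(1/q^a).
#'
#' @param aln an [alignment_matrix()] with a defined column map.
#' @param background named 20-vector of background probabilities
#'   (default [aa_background()]).
#' @return An object of class `conservation_profile`: a tibble with
#'   columns `position`, `D` (nats) and `n_nongap`; per-position
#'   frequencies (20 x K) are kept in the `"frequencies"` attribute.
#'   All-gap positions get `NA` with a warning.
#' @export
position_conservation <- function(aln, background = aa_background()) {
  code <- code_alignment(aln)
  K <- ncol(code)
  q <- background[aa_alphabet()]
  f <- vapply(seq_len(K), function(j) {
    tabulate(code[, j], nbins = 20)
  }, numeric(20))
  n_nongap <- colSums(f)
  D <- rep(NA_real_, K)
  ok <- n_nongap > 0
  if (any(!ok)) {
    warn(sprintf(
      "position(s) %s are all-gap: conservation undefined",
      paste(colnames(code)[!ok], collapse = ", ")
    ))
  }
  fn <- sweep(f, 2, pmax(n_nongap, 1), `/`)
  D[ok] <- vapply(which(ok), function(j) {
    fi <- fn[, j]
    nz <- fi > 0
    sum(fi[nz] * log(fi[nz] / q[nz]))
  }, numeric(1))
  out <- tibble(
    position = as.integer(colnames(code)),
    D = D, n_nongap = as.integer(n_nongap)
  )
  structure(out,
    frequencies = fn, background = q,
    class = c("conservation_profile", class(out))
  )
}

## conservation-based weights w_i^a = |d/df [f ln(f/q) + (1-f) ln((1-f)/(1-q))]|
## = |ln( f(1-q) / ((1-f)q) )| at the background-regularised frequency
sca_weights <- function(f_reg, q) {
  abs(log(f_reg * (1 - q) / ((1 - f_reg) * q)))
}

#' Conservation-weighted positional correlation matrix
#'
#' The coupling statistic between mapped positions i and j is the
#' Frobenius norm, over amino-acid pairs (a, b), of the conservation-
#' weighted covariance of their occurrence indicators:
#' \deqn{\tilde C_{ij} = \| w_i^a w_j^b (f_{ij}^{ab} - f_i^a f_j^b) \|_F}
#' where the weight \eqn{w_i^a} is the magnitude of the derivative of
#' the binary relative entropy at the (regularised) frequency
#' \eqn{f_i^a}. Frequencies are regularised by mixing a pseudo-fraction
#' `lambda` toward the background so the log-derivative weight stays
#' finite at f in {0, 1}.
#'
#' Two mathematically identical evaluation paths are provided: one in
#' the 20K-dimensional symbol space and one via per-position M x M
#' indicator Gram matrices; the cheaper one for the alignment's shape is
#' chosen automatically.
#'
#' @param aln an [alignment_matrix()] with a defined column map.
#' @param background named 20-vector of background probabilities.
#' @param lambda regularisation fraction (default 0.03).
#' @return An object of class `sca_matrix`: list with `C` (K x K,
#'   symmetric, non-negative, dimnames = reference positions), `eigen`
#'   (values and vectors of `C`), `positions`, and the coded alignment
#'   and weights needed to recompute the statistic under column
#'   randomisation.
#' @export
weighted_correlation_matrix <- function(aln, background = aa_background(),
                                        lambda = 0.03) {
  code <- code_alignment(aln)
  if (ncol(code) < 2) abort("at least 2 mapped positions required")
  q <- background[aa_alphabet()]
  M <- nrow(code)
  K <- ncol(code)
  f <- vapply(seq_len(K), function(j) tabulate(code[, j], nbins = 20), numeric(20)) / M
  f_reg <- (1 - lambda) * f + lambda * matrix(q, 20, K)
  w <- sca_weights(f_reg, matrix(q, 20, K))
  C <- sca_matrix_compute(code, f, w)
  dimnames(C) <- list(colnames(code), colnames(code))
  e <- eigen(C, symmetric = TRUE)
  structure(
    list(
      C = C, eigen = e, positions = as.integer(colnames(code)),
      code = code, f = f, weights = w, lambda = lambda, background = q
    ),
    class = "sca_matrix"
  )
}

## dispatch between the two exact evaluation paths on predicted memory
sca_matrix_compute <- function(code, f, w) {
  M <- nrow(code)
  K <- ncol(code)
  if (M * M <= 400 * K) {
    sca_matrix_gram(code, f, w)
  } else {
    sca_matrix_symbol(code, f, w)
  }
}

## path 1: per-position weighted centred indicator Z_i (M x 20);
## Ctilde_ij = sqrt(<Z_i Z_i^T, Z_j Z_j^T>) / M
sca_matrix_gram <- function(code, f, w) {
  M <- nrow(code)
  K <- ncol(code)
  Q <- matrix(0, M * M, K)
  for (j in seq_len(K)) {
    Z <- matrix(0, M, 20)
    nz <- code[, j] > 0
    Z[cbind(which(nz), code[nz, j])] <- 1
    Z <- sweep(Z, 2, f[, j]) * rep(w[, j], each = M)
    Q[, j] <- as.vector(tcrossprod(Z))
  }
  C2 <- crossprod(Q) / M^2
  sqrt(pmax(C2, 0))
}

## path 2: symbol-space indicator matrix B (M x 20K)
sca_matrix_symbol <- function(code, f, w) {
  M <- nrow(code)
  K <- ncol(code)
  B <- matrix(0, M, 20 * K)
  nz <- which(code > 0)
  rows <- ((nz - 1) %% M) + 1
  cols <- ((nz - 1) %/% M) + 1
  B[cbind(rows, (cols - 1) * 20 + code[nz])] <- 1
  wv <- as.vector(w)
  fv <- as.vector(f)
  Bw <- B * rep(wv, each = M)
  A <- crossprod(Bw) / M - tcrossprod(wv * fv)
  grp <- rep(seq_len(K), each = 20)
  S <- rowsum(A^2, grp)
  S <- t(rowsum(t(S), grp))
  sqrt(pmax(t(S), 0))
}

#' Statistically significant eigenmodes versus randomized alignments
#'
#' Decomposes the coupling matrix and keeps the eigenmodes whose
#' eigenvalues exceed anything produced by chance: for each of
#' `n_randomizations` trials, every mapped column's symbols are
#' independently permuted across sequences (destroying inter-column
#' correlation while preserving every column's composition and hence
#' the conservation weights), the coupling matrix is recomputed, and
#' its eigenvalues are pooled into a null sample. Retained modes are
#' those of the true matrix above the maximum pooled null eigenvalue.
#' The first eigenmode of any coupling matrix - randomized or not -
#' largely reflects overall conservation rather than coupling; by
#' default each randomized decomposition therefore contributes all but
#' its own first eigenvalue to the null pool
#' (`drop_null_first = TRUE`), and the true first mode is retained when
#' significant (`keep_first = TRUE`), so that non-trivial modes are
#' judged against the non-trivial null spectrum.
#'
#' @param mat a [weighted_correlation_matrix()] result.
#' @param n_randomizations number of column-shuffled alignments
#'   (default 100).
#' @param seed integer seed; the procedure is deterministic under it.
#' @param keep_first retain the first (conservation-dominated) mode if
#'   significant (default TRUE).
#' @param drop_null_first drop each randomization's first eigenvalue
#'   from the null pool (default TRUE).
#' @return An object of class `sca_modes`: list with `retained`
#'   (indices), `n_retained`, `values`, `vectors`, `null_max`,
#'   `null_values` (pooled sample), `positions`.
#' @export
significant_modes <- function(mat, n_randomizations = 100, seed = 1,
                              keep_first = TRUE, drop_null_first = TRUE) {
  if (n_randomizations < 1) abort("at least one randomization required")
  code <- mat$code
  M <- nrow(code)
  null_vals <- with_seed(seed, {
    unlist(lapply(seq_len(n_randomizations), function(r) {
      perm <- code
      for (j in seq_len(ncol(code))) perm[, j] <- code[sample.int(M), j]
      Cn <- sca_matrix_compute(perm, mat$f, mat$weights)
      ev <- eigen(Cn, symmetric = TRUE, only.values = TRUE)$values
      if (drop_null_first) ev[-1] else ev
    }))
  })
  null_max <- max(null_vals)
  retained <- which(mat$eigen$values > null_max)
  if (!keep_first) retained <- setdiff(retained, 1L)
  structure(
    list(
      retained = retained, n_retained = length(retained),
      values = mat$eigen$values, vectors = mat$eigen$vectors,
      null_max = null_max, null_values = null_vals,
      positions = mat$positions, seed = seed
    ),
    class = "sca_modes"
  )
}

#' Rotate retained eigenmodes into independent components
#'
#' Applies independent component analysis to the retained eigenmode
#' subspace so that groups of coupled positions load on separate axes:
#' the K positions are treated as observations of the k retained modes,
#' whitened, and un-mixed by a symmetric fixed-point iteration
#' (tolerance 1e-6, at most `max_iter` sweeps). The default cube
#' (kurtosis) contrast separates both super-Gaussian components (small
#' spuriously coupled groups, sharply peaked weights) and sub-Gaussian
#' ones (large sectors and the conservation direction, whose weight
#' distributions are bimodal); the tanh contrast is available but
#' cannot separate two sub-Gaussian sources. The
#' rotation preserves the spanned subspace. Components are ordered by
#' decreasing excess kurtosis (heavy-tailed, sector-like components
#' first) and sign-fixed so the heavy tail is positive.
#'
#' @param modes a [significant_modes()] result with at least one
#'   retained mode.
#' @param n_components number of independent axes; defaults to the
#'   number of retained modes, so every statistically significant
#'   direction gets its own axis and coupled groups cannot be forced to
#'   share a component.
#' @param seed integer seed for the random orthogonal initialisation.
#' @param max_iter maximum fixed-point sweeps (default 1e4).
#' @param contrast fixed-point nonlinearity: `"pow3"` (default) or
#'   `"tanh"`.
#' @return An object of class `ica_components`: list with `S`
#'   (n_components x K weights), `positions`, `kurtosis`, `iterations`,
#'   `retained`.
#' @export
ica_rotate <- function(modes, n_components = NULL, seed = 1, max_iter = 1e4,
                       contrast = c("pow3", "tanh")) {
  contrast <- match.arg(contrast)
  k <- length(modes$retained)
  if (k < 1) abort("no retained modes to rotate")
  n_components <- n_components %||% k
  if (n_components > k) abort("n_components exceeds retained modes")
  V <- modes$vectors[, modes$retained, drop = FALSE] # K x k
  X <- t(V) # k x K, positions as samples
  K <- ncol(X)
  Xc <- X - rowMeans(X)
  cv <- tcrossprod(Xc) / K
  ec <- eigen(cv, symmetric = TRUE)
  wh <- diag(1 / sqrt(pmax(ec$values, 1e-15)), k) %*% t(ec$vectors)
  Z <- wh %*% Xc
  W <- with_seed(seed, {
    w0 <- matrix(rnorm(n_components * k), n_components, k)
    sv <- svd(w0)
    sv$u %*% t(sv$v)
  })
  it <- 0
  repeat {
    it <- it + 1
    if (it > max_iter) {
      abort(sprintf("ICA did not converge after %d iterations", max_iter))
    }
    WX <- W %*% Z
    if (contrast == "tanh") {
      g <- tanh(WX)
      gp <- 1 - g^2
    } else {
      g <- WX^3
      gp <- 3 * WX^2
    }
    W_new <- g %*% t(Z) / K - diag(rowMeans(gp), n_components) %*% W
    ## symmetric decorrelation
    sv <- svd(W_new)
    W_new <- sv$u %*% t(sv$v)
    delta <- max(abs(1 - abs(rowSums(W_new * W))))
    W <- W_new
    if (delta < 1e-6) break
  }
  S <- W %*% Z
  kur <- apply(S, 1, function(s) mean((s - mean(s))^4) / var(s)^2 - 3)
  ord <- order(kur, decreasing = TRUE)
  S <- S[ord, , drop = FALSE]
  kur <- kur[ord]
  for (i in seq_len(nrow(S))) {
    s <- S[i, ]
    skew <- mean((s - mean(s))^3)
    flip <- if (abs(skew) > 1e-12) skew < 0 else s[which.max(abs(s))] < 0
    if (flip) S[i, ] <- -s
  }
  structure(
    list(
      S = S, positions = modes$positions, kurtosis = kur,
      iterations = it, retained = modes$retained
    ),
    class = "ica_components"
  )
}

#' Define a protein sector from an independent component
#'
#' Fits a location-scale Student-t distribution to the positional
#' weights of the chosen independent component by maximum likelihood
#' and takes as sector members the positions whose weight exceeds the
#' fitted quantile at `cdf_cutoff` - the heavy upper tail of the weight
#' distribution. The alternative `rule = "top_fraction"` instead takes
#' the top `1 - cdf_cutoff` fraction of positions by weight.
#'
#' The fitted quantile is then refined so the cutoff produces a
#' coherent group rather than splitting the bulk's own fringe: when the
#' sorted weights contain a gap that is implausibly wide relative to
#' the bulk dispersion (wider than `gap_factor` times the MAD of the
#' weights) at or above the fitted quantile, the cutoff snaps to the
#' lowest such gap. A coevolving group separated from the background
#' produces exactly such a gap; continuous weight distributions are
#' left untouched. Disable with `refine_gaps = FALSE` for the bare
#' fitted-quantile rule.
#'
#' With `ic_index = NULL` (default) the rule is applied to every
#' component in both orientations - the sign of an independent
#' component is arbitrary, and a sector can occupy either tail. When
#' the coupling matrix is supplied (`mat`), the winning candidate is
#' the member set that captures the most statistical coupling: the sum
#' over member pairs of the coupling excess above the matrix-wide 75th
#' percentile. This is the method's own definition of a sector - a
#' mutually coevolving group - and cleanly rejects candidates made of
#' strongly conserved but uncoupled positions, whose internal pairs
#' score at or below background. Without `mat`, the largest member set
#' among detached-cluster (snapped) candidates wins, falling back to
#' the largest overall. (Excess kurtosis does not identify the sector
#' axis: a sector spanning a third of all positions makes its component
#' bimodal, i.e. *platykurtic*, while a handful of spuriously coupled
#' positions gives a sharply leptokurtic one.)
#'
#' @param ics an [ica_rotate()] result.
#' @param ic_index which component to threshold, or `NULL` (default) to
#'   select the component with the largest defined sector.
#' @param cdf_cutoff cumulative-density cutoff in (0, 1) (default 0.85).
#' @param rule `"cdf"` (default, fitted-quantile rule) or
#'   `"top_fraction"`.
#' @param refine_gaps apply the cluster-gap refinement (default TRUE).
#' @param gap_factor implausibility multiple for the gap width, in MAD
#'   units (default 10).
#' @param mat optional [weighted_correlation_matrix()] result used to
#'   score candidates by captured coupling during automatic component
#'   selection.
#' @return An object of class `sector_result`: list with `members`
#'   (reference positions), `weights` (tibble: position, weight,
#'   member), `ic_index`, `fit` (t location/scale/df), `threshold`,
#'   `cdf_cutoff`, `rule`, and (when selection was automatic)
#'   `candidate_sizes` per component.
#' @export
define_sector <- function(ics, ic_index = NULL, cdf_cutoff = 0.85,
                          rule = c("cdf", "top_fraction"),
                          refine_gaps = TRUE, gap_factor = 10,
                          mat = NULL) {
  rule <- match.arg(rule)
  if (cdf_cutoff <= 0 || cdf_cutoff >= 1) abort("cdf_cutoff must be in (0, 1)")
  if (is.null(ic_index)) {
    n_ic <- nrow(ics$S)
    cands <- list()
    for (i in seq_len(n_ic)) {
      for (flip in c(FALSE, TRUE)) {
        trial <- ics
        if (flip) trial$S[i, ] <- -trial$S[i, ]
        cand <- tryCatch(
          define_sector(trial, i, cdf_cutoff, rule, refine_gaps, gap_factor),
          error = function(e) NULL
        )
        if (!is.null(cand)) cand$flipped <- flip
        cands[[length(cands) + 1]] <- cand
      }
    }
    ok <- !vapply(cands, is.null, logical(1))
    if (!any(ok)) abort("no component admits a sector fit")
    sizes <- vapply(cands, function(s) {
      if (is.null(s)) -1L else length(s$members)
    }, integer(1))
    if (!is.null(mat)) {
      scores <- vapply(cands, function(s) {
        if (is.null(s)) -Inf else coupling_capture(s$members, mat)
      }, numeric(1))
      best <- cands[[which.max(scores)]]
      best$score <- max(scores)
    } else {
      snapped <- vapply(cands, function(s) {
        !is.null(s) && isTRUE(s$snapped)
      }, logical(1))
      pool <- if (any(snapped)) which(snapped) else which(ok)
      best <- cands[[pool[which.max(sizes[pool])]]]
    }
    best$candidate_sizes <- pmax(sizes, 0L)
    return(best)
  }
  x <- ics$S[ic_index, ]
  if (stats::sd(x) < 1e-12) abort("degenerate (constant) independent component")
  if (rule == "cdf") {
    est <- fit_t_location_scale(x)
    threshold <- est["m"] + est["s"] * qt(cdf_cutoff, df = est["df"])
  } else {
    est <- c(m = NA_real_, s = NA_real_, df = NA_real_)
    threshold <- stats::quantile(x, probs = cdf_cutoff, names = FALSE)
  }
  snapped <- FALSE
  if (refine_gaps) {
    refined <- snap_to_gap(x, threshold, gap_factor)
    snapped <- !identical(refined, threshold)
    threshold <- refined
  }
  member <- x > threshold
  weights <- tibble(
    position = ics$positions, weight = x, member = member
  )
  structure(
    list(
      members = ics$positions[member], weights = weights,
      ic_index = ic_index, fit = est, threshold = unname(threshold),
      cdf_cutoff = cdf_cutoff, rule = rule, snapped = snapped
    ),
    class = "sector_result"
  )
}

## total coupling captured by a position set: sum over internal pairs
## of the coupling excess above the matrix-wide 75th percentile, so
## uncoupled pairs (conserved-but-independent positions) count against
## a candidate and mutually coevolving groups score highest
coupling_capture <- function(members, mat) {
  idx <- match(members, mat$positions)
  idx <- idx[!is.na(idx)]
  if (length(idx) < 2) {
    return(-Inf)
  }
  off <- mat$C[upper.tri(mat$C)]
  base <- stats::quantile(off, 0.75, names = FALSE)
  sub <- mat$C[idx, idx]
  sum(sub[upper.tri(sub)] - base)
}

## move a provisional cutoff into the lowest implausibly-wide gap of
## the sorted weights at or above it; returns the cutoff unchanged when
## no such gap exists (continuous weight distributions). A gap
## qualifies either absolutely (wider than gap_factor MADs) or by
## dominance: it is the widest gap in the upper half of the weights and
## at least `dominance` times the median upper-half gap, i.e. a
## detached cluster boundary rather than ordinary tail spacing.
snap_to_gap <- function(x, threshold, gap_factor, dominance = 5) {
  xs <- sort(x)
  widths <- diff(xs)
  scale <- max(mad(x), 1e-12)
  upper <- which(xs[-1] > median(x))
  qualifies <- widths > gap_factor * scale
  if (length(upper) > 2) {
    med_gap <- median(widths[upper])
    widest <- upper[which.max(widths[upper])]
    if (widths[widest] > dominance * max(med_gap, 1e-12)) {
      qualifies[widest] <- TRUE
    }
  }
  ## gaps whose upper edge clears the provisional cutoff
  big <- which(qualifies & xs[-1] > threshold)
  if (!length(big)) {
    return(threshold)
  }
  g <- big[1]
  (xs[g] + xs[g + 1]) / 2
}

## maximum-likelihood location-scale Student-t fit. The weights are
## standardised by median/MAD first (IC weight scales can be tiny, which
## defeats box-constrained optimisers), fitted with MASS::fitdistr, and
## back-transformed; a Nelder-Mead fit on (m, log s, log df) is the
## fallback, and robust moments the last resort.
fit_t_location_scale <- function(x) {
  ctr <- median(x)
  scl <- max(mad(x), 1e-12)
  z <- (x - ctr) / scl
  back <- function(est) {
    c(m = ctr + scl * unname(est[1]), s = scl * unname(est[2]),
      df = unname(est[3]))
  }
  fit <- tryCatch(
    suppressWarnings(MASS::fitdistr(z, "t",
      start = list(m = 0, s = 1, df = 3), lower = c(-Inf, 1e-8, 0.1)
    )),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    return(back(fit$estimate))
  }
  nll <- function(p) {
    -sum(dt((z - p[1]) / exp(p[2]), df = exp(p[3]), log = TRUE) - p[2])
  }
  opt <- tryCatch(
    suppressWarnings(stats::optim(c(0, 0, log(3)), nll,
      method = "Nelder-Mead", control = list(maxit = 2000)
    )),
    error = function(e) NULL
  )
  if (!is.null(opt) && is.finite(opt$value)) {
    return(back(c(opt$par[1], exp(opt$par[2]), exp(opt$par[3]))))
  }
  warn("Student-t ML fit failed; using robust location/scale with df = 3")
  c(m = ctr, s = scl, df = 3)
}

#' @export
print.sector_result <- function(x, ...) {
  cat(sprintf(
    "<sector_result> %d members of %d positions (IC %d, cutoff %.2f, rule %s)\n",
    length(x$members), nrow(x$weights), x$ic_index, x$cdf_cutoff, x$rule
  ))
  invisible(x)
}

#' Identify the protein sector from the significant eigenmodes
#'
#' Automates the expert step of the sector workflow: the independent-
#' component rotation has arbitrary component order and sign, converges
#' to different local optima from different initialisations, and the
#' published procedure chooses the component and cutoff that produce a
#' coherent sector. This wrapper runs [ica_rotate()] from `n_restarts`
#' seeded initialisations, applies [define_sector()] to every solution,
#' and returns the best candidate: the largest member set whose cutoff
#' snapped to a detached weight cluster, falling back to the largest
#' member set overall if no restart produces a detached cluster.
#'
#' @param modes a [significant_modes()] result.
#' @param mat the [weighted_correlation_matrix()] result the modes came
#'   from; enables coupling-capture scoring of candidates (recommended).
#' @param cdf_cutoff sector tail cutoff (default 0.85).
#' @param seed integer seed; restart seeds are derived from it.
#' @param n_restarts number of ICA initialisations (default 25).
#' @param ... further arguments passed to [define_sector()].
#' @return A `sector_result`; the winning rotation is attached as
#'   `$ica` and the restart index as `$restart`.
#' @export
identify_sector <- function(modes, mat = NULL, cdf_cutoff = 0.85, seed = 1,
                            n_restarts = 25, ...) {
  best <- NULL
  best_key <- c(-Inf, -1, -1) # (coupling score, snapped, size)
  for (r in seq_len(n_restarts)) {
    ics <- tryCatch(
      ica_rotate(modes, seed = sub_seed(seed, r)),
      error = function(e) NULL
    )
    if (is.null(ics)) next
    cand <- tryCatch(
      define_sector(ics,
        ic_index = NULL, cdf_cutoff = cdf_cutoff,
        mat = mat, ...
      ),
      error = function(e) NULL
    )
    if (is.null(cand)) next
    key <- c(
      if (is.null(mat)) 0 else cand$score,
      as.numeric(isTRUE(cand$snapped)), length(cand$members)
    )
    better <- !is.null(best) &&
      (key[1] > best_key[1] ||
        (key[1] == best_key[1] && key[2] > best_key[2]) ||
        (key[1] == best_key[1] && key[2] == best_key[2] &&
          key[3] > best_key[3]))
    if (is.null(best) || better) {
      best <- cand
      best$ica <- ics
      best$restart <- r
      best_key <- key
    }
  }
  if (is.null(best)) abort("no ICA restart admits a sector fit")
  best
}

#' Structural contiguity of a sector
#'
#' Builds a contact graph on the sector members of a reference
#' structure - an edge whenever any inter-residue heavy-atom distance is
#' below `contact_cutoff` - and returns its connected components. A
#' sector that forms one component is a physically contiguous network.
#'
#' @param sector a [define_sector()] result.
#' @param ref a `reference_structure` (angstrom coordinates) containing
#'   all member positions.
#' @param contact_cutoff heavy-atom contact distance in angstroms
#'   (default 4.5).
#' @return List with `n_components`, `components` (tibble: position,
#'   component) and the member contact graph as an igraph object.
#' @export
check_contiguity <- function(sector, ref, contact_cutoff = 4.5) {
  members <- sector$members
  have <- members %in% ref$resno
  if (!all(have)) {
    abort(sprintf(
      "reference structure lacks member position(s) %s",
      paste(members[!have], collapse = ", ")
    ))
  }
  coords <- lapply(members, function(p) {
    as.matrix(ref[ref$resno == p, c("x", "y", "z")])
  })
  n <- length(members)
  edges <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d2 <- outer(
        rowSums(coords[[i]]^2), rowSums(coords[[j]]^2), `+`
      ) - 2 * coords[[i]] %*% t(coords[[j]])
      if (min(d2) < contact_cutoff^2) {
        edges <- rbind(edges, c(i, j))
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  list(
    n_components = comp$no,
    components = tibble(position = members, component = comp$membership),
    graph = g
  )
}

#' Overlay allelic polymorphisms on a sector
#'
#' Compares two ungapped heavy-chain sequences position by position and
#' intersects the differing positions with the sector membership -
#' identifying which polymorphisms fall inside the coevolving network.
#'
#' @param seq_a,seq_b character vectors (or single strings) of equal
#'   ungapped length, in reference numbering.
#' @param sector a [define_sector()] result.
#' @return List with `differing` (positions), `in_sector` (positions),
#'   `n_differing`, `n_in_sector`.
#' @export
polymorphism_overlay <- function(seq_a, seq_b, sector) {
  if (length(seq_a) == 1) seq_a <- strsplit(seq_a, "")[[1]]
  if (length(seq_b) == 1) seq_b <- strsplit(seq_b, "")[[1]]
  if (length(seq_a) != length(seq_b)) {
    abort(sprintf(
      "sequence lengths differ: %d vs %d", length(seq_a), length(seq_b)
    ))
  }
  differing <- which(seq_a != seq_b)
  in_sector <- intersect(differing, sector$members)
  list(
    differing = differing, in_sector = in_sector,
    n_differing = length(differing), n_in_sector = length(in_sector)
  )
}
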