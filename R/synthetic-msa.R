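#' Recipe for a synthetic alignment with a planted coevolving sector
#'
#' Describes an alignment in which most columns are drawn i.i.d. from a
#' background amino-acid composition, designated columns are strongly
#' conserved, and one planted group of positions coevolves through a
#' shared latent binary state: with probability `sector_coupling` a
#' sequence adopts the designated joint sector state at every sector
#' position, otherwise those positions revert to background. This shared
#' latent state is the simplest mechanism that guarantees a rank-one
#' dominant coupling mode, matching the detection assumption of
#' statistical coupling analysis. Optional `secondary_groups` plant
#' additional, weaker coupled groups (pseudo-sectors).
#'
#' @param n_seqs number of sequences (the first is the gap-free query).
#' @param n_positions alignment length (the query is gap-free, so
#'   columns equal reference positions).
#' @param background named 20-vector of amino-acid probabilities summing
#'   to 1 (tolerance 1e-12); defaults to [aa_background()].
#' @param conserved data frame with columns `position`, `symbol`, `prob`:
#'   each such column draws `symbol` with probability `prob`, otherwise
#'   background.
#' @param sector_positions ordered positions of the planted sector.
#' @param sector_coupling probability in `[0, 1]` of the correlated joint
#'   state.
#' @param sector_symbols designated symbol per sector position (recycled;
#'   default `"W"`, a rare background residue, so the coupled state is
#'   well separated from background draws).
#' @param secondary_groups optional list of `list(positions=, coupling=,
#'   symbols=)` for additional planted groups; all position sets must be
#'   disjoint.
#' @param query_id label given to the first (query) sequence.
#' @param seed integer seed.
#' @return An object of class `msa_recipe`.
#' @export
msa_recipe <- function(n_seqs, n_positions, background = aa_background(),
                       conserved = NULL, sector_positions = integer(0),
                       sector_coupling = 0, sector_symbols = "W",
                       secondary_groups = list(), query_id = "query",
                       seed = 1) {
  if (abs(sum(background) - 1) > 1e-12) {
    abort("background frequencies must sum to 1 (tolerance 1e-12)")
  }
  if (sector_coupling < 0 || sector_coupling > 1) {
    abort("sector_coupling must lie in [0, 1]")
  }
  conserved <- if (is.null(conserved)) {
    tibble(position = integer(0), symbol = character(0), prob = numeric(0))
  } else {
    as_tibble(conserved)
  }
  groups <- c(
    if (length(sector_positions)) {
      list(list(
        positions = as.integer(sector_positions),
        coupling = sector_coupling,
        symbols = rep_len(sector_symbols, length(sector_positions))
      ))
    },
    secondary_groups
  )
  all_pos <- c(conserved$position, unlist(lapply(groups, `[[`, "positions")))
  if (anyDuplicated(all_pos)) {
    abort("conserved and coupled position sets must be disjoint")
  }
  if (length(all_pos) && max(all_pos) > n_positions) {
    abort(sprintf(
      "designated position %d exceeds alignment length %d",
      max(all_pos), n_positions
    ))
  }
  structure(
    list(
      n_seqs = n_seqs, n_positions = n_positions, background = background,
      conserved = conserved, groups = groups, query_id = query_id,
      seed = seed
    ),
    class = "msa_recipe"
  )
}

#' Generate a synthetic alignment from a recipe
#'
#' @param recipe an [msa_recipe()].
#' @return An [alignment_matrix()] whose first sequence is the gap-free
#'   query, carrying the dominant conserved symbols and the correlated
#'   sector state (as the real query carries its own sector residues).
#'   Deterministic for a fixed recipe.
#' @export
generate_msa <- function(recipe) {
  stopifnot(inherits(recipe, "msa_recipe"))
  aa <- aa_alphabet()
  M <- recipe$n_seqs
  L <- recipe$n_positions
  with_seed(recipe$seed, {
    mat <- matrix(sample(aa, M * L, replace = TRUE, prob = recipe$background),
      M, L
    )
    if (nrow(recipe$conserved)) {
      for (r in seq_len(nrow(recipe$conserved))) {
        j <- recipe$conserved$position[r]
        hit <- runif(M) < recipe$conserved$prob[r]
        mat[hit, j] <- recipe$conserved$symbol[r]
      }
    }
    for (g in recipe$groups) {
      correlated <- runif(M) < g$coupling
      for (k in seq_along(g$positions)) {
        mat[correlated, g$positions[k]] <- g$symbols[k]
      }
    }
    ## query: dominant conserved symbols and the correlated joint state
    if (nrow(recipe$conserved)) {
      mat[1, recipe$conserved$position] <- recipe$conserved$symbol
    }
    for (g in recipe$groups) mat[1, g$positions] <- g$symbols
    ids <- c(recipe$query_id, sprintf("seq_%03d", seq_len(M - 1) + 1))
    alignment_matrix(mat, ids = ids, query_id = recipe$query_id)
  })
}

#' Synthetic stand-in for the MHC I heavy-chain alignment
#'
#' The alignment actually used for the published sector analysis (141
#' heavy-chain sequences, query ungapped length 274) is a supplementary
#' file that is not redistributed here. This recipe generates a
#' clearly-synthetic stand-in with the same dimensions: 141 sequences
#' over 274 gap-free query positions, 50 strongly conserved background
#' positions, a planted 85-position sector (31% of positions) that
#' includes the sector residues named in the source analysis (22, 71,
#' 96, 129, 150, 177-179, 191, 220, 224, 264), and two weaker planted
#' pseudo-groups emulating discarded pseudo-sectors. It reproduces the
#' statistical structure the sector pipeline assumes, not the real
#' evolutionary record.
#'
#' @param seed integer seed.
#' @param sector_coupling coupling probability of the planted sector.
#' @return An [msa_recipe()]; the planted sector is in the
#'   `"planted_sector"` attribute.
#' @export
synthetic_mhc_recipe <- function(seed = 101, sector_coupling = 0.8) {
  sector <- synthetic_mhc_sector()
  poly <- synthetic_mhc_polymorphic()
  free <- setdiff(seq_len(274), c(sector, poly))
  ## 120 conserved positions spread over the non-sector remainder, with
  ## heterogeneous conservation strengths: class I heavy chains are
  ## highly conserved outside the binding groove, and real conservation
  ## varies continuously from position to position rather than sitting
  ## at one common level
  cons_pos <- free[seq(1, length(free), length.out = 120)]
  cons_sym <- rep(c("G", "P", "C", "L", "D"), length.out = 120)
  cons_prob <- seq(0.55, 0.97, length.out = 120)
  spread <- function(pool, n) pool[round(seq(2, length(pool) - 1, length.out = n))]
  rest <- setdiff(free, cons_pos)
  group2 <- list(
    positions = spread(rest, 8),
    coupling = 0.5, symbols = rep("H", 8)
  )
  group3 <- list(
    positions = spread(setdiff(rest, group2$positions), 6),
    coupling = 0.45, symbols = rep("M", 6)
  )
  rec <- msa_recipe(
    n_seqs = 141, n_positions = 274,
    conserved = tibble(position = cons_pos, symbol = cons_sym, prob = cons_prob),
    sector_positions = sector, sector_coupling = sector_coupling,
    sector_symbols = "W",
    secondary_groups = list(group2, group3),
    query_id = "query_heavy_chain", seed = seed
  )
  attr(rec, "planted_sector") <- sector
  rec
}

#' @rdname synthetic_mhc_recipe
#' @details `synthetic_mhc_sector()` returns the frozen 85-position
#'   planted sector; `synthetic_mhc_polymorphic()` the 8 positions at
#'   which the two synthetic alleles differ (2 of which, 22 and 220, are
#'   sector members).
#' @export
synthetic_mhc_sector <- function() {
  c(
    5:8, 22:30, 45:52, 57:63, 71, 74, 77, 80, 84, 88, 92, 96,
    99:104, 113:118, 129, 132, 135, 138, 142, 146, 150, 154, 158,
    161:165, 171, 174, 177:179, 185, 188, 191, 195, 202, 206, 210,
    214, 217, 220, 224, 228, 235, 241, 247, 253, 259, 264
  )
}

#' @rdname synthetic_mhc_recipe
#' @export
synthetic_mhc_polymorphic <- function() {
  c(11L, 22L, 35L, 66L, 79L, 110L, 126L, 220L)
}

#' Synthetic allele pair for the polymorphism overlay
#'
#' Returns two ungapped heavy-chain sequences: the query of `aln` and a
#' second synthetic allele differing from it at exactly the 8 positions
#' of [synthetic_mhc_polymorphic()] (each substituted to the next
#' amino-acid in alphabet order). A labelled stand-in for the two real
#' alleles, whose sequences are not redistributed here.
#'
#' @param aln alignment generated from [synthetic_mhc_recipe()].
#' @return Named list with character-vector sequences `allele_a` and
#'   `allele_b`.
#' @export
synthetic_allele_pair <- function(aln) {
  a <- query_sequence(aln)
  b <- a
  aa <- aa_alphabet()
  for (p in synthetic_mhc_polymorphic()) {
    b[p] <- aa[(match(a[p], aa) %% 20) + 1]
  }
  list(allele_a = a, allele_b = b)
}

#' Synthetic folded reference structure
#'
#' Places one CA pseudo-atom per residue along a compact serpentine path
#' through a 3-D lattice with 3.8-angstrom spacing, giving a globular
#' synthetic fold with realistic short- and long-range contact density
#' for contiguity checks. It is a geometric stand-in, not a model of any
#' real structure.
#'
#' @param n_res number of residues.
#' @param spacing lattice spacing (angstrom).
#' @return A `reference_structure` (coordinates in angstroms).
#' @export
synthetic_reference_structure <- function(n_res = 274, spacing = 3.8) {
  side <- ceiling(n_res^(1 / 3))
  coords <- matrix(NA_real_, n_res, 3)
  i <- 0
  for (z in seq_len(side)) {
    ys <- if (z %% 2 == 1) seq_len(side) else rev(seq_len(side))
    for (y in ys) {
      xs <- if ((y + z) %% 2 == 0) seq_len(side) else rev(seq_len(side))
      for (x in xs) {
        i <- i + 1
        if (i > n_res) break
        coords[i, ] <- c(x, y, z) * spacing
      }
      if (i > n_res) break
    }
    if (i > n_res) break
  }
  reference_structure(tibble(
    resno = seq_len(n_res), resid = "ALA", elety = "CA",
    x = coords[, 1], y = coords[, 2], z = coords[, 3]
  ))
}
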