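test_that("positional conservation matches closed-form relative entropy", {
  q <- rep(0.05, 20)
  names(q) <- aa_alphabet()
  ## fully conserved alanine column under a flat background: D = ln(20)
  aln <- alignment_matrix(
    matrix(c(rep("A", 40), sample(aa_alphabet(), 40, TRUE)), 40, 2),
    query_id = NULL
  )
  cons <- position_conservation(aln, background = q)
  expect_equal(cons$D[1], log(20), tolerance = 1e-12)
  expect_equal(cons$D[1], log(1 / q["A"]), ignore_attr = TRUE)

  ## frequencies exactly at background: D = 0
  bal <- alignment_matrix(matrix(rep(aa_alphabet(), 2), 40, 1))
  cons2 <- position_conservation(bal, background = q)
  expect_equal(cons2$D[1], 0, tolerance = 1e-12)

  ## D > 0 whenever frequencies differ from background
  skew <- alignment_matrix(matrix(c(rep("W", 30), rep("Y", 10)), 40, 1))
  expect_gt(position_conservation(skew, background = q)$D[1], 0)

  ## all-gap mapped position: missing with a warning
  gappy <- alignment_matrix(rbind(c("A", "C"), c("A", "-"), c("A", "-")))
  gappy$seqs[, 2] <- "-"
  gappy$column_map <- c(1L, 2L) # force mapping to exercise the branch
  expect_warning(cg <- position_conservation(gappy), "all-gap")
  expect_true(is.na(cg$D[2]))
})

test_that("coupling matrix is symmetric, non-negative, and both evaluation paths agree", {
  aln <- generate_msa(msa_recipe(
    n_seqs = 60, n_positions = 12,
    sector_positions = c(3, 8), sector_coupling = 0.9, seed = 2
  ))
  mat <- weighted_correlation_matrix(aln)
  C <- mat$C
  expect_equal(C, t(C))
  expect_true(all(C >= 0))

  code <- sectordyn:::code_alignment(aln)
  f <- mat$f
  w <- mat$weights
  expect_equal(
    sectordyn:::sca_matrix_gram(code, f, w),
    sectordyn:::sca_matrix_symbol(code, f, w),
    tolerance = 1e-10, ignore_attr = TRUE
  )
})

test_that("perfectly copied columns dominate their rows of the coupling matrix", {
  set.seed(3)
  base <- matrix(sample(aa_alphabet(), 80 * 10, TRUE), 80, 10)
  base[, 7] <- base[, 2] # column 7 copies column 2
  aln <- alignment_matrix(base)
  C <- weighted_correlation_matrix(aln)$C
  off <- C
  diag(off) <- 0
  expect_equal(unname(which.max(off[2, ])), 7)
  expect_equal(unname(which.max(off[7, ])), 2)
})

test_that("independent columns give near-zero coupling relative to the shuffle null", {
  aln <- generate_msa(msa_recipe(n_seqs = 1000, n_positions = 12, seed = 9))
  mat <- weighted_correlation_matrix(aln)
  off <- mat$C
  diag(off) <- NA
  ## null scale: same statistic on a column-shuffled copy of the alignment
  code <- sectordyn:::code_alignment(aln)
  set.seed(10)
  nulls <- replicate(5, {
    perm <- apply(code, 2, sample)
    Cn <- sectordyn:::sca_matrix_compute(perm, mat$f, mat$weights)
    diag(Cn) <- NA
    Cn
  })
  expect_lt(max(off, na.rm = TRUE), 3 * max(abs(nulls), na.rm = TRUE))
})

test_that("mode significance is driven by planted coupling, not conservation", {
  ## degenerate alignment equal to its own column shuffle: one repeated
  ## sequence has zero sampling variance, no non-trivial retained modes
  rep_aln <- alignment_matrix(matrix(rep(c("A", "C", "D", "E"), each = 30), 30, 4))
  mat0 <- weighted_correlation_matrix(rep_aln)
  sm0 <- significant_modes(mat0, n_randomizations = 5, seed = 1)
  expect_length(setdiff(sm0$retained, 1L), 0)

  ## independent columns: column-shuffle null self-consistency
  ind <- generate_msa(msa_recipe(n_seqs = 300, n_positions = 30, seed = 13))
  smi <- significant_modes(
    weighted_correlation_matrix(ind),
    n_randomizations = 20, seed = 5
  )
  expect_length(setdiff(smi$retained, 1L), 0)

  ## planted group: at least one retained mode loading on the planted set
  aln <- generate_msa(planted_recipe(seed = 11))
  mat <- weighted_correlation_matrix(aln)
  sm <- significant_modes(mat, n_randomizations = 20, seed = 5)
  expect_gte(sm$n_retained, 1)
  lead <- sm$vectors[, sm$retained[1]]
  top10 <- sm$positions[order(abs(lead), decreasing = TRUE)[1:10]]
  expect_setequal(top10, planted_positions())

  ## determinism under fixed seed
  sm2 <- significant_modes(mat, n_randomizations = 20, seed = 5)
  expect_identical(sm$null_values, sm2$null_values)
  expect_error(significant_modes(mat, n_randomizations = 0), "one randomization")
})

test_that("ICA preserves the retained subspace and separates planted groups", {
  groups <- list(
    a = seq(5, 50, 5), # 10 positions
    b = c(53, 58, 63, 68, 73, 78, 83, 88) # 8 positions
  )
  rec <- msa_recipe(
    n_seqs = 500, n_positions = 90,
    sector_positions = groups$a, sector_coupling = 0.9,
    sector_symbols = "W",
    secondary_groups = list(list(
      positions = groups$b, coupling = 0.85, symbols = rep("H", 8)
    )),
    seed = 21
  )
  mat <- weighted_correlation_matrix(generate_msa(rec))
  sm <- significant_modes(mat, n_randomizations = 15, seed = 2)
  expect_gte(sm$n_retained, 2)
  ics <- ica_rotate(sm, n_components = 2, seed = 2)

  ## rotation stays inside span(retained modes + intercept)
  V <- sm$vectors[, sm$retained, drop = FALSE]
  basis <- cbind(1, V)
  for (i in 1:2) {
    s <- ics$S[i, ]
    resid <- s - basis %*% qr.solve(basis, s)
    expect_lt(max(abs(resid)), 1e-6)
  }

  ## each IC loads on one group; cross-loading < 10% of main loading
  load <- function(s, pos) max(abs(s[match(pos, ics$positions)]))
  main_ic <- which.max(c(load(ics$S[1, ], groups$a), load(ics$S[2, ], groups$a)))
  other_ic <- 3 - main_ic
  expect_lt(
    load(ics$S[main_ic, ], groups$b), 0.1 * load(ics$S[main_ic, ], groups$a)
  )
  expect_lt(
    load(ics$S[other_ic, ], groups$a), 0.1 * load(ics$S[other_ic, ], groups$b)
  )

  ## deterministic under fixed seed
  ics2 <- ica_rotate(sm, n_components = 2, seed = 2)
  expect_identical(ics$S, ics2$S)
  expect_error(ica_rotate(sm, n_components = 50), "exceeds")
})

test_that("sector definition thresholds the fitted tail exactly on constructed weights", {
  set.seed(42)
  w <- c(rnorm(95, 0, 0.1), rep(10, 5))[order(runif(100))]
  ics <- structure(
    list(
      S = matrix(w, 1), positions = 1:100, kurtosis = 1,
      iterations = 1, retained = 1
    ),
    class = "ica_components"
  )
  sec <- define_sector(ics, 1, 0.85)
  expect_setequal(sec$members, which(w == 10))

  ## monotone shrinkage toward the cutoff -> 1 limit
  sizes <- vapply(
    c(0.5, 0.85, 0.95, 0.999),
    function(ct) length(define_sector(ics, 1, ct)$members), numeric(1)
  )
  expect_true(all(diff(sizes) <= 0))

  flat <- ics
  flat$S[] <- 1
  expect_error(define_sector(flat, 1), "degenerate")
  expect_error(define_sector(ics, 1, cdf_cutoff = 1), "in \\(0, 1\\)")

  ## top-fraction alternative takes exactly the stated count
  tf <- define_sector(ics, 1, 0.85, rule = "top_fraction", refine_gaps = FALSE)
  expect_equal(length(tf$members), 15)
})

test_that("end-to-end planted-sector recovery meets precision and recall 0.9", {
  aln <- generate_msa(planted_recipe(seed = 11, coupling = 0.8))
  mat <- weighted_correlation_matrix(aln)
  sm <- significant_modes(mat, n_randomizations = 20, seed = 3)
  sec <- identify_sector(sm, mat = mat, seed = 3)
  planted <- planted_positions()
  precision <- mean(sec$members %in% planted)
  recall <- mean(planted %in% sec$members)
  expect_gte(precision, 0.9)
  expect_gte(recall, 0.9)
})

test_that("contiguity components follow the contact graph", {
  ## two residues 3 A apart: one component at 4.5 A cutoff
  ref2 <- sectordyn:::reference_structure(tibble::tibble(
    resno = c(22L, 220L), resid = "ALA", elety = "CA",
    x = c(0, 3), y = 0, z = 0
  ))
  sec <- structure(
    list(members = c(22L, 220L), weights = tibble::tibble(
      position = c(22L, 220L), weight = 1, member = TRUE
    )),
    class = "sector_result"
  )
  expect_equal(check_contiguity(sec, ref2, 4.5)$n_components, 1)

  ## far-apart members with no bridge: more than one component
  ref_far <- sectordyn:::reference_structure(tibble::tibble(
    resno = c(22L, 220L), resid = "ALA", elety = "CA",
    x = c(0, 50), y = 0, z = 0
  ))
  expect_equal(check_contiguity(sec, ref_far, 4.5)$n_components, 2)

  ## single-member sector: one component
  one <- structure(list(members = 22L), class = "sector_result")
  expect_equal(check_contiguity(one, ref2, 4.5)$n_components, 1)

  missing <- structure(list(members = c(22L, 99L)), class = "sector_result")
  expect_error(check_contiguity(missing, ref2), "99")
})

test_that("polymorphism overlay counts differences and sector intersections", {
  sec <- structure(list(members = c(22L, 150L, 220L)), class = "sector_result")
  a <- strrep("A", 250)
  expect_equal(polymorphism_overlay(a, a, sec)$n_differing, 0)

  b <- strsplit(a, "")[[1]]
  b[c(22, 77, 220)] <- "W"
  ov <- polymorphism_overlay(a, paste(b, collapse = ""), sec)
  expect_identical(ov$differing, c(22L, 77L, 220L))
  expect_identical(ov$in_sector, c(22L, 220L))
  expect_equal(ov$n_in_sector, 2)

  expect_error(polymorphism_overlay("AAA", "AAAA", sec), "lengths differ")
})
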