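# sectordyn

Protein plasticity — the intrinsic ability of a structure to change shape —
from two complementary directions: molecular-dynamics trajectories and the
evolutionary record of a protein family. The package grew out of the
biology of class I major histocompatibility complex (MHC I) molecules,
whose alleles differ in how readily they explore conformations while
selecting peptides, but every stage is generic structural bioinformatics.

Four analysis stages, each usable on its own:

* **Dihedral flexibility** — per-residue dispersion of the backbone φ
  torsion (about the N–Cα bond) over a trajectory, using the circular
  standard deviation √(−2 ln R̄)·180/π so that residues straddling the
  ±180° wrap are measured correctly; sites above a threshold (default
  25°) are flagged as flexible and compared between states
  (`compute_phi_series()`, `circular_sd()`, `flexible_sites()`,
  `compare_states()`).
* **Essential dynamics** — mass-weighted principal component analysis of
  backbone fluctuations: C = √(mₐm_b)(⟨xₐx_b⟩ − ⟨xₐ⟩⟨x_b⟩), eigenmodes,
  projections p_i(t) = μᵢᵀ(x(t) − ⟨x⟩), reconstruction, cumulative
  variance fractions, mode-extreme structures for porcupine-style export,
  and block-RMSF stability checks (`superpose()`, `build_covariance()`,
  `eigendecompose()`, `project_trajectory()`, `reconstruct()`,
  `mode_extremes()`, `block_rmsf()`).
* **Free-energy landscapes** — the joint density of the top two principal
  coordinates as a Boltzmann ensemble, G = −ln(P/P_max) in kT, with
  masked empty bins, shot-noise-aware minima detection and exact minimax
  barriers via a watershed sweep (`estimate_density()`,
  `to_free_energy()`, `find_minima()`, `marginal_density()`).
* **Statistical coupling analysis (SCA)** — Kullback–Leibler positional
  conservation D_i, a conservation-weighted positional correlation
  matrix, eigenmode significance against column-randomized alignments,
  independent-component rotation, Student-t tail sector definition,
  structural contiguity and polymorphism overlays
  (`position_conservation()`, `weighted_correlation_matrix()`,
  `significant_modes()`, `ica_rotate()`, `define_sector()`,
  `identify_sector()`, `check_contiguity()`, `polymorphism_overlay()`).

Because production trajectories and curated alignments are large external
artifacts, the package ships synthetic-data generators with known ground
truth — trajectories fluctuating along planted orthonormal modes,
wrapped-normal dihedral series, and alignments with a planted coevolving
sector — so every stage is testable end to end
(`generate_trajectory()`, `generate_dihedral_series()`, `generate_msa()`,
`synthetic_mhc_recipe()`). Results are tibbles or carry broom-style
`tidy()`/`glance()` methods and ggplot2 `autoplot()` quick-looks.

## Worked example: recovering a planted sector

The synthetic heavy-chain stand-in plants an 85-position sector (31% of a
274-position chain, including positions 22 and 220) in a 141-sequence
alignment with realistic conservation structure:

```r
library(sectordyn)

aln <- generate_msa(synthetic_mhc_recipe(seed = 101))
aln
#> <alignment_matrix> 141 sequences x 274 columns, query 'query_heavy_chain' (274 mapped positions)

mat    <- weighted_correlation_matrix(aln)
modes  <- significant_modes(mat, n_randomizations = 100, seed = 7)
glance(modes)
#> # A tibble: 1 x 3
#>   n_retained null_max n_null
#> 1          4     10.2  27300

sector <- identify_sector(modes, mat = mat, cdf_cutoff = 0.85, seed = 7)
sector
#> <sector_result> 85 members of 274 positions (IC 4, cutoff 0.85, rule cdf)

pair <- synthetic_allele_pair(aln)
polymorphism_overlay(pair$allele_a, pair$allele_b, sector)[c("n_differing", "in_sector")]
#> $n_differing
#> [1] 8
#> $in_sector
#> [1]  22 220
```

Four eigenmodes of the coupling matrix exceed everything produced by 100
column-shuffled alignments; rotating that subspace and thresholding the
fitted Student-t tail at 85% cumulative density recovers the planted
sector exactly — 85 members, 31% of positions — and the allele overlay
finds 2 of the 8 polymorphic positions inside it (22 and 220).

The circular statistic behind the flexibility stage, on a wrapped-normal
series with a planted 25° spread:

```r
phi <- generate_dihedral_series(1e5, mean_deg = 0, circ_sd_deg = 25, seed = 1)
circular_sd(phi)
#> [1] 25.09
circular_sd(rep(c(179, -179), 50))   # naive linear SD would report 179.9
#> [1] 1
```

`run_pipeline(pipeline_config(...))` chains the stages (simulate → flex →
pca → landscape → sca → report) with seeded determinism and provenance
headers on every output table; `inst/scripts/run_pipeline.R` is a thin
command-line wrapper.

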