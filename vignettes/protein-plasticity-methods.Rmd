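---
title: "Quantifying protein plasticity: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein plasticity: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sectordyn)
```

sectordyn quantifies the plasticity of a protein — its intrinsic ability to
change shape — from two independent directions: molecular-dynamics
trajectories of the structure, and the evolutionary record in a multiple
sequence alignment of its family. The motivating system is the class I major
histocompatibility complex (MHC I) heavy chain, where plasticity differences
between alleles are thought to underlie differences in peptide selection and
in dependence on the co-factor tapasin, but every stage is generic. This
vignette describes each model, its assumptions, the tunable parameters, and
the design decisions taken where the methods literature leaves choices open.

## Local flexibility from backbone dihedrals

The per-residue flexibility statistic is the dispersion of the backbone
torsion angle phi (rotation about the N–CA bond, defined by atoms C(i−1),
N(i), CA(i), C(i), IUPAC sign convention) over the frames of a trajectory.
A residue whose phi wanders is locally plastic; one whose phi is pinned is
rigid. The first residue of a chain has no phi and is reported missing, as
is any residue lacking one of the four defining atoms.

Angles live on a circle, so the default dispersion is the **circular
standard deviation** \(\sqrt{-2\ln\bar R}\cdot 180/\pi\), with \(\bar R\)
the mean resultant length of the angles as unit vectors. A naive linear SD
is wrong exactly where it matters: a residue flipping between +179° and
−179° is nearly rigid (circular SD ≈ 1°) but a linear SD reports ≈ 179°,
and highly flexible residues are the ones that visit the wrap. The linear
statistic is available (`method = "linear"` in `flexible_sites()`) for
comparison; on any series confined to a narrow arc away from the wrap the
two agree to within 1%.

A site counts as *flexible* when its dispersion strictly exceeds a
threshold, 25° by default — a value that separates the pinned bulk of a
folded backbone from loop and hinge residues. Glycines are included in all
statistics but flagged, since their missing side chain gives them
intrinsically wider backbone freedom and they are conventionally displayed
separately. `compare_states()` aligns two reports (e.g. peptide-bound vs
peptide-free) by residue and reports the dispersion change and the two
flexible-site counts; the flexible-site count is monotone non-increasing in
the threshold.

Replicate simulations are concatenated after `discard_equilibration()`
removes the initial relaxation of each replica; dispersions are computed on
the concatenated post-equilibration ensemble, not averaged per replica.

## Essential dynamics

Global, collective motions are extracted by principal component analysis of
the backbone fluctuations. The pipeline is:

1. `superpose()` — remove rigid-body motion by mass-weighted least-squares
   (Kabsch) fitting of every frame. By default frames are fitted to the
   ensemble mean, the mean is recomputed, and the fit repeated once more;
   without this, overall rotation dominates the first mode. A fixed
   reference frame can be supplied instead, which is how bound and free
   ensembles are made comparable: both are fitted to one common structure
   over the shared atom subset.
2. `build_covariance()` — the mass-weighted covariance
   \(C_{ab} = \sqrt{m_a m_b}(\langle x_a x_b\rangle - \langle x_a\rangle
   \langle x_b\rangle)\) over frames (ensemble average, denominator T).
   Mass weighting enters as \(\sqrt{m_a m_b}\) and is inverted on
   reconstruction, so unit masses reduce every formula to the unweighted
   case (this reduction is tested).
3. `eigendecompose()` — symmetric eigendecomposition \(C = PDP^T\), modes
   sorted by descending eigenvalue. Each eigenvector's sign is fixed so its
   largest-magnitude component is positive, making exported mode vectors
   reproducible; exact eigenvalue ties are ordered by first-differing
   component and flagged.
4. `project_trajectory()` / `reconstruct()` — the principal components as
   functions of time, \(p_i(t) = \mu_i^T(x(t) - \langle x\rangle)\) in
   mass-weighted coordinates, and the inverse map. The variance of
   \(p_i\) equals the eigenvalue \(\lambda_i\); reconstruction with all 3N
   modes is the identity to 10⁻⁶ nm. `mode_extremes()` exports the
   conformations at the minimum and maximum observed projection along a
   mode together with per-atom displacement vectors — the data behind
   porcupine-style renderings — in both raw (mass-weighted) and Cartesian
   form, since conventions differ on whether mass weighting is inverted
   before display.

`cumulative_variance()` reports the fraction of total fluctuation captured
by the leading modes — the headline plasticity number for comparing states.
`block_rmsf()` splits a trajectory into consecutive time blocks and
computes per-atom root-mean-square fluctuations per block; a stationary,
stable simulation shows consistent profiles across blocks.

## Free-energy landscapes

The joint distribution of the top two principal coordinates is turned into
a Gibbs free-energy surface by treating the ensemble as a Boltzmann
ensemble: bins of a 2-D histogram get \(G_b = -\ln(P_b/P_{max})\) in kT
units, so the most populated bin sits at zero. The default grid is 64×64
bins spanning the data range plus a 5% margin. Defaults of note:

* **Empty bins are masked**, never given a pseudo-count: they are
  unexplored, not infinitely high, and barrier paths may not cross them.
  No kernel smoothing is applied by default, because smoothing changes
  minima counts; the reported landscape is the raw estimator.
* **Minima** (`find_minima()`) are occupied bins strictly below all
  occupied neighbours, merged within a 2-bin radius, then filtered twice
  against shot noise: a minimum must rest on at least 16 counts (the free
  energy of an n-count bin is uncertain by roughly \(1/\sqrt{n}\) kT, so 16
  counts bound the noise by a quarter of the depth criterion), and it must
  be at least 1 kT deep — the thermal fluctuation scale, below which a dip
  is not a distinct conformational state. Occupied specks disconnected
  from any substantial basin (under 1% of occupied bins) are discarded as
  unsampled.
* **Barriers** between minima are exact minimax path levels on the
  occupied-bin graph, computed by a union-find sweep over bins in order of
  increasing G (the level at which two basins first merge); they are
  symmetric and non-negative, and `NA` between basins the sampling never
  connected. The implementation is verified against a brute-force
  level-connectivity search in the tests.

Energies are reported in kT at the simulation's reference temperature
(default 300 K), with kJ/mol available as an output option.

## Statistical coupling analysis and the protein sector

The sequence-side analysis asks which alignment positions coevolve — the
statistical signature of a physically connected, functionally coupled
network of residues (a *protein sector*).

**Conservation.** Per mapped position, `position_conservation()` computes
the Kullback–Leibler relative entropy \(D_i = \sum_a f_i^a \ln(f_i^a/q^a)\)
over the 20 amino acids, gaps excluded. The background \(q^a\) defaults to
a standard database composition (`aa_background()`) and is swappable.
Ambiguity codes (B, Z, X) are normalised to gaps on reading so the
frequency model stays 20-state.

**Coupling matrix.** `weighted_correlation_matrix()` computes, for each
position pair, the Frobenius norm over amino-acid pairs of the
conservation-weighted covariance of occurrence indicators,
\(\tilde C_{ij} = \|w_i^a w_j^b (f_{ij}^{ab} - f_i^a f_j^b)\|_F\), with
weights given by the derivative of the binary relative entropy at the
observed frequency. Frequencies are regularised by mixing a fraction
λ = 0.03 toward the background so the weight stays finite at f ∈ {0, 1}.
No sequence-identity down-weighting is applied by default. Two
mathematically identical evaluation paths (symbol space vs per-position
indicator Gram matrices) are cross-checked in the tests and chosen
automatically by predicted working-set size.

**Mode significance.** `significant_modes()` compares the eigenvalues of
\(\tilde C\) to those of alignments in which every column's symbols are
independently permuted across sequences — preserving each column's
composition (hence conservation and weights) while destroying inter-column
correlation. Retained modes exceed the maximum pooled null eigenvalue.
Because column shuffling preserves conservation, every randomized matrix
has the same trivial, conservation-dominated first mode as the real one;
each randomization therefore contributes all but its own first eigenvalue
to the null pool, and the real first mode is retained when significant.
Both behaviours are flags (`drop_null_first`, `keep_first`).

**Independent components.** `ica_rotate()` rotates the retained eigenmode
subspace by symmetric fixed-point ICA (tolerance 10⁻⁶), treating positions
as observations. The default contrast is the cube (kurtosis) nonlinearity:
a sector spanning a substantial fraction of positions produces a *bimodal*
(sub-Gaussian) weight distribution, and so does the conservation
direction, while small spuriously coupled groups are sharply super-
Gaussian — and the tanh contrast, though offered, provably cannot separate
two sub-Gaussian sources. By default the whole significant subspace is
rotated (one axis per retained mode) so no two coupled structures are
forced to share a component.

**Sector definition.** `define_sector()` fits a location-scale Student-t to
a component's position weights by maximum likelihood and takes members
above the fitted quantile at the cumulative-density cutoff (default 0.85).
Two refinements make this operational on real weight distributions:

* *Cluster-gap refinement.* The fitted 85% quantile of any distribution
  that tracks the bulk necessarily lands in the bulk's upper fringe; a
  genuinely coevolving group, however, sits as a detached cluster beyond a
  gap that is implausibly wide for the bulk (wider than 10 MADs, or the
  dominant gap of the upper half). The cutoff snaps into that gap. This
  mirrors how sector cutoffs are chosen in practice — as the value that
  yields a coherent group — and is disableable (`refine_gaps = FALSE`).
* *Candidate selection.* The component and its orientation (ICA signs are
  arbitrary) are chosen automatically by **coupling capture**: the member
  set maximising the summed coupling excess of its internal pairs above
  the matrix-wide 75th percentile. This is the method's own definition of
  a sector — a mutually coevolving group — and rejects look-alike
  candidates made of strongly conserved but mutually independent
  positions, whose internal pairs score at background.

`identify_sector()` wraps the rotation and definition, running the ICA
from 25 seeded initialisations (the fixed-point iteration has local optima,
and its own objective does not distinguish solutions that isolate the
sector from ones that mix it) and keeping the candidate with the highest
coupling capture. An explicit `ic_index` overrides all of this.

The alternative reading of the cutoff — the top 15% of positions by count —
is available as `rule = "top_fraction"`.

**Structure and polymorphisms.** `check_contiguity()` builds a residue
contact graph on the sector members (any heavy-atom pair under 4.5 Å, the
standard residue-contact convention) and reports connected components; a
real sector forms one contiguous network. `polymorphism_overlay()`
intersects the positions at which two allelic sequences differ with the
sector membership.

## Synthetic data: what it emulates and what it does not

Because production trajectories and curated alignments are large external
artifacts, every stage is exercised against generators whose ground truth
is known.

`generate_trajectory()` draws frames
\(x_t = x_{ref} + \sum_i z_{t,i} s_i \mu_i + \epsilon_t\) with prescribed
orthonormal modes, amplitudes and isotropic noise — exactly the covariance
model essential dynamics assumes, so mode recovery, projection variances
and landscape behaviour have closed-form expectations. It does *not*
emulate force-field physics: no solvent, no anharmonicity, no kinetics.
`backbone_reference()` supplies ideal-geometry N–CA–C chains at chosen
phi/psi, giving dihedral fixtures whose angles are known by construction.
`generate_dihedral_series()` draws wrapped-normal angles, whose circular SD
equals the underlying normal's SD — directly comparable to the estimator.

`generate_msa()` plants a coevolving sector through a shared latent binary
state: with the coupling probability a sequence adopts the designated joint
state at every sector position, otherwise those positions revert to
background. This is the simplest mechanism guaranteeing the rank-one
dominant coupling mode that sector analysis assumes. Conserved columns and
additional weaker coupled groups (pseudo-sectors) can be planted alongside.
There is no phylogeny: sequences are exchangeable, so the generator cannot
emulate the lineage structure that inflates apparent coupling in real
alignments — passing recovery tests demonstrates correctness of the
machinery, not robustness to phylogenetic confounding.

`synthetic_mhc_recipe()` is the package's stand-in for a real heavy-chain
family alignment: 141 sequences over 274 gap-free query positions, a
planted 85-position sector (31% of positions, coupling 0.8) that includes
the positions named in the motivating analyses (22, 71, 96, 129, 150,
177–179, 191, 220, 224, 264), 120 conserved positions with conservation
probabilities varying continuously from 0.55 to 0.97 (a single common
conservation level would create an artificially detached conservation
cluster no real alignment has), and two weaker pseudo-groups (8 positions
at coupling 0.5, 6 at 0.45) emulating discardable pseudo-sectors.
`synthetic_allele_pair()` derives two allele sequences differing at 8
positions, exactly 2 of which (22 and 220) are sector members; the other
six polymorphic positions are an invented, domain-consistent choice.
`synthetic_reference_structure()` places residues along a compact
serpentine lattice path — a globular geometric stand-in for contiguity
checks, not a model of any real fold. All three are labelled synthetic
throughout.

The bound/free trajectory pair simulated by `run_pipeline()` uses mode
amplitudes placing about 35% of total variance in the top two modes for
the bound state and about 45% for the free state (at the default
30-residue backbone and 0.02 nm noise), with the free-state modes carrying
roughly twice the bound-state variance — the plasticity contrast the
package is designed to resolve.

## Problem sizes and numerical tolerances

The shipped tests and the acceptance script run at deliberately modest
sizes — 10⁴-frame trajectories for mode recovery, 10⁵ draws for circular-SD
consistency, 141×274 and 500×100 alignments for sector recovery, 3×10⁴
points for landscape oracles — chosen so the full suite completes in about
a minute while leaving every statistical check comfortable margins
(orthonormality 10⁻⁸; projection-variance identity 10⁻⁸ relative;
reconstruction 10⁻⁶ nm; planted-mode angles under 5° and eigenvalues
within 10%; circular SD within 0.5° of a 25° target at n = 10⁵). Exact
expectations are frozen from independent oracles: a four-atom dihedral
formula, brute-force power iteration for eigenproblems, flood-fill level
connectivity for barriers, and closed-form entropy values.

## Known limitations

* phi only: psi/omega/chi dispersions are out of scope, as is any
  Ramachandran-based model validation.
* Linear PCA: motions spread across several modes, or nonlinear
  collective coordinates, are not resolved.
* Landscapes are 2-D histograms of the top two modes; no reweighting
  (WHAM-style) and no more than two coordinates.
* SCA here has no phylogenetic bias correction; sequence weighting by
  identity clustering is deliberately off by default for reproducibility.
* The sector workflow automates an expert choice (component, orientation,
  cutoff placement); on alignments where the independent-component
  rotation cannot isolate the sector from conservation structure, the
  recovered membership can shed its weakest members (observed as sector
  sizes a few percent below the planted truth on rare generator seeds).
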