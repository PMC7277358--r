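---
title: "Methods: network prioritization and trajectory dynamics of SF3B1 K700E"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network prioritization and trajectory dynamics of SF3B1 K700E}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicedyn)
```

## Scope and model

`splicedyn` implements the analytical layer of a molecular-modelling
study of the SF3B1 K700E hotspot mutation in the SF3b complex of the
spliceosome: which gene and which mutation to study (network
prioritization over splicing factors), and what the mutation does to
the dynamics of the complex (trajectory descriptors, essential
dynamics, cross-correlation structure). Running molecular dynamics
itself is out of scope; the package consumes structures and
trajectories, and ships a synthetic-trajectory module so that every
estimator can be validated against known ground truth at desk scale.

Units are fixed throughout: distances in nanometres, times in
picoseconds, residue numbers in author (PDB) numbering so that ranges
quoted for this system — residue 700 of SF3B1, p14 residues 20–100,
the correlation regions 455–832 and 932–1300 — can be used verbatim.

## Network prioritization

The gene network is an undirected, unweighted graph: nodes are gene
symbols, edges experimental interactions from a STRING-style export.
Evidence scores gate edge inclusion only; distances treat every
retained edge as binary. Per connected component we compute, from
breadth-first distances $d(u,v)$:

* eccentricity $e(u) = \max_v d(u,v)$,
* closeness $c(u) = 1 / \overline{d}(u)$, the reciprocal of the mean
  distance to the other component members (equivalently
  $(n-1)/\sum_v d(u,v)$),
* radiality $r(u) = (\Delta + 1 - \overline{d}(u))/\Delta$, with
  $\Delta$ the component diameter.

The upstream network tools name these metrics but never define them; the
definitions above are therefore stated explicitly and pinned by the
identity $r = (\Delta + 1 - 1/c)/\Delta$, which tests enforce to
1e-12. Isolated nodes get undefined (`NA`) metrics rather than zeros —
a 0 closeness would silently sort real genes below unreachable ones.
The reported SF3B1 triple (closeness 0.58, radiality 0.88,
eccentricity 5) is self-consistent under these conventions with a
component of diameter 6, which is the consistency check the acceptance
suite runs; reproducing the full table would require the original
exported network.

Somatic-mutation records follow the COSMIC export dialect. The filter
keeps records that simultaneously match the histology, are missense
substitutions, carry a `pathogenic` FATHMM class, and have a FATHMM
score strictly greater than 0.9 — a deliberate raise over the
predictor's nominal 0.5 boundary to suppress false positives. Records
with missing scores are dropped. Ranking ties (gene counts, most
frequent amino-acid change) are broken lexicographically so reports
are byte-reproducible under any record or edge order.

One arithmetic caveat is inherited from the source material: the
per-change sample counts for SF3B1 (45 + 21 unknown + five changes in
2 samples each + 44 singletons) sum to 120, not the stated 115, and
45/120 is 37.5%, not "40%". The package reports exact fractions and
makes no attempt to reproduce the rounded headline number.

## Trajectory descriptors

**Superposition.** Rigid-body motion is removed with a weighted Kabsch
fit (SVD of the weighted cross-covariance, determinant-corrected so
reflections are excluded). Collinear point sets leave the rotation
underdetermined and raise an error rather than returning an arbitrary
frame.

**RMSD.** $\mathrm{RMSD} = \sqrt{\tfrac1n \sum_i d_i^2}$ over paired
atoms. By default each frame is first superposed on the reference
frame (frame 1, the initial structure of the run) using the backbone
selection; a `fit = FALSE` switch exists because the analytic tests
need raw displacements. Under isotropic per-coordinate noise of
standard deviation $\sigma$ about a fixed reference,
$n\,\mathrm{RMSD}^2/\sigma^2 \sim \chi^2_{3n}$, so
$\langle\mathrm{RMSD}^2\rangle = 3\sigma^2$ — the closed-form limit
the acceptance suite checks at $T = 10{,}000$ frames. That limit holds
against a noise-free reference; measuring against a noisy frame
doubles it, which is why the test plants frame 1 exactly.

**Contacts.** The contact count between two disjoint atom groups is
the number of cross pairs within the cutoff, boundary inclusive
(`<=`). Pair counting — not residue counting — is stated explicitly
because "number of contacts" is ambiguous; it matches the behaviour of
minimum-distance tools. Defaults follow the study: 0.3 nm for the
mutated-residue side chain against pre-mRNA, 3 nm for p14 (SF3B6)
side chains (residues 20–100) against pre-mRNA. The 3 nm value is
unusually large for a contact cutoff; it is implemented verbatim and
flagged here. Hydrogens, when present, are part of side-chain
selections — the original analysis ran on a solvated all-atom model —
and the K700-interface measurement is reported both with and without
them because it is sensitive to protonation.

**RMSF.** Per-atom root-mean-square fluctuation about either the
time-average position (default) or the initial frame. The source
equation mixes the two reference conventions in prose, so the
reference is an explicit switch and both variants are tested
(an atom oscillating $\pm\delta$ has RMSF $\delta$ about its mean and
$\delta\sqrt2$ about an endpoint).

## Essential dynamics

The positional covariance matrix of the C$\alpha$ selection is the
time average of outer products of displacements from the time-mean
structure, after superposing every frame onto that mean (fit to frame
1, compute the mean, refit to the mean once). Weighting is uniform by
default; mass weighting (the $\sqrt{m_im_j}$ convention) is an option
because the source never states which was used. Eigendecomposition
yields modes sorted by descending eigenvalue; eigenvalues are clipped
at zero and eigenvector signs are fixed deterministically (largest-
magnitude component positive) so projections are reproducible across
platforms. The variance fraction of the top $k$ modes is the ratio of
their eigenvalue sum to the total; in the emulated system the first
two eigenvectors carry about 37% and 15% — more than half of the
overall motion.

Projection supports a *different* trajectory on a stored basis (the
mutant on the wild-type modes), which requires equal atom counts;
mismatches are an error, never an implicit mapping. Per-mode RMSF for
a mode subset $S$ is
$\sqrt{\sum_{k \in S} \lambda_k \lVert v_k^{(i)}\rVert^2 / w_i}$ per
atom $i$; with $S$ equal to all modes this reduces to the trajectory
RMSF (Parseval identity, checked numerically to 1e-6).

Mode sets persist as plain-text TSV files (eigenvalues, eigenvectors,
mean structure, weights under a shared prefix) with a lossless
round-trip; a text serialization keeps the artifacts portable and
diffable.

## Dynamic cross-correlation

$\mathrm{DCC}(i,j) = \langle \Delta r_i \cdot \Delta r_j \rangle_t /
\sqrt{\langle\lVert\Delta r_i\rVert^2\rangle_t
\langle\lVert\Delta r_j\rVert^2\rangle_t}$, displacements about each
atom's time mean, whole-trajectory ensemble average (no windowing).
Frames are superposed to the mean structure first by default: residual
rigid-body motion would saturate all correlations toward $\pm 1$.
Atoms with zero fluctuation have undefined correlation; their rows and
columns propagate as `NA` with a warning, never as silent zeros. Block
summaries (mean or median over a region-pair submatrix, diagonal
excluded on overlap) quantify the coupling contrasts: strong positive
correlation within residues 455–832 and negative correlation between
455–832 and 932–1300 in the wild type, both attenuated in the mutant.

## The synthetic-data module

Every generator is a pure function of its arguments including the
seed (base R Mersenne–Twister, no global state), so identical inputs
give byte-identical outputs.

* **Chain references** place C$\alpha$ atoms at exactly 0.38 nm
  spacing (planar zig-zag or helical trace), with optional placeholder
  backbone/side-chain/hydrogen atoms so atom-class selections are
  meaningful.
* **Mode trajectories** are reference + low-rank Gaussian mode
  displacements + isotropic noise, optionally with a random rigid
  transform per frame. Planted mode directions are orthogonalized
  against the six rigid-body degrees of freedom of the reference;
  without this, superposition absorbs part of the planted variance
  and no generator can be recovered exactly. For targeted variance
  fractions, `calibrated_mode_plant()` does the accounting: each mode
  direction also receives the noise variance $\sigma^2$, and
  superposition removes about six degrees of freedom of noise, so the
  residual fraction spreads over $3N - 6 - K$ directions. With the
  naive $\lambda_k = f_k V$ planting the measured fractions are biased
  upward by about 0.014 under these settings; the calibration makes
  the planted ground truth exactly $f_k$ of observable variance.
* **Block-correlated trajectories** move residue groups by shared
  scalar latents along a common direction plus per-atom noise; the
  population cross-correlation between groups $g,h$ is
  $\rho_{gh}\, v/(v + 3\sigma^2)$ in closed form. These trajectories
  carry no rigid-body component, and the closed form holds for raw
  displacements, so block analyses run with superposition disabled; a
  fitted analysis would absorb part of the planted collective motion
  (the group latents project onto global translation).
* **Contact scenarios** separate two matched atom groups linearly,
  $d(t) = d_0 + vt$, so the crossing time of a cutoff $c$ is exactly
  $t^\ast = (c - d_0)/v$ and the noiseless contact series hits zero at
  the first frame past $t^\ast$.
* **Network/mutation fixtures** plant exact per-gene filter-surviving
  counts (hub strictly maximal — the breast-carcinoma defaults give
  SF3B1 34 against DHX15 13, PRPF19 6, U2AF2 2, SRSF1 2, SF3A2 1)
  plus distractor records that each fail exactly one filter
  criterion. A separate per-sample SF3B1 table carries the reported
  per-change counts (K700E in 45 samples).
* **The K700 interface model** is a synthetic stand-in for the
  prepared spliceosome structure: a lysine-700 side chain reaching
  toward a short RNA, planted at 0.19 nm (heavy atoms) and 0.09 nm
  (with the amine hydrogen) minimum distance. It demonstrates the
  measurement and its protonation sensitivity; it is not the
  experimental structure, and results on it say nothing about the
  real complex.

What the generators deliberately do not emulate: force-field physics,
solvent, thermostats, anharmonicity, and the slow conformational
relaxation of a real 500 ns run. Passing recovery tests therefore
shows that the estimators are correct and well-calibrated on their
own model class, not that the biological conclusions transfer.

## Problem sizes and numerical choices

Analyses in the shipped scripts use 94-residue chains whose residue
numbers span 455–1300 in steps of 9, 600-frame trajectories at 100 ps
spacing (semantically a 60 ns window); recovery and closed-form tests
use up to 10,000 frames on smaller chains. These sizes were chosen so
the whole suite runs in minutes on one core while keeping Monte-Carlo
error comfortably inside the stated tolerances (variance fractions
within ±0.03 at $T = 5000$; block correlations within ±0.05).

Other numerical decisions: symmetric matrices are symmetrized
($\tfrac12(C + C^\top)$) before `eigen` and inputs asymmetric beyond
1e-8 are rejected; negative eigenvalues from roundoff are clipped at
zero; DCCM entries are clamped to $[-1, 1]$ and the diagonal set to
exactly 1; the contact boundary uses `<=` on squared distances
computed with identical arithmetic on both sides; degenerate inputs
(empty selections, overlapping contact groups, zero-variance spectra,
single-frame trajectories) raise errors or warnings rather than
returning conventional values.

## Known limitations

* No periodic-boundary minimum-image handling: inputs are assumed
  whole and unwrapped.
* Insertion codes in PDB files are rejected; mmCIF is not read.
* XTC trajectories are not read (no installed decoder); DCD and the
  plain-text XYZ interchange format are supported.
* Terminal OXT atoms fall into side-chain selections because the
  amino-acid backbone set is fixed to {N, CA, C, O}.
* Centrality conventions (closeness as reciprocal mean intra-component
  distance; radiality via component diameter) are stated choices; the
  original network tool's exact conventions are not documented.
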