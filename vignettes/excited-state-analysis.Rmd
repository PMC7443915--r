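---
title: "Fragment-resolved excited-state analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-resolved excited-state analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcexciton)
```

## The problem

The Photosystem II reaction center holds six chlorin pigments — the
special-pair chlorophylls P~D1~ and P~D2~, accessory chlorophylls Chl~D1~
and Chl~D2~, and pheophytins Phe~D1~ and Phe~D2~ — on two quasi-symmetric
branches, of which only the D1 ("active") branch performs productive charge
separation toward Phe~D1~. TDDFT calculations on such multi-chromophore
models produce tens of excited states, each a superposition of
occupied→virtual one-electron transitions, and the scientific questions are
*which pigment* each state excites, *which way* charge flows within it, and
*how* the resulting bands respond to perturbations such as axial-ligand
mutations of the special pair. This package turns those questions into
deterministic, tested operations on a neutral data model of the calculation
output.

## The analysis chain

**Mulliken MO composition.** For an S-normalized MO with coefficients
$c$, the weight carried by basis function $\mu$ is
$\Theta_\mu = \sum_\nu c_\mu c_\nu S_{\mu\nu}$, i.e. the diagonal of $PS$
for the rank-1 density $P = cc^\top$. Off-diagonal overlap terms are split
half-and-half between centers — the standard Mulliken MO-composition
convention. Summing $\Theta_\mu$ over the basis functions of each cofactor's
atoms gives percentage contributions that total exactly 100; individual
entries may be slightly negative, a known Mulliken artifact that we report
as-is because clipping would silently break normalization and mask basis
pathologies.

**State labels.** Under the restricted (closed-shell) printing convention a
transition with CI amplitude $c$ contributes $200c^2$ percent to its state
(so $|c| = 0.57$ reads as ≈65%); squared amplitudes renormalized over the
state's transitions give weights summing to one. A state is labeled as an
excitation of the fragment with the largest weight-averaged contribution to
the occupied MOs of its transitions. Ties within $10^{-6}$ fall back to the
dominant transition's own occupied-MO argmax, then to lexicographic order;
the environment bucket (all unassigned atoms) only wins if it beats every
cofactor. De-excitation amplitudes, when present, are carried through the
data model but excluded from the weights, matching the convention in which
printed contribution percentages are quoted.

**CT direction.** For each transition the per-fragment change
$\Delta_F = \%^{\text{virt}}_F - \%^{\text{occ}}_F$ defines the donor
(most negative $\Delta$), acceptor (most positive) and magnitude
($\Delta_{\text{acceptor}}$, percentage points). The branch topology —
P~D1~/P~D2~ jointly at rank 0 as a shared origin, Chl at rank 1 and Phe at
rank 2 on each branch — converts the pair into a category: `up-active`,
`down-active`, `up-inactive`, `down-inactive`, `within-P` (between the two
special-pair chlorophylls), `local` (below threshold), or `other`
(cross-branch pairs away from P, or fragments outside the topology such as
residues and waters, which participate in profiles but carry no branch).
Treating the P pair as a shared origin reflects its role as a joint
excitation precursor; transfers P→Chl/Phe on either branch count as "up"
that branch. The donor/acceptor-extremes rule gives exactly one category
per transition rather than a full transport decomposition; heavily mixed
transitions land in `other` instead of being silently re-binned.

**CT extent.** The unrelaxed difference density
$\Delta P = \sum_t w_t (c_{a_t}c_{a_t}^\top - c_{i_t}c_{i_t}^\top)$ (CI
weights $w_t$ summing to 1) is Mulliken-partitioned onto atoms,
$\Delta n_A = \sum_{\mu \in A} (\Delta P\, S)_{\mu\mu}$, which conserves
particle number identically. The barycenters of the atoms gaining and
losing density give the increment/depletion centroids; their separation is
$D_{CT}$ (Å), and a state is CT when the nearest atoms to the two centroids
(Euclidean distance, ties to the lower atom index for determinism) lie on
different cofactors. We deliberately work with atom-resolved point
populations rather than a spatial grid: grid densities require evaluating
basis functions, which sits outside this package's format-level scope,
while the atomic variant preserves the decision rule (nearest atom →
cofactor identity) and is exactly testable against a brute-force
density-matrix oracle. Whether a reference calculation's centroids used
relaxed or unrelaxed densities is generally not recoverable from its
output, so results here are comparable in kind but not guaranteed
numerically identical to density-grid implementations.

**Spectra and band shifts.** Sticks broaden as
$A(E) = \sum_k f_k \exp(-(E - E_k)^2 / 2\sigma^2)$ on an energy grid,
reported against wavelength. Constant energy-axis width is the conventional
reading when no lineshape is specified, and keeps the broadened integral
equal to $\sigma\sqrt{2\pi}\sum_k f_k$ — a property the tests exploit as a
quadrature oracle. A cofactor band (e.g. the P~D1~ Soret band) broadens
only the states labeled with that cofactor inside a wavelength window; the
peak is the grid argmax refined by a parabola through the three
neighbouring points, giving sub-step stability for shift comparisons.
Peak-height normalization, used for display, never moves the peak.
Mutant-vs-wild-type reports quote
$\Delta\lambda = \lambda_{\text{mut}} - \lambda_{\text{WT}}$, negative =
blue.

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `ct_threshold` (`analysis_config`) | 5 | percentage points | Minimum donor→acceptor transfer to call a transition CT. No universal cutoff exists for this quantity; 5 pp cleanly separates designed-local from designed-CT synthetic transitions and is far below the ≳80 pp transfers of well-localized CT states, so conclusions are insensitive to it over a wide range. Configurable. |
| `sigma` (`spectrum_config`) | 0.05 | eV | Broadening width: merges the six Qy states into one band while keeping Qy/Qx/Soret resolved. Purely presentational — band membership and shift directions, not curve shapes, are the supported conclusions. |
| grid | 1.55–3.60, step 0.001 | eV | Covers Qy through Soret for chlorins (~350–800 nm) with ≲1.5 meV peak quantization before parabolic refinement. |
| band index ranges | Qy 1–6, Qx 7–12, Soret 13–22 | state index | The standard partition of the 22 lowest states of six-chlorin RC models; an explicit wavelength window (e.g. 396–443 nm for the Soret census) can override it. |
| `localization` ρ (`scenario`) | 0.9 | fraction | Home-fragment Mulliken weight of generated MOs. 0.9 represents strong-but-imperfect localization with visible inter-pigment delocalization tails, the regime in which cofactor assignment is meaningful. |
| `coupling` ε (`scenario`) | 0.1 | — | Off-diagonal AO overlap scale; kept below 0.3 and auto-halved until the overlap is safely positive definite (smallest eigenvalue > 0.05). |
| `delta_e` (`scenario`) | +0.02 | eV | Mutant perturbation applied to P~D1~-labeled states; ±0.02 eV (~3 nm at 420 nm) is the scale of axial-ligand-induced site-energy shifts. |

## What the generator emulates — and what it does not

`make_record()` builds records whose *statistical structure* matches what
the analysis assumes: six (or fewer) cofactors as disjoint atom clusters at
least 8 Å apart, arranged as two compact parallel branch rows like the real
pigment cluster rather than a long chain (so the nearest-atom rule is
unambiguous); one occupied and two virtual MOs per fragment, each holding
ρ ± 0.02 of its Mulliken weight on its home fragment (iterative
on/off-block rescaling with S-renormalization, ≤100 damped iterations,
failing loudly with the achieved weight otherwise); occupied MOs weighted
toward one end of their cluster and virtuals toward the other, so every
excitation carries the definite intra-fragment redistribution a real
orbital's nodal-structure change produces; states with one dominant
transition whose printed contribution falls in 50–80% plus a weak local
minor transition; bright oscillator strengths uniform(0.3, 0.6) versus dark
uniform(0, 0.05); Soret scenarios planting six P~D1~ and two P~D2~ states
among the ten states of the 396–443 nm window, mirroring the band census of
large RC models; and mutant pairs differing only by `delta_e` on
P~D1~-labeled states, with energy spacings wide enough that the shift never
reorders states or pushes them out of the window.

It does **not** emulate real chlorin electronic structure: no physical
basis sets or integrals, no exchange–correlation physics, no vibronic
structure, no realistic transition-dipole orientations, and no
environment-induced site-energy disorder. Passing tests therefore
demonstrate that the *analysis logic* — decomposition, labeling,
classification, band arithmetic — is correct on data with known answers,
not that any particular quantum-chemical model of the RC is accurate.

## Numerical choices

* Single unit system: Å, eV, with the conversion constant fixed at
  1239.841984 eV·nm (`EV_NM`); FCHK coordinates are converted from Bohr on
  read. Wavelengths are always recomputed from energies, never trusted from
  logs.
* Amplitude signs are preserved as printed, with no phase fixing — only
  squared quantities are consumed downstream.
* Overlap matrices are accepted from the input file or supplied separately,
  never recomputed from basis exponents; a record without overlap is valid
  but Mulliken operations refuse to run on it, naming the stage.
* The JSON record container serializes numbers at 17 significant digits,
  which round-trips IEEE doubles bit-exactly (the test suite asserts
  `identical()` on re-read coefficient matrices).
* Ties: nearest-atom ties break to the lower atom index; label ties to the
  dominant transition's argmax, then lexicographic. All generator
  randomness flows from a single scenario seed, so records, sidecars and
  every downstream table are byte-reproducible.
* Degenerate difference densities (no gain or no loss anywhere) return an
  explicit non-CT report with $D_{CT}=0$ rather than dividing by zero.

## Problem sizes used in validation

The shipped suites run at desk scale: ≥50 random overlap/coefficient
systems (≤30 basis functions) against the brute-force density-partition
oracle; ≥100 generated states for label recovery; 120 planted transitions
for direction recovery and occupied/virtual antisymmetry; 90 states for
difference-density conservation and CT-extent consistency; 20 seeds for
mutant shift sign and first-order magnitude (within 20% of
$-\lambda^2\Delta E / 1239.84$); and a full synth→analyze→spectrum
determinism check on a 22-state record. The same measurements, recomputed
from scratch, are what `scripts/acceptance.R` reports.

## Known limitations

Restricted (closed-shell) calculations only; no natural-transition-orbital
construction, exciton-coupling Hamiltonians, or Löwdin/Hirshfeld
alternatives to Mulliken; no Lorentzian/Voigt lineshapes or fits to
experimental spectra; Mulliken percentages inherit that method's
basis-set sensitivity; and the FCHK reader covers the documented key subset
(s/p/sp/d/f shells), not arbitrary checkpoint content. The printed-amplitude
normalization of any particular program's log should be confirmed against
one known file before quantitative comparisons; the 200·c² restricted
convention is declared in `analysis_config()` rather than assumed silently.
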