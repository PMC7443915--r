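# rcexciton

Fragment-resolved analysis of TDDFT excited states for multi-chromophore
pigment–protein assemblies, built around the Photosystem II reaction center
(PSII RC): the special-pair chlorophylls P<sub>D1</sub>/P<sub>D2</sub>, the
accessory chlorophylls Chl<sub>D1</sub>/Chl<sub>D2</sub> and the pheophytins
Phe<sub>D1</sub>/Phe<sub>D2</sub>, arranged on the active (D1) and inactive
(D2) branches.

Given an excited-state calculation record — geometry, AO basis-to-atom map,
overlap matrix S, MO coefficients c, and excited states with occupied→virtual
CI amplitudes — the package answers the questions a photosynthesis
spectroscopist asks of such output:

* **Which cofactor does each orbital live on?** Mulliken MO composition:
  Θ<sub>μ</sub>(i) = Σ<sub>ν</sub> c<sub>μi</sub> c<sub>νi</sub> S<sub>μν</sub>,
  summed over the basis functions of each cofactor's atoms and reported as
  percentages (`fragment_profile()`, `all_profiles()`).
* **Which cofactor is each state an excitation of?** Each state is labeled by
  the fragment with the largest CI-weight-averaged contribution to the
  occupied MOs of its transitions; a transition with printed amplitude c
  contributes 200·c² percent under the restricted convention
  (`transition_weights()`, `assign_state_label()`).
* **Which way does charge move?** Per transition, the change in fragment
  weight between occupied and virtual MO defines donor, acceptor and
  transfer magnitude; the D1/D2 branch topology turns that pair into a
  direction category — up/down the active or inactive branch, within the
  special pair, local, or other (`transition_ct()`, `state_character()`).
* **How far does charge move?** The unrelaxed difference density is
  Mulliken-partitioned onto atoms; the barycenters of density depletion and
  increment give D<sub>CT</sub>, and the state is flagged CT when the atoms
  nearest the two centroids sit on different cofactors (`ct_extent()`).
* **What does the spectrum look like, and how do mutations shift it?**
  Oscillator-strength-weighted Gaussian broadening on an energy grid, band
  reports for the Qy/Qx/Soret regions, isolation of the states dominated by
  one cofactor (e.g. P<sub>D1</sub>) and wild-type-vs-mutant peak-shift
  reports (`broaden()`, `cofactor_band()`, `compare_bands()`).

Readers are provided for a formatted-checkpoint (FCHK) subset and for the
textual excitation-log dialect, plus a lossless JSON record container. A
synthetic-data generator (`scenario()`, `make_record()`) emits toy records
with ground-truth sidecars — fragment-localized MOs at a controllable
localization, planted CT directions, Soret band structure, mutant shift
pairs — so the whole pipeline is testable without any electronic-structure
calculation.

## Worked example

Generate a wild-type/mutant pair of 22-state records (six cofactors, 60
basis functions, MOs 90% localized on their home chromophore), characterize
the states, and measure the P<sub>D1</sub> Soret band shift caused by
raising every P<sub>D1</sub> excitation by 0.02 eV (a His→Ala-style ligand
perturbation of the D1-side special-pair chlorophyll):

```r
library(rcexciton)

pair  <- make_record(scenario("mutant-shift-pair", delta_e = 0.02, seed = 11))
profs <- all_profiles(pair$record, pair$fmap)
round(profs[1:3, ], 2)
#>     PD1   PD2 ChlD1 ChlD2 PheD1 PheD2 environment
#> 1 89.87  1.55  3.21  2.72  0.88  1.76           0
#> 2  1.23 90.03  0.89  2.67  2.38  2.80           0
#> 3  1.86  1.89 90.06  1.64  1.77  2.78           0

chars <- characterize_states(pair$record, pair$fmap)
head(state_table(chars), 6)
#>   state energy_eV wavelength_nm      f label dominant_occ dominant_virt dominant_percent
#> 1     1    1.7808        696.21 0.3095 PheD1            5            11            65.84
#> 2     2    1.8270        678.63 0.4216 PheD2            6            12            59.90
#> 3     3    1.8756        661.05 0.0227   PD1            1             7            74.26
#> 4     4    1.9224        644.96 0.0115   PD2            2             8            72.76
#> 5     5    1.9738        628.13 0.3444 ChlD1            3             9            68.14
#> 6     6    2.0180        614.38 0.0199 ChlD2            4            10            71.97
```

Each MO is ~90% on one cofactor (row 1: P<sub>D1</sub>), and the six lowest
(Qy) states are one excitation per chlorin, with the pheophytin and
Chl<sub>D1</sub> states bright — dominant transitions contribute 60–74%
of each state on the printed 200·c² scale.

```r
labels <- vapply(chars, function(x) x$label, character(1))
count_labels(pair$record$states, labels, c(396, 443))
#> ChlD1 ChlD2   PD1   PD2 PheD1 PheD2
#>     0     0     6     2     1     1

wt  <- cofactor_band(pair$record$states, labels, "PD1")
mut <- cofactor_band(pair$mutant$states,  labels, "PD1")
wt
#> <rc_band PD1> 6 state(s) [14,15,17,18,19,22], peak 418.28 nm
compare_bands(wt, mut)$delta_lambda_nm   #> -2.82  (direction "blue")
```

Of the ten Soret-window states (396–443 nm), six are P<sub>D1</sub>
excitations and eight are special-pair excitations overall. Summing the
Gaussian-broadened P<sub>D1</sub>-dominated states gives a band peaking at
418.3 nm; the +0.02 eV mutant moves it 2.8 nm to the blue, matching the
first-order expectation −λ²ΔE/1239.84 ≈ −2.8 nm.

End-to-end drivers (`rc_synth()`, `rc_analyze()`, `rc_spectrum_report()`)
write all of the above as TSV/CSV tables; the same workflow is scriptable
via `inst/cli/rcexciton.R` with subcommands `synth`, `analyze`, `spectrum`.

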