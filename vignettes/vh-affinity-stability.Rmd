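---
title: "Quantifying affinity/stability trade-offs in evolved VH domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying affinity/stability trade-offs in evolved VH domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vhmature)
```

## The scientific problem

Affinity maturation of antibodies accumulates mutations in and around the
complementarity-determining regions (CDRs). Some of those mutations buy
binding affinity at the price of thermodynamic stability; others are
compensatory, restoring the stability the affinity mutations spent. To
resolve which is which, each evolved variant in a maturation lineage is
compared against *single-reversion constructs* — the same variant with one
acquired mutation reverted to the parental residue — on two axes:

* **Affinity**: equilibrium association constants \(K_A = 1/K_D\) from
  yeast-surface-display titrations read out as mean fluorescence.
* **Stability**: apparent melting temperatures \(T_m^*\) from circular
  dichroism (CD) thermal scans.

A mutation whose reversion *lowers* affinity is affinity-enhancing; one
whose reversion *raises* \(T_m^*\) is destabilizing. Crossing the two axes
yields the quadrant classification (enhancing/neutral/reducing ×
stabilizing/neutral/destabilizing) that is the package's final product.

`vhmature` implements the full computational pipeline: sequence handling
under Kabat numbering, both fitters, the statistical classification, a
hydrophobic-probe surface-mapping module for simulation trajectories, and
synthetic-data generators with known ground truth so that every stage is
testable without instrument data.

## Binding model and fitter

Titrations are fit to a one-site saturation isotherm plus a linear
nonspecific term,

\[
\mathrm{APC}(c) \;=\; \mathrm{APC_{min}} \;+\;
\mathrm{APC_{sat}}\,\frac{c}{c + K_D} \;+\; \mathrm{APC_{ns}}\, c ,
\]

with \(c\) the antigen concentration (molar) and APC the mean
fluorescence. Parameters are estimated by minimizing the mean squared
error. The problem has a benign but real multi-modality (a weak binder's
saturating term degenerates into a line), so `fit_isotherm()` uses
multi-start bounded Levenberg–Marquardt: \(K_D\) starts on a 7-point log
grid spanning `[min conc/100, max conc×100]`, the three linear parameters
are initialized by ordinary least squares at each start, and the best
optimum is kept. Bounds: \(\mathrm{APC_{sat}}, \mathrm{APC_{ns}} \ge 0\),
\(K_D\) within `[min conc/1000, max conc×1000]`. \(K_D\) is optimized as
\(\log_{10} K_D\) and the nonspecific slope is concentration-scaled for
conditioning.

**Measurability.** A titration that never approaches saturation cannot
yield a \(K_A\); such variants are reported with a dagger and excluded
from averages. A fit is flagged unmeasurable when any of

1. fitted \(K_D > 10\times\) the highest tested concentration,
2. fitted \(\mathrm{APC_{sat}} \le 3\times\) the residual RMS,
3. the saturable component fails a partial F-test against the nested
   linear (no-saturation) model at \(\alpha = 0.01\).

The third criterion is needed because a \(K_D\) far above the ladder is
*exactly* ridge-degenerate with the nonspecific slope
(\(\mathrm{APC_{sat}}\,c/K_D \approx\) a line), and at realistic noise the
optimizer can land mid-ridge with a formally in-range \(K_D\). All three
thresholds are configurable in `binding_config()`. A variant's replicate
summary (`summarize_affinity()`) is the mean and sample (n−1) SD of
\(K_A\) over measurable replicates; the variant is unmeasurable when more
than half its replicates are.

## Melt analysis

CD thermal scans (ellipticity vs temperature) are reduced to an apparent
melting temperature without assuming reversible unfolding — hence
\(T_m^*\), and no enthalpy or free energy is extracted:

1. **Baselines.** The folded and unfolded ellipticities are fit as linear
   functions of temperature. Windows seed at the outer 15% of the scan
   and *auto-extend* over each plateau — points whose fraction folded
   stays within `plateau_tol` (default 0.05) of 1 or 0, detected on a
   5-point running mean, minus a `window_margin` (default 3 °C) — with
   the fit→transform→re-select loop iterated to convergence. Extending
   the fit across the whole plateau is what controls the dominant error
   term, the baseline value *extrapolated* into the transition; with
   short fixed windows that extrapolation error alone reaches ~1 °C at
   the noise levels used here. A final guard shrinks any window whose
   mean fraction folded departs from its plateau value by more than 0.05.
2. **Fraction folded.** \(f(T) = (\Theta_T - \Theta_U(T)) /
   (\Theta_F(T) - \Theta_U(T))\); values are not clipped to [0, 1].
3. **Transition regression.** The transition region is the dominant
   contiguous run of points with \(0.35 \le f \le 0.65\) (configurable);
   \(T_m^*\) is where the least-squares line through it crosses
   \(f = 0.5\). For near-step transitions that leave the band empty, the
   points flanking the \(f = 0.5\) sign change complete the regression
   (minimum 4 points). Regression on raw ellipticity instead of \(f\) is
   available (`regress_on = "ellipticity"`); the two agree because the
   transform is affine in the signal.

Only the first heating scan feeds the \(T_m^*\) estimate. The repeat scan
feeds `check_reversibility()`: the ratio of folded-window amplitude
(relative to the first scan's unfolded baseline) in the second scan versus
the first. Replicate melts are averaged with sample SD
(`summarize_tm()`). Mean residue ellipticity uses the standard convention
\(\mathrm{MRE} = \theta_\mathrm{mdeg}\,\mathrm{MRW} /
(10\,l_\mathrm{cm}\,c_\mathrm{g/L})\), recorded in the output's
`convention` attribute.

**Known limitation.** Both plateaus must be sampled: when the transition
sits closer than ~8–10 °C to the hot end of the scan (for van't Hoff
widths typical of small domains), the unfolded baseline is contaminated
by the transition tail and \(T_m^*\) biases low by several tenths of a
degree. The scan range should extend well past the hottest transition of
interest.

## Statistical classification

Comparisons use a two-tailed two-sample Student's t-test on
replicate-level values (equal-variance pooled by default, Welch by flag),
with significance stars at p < 0.05 (\*) and p < 0.01 (\*\*), both
strict. Stability comparisons with two melts per side (df = 2) are tested
like any other. No multiple-testing correction is applied; the record
carries raw p-values (Benjamini–Hochberg q-values can be appended
downstream via `p.adjust` if desired).

`reversion_effect()` fills one axis of a trade-off record: delta = context
minus reverted (so positive affinity delta ⇒ enhancing, positive stability
delta ⇒ stabilizing), propagated SDs, and the class — `neutral` when
p ≥ 0.05, otherwise by the delta's sign. When the reversion construct's
affinity is unmeasurable under a measurable context, the p-value is
not-computable (dagger) but the mutation is still classified enhancing:
binding was lost upon reversion, which is the strongest qualitative form
of the comparison. When the context itself is unmeasurable the class is
`not-computable`. `build_tradeoff_table()` walks a lineage, pairs every
single-reversion construct with its context, and emits the
Kabat-position-ordered quadrant table.

## Structure module

For multi-frame structures (multi-model PDB, Å converted to nm on read,
or a minimal XYZ dialect):

* `superpose()` — Kabsch SVD superposition with a determinant guard
  (proper rotations only, never reflections), returning the post-fit
  RMSD. Rank-deficient selections (collinear points, 2 atoms) still
  return the optimal RMSD; the rotation is then simply not unique.
* `rmsd_matrix()` — pairwise post-fit RMSD over frames, default selection
  backbone N/CA/C, probes always excluded.
* `greedy_cluster()` — dominant-structure clustering: repeatedly take the
  frame with the most unassigned neighbors within the cutoff (ties to the
  lowest index) as a center, assign its neighborhood, remove, repeat.
  0.2 nm is the conventional backbone cutoff.
* `probe_density()` — per-heavy-atom mean count of probe particles within
  0.5 nm (minimum-image when a box is present; frames treated as
  independent samples). Raw mean counts are reported by default;
  `normalize = TRUE` divides by the uniform-bulk expectation
  \(n_\mathrm{probes}\,v_\mathrm{cutoff}/V_\mathrm{box}\), turning the
  map into a local enrichment factor. `write_map()` writes the scores
  into the B-factor column of a single-model PDB (probes excluded) for
  structure-viewer coloring.

Running molecular dynamics is out of scope: the module consumes
trajectories. The probe parameters echoed in the generator defaults
(80 methane-like particles, σ = 0.3855 nm, ε = 0.694 kJ/mol, initial
placement ≥ 1 nm from the protein) are provenance metadata, not simulated
physics.

## Synthetic-data generators and the study design

Every generator is a deterministic function of (truth, seed); replicate
k draws from a Lehmer-style substream of the master seed, so adding
replicates never perturbs earlier ones.

* `gen_titration()` — forward binding model plus i.i.d. Gaussian signal
  noise. Default ladder: 10 half-log steps bracketing \(K_D\). Default
  noise 40 a.u. ≈ 2% of the default saturation amplitude, a deliberately
  favorable precision for replicate-averaged mean fluorescence.
* `gen_melt()` — two-state van't Hoff unfolding with \(\Delta C_p = 0\):
  \(\Delta G(T) = \Delta H (1 - T/T_m)\) (absolute temperatures),
  \(f = 1/(1+e^{-\Delta G/RT})\), sloped linear baselines, Gaussian
  noise. This is the simplest forward model whose inverse is the melt
  analysis above; \(\Delta H\) (default 400 kJ/mol, a typical
  small-domain van't Hoff enthalpy) is a generator knob only, never
  estimated from data. Default baselines: slopes −0.01 and −0.002
  mdeg/°C, intercepts −2 and −14 mdeg — an ~11.5 mdeg transition
  amplitude, realistic for a 1-cm cell at 0.1 mg/mL, giving SNR ≈ 38
  against the 0.3 mdeg noise. At \(T = T_m\) the noiseless signal is
  exactly midway between the baselines.
* `gen_trajectory()` — i.i.d. frames (the analysis treats frames as
  samples, so no dynamics): each probe is placed in a thin shell around a
  randomly chosen designated "hydrophobic" atom with odds
  \((E-1)\,n_\mathrm{des}\,v_\mathrm{cutoff}/V_\mathrm{box}\), otherwise
  uniformly in the box at ≥ 0.35 nm from the protein. The normalization
  makes the `enrichment` parameter \(E\) equal the expected
  designated-to-background local density ratio, and \(E = 1\) recovers
  exactly uniform placement. Shells emulate, not simulate, hydrophobic
  attraction.
* `gen_pseries_bundle()` — the full synthetic study: a wild-type VH
  stand-in, four sequentially evolved variants (4, 7, 9 and 12
  accumulated mutations), every single-reversion construct in its
  acquisition context plus all twelve reversions of the most evolved
  variant, and the wild-type scaffold carrying the six key affinity
  mutations. Generating truths (`pseries_truths()`) encode the study's
  qualitative pattern — the first-round variant below the detection
  ladder; R62/N72/R50 affinity-enhancing but destabilizing; K45/K98
  enhancing and stabilizing; R100d the strongest affinity mutation with
  neutral stability; H52/G82b/I100f/I100g/T100h passengers; the
  six-mutation scaffold more stable but >4-fold weaker-binding than the
  fully evolved variant — with anchored melting temperatures (75.0, 73.2,
  65.5, 63.3, 66.0 °C along the lineage; 70.9 °C for the round-1 E45
  reversion; 70.5 °C for the six-mutation scaffold). Neutral-truth
  constructs share *exactly* equal generating values so that noise-free
  runs admit a clean neutral classification (the zero-variance t-test
  branch returns p = 1 for equal means).

**The sequence is synthetic.** The lineage's full residue-by-residue
sequence is a VH3-like stand-in constructed to satisfy every constraint
the mutation lineage imposes — residue identities at all twelve mutated
Kabat positions (with insertion codes 82b, 100d, 100f–100h), the
N-glycosylation sequon N72-T73-S74 created by D72N and destroyed by its
reversion, the grafted 10-residue peptide occupying CDR3 positions
100–100i, and the G-III-A hydrophobic patch at 100e–100i exposed by the
100h reversion. It is labelled synthetic in code and documentation and is
not a transcription of any deposited antibody sequence.

**What passing tests do and do not show.** The generators produce i.i.d.
Gaussian noise, exactly linear baselines, ideal two-state melts, and
frames without time correlation. Real titrations have concentration
errors and avidity artifacts; real melts have curved baselines,
aggregation above the transition, and scan-rate effects; real
trajectories are autocorrelated. Passing the recovery suites therefore
demonstrates correctness of the *inverse analysis* under its own forward
model, not robustness to every instrument pathology.

## Kabat conventions

Insertion codes 'a'–'z' are accepted; the empty code sorts before 'a'.
CDR boundaries ship as an overridable JSON configuration
(`inst/extdata/kabat_cdr_default.json`): CDR1 31–35, CDR2 50–65, CDR3
95–102 — the standard Kabat heavy-chain definitions, *not* bounds
verified against any particular study — plus the non-canonical CDR4 loop
at 71–78. An inserted position belongs to the region of its parent
number, which places 100a–100k in CDR3. The sequon scan runs on the
linear residue string, ignoring numbering gaps, because glycosylation is
sequence-local.

## Numerical choices and degenerate inputs

* Titrations need ≥ 5 distinct concentrations spanning ≥ 2 decades;
  anything less is an error, not a bad fit.
* Zero-variance t-test inputs (possible at noise 0) short-circuit to
  p = 1 (equal means) or p = 0; samples with < 2 values yield a
  not-computable record rather than an error.
* Greedy clustering ties break to the lowest frame index; at vanishing
  cutoff every frame is a singleton, at infinite cutoff one cluster.
* `probe_density()` refuses cutoffs above half the smallest box length
  (minimum-image validity).
* Melt grids must be strictly increasing; baselines that cross inside
  the scan raise an error rather than returning a misscaled fraction.

## Problem sizes

The shipped test-suite and acceptance runs use 2 replicate melts per
construct on a 25–95 °C, 0.5 °C grid; 4 replicate titrations per
construct on a 10-point half-log ladder; 50-truth fitter/oracle sweeps;
100 random 20-frame clustering matrices; 200-frame, 80-probe
trajectories; and 10,000 null t-test simulations — sizes chosen so the
statistical assertions are sharp while the whole suite runs in well under
a minute per module.
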