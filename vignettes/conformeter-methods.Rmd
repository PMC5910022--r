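---
title: "Methods: conformational-state metrics, HDX sub-localization and SAXS analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational-state metrics, HDX sub-localization and SAXS analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conformeter)
```

# The problem

Clamshell metalloproteases such as insulin-degrading enzyme (IDE) enclose
their substrates in a chamber formed by two ~55 kDa halves (IDE-N = domains
D1+D2, IDE-C = D3+D4) connected by a hinge loop. Catalysis requires cycling
between open states that admit substrate and closed states that commit it.
This package quantifies where a given atomic model sits on that axis, and
connects the structural picture to two solution techniques that report on
the same motion: hydrogen–deuterium exchange mass spectrometry (HDX-MS,
local stability and protection) and small-angle X-ray scattering (SAXS,
global size and its kinetics).

# Conformational-state metrics

For every subunit chain the package computes three numbers and one label.

**D1–D4 COM distance.** Centres of mass are mass-weighted over heavy atoms
by default. A Cα-only weighting is offered because cryoEM models frequently
lack side chains in flexible regions; for a complete model the two
weightings differ by well under the between-state differences, and any
acceptance band on these metrics absorbs the choice.

**COM dihedral.** The torsion of the 4-point chain COM(D1) → COM(D2) →
COM(D3) → COM(D4), reported as an absolute value in [0°, 180°] because the
sign convention depends on chain handedness, not on the biology; the signed
value is available (`signed = TRUE`) for diagnostics. The atan2 formulation
is used; tests check it against an independent normal-vector construction.

**Buried N/C interface.** `BSA = SASA(N) + SASA(C) − SASA(N∪C)`, both sides
summed. The halved "interface area" convention used by PISA-style tools is
available via `halved = TRUE`; the default is the explicit total because the
convention is otherwise invisible in a single number. SASA is Shrake–Rupley:
Bondi van der Waals radii, probe 1.4 Å, 960 deterministic golden-spiral test
points per atom (no RNG). Convergence is tested: doubling the point count
moves totals by < 0.5%.

**State label.** States are classified against a closed reference computed
with identical domain bounds and weighting. The literature describes states
descriptively rather than by cut-offs; the defaults here are motivated by
the printed spreads — open-family subunits sit 5–24 Å further apart and
7–17° more twisted than closed-family subunits, and the partially-closed
state differs from closed by an approximately 2° dihedral *decrease* at
essentially unchanged distance. Defaults (all config-overridable):

| label | rule |
|---|---|
| C  | Δdist < 2 Å and \|Δdihedral\| < 2° |
| pC | Δdist < 2 Å and Δdihedral ≤ −2° |
| pO | 2 ≤ Δdist < 12 Å |
| O  | Δdist ≥ 12 Å |

The 12 Å O/pO split is the midpoint of the printed 5–24 Å span. On
noise-free generator output the classification recovers the generated label
in 100% of cases (tested).

**Domain bounds.** The conventional IDE partition is shipped as a default
(D1 43–285, D2 286–515, D3 542–768, D4 769–1016, door subdomain 170–237,
author numbering) and is fully user-editable — the analyses themselves are
agnostic to the protein.

# Superposition

Kabsch: SVD of the covariance of centred paired coordinates, with the
reflection branch corrected to a proper rotation (det +1). Pairing is by
shared (chain, residue, atom-name) keys, Cα by default; no outlier-rejection
cycles are run by default so reported RMSDs are single-pass and
reproducible. `domain_anchored_displacement()` superposes on an anchor
domain only and then reads off the probe domain's residual best-fit rotation
angle — on the synthetic hinge this recovers the generated opening angle to
0.1°, which is the package's internal check that "align on one lobe, watch
the other move" is implemented correctly.

# HDX-MS pipeline

**Uptake.** Centroid masses are converted to deuteron counts with the
two-control correction `D = n_exch (m_t − m_ND)/(m_FD − m_ND)`; the
non-deuterated and fully-deuterated controls bracket the scale and absorb
back-exchange during workup. Exchangeable amides are `length − 1 − #P(≥2)`
(the N-terminal residue and prolines retain no label); the stricter
convention that also discards position 2 is a switch (`skip_first = 2`).
Centroids outside the control bracket are clamped with a warning, never
silently.

**Significance.** One rule, matching the single-threshold language of the
field: a peptide or segment is significant when the maximum of |Δ%D| across
time points exceeds 10%. No per-time multiple-testing machinery is layered
on top, deliberately — the threshold already operates on the maximum.

**Sub-localization.** Overlapping peptides carry sub-peptide information at
their boundaries. The covered region is cut into minimal segments at the
union of all peptide start/end boundaries, and per-amide fractional uptake
f_j per segment is solved from A·f = b (A counts exchangeable amides of
segment j inside peptide i, b is the peptide deuteron count) under
0 ≤ f ≤ 1. The solver is box-constrained L-BFGS-B followed by an exact
least-squares polish on the variables away from their bounds, so full-rank
systems are exact to ~1e-9. Segments whose value the peptide set cannot pin
down (tested per column: is the unit vector in the row space of A?) are
flagged `underdetermined` and reported at their shortest supporting
peptide's value — flagged, never silently averaged. The original in-house
program that motivated this stage is undescribed in the literature; this
construction is a declared reconstruction validated by self-consistency
(per-peptide conservation to 1e-6 on full-rank systems) and synthetic
recovery, not by equivalence to that program.

# SAXS

**Guinier.** Weighted fit of ln I on q² iterated until the window satisfies
q·Rg ≤ 1.3 (the standard globular-particle limit, configurable). Exact to
1e-6 relative error on noiseless Gaussian curves (tested).

**Model Rg and p(r).** `Rg = sqrt(Σ w|r−COM|²/Σw)` with mass, uniform or
electron weights. p(r) is the weighted histogram of pairwise distances with
bins centred on multiples of the bin width. The Rg moment uses the exact
identity `Σ_{i≠j} w_i w_j r_ij² = 2W²Rg²`, i.e. the self-term Σw² joins the
denominator; this matters only for tiny point sets (it makes the two-point
example exact) and vanishes at protein size.

**Debye curves are labelled coarse.** Residue-centroid scatterers with
electron-count weights, no hydration shell, no excluded-volume term. They
are fit for comparing models against each other and for χ ranking against
experimental curves with a free scale factor — not for absolute-scale
CRYSOL-grade prediction, and outputs carry a `coarse` attribute to say so.
Rg values in the source study were obtained by regularized indirect Fourier
inversion (GNOM); this package reports Guinier and p(r)-moment estimates
instead and does not implement regularized inversion, stated openly.

**Kinetics.** `Rg(t) = Rg_f + (Rg_i − Rg_f) e^{−t/τ}` is fitted by
profiling: at fixed τ the two amplitudes are a linear solve, so τ is located
on a decade-spaced grid spanning the observation window and refined by 1-D
minimisation. This is deterministic and cannot be trapped by amplitude
non-linearity; a constant series is an explicit error, not a silent τ→∞.

# The synthetic world

The generators state the conditions the analyses assume; their defaults are
fixed once and not tuned against test outcomes.

* **Hinge model** (`make_hinge_model()`): two Cα-trace lobes of four ideal
  helices each (1.5 Å rise, 100°/residue, 2.3 Å radius), stacked face to
  face and joined by a 3-residue linker; 60 residues per lobe by default.
  Lobe 2 rotates rigidly about an axis through the hinge. The default axis
  is tilted off the interface normal plane — a purely geometric choice made
  so that opening changes the COM dihedral as well as the D1–D4 distance
  (an axis in the COM plane would leave the dihedral degenerate). B factors
  are 30 Å² baseline with seeded 0.5 Å² jitter plus a door-region offset.
  Coordinates are analytic; the seed affects only B factors.
* **HDX** (`hdx_ground_truth()` / `make_hdx_dataset()`): per-residue rates
  log-uniform over 10⁻⁵–1 s⁻¹ so the 10–100,000 s schedule spans the
  uptake curves; peptides of length 12 tiled at half-length stride plus
  short anchor peptides every four strides (variable-length digestion —
  a pure half-overlap tiling is one equation short of full rank and would
  make every segment undetermined); protection modelled as rate division
  (default: factor 3 over residues 25–48 in the bound condition, which
  plants segment-level |Δ%D| maxima around 20%); Gaussian noise of 1% of
  the true deuteron count, emulating triplicates with SD below 2% of the
  mean; back-exchange retention 0.7.
* **SAXS** (`make_saxs_data()` / `make_kinetic_series()`): Debye or ideal
  Gaussian curves with relative Gaussian noise; kinetic series with
  Rg 40 → 35 Å, τ = 0.1 s, 30 points over 0–2 s, 1% noise.

What a green test does establish: the estimators invert the generative
models they assume, at the stated noise, with the stated error bounds. What
it does not: realism of full-atom packing (the lobes are Cα-only), EX1/
bimodal exchange regimes (uptake is a sum of independent exponentials),
inter-peptide systematic errors in HDX, or instrument effects in SAXS
(no buffer subtraction, smearing or frame deconvolution).

# Numerical choices and degenerate inputs

* Sphere sampling is deterministic (golden-section spiral); SASA has no RNG.
* Empty selections, all-collinear point sets, flat scattering curves,
  constant kinetic series, and equilibrium controls at or below the
  non-deuterated mass are explicit classified errors (config / input /
  numerical), not NA propagation.
* Insertion codes sort after their base residue number; author numbering is
  authoritative throughout, and no sequence-based renumbering is attempted.
* Occupancies weight nothing: one altloc is kept per atom (highest
  occupancy by default) and carries its full mass.
* Pipeline outputs are written atomically (temp file + rename) so a failed
  stage never leaves a truncated report next to a config that claims
  success.

# Known limitations

Interface analysis is geometric burial only — no ΔG, hydrogen-bond or
residue-pairing energetics. The coarse Debye predictor underestimates
contrast effects at q beyond ~0.25 Å⁻¹. Whole-dimer vs per-subunit RMSD
conventions differ between studies; `rmsd_compare()` reports whichever
selection it is given, so both can be computed explicitly. Deposited-model
validation requires fetching PDB entries and is therefore not part of the
offline test suite.
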