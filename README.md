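# conformeter

Quantitative structural analysis of clamshell (two-lobed) proteases such as
insulin-degrading enzyme (IDE), whose catalytic chamber opens and closes by a
rigid-body hinge motion between an N-terminal half (IDE-N = domains D1+D2)
and a C-terminal half (IDE-C = D3+D4). The package quantifies where each
subunit sits on the open–closed axis and ties that to solution observables
from HDX-MS and SAXS, with seeded synthetic generators so every stage can be
exercised and validated at desk scale.

## What it computes

**Conformational-state metrics.** For each subunit: the distance between the
centres of mass of D1 and D4, `d(COM_D1, COM_D4)`; the absolute torsion of
the four-domain chain, `|dihedral(COM_D1, COM_D2, COM_D3, COM_D4)|`; the
buried surface between the two halves, `BSA = SASA(N) + SASA(C) − SASA(N∪C)`
(Shrake–Rupley point sampling, Bondi radii, 1.4 Å probe); and region-averaged
B factors. Subunits are classified open (O), partially open (pO), partially
closed (pC) or closed (C) by configurable cut-offs on the change relative to
a closed reference — open-family states sit 5–24 Å further apart and 7–17°
more twisted, while pC differs from C by a ~2° dihedral decrease at
essentially unchanged distance.

**Superposition.** Kabsch least-squares rigid alignment (SVD with proper
rotation correction) for RMSD comparisons, plus domain-anchored alignment
that isolates the hinge swing: superpose on one lobe, measure the other
lobe's residual rotation angle and COM displacement.

**HDX-MS.** Deuterium uptake with the two-control back-exchange correction
`D = n_exch · (m_t − m_ND) / (m_FD − m_ND)`, replicate statistics,
condition-vs-reference differentials with a single significance rule
(max over time points of |Δ%D| > 10%), and sub-localization of uptake to
minimal residue segments using all overlapping peptic peptides, solved as a
bounded least-squares system with explicit flagging of under-determined
segments.

**SAXS.** Guinier fits (`ln I ≈ ln I₀ − q²Rg²/3`, window iterated to
`q·Rg ≤ 1.3`), coordinate Rg and pair-distance distribution `p(r)` from
models, a coarse Debye curve `I(q) = Σᵢⱼ wᵢwⱼ sin(qr)/qr` at residue
centroids (explicitly not a CRYSOL-grade predictor), χ goodness-of-fit with
free scale, and single-exponential relaxation fits
`Rg(t) = Rg_f + (Rg_i − Rg_f)·e^(−t/τ)` for time-resolved open→closed
kinetics.

## Worked example

```r
library(conformeter)

dom <- hinge_domains()
ref <- conformation_report(make_hinge_model(opening_angle = 0),
                           domains = dom, compute_bsa = FALSE)
reference <- list(d1d4_distance = ref$d1d4_distance[1],
                  com_dihedral_abs = ref$com_dihedral_abs[1])

conformation_report(make_hinge_model(opening_angle = 0, dimerize = TRUE),
                    domains = dom, reference = reference) |>
  dplyr::select(chain, d1d4_distance, com_dihedral_abs, buried_area, state)
#> # A tibble: 2 × 5
#>   chain d1d4_distance com_dihedral_abs buried_area state
#> 1 A              12.1                0        388. C
#> 2 B              12.1                0        388. C
```

Both subunits of the closed synthetic dimer classify as C: 12.1 Å D1–D4
distance, 388 Å² buried between the halves. Opening the hinge to 30° moves
the same subunit to 29.7 Å and state O, and shrinks the buried interface.

```r
ks <- make_kinetic_series(tau = 0.1, noise_pct = 1, seed = 1)
fit_exp_decay(ks$time_s, ks$rg, ks$sigma)
#> Single-exponential relaxation: tau 0.1094 s, Rg 39.69 -> 35.03 A (RMS 0.315, n=30)
```

A simulated substrate-induced collapse (Rg 40 → 35 Å, τ = 0.1 s, 1% noise)
is recovered within noise.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates all inputs from the package's own generators under the given
seed, reruns the three stages end to end — synthetic closed/open
conformational reports, the HDX differential with its planted protected
region, and the SAXS Guinier/p(r)/kinetic fits — logs the recomputed
numbers to stderr, and writes the JSON report to `--out`.
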