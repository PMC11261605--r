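---
title: "Models and methods behind photofibril"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind photofibril}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photofibril)
```

`photofibril` analyses photocontrolled fibrillization of azobenzene-modified
peptides derived from the fibril-forming fragment of parathyroid hormone
(residues 25–37). This vignette records the models, the parameters that
matter, the numerical choices, and the design decisions taken where the
design was genuinely open — the package's reference account of its own
science.

## Sequence model

A peptide is an ordered list of residues from the twenty standard amino
acids plus the `AZO` pseudo-residue (the AMPB photoswitch), numbered
biologically from an offset (25 for this family). `parse_peptide()` infers
the modification record by anchoring the flanks of the `-Azo-` token on the
parent sequence: flanks that tile the whole parent mean an *insertion*
(the photoswitch gets a sub-label such as `28a`, so references like L28 or
F34 stay valid across all variants), anything shorter means an *exchange*
(the photoswitch takes the first replaced residue's number, and numbering
skips the rest — relevant for the double exchange variant).

Charge profiling assigns **formal integer charges** by comparing the pH
with fixed side-chain pKa values; there is no Henderson–Hasselbalch
fractional charging. At pH 7.4 this gives R, K → +1, D, E → −1 and, because
histidine's pKa (≈6) sits below the assay pH, H → 0 — histidine is the
borderline case and is counted as polar, not charged. Terminal charges
(free amine, free acid) are tracked separately from side chains so that
statements like "three positive charges in the RKK stretch" refer to side
chains only. Whether the synthesized C-terminus is amidated is not
documented for this family; the free acid is assumed. The AZO residue is
uncharged and classified hydrophobic.

Hydropathy uses the Kyte–Doolittle scale by default (no scale is canonical
for this analysis; the choice is exposed). The photoswitch's score
`azo_score` defaults to 4.6, just above the most hydrophobic natural
residue (I, 4.5), encoding the observation that the AMPB group increases a
peptide's overall hydrophobicity; it is a parameter, not a measurement. A
5-residue window over the parent fragment puts the most hydrophobic window
at residues 33–37, the C-terminal aggregation-prone region.

## Photoswitch kinetics

The cis/trans populations form a two-state system. In the dark the cis
fraction decays as $f_{cis}(t+\Delta t) = f_{cis}(t)\,2^{-\Delta t/t_{1/2}}$
with the measured thermal half-life (63–97 h across the design family;
default 97 h, the most stable variant). Under irradiation the population
approaches the wavelength's photostationary state (PSS) exponentially,
$f_{cis} \to f_{pss} + (f_{cis}-f_{pss})e^{-k_{irr}\Delta t}$.

Three modelling choices:

- **A single effective rate `k_irr`** stands in for the full photophysics
  (cross-sections, light intensity): only PSS compositions and irradiation
  durations are available as constraints. The default `k_irr = 10`/h makes
  a 30-minute irradiation reach >99% of the PSS, matching the standard
  switching protocol.
- **PSS compositions are inputs.** Defaults take the mid-points of the
  measured ranges: cis fraction 0.86 at 340 nm (range 0.82–0.90) and 0.215
  at 405 nm (range 0.19–0.24). Per-peptide values, where known, are
  supplied by the caller.
- **Thermal relaxation during irradiation is neglected**: with half-lives
  of 63–97 h and irradiation segments of at most 5 h the error is below 4%
  and the approximation keeps each segment a one-parameter exponential.

With populations summing to one exactly after every operation, any fixed
linear absorbance proxy $f_{cis}\varepsilon_{cis} +
f_{trans}\varepsilon_{trans}$ returns to the same value at the same point
of every cycle — the in-silico analogue of the photobleaching control.

## Fibrillization kinetics

ThT fluorescence reports fibril mass. The two-rate nucleation–elongation
model reduces, after moment closure, to

$$\frac{dP}{dt} = k_n m^{n_c} + k_2 m^{n_2} M, \qquad
  \frac{dM}{dt} = 2 k_+ m P,$$

with monomer $m = m_{tot} - M$. Given the reaction orders, the normalized
mass trace depends only on the combined rates
$\lambda = \sqrt{2 k_+ k_n m_0^{n_c}}$ (primary nucleation) and
$\kappa = \sqrt{2 k_+ k_2 m_0^{n_2+1}}$ (secondary nucleation). A
fluorescence trace is $\Delta F(t) = \mathrm{baseline} + \Delta F_{pl}\,
M(t)/m_{tot}$. Reaction orders default to $n_c = n_2 = 2$ (not determined
for this system; exposed as arguments).

**How the curve is evaluated.** The widely used algebraic fixed-point
solution of these equations is implemented
(`fibril_mass_fraction(method = "fixed_point")`), and during development it
was checked against dense numerical integration of the moment equations.
It reproduces the exact behaviour at the origin (value, slope and curvature
$\lambda^2$) and the exact terminal relaxation rate
$k_\infty = \sqrt{2\kappa^2/(n_2(n_2+1)) + 2\lambda^2/n_c}$, but its
mid-transition error grows to ~10% of the plateau once primary nucleation
contributes comparably to secondary ($\kappa/\lambda \lesssim 10$), and its
$\kappa \to 0$ limit is $1-(1+\lambda t)e^{-\lambda t}$ rather than the
exact primary-only solution
$1-\mathrm{sech}^{2/n_c}(\sqrt{n_c/2}\,\lambda t)$. Because the package's
correctness contract is agreement with the moment equations themselves (to
1% of the plateau, everywhere), the default method integrates them
directly with a compiled fixed-step RK4 scheme (step bounded by 0.1 over
the fastest rate, local error well below $10^{-6}$; early exit once the
curve saturates). The fixed-point algebra remains available, documented,
and tested in the secondary-dominated regime where it is a controlled
approximation. The exact primary-only sech form is used for
$\kappa < 10^{-8}$/h, and $\lambda = 0$ (unseeded, no primary nucleation)
yields the identically flat curve.

**Derived times.** `t_char_of()` solves $M(t)/m_{tot} = 1/2$ by bracketing
plus root refinement (the root exists and is unique by monotonicity).
`t_lag_of()` uses the tangent construction: find the time $t^\*$ of maximal
slope and extrapolate the tangent back to baseline, clipping at zero; a
threshold variant (time to reach 10% of the plateau, configurable) is
selectable. The tangent intercept always lies at or before the half-time
for these sigmoids.

**Fitting.** `fit_trace()` minimizes least squares over
$(\log\lambda, \log\kappa, \Delta F_{pl}, \mathrm{baseline})$ with orders
fixed. Baseline and amplitude initialize from the trace extrema; without a
user-supplied start the rates are multi-started on a 5×5 log-spaced grid
centred on the observed half-rise time, the three best starts refined by
Nelder–Mead then BFGS. Rates are confined to $[10^{-6}, 10^4]$/h —
combinations outside that window are meaningless on plate-reader time
scales and can demand unbounded integration work. Traces whose dynamic
range is under five times the point-to-point noise estimate are rejected
with a "no growth phase detected" diagnostic. Replicates are fitted
individually (the pooled alternative is easy to build from the tidy trace
table but is not the default, since replicate wells differ in amplitude).

The critical concentration converts to the elongation standard free energy
as $\Delta G^0 = RT\ln(c_{cr}/1\,\mathrm{M})$, with the temperature
supplied by the caller (310.15 K, the assay temperature, as default).

## Cross-β lattice models

The structural questions the data can answer — which repeats a topology
produces, whether a residue pair can sit within 6 Å across strands — are
resolvable at centroid resolution, so the lattice model is deliberately
coarse: one backbone point and one sidechain centroid per residue, plus two
ring centroids for the azobenzene. Strands run along x at 3.4 Å per
residue (a typical β-strand pitch; configurable), stack along y at the
WAXS-assigned 4.7 Å, and sheets stack along z at 10.3 Å. Sidechain
centroids alternate ±2.5 Å normal to the sheet plane with residue parity
(the β-pleat). Antiparallel in-sheet arrangements flip alternate strands,
so residue $i$ of an up-strand faces residue $L+1-i+r$ of its neighbours at
registry offset $r$; zero offset is in-register. Antiparallel sheet
orientation flips alternate sheets. There is no fibril twist — twist is an
emergent feature of molecular dynamics, outside this package's scope — and
no energy model.

Two consequences follow directly from the geometry. In a 13-mer,
head-to-tail pairing maps index 4 (L28) onto index 10 (F34), so the
antiparallel in-register model puts L28 and F34 on adjacent strands exactly
one strand spacing (4.7 Å) apart — inside the ~6 Å detection range of a
spin-diffusion cross-peak — while the parallel in-register model separates
them by six residue rises (>20 Å). And an antiparallel sheet has a
two-strand repeating unit, adding a diffraction repeat at twice the
interstrand spacing (9.4 Å for the default 4.7 Å); a parallel sheet does
not.

The azobenzene rings are placed along the strand axis, so in-register
stacking spaces them at the interstrand distance. The π-stacking target
(3.8 Å) and the β-sheet spacing (4.7 Å) are therefore in conflict by
construction; the model records this as a flag (`pi_mismatch`) rather than
distorting the lattice, mirroring the physical tension that broadens the
experimental diffraction of the photoswitch variant. For the same variant
the intersheet spacing is experimentally unresolved (it may hide under the
9.2 Å signal); P4 models fall back to the default 10.3 Å with that caveat.

## Topology inference

Candidates are the Cartesian product of in-sheet arrangement, sheet
orientation and integer registry offsets in $[-r_{max}, r_{max}]$
(enumeration caps at offsets of ±3; at $r_{max}=0$ there are four
candidates). Parallel offsets $\pm r$ produce the same facing-pair map and
are deduplicated. Scoring checks each WAXS constraint by whether a
predicted repeat lies within 0.2 Å (the observed spread between samples —
4.6 vs 4.7 Å — motivates the default) and each contact constraint by the
model's minimum inter-strand distance against its bound. An *absent* peak
is satisfied only when no predicted repeat falls within tolerance: absence
is treated as evidence, exactly as the missing 9.4 Å reflection argues for
parallel strands. The score is satisfied minus violated; ties break
deterministically (fewer violations, smaller |offset|, parallel first).

The sheet orientation is genuinely under-determined by WAXS and the single
ssNMR bound — resolving it originally required stability simulations and
charge complementarity. An optional coarse electrostatic bonus (+1 per
oppositely charged terminal pair within 8 Å across sheets) is provided but
**off by default**, so the core ranking reflects only measured constraints.

## Coupled photoswitching–aggregation simulator

`simulate_cycles()` tracks peptide mass in three pools — cis monomer,
trans monomer, fibril — plus an optional "lost" pool. Monomers
interconvert with the photoswitch kinetics above; the trans pool feeds
fibril mass through the moment equations evaluated at the instantaneous
monomer concentration; the cis pool's rates are scaled by `cis_factor`,
default 0 (aggregation-incompetent on simulation time scales — the cis
form needs tens of hours to fibrillize). During 340 nm segments fibril
mass is released as monomer at first-order rate `k_release` (default
1.5/h, so a 5 h irradiation completes the degradation) toward a floor of
`retention` times the fibril mass at segment entry. No rate law for
photo-induced disassembly is measurable from the available observations;
first-order release with a retained floor is the minimal model consistent
with degradation being *partial*, and the default retention of 0.18
mirrors the residual trans fraction of the 340 nm PSS (trans:cis 18:82) —
the stated reason the recovery is incomplete. Released monomers enter the
cis pool, since release is driven by in-fibril trans→cis isomerization.
Whether fibrils fragment or depolymerize from their ends is not decidable
here; the release model is a declared approximation.

All inter-pool fluxes are antisymmetric, so total mass is conserved to
machine precision regardless of step size; the integrator (RK4, substeps
≤ 0.005 h) still aborts if any pool undershoots below tolerance.
Turbidity is summarized as $T = e^{-a M_{fibril}}$, a Beer–Lambert-like
proxy whose coefficient $a$ (default 3) is a display parameter — the
transmission record it emulates is qualitative. `cycle_loss` (default 0)
removes a fraction of fibril mass to the lost pool at each degradation
onset, emulating aggregates adhering to the plate walls and reproducing
the decline of successive cycle amplitudes when enabled.

## Synthetic data: what it emulates, and what a green test establishes

`gen_tht_trace()` samples the model curve at the plate reader's 5-minute
cadence and adds i.i.d. Gaussian noise (default σ = 2 a.u. against a
100 a.u. plateau, i.e. 2%, matching the visual noise level of plate-reader
data; real noise is likely heteroscedastic, which is deliberately not
modelled). A quench factor shrinks the plateau, emulating fluorescence
quenching by the azobenzene. Default generating rates (λ = 0.1/h,
κ = 0.8/h) give a lag of ~3.5 h and half-time of ~6.5 h over a 24 h trace
— the time scales of the fast-fibrillizing variants. `gen_waxs_peaks()`
jitters the predicted repeats (default 0.05 Å, a quarter of the matching
tolerance); `gen_contacts()` thresholds model distances at 6 Å. All
generators are bit-reproducible under a seed.

A green round-trip (generate → analyse → recover) therefore establishes
internal consistency of the pipeline under the stated noise model — it
does not validate the kinetic model against real plate-reader noise,
baseline drift, or the scattering artefacts of precipitating fibrils, and
the structural closure tests certify the constraint logic, not the
physical correctness of an idealized, twist-free lattice.

## Interfaces and formats

ThT traces travel as CSV (`time_h, fluorescence_au, replicate`), constraint
sets and illumination schedules as JSON, lattice models as pseudo-atom PDB
(chain per strand, segment per sheet, sub-labels as insertion codes). YAML
was considered for schedules and dropped: JSON covers the need without an
extra dependency. The design table of the parent and its twelve variants —
including the measured cis half-lives for the seven variants that have them
(63–97 h) — ships as a TSV fixture validated on load; the source material
counts "11 novel" designs in one place and lists twelve, a discrepancy the
fixture preserves by carrying all twelve rows. The package's functions are
its interface; the acceptance script under `scripts/` is the only
command-line entry point.

## Known limitations

- Reaction orders are fixed during fitting; no multi-concentration global
  fits, no oligomer-resolved kinetics, no ThT binding photophysics.
- The photoswitch model has no wavelength resolution or quantum yields;
  `k_irr` lumps intensity and cross-section.
- Lattice models are rigid, twist-free and coarse; they predict peak
  positions and centroid distances, not scattering intensities.
- The degradation law (first-order release, retained floor) is an
  assumption; only its qualitative consequences (partial degradation,
  incomplete transmission recovery) are constrained by observation.
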