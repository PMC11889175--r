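---
title: "Modeling a sodium-pumping ferredoxin:NAD+ oxidoreductase"
author: "rnfpump"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling a sodium-pumping ferredoxin:NAD+ oxidoreductase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnfpump)
```

## Scope

`rnfpump` models a membrane-bound Rnf-type complex: a
ferredoxin:NAD⁺ oxidoreductase that uses the free energy of electron
transfer from low-potential ferredoxin (E°′ ≈ −450 mV) to NAD⁺
(E°′ ≈ −320 mV) to pump 2 Na⁺ per NADH across the membrane. The package
has three layers: closed-form bioenergetics and electron-transfer (ET)
kinetics, a ten-state master-equation pump model, and structure/trajectory
analysis tools validated against deterministic synthetic generators with
known ground truth.

## Thermodynamic framework

Redox reaction free energies follow `ΔG°′ = −nF(E_acc − E_don)`. Each
output unit carries its own conventional Faraday constant — 23.061
kcal mol⁻¹ V⁻¹, 96.485 kJ mol⁻¹ V⁻¹, or 1000 meV V⁻¹ — rather than
converting between units, so every reported value matches the standard
arithmetic for that unit exactly (23.061 × 4.184 = 96.487 differs from
96.485 in the fifth digit).

```{r thermo}
fd  <- redox_couple("Fd", -450)
nad <- redox_couple("NAD+", -320)
reaction_free_energy(fd, nad, n = 2)                 # kcal/mol
reaction_free_energy(fd, nad, n = 2, units = "meV")  # meV, exact
```

Pumping stalls when the sodium-motive force (SMF) consumes the full
per-electron driving force: `breakeven_smf()` divides the driving force by
the Na⁺/e⁻ stoichiometry. Redox-coupled Na⁺ binding is treated as a
thermodynamic cycle: if the site binds Na⁺ more tightly when the adjacent
cluster is reduced, the difference in binding free energies must appear as
a midpoint-potential shift `ΔE_m = ΔΔG_bind / F`
(`binding_redox_shift()`). With oxidised/reduced binding energies of
−1/−3 kcal mol⁻¹ the shift is ≈ 87 mV; with 0/−3 it is ≈ 130 mV. Both
parameterizations are exposed rather than choosing one, since the coupling
strength is a model input, not a derived quantity.

## Electron-transfer kinetics

Inter-cofactor tunneling rates use the empirical distance ruler

log₁₀ k = 15 − 0.6 R − 3.1 (ΔG + λ)² / λ

with the edge-to-edge distance R in Å and ΔG, λ in eV (default
λ = 0.7 eV). Conformational steps use the Eyring form
`k = κ (k_B T / h) exp(−ΔG‡ / RT)` at 310 K, and reverse rates always come
from detailed balance, `k_rev = k_fwd exp(ΔG / RT)`. A serial chain's
overall time is the sum of inverse forward rates — a deliberate
lower-bound approximation that ignores back-transfer; the full kinetics
live in the master-equation model. At the complex's 15–20 Å spacings and
−0.13 eV total drop, a six-hop chain takes tens of milliseconds, which is
the observed catalytic timescale: the wire itself is rate-limiting, so
coupling steps must be at least that fast.

## The ten-state pump cycle

`build_canonical_cycle()` constructs states i–x covering two
Na⁺-translocation strokes (each: ET into the gating cluster, Na⁺ uptake
from the inside, inward→outward conformational change, ET out plus Na⁺
release outside) followed by hydride transfer to NAD⁺. Key parameters
(`cycle_params()`):

| parameter | default | meaning |
|---|---|---|
| `fd_mV`, `nad_mV` | −450, −320 | terminal midpoint potentials |
| `dG_bind_oxidized_kcal`, `dG_bind_reduced_kcal` | −1, −3 | Na⁺ site affinity by cluster redox state |
| `barrier_conf_reduced_kcal`, `barrier_conf_oxidized_kcal` | 4, 10 | conformational barrier with/without reduction |
| `barrier_binding_kcal`, `barrier_hydride_kcal` | 3, 5 | uptake and hydride barriers |
| `electrogenic` | 0.3/0.4/0.3 | charge moved per step (uptake/translocation/release) |
| `na_per_cycle` | 2 | pumped stoichiometry |
| `temperature_K` | 310 | physiological temperature |

Design decisions:

- **Exact closure.** The step free energies around the cycle must sum to
  `ΔG_rxn + n_Na F·SMF`. The two release steps absorb the remainder of the
  per-stroke ET free energy after uptake and the conformational step, so
  closure holds identically; `cycle_closure_check()` verifies it and
  `build_canonical_cycle()` refuses inconsistent parameter sets.
- **Electrogenicity constraint.** The per-step electrogenic fractions of
  each stroke must sum to `na_per_cycle / 2`, i.e. the charge bookkeeping
  matches the stoichiometry. Setting `na_per_cycle = 0` with zero
  electrogenic fractions yields an uncoupled cycle whose kinetics are
  SMF-invariant — a built-in control.
- **Symmetric SMF split.** The SMF contribution of each electrogenic step
  is split half onto the forward rate and half onto the reverse rate. Any
  split preserves the equilibrium constant; the symmetric choice avoids
  biasing barrier heights and makes the break-even point depend only on
  thermodynamics.
- **Steady state via null space.** The generator matrix `K` (columns sum
  to zero) is solved by SVD null space with a strong-connectivity check;
  at break-even every edge flux vanishes (global detailed balance), which
  the tests assert to within 10⁻⁶ of the slowest rate.

```{r cycle}
m <- build_canonical_cycle()
cycle_closure_check(m)
steady_state(m)$na_flux          # Na+/s at SMF = 0
steady_state(m, smf_mV = 130)$na_flux  # ~0 at break-even
```

A `"fd-low"` preset (`make_cycle_params("fd-low")`) uses E°′(Fd) =
−500 mV, moving break-even to 180 mV — relevant when the physiological
SMF exceeds 130 mV.

Time courses: the deterministic path integrates the master equation with
`deSolve::ode` (lsoda, rtol 10⁻⁹ / atol 10⁻¹²) plus an auxiliary state
accumulating pumped Na⁺; the stochastic path is an exact Gillespie
sampler. Because the cycle's fastest rates reach ~5×10¹⁰ s⁻¹, exact
event-driven sampling to steady state would require ~10⁹ events per
trajectory; the samplers are therefore cross-validated on fast transients
(and on small non-stiff models over long horizons), where the two
independent code paths must and do agree within Monte-Carlo error.

## Structure and cofactor analysis

Structures load through `bio3d` (PDB and mmCIF). Cofactors are grouped
from HETATM records (SF4, FES, FMN, RBF, NAD; unrecognized Fe-containing
residues are kept with a warning). Conventions:

- **Iron inventory** is a hard count: 4 per 4Fe–4S, 2 per 2Fe–2S. Variant
  deltas (`variant_fe_delta()`) are computed by removing the named
  cofactor, so a missing 2Fe–2S cluster costs exactly 2 Fe.
- **Edge-to-edge distances** are minimum heavy-atom separations. Two
  conventions are exposed: `all-heavy` and `conjugated-only` (flavins
  restricted to the isoalloxazine ring, the ET-active moiety). The
  conjugated-only distance can only be larger; both are reported rather
  than choosing silently.
- **ET chains** (`build_et_chain()`) pick, among all simple paths whose
  every hop is below a distance ceiling (default 25 Å), the one with
  minimal total distance; ties break on fewer hops, then lexicographic
  order, so results are reproducible. When endpoints are disconnected the
  bottleneck gap (the smallest ceiling that would connect them) is
  reported instead.
- **Ligand detection** takes S/O/N atoms within 2.6 Å of any cluster Fe,
  one closest atom per residue, and warns above four donors per cluster.

## Trajectory analysis

- **Conformational classification** compares inner- and outer-gate
  distances to open/closed thresholds (defaults 9/6 Å) with the band
  between them split at its midpoint, making labels independent of frame
  order. Frames with both gates open are labelled `leak` and counted — in
  an alternating-access pump they indicate either a sampling artifact or
  genuine uncoupling, so they are surfaced rather than folded into another
  class.
- **PMFs** come from Boltzmann inversion, `F = −RT ln p`, on a 2D
  histogram (default 25×25), shifted so min F = 0, with empty bins `NA`
  (not zero — absence of samples is not infinite free energy evidence,
  and downstream fits must exclude them). The implementation is validated
  by recovering the analytic curvature `RT/σ²` of a sampled Gaussian to
  within a few percent.
- **Pathway continuity** voxelizes the protein (van der Waals radii plus
  a 1.4 Å probe, default 0.8 Å grid) and flood-fills 6-connected free
  voxels from the cytoplasmic face; a pathway exists if the fill reaches
  the far face. The test is conservative in the probe radius: enlarging
  the probe can only close pathways, which the tests verify.

## Synthetic generators and what the tests show

`make_toy_complex()` emits a PDB with 15 cofactors in a linear chain
(10 × 4Fe–4S, 1 × 2Fe–2S, 3 flavins, 1 riboflavin; 42 Fe total), four
ligating cysteines at 2.3 Å, an Arg–Glu ion pair, gate atoms, and a
membrane slab with an optional bore. `make_two_state_trajectory()` emits
an alternating-access trajectory from a two-state Markov chain (stationary
inward fraction 0.6) with redox-conditional buried-site Na⁺ occupancy and
state-conditional ion-pair opening, plus a per-frame ground-truth table.
Both are byte-reproducible under a seed, and bulk ions are kept > 3 Å from
the buried site so occupancy is recoverable from coordinates alone.

Passing the recovery tests shows that the analysis pipeline inverts its
own generative model at realistic noise levels — selection, classification,
fractions, densities, PMFs and continuity all recover the generating
parameters within correctly-propagated statistical tolerances (binomial
for independent draws; Markov-chain CLT with variance inflation
(1+ρ)/(1−ρ) for the autocorrelated state sequence, where a naive binomial
band would spuriously reject). It does **not** show that the pipeline is
robust to force-field artifacts, periodic-boundary wrapping, or
non-Markovian gating found in real simulation data.

## Limitations

- The cycle model is a single-complex Markov model: no explicit membrane
  potential vs ΔpNa split (the SMF enters as one electrochemical term), no
  slip transitions, and no substrate-concentration dependence.
- The tunneling ruler's coefficients are the standard generic values; the
  inter-cofactor distance defaults are representative spacings, not
  measurements of a specific structure, and should be replaced with
  distances from `build_et_chain()` on a real model when available.
- Pathway continuity is geometric only — no electrostatics or dynamics —
  and depends on the probe radius; defaults correspond to a water-sized
  probe.
- The stochastic sampler is exact but cannot practically reach steady
  state on the stiff ten-state cycle; use the deterministic path (or
  `steady_state()`) for long-time behaviour.
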