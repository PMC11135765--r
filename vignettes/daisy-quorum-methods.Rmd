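---
title: "Daisy quorum drive: model, assumptions and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Daisy quorum drive: model, assumptions and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model implemented by `daisyquorum`,
the assumptions baked into it, the numerical choices behind every analysis
routine, and the limits of what the package's simulations can say about
real populations.

## 1. The genetic system

A daisy quorum construct has two components on a genome of `n + 2` loci:

* **Daisy chain** (loci A₁, …, Aₙ₋₁, B): each locus carries CRISPR
  machinery whose guide RNA targets the wildtype allele at the *next*
  locus; the last driver B carries two guides targeting the wildtype
  alleles at both cargo loci.  Nothing targets the first locus, so the
  chain cannot sustain itself.  Every daisy allele also carries a
  deleterious element, the *drive load* `s_d`, acting multiplicatively:
  an individual carrying `j` daisy alleles pays `(1 - s_d)^j`.
* **Fitness valley cargo** (loci C and D): each engineered allele carries
  a toxin, the matching antidote for the *other* locus's toxin, and the
  payload.  An individual with engineered alleles at exactly one of the
  two cargo loci expresses an unsuppressed toxin and pays `1 - s_t`; the
  payload costs `1 - s_p` and is dominant by default.  Rare cargo alleles
  are therefore selected against, common ones favoured: a two-peaked
  fitness landscape whose interior unstable equilibrium sets the
  introduction threshold (the "quorum").

The intended behaviour, which the simulations reproduce, is a relay: the
chain temporarily biases transmission of the cargo and pushes it over its
threshold, then selection against the drive load removes every CRISPR
element, leaving only the high-threshold construct, which resists both
reinvasion by wildtype migrants and onward spread into neighbouring
populations.

### Assumptions

* Diploid, randomly mating population; discrete non-overlapping
  generations; no sex differences.
* Homology-directed repair always succeeds when conversion happens:
  resistance alleles arising from end-joining are **not** modelled.  This
  is a best-case assumption, defensible mainly because the chain drives
  only transiently; taxa with inefficient homology-directed repair are
  outside the model's scope.
* No mutation, no off-target effects, no genotype-by-environment
  interaction; fitness components multiply across loci.
* The deterministic modules assume an effectively infinite population;
  finite-size effects are handled by the stochastic module only.

### Conversion semantics

Conversion happens in the germline and is judged on the **birth
genotype**: for every driver locus at which the diploid carries at least
one engineered allele, a *heterozygous* target locus is converted to
engineered-homozygous with probability δ; a homozygous-wildtype target has
no engineered template and is never converted.  Conversions at distinct
targets (including C and D under the last driver) are independent.
Recombination follows conversion.

Two facts are worth recording.  First, judging all conversions on the
birth genotype is provably identical to a sequential cascade down the
chain: conversion only acts on heterozygous targets, and at a heterozygous
target the driver allele of the following step is already present, so
"newly converted" drivers never enable a conversion that was not already
enabled.  Second, treating the two cargo-locus conversions as independent
events (rather than one joint cut-both-or-neither event) is what makes the
linearised growth rate of the rare CD haplotype come out as
`(1 - s_p)(1 + δ_c² - r(1 - δ_c)²)`; the joint variant gives a different
(and inconsistent) invasion boundary.  Independence is therefore not a
free choice here.

### The recursion

The census is at gametes.  One generation is random union → diploid
selection → conversion → meiosis:

    X'_g ∝ Σ_{g1,g2} X_{g1} X_{g2} W(g1,g2) P(g | g1,g2),

normalised by the mean fitness (sum of numerators).  The engine
precomputes `W` and `P` over all `2^(n+2)` gametes once per model object;
a generation is then two matrix products, and a matrix of per-patch states
can be advanced in a single call.  Segregation probabilities are computed
by a forward recursion over loci that tracks which parental chromosome the
gamete is currently copying, with adjacent recombination fractions
(`R` between daisy loci, 0.5 between chain and cargo by default, `r`
between C and D).  A state whose mean fitness is exactly zero (every
genotype present is lethal) raises an explicit degenerate-state error
rather than returning NaNs.

## 2. Fitness schemes

All schemes are normalised so that the fully engineered cargo genotype
CD/CD has fitness `1 - s_p`; they differ in how partial genotypes express
the payload:

* **dominant** (default): `1 - s_p` whenever at least one engineered
  cargo allele is present.  This is the only scheme under which fixation
  of the construct is (marginally) stable — at fixation, rare single
  engineered haplotypes are selectively neutral at linear order, and the
  equilibrium attracts through second-order terms.
* **multiplicative**: `(1 - s_p)^(k/4)` with `k` the number of engineered
  cargo alleles (payload expression proportional to dose, within and
  between loci).  A double heterozygote Cd/cD then out-competes the CD/CD
  homozygote while also escaping the toxin, so fixation is unstable and
  the high-frequency attractor is an interior equilibrium.
* **recessive**: `(1 - s_p)^(h/2)` with `h` the number of cargo loci
  homozygous for the engineered allele.

The normalisation (full genotype always at `1 - s_p`) was chosen over a
naive per-allele factor `(1 - s_p)^k` because only the normalised forms
reproduce the critical payloads at which the interior equilibria of the
valley subsystem vanish under both a weak and a lethal toxin load
(sections 4 and 6), and because they keep `s_p` comparable across schemes.

Two further valley variants are provided: a **haploinsufficient gene
swap**, where the construct exchanges two dosage-sensitive genes between
the loci — an individual needs two functional copies of each (c-or-D, and
d-or-C) and pays `1 - s_t` when deficient — and a **single-allele
multiplicative payload** (`dhole_champer`), the fitness regime of earlier
two-locus toxin–antidote studies, with the payload on allele C only.  A
**cargo-only** mode (single payload locus, no toxin) serves as the
plain-daisy-chain comparison case.

## 3. Single-population analyses

**Trajectories** (`simulate_population`) release the engineered gamete at
frequency `f0` immediately before reproduction, the remainder wildtype.

**Release thresholds** (`release_threshold`, `separatrix_threshold`)
bisect `f0` to a tolerance of `1e-3` (`1e-4` for the valley-only ray).
Success means the engineered C-allele frequency exceeds 0.99 **at** the
horizon (500 generations by default).  Evaluating at the horizon, not "at
any time", matters: a release near fixation starts above 0.99 and then
collapses, and must not be counted as a success.  The 0.99 criterion is
used because the deterministic recursions approach fixation only
asymptotically; the default horizon is long enough that the reported
thresholds are insensitive to doubling it, except within one bisection
step of the boundary.

**Equilibria** (`find_equilibria`) exploit the symmetry `X_cD = X_Cd` of
any CD-release trajectory: interior symmetric fixed points are found by
Newton iteration (finite-difference Jacobian, step `1e-7`) from a 60-point
grid of starting values, merged at distance `1e-6`, with residuals below
`1e-10`.  Stability is classified from the eigenvalues of the
numerically differentiated map (central differences, step `1e-6`, in the
three free coordinates).  When the leading eigenvalue sits on the unit
circle — as it always does at construct fixation under a dominant payload
— a nonlinear probe decides: the state is displaced 1% towards the
simplex centre, iterated 500 generations, and classed stable/unstable/
marginal according to whether the displacement shrank below 0.9× its
initial size, grew beyond 3×, or neither.  The neutral model
(`s_t = s_p = 0`), where every linkage-equilibrium state is a fixed point,
is correctly reported as a family of marginal equilibria.

**Invasion analysis** (`invasion_eigenvalues`, `critical_drive_force`).
The *drive force* δ_c is the conversion probability currently experienced
by the cargo: δ times the frequency of driver-B carriers among cargo-locus
heterozygotes (`effective_drive_force`; 0 by convention when no
heterozygotes exist).  Holding δ_c constant, the rare cargo grows through
two routes with linearised rates

    λ1 = (1 + δ_c)(1 - s_p)(1 - s_t)          (single allele, pays the toxin)
    λ2 = (1 - s_p)(1 + δ_c² - r(1 - δ_c)²)    (intact CD haplotype, broken by recombination)

λ2 was re-derived from the branching process of a rare CD haplotype on a
wildtype background with independent conversion at both loci; it agrees
with the numerically linearised recursion to better than `1e-6` (a test
asserts this) and yields, at free recombination, the critical force
`δ_c* = √(2/(1 - s_p)) − 1`, which equals 1 exactly at `s_p = 1/2` — a
dominant payload costing more than half can never invade.  The toxin load
at which the interior unstable equilibrium sits exactly at allele
frequency 1/2 has the closed form

    s_t = s_p √( r / (2 (1 - s_p) (2 r (1 - s_p) - s_p)) ),

validated against the numerically located equilibrium at several payload
values (the equilibrium lands at 0.5 to `1e-6`).

## 4. Interior-equilibrium disappearance scans

For the multiplicative and recessive payload schemes the interior stable
and unstable equilibria approach each other as `s_p` grows and annihilate
at a critical payload.  `payload_vanishing_point` scans `s_p` upward at a
resolution of 0.001, tracking the equilibria by continuation (the previous
step's solutions seed Newton's method; a full grid search confirms any
apparent absence).  At `s_t = 0.1, r = 1/2` the scans place the
annihilation at `s_p = 0.106` (multiplicative; 0.11 to two decimals) and
`s_p = 0.097` (recessive) — in the recessive case the pair is gone by
0.097 even under a 1200-point start grid, so the critical value lies
between 0.096 and 0.097 in this implementation.

## 5. Spatial models

**Stepping stone** (`run_spread`, `migration_sweep`,
`swamping_threshold`): `M = 101` patches in a line; per generation,
interior patches first exchange a fraction `m/2` of their gamete pool with
each neighbour (boundary patches keep `1 − m/2` and trade `m/2` with their
single neighbour, making the kernel doubly stochastic), then each patch
runs one generation of local dynamics.  *Spread extent* is the number of
patches with payload-allele frequency above 0.5 at the horizon (1000
generations), matching how the space–migration phase diagrams are read:
confinement (low `m`), expansion (intermediate `m`), and gene swamping
(high `m`, where wildtype immigration holds the release patch below its
quorum).  The swamping threshold is found by bisection on `m` between a
rate that establishes and one that fails.

**Continuous space** (`build_landscape`, `run_reaction_diffusion`,
`asymptotic_wave_speed`, `patchiness_sweep`): space is a chain of cells;
per substep of length `dt` a cell sends `D·dt/d²` of its population across
each edge, with `d` the distance between cell centres.  The classical
stability condition `D·dt/dx² ≤ 1/2` is enforced for homogeneous grids
(the defaults `D = 0.2, dt = 0.1, dx = 0.25` give hop probability 0.32);
on random landscapes, built by drawing boundary positions uniformly over
the domain (seeded, reproducible), hop probabilities are capped at 0.45 so
that arbitrarily short edges stay valid — a capped pair of cells simply
behaves as well-mixed, while wide gaps act as dispersal barriers.  A
point-release variance test pins the discretisation to Var = 2Dt.

Each generation of local dynamics is split into `1/dt` partial updates
interleaved with diffusion, `x ← (1 − dt)·x + dt·f(x)` with `f` the
one-generation map — a fractional-interpolation approximation of
continuous time that reuses the exact discrete-generation engine.  The
front is the position where the payload-allele frequency crosses 0.5
(linearly interpolated); the *left* front is tracked, which is the robust
choice on heterogeneous landscapes where the two fronts pin independently.
The asymptotic speed is the least-squares slope over the final 25% of the
recorded front positions, sign-flipped so that positive means expansion;
if the front is absent from the fit window (never formed, or contracted
out of existence) the result is flagged rather than fitted.

Default problem sizes: domain `L = 200` with 800 cells, runs of 1400
generations for asymptotic speeds and a release half-width of 55 spatial
units, chosen so that even a construct contracting at the observed
~0.036 spatial units per unit time retains a front throughout the fit
window.  The refinement check (halving `dx` changes the contraction speed
by about 2%) supports treating these grids as effectively continuous.

## 6. Stochastic demography

The individual-based module tracks integer counts of diploid genotypes per
patch.  One generation: each individual migrates to an adjacent patch with
probability `m` (boundary patches `m/2`, mirroring the deterministic
kernel); each patch then produces `Poisson(N·F·W̄)` offspring, truncated
at the carrying capacity `K` (uniform culling), where `F` is the fertility
at low density and `W̄` the patch's mean relative fitness.  Offspring are
formed by drawing two gametes independently from the patch's
fitness-weighted gamete output pool — exactly equivalent to sampling two
parents proportional to fitness and one gamete from each parent's
drive-aware meiosis, because parents are sampled with replacement.  The
offspring-number model (Poisson, then truncation) is deliberately the
simplest scheme in which `F·W̄` acts as a replacement-rate threshold near
1; it is isolated in one function so alternatives can be swapped in.

With `F = 1.2` and a payload of 0.1 a patch persists after fixation
(`1.2 × 0.9 > 1`): population modification.  With `F = 1.05` fixation is
followed by deterministic decline to extinction (`1.05 × 0.9 < 1`):
suppression, with wildtype recolonisation from neighbouring patches when
migration reconnects them.  The tests exercise these regimes at `K` =
2000 (and the weak-convergence check at `K = 10⁵` against the
deterministic recursion); the replicate summaries report per-generation,
per-patch medians and quartiles from a single seeded stream, so they are
bitwise reproducible.

## 7. What the scenario generator does and does not emulate

The preset scenarios (`dqd_preset`) reproduce published parameter regimes:
conversion probabilities 0.9–0.95 (achieved experimentally in several
insect systems), drive loads 0.02–0.1, a strong toxin (0.9) with payloads
0.1–0.35, free recombination throughout, central releases at `f0 = 0.05`.
They emulate the *genetics* of the design faithfully, but not: resistance
evolution (the main empirical threat to any CRISPR-based system), sex
structure and sex-specific fitness, age structure or overlapping
generations, mate-finding at low density, density-dependent dispersal, or
two-dimensional landscape geometry (the 1-D patchiness sweep covers the
qualitative effect of clumping; true 2-D range dynamics are out of scope).
Passing tests therefore demonstrate internal correctness of the model and
its analyses — not field efficacy.

## 8. Known limitations and open edges

* The release threshold of longer chains is extremely sensitive to the
  drive load, which sets how many generations the relay keeps pushing:
  for the three-driver chain at δ = 0.95 and `s_d = 0.1` the bisection
  threshold is 0.069, and it falls steeply as the load is lightened.
  Designs relying on long chains should treat `s_d` as the critical
  engineering parameter.
* Construct fixation under a dominant payload is only marginally stable
  (leading eigenvalue exactly 1); convergence to fixation is algebraic,
  which is why fixation criteria are phrased as frequency-0.99 crossings.
* The stepping-stone swamping boundary is an empirical bisection output
  (about 0.093 at the reference parameters), not a sharp analytic
  constant; it depends on the release size and the topology.
* Wave speeds are asymptotic fits; on finite domains the fit window must
  not include the transient drive-driven expansion, and the defaults are
  sized accordingly.  Runs shorter than ~1000 generations at the
  reference parameters report transient, not asymptotic, speeds.
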