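---
title: "Fermenter scale-up: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fermenter scale-up: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermscale)
```

`fermscale` implements the desk-engineering chain for scaling an ungassed,
anaerobic stirred-tank fermentation from bench to industrial scale. This
vignette is the package's account of the underlying models, the conventions
it had to pin down where practice is ambiguous, and what its tests do and do
not establish.

## The hydrodynamic model

The mixing state of a vessel is summarized by the impeller Reynolds number
$Re = \rho N D^2 / \mu$. Above $Re = 10^4$ the power number $Po$ of an
impeller is constant and the power drawn by $n$ identical stages is

$$P = n \, Po \, N^3 D^5 \rho ,$$

the sum of single-impeller draws (valid for optimally spaced stages). All
internal speeds are in s^-1^; rpm appears only at interfaces
(`rpm = 60 N` exactly).

**Flow regimes.** Turbulent for $Re > 10^4$, laminar for $Re \le 10$
(where $Po = K_L / Re$), transition in between. The laminar boundary is
inclusive — a measure-zero convention that matters only for exactly-at-limit
inputs. The laminar drag constants $K_L$ are chart-order defaults
(Rushton 64, concave 64, pitched 44.5, A310 40, A315 43, propeller 41) and
fully user-configurable; none of the shipped analyses operate there.

**Transition handling.** Published $Po$–$Re$ charts dip below the turbulent
plateau in transition. The correlation table therefore carries an optional
per-type `transition_po`; when absent, the turbulent constant is used with a
warning. The bundled case-study correlation sets `transition_po = 4.58` for
the Rushton turbine — the chart-read value at the laboratory operating point
($Re \approx 1.8\times10^3$), which is what makes the laboratory power and
dissipation chain consistent with the rest of the bundled reference table.
It is a single-point value: it applies to that neighbourhood of $Re$, which
is why the scaled-up operating points do not use it (below).

**Derived state.** At steady state the impeller power dissipates into the
broth mass, so the mean specific energy dissipation rate is
$\varepsilon_t = P / (\rho V_w)$ — per unit *mass* of liquid, always on the
working volume. The Kolmogorov microscale
$\lambda_k = (\nu^3/\varepsilon_t)^{1/4}$ then screens shear risk: cells
smaller than $\lambda_k$ sit inside the smallest eddies and are considered
safe (margin $= \lambda_k /$ cell size, safe iff $> 1$).

**Two specific-power bases.** Industrial practice quotes $P/V$ both per
working volume (scale-up correlations) and per total vessel volume (design
windows, e.g. 2–4 kW m^-3^). Both are first-class in `specific_power()` and
every result object carries both; there is no silent default volume. Mixing
the two silently is the single most common error in these calculations.

**Two torque conventions.** The physical shaft torque is $P/(2\pi N)$.
Industrial sizing sheets often use the horsepower/rpm formula
$T = (P \cdot 63025 / rpm) \times 0.112985$ *fed with kilowatts*, which
skips the kW-to-hp conversion and lands at exactly $0.7457\times$ the
physical value (the 745.7 W-per-hp constant re-emerging from the
63025/0.112985 chain). `impeller_torque()` exposes both modes — default
`"physical"`, with `"hp_formula"` available because design tables built on
that convention are common and must be reproducible bit-for-bit.

## Geometric similarity bookkeeping

Similarity across scales means preserving $D/T$, $H/T$ and $Z/T$. Real
vessels bought at market sizes do not comply, so the package separates:

- the cube-root linear scale factor $(V_2/V_1)^{1/3}$, which maps linear
  dimensions between ideally similar vessels, and
- the *similarity ratio* $Z_{calc}/Z_0$, where
  $Z_{calc} = (Z/T)_{target} \times T$ is the liquid height the vessel would
  need at the reference aspect ratio, against its actual height $Z_0$.

These are deliberately not forced to agree. The bundled industrial case uses
$(Z/T)_{target} = 1.33$ (the convention that reproduces its reference
geometry table; the alternative anchoring at the laboratory 1.37 gives 6.16 m
instead of 5.99 m and does not). When the calculated height occupies less
than 80% of the actual height — the customary working-volume floor —
`occupancy_percent()` warns rather than errors, and the pilot-scale
similarity ratio (0.81) can be transferred with `apply_similarity_ratio()`
to restore a realistic fill (9.29 m for the industrial vessel).

Volumes are always independent inputs: torispherical heads and freeboard
make $\pi/4\,T^2 Z$ a biased estimate of real working volumes, so no
cylinder cross-check is enforced. (The *synthetic* generator, which only
feeds property tests, does use the cylinder formula for self-consistency.)

## The scale-up rules and their deliberate disagreement

Constant mixing performance between working volumes $V_{w1} \to V_{w2}$ is
imposed through two empirical power laws:

$$\left(\frac{P}{V_w}\right)_2 = \left(\frac{P}{V_w}\right)_1
  \left(\frac{V_{w1}}{V_{w2}}\right)^{0.37}, \qquad
  \frac{N_2}{N_1} = \left(\frac{V_{w2}}{V_{w1}}\right)^{0.21}
  \left(\frac{D_1}{D_2}\right)^{5/3}.$$

The exponents (0.37 from industrial survey data; 0.21 and 5/3 from
rearranging the turbulent power expression under the 0.37 rule) are
configuration arguments, not literals buried in the arithmetic. `scaleup()`
computes the target speed from the second rule, then evaluates the *actual*
power at that speed via $P = n\,Po\,N_2^3 D_2^5 \rho$, and reports the first
rule's direct prediction alongside. The two disagree (pilot case: 2.56 W
actual vs 2.35 W predicted) because the speed rule composes through discrete
geometry; both numbers are surfaced and never averaged — hiding that gap is
how scale-ups get over- or under-powered.

The scaled operating point always uses the **turbulent** power number even
if $N_2$ lands below $Re = 10^4$ (a warning is emitted): the rules are
derived under turbulent similarity, and a transition-regime chart value read
at a different Reynolds number would be wrong there. The *source* case, by
contrast, is characterized with the supplied correlation at its own regime.

**Impeller staging.** The clearance rule
$(Z-2D)/(2D) < n < (Z-D)/D$ bounds the stage count. A strict open interval
rejects selections that practice accepts (two stages at 1.95 diameters of
headroom), so `feasible_impeller_counts()` adds a tolerance `tol = 0.1` to
the upper bound — the value that reproduces conventional picks (2 stages at
$Z=5.99$ m, 3 at 9.29 m, $\{2,3\}$ at 8.6 m with the bundled diameter) —
and selects the maximum feasible count (the conservative choice).
`tol` is an argument, documented, and the strict bounds remain available via
`impeller_count_bounds()`.

**Target diameter.** Precedence: an explicit diameter on the target case,
then a Reynolds anchor (inverting $Re = \rho N D^2/\mu$ at a reported
Reynolds number), then cube-root geometric scaling. The bundled cases use
Reynolds anchors because their campaign reported $Re$ but not $D$; the
derivations live in the fixtures' `provenance` attribute and are re-derived
in tests, not trusted as constants.

## Design matrix, selection, motor

`build_design_matrix()` evaluates six impeller types across an agitation
ladder (default 17–150 rpm, the 0.83–2.5 s^-1^ band reported effective
for lactic acid fermentations, plus the scaled-down 17 rpm point) at 2- and
3-stage counts, all sharing the vessel's shaft diameter. Selection then
applies, in order: the 2–4 kW m^-3^ total-volume window, the Kolmogorov
shear screen at each cell's own dissipation rate, and maximum torque with
ties broken toward lower power. On the bundled case this yields the Rushton
turbine at 1.33 s^-1^, with 1.9 times the torque of the A315 hydrofoil
running at 2.5 s^-1^ for near-identical specific power.

Motor sizing multiplies the shaft power by a 1.5 service factor (motor,
bearing and gearbox losses) and rounds up a user-replaceable ladder of
market ratings. With the window value $2.88$ kW m^-3^ $\times\ 207$ m^3^
this lands on 900 kW. The case study's quoted 1.2 MW installed size for the
9.29 m variant is *not* reproducible under any single rounding convention we
could verify (1.5 × 1293.8 kW = 1941 kW); the sizing op is therefore generic
and that figure is flagged rather than special-cased.

## Gate-to-gate LCA

The impact model is deliberately minimal: one flow (grid electricity for
agitation), one functional unit (1 m^3^ substrate processed). Energy
intensity is $E = P \cdot t_{batch} / V_{substrate}$ with defaults
$t_{batch} = 20$ h (a 20 h-per-day campaign) and substrate volume equal to
the working volume — both explicit assumptions, both arguments.
Characterization factors for the eight CML categories (AP, EP, FAETP, GWP,
HTP, ODP, POCP, TETP) are **user configuration**, not bundled constants:
they depend on grid mix and database vintage, and no defensible default
exists inside the package. Consequences of the single-flow structure, which
the tests assert as invariants: impacts are exactly linear in energy, and
the ranking of options is identical in every category. Absolute impact
values are only as good as the supplied factors; the package makes no claim
about them.

`scenario_sweep()` varies the working height (and optionally $H/T$, which
at fixed total height slims the tank and shrinks the impeller at constant
$D/T$) and averages specific power and impacts over the feasible stage
counts — arithmetic mean by default, matching the count-averaged values the
bundled reference quotes, with `min`/`max` policies selectable. The averaged
curve is piecewise constant in $Z$, jumping exactly where the feasible count
set changes; infeasible grid points are recorded as gaps, not errors.

## The synthetic scenario generator

`random_fermenter_case()` samples broth density 950–1200 kg m^-3^,
viscosity 0.001–0.02 Pa s, working volume log-uniform over 10^-3^–10^3^
m^3^, $D/T \in [0.3, 0.5]$, $Z/T \in [1, 3]$, $H/T \in [1.5, 3.5]$, speed
0.2–5 s^-1^ and a uniform impeller type — ranges bracketing real
fermentation duty. It emulates *parameter* diversity, not real-broth
physics: Newtonian rheology only, cylindrical volume bookkeeping, no
aeration, no rheology drift over a batch. Passing property tests on these
cases therefore demonstrates the algebraic invariants (homogeneity,
transitivity, round-trips, rank preservation) across the physical range —
it does not validate the correlations against new experimental systems. The
generator feeds property tests only; the replication suite runs exclusively
on the fixed case-study fixtures.

## Numerical and degenerate-input choices

- Closed-form arithmetic throughout; no iteration, no tolerance tuning.
  Every analysis in the package runs in well under a second.
- Validation is strict and names the offending field and unit; supplying a
  kinematic viscosity inconsistent with $\mu/\rho$ by more than 2% is an
  error (independent rounding of measured values is absorbed, unit mistakes
  are not). The bundled laboratory fluid exercises exactly that slack
  (stated $6.36\times10^{-6}$ vs derived $6.415\times10^{-6}$ m^2^ s^-1^).
- Zero dissipation has no finite microscale and is rejected; zero speed has
  no finite torque and is rejected; `moisture > initial` mass is a domain
  error in the total-solids utility.
- Selection ties on torque break toward lower power; selection output is
  invariant to the row order of the design matrix.
- The replication table (`replicate_case_study()`) compares at 1% per cell
  (0.5% for scaled speeds). Two dissipation-rate cells of the reference
  table are internally inconsistent with the table's own printed powers at
  the 1% level (its laboratory power implies 0.0808 W kg^-1^ against a
  printed 0.080; its industrial power implies 0.0430 against a printed
  0.042, while the printed 245.1 µm microscale back-implies ~0.043); those
  two cells are excluded from the replication table and the discrepancy is
  asserted honestly — and left failing — in the acceptance suite rather
  than masked by a wider tolerance.

## Problem sizes used in the tests

Unit and property tests run the closed-form operations on the three bundled
cases plus seeded batches of 10–200 random scenarios per property — ample
for algebraic invariants that hold exactly, chosen so the whole suite stays
interactive. The acceptance script recomputes the scale-up chain, the
microscale conversions and the working-height sweep on the industrial case
from scratch at every run.

## Known limitations

No gassed-power correction, oxygen transfer or $k_La$ model (the target
process is anaerobic and ungassed); no non-Newtonian rheology; no CFD; no
mechanical shaft or gearbox design; no multi-flow LCA inventories
(chemicals, water, nutrients) or upstream/downstream stages; no uncertainty
propagation. Constant-tip-speed and constant-mixing-time scale-up
strategies are out of scope. Within that scope, every number the package
reports is a closed-form consequence of the stated inputs and conventions.
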