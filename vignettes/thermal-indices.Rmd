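---
title: "Thermal indices and mean radiant temperature: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal indices and mean radiant temperature: models, parameters, design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`thermidx` computes the rational human thermal indices PMV, SET*, PET,
mPET and UTCI from point meteorological records, together with the
auxiliary quantities they need: vapour pressure / relative humidity
exchange, wind at the 1.1 m biometeorological reference height, and a
simulated mean radiant temperature `Tmrt`.  This vignette explains the
models, the parameters that matter, and every place where the design
was genuinely open and we had to freeze a choice.

## Shared primitives

**Saturation curve.**  All humidity conversions use the Magnus form
over liquid water, `es(Ta) = 6.107 * 10^(7.5 Ta / (237.3 + Ta))` hPa,
for all temperatures.  No ice branch is used: the constant set follows
the Munich energy-balance (MEMI) tradition, and a single branch keeps
the VP/RH round trip an exact identity.  Supersaturated station
records (VP above saturation) warn and cap RH at 100 % instead of
erroring, because real archives contain them.

**Wind profile.**  Heights are exchanged with a power law
`v(z2) = v(z1) (z2/z1)^p` with the open-terrain exponent `p = 0.12`.
The same profile (and exponent) is used in both directions: reducing
10 m station winds to 1.1 m, and raising the package-wide 1.1 m input
back to the 10 m height required by the UTCI polynomial.  The exponent
is exposed as an argument; the source material names only an
"exponential function", so exact numeric agreement with any particular
original implementation is not claimable.

**Subject.**  A standard subject (work 80 W above basal, 1.75 m,
75 kg, 35 y, male, standing) is the default everywhere.  Basal
metabolism uses the Harris-Benedict-type fit of the MEMI tradition
(sex-specific, in W for the whole body); the same basal model feeds
PMV, SET*, PET and mPET so that the indices are comparable.  PMV also
accepts a direct `met_rate` in W/m^2 for comfort-standard rows where M
is prescribed.

## Mean radiant temperature

`tmrt_calc()` chains five stages; each stage is exported and
independently testable.

1. **Solar position** - Astronomical-Almanac low-precision ephemeris
   (mean longitude/anomaly, ecliptic longitude, sidereal hour angle),
   accurate to about 0.01 degrees.  Inputs carry a day-of-year but no
   calendar year, so the ephemeris is evaluated in a fixed non-leap
   reference year (2023); the test oracle is an independent published
   algorithm (Spencer declination and equation of time) and agreement
   is required to 0.5 degrees.
2. **Clear-sky shortwave** - beam from the 1367 W/m^2 solar constant
   with Beer extinction `exp(-0.8662 ltf m dR)` (Kasten-Young relative
   air mass `m`, Kasten Rayleigh optical thickness `dR(m)`, Linke
   turbidity `ltf`, elevation factor `exp(-z/8434)`).  Diffuse is the
   fixed fraction 0.3 of the extinguished irradiance projected on the
   horizontal; `Gmax = Imax cos z + Dmax`.  Default `ltf = 3`
   (rural-to-suburban air); the vapour pressure argument is accepted
   for interface completeness but water-vapour extinction is treated
   as part of `ltf`.
3. **Cloud / measured radiation** - without a measurement,
   `Gtat = Gmax (1 - 0.75 (N/8)^3.4)` (Kasten-Czeplak); the diffuse
   fraction interpolates from the clear-sky share to 1 at full
   overcast.  A measured `G` wins over the cloud law, split by
   `DGratio` when given; `RedGChk` optionally reduces a preset `G` by
   the sky-view factor.  At `RH >= foglimit` (default 90 %) all
   shortwave is treated as diffuse.
4. **Longwave and surface temperature** - clear-sky atmospheric
   emissivity `0.82 - 0.25 * 10^(-0.094 VP)` (Angstrom type) with
   cloud enhancement `(1 + 0.22 (N/8)^2)`, capped at 1.  The ground
   temperature solves a linearised balance of absorbed shortwave
   `(1 - alb) Gtat`, net longwave, and a turbulent loss
   `h_s (1 + 1/bowen)(Tob - Ta)` with `h_s = 5.9 + 4.1 v`; at most 10
   Newton steps to 0.01 K.  `Eu` is surface emission at `Tob`; the
   lateral term `Es` radiates at the mean of air and surface
   temperature - the source temperature of lateral surroundings is
   genuinely unstated in the material this package follows, and the
   50/50 mix is our flagged choice.
5. **Composition** - absorbed shortwave
   `ak (fp I + 0.5 (OmegaF D + alb G))` with body absorptivity
   `ak = 1 - albhum` and the standing-person projected-area factor
   `fp(altitude) = 0.308 cos(alt (0.998 - alt^2/50000))` (the
   published fit takes solar altitude, peaking near the horizon);
   longwave weighted `0.3 sky + 0.3 ground + 0.4 lateral`, the
   obstructed sky share replaced by obstacles radiating at air
   temperature.  `Tmrt = ((SW/eps_p + LW/eps_s)/sigma)^(1/4)` with
   `eps_p = eps_s = 0.97`, so an isothermal enclosure of emissivity
   0.97 reproduces its own temperature exactly - the model's hardest
   invariant, tested to 1e-6 K.

The sky-view factor `OmegaF` is accepted and applied in composition
(diffuse shortwave and sky longwave), although the original interface
this package mirrors fixes it at 1.0; reducing it below 1 under a
clear noon sky lowers `Tmrt`, which is asserted as a directional test.

## PMV

Fanger's steady-state load: clothing surface temperature from the
standard averaged iteration (linear in `Tcl^4`, tolerance 1e-3 K, 150
iterations), convective coefficient
`max(2.38 |Tcl - Ta|^0.25, 12.1 sqrt(v))`, then
`PMV = (0.303 e^(-0.036 M) + 0.028) L`.  Output is the interface
triple `{PMV, Teq, hclo}` - no PPD.  `Teq` is defined here as the
uniform temperature (`Ta = Tmrt`, same wind and relative humidity) at
which the load vanishes, found by bisection on [-40, 60] C to 0.01 K;
how the original derived its `Teq` is unstated, and our zero-load
definition has the testable property that re-feeding `Teq` returns
`|PMV| < 0.05`.  `hclo` is the dry conduction through the clothing at
the converged state.  Validation: five comfort-standard rows
reproduced within 0.01 PMV (the test tolerance is the standard's
0.1).

## SET*

A 60-minute Gagge two-node simulation (1-minute explicit steps from
the neutral state) followed by the standard-environment match.
Control constants, all in one place (`.TN`): vasodilation gain 120
L/(m^2 h K), vasoconstriction 0.5 1/K, sweating gain 170 g/(m^2 h K)
with `exp(warm_skin/10.7)` amplification, shivering
`19.4 colds coldc` W/m^2, skin blood flow clamped to [0.5, 90]
L/(m^2 h), sweat to 500 g/(m^2 h), wettedness floor 0.06 and cap
`0.59 v^-0.08` (clothed).  The skin-mass fraction fit
`0.0417737 + 0.7451833/(skbf + 0.585417)` is clamped to [0.04, 0.35];
the raw fit exceeds the physiological band under strong
vasoconstriction.  The standard environment is `Tmrt = Ta`, still air
(we freeze the still-air convective floor at `chc = 3` W/(m^2 K),
equivalent to about 0.15 m/s; whether the original used 0.1 or
0.15 m/s is unstated), RH 50 %, and standard clothing
`1.52/(met + 0.6944) - 0.1835` clo; SET* solves the matched heat-loss
equation by bisection to 0.01 K.  Reflexivity (standard environment
maps to itself within 0.5 K) is asserted on the grid 18-32 C, the
span where the standard environment is a sensible description of the
actual one.

## PET

The MEMI steady state solves three nested balances - core (metabolism
plus respiration against blood-flow transport with vasomotor control),
clothing surface (conduction against convection and radiation), and
skin (transport, dry exchange, diffusion `Ed`, regulatory sweating
`Esw` with a wettedness cap) - by nested 1-D root finding to below
0.1 W.  Sign convention: gains positive, so
`h + Ere + csum + rsum + Ed + Esw = 0` at the solution, which is the
closure invariant tested on random conditions.  PET maps the actual
state to the reference climate `Tmrt = Ta_ref`, `v = 0.1` m/s,
`VP = 12` hPa, `work = 80` W, `icl = 0.9` clo by matching the skin
temperature (bisection to 0.01 K); the matched reference core
temperature is verified and a mismatch above 0.2 K warns - a 1-D
equivalence cannot pin both state variables, the classical ambiguity
of this mapping.  Two numerical notes: the reference VP of 12 hPa is
supersaturated below about 9.7 C (RH capped, as the convention
requires), and under strong cold stress the reference construct needs
skin temperatures below the physiological floor, so the internal
reference solve extends its bracket to [-35, 45] C while actual
environments keep the [0.5, 45] C contract.  The actual-environment
physiological envelope ends around Ta = -10 C with strong wind, where
no steady skin temperature above 0.5 C exists; such records raise the
documented computational error.

## mPET

A compact multi-node body: head, trunk, arms and legs as concentric
core/muscle/fat/skin layers coupled to a central blood pool
(17 states), with quasi-steady per-segment clothing.  Geometry (area
fractions 0.07/0.36/0.19/0.38, mass fractions 0.07/0.50/0.12/0.31,
per-segment layer splits), conductances (13/16/21 W/(m^2 K) between
layers, in series equivalent to the classical 5.28 core-skin value),
perfusion (45/6/1.5 L/(m^2 h) for core/muscle/fat; skin by the
vasomotor law) and the central control laws (same family as the
two-node constants; sweating gain 304.94 g/(m^2 h K) on the
0.1/0.9-weighted body temperature) are frozen in one table (`.MN`).
Clothing vapour transfer is humidity-sensitive: moisture permeability
`im = 0.38 (1 - 0.25 RH/100)`, so humid air degrades the ensemble's
evaporative conductance.  The head wears a fixed 0.1 clo; the other
segments wear the subject's insulation.

**Adaptive clothing.**  `auto_clothing(Ta) = clamp(0.9 - 0.0425
(Ta - 20), 0.3, 2.6)` clo: continuous, monotone non-increasing, pinned
to PET's 0.9 clo at 20 C, reaching the summer bound 0.3 near 34 C and
2.0 clo at -6 C.  The slope is our frozen choice spanning the full
wardrobe over roughly -20 to +34 C.

**Semi-steady state.**  1-minute explicit steps until max |dT/dt| over
all nodes is below 0.01 K/min *and* the whole-body flux residual is
below 1 W, or 480 simulated minutes elapse (then a warning and a
`converged = FALSE` flag, never an exception).  The residual condition
is part of the criterion because a single large node at 0.01 K/min can
still store tens of watts; both published statements of the criterion
are honoured by the conjunction.

**The equivalence run.**  mPET uses PET's reference climate.  The
clothing ensemble is chosen once from the *actual* environment (auto
rule at the actual Ta, or the user's fixed `icl`) and worn unchanged
in the reference run.  This is the one place we overrode a stated
design idea (clothing in the reference run re-chosen by the same
rule): re-adapting clothing to the reference temperature cancels - in
fact inverts - the damping that adaptive clothing is supposed to
produce, contradicting the required qualitative structure (mPET
compressing extremes relative to PET, departures concentrated above
about 28 C PET).  With the ensemble fixed across both runs the
reference identity `mPET(reference climate) = Ta` is exact by
construction, and the damping emerges from the physics: a warmly
dressed subject is less sensitive to cold wind than the reference
0.9-clo construct of PET, and a lightly dressed subject sheds heat
better in warmth.

## UTCI

The operational 6th-order polynomial in (Ta, v10, Tmrt - Ta, pa), 210
coefficients embedded verbatim with a term-count and checksum
assertion at first use, validated against an independent
implementation to 5e-7 K on 1350 grid points (a frozen 1080-point
oracle grid ships with the package and is re-checked at test time to
0.1 K).  Wind enters at 1.1 m and is converted up to 10 m with the
shared profile; converted winds below the polynomial's 0.5 m/s floor
are clamped with a log message, and a `v10` argument bypasses the
conversion.  Out-of-box input errors by default, naming the violated
bound; `clamp = TRUE` clamps and logs.  One known property worth
stating: at the nominal reference state (Tmrt = Ta, v10 = 0.5,
RH = 50 %) the polynomial's offset is *not* bounded by 1 K everywhere -
it reaches +1.5 K at Ta = 35 C, because above 29 C the operational
reference humidity is capped at 20 hPa while RH 50 % at 35 C is
28 hPa.  This is a property of the published regression (our
independent oracle reproduces it bit-for-bit), and the acceptance test
records it honestly rather than hiding it.

## Synthetic weather generator

`generate_fixture_series()` emulates a plausible mid-latitude hourly
station record and nothing more: sinusoidal diurnal air temperature
(minimum near 05 LT) with AR(1) noise (phi = 0.8), relative humidity
anti-correlated with temperature and clamped to preset bounds, bounded
AR(1) wind at 10 m, cloud octas as a persistent Markov chain (stay
probability 0.7), and a fixed site per preset (temperate: 48 N,
summer; hot-humid: subtropical coast; cold: 60 N, winter).  Presets
state means and amplitudes a field scientist would call typical
(temperate 15 +/- 6 C; hot-humid 28 +/- 4 C, RH floor 40 %; cold
-5 +/- 3 C).  What it does *not* emulate: weather fronts, radiation
measurement error, urban canyon geometry, diurnal wind cycles, or any
correlation between cloud and temperature.  A green ensemble test
therefore establishes internal consistency of the index engines on
plausible marginal distributions, not agreement with any real
station.

## Numerical choices and degenerate inputs

* All equivalence mappings use bisection to 0.01 K; brackets are
  probed adaptively and shrink to the feasible band before bisecting.
* `uniroot` tolerances of 1e-6..1e-7 K keep flux closures well inside
  their 0.1/0.5/1 W assertions.
* Identical inputs give bit-identical outputs; there is no randomness
  anywhere outside the fixture generator, which is seeded.
* "Now time" defaults resolve from the system clock once per call and
  are logged; all tests pass explicit times.
* Degenerate inputs (zero wind, RH 0 or 100, sun exactly at the
  horizon, `minutes = 0`) are covered by unit tests; zero wind is
  floored at the still-air value each engine's convective law assumes.

## Known limitations

* Numeric identity with any historical implementation of the same
  index family is not claimable where the source material leaves the
  formula dialect unstated (wind profile, clear-sky model, surface
  balance, multi-node geometry); every frozen dialect is listed above.
* The PET/mPET physiological envelope excludes deep-cold windy
  extremes (no steady state above the 0.5 C skin floor); such records
  error (PET) or return flagged states (mPET).
* Fisheye-photo or obstacle-map horizon limitation, shadow casting and
  gridded/netCDF input are out of scope.
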