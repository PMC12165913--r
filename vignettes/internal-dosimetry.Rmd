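---
title: "Internal dosimetry with intdose: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Internal dosimetry with intdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intdose)
```

## The computational chain

`intdose` computes organ absorbed doses and effective dose for
radiopharmaceuticals from three ingredients:

1. a **decay scheme** per nuclide — discrete photon, electron and alpha
   lines (energy $E_i$ in MeV, yield $Y_i$ per nuclear transformation),
   an optional tabulated beta spectrum, and progeny branches;
2. **specific absorbed fractions** (SAFs) $\Phi(r_T \leftarrow r_S, E)$
   in kg⁻¹ per radiation type on an energy grid, together with the region
   masses of a reference phantom;
3. **time-integrated activity coefficients** (TIACs) $\tilde A/A_0$ in
   hours per source region, either given directly or obtained by fitting
   retention curves to time–activity samples.

The S-value for a region pair is
$S(r_T \leftarrow r_S) = \sum_i E_i Y_i \Phi(r_T \leftarrow r_S, E_i)$
converted MeV→J ($1.602176634\times10^{-13}$), in Gy per nuclear
transformation; beta emitters replace the sum by a trapezoidal integral of
$E\,\rho(E)\,\Phi_e(E)$ over the spectrum grid. Doses follow as
$D = \sum_S (\tilde A/A_0)\, S$ with one fixed unit multiplier:

> TIAC [h] × 3.6·10⁹ nt/(MBq·h) × S [Gy/nt] × 10³ = D [mGy/MBq],

i.e. a single factor of $3.6\times10^{12}$ applied in `absorbed_dose()`
and nowhere else. The factor follows from 1 MBq·h = $10^6$ decays/s ×
3600 s; centralizing it keeps every module in its natural units (MeV,
hours, MBq, kg).

The effective dose weights radiation-weighted ($w_R$: photons and
electrons 1, alphas 20) and sex-averaged organ equivalent doses with a
tissue-weighting set $w_T$ that sums to exactly 1. Both shipped schemes
treat "Remainder tissues" as the **unweighted arithmetic mean** of a
sex-specific constituent list (13 organs in the current scheme, with the
prostate for males and the uterus/cervix for females). The
detriment-adjusted variant applies the same weighting per sex without the
/2 average; with our convention for sex-specific organs (each sex
contributes its own organ's equivalent dose) the sex-averaged effective
dose is identically the mean of the two sex-specific values.

## Numerical choices

**SAF energy interpolation** is log–log linear with end clamping. SAF
tables span decades in both energy and magnitude, where log–log
interpolation is standard practice; clamping below the lowest grid point
avoids unphysical extrapolation for very soft emissions. Zero-valued
nodes (where the logarithm is undefined) switch the affected pair to
linear interpolation. Grid nodes reproduce stored values exactly.

**Beta quadrature** is trapezoidal **on the spectrum's own grid**, with
the electron SAF interpolated to each spectrum node. Spectra are denser
than SAF grids, so this keeps the quadrature error in the better-resolved
table; higher-order schemes are unwarranted on dense tabulated data.

**Bateman chains** use the closed-form partial-fraction solution in
activity form. When any two decay constants agree to better than a
relative $10^{-9}$ the partial fractions suffer catastrophic
cancellation, so the solver routes to a matrix exponential of the
lower-bidiagonal chain matrix — the confluent limit evaluated stably for
any multiplicity. The suite checks both paths against a stiff ODE
integration; note that an ODE oracle at rtol $10^{-12}$ resolves
activities only to about $10^{-12}$ *absolute* on the administered-
activity scale, so relative comparisons are made where activities are
representable.

**Retention fitting** minimizes the unweighted SSE on normalized
activities (a relative, log-residual objective is available via
`weighting = "relative"`; the choice is exposed because the literature
does not standardize it). Rates are optimized on the log scale to keep
them positive. Initialization is a multistart over rate combinations
log-spaced between $1/(10\,t_{max})$ and $10/t_{min}$, with amplitudes
obtained by linear least squares given the rates (variable projection)
and Levenberg–Marquardt refinement per start; the best SSE wins, and rate
vectors are reported sorted decreasing as a tie-break. The five fitting
systems presented in the interactive tool are a subset of the nine
combinations {direct, 1 uptake, 2 uptakes} × {1, 2, 3 retention terms};
the library accepts all nine since they share one implementation, and the
menu restriction is a front-end decision.

**Decay-correction semantics** are an explicit flag on every
time–activity curve: if samples were decay-corrected, fitted rates are
biological and the physical constant is re-added during TIAC integration;
otherwise rates are effective and used as-is. TIACs are integrated
analytically (every model term is an exponential after expanding the
uptake factors), including finite integration periods; a zero total rate
over an infinite period raises a divergence error rather than returning
infinity.

**The dynamic bladder** integrates
$\mathrm{d}A/\mathrm{d}t = r(t) - \lambda A$ piecewise between voids with
an embedded Runge–Kutta pair (`ode45`). Multistep methods were found to
under-resolve the pure quadrature states (the running integrals of
activity and of activity × S(V)) that do not feed back into the
dynamics, so the solver choice is deliberate. Voids assume **well-mixed
urine**: volume drops to the residual and activity scales by the retained
volume fraction — the simplest defensible mixing assumption. The first
void occurs one voiding interval (default 3.5 h) after administration
unless an explicit schedule is given; hydration is an additive flow term
over a user window. The volume-dependent content→wall S-value is
interpolated log–log in volume, which reproduces power-law curves
exactly.

**Sphere progeny** kinetics assume the parent's retention in the sphere
is mono-exponential with effective clearance $1/\mathrm{TIAC}$ (the only
rate consistent with unit initial content and the given TIAC), and that
progeny are produced in place with no washout, decaying with their own
physical constants. The member activities then follow a Bateman cascade
driven by the parent's effective clearance, and at $T_D = \infty$ each
member's TIAC is the cumulative branching fraction times the parent
TIAC — a closed form the tests verify independently. Absorbed fractions
are interpolated bilinearly in (log V, log E), exact at grid nodes.

**Age/weight interpolation** is piecewise linear on the dose scale by
default, with a log-linear option since paediatric doses span decades.
No extrapolation is permitted outside the node range (ages 0–20 years;
weights bounded by the per-sex reference series, 3.5–73 kg male and
3.5–64 kg female by default). The effective dose is never interpolated
directly — it is recomputed from the interpolated organ doses, so the
weighting identity $\sum_T w_T = 1$ is preserved exactly at every
abscissa. The derived 100-day infant (fixed interpolation fraction
0.6528 between the newborn and 1-year S-coefficients) can be inserted as
an optional node at 0.274 y; the newborn node itself sits at age 0.

## The blood rule and the source region "Other"

The composite source "Other" covers all soft tissues in exchange with the
circulating blood that a biokinetic model does not list explicitly; organ
contents and air are excluded by construction (the eligible list is
phantom configuration). Its SAF is the mass-weighted mean of the
constituents. If a model does **not** declare "Blood" as a source, the
blood-bearing regions representable only through the blood (large
vessels, heart content) are folded into "Other" with an effective mass
equal to their share of the blood mass, so the circulating blood is never
silently dropped; if "Blood" is explicit, nothing is folded, avoiding a
decay being counted in two source regions. The shipped region vocabulary
covers the targets required by the weighting schemes and the common
sources; the authoritative region set of any real calculation is the
loaded SAF table, against which all inputs are validated. (The published
target-region count differs between sources by one; the package is
data-driven and does not hard-code a count.)

## What the fixture generator does and does not emulate

`make_conserving_phantom()` builds miniature phantoms whose SAFs satisfy
$\sum_T m_T \Phi(T \leftarrow S, E) = 1$ **exactly** at every grid
energy: all emitted energy is absorbed somewhere. This makes whole-body
energy closure of the S-matrix an algebraic identity and pins down the
unit chain end to end. Real SAF tables are *sub*-unitary (bremsstrahlung
and photon escape), energy-dependent, and strongly asymmetric between
organ pairs; the fixtures are none of these. Toy nuclides carry known
energy totals; time–activity fixtures sample a stored ground-truth
retention model at log-spaced times with multiplicative lognormal noise
(default σ = 5%, a typical quantification uncertainty), so recovery
experiments have an exact reference. Passing tests therefore demonstrate
the correctness of the computational chain — interpolation, quadrature,
unit handling, weighting — not the realism of any anatomical or
biokinetic input: with real decay and SAF supplements the same code path
produces reference results, but those inputs are licensed data the user
must supply.

Test problem sizes are chosen to exercise every code path while keeping
the default suite fast: 5-region phantoms, 8-point energy grids,
2–4-member chains (100 seeded random chains in the chain property), 200
seeded replicates in the rate-recovery experiment, and 10-sample
time–activity curves. Generation is bit-reproducible for a fixed seed and
restores the caller's RNG state.

## Known limitations

* The voxel-phantom Monte Carlo generation of SAFs is upstream of this
  package and out of scope; SAF tables are inputs.
* Published biokinetic models (FDG, pertechnetate, iodide) are external
  inputs, not bundled.
* The sphere module treats lesions as homogeneous spheres; no
  non-spherical geometry.
* The dynamic bladder computes the wall dose from the content only; no
  foetal/uterus dosimetry from bladder content.
* Uncertainty propagation and risk coefficients per sievert are not
  implemented.
* The older weighting scheme's remainder constituent list is shipped as
  editable configuration (its historical mass-weighted splitting rule is
  simplified to the same arithmetic-mean rule used by the current
  scheme, with the colon standing in for the upper large intestine).

## A compact end-to-end run

```{r example}
spec <- fixture_spec(seed = 7)
fx <- make_conserving_phantom(spec)
nuc <- make_toy_nuclide(spec, "mixed")
regions <- names(fx$phantom$region_masses)
sm <- s_matrix(nuc, fx$phantom, fx$saf, sources = regions,
               targets = regions)
tiac <- setNames(c(2.0, 0.8, 0.5, 0.3, 0.1), regions)
absorbed_dose(tiac, sm, sex = "male")
```

The energy-conservation identity of the fixture can be checked directly:

```{r closure}
m <- fx$phantom$region_masses
delta_total <- sum(vapply(nuc$emissions, function(e)
  if (e$kind == "beta_spectrum_ref") 0 else delta_per_transformation(e),
  numeric(1))) + delta_per_transformation(nuc$beta)
c(absorbed_J_per_nt = sum(m * sm$values[, "region_1"]),
  emitted_J_per_nt = delta_total * 1.602176634e-13)
```
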