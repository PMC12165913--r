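# intdose

Internal radiation dosimetry for diagnostic nuclear medicine in R.

When a patient is administered a radiopharmaceutical, the absorbed dose to
organs and tissues cannot be measured directly: it is computed from (i) the
nuclear decay scheme of the radionuclide, (ii) tabulated specific absorbed
fractions (SAFs) describing how emitted energy deposits between source and
target regions of a reference phantom, and (iii) a biokinetic description
of where the activity resides over time. `intdose` implements that
computational chain for reference phantoms of both sexes and six ages
(newborn to adult), in the style of the ICRP framework for internal dose
assessment, and is aimed at medical physicists and dosimetry researchers
who want a scriptable, fully testable implementation of the pipeline.

## The model

The mean absorbed dose to a target region $r_T$ for a time-independent
system is

$$D(r_T, T_D) = \sum_{r_S} \tilde{A}(r_S, T_D)\; S(r_T \leftarrow r_S),$$

where $\tilde{A}(r_S, T_D)$ is the time-integrated (cumulated) activity in
source region $r_S$ over the integration period $T_D$ (normally
$\infty$), carried here as a time-integrated activity coefficient
$\tilde{A}/A_0$ in hours, and

$$S(r_T \leftarrow r_S) = \sum_i \Delta_i\, \Phi(r_T \leftarrow r_S, E_i),
\qquad \Delta_i = E_i Y_i,$$

is the mean absorbed dose per nuclear transformation, with
$\Phi(r_T \leftarrow r_S, E)$ the specific absorbed fraction (kg⁻¹) and
$E_i$, $Y_i$ the energy and yield of the $i$-th emission. The sum runs
over photons, electrons and alpha particles; for beta emitters the sum is
replaced by an integral over the tabulated beta spectrum. The effective
dose weights the sex-averaged, radiation-weighted organ equivalent doses
with tissue weighting factors $w_T$,

$$E = \sum_T w_T \sum_R
  \frac{w_R D_R(r_T)^{male} + w_R D_R(r_T)^{female}}{2},$$

with $w_R = 1$ for photons/electrons and $20$ for alphas; both the older
and the current $w_T$ sets are shipped, plus a sex-specific
(detriment-adjusted) variant that skips the sex average.

Around that core the package provides:

* **Decay data**: emission lists, tabulated beta spectra, serial decay
  chains with closed-form Bateman solving (`bateman_activities()`),
  a documented CSV fixture dialect (`read_decay_fixture()`).
* **Phantoms and SAFs**: log–log SAF energy interpolation
  (`saf_at_energy()`), mass-weighted composition of the source region
  "Other" (`compose_other_saf()`), the circulating-blood folding rule
  (`apply_blood_rule()`), and the derived 100-day infant
  (`infant_s()`, fraction 0.6528 between newborn and 1-year S-values).
* **Biokinetics**: compartmental retention-curve fitting (direct / one or
  two uptakes × 1–3 retention exponentials, `fit_retention()`), analytic
  TIAC integration (`tiac_from_fit()`), linear compartment solving
  (`solve_compartments()`).
* **Dynamic bladder**: time-dependent content activity and volume with
  voiding, residual/initial content and hydration
  (`bladder_content()`), volume-dependent content→wall S-values
  (`wall_dose_dynamic()`).
* **Spheres**: absorbed dose to spherical volumes with a
  photon/electron/alpha breakdown and Bateman progeny in-growth
  (`sphere_s()`, `sphere_dose_with_progeny()`).
* **Age/weight interpolation**: organ doses at arbitrary age (0–20 y) or
  body weight, with the effective dose recomputed from the interpolated
  organ doses (`interp_by_age()`, `interp_by_weight()`).
* **Fixtures**: a seeded generator of miniature, analytically solvable
  phantoms, nuclides and time–activity data (`make_conserving_phantom()`
  and friends) so the entire pipeline is testable without any external
  data. The licensed decay/SAF electronic supplements are deliberately
  never bundled; adapters validate and refuse until the user supplies
  them in the documented CSV dialects.

## Worked example

A five-region energy-conserving phantom, a toy mixed emitter
(photon + electron lines + beta spectrum), and a TIAC vector:

```r
library(intdose)

spec <- fixture_spec(seed = 7)
fx   <- make_conserving_phantom(spec)
nuc  <- make_toy_nuclide(spec, "mixed")
regions <- names(fx$phantom$region_masses)

sm <- s_matrix(nuc, fx$phantom, fx$saf, sources = regions, targets = regions)
tiac <- setNames(c(2.0, 0.8, 0.5, 0.3, 0.1), regions)
absorbed_dose(tiac, sm, sex = "male")
```

```
<dose_result adult_male (male)>  [mGy/MBq]
   target photon electron alpha    beta  total
 region_1 0.1841  0.01591     0 0.01543 0.2154
 region_2 0.3574  0.02268     0 0.02200 0.4021
 region_3 1.8010  0.07839     0 0.07602 1.9560
 region_4 1.5540  0.11180     0 0.10850 1.7740
 region_5 0.6684  0.04715     0 0.04573 0.7612
```

Each row is the absorbed dose per administered MBq: for example,
`region_3` receives 1.956 mGy/MBq, of which 1.801 mGy/MBq comes from
photons and 0.076 mGy/MBq from the beta spectrum. The unit chain is
TIAC[h] × 3.6·10⁹ transformations/(MBq·h) × S[Gy/nt] × 10³ mGy/Gy.

A retention fit integrates to its TIAC analytically; e.g. a
two-exponential biological retention under a 1.83 h half-life nuclide:

```r
f <- retention_fit("direct", a = c(0.6, 0.3), lambda = c(0.5, 0.05),
                   decay_corrected = TRUE)
tiac_from_fit(f, lambda_phys = log(2) / 1.83)
#> [1] 1.382451
```

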