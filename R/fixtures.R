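#' Fixture generation settings
#'
#' Seeded settings for the miniature, analytically solvable fixtures used
#' throughout the test-suite and the worked examples: a small
#' energy-conserving phantom, toy nuclides with known energy totals, and
#' noisy time-activity curves with stored ground truth. Generation is
#' bit-reproducible for a fixed seed.
#'
#' @param seed Integer RNG seed.
#' @param n_regions Number of phantom regions (default 5).
#' @param energy_grid SAF/AF energy grid (MeV).
#' @param sigma Multiplicative lognormal noise level for time-activity
#'   sampling (default 0.05, i.e. 5%).
#' @param scenario Free-form scenario tag.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_regions = 5L,
                         energy_grid = 10^seq(-2, 1, length.out = 8),
                         sigma = 0.05, scenario = "default") {
  if (n_regions < 2L) .stopf("need at least 2 regions")
  structure(list(seed = as.integer(seed), n_regions = as.integer(n_regions),
                 energy_grid = energy_grid, sigma = sigma,
                 scenario = scenario), class = "fixture_spec")
}

# run expr with a locally seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Generate an energy-conserving phantom and SAF table
#'
#' Builds a miniature phantom with `n_regions` soft-tissue regions and SAF
#' tables for photons, electrons and alphas constructed so that
#' `sum_T m_T Phi(T <- S, E) = 1` exactly at every grid energy (all
#' emitted energy is absorbed somewhere in the body). This makes the
#' whole-body closure of S-values an exact identity and is the anchor for
#' the energy-conservation tests. When `with_blood` is set, an extra
#' blood-bearing region ("vessels") carrying a share of the blood mass is
#' added and flagged as representable only through the blood.
#'
#' @param spec A [fixture_spec()].
#' @param with_blood Add a blood-only region and blood fractions.
#' @return `list(phantom =, saf =)`.
#' @export
make_conserving_phantom <- function(spec = fixture_spec(),
                                    with_blood = FALSE) {
  .with_seed(spec$seed, {
    n <- spec$n_regions
    regions <- paste0("region_", seq_len(n))
    masses <- stats::setNames(round(stats::runif(n, 0.05, 2), 4), regions)
    blood_only <- character(); bf <- numeric(); bm <- 0
    if (with_blood) {
      regions <- c(regions, "vessels")
      masses <- c(masses, vessels = 0.3)
      blood_only <- "vessels"
      bf <- stats::setNames(rep(1 / length(regions), length(regions)),
                            regions)
      bm <- 0.5
    }
    egrid <- spec$energy_grid
    rows <- list()
    for (rt in c("photon", "electron", "alpha")) {
      for (s in regions) {
        x <- stats::runif(length(regions), 0.2, 1)
        share <- x / sum(x)             # fractions absorbed per target
        phi <- share / masses           # Phi = share / m_T  (1/kg)
        for (ti in seq_along(regions)) {
          rows[[length(rows) + 1L]] <- data.frame(
            rtype = rt, target = regions[ti], source = s,
            E_MeV = egrid, phi_per_kg = unname(phi[ti]),
            stringsAsFactors = FALSE)
        }
      }
    }
    ph <- phantom(sex = "male", age_class = "adult",
                  total_mass = sum(masses), region_masses = masses,
                  blood_fractions = bf, blood_mass = bm,
                  other_eligible = setdiff(regions, blood_only),
                  blood_only_regions = blood_only)
    list(phantom = ph, saf = saf_table(ph$id, do.call(rbind, rows)))
  })
}

#' Generate a toy nuclide with a known energy total
#'
#' @param spec A [fixture_spec()] (seed only used for `"mixed"`).
#' @param kind `"gamma"` (one 0.14 MeV photon line, Y = 0.89),
#'   `"beta"` (uniform spectrum on \[0, 1\] MeV, unit yield),
#'   `"alpha"` (one 5 MeV alpha, Y = 1),
#'   `"mixed"` (photon + electron lines + beta spectrum), or
#'   `"chain2"` (two-member chain, returns a [decay_chain()]).
#' @param half_life Parent half-life in seconds (default 6 h).
#' @return A [nuclide()], or a [decay_chain()] for `"chain2"`.
#' @export
make_toy_nuclide <- function(spec = fixture_spec(), kind = "gamma",
                             half_life = 6 * 3600) {
  kind <- match.arg(kind, c("gamma", "beta", "alpha", "mixed", "chain2"))
  switch(kind,
    gamma = nuclide("Toy-G", half_life,
                    list(emission("photon", 0.14, 0.89))),
    beta = {
      grid <- seq(1e-4, 1, length.out = 201)
      nuclide("Toy-B", half_life,
              list(emission("beta_spectrum_ref", yield = beta_yield(
                beta_spectrum(grid, rep(1, length(grid)))))),
              beta = beta_spectrum(grid, rep(1, length(grid))))
    },
    alpha = nuclide("Toy-A", half_life,
                    list(emission("alpha", 5, 1))),
    mixed = .with_seed(spec$seed, {
      grid <- seq(1e-4, 0.8, length.out = 101)
      dens <- 0.5 * (1 - grid / 0.8)          # triangular, yield 0.2
      dens <- dens / pracma::trapz(grid, dens) * 0.2
      nuclide("Toy-M", half_life,
              list(emission("photon", round(stats::runif(1, 0.1, 1), 3),
                            0.85),
                   emission("electron", 0.05, 1.1),
                   emission("beta_spectrum_ref", yield = 0.2)),
              beta = beta_spectrum(grid, dens))
    }),
    chain2 = {
      parent <- nuclide("Toy-P", half_life,
                        list(emission("photon", 0.2, 0.9)),
                        progeny = data.frame(id = "Toy-D", frac = 1))
      child <- nuclide("Toy-D", half_life / 3,
                       list(emission("electron", 0.3, 1)))
      decay_chain(list(parent, child), branching = 1)
    })
}

#' Sample a noisy time-activity curve from a known retention model
#'
#' Samples the true retention model at log-spaced times with seeded
#' multiplicative lognormal noise; the truth is attached for recovery
#' experiments.
#'
#' @param spec A [fixture_spec()] (seed and `sigma`).
#' @param truth A [retention_fit()] used as ground truth.
#' @param n Number of samples (default 10).
#' @param t_min,t_max Sampling window (hours).
#' @param A0 Administered activity (MBq).
#' @return An [activity_curve()] with attribute `"truth"`.
#' @export
make_time_activity <- function(spec = fixture_spec(), truth, n = 10L,
                               t_min = 0.25, t_max = 48, A0 = 1) {
  stopifnot(inherits(truth, "retention_fit"))
  .with_seed(spec$seed, {
    t <- exp(seq(log(t_min), log(t_max), length.out = n))
    y <- retention_value(truth, t) * A0
    if (spec$sigma > 0)
      y <- y * exp(stats::rnorm(n, 0, spec$sigma))
    cur <- activity_curve("fixture", t, pmax(y, 0),
                          decay_corrected = truth$decay_corrected)
    attr(cur, "truth") <- truth
    cur
  })
}

#' Generate a sphere AF table with simple analytic structure
#'
#' Electron/alpha AF rises with volume towards 1; photon AF is smaller.
#' Values are exact at grid nodes and non-decreasing in volume.
#'
#' @param spec A [fixture_spec()].
#' @param tissue_id Material id.
#' @param density Density (g/cm^3).
#' @param volumes Volume grid (cm^3).
#' @return A [sphere_af_table()].
#' @export
make_sphere_af <- function(spec = fixture_spec(), tissue_id = 1,
                           density = 1,
                           volumes = c(0.01, 0.1, 1, 10, 100, 1000, 3000)) {
  eg <- spec$energy_grid
  rows <- list()
  for (rt in c("photon", "electron", "alpha")) {
    base <- switch(rt, photon = 0.05, electron = 0.6, alpha = 0.95)
    for (vi in seq_along(volumes)) {
      vfac <- volumes[vi]^0.15 / max(volumes)^0.15
      af <- pmin(base * vfac * (1 + 0.1 / (1 + eg)), 1)
      rows[[length(rows) + 1L]] <- data.frame(
        rtype = rt, V_cm3 = volumes[vi], E_MeV = eg, af = af,
        stringsAsFactors = FALSE)
    }
  }
  sphere_af_table(tissue_id, density, do.call(rbind, rows))
}

#' Generate a volume-dependent bladder wall S-value curve
#'
#' `S(V) = s_ref x (V_ref / V)^p`: decreasing in volume, log-log linear,
#' the shape of content-to-wall S-values as the content grows.
#'
#' @param phantom_id Phantom id tag.
#' @param s_ref S at `V_ref` (Gy/nt).
#' @param V_ref Reference volume (mL).
#' @param p Power-law exponent (default 2/3, a surface-to-volume scaling).
#' @param volumes Volume grid (mL).
#' @return A [wall_svalue_curve()].
#' @export
make_wall_curve <- function(phantom_id = "adult_male", s_ref = 1e-15,
                            V_ref = 200, p = 2 / 3,
                            volumes = c(10, 25, 50, 100, 200, 400, 800)) {
  wall_svalue_curve(phantom_id, volumes, s_ref * (V_ref / volumes)^p)
}

#' Uniform-dose fixture for the weighting schemes
#'
#' Dose results for both sexes in which every target needed by the scheme
#' (weighted tissues, sex-specific organs, remainder constituents)
#' receives the same absorbed dose; the effective dose then equals that
#' dose exactly because the tissue weights sum to 1.
#'
#' @param cfg A [weighting_config()].
#' @param dose The uniform absorbed dose (mGy/MBq).
#' @param rtype Radiation type carrying the dose (default photon).
#' @return `list(male =, female =)` of [dose_result()].
#' @export
make_uniform_dose <- function(cfg = weighting_config("ICRP103"), dose = 1,
                              rtype = "photon") {
  build <- function(sex) {
    targets <- unique(c(cfg$w_T[[paste0(sex, "_target")]],
                        cfg$remainder[[sex]]))
    targets <- setdiff(targets, "remainder")
    df <- data.frame(target = targets, stringsAsFactors = FALSE)
    for (r in c("photon", "electron", "alpha", "beta")) df[[r]] <- 0
    df[[rtype]] <- dose
    dose_result(paste0("uniform_", sex), sex, df)
  }
  list(male = build("male"), female = build("female"))
}
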