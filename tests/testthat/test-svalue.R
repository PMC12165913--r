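mev_j <- 1.602176634e-13

# flat electron+photon SAF with phi = 1/M for self-irradiation of 't'
self_saf <- function(M = 1) {
  saf_table("p", expand.grid(
    rtype = c("photon", "electron", "alpha"), target = "t", source = "t",
    E_MeV = c(0.001, 10), stringsAsFactors = FALSE) |>
      transform(phi_per_kg = 1 / M))
}

test_that("S-value of a local-absorption electron line is E*Y/M in joules", {
  st <- self_saf(M = 1)
  nuc <- nuclide("E1", 3600, list(emission("electron", 1, 1)))
  expect_equal(s_value(nuc, st, "t", "t"), mev_j, tolerance = 1e-12)
  # no emissions -> 0
  expect_equal(s_value(nuclide("Z", 10), st, "t", "t"), 0)
})

test_that("S is linear in emission lines and yields", {
  st <- self_saf()
  n1 <- nuclide("L1", 3600, list(emission("photon", 0.3, 0.5)))
  n2 <- nuclide("L2", 3600, list(emission("electron", 0.8, 0.2)))
  n12 <- nuclide("L12", 3600, list(emission("photon", 0.3, 0.5),
                                   emission("electron", 0.8, 0.2)))
  expect_equal(s_value(n12, st, "t", "t"),
               s_value(n1, st, "t", "t") + s_value(n2, st, "t", "t"))
  n2x <- nuclide("L2x", 3600, list(emission("electron", 0.8, 0.4)))
  expect_equal(s_value(n2x, st, "t", "t"), 2 * s_value(n2, st, "t", "t"))
})

test_that("beta S-value integrates the spectrum against the electron SAF", {
  st <- self_saf(M = 1)
  grid <- seq(1e-4, 1, length.out = 2001)
  nuc <- nuclide("B1", 3600,
                 list(emission("beta_spectrum_ref", yield = 1)),
                 beta = beta_spectrum(grid, rep(1, length(grid))))
  # uniform density on [0,1] with phi = 1: S = 0.5 * MeV->J
  expect_equal(s_beta(nuc, st, "t", "t"), 0.5 * mev_j, tolerance = 1e-6)
  expect_equal(s_value(nuc, st, "t", "t"), s_beta(nuc, st, "t", "t"))
  # zero density -> 0
  nuc0 <- nuclide("B0", 3600, beta = beta_spectrum(grid, rep(0, length(grid))))
  expect_equal(s_beta(nuc0, st, "t", "t"), 0)
})

test_that("a narrow beta peak approaches the discrete-line S-value", {
  # energy-dependent SAF so that the collapsing peak has to converge to
  # the SAF evaluated exactly at the line energy
  st <- saf_table("p", data.frame(
    rtype = "electron", target = "t", source = "t",
    E_MeV = c(0.01, 10), phi_per_kg = c(1e-1, 1e-3)))
  E0 <- 0.4; Y <- 0.7
  line <- s_value(nuclide("D", 1, list(emission("electron", E0, Y))),
                  st, "t", "t")
  err <- vapply(c(1e-2, 1e-3, 1e-4), function(w) {
    grid <- seq(E0 - w, E0 + w, length.out = 41)
    dens <- pmax(1 - abs(grid - E0) / w, 0) * Y / w  # triangle of area Y
    s <- s_beta(nuclide("T", 1, beta = beta_spectrum(grid, dens)), st, "t", "t")
    abs(s - line) / line
  }, numeric(1))
  # the peak collapses onto the discrete line as the width shrinks
  expect_lt(err[3], 1e-6)
  expect_true(all(diff(err) < 0))
})

test_that("a declared beta branch without a spectrum is an error", {
  st <- self_saf()
  nuc <- nuclide("NB", 3600, list(emission("beta_spectrum_ref", yield = 0.5)))
  expect_error(s_beta(nuc, st, "t", "t"), "beta branch")
  # and a missing radiation-type grid is named
  st_ph <- saf_table("p", data.frame(rtype = "photon", target = "t",
                                     source = "t", E_MeV = c(0.01, 1),
                                     phi_per_kg = 1))
  nal <- nuclide("AL", 10, list(emission("alpha", 5, 1)))
  expect_error(s_value(nal, st_ph, "t", "t"), "alpha")
})

test_that("the S-matrix matches an elementwise brute-force oracle", {
  spec <- fixture_spec(seed = 21)
  fx <- make_conserving_phantom(spec)
  nuc <- make_toy_nuclide(spec, "mixed")
  regions <- names(fx$phantom$region_masses)
  sm <- s_matrix(nuc, fx$phantom, fx$saf, sources = regions,
                 targets = regions)
  for (s in regions) for (t in regions) {
    expect_equal(sm$values[t, s], brute_force_s(nuc, fx$saf, t, s),
                 tolerance = 1e-10)
  }
  # 1x1 request consistency and order invariance
  one <- s_matrix(nuc, fx$phantom, fx$saf, sources = regions[1],
                  targets = regions[2])
  expect_equal(one$values[1, 1], sm$values[regions[2], regions[1]])
  perm <- s_matrix(nuc, fx$phantom, fx$saf, sources = regions,
                   targets = rev(regions))
  expect_equal(perm$values[regions, regions], sm$values[regions, regions])
})

test_that("radiation-type breakdown is non-negative and sums to the total", {
  spec <- fixture_spec(seed = 22)
  fx <- make_conserving_phantom(spec)
  nuc <- make_toy_nuclide(spec, "mixed")
  comp <- s_value(nuc, fx$saf, "region_1", "region_2", breakdown = TRUE)
  expect_true(all(comp >= 0))
  expect_equal(sum(comp), s_value(nuc, fx$saf, "region_1", "region_2"),
               tolerance = 1e-15)
})

test_that("whole-body closure holds on an energy-conserving phantom", {
  spec <- fixture_spec(seed = 23)
  fx <- make_conserving_phantom(spec)
  for (kind in c("gamma", "alpha", "mixed")) {
    nuc <- make_toy_nuclide(spec, kind)
    regions <- names(fx$phantom$region_masses)
    sm <- s_matrix(nuc, fx$phantom, fx$saf, regions, regions)
    delta_total <- sum(vapply(nuc$emissions, function(e)
      if (e$kind == "beta_spectrum_ref") 0 else delta_per_transformation(e),
      numeric(1)))
    if (!is.null(nuc$beta))
      delta_total <- delta_total + delta_per_transformation(nuc$beta)
    m <- fx$phantom$region_masses
    for (s in regions) {
      absorbed <- sum(m * sm$values[regions, s])  # Gy*kg = J per nt
      expect_equal(absorbed, delta_total * mev_j, tolerance = 1e-6)
    }
  }
})

test_that("S-matrix export writes one row per region pair", {
  spec <- fixture_spec(seed = 24)
  fx <- make_conserving_phantom(spec)
  nuc <- make_toy_nuclide(spec, "gamma")
  regions <- names(fx$phantom$region_masses)
  sm <- s_matrix(nuc, fx$phantom, fx$saf, regions, regions)
  path <- file.path(tempdir(), "smat.csv")
  long <- smatrix_to_long(sm, path)
  expect_equal(nrow(long), length(regions)^2)
  back <- read.csv(path)
  expect_equal(back$S_Gy_per_nt,
               sm$values[cbind(back$target, back$source)])
  expect_equal(long$photon + long$electron + long$alpha + long$beta,
               long$S_Gy_per_nt, tolerance = 1e-15)
})
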