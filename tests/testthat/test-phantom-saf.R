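simple_saf <- function(phi_lo = 1e-2, phi_hi = 1e-3) {
  saf_table("p", data.frame(
    rtype = "photon", target = "t", source = "s",
    E_MeV = c(0.1, 1.0), phi_per_kg = c(phi_lo, phi_hi)))
}

test_that("SAF interpolation is exact at nodes and log-log between them", {
  st <- simple_saf()
  expect_equal(saf_at_energy(st, "t", "s", "photon", 0.1), 1e-2)
  expect_equal(saf_at_energy(st, "t", "s", "photon", 1.0), 1e-3)
  # geometric midpoint in log-E gives the geometric mean of the node values
  expect_equal(saf_at_energy(st, "t", "s", "photon", sqrt(0.1)),
               10^-2.5, tolerance = 1e-12)
  # clamping outside the grid
  expect_equal(saf_at_energy(st, "t", "s", "photon", 0.01), 1e-2)
  expect_equal(saf_at_energy(st, "t", "s", "photon", 10), 1e-3)
})

test_that("constant SAF stays constant and monotone nodes stay monotone", {
  stc <- saf_table("p", data.frame(
    rtype = "photon", target = "t", source = "s",
    E_MeV = c(0.1, 0.5, 2), phi_per_kg = 7e-3))
  for (E in c(0.1, 0.3, 0.77, 2))
    expect_equal(saf_at_energy(stc, "t", "s", "photon", E), 7e-3)
  st <- simple_saf()
  E <- exp(seq(log(0.1), log(1), length.out = 50))
  v <- saf_at_energy(st, "t", "s", "photon", E)
  expect_true(all(diff(v) <= 1e-15))
})

test_that("unknown region pairs list the available sources", {
  st <- simple_saf()
  expect_error(saf_at_energy(st, "t", "nope", "photon", 0.5),
               "available sources.*s")
})

test_that("the Other-region SAF is the mass-weighted constituent mean", {
  regions <- c("a", "b")
  df <- expand.grid(rtype = "photon", target = "t",
                    source = regions, E_MeV = c(0.1, 1),
                    stringsAsFactors = FALSE)
  df$phi_per_kg <- ifelse(df$source == "a", 4, 8)
  df <- rbind(df, data.frame(rtype = "photon", target = "t", source = "t",
                             E_MeV = c(0.1, 1), phi_per_kg = 1))
  st <- saf_table("p", df)
  ph <- phantom("male", "adult", 5,
                c(a = 1, b = 3, t = 1), other_eligible = c("a", "b"))

  # masses 1 kg and 3 kg, phi 4 and 8 -> (1*4 + 3*8)/4 = 7
  aug <- compose_other_saf(st, model_sources = character(), phantom = ph)
  expect_equal(saf_at_energy(aug, "t", "Other", "photon", 0.5), 7)

  # single constituent: that region's phi exactly
  aug1 <- compose_other_saf(st, model_sources = "b", phantom = ph)
  expect_equal(saf_at_energy(aug1, "t", "Other", "photon", 0.1), 4)

  # equal masses: plain mean
  ph2 <- phantom("male", "adult", 5, c(a = 2, b = 2, t = 1),
                 other_eligible = c("a", "b"))
  aug2 <- compose_other_saf(st, model_sources = character(), phantom = ph2)
  expect_equal(saf_at_energy(aug2, "t", "Other", "photon", 1), 6)

  expect_error(compose_other_saf(st, model_sources = c("a", "b"),
                                 phantom = ph), "empty constituent")
})

test_that("Other composition respects the mass-weighted conservation bound", {
  fx <- make_conserving_phantom(fixture_spec(seed = 11))
  aug <- compose_other_saf(fx$saf, model_sources = "region_1",
                           phantom = fx$phantom)
  m <- fx$phantom$region_masses
  for (rt in names(aug$rtypes)) {
    arr <- aug$rtypes[[rt]]$phi
    tg <- dimnames(arr)[[1]]
    other_sum <- sum(m[tg] * arr[, "Other", 1])
    per_source <- vapply(setdiff(dimnames(arr)[[2]], "Other"),
                         function(s) sum(m[tg] * arr[, s, 1]), numeric(1))
    expect_lte(other_sum, max(per_source) + 1e-12)
  }
})

test_that("the blood rule folds blood-only regions into Other", {
  regions <- c(r1 = 1, r2 = 2, vessels = 0.3)
  ph <- phantom("female", "adult", 4, regions,
                blood_fractions = c(r1 = 0.3, r2 = 0.3, vessels = 0.4),
                blood_mass = 0.5,
                other_eligible = c("r1", "r2"),
                blood_only_regions = "vessels")
  # model with explicit Blood: composition unchanged
  cons <- apply_blood_rule(c("Blood", "r1"), ph)
  expect_named(cons, "r2")
  expect_equal(unname(cons["r2"]), 2)
  # model without Blood: vessels gains weight = blood share * blood mass
  cons2 <- apply_blood_rule("r1", ph)
  expect_setequal(names(cons2), c("r2", "vessels"))
  expect_equal(unname(cons2["vessels"]), 0.5 * 0.4)
  # all blood fractions zero: identical to no rule
  ph0 <- phantom("female", "adult", 4, regions,
                 blood_fractions = c(r1 = 0, r2 = 0, vessels = 0),
                 blood_mass = 0.5, other_eligible = c("r1", "r2"),
                 blood_only_regions = "vessels")
  expect_named(apply_blood_rule("r1", ph0), "r2")
  # missing blood fraction for a needed region errors
  phm <- phantom("female", "adult", 4, regions,
                 blood_fractions = c(r1 = 0.3), blood_mass = 0.5,
                 other_eligible = c("r1", "r2"),
                 blood_only_regions = "vessels")
  expect_error(apply_blood_rule("r1", phm), "blood_fractions missing")
})

test_that("the 100-day infant derivation interpolates with fraction 0.6528", {
  expect_identical(infant_s(1, 0), 0.6528)
  expect_equal(infant_s(0, 1), 0.3472)
  expect_equal(infant_s(3, 3), 3)  # fixed point
  # linear and order preserving on matrices
  set.seed(5)
  s0 <- matrix(runif(9), 3)
  s1 <- s0 + matrix(runif(9), 3)  # s1 >= s0
  s100 <- infant_s(s1, s0)
  expect_true(all(s100 >= s0 & s100 <= s1))
  expect_equal(infant_s(2 * s1, 2 * s0), 2 * s100)
})

test_that("SAF fixtures round-trip through the CSV dialect", {
  fx <- make_conserving_phantom(fixture_spec(seed = 3), with_blood = TRUE)
  prefix <- file.path(tempdir(), "saffix")
  write_saf_fixture(fx$phantom, fx$saf, prefix)
  back <- read_saf_fixture(prefix)
  id <- fx$phantom$id
  expect_equal(back[[id]]$phantom$region_masses, fx$phantom$region_masses)
  expect_equal(back[[id]]$phantom$blood_fractions, fx$phantom$blood_fractions)
  expect_equal(back[[id]]$phantom$blood_only_regions,
               fx$phantom$blood_only_regions)
  for (rt in names(fx$saf$rtypes))
    expect_equal(back[[id]]$saf$rtypes[[rt]]$phi, fx$saf$rtypes[[rt]]$phi)
})

test_that("SAF conservation bound validation catches violations", {
  fx <- make_conserving_phantom(fixture_spec(seed = 9))
  expect_true(check_saf_conservation(fx$saf, fx$phantom, tol = 1e-9))
  bad <- fx$saf
  bad$rtypes$photon$phi[] <- bad$rtypes$photon$phi * 2
  expect_error(check_saf_conservation(bad, fx$phantom), "conservation violated")
})
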