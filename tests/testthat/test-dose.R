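test_that("the TIAC-to-dose unit chain carries 3.6e9 nt per MBq.h", {
  u <- dose_units()
  expect_equal(u$nt_per_mbq_hour, 3.6e9)
  expect_equal(u$dose_multiplier_mgy, 3.6e12)
})

test_that("absorbed dose combines TIACs and S-values with the unit chain", {
  spec <- fixture_spec(seed = 31)
  fx <- make_conserving_phantom(spec)
  regions <- names(fx$phantom$region_masses)
  nuc <- make_toy_nuclide(spec, "gamma")
  sm <- s_matrix(nuc, fx$phantom, fx$saf, regions, regions)

  # all TIACs zero -> all doses zero
  z <- absorbed_dose(setNames(rep(0, length(regions)), regions), sm, "male")
  expect_true(all(z$doses$total == 0))

  # single source with TIAC 1 h and a hand-built S of 1e-15 Gy/nt
  sm1 <- sm
  for (r in names(sm1$breakdown)) sm1$breakdown[[r]][] <- 0
  sm1$breakdown$photon["region_1", "region_2"] <- 1e-15
  sm1$values <- Reduce(`+`, sm1$breakdown)
  d <- absorbed_dose(c(region_2 = 1), sm1, "male")
  expect_equal(d$doses$total[d$doses$target == "region_1"], 3.6e-3,
               tolerance = 1e-12)

  # doubling a TIAC doubles that source's contribution
  t1 <- setNames(runif(length(regions), 0.1, 2), regions)
  d1 <- absorbed_dose(t1, sm, "male")
  t2 <- t1; t2["region_1"] <- 2 * t1["region_1"]
  d2 <- absorbed_dose(t2, sm, "male")
  extra <- as.numeric(sm$values[, "region_1"] * t1["region_1"] * 3.6e12)
  expect_equal(d2$doses$total, d1$doses$total + extra, tolerance = 1e-9)

  expect_error(absorbed_dose(c(nowhere = 1), sm, "male"), "nowhere")
})

test_that("the remainder dose is the arithmetic mean of 13 tissues", {
  cfg <- weighting_config("ICRP103")
  cons <- cfg$remainder$male
  expect_length(cons, 13L)

  mk <- function(doses) {
    dose_result("p", "male",
                data.frame(target = cons, total = doses))
  }
  expect_equal(unname(remainder_dose(mk(rep(4, 13)), cfg)["total"]), 4)
  expect_equal(unname(remainder_dose(mk(c(rep(0, 12), 13)), cfg)["total"]), 1)
  expect_equal(unname(remainder_dose(mk(1:13), cfg)["total"]), 7)
  # female list swaps the prostate for the uterus/cervix
  expect_true("uterus_cervix" %in% cfg$remainder$female)
  expect_false("prostate" %in% cfg$remainder$female)
  # missing constituent is named
  short <- dose_result("p", "male",
                       data.frame(target = cons[-1], total = 1))
  expect_error(remainder_dose(short, cfg), cons[1])
})

test_that("tissue weights sum to one and carry the scheme anchors", {
  for (sch in c("ICRP103", "ICRP60")) {
    cfg <- weighting_config(sch)
    expect_equal(sum(cfg$w_T$weight), 1, tolerance = 1e-14)
    expect_identical(unname(cfg$w_R["alpha"]), 20)
    expect_identical(unname(cfg$w_R["photon"]), 1)
  }
  expect_identical(
    weighting_config("ICRP103")$w_T$weight[
      weighting_config("ICRP103")$w_T$tissue == "thyroid"], 0.04)
  expect_identical(
    weighting_config("ICRP60")$w_T$weight[
      weighting_config("ICRP60")$w_T$tissue == "thyroid"], 0.05)
})

test_that("a uniform organ dose gives an equal effective dose", {
  for (sch in c("ICRP103", "ICRP60")) {
    cfg <- weighting_config(sch)
    u <- make_uniform_dose(cfg, dose = 1)
    expect_equal(effective_dose(u$male, u$female, cfg), 1, tolerance = 1e-12)
    z <- make_uniform_dose(cfg, dose = 0)
    expect_equal(effective_dose(z$male, z$female, cfg), 0)
  }
})

test_that("single-tissue fixtures reproduce the weighting arithmetic", {
  cfg <- weighting_config("ICRP103")
  u <- make_uniform_dose(cfg, dose = 0)
  thy <- function(res, dose) {
    res$doses$photon[res$doses$target == "thyroid"] <- dose
    res$doses$total <- rowSums(res$doses[c("photon", "electron",
                                           "alpha", "beta")])
    res
  }
  m <- thy(u$male, 1); f <- thy(u$female, 1)
  expect_equal(effective_dose(m, f, cfg), 0.04, tolerance = 1e-12)
  # detriment-adjusted: no sex averaging
  m2 <- thy(u$male, 2)
  expect_equal(detriment_adjusted(m2, cfg), 0.08, tolerance = 1e-12)
  expect_equal(detriment_adjusted(u$female, cfg), 0)
  # alpha radiation picks up w_R = 20
  ua <- make_uniform_dose(cfg, dose = 1, rtype = "alpha")
  expect_equal(effective_dose(ua$male, ua$female, cfg), 20, tolerance = 1e-9)
})

test_that("effective dose is the mean of the sex-specific doses", {
  cfg <- weighting_config("ICRP103")
  set.seed(8)
  u <- make_uniform_dose(cfg, dose = 1)
  jitter <- function(res) {
    res$doses$photon <- res$doses$photon * runif(nrow(res$doses), 0.5, 2)
    res$doses$total <- rowSums(res$doses[c("photon", "electron",
                                           "alpha", "beta")])
    res
  }
  m <- jitter(u$male); f <- jitter(u$female)
  expect_equal(effective_dose(m, f, cfg),
               (detriment_adjusted(m, cfg) + detriment_adjusted(f, cfg)) / 2,
               tolerance = 1e-12)
})

test_that("effective dose is monotone in every organ dose", {
  cfg <- weighting_config("ICRP103")
  u <- make_uniform_dose(cfg, dose = 1)
  e0 <- effective_dose(u$male, u$female, cfg)
  for (tg in c("liver", "testes", "muscle")) {
    m <- u$male
    m$doses$photon[m$doses$target == tg] <- 2
    m$doses$total <- rowSums(m$doses[c("photon", "electron", "alpha", "beta")])
    expect_gte(effective_dose(m, u$female, cfg), e0)
  }
})

test_that("self-irradiation mass adjustment rescales only the self term", {
  expect_equal(mass_scaling_factor(2.36, 1.8), 2.36 / 1.8)
  expect_identical(signif(mass_scaling_factor(2.36, 1.8), 2), 1.3)
  spec <- fixture_spec(seed = 33)
  fx <- make_conserving_phantom(spec)
  nuc <- make_toy_nuclide(spec, "gamma")
  regions <- names(fx$phantom$region_masses)
  sm <- s_matrix(nuc, fx$phantom, fx$saf, regions, regions)
  adj <- adjust_self_mass(sm, "region_1", 2, 1)
  expect_equal(adj$values["region_1", "region_1"],
               2 * sm$values["region_1", "region_1"])
  off <- sm$values; off["region_1", "region_1"] <- NA
  adj_off <- adj$values; adj_off["region_1", "region_1"] <- NA
  expect_equal(adj_off, off)
})
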