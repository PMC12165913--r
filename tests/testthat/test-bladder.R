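no_void <- function(flow = 60, ...) {
  bladder_params(urine_flow = flow, voiding_interval = 1000, ...)
}

test_that("zero inflow and empty bladder stay at zero activity", {
  bc <- bladder_content(function(t) 0 * t, no_void(), lambda_phys = 0.2,
                        horizon = 12)
  expect_true(all(abs(bc$A) < 1e-12))
  expect_equal(content_tiac(bc), 0, tolerance = 1e-12)
})

test_that("constant inflow without voiding follows the closed-form ODE", {
  r <- 0.4; lam <- 0.35
  bc <- bladder_content(function(t) rep(r, length(t)), no_void(),
                        lambda_phys = lam, horizon = 10)
  expect_equal(bc$A, r / lam * (1 - exp(-lam * bc$times)), tolerance = 1e-7)
  # content TIAC matches the analytic integral of the same curve
  T <- 10
  expect_equal(content_tiac(bc),
               r / lam * (T - (1 - exp(-lam * T)) / lam), tolerance = 1e-7)
})

test_that("complete voiding empties the content instantly", {
  par <- bladder_params(urine_flow = 60, voiding_interval = 2,
                        residual_volume = 0)
  bc <- bladder_content(function(t) rep(0.5, length(t)), par,
                        lambda_phys = 0.1, horizon = 5)
  i <- which(bc$times == 2)
  expect_length(i, 2L)          # segment end and restart share the time
  expect_gt(bc$A[i[1]], 0)
  expect_equal(bc$A[i[2]], 0, tolerance = 1e-12)
})

test_that("well-mixed voids keep the residual volume fraction of activity", {
  par <- bladder_params(urine_flow = 100, voiding_interval = 2,
                        residual_volume = 20, initial_volume = 50)
  bc <- bladder_content(function(t) rep(1, length(t)), par,
                        lambda_phys = 0, horizon = 2.5)
  i <- which(bc$times == 2)
  V_before <- 50 + 100 * 2
  expect_equal(bc$V[i[1]], V_before, tolerance = 1e-9)
  expect_equal(bc$A[i[2]], bc$A[i[1]] * 20 / V_before, tolerance = 1e-9)
  expect_equal(bc$V[i[2]], 20)
})

test_that("a constant wall S-value reduces the model to the static form", {
  par <- bladder_params(urine_flow = 60, voiding_interval = 3.5,
                        residual_volume = 10, initial_volume = 25)
  lam <- 0.15
  infun <- function(t) 0.3 * exp(-0.2 * t)
  bc <- bladder_content(infun, par, lambda_phys = lam, horizon = 24)
  s <- 2e-15
  curve <- wall_svalue_curve("p", c(1, 1000), c(s, s))
  expect_equal(wall_dose_dynamic(bc, curve),
               content_tiac(bc) * s * 3.6e12, tolerance = 1e-8)
})

test_that("an inverse-volume S-value yields the logarithmic closed form", {
  # constant activity (no decay, no inflow, initial activity 1),
  # V(t) = V0 + f t, S(V) = c / V  ->  D = (c/f) log(1 + f T / V0)
  V0 <- 50; f <- 80; cS <- 5e-14; T <- 6
  par <- bladder_params(urine_flow = f, voiding_interval = 1000,
                        initial_volume = V0)
  bc <- bladder_content(function(t) 0 * t, par, lambda_phys = 0,
                        horizon = T, initial_activity = 1)
  vg <- exp(seq(log(10), log(1000), length.out = 12))
  curve <- wall_svalue_curve("p", vg, cS / vg)  # log-log exact power law
  want <- cS / f * log((V0 + f * T) / V0) * 3.6e12
  expect_equal(wall_dose_dynamic(bc, curve), want, tolerance = 1e-6)
})

test_that("shorter voiding intervals never increase the wall dose", {
  infun <- function(t) 0.5 * exp(-0.3 * t)
  curve <- make_wall_curve()
  doses <- vapply(c(0.5, 1, 2, 3.5, 6), function(iv) {
    par <- bladder_params(urine_flow = 60, voiding_interval = iv,
                          residual_volume = 5)
    bc <- bladder_content(infun, par, lambda_phys = 0.1, horizon = 24)
    wall_dose_dynamic(bc, curve)
  }, numeric(1))
  expect_true(all(diff(doses) >= -1e-10))
})

test_that("voiding cannot increase the content TIAC", {
  infun <- function(t) 0.5 * exp(-0.3 * t)
  lam <- 0.1
  par_v <- bladder_params(urine_flow = 60, voiding_interval = 3.5)
  bc_v <- bladder_content(infun, par_v, lam, horizon = 24)
  bc_nv <- bladder_content(infun, no_void(), lam, horizon = 24)
  expect_lte(content_tiac(bc_v), content_tiac(bc_nv))
})

test_that("activity balance closes: inflow = decayed + voided + residual", {
  infun <- function(t) 0.8 * exp(-0.25 * t)
  par <- bladder_params(urine_flow = 90, voiding_interval = 2.5,
                        residual_volume = 15, initial_volume = 10)
  bc <- bladder_content(infun, par, lambda_phys = 0.3, horizon = 30)
  expect_equal(bc$inflow,
               bc$decayed + bc$voided + bc$residual_activity,
               tolerance = 1e-6)
})

test_that("hydration speeds up volume growth inside its window", {
  h <- list(extra_flow = 120, start = 1, end = 3)
  par <- bladder_params(urine_flow = 60, voiding_interval = 1000,
                        hydration = h)
  bc <- bladder_content(function(t) 0 * t, par, 0, horizon = 5)
  v_at <- function(tt) bc$V[which.min(abs(bc$times - tt))]
  expect_equal(v_at(1), 60, tolerance = 1)
  expect_equal(v_at(3), 60 * 3 + 120 * 2, tolerance = 1)
  expect_equal(v_at(5), 60 * 5 + 120 * 2, tolerance = 1)
})

test_that("parameter validation rejects unphysical settings", {
  expect_error(bladder_params(urine_flow = 0), "positive")
  expect_error(bladder_params(60, voiding_interval = -1), "positive")
  expect_error(bladder_params(60, residual_volume = -5), ">= 0")
  bc <- bladder_content(function(t) 0 * t, no_void(), 0.1, horizon = 1)
  expect_error(wall_dose_dynamic(bc, make_wall_curve(), horizon = -1), "> 0")
})
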