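# Independent oracles used across the suite. These never call the code
# paths they check: the chain oracle is a stiff ODE integration, the TIAC
# oracle is adaptive quadrature of the evaluated retention curve.

# activities of a serial chain by direct ODE integration (nuclei form)
ode_chain_oracle <- function(lambda, branching, A0, times,
                             rtol = 1e-12, atol = 1e-16) {
  n <- length(lambda)
  deriv <- function(t, N, p) {
    dN <- -lambda * N
    if (n > 1L) {
      for (i in seq_len(n - 1L))
        dN[i + 1L] <- dN[i + 1L] + branching[i] * lambda[i] * N[i]
    }
    list(dN)
  }
  N0 <- c(A0 / lambda[1], rep(0, n - 1L))
  sol <- deSolve::lsoda(N0, unique(c(0, times)), deriv, NULL,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  N <- sol[match(times, sol[, 1]), -1, drop = FALSE]
  sweep(N, 2, lambda, `*`)
}

# adaptive-quadrature TIAC of a retention fit (with physical decay)
quad_tiac_oracle <- function(fit, lambda_phys = 0, T_D = Inf) {
  decay <- if (fit$decay_corrected) lambda_phys else 0
  f <- function(t) retention_value(fit, t) * exp(-decay * t)
  upper <- if (is.infinite(T_D)) Inf else T_D
  # roundoff warnings near the requested precision are expected; the value
  # is validated by the comparison itself
  suppressWarnings(
    stats::integrate(f, 0, upper, rel.tol = 1e-11, abs.tol = 1e-13,
                     subdivisions = 500L)$value)
}

# brute-force S-value: direct sum over emission lines against the stored
# SAF grid (fixture SAFs are constant in energy so no interpolation enters)
brute_force_s <- function(nuc, saf, target, source) {
  mev_j <- 1.602176634e-13
  s <- 0
  for (e in nuc$emissions) {
    if (e$kind == "beta_spectrum_ref" || e$yield == 0) next
    tab <- saf$rtypes[[e$kind]]
    phi <- tab$phi[target, source, 1]
    s <- s + e$energy * e$yield * phi * mev_j
  }
  if (!is.null(nuc$beta)) {
    tab <- saf$rtypes[["electron"]]
    phi <- tab$phi[target, source, 1]
    sp <- nuc$beta
    s <- s + pracma::trapz(sp$energy, sp$energy * sp$density) * phi * mev_j
  }
  s
}

# phantom-node ladder with linearly age-dependent uniform doses, one sex
make_test_nodes <- function(sex = "male",
                            ages = c(0, 1, 5, 10, 15, 20),
                            weights = c(3.5, 10, 19, 32, 56, 73),
                            base = 10, slope = -0.45) {
  cfg <- weighting_config("ICRP103")
  lapply(seq_along(ages), function(i) {
    u <- make_uniform_dose(cfg, dose = base + slope * ages[i])[[sex]]
    phantom_node(sprintf("node_%d_%s", i, sex), ages[i], weights[i], sex, u)
  })
}
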