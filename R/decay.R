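#' Single radiation emission of a decay scheme
#'
#' One line of a nuclide's emission list: a discrete photon, electron or
#' alpha line, or a reference to a tabulated beta spectrum.
#'
#' @param kind One of `"photon"`, `"electron"`, `"alpha"`,
#'   `"beta_spectrum_ref"`.
#' @param energy Energy per particle in MeV (omitted for
#'   `beta_spectrum_ref`).
#' @param yield Particles per nuclear transformation (>= 0).
#' @return An object of class `emission`.
#' @export
emission <- function(kind, energy = NULL, yield) {
  kind <- match.arg(kind, c("photon", "electron", "alpha", "beta_spectrum_ref"))
  if (!.is_num1(yield) || yield < 0)
    .stopf("emission yield must be a single non-negative number, got %s",
           deparse(yield))
  if (kind != "beta_spectrum_ref") {
    if (is.null(energy) || !.is_num1(energy) || energy <= 0)
      .stopf("discrete %s emission requires a single positive energy (MeV)", kind)
  } else {
    energy <- NULL
  }
  structure(list(kind = kind, energy = energy, yield = yield),
            class = "emission")
}

#' Tabulated beta spectrum
#'
#' Energy density of beta particles per nuclear transformation on a strictly
#' increasing MeV grid. The trapezoidal integral of `density` over the grid
#' is the beta branch yield (particles/nt).
#'
#' @param energy Strictly increasing energy grid (MeV).
#' @param density Particles per MeV per nuclear transformation (>= 0).
#' @return An object of class `beta_spectrum`.
#' @export
beta_spectrum <- function(energy, density) {
  if (length(energy) < 2L || any(diff(energy) <= 0))
    .stopf("beta spectrum energy grid must be strictly increasing with >= 2 points")
  if (length(density) != length(energy) || any(density < 0) || anyNA(density))
    .stopf("beta spectrum density must be non-negative and match the grid length")
  structure(list(energy = as.numeric(energy), density = as.numeric(density)),
            class = "beta_spectrum")
}

#' Nuclide decay scheme
#'
#' @param id Nuclide name, e.g. `"F-18"`, `"Tc-99m"`.
#' @param half_life Physical half-life in seconds (`Inf` for a stable member
#'   of a chain).
#' @param emissions List of [emission()] objects.
#' @param beta Optional [beta_spectrum()].
#' @param progeny Optional data.frame with columns `id`, `frac` (branching
#'   fractions in \[0,1\], summing to at most 1).
#' @return An object of class `nuclide`.
#' @export
nuclide <- function(id, half_life, emissions = list(), beta = NULL,
                    progeny = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    .stopf("nuclide id must be a non-empty string")
  if (!.is_num1(half_life) || half_life <= 0)
    .stopf("nuclide '%s': half_life must be positive (seconds)", id)
  if (!all(vapply(emissions, inherits, logical(1), "emission")))
    .stopf("nuclide '%s': emissions must be a list of emission objects", id)
  if (!is.null(beta) && !inherits(beta, "beta_spectrum"))
    .stopf("nuclide '%s': beta must be a beta_spectrum or NULL", id)
  if (is.null(progeny)) {
    progeny <- data.frame(id = character(), frac = numeric(),
                          stringsAsFactors = FALSE)
  } else {
    progeny <- as.data.frame(progeny, stringsAsFactors = FALSE)
    if (!all(c("id", "frac") %in% names(progeny)))
      .stopf("nuclide '%s': progeny needs columns id, frac", id)
    if (any(progeny$frac < 0 | progeny$frac > 1) || sum(progeny$frac) > 1 + 1e-12)
      .stopf("nuclide '%s': branching fractions must lie in [0,1] and sum to <= 1", id)
  }
  structure(list(id = id, half_life = half_life, emissions = emissions,
                 beta = beta, progeny = progeny),
            class = "nuclide")
}

#' @export
print.nuclide <- function(x, ...) {
  cat(sprintf("<nuclide %s>  T1/2 = %.6g s, %d emission line(s)%s%s\n",
              x$id, x$half_life, length(x$emissions),
              if (!is.null(x$beta)) ", beta spectrum" else "",
              if (nrow(x$progeny)) sprintf(", %d progeny", nrow(x$progeny)) else ""))
  invisible(x)
}

#' Serial decay chain
#'
#' An ordered serial chain: member `i` decays into member `i+1` with the
#' given branching fraction. The first member is the administered parent.
#'
#' @param nuclides List of [nuclide()] objects (parent first).
#' @param branching Numeric vector of length `length(nuclides) - 1`:
#'   branching fraction from member `i` to member `i+1`.
#' @return An object of class `decay_chain`.
#' @export
decay_chain <- function(nuclides, branching = NULL) {
  if (!length(nuclides) || !all(vapply(nuclides, inherits, logical(1), "nuclide")))
    .stopf("decay_chain needs a non-empty list of nuclide objects")
  ids <- vapply(nuclides, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    .stopf("decay_chain is cyclic or duplicated: repeated member '%s'",
           ids[duplicated(ids)][1])
  n <- length(nuclides)
  if (is.null(branching)) branching <- rep(1, max(n - 1L, 0L))
  if (length(branching) != n - 1L || any(branching < 0 | branching > 1))
    .stopf("branching must have length %d with values in [0,1]", n - 1L)
  if (is.infinite(nuclides[[1]]$half_life))
    .stopf("chain parent must be radioactive")
  structure(list(nuclides = nuclides, branching = as.numeric(branching)),
            class = "decay_chain")
}

#' Emitted energy per nuclear transformation
#'
#' For a discrete emission this is the product `E * Y`; for a beta spectrum
#' it is the trapezoidal integral of `E * density(E)` over the stored grid.
#'
#' @param x An [emission()] or [beta_spectrum()].
#' @return Energy per transformation in MeV/nt.
#' @examples
#' delta_per_transformation(emission("photon", 1.0, 0.5))  # 0.5
#' @export
delta_per_transformation <- function(x) UseMethod("delta_per_transformation")

#' @export
delta_per_transformation.emission <- function(x) {
  if (x$kind == "beta_spectrum_ref")
    .stopf("a beta_spectrum_ref carries no energy; integrate the spectrum instead")
  x$energy * x$yield
}

#' @export
delta_per_transformation.beta_spectrum <- function(x) {
  pracma::trapz(x$energy, x$energy * x$density)
}

#' Yield of a beta spectrum
#'
#' Trapezoidal integral of the density (particles per nt).
#' @param spec A [beta_spectrum()].
#' @return Particles per nuclear transformation.
#' @export
beta_yield <- function(spec) {
  stopifnot(inherits(spec, "beta_spectrum"))
  pracma::trapz(spec$energy, spec$density)
}

# Bateman partial-fraction coefficients for the activity of each member:
# A_k(t) = sum_i coef[k, i] * exp(-lambda_i * t), for distinct lambdas.
.bateman_coeffs <- function(lambda, branching, A0) {
  n <- length(lambda)
  coef <- matrix(0, n, n)
  # nuclei form: N_k(t) = N1(0) * prod(b_i lambda_i, i<k) *
  #              sum_{i<=k} exp(-l_i t) / prod_{j<=k, j!=i}(l_j - l_i)
  N1 <- A0 / lambda[1]
  for (k in seq_len(n)) {
    pref <- N1 * prod(branching[seq_len(k - 1L)] * lambda[seq_len(k - 1L)])
    for (i in seq_len(k)) {
      den <- prod(lambda[setdiff(seq_len(k), i)] - lambda[i])
      # activity of member k: lambda_k * N_k
      coef[k, i] <- lambda[k] * pref / den
    }
  }
  coef
}

#' Activities along a serial decay chain (Bateman solution)
#'
#' Closed-form Bateman solution with branching for the activity of every
#' chain member. Decay constants with relative differences below `1e-9`
#' (the confluent, equal-rate case) are routed to a matrix-exponential
#' evaluation of the chain, which is the stable limit form.
#'
#' @param chain A [decay_chain()].
#' @param A0 Parent activity at `t = 0` (MBq).
#' @param times Times in hours (>= 0).
#' @return A matrix `length(times) x n_members` of activities (MBq), with
#'   member ids as column names.
#' @export
bateman_activities <- function(chain, A0, times) {
  stopifnot(inherits(chain, "decay_chain"))
  if (!is.numeric(times) || any(times < 0))
    .stopf("times must be non-negative hours")
  lambda <- vapply(chain$nuclides, function(n) .lambda_per_h(n$half_life),
                   numeric(1))
  n <- length(lambda)
  ids <- vapply(chain$nuclides, `[[`, character(1), "id")

  degenerate <- FALSE
  if (n > 1L) {
    d <- abs(outer(lambda, lambda, "-"))
    scale <- pmax(outer(lambda, lambda, pmax), .Machine$double.xmin)
    rel <- d / scale
    diag(rel) <- Inf
    degenerate <- any(rel < 1e-9)
  }

  out <- matrix(0, length(times), n, dimnames = list(NULL, ids))
  if (!degenerate) {
    coef <- .bateman_coeffs(lambda, chain$branching, A0)
    for (k in seq_len(n)) {
      out[, k] <- colSums(coef[k, seq_len(k)] *
                            exp(-outer(lambda[seq_len(k)], times)))
    }
  } else {
    # confluent limit: N' = M N with lower-bidiagonal M, N(t) = expm(Mt) N0
    M <- diag(-lambda, n)
    for (i in seq_len(n - 1L)) M[i + 1L, i] <- chain$branching[i] * lambda[i]
    N0 <- c(A0 / lambda[1], rep(0, n - 1L))
    for (ti in seq_along(times)) {
      Nt <- as.numeric(Matrix::expm(M * times[ti]) %*% N0)
      out[ti, ] <- lambda * Nt
    }
  }
  out[abs(out) < 1e-300] <- 0
  out
}

# time-integrals of member activities from 0 to T_D (hours); used by the
# sphere progeny module. Requires distinct lambdas (checked by caller).
.bateman_tiac <- function(lambda, branching, A0, T_D = Inf) {
  n <- length(lambda)
  coef <- .bateman_coeffs(lambda, branching, A0)
  vapply(seq_len(n), function(k) {
    if (lambda[k] == 0) return(0)  # stable member: no activity
    li <- lambda[seq_len(k)]
    ci <- coef[k, seq_len(k)]
    if (is.infinite(T_D)) sum(ci / li)
    else sum(ci * (1 - exp(-li * T_D)) / li)
  }, numeric(1))
}
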