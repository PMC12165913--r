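#' Beta-spectrum contribution to an S-value
#'
#' The discrete sum over emissions is replaced by an integral over the beta
#' energy distribution: `S_beta = int E rho(E) Phi_e(E) dE` (converted to
#' Gy/nt). The quadrature is trapezoidal on the spectrum's own grid, with
#' the electron SAF interpolated to each spectrum node (spectra are denser
#' than SAF grids, which keeps the quadrature error in the spectrum, not
#' the SAF).
#'
#' @param nuc A [nuclide()].
#' @param saf A [saf_table()].
#' @param target,source Region names.
#' @return S_beta in Gy per nuclear transformation.
#' @export
s_beta <- function(nuc, saf, target, source) {
  stopifnot(inherits(nuc, "nuclide"))
  has_ref <- any(vapply(nuc$emissions, function(e)
    e$kind == "beta_spectrum_ref" && e$yield > 0, logical(1)))
  if (is.null(nuc$beta)) {
    if (has_ref)
      .stopf("nuclide '%s' declares a beta branch but carries no spectrum", nuc$id)
    return(0)
  }
  sp <- nuc$beta
  phi <- saf_at_energy(saf, target, source, "electron", sp$energy)
  pracma::trapz(sp$energy, sp$energy * sp$density * phi) * .MEV_J
}

#' S-value for one (target, source) pair
#'
#' Mean absorbed dose to the target per nuclear transformation in the
#' source: `S = sum_i Delta_i Phi(r_T <- r_S, E_i) + S_beta`, with
#' `Delta_i = E_i Y_i` converted from MeV to joules so that S is in Gy/nt.
#' Each discrete emission is looked up on the SAF grid of its radiation
#' type; the beta spectrum is handled by [s_beta()].
#'
#' @inheritParams s_beta
#' @param breakdown If `TRUE`, return a named vector with the
#'   photon/electron/alpha/beta components instead of the scalar total.
#' @return S in Gy/nt (scalar), or the per-radiation-type components.
#' @export
s_value <- function(nuc, saf, target, source, breakdown = FALSE) {
  stopifnot(inherits(nuc, "nuclide"), inherits(saf, "saf_table"))
  comp <- c(photon = 0, electron = 0, alpha = 0, beta = 0)
  for (e in nuc$emissions) {
    if (e$kind == "beta_spectrum_ref") next  # handled via the spectrum
    if (e$yield == 0) next
    if (is.null(saf$rtypes[[e$kind]]))
      .stopf("nuclide '%s' emits %s radiation but the SAF table has no '%s' grid",
             nuc$id, e$kind, e$kind)
    phi <- saf_at_energy(saf, target, source, e$kind, e$energy)
    comp[e$kind] <- comp[e$kind] + e$energy * e$yield * phi * .MEV_J
  }
  comp["beta"] <- s_beta(nuc, saf, target, source)
  if (breakdown) comp else sum(comp)
}

#' Assemble an S-matrix over region pairs
#'
#' Dense matrix of S-values (Gy/nt) for the requested targets and sources,
#' with a per-radiation-type breakdown. If `"Other"` is among the sources,
#' its SAF column is composed first via [compose_other_saf()] (which needs
#' `phantom` and the model's explicit source list).
#'
#' @param nuc A [nuclide()].
#' @param phantom A [phantom()] (required when `"Other"` is requested).
#' @param saf A [saf_table()].
#' @param sources,targets Character vectors of region names.
#' @param model_sources Explicit sources of the biokinetic model, used for
#'   the "Other" composition; defaults to `setdiff(sources, "Other")`.
#' @return An object of class `smatrix`: fields `nuclide_id`, `phantom_id`,
#'   `values` (targets x sources), `breakdown` (list of matrices per
#'   radiation type).
#' @export
s_matrix <- function(nuc, phantom = NULL, saf, sources, targets,
                     model_sources = setdiff(sources, "Other")) {
  if ("Other" %in% sources) {
    if (is.null(phantom))
      .stopf("composing source 'Other' requires the phantom")
    saf <- compose_other_saf(saf, model_sources, phantom)
  }
  rts <- c("photon", "electron", "alpha", "beta")
  bk <- lapply(rts, function(r)
    matrix(0, length(targets), length(sources),
           dimnames = list(targets, sources)))
  names(bk) <- rts
  for (s in sources) for (t in targets) {
    comp <- s_value(nuc, saf, t, s, breakdown = TRUE)
    for (r in rts) bk[[r]][t, s] <- comp[r]
  }
  values <- Reduce(`+`, bk)
  structure(list(nuclide_id = nuc$id,
                 phantom_id = if (is.null(phantom)) saf$phantom_id
                              else phantom$id,
                 values = values, breakdown = bk),
            class = "smatrix")
}

#' @export
print.smatrix <- function(x, ...) {
  cat(sprintf("<smatrix %s @ %s>  %d targets x %d sources [Gy/nt]\n",
              x$nuclide_id, x$phantom_id, nrow(x$values), ncol(x$values)))
  print(signif(x$values, 4))
  invisible(x)
}

#' Export an S-matrix as a long data.frame / CSV
#'
#' @param x An [s_matrix()] object.
#' @param path Optional CSV path; when given the table is also written.
#' @return Long data.frame with columns nuclide, phantom, target, source,
#'   S_Gy_per_nt and the photon/electron/alpha/beta components.
#' @export
smatrix_to_long <- function(x, path = NULL) {
  stopifnot(inherits(x, "smatrix"))
  g <- expand.grid(target = rownames(x$values), source = colnames(x$values),
                   stringsAsFactors = FALSE)
  out <- data.frame(
    nuclide = x$nuclide_id, phantom = x$phantom_id,
    target = g$target, source = g$source,
    S_Gy_per_nt = x$values[cbind(g$target, g$source)],
    photon = x$breakdown$photon[cbind(g$target, g$source)],
    electron = x$breakdown$electron[cbind(g$target, g$source)],
    alpha = x$breakdown$alpha[cbind(g$target, g$source)],
    beta = x$breakdown$beta[cbind(g$target, g$source)],
    stringsAsFactors = FALSE)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
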