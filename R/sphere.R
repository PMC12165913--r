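#' Absorbed-fraction table for spherical volumes
#'
#' Absorbed fractions AF(V, E) for a homogeneous sphere of one tissue
#' material, per radiation type, on a (volume, energy) grid. AF values are
#' dimensionless in \[0, 1\] and should be non-decreasing in volume at
#' fixed energy (larger spheres absorb more of the emitted energy); a
#' violation triggers a warning, not an error, since sparse measured
#' tables can be noisy.
#'
#' @param tissue_id Tissue material identifier (the sphere module carries
#'   user-defined materials, conventionally numbered 1-21).
#' @param density Density (g/cm^3).
#' @param data Long-format data.frame with columns `rtype`, `V_cm3`,
#'   `E_MeV`, `af`; every rtype must cover its full (V, E) grid.
#' @return An object of class `sphere_af_table`.
#' @export
sphere_af_table <- function(tissue_id, density, data) {
  if (!.is_num1(density) || density <= 0)
    .stopf("density must be positive (g/cm3)")
  need <- c("rtype", "V_cm3", "E_MeV", "af")
  if (!all(need %in% names(data)))
    .stopf("sphere AF data needs columns: %s", paste(need, collapse = ", "))
  if (any(data$af < 0 | data$af > 1))
    .stopf("absorbed fractions must lie in [0, 1]")
  tabs <- list()
  for (rt in unique(data$rtype)) {
    d <- data[data$rtype == rt, , drop = FALSE]
    vg <- sort(unique(d$V_cm3)); eg <- sort(unique(d$E_MeV))
    m <- matrix(NA_real_, length(vg), length(eg))
    m[cbind(match(d$V_cm3, vg), match(d$E_MeV, eg))] <- d$af
    if (anyNA(m))
      .stopf("sphere AF table: incomplete (V, E) grid for rtype '%s'", rt)
    if (length(vg) > 1L && any(apply(m, 2, function(col) any(diff(col) < -1e-12))))
      warning(sprintf("AF not non-decreasing in volume for rtype '%s'", rt),
              call. = FALSE)
    tabs[[rt]] <- list(volume = vg, energy = eg, af = m)
  }
  structure(list(tissue_id = tissue_id, density = density, rtypes = tabs),
            class = "sphere_af_table")
}

# bilinear interpolation of AF in (log V, log E); exact at grid nodes,
# clamped outside the grid.
.af_at <- function(tab, V, E) {
  lv <- log(pmin(pmax(V, tab$volume[1]), tab$volume[length(tab$volume)]))
  gx <- log(tab$volume); gy <- log(tab$energy)
  le <- log(pmin(pmax(E, tab$energy[1]), tab$energy[length(tab$energy)]))
  vapply(seq_along(le), function(j) {
    i <- max(findInterval(lv, gx), 1L); i <- min(i, length(gx) - 1L)
    if (length(gx) == 1L) i <- 1L
    k <- max(findInterval(le[j], gy), 1L); k <- min(k, length(gy) - 1L)
    if (length(gy) == 1L) k <- 1L
    if (length(gx) == 1L) {
      a <- tab$af[1, k]; b <- tab$af[1, min(k + 1L, length(gy))]
      ty <- if (length(gy) == 1L) 0 else (le[j] - gy[k]) / (gy[k + 1L] - gy[k])
      return((1 - ty) * a + ty * b)
    }
    tx <- (lv - gx[i]) / (gx[i + 1L] - gx[i])
    ty <- if (length(gy) == 1L) 0 else (le[j] - gy[k]) / (gy[k + 1L] - gy[k])
    k2 <- min(k + 1L, length(gy))
    (1 - tx) * (1 - ty) * tab$af[i, k] + tx * (1 - ty) * tab$af[i + 1L, k] +
      (1 - tx) * ty * tab$af[i, k2] + tx * ty * tab$af[i + 1L, k2]
  }, numeric(1))
}

#' S-value for a sphere of a given volume
#'
#' Self-irradiation S-value of a homogeneous sphere: the SAF is
#' `AF(E, V) / mass` with `mass = density x volume`, combined with the
#' nuclide's discrete emissions and beta spectrum exactly as in the
#' phantom S-value. AF is interpolated bilinearly in (log E, log V); the
#' beta spectrum uses the electron AF grid.
#'
#' @param nuc A [nuclide()].
#' @param table A [sphere_af_table()].
#' @param volume Sphere volume (cm^3), within the table's volume grid.
#' @param breakdown Return the photon/electron/alpha/beta split instead of
#'   the total.
#' @return S in Gy/nt (scalar or named components).
#' @export
sphere_s <- function(nuc, table, volume, breakdown = FALSE) {
  stopifnot(inherits(nuc, "nuclide"), inherits(table, "sphere_af_table"))
  vr <- range(unlist(lapply(table$rtypes, `[[`, "volume")))
  if (!.is_num1(volume) || volume < vr[1] || volume > vr[2])
    .stopf("volume %.4g cm3 outside the tabulated range [%.4g, %.4g]",
           volume, vr[1], vr[2])
  mass_kg <- table$density * volume / 1000
  comp <- c(photon = 0, electron = 0, alpha = 0, beta = 0)
  for (e in nuc$emissions) {
    if (e$kind == "beta_spectrum_ref" || e$yield == 0) next
    tab <- table$rtypes[[e$kind]]
    if (is.null(tab))
      .stopf("sphere AF table has no grid for radiation type '%s'", e$kind)
    af <- .af_at(tab, volume, e$energy)
    comp[e$kind] <- comp[e$kind] + e$energy * e$yield * af / mass_kg * .MEV_J
  }
  if (!is.null(nuc$beta)) {
    tab <- table$rtypes[["electron"]]
    if (is.null(tab))
      .stopf("beta spectrum requires an electron AF grid")
    sp <- nuc$beta
    af <- .af_at(tab, volume, sp$energy)
    comp["beta"] <- pracma::trapz(sp$energy,
                                  sp$energy * sp$density * af) /
      mass_kg * .MEV_J
  } else if (any(vapply(nuc$emissions, function(e)
    e$kind == "beta_spectrum_ref" && e$yield > 0, logical(1)))) {
    .stopf("nuclide '%s' declares a beta branch but carries no spectrum", nuc$id)
  }
  if (breakdown) comp else sum(comp)
}

#' Sphere dose with progeny in-growth
#'
#' Dose to a sphere per administered MBq of the chain parent, itemized per
#' chain member. The parent's retention in the sphere is taken as
#' mono-exponential with effective clearance `1/tiac_parent` (so that the
#' retention integrates to the given TIAC from unit initial content);
#' progeny are produced in place with no washout and decay with their own
#' physical constants, so the member activities follow the Bateman cascade
#' driven by the parent's effective clearance. At `T_D = Inf` each
#' member's TIAC equals the cumulative branching fraction times the parent
#' TIAC.
#'
#' @param chain A [decay_chain()].
#' @param table A [sphere_af_table()] (same tissue for all members).
#' @param volume Sphere volume (cm^3).
#' @param tiac_parent Parent TIAC in the sphere (hours).
#' @param T_D Integration period (hours, default `Inf`).
#' @return data.frame with per-member `nuclide`, `tiac_h`, `dose_mGy_per_MBq`
#'   and the radiation-type dose split; total dose as attribute `"total"`.
#' @export
sphere_dose_with_progeny <- function(chain, table, volume, tiac_parent,
                                     T_D = Inf) {
  stopifnot(inherits(chain, "decay_chain"))
  if (!.is_num1(tiac_parent) || tiac_parent <= 0)
    .stopf("tiac_parent must be positive (hours)")
  lambda_phys <- vapply(chain$nuclides, function(n)
    .lambda_per_h(n$half_life), numeric(1))
  lambda_eff <- c(1 / tiac_parent, lambda_phys[-1])
  if (length(lambda_eff) > 1L) {
    rel <- abs(outer(lambda_eff, lambda_eff, "-")) /
      pmax(outer(lambda_eff, lambda_eff, pmax), .Machine$double.xmin)
    diag(rel) <- Inf
    if (any(rel < 1e-9))
      .stopf(paste0("near-equal effective decay constants in the sphere ",
                    "chain; perturb tiac_parent slightly"))
  }
  tiacs <- .bateman_tiac(lambda_eff, chain$branching, A0 = 1, T_D = T_D)
  rows <- lapply(seq_along(chain$nuclides), function(k) {
    comp <- sphere_s(chain$nuclides[[k]], table, volume, breakdown = TRUE)
    d <- comp * tiacs[k] * .D_MULT
    data.frame(nuclide = chain$nuclides[[k]]$id, tiac_h = tiacs[k],
               dose_mGy_per_MBq = sum(d),
               photon = d[["photon"]], electron = d[["electron"]],
               alpha = d[["alpha"]], beta = d[["beta"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "total") <- sum(out$dose_mGy_per_MBq)
  out
}

#' Read a sphere AF table from the long CSV dialect
#'
#' Columns: `tissue, density_g_cm3, rtype, V_cm3, E_MeV, af`.
#' @param path CSV path.
#' @return Named list of [sphere_af_table()] per tissue id.
#' @export
read_sphere_af <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tissue", "density_g_cm3", "rtype", "V_cm3", "E_MeV", "af")
  if (!all(need %in% names(d)))
    .stopf("%s: needs columns %s", path, paste(need, collapse = ", "))
  lapply(split(d, d$tissue), function(g)
    sphere_af_table(g$tissue[1], g$density_g_cm3[1],
                    g[c("rtype", "V_cm3", "E_MeV", "af")]))
}
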