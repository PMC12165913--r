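#' Read a SAF fixture (long CSV dialect)
#'
#' Three plain CSV tables sharing a path prefix mirror the structure of the
#' published SAF electronic supplements at miniature scale:
#'
#' * `<prefix>_saf.csv`: `phantom, rtype, target, source, E_MeV, phi_per_kg`;
#' * `<prefix>_masses.csv`: `phantom, region, mass_kg, total_mass_kg, sex,
#'   age_class, other_eligible, blood_only` (logical flags);
#' * `<prefix>_blood.csv` (optional): `phantom, region, blood_fraction,
#'   blood_mass_kg`.
#'
#' @param prefix Path prefix of the fixture.
#' @return Named list per phantom id: `list(phantom =, saf =)`.
#' @export
read_saf_fixture <- function(prefix) {
  saf_path <- paste0(prefix, "_saf.csv")
  mas_path <- paste0(prefix, "_masses.csv")
  blo_path <- paste0(prefix, "_blood.csv")
  for (p in c(saf_path, mas_path))
    if (!file.exists(p)) .stopf("SAF fixture file not found: %s", p)
  saf <- utils::read.csv(saf_path, stringsAsFactors = FALSE)
  mas <- utils::read.csv(mas_path, stringsAsFactors = FALSE)
  blo <- if (file.exists(blo_path))
    utils::read.csv(blo_path, stringsAsFactors = FALSE) else NULL

  out <- list()
  for (ph in unique(mas$phantom)) {
    m <- mas[mas$phantom == ph, , drop = FALSE]
    rm <- stats::setNames(m$mass_kg, m$region)
    bf <- numeric(); bm <- 0
    if (!is.null(blo)) {
      b <- blo[blo$phantom == ph, , drop = FALSE]
      if (nrow(b)) {
        bf <- stats::setNames(b$blood_fraction, b$region)
        bm <- b$blood_mass_kg[1]
      }
    }
    pobj <- phantom(sex = m$sex[1], age_class = m$age_class[1],
                    total_mass = m$total_mass_kg[1], region_masses = rm,
                    blood_fractions = bf, blood_mass = bm,
                    other_eligible = m$region[as.logical(m$other_eligible)],
                    blood_only_regions = m$region[as.logical(m$blood_only)])
    s <- saf[saf$phantom == ph, , drop = FALSE]
    out[[ph]] <- list(phantom = pobj, saf = saf_table(ph, s))
  }
  out
}

#' Write a SAF fixture (long CSV dialect)
#'
#' Inverse of [read_saf_fixture()] for a single phantom + SAF table pair.
#'
#' @param phantom A [phantom()].
#' @param saf A [saf_table()].
#' @param prefix Path prefix for the output.
#' @return `prefix`, invisibly.
#' @export
write_saf_fixture <- function(phantom, saf, prefix) {
  rows <- list()
  for (rt in names(saf$rtypes)) {
    tab <- saf$rtypes[[rt]]
    dn <- dimnames(tab$phi)
    g <- expand.grid(target = dn[[1]], source = dn[[2]],
                     ei = seq_along(tab$energy), stringsAsFactors = FALSE)
    idx <- cbind(match(g$target, dn[[1]]), match(g$source, dn[[2]]), g$ei)
    rows[[rt]] <- data.frame(
      phantom = phantom$id, rtype = rt, target = g$target, source = g$source,
      E_MeV = tab$energy[g$ei], phi_per_kg = tab$phi[idx],
      stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, rows), paste0(prefix, "_saf.csv"),
                   row.names = FALSE)
  regs <- names(phantom$region_masses)
  utils::write.csv(data.frame(
    phantom = phantom$id, region = regs,
    mass_kg = unname(phantom$region_masses),
    total_mass_kg = phantom$total_mass, sex = phantom$sex,
    age_class = phantom$age_class,
    other_eligible = regs %in% phantom$other_eligible,
    blood_only = regs %in% phantom$blood_only_regions,
    stringsAsFactors = FALSE), paste0(prefix, "_masses.csv"),
    row.names = FALSE)
  if (length(phantom$blood_fractions)) {
    utils::write.csv(data.frame(
      phantom = phantom$id, region = names(phantom$blood_fractions),
      blood_fraction = unname(phantom$blood_fractions),
      blood_mass_kg = phantom$blood_mass, stringsAsFactors = FALSE),
      paste0(prefix, "_blood.csv"), row.names = FALSE)
  }
  invisible(prefix)
}

#' Adapter stub for the published SAF electronic supplements
#'
#' The adult and paediatric SAF electronic supplements are user-supplied
#' data and are never bundled. Convert them once to the CSV dialect of
#' [read_saf_fixture()]; this stub validates paths and points there.
#'
#' @param path Path to a user-supplied supplement file.
#' @return Does not return; raises an informative error.
#' @export
read_icrp_saf <- function(path) {
  if (!file.exists(path))
    .stopf("SAF supplement file not found: %s (user-supplied, never bundled)", path)
  .stopf(paste0(
    "direct parsing of the SAF electronic supplements is not bundled; ",
    "convert them to the documented CSV dialect (see ?read_saf_fixture) ",
    "and load with read_saf_fixture()"))
}

#' Validate the energy-conservation bound of a SAF table
#'
#' For each source and grid energy the mass-weighted sum over targets of
#' the SAF cannot exceed 1 (the absorbed energy cannot exceed the emitted
#' energy): `sum_T m_T Phi(T <- S, E) <= 1 + tol`.
#'
#' @param table A [saf_table()].
#' @param phantom A [phantom()] supplying the target masses.
#' @param tol Tolerance (default `1e-6`).
#' @return Invisibly `TRUE`; raises an error on violation.
#' @export
check_saf_conservation <- function(table, phantom, tol = 1e-6) {
  for (rt in names(table$rtypes)) {
    arr <- table$rtypes[[rt]]$phi
    tg <- dimnames(arr)[[1]]
    m <- phantom$region_masses[tg]
    if (anyNA(m)) .stopf("phantom lacks masses for target(s): %s",
                         paste(tg[is.na(m)], collapse = ", "))
    ws <- apply(arr, c(2, 3), function(v) sum(v * m))
    if (any(ws > 1 + tol))
      .stopf("SAF conservation violated for rtype '%s': max mass-weighted sum %.8g",
             rt, max(ws))
  }
  invisible(TRUE)
}
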