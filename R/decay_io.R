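#' Read a decay-scheme fixture (CSV trio dialect)
#'
#' The fixture dialect mirrors the structure of the ICRP nuclear-decay
#' electronic files at miniature scale, as three plain CSV tables sharing a
#' path prefix:
#'
#' * `<prefix>_index.csv`: `id, half_life_s, progeny, branching` where
#'   `progeny`/`branching` are `;`-separated lists (empty for none);
#' * `<prefix>_emissions.csv`: `id, kind, E_MeV, yield` with kind in
#'   photon/electron/alpha/beta_spectrum_ref (`E_MeV` empty for the latter);
#' * `<prefix>_beta.csv` (optional): `id, E_MeV, density` rows forming each
#'   nuclide's beta spectrum in grid order.
#'
#' Adapters for the real ICRP-07.NDX/RAD/BET files are intentionally not
#' bundled; see [read_icrp107()].
#'
#' @param prefix Path prefix of the fixture trio.
#' @return A named list of [nuclide()] objects. Progeny ids not present in
#'   the set are kept but flagged with a warning.
#' @export
read_decay_fixture <- function(prefix) {
  idx_path <- paste0(prefix, "_index.csv")
  emi_path <- paste0(prefix, "_emissions.csv")
  bet_path <- paste0(prefix, "_beta.csv")
  if (!file.exists(idx_path))
    .stopf("decay fixture index not found: %s", idx_path)
  idx <- utils::read.csv(idx_path, stringsAsFactors = FALSE,
                         colClasses = c(id = "character"))
  if (!nrow(idx)) return(structure(list(), names = character()))
  need <- c("id", "half_life_s", "progeny", "branching")
  if (!all(need %in% names(idx)))
    .stopf("%s: missing column(s) %s", idx_path,
           paste(setdiff(need, names(idx)), collapse = ", "))

  emi <- if (file.exists(emi_path)) {
    utils::read.csv(emi_path, stringsAsFactors = FALSE,
                    colClasses = c(id = "character"))
  } else data.frame(id = character(), kind = character(),
                    E_MeV = numeric(), yield = numeric())
  bet <- if (file.exists(bet_path)) {
    utils::read.csv(bet_path, stringsAsFactors = FALSE,
                    colClasses = c(id = "character"))
  } else NULL

  nucs <- list()
  for (r in seq_len(nrow(idx))) {
    row <- idx[r, ]
    if (!is.finite(row$half_life_s) || row$half_life_s <= 0)
      .stopf("%s line %d (id '%s'): half_life_s must be positive",
             idx_path, r + 1L, row$id)
    prog <- NULL
    if (!is.na(row$progeny) && nzchar(trimws(row$progeny))) {
      pid <- strsplit(trimws(row$progeny), ";", fixed = TRUE)[[1]]
      pfr <- as.numeric(strsplit(trimws(row$branching), ";", fixed = TRUE)[[1]])
      if (length(pid) != length(pfr) || anyNA(pfr))
        .stopf("%s line %d (id '%s'): progeny/branching lists disagree",
               idx_path, r + 1L, row$id)
      prog <- data.frame(id = pid, frac = pfr, stringsAsFactors = FALSE)
    }
    er <- emi[emi$id == row$id, , drop = FALSE]
    ems <- lapply(seq_len(nrow(er)), function(i) {
      k <- er$kind[i]
      if (!k %in% c("photon", "electron", "alpha", "beta_spectrum_ref"))
        .stopf("%s: id '%s' row %d: unknown emission kind '%s'",
               emi_path, row$id, i, k)
      if (k == "beta_spectrum_ref") emission(k, yield = er$yield[i])
      else emission(k, er$E_MeV[i], er$yield[i])
    })
    bspec <- NULL
    if (!is.null(bet)) {
      br <- bet[bet$id == row$id, , drop = FALSE]
      if (nrow(br)) bspec <- beta_spectrum(br$E_MeV, br$density)
    }
    nucs[[row$id]] <- nuclide(row$id, row$half_life_s, ems, bspec, prog)
    if (!is.null(bspec)) {
      y_ref <- sum(er$yield[er$kind == "beta_spectrum_ref"])
      y_int <- beta_yield(bspec)
      if (y_ref > 0 && abs(y_int - y_ref) > 1e-6 * max(y_ref, 1e-30))
        warning(sprintf(
          "nuclide '%s': beta spectrum integral %.8g differs from declared branch yield %.8g",
          row$id, y_int, y_ref), call. = FALSE)
    }
  }
  known <- names(nucs)
  for (nm in known) {
    miss <- setdiff(nucs[[nm]]$progeny$id, known)
    if (length(miss))
      warning(sprintf("nuclide '%s': progeny not in set: %s",
                      nm, paste(miss, collapse = ", ")), call. = FALSE)
  }
  nucs
}

#' Write a decay-scheme fixture (CSV trio dialect)
#'
#' Inverse of [read_decay_fixture()].
#'
#' @param nuclides Named list of [nuclide()] objects.
#' @param prefix Path prefix for the output trio.
#' @return `prefix`, invisibly.
#' @export
write_decay_fixture <- function(nuclides, prefix) {
  idx <- do.call(rbind, lapply(nuclides, function(n) {
    data.frame(id = n$id, half_life_s = n$half_life,
               progeny = paste(n$progeny$id, collapse = ";"),
               branching = paste(format(n$progeny$frac, digits = 17),
                                 collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(idx))
    idx <- data.frame(id = character(), half_life_s = numeric(),
                      progeny = character(), branching = character())
  utils::write.csv(idx, paste0(prefix, "_index.csv"), row.names = FALSE)

  emi <- do.call(rbind, lapply(nuclides, function(n) {
    if (!length(n$emissions)) return(NULL)
    do.call(rbind, lapply(n$emissions, function(e) {
      data.frame(id = n$id, kind = e$kind,
                 E_MeV = if (is.null(e$energy)) NA_real_ else e$energy,
                 yield = e$yield, stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(emi))
    emi <- data.frame(id = character(), kind = character(),
                      E_MeV = numeric(), yield = numeric())
  utils::write.csv(emi, paste0(prefix, "_emissions.csv"), row.names = FALSE)

  bet <- do.call(rbind, lapply(nuclides, function(n) {
    if (is.null(n$beta)) return(NULL)
    data.frame(id = n$id, E_MeV = n$beta$energy, density = n$beta$density,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(bet))
    utils::write.csv(bet, paste0(prefix, "_beta.csv"), row.names = FALSE)
  invisible(prefix)
}

#' Adapter stub for the ICRP Publication 107 electronic files
#'
#' The real nuclear-decay electronic supplement (NDX/RAD/BET files) is
#' licensed data that users must supply themselves; it is never bundled.
#' This adapter validates the paths and instructs how to convert the files
#' into the fixture dialect of [read_decay_fixture()].
#'
#' @param ndx,rad,bet Paths to the user-supplied files.
#' @return Does not return; raises an informative error until user-supplied
#'   files are converted with an external one-off script.
#' @export
read_icrp107 <- function(ndx, rad, bet = NULL) {
  for (p in c(ndx, rad, bet)) {
    if (!is.null(p) && !file.exists(p))
      .stopf("ICRP 107 file not found: %s (the electronic supplement is user-supplied, never bundled)", p)
  }
  .stopf(paste0(
    "direct parsing of the ICRP 107 electronic files is not bundled; ",
    "convert them to the documented CSV fixture dialect ",
    "(see ?read_decay_fixture) and load with read_decay_fixture()"))
}
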