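#' Tissue- and radiation-weighting configuration
#'
#' Shipped weighting sets for the two tissue-weighting schemes. Each scheme
#' maps weighted tissues to canonical target names (sex-specific where
#' needed: gonads resolve to testes/ovaries, the remainder constituent list
#' includes the prostate for males and the uterus/cervix for females). The
#' radiation weighting factors are 1 for photons and electrons (incl. beta)
#' and 20 for alpha particles. Tissue weights sum to exactly 1 per scheme.
#'
#' @param scheme `"ICRP103"` (default) or `"ICRP60"`.
#' @return An object of class `weighting_config` with fields `scheme`,
#'   `w_T` (data.frame tissue/weight/male_target/female_target),
#'   `remainder` (per-sex constituent lists), `w_R` (named vector).
#' @examples
#' cfg <- weighting_config("ICRP103")
#' cfg$w_T$weight[cfg$w_T$tissue == "thyroid"]  # 0.04
#' @export
weighting_config <- function(scheme = c("ICRP103", "ICRP60")) {
  scheme <- match.arg(scheme)
  if (scheme == "ICRP103") {
    w_T <- data.frame(
      tissue = c("red_marrow", "colon", "lung", "stomach", "breast",
                 "remainder", "gonads", "bladder", "oesophagus", "liver",
                 "thyroid", "endosteum", "brain", "salivary_glands", "skin"),
      weight = c(0.12, 0.12, 0.12, 0.12, 0.12,
                 0.12, 0.08, 0.04, 0.04, 0.04,
                 0.04, 0.01, 0.01, 0.01, 0.01),
      stringsAsFactors = FALSE)
    rem_common <- c("adrenals", "extrathoracic_region", "gallbladder",
                    "heart_wall", "kidneys", "lymphatic_nodes", "muscle",
                    "oral_mucosa", "pancreas", "small_intestine", "spleen",
                    "thymus")
    remainder <- list(male = c(rem_common, "prostate"),
                      female = c(rem_common, "uterus_cervix"))
  } else {
    w_T <- data.frame(
      tissue = c("gonads", "red_marrow", "colon", "lung", "stomach",
                 "bladder", "breast", "liver", "oesophagus", "thyroid",
                 "skin", "endosteum", "remainder"),
      weight = c(0.20, 0.12, 0.12, 0.12, 0.12,
                 0.05, 0.05, 0.05, 0.05, 0.05,
                 0.01, 0.01, 0.05),
      stringsAsFactors = FALSE)
    rem_common <- c("adrenals", "brain", "colon", "small_intestine",
                    "kidneys", "muscle", "pancreas", "spleen", "thymus")
    remainder <- list(male = rem_common,
                      female = c(rem_common, "uterus_cervix"))
  }
  stopifnot(abs(sum(w_T$weight) - 1) < 1e-12)
  w_T$male_target <- ifelse(w_T$tissue == "gonads", "testes", w_T$tissue)
  w_T$female_target <- ifelse(w_T$tissue == "gonads", "ovaries", w_T$tissue)
  structure(list(scheme = scheme, w_T = w_T, remainder = remainder,
                 w_R = c(photon = 1, electron = 1, beta = 1, alpha = 20)),
            class = "weighting_config")
}

#' Per-target dose result for one phantom
#'
#' @param phantom_id Phantom identifier.
#' @param sex `"male"` or `"female"`.
#' @param doses data.frame with columns `target` and the radiation-type
#'   components `photon`, `electron`, `alpha`, `beta` (mGy/MBq); a single
#'   `total` column is accepted and treated as pure photon dose.
#' @return An object of class `dose_result`; `$doses$total` is the
#'   component sum.
#' @export
dose_result <- function(phantom_id, sex, doses) {
  sex <- match.arg(sex, c("male", "female"))
  doses <- as.data.frame(doses, stringsAsFactors = FALSE)
  rts <- c("photon", "electron", "alpha", "beta")
  if (!"target" %in% names(doses)) .stopf("doses needs a 'target' column")
  if (!any(rts %in% names(doses))) {
    if (!"total" %in% names(doses))
      .stopf("doses needs radiation-type columns or a 'total' column")
    doses$photon <- doses$total
  }
  for (r in rts) if (!r %in% names(doses)) doses[[r]] <- 0
  if (any(as.matrix(doses[rts]) < 0)) .stopf("doses must be >= 0")
  doses$total <- rowSums(doses[rts])
  structure(list(phantom_id = phantom_id, sex = sex,
                 doses = doses[c("target", rts, "total")]),
            class = "dose_result")
}

#' @export
print.dose_result <- function(x, ...) {
  cat(sprintf("<dose_result %s (%s)>  [mGy/MBq]\n", x$phantom_id, x$sex))
  df <- x$doses
  df[-1] <- lapply(df[-1], signif, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

# dose components of one target as a named vector (photon/electron/alpha/beta)
.dose_components <- function(result, target) {
  i <- match(target, result$doses$target)
  if (is.na(i))
    .stopf("dose_result (%s) lacks target '%s'", result$phantom_id, target)
  unlist(result$doses[i, c("photon", "electron", "alpha", "beta")])
}

# radiation-weighted (equivalent) dose of one target, mSv/MBq
.equivalent_dose <- function(result, target, cfg) {
  sum(.dose_components(result, target) * cfg$w_R[c("photon", "electron",
                                                   "alpha", "beta")])
}

#' Organ absorbed doses from TIACs and an S-matrix
#'
#' `D(r_T) = sum_S TIAC(r_S) x S(r_T <- r_S)` with the unit chain
#' TIAC\[h\] x 3.6e9 \[nt/(MBq.h)\] x S\[Gy/nt\] x 1e3 \[mGy/Gy\], i.e. a
#' single multiplier of 3.6e12 (see [dose_units()]).
#'
#' @param tiac Named numeric vector: source region -> TIAC (hours).
#' @param smat An [s_matrix()] object; every TIAC source must have a
#'   column (compose "Other" beforehand if the model uses it).
#' @param sex Sex of the phantom the S-matrix belongs to.
#' @return A [dose_result()] with the radiation-type breakdown (mGy/MBq).
#' @export
absorbed_dose <- function(tiac, smat, sex) {
  stopifnot(inherits(smat, "smatrix"))
  if (any(tiac < 0)) .stopf("TIACs must be >= 0")
  orphan <- setdiff(names(tiac), colnames(smat$values))
  if (length(orphan))
    .stopf("TIAC source(s) with no S-matrix column: %s",
           paste(orphan, collapse = ", "))
  src <- names(tiac)
  rts <- c("photon", "electron", "alpha", "beta")
  comp <- lapply(rts, function(r)
    as.numeric(smat$breakdown[[r]][, src, drop = FALSE] %*% tiac) * .D_MULT)
  names(comp) <- rts
  doses <- data.frame(target = rownames(smat$values), comp,
                      stringsAsFactors = FALSE)
  dose_result(smat$phantom_id, sex, doses)
}

#' Remainder-tissues dose
#'
#' The composite target "Remainder tissues" is the unweighted arithmetic
#' mean of the absorbed doses of 13 specified organs and tissues (the list
#' is sex-specific: prostate for males, uterus/cervix for females under
#' the ICRP 103 scheme).
#'
#' @param result A [dose_result()].
#' @param cfg A [weighting_config()].
#' @param sex Defaults to the result's sex.
#' @return Named vector of the remainder components and total (mGy/MBq).
#' @export
remainder_dose <- function(result, cfg = weighting_config("ICRP103"),
                           sex = result$sex) {
  stopifnot(inherits(result, "dose_result"))
  cons <- cfg$remainder[[sex]]
  miss <- setdiff(cons, result$doses$target)
  if (length(miss))
    .stopf("remainder constituent(s) missing from result: %s",
           paste(miss, collapse = ", "))
  comp <- rowMeans(vapply(cons, function(tg) .dose_components(result, tg),
                          numeric(4)))
  c(comp, total = sum(comp))
}

# equivalent dose of a weighted tissue for one sex; remainder handled via
# the arithmetic-mean rule.
.tissue_equivalent <- function(result, tissue, cfg) {
  if (tissue == "remainder") {
    comp <- remainder_dose(result, cfg)[c("photon", "electron", "alpha", "beta")]
    return(sum(comp * cfg$w_R[c("photon", "electron", "alpha", "beta")]))
  }
  target <- cfg$w_T[[paste0(result$sex, "_target")]][
    match(tissue, cfg$w_T$tissue)]
  .equivalent_dose(result, target, cfg)
}

#' Effective dose (sex-averaged)
#'
#' `E = sum_T w_T [w_R D_R(male) + w_R D_R(female)] / 2`: the
#' radiation-weighted equivalent doses of the Reference Male and Reference
#' Female are averaged per tissue, then tissue-weighted and summed.
#' Sex-specific organs contribute their single-sex equivalent dose to the
#' average (gonads: testes vs ovaries; remainder: prostate vs
#' uterus/cervix), per the reference-person convention.
#'
#' @param male,female [dose_result()] objects for the same age class.
#' @param cfg A [weighting_config()].
#' @return Effective dose in mSv/MBq.
#' @export
effective_dose <- function(male, female, cfg = weighting_config("ICRP103")) {
  stopifnot(inherits(male, "dose_result"), inherits(female, "dose_result"))
  if (male$sex != "male" || female$sex != "female")
    .stopf("effective_dose expects a male and a female dose_result")
  E <- 0
  for (i in seq_len(nrow(cfg$w_T))) {
    tissue <- cfg$w_T$tissue[i]
    Hm <- .tissue_equivalent(male, tissue, cfg)
    Hf <- .tissue_equivalent(female, tissue, cfg)
    E <- E + cfg$w_T$weight[i] * (Hm + Hf) / 2
  }
  E
}

#' Detriment-adjusted (sex-specific) effective dose
#'
#' The same tissue- and radiation-weighted sum as [effective_dose()] but
#' without the sex average: the equivalent doses of one sex only are
#' weighted and summed, giving a sex-specific effective dose.
#'
#' @param result A [dose_result()] for one sex.
#' @param cfg A [weighting_config()].
#' @return Sex-specific effective dose in mSv/MBq.
#' @export
detriment_adjusted <- function(result, cfg = weighting_config("ICRP103")) {
  stopifnot(inherits(result, "dose_result"))
  sum(vapply(seq_len(nrow(cfg$w_T)), function(i)
    cfg$w_T$weight[i] * .tissue_equivalent(result, cfg$w_T$tissue[i], cfg),
    numeric(1)))
}

#' Self-irradiation mass-adjustment factor
#'
#' When a target's mass is altered (e.g. to adjust the self-irradiation
#' term to a patient-specific organ mass), the self-absorbed dose rescales
#' by the mass ratio `m_ref / m_new`, since absorbed dose is energy per
#' mass.
#'
#' @param m_ref Reference target mass (kg).
#' @param m_new Altered target mass (kg).
#' @return The dimensionless rescale factor.
#' @examples
#' signif(mass_scaling_factor(2.36, 1.8), 2)  # 1.3
#' @export
mass_scaling_factor <- function(m_ref, m_new) {
  if (m_ref <= 0 || m_new <= 0) .stopf("masses must be positive (kg)")
  m_ref / m_new
}

#' Rescale the self-irradiation terms of an S-matrix for an altered mass
#'
#' Multiplies the (target <- target) element of every radiation-type
#' component by `m_ref / m_new`; the dose engine can then run a second
#' pass with the adjusted matrix.
#'
#' @param smat An [s_matrix()] object.
#' @param target Target whose mass is overridden.
#' @param m_ref,m_new Reference and altered masses (kg).
#' @return The adjusted `smatrix`.
#' @export
adjust_self_mass <- function(smat, target, m_ref, m_new) {
  stopifnot(inherits(smat, "smatrix"))
  if (!(target %in% rownames(smat$values)) ||
      !(target %in% colnames(smat$values)))
    .stopf("'%s' must be present as both target and source", target)
  f <- mass_scaling_factor(m_ref, m_new)
  for (r in names(smat$breakdown))
    smat$breakdown[[r]][target, target] <- smat$breakdown[[r]][target, target] * f
  smat$values <- Reduce(`+`, smat$breakdown)
  smat
}
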