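#' Reference phantom
#'
#' Anatomical description of one reference individual: region masses, total
#' mass, and the regional distribution of the circulating blood. The
#' `other_eligible` set lists the soft-tissue source regions that may be
#' folded into the composite source region "Other" (organ contents and air
#' are excluded: "Other" covers only tissues in exchange with the
#' circulating blood). `blood_only_regions` are blood-bearing regions (e.g.
#' large vessels, heart content) that no biokinetic model represents
#' explicitly; when a model omits the source region "Blood", these are
#' folded into "Other" with their share of the blood mass.
#'
#' @param sex `"male"` or `"female"`.
#' @param age_class One of `"newborn_0d"`, `"1y"`, `"5y"`, `"10y"`,
#'   `"15y"`, `"adult"`.
#' @param total_mass Total body mass (kg).
#' @param region_masses Named numeric vector of region masses (kg).
#' @param blood_fractions Named numeric vector: fraction of the total blood
#'   volume residing in each region (>= 0, sum <= 1).
#' @param blood_mass Total mass of the circulating blood (kg).
#' @param other_eligible Character vector of regions eligible for "Other"
#'   (defaults to all regions with a mass).
#' @param blood_only_regions Character vector, subset of regions
#'   representable only through the blood (default none).
#' @return An object of class `phantom`.
#' @export
phantom <- function(sex, age_class, total_mass, region_masses,
                    blood_fractions = numeric(), blood_mass = 0,
                    other_eligible = names(region_masses),
                    blood_only_regions = character()) {
  sex <- match.arg(sex, c("male", "female"))
  age_class <- match.arg(age_class,
                         c("newborn_0d", "1y", "5y", "10y", "15y", "adult"))
  if (!.is_num1(total_mass) || total_mass <= 0)
    .stopf("total_mass must be positive (kg)")
  if (is.null(names(region_masses)) || any(region_masses <= 0))
    .stopf("region_masses must be a named vector of positive masses (kg)")
  if (length(blood_fractions)) {
    if (is.null(names(blood_fractions)) || any(blood_fractions < 0))
      .stopf("blood_fractions must be named and non-negative")
    if (sum(blood_fractions) > 1 + 1e-9)
      .stopf("blood_fractions sum to %.6g > 1", sum(blood_fractions))
  }
  if (!all(other_eligible %in% names(region_masses)))
    .stopf("other_eligible contains unknown region(s): %s",
           paste(setdiff(other_eligible, names(region_masses)), collapse = ", "))
  structure(list(
    id = paste(age_class, sex, sep = "_"),
    sex = sex, age_class = age_class,
    total_mass = total_mass,
    region_masses = region_masses,
    blood_fractions = blood_fractions,
    blood_mass = blood_mass,
    other_eligible = other_eligible,
    blood_only_regions = blood_only_regions), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom %s>  %.3g kg, %d regions\n",
              x$id, x$total_mass, length(x$region_masses)))
  invisible(x)
}

#' Specific-absorbed-fraction table for one phantom
#'
#' Stores the SAF values Phi(r_T <- r_S, E) in 1/kg on an energy grid per
#' radiation type, as dense arrays `[target, source, energy]`.
#'
#' @param phantom_id Identifier of the phantom the table belongs to.
#' @param data Long-format data.frame with columns
#'   `rtype` (photon/electron/alpha), `target`, `source`, `E_MeV`,
#'   `phi_per_kg`. Every (target, source) pair of an rtype must cover the
#'   full energy grid of that rtype.
#' @return An object of class `saf_table`.
#' @export
saf_table <- function(phantom_id, data) {
  need <- c("rtype", "target", "source", "E_MeV", "phi_per_kg")
  if (!all(need %in% names(data)))
    .stopf("saf_table data needs columns: %s", paste(need, collapse = ", "))
  if (any(data$phi_per_kg < 0) || anyNA(data$phi_per_kg))
    .stopf("SAF values must be non-negative")
  tabs <- list()
  for (rt in unique(data$rtype)) {
    d <- data[data$rtype == rt, , drop = FALSE]
    egrid <- sort(unique(d$E_MeV))
    tg <- sort(unique(d$target)); sr <- sort(unique(d$source))
    arr <- array(NA_real_, dim = c(length(tg), length(sr), length(egrid)),
                 dimnames = list(tg, sr, NULL))
    ii <- cbind(match(d$target, tg), match(d$source, sr),
                match(d$E_MeV, egrid))
    arr[ii] <- d$phi_per_kg
    if (anyNA(arr))
      .stopf("saf_table: incomplete energy coverage for rtype '%s'", rt)
    tabs[[rt]] <- list(energy = egrid, phi = arr)
  }
  structure(list(phantom_id = phantom_id, rtypes = tabs),
            class = "saf_table")
}

#' @export
print.saf_table <- function(x, ...) {
  for (rt in names(x$rtypes)) {
    d <- dim(x$rtypes[[rt]]$phi)
    cat(sprintf("<saf_table %s> %s: %d targets x %d sources x %d energies\n",
                x$phantom_id, rt, d[1], d[2], d[3]))
  }
  invisible(x)
}

#' List the sources available in a SAF table
#' @param table A [saf_table()].
#' @param rtype Radiation type.
#' @return Character vector of source region names.
#' @export
saf_sources <- function(table, rtype) {
  rt <- table$rtypes[[rtype]]
  if (is.null(rt)) .stopf("no SAF grid for radiation type '%s'", rtype)
  dimnames(rt$phi)[[2]]
}

# log-log interpolation of a positive tabulated function with end clamping;
# falls back to linear if any node value is zero (log undefined).
.interp_loglog <- function(xgrid, y, xout) {
  if (length(xgrid) == 1L) return(rep(y, length(xout)))
  if (all(y > 0) && all(xgrid > 0)) {
    exp(stats::approx(log(xgrid), log(y), xout = log(pmax(xout, min(xgrid))),
                      rule = 2, ties = "ordered")$y)
  } else {
    stats::approx(xgrid, y, xout = xout, rule = 2, ties = "ordered")$y
  }
}

#' SAF value at an arbitrary energy
#'
#' Log-log linear interpolation on the energy grid; at a grid node the
#' stored value is returned exactly; outside the grid the end value is
#' clamped (no extrapolation). Zero-valued nodes switch the affected pair
#' to linear interpolation since the logarithm is undefined.
#'
#' @param table A [saf_table()].
#' @param target,source Region names.
#' @param rtype Radiation type (`"photon"`, `"electron"`, `"alpha"`).
#' @param E Energy (MeV), vectorized.
#' @return Phi in 1/kg.
#' @export
saf_at_energy <- function(table, target, source, rtype, E) {
  stopifnot(inherits(table, "saf_table"))
  if (any(E <= 0)) .stopf("energy must be positive (MeV)")
  rt <- table$rtypes[[rtype]]
  if (is.null(rt)) .stopf("no SAF grid for radiation type '%s'", rtype)
  dn <- dimnames(rt$phi)
  if (!target %in% dn[[1]] || !source %in% dn[[2]])
    .stopf("no SAF entry for (%s <- %s) [%s]; available sources: %s",
           target, source, rtype, paste(dn[[2]], collapse = ", "))
  y <- rt$phi[target, source, ]
  .interp_loglog(rt$energy, y, E)
}

#' Fold the circulating blood into the composite source "Other"
#'
#' Determines the constituent regions (with their masses) of the composite
#' source region "Other" for a given biokinetic model. The base constituents
#' are the phantom's Other-eligible soft tissues minus the model's explicit
#' sources. If the model does not declare the source region "Blood", the
#' blood-bearing regions representable only through the blood (e.g. large
#' vessels, heart content) are added with an effective mass equal to their
#' share of the total blood mass, so the phantom's circulating blood is not
#' silently dropped from the dose calculation. If "Blood" is an explicit
#' source, no blood mass is folded in (the partition avoids counting a
#' decay in more than one source region).
#'
#' @param model_sources Character vector of the biokinetic model's explicit
#'   source regions.
#' @param phantom A [phantom()].
#' @return Named numeric vector: constituent region -> mass (kg) entering
#'   the mass-weighted "Other" composition.
#' @export
apply_blood_rule <- function(model_sources, phantom) {
  stopifnot(inherits(phantom, "phantom"))
  cons <- setdiff(phantom$other_eligible, model_sources)
  out <- phantom$region_masses[cons]
  if (!("Blood" %in% model_sources)) {
    extra <- setdiff(phantom$blood_only_regions, model_sources)
    for (r in extra) {
      bf <- phantom$blood_fractions[r]
      if (is.na(bf) || is.null(bf))
        .stopf("blood rule: blood_fractions missing for region '%s'", r)
      if (bf > 0) {
        add <- phantom$blood_mass * unname(bf)
        out[r] <- if (r %in% names(out)) out[r] + add else add
      }
    }
  }
  out[out > 0]
}

#' Compose the SAF of the source region "Other"
#'
#' The composite source "Other" has no stored SAF values; its SAF is the
#' mass-weighted mean of its constituent regions' SAFs:
#' `Phi(r_T <- Other, E) = sum_s M_s Phi(r_T <- s, E) / sum_s M_s`.
#'
#' @param table A [saf_table()].
#' @param model_sources Explicit sources of the biokinetic model (excluded
#'   from "Other").
#' @param phantom A [phantom()]; supplies masses and the eligible set.
#' @param constituents Optional named mass vector overriding the default
#'   composition from [apply_blood_rule()].
#' @return A new [saf_table()] with source `"Other"` added to every
#'   radiation type.
#' @export
compose_other_saf <- function(table, model_sources, phantom,
                              constituents = NULL) {
  stopifnot(inherits(table, "saf_table"))
  if (is.null(constituents))
    constituents <- apply_blood_rule(model_sources, phantom)
  if (!length(constituents))
    .stopf("source region 'Other' has an empty constituent set")
  M_other <- sum(constituents)
  out <- table
  for (rt in names(table$rtypes)) {
    arr <- table$rtypes[[rt]]$phi
    srcs <- dimnames(arr)[[2]]
    miss <- setdiff(names(constituents), srcs)
    if (length(miss))
      .stopf("compose_other_saf: no SAF column for constituent(s): %s [%s]",
             paste(miss, collapse = ", "), rt)
    w <- constituents / M_other
    other <- apply(arr[, names(constituents), , drop = FALSE], c(1, 3),
                   function(v) sum(v * w))
    newarr <- array(NA_real_,
                    dim = dim(arr) + c(0, 1, 0),
                    dimnames = list(dimnames(arr)[[1]], c(srcs, "Other"), NULL))
    newarr[, srcs, ] <- arr
    newarr[, "Other", ] <- other
    out$rtypes[[rt]]$phi <- newarr
  }
  attr(out, "other_constituents") <- constituents
  out
}

#' S-coefficients of the 100-day reference infant
#'
#' The 100-day infant phantom is always derived, never stored: its
#' S-coefficients are a fixed-fraction interpolation between the newborn
#' (0 day) and the 1-year phantoms,
#' `S_100d = 0.6528 * (S_1yr - S_0day) + S_0day`,
#' applied elementwise (scalars or whole S-matrices).
#'
#' @param s_1yr,s_0day S-values (Gy/nt) of the same (target, source,
#'   nuclide) for the 1-year and newborn phantoms; scalars, vectors,
#'   matrices, or [s_matrix()] objects of identical shape.
#' @return Same shape as the inputs: the 100-day infant S-values.
#' @examples
#' infant_s(1, 0)  # 0.6528
#' @export
infant_s <- function(s_1yr, s_0day) {
  f <- 0.6528
  if (inherits(s_1yr, "smatrix") && inherits(s_0day, "smatrix")) {
    if (!identical(dim(s_1yr$values), dim(s_0day$values)) ||
        !identical(dimnames(s_1yr$values), dimnames(s_0day$values)))
      .stopf("infant_s: S-matrix shapes disagree")
    out <- s_1yr
    out$values <- f * (s_1yr$values - s_0day$values) + s_0day$values
    for (rt in names(out$breakdown))
      out$breakdown[[rt]] <- f * (s_1yr$breakdown[[rt]] -
                                    s_0day$breakdown[[rt]]) +
        s_0day$breakdown[[rt]]
    out$phantom_id <- "infant_100d"
    return(out)
  }
  if (!identical(dim(s_1yr), dim(s_0day)) ||
      length(s_1yr) != length(s_0day))
    .stopf("infant_s: input shapes disagree")
  f * (s_1yr - s_0day) + s_0day
}
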