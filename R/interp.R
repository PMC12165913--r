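#' Phantom node for age/weight interpolation
#'
#' One fixed reference phantom with its age (years; adult = 20), reference
#' total body weight (kg) and computed [dose_result()].
#'
#' @param phantom_id Identifier.
#' @param age Age in years (newborn = 0, adult = 20).
#' @param weight Reference total body weight (kg).
#' @param sex `"male"` or `"female"`.
#' @param result A [dose_result()].
#' @return An object of class `phantom_node`.
#' @export
phantom_node <- function(phantom_id, age, weight, sex, result) {
  stopifnot(inherits(result, "dose_result"))
  if (age < 0 || age > 20) .stopf("node age must lie in [0, 20] years")
  if (weight <= 0) .stopf("node weight must be positive (kg)")
  structure(list(phantom_id = phantom_id, age = age, weight = weight,
                 sex = match.arg(sex, c("male", "female")),
                 result = result), class = "phantom_node")
}

# generic 1-D interpolation of dose results over an abscissa
.interp_nodes <- function(nodes, x, xfield, log_scale = FALSE) {
  xs <- vapply(nodes, `[[`, numeric(1), xfield)
  if (any(duplicated(xs))) .stopf("nodes must have distinct %s values", xfield)
  ord <- order(xs)
  nodes <- nodes[ord]; xs <- xs[ord]
  if (x < xs[1] || x > xs[length(xs)])
    .stopf("%s %.4g outside the node range [%.4g, %.4g]; no extrapolation",
           xfield, x, xs[1], xs[length(xs)])
  hit <- which(abs(xs - x) < 1e-12)
  if (length(hit)) return(nodes[[hit[1]]]$result)

  i <- findInterval(x, xs)
  lo <- nodes[[i]]$result; hi <- nodes[[i + 1L]]$result
  if (!identical(lo$doses$target, hi$doses$target))
    .stopf("bracketing nodes carry different target lists")
  w <- (x - xs[i]) / (xs[i + 1L] - xs[i])
  rts <- c("photon", "electron", "alpha", "beta")
  out <- lo$doses
  for (r in rts) {
    a <- lo$doses[[r]]; b <- hi$doses[[r]]
    out[[r]] <- if (log_scale) {
      ifelse(a > 0 & b > 0, exp((1 - w) * log(a) + w * log(b)),
             (1 - w) * a + w * b)
    } else (1 - w) * a + w * b
  }
  dose_result(sprintf("%s_interp_%s_%.4g", lo$sex, xfield, x), lo$sex, out)
}

#' Interpolate organ doses to an arbitrary age
#'
#' Per-organ piecewise-linear interpolation in age between the bracketing
#' phantom nodes (optionally log-linear on the dose scale, since
#' paediatric doses span decades). At a node age the node's result is
#' returned exactly; outside \[0, 20\] years (or the node range) an error
#' is raised - no extrapolation. The effective dose is not interpolated
#' directly: recompute it from the interpolated organ doses with
#' [effective_dose()].
#'
#' @param nodes List of [phantom_node()] objects of one sex.
#' @param age Age in years.
#' @param log_scale Interpolate on the log-dose scale (default linear).
#' @return A [dose_result()] at the requested age.
#' @export
interp_by_age <- function(nodes, age, log_scale = FALSE) {
  if (age < 0 || age > 20) .stopf("age must lie in [0, 20] years")
  .interp_nodes(nodes, age, "age", log_scale)
}

#' Interpolate organ doses to an arbitrary total body weight
#'
#' As [interp_by_age()] with the reference phantom weights as abscissa.
#' The valid range is the sex-specific node range (3.5-73 kg for the male,
#' 3.5-64 kg for the female reference series).
#'
#' @param nodes List of [phantom_node()] objects.
#' @param weight Total body weight (kg).
#' @param sex Sex whose node series to use.
#' @param log_scale Interpolate on the log-dose scale.
#' @return A [dose_result()] at the requested weight.
#' @export
interp_by_weight <- function(nodes, weight, sex, log_scale = FALSE) {
  sex <- match.arg(sex, c("male", "female"))
  nodes <- nodes[vapply(nodes, `[[`, character(1), "sex") == sex]
  if (!length(nodes)) .stopf("no nodes for sex '%s'", sex)
  .interp_nodes(nodes, weight, "weight", log_scale)
}

#' Effective dose at an arbitrary age or weight
#'
#' Interpolates the organ doses of both sexes and recomputes the effective
#' dose from the interpolated doses (the effective dose itself is never
#' interpolated).
#'
#' @param nodes_male,nodes_female Per-sex lists of [phantom_node()].
#' @param cfg A [weighting_config()].
#' @param age Age in years, or `NULL`.
#' @param weight Weight in kg, or `NULL` (exactly one of age/weight).
#' @param log_scale Passed through to the interpolators.
#' @return List: `male`, `female` (interpolated [dose_result()]s),
#'   `effective` (mSv/MBq), `detriment_male`, `detriment_female`.
#' @export
interp_effective_dose <- function(nodes_male, nodes_female,
                                  cfg = weighting_config("ICRP103"),
                                  age = NULL, weight = NULL,
                                  log_scale = FALSE) {
  if (is.null(age) == is.null(weight))
    .stopf("give exactly one of age or weight")
  if (!is.null(age)) {
    m <- interp_by_age(nodes_male, age, log_scale)
    f <- interp_by_age(nodes_female, age, log_scale)
  } else {
    m <- interp_by_weight(nodes_male, weight, "male", log_scale)
    f <- interp_by_weight(nodes_female, weight, "female", log_scale)
  }
  list(male = m, female = f,
       effective = effective_dose(m, f, cfg),
       detriment_male = detriment_adjusted(m, cfg),
       detriment_female = detriment_adjusted(f, cfg))
}
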