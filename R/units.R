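#' Physical constants and unit conversions
#'
#' All unit conversions used by the dose pipeline are centralized here.
#' Internally the package works in MeV (energies), hours (times), MBq
#' (activities) and kg (masses); S-values are in Gy per nuclear
#' transformation (nt) and doses in mGy per administered MBq.
#'
#' * `mev_to_joule`: 1 MeV in joules (CODATA exact elementary charge).
#' * `nt_per_mbq_hour`: nuclear transformations in 1 MBq.h
#'   (1e6 decay/s x 3600 s = 3.6e9).
#' * `dose_multiplier_mgy`: converts TIAC\[h\] x S\[Gy/nt\] into mGy/MBq,
#'   i.e. `nt_per_mbq_hour * 1e3`.
#'
#' @return A named list of the three constants.
#' @examples
#' dose_units()$nt_per_mbq_hour  # 3.6e9
#' @export
dose_units <- function() {
  list(
    mev_to_joule      = 1.602176634e-13,
    nt_per_mbq_hour   = 3.6e9,
    dose_multiplier_mgy = 3.6e9 * 1e3
  )
}

# internal shorthands
.MEV_J   <- 1.602176634e-13
.NT_MBQH <- 3.6e9
.D_MULT  <- 3.6e12  # TIAC[h] * S[Gy/nt] -> mGy/MBq

.LN2 <- log(2)

# half-life in seconds -> decay constant per hour
.lambda_per_h <- function(half_life_s) {
  ifelse(is.infinite(half_life_s), 0, .LN2 / half_life_s * 3600)
}

.is_num1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
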