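# Per-subject wave-reflection indices and blood-pressure summaries.
#
# The first Gaussian is read as the forward (ejection) component and
# the second as the main reflected component.  Subject-level indices
# are the arithmetic means over the fitted episodes of the first and
# second sub-waves' peak positions and heights, with two derived
# measures: the peak position interval C_ref_forw = C2 - C1 (timing of
# reflection on the normalized beat axis) and the peak height ratio
# H_ref_forw = 100 * H2 / H1 (amplitude of reflection relative to the
# forward wave, in percent).

#' Compute subject-level wave-reflection indices
#'
#' Averages the first and second Gaussians' peak positions and heights
#' over the supplied fits, then derives the peak position interval and
#' peak height ratio from the averaged values (ratio of means, not mean
#' of ratios).
#'
#' @param fits a list of `pulse_fit` objects and/or
#'   [gaussian_triplet()]s (a single object is also accepted).
#' @return a one-row data frame of class `subject_indices` with columns
#'   `C1`, `C2`, `H1`, `H2`, `C_ref_forw`, `H_ref_forw` (percent) and
#'   `n_episodes`.
#' @export
compute_indices <- function(fits) {
  if (inherits(fits, c("pulse_fit", "gaussian_triplet"))) fits <- list(fits)
  if (!is.list(fits) || !length(fits)) stop("`fits` must be a non-empty list", call. = FALSE)
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("`fits` contains no successful fits", call. = FALSE)
  trip <- lapply(fits, function(f) {
    if (inherits(f, "pulse_fit")) f$params
    else as_gaussian_triplet(f)
  })
  C1 <- mean(vapply(trip, function(p) p$C[1], numeric(1)))
  C2 <- mean(vapply(trip, function(p) p$C[2], numeric(1)))
  H1 <- mean(vapply(trip, function(p) p$H[1], numeric(1)))
  H2 <- mean(vapply(trip, function(p) p$H[2], numeric(1)))
  out <- data.frame(C1 = C1, C2 = C2, H1 = H1, H2 = H2,
                    C_ref_forw = C2 - C1,
                    H_ref_forw = 100 * H2 / H1,
                    n_episodes = length(trip))
  class(out) <- c("subject_indices", "data.frame")
  out
}

#' Blood-pressure summary from paired auscultatory readings
#'
#' SBP and DBP are the means of the two readings; mean arterial
#' pressure and pulse pressure follow the classic formulas
#' `MAP = DBP + (SBP - DBP) / 3` and `PP = SBP - DBP`.
#'
#' @param sbp_readings numeric vector of systolic readings (mmHg),
#'   typically length 2.
#' @param dbp_readings numeric vector of diastolic readings (mmHg),
#'   same length.
#' @return a one-row data frame with `SBP`, `DBP`, `MAP`, `PP` (mmHg).
#' @export
compute_pressures <- function(sbp_readings, dbp_readings) {
  if (length(sbp_readings) != length(dbp_readings))
    stop("readings must be paired", call. = FALSE)
  if (any(sbp_readings <= dbp_readings))
    stop("every SBP reading must exceed its paired DBP reading", call. = FALSE)
  SBP <- mean(sbp_readings)
  DBP <- mean(dbp_readings)
  data.frame(SBP = SBP, DBP = DBP,
             MAP = DBP + (SBP - DBP) / 3,
             PP = SBP - DBP)
}
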