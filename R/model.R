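# The three-Gaussian pulse model and its least-squares objective.
#
# A normalized radial pulse S(n), n = 1..1000, is modeled as the sum of
# three positive Gaussian sub-waves.  The first sub-wave is interpreted as
# the forward (ejection) component, the second as the main reflected
# component, and the third as the late diastolic component.  Each sub-wave
# is parameterized by peak height H_k, half-width W_k and peak position
# C_k, with the ordering constraint 1 < C1 < C2 < C3 < 1000.

#' Evaluate a single Gaussian sub-wave
#'
#' Computes `H * exp(-(n - C)^2 / (2 * W^2))`, the sub-wave used by the
#' pulse decomposition.  `W` is the width scale of the Gaussian (the
#' half-width parameter of the decomposition).
#'
#' @param n sample positions (numeric vector).
#' @param H peak height, > 0.
#' @param W half-width in samples, > 0.
#' @param C peak position in samples.
#' @return numeric vector of sub-wave values at `n`.
#' @examples
#' gaussian_wave(150, H = 0.8, W = 60, C = 150)  # equals H at the peak
#' @export
gaussian_wave <- function(n, H, W, C) {
  if (!is.numeric(W) || any(W <= 0)) stop("`W` must be positive", call. = FALSE)
  if (!is.numeric(H) || any(H <= 0)) stop("`H` must be positive", call. = FALSE)
  H * exp(-(n - C)^2 / (2 * W^2))
}

#' Construct a validated Gaussian triplet
#'
#' Bundles the nine decomposition parameters (three heights, three
#' half-widths, three peak positions) and enforces the ordering
#' constraint `1 < C1 < C2 < C3 < 1000`.
#'
#' @param H numeric length-3, peak heights, all > 0.
#' @param W numeric length-3, half-widths in samples, all > 0.
#' @param C numeric length-3, peak positions in samples, strictly
#'   increasing within (1, 1000).
#' @return an object of class `gaussian_triplet`.
#' @export
gaussian_triplet <- function(H, W, C) {
  if (length(H) != 3L || length(W) != 3L || length(C) != 3L)
    stop("`H`, `W` and `C` must each have length 3", call. = FALSE)
  if (any(!is.finite(c(H, W, C)))) stop("parameters must be finite", call. = FALSE)
  if (any(H <= 0)) stop("all peak heights must be positive", call. = FALSE)
  if (any(W <= 0)) stop("all half-widths must be positive", call. = FALSE)
  if (!(1 < C[1] && C[1] < C[2] && C[2] < C[3] && C[3] < 1000))
    stop("peak positions must satisfy 1 < C1 < C2 < C3 < 1000", call. = FALSE)
  structure(list(H = as.numeric(H), W = as.numeric(W), C = as.numeric(C)),
            class = "gaussian_triplet")
}

#' @export
print.gaussian_triplet <- function(x, ...) {
  cat("Gaussian triplet (H = height, W = half-width, C = position)\n")
  m <- rbind(H = x$H, W = x$W, C = x$C)
  colnames(m) <- c("forward", "reflected", "diastolic")
  print(round(m, 3))
  invisible(x)
}

#' Superimposed three-Gaussian model curve
#'
#' Evaluates the sum of the three Gaussian sub-waves on the canonical
#' sample axis `n = 1..n_points`.
#'
#' @param params a [gaussian_triplet()], or a list with elements `H`, `W`,
#'   `C` (validated on entry).
#' @param n_points length of the canonical axis (default 1000).
#' @return numeric vector of `n_points` model values.
#' @export
model_curve <- function(params, n_points = 1000L) {
  params <- as_gaussian_triplet(params)
  n <- seq_len(n_points)
  gaussian_wave(n, params$H[1], params$W[1], params$C[1]) +
    gaussian_wave(n, params$H[2], params$W[2], params$C[2]) +
    gaussian_wave(n, params$H[3], params$W[3], params$C[3])
}

as_gaussian_triplet <- function(params) {
  if (inherits(params, "gaussian_triplet")) return(params)
  if (is.list(params) && all(c("H", "W", "C") %in% names(params)))
    return(gaussian_triplet(params$H, params$W, params$C))
  stop("`params` must be a gaussian_triplet or a list with H, W, C", call. = FALSE)
}

#' Sum-of-squared-errors fitting objective
#'
#' The score minimized by the pulse fit: the sum over the canonical axis
#' of squared differences between the normalized pulse and the
#' superimposed model curve.
#'
#' @param params a [gaussian_triplet()] (or coercible list).
#' @param S the target pulse: a [normalized_pulse] object or a numeric
#'   vector on the canonical axis.
#' @return non-negative scalar score.
#' @export
pulse_objective <- function(params, S) {
  S <- pulse_samples(S)
  r <- S - model_curve(as_gaussian_triplet(params), n_points = length(S))
  sum(r * r)
}

# Extract the sample vector from a normalized_pulse or plain numeric.
pulse_samples <- function(S) {
  if (inherits(S, "normalized_pulse")) return(S$samples)
  if (is.numeric(S) && length(S) >= 3L) return(as.numeric(S))
  stop("`S` must be a normalized_pulse or a numeric vector", call. = FALSE)
}
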