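# Width and amplitude normalization of pulse episodes to the canonical
# 1000-sample, [0, 1]-amplitude representation S(n).

#' Resample an episode to a fixed length
#'
#' Interpolates the episode onto `L` uniformly spaced points spanning
#' the original samples, preserving the first and last values.  Linear
#' interpolation is the default; cubic (spline) interpolation is
#' available.
#'
#' @param episode numeric vector, length >= 3.
#' @param L output length (default 1000).
#' @param method `"linear"` or `"cubic"`.
#' @return numeric vector of exactly `L` samples.
#' @export
width_normalize <- function(episode, L = 1000L, method = c("linear", "cubic")) {
  method <- match.arg(method)
  n <- length(episode)
  if (n < 3) stop("`episode` must have at least 3 samples", call. = FALSE)
  xout <- seq(1, n, length.out = L)
  if (method == "linear")
    stats::approx(seq_len(n), episode, xout = xout)$y
  else
    stats::spline(seq_len(n), episode, xout = xout)$y
}

#' Min-max amplitude normalization
#'
#' Maps an episode affinely onto `[0, 1]`:
#' `(episode - min) / (max - min)`.
#'
#' @param episode numeric vector with a non-degenerate range.
#' @return an object of class `normalized_pulse`: a list with `samples`
#'   (the scaled values), `source_len` (input length) and `source_range`
#'   (input min and max, in the input's units).
#' @export
amplitude_normalize <- function(episode) {
  rng <- range(episode)
  if (!all(is.finite(rng))) stop("`episode` contains non-finite values", call. = FALSE)
  if (rng[2] <= rng[1])
    stop("degenerate amplitude range: episode is constant", call. = FALSE)
  structure(list(samples = (episode - rng[1]) / (rng[2] - rng[1]),
                 source_len = length(episode),
                 source_range = rng),
            class = "normalized_pulse")
}

#' Normalize an episode to the canonical representation
#'
#' Width normalization (to `L` samples) followed by amplitude
#' normalization (to `[0, 1]`), in that order.
#'
#' @param episode numeric vector, length >= 3.
#' @param L canonical length (default 1000).
#' @param method interpolation method for [width_normalize()].
#' @return a `normalized_pulse` whose `samples` have length `L`,
#'   minimum 0 and maximum 1; `source_len` and `source_range` describe
#'   the original episode.
#' @export
normalize_episode <- function(episode, L = 1000L, method = "linear") {
  n <- length(episode)
  rng <- range(episode)
  out <- amplitude_normalize(width_normalize(episode, L = L, method = method))
  out$source_len <- n
  out$source_range <- rng
  out
}

#' @export
print.normalized_pulse <- function(x, ...) {
  cat(sprintf("normalized_pulse: %d samples in [0, 1] (source: %d samples, range %.4g..%.4g)\n",
              length(x$samples), x$source_len, x$source_range[1], x$source_range[2]))
  invisible(x)
}
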