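# Signal pretreatment: baseline-wander removal, R-peak detection,
# pulse-foot detection, ectopic-beat exclusion and beat segmentation.
#
# Sample-index convention: all annotation indices (R-peaks, feet) are
# 0-based, and episode ranges are half-open [foot_i, foot_{i+1}).

#' Remove slow baseline wander
#'
#' Removes the 0-`cutoff` Hz band (default 0-0.05 Hz) from a signal.
#' The baseline is estimated by block-mean decimation followed by a
#' least-squares projection of the decimated signal onto the subspace
#' spanned by slow Fourier components (all frequencies at or below the
#' cutoff) plus a cubic polynomial trend, then interpolated back to the
#' full rate and subtracted.
#'
#' Because the subtracted baseline lies entirely in the 0-cutoff
#' subspace, beat morphology cannot be phase-distorted (the operation is
#' zero-phase by construction).  The passband is exact except within
#' roughly `1/cutoff` seconds of the record edges, where slow components
#' are estimated from one-sided information.
#'
#' @param signal numeric vector.
#' @param fs sampling rate in Hz.
#' @param cutoff upper edge of the removed band, Hz.
#' @return numeric vector of the same length with the slow band removed.
#' @export
remove_baseline <- function(signal, fs, cutoff = 0.05) {
  if (length(signal) == 0) stop("`signal` must be non-empty", call. = FALSE)
  stop_if_not_scalar_pos(fs, "fs")
  stop_if_not_scalar_pos(cutoff, "cutoff")
  n <- length(signal)
  dec <- max(1L, as.integer(floor(fs / max(4, 100 * cutoff))))
  nblk <- as.integer(floor(n / dec))
  if (nblk < 8) return(signal - mean(signal))
  xb <- colMeans(matrix(signal[seq_len(nblk * dec)], nrow = dec))
  tb <- ((seq_len(nblk) - 0.5) * dec) / fs
  Tdur <- n / fs
  kmax <- as.integer(floor(Tdur * cutoff))
  tt <- tb / Tdur - 0.5
  B <- cbind(1, tt, tt^2, tt^3)
  if (kmax >= 1) {
    ks <- seq_len(kmax)
    B <- cbind(B,
               do.call(cbind, lapply(ks, function(k) cos(2 * pi * k * tb / Tdur))),
               do.call(cbind, lapply(ks, function(k) sin(2 * pi * k * tb / Tdur))))
  }
  bl <- drop(B %*% stats::.lm.fit(B, xb)$coefficients)
  blf <- stats::approx(tb * fs, bl, xout = seq_len(n), rule = 2)$y
  signal - blf
}

# Zero-phase difference-of-boxcars band-pass used for R-peak emphasis:
# subtract a long moving average (removes wander) and smooth with a short
# one (suppresses high-frequency noise).
bandpass_boxcar <- function(x, fs, long_s = 0.20, short_s = 0.02) {
  ma <- function(v, w) {
    w <- max(1L, as.integer(round(w)))
    if (w %% 2 == 0) w <- w + 1L
    y <- stats::filter(v, rep(1 / w, w), sides = 2)
    y[is.na(y)] <- v[is.na(y)]
    as.numeric(y)
  }
  ma(x, short_s * fs) - ma(x, long_s * fs)
}

#' Detect ECG R-peaks
#'
#' Band-pass emphasis (difference of zero-phase moving averages),
#' amplitude thresholding relative to the record's own scale, a
#' refractory period, and refinement to the local maximum of the raw
#' signal.  The detector is invariant to global amplitude scaling.
#'
#' @param ecg numeric ECG channel.
#' @param fs sampling rate in Hz.
#' @param threshold_frac detection threshold as a fraction of the
#'   emphasized signal's 99.5th percentile.
#' @param refractory minimum peak separation in seconds.
#' @return strictly increasing 0-based sample indices, one per beat.
#' @export
detect_r_peaks <- function(ecg, fs, threshold_frac = 0.4, refractory = 0.25) {
  if (length(ecg) < 4) stop("`ecg` is too short", call. = FALSE)
  stop_if_not_scalar_pos(fs, "fs")
  y <- bandpass_boxcar(ecg, fs)
  a <- abs(y)
  scale <- stats::quantile(a, 0.995, names = FALSE)
  if (!is.finite(scale) || scale <= 0)
    stop("R-peak detection failed: no activity in the ECG channel", call. = FALSE)
  thr <- threshold_frac * scale
  above <- which(a > thr)
  if (!length(above)) stop("R-peak detection failed: no peaks above threshold", call. = FALSE)
  # group threshold crossings into candidate events
  grp <- cumsum(c(1, diff(above) > 1))
  cand <- vapply(split(above, grp), function(ix) ix[which.max(a[ix])], numeric(1))
  cand <- sort(cand)
  # enforce refractory period, keeping the larger peak
  ref <- refractory * fs
  keep <- c()
  for (p in cand) {
    if (length(keep) && p - keep[length(keep)] < ref) {
      if (a[p] > a[keep[length(keep)]]) keep[length(keep)] <- p
    } else keep <- c(keep, p)
  }
  # refine on the raw channel
  half <- as.integer(round(0.025 * fs))
  peaks <- vapply(keep, function(p) {
    w0 <- max(1, p - half); w1 <- min(length(ecg), p + half)
    w0 + which.max(ecg[w0:w1]) - 1
  }, numeric(1))
  peaks <- sort(unique(peaks))
  if (length(peaks) < 1) stop("R-peak detection failed", call. = FALSE)
  as.integer(peaks - 1)   # 0-based
}

# Change-point foot localization in one search window (0-based bounds).
# Two-line likelihood-ratio score around a coarse smoothed minimum.
foot_in_window <- function(x, w0, w1, smooth_w = 21L, halfwin = 20L, search = 35L) {
  w0 <- max(halfwin, w0); w1 <- min(length(x) - halfwin - 1, w1)
  if (w1 - w0 < 2 * halfwin + 5) return(NA_real_)
  seg <- x[(w0:w1) + 1]
  n <- length(seg)
  sm <- stats::filter(seg, rep(1 / smooth_w, smooth_w), sides = 2)
  bad <- is.na(sm); sm[bad] <- seg[bad]
  ipk <- which.max(sm)
  if (ipk < 5) return(NA_real_)
  coarse <- which.min(sm[1:ipk])
  cand <- max(halfwin + 1, coarse - search):min(n - halfwin, coarse + search)
  if (length(cand) < 3) return(NA_real_)
  tl <- seq_len(halfwin)
  Xl <- cbind(1, tl)
  Xs <- cbind(1, seq_len(2 * halfwin))
  score <- vapply(cand, function(b) {
    yl <- seg[(b - halfwin):(b - 1)]
    yr <- seg[b:(b + halfwin - 1)]
    rl <- stats::.lm.fit(Xl, yl)$residuals
    rr <- stats::.lm.fit(Xl, yr)$residuals
    rs <- stats::.lm.fit(Xs, c(yl, yr))$residuals
    sum(rs * rs) - sum(rl * rl) - sum(rr * rr)
  }, numeric(1))
  ssc <- stats::filter(score, rep(1 / 7, 7), sides = 2)
  ssc[is.na(ssc)] <- -Inf
  b <- cand[which.max(ssc)]
  # require a rising edge to the right of the breakpoint
  cr <- stats::.lm.fit(Xl, seg[b:(b + halfwin - 1)])$coefficients
  cl <- stats::.lm.fit(Xl, seg[(b - halfwin):(b - 1)])$coefficients
  if (cr[2] <= 0 || cr[2] <= cl[2]) return(NA_real_)
  w0 + b - 1
}

#' Detect pulse feet on the pressure channel
#'
#' Locates the onset (foot) of each beat in the window following its
#' R-peak.  The onset is modeled as a change point between the late
#' diastolic decay and the systolic upstroke: within a search window a
#' coarse minimum of the smoothed signal is refined by maximizing a
#' two-line likelihood-ratio score.  Detected R-to-foot delays are then
#' regularized across the record: since pulse transit time is nearly
#' constant within a recording, feet whose delay deviates from the
#' record median by more than `delay_tol` seconds are replaced by the
#' median-delay prediction.
#'
#' Beats whose window contains no rising edge are flagged `NA` and
#' excluded downstream.
#'
#' @param rapw numeric pressure channel (baseline-corrected).
#' @param fs sampling rate in Hz.
#' @param r_peaks 0-based R-peak indices from [detect_r_peaks()].
#' @param delay_tol tolerance on the R-to-foot delay deviation (s).
#' @return numeric vector of 0-based foot indices, `NA` where detection
#'   failed; strictly increasing over the non-`NA` entries.
#' @export
detect_pulse_feet <- function(rapw, fs, r_peaks, delay_tol = 0.010) {
  if (!length(r_peaks)) stop("`r_peaks` must be non-empty", call. = FALSE)
  if (any(diff(r_peaks) <= 0)) stop("`r_peaks` must be strictly increasing", call. = FALSE)
  nb <- length(r_peaks)
  feet <- rep(NA_real_, nb)
  for (i in seq_len(nb)) {
    r <- r_peaks[i]
    upper <- if (i < nb) r_peaks[i + 1] - 1 else min(length(rapw) - 1, r + round(0.6 * fs))
    w0 <- r + round(0.03 * fs)
    w1 <- min(r + round(0.45 * fs), upper)
    feet[i] <- foot_in_window(rapw, w0, w1)
  }
  d <- feet - r_peaks
  med <- stats::median(d, na.rm = TRUE)
  if (is.finite(med)) {
    out <- is.na(d) | abs(d - med) > delay_tol * fs
    feet[out] <- r_peaks[out] + round(med)
    # entries replaced by prediction may exceed the record: drop those
    feet[feet > length(rapw) - 1] <- NA_real_
  }
  ok <- !is.na(feet)
  if (any(diff(feet[ok]) <= 0))
    stop("foot detection produced non-increasing indices", call. = FALSE)
  feet
}

#' Flag ectopic beats from RR intervals
#'
#' A beat interval deviating by more than `threshold` (relative) from
#' the running median RR over `window` beats marks both bounding beats
#' as ectopic.
#'
#' @param r_peaks 0-based R-peak indices (>= 3 beats).
#' @param fs sampling rate in Hz (kept for interface symmetry; the rule
#'   is scale-free).
#' @param threshold relative deviation tolerance (default 0.2).
#' @param window running-median window in beats (odd, default 7).
#' @return logical vector, one entry per beat; `TRUE` marks ectopy.
#' @export
exclude_ectopic <- function(r_peaks, fs = 1000, threshold = 0.2, window = 7L) {
  if (length(r_peaks) < 3) stop("need at least 3 beats", call. = FALSE)
  rr <- diff(r_peaks)
  k <- min(window, length(rr))
  if (k %% 2 == 0) k <- k - 1L
  med <- if (k >= 3) stats::runmed(rr, k, endrule = "median") else rep(stats::median(rr), length(rr))
  dev <- abs(rr - med) / med
  bad <- dev > threshold
  mask <- rep(FALSE, length(r_peaks))
  mask[which(bad)] <- TRUE       # beat before the anomalous interval
  mask[which(bad) + 1] <- TRUE   # beat after it
  mask
}

#' Select consecutive clean pulse episodes
#'
#' Returns the earliest run of `k` consecutive non-flagged beats, each
#' episode being the half-open sample range `[foot_i, foot_{i+1})` of
#' the pressure channel.
#'
#' @param rapw numeric pressure channel.
#' @param feet 0-based foot indices (possibly with `NA` for failed
#'   beats, which are treated as flagged).
#' @param mask per-beat logical ectopy flags aligned with `feet`.
#' @param k number of episodes to select (default 10).
#' @return a list with `episodes` (list of numeric vectors), `start_beat`
#'   (1-based beat number of the first episode) and `feet_used`
#'   (0-based boundaries, length `k + 1`).
#' @export
segment_and_select <- function(rapw, feet, mask, k = 10L) {
  if (length(feet) != length(mask))
    stop("`feet` and `mask` must be aligned", call. = FALSE)
  nb <- length(feet)
  usable <- !mask & !is.na(feet)
  # beat i also needs a valid closing boundary foot_{i+1}
  closes <- c(!is.na(feet[-1]), FALSE)
  ok <- usable & closes
  run <- rle(ok)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1
  good <- which(run$values & run$lengths >= k)
  if (!length(good)) {
    longest <- if (any(run$values)) max(run$lengths[run$values]) else 0
    stop(sprintf("no run of %d consecutive clean beats (longest clean run: %d)",
                 k, longest), call. = FALSE)
  }
  s <- starts[good[1]]
  idx <- s:(s + k - 1)
  eps <- lapply(idx, function(i) rapw[(feet[i] + 1):feet[i + 1]])
  list(episodes = eps, start_beat = s,
       feet_used = feet[s:(s + k)])
}

#' Annotate a raw record
#'
#' Convenience wrapper running baseline removal, R-peak detection, foot
#' detection and ectopic flagging on a [raw_record].
#'
#' @param record a [raw_record].
#' @param cutoff baseline-removal cutoff (Hz).
#' @param ectopic_threshold relative RR deviation flagged as ectopic.
#' @return a list with the baseline-corrected channels and a
#'   `beat_annotations` data frame (0-based `r_peak`, `foot`, logical
#'   `ectopic`).
#' @export
annotate_record <- function(record, cutoff = 0.05, ectopic_threshold = 0.2) {
  if (!inherits(record, "raw_record")) stop("`record` must be a raw_record", call. = FALSE)
  ecg <- remove_baseline(record$ecg, record$fs, cutoff)
  rapw <- remove_baseline(record$rapw, record$fs, cutoff)
  r <- detect_r_peaks(ecg, record$fs)
  feet <- detect_pulse_feet(rapw, record$fs, r)
  mask <- exclude_ectopic(r, record$fs, threshold = ectopic_threshold)
  list(ecg = ecg, rapw = rapw,
       beat_annotations = data.frame(beat = seq_along(r), r_peak = r,
                                     foot = feet, ectopic = mask))
}
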