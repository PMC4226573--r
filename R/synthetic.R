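# Synthetic beat-level data: single pulse episodes and two-channel
# ECG + RAPW pulse trains with known ground truth.
#
# The generator exists so that every downstream stage (detection,
# segmentation, normalization, fitting, indices) can be tested against a
# known truth without any recorded data.

#' Ground-truth parameters for a synthetic pulse
#'
#' Describes one beat on the canonical 1000-sample axis: the three
#' Gaussian sub-waves plus the observation model (additive white noise
#' and slow baseline wander applied at the train level).
#'
#' Defaults describe a physiologic radial pulse: forward wave peaking
#' near 14% of the cycle, reflected wave near 25%, and a late, wide
#' diastolic wave whose decay runs into the next pulse foot.
#'
#' @param H,W,C length-3 numeric: peak heights (unitless, in (0, 1.2]),
#'   half-widths (canonical samples) and peak positions (canonical
#'   samples, strictly increasing in (1, 1000)).
#' @param noise_sd standard deviation of additive white noise (unitless
#'   amplitude; the normalized pulse has unit range).
#' @param baseline_amp amplitude of sinusoidal baseline wander.
#' @param baseline_freq baseline-wander frequency in Hz, below 0.05.
#' @return an object of class `pulse_ground_truth`.
#' @export
pulse_ground_truth <- function(H = c(0.75, 0.70, 0.30),
                               W = c(55, 90, 180),
                               C = c(140, 250, 600),
                               noise_sd = 0.01,
                               baseline_amp = 0.1,
                               baseline_freq = 0.02) {
  params <- gaussian_triplet(H, W, C)  # validates H, W, C and ordering
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stop("`noise_sd` must be a single non-negative number", call. = FALSE)
  if (baseline_amp < 0) stop("`baseline_amp` must be non-negative", call. = FALSE)
  if (baseline_freq <= 0 || baseline_freq >= 0.05)
    stop("`baseline_freq` must lie in (0, 0.05) Hz", call. = FALSE)
  structure(list(H = params$H, W = params$W, C = params$C,
                 noise_sd = noise_sd,
                 baseline_amp = baseline_amp,
                 baseline_freq = baseline_freq),
            class = c("pulse_ground_truth"))
}

#' Specification of a synthetic pulse train
#'
#' @param n_beats number of beats (>= 1).
#' @param fs sampling rate in Hz.
#' @param mean_rr mean beat interval in seconds.
#' @param rr_jitter_sd standard deviation of beat-interval jitter (s).
#' @param ectopic_beats integer beat numbers (1-based) whose interval is
#'   shortened by 40%, emulating premature beats.
#' @param shape_jitter_sd relative standard deviation of beat-to-beat
#'   variation applied to the ground-truth heights (0 disables it).
#' @param seed integer seed controlling all randomness in the train.
#' @return an object of class `train_spec`.
#' @export
train_spec <- function(n_beats = 14L, fs = 1000, mean_rr = 0.8,
                       rr_jitter_sd = 0.01, ectopic_beats = integer(0),
                       shape_jitter_sd = 0, seed = 1L) {
  if (n_beats < 1) stop("`n_beats` must be >= 1", call. = FALSE)
  stop_if_not_scalar_pos(fs, "fs")
  stop_if_not_scalar_pos(mean_rr, "mean_rr")
  if (rr_jitter_sd < 0) stop("`rr_jitter_sd` must be >= 0", call. = FALSE)
  if (length(ectopic_beats) && (any(ectopic_beats < 1) || any(ectopic_beats > n_beats)))
    stop("`ectopic_beats` must index beats in 1..n_beats", call. = FALSE)
  structure(list(n_beats = as.integer(n_beats), fs = fs, mean_rr = mean_rr,
                 rr_jitter_sd = rr_jitter_sd,
                 ectopic_beats = as.integer(ectopic_beats),
                 shape_jitter_sd = shape_jitter_sd, seed = as.integer(seed)),
            class = "train_spec")
}

#' Generate one synthetic pulse episode
#'
#' Evaluates the three-Gaussian model on samples `1..length` and adds
#' white noise of standard deviation `noise_sd`.  With `noise_sd = 0`
#' the output equals [model_curve()] of the same parameters exactly.
#'
#' @param gt a [pulse_ground_truth()].
#' @param length episode length in samples (>= 3).
#' @param seed integer seed (the same seed reproduces the same noise).
#' @return numeric vector of `length` samples.
#' @export
generate_pulse_episode <- function(gt, length = 1000L, seed = 1L) {
  if (!inherits(gt, "pulse_ground_truth"))
    stop("`gt` must be a pulse_ground_truth object", call. = FALSE)
  if (length < 3) stop("`length` must be >= 3", call. = FALSE)
  base <- model_curve(gt, n_points = length)
  if (gt$noise_sd > 0)
    base <- base + with_seed(seed, stats::rnorm(length, 0, gt$noise_sd))
  base
}

#' Generate a synchronized ECG + RAPW pulse train
#'
#' Builds a two-channel record: an ECG-like channel carrying a narrow
#' spike template at each R-peak, and a RAPW channel obtained by
#' concatenating per-beat episodes, each the canonical three-Gaussian
#' beat resampled to its own beat duration.  Slow sinusoidal baseline
#' wander and white noise are added to the pressure channel; the ECG
#' channel receives the same wander at reduced amplitude.  Each R-peak
#' precedes its pulse foot by a fixed pulse-transit delay.
#'
#' Beats listed in `spec$ectopic_beats` have their interval shortened by
#' 40%, mimicking a premature beat.
#'
#' All sample indices in the returned ground-truth annotations are
#' 0-based.
#'
#' @param gt a [pulse_ground_truth()].
#' @param spec a [train_spec()].
#' @return an object of class `raw_record`: a list with numeric channels
#'   `ecg` and `rapw`, sampling rate `fs`, and a `truth` list holding
#'   0-based `r_peaks` and `feet` plus the per-beat parameters.
#' @export
generate_pulse_train <- function(gt, spec) {
  if (!inherits(gt, "pulse_ground_truth")) stop("`gt` must be a pulse_ground_truth", call. = FALSE)
  if (!inherits(spec, "train_spec")) stop("`spec` must be a train_spec", call. = FALSE)
  fs <- spec$fs
  with_seed(spec$seed, {
    rr <- spec$mean_rr + stats::rnorm(spec$n_beats, 0, spec$rr_jitter_sd)
    rr <- pmax(rr, 0.3)                      # physiological floor
    rr[spec$ectopic_beats] <- rr[spec$ectopic_beats] * 0.6
    lens <- pmax(3L, as.integer(round(rr * fs)))
    lead <- as.integer(round(0.5 * fs))      # quiet lead-in before first foot
    tail_pad <- as.integer(round(0.3 * fs))
    feet <- lead + c(0L, cumsum(lens[-spec$n_beats]))
    total <- lead + sum(lens) + tail_pad
    rapw <- numeric(total)
    # records start and end mid-cycle: the lead-in carries the diastolic
    # tail of a virtual previous beat, the tail pad the rise of a virtual
    # next one, so the signal is beat-stationary across its whole span
    L0 <- lens[1]
    lead_canon <- (1000 * (L0 - lead + seq_len(lead) - 1) / L0) + 1
    keep <- lead_canon >= 1
    rapw[seq_len(lead)[keep]] <- gaussian_wave(lead_canon[keep], gt$H[1], gt$W[1], gt$C[1]) +
      gaussian_wave(lead_canon[keep], gt$H[2], gt$W[2], gt$C[2]) +
      gaussian_wave(lead_canon[keep], gt$H[3], gt$W[3], gt$C[3])
    Ln <- lens[spec$n_beats]
    tail_canon <- (1000 * (seq_len(tail_pad) - 1) / Ln) + 1
    rapw[lead + sum(lens) + seq_len(tail_pad)] <-
      gaussian_wave(tail_canon, gt$H[1], gt$W[1], gt$C[1]) +
      gaussian_wave(tail_canon, gt$H[2], gt$W[2], gt$C[2]) +
      gaussian_wave(tail_canon, gt$H[3], gt$W[3], gt$C[3])
    beat_params <- vector("list", spec$n_beats)
    for (i in seq_len(spec$n_beats)) {
      Hi <- gt$H
      if (spec$shape_jitter_sd > 0)
        Hi <- pmax(0.05, Hi * (1 + stats::rnorm(3, 0, spec$shape_jitter_sd)))
      L <- lens[i]
      ncanon <- (seq_len(L) - 1) * 1000 / L + 1
      cur <- gaussian_wave(ncanon, Hi[1], gt$W[1], gt$C[1]) +
             gaussian_wave(ncanon, Hi[2], gt$W[2], gt$C[2]) +
             gaussian_wave(ncanon, Hi[3], gt$W[3], gt$C[3])
      rapw[feet[i] + seq_len(L)] <- cur
      beat_params[[i]] <- list(H = Hi, W = gt$W, C = gt$C)
    }
    # ECG: narrow Gaussian spike, R-peak a fixed transit delay before each foot
    ptt <- as.integer(round(0.15 * fs))
    r_peaks <- feet - ptt
    ecg <- numeric(total)
    spike_half <- as.integer(round(0.02 * fs))
    spike_sd <- 0.004 * fs
    for (r in r_peaks) {
      idx <- (r - spike_half):(r + spike_half)
      keep <- idx >= 0 & idx < total
      ecg[idx[keep] + 1] <- ecg[idx[keep] + 1] + exp(-(idx[keep] - r)^2 / (2 * spike_sd^2))
    }
    tsec <- (seq_len(total) - 1) / fs
    wander <- gt$baseline_amp * sin(2 * pi * gt$baseline_freq * tsec)
    rapw <- rapw + wander + stats::rnorm(total, 0, gt$noise_sd)
    ecg <- ecg + 0.2 * wander + stats::rnorm(total, 0, 0.25 * gt$noise_sd)
    structure(list(ecg = ecg, rapw = rapw, fs = fs,
                   truth = list(r_peaks = r_peaks, feet = feet,
                                beat_lengths = lens, beat_params = beat_params)),
              class = "raw_record")
  })
}

#' Construct a raw two-channel record
#'
#' @param ecg,rapw equal-length numeric channels.
#' @param fs sampling rate in Hz.
#' @param truth optional ground-truth annotations (generator output).
#' @return an object of class `raw_record`.
#' @export
raw_record <- function(ecg, rapw, fs, truth = NULL) {
  if (length(ecg) != length(rapw))
    stop("`ecg` and `rapw` must have equal length", call. = FALSE)
  stop_if_not_scalar_pos(fs, "fs")
  structure(list(ecg = as.numeric(ecg), rapw = as.numeric(rapw),
                 fs = fs, truth = truth),
            class = "raw_record")
}

#' @export
print.raw_record <- function(x, ...) {
  cat(sprintf("raw_record: %d samples at %g Hz (%.1f s)%s\n",
              length(x$rapw), x$fs, length(x$rapw) / x$fs,
              if (!is.null(x$truth)) sprintf(", %d annotated beats", length(x$truth$feet)) else ""))
  invisible(x)
}

#' Write a raw record to CSV with a JSON sidecar
#'
#' The CSV holds columns `ecg` and `rapw`; the sidecar stores the
#' sampling rate and any ground-truth annotations.
#'
#' @param record a [raw_record].
#' @param path CSV output path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_raw_record <- function(record, path) {
  if (!inherits(record, "raw_record")) stop("`record` must be a raw_record", call. = FALSE)
  utils::write.csv(data.frame(ecg = record$ecg, rapw = record$rapw),
                   path, row.names = FALSE)
  meta <- list(fs = record$fs, truth = record$truth)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a raw record written by [write_raw_record()]
#'
#' @param path CSV path; `<path>.json` is read if present, otherwise
#'   `fs` must be supplied.
#' @param fs sampling rate override (Hz).
#' @return a [raw_record].
#' @export
read_raw_record <- function(path, fs = NULL) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path), call. = FALSE)
  d <- utils::read.csv(path)
  if (!all(c("ecg", "rapw") %in% names(d)))
    stop("record CSV must have columns `ecg` and `rapw`", call. = FALSE)
  truth <- NULL
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(fs)) fs <- meta$fs
    truth <- meta$truth
  }
  if (is.null(fs)) stop("no sampling rate: supply `fs` or a JSON sidecar", call. = FALSE)
  raw_record(d$ecg, d$rapw, fs, truth)
}
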