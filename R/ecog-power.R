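#' @noRd
# zero-phase filtering with reflection padding: the signal is extended at
# both ends by a time-reversed copy of length pad_n before forward-backward
# filtering, and the extension discarded afterwards. Keeps filter transients
# out of the retained span.
filtfilt_padded <- function(filt, x, pad_n) {
  n <- length(x)
  pad_n <- min(pad_n, n - 1)
  if (pad_n > 0) {
    head_ref <- 2 * x[1] - x[(pad_n + 1):2]
    tail_ref <- 2 * x[n] - x[(n - 1):(n - pad_n)]
    xp <- c(head_ref, x, tail_ref)
  } else xp <- x
  y <- signal::filtfilt(filt, xp)
  y[(pad_n + 1):(pad_n + n)]
}

apply_channelwise <- function(rec, fun, step) {
  out <- rec
  for (i in seq_len(nrow(rec$samples))) out$samples[i, ] <- fun(rec$samples[i, ])
  out$provenance <- c(rec$provenance, step)
  out
}

#' Downsample a recording
#'
#' Anti-alias lowpass (8th-order Butterworth at 80% of the new Nyquist,
#' zero-phase) followed by decimation. The target rate must divide the
#' current rate. Markers are rescaled to the new sample units, flooring
#' onsets and ceiling offsets so no labelled sample is lost.
#'
#' @param rec An [ecog_recording()].
#' @param fs_target New sampling rate in Hz.
#' @return The downsampled [ecog_recording()].
#' @export
downsample <- function(rec, fs_target) {
  stopifnot(inherits(rec, "ecog_recording"))
  if (fs_target > rec$fs)
    abort("fs_target exceeds the recording sampling rate",
          class = "glio_argument_error")
  if (fs_target == rec$fs) return(rec)
  fac <- rec$fs / fs_target
  if (abs(fac - round(fac)) > 1e-9)
    abort("fs_target must divide fs", class = "glio_argument_error")
  fac <- round(fac)
  aa <- signal::butter(8, 0.8 / fac, type = "low")
  keep <- seq(1, n_samples(rec), by = fac)
  out <- rec
  out$samples <- matrix(0, nrow(rec$samples), length(keep),
                        dimnames = list(rownames(rec$samples), NULL))
  for (i in seq_len(nrow(rec$samples)))
    out$samples[i, ] <- filtfilt_padded(aa, rec$samples[i, ], round(rec$fs))[keep]
  out$fs <- fs_target
  out$markers <- mutate(rec$markers,
                        onset = floor((.data$onset - 1) / fac) + 1L,
                        offset = pmin(as.integer(ceiling(.data$offset / fac)),
                                      length(keep)))
  out$provenance <- c(rec$provenance, sprintf("downsample:%gHz", fs_target))
  out
}

#' Bipolar re-referencing along strips
#'
#' Each strip of m electrodes, ordered by position along the strip, yields
#' m - 1 derived channels (electrode k minus electrode k+1). Any signal
#' common to all electrodes of a strip -- notably the shared scalp reference
#' -- cancels exactly.
#'
#' @param rec An [ecog_recording()].
#' @return An [ecog_recording()] with the derived channels, named
#'   `<a>-<b>`.
#' @export
bipolar_rereference <- function(rec) {
  stopifnot(inherits(rec, "ecog_recording"))
  ch <- arrange(rec$channels, .data$strip_id, .data$index_in_strip)
  pieces <- list(); tabs <- list()
  for (s in unique(ch$strip_id)) {
    rows <- ch[ch$strip_id == s, ]
    if (nrow(rows) < 2)
      abort(sprintf("strip %s has fewer than 2 channels; cannot derive bipolar pairs", s),
            class = "glio_argument_error")
    a <- rows$channel_id[-nrow(rows)]; b <- rows$channel_id[-1]
    der <- rec$samples[a, , drop = FALSE] - rec$samples[b, , drop = FALSE]
    rownames(der) <- paste0(a, "-", b)
    pieces[[s]] <- der
    tabs[[s]] <- tibble(channel_id = rownames(der), strip_id = s,
                        index_in_strip = seq_len(nrow(der)))
  }
  out <- rec
  out$samples <- do.call(rbind, pieces)
  out$channels <- bind_rows(tabs)
  out$provenance <- c(rec$provenance, "bipolar")
  out
}

# RBJ biquad notch at f0 with quality factor Q
notch_biquad <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b = b / a[1], a = a / a[1])
}

# integer harmonics of each base strictly below Nyquist
harmonics_below_nyquist <- function(bases, fs) {
  unlist(lapply(bases, function(b) b * seq_len(floor((fs / 2 - 1e-9) / b))))
}

#' Notch out line noise and its harmonics
#'
#' Applies a narrow zero-phase IIR notch (biquad, quality factor 30) at
#' every integer harmonic of each base frequency below Nyquist. Narrow
#' notches leave the high-gamma band between equipment-line harmonics
#' essentially untouched.
#'
#' @param rec An [ecog_recording()].
#' @param base_freqs Base frequencies in Hz (all must be below Nyquist).
#' @param Q Notch quality factor.
#' @return The filtered [ecog_recording()].
#' @export
notch_filter <- function(rec, base_freqs = c(50, 79), Q = 30) {
  stopifnot(inherits(rec, "ecog_recording"))
  if (any(base_freqs >= rec$fs / 2))
    abort("notch base at or above Nyquist", class = "glio_argument_error")
  freqs <- harmonics_below_nyquist(base_freqs, rec$fs)
  filts <- lapply(freqs, notch_biquad, fs = rec$fs, Q = Q)
  apply_channelwise(rec, function(x) {
    for (f in filts) x <- filtfilt_padded(f, x, round(rec$fs))
    x
  }, sprintf("notch:%s", paste(base_freqs, collapse = "+")))
}

# zero-phase Butterworth bandpass. The direct 4th-order bandpass (8 poles)
# is numerically unstable for very narrow normalised bands (delta, alpha at
# 2 kHz); when its output goes non-finite, an equivalent cascade of 4th-order
# low- and high-pass sections is used instead.
bandpass_filter <- function(x, band, fs) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  y <- filtfilt_padded(bf, x, round(fs))
  if (all(is.finite(y))) return(y)
  lp <- signal::butter(4, band[2] / (fs / 2), type = "low")
  hp <- signal::butter(4, band[1] / (fs / 2), type = "high")
  filtfilt_padded(hp, filtfilt_padded(lp, x, round(fs)), round(fs))
}

# analytic signal via FFT (one-sided spectrum doubling)
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Instantaneous band power
#'
#' Zero-phase 4th-order Butterworth bandpass followed by the Hilbert
#' envelope: instantaneous power is the squared magnitude of the analytic
#' signal of the band-limited data, in microvolt squared.
#'
#' @param rec An [ecog_recording()].
#' @param band Length-2 numeric band edges in Hz, strictly inside
#'   (0, Nyquist).
#' @param band_name Label carried into downstream results.
#' @return A `power_timeseries`: like a recording but `samples` holds
#'   non-negative instantaneous power.
#' @export
bandpass_power <- function(rec, band, band_name = paste0(band[1], "-", band[2], "Hz")) {
  stopifnot(inherits(rec, "ecog_recording"))
  if (band[1] <= 0 || band[2] >= rec$fs / 2 || band[1] >= band[2])
    abort("band must lie strictly inside (0, Nyquist)",
          class = "glio_argument_error")
  out <- apply_channelwise(rec, function(x) {
    xb <- bandpass_filter(x, band, rec$fs)
    Mod(analytic_signal(xb))^2
  }, sprintf("bandpass_power:%s", band_name))
  out$band <- band_name
  class(out) <- c("power_timeseries", class(out))
  out
}

trim_rule_s <- function(condition) {
  switch(condition,
         rest = c(2, 2),   # seconds trimmed from start, end
         easy = c(1, 1),
         hard = c(4, 1),   # 1 s marker slack + 3 s initial easy phase
         abort(paste("unknown condition", condition), class = "glio_format_error"))
}

#' Segment a power timeseries into trimmed condition trials
#'
#' Manual marker placement is compensated by trimming each trial: rest
#' trials lose 2 s at both ends, easy trials 1 s at both ends, and hard
#' (switch) trials additionally lose 3 s at the start covering the initial
#' easy phase of the switch task (1 + 3 s at the start, 1 s at the end).
#'
#' @param pw A `power_timeseries` from [bandpass_power()].
#' @return A `segmented_power`: tibble with one row per
#'   (channel, condition, trial) and a list-column `power` of retained
#'   samples, plus `fs`, `band` and provenance attributes.
#' @export
segment_trials <- function(pw) {
  stopifnot(inherits(pw, "power_timeseries"))
  fs <- pw$fs
  mk <- pw$markers
  segs <- list()
  for (i in seq_len(nrow(mk))) {
    tr <- trim_rule_s(mk$condition[i]) * fs
    a <- mk$onset[i] + tr[1]; b <- mk$offset[i] - tr[2]
    if (a > b)
      abort(sprintf("trial %s (%s) shorter than its trim of %g s",
                    mk$trial_id[i], mk$condition[i], sum(tr) / fs),
            class = "glio_argument_error")
    for (ch in rownames(pw$samples))
      segs[[length(segs) + 1]] <- tibble(
        channel_id = ch, condition = mk$condition[i],
        trial_id = mk$trial_id[i],
        power = list(pw$samples[ch, a:b]))
  }
  out <- bind_rows(segs)
  structure(out, fs = fs, band = pw$band %||% "hg",
            provenance = c(pw$provenance, "segment_trials"),
            class = c("segmented_power", class(out)))
}

#' Run the full preprocessing chain
#'
#' Fixed stage order: downsample, bipolar re-reference, notch, bandpass
#' power, trial segmentation.
#'
#' @param rec An [ecog_recording()].
#' @param cfg A [glio_config()].
#' @param band Band edges in Hz (defaults to the configured high-gamma
#'   band).
#' @param band_name Band label.
#' @return A `segmented_power`.
#' @export
preprocess_ecog <- function(rec, cfg = glio_config(), band = cfg$hg_band,
                            band_name = "hg") {
  rec |>
    downsample(cfg$fs_target) |>
    bipolar_rereference() |>
    notch_filter(cfg$notch_bases) |>
    bandpass_power(band, band_name) |>
    segment_trials()
}
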