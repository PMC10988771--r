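#' Specification for a synthetic ECoG recording
#'
#' Describes a trial-structured multichannel recording emulating intraoperative
#' strip ECoG: pink (1/f) broadband background, sinusoidal line noise at the
#' mains frequency and an equipment line, and a band-limited high-gamma
#' carrier whose envelope power is multiplied by planted condition factors
#' during task trials. Because the effect is multiplicative on power, each
#' channel's true percentage signal change has the closed form
#' (factor - 1) * 100.
#'
#' @param n_strips Number of electrode strips.
#' @param electrodes_per_strip Electrodes per strip (strips carry 4 in the
#'   emulated recordings).
#' @param fs Sampling rate in Hz.
#' @param trial_plan Tibble/data frame with columns `condition`
#'   (rest/easy/hard), `duration_s`, `repeats`. Trials are laid out in
#'   condition blocks separated by `gap_s` of unlabelled recording.
#' @param easy_factor,hard_factor Numeric vectors (recycled over channels):
#'   multiplicative high-gamma power factors for easy-vs-rest and
#'   hard-vs-easy.
#' @param noise_exponent Spectral exponent of the 1/f background (power ~
#'   1/f^exponent).
#' @param noise_amp RMS amplitude (microvolt) of the broadband background.
#' @param hg_amp RMS amplitude (microvolt) of the high-gamma carrier at
#'   rest.
#' @param line_amp Named numeric: sinusoid amplitudes at the line
#'   frequencies (names are frequencies in Hz).
#' @param gap_s Unlabelled gap between consecutive trials, seconds.
#' @param rng_seed Integer seed; the generator is a pure function of spec +
#'   seed.
#' @return An `ecog_sim_spec`.
#' @export
ecog_sim_spec <- function(n_strips = 1, electrodes_per_strip = 4, fs = 2000,
                          trial_plan = tibble(
                            condition = c("rest", "easy", "hard"),
                            duration_s = c(120, 20, 20),
                            repeats = c(1L, 4L, 4L)),
                          easy_factor = 1, hard_factor = 1,
                          noise_exponent = 1, noise_amp = 10,
                          hg_amp = 8, line_amp = c(`50` = 10, `79` = 5),
                          gap_s = 2, rng_seed = 1L) {
  trial_plan <- as_tibble(trial_plan)
  stopifnot(all(trial_plan$duration_s > 0), all(trial_plan$repeats >= 1))
  if (any(easy_factor <= 0) || any(hard_factor <= 0))
    abort("condition power factors must be > 0", class = "glio_argument_error")
  structure(list(n_strips = n_strips, electrodes_per_strip = electrodes_per_strip,
                 fs = fs, trial_plan = trial_plan,
                 easy_factor = easy_factor, hard_factor = hard_factor,
                 noise_exponent = noise_exponent, noise_amp = noise_amp,
                 hg_amp = hg_amp, line_amp = line_amp, gap_s = gap_s,
                 rng_seed = as.integer(rng_seed)),
            class = "ecog_sim_spec")
}

# pink-ish noise by spectral shaping of white gaussian noise:
# amplitude spectrum scaled by f^(-expo/2), DC removed, normalised to unit RMS
shaped_noise <- function(n, exponent) {
  x <- stats::rnorm(n)
  X <- fft(x)
  f <- c(1, seq_len(n - 1))                      # avoid dividing by 0 at DC
  f <- pmin(f, n - f + 1)                        # mirror for negative freqs
  X <- X * f^(-exponent / 2)
  X[1] <- 0
  out <- Re(fft(X, inverse = TRUE)) / n
  out / sd(out)
}

# band-limited gaussian carrier, unit RMS
band_carrier <- function(n, fs, band) {
  x <- bandpass_filter(stats::rnorm(n), band, fs)
  x / sd(x)
}

#' Simulate a trial-structured ECoG recording with planted power effects
#'
#' @param spec An [ecog_sim_spec()].
#' @return A list: `recording` (an [ecog_recording()]) and `ground_truth`, a
#'   tibble with one row per channel x contrast giving the true percentage
#'   signal change `psc_true = (factor - 1) * 100`.
#' @export
simulate_ecog <- function(spec) {
  stopifnot(inherits(spec, "ecog_sim_spec"))
  set.seed(spec$rng_seed)
  fs <- spec$fs
  n_ch <- spec$n_strips * spec$electrodes_per_strip
  easy_f <- rep_len(spec$easy_factor, n_ch)
  hard_f <- rep_len(spec$hard_factor, n_ch)

  # lay out trials: lead-in gap, then each plan row's repeats in sequence
  rows <- tidyr::uncount(spec$trial_plan, .data$repeats)
  onset_s <- spec$gap_s + cumsum(c(0, head(rows$duration_s + spec$gap_s, -1)))
  markers <- tibble(trial_id = seq_len(nrow(rows)), condition = rows$condition,
                    onset = floor(onset_s * fs) + 1L,
                    offset = floor((onset_s + rows$duration_s) * fs))
  total_n <- max(markers$offset) + round(spec$gap_s * fs)

  t_axis <- (seq_len(total_n) - 1) / fs
  # per-sample power multiplier per condition (shared layout across channels)
  cond_of_sample <- rep(NA_character_, total_n)
  for (i in seq_len(nrow(markers)))
    cond_of_sample[markers$onset[i]:markers$offset[i]] <- markers$condition[i]

  samples <- matrix(0, n_ch, total_n)
  ids <- as.vector(t(outer(seq_len(spec$n_strips), seq_len(spec$electrodes_per_strip),
                           function(s, e) sprintf("S%dE%d", s, e))))
  line <- rep(0, total_n)
  for (f0 in as.numeric(names(spec$line_amp)))
    line <- line + spec$line_amp[[as.character(f0)]] *
      sin(2 * pi * f0 * t_axis + stats::runif(1, 0, 2 * pi))
  for (ch in seq_len(n_ch)) {
    bg <- spec$noise_amp * shaped_noise(total_n, spec$noise_exponent)
    carrier <- spec$hg_amp * band_carrier(total_n, fs, c(70, 250))
    fac <- rep(1, total_n)
    fac[which(cond_of_sample == "easy")] <- easy_f[ch]
    fac[which(cond_of_sample == "hard")] <- easy_f[ch] * hard_f[ch]
    samples[ch, ] <- bg + line + sqrt(fac) * carrier
  }
  rownames(samples) <- ids
  gt <- bind_rows(
    tibble(channel_id = ids, contrast = "easy_gt_rest",
           factor = easy_f, psc_true = (easy_f - 1) * 100),
    tibble(channel_id = ids, contrast = "hard_gt_easy",
           factor = hard_f, psc_true = (hard_f - 1) * 100))
  list(recording = ecog_recording(samples, fs, markers = markers,
                                  provenance = "simulate_ecog"),
       ground_truth = gt)
}
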