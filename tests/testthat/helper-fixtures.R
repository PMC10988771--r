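# shared fixture builders; everything is generated in code at test time

# a small recording with two 4-electrode strips and simple markers
tiny_recording <- function(n = 2000, fs = 1000, seed = 1) {
  set.seed(seed)
  ids <- sprintf("S%dE%d", rep(1:2, each = 4), rep(1:4, 2))
  m <- matrix(rnorm(8 * n, sd = 30), 8, n, dimnames = list(ids, NULL))
  ecog_recording(m, fs,
                 markers = tibble::tibble(trial_id = 1:2,
                                          condition = c("rest", "easy"),
                                          onset = c(1L, as.integer(n / 2)),
                                          offset = c(as.integer(n / 4), n)))
}

# build a segmented_power object directly from explicit per-trial vectors:
# trials = list of list(channel_id, condition, trial_id, power)
make_segmented <- function(trials, fs = 10, band = "hg") {
  tab <- dplyr::bind_rows(lapply(trials, function(tr)
    tibble::tibble(channel_id = tr$channel_id, condition = tr$condition,
                   trial_id = tr$trial_id, power = list(tr$power))))
  structure(tab, fs = fs, band = band, provenance = "fixture",
            class = c("segmented_power", class(tab)))
}

# independent brute-force oracle for the rotation permutation null:
# for every integer shift of the loop, recompute condition means and PSC
# by explicit elementwise indexing of the rotated series
oracle_rotation_pscs <- function(values, condition, lens) {
  L <- sum(lens)
  starts <- cumsum(lens) - lens + 1
  pscs <- numeric(L - 1)
  for (shift in seq_len(L - 1)) {
    sums <- c(easy = 0, hard = 0, rest = 0); ns <- c(easy = 0, hard = 0, rest = 0)
    for (i in seq_along(lens)) {
      pos <- ((starts[i] + shift):(starts[i] + shift + lens[i] - 1) - 1) %% L + 1
      sums[condition[i]] <- sums[condition[i]] + sum(values[pos])
      ns[condition[i]] <- ns[condition[i]] + lens[i]
    }
    m1 <- sums[["hard"]] / ns[["hard"]]; m2 <- sums[["easy"]] / ns[["easy"]]
    pscs[shift] <- (m1 / m2 - 1) * 100
  }
  pscs
}

# lean null-electrode path used by calibration/property tests: the planted
# data carry no line noise, so the notch stage is omitted
null_electrode_p <- function(seed, n_rotations = 2000, easy_factor = 1,
                             hard_factor = 1, noise_amp = 10, hg_amp = 8) {
  plan <- tibble::tibble(condition = c("easy", "hard"), duration_s = 10,
                         repeats = 4L)
  sim <- simulate_ecog(ecog_sim_spec(n_strips = 1, electrodes_per_strip = 2,
                                     trial_plan = plan,
                                     easy_factor = easy_factor,
                                     hard_factor = hard_factor,
                                     noise_amp = noise_amp, hg_amp = hg_amp,
                                     line_amp = c(`50` = 0),
                                     rng_seed = seed))
  seg <- sim$recording |> bipolar_rereference() |>
    bandpass_power(c(70, 250), "hg") |> segment_trials()
  rotation_permutation_test(seg, contrast_spec("hard_gt_easy"),
                            n_rotations, rng_seed = seed)$p
}

# pure sinusoid recording on one 2-electrode strip (bipolar-safe)
tone_recording <- function(freq, fs = 2000, dur = 10, amp = 10) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- amp * sin(2 * pi * freq * t)
  m <- rbind(S1E1 = x, S1E2 = -x)   # derived channel carries 2x the tone
  ecog_recording(m, fs)
}

rms <- function(x) sqrt(mean(x^2))

# smooth rotation-isotropic surface map: random linear + quadratic form
# of the vertex coordinates (low-order spherical pattern)
smooth_random_map <- function(mesh, seed) {
  set.seed(seed)
  V <- mesh$vertices
  a <- rnorm(3)
  G <- matrix(rnorm(9), 3); G <- (G + t(G)) / 2
  surface_map(as.numeric(V %*% a + rowSums((V %*% G) * V)))
}
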