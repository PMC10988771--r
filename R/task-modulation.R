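#' Mean power per condition
#'
#' Pooled-sample definition: the mean over the concatenation of all retained
#' samples of all trials of the condition, so trials are weighted by their
#' length, not equally.
#'
#' @param seg A `segmented_power` from [segment_trials()].
#' @param condition Condition name.
#' @return Named numeric, one mean per channel.
#' @export
condition_mean_power <- function(seg, condition) {
  rows <- seg[seg$condition == condition, ]
  if (!nrow(rows))
    abort(paste("no trials of condition", condition),
          class = "glio_argument_error")
  vapply(split(rows$power, rows$channel_id),
         function(ps) mean(unlist(ps)), numeric(1))
}

#' Percentage signal change
#'
#' `((p1 / p2) - 1) * 100`: the per-electrode contrast statistic comparing
#' mean band power between two conditions.
#'
#' @param p1,p2 Mean power in the numerator / denominator condition.
#' @return Percent change.
#' @export
#' @examples
#' percent_signal_change(2, 1)   # 100
percent_signal_change <- function(p1, p2) {
  if (any(p2 == 0))
    abort("denominator condition has zero mean power; contrast undefined",
          class = "glio_argument_error")
  ((p1 / p2) - 1) * 100
}

#' Contrast specification
#'
#' @param name `"hard_gt_easy"` or `"easy_gt_rest"` (any pair of distinct
#'   conditions is accepted).
#' @return A list with `name`, `condition_1` (numerator), `condition_2`.
#' @export
contrast_spec <- function(name = c("hard_gt_easy", "easy_gt_rest")) {
  name <- match.arg(name)
  parts <- strsplit(name, "_gt_")[[1]]
  list(name = name, condition_1 = parts[1], condition_2 = parts[2])
}

# Build the rotation loop for one channel: trials of both contrast
# conditions concatenated serially in recorded order, last joined to first.
build_loop <- function(rows) {
  rows <- rows[order(rows$trial_id), ]
  lens <- lengths(rows$power)
  ends <- cumsum(lens)
  list(values = unlist(rows$power), condition = rows$condition,
       start = ends - lens + 1, end = ends, L = sum(lens))
}

# condition means under a vector of loop shifts, via a doubled prefix sum;
# returns a matrix (length(shifts) x 2) of [cond1, cond2] means
rotated_means <- function(loop, cond1, cond2, shifts) {
  S <- c(0, cumsum(c(loop$values, loop$values)))
  sums1 <- numeric(length(shifts)); sums2 <- numeric(length(shifts))
  is1 <- loop$condition == cond1
  n1 <- sum(loop$end[is1] - loop$start[is1] + 1)
  n2 <- sum(loop$end[!is1] - loop$start[!is1] + 1)
  for (i in seq_along(loop$start)) {
    seg <- S[loop$end[i] + 1 + shifts] - S[loop$start[i] + shifts]
    if (is1[i]) sums1 <- sums1 + seg else sums2 <- sums2 + seg
  }
  cbind(sums1 / n1, sums2 / n2)
}

#' Loop-rotation permutation test for a power contrast
#'
#' For each channel, all trials of the two contrast conditions are
#' concatenated serially into a loop (end joined to start). Each rotation
#' draws one integer jitter, shared by every trial marker, shifting all
#' onsets/offsets around the loop; condition means and the percentage
#' signal change are recomputed on the rotated series. This preserves trial
#' lengths and the temporal autocorrelation of the power series. The
#' two-tailed p-value is `2 * min(r_low, r_high)` with the finite-sample
#' `(count + 1) / (n + 1)` correction, capped at 1.
#'
#' Jitters are drawn uniformly from {1, ..., L-1}; when `n_rotations >=
#' L - 1` every distinct shift is enumerated instead and the null is exact.
#'
#' @param seg A `segmented_power`.
#' @param contrast A [contrast_spec()].
#' @param n_rotations Number of rotations.
#' @param rng_seed Integer seed.
#' @param alpha Two-tailed significance level.
#' @return A tibble (class `contrast_result`), one row per channel:
#'   `channel_id`, `band`, `contrast`, `psc`, `p`, `significant`,
#'   `n_rotations`, surrogate summary columns and a `degenerate` flag.
#' @export
rotation_permutation_test <- function(seg, contrast = contrast_spec(),
                                      n_rotations = 1000, rng_seed = 1L,
                                      alpha = 0.05) {
  stopifnot(inherits(seg, "segmented_power"))
  conds <- c(contrast$condition_1, contrast$condition_2)
  if (!all(conds %in% seg$condition))
    abort(sprintf("contrast conditions (%s) not all present",
                  paste(conds, collapse = ", ")),
          class = "glio_argument_error")
  sub <- seg[seg$condition %in% conds, ]
  set.seed(rng_seed)
  out <- list()
  for (ch in unique(sub$channel_id)) {
    loop <- build_loop(sub[sub$channel_id == ch, ])
    if (loop$L < 2) abort("loop too short", class = "glio_argument_error")
    if (n_rotations >= loop$L - 1) shifts <- seq_len(loop$L - 1)
    else shifts <- sample.int(loop$L - 1, n_rotations, replace = TRUE)
    obs_m <- rotated_means(loop, conds[1], conds[2], 0L)
    obs <- percent_signal_change(obs_m[1], obs_m[2])
    sur_m <- rotated_means(loop, conds[1], conds[2], shifts)
    sur <- percent_signal_change(sur_m[, 1], sur_m[, 2])
    nr <- length(sur)
    degenerate <- all(abs(sur - obs) < 1e-12)
    if (degenerate) p <- 1 else {
      r_high <- (sum(sur >= obs) + 1) / (nr + 1)
      r_low <- (sum(sur <= obs) + 1) / (nr + 1)
      p <- min(1, 2 * min(r_low, r_high))
    }
    out[[ch]] <- tibble(
      channel_id = ch, band = attr(seg, "band"), contrast = contrast$name,
      psc = obs, p = p, significant = p < alpha, n_rotations = nr,
      surrogate_mean = mean(sur), surrogate_sd = sd(sur),
      surrogate_q025 = unname(quantile(sur, 0.025)),
      surrogate_q975 = unname(quantile(sur, 0.975)),
      degenerate = degenerate,
      surrogates = list(sur))
  }
  res <- bind_rows(out)
  class(res) <- c("contrast_result", class(res))
  res
}

#' Per-band contrast analysis
#'
#' Runs the percentage-signal-change contrast and rotation permutation test
#' for the high-gamma band plus the configured extra bands (delta, alpha,
#' beta, gamma), producing one result row per (channel, band, contrast).
#'
#' @param rec A raw [ecog_recording()].
#' @param cfg A [glio_config()].
#' @param contrasts List of [contrast_spec()]s.
#' @param n_rotations Rotations per test (defaults to the configured count).
#' @return A `contrast_result` tibble.
#' @export
run_band_analysis <- function(rec, cfg = glio_config(),
                              contrasts = list(contrast_spec("hard_gt_easy"),
                                               contrast_spec("easy_gt_rest")),
                              n_rotations = cfg$n_rotations) {
  bands <- c(list(hg = cfg$hg_band), cfg$extra_bands)
  pre <- rec |> downsample(cfg$fs_target) |> bipolar_rereference() |>
    notch_filter(cfg$notch_bases)
  res <- list()
  for (bn in names(bands)) {
    seg <- pre |> bandpass_power(bands[[bn]], bn) |> segment_trials()
    for (ct in contrasts)
      res[[paste(bn, ct$name)]] <-
        rotation_permutation_test(seg, ct, n_rotations,
                                  rng_seed = cfg$rng_seed,
                                  alpha = cfg$alpha_level)
  }
  out <- bind_rows(res)
  class(out) <- c("contrast_result", class(out))
  out
}
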