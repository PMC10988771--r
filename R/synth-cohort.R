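#' Specification for a synthetic patient cohort
#'
#' One row per patient with tumour-network connectivity drawn from a
#' location-shifted normal distribution, demographic and clinical
#' categoricals, a standardised pre-operative score, and a follow-up score
#' generated from a linear model with planted coefficients. Continuous
#' predictors enter the generating model z-scored within the cohort, so the
#' planted coefficients are directly comparable to the standardised
#' estimates the model fitters report; categorical dummies enter as 0/1.
#'
#' @param n_patients Number of patients (must exceed the predictor count by
#'   at least 2).
#' @param conn_mean Named numeric: mean connectivity per tumour location
#'   (`frontal`, `insula`, `temporal`).
#' @param conn_sd Connectivity standard deviation within location.
#' @param coefs Named numeric of planted outcome-model coefficients:
#'   `intercept`, `conn`, `preop`, `loc_insula`, `loc_temporal`,
#'   `hemi_right`, `age`, `gender_male`, `tp_month3`, `tp_postop`.
#' @param residual_sd Residual sd of the follow-up score.
#' @param missing_frac Fraction of patients with a missing follow-up score.
#' @param rng_seed Integer seed.
#' @return A `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_patients = 17,
                            conn_mean = c(frontal = 0.10, insula = 0.30,
                                          temporal = 0.15),
                            conn_sd = 0.08,
                            coefs = c(intercept = 0, conn = 0, preop = 0.3,
                                      loc_insula = 0, loc_temporal = 0,
                                      hemi_right = 0, age = 0,
                                      gender_male = 0, tp_month3 = 0,
                                      tp_postop = 0),
                            residual_sd = 1, missing_frac = 0,
                            rng_seed = 1L) {
  defaults <- c(intercept = 0, conn = 0, preop = 0, loc_insula = 0,
                loc_temporal = 0, hemi_right = 0, age = 0, gender_male = 0,
                tp_month3 = 0, tp_postop = 0)
  defaults[names(coefs)] <- coefs
  if (n_patients < length(defaults) + 1)
    abort("n_patients must be at least the number of predictors + 2",
          class = "glio_argument_error")
  structure(list(n_patients = as.integer(n_patients), conn_mean = conn_mean,
                 conn_sd = conn_sd, coefs = defaults,
                 residual_sd = residual_sd, missing_frac = missing_frac,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_sim_spec")
}

#' Simulate a patient cohort table
#'
#' @param spec A [cohort_sim_spec()].
#' @return A tibble with columns `patient_id`, `tumour_network_connectivity`,
#'   `location`, `hemisphere`, `overlap_with_network`, `antiseizure`, `age`,
#'   `gender`, `preop_score`, `followup_score`, `latest_timepoint`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  set.seed(spec$rng_seed)
  n <- spec$n_patients
  location <- sample(names(spec$conn_mean), n, replace = TRUE)
  conn <- stats::rnorm(n, spec$conn_mean[location], spec$conn_sd)
  hemisphere <- sample(c("left", "right"), n, replace = TRUE)
  gender <- sample(c("female", "male"), n, replace = TRUE)
  antiseizure <- sample(c("no", "yes"), n, replace = TRUE)
  age <- round(stats::runif(n, 20, 60))
  overlap <- stats::rpois(n, 20)
  preop <- stats::rnorm(n)
  timepoint <- sample(c("post-op", "month 3", "month 12"), n, replace = TRUE)
  z <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  b <- spec$coefs
  mu <- b["intercept"] + b["conn"] * z(conn) + b["preop"] * z(preop) +
    b["loc_insula"] * (location == "insula") +
    b["loc_temporal"] * (location == "temporal") +
    b["hemi_right"] * (hemisphere == "right") +
    b["age"] * z(age) + b["gender_male"] * (gender == "male") +
    b["tp_month3"] * (timepoint == "month 3") +
    b["tp_postop"] * (timepoint == "post-op")
  followup <- as.numeric(mu) + stats::rnorm(n, sd = spec$residual_sd)
  miss <- stats::runif(n) < spec$missing_frac
  followup[miss] <- NA_real_
  tibble(patient_id = sprintf("P%02d", seq_len(n)),
         tumour_network_connectivity = conn,
         location = location, hemisphere = hemisphere,
         overlap_with_network = overlap, antiseizure = antiseizure,
         age = age, gender = gender, preop_score = preop,
         followup_score = followup, latest_timepoint = timepoint)
}

#' Simulate per-electrode feature rows for the association grid
#'
#' Generates the electrode-level table linking task contrasts to per-network
#' connectivity: for each participant and electrode, per-network median
#' connectivity values (Fisher-z units) and a percentage-signal-change
#' response generated as `psc = intercept_p + slope * fc[target_network] +
#' noise`, with a participant-specific random intercept. Used to exercise
#' the mixed-effects grid with known ground truth.
#'
#' @param n_participants,electrodes_each Cohort layout.
#' @param networks Character vector of network names.
#' @param contrasts Character vector of contrast names.
#' @param slope Planted fixed-effect slope of psc on the target network's
#'   connectivity (same slope for every contrast).
#' @param target_network Network whose connectivity drives psc.
#' @param intercept_sd Sd of the participant random intercept.
#' @param noise_sd Residual sd of psc.
#' @param rng_seed Integer seed.
#' @return Tibble with columns `participant_id`, `electrode_id`, `contrast`,
#'   `psc`, and one `fc_<network>` column per network.
#' @export
simulate_electrode_features <- function(n_participants = 8, electrodes_each = 5,
                                        networks = paste0("net", 1:7),
                                        contrasts = c("hard_gt_easy", "easy_gt_rest"),
                                        slope = 0, target_network = networks[1],
                                        intercept_sd = 5, noise_sd = 5,
                                        rng_seed = 1L) {
  set.seed(rng_seed)
  base <- tidyr::expand_grid(participant_id = sprintf("P%02d", seq_len(n_participants)),
                             electrode_id = sprintf("E%02d", seq_len(electrodes_each)))
  fc <- matrix(stats::rnorm(nrow(base) * length(networks), sd = 0.3),
               nrow(base), length(networks),
               dimnames = list(NULL, paste0("fc_", networks)))
  ri <- stats::rnorm(n_participants, sd = intercept_sd)
  names(ri) <- sprintf("P%02d", seq_len(n_participants))
  out <- tidyr::expand_grid(base, contrast = contrasts)
  fc_rep <- fc[rep(seq_len(nrow(base)), each = length(contrasts)), , drop = FALSE]
  psc <- ri[out$participant_id] +
    slope * fc_rep[, paste0("fc_", target_network)] +
    stats::rnorm(nrow(out), sd = noise_sd)
  bind_cols(out, as_tibble(fc_rep), tibble(psc = as.numeric(psc)))
}
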