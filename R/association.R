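z_score <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) abort("cannot standardise a constant column",
                                     class = "glio_argument_error")
  (x - mean(x)) / s
}

#' Mixed-effects grid relating task contrasts to network connectivity
#'
#' Fits one linear mixed-effects model per (contrast, network) pair --
#' percentage signal change as the response, the network's median
#' connectivity as the fixed effect, and a participant random intercept --
#' and evaluates the connectivity term with a Type II Wald chi-square test
#' (1 df, computed as `(estimate / SE)^2`). With 2 contrasts and 7 networks
#' this is the standard 14-model grid.
#'
#' @param rows Tibble of electrode feature rows: `participant_id`,
#'   `electrode_id`, `contrast`, `psc`, and one `fc_<network>` column per
#'   network (see [simulate_electrode_features()]).
#' @param networks Character vector of network names (default: parsed from
#'   the `fc_` columns).
#' @param contrasts Character vector of contrast names (default: those
#'   present).
#' @return A tibble (class `psc_fc_grid`), one row per model: `contrast`,
#'   `network`, `estimate` (slope), `se`, `chisq`, `df`, `p`, `n`,
#'   `singular`.
#' @export
fit_psc_fc_grid <- function(rows, networks = NULL, contrasts = NULL) {
  fc_cols <- grep("^fc_", names(rows), value = TRUE)
  networks <- networks %||% sub("^fc_", "", fc_cols)
  contrasts <- contrasts %||% unique(rows$contrast)
  if (length(unique(rows$participant_id)) < 2)
    abort("need at least 2 participants", class = "glio_argument_error")
  out <- list()
  for (ct in contrasts) for (nw in networks) {
    d <- rows[rows$contrast == ct, ]
    d$fc <- d[[paste0("fc_", nw)]]
    fit <- suppressMessages(
      lme4::lmer(psc ~ fc + (1 | participant_id), data = d, REML = TRUE))
    est <- lme4::fixef(fit)[["fc"]]
    se <- sqrt(diag(as.matrix(vcov(fit))))[["fc"]]
    chisq <- (est / se)^2
    out[[paste(ct, nw)]] <- tibble(
      contrast = ct, network = nw, estimate = est, se = se,
      chisq = chisq, df = 1L,
      p = pchisq(chisq, df = 1, lower.tail = FALSE),
      n = nrow(d), singular = lme4::isSingular(fit))
  }
  res <- bind_rows(out)
  class(res) <- c("psc_fc_grid", class(res))
  res
}

# standardised design: response and continuous predictors z-scored,
# categorical dummies left 0/1 with the stated reference levels
std_model_data <- function(d, response, continuous, factors) {
  for (v in continuous) d[[v]] <- z_score(d[[v]])
  d[[response]] <- z_score(d[[response]])
  for (f in names(factors)) d[[f]] <- stats::relevel(factor(d[[f]]), factors[[f]])
  d
}

report_lm <- function(fit, response, n) {
  sm <- summary(fit)$coefficients
  if (any(is.na(coef(fit))))
    abort(paste("rank-deficient model; aliased terms:",
                paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
          class = "glio_argument_error")
  res <- tibble(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                statistic = sm[, 3], p = sm[, 4])
  structure(list(response = response, terms = res, n = n, fit = fit),
            class = "glio_model_report")
}

#' @export
print.glio_model_report <- function(x, ...) {
  cat(sprintf("<glio_model_report> response = %s (n = %d)\n", x$response, x$n))
  print(as.data.frame(x$terms), digits = 3)
  invisible(x)
}

#' Tumour-network connectivity vs tumour location
#'
#' Linear model with mean tumour-network connectivity as the response and
#' tumour location, hemisphere, network overlap, age, gender and
#' antiseizure medication as predictors. Estimates are standardised:
#' response and continuous predictors are z-scored, categorical dummies
#' stay 0/1 with reference levels frontal / left / female / no.
#'
#' @param cohort A cohort tibble (see [simulate_cohort()]).
#' @return A `glio_model_report`.
#' @export
fit_location_model <- function(cohort) {
  if (length(unique(cohort$location)) < 2)
    abort("need at least 2 tumour location levels", class = "glio_argument_error")
  d <- std_model_data(cohort, "tumour_network_connectivity",
                      continuous = c("overlap_with_network", "age"),
                      factors = c(location = "frontal", hemisphere = "left",
                                  gender = "female", antiseizure = "no"))
  fit <- lm(tumour_network_connectivity ~ location + hemisphere +
              overlap_with_network + antiseizure + age + gender, data = d)
  report_lm(fit, "tumour_network_connectivity", nrow(d))
}

#' Longitudinal cognitive outcome model
#'
#' Linear model predicting the latest follow-up score from the
#' pre-operative score, pre-operative tumour-network connectivity, tumour
#' location, hemisphere, age, gender and the timepoint of the latest
#' assessment (dummy coded, reference month 12). Scores are expected in
#' healthy-normed Z units. With `sensitivity = TRUE`, patients whose latest
#' assessment was immediately post-operative are dropped, restricting to
#' follow-ups of three months or more.
#'
#' @param cohort A cohort tibble.
#' @param outcome Name of the follow-up score column.
#' @param sensitivity Drop `latest_timepoint == "post-op"` rows first.
#' @param min_rows Minimum complete rows required.
#' @return A `glio_model_report` (its `n` reports the rows used).
#' @export
fit_outcome_model <- function(cohort, outcome = "followup_score",
                              sensitivity = FALSE, min_rows = 8) {
  d <- cohort
  if (sensitivity) d <- d[d$latest_timepoint != "post-op", ]
  used <- c(outcome, "preop_score", "tumour_network_connectivity", "location",
            "hemisphere", "age", "gender", "latest_timepoint")
  d <- d[complete.cases(d[, used]), ]
  if (nrow(d) < min_rows)
    abort(sprintf("only %d complete rows; need at least %d", nrow(d), min_rows),
          class = "glio_argument_error")
  d$.response <- d[[outcome]]
  d <- std_model_data(d, ".response",
                      continuous = c("preop_score", "tumour_network_connectivity",
                                     "age"),
                      factors = c(location = "frontal", hemisphere = "left",
                                  gender = "female",
                                  latest_timepoint = "month 12"))
  fit <- lm(.response ~ preop_score + tumour_network_connectivity + location +
              hemisphere + latest_timepoint + age + gender, data = d)
  report_lm(fit, outcome, nrow(d))
}
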