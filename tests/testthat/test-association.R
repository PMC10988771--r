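test_that("the mixed-model grid has one report per contrast x network", {
  rows <- simulate_electrode_features(rng_seed = 1)
  g <- fit_psc_fc_grid(rows)
  expect_s3_class(g, "psc_fc_grid")
  expect_equal(nrow(g), 14)
  expect_equal(nrow(dplyr::distinct(g, contrast, network)), 14)
  expect_true(all(g$df == 1))
  expect_error(fit_psc_fc_grid(dplyr::filter(rows, participant_id == "P01")),
               class = "glio_argument_error")
})

test_that("a planted fixed-effect slope is recovered and the Wald test agrees with car", {
  rows <- simulate_electrode_features(n_participants = 8, electrodes_each = 5,
                                      slope = 2, noise_sd = 0.1,
                                      rng_seed = 2)
  g <- fit_psc_fc_grid(rows)
  est <- g$estimate[g$network == "net1" & g$contrast == "hard_gt_easy"]
  expect_lt(abs(est - 2), 0.2)
  # independent cross-check of the Wald chi-square against car::Anova
  skip_if_not_installed("car")
  d <- dplyr::filter(rows, contrast == "hard_gt_easy")
  d$fc <- d$fc_net1
  fit <- lme4::lmer(psc ~ fc + (1 | participant_id), data = d)
  a <- car::Anova(fit, type = "II")
  grow <- g[g$network == "net1" & g$contrast == "hard_gt_easy", ]
  expect_equal(grow$chisq, a$Chisq[1], tolerance = 1e-6)
  expect_equal(grow$p, a$`Pr(>Chisq)`[1], tolerance = 1e-6)
})

test_that("null slopes reject at roughly the nominal rate", {
  rej <- 0
  for (i in 1:100) {
    rows <- simulate_electrode_features(slope = 0, rng_seed = 300 + i)
    d <- dplyr::filter(rows, contrast == "hard_gt_easy")
    d$fc <- d$fc_net1
    fit <- lme4::lmer(psc ~ fc + (1 | participant_id), data = d)
    est <- lme4::fixef(fit)[["fc"]]
    se <- sqrt(diag(as.matrix(vcov(fit))))[["fc"]]
    if (pchisq((est / se)^2, 1, lower.tail = FALSE) < 0.05) rej <- rej + 1
  }
  expect_gte(rej, 1)    # not pathologically conservative
  expect_lte(rej, 12)   # within binomial slack of 5/100
})

test_that("with no random-intercept variance the mixed slope equals pooled OLS", {
  rows <- simulate_electrode_features(slope = 1.5, intercept_sd = 0,
                                      noise_sd = 1, rng_seed = 4)
  d <- dplyr::filter(rows, contrast == "hard_gt_easy")
  d$fc <- d$fc_net1
  g <- fit_psc_fc_grid(rows)
  ols <- coef(lm(psc ~ fc, data = d))[["fc"]]
  grow <- g[g$network == "net1" & g$contrast == "hard_gt_easy", ]
  expect_true(grow$singular)      # variance collapses to the boundary
  expect_equal(grow$estimate, ols, tolerance = 1e-6)
})

test_that("location model recovers a planted insula shift and rejects degenerate input", {
  signs <- vapply(1:40, function(i) {
    co <- simulate_cohort(cohort_sim_spec(
      n_patients = 100, conn_mean = c(frontal = 0.1, insula = 0.3,
                                      temporal = 0.1),
      conn_sd = 0.05, rng_seed = 500 + i))
    td <- tidy(fit_location_model(co))
    td$estimate[td$term == "locationinsula"]
  }, numeric(1))
  expect_gte(mean(signs > 0), 0.95)
  co <- simulate_cohort(cohort_sim_spec(rng_seed = 1))
  co$location <- "frontal"
  expect_error(fit_location_model(co), class = "glio_argument_error")
})

test_that("null location effects give |t| < 2 in most replicates, per term", {
  tmat <- t(vapply(1:200, function(i) {
    co <- simulate_cohort(cohort_sim_spec(
      n_patients = 60, conn_mean = c(frontal = 0.2, insula = 0.2,
                                     temporal = 0.2),
      conn_sd = 0.05, rng_seed = 700 + i))
    td <- tidy(fit_location_model(co))
    abs(td$statistic[td$term != "(Intercept)"])
  }, numeric(7)))
  # for every predictor, |t| < 2 in at least 90% of replicates
  expect_true(all(colMeans(tmat < 2) >= 0.9))
})

test_that("outcome model honours the sensitivity filter and row minimums", {
  co <- simulate_cohort(cohort_sim_spec(n_patients = 20, rng_seed = 8))
  co$latest_timepoint <- rep(c("post-op", "month 3", "month 12"),
                             length.out = 20)
  co$latest_timepoint[1:3] <- "post-op"
  full <- fit_outcome_model(co)
  sens <- fit_outcome_model(co, sensitivity = TRUE)
  expect_equal(full$n, 20)
  expect_equal(sens$n, 20 - sum(co$latest_timepoint == "post-op"))
  co$followup_score <- NA_real_
  expect_error(fit_outcome_model(co), "complete rows",
               class = "glio_argument_error")
  # glance reports model-level fit
  gl <- glance(full)
  expect_equal(gl$n, 20)
  expect_true(gl$r_squared >= 0 && gl$r_squared <= 1)
})

test_that("standardisation is idempotent and leaves dummies untouched", {
  co <- simulate_cohort(cohort_sim_spec(n_patients = 80,
                                        coefs = c(conn = 0.5),
                                        residual_sd = 0.3, rng_seed = 9))
  t1 <- tidy(fit_outcome_model(co))
  co2 <- co
  z <- function(x) (x - mean(x)) / sd(x)
  co2$tumour_network_connectivity <- z(co2$tumour_network_connectivity)
  co2$preop_score <- z(co2$preop_score)
  co2$age <- z(co2$age)
  co2$followup_score <- z(co2$followup_score)
  t2 <- tidy(fit_outcome_model(co2))
  expect_equal(t1$estimate, t2$estimate, tolerance = 1e-10)
  # dummy terms stay 0/1: their estimates are shifts in response-sd units
  expect_true(any(grepl("location", t1$term)))
})
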