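test_that("planted ECoG ground truth follows (factor - 1) * 100 and is reproducible", {
  plan <- tibble::tibble(condition = c("rest", "easy", "hard"),
                         duration_s = c(10, 6, 6), repeats = c(1L, 2L, 2L))
  null_spec <- ecog_sim_spec(trial_plan = plan, rng_seed = 5)
  sim <- simulate_ecog(null_spec)
  expect_true(all(sim$ground_truth$psc_true == 0))
  spec2 <- ecog_sim_spec(trial_plan = plan, hard_factor = 2, rng_seed = 5)
  gt2 <- simulate_ecog(spec2)$ground_truth
  expect_true(all(gt2$psc_true[gt2$contrast == "hard_gt_easy"] == 100))
  expect_true(all(gt2$psc_true[gt2$contrast == "easy_gt_rest"] == 0))
  # same spec + seed -> bit-identical recording
  again <- simulate_ecog(null_spec)
  expect_identical(again$recording$samples, sim$recording$samples)
  expect_identical(again$recording$markers, sim$recording$markers)
})

test_that("BOLD tumour coupling reproduces the closed-form attenuation", {
  w <- 0.6; sig <- 1
  spec <- bold_sim_spec(coupling = c(w, rep(0, 6)), noise_sd = sig,
                        tumour_radius_vox = 4, tumour_centre = c(7, 7, 7),
                        rng_seed = 11)
  sim <- simulate_bold(spec)
  g <- spec$grid_shape
  flat <- matrix(sim$bold$data, prod(g), spec$n_volumes)
  tum <- which(sim$masks$tumour$data != 0, arr.ind = TRUE)
  expect_gt(nrow(tum), 100)
  lin <- (tum[, 3] - 1) * g[1] * g[2] + (tum[, 2] - 1) * g[1] + tum[, 1]
  r_obs <- as.numeric(cor(t(flat[lin, ]), sim$courses[, 1]))
  r_theory <- w / sqrt(w^2 + sig^2)
  expect_lt(abs(mean(r_obs) - r_theory), 0.05)
  expect_equal(unique(sim$ground_truth$r_true[sim$ground_truth$network == 1]),
               r_theory, tolerance = 1e-12)
  # null coupling: mean tumour-course correlation near zero
  sim0 <- simulate_bold(bold_sim_spec(rng_seed = 12))
  flat0 <- matrix(sim0$bold$data, prod(g), 200)
  tum0 <- which(sim0$masks$tumour$data != 0)
  r0 <- as.numeric(cor(t(flat0[tum0, ]), sim0$courses[, 1]))
  expect_lt(abs(mean(r0)), 3 / sqrt(200))
  # noiseless, full coupling: sample r is exactly 1
  sim1 <- simulate_bold(bold_sim_spec(coupling = c(1, rep(0, 6)),
                                      noise_sd = 0, rng_seed = 13))
  flat1 <- matrix(sim1$bold$data, prod(g), 200)
  tum1 <- which(sim1$masks$tumour$data != 0)
  r1 <- as.numeric(cor(t(flat1[tum1, ]), sim1$courses[, 1]))
  expect_true(all(abs(r1 - 1) < 1e-10))
  # tumour outside the grid is a range error
  expect_error(bold_sim_spec(tumour_centre = c(1, 1, 1)),
               class = "glio_range_error")
})

test_that("icosphere has the expected combinatorics and unit vertices", {
  m0 <- make_icosphere(0)
  expect_equal(nrow(m0$vertices), 12)
  expect_equal(nrow(m0$faces), 20)
  m2 <- make_icosphere(2)
  expect_equal(nrow(m2$vertices), 162)       # 10 * 4^2 + 2
  expect_equal(nrow(m2$faces), 20 * 16)
  expect_true(all(abs(sqrt(rowSums(m2$vertices^2)) - 1) < 1e-9))
  # Euler characteristic of a sphere: V - E + F = 2 (E = 3F/2)
  expect_equal(nrow(m2$vertices) - 3 * nrow(m2$faces) / 2 + nrow(m2$faces), 2)
})

test_that("random parcellations are non-empty, contiguous and reproducible", {
  mesh <- make_icosphere(3)
  labels <- make_parcellation(mesh, 7, rng_seed = 3)
  expect_equal(sort(unique(labels)), 1:7)
  # contiguity by breadth-first search over the mesh adjacency graph
  adj <- gliocircuit:::mesh_adjacency(mesh)
  for (k in 1:7) {
    members <- which(labels == k)
    seen <- members[1]; frontier <- members[1]
    while (length(frontier)) {
      nxt <- setdiff(intersect(unlist(adj[frontier]), members), seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    expect_setequal(seen, members)
  }
  expect_identical(make_parcellation(mesh, 7, rng_seed = 3), labels)
  expect_true(all(make_parcellation(mesh, 1) == 1L))
})

test_that("cohort generator honours planted coefficients and missingness", {
  # planted connectivity coefficient recovered at large n, small noise
  co <- simulate_cohort(cohort_sim_spec(n_patients = 200,
                                        coefs = c(conn = 1.0),
                                        residual_sd = 0.1, rng_seed = 21))
  est <- tidy(fit_outcome_model(co))
  slope <- est$estimate[est$term == "tumour_network_connectivity"]
  expect_lt(abs(slope - 1.0), 0.1)
  # missingness flags empty follow-up cells
  com <- simulate_cohort(cohort_sim_spec(n_patients = 50, missing_frac = 0.3,
                                         rng_seed = 22))
  expect_gt(sum(is.na(com$followup_score)), 0)
  expect_true(all(!is.na(com$preop_score)))
  # all-zero coefficients: connectivity CI covers 0 in >= 90% of replicates
  cover <- 0
  for (i in 1:100) {
    c0 <- simulate_cohort(cohort_sim_spec(n_patients = 40,
                                          coefs = c(intercept = 0),
                                          residual_sd = 1, rng_seed = 100 + i))
    td <- tidy(fit_outcome_model(c0))
    row <- td[td$term == "tumour_network_connectivity", ]
    tq <- qt(0.975, df = 40 - nrow(td))
    if (abs(row$estimate) < tq * row$se) cover <- cover + 1
  }
  expect_gte(cover, 90)
})
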