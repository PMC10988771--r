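mask_from_voxels <- function(vox1, g = c(10, 10, 10), affine = diag(4)) {
  a <- array(0, g); a[vox1] <- 1
  glio_volume(a, affine)
}

test_that("electrode snapping is nearest-neighbour with the 10 mm tie rule", {
  msk <- mask_from_voxels(rbind(c(3, 3, 3)))
  hit <- snap_electrode_to_cortex(c(2, 2, 2), msk)
  expect_equal(unname(hit$world), c(2, 2, 2))   # already on the voxel centre
  expect_equal(unname(hit$voxel), c(2, 2, 2))   # 0-based index
  # two candidates equidistant from the coordinate; the neighbour electrode
  # at 10 mm from one of them decides
  msk2 <- mask_from_voxels(rbind(c(1, 5, 5), c(9, 5, 5)))  # world x = 0 and 8
  hit2 <- snap_electrode_to_cortex(c(4, 4, 4), msk2,
                                   neighbours_mm = list(c(0, 4, 14)))
  # candidate (0,4,4): 10 mm from neighbour; candidate (8,4,4): 12.8 mm
  expect_equal(unname(hit2$world), c(0, 4, 4))
  expect_error(snap_electrode_to_cortex(c(0, 0, 0), glio_volume(array(0, c(3, 3, 3)))),
               class = "glio_argument_error")
  expect_warning(snap_electrode_to_cortex(c(50, 50, 50), msk), "mm")
})

test_that("seed spheres match the brute-force lattice count and respect the mask", {
  g <- c(11, 11, 11)
  paren <- glio_volume(array(1, g), diag(4))
  centre <- c(5, 5, 5)                     # world mm of voxel (6,6,6)
  sph <- make_seed(centre, 2.5, paren)
  # independent enumeration of lattice offsets with |v| <= 2.5
  off <- as.matrix(expand.grid(-3:3, -3:3, -3:3))
  expect_equal(nrow(sph$idx1), sum(rowSums(off^2) <= 2.5^2))   # 81
  # half-space mask keeps only in-mask voxels
  half <- array(1, g); half[1:6, , ] <- 0
  sph2 <- make_seed(centre, 2.5, glio_volume(half, diag(4)))
  expect_true(all(sph2$idx1[, 1] >= 7))
  expect_lt(nrow(sph2$idx1), nrow(sph$idx1))
  # sub-voxel radius keeps a single voxel
  expect_equal(nrow(make_seed(centre, 0.4, paren)$idx1), 1)
  expect_error(make_seed(c(500, 0, 0), 2.5, paren), class = "glio_argument_error")
})

test_that("seed FC maps give exact Fisher z values and clip r = 1", {
  set.seed(5)
  g <- c(8, 8, 8); TT <- 201
  paren <- glio_volume(array(1, g), diag(4))
  dat <- array(rnorm(prod(g) * TT), c(g, TT))
  # seed at a single voxel; engineer one voxel with exact r = 0.5
  seed_vox <- c(2, 2, 2); probe <- c(6, 6, 6)
  s <- dat[seed_vox[1], seed_vox[2], seed_vox[3], ]
  e <- rnorm(TT); e <- resid(lm(e ~ s)); e <- e / sd(e)
  zs <- (s - mean(s)) / sd(s)
  dat[probe[1], probe[2], probe[3], ] <- 0.5 * zs + sqrt(0.75) * e
  bold <- glio_volume(dat, diag(4))
  sph <- make_seed(seed_vox - 1, 0.4, paren)   # world = voxel - 1 here
  cmap <- seed_fc_map(bold, sph, paren, fwhm_mm = 0)
  expect_equal(cmap$z[probe[1], probe[2], probe[3]], atanh(0.5),
               tolerance = 1e-6)
  # the seed voxel correlates perfectly with itself: clipped, finite
  expect_equal(cmap$z[seed_vox[1], seed_vox[2], seed_vox[3]],
               atanh(1 - 1e-7), tolerance = 1e-6)
  expect_true(all(is.finite(cmap$z[paren$data != 0])))
  # null voxels: |z| < 0.25 for at least 95% (sd ~ 1/sqrt(TT-3))
  zq <- cmap$z[paren$data != 0]
  expect_gt(mean(abs(zq) < 0.25), 0.95)
})

test_that("FC values at a world coordinate are invariant to voxel storage order", {
  set.seed(6)
  g <- c(8, 8, 8); TT <- 60
  dat <- array(rnorm(prod(g) * TT), c(g, TT))
  paren <- glio_volume(array(1, g), diag(4))
  bold <- glio_volume(dat, diag(4))
  sph <- make_seed(c(3, 3, 3), 1.2, paren)
  z1 <- seed_fc_map(bold, sph, paren, fwhm_mm = 0)$z
  # permute storage so array axis 1 <-> 2; adjust the affine accordingly
  perm <- c(2, 1, 3)
  P <- rbind(c(0, 1, 0, 0), c(1, 0, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1))
  bold2 <- glio_volume(aperm(dat, c(perm, 4)), diag(4) %*% P)
  paren2 <- glio_volume(aperm(paren$data, perm), diag(4) %*% P)
  sph2 <- make_seed(c(3, 3, 3), 1.2, paren2)
  z2 <- seed_fc_map(bold2, sph2, paren2, fwhm_mm = 0)$z
  expect_equal(aperm(z2, perm), z1, tolerance = 1e-10)
})

test_that("masked smoothing roughly preserves the parenchyma mean", {
  set.seed(7)
  sim <- simulate_bold(bold_sim_spec(coupling = c(0.5, rep(0, 6)),
                                     rng_seed = 51))
  ctr <- voxel_to_world(sim$bold$affine, matrix(c(9, 9, 9), 1))
  sph <- make_seed(ctr, 2.5, sim$masks$parenchyma)
  m0 <- seed_fc_map(sim$bold, sph, sim$masks$parenchyma, fwhm_mm = 0)
  m5 <- seed_fc_map(sim$bold, sph, sim$masks$parenchyma, fwhm_mm = 5)
  p <- sim$masks$parenchyma$data != 0
  expect_lt(abs(mean(m5$z[p]) - mean(m0$z[p])) / max(abs(mean(m0$z[p])), 0.01),
            0.25)
  # smoothing shrinks extremes but keeps the map finite
  expect_true(all(is.finite(m5$z[p])))
  expect_lt(max(m5$z[p]), max(m0$z[p]) + 1e-9)
})

test_that("volume-to-surface projection is nearest-voxel with a distance bound", {
  g <- c(8, 8, 8)
  zarr <- array(NA_real_, g)
  paren <- array(0, g); paren[2:7, 2:7, 2:7] <- 1
  zarr[paren == 1] <- 0.7
  cmap <- structure(list(z = zarr, affine = diag(4), parenchyma = paren == 1,
                         n_zero_variance = 0L, provenance = "fixture"),
                    class = "connectivity_map")
  mesh <- make_icosphere(1)
  vc <- sweep(mesh$vertices * 2, 2, c(4, 4, 4), "+")  # sphere inside the cube
  sm <- volume_to_surface(cmap, vc)
  expect_true(all(sm$valid))
  expect_true(all(sm$values == 0.7))        # constant map -> constant surface
  # a vertex exactly at a voxel centre takes that voxel's value
  zarr2 <- zarr; zarr2[4, 4, 4] <- -1.5
  cmap$z <- zarr2
  vc2 <- rbind(c(3, 3, 3), vc[-1, ])        # world (3,3,3) = voxel (4,4,4)
  sm2 <- volume_to_surface(cmap, vc2)
  expect_equal(sm2$values[1], -1.5)
  # far vertices are masked invalid
  vc3 <- rbind(c(80, 80, 80), vc[-1, ])
  sm3 <- volume_to_surface(cmap, vc3)
  expect_false(sm3$valid[1])
  expect_error(volume_to_surface(cmap, matrix(100, 4, 3)),
               class = "glio_argument_error")
})

test_that("tumour-network statistic excludes overlap and controls FWER", {
  # noiseless full coupling: every voxel survives with r = 1
  sim1 <- simulate_bold(bold_sim_spec(coupling = c(1, rep(0, 6)),
                                      noise_sd = 0, rng_seed = 61))
  net1 <- glio_volume((sim1$masks$network$data == 1) * 1, sim1$bold$affine)
  tn1 <- tumour_network_connectivity(sim1$bold, sim1$masks$tumour, net1)
  expect_equal(tn1$n_survivors, tn1$n_tested)
  expect_equal(tn1$mean_connectivity, 1, tolerance = 1e-6)
  # null coupling: Bonferroni yields no survivors in this run
  sim0 <- simulate_bold(bold_sim_spec(rng_seed = 62))
  net0 <- glio_volume((sim0$masks$network$data == 1) * 1, sim0$bold$affine)
  tn0 <- tumour_network_connectivity(sim0$bold, sim0$masks$tumour, net0)
  expect_equal(tn0$n_survivors, 0)
  expect_true(is.na(tn0$mean_connectivity))
  # survivor set shrinks weakly as alpha decreases
  simw <- simulate_bold(bold_sim_spec(coupling = c(0.35, rep(0, 6)),
                                      rng_seed = 63))
  netw <- glio_volume((simw$masks$network$data == 1) * 1, simw$bold$affine)
  n_surv <- vapply(c(0.2, 0.05, 0.01, 0.001), function(a)
    tumour_network_connectivity(simw$bold, simw$masks$tumour, netw, a)$n_survivors,
    numeric(1))
  expect_true(all(diff(n_surv) <= 0))
  # tumour fully inside the network mask -> overlap-exclusion error
  tum_in_net <- glio_volume((simw$masks$network$data == 1) * 1, simw$bold$affine)
  expect_error(tumour_network_connectivity(simw$bold, tum_in_net, netw),
               "overlap", class = "glio_argument_error")
})
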