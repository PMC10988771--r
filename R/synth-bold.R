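#' Specification for a synthetic resting-state BOLD volume
#'
#' Voxel timeseries are generated as loadings on K latent network
#' timecourses plus white noise: networks partition the parenchyma (minus
#' the tumour) into contiguous cells, each cell's voxels loading 1.0 on its
#' own unit-variance course. Tumour voxels couple to the networks through
#' the `coupling` weights: ts = sum_k w_k course_k + noise_sd * eps, so the
#' population correlation of a tumour voxel with course k has the closed
#' form w_k / sqrt(sum_j w_j^2 + noise_sd^2). The grid is deliberately small
#' (desk scale); the real acquisition is emulated in structure, not size.
#'
#' @param grid_shape Integer length-3 voxel grid.
#' @param voxel_mm Isotropic voxel size in mm (sets the affine).
#' @param tr_s Repetition time in seconds (metadata only).
#' @param n_volumes Number of timepoints.
#' @param n_networks K, number of latent networks.
#' @param noise_sd Voxel noise standard deviation (courses have unit sd).
#' @param tumour_centre 1-based voxel coordinates of the tumour ball centre.
#' @param tumour_radius_vox Tumour ball radius in voxels.
#' @param coupling Numeric length-K weights in [0, 1]: coupling of every
#'   tumour voxel to each network course.
#' @param rng_seed Integer seed.
#' @return A `bold_sim_spec`.
#' @export
bold_sim_spec <- function(grid_shape = c(20, 20, 20), voxel_mm = 2,
                          tr_s = 1.06, n_volumes = 200, n_networks = 7,
                          noise_sd = 1,
                          tumour_centre = c(6, 6, 6), tumour_radius_vox = 3,
                          coupling = rep(0, n_networks), rng_seed = 1L) {
  stopifnot(length(grid_shape) == 3, n_volumes >= 4, n_networks >= 1)
  if (any(coupling < 0) || any(coupling > 1))
    abort("coupling weights must lie in [0, 1]", class = "glio_argument_error")
  if (any(tumour_centre - tumour_radius_vox < 1) ||
      any(tumour_centre + tumour_radius_vox > grid_shape))
    abort("tumour mask outside grid", class = "glio_range_error")
  structure(list(grid_shape = as.integer(grid_shape), voxel_mm = voxel_mm,
                 tr_s = tr_s, n_volumes = as.integer(n_volumes),
                 n_networks = as.integer(n_networks), noise_sd = noise_sd,
                 tumour_centre = tumour_centre,
                 tumour_radius_vox = tumour_radius_vox,
                 coupling = rep_len(coupling, n_networks),
                 rng_seed = as.integer(rng_seed)),
            class = "bold_sim_spec")
}

#' Simulate a 4D BOLD volume with latent networks and a coupled tumour
#'
#' @param spec A [bold_sim_spec()].
#' @return A list with `bold` (4D [glio_volume()]), `masks` (list of 3D
#'   volumes: `parenchyma`, `tumour`, `network` where network voxels carry
#'   labels 1..K), `courses` (n_volumes x K matrix of latent timecourses)
#'   and `ground_truth` (tibble: per tumour voxel and network, the planted
#'   coupling `w` and population correlation `r_true`).
#' @export
simulate_bold <- function(spec) {
  stopifnot(inherits(spec, "bold_sim_spec"))
  set.seed(spec$rng_seed)
  g <- spec$grid_shape; K <- spec$n_networks; TT <- spec$n_volumes
  affine <- diag(c(rep(spec$voxel_mm, 3), 1))

  idx <- as.matrix(expand.grid(i = seq_len(g[1]), j = seq_len(g[2]),
                               k = seq_len(g[3])))
  centre <- (g + 1) / 2
  # parenchyma: inscribed ellipsoid, the usual brain-in-box stand-in
  inside <- rowSums(sweep(idx, 2, centre)^2 / ((g / 2)^2)) <= 1
  parenchyma <- array(FALSE, g); parenchyma[idx[inside, , drop = FALSE]] <- TRUE

  tum_d2 <- rowSums(sweep(idx, 2, spec$tumour_centre)^2)
  tumour <- array(FALSE, g)
  tumour[idx[tum_d2 <= spec$tumour_radius_vox^2, , drop = FALSE]] <- TRUE
  tumour <- tumour & parenchyma

  # contiguous network cells: Voronoi partition of parenchyma-minus-tumour
  healthy_idx <- idx[inside & !tumour[idx], , drop = FALSE]
  seeds <- healthy_idx[sample.int(nrow(healthy_idx), K), , drop = FALSE]
  d2 <- sapply(seq_len(K), function(k) rowSums(sweep(healthy_idx, 2, seeds[k, ])^2))
  lab <- max.col(-d2, ties.method = "first")
  network <- array(0L, g); network[healthy_idx] <- lab

  courses <- matrix(stats::rnorm(TT * K), TT, K)
  courses <- scale(courses)          # unit sample sd, zero mean

  dat <- array(stats::rnorm(prod(g) * TT, sd = spec$noise_sd), c(g, TT))
  flat <- matrix(dat, prod(g), TT)
  vox_lin <- function(sub) (sub[, 3] - 1) * g[1] * g[2] + (sub[, 2] - 1) * g[1] + sub[, 1]
  for (k in seq_len(K)) {
    lin <- vox_lin(healthy_idx[lab == k, , drop = FALSE])
    flat[lin, ] <- flat[lin, ] + matrix(courses[, k], length(lin), TT, byrow = TRUE)
  }
  tum_sub <- which(tumour, arr.ind = TRUE)
  if (nrow(tum_sub)) {
    mix <- courses %*% spec$coupling
    lin <- vox_lin(tum_sub)
    flat[lin, ] <- flat[lin, ] + matrix(mix, length(lin), TT, byrow = TRUE)
  }
  dat <- array(flat, c(g, TT))

  denom <- sqrt(sum(spec$coupling^2) + spec$noise_sd^2)
  gt <- tidyr::expand_grid(voxel = seq_len(nrow(tum_sub)),
                           network = seq_len(K)) |>
    mutate(i = tum_sub[.data$voxel, 1], j = tum_sub[.data$voxel, 2],
           k = tum_sub[.data$voxel, 3],
           w = spec$coupling[.data$network],
           r_true = if (denom > 0) .data$w / denom else 0)

  list(bold = glio_volume(dat, affine),
       masks = list(parenchyma = glio_volume(parenchyma * 1, affine),
                    tumour = glio_volume(tumour * 1, affine),
                    network = glio_volume(network, affine)),
       courses = courses,
       ground_truth = gt)
}
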