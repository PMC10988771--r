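#' Snap an electrode coordinate to the nearest cortex/tumour voxel
#'
#' Returns the mask voxel minimising Euclidean distance (world mm) to the
#' recorded coordinate, so that seeds placed around electrode locations
#' sample cortical tissue. Among candidates equidistant at voxel precision,
#' the voxel whose distances to already-snapped neighbouring electrodes are
#' closest to the 10 mm centre-to-centre strip spacing (minimal
#' sum |d - 10|) is chosen. Coordinates farther than `max_dist_mm` from any
#' mask voxel are snapped with a warning.
#'
#' @param coord_mm Length-3 world coordinate in mm.
#' @param mask A 3D [glio_volume()], nonzero over grey matter / tumour.
#' @param neighbours_mm Optional list/matrix of already-snapped neighbour
#'   coordinates (mm) used by the spacing tie-break.
#' @param spacing_mm Nominal electrode spacing (mm).
#' @param max_dist_mm Distance beyond which a warning is raised.
#' @param tie_tol_mm Distances within this of the minimum count as tied.
#' @return A list: `world` (snapped mm coordinate), `voxel` (0-based index),
#'   `dist_mm`.
#' @export
snap_electrode_to_cortex <- function(coord_mm, mask, neighbours_mm = NULL,
                                     spacing_mm = 10, max_dist_mm = 20,
                                     tie_tol_mm = 1e-6) {
  xyz <- mask_world_coords(mask$data, mask$affine)
  if (!nrow(xyz)) abort("mask is empty", class = "glio_argument_error")
  d <- sqrt(colSums((t(xyz) - as.numeric(coord_mm))^2))
  dmin <- min(d)
  if (dmin > max_dist_mm)
    warn(sprintf("electrode is %.1f mm from the nearest mask voxel", dmin))
  cand <- which(d - dmin <= tie_tol_mm)
  if (length(cand) > 1 && !is.null(neighbours_mm)) {
    nb <- matrix(unlist(neighbours_mm), ncol = 3, byrow = is.list(neighbours_mm))
    cost <- vapply(cand, function(ci) {
      sum(abs(sqrt(rowSums((nb - matrix(xyz[ci, ], nrow(nb), 3,
                                        byrow = TRUE))^2)) - spacing_mm))
    }, numeric(1))
    cand <- cand[which.min(cost)]
  } else cand <- cand[1]
  list(world = xyz[cand, ], voxel = attr(xyz, "idx1")[cand, ] - 1L,
       dist_mm = dmin)
}

#' Build a parenchyma-masked seed sphere
#'
#' Voxels whose centres lie within `radius_mm` of the seed centre,
#' intersected with the parenchyma mask, so the seed covers only brain
#' tissue.
#'
#' @param centre_mm Length-3 world coordinate of the sphere centre (mm).
#' @param radius_mm Sphere radius in mm.
#' @param parenchyma 3D [glio_volume()] parenchyma mask.
#' @return A `seed_sphere`: list with `centre_mm`, `radius_mm`, `idx1`
#'   (n x 3 1-based voxel indices), `world` (n x 3 mm).
#' @export
make_seed <- function(centre_mm, radius_mm, parenchyma) {
  stopifnot(radius_mm > 0)
  xyz <- mask_world_coords(parenchyma$data, parenchyma$affine)
  d2 <- colSums((t(xyz) - as.numeric(centre_mm))^2)
  keep <- d2 <= radius_mm^2
  if (!any(keep))
    abort("seed sphere contains no parenchyma voxels",
          class = "glio_argument_error")
  structure(list(centre_mm = as.numeric(centre_mm), radius_mm = radius_mm,
                 idx1 = attr(xyz, "idx1")[keep, , drop = FALSE],
                 world = xyz[keep, , drop = FALSE]),
            class = "seed_sphere")
}

lin_index <- function(idx1, g) {
  (idx1[, 3] - 1) * g[1] * g[2] + (idx1[, 2] - 1) * g[1] + idx1[, 1]
}

# separable Gaussian convolution of a 3D array (zero padding at edges)
gauss_smooth3d <- function(arr, sigma_vox) {
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    hw <- max(1L, ceiling(3 * s))
    k <- exp(-((-hw:hw)^2) / (2 * s^2)); k <- k / sum(k)
    arr <- conv_along(arr, k, axis)
  }
  arr
}

conv_along <- function(arr, k, axis) {
  d <- dim(arr); hw <- (length(k) - 1) / 2
  perm <- switch(axis, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
  a <- aperm(arr, perm)
  m <- matrix(a, dim(a)[1], prod(dim(a)[-1]))
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  mp <- rbind(matrix(0, hw, ncol(m)), m, matrix(0, hw, ncol(m)))
  for (o in seq_along(k))
    out <- out + k[o] * mp[(o):(o + n - 1), , drop = FALSE]
  a <- array(out, dim(a))
  aperm(a, order(perm))
}

#' Seed-based functional connectivity map
#'
#' Correlates the mean BOLD timeseries over the seed with every parenchyma
#' voxel (Pearson), applies the Fisher r-to-z transform (r clipped to
#' +/-(1 - 1e-7) so the map is finite), and smooths with a Gaussian kernel
#' of the given FWHM using masked normalised convolution so values outside
#' the parenchyma never bleed in.
#'
#' @param bold 4D [glio_volume()].
#' @param seed A [make_seed()] sphere.
#' @param parenchyma 3D parenchyma mask volume.
#' @param fwhm_mm Smoothing FWHM in mm (0 disables smoothing).
#' @return A `connectivity_map`: list with `z` (3D array, NA outside
#'   parenchyma), `affine`, `parenchyma`, `n_zero_variance` and provenance.
#' @export
seed_fc_map <- function(bold, seed, parenchyma, fwhm_mm = 5) {
  g <- dim(bold$data)[1:3]; TT <- dim(bold$data)[4]
  if (is.na(TT) || TT < 3) abort("need >= 3 timepoints", class = "glio_argument_error")
  flat <- matrix(bold$data, prod(g), TT)
  seed_ts <- colMeans(flat[lin_index(seed$idx1, g), , drop = FALSE])
  pidx <- which(parenchyma$data != 0, arr.ind = TRUE)
  plin <- lin_index(pidx, g)
  X <- flat[plin, , drop = FALSE]
  xc <- X - rowMeans(X)
  sc <- seed_ts - mean(seed_ts)
  denom <- sqrt(rowSums(xc^2) * sum(sc^2))
  zero_var <- denom == 0
  r <- numeric(length(denom))
  r[!zero_var] <- (xc %*% sc)[!zero_var] / denom[!zero_var]
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  zarr <- array(NA_real_, g)
  zarr[pidx] <- z
  if (fwhm_mm > 0) {
    sp <- sqrt(colSums(bold$affine[1:3, 1:3]^2))
    sigma <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / sp
    m <- array(0, g); m[pidx] <- 1
    zz <- zarr; zz[is.na(zz)] <- 0
    num <- gauss_smooth3d(zz * m, sigma)
    den <- gauss_smooth3d(m, sigma)
    sm <- array(NA_real_, g)
    sm[pidx] <- num[pidx] / den[pidx]
    zarr <- sm
  }
  structure(list(z = zarr, affine = bold$affine,
                 parenchyma = parenchyma$data != 0,
                 n_zero_variance = sum(zero_var),
                 provenance = sprintf("seed_fc_map fwhm=%gmm", fwhm_mm)),
            class = "connectivity_map")
}

#' Project a volumetric map onto surface vertices
#'
#' Each vertex takes the value of its nearest in-parenchyma voxel centre
#' (world mm) within `bound_mm`; vertices with no voxel in range are masked
#' invalid.
#'
#' @param cmap A `connectivity_map` from [seed_fc_map()].
#' @param vertex_coords_mm n x 3 matrix of vertex world coordinates.
#' @param bound_mm Maximum vertex-to-voxel distance.
#' @return A [surface_map()].
#' @export
volume_to_surface <- function(cmap, vertex_coords_mm, bound_mm = 3) {
  pidx <- which(cmap$parenchyma & !is.na(cmap$z), arr.ind = TRUE)
  xyz <- voxel_to_world(cmap$affine, pidx - 1)
  vals <- cmap$z[pidx]
  V <- matrix(as.numeric(vertex_coords_mm), ncol = 3)
  nn <- integer(nrow(V)); nd <- numeric(nrow(V))
  # chunked brute-force nearest neighbour
  step <- 2000L
  for (a in seq(1, nrow(V), by = step)) {
    b <- min(a + step - 1L, nrow(V))
    d2 <- outer(rowSums(V[a:b, , drop = FALSE]^2), rowSums(xyz^2), "+") -
      2 * V[a:b, , drop = FALSE] %*% t(xyz)
    nn[a:b] <- max.col(-d2, ties.method = "first")
    nd[a:b] <- sqrt(pmax(d2[cbind(seq_len(b - a + 1), nn[a:b])], 0))
  }
  valid <- nd <= bound_mm
  if (!any(valid)) abort("no vertex lies within the distance bound of parenchyma",
                         class = "glio_argument_error")
  out <- rep(NA_real_, nrow(V))
  out[valid] <- vals[nn[valid]]
  surface_map(out, valid)
}

#' Tumour-network connectivity with Bonferroni FWER thresholding
#'
#' Correlates each tumour voxel's timeseries with the mean timeseries of a
#' network mask (voxels where tumour and network overlap are excluded and
#' their count reported as a covariate), derives two-sided p-values from
#' the exact t transform `t = r * sqrt((n-2)/(1-r^2))`, keeps voxels with
#' `p < alpha_fwer / m` (Bonferroni over the m tested voxels), and reports
#' the mean correlation over surviving voxels.
#'
#' @param bold 4D [glio_volume()].
#' @param tumour_mask,network_mask 3D mask volumes.
#' @param alpha_fwer Family-wise error level.
#' @return A `tumour_network_result`: list with `voxels` (tibble of per-voxel
#'   r, p, survived), `mean_connectivity` (NA if no survivors),
#'   `n_survivors`, `n_tested`, `n_overlap_excluded`.
#' @export
tumour_network_connectivity <- function(bold, tumour_mask, network_mask,
                                        alpha_fwer = 0.05) {
  g <- dim(bold$data)[1:3]; TT <- dim(bold$data)[4]
  if (is.na(TT) || TT < 4) abort("need >= 4 timepoints", class = "glio_argument_error")
  tum <- tumour_mask$data != 0; net <- network_mask$data != 0
  overlap <- tum & net
  test_idx <- which(tum & !overlap, arr.ind = TRUE)
  if (!nrow(test_idx))
    abort("all tumour voxels overlap the network mask; nothing to test after overlap exclusion",
          class = "glio_argument_error")
  flat <- matrix(bold$data, prod(g), TT)
  ref <- colMeans(flat[lin_index(which(net, arr.ind = TRUE), g), , drop = FALSE])
  X <- flat[lin_index(test_idx, g), , drop = FALSE]
  xc <- X - rowMeans(X); rc <- ref - mean(ref)
  denom <- sqrt(rowSums(xc^2) * sum(rc^2))
  r <- ifelse(denom > 0, (xc %*% rc) / denom, 0)
  r <- as.numeric(r)
  tstat <- r * sqrt((TT - 2) / pmax(1 - r^2, 1e-15))
  p <- 2 * pt(abs(tstat), df = TT - 2, lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin)
  m <- length(p)
  survived <- p < alpha_fwer / m
  vox <- tibble(i = test_idx[, 1], j = test_idx[, 2], k = test_idx[, 3],
                r = r, p = p, survived = survived)
  structure(list(voxels = vox,
                 mean_connectivity = if (any(survived)) mean(r[survived]) else NA_real_,
                 n_survivors = sum(survived), n_tested = m,
                 n_overlap_excluded = sum(overlap)),
            class = "tumour_network_result")
}

#' @export
print.tumour_network_result <- function(x, ...) {
  cat(sprintf("<tumour_network_result> %d/%d voxels survive FWER; %d overlap-excluded; mean r = %s\n",
              x$n_survivors, x$n_tested, x$n_overlap_excluded,
              ifelse(is.na(x$mean_connectivity), "NA",
                     sprintf("%.3f", x$mean_connectivity))))
  invisible(x)
}
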