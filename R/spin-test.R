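#' Per-network median of a surface map
#'
#' @param map A [surface_map()].
#' @param labels Integer parcellation labels (0 = unassigned, excluded).
#' @return Named numeric of medians over valid vertices per network; NA for
#'   a network with no valid vertex.
#' @export
network_medians <- function(map, labels) {
  stopifnot(length(labels) == length(map$values))
  ks <- sort(unique(labels[labels > 0]))
  vapply(ks, function(k) {
    v <- map$values[labels == k & map$valid]
    if (!length(v)) NA_real_ else median(v)
  }, numeric(1)) |> setNames(as.character(ks))
}

#' Uniform random 3D rotation
#'
#' Drawn uniformly on SO(3) via a uniform unit quaternion (4 iid normals,
#' normalised); the returned matrix is orthogonal with determinant +1.
#'
#' @return A 3 x 3 rotation matrix.
#' @export
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Spin surrogate of a surface map
#'
#' The surrogate value at vertex v is the original value at the vertex
#' nearest to R v (nearest neighbour on the sphere, i.e. maximal dot
#' product). If that nearest pre-image vertex is invalid, v becomes invalid
#' in the surrogate. Parcel labels are never rotated -- only the map moves.
#'
#' @param map A [surface_map()].
#' @param mesh A unit-sphere [surface_mesh()].
#' @param rotation A 3 x 3 rotation matrix.
#' @return A [surface_map()].
#' @export
spin_surrogate <- function(map, mesh, rotation) {
  nn <- spin_nn(mesh$vertices, rotation)
  surface_map(map$values[nn], map$valid[nn])
}

spin_nn <- function(V, rotation) {
  W <- V %*% t(rotation)          # rotated vertex positions
  max.col(W %*% t(V), ties.method = "first")
}

#' Spin permutation test for network co-localisation
#'
#' Compares each network's observed median map value against the null
#' distribution of medians from spatially rotated surrogate maps. Rotation
#' preserves the spatial autocorrelation of the map while breaking its
#' alignment with the parcellation. The two-tailed p-value is
#' `2 * min(#{null <= obs} + 1, #{null >= obs} + 1) / (n_valid + 1)`,
#' capped at 1; a network is flagged over-represented (`direction =
#' "over"`) or under-represented when p < alpha, by the smaller tail.
#' Surrogates in which a network retains no valid vertex contribute no null
#' draw for that network.
#'
#' @param map A [surface_map()].
#' @param labels Integer parcellation labels.
#' @param mesh Unit-sphere [surface_mesh()].
#' @param n_surrogates Number of random rotations (>= 100).
#' @param rng_seed Integer seed.
#' @param alpha Two-tailed level.
#' @return A tibble (class `spin_test_result`): per network the observed
#'   median, null percentile, two-tailed `p`, `direction`
#'   (over/under/none), and `n_valid_null`.
#' @export
spin_test <- function(map, labels, mesh, n_surrogates = 1000, rng_seed = 1L,
                      alpha = 0.05) {
  if (n_surrogates < 100)
    abort("n_surrogates must be >= 100", class = "glio_argument_error")
  set.seed(rng_seed)
  obs <- network_medians(map, labels)
  ks <- names(obs)
  null_m <- matrix(NA_real_, n_surrogates, length(ks),
                   dimnames = list(NULL, ks))
  for (s in seq_len(n_surrogates)) {
    sur <- spin_surrogate(map, mesh, random_rotation())
    null_m[s, ] <- network_medians(sur, labels)
  }
  out <- list()
  for (k in ks) {
    null_k <- null_m[, k]; null_k <- null_k[!is.na(null_k)]
    nv <- length(null_k)
    if (nv == 0 || is.na(obs[[k]])) {
      out[[k]] <- tibble(network = k, observed_median = obs[[k]],
                         percentile = NA_real_, p = NA_real_,
                         direction = "none", n_valid_null = nv)
      next
    }
    n_le <- sum(null_k <= obs[[k]]); n_ge <- sum(null_k >= obs[[k]])
    degenerate <- all(abs(null_k - null_k[1]) < 1e-15) && obs[[k]] == null_k[1]
    p <- if (degenerate) 1 else min(1, 2 * min(n_le + 1, n_ge + 1) / (nv + 1))
    direction <- if (p < alpha) { if (n_ge < n_le) "over" else "under" } else "none"
    out[[k]] <- tibble(network = k, observed_median = obs[[k]],
                       percentile = 100 * n_le / nv, p = p,
                       direction = direction, n_valid_null = nv)
  }
  res <- bind_rows(out)
  attr(res, "n_surrogates") <- n_surrogates
  class(res) <- c("spin_test_result", class(res))
  res
}
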