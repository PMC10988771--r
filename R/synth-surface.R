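#' Icosphere mesh
#'
#' Unit-sphere triangular mesh built by repeated 4-fold subdivision of a
#' regular icosahedron, the standard stand-in for a spherical cortical
#' registration surface. Vertex count is 10 * 4^s + 2.
#'
#' @param subdivisions Non-negative integer subdivision count.
#' @return A [surface_mesh()] with unit-norm vertices.
#' @export
#' @examples
#' m <- make_icosphere(2)
#' nrow(m$vertices)   # 162
make_icosphere <- function(subdivisions = 3) {
  stopifnot(subdivisions >= 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_mid <- new.env(hash = TRUE)
    nv <- nrow(v)
    verts <- vector("list", 0)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- edge_mid[[key]]
      if (!is.null(hit)) return(hit)
      m <- v[a, ] + v[b, ]
      m <- m / sqrt(sum(m^2))
      verts[[length(verts) + 1]] <<- m
      idx <- nv + length(verts)
      edge_mid[[key]] <- idx
      idx
    }
    newf <- matrix(0L, nrow(f) * 4, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf[(i - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, verts))
    f <- newf
  }
  surface_mesh(v, f)
}

#' Random contiguous parcellation of a sphere mesh
#'
#' Assigns labels 1..K by nearest of K seed vertices drawn at random
#' (geodesic distance approximated by the Euclidean chord, which is monotone
#' in arc length on the unit sphere). The resulting cells are spherical
#' Voronoi regions, hence spatially contiguous on the mesh graph; used as a
#' stand-in for a canonical functional network parcellation.
#'
#' @param mesh A [surface_mesh()] on the unit sphere.
#' @param K Number of parcels (>= 1, <= vertex count).
#' @param rng_seed Integer seed.
#' @param method `"random"` draws the K seed vertices uniformly (parcel
#'   sizes vary, like real functional networks); `"farthest"` uses
#'   farthest-point sampling from a random start, giving K well-separated
#'   seeds and parcels of similar size.
#' @return Integer vector of labels in 1..K, one per vertex.
#' @export
make_parcellation <- function(mesh, K = 7, rng_seed = 1L,
                              method = c("random", "farthest")) {
  method <- match.arg(method)
  nv <- nrow(mesh$vertices)
  stopifnot(K >= 1, K <= nv)
  set.seed(rng_seed)
  if (method == "random") {
    seeds <- sample.int(nv, K)
  } else {
    seeds <- sample.int(nv, 1)
    while (length(seeds) < K) {
      d <- mesh$vertices %*% t(mesh$vertices[seeds, , drop = FALSE])
      seeds <- c(seeds, which.min(apply(d, 1, max)))
    }
  }
  # nearest seed by maximal dot product (equivalent to minimal chord)
  d <- mesh$vertices %*% t(mesh$vertices[seeds, , drop = FALSE])
  labels <- max.col(d, ties.method = "first")
  # every label non-empty by construction (each seed is its own nearest)
  as.integer(labels)
}

# vertex adjacency list from faces (used by tests and parcel audits)
mesh_adjacency <- function(mesh) {
  nv <- nrow(mesh$vertices)
  adj <- vector("list", nv)
  e <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  sp <- split(e[, 2], e[, 1])
  for (nm in names(sp)) adj[[as.integer(nm)]] <- unique(sp[[nm]])
  adj
}
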