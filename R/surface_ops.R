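# Shared computational geometry on the surface mesh: geodesic
# neighbourhoods, tangent-plane gradients of scalar maps, geodesic Gaussian
# smoothing, minima-seeded watershed, and uniform spherical rotations with
# nearest-neighbour resampling.  Medial-wall vertices are excluded from all
# operations and carry NA in scalar outputs / 0 in label outputs.

# CSR adjacency for the C++ primitives (0-based).
mesh_csr <- function(mesh) {
  mesh_cached(mesh, "csr", function() {
    adj <- mesh_adjacency(mesh)
    deg <- lengths(adj)
    list(off = c(0L, cumsum(deg)), nbr = unlist(adj, use.names = FALSE) - 1L)
  })
}

#' Geodesic neighbourhood of a vertex
#'
#' All non-medial-wall vertices within graph-geodesic distance (shortest
#' path over mesh edge lengths) `radius_mm` of `vertex`, including the
#' vertex itself.
#'
#' @param mesh a `surface_mesh`.
#' @param vertex vertex index (1-based).
#' @param radius_mm geodesic radius in mm.
#' @return integer vector of vertex indices.
#' @export
neighborhood <- function(mesh, vertex, radius_mm) {
  if (vertex < 1 || vertex > n_vertices(mesh)) stopf("invalid vertex")
  d <- geodesic_distances(mesh, vertex)[1, ]
  which(d <= radius_mm + 1e-12 & !mesh$medial_wall)
}

# Orthonormal tangent basis (e1, e2) at every vertex of the sphere.
tangent_basis <- function(mesh) {
  mesh_cached(mesh, "tangent", function() {
    n <- mesh$sphere
    a <- matrix(rep(c(1, 0, 0), each = nrow(n)), ncol = 3)
    flip <- abs(n[, 1]) > 0.9
    a[flip, ] <- matrix(rep(c(0, 1, 0), each = sum(flip)), ncol = 3)
    e1 <- cross3(n, a)
    e1 <- e1 / sqrt(rowSums(e1^2))
    e2 <- cross3(n, e1)
    list(e1 = e1, e2 = e2)
  })
}

# Sparse V x V operators (Gx, Gy) whose rows give the tangent-plane
# least-squares slope of a scalar map over the 1-ring; valid[v] FALSE where
# fewer than 3 valid neighbours support the fit.
gradient_operators <- function(mesh) {
  mesh_cached(mesh, "gradops", function() {
    V <- n_vertices(mesh)
    adj <- mesh_adjacency(mesh)
    tb <- tangent_basis(mesh)
    ii <- jj <- vector("list", V)
    gx <- gy <- vector("list", V)
    valid <- rep(FALSE, V)
    for (v in seq_len(V)) {
      if (mesh$medial_wall[v]) next
      nb <- adj[[v]]
      nb <- nb[!mesh$medial_wall[nb]]
      if (length(nb) < 3) next
      d <- mesh$vertices[nb, , drop = FALSE] -
        matrix(mesh$vertices[v, ], length(nb), 3, byrow = TRUE)
      X <- cbind(1, d %*% tb$e1[v, ], d %*% tb$e2[v, ])
      X <- rbind(c(1, 0, 0), X)  # the vertex itself at the origin
      P <- tryCatch(solve(crossprod(X), t(X)), error = function(e) NULL)
      if (is.null(P)) next
      idx <- c(v, nb)
      ii[[v]] <- rep.int(v, length(idx))
      jj[[v]] <- idx
      gx[[v]] <- P[2, ]
      gy[[v]] <- P[3, ]
      valid[v] <- TRUE
    }
    iv <- unlist(ii)
    jv <- unlist(jj)
    Gx <- Matrix::sparseMatrix(i = iv, j = jv, x = unlist(gx), dims = c(V, V))
    Gy <- Matrix::sparseMatrix(i = iv, j = jv, x = unlist(gy), dims = c(V, V))
    list(Gx = Gx, Gy = Gy, valid = valid)
  })
}

#' Gradient magnitude of a scalar map on the mesh
#'
#' Fits a linear function of the two tangent-plane coordinates over each
#' vertex's 1-ring (least squares) and returns the norm of the fitted slope
#' (map units per mm).  Vertices with fewer than 3 valid neighbours, and
#' medial-wall vertices, return NA.
#'
#' @param mesh a `surface_mesh`.
#' @param values numeric per-vertex map (or a V x k matrix of maps).
#' @return per-vertex gradient magnitude, same shape as `values`.
#' @export
gradient_magnitude <- function(mesh, values) {
  ops <- gradient_operators(mesh)
  m <- as.matrix(values)
  m[is.na(m)] <- 0
  m[mesh$medial_wall, ] <- 0
  gx <- as.matrix(ops$Gx %*% m)
  gy <- as.matrix(ops$Gy %*% m)
  out <- sqrt(gx^2 + gy^2)
  out[!ops$valid, ] <- NA_real_
  if (is.matrix(values)) out else out[, 1]
}

# Gaussian smoothing weight matrix at a given FWHM (geodesic, truncated 3
# sigma, rows renormalised over valid neighbours).
smoothing_matrix <- function(mesh, fwhm_mm) {
  key <- sprintf("smooth_%g", fwhm_mm)
  mesh_cached(mesh, key, function() {
    sigma <- fwhm_mm / sqrt(8 * log(2))
    cutoff <- 3 * sigma
    valid <- which(!mesh$medial_wall)
    g <- mesh_graph(mesh)
    d <- igraph::distances(g, v = valid, to = valid, weights = mesh$edge_lengths)
    w <- exp(-d^2 / (2 * sigma^2))
    w[d > cutoff] <- 0
    w <- w / rowSums(w)
    V <- n_vertices(mesh)
    nz <- which(w > 0, arr.ind = TRUE)
    Matrix::sparseMatrix(i = valid[nz[, 1]], j = valid[nz[, 2]],
                         x = w[nz], dims = c(V, V))
  })
}

#' Geodesic Gaussian smoothing of a scalar map
#'
#' Kernel sigma = `fwhm_mm / sqrt(8 ln 2)`, truncated at 3 sigma, weights
#' renormalised to sum to one over valid (non-medial) neighbours, so a
#' constant map is a fixed point.
#'
#' @inheritParams gradient_magnitude
#' @param fwhm_mm kernel full width at half maximum in mm.
#' @return smoothed map, same shape as `values`; NA on the medial wall.
#' @export
smooth_map <- function(mesh, values, fwhm_mm) {
  if (fwhm_mm <= 0) stopf("fwhm_mm must be positive")
  W <- smoothing_matrix(mesh, fwhm_mm)
  m <- as.matrix(values)
  m[is.na(m)] <- 0
  m[mesh$medial_wall, ] <- 0
  out <- as.matrix(W %*% m)
  out[mesh$medial_wall, ] <- NA_real_
  if (is.matrix(values)) out else out[, 1]
}

#' Local minima of a scalar map
#'
#' Vertices whose value is less than or equal to all valid 1-ring
#' neighbours; connected plateaus of equal-valued minima are collapsed to
#' their lowest vertex index.  With `min_depth > 0` the map first passes
#' through an h-minima transform (morphological reconstruction), which
#' fills basins shallower than `min_depth` so only minima of at least
#' that depth survive.
#'
#' @inheritParams gradient_magnitude
#' @param min_depth minimum basin depth (map units; 0 disables pruning).
#' @return sorted integer vector of minimum vertices.
#' @export
local_minima <- function(mesh, values, min_depth = 0) {
  csr <- mesh_csr(mesh)
  v <- as.numeric(values)
  if (min_depth > 0)
    v <- .hminima_cpp(csr$off, csr$nbr, v, mesh$medial_wall, min_depth)
  .local_minima_cpp(csr$off, csr$nbr, v, mesh$medial_wall) + 1L
}

#' h-minima transform of a scalar map
#'
#' Morphological reconstruction by erosion of `values + min_depth` over
#' `values`: basins shallower than `min_depth` relative to their lowest
#' saddle are filled, leaving deeper structure (and value ordering
#' elsewhere) intact.
#'
#' @inheritParams gradient_magnitude
#' @param min_depth basin depth threshold (map units).
#' @return transformed map, same length.
#' @export
hminima <- function(mesh, values, min_depth) {
  csr <- mesh_csr(mesh)
  .hminima_cpp(csr$off, csr$nbr, as.numeric(values), mesh$medial_wall,
               min_depth)
}

#' Minima-seeded watershed segmentation
#'
#' Beucher-style flooding by ascending map value from the seed vertices.
#' A vertex adjacent to two or more distinct basins when it floods becomes
#' a ridge (label 0, `ridge` TRUE).  Vertices above `ceiling` stay
#' unassigned (label 0, not ridge).  Ties break by (value, vertex index),
#' so the result is deterministic; labels depend only on the ordering of
#' map values (invariant under monotone transforms).
#'
#' @inheritParams gradient_magnitude
#' @param seeds integer vector of distinct non-medial seed vertices.
#' @param ceiling optional flooding ceiling (map units); `NULL` floods all.
#' @return list with `labels` (per-vertex int, seed k -> label k, 0 =
#'   ridge/unassigned/medial) and `ridge` (logical per vertex).
#' @export
watershed <- function(mesh, values, seeds, ceiling = NULL) {
  if (length(seeds) == 0) stopf("empty seed set")
  if (anyDuplicated(seeds)) stopf("seeds must be distinct")
  if (any(mesh$medial_wall[seeds])) stopf("seeds must be non-medial vertices")
  csr <- mesh_csr(mesh)
  res <- .watershed_cpp(csr$off, csr$nbr, as.numeric(values),
                        mesh$medial_wall, as.integer(seeds) - 1L,
                        if (is.null(ceiling)) Inf else ceiling)
  res
}

# Uniformly random rotation matrix from a seeded quaternion.
random_rotation_matrix <- function(seed) {
  q <- local_seed(seed, rnorm(4))
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Randomly rotate a surface map or labelling (spin null)
#'
#' Applies a uniform random 3D rotation (seeded quaternion) to the
#' spherical coordinates and resamples the payload by nearest neighbour:
#' each destination vertex takes the value of the nearest source vertex
#' under the inverse rotation.  Destination vertices whose source lands on
#' the medial wall are invalid (NA for numeric maps, 0 for integer
#' labels); medial-wall destinations are likewise invalid.  The set of
#' invalid destinations is attached as `attr(, "invalid")`.
#'
#' @param mesh a `surface_mesh` with spherical coordinates.
#' @param payload numeric per-vertex map, or integer per-vertex labels.
#' @param seed integer seed for the quaternion.
#' @param rotation optional fixed 3 x 3 rotation matrix (overrides `seed`).
#' @return rotated payload, same length/type, with attribute `invalid`.
#' @export
random_rotation <- function(mesh, payload, seed = 1L, rotation = NULL) {
  R <- if (is.null(rotation)) random_rotation_matrix(seed) else rotation
  # destination vertex d receives the payload of the source vertex nearest
  # to R^T p_d  (equivalently, source points are rotated by R onto d)
  src_pos <- mesh$sphere %*% R
  idx <- max.col(src_pos %*% t(mesh$sphere), ties.method = "first")
  out <- payload[idx]
  invalid <- mesh$medial_wall[idx] | mesh$medial_wall
  if (is.double(payload)) out[invalid] <- NA_real_ else out[invalid] <- 0L
  attr(out, "invalid") <- which(invalid)
  attr(out, "source_index") <- idx
  out
}
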