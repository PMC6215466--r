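# Discrete parcels from a cohort boundary map: thresholded minima-seeded
# watershed, plus parcel descriptive statistics.

#' Parcellate a boundary map
#'
#' `threshold_q` is the fraction of strongest boundary values treated as
#' boundary and excluded from flooding: the flooding ceiling is the
#' `1 - threshold_q` quantile of the boundary values over non-medial
#' vertices.  The default 35% is the operating point balancing over-
#' against under-segmentation (lower thresholds leave more floodable
#' surface and seeds, giving over-segmented maps; higher thresholds
#' drop weak borders and under-segment).  Seeds are the local minima of
#' the (optionally pre-smoothed, depth-pruned) boundary map among
#' below-ceiling vertices; minima within `dedup_mm` geodesic distance of
#' a stronger (lower-valued) minimum are merged.  Vertices above the
#' ceiling, ridge vertices, and single-vertex parcels are left
#' unassigned (label 0); every parcel is a connected component; labels
#' are assigned in seed vertex order, so identical inputs give identical
#' labels.
#'
#' @param boundary a `boundary_map` (or numeric per-vertex map).
#' @param mesh a `surface_mesh`.
#' @param threshold_q fraction of strongest boundary values excluded from
#'   flooding, in (0, 1); default 0.35.
#' @param dedup_mm seed de-duplication radius (default 3 mm).
#' @param min_depth_frac h-minima depth for seeding/flooding, as a
#'   fraction of the working map's 5-95 percentile spread (default 0.2,
#'   matching the per-column pruning in [boundary_map()]); 0 disables.
#' @param presmooth_fwhm geodesic Gaussian smoothing of the boundary map
#'   before seeding/flooding (default 6 mm, the pipeline's smoothing
#'   scale; 0 disables).  Stabilizes parcel cores against residual ridge
#'   noise; the input boundary map is left untouched.
#' @return object of class `parcellation`: `labels` (per-vertex int, 0 =
#'   boundary/unassigned/medial), `parcel_ids`, `seed_vertices`,
#'   `threshold_q`.
#' @export
parcellate <- function(boundary, mesh, threshold_q = 0.35, dedup_mm = 3,
                       min_depth_frac = 0.2, presmooth_fwhm = 6) {
  if (threshold_q <= 0 || threshold_q >= 1) stopf("threshold_q must be in (0,1)")
  vals <- boundary_values(boundary)
  ok <- !is.na(vals) & !mesh$medial_wall
  if (presmooth_fwhm > 0) vals <- smooth_map(mesh, vals, presmooth_fwhm)
  if (min_depth_frac > 0) {
    raw <- vals
    spread <- diff(quantile(vals[ok], c(0.05, 0.95), names = FALSE))
    if (spread > 0) vals <- hminima(mesh, vals, min_depth_frac * spread)
    vals[!ok] <- raw[!ok]
  }
  ceiling_val <- quantile(vals[ok], 1 - threshold_q, names = FALSE)
  masked <- vals
  masked[!ok | vals > ceiling_val] <- NA_real_
  seeds <- local_minima(mesh, masked)
  if (length(seeds) == 0) stopf("no watershed seeds below the ceiling")
  # de-duplicate: drop minima within dedup_mm of a stronger minimum
  if (length(seeds) > 1 && dedup_mm > 0) {
    ordv <- order(vals[seeds], seeds)
    seeds_sorted <- seeds[ordv]
    d <- geodesic_distances(mesh, seeds_sorted)[, seeds_sorted, drop = FALSE]
    keep <- rep(TRUE, length(seeds_sorted))
    for (k in seq_along(seeds_sorted)[-1]) {
      if (any(keep[seq_len(k - 1)] & d[seq_len(k - 1), k] <= dedup_mm))
        keep[k] <- FALSE
    }
    seeds <- sort(seeds_sorted[keep])
  }
  ws <- watershed(mesh, vals, seeds, ceiling = ceiling_val)
  labels <- ws$labels
  labels <- enforce_connected(mesh, labels)
  sizes <- tabulate(labels)
  drop <- which(sizes <= 1)
  if (length(drop)) labels[labels %in% drop] <- 0L
  labels <- relabel_by_first_vertex(labels)
  structure(list(labels = labels, parcel_ids = sort(unique(labels[labels > 0])),
                 seed_vertices = seeds, threshold_q = threshold_q,
                 ceiling = ceiling_val),
            class = "parcellation")
}

# Split any disconnected label into its connected components.
enforce_connected <- function(mesh, labels) {
  e <- mesh$edges
  same <- labels[e[, 1]] > 0 & labels[e[, 1]] == labels[e[, 2]]
  g <- igraph::graph_from_edgelist(e[same, , drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(labels) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  out <- integer(length(labels))
  pos <- labels > 0
  out[pos] <- comp[pos]
  relabel_by_first_vertex(out)
}

relabel_by_first_vertex <- function(labels) {
  pos <- which(labels > 0)
  u <- labels[pos][!duplicated(labels[pos])]
  out <- integer(length(labels))
  out[pos] <- match(labels[pos], u)
  out
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("parcellation: %d parcels (threshold_q = %.2f), %d assigned / %d vertices\n",
              length(x$parcel_ids), x$threshold_q, sum(x$labels > 0),
              length(x$labels)))
  invisible(x)
}

parcel_labels <- function(x) if (inherits(x, "parcellation")) x$labels else as.integer(x)

#' Parcel descriptive statistics
#'
#' Vertex counts, surface areas (each vertex carries one third of every
#' incident face's area) and centroids (member coordinate mean, projected
#' to the nearest member vertex so the centroid lies on the parcel).
#'
#' @param parcellation a `parcellation` (or integer label vector).
#' @param mesh a `surface_mesh`.
#' @return list: `n_parcels`, `sizes`, `areas_mm2`, `centroids` (parcel x 3
#'   mm), `centroid_vertex`.
#' @export
parcel_stats <- function(parcellation, mesh) {
  labels <- parcel_labels(parcellation)
  ids <- sort(unique(labels[labels > 0]))
  va <- vertex_areas(mesh)
  sizes <- as.integer(table(factor(labels[labels > 0], levels = ids)))
  areas <- as.numeric(tapply(va[labels > 0], factor(labels[labels > 0], levels = ids), sum))
  centroids <- matrix(NA_real_, length(ids), 3)
  cvert <- integer(length(ids))
  for (k in seq_along(ids)) {
    m <- which(labels == ids[k])
    cm <- colMeans(mesh$vertices[m, , drop = FALSE])
    d2 <- rowSums((mesh$vertices[m, , drop = FALSE] -
                   matrix(cm, length(m), 3, byrow = TRUE))^2)
    cvert[k] <- m[which.min(d2)]
    centroids[k, ] <- mesh$vertices[cvert[k], ]
  }
  list(n_parcels = length(ids), parcel_ids = ids, sizes = sizes,
       areas_mm2 = areas, centroids = centroids, centroid_vertex = cvert)
}
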