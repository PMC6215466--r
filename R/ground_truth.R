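# Planted areal and system structure: geodesic Voronoi parcels from
# farthest-point-sampled seeds, grouped into spatially coherent systems.
# This is the ground truth against which boundary-map and parcellation
# recovery are measured.

#' Plant a ground-truth parcellation with nested systems
#'
#' Seeds are chosen by farthest-point sampling over geodesic distance
#' (keeping parcel sizes within a bounded factor of each other), parcels
#' are the geodesic Voronoi cells of the seeds, and parcels are grouped
#' into `n_systems` spatially coherent systems by k-means on the seed
#' coordinates.  Systems are typed sensory-motor or association: the
#' `n_sensorimotor` systems farthest from the medial-wall pole are
#' sensory-motor (association cortex thins more with age in the
#' simulator, so the typing matters downstream).
#'
#' @param mesh a `surface_mesh`.
#' @param n_parcels number of parcels (>= `n_systems`, at most a quarter of
#'   the non-medial vertex count).
#' @param n_systems number of systems (>= 2).
#' @param seed integer seed (first sample vertex, k-means).
#' @param n_sensorimotor how many systems are typed sensory-motor
#'   (default `round(0.4 * n_systems)`, e.g. 2 of 5).
#' @return object of class `ground_truth`: `labels` (per-vertex parcel, 0 =
#'   medial), `seed_vertices`, `system_of_parcel` (int per parcel),
#'   `system_type` (character per system), `boundary_vertices`, `seed`.
#' @export
plant_parcellation <- function(mesh, n_parcels, n_systems, seed = 1L,
                               n_sensorimotor = max(1L, round(0.4 * n_systems))) {
  valid <- which(!mesh$medial_wall)
  if (n_systems < 2 || n_parcels < n_systems)
    stopf("need n_parcels >= n_systems >= 2")
  if (n_parcels > length(valid) / 4)
    stopf("n_parcels exceeds a quarter of the non-medial vertex count")
  g <- mesh_graph(mesh)
  first <- local_seed(child_seed(seed, 1L), sample(valid, 1))
  seeds <- integer(n_parcels)
  seeds[1] <- first
  dmin <- geodesic_distances(mesh, first)[1, ]
  if (any(!is.finite(dmin[valid]))) stopf("mesh is disconnected")
  for (k in seq_len(n_parcels - 1)) {
    cand <- valid[which.max(dmin[valid])]
    seeds[k + 1] <- cand
    dmin <- pmin(dmin, geodesic_distances(mesh, cand)[1, ])
  }
  dmat <- geodesic_distances(mesh, seeds)   # n_parcels x V
  labels <- integer(n_vertices(mesh))
  labels[valid] <- apply(dmat[, valid, drop = FALSE], 2, which.min)
  km <- local_seed(child_seed(seed, 2L),
                   kmeans(mesh$vertices[seeds, ], centers = n_systems,
                          nstart = 20, iter.max = 100))
  system_of_parcel <- km$cluster
  # type the systems: those farthest (on average) from the medial pole are
  # sensory-motor
  polar <- mesh$sphere[seeds, 3]
  sys_polar <- tapply(polar, system_of_parcel, mean)
  sm <- as.integer(names(sort(sys_polar)))[seq_len(min(n_sensorimotor, n_systems - 1))]
  system_type <- ifelse(seq_len(n_systems) %in% sm, "sensory-motor", "association")
  truth <- list(
    labels = labels, seed_vertices = seeds,
    system_of_parcel = system_of_parcel, system_type = system_type,
    boundary_vertices = boundary_vertices(mesh, labels),
    seed = as.integer(seed)
  )
  class(truth) <- "ground_truth"
  truth
}

# Vertices with at least one 1-ring neighbour in a different (positive)
# parcel; 0-labelled and medial vertices never qualify.
boundary_vertices <- function(mesh, labels) {
  e <- mesh$edges
  la <- labels[e[, 1]]
  lb <- labels[e[, 2]]
  diff <- la > 0 & lb > 0 & la != lb
  sort(unique(c(e[diff, 1], e[diff, 2])))
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d parcels in %d systems (%d sensory-motor), %d border vertices\n",
              length(x$seed_vertices), length(x$system_type),
              sum(x$system_type == "sensory-motor"), length(x$boundary_vertices)))
  invisible(x)
}

# Per-vertex system labels induced by a parcel labelling.
system_labels <- function(labels, system_of_parcel) {
  out <- integer(length(labels))
  pos <- labels > 0
  out[pos] <- system_of_parcel[labels[pos]]
  out
}
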