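# Convenience wrappers binding each evaluation statistic to its rotation
# null: boundary-map Dice Z, homogeneity Z, parcel-overlap Z, matched-RSFC
# Z, ARI Z, and task-SD Z.  In every case the *first* payload (by
# convention the reference/young-cohort map or parcellation) is rotated.

#' Z score for boundary-map Dice against rotated maps
#'
#' @param mapA reference boundary map (rotated to build the null).
#' @param mapB comparison boundary map.
#' @param mesh a `surface_mesh`.
#' @param top_q threshold fraction for binarization.
#' @param n_rot,seed rotation-null parameters.
#' @return a `null_model_result`.
#' @export
dice_z <- function(mapA, mapB, mesh, top_q, n_rot = 100, seed = 1L) {
  actual <- dice_boundary(mapA, mapB, top_q)
  rotation_null(boundary_values(mapA), mesh,
                statistic = function(rot) dice_boundary(rot, mapB, top_q),
                actual = actual, n_rot = n_rot, seed = seed, mode = "map")
}

#' Z score for parcellation homogeneity against rotated parcellations
#'
#' @param parcellation parcellation under test (rotated for the null).
#' @param zmaps cohort mean V x V Fisher-z connectivity matrix.
#' @param mesh a `surface_mesh`.
#' @param n_rot,seed rotation-null parameters.
#' @return a `null_model_result` (actual = mean homogeneity).
#' @export
homogeneity_z <- function(parcellation, zmaps, mesh, n_rot = 100, seed = 1L) {
  labels <- parcel_labels(parcellation)
  ids <- sort(unique(labels[labels > 0]))
  sizes <- tabulate(labels, nbins = max(ids))[ids]
  actual <- homogeneity(labels, zmaps, ids = ids)
  stat <- function(rot) {
    rl <- as.integer(rot)
    valid <- rotated_parcel_valid(rl, ids, sizes)
    homogeneity(rl, zmaps, parcel_valid = valid, ids = ids)$per_parcel
  }
  rotation_null(labels, mesh, stat, actual = actual$mean_homogeneity,
                n_rot = n_rot, seed = seed, mode = "units")
}

#' Z score for mean matched-parcel overlap against rotated parcellations
#'
#' Parcels of `parcA` are matched to `parcB` by maximal Jaccard; the null
#' rematches `parcA` against rotated versions of `parcB`.  A-parcels whose
#' overlap with every rotated parcel is zero (landed on the rotated medial
#' wall) are invalid for that rotation.
#'
#' @param parcA non-reference parcellation (fixed).
#' @param parcB reference parcellation (rotated for the null).
#' @param mesh a `surface_mesh`.
#' @param n_rot,seed rotation-null parameters.
#' @return a `null_model_result` (actual = mean Jaccard overlap).
#' @export
overlap_z <- function(parcA, parcB, mesh, n_rot = 100, seed = 1L) {
  a <- parcel_labels(parcA)
  b <- parcel_labels(parcB)
  actual <- match_parcels(a, b)$mean_overlap
  stat <- function(rot) {
    rl <- as.integer(rot)
    if (!any(rl > 0)) return(rep(NA_real_, length(unique(a[a > 0]))))
    m <- match_parcels(a, rl)
    out <- m$pairs$jaccard
    out[out == 0] <- NA_real_
    out
  }
  rotation_null(b, mesh, stat, actual = actual, n_rot = n_rot, seed = seed,
                mode = "units")
}

#' Z score for matched-parcel RSFC similarity against rotated parcellations
#'
#' @inheritParams overlap_z
#' @param zmapsA,zmapsB cohort mean connectivity matrices for the two
#'   cohorts.
#' @return a `null_model_result` (actual = mean matched-pair correlation).
#' @export
rsfc_similarity_z <- function(parcA, parcB, zmapsA, zmapsB, mesh,
                              n_rot = 100, seed = 1L) {
  a <- parcel_labels(parcA)
  b <- parcel_labels(parcB)
  m0 <- match_parcels(a, b)
  actual <- matched_rsfc_similarity(m0, a, b, zmapsA, zmapsB)$mean_similarity
  idsA <- sort(unique(a[a > 0]))
  stat <- function(rot) {
    rl <- as.integer(rot)
    if (!any(rl > 0)) return(rep(NA_real_, length(idsA)))
    m <- match_parcels(a, rl)
    bad <- m$pairs$jaccard == 0
    r <- suppressWarnings(
      matched_rsfc_similarity(m, a, rl, zmapsA, zmapsB)$per_pair)
    r[bad] <- NA_real_
    r
  }
  rotation_null(b, mesh, stat, actual = actual, n_rot = n_rot, seed = seed,
                mode = "units")
}

#' Z score for the ARI of two parcellations against rotated parcellations
#'
#' @param parcA reference parcellation (rotated for the null).
#' @param parcB comparison parcellation.
#' @param mesh a `surface_mesh`.
#' @param n_rot,seed rotation-null parameters.
#' @return a `null_model_result` (actual = ARI of the two labelings).
#' @export
ari_z <- function(parcA, parcB, mesh, n_rot = 100, seed = 1L) {
  a <- parcel_labels(parcA)
  b <- parcel_labels(parcB)
  actual <- adjusted_rand(a, b)
  rotation_null(a, mesh,
                statistic = function(rot) adjusted_rand(as.integer(rot), b),
                actual = actual, n_rot = n_rot, seed = seed, mode = "scalar")
}

#' Z score for within-parcel task-beta SD against rotated parcellations
#'
#' Lower-tail null: a parcellation aligned with the functional layout has
#' *smaller* within-parcel SD than its rotated versions.
#'
#' @param parcellation parcellation under test (rotated for the null).
#' @param betas V x conditions beta matrix (e.g. cohort mean).
#' @param mesh a `surface_mesh`.
#' @param n_rot,seed rotation-null parameters.
#' @return a `null_model_result` (actual = mean within-parcel SD).
#' @export
task_sd_z <- function(parcellation, betas, mesh, n_rot = 100, seed = 1L) {
  labels <- parcel_labels(parcellation)
  ids <- sort(unique(labels[labels > 0]))
  sizes <- tabulate(labels, nbins = max(ids))[ids]
  actual <- task_sd(labels, betas, ids = ids)$mean_sd
  stat <- function(rot) {
    rl <- as.integer(rot)
    valid <- rotated_parcel_valid(rl, ids, sizes)
    task_sd(rl, betas, parcel_valid = valid, ids = ids)$per_parcel
  }
  rotation_null(labels, mesh, stat, actual = actual, n_rot = n_rot,
                seed = seed, mode = "units", alternative = "less")
}
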