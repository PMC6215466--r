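# Boundary-map and parcellation comparison statistics, and the rotation
# (spin) null machinery that turns each statistic into a Z score:
#   Z = (actual - mean(null)) / sd(null)
# with the null built from seeded uniform rotations of the payload on the
# sphere.  Units (vertices or parcels) that a rotation pushes into the
# medial wall are invalid for that rotation and are replaced by the unit's
# mean over the valid rotations before aggregation.

#' Dice coefficient of two thresholded boundary maps
#'
#' Each map is binarized at its own top-`top_q` quantile (strongest
#' boundaries retained); Dice = 2|A&B| / (|A| + |B|).  Empty
#' binarizations give 0.
#'
#' @param mapA,mapB `boundary_map`s or numeric per-vertex maps on a shared
#'   mesh.
#' @param top_q fraction of strongest boundary values retained.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_boundary <- function(mapA, mapB, top_q) {
  a <- boundary_values(mapA)
  b <- boundary_values(mapB)
  if (length(a) != length(b)) stopf("maps are on different meshes")
  ok <- !is.na(a) & !is.na(b)
  A <- binarize_top(ifelse(ok, a, NA), top_q) & ok
  B <- binarize_top(ifelse(ok, b, NA), top_q) & ok
  denom <- sum(A) + sum(B)
  if (denom == 0) return(0)
  2 * sum(A & B) / denom
}

#' Pearson correlation of two surface maps
#'
#' Computed over vertices valid (non-NA, non-medial) in both maps.
#'
#' @inheritParams dice_boundary
#' @return Pearson r.
#' @export
map_correlation <- function(mapA, mapB) {
  a <- boundary_values(mapA)
  b <- boundary_values(mapB)
  ok <- !is.na(a) & !is.na(b)
  if (sd(a[ok]) == 0 || sd(b[ok]) == 0)
    stopf("correlation undefined for a constant map")
  cor(a[ok], b[ok])
}

#' Rotation (spin) null model for a surface statistic
#'
#' Evaluates `statistic` on `n_rot` seeded uniform rotations of `payload`
#' and summarizes the null as mean, SD, Z = (actual - mean)/SD and a
#' one-sided p (fraction of null values at least as extreme as `actual`
#' in the direction of `alternative`).
#'
#' Three handling modes for rotation-invalid entries:
#' \describe{
#'   \item{`"map"`}{`payload` is a numeric map; destination vertices whose
#'     source rotated into the medial wall are imputed with that vertex's
#'     mean over the valid rotations, then `statistic(map)` is evaluated
#'     per rotation.}
#'   \item{`"units"`}{`statistic(rotated_payload)` returns a per-unit
#'     vector (e.g. per parcel) with NA for units invalid under that
#'     rotation; NAs are imputed with the unit's mean over valid
#'     rotations, and each rotation's null value is the unit mean.}
#'   \item{`"scalar"`}{`statistic(rotated_payload)` returns the null
#'     scalar directly.}
#' }
#'
#' @param payload numeric per-vertex map or integer per-vertex labels.
#' @param mesh a `surface_mesh`.
#' @param statistic function of the rotated payload.
#' @param actual the observed statistic value.
#' @param n_rot number of rotations (default 100).
#' @param seed integer seed.
#' @param mode one of `"scalar"`, `"map"`, `"units"`.
#' @param alternative `"greater"` if large values of the statistic are the
#'   interesting direction, `"less"` otherwise.
#' @return object of class `null_model_result`: `actual`, `null_values`,
#'   `null_mean`, `null_sd`, `z`, `p`, `n_rotations`.
#' @export
rotation_null <- function(payload, mesh, statistic, actual, n_rot = 100,
                          seed = 1L, mode = c("scalar", "map", "units"),
                          alternative = c("greater", "less")) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  seeds <- vapply(seq_len(n_rot), function(k) child_seed(seed, k), integer(1))
  if (mode == "map") {
    rot <- vapply(seeds, function(s) {
      r <- random_rotation(mesh, as.numeric(payload), seed = s)
      as.numeric(r)
    }, numeric(length(payload)))
    imput <- rowMeans(rot, na.rm = TRUE)
    null_values <- apply(rot, 2, function(col) {
      miss <- is.na(col) & !mesh$medial_wall & !is.na(imput)
      col[miss] <- imput[miss]
      statistic(col)
    })
  } else if (mode == "units") {
    per_unit <- lapply(seeds, function(s)
      statistic(random_rotation(mesh, payload, seed = s)))
    U <- do.call(cbind, per_unit)
    unit_mean <- rowMeans(U, na.rm = TRUE)
    dead <- !is.finite(unit_mean)
    if (any(dead))
      warnf("%d unit(s) invalid in every rotation; excluded", sum(dead))
    null_values <- apply(U, 2, function(col) {
      col[is.na(col)] <- unit_mean[is.na(col)]
      mean(col[!dead])
    })
  } else {
    null_values <- vapply(seeds, function(s)
      statistic(random_rotation(mesh, payload, seed = s)), numeric(1))
  }
  null_mean <- mean(null_values)
  null_sd <- sd(null_values)
  if (is.na(null_sd) || null_sd == 0) {
    z <- if (actual > null_mean) Inf else if (actual < null_mean) -Inf else 0
  } else {
    z <- (actual - null_mean) / null_sd
  }
  p <- if (alternative == "greater") mean(null_values >= actual)
       else mean(null_values <= actual)
  structure(list(actual = actual, null_values = null_values,
                 null_mean = null_mean, null_sd = null_sd, z = z, p = p,
                 n_rotations = n_rot, alternative = alternative),
            class = "null_model_result")
}

#' @export
print.null_model_result <- function(x, ...) {
  cat(sprintf("null_model_result: actual %.4f, null %.4f +/- %.4f (n=%d), Z = %.2f, p = %.3f\n",
              x$actual, x$null_mean, x$null_sd, x$n_rotations, x$z, x$p))
  invisible(x)
}

# Parcel adjacency: two parcels are immediately adjacent when some pair of
# their member vertices is within `hops` mesh edges (default 3), so
# parcels separated only by the label-0 boundary ribbon of a watershed
# parcellation still count as neighbours.
parcel_adjacency <- function(mesh, labels, ids, hops = 3L) {
  V <- n_vertices(mesh)
  e <- mesh$edges
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2], seq_len(V)),
                            j = c(e[, 2], e[, 1], seq_len(V)),
                            x = 1, dims = c(V, V))
  K <- length(ids)
  Ind <- Matrix::sparseMatrix(i = which(labels > 0),
                              j = match(labels[labels > 0], ids),
                              x = 1, dims = c(V, K))
  reach <- Ind
  for (h in seq_len(hops)) reach <- A %*% reach
  M <- as.matrix(Matrix::crossprod(Ind, reach) > 0)
  diag(M) <- FALSE
  M | t(M)
}

# Fraction of a rotated parcel retained: parcels keeping < `min_frac` of
# their original vertex count under a rotation count as invalid (rotated
# into the medial wall).  `ids`/`sizes_orig` define the unit universe.
rotated_parcel_valid <- function(labels_rot, ids, sizes_orig, min_frac = 0.75) {
  sz <- tabulate(labels_rot[labels_rot > 0], nbins = max(ids))
  sz[ids] >= min_frac * sizes_orig
}

#' Parcel homogeneity (PC1 variance explained)
#'
#' For each parcel, a PCA of the member vertices' whole-surface mean
#' connectivity maps; homogeneity is the percentage of variance explained
#' by the first principal component.  The mean over parcels summarizes a
#' parcellation.
#'
#' @param parcellation a `parcellation` or integer label vector (0 =
#'   unassigned; parcels need >= 2 vertices to contribute).
#' @param zmaps V x V mean Fisher-z connectivity matrix.
#' @param parcel_valid optional logical per parcel; invalid parcels get NA
#'   (used by the rotation null).
#' @param ids optional fixed parcel-id universe (defaults to the labels
#'   present); parcels absent from `labels` return NA.
#' @return object of class `homogeneity_result`: `per_parcel` (percent,
#'   NA for invalid/degenerate parcels), `mean_homogeneity`.
#' @export
homogeneity <- function(parcellation, zmaps, parcel_valid = NULL, ids = NULL) {
  labels <- parcel_labels(parcellation)
  if (is.null(ids)) ids <- sort(unique(labels[labels > 0]))
  cols <- which(colSums(is.na(zmaps)) < nrow(zmaps))
  per <- rep(NA_real_, length(ids))
  names(per) <- ids
  for (k in seq_along(ids)) {
    if (!is.null(parcel_valid) && !isTRUE(parcel_valid[k])) next
    m <- which(labels == ids[k])
    if (length(m) < 2) next
    X <- zmaps[m, cols, drop = FALSE]
    X <- X[, colSums(is.na(X)) == 0, drop = FALSE]
    if (ncol(X) < 2) next
    # each map is demeaned (its offset carries no pattern information), so
    # homogeneity is invariant to adding a constant to all maps
    Xc <- X - rowMeans(X)
    G <- tcrossprod(Xc)
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
    tot <- sum(pmax(ev, 0))
    per[k] <- if (tot <= 1e-12) {
      warnf("parcel %d has rank-0 connectivity; homogeneity set to 100", ids[k])
      100
    } else 100 * max(ev) / tot
  }
  structure(list(per_parcel = per,
                 mean_homogeneity = mean(per, na.rm = TRUE)),
            class = "homogeneity_result")
}

#' Silhouette coefficient of a parcellation
#'
#' Dissimilarity is 1 - Pearson correlation between whole-surface
#' connectivity maps.  For vertex i, `a_i` is the mean dissimilarity to
#' the other members of its parcel and `b_i` the mean dissimilarity to
#' all members of all 1-ring-adjacent parcels (pooled); the coefficient
#' is `(b_i - a_i) / max(a_i, b_i)`.
#'
#' @param parcellation a `parcellation` or integer label vector.
#' @param zmaps V x V mean Fisher-z connectivity matrix.
#' @param mesh a `surface_mesh` (for parcel adjacency).
#' @return object of class `silhouette_result`: `per_vertex` (NA for
#'   unassigned/isolated vertices), `a_i`, `b_i`, `mean_coef`.
#' @export
silhouette_coefficient <- function(parcellation, zmaps, mesh) {
  labels <- parcel_labels(parcellation)
  valid_row <- rowSums(is.na(zmaps)) < ncol(zmaps)
  C <- whole_surface_row_correlation(zmaps, valid_row)
  silhouette_core(C, labels, mesh, which(valid_row))
}

# Row-correlation matrix of the whole-surface maps over valid vertices.
whole_surface_row_correlation <- function(zmaps, valid_row) {
  X <- zmaps[valid_row, , drop = FALSE]
  X <- X[, colSums(is.na(X)) == 0, drop = FALSE]
  Xs <- X - rowMeans(X)
  Xs <- Xs / sqrt(rowSums(Xs^2))
  tcrossprod(Xs)
}

# Silhouette given a precomputed row-correlation matrix `C` over the
# vertices `ok_vertices` (so rotation nulls reuse C across rotations).
silhouette_core <- function(C, labels, mesh, ok_vertices) {
  ids <- sort(unique(labels[labels > 0]))
  K <- length(ids)
  inC <- match(seq_along(labels), ok_vertices)   # vertex -> row of C
  ok <- which(labels > 0 & !is.na(inC))
  li <- match(labels[ok], ids)
  rows <- inC[ok]
  Ind <- matrix(0, nrow(C), K)
  Ind[cbind(rows, li)] <- 1
  Ssum <- (C %*% Ind)[rows, , drop = FALSE]  # sum of r to each parcel
  nk <- colSums(Ind)
  adj <- parcel_adjacency(mesh, labels, ids)
  a_i <- b_i <- s <- rep(NA_real_, length(labels))
  for (k in seq_len(K)) {
    if (nk[k] < 2) next
    nbk <- which(adj[k, ] & nk > 0)
    if (length(nbk) == 0) next
    mem <- which(li == k)
    av <- 1 - (Ssum[mem, k] - 1) / (nk[k] - 1)   # exclude self (r = 1)
    bv <- 1 - rowSums(Ssum[mem, nbk, drop = FALSE]) / sum(nk[nbk])
    vv <- ok[mem]
    a_i[vv] <- av
    b_i[vv] <- bv
    denom <- pmax(av, bv)
    s[vv] <- ifelse(denom == 0, 0, (bv - av) / denom)
  }
  structure(list(per_vertex = s, a_i = a_i, b_i = b_i,
                 mean_coef = mean(s, na.rm = TRUE)),
            class = "silhouette_result")
}

#' Z score for the mean silhouette against rotated parcellations
#'
#' The vertex-map row-correlation matrix is computed once and reused
#' across rotations; each rotation's null value is the mean silhouette of
#' the rotated parcellation (rotation-invalid vertices are unassigned).
#'
#' @param parcellation parcellation under test (rotated for the null).
#' @param zmaps cohort mean V x V Fisher-z connectivity matrix.
#' @param mesh a `surface_mesh`.
#' @param n_rot,seed rotation-null parameters.
#' @return a `null_model_result` (actual = mean silhouette coefficient).
#' @export
silhouette_z <- function(parcellation, zmaps, mesh, n_rot = 100, seed = 1L) {
  labels <- parcel_labels(parcellation)
  valid_row <- rowSums(is.na(zmaps)) < ncol(zmaps)
  C <- whole_surface_row_correlation(zmaps, valid_row)
  okv <- which(valid_row)
  actual <- silhouette_core(C, labels, mesh, okv)$mean_coef
  rotation_null(labels, mesh,
                statistic = function(rot)
                  silhouette_core(C, as.integer(rot), mesh, okv)$mean_coef,
                actual = actual, n_rot = n_rot, seed = seed, mode = "scalar")
}

#' Match parcels across two parcellations by maximal Jaccard overlap
#'
#' The full Jaccard table (intersection over union of vertex sets) is
#' computed over all parcel pairs; each A-parcel is matched to its
#' maximal-overlap B-parcel (ties to the lower B label; multiple A
#' parcels may share a B parcel).
#'
#' @param parcA,parcB `parcellation`s or integer label vectors on a shared
#'   mesh.
#' @return object of class `parcel_match`: `pairs` (data.frame parcel_A,
#'   parcel_B, jaccard), `jaccard_table`, `mean_overlap`.
#' @export
match_parcels <- function(parcA, parcB) {
  a <- parcel_labels(parcA)
  b <- parcel_labels(parcB)
  if (length(a) != length(b)) stopf("parcellations are on different meshes")
  idsA <- sort(unique(a[a > 0]))
  idsB <- sort(unique(b[b > 0]))
  if (length(idsA) == 0 || length(idsB) == 0)
    stopf("empty parcellation")
  tab <- table(factor(a, levels = idsA), factor(b, levels = idsB))
  nA <- as.integer(table(factor(a[a > 0], levels = idsA)))
  nB <- as.integer(table(factor(b[b > 0], levels = idsB)))
  inter <- as.matrix(tab)
  uni <- outer(nA, nB, `+`) - inter
  J <- inter / uni
  best <- apply(J, 1, which.max)         # first max = lowest B label
  pairs <- data.frame(parcel_A = idsA, parcel_B = idsB[best],
                      jaccard = J[cbind(seq_along(idsA), best)])
  structure(list(pairs = pairs, jaccard_table = J,
                 mean_overlap = mean(pairs$jaccard)),
            class = "parcel_match")
}

#' RSFC-map similarity of matched parcels
#'
#' Each parcel's RSFC map is the mean of its member vertices' whole-surface
#' connectivity maps; matched pairs are compared by Pearson correlation
#' over target vertices valid in both cohorts.
#'
#' @param match a `parcel_match` from [match_parcels()].
#' @param parcA,parcB the matched parcellations.
#' @param zmapsA,zmapsB cohort mean V x V Fisher-z matrices.
#' @return list: `per_pair` (r per matched pair), `mean_similarity`.
#' @export
matched_rsfc_similarity <- function(match, parcA, parcB, zmapsA, zmapsB) {
  a <- parcel_labels(parcA)
  b <- parcel_labels(parcB)
  mapsA <- parcel_mean_maps(a, zmapsA)
  mapsB <- parcel_mean_maps(b, zmapsB)
  okcol <- colSums(is.na(mapsA)) == 0 & colSums(is.na(mapsB)) == 0
  pr <- rep(NA_real_, nrow(match$pairs))
  for (i in seq_len(nrow(match$pairs))) {
    pa <- as.character(match$pairs$parcel_A[i])
    pb <- as.character(match$pairs$parcel_B[i])
    x <- mapsA[pa, okcol]
    y <- mapsB[pb, okcol]
    if (sd(x) == 0 || sd(y) == 0) {
      warnf("degenerate RSFC map for pair (%s, %s); skipped", pa, pb)
      next
    }
    pr[i] <- cor(x, y)
  }
  list(per_pair = pr, mean_similarity = mean(pr, na.rm = TRUE))
}

# Parcel-mean whole-surface maps: rows = parcels (named), cols = vertices.
parcel_mean_maps <- function(labels, zmaps) {
  ids <- sort(unique(labels[labels > 0]))
  out <- matrix(NA_real_, length(ids), ncol(zmaps),
                dimnames = list(ids, NULL))
  for (k in seq_along(ids)) {
    rows <- zmaps[labels == ids[k], , drop = FALSE]
    out[k, ] <- colMeans(rows)
  }
  out
}

#' Adjusted Rand index of two labelings
#'
#' Standard pair-counting ARI from the contingency table; vertices
#' unassigned (label 0) in either labeling are excluded pairwise.
#'
#' @param labelsA,labelsB integer label vectors (same vertex set).
#' @return ARI (1 = identical, ~0 = chance).
#' @export
adjusted_rand <- function(labelsA, labelsB) {
  a <- parcel_labels(labelsA)
  b <- parcel_labels(labelsB)
  if (length(a) != length(b)) stopf("label vectors differ in length")
  ok <- a > 0 & b > 0
  a <- a[ok]
  b <- b[ok]
  if (length(a) < 2) stopf("fewer than 2 jointly assigned vertices")
  if (length(unique(a)) == 1 && length(unique(b)) == 1) {
    warnf("both labelings constant; ARI defined by identity")
    return(if (all(a == a[1]) && all(b == b[1])) 1 else 0)
  }
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n2 <- ch2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(0)
  (sum_ij - expected) / (maxi - expected)
}

#' Within-parcel SD of task beta maps
#'
#' Per parcel and condition, the SD of beta values over member vertices;
#' averaged over conditions, then parcels.  Single-vertex parcels are
#' excluded.  Good (functionally aligned) parcellations have a smaller
#' mean SD than rotated nulls, so the Z uses the lower tail.
#'
#' @param parcellation a `parcellation` or integer label vector.
#' @param betas V x conditions matrix of beta values.
#' @param parcel_valid optional per-parcel validity (rotation null).
#' @param ids optional fixed parcel-id universe (rotation null).
#' @return list: `per_parcel` (mean-over-conditions SD; NA where invalid),
#'   `mean_sd`.
#' @export
task_sd <- function(parcellation, betas, parcel_valid = NULL, ids = NULL) {
  labels <- parcel_labels(parcellation)
  betas <- as.matrix(betas)
  if (is.null(ids)) ids <- sort(unique(labels[labels > 0]))
  per <- rep(NA_real_, length(ids))
  names(per) <- ids
  for (k in seq_along(ids)) {
    if (!is.null(parcel_valid) && !isTRUE(parcel_valid[k])) next
    m <- which(labels == ids[k])
    B <- betas[m, , drop = FALSE]
    B <- B[rowSums(is.na(B)) == 0, , drop = FALSE]
    if (nrow(B) < 2) next
    per[k] <- mean(apply(B, 2, sd))
  }
  list(per_parcel = per, mean_sd = mean(per, na.rm = TRUE))
}

#' Vertex-wise regression of boundary differences on structural differences
#'
#' Ordinary least squares of |delta boundary| on |delta thickness| and
#' |delta deformation| (absolute values taken inside), over vertices valid
#' in all three maps, with an optional interaction term.
#'
#' @param delta_boundary,delta_thickness,delta_deformation per-vertex
#'   difference maps (cohort B minus cohort A).
#' @param interaction include the thickness x deformation product term.
#' @return list: `coefficients`, `t`, `p`, `F`, `df`, `p_F`, `r_squared`,
#'   `n`, plus the fitted `lm` object as `fit`.
#' @export
boundary_diff_regression <- function(delta_boundary, delta_thickness,
                                     delta_deformation, interaction = FALSE) {
  y <- abs(boundary_values(delta_boundary))
  x1 <- abs(delta_thickness)
  x2 <- abs(delta_deformation)
  ok <- !is.na(y) & !is.na(x1) & !is.na(x2)
  d <- data.frame(y = y[ok], thickness = x1[ok], deformation = x2[ok])
  form <- if (interaction) y ~ thickness * deformation else y ~ thickness + deformation
  fit <- lm(form, data = d)
  X <- stats::model.matrix(fit)
  kappa_val <- kappa(crossprod(X))
  if (kappa_val > 1e10) warnf("ill-conditioned design (kappa = %.2e)", kappa_val)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(coefficients = coef(fit),
       t = sm$coefficients[, "t value"],
       p = sm$coefficients[, "Pr(>|t|)"],
       F = unname(fstat[1]), df = unname(fstat[2:3]),
       p_F = pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
       r_squared = sm$r.squared, n = nrow(d), fit = fit)
}

#' One-way ANOVA from printed group summaries
#'
#' Reconstructs the F test from group means, SDs and sizes:
#' SSB = sum n_i (m_i - grand mean)^2, SSW = sum (n_i - 1) sd_i^2,
#' F = (SSB / (k - 1)) / (SSW / (N - k)).
#'
#' @param group_means,group_sds,group_ns numeric vectors, one entry per
#'   group (k >= 2 groups, all n >= 2, all sd >= 0).
#' @return list: `F`, `df_between`, `df_within`, `p`.
#' @export
anova_from_summary <- function(group_means, group_sds, group_ns) {
  k <- length(group_means)
  if (k < 2 || length(group_sds) != k || length(group_ns) != k)
    stopf("need matching means/sds/ns for >= 2 groups")
  if (any(group_sds < 0)) stopf("standard deviations must be >= 0")
  if (any(group_ns < 2)) stopf("group sizes must be >= 2")
  N <- sum(group_ns)
  gm <- sum(group_ns * group_means) / N
  ssb <- sum(group_ns * (group_means - gm)^2)
  ssw <- sum((group_ns - 1) * group_sds^2)
  Fv <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = Fv, df_between = k - 1, df_within = N - k,
       p = pf(Fv, k - 1, N - k, lower.tail = FALSE))
}
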