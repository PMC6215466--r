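# Cohort-level RSFC boundary mapping.
#
# Per subject: whole-surface vertex-to-vertex correlation maps, Fisher
# z-transformed (full distribution, negative and positive).  Per bootstrap
# sample: subject z-maps are averaged, the vertex-wise RSFC similarity
# matrix is computed (spatial correlation between connectivity rows, with
# the two self entries excluded), each similarity column is turned into a
# tangent-plane gradient-magnitude map and smoothed; gradient matrices are
# averaged over bootstraps.  Finally a watershed is run on every column of
# the average gradient matrix and the binary ridge images are averaged
# into the cohort boundary map (per-vertex RSFC transition probability).

#' Whole-surface connectivity maps for one subject
#'
#' Pearson correlation over the retained frames between every vertex pair,
#' Fisher z-transformed (r clipped to +/-(1 - 1e-7)).  Zero-variance and
#' medial-wall vertices carry NA rows/columns.
#'
#' @param clean a `clean_series` from [preprocess_subject()] (or any list
#'   with `timeseries`), or a bare vertex x frame matrix.
#' @param mesh optional `surface_mesh` used to blank medial-wall rows.
#' @return V x V symmetric matrix of Fisher z values.
#' @export
subject_connectivity <- function(clean, mesh = NULL) {
  ts <- if (is.list(clean)) clean$timeseries else clean
  if (is.list(clean) && isFALSE(clean$usable))
    stopf("subject is not usable (too few retained frames)")
  sds <- apply(ts, 1, sd)
  z <- fisher_z(suppressWarnings(cor(t(ts))))
  bad <- sds == 0 | is.na(sds)
  if (!is.null(mesh)) bad <- bad | mesh$medial_wall
  z[bad, ] <- NA_real_
  z[, bad] <- NA_real_
  z
}

#' Vertex-wise RSFC similarity matrix
#'
#' Entry (i, j) is the Pearson correlation between connectivity rows i and
#' j of the mean z-map matrix, with target entries i and j excluded from
#' both rows (the trivially inflated self terms).  Computed by closed-form
#' correction of full-matrix cross-products, so no per-pair loop is
#' needed.  The diagonal is 1 by construction.
#'
#' @param zmaps V x V symmetric mean Fisher-z connectivity matrix (NA
#'   rows mark invalid vertices).
#' @return V x V symmetric similarity matrix (NA rows for invalid vertices).
#' @export
similarity_matrix <- function(zmaps) {
  V <- nrow(zmaps)
  ok <- which(rowSums(is.na(zmaps)) < V)
  M <- zmaps[ok, ok, drop = FALSE]
  n <- length(ok) - 2
  D <- diag(M)
  S <- rowSums(M)
  Q <- tcrossprod(M)
  Q2 <- rowSums(M^2)
  # row i with columns {i, j} removed: sum, sum of squares, cross term
  Si <- outer(S - D, rep(1, length(ok))) - M          # S_i - D_i - M_ij
  Sj <- t(Si)
  Qi <- outer(Q2 - D^2, rep(1, length(ok))) - M^2
  Qj <- t(Qi)
  Cij <- Q - outer(D, rep(1, length(ok))) * M - M * outer(rep(1, length(ok)), D)
  num <- Cij - Si * Sj / n
  den <- sqrt(pmax(Qi - Si^2 / n, 0) * pmax(Qj - Sj^2 / n, 0))
  R <- num / den
  diag(R) <- 1
  R[!is.finite(R)] <- 0
  out <- matrix(NA_real_, V, V)
  out[ok, ok] <- R
  out
}

#' Bootstrap-averaged RSFC similarity gradient matrix for a cohort
#'
#' For each of `n_boot` bootstrap samples (subjects drawn with
#' replacement, same cohort size): average the subjects' z-maps, compute
#' the similarity matrix, convert every column to a gradient-magnitude
#' map and smooth it (`fwhm_mm`); the per-column matrices are averaged
#' over bootstraps.  Deterministic given `seed`.
#'
#' @param zmaps_list list of per-subject V x V Fisher-z matrices (usable
#'   subjects only), length >= 2.
#' @param mesh a `surface_mesh`.
#' @param n_boot number of bootstrap samples (default 100).
#' @param fwhm_mm smoothing kernel FWHM (default 6 mm).
#' @param seed integer seed for the resampling.
#' @param boot_index optional list of index vectors overriding the random
#'   bootstrap samples (e.g. `list(seq_along(zmaps_list))` for the
#'   degenerate identity bootstrap).
#' @return V x V mean gradient matrix (columns = seed-vertex gradient
#'   maps; NA on medial wall).
#' @export
cohort_bootstrap_gradient <- function(zmaps_list, mesh, n_boot = 100,
                                      fwhm_mm = 6, seed = 1L,
                                      boot_index = NULL) {
  ns <- length(zmaps_list)
  if (ns < 2 && is.null(boot_index)) stopf("need >= 2 usable subjects")
  if (is.null(boot_index)) {
    boot_index <- local_seed(child_seed(seed, 17L),
                             lapply(seq_len(n_boot),
                                    function(i) sample.int(ns, ns, replace = TRUE)))
  }
  V <- n_vertices(mesh)
  ops <- gradient_operators(mesh)
  W <- smoothing_matrix(mesh, fwhm_mm)
  acc <- matrix(0, V, V)
  for (b in seq_along(boot_index)) {
    idx <- boot_index[[b]]
    mz <- Reduce(`+`, zmaps_list[idx]) / length(idx)
    sim <- similarity_matrix(mz)
    sim[is.na(sim)] <- 0
    sim[mesh$medial_wall, ] <- 0
    gx <- as.matrix(ops$Gx %*% sim)
    gy <- as.matrix(ops$Gy %*% sim)
    acc <- acc + as.matrix(W %*% sqrt(gx^2 + gy^2))
  }
  grad <- acc / length(boot_index)
  grad[mesh$medial_wall, ] <- NA_real_
  grad[!ops$valid, ] <- NA_real_
  grad[, mesh$medial_wall] <- NA_real_
  grad
}

#' Cohort boundary map from the mean gradient matrix
#'
#' For every seed column of the mean gradient matrix, local minima are
#' found and a full (no-ceiling) watershed is run; the binary ridge images
#' are averaged over seed columns, giving the per-vertex probability of
#' being an RSFC transition.
#'
#' @param grad_matrix V x V mean gradient matrix (from
#'   [cohort_bootstrap_gradient()]).
#' @param mesh a `surface_mesh`.
#' @param min_depth_frac h-minima depth for each column's watershed, as a
#'   fraction of the column's 5-95 percentile spread (default 0.2);
#'   suppresses basins arising from the flat noise floor of averaged
#'   gradient maps.  0 disables pruning.
#' @return object of class `boundary_map`: `values` in `[0, 1]` (NA on
#'   medial wall), `n_columns` used.
#' @export
boundary_map <- function(grad_matrix, mesh, min_depth_frac = 0.2) {
  csr <- mesh_csr(mesh)
  cols <- which(!mesh$medial_wall & colSums(is.na(grad_matrix)) < nrow(grad_matrix))
  res <- .boundary_accumulate_cpp(csr$off, csr$nbr, grad_matrix,
                                  mesh$medial_wall, cols - 1L,
                                  min_depth_frac)
  vals <- res$count / max(res$n_cols, 1)
  vals[mesh$medial_wall] <- NA_real_
  structure(list(values = vals, n_columns = res$n_cols), class = "boundary_map")
}

#' @export
print.boundary_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("boundary_map: %d vertices, mean %.3f, max %.3f (%d seed columns)\n",
              length(x$values), mean(v), max(v), x$n_columns))
  invisible(x)
}

boundary_values <- function(x) if (inherits(x, "boundary_map")) x$values else x

# Binarize a map to its top-q fraction of valid vertices (rank-based, so
# ties at the threshold cannot inflate the selection; ties broken by
# vertex index for determinism).
binarize_top <- function(values, top_q) {
  v <- values
  ok <- which(!is.na(v))
  k <- round(top_q * length(ok))
  out <- rep(FALSE, length(v))
  if (k > 0) {
    ord <- ok[order(-v[ok], ok)]
    out[ord[seq_len(min(k, length(ord)))]] <- TRUE
  }
  out
}

#' Conjunction of thresholded boundary maps
#'
#' Each map is binarized at its own top-`top_q` quantile and the binary
#' maps are summed per vertex (0 .. number of maps).
#'
#' @param maps list of `boundary_map`s (or numeric per-vertex maps) on a
#'   common mesh.
#' @param top_q fraction of strongest boundary values retained.
#' @return integer per-vertex count map (NA where all maps invalid).
#' @export
boundary_conjunction <- function(maps, top_q) {
  vals <- lapply(maps, boundary_values)
  if (length(unique(lengths(vals))) != 1) stopf("maps are on different meshes")
  bins <- lapply(vals, binarize_top, top_q = top_q)
  counts <- Reduce(`+`, lapply(bins, as.integer))
  counts[Reduce(`&`, lapply(vals, is.na))] <- NA_integer_
  counts
}
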