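# Parcel-graph construction and large-scale system analysis: edge-density
# thresholding with a short-distance exclusion, map-equation community
# detection with bootstrap mode consensus and cross-density consensus,
# system matching against a reference, and brain system segregation.

#' Build a subject's parcel graph
#'
#' Node time series are the mean over member vertices of the cleaned
#' series; pairwise Pearson correlations are Fisher z-transformed.
#' Node pairs whose parcel centroids are closer than `exclusion_mm`
#' (Euclidean, anatomical coordinates) are flagged and carry no edge at
#' any density; negative edges are retained in the z-matrix but never
#' selected by thresholding and are excluded from segregation means.
#'
#' @param parcellation a `parcellation` or integer label vector.
#' @param clean a `clean_series` (or vertex x frame matrix).
#' @param mesh a `surface_mesh`.
#' @param exclusion_mm centroid-distance exclusion (default 20 mm).
#' @return object of class `parcel_graph`: `z` (node x node Fisher z,
#'   diagonal NA), `excluded` (logical node x node), `centroids`,
#'   `parcel_ids`, `age`, `cohort`.
#' @export
build_graph <- function(parcellation, clean, mesh, exclusion_mm = 20) {
  labels <- parcel_labels(parcellation)
  ts <- if (is.list(clean)) clean$timeseries else clean
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) < 2) stopf("need >= 2 parcels")
  node_ts <- t(vapply(ids, function(k) colMeans(ts[labels == k, , drop = FALSE]),
                      numeric(ncol(ts))))
  z <- fisher_z(suppressWarnings(cor(t(node_ts))))
  diag(z) <- NA_real_
  st <- parcel_stats(labels, mesh)
  cen <- st$centroids
  dmat <- as.matrix(dist(cen))
  excluded <- dmat < exclusion_mm
  diag(excluded) <- TRUE
  structure(list(z = z, excluded = excluded, centroids = cen,
                 parcel_ids = ids,
                 age = if (is.list(clean)) clean$age else NA_real_,
                 cohort = if (is.list(clean)) clean$cohort else NA_character_),
            class = "parcel_graph")
}

#' Threshold a parcel graph at an edge density
#'
#' Candidate edges are positive, non-excluded pairs; the top
#' `round(density * n(n-1)/2)` by z are kept, ties broken by
#' (z, node-pair lexicographic order).
#'
#' @param graph a `parcel_graph`, or a plain z matrix.
#' @param density edge density in (0, 1].
#' @param excluded optional exclusion matrix when `graph` is a matrix.
#' @return data.frame `i`, `j`, `w` (kept edges, i < j).
#' @export
threshold_density <- function(graph, density, excluded = NULL) {
  if (density <= 0 || density > 1) stopf("density must be in (0, 1]")
  z <- if (inherits(graph, "parcel_graph")) graph$z else graph
  if (inherits(graph, "parcel_graph")) excluded <- graph$excluded
  n <- nrow(z)
  ut <- which(upper.tri(z), arr.ind = TRUE)
  w <- z[ut]
  cand <- w > 0 & !is.na(w)
  if (!is.null(excluded)) cand <- cand & !excluded[ut]
  m <- round(density * n * (n - 1) / 2)
  idx <- which(cand)
  if (length(idx) < m) {
    warnf("only %d candidate edges for %d requested; keeping all",
          length(idx), m)
    m <- length(idx)
  }
  ord <- idx[order(-w[idx], ut[idx, 1], ut[idx, 2])]
  keep <- ord[seq_len(m)]
  data.frame(i = ut[keep, 1], j = ut[keep, 2], w = w[keep])
}

#' Default edge-density grid
#'
#' 3 to 5 percent in steps of 0.1 percent, then 6 to 10 percent in steps
#' of 1 percent.
#'
#' @return numeric vector of densities (fractions).
#' @export
density_grid <- function() {
  c(seq(0.030, 0.050, by = 0.001), seq(0.06, 0.10, by = 0.01))
}

#' Two-level map-equation community detection
#'
#' Minimizes the two-level map equation (description length of a random
#' walk) by seeded greedy node moving with Louvain-style aggregation and
#' `n_restarts` restarts; deterministic given `seed`.  Isolated nodes
#' become singletons.
#'
#' @param edges data.frame `i`, `j`, `w` (1-based, positive weights), e.g.
#'   from [threshold_density()].
#' @param n_nodes number of nodes.
#' @param seed integer seed.
#' @param n_restarts restarts (best kept; default 10).
#' @return list: `membership` (1..k, labelled by first appearance),
#'   `codelength` (bits).
#' @export
map_equation_partition <- function(edges, n_nodes, seed = 1L, n_restarts = 10L) {
  if (nrow(edges) == 0) stopf("need at least one edge")
  .map_equation_cpp(as.integer(n_nodes), as.integer(edges$i) - 1L,
                    as.integer(edges$j) - 1L, as.numeric(edges$w),
                    as.integer(seed), as.integer(n_restarts))
}

# Align labels of `part` to `ref` by greedy maximal-Jaccard matching of
# communities; unmatched communities get fresh labels.
align_partition <- function(part, ref) {
  pu <- sort(unique(part))
  ru <- sort(unique(ref))
  J <- matrix(0, length(pu), length(ru))
  for (a in seq_along(pu)) for (b in seq_along(ru)) {
    ia <- part == pu[a]
    ib <- ref == ru[b]
    J[a, b] <- sum(ia & ib) / sum(ia | ib)
  }
  out <- integer(length(part))
  taken_p <- rep(FALSE, length(pu))
  taken_r <- rep(FALSE, length(ru))
  mapping <- integer(length(pu))
  ord <- order(-J)
  for (o in ord) {
    a <- (o - 1) %% length(pu) + 1
    b <- (o - 1) %/% length(pu) + 1
    if (J[a, b] <= 0) break
    if (taken_p[a] || taken_r[b]) next
    mapping[a] <- ru[b]
    taken_p[a] <- TRUE
    taken_r[b] <- TRUE
  }
  nxt <- max(ru) + 1L
  for (a in seq_along(pu)) {
    if (mapping[a] == 0L) {
      mapping[a] <- nxt
      nxt <- nxt + 1L
    }
  }
  mapping[match(part, pu)]
}

#' Bootstrap modal community assignment at one edge density
#'
#' Per bootstrap sample (subjects drawn with replacement): average the
#' subjects' z-matrices, threshold at `density`, partition with the map
#' equation; partitions are aligned to the first bootstrap's partition by
#' maximal-Jaccard label matching, and each node's modal (most common)
#' aligned assignment is returned.
#'
#' @param graphs list of `parcel_graph`s for the cohort's subjects.
#' @param density edge density.
#' @param n_boot bootstrap samples (the study-scale default is 1000;
#'   scale down for desk-scale runs).
#' @param seed integer seed.
#' @param n_restarts map-equation restarts per bootstrap.
#' @return integer modal community label per node.
#' @export
bootstrap_mode_communities <- function(graphs, density, n_boot = 1000,
                                       seed = 1L, n_restarts = 5L) {
  ns <- length(graphs)
  if (ns < 2) stopf("need >= 2 subjects")
  n <- nrow(graphs[[1]]$z)
  excl <- graphs[[1]]$excluded
  samples <- local_seed(child_seed(seed, 71L),
                        lapply(seq_len(n_boot),
                               function(i) sample.int(ns, ns, replace = TRUE)))
  parts <- matrix(0L, n, n_boot)
  for (b in seq_len(n_boot)) {
    mz <- Reduce(`+`, lapply(graphs[samples[[b]]], `[[`, "z")) / ns
    edges <- threshold_density(mz, density, excluded = excl)
    if (nrow(edges) == 0) {
      parts[, b] <- seq_len(n)
      next
    }
    p <- map_equation_partition(edges, n, seed = child_seed(seed, 1000L + b),
                                n_restarts = n_restarts)$membership
    parts[, b] <- if (b == 1) p else align_partition(p, parts[, 1])
  }
  apply(parts, 1, function(x) {
    tb <- table(x)
    as.integer(names(tb)[which.max(tb)])   # ties -> smallest label
  })
}

#' Cross-density consensus of modal community assignments
#'
#' Densities are processed from sparsest to densest.  Partitions are first
#' label-aligned across the grid (chained maximal-Jaccard matching).
#' Communities with fewer than `min_size` nodes, and communities present
#' at only one density, are dissolved; a dissolved node takes its
#' assignment at the nearest less-sparse density where that assignment is
#' valid, and any node still unresolved takes its majority assignment
#' across densities (the codified replacement for per-node manual
#' reassignment).  Deterministic.
#'
#' @param assignments node x density integer matrix of modal assignments,
#'   columns ordered from sparsest to densest density.
#' @param densities numeric vector labelling the columns.
#' @param min_size minimum community size (default 6).
#' @return list of class `system_partition`: `consensus` (node labels,
#'   compacted), `aligned` (aligned assignment matrix), `densities`.
#' @export
cross_density_consensus <- function(assignments, densities, min_size = 6L) {
  A <- as.matrix(assignments)
  nd <- ncol(A)
  if (nd != length(densities)) stopf("assignment/density mismatch")
  for (d in seq_len(nd)[-1]) A[, d] <- align_partition(A[, d], A[, d - 1])
  labs <- sort(unique(as.vector(A)))
  present <- vapply(labs, function(l) sum(colSums(A == l) > 0), integer(1))
  valid_at <- function(l, d) {
    sum(A[, d] == l) >= min_size && present[match(l, labs)] > 1
  }
  consensus <- A[, 1]
  for (v in seq_len(nrow(A))) {
    if (valid_at(consensus[v], 1)) next
    resolved <- FALSE
    for (d in seq_len(nd)[-1]) {
      if (valid_at(A[v, d], d)) {
        consensus[v] <- A[v, d]
        resolved <- TRUE
        break
      }
    }
    if (!resolved) {
      tb <- table(A[v, ])
      big <- names(tb)[tb == max(tb)]
      consensus[v] <- as.integer(big[1])   # ties -> smallest label
    }
  }
  consensus <- match(consensus, sort(unique(consensus)))
  structure(list(consensus = consensus, aligned = A, densities = densities),
            class = "system_partition")
}

#' Match consensus communities to reference systems
#'
#' Each consensus community is labelled by the reference system with
#' which it shares the most nodes; per-system spatial agreement is the
#' Dice coefficient of the vertex maps, with a rotation-null Z per system
#' (null = Dice against rotated reference system maps; rotations pushing
#' a system into the medial wall are imputed with the system's mean null
#' Dice, following the valid-rotation averaging rule).
#'
#' @param consensus integer community label per node.
#' @param reference integer reference system per node (e.g. planted
#'   systems).
#' @param parcellation the node-defining `parcellation`.
#' @param mesh a `surface_mesh`.
#' @param n_rot rotations for the null (default 100).
#' @param seed integer seed.
#' @return list: `system_of_community` (named map), `matched` (per-node
#'   matched system labels), `dice` (per system), `null` (list of
#'   `null_model_result` per system).
#' @export
match_systems <- function(consensus, reference, parcellation, mesh,
                          n_rot = 100, seed = 1L) {
  labels <- parcel_labels(parcellation)
  comm <- sort(unique(consensus))
  sys_of_comm <- vapply(comm, function(cm) {
    tb <- table(reference[consensus == cm])
    as.integer(names(tb)[which.max(tb)])
  }, integer(1))
  names(sys_of_comm) <- comm
  matched <- sys_of_comm[match(consensus, comm)]
  # vertex maps
  node_of_vertex <- match(labels, sort(unique(labels[labels > 0])))
  cons_map <- ref_map <- integer(length(labels))
  ok <- !is.na(node_of_vertex)
  cons_map[ok] <- matched[node_of_vertex[ok]]
  ref_map[ok] <- reference[node_of_vertex[ok]]
  systems <- sort(unique(reference))
  dice_bin <- function(x, y) {
    d <- sum(x) + sum(y)
    if (d == 0) 0 else 2 * sum(x & y) / d
  }
  sizes <- vapply(systems, function(s) sum(ref_map == s), integer(1))
  nulls <- list()
  dice <- numeric(length(systems))
  rot_seeds <- vapply(seq_len(n_rot), function(k) child_seed(seed, 400L + k),
                      integer(1))
  rot_maps <- lapply(rot_seeds, function(s)
    random_rotation(mesh, as.integer(ref_map), seed = s))
  for (si in seq_along(systems)) {
    s <- systems[si]
    actual <- dice_bin(cons_map == s, ref_map == s)
    per_rot <- vapply(rot_maps, function(rm) {
      kept <- sum(rm == s)
      if (kept < 0.75 * sizes[si]) return(NA_real_)  # rotated into medial wall
      dice_bin(cons_map == s, rm == s)
    }, numeric(1))
    imput <- mean(per_rot, na.rm = TRUE)
    per_rot[is.na(per_rot)] <- imput
    nsd <- sd(per_rot)
    z <- if (is.na(nsd) || nsd == 0) {
      if (actual > mean(per_rot)) Inf else if (actual < mean(per_rot)) -Inf else 0
    } else (actual - mean(per_rot)) / nsd
    nulls[[as.character(s)]] <- structure(
      list(actual = actual, null_values = per_rot, null_mean = mean(per_rot),
           null_sd = nsd, z = z, p = mean(per_rot >= actual),
           n_rotations = n_rot, alternative = "greater"),
      class = "null_model_result")
    dice[si] <- actual
  }
  names(dice) <- systems
  list(system_of_community = sys_of_comm, matched = matched, dice = dice,
       null = nulls)
}

#' Brain system segregation
#'
#' Segregation = (mean within-system z - mean between-system z) / mean
#' within-system z, computed on positive, non-excluded edges only.
#' Scopes: `"overall"` pools all within- and between-system pairs;
#' `"association"` and `"sensory-motor"` average per-system means of that
#' type against all other systems; `"association-to-sensory"` contrasts
#' association within-system connectivity with association-to-sensory
#' between-type connectivity.
#'
#' @param z node x node Fisher-z matrix (a `parcel_graph` also works).
#' @param systems integer system label per node.
#' @param system_type character per system id (`"association"` /
#'   `"sensory-motor"`); required for typed scopes.
#' @param scope one of `"overall"`, `"association"`, `"sensory-motor"`,
#'   `"association-to-sensory"`.
#' @param excluded optional logical exclusion matrix.
#' @return list of class `segregation_result`: `z_within`, `z_between`,
#'   `segregation`, `scope`.
#' @export
system_segregation <- function(z, systems, system_type = NULL,
                               scope = c("overall", "association",
                                         "sensory-motor",
                                         "association-to-sensory"),
                               excluded = NULL) {
  scope <- match.arg(scope)
  if (inherits(z, "parcel_graph")) {
    if (is.null(excluded)) excluded <- z$excluded
    z <- z$z
  }
  n <- nrow(z)
  ut <- which(upper.tri(z), arr.ind = TRUE)
  w <- z[ut]
  ok <- !is.na(w) & w > 0
  if (!is.null(excluded)) ok <- ok & !excluded[ut]
  si <- systems[ut[, 1]]
  sj <- systems[ut[, 2]]
  sys_ids <- sort(unique(systems))
  if (scope == "overall") {
    zw <- mean(w[ok & si == sj])
    zb <- mean(w[ok & si != sj])
  } else {
    if (is.null(system_type)) stopf("system_type required for scope '%s'", scope)
    type_of <- function(s) system_type[s]
    in_type <- if (scope == "sensory-motor") "sensory-motor" else "association"
    focal <- sys_ids[vapply(sys_ids, function(s) type_of(s) == in_type, logical(1))]
    if (length(focal) == 0) stopf("no systems of type '%s'", in_type)
    per_w <- per_b <- rep(NA_real_, length(focal))
    for (k in seq_along(focal)) {
      s <- focal[k]
      per_w[k] <- mean(w[ok & si == s & sj == s])
      other <- switch(scope,
        "association" = ,
        "sensory-motor" = (si == s | sj == s) & si != sj,
        "association-to-sensory" =
          ((si == s & type_of(sj) == "sensory-motor") |
           (sj == s & type_of(si) == "sensory-motor")))
      per_b[k] <- mean(w[ok & other])
    }
    zw <- mean(per_w, na.rm = TRUE)
    zb <- mean(per_b, na.rm = TRUE)
  }
  if (!is.finite(zw) || zw <= 0)
    stopf("segregation undefined: mean within-system connectivity <= 0")
  if (!is.finite(zb)) zb <- 0
  structure(list(z_within = zw, z_between = zb,
                 segregation = (zw - zb) / zw, scope = scope),
            class = "segregation_result")
}

#' Age trend of per-subject system segregation
#'
#' Pearson correlation of segregation with age, plus linear and cubic
#' polynomial OLS fits with their overall model F tests.
#'
#' @param segregation numeric per subject.
#' @param ages numeric per subject (years).
#' @return list: `r`, `p_r`, `linear` (list F, df, p, coefficients),
#'   `cubic` (same).
#' @export
segregation_age_trend <- function(segregation, ages) {
  if (length(segregation) < 10) stopf("need >= 10 subjects")
  if (sd(segregation) == 0) stopf("segregation is constant; trend undefined")
  ct <- cor.test(segregation, ages)
  fit_block <- function(fit) {
    sm <- summary(fit)
    fs <- sm$fstatistic
    list(F = unname(fs[1]), df = unname(fs[2:3]),
         p = pf(fs[1], fs[2], fs[3], lower.tail = FALSE),
         coefficients = coef(fit))
  }
  lin <- lm(segregation ~ ages)
  cub <- lm(segregation ~ ages + I(ages^2) + I(ages^3))
  list(r = unname(ct$estimate), p_r = ct$p.value,
       linear = fit_block(lin), cubic = fit_block(cub))
}
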