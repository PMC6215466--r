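test_that("Fisher z transform clips perfect correlations and matches atanh", {
  expect_equal(fisher_z(0.5), atanh(0.5), tolerance = 1e-12)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_equal(fisher_z(-1), -atanh(1 - 1e-7))
})

test_that("subject connectivity matches a brute-force per-pair loop and
          handles identical and degenerate series", {
  set.seed(17)
  ts <- matrix(rnorm(20 * 40), 20, 40)
  ts[2, ] <- ts[1, ]                      # identical pair
  z <- subject_connectivity(list(timeseries = ts, usable = TRUE))
  expect_equal(z[1, 2], atanh(1 - 1e-7))  # clip ceiling
  for (i in c(3, 7)) for (j in c(5, 12)) {
    expect_equal(z[i, j], atanh(cor_oracle(ts[i, ], ts[j, ])),
                 tolerance = 1e-10)
  }
  ts2 <- ts
  ts2[4, ] <- 2.2                          # zero variance
  z2 <- suppressWarnings(subject_connectivity(list(timeseries = ts2,
                                                   usable = TRUE)))
  expect_true(all(is.na(z2[4, ])))
  expect_true(all(is.na(z2[, 4])))
})

test_that("similarity matrix equals the brute-force row correlation with
          self-entry exclusion", {
  set.seed(23)
  n <- 15
  M <- matrix(rnorm(n * n), n, n)
  M <- (M + t(M)) / 2                      # symmetric like a z-matrix
  S <- similarity_matrix(M)
  oracle <- function(i, j) {
    keep <- setdiff(seq_len(n), c(i, j))
    cor_oracle(M[i, keep], M[j, keep])
  }
  for (i in c(1, 4, 9)) for (j in c(2, 7, 15)) {
    if (i == j) next
    expect_equal(S[i, j], oracle(i, j), tolerance = 1e-10)
  }
  expect_equal(diag(S), rep(1, n))
  # duplicate rows give similarity 1
  M2 <- M
  M2[3, ] <- M2[5, ]
  M2[, 3] <- M2[, 5]
  M2[3, 3] <- M2[5, 5]
  M2[3, 5] <- M2[5, 3]
  S2 <- similarity_matrix(M2)
  expect_equal(S2[3, 5], 1, tolerance = 1e-9)
})

test_that("similarity matrix is symmetric and NA rows propagate", {
  M <- mean_zmap3()
  S <- similarity_matrix(M)
  ok <- which(!is.na(S[, 1]))[1:50]
  expect_equal(S[ok, ok], t(S[ok, ok]), tolerance = 1e-10)
  medial <- which(mesh3()$medial_wall)
  expect_true(all(is.na(S[medial, ])))
})

test_that("degenerate identity bootstrap equals the single-pass pipeline", {
  m <- mesh3()
  zl <- zmaps3()
  ident <- cohort_bootstrap_gradient(zl, m, boot_index = list(seq_along(zl)))
  # independent single pass through the stated column operations
  mz <- Reduce(`+`, zl) / length(zl)
  sim <- similarity_matrix(mz)
  sim[is.na(sim)] <- 0
  sim[m$medial_wall, ] <- 0
  gm <- gradient_magnitude(m, sim)
  gm[is.na(gm)] <- 0
  sm <- smooth_map(m, gm, 6)
  ok <- !is.na(ident) & !is.na(sm)
  expect_equal(ident[ok], sm[ok], tolerance = 1e-10)
})

test_that("bootstrap gradient is deterministic in the seed and the
          boundary pipeline is invariant to global time-series scaling", {
  m <- mesh3()
  zl <- zmaps3()
  g1 <- cohort_bootstrap_gradient(zl, m, n_boot = 4, seed = 5)
  g2 <- cohort_bootstrap_gradient(zl, m, n_boot = 4, seed = 5)
  expect_identical(g1, g2)
  g3 <- cohort_bootstrap_gradient(zl, m, n_boot = 4, seed = 6)
  expect_false(identical(g1, g3))
  # correlation invariance: scaling a subject's series leaves z-maps intact
  cl <- clean3()[[1]]
  z1 <- subject_connectivity(cl, m)
  z2 <- subject_connectivity(list(timeseries = 3.7 * cl$timeseries,
                                  usable = TRUE), m)
  expect_equal(z1, z2, tolerance = 1e-12)
})

test_that("a constructed gradient matrix with identical ridge columns
          yields a boundary map of exactly the ridge indicator", {
  m <- mesh3()
  valid <- which(!m$medial_wall)
  a <- valid[which.min(m$sphere[valid, 1])]
  b <- valid[which.max(m$sphere[valid, 1])]
  g <- igraph::graph_from_edgelist(m$edges, directed = FALSE)
  d <- igraph::distances(g, v = c(a, b), weights = m$edge_lengths)
  col <- pmin(d[1, ], d[2, ])
  ws <- watershed(m, col, c(a, b))
  G <- matrix(col, nrow(m$vertices), nrow(m$vertices))
  bm <- boundary_map(G, m, min_depth_frac = 0)
  expect_true(all(bm$values[ws$ridge] == 1))
  expect_true(all(bm$values[!ws$ridge & !m$medial_wall] == 0))
  expect_true(all(bm$values >= 0 & bm$values <= 1, na.rm = TRUE))
})

test_that("boundary conjunction counts binarized maps per vertex", {
  m <- mesh3()
  set.seed(9)
  v <- rnorm(nrow(m$vertices))
  v[m$medial_wall] <- NA
  maps <- list(v, v, v, v, v)
  cj <- boundary_conjunction(maps, 0.25)
  expect_true(all(cj[!is.na(cj)] %in% c(0L, 5L)))
  cj2 <- boundary_conjunction(maps, 1.0)
  expect_true(all(cj2[!is.na(cj2)] == 5L))
  expect_error(boundary_conjunction(list(v, v[-1]), 0.5), "meshes")
})

test_that("split-half cohorts from the same generative spec produce
          strongly correlated mean gradients", {
  # disjoint half-cohorts near the default signal-to-noise conditions
  m <- mesh3()
  sp <- cohort_spec("half", c(20, 34), 16, frames = 200,
                    motion_spike_rate = 0, seed = 19)
  subs <- simulate_cohort(m, truth3(), sp)
  zl <- lapply(subs, function(s)
    subject_connectivity(list(timeseries = s$timeseries, usable = TRUE), m))
  g1 <- cohort_bootstrap_gradient(zl[1:8], m, n_boot = 6, seed = 1)
  g2 <- cohort_bootstrap_gradient(zl[9:16], m, n_boot = 6, seed = 2)
  ok <- !is.na(g1) & !is.na(g2)
  expect_gt(cor(g1[ok], g2[ok]), 0.9)
})
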