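test_that("two cliques joined by a weak edge split into the planted
          communities; uniform complete graphs stay whole", {
  cl <- expand.grid(i = 1:5, j = 1:5)
  cl <- cl[cl$i < cl$j, ]
  edges <- rbind(
    data.frame(i = cl$i, j = cl$j, w = 1),
    data.frame(i = cl$i + 5, j = cl$j + 5, w = 1),
    data.frame(i = 5, j = 6, w = 0.1)
  )
  p <- map_equation_partition(edges, 10, seed = 3)
  expect_equal(length(unique(p$membership)), 2)
  expect_equal(length(unique(p$membership[1:5])), 1)
  expect_equal(length(unique(p$membership[6:10])), 1)
  full <- expand.grid(i = 1:6, j = 1:6)
  full <- full[full$i < full$j, ]
  full$w <- 1
  p2 <- map_equation_partition(full, 6, seed = 3)
  expect_equal(length(unique(p2$membership)), 1)
})

test_that("greedy map-equation codelength attains the exhaustive minimum
          on random graphs with up to 8 nodes", {
  set.seed(101)
  parts <- list(`5` = all_partitions(5), `7` = all_partitions(7))
  for (trial in 1:15) {
    n <- sample(c(5, 7), 1)
    repeat {
      a <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      keep <- runif(nrow(a)) < 0.5
      if (sum(keep) >= n - 1) break
    }
    edges <- data.frame(i = a[keep, 1], j = a[keep, 2],
                        w = round(runif(sum(keep), 0.1, 2), 2))
    got <- map_equation_partition(edges, n, seed = trial, n_restarts = 10)
    best <- min(vapply(parts[[as.character(n)]], function(mb)
      codelength_oracle(n, edges, mb), numeric(1)))
    expect_lte(got$codelength, best + 1e-9)
    expect_equal(got$codelength,
                 codelength_oracle(n, edges, got$membership),
                 tolerance = 1e-9)
  }
})

test_that("density thresholding keeps the exact edge count, excludes
          short-distance and negative pairs, and nests across densities", {
  set.seed(111)
  n <- 40
  z <- matrix(rnorm(n * n), n, n)
  z <- (z + t(z)) / 2
  diag(z) <- NA
  excl <- matrix(FALSE, n, n)
  excl[1, 2] <- excl[2, 1] <- TRUE
  e5 <- threshold_density(z, 0.05, excluded = excl)
  expect_equal(nrow(e5), round(0.05 * n * (n - 1) / 2))
  expect_equal(round(0.05 * 40 * 39 / 2), 39)
  expect_true(all(e5$w > 0))
  expect_false(any(e5$i == 1 & e5$j == 2))
  e10 <- threshold_density(z, 0.10, excluded = excl)
  key <- function(d) paste(d$i, d$j)
  expect_true(all(key(e5) %in% key(e10)))
  pos <- z; pos[] <- abs(z); diag(pos) <- NA
  eall <- threshold_density(pos, 1.0)
  expect_equal(nrow(eall), n * (n - 1) / 2)
  expect_identical(density_grid(),
                   c(seq(0.030, 0.050, by = 0.001), seq(0.06, 0.10, by = 0.01)))
})

test_that("parcel graphs match a brute-force mean-then-correlate oracle
          with the 20 mm exclusion", {
  m <- mesh3()
  tr <- truth3()
  cl <- clean3()[[1]]
  g <- build_graph(tr$labels, cl, m)
  expect_identical(eval(formals(build_graph)$exclusion_mm), 20)
  ids <- sort(unique(tr$labels[tr$labels > 0]))
  for (a in c(1, 4)) for (b in c(2, 9)) {
    sa <- colMeans(cl$timeseries[tr$labels == ids[a], ])
    sb <- colMeans(cl$timeseries[tr$labels == ids[b], ])
    expect_equal(g$z[a, b], atanh(cor_oracle(sa, sb)), tolerance = 1e-10)
  }
  expect_true(all(is.na(diag(g$z))))
  d12 <- sqrt(sum((g$centroids[1, ] - g$centroids[2, ])^2))
  expect_equal(g$excluded[1, 2], d12 < 20)
  # identical node series hit the Fisher clip ceiling
  cl2 <- cl
  cl2$timeseries[tr$labels == ids[2], ] <-
    rep(colMeans(cl$timeseries[tr$labels == ids[1], ]),
        each = sum(tr$labels == ids[2]))
  g2 <- build_graph(tr$labels, cl2, m)
  expect_equal(g2$z[1, 2], atanh(1 - 1e-7))
})

test_that("bootstrap modal communities recover planted systems and the
          degenerate bootstrap equals the single-sample partition", {
  m <- mesh3()
  tr <- truth3()
  graphs <- lapply(clean3(), function(cl) build_graph(tr$labels, cl, m))
  sysv <- tr$system_of_parcel
  # density chosen for the 20-node fixture graph (degree ~4, the regime
  # the percent-density grid produces at study-scale node counts)
  modal <- bootstrap_mode_communities(graphs, 0.20, n_boot = 24, seed = 5)
  expect_gte(adjusted_rand(modal, sysv), 0.8)
  # identical subjects: mode equals the single-sample partition
  same <- graphs[c(1, 1, 1)]
  mz <- graphs[[1]]$z
  edges <- threshold_density(mz, 0.10, excluded = graphs[[1]]$excluded)
  single <- map_equation_partition(edges, nrow(mz), seed = 1001)$membership
  modal2 <- bootstrap_mode_communities(same, 0.10, n_boot = 5, seed = 9)
  expect_gte(adjusted_rand(modal2, single), 0.999)
})

test_that("cross-density consensus applies the size and persistence rules
          deterministically", {
  A <- cbind(c(1, 1, 1, 1, 1, 1, 2, 2, 2, 2, 2, 2),
             c(1, 1, 1, 1, 1, 1, 2, 2, 2, 2, 2, 2),
             c(1, 1, 1, 1, 1, 1, 2, 2, 2, 2, 2, 2))
  cons <- cross_density_consensus(A, c(0.03, 0.05, 0.10), min_size = 6)
  expect_equal(cons$consensus, A[, 1])
  # a 3-node community present only at the sparsest density dissolves into
  # the community those nodes hold at denser thresholds
  B <- A
  B[1:3, 1] <- 3
  consB <- cross_density_consensus(B, c(0.03, 0.05, 0.10), min_size = 6)
  expect_equal(consB$consensus[1:3], rep(1, 3))
  expect_identical(eval(formals(cross_density_consensus)$min_size), 6L)
})

test_that("system segregation follows (Zw - Zb)/Zw with type-wise scopes
          and excludes negative edges", {
  z <- matrix(0.1, 6, 6)
  systems <- c(1, 1, 2, 2, 3, 3)
  z[1, 2] <- z[2, 1] <- 0.5
  z[3, 4] <- z[4, 3] <- 0.5
  z[5, 6] <- z[6, 5] <- 0.5
  diag(z) <- NA
  s <- system_segregation(z, systems)
  expect_equal(s$segregation, (0.5 - 0.1) / 0.5)
  z2 <- z
  z2[z2 == 0.1] <- 0.5
  expect_equal(system_segregation(z2, systems)$segregation, 0)
  # Zb = 0 after negative-edge exclusion
  z3 <- z
  z3[z3 == 0.1] <- -0.2
  expect_equal(system_segregation(z3, systems)$segregation, 1)
  st <- c("association", "association", "sensory-motor")
  sa <- system_segregation(z, systems, system_type = st, scope = "association")
  expect_equal(sa$segregation, (0.5 - 0.1) / 0.5)
  s2 <- system_segregation(z, systems, system_type = st,
                           scope = "association-to-sensory")
  expect_equal(s2$z_within, 0.5)
  expect_equal(s2$z_between, 0.1)
})

test_that("segregation-age trends recover exact linear dependence and
          reject permuted ages", {
  ages <- seq(20, 90, length.out = 120)
  seg <- 0.9 - 0.004 * ages
  tr <- suppressWarnings(segregation_age_trend(seg, ages))
  expect_equal(tr$r, -1, tolerance = 1e-12)
  expect_lt(abs(tr$cubic$coefficients["I(ages^3)"]), 1e-10)
  set.seed(121)
  seg2 <- 0.9 - 0.004 * ages + rnorm(120, 0, 0.02)
  hits <- mean(replicate(100, {
    abs(segregation_age_trend(seg2, sample(ages))$r) < 0.2
  }))
  expect_gte(hits, 0.95)
})
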