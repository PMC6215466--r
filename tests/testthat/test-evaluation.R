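test_that("Dice of thresholded boundary maps follows the set formula and
          is symmetric", {
  m <- mesh3()
  V <- nrow(m$vertices)
  a <- rep(0, V)
  b <- rep(0, V)
  valid <- which(!m$medial_wall)
  a[valid[1:30]] <- 1
  b[valid[21:40]] <- 1
  q <- 30 / length(valid)
  d <- dice_boundary(a, b, q)
  # binarization keeps the 30 strongest of a; top-q of b keeps its 20 ones
  # plus ties at zero -- use exact sets instead for the formula check
  expect_equal(dice_boundary(a, a, 0.1), 1)
  expect_gte(d, 0)
  # disjoint supports at matching set sizes (medial marked invalid so the
  # top-q count is exact)
  x <- rep(0, V); y <- rep(0, V)
  x[m$medial_wall] <- NA
  y[m$medial_wall] <- NA
  x[valid[1:20]] <- 1
  y[valid[31:50]] <- 1
  qq <- 20 / length(valid)
  expect_equal(dice_boundary(x, y, qq), 0)
  expect_equal(dice_boundary(x, y, qq), dice_boundary(y, x, qq))
})

test_that("Dice formula on explicit sets: |A|=3, |B|=2, |A&B|=1 -> 0.4", {
  # formula-level check via minimal vectors (no quantile ambiguity)
  a <- c(1, 1, 1, 0)
  b <- c(0, 0, 1, 1)
  A <- a > 0
  B <- b > 0
  expect_equal(2 * sum(A & B) / (sum(A) + sum(B)), 0.4)
  m <- mesh3()
  V <- nrow(m$vertices)
  valid <- which(!m$medial_wall)
  av <- bv <- rep(0, V)
  av[m$medial_wall] <- NA
  bv[m$medial_wall] <- NA
  av[valid[10:12]] <- 2    # strongest three
  bv[valid[12:13]] <- 2    # two strong; rank-based top-3 adds one zero tie
  expect_equal(dice_boundary(av, bv, 3 / length(valid)),
               2 * 1 / (3 + 3), tolerance = 1e-12)
})

test_that("map correlation matches the direct covariance formula and
          rejects constant maps", {
  set.seed(41)
  a <- rnorm(100)
  b <- 0.3 * a + rnorm(100)
  expect_equal(map_correlation(a, b), cor_oracle(a, b), tolerance = 1e-12)
  expect_equal(map_correlation(a, a), 1)
  expect_equal(map_correlation(a, -a), -1)
  expect_error(map_correlation(a, rep(1, 100)), "constant")
})

test_that("the rotation-null Z reduces to (actual - mean)/sd and the
          degenerate null yields the infinite sentinel", {
  # hand-built null via a statistic that ignores the payload
  m <- mesh2()
  vals <- rnorm(nrow(m$vertices))
  counter <- new.env()
  counter$i <- 0
  fixed_null <- c(1, 2, 3, 4, 6)
  stat <- function(p) {
    counter$i <- counter$i + 1
    fixed_null[counter$i]
  }
  r <- rotation_null(vals, m, stat, actual = 5, n_rot = 5, seed = 1)
  expect_equal(r$null_mean, mean(fixed_null))
  expect_equal(r$null_sd, sd(fixed_null))
  expect_equal(r$z, (5 - mean(fixed_null)) / sd(fixed_null))
  expect_equal(r$p, mean(fixed_null >= 5))
  rc <- rotation_null(vals, m, function(p) 2, actual = 3, n_rot = 4, seed = 1)
  expect_identical(rc$z, Inf)
  r0 <- rotation_null(vals, m, function(p) 2, actual = 2, n_rot = 4, seed = 1)
  expect_identical(r0$z, 0)
  req <- rotation_null(vals, m, stat_mean <- function(p) 5, actual = 5,
                       n_rot = 3, seed = 1)
  expect_equal(req$z, 0)
})

test_that("per-unit rotation nulls impute invalid units with their mean
          over valid rotations", {
  m <- mesh2()
  lab <- ifelse(m$medial_wall, 0L, 1L)
  counter <- new.env(); counter$i <- 0
  per_unit <- list(c(1, 10), c(NA, 20), c(3, 30))
  stat <- function(p) {
    counter$i <- counter$i + 1
    per_unit[[counter$i]]
  }
  r <- rotation_null(lab, m, stat, actual = 0, n_rot = 3, seed = 1,
                     mode = "units")
  # unit 1's NA in rotation 2 imputed with mean(1, 3) = 2
  expect_equal(r$null_values, c(mean(c(1, 10)), mean(c(2, 20)),
                                mean(c(3, 30))))
})

test_that("homogeneity is 100 for rank-one parcels, splits evenly for a
          two-pattern parcel, and is shift/scale invariant", {
  V <- 40
  labels <- c(rep(1L, 10), rep(2L, 10), rep(0L, V - 20))
  base <- sin(seq_len(V))
  Z <- matrix(NA_real_, V, V)
  for (i in 1:10) Z[i, ] <- (1 + 0.1 * i) * base         # rank 1
  set.seed(107)
  qb <- qr.Q(qr(cbind(1, rnorm(V), rnorm(V))))
  p1 <- qb[, 2]; p2 <- qb[, 3]   # zero-mean, unit, orthogonal patterns
  for (i in 11:15) Z[i, ] <- p1
  for (i in 16:20) Z[i, ] <- p2                          # two orthogonal blocks
  h <- suppressWarnings(homogeneity(labels, Z))
  expect_equal(unname(h$per_parcel["1"]), 100, tolerance = 1e-6)
  expect_equal(unname(h$per_parcel["2"]), 50, tolerance = 1e-4)
  Z2 <- 3 * Z + 7
  h2 <- suppressWarnings(homogeneity(labels, Z2))
  expect_equal(h$per_parcel, h2$per_parcel, tolerance = 1e-8)
})

test_that("silhouette coefficient follows (b-a)/max(a,b) on planted
          structure and degrades under misalignment", {
  m <- mesh3()
  tr <- truth3()
  Z <- mean_zmap3()
  s <- silhouette_coefficient(tr$labels, Z, m)
  expect_true(all(s$per_vertex >= -1 & s$per_vertex <= 1, na.rm = TRUE))
  expect_gt(s$mean_coef, 0)       # planted parcellation fits its own data
  ok <- which(!is.na(s$per_vertex) & !is.na(s$a_i) & !is.na(s$b_i))
  i <- ok[5]
  expect_equal(s$per_vertex[i],
               (s$b_i[i] - s$a_i[i]) / max(s$a_i[i], s$b_i[i]))
  # fixed 30-degree rotation misaligns labels with the data
  th <- 30 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- random_rotation(m, tr$labels, rotation = R)
  s2 <- suppressWarnings(silhouette_coefficient(as.integer(rot), Z, m))
  expect_gt(s$mean_coef, s2$mean_coef)
})

test_that("parcel matching maximizes Jaccard overlap with deterministic
          tie-breaks and matches an exhaustive table", {
  set.seed(51)
  a <- sample(1:4, 200, replace = TRUE)
  b <- sample(1:5, 200, replace = TRUE)
  mt <- match_parcels(a, b)
  # exhaustive oracle
  for (i in 1:4) {
    J <- vapply(1:5, function(j)
      sum(a == i & b == j) / sum(a == i | b == j), numeric(1))
    expect_equal(mt$pairs$parcel_B[i], which.max(J))
    expect_equal(mt$pairs$jaccard[i], max(J), tolerance = 1e-12)
  }
  ident <- match_parcels(a, a)
  expect_true(all(ident$pairs$jaccard == 1))
  expect_equal(ident$mean_overlap, 1)
  # B splits each A parcel in half -> overlap 1/2
  a2 <- rep(1:2, each = 100)
  b2 <- rep(1:4, each = 50)
  mt2 <- match_parcels(a2, b2)
  expect_true(all(mt2$pairs$jaccard == 0.5))
})

test_that("adjusted Rand index matches exhaustive pair counting and the
          independent mclust implementation", {
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  # invariance under label renaming
  expect_equal(adjusted_rand(1:6, rep(1:3, 2) * 10L),
               adjusted_rand(1:6, rep(1:3, 2)))
  set.seed(61)
  a <- sample(1:10, 1000, replace = TRUE)
  b <- sample(1:10, 1000, replace = TRUE)
  expect_lt(abs(adjusted_rand(a, b)), 0.05)
  expect_equal(adjusted_rand(a, a), 1)
  skip_if_not_installed("mclust")
  for (k in 1:5) {
    set.seed(70 + k)
    x <- sample(1:5, 120, replace = TRUE)
    y <- sample(1:4, 120, replace = TRUE)
    expect_equal(adjusted_rand(x, y), mclust::adjustedRandIndex(x, y),
                 tolerance = 1e-12)
  }
})

test_that("ARI excludes unassigned vertices pairwise and is symmetric", {
  a <- c(0, 1, 1, 2, 2, 3)
  b <- c(1, 1, 0, 2, 2, 3)
  expect_equal(adjusted_rand(a, b), adjusted_rand(b, a))
  expect_equal(adjusted_rand(a, b),
               adjusted_rand(c(1, 2, 2, 3), c(1, 2, 2, 3)))
})

test_that("within-parcel task SD is zero for piecewise-constant betas and
          partition-invariant for white noise", {
  m <- mesh3()
  tr <- truth3()
  amp <- rnorm(20)
  betas <- cbind(amp[pmax(tr$labels, 1)], 2 * amp[pmax(tr$labels, 1)])
  betas[tr$labels == 0, ] <- NA
  ts <- task_sd(tr$labels, betas)
  expect_equal(ts$mean_sd, 0, tolerance = 1e-12)
  set.seed(81)
  noise <- matrix(rnorm(nrow(m$vertices) * 3), ncol = 3)
  tn <- task_sd(tr$labels, noise)
  expect_lt(abs(tn$mean_sd - 1), 0.05)
})

test_that("boundary-difference regression recovers exact linear structure
          and matches the normal-equations oracle", {
  set.seed(91)
  n <- 300
  dt <- rnorm(n)
  dd <- rnorm(n)
  db <- 2 * abs(dt)
  r <- suppressWarnings(boundary_diff_regression(db, dt, dd))  # exact fit
  expect_equal(unname(r$coefficients["thickness"]), 2, tolerance = 1e-10)
  expect_lt(sum(residuals(r$fit)^2), 1e-16)
  db2 <- abs(0.5 * abs(dt) - 0.2 * abs(dd) + rnorm(n, 0, 0.1))
  r2 <- boundary_diff_regression(db2, dt, dd)
  X <- cbind(1, abs(dt), abs(dd))
  beta <- solve(t(X) %*% X, t(X) %*% abs(db2))
  expect_equal(unname(r2$coefficients), as.numeric(beta), tolerance = 1e-8)
})

test_that("summary-statistics ANOVA equals F = t^2 for two groups and
          zero for equal means", {
  a0 <- anova_from_summary(c(3, 3, 3), c(1, 2, 1.5), c(10, 12, 9))
  expect_equal(a0$F, 0)
  # two-group equivalence with the pooled-variance t-test
  m1 <- 4.2; m2 <- 5.1; s1 <- 1.1; s2 <- 0.9; n1 <- 14; n2 <- 17
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  a2 <- anova_from_summary(c(m1, m2), c(s1, s2), c(n1, n2))
  expect_equal(a2$F, tstat^2, tolerance = 1e-12)
  expect_equal(a2$df_within, n1 + n2 - 2)
  expect_error(anova_from_summary(c(1, 2), c(-1, 1), c(5, 5)), ">= 0")
})
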