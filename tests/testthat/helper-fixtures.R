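# Shared fixtures, built once per test run.  Everything is generated in
# code; meshes are memoised because geodesic caches are the slow part.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

mesh2 <- function() fixture("mesh2", function() make_sphere_mesh(2))
mesh3 <- function() fixture("mesh3", function() make_sphere_mesh(3))
mesh4 <- function() fixture("mesh4", function() make_sphere_mesh(4))

# small planted cohort on the subdivision-3 mesh (642 vertices)
truth3 <- function() fixture("truth3", function()
  plant_parcellation(mesh3(), 20, 4, seed = 3))

cohort3 <- function() fixture("cohort3", function() {
  sp <- cohort_spec("fix", c(20, 34), 8, frames = 140, seed = 5)
  simulate_cohort(mesh3(), truth3(), sp)
})

clean3 <- function() fixture("clean3", function()
  preprocess_cohort(cohort3(), mesh3()))

zmaps3 <- function() fixture("zmaps3", function()
  lapply(clean3(), subject_connectivity, mesh = mesh3()))

mean_zmap3 <- function() fixture("mean_zmap3", function()
  Reduce(`+`, zmaps3()) / length(zmaps3()))

# cohort boundary map for the small planted cohort
test_boundary_map <- function() fixture("bmap3", function() {
  grad <- cohort_bootstrap_gradient(zmaps3(), mesh3(), n_boot = 8, seed = 4)
  boundary_map(grad, mesh3())
})

test_parcellation <- function() fixture("parc3", function()
  parcellate(test_boundary_map(), mesh3()))

# evaluate `code` under a fixed seed without leaking RNG state between tests
local_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  code
}

# an independent brute-force Pearson correlation (oracle)
cor_oracle <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Independent R implementation of the two-level map equation codelength
# (kept deliberately separate from the C++ optimizer it checks).
codelength_oracle <- function(n, edges, membership) {
  W <- sum(edges$w)
  plogp <- function(x) ifelse(x > 0, x * log2(x), 0)
  p <- numeric(n)
  for (e in seq_len(nrow(edges))) {
    v <- edges$w[e] / (2 * W)
    p[edges$i[e]] <- p[edges$i[e]] + v
    p[edges$j[e]] <- p[edges$j[e]] + v
  }
  mods <- sort(unique(membership))
  q <- m <- numeric(length(mods))
  for (k in seq_along(mods)) {
    inmod <- membership == mods[k]
    m[k] <- sum(p[inmod])
    cross <- xor(inmod[edges$i], inmod[edges$j])
    q[k] <- sum(edges$w[cross]) / (2 * W)
  }
  plogp(sum(q)) - 2 * sum(plogp(q)) - sum(plogp(p)) + sum(plogp(q + m))
}

# enumerate all set partitions of 1..n (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(assign, maxlab) {
    k <- length(assign) + 1
    if (k > n) {
      out[[length(out) + 1]] <<- assign
      return()
    }
    for (lab in seq_len(maxlab + 1))
      rec(c(assign, lab), max(maxlab, lab))
  }
  rec(integer(0), 0L)
  out
}
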