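# Triangulated spherical meshes: the geometry substrate for boundary mapping.
#
# A `surface_mesh` mimics a standard-mesh cortical hemisphere (e.g. a 32k
# registered sphere): anatomical coordinates, unit-sphere coordinates, faces,
# and a medial-wall mask marking non-cortical vertices that every analysis
# step must ignore.  An icosphere is used so that spherical rotation nulls
# are exact and geodesics are well approximated by edge-graph shortest paths.

#' Build an icosphere surface mesh with a medial-wall cap
#'
#' Subdivides an icosahedron `subdivisions` times, projects vertices to a
#' sphere of radius `radius_mm`, and marks a polar cap of angular radius
#' `medial_cap_deg` around the +z pole as medial wall (a single connected
#' component, mirroring the non-cortical medial wall of registered
#' cortical meshes).  Vertex count is `10 * 4^subdivisions + 2`.
#'
#' @param subdivisions integer in `[2, 6]`; 4 gives 2562 vertices.
#' @param radius_mm sphere radius in mm (default 50, roughly a hemisphere).
#' @param medial_cap_deg angular radius of the medial-wall cap in degrees.
#' @param seed integer; kept for interface symmetry (the mesh is
#'   deterministic).
#' @return an object of class `surface_mesh`: list with `vertices` (V x 3
#'   anatomical mm), `sphere` (V x 3 unit coordinates), `faces` (F x 3,
#'   1-based), `medial_wall` (logical V), `edges` (E x 2), `edge_lengths`
#'   (mm), `radius_mm`.
#' @export
make_sphere_mesh <- function(subdivisions, radius_mm = 50, medial_cap_deg = 18,
                             seed = 1L) {
  if (length(subdivisions) != 1 || subdivisions < 2 || subdivisions > 6)
    stopf("subdivisions must be a single integer in [2, 6]")
  ico <- icosahedron()
  v <- ico$v
  f <- ico$f
  for (i in seq_len(subdivisions)) {
    s <- subdivide_once(v, f)
    v <- s$v
    f <- s$f
  }
  v <- v / sqrt(rowSums(v^2))
  edges <- faces_to_edges(f)
  medial <- acos(pmin(pmax(v[, 3], -1), 1)) <= medial_cap_deg * pi / 180
  vertices <- v * radius_mm
  el <- sqrt(rowSums((vertices[edges[, 1], , drop = FALSE] -
                      vertices[edges[, 2], , drop = FALSE])^2))
  mesh <- list(
    vertices = vertices, sphere = v, faces = f,
    medial_wall = medial, edges = edges, edge_lengths = el,
    radius_mm = radius_mm, subdivisions = subdivisions,
    cache = new.env(parent = emptyenv())
  )
  class(mesh) <- "surface_mesh"
  mesh
}

icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t,  0), c(1,  t,  0), c(-1, -t,  0), c(1, -t,  0),
    c(0, -1,  t), c(0,  1,  t), c(0, -1, -t), c(0,  1, -t),
    c(t,  0, -1), c(t,  0,  1), c(-t,  0, -1), c(-t,  0,  1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  list(v = v, f = f)
}

subdivide_once <- function(v, f) {
  nv <- nrow(v)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- (e[, 1] - 1) * nv + e[, 2]
  uk <- !duplicated(key)
  ue <- e[uk, , drop = FALSE]
  mid_id <- nv + match(key, key[uk])
  mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
  mids <- mids / sqrt(rowSums(mids^2))
  nf <- nrow(f)
  m12 <- mid_id[seq_len(nf)]
  m23 <- mid_id[nf + seq_len(nf)]
  m31 <- mid_id[2 * nf + seq_len(nf)]
  newf <- rbind(
    cbind(f[, 1], m12, m31),
    cbind(f[, 2], m23, m12),
    cbind(f[, 3], m31, m23),
    cbind(m12, m23, m31)
  )
  list(v = rbind(v, mids), f = newf)
}

faces_to_edges <- function(f) {
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[!duplicated(e), , drop = FALSE]
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf(
    "surface_mesh: %d vertices (%d medial wall), %d faces, radius %.1f mm\n",
    nrow(x$vertices), sum(x$medial_wall), nrow(x$faces), x$radius_mm))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

mesh_cached <- function(mesh, key, fn) {
  if (is.null(mesh$cache[[key]])) mesh$cache[[key]] <- fn()
  mesh$cache[[key]]
}

# 1-ring adjacency as a list of integer vectors (includes medial vertices;
# callers filter as needed).
mesh_adjacency <- function(mesh) {
  mesh_cached(mesh, "adjacency", function() {
    V <- n_vertices(mesh)
    e <- mesh$edges
    adj <- split(c(e[, 2], e[, 1]), factor(c(e[, 1], e[, 2]), levels = seq_len(V)))
    lapply(adj, as.integer)
  })
}

mesh_graph <- function(mesh) {
  mesh_cached(mesh, "graph", function() {
    g <- igraph::graph_from_edgelist(mesh$edges, directed = FALSE)
    igraph::E(g)$weight <- mesh$edge_lengths
    g
  })
}

# Geodesic distances (edge-graph shortest paths, mm) from each of `from`
# to all vertices; |from| x V matrix.
geodesic_distances <- function(mesh, from) {
  igraph::distances(mesh_graph(mesh), v = from, weights = mesh$edge_lengths)
}

# Per-vertex area: one third of each incident face's area.
vertex_areas <- function(mesh) {
  mesh_cached(mesh, "vertex_areas", function() {
    f <- mesh$faces
    p1 <- mesh$vertices[f[, 1], , drop = FALSE]
    p2 <- mesh$vertices[f[, 2], , drop = FALSE]
    p3 <- mesh$vertices[f[, 3], , drop = FALSE]
    cr <- cross3(p2 - p1, p3 - p1)
    fa <- 0.5 * sqrt(rowSums(cr^2))
    va <- numeric(n_vertices(mesh))
    for (k in 1:3) {
      t <- tapply(fa, f[, k], sum)
      va[as.integer(names(t))] <- va[as.integer(names(t))] + t
    }
    va / 3
  })
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Write / read a mesh as a plain-text TSV trio
#'
#' `vertices.tsv` (x, y, z anatomical mm), `faces.tsv` (i, j, k, 0-based),
#' `medialwall.tsv` (0/1), plus `sphere.tsv` (unit coordinates).
#'
#' @param mesh a `surface_mesh`.
#' @param dir output directory (created if missing).
#' @return `write_mesh_tsv` returns `dir` invisibly; `read_mesh_tsv`
#'   returns a `surface_mesh`.
#' @export
write_mesh_tsv <- function(mesh, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f, cn) {
    colnames(x) <- cn
    write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wt(mesh$vertices, "vertices.tsv", c("x", "y", "z"))
  wt(mesh$sphere, "sphere.tsv", c("x", "y", "z"))
  wt(mesh$faces - 1L, "faces.tsv", c("i", "j", "k"))
  wt(matrix(as.integer(mesh$medial_wall)), "medialwall.tsv", "medial")
  invisible(dir)
}

#' @rdname write_mesh_tsv
#' @export
read_mesh_tsv <- function(dir) {
  rd <- function(f) as.matrix(read.delim(file.path(dir, f)))
  vertices <- rd("vertices.tsv")
  sphere <- rd("sphere.tsv")
  faces <- rd("faces.tsv") + 1L
  storage.mode(faces) <- "integer"
  medial <- as.logical(rd("medialwall.tsv")[, 1])
  edges <- faces_to_edges(faces)
  el <- sqrt(rowSums((vertices[edges[, 1], , drop = FALSE] -
                      vertices[edges[, 2], , drop = FALSE])^2))
  mesh <- list(vertices = vertices, sphere = sphere, faces = faces,
               medial_wall = medial, edges = edges, edge_lengths = el,
               radius_mm = mean(sqrt(rowSums(vertices^2))),
               subdivisions = NA_integer_,
               cache = new.env(parent = emptyenv()))
  class(mesh) <- "surface_mesh"
  mesh
}
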