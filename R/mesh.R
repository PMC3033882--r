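#' Triangle mesh objects
#'
#' A `surf_mesh` is the shared template geometry on which all subjects'
#' per-vertex overlays live: a vertex coordinate matrix (mm), a face index
#' matrix, and (optionally cached) outward unit vertex normals. All vertex
#' indices in this package are 1-based.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param normals optional numeric matrix of outward unit vertex normals.
#' @param validate check mesh invariants (indices in range, no degenerate
#'   faces, no edge shared by more than two faces, finite coordinates).
#' @return an object of class `surf_mesh`.
#' @export
surf_mesh <- function(vertices, faces, normals = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  m <- structure(list(vertices = vertices, faces = faces, normals = normals),
                 class = "surf_mesh")
  if (validate) validate_mesh(m)
  m
}

#' @rdname surf_mesh
#' @param x object to test
#' @export
is_surf_mesh <- function(x) inherits(x, "surf_mesh")

#' @export
print.surf_mesh <- function(x, ...) {
  cat(sprintf("<surf_mesh: %d vertices, %d faces, area %.1f mm^2>\n",
              n_vertices(x), nrow(x$faces), sum(face_areas(x))))
  invisible(x)
}

#' Number of vertices of a mesh
#' @param mesh a `surf_mesh`
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

validate_mesh <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (!all(is.finite(v))) stop("mesh coordinates must be finite")
  if (nrow(f) > 0L) {
    if (min(f) < 1L || max(f) > nrow(v)) stop("face index out of range")
    if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
      stop("degenerate face (repeated vertex index)")
    # undirected edges: each may be shared by at most 2 faces
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    if (any(tabulate(factor(key)) > 2L))
      stop("non-manifold edge (shared by more than 2 faces)")
  }
  invisible(TRUE)
}

#' Undirected edge list of a mesh
#'
#' @param mesh a `surf_mesh`
#' @return integer matrix with two columns, each row one undirected edge,
#'   smaller index first, no duplicates.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

edge_lengths <- function(mesh, edges = mesh_edges(mesh)) {
  d <- mesh$vertices[edges[, 1], , drop = FALSE] -
    mesh$vertices[edges[, 2], , drop = FALSE]
  sqrt(rowSums(d * d))
}

#' One-ring vertex adjacency as a sparse matrix
#' @param mesh a `surf_mesh`
#' @return symmetric sparse 0/1 adjacency matrix.
#' @export
mesh_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  n <- n_vertices(mesh)
  Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                       x = 1, dims = c(n, n))
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  0.5 * sqrt(rowSums(cross3(a, b)^2))
}

#' Barycentric vertex areas
#'
#' Each vertex receives one third of the summed areas of its incident
#' triangles (the barycentric lumped-mass rule, robust on obtuse triangles).
#' The vertex areas sum exactly to the total mesh surface area.
#'
#' @param mesh a `surf_mesh`
#' @return numeric vector of per-vertex areas in mm^2.
#' @export
vertex_areas <- function(mesh) {
  fa <- face_areas(mesh)
  idx <- as.vector(mesh$faces)
  w <- rep(fa / 3, 3L)
  out <- numeric(n_vertices(mesh))
  agg <- rowsum(w, group = idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Outward unit vertex normals
#'
#' Area-weighted average of incident face normals (face winding defines
#' "outward"; all meshes generated by this package are counter-clockwise
#' when seen from outside).
#'
#' @param mesh a `surf_mesh`
#' @return numeric matrix of unit normals, one row per vertex.
#' @export
vertex_normals <- function(mesh) {
  if (!is.null(mesh$normals)) return(mesh$normals)
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cross3(a, b)  # |fn| = 2 * face area -> area weighting for free
  n <- matrix(0, n_vertices(mesh), 3)
  for (j in 1:3) {
    agg <- rowsum(fn, group = f[, j])
    n[as.integer(rownames(agg)), ] <- n[as.integer(rownames(agg)), ] + agg
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

mesh_graph <- function(mesh) {
  e <- mesh_edges(mesh)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::E(g)$weight <- edge_lengths(mesh, e)
  if (igraph::vcount(g) < n_vertices(mesh))
    g <- igraph::add_vertices(g, n_vertices(mesh) - igraph::vcount(g))
  g
}

#' Geodesic distance to a set of source vertices
#'
#' Shortest-path (Dijkstra) distance along mesh edges from every vertex to
#' the nearest source vertex. This is an upper bound on the true polyhedral
#' geodesic; see `Details`.
#'
#' @details The edge graph is optionally augmented with straight-line chords
#'   between second-ring neighbours (`chords = TRUE`, the default), which
#'   tightens the well-known metrication overestimate of pure edge-graph
#'   Dijkstra (up to 15% along directions between edge orientations) to a
#'   few percent on regular meshes. With `chords = FALSE` the distance is a
#'   strict upper bound on the true geodesic.
#'
#' @param mesh a `surf_mesh`
#' @param sources integer vector of source vertex indices (1-based), nonempty.
#' @param chords add 2-ring straight-line shortcut edges (default `TRUE`).
#' @return numeric vector of distances in mm; `Inf` for vertices in
#'   components containing no source.
#' @export
geodesic_distance <- function(mesh, sources, chords = TRUE) {
  sources <- as.integer(sources)
  if (length(sources) == 0L) stop("sources must be nonempty")
  n <- n_vertices(mesh)
  if (any(sources < 1L | sources > n)) stop("source vertex index out of range")
  e <- mesh_edges(mesh)
  w <- edge_lengths(mesh, e)
  if (chords) {
    e2 <- second_ring_chords(mesh)
    if (nrow(e2) > 0) {
      d <- mesh$vertices[e2[, 1], , drop = FALSE] -
        mesh$vertices[e2[, 2], , drop = FALSE]
      e <- rbind(e, e2)
      w <- c(w, sqrt(rowSums(d * d)))
    }
  }
  # virtual super-source node n+1 connected to all sources at zero cost
  e <- rbind(e, cbind(rep.int(n + 1L, length(sources)), sources))
  w <- c(w, rep(0, length(sources)))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::E(g)$weight <- w
  if (igraph::vcount(g) < n + 1L)
    g <- igraph::add_vertices(g, n + 1L - igraph::vcount(g))
  d <- igraph::distances(g, v = n + 1L, algorithm = "dijkstra")[1, ]
  unname(d[seq_len(n)])
}

# chords across each interior edge: connect the two vertices opposite a
# shared edge (the "flip" diagonal of the quad formed by two adjacent faces)
second_ring_chords <- function(mesh) {
  f <- mesh$faces
  # for each face corner, (edge, opposite vertex)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  opp <- c(f[, 3], f[, 1], f[, 2])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  sp <- split(opp, key)
  sp <- sp[lengths(sp) == 2L]
  if (length(sp) == 0L) return(matrix(integer(0), 0, 2))
  out <- matrix(unlist(sp, use.names = FALSE), ncol = 2, byrow = TRUE)
  out <- cbind(pmin(out[, 1], out[, 2]), pmax(out[, 1], out[, 2]))
  unique(out)
}

one_ring_list <- function(mesh) {
  e <- mesh_edges(mesh)
  n <- n_vertices(mesh)
  adj <- vector("list", n)
  sp1 <- split(e[, 2], e[, 1])
  sp2 <- split(e[, 1], e[, 2])
  for (k in names(sp1)) adj[[as.integer(k)]] <- c(adj[[as.integer(k)]], sp1[[k]])
  for (k in names(sp2)) adj[[as.integer(k)]] <- c(adj[[as.integer(k)]], sp2[[k]])
  adj
}

#' Icosphere mesh
#'
#' Recursively subdivided icosahedron projected onto a sphere; the standard
#' closed 2-manifold test geometry. Vertex count is `10 * 4^s + 2`.
#'
#' @param subdivisions number of 4-to-1 subdivision passes (0 = icosahedron);
#'   guarded at 7 to avoid accidental multi-gigabyte meshes.
#' @param radius sphere radius in mm.
#' @return a `surf_mesh` with outward normals.
#' @export
make_icosphere <- function(subdivisions = 3, radius = 50) {
  if (subdivisions < 0) stop("subdivisions must be >= 0")
  if (subdivisions > 7) stop("subdivisions > 7 refused (size guard)")
  if (radius <= 0) stop("radius must be positive")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    ekey <- pmin(e[, 1], e[, 2]) * (nv + 1) + pmax(e[, 1], e[, 2])
    ue <- !duplicated(ekey)
    mid_id <- integer(length(ekey))
    mid_id[ue] <- nv + seq_len(sum(ue))
    mid_id[!ue] <- mid_id[ue][match(ekey[!ue], ekey[ue])]
    mids <- (v[e[ue, 1], , drop = FALSE] + v[e[ue, 2], , drop = FALSE]) / 2
    v <- rbind(v, mids)
    nf <- nrow(f)
    m12 <- mid_id[seq_len(nf)]
    m23 <- mid_id[nf + seq_len(nf)]
    m31 <- mid_id[2 * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23),
               cbind(m12, m23, m31))
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  m <- surf_mesh(v, f, validate = FALSE)
  m$normals <- v / radius
  m
}

#' Triangulated planar grid mesh
#'
#' Regular grid in the z = 0 plane with each cell split into two triangles;
#' used for smoothing-kernel calibration checks and as a flat fixture.
#' Normals point along +z.
#'
#' @param nx,ny number of vertices along x and y.
#' @param spacing grid spacing in mm.
#' @return a `surf_mesh`.
#' @export
make_planar_grid <- function(nx, ny, spacing = 1) {
  if (nx < 2 || ny < 2) stop("grid must be at least 2 x 2")
  xs <- (seq_len(nx) - 1) * spacing
  ys <- (seq_len(ny) - 1) * spacing
  v <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)
  id <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1L), times = ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  f <- rbind(cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)),
             cbind(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L)))
  m <- surf_mesh(v, f, validate = FALSE)
  m$normals <- matrix(rep(c(0, 0, 1), each = nrow(v)), ncol = 3)
  m
}

# fingerprint used to key per-mesh caches (calibration, operators)
mesh_key <- function(mesh) {
  v <- mesh$vertices
  paste(nrow(v), nrow(mesh$faces),
        format(sum(v), digits = 17), format(sum(v * v), digits = 17),
        sep = "|")
}
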