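# Shared fixtures and independent oracles for the test suite. All oracles
# here are deliberately naive (loops, breadth-first search) so they stay
# independent of the package's igraph / Matrix code paths.

make_tetrahedron <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  surf_mesh(v, f)
}

# adjacency list built directly from faces, no package helpers
oracle_adjacency <- function(mesh) {
  n <- n_vertices(mesh)
  adj <- vector("list", n)
  for (r in seq_len(nrow(mesh$faces))) {
    tri <- mesh$faces[r, ]
    for (p in list(c(1, 2), c(2, 3), c(1, 3))) {
      a <- tri[p[1]]; b <- tri[p[2]]
      adj[[a]] <- union(adj[[a]], b)
      adj[[b]] <- union(adj[[b]], a)
    }
  }
  adj
}

# brute-force BFS connected components of a vertex subset
oracle_components <- function(mesh, members, adj = oracle_adjacency(mesh)) {
  members <- sort(members)
  seen <- logical(n_vertices(mesh))
  comps <- list()
  inset <- logical(n_vertices(mesh)); inset[members] <- TRUE
  for (s in members) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; comp <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      for (nb in adj[[v]]) {
        if (inset[nb] && !seen[nb]) { seen[nb] <- TRUE; queue <- c(queue, nb) }
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# canonical form for comparing component lists
canon_components <- function(comps) {
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, function(x) x[1], numeric(1)))]
}

# naive nearest-vertex assignment (double loop)
oracle_nearest_vertex <- function(mesh, points) {
  apply(points, 1, function(p) {
    which.min(colSums((t(mesh$vertices) - p)^2))
  })
}

# geodesic disc membership straight from the exported distance function
geodesic_disc <- function(mesh, center, radius) {
  which(geodesic_distance(mesh, center) <= radius)
}

# wrap plain z values into a minimal zmap-shaped object
as_zmap <- function(z, measure = "thickness", subject = "s") {
  structure(list(z = z, measure = measure, subject = subject), class = "zmap")
}

# cluster_set from explicit vertex sets (for metric tests)
fake_cluster_set <- function(mesh, vertex_sets, threshold = 4) {
  z <- numeric(n_vertices(mesh))
  clusters <- lapply(vertex_sets, function(vs) {
    list(vertices = sort(vs), peak_z = 5, peak_vertex = vs[1],
         area = sum(vertex_areas(mesh)[vs]), sign = "positive")
  })
  structure(list(clusters = clusters, threshold = threshold,
                 tail = "two_sided", min_area = 0, measure = "thickness",
                 subject = "s"),
            class = "cluster_set")
}
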