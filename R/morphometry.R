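# Morphometric measures computed from geometry and image intensities:
# cortical thickness, gray/white intensity contrast, offset intensity
# sampling, and discrete mean curvature.

#' Pair of corresponding white and pial surfaces
#'
#' Vertex i of the white surface corresponds to vertex i of the pial
#' surface (correspondence is assumed established upstream).
#'
#' @param white,pial `surf_mesh` objects with equal vertex counts.
#' @export
corresponding_surfaces <- function(white, pial) {
  if (n_vertices(white) != n_vertices(pial))
    stop("white and pial surfaces must have equal vertex counts")
  structure(list(white = white, pial = pial), class = "corresponding_surfaces")
}

#' Cortical thickness
#'
#' At each vertex, the average of (1) the shortest distance from the white
#' vertex to the pial surface and (2) the shortest distance from the
#' corresponding pial vertex to the white surface. Distances are true
#' point-to-triangle distances (not vertex-to-vertex), using candidate
#' triangles around the `k` nearest target vertices.
#'
#' @param surfaces a `corresponding_surfaces` pair (or the white mesh, with
#'   `pial` given separately).
#' @param pial pial mesh when `surfaces` is the white mesh.
#' @param k number of nearest target vertices whose incident triangles are
#'   searched exactly.
#' @return a `vertex_overlay` of thickness in mm (nonnegative).
#' @export
compute_thickness <- function(surfaces, pial = NULL, k = 8L) {
  if (inherits(surfaces, "corresponding_surfaces")) {
    white <- surfaces$white; pial <- surfaces$pial
  } else {
    white <- surfaces
    if (is.null(pial)) stop("pial surface required")
  }
  if (n_vertices(white) != n_vertices(pial))
    stop("white and pial surfaces must have equal vertex counts")
  if (sum(face_areas(pial)) <= 0 || sum(face_areas(white)) <= 0)
    stop("degenerate (zero-area) surface")
  d1 <- point_to_surface_distance(white$vertices, pial, k = k)
  d2 <- point_to_surface_distance(pial$vertices, white, k = k)
  vertex_overlay((d1 + d2) / 2, measure = "thickness", units = "mm")
}

# shortest distance from each query point to the target mesh surface
point_to_surface_distance <- function(points, target, k = 8L) {
  v <- target$vertices
  f <- target$faces
  k <- min(k, nrow(v))
  # faces incident to each target vertex
  finc <- split(rep(seq_len(nrow(f)), 3L), as.vector(f))
  np <- nrow(points)
  out <- numeric(np)
  chunk <- max(1L, floor(2e6 / nrow(v)))
  for (start in seq(1L, np, by = chunk)) {
    sel <- start:min(start + chunk - 1L, np)
    p <- points[sel, , drop = FALSE]
    d2 <- outer(rowSums(p^2), rowSums(v^2), "+") - 2 * p %*% t(v)
    for (r in seq_along(sel)) {
      ord <- order(d2[r, ])[seq_len(k)]
      cand <- unique(unlist(finc[as.character(ord)], use.names = FALSE))
      if (length(cand) == 0L) {  # isolated target vertices: fall back
        out[sel[r]] <- sqrt(max(0, min(d2[r, ])))
        next
      }
      tri <- f[cand, , drop = FALSE]
      out[sel[r]] <- min(point_triangle_distance(
        points[sel[r], ],
        v[tri[, 1], , drop = FALSE],
        v[tri[, 2], , drop = FALSE],
        v[tri[, 3], , drop = FALSE]))
    }
  }
  out
}

# exact distance from one point to many triangles: the closest point is the
# in-plane projection when its barycentric coordinates are all nonnegative,
# otherwise it lies on one of the three edges
point_triangle_distance <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a
  n <- cross3(ab, ac)
  nn <- rowSums(n^2)
  ap <- sweep(-a, 2, p, "+")  # p - a
  dist_seg <- function(s0, s1) {
    d <- s1 - s0
    sp <- sweep(-s0, 2, p, "+")
    t <- rowSums(sp * d) / pmax(rowSums(d * d), .Machine$double.xmin)
    t <- pmin(pmax(t, 0), 1)
    cp <- s0 + d * t
    diff <- sweep(-cp, 2, p, "+")
    rowSums(diff^2)
  }
  d2 <- pmin(dist_seg(a, b), dist_seg(b, c), dist_seg(c, a))
  ok <- nn > 0
  if (any(ok)) {
    # barycentric coordinates of the in-plane projection
    d00 <- rowSums(ab * ab); d01 <- rowSums(ab * ac); d11 <- rowSums(ac * ac)
    d20 <- rowSums(ap * ab); d21 <- rowSums(ap * ac)
    denom <- d00 * d11 - d01 * d01
    okd <- ok & denom > 0
    vb <- (d11 * d20 - d01 * d21) / denom
    wb <- (d00 * d21 - d01 * d20) / denom
    inside <- okd & vb >= 0 & wb >= 0 & (vb + wb) <= 1
    if (any(inside)) {
      plane <- (rowSums(ap * n))^2 / nn
      d2[inside] <- pmin(d2[inside], plane[inside])
    }
  }
  sqrt(pmax(d2, 0))
}

#' Sample an intensity volume at a signed offset along vertex normals
#'
#' Value at vertex v is the trilinear interpolation of the volume at
#' `v + offset * normal(v)`; positive offsets sample above the surface
#' (gray side), negative below (white side). Sample points falling outside
#' the volume are flagged missing (`NA`).
#'
#' @param volume an `intensity_volume`.
#' @param mesh a `surf_mesh` with outward unit normals (computed if absent).
#' @param offset signed offset in mm.
#' @param measure measure token for the returned overlay.
#' @return a `vertex_overlay`.
#' @export
sample_volume_at_offset <- function(volume, mesh, offset, measure = "other") {
  nrm <- vertex_normals(mesh)
  pts <- mesh$vertices + offset * nrm
  vertex_overlay(trilinear_sample(volume, pts), measure = measure)
}

trilinear_sample <- function(volume, points) {
  inv <- solve(volume$affine)
  vox <- cbind(points, 1) %*% t(inv)
  x <- vox[, 1]; y <- vox[, 2]; z <- vox[, 3]
  dm <- dim(volume$data)
  i0 <- floor(x); j0 <- floor(y); k0 <- floor(z)
  fx <- x - i0; fy <- y - j0; fz <- z - k0
  ok <- i0 >= 0 & j0 >= 0 & k0 >= 0 &
    (i0 + 1) <= (dm[1] - 1) & (j0 + 1) <= (dm[2] - 1) & (k0 + 1) <= (dm[3] - 1)
  out <- rep(NA_real_, nrow(points))
  if (!any(ok)) return(out)
  gi <- i0[ok] + 1L; gj <- j0[ok] + 1L; gk <- k0[ok] + 1L
  fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
  arr <- volume$data
  at <- function(di, dj, dk) arr[cbind(gi + di, gj + dj, gk + dk)]
  c00 <- at(0L, 0L, 0L) * (1 - fx) + at(1L, 0L, 0L) * fx
  c10 <- at(0L, 1L, 0L) * (1 - fx) + at(1L, 1L, 0L) * fx
  c01 <- at(0L, 0L, 1L) * (1 - fx) + at(1L, 0L, 1L) * fx
  c11 <- at(0L, 1L, 1L) * (1 - fx) + at(1L, 1L, 1L) * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[ok] <- c0 * (1 - fz) + c1 * fz
  out
}

#' Gray/white matter intensity contrast
#'
#' Non-normalized intensity contrast `(gray - white) / (gray + white)`
#' between samples taken just above and just below the gray/white
#' interface (conventionally 0.5 mm each way). With positive intensities
#' and white brighter than gray the contrast lies in (-1, 0); values nearer
#' zero indicate more blurring of the gray/white boundary. Vertices where
#' `gray + white = 0` are flagged missing. The measure is invariant under
#' global multiplicative intensity rescaling.
#'
#' @param gray,white per-vertex intensity overlays sampled on the same mesh.
#' @return a dimensionless `vertex_overlay` with measure `"gwc"`.
#' @export
compute_gwc <- function(gray, white) {
  g <- overlay_values(gray); w <- overlay_values(white)
  if (length(g) != length(w)) stop("gray and white overlays differ in length")
  s <- g + w
  out <- (g - w) / s
  out[!is.na(s) & s == 0] <- NA_real_
  vertex_overlay(out, measure = "gwc", units = "")
}

#' Discrete mean curvature
#'
#' Cotangent-Laplacian mean-curvature-normal magnitude with barycentric
#' vertex areas; the sign is taken from the outward normal so that
#' convex-outward regions (gyral crowns, spheres) are positive. On a sphere
#' of radius R the estimate converges to 1/R. Quantifies the "sharpness"
#' of cortical folding. Isolated vertices are flagged missing.
#'
#' @param mesh a `surf_mesh`.
#' @return a `vertex_overlay` with measure `"curv"`, units 1/mm.
#' @export
compute_mean_curvature <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  n <- n_vertices(mesh)
  # cotangent weights accumulated per half-edge, plus mixed Voronoi areas
  acc_i <- integer(0); acc_j <- integer(0); acc_w <- numeric(0)
  cots <- matrix(0, nrow(f), 3)  # cot of the angle at each corner
  for (corner in 1:3) {
    i <- f[, corner %% 3 + 1]         # edge endpoints opposite this corner
    j <- f[, (corner + 1) %% 3 + 1]
    k <- f[, corner]
    u <- v[i, , drop = FALSE] - v[k, , drop = FALSE]
    w <- v[j, , drop = FALSE] - v[k, , drop = FALSE]
    cot <- rowSums(u * w) / pmax(sqrt(rowSums(cross3(u, w)^2)), 1e-300)
    cots[, corner] <- cot
    acc_i <- c(acc_i, i, j); acc_j <- c(acc_j, j, i); acc_w <- c(acc_w, cot, cot)
  }
  W <- Matrix::sparseMatrix(i = acc_i, j = acc_j, x = acc_w / 2, dims = c(n, n))
  A <- mixed_voronoi_areas(mesh, cots)
  # with w_ij = (cot a + cot b)/2: sum w_ij (x_j - x_i) / (2A) = -H n
  lap <- as.matrix(W %*% v) - Matrix::rowSums(W) * v
  Hn <- lap / (2 * pmax(A, 1e-300))
  nrm <- vertex_normals(mesh)
  h <- sqrt(rowSums(Hn^2)) * sign(-rowSums(Hn * nrm))
  h[A == 0] <- NA_real_
  vertex_overlay(h, measure = "curv", units = "1/mm")
}

# Voronoi vertex areas with the standard mixed-area fallback for obtuse
# triangles (half the face area at the obtuse corner, a quarter elsewhere);
# used only by the curvature operator, where the Voronoi dual is the
# consistent mass so the sphere limit 1/R is met at irregular vertices too
mixed_voronoi_areas <- function(mesh, cots) {
  v <- mesh$vertices; f <- mesh$faces
  n <- n_vertices(mesh)
  fa <- face_areas(mesh)
  # squared edge lengths opposite each corner
  e2 <- matrix(0, nrow(f), 3)
  for (corner in 1:3) {
    i <- f[, corner %% 3 + 1]; j <- f[, (corner + 1) %% 3 + 1]
    e2[, corner] <- rowSums((v[i, , drop = FALSE] - v[j, , drop = FALSE])^2)
  }
  obtuse_corner <- apply(cots < 0, 1, function(x) if (any(x)) which(x)[1] else 0L)
  contrib <- matrix(0, nrow(f), 3)
  reg <- obtuse_corner == 0L
  for (corner in 1:3) {
    others <- setdiff(1:3, corner)
    # Voronoi: 1/8 * sum over the two edges at this corner of |e|^2 cot(opp)
    contrib[reg, corner] <-
      (e2[reg, others[1]] * cots[reg, others[1]] +
       e2[reg, others[2]] * cots[reg, others[2]]) / 8
    contrib[!reg, corner] <- ifelse(obtuse_corner[!reg] == corner,
                                    fa[!reg] / 2, fa[!reg] / 4)
  }
  out <- numeric(n)
  for (corner in 1:3) {
    agg <- rowsum(contrib[, corner], group = f[, corner])
    idx <- as.integer(rownames(agg))
    out[idx] <- out[idx] + agg[, 1]
  }
  out
}
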