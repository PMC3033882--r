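# Projection of volumetric lesion tracings onto the surface, and
# morphological operations on vertex sets.

#' Project a binary voxel mask onto the surface as a label
#'
#' Every nonzero voxel is assigned to its nearest surface vertex (Euclidean
#' distance between the voxel center, mapped through the volume affine, and
#' the vertex coordinates; ties broken by lowest vertex index). Because the
#' surface has sub-voxel resolution, the raw projection can leave pinholes;
#' a morphological closing fills them (see [close_label()]).
#'
#' @param mesh a `surf_mesh`.
#' @param mask an `intensity_volume` whose nonzero voxels form the mask,
#'   or a plain 3D 0/1 array (identity affine).
#' @param close_rings closing radius in one-ring steps (0 disables closing).
#' @return a `lesion_label` with source `"projected"`; empty mask gives an
#'   empty label.
#' @export
project_voxel_mask_to_label <- function(mesh, mask, close_rings = 1L) {
  if (!inherits(mask, "intensity_volume")) mask <- intensity_volume(mask)
  idx <- which(mask$data != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(lesion_label(integer(0), source = "projected"))
  # voxel centers: 0-based indices through the affine
  pts <- cbind(idx - 1, 1) %*% t(mask$affine)
  pts <- pts[, 1:3, drop = FALSE]
  nv <- nearest_vertex(mesh, pts)
  label <- lesion_label(sort(unique(nv)), source = "projected",
                        n_vertices = n_vertices(mesh))
  if (close_rings >= 1L) label <- close_label(mesh, label, rings = close_rings)
  label
}

# chunked brute-force nearest mesh vertex for a set of points; ties go to
# the lowest index (which.min semantics)
nearest_vertex <- function(mesh, points) {
  v <- mesh$vertices
  points <- matrix(points, ncol = 3)
  out <- integer(nrow(points))
  chunk <- max(1L, floor(2e6 / nrow(v)))
  for (start in seq(1L, nrow(points), by = chunk)) {
    sel <- start:min(start + chunk - 1L, nrow(points))
    p <- points[sel, , drop = FALSE]
    # squared distances via expansion; v fixed across the chunk
    d2 <- outer(rowSums(p^2), rowSums(v^2), "+") - 2 * p %*% t(v)
    out[sel] <- max.col(-d2, ties.method = "first")
  }
  out
}

#' Morphological closing of a label on the mesh
#'
#' Dilation by `rings` one-ring steps followed by erosion by the same
#' number of steps. Closing is extensive (`label` is always contained in
#' the result) and idempotent at a fixed radius; it fills enclosed holes of
#' up to roughly `rings` vertices.
#'
#' @param mesh a `surf_mesh`.
#' @param label a `lesion_label`.
#' @param rings closing radius in one-ring steps, >= 1.
#' @return a closed `lesion_label` (same source token).
#' @export
close_label <- function(mesh, label, rings = 1L) {
  if (rings < 1L) stop("rings must be >= 1")
  idx <- label_vertices(label)
  if (length(idx) == 0L) return(label)
  adj <- mesh_adjacency(mesh)
  n <- n_vertices(mesh)
  inside <- logical(n)
  inside[idx] <- TRUE
  for (i in seq_len(rings)) inside <- inside | (adj %*% inside)[, 1] > 0
  # erosion: keep vertices whose full closed one-ring stays inside
  deg <- Matrix::rowSums(adj)
  for (i in seq_len(rings)) inside <- inside & (adj %*% inside)[, 1] >= deg
  closed <- which(inside | seq_len(n) %in% idx)  # extensive by construction
  lesion_label(closed, source = attr(label, "source"), n_vertices = n)
}
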