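#' Per-vertex scalar overlays and lesion labels
#'
#' A `vertex_overlay` is a numeric vector with one value per mesh vertex and
#' two attributes: the measure name (e.g. `"thickness"`, `"gwc"`, `"lgi"`,
#' `"sulc"`, `"curv"`, `"jacobian"`) and its units (`"mm"` for thickness,
#' dimensionless for gray/white contrast, `"1/mm"` for curvature). Missing
#' values are flagged as `NA` and propagate through smoothing and z-scoring.
#'
#' @param values numeric vector, one value per vertex.
#' @param measure measure name token.
#' @param units unit string.
#' @return numeric vector of class `vertex_overlay`.
#' @export
vertex_overlay <- function(values, measure = "other", units = "") {
  structure(as.numeric(values), measure = measure, units = units,
            class = "vertex_overlay")
}

#' @rdname vertex_overlay
#' @param x an overlay (or plain numeric vector)
#' @export
overlay_measure <- function(x) {
  m <- attr(x, "measure")
  if (is.null(m)) "other" else m
}

overlay_values <- function(x) as.numeric(x)

#' Lesion label: a set of mesh vertices
#'
#' @param vertices integer vector of 1-based vertex indices; duplicates are
#'   an error (set semantics).
#' @param source one of `"manual_tracing"`, `"synthetic"`, `"projected"`.
#' @param n_vertices optional mesh vertex count for range checking.
#' @return sorted integer vector of class `lesion_label`.
#' @export
lesion_label <- function(vertices, source = "manual_tracing",
                         n_vertices = NULL) {
  v <- as.integer(vertices)
  if (anyDuplicated(v)) stop("duplicate vertex index in label")
  if (length(v) && min(v) < 1L) stop("label vertex index out of range")
  if (!is.null(n_vertices) && length(v) && max(v) > n_vertices)
    stop("label vertex index out of range for mesh")
  structure(sort(v), source = source, class = "lesion_label")
}

label_vertices <- function(label) as.integer(label)

#' @export
print.lesion_label <- function(x, ...) {
  cat(sprintf("<lesion_label: %d vertices, source=%s>\n",
              length(x), attr(x, "source")))
  invisible(x)
}

#' Intensity volume: a 3D scalar array with a voxel-to-mm affine
#'
#' The affine maps 0-based voxel indices (NIfTI convention) to surface mm
#' coordinates.
#'
#' @param data 3D numeric array.
#' @param affine 4x4 invertible matrix.
#' @export
intensity_volume <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4))) stop("affine must be 4x4")
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps)
    stop("affine must be invertible")
  structure(list(data = data, affine = affine), class = "intensity_volume")
}

#' Read / write a NIfTI intensity volume
#' @param path file path.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  intensity_volume(as.array(img), affine = unclass(RNifti::xform(img)))
}

#' @rdname read_volume
#' @param volume an `intensity_volume`.
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  RNifti::sform(img) <- structure(volume$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
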