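# FreeSurfer-dialect file I/O. All binary formats are big-endian.
# Triangle surface magic: 0xFFFFFE; curv "new format" magic: 0xFFFFFF.

TRIANGLE_MAGIC <- c(0xff, 0xff, 0xfe)
CURV_MAGIC <- c(0xff, 0xff, 0xff)

read_be_int <- function(con, n) readBin(con, "integer", n = n, size = 4L, endian = "big")
read_be_float <- function(con, n) readBin(con, "numeric", n = n, size = 4L, endian = "big")

#' Read / write a triangulated cortical surface
#'
#' Reads the binary triangle-file dialect (3-byte magic, creator comment
#' terminated by two newlines, big-endian vertex/face counts, float32
#' coordinates, int32 0-based face indices) or, as a plain-text fallback,
#' an OFF file. `write_surface` is the exact inverse: a written-then-read
#' mesh reproduces coordinates to float32 precision (byte-stable for
#' geometry fields).
#'
#' @param path file path.
#' @return a `surf_mesh`.
#' @export
read_surface <- function(path) {
  if (!file.exists(path)) stop("surface file does not exist: ", path)
  head <- readBin(path, "raw", n = 3L)
  if (length(head) == 3L && all(as.integer(head) == TRIANGLE_MAGIC)) {
    return(read_surface_binary(path))
  }
  txt <- tryCatch(readLines(path, warn = FALSE), error = function(e) NULL)
  if (!is.null(txt) && length(txt) && grepl("^OFF", trimws(txt[1]))) {
    return(read_surface_off(txt))
  }
  stop("unrecognized surface format (bad magic): ", path)
}

read_surface_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 3L)
  # creator comment: terminated by "\n\n"
  prev <- as.raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0L) stop("truncated surface file: ", path)
    if (b == as.raw(10) && prev == as.raw(10)) break
    prev <- b
  }
  counts <- read_be_int(con, 2L)
  if (length(counts) < 2L || any(counts < 0L)) stop("truncated surface file: ", path)
  nv <- counts[1]; nf <- counts[2]
  coords <- read_be_float(con, 3L * nv)
  faces <- read_be_int(con, 3L * nf)
  if (length(coords) < 3L * nv || length(faces) < 3L * nf)
    stop("truncated surface file: ", path)
  v <- matrix(coords, ncol = 3L, byrow = TRUE)
  f <- matrix(faces, ncol = 3L, byrow = TRUE) + 1L
  surf_mesh(v, f)
}

read_surface_off <- function(lines) {
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (!grepl("^OFF$", trimws(lines[1]))) stop("not an OFF file")
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  if (length(lines) < 2 + nv + nf) stop("truncated OFF file")
  v <- matrix(scan(text = lines[3:(2 + nv)], quiet = TRUE), ncol = 3, byrow = TRUE)
  frows <- lines[(3 + nv):(2 + nv + nf)]
  f <- t(vapply(frows, function(l) {
    x <- scan(text = l, quiet = TRUE)
    if (x[1] != 3) stop("only triangular OFF faces supported")
    as.integer(x[2:4]) + 1L
  }, integer(3)))
  rownames(f) <- NULL
  surf_mesh(v, f)
}

#' @rdname read_surface
#' @param mesh a `surf_mesh`.
#' @param format `"binary"` (default) or `"off"`.
#' @param comment creator comment stored in the binary header.
#' @export
write_surface <- function(mesh, path, format = c("binary", "off"),
                          comment = "created by surfmorph") {
  format <- match.arg(format)
  if (format == "off") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("OFF", con)
    writeLines(sprintf("%d %d 0", n_vertices(mesh), nrow(mesh$faces)), con)
    utils::write.table(format(mesh$vertices, digits = 9, trim = TRUE,
                              scientific = FALSE),
                       con, row.names = FALSE, col.names = FALSE, quote = FALSE)
    utils::write.table(cbind(3L, mesh$faces - 1L), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(TRIANGLE_MAGIC), con)
  writeBin(charToRaw(paste0(comment, "\n\n")), con)
  writeBin(c(n_vertices(mesh), nrow(mesh$faces)), con, size = 4L, endian = "big")
  writeBin(as.numeric(t(mesh$vertices)), con, size = 4L, endian = "big")
  writeBin(as.integer(t(mesh$faces) - 1L), con, size = 4L, endian = "big")
  invisible(path)
}

#' Read / write a per-vertex scalar overlay ("curv" new format)
#'
#' Big-endian binary: 3-byte magic, int32 vertex count, face count, values
#' per vertex (always 1 here), then float32 values. Round-trips preserve
#' values to float32 precision.
#'
#' @param path file path.
#' @param n_vertices expected vertex count of the mesh the overlay lives on;
#'   a mismatch is a consistency error.
#' @param measure,units metadata attached to the returned overlay.
#' @return a `vertex_overlay`.
#' @export
read_overlay <- function(path, n_vertices, measure = "other", units = "") {
  if (!file.exists(path)) stop("overlay file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- as.integer(readBin(con, "raw", n = 3L))
  if (length(magic) < 3L || !all(magic == CURV_MAGIC))
    stop("not a new-format curv overlay (bad magic): ", path)
  hdr <- read_be_int(con, 3L)
  if (length(hdr) < 3L) stop("truncated overlay file: ", path)
  if (hdr[3] != 1L) stop("only 1 value per vertex supported")
  if (hdr[1] != n_vertices)
    stop(sprintf("overlay has %d vertices but mesh has %d", hdr[1], n_vertices))
  vals <- read_be_float(con, hdr[1])
  if (length(vals) < hdr[1]) stop("truncated overlay file: ", path)
  vertex_overlay(vals, measure = measure, units = units)
}

#' @rdname read_overlay
#' @param overlay numeric vector of per-vertex values.
#' @param n_faces face count written to the header (metadata only).
#' @export
write_overlay <- function(overlay, path, n_faces = 0L) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(CURV_MAGIC), con)
  writeBin(c(length(overlay), as.integer(n_faces), 1L), con,
           size = 4L, endian = "big")
  writeBin(as.numeric(overlay), con, size = 4L, endian = "big")
  invisible(path)
}

#' Read / write an ASCII label (set of vertices)
#'
#' Format: one `#`-prefixed comment line, a count line, then one row per
#' vertex: 0-based index, x, y, z, value. Duplicate or out-of-range indices
#' are consistency errors.
#'
#' @param path file path.
#' @param n_vertices vertex count of the mesh (range check).
#' @param source provenance token stored on the returned label.
#' @return a `lesion_label` (1-based indices).
#' @export
read_label <- function(path, n_vertices, source = "manual_tracing") {
  if (!file.exists(path)) stop("label file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("malformed label file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || n < 0) stop("malformed label count line: ", path)
  if (length(lines) < 2L + n) stop("truncated label file: ", path)
  if (n == 0L) return(lesion_label(integer(0), source = source))
  rows <- lapply(lines[2L + seq_len(n)], function(l) {
    x <- suppressWarnings(scan(text = l, quiet = TRUE))
    if (length(x) < 1L || anyNA(x[1])) stop("malformed label row: ", l)
    x
  })
  idx0 <- vapply(rows, function(x) as.integer(x[1]), integer(1))
  if (any(idx0 < 0L) || any(idx0 >= n_vertices))
    stop("label vertex index out of range for mesh")
  lesion_label(idx0 + 1L, source = source, n_vertices = n_vertices)
}

#' @rdname read_label
#' @param label a `lesion_label`.
#' @param mesh the mesh supplying row coordinates.
#' @export
write_label <- function(label, path, mesh) {
  idx <- label_vertices(label)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#!ascii label, surfmorph (source=%s)",
                     attr(label, "source")), con)
  writeLines(as.character(length(idx)), con)
  if (length(idx)) {
    co <- mesh$vertices[idx, , drop = FALSE]
    writeLines(sprintf("%d  %.6f  %.6f  %.6f 0.000000",
                       idx - 1L, co[, 1], co[, 2], co[, 3]), con)
  }
  invisible(path)
}
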