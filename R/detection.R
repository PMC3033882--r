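# Vertex-wise normative modelling and cluster extraction: fit per-vertex
# mean/SD across a control cohort, z-score single subjects (leave-one-out
# for the controls themselves), and extract supra-threshold connected
# clusters with an area criterion.

#' Fit a vertex-wise normative model from a control cohort
#'
#' Per-vertex sample mean and unbiased (n-1) standard deviation of a
#' measure across control subjects. To avoid infinite z-scores at
#' degenerate vertices the SD is floored at a small fraction of the
#' cohort-wide median SD.
#'
#' @param cohort list of `vertex_overlay`s (one per control hemisphere, all
#'   on the same mesh and measure, already smoothed at `fwhm`), or a
#'   numeric matrix with one column per subject.
#' @param fwhm the smoothing FWHM (mm) the overlays were smoothed at;
#'   recorded on the model and enforced when scoring subjects.
#' @param sd_floor_rel floor as a fraction of the median positive SD.
#' @return an object of class `normative_model` with fields `mean`, `sd`,
#'   `n_subjects`, `fwhm`, `measure`, `sd_floor`.
#' @export
fit_normative <- function(cohort, fwhm = 0, sd_floor_rel = 1e-6) {
  x <- cohort_matrix(cohort)
  if (ncol(x) < 2L) stop("normative model needs at least 2 subjects")
  measure <- attr(x, "measure")
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  pos <- sdv[!is.na(sdv) & sdv > 0]
  base <- if (length(pos)) stats::median(pos) else 1
  floor_val <- max(sd_floor_rel * base, .Machine$double.xmin)
  sdv <- pmax(sdv, floor_val)
  structure(list(measure = measure, mean = mu, sd = sdv,
                 n_subjects = ncol(x), fwhm = fwhm, sd_floor = floor_val),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("<normative_model: %s, n=%d, fwhm=%g mm, %d vertices>\n",
              x$measure, x$n_subjects, x$fwhm, length(x$mean)))
  invisible(x)
}

# coerce a list of overlays (or a matrix) to a vertex x subject matrix,
# checking measure consistency
cohort_matrix <- function(cohort) {
  if (is.matrix(cohort)) {
    m <- attr(cohort, "measure") %||% "other"
    out <- cohort
  } else {
    if (!is.list(cohort)) cohort <- list(cohort)
    measures <- unique(vapply(cohort, overlay_measure, character(1)))
    if (length(measures) > 1L)
      stop("mixed measures in cohort: ", paste(measures, collapse = ", "))
    lens <- unique(lengths(cohort))
    if (length(lens) > 1L) stop("cohort overlays differ in length")
    out <- vapply(cohort, overlay_values, numeric(lens))
    m <- measures
  }
  attr(out, "measure") <- m
  out
}

#' z-score a single subject against a normative model
#'
#' `z = (subject - mean) / SD` per vertex. The subject overlay must be on
#' the same mesh and measure (and smoothed at the model's FWHM). Vertices
#' missing in the subject or the model are flagged missing.
#'
#' @param model a `normative_model`.
#' @param subject a `vertex_overlay`.
#' @param subject_id identifier recorded on the z-map.
#' @return an object of class `zmap` (numeric vector `z` plus metadata).
#' @export
zscore_subject <- function(model, subject, subject_id = "subject") {
  sm <- overlay_measure(subject)
  if (!identical(sm, "other") && !identical(model$measure, "other") &&
      !identical(sm, model$measure))
    stop(sprintf("measure mismatch: model is '%s', subject is '%s'",
                 model$measure, sm))
  x <- overlay_values(subject)
  if (length(x) != length(model$mean))
    stop("subject overlay length does not match model")
  structure(list(z = (x - model$mean) / model$sd,
                 measure = model$measure, subject = subject_id),
            class = "zmap")
}

#' @export
print.zmap <- function(x, ...) {
  cat(sprintf("<zmap: %s / %s, %d vertices, max |z| = %.2f>\n",
              x$subject, x$measure, length(x$z), max(abs(x$z), na.rm = TRUE)))
  invisible(x)
}

#' Leave-one-out z-maps for a control cohort
#'
#' Each control subject is compared to the entire control group less the
#' subject of interest: subject i is z-scored against the model fitted on
#' the remaining n-1 subjects.
#'
#' @inheritParams fit_normative
#' @return list of `zmap`s, one per subject.
#' @export
loo_zscores <- function(cohort, fwhm = 0, sd_floor_rel = 1e-6) {
  x <- cohort_matrix(cohort)
  n <- ncol(x)
  if (n < 3L) stop("leave-one-out needs at least 3 subjects")
  lapply(seq_len(n), function(i) {
    m <- fit_normative(structure(x[, -i, drop = FALSE],
                                 measure = attr(x, "measure")),
                       fwhm = fwhm, sd_floor_rel = sd_floor_rel)
    zscore_subject(m, vertex_overlay(x[, i], measure = attr(x, "measure")),
                   subject_id = paste0("control_", i))
  })
}

#' Extract supra-threshold clusters from a z-map
#'
#' Connected components (mesh edge adjacency) of vertices exceeding the
#' threshold, separately for positive and negative excursions, with
#' components smaller than `min_area` discarded (cluster-extent correction
#' against spurious isolated false positives). Clusters are sorted by peak
#' |z| descending, ties broken by lowest member vertex index.
#'
#' @param mesh a `surf_mesh`.
#' @param zmap a `zmap` (or numeric vector of z values).
#' @param threshold z threshold (> 0).
#' @param tail `"two_sided"` (default; positive and negative excursions
#'   clustered separately), `"positive"`, or `"negative"`.
#' @param min_area minimum cluster surface area in mm^2.
#' @return an object of class `cluster_set`: list of clusters, each with
#'   `vertices`, `peak_z` (signed), `peak_vertex`, `area`, `sign`.
#' @export
extract_clusters <- function(mesh, zmap, threshold, tail = c("two_sided",
                             "positive", "negative"), min_area = 30) {
  tail <- match.arg(tail)
  if (threshold <= 0) stop("threshold must be > 0")
  if (min_area < 0) stop("min_area must be >= 0")
  z <- if (inherits(zmap, "zmap")) zmap$z else as.numeric(zmap)
  if (length(z) != n_vertices(mesh)) stop("z-map length does not match mesh")
  A <- vertex_areas(mesh)
  adj <- mesh_adjacency(mesh)
  clusters <- list()
  grab <- function(members, sgn) {
    peak <- members[which.max(abs(z[members]))]
    list(vertices = sort(members), peak_z = z[peak], peak_vertex = peak,
         area = sum(A[members]), sign = sgn)
  }
  for (sgn in c("positive", "negative")) {
    if (tail == "positive" && sgn == "negative") next
    if (tail == "negative" && sgn == "positive") next
    supra <- if (sgn == "positive") which(!is.na(z) & z > threshold)
             else which(!is.na(z) & z < -threshold)
    if (length(supra) == 0L) next
    comp <- components_on_subset(adj, supra)
    for (members in comp) {
      cl <- grab(members, sgn)
      if (cl$area >= min_area && cl$area > 0) clusters[[length(clusters) + 1L]] <- cl
    }
  }
  if (length(clusters)) {
    peak_abs <- vapply(clusters, function(cl) abs(cl$peak_z), numeric(1))
    first_v <- vapply(clusters, function(cl) cl$vertices[1], numeric(1))
    clusters <- clusters[order(-peak_abs, first_v)]
  }
  structure(list(clusters = clusters, threshold = threshold, tail = tail,
                 min_area = min_area,
                 measure = if (inherits(zmap, "zmap")) zmap$measure else "other",
                 subject = if (inherits(zmap, "zmap")) zmap$subject else NA),
            class = "cluster_set")
}

# connected components of the subgraph induced by `subset` (igraph)
components_on_subset <- function(adj, subset) {
  sub <- adj[subset, subset, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                           diag = FALSE)
  memb <- igraph::components(g)$membership
  lapply(split(seq_along(subset), memb), function(loc) subset[loc])
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set: %d clusters (|z| > %g, tail=%s, min_area=%g mm^2)>\n",
              length(x$clusters), x$threshold, x$tail, x$min_area))
  if (length(x$clusters)) print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.cluster_set <- function(x, ...) {
  if (length(x$clusters) == 0L)
    return(data.frame(id = integer(0), peak_z = numeric(0),
                      peak_vertex = integer(0), area_mm2 = numeric(0),
                      n_vertices = integer(0), sign = character(0)))
  data.frame(
    id = seq_along(x$clusters),
    peak_z = vapply(x$clusters, function(cl) cl$peak_z, numeric(1)),
    peak_vertex = vapply(x$clusters, function(cl) cl$peak_vertex, integer(1)),
    area_mm2 = vapply(x$clusters, function(cl) cl$area, numeric(1)),
    n_vertices = vapply(x$clusters, function(cl) length(cl$vertices), integer(1)),
    sign = vapply(x$clusters, function(cl) cl$sign, character(1)))
}

#' All vertices belonging to any cluster in a set
#' @param clusters a `cluster_set`.
#' @export
cluster_vertices <- function(clusters) {
  sort(unique(unlist(lapply(clusters$clusters, function(cl) cl$vertices))))
}

#' Serialize a cluster set
#'
#' `write_cluster_report` writes a JSON cluster table (id, peak z, peak
#' vertex, area, sign, member vertices); `cluster_id_overlay` returns a
#' per-vertex overlay of cluster ids (0 = background) suitable for writing
#' in curv format.
#'
#' @param clusters a `cluster_set`.
#' @param path output JSON path.
#' @export
write_cluster_report <- function(clusters, path) {
  df <- as.data.frame(clusters)
  out <- list(threshold = clusters$threshold, tail = clusters$tail,
              min_area_mm2 = clusters$min_area, measure = clusters$measure,
              subject = clusters$subject, n_clusters = length(clusters$clusters),
              clusters = df,
              vertices = lapply(clusters$clusters, function(cl) cl$vertices))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cluster_report
#' @param mesh the mesh the clusters live on.
#' @export
cluster_id_overlay <- function(mesh, clusters) {
  out <- numeric(n_vertices(mesh))
  for (i in seq_along(clusters$clusters))
    out[clusters$clusters[[i]]$vertices] <- i
  vertex_overlay(out, measure = "cluster_id")
}

#' False-positive cluster counts in a control cohort across thresholds
#'
#' Leave-one-out z-maps for every control hemisphere, clustered at each
#' threshold; reports how many hemispheres carry at least one cluster and
#' the total cluster count. Both counts are non-increasing in threshold.
#'
#' @param mesh a `surf_mesh`.
#' @param cohort control overlays (list or matrix), pre-smoothed at `fwhm`.
#' @param thresholds numeric vector of z thresholds.
#' @param fwhm smoothing FWHM recorded on the models.
#' @param tail,min_area passed to [extract_clusters()].
#' @return data.frame with columns `threshold`, `n_flagged_hemispheres`,
#'   `n_clusters`.
#' @export
false_positive_counts <- function(mesh, cohort, thresholds, fwhm = 0,
                                  tail = "two_sided", min_area = 30) {
  if (length(thresholds) == 0L) stop("thresholds must be nonempty")
  zmaps <- loo_zscores(cohort, fwhm = fwhm)
  res <- lapply(sort(thresholds), function(th) {
    per <- vapply(zmaps, function(zm) {
      length(extract_clusters(mesh, zm, th, tail = tail,
                              min_area = min_area)$clusters)
    }, numeric(1))
    data.frame(threshold = th, n_flagged_hemispheres = sum(per > 0),
               n_clusters = sum(per))
  })
  do.call(rbind, res)
}

#' Monte-Carlo cluster-extent null
#'
#' Area of the largest supra-threshold cluster under smoothed, per-vertex
#' standardized Gaussian noise, repeated `n_sim` times; the returned
#' quantile (default 95th percentile) can be used as a data-driven
#' `min_area` in [extract_clusters()].
#'
#' @param mesh a `surf_mesh`.
#' @param fwhm smoothing FWHM in mm applied to the noise.
#' @param threshold z threshold.
#' @param n_sim number of noise simulations.
#' @param tail tail passed to clustering.
#' @param probs quantile(s) of the max-cluster-area null to return.
#' @return numeric quantile(s) of the maximum cluster area (mm^2).
#' @export
mc_cluster_extent_null <- function(mesh, fwhm, threshold, n_sim = 100,
                                   tail = "two_sided", probs = 0.95) {
  n <- n_vertices(mesh)
  n_iter <- calibrate_iterations(mesh, fwhm)
  S <- cached_operator(mesh)
  scale <- field_row_norms(mesh, n_iter)
  maxima <- vapply(seq_len(n_sim), function(i) {
    z <- apply_smoothing(S, stats::rnorm(n), n_iter)[, 1] / scale
    cs <- extract_clusters(mesh, z, threshold, tail = tail, min_area = 0)
    if (length(cs$clusters) == 0L) 0
    else max(vapply(cs$clusters, function(cl) cl$area, numeric(1)))
  }, numeric(1))
  stats::quantile(maxima, probs = probs, names = FALSE)
}

# per-vertex standard deviation of n_iter-smoothed unit white noise
# (row norms of the iterated operator), cached per mesh/iteration count
field_row_norms <- function(mesh, n_iter) {
  key <- paste0("rn|", mesh_key(mesh), "|", n_iter)
  hit <- .surfmorph_cache[[key]]
  if (!is.null(hit)) return(hit)
  S <- cached_operator(mesh)
  M <- Matrix::Diagonal(n_vertices(mesh))
  for (i in seq_len(n_iter)) M <- S %*% M
  out <- sqrt(Matrix::rowSums(M * M))
  .surfmorph_cache[[key]] <- out
  out
}
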