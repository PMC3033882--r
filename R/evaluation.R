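# Detection performance metrics: categorical and area-based sensitivity /
# specificity, measure-union detection, ROC curves, the threshold-by-
# smoothing parameter sweep, extra-lesional burden, and intracranial
# electrode classification.

#' Categorical detection: does any cluster hit the lesion?
#'
#' A patient counts as detected (true positive) when at least one
#' supra-threshold cluster shares at least one vertex with the traced
#' lesion label. An optional adjacency tolerance (geodesic mm) also counts
#' clusters whose nearest vertex lies within that distance of the lesion.
#'
#' @param clusters a `cluster_set`.
#' @param lesion a nonempty `lesion_label` on the same mesh.
#' @param mesh required only when `adjacency_mm > 0`.
#' @param adjacency_mm geodesic tolerance in mm (default 0 = strict overlap).
#' @return logical.
#' @export
categorical_detection <- function(clusters, lesion, mesh = NULL,
                                  adjacency_mm = 0) {
  lv <- label_vertices(lesion)
  if (length(lv) == 0L) stop("lesion label is empty")
  cv <- cluster_vertices(clusters)
  if (length(cv) == 0L) return(FALSE)
  if (any(cv %in% lv)) return(TRUE)
  if (adjacency_mm > 0) {
    if (is.null(mesh)) stop("mesh required for adjacency tolerance")
    d <- geodesic_distance(mesh, lv)
    return(min(d[cv]) <= adjacency_mm)
  }
  FALSE
}

#' Detection outcome for one subject and measure
#'
#' @param subject subject identifier.
#' @param measure measure name (or `"union"`).
#' @param detected logical flag (for controls: any cluster at all).
#' @param clusters the `cluster_set` behind the flag.
#' @param lesion the subject's `lesion_label`, or `NULL` for controls.
#' @export
detection_outcome <- function(subject, measure, detected, clusters,
                              lesion = NULL) {
  structure(list(subject = subject, measure = measure,
                 detected = isTRUE(detected), clusters = clusters,
                 lesion = lesion),
            class = "detection_outcome")
}

#' Combine per-measure outcomes by logical OR ("union" detection)
#'
#' Detected iff any component measure detected; the union cluster vertex
#' set is the union of the component cluster vertex sets.
#'
#' @param outcomes list of `detection_outcome`s for the same subject.
#' @return a `detection_outcome` with measure `"union"`.
#' @export
union_detection <- function(outcomes) {
  if (length(outcomes) == 0L) stop("no outcomes to combine")
  subj <- unique(vapply(outcomes, function(o) as.character(o$subject),
                        character(1)))
  if (length(subj) > 1L)
    stop("union over mixed subjects: ", paste(subj, collapse = ", "))
  det <- any(vapply(outcomes, function(o) o$detected, logical(1)))
  all_cl <- unlist(lapply(outcomes, function(o) o$clusters$clusters),
                   recursive = FALSE)
  cs <- structure(list(clusters = all_cl,
                       threshold = outcomes[[1]]$clusters$threshold,
                       tail = outcomes[[1]]$clusters$tail,
                       min_area = outcomes[[1]]$clusters$min_area,
                       measure = "union", subject = subj),
                  class = "cluster_set")
  detection_outcome(subj, "union", det, cs, outcomes[[1]]$lesion)
}

#' Categorical sensitivity and specificity
#'
#' Sensitivity = true positives / (true positives + false negatives) over
#' patients; specificity = true negatives / (true negatives + false
#' positives) over controls. Reported as percentages rounded to one
#' decimal (half away from zero).
#'
#' @param patient_flags logical vector: lesion detected per patient
#'   (hemisphere).
#' @param control_flags logical vector: any cluster at all per control
#'   (hemisphere) -- each `TRUE` is a false positive.
#' @return named numeric vector `c(sensitivity =, specificity =)` in
#'   percent.
#' @export
sens_spec <- function(patient_flags, control_flags) {
  if (length(patient_flags) == 0L || length(control_flags) == 0L)
    stop("patient and control flag vectors must be nonempty")
  sens <- 100 * sum(patient_flags) / length(patient_flags)
  spec <- 100 * sum(!control_flags) / length(control_flags)
  c(sensitivity = round_half_up(sens, 1), specificity = round_half_up(spec, 1))
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' ROC curve and area under the curve from threshold-sweep points
#'
#' Each operating point (one per threshold) is mapped to
#' (1 - specificity, sensitivity); anchors (0,0) and (1,1) are added, the
#' points sorted by x (ties resolved by keeping the maximum y), and the
#' AUC computed by the trapezoid rule.
#'
#' @param sensitivity,specificity numeric vectors in \[0, 1\].
#' @param thresholds optional thresholds labelling the points.
#' @return an object of class `roc_curve` with fields `points`
#'   (data.frame: threshold, fpr, tpr) and `auc`.
#' @export
roc_auc <- function(sensitivity, specificity, thresholds = NULL) {
  if (length(sensitivity) == 0L) stop("at least one operating point required")
  if (length(sensitivity) != length(specificity))
    stop("sensitivity and specificity lengths differ")
  if (any(sensitivity < 0 | sensitivity > 1 | specificity < 0 | specificity > 1))
    stop("sensitivity and specificity must lie in [0, 1]")
  if (is.null(thresholds)) thresholds <- rep(NA_real_, length(sensitivity))
  pts <- data.frame(threshold = c(NA, thresholds, NA),
                    fpr = c(0, 1 - specificity, 1),
                    tpr = c(0, sensitivity, 1))
  pts <- pts[order(pts$fpr, pts$tpr), ]
  # ties in x: keep the maximum y so the curve is a function of fpr
  keep <- !duplicated(pts$fpr, fromLast = TRUE)
  pts <- pts[keep, ]
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve: %d points, AUC = %.3f>\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Area-based lesion coverage metrics
#'
#' All quantities are computed on vertex surface areas (mm^2), not vertex
#' counts. Coverage ratio = supra-threshold area inside the lesion /
#' total lesion area (equals area sensitivity / 100). Area specificity is
#' the fraction of extra-lesional surface correctly left sub-threshold.
#'
#' @param mesh a `surf_mesh`.
#' @param clusters a `cluster_set` (its vertices are the supra-threshold
#'   set).
#' @param lesion a nonempty `lesion_label`.
#' @return named numeric vector `c(coverage_ratio =, area_sensitivity =,
#'   area_specificity =)`; sensitivities/specificities in percent.
#' @export
lesion_coverage_metrics <- function(mesh, clusters, lesion) {
  lv <- label_vertices(lesion)
  if (length(lv) == 0L) stop("lesion label is empty")
  A <- vertex_areas(mesh)
  cv <- cluster_vertices(clusters)
  inside <- intersect(cv, lv)
  lesion_area <- sum(A[lv])
  outside_area <- sum(A) - lesion_area
  tp <- sum(A[inside])
  fp <- sum(A[setdiff(cv, lv)])
  coverage <- tp / lesion_area
  c(coverage_ratio = coverage,
    area_sensitivity = 100 * coverage,
    area_specificity = if (outside_area > 0) 100 * (1 - fp / outside_area) else 100)
}

#' Extra-lesional cluster burden
#'
#' Combined surface area (mm^2) of significantly abnormal cluster vertices
#' falling outside the known lesion label. Together with the area inside
#' the lesion this partitions the total cluster area exactly.
#'
#' @inheritParams lesion_coverage_metrics
#' @return area in mm^2.
#' @export
extra_lesional_area <- function(mesh, clusters, lesion) {
  A <- vertex_areas(mesh)
  cv <- cluster_vertices(clusters)
  sum(A[setdiff(cv, label_vertices(lesion))])
}

#' Threshold-by-smoothing parameter sweep
#'
#' Runs the full detection pipeline over a grid of z thresholds (the
#' conventional sweep is 13 values, z = 1 to 7 in steps of 0.5) and
#' smoothing levels (FWHM 5, 9, 12 mm) for each measure and for the
#' union of thickness and gray/white contrast. Control false-positive
#' flags come from leave-one-out scoring; patient flags from categorical
#' detection against the true labels. Sensitivity is non-increasing in
#' threshold at fixed smoothing.
#'
#' @param mesh a `surf_mesh`.
#' @param patients named list (by measure) of vertex-by-patient matrices of
#'   unsmoothed overlays.
#' @param controls named list (by measure) of vertex-by-control matrices.
#' @param lesions list of `lesion_label`s, one per patient.
#' @param thresholds z thresholds (default `seq(1, 7, by = 0.5)`).
#' @param fwhms smoothing FWHMs in mm (default `c(5, 9, 12)`).
#' @param measures measures to sweep (default: names of `controls`).
#' @param union_measures measures combined by logical OR (default
#'   thickness + gwc when both present).
#' @param tail,min_area passed to [extract_clusters()].
#' @return a data.frame of class `sweep_grid`: measure, fwhm, threshold,
#'   sensitivity, specificity (percent).
#' @export
parameter_sweep <- function(mesh, patients, controls, lesions,
                            thresholds = seq(1, 7, by = 0.5),
                            fwhms = c(5, 9, 12),
                            measures = names(controls),
                            union_measures = intersect(c("thickness", "gwc"),
                                                       measures),
                            tail = "two_sided", min_area = 30) {
  if (length(measures) == 0L) stop("no measures to sweep")
  if (length(lesions) != ncol(patients[[measures[1]]]))
    stop("one lesion label required per patient")
  thresholds <- sort(thresholds)
  rows <- list()
  for (fwhm in fwhms) {
    # per measure: patient flags and control flags at each threshold
    flags_p <- list(); flags_c <- list()
    for (m in measures) {
      ctl <- smooth_matrix(mesh, controls[[m]], fwhm)
      attr(ctl, "measure") <- m
      pat <- smooth_matrix(mesh, patients[[m]], fwhm)
      model <- fit_normative(ctl, fwhm = fwhm)
      zc <- loo_zscores(ctl, fwhm = fwhm)
      zp <- lapply(seq_len(ncol(pat)), function(i)
        zscore_subject(model, vertex_overlay(pat[, i], measure = m),
                       subject_id = paste0("patient_", i)))
      fp <- matrix(FALSE, length(zp), length(thresholds))
      fc <- matrix(FALSE, length(zc), length(thresholds))
      for (ti in seq_along(thresholds)) {
        th <- thresholds[ti]
        fp[, ti] <- vapply(seq_along(zp), function(i) {
          cs <- extract_clusters(mesh, zp[[i]], th, tail = tail,
                                 min_area = min_area)
          categorical_detection(cs, lesions[[i]])
        }, logical(1))
        fc[, ti] <- vapply(zc, function(zm) {
          length(extract_clusters(mesh, zm, th, tail = tail,
                                  min_area = min_area)$clusters) > 0
        }, logical(1))
      }
      flags_p[[m]] <- fp; flags_c[[m]] <- fc
      for (ti in seq_along(thresholds)) {
        ss <- sens_spec(fp[, ti], fc[, ti])
        rows[[length(rows) + 1L]] <- data.frame(
          measure = m, fwhm = fwhm, threshold = thresholds[ti],
          sensitivity = ss[["sensitivity"]], specificity = ss[["specificity"]])
      }
    }
    if (length(union_measures) >= 2L) {
      fp <- Reduce(`|`, flags_p[union_measures])
      fc <- Reduce(`|`, flags_c[union_measures])
      for (ti in seq_along(thresholds)) {
        ss <- sens_spec(fp[, ti], fc[, ti])
        rows[[length(rows) + 1L]] <- data.frame(
          measure = "union", fwhm = fwhm, threshold = thresholds[ti],
          sensitivity = ss[["sensitivity"]], specificity = ss[["specificity"]])
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_grid", "data.frame")
  out
}

#' AUCs per measure and smoothing level from a sweep grid
#'
#' One ROC curve per (measure, fwhm) cell, built from the threshold sweep's
#' operating points.
#'
#' @param grid a `sweep_grid`.
#' @return data.frame: measure, fwhm, auc.
#' @export
sweep_auc <- function(grid) {
  cells <- unique(grid[, c("measure", "fwhm")])
  cells$auc <- vapply(seq_len(nrow(cells)), function(i) {
    g <- grid[grid$measure == cells$measure[i] & grid$fwhm == cells$fwhm[i], ]
    roc_auc(g$sensitivity / 100, g$specificity / 100, g$threshold)$auc
  }, numeric(1))
  rownames(cells) <- NULL
  cells
}

#' Classify an intracranial electrode relative to a lesion
#'
#' The electrode is snapped to the nearest surface vertex; its footprint is
#' the set of vertices within `diameter/2` geodesic mm of that vertex.
#' Classification: `"in_on"` when at least 50% of the footprint area lies
#' inside the lesion; otherwise `"adjacent"` when the snapped vertex lies
#' within `adjacent_mm` geodesic mm of the lesion; otherwise `"outside"`.
#'
#' @param mesh a `surf_mesh`.
#' @param lesion a nonempty `lesion_label`.
#' @param position numeric length-3 electrode position in surface mm space.
#' @param diameter electrode contact diameter in mm (default 4).
#' @param adjacent_mm adjacency band in mm (default 10).
#' @param snap_mm maximum distance from the surface at which the electrode
#'   can be localized; farther is an error.
#' @return one of `"in_on"`, `"adjacent"`, `"outside"`.
#' @export
classify_electrode <- function(mesh, lesion, position, diameter = 4,
                               adjacent_mm = 10, snap_mm = 10) {
  lv <- label_vertices(lesion)
  if (length(lv) == 0L) stop("lesion label is empty")
  if (diameter <= 0) stop("electrode diameter must be > 0")
  d2 <- rowSums(sweep(mesh$vertices, 2, as.numeric(position))^2)
  v0 <- which.min(d2)
  if (sqrt(d2[v0]) > snap_mm)
    stop(sprintf("electrode is %.1f mm from the surface (snap limit %.1f mm)",
                 sqrt(d2[v0]), snap_mm))
  gd <- geodesic_distance(mesh, v0)
  foot <- which(gd <= diameter / 2)
  A <- vertex_areas(mesh)
  frac_in <- sum(A[intersect(foot, lv)]) / sum(A[foot])
  if (frac_in >= 0.5) return("in_on")
  dlab <- geodesic_distance(mesh, lv)
  if (dlab[v0] <= adjacent_mm) "adjacent" else "outside"
}

#' Classify a table of electrodes
#'
#' @param mesh,lesion see [classify_electrode()].
#' @param electrodes data.frame with columns `name`, `x`, `y`, `z` (as read
#'   by [read_electrodes()]).
#' @param ... passed to [classify_electrode()].
#' @return the input data.frame with a `category` column appended.
#' @export
classify_electrodes <- function(mesh, lesion, electrodes, ...) {
  electrodes$category <- vapply(seq_len(nrow(electrodes)), function(i) {
    classify_electrode(mesh, lesion,
                       c(electrodes$x[i], electrodes$y[i], electrodes$z[i]), ...)
  }, character(1))
  electrodes
}

#' Read an electrode coordinate table (CSV: name,x,y,z in surface mm space)
#' @param path CSV path.
#' @export
read_electrodes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("electrode CSV must have columns name,x,y,z")
  df[need]
}
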