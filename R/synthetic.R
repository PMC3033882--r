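# Synthetic study generator: icosphere template meshes, normative control
# cohorts with spatially correlated per-vertex noise, and patients carrying
# implanted focal lesions of controllable geodesic radius and effect size.
# This makes the whole detection pipeline testable without any imaging data.

#' Configuration for a synthetic study
#'
#' Defaults mirror the study conditions the detection method is designed
#' for: a 41-hemisphere normative cohort, cortical-thickness-like overlays
#' (mean 2.5 mm, SD 0.3 mm) and gray/white-contrast-like overlays (mean
#' -0.25, SD 0.03), spatial noise correlation of 10 mm FWHM, and focal
#' lesions of 10 mm geodesic radius with an effect size of 6 SD.
#'
#' @param subdivisions,radius icosphere mesh spec (see [make_icosphere()]).
#' @param n_controls number of control hemispheres (>= 2).
#' @param n_patients number of lesioned patients.
#' @param measures named list; each element a list with fields `mean`
#'   (scalar or per-vertex profile), `sd` (scalar or per-vertex), and
#'   `corr_fwhm` (spatial correlation FWHM of the noise field, mm).
#' @param lesion list with fields `radius` (geodesic mm), `delta` (effect
#'   size in SD units; a scalar, or one value per patient -- `delta = 0`
#'   gives a "null patient" whose true label is still recorded), `sign`
#'   (+1 or -1), and `measures` (which measures carry the lesion; default
#'   all).
#' @param seed integer RNG seed recorded in all outputs.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(subdivisions = 4, radius = 50,
                          n_controls = 41, n_patients = 1,
                          measures = list(
                            thickness = list(mean = 2.5, sd = 0.3,
                                             corr_fwhm = 10),
                            gwc = list(mean = -0.25, sd = 0.03,
                                       corr_fwhm = 10)),
                          lesion = list(radius = 10, delta = 6, sign = 1,
                                        measures = NULL),
                          seed = 1L) {
  if (n_controls < 2) stop("n_controls must be >= 2")
  if (radius <= 0) stop("radius must be > 0")
  if (!all(is.finite(lesion$delta))) stop("lesion delta must be finite")
  if (is.null(lesion$sign)) lesion$sign <- 1
  if (is.null(lesion$measures)) lesion$measures <- names(measures)
  structure(list(subdivisions = subdivisions, radius = radius,
                 n_controls = n_controls, n_patients = n_patients,
                 measures = measures, lesion = lesion,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a synthetic cohort
#'
#' Per subject and measure, the overlay is `mean + sd * field` where
#' `field` is a unit-variance spatially correlated Gaussian field, built by
#' smoothing i.i.d. white noise with the measure's correlation-FWHM kernel
#' and re-standardizing each vertex by the exact per-vertex standard
#' deviation of the smoothed noise (the row norms of the iterated
#' operator). Patients additionally carry a lesion implanted with
#' [implant_lesion()]; lesion centers are drawn with the seeded RNG,
#' excluding vertices within two lesion radii of any previous patient's
#' lesion center. Identical config and seed give identical cohorts.
#'
#' @param config a `cohort_config`.
#' @return an object of class `synthetic_cohort`: fields `mesh`,
#'   `controls` and `patients` (named lists of vertex-by-subject matrices
#'   per measure), `labels` (list of true `lesion_label`s per patient),
#'   and `config`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop("config must be a cohort_config")
  mesh <- make_icosphere(config$subdivisions, config$radius)
  nv <- n_vertices(mesh)
  set.seed(config$seed)
  controls <- list(); patients <- list()
  for (m in names(config$measures)) {
    spec <- config$measures[[m]]
    n_tot <- config$n_controls + config$n_patients
    fields <- correlated_fields(mesh, n_tot, spec$corr_fwhm)
    ov <- spec$mean + spec$sd * fields
    controls[[m]] <- ov[, seq_len(config$n_controls), drop = FALSE]
    patients[[m]] <- ov[, config$n_controls + seq_len(config$n_patients),
                        drop = FALSE]
    attr(controls[[m]], "measure") <- m
    attr(patients[[m]], "measure") <- m
  }
  # implant lesions
  labels <- list()
  centers <- integer(0)
  les <- config$lesion
  deltas <- rep(les$delta, length.out = config$n_patients)
  for (p in seq_len(config$n_patients)) {
    eligible <- seq_len(nv)
    if (length(centers)) {
      d <- geodesic_distance(mesh, centers)
      eligible <- which(d > 2 * les$radius)
      if (length(eligible) == 0L) stop("no eligible lesion center left")
    }
    ctr <- eligible[sample.int(length(eligible), 1L)]
    centers <- c(centers, ctr)
    lab <- NULL
    for (m in les$measures) {
      spec <- config$measures[[m]]
      model <- structure(list(measure = m,
                              mean = rep(spec$mean, length.out = nv),
                              sd = rep(spec$sd, length.out = nv),
                              n_subjects = config$n_controls, fwhm = 0,
                              sd_floor = 0),
                         class = "normative_model")
      res <- implant_lesion(mesh, vertex_overlay(patients[[m]][, p],
                                                 measure = m),
                            center = ctr, radius = les$radius,
                            delta = les$sign * deltas[p], model = model)
      patients[[m]][, p] <- overlay_values(res$overlay)
      lab <- res$label
    }
    if (is.null(lab)) {  # lesion carried by no measure: still define truth
      d <- geodesic_distance(mesh, ctr)
      lab <- lesion_label(which(d <= les$radius), source = "synthetic",
                          n_vertices = nv)
    }
    labels[[p]] <- lab
  }
  structure(list(mesh = mesh, controls = controls, patients = patients,
                 labels = labels, centers = centers, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_cohort: %d controls, %d patients, ",
                     "measures: %s, seed %d>\n"),
              x$config$n_controls, x$config$n_patients,
              paste(names(x$controls), collapse = ", "), x$config$seed))
  invisible(x)
}

# n unit-variance spatially correlated fields (columns), using the
# measure's correlation FWHM; exact per-vertex standardization via the
# iterated-operator row norms
correlated_fields <- function(mesh, n, corr_fwhm) {
  nv <- n_vertices(mesh)
  noise <- matrix(stats::rnorm(nv * n), nv, n)
  if (is.null(corr_fwhm) || corr_fwhm == 0) return(noise)
  n_iter <- calibrate_iterations(mesh, corr_fwhm)
  sm <- apply_smoothing(cached_operator(mesh), noise, n_iter)
  sm / field_row_norms(mesh, n_iter)
}

#' Implant a focal lesion into an overlay
#'
#' The true label is the geodesic disc of the given radius around the
#' center vertex. Inside the label the overlay is shifted by
#' `delta * model SD`, tapered to zero at the rim by a cosine ramp over the
#' outer 20% of the radius (so the lesion boundary is not artificially
#' crisp); outside it is unchanged. Emulates focal cortical thickening or
#' gray/white junction blurring, with `delta` in SD units so effect sizes
#' are scale-free across measures.
#'
#' @param mesh a `surf_mesh`.
#' @param overlay the overlay to modify.
#' @param center lesion center vertex index.
#' @param radius geodesic lesion radius in mm (> 0).
#' @param delta signed effect size in SD units.
#' @param model a `normative_model` supplying the per-vertex SD (or a
#'   numeric SD vector/scalar).
#' @return list with fields `overlay` (modified) and `label` (the true
#'   `lesion_label`, source `"synthetic"`).
#' @export
implant_lesion <- function(mesh, overlay, center, radius, delta, model) {
  nv <- n_vertices(mesh)
  center <- as.integer(center)
  if (center < 1L || center > nv) stop("lesion center vertex out of range")
  if (radius <= 0) stop("lesion radius must be > 0")
  sdv <- if (inherits(model, "normative_model")) model$sd else model
  sdv <- rep(as.numeric(sdv), length.out = nv)
  d <- geodesic_distance(mesh, center)
  inside <- which(d <= radius)
  taper <- rep(1, length(inside))
  rim <- d[inside] > 0.8 * radius
  taper[rim] <- 0.5 * (1 + cos(pi * (d[inside][rim] - 0.8 * radius) /
                                 (0.2 * radius)))
  x <- overlay_values(overlay)
  x[inside] <- x[inside] + delta * sdv[inside] * taper
  list(overlay = vertex_overlay(x, measure = overlay_measure(overlay),
                                units = attr(overlay, "units") %||% ""),
       label = lesion_label(inside, source = "synthetic", n_vertices = nv))
}

#' Write a synthetic cohort to disk
#'
#' Writes the template surface, one curv overlay per subject and measure,
#' one ASCII label per patient, and a JSON manifest recording the config,
#' seed and file inventory. The manifest is sufficient to reload the
#' cohort with [read_cohort()].
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  surf_path <- file.path(dir, "template.surf")
  write_surface(cohort$mesh, surf_path)
  inv <- list(surface = basename(surf_path), controls = list(),
              patients = list(), labels = character(0))
  for (m in names(cohort$controls)) {
    cfiles <- character(0); pfiles <- character(0)
    for (i in seq_len(ncol(cohort$controls[[m]]))) {
      fn <- sprintf("control_%03d.%s.curv", i, m)
      write_overlay(cohort$controls[[m]][, i], file.path(dir, fn))
      cfiles <- c(cfiles, fn)
    }
    for (i in seq_len(ncol(cohort$patients[[m]]))) {
      fn <- sprintf("patient_%03d.%s.curv", i, m)
      write_overlay(cohort$patients[[m]][, i], file.path(dir, fn))
      pfiles <- c(pfiles, fn)
    }
    inv$controls[[m]] <- cfiles
    inv$patients[[m]] <- pfiles
  }
  for (p in seq_along(cohort$labels)) {
    fn <- sprintf("patient_%03d.label", p)
    write_label(cohort$labels[[p]], file.path(dir, fn), cohort$mesh)
    inv$labels <- c(inv$labels, fn)
  }
  manifest <- list(config = unclass(cohort$config), seed = cohort$config$seed,
                   inventory = inv)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' Reload a cohort written by [write_cohort()]
#' @param manifest_path path to `manifest.json`.
#' @return a `synthetic_cohort`-shaped list (mesh, controls, patients,
#'   labels, config).
#' @export
read_cohort <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  mesh <- read_surface(file.path(dir, man$inventory$surface))
  nv <- n_vertices(mesh)
  load_set <- function(files_by_measure) {
    out <- list()
    for (m in names(files_by_measure)) {
      fns <- files_by_measure[[m]]
      mat <- vapply(fns, function(fn) {
        as.numeric(read_overlay(file.path(dir, fn), nv, measure = m))
      }, numeric(nv))
      colnames(mat) <- NULL
      attr(mat, "measure") <- m
      out[[m]] <- mat
    }
    out
  }
  labels <- lapply(man$inventory$labels, function(fn)
    read_label(file.path(dir, fn), nv, source = "synthetic"))
  structure(list(mesh = mesh,
                 controls = load_set(man$inventory$controls),
                 patients = load_set(man$inventory$patients),
                 labels = labels, config = man$config),
            class = "synthetic_cohort")
}
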