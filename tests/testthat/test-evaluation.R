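# Detection metrics: categorical/area sensitivity-specificity, union,
# ROC/AUC, sweep grid, extra-lesional burden, electrode classification.

test_that("categorical detection requires one shared vertex", {
  mesh <- make_icosphere(2, 30)
  lesion <- lesion_label(geodesic_disc(mesh, 1, 10))
  far <- which.max(geodesic_distance(mesh, label_vertices(lesion)))
  cs_far <- fake_cluster_set(mesh, list(geodesic_disc(mesh, far, 5)))
  expect_false(categorical_detection(cs_far, lesion))
  cs_eq <- fake_cluster_set(mesh, list(label_vertices(lesion)))
  expect_true(categorical_detection(cs_eq, lesion))
  # overlap at exactly one vertex counts
  lv <- label_vertices(lesion)
  outside <- setdiff(seq_len(n_vertices(mesh)), lv)
  cs_one <- fake_cluster_set(mesh, list(c(lv[1], outside[1:3])))
  expect_true(categorical_detection(cs_one, lesion))
  expect_error(categorical_detection(cs_eq, lesion_label(integer(0))), "empty")
  # adjacency tolerance rescues a near-miss at the right distance
  gd <- geodesic_distance(mesh, lv)
  v_near <- which(gd > 0)[which.min(gd[gd > 0])]
  cs_near <- fake_cluster_set(mesh, list(v_near))
  expect_false(categorical_detection(cs_near, lesion))
  expect_true(categorical_detection(cs_near, lesion, mesh,
                                    adjacency_mm = gd[v_near] + 1))
  expect_false(categorical_detection(cs_near, lesion, mesh,
                                     adjacency_mm = gd[v_near] / 2))
})

test_that("union detection ORs flags and unions cluster vertex sets", {
  mesh <- make_icosphere(1, 20)
  lesion <- lesion_label(1:5)
  a <- detection_outcome("p1", "thickness", TRUE,
                         fake_cluster_set(mesh, list(1:5)), lesion)
  b <- detection_outcome("p1", "gwc", FALSE,
                         fake_cluster_set(mesh, list(20:22)), lesion)
  u <- union_detection(list(a, b))
  expect_true(u$detected)
  expect_equal(u$measure, "union")
  expect_identical(cluster_vertices(u$clusters), c(1:5, 20:22))

  none <- union_detection(list(
    detection_outcome("p1", "thickness", FALSE, fake_cluster_set(mesh, list())),
    detection_outcome("p1", "gwc", FALSE, fake_cluster_set(mesh, list()))))
  expect_false(none$detected)

  c2 <- detection_outcome("p2", "gwc", TRUE, fake_cluster_set(mesh, list(1:2)))
  expect_error(union_detection(list(a, c2)), "mixed subjects")
})

test_that("sensitivity and specificity follow their defining formulas", {
  ss <- sens_spec(c(TRUE, TRUE, FALSE, FALSE), rep(FALSE, 10))
  expect_equal(unname(ss), c(50, 100))
  ss <- sens_spec(rep(TRUE, 5), rep(TRUE, 5))
  expect_equal(unname(ss), c(100, 0))
  expect_error(sens_spec(logical(0), TRUE), "nonempty")
})

test_that("bundled example detection table reproduces its headline rates", {
  path <- system.file("extdata", "detections_example.csv",
                      package = "surfmorph")
  tab <- read.csv(path)
  expect_equal(nrow(tab), 13L)  # 13 lesional hemispheres
  union_flags <- tab$union_detected == "yes"
  sens <- sens_spec(union_flags, FALSE)[["sensitivity"]]
  expect_equal(sens, 92.3)
  expect_equal(round(sens), 92)
  # union sensitivity >= each component measure's sensitivity
  for (m in c("thickness_detected", "gwc_detected")) {
    expect_gte(sens, sens_spec(tab[[m]] == "yes", FALSE)[["sensitivity"]])
  }
  # fraction of patients with extra-lesional burden
  extra <- tapply(tab$union_extra_mm2, tab$subject, sum)
  expect_equal(sum(extra > 0), 10L)
  expect_equal(length(extra), 11L)
})

test_that("ROC construction and trapezoid AUC", {
  expect_equal(roc_auc(1, 1)$auc, 1.0)
  expect_equal(roc_auc(0.5, 0.5)$auc, 0.5)
  expect_equal(roc_auc(0.8, 0.8)$auc, 0.80)
  r <- roc_auc(c(0.9, 0.6), c(0.5, 0.9), thresholds = c(2, 4))
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  expect_true(r$auc >= 0 && r$auc <= 1)
  expect_error(roc_auc(1.2, 0.5), "\\[0, 1\\]")
  expect_error(roc_auc(numeric(0), numeric(0)), "at least one")
})

test_that("AUC invariants: perfect separation and a random detector", {
  # some threshold separates all patients from all controls -> AUC 1
  r <- roc_auc(c(1, 1, 0.4), c(0.2, 1, 1), thresholds = 1:3)
  expect_equal(r$auc, 1.0)
  # flags independent of case/control status -> AUC near 0.5
  set.seed(17)
  scores <- rnorm(400)
  is_patient <- rep(c(TRUE, FALSE), each = 200)
  ths <- seq(-2.5, 2.5, by = 0.25)
  sens <- vapply(ths, function(t) mean(scores[is_patient] > t), numeric(1))
  spec <- vapply(ths, function(t) mean(scores[!is_patient] <= t), numeric(1))
  expect_lt(abs(roc_auc(sens, spec, ths)$auc - 0.5), 0.07)
})

test_that("area-based coverage metrics work on vertex areas", {
  mesh <- make_icosphere(3, 50)
  A <- vertex_areas(mesh)
  lesion_v <- geodesic_disc(mesh, 1, 15)
  lesion <- lesion_label(lesion_v)

  full <- fake_cluster_set(mesh, list(lesion_v))
  m <- lesion_coverage_metrics(mesh, full, lesion)
  expect_equal(unname(m), c(1, 100, 100))

  none <- fake_cluster_set(mesh, list())
  m <- lesion_coverage_metrics(mesh, none, lesion)
  expect_equal(m[["coverage_ratio"]], 0)
  expect_equal(m[["area_sensitivity"]], 0)

  # half of the lesion AREA (not vertex count), built from cumulative sums
  ord <- lesion_v[order(geodesic_distance(mesh, 1)[lesion_v])]
  cum <- cumsum(A[ord])
  half_set <- ord[seq_len(which.min(abs(cum - sum(A[lesion_v]) / 2)))]
  m <- lesion_coverage_metrics(mesh, fake_cluster_set(mesh, list(half_set)),
                               lesion)
  expect_lt(abs(m[["coverage_ratio"]] - 0.5), 0.05)
  expect_equal(m[["coverage_ratio"]], m[["area_sensitivity"]] / 100)
  expect_error(lesion_coverage_metrics(mesh, full, lesion_label(integer(0))),
               "empty")
})

test_that("extra-lesional area partitions total cluster area exactly", {
  mesh <- make_icosphere(3, 50)
  A <- vertex_areas(mesh)
  lesion <- lesion_label(geodesic_disc(mesh, 1, 12))
  inside_only <- fake_cluster_set(mesh, list(label_vertices(lesion)[1:5]))
  expect_equal(extra_lesional_area(mesh, inside_only, lesion), 0)

  far <- which.max(geodesic_distance(mesh, label_vertices(lesion)))
  out_set <- geodesic_disc(mesh, far, 8)
  outside_only <- fake_cluster_set(mesh, list(out_set))
  expect_equal(extra_lesional_area(mesh, outside_only, lesion), sum(A[out_set]))

  straddle_set <- geodesic_disc(mesh, label_vertices(lesion)[1], 18)
  straddle <- fake_cluster_set(mesh, list(straddle_set))
  outside_part <- setdiff(straddle_set, label_vertices(lesion))
  expect_equal(extra_lesional_area(mesh, straddle, lesion),
               sum(A[outside_part]))
  # conservation: inside + outside = total cluster area
  inside_part <- intersect(straddle_set, label_vertices(lesion))
  expect_equal(extra_lesional_area(mesh, straddle, lesion) +
                 sum(A[inside_part]), sum(A[straddle_set]))
})

test_that("parameter sweep produces a complete, monotone grid", {
  set.seed(41)
  cfg <- cohort_config(subdivisions = 3, n_controls = 8, n_patients = 2,
                       lesion = list(radius = 12, delta = 6, sign = 1,
                                     measures = NULL), seed = 41)
  co <- simulate_cohort(cfg)
  grid <- parameter_sweep(co$mesh, co$patients, co$controls, co$labels,
                          thresholds = seq(1, 7, by = 0.5), fwhms = 5)
  expect_s3_class(grid, "sweep_grid")
  expect_setequal(unique(grid$measure), c("thickness", "gwc", "union"))
  for (m in unique(grid$measure)) {
    g <- grid[grid$measure == m, ]
    expect_equal(nrow(g), 13L)
    expect_equal(g$threshold, seq(1, 7, by = 0.5))
    expect_true(all(diff(g$sensitivity) <= 0))
  }
  # union dominance at each threshold
  for (th in unique(grid$threshold)) {
    g <- grid[grid$threshold == th, ]
    u <- g[g$measure == "union", ]
    comp <- g[g$measure != "union", ]
    expect_gte(u$sensitivity, max(comp$sensitivity))
    expect_lte(u$specificity, min(comp$specificity))
  }
  aucs <- sweep_auc(grid)
  expect_equal(nrow(aucs), 3L)
  expect_true(all(aucs$auc >= 0 & aucs$auc <= 1))
})

test_that("electrodes classify as in/on, adjacent or outside", {
  mesh <- make_icosphere(4, 50)
  center <- 1L
  lesion <- lesion_label(geodesic_disc(mesh, center, 20))
  gd_lesion <- geodesic_distance(mesh, label_vertices(lesion))

  expect_equal(classify_electrode(mesh, lesion, mesh$vertices[center, ]),
               "in_on")
  v_far <- which.min(abs(gd_lesion - 25))
  expect_equal(classify_electrode(mesh, lesion, mesh$vertices[v_far, ]),
               "outside")
  v_adj <- which.min(abs(gd_lesion - 5))
  expect_equal(classify_electrode(mesh, lesion, mesh$vertices[v_adj, ]),
               "adjacent")
  expect_error(classify_electrode(mesh, lesion, c(0, 0, 500)), "snap")
  expect_error(classify_electrode(mesh, lesion_label(integer(0)), c(0, 0, 50)),
               "empty")

  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,x,y,z",
               sprintf("E1,%f,%f,%f", mesh$vertices[center, 1],
                       mesh$vertices[center, 2], mesh$vertices[center, 3]),
               sprintf("E2,%f,%f,%f", mesh$vertices[v_far, 1],
                       mesh$vertices[v_far, 2], mesh$vertices[v_far, 3])), csv)
  out <- classify_electrodes(mesh, lesion, read_electrodes(csv))
  expect_equal(out$category, c("in_on", "outside"))
})
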