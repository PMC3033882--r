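# Surface, overlay and label file round trips plus mesh geometry utilities.

test_that("binary surface write/read round-trips geometry", {
  tet <- make_tetrahedron()
  path <- withr::local_tempfile(fileext = ".surf")
  write_surface(tet, path)
  back <- read_surface(path)
  expect_equal(n_vertices(back), 4L)
  expect_equal(nrow(back$faces), 4L)
  expect_equal(back$vertices, tet$vertices)  # +-1 are exact in float32
  expect_equal(back$faces, tet$faces)

  ico <- make_icosphere(3, 50)
  write_surface(ico, path)
  back <- read_surface(path)
  expect_equal(back$vertices, ico$vertices, tolerance = 1e-6)
  expect_identical(back$faces, ico$faces)

  # byte-stability of the geometry payload
  path2 <- withr::local_tempfile(fileext = ".surf")
  write_surface(back, path2, comment = "created by surfmorph")
  expect_identical(readBin(path, "raw", 1e6), readBin(path2, "raw", 1e6))
})

test_that("surface reader rejects wrong magic and truncation", {
  path <- withr::local_tempfile(fileext = ".surf")
  writeBin(as.raw(c(0x00, 0x01, 0x02, 0x03)), path)
  expect_error(read_surface(path), "magic|format")
  write_surface(make_tetrahedron(), path)
  sz <- file.size(path)
  truncated <- readBin(path, "raw", sz - 10)
  writeBin(truncated, path)
  expect_error(read_surface(path), "truncated")
  expect_error(read_surface(file.path(tempdir(), "nope.surf")), "exist")
})

test_that("OFF text fallback round-trips", {
  ico <- make_icosphere(1, 10)
  path <- withr::local_tempfile(fileext = ".off")
  write_surface(ico, path, format = "off")
  back <- read_surface(path)
  expect_equal(back$vertices, ico$vertices, tolerance = 1e-7)
  expect_identical(back$faces, ico$faces)
})

test_that("overlay write/read round-trips and checks vertex count", {
  path <- withr::local_tempfile(fileext = ".curv")
  write_overlay(rep(2.5, 20), path)
  expect_equal(as.numeric(read_overlay(path, 20)), rep(2.5, 20))

  set.seed(42)
  vals <- rnorm(101)
  write_overlay(vals, path)
  back <- read_overlay(path, 101, measure = "thickness")
  expect_lt(max(abs(as.numeric(back) - vals)), 1e-6)
  expect_equal(overlay_measure(back), "thickness")

  write_overlay(vals[-1], path)
  expect_error(read_overlay(path, 101), "100 vertices but mesh has 101")

  writeBin(as.raw(c(0x00, 0x00, 0x01)), path)
  expect_error(read_overlay(path, 3), "magic")
})

test_that("label write/read round-trips with set semantics", {
  mesh <- make_icosphere(1, 10)
  path <- withr::local_tempfile(fileext = ".label")
  lab <- lesion_label(c(1, 6, 10), source = "manual_tracing")
  write_label(lab, path, mesh)
  back <- read_label(path, n_vertices(mesh))
  expect_identical(label_vertices(back), c(1L, 6L, 10L))

  empty <- lesion_label(integer(0))
  write_label(empty, path, mesh)
  expect_length(label_vertices(read_label(path, n_vertices(mesh))), 0L)

  # vertex index == N (0-based row N) is out of range on an N-vertex mesh
  writeLines(c("#!ascii label", "1",
               sprintf("%d 0 0 0 0", n_vertices(mesh))), path)
  expect_error(read_label(path, n_vertices(mesh)), "out of range")

  writeLines(c("#!ascii label", "1", "abc def"), path)
  expect_error(read_label(path, n_vertices(mesh)))

  expect_error(lesion_label(c(3, 3)), "duplicate")
})

test_that("vertex areas follow the barycentric one-third rule", {
  ico <- make_icosphere(4, 50)
  expect_equal(sum(vertex_areas(ico)), 4 * pi * 50^2, tolerance = 0.01)
  # exact partition of the total triangle area
  expect_equal(sum(vertex_areas(ico)), sum(surfmorph:::face_areas(ico)),
               tolerance = 1e-12)

  tri <- surf_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)),
                   rbind(c(1, 2, 3)))
  expect_equal(vertex_areas(tri), rep(sqrt(3) / 4 / 3, 3))

  big <- tri; big$vertices <- tri$vertices * 2
  expect_equal(vertex_areas(big), 4 * vertex_areas(tri))
})

test_that("geodesic distances behave like shortest on-surface paths", {
  grid <- make_planar_grid(21, 21, 1)
  expect_error(geodesic_distance(grid, integer(0)), "nonempty")

  d <- geodesic_distance(grid, seq_len(n_vertices(grid)))
  expect_true(all(d == 0))

  d <- geodesic_distance(grid, 1)  # corner (0,0); vertex 11 is (10,0)
  expect_equal(d[11], 10)
  # never underestimates the straight-line distance on a flat mesh
  euclid <- sqrt(rowSums(sweep(grid$vertices, 2, grid$vertices[1, ])^2))
  expect_true(all(d >= euclid - 1e-9))

  # disconnected component: two separate triangles
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
             c(10, 10, 0), c(11, 10, 0), c(10, 11, 0))
  two <- surf_mesh(v, rbind(c(1, 2, 3), c(4, 5, 6)))
  d <- geodesic_distance(two, 1)
  expect_true(all(is.infinite(d[4:6])))
  expect_true(all(is.finite(d[1:3])))
})

test_that("voxel mask projection assigns nearest vertices and closes holes", {
  mesh <- make_planar_grid(11, 11, 1)
  # single voxel whose center coincides with vertex (5,5,0) = index 61
  arr <- array(0, dim = c(12, 12, 3))
  arr[6, 6, 2] <- 1
  aff <- diag(4); aff[3, 4] <- -1  # voxel (i,j,k=1) -> z = 0 plane
  vol <- intensity_volume(arr, aff)
  lab <- project_voxel_mask_to_label(mesh, vol, close_rings = 0)
  expect_identical(label_vertices(lab), 61L)

  empty <- intensity_volume(array(0, dim = c(4, 4, 4)))
  expect_length(label_vertices(project_voxel_mask_to_label(mesh, empty)), 0L)
})

test_that("spherical mask projection matches the nearest-vertex oracle", {
  mesh <- make_planar_grid(21, 21, 1)
  # ball of radius 5 mm above the patch center (10, 10, 0)
  dm <- c(25, 25, 7)
  arr <- array(0, dim = dm)
  aff <- diag(4); aff[1:3, 4] <- c(-2, -2, -3)
  for (k in seq_len(dm[3])) {
    ctr <- c(10, 10, 0)
    ijk <- as.matrix(expand.grid(i = 1:dm[1], j = 1:dm[2]))
    xyz <- cbind(ijk[, 1] - 1, ijk[, 2] - 1, k - 1) + rep(aff[1:3, 4], each = nrow(ijk))
    inside <- rowSums(sweep(xyz, 2, ctr)^2) <= 25
    arr[cbind(ijk[inside, , drop = FALSE], k)] <- 1
  }
  vol <- intensity_volume(arr, aff)
  lab <- project_voxel_mask_to_label(mesh, vol, close_rings = 0)

  vox <- which(arr != 0, arr.ind = TRUE)
  pts <- sweep(vox - 1, 2, aff[1:3, 4], "+")
  expected <- sort(unique(oracle_nearest_vertex(mesh, pts)))
  expect_identical(label_vertices(lab), as.integer(expected))

  # label area close to the patch area under the sphere (pi * 5^2)
  area <- sum(vertex_areas(mesh)[label_vertices(lab)])
  expect_lt(abs(area - pi * 25) / (pi * 25), 0.25)
})

test_that("morphological closing fills holes, is monotone and idempotent", {
  mesh <- make_icosphere(3, 50)
  disc <- geodesic_disc(mesh, 1, 15)
  # remove one interior vertex (the disc center itself)
  punctured <- setdiff(disc, 1L)
  closed <- close_label(mesh, lesion_label(punctured), rings = 1)
  expect_true(1L %in% label_vertices(closed))
  expect_true(all(punctured %in% label_vertices(closed)))

  full <- lesion_label(seq_len(n_vertices(mesh)))
  expect_identical(label_vertices(close_label(mesh, full, 1)),
                   label_vertices(full))

  expect_length(label_vertices(close_label(mesh, lesion_label(integer(0)))), 0L)

  set.seed(7)
  for (i in 1:5) {
    lab <- lesion_label(sample(n_vertices(mesh), 40))
    c1 <- close_label(mesh, lab, 1)
    expect_true(all(label_vertices(lab) %in% label_vertices(c1)))
    c2 <- close_label(mesh, c1, 1)
    expect_identical(label_vertices(c2), label_vertices(c1))
  }
  expect_error(close_label(mesh, lesion_label(1L), rings = 0), "rings")
})
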