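test_that("head_surface validates its mesh", {
  expect_error(head_surface(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                            rbind(c(1, 2, 4))), "out of range")
  expect_error(head_surface(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                            rbind(c(1, 2, 3))), "degenerate")
  expect_error(head_surface(tetra_surface()$vertices,
                            tetra_surface()$triangles,
                            fiducials = list(nasion = c(50, 50, 50),
                                             lpa = c(0, 0, 0),
                                             rpa = c(1, 0, 0))),
               "within 2 mm")
})

test_that("headshape_set enforces roles and fiducial labels", {
  pts <- matrix(stats::rnorm(18), 6, 3)
  roles <- c("fiducial", "fiducial", "fiducial", "headshape", "headshape",
             "hpi")
  hs <- headshape_set(pts, roles)
  expect_equal(hs$n, 2)
  expect_error(headshape_set(pts, rep("headshape", 6)), "nasion")
  expect_error(headshape_set(pts, roles,
                             fiducial_labels = c("nasion", "nasion", "rpa")),
               "nasion")
  expect_error(headshape_set(pts, c(roles[-6], "scalp")), "roles must be")
})

test_that("point-to-surface distance handles vertex, face and offset cases", {
  sq <- unit_square_surface()
  expect_equal(nearest_surface_distances(matrix(c(1, 1, 0), 1),
                                         sq)$distances, 0)
  h <- c(0.5, 2, 7.25)
  for (hh in h) {
    expect_equal(nearest_surface_distances(matrix(c(0.25, 0.25, hh), 1),
                                           sq)$distances, hh)
  }
  # beyond the square's edge the distance picks up the lateral component
  d <- nearest_surface_distances(matrix(c(2, 0.5, 1), 1), sq)
  expect_equal(d$distances, sqrt(2))
  expect_equal(drop(d$closest), c(1, 0.5, 0))
})

test_that("distance equals the exhaustive all-triangle oracle", {
  set.seed(71)
  meshes <- list(unit_square_surface(), tetra_surface(),
                 icosahedron_surface(2))
  for (s in meshes) {
    ctr <- colMeans(s$vertices)
    span <- max(abs(sweep(s$vertices, 2, ctr))) * 2.5
    q <- sweep(matrix(stats::runif(150, -span, span), 50, 3), 2, ctr, "+")
    got <- nearest_surface_distances(q, s)$distances
    expect_equal(got, unname(oracle_mesh_distance(q, s)), tolerance = 1e-12)
  }
})

test_that("distance from the centre of a regular icosahedron is its inradius", {
  edge <- 2
  s <- icosahedron_surface(edge)
  inradius <- edge * sqrt(3) / 12 * (3 + sqrt(5))
  expect_equal(nearest_surface_distances(matrix(0, 1, 3), s)$distances,
               inradius, tolerance = 1e-12)
})

test_that("distances are equivariant under rigid motion", {
  set.seed(81)
  s <- icosahedron_surface(3)
  q <- matrix(stats::rnorm(60, sd = 3), 20, 3)
  base <- nearest_surface_distances(q, s)$distances
  for (i in 1:5) {
    tr <- oracle_random_rigid()
    s2 <- head_surface(apply_transform(tr, s$vertices), s$triangles)
    moved <- nearest_surface_distances(apply_transform(tr, q), s2)$distances
    expect_equal(moved, base, tolerance = 1e-9)
  }
})

test_that("defacing removes the nose but not the crown, and is idempotent", {
  spec <- subject_spec(seed = 5, subdivisions = 3L)
  s <- generate_head_surface(spec)
  def <- deface(s)

  expect_lt(nrow(def$vertices), nrow(s$vertices))
  # the nose tip (most anterior point) must be gone
  tip <- s$vertices[which.max(
    apply_transform(fiducial_frame(s$fiducials), s$vertices)[, 2]), ]
  gaps <- nearest_surface_distances(matrix(tip, 1), def)$distances
  expect_gt(gaps, 1)
  # the vertex-most scalp point survives with identical coordinates
  crown <- s$vertices[which.max(
    apply_transform(fiducial_frame(s$fiducials), s$vertices)[, 3]), ]
  expect_equal(nearest_surface_distances(matrix(crown, 1), def)$distances, 0)

  again <- deface(def)
  expect_identical(again$vertices, def$vertices)
  expect_identical(again$triangles, def$triangles)

  # surviving vertices are a subset with unchanged coordinates
  key <- function(v) apply(round(v, 9), 1, paste, collapse = "/")
  expect_true(all(key(def$vertices) %in% key(s$vertices)))
})

test_that("defacing errors when it would gut the mesh or lacks fiducials", {
  s <- icosahedron_surface(3)
  expect_error(deface(s), "fiducials")
  spec <- subject_spec(seed = 5, subdivisions = 3L)
  sh <- generate_head_surface(spec)
  expect_error(deface(sh, behind_nasion = 500, above_nasion = 500),
               "degenerate")
})

test_that("PLY round-trips are exact (ascii and binary little-endian)", {
  s <- tetra_surface()
  for (binary in c(FALSE, TRUE)) {
    path <- withr::local_tempfile(fileext = ".ply")
    write_surface(s, path, binary = binary)
    back <- read_surface(path)
    expect_identical(back$vertices, s$vertices)
    expect_identical(back$triangles, s$triangles)
  }
})

test_that("the reader accepts foreign ascii PLY with float vertices", {
  # hand-written file, independent of write_surface
  txt <- c("ply", "format ascii 1.0", "comment exported elsewhere",
           "element vertex 4",
           "property float x", "property float y", "property float z",
           "element face 2", "property list uchar int vertex_indices",
           "end_header",
           "0 0 0", "1 0 0", "1 1 0", "0 1 0",
           "3 0 1 2", "3 0 2 3")
  path <- withr::local_tempfile(fileext = ".ply")
  writeLines(txt, path)
  s <- read_surface(path)
  expect_equal(s$vertices[3, ], c(1, 1, 0))
  expect_equal(nrow(s$triangles), 2)
  expect_equal(nearest_surface_distances(matrix(c(0.5, 0.5, 2), 1),
                                         s)$distances, 2)
})

test_that("OBJ triangles load; quads are an explicit format error", {
  path <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1/1 2/2 3/3"), path)
  s <- read_surface(path)
  expect_equal(nrow(s$triangles), 1)

  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0", "f 1 2 3 4"),
             path)
  expect_error(read_surface(path), "non-triangular")

  ply_quad <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 4",
               "property double x", "property double y", "property double z",
               "element face 1", "property list uchar int vertex_indices",
               "end_header", "0 0 0", "1 0 0", "1 1 0", "0 1 0",
               "4 0 1 2 3"), ply_quad)
  expect_error(read_surface(ply_quad), "non-triangular")
})

test_that("fiducial sidecars travel with the mesh; missing sidecar is soft", {
  spec <- subject_spec(seed = 7, subdivisions = 3L)
  s <- generate_head_surface(spec)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "head.ply")
  write_surface(s, path)
  back <- read_surface(path)
  expect_equal(back$fiducials, s$fiducials, tolerance = 1e-15)

  file.remove(file.path(dir, "head.json"))
  bare <- read_surface(path)
  expect_null(bare$fiducials)
  expect_error(deface(bare), "fiducials")
})

test_that("surface IO preserves distances through a full round-trip", {
  spec <- subject_spec(seed = 9, subdivisions = 3L)
  s <- generate_head_surface(spec)
  hs <- generate_headshape(s, spec)
  pts <- apply_transform(invert(spec$ground_truth),
                         hs$points[hs$roles == "headshape", ])
  before <- nearest_surface_distances(pts, s)$distances
  path <- withr::local_tempfile(fileext = ".ply")
  write_surface(s, path, binary = TRUE)
  after <- nearest_surface_distances(pts, read_surface(path))$distances
  expect_equal(after, before, tolerance = 1e-12)
})

test_that("headshape text files round-trip including roles and labels", {
  spec <- subject_spec(seed = 3, subdivisions = 3L)
  s <- generate_head_surface(spec)
  hs <- generate_headshape(s, spec)
  path <- withr::local_tempfile(fileext = ".txt")
  write_headshape(hs, path)
  back <- read_headshape(path)
  expect_identical(back$points, hs$points)
  expect_identical(back$roles, hs$roles)
  expect_identical(back$fiducial_labels, hs$fiducial_labels)
  expect_identical(back$n, hs$n)
})
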