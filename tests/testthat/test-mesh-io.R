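test_that("minimal ASCII STL parses to one triangle", {
  f <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid t", "  facet normal 0 0 1", "    outer loop",
               "      vertex 0 0 0", "      vertex 1 0 0",
               "      vertex 0 1 0", "    endloop", "  endfacet",
               "endsolid t"), f)
  m <- load_mesh(f)
  expect_equal(n_vertices(m), 3)
  expect_equal(n_faces(m), 1)
  expect_equal(m$vertices[2, ], c(1, 0, 0))
})

test_that("STL round trips in both encodings and splits quads area-true", {
  m <- quad_mesh()
  fa <- withr::local_tempfile(fileext = ".stl")
  save_mesh(m, fa, format = "stl")
  ra <- load_mesh(fa)
  expect_equal(n_faces(ra), 2)   # quad triangulated on STL export
  expect_equal(sum(mesh_face_areas(ra)), sum(mesh_face_areas(m)),
               tolerance = 1e-9)
  fb <- withr::local_tempfile(fileext = ".stl")
  save_mesh(m, fb, format = "stl_binary")
  rb <- load_mesh(fb)
  expect_equal(sum(mesh_face_areas(rb)), sum(mesh_face_areas(m)),
               tolerance = 1e-6)  # float32 storage
  expect_lt(max(abs(sort(rb$vertices[, 3]) - sort(m$vertices[, 3]))), 1e-5)
})

test_that("OBJ retains quad faces and round trips within 1e-6 mm", {
  m <- quad_mesh()
  f <- withr::local_tempfile(fileext = ".obj")
  save_mesh(m, f)
  r <- load_mesh(f)
  expect_equal(n_faces(r), 1)
  expect_false(is.na(r$faces[1, 4]))   # still a quad
  expect_lt(max(abs(r$vertices - m$vertices)), 1e-6)
})

test_that("PLY round trips exactly with per-face scalar fields", {
  m <- random_tri_mesh(20)
  stress <- stats::runif(n_faces(m), 0, 120)
  for (fmt in c("ply", "ply_binary")) {
    f <- withr::local_tempfile(fileext = ".ply")
    save_mesh(m, f, format = fmt, scalar_fields = list(sigma1 = stress))
    r <- load_mesh(f)
    expect_equal(n_faces(r), n_faces(m))
    expect_lt(max(abs(r$vertices - m$vertices)), 1e-6)
    expect_identical(attr(r, "scalars")$sigma1, stress)  # bit-exact doubles
  }
})

test_that("scalar field length mismatches are dimension errors", {
  f <- withr::local_tempfile(fileext = ".ply")
  expect_error(save_mesh(tri_mesh(), f, scalar_fields = list(s = c(1, 2))),
               "length")
  # empty scalar list writes plain geometry
  save_mesh(tri_mesh(), f, scalar_fields = NULL)
  expect_equal(n_faces(load_mesh(f)), 1)
})

test_that("unreadable files produce located format errors", {
  f <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid x", "  facet normal 0 0 1", "    outer loop",
               "      vertex 0 0 zero", "      vertex 1 0 0",
               "      vertex 0 1 0", "    endloop", "endsolid"), f)
  expect_error(load_mesh(f), "line 4")
  expect_error(load_mesh(withr::local_tempfile(fileext = ".ply")), "")
  g <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("# empty"), g)
  expect_error(load_mesh(g), "empty mesh")
  expect_error(load_mesh("does-not-exist.stl"), "not found")
})

test_that("VTK export writes polydata with cell scalars", {
  m <- quad_mesh()
  f <- withr::local_tempfile(fileext = ".vtk")
  save_mesh(m, f, scalar_fields = list(sigma1 = 3.5))
  txt <- readLines(f)
  expect_true(any(grepl("^DATASET POLYDATA", txt)))
  expect_true(any(grepl("^POLYGONS 1 5", txt)))
  expect_true(any(grepl("^CELL_DATA 1", txt)))
  expect_true(any(grepl("^SCALARS sigma1 double", txt)))
})
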