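test_that("mesh validation rejects malformed input", {
  expect_error(surface_mesh(matrix(0, 0, 3), matrix(1L, 1, 3)), "empty")
  expect_error(surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                            matrix(c(1L, 2L, 4L), 1)), "out of range")
  expect_error(surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                            matrix(c(1L, 1L, 3L), 1)), "degenerate")
  expect_error(surface_mesh(diag(3), rbind(c(1L, 2L, 3L, 2L))), "degenerate")
})

test_that("quads triangulate along the shortest diagonal and conserve area", {
  m <- quad_mesh()   # 1 x 2 rectangle: shortest diagonal is ambiguous-free
  tg <- triangulate_mesh(m)
  expect_equal(nrow(tg$tris), 2)
  expect_equal(tg$face_map, c(1L, 1L))
  expect_equal(mesh_face_areas(m), 2)
  # a skewed quad: total area equals the sum of its two split triangles
  mq <- surface_mesh(rbind(c(0, 0, 0), c(2, 0.5, 0), c(2.2, 2, 0), c(0, 1.8, 0)),
                     matrix(1:4, 1))
  tg2 <- triangulate_mesh(mq)
  v <- tg2$vertices
  areas <- sapply(seq_len(2), function(i) {
    p <- v[tg2$tris[i, ], ]
    0.5 * sqrt(sum(pracma::cross(p[2, ] - p[1, ], p[3, ] - p[1, ])^2))
  })
  expect_equal(mesh_face_areas(mq), sum(areas), tolerance = 1e-12)
})

test_that("face normals follow the winding and are unit length", {
  m <- quad_mesh()
  n <- mesh_face_normals(m)
  expect_equal(as.numeric(n), c(0, 1, 0), tolerance = 1e-12)
  expect_equal(sqrt(sum(mesh_face_normals(tri_mesh())^2)), 1, tolerance = 1e-12)
})

test_that("mean-filter smoothing leaves a plane invariant and flattens a spike", {
  plane <- mesh_plane(2, 2, edge = 0.25, quads = FALSE)
  sm <- smooth_mesh(plane, iterations = 3, weight = 1)
  # interior vertices of a flat grid are fixed points of the mean filter
  expect_lt(max(abs(sm$vertices[, 2] - plane$vertices[, 2])), 1e-9)

  spiked <- plane
  # spike an interior vertex by +1 mm
  interior <- which(abs(plane$vertices[, 1]) < 0.6 &
                      abs(plane$vertices[, 3]) < 0.6)[1]
  spiked$vertices[interior, 2] <- 1
  once <- smooth_mesh(spiked, iterations = 1, weight = 1)
  # full-weight mean filter sends the spike to its neighbour mean (flat)
  expect_lt(abs(once$vertices[interior, 2]), 1e-9)

  expect_identical(smooth_mesh(spiked, iterations = 0), spiked)
})

test_that("smoothing is contractive on convex shapes", {
  cap <- mesh_sphere_cap(5, c(0, 5, 0), cap_angle = pi / 3, edge = 0.5)
  sm <- smooth_mesh(cap, iterations = 5, weight = 0.8)
  vol <- function(m) prod(apply(m$vertices, 2, function(x) diff(range(x))))
  expect_lte(vol(sm), vol(cap) + 1e-12)
})

test_that("smoothing warns on isolated vertices and leaves them unmoved", {
  m <- tri_mesh()
  m$vertices <- rbind(m$vertices, c(9, 9, 9))   # unreferenced vertex
  expect_warning(sm <- smooth_mesh(m, 1, 1), "isolated")
  expect_equal(sm$vertices[4, ], c(9, 9, 9))
})

test_that("smoothing argument contracts are enforced", {
  expect_error(smooth_mesh(tri_mesh(), iterations = -1), "iterations")
  expect_error(smooth_mesh(tri_mesh(), 1, weight = 0), "weight")
  expect_error(smooth_mesh(tri_mesh(), 1, weight = 1.5), "weight")
})
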