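test_that("spatial index answers plane queries exactly", {
  plane <- mesh_plane(2, 2, edge = 1, quads = FALSE)  # small 2x2 plane
  idx <- build_spatial_index(plane)
  g <- signed_gap(c(0.4, 5, 0.4), idx, cutoff = Inf)
  expect_equal(g$gap, 5)
  g2 <- signed_gap(rbind(c(0.2, 1, 0.3), c(0.2, -0.2, 0.3)), idx,
                   cutoff = Inf)
  expect_equal(g2$gap, c(1, -0.2))
  expect_error(build_spatial_index(
    surface_mesh(matrix(0, 1, 3), matrix(1L, 0, 3))), "empty")
})

test_that("indexed queries equal exhaustive search on random meshes", {
  m <- random_tri_mesh(200, seed = 5)
  idx <- build_spatial_index(m)
  set.seed(6)
  q <- matrix(stats::runif(300, -6, 6), ncol = 3)
  a <- signed_gap(q, idx, cutoff = Inf)
  b <- brute_force_signed_gap(q, m)
  expect_identical(a$face, b$face)
  expect_lt(max(abs(a$gap - b$gap)), 1e-12)
})

test_that("a stale spatial index raises a version error", {
  m <- generate_synthetic_dentition(small_arch())
  idx <- build_spatial_index(m$upper)
  m$upper$vertices[1, 2] <- m$upper$vertices[1, 2] + 0.1
  expect_error(resolve_frame(m, identity_transform(), idx), "stale")
})

test_that("far points carry the sentinel and are excluded from contact", {
  plane <- mesh_plane(2, 2, edge = 1, quads = FALSE)
  idx <- build_spatial_index(plane)
  g <- signed_gap(rbind(c(0, 7, 0), c(0, 2, 0)), idx, cutoff = 5)
  expect_identical(g$gap[1], Inf)
  expect_equal(g$gap[2], 2)
  expect_equal(penalty_pressure(g$gap, 100), c(0, 0))
})

test_that("a sphere apex pressed past a plane reads the programmed depth", {
  sph <- mesh_sphere_cap(10, c(0, 10 - 0.1, 0), edge = 0.1)
  idx <- build_spatial_index(sph)
  plane <- mesh_plane(4, 4, edge = 0.1)
  g <- signed_gap(mesh_face_centroids(plane), idx, cutoff = Inf)
  expect_equal(min(g$gap), -0.100, tolerance = 0.005)
})

test_that("foundation stiffness follows k = E/((1-nu^2) h)", {
  expect_equal(foundation_stiffness(material_params()), 84000 / 0.91 / 2,
               tolerance = 1e-12)
  expect_equal(foundation_stiffness(material_params(nu = 0)),
               84000 / 2)
  k1 <- foundation_stiffness(material_params(h_mm = 1))
  k2 <- foundation_stiffness(material_params(h_mm = 2))
  expect_equal(k1, 2 * k2)
  expect_error(material_params(h_mm = -1), "thickness")
})

test_that("penalty pressure is zero when separated and linear in penetration", {
  expect_equal(penalty_pressure(0.3, 100), 0)
  expect_equal(penalty_pressure(-0.01, 100), 1.0)
  pens <- penalty_pressure(-c(0.01, 0.02, 0.05), 100)
  expect_true(all(diff(pens) > 0))
  expect_error(penalty_pressure(-0.1, 0), "stiffness")
})

test_that("Coulomb traction obeys the friction cone and the no-slip convention", {
  fr <- friction_traction(10, c(1, 0, 0), mu = 0.1)
  expect_equal(fr$tau, 1.0)
  expect_equal(fr$direction[1, ], c(-1, 0, 0))   # opposes slip
  expect_equal(friction_traction(0, c(1, 0, 0), 0.1)$tau, 0)
  expect_equal(friction_traction(10, c(0, 0, 0), 0.1)$tau, 0)
  set.seed(3)
  p <- stats::runif(50, 0, 20)
  slip <- matrix(stats::rnorm(150), ncol = 3)
  fr2 <- friction_traction(p, slip, 0.1)
  expect_true(all(fr2$tau <= 0.1 * p + 1e-9))
})

test_that("maximum principal stress is the Mohr's-circle major value", {
  expect_equal(max_principal_stress(3, 2), 4.0)
  expect_equal(max_principal_stress(7, 0), 7)
  expect_equal(max_principal_stress(0, 1), 1.0)
  p <- stats::runif(20, 0, 10); tau <- stats::runif(20, 0, 1)
  s1 <- max_principal_stress(p, tau)
  expect_true(all(s1 >= pmax(p, tau) - 1e-12))
})

test_that("resolve_frame satisfies complementarity and force consistency", {
  m <- generate_synthetic_dentition(small_arch(centric_gap = 0.5))
  idx <- build_spatial_index(m$upper)
  # clench into the penalty layer
  st <- resolve_frame(m, compose_transform(translation = c(0, 0.8, 0)), idx)
  expect_gt(sum(st$contact), 0)
  # complementarity: p and the positive part of the signed gap never coexist
  gpos <- pmax(st$g, 0); gpos[!is.finite(st$g)] <- 1
  expect_equal(max(st$p * gpos), 0)
  expect_equal(st$total_force, sum(st$p * st$area), tolerance = 1e-6)
  expect_true(all(st$sigma1 >= pmax(st$p, st$tau) - 1e-9))
  # p = 0 exactly where there is no penetration
  expect_true(all((st$p > 0) == (st$pen > 0)))

  # separated arches: a valid empty contact state, not an error
  st0 <- resolve_frame(m, identity_transform(), idx)
  expect_equal(st0$contact_area, 0)
  expect_equal(st0$total_force, 0)
  expect_equal(max(st0$sigma1), 0)
})

test_that("the foundation solver reproduces the Winkler sphere force", {
  delta <- 0.1
  sph <- mesh_sphere_cap(10, c(0, 10 - delta, 0), edge = 0.2)
  plane <- mesh_plane(6, 6, edge = 0.15)
  mm <- dentition_model(sph, plane, rep(0L, n_faces(sph)),
                        rep(0L, n_faces(plane)))
  st <- resolve_frame(mm, identity_transform(), build_spatial_index(sph),
                      k = 100)
  expect_equal(st$total_force, 100 * pi * 10 * delta^2, tolerance = 0.03)
})
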