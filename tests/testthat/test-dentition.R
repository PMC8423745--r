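test_that("material parameter invariants are enforced", {
  m <- material_params()
  expect_equal(m$E_gpa, 84)
  expect_equal(m$nu, 0.3)
  expect_equal(m$mu, 0.1)
  expect_error(material_params(E_gpa = -1), "modulus")
  expect_error(material_params(nu = 0.5), "Poisson")
  expect_error(material_params(mu = -0.1), "friction")
  expect_error(material_params(h_mm = 0), "thickness")
})

test_that("generated cusp tips sit at the programmed centric gap", {
  m0 <- generate_synthetic_dentition(small_arch(centric_gap = 0))
  g0 <- apex_gaps(m0)
  expect_lt(max(abs(g0$gap)), 0.01)   # tangential contact at every cusp

  m5 <- generate_synthetic_dentition(small_arch(centric_gap = 0.5))
  expect_lt(max(abs(apex_gaps(m5)$gap - 0.5)), 0.01)
})

test_that("an interference bump closes that tooth's gap by its height", {
  m <- generate_synthetic_dentition(
    small_arch(interference = list(tooth = 43L, height = 0.3)))
  g <- apex_gaps(m)
  gap_43 <- g$gap[g$fdi == 43]
  gap_33 <- g$gap[g$fdi == 33]
  expect_equal(gap_33 - gap_43, 0.3, tolerance = 0.01)
})

test_that("generation is deterministic per seed", {
  a <- generate_synthetic_dentition(small_arch(jitter_sd = 0.05), seed = 3)
  b <- generate_synthetic_dentition(small_arch(jitter_sd = 0.05), seed = 3)
  expect_identical(a$lower$vertices, b$lower$vertices)
  expect_identical(a$upper$vertices, b$upper$vertices)
  c_ <- generate_synthetic_dentition(small_arch(jitter_sd = 0.05), seed = 4)
  expect_false(identical(a$lower$vertices, c_$lower$vertices))
})

test_that("symmetric parameters give an exactly mirror-symmetric model", {
  m <- generate_synthetic_dentition(small_arch())
  refl <- m$lower$vertices
  refl[, 1] <- -refl[, 1]
  # reflected vertex set must coincide with the original (as a set):
  # match rows via rounded keys, then compare exactly
  key <- function(v) paste(round(v[, 1], 6), round(v[, 2], 6),
                           round(v[, 3], 6))
  idx <- match(key(refl), key(m$lower$vertices))
  expect_false(anyNA(idx))
  expect_lt(max(abs(m$lower$vertices[idx, ] - refl)), 1e-9)
})

test_that("colliding tooth placements raise a generation error naming the pair", {
  expect_error(
    generate_synthetic_dentition(arch_params(cusp_base_radius = 6)),
    "FDI.*collide")
})

test_that("arch-span labelling reproduces the generator's ground truth", {
  m <- generate_synthetic_dentition(small_arch())
  p <- attr(m, "params")
  expect_identical(assign_tooth_labels(m$lower, p, "lower"), m$lower_labels)
  expect_identical(assign_tooth_labels(m$upper, p, "upper"), m$upper_labels)
  # every cusp-cap face carries the ground-truth tooth code
  gt <- attr(m, "ground_truth")
  cent <- mesh_face_centroids(m$lower)
  for (i in seq_len(nrow(gt))) {
    near <- which((cent[, 1] - gt$apex_x[i])^2 +
                    (cent[, 3] - gt$apex_z[i])^2 < 1)
    expect_true(all(m$lower_labels[near] == gt$fdi[i]))
  }
})

test_that("a centroid on a span boundary is assigned to the mesial tooth", {
  p <- small_arch()
  g <- occlustress:::arch_geometry(p)
  phi_b <- g$dphi            # boundary between teeth 1 and 2, right side
  xz <- occlustress:::arch_point(g, phi_b)
  # equilateral-ish triangle whose centroid sits exactly on the boundary
  v <- rbind(c(xz[1], 0, xz[2] + 0.2), c(xz[1] - 0.1, 0, xz[2] - 0.1),
             c(xz[1] + 0.1, 0, xz[2] - 0.1))
  ctr <- colMeans(v)
  tri <- surface_mesh(sweep(v, 2, ctr - c(xz[1], 0, xz[2])),
                      matrix(1:3, 1))
  lab <- assign_tooth_labels(tri, p, "lower")
  expect_equal(lab, 41L)     # mesial (position 1), not 42
})

test_that("carving is local, depth-true and an identity at depth zero", {
  m <- generate_synthetic_dentition(
    small_arch(interference = list(tooth = 43L, height = 0.4)))
  gt <- attr(m, "ground_truth")
  apex <- unlist(gt[gt$fdi == 43, c("apex_x", "apex_y", "apex_z")])

  sp0 <- modification_spec(43L, apex, radius = 2, depth = 0)
  expect_equal(carve_region(m$lower, m$lower_labels, sp0)$vertices,
               m$lower$vertices)

  sp <- modification_spec(43L, apex, radius = 2, depth = 0.5)
  carved <- carve_region(m$lower, m$lower_labels, sp)
  # apex height reduced by the full depth (taper = 1 at the centre)
  near_apex <- which((m$lower$vertices[, 1] - apex[1])^2 +
                       (m$lower$vertices[, 3] - apex[3])^2 < 0.05)
  drop <- m$lower$vertices[near_apex, 2] - carved$vertices[near_apex, 2]
  expect_equal(max(drop), 0.5, tolerance = 0.01)
  expect_lte(max(drop), 0.5 + 1e-9)   # never deeper than removal_depth

  # vertices two radii away are untouched exactly
  d <- sqrt(rowSums(sweep(m$lower$vertices, 2, apex)^2))
  far <- d > 2 * sp$radius
  expect_identical(carved$vertices[far, ], m$lower$vertices[far, ])
  # other teeth are untouched even inside the radius
  other <- m$lower_labels != 43L
  ov <- unique(as.vector(m$lower$faces[other, ]))
  ov <- ov[!is.na(ov)]
  expect_identical(carved$vertices[ov, ], m$lower$vertices[ov, ])
})

test_that("carve contracts: bad depth errors, disjoint region is a no-op", {
  m <- generate_synthetic_dentition(small_arch())
  expect_error(modification_spec(43L, c(0, 0, 0), 1, depth = -0.1),
               "removal_depth")
  expect_error(modification_spec(99L, c(0, 0, 0), 1, 0.1), "FDI")
  sp <- modification_spec(43L, c(0, 50, 0), radius = 1, depth = 0.5)
  expect_warning(out <- carve_region(m$lower, m$lower_labels, sp),
                 "does not intersect")
  expect_identical(out$vertices, m$lower$vertices)
})

test_that("seating translates the lower arch to tangential contact", {
  m <- generate_synthetic_dentition(
    small_arch(centric_gap = 0.7, tip_edge = 0.15))
  s <- seat_centric(m)
  expect_equal(attr(s, "seated_by"), 0.7, tolerance = 0.01)
  g <- apex_gaps(s)
  expect_equal(min(g$gap), 0, tolerance = 0.02)
})
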