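test_that("displacement traces parse, validate and re-base", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,dx,dy,dz", "0,0,0,0", "0.001,0.1,0,0", "0.002,0.2,0,0"), f)
  d <- load_displacement_trace(f)
  expect_equal(attr(d, "sampling_rate"), 1000)
  expect_equal(d$dx[3], 0.2)

  writeLines(c("t,dx,dy,dz", "0,1,1,1", "0.001,1.1,1,1"), f)
  expect_message(d2 <- load_displacement_trace(f), "re-based")
  expect_equal(unlist(d2[1, c("dx", "dy", "dz")]), c(dx = 0, dy = 0, dz = 0))
  expect_equal(d2$dx[2], 0.1)

  writeLines(c("time,x", "0,0"), f)
  expect_error(load_displacement_trace(f), "schema")

  expect_error(displacement_trace(c(0, 0.001, 0.005), 0:2, 0:2, 0:2),
               "non-uniform")
})

test_that("plane angles follow the signed-angle definition", {
  tr <- marker_track("sagittal", c(0, 1),
                     rbind(c(0, 0), c(0, 0)), rbind(c(10, 0), c(10, 1)))
  th <- extract_plane_angle(tr)
  expect_equal(th$theta, c(0, atan2(1, 10)), tolerance = 1e-12)

  still <- marker_track("frontal", 0:3, matrix(c(0, 0), 4, 2, byrow = TRUE),
                        matrix(c(5, 5), 4, 2, byrow = TRUE))
  expect_equal(extract_plane_angle(still)$theta, rep(0, 4))

  degen <- marker_track("horizontal", 0:1, rbind(c(1, 1), c(2, 2)),
                        rbind(c(3, 3), c(2, 2)))
  expect_error(extract_plane_angle(degen), "frame 2")
})

test_that("a programmed horizontal rotation of 0.471 rad is recovered", {
  rec <- generate_synthetic_recording("right_excursion", duration = 2)
  th <- extract_plane_angle(rec$tracks$horizontal)
  expect_equal(th$theta[length(th$theta)], 0.471, tolerance = 1e-3)
})

test_that("composed transforms are orthonormal and distance-preserving", {
  expect_equal(compose_transform()$R, diag(3))
  expect_equal(apply_transform(identity_transform(), c(1, 2, 3)), c(1, 2, 3))

  set.seed(11)
  tetra <- matrix(stats::rnorm(12, sd = 30), 4, 3)
  for (a in list(c(0.104, 0.001, 0.003), c(0.111, 0.002, 0.001),
                 c(0.084, 0.001, 0.471), c(0.052, 0.002, 0.179))) {
    tf <- compose_transform(a[1], a[2], a[3], c(1, -2, 0.5), c(0, 5, -40))
    expect_lt(max(abs(t(tf$R) %*% tf$R - diag(3))), 1e-12)
    d0 <- dist(tetra)
    d1 <- dist(apply_transform(tf, tetra))
    expect_lt(max(abs(d1 - d0)), 1e-9)
  }
})

test_that("composition-order sensitivity is small at closing-task magnitudes", {
  # independent brute force over all six orders with locally defined matrices
  Rx <- function(a) rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0), c(-sin(a), 0, cos(a)))
  Rz <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
  a <- c(0.104, 0.001, 0.003)
  Ms <- list(Rx(a[1]), Rz(a[2]), Ry(a[3]))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  set.seed(2)
  pts <- matrix(stats::rnorm(150), ncol = 3)
  pts <- 50 * pts / sqrt(rowSums(pts^2))
  Rs <- lapply(perms, function(o) Ms[[o[1]]] %*% Ms[[o[2]]] %*% Ms[[o[3]]])
  worst <- 0
  for (i in 1:5) for (j in (i + 1):6) {
    d <- sqrt(rowSums((pts %*% t(Rs[[i]]) - pts %*% t(Rs[[j]]))^2))
    worst <- max(worst, d)
  }
  expect_lt(worst, 0.05)
  # the package's fixed order agrees with the matching brute-force order
  tf <- compose_transform(a[1], a[2], a[3])
  expect_equal(tf$R, Ry(a[3]) %*% Rz(a[2]) %*% Rx(a[1]), tolerance = 1e-15)
})

test_that("segment_and_merge bins, interpolates and chains linearly", {
  t_d <- seq(0, 1, by = 1e-3)
  disp <- displacement_trace(t_d, 6.9 * t_d, 0 * t_d, 0 * t_d)
  t_r <- seq(0, 1, by = 1 / 25)
  rot0 <- rotation_trace(t_r, 0 * t_r, 0 * t_r, 0 * t_r)
  n <- 29
  traj <- segment_and_merge(disp, rot0, n)
  expect_equal(nrow(traj), n)
  expect_equal(traj$tx, 6.9 * seq_len(n) / n, tolerance = 1e-9)
  expect_equal(traj$tx[n], 6.9, tolerance = 1e-9)
  expect_equal(max(abs(c(traj$ty, traj$tz, traj$theta_sag, traj$theta_fro,
                         traj$theta_hor))), 0)

  # all-zero recording gives identity transforms
  disp0 <- displacement_trace(t_d, 0 * t_d, 0 * t_d, 0 * t_d)
  tr0 <- segment_and_merge(disp0, rot0, 5)
  for (tf in trajectory_transforms(tr0)) {
    expect_equal(tf$R, diag(3))
    expect_equal(tf$t, c(0, 0, 0))
  }

  expect_error(segment_and_merge(disp, rot0, 2000), "resolution")
  rot_short <- rotation_trace(seq(0, 0.5, by = 1 / 25), 0, 0, 0)
  expect_error(segment_and_merge(disp, rot_short, 10), "coverage")
})

test_that("mirroring reflects translations and plane angles and is an involution", {
  traj <- preset_trajectory("right_excursion", include_rotation = TRUE)
  m <- mirror_trace(traj)
  expect_equal(attr(m, "task"), "left_excursion")
  n <- nrow(traj)
  expect_equal(m$tx[n], -6.9, tolerance = 1e-9)
  expect_equal(m$ty[n], -6.6, tolerance = 1e-9)
  expect_equal(m$theta_sag, traj$theta_sag)       # preserved
  expect_equal(m$theta_hor[n], -0.471, tolerance = 1e-9)
  expect_equal(m$theta_fro, -traj$theta_fro)

  mm <- mirror_trace(m)
  expect_identical(as.data.frame(mm), as.data.frame(traj))
  expect_equal(attr(mm, "task"), "right_excursion")

  # mirroring commutes with time reversal of the pose sequence
  rev_cols <- function(x) { x[rev(seq_len(nrow(x))),
                              c("tx", "ty", "tz", "theta_sag", "theta_fro",
                                "theta_hor")] }
  expect_equal(unname(as.matrix(rev_cols(as.data.frame(m)))),
               unname(as.matrix(rev_cols(as.data.frame(traj)))) %*%
                 diag(c(-1, 1, 1, 1, -1, -1)))

  expect_warning(mirror_trace(preset_trajectory("protrusion", n_segments = 4)),
                 "non-excursion")
})

test_that("synthetic recordings honour the task presets and invert exactly", {
  rec_r <- generate_synthetic_recording("right_excursion", duration = 1.5)
  nd <- nrow(rec_r$disp)
  expect_equal(unlist(rec_r$disp[nd, c("dx", "dy", "dz")]),
               c(dx = 6.9, dy = -6.6, dz = 0))
  rec_l <- generate_synthetic_recording("left_excursion", duration = 1.5)
  expect_equal(unlist(rec_l$disp[nrow(rec_l$disp), c("dx", "dy")]),
               c(dx = -4.1, dy = -1.9))

  # noiseless render-then-extract recovers every programmed angle exactly
  rot <- rotation_trace_from_tracks(rec_r$tracks$sagittal,
                                    rec_r$tracks$frontal,
                                    rec_r$tracks$horizontal)
  gt <- rec_r$ground_truth$angles(rot$t)
  expect_lt(max(abs(as.matrix(rot[, -1]) - gt)), 1e-9)

  expect_error(generate_synthetic_recording("protrusion", duration = 0),
               "duration")
})
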