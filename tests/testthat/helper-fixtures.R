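# shared fixtures, built in code

# one right triangle in the z = 0 plane
tri_mesh <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
               matrix(c(1L, 2L, 3L), 1))
}

# single quad in the y = 0 plane, normal +y
quad_mesh <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(0, 0, 2), c(1, 0, 2), c(1, 0, 0)),
               matrix(c(1L, 2L, 3L, 4L), 1))
}

# random well-formed triangle soup (no degenerate faces)
random_tri_mesh <- function(n_tri = 200, seed = 1) {
  set.seed(seed)
  v <- matrix(stats::runif(9 * n_tri, -5, 5), ncol = 3)
  f <- matrix(seq_len(3 * n_tri), ncol = 3)
  surface_mesh(v, f)
}

# small coarse dentition for fast pipeline tests
small_arch <- function(..., tip_edge = 0.35) {
  arch_params(teeth_per_quadrant = 3, tip_edge = tip_edge, arch_step = 1.5,
              ...)
}

# a constant-velocity straight-line trajectory built directly
linear_trajectory <- function(endpoint, n, task = "right_excursion",
                              duration = 1) {
  s <- seq_len(n) / n
  df <- data.frame(segment = seq_len(n),
                   t_start = (seq_len(n) - 1) * duration / n,
                   t_end = s * duration,
                   tx = endpoint[1] * s, ty = endpoint[2] * s,
                   tz = endpoint[3] * s,
                   theta_sag = 0, theta_fro = 0, theta_hor = 0)
  attr(df, "task") <- task
  attr(df, "rotation_center") <- c(0, 0, 0)
  class(df) <- c("merged_trajectory", "data.frame")
  df
}

expect_mesh_equal <- function(a, b, tol = 1e-9) {
  expect_equal(nrow(a$faces), nrow(b$faces))
  expect_lt(max(abs(a$vertices - b$vertices)), tol)
}
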