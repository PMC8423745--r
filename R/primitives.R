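#' Primitive validation meshes
#'
#' Simple parametric meshes used to validate the contact solver against
#' closed-form results: a rectangular plane grid and a spherical cap.
#'
#' @param width_x,width_z plane extents, mm (centred on the origin).
#' @param edge target element edge length, mm.
#' @param y plane height, mm.
#' @param up orient face normals along +y (`TRUE`) or -y.
#' @param quads emit quadrilaterals (default) or triangles.
#' @return a [surface_mesh()].
#' @export
mesh_plane <- function(width_x = 6, width_z = 6, edge = 0.1, y = 0,
                       up = TRUE, quads = TRUE) {
  nx <- max(1L, ceiling(width_x / edge))
  nz <- max(1L, ceiling(width_z / edge))
  xs <- seq(-width_x / 2, width_x / 2, length.out = nx + 1)
  zs <- seq(-width_z / 2, width_z / 2, length.out = nz + 1)
  verts <- cbind(rep(xs, times = nz + 1), y, rep(zs, each = nx + 1))
  id <- function(i, j) (j - 1L) * (nx + 1L) + i
  i <- rep(seq_len(nx), times = nz)
  j <- rep(seq_len(nz), each = nx)
  a <- id(i, j); b <- id(i + 1L, j); c_ <- id(i + 1L, j + 1L); d <- id(i, j + 1L)
  # (a,b,c,d) winding: +x cross +z edges give -y; reverse for up
  f <- if (up) cbind(a, d, c_, b) else cbind(a, b, c_, d)
  if (!quads) {
    f <- rbind(f[, c(1, 2, 3)], f[, c(1, 3, 4)])
    f <- cbind(f, NA_integer_)
  }
  surface_mesh(verts, f, provenance = "synthetic plane grid")
}

#' @rdname mesh_plane
#' @param radius sphere radius, mm.
#' @param center sphere centre, mm.
#' @param cap_angle polar extent of the cap from the pole, radians.
#' @param pole `"down"` (cap opens downward, apex at the lowest point) or
#'   `"up"`.
#' @export
mesh_sphere_cap <- function(radius = 10, center = c(0, 10, 0),
                            cap_angle = 25 * pi / 180, edge = 0.2,
                            pole = c("down", "up")) {
  pole <- match.arg(pole)
  sgn <- if (pole == "down") -1 else 1
  n_rings <- max(4L, ceiling(radius * cap_angle / edge))
  thetas <- seq(0, cap_angle, length.out = n_rings + 1)[-1]
  n_az <- max(12L, ceiling(2 * pi * radius * sin(cap_angle) / edge))
  az <- seq(0, 2 * pi, length.out = n_az + 1)[-(n_az + 1)]
  rings <- lapply(thetas, function(th)
    cbind(center[1] + radius * sin(th) * cos(az),
          center[2] + sgn * radius * cos(th),
          center[3] + radius * sin(th) * sin(az)))
  verts <- rbind(c(center[1], center[2] + sgn * radius, center[3]),
                 do.call(rbind, rings))
  nr <- length(thetas)
  ring_idx <- function(r) 1 + (r - 1) * n_az + seq_len(n_az)
  i1 <- ring_idx(1)
  nxt <- c(seq_len(n_az)[-1], 1)
  # wind so normals point away from the sphere centre
  fan <- if (pole == "down") cbind(1L, i1, i1[nxt]) else cbind(1L, i1[nxt], i1)
  faces <- list(fan)
  for (r in seq_len(nr - 1)) {
    a <- ring_idx(r); b <- ring_idx(r + 1)
    a2 <- a[nxt]; b2 <- b[nxt]
    faces[[r + 1]] <- if (pole == "down")
      rbind(cbind(a, b, a2), cbind(a2, b, b2))
    else rbind(cbind(a, a2, b), cbind(a2, b2, b))
  }
  f <- do.call(rbind, faces)
  surface_mesh(verts, cbind(f, NA_integer_),
               provenance = "synthetic sphere cap")
}
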