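#' Spatial index over a mesh
#'
#' Builds an axis-aligned bounding-box hierarchy over the (triangulated)
#' faces of a mesh for nearest-triangle and signed-distance queries. The
#' index records a digest of the mesh it was built from; using it against an
#' edited mesh raises a version error.
#'
#' @param mesh a [surface_mesh()] (quads are triangulated internally along
#'   their shortest diagonal).
#' @return a `spatial_index`.
#' @export
build_spatial_index <- function(mesh) {
  validate_mesh(mesh)
  tg <- triangulate_mesh(mesh)
  an <- tri_area_normal(tg$vertices[tg$tris[, 1], , drop = FALSE],
                        tg$vertices[tg$tris[, 2], , drop = FALSE],
                        tg$vertices[tg$tris[, 3], , drop = FALSE])
  ptr <- .bvh_build(tg$vertices, tg$tris)
  structure(list(ptr = ptr, face_map = tg$face_map, normals = an$normal,
                 n_tris = nrow(tg$tris), digest = mesh_digest(mesh)),
            class = "spatial_index")
}

mesh_digest <- function(mesh) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(mesh$vertices, mesh$faces), f)
  unname(tools::md5sum(f))
}

check_index <- function(index, mesh) {
  if (!identical(index$digest, mesh_digest(mesh)))
    stop("stale spatial index: the mesh was edited after the index was ",
         "built; rebuild with build_spatial_index()")
  invisible(TRUE)
}

#' Signed gap from points to an indexed surface
#'
#' For each query point, the distance to the nearest triangle of the indexed
#' mesh, signed by that triangle's outward normal: positive on the outward
#' (separated) side, negative once the point has passed through the surface
#' (penetration). Pairing is re-established fresh at every call (finite
#' sliding, no persistent anchors). Points farther than `cutoff` are
#' reported as `Inf` (the far sentinel) and take no part in contact.
#'
#' @param points n x 3 matrix of query points, mm.
#' @param index a [build_spatial_index()] result.
#' @param cutoff far-field cutoff, mm (applies to separated points).
#' @return list with `gap` (signed, mm; `Inf` = far), `face` (1-based index
#'   into the original face set), `closest` (n x 3), `normal` (n x 3, of the
#'   nearest triangle).
#' @export
signed_gap <- function(points, index, cutoff = 5) {
  pts <- if (is.null(dim(points))) matrix(points, 1, 3) else as.matrix(points)
  q <- .bvh_query(index$ptr, pts)
  nrm <- index$normals[q$face, , drop = FALSE]
  dvec <- pts - q$closest
  s <- ifelse(rowSums(dvec * nrm) >= 0, 1, -1)
  gap <- s * q$distance
  gap[gap > cutoff] <- Inf
  list(gap = gap, face = index$face_map[q$face], closest = q$closest,
       normal = nrm)
}

#' Brute-force nearest-triangle signed gap (oracle)
#'
#' Exhaustive nearest-triangle search in plain R, independent of the
#' compiled spatial index. Intended as the verification oracle on small
#' meshes.
#'
#' @param points n x 3 query points.
#' @param mesh a [surface_mesh()].
#' @param cutoff far cutoff, mm.
#' @return list with `gap` and `face` as in [signed_gap()].
#' @export
brute_force_signed_gap <- function(points, mesh, cutoff = Inf) {
  pts <- if (is.null(dim(points))) matrix(points, 1, 3) else as.matrix(points)
  tg <- triangulate_mesh(mesh)
  A <- tg$vertices[tg$tris[, 1], , drop = FALSE]
  B <- tg$vertices[tg$tris[, 2], , drop = FALSE]
  C <- tg$vertices[tg$tris[, 3], , drop = FALSE]
  an <- tri_area_normal(A, B, C)
  gap <- numeric(nrow(pts))
  face <- integer(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    cp <- closest_point_triangles(pts[i, ], A, B, C)
    d2 <- rowSums(sweep(cp, 2, pts[i, ])^2)
    j <- which.min(d2)   # ties resolve to the lowest face index
    dvec <- pts[i, ] - cp[j, ]
    s <- if (sum(dvec * an$normal[j, ]) >= 0) 1 else -1
    gap[i] <- s * sqrt(d2[j])
    face[i] <- tg$face_map[j]
  }
  gap[gap > cutoff] <- Inf
  list(gap = gap, face = face)
}

# closest point on each triangle (A,B,C rows) to a single point p;
# vectorised Ericson region test
closest_point_triangles <- function(p, A, B, C) {
  ab <- B - A; ac <- C - A
  ap <- sweep(-A, 2, p, `+`)
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- sweep(-B, 2, p, `+`)
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp_ <- sweep(-C, 2, p, `+`)
  d5 <- rowSums(ab * cp_); d6 <- rowSums(ac * cp_)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4
  out <- matrix(NA_real_, nrow(A), 3)
  done <- rep(FALSE, nrow(A))
  take <- function(mask, val) {
    m <- mask & !done
    out[m, ] <<- val[m, , drop = FALSE]
    done <<- done | m
  }
  take(d1 <= 0 & d2 <= 0, A)
  take(d3 >= 0 & d4 <= d3, B)
  v <- d1 / (d1 - d3)
  take(vc <= 0 & d1 >= 0 & d3 <= 0, A + ab * ifelse(is.finite(v), v, 0))
  take(d6 >= 0 & d5 <= d6, C)
  w <- d2 / (d2 - d6)
  take(vb <= 0 & d2 >= 0 & d6 <= 0, A + ac * ifelse(is.finite(w), w, 0))
  w2 <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  take(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0,
       B + (C - B) * ifelse(is.finite(w2), w2, 0))
  denom <- va + vb + vc
  vv <- vb / denom; ww <- vc / denom
  take(rep(TRUE, nrow(A)), A + ab * vv + ac * ww)
  out
}

#' Elastic-foundation (Winkler) penalty stiffness
#'
#' The contact layer is idealised as independent springs distributed over
#' the surface: `k = E* / h` with the plane-strain modulus
#' `E* = E / (1 - nu^2)`, converted to MPa. For the defaults (E = 84 GPa,
#' nu = 0.3, h = 2 mm), k is about 46 154 N mm^-3.
#'
#' @param material a [material_params()].
#' @return foundation stiffness k, N mm^-3 (MPa per mm of penetration).
#' @export
foundation_stiffness <- function(material) {
  if (material$h_mm <= 0) stop("parameter error: foundation thickness must be > 0")
  (material$E_gpa * 1000) / (1 - material$nu^2) / material$h_mm
}

#' Penalty contact pressure
#'
#' `p = k * max(-g, 0)`: zero at or above zero signed gap, linear in
#' penetration.
#'
#' @param g signed gap(s), mm (negative = penetration; `Inf` = far).
#' @param k foundation stiffness, N mm^-3.
#' @return contact pressure, MPa.
#' @export
penalty_pressure <- function(g, k) {
  if (k <= 0) stop("penalty stiffness must be > 0")
  pen <- pmax(-g, 0)
  pen[!is.finite(g)] <- 0
  k * pen
}

#' Coulomb frictional shear traction
#'
#' Rigid Coulomb sliding with no elastic slip: where the in-plane slip speed
#' is positive, `tau = mu * p` opposing the slip direction; at zero slip
#' speed the traction is zero (no stick-force recovery in a kinematically
#' driven model).
#'
#' @param p contact pressure(s), MPa.
#' @param slip n x 3 matrix of in-plane slip velocities, mm/s.
#' @param mu friction coefficient.
#' @param tol slip speed below which the point counts as not sliding.
#' @return list with `tau` (MPa) and `direction` (n x 3 unit vectors, zero
#'   rows where not sliding).
#' @export
friction_traction <- function(p, slip, mu, tol = 1e-9) {
  slip <- if (is.null(dim(slip))) matrix(slip, ncol = 3) else as.matrix(slip)
  speed <- sqrt(rowSums(slip^2))
  sliding <- speed > tol
  tau <- ifelse(sliding, mu * p, 0)
  dir <- matrix(0, nrow(slip), 3)
  dir[sliding, ] <- -slip[sliding, , drop = FALSE] / speed[sliding]
  list(tau = tau, direction = dir)
}

#' Maximum principal contact stress
#'
#' Mohr's-circle major value of the local normal/shear traction pair:
#' `sigma1 = p/2 + sqrt((p/2)^2 + tau^2)`, reported as a positive magnitude.
#'
#' @param p normal pressure, MPa.
#' @param tau shear traction magnitude, MPa.
#' @return sigma1, MPa.
#' @export
max_principal_stress <- function(p, tau) {
  p / 2 + sqrt((p / 2)^2 + tau^2)
}

#' Precompute the contact-side geometry of the moving arch
#'
#' @param mesh the lower (moving) [surface_mesh()].
#' @return list with face `centroids` and `areas` in the reference pose.
#' @export
lower_face_geometry <- function(mesh) {
  list(centroids = mesh_face_centroids(mesh), areas = mesh_face_areas(mesh))
}

#' Resolve contact for one trajectory frame
#'
#' Transforms the lower-face material points (face centroids) by the frame's
#' rigid pose, evaluates signed gaps against the fixed upper arch, and turns
#' penetrations into penalty pressures, Coulomb shear tractions (slip from
#' backward difference against the previous frame; zero on the first frame)
#' and maximum principal contact stress per face.
#'
#' @param model a `dentition_model`.
#' @param transform a `rigid_transform` (absolute pose vs centric).
#' @param index spatial index built on `model$upper`.
#' @param prev_frame the previous `contact_state`, or `NULL` for the first
#'   frame.
#' @param dt time step to the previous frame, s.
#' @param geom optional precomputed [lower_face_geometry()].
#' @param k penalty stiffness override, N mm^-3 (default from the material).
#' @param cutoff far cutoff, mm.
#' @param check_version verify the index matches the upper mesh (digest
#'   comparison); disable inside tight loops that own both objects.
#' @return a `contact_state`: per-face signed gap `g`, penetration `pen`,
#'   pressure `p`, shear `tau`, slip direction, `sigma1`, `area`, `contact`
#'   flag; per-frame `contact_area` (mm^2) and `total_force` (N).
#' @export
resolve_frame <- function(model, transform, index, prev_frame = NULL,
                          dt = 1, geom = NULL, k = NULL, cutoff = 5,
                          check_version = TRUE) {
  if (check_version) check_index(index, model$upper)
  if (is.null(geom)) geom <- lower_face_geometry(model$lower)
  if (is.null(k)) k <- foundation_stiffness(model$material)
  x <- apply_transform(transform, geom$centroids)
  sg <- signed_gap(x, index, cutoff = cutoff)
  p <- penalty_pressure(sg$gap, k)
  if (!is.null(prev_frame)) {
    v <- (x - prev_frame$positions) / dt
    # in-plane component w.r.t. the local contact normal
    vn <- rowSums(v * sg$normal)
    slip <- v - sg$normal * vn
  } else {
    slip <- matrix(0, nrow(x), 3)
  }
  fr <- friction_traction(p, slip, model$material$mu)
  sigma1 <- max_principal_stress(p, fr$tau)
  contact <- p > 0
  structure(list(
    frame = if (is.null(prev_frame)) 1L else prev_frame$frame + 1L,
    g = sg$gap, pen = pmax(-sg$gap, 0) * is.finite(sg$gap),
    p = p, tau = fr$tau, slip_dir = fr$direction, sigma1 = sigma1,
    area = geom$areas, contact = contact, face = sg$face,
    contact_area = sum(geom$areas[contact]),
    total_force = sum(p * geom$areas),
    positions = x), class = "contact_state")
}

#' @export
print.contact_state <- function(x, ...) {
  cat(sprintf(
    "contact_state: %d/%d faces in contact, area %.2f mm^2, force %.2f N, max sigma1 %.2f MPa\n",
    sum(x$contact), length(x$p), x$contact_area, x$total_force,
    if (length(x$sigma1)) max(x$sigma1) else 0))
  invisible(x)
}
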