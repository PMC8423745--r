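#' Surface mesh objects
#'
#' A `surface_mesh` stores an occlusal surface shell as a vertex matrix and a
#' mixed triangle/quadrilateral face matrix. Coordinates are millimetres.
#' Faces are stored as an integer matrix with four columns; triangles carry
#' `NA` in the fourth column. Face normals follow the right-hand rule on the
#' stored vertex order and are expected to point toward the opposing arch on
#' occlusal surfaces.
#'
#' @param vertices numeric matrix (n x 3) of vertex coordinates, mm.
#' @param faces integer matrix (m x 4) of 1-based vertex indices; triangles
#'   use `NA` in column 4. A plain m x 3 matrix is accepted.
#' @param provenance optional character notes recording how the mesh was
#'   produced or altered (e.g. quad triangulation on STL import).
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, provenance = character()) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 3) stop("vertices must be an n x 3 matrix")
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  if (ncol(faces) == 3)
    faces <- cbind(faces, rep(NA_integer_, nrow(faces)))
  if (ncol(faces) != 4) stop("faces must have 3 or 4 columns")
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  m <- structure(list(vertices = vertices, faces = faces,
                      provenance = as.character(provenance)),
                 class = "surface_mesh")
  validate_mesh(m)
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  nq <- sum(!is.na(x$faces[, 4]))
  cat(sprintf("surface_mesh: %d vertices, %d faces (%d tri, %d quad)\n",
              nrow(x$vertices), nrow(x$faces), nrow(x$faces) - nq, nq))
  invisible(x)
}

validate_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(v) == 0 || nrow(f) == 0) stop("empty mesh: no vertices or faces")
  idx <- f[!is.na(f)]
  if (any(idx < 1) || any(idx > nrow(v)))
    stop("face index out of range: every face index must be <= vertex count")
  tri <- is.na(f[, 4])
  degen <- (f[, 1] == f[, 2]) | (f[, 2] == f[, 3]) | (f[, 1] == f[, 3])
  degen[!tri] <- degen[!tri] | (f[!tri, 4] == f[!tri, 1]) |
    (f[!tri, 4] == f[!tri, 2]) | (f[!tri, 4] == f[!tri, 3])
  if (any(degen))
    stop("degenerate face (repeated vertex) at face ",
         paste(utils::head(which(degen), 5), collapse = ", "))
  invisible(mesh)
}

#' Number of faces / vertices
#' @param mesh a `surface_mesh`.
#' @return integer count.
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

#' @rdname n_faces
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' Triangulate a mixed mesh
#'
#' Quadrilaterals are split into two triangles along their shortest diagonal.
#' The returned object carries `face_map`, mapping each output triangle to the
#' 1-based index of the originating face, so per-face attributes (labels,
#' stress fields) can be transported.
#'
#' @param mesh a `surface_mesh`.
#' @return list with `vertices`, `tris` (k x 3 integer) and `face_map`.
#' @export
triangulate_mesh <- function(mesh) {
  f <- mesh$faces
  v <- mesh$vertices
  tri <- is.na(f[, 4])
  tris1 <- f[tri, 1:3, drop = FALSE]
  map1 <- which(tri)
  q <- f[!tri, , drop = FALSE]
  if (nrow(q)) {
    d13 <- rowSums((v[q[, 1], , drop = FALSE] - v[q[, 3], , drop = FALSE])^2)
    d24 <- rowSums((v[q[, 2], , drop = FALSE] - v[q[, 4], , drop = FALSE])^2)
    s13 <- d13 <= d24
    # split (1,2,3)+(1,3,4) on the 1-3 diagonal, (1,2,4)+(2,3,4) on 2-4
    t1 <- cbind(q[, 1], q[, 2], ifelse(s13, q[, 3], q[, 4]))
    t2 <- matrix(0L, nrow(q), 3)
    t2[s13, ] <- q[s13, c(1, 3, 4), drop = FALSE]
    t2[!s13, ] <- q[!s13, c(2, 3, 4), drop = FALSE]
    tris2 <- rbind(t1, t2)
    map2 <- rep(which(!tri), 2L)
  } else {
    tris2 <- matrix(integer(), 0, 3)
    map2 <- integer()
  }
  tris <- rbind(tris1, tris2)
  face_map <- c(map1, map2)
  storage.mode(tris) <- "integer"
  list(vertices = v, tris = tris, face_map = face_map)
}

#' Face centroids, areas and normals
#'
#' Quadrilateral centroids are the mean of the four corners; quad areas and
#' normals are computed from the two triangles of the shortest-diagonal split.
#' Normals are unit length and follow the stored winding.
#'
#' @param mesh a `surface_mesh`.
#' @return `mesh_face_centroids`: m x 3 matrix. `mesh_face_areas`: numeric m.
#'   `mesh_face_normals`: m x 3 matrix of unit normals.
#' @export
mesh_face_centroids <- function(mesh) {
  f <- mesh$faces
  v <- mesh$vertices
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  tri <- is.na(f[, 4])
  cent <- (p1 + p2 + p3) / 3
  if (any(!tri)) {
    q <- which(!tri)
    p4 <- v[f[q, 4], , drop = FALSE]
    cent[q, ] <- (p1[q, , drop = FALSE] + p2[q, , drop = FALSE] +
                    p3[q, , drop = FALSE] + p4) / 4
  }
  cent
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

tri_area_normal <- function(p1, p2, p3) {
  cr <- cross3(p2 - p1, p3 - p1)
  nrm <- sqrt(rowSums(cr^2))
  list(area = nrm / 2, normal = cr / ifelse(nrm > 0, nrm, 1))
}

#' @rdname mesh_face_centroids
#' @export
mesh_face_areas <- function(mesh) {
  tg <- triangulate_mesh(mesh)
  v <- tg$vertices
  an <- tri_area_normal(v[tg$tris[, 1], , drop = FALSE],
                        v[tg$tris[, 2], , drop = FALSE],
                        v[tg$tris[, 3], , drop = FALSE])
  as.numeric(tapply(an$area, tg$face_map, sum))
}

#' @rdname mesh_face_centroids
#' @export
mesh_face_normals <- function(mesh) {
  tg <- triangulate_mesh(mesh)
  v <- tg$vertices
  an <- tri_area_normal(v[tg$tris[, 1], , drop = FALSE],
                        v[tg$tris[, 2], , drop = FALSE],
                        v[tg$tris[, 3], , drop = FALSE])
  w <- an$normal * an$area
  nx <- tapply(w[, 1], tg$face_map, sum)
  ny <- tapply(w[, 2], tg$face_map, sum)
  nz <- tapply(w[, 3], tg$face_map, sum)
  n <- cbind(as.numeric(nx), as.numeric(ny), as.numeric(nz))
  len <- sqrt(rowSums(n^2))
  n / ifelse(len > 0, len, 1)
}

#' Smooth a mesh by iterated one-ring mean filtering
#'
#' Each vertex is moved toward the mean of its one-ring neighbours by
#' `weight`, repeated `iterations` times (umbrella-operator Laplacian
#' smoothing, the discrete analogue of the mean filtering used to denoise
#' scanned casts). Connectivity is unchanged. Isolated vertices (no incident
#' face edge) are left unmoved with a warning.
#'
#' @param mesh a `surface_mesh`.
#' @param iterations non-negative integer.
#' @param weight blending weight in (0, 1].
#' @return the smoothed `surface_mesh`.
#' @export
smooth_mesh <- function(mesh, iterations = 1, weight = 0.5) {
  if (iterations < 0) stop("iterations must be >= 0")
  if (weight <= 0 || weight > 1) stop("weight must be in (0, 1]")
  if (iterations == 0) return(mesh)
  f <- mesh$faces
  # undirected edge list over tri and quad boundaries
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)])
  tri <- is.na(f[, 4])
  e <- rbind(e, f[tri, c(3, 1), drop = FALSE],
             f[!tri, c(3, 4), drop = FALSE], f[!tri, c(4, 1), drop = FALSE])
  e <- rbind(e, e[, c(2, 1)])
  e <- unique(e)
  v <- mesh$vertices
  deg <- tabulate(e[, 1], nbins = nrow(v))
  if (any(deg == 0))
    warning(sum(deg == 0), " isolated vertex/vertices left unmoved")
  has <- deg > 0
  for (it in seq_len(iterations)) {
    sx <- rowsum(v[e[, 2], 1], e[, 1])
    sy <- rowsum(v[e[, 2], 2], e[, 1])
    sz <- rowsum(v[e[, 2], 3], e[, 1])
    ids <- as.integer(rownames(sx))
    mean_nb <- v
    mean_nb[ids, ] <- cbind(sx, sy, sz) / deg[ids]
    v[has, ] <- v[has, ] + weight * (mean_nb[has, , drop = FALSE] -
                                       v[has, , drop = FALSE])
  }
  mesh$vertices <- v
  mesh
}
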