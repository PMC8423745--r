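#' Material and contact parameters
#'
#' Enamel is treated as homogeneous, isotropic and linear elastic. The
#' foundation thickness `h_mm` is the thickness of the elastic surface layer
#' in the Winkler contact idealisation (see [foundation_stiffness()]).
#'
#' @param E_gpa elastic modulus, GPa (default 84, enamel).
#' @param nu Poisson's ratio (default 0.3).
#' @param mu Coulomb friction coefficient (default 0.1).
#' @param h_mm foundation layer thickness, mm (default 2).
#' @return a `material_params` list.
#' @export
material_params <- function(E_gpa = 84, nu = 0.3, mu = 0.1, h_mm = 2) {
  if (E_gpa <= 0) stop("elastic modulus must be positive")
  if (nu < 0 || nu >= 0.5) stop("Poisson ratio must be in [0, 0.5)")
  if (mu < 0) stop("friction coefficient must be >= 0")
  if (h_mm <= 0) stop("foundation thickness must be positive")
  structure(list(E_gpa = E_gpa, nu = nu, mu = mu, h_mm = h_mm),
            class = "material_params")
}

#' Valid FDI tooth codes
#' @return integer vector of the 32 two-digit FDI codes.
#' @export
fdi_codes <- function() as.integer(outer(1:8, c(10, 20, 30, 40), `+`))

#' Mirror an FDI code about the mid-sagittal plane
#' @param code FDI code(s).
#' @return the contralateral code(s): quadrants 1<->2 and 3<->4.
#' @export
mirror_fdi <- function(code) {
  q <- code %/% 10
  p <- code %% 10
  qm <- c(2L, 1L, 4L, 3L)[q]
  out <- ifelse(code == 0L, 0L, qm * 10L + p)
  as.integer(out)
}

validate_labels <- function(labels, mesh) {
  labels <- as.integer(labels)
  if (length(labels) != n_faces(mesh))
    stop("label map length ", length(labels), " does not match face count ",
         n_faces(mesh))
  bad <- setdiff(unique(labels), c(0L, fdi_codes()))
  if (length(bad))
    stop("invalid FDI tooth codes in label map: ", paste(bad, collapse = ", "))
  labels
}

#' Dentition model
#'
#' A fixed maxillary (upper) arch, a moving mandibular (lower) arch, per-face
#' FDI tooth labels and material/contact parameters. Both arches share one
#' coordinate frame; the stored pose is the centric occlusion reference.
#'
#' @param upper,lower [surface_mesh()] objects; upper occlusal normals point
#'   inferiorly (toward the lower arch), lower occlusal normals superiorly.
#' @param upper_labels,lower_labels integer per-face FDI labels (0 =
#'   unassigned).
#' @param material a [material_params()].
#' @return a `dentition_model`.
#' @export
dentition_model <- function(upper, lower, upper_labels, lower_labels,
                            material = material_params()) {
  validate_mesh(upper); validate_mesh(lower)
  structure(list(upper = upper, lower = lower,
                 upper_labels = validate_labels(upper_labels, upper),
                 lower_labels = validate_labels(lower_labels, lower),
                 material = material),
            class = "dentition_model")
}

#' @export
print.dentition_model <- function(x, ...) {
  cat(sprintf(
    "dentition_model: upper %d faces, lower %d faces, %d labelled teeth\n",
    n_faces(x$upper), n_faces(x$lower),
    length(setdiff(unique(c(x$upper_labels, x$lower_labels)), 0L))))
  invisible(x)
}

#' Synthetic arch parameters
#'
#' Parameters of the parametric synthetic dentition: teeth are sphere-capped
#' cusps placed on an elliptic arch curve; the opposing arch is a swept
#' occlusal gutter whose flat fossa floor sits `centric_gap` above the cusp
#' tips and whose inclined walls (the inner inclines of the opposing cusps)
#' provide lateral guidance. An optional interference bump raises one cusp,
#' planting a balancing-side interference.
#'
#' Defaults are chosen so that a 0.5 mm interference engages the guidance
#' wall during a 4.1 mm lateral excursion while sound teeth stay clear of
#' contact (see the package vignette for the closed-form design).
#'
#' @param teeth_per_quadrant teeth per quadrant (<= 8).
#' @param arch_width full arch width, mm (x diameter).
#' @param arch_depth arch depth, mm (z semi-axis).
#' @param cusp_height cusp height above the base plate, mm.
#' @param cusp_tip_radius radius of the spherical cusp tip cap, mm.
#' @param cusp_base_radius cusp base radius, mm.
#' @param cusps_per_tooth cusps per tooth (placed along the tooth span).
#' @param centric_gap programmed vertical gap between cusp tips and the
#'   fossa floor in centric occlusion, mm (>= 0).
#' @param groove_half_width flat fossa floor half-width, mm.
#' @param wall_slope guidance wall slope (vertical rise per unit lateral).
#' @param wall_depth guidance wall vertical extent below the floor, mm.
#' @param apron_width flat apron beyond the wall, mm.
#' @param interference `NULL` or `list(tooth = <FDI code>, height = <mm>)`:
#'   raises that cusp tip, reducing its centric gap by `height`.
#' @param jitter_sd per-tooth positional jitter standard deviation, mm
#'   (0 = exactly symmetric arches).
#' @param tip_edge approximate mesh edge length on the cusp caps, mm.
#' @param arch_step sampling step along the arch curve, mm.
#' @return an `arch_params` list.
#' @export
arch_params <- function(teeth_per_quadrant = 7, arch_width = 50,
                        arch_depth = 45, cusp_height = 9,
                        cusp_tip_radius = 1.6, cusp_base_radius = 2.5,
                        cusps_per_tooth = 1, centric_gap = 0.5,
                        groove_half_width = 3.96, wall_slope = 2,
                        wall_depth = 10, apron_width = 1.5,
                        interference = NULL, jitter_sd = 0,
                        tip_edge = 0.15, arch_step = 1.0) {
  if (teeth_per_quadrant < 1 || teeth_per_quadrant > 8)
    stop("teeth_per_quadrant must be in 1..8")
  if (centric_gap < 0) stop("centric_gap must be >= 0")
  if (!is.null(interference)) {
    stopifnot(is.list(interference), interference$tooth %in% fdi_codes(),
              interference$height >= 0)
  }
  p <- as.list(environment())
  class(p) <- "arch_params"
  p
}

# arch curve helpers -------------------------------------------------------
# x = a sin(phi), z = c (cos(phi) - 1); phi_end puts the last tooth centre
# at phi = 90 deg so the second-molar guidance is exactly transverse
arch_geometry <- function(p) {
  n <- p$teeth_per_quadrant
  a <- p$arch_width / 2
  cc <- p$arch_depth
  phi_end <- (pi / 2) * n / (n - 0.5)
  dphi <- phi_end / n
  centers <- (seq_len(n) - 0.5) * dphi
  list(a = a, c = cc, phi_end = phi_end, dphi = dphi, centers = centers)
}

arch_point <- function(g, phi) cbind(g$a * sin(phi), g$c * (cos(phi) - 1))

# outward (buccal) in-plane unit normal of the arch at phi
arch_outward <- function(g, phi) {
  nx <- sin(phi) / g$a
  nz <- cos(phi) / g$c
  len <- sqrt(nx^2 + nz^2)
  cbind(nx / len, nz / len)
}

# signed arch parameter (phi) of xz points, for labelling
arch_phi_of <- function(g, x, z) atan2(x / g$a, (z + g$c) / g$c)

#' Generate a synthetic dentition in centric relation
#'
#' Builds the lower arch (base strip plus sphere-capped cusps, one tooth per
#' FDI position) and the upper occlusal gutter, labelled with FDI codes, in
#' centric occlusion. Programmed cusp tips sit `centric_gap` below the fossa
#' floor; an interference bump reduces that tooth's gap by its height. With
#' symmetric parameters (and `jitter_sd = 0`) the model is exactly
#' mirror-symmetric about the mid-sagittal plane. Deterministic for a fixed
#' seed.
#'
#' @param params an [arch_params()].
#' @param seed RNG seed fixing the positional jitter.
#' @param material a [material_params()].
#' @return a `dentition_model` with a `ground_truth` attribute (per-tooth
#'   FDI code, cusp apex position and programmed centric gap).
#' @export
generate_synthetic_dentition <- function(params = arch_params(), seed = 1,
                                         material = material_params()) {
  p <- params
  g <- arch_geometry(p)
  set.seed(seed)
  # tooth table: FDI codes and cusp centres (right side phi > 0)
  n <- p$teeth_per_quadrant
  teeth <- data.frame(
    fdi_lower = c(rev(30L + seq_len(n)), 40L + seq_len(n)),
    fdi_upper = c(rev(20L + seq_len(n)), 10L + seq_len(n)),
    phi = c(-rev(g$centers), g$centers))
  jit <- matrix(0, nrow(teeth), 3)
  if (p$jitter_sd > 0)
    jit <- matrix(stats::rnorm(3 * nrow(teeth), 0, p$jitter_sd), ncol = 3)
  gt <- vector("list", nrow(teeth))
  cusp_meshes <- vector("list", nrow(teeth))
  y_floor <- p$centric_gap
  for (i in seq_len(nrow(teeth))) {
    fdi <- teeth$fdi_lower[i]
    bump <- 0
    if (!is.null(p$interference) && p$interference$tooth == fdi)
      bump <- p$interference$height
    gap <- p$centric_gap - bump
    xz <- arch_point(g, teeth$phi[i])
    ctr <- c(xz[1] + jit[i, 1], 0, xz[2] + jit[i, 2])
    tip_y <- y_floor - gap + jit[i, 3]
    # build right-side cusps directly; mirror left-side from the
    # contralateral geometry for exact symmetry when unjittered
    if (teeth$phi[i] >= 0 || p$jitter_sd > 0) {
      cusp_meshes[[i]] <- cusp_mesh(p, ctr, tip_y)
    } else {
      j <- nrow(teeth) + 1 - i   # contralateral tooth index
      fdi_j <- teeth$fdi_lower[j]
      bump_j <- 0
      if (!is.null(p$interference) && p$interference$tooth == fdi_j)
        bump_j <- p$interference$height
      xz_j <- arch_point(g, teeth$phi[j])
      m <- cusp_mesh(p, c(xz_j[1], 0, xz_j[2]),
                     y_floor - (p$centric_gap - bump) )
      m$vertices[, 1] <- -m$vertices[, 1]
      m$faces <- m$faces[, c(3, 2, 1, 4), drop = FALSE]  # restore winding
      cusp_meshes[[i]] <- m
    }
    gt[[i]] <- data.frame(fdi = fdi, apex_x = ctr[1], apex_y = tip_y,
                          apex_z = ctr[3], gap = gap, phi = teeth$phi[i])
  }
  gt <- do.call(rbind, gt)
  # overlap check between adjacent cusps
  ord <- order(gt$phi)
  for (k in seq_len(nrow(gt) - 1)) {
    i <- ord[k]; j <- ord[k + 1]
    d <- sqrt((gt$apex_x[i] - gt$apex_x[j])^2 + (gt$apex_z[i] - gt$apex_z[j])^2)
    if (d < 2 * p$cusp_base_radius)
      stop("generation error: teeth FDI ", gt$fdi[i], " and FDI ", gt$fdi[j],
           " collide (cusp centres ", format(d, digits = 3),
           " mm apart, bases ", 2 * p$cusp_base_radius, " mm wide)")
  }
  base <- base_strip_mesh(p, g)
  lower <- merge_meshes(c(cusp_meshes, list(base)))
  upper <- gutter_mesh(p, g)
  lower_labels <- label_by_arch(lower, p, "lower")
  upper_labels <- label_by_arch(upper, p, "upper")
  model <- dentition_model(upper, lower, upper_labels, lower_labels, material)
  attr(model, "ground_truth") <- gt
  attr(model, "params") <- p
  model
}

# one revolved cusp: spherical tip cap blending into a conical flank
cusp_mesh <- function(p, center, tip_y) {
  r_s <- p$cusp_tip_radius
  cap_deg <- 70 * pi / 180
  n_rings <- max(6L, ceiling(r_s * cap_deg / p$tip_edge))
  n_az <- max(16L, ceiling(2 * pi * r_s * sin(cap_deg) / p$tip_edge))
  thetas <- seq(0, cap_deg, length.out = n_rings + 1)[-1]
  az <- seq(0, 2 * pi, length.out = n_az + 1)[-(n_az + 1)]
  cy <- tip_y - r_s
  rings <- lapply(thetas, function(th)
    cbind(center[1] + r_s * sin(th) * cos(az),
          cy + r_s * cos(th),
          center[3] + r_s * sin(th) * sin(az)))
  # conical flank: from the cap rim down to the base circle
  rim_r <- r_s * sin(cap_deg)
  rim_y <- cy + r_s * cos(cap_deg)
  base_y <- tip_y - p$cusp_height
  n_cone <- 4L
  fr <- seq(0, 1, length.out = n_cone + 1)[-1]
  cone_rings <- lapply(fr, function(u) {
    r <- rim_r + u * (p$cusp_base_radius - rim_r)
    y <- rim_y + u * (base_y - rim_y)
    cbind(center[1] + r * cos(az), y, center[3] + r * sin(az))
  })
  rings <- c(rings, cone_rings)
  verts <- rbind(c(center[1], tip_y, center[3]), do.call(rbind, rings))
  nr <- length(rings)
  faces <- vector("list", nr)
  ring_idx <- function(r) 1 + (r - 1) * n_az + seq_len(n_az)
  # apex fan (wind so normals point outward/up)
  i1 <- ring_idx(1)
  faces[[1]] <- cbind(1L, i1[c(seq_len(n_az)[-1], 1)], i1)
  for (r in seq_len(nr - 1)) {
    a <- ring_idx(r); b <- ring_idx(r + 1)
    a2 <- a[c(seq_len(n_az)[-1], 1)]; b2 <- b[c(seq_len(n_az)[-1], 1)]
    faces[[r + 1]] <- rbind(cbind(a, a2, b), cbind(a2, b2, b))
  }
  f <- do.call(rbind, faces)
  list(vertices = verts, faces = cbind(f, NA_integer_))
}

# flat mandibular base strip under the cusps
base_strip_mesh <- function(p, g) {
  half_w <- p$cusp_base_radius + 1.5
  step <- max(p$arch_step, 1)
  n_arc <- ceiling(g$phi_end * max(g$a, g$c) / step)
  pos <- seq(0, g$phi_end, length.out = n_arc + 1)[-1]
  phis <- c(-rev(pos), 0, pos)
  y <- p$centric_gap - p$centric_gap - p$cusp_height  # tips at ~0, base below
  vs <- c(-half_w, 0, half_w)
  strip_mesh(g, phis, vs, function(v) rep(y, length(v)), up = TRUE)
}

# upper occlusal gutter swept along the arch; normals point down (toward
# the lower arch)
gutter_mesh <- function(p, g) {
  w <- p$groove_half_width
  W_in <- w + p$wall_depth / p$wall_slope
  W_out <- W_in + p$apron_width
  vs <- c(-W_out, -W_in, -(w + W_in) / 2, -w, -w / 2, 0, w / 2, w,
          (w + W_in) / 2, W_in, W_out)
  height <- function(v) {
    p$centric_gap - p$wall_slope * pmin(pmax(abs(v) - w, 0),
                                        p$wall_depth / p$wall_slope)
  }
  step <- max(min(p$arch_step, 1), 0.25)
  n_arc <- ceiling(2 * g$phi_end * max(g$a, g$c) / step / 2)
  pos <- seq(0, g$phi_end, length.out = n_arc + 1)[-1]
  phis <- c(-rev(pos), 0, pos)
  strip_mesh(g, phis, vs, height, up = FALSE)
}

# swept quad strip: arch samples x cross-profile offsets, with height h(v)
strip_mesh <- function(g, phis, vs, height_fun, up = TRUE) {
  pts <- arch_point(g, phis)
  nrm <- arch_outward(g, phis)
  nv <- length(vs)
  np <- length(phis)
  hy <- height_fun(vs)
  verts <- matrix(NA_real_, np * nv, 3)
  for (j in seq_len(nv)) {
    idx <- (j - 1) * np + seq_len(np)
    verts[idx, 1] <- pts[, 1] + vs[j] * nrm[, 1]
    verts[idx, 2] <- hy[j]
    verts[idx, 3] <- pts[, 2] + vs[j] * nrm[, 2]
  }
  faces <- vector("list", nv - 1)
  for (j in seq_len(nv - 1)) {
    a <- (j - 1) * np + seq_len(np - 1)
    b <- a + 1
    c_ <- j * np + seq_len(np - 1) + 1
    d <- c_ - 1
    # winding: (a,b,c,d) = (arch x profile) grid order gives a -y normal
    faces[[j]] <- if (up) cbind(a, d, c_, b) else cbind(a, b, c_, d)
  }
  list(vertices = verts, faces = do.call(rbind, faces))
}

merge_meshes <- function(parts) {
  off <- 0L
  vs <- list(); fs <- list()
  for (m in parts) {
    vs[[length(vs) + 1]] <- m$vertices
    f <- m$faces
    if (ncol(f) == 3) f <- cbind(f, NA_integer_)
    fs[[length(fs) + 1]] <- f + off   # NA + off stays NA
    off <- off + nrow(m$vertices)
  }
  surface_mesh(do.call(rbind, vs), do.call(rbind, fs),
               provenance = "synthetic dentition generator")
}

# label faces by the arch span containing their centroid
label_by_arch <- function(mesh, p, jaw = c("lower", "upper")) {
  jaw <- match.arg(jaw)
  g <- arch_geometry(p)
  cent <- mesh_face_centroids(mesh)
  phi <- arch_phi_of(g, cent[, 1], cent[, 3])
  k <- ceiling(abs(phi) / g$dphi - 1e-12)
  k[k < 1] <- 1L
  out <- integer(nrow(cent))
  inside <- k <= p$teeth_per_quadrant
  q_right <- phi >= 0
  base <- if (jaw == "lower") c(30L, 40L) else c(20L, 10L)
  out[inside & q_right] <- base[2] + k[inside & q_right]
  out[inside & !q_right] <- base[1] + k[inside & !q_right]
  as.integer(out)
}

#' Assign FDI tooth labels from arch-span boundaries
#'
#' Every face receives the label of the arch span (between mesial and distal
#' boundary planes along the arch curve) containing its centroid; a centroid
#' exactly on a boundary is assigned to the mesial span. Faces outside all
#' spans are labelled 0.
#'
#' @param mesh a [surface_mesh()].
#' @param arch_spec an [arch_params()] describing the spans.
#' @param jaw `"lower"` or `"upper"`.
#' @return integer per-face FDI label map.
#' @export
assign_tooth_labels <- function(mesh, arch_spec, jaw = c("lower", "upper")) {
  label_by_arch(mesh, arch_spec, match.arg(jaw))
}

#' Occlusal modification (carving) specification
#'
#' @param target_label FDI code of the tooth to carve.
#' @param center length-3 region centre, mm (reference frame).
#' @param radius spherical region radius, mm (> 0).
#' @param depth removal depth at the region centre, mm (>= 0).
#' @param direction removal direction (unit vector; the surface recedes
#'   along `-direction`). Default: the occlusal axis of a lower tooth.
#' @return a `modification_spec`.
#' @export
modification_spec <- function(target_label, center, radius, depth,
                              direction = c(0, 1, 0)) {
  if (!(target_label %in% fdi_codes())) stop("invalid FDI code: ", target_label)
  if (radius <= 0) stop("region radius must be > 0")
  if (depth < 0) stop("parameter error: removal_depth must be >= 0")
  direction <- as.numeric(direction)
  direction <- direction / sqrt(sum(direction^2))
  structure(list(target_label = as.integer(target_label),
                 center = as.numeric(center), radius = radius,
                 depth = depth, direction = direction),
            class = "modification_spec")
}

#' Carve an occlusal region (virtual morphological modification)
#'
#' Vertices that lie inside the spherical region and belong to at least one
#' face carrying the target label recede along the removal direction by a
#' cosine taper: full `depth` at the region centre, zero at the boundary.
#' All other vertices and the connectivity are unchanged.
#'
#' @param mesh a [surface_mesh()].
#' @param labels per-face FDI label map of `mesh`.
#' @param spec a [modification_spec()].
#' @return the carved `surface_mesh`.
#' @export
carve_region <- function(mesh, labels, spec) {
  labels <- validate_labels(labels, mesh)
  target_faces <- which(labels == spec$target_label)
  v <- mesh$vertices
  d <- sqrt((v[, 1] - spec$center[1])^2 + (v[, 2] - spec$center[2])^2 +
              (v[, 3] - spec$center[3])^2)
  fidx <- mesh$faces[target_faces, , drop = FALSE]
  on_target <- logical(nrow(v))
  on_target[fidx[!is.na(fidx)]] <- TRUE
  sel <- on_target & d < spec$radius
  # does the region intersect any target face at all?
  cent <- mesh_face_centroids(mesh)[target_faces, , drop = FALSE]
  cd <- sqrt(rowSums(sweep(cent, 2, spec$center)^2))
  if (!length(target_faces) || !any(cd < spec$radius)) {
    warning("carve region does not intersect any face labelled ",
            spec$target_label, "; mesh unchanged")
    return(mesh)
  }
  if (any(sel)) {
    taper <- spec$depth * 0.5 * (1 + cos(pi * d[sel] / spec$radius))
    v[sel, ] <- v[sel, , drop = FALSE] -
      outer(taper, spec$direction)
  }
  mesh$vertices <- v
  mesh$provenance <- c(mesh$provenance,
                       sprintf("carved FDI %d: depth %.3g mm, radius %.3g mm",
                               spec$target_label, spec$depth, spec$radius))
  mesh
}

#' Brute-force signed gap at the programmed cusp apices
#'
#' Exhaustive (non-indexed) nearest-triangle query from each generated cusp
#' apex to the upper arch, signed by the upper face normals. Used as the
#' generator's ground-truth gap oracle.
#'
#' @param model a generated `dentition_model` (needs its `ground_truth`).
#' @return data.frame with `fdi` and `gap` (mm, positive = separated).
#' @export
apex_gaps <- function(model) {
  gt <- attr(model, "ground_truth")
  if (is.null(gt)) stop("model carries no generator ground truth")
  pts <- as.matrix(gt[, c("apex_x", "apex_y", "apex_z")])
  gap <- brute_force_signed_gap(pts, model$upper)$gap
  data.frame(fdi = gt$fdi, gap = gap)
}

#' Seat a model into centric contact
#'
#' Translates the lower arch superiorly (+y) by the minimum signed gap so
#' the closest contact pair becomes tangential - the new intercuspal
#' position after an occlusal adjustment.
#'
#' @param model a `dentition_model`.
#' @param cutoff far-field cutoff, mm.
#' @return the seated model; the applied translation is in the `seated_by`
#'   attribute.
#' @export
seat_centric <- function(model, cutoff = 5) {
  idx <- build_spatial_index(model$upper)
  st <- signed_gap(mesh_face_centroids(model$lower), idx)
  gmin <- min(st$gap[is.finite(st$gap)])
  if (is.finite(gmin) && gmin > 0) {
    model$lower$vertices[, 2] <- model$lower$vertices[, 2] + gmin
    gt <- attr(model, "ground_truth")
    if (!is.null(gt)) {
      gt$apex_y <- gt$apex_y + gmin
      gt$gap <- gt$gap - gmin
      attr(model, "ground_truth") <- gt
    }
    attr(model, "seated_by") <- gmin
  } else {
    attr(model, "seated_by") <- 0
  }
  model
}
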