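#' Read a surface mesh from STL, PLY or OBJ
#'
#' STL is detected as ASCII or binary automatically. PLY supports ASCII and
#' binary little-endian files with mixed triangle/quad faces and optional
#' per-face scalar properties (returned in the `scalars` attribute). OBJ
#' keeps quadrilateral faces as quads. STL carries triangles only, so quads
#' written to STL arrive triangulated; a provenance note records this.
#'
#' @param path file path.
#' @param format one of `"stl"`, `"ply"`, `"obj"`; inferred from the file
#'   extension when missing.
#' @return a [surface_mesh()]; per-face scalar fields read from PLY are
#'   attached as the `scalars` attribute (named list of numeric vectors).
#' @export
load_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- infer_format(path, format)
  switch(format,
         stl = read_stl(path),
         ply = read_ply(path),
         obj = read_obj(path),
         stop("unsupported mesh format: ", format))
}

#' Write a surface mesh to STL, PLY, OBJ or VTK
#'
#' PLY and VTK exports can carry per-face scalar fields (e.g. stress maps)
#' bit-exactly as stored (doubles). STL output triangulates quadrilaterals
#' along their shortest diagonal, conserving area.
#'
#' @param mesh a [surface_mesh()].
#' @param path output file path.
#' @param format `"stl"`, `"stl_binary"`, `"ply"`, `"ply_binary"`, `"obj"` or
#'   `"vtk"`; inferred from the extension when missing (text variants).
#' @param scalar_fields optional named list of per-face numeric vectors; only
#'   written for PLY and VTK.
#' @return the path, invisibly.
#' @export
save_mesh <- function(mesh, path, format = NULL, scalar_fields = NULL) {
  validate_mesh(mesh)
  format <- infer_format(path, format)
  if (!is.null(scalar_fields)) {
    if (is.null(names(scalar_fields)) || any(names(scalar_fields) == ""))
      stop("scalar_fields must be a named list")
    for (nm in names(scalar_fields)) {
      if (length(scalar_fields[[nm]]) != n_faces(mesh))
        stop("scalar field '", nm, "' has length ",
             length(scalar_fields[[nm]]), " but the mesh has ",
             n_faces(mesh), " faces")
    }
  }
  switch(format,
         stl = write_stl_ascii(mesh, path),
         stl_binary = write_stl_binary(mesh, path),
         ply = write_ply(mesh, path, scalar_fields, binary = FALSE),
         ply_binary = write_ply(mesh, path, scalar_fields, binary = TRUE),
         obj = write_obj(mesh, path),
         vtk = write_vtk(mesh, path, scalar_fields),
         stop("unsupported mesh format: ", format))
  invisible(path)
}

infer_format <- function(path, format) {
  if (!is.null(format)) return(tolower(format))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("stl", "ply", "obj", "vtk")) return(ext)
  stop("cannot infer mesh format from extension '", ext, "'; pass `format`")
}

## ---- STL ----------------------------------------------------------------

is_binary_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 512)
  txt <- rawToChar(head[head != as.raw(0)])
  # ASCII STL starts with "solid" AND contains "facet" early on
  !(grepl("^\\s*solid", txt, useBytes = TRUE) &&
      grepl("facet", txt, useBytes = TRUE))
}

read_stl <- function(path) {
  if (is_binary_stl(path)) read_stl_binary(path) else read_stl_ascii(path)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines)
  if (length(vl) == 0)
    stop("STL parse error in ", path, ": no 'vertex' lines found ",
         "(first line: '", if (length(lines)) lines[1] else "", "')")
  if (length(vl) %% 3 != 0)
    stop("STL parse error in ", path, ": vertex count ", length(vl),
         " is not a multiple of 3 (near line ", vl[length(vl)], ")")
  coords <- matrix(NA_real_, length(vl), 3)
  for (i in seq_along(vl)) {
    tok <- strsplit(trimws(lines[vl[i]]), "\\s+")[[1]]
    val <- suppressWarnings(as.numeric(tok[2:4]))
    if (length(tok) < 4 || anyNA(val))
      stop("STL parse error in ", path, " at line ", vl[i], ": '",
           lines[vl[i]], "'")
    coords[i, ] <- val
  }
  stl_from_triangles(coords, path)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (is.na(n) || n <= 0)
    stop("STL parse error in ", path, ": bad triangle count at byte offset 80")
  coords <- matrix(NA_real_, n * 3, 3)
  for (i in seq_len(n)) {
    rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
    if (length(rec) < 12)
      stop("STL parse error in ", path, ": truncated record for triangle ",
           i, " at byte offset ", 84 + (i - 1) * 50)
    coords[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    readBin(con, "raw", 2)
  }
  stl_from_triangles(coords, path)
}

stl_from_triangles <- function(coords, path) {
  if (nrow(coords) == 0) stop("empty mesh in ", path)
  # weld identical vertices
  key <- apply(coords, 1, function(r) paste(format(r, digits = 17),
                                            collapse = ","))
  uid <- match(key, unique(key))
  verts <- coords[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  surface_mesh(verts, faces,
               provenance = paste0("read from STL '", basename(path),
                                   "' (triangles only)"))
}

write_stl_ascii <- function(mesh, path) {
  tg <- triangulate_mesh(mesh)
  v <- tg$vertices
  an <- tri_area_normal(v[tg$tris[, 1], , drop = FALSE],
                        v[tg$tris[, 2], , drop = FALSE],
                        v[tg$tris[, 3], , drop = FALSE])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid occlustress", con)
  for (i in seq_len(nrow(tg$tris))) {
    writeLines(sprintf("  facet normal %.9e %.9e %.9e",
                       an$normal[i, 1], an$normal[i, 2], an$normal[i, 3]), con)
    writeLines("    outer loop", con)
    for (j in 1:3) {
      p <- v[tg$tris[i, j], ]
      writeLines(sprintf("      vertex %.9e %.9e %.9e", p[1], p[2], p[3]), con)
    }
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines("endsolid occlustress", con)
}

write_stl_binary <- function(mesh, path) {
  tg <- triangulate_mesh(mesh)
  v <- tg$vertices
  an <- tri_area_normal(v[tg$tris[, 1], , drop = FALSE],
                        v[tg$tris[, 2], , drop = FALSE],
                        v[tg$tris[, 3], , drop = FALSE])
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", "occlustress binary STL"))[1:80]
  writeBin(hdr, con)
  writeBin(as.integer(nrow(tg$tris)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(tg$tris))) {
    rec <- c(an$normal[i, ], t(v[tg$tris[i, ], ]))
    writeBin(as.numeric(rec), con, size = 4, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
}

## ---- OBJ ----------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines)
  fl <- grep("^f\\s", lines)
  if (length(vl) == 0 || length(fl) == 0)
    stop("empty mesh in ", path, ": ", length(vl), " vertices, ",
         length(fl), " faces")
  verts <- matrix(NA_real_, length(vl), 3)
  for (i in seq_along(vl)) {
    tok <- strsplit(trimws(lines[vl[i]]), "\\s+")[[1]]
    val <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(val))
      stop("OBJ parse error in ", path, " at line ", vl[i], ": '",
           lines[vl[i]], "'")
    verts[i, ] <- val
  }
  faces <- matrix(NA_integer_, length(fl), 4)
  for (i in seq_along(fl)) {
    tok <- strsplit(trimws(lines[fl[i]]), "\\s+")[[1]][-1]
    idx <- suppressWarnings(as.integer(sub("/.*$", "", tok)))
    if (anyNA(idx) || !(length(idx) %in% c(3, 4)))
      stop("OBJ parse error in ", path, " at line ", fl[i], ": '",
           lines[fl[i]], "' (only tri/quad faces supported)")
    faces[i, seq_along(idx)] <- idx
  }
  surface_mesh(verts, faces,
               provenance = paste0("read from OBJ '", basename(path), "'"))
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# occlustress OBJ export", con)
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  f <- mesh$faces
  tri <- is.na(f[, 4])
  out <- character(nrow(f))
  out[tri] <- sprintf("f %d %d %d", f[tri, 1], f[tri, 2], f[tri, 3])
  out[!tri] <- sprintf("f %d %d %d %d", f[!tri, 1], f[!tri, 2],
                       f[!tri, 3], f[!tri, 4])
  writeLines(out, con)
}

## ---- PLY ----------------------------------------------------------------

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- read_line_bin(con)
    hdr <- c(hdr, line)
    if (identical(line, "end_header")) break
    if (length(hdr) > 200) stop("PLY parse error in ", path,
                                ": no end_header within 200 lines")
  }
  if (!identical(hdr[1], "ply"))
    stop("PLY parse error in ", path, " at line 1: magic 'ply' missing")
  fmt_line <- grep("^format ", hdr, value = TRUE)
  binary <- grepl("binary_little_endian", fmt_line[1])
  if (!binary && !grepl("ascii", fmt_line[1]))
    stop("PLY parse error in ", path, ": unsupported format '", fmt_line[1],
         "' (ascii and binary_little_endian supported)")
  # parse elements
  elems <- list()
  cur <- NULL
  for (ln in hdr) {
    tok <- strsplit(ln, "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elems[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[tok[5]]] <- list(list = TRUE, size_type = tok[3],
                                    type = tok[4])
      } else {
        cur$props[[tok[3]]] <- list(list = FALSE, type = tok[2])
      }
    }
  }
  if (!is.null(cur)) elems[[cur$name]] <- cur
  if (is.null(elems$vertex) || is.null(elems$face))
    stop("PLY parse error in ", path, ": vertex/face elements missing")
  if (elems$vertex$count == 0 || elems$face$count == 0)
    stop("empty mesh in ", path)
  if (binary) read_ply_binary_body(con, elems, path)
  else read_ply_ascii_body(con, elems, path)
}

ply_type_info <- function(type) {
  switch(type,
         char = , int8 = list(what = "integer", size = 1, signed = TRUE),
         uchar = , uint8 = list(what = "integer", size = 1, signed = FALSE),
         short = , int16 = list(what = "integer", size = 2, signed = TRUE),
         ushort = , uint16 = list(what = "integer", size = 2, signed = FALSE),
         int = , int32 = list(what = "integer", size = 4, signed = TRUE),
         uint = , uint32 = list(what = "integer", size = 4, signed = TRUE),
         float = , float32 = list(what = "numeric", size = 4),
         double = , float64 = list(what = "numeric", size = 8),
         stop("unsupported PLY type: ", type))
}

read_ply_ascii_body <- function(con, elems, path) {
  nv <- elems$vertex$count
  nf <- elems$face$count
  vp <- names(elems$vertex$props)
  verts <- matrix(NA_real_, nv, 3)
  for (i in seq_len(nv)) {
    tok <- suppressWarnings(as.numeric(strsplit(read_line_bin(con),
                                                "\\s+")[[1]]))
    verts[i, ] <- tok[match(c("x", "y", "z"), vp)]
  }
  fp <- elems$face$props
  faces <- matrix(NA_integer_, nf, 4)
  scalars <- lapply(fp[!vapply(fp, `[[`, TRUE, "list")], function(p) numeric(nf))
  for (i in seq_len(nf)) {
    tok <- suppressWarnings(as.numeric(strsplit(read_line_bin(con),
                                                "\\s+")[[1]]))
    pos <- 1
    for (pn in names(fp)) {
      if (fp[[pn]]$list) {
        k <- tok[pos]
        if (!(k %in% c(3, 4)))
          stop("PLY parse error in ", path, ": face ", i, " has ", k,
               " vertices (tri/quad supported)")
        faces[i, seq_len(k)] <- as.integer(tok[pos + seq_len(k)]) + 1L
        pos <- pos + 1 + k
      } else {
        scalars[[pn]][i] <- tok[pos]
        pos <- pos + 1
      }
    }
  }
  finish_ply(verts, faces, scalars, path)
}

read_ply_binary_body <- function(con, elems, path) {
  nv <- elems$vertex$count
  nf <- elems$face$count
  vp <- elems$vertex$props
  verts <- matrix(NA_real_, nv, 3)
  vnames <- names(vp)
  for (i in seq_len(nv)) {
    for (pn in vnames) {
      ti <- ply_type_info(vp[[pn]]$type)
      val <- readBin(con, ti$what, 1, size = ti$size, endian = "little",
                     signed = if (ti$what == "integer" && ti$size < 4)
                       isTRUE(ti$signed) else TRUE)
      if (pn %in% c("x", "y", "z"))
        verts[i, match(pn, c("x", "y", "z"))] <- val
    }
  }
  fp <- elems$face$props
  faces <- matrix(NA_integer_, nf, 4)
  scalars <- lapply(fp[!vapply(fp, `[[`, TRUE, "list")], function(p) numeric(nf))
  for (i in seq_len(nf)) {
    for (pn in names(fp)) {
      p <- fp[[pn]]
      if (p$list) {
        si <- ply_type_info(p$size_type)
        k <- readBin(con, si$what, 1, size = si$size, endian = "little",
                     signed = if (si$size < 4) isTRUE(si$signed) else TRUE)
        ti <- ply_type_info(p$type)
        idx <- readBin(con, ti$what, k, size = ti$size, endian = "little")
        if (!(k %in% c(3, 4)))
          stop("PLY parse error in ", path, ": face ", i, " has ", k,
               " vertices (tri/quad supported)")
        faces[i, seq_len(k)] <- as.integer(idx) + 1L
      } else {
        ti <- ply_type_info(p$type)
        scalars[[pn]][i] <- readBin(con, ti$what, 1, size = ti$size,
                                    endian = "little")
      }
    }
  }
  finish_ply(verts, faces, scalars, path)
}

finish_ply <- function(verts, faces, scalars, path) {
  m <- surface_mesh(verts, faces,
                    provenance = paste0("read from PLY '", basename(path), "'"))
  if (length(scalars)) attr(m, "scalars") <- scalars
  m
}

read_line_bin <- function(con) {
  chars <- raw()
  repeat {
    b <- readBin(con, "raw", 1)
    if (length(b) == 0 || b == as.raw(10)) break
    if (b != as.raw(13)) chars <- c(chars, b)
  }
  rawToChar(chars)
}

write_ply <- function(mesh, path, scalar_fields = NULL, binary = FALSE) {
  nv <- n_vertices(mesh)
  nf <- n_faces(mesh)
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           "comment occlustress export",
           sprintf("element vertex %d", nv),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices")
  for (nm in names(scalar_fields))
    hdr <- c(hdr, sprintf("property double %s", nm))
  hdr <- c(hdr, "end_header")
  f <- mesh$faces
  tri <- is.na(f[, 4])
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
    writeBin(as.numeric(t(mesh$vertices)), con, size = 8, endian = "little")
    for (i in seq_len(nf)) {
      k <- if (tri[i]) 3L else 4L
      writeBin(as.raw(k), con)
      writeBin(as.integer(f[i, seq_len(k)] - 1L), con, size = 4,
               endian = "little")
      for (nm in names(scalar_fields))
        writeBin(as.numeric(scalar_fields[[nm]][i]), con, size = 8,
                 endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(sprintf("%.17g %.17g %.17g", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]), con)
    for (i in seq_len(nf)) {
      k <- if (tri[i]) 3L else 4L
      parts <- c(k, f[i, seq_len(k)] - 1L)
      extra <- vapply(names(scalar_fields),
                      function(nm) sprintf("%.17g", scalar_fields[[nm]][i]),
                      character(1))
      writeLines(paste(c(parts, extra), collapse = " "), con)
    }
  }
}

## ---- VTK (legacy ASCII polydata, export only) ---------------------------

write_vtk <- function(mesh, path, scalar_fields = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "occlustress stress map",
               "ASCII", "DATASET POLYDATA"), con)
  writeLines(sprintf("POINTS %d double", n_vertices(mesh)), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  f <- mesh$faces
  tri <- is.na(f[, 4])
  sizes <- ifelse(tri, 3L, 4L)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), sum(sizes + 1L)), con)
  out <- character(nrow(f))
  out[tri] <- sprintf("3 %d %d %d", f[tri, 1] - 1L, f[tri, 2] - 1L,
                      f[tri, 3] - 1L)
  out[!tri] <- sprintf("4 %d %d %d %d", f[!tri, 1] - 1L, f[!tri, 2] - 1L,
                       f[!tri, 3] - 1L, f[!tri, 4] - 1L)
  writeLines(out, con)
  if (length(scalar_fields)) {
    writeLines(sprintf("CELL_DATA %d", nrow(f)), con)
    for (nm in names(scalar_fields)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", scalar_fields[[nm]]), con)
    }
  }
}
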