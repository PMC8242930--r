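# Readers and writers for OBJ (ASCII), STL (binary and ASCII) and PLY
# (ASCII). Units are taken as meters; no unit inference is attempted.
# Faces are 1-based internally (R convention); OBJ is 1-based on disk,
# PLY and STL are converted at the boundary.

.mesh_format <- function(path, format = NULL) {
  if (!is.null(format)) return(tolower(format))
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("obj", "stl", "ply"))
    stop("cannot infer mesh format from extension '", ext, "'", call. = FALSE)
  ext
}

#' Read a triangle mesh from OBJ, STL or PLY
#'
#' Polygon faces are fan-triangulated. Binary STL is detected from the file
#' size implied by its 80-byte header / 50-byte facet records; STL vertices
#' (stored per facet) are welded under exact coordinate equality.
#'
#' @param path file path.
#' @param format `"obj"`, `"stl"` or `"ply"`; inferred from the extension
#'   when `NULL`.
#' @return a `triangle_mesh`.
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  mesh <- switch(.mesh_format(path, format),
                 obj = .read_obj(path),
                 stl = .read_stl(path),
                 ply = .read_ply(path),
                 stop("unsupported mesh format", call. = FALSE))
  .repair_orientation(mesh)
}

#' Write a triangle mesh to OBJ, STL or PLY
#'
#' The mesh must pass [validate_mesh()]; invalid meshes are refused.
#' STL output is binary (single precision, per the 50-byte record layout);
#' OBJ and PLY are ASCII with 17 significant digits, so coordinates
#' round-trip bit-exactly.
#'
#' @param mesh a `triangle_mesh`.
#' @param path output file path.
#' @param format `"obj"`, `"stl"` or `"ply"`; inferred from the extension
#'   when `NULL`.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  rep_ <- validate_mesh(mesh)
  if (!rep_$ok)
    stop("refusing to write invalid mesh (watertight=", rep_$watertight,
         ", oriented=", rep_$consistently_oriented,
         ", positive_volume=", rep_$positive_volume,
         ", degenerate=", length(rep_$degenerate_faces), ")", call. = FALSE)
  switch(.mesh_format(path, format),
         obj = .write_obj(mesh, path),
         stl = .write_stl(mesh, path),
         ply = .write_ply(mesh, path),
         stop("unsupported mesh format", call. = FALSE))
  invisible(path)
}

# ---- OBJ -------------------------------------------------------------------

.read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vts <- list(); fcs <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    toks <- strsplit(ln, "[ \t]+")[[1]]
    if (toks[1] == "v") {
      xyz <- suppressWarnings(as.numeric(toks[2:4]))
      if (length(toks) < 4L || any(is.na(xyz)))
        stop("OBJ parse error at line ", i, ": bad vertex record", call. = FALSE)
      vts[[length(vts) + 1L]] <- xyz
    } else if (toks[1] == "f") {
      idx <- suppressWarnings(as.integer(sub("/.*$", "", toks[-1])))
      if (length(idx) < 3L || any(is.na(idx)) || any(idx == 0L))
        stop("OBJ parse error at line ", i, ": bad face record", call. = FALSE)
      if (any(idx < 0L))
        stop("OBJ parse error at line ", i,
             ": negative (relative) indices unsupported", call. = FALSE)
      # fan triangulation of polygons
      for (k in 2:(length(idx) - 1L))
        fcs[[length(fcs) + 1L]] <- idx[c(1L, k, k + 1L)]
    }
  }
  if (length(fcs) == 0L) stop("empty mesh: OBJ file has no faces", call. = FALSE)
  triangle_mesh(do.call(rbind, vts), do.call(rbind, fcs))
}

.write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.17g %.17g %.17g",
                     mesh$vertices[, 1L], mesh$vertices[, 2L],
                     mesh$vertices[, 3L]), con)
  writeLines(sprintf("f %d %d %d",
                     mesh$faces[, 1L], mesh$faces[, 2L], mesh$faces[, 3L]), con)
}

# ---- STL -------------------------------------------------------------------

.read_stl <- function(path) {
  sz <- file.size(path)
  if (sz >= 84L) {
    con <- file(path, "rb")
    hdr <- readBin(con, "raw", 80L)
    ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    close(con)
    if (!is.na(ntri) && ntri >= 0L && sz == 84 + 50 * as.numeric(ntri))
      return(.read_stl_binary(path, ntri))
  }
  .read_stl_ascii(path)
}

.read_stl_binary <- function(path, ntri) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 84L))
  if (ntri == 0L) stop("empty mesh: binary STL has zero facets", call. = FALSE)
  tri <- matrix(NA_real_, ntri, 9L)
  for (k in seq_len(ntri)) {
    rec <- readBin(con, "numeric", 12L, size = 4L, endian = "little")
    if (length(rec) < 12L)
      stop("STL parse error: truncated facet record ", k, " of ", ntri,
           call. = FALSE)
    invisible(readBin(con, "raw", 2L))  # attribute byte count
    tri[k, ] <- rec[4:12]               # drop the stored normal
  }
  .weld_tri_soup(tri)
}

.read_stl_ascii <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vlines <- grep("^vertex[ \t]", lines)
  if (length(vlines) == 0L || length(vlines) %% 3L != 0L)
    stop("STL parse error: vertex count ", length(vlines),
         " is not a multiple of 3", call. = FALSE)
  coords <- t(vapply(lines[vlines], function(ln) {
    xyz <- suppressWarnings(as.numeric(strsplit(ln, "[ \t]+")[[1]][2:4]))
    if (any(is.na(xyz))) stop("STL parse error: bad vertex line", call. = FALSE)
    xyz
  }, numeric(3), USE.NAMES = FALSE))
  tri <- matrix(t(coords), ncol = 9L, byrow = TRUE)
  .weld_tri_soup(tri)
}

# weld per-facet vertex records into a shared vertex table (exact equality)
.weld_tri_soup <- function(tri) {
  pts <- rbind(tri[, 1:3, drop = FALSE], tri[, 4:6, drop = FALSE],
               tri[, 7:9, drop = FALSE])
  key <- paste(sprintf("%.17g", pts[, 1L]), sprintf("%.17g", pts[, 2L]),
               sprintf("%.17g", pts[, 3L]))
  uid <- match(key, unique(key))
  verts <- pts[!duplicated(key), , drop = FALSE]
  n <- nrow(tri)
  faces <- cbind(uid[seq_len(n)], uid[n + seq_len(n)], uid[2L * n + seq_len(n)])
  triangle_mesh(verts, faces)
}

.write_stl <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80L), con)
  n <- nrow(mesh$faces)
  writeBin(as.integer(n), con, size = 4L, endian = "little")
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  nx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  ny <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  nz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  len <- pmax(sqrt(nx^2 + ny^2 + nz^2), .Machine$double.xmin)
  for (k in seq_len(n)) {
    rec <- c(nx[k] / len[k], ny[k] / len[k], nz[k] / len[k],
             v[f[k, 1L], ], v[f[k, 2L], ], v[f[k, 3L], ])
    writeBin(rec, con, size = 4L, endian = "little")
    writeBin(as.integer(0L), con, size = 2L, endian = "little")
  }
}

# ---- PLY (ASCII) -----------------------------------------------------------

.read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || trimws(lines[1]) != "ply")
    stop("PLY parse error at line 1: missing 'ply' magic", call. = FALSE)
  i <- 2L; nvert <- NA_integer_; nface <- NA_integer_; in_elem <- ""
  vprops <- character(0)
  while (i <= length(lines)) {
    toks <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (identical(toks[1], "format")) {
      if (!identical(toks[2], "ascii"))
        stop("PLY parse error at line ", i, ": only ASCII PLY supported",
             call. = FALSE)
    } else if (identical(toks[1], "element")) {
      in_elem <- toks[2]
      if (toks[2] == "vertex") nvert <- as.integer(toks[3])
      if (toks[2] == "face") nface <- as.integer(toks[3])
    } else if (identical(toks[1], "property") && in_elem == "vertex" &&
               !identical(toks[2], "list")) {
      vprops <- c(vprops, toks[length(toks)])
    } else if (identical(toks[1], "end_header")) break
    i <- i + 1L
  }
  if (i > length(lines))
    stop("PLY parse error: no end_header", call. = FALSE)
  if (is.na(nvert) || is.na(nface))
    stop("PLY parse error: missing vertex or face element", call. = FALSE)
  if (nface == 0L) stop("empty mesh: PLY file has no faces", call. = FALSE)
  xyz_cols <- match(c("x", "y", "z"), vprops)
  if (any(is.na(xyz_cols)))
    stop("PLY parse error: vertex element lacks x/y/z properties", call. = FALSE)
  body <- lines[(i + 1L):length(lines)]
  body <- body[trimws(body) != ""]
  if (length(body) < nvert + nface)
    stop("PLY parse error: expected ", nvert + nface, " body lines, found ",
         length(body), call. = FALSE)
  verts <- t(vapply(body[seq_len(nvert)], function(ln) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[ \t]+")[[1]]))
    if (length(vals) < length(vprops) || any(is.na(vals[xyz_cols])))
      stop("PLY parse error: bad vertex line", call. = FALSE)
    vals[xyz_cols]
  }, numeric(3), USE.NAMES = FALSE))
  fcs <- list()
  for (k in seq_len(nface)) {
    vals <- suppressWarnings(as.integer(strsplit(trimws(body[nvert + k]),
                                                 "[ \t]+")[[1]]))
    cnt <- vals[1]
    if (is.na(cnt) || cnt < 3L || length(vals) < 1L + cnt || any(is.na(vals)))
      stop("PLY parse error: bad face record ", k, call. = FALSE)
    idx <- vals[2:(1L + cnt)] + 1L   # 0-based on disk
    for (j in 2:(cnt - 1L)) fcs[[length(fcs) + 1L]] <- idx[c(1L, j, j + 1L)]
  }
  triangle_mesh(verts, do.call(rbind, fcs))
}

.write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g",
                     mesh$vertices[, 1L], mesh$vertices[, 2L],
                     mesh$vertices[, 3L]), con)
  writeLines(sprintf("3 %d %d %d",
                     mesh$faces[, 1L] - 1L, mesh$faces[, 2L] - 1L,
                     mesh$faces[, 3L] - 1L), con)
}
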