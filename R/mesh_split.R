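# Planar slicing of watertight meshes into equal-extent sub-segments.
#
# Used for elongate segments (tails), which are cut by n-1 parallel planes
# at equal spacing along a chosen axis; every cut cross-section is closed
# with cap faces so each piece is again a watertight solid. "Equal" means
# equal extent along the slicing axis, not equal volume.

# Clip a watertight mesh with the halfspace a.x <= d, capping the cut.
# Returns NULL when nothing is kept.
.clip_halfspace <- function(mesh, a, d) {
  v <- mesh$vertices; f <- mesh$faces
  s <- as.numeric(v %*% a) - d
  inside <- s <= 0
  nkeep <- inside[f[, 1L]] + inside[f[, 2L]] + inside[f[, 3L]]

  newv <- list()          # intersection points, welded by coordinate key
  newkey <- character(0)
  nv0 <- nrow(v)
  get_cut_vertex <- function(i, j) {
    # canonical endpoint order makes the interpolation bitwise identical
    # for the two triangles sharing the edge
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    t <- s[i] / (s[i] - s[j])
    p <- v[i, ] + t * (v[j, ] - v[i, ])
    key <- paste(i, j)
    hit <- match(key, newkey)
    if (!is.na(hit)) return(nv0 + hit)
    newv[[length(newv) + 1L]] <<- p
    newkey[length(newkey) + 1L] <<- key
    nv0 + length(newv)
  }

  outf <- list()
  emit <- function(tri) outf[[length(outf) + 1L]] <<- tri
  for (k in seq_len(nrow(f))) {
    if (nkeep[k] == 0L) next
    tri <- f[k, ]
    if (nkeep[k] == 3L) { emit(tri); next }
    # Sutherland-Hodgman on the triangle; "inside" is s <= 0
    poly <- integer(0)
    for (e in 1:3) {
      i <- tri[e]; j <- tri[if (e == 3L) 1L else e + 1L]
      ii <- inside[i]; ji <- inside[j]
      if (ii) poly <- c(poly, i)
      if (ii != ji && s[i] != 0 && s[j] != 0)
        poly <- c(poly, get_cut_vertex(i, j))
    }
    if (length(poly) < 3L) next
    for (t in 2:(length(poly) - 1L))
      emit(poly[c(1L, t, t + 1L)])
  }
  if (length(outf) == 0L) return(NULL)
  allv <- rbind(v, do.call(rbind, newv))
  faces <- do.call(rbind, outf)

  # cap: open boundary edges of the kept surface lie in the cut plane;
  # chain them into loops and fan each loop from its centroid, reversed so
  # cap normals point along +a (outward for the kept side)
  de <- .directed_edges(faces)
  dkey <- paste(de[, 1L], de[, 2L])
  rkey <- paste(de[, 2L], de[, 1L])
  open_ <- de[!(rkey %in% dkey), , drop = FALSE]
  caps <- list()
  if (nrow(open_) > 0L) {
    nxt <- new.env(parent = emptyenv())
    for (r in seq_len(nrow(open_)))
      assign(as.character(open_[r, 1L]), open_[r, 2L], envir = nxt)
    visited <- new.env(parent = emptyenv())
    for (r in seq_len(nrow(open_))) {
      start <- open_[r, 1L]
      if (!is.null(visited[[as.character(start)]])) next
      loop <- integer(0)
      cur <- start
      repeat {
        ck <- as.character(cur)
        if (!is.null(visited[[ck]])) break
        visited[[ck]] <- TRUE
        loop <- c(loop, cur)
        nx <- nxt[[ck]]
        if (is.null(nx)) stop("cut produced an open, unchainable boundary",
                              call. = FALSE)
        cur <- nx
        if (cur == start) break
      }
      if (length(loop) < 3L)
        stop("degenerate cut cross-section", call. = FALSE)
      centroid <- colMeans(allv[loop, , drop = FALSE])
      allv <- rbind(allv, centroid)
      ci <- nrow(allv)
      m <- length(loop)
      for (e in seq_len(m)) {
        p <- loop[e]; q <- loop[if (e == m) 1L else e + 1L]
        caps[[length(caps) + 1L]] <- c(ci, q, p)
      }
    }
  }
  if (length(caps)) faces <- rbind(faces, do.call(rbind, caps))
  # drop unreferenced vertices
  keep <- sort(unique(as.vector(faces)))
  triangle_mesh(allv[keep, , drop = FALSE],
                matrix(match(faces, keep), ncol = 3L))
}

#' Split a mesh into equal-extent pieces along an axis
#'
#' Cuts a watertight mesh with `n_segments - 1` parallel planes at equal
#' spacing along the chosen axis, closing every cross-section with cap
#' faces. Pieces are returned proximal to distal, i.e. ordered by
#' decreasing coordinate along the axis. The sum of piece volumes equals
#' the input volume up to floating point.
#'
#' @param mesh a watertight, outward-oriented `triangle_mesh`.
#' @param n_segments number of pieces (>= 1; 1 returns the input unchanged).
#' @param axis `"auto"` (principal axis of the vertex cloud, sign pointing
#'   toward the extreme vertex with the larger absolute coordinate), one of
#'   `"x"`, `"y"`, `"z"`, or a numeric length-3 direction vector.
#' @return list of `n_segments` watertight `triangle_mesh` pieces.
#' @export
split_along_axis <- function(mesh, n_segments, axis = "auto") {
  mesh <- .require_solid(mesh)
  n_segments <- as.integer(n_segments)
  if (is.na(n_segments) || n_segments < 1L)
    stop("n_segments must be a positive integer", call. = FALSE)
  if (n_segments == 1L) return(list(mesh))

  if (is.character(axis)) {
    a <- switch(axis,
      x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1),
      auto = {
        cv <- stats::cov(mesh$vertices)
        ev <- eigen(cv, symmetric = TRUE)
        a0 <- ev$vectors[, 1L]
        pr <- as.numeric(mesh$vertices %*% a0)
        if (max(pr) < -min(pr)) -a0 else a0
      },
      stop("axis must be 'x', 'y', 'z', 'auto' or a length-3 vector",
           call. = FALSE))
  } else {
    a <- as.numeric(axis)
    if (length(a) != 3L || sum(a^2) == 0)
      stop("axis must be a nonzero length-3 vector", call. = FALSE)
    a <- a / sqrt(sum(a^2))
  }

  proj <- as.numeric(mesh$vertices %*% a)
  lo <- min(proj); hi <- max(proj)
  if (hi - lo <= 0) stop("mesh has zero extent along the axis", call. = FALSE)
  cuts <- seq(lo, hi, length.out = n_segments + 1L)

  pieces <- vector("list", n_segments)
  for (i in seq_len(n_segments)) {
    # piece i is the slab [cuts[n+1-i], cuts[n+2-i]]: decreasing coordinate
    upper <- cuts[n_segments + 2L - i]
    lower <- cuts[n_segments + 1L - i]
    piece <- mesh
    if (i > 1L) piece <- .clip_halfspace(piece, a, upper)
    if (!is.null(piece) && i < n_segments)
      piece <- .clip_halfspace(piece, -a, -lower)
    if (is.null(piece))
      stop("degenerate split: cut plane produced an empty piece", call. = FALSE)
    pieces[[i]] <- piece
  }
  pieces
}
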