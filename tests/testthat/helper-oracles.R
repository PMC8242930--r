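# Independent oracles and fixture builders shared across the suite. Every
# oracle here deliberately uses a different algorithm from the code path it
# checks.

# brute-force convex hull volume: enumerate all vertex triples whose plane
# supports the whole cloud (general position assumed), orient outward, sum
# signed origin tetrahedra. O(n^4) but fully vectorized.
oracle_hull_volume <- function(pts) {
  n <- nrow(pts)
  tol <- 1e-9 * max(abs(pts), 1)
  tri <- t(combn(n, 3L))
  A <- pts[tri[, 1L], , drop = FALSE]
  B <- pts[tri[, 2L], , drop = FALSE]
  C <- pts[tri[, 3L], , drop = FALSE]
  e1 <- B - A; e2 <- C - A
  N <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  D <- pts %*% t(N) - rep(rowSums(N * A), each = n)   # n x ntriples
  below <- colSums(D <= tol) == n
  above <- colSums(D >= -tol) == n
  vol <- 0
  det3 <- function(a, b, c_)
    a[1] * (b[2] * c_[3] - b[3] * c_[2]) -
    a[2] * (b[1] * c_[3] - b[3] * c_[1]) +
    a[3] * (b[1] * c_[2] - b[2] * c_[1])
  for (k in which(below | above)) {
    a <- pts[tri[k, 1L], ]; b <- pts[tri[k, 2L], ]; c_ <- pts[tri[k, 3L], ]
    # the triple's own orientation has normal N[k, ]; when every point is
    # "below" that plane, N[k, ] is outward and (a, b, c) is already
    # outward-oriented; otherwise flip
    vol <- vol + (if (below[k]) 1 else -1) * det3(a, b, c_) / 6
  }
  vol
}

# random convex polyhedron: hull of n_pts points on/in a unit-ish ellipsoid
random_hull_mesh <- function(n_pts = 50L, seed = 1L) {
  set.seed(seed)
  pts <- matrix(rnorm(3L * n_pts), ncol = 3L)
  pts <- pts * rep(runif(3, 0.5, 1.5), each = n_pts)
  convex_hull(pts)$hull
}

# normal-equations OLS oracle
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  as.numeric(solve(t(X) %*% X) %*% t(X) %*% y)
}

# explicit-refit LOOCV oracle
oracle_loocv <- function(x, y) {
  err <- vapply(seq_along(x), function(i) {
    fit <- stats::lm(y[-i] ~ x[-i])
    y[i] - (coef(fit)[1] + coef(fit)[2] * x[i])
  }, 0)
  sqrt(mean(err^2))
}

# shared root-to-tip path length oracle computed by walking the edge table
oracle_bm_vcv <- function(tree, species) {
  nt <- length(tree$tip.label)
  parent_edge <- function(node) which(tree$edge[, 2L] == node)
  path_edges <- function(tip) {
    edges <- integer(0)
    node <- tip
    repeat {
      e <- parent_edge(node)
      if (length(e) == 0L) break
      edges <- c(edges, e)
      node <- tree$edge[e, 1L]
    }
    edges
  }
  idx <- match(species, tree$tip.label)
  paths <- lapply(idx, path_edges)
  V <- matrix(0, length(idx), length(idx),
              dimnames = list(species, species))
  for (i in seq_along(idx)) for (j in seq_along(idx))
    V[i, j] <- sum(tree$edge.length[intersect(paths[[i]], paths[[j]])])
  V
}

# watertight bent tube: octagonal multi-ring tube along x with a quadratic
# bend in z (genuinely non-convex, unlike a sheared two-ring prism)
bent_tube_mesh <- function(n_rings = 9L) {
  ang <- seq(0, 2 * pi, length.out = 9L)[-9L]
  k <- length(ang)
  xs <- seq(-1, 1, length.out = n_rings)
  v <- do.call(rbind, lapply(xs, function(x)
    cbind(x, 0.15 * cos(ang), 0.15 * sin(ang))))
  f <- list()
  for (r in seq_len(n_rings - 1L)) {
    o1 <- (r - 1L) * k; o2 <- r * k
    for (i in seq_len(k)) {
      j <- if (i == k) 1L else i + 1L
      f[[length(f) + 1L]] <- c(o1 + i, o1 + j, o2 + j)
      f[[length(f) + 1L]] <- c(o1 + i, o2 + j, o2 + i)
    }
  }
  for (i in 2:(k - 1L)) f[[length(f) + 1L]] <- c(1L, i + 1L, i)
  o <- (n_rings - 1L) * k
  for (i in 2:(k - 1L)) f[[length(f) + 1L]] <- c(o + 1L, o + i, o + i + 1L)
  m <- triangle_mesh(v, do.call(rbind, f))
  m$vertices[, 3L] <- m$vertices[, 3L] + 0.2 * m$vertices[, 1L]^2
  m
}

# mass-weighted composite centre of mass of a list of bsps
composite_com <- function(bsps) {
  m <- vapply(bsps, function(b) b$mass, 0)
  coms <- t(vapply(bsps, function(b) b$com, numeric(3)))
  colSums(coms * m) / sum(m)
}

expect_rel_equal <- function(actual, expected, tol) {
  scale <- pmax(abs(expected), 1e-12)
  expect_true(all(abs(actual - expected) / scale <= tol),
              label = sprintf("max rel err %.3g <= %.3g",
                              max(abs(actual - expected) / scale), tol))
}
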