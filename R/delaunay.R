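# Delaunay triangulation by the Bowyer-Watson incremental algorithm.
# Point sets here are sampling localities (tens of points), so the simple
# O(n^2) insertion is ample. Coordinates are treated as planar (lon, lat);
# edge *lengths* elsewhere use great-circle distance.

# returns integer matrix of triangles (rows: point indices)
delaunay_triangulate <- function(x, y) {
  n <- length(x)
  if (n < 3) abort("Delaunay triangulation needs >= 3 points")
  # collinearity check via maximal triangle area
  area2 <- 0
  for (tri in utils::combn(n, 3, simplify = FALSE)) {
    a <- tri[1]; b <- tri[2]; c <- tri[3]
    area2 <- max(area2, abs((x[b] - x[a]) * (y[c] - y[a]) -
                              (x[c] - x[a]) * (y[b] - y[a])))
    if (area2 > 1e-12) break
  }
  if (area2 <= 1e-12) {
    abort(paste0("all localities are collinear; Delaunay triangulation ",
                 "undefined (consider a complete-graph connectivity fallback)"))
  }

  # super-triangle enclosing all points
  cx <- mean(range(x)); cy <- mean(range(y))
  span <- max(diff(range(x)), diff(range(y))) * 100 + 1
  px <- c(x, cx - 2 * span, cx + 2 * span, cx)
  py <- c(y, cy - span, cy - span, cy + 2 * span)
  tris <- matrix(c(n + 1L, n + 2L, n + 3L), ncol = 3)

  circum <- function(tri) {
    ax <- px[tri[1]]; ay <- py[tri[1]]
    bx <- px[tri[2]]; by <- py[tri[2]]
    cx2 <- px[tri[3]]; cy2 <- py[tri[3]]
    d <- 2 * (ax * (by - cy2) + bx * (cy2 - ay) + cx2 * (ay - by))
    ux <- ((ax^2 + ay^2) * (by - cy2) + (bx^2 + by^2) * (cy2 - ay) +
             (cx2^2 + cy2^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx2 - bx) + (bx^2 + by^2) * (ax - cx2) +
             (cx2^2 + cy2^2) * (bx - ax)) / d
    c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
  }

  for (i in seq_len(n)) {
    bad <- logical(nrow(tris))
    for (t in seq_len(nrow(tris))) {
      cc <- circum(tris[t, ])
      bad[t] <- (px[i] - cc[1])^2 + (py[i] - cc[2])^2 < cc[3] * (1 + 1e-12)
    }
    # boundary of the cavity: edges of bad triangles not shared by two of them
    edges <- NULL
    for (t in which(bad)) {
      tr <- tris[t, ]
      edges <- rbind(edges, tr[c(1, 2)], tr[c(2, 3)], tr[c(3, 1)])
    }
    key <- apply(edges, 1, function(e) paste(sort(e), collapse = "-"))
    keep <- key %in% names(which(table(key) == 1))
    edges <- edges[keep, , drop = FALSE]
    tris <- tris[!bad, , drop = FALSE]
    for (e in seq_len(nrow(edges))) {
      tris <- rbind(tris, c(edges[e, ], i))
    }
  }
  # drop triangles touching the super-triangle
  tris <- tris[apply(tris <= n, 1, all), , drop = FALSE]
  tris
}

# unique undirected edges (two-column integer matrix, a < b) of a triangulation
delaunay_edges <- function(tris) {
  e <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  e <- t(apply(e, 1, sort))
  unique(e)
}
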