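# Voronoi adjacency by direct cell construction.
#
# Each point's Voronoi cell is the intersection of the half-planes bounded
# by the perpendicular bisectors toward every other point, clipped to a
# bounding box. Two points are neighbours iff their cells share an edge of
# positive length inside the box — cells that meet only at a vertex (the
# cocircular tie case, e.g. the diagonals of a perfect square) are not
# neighbours. Cells are built by successive polygon clipping; candidate
# points are visited nearest-first and the scan stops once half the distance
# to the next candidate exceeds the cell's current vertex radius, which
# cannot change the cell.

# Clip a convex polygon (matrix of vertices, counterclockwise) by the
# half-plane {x : (x - m) . n <= 0}. Edges introduced by this clip are
# labelled `label`; `edge_label[i]` labels the edge from vertex i to i+1.
clip_halfplane <- function(poly, edge_label, m, n, label) {
  nv <- nrow(poly)
  s <- (poly[, 1] - m[1]) * n[1] + (poly[, 2] - m[2]) * n[2]
  if (all(s <= 1e-12)) return(list(poly = poly, edge_label = edge_label))
  if (all(s >= -1e-12)) return(NULL)  # cell vanishes
  keep_poly <- matrix(numeric(0), ncol = 2)
  keep_lab <- integer(0)
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    inside_i <- s[i] <= 1e-12
    inside_j <- s[j] <= 1e-12
    if (inside_i) {
      keep_poly <- rbind(keep_poly, poly[i, ])
      if (inside_j) {
        keep_lab <- c(keep_lab, edge_label[i])
      } else {
        t <- s[i] / (s[i] - s[j])
        keep_poly <- rbind(keep_poly, poly[i, ] + t * (poly[j, ] - poly[i, ]))
        # edge from vertex i to the crossing keeps the old label; the new
        # edge along the bisector (crossing to re-entry) gets `label`
        keep_lab <- c(keep_lab, edge_label[i], label)
      }
    } else if (inside_j) {
      t <- s[i] / (s[i] - s[j])
      keep_poly <- rbind(keep_poly, poly[i, ] + t * (poly[j, ] - poly[i, ]))
      keep_lab <- c(keep_lab, edge_label[i])
    }
  }
  if (nrow(keep_poly) < 3) return(NULL)
  list(poly = keep_poly, edge_label = keep_lab)
}

# Voronoi cell of point `i` clipped to bbox; returns the labels of the
# points contributing an edge of length > tol.
voronoi_cell_neighbors <- function(pts, i, bbox, tol = 1e-9) {
  poly <- rbind(
    c(bbox[1], bbox[3]), c(bbox[2], bbox[3]),
    c(bbox[2], bbox[4]), c(bbox[1], bbox[4])
  )
  edge_label <- rep(0L, 4)  # 0 = bounding-box edge
  p <- pts[i, ]
  d2 <- (pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2
  ord <- order(d2)
  ord <- ord[ord != i]
  for (k in ord) {
    # prune: a bisector at distance dk/2 cannot cut a cell whose farthest
    # vertex is nearer than that
    vert_r2 <- max((poly[, 1] - p[1])^2 + (poly[, 2] - p[2])^2)
    if (d2[k] / 4 > vert_r2 + tol) break
    q <- pts[k, ]
    res <- clip_halfplane(poly, edge_label, m = (p + q) / 2, n = q - p,
                          label = k)
    if (is.null(res)) {
      abort("Degenerate geometry: a point's Voronoi cell is empty (duplicate or out-of-box point).")
    }
    poly <- res$poly
    edge_label <- res$edge_label
  }
  nv <- nrow(poly)
  jnext <- c(seq_len(nv)[-1], 1L)
  len <- sqrt((poly[jnext, 1] - poly[, 1])^2 + (poly[jnext, 2] - poly[, 2])^2)
  unique(edge_label[edge_label > 0 & len > tol])
}

#' Voronoi neighbour relation over a point set
#'
#' Computes which pairs of points have Voronoi cells sharing an edge (of
#' positive length) within a bounding box. Cells touching only at a vertex —
#' the cocircular tie case, such as the two diagonals of a perfect square —
#' are not neighbours. The relation is symmetric.
#'
#' @param points Tibble/data frame with columns `x_deg`, `y_deg` (at least 4
#'   non-collinear, distinct points).
#' @param bbox Bounding box `c(x_min, x_max, y_min, y_max)`; defaults to the
#'   points' extent padded by one unit.
#' @return A tibble of neighbour pairs `i`, `j` (row indices, `i < j`).
#' @export
voronoi_neighbors <- function(points, bbox = NULL) {
  pts <- cbind(points$x_deg, points$y_deg)
  n <- nrow(pts)
  if (n < 4) abort("Voronoi adjacency needs at least 4 points.")
  if (anyDuplicated(round(pts / 1e-9)) > 0) {
    abort("Degenerate geometry: duplicate points.")
  }
  # collinearity: rank of centered coordinates
  centered <- sweep(pts, 2, colMeans(pts))
  if (svd(centered)$d[2] < 1e-9 * max(1, svd(centered)$d[1])) {
    abort("Degenerate geometry: all points are collinear.")
  }
  if (is.null(bbox)) {
    bbox <- c(min(pts[, 1]) - 1, max(pts[, 1]) + 1,
              min(pts[, 2]) - 1, max(pts[, 2]) + 1)
  }
  pairs <- purrr::map(seq_len(n), function(idx) {
    nb <- voronoi_cell_neighbors(pts, idx, bbox)
    if (length(nb) == 0) return(NULL)
    tibble(a = as.integer(pmin(idx, nb)), b = as.integer(pmax(idx, nb)))
  })
  # keep only pairs confirmed from both cells (guards the tie tolerance)
  counts <- dplyr::count(bind_rows(pairs), .data$a, .data$b)
  both <- filter(counts, .data$n == 2L)
  arrange(tibble(i = both$a, j = both$b), .data$i, .data$j)
}

#' Adjacency lookup from a neighbour-pair table
#'
#' @param pairs Result of [voronoi_neighbors()].
#' @param n Number of points.
#' @return A list of integer vectors, `adj[[i]]` giving the neighbours of i.
#' @export
neighbor_list <- function(pairs, n) {
  adj <- rep(list(integer(0)), n)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, sort)
}
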