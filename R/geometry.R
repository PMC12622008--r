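# TLS polygon construction and structure-anchored distance axes.
# All geometry is 2D Euclidean in microns; polygons are simple closed
# rings and the boundary counts as inside.

# Connected components of the "within eps" graph, exact pairwise in
# chunks (TLS-zone subsets are small). Components are numbered by their
# smallest member row index so grouping is deterministic.
group_points_eps <- function(xy, eps) {
  n <- nrow(xy)
  if (n == 1L) return(1L)
  edges <- list()
  chunk <- 1000L
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    d2 <- outer(xy[rows, 1], xy[, 1], "-")^2 + outer(xy[rows, 2], xy[, 2], "-")^2
    hit <- which(d2 <= eps^2, arr.ind = TRUE)
    hit[, 1] <- rows[hit[, 1]]
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    edges[[length(edges) + 1L]] <- hit
  }
  e <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  # renumber components by first appearance
  first <- tapply(seq_len(n), comp, min)
  rank <- rank(first)
  as.integer(rank[as.character(comp)])
}

# circumradius of triangle (a, b, c), rows of a 3 x 2 matrix
circumradius <- function(tri) {
  a <- sqrt(sum((tri[1, ] - tri[2, ])^2))
  b <- sqrt(sum((tri[2, ] - tri[3, ])^2))
  c <- sqrt(sum((tri[3, ] - tri[1, ])^2))
  s <- (a + b + c) / 2
  area2 <- s * (s - a) * (s - b) * (s - c)
  if (area2 <= 0) return(Inf)
  a * b * c / (4 * sqrt(area2))
}

# signed shoelace area of an open ring (no repeated end vertex)
shoelace <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(2:nrow(ring), 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Polygon area (shoelace)
#' @param ring two-column vertex matrix; a repeated closing vertex is
#'   tolerated.
#' @return area in square microns.
#' @export
polygon_area <- function(ring) {
  ring <- drop_closing_vertex(ring)
  abs(shoelace(ring))
}

#' Polygon area centroid
#' @inheritParams polygon_area
#' @return length-2 numeric (x, y); vertex mean for degenerate polygons.
#' @export
polygon_centroid <- function(ring) {
  ring <- drop_closing_vertex(ring)
  a <- shoelace(ring)
  if (abs(a) < 1e-12) return(colMeans(ring))
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(2:nrow(ring), 1L)
  cross <- x * y[j] - x[j] * y
  c(sum((x + x[j]) * cross), sum((y + y[j]) * cross)) / (6 * a)
}

drop_closing_vertex <- function(ring) {
  ring <- as.matrix(ring)
  n <- nrow(ring)
  if (n > 1L && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  ring
}

close_ring <- function(ring) rbind(ring, ring[1, , drop = FALSE])

convex_hull_ring <- function(xy) {
  h <- grDevices::chull(xy[, 1], xy[, 2])
  xy[h, , drop = FALSE]
}

#' Concave hull of a point set
#'
#' Alpha-shape-style hull: Delaunay triangles with circumradius at most
#' `concavity` are kept and their outer boundary is returned as a simple
#' ring. With `concavity = Inf` (or degenerate triangulations) the convex
#' hull is returned. If the filtered triangulation does not yield a single
#' outer boundary (too small a concavity for the point spacing), the
#' convex hull is returned with a warning.
#'
#' @param xy two-column coordinate matrix (microns).
#' @param concavity characteristic length scale in microns.
#' @return open vertex ring (matrix, counter-clockwise, no repeated end
#'   vertex).
#' @export
concave_hull <- function(xy, concavity = Inf) {
  xy <- unique(as.matrix(xy))
  if (nrow(xy) < 3L) stop_tls("a hull needs >= 3 distinct points")
  if (!is.finite(concavity)) return(orient_ccw(convex_hull_ring(xy)))
  tri <- tryCatch(
    deldir::triang.list(deldir::deldir(xy[, 1], xy[, 2], suppressMsge = TRUE)),
    error = function(e) NULL)
  if (is.null(tri) || length(tri) == 0L) {
    return(orient_ccw(convex_hull_ring(xy)))
  }
  keep <- Filter(function(t) {
    circumradius(cbind(t$x, t$y)) <= concavity
  }, tri)
  if (length(keep) == 0L) {
    warning("concavity too small for point spacing; returning convex hull")
    return(orient_ccw(convex_hull_ring(xy)))
  }
  # boundary = edges used by exactly one kept triangle
  edge_key <- function(p1, p2) {
    a <- pmin(p1, p2); b <- pmax(p1, p2)
    paste(a[, 1], a[, 2], b[, 1], b[, 2], sep = "_")
  }
  ee <- do.call(rbind, lapply(keep, function(t) {
    v <- cbind(t$x, t$y)
    rbind(cbind(v[1, , drop = FALSE], v[2, , drop = FALSE]),
          cbind(v[2, , drop = FALSE], v[3, , drop = FALSE]),
          cbind(v[3, , drop = FALSE], v[1, , drop = FALSE]))
  }))
  key <- edge_key(ee[, 1:2, drop = FALSE], ee[, 3:4, drop = FALSE])
  once <- names(which(table(key) == 1L))
  bnd <- ee[key %in% once, , drop = FALSE]
  ring <- assemble_ring(bnd)
  if (is.null(ring)) {
    warning("alpha-shape boundary is not a single ring; returning convex hull")
    return(orient_ccw(convex_hull_ring(xy)))
  }
  orient_ccw(ring)
}

# Walk boundary segments (x1 y1 x2 y2 rows) into loops; return the loop
# with the largest enclosed area, or NULL if no closed loop exists.
assemble_ring <- function(bnd) {
  if (nrow(bnd) == 0L) return(NULL)
  pts <- unique(rbind(bnd[, 1:2, drop = FALSE], bnd[, 3:4, drop = FALSE]))
  pid <- function(xy) match(paste(xy[, 1], xy[, 2]), paste(pts[, 1], pts[, 2]))
  e <- cbind(pid(bnd[, 1:2, drop = FALSE]), pid(bnd[, 3:4, drop = FALSE]))
  used <- rep(FALSE, nrow(e))
  loops <- list()
  for (start in seq_len(nrow(e))) {
    if (used[start]) next
    path <- e[start, 1]
    cur <- e[start, 2]
    used[start] <- TRUE
    repeat {
      path <- c(path, cur)
      nxt <- which(!used & (e[, 1] == cur | e[, 2] == cur))
      if (length(nxt) == 0L) break
      nxt <- nxt[1L]
      used[nxt] <- TRUE
      cur <- if (e[nxt, 1] == cur) e[nxt, 2] else e[nxt, 1]
      if (cur == path[1L]) {
        loops[[length(loops) + 1L]] <- path
        break
      }
    }
  }
  if (length(loops) == 0L) return(NULL)
  areas <- vapply(loops, function(l) abs(shoelace(pts[l, , drop = FALSE])),
                  numeric(1))
  pts[loops[[which.max(areas)]], , drop = FALSE]
}

orient_ccw <- function(ring) {
  if (shoelace(ring) < 0) ring[rev(seq_len(nrow(ring))), , drop = FALSE] else ring
}

#' Build TLS polygons from TLS-zone cells
#'
#' Groups TLS-zone cells into spatially separate TLS instances (connected
#' components of the within-`group_eps` graph), computes a concave hull
#' per group of at least three cells, and discards hulls below the
#' `min_area` threshold that distinguishes mature TLS from sparse groups
#' of TLS-zone cells.
#'
#' @param tls_cells cell table subset holding TLS-zone cells only.
#' @param group_eps grouping radius in microns (default 50).
#' @param concavity concave-hull length scale in microns (default 50;
#'   `Inf` gives convex hulls).
#' @param min_area minimum polygon area in square microns (default 5000).
#' @return list of polygons, each `list(tls_id, ring, area, centroid)`
#'   with `ring` a closed vertex matrix; empty list (with a warning) when
#'   no group survives filtering.
#' @export
build_tls_polygons <- function(tls_cells, group_eps = 50, concavity = 50,
                               min_area = 5000) {
  tls_cells <- validate_cell_table(tls_cells)
  if (nrow(tls_cells) < 3L) {
    warning("fewer than 3 TLS-zone cells; no polygons built")
    return(list())
  }
  xy <- cbind(tls_cells$x_um, tls_cells$y_um)
  grp <- group_points_eps(xy, group_eps)
  polys <- list()
  for (g in sort(unique(grp))) {
    pts <- unique(xy[grp == g, , drop = FALSE])
    if (nrow(pts) < 3L) next
    ring <- concave_hull(pts, concavity)
    area <- polygon_area(ring)
    if (area < min_area) next
    polys[[length(polys) + 1L]] <- list(
      tls_id = sprintf("TLS_%d", length(polys) + 1L),
      ring = close_ring(ring),
      area = area,
      centroid = polygon_centroid(ring))
  }
  if (length(polys) == 0L) warning("no TLS polygon survived the area filter")
  polys
}

# min distance from each point to the boundary segments of a closed ring
points_ring_distance <- function(xy, ring) {
  ring <- drop_closing_vertex(ring)
  n_edge <- nrow(ring)
  d <- rep(Inf, nrow(xy))
  for (i in seq_len(n_edge)) {
    p1 <- ring[i, ]; p2 <- ring[if (i == n_edge) 1L else i + 1L, ]
    vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
    len2 <- vx^2 + vy^2
    if (len2 == 0) {
      di <- sqrt((xy[, 1] - p1[1])^2 + (xy[, 2] - p1[2])^2)
    } else {
      t <- ((xy[, 1] - p1[1]) * vx + (xy[, 2] - p1[2]) * vy) / len2
      t <- pmin(1, pmax(0, t))
      di <- sqrt((xy[, 1] - (p1[1] + t * vx))^2 + (xy[, 2] - (p1[2] + t * vy))^2)
    }
    d <- pmin(d, di)
  }
  d
}

points_in_ring <- function(xy, ring, edge_dist = NULL) {
  closed <- close_ring(drop_closing_vertex(ring))
  inside <- as.logical(mgcv::in.out(closed, xy))
  if (is.null(edge_dist)) edge_dist <- points_ring_distance(xy, ring)
  inside | edge_dist <= 1e-9  # boundary counts as inside
}

#' Distance of every cell to the closest TLS polygon
#'
#' Cells inside (or on the boundary of) any TLS polygon get distance 0;
#' other cells get the minimum Euclidean distance to any polygon boundary.
#'
#' @param cells cell table.
#' @param polygons list from [build_tls_polygons()].
#' @return tibble with `cell_id`, `d_tls` (microns; `NA` with a warning
#'   when no polygons exist) and `tls_id` of the containing or nearest
#'   polygon.
#' @export
distance_to_tls <- function(cells, polygons) {
  cells <- validate_cell_table(cells)
  xy <- cbind(cells$x_um, cells$y_um)
  if (length(polygons) == 0L) {
    warning("no TLS polygons; d_tls is undefined")
    return(tibble::tibble(cell_id = cells$cell_id, d_tls = NA_real_,
                          tls_id = NA_character_))
  }
  dmat <- matrix(Inf, nrow(cells), length(polygons))
  for (j in seq_along(polygons)) {
    ring <- polygons[[j]]$ring
    ed <- points_ring_distance(xy, ring)
    inside <- points_in_ring(xy, ring, edge_dist = ed)
    dmat[, j] <- ifelse(inside, 0, ed)
  }
  best <- max.col(-dmat, ties.method = "first")
  tibble::tibble(
    cell_id = cells$cell_id,
    d_tls = dmat[cbind(seq_len(nrow(cells)), best)],
    tls_id = vapply(polygons, `[[`, character(1), "tls_id")[best])
}

#' Mean distance to the k nearest cells of a zone
#'
#' The bronchi distance axis: for cells outside the target zone, the mean
#' Euclidean distance to the `k` nearest zone cells; zone members are set
#' to distance 0.
#'
#' @param cells cell table.
#' @param zones tibble with `cell_id`, `zone` (or a character vector
#'   aligned with `cells`).
#' @param zone target zone name (default `"bronchi"`).
#' @param k number of nearest zone cells to average (default 10).
#' @return tibble with `cell_id` and `d_zone` (microns).
#' @export
distance_to_zone_cells <- function(cells, zones, zone = "bronchi", k = 10) {
  cells <- validate_cell_table(cells)
  zvec <- zone_vector(cells, zones)
  member <- zvec == zone
  n_zone <- sum(member, na.rm = TRUE)
  if (n_zone < k) {
    stop_tls("zone '%s' has %d cells; need >= k = %d", zone, n_zone, k)
  }
  d <- numeric(nrow(cells))
  ref <- cbind(cells$x_um[member], cells$y_um[member])
  qry <- !member
  if (any(qry)) {
    nn <- knn_query(cbind(cells$x_um[qry], cells$y_um[qry]), ref, k = k)
    d[qry] <- rowMeans(nn$dist)
  }
  tibble::tibble(cell_id = cells$cell_id, d_zone = d)
}

zone_vector <- function(cells, zones) {
  if (is.character(zones) && length(zones) == nrow(cells)) return(zones)
  zones <- tibble::as_tibble(zones)
  zvec <- zones$zone[match(cells$cell_id, zones$cell_id)]
  if (anyNA(zvec)) stop_tls("zones do not cover every cell")
  zvec
}

#' Radial partition of TLS into core, outer and surrounding
#'
#' For each TLS polygon, cells inside get the radial distance to the
#' polygon centroid scaled from minimum to maximum within that TLS; cells
#' in the lowest half of the scaled radial distance form the TLS core and
#' the rest the TLS outer region. Cells outside every polygon but within
#' `ring_width` microns of a polygon edge form the surrounding ring.
#'
#' @param cells cell table.
#' @param polygons list from [build_tls_polygons()].
#' @param ring_width surrounding-ring width in microns (default 50).
#' @param split scaled-radial-distance threshold separating core from
#'   outer (default 0.5; core is `r_scaled <= split`).
#' @param split_method `"value"` thresholds the scaled distance itself
#'   (default); `"median"` uses the per-TLS median of the scaled distance.
#' @return tibble with `cell_id`, `tls_id`, `r_scaled` (inside cells),
#'   `ring_dist` (surrounding cells), `category` in
#'   core/outer/surrounding/none.
#' @export
radial_partition <- function(cells, polygons, ring_width = 50, split = 0.5,
                             split_method = c("value", "median")) {
  split_method <- match.arg(split_method)
  cells <- validate_cell_table(cells)
  n <- nrow(cells)
  xy <- cbind(cells$x_um, cells$y_um)
  out <- tibble::tibble(cell_id = cells$cell_id, tls_id = NA_character_,
                        r_scaled = NA_real_, ring_dist = NA_real_,
                        category = "none")
  if (length(polygons) == 0L) return(out)
  edge <- matrix(Inf, n, length(polygons))
  inside <- matrix(FALSE, n, length(polygons))
  for (j in seq_along(polygons)) {
    ed <- points_ring_distance(xy, polygons[[j]]$ring)
    edge[, j] <- ed
    inside[, j] <- points_in_ring(xy, polygons[[j]]$ring, edge_dist = ed)
  }
  inside_any <- rowSums(inside) > 0
  # inside cells: first containing polygon wins (polygons are disjoint in
  # practice; overlap would be a grouping defect)
  for (j in seq_along(polygons)) {
    idx <- which(inside[, j] & is.na(out$tls_id))
    if (length(idx) == 0L) next
    cen <- polygons[[j]]$centroid
    r <- sqrt((xy[idx, 1] - cen[1])^2 + (xy[idx, 2] - cen[2])^2)
    rng <- range(r)
    rs <- if (rng[2] > rng[1]) (r - rng[1]) / (rng[2] - rng[1]) else rep(0, length(r))
    thr <- if (split_method == "value") split else stats::median(rs)
    out$tls_id[idx] <- polygons[[j]]$tls_id
    out$r_scaled[idx] <- rs
    out$category[idx] <- ifelse(rs <= thr, "core", "outer")
    if (length(idx) == 1L) {
      message(sprintf("%s has a single inside cell; r_scaled = 0, core",
                      polygons[[j]]$tls_id))
    }
  }
  # surrounding ring: outside all polygons, edge distance in (0, ring_width]
  min_edge <- apply(edge, 1L, min)
  nearest <- max.col(-edge, ties.method = "first")
  ring_cells <- !inside_any & min_edge > 0 & min_edge <= ring_width
  out$tls_id[ring_cells] <-
    vapply(polygons, `[[`, character(1), "tls_id")[nearest[ring_cells]]
  out$ring_dist[ring_cells] <- min_edge[ring_cells]
  out$category[ring_cells] <- "surrounding"
  out
}
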