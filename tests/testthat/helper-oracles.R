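# Independent brute-force oracles used to cross-check the package's
# geometry and scoring implementations. These deliberately share no code
# with the package internals: ray casting instead of mgcv::in.out,
# full pairwise sorts instead of kd-trees, explicit sort-and-drop trimmed
# means instead of mean(trim =).

# even-odd ray casting, boundary-insensitive (callers pair it with an
# edge-distance tolerance)
oracle_point_in_poly <- function(px, py, ring) {
  ring <- as.matrix(ring)
  if (all(ring[1, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

oracle_seg_dist <- function(px, py, x1, y1, x2, y2) {
  vx <- x2 - x1; vy <- y2 - y1
  len2 <- vx^2 + vy^2
  if (len2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- max(0, min(1, ((px - x1) * vx + (py - y1) * vy) / len2))
  sqrt((px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2)
}

oracle_ring_dist <- function(px, py, ring) {
  ring <- as.matrix(ring)
  if (all(ring[1, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
  n <- nrow(ring)
  d <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    d <- min(d, oracle_seg_dist(px, py, ring[i, 1], ring[i, 2],
                                ring[j, 1], ring[j, 2]))
  }
  d
}

# distance to closest polygon: 0 inside/on boundary, else min edge distance
oracle_dist_to_polys <- function(cells, polygons) {
  vapply(seq_len(nrow(cells)), function(i) {
    px <- cells$x_um[i]; py <- cells$y_um[i]
    dmin <- Inf
    for (p in polygons) {
      ed <- oracle_ring_dist(px, py, p$ring)
      if (ed <= 1e-9 || oracle_point_in_poly(px, py, p$ring)) return(0)
      dmin <- min(dmin, ed)
    }
    dmin
  }, numeric(1))
}

# mean distance to the k nearest zone cells via full pairwise sort
oracle_knn_zone_dist <- function(cells, zone_flag, k) {
  zx <- cells$x_um[zone_flag]; zy <- cells$y_um[zone_flag]
  vapply(seq_len(nrow(cells)), function(i) {
    if (zone_flag[i]) return(0)
    d <- sort(sqrt((zx - cells$x_um[i])^2 + (zy - cells$y_um[i])^2))
    mean(d[seq_len(k)])
  }, numeric(1))
}

oracle_capsule_ids <- function(cells, k, thr, meso_type = "mesothelial") {
  meso <- cells[cells$cell_type == meso_type, ]
  hits <- vapply(seq_len(nrow(cells)), function(i) {
    d <- sort(sqrt((meso$x_um - cells$x_um[i])^2 +
                     (meso$y_um - cells$y_um[i])^2))
    mean(d[seq_len(k)]) <= thr
  }, logical(1))
  cells$cell_id[hits]
}

# all radius-graph edges by pairwise threshold
oracle_radius_edges <- function(cells, radius) {
  n <- nrow(cells)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt((cells$x_um[i] - cells$x_um[j])^2 +
                  (cells$y_um[i] - cells$y_um[j])^2)
      if (d <= radius) out <- rbind(out, c(i, j))
    }
  }
  out
}

# per-zone type x type edge tally from an explicit edge list
oracle_interaction <- function(edges, types, zones, zone, lev) {
  m <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  if (is.null(edges)) return(m)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    if (zones[i] != zone || zones[j] != zone) next
    m[types[i], types[j]] <- m[types[i], types[j]] + 1
    if (types[i] != types[j]) m[types[j], types[i]] <- m[types[j], types[i]] + 1
  }
  m
}

oracle_trimmed_mean <- function(x, trim) {
  x <- sort(x)
  k <- floor(length(x) * trim)
  if (2 * k >= length(x)) return(stats::median(x))
  mean(x[(k + 1):(length(x) - k)])
}

oracle_lr_score <- function(expression, cells, ligand, receptor, sender_type,
                            receiver_ids, range, trim) {
  recv <- cells[cells$cell_id %in% receiver_ids, ]
  senders <- cells[cells$cell_type == sender_type, ]
  if (nrow(senders) == 0 || nrow(recv) == 0) return(0)
  in_range <- vapply(seq_len(nrow(senders)), function(i) {
    any(sqrt((recv$x_um - senders$x_um[i])^2 +
               (recv$y_um - senders$y_um[i])^2) <= range)
  }, logical(1))
  if (!any(in_range)) return(0)
  lig <- as.numeric(expression[senders$cell_id[in_range], ligand])
  rec <- as.numeric(expression[recv$cell_id, receptor])
  oracle_trimmed_mean(lig, trim) * oracle_trimmed_mean(rec, trim)
}

# random scattered-cell instance for the oracle suites
random_instance <- function(n, seed, field = 500, types = c("A", "B", "C")) {
  withr::with_seed(seed, {
    tibble::tibble(
      cell_id = sprintf("c%03d", seq_len(n)),
      x_um = runif(n, 0, field),
      y_um = runif(n, 0, field),
      cell_type = sample(types, n, replace = TRUE))
  })
}

random_polygons <- function(n_poly, seed, field = 500) {
  withr::with_seed(seed, {
    lapply(seq_len(n_poly), function(i) {
      cx <- runif(1, 100, field - 100); cy <- runif(1, 100, field - 100)
      nv <- sample(4:8, 1)
      th <- sort(runif(nv, 0, 2 * pi))
      r <- runif(nv, 30, 80)
      ring <- cbind(cx + r * cos(th), cy + r * sin(th))
      list(tls_id = sprintf("TLS_%d", i), ring = rbind(ring, ring[1, ]),
           area = tlsniche::polygon_area(ring),
           centroid = tlsniche::polygon_centroid(ring))
    })
  })
}
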