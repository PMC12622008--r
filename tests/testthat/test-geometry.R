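square_cells <- function() {
  tibble::tibble(cell_id = sprintf("s%d", 1:4),
                 x_um = c(0, 100, 100, 0), y_um = c(0, 0, 100, 100),
                 cell_type = "B")
}

test_that("convex hull of a square has the exact area", {
  polys <- build_tls_polygons(square_cells(), group_eps = 150,
                              concavity = Inf, min_area = 1000)
  expect_length(polys, 1)
  expect_equal(polys[[1]]$area, 10000)
  expect_equal(unname(polys[[1]]$centroid), c(50, 50))
})

test_that("the minimum-area filter discards small hulls", {
  expect_warning(
    polys <- build_tls_polygons(square_cells(), group_eps = 150,
                                concavity = Inf, min_area = 20000),
    "area filter")
  expect_length(polys, 0)
})

test_that("two separated discs yield two polygons containing their cells", {
  set.seed(71)
  disc <- function(cx, n) {
    r <- 80 * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
    cbind(cx + r * cos(th), 500 + r * sin(th))
  }
  xy <- rbind(disc(200, 100), disc(1200, 100))
  cells <- tibble::tibble(cell_id = sprintf("c%d", 1:200),
                          x_um = xy[, 1], y_um = xy[, 2], cell_type = "B")
  polys <- build_tls_polygons(cells, group_eps = 60, concavity = 60,
                              min_area = 1000)
  expect_length(polys, 2)
  for (g in 1:2) {
    idx <- ((g - 1) * 100 + 1):(g * 100)
    p <- polys[[g]]
    contained <- vapply(idx, function(i) {
      oracle_point_in_poly(cells$x_um[i], cells$y_um[i], p$ring) ||
        oracle_ring_dist(cells$x_um[i], cells$y_um[i], p$ring) <= 1e-6
    }, logical(1))
    expect_gte(mean(contained), 0.95)
  }
})

test_that("concave hulls are tighter than convex hulls on concave shapes", {
  set.seed(72)
  th <- runif(400, 0.25 * pi, 1.75 * pi)  # a C-shaped arc band
  r <- runif(400, 80, 120)
  xy <- cbind(300 + r * cos(th), 300 + r * sin(th))
  concave <- concave_hull(xy, concavity = 40)
  convex <- concave_hull(xy, concavity = Inf)
  expect_lt(polygon_area(concave), 0.8 * polygon_area(convex))
})

test_that("distance to TLS is zero inside and axis-exact outside", {
  sq <- list(list(tls_id = "TLS_1",
                  ring = rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100),
                               c(0, 0)),
                  area = 10000, centroid = c(50, 50)))
  cells <- tibble::tibble(cell_id = c("in", "out", "edge"),
                          x_um = c(50, 150, 100), y_um = c(50, 50, 50),
                          cell_type = "B")
  d <- distance_to_tls(cells, sq)
  expect_equal(d$d_tls, c(0, 50, 0))
  expect_warning(d0 <- distance_to_tls(cells, list()), "undefined")
  expect_true(all(is.na(d0$d_tls)))
})

test_that("distance to TLS matches the brute-force segment oracle", {
  for (seed in c(81, 82)) {
    cells <- random_instance(100, seed = seed)
    polys <- random_polygons(3, seed = seed + 100)
    d <- distance_to_tls(cells, polys)
    expect_equal(d$d_tls, oracle_dist_to_polys(cells, polys),
                 tolerance = 1e-9)
  }
})

test_that("distance to zone cells averages the k nearest members", {
  # bronchi cells at exact distances 10, 20, ..., 100: mean 55
  cells <- tibble::tibble(
    cell_id = c("q", sprintf("b%d", 1:10)),
    x_um = c(0, seq(10, 100, by = 10)), y_um = 0,
    cell_type = "x")
  zones <- c("parenchyma", rep("bronchi", 10))
  d <- distance_to_zone_cells(cells, zones, zone = "bronchi", k = 10)
  expect_equal(d$d_zone[1], 55)
  expect_equal(d$d_zone[2], 0)  # zone member
  expect_error(distance_to_zone_cells(cells, zones, zone = "bronchi", k = 11),
               "need >= k")
})

test_that("zone distances match the sort-and-average oracle", {
  for (seed in c(91, 92)) {
    cells <- random_instance(300, seed = seed)
    flag <- cells$cell_type == "A"
    d <- distance_to_zone_cells(cells, ifelse(flag, "bronchi", "other"),
                                zone = "bronchi", k = 10)
    expect_equal(d$d_zone, oracle_knn_zone_dist(cells, flag, 10),
                 tolerance = 1e-9)
  }
})

test_that("radial scaling is exact at the centroid and the farthest cell", {
  sq <- list(list(tls_id = "TLS_1",
                  ring = rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100),
                               c(0, 0)),
                  area = 1e4, centroid = c(50, 50)))
  cells <- tibble::tibble(cell_id = c("centre", "mid", "corner", "out60"),
                          x_um = c(50, 75, 0, 160),
                          y_um = c(50, 50, 0, 50), cell_type = "B")
  rad <- radial_partition(cells, sq, ring_width = 50)
  expect_equal(rad$r_scaled[rad$cell_id == "centre"], 0)
  expect_equal(rad$category[rad$cell_id == "centre"], "core")
  expect_equal(rad$r_scaled[rad$cell_id == "corner"], 1)
  expect_equal(rad$category[rad$cell_id == "corner"], "outer")
  expect_equal(rad$category[rad$cell_id == "out60"], "none")
})

test_that("radial partition scales and categorizes as specified", {
  set.seed(73)
  th <- runif(200, 0, 2 * pi); r <- 100 * sqrt(runif(200))
  cells <- tibble::tibble(
    cell_id = c(sprintf("c%d", 1:200), "near", "far"),
    x_um = c(500 + r * cos(th), 530 + 100, 500 + 100 + 200),
    y_um = c(500 + r * sin(th), 500, 500),
    cell_type = "B")
  polys <- build_tls_polygons(cells[1:200, ], group_eps = 80,
                              concavity = Inf, min_area = 1000)
  rad <- radial_partition(cells, polys, ring_width = 50)
  inside <- rad[!is.na(rad$r_scaled), ]
  extreme <- inside[which.max(inside$r_scaled), ]
  expect_equal(extreme$r_scaled, 1)
  expect_equal(extreme$category, "outer")
  expect_equal(rad$category[rad$cell_id == "far"], "none")  # > 50 um outside
  # core/outer partition the inside cells, surrounding is disjoint
  expect_true(all(inside$category %in% c("core", "outer")))
  surr <- rad[rad$category == "surrounding", ]
  expect_true(all(surr$ring_dist > 0 & surr$ring_dist <= 50))
  expect_true(all(is.na(surr$r_scaled)))
})

test_that("distance axes are 1-Lipschitz under perturbation", {
  tis <- small_tissue()
  cells <- tis$cells
  polys <- build_tls_polygons(cells[cells$true_zone == "TLS", ])
  d0 <- distance_to_tls(cells, polys)$d_tls
  b0 <- distance_to_zone_cells(cells, cells$true_zone, "bronchi", 10)$d_zone
  # perturb query cells only; polygons and zone reference cells are the
  # fixed geometry the axes are measured against
  delta <- 5
  pert <- cells
  set.seed(55)
  ang <- runif(nrow(cells), 0, 2 * pi)
  nonmember <- cells$true_zone != "bronchi"
  pert$x_um[nonmember] <- cells$x_um[nonmember] + delta * cos(ang)[nonmember]
  pert$y_um[nonmember] <- cells$y_um[nonmember] + delta * sin(ang)[nonmember]
  d1 <- distance_to_tls(pert, polys)$d_tls
  expect_true(all(abs(d1 - d0)[nonmember] <= delta + 1e-9))
  b1 <- distance_to_zone_cells(pert, cells$true_zone, "bronchi", 10)$d_zone
  expect_true(all(abs(b1 - b0)[nonmember] <= delta + 1e-9))
})

test_that("enlarging min_area never increases the polygon count", {
  tis <- small_tissue()
  tls <- tis$cells[tis$cells$true_zone == "TLS", ]
  counts <- vapply(c(0, 2000, 20000, 50000, 2e5), function(a) {
    suppressWarnings(length(build_tls_polygons(tls, min_area = a)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
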