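toy_expr <- function(n = 20, genes = c("g1", "g2")) {
  m <- matrix(rpois(n * length(genes), 5), n, length(genes),
              dimnames = list(sprintf("c%02d", seq_len(n)), genes))
  m
}

test_that("convolution is exact on constants and the identity at window 1", {
  set.seed(41)
  m <- toy_expr()
  m[, "g1"] <- 7
  ax <- setNames(runif(20, 0, 400), rownames(m))
  prof <- convolve_along_axis(m, ax, window = 5, max_dist = 450)
  expect_true(all(prof$profile[, "g1"] == 7))
  raw <- convolve_along_axis(m, ax, window = 1)
  ord <- names(sort(ax))
  expect_equal(raw$profile[, "g2"], m[ord, "g2"])
})

test_that("convolution respects the distance cutoff and ties by cell id", {
  m <- toy_expr(4)
  ax <- setNames(c(100, 500, 100, 460), rownames(m))
  prof <- convolve_along_axis(m, ax, window = 1, max_dist = 450)
  expect_equal(prof$cell_id, c("c01", "c03"))  # ties at 100 sort by id
  expect_error(convolve_along_axis(m, ax + 1000, window = 1), "max_dist")
})

test_that("convolution commutes with adding a constant", {
  set.seed(42)
  m <- toy_expr(50)
  ax <- setNames(runif(50, 0, 400), rownames(m))
  p0 <- convolve_along_axis(m, ax, window = 7)
  p1 <- convolve_along_axis(m + 3, ax, window = 7)
  expect_equal(p1$profile, p0$profile + 3)
})

test_that("convolved gradient profiles are monotone on synthetic tissue", {
  tis <- gradient_tissue()
  cd4 <- tis$cells$cell_id[tis$cells$cell_type %in%
                             c("CD4_Th0", "CD4_Th2", "CD4_other")]
  norm <- normalize_expression(tis$counts)
  d_tls <- setNames(tis$truth$cell_truth$d_tls_true,
                    tis$truth$cell_truth$cell_id)
  prof <- convolve_along_axis(norm[cd4, ], d_tls[cd4], genes = "Tcf7",
                              window = 50, max_dist = 450)
  rho <- cor(seq_along(prof$cell_id), prof$profile[, "Tcf7"],
             method = "spearman")
  expect_lte(rho, -0.9)
})

test_that("weighted KDE obeys its normalization and degeneracy contracts", {
  set.seed(43)
  x <- runif(200, 0, 400); y <- runif(200, 0, 400)
  w <- rexp(200)
  k <- weighted_kde_2d(x, y, w, bandwidth = 30, grid_n = 48)
  dx <- k$x[2] - k$x[1]; dy <- k$y[2] - k$y[1]
  expect_equal(sum(k$z) * dx * dy, 1, tolerance = 1e-6)
  # invariant to rescaling all weights
  k2 <- weighted_kde_2d(x, y, w * 37, bandwidth = 30, grid_n = 48)
  expect_equal(k$z, k2$z)
  # uniform weights equal the unweighted estimate
  ku <- weighted_kde_2d(x, y, rep(1, 200), bandwidth = 30, grid_n = 48)
  ke <- weighted_kde_2d(x, y, rep(2, 200), bandwidth = 30, grid_n = 48)
  expect_equal(ku$z, ke$z)
  # all weight on one cell: mode at that cell
  w1 <- c(1, rep(0, 199))
  k1 <- weighted_kde_2d(x, y, w1, bandwidth = 30, grid_n = 48)
  mode_idx <- which(k1$z == max(k1$z), arr.ind = TRUE)
  expect_lt(abs(k1$x[mode_idx[1]] - x[1]), dx)
  expect_lt(abs(k1$y[mode_idx[2]] - y[1]), dy)
  expect_error(weighted_kde_2d(x, y, rep(0, 200)), "zero")
})

test_that("T/B/P assignment follows the priority and cutoff rules", {
  expect_equal(assign_tbp(0, 400), "T")
  expect_equal(assign_tbp(400, 10), "B")
  expect_equal(assign_tbp(300, 300), "P")
  expect_equal(assign_tbp(500, 300), "none")
  expect_equal(assign_tbp(40, 10), "T")  # T beats B
  # monotone in t_max: raising the threshold never removes T labels
  set.seed(44)
  dt <- runif(200, 0, 500); db <- runif(200, 0, 500)
  t1 <- assign_tbp(dt, db, t_max = 50) == "T"
  t2 <- assign_tbp(dt, db, t_max = 100) == "T"
  expect_true(all(t2[t1]))
})

test_that("region means equal raw rows with one cell per region", {
  m <- toy_expr(3)
  lab <- setNames(c("T", "B", "P"), rownames(m))
  rm <- region_mean_expression(m, lab)
  expect_equal(rm[c("T", "B", "P"), ], m, ignore_attr = TRUE)
})

test_that("region means are label-permutation stable under the null", {
  set.seed(45)
  m <- matrix(rpois(2000, 5), 1000, 2,
              dimnames = list(sprintf("c%04d", 1:1000), c("g1", "g2")))
  lab <- sample(c("T", "P"), 1000, TRUE)
  rm1 <- region_mean_expression(m, setNames(lab, rownames(m)))
  rm2 <- region_mean_expression(m, setNames(sample(lab), rownames(m)))
  se <- sqrt(5 / 500)
  expect_true(all(abs(rm1 - rm2) < 4 * se))
})

test_that("progenitor expression is enriched in T over P regions", {
  tis <- gradient_tissue()
  cd4 <- tis$cells$cell_id[tis$cells$cell_type %in%
                             c("CD4_Th0", "CD4_Th2", "CD4_other")]
  truth <- tis$truth$cell_truth
  tbp <- setNames(assign_tbp(truth$d_tls_true, truth$d_bronchi_true),
                  truth$cell_id)
  norm <- normalize_expression(tis$counts)
  rm <- region_mean_expression(norm[cd4, ], tbp[cd4])
  expect_gte(rm["T", "Tcf7"] / rm["P", "Tcf7"], 2)
})

test_that("marker testing filters on the 5% expression fraction", {
  set.seed(46)
  n <- 200
  counts <- matrix(rpois(n * 2, 5), n, 2,
                   dimnames = list(sprintf("c%03d", 1:n), c("common", "rare")))
  counts[, "rare"] <- 0
  counts[1:4, "rare"] <- 5  # 4% in the first group, 0% elsewhere
  zones <- rep(c("z1", "z2"), each = n / 2)
  res <- zone_marker_test(counts, zones)
  expect_false("rare" %in% res$gene)
  expect_true("common" %in% res$gene)
})

test_that("a strong planted marker passes and BH is monotone", {
  set.seed(47)
  n <- 400
  counts <- matrix(rpois(n * 20, 4), n, 20,
                   dimnames = list(sprintf("c%03d", 1:n),
                                   sprintf("g%02d", 1:20)))
  zones <- rep(c("hi", "rest"), each = n / 2)
  counts[zones == "hi", "g01"] <- rpois(n / 2, 32)  # 8-fold shift
  res <- zone_marker_test(counts, zones)
  expect_true(res$pass[res$gene == "g01" & res$zone == "hi"])
  ord <- order(res$p)
  expect_true(all(diff(rank(res$p_adj[ord], ties.method = "max")) >= 0))
})

test_that("imaging categorization reproduces the stated distance rules", {
  expect_equal(categorize_imaging(30, 300, 300), "TLS")
  expect_equal(categorize_imaging(60, 40, 300), "bronchi")
  expect_equal(categorize_imaging(60, 300, 80), "vessel")
  expect_equal(categorize_imaging(200, 200, 200), "alveolar")
  # vessel clause has priority in the 50-100 um overlap
  expect_equal(categorize_imaging(200, 200, 80), "vessel")
  # boundary cell not captured by any clause
  expect_equal(categorize_imaging(50, 50, 100), "other")
})
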