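test_that("tissue generation is deterministic given the seed", {
  cfg <- sim_config(field_width = 1200, field_height = 1200, n_tls = 1,
                    n_bronchi = 1, n_vessels = 0, seed = 5L)
  t1 <- generate_tissue(cfg)
  t2 <- generate_tissue(cfg)
  expect_identical(t1$cells, t2$cells)
  expect_identical(t1$counts, t2$counts)
  expect_identical(t1$truth$structures, t2$truth$structures)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(gradient_scale = 0), "lengths")
  bad_mx <- default_mixtures()
  bad_mx$tls["B"] <- bad_mx$tls["B"] + 0.1
  expect_error(sim_config(mixtures = bad_mx), "sums to")
  expect_error(sim_config(n_tls = -1), "n_tls")
})

test_that("unplaceable geometry fails naming the structure", {
  expect_error(
    generate_tissue(sim_config(field_width = 900, field_height = 900,
                               n_tls = 8, tls_radius_mean = 300,
                               tls_radius_sd = 1, max_place_attempts = 25,
                               seed = 3L)),
    "could not place structure")
})

test_that("cells respect the generating geometry", {
  tis <- small_tissue()
  cfg_w <- 2000
  expect_true(all(tis$cells$x_um >= 0 & tis$cells$x_um <= cfg_w))
  expect_true(all(tis$cells$y_um >= 0 & tis$cells$y_um <= cfg_w))
  expect_true(all(tis$truth$cell_truth$d_tls_true >= 0))
  expect_true(all(tis$truth$cell_truth$d_bronchi_true >= 0))
  # TLS-member cells lie inside their generating disc
  tls_cells <- tis$cells[tis$cells$true_zone == "TLS", ]
  tls_structs <- tis$truth$structures[tis$truth$structures$kind == "tls", ]
  in_disc <- vapply(seq_len(nrow(tls_cells)), function(i) {
    any(sqrt((tls_structs$cx - tls_cells$x_um[i])^2 +
               (tls_structs$cy - tls_cells$y_um[i])^2) <=
          tls_structs$radius_outer + 1e-9)
  }, logical(1))
  expect_true(all(in_disc))
})

test_that("per-structure cell counts follow Poisson placement", {
  tis <- small_tissue()
  tls_structs <- tis$truth$structures[tis$truth$structures$kind == "tls", ]
  tls_cells <- tis$cells[tis$cells$true_zone == "TLS", ]
  for (j in seq_len(nrow(tls_structs))) {
    d <- sqrt((tls_cells$x_um - tls_structs$cx[j])^2 +
                (tls_cells$y_um - tls_structs$cy[j])^2)
    n_obs <- sum(d <= tls_structs$radius_outer[j] + 1e-9)
    lambda <- 50 * pi * tls_structs$radius_outer[j]^2 / 1e4
    expect_lt(abs(n_obs - lambda), 3 * sqrt(lambda) + 1)
  }
})

test_that("zero gradient amplitude decouples progenitor counts from d_tls", {
  mx <- default_mixtures()
  mx$parenchyma <- c(B = 0, CD4_Th0 = 0.5, CD4_Th2 = 0.3, CD4_other = 0.2,
                     epithelial_bronchus = 0, mesothelial = 0,
                     macrophage = 0, cDC2 = 0, endothelial = 0, other = 0)
  cfg <- sim_config(field_width = 2500, field_height = 2500,
                    n_tls = 2, n_bronchi = 1, n_vessels = 0,
                    densities = c(tls = 40, bronchi = 40, vessel = 30,
                                  capsule = 15, parenchyma = 5),
                    mixtures = mx, gradient_amplitude = 0, seed = 11L)
  tis <- generate_tissue(cfg)
  cd4 <- tis$cells$cell_type %in% c("CD4_Th0", "CD4_Th2", "CD4_other")
  expect_gte(sum(cd4), 2000)
  rho <- cor(tis$truth$cell_truth$d_tls_true[cd4],
             as.numeric(tis$counts[cd4, "Tcf7"]), method = "spearman")
  expect_lt(abs(rho), 0.1)
})

test_that("independent curve fit recovers the gradient length scale", {
  skip_if_not_installed("minpack.lm")
  tis <- gradient_tissue()
  cd4 <- tis$cells$cell_type %in% c("CD4_Th0", "CD4_Th2", "CD4_other")
  expect_gte(sum(cd4), 5000)
  df <- data.frame(d = tis$truth$cell_truth$d_tls_true[cd4],
                   y = as.numeric(tis$counts[cd4, "Tcf7"]))
  fit <- minpack.lm::nlsLM(y ~ a * exp(-d / l) + b, data = df,
                           start = list(a = 10, l = 50, b = 0.5))
  l_hat <- coef(fit)[["l"]]
  expect_gt(l_hat, 80)
  expect_lt(l_hat, 120)
})

test_that("increasing gradient amplitude strengthens the spatial correlation", {
  rhos <- vapply(c(0, 5, 20), function(a) {
    cfg <- sim_config(field_width = 1800, field_height = 1800,
                      n_tls = 2, n_bronchi = 1, n_vessels = 0,
                      gradient_amplitude = a, seed = 21L)
    tis <- generate_tissue(cfg)
    cd4 <- tis$cells$cell_type %in% c("CD4_Th0", "CD4_Th2", "CD4_other")
    abs(cor(tis$truth$cell_truth$d_tls_true[cd4],
            as.numeric(tis$counts[cd4, "Tcf7"]), method = "spearman"))
  }, numeric(1))
  expect_true(all(diff(rhos) > 0))
})

test_that("hashtag droplets match their stated composition", {
  # no background, no doublets: second-highest hashtag is always 0
  h <- generate_hashtag_counts(n_hashtags = 4, n_singlets = 30,
                               signal_mean = 50, background_mean = 0,
                               seed = 2L)
  second <- apply(h$counts, 1L, function(r) sort(r, decreasing = TRUE)[2])
  expect_true(all(second == 0))
  # determinism
  h2 <- generate_hashtag_counts(n_hashtags = 4, n_singlets = 30,
                                signal_mean = 50, background_mean = 0,
                                seed = 2L)
  expect_identical(h$counts, h2$counts)
  # doublets carry two high hashtags
  hd <- generate_hashtag_counts(n_hashtags = 4, n_singlets = 5,
                                n_doublets = 10, signal_mean = 100,
                                background_mean = 1, seed = 3L)
  dbl <- hd$counts[hd$truth$label == "doublet", , drop = FALSE]
  second_dbl <- apply(dbl, 1L, function(r) sort(r, decreasing = TRUE)[2])
  expect_true(all(second_dbl >= 50))
  expect_error(generate_hashtag_counts(0, 10), "hashtag")
  expect_error(generate_hashtag_counts(4, 10, signal_mean = 1,
                                       background_mean = 2), "exceed")
})

test_that("generated singlets satisfy the assignment rule almost surely", {
  h <- generate_hashtag_counts(n_hashtags = 10, n_singlets = 200,
                               signal_mean = 100, background_mean = 1,
                               seed = 9L)
  # brute-force rule application, independent of demux_hashtags()
  ok <- vapply(seq_len(nrow(h$counts)), function(i) {
    r <- sort(h$counts[i, ], decreasing = TRUE)
    top_name <- names(h$counts[i, ])[which.max(h$counts[i, ])]
    r[1] >= 10 && r[1] > 2 * r[2] && top_name == h$truth$hashtag[i]
  }, logical(1))
  expect_gte(mean(ok), 0.99)
})
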