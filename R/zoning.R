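# Zone assignment: neighbor-composition features, a clustering stand-in
# for spatial-neighborhood identification, and the capsule-separation rule.

#' Neighbor cell-type composition features
#'
#' For every cell, the fraction of each cell type among the cell itself and
#' its `k_neighbors` nearest neighbors (Euclidean, microns). Rows sum to 1.
#'
#' @param cells cell table (see [validate_cell_table()]).
#' @param k_neighbors neighborhood size excluding self (default 10).
#' @return numeric matrix, cells x cell types, rownames = cell ids.
#' @export
neighbor_composition_features <- function(cells, k_neighbors = 10) {
  cells <- validate_cell_table(cells)
  n <- nrow(cells)
  if (n < k_neighbors + 1L) {
    stop_tls("need at least k_neighbors + 1 = %d cells, got %d",
             k_neighbors + 1L, n)
  }
  xy <- cbind(cells$x_um, cells$y_um)
  nn <- knn_query(xy, xy, k = k_neighbors + 1L)  # includes self at dist 0
  types <- type_factor(cells$cell_type)
  lev <- levels(types)
  feat <- matrix(0, n, length(lev), dimnames = list(cells$cell_id, lev))
  codes <- as.integer(types)
  for (j in seq_len(ncol(nn$idx))) {
    tc <- codes[nn$idx[, j]]
    feat[cbind(seq_len(n), tc)] <- feat[cbind(seq_len(n), tc)] + 1
  }
  feat / (k_neighbors + 1L)
}

#' Cluster cells into zones from composition features
#'
#' A transparent stand-in for spatial-neighborhood identification: k-means
#' on the neighbor-composition features. When ground-truth zones are
#' supplied, clusters are renamed by their majority true zone (ties and
#' collisions keep a numeric suffix).
#'
#' @param features matrix from [neighbor_composition_features()].
#' @param n_zones number of zones to request.
#' @param seed integer seed for k-means initialisation.
#' @param true_zones optional named character vector (cell id -> zone) used
#'   only to rename clusters.
#' @return tibble with `cell_id`, `zone`, `source = "standin_cluster"`.
#' @export
cluster_zones <- function(features, n_zones, seed = 1L, true_zones = NULL) {
  if (n_zones > nrow(features)) {
    stop_tls("n_zones (%d) exceeds the number of cells (%d)",
             n_zones, nrow(features))
  }
  if (n_zones == 1L) {
    cl <- rep(1L, nrow(features))
  } else {
    km <- with_seed(seed, stats::kmeans(features, centers = n_zones,
                                        nstart = 10, iter.max = 100))
    cl <- km$cluster
  }
  zone <- sprintf("zone_%d", cl)
  if (!is.null(true_zones)) {
    tz <- true_zones[rownames(features)]
    for (k in sort(unique(cl))) {
      tab <- sort(table(tz[cl == k]), decreasing = TRUE)
      if (length(tab) > 0) zone[cl == k] <- names(tab)[1L]
    }
  }
  tibble::tibble(cell_id = rownames(features), zone = zone,
                 source = "standin_cluster")
}

#' Relabel capsule cells by proximity to mesothelial cells
#'
#' Any cell whose mean distance to its `k_meso` nearest mesothelial cells
#' is at most `max_avg_dist` microns is assigned to the capsule zone;
#' all other assignments are left unchanged. Mesothelial cells measure
#' distance to the mesothelial population including themselves.
#'
#' @param cells cell table with `cell_type`.
#' @param zones tibble with `cell_id`, `zone` covering all cells.
#' @param k_meso number of nearest mesothelial cells (default 5).
#' @param max_avg_dist mean-distance threshold in microns (default 100,
#'   inclusive).
#' @param meso_type cell-type label identifying mesothelial cells.
#' @return the `zones` tibble with capsule cells relabelled
#'   (`source = "rule"` for relabelled rows).
#' @export
split_capsule <- function(cells, zones, k_meso = 5, max_avg_dist = 100,
                          meso_type = "mesothelial") {
  cells <- validate_cell_table(cells)
  meso <- cells[cells$cell_type == meso_type, , drop = FALSE]
  if (nrow(meso) < k_meso) {
    stop_tls("capsule rule needs >= %d mesothelial cells, found %d",
             k_meso, nrow(meso))
  }
  zones <- tibble::as_tibble(zones)
  if (!all(cells$cell_id %in% zones$cell_id)) {
    stop_tls("zones must cover every cell in the cell table")
  }
  nn <- knn_query(cbind(cells$x_um, cells$y_um),
                  cbind(meso$x_um, meso$y_um), k = k_meso)
  avg <- rowMeans(nn$dist)
  capsule_ids <- cells$cell_id[avg <= max_avg_dist]
  hit <- zones$cell_id %in% capsule_ids
  zones$zone[hit] <- "capsule"
  if (!"source" %in% names(zones)) zones$source <- "external"
  zones$source[hit] <- "rule"
  zones
}
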