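# Readers and writers for the standard formats, the resolved pipeline
# configuration, and the end-to-end pipeline driver.

#' Read a per-cell spatial table
#'
#' CSV/TSV (by extension) or Parquet (when the arrow package is
#' available). Required columns: `cell_id`, `x_um`, `y_um`, `cell_type`;
#' `zone` and `sample` are optional.
#'
#' @param path file path.
#' @return validated tibble.
#' @export
read_cell_table <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
    csv = utils::read.csv(path, stringsAsFactors = FALSE),
    tsv = utils::read.delim(path, stringsAsFactors = FALSE),
    txt = utils::read.delim(path, stringsAsFactors = FALSE),
    parquet = {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        stop_tls("reading parquet requires the arrow package")
      }
      as.data.frame(arrow::read_parquet(path))
    },
    stop_tls("unsupported cell-table format: .%s", ext))
  validate_cell_table(df)
}

#' Write a cell table to CSV
#' @param cells cell table.
#' @param path output path.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' Read a cells x genes count matrix
#'
#' MatrixMarket (`.mtx` plus barcode and gene TSVs, cells as rows) or a
#' dense CSV whose first column holds cell ids. When a cell table is
#' given, rows are aligned to its cell order; any barcode mismatch is an
#' error.
#'
#' @param path `.mtx` or `.csv` path.
#' @param barcodes_path,genes_path one-column TSVs for `.mtx` input.
#' @param cell_table optional cell table to align against.
#' @return sparse cells x genes count matrix.
#' @export
read_counts <- function(path, barcodes_path = NULL, genes_path = NULL,
                        cell_table = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    if (is.null(barcodes_path) || is.null(genes_path)) {
      stop_tls("MTX input needs barcodes_path and genes_path")
    }
    m <- methods::as(Matrix::readMM(path), "CsparseMatrix")
    rownames(m) <- readLines(barcodes_path)
    colnames(m) <- readLines(genes_path)
  } else if (ext == "csv") {
    df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
    m <- methods::as(Matrix::Matrix(as.matrix(df), sparse = TRUE),
                     "CsparseMatrix")
  } else {
    stop_tls("unsupported counts format: .%s", ext)
  }
  if (!is.null(cell_table)) {
    missing <- setdiff(cell_table$cell_id, rownames(m))
    extra <- setdiff(rownames(m), cell_table$cell_id)
    if (length(missing) || length(extra)) {
      stop_tls("barcode mismatch with cell table (%d missing, %d extra)",
               length(missing), length(extra))
    }
    m <- m[cell_table$cell_id, , drop = FALSE]
  }
  m
}

#' Write a count matrix as MatrixMarket plus barcode/gene TSVs
#' @param counts cells x genes matrix with dimnames.
#' @param dir output directory (created if needed).
#' @return paths of the three files, invisibly.
#' @export
write_counts_mtx <- function(counts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mtx <- file.path(dir, "counts.mtx")
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"), mtx)
  writeLines(rownames(counts), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(counts), file.path(dir, "genes.tsv"))
  invisible(c(mtx, file.path(dir, c("barcodes.tsv", "genes.tsv"))))
}

#' Default pipeline configuration
#'
#' All module parameters with the stated analysis defaults: 10-count /
#' 2x-ratio demultiplexing, 500/500/10% CITE-seq QC, 10-transcript spatial
#' QC, 10 bronchi neighbors, 450 um axis exclusion, 50 um surrounding
#' ring, 0.5 radial split, 100 um / 5 mesothelial capsule rule, trim 0.1
#' and range 50 for ligand-receptor scoring; artifact defaults elsewhere.
#'
#' @param seed integer seed used for every stochastic stage.
#' @return nested list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    sim = list(),  # overrides passed to sim_config()
    demux = list(min_count = 10, ratio = 2),
    qc = list(rna_min = 500, mito_max = 0.10, adt_min = 500,
              isotype_max = 1, spatial_min_counts = 10),
    zoning = list(k_neighbors = 10, n_zones = 6, k_meso = 5,
                  capsule_max_avg_dist = 100, use_standin = FALSE),
    geometry = list(group_eps = 50, concavity = 50, min_area = 5000,
                    bronchi_k = 10, ring_width = 50, split = 0.5),
    axes = list(window = 50, max_dist = 450, t_max = 50, b_max = 50,
                bandwidth = 25, kde_max_cells = 50000),
    markers = list(min_frac = 0.05, alpha = 0.05, lfc_min = 1),
    interaction = list(method = "knn", k = 6, radius = 30,
                       focal_type = "CD4_Th0", range = 50, trim = 0.1,
                       contact_range = 10,
                       ligand = "Cd274", receptor = "Pdcd1",
                       sender_types = c("B", "macrophage", "cDC2")))
  class(cfg) <- "pipeline_config"
  cfg
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' Values in the file override the matching [default_config()] entries;
#' everything else keeps its default.
#'
#' @param path YAML file.
#' @param seed seed used when the file does not set one.
#' @return `pipeline_config` list.
#' @export
read_config <- function(path, seed = 1L) {
  override <- yaml::read_yaml(path)
  cfg <- merge_config(unclass(default_config(seed)), override)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

polygons_to_geojson <- function(polygons, path) {
  features <- lapply(polygons, function(p) {
    ring <- drop_closing_vertex(p$ring)
    coords <- lapply(seq_len(nrow(ring) + 1L), function(i) {
      j <- if (i > nrow(ring)) 1L else i
      c(ring[j, 1], ring[j, 2])
    })
    list(type = "Feature",
         properties = list(tls_id = p$tls_id, area_um2 = p$area,
                           centroid_x_um = p$centroid[1],
                           centroid_y_um = p$centroid[2]),
         geometry = list(type = "Polygon", coordinates = list(coords)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read TLS polygons back from GeoJSON
#' @param path GeoJSON path written by [write_outputs()].
#' @return list of polygons (`tls_id`, `ring`, `area`, `centroid`).
#' @export
read_polygons_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  lapply(gj$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    list(tls_id = f$properties$tls_id, ring = ring,
         area = f$properties$area_um2,
         centroid = c(f$properties$centroid_x_um, f$properties$centroid_y_um))
  })
}

#' Run the full spatial-niche pipeline on synthetic tissue
#'
#' simulate -> spatial QC -> zones (external truth labels plus the capsule
#' rule, or the clustering stand-in) -> TLS polygons -> distance axes ->
#' radial partition -> gradients, T/B/P regions and region means -> zone
#' markers -> interaction matrices and ligand-receptor scores. All
#' randomness derives from `config$seed`; two runs with the same config
#' produce byte-identical outputs.
#'
#' @param config a `pipeline_config` (see [default_config()]).
#' @param outdir optional output directory passed to [write_outputs()].
#' @return list with all intermediate and final results.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL) {
  sim_args <- config$sim
  sim_args$seed <- sim_args$seed %||% config$seed
  scfg <- do.call(sim_config, sim_args)
  tissue <- generate_tissue(scfg)

  kept <- qc_filter_spatial(tissue$counts, config$qc$spatial_min_counts)
  cells <- tissue$cells[tissue$cells$cell_id %in% kept, , drop = FALSE]
  counts <- tissue$counts[cells$cell_id, , drop = FALSE]

  if (isTRUE(config$zoning$use_standin)) {
    feats <- neighbor_composition_features(cells, config$zoning$k_neighbors)
    zones <- cluster_zones(feats, config$zoning$n_zones, seed = config$seed,
                           true_zones = stats::setNames(cells$true_zone,
                                                        cells$cell_id))
  } else {
    zones <- tibble::tibble(cell_id = cells$cell_id, zone = cells$true_zone,
                            source = "external")
  }
  zones <- split_capsule(cells, zones, k_meso = config$zoning$k_meso,
                         max_avg_dist = config$zoning$capsule_max_avg_dist)
  zvec <- stats::setNames(zones$zone, zones$cell_id)

  geo <- config$geometry
  polygons <- build_tls_polygons(cells[zvec[cells$cell_id] == "TLS", ],
                                 group_eps = geo$group_eps,
                                 concavity = geo$concavity,
                                 min_area = geo$min_area)
  ax_tls <- distance_to_tls(cells, polygons)
  ax_bronchi <- distance_to_zone_cells(cells, zones, zone = "bronchi",
                                       k = geo$bronchi_k)
  distances <- tibble::tibble(cell_id = cells$cell_id,
                              d_tls = ax_tls$d_tls,
                              tls_id = ax_tls$tls_id,
                              d_bronchi = ax_bronchi$d_zone)
  radial <- radial_partition(cells, polygons, ring_width = geo$ring_width,
                             split = geo$split)

  norm <- normalize_expression(counts)
  panel <- tissue$gene_info
  cd4 <- cells$cell_id[cells$cell_type %in% CD4_TYPES]
  d_tls_v <- stats::setNames(distances$d_tls, distances$cell_id)
  d_br_v <- stats::setNames(distances$d_bronchi, distances$cell_id)
  axes <- config$axes
  grad_tls <- convolve_along_axis(norm[cd4, , drop = FALSE], d_tls_v[cd4],
                                  genes = panel$gene[panel$class %in%
                                                       c("progenitor", "effector")],
                                  window = axes$window, max_dist = axes$max_dist)
  grad_bronchi <- convolve_along_axis(norm[cd4, , drop = FALSE], d_br_v[cd4],
                                      genes = panel$gene[panel$class %in%
                                                           c("progenitor", "effector")],
                                      window = axes$window,
                                      max_dist = axes$max_dist)
  tbp <- stats::setNames(
    assign_tbp(distances$d_tls, distances$d_bronchi,
               t_max = axes$t_max, b_max = axes$b_max,
               p_max = axes$max_dist),
    distances$cell_id)
  region_means <- region_mean_expression(norm[cd4, , drop = FALSE], tbp[cd4])
  markers <- zone_marker_test(counts, zvec[rownames(counts)],
                              min_frac = config$markers$min_frac,
                              alpha = config$markers$alpha,
                              lfc_min = config$markers$lfc_min)

  icfg <- config$interaction
  graph <- build_spatial_graph(cells, method = icfg$method, k = icfg$k,
                               radius = icfg$radius)
  interactions <- interaction_matrix(
    graph, stats::setNames(cells$cell_type, cells$cell_id), zvec,
    focal_type = icfg$focal_type)

  rad_cat <- stats::setNames(radial$category, radial$cell_id)
  lr <- list()
  for (cat in c("core", "outer", "surrounding")) {
    receivers <- intersect(cd4, radial$cell_id[radial$category == cat])
    for (sender in icfg$sender_types) {
      sc <- lr_spatial_score(counts, cells, icfg$ligand, icfg$receptor,
                             sender, receivers, range = icfg$range,
                             trim = icfg$trim,
                             contact_range = icfg$contact_range)
      lr[[length(lr) + 1L]] <- tibble::tibble(
        ligand = sc$ligand, receptor = sc$receptor, sender = sender,
        receiver_category = cat, score = sc$score,
        n_sender_in_range = sc$n_sender_in_range,
        n_receiver = sc$n_receiver)
    }
  }
  lr <- do.call(rbind, lr)
  lr_mat <- matrix(lr$score, nrow = length(icfg$sender_types),
                   dimnames = list(icfg$sender_types,
                                   c("core", "outer", "surrounding")))
  lr_scaled <- scale_incoming_signals(lr_mat)

  results <- list(config = config, tissue = tissue, cells = cells,
                  counts = counts, zones = zones, polygons = polygons,
                  distances = distances, radial = radial,
                  grad_tls = grad_tls, grad_bronchi = grad_bronchi,
                  tbp = tbp, region_means = region_means, markers = markers,
                  interactions = interactions, lr = lr,
                  lr_scaled = lr_scaled)
  if (!is.null(outdir)) write_outputs(results, outdir)
  results
}

#' Write pipeline outputs to disk
#'
#' Distances, radial records, region labels, region means, marker table,
#' interaction matrices, gradient profiles and ligand-receptor scores as
#' CSV; TLS polygons as GeoJSON (micron coordinates, image convention:
#' y increases downward); a JSON run log carrying the resolved config and
#' its hash. Purely a function of `results`, so reruns with the same
#' config are byte-identical.
#'
#' @param results list from [run_pipeline()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_outputs <- function(results, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  utils::write.csv(results$cells, p("cells.csv"), row.names = FALSE)
  utils::write.csv(results$zones, p("zones.csv"), row.names = FALSE)
  utils::write.csv(results$distances, p("distances.csv"), row.names = FALSE)
  utils::write.csv(results$radial, p("radial.csv"), row.names = FALSE)
  utils::write.csv(data.frame(cell_id = names(results$tbp),
                              region = unname(results$tbp)),
                   p("regions_tbp.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(results$region_means),
                   p("region_means.csv"), row.names = TRUE)
  utils::write.csv(results$markers, p("markers.csv"), row.names = FALSE)
  utils::write.csv(results$lr, p("lr_scores.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(results$lr_scaled), p("lr_scaled.csv"),
                   row.names = TRUE)
  for (ax in c("grad_tls", "grad_bronchi")) {
    gp <- results[[ax]]
    utils::write.csv(
      data.frame(cell_id = gp$cell_id, axis = gp$axis,
                 as.data.frame(gp$profile, check.names = FALSE)),
      p(paste0(ax, ".csv")), row.names = FALSE)
  }
  inter <- do.call(rbind, lapply(names(results$interactions), function(z) {
    m <- results$interactions[[z]]$counts
    data.frame(zone = z, from = rownames(m)[row(m)], to = colnames(m)[col(m)],
               count = as.vector(m))
  }))
  utils::write.csv(inter, p("interaction_counts.csv"), row.names = FALSE)
  polygons_to_geojson(results$polygons, p("polygons.geojson"))
  log <- list(config = unclass(results$config),
              config_hash = config_hash(results$config),
              n_cells = nrow(results$cells),
              n_polygons = length(results$polygons),
              coordinate_convention = "microns, y increases downward")
  jsonlite::write_json(log, p("run_log.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(outdir)
}
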