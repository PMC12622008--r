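# Spatial neighbor graphs, per-zone cell-type interaction matrices and a
# range-gated trimmed-mean ligand-receptor score.

#' Build an undirected spatial neighbor graph
#'
#' Nodes are cells; edges connect spatial neighbors by one of three
#' constructions: mutualised k nearest neighbors (union symmetrization),
#' a fixed radius, or the Delaunay triangulation.
#'
#' @param cells cell table.
#' @param method `"knn"`, `"radius"` or `"delaunay"`.
#' @param k neighbors for `"knn"` (default 6).
#' @param radius edge radius in microns for `"radius"` (default 30).
#' @return an [igraph::graph] with vertex names = cell ids.
#' @export
build_spatial_graph <- function(cells, method = c("knn", "radius", "delaunay"),
                                k = 6, radius = 30) {
  method <- match.arg(method)
  cells <- validate_cell_table(cells)
  n <- nrow(cells)
  if (n < 2L) stop_tls("a spatial graph needs >= 2 cells")
  xy <- cbind(cells$x_um, cells$y_um)
  edges <- switch(
    method,
    knn = {
      kk <- min(k + 1L, n)
      nn <- knn_query(xy, xy, k = kk)
      from <- rep(seq_len(n), kk - 1L)
      to <- as.vector(nn$idx[, -1L, drop = FALSE])
      cbind(pmin(from, to), pmax(from, to))
    },
    radius = {
      e <- list()
      chunk <- 1000L
      for (start in seq(1L, n, by = chunk)) {
        rows <- start:min(start + chunk - 1L, n)
        d2 <- outer(xy[rows, 1], xy[, 1], "-")^2 +
          outer(xy[rows, 2], xy[, 2], "-")^2
        hit <- which(d2 <= radius^2, arr.ind = TRUE)
        hit[, 1] <- rows[hit[, 1]]
        e[[length(e) + 1L]] <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
      }
      do.call(rbind, e)
    },
    delaunay = {
      dd <- deldir::deldir(xy[, 1], xy[, 2], suppressMsge = TRUE)
      cbind(pmin(dd$delsgs$ind1, dd$delsgs$ind2),
            pmax(dd$delsgs$ind1, dd$delsgs$ind2))
    })
  edges <- unique(edges[edges[, 1] != edges[, 2], , drop = FALSE])
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- cells$cell_id
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  g
}

#' Per-zone cell-type interaction matrices
#'
#' Counts spatial-graph edges between cell types within each zone
#' (both endpoints in the zone). Raw counts are always retained; the
#' scaled form divides each row by its maximum.
#'
#' @param graph spatial graph from [build_spatial_graph()].
#' @param cell_types named character vector, cell id -> type.
#' @param zones named character vector, cell id -> zone.
#' @param focal_type optional type whose row is of interest; zones without
#'   any focal cell get a zero row with a warning.
#' @param row_scale also return row-scaled matrices (default `TRUE`).
#' @return named list per zone, each `list(counts, scaled)` of type x type
#'   matrices over all observed types.
#' @export
interaction_matrix <- function(graph, cell_types, zones, focal_type = NULL,
                               row_scale = TRUE) {
  ids <- igraph::V(graph)$name
  stopifnot(!is.null(ids))
  types <- cell_types[ids]
  zvec <- zones[ids]
  if (anyNA(types) || anyNA(zvec)) {
    stop_tls("cell_types and zones must cover every graph vertex")
  }
  lev <- sort(unique(types))
  el <- igraph::as_edgelist(graph, names = FALSE)
  out <- list()
  for (z in sort(unique(zvec))) {
    in_zone <- zvec == z
    m <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
    if (nrow(el) > 0) {
      keep <- in_zone[el[, 1]] & in_zone[el[, 2]]
      for (r in which(keep)) {
        t1 <- types[el[r, 1]]; t2 <- types[el[r, 2]]
        m[t1, t2] <- m[t1, t2] + 1
        if (t1 != t2) m[t2, t1] <- m[t2, t1] + 1
      }
    }
    if (!is.null(focal_type) &&
        (!focal_type %in% lev || sum(types == focal_type & in_zone) == 0L)) {
      warning(sprintf("zone '%s' has no cells of focal type '%s'", z, focal_type))
    }
    scaled <- NULL
    if (row_scale) {
      rmax <- apply(m, 1L, max)
      scaled <- m / ifelse(rmax > 0, rmax, 1)
    }
    out[[z]] <- list(counts = m, scaled = scaled)
  }
  out
}

#' Range-gated trimmed-mean ligand-receptor score
#'
#' A transparent spatial communication score: the trimmed mean of ligand
#' expression over sender-type cells lying within `range` microns of at
#' least one receiver cell, times the trimmed mean of receptor expression
#' over the receiver cells. The score is 0 when no sender is in range.
#' `contact_range` is accepted for interface parity with contact-mediated
#' parameterizations but does not enter this score.
#'
#' @param expression cells x genes matrix, rows named by cell id.
#' @param cells cell table.
#' @param ligand,receptor gene names (must exist in the matrix).
#' @param sender_type cell type of the sender population.
#' @param receiver_ids cell ids of the receiver population (e.g. CD4 cells
#'   of one TLS radial category).
#' @param range interaction range in microns (default 50).
#' @param trim fraction trimmed from each tail of the means (default 0.1).
#' @param contact_range accepted, unused (see above).
#' @return list: `ligand`, `receptor`, `sender_type`, `score`,
#'   `n_sender_in_range`, `n_receiver`.
#' @export
lr_spatial_score <- function(expression, cells, ligand, receptor,
                             sender_type, receiver_ids, range = 50,
                             trim = 0.1, contact_range = 10) {
  cells <- validate_cell_table(cells)
  for (g in c(ligand, receptor)) {
    if (!g %in% colnames(expression)) stop_tls("gene '%s' not in expression matrix", g)
  }
  receiver_ids <- intersect(receiver_ids, cells$cell_id)
  senders <- cells[cells$cell_type == sender_type, , drop = FALSE]
  n_in_range <- 0L
  score <- 0
  if (nrow(senders) > 0 && length(receiver_ids) > 0) {
    recv <- cells[match(receiver_ids, cells$cell_id), , drop = FALSE]
    nn <- knn_query(cbind(senders$x_um, senders$y_um),
                    cbind(recv$x_um, recv$y_um), k = 1L)
    in_range <- nn$dist[, 1] <= range
    n_in_range <- sum(in_range)
    if (n_in_range > 0) {
      lig <- as.numeric(expression[senders$cell_id[in_range], ligand])
      rec <- as.numeric(expression[receiver_ids, receptor])
      score <- trimmed_mean(lig, trim) * trimmed_mean(rec, trim)
    }
  }
  list(ligand = ligand, receptor = receptor, sender_type = sender_type,
       score = score, n_sender_in_range = n_in_range,
       n_receiver = length(receiver_ids))
}

#' Min-max scale incoming signals across receiver categories
#'
#' Per pathway (row), scales scores to `[0, 1]` across receiver groups;
#' constant rows map to all zeros.
#'
#' @param scores pathways x receiver-categories numeric matrix.
#' @return matrix of the same shape scaled row-wise.
#' @export
scale_incoming_signals <- function(scores) {
  scores <- as.matrix(scores)
  t(apply(scores, 1L, function(r) {
    rng <- range(r, na.rm = TRUE)
    if (!is.finite(rng[1]) || rng[2] == rng[1]) return(rep(0, length(r)))
    (r - rng[1]) / (rng[2] - rng[1])
  }))
}
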