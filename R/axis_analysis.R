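# Expression analyses along the structure-anchored distance axes:
# convolved gradients, expression-weighted 2D densities, T/B/P region
# assignment, per-region summaries, zone marker tests and the
# microscopy distance-categorization rule.

#' Normalize a count matrix for expression summaries
#'
#' Per-cell library-size normalization to the median total count followed
#' by `log1p`. Cells with zero total counts are left at zero.
#'
#' @param counts cells x genes count matrix (dense or sparse).
#' @return sparse matrix of normalized log expression.
#' @export
normalize_expression <- function(counts) {
  tot <- Matrix::rowSums(counts)
  sf <- ifelse(tot > 0, stats::median(tot[tot > 0]) / tot, 0)
  norm <- Matrix::Diagonal(x = sf) %*% counts
  dimnames(norm) <- dimnames(counts)
  log1p(methods::as(norm, "CsparseMatrix"))
}

#' Convolved gene expression along a distance axis
#'
#' Cells with axis value at most `max_dist` are ordered by increasing axis
#' value (ties broken by cell id) and each gene's expression is smoothed
#' with a centered moving average over `window` cells, shrinking the
#' window at the profile edges. `window = 1` returns the raw ordered
#' values.
#'
#' @param expression cells x genes matrix (counts or normalized), rows
#'   named by cell id.
#' @param axis named numeric vector of axis values (microns or scaled),
#'   names = cell ids.
#' @param genes genes to profile (default: all columns).
#' @param window moving-average window in cells (default 50).
#' @param max_dist axis cutoff; cells beyond it are excluded (default 450
#'   microns; use `Inf` for scaled axes).
#' @return list of class `gradient_profile`: `cell_id` (ordered), `axis`
#'   (ordered values), `profile` (cells x genes matrix of smoothed
#'   values), `window`.
#' @export
convolve_along_axis <- function(expression, axis, genes = NULL,
                                window = 50, max_dist = 450) {
  stopifnot(window >= 1)
  if (is.null(names(axis))) {
    stopifnot(length(axis) == nrow(expression))
    names(axis) <- rownames(expression)
  }
  genes <- genes %||% colnames(expression)
  keep <- names(axis)[is.finite(axis) & axis <= max_dist]
  keep <- intersect(keep, rownames(expression))
  if (length(keep) == 0L) {
    stop_tls("no cells within max_dist = %g of the axis origin", max_dist)
  }
  ord <- keep[order(axis[keep], keep)]
  vals <- as.matrix(expression[ord, genes, drop = FALSE])
  n <- nrow(vals)
  hl <- floor((window - 1) / 2)
  hh <- floor(window / 2)
  lo <- pmax(1L, seq_len(n) - hl)
  hi <- pmin(n, seq_len(n) + hh)
  smooth <- apply(vals, 2L, function(v) {
    cs <- c(0, cumsum(v))
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  })
  smooth <- matrix(smooth, n, length(genes),
                   dimnames = list(ord, genes))
  structure(list(cell_id = ord, axis = unname(axis[ord]),
                 profile = smooth, window = window),
            class = "gradient_profile")
}

#' Expression-weighted 2D kernel density estimate
#'
#' Gaussian-kernel density on the (d_tls, d_bronchi) plane with per-cell
#' weights (typically a gene's expression) normalized to sum one. The
#' returned grid integrates to 1.
#'
#' @param x,y per-cell coordinates on the two distance axes (microns).
#' @param weights nonnegative per-cell weights, not all zero.
#' @param bandwidth Gaussian kernel bandwidth in microns (default 25).
#' @param grid_n grid resolution per axis (default 64).
#' @param max_cells subsample limit (default 50000).
#' @param seed seed for the subsample draw.
#' @param lims optional c(xmin, xmax, ymin, ymax); defaults to the data
#'   range padded by 3 bandwidths.
#' @return list with grid vectors `x`, `y` and density matrix `z`
#'   (`sum(z) * dx * dy == 1`).
#' @export
weighted_kde_2d <- function(x, y, weights, bandwidth = 25, grid_n = 64,
                            max_cells = 50000, seed = 1L, lims = NULL) {
  stopifnot(length(x) == length(y), length(x) == length(weights))
  if (any(weights < 0)) stop_tls("weights must be nonnegative")
  if (sum(weights) <= 0) stop_tls("all weights are zero")
  n <- length(x)
  if (n > max_cells) {
    idx <- with_seed(seed, sample.int(n, max_cells))
    x <- x[idx]; y <- y[idx]; weights <- weights[idx]
    if (sum(weights) <= 0) stop_tls("all weights are zero after subsampling")
  }
  w <- weights / sum(weights)
  lims <- lims %||% c(range(x) + c(-3, 3) * bandwidth,
                      range(y) + c(-3, 3) * bandwidth)
  gx <- seq(lims[1], lims[2], length.out = grid_n)
  gy <- seq(lims[3], lims[4], length.out = grid_n)
  kx <- stats::dnorm(outer(gx, x, "-") / bandwidth) / bandwidth  # grid_n x n
  ky <- stats::dnorm(outer(gy, y, "-") / bandwidth) / bandwidth
  z <- kx %*% (w * t(ky))
  dx <- gx[2] - gx[1]; dy <- gy[2] - gy[1]
  z <- z / (sum(z) * dx * dy)
  list(x = gx, y = gy, z = z, bandwidth = bandwidth)
}

#' Assign T/B/P spatial regions from the two distance axes
#'
#' T (close to TLS) takes priority over B (close to bronchi); remaining
#' cells within `p_max` on both axes are parenchymal (P), and cells beyond
#' that are unlabelled. The T-over-B priority matters where TLS abut
#' bronchi.
#'
#' @param d_tls,d_bronchi per-cell distances in microns.
#' @param t_max,b_max region thresholds in microns (defaults 50).
#' @param p_max outer cutoff for the P region (default 450).
#' @return character vector in `c("T", "B", "P", "none")`.
#' @export
assign_tbp <- function(d_tls, d_bronchi, t_max = 50, b_max = 50, p_max = 450) {
  stopifnot(length(d_tls) == length(d_bronchi))
  out <- rep("none", length(d_tls))
  out[d_tls <= p_max & d_bronchi <= p_max] <- "P"
  out[d_bronchi <= b_max] <- "B"
  out[d_tls <= t_max] <- "T"
  out
}

#' Mean expression per region
#'
#' @param expression cells x genes matrix, rows named by cell id.
#' @param labels per-cell region labels (named by cell id, or aligned with
#'   the matrix rows).
#' @param genes genes to summarise (default all).
#' @return regions x genes matrix of arithmetic means; regions with no
#'   cells are omitted with a warning.
#' @export
region_mean_expression <- function(expression, labels, genes = NULL) {
  genes <- genes %||% colnames(expression)
  if (!is.null(names(labels))) {
    labels <- labels[rownames(expression)]
  }
  stopifnot(length(labels) == nrow(expression))
  present <- !is.na(labels)
  if (!all(present)) warning("cells with NA labels are dropped")
  m <- as.matrix(expression[present, genes, drop = FALSE])
  lab <- labels[present]
  sums <- rowsum(m, lab)
  counts <- as.vector(table(lab)[rownames(sums)])
  sums / counts
}

#' Zone marker test (rank-sum, one zone vs rest)
#'
#' For each zone, genes expressed (count > 0) in at least `min_frac` of
#' cells of both the zone and the rest are tested zone-vs-rest with a
#' Wilcoxon rank-sum test on normalized expression. P values are
#' Benjamini-Hochberg adjusted across all tests, and a gene passes for a
#' zone iff adjusted p < `alpha` and |log2 fold change| > `lfc_min`
#' (log2FC of normalized means with pseudocount 1).
#'
#' @param expression cells x genes count matrix, rows named by cell id.
#' @param zones per-cell zone labels (aligned with rows or named).
#' @param min_frac expression-fraction filter (default 0.05).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param lfc_min |log2FC| threshold (default 1).
#' @param normalize normalize counts before testing (default `TRUE`).
#' @return tibble with `gene`, `zone`, `log2FC`, `p`, `p_adj`, `pass`.
#' @export
zone_marker_test <- function(expression, zones, min_frac = 0.05,
                             alpha = 0.05, lfc_min = 1, normalize = TRUE) {
  if (!is.null(names(zones))) zones <- zones[rownames(expression)]
  stopifnot(length(zones) == nrow(expression))
  zn <- table(zones)
  usable <- names(zn)[zn >= 2L]
  dropped <- setdiff(names(zn), usable)
  if (length(dropped)) {
    warning("zones with < 2 cells excluded: ", paste(dropped, collapse = ", "))
  }
  if (length(usable) < 2L) stop_tls("marker test needs >= 2 zones with >= 2 cells")
  in_use <- zones %in% usable
  counts <- expression[in_use, , drop = FALSE]
  zones <- zones[in_use]
  # ranks are tested on (library-normalized) expression; the fold change
  # uses normalized means on the linear scale with pseudocount 1
  if (normalize) {
    tot <- Matrix::rowSums(counts)
    sf <- ifelse(tot > 0, stats::median(tot[tot > 0]) / tot, 0)
    norm <- Matrix::Diagonal(x = sf) %*% counts
    dimnames(norm) <- dimnames(counts)
    norm <- methods::as(norm, "CsparseMatrix")
  } else {
    norm <- counts
  }
  detected <- counts > 0
  res <- list()
  for (z in usable) {
    grp <- zones == z
    frac_in <- Matrix::colSums(detected[grp, , drop = FALSE]) / sum(grp)
    frac_out <- Matrix::colSums(detected[!grp, , drop = FALSE]) / sum(!grp)
    test_genes <- colnames(counts)[frac_in >= min_frac & frac_out >= min_frac]
    if (length(test_genes) == 0L) next
    for (g in test_genes) {
      x <- as.numeric(norm[grp, g]); y <- as.numeric(norm[!grp, g])
      p <- stats::wilcox.test(x, y, exact = FALSE)$p.value
      lfc <- log2((mean(x) + 1) / (mean(y) + 1))
      res[[length(res) + 1L]] <- tibble::tibble(
        gene = g, zone = z, log2FC = lfc, p = p)
    }
  }
  if (length(res) == 0L) {
    return(tibble::tibble(gene = character(), zone = character(),
                          log2FC = numeric(), p = numeric(),
                          p_adj = numeric(), pass = logical()))
  }
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$pass <- out$p_adj < alpha & abs(out$log2FC) > lfc_min
  out
}

#' Categorize cells by microscopy distance rules
#'
#' Reproduces the imaging categorization: close to TLS (< 50 um), else
#' close to bronchi (< 50 um), else close to blood vessels (< 100 um and
#' > 50 um from TLS), else alveolar (> 50 um from TLS, bronchi and
#' vessels), else other. As printed, the vessel and alveolar clauses
#' overlap for cells 50-100 um from a vessel and far from everything
#' else; the vessel clause takes priority.
#'
#' @param d_tls,d_bronchi,d_vessel per-cell distances in microns.
#' @return character vector in
#'   `c("TLS", "bronchi", "vessel", "alveolar", "other")`.
#' @export
categorize_imaging <- function(d_tls, d_bronchi, d_vessel) {
  stopifnot(length(d_tls) == length(d_bronchi),
            length(d_tls) == length(d_vessel))
  out <- rep("other", length(d_tls))
  alveolar <- d_tls > 50 & d_bronchi > 50 & d_vessel > 50
  out[alveolar] <- "alveolar"
  out[d_vessel < 100 & d_tls > 50] <- "vessel"
  out[d_bronchi < 50] <- "bronchi"
  out[d_tls < 50] <- "TLS"
  out
}
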