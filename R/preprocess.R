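# Droplet demultiplexing and quality-control rules for CITE-seq and
# imaging-based spatial data.

#' Demultiplex droplets by hashtag counts
#'
#' Assigns each droplet to the hashtag with the highest signal, provided
#' that signal reaches `min_count` and is strictly more than `ratio` times
#' the second most abundant hashtag; otherwise the droplet is left
#' unassigned. Droplets flagged as doublets are labelled `doublet` and
#' excluded from assignment. Ties for the top hashtag are broken by the
#' lowest hashtag (column) index.
#'
#' @param hashtag_counts droplets x hashtags nonnegative count matrix with
#'   at least two hashtag columns.
#' @param min_count minimum top-hashtag count (default 10).
#' @param ratio required multiple over the second hashtag (default 2,
#'   strict inequality).
#' @param doublet_flags optional logical vector marking doublet droplets.
#'   When `NULL` and `naive_doublets = TRUE`, a naive stand-in flags
#'   droplets whose two top hashtags both reach `min_count` and lie within
#'   `ratio` of each other; the stand-in is *not* the external doublet
#'   caller used for real data.
#' @param naive_doublets use the naive doublet stand-in when no flags are
#'   supplied (default `FALSE`).
#' @return tibble with columns `cell_id`, `label` (hashtag name,
#'   `"unassigned"` or `"doublet"`), `top_count`, `second_count`.
#' @export
demux_hashtags <- function(hashtag_counts, min_count = 10, ratio = 2,
                           doublet_flags = NULL, naive_doublets = FALSE) {
  m <- as.matrix(hashtag_counts)
  if (ncol(m) < 2L) {
    stop_tls("demultiplexing needs >= 2 hashtags (got %d); the second-highest signal is undefined", ncol(m))
  }
  if (any(m < 0)) stop_tls("hashtag counts must be nonnegative")
  ids <- rownames(m) %||% sprintf("droplet_%05d", seq_len(nrow(m)))
  hnames <- colnames(m) %||% sprintf("hashtag_%d", seq_len(ncol(m)))

  # top two per row; stable order breaks count ties by lowest column index
  ord1 <- max.col(m, ties.method = "first")
  top <- m[cbind(seq_len(nrow(m)), ord1)]
  m2 <- m
  m2[cbind(seq_len(nrow(m)), ord1)] <- -Inf
  ord2 <- max.col(m2, ties.method = "first")
  second <- m[cbind(seq_len(nrow(m)), ord2)]

  if (is.null(doublet_flags) && naive_doublets) {
    doublet_flags <- top >= min_count & second >= min_count &
      top <= ratio * second
  }
  if (is.null(doublet_flags)) doublet_flags <- rep(FALSE, nrow(m))
  stopifnot(length(doublet_flags) == nrow(m))

  assigned <- top >= min_count & top > ratio * second
  label <- ifelse(doublet_flags, "doublet",
                  ifelse(assigned, hnames[ord1], "unassigned"))
  tibble::tibble(cell_id = ids, label = label,
                 top_count = as.numeric(top),
                 second_count = as.numeric(second))
}

#' Quality-control filter for CITE-seq droplets
#'
#' Keeps a cell iff it has at least `rna_min` RNA counts, at most
#' `mito_max` of counts mapping to mitochondrial genes, at least `adt_min`
#' surface-tag (ADT) counts, and is positive for fewer than two isotype
#' controls. Exclusions are excluded strictly ("fewer than 500", "over
#' 10%"), so cells exactly at a threshold are kept.
#'
#' @param records data frame with columns `cell_id`, `rna_counts`,
#'   `mito_fraction`, `adt_counts`, `isotype_positive_count`.
#' @param rna_min,mito_max,adt_min,isotype_max thresholds; defaults 500,
#'   0.10, 500, 1 (at most one isotype-positive control).
#' @return list with `kept` (character vector of cell ids) and `log`
#'   (tibble of per-cell pass/fail with comma-separated exclusion reasons).
#' @export
qc_filter_cite <- function(records, rna_min = 500, mito_max = 0.10,
                           adt_min = 500, isotype_max = 1) {
  need <- c("cell_id", "rna_counts", "mito_fraction", "adt_counts",
            "isotype_positive_count")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    stop_tls("QC records missing column(s): %s", paste(missing, collapse = ", "))
  }
  if (any(records$mito_fraction < 0 | records$mito_fraction > 1)) {
    stop_tls("mito_fraction must lie in [0, 1]")
  }
  fail <- cbind(
    low_rna = records$rna_counts < rna_min,
    high_mito = records$mito_fraction > mito_max,
    low_adt = records$adt_counts < adt_min,
    isotype = records$isotype_positive_count > isotype_max)
  reasons <- apply(fail, 1L, function(f) paste(colnames(fail)[f], collapse = ","))
  kept <- rowSums(fail) == 0L
  list(kept = records$cell_id[kept],
       log = tibble::tibble(cell_id = records$cell_id, kept = kept,
                            reasons = reasons))
}

#' Quality-control filter for spatial cells
#'
#' Removes cells with fewer than `min_counts` total transcript counts.
#'
#' @param counts cells x genes count matrix (dense or sparse), rows named
#'   by cell id.
#' @param min_counts minimum total transcripts per cell (default 10).
#' @return character vector of kept cell ids.
#' @export
qc_filter_spatial <- function(counts, min_counts = 10) {
  tot <- Matrix::rowSums(counts)
  ids <- rownames(counts) %||% sprintf("cell_%05d", seq_along(tot))
  ids[tot >= min_counts]
}
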