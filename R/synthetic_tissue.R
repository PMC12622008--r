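# Synthetic structured lung-like tissue with known geometric and gradient
# ground truth. TLS are discs of densely packed B / progenitor CD4 cells,
# bronchi are epithelial annuli around an empty lumen, vessels are
# endothelial discs, the capsule is a mesothelial strip along the bottom
# field edge, and the remaining parenchyma is sparse mixed tissue.

CELL_TYPES <- c("B", "CD4_Th0", "CD4_Th2", "CD4_other", "epithelial_bronchus",
                "mesothelial", "macrophage", "cDC2", "endothelial", "other")
CD4_TYPES <- c("CD4_Th0", "CD4_Th2", "CD4_other")
APC_TYPES <- c("B", "macrophage", "cDC2")

#' Default synthetic gene panel
#'
#' A small targeted panel with one class per gene. Classes drive the
#' simulated expression model: `progenitor` genes follow the TLS distance
#' gradient in CD4 cells, `effector` genes follow the bronchi distance
#' gradient in CD4 cells, `structural` genes mark their structural cell
#' type, `housekeeping` genes are flat, `ligand` genes follow the TLS
#' gradient in antigen-presenting cells and `receptor` genes are expressed
#' by CD4 cells.
#'
#' @return a tibble with columns `gene`, `class`, `marker_type`.
#' @export
default_gene_panel <- function() {
  tibble::tibble(
    gene = c("Tcf7", "Il7r", "Slamf6",
             "Gata3", "Cxcr6", "Il1rl1",
             "Epcam", "Cd79a", "Pecam1", "Msln",
             "Actb", "B2m",
             "Cd274", "Pdcd1lg2",
             "Pdcd1"),
    class = c(rep("progenitor", 3), rep("effector", 3), rep("structural", 4),
              rep("housekeeping", 2), rep("ligand", 2), "receptor"),
    marker_type = c(rep(NA, 6),
                    "epithelial_bronchus", "B", "endothelial", "mesothelial",
                    rep(NA, 5))
  )
}

#' Default per-structure cell-type mixtures
#'
#' Probability vectors over the simulated cell types for each structure
#' kind: B-cell/progenitor-CD4-dominated TLS, epithelial bronchi walls
#' with some Th2, endothelial vessels, mesothelial capsule, and mixed
#' parenchyma.
#'
#' @return named list of probability vectors (each sums to 1).
#' @export
default_mixtures <- function() {
  mk <- function(...) {
    v <- stats::setNames(rep(0, length(CELL_TYPES)), CELL_TYPES)
    args <- list(...)
    v[names(args)] <- unlist(args)
    v
  }
  list(
    tls        = mk(B = 0.60, CD4_Th0 = 0.25, CD4_other = 0.05,
                    cDC2 = 0.05, macrophage = 0.05),
    bronchi    = mk(epithelial_bronchus = 0.90, CD4_Th2 = 0.10),
    vessel     = mk(endothelial = 0.90, CD4_other = 0.10),
    capsule    = mk(mesothelial = 0.90, other = 0.10),
    parenchyma = mk(other = 0.45, macrophage = 0.15, CD4_Th2 = 0.18,
                    CD4_other = 0.07, B = 0.05, cDC2 = 0.05, CD4_Th0 = 0.05)
  )
}

#' Build a simulation configuration
#'
#' Collects the geometric layout, per-structure cell densities and
#' mixtures, the gene panel, and the distance-gradient model parameters
#' for the synthetic tissue generator. Expression gradients follow
#' `a * exp(-d / lambda) + b` where `d` is the true distance (microns) to
#' the relevant structure: the TLS axis for progenitor and ligand genes,
#' the bronchi axis for effector genes.
#'
#' @param field_width,field_height field extent in microns.
#' @param n_tls number of TLS discs.
#' @param tls_radius_mean,tls_radius_sd TLS radius distribution (microns).
#' @param n_bronchi number of bronchi (epithelial annuli).
#' @param bronchus_radius lumen radius in microns.
#' @param bronchus_wall epithelial ring width in microns.
#' @param n_vessels number of vessel discs.
#' @param vessel_radius vessel radius in microns.
#' @param capsule_depth depth of the mesothelial strip along the bottom
#'   field edge, microns.
#' @param densities named numeric vector of cells per 1e4 square microns
#'   for `tls`, `bronchi`, `vessel`, `capsule`, `parenchyma`.
#' @param mixtures named list of cell-type probability vectors per
#'   structure kind; each must sum to 1.
#' @param gene_panel tibble as from [default_gene_panel()].
#' @param gradient_amplitude,gradient_scale,gradient_baseline gradient
#'   parameters `a` (expected counts), `lambda` (microns) and `b`
#'   (expected counts).
#' @param dispersion negative-binomial size parameter; `Inf` gives Poisson
#'   counts.
#' @param structure_gap minimum boundary-to-boundary spacing between placed
#'   structures, microns.
#' @param max_place_attempts rejection-sampling bound per structure.
#' @param seed integer seed for the whole tissue draw.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(field_width = 3000, field_height = 3000,
                       n_tls = 3, tls_radius_mean = 150, tls_radius_sd = 20,
                       n_bronchi = 2, bronchus_radius = 100, bronchus_wall = 40,
                       n_vessels = 2, vessel_radius = 60,
                       capsule_depth = 60,
                       densities = c(tls = 60, bronchi = 40, vessel = 30,
                                     capsule = 20, parenchyma = 4),
                       mixtures = default_mixtures(),
                       gene_panel = default_gene_panel(),
                       gradient_amplitude = 20, gradient_scale = 100,
                       gradient_baseline = 1,
                       dispersion = Inf,
                       structure_gap = 120,
                       max_place_attempts = 500,
                       seed = 1L) {
  cfg <- list(field_width = field_width, field_height = field_height,
              n_tls = n_tls, tls_radius_mean = tls_radius_mean,
              tls_radius_sd = tls_radius_sd,
              n_bronchi = n_bronchi, bronchus_radius = bronchus_radius,
              bronchus_wall = bronchus_wall,
              n_vessels = n_vessels, vessel_radius = vessel_radius,
              capsule_depth = capsule_depth,
              densities = densities, mixtures = mixtures,
              gene_panel = tibble::as_tibble(gene_panel),
              gradient_amplitude = gradient_amplitude,
              gradient_scale = gradient_scale,
              gradient_baseline = gradient_baseline,
              dispersion = dispersion,
              structure_gap = structure_gap,
              max_place_attempts = max_place_attempts,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  lens <- c(cfg$field_width, cfg$field_height, cfg$tls_radius_mean,
            cfg$bronchus_radius, cfg$bronchus_wall, cfg$vessel_radius,
            cfg$capsule_depth, cfg$gradient_scale)
  if (any(lens <= 0)) stop_tls("all lengths and gradient_scale must be > 0")
  if (cfg$n_tls < 0) stop_tls("n_tls must be >= 0")
  if (cfg$gradient_amplitude < 0) stop_tls("gradient_amplitude must be >= 0")
  for (kind in names(cfg$mixtures)) {
    mx <- cfg$mixtures[[kind]]
    if (abs(sum(mx) - 1) > 1e-9) {
      stop_tls("mixture for '%s' sums to %.12f, not 1", kind, sum(mx))
    }
    if (any(mx < 0)) stop_tls("mixture for '%s' has negative entries", kind)
  }
  needed <- c("tls", "bronchi", "vessel", "capsule", "parenchyma")
  if (!all(needed %in% names(cfg$densities))) {
    stop_tls("densities must name all of: %s", paste(needed, collapse = ", "))
  }
  cfg
}

# Rejection-sample non-overlapping structure centres. Each structure is a
# disc of effective radius `radius` that must keep `gap` clearance from
# previously placed structures, the field border and the capsule strip.
place_structures <- function(cfg) {
  placed <- data.frame(kind = character(), id = character(),
                       cx = numeric(), cy = numeric(),
                       radius_inner = numeric(), radius_outer = numeric())
  wanted <- list()
  if (cfg$n_tls > 0) {
    for (i in seq_len(cfg$n_tls)) {
      r <- max(20, stats::rnorm(1, cfg$tls_radius_mean, cfg$tls_radius_sd))
      wanted[[length(wanted) + 1L]] <-
        list(kind = "tls", id = sprintf("tls_%d", i), inner = 0, outer = r)
    }
  }
  if (cfg$n_bronchi > 0) {
    for (i in seq_len(cfg$n_bronchi)) {
      wanted[[length(wanted) + 1L]] <-
        list(kind = "bronchi", id = sprintf("bronchus_%d", i),
             inner = cfg$bronchus_radius,
             outer = cfg$bronchus_radius + cfg$bronchus_wall)
    }
  }
  if (cfg$n_vessels > 0) {
    for (i in seq_len(cfg$n_vessels)) {
      wanted[[length(wanted) + 1L]] <-
        list(kind = "vessel", id = sprintf("vessel_%d", i),
             inner = 0, outer = cfg$vessel_radius)
    }
  }
  for (w in wanted) {
    ok <- FALSE
    for (attempt in seq_len(cfg$max_place_attempts)) {
      cx <- stats::runif(1, w$outer + 10, cfg$field_width - w$outer - 10)
      cy <- stats::runif(1, w$outer + 10,
                         cfg$field_height - cfg$capsule_depth - w$outer -
                           cfg$structure_gap)
      if (nrow(placed) > 0) {
        d <- sqrt((placed$cx - cx)^2 + (placed$cy - cy)^2)
        if (any(d < placed$radius_outer + w$outer + cfg$structure_gap)) next
      }
      placed <- rbind(placed, data.frame(
        kind = w$kind, id = w$id, cx = cx, cy = cy,
        radius_inner = w$inner, radius_outer = w$outer))
      ok <- TRUE
      break
    }
    if (!ok) {
      stop_tls("could not place structure '%s' (%s) after %d attempts",
               w$id, w$kind, cfg$max_place_attempts)
    }
  }
  placed
}

sample_in_disc <- function(n, cx, cy, r_inner, r_outer) {
  u <- stats::runif(n)
  r <- sqrt(u * (r_outer^2 - r_inner^2) + r_inner^2)
  th <- stats::runif(n, 0, 2 * pi)
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# Analytic true distance of points to the nearest structure of a kind.
# Discs: max(0, |p - c| - R). Annuli: 0 inside the ring, radial gap
# otherwise (including from inside the lumen).
true_structure_distance <- function(xy, structures, kind) {
  sel <- structures[structures$kind == kind, , drop = FALSE]
  if (nrow(sel) == 0L) return(rep(NA_real_, nrow(xy)))
  d <- matrix(Inf, nrow(xy), nrow(sel))
  for (j in seq_len(nrow(sel))) {
    rho <- sqrt((xy[, 1] - sel$cx[j])^2 + (xy[, 2] - sel$cy[j])^2)
    d[, j] <- pmax(0, pmax(rho - sel$radius_outer[j],
                           sel$radius_inner[j] - rho))
  }
  apply(d, 1L, min)
}

#' Generate synthetic structured tissue
#'
#' Places TLS, bronchi, vessels and a capsule in a rectangular field,
#' populates each structure and the parenchyma with cells at the
#' configured densities and type mixtures, and draws a cells x genes count
#' matrix from the gradient model: for CD4 cells, progenitor-gene expected
#' counts are `a * exp(-d_tls / lambda) + b` and effector-gene expected
#' counts are `a * exp(-d_bronchi / lambda) + b`, with the true analytic
#' distances to the generating geometry. Counts are negative binomial with
#' the configured dispersion (Poisson when `dispersion = Inf`). The whole
#' draw is deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a list with `cells` (tibble: cell_id, x_um, y_um, cell_type,
#'   true_zone, sample), `counts` (sparse cells x genes matrix),
#'   `gene_info` (the panel), and `truth` (structure table, per-cell true
#'   distances, gradient parameters).
#' @export
generate_tissue <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    structures <- place_structures(config)
    dens <- config$densities

    xs <- list(); types <- list(); zones <- list()
    add_cells <- function(xy, kind_mixture, zone) {
      n <- nrow(xy)
      if (n == 0L) return(invisible(NULL))
      mx <- config$mixtures[[kind_mixture]]
      ct <- sample(names(mx), n, replace = TRUE, prob = mx)
      xs[[length(xs) + 1L]] <<- xy
      types[[length(types) + 1L]] <<- ct
      zones[[length(zones) + 1L]] <<- rep(zone, n)
      invisible(NULL)
    }

    for (j in seq_len(nrow(structures))) {
      s <- structures[j, ]
      area <- pi * (s$radius_outer^2 - s$radius_inner^2)
      n <- stats::rpois(1, dens[[s$kind]] * area / 1e4)
      xy <- sample_in_disc(n, s$cx, s$cy, s$radius_inner, s$radius_outer)
      zone <- switch(s$kind, tls = "TLS", bronchi = "bronchi",
                     vessel = "vessel")
      add_cells(xy, s$kind, zone)
    }

    # capsule strip along the bottom edge
    cap_area <- config$field_width * config$capsule_depth
    n_cap <- stats::rpois(1, dens[["capsule"]] * cap_area / 1e4)
    cap_xy <- cbind(stats::runif(n_cap, 0, config$field_width),
                    stats::runif(n_cap, config$field_height - config$capsule_depth,
                                 config$field_height))
    add_cells(cap_xy, "capsule", "capsule")

    # parenchyma: uniform over the field, rejecting structure interiors
    n_par <- stats::rpois(1, dens[["parenchyma"]] *
                            config$field_width * config$field_height / 1e4)
    par_xy <- cbind(stats::runif(n_par, 0, config$field_width),
                    stats::runif(n_par, 0, config$field_height))
    keep <- rep(TRUE, n_par)
    for (j in seq_len(nrow(structures))) {
      s <- structures[j, ]
      rho <- sqrt((par_xy[, 1] - s$cx)^2 + (par_xy[, 2] - s$cy)^2)
      keep <- keep & rho > s$radius_outer
    }
    keep <- keep & par_xy[, 2] < config$field_height - config$capsule_depth
    add_cells(par_xy[keep, , drop = FALSE], "parenchyma", "parenchyma")

    xy <- do.call(rbind, xs)
    cells <- tibble::tibble(
      cell_id = sprintf("cell_%05d", seq_len(nrow(xy))),
      x_um = xy[, 1], y_um = xy[, 2],
      cell_type = unlist(types),
      true_zone = unlist(zones),
      sample = "sim_1")

    d_tls <- true_structure_distance(xy, structures, "tls")
    d_bronchi <- true_structure_distance(xy, structures, "bronchi")

    counts <- draw_counts(cells, d_tls, d_bronchi, config)

    truth <- list(
      structures = tibble::as_tibble(structures),
      cell_truth = tibble::tibble(cell_id = cells$cell_id,
                                  true_zone = cells$true_zone,
                                  d_tls_true = d_tls,
                                  d_bronchi_true = d_bronchi),
      params = list(a = config$gradient_amplitude,
                    lambda = config$gradient_scale,
                    b = config$gradient_baseline,
                    dispersion = config$dispersion))

    list(cells = cells, counts = counts,
         gene_info = config$gene_panel, truth = truth)
  })
}

# Expected-count model per gene class, then one NB/Poisson draw.
draw_counts <- function(cells, d_tls, d_bronchi, config) {
  panel <- config$gene_panel
  a <- config$gradient_amplitude
  lam <- config$gradient_scale
  b <- config$gradient_baseline
  n <- nrow(cells)
  is_cd4 <- cells$cell_type %in% CD4_TYPES
  is_apc <- cells$cell_type %in% APC_TYPES
  mu <- matrix(0, n, nrow(panel), dimnames = list(cells$cell_id, panel$gene))
  for (g in seq_len(nrow(panel))) {
    mu[, g] <- switch(
      panel$class[g],
      progenitor = ifelse(is_cd4, a * exp(-d_tls / lam) + b, b),
      effector = ifelse(is_cd4, a * exp(-d_bronchi / lam) + b, b),
      structural = ifelse(cells$cell_type == panel$marker_type[g], 20, 0.1),
      housekeeping = 5,
      ligand = ifelse(is_apc, a * exp(-d_tls / lam) + b, 0),
      receptor = ifelse(is_cd4, 5, 0.2),
      stop_tls("unknown gene class '%s'", panel$class[g]))
  }
  vals <- if (is.infinite(config$dispersion)) {
    stats::rpois(length(mu), lambda = mu)
  } else {
    stats::rnbinom(length(mu), mu = mu, size = config$dispersion)
  }
  m <- matrix(vals, n, nrow(panel), dimnames = dimnames(mu))
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

#' Generate droplet hashtag counts with ground truth
#'
#' Simulates the hashtag-oligo count matrix of a pooled droplet experiment:
#' singlets carry one high hashtag (Poisson with `signal_mean`) over
#' Poisson background on the others, doublets carry two high hashtags, and
#' empty droplets carry background only.
#'
#' @param n_hashtags number of hashtags in the pool (>= 1).
#' @param n_singlets singlet droplets per hashtag.
#' @param n_doublets doublet droplets (two distinct high hashtags).
#' @param n_empty background-only droplets.
#' @param signal_mean expected counts of a high hashtag; must exceed
#'   `background_mean`.
#' @param background_mean expected background counts (may be 0).
#' @param seed integer seed.
#' @return list with `counts` (droplets x hashtags integer matrix) and
#'   `truth` (tibble: droplet_id, label in singlet/doublet/empty, hashtag).
#' @export
generate_hashtag_counts <- function(n_hashtags, n_singlets, n_doublets = 0,
                                    n_empty = 0, signal_mean = 100,
                                    background_mean = 1, seed = 1L) {
  if (n_hashtags < 1L) stop_tls("at least one hashtag is required")
  if (signal_mean <= 0) stop_tls("signal_mean must be > 0")
  if (background_mean < 0) stop_tls("background_mean must be >= 0")
  if (signal_mean <= background_mean) {
    stop_tls("signal_mean must exceed background_mean")
  }
  n <- n_hashtags * n_singlets + n_doublets + n_empty
  if (n == 0L) stop_tls("no droplets requested")
  with_seed(seed, {
    counts <- matrix(stats::rpois(n * n_hashtags, background_mean),
                     n, n_hashtags,
                     dimnames = list(sprintf("droplet_%05d", seq_len(n)),
                                     sprintf("hashtag_%d", seq_len(n_hashtags))))
    label <- character(n); high <- character(n)
    row <- 0L
    for (h in seq_len(n_hashtags)) {
      for (i in seq_len(n_singlets)) {
        row <- row + 1L
        counts[row, h] <- stats::rpois(1, signal_mean)
        label[row] <- "singlet"; high[row] <- colnames(counts)[h]
      }
    }
    for (i in seq_len(n_doublets)) {
      row <- row + 1L
      hh <- sample.int(n_hashtags, 2L)
      counts[row, hh] <- stats::rpois(2, signal_mean)
      label[row] <- "doublet"
      high[row] <- paste(colnames(counts)[sort(hh)], collapse = "+")
    }
    if (n_empty > 0) {
      label[(row + 1L):n] <- "empty"; high[(row + 1L):n] <- NA_character_
    }
    list(counts = counts,
         truth = tibble::tibble(droplet_id = rownames(counts),
                                label = label, hashtag = high))
  })
}
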