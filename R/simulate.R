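#' Build a simulation configuration
#'
#' Constructs the full specification of a synthetic splice-junction
#' dataset: labelled cell types emitting junction reads whose partner-site
#' choice follows per-cell-type multinomial usage vectors, with optional
#' Dirichlet cell-to-cell usage variability, negative-binomial sequencing
#' depth, planted cell-type usage shifts, a hidden within-type
#' subpopulation, and pseudotime-drifting usage.
#'
#' Every gene carries `n_anchors` donor anchor sites, each with
#' `n_partners` acceptor partners at distinct genomic offsets (rank 1 =
#' nearest). Baseline usage is uniform over partners. For the first
#' `signal_genes` genes, the first half of the cell types shifts
#' probability mass `usage_shift` from the nearest to the farthest partner
#' (and the second half the other way) at anchor 1 only, so multi-anchor
#' genes have exactly one planted variable anchor among inert ones.
#'
#' Defaults describe the calibration conditions used throughout the
#' package: 4 cell types of 50 cells, 2 partners, depth mean 10 with
#' negative-binomial dispersion 2, and no cell-to-cell usage variability
#' (`dirichlet_concentration = Inf`), matching the homogeneity null under
#' which the SpliZ is approximately standard normal.
#'
#' @param n_genes Number of genes.
#' @param cell_types `data.frame` with columns `cell_type`, `tissue`,
#'   `compartment`, `n_cells`; default 4 types x 50 cells in one tissue
#'   and compartment.
#' @param n_cells Cells per type for the default `cell_types` table.
#' @param n_partners Partner acceptor sites per anchor (>= 2).
#' @param n_anchors Donor anchor sites per gene.
#' @param depth_mean,depth_dispersion Negative-binomial mean and size of
#'   per-cell-gene junctional read totals.
#' @param dirichlet_concentration Concentration of the per-cell Dirichlet
#'   perturbation around the cell-type usage vector; `Inf` means every
#'   cell uses the type vector exactly.
#' @param signal_genes Number of genes with planted cell-type usage
#'   shifts.
#' @param usage_shift Total usage difference between shifted-up and
#'   baseline partner probabilities (e.g. 0.4 turns (0.5, 0.5) into
#'   (0.3, 0.7)).
#' @param subpop Optional list `list(cell_type=, proportion=, genes=,
#'   usage_a=, usage_b=)` planting a hidden mixture inside one cell type.
#' @param trajectory Optional list `list(genes=, start=, end=,
#'   steepness=)`; when present, cells get pseudotime ~ U(0, 1) and the
#'   listed genes blend partner usage logistically from `start` to `end`.
#' @param seed Integer seed; the generator is deterministic given the
#'   config.
#' @return A list of class `simulation_config`.
#' @seealso [simulate_dataset()]
#' @export
simulation_config <- function(n_genes = 500,
                              cell_types = NULL,
                              n_cells = 50,
                              n_partners = 2,
                              n_anchors = 1,
                              depth_mean = 10,
                              depth_dispersion = 2,
                              dirichlet_concentration = Inf,
                              signal_genes = 0,
                              usage_shift = 0.4,
                              subpop = NULL,
                              trajectory = NULL,
                              seed = 1) {
  if (is.null(cell_types)) {
    cell_types <- data.frame(
      cell_type = paste0("type", seq_len(4)),
      tissue = "lung", compartment = "immune",
      n_cells = n_cells, stringsAsFactors = FALSE)
  }
  stopifnot(n_partners >= 2, n_anchors >= 1, depth_mean > 0,
            depth_dispersion > 0, dirichlet_concentration > 0,
            signal_genes <= n_genes, usage_shift >= 0, usage_shift <= 1)
  n_types <- nrow(cell_types)
  base <- rep(1 / n_partners, n_partners)
  up <- base; up[1] <- up[1] - usage_shift / 2
  up[n_partners] <- up[n_partners] + usage_shift / 2
  down <- base; down[1] <- down[1] + usage_shift / 2
  down[n_partners] <- down[n_partners] - usage_shift / 2
  up_types <- cell_types$cell_type[seq_len(ceiling(n_types / 2))]

  genes <- vector("list", n_genes)
  names(genes) <- sprintf("gene_%04d", seq_len(n_genes))
  for (g in seq_len(n_genes)) {
    anchors <- vector("list", n_anchors)
    for (a in seq_len(n_anchors)) {
      pos <- g * 100000L + (a - 1L) * 10000L + 1L
      usage <- matrix(base, nrow = n_types, ncol = n_partners,
                      byrow = TRUE,
                      dimnames = list(cell_types$cell_type, NULL))
      variable <- FALSE
      if (g <= signal_genes && a == 1L && usage_shift > 0) {
        usage[rownames(usage) %in% up_types, ] <-
          matrix(up, sum(rownames(usage) %in% up_types), n_partners,
                 byrow = TRUE)
        usage[!rownames(usage) %in% up_types, ] <-
          matrix(down, sum(!rownames(usage) %in% up_types), n_partners,
                 byrow = TRUE)
        variable <- TRUE
      }
      anchors[[a]] <- list(role = "donor", pos = pos,
                           partners = pos + 500L * seq_len(n_partners),
                           usage = usage, variable = variable)
    }
    genes[[g]] <- list(gene = names(genes)[g], chrom = "chr1",
                       strand = "+", anchors = anchors)
  }
  cfg <- list(seed = as.integer(seed), cell_types = cell_types,
              genes = genes,
              dirichlet_concentration = dirichlet_concentration,
              depth_mean = depth_mean,
              depth_dispersion = depth_dispersion,
              signal_genes = names(genes)[seq_len(signal_genes)],
              up_types = up_types,
              subpop = subpop, trajectory = trajectory)
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  for (gn in names(cfg$genes)) {
    for (an in cfg$genes[[gn]]$anchors) {
      if (length(an$partners) < 1L) {
        stop(sprintf("gene %s: anchor at %d has no partner sites",
                     gn, an$pos), call. = FALSE)
      }
      if (anyDuplicated(abs(an$partners - an$pos))) {
        stop(sprintf("gene %s: partner offsets not distinct", gn),
             call. = FALSE)
      }
      if (any(abs(rowSums(an$usage) - 1) > 1e-8) || any(an$usage < 0)) {
        stop(sprintf("gene %s: usage rows must be probability vectors",
                     gn), call. = FALSE)
      }
    }
  }
  if (!is.null(cfg$subpop)) {
    sp <- cfg$subpop
    stopifnot(sp$cell_type %in% cfg$cell_types$cell_type,
              sp$proportion > 0, sp$proportion < 1,
              all(sp$genes %in% names(cfg$genes)))
  }
  if (!is.null(cfg$trajectory)) {
    stopifnot(all(cfg$trajectory$genes %in% names(cfg$genes)))
  }
  cfg
}

#' Read a simulation configuration from YAML
#'
#' The YAML file holds the scalar arguments of [simulation_config()]
#' (plus optional `cell_types`, `subpop` and `trajectory` blocks).
#'
#' @param path Path to a YAML file.
#' @export
read_simulation_config <- function(path) {
  args <- yaml::read_yaml(path)
  if (!is.null(args$cell_types)) {
    args$cell_types <- as.data.frame(args$cell_types,
                                     stringsAsFactors = FALSE)
  }
  for (blk in c("subpop", "trajectory")) {
    if (!is.null(args[[blk]])) args[[blk]] <- as.list(args[[blk]])
  }
  do.call(simulation_config, args)
}

# Vectorised multinomial sampling: one draw per row of `prob`, totals in
# `size`, via sequential conditional binomials.
rmultinom_rows <- function(size, prob) {
  n <- length(size)
  k <- ncol(prob)
  out <- matrix(0L, n, k)
  rem <- as.integer(size)
  remp <- rep(1, n)
  for (j in seq_len(k - 1L)) {
    p <- ifelse(remp > 0, pmin(pmax(prob[, j] / remp, 0), 1), 0)
    draw <- stats::rbinom(n, rem, p)
    out[, j] <- draw
    rem <- rem - draw
    remp <- remp - prob[, j]
  }
  out[, k] <- rem
  out
}

#' Simulate a junction-count dataset with planted truth
#'
#' Draws, for each cell and gene, a total junctional read count from the
#' negative-binomial depth model, assigns reads uniformly to the gene's
#' anchors, and splits each anchor's reads over its partner sites by a
#' multinomial draw from the cell's usage vector (the cell-type vector,
#' optionally Dirichlet-perturbed, and overridden by subpopulation or
#' pseudotime-trajectory blocks). Deterministic given the config seed.
#'
#' @param config A `simulation_config`.
#' @return A list of class `spliz_sim`: `junctions` (canonical junction
#'   table), `cells` (annotations, with `pseudotime` when a trajectory
#'   block is present), and `truth` — the planted-truth record with
#'   `genes` (differential flag, up-shifted types, trajectory drift sign,
#'   subpopulation flag), `anchors` (variable-site flags) and `cells`
#'   (subpopulation membership).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  ct <- config$cell_types
  n_cells <- sum(ct$n_cells)
  type_of <- rep(ct$cell_type, ct$n_cells)
  cells <- data.frame(
    cell_id = sprintf("cell_%05d", seq_len(n_cells)),
    individual = "ind1",
    tissue = rep(ct$tissue, ct$n_cells),
    compartment = rep(ct$compartment, ct$n_cells),
    cell_type = type_of, stringsAsFactors = FALSE)

  traj <- config$trajectory
  if (!is.null(traj)) {
    cells$pseudotime <- stats::runif(n_cells)
    steep <- if (is.null(traj$steepness)) 10 else traj$steepness
    blend <- stats::plogis(steep * (cells$pseudotime - 0.5))
  }
  sp <- config$subpop
  subpop_member <- rep(NA_character_, n_cells)
  if (!is.null(sp)) {
    in_type <- type_of == sp$cell_type
    subpop_member[in_type] <- ifelse(
      stats::runif(sum(in_type)) < sp$proportion, "A", "B")
  }

  acc <- list(cell = list(), gene = list(), chrom = list(),
              strand = list(), donor = list(), acceptor = list(),
              count = list())
  conc <- config$dirichlet_concentration
  type_idx <- match(type_of, ct$cell_type)

  for (gn in names(config$genes)) {
    gspec <- config$genes[[gn]]
    depth <- stats::rnbinom(n_cells, mu = config$depth_mean,
                            size = config$depth_dispersion)
    n_anchors <- length(gspec$anchors)
    if (n_anchors == 1L) {
      anchor_reads <- matrix(depth, ncol = 1L)
    } else {
      anchor_reads <- rmultinom_rows(
        depth, matrix(1 / n_anchors, n_cells, n_anchors))
    }
    for (a in seq_len(n_anchors)) {
      aspec <- gspec$anchors[[a]]
      k <- length(aspec$partners)
      usage <- aspec$usage[type_idx, , drop = FALSE]
      if (!is.null(sp) && gn %in% sp$genes) {
        is_a <- !is.na(subpop_member) & subpop_member == "A"
        is_b <- !is.na(subpop_member) & subpop_member == "B"
        usage[is_a, ] <- matrix(sp$usage_a, sum(is_a), k, byrow = TRUE)
        usage[is_b, ] <- matrix(sp$usage_b, sum(is_b), k, byrow = TRUE)
      }
      if (!is.null(traj) && gn %in% traj$genes) {
        usage <- outer(1 - blend, traj$start) + outer(blend, traj$end)
      }
      if (is.finite(conc)) {
        w <- matrix(stats::rgamma(n_cells * k,
                                  shape = as.vector(t(usage)) * conc),
                    n_cells, k, byrow = TRUE)
        rs <- rowSums(w)
        zero <- rs == 0
        if (any(zero)) w[zero, ] <- usage[zero, , drop = FALSE]
        usage <- w / pmax(rowSums(w), .Machine$double.eps)
      }
      counts <- rmultinom_rows(anchor_reads[, a], usage)
      for (j in seq_len(k)) {
        idx <- which(counts[, j] > 0L)
        if (length(idx) == 0L) next
        i <- length(acc$cell) + 1L
        acc$cell[[i]] <- cells$cell_id[idx]
        acc$gene[[i]] <- rep(gn, length(idx))
        acc$chrom[[i]] <- rep(gspec$chrom, length(idx))
        acc$strand[[i]] <- rep(gspec$strand, length(idx))
        if (aspec$role == "donor") {
          acc$donor[[i]] <- rep(aspec$pos, length(idx))
          acc$acceptor[[i]] <- rep(aspec$partners[j], length(idx))
        } else {
          acc$donor[[i]] <- rep(aspec$partners[j], length(idx))
          acc$acceptor[[i]] <- rep(aspec$pos, length(idx))
        }
        acc$count[[i]] <- counts[idx, j]
      }
    }
  }
  junctions <- data.frame(
    cell_id = unlist(acc$cell), gene = unlist(acc$gene),
    chrom = unlist(acc$chrom), strand = unlist(acc$strand),
    donor_pos = as.integer(unlist(acc$donor)),
    acceptor_pos = as.integer(unlist(acc$acceptor)),
    count = as.integer(unlist(acc$count)), stringsAsFactors = FALSE)
  ord <- order(junctions$gene, junctions$cell_id, junctions$donor_pos,
               junctions$acceptor_pos)
  junctions <- junctions[ord, , drop = FALSE]
  rownames(junctions) <- NULL

  truth <- planted_truth(config, cells$cell_id, subpop_member)
  structure(list(junctions = junctions, cells = cells, truth = truth),
            class = "spliz_sim")
}

planted_truth <- function(config, cell_ids, subpop_member) {
  gn <- names(config$genes)
  traj_genes <- if (is.null(config$trajectory)) character(0) else
    config$trajectory$genes
  drift <- rep(0, length(gn))
  if (length(traj_genes) > 0) {
    tr <- config$trajectory
    # sign of the change in expected partner rank from start to end
    k <- length(tr$start)
    drift[gn %in% traj_genes] <- sign(sum(tr$end * seq_len(k)) -
                                        sum(tr$start * seq_len(k)))
  }
  genes <- data.frame(
    gene = gn,
    differential = gn %in% config$signal_genes,
    up_types = ifelse(gn %in% config$signal_genes,
                      paste(config$up_types, collapse = ","), ""),
    subpop = if (is.null(config$subpop)) FALSE else
      gn %in% config$subpop$genes,
    drift = drift, stringsAsFactors = FALSE)
  anchors <- do.call(rbind, lapply(config$genes, function(g) {
    data.frame(gene = g$gene, chrom = g$chrom,
               pos = vapply(g$anchors, `[[`, numeric(1), "pos"),
               role = vapply(g$anchors, `[[`, character(1), "role"),
               variable = vapply(g$anchors, `[[`, logical(1), "variable"),
               stringsAsFactors = FALSE)
  }))
  rownames(anchors) <- NULL
  list(genes = genes, anchors = anchors,
       cells = data.frame(cell_id = cell_ids, subpop = subpop_member,
                          stringsAsFactors = FALSE))
}

#' Simulate under the exchangeability null
#'
#' Identical to [simulate_dataset()] except that all cell types share one
#' usage vector per anchor (the equal-weight mean of the per-type
#' vectors) and subpopulation/trajectory blocks are dropped, realising
#' the null in which group labels are exchangeable.
#'
#' @param config A `simulation_config`.
#' @export
simulate_null_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  for (gn in names(cfg$genes)) {
    for (a in seq_along(cfg$genes[[gn]]$anchors)) {
      u <- cfg$genes[[gn]]$anchors[[a]]$usage
      pooled <- colMeans(u)
      cfg$genes[[gn]]$anchors[[a]]$usage <-
        matrix(pooled, nrow(u), ncol(u), byrow = TRUE,
               dimnames = dimnames(u))
      cfg$genes[[gn]]$anchors[[a]]$variable <- FALSE
    }
  }
  cfg$subpop <- NULL
  cfg$trajectory <- NULL
  cfg$signal_genes <- character(0)
  simulate_dataset(cfg)
}

#' Simulate a pseudotime trajectory dataset
#'
#' Requires a trajectory block in the config; cells receive pseudotime
#' uniform on (0, 1) and the listed genes blend partner usage
#' logistically between the start and end vectors.
#'
#' @param config A `simulation_config` with a `trajectory` block.
#' @export
simulate_trajectory_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(config$trajectory)) {
    stop("config has no trajectory block", call. = FALSE)
  }
  simulate_dataset(config)
}

#' Write a simulated dataset to disk
#'
#' Writes the canonical junction and cell tables plus
#' `planted_truth.json`.
#'
#' @param sim A `spliz_sim` object.
#' @param dir Output directory (created if needed).
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "spliz_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_junction_table(sim$junctions, file.path(dir, "junctions.tsv"))
  write_cell_annotations(sim$cells, file.path(dir, "cells.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "planted_truth.json"),
                       dataframe = "columns", na = "null")
  invisible(dir)
}

#' @export
print.spliz_sim <- function(x, ...) {
  cat(sprintf(
    "Simulated junction dataset: %d cells, %d genes, %d junction records\n",
    nrow(x$cells), length(unique(x$junctions$gene)), nrow(x$junctions)))
  cat(sprintf("  planted differential genes: %d\n",
              sum(x$truth$genes$differential)))
  invisible(x)
}
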