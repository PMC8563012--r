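#' Build distance-rank models for anchor splice sites
#'
#' For every splice site with at least two observed partner sites in the
#' dataset — donors anchoring over their acceptors and acceptors
#' anchoring over their donors — partners are ranked by unsigned genomic
#' distance from the anchor (rank 1 = nearest; strand never flips ranks),
#' and the population mean and standard deviation of the rank are
#' computed over all reads at the anchor, each read weighted equally.
#' Anchors with a single partner or zero rank variance carry no model and
#' are excluded (a count is logged).
#'
#' If two partners on opposite sides of an anchor were ever exactly
#' equidistant, ties are broken by ascending coordinate (logged).
#'
#' @param junctions A validated junction table.
#' @return A `data.frame` of class `rank_model_set`, one row per
#'   (anchor, partner): `gene`, `chrom`, `anchor_role`, `anchor_pos`,
#'   `partner_pos`, `distance`, `rank`, `count`, and the anchor-level
#'   `mu`, `sigma`, `anchor_reads`, `n_partners`.
#' @seealso [spliz()], [read_residual()]
#' @export
build_rank_models <- function(junctions) {
  stopifnot(nrow(junctions) > 0)
  long <- rbind(
    data.frame(gene = junctions$gene, chrom = junctions$chrom,
               anchor_role = "donor", anchor_pos = junctions$donor_pos,
               partner_pos = junctions$acceptor_pos,
               count = junctions$count, stringsAsFactors = FALSE),
    data.frame(gene = junctions$gene, chrom = junctions$chrom,
               anchor_role = "acceptor", anchor_pos = junctions$acceptor_pos,
               partner_pos = junctions$donor_pos,
               count = junctions$count, stringsAsFactors = FALSE))
  key <- paste(long$gene, long$anchor_role, long$anchor_pos,
               long$partner_pos, sep = "\r")
  agg_count <- rowsum(long$count, key)
  first <- long[!duplicated(key), , drop = FALSE]
  first$count <- agg_count[match(unique(key), rownames(agg_count)), 1]
  first$distance <- abs(first$partner_pos - first$anchor_pos)

  anchor_key <- paste(first$gene, first$anchor_role, first$anchor_pos,
                      sep = "\r")
  pieces <- split(first, anchor_key)
  n_excluded <- 0L
  ties_seen <- FALSE
  models <- lapply(pieces, function(p) {
    if (nrow(p) < 2L) {
      n_excluded <<- n_excluded + 1L
      return(NULL)
    }
    if (anyDuplicated(p$distance)) ties_seen <<- TRUE
    p <- p[order(p$distance, p$partner_pos), , drop = FALSE]
    p$rank <- seq_len(nrow(p))
    w <- p$count / sum(p$count)
    p$mu <- sum(w * p$rank)
    p$sigma <- sqrt(sum(w * (p$rank - p$mu[1])^2))
    if (p$sigma[1] <= 0) {
      n_excluded <<- n_excluded + 1L
      return(NULL)
    }
    p$anchor_reads <- sum(p$count)
    p$n_partners <- nrow(p)
    p
  })
  if (ties_seen) {
    message("build_rank_models: equidistant partners broken by coordinate")
  }
  if (n_excluded > 0L) {
    message(sprintf("build_rank_models: %d anchor(s) without a model",
                    n_excluded))
  }
  out <- do.call(rbind, models)
  if (is.null(out)) {
    out <- first[0, ]
    out$rank <- integer(0); out$mu <- numeric(0); out$sigma <- numeric(0)
    out$anchor_reads <- numeric(0); out$n_partners <- integer(0)
  }
  rownames(out) <- NULL
  class(out) <- c("rank_model_set", "data.frame")
  out
}

#' Residual of a partner rank under an anchor's rank model
#'
#' Converts an observed partner rank into the mean-zero, variance-one
#' residual `(rank - mu) / sigma` of the anchor's population rank
#' distribution: over all reads at the anchor the residuals have mean 0
#' and variance 1 exactly.
#'
#' @param rank Observed partner rank(s).
#' @param model One anchor's rows of a `rank_model_set` (a single `mu`
#'   and `sigma`).
#' @export
read_residual <- function(rank, model) {
  mu <- unique(model$mu)
  sigma <- unique(model$sigma)
  stopifnot(length(mu) == 1L, length(sigma) == 1L, sigma > 0)
  (rank - mu) / sigma
}

# Match junction records to rank models in both anchor directions and
# return one row per (record, modelled anchor) incidence with its
# residual. Workhorse shared by spliz() and the residual matrix.
residual_incidences <- function(junctions, models) {
  mk <- paste(models$gene, models$anchor_role, models$anchor_pos,
              models$partner_pos, sep = "\r")
  resid <- (models$rank - models$mu) / models$sigma
  pieces <- lapply(c("donor", "acceptor"), function(role) {
    if (role == "donor") {
      jk <- paste(junctions$gene, "donor", junctions$donor_pos,
                  junctions$acceptor_pos, sep = "\r")
    } else {
      jk <- paste(junctions$gene, "acceptor", junctions$acceptor_pos,
                  junctions$donor_pos, sep = "\r")
    }
    idx <- match(jk, mk)
    hit <- !is.na(idx)
    data.frame(cell_id = junctions$cell_id[hit],
               gene = junctions$gene[hit],
               anchor_role = rep(role, sum(hit)),
               anchor_pos = if (role == "donor") junctions$donor_pos[hit]
                            else junctions$acceptor_pos[hit],
               rank = models$rank[idx[hit]],
               residual = resid[idx[hit]],
               count = junctions$count[hit], stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

#' Fit the SpliZ to a junction count table
#'
#' The SpliZ is a per-cell, per-gene z-score of splice-partner choice.
#' It is computed in three steps: (1) rank each anchor site's partners by
#' genomic distance ([build_rank_models()]); (2) convert each read's rank
#' to a mean-zero, variance-one residual of the anchor's population rank
#' distribution; (3) for each cell and gene, sum one residual per
#' (read, modelled-anchor) incidence — a read contributes at its donor
#' anchor and at its acceptor anchor whenever each carries a model — and
#' scale by the square root of the number of residuals. Positive scores
#' mean the cell splices to farther-than-average partners (longer
#' introns), negative scores to nearer ones.
#'
#' A score is assigned only to computable cell-gene pairs: those with at
#' least `min_reads` junctional reads for the gene in the cell.
#'
#' @param junctions A junction table (see [read_junction_table()] for the
#'   format; validated on entry).
#' @param min_reads Minimum junctional reads per cell-gene pair (default
#'   5).
#' @param cells Optional cell annotation table, stored for downstream
#'   analyses.
#' @return An object of class `spliz`: list with `scores` (`data.frame`
#'   of `cell_id`, `gene`, `n_reads`, `n_residuals`, `spliz`,
#'   `computable`), `models` (the `rank_model_set`), `junctions`,
#'   `cells`, `min_reads`.
#' @examples
#' jt <- data.frame(
#'   cell_id = c("c1", "c1", "c2"), gene = "g",
#'   chrom = "chr1", strand = "+", donor_pos = 100L,
#'   acceptor_pos = c(500L, 900L, 900L), count = c(3L, 2L, 5L))
#' fit <- spliz(jt, min_reads = 5)
#' fit$scores
#' @export
spliz <- function(junctions, min_reads = 5, cells = NULL) {
  junctions <- validate_junction_table(junctions)
  models <- build_rank_models(junctions)
  inc <- residual_incidences(junctions, models)

  pair_key <- paste(junctions$cell_id, junctions$gene, sep = "\r")
  n_reads <- rowsum(junctions$count, pair_key)
  pairs <- data.frame(
    cell_id = junctions$cell_id[!duplicated(pair_key)],
    gene = junctions$gene[!duplicated(pair_key)],
    stringsAsFactors = FALSE)
  upair <- unique(pair_key)
  pairs$n_reads <- n_reads[match(upair, rownames(n_reads)), 1]

  if (nrow(inc) > 0) {
    ik <- paste(inc$cell_id, inc$gene, sep = "\r")
    ssum <- rowsum(inc$residual * inc$count, ik)
    scnt <- rowsum(inc$count, ik)
    m <- match(upair, rownames(ssum))
    pairs$n_residuals <- ifelse(is.na(m), 0L, scnt[m, 1])
    pairs$sum_resid <- ifelse(is.na(m), 0, ssum[m, 1])
  } else {
    pairs$n_residuals <- 0L
    pairs$sum_resid <- 0
  }
  pairs$computable <- pairs$n_reads >= min_reads & pairs$n_residuals > 0
  pairs$spliz <- ifelse(pairs$computable,
                        pairs$sum_resid / sqrt(pairs$n_residuals), NA_real_)
  no_model <- unique(pairs$gene[!pairs$gene %in% models$gene])
  if (length(no_model) > 0) {
    message(sprintf("spliz: %d gene(s) with no modelled anchors",
                    length(no_model)))
  }
  scores <- pairs[order(pairs$gene, pairs$cell_id),
                  c("cell_id", "gene", "n_reads", "n_residuals",
                    "spliz", "computable")]
  rownames(scores) <- NULL
  structure(list(scores = scores, models = models, junctions = junctions,
                 cells = cells, min_reads = min_reads,
                 call = match.call()),
            class = "spliz")
}

#' @export
print.spliz <- function(x, ...) {
  cat("SpliZ fit\n")
  cat(sprintf("  %d cells, %d genes, %d cell-gene pairs (%d computable, min_reads = %d)\n",
              length(unique(x$scores$cell_id)),
              length(unique(x$scores$gene)), nrow(x$scores),
              sum(x$scores$computable), x$min_reads))
  cat(sprintf("  %d modelled anchor sites\n",
              nrow(unique(x$models[, c("gene", "anchor_role",
                                       "anchor_pos")]))))
  invisible(x)
}

#' @export
summary.spliz <- function(object, ...) {
  s <- object$scores$spliz[object$scores$computable]
  out <- list(n_computable = length(s), mean = mean(s), var = stats::var(s),
              quantiles = stats::quantile(s, c(0, .25, .5, .75, 1)),
              tail_frac = mean(abs(s) > 1.96))
  class(out) <- "summary.spliz"
  out
}

#' @export
print.summary.spliz <- function(x, ...) {
  cat(sprintf("SpliZ scores over %d computable cell-gene pairs\n",
              x$n_computable))
  cat(sprintf("  mean %.4f, variance %.4f, |z|>1.96 fraction %.4f\n",
              x$mean, x$var, x$tail_frac))
  print(round(x$quantiles, 3))
  invisible(x)
}

#' @export
residuals.spliz <- function(object, ...) {
  residual_incidences(object$junctions, object$models)
}

#' Count-weighted average partner rank per cell and anchor
#'
#' The dot-plot summary statistic: for each cell and modelled anchor
#' site, the average partner rank weighted by the number of reads
#' aligning to each partner in that cell. Lies in `[1, K]` for an anchor
#' with K partners.
#'
#' @param junctions Junction table (or a `spliz` fit, from which the
#'   table and models are taken).
#' @param models A `rank_model_set`; ignored when `junctions` is a fit.
#' @return `data.frame`: `cell_id`, `gene`, `anchor_role`, `anchor_pos`,
#'   `n_reads`, `avg_rank`.
#' @export
weighted_average_rank <- function(junctions, models = NULL) {
  if (inherits(junctions, "spliz")) {
    models <- junctions$models
    junctions <- junctions$junctions
  }
  stopifnot(!is.null(models))
  inc <- residual_incidences(junctions, models)
  if (nrow(inc) == 0) {
    return(data.frame(cell_id = character(0), gene = character(0),
                      anchor_role = character(0), anchor_pos = integer(0),
                      n_reads = integer(0), avg_rank = numeric(0)))
  }
  key <- paste(inc$cell_id, inc$gene, inc$anchor_role, inc$anchor_pos,
               sep = "\r")
  wsum <- rowsum(inc$rank * inc$count, key)
  csum <- rowsum(inc$count, key)
  keep <- !duplicated(key)
  out <- data.frame(cell_id = inc$cell_id[keep], gene = inc$gene[keep],
                    anchor_role = inc$anchor_role[keep],
                    anchor_pos = inc$anchor_pos[keep],
                    stringsAsFactors = FALSE)
  m <- match(key[keep], rownames(wsum))
  out$n_reads <- csum[m, 1]
  out$avg_rank <- wsum[m, 1] / csum[m, 1]
  out[order(out$gene, out$cell_id, out$anchor_pos), ]
}
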