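#' Screen genes for pseudotime-correlated splicing
#'
#' For each gene with computable SpliZ in at least `min_cells` cells
#' carrying pseudotime, computes Spearman's correlation between SpliZ
#' and pseudotime (average ranks for ties; p-value by the
#' t-approximation) and applies Bonferroni correction over the tested
#' genes. A gene is significant when `|rho| > rho_threshold` and the
#' adjusted p-value is below `alpha`.
#'
#' @param fit A `spliz` object (or a `data.frame` with `cell_id`,
#'   `gene`, `score`).
#' @param cells Cell annotations with a `pseudotime` column; defaults to
#'   those stored in the fit.
#' @param min_cells Minimum computable cells per tested gene (default
#'   100).
#' @param rho_threshold Correlation magnitude gate (default 0.1).
#' @param alpha Bonferroni-adjusted p-value gate (default 0.05).
#' @return `data.frame` of class `spliz_trajectory`: `gene`, `n_cells`,
#'   `rho`, `p`, `p_bonferroni`, `significant`.
#' @export
trajectory_screen <- function(fit, cells = NULL, min_cells = 100,
                              rho_threshold = 0.1, alpha = 0.05) {
  if (inherits(fit, "spliz")) {
    if (is.null(cells)) cells <- fit$cells
    sc <- fit$scores[fit$scores$computable, , drop = FALSE]
    scores <- data.frame(cell_id = sc$cell_id, gene = sc$gene,
                         score = sc$spliz, stringsAsFactors = FALSE)
  } else {
    scores <- fit
  }
  stopifnot(!is.null(cells), "pseudotime" %in% names(cells))
  pt <- cells$pseudotime[match(scores$cell_id, cells$cell_id)]
  keep <- !is.na(pt)
  scores <- scores[keep, , drop = FALSE]
  pt <- pt[keep]

  rows <- lapply(split(seq_len(nrow(scores)), scores$gene), function(ix) {
    n <- length(ix)
    if (n < min_cells) return(NULL)
    v <- scores$score[ix]
    t <- pt[ix]
    if (stats::sd(v) == 0 || stats::sd(t) == 0) {
      message(sprintf("trajectory_screen: gene %s skipped (constant values)",
                      scores$gene[ix[1]]))
      return(NULL)
    }
    ct <- suppressWarnings(stats::cor.test(v, t, method = "spearman",
                                           exact = FALSE))
    data.frame(gene = scores$gene[ix[1]], n_cells = n,
               rho = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0) {
    stop("no gene passes the cell-count gate", call. = FALSE)
  }
  rows$p_bonferroni <- pmin(1, rows$p * nrow(rows))
  rows$significant <- abs(rows$rho) > rho_threshold &
    rows$p_bonferroni < alpha
  rownames(rows) <- NULL
  class(rows) <- c("spliz_trajectory", "data.frame")
  rows
}

#' Pseudotime-quantile bin summaries
#'
#' Partitions cells into `Q` equal-count bins by pseudotime and reports
#' per-bin means of the SpliZ (and, when supplied, of the weighted
#' average partner rank) — the summaries behind dot/box-plot displays of
#' splicing drift along a trajectory.
#'
#' @param values Per-cell SpliZ values.
#' @param pseudotime Per-cell pseudotime, same length.
#' @param Q Number of quantile bins (>= 2).
#' @param ranks Optional per-cell weighted average ranks.
#' @return `data.frame`: `bin`, `n`, `mean_pseudotime`, `mean_spliz`,
#'   and `mean_rank` when `ranks` given.
#' @export
quantile_bin_summary <- function(values, pseudotime, Q, ranks = NULL) {
  stopifnot(length(values) == length(pseudotime))
  if (Q < 2) stop("Q must be at least 2", call. = FALSE)
  n <- length(values)
  if (n < Q) stop("fewer cells than bins", call. = FALSE)
  bin <- ceiling(rank(pseudotime, ties.method = "first") * Q / n)
  out <- data.frame(
    bin = sort(unique(bin)),
    n = as.integer(table(bin)),
    mean_pseudotime = vapply(split(pseudotime, bin), mean, numeric(1)),
    mean_spliz = vapply(split(values, bin), mean, numeric(1)))
  if (!is.null(ranks)) {
    out$mean_rank <- vapply(split(ranks, bin), mean, numeric(1))
  }
  rownames(out) <- NULL
  out
}
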