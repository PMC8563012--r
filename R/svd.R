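#' Cell-by-anchor residual matrix for one gene
#'
#' Rows are the gene's computable cells, columns its modelled anchor
#' sites (ascending coordinate; donor before acceptor on ties). Each
#' entry is the summed residual of the cell's reads at that anchor
#' (count-weighted), and 0 — the population-mean contribution — where
#' the cell has no reads there. Summing rather than averaging weights a
#' cell's evidence by its read support, so anchors whose usage genuinely
#' varies across cells dominate the decomposition instead of the
#' sampling noise of shallowly covered anchors. Columns are
#' mean-centered before decomposition; the centering vector is
#' recorded.
#'
#' @param fit A `spliz` object.
#' @param gene Gene identifier.
#' @return List of class `residual_matrix`: `matrix` (centered),
#'   `centers`, `anchors` (`data.frame` of the column anchors), `gene`,
#'   `cells` (row names).
#' @export
build_residual_matrix <- function(fit, gene) {
  stopifnot(inherits(fit, "spliz"))
  sc <- fit$scores
  cells <- sc$cell_id[sc$gene == gene & sc$computable]
  anchors <- unique(fit$models[fit$models$gene == gene,
                               c("gene", "chrom", "anchor_role",
                                 "anchor_pos")])
  if (nrow(anchors) == 0L) {
    stop(sprintf("gene %s has no modelled anchors", gene), call. = FALSE)
  }
  if (length(cells) < 2L) {
    stop(sprintf("gene %s has fewer than 2 computable cells", gene),
         call. = FALSE)
  }
  anchors <- anchors[order(anchors$anchor_pos,
                           match(anchors$anchor_role,
                                 c("donor", "acceptor"))), ]
  inc <- residual_incidences(
    fit$junctions[fit$junctions$gene == gene, , drop = FALSE], fit$models)
  inc <- inc[inc$cell_id %in% cells, , drop = FALSE]
  acol <- paste(inc$anchor_role, inc$anchor_pos)
  cols <- paste(anchors$anchor_role, anchors$anchor_pos)
  key <- paste(inc$cell_id, acol, sep = "\r")
  msum <- rowsum(inc$residual * inc$count, key)
  mat <- matrix(0, length(cells), nrow(anchors),
                dimnames = list(cells, cols))
  ki <- match(rownames(msum), key)
  mat[cbind(match(inc$cell_id[ki], cells), match(acol[ki], cols))] <-
    msum[, 1]
  centers <- colMeans(mat)
  structure(list(matrix = sweep(mat, 2, centers), centers = centers,
                 anchors = anchors, gene = gene, cells = cells),
            class = "residual_matrix")
}

#' SpliZVD scores and first singular vector
#'
#' Decomposes the centered residual matrix by SVD. The SpliZVD of a cell
#' is the projection of its row onto the first right singular vector,
#' whose sign is fixed so that its largest-magnitude loading is positive
#' (reproducible across linear-algebra backends).
#'
#' @param rm A `residual_matrix`.
#' @return List: `scores` (named per-cell SpliZVD values), `loadings`
#'   (named first-singular-vector components per anchor), `d` (singular
#'   values), `anchors`, `gene`.
#' @export
compute_splizvd <- function(rm) {
  stopifnot(inherits(rm, "residual_matrix"))
  x <- rm$matrix
  if (all(x == 0)) {
    stop(sprintf("gene %s: residual matrix is all zero", rm$gene),
         call. = FALSE)
  }
  dec <- svd(x)
  v <- dec$v[, 1]
  imax <- which.max(abs(v))
  if (v[imax] < 0) v <- -v
  scores <- drop(x %*% v)
  names(scores) <- rownames(x)
  names(v) <- colnames(x)
  list(scores = scores, loadings = v, d = dec$d, anchors = rm$anchors,
       gene = rm$gene)
}

#' SpliZsites: the anchors loading the first singular vector most
#'
#' The up-to-three anchor sites with the largest-magnitude loadings on
#' the sign-fixed first right singular vector, in descending `|loading|`
#' order (ties broken by ascending coordinate).
#'
#' @param vd Output of [compute_splizvd()].
#' @param n_sites Maximum number of sites (default 3).
#' @return `data.frame`: `gene`, `chrom`, `pos`, `role`, `loading`,
#'   `site_rank`.
#' @export
call_splizsites <- function(vd, n_sites = 3) {
  anchors <- vd$anchors
  ord <- order(-abs(vd$loadings), anchors$anchor_pos)
  take <- ord[seq_len(min(n_sites, length(ord)))]
  data.frame(gene = vd$gene, chrom = anchors$chrom[take],
             pos = anchors$anchor_pos[take],
             role = anchors$anchor_role[take],
             loading = unname(vd$loadings[take]),
             site_rank = seq_along(take), stringsAsFactors = FALSE)
}

#' SpliZVD scores and SpliZsites across genes
#'
#' Convenience drivers looping [build_residual_matrix()] and
#' [compute_splizvd()] over genes. Genes whose residual matrix cannot be
#' built (fewer than 2 computable cells, no modelled anchors, or an
#' all-zero matrix) are skipped with a log message.
#'
#' @param fit A `spliz` object.
#' @param genes Genes to process; default all genes with modelled
#'   anchors.
#' @return For `splizvd_scores`, a `data.frame` `cell_id`, `gene`,
#'   `splizvd`; for `spliz_sites`, the row-bound SpliZsite table.
#' @export
splizvd_scores <- function(fit, genes = NULL) {
  if (is.null(genes)) genes <- unique(fit$models$gene)
  out <- lapply(genes, function(g) {
    vd <- tryCatch(compute_splizvd(build_residual_matrix(fit, g)),
                   error = function(e) NULL)
    if (is.null(vd)) return(NULL)
    data.frame(cell_id = names(vd$scores), gene = g,
               splizvd = unname(vd$scores), stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(out, is.null, logical(1)))
  if (skipped > 0) {
    message(sprintf("splizvd_scores: skipped %d gene(s)", skipped))
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(cell_id = character(0), gene = character(0),
                      splizvd = numeric(0))
  }
  rownames(res) <- NULL
  res
}

#' @rdname splizvd_scores
#' @param n_sites Maximum SpliZsites per gene.
#' @export
spliz_sites <- function(fit, genes = NULL, n_sites = 3) {
  if (is.null(genes)) genes <- unique(fit$models$gene)
  out <- lapply(genes, function(g) {
    vd <- tryCatch(compute_splizvd(build_residual_matrix(fit, g)),
                   error = function(e) NULL)
    if (is.null(vd)) return(NULL)
    call_splizsites(vd, n_sites)
  })
  skipped <- sum(vapply(out, is.null, logical(1)))
  if (skipped > 0) {
    message(sprintf("spliz_sites: skipped %d gene(s)", skipped))
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(gene = character(0), chrom = character(0),
                      pos = integer(0), role = character(0),
                      loading = numeric(0), site_rank = integer(0))
  }
  rownames(res) <- NULL
  res
}
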