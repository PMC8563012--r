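# All injective assignments of clusters to labels, as a list of integer
# vectors (label index per cluster). Exact optimum for the small k used
# here (k <= ~5).
injective_assignments <- function(k, n_labels) {
  stopifnot(k <= n_labels)
  out <- list()
  recurse <- function(chosen, remaining) {
    if (length(chosen) == k) {
      out[[length(out) + 1L]] <<- chosen
      return(invisible())
    }
    for (r in remaining) {
      recurse(c(chosen, r), setdiff(remaining, r))
    }
  }
  recurse(integer(0), seq_len(n_labels))
  out
}

#' Compartment classification from a small SpliZ gene panel
#'
#' Clusters cells by k-means on the SpliZ values of a small gene panel
#' (e.g. two genes), then assigns each cluster to one compartment label
#' so as to minimise classification error (exact minimum-cost matching
#' over injective cluster-to-label assignments), and reports per-label
#' and overall accuracy.
#'
#' Cells are restricted to those with computable SpliZ for ALL panel
#' genes and whose compartment is in `labels`.
#'
#' @param fit A `spliz` object.
#' @param cells Cell annotations; defaults to those stored in the fit.
#' @param genes Panel gene identifiers (columns of the feature matrix).
#' @param labels Compartment labels to classify (default immune,
#'   epithelial, stromal).
#' @param k Number of k-means clusters (default 3).
#' @param seed Seed for the k-means restarts.
#' @param nstart k-means restarts (default 10).
#' @return List of class `compartment_classification`: `n_cells`,
#'   `cluster_to_label`, `confusion` (clusters x labels),
#'   `per_label_accuracy`, `overall_accuracy`, `clusters` (named per
#'   cell).
#' @export
kmeans_compartment_classify <- function(fit, cells = NULL, genes,
                                        labels = c("immune", "epithelial",
                                                   "stromal"),
                                        k = 3, seed = 1, nstart = 10) {
  if (is.null(cells)) cells <- fit$cells
  stopifnot(!is.null(cells), length(genes) >= 1)
  if (k > length(labels)) {
    warning("more clusters than labels; assignment cannot be a bijection")
  }
  sc <- fit$scores[fit$scores$computable & fit$scores$gene %in% genes, ]
  wide <- stats::reshape(sc[, c("cell_id", "gene", "spliz")],
                         idvar = "cell_id", timevar = "gene",
                         direction = "wide")
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  comp <- cells$compartment[match(wide$cell_id, cells$cell_id)]
  keep <- !is.na(comp) & comp %in% labels
  x <- as.matrix(wide[keep, -1, drop = FALSE])
  rownames(x) <- wide$cell_id[keep]
  comp <- comp[keep]
  if (nrow(x) < k) stop("fewer cells than clusters", call. = FALSE)

  if (nrow(unique(x)) < k) {
    # degenerate geometry: force a single cluster
    clusters <- rep(1L, nrow(x))
  } else {
    set.seed(seed)
    clusters <- stats::kmeans(x, centers = k, nstart = nstart)$cluster
  }
  confusion <- table(cluster = clusters, label = factor(comp,
                                                        levels = labels))
  k_eff <- nrow(confusion)
  assigns <- injective_assignments(min(k_eff, length(labels)),
                                   length(labels))
  correct <- vapply(assigns, function(a) {
    sum(confusion[cbind(seq_len(length(a)), a)])
  }, numeric(1))
  best <- assigns[[which.max(correct)]]
  cluster_to_label <- stats::setNames(labels[best],
                                      rownames(confusion)[seq_along(best)])
  predicted <- cluster_to_label[as.character(clusters)]
  per_label <- vapply(labels, function(l) {
    tot <- sum(comp == l)
    if (tot == 0) return(NA_real_)
    sum(predicted == l & comp == l) / tot
  }, numeric(1))
  structure(list(n_cells = nrow(x), cluster_to_label = cluster_to_label,
                 confusion = confusion, per_label_accuracy = per_label,
                 overall_accuracy = mean(predicted == comp),
                 clusters = stats::setNames(clusters, rownames(x))),
            class = "compartment_classification")
}

#' @export
print.compartment_classification <- function(x, ...) {
  cat(sprintf(
    "Compartment classification over %d cells: overall accuracy %.3f\n",
    x$n_cells, x$overall_accuracy))
  acc <- x$per_label_accuracy
  for (l in names(acc)) {
    cat(sprintf("  %-12s %.3f\n", l, acc[l]))
  }
  invisible(x)
}
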