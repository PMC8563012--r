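#' Group labels for differential splicing
#'
#' Cell-type groups are defined by tissue, compartment and annotated cell
#' type jointly (e.g. "lung immune macrophage"); compartment groups pool
#' each compartment across tissues.
#'
#' @param cells Cell annotation table.
#' @param grouping `"cell_type"` or `"compartment"`.
#' @return Character vector of group labels, one per row of `cells`.
#' @export
group_labels <- function(cells, grouping = c("cell_type", "compartment")) {
  grouping <- match.arg(grouping)
  if (grouping == "cell_type") {
    paste(cells$tissue, cells$compartment, cells$cell_type)
  } else {
    cells$compartment
  }
}

#' Per-gene group medians of splicing scores
#'
#' Medians are taken over computable cells only; a group is eligible for
#' a gene only when it has at least `min_cells` computable cells. Genes
#' with fewer than two eligible groups are excluded from testing (their
#' rows simply do not appear).
#'
#' @param scores `data.frame` with columns `cell_id`, `gene`, `score`
#'   (only computable scores; `NA` rows are dropped).
#' @param cells Cell annotation table covering the scored cells.
#' @param grouping Passed to [group_labels()].
#' @param min_cells Minimum computable cells per eligible group.
#' @return `data.frame`: `gene`, `group`, `tissue`, `compartment`,
#'   `n_cells`, `median`.
#' @export
group_medians <- function(scores, cells,
                          grouping = c("cell_type", "compartment"),
                          min_cells = 10) {
  grouping <- match.arg(grouping)
  scores <- scores[!is.na(scores$score), , drop = FALSE]
  idx <- match(scores$cell_id, cells$cell_id)
  if (anyNA(idx)) stop("scored cells missing from annotations",
                       call. = FALSE)
  grp <- group_labels(cells, grouping)[idx]
  key <- paste(scores$gene, grp, sep = "\r")
  med <- vapply(split(scores$score, key), stats::median, numeric(1))
  n <- vapply(split(scores$score, key), length, integer(1))
  keep <- !duplicated(key)
  out <- data.frame(gene = scores$gene[keep], group = grp[keep],
                    tissue = cells$tissue[idx][keep],
                    compartment = cells$compartment[idx][keep],
                    stringsAsFactors = FALSE)
  m <- match(key[keep], names(med))
  out$n_cells <- n[m]
  out$median <- unname(med[m])
  out <- out[out$n_cells >= min_cells, , drop = FALSE]
  eligible <- table(out$gene)
  out <- out[out$gene %in% names(eligible)[eligible >= 2], , drop = FALSE]
  out <- out[order(out$gene, out$group), ]
  rownames(out) <- NULL
  out
}

#' Analytic screening p-value from group medians
#'
#' Under the homogeneity null the SpliZ is approximately standard normal
#' per cell, so the median of an n-cell group is asymptotically
#' N(0, pi/(2n)). Each group median gets a two-sided normal p-value; the
#' gene-level p is the Sidak combination of the minimum group p across G
#' groups, `1 - (1 - p_min)^G`. This cheap analytic p serves as a 0.05
#' screen; permutation then refines it.
#'
#' @param medians,sizes Numeric vectors of eligible group medians and
#'   their cell counts.
#' @return The gene-level screening p-value.
#' @export
median_null_pvalue <- function(medians, sizes) {
  stopifnot(length(medians) == length(sizes), length(medians) >= 2,
            all(sizes >= 1))
  z <- medians / sqrt(pi / (2 * sizes))
  p <- 2 * stats::pnorm(-abs(z))
  1 - (1 - min(p))^length(p)
}

#' Permutation refinement of a gene's differential p-value
#'
#' Permutes group labels across the gene's computable cells and
#' recomputes the gene-level statistic each time;
#' `p = (1 + #{permuted at least as extreme}) / (1 + B)`. The ordering
#' statistic is the largest standardised group median `max_g
#' |median_g| / sqrt(pi / (2 n_g))` — strictly monotone in the Sidak
#' min-p (group count is fixed), but free of the floating-point
#' underflow that ties extreme p-values at zero. Group sizes (and hence
#' eligibility) are invariant under label permutation. Early stopping is
#' allowed once `early_stop` exceedances are seen, preserving an
#' unbiased conservative estimate where precision is no longer needed.
#'
#' @param values Scores of the gene's computable cells.
#' @param labels Group label per value.
#' @param B Number of permutations (default 1000; below 100 a warning).
#' @param seed Integer seed; results are deterministic given it.
#' @param min_cells Minimum cells per eligible group.
#' @param early_stop Exceedance count at which to stop early (set `Inf`
#'   to disable).
#' @return The permutation p-value (floor `1/(B+1)`).
#' @export
permutation_refine <- function(values, labels, B = 1000, seed = 1,
                               min_cells = 10, early_stop = 50) {
  if (B < 100) warning("permutation_refine: B < 100 gives coarse p-values")
  idx <- split(seq_along(values), labels)
  idx <- idx[vapply(idx, length, integer(1)) >= min_cells]
  stopifnot(length(idx) >= 2)
  null_sd <- sqrt(pi / (2 * vapply(idx, length, integer(1))))
  stat <- function(v) {
    max(abs(vapply(idx, function(i) stats::median(v[i]), numeric(1))) /
          null_sd)
  }
  observed <- stat(values)
  set.seed(seed)
  exceed <- 0L
  b_done <- 0L
  for (b in seq_len(B)) {
    b_done <- b
    if (stat(values[sample.int(length(values))]) >= observed) {
      exceed <- exceed + 1L
      if (exceed >= early_stop) break
    }
  }
  (1 + exceed) / (1 + b_done)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false discovery rate control with monotonicity
#' enforcement, with input validation.
#'
#' @param p Finite p-values in `[0, 1]`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be finite and in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Call differentially spliced genes across cell types or compartments
#'
#' For each gene with at least two eligible groups (>= `min_cells`
#' computable cells each), computes group medians, the analytic
#' screening p-value ([median_null_pvalue()]), permutation refinement
#' for genes passing the 0.05 screen ([permutation_refine()]), and
#' Benjamini-Hochberg adjustment across all tested genes. Effect size is
#' the largest-magnitude group median. A gene is called significant when
#' adjusted p < `alpha`, effect size exceeds `effect_threshold` (0.5 for
#' SpliZ, 3.5 for SpliZVD), and the mode-specific consistency gate
#' passes: in cell-type mode some tissue+compartment context must
#' contain two eligible groups whose medians differ by at least
#' `context_delta`; in compartment mode the extreme compartment's
#' per-tissue medians (tissues with >= `min_cells` computable cells)
#' must all share the pooled sign.
#'
#' @param fit A `spliz` object.
#' @param cells Cell annotations; defaults to those stored in the fit.
#' @param grouping `"cell_type"` or `"compartment"`.
#' @param stat `"spliz"` or `"splizvd"`.
#' @param min_cells Minimum computable cells per eligible group.
#' @param B,seed Permutation count and seed.
#' @param alpha Adjusted p-value cutoff (default 0.05).
#' @param effect_threshold Effect-size gate; default 0.5 (SpliZ) or 3.5
#'   (SpliZVD).
#' @param context_delta Required within-tissue-compartment median
#'   difference in cell-type mode (default 0.5).
#' @return Object of class `spliz_diff`: list with `results` (per-gene
#'   `data.frame`), `group_medians`, and the parameters.
#' @export
spliz_differential <- function(fit, cells = NULL,
                               grouping = c("cell_type", "compartment"),
                               stat = c("spliz", "splizvd"),
                               min_cells = 10, B = 1000, seed = 1,
                               alpha = 0.05, effect_threshold = NULL,
                               context_delta = 0.5) {
  grouping <- match.arg(grouping)
  stat <- match.arg(stat)
  if (is.null(cells)) cells <- fit$cells
  stopifnot(!is.null(cells))
  if (is.null(effect_threshold)) {
    effect_threshold <- if (stat == "spliz") 0.5 else 3.5
  }
  scores <- if (stat == "spliz") {
    sc <- fit$scores[fit$scores$computable, , drop = FALSE]
    data.frame(cell_id = sc$cell_id, gene = sc$gene, score = sc$spliz,
               stringsAsFactors = FALSE)
  } else {
    sv <- splizvd_scores(fit)
    data.frame(cell_id = sv$cell_id, gene = sv$gene, score = sv$splizvd,
               stringsAsFactors = FALSE)
  }
  gm <- group_medians(scores, cells, grouping, min_cells)
  genes <- unique(gm$gene)
  if (length(genes) == 0) {
    stop("no gene has two eligible groups", call. = FALSE)
  }
  message(sprintf("spliz_differential: testing %d gene(s) [%s, %s]",
                  length(genes), grouping, stat))

  idx_all <- match(scores$cell_id, cells$cell_id)
  grp_all <- group_labels(cells, grouping)[idx_all]
  results <- lapply(seq_along(genes), function(gi) {
    g <- genes[gi]
    rows <- gm[gm$gene == g, ]
    p_raw <- median_null_pvalue(rows$median, rows$n_cells)
    p_perm <- NA_real_
    if (p_raw < 0.05) {
      sel <- scores$gene == g & grp_all %in% rows$group
      p_perm <- permutation_refine(scores$score[sel], grp_all[sel],
                                   B = B, seed = seed + gi,
                                   min_cells = min_cells)
    }
    ext <- which.max(abs(rows$median))
    delta <- NA_real_
    if (grouping == "cell_type") {
      ctx <- paste(rows$tissue, rows$compartment)
      deltas <- vapply(split(rows$median, ctx), function(m) {
        if (length(m) < 2) NA_real_ else max(m) - min(m)
      }, numeric(1))
      if (any(!is.na(deltas))) delta <- max(deltas, na.rm = TRUE)
    }
    consistent <- TRUE
    if (grouping == "compartment") {
      ext_comp <- rows$group[ext]
      sel <- scores$gene == g &
        cells$compartment[idx_all] == ext_comp
      tis <- cells$tissue[idx_all][sel]
      v <- scores$score[sel]
      tmed <- vapply(split(v, tis), stats::median, numeric(1))
      tn <- vapply(split(v, tis), length, integer(1))
      tmed <- tmed[tn >= min_cells]
      pooled_sign <- sign(rows$median[ext])
      consistent <- length(tmed) == 0 ||
        all(sign(tmed) == pooled_sign | tmed == 0)
    }
    data.frame(gene = g, n_groups = nrow(rows),
               p_raw = p_raw, p_perm = p_perm,
               p = ifelse(is.na(p_perm), p_raw, p_perm),
               effect_size = abs(rows$median[ext]),
               extreme_group = rows$group[ext],
               extreme_median = rows$median[ext],
               within_context_delta = delta,
               consistent = consistent, stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, results)
  results$p_bh <- bh_adjust(results$p)
  results <- call_significant(results, grouping, effect_threshold,
                              alpha, context_delta)
  structure(list(results = results, group_medians = gm,
                 grouping = grouping, stat = stat, min_cells = min_cells,
                 alpha = alpha, effect_threshold = effect_threshold,
                 context_delta = context_delta),
            class = "spliz_diff")
}

#' Apply the significance gates to a differential results table
#'
#' @param results Per-gene results `data.frame` with `p_bh`,
#'   `effect_size`, `within_context_delta`, `consistent`.
#' @param grouping,effect_threshold,alpha,context_delta See
#'   [spliz_differential()].
#' @export
call_significant <- function(results, grouping, effect_threshold,
                             alpha = 0.05, context_delta = 0.5) {
  gate <- results$p_bh < alpha & results$effect_size > effect_threshold
  if (grouping == "cell_type") {
    gate <- gate & !is.na(results$within_context_delta) &
      results$within_context_delta >= context_delta
  } else {
    gate <- gate & results$consistent
  }
  results$significant <- gate
  results
}

#' @export
print.spliz_diff <- function(x, ...) {
  cat(sprintf("Differential splicing (%s, %s): %d gene(s) tested, %d significant\n",
              x$grouping, x$stat, nrow(x$results),
              sum(x$results$significant)))
  cat(sprintf("  gates: BH p < %g, effect > %g%s\n", x$alpha,
              x$effect_threshold,
              if (x$grouping == "cell_type")
                sprintf(", within-context delta >= %g", x$context_delta)
              else ", per-tissue sign consistency"))
  invisible(x)
}

#' Concordance of group medians between two runs
#'
#' Restricts to genes called significant in both runs, matches
#' (gene, group) pairs present in both, and returns the Pearson
#' correlation of their medians.
#'
#' @param diff_a,diff_b `spliz_diff` objects from comparable runs (the
#'   input tables should be subset to shared junctions and groups before
#'   fitting).
#' @param significant_only Restrict to genes significant in both runs
#'   (default) or use all tested genes.
#' @return List: `r`, `n_pairs`, `genes`.
#' @export
replicate_concordance <- function(diff_a, diff_b, significant_only = TRUE) {
  ga <- if (significant_only)
    diff_a$results$gene[diff_a$results$significant] else
      diff_a$results$gene
  gb <- if (significant_only)
    diff_b$results$gene[diff_b$results$significant] else
      diff_b$results$gene
  shared <- intersect(ga, gb)
  ma <- diff_a$group_medians[diff_a$group_medians$gene %in% shared, ]
  mb <- diff_b$group_medians[diff_b$group_medians$gene %in% shared, ]
  key_a <- paste(ma$gene, ma$group, sep = "\r")
  key_b <- paste(mb$gene, mb$group, sep = "\r")
  common <- intersect(key_a, key_b)
  if (length(common) < 3) {
    stop("fewer than 3 matched (gene, group) pairs", call. = FALSE)
  }
  r <- stats::cor(ma$median[match(common, key_a)],
                  mb$median[match(common, key_b)])
  list(r = r, n_pairs = length(common), genes = shared)
}

#' Concordance as a function of the effect-size threshold
#'
#' For each candidate threshold, recomputes replicate concordance over
#' genes passing adjusted p < `alpha` and effect size > threshold in
#' both runs. Thresholds leaving fewer than 3 matched pairs yield `NA`.
#'
#' @param diff_a,diff_b `spliz_diff` objects.
#' @param thresholds Candidate effect-size cutoffs.
#' @param alpha Adjusted p-value gate applied in both runs.
#' @return `data.frame`: `threshold`, `n_genes`, `r`.
#' @export
effect_size_sweep <- function(diff_a, diff_b,
                              thresholds = seq(0, 2, by = 0.25),
                              alpha = 0.05) {
  rows <- lapply(thresholds, function(thr) {
    pass <- function(d) {
      d$results$gene[d$results$p_bh < alpha & d$results$effect_size > thr]
    }
    shared <- intersect(pass(diff_a), pass(diff_b))
    ma <- diff_a$group_medians[diff_a$group_medians$gene %in% shared, ]
    mb <- diff_b$group_medians[diff_b$group_medians$gene %in% shared, ]
    key_a <- paste(ma$gene, ma$group, sep = "\r")
    key_b <- paste(mb$gene, mb$group, sep = "\r")
    common <- intersect(key_a, key_b)
    r <- if (length(common) < 3) NA_real_ else
      stats::cor(ma$median[match(common, key_a)],
                 mb$median[match(common, key_b)])
    data.frame(threshold = thr, n_genes = length(shared), r = r)
  })
  do.call(rbind, rows)
}
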