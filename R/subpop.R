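# Univariate Gaussian mixture EM with seeded restarts. Returns weights,
# means, variances, responsibilities, loglik. Component variances are
# floored at var_floor_frac * sample variance: the SpliZ is quantized at
# low read depth (many exactly tied values), and a component narrower
# than the quantization scale is a spike on ties, not a subpopulation —
# with an unbounded likelihood that would otherwise dominate EM.
fit_gmm_em <- function(x, k, init_means, max_iter = 500, tol = 1e-8,
                       var_floor_frac = 0.05) {
  n <- length(x)
  floor_var <- var_floor_frac * max(stats::var(x), .Machine$double.eps)
  w <- rep(1 / k, k)
  mu <- init_means
  v <- rep(max(stats::var(x), floor_var), k)
  ll_old <- -Inf
  z <- matrix(0, n, k)
  for (iter in seq_len(max_iter)) {
    for (j in seq_len(k)) {
      z[, j] <- w[j] * stats::dnorm(x, mu[j], sqrt(v[j]))
    }
    rs <- rowSums(z)
    rs[rs == 0] <- .Machine$double.xmin
    ll <- sum(log(rs))
    z <- z / rs
    nk <- colSums(z)
    nk[nk == 0] <- .Machine$double.eps
    w <- nk / n
    mu <- colSums(z * x) / nk
    v <- pmax(colSums(z * (outer(x, mu, "-"))^2) / nk, floor_var)
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(k = k, weight = w, mean = mu, var = v, z = z, loglik = ll)
}

icl_value <- function(fit, n) {
  z <- pmax(fit$z, .Machine$double.xmin)
  entropy <- -sum(fit$z * log(z))
  npar <- 3 * fit$k - 1
  fit$loglik - 0.5 * npar * log(n) - entropy
}

# Selected component count: the maximum of the (entropy-penalised) ICL
# curve, ties broken toward smaller k. Because ICL charges both a BIC
# complexity term and the assignment entropy, its maximum sits at the
# bend of the fit-complexity trade-off: unimodal data peak at k = 1,
# well-separated mixtures at the true k.
icl_select <- function(icl) {
  which.max(icl)
}

#' Fit Gaussian mixtures with ICL model selection
#'
#' Fits univariate Gaussian mixtures with k = 1..`k_max` components by
#' EM (multiple seeded restarts, best ICL kept) to the SpliZ values of
#' one gene within one cell type, and selects k at the maximum of the
#' ICL curve. ICL is the BIC-penalised complete-data criterion:
#' log-likelihood minus half the parameter count times log n, minus the
#' soft-assignment entropy — so it favours well-separated components
#' over merely well-fitting ones, and its peak marks the point where
#' added components stop paying for their complexity.
#'
#' Component variances are floored at `var_floor_frac` times the sample
#' variance. The SpliZ is a scaled count statistic and is quantized at
#' typical read depths, so exactly tied values are common; a component
#' narrower than that resolution is a spike on ties — the stochastic
#' binary-inclusion artifact — not a cell subpopulation.
#'
#' @param values Per-cell SpliZ values (>= `min_n`).
#' @param k_max Largest component count considered (default 5).
#' @param seed Integer seed; fits are deterministic given it.
#' @param n_restarts EM restarts per k (default 10; the first uses
#'   quantile-spread means, the rest random draws).
#' @param min_n Minimum number of values (default 20).
#' @param var_floor_frac Component variance floor as a fraction of the
#'   sample variance (default 0.05).
#' @return List of class `gmm_icl`: `fits` (best fit per k), `icl`
#'   (numeric vector), `selected_k`, `n`.
#' @export
fit_gmm_icl <- function(values, k_max = 5, seed = 1, n_restarts = 10,
                        min_n = 20, var_floor_frac = 0.05) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < min_n) {
    stop(sprintf("need at least %d values, got %d", min_n, n),
         call. = FALSE)
  }
  k_max <- min(k_max, length(unique(values)))
  set.seed(seed)
  fits <- vector("list", k_max)
  icl <- numeric(k_max)
  for (k in seq_len(k_max)) {
    best <- NULL
    best_icl <- -Inf
    for (r in seq_len(n_restarts)) {
      init <- if (r == 1L) {
        stats::quantile(values, probs = (seq_len(k) - 0.5) / k,
                        names = FALSE)
      } else {
        sample(values, k)
      }
      fit <- fit_gmm_em(values, k, init,
                        var_floor_frac = var_floor_frac)
      cand <- icl_value(fit, n)
      if (cand > best_icl) {
        best <- fit
        best_icl <- cand
      }
      if (k == 1L) break  # k = 1 has a closed-form optimum
    }
    best$icl <- best_icl
    best$assignment <- max.col(best$z)
    fits[[k]] <- best
    icl[k] <- best_icl
  }
  structure(list(fits = fits, icl = icl, selected_k = icl_select(icl),
                 n = n, values = values),
            class = "gmm_icl")
}

#' Bhattacharyya distance between two univariate Gaussians
#'
#' `D = (m1 - m2)^2 / (4 (v1 + v2)) + log((v1 + v2) / (2 sqrt(v1 v2))) / 2`.
#' Symmetric, nonnegative, and zero iff the distributions coincide.
#'
#' @param mean1,var1,mean2,var2 Component moments; variances must be
#'   positive.
#' @export
bhattacharyya <- function(mean1, var1, mean2, var2) {
  if (any(var1 <= 0) || any(var2 <= 0)) {
    stop("variances must be positive", call. = FALSE)
  }
  (mean1 - mean2)^2 / (4 * (var1 + var2)) +
    0.5 * log((var1 + var2) / (2 * sqrt(var1 * var2)))
}

min_pairwise_bhattacharyya <- function(fit) {
  k <- fit$k
  if (k < 2) return(Inf)
  d <- Inf
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d <- min(d, bhattacharyya(fit$mean[i], fit$var[i],
                                fit$mean[j], fit$var[j]))
    }
  }
  d
}

#' Call splicing-defined subpopulations within one cell type
#'
#' Starting from the ICL-selected component count, checks whether the
#' fitted subclusters are separated enough (minimum pairwise
#' Bhattacharyya distance > `gate`); if not, the component count is
#' decremented and the mixture refitted, until either a separated k >= 2
#' is accepted or k = 1 is reached (no subpopulations).
#'
#' @param values Per-cell SpliZ values for one gene and cell type.
#' @param k_max,seed,n_restarts,min_n,var_floor_frac Passed to
#'   [fit_gmm_icl()].
#' @param gate Bhattacharyya separation threshold (default 0.5).
#' @return List of class `subpop_call`: `k`, `accepted`,
#'   `min_distance`, `assignment` (hard labels, all 1 when rejected),
#'   `fit`, `icl_selected_k`.
#' @export
call_subpopulations <- function(values, k_max = 5, seed = 1,
                                n_restarts = 10, min_n = 20, gate = 0.5,
                                var_floor_frac = 0.05) {
  fits <- fit_gmm_icl(values, k_max = k_max, seed = seed,
                      n_restarts = n_restarts, min_n = min_n,
                      var_floor_frac = var_floor_frac)
  k <- fits$selected_k
  while (k >= 2) {
    fit <- fits$fits[[k]]
    d <- min_pairwise_bhattacharyya(fit)
    if (d > gate) {
      return(structure(list(k = k, accepted = TRUE, min_distance = d,
                            assignment = fit$assignment, fit = fit,
                            icl_selected_k = fits$selected_k),
                       class = "subpop_call"))
    }
    k <- k - 1
  }
  structure(list(k = 1L, accepted = FALSE, min_distance = NA_real_,
                 assignment = rep(1L, fits$n), fit = fits$fits[[1]],
                 icl_selected_k = fits$selected_k),
            class = "subpop_call")
}

#' @export
print.subpop_call <- function(x, ...) {
  if (x$accepted) {
    cat(sprintf(
      "Subpopulations: accepted k = %d (min Bhattacharyya %.3f; ICL knee at %d)\n",
      x$k, x$min_distance, x$icl_selected_k))
  } else {
    cat(sprintf("Subpopulations: none (ICL knee at %d, separation gate failed)\n",
                x$icl_selected_k))
  }
  invisible(x)
}

#' Probability that all two-read cells are isoform-pure
#'
#' Under independent sampling of two reads from Binomial(2, p), the
#' chance a cell is "pure" (both reads to the same partner) is
#' `1 - 2 p (1 - p)`; the probability that all n two-read cells are pure
#' is that raised to the n-th power.
#'
#' @param p_hat Pooled fraction of the anchor's reads going to the
#'   designated partner.
#' @param n Number of cells with exactly two reads at the anchor.
#' @export
two_read_pure_probability <- function(p_hat, n) {
  stopifnot(p_hat >= 0, p_hat <= 1, n >= 0)
  (1 - 2 * p_hat * (1 - p_hat))^n
}

#' Two-read binomial consistency test at a two-partner anchor
#'
#' Tests whether cells with exactly two reads at a two-partner anchor
#' are "pure" (both reads to the same partner site) more often than
#' independent read sampling allows — evidence of per-cell splicing
#' states rather than stochastic binary inclusion. Pools all reads at
#' the anchor to estimate the designated partner's usage `p_hat`, then
#' computes the exact probability that every two-read cell is pure under
#' independent Binomial(2, p_hat) sampling.
#'
#' @param junctions Junction table (typically subset to the cells of
#'   interest, e.g. one cell type).
#' @param gene Gene identifier.
#' @param anchor_pos,anchor_role The anchor splice site.
#' @param partners Optional two partner positions to restrict to; by
#'   default all observed partners (must be exactly 2).
#' @param partner Designated partner position for `p_hat`; default the
#'   majority partner.
#' @return List: `p_hat`, `n_two_read_cells`, `n_pure`, `probability`
#'   (that ALL two-read cells are pure), `partner`, read totals.
#' @export
two_read_consistency_test <- function(junctions, gene, anchor_pos,
                                      anchor_role = c("donor", "acceptor"),
                                      partners = NULL, partner = NULL) {
  anchor_role <- match.arg(anchor_role)
  j <- junctions[junctions$gene == gene, , drop = FALSE]
  if (anchor_role == "donor") {
    j <- j[j$donor_pos == anchor_pos, , drop = FALSE]
    j$partner_pos <- j$acceptor_pos
  } else {
    j <- j[j$acceptor_pos == anchor_pos, , drop = FALSE]
    j$partner_pos <- j$donor_pos
  }
  if (!is.null(partners)) {
    j <- j[j$partner_pos %in% partners, , drop = FALSE]
  }
  obs_partners <- sort(unique(j$partner_pos))
  if (length(obs_partners) != 2) {
    stop(sprintf("anchor must have exactly 2 partners under consideration (got %d)",
                 length(obs_partners)), call. = FALSE)
  }
  totals <- vapply(split(j$count, j$partner_pos), sum, numeric(1))
  if (is.null(partner)) {
    partner <- as.integer(names(totals)[which.max(totals)])
  }
  p_hat <- totals[as.character(partner)] / sum(totals)
  per_cell <- rowsum(j$count, j$cell_id)
  two_read <- rownames(per_cell)[per_cell[, 1] == 2]
  if (length(two_read) == 0) {
    stop("no cells with exactly two reads at the anchor", call. = FALSE)
  }
  jj <- j[j$cell_id %in% two_read, , drop = FALSE]
  max_per_cell <- vapply(split(jj$count, jj$cell_id), max, numeric(1))
  n_pure <- sum(max_per_cell == 2)
  list(p_hat = unname(p_hat), n_two_read_cells = length(two_read),
       n_pure = n_pure,
       probability = two_read_pure_probability(unname(p_hat),
                                               length(two_read)),
       partner = partner, partner_reads = totals,
       total_reads = sum(totals))
}
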