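test_that("group medians respect the 10-cell eligibility gate", {
  cells <- make_cells(paste0("c", 1:30),
                      cell_type = rep(c("a", "b", "d"), c(11, 10, 9)))
  scores <- data.frame(cell_id = cells$cell_id, gene = "g1",
                       score = c(seq(-1, 1, length.out = 11),
                                 rnorm(10), rnorm(9)))
  gm <- group_medians(scores, cells)
  expect_equal(sort(unique(gm$group)),
               c("lung immune a", "lung immune b"))  # group d: 9 cells
  expect_equal(gm$median[gm$group == "lung immune a"], 0)

  # medians invariant to within-group cell order
  perm <- sample(nrow(scores))
  gm2 <- group_medians(scores[perm, ], cells)
  expect_equal(gm2, gm)

  # a gene with fewer than two eligible groups disappears
  cells2 <- make_cells(paste0("c", 1:15),
                       cell_type = rep(c("a", "b"), c(12, 3)))
  scores2 <- data.frame(cell_id = cells2$cell_id, gene = "g1",
                        score = rnorm(15))
  expect_equal(nrow(group_medians(scores2, cells2)), 0)
})

test_that("analytic median p-values match the closed-form normal tail", {
  expect_equal(median_null_pvalue(c(0, 0), c(50, 50)), 1)
  # group of 100 cells with median 0.5: null sd sqrt(pi/200) ~ 0.1253,
  # z ~ 3.99, two-sided p ~ 6.6e-5; Sidak over 2 groups
  p1 <- 2 * pnorm(-0.5 / sqrt(pi / 200))
  expect_equal(p1, 6.6e-5, tolerance = 0.01)
  expect_equal(median_null_pvalue(c(0.5, 0), c(100, 100)),
               1 - (1 - p1)^2, tolerance = 1e-12)
  # monotone nonincreasing in the largest |median| at fixed sizes
  ps <- vapply(seq(0, 2, by = 0.1), function(m) {
    median_null_pvalue(c(m, 0.1), c(40, 40))
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("permutation p-values agree with exhaustive enumeration on a toy", {
  # 8 cells, two groups of 4: compare against the exact permutation
  # distribution enumerated over all 8! relabelings (equivalently all
  # assignments; the statistic depends only on the grouping)
  values <- c(0.3, -1.2, 2.1, 0.4, -0.6, 1.8, -0.2, 0.9)
  labels <- rep(c("a", "b"), each = 4)
  null_sd <- sqrt(pi / 8)
  stat <- function(perm) {
    max(abs(c(median(values[perm[1:4]]), median(values[perm[5:8]])))) /
      null_sd
  }
  obs <- stat(1:8)
  combos <- combn(8, 4)
  exact <- mean(apply(combos, 2, function(ix) {
    stat(c(ix, setdiff(1:8, ix))) >= obs
  }))
  p <- permutation_refine(values, labels, B = 4000, seed = 3,
                          min_cells = 4, early_stop = Inf)
  se <- sqrt(exact * (1 - exact) / 4000)
  expect_lt(abs(p - exact), 4 * se + 2 / 4000)
})

test_that("permutation refinement is seeded, powered, and floored", {
  set.seed(1)
  values <- c(rnorm(50, 2), rnorm(150))
  labels <- rep(c("a", "b", "d", "e"), each = 50)
  p1 <- permutation_refine(values, labels, B = 500, seed = 11)
  p2 <- permutation_refine(values, labels, B = 500, seed = 11)
  expect_identical(p1, p2)
  expect_equal(p1, 1 / 501)  # planted +2 shift: no permutation exceeds
  expect_warning(permutation_refine(values, labels, B = 50, seed = 1),
                 "coarse")
})

test_that("BH adjustment matches the hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.5, NA)), "finite")
})

test_that("significance needs the p, effect-size and context gates together", {
  base <- data.frame(gene = c("g1", "g2", "g3"),
                     p_bh = c(0.01, 0.2, 0.01),
                     effect_size = c(0.3, 2.0, 1.0),
                     within_context_delta = c(0.8, 0.8, 0.8),
                     consistent = TRUE)
  out <- call_significant(base, "cell_type", effect_threshold = 0.5)
  expect_equal(out$significant, c(FALSE, FALSE, TRUE))
  # in compartment mode the delta is replaced by sign consistency
  base$consistent <- c(TRUE, TRUE, FALSE)
  out <- call_significant(base, "compartment", effect_threshold = 0.5)
  expect_equal(out$significant, c(FALSE, FALSE, FALSE))
})

test_that("planted usage shifts are called with the right direction", {
  ct <- data.frame(cell_type = c("a", "b"), tissue = "lung",
                   compartment = "immune", n_cells = 120)
  cfg <- simulation_config(n_genes = 6, cell_types = ct,
                           signal_genes = 3, usage_shift = 0.5,
                           depth_mean = 10, seed = 41)
  sim <- simulate_dataset(cfg)
  fit <- spliz(sim$junctions, cells = sim$cells)
  d <- spliz_differential(fit, B = 300, seed = 5)
  truth <- sim$truth$genes
  called <- d$results$significant[match(truth$gene, d$results$gene)]
  expect_true(all(called[truth$differential]))
  expect_false(any(called[!truth$differential], na.rm = TRUE))
  # planted direction: the up-shifted type favours farther partners
  for (g in truth$gene[truth$differential]) {
    row <- d$results[d$results$gene == g, ]
    is_up <- grepl(" a$", row$extreme_group)
    expect_equal(sign(row$extreme_median), if (is_up) 1 else -1)
  }
})

test_that("calls are invariant to input row order", {
  ct <- data.frame(cell_type = c("a", "b"), tissue = "lung",
                   compartment = "immune", n_cells = 40)
  cfg <- simulation_config(n_genes = 4, cell_types = ct,
                           signal_genes = 2, usage_shift = 0.6, seed = 13)
  sim <- simulate_dataset(cfg)
  fit1 <- spliz(sim$junctions, cells = sim$cells)
  shuffled <- sim$junctions[sample(nrow(sim$junctions)), ]
  fit2 <- spliz(shuffled, cells = sim$cells)
  d1 <- spliz_differential(fit1, B = 200, seed = 9)
  d2 <- spliz_differential(fit2, B = 200, seed = 9)
  expect_equal(d1$results[order(d1$results$gene), ],
               d2$results[order(d2$results$gene), ], ignore_attr = TRUE)
})

test_that("compartment-mode consistency gate checks per-tissue signs", {
  # compartment signal consistent across two tissues
  ct <- data.frame(cell_type = c("a1", "b1", "a2", "b2"),
                   tissue = rep(c("lung", "muscle"), each = 2),
                   compartment = rep(c("immune", "epithelial"), 2),
                   n_cells = 60)
  cfg <- simulation_config(n_genes = 4, cell_types = ct,
                           signal_genes = 2, usage_shift = 0.5,
                           depth_mean = 10, seed = 77)
  # up-shift the immune types in both tissues (constructor pairs by
  # order: a1, b1 are "up"); rebuild usage so compartments differ
  for (g in cfg$signal_genes) {
    u <- cfg$genes[[g]]$anchors[[1]]$usage
    u[c("a1", "a2"), ] <- matrix(c(0.25, 0.75), 2, 2, byrow = TRUE)
    u[c("b1", "b2"), ] <- matrix(c(0.75, 0.25), 2, 2, byrow = TRUE)
    cfg$genes[[g]]$anchors[[1]]$usage <- u
    cfg$up_types <- c("a1", "a2")
  }
  sim <- simulate_dataset(cfg)
  fit <- spliz(sim$junctions, cells = sim$cells)
  d <- spliz_differential(fit, grouping = "compartment", B = 300,
                          seed = 3)
  res <- d$results[d$results$gene %in% cfg$signal_genes, ]
  expect_true(all(res$consistent))
  expect_true(all(res$significant))
})

test_that("replicate concordance and the effect-size sweep behave", {
  ct <- data.frame(cell_type = c("a", "b"), tissue = "lung",
                   compartment = "immune", n_cells = 100)
  mk <- function(seed) {
    cfg <- simulation_config(n_genes = 8, cell_types = ct,
                             signal_genes = 4, usage_shift = 0.5,
                             depth_mean = 10, seed = seed)
    # flip the direction of half the planted genes so concordance
    # reflects gene identity, not one shared effect pattern
    for (g in cfg$signal_genes[c(3, 4)]) {
      u <- cfg$genes[[g]]$anchors[[1]]$usage
      cfg$genes[[g]]$anchors[[1]]$usage <- u[rev(seq_len(nrow(u))), ,
                                             drop = FALSE]
      dimnames(cfg$genes[[g]]$anchors[[1]]$usage) <- dimnames(u)
    }
    sim <- simulate_dataset(cfg)
    spliz_differential(spliz(sim$junctions, cells = sim$cells),
                       B = 200, seed = seed)
  }
  d1 <- mk(101)
  d2 <- mk(202)
  same <- replicate_concordance(d1, d1)
  expect_equal(same$r, 1)
  rep_r <- replicate_concordance(d1, d2)
  expect_gt(rep_r$r, 0.9)

  sweep <- effect_size_sweep(d1, d2, thresholds = c(0, 0.5, 10))
  expect_true(is.na(sweep$r[sweep$threshold == 10]))
  expect_gt(sweep$r[sweep$threshold == 0.5], 0.9)

  # shuffling gene labels in one replicate destroys concordance
  set.seed(1)
  shuffled_r <- replicate(10, {
    d3 <- d2
    relab <- setNames(sample(unique(d2$group_medians$gene)),
                      unique(d2$group_medians$gene))
    d3$group_medians$gene <- unname(relab[d3$group_medians$gene])
    d3$results$gene <- unname(relab[d3$results$gene])
    tryCatch(abs(replicate_concordance(d1, d3)$r),
             error = function(e) NA_real_)
  })
  expect_lt(mean(shuffled_r, na.rm = TRUE), 0.6)
})
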