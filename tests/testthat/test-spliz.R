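test_that("partners are ranked by genomic distance from the anchor", {
  # a 5' splice site with two 3' partners: the nearer gets rank 1
  jt <- make_junctions(c("c1", "c1"), 56160320,
                       c(56160626, 56161387), c(5, 5))
  m <- build_rank_models(jt)
  donor <- m[m$anchor_role == "donor", ]
  expect_equal(donor$rank[donor$partner_pos == 56160626], 1)
  expect_equal(donor$rank[donor$partner_pos == 56161387], 2)

  # strand does not flip ranks: same table on the minus strand
  jt$strand <- "-"
  m2 <- build_rank_models(jt)
  expect_equal(m2$rank, m$rank)
})

test_that("anchors with a single partner carry no model", {
  jt <- make_junctions("c1", 100, 500, 5)
  expect_message(m <- build_rank_models(jt), "without a model")
  expect_equal(nrow(m), 0)
})

test_that("rank residuals are exact population z-scores", {
  # 50/50 split: mu 1.5, sigma 0.5, residuals -1 and +1
  jt <- make_junctions(c("c1", "c2"), 100, c(500, 2000), c(10, 10))
  m <- build_rank_models(jt)
  donor <- m[m$anchor_role == "donor", ]
  expect_equal(unique(donor$mu), 1.5)
  expect_equal(unique(donor$sigma), 0.5)
  expect_equal(read_residual(c(1, 2), donor), c(-1, 1))

  # 80/20 split: mu 1.2, sigma 0.4, residuals -0.5 and +2.0
  jt <- make_junctions(c("c1", "c2"), 100, c(500, 2000), c(16, 4))
  donor <- build_rank_models(jt)
  donor <- donor[donor$anchor_role == "donor", ]
  expect_equal(read_residual(c(1, 2), donor), c(-0.5, 2.0))
  expect_equal(read_residual(unique(donor$mu) , donor), 0,
               tolerance = 1e-12)

  # at every modelled anchor of a random dataset, read-weighted
  # residuals have mean 0 and variance 1 exactly
  sim <- simulate_dataset(simulation_config(n_genes = 10, n_cells = 30,
                                            n_partners = 3, seed = 12))
  m <- build_rank_models(sim$junctions)
  for (key in unique(paste(m$gene, m$anchor_role, m$anchor_pos))) {
    a <- m[paste(m$gene, m$anchor_role, m$anchor_pos) == key, ]
    r <- (a$rank - a$mu) / a$sigma
    w <- a$count / sum(a$count)
    expect_equal(sum(w * r), 0, tolerance = 1e-12)
    expect_equal(sum(w * r^2), 1, tolerance = 1e-12)
  }
})

test_that("the SpliZ is the scaled residual sum over read-anchor incidences", {
  # 4 reads, all to the farther partner of a 50/50 anchor: residual +1
  # each, SpliZ = 4 / sqrt(4) = 2 (population cells fix the 50/50 split)
  jt <- rbind(make_junctions("c1", 100, 2000, 4),
              make_junctions("c2", 100, 500, 4))
  fit <- spliz(jt, min_reads = 4)
  s <- fit$scores
  expect_equal(s$spliz[s$cell_id == "c1"], 2.0)
  expect_equal(s$spliz[s$cell_id == "c2"], -2.0)

  # the same cell is not computable at the default 5-read gate
  fit5 <- spliz(jt, min_reads = 5)
  expect_false(any(fit5$scores$computable))
  expect_true(all(is.na(fit5$scores$spliz)))

  # a cell whose reads sit at the population mean rank scores 0
  jt <- rbind(make_junctions("c1", 100, c(500, 2000), c(3, 3)),
              make_junctions("c2", 100, c(500, 2000), c(2, 2)))
  fit <- spliz(jt, min_reads = 4)
  expect_equal(fit$scores$spliz, c(0, 0))
})

test_that("SpliZ reduces to an increasing affine function of PSI", {
  # single two-partner anchor, fixed read count n: over all n+1 possible
  # cells the SpliZ must be exactly affine and increasing in the
  # fraction of reads to the farther partner
  for (n in 2:12) {
    jt <- two_partner_population(n)
    fit <- spliz(jt, min_reads = n)
    s <- fit$scores[order(fit$scores$cell_id), ]
    expect_equal(nrow(s), n + 1)
    psi <- (0:n) / n
    d <- diff(s$spliz) / diff(psi)
    expect_true(all(d > 0))
    expect_equal(max(d) - min(d), 0, tolerance = 1e-9)
  }
})

test_that("shifting reads toward nearer partners strictly lowers the SpliZ", {
  jt <- two_partner_population(6)
  fit <- spliz(jt, min_reads = 6)
  s <- fit$scores[order(fit$scores$cell_id), ]
  expect_true(all(diff(s$spliz) > 0))  # cells ordered by far-partner use
})

test_that("relabelling cells permutes but never changes the score multiset", {
  sim <- simulate_dataset(simulation_config(n_genes = 5, n_cells = 30,
                                            seed = 31))
  fit <- spliz(sim$junctions)
  relab <- sim$junctions
  ids <- unique(relab$cell_id)
  new_ids <- setNames(sample(ids), ids)
  relab$cell_id <- unname(new_ids[relab$cell_id])
  fit2 <- spliz(relab)
  for (g in unique(fit$scores$gene)) {
    a <- sort(fit$scores$spliz[fit$scores$gene == g &
                                 fit$scores$computable])
    b <- sort(fit2$scores$spliz[fit2$scores$gene == g &
                                  fit2$scores$computable])
    expect_equal(a, b)
  }
})

test_that("weighted average partner rank matches its definition", {
  jt <- rbind(make_junctions("c1", 100, c(500, 2000), c(3, 1)),
              make_junctions("c2", 100, 500, 4))
  war <- weighted_average_rank(jt, build_rank_models(jt))
  expect_equal(war$avg_rank[war$cell_id == "c1"], 1.25)
  expect_equal(war$avg_rank[war$cell_id == "c2"], 1.0)

  # 3-partner anchor, one read each: (1+2+3)/3 = 2
  jt <- make_junctions("c1", 100, c(500, 2000, 4000), c(1, 1, 1))
  jt <- rbind(jt, make_junctions("c2", 100, c(500, 2000, 4000),
                                 c(2, 1, 1)))
  war <- weighted_average_rank(jt, build_rank_models(jt))
  expect_equal(war$avg_rank[war$cell_id == "c1"], 2.0)
})

test_that("residuals method exposes per-incidence residuals", {
  jt <- rbind(make_junctions("c1", 100, c(500, 2000), c(3, 3)),
              make_junctions("c2", 100, c(500, 2000), c(1, 5)))
  fit <- spliz(jt)
  inc <- residuals(fit)
  expect_true(all(c("cell_id", "rank", "residual", "count") %in%
                    names(inc)))
  # one modelled anchor (the donor); each junction row one incidence
  expect_equal(nrow(inc), 4)
})
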