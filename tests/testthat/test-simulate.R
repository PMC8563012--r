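test_that("the generator is deterministic given its seed", {
  cfg <- simulation_config(n_genes = 10, n_cells = 20,
                           signal_genes = 3, seed = 99)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$junctions, b$junctions)
  expect_identical(a$cells, b$cells)
  expect_identical(a$truth, b$truth)
})

test_that("counts are positive integers", {
  sim <- simulate_dataset(simulation_config(n_genes = 10, n_cells = 20,
                                            seed = 5))
  expect_true(all(sim$junctions$count >= 1))
  expect_type(sim$junctions$count, "integer")
})

test_that("with no Dirichlet noise, one type's partner fractions match its usage", {
  # single cell type, deep coverage: law of large numbers
  ct <- data.frame(cell_type = "a", tissue = "lung",
                   compartment = "immune", n_cells = 200)
  cfg <- simulation_config(n_genes = 5, cell_types = ct,
                           depth_mean = 50, dirichlet_concentration = Inf,
                           seed = 3)
  sim <- simulate_dataset(cfg)
  j <- sim$junctions
  near <- tapply(j$count[j$acceptor_pos - j$donor_pos == 500],
                 j$gene[j$acceptor_pos - j$donor_pos == 500], sum)
  tot <- tapply(j$count, j$gene, sum)
  frac <- near / tot[names(near)]
  expect_true(all(abs(frac - 0.5) < 0.02))
})

test_that("planted 0.9/0.1 usage is recovered in per-type read fractions", {
  # two types, usage (0.1, 0.9) vs (0.9, 0.1) on (near, far):
  # binomial SE at ~200 cells x depth 20 is well under 0.03
  ct <- data.frame(cell_type = c("a", "b"), tissue = "lung",
                   compartment = "immune", n_cells = 200)
  cfg <- simulation_config(n_genes = 2, cell_types = ct,
                           depth_mean = 20, signal_genes = 2,
                           usage_shift = 0.8, seed = 17)
  sim <- simulate_dataset(cfg)
  j <- sim$junctions
  type <- sim$cells$cell_type[match(j$cell_id, sim$cells$cell_id)]
  far <- j$acceptor_pos - j$donor_pos == 1000
  for (ty in c("a", "b")) {
    frac_far <- sum(j$count[far & type == ty]) / sum(j$count[type == ty])
    expected <- if (ty == "a") 0.9 else 0.1
    expect_lt(abs(frac_far - expected), 0.03)
  }
})

test_that("the null generator equals the plain one for a single cell type", {
  ct <- data.frame(cell_type = "a", tissue = "lung",
                   compartment = "immune", n_cells = 30)
  cfg <- simulation_config(n_genes = 5, cell_types = ct, seed = 8)
  expect_identical(simulate_dataset(cfg)$junctions,
                   simulate_null_dataset(cfg)$junctions)
})

test_that("group labels are exchangeable under the null generator", {
  # per-type mean weighted rank should be indistinguishable across types
  cfg <- simulation_config(n_genes = 40, n_cells = 40, seed = 21)
  sim <- simulate_null_dataset(cfg)
  j <- sim$junctions
  type <- sim$cells$cell_type[match(j$cell_id, sim$cells$cell_id)]
  far <- j$acceptor_pos - j$donor_pos == 1000
  frac <- vapply(split(seq_len(nrow(j)), type), function(ix) {
    sum(j$count[intersect(ix, which(far))]) / sum(j$count[ix])
  }, numeric(1))
  # all types share usage 0.5; two-proportion z across extreme types
  n_reads <- vapply(split(j$count, type), sum, numeric(1))
  se <- sqrt(0.25 * (1 / min(n_reads) + 1 / max(n_reads)))
  expect_lt(max(frac) - min(frac), 4 * se + 0.02)
})

test_that("degenerate configs are rejected", {
  cfg <- simulation_config(n_genes = 2, n_cells = 5, seed = 1)
  cfg$genes$gene_0001$anchors[[1]]$partners <- integer(0)
  expect_error(validate_simulation_config <- splizr:::validate_simulation_config(cfg),
               "no partner sites")
  cfg <- simulation_config(n_genes = 2, n_cells = 5, seed = 1)
  cfg$genes$gene_0001$anchors[[1]]$usage[1, ] <- c(0.7, 0.7)
  expect_error(splizr:::validate_simulation_config(cfg), "probability")
})

test_that("trajectory datasets carry reproducible pseudotime", {
  cfg <- simulation_config(n_genes = 3, n_cells = 25,
                           trajectory = list(genes = "gene_0001",
                                             start = c(0.9, 0.1),
                                             end = c(0.1, 0.9),
                                             steepness = 10),
                           seed = 4)
  a <- simulate_trajectory_dataset(cfg)
  b <- simulate_trajectory_dataset(cfg)
  expect_true("pseudotime" %in% names(a$cells))
  expect_identical(a$cells$pseudotime, b$cells$pseudotime)
  expect_true(all(a$cells$pseudotime >= 0 & a$cells$pseudotime <= 1))
  expect_error(simulate_trajectory_dataset(
    simulation_config(n_genes = 2, n_cells = 5, seed = 1)),
    "trajectory block")
})

test_that("simulation configs round-trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_genes = 6, n_cells = 15, signal_genes = 2,
                        usage_shift = 0.6, depth_mean = 12, seed = 31),
                   path)
  cfg <- read_simulation_config(path)
  expect_s3_class(cfg, "simulation_config")
  expect_length(cfg$genes, 6)
  expect_identical(simulate_dataset(cfg)$junctions,
                   simulate_dataset(simulation_config(
                     n_genes = 6, n_cells = 15, signal_genes = 2,
                     usage_shift = 0.6, depth_mean = 12,
                     seed = 31))$junctions)
})

test_that("simulations write a readable bundle with planted truth", {
  sim <- simulate_dataset(simulation_config(n_genes = 3, n_cells = 8,
                                            signal_genes = 1, seed = 2))
  dir <- tempfile()
  write_simulation(sim, dir)
  expect_equal(read_junction_table(file.path(dir, "junctions.tsv")),
               sim$junctions, ignore_attr = TRUE)
  truth <- jsonlite::read_json(file.path(dir, "planted_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$genes$differential, sim$truth$genes$differential)
})
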