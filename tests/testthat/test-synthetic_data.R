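test_that("identical configurations reproduce byte-identical data", {
  cfg <- small_sc_config(seed = 42)
  a <- simulate_single_cell(cfg)
  b <- simulate_single_cell(cfg)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$cells, b$cells)
  ba <- simulate_bulk_cohort(cfg)
  bb <- simulate_bulk_cohort(cfg)
  expect_identical(ba$expr, bb$expr)
  expect_identical(ba$clinical, bb$clinical)
})

test_that("configuration invariants are enforced with the field named", {
  expect_error(sim_config(dropout_rate = 1.2), "dropout_rate")
  expect_error(sim_config(censor_rate = -0.1), "censor_rate")
  expect_error(sim_config(n_tfs = 100, targets_per_regulon = 30,
                          n_genes = 2000), "n_genes|targets_per_regulon")
  expect_error(sim_config(shifted_module = 9), "shifted_module")
})

test_that("planted regulons partition targets and modules partition TFs", {
  sim <- simulate_single_cell(small_sc_config(seed = 5))
  targets <- unlist(sim$truth$regulons)
  expect_false(anyDuplicated(targets) > 0)
  expect_setequal(names(sim$truth$modules), names(sim$truth$regulons))
  expect_true(all(sim$truth$modules %in% 1:4))
})

test_that("full dropout yields an all-zero matrix", {
  sim <- simulate_single_cell(small_sc_config(seed = 1, dropout_rate = 1))
  expect_equal(sum(sim$counts), 0)
})

test_that("without dropout the counts are overdispersed (var >= mean)", {
  sim <- simulate_single_cell(small_sc_config(seed = 2, dropout_rate = 0))
  m <- as.matrix(sim$counts)
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  keep <- mu > 1
  expect_gt(mean(v[keep] >= mu[keep]), 0.9)
})

test_that("a zero activity shift leaves conditions exchangeable", {
  sim <- simulate_single_cell(small_sc_config(seed = 3, activity_shift = 0))
  wt <- sim$cells$condition == "WT"
  lat <- sim$truth$tf_activity
  gaps <- rowMeans(lat[, wt]) - rowMeans(lat[, !wt])
  # per-TF null gap has sd sqrt(2 * 2/250) ~ 0.13; max over 12 TFs stays
  # within ~3.5 sd
  expect_lt(max(abs(gaps)), 0.45)
  A <- score_all(lognormalize(sim$counts), sim$truth$regulons, 0.05)
  ras_gap <- rowMeans(A[, wt]) - rowMeans(A[, !wt])
  expect_lt(max(abs(ras_gap)), 0.05)
})

test_that("larger activity shifts produce larger activity gaps", {
  gap_at <- function(shift) {
    sim <- simulate_single_cell(small_sc_config(seed = 4,
                                                activity_shift = shift))
    wt <- sim$cells$condition == "WT"
    sh <- names(sim$truth$modules)[sim$truth$modules ==
                                     sim$truth$shifted_module]
    A <- score_all(lognormalize(sim$counts), sim$truth$regulons[sh], 0.05)
    mean(rowMeans(A[, wt]) - rowMeans(A[, !wt]))
  }
  g0 <- gap_at(0.5); g1 <- gap_at(1.5); g2 <- gap_at(3)
  expect_gt(g1, g0)
  expect_gt(g2, g1)
})

test_that("the planted activity gap is stable across independent draws", {
  # two independent simulations of the same configuration agree on the
  # shifted-module RAS gap within Monte-Carlo error
  gap <- vapply(c(7, 77), function(s) {
    sim <- simulate_single_cell(sim_config(n_cells_per_condition = 400,
                                           n_genes = 700, n_tfs = 10,
                                           targets_per_regulon = 20,
                                           n_modules = 2, seed = s))
    wt <- sim$cells$condition == "WT"
    sh <- names(sim$truth$modules)[sim$truth$modules ==
                                     sim$truth$shifted_module]
    A <- score_all(lognormalize(sim$counts), sim$truth$regulons[sh], 0.05)
    mean(rowMeans(A[, wt]) - rowMeans(A[, !wt]))
  }, numeric(1))
  expect_gt(min(gap), 0.02)
  expect_lt(abs(gap[1] - gap[2]), 0.03)
})

test_that("bulk cohort censoring behaves as configured", {
  cfg0 <- small_sc_config(seed = 8, censor_rate = 0)
  b0 <- simulate_bulk_cohort(cfg0)
  expect_true(all(b0$clinical$event == 1))
  expect_true(all(b0$clinical$time > 0))
  cfg3 <- small_sc_config(seed = 8, censor_rate = 0.3, n_samples = 400)
  b3 <- simulate_bulk_cohort(cfg3)
  expect_lt(abs(mean(1 - b3$clinical$event) - 0.3), 0.1)
  expect_error(simulate_bulk_cohort(small_sc_config(seed = 1,
                                                    n_samples = 30)),
               "n_samples")
})

test_that("the true linear predictor's concordance matches the all-pairs oracle", {
  cfg <- sim_config(seed = 3, n_samples = 300, beta = 1)
  b <- simulate_bulk_cohort(cfg)
  cl <- b$clinical
  expect_equal(cindex(b$truth$lp, cl$time, cl$event),
               brute_cindex(b$truth$lp, cl$time, cl$event), tolerance = 0)
  expect_gt(cindex(b$truth$lp, cl$time, cl$event), 0.8)
})

test_that("a null hazard yields chance-level concordance on fresh draws", {
  cfg <- small_sc_config(seed = 12, beta = 0, n_samples = 300)
  b <- simulate_bulk_cohort(cfg)
  score <- rowMeans(b$expr[, b$truth$signature_genes])
  ci <- cindex(score, b$clinical$time, b$clinical$event)
  expect_gt(ci, 0.44)
  expect_lt(ci, 0.56)
})

test_that("generated gene-set collections are valid GMT with planted overlap", {
  b <- simulate_bulk_cohort(small_sc_config(seed = 9, n_samples = 200))
  path <- file.path(tempdir(), "sets.gmt")
  sets <- make_gene_sets(b$truth, n_sets = 13, set_size = 50,
                         overlap = 0.8, seed = 2, file = path)
  lines <- readLines(path)
  expect_length(lines, 13)
  expect_true(all(lengths(strsplit(lines, "\t")) >= 3))
  expect_identical(read_gmt(path), sets)
  # with high overlap, every set separates the planted subtypes
  sc <- ssgsea_score(t(b$expr), sets)
  lab <- b$truth$subtype[rownames(sc)]
  gap <- colMeans(sc[lab == "C1", ]) - colMeans(sc[lab == "C2", ])
  expect_true(all(gap > 0))
})
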