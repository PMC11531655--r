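test_that("meta-cell aggregation partitions cells and averages profiles", {
  m <- rand_expr(30, 60, seed = 41, lambda = 6)
  norm <- lognormalize(m)
  mc <- build_metacells(norm, 12, n_pcs = 10, seed = 1)
  expect_length(mc$membership, 60)
  expect_equal(sum(table(mc$membership)), 60)
  k <- mc$membership[5]
  expect_equal(mc$profiles[, k],
               rowMeans(as.matrix(norm[, mc$membership == k, drop = FALSE])))
})

test_that("as many meta-cells as cells is the identity mapping", {
  m <- rand_expr(20, 25, seed = 42)
  mc <- build_metacells(m, 25, seed = 1)
  expect_equal(unname(as.matrix(mc$profiles)), unname(as.matrix(m)))
  expect_equal(mc$membership, 1:25)
})

test_that("meta-cells are more homogeneous in latent activity than the pool", {
  sim <- simulate_single_cell(small_sc_config(seed = 43))
  norm <- normalize_and_select_hvg(sim$counts, 500)
  mc <- build_metacells(norm, 50, seed = 1)
  lat <- sim$truth$tf_activity
  within <- mean(vapply(split(seq_len(ncol(lat)), mc$membership),
                        function(j) mean(apply(lat[, j, drop = FALSE], 1,
                                               var)),
                        numeric(1)), na.rm = TRUE)
  global <- mean(apply(lat, 1, var))
  expect_lt(within, global)
})

test_that("a target identical to a TF profile gets essentially all importance", {
  set.seed(44)
  prof <- matrix(rnorm(3 * 40), 3, 40,
                 dimnames = list(c("TFa", "TFb", "Y"), NULL))
  prof["Y", ] <- prof["TFa", ]
  for (method in c("gbm", "lm")) {
    e <- infer_coexpression(prof, c("TFa", "TFb"), method = method)
    ey <- e[e$target == "Y", ]
    expect_gte(ey$importance[ey$tf == "TFa"] / sum(ey$importance), 0.99)
  }
})

test_that("per-target importances are non-negative shares summing to <= 1", {
  sim <- simulate_single_cell(small_sc_config(seed = 45))
  norm <- lognormalize(sim$counts)[1:250, ]
  for (method in c("gbm", "lm", "spearman")) {
    e <- infer_coexpression(norm, names(sim$truth$regulons),
                            method = method, seed = 1)
    expect_true(all(e$importance > 0))
    sums <- tapply(e$importance, e$target, sum)
    expect_true(all(sums <= 1 + 1e-8))
  }
})

test_that("permuting a target's profile destroys its planted edge", {
  sim <- simulate_single_cell(small_sc_config(seed = 46))
  norm <- as.matrix(lognormalize(sim$counts))
  tf <- names(sim$truth$regulons)[1]
  tgt <- names(which.max(sim$truth$weights[[tf]]))  # strongest planted edge
  imp_of <- function(mat) {
    e <- infer_coexpression(mat, names(sim$truth$regulons), method = "lm")
    i <- e$importance[e$tf == tf & e$target == tgt]
    if (length(i)) i else 0
  }
  before <- imp_of(norm)
  set.seed(9)
  norm[tgt, ] <- sample(norm[tgt, ])
  after <- imp_of(norm)
  expect_gt(before, 0.02)      # the planted edge carries clear importance
  expect_lt(after, before / 5) # permutation destroys it
})

test_that("co-expression inference is deterministic under a fixed seed", {
  sim <- simulate_single_cell(small_sc_config(seed = 47))
  norm <- lognormalize(sim$counts)[1:150, 1:120]
  e1 <- infer_coexpression(norm, names(sim$truth$regulons), seed = 3)
  e2 <- infer_coexpression(norm, names(sim$truth$regulons), seed = 3)
  expect_identical(e1, e2)
})

test_that("regulon assembly prunes by prior, size and self-loops", {
  edges <- data.frame(
    tf = rep(c("TF1", "TF2"), c(12, 11)),
    target = c(sprintf("A%02d", 1:12), "TF2", sprintf("B%02d", 1:10)),
    importance = c(seq(0.9, 0.2, length.out = 12),
                   seq(0.8, 0.2, length.out = 11)))
  all_pairs <- expand.grid(tf = c("TF1", "TF2"),
                           target = unique(edges$target),
                           stringsAsFactors = FALSE)
  regs <- assemble_regulons(edges, all_pairs, min_regulon_size = 10)
  expect_named(regs, c("TF1", "TF2"))
  expect_equal(unname(regs$TF1$targets), sprintf("A%02d", 1:12))
  expect_false("TF2" %in% regs$TF2$targets)  # self-loop removed
  expect_length(regs$TF2$targets, 10)
  # dropping one TF1 candidate from the prior leaves 11 targets; dropping
  # three leaves 9 < 10 and the regulon disappears
  pruned <- all_pairs[!(all_pairs$tf == "TF1" &
                          all_pairs$target %in% c("A01", "A02", "A03")), ]
  regs2 <- assemble_regulons(edges, pruned, min_regulon_size = 10)
  expect_named(regs2, "TF2")
  expect_error(assemble_regulons(edges, all_pairs[0, ], 10), "prior")
})

test_that("edge ranking average precision behaves at its extremes", {
  truth <- list(TF1 = c("a", "b"))
  perfect <- data.frame(tf = "TF1", target = c("a", "b", "c"),
                        importance = c(3, 2, 1))
  expect_equal(edge_pr_auc(perfect, truth), 1)
  bad <- data.frame(tf = "TF1", target = c("c", "d"), importance = c(2, 1))
  expect_equal(edge_pr_auc(bad, truth), 0)
})
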