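test_that("identical groups produce null DE and no threshold passes", {
  set.seed(81)
  half <- matrix(rnorm(50 * 8, 5), 50, 8,
                 dimnames = list(sprintf("g%02d", 1:50), NULL))
  m <- cbind(half, half)
  g <- rep(c("a", "b"), each = 8)
  de <- differential_expression(m, g)
  expect_true(all(de$p > 0.9))
  expect_true(all(abs(de$logFC) < 1e-12))
  expect_equal(sum(de$adj_p < 0.05 & abs(de$logFC) > 1), 0)
})

test_that("a strongly shifted gene passes both DE thresholds", {
  set.seed(82)
  m <- matrix(rnorm(20 * 40, 4, 0.1), 20, 40,
              dimnames = list(sprintf("g%02d", 1:20), NULL))
  m["g05", 1:20] <- rnorm(20, 8 * log(2), 0.1)  # ~8 vs ~4 in log2 units
  m["g05", 21:40] <- rnorm(20, 2 * log(2), 0.1)
  de <- differential_expression(m, rep(c("a", "b"), each = 20))
  row <- de[de$gene == "g05", ]
  expect_lt(row$adj_p, 0.05)
  expect_gt(row$logFC, 1)
  expect_error(differential_expression(m, rep(c("a", "b"), c(38, 2))),
               "at least 3")
})

test_that("the DE test is calibrated on null genes", {
  set.seed(83)
  m <- matrix(rnorm(1000 * 30), 1000, 30,
              dimnames = list(sprintf("g%04d", 1:1000), NULL))
  de <- differential_expression(m, rep(c("a", "b"), each = 15))
  frac <- mean(de$p < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("signature construction intersects regulon and DE genes", {
  de <- data.frame(gene = c("t1", "t2", "t3", "TFX", "other"),
                   logFC = c(2, -1.5, 0.2, 1.4, 3),
                   p = c(1e-5, 1e-4, 0.5, 1e-3, 1e-6))
  de$adj_p <- p.adjust(de$p, "BH")
  reg <- list(tf = "TFX", targets = c("t1", "t2", "t3"))
  expect_message(sig <- build_signature(reg, de), "3/4")
  expect_setequal(sig, c("TFX", "t1", "t2"))
  up_only <- build_signature(reg, de, direction = "up")
  expect_setequal(up_only, c("TFX", "t1"))
  reg2 <- list(tf = "Z", targets = c("zz1", "zz2"))
  expect_error(build_signature(reg2, de), "empty signature")
})

test_that("a single full-sample resampling gives a binary consensus matrix", {
  set.seed(84)
  x <- rbind(matrix(rnorm(20 * 5, 0), 20, 5),
             matrix(rnorm(20 * 5, 4), 20, 5))
  cc <- consensus_cluster(x, k_range = 2, n_resamples = 1,
                          sample_frac = 0.999, feature_frac = 1, seed = 1)
  expect_true(all(cc$consensus[["2"]] %in% c(0, 1)))
})

test_that("consensus entries are frequencies and labels partition samples", {
  set.seed(85)
  x <- matrix(rnorm(60 * 8), 60, 8,
              dimnames = list(sprintf("s%02d", 1:60), NULL))
  cc <- consensus_cluster(x, k_range = 2:4, n_resamples = 40, seed = 2)
  for (cm in cc$consensus) {
    expect_true(all(cm >= 0 & cm <= 1))
    expect_equal(cm, t(cm))
  }
  expect_length(cc$labels, 60)
  expect_warning(consensus_cluster(x, k_range = 2:30, n_resamples = 10,
                                   seed = 1), "clipped")
})

test_that("well-separated planted subtypes are recovered with k = 2", {
  b <- simulate_bulk_cohort(small_sc_config(seed = 86, n_samples = 150))
  x <- b$expr[, b$truth$subtype_genes]
  cc <- consensus_cluster(x, k_range = 2:5, n_resamples = 60, seed = 3)
  expect_equal(cc$selected_k, 2)
  expect_gte(ari(cc$labels, b$truth$subtype), 0.9)
})

test_that("consensus partitions are stable under sample reordering", {
  set.seed(87)
  x <- rbind(matrix(rnorm(40 * 6, 0), 40, 6),
             matrix(rnorm(40 * 6, 5), 40, 6))
  rownames(x) <- sprintf("s%02d", 1:80)
  perm <- sample(80)
  a <- consensus_cluster(x, k_range = 2, n_resamples = 30, seed = 4)
  b <- consensus_cluster(x[perm, ], k_range = 2, n_resamples = 30, seed = 4)
  expect_equal(ari(a$labels[perm], b$labels), 1)
})

test_that("log-rank on a six-sample toy matches the hand-computed statistic", {
  # times/events chosen so expected counts are easy to accumulate by hand
  cl <- data.frame(time = c(1, 2, 3, 4, 5, 6),
                   event = c(1, 1, 1, 1, 0, 1))
  labels <- c("A", "B", "A", "B", "A", "B")
  cohort <- list(clinical = cl)
  got <- compare_subtypes(cohort, labels)
  # independent accumulation of observed - expected events for group A
  at_risk <- function(t) which(cl$time >= t)
  o_minus_e <- 0; v <- 0
  for (t in cl$time[cl$event == 1]) {
    r <- at_risk(t); n <- length(r); nA <- sum(labels[r] == "A")
    d <- sum(cl$time == t & cl$event == 1)
    oA <- sum(cl$time == t & cl$event == 1 & labels == "A")
    o_minus_e <- o_minus_e + (oA - d * nA / n)
    if (n > 1) v <- v + d * (nA / n) * (1 - nA / n) * (n - d) / (n - 1)
  }
  expect_equal(got$logrank_chisq, o_minus_e^2 / v, tolerance = 1e-10)
})

test_that("identical survival gives a null log-rank; planted hazard a strong one", {
  half <- data.frame(time = rep(c(3, 6, 9, 12, 15), 4),
                     event = rep(c(1, 1, 0, 1, 1), 4))
  cohort <- list(clinical = rbind(half, half))
  labels <- rep(c("A", "B"), each = nrow(half))
  res <- compare_subtypes(cohort, labels)
  expect_gt(res$logrank_p, 0.9)
  set.seed(88)
  n <- 150
  grp <- rep(c("A", "B"), each = n / 2)
  t_true <- rexp(n, rate = ifelse(grp == "A", 0.09, 0.03))  # HR = 3
  cens <- rexp(n, 0.01)
  cohort2 <- list(clinical = data.frame(time = pmin(t_true, cens),
                                        event = as.integer(t_true <= cens)))
  res2 <- compare_subtypes(cohort2, grp)
  expect_lt(res2$logrank_p, 0.01)
})

test_that("subtype comparisons include per-set score tests", {
  b <- simulate_bulk_cohort(small_sc_config(seed = 89, n_samples = 120))
  sets <- make_gene_sets(b$truth, n_sets = 5, set_size = 30, overlap = 0.8,
                         seed = 1)
  sc <- ssgsea_score(t(b$expr), sets)
  res <- compare_subtypes(b, b$truth$subtype, sc)
  expect_equal(nrow(res$set_table), 5)
  expect_true(all(res$set_table$adj_p >= res$set_table$p - 1e-15))
  expect_true(all(res$set_table$p < 0.05))
})
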