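test_that("concordance hits its extremes and matches the pair oracle", {
  time <- c(2, 5, 9, 1, 7)
  event <- c(1, 1, 0, 1, 1)
  expect_equal(cindex(-time, time, event), 1)
  expect_equal(cindex(time, time, event), 0)
  toy_scores <- c(3, 1, 2, 5, 4)
  expect_equal(cindex(toy_scores, time, event),
               brute_cindex(toy_scores, time, event))
  expect_error(cindex(1:3, c(5, 5, 5), c(0, 0, 0)), "comparable")
})

test_that("concordance matches exhaustive enumeration on random instances", {
  for (s in 1:20) {
    set.seed(s + 900)
    n <- sample(5:12, 1)
    scores <- sample(1:6, n, replace = TRUE)  # ties included
    time <- sample(1:8, n, replace = TRUE)
    event <- rbinom(n, 1, 0.7)
    if (sum(outer(time, time, "<") & event == 1) == 0) next
    expect_equal(cindex(scores, time, event),
                 brute_cindex(scores, time, event))
  }
})

test_that("concordance respects its algebraic identities", {
  set.seed(91)
  n <- 60
  scores <- rnorm(n); time <- rexp(n); event <- rbinom(n, 1, 0.8)
  c1 <- cindex(scores, time, event)
  expect_equal(c1 + cindex(-scores, time, event), 1)
  expect_equal(cindex(exp(scores) + 5, time, event), c1)
  # agreement with the survival package (which counts higher x ~ longer
  # survival, the mirror of a risk score)
  ref <- survival::concordance(survival::Surv(time, event) ~ scores)
  expect_equal(c1, 1 - ref$concordance, tolerance = 1e-12)
})

test_that("random scores sit at chance concordance", {
  set.seed(92)
  n <- 2000
  ci <- cindex(rnorm(n), rexp(n), rbinom(n, 1, 0.8))
  expect_lt(abs(ci - 0.5), 0.03)
})

test_that("Cox screening keeps planted genes, skips constant ones, stays calibrated", {
  cfg <- small_sc_config(seed = 93, n_samples = 300, beta = 1)
  b <- simulate_bulk_cohort(cfg)
  b$expr[, "GENE0001"] <- 3  # constant gene
  expect_warning(res <- cox_screen(b, p_thresh = 0.05), "skipped")
  expect_false("GENE0001" %in% res$gene)
  planted <- res[res$gene %in% b$truth$signature_genes, ]
  expect_equal(nrow(planted), length(b$truth$signature_genes))
  expect_true(all(planted$p < 1e-4))
  expect_true(all(planted$HR > 1))
  # null genes retained at roughly the nominal rate
  null_genes <- setdiff(colnames(b$expr), b$truth$subtype_genes)[1:500]
  kept <- mean(null_genes %in% res$gene)
  expect_gt(kept, 0.02); expect_lt(kept, 0.09)
})

test_that("the model input gene set is a strict three-way intersection", {
  expect_setequal(build_input_geneset(c("a", "b"), c("b", "a"), c("a", "b")),
                  c("a", "b"))
  expect_error(build_input_geneset(c("a"), c("b"), c("c")), "empty")
  expect_error(build_input_geneset(character(), "a", "b"), "non-empty")
})

test_that("time-dependent AUC reduces to the plain AUC without censoring", {
  set.seed(94)
  n <- 80
  time <- rexp(n); event <- rep(1L, n); scores <- rnorm(n)
  h <- median(time)
  case <- time <= h; ctrl <- time > h
  plain <- mean(outer(scores[case], scores[ctrl], ">") +
                  0.5 * outer(scores[case], scores[ctrl], "=="))
  expect_equal(time_dependent_auc(scores, time, event, h), plain,
               tolerance = 1e-12)
})

test_that("an oracle risk score discriminates at every yearly horizon", {
  b <- simulate_bulk_cohort(sim_config(seed = 95, n_samples = 250))
  cl <- b$clinical
  auc <- vapply(12 * (1:5), function(h)
    time_dependent_auc(b$truth$lp, cl$time, cl$event, h), numeric(1))
  auc <- auc[!is.na(auc)]
  expect_gt(length(auc), 0)
  expect_true(all(auc > 0.8))
})

test_that("median stratification splits evenly and degenerate scores warn", {
  b <- simulate_bulk_cohort(small_sc_config(seed = 96, n_samples = 101))
  scores <- seq_len(101)  # distinct
  st <- stratify_and_evaluate(scores, b)
  expect_equal(as.integer(sort(table(st$group))), c(50L, 51L))
  expect_lt(st$logrank_p, 1.0000001)
  expect_warning(st2 <- stratify_and_evaluate(rep(1, 101), b),
                 "degenerate")
  expect_true(is.na(st2$logrank_p))
})

test_that("the model grid is deterministic and its leaderboard well-formed", {
  cfg <- small_sc_config(seed = 97, n_samples = 120)
  train <- simulate_bulk_cohort(cfg)
  cfg2 <- cfg; cfg2$seed <- 98L
  test1 <- simulate_bulk_cohort(cfg2)
  genes <- train$truth$signature_genes
  g1 <- fit_model_grid(train, list(test1), genes,
                       selectors = "none", seed = 5)
  g2 <- fit_model_grid(train, list(test1), genes,
                       selectors = "none", seed = 5)
  expect_identical(g1$leaderboard, g2$leaderboard)
  expect_equal(nrow(g1$leaderboard), 6)
  expect_false(is.unsorted(-g1$leaderboard$mean_test_cindex))
  expect_true(all(g1$leaderboard$train_cindex > 0.5))
  best <- g1$best
  expect_true(all(best$features %in% genes))
  expect_equal(length(best$predict(test1$expr)), 120)
})

test_that("selected features never leave the input gene set", {
  cfg <- small_sc_config(seed = 99, n_samples = 150)
  train <- simulate_bulk_cohort(cfg)
  genes <- c(train$truth$signature_genes, "GENE0002", "GENE0003")
  tp <- list(x = train$expr[, genes], time = train$clinical$time,
             event = train$clinical$event)
  for (sel in c("lasso", "stepwise", "rsf_importance")) {
    feats <- scregulon:::select_features(sel, tp$x, tp$time, tp$event,
                                         seed = 2)
    expect_true(all(feats %in% genes))
  }
})
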