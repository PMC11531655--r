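cohort_parts <- function(cohort, genes = NULL) {
  x <- as.matrix(cohort$expr)
  if (!is.null(genes)) x <- x[, genes, drop = FALSE]
  list(x = x, time = cohort$clinical$time,
       event = cohort$clinical$event)
}

#' Univariate Cox proportional-hazards screening
#'
#' Fits one Cox model per gene (Efron tie handling, tight convergence
#' tolerance) and keeps genes with p below the threshold. Constant genes
#' and non-converging fits are skipped with a warning.
#'
#' @param cohort a survival cohort (samples x genes \code{expr} +
#'   \code{clinical} with time/event).
#' @param genes genes to screen (default: all columns).
#' @param p_thresh retention threshold on the Wald p-value (default 0.05).
#' @return data frame (gene, HR, p) for retained genes, sorted by p.
#' @export
cox_screen <- function(cohort, genes = NULL, p_thresh = 0.05) {
  parts <- cohort_parts(cohort, genes)
  if (sum(parts$event) < 10)
    stop("cox_screen needs at least 10 events", call. = FALSE)
  y <- survival::Surv(parts$time, parts$event)
  ctrl <- survival::coxph.control(eps = 1e-8, iter.max = 50)
  skipped <- 0L
  rows <- lapply(colnames(parts$x), function(g) {
    x <- parts$x[, g]
    if (stats::sd(x) == 0) { skipped <<- skipped + 1L; return(NULL) }
    fit <- tryCatch(
      survival::coxph(y ~ x, ties = "efron", control = ctrl),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit) || is.na(stats::coef(fit))) {
      skipped <<- skipped + 1L; return(NULL)
    }
    s <- summary(fit)$coefficients
    data.frame(gene = g, HR = s[1, "exp(coef)"], p = s[1, "Pr(>|z|)"],
               stringsAsFactors = FALSE)
  })
  if (skipped)
    warning(skipped, " genes skipped (constant or non-converging)",
            call. = FALSE)
  out <- do.call(rbind, rows)
  out <- out[out$p < p_thresh, , drop = FALSE]
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect Cox, differential and subtype gene lists
#'
#' The model-input gene set is the three-way intersection of univariate-Cox
#' prognostic genes, differentially expressed genes, and subtype signature
#' genes; the Venn counts are logged.
#'
#' @param cox_genes,de_genes,subtype_genes non-empty character vectors.
#' @return character vector (sorted) of the intersection.
#' @export
build_input_geneset <- function(cox_genes, de_genes, subtype_genes) {
  if (!length(cox_genes) || !length(de_genes) || !length(subtype_genes))
    stop("all three gene lists must be non-empty", call. = FALSE)
  inter <- sort(Reduce(intersect, list(cox_genes, de_genes, subtype_genes)))
  message("build_input_geneset: |cox|=", length(unique(cox_genes)),
          " |de|=", length(unique(de_genes)),
          " |subtype|=", length(unique(subtype_genes)),
          " |intersection|=", length(inter))
  if (!length(inter))
    stop("empty three-way intersection of cox/de/subtype genes",
         call. = FALSE)
  inter
}

#' Harrell's concordance index
#'
#' Over comparable pairs (the earlier time has an observed event), a pair is
#' concordant when the higher risk score belongs to the shorter survival
#' time; score ties count 0.5. Satisfies
#' \code{cindex(s) + cindex(-s) = 1} in the absence of score ties and is
#' invariant to strictly monotone transforms of the scores.
#'
#' @param scores numeric risk scores (higher = worse).
#' @param time survival/censoring times.
#' @param event event indicator (1 = event, 0 = censored).
#' @return concordance in \[0, 1\]; zero comparable pairs is an error.
#' @export
cindex <- function(scores, time, event) {
  stopifnot(length(scores) == length(time), length(time) == length(event))
  dt <- outer(time, time, "<")           # dt[i,j]: t_i < t_j
  comparable <- dt & (event == 1)        # row i must have an event
  n_comp <- sum(comparable)
  if (n_comp == 0)
    stop("no comparable pairs: concordance undefined", call. = FALSE)
  ds <- outer(scores, scores, "-")
  conc <- sum(comparable & ds > 0) + 0.5 * sum(comparable & ds == 0)
  conc / n_comp
}

#' Time-dependent ROC AUC with censoring weights
#'
#' Cumulative-case / dynamic-control AUC at a fixed horizon: cases are
#' samples with an observed event by the horizon, controls are samples
#' still at risk after it; both are weighted by the inverse probability of
#' censoring from the Kaplan-Meier estimate of the censoring distribution.
#'
#' @param scores numeric risk scores (higher = worse).
#' @param time,event survival data.
#' @param horizon evaluation time (same units as \code{time}).
#' @return AUC in \[0, 1\] (NA when there are no cases or no controls).
#' @export
time_dependent_auc <- function(scores, time, event, horizon) {
  cens_fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G <- stats::stepfun(cens_fit$time, c(1, cens_fit$surv))
  case <- which(time <= horizon & event == 1)
  ctrl <- which(time > horizon)
  if (!length(case) || !length(ctrl)) return(NA_real_)
  wc <- 1 / pmax(G(pmin(time[case], horizon) - 1e-12), 1e-8)
  wk <- rep(1 / pmax(G(horizon), 1e-8), length(ctrl))
  ds <- outer(scores[case], scores[ctrl], "-")
  wmat <- outer(wc, wk)
  sum(wmat * ((ds > 0) + 0.5 * (ds == 0))) / sum(wmat)
}

# ---- model registry --------------------------------------------------

fit_cox_glmnet <- function(x, time, event, alpha, seed) {
  set.seed(seed)
  foldid <- sample(rep_len(1:5, nrow(x)))
  cv <- glmnet::cv.glmnet(x, survival::Surv(time, event), family = "cox",
                          alpha = alpha, foldid = foldid, nfolds = 5)
  list(predict = function(newx)
    as.numeric(stats::predict(cv, newx = newx[, rownames(cv$glmnet.fit$beta),
                                              drop = FALSE],
                              s = "lambda.min", type = "link")),
    features = rownames(cv$glmnet.fit$beta)[
      as.numeric(stats::coef(cv, s = "lambda.min")) != 0])
}

fit_cox_stepwise <- function(x, time, event) {
  df <- data.frame(x, check.names = FALSE)
  safe <- make.names(colnames(df)); map <- stats::setNames(colnames(df), safe)
  colnames(df) <- safe
  df$.time <- time; df$.event <- event
  full <- survival::coxph(survival::Surv(.time, .event) ~ .,
                          data = df, ties = "efron",
                          control = survival::coxph.control(iter.max = 50))
  fit <- tryCatch(
    suppressWarnings(stats::step(full, direction = "both", trace = 0)),
    error = function(e) full)
  feats <- intersect(names(stats::coef(fit)), safe)
  list(predict = function(newx) {
    nd <- data.frame(newx, check.names = FALSE)
    colnames(nd) <- make.names(colnames(nd))
    as.numeric(stats::predict(fit, newdata = nd, type = "lp"))
  }, features = unname(map[feats]))
}

# Componentwise likelihood boosting for the Cox model: at each step the
# single feature whose univariate update (with the current linear predictor
# as offset) most improves the partial likelihood is advanced by a damped
# Newton step.
fit_cox_boost <- function(x, time, event, steps = 50, nu = 0.1) {
  y <- survival::Surv(time, event)
  beta <- stats::setNames(numeric(ncol(x)), colnames(x))
  eta <- rep(0, nrow(x))
  ctrl <- survival::coxph.control(iter.max = 25)
  for (s in seq_len(steps)) {
    best <- NULL
    for (j in seq_len(ncol(x))) {
      fit <- tryCatch(
        survival::coxph(y ~ x[, j] + offset(eta), ties = "efron",
                        control = ctrl),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(fit) || is.na(stats::coef(fit))) next
      ll <- fit$loglik[2]
      if (is.null(best) || ll > best$ll)
        best <- list(j = j, b = unname(stats::coef(fit)), ll = ll)
    }
    if (is.null(best)) break
    beta[best$j] <- beta[best$j] + nu * best$b
    eta <- as.numeric(x %*% beta)
  }
  list(predict = function(newx)
    as.numeric(newx[, names(beta), drop = FALSE] %*% beta),
    features = names(beta)[beta != 0])
}

fit_rsf <- function(x, time, event, seed, num_trees = 500,
                    importance = "none") {
  df <- data.frame(x, check.names = FALSE)
  safe <- make.names(colnames(df)); map <- stats::setNames(colnames(df), safe)
  colnames(df) <- safe
  df$.time <- time; df$.event <- event
  fit <- ranger::ranger(survival::Surv(.time, .event) ~ ., data = df,
                        num.trees = num_trees, seed = seed,
                        importance = importance,
                        respect.unordered.factors = TRUE)
  list(predict = function(newx) {
    nd <- data.frame(newx, check.names = FALSE)
    colnames(nd) <- make.names(colnames(nd))
    rowSums(stats::predict(fit, data = nd)$chf)  # ensemble mortality
  },
  importance = if (importance != "none")
    stats::setNames(fit$variable.importance, map[names(fit$variable.importance)])
  else NULL,
  features = unname(map[safe]))
}

grid_selectors <- function() c("none", "lasso", "stepwise", "rsf_importance")
grid_models <- function() c("rsf", "lasso", "ridge", "enet", "stepwise",
                            "coxboost")

select_features <- function(selector, x, time, event, seed) {
  feats <- switch(
    selector,
    none = colnames(x),
    lasso = fit_cox_glmnet(x, time, event, alpha = 1, seed)$features,
    stepwise = fit_cox_stepwise(x, time, event)$features,
    rsf_importance = {
      imp <- fit_rsf(x, time, event, seed, num_trees = 300,
                     importance = "permutation")$importance
      names(imp)[imp > 0]
    })
  if (length(feats) < 2) feats <- colnames(x)  # degenerate selection
  feats
}

fit_final <- function(model, x, time, event, seed) {
  switch(model,
         rsf = fit_rsf(x, time, event, seed),
         lasso = fit_cox_glmnet(x, time, event, alpha = 1, seed),
         ridge = fit_cox_glmnet(x, time, event, alpha = 0, seed),
         enet = fit_cox_glmnet(x, time, event, alpha = 0.5, seed),
         stepwise = fit_cox_stepwise(x, time, event),
         coxboost = fit_cox_boost(x, time, event))
}

#' Multi-algorithm survival model grid with C-index leaderboard
#'
#' Crosses feature selectors (none, lasso-Cox, stepwise-Cox,
#' RSF permutation importance) with final models (random survival forest,
#' lasso/ridge/elastic-net Cox, stepwise Cox, componentwise-boosting Cox),
#' excluding the redundant selector = final pairs. Every combination is
#' fitted on the training cohort with a fixed seed and evaluated frozen on
#' each test cohort; the leaderboard ranks combinations by mean test
#' C-index. Cohorts with fewer than 10 events are excluded with a warning.
#'
#' @param train training cohort (\code{expr} samples x genes +
#'   \code{clinical}).
#' @param tests list of test cohorts.
#' @param geneset model input genes (intersected with every cohort's genes,
#'   logged).
#' @param selectors,models subsets of the registry (defaults: all).
#' @param seed RNG seed shared by all stochastic fits.
#' @return list: \code{leaderboard} (selector, model, train C-index, one
#'   column per test cohort, mean test C-index; sorted descending),
#'   \code{best} (risk_model for the top row), \code{models} (all fitted
#'   risk_model objects).
#' @export
fit_model_grid <- function(train, tests, geneset,
                           selectors = grid_selectors(),
                           models = grid_models(), seed = 1L) {
  genes <- Reduce(intersect, c(list(geneset, colnames(train$expr)),
                               lapply(tests, function(co)
                                 colnames(co$expr))))
  if (length(genes) < length(unique(geneset)))
    message("fit_model_grid: gene set restricted to ", length(genes),
            " genes shared by all cohorts")
  if (length(genes) < 2) stop("fewer than 2 usable genes", call. = FALSE)
  keep <- vapply(tests, function(co) sum(co$clinical$event) >= 10, TRUE)
  if (any(!keep)) {
    warning(sum(!keep), " test cohorts excluded with < 10 events",
            call. = FALSE)
    tests <- tests[keep]
  }
  tp <- cohort_parts(train, genes)
  if (sum(tp$event) < 10)
    stop("training cohort has fewer than 10 events", call. = FALSE)
  test_parts <- lapply(tests, cohort_parts, genes = genes)

  combos <- expand.grid(selector = selectors, model = models,
                        stringsAsFactors = FALSE)
  same <- (combos$selector == "lasso" & combos$model == "lasso") |
    (combos$selector == "stepwise" & combos$model == "stepwise")
  combos <- combos[!same, , drop = FALSE]

  sel_cache <- list()
  fitted <- vector("list", nrow(combos))
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    sel <- combos$selector[i]; mod <- combos$model[i]
    if (is.null(sel_cache[[sel]]))
      sel_cache[[sel]] <- select_features(sel, tp$x, tp$time, tp$event,
                                          seed)
    feats <- sel_cache[[sel]]
    fit <- fit_final(mod, tp$x[, feats, drop = FALSE], tp$time, tp$event,
                     seed)
    train_scores <- fit$predict(tp$x[, feats, drop = FALSE])
    tr_c <- cindex(train_scores, tp$time, tp$event)
    te_c <- vapply(test_parts, function(p)
      cindex(fit$predict(p$x[, feats, drop = FALSE]), p$time, p$event),
      numeric(1))
    fitted[[i]] <- structure(
      list(selector = sel, model = mod, features = feats,
           predict = local({
             f <- fit; fe <- feats
             function(newx) f$predict(as.matrix(newx)[, fe, drop = FALSE])
           }),
           train_scores = train_scores, train_cindex = tr_c,
           test_cindex = te_c),
      class = "risk_model")
    rows[[i]] <- data.frame(selector = sel, model = mod,
                            train_cindex = tr_c,
                            t(stats::setNames(
                              te_c, paste0("test", seq_along(te_c)))),
                            mean_test_cindex = mean(te_c),
                            stringsAsFactors = FALSE)
  }
  lb <- do.call(rbind, rows)
  ord <- order(-lb$mean_test_cindex, lb$selector, lb$model)
  lb <- lb[ord, , drop = FALSE]
  rownames(lb) <- NULL
  list(leaderboard = lb, best = fitted[[ord[1]]], models = fitted[ord])
}

#' Risk stratification, survival curves and time-dependent ROC
#'
#' Scores a cohort with a fitted risk model, splits at the median training
#' score into high/low risk groups, compares them by Kaplan-Meier and
#' log-rank, and reports the IPCW time-dependent ROC AUC at the requested
#' horizons (years 1-5 by default).
#'
#' @param model a \code{risk_model} from \code{\link{fit_model_grid}}, or a
#'   numeric score vector.
#' @param cohort cohort to evaluate.
#' @param horizons evaluation times in months (default 12, 24, ..., 60).
#' @param cutoff risk-group cutoff; defaults to the median training score
#'   (median of \code{scores} when a bare vector is given).
#' @return list: scores, group factor (high/low), km (survfit),
#'   logrank_chisq, logrank_p, auc (data frame horizon/auc), cindex.
#' @export
stratify_and_evaluate <- function(model, cohort, horizons = 12 * (1:5),
                                  cutoff = NULL) {
  if (inherits(model, "risk_model")) {
    scores <- model$predict(as.matrix(cohort$expr))
    if (is.null(cutoff)) cutoff <- stats::median(model$train_scores)
  } else {
    scores <- as.numeric(model)
    if (is.null(cutoff)) cutoff <- stats::median(scores)
  }
  cl <- cohort$clinical
  group <- factor(ifelse(scores > cutoff, "high", "low"),
                  levels = c("low", "high"))
  out <- list(scores = scores, group = group,
              cindex = cindex(scores, cl$time, cl$event),
              auc = data.frame(
                horizon = horizons,
                auc = vapply(horizons, function(h)
                  time_dependent_auc(scores, cl$time, cl$event, h),
                  numeric(1))))
  if (length(unique(group)) < 2) {
    warning("degenerate scores: all samples in one risk group; ",
            "log-rank skipped", call. = FALSE)
    out$km <- NULL; out$logrank_chisq <- NA_real_; out$logrank_p <- NA_real_
  } else {
    sf <- survival::survfit(survival::Surv(cl$time, cl$event) ~ group)
    sd <- survival::survdiff(survival::Surv(cl$time, cl$event) ~ group)
    out$km <- sf
    out$logrank_chisq <- unname(sd$chisq)
    out$logrank_p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  }
  out
}
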