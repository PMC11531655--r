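#' Aggregate cells into meta-cells
#'
#' Runs PCA on the (log-normalized, HVG-restricted) matrix, k-means with
#' \code{k = n_metacells} on the top \code{n_pcs} components, and averages
#' member columns into meta-cell profiles. When \code{n_metacells} equals
#' the number of cells, cells map to themselves. On an empty-cluster
#' failure the clustering is re-seeded once before erroring.
#'
#' @param m genes x cells matrix.
#' @param n_metacells number of meta-cells (< number of cells, or equal for
#'   the identity mapping).
#' @param n_pcs principal components used for clustering.
#' @param seed RNG seed for k-means.
#' @param condition optional per-cell condition labels; the meta-cell label
#'   is the member majority vote.
#' @return list with \code{profiles} (genes x meta-cells mean expression),
#'   \code{membership} (cell -> meta-cell integer map) and \code{condition}
#'   (per-meta-cell majority label, if supplied).
#' @export
build_metacells <- function(m, n_metacells, n_pcs = 20, seed = 1L,
                            condition = NULL) {
  n <- ncol(m)
  if (n_metacells > n)
    stop("'n_metacells' exceeds the number of cells", call. = FALSE)
  if (n_metacells == n) {
    member <- seq_len(n)
  } else {
    x <- as.matrix(Matrix::t(m))
    n_pcs <- min(n_pcs, ncol(x) - 1L, n - 1L)
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)
    km <- NULL
    for (attempt in 0:1) {
      set.seed(seed + attempt)
      km <- tryCatch(
        stats::kmeans(pc$x, centers = n_metacells, iter.max = 100,
                      nstart = 1),
        error = function(e) NULL)
      if (!is.null(km) && all(km$size > 0)) break
    }
    if (is.null(km) || any(km$size == 0))
      stop("meta-cell clustering produced an empty cluster twice",
           call. = FALSE)
    member <- km$cluster
  }
  idx <- split(seq_len(n), member)
  profiles <- vapply(idx, function(j)
    Matrix::rowMeans(m[, j, drop = FALSE]), numeric(nrow(m)))
  rownames(profiles) <- rownames(m)
  colnames(profiles) <- sprintf("MC%04d", seq_along(idx))
  cond <- NULL
  if (!is.null(condition))
    cond <- vapply(idx, function(j)
      names(which.max(table(condition[j]))), "")
  list(profiles = profiles, membership = member, condition = cond)
}

#' Infer a co-expression network between TFs and targets
#'
#' For every non-TF gene, regresses the target's profile on all TF profiles
#' and converts the fit into per-TF edge importances. \code{method = "gbm"}
#' (default) fits a gradient-boosted stump ensemble and uses each TF's
#' share of the total split gain, scaled by the ensemble's explained
#' variance so that poorly predicted (noise) targets cannot emit
#' high-importance edges. \code{method = "lm"} uses the squared
#' t-statistic share of a joint linear model, likewise scaled by R-squared
#' — a fast conditional alternative. \code{method = "spearman"} is the
#' cheap marginal baseline (normalized absolute Spearman correlation,
#' scaled by the strongest correlation). In every case importances are
#' non-negative and sum to at most 1 per target; edges with importance > 0
#' are returned sorted by descending importance.
#'
#' Attribution among co-active TFs of the same module relies on each TF's
#' private activity component, so the profile matrix should preserve
#' single-cell (or fine meta-cell) resolution; coarse averaging removes
#' exactly that component.
#'
#' @param mc genes x cells or genes x meta-cells profile matrix (or the
#'   list returned by \code{\link{build_metacells}}).
#' @param tfs character vector of TF symbols; TFs absent from the matrix are
#'   dropped with a warning.
#' @param method "gbm", "lm" or "spearman".
#' @param seed RNG seed for the tree ensemble.
#' @param nrounds,max_depth,eta boosting hyperparameters (fixed defaults:
#'   15 stumps, learning rate 0.5).
#' @return data frame with columns \code{tf}, \code{target},
#'   \code{importance}.
#' @export
infer_coexpression <- function(mc, tfs, method = c("gbm", "lm", "spearman"),
                               seed = 1L, nrounds = 15, max_depth = 1,
                               eta = 0.5) {
  method <- match.arg(method)
  if (is.list(mc) && !is.null(mc$profiles)) mc <- mc$profiles
  if (ncol(mc) < 20)
    stop("co-expression inference needs at least 20 profiles",
         call. = FALSE)
  present <- intersect(tfs, rownames(mc))
  if (length(present) < length(tfs))
    warning(length(tfs) - length(present),
            " TFs absent from the matrix were dropped", call. = FALSE)
  if (length(present) < 2)
    stop("fewer than 2 TFs present in the matrix", call. = FALSE)
  targets <- setdiff(rownames(mc), present)
  X <- t(as.matrix(mc[present, , drop = FALSE]))
  colnames(X) <- present

  if (method == "spearman") {
    rx <- apply(X, 2, rank)
    Y <- apply(t(as.matrix(mc[targets, , drop = FALSE])), 2, rank)
    cc <- abs(stats::cor(rx, Y))
    cc[is.na(cc)] <- 0
    shares <- sweep(cc, 2, pmax(colSums(cc), .Machine$double.eps), "/")
    shares <- sweep(shares, 2, apply(cc, 2, max), "*")
    edges <- data.frame(
      tf = rep(present, times = length(targets)),
      target = rep(targets, each = length(present)),
      importance = as.vector(shares), stringsAsFactors = FALSE)
  } else if (method == "lm") {
    Xs <- scale(X)
    Xs[is.na(Xs)] <- 0
    res <- lapply(targets, function(g) {
      y <- as.numeric(mc[g, ])
      if (stats::sd(y) == 0) return(NULL)
      f <- stats::lm.fit(cbind(1, Xs), y)
      s2 <- sum(f$residuals^2) / f$df.residual
      se <- sqrt(diag(chol2inv(qr.R(f$qr))) * s2)
      t2 <- ((f$coefficients / se)[-1])^2
      t2[!is.finite(t2)] <- 0
      r2 <- max(0, 1 - sum(f$residuals^2) / sum((y - mean(y))^2))
      if (sum(t2) == 0) return(NULL)
      data.frame(tf = present, target = g,
                 importance = t2 / sum(t2) * r2, stringsAsFactors = FALSE)
    })
    edges <- do.call(rbind, res)
  } else {
    set.seed(seed)
    params <- list(max_depth = max_depth, eta = eta, nthread = 1,
                   subsample = 1, colsample_bytree = 1,
                   objective = "reg:squarederror")
    res <- lapply(targets, function(g) {
      y <- as.numeric(mc[g, ])
      if (stats::sd(y) == 0) return(NULL)
      d <- xgboost::xgb.DMatrix(X, label = y)
      bst <- xgboost::xgb.train(params = params, data = d,
                                nrounds = nrounds, verbose = 0)
      imp <- xgboost::xgb.importance(model = bst)
      if (is.null(imp) || nrow(imp) == 0) return(NULL)
      r2 <- max(0, 1 - mean((y - stats::predict(bst, d))^2) /
                  stats::var(y))
      data.frame(tf = imp$Feature, target = g,
                 importance = imp$Gain * r2, stringsAsFactors = FALSE)
    })
    edges <- do.call(rbind, res)
  }
  if (is.null(edges)) edges <- data.frame(tf = character(),
                                          target = character(),
                                          importance = numeric())
  edges <- edges[edges$importance > 0, , drop = FALSE]
  edges <- edges[order(-edges$importance, edges$tf, edges$target), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Assemble regulons from a co-expression edge table and a motif prior
#'
#' Keeps an edge (tf, target) only when the target is a candidate of that TF
#' in the prior table (the stand-in for the motif-database pruning step),
#' groups surviving edges by TF, and drops regulons with fewer than
#' \code{min_regulon_size} targets. Targets are ordered by descending
#' importance; assembly is deterministic given edges and prior.
#'
#' @param edges data frame (tf, target, importance).
#' @param prior data frame (tf, target) of candidate pairs; pruning is
#'   mandatory, so an empty prior is an error.
#' @param min_regulon_size minimum surviving target count (default 10).
#' @return named list of \code{regulon} objects: \code{list(tf, targets,
#'   weights)}.
#' @export
assemble_regulons <- function(edges, prior, min_regulon_size = 10) {
  if (is.null(prior) || nrow(prior) == 0)
    stop("empty motif prior: prior-based pruning is mandatory",
         call. = FALSE)
  keep <- paste(edges$tf, edges$target) %in% paste(prior$tf, prior$target)
  edges <- edges[keep & edges$tf != edges$target, , drop = FALSE]
  out <- lapply(split(edges, edges$tf), function(e) {
    e <- e[order(-e$importance, e$target), , drop = FALSE]
    list(tf = e$tf[1], targets = e$target,
         weights = stats::setNames(e$importance, e$target))
  })
  out <- out[vapply(out, function(r) length(r$targets), 1L) >=
               min_regulon_size]
  out <- out[order(names(out))]
  lapply(out, function(r) structure(r, class = "regulon"))
}

#' Average precision of an edge ranking against planted truth
#'
#' Ranks emitted edges by descending importance and computes the average
#' precision (area under the precision-recall curve) against the planted
#' TF -> target map; planted edges never emitted count as never retrieved.
#'
#' @param edges data frame (tf, target, importance).
#' @param truth named list TF -> character vector of true targets.
#' @return average precision in \[0, 1\].
#' @export
edge_pr_auc <- function(edges, truth) {
  true_pairs <- unlist(lapply(names(truth), function(tf)
    paste(tf, truth[[tf]])), use.names = FALSE)
  ord <- order(-edges$importance)
  hits <- paste(edges$tf, edges$target)[ord] %in% true_pairs
  if (!length(true_pairs)) return(NA_real_)
  prec_at_hit <- cumsum(hits)[hits] / which(hits)
  sum(prec_at_hit) / length(true_pairs)
}

#' Mean Jaccard overlap of recovered regulons with planted regulons
#'
#' @param regulons list of regulon objects (from
#'   \code{\link{assemble_regulons}}).
#' @param truth named list TF -> true target vector; TFs with no recovered
#'   regulon score 0.
#' @return mean per-TF Jaccard index.
#' @export
regulon_jaccard <- function(regulons, truth) {
  rec <- stats::setNames(lapply(regulons, `[[`, "targets"),
                         vapply(regulons, `[[`, "", "tf"))
  j <- vapply(names(truth), function(tf) {
    a <- truth[[tf]]; b <- rec[[tf]]
    if (is.null(b)) return(0)
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1))
  mean(j)
}
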