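#' Differential expression by Wilcoxon rank-sum test
#'
#' Tests every gene between two groups with a two-sided Wilcoxon rank-sum
#' test (normal approximation with continuity correction) on log-normalized
#' expression; logFC is the difference of group means on the log2 scale
#' (group1 - group2, group order = sorted label order unless the labels are
#' factors). P-values are Benjamini-Hochberg adjusted.
#'
#' @param m genes x samples (or cells) log-normalized matrix; values are
#'   converted to log2 units for the fold change.
#' @param groups two-level label vector; both groups need >= 3 columns.
#' @return data frame: gene, logFC, p, adj_p (one row per tested gene).
#' @export
differential_expression <- function(m, groups) {
  g <- if (is.factor(groups)) droplevels(groups) else factor(groups)
  if (nlevels(g) != 2)
    stop("differential expression needs exactly 2 groups", call. = FALSE)
  if (any(table(g) < 3))
    stop("both groups need at least 3 samples", call. = FALSE)
  i1 <- which(g == levels(g)[1])
  i2 <- which(g == levels(g)[2])
  mm <- as.matrix(m) / log(2)  # natural-log input -> log2 units
  res <- t(apply(mm, 1, function(x) {
    lfc <- mean(x[i1]) - mean(x[i2])
    p <- if (stats::sd(x) == 0) 1 else
      suppressWarnings(stats::wilcox.test(x[i1], x[i2],
                                          exact = FALSE)$p.value)
    c(lfc, p)
  }))
  out <- data.frame(gene = rownames(m), logFC = res[, 1], p = res[, 2],
                    adj_p = stats::p.adjust(res[, 2], "BH"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Regulon-and-DE signature construction
#'
#' Intersects a regulon's genes (targets plus the TF itself) with the genes
#' passing the differential-expression thresholds (adjusted p < adj_p and
#' |logFC| > logfc; set \code{direction = "up"} to require logFC > logfc
#' only).
#'
#' @param regulon a regulon object or character vector of genes.
#' @param de a \code{\link{differential_expression}} table.
#' @param adj_p,logfc selection thresholds (defaults 0.05 and 1).
#' @param direction "both" (|logFC|) or "up" (signed logFC).
#' @return character vector of signature genes.
#' @export
build_signature <- function(regulon, de, adj_p = 0.05, logfc = 1,
                            direction = c("both", "up")) {
  direction <- match.arg(direction)
  genes <- if (is.list(regulon)) c(regulon$tf, regulon$targets)
           else regulon
  pass <- de$adj_p < adj_p &
    (if (direction == "both") abs(de$logFC) > logfc else de$logFC > logfc)
  sig <- intersect(genes, de$gene[pass])
  if (!length(sig))
    stop("empty signature: no regulon gene passes the DE thresholds; ",
         "review adj_p/logfc", call. = FALSE)
  message("build_signature: ", length(sig), "/", length(genes),
          " regulon genes pass the DE thresholds")
  sig
}

#' Consensus clustering for subtype discovery
#'
#' For each candidate k, repeatedly subsamples samples (fraction
#' \code{sample_frac}) and features (fraction \code{feature_frac}), runs
#' k-means on the subsample, and accumulates co-assignment frequencies over
#' co-sampled pairs into a consensus matrix. Final labels come from
#' hierarchical clustering (average linkage) of 1 - consensus; k is
#' selected by the largest relative delta-area of the consensus CDF
#' (reported and overridable downstream).
#'
#' @param x samples x features matrix (e.g. expression restricted to a
#'   signature).
#' @param k_range candidate cluster numbers (clipped with a warning to
#'   \[2, n/3\]).
#' @param n_resamples resampling iterations per k (>= 50 advised; >= 1
#'   enforced).
#' @param sample_frac sample subsampling fraction in (0.5, 1); 1 is allowed
#'   for the degenerate single-partition case.
#' @param feature_frac feature subsampling fraction.
#' @param seed RNG seed.
#' @return list of class \code{consensus_result}: \code{consensus} (list of
#'   matrices per k), \code{selected_k}, \code{labels} (for selected k),
#'   \code{labels_by_k}, \code{cdf_area}, \code{delta_area}.
#' @export
consensus_cluster <- function(x, k_range = 2:6, n_resamples = 100,
                              sample_frac = 0.8, feature_frac = 0.8,
                              seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  kmax <- max(2, floor(n / 3))
  if (any(k_range > kmax) || any(k_range < 2)) {
    warning("k_range clipped to [2, ", kmax, "]", call. = FALSE)
    k_range <- k_range[k_range >= 2 & k_range <= kmax]
  }
  if (!length(k_range)) stop("empty k_range after clipping", call. = FALSE)
  set.seed(seed)
  ns <- max(2, round(sample_frac * n))
  nf <- max(1, round(feature_frac * ncol(x)))
  consensus <- list()
  labels_by_k <- list()
  for (k in k_range) {
    co <- matrix(0, n, n)
    cnt <- matrix(0, n, n)
    for (b in seq_len(n_resamples)) {
      s <- sort(sample.int(n, ns))
      f <- sample.int(ncol(x), nf)
      km <- suppressWarnings(
        stats::kmeans(x[s, f, drop = FALSE], centers = k, iter.max = 50,
                      nstart = 1))
      cl <- km$cluster
      same <- outer(cl, cl, "==")
      co[s, s] <- co[s, s] + same
      cnt[s, s] <- cnt[s, s] + 1
    }
    cm <- ifelse(cnt > 0, co / cnt, 0)
    diag(cm) <- 1
    rownames(cm) <- colnames(cm) <- rownames(x)
    consensus[[as.character(k)]] <- cm
    hc <- stats::hclust(stats::as.dist(1 - cm), method = "average")
    labels_by_k[[as.character(k)]] <- stats::cutree(hc, k = k)
  }
  # CDF area over the off-diagonal consensus values, per k
  area <- vapply(consensus, function(cm) {
    v <- sort(cm[upper.tri(cm)])
    grid <- seq(0, 1, length.out = 101)
    cdf <- vapply(grid, function(t) mean(v <= t), numeric(1))
    sum(diff(grid) * cdf[-1])
  }, numeric(1))
  delta <- numeric(length(area))
  delta[1] <- area[1]
  if (length(area) > 1)
    delta[-1] <- diff(area) / area[-length(area)]
  names(delta) <- names(area)
  selected <- k_range[which.max(delta)]
  structure(list(consensus = consensus, selected_k = selected,
                 labels = labels_by_k[[as.character(selected)]],
                 labels_by_k = labels_by_k, cdf_area = area,
                 delta_area = delta, k_range = k_range),
            class = "consensus_result")
}

#' Compare survival and gene-set scores between subtypes
#'
#' Kaplan-Meier curves per subtype, the log-rank test between them, and
#' (optionally) per-set two-sided Wilcoxon comparisons of ssGSEA scores
#' with Benjamini-Hochberg adjustment.
#'
#' @param cohort a \code{bulk_sim} or list with \code{clinical}
#'   (time, event).
#' @param labels per-sample subtype labels (>= 2 levels).
#' @param set_scores optional samples x sets score matrix.
#' @return list: \code{km} (survfit object), \code{logrank_chisq},
#'   \code{logrank_p}, \code{set_table} (set, median per subtype, p,
#'   adj_p) when scores are given.
#' @export
compare_subtypes <- function(cohort, labels, set_scores = NULL) {
  cl <- cohort$clinical
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop("need at least 2 subtypes", call. = FALSE)
  ev <- tapply(cl$event, labels, sum)
  if (any(ev == 0))
    warning("subtype with zero events: log-rank may be unreliable",
            call. = FALSE)
  sf <- survival::survfit(survival::Surv(cl$time, cl$event) ~ labels)
  sd <- survival::survdiff(survival::Surv(cl$time, cl$event) ~ labels)
  p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1, lower.tail = FALSE)
  out <- list(km = sf, logrank_chisq = unname(sd$chisq), logrank_p = p)
  if (!is.null(set_scores)) {
    lev <- sort(unique(labels))
    tab <- do.call(rbind, lapply(colnames(set_scores), function(s) {
      x <- set_scores[, s]
      pv <- suppressWarnings(
        stats::wilcox.test(x[labels == lev[1]], x[labels == lev[2]],
                           exact = FALSE)$p.value)
      data.frame(set = s,
                 median_1 = stats::median(x[labels == lev[1]]),
                 median_2 = stats::median(x[labels == lev[2]]),
                 p = pv, stringsAsFactors = FALSE)
    }))
    names(tab)[2:3] <- paste0("median_", lev)
    tab$adj_p <- stats::p.adjust(tab$p, "BH")
    out$set_table <- tab
  }
  out
}
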