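# Per-cell descending expression ranks with ties broken by input gene
# order (stable): rank 1 = highest expression.
expression_ranks <- function(m) {
  n <- nrow(m)
  apply(as.matrix(m), 2, function(x) {
    r <- integer(n)
    r[order(-x)] <- seq_len(n)  # order() is stable: ties keep input order
    r
  })
}

aucell_from_ranks <- function(ranks, target_idx, K) {
  G <- length(target_idx)
  if (G == 0) return(rep(NA_real_, ncol(ranks)))
  max_area <- sum(pmin(seq_len(K), G))
  P <- ranks[target_idx, , drop = FALSE]
  contrib <- pmax(K - P + 1, 0)
  ras <- colSums(contrib) / max_area
  pmin(pmax(ras, 0), 1)
}

#' AUCell-style regulon activity score for one regulon
#'
#' Per cell, genes are ranked by descending expression (ties broken stably
#' by input gene order); the recovery curve counts regulon genes within the
#' top k ranks for k = 1..K with \code{K = floor(top_frac * n_genes)}; the
#' score is the exact area under this cumulative curve divided by the
#' maximal possible area (all regulon genes at the very top), clipped to
#' \[0, 1\]. The score depends on expression only through ranks, so it is
#' invariant to any monotone transform of a cell's expression values.
#'
#' @param m genes x cells expression matrix.
#' @param regulon a regulon object (\code{list(tf, targets, ...)}) or a
#'   character vector of target symbols.
#' @param top_frac fraction of top-ranked genes considered (default 0.05).
#' @return numeric vector of per-cell scores in \[0, 1\]; all-missing
#'   regulons yield NA with a warning.
#' @export
aucell_score <- function(m, regulon, top_frac = 0.05) {
  if (top_frac <= 0 || top_frac >= 1)
    stop("'top_frac' must be in (0, 1)", call. = FALSE)
  targets <- if (is.list(regulon)) regulon$targets else regulon
  idx <- which(rownames(m) %in% targets)
  if (length(idx) < length(targets))
    message("aucell_score: ", length(targets) - length(idx),
            " regulon genes absent from the matrix")
  if (!length(idx)) {
    warning("no regulon gene present in the matrix; returning NA",
            call. = FALSE)
    return(rep(NA_real_, ncol(m)))
  }
  K <- max(1L, floor(top_frac * nrow(m)))
  ranks <- expression_ranks(m)
  stats::setNames(aucell_from_ranks(ranks, idx, K), colnames(m))
}

#' Regulon activity matrix for a regulon collection
#'
#' Applies \code{\link{aucell_score}} to every regulon, sharing one rank
#' computation across regulons.
#'
#' @inheritParams aucell_score
#' @param regulons named list of regulon objects (or target vectors).
#' @return regulons x cells activity matrix with values in \[0, 1\].
#' @export
score_all <- function(m, regulons, top_frac = 0.05) {
  if (top_frac <= 0 || top_frac >= 1)
    stop("'top_frac' must be in (0, 1)", call. = FALSE)
  K <- max(1L, floor(top_frac * nrow(m)))
  ranks <- expression_ranks(m)
  rows <- lapply(regulons, function(r) {
    targets <- if (is.list(r)) r$targets else r
    idx <- which(rownames(m) %in% targets)
    if (!length(idx))
      warning("regulon with no gene in the matrix scored as NA",
              call. = FALSE)
    aucell_from_ranks(ranks, idx, K)
  })
  A <- do.call(rbind, rows)
  nm <- names(regulons)
  if (is.null(nm))
    nm <- vapply(regulons, function(r)
      if (is.list(r)) r$tf else NA_character_, "")
  dimnames(A) <- list(nm, colnames(m))
  A
}

#' Group-specific regulons by one-way ANOVA
#'
#' Tests every regulon's activity across cell groups with a one-way ANOVA,
#' adjusts p-values across regulons by Benjamini-Hochberg, and sorts by
#' adjusted p then descending F. Groups with fewer than 3 cells are
#' excluded with a warning.
#'
#' @param A regulons x cells activity matrix.
#' @param groups per-cell group labels (condition or cell type).
#' @return data frame: regulon, F, p, adj_p, then one mean column per group;
#'   sorted by adj_p and descending F.
#' @export
group_specific_regulons <- function(A, groups) {
  groups <- as.character(groups)
  tab <- table(groups)
  small <- names(tab)[tab < 3]
  if (length(small)) {
    warning("groups excluded with fewer than 3 cells: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !groups %in% small
    A <- A[, keep, drop = FALSE]
    groups <- groups[keep]
  }
  lev <- sort(unique(groups))
  if (length(lev) < 2)
    stop("fewer than 2 usable groups for ANOVA", call. = FALSE)
  g <- factor(groups, levels = lev)
  res <- t(apply(A, 1, function(y) {
    means <- tapply(y, g, mean)
    if (stats::sd(y) == 0) return(c(0, 1, means))
    ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
    c(unname(ft$statistic), unname(ft$p.value), means)
  }))
  out <- data.frame(regulon = rownames(A), F = res[, 1], p = res[, 2],
                    adj_p = stats::p.adjust(res[, 2], "BH"),
                    res[, -(1:2), drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out)[-(1:4)] <- paste0("mean_", lev)
  out <- out[order(out$adj_p, -out$F), , drop = FALSE]
  rownames(out) <- NULL
  out
}
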