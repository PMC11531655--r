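# Weighted Kolmogorov-Smirnov running-sum enrichment score for one set.
# scores must be sorted descending; hit increments are proportional to
# |score|^weight_p, miss decrements are uniform over non-members.
gsea_es <- function(hit, scores, weight_p = 1) {
  N <- length(hit)
  Nh <- sum(hit)
  if (Nh == 0 || Nh == N) return(0)
  w <- abs(scores)^weight_p
  wh <- w * hit
  denom <- sum(wh)
  if (denom == 0) wh[hit] <- 1 / Nh else wh <- wh / denom
  running <- cumsum(wh - (!hit) / (N - Nh))
  running[which.max(abs(running))]
}

#' Pre-ranked gene set enrichment analysis
#'
#' Computes the weighted Kolmogorov-Smirnov enrichment score on a ranked
#' gene list (hit increments proportional to |score|^\code{weight_p}, miss
#' decrements uniform), builds the null by gene-label permutation with a
#' fixed seed, normalizes sign-stratified
#' (\eqn{NES = ES / \mathrm{mean}(|ES_{null}|)} over same-sign nulls), and
#' adjusts p-values across gene sets by Benjamini-Hochberg. Ties in the
#' ranking are broken by symbol order.
#'
#' @param scores named numeric vector (gene-level statistic); no duplicate
#'   gene names.
#' @param gene_sets named list of character vectors.
#' @param weight_p enrichment weight (default 1).
#' @param n_perm number of gene-label permutations (>= 100).
#' @param seed RNG seed.
#' @param min_size sets with a smaller intersection with the ranking are
#'   skipped with a warning (default 3).
#' @return data frame: set, size, ES, NES, p, adj_p.
#' @export
gsea_preranked <- function(scores, gene_sets, weight_p = 1, n_perm = 1000,
                           seed = 1L, min_size = 3) {
  if (anyDuplicated(names(scores)))
    stop("duplicate gene names in the ranking", call. = FALSE)
  if (n_perm < 100) stop("'n_perm' must be >= 100", call. = FALSE)
  ord <- order(-scores, names(scores))
  scores <- scores[ord]
  genes <- names(scores)
  N <- length(genes)
  set.seed(seed)
  res <- lapply(names(gene_sets), function(nm) {
    members <- intersect(gene_sets[[nm]], genes)
    if (length(members) < min_size) {
      warning("gene set '", nm, "' skipped: fewer than ", min_size,
              " genes in the ranking", call. = FALSE)
      return(NULL)
    }
    hit <- genes %in% members
    es <- gsea_es(hit, scores, weight_p)
    Nh <- sum(hit)
    null_es <- vapply(seq_len(n_perm), function(b) {
      h <- logical(N)
      h[sample.int(N, Nh)] <- TRUE
      gsea_es(h, scores, weight_p)
    }, numeric(1))
    same <- null_es[sign(null_es) == sign(es)]
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    data.frame(set = nm, size = Nh, ES = es, NES = nes, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(set = character(), size = integer(), ES = numeric(),
                      NES = numeric(), p = numeric(), adj_p = numeric()))
  out$adj_p <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}

#' Single-sample gene set enrichment (ssGSEA) scores
#'
#' Per sample, genes are ranked by descending expression; the score of a set
#' is the sum over all ranks of the difference between the weighted hit CDF
#' (weights \eqn{(N - i + 1)^\alpha} for the gene at descending position i)
#' and the uniform miss CDF. Depending only on ranks, the score is
#' invariant to monotone transforms of a sample's expression.
#'
#' @param expr genes x samples expression matrix.
#' @param sets named list of character vectors.
#' @param alpha rank-weighting exponent (default 0.25, must be > 0).
#' @param normalize min-max normalize each set's scores across samples.
#' @param min_size sets with fewer overlapping genes are skipped with a
#'   warning.
#' @return samples x sets score matrix.
#' @export
ssgsea_score <- function(expr, sets, alpha = 0.25, normalize = FALSE,
                         min_size = 3) {
  if (alpha <= 0) stop("'alpha' must be positive", call. = FALSE)
  genes <- rownames(expr)
  N <- length(genes)
  keep <- vapply(sets, function(s) length(intersect(s, genes)) >= min_size,
                 TRUE)
  if (any(!keep))
    warning(sum(!keep), " gene sets skipped: fewer than ", min_size,
            " genes in the matrix", call. = FALSE)
  sets <- sets[keep]
  member <- lapply(sets, function(s) genes %in% s)
  scores <- apply(as.matrix(expr), 2, function(x) {
    o <- order(-x, seq_along(x))
    rank_desc <- integer(N)
    rank_desc[o] <- seq_len(N)
    w <- (N - rank_desc + 1)^alpha  # weight by descending-rank position
    vapply(member, function(hit) {
      hit_o <- hit[o]
      wh <- w[o] * hit_o
      hit_cdf <- cumsum(wh) / sum(wh)
      miss_cdf <- cumsum(!hit_o) / (N - sum(hit_o))
      sum(hit_cdf - miss_cdf)
    }, numeric(1))
  })
  out <- t(matrix(scores, nrow = length(sets),
                  dimnames = list(names(sets), colnames(expr))))
  if (normalize && nrow(out) > 1) {
    rng <- apply(out, 2, range)
    span <- pmax(rng[2, ] - rng[1, ], .Machine$double.eps)
    out <- sweep(sweep(out, 2, rng[1, ], "-"), 2, span, "/")
  }
  out
}
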