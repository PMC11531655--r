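# Independent brute-force oracles. These deliberately re-derive each
# statistic from its definition with plain loops, sharing no code with the
# package implementations they check.

# Recovery-curve AUC for one cell: rank genes by descending expression
# (ties by input order), walk k = 1..K counting regulon genes seen so far,
# and normalize by the best achievable area.
brute_aucell <- function(x, targets, top_frac) {
  n <- length(x)
  K <- max(1, floor(top_frac * n))
  ord <- order(-x)  # stable
  is_target <- names(x)[ord] %in% targets
  G <- sum(names(x) %in% targets)
  if (G == 0) return(NA_real_)
  curve <- numeric(K)
  seen <- 0
  for (k in 1:K) {
    if (is_target[k]) seen <- seen + 1
    curve[k] <- seen
  }
  best <- numeric(K)
  for (k in 1:K) best[k] <- min(k, G)
  sum(curve) / sum(best)
}

# CSI by definition: count third parties below both correlations minus the
# margin, via an explicit triple loop.
brute_csi <- function(A, delta) {
  r <- stats::cor(t(A))
  N <- nrow(A)
  out <- matrix(0, N, N, dimnames = dimnames(r))
  for (i in 1:N) for (j in 1:N) {
    if (i == j) { out[i, j] <- 1; next }
    cnt <- 0
    for (k in 1:N) {
      if (k == i || k == j) next
      if (r[i, k] < r[i, j] - delta && r[j, k] < r[i, j] - delta)
        cnt <- cnt + 1
    }
    out[i, j] <- cnt / (N - 2)
  }
  out
}

# Harrell's C by exhaustive pair enumeration.
brute_cindex <- function(scores, time, event) {
  conc <- 0; comp <- 0
  n <- length(scores)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      comp <- comp + 1
      if (scores[i] > scores[j]) conc <- conc + 1
      else if (scores[i] == scores[j]) conc <- conc + 0.5
    }
  }
  if (comp == 0) return(NA_real_)
  conc / comp
}

# Weighted KS enrichment score traced step by step.
brute_gsea_es <- function(ranked_scores, set, weight_p = 1) {
  genes <- names(ranked_scores)
  N <- length(genes)
  hits <- genes %in% set
  Nh <- sum(hits)
  if (Nh == 0 || Nh == N) return(0)
  wsum <- sum(abs(ranked_scores[hits])^weight_p)
  running <- 0
  best <- 0
  for (i in 1:N) {
    if (hits[i]) running <- running + abs(ranked_scores[i])^weight_p / wsum
    else running <- running - 1 / (N - Nh)
    if (abs(running) > abs(best)) best <- running
  }
  unname(best)
}

# ssGSEA score of one sample by direct summation.
brute_ssgsea <- function(x, set, alpha = 0.25) {
  N <- length(x)
  ord <- order(-x, seq_along(x))
  hits <- names(x)[ord] %in% set
  Nh <- sum(hits)
  w <- (N - seq_len(N) + 1)^alpha
  hit_cum <- 0; miss_cum <- 0; total <- 0
  wsum <- sum(w[hits])
  for (i in 1:N) {
    if (hits[i]) hit_cum <- hit_cum + w[i] / wsum
    else miss_cum <- miss_cum + 1 / (N - Nh)
    total <- total + hit_cum - miss_cum
  }
  unname(total)
}

# Adjusted Rand index between two partitions.
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# Small named random expression matrix.
rand_expr <- function(n_genes, n_cells, seed, lambda = 5) {
  set.seed(seed)
  m <- matrix(stats::rpois(n_genes * n_cells, lambda), n_genes, n_cells,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("c%02d", seq_len(n_cells))))
  m
}

# Reduced single-cell configuration for cheap tests.
small_sc_config <- function(seed, ...) {
  sim_config(n_cells_per_condition = 250, n_genes = 700, n_tfs = 12,
             targets_per_regulon = 15, seed = seed, ...)
}
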