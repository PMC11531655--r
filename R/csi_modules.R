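#' Connection Specificity Index between regulons
#'
#' From the Pearson correlation matrix r of activity rows, the CSI of a
#' regulon pair (i, j) is the fraction of the other N - 2 regulons k whose
#' correlations with both i and j fall below r(i, j) - delta:
#' \deqn{CSI(i,j) = |\{k \ne i,j : r(i,k) < r(i,j)-\delta \wedge
#'  r(j,k) < r(i,j)-\delta\}| / (N-2).}
#' The diagonal is 1 by convention. Constant activity rows get correlation 0
#' with every other row (logged).
#'
#' @param A regulons x cells activity matrix with at least 3 rows.
#' @param delta correlation margin (default 0.05).
#' @return symmetric CSI matrix in \[0, 1\] with unit diagonal; the
#'   underlying correlation matrix is attached as \code{attr(, "cor")}.
#' @export
compute_csi <- function(A, delta = 0.05) {
  N <- nrow(A)
  if (N < 3)
    stop("CSI needs at least 3 regulons (denominator N - 2)", call. = FALSE)
  sds <- apply(A, 1, stats::sd)
  if (any(sds == 0))
    message("compute_csi: ", sum(sds == 0),
            " constant activity rows set to correlation 0")
  r <- suppressWarnings(stats::cor(t(A)))
  r[is.na(r)] <- 0
  diag(r) <- 1
  csi <- matrix(0, N, N, dimnames = dimnames(r))
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      thr <- r[i, j] - delta
      k <- setdiff(seq_len(N), c(i, j))
      csi[i, j] <- csi[j, i] <- sum(r[i, k] < thr & r[j, k] < thr) / (N - 2)
    }
  }
  diag(csi) <- 1
  attr(csi, "cor") <- r
  csi
}

#' Cut regulon modules from a CSI dendrogram
#'
#' Hierarchically clusters the CSI row vectors (Euclidean distance, Ward
#' linkage by default) and cuts the dendrogram at the given height; module
#' ids are renumbered 1..k by first appearance in dendrogram leaf order.
#' Singleton modules are permitted; raising the height never increases the
#' module count.
#'
#' @param csi CSI matrix from \code{\link{compute_csi}}.
#' @param height cut height (default 8).
#' @param linkage hclust agglomeration method (default "ward.D2").
#' @return list of class \code{module_assignment}: \code{assignment}
#'   (named integer vector regulon -> module), \code{height},
#'   \code{hclust}.
#' @export
cut_modules <- function(csi, height = 8, linkage = "ward.D2") {
  if (any(!is.finite(csi)))
    stop("non-finite CSI entries", call. = FALSE)
  hc <- stats::hclust(stats::dist(csi), method = linkage)
  raw <- stats::cutree(hc, h = height)
  # renumber by first appearance along the dendrogram leaves
  leaf_order <- raw[hc$order]
  map <- stats::setNames(seq_along(unique(leaf_order)), unique(leaf_order))
  assignment <- unname(map[as.character(raw)])
  names(assignment) <- names(raw)
  structure(list(assignment = assignment, height = height, hclust = hc),
            class = "module_assignment")
}

#' Module activity and per-condition module contrast
#'
#' Module activity is the unweighted mean activity of member regulons per
#' cell. When condition labels are supplied, per-condition module means and
#' the WT - MUT difference (the "most condition-shifted module" contrast)
#' are reported as well.
#'
#' @param A regulons x cells activity matrix.
#' @param modules a \code{module_assignment} (or named integer vector)
#'   covering all rows of \code{A}.
#' @param condition optional per-cell condition labels.
#' @return list: \code{activity} (modules x cells), and when conditions are
#'   given \code{condition_means} (modules x conditions) and
#'   \code{difference} (WT - MUT, or first - second level).
#' @export
module_activity <- function(A, modules, condition = NULL) {
  asg <- if (inherits(modules, "module_assignment")) modules$assignment
         else modules
  if (!all(rownames(A) %in% names(asg)))
    stop("module assignment does not cover all regulon rows", call. = FALSE)
  asg <- asg[rownames(A)]
  ids <- sort(unique(asg))
  act <- do.call(rbind, lapply(ids, function(k)
    colMeans(A[asg == k, , drop = FALSE])))
  rownames(act) <- paste0("M", ids)
  colnames(act) <- colnames(A)
  out <- list(activity = act)
  if (!is.null(condition)) {
    condition <- as.character(condition)
    lev <- if (all(c("WT", "MUT") %in% condition)) c("WT", "MUT")
           else unique(condition)
    cm <- vapply(lev, function(l)
      rowMeans(act[, condition == l, drop = FALSE]), numeric(nrow(act)))
    cm <- matrix(cm, nrow = nrow(act),
                 dimnames = list(rownames(act), lev))
    out$condition_means <- cm
    if (ncol(cm) >= 2) out$difference <- cm[, 1] - cm[, 2]
  }
  out
}
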