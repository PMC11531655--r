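#' Default marker table for manual cell-type annotation
#'
#' Literature/CellMarker-derived marker genes for the eight glioma
#' microenvironment cell types used throughout the pipeline. The list order
#' is the documented tie-break order for \code{\link{annotate_cells}}.
#'
#' @return named list: cell type -> character vector of marker symbols.
#' @export
default_markers <- function() {
  list(
    astrocyte       = c("S100B", "AQP4", "GFAP"),
    microglia       = c("CSF1R", "CX3CR1", "P2RY12", "TMEM119"),
    oligodendrocyte = c("OLIG1", "MAG", "OLIG2", "PLP1", "MOG", "MBP"),
    epithelial      = c("CD44", "CDH2"),
    macrophage      = c("AIF1", "CD163", "CD68"),
    neuron          = c("DCX", "MAP2", "STMN2"),
    t_cell          = c("CD3D", "CD3E", "CD8A"),
    endothelial     = c("VWF", "CD34", "FLT1", "CLDN5"))
}

ribosomal_genes <- function(genes) grepl("^RP[SL]", genes)

#' Cell-level quality control
#'
#' Keeps cells whose detected-gene count lies in
#' \[\code{min_genes}, \code{max_genes}\] and whose ribosomal count fraction
#' (genes with an RPS/RPL symbol prefix) is strictly below
#' \code{max_ribo_frac}. Removal counts per criterion are reported and
#' attached as the \code{"qc"} attribute.
#'
#' @param m genes x cells count matrix (dense or sparse).
#' @param min_genes,max_genes detected-gene bounds (defaults 200 and 7000).
#' @param max_ribo_frac ribosomal-fraction cutoff, strict (default 0.05).
#' @return the column-filtered matrix, with a per-cell QC data frame in
#'   \code{attr(, "qc")}.
#' @export
filter_cells <- function(m, min_genes = 200, max_genes = 7000,
                         max_ribo_frac = 0.05) {
  if (min_genes > max_genes)
    stop("configuration error: 'min_genes' exceeds 'max_genes'",
         call. = FALSE)
  detected <- Matrix::colSums(m > 0)
  total <- Matrix::colSums(m)
  ribo_idx <- ribosomal_genes(rownames(m))
  ribo <- if (any(ribo_idx))
    Matrix::colSums(m[ribo_idx, , drop = FALSE]) else rep(0, ncol(m))
  ribo_frac <- ifelse(total > 0, ribo / total, 0)
  low <- detected < min_genes
  high <- detected > max_genes
  ribo_bad <- ribo_frac >= max_ribo_frac
  keep <- !(low | high | ribo_bad)
  if (!any(keep))
    stop("quality control removed every cell (", sum(low), " below ",
         min_genes, " genes, ", sum(high), " above ", max_genes,
         ", ", sum(ribo_bad), " at ribosomal fraction >= ", max_ribo_frac,
         ")", call. = FALSE)
  message("filter_cells: removed ", sum(!keep), "/", ncol(m), " cells (",
          sum(low), " low-gene, ", sum(high), " high-gene, ",
          sum(ribo_bad), " ribosomal)")
  out <- m[, keep, drop = FALSE]
  attr(out, "qc") <- data.frame(
    barcode = colnames(m), n_genes = as.integer(detected),
    ribo_frac = as.numeric(ribo_frac), keep = keep,
    stringsAsFactors = FALSE)
  out
}

#' Library-size normalization
#'
#' Scales every cell to \code{target_sum} total counts and applies log1p
#' (unless \code{log = FALSE}). Cells with zero total counts are left at
#' zero.
#'
#' @param m genes x cells count matrix.
#' @param target_sum per-cell total after scaling (default 1e4).
#' @param log apply log1p after scaling (default TRUE).
#' @return normalized matrix of the same shape.
#' @export
lognormalize <- function(m, target_sum = 1e4, log = TRUE) {
  tot <- Matrix::colSums(m)
  sf <- ifelse(tot > 0, target_sum / tot, 0)
  if (inherits(m, "sparseMatrix")) {
    out <- m %*% Matrix::Diagonal(x = sf)
    if (log) out@x <- log1p(out@x)
    dimnames(out) <- dimnames(m)
  } else {
    out <- sweep(m, 2, sf, "*")
    if (log) out <- log1p(out)
  }
  out
}

#' Highly variable gene selection by binned dispersion
#'
#' Ranks genes by the z-scored dispersion (variance / mean of log-normalized
#' values) within 20 mean-expression bins and returns the top \code{n_hvg}
#' symbols; ties are broken by gene order. Genes with zero mean are never
#' selected while any expressed gene remains.
#'
#' @param norm log-normalized genes x cells matrix.
#' @param n_hvg number of genes to select; clamped (with a warning) to the
#'   number of expressed genes.
#' @param n_bins number of mean bins (default 20).
#' @return character vector of selected gene symbols, in input gene order.
#' @export
select_hvg <- function(norm, n_hvg = 2000, n_bins = 20) {
  mu <- Matrix::rowMeans(norm)
  ex2 <- Matrix::rowMeans(norm^2)
  v <- pmax(ex2 - mu^2, 0) * ncol(norm) / max(1, ncol(norm) - 1)
  disp <- ifelse(mu > 0, v / mu, NA_real_)
  expressed <- which(!is.na(disp))
  if (n_hvg > length(expressed)) {
    warning("n_hvg (", n_hvg, ") exceeds the ", length(expressed),
            " expressed genes; clamped", call. = FALSE)
    n_hvg <- length(expressed)
  }
  bins <- cut(rank(mu[expressed], ties.method = "first"),
              breaks = min(n_bins, length(expressed)), labels = FALSE)
  z <- stats::ave(disp[expressed], bins, FUN = function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  z[v[expressed] == 0] <- -Inf  # constant genes rank behind all variable ones
  ord <- expressed[order(-z, expressed)]
  sel <- sort(ord[seq_len(n_hvg)])
  rownames(norm)[sel]
}

#' Normalize and restrict to highly variable genes
#'
#' Convenience wrapper: library-size log-normalizes all genes, then
#' restricts the matrix to the top \code{n_hvg} variable genes
#' (normalization always happens on the full gene set first).
#'
#' @inheritParams lognormalize
#' @inheritParams select_hvg
#' @return log-normalized matrix restricted to the selected genes, with the
#'   selection in \code{attr(, "hvg")}.
#' @export
normalize_and_select_hvg <- function(m, n_hvg = 2000, target_sum = 1e4) {
  norm <- lognormalize(m, target_sum)
  hvg <- select_hvg(norm, n_hvg)
  out <- norm[hvg, , drop = FALSE]
  attr(out, "hvg") <- hvg
  out
}

#' Marker-based cell-type annotation
#'
#' Scores every cell for each cell type as the mean library-size-normalized
#' expression of that type's markers present in the matrix, and labels the
#' cell with the arg-max type. Scoring is done on the linear normalized
#' scale (not log), so one strongly detected marker outweighs background;
#' ties are broken by the type order of the marker table.
#'
#' @param m genes x cells count matrix (all genes, so that markers outside
#'   any HVG subset are still usable); normalized internally.
#' @param markers named list of marker symbols per type
#'   (default \code{\link{default_markers}}).
#' @param target_sum library-size normalization total (default 1e4).
#' @return factor of cell-type labels (one per cell), with the score matrix
#'   in \code{attr(, "scores")}.
#' @export
annotate_cells <- function(m, markers = default_markers(),
                           target_sum = 1e4) {
  norm <- lognormalize(m, target_sum, log = FALSE)
  present <- lapply(markers, intersect, x = rownames(norm))
  missing <- mapply(function(a, b) length(b) - length(a), present, markers)
  if (any(missing > 0))
    message("annotate_cells: ", sum(missing), " marker genes absent from ",
            "the matrix")
  usable <- names(present)[vapply(present, length, 1L) > 0]
  if (!length(usable))
    stop("annotation error: no marker gene of any cell type is present",
         call. = FALSE)
  scores <- do.call(rbind, lapply(present[usable], function(g)
    Matrix::colMeans(norm[g, , drop = FALSE])))
  lab <- usable[apply(scores, 2, which.max)]  # which.max: first = tie rule
  tab <- table(factor(lab, levels = names(markers)))
  message("annotate_cells: ",
          paste(names(tab), sprintf("%.1f%%", 100 * tab / ncol(norm)),
                collapse = ", "))
  out <- stats::setNames(factor(lab, levels = names(markers)),
                         colnames(norm))
  attr(out, "scores") <- scores
  out
}
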