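#' Read an expression matrix (MatrixMarket or CSV)
#'
#' MTX input is a directory (or the \code{matrix.mtx} path) with
#' \code{matrix.mtx}, \code{features.tsv} and \code{barcodes.tsv}; the MTX
#' header is validated against the feature/barcode line counts and the
#' number of entry lines before parsing. CSV input has genes as rows
#' (first column = symbol) and cells as columns. Duplicate gene symbols are
#' collapsed by summation and logged.
#'
#' @param path directory or file path.
#' @param format "auto" (by extension/contents), "mtx" or "csv".
#' @return genes x cells matrix (sparse for MTX, dense for CSV) with unique
#'   gene symbols.
#' @export
read_expression <- function(path, format = c("auto", "mtx", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path) || grepl("\\.mtx$", path)) "mtx" else "csv"
  m <- if (format == "mtx") read_mtx_dir(path) else read_expression_csv(path)
  dup <- duplicated(rownames(m))
  if (any(dup)) {
    message("read_expression: collapsing ", sum(dup),
            " duplicate gene symbols by sum")
    grp <- factor(rownames(m), levels = unique(rownames(m)))
    agg <- Matrix::sparseMatrix(
      i = as.integer(grp), j = seq_along(grp), x = 1,
      dims = c(nlevels(grp), length(grp)))
    m2 <- agg %*% m
    rownames(m2) <- levels(grp)
    colnames(m2) <- colnames(m)
    m <- if (inherits(m, "sparseMatrix")) m2 else as.matrix(m2)
  }
  m
}

read_mtx_dir <- function(path) {
  if (!dir.exists(path) && grepl("\\.mtx$", path)) path <- dirname(path)
  mtx <- file.path(path, "matrix.mtx")
  feat <- file.path(path, "features.tsv")
  bc <- file.path(path, "barcodes.tsv")
  for (f in c(mtx, feat, bc))
    if (!file.exists(f)) stop("missing file: ", f, call. = FALSE)
  lines <- readLines(mtx)
  body <- lines[!startsWith(lines, "%")]
  hdr <- as.numeric(strsplit(trimws(body[1]), "\\s+")[[1]])
  if (length(hdr) != 3 || anyNA(hdr))
    stop("format error: malformed MatrixMarket size line", call. = FALSE)
  n_entries <- length(body) - 1L
  if (n_entries != hdr[3])
    stop("format error: MTX header declares ", hdr[3],
         " entries but the file contains ", n_entries, call. = FALSE)
  genes <- utils::read.delim(feat, header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  cells <- readLines(bc)
  if (length(genes) != hdr[1] || length(cells) != hdr[2])
    stop("format error: MTX declares ", hdr[1], " x ", hdr[2],
         " but features.tsv has ", length(genes),
         " rows and barcodes.tsv has ", length(cells), call. = FALSE)
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  dimnames(m) <- list(genes, cells)
  m
}

read_expression_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  sym <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad))
        stop("parse error: non-numeric value in column ", colnames(df)[j],
             ", line ", bad[1] + 1L, " of ", path, call. = FALSE)
      df[[j]] <- num
    }
  }
  m <- as.matrix(df)
  rownames(m) <- sym
  m
}

#' Write an expression matrix
#'
#' @param m genes x cells matrix.
#' @param path output directory (MTX triple) or file path (CSV).
#' @param format "mtx" or "csv".
#' @return invisibly, the written path.
#' @export
write_expression <- function(m, path, format = c("mtx", "csv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                "generalMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(rownames(m), file.path(path, "features.tsv"))
    writeLines(colnames(m), file.path(path, "barcodes.tsv"))
  } else {
    df <- data.frame(gene = rownames(m), as.matrix(m), check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read / write GMT gene-set collections
#'
#' GMT is tab-separated: set name, description, then gene symbols.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3
  if (any(bad))
    stop("format error: GMT line ", which(bad)[1],
         " has fewer than 3 fields", call. = FALSE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional description field per set (default "na").
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, d, g) paste(c(nm, d, g), collapse = "\t"),
                  names(sets), descriptions, sets)
  writeLines(unname(lines), path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every stage parameter with its default: QC bounds
#' (\code{min_genes} 200, \code{max_genes} 7000, ribosomal fraction < 0.05),
#' 2000 HVGs, minimum regulon size 10, AUCell top fraction 0.05, CSI margin
#' 0.05 and dendrogram cut height 8, differential-expression thresholds
#' adjusted p < 0.05 and |logFC| > 1, consensus-clustering k range and
#' resampling, and the survival-grid settings. Every numeric parameter is
#' validated against its documented range before any stage runs.
#'
#' @param sim \code{\link{sim_config}} used for the synthetic inputs; the
#'   pipeline default is a reduced desk-scale configuration.
#' @param min_genes,max_genes,max_ribo_frac QC bounds.
#' @param n_hvg highly variable genes to keep.
#' @param target_sum library-size normalization total.
#' @param cells_per_metacell average meta-cell occupancy; the default 1
#'   keeps single-cell resolution (no aggregation), which preserves the
#'   TF-specific signal that edge attribution relies on.
#' @param n_pcs principal components for meta-cell clustering.
#' @param grn_method "gbm" (tree ensemble) or "spearman" (fallback).
#' @param decoys_per_tf decoy candidates per TF in the motif prior.
#' @param min_regulon_size minimum surviving regulon size (default 10).
#' @param top_frac AUCell top fraction.
#' @param csi_delta CSI correlation margin.
#' @param csi_linkage,csi_cut_height hierarchical linkage and cut height.
#' @param de_adj_p,de_logfc differential-expression thresholds.
#' @param consensus_k candidate subtype numbers.
#' @param n_resamples,sample_frac,feature_frac consensus resampling scheme.
#' @param n_gene_sets,set_size,set_overlap synthetic gene-set collection.
#' @param cox_p univariate Cox screening threshold.
#' @param n_test_cohorts simulated external validation cohorts.
#' @param horizons_months time-dependent ROC horizons (default years 1-5).
#' @param seed master seed; stage seeds are derived deterministically.
#' @return validated list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(sim = sim_config(n_cells_per_condition = 500,
                                             n_genes = 1200, n_tfs = 40,
                                             targets_per_regulon = 15,
                                             n_samples = 160),
                            min_genes = 200, max_genes = 7000,
                            max_ribo_frac = 0.05, n_hvg = 2000,
                            target_sum = 1e4, cells_per_metacell = 1,
                            n_pcs = 20, grn_method = "gbm",
                            decoys_per_tf = 20, min_regulon_size = 10,
                            top_frac = 0.05, csi_delta = 0.05,
                            csi_linkage = "ward.D2", csi_cut_height = 8,
                            de_adj_p = 0.05, de_logfc = 1,
                            consensus_k = 2:6, n_resamples = 100,
                            sample_frac = 0.8, feature_frac = 0.8,
                            n_gene_sets = 13, set_size = 50,
                            set_overlap = 0.8, cox_p = 0.05,
                            n_test_cohorts = 2,
                            horizons_months = 12 * (1:5), seed = 1L) {
  cfg <- c(list(sim = sim), mget(setdiff(names(formals()), "sim")))
  cfg$seed <- as.integer(seed)
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  err <- function(...) stop("configuration error: ", ..., call. = FALSE)
  if (!inherits(cfg$sim, "sim_config")) err("'sim' must be a sim_config")
  if (cfg$min_genes > cfg$max_genes) err("'min_genes' exceeds 'max_genes'")
  if (cfg$min_genes < 0) err("'min_genes' must be non-negative")
  if (cfg$max_ribo_frac < 0 || cfg$max_ribo_frac > 1)
    err("'max_ribo_frac' must be in [0, 1]")
  if (cfg$n_hvg < 1) err("'n_hvg' must be positive")
  if (cfg$top_frac <= 0 || cfg$top_frac >= 1)
    err("'top_frac' must be in (0, 1)")
  if (cfg$csi_delta < 0 || cfg$csi_delta >= 1)
    err("'csi_delta' must be in [0, 1)")
  if (cfg$csi_cut_height < 0) err("'csi_cut_height' must be non-negative")
  if (cfg$de_adj_p <= 0 || cfg$de_adj_p > 1) err("'de_adj_p' outside (0, 1]")
  if (cfg$min_regulon_size < 1) err("'min_regulon_size' must be >= 1")
  if (any(cfg$consensus_k < 2)) err("'consensus_k' values must be >= 2")
  if (cfg$sample_frac <= 0.5 || cfg$sample_frac >= 1)
    err("'sample_frac' must be in (0.5, 1)")
  if (cfg$n_resamples < 1) err("'n_resamples' must be positive")
  if (cfg$cox_p <= 0 || cfg$cox_p > 1) err("'cox_p' outside (0, 1]")
  if (!cfg$grn_method %in% c("gbm", "lm", "spearman"))
    err("'grn_method' must be one of \"gbm\", \"lm\", \"spearman\"")
  if (any(cfg$horizons_months <= 0)) err("'horizons_months' must be positive")
  invisible(cfg)
}

stage_log <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

#' Run the full regulon pipeline on synthetic data
#'
#' Executes, in order: single-cell simulation, MTX round-trip, quality
#' control, normalization + HVG selection, marker annotation, meta-cell
#' aggregation, co-expression GRN inference, prior-based regulon assembly,
#' AUCell activity scoring, ANOVA for condition-specific regulons, CSI and
#' module discovery, module activity, single-cell differential expression,
#' signature construction from the most condition-specific regulon,
#' bulk-cohort simulation, consensus-clustering subtyping, ssGSEA subtype
#' comparison, univariate Cox screening, input-gene-set intersection, the
#' survival model grid, and risk stratification with time-dependent ROC.
#' Every stage writes a TSV artifact into \code{out_dir} and logs its
#' input/output dimensions; any stage failure aborts with the stage name
#' while earlier artifacts are retained.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with every stage's in-memory result and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  seed <- config$seed

  # --- single-cell side -----------------------------------------------
  sc_cfg <- config$sim; sc_cfg$seed <- seed
  sim <- run_stage("simulate", simulate_single_cell(sc_cfg))
  stage_log("simulate", nrow(sim$counts), " genes x ", ncol(sim$counts),
            " cells")
  write_expression(sim$counts, file.path(out_dir, "sim_sc"), "mtx")
  write_tsv(sim$cells, file.path(out_dir, "cell_metadata.tsv"))
  m <- run_stage("read", read_expression(file.path(out_dir, "sim_sc")))

  filt <- run_stage("qc", filter_cells(m, config$min_genes,
                                       config$max_genes,
                                       config$max_ribo_frac))
  write_tsv(attr(filt, "qc"), file.path(out_dir, "qc_cells.tsv"))
  stage_log("qc", ncol(m), " -> ", ncol(filt), " cells")
  cells <- sim$cells[match(colnames(filt), sim$cells$barcode), ]

  norm <- run_stage("normalize", lognormalize(filt, config$target_sum))
  hvg <- run_stage("hvg", suppressWarnings(
    select_hvg(norm, config$n_hvg)))
  stage_log("hvg", length(hvg), " highly variable genes")
  writeLines(hvg, file.path(out_dir, "hvg.txt"))

  labels <- run_stage("annotate", annotate_cells(filt))
  prop <- as.data.frame(table(label = labels) / length(labels))
  write_tsv(data.frame(cell_type = prop$label,
                       proportion = prop$Freq),
            file.path(out_dir, "cell_type_proportions.tsv"))

  n_mc <- max(20L, ceiling(ncol(filt) / config$cells_per_metacell))
  mc <- run_stage("metacells",
                  build_metacells(norm[hvg, , drop = FALSE], n_mc,
                                  config$n_pcs, seed = seed + 1L,
                                  condition = cells$condition))
  stage_log("metacells", ncol(filt), " cells -> ", ncol(mc$profiles),
            " metacells")

  tfs <- names(sim$truth$regulons)
  writeLines(tfs, file.path(out_dir, "tf_list.txt"))
  prior <- make_motif_prior(sim, config$decoys_per_tf, seed = seed + 2L)
  write_tsv(prior, file.path(out_dir, "motif_prior.tsv"))
  edges <- run_stage("grn",
                     infer_coexpression(mc$profiles, tfs,
                                        method = config$grn_method,
                                        seed = seed + 3L))
  write_tsv(edges, file.path(out_dir, "grn_edges.tsv"))
  stage_log("grn", nrow(edges), " edges")

  regulons <- run_stage("regulons",
                        assemble_regulons(edges, prior,
                                          config$min_regulon_size))
  stage_log("regulons", length(regulons), " regulons of size >= ",
            config$min_regulon_size)
  write_tsv(data.frame(
    tf = rep(vapply(regulons, `[[`, "", "tf"),
             vapply(regulons, function(r) length(r$targets), 1L)),
    target = unlist(lapply(regulons, `[[`, "targets")),
    weight = unlist(lapply(regulons, `[[`, "weights"))),
    file.path(out_dir, "regulons.tsv"))

  A <- run_stage("activity", score_all(norm, regulons, config$top_frac))
  write_tsv(data.frame(regulon = rownames(A), as.data.frame(as.matrix(A)),
                       check.names = FALSE),
            file.path(out_dir, "ras.tsv"))
  stage_log("activity", nrow(A), " regulons x ", ncol(A), " cells")

  anova <- run_stage("anova",
                     group_specific_regulons(A, cells$condition))
  write_tsv(anova, file.path(out_dir, "regulon_anova.tsv"))

  csi <- run_stage("csi", compute_csi(A, config$csi_delta))
  write_tsv(data.frame(regulon = rownames(csi),
                       as.data.frame(csi, check.names = FALSE)),
            file.path(out_dir, "csi.tsv"))
  modules <- run_stage("modules",
                       cut_modules(csi, height = config$csi_cut_height,
                                   linkage = config$csi_linkage))
  write_tsv(data.frame(regulon = names(modules$assignment),
                       module = paste0("M", modules$assignment)),
            file.path(out_dir, "modules.tsv"))
  stage_log("modules", max(modules$assignment), " modules at height ",
            config$csi_cut_height)
  ma <- run_stage("module_activity",
                  module_activity(A, modules, condition = cells$condition))
  write_tsv(data.frame(module = rownames(ma$condition_means),
                       ma$condition_means,
                       difference = ma$difference, check.names = FALSE),
            file.path(out_dir, "module_activity_by_condition.tsv"))

  de_sc <- run_stage("de_sc",
                     differential_expression(norm, cells$condition))
  write_tsv(de_sc, file.path(out_dir, "de_single_cell.tsv"))
  top_tf <- anova$regulon[1]
  stage_log("signature", "most condition-specific regulon: ", top_tf)
  top_reg <- regulons[[which(vapply(regulons, `[[`, "", "tf") == top_tf)]]
  sig <- run_stage("signature",
                   build_signature(top_reg, de_sc,
                                   adj_p = config$de_adj_p,
                                   logfc = config$de_logfc))
  writeLines(sig, file.path(out_dir, "signature_genes.txt"))

  # --- bulk side ------------------------------------------------------
  mk_cohort <- function(s) {
    cfg <- config$sim; cfg$seed <- s
    simulate_bulk_cohort(cfg)
  }
  train <- run_stage("bulk", mk_cohort(seed + 101L))
  tests <- lapply(seq_len(config$n_test_cohorts),
                  function(i) mk_cohort(seed + 101L + i))
  stage_log("bulk", "train n=", nrow(train$expr), ", ",
            length(tests), " test cohorts")

  sig_b <- intersect(sig, colnames(train$expr))
  cc <- run_stage("subtype",
                  consensus_cluster(train$expr[, sig_b, drop = FALSE],
                                    k_range = config$consensus_k,
                                    n_resamples = config$n_resamples,
                                    sample_frac = config$sample_frac,
                                    feature_frac = config$feature_frac,
                                    seed = seed + 4L))
  labels_b <- paste0("C", cc$labels)
  write_tsv(data.frame(sample = rownames(train$expr), subtype = labels_b),
            file.path(out_dir, "subtype_labels.tsv"))
  stage_log("subtype", "selected k = ", cc$selected_k)

  sets <- make_gene_sets(train$truth, config$n_gene_sets, config$set_size,
                         overlap = config$set_overlap, seed = seed + 5L,
                         file = file.path(out_dir, "gene_sets.gmt"))
  sets <- read_gmt(file.path(out_dir, "gene_sets.gmt"))
  scores <- run_stage("ssgsea",
                      ssgsea_score(t(train$expr), sets))
  cmp <- run_stage("compare_subtypes",
                   compare_subtypes(train, labels_b, scores))
  write_tsv(cmp$set_table, file.path(out_dir, "subtype_set_scores.tsv"))
  write_tsv(data.frame(statistic = c("logrank_chisq", "logrank_p"),
                       value = c(cmp$logrank_chisq, cmp$logrank_p)),
            file.path(out_dir, "subtype_logrank.tsv"))

  de_bulk <- run_stage("de_bulk",
                       differential_expression(t(train$expr), labels_b))
  write_tsv(de_bulk, file.path(out_dir, "de_subtypes.tsv"))
  subtype_pass <- de_bulk$gene[de_bulk$adj_p < config$de_adj_p &
                                 abs(de_bulk$logFC) > config$de_logfc]
  de_sc_pass <- de_sc$gene[de_sc$adj_p < config$de_adj_p &
                             abs(de_sc$logFC) > config$de_logfc]

  coxg <- run_stage("cox_screen",
                    cox_screen(train, p_thresh = config$cox_p))
  write_tsv(coxg, file.path(out_dir, "cox_screen.tsv"))
  geneset <- run_stage("input_geneset",
                       build_input_geneset(
                         coxg$gene[coxg$p < config$cox_p],
                         de_sc_pass, subtype_pass))
  writeLines(geneset, file.path(out_dir, "model_input_genes.txt"))

  grid <- run_stage("model_grid",
                    fit_model_grid(train, tests, geneset,
                                   seed = seed + 6L))
  write_tsv(grid$leaderboard, file.path(out_dir, "model_leaderboard.tsv"))
  stage_log("model_grid", "best: ", grid$best$selector, " + ",
            grid$best$model, " (mean test C-index ",
            sprintf("%.3f", grid$leaderboard$mean_test_cindex[1]), ")")

  strat <- run_stage("stratify",
                     stratify_and_evaluate(grid$best, train,
                                           horizons = config$horizons_months))
  write_tsv(strat$auc, file.path(out_dir, "roc_auc_by_year.tsv"))
  write_tsv(data.frame(sample = rownames(train$expr),
                       risk_score = strat$scores, group = strat$group),
            file.path(out_dir, "risk_scores.tsv"))

  manifest <- list(
    package = "scregulon",
    config = unclass(config[setdiff(names(config), "sim")]),
    sim = unclass(config$sim),
    n_cells_qc = ncol(filt), n_regulons = length(regulons),
    n_modules = max(modules$assignment),
    selected_k = cc$selected_k,
    best_model = paste(grid$best$selector, grid$best$model, sep = "+"),
    mean_test_cindex = grid$leaderboard$mean_test_cindex[1])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(sim = sim, qc = filt, hvg = hvg, labels = labels,
                 metacells = mc, edges = edges, regulons = regulons,
                 activity = A, anova = anova, csi = csi, modules = modules,
                 module_activity = ma, signature = sig, train = train,
                 tests = tests, consensus = cc, subtype_labels = labels_b,
                 compare = cmp, de_bulk = de_bulk, cox = coxg,
                 geneset = geneset, grid = grid, stratified = strat,
                 manifest = manifest))
}
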