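#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic single-cell and
#' bulk-cohort generators. Defaults describe the canonical simulated study:
#' 3,000 cells (1,500 per IDH condition), 2,000 genes, 50 transcription
#' factors with 20 dedicated targets each, four regulon modules of which one
#' (the "M4" analogue) carries a condition-dependent activity shift, and a
#' 200-sample survival cohort with two planted expression subtypes and a
#' hazard linear in the planted signature genes.
#'
#' @param n_cells_per_condition cells simulated for each condition (WT, MUT).
#' @param n_genes total genes in the universe (TFs + targets + markers +
#'   ribosomal + filler).
#' @param n_tfs number of transcription factors, each owning one regulon.
#' @param targets_per_regulon dedicated target genes per TF; targets are
#'   disjoint across TFs so every planted target belongs to exactly one
#'   regulon.
#' @param n_modules number of co-active regulon modules; TFs are split into
#'   contiguous, near-equal modules.
#' @param shifted_module index of the module whose latent activity is shifted
#'   in condition WT (defaults to the last module).
#' @param activity_shift log-scale mean shift of the shifted module's latent
#'   activity in WT relative to MUT cells.
#' @param dropout_rate probability that any count is zeroed after sampling
#'   (uniform Bernoulli dropout).
#' @param nb_dispersion negative-binomial dispersion (size); variance is
#'   \eqn{\mu + \mu^2/dispersion}.
#' @param baseline_log_mean,baseline_log_sd log-normal parameters of per-gene
#'   baseline mean expression.
#' @param weight_range range of the per-edge (and per-TF-gene) regulatory
#'   weights, drawn uniformly.
#' @param tf_noise_sd standard deviation of the TF-specific latent component
#'   added on top of the shared module latent.
#' @param marker_fold multiplicative elevation of a marker gene's mean in
#'   cells of its own type.
#' @param marker_off_scale multiplicative suppression of a marker gene's
#'   mean outside its own type; markers are near-exclusive in real tissue,
#'   not merely elevated.
#' @param n_samples bulk-cohort size (must be at least 40 when simulating).
#' @param n_signature_genes planted prognostic signature size; these genes
#'   are drawn from the shifted module's targets, are subtype-shifted, and
#'   carry the hazard coefficient \code{beta}.
#' @param subtype_sep separation, in units of the bulk noise SD, between the
#'   two subtype means on subtype-shifted genes.
#' @param beta log-hazard coefficient per signature gene.
#' @param censor_rate target fraction of censored samples in \[0,1\].
#' @param baseline_hazard baseline exponential hazard (per month).
#' @param bulk_noise_sd residual SD of bulk log-expression.
#' @param seed integer RNG seed; identical configurations (including seed)
#'   yield byte-identical output.
#'
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_cells_per_condition = 1500,
                       n_genes = 2000,
                       n_tfs = 50,
                       targets_per_regulon = 20,
                       n_modules = 4,
                       shifted_module = n_modules,
                       activity_shift = 1.5,
                       dropout_rate = 0.3,
                       nb_dispersion = 2,
                       baseline_log_mean = log(2),
                       baseline_log_sd = 0.5,
                       weight_range = c(0.4, 1.0),
                       tf_noise_sd = 1,
                       marker_fold = 20,
                       marker_off_scale = 0.25,
                       n_samples = 200,
                       n_signature_genes = 20,
                       subtype_sep = 2,
                       beta = 1,
                       censor_rate = 0.3,
                       baseline_hazard = 0.02,
                       bulk_noise_sd = 1,
                       seed = 1L) {
  cfg <- list(
    n_cells_per_condition = as.integer(n_cells_per_condition),
    n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
    targets_per_regulon = as.integer(targets_per_regulon),
    n_modules = as.integer(n_modules),
    shifted_module = as.integer(shifted_module),
    activity_shift = activity_shift, dropout_rate = dropout_rate,
    nb_dispersion = nb_dispersion, baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd, weight_range = weight_range,
    tf_noise_sd = tf_noise_sd, marker_fold = marker_fold,
    marker_off_scale = marker_off_scale,
    n_samples = as.integer(n_samples),
    n_signature_genes = as.integer(n_signature_genes),
    subtype_sep = subtype_sep, beta = beta, censor_rate = censor_rate,
    baseline_hazard = baseline_hazard, bulk_noise_sd = bulk_noise_sd,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk_rate <- function(x, nm) {
    if (!is.numeric(cfg[[x]]) || length(cfg[[x]]) != 1 ||
        is.na(cfg[[x]]) || cfg[[x]] < 0 || cfg[[x]] > 1)
      stop("configuration error: '", x, "' must be a rate in [0, 1]",
           call. = FALSE)
  }
  chk_pos <- function(x) {
    if (!is.numeric(cfg[[x]]) || length(cfg[[x]]) != 1 ||
        is.na(cfg[[x]]) || cfg[[x]] <= 0)
      stop("configuration error: '", x, "' must be positive", call. = FALSE)
  }
  for (f in c("n_cells_per_condition", "n_genes", "n_tfs",
              "targets_per_regulon", "n_modules", "nb_dispersion",
              "tf_noise_sd", "marker_fold", "n_samples",
              "n_signature_genes", "baseline_hazard", "bulk_noise_sd"))
    chk_pos(f)
  for (f in c("dropout_rate", "censor_rate")) chk_rate(f)
  if (cfg$n_tfs * cfg$targets_per_regulon > cfg$n_genes)
    stop("configuration error: 'n_tfs' x 'targets_per_regulon' exceeds ",
         "'n_genes'", call. = FALSE)
  reserved <- cfg$n_tfs + cfg$n_tfs * cfg$targets_per_regulon +
    length(unlist(default_markers())) + 20L
  if (reserved > cfg$n_genes)
    stop("configuration error: 'n_genes' (", cfg$n_genes, ") too small for ",
         cfg$n_tfs, " TFs, their targets, marker and ribosomal genes (need ",
         reserved, ")", call. = FALSE)
  if (cfg$shifted_module < 1 || cfg$shifted_module > cfg$n_modules)
    stop("configuration error: 'shifted_module' outside 1..n_modules",
         call. = FALSE)
  if (length(cfg$weight_range) != 2 || diff(cfg$weight_range) < 0 ||
      any(cfg$weight_range < 0))
    stop("configuration error: 'weight_range' must be an increasing ",
         "non-negative pair", call. = FALSE)
  invisible(cfg)
}

# Deterministic gene universe shared by the single-cell and bulk generators:
# TF symbols first, then the disjoint target blocks, then marker genes,
# 20 ribosomal (RPS/RPL) genes, and filler genes up to n_genes.
gene_universe <- function(cfg) {
  markers <- default_markers()
  tfs <- sprintf("TF%03d", seq_len(cfg$n_tfs))
  n_tg <- cfg$n_tfs * cfg$targets_per_regulon
  targets <- sprintf("TG%04d", seq_len(n_tg))
  marker_genes <- unname(unlist(markers))
  ribo <- c(sprintf("RPS%d", 1:10), sprintf("RPL%d", 1:10))
  n_fill <- cfg$n_genes - cfg$n_tfs - n_tg - length(marker_genes) -
    length(ribo)
  filler <- if (n_fill > 0) sprintf("GENE%04d", seq_len(n_fill)) else
    character()
  genes <- c(tfs, targets, marker_genes, ribo, filler)
  target_of <- split(targets, rep(seq_len(cfg$n_tfs),
                                  each = cfg$targets_per_regulon))
  names(target_of) <- tfs
  module_of <- sort(rep_len(seq_len(cfg$n_modules), cfg$n_tfs))
  names(module_of) <- tfs
  list(genes = genes, tfs = tfs, targets = targets, target_of = target_of,
       module_of = module_of, marker_genes = marker_genes,
       marker_table = markers, ribo = ribo, filler = filler)
}

#' Simulate a single-cell experiment with planted regulons and modules
#'
#' Generates negative-binomial counts with uniform dropout from a latent
#' activity model: each module m has a per-cell latent
#' \eqn{a_{m} = \mu_m(\mathrm{condition}) + N(0,1)} where the shifted
#' module's mean is \code{activity_shift} in WT cells and 0 otherwise; each
#' TF adds an independent \eqn{N(0, tf\_noise\_sd^2)} component; a TF gene
#' and each of its targets have mean
#' \eqn{\mu = \mathrm{baseline} \cdot e^{w a}} with per-edge weight w.
#' Marker genes are suppressed to \code{marker_off_scale} of baseline
#' outside their own cell type and elevated \code{marker_fold}-fold within
#' it, emulating marker exclusivity.
#'
#' @param config a \code{\link{sim_config}}.
#' @return A list of class \code{sc_sim} with elements \code{counts}
#'   (sparse genes x cells matrix), \code{cells} (data frame: barcode,
#'   condition, cell_type) and \code{truth} (regulon map, edge weights,
#'   module map, per-condition module activity means, TF latent activities,
#'   marker table).
#' @export
simulate_single_cell <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  uni <- gene_universe(config)
  n <- 2L * config$n_cells_per_condition
  condition <- rep(c("WT", "MUT"), each = config$n_cells_per_condition)
  types <- names(uni$marker_table)
  cell_type <- sample(types, n, replace = TRUE)

  # latent activities: module-level shared + TF-specific
  mod_lat <- matrix(stats::rnorm(config$n_modules * n), config$n_modules, n)
  mod_means <- matrix(0, config$n_modules, 2,
                      dimnames = list(paste0("M", seq_len(config$n_modules)),
                                      c("WT", "MUT")))
  mod_means[config$shifted_module, "WT"] <- config$activity_shift
  mod_lat[config$shifted_module, condition == "WT"] <-
    mod_lat[config$shifted_module, condition == "WT"] + config$activity_shift
  tf_lat <- mod_lat[uni$module_of, , drop = FALSE] +
    matrix(stats::rnorm(config$n_tfs * n, sd = config$tf_noise_sd),
           config$n_tfs, n)
  rownames(tf_lat) <- uni$tfs

  baseline <- exp(stats::rnorm(config$n_genes, config$baseline_log_mean,
                               config$baseline_log_sd))
  names(baseline) <- uni$genes
  w_tf <- stats::runif(config$n_tfs, config$weight_range[1],
                       config$weight_range[2])
  names(w_tf) <- uni$tfs
  w_target <- stats::runif(length(uni$targets), config$weight_range[1],
                           config$weight_range[2])
  names(w_target) <- uni$targets

  mu <- matrix(baseline, config$n_genes, n,
               dimnames = list(uni$genes, NULL))
  mu[uni$tfs, ] <- mu[uni$tfs, ] * exp(w_tf * tf_lat)
  tf_idx <- rep(seq_len(config$n_tfs), each = config$targets_per_regulon)
  mu[uni$targets, ] <- mu[uni$targets, ] *
    exp(w_target * tf_lat[tf_idx, , drop = FALSE])
  for (ty in types) {
    mk <- uni$marker_table[[ty]]
    mu[mk, ] <- mu[mk, ] * config$marker_off_scale
    cols <- which(cell_type == ty)
    if (length(cols))
      mu[mk, cols] <- mu[mk, cols] *
        (config$marker_fold / config$marker_off_scale)
  }

  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = config$nb_dispersion),
                   nrow(mu), ncol(mu), dimnames = dimnames(mu))
  if (config$dropout_rate > 0)
    counts[stats::runif(length(counts)) < config$dropout_rate] <- 0
  barcodes <- sprintf("%s_%04d", condition,
                      stats::ave(seq_len(n), condition, FUN = seq_along))
  colnames(counts) <- barcodes

  weights <- lapply(uni$tfs, function(tf) {
    w <- w_target[uni$target_of[[tf]]]
    w
  })
  names(weights) <- uni$tfs
  out <- list(
    counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
    cells = data.frame(barcode = barcodes, condition = condition,
                       cell_type = cell_type, stringsAsFactors = FALSE),
    truth = list(regulons = uni$target_of, weights = weights,
                 tf_weights = w_tf, modules = uni$module_of,
                 shifted_module = config$shifted_module,
                 module_means = mod_means, tf_activity = tf_lat,
                 cell_types = cell_type, marker_table = uni$marker_table,
                 genes = uni$genes),
    config = config)
  class(out) <- "sc_sim"
  out
}

#' Simulate a bulk survival cohort with planted subtypes and hazard
#'
#' Bulk log-expression is gene baseline + Gaussian noise; the planted
#' signature genes (drawn deterministically from the shifted module's
#' targets) and an equally sized set of additional subtype genes are shifted
#' by \code{subtype_sep} noise-SDs between the two subtypes. Survival times
#' are exponential with hazard
#' \eqn{h_0 \exp(\sum_j \beta (x_j - \bar\mu_j))} over the signature genes;
#' censoring is independent exponential with its rate calibrated by
#' root-finding so the expected censored fraction equals
#' \code{censor_rate}.
#'
#' @param config a \code{\link{sim_config}} with \code{n_samples >= 40}.
#' @return A list of class \code{bulk_sim} with \code{expr} (samples x genes
#'   log-expression), \code{clinical} (sample, time in months, event 0/1,
#'   grade), and \code{truth} (subtype labels, signature genes with true
#'   beta, subtype genes, true linear predictor).
#' @export
simulate_bulk_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  if (config$n_samples < 40)
    stop("configuration error: 'n_samples' must be >= 40", call. = FALSE)
  set.seed(config$seed)
  uni <- gene_universe(config)
  shifted_tfs <- names(uni$module_of)[uni$module_of == config$shifted_module]
  pool <- unlist(uni$target_of[shifted_tfs], use.names = FALSE)
  if (config$n_signature_genes > length(pool))
    stop("configuration error: 'n_signature_genes' exceeds the shifted ",
         "module's ", length(pool), " target genes", call. = FALSE)
  # every shifted-module target is subtype-shifted (module-driven subtypes);
  # the prognostic signature is spread round-robin across the module's TFs
  # so each regulon of the module carries part of the hazard
  subtype_genes <- pool
  round_robin <- as.vector(t(matrix(pool, nrow = config$targets_per_regulon)))
  signature <- round_robin[seq_len(config$n_signature_genes)]

  n <- config$n_samples
  subtype <- sample(c("C1", "C2"), n, replace = TRUE)
  gene_mu <- stats::rnorm(config$n_genes, mean = 3, sd = 1)
  names(gene_mu) <- uni$genes
  expr <- matrix(stats::rnorm(n * config$n_genes, sd = config$bulk_noise_sd),
                 n, config$n_genes,
                 dimnames = list(sprintf("S%04d", seq_len(n)), uni$genes))
  expr <- sweep(expr, 2, gene_mu, "+")
  half <- config$subtype_sep * config$bulk_noise_sd / 2
  expr[subtype == "C1", subtype_genes] <-
    expr[subtype == "C1", subtype_genes] + half
  expr[subtype == "C2", subtype_genes] <-
    expr[subtype == "C2", subtype_genes] - half

  centered <- sweep(expr[, signature, drop = FALSE], 2,
                    gene_mu[signature], "-")
  lp <- config$beta * rowSums(centered)
  lp <- lp - mean(lp)
  t_event <- stats::rexp(n, rate = config$baseline_hazard * exp(lp))
  if (config$censor_rate <= 0) {
    time <- t_event
    event <- rep(1L, n)
  } else if (config$censor_rate >= 1) {
    time <- t_event * stats::runif(n)
    event <- rep(0L, n)
  } else {
    f <- function(lam) mean(1 - exp(-lam * t_event)) - config$censor_rate
    lam <- stats::uniroot(f, lower = 1e-12, upper = 1e12,
                          extendInt = "upX", tol = 1e-10)$root
    cens <- stats::rexp(n, rate = lam)
    time <- pmin(t_event, cens)
    event <- as.integer(t_event <= cens)
  }

  out <- list(
    expr = expr,
    clinical = data.frame(sample = rownames(expr), time = time,
                          event = event,
                          grade = sample(2:4, n, replace = TRUE),
                          stringsAsFactors = FALSE),
    truth = list(subtype = stats::setNames(subtype, rownames(expr)),
                 signature_genes = signature, beta = config$beta,
                 subtype_genes = subtype_genes, lp = lp,
                 genes = uni$genes),
    config = config)
  class(out) <- "bulk_sim"
  out
}

#' Motif-prior table for regulon assembly
#'
#' Builds a TF -> candidate-target prior standing in for a cisTarget motif
#' database: every planted target of a TF plus \code{decoys_per_tf} decoy
#' genes drawn from outside its regulon.
#'
#' @param sim an \code{sc_sim} object (or its \code{truth} element).
#' @param decoys_per_tf decoy candidate targets per TF.
#' @param seed RNG seed for decoy sampling.
#' @return data frame with columns \code{tf}, \code{target}.
#' @export
make_motif_prior <- function(sim, decoys_per_tf = 20, seed = 1L) {
  truth <- if (inherits(sim, "sc_sim")) sim$truth else sim
  set.seed(seed)
  rows <- lapply(names(truth$regulons), function(tf) {
    own <- truth$regulons[[tf]]
    cand <- setdiff(truth$genes, c(tf, own))
    decoys <- sample(cand, min(decoys_per_tf, length(cand)))
    data.frame(tf = tf, target = c(own, decoys), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate gene-set collections overlapping planted signal
#'
#' Draws \code{n_sets} gene sets of \code{set_size} genes whose overlap with
#' the planted signature/subtype genes is the configured fraction; the
#' remainder is sampled from the rest of the gene universe. Emulates curated
#' death-pathway / immune-feature collections.
#'
#' @param truth the \code{truth} element of a \code{bulk_sim} (or the object
#'   itself).
#' @param n_sets number of sets (default 13).
#' @param set_size genes per set.
#' @param overlap fraction of each set drawn from planted signal genes.
#' @param seed RNG seed.
#' @param file optional path; when given the collection is written as GMT.
#' @return named list of character vectors (a gene-set collection).
#' @export
make_gene_sets <- function(truth, n_sets = 13, set_size = 50, overlap = 0.5,
                           seed = 1L, file = NULL) {
  if (inherits(truth, "bulk_sim")) truth <- truth$truth
  if (overlap < 0 || overlap > 1)
    stop("configuration error: 'overlap' must be in [0, 1]", call. = FALSE)
  if (set_size > length(truth$genes))
    stop("configuration error: 'set_size' exceeds the gene universe",
         call. = FALSE)
  set.seed(seed)
  signal <- truth$subtype_genes
  rest <- setdiff(truth$genes, signal)
  sets <- lapply(seq_len(n_sets), function(i) {
    k_sig <- min(round(overlap * set_size), length(signal))
    c(sample(signal, k_sig), sample(rest, set_size - k_sig))
  })
  names(sets) <- sprintf("PATHWAY_%02d", seq_len(n_sets))
  if (!is.null(file)) write_gmt(sets, file)
  sets
}
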