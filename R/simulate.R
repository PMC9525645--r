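# Synthetic two-condition single-cell cohorts and bulk survival cohorts with
# planted effects, giving every downstream statistic a ground-truth surface.

#' Derive a stage-level seed from the global seed
#'
#' All randomness in the package derives from one global seed through this
#' rule: \code{child_seed(seed, tag)} hashes the tag into an offset so that
#' stages draw from distinct, reproducible streams. Results stay below 2^31.
#' @param seed global integer seed
#' @param tag character stream label
#' @return derived integer seed
#' @export
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Build a simulation configuration
#'
#' Defaults describe a matched-cohort study: 10 tumor and 10 normal samples,
#' negative-binomial counts (variance mu + mu^2/theta), per-sample cell-type
#' fractions drawn from a Dirichlet with concentration 50 around condition
#' targets, per-type marker blocks, Gaussian-blob embeddings, uniform
#' depth multipliers and a Beta doublet-score mixture.
#'
#' @param n_samples_per_condition samples per condition (default 10)
#' @param cells_per_sample mean cells per sample (default 150); counts are
#'   NB-distributed around it with size \code{cells_dispersion}
#' @param cells_dispersion NB size of the per-sample cell count (default 20)
#' @param cell_types named numeric vector of baseline proportions (sum 1)
#' @param composition_effects named multiplicative proportion shifts applied in
#'   tumor samples before re-closure (e.g. \code{c(TypeA = 2)})
#' @param n_genes number of genes
#' @param target_umi expected per-cell total UMI at depth multiplier 1
#'   (default 2000, a typical droplet depth); sets the scale of the baseline
#'   gene means so cohorts are realistic for any \code{n_genes}
#' @param base_mean_log mean of log gene baseline means; default
#'   \code{log(target_umi / n_genes) - base_mean_sd^2 / 2} so that gene means
#'   are lognormal with expectation \code{target_umi / n_genes}
#' @param base_mean_sd sd of log gene baseline means (default 1)
#' @param dispersion common NB size parameter theta (default 2)
#' @param marker_genes_per_type genes given elevated mean in each type
#' @param marker_fc fold elevation of marker genes (default 8)
#' @param de_effects list of lists with fields \code{cell_type}, \code{genes}
#'   (indices or symbols), \code{log2fc}; applied in tumor cells of that type
#' @param lr_plants list of lists with fields \code{ligand}, \code{sender},
#'   \code{receptor}, \code{receiver}, \code{effect} (fold elevation of the
#'   ligand in sender cells and receptor in receiver cells)
#' @param dirichlet_conc Dirichlet concentration around target proportions
#' @param embedding_spread sd of each type's Gaussian blob (default 0.6)
#' @param depth_range per-cell library-size multiplier range (default c(0.7, 1.4))
#' @param doublet_rate fraction of cells drawn from the high doublet-score
#'   component (default 0.05)
#' @param seed integer seed; fully determines the cohort
#' @return a \code{SimulationConfig} list.
#' @export
simulation_config <- function(n_samples_per_condition = 10,
                              cells_per_sample = 150,
                              cells_dispersion = 20,
                              cell_types = c(Tcell = 0.4, Myeloid = 0.35, Stroma = 0.25),
                              composition_effects = NULL,
                              n_genes = 300,
                              target_umi = 2000,
                              base_mean_log = NULL,
                              base_mean_sd = 1,
                              dispersion = 2,
                              marker_genes_per_type = 10,
                              marker_fc = 8,
                              de_effects = list(),
                              lr_plants = list(),
                              dirichlet_conc = 50,
                              embedding_spread = 0.6,
                              depth_range = c(0.7, 1.4),
                              doublet_rate = 0.05,
                              seed = 1L) {
  if (abs(sum(cell_types) - 1) > 1e-8) stop("baseline proportions must sum to 1")
  if (any(cell_types <= 0)) stop("baseline proportions must be positive")
  if (dispersion <= 0 || cells_dispersion <= 0) stop("NB dispersions must be > 0")
  if (!is.null(composition_effects) && any(composition_effects <= 0))
    stop("composition effects must be positive")
  if (doublet_rate < 0 || doublet_rate > 1) stop("doublet_rate must be in [0,1]")
  if (is.null(base_mean_log))
    base_mean_log <- log(target_umi / n_genes) - base_mean_sd^2 / 2
  structure(as.list(environment()), class = "SimulationConfig")
}

.rdirichlet <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate a matched tumor/normal single-cell cohort
#'
#' Counts are NB(mu, theta) with mu = gene baseline x type marker effect x
#' condition DE effect x ligand-receptor plant x per-cell depth. Per-sample
#' cell-type fractions are Dirichlet around condition-specific targets;
#' embeddings are per-type Gaussian blobs; doublet scores follow a Beta
#' mixture with a planted high-score fraction.
#'
#' @param config a \code{SimulationConfig}
#' @return list with \code{cm} (CellMatrix with full metadata) and
#'   \code{truth} (planted types, DE genes, compositional shifts, LR plants).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(child_seed(config$seed, "cohort"))
  ct_names <- names(config$cell_types)
  n_types <- length(ct_names)
  genes <- sprintf("G%04d", seq_len(config$n_genes))

  base_mu <- exp(rnorm(config$n_genes, config$base_mean_log, config$base_mean_sd))
  names(base_mu) <- genes

  # per-type multiplicative effects: marker blocks at the head of the gene list
  type_fx <- matrix(1, config$n_genes, n_types, dimnames = list(genes, ct_names))
  marker_map <- list()
  if (config$marker_genes_per_type > 0) {
    for (k in seq_len(n_types)) {
      idx <- ((k - 1) * config$marker_genes_per_type + 1):(k * config$marker_genes_per_type)
      idx <- idx[idx <= config$n_genes]
      type_fx[idx, k] <- config$marker_fc
      marker_map[[ct_names[k]]] <- genes[idx]
    }
  }

  # condition/type DE effects
  de_fx <- array(1, dim = c(config$n_genes, n_types),
                 dimnames = list(genes, ct_names))
  de_truth <- list()
  for (e in config$de_effects) {
    gi <- if (is.character(e$genes)) match(e$genes, genes) else e$genes
    de_fx[gi, e$cell_type] <- de_fx[gi, e$cell_type] * 2^e$log2fc
    de_truth[[length(de_truth) + 1]] <-
      list(cell_type = e$cell_type, genes = genes[gi], log2fc = e$log2fc)
  }

  # ligand-receptor plants (condition-independent co-elevation)
  lr_fx <- matrix(1, config$n_genes, n_types, dimnames = list(genes, ct_names))
  for (p in config$lr_plants) {
    lr_fx[p$ligand, p$sender] <- lr_fx[p$ligand, p$sender] * p$effect
    lr_fx[p$receptor, p$receiver] <- lr_fx[p$receptor, p$receiver] * p$effect
  }

  # condition-specific composition targets
  prop <- rbind(tumor = config$cell_types, normal = config$cell_types)
  if (!is.null(config$composition_effects)) {
    shift <- config$composition_effects
    prop["tumor", names(shift)] <- prop["tumor", names(shift)] * shift
    prop["tumor", ] <- prop["tumor", ] / sum(prop["tumor", ])
  }

  centers <- cbind(x = 4 * cos(2 * pi * seq_len(n_types) / n_types),
                   y = 4 * sin(2 * pi * seq_len(n_types) / n_types))
  rownames(centers) <- ct_names

  n_s <- config$n_samples_per_condition
  samples <- c(sprintf("T%02d", seq_len(n_s)), sprintf("N%02d", seq_len(n_s)))
  cond_of <- rep(c("tumor", "normal"), each = n_s)

  blocks <- vector("list", length(samples))
  meta_blocks <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    n_cells <- max(20L, rnbinom(1, mu = config$cells_per_sample,
                                size = config$cells_dispersion))
    frac <- .rdirichlet(config$dirichlet_conc * prop[cond_of[si], ])
    types <- sample(ct_names, n_cells, replace = TRUE, prob = frac)
    depth <- runif(n_cells, config$depth_range[1], config$depth_range[2])
    mu_fac <- type_fx[, types, drop = FALSE] * lr_fx[, types, drop = FALSE]
    if (cond_of[si] == "tumor")
      mu_fac <- mu_fac * de_fx[, types, drop = FALSE]
    mu <- base_mu * mu_fac * rep(depth, each = config$n_genes)
    cnt <- matrix(rnbinom(length(mu), mu = mu, size = config$dispersion),
                  nrow = config$n_genes)
    blocks[[si]] <- methods::as(Matrix::Matrix(cnt, sparse = TRUE), "generalMatrix")
    is_dbl <- runif(n_cells) < config$doublet_rate
    ds <- ifelse(is_dbl, rbeta(n_cells, 8, 2), rbeta(n_cells, 2, 30))
    meta_blocks[[si]] <- data.frame(
      sample = samples[si], condition = cond_of[si], cell_type = types,
      x = rnorm(n_cells, centers[types, "x"], config$embedding_spread),
      y = rnorm(n_cells, centers[types, "y"], config$embedding_spread),
      doublet_score = pmin(pmax(ds, 0), 1))
  }
  counts <- do.call(cbind, blocks)
  meta <- do.call(rbind, meta_blocks)
  rownames(counts) <- genes
  colnames(counts) <- sprintf("cell%06d", seq_len(ncol(counts)))

  truth <- list(cell_type = meta$cell_type,
                markers = marker_map,
                de = de_truth,
                composition = prop,
                lr = config$lr_plants,
                base_mu = base_mu,
                dispersion = config$dispersion)
  list(cm = cell_matrix(counts, meta = meta), truth = truth)
}

#' Simulate a bulk expression cohort with signature-dependent hazard
#'
#' Per-sample log-scale expression is Gaussian; event times are exponential
#' with log-hazard linear in the standardized mean expression of the signature
#' genes; censoring is independent exponential tuned to the requested rate.
#'
#' @param n_samples cohort size
#' @param genes gene symbols of the expression matrix
#' @param signature a \code{GeneSet}; must be a subset of \code{genes}
#' @param hazard_log_hr log hazard ratio per SD of signature score (0 = null)
#' @param censor_rate target fraction censored (0 = all events observed)
#' @param seed integer seed
#' @return object of class \code{SurvivalCohort}: list with \code{expression}
#'   (samples x genes, log scale), \code{time}, \code{event}, \code{score}.
#' @export
simulate_bulk_survival <- function(n_samples, genes, signature,
                                   hazard_log_hr = 0, censor_rate = 0.3,
                                   seed = 1L) {
  if (length(signature$genes) == 0) stop("empty signature")
  if (!all(signature$genes %in% genes)) stop("signature not a subset of genes")
  set.seed(child_seed(seed, "bulk_survival"))
  g_mu <- rnorm(length(genes), 5, 1)
  expr <- matrix(rnorm(n_samples * length(genes), rep(g_mu, each = n_samples), 1),
                 nrow = n_samples, dimnames = list(sprintf("S%04d", seq_len(n_samples)),
                                                   genes))
  score <- rowMeans(expr[, signature$genes, drop = FALSE])
  z <- as.numeric(scale(score))
  t_event <- rexp(n_samples, rate = 0.1 * exp(hazard_log_hr * z))
  if (censor_rate > 0) {
    t_cens <- rexp(n_samples, rate = 0.1 * censor_rate / (1 - censor_rate))
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1L, n_samples)
  }
  structure(list(expression = expr, time = time, event = event, score = score),
            class = "SurvivalCohort")
}

#' Read a bulk survival cohort from a wide TSV
#'
#' Expects columns \code{sample}, \code{time}, \code{event}, optional
#' \code{stage}, followed by one column per gene (log-scale expression).
#' @param path TSV path
#' @param log1p_transform set TRUE for raw-count cohorts to apply log1p
#' @return a \code{SurvivalCohort}.
#' @export
read_survival_cohort <- function(path, log1p_transform = FALSE) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  clinical <- intersect(c("sample", "time", "event", "stage"), colnames(tab))
  genes <- setdiff(colnames(tab), clinical)
  expr <- as.matrix(tab[, genes, drop = FALSE])
  rownames(expr) <- tab$sample
  if (log1p_transform) expr <- log1p(expr)
  structure(list(expression = expr, time = tab$time, event = as.integer(tab$event),
                 stage = if ("stage" %in% clinical) tab$stage else NULL),
            class = "SurvivalCohort")
}
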