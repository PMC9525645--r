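# Config-driven orchestration: one entry point runs QC, normalization,
# scoring, abundance, expression distance, markers, signature selection,
# interactions and survival in dependency order, writing TSV outputs and a
# per-stage manifest. Two parameter profiles are exposed: the study defaults
# and a reduced test scale.

#' Study-default pipeline parameters
#'
#' The thresholds used throughout the analysis: 700-UMI and 0.4-doublet QC
#' cutoffs, 10 percent ligand/receptor detection screen, marker-Z cutoff 3,
#' 1000 permutations, 100 bootstrap rounds, top/bottom 25 percent survival
#' strata, 400-bin density grids, 10-cell pseudobulk minimum and 40-cell
#' per-sample minimum for subtype analyses.
#' @return named list of parameters.
#' @export
paper_defaults <- function() {
  list(min_umi = 700, max_doublet = 0.4, scale = 1e4, pseudocount = 1,
       lr_min_frac = 0.10, z_min = 3, n_perm = 1000, n_boot = 1000,
       n_boot_survival = 100, quartile = 0.25, gridsize = 400,
       min_cells_pseudobulk = 10, min_cells_subtype = 40,
       n_rounds_distance = 100, cells_per_boot = 1000)
}

#' Reduced test-scale pipeline parameters
#'
#' Same structure as \code{\link{paper_defaults}} with smaller grids and
#' fewer resampling rounds for fast exploratory runs.
#' @return named list of parameters.
#' @export
test_profile <- function() {
  p <- paper_defaults()
  p$gridsize <- 100; p$n_perm <- 200; p$n_boot <- 200
  p$n_rounds_distance <- 5; p$cells_per_boot <- 500
  p
}

#' Assemble a pipeline configuration
#'
#' @param matrix_dir 10x-style triplet directory (with metadata.tsv), or NULL
#'   when a CellMatrix is passed to \code{run_pipeline} directly
#' @param gene_sets path to a gene-set TSV/GMT, or a list of GeneSets
#' @param lr_pairs path to an LR pair TSV, or an LRPairTable
#' @param survival_cohort path to a wide survival TSV, or a SurvivalCohort
#' @param survival_signature GeneSet (or gene-set file) scored on the bulk
#'   cohort; defaults to \code{gene_sets}
#' @param stages character vector of stages to run, among qc, normalize,
#'   score, abundance, distance, markers, interactions, survival
#' @param params parameter list (default \code{\link{paper_defaults}});
#'   unknown parameter names are rejected
#' @param seed global seed
#' @return \code{PipelineConfig} list.
#' @export
pipeline_config <- function(matrix_dir = NULL, gene_sets = NULL,
                            lr_pairs = NULL, survival_cohort = NULL,
                            survival_signature = NULL,
                            stages = c("qc", "normalize", "score", "abundance",
                                       "distance", "markers", "interactions",
                                       "survival"),
                            params = paper_defaults(), seed = 1L) {
  known <- names(paper_defaults())
  bad <- setdiff(names(params), known)
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
  params <- utils::modifyList(paper_defaults(), params)
  all_stages <- c("qc", "normalize", "score", "abundance", "distance",
                  "markers", "interactions", "survival")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  structure(list(matrix_dir = matrix_dir, gene_sets = gene_sets,
                 lr_pairs = lr_pairs, survival_cohort = survival_cohort,
                 survival_signature = survival_signature,
                 stages = stages, params = params, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with keys matching \code{\link{pipeline_config}}
#' @return \code{PipelineConfig}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

.stage_log <- function(manifest, stage, outputs, params, t0) {
  manifest[[stage]] <- list(stage = stage, status = "success",
                            outputs = outputs, parameters = params,
                            runtime_s = round(as.numeric(Sys.time()) - t0, 3))
  manifest
}

#' Run the pipeline on a cohort
#'
#' Executes the enabled stages in dependency order (QC before normalization,
#' normalization before all expression statistics; survival runs
#' independently), writes every result table as TSV into \code{outdir} and a
#' \code{manifest.json} recording stage status, parameters, seed and runtime.
#' Stage prerequisites are checked up front: a stage whose required metadata
#' or upstream stage is missing raises an error naming it.
#'
#' @param config a \code{PipelineConfig}
#' @param outdir output directory (created)
#' @param cm optional CellMatrix (used instead of reading
#'   \code{config$matrix_dir})
#' @return \code{outdir}, invisibly; side effect: result TSVs and manifest.
#' @export
run_pipeline <- function(config, outdir, cm = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  manifest <- list()
  stages <- config$stages

  if (is.null(cm) && any(stages != "survival")) {
    if (is.null(config$matrix_dir)) stop("no input matrix: set matrix_dir or pass cm")
    cm <- read_10x_mtx(config$matrix_dir)
    meta_f <- file.path(config$matrix_dir, "metadata.tsv")
    if (file.exists(meta_f)) cm <- attach_metadata(cm, meta_f)
  }
  needs_types <- intersect(stages, c("distance", "markers", "interactions"))
  if (length(needs_types) && !"cell_type" %in% colnames(cm$meta))
    stop("stage ", needs_types[1], " requires cell_type metadata, which is absent")
  if ("score" %in% stages && is.null(config$gene_sets))
    stop("stage score requires gene_sets")
  if ("interactions" %in% stages && is.null(config$lr_pairs))
    stop("stage interactions requires lr_pairs")
  if ("survival" %in% stages && is.null(config$survival_cohort))
    stop("stage survival requires survival_cohort")

  if ("qc" %in% stages) {
    t0 <- as.numeric(Sys.time())
    cm <- filter_cells(cm, min_umi = p$min_umi,
                       max_doublet = if ("doublet_score" %in% colnames(cm$meta))
                         p$max_doublet else NULL)
    manifest <- .stage_log(manifest, "qc", character(0),
                           p[c("min_umi", "max_doublet")], t0)
  }

  nm <- NULL
  if (any(stages %in% c("normalize", "score", "markers", "interactions"))) {
    t0 <- as.numeric(Sys.time())
    nm <- normalize_cells(cm, scale = p$scale, pseudocount = p$pseudocount)
    manifest <- .stage_log(manifest, "normalize", character(0),
                           p[c("scale", "pseudocount")], t0)
  }

  if ("score" %in% stages) {
    t0 <- as.numeric(Sys.time())
    sets <- if (is.character(config$gene_sets)) read_gene_sets(config$gene_sets)
            else config$gene_sets
    outs <- character(0)
    comp <- list()
    for (gs in sets) {
      sc <- score_samples(score_cells(nm, gs), cm)
      f <- file.path(outdir, paste0("scores_", gs$name, ".tsv"))
      write_scores(sc, f); outs <- c(outs, f)
      comp[[gs$name]] <- compare_scores(sc)
    }
    f <- file.path(outdir, "score_comparisons.tsv")
    write.table(do.call(rbind, comp), f, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- .stage_log(manifest, "score", c(outs, f), list(), t0)
  }

  if ("abundance" %in% stages) {
    t0 <- as.numeric(Sys.time())
    outs <- character(0)
    pt <- proportion_tests(cm)
    f <- file.path(outdir, "proportion_tests.tsv")
    write.table(pt, f, sep = "\t", quote = FALSE, row.names = FALSE)
    outs <- c(outs, f)
    if (all(c("x", "y") %in% colnames(cm$meta))) {
      dg <- quantile_normalize_grids(estimate_density(cm, gridsize = p$gridsize))
      dd <- density_diff(dg)
      f <- file.path(outdir, "density_diff.tsv")
      write_density_diff(dd, f, file.path(outdir, "density_diff.png"))
      outs <- c(outs, f)
    }
    fr <- cell_type_fractions(cm)
    coda <- coda_coefficients(fr$counts, fr$condition, n_boot = p$n_boot,
                              cells_per_boot = p$cells_per_boot,
                              seed = config$seed)
    f <- file.path(outdir, "coda_coefficients.tsv")
    write_coda(coda, f)
    manifest <- .stage_log(manifest, "abundance", c(outs, f),
                           p[c("gridsize", "n_boot", "cells_per_boot")], t0)
  }

  pb <- NULL
  if (any(stages %in% c("distance", "markers", "interactions"))) {
    pb <- make_pseudobulk(cm, min_cells = p$min_cells_pseudobulk)
  }

  if ("distance" %in% stages) {
    t0 <- as.numeric(Sys.time())
    dr <- celltype_distance(cm, min_cells = p$min_cells_pseudobulk,
                            n_rounds = p$n_rounds_distance, seed = config$seed)
    pt <- distance_permutation_test(dr, n_perm = p$n_perm, seed = config$seed)
    f1 <- file.path(outdir, "expression_distance.tsv")
    write.table(pt, f1, sep = "\t", quote = FALSE, row.names = FALSE)
    sm <- overall_sample_distance(pb)
    f2 <- file.path(outdir, "sample_distance_matrix.tsv")
    write.table(sm$distance_matrix, f2, sep = "\t", quote = FALSE)
    f3 <- file.path(outdir, "sample_mds.tsv")
    write.table(data.frame(sample = rownames(sm$mds_coords), sm$mds_coords,
                           condition = sm$condition),
                f3, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- .stage_log(manifest, "distance", c(f1, f2, f3),
                           p["n_rounds_distance"], t0)
  }

  markers <- NULL
  if (any(stages %in% c("markers", "interactions"))) {
    t0 <- as.numeric(Sys.time())
    markers <- marker_genes(nm, cm$meta$cell_type, z_min = p$z_min)
    if ("markers" %in% stages) {
      f <- file.path(outdir, "markers.tsv")
      write.table(markers, f, sep = "\t", quote = FALSE, row.names = FALSE)
      manifest <- .stage_log(manifest, "markers", f, p["z_min"], t0)
    }
  }

  if ("interactions" %in% stages) {
    t0 <- as.numeric(Sys.time())
    pairs <- if (is.character(config$lr_pairs)) read_lr_pairs(config$lr_pairs)
             else config$lr_pairs
    cand <- screen_pairs(nm, cm$meta$cell_type, pairs, min_frac = p$lr_min_frac)
    cand <- score_pairs(nm, cm$meta$cell_type, cand)
    cand <- lr_permutation_test(nm, cm$meta$cell_type, cand,
                                n_perm = p$n_perm, seed = config$seed)
    cand <- specificity_filter(markers, cand, z_min = p$z_min)
    f <- file.path(outdir, "interactions.tsv")
    write.table(cand, f, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- .stage_log(manifest, "interactions", f,
                           p[c("lr_min_frac", "n_perm", "z_min")], t0)
  }

  if ("survival" %in% stages) {
    t0 <- as.numeric(Sys.time())
    sig_in <- if (!is.null(config$survival_signature)) config$survival_signature
              else config$gene_sets
    if (is.null(sig_in)) stop("stage survival requires survival_signature or gene_sets")
    sets <- if (is.character(sig_in)) read_gene_sets(sig_in)
            else if (inherits(sig_in, "GeneSet")) list(sig_in) else sig_in
    cohort <- if (is.character(config$survival_cohort))
      read_survival_cohort(config$survival_cohort) else config$survival_cohort
    rows <- lapply(sets, function(gs) {
      st <- reproducibility_power(cohort, gs, n_boot = p$n_boot_survival,
                                  q = p$quartile, seed = config$seed)
      data.frame(set = gs$name, logrank_p = st$p, power_p = st$power_p,
                 n_genes = st$n_genes_used)
    })
    f <- file.path(outdir, "survival.tsv")
    write.table(do.call(rbind, rows), f, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- .stage_log(manifest, "survival", f,
                           p[c("n_boot_survival", "quartile")], t0)
  }

  manifest$seed <- config$seed
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
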