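# Simulation studies that exercise the whole pipeline against ground truth:
# false-positive calibration on exchangeable cohorts, recovery of planted
# compositional / expression / ligand-receptor effects, and the power and
# conservatism of the survival reproducibility-power p-value.

.null_cohort_config <- function(seed, n_samples = 5, cells = 80, genes = 60) {
  simulation_config(n_samples_per_condition = n_samples,
                    cells_per_sample = cells, n_genes = genes,
                    cell_types = c(A = 0.4, B = 0.35, C = 0.25),
                    marker_genes_per_type = 0, doublet_rate = 0, seed = seed)
}

#' Null calibration of the two-condition tests
#'
#' Simulates exchangeable cohorts (no compositional, expression or
#' ligand-receptor effects; tumor and normal samples drawn from one law) and
#' measures how often each test rejects at nominal 0.05: the per-type
#' proportion rank-sum test, the expression-distance permutation test, the
#' BH-adjusted ligand-receptor permutation test, and the fraction of occupied
#' density bins with |Z| > 1.96. Cohorts use 5 + 5 samples of ~80 cells over
#' 60 genes and 3 cell types; densities are evaluated on the first
#' \code{density_cohorts} cohorts at grid size 40.
#'
#' @param n_cohorts cohorts simulated (default 200)
#' @param density_cohorts cohorts entering the density calibration (default 100)
#' @param n_perm_distance sample-label permutations per cohort (default 60)
#' @param n_perm_lr cell-label permutations per cohort (default 100)
#' @param seed integer seed
#' @return list of rejection rates and the counts they are based on.
#' @export
calibrate_null <- function(n_cohorts = 200, density_cohorts = 100,
                           n_perm_distance = 60, n_perm_lr = 100, seed = 1L) {
  prop_p <- c(); dist_p <- c(); lr_sig <- c(); dens_flag <- c()
  for (i in seq_len(n_cohorts)) {
    cfg <- .null_cohort_config(child_seed(seed, paste0("null", i)))
    sim <- simulate_cohort(cfg)
    cm <- sim$cm
    suppressMessages({
      pt <- proportion_tests(cm)
      prop_p <- c(prop_p, pt$p)

      dr <- suppressWarnings(celltype_distance(cm, min_cells = 10, n_rounds = 2,
                                               seed = child_seed(seed, paste0("d", i))))
      if (length(dr$per_type)) {
        dp <- distance_permutation_test(dr, n_perm = n_perm_distance,
                                        seed = child_seed(seed, paste0("dp", i)))
        dist_p <- c(dist_p, dp$p)
      }

      pairs <- lr_pair_table(sprintf("G%04d", c(5, 15, 25)),
                             sprintf("G%04d", c(35, 45, 55)))
      cand <- screen_pairs(normalize_cells(cm), cm$meta$cell_type, pairs)
      if (nrow(cand)) {
        res <- lr_permutation_test(normalize_cells(cm), cm$meta$cell_type,
                                   cand, n_perm = n_perm_lr,
                                   seed = child_seed(seed, paste0("lr", i)))
        lr_sig <- c(lr_sig, res$p_adj < 0.05)
      }

      if (i <= density_cohorts) {
        dg <- quantile_normalize_grids(estimate_density(cm, gridsize = 40))
        dd <- density_diff(dg)
        dens_flag <- c(dens_flag, mean(abs(dd$z[dd$mask]) > 1.96))
      }
    })
  }
  list(fpr_proportion = mean(prop_p < 0.05), n_proportion = length(prop_p),
       fpr_distance = mean(dist_p < 0.05), n_distance = length(dist_p),
       fpr_lr = mean(lr_sig), n_lr = length(lr_sig),
       density_flag_rate = mean(dens_flag), n_density = length(dens_flag))
}

#' Recovery of planted effects by the abundance, distance and LR stages
#'
#' Three planted-effect studies at the study's design scale: (i) a cell type
#' whose tumor proportion is doubled (10 + 10 samples) must earn a positive
#' compositional separating coefficient in nearly all bootstrap draws and a
#' significant proportion test in most runs; (ii) condition-specific DE
#' planted in one cell type must give that type the largest normalized
#' expression distance; (iii) a planted ligand-receptor co-elevation (fold 4)
#' must reach BH-adjusted significance.
#'
#' @param n_runs_proportion runs for the proportion-test power (default 100)
#' @param n_runs_distance runs for the distance ranking (default 100)
#' @param n_runs_lr runs for the LR recovery (default 50)
#' @param n_boot_coda bootstrap draws for the compositional study (default 1000)
#' @param seed integer seed
#' @return list of recovery rates and the planted-signature flags.
#' @export
recover_planted <- function(n_runs_proportion = 100, n_runs_distance = 100,
                            n_runs_lr = 50, n_boot_coda = 1000, seed = 1L) {
  doubled <- function(s, cells) simulation_config(
    n_samples_per_condition = 10, cells_per_sample = cells,
    cell_types = c(A = 0.2, B = 0.45, C = 0.35),
    composition_effects = c(A = 2), marker_genes_per_type = 0,
    n_genes = 10, seed = s)

  # (i) compositional: bootstrap sign stability + proportion-test power
  sim <- simulate_cohort(doubled(child_seed(seed, "coda"), 200))
  fr <- suppressMessages(cell_type_fractions(sim$cm))
  coda <- coda_coefficients(fr$counts, fr$condition, n_boot = n_boot_coda,
                            cells_per_boot = 1000,
                            seed = child_seed(seed, "codaboot"))
  coda_pos <- coda$positive_fraction[["A"]]

  prop_hits <- vapply(seq_len(n_runs_proportion), function(i) {
    s <- simulate_cohort(doubled(child_seed(seed, paste0("prop", i)), 150))
    pt <- suppressMessages(proportion_tests(s$cm))
    pt$p[pt$cell_type == "A"] < 0.05
  }, logical(1))

  # (ii) planted DE in one type dominates the normalized distance ranking
  dist_hits <- vapply(seq_len(n_runs_distance), function(i) {
    cfg <- simulation_config(
      n_samples_per_condition = 5, cells_per_sample = 150, n_genes = 200,
      cell_types = c(A = 0.5, B = 0.5), marker_genes_per_type = 0,
      de_effects = list(list(cell_type = "A", genes = 101:130, log2fc = 2)),
      seed = child_seed(seed, paste0("dist", i)))
    s <- simulate_cohort(cfg)
    dr <- suppressWarnings(suppressMessages(
      celltype_distance(s$cm, n_rounds = 2,
                        seed = child_seed(seed, paste0("distsub", i)))))
    tab <- dr$table
    tab$normalized_distance[tab$cell_type == "A"] ==
      max(tab$normalized_distance)
  }, logical(1))

  # (iii) planted LR co-elevation reaches adjusted significance
  lr_hits <- vapply(seq_len(n_runs_lr), function(i) {
    cfg <- simulation_config(
      n_samples_per_condition = 4, cells_per_sample = 150, n_genes = 120,
      cell_types = c(Tcell = 0.4, Myeloid = 0.3, Stroma = 0.3),
      lr_plants = list(list(ligand = "G0100", sender = "Myeloid",
                            receptor = "G0110", receiver = "Stroma",
                            effect = 4)),
      seed = child_seed(seed, paste0("lrp", i)))
    s <- simulate_cohort(cfg)
    nm <- normalize_cells(s$cm)
    pairs <- lr_pair_table(c("G0100", "G0050"), c("G0110", "G0060"))
    cand <- suppressMessages(screen_pairs(nm, s$cm$meta$cell_type, pairs))
    res <- lr_permutation_test(nm, s$cm$meta$cell_type, cand, n_perm = 200,
                               seed = child_seed(seed, paste0("lrt", i)))
    hit <- res[res$pair_id == "G0100_G0110" & res$sender == "Myeloid" &
                 res$receiver == "Stroma", ]
    nrow(hit) == 1 && hit$p_adj < 0.05
  }, logical(1))

  list(coda_positive_fraction = coda_pos,
       proportion_power = mean(prop_hits), n_proportion = length(prop_hits),
       distance_top_rate = mean(dist_hits), n_distance = length(dist_hits),
       lr_recovery = mean(lr_hits), n_lr = length(lr_hits))
}

#' Planted-signature selection study
#'
#' Builds a cohort with tumor subclones C1-C4 where one gene is elevated only
#' in the C4 subclone and a second, confounded gene is equally elevated in C4
#' and in macrophages; the multi-round selection must keep the first and drop
#' the second.
#'
#' @param seed integer seed
#' @return list with logical \code{planted_in_final} and
#'   \code{confounded_excluded}.
#' @export
signature_selection_study <- function(seed = 1L) {
  cfg <- simulation_config(
    n_samples_per_condition = 4, cells_per_sample = 250, n_genes = 300,
    cell_types = c(Tumor = 0.5, Tcell = 0.25, Myeloid = 0.25),
    seed = child_seed(seed, "sigsel"))
  sim <- simulate_cohort(cfg)
  cm <- sim$cm
  set.seed(child_seed(seed, "subclones"))
  tum <- cm$meta$cell_type == "Tumor"
  sub <- rep(NA_character_, ncol(cm$counts))
  sub[tum] <- sample(paste0("C", 1:4), sum(tum), replace = TRUE)
  counts <- as.matrix(cm$counts)
  c4 <- which(!is.na(sub) & sub == "C4")
  mac <- which(cm$meta$cell_type == "Myeloid")
  counts["G0200", c4] <- counts["G0200", c4] + stats::rpois(length(c4), 20)
  counts["G0201", c4] <- counts["G0201", c4] + stats::rpois(length(c4), 20)
  counts["G0201", mac] <- counts["G0201", mac] + stats::rpois(length(mac), 20)
  nm <- normalize_cells(cell_matrix(counts, meta = cm$meta))
  sel <- select_metastatic_signature(nm, sub, cm$meta$cell_type,
                                     tumor_types = "Tumor", target = "C4",
                                     top_n = 10)
  list(planted_in_final = "G0200" %in% sel$final$genes,
       confounded_excluded = !"G0201" %in% sel$final$genes,
       n_final = length(sel$final$genes))
}

#' Power and conservatism of the reproducibility-power p-value
#'
#' Simulates bulk cohorts of \code{n_samples} with a 10-gene signature whose
#' standardized score carries log hazard ratio \code{hazard_log_hr}
#' (alternative) or 0 (null), runs the quartile-stratified log-rank analysis
#' with 100 gene-bootstrap rounds, and reports how often the 0.95-quantile
#' bootstrap p-value falls below 0.05 in each regime.
#'
#' @param n_runs_alt alternative-cohort runs (default 50)
#' @param n_runs_null null-cohort runs (default 100)
#' @param n_samples cohort size (default 300)
#' @param hazard_log_hr alternative log hazard ratio (default 0.7)
#' @param seed integer seed
#' @return list with \code{power_rate}, \code{null_rate} and run counts.
#' @export
survival_power_study <- function(n_runs_alt = 50, n_runs_null = 100,
                                 n_samples = 300, hazard_log_hr = 0.7,
                                 seed = 1L) {
  genes <- sprintf("B%03d", 1:50)
  sig <- gene_set("sig10", genes[1:10])
  run <- function(hr, tag, i) {
    coh <- simulate_bulk_survival(n_samples, genes, sig, hazard_log_hr = hr,
                                  censor_rate = 0.3,
                                  seed = child_seed(seed, paste0(tag, i)))
    st <- suppressMessages(
      reproducibility_power(coh, sig, n_boot = 100,
                            seed = child_seed(seed, paste0(tag, "b", i))))
    st$power_p < 0.05
  }
  alt <- vapply(seq_len(n_runs_alt), function(i) run(hazard_log_hr, "alt", i),
                logical(1))
  nul <- vapply(seq_len(n_runs_null), function(i) run(0, "null", i), logical(1))
  list(power_rate = mean(alt), n_alt = length(alt),
       null_rate = mean(nul), n_null = length(nul))
}
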