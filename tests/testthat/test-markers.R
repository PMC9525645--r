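nm_from <- function(values) {
  structure(list(values = methods::as(Matrix::Matrix(values, sparse = TRUE),
                                      "generalMatrix")),
            class = "NormalizedMatrix")
}

test_that("marker Z is signed, null at equality, and huge for exclusive genes", {
  set.seed(2)
  n_in <- 50; n_out <- 500
  vals <- rbind(flat = rep(1.5, n_in + n_out),
                excl = c(rep(5, n_in), rep(0, n_out)),
                noise = rnorm(n_in + n_out))
  colnames(vals) <- paste0("c", seq_len(ncol(vals)))
  cl <- c(rep("A", n_in), rep("B", n_out))
  tab <- marker_genes(nm_from(vals), cl)

  a <- tab[tab$cluster == "A", ]
  expect_equal(a$z[a$gene == "flat"], 0)
  expect_false(a$marker[a$gene == "flat"])
  expect_true(a$marker[a$gene == "excl"])
  expect_equal(a$frac_in[a$gene == "excl"], 1)
  expect_equal(a$frac_out[a$gene == "excl"], 0)
  # Z and p are mutually consistent
  expect_equal(abs(a$z), qnorm(a$p / 2, lower.tail = FALSE), tolerance = 1e-9)

  expect_warning(marker_genes(nm_from(vals), c("A", "A", rep("B", ncol(vals) - 2))),
                 "fewer than 3")
  expect_error(marker_genes(nm_from(vals), rep("A", ncol(vals))), "2 clusters")
})

test_that("marker Z agrees with exact rank-sum enumeration in small clusters", {
  set.seed(5)
  for (rep_i in 1:5) {
    v <- matrix(sample(seq(0.1, 10, by = 0.1), 8), nrow = 1,
                dimnames = list("g", paste0("c", 1:8)))
    cl <- c(rep("A", 4), rep("B", 4))
    tab <- marker_genes(nm_from(v), cl)
    p_exact <- enum_ranksum_p(v[1, 1:4], v[1, 5:8])
    z_exact <- qnorm(p_exact / 2, lower.tail = FALSE)
    expect_lt(abs(abs(tab$z[tab$cluster == "A"][1]) - z_exact), 0.05)
  }
})

test_that("on exchangeable null data at most ~1% of genes reach Z > 3", {
  cfg <- null_config(61, n_samples = 2, cells = 300, genes = 250,
                     types = c(A = 0.5, B = 0.5))
  sim <- simulate_cohort(cfg)
  nm <- normalize_cells(sim$cm)
  tab <- marker_genes(nm, sim$cm$meta$cell_type)
  expect_lte(mean(tab$z > 3), 0.01)
})

test_that("pseudobulk DE recovers planted fold changes and respects contrasts", {
  cfg <- simulation_config(
    n_samples_per_condition = 6, cells_per_sample = 120, n_genes = 1000,
    cell_types = c(A = 1), marker_genes_per_type = 0, dispersion = 10,
    de_effects = list(list(cell_type = "A", genes = 1:100, log2fc = 1)),
    seed = 71)
  sim <- simulate_cohort(cfg)
  pb <- make_pseudobulk(sim$cm)
  de <- pseudobulk_de(pb, "A")
  planted <- de$log2FoldChange[1:100]
  expect_gte(mean(abs(planted - 1) <= 0.3), 0.9)
  # unplanted genes sit at the depth-offset baseline: planting 10% of the
  # transcriptome at 2x raises tumor totals ~1.1x, shifting the baseline by
  # about -log2(1.1); they stay well separated from the planted block
  base <- mean(de$log2FoldChange[101:1000])
  expect_lt(abs(base + log2(1.1)), 0.06)
  expect_gt(mean(planted) - base, 0.8)
  expect_true(all(de$p_adj >= de$p - 1e-12))

  # swapping condition labels negates the fold changes
  pb_sw <- pb
  pb_sw$condition <- ifelse(pb$condition == "tumor", "normal", "tumor")
  de_sw <- pseudobulk_de(pb_sw, "A")
  expect_equal(de_sw$log2FoldChange, -de$log2FoldChange, tolerance = 1e-6)

  expect_error(pseudobulk_de(pb, "missing_type"), "no profiles")

  # a gene with identical profiles across all samples carries no signal
  cfg0 <- null_config(73, n_samples = 4, cells = 100, genes = 60,
                      types = c(A = 1))
  pb0 <- make_pseudobulk(simulate_cohort(cfg0)$cm)
  pb0$profiles[5, ] <- 7
  de0 <- pseudobulk_de(pb0, "A")
  expect_lt(abs(de0$log2FoldChange[5]), 0.2)
  expect_gt(de0$p[5], 0.5)
})

test_that("NB-GLM fold changes agree with an independent DESeq2 fit", {
  # a small planted fraction keeps total-count and median-of-ratios size
  # factors close, so the two normalizations are comparable gene by gene
  cfg <- simulation_config(
    n_samples_per_condition = 5, cells_per_sample = 100, n_genes = 300,
    cell_types = c(A = 1), marker_genes_per_type = 0, dispersion = 10,
    de_effects = list(list(cell_type = "A", genes = 1:15, log2fc = 1)),
    seed = 72)
  sim <- simulate_cohort(cfg)
  pb <- make_pseudobulk(sim$cm)
  de <- pseudobulk_de(pb, "A")

  mat <- round(pb$profiles)
  storage.mode(mat) <- "integer"
  coldata <- S4Vectors::DataFrame(condition = factor(pb$condition,
                                                     levels = c("normal", "tumor")))
  dds <- DESeq2::DESeqDataSetFromMatrix(mat, coldata, ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds)
  ok <- !is.na(res$log2FoldChange)
  expect_gt(cor(de$log2FoldChange[ok], res$log2FoldChange[ok]), 0.95)
  expect_lt(mean(abs(de$log2FoldChange[1:15] - res$log2FoldChange[1:15])), 0.25)
})

test_that("multi-round selection keeps target-specific genes and drops confounded ones", {
  cfg <- simulation_config(
    n_samples_per_condition = 4, cells_per_sample = 250, n_genes = 300,
    cell_types = c(Tumor = 0.5, Tcell = 0.25, Myeloid = 0.25), seed = 11)
  sim <- simulate_cohort(cfg)
  cm <- sim$cm
  tum <- cm$meta$cell_type == "Tumor"
  sub <- rep(NA_character_, ncol(cm$counts))
  set.seed(12)
  sub[tum] <- sample(paste0("C", 1:4), sum(tum), replace = TRUE)
  counts <- as.matrix(cm$counts)
  c4 <- which(sub == "C4"); mac <- which(cm$meta$cell_type == "Myeloid")
  counts["G0200", c4] <- counts["G0200", c4] + rpois(length(c4), 20)
  counts["G0201", c4] <- counts["G0201", c4] + rpois(length(c4), 20)
  counts["G0201", mac] <- counts["G0201", mac] + rpois(length(mac), 20)
  cm2 <- cell_matrix(counts, meta = cm$meta)
  nm <- normalize_cells(cm2)
  sel <- select_metastatic_signature(nm, sub, cm2$meta$cell_type,
                                     tumor_types = "Tumor", target = "C4",
                                     top_n = 10)
  # the clean C4 gene passes both rounds; the macrophage-confounded gene is
  # outranked by genes genuinely specific to tumor cells in round 2
  expect_true("G0200" %in% sel$final$genes)
  expect_false("G0201" %in% sel$final$genes)
  expect_true(all(sel$final$genes %in% sel$round1_top))
  expect_true(all(sel$final$genes %in% sel$round2_top))

  # relabeling non-target subclones leaves the signature unchanged
  sub_rl <- sub
  sub_rl[sub %in% c("C1", "C2", "C3")] <-
    c(C1 = "K3", C2 = "K1", C3 = "K2")[sub[sub %in% c("C1", "C2", "C3")]]
  sel_rl <- select_metastatic_signature(nm, sub_rl, cm2$meta$cell_type,
                                        tumor_types = "Tumor", target = "C4",
                                        top_n = 10)
  expect_identical(sel_rl$final$genes, sel$final$genes)

  # a target with no enriched genes at all yields an empty signature:
  # with fully tied expression every Z is 0, so no gene passes either round
  n0 <- 700
  counts0 <- matrix(1, 30, n0,
                    dimnames = list(paste0("g", 1:30), paste0("c", 1:n0)))
  types0 <- rep(c("Tumor", "Tcell", "Myeloid"), length.out = n0)
  sub0 <- ifelse(types0 == "Tumor",
                 rep(paste0("C", 1:4), length.out = n0), NA)
  nm0 <- normalize_cells(cell_matrix(counts0))
  expect_warning(
    sel0 <- select_metastatic_signature(nm0, sub0, types0,
                                        tumor_types = "Tumor", target = "C4",
                                        top_n = 5),
    "empty intersection")
  expect_length(sel0$final$genes, 0)
})
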