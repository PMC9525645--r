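density_fixture <- function(seed = 1, n_per = 3) {
  cfg <- null_config(seed, n_samples = n_per, cells = 60, genes = 10)
  simulate_cohort(cfg)$cm
}

test_that("per-sample densities integrate to one on the shared grid", {
  cm <- density_fixture()
  dg <- estimate_density(cm, gridsize = 40)
  sums <- vapply(dg$grids, function(g) sum(g) * dg$bin_area, numeric(1))
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(vapply(dg$grids, function(g) all(g >= 0), TRUE)))

  # two samples with identical coordinates get identical grids
  meta <- cm$meta
  s1 <- which(meta$sample == meta$sample[1])
  meta2 <- meta[c(s1, s1), ]
  meta2$sample <- rep(c("X1", "X2"), each = length(s1))
  cm2 <- cell_matrix(cm$counts[, c(s1, s1)],
                     cell_ids = paste0("c", seq_len(2 * length(s1))),
                     meta = meta2)
  dg2 <- estimate_density(cm2, gridsize = 30)
  expect_equal(dg2$grids$X1, dg2$grids$X2)

  # samples with < 10 cells are excluded with a warning
  meta3 <- meta; meta3$sample[1:5] <- "tiny"
  cm3 <- cell_matrix(cm$counts, meta = meta3)
  expect_warning(dg3 <- estimate_density(cm3, gridsize = 20), "fewer than 10")
  expect_false("tiny" %in% names(dg3$grids))
})

test_that("quantile normalization equalizes sorted vectors and is rank-faithful", {
  cm <- density_fixture(2)
  dg <- estimate_density(cm, gridsize = 30)
  qn <- quantile_normalize_grids(dg)
  sorted <- vapply(qn$grids, function(g) sort(as.vector(g)),
                   numeric(length(qn$grids[[1]])))
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-10))

  # identical grids are unchanged (up to the common reference, i.e. themselves)
  dg2 <- dg; dg2$grids <- dg$grids[c(1, 1)]
  names(dg2$grids) <- c("a", "b")
  qn2 <- quantile_normalize_grids(dg2)
  expect_equal(qn2$grids$a, dg$grids[[1]])

  # grids that are monotone transforms of each other normalize identically
  dg3 <- dg2
  dg3$grids$b <- sqrt(dg3$grids$b) + 2
  qn3 <- quantile_normalize_grids(dg3)
  expect_equal(qn3$grids$a, qn3$grids$b)
})

test_that("the density Z map honors the mask, symmetry and null contracts", {
  cm <- density_fixture(3, n_per = 3)
  dg <- quantile_normalize_grids(estimate_density(cm, gridsize = 30))

  # identical grid sets in both groups -> Z = 0 on the mask
  dgi <- dg
  tum <- names(dg$condition)[dg$condition == "tumor"]
  nor <- names(dg$condition)[dg$condition != "tumor"]
  for (k in seq_along(nor)) dgi$grids[[nor[k]]] <- dgi$grids[[tum[k]]]
  dd0 <- density_diff(dgi)
  expect_true(all(dd0$z == 0))

  # swapping condition labels flips the sign of Z
  dd <- density_diff(dg)
  dgs <- dg
  dgs$condition <- ifelse(dg$condition == "tumor", "normal", "tumor")
  dds <- density_diff(dgs)
  expect_equal(dds$z, -dd$z)

  # unoccupied bins are masked and zero
  expect_true(all(dd$z[!dd$mask] == 0))
  expect_true(any(!dd$mask))
})

test_that("a strong planted abundance blob is localized by the Z map", {
  hits <- 0
  for (s in 1:10) {
    cfg <- simulation_config(
      n_samples_per_condition = 5, cells_per_sample = 150, n_genes = 10,
      cell_types = c(A = 0.35, B = 0.3, C = 0.3, Planted = 0.05),
      composition_effects = c(Planted = 6), marker_genes_per_type = 0,
      seed = 100 + s)
    sim <- simulate_cohort(cfg)
    dg <- quantile_normalize_grids(estimate_density(sim$cm, gridsize = 40))
    dd <- density_diff(dg)
    ij <- which(dd$z == max(dd$z), arr.ind = TRUE)[1, ]
    peak <- c(dd$xgrid[ij[1]], dd$ygrid[ij[2]])
    # the planted type is the 4th blob on the circle of radius 4
    center <- 4 * c(cos(2 * pi * 4 / 4), sin(2 * pi * 4 / 4))
    if (sqrt(sum((peak - center)^2)) < 3 * 0.6) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("proportion tests compute fractions per denominator and adjust p", {
  counts <- matrix(1, 2, 10, dimnames = list(c("g1", "g2"), paste0("c", 1:10)))
  meta <- data.frame(sample = "S1", condition = "tumor",
                     cell_type = c(rep("Macro-2", 4), rep("Macro-1", 4),
                                   rep("CD8", 2)))
  cm <- cell_matrix(counts, meta = meta)
  parent <- c(`Macro-1` = "myeloid", `Macro-2` = "myeloid", CD8 = "tcell")
  fr <- cell_type_fractions(cm, parent_map = parent)
  # 4 of 8 myeloid cells are Macro-2
  expect_equal(fr$fractions["S1", "Macro-2"], 0.5)
  expect_equal(fr$fractions["S1", "CD8"], 1)

  # identical fraction vectors across conditions -> exact p = 1 everywhere
  n_cells <- 30
  meta2 <- do.call(rbind, lapply(1:6, function(i) data.frame(
    sample = sprintf("S%d", i),
    condition = if (i <= 3) "tumor" else "normal",
    cell_type = rep(c("A", "B", "C"), c(10, 12, 8)))))
  cm2 <- cell_matrix(matrix(1, 1, 6 * n_cells,
                            dimnames = list("g1", paste0("c", 1:(6 * n_cells)))),
                     meta = meta2)
  pt <- proportion_tests(cm2)
  expect_true(all(pt$p == 1))
  expect_true(all(pt$p_adj >= pt$p - 1e-12))
})

test_that("CoDA coefficients live in CLR space with the stated invariances", {
  set.seed(1)
  counts <- matrix(rpois(10 * 4, 200), 10, 4,
                   dimnames = list(paste0("S", 1:10), LETTERS[1:4]))
  cond <- rep(c("tumor", "normal"), each = 5)
  res <- coda_coefficients(counts, cond, n_boot = 20, cells_per_boot = 200, seed = 2)

  # CLR zero-sum and unit scale
  expect_lt(abs(sum(res$coefficients)), 1e-8)
  expect_equal(sum(res$coefficients^2), 1)

  # invariance to cell-type ordering (coefficients permute along)
  perm <- c(3, 1, 4, 2)
  res2 <- coda_coefficients(counts[, perm], cond, n_boot = 1,
                            cells_per_boot = 50, seed = 2)
  expect_equal(res2$coefficients[colnames(counts)], res$coefficients,
               tolerance = 1e-8)

  # uniform compositions have ILR coordinates exactly 0
  u <- matrix(1 / 4, 2, 4)
  basis <- sccompare:::.helmert_basis(4)
  expect_true(all(abs(sccompare:::.clr(u) %*% basis) < 1e-12))

  expect_error(coda_coefficients(counts[c(1, 2, 6, 7), ], cond[c(1, 2, 6, 7)]),
               "3 samples")
  counts0 <- cbind(counts, E = 0)
  expect_warning(coda_coefficients(counts0, cond, n_boot = 1,
                                   cells_per_boot = 50, seed = 3), "absent")
})

test_that("a doubled cell type gets a positive separating coefficient", {
  cfg <- simulation_config(n_samples_per_condition = 10, cells_per_sample = 200,
                           cell_types = c(A = 0.2, B = 0.45, C = 0.35),
                           composition_effects = c(A = 2),
                           marker_genes_per_type = 0, n_genes = 10, seed = 21)
  sim <- simulate_cohort(cfg)
  fr <- cell_type_fractions(sim$cm)
  res <- coda_coefficients(fr$counts, fr$condition, n_boot = 200,
                           cells_per_boot = 500, seed = 4)
  expect_gt(res$coefficients["A"], 0)
  expect_gte(res$positive_fraction[["A"]], 0.95)
})
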