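test_that("pseudobulk sums member cells and applies the 10-cell minimum", {
  counts <- cbind(c(1, 0), c(2, 3))
  rownames(counts) <- c("g1", "g2"); colnames(counts) <- c("c1", "c2")
  meta <- data.frame(sample = "S1", condition = "tumor", cell_type = "A")
  meta <- meta[c(1, 1), ]
  cm <- cell_matrix(counts, meta = meta)
  pb <- make_pseudobulk(cm, min_cells = 1)
  expect_equal(unname(pb$profiles[, 1]), c(3, 3))

  # a 9-cell profile is excluded at min_cells = 10; proportions still sum to 1
  cfg <- null_config(5, n_samples = 2, cells = 60, genes = 20,
                     types = c(A = 0.85, B = 0.15))
  sim <- simulate_cohort(cfg)
  meta2 <- sim$cm$meta
  s1 <- meta2$sample == unique(meta2$sample)[1]
  meta2$cell_type[s1] <- c(rep("B", 9), rep("A", sum(s1) - 9))
  cm2 <- cell_matrix(sim$cm$counts, meta = meta2)
  expect_message(pb2 <- make_pseudobulk(cm2, min_cells = 10), "excluded")
  expect_false(any(pb2$sample == unique(meta2$sample)[1] & pb2$cell_type == "B"))
  expect_equal(unname(rowSums(pb2$proportions)), rep(1, nrow(pb2$proportions)))
})

test_that("pair_distance is a correlation distance with depth invariance", {
  a <- c(5, 1, 9, 3)
  expect_equal(pair_distance(a, a), 0)
  expect_equal(pair_distance(a, 5 * a), 0)

  # exactly anti-correlated log profiles give distance 2
  x <- c(1, 2, 3, 4)
  la <- log1p(x / sum(x) * 1e6)
  lb <- 2 * mean(la) - la               # reflected: cor = -1
  b <- (exp(lb) - 1) * sum(x) / 1e6     # invert the transform at equal depth
  expect_equal(pair_distance(x, b), 2, tolerance = 1e-9)

  expect_error(pair_distance(c(2, 2, 2), c(1, 2, 3)), "zero-variance")
})

test_that("celltype_distance matches the direct computation when subsampling is degenerate", {
  # equal cell counts everywhere: n_rounds = 1 subsamples every cell once
  set.seed(8)
  n_per <- 12
  counts <- matrix(rpois(50 * 4 * n_per, 5), 50)
  rownames(counts) <- paste0("g", 1:50)
  colnames(counts) <- paste0("c", seq_len(ncol(counts)))
  meta <- data.frame(sample = rep(paste0("S", 1:4), each = n_per),
                     condition = rep(c("tumor", "normal"), each = 2 * n_per),
                     cell_type = "A")
  cm <- cell_matrix(counts, meta = meta)
  dr <- celltype_distance(cm, min_cells = 10, n_rounds = 1, seed = 1)

  pb <- make_pseudobulk(cm, min_cells = 10)
  d_direct <- outer(1:4, 1:4, Vectorize(function(i, j)
    if (i == j) 0 else pair_distance(pb$profiles[, i], pb$profiles[, j])))
  expect_equal(unname(dr$per_type$A$dist), d_direct, tolerance = 1e-12)

  nd <- dr$table$normalized_distance
  expect_equal(nd, median(d_direct[1:2, 3:4]) /
                 median(c(d_direct[1, 2], d_direct[3, 4])))
})

test_that("null cohorts give normalized distance near 1; planted DE dominates", {
  cfg <- null_config(31, n_samples = 5, cells = 150, genes = 200,
                     types = c(A = 1))
  sim <- simulate_cohort(cfg)
  dr <- celltype_distance(sim$cm, n_rounds = 3, seed = 2)
  expect_gt(dr$table$normalized_distance, 0.8)
  expect_lt(dr$table$normalized_distance, 1.25)

  cfg2 <- simulation_config(
    n_samples_per_condition = 5, cells_per_sample = 150, n_genes = 200,
    cell_types = c(A = 0.5, B = 0.5), marker_genes_per_type = 0,
    de_effects = list(list(cell_type = "A", genes = 101:130, log2fc = 2)),
    seed = 32)
  sim2 <- simulate_cohort(cfg2)
  dr2 <- celltype_distance(sim2$cm, n_rounds = 3, seed = 3)
  tab <- dr2$table
  expect_gt(tab$normalized_distance[tab$cell_type == "A"],
            tab$normalized_distance[tab$cell_type == "B"])
})

test_that("few distinct label splits trigger exhaustive enumeration", {
  cfg <- simulation_config(
    n_samples_per_condition = 3, cells_per_sample = 100, n_genes = 100,
    cell_types = c(A = 1), marker_genes_per_type = 0,
    de_effects = list(list(cell_type = "A", genes = 1:20, log2fc = 1.5)),
    seed = 33)
  sim <- simulate_cohort(cfg)
  dr <- celltype_distance(sim$cm, n_rounds = 2, seed = 4)

  # drop one normal sample: 3v2 has C(5,3) = 10 < 20 splits -> exact path
  keep <- 1:5
  dr$per_type$A$dist <- dr$per_type$A$dist[keep, keep]
  dr$per_type$A$condition <- dr$per_type$A$condition[keep]
  d <- dr$per_type$A$dist; cond <- dr$per_type$A$condition
  res_exact <- distance_permutation_test(dr, n_perm = 1000, seed = 5)
  expect_equal(res_exact$method, "exact")

  combs <- utils::combn(5, 3)
  stats <- apply(combs, 2, function(ix) {
    cc <- rep("normal", 5); cc[ix] <- "tumor"
    sccompare:::.normalized_distance(d, cc)
  })
  obs <- sccompare:::.normalized_distance(d, cond)
  expect_equal(res_exact$p, mean(stats >= obs - 1e-12))

  # label-swap symmetry: renaming tumor <-> normal leaves p unchanged
  dr_sw <- dr
  dr_sw$per_type$A$condition <- ifelse(cond == "tumor", "normal", "tumor")
  res_sw <- distance_permutation_test(dr_sw, n_perm = 1000, seed = 5)
  expect_equal(res_sw$p, res_exact$p)
})

test_that("Monte-Carlo permutation p approximates enumeration at 3v3", {
  cfg <- simulation_config(
    n_samples_per_condition = 3, cells_per_sample = 100, n_genes = 100,
    cell_types = c(A = 1), marker_genes_per_type = 0,
    de_effects = list(list(cell_type = "A", genes = 1:20, log2fc = 1)),
    seed = 35)
  sim <- simulate_cohort(cfg)
  dr <- celltype_distance(sim$cm, n_rounds = 2, seed = 6)
  d <- dr$per_type$A$dist
  combs <- utils::combn(6, 3)
  obs <- sccompare:::.normalized_distance(d, dr$per_type$A$condition)
  stats <- apply(combs, 2, function(ix) {
    cc <- rep("normal", 6); cc[ix] <- "tumor"
    sccompare:::.normalized_distance(d, cc)
  })
  p_enum <- mean(stats >= obs - 1e-12)
  n_perm <- 400
  res <- distance_permutation_test(dr, n_perm = n_perm, seed = 7)
  expect_equal(res$method, "monte-carlo")
  expect_lt(abs(res$p - p_enum), 1 / sqrt(n_perm) + 1 / n_perm)

  # observed below every permuted value -> p = 1 by the add-one formula
  dr1 <- dr
  dr1$per_type$A$dist <- d
  # make the labeled split the *smallest* statistic by inverting distances
  dmax <- max(d)
  dr1$per_type$A$dist <- dmax - d; diag(dr1$per_type$A$dist) <- 0
  res1 <- distance_permutation_test(dr1, n_perm = 50, seed = 8)
  expect_gte(res1$p, 0.9)
})

test_that("overall sample distance weights shared types and embeds with MDS", {
  # 3 equidistant samples -> equilateral MDS triangle up to rigid motion
  d3 <- matrix(1, 3, 3) - diag(3)
  xy <- cmdscale(as.dist(d3), k = 2)
  sides <- as.numeric(dist(xy))
  expect_true(all(abs(sides / sides[1] - 1) < 1e-6))

  set.seed(9)
  counts <- matrix(rpois(40 * 90, 6), 40,
                   dimnames = list(paste0("g", 1:40), paste0("c", 1:90)))
  meta <- data.frame(sample = rep(c("S1", "S2", "S3"), each = 30),
                     condition = c(rep("tumor", 60), rep("normal", 30)),
                     cell_type = rep(c("A", "A", "B"), each = 30))
  # S3 has only type B; S1/S2 only type A -> S1-S3 share no type
  cm <- cell_matrix(counts, meta = meta)
  pb <- make_pseudobulk(cm)
  expect_message(sm <- overall_sample_distance(pb), "share no cell type")
  expect_equal(unname(diag(sm$distance_matrix)), c(0, 0, 0))
  expect_equal(sm$distance_matrix, t(sm$distance_matrix))
  # imputed pairs equal the matrix maximum
  expect_equal(sm$distance_matrix["S1", "S3"], max(sm$distance_matrix))
  expect_equal(dim(sm$mds_coords), c(3L, 2L))

  # identical samples are at distance 0
  meta2 <- data.frame(sample = rep(c("S1", "S2", "S3"), each = 30),
                      condition = "tumor", cell_type = "A")
  cm2 <- cell_matrix(cbind(counts[, 1:30], counts[, 1:30], counts[, 1:30]),
                     cell_ids = paste0("d", 1:90), meta = meta2)
  # degenerate all-zero distances: cmdscale warns about zero eigenvalues
  sm2 <- suppressWarnings(overall_sample_distance(make_pseudobulk(cm2)))
  expect_equal(max(sm2$distance_matrix), 0)
})
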