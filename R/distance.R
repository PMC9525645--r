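# Pseudobulk ("mini-bulk") construction, between/within-condition normalized
# expression distance with cell-count-matched subsampling, a sample-label
# permutation test, and the weighted overall sample distance with classical MDS.

#' Sum cells into per-(sample, cell-type) pseudobulk profiles
#'
#' @param cm a CellMatrix with sample and cell_type metadata
#' @param min_cells minimum cells for a profile to be kept (default 10);
#'   excluded profiles are reported via a message
#' @return object of class \code{Pseudobulk}: list with \code{profiles}
#'   (genes x profiles matrix), \code{sample}, \code{cell_type},
#'   \code{condition}, \code{n_cells} per profile, and \code{proportions}
#'   (samples x types, over all unfiltered types).
#' @export
make_pseudobulk <- function(cm, min_cells = 10) {
  meta <- cm$meta
  if (!all(c("sample", "cell_type") %in% colnames(meta)))
    stop("sample and cell_type metadata required")
  ok <- !is.na(meta$cell_type)
  if (any(!ok)) message(sum(!ok), " cells without cell_type excluded from pseudobulk")
  grp <- factor(paste(meta$sample, meta$cell_type, sep = "\r"))
  grp[!ok] <- NA
  ind <- Matrix::sparseMatrix(i = which(ok), j = as.integer(grp[ok]),
                              x = 1, dims = c(ncol(cm$counts), nlevels(grp)))
  prof <- as.matrix(cm$counts %*% ind)
  parts <- do.call(rbind, strsplit(levels(grp), "\r", fixed = TRUE))
  n_cells <- as.integer(table(grp))
  cnt_tab <- as.matrix(table(meta$sample[ok], meta$cell_type[ok]))
  proportions <- cnt_tab / rowSums(cnt_tab)
  cond <- vapply(parts[, 1], function(s)
    as.character(meta$condition[meta$sample == s][1]), "")
  keep <- n_cells >= min_cells
  if (any(!keep))
    message(sum(!keep), " pseudobulk profiles under ", min_cells, " cells excluded")
  rownames(prof) <- rownames(cm$counts)
  structure(list(profiles = prof[, keep, drop = FALSE],
                 sample = parts[keep, 1], cell_type = parts[keep, 2],
                 condition = unname(cond[keep]), n_cells = n_cells[keep],
                 proportions = proportions, min_cells = min_cells),
            class = "Pseudobulk")
}

#' Correlation distance between two pseudobulk profiles
#'
#' Profiles are depth-normalized (counts per million), log1p-transformed over
#' the genes expressed in at least one of the two profiles, and compared with
#' Pearson correlation; the distance is 1 - r.
#'
#' @param a,b non-negative count vectors over identical gene lists
#' @return distance in [0, 2].
#' @export
pair_distance <- function(a, b) {
  use <- a > 0 | b > 0
  la <- log1p(a[use] / sum(a) * 1e6)
  lb <- log1p(b[use] / sum(b) * 1e6)
  if (sd(la) == 0 || sd(lb) == 0) stop("zero-variance profile")
  1 - cor(la, lb)
}

.pairwise_dist <- function(mat) {
  # mat: genes x profiles; pairwise 1 - cor of log1p CPM over pair-expressed genes
  n <- ncol(mat)
  d <- matrix(0, n, n, dimnames = list(colnames(mat), colnames(mat)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- pair_distance(mat[, i], mat[, j])
  d
}

#' Normalized expression distance per cell type
#'
#' For each cell type present in at least 2 samples per condition, the
#' per-sample profiles are repeatedly subsampled (without replacement) to the
#' minimum cell count among the contributing samples, pairwise correlation
#' distances are recomputed, and the averaged distances yield
#' median(between-condition pairs) / median(within-condition pairs).
#'
#' @param cm a CellMatrix
#' @param min_cells minimum cells per (sample, type) to contribute (default 10)
#' @param n_rounds subsampling rounds (default 100)
#' @param seed integer seed for the subsampling
#' @return object of class \code{DistanceResult}: per-type list with the
#'   averaged pairwise distance matrix, sample conditions, and a data.frame
#'   \code{table} of normalized distances; types present in only one
#'   condition are skipped with a warning.
#' @export
celltype_distance <- function(cm, min_cells = 10, n_rounds = 100, seed = 1L) {
  meta <- cm$meta
  set.seed(child_seed(seed, "celltype_distance"))
  types <- unique(as.character(meta$cell_type[!is.na(meta$cell_type)]))
  per_type <- list()
  for (tp in types) {
    sel <- which(!is.na(meta$cell_type) & meta$cell_type == tp)
    tab <- table(meta$sample[sel])
    smp <- names(tab)[tab >= min_cells]
    cond <- vapply(smp, function(s)
      as.character(meta$condition[meta$sample == s][1]), "")
    if (length(unique(cond)) < 2 || min(table(cond)) < 2) {
      warning("cell type ", tp, " lacks 2 samples per condition; skipped")
      next
    }
    cells_by_smp <- split(sel, as.character(meta$sample[sel]))[smp]
    m <- min(lengths(cells_by_smp))
    acc <- matrix(0, length(smp), length(smp))
    for (r in seq_len(n_rounds)) {
      prof <- vapply(cells_by_smp, function(ix)
        Matrix::rowSums(cm$counts[, sample(ix, m), drop = FALSE]),
        numeric(nrow(cm$counts)))
      acc <- acc + .pairwise_dist(prof)
    }
    acc <- acc / n_rounds
    dimnames(acc) <- list(smp, smp)
    per_type[[tp]] <- list(dist = acc, condition = cond)
  }
  tab <- do.call(rbind, lapply(names(per_type), function(tp) {
    nd <- .normalized_distance(per_type[[tp]]$dist, per_type[[tp]]$condition)
    data.frame(cell_type = tp, normalized_distance = nd,
               n_samples = ncol(per_type[[tp]]$dist))
  }))
  structure(list(per_type = per_type, table = tab, n_rounds = n_rounds),
            class = "DistanceResult")
}

.normalized_distance <- function(d, condition) {
  tum <- condition == "tumor"
  between <- d[tum, !tum, drop = FALSE]
  within <- c(d[tum, tum][upper.tri(d[tum, tum, drop = FALSE])],
              d[!tum, !tum][upper.tri(d[!tum, !tum, drop = FALSE])])
  median(between) / median(within)
}

#' Permutation test of the normalized expression distance
#'
#' Sample condition labels are permuted; the normalized distance is
#' recomputed from the (subsampling-averaged) pairwise distance matrix under
#' each relabeling. With fewer than 20 distinct label splits the full
#' enumeration is used instead of Monte-Carlo (reported in the output).
#' Monte-Carlo p-values use the add-one estimator
#' p = (1 + #\{permuted >= observed\}) / (1 + n_perm).
#'
#' @param dist_result a \code{DistanceResult} from \code{celltype_distance}
#' @param n_perm Monte-Carlo permutations (default 1000)
#' @param seed integer seed
#' @return data.frame per cell type: observed normalized distance, p, method.
#' @export
distance_permutation_test <- function(dist_result, n_perm = 1000, seed = 1L) {
  set.seed(child_seed(seed, "distance_perm"))
  out <- lapply(names(dist_result$per_type), function(tp) {
    d <- dist_result$per_type[[tp]]$dist
    cond <- dist_result$per_type[[tp]]$condition
    obs <- .normalized_distance(d, cond)
    n <- length(cond); n_t <- sum(cond == "tumor")
    n_distinct <- choose(n, n_t)
    if (n_distinct < 20) {
      combs <- utils::combn(n, n_t)
      stats <- apply(combs, 2, function(ix) {
        cc <- rep("normal", n); cc[ix] <- "tumor"
        .normalized_distance(d, cc)
      })
      p <- mean(stats >= obs - 1e-12)
      method <- "exact"
    } else {
      stats <- replicate(n_perm, .normalized_distance(d, sample(cond)))
      p <- (1 + sum(stats >= obs - 1e-12)) / (1 + n_perm)
      method <- "monte-carlo"
    }
    data.frame(cell_type = tp, normalized_distance = obs, p = p,
               method = method, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Overall between-sample expression distance and MDS map
#'
#' The distance between two samples is the weighted mean of the per-cell-type
#' pseudobulk correlation distances over cell types passing the profile
#' minimum in both samples, weighted by the smaller of the two samples'
#' proportions of that type. Sample pairs sharing no type get the matrix
#' maximum (reported). The matrix is projected to 2-D by classical
#' (Torgerson) multidimensional scaling.
#'
#' @param pb a \code{Pseudobulk}
#' @return object of class \code{SampleMap}: list with \code{distance_matrix}
#'   (samples x samples), \code{mds_coords} (samples x 2) and \code{condition}.
#' @export
overall_sample_distance <- function(pb) {
  samples <- unique(pb$sample)
  if (length(samples) < 3) stop("at least 3 samples required")
  n <- length(samples)
  d <- matrix(NA_real_, n, n, dimnames = list(samples, samples))
  diag(d) <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    si <- samples[i]; sj <- samples[j]
    types <- intersect(pb$cell_type[pb$sample == si], pb$cell_type[pb$sample == sj])
    num <- 0; den <- 0
    for (tp in types) {
      w <- min(pb$proportions[si, tp], pb$proportions[sj, tp])
      if (w <= 0) next
      a <- pb$profiles[, pb$sample == si & pb$cell_type == tp]
      b <- pb$profiles[, pb$sample == sj & pb$cell_type == tp]
      num <- num + w * pair_distance(a, b)
      den <- den + w
    }
    d[i, j] <- d[j, i] <- if (den > 0) num / den else NA_real_
  }
  if (anyNA(d)) {
    message(sum(is.na(d)) / 2, " sample pairs share no cell type; distance imputed as max")
    d[is.na(d)] <- max(d, na.rm = TRUE)
  }
  coords <- cmdscale(as.dist(d), k = 2)
  cond <- vapply(samples, function(s)
    pb$condition[pb$sample == s][1], "")
  structure(list(distance_matrix = d, mds_coords = coords, condition = cond),
            class = "SampleMap")
}

#' @importFrom stats as.dist
NULL
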