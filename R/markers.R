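# Wilcoxon-Z marker detection (one-vs-rest rank-sum with a signed Z statistic),
# pseudobulk two-condition differential expression under a negative-binomial
# GLM, and the multi-round tumor-subclone signature selection.

# rank-sum Z for each gene: values in group vs rest, tie-corrected normal
# approximation with continuity correction, signed by the mean difference.
.ranksum_z_matrix <- function(vals, in_group) {
  n1 <- sum(in_group); n2 <- sum(!in_group)
  N <- n1 + n2
  mu <- n1 * n2 / 2
  apply(vals, 1, function(v) {
    r <- rank(v)
    U <- sum(r[in_group]) - n1 * (n1 + 1) / 2
    tie_tab <- table(v)
    tie_term <- sum(tie_tab^3 - tie_tab)
    sig2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (sig2 <= 0) return(c(z = 0, p = 1))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    c(z = abs(z) * sign(mean(v[in_group]) - mean(v[!in_group])), p = p)
  })
}

#' One-vs-rest Wilcoxon-Z marker genes per cluster
#'
#' For every cluster, each gene is tested with a two-sided rank-sum test of
#' the cluster's cells against all other cells. The reported Z is the normal
#' quantile of p/2 signed by the direction of the mean difference (positive =
#' up in the cluster); genes with Z above \code{z_min} are flagged as markers.
#' Clusters with fewer than 3 cells are skipped with a warning.
#'
#' @param nm a \code{NormalizedMatrix}
#' @param clusters per-cell cluster labels
#' @param z_min marker threshold on Z (default 3)
#' @return \code{MarkerTable} data.frame: cluster, gene, z, p, fraction
#'   expressing inside/outside, log2 fold change of means, marker flag.
#' @export
marker_genes <- function(nm, clusters, z_min = 3) {
  clusters <- as.character(clusters)
  if (length(unique(clusters)) < 2) stop("at least 2 clusters required")
  vals <- as.matrix(nm$values)
  out <- list()
  for (cl in unique(clusters)) {
    ing <- clusters == cl
    if (sum(ing) < 3) {
      warning("cluster ", cl, " has fewer than 3 cells; skipped")
      next
    }
    zp <- .ranksum_z_matrix(vals, ing)
    m_in <- rowMeans(vals[, ing, drop = FALSE])
    m_out <- rowMeans(vals[, !ing, drop = FALSE])
    out[[cl]] <- data.frame(
      cluster = cl, gene = rownames(vals),
      z = zp["z", ], p = zp["p", ],
      frac_in = rowMeans(vals[, ing, drop = FALSE] > 0),
      frac_out = rowMeans(vals[, !ing, drop = FALSE] > 0),
      log2fc = log2((pmax(m_in, 0) + 1e-9) / (pmax(m_out, 0) + 1e-9)),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  tab <- do.call(rbind, out)
  tab$marker <- tab$z > z_min
  rownames(tab) <- NULL
  tab
}

#' Pseudobulk tumor-vs-normal differential expression (NB GLM)
#'
#' Fits, per gene, a negative-binomial generalized linear model of the
#' per-sample pseudobulk counts with a condition factor and a log-total
#' offset; reports the Wald p of the condition coefficient, the tumor/normal
#' log2 fold change, and BH-adjusted p-values. Genes whose NB fit fails fall
#' back to a Poisson GLM (recorded in the \code{fit} column).
#'
#' @param pb a \code{Pseudobulk}
#' @param cell_type the cell type to test
#' @param min_cells minimum member cells for a sample's profile (profiles were
#'   already filtered at pseudobulk construction; this re-checks the contract)
#' @return \code{DETable} data.frame: gene, log2FoldChange, p, p_adj, fit,
#'   with the contrast metadata in attributes.
#' @export
pseudobulk_de <- function(pb, cell_type, min_cells = 10) {
  sel <- pb$cell_type == cell_type & pb$n_cells >= min_cells
  if (!any(sel)) stop("no profiles for cell type ", cell_type)
  prof <- pb$profiles[, sel, drop = FALSE]
  cond <- factor(pb$condition[sel], levels = c("normal", "tumor"))
  if (any(table(cond) < 2))
    stop("cell type ", cell_type, ": fewer than 2 samples per condition")
  off <- log(colSums(prof))
  res <- t(vapply(seq_len(nrow(prof)), function(g) {
    y <- prof[g, ]
    if (all(y == y[1])) {
      # no variation: the GLM is degenerate; a constant gene carries no signal
      return(c(lfc = 0, p = 1, fit = 0))
    }
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(y ~ cond + offset(off))),
      error = function(e) NULL)
    kind <- 1
    if (is.null(fit) || !fit$converged) {
      fit <- suppressWarnings(glm(y ~ cond + offset(off), family = poisson()))
      kind <- 2
    }
    cf <- summary(fit)$coefficients
    if (!"condtumor" %in% rownames(cf)) return(c(lfc = 0, p = 1, fit = kind))
    c(lfc = cf["condtumor", 1] / log(2), p = cf["condtumor", 4], fit = kind)
  }, numeric(3)))
  out <- data.frame(gene = rownames(prof),
                    log2FoldChange = res[, "lfc"],
                    p = res[, "p"],
                    p_adj = p.adjust(res[, "p"], "BH"),
                    fit = c("constant", "nb", "poisson")[res[, "fit"] + 1],
                    stringsAsFactors = FALSE)
  attr(out, "contrast") <- "tumor_vs_normal"
  attr(out, "cell_type") <- cell_type
  attr(out, "samples") <- pb$sample[sel]
  out
}

.top_positive <- function(tab, top_n) {
  tab <- tab[tab$z > 0, , drop = FALSE]
  # rank by Z, ties by |log2FC| then symbol
  ord <- order(-tab$z, -abs(tab$log2fc), tab$gene)
  head(tab$gene[ord], top_n)
}

#' Multi-round selection of a metastasis-associated tumor signature
#'
#' Round 1 ranks genes by their one-vs-rest Wilcoxon Z for the target tumor
#' subclone against the other subclones (tumor cells only) and keeps the top
#' \code{top_n} positively enriched genes. Round 2 repeats the ranking for the
#' target subclone's cells against all non-tumor cell populations, keeping the
#' genes specific to tumor cells. The final signature is the intersection,
#' ordered by round-1 rank; an empty intersection is a valid (warned) result.
#'
#' @param nm a \code{NormalizedMatrix} over all cells
#' @param subclone per-cell tumor subclone label (NA for non-tumor cells)
#' @param cell_type per-cell population label (used to find non-tumor cells)
#' @param tumor_types cell_type labels that denote tumor cells
#' @param target the subclone whose signature is sought (default "C4")
#' @param top_n genes kept per round (default 100)
#' @return object of class \code{SignatureSelection}: \code{round1_top},
#'   \code{round2_top} (ranked character vectors) and \code{final} (GeneSet,
#'   possibly empty genes list).
#' @export
select_metastatic_signature <- function(nm, subclone, cell_type,
                                        tumor_types = "Tumor",
                                        target = "C4", top_n = 100) {
  is_tumor <- cell_type %in% tumor_types
  if (sum(!is.na(subclone) & subclone == target) < 50)
    stop("target subclone has fewer than 50 cells")
  if (length(unique(cell_type[!is_tumor])) < 2)
    stop("at least 2 non-tumor cell populations required")

  # round 1: target vs other subclones, within tumor cells
  tum_idx <- which(is_tumor & !is.na(subclone))
  nm_t <- list(values = nm$values[, tum_idx, drop = FALSE])
  tab1 <- marker_genes(structure(nm_t, class = "NormalizedMatrix"),
                       ifelse(subclone[tum_idx] == target, target, "other"))
  tab1 <- tab1[tab1$cluster == target, , drop = FALSE]
  round1 <- .top_positive(tab1, top_n)

  # round 2: target cells vs all non-tumor populations
  idx2 <- which((!is.na(subclone) & subclone == target) | !is_tumor)
  lab2 <- ifelse(!is.na(subclone[idx2]) & subclone[idx2] == target,
                 target, "non_tumor")
  nm_2 <- list(values = nm$values[, idx2, drop = FALSE])
  tab2 <- marker_genes(structure(nm_2, class = "NormalizedMatrix"), lab2)
  tab2 <- tab2[tab2$cluster == target, , drop = FALSE]
  round2 <- .top_positive(tab2, top_n)

  final_genes <- round1[round1 %in% round2]
  if (length(final_genes) == 0) {
    warning("empty intersection: no genes pass both rounds")
    final <- structure(list(name = paste0(target, "_signature"),
                            genes = character(0)), class = "GeneSet")
  } else {
    final <- gene_set(paste0(target, "_signature"), final_genes)
  }
  structure(list(round1_top = round1, round2_top = round2, final = final),
            class = "SignatureSelection")
}
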