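# Gene-set signature scores: per-cell averages of normalized expression, sample
# means (optionally restricted to one cell type) and two-group rank-sum tests.

#' Per-cell signature scores
#'
#' The score of a cell is the arithmetic mean of its normalized expression
#' values over the genes of the set that are present in the matrix. Genes
#' missing from the matrix are dropped (reported via a message); they never
#' change the scores of the remaining genes.
#'
#' @param nm a \code{NormalizedMatrix}
#' @param gs a \code{GeneSet}
#' @return object of class \code{SignatureScores} with \code{per_cell},
#'   \code{gene_set_name} and \code{n_genes_used}.
#' @export
score_cells <- function(nm, gs) {
  present <- intersect(gs$genes, rownames(nm$values))
  if (length(present) == 0)
    stop(sprintf("no genes of set '%s' present in matrix (missing: %s)",
                 gs$name, paste(gs$genes, collapse = ", ")))
  missing <- setdiff(gs$genes, present)
  if (length(missing))
    message(length(missing), " genes of set '", gs$name,
            "' absent from matrix: ", paste(missing, collapse = ", "))
  per_cell <- Matrix::colSums(nm$values[present, , drop = FALSE]) / length(present)
  structure(list(per_cell = per_cell, per_sample = NULL,
                 gene_set_name = gs$name, n_genes_used = length(present)),
            class = "SignatureScores")
}

#' Per-sample signature scores
#'
#' Averages per-cell scores within each sample, optionally restricted to one
#' cell type. Samples with no contributing cells get \code{NA} (reported).
#'
#' @param scores a \code{SignatureScores} with per-cell values
#' @param cm the CellMatrix the scores were computed on (for metadata)
#' @param restrict_cell_type optional cell-type label to restrict averaging to
#' @return \code{SignatureScores} with a named \code{per_sample} vector and a
#'   \code{condition} vector aligned to it.
#' @export
score_samples <- function(scores, cm, restrict_cell_type = NULL) {
  stopifnot(inherits(scores, "SignatureScores"))
  meta <- cm$meta
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(restrict_cell_type)) {
    if (!restrict_cell_type %in% meta$cell_type)
      stop("cell type '", restrict_cell_type, "' not present")
    keep <- !is.na(meta$cell_type) & meta$cell_type == restrict_cell_type
  }
  samples <- unique(as.character(meta$sample))
  per_sample <- vapply(samples, function(s) {
    i <- keep & meta$sample == s
    if (!any(i)) NA_real_ else mean(scores$per_cell[i])
  }, numeric(1))
  if (anyNA(per_sample))
    message(sum(is.na(per_sample)), " samples had no contributing cells")
  cond <- vapply(samples, function(s)
    as.character(meta$condition[meta$sample == s][1]), "")
  scores$per_sample <- per_sample
  scores$condition <- cond
  scores
}

#' Two-sided Wilcoxon rank-sum test with an exact/approximate policy
#'
#' Uses the exact distribution when the pooled size is at most
#' \code{exact_max} and there are no ties; otherwise the normal approximation
#' with tie-corrected variance and continuity correction. The policy actually
#' used is recorded in the result.
#'
#' @param x,y numeric vectors for the two groups
#' @param exact_max pooled-size cutoff for the exact method (default 20)
#' @return list with \code{statistic} (Mann-Whitney U of x vs y), \code{p}
#'   and \code{method} ("exact" or "approximate").
#' @export
rank_sum_test <- function(x, y, exact_max = 20) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(unique(c(x, y))) == 1)   # fully tied: no evidence either way
    return(list(statistic = length(x) * length(y) / 2, p = 1, method = "degenerate"))
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && (length(x) + length(y)) <= exact_max
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE,
                                     alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p = min(ht$p.value, 1),
       method = if (exact) "exact" else "approximate")
}

#' Compare per-sample signature scores between the two conditions
#'
#' @param scores a \code{SignatureScores} with per-sample values (from
#'   \code{\link{score_samples}})
#' @param condition optional condition vector aligned to \code{per_sample};
#'   defaults to the one recorded by \code{score_samples}
#' @return one-row data.frame: set name, group sizes, rank-sum statistic,
#'   two-sided p and the exact/approximate policy used.
#' @export
compare_scores <- function(scores, condition = scores$condition) {
  v <- scores$per_sample
  ok <- !is.na(v)
  v <- v[ok]; condition <- condition[ok]
  lv <- unique(condition)
  if (length(lv) != 2) stop("exactly two condition labels required")
  lv <- if ("tumor" %in% lv) c("tumor", setdiff(lv, "tumor")) else sort(lv)
  g1 <- v[condition == lv[1]]; g2 <- v[condition == lv[2]]
  if (length(g1) < 2 || length(g2) < 2)
    stop("each group needs at least 2 samples")
  ht <- rank_sum_test(g1, g2)
  data.frame(set = scores$gene_set_name, group1 = lv[1], group2 = lv[2],
             n1 = length(g1), n2 = length(g2),
             statistic = ht$statistic, p = ht$p, method = ht$method,
             stringsAsFactors = FALSE)
}

#' Write per-sample scores and a comparison table as TSV
#' @param scores a SignatureScores with per-sample values
#' @param path output TSV path
#' @return \code{path}, invisibly.
#' @export
write_scores <- function(scores, path) {
  tab <- data.frame(sample = names(scores$per_sample),
                    condition = scores$condition,
                    score = unname(scores$per_sample),
                    set = scores$gene_set_name)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
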