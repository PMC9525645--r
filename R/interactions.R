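# Ligand-receptor inference: expression-fraction screening, mean-product
# scoring, a global cell-identity permutation null with BH adjustment, and the
# specificity (marker-Z) and tumor-upregulation (log2FC) filters.

#' Read a CellPhoneDB-style ligand-receptor pair table
#' @param path two-column TSV (ligand, receptor), optional third id column;
#'   a header line is detected and skipped.
#' @return \code{LRPairTable} data.frame with columns ligand, receptor, pair_id.
#' @export
read_lr_pairs <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (tolower(tab[1, 1]) %in% c("ligand", "ligand_gene"))
    tab <- tab[-1, , drop = FALSE]
  lr_pair_table(tab[[1]], tab[[2]],
                if (ncol(tab) >= 3) tab[[3]] else NULL)
}

#' Construct an LRPairTable
#' @param ligand,receptor gene symbol vectors
#' @param pair_id optional unique ids (default ligand_receptor)
#' @return data.frame of class \code{LRPairTable}.
#' @export
lr_pair_table <- function(ligand, receptor, pair_id = NULL) {
  if (any(!nzchar(ligand)) || any(!nzchar(receptor)))
    stop("empty gene symbols in pair table")
  if (is.null(pair_id)) pair_id <- paste(ligand, receptor, sep = "_")
  if (anyDuplicated(pair_id)) stop("duplicate pair ids")
  structure(data.frame(ligand = ligand, receptor = receptor, pair_id = pair_id,
                       stringsAsFactors = FALSE),
            class = c("LRPairTable", "data.frame"))
}

.type_means <- function(vals, types) {
  tf <- factor(types)
  cnt <- as.vector(table(tf))
  mm <- t(rowsum(t(vals), tf)) / rep(cnt, each = nrow(vals))
  mm
}

.type_fracs <- function(vals, types) {
  tf <- factor(types)
  cnt <- as.vector(table(tf))
  t(rowsum(0 + t(vals > 0), tf)) / rep(cnt, each = nrow(vals))
}

#' Screen ligand-receptor pairs by expression fraction
#'
#' Keeps (pair, sender, receiver) triples whose ligand is detected (nonzero)
#' in strictly more than \code{min_frac} of the sender cells and whose
#' receptor is detected in strictly more than \code{min_frac} of the receiver
#' cells. Pairs whose genes are absent from the matrix are dropped (reported).
#'
#' @param nm a \code{NormalizedMatrix}
#' @param cell_type per-cell type labels
#' @param pairs an \code{LRPairTable}
#' @param min_frac detection-fraction cutoff (default 0.10, strict)
#' @return data.frame of candidate triples: pair_id, ligand, receptor,
#'   sender, receiver.
#' @export
screen_pairs <- function(nm, cell_type, pairs, min_frac = 0.10) {
  genes <- rownames(nm$values)
  present <- pairs$ligand %in% genes & pairs$receptor %in% genes
  if (any(!present))
    message(sum(!present), " pairs dropped: gene absent from matrix")
  pairs <- pairs[present, , drop = FALSE]
  used <- unique(c(pairs$ligand, pairs$receptor))
  fr <- .type_fracs(as.matrix(nm$values[used, , drop = FALSE]), cell_type)
  types <- colnames(fr)
  grid <- expand.grid(pi = seq_len(nrow(pairs)), sender = types,
                      receiver = types, stringsAsFactors = FALSE)
  ok <- fr[cbind(match(pairs$ligand[grid$pi], used), match(grid$sender, types))] > min_frac &
        fr[cbind(match(pairs$receptor[grid$pi], used), match(grid$receiver, types))] > min_frac
  data.frame(pair_id = pairs$pair_id[grid$pi[ok]],
             ligand = pairs$ligand[grid$pi[ok]],
             receptor = pairs$receptor[grid$pi[ok]],
             sender = grid$sender[ok], receiver = grid$receiver[ok],
             stringsAsFactors = FALSE)
}

#' Score candidate ligand-receptor triples
#'
#' Score = mean normalized ligand expression over sender cells times mean
#' normalized receptor expression over receiver cells.
#'
#' @param nm a \code{NormalizedMatrix}
#' @param cell_type per-cell type labels
#' @param candidates data.frame from \code{\link{screen_pairs}}
#' @return the candidates with a \code{score} column appended.
#' @export
score_pairs <- function(nm, cell_type, candidates) {
  used <- unique(c(candidates$ligand, candidates$receptor))
  mm <- .type_means(as.matrix(nm$values[used, , drop = FALSE]), cell_type)
  types <- colnames(mm)
  candidates$score <-
    mm[cbind(match(candidates$ligand, used), match(candidates$sender, types))] *
    mm[cbind(match(candidates$receptor, used), match(candidates$receiver, types))]
  candidates
}

#' Permutation test of ligand-receptor scores
#'
#' Cell-type labels are shuffled globally (preserving the type composition)
#' and scores recomputed per permutation; per triple,
#' p = (1 + #\{permuted >= observed\}) / (1 + n_perm), BH-adjusted across all
#' triples.
#'
#' @param nm a \code{NormalizedMatrix}
#' @param cell_type per-cell type labels
#' @param candidates scored candidates (from \code{\link{score_pairs}};
#'   scores are recomputed if absent)
#' @param n_perm permutations (default 1000)
#' @param seed integer seed
#' @return candidates with \code{p} and \code{p_adj} columns appended.
#' @export
lr_permutation_test <- function(nm, cell_type, candidates, n_perm = 1000,
                                seed = 1L) {
  if (is.null(candidates$score))
    candidates <- score_pairs(nm, cell_type, candidates)
  if (length(unique(cell_type)) < 2) stop("at least 2 cell types required")
  set.seed(child_seed(seed, "lr_perm"))
  used <- unique(c(candidates$ligand, candidates$receptor))
  vals <- as.matrix(nm$values[used, , drop = FALSE])
  li <- match(candidates$ligand, used); ri <- match(candidates$receptor, used)
  exceed <- integer(nrow(candidates))
  for (b in seq_len(n_perm)) {
    perm <- sample(cell_type)
    mm <- .type_means(vals, perm)
    types <- colnames(mm)
    sc <- mm[cbind(li, match(candidates$sender, types))] *
          mm[cbind(ri, match(candidates$receiver, types))]
    exceed <- exceed + (sc >= candidates$score - 1e-12)
  }
  candidates$p <- (1 + exceed) / (1 + n_perm)
  candidates$p_adj <- p.adjust(candidates$p, "BH")
  candidates
}

#' Specificity filter on marker Z scores
#'
#' Keeps triples whose ligand has one-vs-rest marker Z at least \code{z_min}
#' in the sender type and whose receptor reaches \code{z_min} in the receiver
#' type (other cell types as background).
#'
#' @param marker_table \code{MarkerTable} from \code{\link{marker_genes}} over
#'   the same cell-type labels
#' @param candidates candidate triples
#' @param z_min marker-Z cutoff (default 3)
#' @return filtered candidates with ligand/receptor specificity Z columns.
#' @export
specificity_filter <- function(marker_table, candidates, z_min = 3) {
  key <- paste(marker_table$cluster, marker_table$gene, sep = "\r")
  zl <- marker_table$z[match(paste(candidates$sender, candidates$ligand, sep = "\r"), key)]
  zr <- marker_table$z[match(paste(candidates$receiver, candidates$receptor, sep = "\r"), key)]
  zl[is.na(zl)] <- -Inf; zr[is.na(zr)] <- -Inf
  candidates$ligand_specificity_z <- zl
  candidates$receptor_specificity_z <- zr
  candidates[zl >= z_min & zr >= z_min, , drop = FALSE]
}

#' Tumor-upregulation filter on pseudobulk DE tables
#'
#' Keeps triples whose ligand (tested in the sender type) and/or receptor
#' (receiver type) are upregulated in tumor, i.e. log2FoldChange strictly
#' positive; \code{mode} selects whether both or either gene must pass.
#' Triples involving a type without a DE table are dropped with a warning.
#'
#' @param de_tables named list of \code{DETable}s, one per cell type
#' @param candidates candidate triples
#' @param mode "both" (default, stricter) or "either"
#' @return filtered candidates with ligand/receptor log2FC columns.
#' @export
condition_filter <- function(de_tables, candidates, mode = c("both", "either")) {
  mode <- match.arg(mode)
  get_lfc <- function(type, gene) {
    tab <- de_tables[[type]]
    if (is.null(tab)) return(NA_real_)
    lfc <- tab$log2FoldChange[match(gene, tab$gene)]
    if (length(lfc) == 0) NA_real_ else lfc
  }
  lf <- mapply(get_lfc, candidates$sender, candidates$ligand)
  rf <- mapply(get_lfc, candidates$receiver, candidates$receptor)
  missing <- is.na(lf) | is.na(rf)
  if (any(missing))
    warning(sum(missing), " triples dropped: missing DE table or gene")
  candidates$ligand_log2fc <- lf
  candidates$receptor_log2fc <- rf
  keep <- if (mode == "both") lf > 0 & rf > 0 else lf > 0 | rf > 0
  keep[is.na(keep)] <- FALSE
  candidates[keep, , drop = FALSE]
}
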