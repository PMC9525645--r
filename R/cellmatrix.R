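#' @importFrom Matrix readMM writeMM colSums rowSums rowMeans t sparseMatrix Diagonal
#' @importFrom stats median quantile rnorm rexp runif rbeta rgamma rnbinom
#'   wilcox.test t.test qnorm pnorm pchisq p.adjust cor cmdscale cov
#'   complete.cases setNames rmultinom coef glm poisson offset sd var
#' @importFrom utils read.delim write.table head
NULL

# ---- CellMatrix --------------------------------------------------------------

#' Construct a CellMatrix
#'
#' A \code{CellMatrix} bundles a sparse non-negative integer gene x cell count
#' matrix with per-cell metadata (sample id, condition in \{tumor, normal\},
#' cell-type label, optional 2-D embedding coordinates and doublet score).
#' Per-cell total UMI counts are derived, never stored.
#'
#' @param counts gene x cell matrix (coerced to \code{dgCMatrix}); no negative
#'   entries allowed.
#' @param gene_ids unique gene symbols (defaults to rownames).
#' @param cell_ids unique cell barcodes (defaults to colnames).
#' @param meta optional data.frame of per-cell metadata with columns among
#'   \code{sample}, \code{condition}, \code{cell_type}, \code{x}, \code{y},
#'   \code{doublet_score}; one row per cell, in cell order.
#' @return object of class \code{CellMatrix}.
#' @export
cell_matrix <- function(counts, gene_ids = rownames(counts),
                        cell_ids = colnames(counts), meta = NULL) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (any(counts@x < 0)) stop("counts contain negative entries")
  if (is.null(cell_ids) && ncol(counts) == 0) cell_ids <- character(0)
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("gene_ids and cell_ids are required")
  gene_ids <- as.character(gene_ids); cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(counts) || length(cell_ids) != ncol(counts))
    stop("id lengths do not match matrix dimensions")
  if (anyDuplicated(gene_ids)) stop("duplicate gene symbols")
  if (anyDuplicated(cell_ids)) stop("duplicate cell barcodes")
  dimnames(counts) <- list(gene_ids, cell_ids)
  if (is.null(meta)) {
    meta <- data.frame(row.names = cell_ids)
  } else {
    meta <- as.data.frame(meta)
    if (nrow(meta) != ncol(counts)) stop("metadata rows != number of cells")
    rownames(meta) <- cell_ids
  }
  structure(list(counts = counts, meta = meta), class = "CellMatrix")
}

#' @export
print.CellMatrix <- function(x, ...) {
  cat(sprintf("CellMatrix: %d genes x %d cells\n", nrow(x$counts), ncol(x$counts)))
  cat("metadata columns:", if (ncol(x$meta)) paste(colnames(x$meta), collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' @export
dim.CellMatrix <- function(x) dim(x$counts)

#' Per-cell total UMI counts
#' @param cm a CellMatrix
#' @return integer vector, one entry per cell (column sums of counts).
#' @export
total_umi <- function(cm) Matrix::colSums(cm$counts)

#' Subset a CellMatrix to a set of cells
#' @param cm a CellMatrix
#' @param cells logical/integer/character index of cells to keep
#' @return CellMatrix restricted to the selected cells.
#' @export
subset_cells <- function(cm, cells) {
  cell_matrix(cm$counts[, cells, drop = FALSE],
              meta = cm$meta[cells, , drop = FALSE])
}

# ---- 10x-style triplet IO ----------------------------------------------------

.find_10x_file <- function(dir_path, stems) {
  for (s in stems) for (ext in c("", ".gz")) {
    f <- file.path(dir_path, paste0(s, ext))
    if (file.exists(f)) return(f)
  }
  stop(sprintf("missing file: none of {%s} found in %s",
               paste(stems, collapse = ", "), dir_path))
}

#' Read a 10x-style MTX triplet directory
#'
#' Expects \code{matrix.mtx}, \code{features.tsv} (or \code{genes.tsv}) and
#' \code{barcodes.tsv}, optionally gzipped. Gene symbols are taken from the
#' last non-id column of the feature table (10x writes id, symbol, type).
#'
#' @param dir_path directory containing the triplet
#' @param permissive if TRUE, duplicated gene symbols keep the first
#'   occurrence (dropped rows are reported via a message) instead of erroring.
#' @return a CellMatrix without metadata (attach it with
#'   \code{\link{attach_metadata}}).
#' @export
read_10x_mtx <- function(dir_path, permissive = FALSE) {
  mtx_f <- .find_10x_file(dir_path, "matrix.mtx")
  feat_f <- .find_10x_file(dir_path, c("features.tsv", "genes.tsv"))
  bc_f <- .find_10x_file(dir_path, "barcodes.tsv")
  m <- Matrix::readMM(mtx_f)
  feats <- read.delim(feat_f, header = FALSE, stringsAsFactors = FALSE)
  bcs <- readLines(bc_f)
  bcs <- sub("\t.*", "", bcs[nzchar(bcs)])
  if (length(bcs) == 0 && ncol(m) > 0)
    stop("integrity error: empty barcode file for a non-empty matrix")
  if (nrow(feats) != nrow(m))
    stop(sprintf("integrity error: %d features listed but matrix has %d rows",
                 nrow(feats), nrow(m)))
  if (length(bcs) != ncol(m))
    stop(sprintf("integrity error: %d barcodes listed but matrix has %d columns",
                 length(bcs), ncol(m)))
  if (length(m@x) && any(m@x < 0))
    stop("integrity error: negative entries in count matrix")
  symbols <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
  if (anyDuplicated(symbols)) {
    if (!permissive) stop("duplicate gene symbols in feature file")
    keep <- !duplicated(symbols)
    message(sum(!keep), " duplicated gene symbols dropped (first occurrence kept)")
    m <- m[keep, , drop = FALSE]; symbols <- symbols[keep]
  }
  cell_matrix(m, gene_ids = symbols, cell_ids = bcs)
}

#' Write a CellMatrix as a 10x-style MTX triplet (plus metadata TSV)
#' @param cm a CellMatrix
#' @param dir_path output directory (created if absent)
#' @return \code{dir_path}, invisibly.
#' @export
write_10x_mtx <- function(cm, dir_path) {
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(cm$counts, file.path(dir_path, "matrix.mtx"))
  write.table(data.frame(id = rownames(cm$counts), symbol = rownames(cm$counts),
                         type = "Gene Expression"),
              file.path(dir_path, "features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(data.frame(colnames(cm$counts)),
              file.path(dir_path, "barcodes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (ncol(cm$meta)) {
    out <- cbind(barcode = rownames(cm$meta), cm$meta)
    write.table(out, file.path(dir_path, "metadata.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir_path)
}

#' Attach per-cell metadata from a barcode-keyed table
#'
#' @param cm a CellMatrix
#' @param table data.frame or TSV path with a \code{barcode} column (or first
#'   column) and columns among \code{sample}, \code{condition},
#'   \code{cell_type}, \code{x}, \code{y}, \code{doublet_score}.
#' @param permissive if TRUE, cells missing from the table are dropped (their
#'   count is reported); otherwise missing cells are an error.
#' @return CellMatrix with metadata joined by barcode.
#' @export
attach_metadata <- function(cm, table, permissive = FALSE) {
  if (is.character(table)) table <- read.delim(table, stringsAsFactors = FALSE)
  table <- as.data.frame(table)
  key <- if ("barcode" %in% colnames(table)) "barcode" else colnames(table)[1]
  bc <- as.character(table[[key]])
  if (anyDuplicated(bc)) stop("duplicate barcodes in metadata table")
  known <- c("sample", "condition", "cell_type", "x", "y", "doublet_score")
  cols <- intersect(colnames(table), known)
  present <- colnames(cm$counts) %in% bc
  if (!all(present)) {
    if (!permissive)
      stop(sum(!present), " cells absent from metadata table")
    message(sum(!present), " cells absent from metadata table were dropped")
    cm <- subset_cells(cm, present)
  }
  idx <- match(colnames(cm$counts), bc)
  meta <- table[idx, cols, drop = FALSE]
  rownames(meta) <- colnames(cm$counts)
  if ("doublet_score" %in% cols) {
    ds <- meta$doublet_score
    if (any(ds < 0 | ds > 1, na.rm = TRUE)) stop("doublet_score outside [0,1]")
  }
  cell_matrix(cm$counts, meta = meta)
}

#' Check that the condition labels form exactly two groups
#' @param cm a CellMatrix with a \code{condition} metadata column
#' @return the two condition labels, tumor-like label first when recognizable.
#' @export
condition_levels <- function(cm) {
  if (!"condition" %in% colnames(cm$meta)) stop("condition metadata absent")
  lv <- unique(as.character(cm$meta$condition))
  if (length(lv) != 2)
    stop(sprintf("two-group analysis requires exactly 2 condition labels, found %d (%s)",
                 length(lv), paste(lv, collapse = ", ")))
  if ("tumor" %in% lv) c("tumor", setdiff(lv, "tumor")) else sort(lv)
}

# ---- QC ----------------------------------------------------------------------

#' Quality-control filter on UMI depth and doublet score
#'
#' Retains cells with at least \code{min_umi} total UMI ("fewer than 700" are
#' excluded, so 700 itself is kept) and with doublet score at most
#' \code{max_doublet} (scores strictly above the cutoff are removed). Counts
#' removed per criterion and per sample are reported via messages.
#'
#' @param cm a CellMatrix
#' @param min_umi minimum per-cell total UMI retained (default 700)
#' @param max_doublet maximum doublet score retained (default 0.4); set to
#'   \code{NULL} to skip (required when no doublet scores are attached).
#' @return filtered CellMatrix (possibly with zero cells, with a warning).
#' @export
filter_cells <- function(cm, min_umi = 700, max_doublet = 0.4) {
  if (ncol(cm$counts) == 0) {
    warning("input has zero cells")
    return(cm)
  }
  umi_ok <- total_umi(cm) >= min_umi
  if (!is.null(max_doublet)) {
    if (!"doublet_score" %in% colnames(cm$meta))
      stop("doublet_score metadata required for doublet filtering; pass max_doublet = NULL to skip")
    dbl_ok <- cm$meta$doublet_score <= max_doublet
  } else dbl_ok <- rep(TRUE, ncol(cm$counts))
  keep <- umi_ok & dbl_ok
  smp <- if ("sample" %in% colnames(cm$meta)) as.character(cm$meta$sample)
         else rep("(all)", ncol(cm$counts))
  for (s in unique(smp)) {
    i <- smp == s
    message(sprintf("QC %s: %d cells below %d UMI, %d above doublet cutoff, %d/%d kept",
                    s, sum(!umi_ok & i), min_umi, sum(umi_ok & !dbl_ok & i),
                    sum(keep & i), sum(i)))
  }
  out <- subset_cells(cm, keep)
  if (ncol(out$counts) == 0) warning("all cells removed by QC")
  out
}

# ---- Normalization -----------------------------------------------------------

#' Depth-normalize and log-transform counts
#'
#' Each cell is scaled to a common depth (counts divided by the cell's total
#' UMI and multiplied by \code{scale}) and then log-transformed with a
#' pseudocount: \code{log(x + pseudocount) - log(pseudocount)} in base
#' \code{base}, which for the defaults is \code{log1p} of counts-per-10k.
#' All-zero cells map to all-zero columns.
#'
#' @param cm a CellMatrix
#' @param scale common target depth (default 10000)
#' @param pseudocount added before the log (default 1)
#' @param base log base (default \code{exp(1)})
#' @return object of class \code{NormalizedMatrix} with fields \code{values}
#'   (sparse genes x cells), \code{meta} (carried over) and \code{provenance}.
#' @export
normalize_cells <- function(cm, scale = 1e4, pseudocount = 1, base = exp(1)) {
  tot <- total_umi(cm)
  sf <- ifelse(tot > 0, scale / tot, 0)
  v <- cm$counts %*% Matrix::Diagonal(x = sf)
  v <- methods::as(v, "generalMatrix")
  # log(x + c) - log(c) keeps structural zeros at zero for any pseudocount
  v@x <- (log(v@x + pseudocount) - log(pseudocount)) / log(base)
  dimnames(v) <- dimnames(cm$counts)
  structure(list(values = v, meta = cm$meta,
                 provenance = list(scale = scale, pseudocount = pseudocount,
                                   base = base)),
            class = "NormalizedMatrix")
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf("NormalizedMatrix: %d genes x %d cells (scale %g, pseudocount %g)\n",
              nrow(x$values), ncol(x$values), x$provenance$scale,
              x$provenance$pseudocount))
  invisible(x)
}

# ---- Gene sets ---------------------------------------------------------------

#' Construct a GeneSet
#' @param name set name
#' @param genes character vector of gene symbols (non-empty, duplicates removed)
#' @return object of class \code{GeneSet}.
#' @export
gene_set <- function(name, genes) {
  genes <- as.character(genes)
  if (length(genes) == 0) stop("empty gene set")
  genes <- unique(genes)
  structure(list(name = name, genes = genes), class = "GeneSet")
}

#' Read gene sets from a two-column TSV (set, gene) or GMT file
#' @param path file path; format chosen by extension (\code{.gmt} vs TSV)
#' @return named list of \code{GeneSet} objects.
#' @export
read_gene_sets <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    sets <- lapply(strsplit(lines, "\t"), function(f)
      gene_set(f[1], f[-(1:2)][nzchar(f[-(1:2)])]))
  } else {
    tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    sets <- lapply(split(tab[[2]], tab[[1]]), function(g) g)
    sets <- mapply(gene_set, names(sets), sets, SIMPLIFY = FALSE)
  }
  setNames(sets, vapply(sets, `[[`, "", "name"))
}

#' Write gene sets as a two-column TSV
#' @param sets list of GeneSet objects (or a single GeneSet)
#' @param path output path
#' @return \code{path}, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  if (inherits(sets, "GeneSet")) sets <- list(sets)
  tab <- do.call(rbind, lapply(sets, function(s)
    data.frame(set = s$name, gene = s$genes)))
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
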