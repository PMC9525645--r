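# Differential cell abundance: per-sample kernel density on a shared 2-D
# embedding grid with quantile normalization and a per-bin Welch Z map; direct
# cell-type proportion tests; compositional (ILR + discriminant) analysis with
# a sample-and-cell bootstrap.

.nrd_safe <- function(v, lim) {
  h <- tryCatch(MASS::bandwidth.nrd(v), error = function(e) 0)
  if (!is.finite(h) || h <= 0) h <- max(diff(lim) / 25, 1e-6)
  h
}

#' Per-sample kernel density grids on a shared embedding bounding box
#'
#' Gaussian-kernel density per sample on a shared \code{gridsize x gridsize}
#' grid covering all samples' embedding coordinates (expanded slightly so the
#' kernels' mass is captured). Bandwidths are the normal-reference
#' (Scott-type) rule per sample and axis. Each grid is renormalized so that
#' density times bin area sums to 1. Samples with fewer than 10 cells are
#' excluded with a warning.
#'
#' @param cm a CellMatrix with \code{x}, \code{y} embedding metadata
#' @param gridsize grid resolution per axis (default 400)
#' @return object of class \code{DensityGrid}: list with \code{grids} (named
#'   list of gridsize x gridsize matrices), \code{xgrid}, \code{ygrid},
#'   \code{bin_area}, \code{cell_counts} (per-bin occupancy over all cells)
#'   and \code{condition} per sample.
#' @export
estimate_density <- function(cm, gridsize = 400) {
  meta <- cm$meta
  if (!all(c("x", "y") %in% colnames(meta))) stop("embedding (x, y) absent")
  pad_x <- 0.1 * diff(range(meta$x)); pad_y <- 0.1 * diff(range(meta$y))
  xlim <- range(meta$x) + c(-1, 1) * max(pad_x, 1e-3)
  ylim <- range(meta$y) + c(-1, 1) * max(pad_y, 1e-3)
  samples <- unique(as.character(meta$sample))
  grids <- list(); cond <- character(0)
  for (s in samples) {
    i <- meta$sample == s
    if (sum(i) < 10) {
      warning("sample ", s, " has fewer than 10 cells; excluded from density")
      next
    }
    h <- c(.nrd_safe(meta$x[i], xlim), .nrd_safe(meta$y[i], ylim))
    kd <- MASS::kde2d(meta$x[i], meta$y[i], h = h, n = gridsize,
                      lims = c(xlim, ylim))
    bin_area <- diff(kd$x[1:2]) * diff(kd$y[1:2])
    grids[[s]] <- kd$z / (sum(kd$z) * bin_area)
    cond[s] <- as.character(meta$condition[i][1])
  }
  if (length(grids) < 1) stop("no sample with enough cells for density estimation")
  xgrid <- seq(xlim[1], xlim[2], length.out = gridsize)
  ygrid <- seq(ylim[1], ylim[2], length.out = gridsize)
  xi <- findInterval(meta$x, xgrid, all.inside = TRUE)
  yi <- findInterval(meta$y, ygrid, all.inside = TRUE)
  occ <- matrix(0L, gridsize, gridsize)
  tb <- table(xi, yi)
  occ[cbind(as.integer(rownames(tb))[row(tb)],
            as.integer(colnames(tb))[col(tb)])] <- as.integer(tb)
  structure(list(grids = grids, xgrid = xgrid, ygrid = ygrid,
                 bin_area = diff(xgrid[1:2]) * diff(ygrid[1:2]),
                 cell_counts = occ, condition = cond),
            class = "DensityGrid")
}

#' Quantile-normalize per-sample density grids
#'
#' After normalization, the sorted value vectors of all samples are identical
#' (the mean of the per-sample order statistics); within-sample ranks are
#' preserved and ties map to the mean of the tied reference quantiles.
#'
#' @param dens a \code{DensityGrid}
#' @return the \code{DensityGrid} with normalized grids.
#' @export
quantile_normalize_grids <- function(dens) {
  if (length(dens$grids) < 2) stop("at least 2 grids required")
  dims <- dim(dens$grids[[1]])
  if (!all(vapply(dens$grids, function(g) identical(dim(g), dims), TRUE)))
    stop("grid shape mismatch")
  m <- vapply(dens$grids, as.vector, numeric(prod(dims)))
  qn <- limma::normalizeQuantiles(m, ties = TRUE)
  dens$grids <- setNames(lapply(seq_len(ncol(qn)), function(j)
    matrix(qn[, j], dims[1], dims[2])), colnames(m))
  dens
}

#' Per-bin differential density Z map
#'
#' For every grid bin occupied by at least \code{min_cells_per_bin} cells, a
#' Welch two-sample t statistic across samples (tumor minus normal) is
#' converted into a signed Z score (positive = denser in tumor). Bins with
#' zero variance in both groups and equal means get Z = 0; unoccupied bins are
#' masked and set to 0.
#'
#' @param dens a \code{DensityGrid} (typically quantile-normalized)
#' @param min_cells_per_bin occupancy needed for a bin to enter the map
#' @return object of class \code{DensityDiffMap}: list with \code{z} (matrix),
#'   \code{mask} (logical matrix), \code{xgrid}, \code{ygrid}.
#' @export
density_diff <- function(dens, min_cells_per_bin = 1) {
  cond <- dens$condition
  tum <- names(cond)[cond == "tumor"]; nor <- names(cond)[cond != "tumor"]
  if (length(tum) < 2 || length(nor) < 2)
    stop("at least 2 samples per condition required")
  dims <- dim(dens$grids[[1]])
  A <- vapply(dens$grids[tum], as.vector, numeric(prod(dims)))
  B <- vapply(dens$grids[nor], as.vector, numeric(prod(dims)))
  m1 <- rowMeans(A); m2 <- rowMeans(B)
  v1 <- apply(A, 1, var); v2 <- apply(B, 1, var)
  n1 <- ncol(A); n2 <- ncol(B)
  se2 <- v1 / n1 + v2 / n2
  tstat <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)), 1)
  p <- 2 * stats::pt(-abs(tstat), df)
  z <- sign(tstat) * qnorm(pmax(p / 2, .Machine$double.xmin), lower.tail = FALSE)
  z[se2 == 0 & m1 == m2] <- 0
  mask <- as.vector(dens$cell_counts >= min_cells_per_bin)
  z[!mask] <- 0
  structure(list(z = matrix(z, dims[1], dims[2]),
                 mask = matrix(mask, dims[1], dims[2]),
                 xgrid = dens$xgrid, ygrid = dens$ygrid),
            class = "DensityDiffMap")
}

#' Export a differential-density map as TSV (and optionally PNG)
#' @param map a DensityDiffMap
#' @param path output TSV path
#' @param png_path optional PNG heatmap path
#' @return \code{path}, invisibly.
#' @export
write_density_diff <- function(map, path, png_path = NULL) {
  tab <- data.frame(x = rep(map$xgrid, times = length(map$ygrid)),
                    y = rep(map$ygrid, each = length(map$xgrid)),
                    z = as.vector(map$z), mask = as.vector(map$mask))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 700, height = 600)
    zl <- max(abs(map$z), 1e-9)
    graphics::image(map$xgrid, map$ygrid, map$z, zlim = c(-zl, zl),
                    col = grDevices::hcl.colors(101, "Blue-Red 3"),
                    xlab = "embedding 1", ylab = "embedding 2",
                    main = "differential cell density (Z)")
    grDevices::dev.off()
  }
  invisible(path)
}

# ---- proportion tests --------------------------------------------------------

#' Per-sample cell-type fractions
#'
#' @param cm a CellMatrix with sample and cell_type metadata (cells without a
#'   type label are excluded, with a message)
#' @param parent_map optional named vector mapping cell type -> parent
#'   compartment; when given, each type's denominator is the sample's cell
#'   count in that compartment rather than all cells.
#' @return list with \code{fractions} (samples x types), \code{counts}
#'   (samples x types integer) and \code{condition} per sample.
#' @export
cell_type_fractions <- function(cm, parent_map = NULL) {
  meta <- cm$meta
  if (!all(c("sample", "cell_type") %in% colnames(meta)))
    stop("sample and cell_type metadata required")
  drop <- is.na(meta$cell_type)
  if (any(drop)) {
    message(sum(drop), " cells without a cell_type label excluded")
    meta <- meta[!drop, , drop = FALSE]
  }
  counts <- as.matrix(table(meta$sample, meta$cell_type))
  types <- colnames(counts)
  if (is.null(parent_map)) {
    denom <- matrix(rowSums(counts), nrow(counts), ncol(counts))
  } else {
    denom <- vapply(types, function(tp) {
      members <- names(parent_map)[parent_map == parent_map[[tp]]]
      rowSums(counts[, intersect(members, types), drop = FALSE])
    }, numeric(nrow(counts)))
  }
  frac <- counts / denom
  if (any(denom == 0)) {
    message(sum(denom == 0), " sample/type denominators were zero (fraction set NA)")
    frac[denom == 0] <- NA
  }
  cond <- vapply(rownames(counts), function(s)
    as.character(meta$condition[meta$sample == s][1]), "")
  list(fractions = frac, counts = counts, condition = cond)
}

#' Rank-sum tests of per-sample cell-type fractions, tumor vs normal
#'
#' @param cm a CellMatrix
#' @param parent_map optional type -> parent compartment map (fractions are
#'   then computed within the parent compartment)
#' @return data.frame with per-type mean fractions, rank-sum statistic,
#'   two-sided p and BH-adjusted p.
#' @export
proportion_tests <- function(cm, parent_map = NULL) {
  fr <- cell_type_fractions(cm, parent_map)
  tum <- fr$condition == "tumor"
  res <- lapply(colnames(fr$fractions), function(tp) {
    x <- fr$fractions[tum, tp]; y <- fr$fractions[!tum, tp]
    ht <- rank_sum_test(x, y)
    data.frame(cell_type = tp,
               mean_tumor = mean(x, na.rm = TRUE),
               mean_normal = mean(y, na.rm = TRUE),
               statistic = ht$statistic, p = ht$p, method = ht$method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- p.adjust(out$p, "BH")
  out
}

# ---- compositional analysis --------------------------------------------------

.helmert_basis <- function(D) {
  # orthonormal ILR contrast basis (rows of the Helmert matrix, normalized)
  H <- stats::contr.helmert(D)       # D x (D-1)
  sweep(H, 2, sqrt(colSums(H^2)), "/")
}

.clr <- function(x) {
  lx <- log(x)
  lx - rowMeans(lx)
}

.coda_axis <- function(counts, condition, basis) {
  # multiplicative zero replacement: 0.5 / sample total, then closure
  tot <- rowSums(counts)
  frac <- counts / tot
  repl <- 0.5 / tot
  frac <- frac + (frac == 0) * repl
  frac <- frac / rowSums(frac)
  ilr <- .clr(frac) %*% basis
  grp <- factor(condition == "tumor", levels = c(FALSE, TRUE))
  ld <- tryCatch(MASS::lda(ilr, grouping = grp), error = function(e) NULL)
  a <- if (!is.null(ld)) ld$scaling[, 1] else {
    # ridge Fisher direction as a fallback for degenerate within-class scatter
    mu_d <- colMeans(ilr[grp == TRUE, , drop = FALSE]) -
            colMeans(ilr[grp == FALSE, , drop = FALSE])
    Sw <- cov(ilr - rowsum(ilr, grp)[grp, ] / as.vector(table(grp))[grp])
    solve(Sw + diag(1e-6, ncol(ilr)), mu_d)
  }
  coef <- as.vector(basis %*% a)          # back to CLR space: sums to zero
  proj <- ilr %*% a
  if (mean(proj[grp == TRUE]) < mean(proj[grp == FALSE])) coef <- -coef
  coef / sqrt(sum(coef^2))
}

#' Compositional separating coefficients with sample-and-cell bootstrap
#'
#' Cell-type fractions are mapped to isometric log-ratio coordinates through a
#' fixed orthonormal (Helmert-type) contrast basis, a two-group canonical
#' discriminant axis (tumor vs normal) is fitted, and its loadings are mapped
#' back through the basis into centered log-ratio space, giving one
#' basis-invariant coefficient per cell type (positive = enriched in tumor;
#' coefficients sum to zero and are scaled to unit norm). Robustness is
#' assessed by bootstrap: each round resamples samples with replacement within
#' each condition and then draws \code{cells_per_boot} cells per condition
#' (without replacement from the pooled resampled cells) before recomputing
#' the axis. Zero fractions are replaced by 0.5 / (sample cell count) before
#' closure.
#'
#' @param counts samples x cell-types integer matrix of cell counts (e.g.
#'   \code{cell_type_fractions(cm)$counts})
#' @param condition per-sample condition labels aligned to rows
#' @param n_boot bootstrap rounds (default 1000)
#' @param cells_per_boot cells drawn per condition per round (default 1000)
#' @param seed integer seed for the bootstrap
#' @return object of class \code{CompositionResult}: list with
#'   \code{coefficients} (named per type), \code{bootstrap_draws}
#'   (n_boot x types matrix) and \code{positive_fraction} per type.
#' @export
coda_coefficients <- function(counts, condition, n_boot = 1000,
                              cells_per_boot = 1000, seed = 1L) {
  counts <- as.matrix(counts)
  keep <- colSums(counts) > 0
  if (!all(keep)) {
    warning(sum(!keep), " cell types absent from every sample dropped")
    counts <- counts[, keep, drop = FALSE]
  }
  if (length(unique(condition)) != 2 || min(table(condition)) < 3)
    stop("two conditions with at least 3 samples per condition required")
  D <- ncol(counts)
  basis <- .helmert_basis(D)
  coef <- .coda_axis(counts, condition, basis)
  names(coef) <- colnames(counts)

  set.seed(child_seed(seed, "coda_boot"))
  draws <- matrix(NA_real_, n_boot, D, dimnames = list(NULL, colnames(counts)))
  grp_idx <- split(seq_len(nrow(counts)), condition == "tumor")
  for (b in seq_len(n_boot)) {
    rows <- list(); conds <- character(0)
    for (g in names(grp_idx)) {
      pick <- sample(grp_idx[[g]], length(grp_idx[[g]]), replace = TRUE)
      # pooled cells of the resampled samples, tagged by bootstrap replicate
      pool_rep <- rep(seq_along(pick), rowSums(counts)[pick])
      pool_type <- unlist(lapply(pick, function(i)
        rep(seq_len(D), counts[i, ])), use.names = FALSE)
      n_draw <- min(cells_per_boot, length(pool_type))
      sel <- sample.int(length(pool_type), n_draw)
      tb <- matrix(0, length(pick), D)
      inc <- table(factor(pool_rep[sel], levels = seq_along(pick)),
                   factor(pool_type[sel], levels = seq_len(D)))
      tb[] <- as.integer(inc)
      nonempty <- rowSums(tb) > 0
      rows[[g]] <- tb[nonempty, , drop = FALSE]
      conds <- c(conds, rep(if (g == "TRUE") "tumor" else "normal",
                            sum(nonempty)))
    }
    bc <- do.call(rbind, rows)
    if (min(table(conds)) < 2) next
    draws[b, ] <- tryCatch(.coda_axis(bc, conds, basis),
                           error = function(e) rep(NA_real_, D))
  }
  structure(list(coefficients = coef, bootstrap_draws = draws,
                 positive_fraction = colMeans(draws > 0, na.rm = TRUE)),
            class = "CompositionResult")
}

#' Export compositional coefficients with bootstrap quantiles as TSV
#' @param res a CompositionResult
#' @param path output path
#' @return \code{path}, invisibly.
#' @export
write_coda <- function(res, path) {
  qs <- t(apply(res$bootstrap_draws, 2, quantile,
                probs = c(0.025, 0.25, 0.5, 0.75, 0.975), na.rm = TRUE))
  tab <- data.frame(cell_type = names(res$coefficients),
                    coefficient = unname(res$coefficients),
                    qs, check.names = FALSE,
                    positive_fraction = unname(res$positive_fraction))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
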