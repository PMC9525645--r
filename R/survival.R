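# Signature-stratified survival: quartile grouping on the mean signature
# expression, the two-sided log-rank test, and the bootstrap
# "reproducibility power" p-value (the 0.95 quantile of log-rank p over
# gene-resampled signatures).

#' Quartile stratification of samples by score
#'
#' Assigns the top \code{floor(q * n)} scores to "high" and the bottom
#' \code{floor(q * n)} to "low"; the remainder is "excluded". Ties straddling
#' a cutoff are broken by stable sample order (the tie count is reported).
#'
#' @param scores per-sample numeric scores
#' @param q tail fraction per group (default 0.25)
#' @return character vector in \{"high", "low", "excluded"\} aligned to scores.
#' @export
stratify_quartiles <- function(scores, q = 0.25) {
  n <- length(scores)
  if (n < 8) stop("at least 8 samples required")
  if (length(unique(scores)) == 1) stop("all scores identical: no stratification possible")
  k <- floor(q * n)
  ord_hi <- order(-scores, seq_len(n))   # stable under ties
  ord_lo <- order(scores, seq_len(n))
  grp <- rep("excluded", n)
  grp[ord_hi[seq_len(k)]] <- "high"
  grp[ord_lo[seq_len(k)]] <- "low"
  cut_hi <- scores[ord_hi[k]]; cut_lo <- scores[ord_lo[k]]
  n_tied <- sum(scores == cut_hi) + sum(scores == cut_lo) - 2
  if (n_tied > 0)
    message(n_tied, " tied scores at a quartile boundary; stable-order assignment")
  grp
}

#' Two-sided log-rank test between high and low groups
#'
#' Standard log-rank chi-square on 1 df via \code{survival::survdiff}; with no
#' events the statistic is 0 and p = 1 by convention (warned).
#'
#' @param groups per-sample labels; only "high" and "low" enter the test
#' @param time follow-up times
#' @param event event indicators (1 = event)
#' @return list with \code{statistic} (chi-square) and \code{p}.
#' @export
logrank_test <- function(groups, time, event) {
  use <- groups %in% c("high", "low")
  if (!any(groups[use] == "high") || !any(groups[use] == "low"))
    stop("both groups must be non-empty")
  if (sum(event[use]) == 0) {
    warning("no events observed; log-rank statistic 0 by convention")
    return(list(statistic = 0, p = 1))
  }
  sd <- survival::survdiff(survival::Surv(time[use], event[use]) ~ groups[use])
  list(statistic = unname(sd$chisq), p = pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Bootstrap reproducibility power of a signature's survival association
#'
#' The per-sample score is the mean (log-scale) expression of the signature
#' genes; samples are quartile-stratified and tested with the log-rank test.
#' The signature's genes are then resampled with replacement (at the original
#' size) for \code{n_boot} rounds, the analysis repeated, and the
#' \code{quantile} (default 0.95) of the bootstrap p-values reported as the
#' reproducibility-power p-value.
#'
#' @param cohort a \code{SurvivalCohort}
#' @param signature a \code{GeneSet} (at least 2 genes present in the cohort)
#' @param n_boot bootstrap rounds (default 100)
#' @param quantile_level quantile of the bootstrap p-values reported (default 0.95)
#' @param q tail fraction per stratum (default 0.25)
#' @param seed integer seed
#' @param log1p_transform set TRUE if the cohort holds raw counts
#' @return object of class \code{StratifiedTest}: group assignment, log-rank
#'   statistic and p for the unresampled signature, \code{bootstrap_p} vector
#'   and \code{power_p}.
#' @export
reproducibility_power <- function(cohort, signature, n_boot = 100,
                                  quantile_level = 0.95, q = 0.25, seed = 1L,
                                  log1p_transform = FALSE) {
  expr <- cohort$expression
  if (log1p_transform) expr <- log1p(expr)
  genes <- intersect(signature$genes, colnames(expr))
  if (length(genes) < 2)
    stop("fewer than 2 signature genes present in cohort")
  run_once <- function(gs) {
    score <- rowMeans(expr[, gs, drop = FALSE])
    if (length(unique(score)) == 1) return(NULL)
    grp <- stratify_quartiles(score, q)
    logrank_test(grp, cohort$time, cohort$event)
  }
  base_score <- rowMeans(expr[, genes, drop = FALSE])
  groups <- stratify_quartiles(base_score, q)
  base <- logrank_test(groups, cohort$time, cohort$event)
  set.seed(child_seed(seed, "reproducibility_power"))
  boot_p <- vapply(seq_len(n_boot), function(b) {
    res <- run_once(sample(genes, length(genes), replace = TRUE))
    if (is.null(res)) NA_real_ else res$p
  }, numeric(1))
  structure(list(groups = groups, statistic = base$statistic, p = base$p,
                 bootstrap_p = boot_p,
                 power_p = unname(quantile(boot_p, quantile_level, na.rm = TRUE)),
                 n_genes_used = length(genes)),
            class = "StratifiedTest")
}

#' Kaplan-Meier plot of the stratified groups
#' @param st a StratifiedTest
#' @param cohort the SurvivalCohort it was computed on
#' @param path PNG output path
#' @return \code{path}, invisibly.
#' @export
plot_km <- function(st, cohort, path) {
  use <- st$groups %in% c("high", "low")
  fit <- survival::survfit(survival::Surv(cohort$time[use], cohort$event[use]) ~
                             st$groups[use])
  grDevices::png(path, width = 700, height = 600)
  plot(fit, col = c("red", "blue"), xlab = "time", ylab = "survival",
       main = sprintf("log-rank p = %.3g (power p = %.3g)", st$p, st$power_p))
  graphics::legend("topright", legend = c("high", "low"),
                   col = c("red", "blue"), lty = 1)
  grDevices::dev.off()
  invisible(path)
}
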