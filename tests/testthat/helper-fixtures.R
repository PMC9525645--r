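# Shared fixture builders. Everything is generated in code; no stored data.

# tiny deterministic CellMatrix with full metadata
tiny_cm <- function() {
  counts <- matrix(c(1, 0, 2,
                     3, 1, 0,
                     0, 4, 5,
                     2, 2, 2), nrow = 4, byrow = TRUE,
                   dimnames = list(paste0("g", 1:4), paste0("c", 1:3)))
  meta <- data.frame(sample = c("S1", "S1", "S2"),
                     condition = c("tumor", "tumor", "normal"),
                     cell_type = c("A", "B", "A"),
                     x = c(0, 1, 2), y = c(0, 1, 2),
                     doublet_score = c(0.1, 0.2, 0.3))
  cell_matrix(counts, meta = meta)
}

# exchangeable two-condition cohort (no planted effects, no type markers)
null_config <- function(seed, n_samples = 5, cells = 80, genes = 60,
                        types = c(A = 0.4, B = 0.35, C = 0.25)) {
  simulation_config(n_samples_per_condition = n_samples,
                    cells_per_sample = cells, n_genes = genes,
                    cell_types = types, marker_genes_per_type = 0,
                    doublet_rate = 0, seed = seed)
}

# exact two-sided rank-sum p by full enumeration of group assignments
enum_ranksum_p <- function(x, y) {
  v <- c(x, y); n <- length(v); n1 <- length(x)
  r <- rank(v)
  obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(n, n1)
  stats <- apply(combs, 2, function(ix) sum(r[ix]))
  mu <- n1 * (n + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# closed-form log-rank (observed minus expected) for two groups, all times
# distinct; returns the 1-df chi-square
logrank_closed_form <- function(time, event, is_high) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; is_high <- is_high[ord]
  O <- 0; E <- 0; V <- 0
  for (i in seq_along(time)) {
    if (!event[i]) next
    at_risk <- time >= time[i]
    n <- sum(at_risk); n1 <- sum(at_risk & is_high)
    O <- O + is_high[i]
    E <- E + n1 / n
    if (n > 1) V <- V + n1 * (n - n1) / n^2
  }
  (O - E)^2 / V
}
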