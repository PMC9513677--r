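# Independent oracles kept deliberately naive: direct loops and exhaustive
# enumeration, never sharing code with the package implementation.

# Frame-by-frame occupancy count over a closed time window.
bf_occupancy <- function(time_ps, distance_nm, t_start, t_end, cutoff = 0.35) {
  n_in <- 0L
  n_bonded <- 0L
  for (i in seq_along(time_ps)) {
    if (time_ps[i] >= t_start && time_ps[i] <= t_end) {
      n_in <- n_in + 1L
      if (distance_nm[i] <= cutoff) n_bonded <- n_bonded + 1L
    }
  }
  list(pct = 100 * n_bonded / n_in, n = n_in)
}

# Upper-tail hypergeometric probability by full enumeration of all
# n-subsets of a background of size N with K annotated items. Feasible for
# N <= ~30.
enum_hyper_p <- function(k, n, K, N) {
  items <- c(rep(1L, K), rep(0L, N - K))
  subsets <- utils::combn(N, n)
  hits <- 0L
  for (j in seq_len(ncol(subsets))) {
    if (sum(items[subsets[, j]]) >= k) hits <- hits + 1L
  }
  hits / ncol(subsets)
}

# Same probability via the exact combinatorial sum (works for any N).
sum_hyper_p <- function(k, n, K, N) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Adjusted Rand index between two labelings (delegates to mclust, an
# implementation independent of this package).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Spearman correlation magnitude between per-sample ion intensity and
# injection order, worst case over ions.
max_drift_rho <- function(intensities, meta) {
  idx <- meta$injection_index[match(intensities$sample_id, meta$sample_id)]
  ions <- setdiff(names(intensities), "sample_id")
  max(vapply(ions, function(ion) {
    abs(cor(rank(intensities[[ion]]), rank(idx)))
  }, numeric(1)))
}

# Log2 fold-change of a strain vs control estimated directly from a
# corrected matrix by group means.
direct_log2fc <- function(intensities, meta, strain, ion,
                          control = "control") {
  li <- log2(intensities[[ion]])
  ids <- intensities$sample_id
  s <- meta$strain[match(ids, meta$sample_id)]
  mean(li[s == strain]) - mean(li[s == control])
}
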