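# Independent brute-force oracles, deliberately written as literal loops so
# they share no code path with the implementation they check.

# weighted-KS enrichment score by stepping through the ranked list one
# position at a time
oracle_es <- function(ranked, gene_set, weight = 1) {
  genes <- names(ranked)
  n <- length(genes)
  hit <- genes %in% gene_set
  nh <- sum(hit)
  denom <- sum(abs(ranked[hit])^weight)
  running <- numeric(n)
  s <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      s <- s + if (denom > 0) abs(ranked[i])^weight / denom else 1 / nh
    } else {
      s <- s - 1 / (n - nh)
    }
    running[i] <- s
  }
  best <- 0
  for (i in seq_len(n)) {
    if (abs(running[i]) > abs(best) + 1e-12) best <- running[i]
  }
  best
}

# strong-effects, small-noise study conditions: planted index fold changes
# kept away from the 1.5 classification boundary
strong_config <- function(seed, n_genes = 200L, n_up = 117L, n_down = 159L,
                          n_unchanged = 120L, ...) {
  sim_config(n_up = n_up, n_down = n_down, n_unchanged = n_unchanged,
             n_genes = n_genes,
             fc_up_range = c(2, 21.3), fc_down_range = c(-7.5, -2),
             fc_unchanged_range = c(-1.25, 1.25),
             noise_sd = 0.1, seed = seed, ...)
}
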