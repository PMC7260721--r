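# Independent brute-force oracles, kept deliberately naive.

# Step-up FDR by direct evaluation of min_{j >= i} p_(j) * m / j.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  po <- p[o]
  adj <- vapply(seq_len(m), function(i) {
    min(1, min(po[i:m] * m / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Upper-tail overlap probability by exhaustive enumeration of every
# possible draw of |B| elements from the universe.
hyper_brute <- function(n_a, n_b, n_universe, k_obs) {
  draws <- utils::combn(n_universe, n_b)
  # elements 1..n_a are the "successes"
  hits <- colSums(draws <= n_a)
  mean(hits >= k_obs)
}

# Agreement of two hard clusterings up to label permutation.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Small null-model simulation config (no responders, nothing planted).
null_sim_config <- function(n_genes, seed, studies_per_stress = 1L, ...) {
  simulate_config(n_genes = n_genes, frac_responsive_per_stress = 0,
                  studies_per_stress = studies_per_stress,
                  n_mutant_specific = c(gpa1 = 150L, agb1 = 120L),
                  planted_intersection = c(gpa1 = 0L, agb1 = 0L),
                  seed = seed, ...)
}

# Per-study entries in the layout meta_combine() expects, from a
# simulated compendium.
deg_studies <- function(sim, ...) {
  lapply(sim$datasets, function(d) {
    grp <- stats::setNames(d$sample_info$condition, d$sample_info$sample)
    list(stress = d$stress, study = d$study,
         deg = run_deg(d$matrix, grp, c("stress", "control"), ...))
  })
}
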