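# Shared fixtures, all generated in code.

# small random dosage matrix with optional missingness
random_dosages <- function(n, m, missing_rate = 0, seed = 1,
                           values = c(0, 1, 2)) {
  set.seed(seed)
  g <- matrix(sample(values, n * m, replace = TRUE), n, m,
              dimnames = list(sprintf("L%03d", seq_len(n)),
                              sprintf("M%04d", seq_len(m))))
  if (missing_rate > 0) g[runif(n * m) < missing_rate] <- NA
  g
}

# inbred panel (dosages 0/2) with guaranteed polymorphic markers
random_inbreds <- function(n, m, seed = 1) {
  set.seed(seed)
  repeat {
    g <- matrix(2 * rbinom(n * m, 1, runif(m, 0.2, 0.8)[rep(seq_len(m), each = n)]),
                n, m,
                dimnames = list(sprintf("L%03d", seq_len(n)),
                                sprintf("M%04d", seq_len(m))))
    p <- colMeans(g) / 2
    if (all(p > 0 & p < 1)) return(g)
  }
}

# an additive training problem: hybrids of a simulated panel, trait at h2
sim_training_problem <- function(n_lines = 60, n_markers = 400, n_qtl = 80,
                                 n_hybrids = 300, h2 = 0.8, seed = 11,
                                 groups = c(A = 20, B = 20, C = 20)) {
  cfg <- sim_config(n_lines_per_group = groups, n_markers = n_markers,
                    n_qtl = n_qtl, h2_target = h2, seed = seed)
  st <- simulate_study(cfg, n_hybrids = n_hybrids)
  keep <- filter_hybrid_markers(st$founders, min_rare_allele = 0)$genotypes
  st$hybrids <- st$hybrids[, colnames(keep), drop = FALSE]
  st$founders_kept <- impute_missing(keep)
  st
}

expect_symmetric <- function(m, tol = 1e-10) {
  expect_lt(max(abs(m - t(m))), tol)
}
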