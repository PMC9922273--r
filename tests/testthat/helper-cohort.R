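# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

# a mid-sized cohort exercised by several module tests
small_cohort <- function() {
  if (is.null(.fixtures$coh)) {
    cfg <- sim_config(n_samples = 400, n_variants = 200, n_analytes = 80,
                      cis_effect_dist = "fixed", seed = 2024L)
    .fixtures$coh <- simulate_cohort(cfg)
  }
  .fixtures$coh
}

# independent brute-force Benjamini-Hochberg (step-up, no p.adjust)
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    prev <- min(prev, m / k * p[o[k]])
    adj[o[k]] <- prev
  }
  pmin(adj, 1)
}

# independent greedy clumping oracle (quadratic scan)
brute_clump <- function(p, r2, r2_max) {
  remaining <- order(p)
  kept <- integer(0)
  while (length(remaining)) {
    best <- remaining[1L]
    kept <- c(kept, best)
    remaining <- remaining[r2[remaining, best] <= r2_max]
  }
  sort(kept)
}

# adjusted Rand index between two labelings (via mclust when available)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
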