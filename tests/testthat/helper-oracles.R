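# Independent oracles used across tests. These deliberately avoid the code
# paths they check: explicit loops and from-definition formulas only.

# one-way variance components from definitions (loops, no closed form reuse)
oracle_icc1 <- function(values) {
  n <- nrow(values); k <- ncol(values)
  grand <- mean(values)
  ssb <- 0
  for (i in seq_len(n)) ssb <- ssb + k * (mean(values[i, ]) - grand)^2
  ssw <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(k)) ssw <- ssw + (values[i, j] - mean(values[i, ]))^2
  }
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  (msb - msw) / (msb + (k - 1) * msw)
}

# Benjamini-Hochberg step-up from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (r in m:1) {
    val <- min(prev, p[o[r]] * m / r)
    q[o[r]] <- val
    prev <- val
  }
  pmin(q, 1)
}

# two-way additive ANOVA sums of squares from definitions, one probe
oracle_anova_f <- function(long) {
  arrs <- sort(unique(long$array))
  dons <- sort(unique(long$donor))
  a <- length(arrs); n <- length(dons)
  grand <- mean(long$beta)
  ss_array <- 0
  for (arr in arrs) {
    ss_array <- ss_array + n * (mean(long$beta[long$array == arr]) - grand)^2
  }
  ss_donor <- 0
  for (d in dons) {
    ss_donor <- ss_donor + a * (mean(long$beta[long$donor == d]) - grand)^2
  }
  ss_tot <- sum((long$beta - grand)^2)
  ss_res <- ss_tot - ss_array - ss_donor
  f <- (ss_array / (a - 1)) / (ss_res / ((a - 1) * (n - 1)))
  list(f = f, p = pf(f, a - 1, (a - 1) * (n - 1), lower.tail = FALSE))
}

# strict from-definition cis/trans classifier, one pair at a time
oracle_mqtl_pair <- function(snp_chr, snp_pos, cpg_chr, cpg_pos, p) {
  same <- identical(as.character(snp_chr), as.character(cpg_chr))
  d <- abs(snp_pos - cpg_pos)
  cis <- same && d < 1e6 && p < 1e-8
  trans <- (!same || d > 1e6) && p < 1e-14
  c(cis = cis, trans = trans)
}

# small simulated dataset shared by several test files
tiny_sim <- function(seed = 42, ...) {
  args <- list(n_cpg = 300, n_sex_cpgs = 15, n_probe_replicates = 3,
               clock_sizes = c(8, 12), seed = seed)
  args[names(list(...))] <- list(...)
  simulate_arrays(do.call(sim_config, args))
}

# replicate-free donor-labelled matrices per array, optionally cg- or
# rs-only
donor_matrices <- function(sim, category = NULL) {
  out <- lapply(names(sim$betas), function(arr) {
    B <- as_beta_matrix(sim$betas[[arr]])
    map <- sim$sample_maps[[arr]]
    map <- map[match(colnames(B), map$position_id), ]
    B <- B[, !map$is_replicate, drop = FALSE]
    colnames(B) <- map$donor_id[!map$is_replicate]
    if (!is.null(category)) {
      m <- sim$manifests[[arr]]
      B <- B[m$probe_id[m$category == category], , drop = FALSE]
    }
    B
  })
  names(out) <- names(sim$betas)
  out
}
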