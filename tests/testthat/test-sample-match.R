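test_that("genotype calling applies thresholds with het boundaries", {
  B <- matrix(c(0.02, 0.5, 0.97, 0.25, 0.75, NA), 6, 1,
              dimnames = list(paste0("rs", 1:6), "s1"))
  calls <- call_genotypes(B)
  expect_equal(unname(calls[1:5, 1]), c(0L, 1L, 2L, 1L, 1L))
  expect_true(is.na(calls[6, 1]))
  expect_error(call_genotypes(B, t1 = 0.8, t2 = 0.2), "t1 < t2")
  expect_error(call_genotypes(matrix(1.2, 1, 1, dimnames = list("rs1", "a"))),
               "\\[0, 1\\]")
})

test_that("calls are perfect when noise keeps the genotype modes separated", {
  sim <- tiny_sim(seed = 23, noise_sd = 0.04, n_corrupt_snp_probes = 0)
  snp <- donor_matrices(sim, "rs")
  geno <- as_beta_matrix(sim$truth$snp_genotypes)
  for (arr in names(snp)) {
    calls <- call_genotypes(snp[[arr]])
    expect_equal(unname(calls),
                 unname(2 * geno[rownames(calls), colnames(calls)]),
                 ignore_attr = TRUE)
  }
})

test_that("identical call matrices match to the identity with concordance 1", {
  set.seed(5)
  calls <- matrix(sample(0:2, 40, TRUE), 8, 5,
                  dimnames = list(paste0("rs", 1:8), paste0("d", 1:5)))
  m <- match_samples(list(a = calls, b = calls))
  expect_true(all(m$assignment$assigned))
  expect_equal(m$assignment$matched_donor, m$assignment$donor)
  expect_equal(assignment_accuracy(m)$accuracy, 1)
  self <- m$concordance[m$concordance$sample_a == m$concordance$sample_b, ]
  expect_true(all(self$concordance == 1))
})

test_that("concordance is symmetric in the pair", {
  sim <- tiny_sim(seed = 29)
  snp <- donor_matrices(sim, "rs")
  calls <- lapply(snp, call_genotypes)
  m_ab <- match_samples(calls[c(1, 3)])
  m_ba <- match_samples(calls[c(3, 1)])
  j <- merge(m_ab$concordance, m_ba$concordance,
             by.x = c("sample_a", "sample_b"),
             by.y = c("sample_b", "sample_a"))
  expect_equal(nrow(j), nrow(m_ab$concordance))
  expect_equal(unname(j$concordance.x), unname(j$concordance.y))
})

test_that("corruption breaks beta-based matching and exclusion repairs it", {
  sim <- tiny_sim(seed = 37)
  excl <- recommend_exclusions(detect_snp_mismatches(sim$manifests))
  snp <- donor_matrices(sim, "rs")
  incl <- match_samples(snp, statistic = "beta", donor_maps = NULL)
  excl_m <- match_samples(snp, exclude = excl, statistic = "beta")
  acc_incl <- assignment_accuracy(incl)
  acc_excl <- assignment_accuracy(excl_m)
  expect_lt(acc_incl$accuracy, 1)
  expect_equal(acc_excl$accuracy, 1)
  # the dendrogram shows the same failure: newest-array samples cluster
  # by array, so their nearest older sample is ambiguous or wrong
  expect_lt(mean(cluster_match(incl)$matched), 1)
  expect_equal(mean(cluster_match(excl_m)$matched), 1)
})

test_that("call-based matching is robust to the corruption failure mode", {
  sim <- tiny_sim(seed = 41)
  snp <- donor_matrices(sim, "rs")
  calls <- lapply(snp, call_genotypes)
  m <- match_samples(calls)  # corrupted probes included
  expect_equal(assignment_accuracy(m)$accuracy, 1)
})

test_that("excluding corrupted probes never lowers assignment accuracy", {
  for (seed in c(2, 8)) {
    sim <- tiny_sim(seed = seed)
    excl <- recommend_exclusions(detect_snp_mismatches(sim$manifests))
    for (stat in c("calls", "beta")) {
      by_array <- donor_matrices(sim, "rs")
      if (stat == "calls") by_array <- lapply(by_array, call_genotypes)
      a0 <- assignment_accuracy(match_samples(by_array, statistic = stat))
      a1 <- assignment_accuracy(match_samples(by_array, exclude = excl,
                                              statistic = stat))
      expect_gte(a1$accuracy, a0$accuracy)
    }
  }
})

test_that("noise-free uncorrupted data cluster each donor tightly", {
  sim <- tiny_sim(seed = 3, noise_sd = 0, array_bias_sd = 0,
                  n_corrupt_snp_probes = 0)
  snp <- donor_matrices(sim, "rs")
  m <- match_samples(snp, statistic = "beta")
  cop <- as.matrix(stats::cophenetic(m$hclust))
  ids <- rownames(cop)
  donor <- sub("^.*::", "", ids)
  for (d in unique(donor)) {
    idx <- which(donor == d)
    expect_equal(max(cop[idx, idx]), 0)
  }
})

test_that("matching refuses to run on too few shared probes", {
  calls <- matrix(0L, 3, 4, dimnames = list(paste0("rs", 1:3),
                                            paste0("d", 1:4)))
  expect_error(match_samples(list(a = calls, b = calls)), "shared probes")
})

test_that("a permuted sample is never credited to the wrong donor", {
  # 4-donor toy: donor calls distinct; one newest sample gets donor 2's
  # fingerprint, so it must match donor 2, not its own label
  set.seed(9)
  calls <- matrix(sample(0:2, 4 * 12, TRUE), 12, 4,
                  dimnames = list(paste0("rs", 1:12), paste0("d", 1:4)))
  newest <- calls
  newest[, "d1"] <- calls[, "d2"]
  m <- match_samples(list(old = calls, new = newest))
  a <- m$assignment
  expect_equal(a$matched_donor[a$sample == "d1"], "d2")
  expect_equal(a$matched_donor[a$sample == "d3"], "d3")
})

test_that("the dendrogram exports as newick", {
  sim <- tiny_sim(seed = 29)
  calls <- lapply(donor_matrices(sim, "rs"), call_genotypes)
  m <- match_samples(calls)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_match_newick(m, f)
  phy <- ape::read.tree(f)
  expect_equal(length(phy$tip.label), 90)  # 30 donors x 3 arrays
})
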