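test_that("noise-free sex effects are recovered exactly", {
  sim <- tiny_sim(seed = 51, noise_sd = 0, array_bias_sd = 0)
  mats <- donor_matrices(sim, "cg")
  res <- fit_ewas(mats[[1]], sim$truth$pheno, "sex")
  sexp <- sim$truth$sex_effect_probes$probe_id
  expect_equal(res$effect[match(sexp, res$probe_id)],
               rep(-0.05, length(sexp)), tolerance = 1e-12)
  # sign convention: effect = level 2 minus level 1 of factor(sex) = M - F
})

test_that("constant per-probe array offsets cannot change effect estimates", {
  sim <- tiny_sim(seed = 52, noise_sd = 0, n_corrupt_snp_probes = 0,
                  array_offsets = c(0, 0.04, -0.03), n_probe_replicates = 0)
  mats <- donor_matrices(sim, "cg")
  shared <- sim$truth$shared_cpgs
  # keep probes where no array clips, so the offset stays a pure intercept
  truth <- as_beta_matrix(sim$truth$true_beta)
  mu <- rowMeans(truth)
  keep <- intersect(shared, names(mu)[mu > 0.1 & mu < 0.9])
  res <- lapply(mats, function(B) {
    fit_ewas(B[keep, ], sim$truth$pheno, "sex",
             covariates = c("site", "birthweight"))
  })
  expect_equal(res[[2]]$effect, res[[1]]$effect, tolerance = 1e-10)
  expect_equal(res[[3]]$effect, res[[1]]$effect, tolerance = 1e-10)
})

test_that("OLS effects and t statistics match limma's least squares", {
  skip_if_not_installed("limma")
  sim <- tiny_sim(seed = 53)
  B <- donor_matrices(sim, "cg")[[2]]
  ph <- sim$truth$pheno
  res <- fit_ewas(B, ph, "sex", covariates = c("site", "birthweight"))
  design <- stats::model.matrix(~ factor(sex) + factor(site) + birthweight,
                                data = ph)
  fit <- limma::lmFit(B, design)
  expect_equal(res$effect, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  ols_t <- fit$coefficients[, 2] / (fit$stdev.unscaled[, 2] * fit$sigma)
  expect_equal(res$t_stat, unname(ols_t), tolerance = 1e-8)
})

test_that("a permuted trait yields uniform p-values", {
  sim <- tiny_sim(seed = 54, n_cpg = 2500, n_sex_cpgs = 0,
                  n_probe_replicates = 0, clock_sizes = integer(0))
  B <- donor_matrices(sim, "cg")[[1]]
  ph <- sim$truth$pheno
  set.seed(99)
  ph$sex <- sample(ph$sex)
  res <- fit_ewas(B, ph, "sex", covariates = c("site", "birthweight"))
  ks <- stats::ks.test(res$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("degenerate designs fail with the offending column named", {
  sim <- tiny_sim(seed = 55)
  B <- donor_matrices(sim, "cg")[[1]]
  ph <- sim$truth$pheno
  ph$sexcopy <- ph$sex
  expect_error(fit_ewas(B, ph, "sex", covariates = "sexcopy"), "sexcopy")
  expect_error(fit_ewas(B, ph[1:10, ], "sex"), "appear in")
})

test_that("effect estimates are invariant to affine covariate rescaling", {
  sim <- tiny_sim(seed = 56)
  B <- donor_matrices(sim, "cg")[[1]]
  ph <- sim$truth$pheno
  r1 <- fit_ewas(B, ph, "sex", covariates = "birthweight")
  ph$birthweight <- (ph$birthweight - 3000) / 500
  r2 <- fit_ewas(B, ph, "sex", covariates = "birthweight")
  expect_equal(r2$effect, r1$effect, tolerance = 1e-10)
  expect_equal(r2$p, r1$p, tolerance = 1e-10)
})

test_that("overlap report handles the identity and disjoint extremes", {
  mk <- function(p, ids = paste0("cg", seq_along(p))) {
    structure(tibble::tibble(probe_id = ids, effect = 0.1, se = 0.01,
                             t_stat = 10, p = p, q = p, n_used = 30),
              class = c("meth_ewas", "tbl_df", "tbl", "data.frame"))
  }
  same <- mk(c(1e-10, 1e-10, 0.5))
  conc <- cross_array_overlap(list(a = same, b = same))
  expect_equal(conc$by_threshold$fraction_shared, c(1, 1))

  a <- mk(c(1e-10, 0.5, 0.5, 0.5))
  b <- mk(c(0.5, 0.5, 1e-10, 0.5))
  conc2 <- cross_array_overlap(list(a = a, b = b))
  expect_equal(conc2$by_threshold$fraction_shared, c(0, 0))
  expect_error(cross_array_overlap(list(a = mk(0.5, "x"), b = mk(0.5, "y"))),
               "intersection")
})

test_that("effect comparison counts sign discordance and correlation", {
  ids <- paste0("cg", 1:6)
  mk <- function(effects) {
    tibble::tibble(probe_id = ids, effect = effects, se = 0.01,
                   t_stat = 1, p = 0.5, q = 0.5, n_used = 30)
  }
  e <- c(0.05, -0.02, 0.01, 0.04, -0.03, 0)
  same <- compare_effects(mk(e), mk(e), ids)
  expect_equal(same$pearson_r, 1)
  expect_equal(same$discordant_count, 0)
  flipped <- compare_effects(mk(e), mk(-e), ids)
  expect_equal(flipped$pearson_r, -1)
  expect_equal(flipped$discordant_count, 5)  # the zero effect is excluded
  const <- compare_effects(mk(rep(0.1, 6)), mk(e), ids)
  expect_true(is.na(const$pearson_r))
  expect_error(compare_effects(mk(e), mk(e), ids[1:2]), ">= 3")
})

test_that("cross-array effect agreement strengthens as noise falls", {
  rs <- vapply(c(0.06, 0.02, 0.004), function(ns) {
    sim <- tiny_sim(seed = 57, noise_sd = ns)
    mats <- donor_matrices(sim, "cg")
    shared <- sim$truth$shared_cpgs
    res <- lapply(mats[c(1, 2)], function(B) {
      fit_ewas(collapse_replicate_probes(B)[shared, ], sim$truth$pheno, "sex")
    })
    cor(res[[1]]$effect, res[[2]]$effect)
  }, numeric(1))
  expect_true(all(diff(rs) > 0))
  expect_gt(rs[3], 0.99)
})
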