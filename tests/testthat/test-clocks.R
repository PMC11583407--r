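toy_clock <- function(weights, intercept = 0, transform = "identity",
                      impute = NULL) {
  clock_definition("toy", intercept, weights, transform,
                   impute_values = impute)
}

test_that("clock definitions are validated", {
  expect_error(clock_definition("x", 0, numeric(0)), "non-empty")
  expect_error(clock_definition("x", 0, c(0.1, 0.2)), "named")
  expect_error(clock_definition("x", 0, c(cg1 = 0.1),
                                transform = "horvath-age", adult_age = 0),
               "adult_age")
})

test_that("missing weight accounting follows absolute-weight normalization", {
  w <- c(cg1 = 2, cg2 = -1, cg3 = 1)
  clk <- toy_clock(w)
  none <- missing_weight_share(clk, names(w))
  expect_equal(none$pct_missing_probes, 0)
  expect_equal(none$pct_missing_weight, 0)
  one <- missing_weight_share(clk, c("cg2", "cg3"))
  expect_equal(one$pct_missing_probes, 100 / 3)
  expect_equal(one$pct_missing_weight, 50)  # |2| of |2|+|1|+|1|
  # equal |weights|: k of n missing gives 100 k / n on both metrics
  eq <- toy_clock(setNames(rep(c(1, -1), 5), paste0("cg", 1:10)))
  sh <- missing_weight_share(eq, paste0("cg", 1:7))
  expect_equal(sh$pct_missing_probes, 30)
  expect_equal(sh$pct_missing_weight, 30)
})

test_that("weight shares are invariant to positive rescaling", {
  w <- c(cg1 = 0.5, cg2 = -3, cg3 = 0.1)
  avail <- c("cg1", "cg3")
  a <- missing_weight_share(toy_clock(w), avail)
  b <- missing_weight_share(toy_clock(w * 7), avail)
  expect_equal(a$pct_missing_weight, b$pct_missing_weight)
})

test_that("zero missing weight iff every missing probe has zero weight", {
  clk <- toy_clock(c(cg1 = 1, cg2 = 0, cg3 = 2))
  expect_equal(missing_weight_share(clk, c("cg1", "cg3"))$pct_missing_weight,
               0)
  expect_gt(missing_weight_share(clk, c("cg2", "cg3"))$pct_missing_weight, 0)
})

test_that("age estimation is the transformed linear predictor", {
  B <- matrix(0.5, 1, 2, dimnames = list("cg1", c("s1", "s2")))
  est <- estimate_age(B, toy_clock(c(cg1 = 2), intercept = 10))
  expect_equal(est$estimate, c(11, 11))
  # horvath transform anchors: x = 0 maps to adult_age
  Bz <- matrix(0, 1, 1, dimnames = list("cg1", "s1"))
  esth <- estimate_age(Bz, toy_clock(c(cg1 = 5), transform = "horvath-age"))
  expect_equal(esth$estimate, 20)
})

test_that("imputation policies fill missing clock probes as documented", {
  B <- matrix(c(0.2, 0.6), 2, 1, dimnames = list(c("cg1", "cg2"), "s1"))
  clk <- toy_clock(c(cg1 = 1, cg2 = 1, cg3 = 10), intercept = 0,
                   impute = c(cg1 = 0.2, cg2 = 0.6, cg3 = 0.4))
  drop <- estimate_age(B, clk, impute_policy = "drop")
  expect_equal(drop$estimate, 0.8)
  expect_equal(drop$n_missing, 1)
  zero <- estimate_age(B, clk, impute_policy = "zero")
  expect_equal(zero$estimate, 0.8)
  tm <- estimate_age(B, clk, impute_policy = "training_mean")
  expect_equal(tm$estimate, 0.8 + 10 * 0.4)
  # all probes missing with training means: degenerate closed form
  B2 <- matrix(0.5, 1, 1, dimnames = list("cgX", "s1"))
  allm <- estimate_age(B2, clk, impute_policy = "training_mean")
  expect_equal(allm$estimate, 0.2 + 0.6 + 4)
  expect_error(estimate_age(B2, clk, impute_policy = "drop"), "no clock")
  # per-sample NA falls back to the probe's cohort mean
  B3 <- matrix(c(0.2, 0.4, NA, 0.6), 2, 2,
               dimnames = list(c("cg1", "cg2"), c("s1", "s2")))
  est3 <- estimate_age(B3, toy_clock(c(cg1 = 1, cg2 = 1)),
                       impute_policy = "drop")
  expect_equal(est3$estimate, c(0.2 + 0.4, 0.2 + 0.6))
})

test_that("missing shares propagate into estimates", {
  B <- matrix(0.5, 2, 1, dimnames = list(c("cg1", "cg3"), "s1"))
  clk <- toy_clock(c(cg1 = 1, cg2 = 3, cg3 = -1))
  est <- estimate_age(B, clk, impute_policy = "drop")
  expect_equal(est$pct_missing_probes, 100 / 3)
  expect_equal(est$pct_missing_weight, 60)
})

test_that("clock CSVs round-trip including metadata", {
  clk <- clock_definition("demo", 1.5, c(cg1 = 0.2, cg2 = -0.4),
                          transform = "horvath-age", adult_age = 18,
                          impute_values = c(cg1 = 0.5, cg2 = 0.3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_clock(clk, f)
  back <- read_clock(f)
  expect_equal(back$name, "demo")
  expect_equal(back$intercept, 1.5)
  expect_equal(back$transform, "horvath-age")
  expect_equal(back$adult_age, 18)
  expect_equal(back$weights, clk$weights)
  expect_equal(back$impute_values, clk$impute_values)
})

test_that("a constant shift shows up as the pairwise difference score", {
  est_a <- tibble::tibble(sample_id = paste0("s", 1:10), clock = "c",
                          estimate = 1:10 + 0)
  est_b <- est_a
  est_b$estimate <- est_b$estimate + 2
  cmp <- compare_estimates(list(old = est_a, new = est_b))
  expect_equal(cmp$pairs$pearson_r, 1)
  expect_equal(cmp$pairs$mean_diff, -2)  # earlier minus later
  expect_error(compare_estimates(list(old = est_a[1:2, ], new = est_b[1:2, ])),
               ">= 3")
})

test_that("cross-array agreement degrades as missing clock weight grows", {
  sim <- tiny_sim(seed = 61, clock_sizes = c(10), noise_sd = 0.02)
  clk <- sim$truth$clocks[[1]]
  mats <- donor_matrices(sim)
  A <- mats[[1]]
  ref <- estimate_age(A, clk, impute_policy = "drop")
  shares <- c(); rs <- c()
  for (m in c(0, 2, 4, 6, 8)) {
    Bm <- mats[[2]][setdiff(rownames(mats[[2]]),
                            names(clk$weights)[seq_len(m)]), ]
    est <- estimate_age(Bm, clk, impute_policy = "drop")
    shares <- c(shares, est$pct_missing_weight[1])
    rs <- c(rs, cor(ref$estimate, est$estimate))
  }
  expect_true(all(diff(shares) > 0))
  expect_lt(cor(shares, rs, method = "spearman"), -0.8)
})
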