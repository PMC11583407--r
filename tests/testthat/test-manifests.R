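make_manifest <- function(ids, category = "cg", seq = "ACGTACGT",
                          channel = "Both", next_base = "none") {
  tibble::tibble(
    probe_id = ids, category = category, design_type = "II",
    probe_sequence = seq, color_channel = channel, next_base = next_base,
    chr = "1", pos = seq_along(ids)
  )
}

test_that("manifest parsing accepts canonical and Illumina-style headers", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "m.csv")
  writeLines(c(
    "IlmnID,Category,Infinium_Design_Type,AlleleA_ProbeSeq,Color_Channel,Next_Base,CHR,MAPINFO",
    "cg00000029,cg,II,ACGTACGT,none,none,16,53434200",
    "cg00000108_BC11,cg,I,TTTTACGT,Red,A,3,37417715"
  ), f)
  m <- read_manifest(f)
  expect_equal(nrow(m), 2)
  expect_equal(m$probe_id[1], "cg00000029")
  expect_equal(m$pos[1], 53434200L)
  expect_equal(m$base_id, c("cg00000029", "cg00000108"))
})

test_that("replicate suffixes strip to the locus id", {
  expect_equal(probe_base_id("cg00000029_BC11"), "cg00000029")
  expect_equal(probe_base_id(c("cg1_TC21", "rs12345", "cg2")),
               c("cg1", "rs12345", "cg2"))
})

test_that("malformed manifests fail with the offending detail named", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "empty.csv")
  writeLines("probe_id,category", f)
  expect_error(read_manifest(f))
  expect_error(read_manifest(make_manifest(c("a", "a"))), "duplicate")
  bad <- make_manifest("a")
  bad$color_channel <- NULL
  expect_error(read_manifest(bad), "color_channel")
})

test_that("probe overlap partitions the union across arrays", {
  m1 <- make_manifest(c("cg1", "cg2", "cg3"))
  m2 <- make_manifest(c("cg2", "cg3", "cg4"))
  m3 <- make_manifest(c("cg3", "cg5"))
  ov <- intersect_probes(list(a = m1, b = m2, c = m3))
  expect_equal(sum(ov$n), 5)  # regions partition the union
  expect_setequal(shared_probes(ov), "cg3")

  ident <- intersect_probes(list(a = m1, b = m1))
  expect_equal(shared_probes(ident), m1$probe_id)
  disj <- intersect_probes(list(a = m1, b = make_manifest("cg9")))
  expect_length(shared_probes(disj), 0)
})

test_that("overlap bookkeeping recovers the generator's shared fraction", {
  for (f in c(0.25, 0.6)) {
    sim <- tiny_sim(seed = 2, overlap_fraction = f, n_sex_cpgs = 5,
                    clock_sizes = c(5), n_probe_replicates = 0)
    ov <- intersect_probes(sim$manifests)
    expect_length(shared_probes(ov), round(f * 300))
  }
})

test_that("SNP mismatch detection flags exactly the altered attributes", {
  old <- make_manifest(c("rs1", "rs2", "rs3"), category = "rs",
                       channel = "Red", next_base = "A")
  new <- old
  new$color_channel[2] <- "Grn"  # only the channel changes on rs2
  rep <- detect_snp_mismatches(list(a = old, b = old, c = new))
  expect_equal(sum(rep$bad_metric), 1)
  r2 <- rep[rep$probe_id == "rs2", ]
  expect_true(r2$channel_mismatch)
  expect_false(r2$seq_mismatch)
  expect_false(r2$nextbase_mismatch)

  clean <- detect_snp_mismatches(list(a = old, b = old, c = old))
  expect_equal(sum(clean$bad_metric), 0)
})

test_that("older-array disagreement yields not-comparable, never bad", {
  old1 <- make_manifest("rs1", category = "rs", channel = "Red")
  old2 <- make_manifest("rs1", category = "rs", channel = "Grn")
  new <- make_manifest("rs1", category = "rs", channel = "Both")
  rep <- detect_snp_mismatches(list(a = old1, b = old2, c = new))
  expect_false(rep$comparable)
  expect_false(rep$bad_metric)
})

test_that("synthetic corruption is recovered exactly, across seeds", {
  for (seed in c(1, 7, 19)) {
    sim <- tiny_sim(seed = seed)
    rep <- detect_snp_mismatches(sim$manifests)
    expect_setequal(recommend_exclusions(rep),
                    sim$truth$corrupted_snp_probes)
  }
})

test_that("detection filter applies the strict more-than-20% rule", {
  B <- matrix(0.5, 3, 10,
              dimnames = list(c("p1", "p2", "p3"), paste0("s", 1:10)))
  detp <- matrix(0, 3, 10, dimnames = dimnames(B))
  beads <- matrix(10, 3, 10, dimnames = dimnames(B))
  detp["p2", 1:3] <- 0.5       # fails 30% of samples -> removed
  beads["p3", 1:2] <- 1        # fails exactly 20% -> retained (strict >)
  res <- filter_probes(B, detp, beads)
  expect_equal(res$removed, "p2")
  expect_equal(rownames(res$beta), c("p1", "p3"))

  clean <- filter_probes(B, matrix(0, 3, 10, dimnames = dimnames(B)),
                         matrix(10, 3, 10, dimnames = dimnames(B)))
  expect_length(clean$removed, 0)

  # idempotence
  again <- filter_probes(res$beta, detp[rownames(res$beta), ],
                         beads[rownames(res$beta), ])
  expect_length(again$removed, 0)
  expect_error(filter_probes(B, detp[, 1:5]), "dimensions")
})

test_that("either quality criterion alone can fail a sample", {
  B <- matrix(0.5, 1, 4, dimnames = list("p", paste0("s", 1:4)))
  detp <- matrix(c(0.5, 0, 0, 0), 1, 4, dimnames = dimnames(B))
  beads <- matrix(c(10, 1, 10, 10), 1, 4, dimnames = dimnames(B))
  # 2 of 4 samples fail (one by p, one by beads) = 50% > 20%
  expect_equal(filter_probes(B, detp, beads)$removed, "p")
})

test_that("replicate-probe collapsing follows the requested policy", {
  B <- matrix(c(0.2, 0.4, 0.7), 3, 2,
              dimnames = list(c("cg1_TC11", "cg1_TC21", "cg2"), c("a", "b")))
  m <- collapse_replicate_probes(B, policy = "mean")
  expect_equal(unname(m["cg1", 1]), 0.3)
  expect_equal(unname(m["cg2", 1]), 0.7)
  f <- collapse_replicate_probes(B, policy = "first")
  expect_equal(unname(f["cg1", 1]), 0.2)  # cg1_TC11 sorts first
  # no replicates: identity up to renaming
  B2 <- matrix(0.5, 2, 2, dimnames = list(c("cg1", "cg2"), c("a", "b")))
  expect_equal(collapse_replicate_probes(B2), B2)
  expect_error(collapse_replicate_probes(B, policy = "median"))
})
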