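#' Simulation configuration for a multi-array methylation dataset
#'
#' Builds and validates the configuration for [simulate_arrays()]. Defaults
#' emulate a three-generation array comparison on one cohort: 30 donors
#' (15 female, 15 male, blood drawn around age 5), three array generations
#' measuring the same donors, two donors duplicated on every array as
#' technical replicates, 57 SNP fingerprint probes of which 21 are corrupted
#' on the newest array by a probe-design change (sequence / color channel /
#' next base), and per-probe per-array offsets whose magnitude has median
#' ~0.01 on the beta scale.
#'
#' @param n_samples Number of donors.
#' @param n_cpg Total number of CpG (cg) probes across the probe universe.
#' @param n_snp_probes Number of SNP fingerprint (rs) probes, present on all
#'   arrays.
#' @param n_arrays Number of array generations (the last one is "newest").
#' @param overlap_fraction Fraction of the CpG universe present on every
#'   array; the remainder is split into array-exclusive sets.
#' @param n_shared_replicates Number of donors measured twice on every array.
#' @param array_bias_sd SD of per-probe per-array additive offsets (beta
#'   scale). The default 0.0148 puts the median absolute offset at ~0.01.
#' @param array_offsets Optional numeric vector of length `n_arrays`:
#'   constant per-array offsets applied to every CpG probe instead of random
#'   per-probe offsets (used for bias-recovery experiments).
#' @param noise_sd SD of technical measurement noise (beta scale).
#' @param between_sd SD of person-to-person variation on the logit scale for
#'   ordinary CpGs.
#' @param n_sex_cpgs Number of CpGs carrying a true sex effect.
#' @param sex_effect_size True beta difference (female minus male) at sex
#'   CpGs.
#' @param n_corrupt_snp_probes Number of rs probes whose design differs on
#'   the newest array; their measured betas there read the opposite allele
#'   (beta flipped to 1 - beta), the failure mode of a color-channel swap.
#' @param n_probe_replicates Number of shared CpGs that appear as two
#'   suffixed replicate probes on the newest array (e.g. `cg..._TC11`).
#' @param clock_sizes Integer vector: sizes of the toy clocks built from the
#'   ground truth.
#' @param maf_range Range of minor-allele frequencies for rs probes.
#' @param age_range Donor age range in years (uniform).
#' @param seed Integer seed; one global stream drives all randomness.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 30,
                       n_cpg = 2000,
                       n_snp_probes = 57,
                       n_arrays = 3,
                       overlap_fraction = 0.4,
                       n_shared_replicates = 2,
                       array_bias_sd = 0.0148,
                       array_offsets = NULL,
                       noise_sd = 0.03,
                       between_sd = 0.4,
                       n_sex_cpgs = 50,
                       sex_effect_size = 0.05,
                       n_corrupt_snp_probes = 21,
                       n_probe_replicates = 5,
                       clock_sizes = c(10, 25),
                       maf_range = c(0.2, 0.45),
                       age_range = c(4.6, 5.5),
                       seed = 1L) {
  cfg <- list(
    n_samples = n_samples, n_cpg = n_cpg, n_snp_probes = n_snp_probes,
    n_arrays = n_arrays, overlap_fraction = overlap_fraction,
    n_shared_replicates = n_shared_replicates,
    array_bias_sd = array_bias_sd, array_offsets = array_offsets,
    noise_sd = noise_sd, between_sd = between_sd,
    n_sex_cpgs = n_sex_cpgs, sex_effect_size = sex_effect_size,
    n_corrupt_snp_probes = n_corrupt_snp_probes,
    n_probe_replicates = n_probe_replicates,
    clock_sizes = clock_sizes, maf_range = maf_range,
    age_range = age_range, seed = as.integer(seed)
  )
  counts <- c("n_samples", "n_cpg", "n_snp_probes", "n_arrays",
              "n_shared_replicates", "n_sex_cpgs", "n_corrupt_snp_probes",
              "n_probe_replicates")
  for (f in counts) {
    if (length(cfg[[f]]) != 1 || is.na(cfg[[f]]) || cfg[[f]] < 0) {
      abort(paste0("`", f, "` must be a single non-negative count"))
    }
  }
  if (cfg$n_arrays < 2) abort("`n_arrays` must be >= 2")
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    abort("`overlap_fraction` must be in [0, 1]")
  }
  if (array_bias_sd < 0 || noise_sd < 0 || between_sd < 0) {
    abort("standard deviations must be >= 0")
  }
  if (n_shared_replicates > n_samples) {
    abort("`n_shared_replicates` must not exceed `n_samples`")
  }
  if (!is.null(array_offsets) && length(array_offsets) != n_arrays) {
    abort("`array_offsets` must have one value per array")
  }
  n_shared <- round(overlap_fraction * n_cpg)
  if (n_shared < 2) {
    abort("config rejected: overlap yields fewer than 2 shared CpGs")
  }
  if (n_snp_probes - n_corrupt_snp_probes < 2) {
    abort("config rejected: fewer than 2 SNP probes survive uncorrupted")
  }
  if (n_sex_cpgs + 2 * max(c(0L, clock_sizes)) + n_probe_replicates >
        n_shared) {
    abort("shared CpG pool too small for sex CpGs + clock CpGs + replicate probes")
  }
  structure(cfg, class = "sim_config")
}

array_names <- function(n) {
  if (n == 3) c("450Kstyle", "EPICv1style", "EPICv2style")
  else paste0("array", seq_len(n))
}

random_seq <- function(n, len = 12) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate a multi-array methylation dataset with known ground truth
#'
#' Generates one beta matrix and one probe manifest per array generation,
#' plus the ground truth used to create them. CpG betas follow a bimodal
#' mixture (40% Beta(1,10), 40% Beta(10,1), 20% Beta(2,2) probe means, with
#' logit-normal person-to-person jitter); rs-probe betas sit at the expected
#' genotype fractions {0, 0.5, 1}. Measured beta = clip(true + array offset
#' + technical noise, 0, 1). A configurable number of donors appears twice
#' per array under distinct position ids. On the newest array,
#' `n_corrupt_snp_probes` rs probes carry altered design attributes in the
#' manifest and their betas read the opposite allele (1 - true), and
#' `n_probe_replicates` shared CpGs are split into two suffixed replicate
#' probes.
#'
#' @param config A [sim_config()].
#' @return A `meth_sim` list with elements `betas` (named list of beta
#'   tibbles), `manifests` (named list of manifest tibbles), `sample_maps`
#'   (named list of tibbles: position_id, donor_id, is_replicate), `truth`
#'   (ground-truth list, see Details), and `config`.
#' @details `truth` contains `true_beta` (probes x donors tibble), `pheno`
#'   (donor_id, sex, age and nuisance covariates), `array_offsets` (long
#'   tibble: probe_id, array, offset), `sex_effect_probes`, `age_probes`,
#'   `snp_genotypes` (expected betas), `corrupted_snp_probes`, and `clocks`
#'   (toy [clock_definition()]s fit on the noise-free data).
#' @export
simulate_arrays <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  arrays <- array_names(config$n_arrays)
  newest <- arrays[length(arrays)]
  n <- config$n_samples

  donors <- sprintf("D%02d", seq_len(n))
  sex <- rep(c("F", "M"), length.out = n)
  age <- runif(n, config$age_range[1], config$age_range[2])
  pheno <- tibble(
    donor_id = donors, sex = sex, age = age,
    site = sample(c("A", "B"), n, replace = TRUE),
    birthweight = rnorm(n, 3100, 650),
    gestational_age = rnorm(n, 38.5, 2.6),
    smoking = rbinom(n, 1, 0.35)
  )

  ## ---- probe universe -------------------------------------------------
  cpg_ids <- sprintf("cg%08d", seq_len(config$n_cpg))
  n_shared <- round(config$overlap_fraction * config$n_cpg)
  shared <- cpg_ids[seq_len(n_shared)]
  leftover <- setdiff(cpg_ids, shared)
  excl <- replicate(config$n_arrays, character(0), simplify = FALSE)
  if (length(leftover)) {
    grp <- rep(seq_len(config$n_arrays), length.out = length(leftover))
    for (a in seq_len(config$n_arrays)) excl[[a]] <- leftover[grp == a]
  }
  rs_ids <- sprintf("rs%06d", seq_len(config$n_snp_probes))

  ## special probe sets (all within the shared pool)
  pool <- shared
  sex_probes <- character(0)
  if (config$n_sex_cpgs > 0) {
    sex_probes <- sample(pool, config$n_sex_cpgs)
    pool <- setdiff(pool, sex_probes)
  }
  n_age <- max(c(0L, config$clock_sizes))
  age_probes <- character(0)
  age_probes_horvath <- character(0)
  if (n_age > 0) {
    age_probes <- sample(pool, n_age)
    pool <- setdiff(pool, age_probes)
    age_probes_horvath <- sample(pool, n_age)
    pool <- setdiff(pool, age_probes_horvath)
  }
  rep_probes <- character(0)
  if (config$n_probe_replicates > 0) {
    rep_probes <- sample(pool, config$n_probe_replicates)
  }

  ## ---- true betas ------------------------------------------------------
  comp <- sample(1:3, config$n_cpg, replace = TRUE, prob = c(.4, .4, .2))
  mu <- numeric(config$n_cpg)
  mu[comp == 1] <- rbeta(sum(comp == 1), 1, 10)
  mu[comp == 2] <- rbeta(sum(comp == 2), 10, 1)
  mu[comp == 3] <- rbeta(sum(comp == 3), 2, 2)
  mu <- pmin(0.999, pmax(0.001, mu))
  names(mu) <- cpg_ids

  true_cg <- inv_logit(matrix(logit(mu), config$n_cpg, n) +
                         matrix(rnorm(config$n_cpg * n, 0, config$between_sd),
                                config$n_cpg, n))
  rownames(true_cg) <- cpg_ids
  colnames(true_cg) <- donors

  # sex CpGs: flat baseline in a safe range plus an exact female offset,
  # no person jitter, so the configured delta is recoverable exactly
  if (length(sex_probes)) {
    base_sex <- runif(length(sex_probes), 0.2, 0.7)
    true_cg[sex_probes, ] <-
      matrix(base_sex, length(sex_probes), n) +
      config$sex_effect_size * matrix(rep(sex == "F", each = length(sex_probes)),
                                      length(sex_probes), n)
  }
  # age CpGs: deterministic affine function of age (one pool per clock
  # output scale), slopes well away from 0, bounded so clipping never
  # triggers; the horvath pool is affine in the transformed age so clocks
  # with that output transform can reproduce age exactly
  affine_pool <- function(probes, target) {
    u <- target - mean(target)
    u <- u / max(abs(u))
    ctr <- runif(length(probes), 0.35, 0.65)
    slp <- sample(c(-1, 1), length(probes), TRUE) *
      runif(length(probes), 0.02, 0.06)
    ctr + outer(slp, u)
  }
  if (length(age_probes)) {
    true_cg[age_probes, ] <- affine_pool(age_probes, age)
    true_cg[age_probes_horvath, ] <-
      affine_pool(age_probes_horvath, horvath_forward(age, 20))
  }
  stopifnot(all(true_cg >= 0 & true_cg <= 1))

  ## rs probes: genotypes -> expected betas
  maf <- runif(config$n_snp_probes, config$maf_range[1], config$maf_range[2])
  geno <- matrix(rbinom(config$n_snp_probes * n, 2,
                        rep(maf, n)), config$n_snp_probes, n) / 2
  rownames(geno) <- rs_ids
  colnames(geno) <- donors
  corrupted <- character(0)
  if (config$n_corrupt_snp_probes > 0) {
    corrupted <- sample(rs_ids, config$n_corrupt_snp_probes)
  }

  ## ---- per-array offsets ----------------------------------------------
  offsets <- lapply(seq_along(arrays), function(a) {
    if (!is.null(config$array_offsets)) {
      off <- rep(config$array_offsets[a], config$n_cpg)
    } else if (config$array_bias_sd > 0) {
      off <- rnorm(config$n_cpg, 0, config$array_bias_sd)
    } else {
      off <- rep(0, config$n_cpg)
    }
    names(off) <- cpg_ids
    off
  })
  names(offsets) <- arrays

  ## ---- manifests -------------------------------------------------------
  design_type <- sample(c("I", "II"), config$n_cpg + config$n_snp_probes,
                        replace = TRUE, prob = c(0.3, 0.7))
  all_ids <- c(cpg_ids, rs_ids)
  consensus <- tibble(
    probe_id = all_ids,
    category = c(rep("cg", config$n_cpg), rep("rs", config$n_snp_probes)),
    design_type = design_type,
    probe_sequence = random_seq(length(all_ids)),
    color_channel = ifelse(design_type == "I",
                           sample(c("Red", "Grn"), length(all_ids), TRUE),
                           "Both"),
    next_base = ifelse(design_type == "I",
                       sample(c("A", "C", "G", "T"), length(all_ids), TRUE),
                       "none"),
    chr = as.character(sample(1:22, length(all_ids), TRUE)),
    pos = sample.int(5e7, length(all_ids))
  )

  ## which attribute(s) get corrupted per corrupted probe (>= 1 each)
  corrupt_attrs <- lapply(corrupted, function(p) {
    k <- sample(1:3, 1)
    sample(c("probe_sequence", "color_channel", "next_base"), k)
  })
  names(corrupt_attrs) <- corrupted

  manifests <- lapply(seq_along(arrays), function(a) {
    ids <- c(shared, excl[[a]], rs_ids)
    m <- consensus[match(ids, consensus$probe_id), ]
    if (arrays[a] == newest) {
      for (p in corrupted) {
        i <- match(p, m$probe_id)
        attrs <- corrupt_attrs[[p]]
        if ("probe_sequence" %in% attrs) {
          s <- strsplit(m$probe_sequence[i], "")[[1]]
          s[1] <- setdiff(c("A", "C", "G", "T"), s[1])[1]
          m$probe_sequence[i] <- paste(s, collapse = "")
        }
        if ("color_channel" %in% attrs) {
          m$color_channel[i] <- switch(m$color_channel[i],
                                       Red = "Grn", Grn = "Red", Both = "Red")
        }
        if ("next_base" %in% attrs) {
          nb <- m$next_base[i]
          m$next_base[i] <-
            if (nb == "none") "A" else setdiff(c("A", "C", "G", "T"), nb)[1]
        }
      }
      if (length(rep_probes)) {
        keep <- m$probe_id %in% rep_probes
        dup <- m[keep, ]
        r1 <- dup; r1$probe_id <- paste0(dup$probe_id, "_TC11")
        r2 <- dup; r2$probe_id <- paste0(dup$probe_id, "_TC21")
        m <- bind_rows(m[!keep, ], r1, r2)
      }
    }
    m
  })
  names(manifests) <- arrays

  ## ---- measured betas --------------------------------------------------
  rep_donors <- if (config$n_shared_replicates > 0) {
    sample(donors, config$n_shared_replicates)
  } else character(0)

  sample_maps <- lapply(arrays, function(arr) {
    tibble(
      position_id = sprintf("%s_P%02d", arr, seq_len(n + length(rep_donors))),
      donor_id = c(donors, rep_donors),
      is_replicate = c(rep(FALSE, n), rep(TRUE, length(rep_donors)))
    )
  })
  names(sample_maps) <- arrays

  betas <- lapply(seq_along(arrays), function(a) {
    arr <- arrays[a]
    map <- sample_maps[[arr]]
    pids <- manifests[[arr]]$probe_id
    base <- probe_base_id(pids)
    truth_rows <- rbind(true_cg, geno)[base, , drop = FALSE]
    M <- truth_rows[, map$donor_id, drop = FALSE]
    is_cg <- base %in% cpg_ids
    M[is_cg, ] <- M[is_cg, ] + offsets[[a]][base[is_cg]]
    if (arr == newest && length(corrupted)) {
      flip <- base %in% corrupted
      M[flip, ] <- 1 - M[flip, ]
    }
    if (config$noise_sd > 0) {
      M <- M + matrix(rnorm(length(M), 0, config$noise_sd), nrow(M), ncol(M))
    }
    M <- clip01(M)
    rownames(M) <- pids
    colnames(M) <- map$position_id
    as_beta_tibble(M)
  })
  names(betas) <- arrays

  truth <- structure(list(
    true_beta = as_beta_tibble(true_cg),
    pheno = pheno,
    array_offsets = purrr::map_dfr(arrays, function(arr) {
      tibble(probe_id = cpg_ids, array = arr, offset = unname(offsets[[arr]]))
    }),
    sex_effect_probes = tibble(probe_id = sex_probes,
                               delta = rep(config$sex_effect_size,
                                           length(sex_probes))),
    age_probes = age_probes,
    age_probes_horvath = age_probes_horvath,
    snp_genotypes = as_beta_tibble(geno),
    corrupted_snp_probes = corrupted,
    shared_cpgs = shared,
    replicate_donors = rep_donors,
    clocks = list()
  ), class = "meth_truth")

  sim <- structure(list(betas = betas, manifests = manifests,
                        sample_maps = sample_maps, truth = truth,
                        config = config), class = "meth_sim")
  if (length(config$clock_sizes)) {
    trans <- rep(c("identity", "horvath-age"),
                 length.out = length(config$clock_sizes))
    sim$truth$clocks <- purrr::map2(
      config$clock_sizes, trans,
      function(k, tr) generate_clock(k, sim$truth, transform = tr)
    )
    names(sim$truth$clocks) <- paste0("toyclock", seq_along(config$clock_sizes))
  }
  sim
}

#' @export
print.meth_sim <- function(x, ...) {
  cat("Simulated multi-array methylation dataset\n")
  cat("  arrays:", paste(names(x$betas), collapse = ", "), "\n")
  cat("  donors:", x$config$n_samples,
      "(+", x$config$n_shared_replicates, "replicate positions/array)\n")
  cat("  CpG probes:", x$config$n_cpg,
      "| SNP probes:", x$config$n_snp_probes,
      "(", length(x$truth$corrupted_snp_probes), "corrupted on newest )\n")
  invisible(x)
}

#' Construct a toy clock that recovers donor age from the noise-free data
#'
#' Selects probes from the generator's designated age-dependent CpGs (the
#' pool matching the requested output transform) and solves for intercept
#' and weights analytically: each such probe is an exact affine function of
#' the (transformed) age, `b_i = c_i + s_i * (y - mean(y))`, so the weights
#' `w_i = 1 / (k * s_i)` with intercept `mean(y) - sum(c_i / s_i) / k`
#' reproduce the target exactly while spreading weight across all k probes.
#' The achieved maximum absolute residual on the noise-free data is
#' attached as attribute `max_resid` (numerically zero).
#'
#' @param n_cpgs Number of clock CpGs (must not exceed the number of
#'   designated age probes, which is bounded by the shared CpG pool, and
#'   must be below the number of samples).
#' @param truth Ground-truth list from [simulate_arrays()].
#' @param transform `"identity"` or `"horvath-age"`.
#' @param adult_age Anchor age for the `"horvath-age"` transform; exact age
#'   recovery holds for the generator's anchor of 20.
#' @return A [clock_definition()].
#' @export
generate_clock <- function(n_cpgs, truth, transform = "identity",
                           adult_age = 20) {
  transform <- match.arg(transform, c("identity", "horvath-age"))
  if (n_cpgs < 1) abort("`n_cpgs` must be >= 1")
  pool <- if (transform == "identity") truth$age_probes
          else truth$age_probes_horvath
  if (n_cpgs > length(pool)) {
    abort(paste0("`n_cpgs` exceeds the ", length(pool),
                 " designated age-dependent shared CpGs"))
  }
  probes <- pool[seq_len(n_cpgs)]
  B <- as_beta_matrix(truth$true_beta)[probes, , drop = FALSE]
  n <- ncol(B)
  if (n <= n_cpgs) {
    abort("singular design: need more samples than clock CpGs")
  }
  age <- truth$pheno$age
  y <- if (transform == "identity") age else horvath_forward(age, adult_age)
  yc <- y - mean(y)
  # exact per-probe slope/intercept of beta on centered target
  s <- drop(B %*% yc) / sum(yc^2)
  if (any(abs(s) < 1e-12)) abort("degenerate age probe with zero slope")
  cc <- rowMeans(B)
  k <- length(probes)
  w <- 1 / (k * s)
  intercept <- mean(y) - sum(cc / s) / k
  clk <- clock_definition(
    name = paste0("toy_", transform, "_", n_cpgs),
    intercept = intercept,
    weights = setNames(unname(w), probes),
    transform = transform,
    adult_age = adult_age,
    impute_values = setNames(cc, probes)
  )
  x <- intercept + drop(crossprod(B, w))
  attr(clk, "max_resid") <- max(abs(x - y))
  clk
}

#' Write a simulated dataset to a directory
#'
#' Beta matrices as TSV (probes x sample positions), manifests and sample
#' maps as CSV, phenotypes as CSV, ground truth as CSV/JSON, clocks as clock
#' CSVs.
#'
#' @param sim A `meth_sim` from [simulate_arrays()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (arr in names(sim$betas)) {
    write_beta(sim$betas[[arr]], file.path(dir, paste0("beta_", arr, ".tsv")))
    readr::write_csv(sim$manifests[[arr]],
                     file.path(dir, paste0("manifest_", arr, ".csv")),
                     progress = FALSE)
    readr::write_csv(sim$sample_maps[[arr]],
                     file.path(dir, paste0("samples_", arr, ".csv")),
                     progress = FALSE)
  }
  readr::write_csv(sim$truth$pheno, file.path(dir, "pheno.csv"),
                   progress = FALSE)
  readr::write_tsv(sim$truth$true_beta, file.path(dir, "true_beta.tsv"),
                   progress = FALSE)
  readr::write_csv(sim$truth$array_offsets, file.path(dir, "array_offsets.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(sex_effect_probes = sim$truth$sex_effect_probes,
         corrupted_snp_probes = sim$truth$corrupted_snp_probes,
         replicate_donors = sim$truth$replicate_donors,
         age_probes = sim$truth$age_probes,
         seed = sim$config$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  for (nm in names(sim$truth$clocks)) {
    write_clock(sim$truth$clocks[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  invisible(dir)
}
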