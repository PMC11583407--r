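#' Classify mQTL pairs as cis or trans
#'
#' A SNP-CpG pair is *cis* when the SNP lies on the same chromosome within
#' strictly less than 1 Mb of the CpG with p < 1e-8, and *trans* when the
#' SNP is on a different chromosome or strictly more than 1 Mb away with
#' p < 1e-14. A pair at exactly 1 Mb satisfies neither definition. Per CpG,
#' the class is the union over its pairs: `cis`, `trans`, `both`, or
#' `none`.
#'
#' @param pairs Data frame with columns `snp_chr`, `snp_pos`, `cpg_chr`,
#'   `cpg_pos`, `p` (1-based positions, p in (0, 1]); an optional `cpg_id`
#'   column names the CpG, otherwise `chr:pos` is used. Malformed rows
#'   (missing fields, p outside (0, 1]) are skipped with a message giving
#'   the count.
#' @param cis_window Distance bound in bp (default 1e6).
#' @param cis_p,trans_p Significance bounds (defaults 1e-8, 1e-14).
#' @return Tibble: `cpg_id`, `cpg_chr`, `cpg_pos`, `n_pairs`, `mqtl_class`.
#' @export
classify_mqtl <- function(pairs, cis_window = 1e6, cis_p = 1e-8,
                          trans_p = 1e-14) {
  pairs <- as_tibble(pairs)
  need <- c("snp_chr", "snp_pos", "cpg_chr", "cpg_pos", "p")
  missing <- setdiff(need, names(pairs))
  if (length(missing)) {
    abort(paste0("pairs table missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad <- !complete.cases(pairs[need]) | pairs$p <= 0 | pairs$p > 1 |
    pairs$snp_pos < 1 | pairs$cpg_pos < 1
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    message(sum(bad), " malformed mQTL pair row(s) skipped")
    pairs <- pairs[!bad, , drop = FALSE]
  }
  if (!"cpg_id" %in% names(pairs)) {
    pairs$cpg_id <- paste0(pairs$cpg_chr, ":", pairs$cpg_pos)
  }
  same_chr <- as.character(pairs$snp_chr) == as.character(pairs$cpg_chr)
  dist <- abs(pairs$snp_pos - pairs$cpg_pos)
  is_cis <- same_chr & dist < cis_window & pairs$p < cis_p
  is_trans <- (!same_chr | dist > cis_window) & pairs$p < trans_p
  at_boundary <- same_chr & dist == cis_window
  if (any(at_boundary)) {
    message(sum(at_boundary), " pair(s) at exactly ", cis_window,
            " bp classify as neither cis nor trans")
  }
  pairs |>
    mutate(is_cis = is_cis, is_trans = is_trans) |>
    group_by(.data$cpg_id, .data$cpg_chr, .data$cpg_pos) |>
    summarise(
      n_pairs = dplyr::n(),
      mqtl_class = dplyr::case_when(
        any(is_cis) & any(is_trans) ~ "both",
        any(is_cis) ~ "cis",
        any(is_trans) ~ "trans",
        TRUE ~ "none"
      ),
      .groups = "drop"
    )
}

#' Assemble a per-probe lookup report
#'
#' Left-joins whatever upstream result tables are supplied into one
#' per-probe table keyed on `base_id`; absent stages simply contribute no
#' columns (never fabricated values). Presence flags per array come from
#' the manifests when supplied.
#'
#' @param probe_ids Character vector defining the report rows (base ids).
#' @param manifests Optional named list of manifests (adds `on_<array>`
#'   presence flags).
#' @param reliability Optional named list of `cpg_reliability` tibbles per
#'   array (adds `icc_<array>`, `iqr_<array>`, `informative_<array>`).
#' @param bias Optional `array_bias` tibble.
#' @param mqtl Optional output of [classify_mqtl()] with a `cpg_id` column
#'   matching base ids.
#' @param provenance Optional named list recorded as an attribute (seeds,
#'   versions, decisions).
#' @return A `probe_report` tibble.
#' @export
build_report <- function(probe_ids, manifests = NULL, reliability = NULL,
                         bias = NULL, mqtl = NULL, provenance = list()) {
  if (is.null(manifests) && is.null(reliability) && is.null(bias) &&
      is.null(mqtl)) {
    abort("supply at least one upstream result table")
  }
  rep <- tibble(base_id = probe_ids)
  if (!is.null(manifests)) {
    for (arr in names(manifests)) {
      m <- with_base_id(manifests[[arr]])
      rep[[paste0("on_", arr)]] <- rep$base_id %in% m$base_id
    }
  }
  if (!is.null(reliability)) {
    for (arr in names(reliability)) {
      r <- reliability[[arr]]
      r$base_id <- probe_base_id(r$probe_id)
      r <- r |>
        group_by(.data$base_id) |>
        summarise(icc = mean(.data$icc), iqr = mean(.data$iqr),
                  informative = any(.data$informative), .groups = "drop")
      names(r)[-1] <- paste0(names(r)[-1], "_", arr)
      rep <- left_join(rep, r, by = "base_id")
    }
  }
  if (!is.null(bias)) {
    b <- as_tibble(bias)
    b$base_id <- probe_base_id(b$probe_id)
    unknown <- setdiff(b$base_id, rep$base_id)
    if (length(unknown)) {
      abort(paste0("bias table contains probes outside the report universe: ",
                   paste(utils::head(unknown, 3), collapse = ", ")))
    }
    rep <- left_join(rep, select(b, -"probe_id"), by = "base_id")
  }
  if (!is.null(mqtl)) {
    rep <- left_join(rep,
                     select(rename(mqtl, base_id = "cpg_id"),
                            "base_id", "mqtl_class"),
                     by = "base_id")
  }
  provenance$package_version <- as.character(utils::packageVersion("crossmeth"))
  structure(rep, class = c("probe_report", class(rep)),
            provenance = provenance)
}

#' Write / read a probe report (CSV + JSON-lines)
#'
#' @param report A `probe_report`.
#' @param path CSV path (a `.jsonl` sibling is written alongside).
#' @return `read_report()` returns the tibble.
#' @export
write_report <- function(report, path) {
  readr::write_csv(report, path, progress = FALSE)
  jl <- sub("\\.csv$", ".jsonl", path)
  con <- file(jl, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(report))) {
    writeLines(jsonlite::toJSON(as.list(report[i, ]), auto_unbox = TRUE,
                                digits = NA, na = "null"), con)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes simulate -> manifest harmonization -> reliability -> array bias
#' -> sample matching -> EWAS concordance -> clocks -> report, in
#' dependency order, skipping stages not requested, and writes each stage's
#' outputs under `out_dir`. The configuration can be a YAML file or a list
#' with elements `simulate` (arguments to [sim_config()]) and `stages`
#' (character vector among `"reliability"`, `"bias"`, `"match"`, `"ewas"`,
#' `"clocks"`, `"report"`).
#'
#' @param config YAML path or list.
#' @param out_dir Output directory.
#' @param seed Optional seed overriding the config's.
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(paste0("config file not found: ", config))
    }
    config <- yaml::read_yaml(config)
  }
  stages <- config$stages %||% c("reliability", "bias", "match", "ewas",
                                 "clocks", "report")
  sim_args <- config$simulate %||% list()
  if (!is.null(seed)) sim_args$seed <- seed
  cfg <- do.call(sim_config, sim_args)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " [", ..., "]")
    cat(msg, "\n", file = file.path(out_dir, "pipeline.log"), append = TRUE)
  }
  run_stage <- function(name, expr) {
    log_line(name, " start")
    res <- tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
    log_line(name, " done")
    res
  }

  results <- list()
  sim <- run_stage("simulate", simulate_arrays(cfg))
  write_dataset(sim, file.path(out_dir, "data"))
  results$sim <- sim

  mismatch <- run_stage("annotate", detect_snp_mismatches(sim$manifests))
  overlap <- intersect_probes(sim$manifests)
  readr::write_csv(select(mismatch, -dplyr::any_of("probes")),
                   file.path(out_dir, "snp_mismatch.csv"), progress = FALSE)
  results$mismatch <- mismatch
  results$overlap <- overlap

  no_reps <- lapply(names(sim$betas), function(arr) {
    B <- as_beta_matrix(sim$betas[[arr]])
    map <- sim$sample_maps[[arr]]
    map <- map[match(colnames(B), map$position_id), ]
    B <- B[, !map$is_replicate, drop = FALSE]
    colnames(B) <- map$donor_id[!map$is_replicate]
    B
  })
  names(no_reps) <- names(sim$betas)
  cg_only <- lapply(names(no_reps), function(arr) {
    m <- sim$manifests[[arr]]
    no_reps[[arr]][m$probe_id[m$category == "cg"], , drop = FALSE]
  })
  names(cg_only) <- names(no_reps)

  if ("reliability" %in% stages) {
    rel <- run_stage("reliability", {
      out <- lapply(names(sim$betas), function(arr) {
        m <- sim$manifests[[arr]]
        B <- as_beta_matrix(sim$betas[[arr]])
        reliability_table(B[m$probe_id[m$category == "cg"], , drop = FALSE],
                          sim$sample_maps[[arr]])
      })
      names(out) <- names(sim$betas)
      out
    })
    for (arr in names(rel)) {
      readr::write_csv(rel[[arr]],
                       file.path(out_dir, paste0("reliability_", arr, ".csv")),
                       progress = FALSE)
    }
    results$reliability <- rel
  }

  if ("bias" %in% stages) {
    bias <- run_stage("bias", array_bias(cg_only))
    readr::write_csv(bias, file.path(out_dir, "array_bias.csv"),
                     progress = FALSE)
    results$bias <- bias
  }

  if ("match" %in% stages) {
    match_res <- run_stage("match", {
      snp <- lapply(names(no_reps), function(arr) {
        m <- sim$manifests[[arr]]
        no_reps[[arr]][m$probe_id[m$category == "rs"], , drop = FALSE]
      })
      names(snp) <- names(no_reps)
      calls <- lapply(snp, call_genotypes)
      match_samples(calls, exclude = recommend_exclusions(mismatch))
    })
    readr::write_csv(match_res$assignment,
                     file.path(out_dir, "sample_match.csv"), progress = FALSE)
    write_match_newick(match_res, file.path(out_dir, "sample_match.nwk"))
    results$match <- match_res
  }

  if ("ewas" %in% stages) {
    ew <- run_stage("ewas", {
      shared <- shared_probes(overlap)
      res <- lapply(names(cg_only), function(arr) {
        B <- collapse_replicate_probes(cg_only[[arr]])
        fit_ewas(B[intersect(shared, rownames(B)), , drop = FALSE],
                 sim$truth$pheno, trait = "sex",
                 covariates = c("site", "birthweight"))
      })
      names(res) <- names(cg_only)
      res
    })
    conc <- cross_array_overlap(ew)
    for (arr in names(ew)) {
      readr::write_csv(ew[[arr]],
                       file.path(out_dir, paste0("ewas_", arr, ".csv")),
                       progress = FALSE)
    }
    jsonlite::write_json(conc$by_threshold,
                         file.path(out_dir, "ewas_concordance.json"),
                         auto_unbox = TRUE, digits = NA)
    results$ewas <- ew
    results$concordance <- conc
  }

  if ("clocks" %in% stages && length(sim$truth$clocks)) {
    est <- run_stage("clocks", {
      purrr::map_dfr(names(sim$betas), function(arr) {
        purrr::map_dfr(sim$truth$clocks, function(clk) {
          mutate(estimate_age(no_reps[[arr]], clk), array = arr)
        })
      })
    })
    readr::write_csv(est, file.path(out_dir, "clock_estimates.csv"),
                     progress = FALSE)
    results$clock_estimates <- est
    results$clock_comparison <- compare_estimates(est)
  }

  if ("report" %in% stages) {
    rep <- run_stage("report", {
      build_report(
        probe_ids = sort(unique(unlist(lapply(sim$manifests, function(m) {
          probe_base_id(m$probe_id[m$category == "cg"])
        })))),
        manifests = sim$manifests,
        reliability = results$reliability,
        bias = results$bias,
        provenance = list(seed = cfg$seed, stages = stages)
      )
    })
    write_report(rep, file.path(out_dir, "probe_report.csv"))
    results$report <- rep
  }
  invisible(results)
}
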