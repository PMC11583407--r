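#' Define a linear epigenetic clock
#'
#' A clock is an intercept plus signed per-CpG weights, optionally followed
#' by a nonlinear output transform. The `"horvath-age"` transform maps the
#' linear predictor x to age as `(1 + a) * exp(x) - 1` for `x < 0` and
#' `(1 + a) * x + a` otherwise, with anchor age `a = adult_age`.
#'
#' @param name Clock name.
#' @param intercept Intercept of the linear predictor.
#' @param weights Named numeric vector, probe id -> signed weight.
#' @param transform `"identity"` or `"horvath-age"`.
#' @param adult_age Anchor age for `"horvath-age"` (must be > 0).
#' @param impute_values Optional named numeric vector of training-mean betas
#'   for imputation of missing probes.
#' @return A `clock_definition` list.
#' @export
clock_definition <- function(name, intercept, weights,
                             transform = c("identity", "horvath-age"),
                             adult_age = 20, impute_values = NULL) {
  transform <- match.arg(transform)
  if (!length(weights)) abort("`weights` must be non-empty")
  if (is.null(names(weights)) || any(names(weights) == "")) {
    abort("`weights` must be named by probe id")
  }
  if (transform == "horvath-age" && adult_age <= 0) {
    abort("`adult_age` must be > 0")
  }
  structure(list(name = name, intercept = intercept, weights = weights,
                 transform = transform, adult_age = adult_age,
                 impute_values = impute_values),
            class = "clock_definition")
}

#' @export
print.clock_definition <- function(x, ...) {
  cat("Epigenetic clock '", x$name, "': ", length(x$weights),
      " CpGs, transform ", x$transform, "\n", sep = "")
  invisible(x)
}

horvath_transform <- function(x, adult_age) {
  ifelse(x < 0, (1 + adult_age) * exp(x) - 1, (1 + adult_age) * x + adult_age)
}

horvath_forward <- function(age, adult_age) {
  ifelse(age < adult_age,
         log((age + 1) / (adult_age + 1)),
         (age - adult_age) / (adult_age + 1))
}

apply_transform <- function(x, clock) {
  switch(clock$transform,
         identity = x,
         `horvath-age` = horvath_transform(x, clock$adult_age))
}

#' Read / write a clock coefficient CSV
#'
#' The CSV holds columns `probe_id`, `weight`, preceded by metadata header
#' lines `#name`, `#intercept`, `#transform`, `#adult_age` and optionally a
#' third column `impute_value`.
#'
#' @param path File path.
#' @return `read_clock()` returns a [clock_definition()].
#' @export
read_clock <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (l in meta_lines) {
    kv <- strsplit(sub("^#", "", l), "[=,:] *")[[1]]
    meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  body <- readr::read_csv(I(grep("^#", lines, invert = TRUE, value = TRUE)),
                          show_col_types = FALSE, progress = FALSE)
  if (!all(c("probe_id", "weight") %in% names(body))) {
    abort("clock CSV needs columns probe_id, weight")
  }
  clock_definition(
    name = meta$name %||% basename(path),
    intercept = as.numeric(meta$intercept %||% 0),
    weights = setNames(body$weight, body$probe_id),
    transform = meta$transform %||% "identity",
    adult_age = as.numeric(meta$adult_age %||% 20),
    impute_values = if ("impute_value" %in% names(body)) {
      setNames(body$impute_value, body$probe_id)
    }
  )
}

#' @param clock A [clock_definition()].
#' @rdname read_clock
#' @export
write_clock <- function(clock, path) {
  hdr <- c(paste0("#name: ", clock$name),
           paste0("#intercept: ", format(clock$intercept, digits = 17)),
           paste0("#transform: ", clock$transform),
           paste0("#adult_age: ", clock$adult_age))
  body <- tibble(probe_id = names(clock$weights),
                 weight = unname(clock$weights))
  if (!is.null(clock$impute_values)) {
    body$impute_value <- unname(clock$impute_values[body$probe_id])
  }
  writeLines(hdr, path)
  suppressWarnings(
    utils::write.table(body, path, append = TRUE, sep = ",",
                       row.names = FALSE, quote = FALSE)
  )
  invisible(path)
}

#' Share of clock probes and clock weight missing from an array
#'
#' Normalizes the absolute values of the clock's weights to sum to 100%
#' and reports (1) the percentage of clock CpGs absent from `available`
#' and (2) the percentage of the normalized weight mass those missing CpGs
#' carry. Absolute values are used because clock weights are signed and only
#' |w| yields shares that are non-negative and sum to 100. Both values are
#' returned unrounded.
#'
#' @param clock A [clock_definition()].
#' @param available Character vector of probe (base) ids present on the
#'   array.
#' @return Named list: `pct_missing_probes`, `pct_missing_weight`,
#'   `n_missing`, `missing` (probe ids).
#' @export
missing_weight_share <- function(clock, available) {
  probes <- names(clock$weights)
  missing <- setdiff(probes, probe_base_id(available))
  w <- abs(clock$weights)
  total <- sum(w)
  list(
    pct_missing_probes = 100 * length(missing) / length(probes),
    pct_missing_weight = if (total == 0) 0 else
      100 * sum(w[missing]) / total,
    n_missing = length(missing),
    missing = missing
  )
}

#' Estimate epigenetic age from a beta matrix
#'
#' Computes the clock's linear predictor per sample and applies the output
#' transform. Probes absent from the matrix are handled per
#' `impute_policy`: `"training_mean"` substitutes the clock's stored
#' training means (falls back to an error if the clock carries none),
#' `"cohort_mean"` (default) substitutes the probe's mean across the
#' supplied samples — which for a missing probe is undefined and therefore
#' also falls back to dropping the term — `"zero"` substitutes 0, `"drop"`
#' omits the term. Per-sample missing betas (NA) follow the same policy
#' using the cohort mean of that probe.
#'
#' @param beta Beta tibble or matrix (probes x samples); EPICv2-style
#'   replicate probes are matched on `base_id` (collapsed by mean).
#' @param clock A [clock_definition()].
#' @param impute_policy One of `"cohort_mean"`, `"training_mean"`,
#'   `"zero"`, `"drop"`.
#' @return A `clock_estimate` tibble: `sample_id`, `clock`, `estimate`,
#'   `n_missing`, `pct_missing_probes`, `pct_missing_weight`,
#'   `impute_policy`.
#' @export
estimate_age <- function(beta, clock,
                         impute_policy = c("cohort_mean", "training_mean",
                                           "zero", "drop")) {
  impute_policy <- match.arg(impute_policy)
  B <- as_beta_matrix(beta)
  B <- collapse_replicate_probes(B)
  probes <- names(clock$weights)
  present <- intersect(probes, rownames(B))
  full_impute <- impute_policy == "training_mean" &&
    !is.null(clock$impute_values) &&
    all(probes %in% names(clock$impute_values))
  if (!length(present) && !full_impute) {
    abort("no clock probes present in `beta`")
  }
  mws <- missing_weight_share(clock, rownames(B))
  missing <- mws$missing

  sub <- B[present, , drop = FALSE]
  # per-sample NAs: replace by the probe's cohort mean
  if (anyNA(sub)) {
    rm <- rowMeans(sub, na.rm = TRUE)
    idx <- which(is.na(sub), arr.ind = TRUE)
    sub[idx] <- rm[idx[, 1]]
  }
  x <- clock$intercept + drop(crossprod(sub, clock$weights[present]))
  if (length(missing)) {
    fill <- switch(impute_policy,
      training_mean = {
        if (is.null(clock$impute_values) ||
            !all(missing %in% names(clock$impute_values))) {
          abort("clock carries no training means for the missing probes")
        }
        sum(clock$weights[missing] * clock$impute_values[missing])
      },
      cohort_mean = 0,   # no cohort values exist for an absent probe
      zero = 0,
      drop = 0
    )
    x <- x + fill
  }
  est <- unname(apply_transform(x, clock))
  out <- tibble(
    sample_id = colnames(B),
    clock = clock$name,
    estimate = est,
    n_missing = mws$n_missing,
    pct_missing_probes = mws$pct_missing_probes,
    pct_missing_weight = mws$pct_missing_weight,
    impute_policy = impute_policy
  )
  structure(out, class = c("clock_estimate", class(out)))
}

#' Compare epigenetic age estimates across arrays
#'
#' For every clock and every array pair, the Pearson correlation over
#' shared samples and per-sample difference scores (earlier-generation
#' estimate minus later, reading array order left to right).
#'
#' @param estimates Named list (array name -> `clock_estimate` tibble,
#'   ordered oldest to newest) or a single tibble with an `array` column.
#' @return A `clock_comparison` list: `pairs` (tibble: clock, array_a,
#'   array_b, pearson_r, mean_diff, sd_diff, n), `differences` (per-sample
#'   tibble with `difference = estimate_a - estimate_b`).
#' @export
compare_estimates <- function(estimates) {
  if (is.data.frame(estimates)) {
    stopifnot("array" %in% names(estimates))
    estimates <- split(estimates, estimates$array)
  }
  arrays <- names(estimates)
  pairs <- utils::combn(length(arrays), 2)
  diffs <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- arrays[pairs[1, j]]; b <- arrays[pairs[2, j]]
    inner_join(estimates[[a]], estimates[[b]],
               by = c("sample_id", "clock"), suffix = c("_a", "_b")) |>
      mutate(array_a = a, array_b = b,
             difference = .data$estimate_a - .data$estimate_b)
  })
  summ <- diffs |>
    group_by(.data$clock, .data$array_a, .data$array_b) |>
    summarise(
      n = dplyr::n(),
      pearson_r = if (dplyr::n() >= 3 && sd(.data$estimate_a) > 0 &&
                        sd(.data$estimate_b) > 0)
        cor(.data$estimate_a, .data$estimate_b) else NA_real_,
      mean_diff = mean(.data$difference),
      sd_diff = sd(.data$difference),
      .groups = "drop"
    )
  if (any(summ$n < 3)) abort("need >= 3 shared samples per array pair")
  structure(list(pairs = summ, differences = diffs),
            class = "clock_comparison")
}
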