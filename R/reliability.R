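#' One-way random-effects intraclass correlation, ICC(1)
#'
#' Computes ICC(1) = (MSB - MSW) / (MSB + (k - 1) MSW) from the one-way
#' ANOVA decomposition over subjects, where each subject contributes k
#' technical replicate measurements. The estimate is returned unclipped:
#' negative values (within-subject variance exceeding between-subject
#' variance) are legitimate and kept so the empirical ICC distribution can
#' be examined. When the denominator is exactly zero (all values identical)
#' the ICC is undefined and `NA` is returned.
#'
#' @param values Numeric matrix, subjects in rows and replicates in columns
#'   (balanced: equal replicate count per subject), or a list of equal-length
#'   numeric vectors.
#' @return A single numeric ICC (may be negative), or `NA`.
#' @export
compute_icc <- function(values) {
  if (is.list(values) && !is.data.frame(values)) {
    lens <- lengths(values)
    if (length(unique(lens)) != 1) {
      abort("unbalanced design: all subjects need the same replicate count")
    }
    values <- do.call(rbind, values)
  }
  values <- as.matrix(values)
  if (anyNA(values)) {
    abort("unbalanced design: missing values not allowed (balanced ICC(1))")
  }
  n <- nrow(values)
  k <- ncol(values)
  if (n < 2) abort("need >= 2 subjects")
  if (k < 2) abort("need >= 2 replicates per subject")
  subj_means <- rowMeans(values)
  grand <- mean(values)
  ssb <- k * sum((subj_means - grand)^2)
  ssw <- sum((values - subj_means)^2)
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  denom <- msb + (k - 1) * msw
  if (denom == 0) return(NA_real_)
  (msb - msw) / denom
}

#' Interquartile range of per-probe betas
#'
#' Q3 - Q1 with linear interpolation between order statistics (type-7
#' quantiles, the R default). Callers should exclude technical replicates so
#' the spread reflects between-person variability.
#'
#' @param betas Numeric vector of beta values for one probe across samples.
#' @param min_n Minimum number of non-missing values (default 4); below
#'   this, `NA` is returned.
#' @return A single numeric IQR (>= 0), or `NA`.
#' @export
compute_iqr <- function(betas, min_n = 4) {
  betas <- betas[!is.na(betas)]
  if (length(betas) < min_n) return(NA_real_)
  q <- quantile(betas, c(0.25, 0.75), names = FALSE, type = 7)
  q[2] - q[1]
}

#' Per-probe reliability table for one array
#'
#' Combines replicate-based ICC(1) with the between-person IQR, and flags
#' probes as informative when ICC > `icc_thresh` and IQR > `iqr_thresh`
#' (both strict). ICC uses the donors measured more than once on the array;
#' IQR uses each donor's first (non-replicate) position only.
#'
#' @param beta Beta tibble or matrix for one array (probes x positions).
#' @param sample_map Tibble with `position_id`, `donor_id`, `is_replicate`
#'   mapping positions to donors.
#' @param icc_thresh,iqr_thresh Informative thresholds (strict `>`).
#' @return A `cpg_reliability` tibble: `probe_id`, `icc`, `iqr`,
#'   `informative`, `n_subjects`, `n_reps`.
#' @export
reliability_table <- function(beta, sample_map, icc_thresh = 0.5,
                              iqr_thresh = 0.01) {
  B <- as_beta_matrix(beta)
  missing_pos <- setdiff(colnames(B), sample_map$position_id)
  if (length(missing_pos)) {
    abort(paste0("positions absent from sample_map: ",
                 paste(utils::head(missing_pos, 3), collapse = ", ")))
  }
  map <- sample_map[match(colnames(B), sample_map$position_id), ]
  dup_donors <- unique(map$donor_id[duplicated(map$donor_id)])
  if (length(dup_donors) < 2) {
    abort("need >= 2 donors with replicate measurements for ICC")
  }
  reps <- lapply(dup_donors, function(d) which(map$donor_id == d))
  k <- unique(lengths(reps))
  if (length(k) != 1) {
    abort("unbalanced replicate design: subset donors to equal counts first")
  }
  # one-way ANOVA decomposition vectorized across probes
  n_subj <- length(reps)
  rep_cols <- unlist(reps)
  subj_means <- vapply(reps, function(idx) {
    rowMeans(B[, idx, drop = FALSE])
  }, numeric(nrow(B)))
  grand <- rowMeans(B[, rep_cols, drop = FALSE])
  ssb <- k * rowSums((subj_means - grand)^2)
  ssw <- rowSums(vapply(seq_along(reps), function(j) {
    rowSums((B[, reps[[j]], drop = FALSE] - subj_means[, j])^2)
  }, numeric(nrow(B))))
  msb <- ssb / (n_subj - 1)
  msw <- ssw / (n_subj * (k - 1))
  denom <- msb + (k - 1) * msw
  icc <- ifelse(denom == 0, NA_real_, (msb - msw) / denom)

  primary <- !map$is_replicate
  iqr <- apply(B[, primary, drop = FALSE], 1, compute_iqr)

  out <- tibble(
    probe_id = rownames(B),
    icc = icc,
    iqr = unname(iqr),
    n_subjects = length(dup_donors),
    n_reps = k
  )
  out <- classify_informative(out, icc_thresh, iqr_thresh)
  structure(out, class = c("cpg_reliability", class(out)))
}

#' Flag informative probes
#'
#' A probe is informative when it is reliable (ICC strictly above
#' `icc_thresh`) and shows measurable between-person variability (IQR
#' strictly above `iqr_thresh`). Probes with missing ICC or IQR are not
#' informative.
#'
#' @param table Tibble with `icc` and `iqr` columns.
#' @param icc_thresh,iqr_thresh Strict thresholds (defaults 0.5 and 0.01).
#' @return The table with an `informative` logical column; the per-table
#'   count is attached as attribute `n_informative`.
#' @export
classify_informative <- function(table, icc_thresh = 0.5, iqr_thresh = 0.01) {
  if (!all(c("icc", "iqr") %in% names(table))) {
    abort("`table` must have `icc` and `iqr` columns")
  }
  table$informative <- !is.na(table$icc) & !is.na(table$iqr) &
    table$icc > icc_thresh & table$iqr > iqr_thresh
  attr(table, "n_informative") <- sum(table$informative)
  table
}
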