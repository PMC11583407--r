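#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname tidiers
#' @title Broom-style tidiers for crossmeth result objects
#' @description `tidy()` returns the per-probe (or per-pair) tibble;
#'   `glance()` returns a one-row summary.
#' @param x A crossmeth result object.
#' @param ... Unused.
#' @export
tidy.meth_ewas <- function(x, ...) as_tibble(x)

#' @rdname tidiers
#' @export
glance.meth_ewas <- function(x, ...) {
  tibble(
    n_probes = nrow(x),
    n_sig_q05 = sum(x$q < 0.05, na.rm = TRUE),
    n_sig_p1e8 = sum(x$p < 1e-8, na.rm = TRUE),
    median_abs_effect = median(abs(x$effect), na.rm = TRUE),
    df_resid = attr(x, "df_resid"),
    method = attr(x, "method")
  )
}

#' @rdname tidiers
#' @export
tidy.array_bias <- function(x, ...) as_tibble(x)

#' @rdname tidiers
#' @param sig_q,big_diff Passed to [summarize_bias()].
#' @export
glance.array_bias <- function(x, sig_q = 0.05, big_diff = 0.05, ...) {
  summarize_bias(x, sig_q = sig_q, big_diff = big_diff)
}

#' @rdname tidiers
#' @export
tidy.cpg_reliability <- function(x, ...) as_tibble(x)

#' @rdname tidiers
#' @export
glance.cpg_reliability <- function(x, ...) {
  tibble(
    n_probes = nrow(x),
    median_icc = median(x$icc, na.rm = TRUE),
    median_iqr = median(x$iqr, na.rm = TRUE),
    n_informative = sum(x$informative, na.rm = TRUE)
  )
}

#' @rdname tidiers
#' @export
tidy.sample_match <- function(x, ...) x$concordance

#' @rdname tidiers
#' @export
glance.sample_match <- function(x, ...) {
  acc <- assignment_accuracy(x)
  tibble(
    n_newest_samples = acc$n,
    n_correct = acc$n_correct,
    accuracy = acc$accuracy,
    n_probes = x$n_probes,
    n_excluded = length(x$excluded),
    statistic = x$statistic
  )
}

#' @rdname tidiers
#' @export
tidy.clock_comparison <- function(x, ...) x$pairs

#' @rdname tidiers
#' @export
glance.clock_comparison <- function(x, ...) {
  x$pairs |>
    group_by(.data$array_a, .data$array_b) |>
    summarise(mean_r = mean(.data$pearson_r, na.rm = TRUE),
              n_clocks = dplyr::n(), .groups = "drop")
}

#' @rdname tidiers
#' @export
tidy.ewas_concordance <- function(x, ...) x$by_threshold

#' @rdname tidiers
#' @export
tidy.probe_overlap <- function(x, ...) {
  tibble(region = x$region, n = x$n)
}
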