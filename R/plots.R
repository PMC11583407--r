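#' @importFrom ggplot2 ggplot aes geom_histogram geom_point geom_vline
#'   geom_hline geom_tile geom_abline facet_wrap labs theme_minimal autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot the per-probe reliability distribution
#'
#' ICC histogram with the good-quality threshold marked, and the IQR
#' distribution on -log10 scale with the measurable-variability threshold.
#'
#' @param object A `cpg_reliability` tibble.
#' @param icc_thresh,iqr_thresh Threshold lines.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cpg_reliability <- function(object, icc_thresh = 0.5,
                                     iqr_thresh = 0.01, ...) {
  df <- tidyr::pivot_longer(
    tibble(icc = object$icc, `-log10(iqr)` = -log10(pmax(object$iqr, 1e-6))),
    dplyr::everything(), names_to = "metric", values_to = "value"
  )
  thr <- tibble(metric = c("icc", "-log10(iqr)"),
                value = c(icc_thresh, -log10(iqr_thresh)))
  ggplot(df, aes(x = .data$value)) +
    geom_histogram(bins = 40, fill = "grey35") +
    geom_vline(data = thr, aes(xintercept = .data$value),
               linetype = "dashed", colour = "red") +
    facet_wrap(~metric, scales = "free") +
    labs(x = NULL, y = "CpG probes",
         title = "Probe reliability: ICC and IQR") +
    theme_minimal()
}

#' Plot per-probe array-bias magnitudes
#'
#' Histogram of the largest absolute pairwise between-array difference per
#' probe (percent DNAm), with the large-bias threshold marked.
#'
#' @param object An `array_bias` tibble.
#' @param big_diff Threshold line (beta scale).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.array_bias <- function(object, big_diff = 0.05, ...) {
  ggplot(tibble(d = 100 * object$max_abs_diff), aes(x = .data$d)) +
    geom_histogram(bins = 50, fill = "grey35") +
    geom_vline(xintercept = 100 * big_diff, linetype = "dashed",
               colour = "red") +
    labs(x = "max |between-array difference| (% DNAm)", y = "CpG probes",
         title = "Array-level bias per probe") +
    theme_minimal()
}

#' Volcano-style view of an EWAS result
#'
#' @param object A `meth_ewas` tibble.
#' @param p_thresh Stringent threshold line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.meth_ewas <- function(object, p_thresh = 1e-8, ...) {
  ggplot(tibble(effect = object$effect,
                mlp = -log10(pmax(object$p, 1e-300))),
         aes(x = .data$effect, y = .data$mlp)) +
    geom_point(alpha = 0.4, size = 0.8) +
    geom_hline(yintercept = -log10(p_thresh), linetype = "dashed",
               colour = "red") +
    labs(x = expression(Delta * beta), y = expression(-log[10](p)),
         title = paste0("EWAS of ", attr(object, "trait") %||% "trait")) +
    theme_minimal()
}

#' Concordance heatmap of cross-array sample matching
#'
#' Newest-array samples against older-array samples; correct matches light
#' up the diagonal blocks.
#'
#' @param object A `sample_match`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sample_match <- function(object, ...) {
  ggplot(object$concordance,
         aes(x = .data$sample_b, y = .data$sample_a,
             fill = .data$concordance)) +
    geom_tile() +
    facet_wrap(~array_b, scales = "free_x") +
    labs(x = "older-array sample", y = "newest-array sample",
         fill = "concordance",
         title = paste0("Sample matching (", object$statistic,
                        " statistic)")) +
    theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Pairwise clock-estimate agreement across arrays
#'
#' Scatter of epigenetic age estimates for each array pair and clock, with
#' the identity line.
#'
#' @param object A `clock_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.clock_comparison <- function(object, ...) {
  ggplot(object$differences,
         aes(x = .data$estimate_a, y = .data$estimate_b)) +
    geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    geom_point(alpha = 0.6, size = 0.9) +
    facet_wrap(~ clock + array_a + array_b, scales = "free",
               labeller = ggplot2::label_wrap_gen(multi_line = FALSE)) +
    labs(x = "earlier-generation estimate (years)",
         y = "later-generation estimate (years)",
         title = "Epigenetic age estimates across arrays") +
    theme_minimal()
}
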