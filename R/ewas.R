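#' Per-probe EWAS of a binary trait with covariates
#'
#' Fits, for every probe, an ordinary least-squares regression of beta on
#' the trait plus covariates; the reported effect is the trait coefficient
#' (difference in mean beta between trait groups, second factor level minus
#' first, holding covariates fixed). p-values come from the t distribution
#' with residual degrees of freedom; q-values are BH-adjusted across probes
#' within the array. All probes share one design matrix, so the fit is a
#' single QR decomposition applied to the whole beta matrix.
#'
#' @param beta Beta tibble or matrix (probes x samples); columns must match
#'   `pheno[[id_col]]`.
#' @param pheno Data frame of per-sample phenotypes.
#' @param trait Name of the binary trait column (factor, character, or
#'   0/1); the effect sign follows the factor level order (last minus
#'   first).
#' @param covariates Character vector of covariate column names (numeric or
#'   two-level).
#' @param id_col Column of `pheno` holding sample ids (default
#'   `"donor_id"`).
#' @return A `meth_ewas` tibble: `probe_id`, `effect`, `se`, `t_stat`, `p`,
#'   `q`, `n_used`.
#' @export
fit_ewas <- function(beta, pheno, trait, covariates = character(0),
                     id_col = "donor_id") {
  B <- as_beta_matrix(beta)
  if (!all(colnames(B) %in% pheno[[id_col]])) {
    abort("all beta columns must appear in `pheno`")
  }
  ph <- pheno[match(colnames(B), pheno[[id_col]]), , drop = FALSE]
  tr <- ph[[trait]]
  if (anyNA(tr)) abort("missing trait values are not allowed")
  if (!is.numeric(tr)) tr <- as.numeric(factor(tr)) - 1
  if (length(unique(tr)) != 2) abort("`trait` must be binary")

  X <- cbind(`(Intercept)` = 1, trait = tr)
  for (cv in covariates) {
    v <- ph[[cv]]
    if (is.null(v)) abort(paste0("covariate not found: ", cv))
    if (!is.numeric(v)) v <- as.numeric(factor(v)) - 1
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p + 1) abort("too few samples for this design")
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    abort(paste0("collinear design; offending column(s): ",
                 paste(bad, collapse = ", ")))
  }
  Y <- t(B)                                  # samples x probes
  coefs <- qr.coef(qrX, Y)                   # p x probes
  resid <- Y - X %*% coefs
  df <- n - p
  sigma2 <- colSums(resid^2) / df
  XtXinv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot),
                                drop = FALSE]
  j <- match("trait", colnames(X))
  se <- sqrt(sigma2 * XtXinv[j, j])
  eff <- coefs[j, ]
  tval <- ifelse(se == 0, ifelse(eff == 0, 0, Inf), eff / se)
  pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  out <- tibble(
    probe_id = rownames(B),
    effect = unname(eff),
    se = unname(se),
    t_stat = unname(tval),
    p = unname(pval),
    q = p.adjust(pval, method = "BH"),
    n_used = n
  )
  structure(out, class = c("meth_ewas", class(out)),
            trait = trait, covariates = covariates, method = "ols",
            df_resid = df)
}

venn_regions <- function(sets) {
  universe <- unique(unlist(sets))
  if (!length(universe)) {
    return(tibble(region = character(0), n = integer(0)))
  }
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  key <- apply(member, 1, function(r) paste(names(sets)[r], collapse = "+"))
  tibble(region = key) |>
    group_by(.data$region) |>
    summarise(n = dplyr::n(), .groups = "drop")
}

#' Cross-array overlap of EWAS hits
#'
#' Restricts all result tables to their common probe universe, then counts,
#' at an FDR threshold and at a stringent p threshold, which probes are
#' significant on which arrays (Venn regions). The "stable across all
#' arrays" fraction uses the union of probes significant on at least one
#' array as denominator.
#'
#' @param results Named list of `meth_ewas` tibbles, one per array.
#' @param q_thresh FDR threshold (default 0.05); q is recomputed within the
#'   shared probe universe.
#' @param p_thresh Stringent p threshold (default 1e-8).
#' @return An `ewas_concordance` list: `by_threshold` (tibble: threshold,
#'   shared_all, union, fraction_shared), `venn` (named list of region
#'   tibbles), `sig_probes` (named list of per-threshold union probe sets),
#'   `probes` (shared universe).
#' @export
cross_array_overlap <- function(results, q_thresh = 0.05, p_thresh = 1e-8) {
  if (is.null(names(results)) || any(names(results) == "")) {
    names(results) <- paste0("array", seq_along(results))
  }
  probes <- Reduce(intersect, lapply(results, function(r) r$probe_id))
  if (!length(probes)) abort("empty probe intersection across results")
  sub <- lapply(results, function(r) {
    r <- r[match(probes, r$probe_id), ]
    r$q <- p.adjust(r$p, method = "BH")   # FDR within the shared universe
    r
  })
  sets_q <- lapply(sub, function(r) r$probe_id[r$q < q_thresh])
  sets_p <- lapply(sub, function(r) r$probe_id[r$p < p_thresh])
  frac <- function(sets) {
    u <- unique(unlist(sets))
    shared <- Reduce(intersect, sets)
    tibble(shared_all = length(shared), union = length(u),
           fraction_shared = if (length(u)) length(shared) / length(u)
                             else NA_real_)
  }
  by_thr <- bind_rows(
    mutate(frac(sets_q), threshold = paste0("q<", q_thresh), .before = 1),
    mutate(frac(sets_p), threshold = paste0("p<", p_thresh), .before = 1)
  )
  structure(list(
    by_threshold = by_thr,
    venn = list(q = venn_regions(sets_q), p = venn_regions(sets_p)),
    sig_probes = list(q = unique(unlist(sets_q)), p = unique(unlist(sets_p))),
    probes = probes,
    thresholds = c(q = q_thresh, p = p_thresh)
  ), class = "ewas_concordance")
}

#' Compare effect estimates between two arrays
#'
#' Pearson correlation of the per-probe effects over a significant probe
#' set, and the probes whose effect signs disagree between the two arrays.
#' Probes with a zero effect on either array are excluded from discordance
#' (a zero is discordant with nothing).
#'
#' @param result_a,result_b `meth_ewas` tibbles.
#' @param sig_probes Probe ids over which to compare (typically probes
#'   passing the stringent threshold on any array); must have >= 3 entries
#'   present in both results.
#' @return List: `pearson_r` (`NA` when an effect vector is constant),
#'   `n_probes`, `discordant` (tibble of discordant probes with both
#'   effects), `discordant_count`, `discordant_fraction`.
#' @export
compare_effects <- function(result_a, result_b, sig_probes) {
  common <- intersect(intersect(result_a$probe_id, result_b$probe_id),
                      sig_probes)
  if (length(common) < 3) abort("need >= 3 shared significant probes")
  ea <- result_a$effect[match(common, result_a$probe_id)]
  eb <- result_b$effect[match(common, result_b$probe_id)]
  r <- if (sd(ea) == 0 || sd(eb) == 0) NA_real_ else cor(ea, eb)
  nonzero <- ea != 0 & eb != 0
  disc <- nonzero & sign(ea) != sign(eb)
  list(
    pearson_r = r,
    n_probes = length(common),
    discordant = tibble(probe_id = common[disc],
                        effect_a = ea[disc], effect_b = eb[disc]),
    discordant_count = sum(disc),
    discordant_fraction = sum(disc) / length(common)
  )
}
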