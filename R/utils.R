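#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn :=
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join bind_rows bind_cols rename distinct across n
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats pf ptukey quantile sd var median p.adjust cor
#'   rnorm runif rbinom rbeta complete.cases setNames hclust as.dist
#'   cophenetic lm.fit pt
NULL

# A beta "matrix" travels through the package as a tibble with a `probe_id`
# column followed by one numeric column per sample position; internally most
# numerics run on a plain matrix (probes x samples).

#' Convert a beta tibble to a numeric matrix
#'
#' @param beta A tibble with a `probe_id` column and numeric sample columns,
#'   or a numeric matrix with probe rownames (returned as-is).
#' @return Numeric matrix, probes in rows (rownames = probe ids), samples in
#'   columns.
#' @export
as_beta_matrix <- function(beta) {
  if (is.matrix(beta)) {
    if (is.null(rownames(beta))) abort("beta matrix must have probe rownames")
    return(beta)
  }
  if (!is.data.frame(beta) || !"probe_id" %in% names(beta)) {
    abort("beta must be a matrix or a data frame with a `probe_id` column")
  }
  m <- as.matrix(beta[setdiff(names(beta), "probe_id")])
  storage.mode(m) <- "double"
  rownames(m) <- beta$probe_id
  m
}

#' Convert a probes-by-samples matrix to a beta tibble
#'
#' @param m Numeric matrix with probe rownames.
#' @return Tibble with `probe_id` plus one column per sample.
#' @export
as_beta_tibble <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  out <- as_tibble(m)
  dplyr::bind_cols(tibble(probe_id = rownames(m)), out)
}

#' Read / write a beta matrix as TSV
#'
#' Probes are rows; the header row carries sample position ids; the first
#' column is `probe_id`.
#'
#' @param path File path.
#' @return `read_beta()` returns a beta tibble.
#' @export
read_beta <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @param beta Beta tibble or matrix.
#' @rdname read_beta
#' @export
write_beta <- function(beta, path) {
  if (is.matrix(beta)) beta <- as_beta_tibble(beta)
  readr::write_tsv(beta, path, progress = FALSE)
  invisible(path)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)  # x first: keeps dim attributes

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# %||% re-exported use
`%||%` <- function(a, b) if (is.null(a)) b else a
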