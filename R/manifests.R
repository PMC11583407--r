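MANIFEST_COLS <- c("probe_id", "category", "design_type", "probe_sequence",
                   "color_channel", "next_base", "chr", "pos")

# Illumina-style CSV headers accepted as aliases
MANIFEST_ALIASES <- c(
  IlmnID = "probe_id", Category = "category",
  Infinium_Design_Type = "design_type", AlleleA_ProbeSeq = "probe_sequence",
  Color_Channel = "color_channel", Next_Base = "next_base",
  CHR = "chr", MAPINFO = "pos"
)

#' Strip the replicate suffix from probe ids
#'
#' Newer array designs carry several physical probes per CpG, distinguished
#' by an underscore-delimited trailing alphanumeric token (e.g.
#' `cg00000029_TC11`). Cross-array joins must happen on the CpG locus, so
#' that token is removed. rs identifiers never carry suffixes but are passed
#' through the same rule for uniformity.
#'
#' @param probe_id Character vector of probe ids.
#' @return Character vector of base ids.
#' @export
probe_base_id <- function(probe_id) {
  sub("_[A-Za-z0-9]+$", "", probe_id)
}

#' Read a probe manifest CSV
#'
#' Accepts either the package's canonical column names (`probe_id`,
#' `category`, `design_type`, `probe_sequence`, `color_channel`,
#' `next_base`, `chr`, `pos`) or the Illumina-style aliases (`IlmnID`,
#' `Category`, `Infinium_Design_Type`, `AlleleA_ProbeSeq`, `Color_Channel`,
#' `Next_Base`, `CHR`, `MAPINFO`). Coordinates are 1-based; the genome build
#' is whatever the manifest declares. A `base_id` column (replicate suffix
#' stripped) is added.
#'
#' @param path CSV file path, or a data frame already holding the columns.
#' @return Manifest tibble with a `base_id` column.
#' @export
read_manifest <- function(path) {
  m <- if (is.data.frame(path)) {
    as_tibble(path)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  hit <- names(m) %in% names(MANIFEST_ALIASES)
  names(m)[hit] <- MANIFEST_ALIASES[names(m)[hit]]
  if (nrow(m) == 0) abort("manifest is empty")
  missing <- setdiff(MANIFEST_COLS, names(m))
  if (length(missing)) {
    abort(paste0("manifest is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(m$probe_id)) {
    abort(paste0("duplicate probe_id in manifest: ",
                 m$probe_id[duplicated(m$probe_id)][1]))
  }
  m$pos <- as.integer(m$pos)
  m$chr <- as.character(m$chr)
  m$base_id <- probe_base_id(m$probe_id)
  dplyr::relocate(m, dplyr::all_of(MANIFEST_COLS), "base_id")
}

with_base_id <- function(m) {
  if (!"base_id" %in% names(m)) m$base_id <- probe_base_id(m$probe_id)
  m
}

#' Venn partition of CpG probes across array manifests
#'
#' Computes, on `base_id` within category `cg`, which probes are exclusive
#' to each array, shared by each subset of arrays, and shared by all. The
#' regions partition the union of all cg probes.
#'
#' @param manifests Named list of >= 2 manifest tibbles (see
#'   [read_manifest()]).
#' @param category Probe category to partition (default `"cg"`).
#' @return A `probe_overlap` tibble with columns `region` (array names
#'   joined by `+`), `n`, and a list-column `probes`.
#' @export
intersect_probes <- function(manifests, category = "cg") {
  if (length(manifests) < 2) abort("need at least 2 manifests")
  if (is.null(names(manifests)) || any(names(manifests) == "")) {
    names(manifests) <- paste0("array", seq_along(manifests))
  }
  sets <- lapply(manifests, function(m) {
    m <- with_base_id(m)
    unique(m$base_id[m$category == category])
  })
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  key <- apply(member, 1, function(r) {
    paste(names(manifests)[r], collapse = "+")
  })
  out <- tibble(region = key, probe = universe) |>
    group_by(.data$region) |>
    summarise(n = dplyr::n(), probes = list(.data$probe), .groups = "drop")
  all_key <- paste(names(manifests), collapse = "+")
  if (!all_key %in% out$region) {
    out <- bind_rows(out, tibble(region = all_key, n = 0L,
                                 probes = list(character(0))))
  }
  out <- arrange(out, dplyr::desc(.data$n))
  structure(out, class = c("probe_overlap", class(out)),
            arrays = names(manifests), shared_all = all_key)
}

#' Probes shared by every array
#'
#' @param overlap A `probe_overlap` from [intersect_probes()].
#' @return Character vector of base ids present on all arrays.
#' @export
shared_probes <- function(overlap) {
  key <- attr(overlap, "shared_all")
  overlap$probes[[match(key, overlap$region)]]
}

#' Detect SNP fingerprint probes whose design changed on the newest array
#'
#' For every rs probe present on the newest array and on at least one older
#' array, the probe sequence, color channel, and next base are compared
#' against the older arrays' consensus. Any disagreement flags the probe
#' (`bad_metric`). Probes absent from all older arrays, or whose older
#' arrays disagree among themselves, are reported `comparable = FALSE` and
#' never flagged.
#'
#' @param manifests Named list of manifests; the last element is taken as
#'   the newest array.
#' @return A `snp_mismatch` tibble with one row per rs probe on the newest
#'   array: presence flags per array, `seq_mismatch`, `channel_mismatch`,
#'   `nextbase_mismatch`, `comparable`, `bad_metric`.
#' @export
detect_snp_mismatches <- function(manifests) {
  if (length(manifests) < 2) abort("need at least 2 manifests")
  if (is.null(names(manifests)) || any(names(manifests) == "")) {
    names(manifests) <- paste0("array", seq_along(manifests))
  }
  manifests <- lapply(manifests, with_base_id)
  newest <- names(manifests)[length(manifests)]
  older <- names(manifests)[-length(manifests)]
  rs_new <- manifests[[newest]] |> filter(.data$category == "rs")
  if (nrow(rs_new) == 0) {
    warn("no rs probes in the newest manifest; empty mismatch report")
  }
  attrs <- c(seq = "probe_sequence", channel = "color_channel",
             nextbase = "next_base")
  rows <- purrr::map_dfr(seq_len(nrow(rs_new)), function(i) {
    bid <- rs_new$base_id[i]
    old_rows <- purrr::map(older, function(a) {
      m <- manifests[[a]]
      m[m$category == "rs" & m$base_id == bid, , drop = FALSE]
    })
    names(old_rows) <- older
    present <- vapply(old_rows, nrow, integer(1)) > 0
    res <- tibble(probe_id = rs_new$probe_id[i], base_id = bid)
    for (a in older) res[[paste0("on_", a)]] <- unname(present[a])
    res[[paste0("on_", newest)]] <- TRUE
    if (!any(present)) {
      res$seq_mismatch <- NA
      res$channel_mismatch <- NA
      res$nextbase_mismatch <- NA
      res$comparable <- FALSE
      res$bad_metric <- FALSE
      return(res)
    }
    flags <- logical(3); names(flags) <- names(attrs)
    consensus_ok <- TRUE
    for (k in names(attrs)) {
      vals <- unlist(lapply(old_rows[present], function(r) r[[attrs[k]]]))
      if (length(unique(vals)) > 1) {
        consensus_ok <- FALSE
        flags[k] <- NA
      } else {
        flags[k] <- !identical(unname(vals[1]), rs_new[[attrs[k]]][i])
      }
    }
    res$seq_mismatch <- flags["seq"]
    res$channel_mismatch <- flags["channel"]
    res$nextbase_mismatch <- flags["nextbase"]
    res$comparable <- consensus_ok
    res$bad_metric <- consensus_ok && any(flags, na.rm = TRUE)
    res
  })
  if (nrow(rs_new) == 0) {
    rows <- tibble(probe_id = character(0), base_id = character(0),
                   seq_mismatch = logical(0), channel_mismatch = logical(0),
                   nextbase_mismatch = logical(0), comparable = logical(0),
                   bad_metric = logical(0))
  }
  structure(rows, class = c("snp_mismatch", class(rows)),
            newest = newest, older = older)
}

#' Detection-based probe filter
#'
#' Removes a probe when the fraction of samples failing quality (detection
#' p above `p_thresh` OR bead count below `bead_thresh`) is strictly greater
#' than `sample_fraction`. The filter is idempotent.
#'
#' @param beta Beta tibble or matrix (probes x samples).
#' @param detection_p,beads Matrices (or beta-shaped tibbles) aligned with
#'   `beta`; either may be `NULL`, in which case that criterion never fails.
#' @param p_thresh Detection-p threshold (fail when p > this).
#' @param bead_thresh Minimum bead count (fail when beads < this).
#' @param sample_fraction Removal requires failing fraction strictly above
#'   this value.
#' @return List with `beta` (filtered, same representation as input) and
#'   `removed` (character vector of probe ids).
#' @export
filter_probes <- function(beta, detection_p = NULL, beads = NULL,
                          p_thresh = 0.01, bead_thresh = 3,
                          sample_fraction = 0.20) {
  was_tibble <- !is.matrix(beta)
  B <- as_beta_matrix(beta)
  fail <- matrix(FALSE, nrow(B), ncol(B))
  check_dim <- function(M, what) {
    M <- as_beta_matrix(M)
    if (!identical(dim(M), dim(B))) {
      abort(paste0("`", what, "` dimensions do not match `beta`"))
    }
    if (!is.null(rownames(M)) && !identical(rownames(M), rownames(B))) {
      M <- M[rownames(B), , drop = FALSE]
    }
    M
  }
  if (!is.null(detection_p)) fail <- fail | (check_dim(detection_p, "detection_p") > p_thresh)
  if (!is.null(beads)) fail <- fail | (check_dim(beads, "beads") < bead_thresh)
  frac <- rowMeans(fail)
  removed <- rownames(B)[frac > sample_fraction]
  kept <- B[!(rownames(B) %in% removed), , drop = FALSE]
  list(beta = if (was_tibble) as_beta_tibble(kept) else kept,
       removed = removed)
}

#' Collapse replicate probes to one row per CpG locus
#'
#' Arrays carrying several physical probes per CpG are reduced to one value
#' per `base_id`.
#'
#' @param beta Beta tibble or matrix.
#' @param manifest Manifest covering `beta`'s probes (used only to validate
#'   coverage; collapsing itself keys on the probe ids).
#' @param policy `"mean"` (default), `"first"` (lexicographically first
#'   probe id), or `"best_detection"` (requires `detection_p`; keeps the
#'   replicate with the lowest mean detection p).
#' @param detection_p Detection-p matrix aligned with `beta`, for
#'   `"best_detection"`.
#' @return Beta tibble/matrix with `base_id`s as probe ids.
#' @export
collapse_replicate_probes <- function(beta, manifest = NULL,
                                      policy = c("mean", "first",
                                                 "best_detection"),
                                      detection_p = NULL) {
  policy <- match.arg(policy)
  was_tibble <- !is.matrix(beta)
  B <- as_beta_matrix(beta)
  if (!is.null(manifest)) {
    manifest <- with_base_id(manifest)
    unknown <- setdiff(rownames(B), manifest$probe_id)
    if (length(unknown)) {
      abort(paste0("probes absent from manifest: ",
                   paste(utils::head(unknown, 3), collapse = ", ")))
    }
  }
  base <- probe_base_id(rownames(B))
  if (!anyDuplicated(base)) {
    rownames(B) <- base
    return(if (was_tibble) as_beta_tibble(B) else B)
  }
  groups <- split(seq_len(nrow(B)), base)
  out <- matrix(NA_real_, length(groups), ncol(B),
                dimnames = list(names(groups), colnames(B)))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    if (length(idx) == 1) {
      out[g, ] <- B[idx, ]
    } else if (policy == "mean") {
      out[g, ] <- colMeans(B[idx, , drop = FALSE])
    } else if (policy == "first") {
      out[g, ] <- B[idx[order(rownames(B)[idx])][1], ]
    } else {
      if (is.null(detection_p)) {
        abort("policy 'best_detection' requires `detection_p`")
      }
      D <- as_beta_matrix(detection_p)
      out[g, ] <- B[idx[which.min(rowMeans(D[idx, , drop = FALSE]))], ]
    }
  }
  if (was_tibble) as_beta_tibble(out) else out
}

#' Probes recommended for exclusion before sample matching
#'
#' Returns every rs probe flagged `bad_metric` by
#' [detect_snp_mismatches()] — the probes whose design changed on the newest
#' array and which corrupt cross-array fingerprint matching.
#'
#' @param mismatch A `snp_mismatch` report.
#' @return Character vector of base ids.
#' @export
recommend_exclusions <- function(mismatch) {
  mismatch$base_id[mismatch$bad_metric]
}
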