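#' Call genotypes from SNP fingerprint probe betas
#'
#' rs-probe betas cluster near 0, 0.5, and 1 by genotype. Calls count copies
#' of the B-allele proxy: beta < `t1` gives 0, beta > `t2` gives 2,
#' anything else (boundaries included) is conservatively called
#' heterozygous (1). Missing betas propagate to missing calls.
#'
#' @param snp_beta Beta tibble or matrix of rs probes (probes x samples).
#' @param t1,t2 Call thresholds, `0 < t1 < t2 < 1`.
#' @return A `genotype_calls` integer matrix (probes x samples) with
#'   thresholds attached as attributes.
#' @export
call_genotypes <- function(snp_beta, t1 = 0.25, t2 = 0.75) {
  if (!(t1 > 0 && t2 < 1 && t1 < t2)) {
    abort("thresholds must satisfy 0 < t1 < t2 < 1")
  }
  B <- as_beta_matrix(snp_beta)
  if (any(B < 0 | B > 1, na.rm = TRUE)) abort("betas must lie in [0, 1]")
  calls <- matrix(1L, nrow(B), ncol(B), dimnames = dimnames(B))
  calls[B < t1] <- 0L
  calls[B > t2] <- 2L
  calls[is.na(B)] <- NA_integer_
  structure(calls, class = c("genotype_calls", class(calls)),
            t1 = t1, t2 = t2)
}

# distance matrix across all samples of all arrays
# statistic "calls": 1 - call concordance; "beta": root-mean-square beta
# difference over shared probes
cross_array_distance <- function(by_array, exclude, statistic) {
  probes <- Reduce(intersect, lapply(by_array, rownames))
  probes <- setdiff(probes, exclude)
  mats <- purrr::imap(by_array, function(M, arr) {
    M <- M[probes, , drop = FALSE]
    colnames(M) <- paste0(arr, "::", colnames(M))
    M
  })
  big <- do.call(cbind, mats)
  ns <- ncol(big)
  D <- matrix(0, ns, ns, dimnames = list(colnames(big), colnames(big)))
  S <- matrix(NA_real_, ns, ns, dimnames = dimnames(D))  # shared co-called n
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      ok <- !is.na(big[, i]) & !is.na(big[, j])
      S[i, j] <- S[j, i] <- sum(ok)
      d <- if (statistic == "calls") {
        1 - mean(big[ok, i] == big[ok, j])
      } else {
        sqrt(mean((big[ok, i] - big[ok, j])^2))
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  list(D = D, shared = S, n_probes = length(probes))
}

#' Match samples across arrays from SNP fingerprint probes
#'
#' Computes pairwise concordance between every newest-array sample and every
#' older-array sample over the shared, co-called, non-excluded rs probes,
#' assigns each newest-array sample to the donor of maximal concordance
#' (ties between different donors leave the sample unmatched, with a
#' warning), and builds an average-linkage dendrogram over all samples from
#' all arrays on distance 1 - concordance.
#'
#' Two matching statistics are available: `"calls"` (default; concordance =
#' fraction of co-called probes with equal genotype calls, robust to
#' array-level intensity shifts) and `"beta"` (similarity derived from the
#' root-mean-square difference of raw betas, the statistic under which
#' probe-design corruption on the newest array manifests as array-wise
#' clustering).
#'
#' @param by_array Named list (one element per array, newest last) of
#'   [call_genotypes()] matrices (for `statistic = "calls"`) or rs-probe
#'   beta matrices/tibbles (for `statistic = "beta"`).
#' @param exclude Character vector of probe (base) ids to drop before
#'   matching, e.g. from [recommend_exclusions()].
#' @param donor_maps Optional named list of sample maps (`position_id`,
#'   `donor_id`); when supplied, assignment correctness is donor-level and
#'   ties within the same donor are not treated as ambiguous.
#' @param statistic `"calls"` or `"beta"`.
#' @param min_shared Minimum number of shared co-called probes required.
#' @return A `sample_match` list: `concordance` (tibble: sample_a, array_a,
#'   sample_b, array_b, n_shared, concordance), `assignment` (tibble per
#'   newest-array sample: best older-array sample, its donor, concordance,
#'   `assigned` flag), `hclust` (average-linkage tree over all samples),
#'   `statistic`, `excluded`.
#' @export
match_samples <- function(by_array, exclude = character(0),
                          donor_maps = NULL,
                          statistic = c("calls", "beta"),
                          min_shared = 5) {
  statistic <- match.arg(statistic)
  if (length(by_array) < 2) abort("need >= 2 arrays")
  if (is.null(names(by_array)) || any(names(by_array) == "")) {
    names(by_array) <- paste0("array", seq_along(by_array))
  }
  mats <- lapply(by_array, function(M) {
    M <- if (is.data.frame(M)) as_beta_matrix(M) else as.matrix(M)
    rownames(M) <- probe_base_id(rownames(M))
    M
  })
  cd <- cross_array_distance(mats, exclude, statistic)
  if (cd$n_probes < min_shared) {
    abort(paste0("only ", cd$n_probes,
                 " shared probes remain after exclusion (need >= ",
                 min_shared, ")"))
  }
  arrays <- names(by_array)
  newest <- arrays[length(arrays)]
  ids <- rownames(cd$D)
  arr_of <- sub("::.*$", "", ids)
  pos_of <- sub("^.*::", "", ids)
  donor_of <- pos_of
  if (!is.null(donor_maps)) {
    for (a in arrays) {
      sel <- arr_of == a
      donor_of[sel] <- donor_maps[[a]]$donor_id[
        match(pos_of[sel], donor_maps[[a]]$position_id)]
    }
  }

  sim <- 1 - cd$D
  new_idx <- which(arr_of == newest)
  old_idx <- which(arr_of != newest)
  conc <- purrr::map_dfr(new_idx, function(i) {
    tibble(sample_a = pos_of[i], array_a = newest,
           sample_b = pos_of[old_idx], array_b = arr_of[old_idx],
           donor_b = donor_of[old_idx],
           n_shared = cd$shared[i, old_idx],
           concordance = sim[i, old_idx])
  })
  low <- conc$n_shared < min_shared
  if (any(low)) {
    abort(paste0("a sample pair shares only ", min(conc$n_shared),
                 " co-called probes (need >= ", min_shared, ")"))
  }

  assignment <- purrr::map_dfr(new_idx, function(i) {
    s <- sim[i, old_idx]
    best <- max(s)
    hits <- old_idx[s == best]
    hit_donors <- unique(donor_of[hits])
    if (length(hit_donors) > 1) {
      warn(paste0("tie for sample ", pos_of[i],
                  " between donors ", paste(hit_donors, collapse = ", "),
                  "; left unmatched"))
      tibble(sample = pos_of[i], donor = donor_of[i],
             matched_sample = NA_character_, matched_array = NA_character_,
             matched_donor = NA_character_, concordance = best,
             assigned = FALSE)
    } else {
      j <- hits[1]
      tibble(sample = pos_of[i], donor = donor_of[i],
             matched_sample = pos_of[j], matched_array = arr_of[j],
             matched_donor = hit_donors, concordance = best,
             assigned = TRUE)
    }
  })

  hc <- hclust(as.dist(cd$D), method = "average")
  structure(list(concordance = conc, assignment = assignment, hclust = hc,
                 statistic = statistic, excluded = exclude,
                 n_probes = cd$n_probes, arrays = arrays,
                 donor_of = setNames(donor_of, ids)),
            class = "sample_match")
}

#' @export
print.sample_match <- function(x, ...) {
  cat("Cross-array sample matching (", x$statistic, " statistic, ",
      x$n_probes, " probes, ", length(x$excluded), " excluded)\n", sep = "")
  ok <- x$assignment$assigned &
    x$assignment$matched_donor == x$assignment$donor
  cat("  newest-array samples:", nrow(x$assignment),
      "| correctly assigned:", sum(ok, na.rm = TRUE), "\n")
  invisible(x)
}

#' Donor-level assignment accuracy
#'
#' Fraction of newest-array samples assigned to their true donor (requires
#' `donor_maps` to have been passed to [match_samples()], or position ids
#' equal to donor ids).
#'
#' @param match A `sample_match`.
#' @return A list: `n`, `n_correct`, `accuracy`, `misassigned` (sample ids
#'   not mapped to their own donor, including unmatched).
#' @export
assignment_accuracy <- function(match) {
  a <- match$assignment
  correct <- a$assigned & !is.na(a$matched_donor) & a$matched_donor == a$donor
  list(n = nrow(a), n_correct = sum(correct),
       accuracy = mean(correct),
       misassigned = a$sample[!correct])
}

#' Cluster-based cross-array pairing from the dendrogram
#'
#' For each newest-array sample, finds the older-array sample with the
#' smallest cophenetic distance in the average-linkage tree. When the
#' corrupted probes are included under the `"beta"` statistic, newest-array
#' samples merge with each other before joining any older-array sample, so
#' this pairing breaks — the mismatch mode seen when clustering raw SNP
#' betas across array generations.
#'
#' @param match A `sample_match`.
#' @return Tibble per newest-array sample: `sample`, `donor`,
#'   `nearest_sample`, `nearest_donor`, `cophenetic_distance`, `matched`
#'   (nearest donor equals own donor, FALSE on ties across donors).
#' @export
cluster_match <- function(match) {
  cop <- as.matrix(cophenetic(match$hclust))
  ids <- rownames(cop)
  arr_of <- sub("::.*$", "", ids)
  newest <- match$arrays[length(match$arrays)]
  donor_of <- match$donor_of[ids]
  new_idx <- which(arr_of == newest)
  old_idx <- which(arr_of != newest)
  purrr::map_dfr(new_idx, function(i) {
    d <- cop[i, old_idx]
    best <- min(d)
    hits <- old_idx[d == best]
    hit_donors <- unique(donor_of[hits])
    tibble(sample = sub("^.*::", "", ids[i]),
           donor = unname(donor_of[i]),
           nearest_sample = sub("^.*::", "", ids[hits[1]]),
           nearest_donor = hit_donors[1],
           cophenetic_distance = best,
           matched = length(hit_donors) == 1 &&
             hit_donors == donor_of[i])
  })
}

#' Export the matching dendrogram as newick
#'
#' @param match A `sample_match`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_match_newick <- function(match, path) {
  phy <- ape::as.phylo(match$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
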