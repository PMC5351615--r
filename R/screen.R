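# Epi-driver screen: cross-pair DMF intersection, direction consistency,
# progression-pattern classification.

#' Intersect per-pair DMF sets
#'
#' Builds the shared-DMF table over the union of significant fragments,
#' flags those significant in every pair, and reports pairwise overlap
#' percentages (`|A∩B| / min(|A|,|B|) * 100`, denominator configurable) and
#' the percentage of shared fragments changing in the same direction.
#'
#' @param dmf_sets Named list (one per pair) of [call_dmfs()] tables from the
#'   same catalog.
#' @param overlap_denominator "min" (default) or "union".
#' @return list(shared, pairwise_overlap, direction_consistency,
#'   significant_ids). `shared` has one row per fragment significant in at
#'   least one pair, with `n_pairs_significant`, `in_all`,
#'   `direction_consistent`, `consensus_direction` and one direction column
#'   per pair.
#' @export
intersect_dmfs <- function(dmf_sets, overlap_denominator = c("min", "union")) {
  overlap_denominator <- match.arg(overlap_denominator)
  .assert(length(dmf_sets) >= 2, "need at least two pair DMF sets")
  .assert(!is.null(names(dmf_sets)) && all(nzchar(names(dmf_sets))),
          "dmf_sets must be named by pair")
  pairs <- names(dmf_sets)
  sig <- lapply(dmf_sets, function(d) d[d$significant, , drop = FALSE])
  sig_ids <- lapply(sig, `[[`, "fragment_id")

  union_ids <- sort(unique(unlist(sig_ids)))
  coords <- do.call(rbind, lapply(dmf_sets, function(d)
    d[, c("fragment_id", "chrom", "start", "end")]))
  coords <- coords[!duplicated(coords$fragment_id), , drop = FALSE]
  shared <- coords[match(union_ids, coords$fragment_id), , drop = FALSE]
  dirs <- matrix(NA_character_, length(union_ids), length(pairs),
                 dimnames = list(union_ids, pairs))
  for (p in pairs) {
    i <- match(sig_ids[[p]], union_ids)
    dirs[i, p] <- sig[[p]]$direction
  }
  n_sig <- rowSums(!is.na(dirs))
  consistent <- apply(dirs, 1, function(d) {
    d <- d[!is.na(d)]
    length(unique(d)) <= 1
  })
  consensus <- apply(dirs, 1, function(d) {
    d <- unique(d[!is.na(d)])
    if (length(d) == 1) d else "mixed"
  })
  shared$n_pairs_significant <- as.integer(n_sig)
  shared$in_all <- n_sig == length(pairs)
  for (p in pairs) shared[[paste0("direction_", p)]] <- dirs[, p]
  shared$direction_consistent <- consistent
  shared$consensus_direction <- consensus
  rownames(shared) <- NULL

  np <- length(pairs)
  ov <- matrix(NA_real_, np, np, dimnames = list(pairs, pairs))
  dc <- matrix(NA_real_, np, np, dimnames = list(pairs, pairs))
  for (i in seq_len(np)) for (j in seq_len(np)) {
    if (i == j) next
    a <- sig_ids[[i]]; b <- sig_ids[[j]]
    inter <- intersect(a, b)
    denom <- if (overlap_denominator == "min") min(length(a), length(b))
             else length(union(a, b))
    ov[i, j] <- if (denom > 0) 100 * length(inter) / denom else 0
    if (length(inter)) {
      da <- sig[[i]]$direction[match(inter, a)]
      db <- sig[[j]]$direction[match(inter, b)]
      dc[i, j] <- 100 * mean(da == db)
    }
  }
  list(shared = shared, pairwise_overlap = ov, direction_consistency = dc,
       significant_ids = sig_ids)
}

#' Direction-consistent shared DMF sets
#'
#' Partitions the shared-in-all, direction-consistent DMFs into the
#' hypermethylated-in-all and hypomethylated-in-all sets; mixed-direction
#' fragments are excluded from both.
#'
#' @param shared The `shared` table from [intersect_dmfs()].
#' @return list(hyper_in_all, hypo_in_all) of fragment ids.
#' @export
common_direction_dmfs <- function(shared) {
  keep <- shared$in_all & shared$direction_consistent
  list(hyper_in_all = shared$fragment_id[keep & shared$consensus_direction == "hyper"],
       hypo_in_all = shared$fragment_id[keep & shared$consensus_direction == "hypo"])
}

#' Classify two-step progression patterns
#'
#' For fragments significant in both the normal-vs-primary and the
#' primary-vs-metastatic comparison of a pair, the pattern is the pair of
#' directions, e.g. "hyper-hypo" for a gain followed by a loss. Fragments
#' significant in only one step are excluded.
#'
#' @param dmfs_normal_primary,dmfs_primary_metastatic Named lists (by pair)
#'   of [call_dmfs()] tables for the two steps.
#' @return data.frame(fragment_id, pair_id, step1, step2, pattern).
#' @export
classify_progression_pattern <- function(dmfs_normal_primary,
                                         dmfs_primary_metastatic) {
  pairs <- intersect(names(dmfs_normal_primary), names(dmfs_primary_metastatic))
  .assert(length(pairs) >= 1, "no common pairs between the two steps")
  rows <- lapply(pairs, function(p) {
    s1 <- dmfs_normal_primary[[p]]
    s2 <- dmfs_primary_metastatic[[p]]
    s1 <- s1[s1$significant, , drop = FALSE]
    s2 <- s2[s2$significant, , drop = FALSE]
    ids <- intersect(s1$fragment_id, s2$fragment_id)
    if (!length(ids)) return(NULL)
    d1 <- s1$direction[match(ids, s1$fragment_id)]
    d2 <- s2$direction[match(ids, s2$fragment_id)]
    data.frame(fragment_id = ids, pair_id = p, step1 = d1, step2 = d2,
               pattern = paste0(d1, "-", d2), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(fragment_id = character(), pair_id = character(),
                      step1 = character(), step2 = character(),
                      pattern = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
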