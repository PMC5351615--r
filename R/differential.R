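# Per-pair differentially methylated fragment (DMF) calling: two-sided
# Fisher's exact test on pooled fragment counts, Bonferroni correction, and
# the 25% mean methylation difference threshold.

#' Two-sided Fisher's exact test for 2x2 methylation tables
#'
#' The table is (methylated, unmethylated) x (sample A, sample B) with pooled
#' fragment counts. The exact two-sided p sums hypergeometric probabilities
#' of every table with the same margins whose probability is at most that of
#' the observed table, with a `1 + 1e-7` relative tolerance for floating-point
#' ties. Vectorised over tables.
#'
#' @param meth_a,unmeth_a,unmeth_b,meth_b Non-negative counts; both row sums
#'   (per-sample totals) must be positive.
#' @return Vector of p-values in (0, 1].
#' @export
fisher_exact_two_sided <- function(meth_a, unmeth_a, meth_b, unmeth_b) {
  n <- length(meth_a)
  .assert(all(c(meth_a, unmeth_a, meth_b, unmeth_b) >= 0), "negative counts")
  ra <- meth_a + unmeth_a
  rb <- meth_b + unmeth_b
  .assert(all(ra > 0) && all(rb > 0),
          "zero-margin table: fragment should have been filtered upstream")
  vapply(seq_len(n), function(i) {
    r1 <- ra[i]; r2 <- rb[i]; c1 <- meth_a[i] + meth_b[i]
    support <- max(0L, c1 - r2):min(c1, r1)
    d <- stats::dhyper(support, r1, r2, c1)
    obs <- d[match(meth_a[i], support)]
    min(1, sum(d[d <= obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Bonferroni adjustment
#'
#' @param p P-values.
#' @param m Number of tests in the family (fragments tested in this pair
#'   comparison).
#' @export
bonferroni <- function(p, m) {
  .assert(m >= 1, "m must be >= 1")
  pmin(1, p * m)
}

#' Call differentially methylated fragments between two samples
#'
#' The tested set is the fragments analysable in both samples; the Bonferroni
#' family size is the size of that set. A fragment is a DMF iff the adjusted
#' p is below `alpha` and the absolute difference of pooled-read fractions is
#' at least `delta_min` (inclusive). `delta = level_b - level_a`; direction
#' is "hyper" when sample B is more methylated.
#'
#' @param frag_table_a,frag_table_b [fragment_methylation()] tables built
#'   with identical catalog and filters; A is the earlier state (normal or
#'   primary), B the later (primary or metastatic).
#' @param pair_id Pair label carried into the records.
#' @param comparison "normal_vs_primary" or "primary_vs_metastatic".
#' @param alpha Significance level on the Bonferroni-adjusted p.
#' @param delta_min Minimum |delta| (inclusive).
#' @return data.frame of DMF records for all tested fragments, ordered by
#'   (chrom, start), with attribute `m` (family size).
#' @export
call_dmfs <- function(frag_table_a, frag_table_b, pair_id = NA_character_,
                      comparison = c("primary_vs_metastatic", "normal_vs_primary"),
                      alpha = 0.05, delta_min = 0.25) {
  comparison <- match.arg(comparison)
  common <- intersect(frag_table_a$fragment_id, frag_table_b$fragment_id)
  .assert(length(common) > 0, "no fragments analysable in both samples")
  a <- frag_table_a[match(common, frag_table_a$fragment_id), ]
  b <- frag_table_b[match(common, frag_table_b$fragment_id), ]
  m <- length(common)
  p <- fisher_exact_two_sided(a$pooled_meth, a$pooled_unmeth,
                              b$pooled_meth, b$pooled_unmeth)
  delta <- b$level - a$level
  out <- data.frame(fragment_id = common, chrom = a$chrom, start = a$start,
                    end = a$end, pair_id = pair_id, comparison = comparison,
                    level_a = a$level, level_b = b$level, delta = delta,
                    p = p, p_adj = bonferroni(p, m),
                    direction = ifelse(delta > 0, "hyper", "hypo"),
                    stringsAsFactors = FALSE)
  out$significant <- out$p_adj < alpha & abs(out$delta) >= delta_min - 1e-12
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "m") <- m
  out
}

#' Count significant DMFs by direction
#'
#' @param dmfs A [call_dmfs()] table.
#' @return Named integer vector c(hyper = , hypo = ).
#' @export
summarize_direction <- function(dmfs) {
  sig <- dmfs[dmfs$significant, , drop = FALSE]
  c(hyper = sum(sig$direction == "hyper"),
    hypo = sum(sig$direction == "hypo"))
}
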