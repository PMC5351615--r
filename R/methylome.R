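# Sample methylomes: per-CpG counts, replicate merging, coverage filters,
# fragment-level methylation and sample-level summaries.

#' Construct a sample methylome
#'
#' @param sample_id Sample identifier.
#' @param role One of "normal", "primary", "metastatic".
#' @param pair_id Pair identifier (NA for the normal sample).
#' @param cpgs data.frame(chrom, pos, meth, unmeth); `pos` is the 0-based
#'   forward-strand C offset, one row per CpG.
#' @export
sample_methylome <- function(sample_id, role, pair_id = NA_character_,
                             cpgs = data.frame(chrom = character(), pos = integer(),
                                               meth = integer(), unmeth = integer())) {
  .assert(role %in% c("normal", "primary", "metastatic"),
          "role must be normal/primary/metastatic")
  .assert(all(cpgs$meth >= 0) && all(cpgs$unmeth >= 0), "negative counts")
  key <- paste(cpgs$chrom, cpgs$pos)
  .assert(!anyDuplicated(key), "duplicate CpG positions")
  cpgs <- cpgs[order(cpgs$chrom, cpgs$pos), , drop = FALSE]
  rownames(cpgs) <- NULL
  structure(list(sample_id = sample_id, role = role, pair_id = pair_id,
                 cpgs = cpgs),
            class = "sample_methylome")
}

#' @export
print.sample_methylome <- function(x, ...) {
  cat(sprintf("sample_methylome '%s' (%s, pair %s): %d CpGs, mean coverage %.1f\n",
              x$sample_id, x$role, x$pair_id %||% NA, nrow(x$cpgs),
              mean(x$cpgs$meth + x$cpgs$unmeth)))
  invisible(x)
}

#' Read a Bismark-style coverage file
#'
#' Expects 6 tab-separated columns: chrom, start (1-based), end, percent
#' methylation, count methylated, count unmethylated. Positions are converted
#' to 0-based C offsets; rows whose percent disagrees with the counts by more
#' than 0.1 raise an error (corruption guard); duplicate positions (e.g. the
#' two strands of one CpG) are merged by summing counts.
#'
#' @param path Coverage file path.
#' @inheritParams sample_methylome
#' @export
read_coverage_file <- function(path, sample_id, role, pair_id = NA_character_) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", col.names = c("chrom", "start", "end",
                                                      "percent", "meth", "unmeth"),
                      colClasses = c("character", "integer", "integer",
                                     "numeric", "integer", "integer")),
    error = function(e) stop(sprintf("malformed coverage file '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE))
  bad <- which(df$meth < 0 | df$unmeth < 0)
  .assert(!length(bad), sprintf("negative counts at line %d of %s", bad[1], path))
  tot <- df$meth + df$unmeth
  zero <- which(tot == 0)
  .assert(!length(zero), sprintf("zero-coverage row at line %d of %s", zero[1], path))
  off <- which(abs(df$percent - 100 * df$meth / tot) > 0.1)
  .assert(!length(off), sprintf(
    "percent/count mismatch at line %d of %s (percent %.4g, counts %d/%d)",
    off[1], path, df$percent[off[1]], df$meth[off[1]], df$unmeth[off[1]]))
  pos0 <- df$start - 1L
  key <- paste(df$chrom, pos0)
  meth <- rowsum(df$meth, key)
  unmeth <- rowsum(df$unmeth, key)
  first <- !duplicated(key)
  ord <- match(rownames(meth), key[first])
  cpgs <- data.frame(chrom = df$chrom[first][ord], pos = pos0[first][ord],
                     meth = as.integer(meth), unmeth = as.integer(unmeth),
                     stringsAsFactors = FALSE)
  sample_methylome(sample_id, role, pair_id, cpgs)
}

#' Write a sample methylome as a Bismark-style coverage file
#' @export
write_coverage_file <- function(sm, path) {
  cp <- sm$cpgs
  pct <- 100 * cp$meth / (cp$meth + cp$unmeth)
  out <- data.frame(cp$chrom, cp$pos + 1L, cp$pos + 1L,
                    formatC(pct, format = "f", digits = 4), cp$meth, cp$unmeth)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Combine replicate libraries of one sample
#'
#' Per-CpG counts are summed over the union of positions; commutative and
#' associative.
#' @param a,b `sample_methylome` objects with identical metadata.
#' @export
merge_replicates <- function(a, b) {
  .assert(a$role == b$role && identical(a$sample_id, b$sample_id) &&
          identical(is.na(a$pair_id), is.na(b$pair_id)) &&
          (is.na(a$pair_id) || a$pair_id == b$pair_id),
          "replicates must share sample metadata")
  both <- rbind(a$cpgs, b$cpgs)
  key <- paste(both$chrom, both$pos)
  meth <- rowsum(both$meth, key)
  unmeth <- rowsum(both$unmeth, key)
  first <- !duplicated(key)
  ord <- match(rownames(meth), key[first])
  cpgs <- data.frame(chrom = both$chrom[first][ord], pos = both$pos[first][ord],
                     meth = as.integer(meth), unmeth = as.integer(unmeth),
                     stringsAsFactors = FALSE)
  sample_methylome(a$sample_id, a$role, a$pair_id, cpgs)
}

.common_fractions <- function(a, b, cov_min) {
  ka <- paste(a$cpgs$chrom, a$cpgs$pos)
  kb <- paste(b$cpgs$chrom, b$cpgs$pos)
  cova <- a$cpgs$meth + a$cpgs$unmeth
  covb <- b$cpgs$meth + b$cpgs$unmeth
  ka <- ka[cova >= cov_min]
  fa <- (a$cpgs$meth / cova)[cova >= cov_min]
  kb2 <- kb[covb >= cov_min]
  fb <- (b$cpgs$meth / covb)[covb >= cov_min]
  common <- intersect(ka, kb2)
  list(fa = fa[match(common, ka)], fb = fb[match(common, kb2)], n = length(common))
}

#' Pearson correlation between replicate libraries
#'
#' Computed over per-CpG methylation fractions at positions covered by at
#' least `cov_min` reads in both libraries.
#' @param a,b `sample_methylome` objects.
#' @param cov_min Minimum coverage per CpG in each library.
#' @return list(r, n_common).
#' @export
replicate_correlation <- function(a, b, cov_min = 10) {
  cf <- .common_fractions(a, b, cov_min)
  .assert(cf$n >= 3, sprintf(
    "only %d common CpGs pass coverage >= %d; need >= 3", cf$n, cov_min))
  list(r = stats::cor(cf$fa, cf$fb), n_common = cf$n)
}

#' Fragment-level methylation for one sample
#'
#' A fragment is analysable for a sample iff at least `min_cpgs` of its CpGs
#' are covered by `cov_min` or more reads. Pooled counts then sum over all of
#' the fragment's CpGs with any coverage, so the estimate uses all reads once
#' the evidence gate passes; the fragment level is the pooled read fraction.
#'
#' @param sample A `sample_methylome`.
#' @param catalog `fragment_catalog` with CpGs assigned.
#' @param cov_min Per-CpG coverage threshold for the gate.
#' @param min_cpgs Minimum qualifying CpGs.
#' @return data.frame(fragment_id, chrom, start, end, pooled_meth,
#'   pooled_unmeth, n_cpgs_covered, level), analysable fragments only.
#' @export
fragment_methylation <- function(sample, catalog, cov_min = 10, min_cpgs = 2) {
  .assert(!is.null(catalog$cpgs), "catalog CpGs must be assigned")
  cp <- catalog$cpgs[!is.na(catalog$cpgs$fragment_id), , drop = FALSE]
  key_cat <- paste(cp$chrom, cp$pos)
  key_sam <- paste(sample$cpgs$chrom, sample$cpgs$pos)
  m <- match(key_cat, key_sam)
  meth <- ifelse(is.na(m), 0L, sample$cpgs$meth[m])
  unmeth <- ifelse(is.na(m), 0L, sample$cpgs$unmeth[m])
  cov <- meth + unmeth
  pooled_m <- rowsum(meth * (cov > 0), cp$fragment_id)
  pooled_u <- rowsum(unmeth * (cov > 0), cp$fragment_id)
  n_cov <- rowsum(as.integer(cov >= cov_min), cp$fragment_id)
  ids <- rownames(pooled_m)
  ok <- n_cov[, 1] >= min_cpgs
  fr <- catalog$fragments
  idx <- match(ids[ok], fr$fragment_id)
  out <- data.frame(fragment_id = ids[ok],
                    chrom = fr$chrom[idx], start = fr$start[idx],
                    end = fr$end[idx],
                    pooled_meth = as.integer(pooled_m[ok, 1]),
                    pooled_unmeth = as.integer(pooled_u[ok, 1]),
                    n_cpgs_covered = as.integer(n_cov[ok, 1]),
                    stringsAsFactors = FALSE)
  out$level <- out$pooled_meth / (out$pooled_meth + out$pooled_unmeth)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Global mean methylation of a sample, in percent
#'
#' Unweighted mean of per-CpG methylation fractions over CpGs covered by
#' `cov_min` or more reads.
#' @inheritParams replicate_correlation
#' @param sample A `sample_methylome`.
#' @export
global_mean_methylation <- function(sample, cov_min = 10) {
  cov <- sample$cpgs$meth + sample$cpgs$unmeth
  keep <- cov >= cov_min
  .assert(any(keep), sprintf("no CpGs with coverage >= %d", cov_min))
  100 * mean(sample$cpgs$meth[keep] / cov[keep])
}

#' Histogram of fragment methylation levels
#'
#' Bins are half-open `[lo, hi)`, the last bin closed.
#' @param frag_table Output of [fragment_methylation()].
#' @param n_bins Number of equal-width bins on [0, 1].
#' @return data.frame(bin_low, bin_high, count).
#' @export
methylation_histogram <- function(frag_table, n_bins = 20) {
  .assert(nrow(frag_table) > 0, "empty fragment table")
  br <- seq(0, 1, length.out = n_bins + 1)
  idx <- pmin(findInterval(frag_table$level, br), n_bins)  # last bin closed
  counts <- tabulate(idx, nbins = n_bins)
  data.frame(bin_low = br[-length(br)], bin_high = br[-1], count = counts)
}

#' Hierarchical clustering of sample methylomes
#'
#' Distance is `1 - Pearson r` over per-CpG methylation fractions at
#' positions covered by `cov_min` or more reads in every sample;
#' average-linkage agglomeration. Samples are ordered by id first so ties
#' break deterministically.
#'
#' @param samples Named or unnamed list of `sample_methylome` objects.
#' @param cov_min Coverage threshold applied in every sample.
#' @return An [stats::hclust] tree with an `n_cpgs` attribute.
#' @export
cluster_samples <- function(samples, cov_min = 10) {
  ids <- vapply(samples, function(s) s$sample_id, "")
  .assert(!anyDuplicated(ids), "duplicate sample ids")
  samples <- samples[order(ids)]
  ids <- sort(ids)
  keys <- lapply(samples, function(s) {
    cov <- s$cpgs$meth + s$cpgs$unmeth
    paste(s$cpgs$chrom, s$cpgs$pos)[cov >= cov_min]
  })
  common <- Reduce(intersect, keys)
  .assert(length(common) >= 3, sprintf(
    "only %d CpGs covered >= %d in all samples; need >= 3", length(common), cov_min))
  frac <- vapply(samples, function(s) {
    k <- paste(s$cpgs$chrom, s$cpgs$pos)
    i <- match(common, k)
    s$cpgs$meth[i] / (s$cpgs$meth[i] + s$cpgs$unmeth[i])
  }, numeric(length(common)))
  colnames(frac) <- ids
  d <- stats::as.dist(1 - stats::cor(frac))
  hc <- stats::hclust(d, method = "average")
  attr(hc, "n_cpgs") <- length(common)
  hc
}

#' Write a clustering tree as Newick
#' @param hc An [stats::hclust] object.
#' @param path Output file.
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Mean methylation by genomic element class
#'
#' Each CpG is assigned one class with precedence promoter > gene body >
#' intergenic; promoters are strand-aware windows around the TSS
#' (`promoter_window = c(-2000, 500)` means 2 kb upstream to 500 bp
#' downstream). Class means are over per-CpG fractions at coverage
#' `>= cov_min`.
#'
#' @param sample A `sample_methylome`.
#' @param genes data.frame(chrom, start, end, strand, gene_id) in 0-based
#'   half-open coordinates, or NULL (everything intergenic).
#' @param promoter_window Window around the TSS, bases.
#' @param cov_min Coverage threshold.
#' @return data.frame(class, n_cpgs, mean_methylation).
#' @export
element_distribution <- function(sample, genes = NULL,
                                 promoter_window = c(-2000, 500), cov_min = 10) {
  cp <- sample$cpgs
  cov <- cp$meth + cp$unmeth
  cp <- cp[cov >= cov_min, , drop = FALSE]
  frac <- cp$meth / (cp$meth + cp$unmeth)
  cls <- rep("intergenic", nrow(cp))
  if (!is.null(genes) && nrow(genes)) {
    cp_gr <- GenomicRanges::GRanges(cp$chrom, IRanges::IRanges(cp$pos + 1L, cp$pos + 1L))
    gr <- .genes_gr(genes)
    prom <- GenomicRanges::promoters(gr, upstream = -promoter_window[1],
                                     downstream = promoter_window[2])
    prom <- GenomicRanges::trim(prom)
    in_body <- IRanges::overlapsAny(cp_gr, gr, ignore.strand = TRUE)
    in_prom <- IRanges::overlapsAny(cp_gr, prom, ignore.strand = TRUE)
    cls[in_body] <- "gene_body"
    cls[in_prom] <- "promoter"
  }
  out <- data.frame(class = c("promoter", "gene_body", "intergenic"),
                    stringsAsFactors = FALSE)
  out$n_cpgs <- vapply(out$class, function(k) sum(cls == k), integer(1))
  out$mean_methylation <- vapply(out$class, function(k)
    if (any(cls == k)) mean(frac[cls == k]) else NA_real_, numeric(1))
  out
}

# genes data.frame (0-based half-open) -> GRanges (1-based)
.genes_gr <- function(genes) {
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(genes$start + 1L, genes$end),
                         strand = genes$strand %||% "+",
                         gene_id = genes$gene_id)
}
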