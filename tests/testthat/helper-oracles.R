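# Independent reference implementations used to check the package's
# statistics, plus shared fixtures built once per test run.

# naive MspI digestion by plain string scan (gregexpr), independent of the
# Biostrings-based implementation
naive_digest <- function(seq) {
  s <- toupper(seq)
  occ <- gregexpr("CCGG", s, fixed = TRUE)[[1]]
  if (occ[1] == -1 || length(occ) < 2) {
    return(data.frame(start = integer(), end = integer()))
  }
  cuts <- as.integer(occ)      # 1-based CCGG start == 0-based start + 1 = cut
  data.frame(start = cuts[-length(cuts)], end = cuts[-1])
}

# two-sided Fisher p by direct enumeration of table probabilities from
# binomial coefficients
fisher_oracle <- function(ma, ua, mb, ub) {
  r1 <- ma + ua; r2 <- mb + ub; c1 <- ma + mb
  a <- max(0, c1 - r2):min(c1, r1)
  w <- choose(r1, a) * choose(r2, c1 - a)
  pr <- w / sum(w)
  obs <- pr[match(ma, a)]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# exact two-sided Mann-Whitney p by full label-permutation enumeration
mw_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  v <- c(x, y)
  idx <- utils::combn(nx + ny, nx)
  U_all <- apply(idx, 2, function(i) {
    r <- rank(v)
    sum(r[i]) - nx * (nx + 1) / 2
  })
  r <- rank(v)
  U_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  min(1, 2 * min(mean(U_all <= U_obs), mean(U_all >= U_obs)))
}

# hand-built fragment catalog for unit tests
manual_catalog <- function(fragments, cpgs) {
  fragments$length <- fragments$end - fragments$start
  counts <- table(cpgs$fragment_id[!is.na(cpgs$fragment_id)])
  fragments$n_cpgs <- as.integer(counts[fragments$fragment_id])
  fragments$n_cpgs[is.na(fragments$n_cpgs)] <- 0L
  structure(list(fragments = fragments, cpgs = cpgs, genome_id = "manual",
                 size_min = NA_integer_, size_max = NA_integer_),
            class = "fragment_catalog")
}

# minimal fragment_methylation-shaped table from pooled counts
manual_frag_table <- function(fragment_id, pooled_meth, pooled_unmeth,
                              chrom = "chr1", start = seq_along(fragment_id) * 1000L,
                              n_cpgs_covered = 2L) {
  data.frame(fragment_id = fragment_id, chrom = chrom, start = start,
             end = start + 100L, pooled_meth = pooled_meth,
             pooled_unmeth = pooled_unmeth, n_cpgs_covered = n_cpgs_covered,
             level = pooled_meth / (pooled_meth + pooled_unmeth),
             stringsAsFactors = FALSE)
}

# shared simulated genome + catalog, built once per test session
.fixture_env <- new.env(parent = emptyenv())
shared_fixture <- function() {
  if (is.null(.fixture_env$catalog)) {
    .fixture_env$genome <- generate_genome(seed = 42)
    .fixture_env$catalog <- build_catalog(.fixture_env$genome$sequences)
  }
  list(genome = .fixture_env$genome, catalog = .fixture_env$catalog)
}

# larger genome for the null/recovery studies (about 2000 fragments)
shared_fixture_large <- function() {
  if (is.null(.fixture_env$catalog_l)) {
    .fixture_env$genome_l <- generate_genome(n_chroms = 3, seed = 43)
    .fixture_env$catalog_l <- build_catalog(.fixture_env$genome_l$sequences)
  }
  list(genome = .fixture_env$genome_l, catalog = .fixture_env$catalog_l)
}

# restrict a catalog to its first n fragments (keeps CpG assignment)
subset_catalog <- function(catalog, n) {
  keep <- catalog$fragments$fragment_id[seq_len(n)]
  catalog$fragments <- catalog$fragments[seq_len(n), , drop = FALSE]
  catalog$cpgs <- catalog$cpgs[!is.na(catalog$cpgs$fragment_id) &
                               catalog$cpgs$fragment_id %in% keep, , drop = FALSE]
  rownames(catalog$fragments) <- rownames(catalog$cpgs) <- NULL
  catalog
}

# run one simulated study and return per-pair primary-vs-metastatic DMF sets
run_pair_dmfs <- function(catalog, design, planted = NULL,
                          min_cpgs_planted = 2, alpha = 0.05, delta_min = 0.25) {
  truth <- plan_methylation_states(catalog, design, planted,
                                   min_cpgs_planted = min_cpgs_planted,
                                   seed = design$seed)
  libs <- simulate_counts(truth, catalog, design)
  pairs <- paste0("pair", seq_len(design$n_pairs))
  dmfs <- lapply(seq_len(design$n_pairs), function(i) {
    call_dmfs(fragment_methylation(libs[[paste0("P", i)]], catalog),
              fragment_methylation(libs[[paste0("M", i)]], catalog),
              pair_id = pairs[i], alpha = alpha, delta_min = delta_min)
  })
  names(dmfs) <- pairs
  list(truth = truth, libs = libs, dmfs = dmfs)
}
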