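# Synthetic-data module: genomes, designed methylation states with planted
# DMFs, simulated bisulfite counts, array-style cohort matrices and
# expression tables, all with recorded ground truth.

#' Describe a paired primary/metastatic study
#'
#' Defaults emulate the structure of a paired cell-line study: one normal
#' melanocyte line, three primary/metastatic pairs, and replicate libraries
#' for the normal line and the first primary.
#'
#' @param n_pairs Number of primary/metastatic pairs (>= 1).
#' @param include_normal Include a normal reference sample.
#' @param replicate_samples Sample ids sequenced as duplicate libraries.
#' @param coverage_mean Mean reads per CpG per library.
#' @param dispersion Overdispersion: negative-binomial coverage dispersion
#'   and beta-binomial intra-class correlation. 0 gives Poisson/binomial.
#' @param pair_jitter SD of a per-fragment baseline shift shared by the two
#'   members of a pair (0 disables; used to emulate pair-distinct epigenomes).
#' @param seed Master RNG seed for stages derived from this design.
#' @return A `study_design` list with a `samples` table.
#' @export
study_design <- function(n_pairs = 3, include_normal = TRUE,
                         replicate_samples = if (include_normal) c("normal", "P1") else "P1",
                         coverage_mean = 30, dispersion = 0.1,
                         pair_jitter = 0, seed = 1L) {
  .assert(n_pairs >= 1, "n_pairs must be >= 1")
  .assert(coverage_mean > 0, "coverage_mean must be > 0")
  .assert(dispersion >= 0 && dispersion < 1, "dispersion must be in [0,1)")
  samples <- data.frame(
    sample_id = c(if (include_normal) "normal",
                  paste0("P", seq_len(n_pairs)), paste0("M", seq_len(n_pairs))),
    role = c(if (include_normal) "normal",
             rep("primary", n_pairs), rep("metastatic", n_pairs)),
    pair_id = c(if (include_normal) NA_character_,
                paste0("pair", seq_len(n_pairs)), paste0("pair", seq_len(n_pairs))),
    stringsAsFactors = FALSE)
  .assert(all(replicate_samples %in% samples$sample_id),
          "replicate_samples must name samples in the design")
  structure(list(n_pairs = as.integer(n_pairs), include_normal = include_normal,
                 replicate_samples = replicate_samples,
                 coverage_mean = coverage_mean, dispersion = dispersion,
                 pair_jitter = pair_jitter, seed = as.integer(seed),
                 samples = samples),
            class = "study_design")
}

# interior sequence between two MspI half-sites: random bases with CG
# dinucleotides injected at rate p_cpg, scrubbed of accidental CCGG
.interior_seq <- function(len, p_cpg) {
  if (len <= 0) return("")
  b <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
              prob = c(0.3, 0.2, 0.2, 0.3))
  if (len >= 2) {
    slots <- seq(1L, len - 1L, by = 2L)
    ins <- slots[stats::runif(length(slots)) < p_cpg]
    b[ins] <- "C"
    b[ins + 1L] <- "G"
  }
  s <- paste(b, collapse = "")
  while (grepl("CCGG", s, fixed = TRUE)) s <- gsub("CCGG", "CTGG", s, fixed = TRUE)
  s
}

#' Generate a synthetic genome with MspI sites and CpG islands
#'
#' Sequences are assembled between explicitly placed CCGG sites so the
#' digested fragment lengths span the RRBS analysis window; mean cut-to-cut
#' distance is `1/ccgg_rate` with gamma-distributed spread. `cgi_blocks`
#' runs of short, CpG-dense fragments per chromosome act as CpG islands and
#' their coordinates are recorded.
#'
#' @param n_chroms,chrom_len Number and approximate length (bp) of chromosomes.
#' @param ccgg_rate Expected MspI sites per bp (default one per 150 bp).
#' @param cgi_blocks CpG-island blocks per chromosome.
#' @param p_cpg_background,p_cpg_island CG injection rate per 2-bp slot.
#' @param seed RNG seed; output is byte-deterministic given the seed.
#' @return `synthetic_genome`: list(sequences, islands).
#' @export
generate_genome <- function(n_chroms = 2, chrom_len = 200000, ccgg_rate = 1 / 150,
                            cgi_blocks = 4, p_cpg_background = 0.02,
                            p_cpg_island = 0.12, seed = 1L) {
  .assert(chrom_len >= 1000, "chrom_len must be >= 1000")
  set.seed(seed)
  sequences <- character(n_chroms)
  names(sequences) <- paste0("chr", seq_len(n_chroms))
  islands <- list()
  for (ci in seq_len(n_chroms)) {
    chrom <- names(sequences)[ci]
    if (ccgg_rate > 0) {
      n_frag_est <- ceiling(chrom_len * ccgg_rate * 1.2) + 10L
      lens <- pmax(6L, round(stats::rgamma(n_frag_est, shape = 2,
                                           scale = (1 / ccgg_rate) / 2)))
      island_flag <- rep(FALSE, n_frag_est)
      if (cgi_blocks > 0 && n_frag_est > 30L) {
        starts <- sort(sample(seq_len(n_frag_est - 6L), cgi_blocks))
        for (s in starts) {
          idx <- s:(s + 3L)
          island_flag[idx] <- TRUE
          lens[idx] <- round(stats::runif(length(idx), 60, 140))
        }
      }
      keep <- cumsum(lens) <= chrom_len
      lens <- lens[keep]
      island_flag <- island_flag[keep]
      n_frag <- length(lens)
    } else {
      n_frag <- 0L
    }
    if (n_frag == 0L) {
      sequences[ci] <- .interior_seq(chrom_len, p_cpg_background)
      next
    }
    lead <- .interior_seq(round(stats::runif(1, 50, 200)), p_cpg_background)
    tail <- .interior_seq(round(stats::runif(1, 50, 200)), p_cpg_background)
    interiors <- vapply(seq_len(n_frag), function(k) {
      .interior_seq(lens[k] - 4L, if (island_flag[k]) p_cpg_island else p_cpg_background)
    }, character(1))
    sequences[ci] <- paste0(lead, paste0("CCGG", interiors, collapse = ""),
                            "CCGG", tail)
    # site k (0-based offset of its first C): cumulative over interiors
    site <- nchar(lead) + c(0L, cumsum(4L + nchar(interiors)))
    cuts <- site + 1L
    if (any(island_flag)) {
      r <- rle(island_flag)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      isl <- which(r$values)
      islands[[length(islands) + 1L]] <-
        data.frame(chrom = chrom, start = cuts[starts[isl]],
                   end = cuts[ends[isl] + 1L], stringsAsFactors = FALSE)
    }
  }
  islands <- if (length(islands)) do.call(rbind, islands) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  rownames(islands) <- NULL
  gen <- structure(list(sequences = sequences, islands = islands),
                   class = "synthetic_genome")
  n_ok <- sum(digest_genome(sequences)$fragments$length >= 40 &
              digest_genome(sequences)$fragments$length <= 220)
  .assert(n_ok > 0, sprintf(
    "generated genome yields zero 40-220 bp fragments (ccgg_rate = %g); increase ccgg_rate or chrom_len",
    ccgg_rate))
  gen
}

#' Declare fragments to plant as differential
#'
#' @param scope `"shared"` (all pairs) or a pair id (private to that pair).
#' @param direction Primary-to-metastatic direction, `"hyper"` or `"hypo"`
#'   (NA when only a normal-to-primary change is planted).
#' @param delta True methylation shift per step, in (0, 1].
#' @param n_fragments Number of fragments to plant.
#' @param step1 Optional normal-to-primary direction, for progression
#'   patterns.
#' @return One-row data.frame; `rbind()` rows to build a planting plan.
#' @export
planted_dmfs <- function(scope, direction, delta, n_fragments,
                         step1 = NA_character_) {
  data.frame(scope = scope, direction = direction, delta = delta,
             n_fragments = as.integer(n_fragments), step1 = step1,
             stringsAsFactors = FALSE)
}

#' Default planting plan for the simulated study
#'
#' 20 shared DMFs (10 hyper, 10 hypo, true shift 0.5) plus 30 private DMFs
#' per pair (15 hyper, 15 hypo).
#' @param n_pairs Number of pairs in the design.
#' @param delta True shift.
#' @export
default_planted <- function(n_pairs = 3, delta = 0.5) {
  rows <- list(planted_dmfs("shared", "hyper", delta, 10),
               planted_dmfs("shared", "hypo", delta, 10))
  for (p in paste0("pair", seq_len(n_pairs))) {
    rows <- c(rows, list(planted_dmfs(p, "hyper", delta, 15),
                         planted_dmfs(p, "hypo", delta, 15)))
  }
  do.call(rbind, rows)
}

#' Planting plan covering the four progression patterns
#'
#' Shared fragments changing in both the normal-to-primary and the
#' primary-to-metastatic step, one block per pattern
#' (hyper-hyper, hyper-hypo, hypo-hyper, hypo-hypo).
#' @param delta True shift per step.
#' @param n_per_pattern Fragments per pattern.
#' @export
progression_planted <- function(delta = 0.4, n_per_pattern = 5) {
  do.call(rbind, list(
    planted_dmfs("shared", "hyper", delta, n_per_pattern, step1 = "hyper"),
    planted_dmfs("shared", "hypo",  delta, n_per_pattern, step1 = "hyper"),
    planted_dmfs("shared", "hyper", delta, n_per_pattern, step1 = "hypo"),
    planted_dmfs("shared", "hypo",  delta, n_per_pattern, step1 = "hypo")))
}

.dir_sign <- function(d) ifelse(is.na(d), 0, ifelse(d == "hyper", 1, -1))

#' Design true methylation states with planted DMFs
#'
#' Background fragments draw a common level from a bimodal Beta mixture
#' concentrated near 0.05 and 0.95 (the bimodal hypo/hyper pattern of
#' somatic methylomes). Planted shared DMFs shift every metastatic sample by
#' +/- delta relative to its primary; private DMFs shift one pair only;
#' optional normal-to-primary shifts create the four progression patterns.
#' Shifts are applied then clipped to [0,1]; planted base levels are drawn so
#' clipping is avoided whenever the requested path fits in (0.02, 0.98).
#'
#' @param catalog `fragment_catalog` with CpGs assigned.
#' @param design A [study_design()].
#' @param planted data.frame from [planted_dmfs()] rows, or NULL for pure
#'   background.
#' @param min_cpgs_planted Minimum CpGs a fragment needs to be eligible for
#'   planting (default 2).
#' @param seed RNG seed (defaults to the design master seed).
#' @return `truth_table`: list(levels matrix fragments x samples, labels,
#'   samples, design).
#' @export
plan_methylation_states <- function(catalog, design, planted = NULL,
                                    min_cpgs_planted = 2, seed = design$seed) {
  .assert(inherits(catalog, "fragment_catalog"), "catalog must be a fragment_catalog")
  .assert(!is.null(catalog$cpgs), "catalog CpGs must be assigned first")
  .assert(inherits(design, "study_design"), "design must be a study_design")
  set.seed(seed)
  fr <- catalog$fragments
  samples <- design$samples
  nfrag <- nrow(fr)
  pair_ids <- paste0("pair", seq_len(design$n_pairs))

  labels <- data.frame(fragment_id = fr$fragment_id, label = "background",
                       scope = NA_character_, dir_normal_primary = NA_character_,
                       dir_primary_metastatic = NA_character_,
                       delta_true = NA_real_, pattern = NA_character_,
                       stringsAsFactors = FALSE)

  # bimodal background: half near full, half near none
  lo <- stats::rbeta(nfrag, 2, 38)
  hi <- stats::rbeta(nfrag, 38, 2)
  base <- ifelse(stats::runif(nfrag) < 0.5, lo, hi)

  levels <- matrix(rep(base, nrow(samples)), nrow = nfrag,
                   dimnames = list(fr$fragment_id, samples$sample_id))

  if (!is.null(planted) && nrow(planted)) {
    .assert(all(planted$delta > 0 & planted$delta <= 1),
            "planted delta must be in (0,1]")
    .assert(all(planted$scope %in% c("shared", pair_ids)),
            "planted scope must be 'shared' or a pair id")
    .assert(all(is.na(planted$step1)) || design$include_normal,
            "step1 planting requires include_normal = TRUE")
    eligible <- fr$fragment_id[fr$n_cpgs >= min_cpgs_planted]
    need <- sum(planted$n_fragments)
    .assert(need <= length(eligible), sprintf(
      "requested %d planted fragments but only %d have >= %d CpGs",
      need, length(eligible), min_cpgs_planted))
    chosen <- sample(eligible, need)
    at <- 0L
    for (i in seq_len(nrow(planted))) {
      row <- planted[i, ]
      ids <- chosen[(at + 1L):(at + row$n_fragments)]
      at <- at + row$n_fragments
      s1 <- .dir_sign(row$step1)
      s2 <- .dir_sign(row$direction)
      path <- c(0, s1 * row$delta, s1 * row$delta + s2 * row$delta)
      b_lo <- 0.02 - min(path)
      b_hi <- 0.98 - max(path)
      b <- if (b_lo <= b_hi) stats::runif(length(ids), b_lo, b_hi)
           else rep(if (max(path) > 0) 0.02 else 0.98, length(ids))
      target_pairs <- if (row$scope == "shared") pair_ids else row$scope
      idx <- match(ids, fr$fragment_id)
      if (design$include_normal) levels[idx, "normal"] <- b
      # primaries/metastatics: scoped pairs move along the path, others keep base
      for (p in pair_ids) {
        pcol <- samples$sample_id[samples$role == "primary" & samples$pair_id == p]
        mcol <- samples$sample_id[samples$role == "metastatic" & samples$pair_id == p]
        if (p %in% target_pairs) {
          levels[idx, pcol] <- b + s1 * row$delta
          levels[idx, mcol] <- b + s1 * row$delta + s2 * row$delta
        } else {
          levels[idx, c(pcol, mcol)] <- b
        }
      }
      lab <- match(ids, labels$fragment_id)
      labels$label[lab] <- if (row$scope == "shared") "dmf_shared" else "dmf_private"
      labels$scope[lab] <- row$scope
      labels$dir_normal_primary[lab] <- row$step1
      labels$dir_primary_metastatic[lab] <- row$direction
      labels$delta_true[lab] <- row$delta
      labels$pattern[lab] <- if (!is.na(row$step1) && !is.na(row$direction))
        paste0(row$step1, "-", row$direction) else NA_character_
    }
  }

  if (design$pair_jitter > 0) {
    for (p in pair_ids) {
      cols <- samples$sample_id[!is.na(samples$pair_id) & samples$pair_id == p]
      jit <- stats::rnorm(nfrag, 0, design$pair_jitter)
      levels[, cols] <- levels[, cols] + jit
    }
  }
  levels <- clip01(levels)
  structure(list(levels = levels, labels = labels, samples = samples,
                 design = design),
            class = "truth_table")
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf("truth_table: %d fragments x %d samples; planted: %s\n",
              nrow(x$levels), ncol(x$levels),
              paste(names(table(x$labels$label)), table(x$labels$label),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Simulate per-CpG bisulfite read counts
#'
#' For each CpG in each library, coverage is negative-binomial with mean
#' `coverage_mean` and dispersion `dispersion` (0 gives Poisson) and the
#' methylated count is beta-binomial around the fragment's true level
#' (dispersion 0 gives binomial). Replicate libraries are independent draws
#' from identical truth. CpGs drawing zero coverage are omitted, as in real
#' coverage files.
#'
#' @param truth A `truth_table`.
#' @param catalog The catalog the truth was planned on (CpGs assigned).
#' @param design The [study_design()].
#' @param seed RNG seed (defaults to master seed + 1).
#' @return Named list of `sample_methylome` objects, one per library;
#'   replicate libraries are suffixed `_rep2`.
#' @export
simulate_counts <- function(truth, catalog, design = truth$design,
                            seed = design$seed + 1L) {
  .assert(inherits(truth, "truth_table"), "truth must be a truth_table")
  cp <- catalog$cpgs[!is.na(catalog$cpgs$fragment_id), , drop = FALSE]
  .assert(all(cp$fragment_id %in% rownames(truth$levels)),
          "truth does not cover all catalog fragments")
  set.seed(seed)
  fidx <- match(cp$fragment_id, rownames(truth$levels))
  d <- design$dispersion
  libs <- list()
  for (si in seq_len(nrow(truth$samples))) {
    srow <- truth$samples[si, ]
    level <- truth$levels[fidx, srow$sample_id]
    n_rep <- 1L + (srow$sample_id %in% design$replicate_samples)
    for (r in seq_len(n_rep)) {
      n <- nrow(cp)
      cov <- if (d > 0) stats::rnbinom(n, size = 1 / d, mu = design$coverage_mean)
             else stats::rpois(n, design$coverage_mean)
      p <- level
      if (d > 0) {
        mid <- level > 0 & level < 1
        a <- level * (1 - d) / d
        b <- (1 - level) * (1 - d) / d
        p[mid] <- stats::rbeta(sum(mid), a[mid], b[mid])
      }
      cov <- as.integer(cov)
      meth <- as.integer(stats::rbinom(n, cov, p))
      keep <- cov > 0
      lib_id <- if (r == 1L) srow$sample_id else paste0(srow$sample_id, "_rep2")
      libs[[lib_id]] <- sample_methylome(
        sample_id = srow$sample_id, role = srow$role, pair_id = srow$pair_id,
        cpgs = data.frame(chrom = cp$chrom[keep], pos = cp$pos[keep],
                          meth = meth[keep], unmeth = cov[keep] - meth[keep],
                          stringsAsFactors = FALSE))
    }
  }
  libs
}

#' Describe a simulated array-style cohort
#'
#' Defaults mirror a large melanoma cohort: 99 primary and 359 metastatic
#' samples assayed on probes placed near the discovery DMFs.
#'
#' @param n_primary,n_metastatic Sample counts (>= 2 each).
#' @param probe_offset Fixed probe offset in bp from the fragment edge
#'   (negative = upstream of the start, positive = downstream of the end,
#'   0 = inside). NULL draws uniformly within `c(-window, window)`.
#' @param beta_noise SD of Gaussian noise on beta values (clipped to [0,1]).
#' @param n_decoy Decoy probes placed > 10 kb from any DMF.
#' @param window Maximum |offset| for a matched probe (bp).
#' @export
cohort_design <- function(n_primary = 99, n_metastatic = 359,
                          probe_offset = NULL, beta_noise = 0.05,
                          n_decoy = 50, window = 500) {
  .assert(n_primary >= 2 && n_metastatic >= 2, "cohort needs >= 2 samples per group")
  if (!is.null(probe_offset))
    .assert(all(abs(probe_offset) <= window),
            sprintf("matched probe offset must be within +/-%d bp", window))
  structure(list(n_primary = as.integer(n_primary),
                 n_metastatic = as.integer(n_metastatic),
                 probe_offset = probe_offset, beta_noise = beta_noise,
                 n_decoy = as.integer(n_decoy), window = as.integer(window)),
            class = "cohort_design")
}

#' Simulate a cohort beta matrix around planted DMFs
#'
#' One probe per selected DMF at the designed offset, with beta values drawn
#' around the group-specific true levels (primary samples around the primary
#' mean, metastatic around the metastatic mean), plus decoy probes far from
#' any DMF whose two groups share one level.
#'
#' @param truth `truth_table`.
#' @param catalog The catalog (for fragment coordinates).
#' @param cohort A [cohort_design()].
#' @param dmf_subset Fragment ids to place probes on; default all planted
#'   shared DMFs.
#' @param seed RNG seed.
#' @return `cohort_sim`: list(probes, beta matrix probes x samples, groups).
#' @export
simulate_cohort <- function(truth, catalog, cohort = cohort_design(),
                            dmf_subset = NULL, seed = truth$design$seed + 2L) {
  .assert(inherits(cohort, "cohort_design"), "cohort must be a cohort_design")
  set.seed(seed)
  fr <- catalog$fragments
  if (is.null(dmf_subset))
    dmf_subset <- truth$labels$fragment_id[truth$labels$label == "dmf_shared"]
  .assert(all(dmf_subset %in% fr$fragment_id), "unknown fragment in dmf_subset")
  sm <- truth$samples
  pri_cols <- sm$sample_id[sm$role == "primary"]
  met_cols <- sm$sample_id[sm$role == "metastatic"]
  lev_p <- rowMeans(truth$levels[dmf_subset, pri_cols, drop = FALSE])
  lev_m <- rowMeans(truth$levels[dmf_subset, met_cols, drop = FALSE])

  f <- fr[match(dmf_subset, fr$fragment_id), , drop = FALSE]
  off <- if (is.null(cohort$probe_offset))
    round(stats::runif(nrow(f), -cohort$window, cohort$window))
  else rep_len(cohort$probe_offset, nrow(f))
  .assert(all(abs(off) <= cohort$window),
          sprintf("matched probe offset must be within +/-%d bp", cohort$window))
  pos <- ifelse(off >= 0, f$end - 1L + off, f$start + off)
  probes <- data.frame(probe_id = sprintf("probe_%03d", seq_len(nrow(f))),
                       chrom = f$chrom, pos = as.integer(pos),
                       fragment_id = f$fragment_id, offset = as.integer(off),
                       stringsAsFactors = FALSE)
  # decoys: beyond the last fragment of the first chromosome, > 10 kb away
  if (cohort$n_decoy > 0) {
    chrom1 <- fr$chrom[1]
    base_pos <- max(fr$end[fr$chrom == chrom1]) + 20000L
    dec_lev <- clip01(ifelse(stats::runif(cohort$n_decoy) < 0.5,
                             stats::rbeta(cohort$n_decoy, 2, 38),
                             stats::rbeta(cohort$n_decoy, 38, 2)))
    probes <- rbind(probes, data.frame(
      probe_id = sprintf("decoy_%03d", seq_len(cohort$n_decoy)),
      chrom = chrom1, pos = base_pos + seq_len(cohort$n_decoy) * 100L,
      fragment_id = NA_character_, offset = NA_integer_,
      stringsAsFactors = FALSE))
    lev_p <- c(lev_p, dec_lev)
    lev_m <- c(lev_m, dec_lev)
  }
  samp_ids <- c(sprintf("C_P%03d", seq_len(cohort$n_primary)),
                sprintf("C_M%03d", seq_len(cohort$n_metastatic)))
  groups <- data.frame(sample_id = samp_ids,
                       group = c(rep("primary", cohort$n_primary),
                                 rep("metastatic", cohort$n_metastatic)),
                       stringsAsFactors = FALSE)
  npr <- nrow(probes)
  beta <- matrix(NA_real_, npr, length(samp_ids),
                 dimnames = list(probes$probe_id, samp_ids))
  for (j in seq_along(samp_ids)) {
    mu <- if (groups$group[j] == "primary") lev_p else lev_m
    beta[, j] <- if (cohort$beta_noise > 0)
      clip01(mu + stats::rnorm(npr, 0, cohort$beta_noise)) else mu
  }
  structure(list(probes = probes, beta = beta, groups = groups,
                 design = cohort),
            class = "cohort_sim")
}

#' Simulate expression as a monotone function of methylation
#'
#' `expression = sign * beta + Gaussian noise`; with zero noise the Spearman
#' correlation between beta and expression is exactly `sign`.
#'
#' @param beta Numeric vector of beta values.
#' @param sign +1 or -1, the planted methylation-expression direction.
#' @param noise_sd Gaussian noise SD.
#' @param seed Optional seed.
#' @export
simulate_expression <- function(beta, sign = 1, noise_sd = 0, seed = NULL) {
  .assert(sign %in% c(-1, 1), "sign must be +1 or -1")
  if (!is.null(seed)) set.seed(seed)
  sign * beta + if (noise_sd > 0) stats::rnorm(length(beta), 0, noise_sd) else 0
}

#' Simulate a cohort expression table for gene-probe links
#'
#' @param cohort A `cohort_sim`.
#' @param links data.frame(gene_id, probe_id, sign).
#' @param noise_sd Gaussian noise SD.
#' @param seed RNG seed.
#' @return Matrix genes x samples.
#' @export
simulate_expression_table <- function(cohort, links, noise_sd = 0.25,
                                      seed = 1L) {
  .assert(all(links$probe_id %in% rownames(cohort$beta)),
          "links reference unknown probe ids")
  set.seed(seed)
  expr <- t(vapply(seq_len(nrow(links)), function(i) {
    simulate_expression(cohort$beta[links$probe_id[i], ], links$sign[i], noise_sd)
  }, numeric(ncol(cohort$beta))))
  rownames(expr) <- links$gene_id
  colnames(expr) <- colnames(cohort$beta)
  expr
}

#' Write / read a truth table as versioned TSV
#'
#' Round-trips exactly: levels are written at full double precision.
#' @export
write_truth_table <- function(truth, path) {
  lev <- truth$levels
  wide <- cbind(truth$labels,
                as.data.frame(apply(lev, 2, function(x) format(x, digits = 17, trim = TRUE,
                                                               scientific = FALSE)),
                              stringsAsFactors = FALSE))
  meta <- c("dmfscreen truth_table v1",
            paste0("samples ", paste(truth$samples$sample_id,
                                     truth$samples$role,
                                     ifelse(is.na(truth$samples$pair_id), ".",
                                            truth$samples$pair_id),
                                     sep = ":", collapse = ",")))
  write_tsv_meta(wide, path, meta)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  first <- readLines(path, n = 2)
  .assert(grepl("truth_table v1", first[1]), "not a dmfscreen truth_table file")
  sam <- sub("^# samples ", "", first[2])
  parts <- strsplit(strsplit(sam, ",")[[1]], ":")
  samples <- data.frame(sample_id = vapply(parts, `[`, "", 1),
                        role = vapply(parts, `[`, "", 2),
                        pair_id = vapply(parts, `[`, "", 3),
                        stringsAsFactors = FALSE)
  samples$pair_id[samples$pair_id == "."] <- NA_character_
  df <- read_tsv_meta(path)
  label_cols <- c("fragment_id", "label", "scope", "dir_normal_primary",
                  "dir_primary_metastatic", "delta_true", "pattern")
  labels <- df[, label_cols]
  for (cc in c("scope", "dir_normal_primary", "dir_primary_metastatic", "pattern"))
    labels[[cc]] <- as.character(labels[[cc]])
  lev <- as.matrix(df[, samples$sample_id, drop = FALSE])
  storage.mode(lev) <- "double"
  rownames(lev) <- labels$fragment_id
  structure(list(levels = lev, labels = labels, samples = samples,
                 design = NULL),
            class = "truth_table")
}
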