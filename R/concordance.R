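# Validation statistics: cross-platform concordance, Bland-Altman agreement,
# cohort rank tests and methylation-expression correlation.

#' Per-CpG concordance between two platforms
#'
#' Pearson correlation over matched per-CpG methylation fractions, with the
#' two-tailed p from the t transform.
#'
#' @param pairs data.frame with `frac1`, `frac2` (and optionally `chrom`,
#'   `pos`, `amplicon_id`).
#' @return list(r, p, n).
#' @export
per_cpg_concordance <- function(pairs) {
  .assert(nrow(pairs) >= 3, "need at least 3 matched CpGs")
  ct <- stats::cor.test(pairs$frac1, pairs$frac2, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(pairs))
}

#' Per-amplicon concordance between two platforms
#'
#' CpG fractions are averaged per amplicon on each platform before the
#' Pearson correlation; averaging independent noise improves agreement.
#'
#' @param pairs data.frame with `frac1`, `frac2`, `amplicon_id`.
#' @return list(r, p, n) with n the number of amplicons.
#' @export
per_amplicon_concordance <- function(pairs) {
  m1 <- tapply(pairs$frac1, pairs$amplicon_id, mean)
  m2 <- tapply(pairs$frac2, pairs$amplicon_id, mean)
  .assert(length(m1) >= 3, "need at least 3 amplicons")
  ct <- stats::cor.test(as.numeric(m1), as.numeric(m2), method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(m1))
}

#' Bland-Altman agreement between two platforms
#'
#' Differences are platform2 - platform1; bias is their mean, `sd_bias` the
#' sample SD (n-1 denominator), and the limits of agreement are
#' `bias +/- 1.96 * sd_bias`.
#'
#' @param frac1,frac2 Paired measurements, or a data.frame with columns
#'   `frac1`/`frac2` as single argument.
#' @return list(bias, sd_bias, limit_low, limit_high, n).
#' @export
bland_altman <- function(frac1, frac2 = NULL) {
  if (is.data.frame(frac1)) {
    frac2 <- frac1$frac2
    frac1 <- frac1$frac1
  }
  .assert(length(frac1) == length(frac2), "unpaired inputs")
  .assert(length(frac1) >= 2, "need at least 2 pairs")
  d <- frac2 - frac1
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd_bias = s,
       limit_low = bias - 1.96 * s, limit_high = bias + 1.96 * s,
       n = length(d))
}

#' Mann-Whitney U test
#'
#' U counts x-over-y wins (ties half). The exact two-sided p
#' (`2 * min(P(U <= u), P(U >= u))`, capped at 1) is used when
#' `n_x + n_y <= 20` and there are no ties; otherwise a normal approximation
#' with tie correction and continuity correction. The `method` element
#' reports which path was used.
#'
#' @param x,y Non-empty numeric groups.
#' @return list(U, p, method).
#' @export
mann_whitney_u <- function(x, y) {
  nx <- length(x); ny <- length(y)
  .assert(nx >= 1 && ny >= 1, "both groups must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (nx + ny <= 20 && !ties) {
    p <- min(1, 2 * min(stats::pwilcox(U, nx, ny),
                        1 - stats::pwilcox(U - 1, nx, ny)))
    method <- "exact"
  } else {
    mu <- nx * ny / 2
    nt <- table(c(x, y))
    N <- nx + ny
    sigma2 <- nx * ny / 12 * ((N + 1) - sum(nt^3 - nt) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  list(U = U, p = p, method = method)
}

#' Shapiro-Wilk normality gate
#'
#' Annotates whether a parametric t test would have been admissible; the
#' rank test is computed regardless downstream.
#'
#' @param values Numeric vector, n >= 3.
#' @param alpha Gate level.
#' @return list(normal, p).
#' @export
shapiro_gate <- function(values, alpha = 0.05) {
  .assert(length(values) >= 3, "Shapiro-Wilk needs n >= 3")
  p <- stats::shapiro.test(values)$p.value
  list(normal = p >= alpha, p = p)
}

#' Spearman correlation between methylation and expression
#'
#' Rho over average ranks; exact two-sided p by full permutation enumeration
#' for n <= 9 without ties, t approximation otherwise.
#'
#' @param beta,expression Paired vectors, n >= 4.
#' @return list(rho, p, method).
#' @export
spearman_meth_expr <- function(beta, expression) {
  n <- length(beta)
  .assert(length(expression) == n, "unpaired inputs")
  .assert(n >= 4, "need n >= 4")
  rx <- rank(beta); ry <- rank(expression)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(beta) > 0 || anyDuplicated(expression) > 0
  if (n <= 9 && !ties) {
    rho_perm <- .spearman_null(n)
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- max(2 * stats::pt(-abs(tstat), n - 2), .Machine$double.xmin)
    method <- "t-approx"
  }
  list(rho = rho, p = p, method = method)
}

# all-permutation null distribution of Spearman rho for untied ranks
.spearman_null <- function(n) {
  perms <- .perm_matrix(n)
  s <- colSums((t(perms) - seq_len(n))^2)
  1 - 6 * s / (n * (n^2 - 1))
}

.perm_matrix <- function(n) {
  if (n == 1) return(matrix(1L))
  p <- .perm_matrix(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, p + (p >= i))))
}

#' Validate shared DMFs against an array-style cohort
#'
#' A probe matches a DMF when its single-base coordinate overlaps the
#' fragment or lies within `window` bp of either edge; a probe matching
#' several DMFs is resolved to the one with the nearest midpoint. Each
#' matched probe is tested primary vs metastatic with [mann_whitney_u()];
#' direction concordance compares the sign of the metastatic-minus-primary
#' median difference with the discovery consensus direction. A Bonferroni
#' column is emitted for transparency but raw p-values drive nothing here.
#'
#' @param dmfs data.frame(fragment_id, chrom, start, end,
#'   consensus_direction).
#' @param cohort A `cohort_sim`, or list(probes, beta, groups) of the same
#'   shape.
#' @param window Matching window in bp.
#' @param alpha Level used only for the significant flag column.
#' @return data.frame, one row per matched probe; zero rows (with a warning)
#'   when nothing matches.
#' @export
cohort_validate <- function(dmfs, cohort, window = 500, alpha = 0.05) {
  probes <- cohort$probes
  beta <- cohort$beta
  groups <- cohort$groups
  pri <- groups$sample_id[groups$group == "primary"]
  met <- groups$sample_id[groups$group == "metastatic"]
  rows <- list()
  for (i in seq_len(nrow(probes))) {
    hit <- which(probes$chrom[i] == dmfs$chrom &
                 probes$pos[i] >= dmfs$start - window &
                 probes$pos[i] <= dmfs$end - 1L + window)
    if (!length(hit)) next
    if (length(hit) > 1) {
      midd <- abs(probes$pos[i] - (dmfs$start[hit] + dmfs$end[hit]) / 2)
      hit <- hit[which.min(midd)]
    }
    x <- beta[probes$probe_id[i], pri]
    y <- beta[probes$probe_id[i], met]
    mw <- mann_whitney_u(x, y)
    dmed <- stats::median(y) - stats::median(x)
    cons <- dmfs$consensus_direction[hit]
    rows[[length(rows) + 1L]] <- data.frame(
      probe_id = probes$probe_id[i], fragment_id = dmfs$fragment_id[hit],
      median_primary = stats::median(x), median_metastatic = stats::median(y),
      U = mw$U, p = mw$p, test_method = mw$method,
      direction_concordant = (dmed > 0 && cons == "hyper") ||
        (dmed < 0 && cons == "hypo"),
      significant = mw$p < alpha, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    warning("no probes matched any DMF within the window")
    return(data.frame(probe_id = character(), fragment_id = character(),
                      median_primary = numeric(), median_metastatic = numeric(),
                      U = numeric(), p = numeric(), test_method = character(),
                      direction_concordant = logical(), significant = logical(),
                      p_bonferroni = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  rownames(out) <- NULL
  out
}

#' Simulate two platforms measuring common truth
#'
#' Utility for concordance checks: methylation is regional, so one true
#' fraction is drawn per amplicon and shared by its CpGs; each platform adds
#' independent Gaussian noise per CpG.
#'
#' @param n_cpgs Number of CpGs.
#' @param cpgs_per_amplicon Amplicon size.
#' @param noise_sd Per-platform, per-CpG noise SD.
#' @param seed RNG seed.
#' @return data.frame(chrom, pos, frac1, frac2, amplicon_id).
#' @export
simulate_platform_pair <- function(n_cpgs = 200, cpgs_per_amplicon = 10,
                                   noise_sd = 0.1, seed = 1L) {
  set.seed(seed)
  n_amp <- ceiling(n_cpgs / cpgs_per_amplicon)
  truth <- rep(stats::runif(n_amp), each = cpgs_per_amplicon)[seq_len(n_cpgs)]
  data.frame(chrom = "chr1", pos = seq_len(n_cpgs) * 50L,
             frac1 = clip01(truth + stats::rnorm(n_cpgs, 0, noise_sd)),
             frac2 = clip01(truth + stats::rnorm(n_cpgs, 0, noise_sd)),
             amplicon_id = sprintf("amp_%03d",
                                   (seq_len(n_cpgs) - 1L) %/% cpgs_per_amplicon + 1L),
             stringsAsFactors = FALSE)
}
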