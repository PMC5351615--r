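# Coverage ingestion, replicate merging, fragment methylation and
# sample-level summaries

write_cov <- function(lines) {
  path <- tempfile(fileext = ".cov")
  writeLines(lines, path)
  path
}

test_that("coverage reader converts coordinates, merges strands and guards corruption", {
  sm <- read_coverage_file(write_cov("chr1\t11\t11\t100.0000\t5\t0"),
                           "s1", "primary", "pair1")
  expect_equal(sm$cpgs$pos, 10L)
  expect_equal(sm$cpgs$meth, 5L)

  sm2 <- read_coverage_file(write_cov(c("chr1\t11\t11\t75.0000\t3\t1",
                                        "chr1\t11\t11\t50.0000\t2\t2")),
                            "s1", "primary")
  expect_equal(sm2$cpgs$meth, 5L)
  expect_equal(sm2$cpgs$unmeth, 3L)

  expect_error(read_coverage_file(write_cov("chr1\t11\t11\t50.0\t5\t0"),
                                  "s1", "primary"), "mismatch at line 1")
  expect_error(read_coverage_file(write_cov("chr1\t11\t11\tbroken\t5\t0"),
                                  "s1", "primary"), "malformed")
  expect_error(read_coverage_file(write_cov("chr1\t11\t11\t100.0\t-5\t0"),
                                  "s1", "primary"), "malformed|negative")
})

test_that("coverage files round-trip through the writer", {
  fx <- shared_fixture()
  des <- study_design(n_pairs = 1, include_normal = FALSE,
                      replicate_samples = character(), seed = 21)
  libs <- simulate_counts(plan_methylation_states(fx$catalog, des),
                          fx$catalog, des)
  path <- tempfile(fileext = ".cov")
  write_coverage_file(libs$P1, path)
  back <- read_coverage_file(path, "P1", "primary", "pair1")
  expect_identical(back$cpgs, libs$P1$cpgs)
})

test_that("replicate merging sums counts and is commutative/associative", {
  mk <- function(pos, meth, unmeth)
    sample_methylome("s", "primary", "pair1",
                     data.frame(chrom = rep("chr1", length(pos)), pos = pos,
                                meth = meth, unmeth = unmeth))
  a <- mk(c(10L, 20L), c(5L, 3L), c(5L, 1L))
  b <- mk(c(10L, 30L), c(5L, 2L), c(5L, 2L))
  ab <- merge_replicates(a, b)
  expect_equal(ab$cpgs$meth[ab$cpgs$pos == 10], 10L)
  expect_equal(ab$cpgs$unmeth[ab$cpgs$pos == 10], 10L)
  expect_equal(ab$cpgs$meth[ab$cpgs$pos == 20], 3L)  # only in a, carried through
  expect_identical(ab$cpgs, merge_replicates(b, a)$cpgs)
  cc <- mk(c(20L, 30L), c(1L, 1L), c(0L, 0L))
  expect_identical(merge_replicates(merge_replicates(a, b), cc)$cpgs,
                   merge_replicates(a, merge_replicates(b, cc))$cpgs)
  empty <- mk(integer(), integer(), integer())
  expect_identical(merge_replicates(a, empty)$cpgs, a$cpgs)
  bad <- mk(10L, 1L, 1L); bad$role <- "metastatic"
  expect_error(merge_replicates(a, bad), "metadata")
})

test_that("replicate correlation honours the coverage filter", {
  mk <- function(meth, unmeth)
    sample_methylome("s", "primary", "pair1",
                     data.frame(chrom = "chr1",
                                pos = seq_along(meth) * 10L,
                                meth = meth, unmeth = unmeth))
  a <- mk(c(0L, 5L, 10L), c(10L, 5L, 0L))
  expect_equal(replicate_correlation(a, a)$r, 1.0)
  b <- mk(c(10L, 5L, 0L), c(0L, 5L, 10L))
  expect_equal(replicate_correlation(a, b)$r, -1.0)
  thin <- mk(c(0L, 5L, 4L), c(10L, 5L, 5L))  # third CpG below 10x
  expect_error(replicate_correlation(a, thin), "need >= 3")
})

test_that("simulated replicates correlate strongly at 30x", {
  fx <- shared_fixture()
  des <- study_design(seed = 22)
  tr <- plan_methylation_states(fx$catalog, des)
  libs <- simulate_counts(tr, fx$catalog, des)
  rc <- replicate_correlation(libs$normal, libs$normal_rep2)
  expect_gte(rc$r, 0.9)
  expect_gt(rc$n_common, 1000)
})

test_that("fragment analysability requires >= min_cpgs CpGs at >= cov_min reads", {
  cat0 <- manual_catalog(
    data.frame(fragment_id = "f1", chrom = "chr1", start = 0L, end = 100L),
    data.frame(chrom = "chr1", pos = c(10L, 20L, 30L), fragment_id = "f1"))
  mk <- function(cov, meth = pmin(cov, 1L))
    sample_methylome("s", "primary", "pair1",
                     data.frame(chrom = "chr1", pos = c(10L, 20L, 30L)[cov > 0],
                                meth = meth[cov > 0],
                                unmeth = (cov - meth)[cov > 0]))
  ok <- fragment_methylation(mk(c(12L, 11L, 0L)), cat0)
  expect_equal(nrow(ok), 1L)
  expect_equal(ok$n_cpgs_covered, 2L)
  expect_equal(nrow(fragment_methylation(mk(c(12L, 9L, 0L)), cat0)), 0L)

  # pooled level over all covered CpGs: (8,2) + (6,4) -> 14/20
  pool <- fragment_methylation(
    sample_methylome("s", "primary", "pair1",
                     data.frame(chrom = "chr1", pos = c(10L, 20L),
                                meth = c(8L, 6L), unmeth = c(2L, 4L))), cat0)
  expect_equal(pool$level, 0.7)
  expect_equal(pool$pooled_meth, 14L)
})

test_that("merged replicates pool to the sum of per-replicate pooled counts", {
  fx <- shared_fixture()
  des <- study_design(seed = 23)
  libs <- simulate_counts(plan_methylation_states(fx$catalog, des),
                          fx$catalog, des)
  fa <- fragment_methylation(libs$normal, fx$catalog)
  fb <- fragment_methylation(libs$normal_rep2, fx$catalog)
  fm <- fragment_methylation(merge_replicates(libs$normal, libs$normal_rep2),
                             fx$catalog)
  both <- intersect(fa$fragment_id, fb$fragment_id)
  expect_equal(fm$pooled_meth[match(both, fm$fragment_id)],
               fa$pooled_meth[match(both, fa$fragment_id)] +
                 fb$pooled_meth[match(both, fb$fragment_id)])
})

test_that("global mean methylation averages per-CpG fractions in percent", {
  mk <- function(meth, unmeth)
    sample_methylome("s", "primary", "pair1",
                     data.frame(chrom = "chr1", pos = seq_along(meth) * 10L,
                                meth = meth, unmeth = unmeth))
  expect_equal(global_mean_methylation(mk(c(10L, 12L), c(0L, 0L))), 100)
  expect_equal(global_mean_methylation(mk(c(10L, 0L), c(0L, 10L))), 50)
  expect_error(global_mean_methylation(mk(3L, 3L)), "no CpGs")
  # simulator: uniform truth 0.47 at 50x recovers 47 +/- 1
  fx <- shared_fixture()
  des <- study_design(n_pairs = 1, include_normal = FALSE,
                      replicate_samples = character(), coverage_mean = 50,
                      dispersion = 0, seed = 24)
  tr <- plan_methylation_states(fx$catalog, des)
  tr$levels[] <- 0.47
  libs <- simulate_counts(tr, fx$catalog, des)
  expect_lt(abs(global_mean_methylation(libs$P1) - 47), 1)
})

test_that("methylation histogram uses half-open bins with the last closed", {
  tab <- data.frame(level = c(0, 0, 0))
  h <- methylation_histogram(tab)
  expect_equal(h$count[1], 3L)
  expect_equal(sum(h$count), 3L)
  h2 <- methylation_histogram(data.frame(level = c(0.05, 1.0, 1.0)), n_bins = 20)
  expect_equal(h2$count[20], 2L)  # level 1 falls in the closed last bin
  expect_error(methylation_histogram(data.frame(level = numeric())), "empty")
  # bimodal background puts its mass in the outer bins
  fx <- shared_fixture()
  des <- study_design(n_pairs = 1, include_normal = FALSE,
                      replicate_samples = character(), seed = 25)
  libs <- simulate_counts(plan_methylation_states(fx$catalog, des),
                          fx$catalog, des)
  hb <- methylation_histogram(fragment_methylation(libs$P1, fx$catalog))
  outer <- sum(hb$count[c(1, 2, 19, 20)])
  expect_gt(outer / sum(hb$count), 0.6)
})

test_that("clustering pairs each primary with its own metastatic sample", {
  fx <- shared_fixture()
  des <- study_design(pair_jitter = 0.08, seed = 26)
  libs <- simulate_counts(plan_methylation_states(fx$catalog, des),
                          fx$catalog, des)
  main <- libs[c("normal", "P1", "P2", "P3", "M1", "M2", "M3")]
  hc <- cluster_samples(main)
  m <- stats::cutree(hc, k = 4)
  for (i in 1:3)
    expect_equal(m[[paste0("P", i)]], m[[paste0("M", i)]])
  expect_equal(length(unique(m[c("P1", "P2", "P3", "normal")])), 4L)
  # identical samples merge first at distance ~0
  dup <- libs$P1; dup$sample_id <- "P1copy"
  hc2 <- cluster_samples(c(main, list(dup)))
  first <- hc2$labels[-hc2$merge[1, ]]
  expect_setequal(first, c("P1", "P1copy"))
  # two samples: a single merge
  hc3 <- cluster_samples(libs[c("P1", "M1")])
  expect_equal(nrow(hc3$merge), 1L)
  # newick export round-trips through ape
  path <- tempfile(fileext = ".nwk")
  write_newick(hc, path)
  expect_setequal(ape::read.tree(path)$tip.label, names(main))
})

test_that("element classes follow promoter > gene body > intergenic precedence", {
  mk <- sample_methylome("s", "primary", "pair1",
                         data.frame(chrom = "chr1",
                                    pos = c(500L, 3000L, 9000L),
                                    meth = c(10L, 10L, 0L),
                                    unmeth = c(0L, 0L, 10L)))
  none <- element_distribution(mk, NULL)
  expect_equal(none$n_cpgs[none$class == "intergenic"], 3L)
  genes <- data.frame(chrom = "chr1", start = c(2000L, 2500L), end = c(4000L, 3500L),
                      strand = c("+", "+"), gene_id = c("g1", "g2"))
  # CpG at 500 sits in g1's promoter window ([-2000,+500) of TSS 2000) while
  # inside no gene; CpG at 3000 is offset +500 from g2's TSS -- outside the
  # half-open promoter window, so the gene bodies claim it
  ed <- element_distribution(mk, genes)
  expect_equal(ed$n_cpgs[ed$class == "promoter"], 1L)
  expect_equal(ed$n_cpgs[ed$class == "gene_body"], 1L)
  expect_equal(ed$n_cpgs[ed$class == "intergenic"], 1L)
  expect_equal(ed$mean_methylation[ed$class == "intergenic"], 0)
})
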