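# Cross-pair intersection, direction consistency, progression patterns,
# annotation and gene association

mk_dmfs <- function(ids, direction = "hyper", sig = TRUE, pair = "pairX") {
  n <- length(ids)
  data.frame(fragment_id = ids, chrom = "chr1",
             start = as.integer(seq_len(n) * 1000L),
             end = as.integer(seq_len(n) * 1000L + 100L), pair_id = pair,
             comparison = "primary_vs_metastatic", level_a = 0.2, level_b = 0.7,
             delta = ifelse(direction == "hyper", 0.5, -0.5),
             p = 1e-9, p_adj = 1e-6,
             direction = direction, significant = sig, stringsAsFactors = FALSE)
}

test_that("pairwise overlap and shared-in-all behave on degenerate sets", {
  d1 <- mk_dmfs(paste0("f", 1:10), pair = "pair1")
  d2 <- mk_dmfs(paste0("g", 1:10), pair = "pair2")
  sc <- intersect_dmfs(list(pair1 = d1, pair2 = d2))
  expect_equal(sum(sc$shared$in_all), 0L)
  expect_equal(sc$pairwise_overlap["pair1", "pair2"], 0)

  sc2 <- intersect_dmfs(list(pair1 = d1, pair2 = mk_dmfs(paste0("f", 1:10), pair = "pair2")))
  expect_equal(sc2$pairwise_overlap["pair1", "pair2"], 100)
  expect_equal(sum(sc2$shared$in_all), 10L)
  expect_equal(sc2$direction_consistency["pair1", "pair2"], 100)

  # empty significant set: shared-in-all empty, not an error
  d0 <- mk_dmfs("f1", sig = FALSE, pair = "pair2")
  sc3 <- intersect_dmfs(list(pair1 = d1, pair2 = d0))
  expect_equal(sum(sc3$shared$in_all), 0L)

  # order independence
  d3 <- mk_dmfs(paste0("f", 5:14), pair = "pair3")
  a <- intersect_dmfs(list(pair1 = d1, pair2 = d2, pair3 = d3))
  b <- intersect_dmfs(list(pair3 = d3, pair1 = d1, pair2 = d2))
  expect_setequal(a$shared$fragment_id[a$shared$in_all],
                  b$shared$fragment_id[b$shared$in_all])
  expect_equal(a$pairwise_overlap["pair1", "pair3"],
               b$pairwise_overlap["pair1", "pair3"])
})

test_that("direction-consistent sets exclude mixed fragments and stay disjoint", {
  d1 <- mk_dmfs(c("f1", "f2"), c("hyper", "hyper"), pair = "pair1")
  d2 <- mk_dmfs(c("f1", "f2"), c("hyper", "hyper"), pair = "pair2")
  d3 <- mk_dmfs(c("f1", "f2"), c("hyper", "hypo"), pair = "pair3")
  sc <- intersect_dmfs(list(pair1 = d1, pair2 = d2, pair3 = d3))
  cd <- common_direction_dmfs(sc$shared)
  expect_equal(cd$hyper_in_all, "f1")
  expect_equal(length(cd$hypo_in_all), 0L)  # f2 is mixed: excluded from both
  expect_equal(sc$shared$consensus_direction[sc$shared$fragment_id == "f2"],
               "mixed")
  expect_length(intersect(cd$hyper_in_all, cd$hypo_in_all), 0)
  all_hyper <- common_direction_dmfs(
    intersect_dmfs(list(pair1 = d1, pair2 = d2))$shared)
  expect_setequal(all_hyper$hyper_in_all, c("f1", "f2"))
})

test_that("progression patterns pair the two step directions", {
  np <- list(pair1 = mk_dmfs(c("f1", "f2", "f3"), c("hyper", "hyper", "hypo"),
                             sig = c(TRUE, TRUE, FALSE), pair = "pair1"))
  pm <- list(pair1 = mk_dmfs(c("f1", "f2", "f4"), c("hyper", "hypo", "hyper"),
                             pair = "pair1"))
  pt <- classify_progression_pattern(np, pm)
  expect_equal(nrow(pt), 2L)  # f3 and f4 significant in only one step
  expect_equal(pt$pattern[pt$fragment_id == "f1"], "hyper-hyper")
  expect_equal(pt$pattern[pt$fragment_id == "f2"], "hyper-hypo")
})

test_that("overlap fractions are exact and monotone in the track", {
  set <- data.frame(fragment_id = paste0("f", 1:100), chrom = "chr1",
                    start = seq(0L, by = 1000L, length.out = 100))
  set$end <- set$start + 100L
  genome_track <- data.frame(chrom = "chr1", start = 0L, end = 200000L)
  empty_track <- data.frame(chrom = character(), start = integer(), end = integer())
  sine31 <- data.frame(chrom = "chr1", start = set$start[1:31] + 50L,
                       end = set$start[1:31] + 60L)
  fr <- feature_overlap_fractions(set, list(all = genome_track,
                                            none = empty_track, SINE = sine31))
  expect_equal(unname(fr["all"]), 1.0)
  expect_equal(unname(fr["none"]), 0.0)
  expect_identical(unname(fr["SINE"]), 0.31)
  # adding intervals can only increase the fraction
  more <- rbind(sine31, data.frame(chrom = "chr1", start = set$start[32] + 1L,
                                   end = set$start[32] + 2L))
  expect_gte(feature_overlap_fractions(set, list(SINE = more))[["SINE"]],
             fr[["SINE"]])
})

test_that("annotation assigns gene, CpG-island and repeat context with precedence", {
  genes <- data.frame(chrom = "chr1", start = 10000L, end = 20000L,
                      strand = "+", gene_id = "EBF3like")
  exons <- data.frame(chrom = "chr1", start = c(10000L, 15000L),
                      end = c(10500L, 15500L), strand = "+",
                      gene_id = "EBF3like")
  cgi <- data.frame(chrom = "chr1", start = 9900L, end = 10300L)
  reps <- data.frame(chrom = "chr1", start = c(40000L, 40050L),
                     end = c(40100L, 40120L), class = c("SINE", "LINE"))
  frs <- data.frame(
    fragment_id = c("promoter_993", "exonic", "intronic", "island_edge",
                    "shore_frag", "far_frag"),
    chrom = "chr1",
    start = c(9000L, 15100L, 12000L, 10250L, 10300L, 40000L),
    end   = c(9014L, 15200L, 12100L, 10350L, 10400L, 40100L))
  ann <- annotate_dmfs(frs, list(genes = genes, exons = exons), cgi = cgi,
                       repeats = reps)
  a <- function(id, col) ann[[col]][ann$fragment_id == id]
  # midpoint (9000+9014)/2 = 9007 -> 993 bp upstream of TSS 10000
  expect_equal(a("promoter_993", "gene_context"), "promoter")
  expect_equal(a("promoter_993", "dist_tss"), -993)
  expect_equal(a("promoter_993", "nearest_gene"), "EBF3like")
  expect_equal(a("exonic", "gene_context"), "exon")
  expect_equal(a("intronic", "gene_context"), "intron")
  expect_equal(a("island_edge", "cgi_context"), "island_core")
  # fragment starting exactly at the island end: 0 bp gap -> shore
  expect_equal(a("shore_frag", "cgi_context"), "shore")
  expect_equal(a("far_frag", "cgi_context"), "open_sea")
  expect_equal(a("far_frag", "repeat_classes"), "LINE,SINE")
  expect_equal(a("far_frag", "gene_context"), "intergenic")
  # every fragment gets exactly one context of each kind
  expect_true(all(ann$gene_context %in%
                    c("promoter", "exon", "intron", "gene_body", "intergenic")))
  expect_true(all(ann$cgi_context %in% c("island_core", "shore", "open_sea")))
  # shore width is respected
  ann2 <- annotate_dmfs(frs, NULL, cgi = cgi, shore_width = 50)
  expect_equal(ann2$cgi_context[ann2$fragment_id == "shore_frag"], "shore")
  far <- data.frame(fragment_id = "f", chrom = "chr1",
                    start = 10300L + 51L, end = 10300L + 151L)
  expect_equal(annotate_dmfs(far, NULL, cgi = cgi, shore_width = 50)$cgi_context,
               "open_sea")
})

test_that("gene association groups DMFs and honours the distance cap", {
  genes <- data.frame(chrom = "chr1", start = 100000L, end = 150000L,
                      strand = "+", gene_id = "g1")
  frs <- data.frame(fragment_id = c("i1", "i2", "up22k"),
                    chrom = "chr1",
                    start = c(120000L, 130000L, 100000L - 22000L - 50L),
                    end = c(120100L, 130100L, 100000L - 22000L + 50L))
  ann <- annotate_dmfs(frs, genes)
  ann$direction <- c("hypo", "hypo", "hyper")
  res <- associate_genes(ann, distance_cap = 50000)
  g1 <- res$genes[res$genes$gene_id == "g1", ]
  expect_equal(g1$n_dmfs, 3L)
  expect_equal(g1$consensus_direction, "mixed")
  # 22 kb upstream: assigned under a 50 kb cap, unassigned under 10 kb
  res10 <- associate_genes(ann, distance_cap = 10000)
  expect_true("up22k" %in% res10$unassigned)
  expect_equal(res10$genes$n_dmfs, 2L)
  expect_equal(res10$genes$consensus_direction, "hypo")
})
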