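# Annotation of DMFs against gene models, CpG islands/shores, repeats and
# user-supplied regulatory-feature tracks. All intervals are 0-based
# half-open on the package side; rtracklayer converts standard formats.

.intervals_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
}

#' Read a BED3/BED6 track into a 0-based interval table
#'
#' @param path BED file.
#' @return data.frame(chrom, start, end[, name]).
#' @export
read_bed_track <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  if (!is.null(gr$name)) out$name <- gr$name
  out
}

#' Read gene models from a GTF file
#'
#' @param path GTF with `gene` (or transcript) and `exon` records.
#' @return list(genes, exons) of 0-based interval tables with `strand` and
#'   `gene_id`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "GTF")
  to_df <- function(g) data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
                                  start = GenomicRanges::start(g) - 1L,
                                  end = GenomicRanges::end(g),
                                  strand = as.character(GenomicRanges::strand(g)),
                                  gene_id = g$gene_id, stringsAsFactors = FALSE)
  genes <- gr[gr$type == "gene"]
  if (!length(genes)) genes <- gr[gr$type == "transcript"]
  .assert(length(genes) > 0, sprintf("no gene/transcript records in %s", path))
  exons <- gr[gr$type == "exon"]
  list(genes = to_df(genes),
       exons = if (length(exons)) to_df(exons) else NULL)
}

#' Annotate fragments with gene, CpG-island and repeat context
#'
#' Gene context uses any-overlap with precedence promoter > exon > intron >
#' intergenic (exon/intron collapse to "gene_body" when no exon table is
#' given). The CpG-island context is `island_core` for any overlap with an
#' island, `shore` within `shore_width` bp of an island without overlapping,
#' else `open_sea`. Distance to TSS is the signed strand-aware offset of the
#' fragment midpoint (negative = upstream); the nearest gene is the
#' promoter/body gene when there is one, otherwise the gene with the closest
#' TSS.
#'
#' @param fragments data.frame(fragment_id, chrom, start, end).
#' @param gene_models list(genes, exons) as from [read_gene_models()], or a
#'   plain genes data.frame, or NULL.
#' @param cgi CpG-island interval table (chrom, start, end) or NULL.
#' @param repeats Repeat track (chrom, start, end, class) or NULL.
#' @param shore_width Shore width in bp.
#' @param promoter_window Window around the TSS, bases, default
#'   `c(-2000, 500)`.
#' @return data.frame(fragment_id, gene_context, nearest_gene, dist_tss,
#'   cgi_context, repeat_classes).
#' @export
annotate_dmfs <- function(fragments, gene_models = NULL, cgi = NULL,
                          repeats = NULL, shore_width = 2000,
                          promoter_window = c(-2000, 500)) {
  n <- nrow(fragments)
  fr_gr <- .intervals_gr(fragments)
  mid <- floor((fragments$start + fragments$end) / 2)

  gene_context <- rep("intergenic", n)
  nearest_gene <- rep(NA_character_, n)
  dist_tss <- rep(NA_real_, n)
  genes <- if (is.list(gene_models) && !is.data.frame(gene_models))
    gene_models$genes else gene_models
  exons <- if (is.list(gene_models) && !is.data.frame(gene_models))
    gene_models$exons else NULL
  if (!is.null(genes) && nrow(genes)) {
    if (anyDuplicated(genes$gene_id))
      stop(sprintf("duplicate gene model record: %s",
                   genes$gene_id[duplicated(genes$gene_id)][1]), call. = FALSE)
    g_gr <- .genes_gr(genes)
    prom <- GenomicRanges::trim(
      GenomicRanges::promoters(g_gr, upstream = -promoter_window[1],
                               downstream = promoter_window[2]))
    tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
    sgn <- ifelse(genes$strand == "-", -1L, 1L)
    in_body <- IRanges::overlapsAny(fr_gr, g_gr, ignore.strand = TRUE)
    gene_context[in_body] <- if (is.null(exons)) "gene_body" else "intron"
    if (!is.null(exons) && nrow(exons)) {
      e_gr <- .intervals_gr(exons)
      gene_context[IRanges::overlapsAny(fr_gr, e_gr, ignore.strand = TRUE)] <- "exon"
    }
    prom_hits <- GenomicRanges::findOverlaps(fr_gr, prom, ignore.strand = TRUE)
    gene_context[unique(S4Vectors::queryHits(prom_hits))] <- "promoter"
    body_hits <- GenomicRanges::findOverlaps(fr_gr, g_gr, ignore.strand = TRUE)
    for (i in seq_len(n)) {
      same <- which(genes$chrom == fragments$chrom[i])
      if (!length(same)) next
      dists <- (mid[i] - tss[same]) * sgn[same]
      cand <- same
      hit <- S4Vectors::subjectHits(prom_hits)[S4Vectors::queryHits(prom_hits) == i]
      if (!length(hit))
        hit <- S4Vectors::subjectHits(body_hits)[S4Vectors::queryHits(body_hits) == i]
      if (length(hit)) cand <- hit
      dists <- (mid[i] - tss[cand]) * sgn[cand]
      k <- which.min(abs(dists))
      nearest_gene[i] <- genes$gene_id[cand[k]]
      dist_tss[i] <- dists[k]
    }
  }

  cgi_context <- rep("open_sea", n)
  if (!is.null(cgi) && nrow(cgi)) {
    c_gr <- .intervals_gr(cgi)
    core <- IRanges::overlapsAny(fr_gr, c_gr)
    d <- GenomicRanges::distanceToNearest(fr_gr, c_gr)
    dist <- rep(Inf, n)
    dist[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
    cgi_context[!core & dist <= shore_width] <- "shore"
    cgi_context[core] <- "island_core"
  }

  repeat_classes <- rep("", n)
  if (!is.null(repeats) && nrow(repeats)) {
    r_gr <- .intervals_gr(repeats)
    hits <- GenomicRanges::findOverlaps(fr_gr, r_gr)
    if (length(hits)) {
      cls <- tapply(repeats$class[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits),
                    function(x) paste(sort(unique(x)), collapse = ","))
      repeat_classes[as.integer(names(cls))] <- unname(cls)
    }
  }

  data.frame(fragment_id = fragments$fragment_id, gene_context = gene_context,
             nearest_gene = nearest_gene, dist_tss = dist_tss,
             cgi_context = cgi_context, repeat_classes = repeat_classes,
             stringsAsFactors = FALSE)
}

#' Fraction of a DMF set overlapping each feature track
#'
#' Any-overlap (>= 1 bp); values on a 0-1 scale, one per named track.
#'
#' @param dmf_set data.frame(fragment_id, chrom, start, end).
#' @param tracks Named list of interval tables (chrom, start, end).
#' @return Named numeric vector of fractions.
#' @export
feature_overlap_fractions <- function(dmf_set, tracks) {
  .assert(!is.null(names(tracks)) && all(nzchar(names(tracks))),
          "tracks must be named")
  if (!nrow(dmf_set)) return(setNames(rep(NA_real_, length(tracks)), names(tracks)))
  fr_gr <- .intervals_gr(dmf_set)
  vapply(tracks, function(tr) {
    if (is.null(tr) || !nrow(tr)) return(0)
    mean(IRanges::overlapsAny(fr_gr, .intervals_gr(tr)))
  }, numeric(1))
}

#' Summarise annotated DMFs per gene
#'
#' Groups DMFs by nearest gene; intergenic DMFs whose TSS distance exceeds
#' `distance_cap` are reported unassigned.
#'
#' @param annotation [annotate_dmfs()] output, optionally with a `direction`
#'   column.
#' @param distance_cap Maximum |distance to TSS| in bp for assigning an
#'   intergenic DMF to its nearest gene.
#' @return list(genes = data.frame(gene_id, n_dmfs, contexts,
#'   consensus_direction), unassigned = fragment ids).
#' @export
associate_genes <- function(annotation, distance_cap = 50000) {
  assigned <- !is.na(annotation$nearest_gene) &
    (annotation$gene_context != "intergenic" |
       abs(annotation$dist_tss) <= distance_cap)
  a <- annotation[assigned, , drop = FALSE]
  genes <- if (nrow(a)) {
    sp <- split(a, a$nearest_gene)
    do.call(rbind, lapply(names(sp), function(g) {
      d <- sp[[g]]
      cons <- if ("direction" %in% names(d)) {
        u <- unique(d$direction)
        if (length(u) == 1) u else "mixed"
      } else NA_character_
      data.frame(gene_id = g, n_dmfs = nrow(d),
                 contexts = paste(sort(unique(d$gene_context)), collapse = ","),
                 consensus_direction = cons, stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(gene_id = character(), n_dmfs = integer(),
               contexts = character(), consensus_direction = character(),
               stringsAsFactors = FALSE)
  }
  rownames(genes) <- NULL
  list(genes = genes, unassigned = annotation$fragment_id[!assigned])
}
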