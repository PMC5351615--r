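# In-silico MspI digestion: the fragment catalog that defines the unit of
# analysis for fragment-based RRBS methylomes.
#
# Coordinates are 0-based half-open throughout the package; file readers and
# writers convert at the boundary (Bismark coverage is 1-based).

.as_dna <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    seqs <- genome
  } else if (is.character(genome)) {
    .assert(length(genome) > 0, "empty sequence set")
    .assert(!is.null(names(genome)) && all(nzchar(names(genome))),
            "sequences must be named by chromosome")
    bad <- grepl("[^ACGTNacgtn]", genome)
    .assert(!any(bad), sprintf("sequence '%s' contains letters outside A/C/G/T/N",
                               names(genome)[bad][1]))
    seqs <- Biostrings::DNAStringSet(toupper(genome))
  } else {
    stop("genome must be a named character vector or a DNAStringSet")
  }
  .assert(length(seqs) > 0, "empty sequence set")
  seqs
}

#' Digest genome sequences with MspI in silico
#'
#' MspI recognises CCGG and cuts C^CGG, so every CCGG occurrence on the
#' forward strand places a cut at `offset + 1` (0-based). Fragments are the
#' intervals between consecutive cuts; chromosome-terminal pieces (which have
#' only one cut end) are excluded. The recognition site is palindromic, so a
#' single forward-strand scan captures both strands.
#'
#' @param genome Named character vector of sequences (A/C/G/T/N,
#'   case-insensitive) or a [Biostrings::DNAStringSet].
#' @param genome_id Label stored in the catalog.
#' @return A `fragment_catalog`: list with `fragments` (data.frame with
#'   `fragment_id`, `chrom`, `start`, `end`, `length`, `n_cpgs`), `cpgs`
#'   (NULL until [assign_cpgs_to_fragments()] is run), `genome_id`,
#'   `size_min`, `size_max`.
#' @examples
#' cat <- digest_genome(c(chrA = "TTCCGGAATTCCGGTT"))
#' cat$fragments # one fragment [3,11)
#' @export
digest_genome <- function(genome, genome_id = "genome") {
  seqs <- .as_dna(genome)
  frags <- lapply(seq_along(seqs), function(i) {
    chrom <- names(seqs)[i]
    hits <- Biostrings::matchPattern("CCGG", seqs[[i]], fixed = TRUE)
    cuts <- (Biostrings::start(hits) - 1L) + 1L   # 0-based cut coordinates
    if (length(cuts) < 2L) {
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE))
    }
    data.frame(chrom = chrom,
               start = cuts[-length(cuts)],
               end   = cuts[-1L],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, frags)
  if (is.null(df) || nrow(df) == 0L) {
    df <- data.frame(chrom = character(), start = integer(), end = integer(),
                     stringsAsFactors = FALSE)
  }
  df$length <- df$end - df$start
  df$fragment_id <- if (nrow(df)) sprintf("%s:%d-%d", df$chrom, df$start, df$end) else character()
  df$n_cpgs <- rep(NA_integer_, nrow(df))
  df <- df[, c("fragment_id", "chrom", "start", "end", "length", "n_cpgs")]
  rownames(df) <- NULL
  structure(list(fragments = df, cpgs = NULL, genome_id = genome_id,
                 size_min = NA_integer_, size_max = NA_integer_),
            class = "fragment_catalog")
}

#' @export
print.fragment_catalog <- function(x, ...) {
  cat(sprintf("fragment_catalog '%s': %d fragments", x$genome_id, nrow(x$fragments)))
  if (!is.na(x$size_min)) cat(sprintf(" (size-filtered to [%d,%d] bp)", x$size_min, x$size_max))
  cat(sprintf("; CpGs %s\n", if (is.null(x$cpgs)) "unassigned" else "assigned"))
  invisible(x)
}

#' Retain fragments within a size window
#'
#' RRBS analyses restrict to fragments in a length band (40-220 bp by
#' default); bounds are inclusive.
#'
#' @param catalog A `fragment_catalog`.
#' @param min_len,max_len Inclusive length bounds in bp.
#' @export
filter_fragments_by_size <- function(catalog, min_len = 40, max_len = 220) {
  .assert(inherits(catalog, "fragment_catalog"), "not a fragment_catalog")
  .assert(min_len <= max_len, "min_len must be <= max_len")
  keep <- catalog$fragments$length >= min_len & catalog$fragments$length <= max_len
  catalog$fragments <- catalog$fragments[keep, , drop = FALSE]
  rownames(catalog$fragments) <- NULL
  if (!is.null(catalog$cpgs)) {
    catalog$cpgs <- catalog$cpgs[is.na(catalog$cpgs$fragment_id) |
                                 catalog$cpgs$fragment_id %in% catalog$fragments$fragment_id, ,
                                 drop = FALSE]
    rownames(catalog$cpgs) <- NULL
  }
  catalog$size_min <- as.integer(min_len)
  catalog$size_max <- as.integer(max_len)
  catalog
}

#' Locate CpG dinucleotides
#'
#' Returns the 0-based offset of the C of every CG dinucleotide on the
#' forward strand, per chromosome. Reads reported on the reverse-strand G are
#' collapsed onto this C position at coverage-read time, the usual RRBS
#' convention. N breaks a match.
#'
#' @inheritParams digest_genome
#' @return Named list of sorted integer vectors.
#' @export
locate_cpgs <- function(genome) {
  seqs <- .as_dna(genome)
  out <- lapply(seq_along(seqs), function(i) {
    hits <- Biostrings::matchPattern("CG", seqs[[i]], fixed = TRUE)
    as.integer(Biostrings::start(hits) - 1L)
  })
  names(out) <- names(seqs)
  out
}

#' Assign CpG sites to catalog fragments
#'
#' Each CpG is assigned to the unique fragment whose half-open interval
#' contains its C offset; CpGs outside every fragment stay unassigned
#' (`fragment_id` NA). Overlapping fragments violate the catalog invariant
#' and raise an error.
#'
#' @param cpgs Named list of per-chromosome 0-based C offsets, as returned by
#'   [locate_cpgs()].
#' @param catalog A `fragment_catalog`.
#' @return The catalog with `cpgs` populated and per-fragment `n_cpgs` counts.
#' @export
assign_cpgs_to_fragments <- function(cpgs, catalog) {
  .assert(inherits(catalog, "fragment_catalog"), "not a fragment_catalog")
  fr <- catalog$fragments
  rows <- lapply(names(cpgs), function(chrom) {
    pos <- sort(as.integer(cpgs[[chrom]]))
    if (!length(pos)) return(NULL)
    f <- fr[fr$chrom == chrom, , drop = FALSE]
    fid <- rep(NA_character_, length(pos))
    if (nrow(f)) {
      f <- f[order(f$start), , drop = FALSE]
      if (nrow(f) > 1L && any(f$start[-1L] < f$end[-nrow(f)]))
        stop(sprintf("overlapping fragments on %s", chrom), call. = FALSE)
      idx <- findInterval(pos, f$start)
      hit <- idx > 0L
      hit[hit] <- pos[hit] < f$end[idx[hit]]
      fid[hit] <- f$fragment_id[idx[hit]]
    }
    data.frame(chrom = chrom, pos = pos, fragment_id = fid,
               stringsAsFactors = FALSE)
  })
  cp <- do.call(rbind, rows)
  if (is.null(cp)) cp <- data.frame(chrom = character(), pos = integer(),
                                    fragment_id = character(), stringsAsFactors = FALSE)
  rownames(cp) <- NULL
  catalog$cpgs <- cp
  counts <- table(cp$fragment_id[!is.na(cp$fragment_id)])
  catalog$fragments$n_cpgs <- as.integer(counts[catalog$fragments$fragment_id])
  catalog$fragments$n_cpgs[is.na(catalog$fragments$n_cpgs)] <- 0L
  catalog
}

#' Build a fully annotated catalog from a genome
#'
#' Convenience wrapper: digest, size-filter and assign CpGs in one call.
#' @inheritParams digest_genome
#' @inheritParams filter_fragments_by_size
#' @export
build_catalog <- function(genome, min_len = 40, max_len = 220, genome_id = "genome") {
  cat <- digest_genome(genome, genome_id = genome_id)
  cat <- filter_fragments_by_size(cat, min_len, max_len)
  assign_cpgs_to_fragments(locate_cpgs(genome), cat)
}

#' Write a fragment catalog as BED6
#'
#' Columns: chrom, start, end, fragment id, length (score), "+".
#' @export
write_catalog_bed <- function(catalog, path) {
  fr <- catalog$fragments
  bed <- data.frame(fr$chrom, fr$start, fr$end, fr$fragment_id, fr$length, "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a multi-record FASTA file
#'
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write sequences to FASTA
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}
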