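# In-silico digestion: reference genomes into fragment maps, concatemer reads
# into segments. Coordinates are 0-based half-open throughout; conversion to
# 1-based happens only at serialization boundaries.

#' Digest a reference genome into a fragment map
#'
#' Cuts every chromosome at the enzyme's cut sites and returns the resulting
#' fragment tiling. Fragments per chromosome cover the sequence exactly:
#' first start = 0, last end = chromosome length, adjacent fragments abut, and
#' the fragment count equals the number of cut sites + 1.
#'
#' @param genome FASTA path, `DNAStringSet`, or named character vector.
#' @param enzyme a [restriction_enzyme()] or built-in name.
#' @return a `data.table` (class `cifi_fragment_map`) with columns `chrom`
#'   (factor, genome order), `start`, `end` (0-based half-open), and a
#'   genome-wide 0-based `fragment_index`. Attribute `chromsizes` carries the
#'   named chromosome lengths.
#' @export
digest_genome <- function(genome, enzyme) {
  enzyme <- as_enzyme(enzyme)
  g <- as_genome(genome)
  per_chrom <- lapply(names(g), function(cn) {
    cuts <- find_cut_sites(g[[cn]], enzyme)
    L <- nchar(g[[cn]])
    edges <- c(0L, cuts, L)
    data.table::data.table(chrom = cn,
                           start = edges[-length(edges)],
                           end = edges[-1])
  })
  fm <- data.table::rbindlist(per_chrom)
  fm[, chrom := factor(chrom, levels = names(g))]
  fm[, fragment_index := seq_len(.N) - 1L]
  data.table::setattr(fm, "chromsizes", stats::setNames(nchar(g), names(g)))
  data.table::setattr(fm, "enzyme", enzyme)
  data.table::setattr(fm, "class", c("cifi_fragment_map", class(fm)))
  fm[]
}

#' Split one concatemer read at cut sites
#'
#' Partitions the read sequence at every cut site of the enzyme. All segments
#' are returned (so their concatenation reconstructs the read exactly);
#' segments shorter than `min_segment_length` carry `filtered = TRUE` and are
#' excluded from downstream pairing but kept for the partition invariant.
#' Ordinals count all segments, filtered or not.
#'
#' @param read_id read identifier.
#' @param sequence read sequence (DNA string).
#' @param enzyme a [restriction_enzyme()] or built-in name.
#' @param min_segment_length minimum segment length in bp (default 20, below
#'   any mappable length; prevents zero-information slivers).
#' @return `data.table` with columns `read_id`, `ordinal` (0-based),
#'   `read_start`, `read_end` (0-based half-open), `sequence`, `filtered`.
#'   Empty sequence returns a zero-row table with attribute `n_empty = 1`.
#' @export
digest_read <- function(read_id, sequence, enzyme, min_segment_length = 20L) {
  enzyme <- as_enzyme(enzyme)
  if (min_segment_length < 1L) stop("min_segment_length must be >= 1")
  s <- check_dna(sequence, "read sequence")
  empty <- data.table::data.table(
    read_id = character(0), ordinal = integer(0), read_start = integer(0),
    read_end = integer(0), sequence = character(0), filtered = logical(0))
  if (nchar(s) == 0L) {
    warning("digest_read: empty sequence for read '", read_id, "'")
    data.table::setattr(empty, "n_empty", 1L)
    return(empty)
  }
  cuts <- find_cut_sites(s, enzyme)
  edges <- c(0L, cuts, nchar(s))
  starts <- edges[-length(edges)]
  ends <- edges[-1]
  data.table::data.table(
    read_id = read_id,
    ordinal = seq_along(starts) - 1L,
    read_start = starts,
    read_end = ends,
    sequence = substring(s, starts + 1L, ends),
    filtered = (ends - starts) < min_segment_length
  )
}

#' Digest many reads
#'
#' Vectorized wrapper around [digest_read()] for a set of reads (FASTA/FASTQ
#' path, gzip-transparent, or a named character vector).
#'
#' @param reads FASTA/FASTQ path or named character vector of read sequences.
#' @param enzyme a [restriction_enzyme()] or built-in name.
#' @param min_segment_length minimum segment length in bp.
#' @return one `data.table` of segments (see [digest_read()]); attribute
#'   `n_empty` counts empty input reads.
#' @export
digest_reads <- function(reads, enzyme, min_segment_length = 20L) {
  seqs <- as_reads(reads)
  enzyme <- as_enzyme(enzyme)
  if (min_segment_length < 1L) stop("min_segment_length must be >= 1")
  n_empty <- sum(nchar(seqs) == 0L)
  if (n_empty > 0L) {
    warning("digest_reads: ", n_empty, " empty read(s) skipped")
    seqs <- seqs[nchar(seqs) > 0L]
  }
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("read '", names(seqs)[which(bad)[1]], "' contains non-DNA characters")
  ss <- Biostrings::DNAStringSet(seqs)
  fixed <- if (grepl("[^ACGT]", enzyme$motif)) "subject" else TRUE
  hits <- Biostrings::vmatchPattern(enzyme$motif, ss, fixed = fixed)
  L <- nchar(seqs)
  cuts_list <- lapply(seq_along(seqs), function(i) {
    cuts <- IRanges::start(hits[[i]]) - 1L + enzyme$cut_offset
    cuts <- cuts[cuts > 0L & cuts < L[i]]
    c(0L, sort(unique(as.integer(cuts))), L[i])
  })
  nseg <- lengths(cuts_list) - 1L
  edges <- unlist(cuts_list, use.names = FALSE)
  drop_last <- cumsum(nseg + 1L)              # index of each read's final edge
  starts <- edges[-drop_last]
  ends <- edges[-c(1L, drop_last[-length(drop_last)] + 1L)]
  res <- data.table::data.table(
    read_id = rep(names(seqs), nseg),
    ordinal = unlist(lapply(nseg, seq_len), use.names = FALSE) - 1L,
    read_start = starts,
    read_end = ends,
    sequence = substring(rep(seqs, nseg), starts + 1L, ends),
    filtered = (ends - starts) < min_segment_length
  )
  data.table::setattr(res, "n_empty", n_empty)
  res[]
}

# Resolve reads into a named character vector (FASTA/FASTQ path or vector).
as_reads <- function(reads) {
  if (is.character(reads) && length(reads) == 1L && is.null(names(reads)) &&
      file.exists(reads)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads)) "fastq" else "fasta"
    ss <- Biostrings::readDNAStringSet(reads, format = fmt)
    seqs <- as.character(ss)
    names(seqs) <- sub("\\s.*$", "", names(ss))
    return(seqs)
  }
  if (!is.character(reads) || is.null(names(reads)))
    stop("reads must be a FASTA/FASTQ path or a named character vector")
  reads
}

#' Segment summary statistics
#'
#' Medians (lower-median convention) and histograms of segments per read and
#' segment length, over unfiltered segments.
#'
#' @param segments segment table from [digest_reads()].
#' @param binwidth_length histogram bin width for segment length (bp).
#' @return list with `median_segments_per_read`, `median_segment_length`,
#'   `n_reads`, `n_segments`, and histograms `hist_segments_per_read`,
#'   `hist_segment_length` as `data.table`s of (edge, count): counts of values
#'   in `[edge, edge + width)`.
#' @export
segment_stats <- function(segments, binwidth_length = 50L) {
  if (nrow(segments) == 0L) stop("segment_stats: no segments")
  keep <- segments[filtered == FALSE]
  per_read <- keep[, .(n_seg = .N), by = read_id]
  lens <- keep[, read_end - read_start]
  hist_counts <- function(x, w) {
    edge <- as.integer((x %/% w) * w)
    dt <- data.table::data.table(edge = edge)[, .(count = .N), by = edge]
    data.table::setorder(dt, edge)
    dt[]
  }
  list(
    median_segments_per_read = median_low(per_read$n_seg),
    median_segment_length = median_low(lens),
    n_reads = nrow(per_read),
    n_segments = nrow(keep),
    hist_segments_per_read = hist_counts(per_read$n_seg, 1L),
    hist_segment_length = hist_counts(lens, binwidth_length)
  )
}

#' Write digested segments (FASTQ + TSV sidecar)
#'
#' Segment names follow the aligner-facing contract
#' `{read_id}:{ordinal}:{read_start}:{read_end}`. Filtered segments are
#' excluded from the FASTQ but present in the sidecar with `filtered = 1`.
#'
#' @param segments segment table from [digest_reads()].
#' @param out_prefix output path prefix; writes `<prefix>.segments.fastq` and
#'   `<prefix>.segments.tsv`.
#' @return named character vector of the two paths, invisibly.
#' @export
write_segments <- function(segments, out_prefix) {
  keep <- segments[filtered == FALSE]
  nm <- keep[, paste(read_id, ordinal, read_start, read_end, sep = ":")]
  fq <- paste0(out_prefix, ".segments.fastq")
  write_fastq(stats::setNames(keep$sequence, nm), fq)
  tsv <- paste0(out_prefix, ".segments.tsv")
  side <- segments[, .(read_id, ordinal, read_start, read_end,
                       filtered_flag = as.integer(filtered))]
  data.table::fwrite(side, tsv, sep = "\t")
  invisible(c(fastq = fq, tsv = tsv))
}

#' Write a fragment map as BED
#'
#' 0-based half-open BED with the fragment index in the name column.
#'
#' @param fragment_map from [digest_genome()].
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_fragment_bed <- function(fragment_map, path) {
  bed <- fragment_map[, .(chrom = as.character(chrom), start, end,
                          name = fragment_index)]
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
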