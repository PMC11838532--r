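# Ingestion of per-segment ("monomer") alignments and selection of one
# placement per segment.

#' Ingest per-segment alignments and select one placement per segment
#'
#' Accepts either a BAM of aligned segments whose names follow the
#' `{read_id}:{ordinal}:{read_start}:{read_end}` contract, or the simulator's
#' plain-text oracle TSV (`read_id ordinal chrom start end strand mapq`).
#' For every (read_id, ordinal) with at least one mapping of
#' `mapq >= mapq_min`, exactly one alignment is selected: primary records
#' always beat secondary/supplementary; ties are broken by longest aligned
#' span, then smallest (chrom, start). Segments whose best mapping falls
#' below `mapq_min`, and unmapped segments, are dropped and counted.
#'
#' @param source BAM path, oracle TSV path, or a data.frame/data.table with
#'   oracle columns.
#' @param mapq_min minimum MAPQ (applied before pair expansion; default 1,
#'   the headline stratum of MAPQ-based comparisons).
#' @param chrom_order character vector fixing chromosome order (genome order);
#'   defaults to the order of first appearance (TSV) or the BAM header order.
#' @param fragment_map optional [digest_genome()] output; when given, each
#'   monomer is annotated with the `fragment_index` of the nearest fragment by
#'   alignment midpoint, and reference names are checked against it.
#' @return `data.table` of monomers: `read_id`, `ordinal`, `chrom` (factor in
#'   genome order), `start`, `end` (0-based half-open), `strand`, `mapq`, and
#'   `fragment_index` if a fragment map was supplied. Attribute `counts` is a
#'   named vector: `n_alignments`, `n_segments_aligned`, `n_selected`,
#'   `n_below_mapq`.
#' @export
ingest_alignments <- function(source, mapq_min = 1L, chrom_order = NULL,
                              fragment_map = NULL) {
  aln <- read_alignment_source(source, chrom_order)
  if (!is.null(fragment_map)) {
    fm_chroms <- levels(fragment_map$chrom)
    unknown <- setdiff(levels(aln$chrom), fm_chroms)
    if (length(unknown))
      stop("alignment reference(s) not in fragment map: ",
           paste(unknown, collapse = ", "))
  }
  n_alignments <- nrow(aln)
  n_segments_aligned <- nrow(unique(aln[, .(read_id, ordinal)]))
  # Selection: primary first, then span, then (chrom, start); within those,
  # highest mapq first so the best placement's mapq is what gets thresholded.
  data.table::setorder(aln, read_id, ordinal, -is_primary, -mapq, -span, chrom, start)
  sel <- aln[, .SD[1L], by = .(read_id, ordinal)]
  n_below <- sel[, sum(mapq < mapq_min)]
  sel <- sel[mapq >= mapq_min]
  sel[, c("is_primary", "span") := NULL]
  if (!is.null(fragment_map)) {
    sel <- assign_fragments(sel, fragment_map)
  }
  data.table::setorder(sel, read_id, ordinal)
  data.table::setattr(sel, "counts", c(
    n_alignments = n_alignments,
    n_segments_aligned = n_segments_aligned,
    n_selected = nrow(sel),
    n_below_mapq = n_below
  ))
  sel[]
}

# Internal: normalize any supported alignment source into one data.table with
# columns read_id, ordinal, chrom (factor), start, end, strand, mapq,
# is_primary, span.
read_alignment_source <- function(source, chrom_order = NULL) {
  if (is.data.frame(source)) {
    aln <- data.table::as.data.table(source)
  } else if (is.character(source) && length(source) == 1L) {
    if (grepl("\\.bam$", source, ignore.case = TRUE)) {
      return(read_bam_alignments(source))
    }
    aln <- data.table::fread(source)
  } else {
    stop("unsupported alignment source")
  }
  need <- c("read_id", "ordinal", "chrom", "start", "end", "strand", "mapq")
  miss <- setdiff(need, names(aln))
  if (length(miss))
    stop("oracle alignment table lacks column(s): ", paste(miss, collapse = ", "))
  aln <- aln[, intersect(c(need, "is_primary"), names(aln)), with = FALSE]
  if (is.null(chrom_order)) chrom_order <- unique(as.character(aln$chrom))
  aln[, chrom := factor(as.character(chrom), levels = chrom_order)]
  if (anyNA(aln$chrom)) stop("alignment chromosome not in chrom_order")
  if (!"is_primary" %in% names(aln)) aln[, is_primary := TRUE]
  if (aln[, any(end <= start)]) stop("alignment with end <= start")
  if (aln[, any(mapq < 0L | mapq > 60L)]) stop("MAPQ outside [0, 60]")
  aln[, span := end - start]
  aln
}

# Internal: load a BAM of digested segments (names follow the segment
# contract) into the normalized alignment table.
read_bam_alignments <- function(path) {
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "mapq", "cigar"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  mapped <- !bitwAnd(b$flag, 4L)
  if (!any(mapped)) stop("BAM contains no mapped records: ", path)
  qn <- b$qname[mapped]
  parts <- data.table::tstrsplit(qn, ":", fixed = TRUE)
  ok <- length(parts) == 4L && !anyNA(suppressWarnings(as.integer(parts[[2]])))
  if (!ok) {
    bad <- if (length(parts) == 4L)
      qn[which(is.na(suppressWarnings(as.integer(parts[[2]]))))[1]]
    else qn[lengths(strsplit(qn, ":", fixed = TRUE)) != 4L][1]
    stop("segment name does not match '{read_id}:{ordinal}:{start}:{end}': ", bad)
  }
  flag <- b$flag[mapped]
  ref_len <- cigar_reference_span(b$cigar[mapped])
  data.table::data.table(
    read_id = parts[[1]],
    ordinal = as.integer(parts[[2]]),
    chrom = factor(as.character(b$rname[mapped]), levels = levels(b$rname)),
    start = b$pos[mapped] - 1L,                     # BAM pos is 1-based
    end = b$pos[mapped] - 1L + ref_len,
    strand = as.character(b$strand[mapped]),
    mapq = as.integer(b$mapq[mapped]),
    is_primary = !bitwAnd(flag, 256L + 2048L),
    span = ref_len
  )
}

# Reference span consumed by a CIGAR string (M/D/N/=/X operations).
cigar_reference_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", toks))
    op <- sub("^[0-9]+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

# Annotate monomers with the fragment whose midpoint is nearest the
# alignment midpoint (rolling join per chromosome).
assign_fragments <- function(monomers, fragment_map) {
  fm <- data.table::as.data.table(fragment_map)[
    , .(chrom = as.character(chrom), midpoint = (start + end) / 2, fragment_index)]
  mm <- data.table::copy(monomers)
  mm[, midpoint := (start + end) / 2]
  data.table::setkey(fm, chrom, midpoint)
  mm[, chrom_chr := as.character(chrom)]
  idx <- fm[mm[, .(chrom = chrom_chr, midpoint)], on = c("chrom", "midpoint"),
            roll = "nearest", x.fragment_index]
  mm[, fragment_index := idx]
  mm[, c("midpoint", "chrom_chr") := NULL]
  mm[]
}

#' Write the oracle alignment TSV
#'
#' @param monomers alignment table with oracle columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_oracle_tsv <- function(monomers, path) {
  cols <- intersect(c("read_id", "ordinal", "chrom", "start", "end",
                      "strand", "mapq"), names(monomers))
  data.table::fwrite(monomers[, cols, with = FALSE], path, sep = "\t")
  invisible(path)
}
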