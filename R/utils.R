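# Internal helpers shared across modules.

#' @import data.table
#' @importFrom methods is
NULL

# Silence R CMD check notes for data.table NSE columns.
utils::globalVariables(c(
  ".", ".N", ".I", ".SD", "read_id", "ordinal", "chrom", "start",
  "end", "strand", "mapq", "fragment_index", "filtered",
  "read_start", "read_end", "chrom1", "chrom2", "pos1", "pos2", "strand1",
  "strand2", "ord1", "ord2", "pair_type", "duplicate_flag", "bin1", "bin2",
  "count", "bin_id", "n_seg", "midpoint", "depth",
  "is_primary", "span", "length_", "class_", "weight",
  "start_bin", "end_bin", "domain_id", "N", "V1",
  "chrom_chr", "x.fragment_index", "depth_a", "depth_b", "threshold",
  "core", "aln_start", "aln_end", "edge", "duplicate_of", "start1", "start2",
  "is_anchor"
))

#' Lower median
#'
#' Median using the lower-median convention: for an even number of values the
#' smaller of the two central order statistics is returned (so the median of
#' integer data is always an observed value).
#'
#' @param x numeric vector, length >= 1.
#' @return a single value from `x`.
#' @export
median_low <- function(x) {
  if (length(x) == 0L) stop("median_low: empty input")
  xs <- sort(x)
  xs[ceiling(length(xs) / 2)]
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (ACGTN, case-insensitive).
#' @return character vector of reverse complements, uppercase.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Validate a DNA character scalar; returns the uppercased sequence.
# N is allowed (it never matches a motif); anything else is rejected.
check_dna <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L)
    stop(what, " must be a single character string")
  s <- toupper(sequence)
  if (nchar(s) > 0L && grepl("[^ACGTN]", s))
    stop(what, " contains non-DNA characters (only A,C,G,T,N allowed)")
  s
}

#' Read a chrom.sizes file
#'
#' Two-column whitespace-separated text: chromosome name, length in bp.
#' Order in the file defines the genome's chromosome order.
#'
#' @param path file path.
#' @return named integer-ish numeric vector of chromosome lengths, in file order.
#' @export
read_chromsizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, col.names = c("chrom", "size"))
  stats::setNames(as.numeric(dt$size), as.character(dt$chrom))
}

#' Write a chrom.sizes file
#'
#' @param chromsizes named numeric vector (names = chromosomes, values = bp).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_chromsizes <- function(chromsizes, path) {
  data.table::fwrite(
    data.table::data.table(chrom = names(chromsizes), size = as.integer(chromsizes)),
    path, sep = "\t", col.names = FALSE
  )
  invisible(path)
}

# Resolve a genome argument into a named uppercase character vector of
# sequences. Accepts a FASTA path, a Biostrings::DNAStringSet, or a named
# character vector.
as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      is.null(names(genome))) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
    # FASTA descriptions: keep the first word as the sequence name
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    genome <- seqs
  }
  if (!is.character(genome) || is.null(names(genome)))
    stop("genome must be a FASTA path, DNAStringSet, or named character vector")
  if (length(genome) == 0L) stop("genome is empty")
  if (anyDuplicated(names(genome))) stop("duplicate sequence names in genome")
  zl <- nchar(genome) == 0L
  if (any(zl))
    stop("zero-length sequence in genome: ", names(genome)[which(zl)[1]])
  toupper(genome)
}

# Internal: named chromosome sizes from a genome object.
genome_sizes <- function(genome) {
  g <- as_genome(genome)
  stats::setNames(nchar(g), names(g))
}

#' Write sequences as FASTQ
#'
#' Plain four-line-per-record FASTQ with a constant quality character.
#' (The Biostrings FASTQ writer aborts on records longer than its internal
#' line buffer, which concatemer reads routinely exceed.)
#'
#' @param seqs named character vector of sequences.
#' @param path output path (".gz" suffix enables gzip).
#' @param qual quality character replicated across each record (default "I",
#'   Phred 40).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path, qual = "I") {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  rec <- paste0("@", names(seqs), "\n", seqs, "\n+\n",
                strrep(qual, nchar(seqs)))
  writeLines(rec, con)
  invisible(path)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path (".gz" suffix enables gzip).
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = width)
  invisible(path)
}
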