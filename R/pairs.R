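# Pairwise expansion of multi-way contacts and 4DN pairs I/O.
#
# A read with n aligned monomers encodes C(n,2) pairwise contacts; expanding
# them makes multi-contact long-read data consumable by standard Hi-C tooling
# (one n=17 read yields 136 pairs, the information of 272 paired-end reads).

#' Expand monomers into all pairwise contacts
#'
#' For every read, emits all unordered monomer pairs, i.e. `n*(n-1)/2` pairs
#' for a read with `n` monomers. The anchor position of a monomer is its
#' 5'-most reference coordinate (alignment start), matching short-read Hi-C
#' convention. Mates are normalized to the upper triangle: (chrom1, pos1) <=
#' (chrom2, pos2) under (genome chromosome order, position).
#'
#' @param monomers monomer table from [ingest_alignments()] (one row per
#'   (read_id, ordinal); `chrom` must be a factor in genome order).
#' @return `data.table` of pairs: `read_id`, `chrom1`, `pos1`, `strand1`,
#'   `chrom2`, `pos2`, `strand2` (positions 0-based here; serialized 1-based),
#'   `ord1 < ord2` (read ordinals), `pair_type` ("cis"/"trans"),
#'   `duplicate_flag` (all `FALSE`).
#' @export
expand_pairs <- function(monomers) {
  mm <- data.table::as.data.table(monomers)
  if (nrow(mm) == 0L) return(empty_pairs())
  if (!is.factor(mm$chrom)) stop("monomers$chrom must be a factor in genome order")
  if (anyDuplicated(mm[, .(read_id, ordinal)]))
    stop("monomers must be unique on (read_id, ordinal); run ingest_alignments first")
  data.table::setorder(mm, read_id, ordinal)
  sizes <- mm[, .N, by = read_id]$N
  offs <- cumsum(c(0L, sizes[-length(sizes)]))
  keep <- sizes >= 2L
  if (!any(keep)) return(empty_pairs())
  idx <- pair_index_blocks(sizes[keep], offs[keep])
  a <- mm[idx$i]
  b <- mm[idx$j]
  ci <- as.integer(a$chrom); cj <- as.integer(b$chrom)
  swap <- (cj < ci) | (cj == ci & b$start < a$start)
  pairs <- data.table::data.table(
    read_id = a$read_id,
    chrom1 = ifelse(swap, as.integer(b$chrom), as.integer(a$chrom)),
    pos1 = ifelse(swap, b$start, a$start),
    strand1 = ifelse(swap, b$strand, a$strand),
    chrom2 = ifelse(swap, as.integer(a$chrom), as.integer(b$chrom)),
    pos2 = ifelse(swap, a$start, b$start),
    strand2 = ifelse(swap, a$strand, b$strand),
    ord1 = a$ordinal,
    ord2 = b$ordinal
  )
  lev <- levels(mm$chrom)
  pairs[, chrom1 := factor(lev[chrom1], levels = lev)]
  pairs[, chrom2 := factor(lev[chrom2], levels = lev)]
  pairs[, pair_type := ifelse(chrom1 == chrom2, "cis", "trans")]
  pairs[, duplicate_flag := FALSE]
  pairs[]
}

# All (i < j) index pairs for consecutive blocks of the given sizes/offsets.
pair_index_blocks <- function(sizes, offsets) {
  i_loc <- unlist(lapply(sizes, function(n) rep.int(seq_len(n - 1L), (n - 1L):1L)),
                  use.names = FALSE)
  j_loc <- unlist(lapply(sizes, function(n) sequence((n - 1L):1L, from = 2:n)),
                  use.names = FALSE)
  off <- rep.int(offsets, sizes * (sizes - 1L) / 2L)
  list(i = off + i_loc, j = off + j_loc)
}

empty_pairs <- function() {
  data.table::data.table(
    read_id = character(0), chrom1 = factor(), pos1 = integer(0),
    strand1 = character(0), chrom2 = factor(), pos2 = integer(0),
    strand2 = character(0), ord1 = integer(0), ord2 = integer(0),
    pair_type = character(0), duplicate_flag = logical(0))
}

#' Flag duplicate pairs
#'
#' Among pairs identical on (chrom1, pos1, strand1, chrom2, pos2, strand2)
#' that come from *different* reads, all but the first are flagged as
#' duplicates (the pair-level analogue of PCR-duplicate marking). Pairs from
#' the same read are never flagged against each other. Input must be sorted
#' by (chrom1, pos1, chrom2, pos2).
#'
#' @param pairs pair table sorted by (chrom1, pos1, chrom2, pos2).
#' @return the table with `duplicate_flag` set.
#' @export
dedup_pairs <- function(pairs) {
  p <- data.table::as.data.table(pairs)
  if (nrow(p) == 0L) return(p)
  o <- order(as.integer(p$chrom1), p$pos1, as.integer(p$chrom2), p$pos2)
  if (!identical(o, seq_len(nrow(p))))
    stop("dedup_pairs: input not sorted by (chrom1, pos1, chrom2, pos2)")
  p[, duplicate_flag := read_id != read_id[1L],
    by = .(chrom1, pos1, strand1, chrom2, pos2, strand2)]
  p[]
}

#' Sort pairs into canonical order
#'
#' (chrom1, pos1, chrom2, pos2, strand1, strand2, read_id), chromosomes in
#' genome order.
#'
#' @param pairs pair table.
#' @return sorted copy.
#' @export
sort_pairs <- function(pairs) {
  p <- data.table::copy(data.table::as.data.table(pairs))
  data.table::setorder(p, chrom1, pos1, chrom2, pos2, strand1, strand2, read_id)
  p[]
}

#' Fraction of cis (intrachromosomal) contacts
#'
#' Computed over non-duplicate pairs.
#'
#' @param pairs pair table.
#' @return numeric in `[0, 1]`.
#' @export
cis_fraction <- function(pairs) {
  p <- data.table::as.data.table(pairs)[duplicate_flag == FALSE]
  if (nrow(p) == 0L) stop("cis_fraction: no non-duplicate pairs")
  p[, mean(pair_type == "cis")]
}

#' Write pairs in 4DN pairs format
#'
#' `## pairs format v1.0` header, `#chromsize:` lines in genome order, then
#' columns readID chr1 pos1 chr2 pos2 strand1 strand2 with 1-based positions
#' and upper-triangle mate ordering.
#'
#' @param pairs pair table (0-based internal positions).
#' @param chromsizes named numeric vector in genome order.
#' @param path output path (".gz" suffix enables gzip).
#' @param drop_duplicates drop pairs with `duplicate_flag` (default TRUE).
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, chromsizes, path, drop_duplicates = TRUE) {
  p <- data.table::as.data.table(pairs)
  if (drop_duplicates) p <- p[duplicate_flag == FALSE]
  unknown <- setdiff(unique(c(as.character(p$chrom1), as.character(p$chrom2))),
                     names(chromsizes))
  if (length(unknown))
    stop("pair on chromosome absent from chromsizes: ",
         paste(unknown, collapse = ", "))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  hdr <- c("## pairs format v1.0",
           "#shape: upper triangle",
           sprintf("#chromsize: %s %d", names(chromsizes), as.integer(chromsizes)),
           "#columns: readID chrom1 pos1 chrom2 pos2 strand1 strand2")
  writeLines(hdr, con)
  if (nrow(p) > 0L) {
    body <- p[, paste(read_id, as.character(chrom1), pos1 + 1L,
                      as.character(chrom2), pos2 + 1L, strand1, strand2,
                      sep = "\t")]
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a 4DN pairs file
#'
#' @param path pairs file (optionally gzipped) written by [write_pairs()] or
#'   compatible.
#' @return pair table with 0-based positions, `chrom1`/`chrom2` factors in the
#'   header's chromsize order, and `pair_type` recomputed. Attribute
#'   `chromsizes` carries the header sizes.
#' @export
read_pairs <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  hdr <- character(0)
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L || !startsWith(ln, "#")) break
    hdr <- c(hdr, ln)
  }
  close(con)
  cs_lines <- grep("^#chromsize:", hdr, value = TRUE)
  cs <- do.call(rbind, strsplit(sub("^#chromsize:\\s*", "", cs_lines), "\\s+"))
  chromsizes <- stats::setNames(as.numeric(cs[, 2]), cs[, 1])
  cols <- c("read_id", "chrom1", "pos1", "chrom2", "pos2", "strand1", "strand2")
  has_body <- length(ln) == 1L && !startsWith(ln, "#")
  p <- if (has_body) {
    # read through a connection: gzip-transparent without extra packages
    con2 <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
    body <- readLines(con2)
    close(con2)
    data.table::fread(text = body[!startsWith(body, "#")], header = FALSE,
                      col.names = cols)
  } else {
    data.table::data.table(read_id = character(0), chrom1 = character(0),
                           pos1 = integer(0), chrom2 = character(0),
                           pos2 = integer(0), strand1 = character(0),
                           strand2 = character(0))
  }
  if (nrow(p) > 0L) {
    p[, pos1 := pos1 - 1L]
    p[, pos2 := pos2 - 1L]
  }
  p[, chrom1 := factor(as.character(chrom1), levels = names(chromsizes))]
  p[, chrom2 := factor(as.character(chrom2), levels = names(chromsizes))]
  p[, pair_type := ifelse(chrom1 == chrom2, "cis", "trans")]
  p[, duplicate_flag := FALSE]
  data.table::setattr(p, "chromsizes", chromsizes)
  p[]
}

#' Pair-level summary statistics
#'
#' Counters over the contact-expansion stage, reported for all four
#' combinations of MAPQ filtering (implicit in the monomers supplied) and
#' duplicate handling.
#'
#' @param pairs pair table after [dedup_pairs()].
#' @param monomers optional monomer table for segment counters.
#' @return named list: `n_pairs`, `n_duplicates`, `n_pairs_nodup`,
#'   `n_illumina_equivalent_reads` (2 x n_pairs: each expanded pair carries
#'   the information of one short-read pair, i.e. two reads),
#'   `cis_fraction`, `cis_fraction_all` (including duplicates), plus
#'   `n_reads`, `n_monomers` when monomers are given.
#' @export
pair_stats <- function(pairs, monomers = NULL) {
  p <- data.table::as.data.table(pairs)
  out <- list(
    n_pairs = nrow(p),
    n_duplicates = sum(p$duplicate_flag),
    n_pairs_nodup = sum(!p$duplicate_flag),
    n_illumina_equivalent_reads = 2L * nrow(p),
    cis_fraction = if (any(!p$duplicate_flag)) cis_fraction(p) else NA_real_,
    cis_fraction_all = if (nrow(p)) mean(p$pair_type == "cis") else NA_real_
  )
  if (!is.null(monomers)) {
    out$n_reads <- length(unique(monomers$read_id))
    out$n_monomers <- nrow(monomers)
  }
  out
}
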