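# Binned sparse contact matrices: bin table, pair binning, coarsening,
# triplet dump, and cross-map correlation.

#' Genome bin table at a fixed resolution
#'
#' Tiles every chromosome with `resolution`-bp bins (last bin may be short)
#' and assigns dense, contiguous global bin indices in genome order.
#'
#' @param chromsizes named numeric vector in genome order.
#' @param resolution bin size in bp (e.g. 50000 or 2500000).
#' @return `data.table` with `chrom` (factor), `start`, `end`, `bin_id`
#'   (1-based global index); attributes `resolution`, `chromsizes`.
#' @export
bin_table <- function(chromsizes, resolution) {
  if (resolution < 1) stop("resolution must be positive")
  per <- lapply(names(chromsizes), function(cn) {
    L <- chromsizes[[cn]]
    starts <- seq(0L, L - 1L, by = resolution)
    data.table::data.table(chrom = cn, start = as.integer(starts),
                           end = as.integer(pmin(starts + resolution, L)))
  })
  bt <- data.table::rbindlist(per)
  bt[, chrom := factor(chrom, levels = names(chromsizes))]
  bt[, bin_id := .I]
  data.table::setattr(bt, "resolution", resolution)
  data.table::setattr(bt, "chromsizes", chromsizes)
  bt[]
}

# Map (chrom, 0-based pos) to global bin ids for a bin table.
pos_to_bin <- function(bt, chrom, pos) {
  chromsizes <- attr(bt, "chromsizes")
  res <- attr(bt, "resolution")
  offsets <- c(0L, cumsum(ceiling(chromsizes / res)))
  names(offsets) <- c(names(chromsizes), "_end")
  ci <- match(as.character(chrom), names(chromsizes))
  if (anyNA(ci)) stop("position on chromosome absent from bin table")
  bad <- pos < 0 | pos >= chromsizes[ci]
  if (any(bad)) {
    k <- which(bad)[1]
    stop(sprintf("pair coordinate outside chromosome: %s:%d",
                 as.character(chrom)[k], pos[k]))
  }
  as.integer(offsets[ci] + pos %/% res + 1L)
}

#' Bin contact pairs into a sparse contact matrix
#'
#' Each non-duplicate pair increments exactly one (i, j) cell with i <= j;
#' the matrix total equals the number of pairs binned.
#'
#' @param pairs pair table (duplicates are excluded here).
#' @param bt bin table from [bin_table()].
#' @return a `cifi_matrix`: list with `bins`, `counts` (upper-triangular
#'   `dgCMatrix`), `resolution`, `chromsizes`, `normalization = "raw"`,
#'   `weights = NULL`.
#' @export
bin_pairs <- function(pairs, bt) {
  p <- data.table::as.data.table(pairs)[duplicate_flag == FALSE]
  n <- nrow(bt)
  if (nrow(p) > 0L) {
    i <- pos_to_bin(bt, p$chrom1, p$pos1)
    j <- pos_to_bin(bt, p$chrom2, p$pos2)
    swap <- j < i
    tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
    counts <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  } else {
    counts <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                   dims = c(n, n))
  }
  new_cifi_matrix(bt, methods::as(counts, "CsparseMatrix"))
}

new_cifi_matrix <- function(bt, counts, normalization = "raw", weights = NULL) {
  structure(list(bins = bt, counts = counts,
                 resolution = attr(bt, "resolution"),
                 chromsizes = attr(bt, "chromsizes"),
                 normalization = normalization, weights = weights),
            class = "cifi_matrix")
}

#' @export
print.cifi_matrix <- function(x, ...) {
  cat(sprintf("<contact matrix: %d bins @ %s bp, total %s, %s>\n",
              nrow(x$bins), format(x$resolution, big.mark = ","),
              format(sum(x$counts), big.mark = ","), x$normalization))
  invisible(x)
}

#' Total contact count of a matrix
#' @param mat a `cifi_matrix`.
#' @return numeric scalar.
#' @export
matrix_total <- function(mat) sum(mat$counts)

#' Coarsen a contact matrix to a larger resolution
#'
#' Aggregates bins chromosome by chromosome; the target resolution must be an
#' integer multiple of the source resolution. Counts are summed exactly, so
#' the coarse matrix is identical to binning the pairs directly at the coarse
#' resolution.
#'
#' @param mat a raw `cifi_matrix`.
#' @param resolution target resolution (multiple of `mat$resolution`).
#' @return a raw `cifi_matrix` at the coarse resolution.
#' @export
coarsen_matrix <- function(mat, resolution) {
  if (resolution %% mat$resolution != 0)
    stop("target resolution must be a multiple of the source resolution")
  bt2 <- bin_table(mat$chromsizes, resolution)
  # map fine bin -> coarse bin via bin start positions
  map <- pos_to_bin(bt2, mat$bins$chrom, mat$bins$start)
  tri <- Matrix::summary(mat$counts)
  i2 <- map[tri$i]; j2 <- map[tri$j]
  swap <- j2 < i2
  tmp <- i2[swap]; i2[swap] <- j2[swap]; j2[swap] <- tmp
  counts <- Matrix::sparseMatrix(i = i2, j = j2, x = tri$x,
                                 dims = c(nrow(bt2), nrow(bt2)))
  new_cifi_matrix(bt2, methods::as(counts, "CsparseMatrix"))
}

# Full symmetric form (upper triangle mirrored; diagonal kept once).
full_symmetric <- function(counts) {
  counts + Matrix::t(counts) - Matrix::Diagonal(x = Matrix::diag(counts))
}

#' Extract one chromosome as a dense symmetric matrix
#'
#' @param mat a `cifi_matrix`.
#' @param chrom chromosome name.
#' @param balanced apply balancing weights if present.
#' @return dense symmetric base matrix (bins of `chrom` only). Masked bins
#'   (weight `NA`) become `NA` rows/columns when `balanced = TRUE`.
#' @export
chrom_matrix <- function(mat, chrom, balanced = FALSE) {
  ids <- mat$bins[as.character(mat$bins$chrom) == as.character(chrom), bin_id]
  if (length(ids) == 0L) stop("unknown chromosome: ", chrom)
  m <- as.matrix(full_symmetric(mat$counts)[ids, ids, drop = FALSE])
  if (balanced) {
    if (is.null(mat$weights)) stop("matrix has no balancing weights")
    w <- mat$weights[ids]
    m <- m * outer(w, w)
  }
  m
}

#' Dump matrix counts as triplets
#'
#' Plain-text triplet export (the native counterpart of a juicer-style dump):
#' one record per nonzero upper-triangle cell of the requested region pair,
#' ordered by (bin1, bin2).
#'
#' @param mat a `cifi_matrix`.
#' @param region1,region2 `"chrom"` or `"chrom:start-end"` (1-based, closed);
#'   `region2` defaults to `region1`.
#' @param balanced dump balanced counts instead of raw.
#' @return `data.table` with `bin1`, `bin2` (global bin ids), `start1`,
#'   `start2` (bin starts, 0-based), `count`.
#' @export
dump_counts <- function(mat, region1, region2 = region1, balanced = FALSE) {
  ids1 <- region_bins(mat$bins, region1)
  ids2 <- region_bins(mat$bins, region2)
  tri <- Matrix::summary(mat$counts)
  keep <- (tri$i %in% ids1 & tri$j %in% ids2) |
          (tri$i %in% ids2 & tri$j %in% ids1)
  tri <- tri[keep, , drop = FALSE]
  dt <- data.table::data.table(bin1 = tri$i, bin2 = tri$j, count = tri$x)
  if (balanced) {
    if (is.null(mat$weights)) stop("matrix has no balancing weights")
    dt[, count := count * mat$weights[bin1] * mat$weights[bin2]]
  }
  dt[, start1 := mat$bins$start[bin1]]
  dt[, start2 := mat$bins$start[bin2]]
  data.table::setorder(dt, bin1, bin2)
  dt[, .(bin1, bin2, start1, start2, count)]
}

# Parse "chrom" or "chrom:start-end" (1-based closed) into global bin ids.
region_bins <- function(bins, region) {
  m <- regmatches(region, regexec("^([^:]+)(?::([0-9,]+)-([0-9,]+))?$", region))[[1]]
  if (length(m) == 0L) stop("cannot parse region: ", region)
  cn <- m[2]
  sel <- bins[as.character(chrom) == cn]
  if (nrow(sel) == 0L) stop("unknown chromosome in region: ", region)
  if (m[3] != "") {
    lo <- as.numeric(gsub(",", "", m[3])) - 1  # to 0-based
    hi <- as.numeric(gsub(",", "", m[4]))
    sel <- sel[end > lo & start < hi]
  }
  sel$bin_id
}

#' Correlate two contact matrices
#'
#' Pearson correlation of `log1p`-transformed counts over the union of
#' nonzero cells of the two matrices, optionally restricted to a set of bins
#' (e.g. "unique" vs "SD/centromere" bins). Matrices must share a bin table.
#'
#' @param a,b `cifi_matrix` objects on identical bin tables.
#' @param bin_mask optional logical or integer vector of bins to keep (a cell
#'   is kept when both its bins are in the mask).
#' @param balanced correlate balanced counts (both matrices need weights).
#' @param log transform counts with `log1p` before correlating (default TRUE).
#' @return list with `r`, `r2`, `n_cells`.
#' @export
correlate_matrices <- function(a, b, bin_mask = NULL, balanced = FALSE,
                               log = TRUE) {
  if (nrow(a$bins) != nrow(b$bins) || a$resolution != b$resolution)
    stop("matrices have different bin tables")
  ta <- Matrix::summary(a$counts)
  tb <- Matrix::summary(b$counts)
  key <- function(t) paste(t$i, t$j)
  cells <- unique(c(key(ta), key(tb)))
  ij <- do.call(rbind, strsplit(cells, " "))
  i <- as.integer(ij[, 1]); j <- as.integer(ij[, 2])
  if (!is.null(bin_mask)) {
    if (is.logical(bin_mask)) bin_mask <- which(bin_mask)
    keep <- i %in% bin_mask & j %in% bin_mask
    i <- i[keep]; j <- j[keep]
  }
  va <- get_cells(a, i, j, balanced)
  vb <- get_cells(b, i, j, balanced)
  if (log) { va <- log1p(va); vb <- log1p(vb) }
  ok <- is.finite(va) & is.finite(vb)
  r <- stats::cor(va[ok], vb[ok])
  list(r = r, r2 = r^2, n_cells = sum(ok))
}

get_cells <- function(mat, i, j, balanced = FALSE) {
  v <- mat$counts[cbind(i, j)]
  if (balanced) {
    if (is.null(mat$weights)) stop("matrix has no balancing weights")
    v <- v * mat$weights[i] * mat$weights[j]
  }
  as.numeric(v)
}

#' Write a matrix as triplet text + chromsizes
#'
#' The canonical interchange: `<prefix>.counts.tsv` with global bin triplets
#' and `<prefix>.bins.tsv` with the bin table (plus a `weight` column when
#' balanced).
#'
#' @param mat a `cifi_matrix`.
#' @param out_prefix output path prefix.
#' @return named character vector of paths, invisibly.
#' @export
write_matrix <- function(mat, out_prefix) {
  tri <- Matrix::summary(mat$counts)
  dt <- data.table::data.table(bin1 = tri$i, bin2 = tri$j, count = tri$x)
  data.table::setorder(dt, bin1, bin2)
  counts_path <- paste0(out_prefix, ".counts.tsv")
  data.table::fwrite(dt, counts_path, sep = "\t")
  bins <- data.table::copy(mat$bins)
  if (!is.null(mat$weights)) bins[, weight := mat$weights]
  bins_path <- paste0(out_prefix, ".bins.tsv")
  data.table::fwrite(bins, bins_path, sep = "\t")
  invisible(c(counts = counts_path, bins = bins_path))
}

#' Read a matrix written by [write_matrix()]
#'
#' @param out_prefix prefix used at write time.
#' @param chromsizes named chromosome sizes (genome order).
#' @param resolution bin size in bp.
#' @return a `cifi_matrix`.
#' @export
read_matrix <- function(out_prefix, chromsizes, resolution) {
  bt <- bin_table(chromsizes, resolution)
  bins_in <- data.table::fread(paste0(out_prefix, ".bins.tsv"))
  if (nrow(bins_in) != nrow(bt)) stop("bin table mismatch on read_matrix")
  tri <- data.table::fread(paste0(out_prefix, ".counts.tsv"))
  counts <- Matrix::sparseMatrix(i = tri$bin1, j = tri$bin2, x = tri$count,
                                 dims = c(nrow(bt), nrow(bt)))
  w <- if ("weight" %in% names(bins_in)) bins_in$weight else NULL
  new_cifi_matrix(bt, methods::as(counts, "CsparseMatrix"),
                  normalization = if (is.null(w)) "raw" else "KR",
                  weights = w)
}
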