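# QC analyses: distance-decay profile of cis contacts, MAPQ-stratified
# mapping rates by annotation class, and windowed read-coverage tracks.

#' Distance-decay profile of cis contacts
#'
#' Histograms pairwise intrachromosomal distances (|pos2 - pos1|) of
#' non-duplicate cis pairs into log10-spaced bins, and reports per-bin
#' frequency normalized by bin width (the P(s) curve). 3C data follow an
#' approximate power law, so the log-log slope of the normalized frequency
#' estimates the decay exponent.
#'
#' @param pairs pair table.
#' @param n_bins number of log-spaced bins (default 64).
#' @param min_dist minimum distance in bp; closer pairs are excluded and
#'   counted (default 100).
#' @param max_dist upper edge in bp (default `10^8.5`, beyond any human
#'   chromosome).
#' @return list of class `cifi_decay`: `edges` (length `n_bins + 1`),
#'   `counts`, `freq` (count / bin width), `n_below_min`, `n_cis`. All-trans
#'   input returns zero counts with a warning.
#' @export
decay_profile <- function(pairs, n_bins = 64L, min_dist = 100, max_dist = 10^8.5) {
  p <- data.table::as.data.table(pairs)[duplicate_flag == FALSE & pair_type == "cis"]
  edges <- 10^seq(log10(min_dist), log10(max_dist), length.out = n_bins + 1L)
  out <- structure(list(edges = edges, counts = integer(n_bins),
                        freq = numeric(n_bins), n_below_min = 0L, n_cis = 0L),
                   class = "cifi_decay")
  if (nrow(p) == 0L) {
    warning("decay_profile: no cis pairs")
    return(out)
  }
  d <- abs(p$pos2 - p$pos1)
  out$n_below_min <- sum(d < min_dist)
  d <- d[d >= min_dist & d < max_dist]
  out$n_cis <- length(d)
  if (length(d) == 0L) return(out)
  idx <- findInterval(d, edges, rightmost.closed = TRUE)
  cnt <- tabulate(idx, nbins = n_bins)
  out$counts <- cnt
  out$freq <- cnt / diff(edges)
  out
}

#' Fit the distance-decay exponent
#'
#' Ordinary least squares of log10(frequency) on log10(distance midpoint)
#' over bins with nonzero counts inside `[fit_min, fit_max]`; returns the
#' slope (so a P(s) ~ s^-1 profile gives about -1).
#'
#' @param profile a `cifi_decay` from [decay_profile()].
#' @param fit_min,fit_max distance range used for the fit (defaults 1 kbp to
#'   10 Mbp, the quasi-linear regime).
#' @return list with `slope`, `intercept`, `n_bins_used`.
#' @export
fit_decay_exponent <- function(profile, fit_min = 1e3, fit_max = 1e7) {
  mids <- sqrt(profile$edges[-1] * profile$edges[-length(profile$edges)])
  use <- profile$counts > 0 & mids >= fit_min & mids <= fit_max
  if (sum(use) < 3L) stop("fit_decay_exponent: fewer than 3 usable bins")
  fit <- stats::lm(log10(profile$freq[use]) ~ log10(mids[use]))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n_bins_used = sum(use))
}

#' MAPQ-stratified mapping rates by annotation class
#'
#' For each annotation class (e.g. Alu, L1, SD, centromere, unique) and each
#' MAPQ threshold, the fraction of segments whose selected (best) alignment
#' overlaps the class by >= 1 bp and has MAPQ >= threshold, out of segments in
#' the class with any alignment. A segment overlapping two classes counts in
#' both (classes are analyzed independently). Classes with zero overlapping
#' segments are absent from the output rather than reported as 0.
#'
#' @param monomers monomer table including sub-threshold alignments (i.e.
#'   [ingest_alignments()] with `mapq_min = 0`).
#' @param annotations named list of per-class intervals: BED paths or
#'   data.frames with columns chrom, start, end (0-based half-open).
#' @param thresholds MAPQ thresholds (default `c(1, 10, 20, 30, 60)`).
#' @return `data.table` with `class_`, `threshold`, `n_in_class`,
#'   `n_at_threshold`, `fraction`. Fractions are non-increasing in threshold
#'   within a class.
#' @export
mapq_by_class <- function(monomers, annotations,
                          thresholds = c(1L, 10L, 20L, 30L, 60L)) {
  mm <- data.table::as.data.table(monomers)
  if (nrow(mm) == 0L) stop("mapq_by_class: no alignments")
  gr <- GenomicRanges::GRanges(as.character(mm$chrom),
                               IRanges::IRanges(mm$start + 1L, mm$end))
  res <- lapply(names(annotations), function(cls) {
    ann <- read_bed(annotations[[cls]])
    agr <- GenomicRanges::GRanges(ann$chrom, IRanges::IRanges(ann$start + 1L, ann$end))
    # suppressed warning: a class may live entirely on chromosomes with no
    # alignments (that is exactly the "absent class" case)
    ov <- suppressWarnings(GenomicRanges::findOverlaps(gr, agr))
    hit <- unique(S4Vectors::queryHits(ov))
    if (length(hit) == 0L) return(NULL)
    q <- mm$mapq[hit]
    data.table::data.table(
      class_ = cls,
      threshold = as.integer(thresholds),
      n_in_class = length(q),
      n_at_threshold = vapply(thresholds, function(t) sum(q >= t), integer(1)),
      fraction = vapply(thresholds, function(t) mean(q >= t), numeric(1))
    )
  })
  data.table::rbindlist(res)
}

# Read BED (path or data.frame) into a data.table(chrom, start, end).
read_bed <- function(x) {
  if (is.data.frame(x)) {
    dt <- data.table::as.data.table(x)
    data.table::setnames(dt, 1:3, c("chrom", "start", "end"))
    return(dt[, .(chrom = as.character(chrom), start, end)])
  }
  dt <- data.table::fread(x, header = FALSE, select = 1:3,
                          col.names = c("chrom", "start", "end"))
  dt[, chrom := as.character(chrom)]
  dt[]
}

#' Sliding-window mean coverage track
#'
#' Mean per-base alignment depth in sliding windows (default 5 kbp windows
#' stepping 4 kbp, i.e. 1 kbp overlap between successive windows).
#'
#' @param monomers monomer alignment table.
#' @param chromsizes named chromosome sizes.
#' @param window window size in bp (default 5000).
#' @param step window step in bp (default 4000; must be < window so that
#'   windows overlap by `window - step`).
#' @return `data.table` track: `chrom`, `start`, `end`, `depth` (mean
#'   per-base coverage; last window truncated at the chromosome end).
#' @export
windowed_coverage <- function(monomers, chromsizes, window = 5000L, step = 4000L) {
  if (!(window > step && step > 0L)) stop("need window > step > 0")
  mm <- data.table::as.data.table(monomers)
  out <- lapply(names(chromsizes), function(cn) {
    L <- as.integer(chromsizes[[cn]])
    sel <- mm[as.character(chrom) == cn]
    cov <- IRanges::coverage(IRanges::IRanges(sel$start + 1L, sel$end), width = L)
    starts <- seq(0L, max(0L, L - 1L), by = step)
    ends <- pmin(starts + window, L)
    v <- IRanges::Views(cov, start = starts + 1L, end = ends)
    data.table::data.table(chrom = cn, start = starts, end = ends,
                           depth = IRanges::viewMeans(v))
  })
  data.table::rbindlist(out)
}

#' Compare two coverage tracks
#'
#' Both tracks are normalized to genome-wide mean depth 1, smoothed with a
#' centered rolling mean over `k` windows, and differenced (A - B). Tracks
#' must be on identical windows.
#'
#' @param a,b coverage tracks from [windowed_coverage()].
#' @param k rolling-mean width in windows (default 25).
#' @return `data.table`: `chrom`, `start`, `end`, `depth_a`, `depth_b`
#'   (normalized, smoothed) and `diff`.
#' @export
compare_tracks <- function(a, b, k = 25L) {
  if (nrow(a) != nrow(b) || !all(a$start == b$start) ||
      !all(as.character(a$chrom) == as.character(b$chrom)))
    stop("tracks are on different windows")
  norm <- function(x) if (mean(x) > 0) x / mean(x) else x
  out <- data.table::data.table(chrom = a$chrom, start = a$start, end = a$end)
  sm <- function(x) {
    y <- data.table::frollmean(x, k, align = "center")
    y[is.na(y)] <- x[is.na(y)]  # edges: fall back to the raw value
    y
  }
  out[, depth_a := norm(a$depth)]
  out[, depth_b := norm(b$depth)]
  out[, depth_a := sm(depth_a), by = chrom]   # smooth within chromosomes
  out[, depth_b := sm(depth_b), by = chrom]
  out[, diff := depth_a - depth_b]
  out[]
}

#' Write a coverage track as bedGraph
#'
#' @param track from [windowed_coverage()]; the `value_col` column is written.
#' @param path output path.
#' @param value_col column to export (default "depth").
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, value_col = "depth") {
  dt <- track[, .(chrom = as.character(chrom), start, end,
                  value = get(value_col))]
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
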