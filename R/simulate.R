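# Concatemer-read simulator with known contact structure.
#
# Reads are built fragment-by-fragment from an in-silico digested synthetic
# genome: an anchor restriction fragment plus partners drawn either in trans
# (uniform fragment on another chromosome) or in cis with partner distance s
# between fragment midpoints drawn with probability proportional to s^-alpha,
# emulating the power-law distance decay of 3C contacts. The junction between
# consecutive monomers reconstitutes the full recognition motif exactly once
# (the signature of a sticky-end ligation product). Because the built-in
# motifs are borderless (no proper prefix equals a suffix) and palindromic,
# no spurious motif can straddle a junction or arise inside a monomer core,
# so in-silico digestion of a simulated read recovers the monomer boundaries
# exactly. Truth tables and perfect "oracle" alignments accompany every read.

#' Simulator configuration
#'
#' Defaults describe a small but realistic world: a two-chromosome genome at
#' human-like GC, DpnII digestion, reads with a median of 17 segments
#' (shifted negative binomial, dispersion 1.5), cis decay exponent 1, a 25%
#' trans-contact fraction, and a 1.8% read-duplication rate.
#'
#' @param seed integer RNG seed.
#' @param n_chroms number of chromosomes.
#' @param chrom_lengths integer vector of lengths (recycled to `n_chroms`).
#' @param gc GC content of the random genome.
#' @param enzyme built-in enzyme name or [restriction_enzyme()].
#' @param n_reads number of concatemer reads.
#' @param median_segments target median monomers per read.
#' @param dispersion negative-binomial size parameter of the segment-count
#'   distribution.
#' @param alpha cis decay exponent (P(s) ~ s^-alpha), > 0.
#' @param trans_fraction probability that a partner monomer is trans
#'   (ignored when the genome has a single chromosome).
#' @param dup_rate fraction of reads duplicated verbatim (PCR-duplicate
#'   emulation).
#' @param duplication optional planted segmental duplication:
#'   `list(chrom, start, end, dest_chrom, dest_start, identity)`; the source
#'   interval is copied to the destination with per-base substitution rate
#'   `1 - identity`, and monomers inside either copy get MAPQ 0 in the oracle
#'   alignments (multi-mapping ambiguity).
#' @param tad_blocks optional planted domain structure: named list per
#'   chromosome of boundary positions in bp; cis partners in the anchor's
#'   domain get their sampling weight multiplied by `within_ratio`.
#' @param within_ratio within-domain contact weight multiplier (default 4).
#' @return list of class `cifi_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_lengths = 1e6,
                       gc = 0.41,
                       enzyme = "DpnII",
                       n_reads = 1000L,
                       median_segments = 17L,
                       dispersion = 1.5,
                       alpha = 1.0,
                       trans_fraction = 0.25,
                       dup_rate = 0.018,
                       duplication = NULL,
                       tad_blocks = NULL,
                       within_ratio = 4) {
  stopifnot(trans_fraction >= 0, trans_fraction <= 1,
            dup_rate >= 0, dup_rate < 1,
            median_segments >= 1, alpha > 0, gc > 0, gc < 1)
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_lengths = rep_len(as.integer(chrom_lengths), n_chroms),
              gc = gc, enzyme = as_enzyme(enzyme), n_reads = as.integer(n_reads),
              median_segments = as.integer(median_segments),
              dispersion = dispersion, alpha = alpha,
              trans_fraction = trans_fraction, dup_rate = dup_rate,
              duplication = duplication, tad_blocks = tad_blocks,
              within_ratio = within_ratio)
  class(cfg) <- "cifi_sim_config"
  cfg
}

#' Simulate a genome and its fragment map
#'
#' I.i.d. random sequence at the configured GC content; the optional planted
#' duplication is implanted before digestion. Deterministic for a fixed seed.
#'
#' @param config a [sim_config()].
#' @return list: `genome` (named character), `chromsizes`, `fragment_map`
#'   (from [digest_genome()]), `duplication_intervals` (`data.table` of the
#'   two copies, or NULL).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  base_p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
              G = config$gc / 2, T = (1 - config$gc) / 2)
  genome <- vapply(seq_len(config$n_chroms), function(i) {
    paste(sample(names(base_p), config$chrom_lengths[i], replace = TRUE,
                 prob = base_p), collapse = "")
  }, character(1))
  names(genome) <- paste0("chr", seq_len(config$n_chroms))
  dup_iv <- NULL
  if (!is.null(config$duplication)) {
    d <- config$duplication
    src <- substring(genome[[d$chrom]], d$start + 1L, d$end)
    sub_rate <- 1 - d$identity
    chars <- strsplit(src, "")[[1]]
    hit <- which(stats::runif(length(chars)) < sub_rate)
    if (length(hit)) {
      chars[hit] <- vapply(chars[hit], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    }
    copy <- paste(chars, collapse = "")
    g <- genome[[d$dest_chrom]]
    genome[[d$dest_chrom]] <- paste0(
      substring(g, 1L, d$dest_start),
      copy,
      substring(g, d$dest_start + nchar(copy) + 1L, nchar(g)))
    dup_iv <- data.table::data.table(
      chrom = c(d$chrom, d$dest_chrom),
      start = c(d$start, d$dest_start),
      end = c(d$end, d$dest_start + nchar(copy)))
  }
  fm <- digest_genome(genome, config$enzyme)
  list(genome = genome,
       chromsizes = stats::setNames(nchar(genome), names(genome)),
       fragment_map = fm,
       duplication_intervals = dup_iv)
}

# Solve for the negative-binomial mu whose shifted (1 + NB) median hits the
# target; deterministic.
nb_mu_for_median <- function(median_target, size) {
  target <- median_target - 1L
  if (target == 0L) return(0.01)
  f <- function(mu) stats::qnbinom(0.5, size = size, mu = mu) - target
  hi <- max(10, target * 10)
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(1e-3, hi))$root
}

#' Simulate concatemer reads with truth tables
#'
#' See the module header for the generative model. Monomer strands are
#' uniform random. The oracle alignment interval of a monomer is the
#' fragment interval for forward monomers and the interval shifted by
#' `len(motif) - 2 * cut_offset` for reverse monomers (the cut-offset shift
#' of a reverse-complemented ligation product).
#'
#' @param sim output of [simulate_genome()].
#' @param config the same [sim_config()].
#' @param sequences assemble read sequences (default TRUE; FALSE skips
#'   sequence assembly when only truth/alignments are needed).
#' @return list: `reads` (named character, or NULL), `truth` (`data.table`:
#'   `read_id`, `ordinal`, `fragment_index`, `chrom`, `start`, `end`
#'   (fragment interval), `strand`, `read_start`, `read_end`, `mapq`,
#'   `is_anchor` (TRUE for the read's anchor monomer, whose partner
#'   distances follow the sampled decay law directly), `duplicate_of`),
#'   `oracle` (alignment table: `read_id`, `ordinal`,
#'   `chrom`, `start`, `end` (strand-aware interval), `strand`, `mapq`).
#' @export
simulate_reads <- function(sim, config, sequences = TRUE) {
  set.seed(config$seed + 1L)
  fm <- data.table::copy(data.table::as.data.table(sim$fragment_map))
  enz <- config$enzyme
  M <- nchar(enz$motif); cu <- enz$cut_offset
  shift <- M - 2L * cu
  chroms <- names(sim$chromsizes)
  trans_fraction <- if (length(chroms) > 1L) config$trans_fraction else 0
  fm[, chrom := as.character(chrom)]
  # eligible fragments: interior (not first/last of chromosome), non-empty
  # core, and strand-shifted interval within the chromosome
  elig <- fm[, .SD[-c(1L, .N)], by = chrom]
  elig <- elig[(end - start) > M + 1L]
  elig <- elig[end + abs(shift) <= sim$chromsizes[chrom] &
               start - abs(shift) >= 0]
  cnt <- elig[, .N, by = chrom]
  if (nrow(cnt) < length(chroms) || any(cnt$N < 10L))
    stop("fewer than 10 eligible fragments on some chromosome; enlarge the genome")
  elig[, midpoint := (start + end) / 2]
  rows_by_chrom <- split(seq_len(nrow(elig)),
                         factor(elig$chrom, levels = chroms))
  n_per_chrom <- lengths(rows_by_chrom)
  mids <- elig$midpoint
  dom <- rep(1L, nrow(elig))
  if (!is.null(config$tad_blocks)) {
    for (cn in names(config$tad_blocks)) {
      rc <- rows_by_chrom[[cn]]
      dom[rc] <- findInterval(mids[rc], sort(config$tad_blocks[[cn]])) + 1L
    }
  }

  mu <- nb_mu_for_median(config$median_segments, config$dispersion)
  n_seg <- 1L + stats::rnbinom(config$n_reads, size = config$dispersion, mu = mu)

  picks <- vector("list", config$n_reads)
  anchor_ord <- integer(config$n_reads)
  chrom_ids <- seq_along(chroms)
  for (r in seq_len(config$n_reads)) {
    n <- n_seg[r]
    a_chrom <- chrom_ids[sample.int(length(chrom_ids), 1L, prob = n_per_chrom)]
    rc <- rows_by_chrom[[a_chrom]]
    anchor <- rc[sample.int(length(rc), 1L)]
    sel <- anchor
    if (n > 1L) {
      n_trans <- stats::rbinom(1L, n - 1L, trans_fraction)
      if (n_trans > 0L) {
        oth <- chrom_ids[-a_chrom]
        tc <- oth[sample.int(length(oth), n_trans, replace = TRUE,
                             prob = n_per_chrom[oth])]
        tsel <- vapply(tc, function(ci) {
          rr <- rows_by_chrom[[ci]]
          rr[sample.int(length(rr), 1L)]
        }, integer(1))
        sel <- c(sel, tsel)
      }
      n_cis <- n - 1L - n_trans
      if (n_cis > 0L) {
        d <- abs(mids[rc] - mids[anchor])
        wgt <- pmax(d, 1)^(-config$alpha)
        wgt[rc == anchor] <- 0
        if (!is.null(config$tad_blocks)) {
          same <- dom[rc] == dom[anchor]
          wgt[same] <- wgt[same] * config$within_ratio
        }
        sel <- c(sel, rc[sample.int(length(rc), n_cis, replace = TRUE, prob = wgt)])
      }
      sel <- sel[sample.int(length(sel))]  # shuffle monomer order
    }
    picks[[r]] <- sel
    anchor_ord[r] <- which(sel == anchor)[1] - 1L
  }
  nseg_eff <- lengths(picks)
  flat <- unlist(picks, use.names = FALSE)
  truth <- elig[flat, .(fragment_index, chrom, start, end)]
  truth[, read_id := rep(sprintf("read%06d", seq_len(config$n_reads)), nseg_eff)]
  truth[, ordinal := unlist(lapply(nseg_eff, seq_len), use.names = FALSE) - 1L]
  truth[, is_anchor := ordinal == rep(anchor_ord, nseg_eff)]
  truth[, strand := sample(c("+", "-"), .N, replace = TRUE)]
  # read-local boundaries: every monomer occupies exactly fragment-length bp
  truth[, length_ := end - start]
  truth[, read_end := cumsum(length_), by = read_id]
  truth[, read_start := read_end - length_]
  truth[, length_ := NULL]
  truth[, mapq := 60L]
  if (!is.null(sim$duplication_intervals)) {
    di <- sim$duplication_intervals
    for (k in seq_len(nrow(di))) {
      truth[chrom == di$chrom[k] & start < di$end[k] & end > di$start[k],
            mapq := 0L]
    }
  }
  truth[, duplicate_of := NA_character_]
  data.table::setcolorder(truth, c("read_id", "ordinal", "fragment_index",
                                   "chrom", "start", "end", "strand",
                                   "read_start", "read_end", "mapq",
                                   "is_anchor", "duplicate_of"))
  reads <- if (sequences) assemble_reads(truth, sim$genome, enz) else NULL
  list(reads = reads, truth = truth,
       oracle = truth_to_oracle(truth, enz))
}

# Oracle alignments from a truth table: reverse-strand monomers map to the
# fragment interval shifted by motif_len - 2 * cut_offset.
truth_to_oracle <- function(truth, enzyme) {
  sh <- nchar(enzyme$motif) - 2L * enzyme$cut_offset
  o <- truth[, .(read_id, ordinal, chrom, start, end, strand, mapq)]
  o[strand == "-", `:=`(start = start + sh, end = end + sh)]
  o[]
}

# Assemble read sequences: motif-prefix + core_1 + motif + core_2 + ... +
# motif + core_n + motif-suffix, cores strand-aware. A fragment [s,e) carries
# m[cut..M) at its start and m[0..cut) at its end (cut-site boundaries), so
# its core is [s + M - cut, e - cut).
assemble_reads <- function(truth, genome, enz) {
  M <- nchar(enz$motif); cu <- enz$cut_offset
  lead <- substring(enz$motif, cu + 1L, M)   # m[cut..M)
  trail <- substring(enz$motif, 1L, cu)      # m[0..cut)
  tr <- truth[, .(read_id, chrom = as.character(chrom), start, end, strand)]
  tr[, core := substring(genome[chrom], start + (M - cu) + 1L, end - cu)]
  rev_idx <- which(tr$strand == "-")
  if (length(rev_idx)) tr[rev_idx, core := revcomp(core)]
  reads <- tr[, paste0(lead, paste(core, collapse = enz$motif), trail),
              by = read_id]
  stats::setNames(reads$V1, reads$read_id)
}

#' Append exact-copy duplicate reads
#'
#' Copies `ceiling(rate * n)` randomly chosen reads verbatim under new ids
#' (`<id>_dup`), linking them in the truth table via `duplicate_of`.
#'
#' @param reads named character vector of read sequences (or NULL).
#' @param truth truth table from [simulate_reads()].
#' @param rate duplication rate in `[0, 1)`.
#' @param seed RNG seed for the choice of copied reads.
#' @return list with augmented `reads` and `truth`.
#' @export
inject_duplicates <- function(reads, truth, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(list(reads = reads, truth = truth))
  set.seed(seed)
  ids <- unique(truth$read_id)
  n_dup <- ceiling(rate * length(ids))
  pick <- sample(ids, n_dup)
  extra <- data.table::copy(truth[read_id %in% pick])
  extra[, duplicate_of := read_id]
  extra[, read_id := paste0(read_id, "_dup")]
  truth2 <- data.table::rbindlist(list(truth, extra), use.names = TRUE)
  reads2 <- reads
  if (!is.null(reads)) {
    reads2 <- c(reads, stats::setNames(reads[pick], paste0(pick, "_dup")))
  }
  list(reads = reads2, truth = truth2)
}

#' Run the full simulation and write all outputs
#'
#' Convenience wrapper: genome + fragment map + reads + truth + oracle, with
#' duplicates injected at the configured rate, optionally written as
#' plain-text files (FASTA, chrom.sizes, fragment BED, reads FASTQ, truth and
#' oracle TSV).
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if missing); NULL skips writing.
#' @param sequences assemble read sequences (see [simulate_reads()]).
#' @return list: `genome`, `chromsizes`, `fragment_map`,
#'   `duplication_intervals`, `reads`, `truth`, `oracle`, plus `paths` when
#'   `out_dir` is given.
#' @export
run_simulation <- function(config, out_dir = NULL, sequences = TRUE) {
  sim <- simulate_genome(config)
  rr <- simulate_reads(sim, config, sequences = sequences)
  dup <- inject_duplicates(rr$reads, rr$truth, config$dup_rate,
                           seed = config$seed + 2L)
  out <- list(genome = sim$genome, chromsizes = sim$chromsizes,
              fragment_map = sim$fragment_map,
              duplication_intervals = sim$duplication_intervals,
              reads = dup$reads, truth = dup$truth,
              oracle = truth_to_oracle(dup$truth, config$enzyme))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- list(
      fasta = file.path(out_dir, "genome.fa"),
      chromsizes = file.path(out_dir, "genome.chrom.sizes"),
      fragments = file.path(out_dir, "fragments.bed"),
      reads = file.path(out_dir, "reads.fastq"),
      truth = file.path(out_dir, "truth.tsv"),
      oracle = file.path(out_dir, "oracle.tsv"))
    write_fasta(sim$genome, p$fasta)
    write_chromsizes(sim$chromsizes, p$chromsizes)
    write_fragment_bed(sim$fragment_map, p$fragments)
    if (!is.null(out$reads)) write_fastq(out$reads, p$reads)
    data.table::fwrite(out$truth, p$truth, sep = "\t")
    data.table::fwrite(out$oracle, p$oracle, sep = "\t")
    out$paths <- p
  }
  out
}
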