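# End-to-end pipeline: digest -> ingest -> pairs -> matrix -> qc (-> tads),
# with a machine-readable run manifest.

#' Run the full contact pipeline
#'
#' Executes the standard stage order on one set of inputs and writes all
#' stage outputs plus a JSON manifest with per-stage counters. Deterministic:
#' identical inputs produce byte-identical outputs.
#'
#' @param config named list (or path to a JSON config) with entries:
#'   \describe{
#'     \item{reads}{FASTA/FASTQ path or named character vector (optional if
#'       `alignments` is given).}
#'     \item{genome}{FASTA path / named character vector (optional when
#'       `chromsizes` is given).}
#'     \item{chromsizes}{chrom.sizes path or named vector.}
#'     \item{enzyme}{built-in name, or list(name, motif, cut_offset).}
#'     \item{alignments}{BAM path or oracle TSV path/table.}
#'     \item{mapq_min}{MAPQ floor before pair expansion (default 1).}
#'     \item{min_segment_length}{digestion floor (default 20).}
#'     \item{resolutions}{bin sizes in bp (default c(50000, 2500000)).}
#'     \item{balance}{run KR balancing on each matrix (default TRUE).}
#'     \item{tads}{call TADs on the finest resolution (default FALSE).}
#'     \item{tad_w}{TAD window half-width in bins (default 5).}
#'     \item{out_dir}{output directory.}
#'   }
#' @return the run manifest (list), invisibly written as
#'   `<out_dir>/manifest.json`. Stage outputs land in `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- config
  if (is.null(cfg$out_dir)) stop("[config] out_dir is required")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  mapq_min <- cfg$mapq_min %||% 1L
  min_seg <- cfg$min_segment_length %||% 20L
  resolutions <- cfg$resolutions %||% c(50000, 2500000)
  # the enzyme is only needed when reads are digested here
  enzyme <- NULL
  if (!is.null(cfg$enzyme)) {
    enzyme <- if (is.list(cfg$enzyme))
      restriction_enzyme(cfg$enzyme$name %||% "custom", cfg$enzyme$motif,
                         cfg$enzyme$cut_offset)
    else as_enzyme(cfg$enzyme)
  }

  manifest <- list(tool = "cifi", version = as.character(utils::packageVersion("cifi")),
                   stages = list(), outputs = list())

  chromsizes <- NULL
  if (!is.null(cfg$chromsizes)) {
    chromsizes <- if (is.character(cfg$chromsizes) && length(cfg$chromsizes) == 1L)
      read_chromsizes(cfg$chromsizes) else cfg$chromsizes
  }
  if (!is.null(cfg$genome)) {
    g <- as_genome(cfg$genome)
    if (is.null(chromsizes)) chromsizes <- stats::setNames(nchar(g), names(g))
  }
  if (is.null(chromsizes)) stop("[config] need genome or chromsizes")

  # -- stage: digest ---------------------------------------------------------
  segments <- NULL
  if (!is.null(cfg$reads)) {
    if (is.null(enzyme)) stop("[digest] reads given but no enzyme configured")
    segments <- digest_reads(cfg$reads, enzyme, min_segment_length = min_seg)
    write_segments(segments, file.path(cfg$out_dir, "run"))
    manifest$stages$digest <- list(
      n_reads = length(unique(segments$read_id)),
      n_segments = nrow(segments),
      n_filtered = sum(segments$filtered))
  }

  # -- stage: ingest ---------------------------------------------------------
  if (is.null(cfg$alignments))
    stop("[ingest] config must name a BAM or oracle alignment TSV")
  monomers <- ingest_alignments(cfg$alignments, mapq_min = mapq_min,
                                chrom_order = names(chromsizes))
  cnts <- attr(monomers, "counts")
  manifest$stages$ingest <- as.list(cnts)
  if (!is.null(segments)) {
    # counter consistency: every selected monomer is a digested segment
    seg_keys <- segments[filtered == FALSE, paste(read_id, ordinal)]
    mono_keys <- monomers[, paste(read_id, ordinal)]
    manifest$stages$ingest$n_monomers_not_in_digest <-
      sum(!mono_keys %in% seg_keys)
  }

  # -- stage: pairs ----------------------------------------------------------
  pairs <- expand_pairs(monomers)
  pairs <- sort_pairs(pairs)
  pairs <- dedup_pairs(pairs)
  pairs_path <- file.path(cfg$out_dir, "run.pairs")
  write_pairs(pairs, chromsizes, pairs_path, drop_duplicates = TRUE)
  st <- pair_stats(pairs, monomers)
  manifest$stages$pairs <- st
  manifest$outputs$pairs <- pairs_path

  # -- stage: matrix ---------------------------------------------------------
  manifest$stages$matrix <- list()
  for (res in resolutions) {
    bt <- bin_table(chromsizes, res)
    cm <- bin_pairs(pairs, bt)
    if (isTRUE(cfg$balance %||% TRUE)) {
      cm <- tryCatch(kr_balance(cm), error = function(e) {
        warning("[matrix] balancing failed at ", res, " bp: ", conditionMessage(e))
        cm
      })
    }
    prefix <- file.path(cfg$out_dir, sprintf("run.%d", as.integer(res)))
    write_matrix(cm, prefix)
    manifest$stages$matrix[[as.character(res)]] <- list(
      resolution = res, n_bins = nrow(cm$bins),
      total = matrix_total(cm), normalization = cm$normalization)
    manifest$outputs[[paste0("matrix_", res)]] <- paste0(prefix, ".counts.tsv")
    if (res == min(resolutions)) cm_fine <- cm
  }

  # -- stage: qc -------------------------------------------------------------
  decay <- decay_profile(pairs)
  manifest$stages$qc <- list(
    n_cis = decay$n_cis,
    n_below_min_dist = decay$n_below_min,
    cis_fraction = st$cis_fraction)
  cov <- windowed_coverage(monomers, chromsizes)
  write_bedgraph(cov, file.path(cfg$out_dir, "run.coverage.bedgraph"))

  # -- stage: tads (optional) ------------------------------------------------
  if (isTRUE(cfg$tads)) {
    tads <- call_tads(cm_fine, w = cfg$tad_w %||% 5L)
    write_tads_bed(tads, file.path(cfg$out_dir, "run.tads.bed"))
    manifest$stages$tads <- list(n_domains = nrow(tads))
  }

  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest$outputs$manifest <- manifest_path
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
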