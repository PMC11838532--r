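# Alignment ingestion, pairwise expansion, dedup, pairs I/O.

make_monomers <- function(n, read_id = "r1", chrom = "chr1",
                          chrom_levels = c("chr1", "chr2")) {
  data.table::data.table(
    read_id = read_id,
    ordinal = seq_len(n) - 1L,
    chrom = factor(chrom, levels = chrom_levels),
    start = seq(1000L, by = 500L, length.out = n),
    end = seq(1300L, by = 500L, length.out = n),
    strand = rep(c("+", "-"), length.out = n),
    mapq = 60L)
}

test_that("ingest_alignments selects primary, best placements", {
  aln <- data.table::data.table(
    read_id = c("r1", "r1", "r1", "r2", "r3"),
    ordinal = c(0L, 0L, 1L, 0L, 0L),
    chrom = c("chr1", "chr2", "chr1", "chr1", "chr1"),
    start = c(100L, 900L, 5000L, 10L, 20L),
    end = c(400L, 1200L, 5300L, 310L, 320L),
    strand = c("+", "+", "-", "+", "+"),
    mapq = c(60L, 0L, 30L, 0L, 1L),
    is_primary = c(TRUE, FALSE, TRUE, TRUE, TRUE))
  mono <- ingest_alignments(aln, mapq_min = 1L, chrom_order = c("chr1", "chr2"))
  # r1:0 -> the primary; r2:0 dropped (below threshold); r3 kept at mapq 1
  expect_equal(nrow(mono), 3L)
  expect_equal(mono[read_id == "r1" & ordinal == 0, start], 100L)
  expect_false("r2" %in% mono$read_id)
  cnt <- attr(mono, "counts")
  expect_equal(unname(cnt["n_below_mapq"]), 1L)
  expect_equal(unname(cnt["n_segments_aligned"]), 4L)

  # secondary never beats primary even at higher mapq
  aln2 <- data.table::data.table(
    read_id = "x", ordinal = 0L, chrom = c("chr1", "chr2"),
    start = c(0L, 0L), end = c(100L, 100L), strand = "+",
    mapq = c(10L, 60L), is_primary = c(TRUE, FALSE))
  m2 <- ingest_alignments(aln2, mapq_min = 1L, chrom_order = c("chr1", "chr2"))
  expect_equal(as.character(m2$chrom), "chr1")

  expect_error(
    ingest_alignments(data.table::data.table(read_id = "a", ordinal = 0L,
                                             chrom = "chr1", start = 5L,
                                             end = 5L, strand = "+", mapq = 60L)),
    "end <= start")
})

test_that("BAM ingestion honours the segment-name contract", {
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "seg.sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:chr1\tLN:10000",
    "@SQ\tSN:chr2\tLN:8000",
    # primary mapq 60 and a secondary for the same segment
    "r1:0:0:300\t0\tchr1\t101\t60\t300M\t*\t0\t0\t*\t*",
    "r1:0:0:300\t256\tchr2\t201\t0\t300M\t*\t0\t0\t*\t*",
    "r1:1:300:650\t16\tchr1\t2001\t30\t100M50D200M\t*\t0\t0\t*\t*",
    "r2:0:0:200\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "seg"), overwrite = TRUE)
  mono <- ingest_alignments(bam, mapq_min = 1L)
  expect_equal(nrow(mono), 2L)
  r10 <- mono[read_id == "r1" & ordinal == 0]
  expect_equal(as.character(r10$chrom), "chr1")
  expect_equal(r10$start, 100L)   # 1-based BAM pos -> 0-based
  expect_equal(r10$end, 400L)
  r11 <- mono[read_id == "r1" & ordinal == 1]
  expect_equal(r11$strand, "-")
  expect_equal(r11$end - r11$start, 350L)  # CIGAR reference span incl. D

  # malformed names are a hard error
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:10000",
               "weird_name\t0\tchr1\t1\t60\t50M\t*\t0\t0\t*\t*"),
             file.path(dir, "bad.sam"))
  bad <- Rsamtools::asBam(file.path(dir, "bad.sam"), file.path(dir, "bad"),
                          overwrite = TRUE)
  expect_error(ingest_alignments(bad), "does not match")
})

test_that("expand_pairs emits all C(n,2) unordered pairs", {
  expect_equal(nrow(expand_pairs(make_monomers(2))), 1L)
  expect_equal(nrow(expand_pairs(make_monomers(4))), 6L)
  expect_equal(nrow(expand_pairs(make_monomers(17))), 136L)
  expect_equal(nrow(expand_pairs(make_monomers(1))), 0L)
  expect_equal(nrow(expand_pairs(make_monomers(2)[0])), 0L)

  # counts n(n-1)/2 for n in 0..50, and exact pair sets vs combn for small n
  for (n in c(0:8, 20, 50)) {
    mm <- make_monomers(max(n, 1))[seq_len(n)]
    p <- expand_pairs(mm)
    expect_equal(nrow(p), n * (n - 1) / 2)
    if (n >= 2 && n <= 8) {
      expect_equal(unname(as.data.frame(p[, .(ord1, ord2)])),
                   unname(as.data.frame(t(utils::combn(0:(n - 1), 2)))),
                   ignore_attr = TRUE)
    }
  }
})

test_that("mate order is normalized to the upper triangle", {
  mm <- make_monomers(3)
  mm$chrom <- factor(c("chr2", "chr1", "chr1"), levels = c("chr1", "chr2"))
  mm$start <- c(100L, 900L, 200L)
  mm$end <- mm$start + 100L
  p <- expand_pairs(mm)
  ci1 <- as.integer(p$chrom1); ci2 <- as.integer(p$chrom2)
  expect_true(all(ci1 < ci2 | (ci1 == ci2 & p$pos1 <= p$pos2)))
  expect_equal(sort(p$pair_type), c("cis", "trans", "trans"))

  # permuting the monomers never changes the serialized pair set
  p2 <- expand_pairs(mm[c(3, 1, 2)][, ordinal := 0:2])
  cols <- c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")
  expect_equal(as.data.frame(sort_pairs(p)[, cols, with = FALSE]),
               as.data.frame(sort_pairs(p2)[, cols, with = FALSE]))
})

test_that("dedup_pairs flags cross-read duplicates only", {
  mk <- function(read, pos1, pos2, s2 = "+") data.table::data.table(
    read_id = read, chrom1 = factor("chr1"), pos1 = pos1, strand1 = "+",
    chrom2 = factor("chr1"), pos2 = pos2, strand2 = s2,
    ord1 = 0L, ord2 = 1L, pair_type = "cis", duplicate_flag = FALSE)
  p <- data.table::rbindlist(list(mk("a", 10L, 50L), mk("b", 10L, 50L),
                                  mk("c", 10L, 60L)))
  d <- dedup_pairs(p)
  expect_equal(d$duplicate_flag, c(FALSE, TRUE, FALSE))

  # strand difference protects from flagging
  p2 <- data.table::rbindlist(list(mk("a", 10L, 50L, "+"), mk("b", 10L, 50L, "-")))
  expect_equal(dedup_pairs(p2)$duplicate_flag, c(FALSE, FALSE))

  # same-read pairs never flag each other
  p3 <- data.table::rbindlist(list(mk("a", 10L, 50L), mk("a", 10L, 50L)))
  expect_equal(dedup_pairs(p3)$duplicate_flag, c(FALSE, FALSE))

  expect_error(dedup_pairs(data.table::rbindlist(list(mk("a", 99L, 100L),
                                                      mk("b", 10L, 50L)))),
               "not sorted")
})

test_that("cis_fraction counts non-duplicate pairs", {
  p <- expand_pairs(make_monomers(4))
  expect_equal(cis_fraction(p), 1.0)
  p$pair_type <- c("cis", "cis", "cis", "trans", "cis", "cis")
  p$duplicate_flag <- c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  expect_equal(cis_fraction(p), 0.75)
})

test_that("pairs files round-trip through the 4DN format", {
  dir <- withr::local_tempdir()
  cs <- c(chrA = 1000, chrB = 500)
  p <- data.table::data.table(
    read_id = "r", chrom1 = factor("chrA", levels = names(cs)), pos1 = 11L,
    strand1 = "+", chrom2 = factor("chrA", levels = names(cs)), pos2 = 51L,
    strand2 = "-", ord1 = 0L, ord2 = 1L, pair_type = "cis",
    duplicate_flag = FALSE)
  path <- file.path(dir, "t.pairs")
  write_pairs(p, cs, path)
  lines <- readLines(path)
  expect_equal(lines[1], "## pairs format v1.0")
  expect_true(any(grepl("^#chromsize: chrA 1000$", lines)))
  body <- lines[!startsWith(lines, "#")]
  expect_equal(body, "r\tchrA\t12\tchrA\t52\t+\t-")  # 1-based on disk

  rt <- read_pairs(path)
  expect_equal(rt$pos1, p$pos1)
  expect_equal(rt$pos2, p$pos2)
  expect_equal(as.character(rt$chrom1), "chrA")
  expect_equal(attr(rt, "chromsizes"), cs)

  # empty set -> header-only file, still parseable
  write_pairs(p[0], cs, file.path(dir, "e.pairs"))
  e <- read_pairs(file.path(dir, "e.pairs"))
  expect_equal(nrow(e), 0L)

  # gzip transparent
  write_pairs(p, cs, file.path(dir, "t.pairs.gz"))
  expect_equal(read_pairs(file.path(dir, "t.pairs.gz"))$pos1, p$pos1)

  expect_error(write_pairs(p, c(chrX = 100), file.path(dir, "x.pairs")),
               "absent from chromsizes")
})

test_that("pair counts are conserved and distances match simulator truth", {
  ss <- std_sim()
  sim <- ss$sim
  mono <- ingest_alignments(sim$oracle, mapq_min = 1L,
                            chrom_order = names(sim$chromsizes))
  p <- expand_pairs(mono)
  n_per_read <- mono[, .N, by = read_id]$N
  expect_equal(nrow(p), sum(choose(n_per_read, 2)))

  # >= 99% of cis pairs at the truth fragment distance up to the cut-offset
  # shift (4 bp for DpnII reverse-strand monomers)
  tr <- sim$truth
  key <- tr[, .(read_id, ordinal, tstart = start)]
  pj <- merge(p[pair_type == "cis"],
              key[, .(read_id, ord1 = ordinal, t1 = tstart)],
              by = c("read_id", "ord1"))
  pj <- merge(pj, key[, .(read_id, ord2 = ordinal, t2 = tstart)],
              by = c("read_id", "ord2"))
  shift_ok <- abs(abs(pj$pos2 - pj$pos1) - abs(pj$t2 - pj$t1)) <= 4L
  expect_gte(mean(shift_ok), 0.99)

  # duplicate flagging captures exactly the copied reads' pairs (plus at
  # most a sliver of coincidental cross-read repeats)
  pd <- dedup_pairs(sort_pairs(p))
  dup_ids <- unique(tr[!is.na(duplicate_of), read_id])
  n_dup_pairs <- pd[read_id %in% dup_ids, .N]
  expect_equal(mean(pd[read_id %in% dup_ids, duplicate_flag]), 1)  # full recall
  # this fixture's genome is tiny (2 x 400 kbp), so coincidental cross-read
  # repeats add a few percent on top of the true copies
  expect_gte(sum(pd$duplicate_flag), n_dup_pairs)
  expect_lt(sum(pd$duplicate_flag) - n_dup_pairs, 0.05 * nrow(pd))
})
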