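# Binning, coarsening, KR balancing, dump and correlation.

simple_pairs <- function(chrom1, pos1, chrom2, pos2, levels = c("chr1", "chr2")) {
  data.table::data.table(
    read_id = paste0("r", seq_along(pos1)),
    chrom1 = factor(chrom1, levels = levels), pos1 = as.integer(pos1),
    strand1 = "+",
    chrom2 = factor(chrom2, levels = levels), pos2 = as.integer(pos2),
    strand2 = "+", ord1 = 0L, ord2 = 1L,
    pair_type = ifelse(chrom1 == chrom2, "cis", "trans"),
    duplicate_flag = FALSE)
}

test_that("bin_table tiles the genome with dense global indices", {
  cs <- c(chr1 = 120001, chr2 = 50000)
  bt <- bin_table(cs, 50000)
  expect_equal(nrow(bt), 3L + 1L)      # ceil(120001/50k)=3, ceil(50000/50k)=1
  expect_equal(bt$bin_id, 1:4)
  expect_equal(bt[3, end], 120001L)    # last bin short
  expect_equal(bt[4, start], 0L)
})

test_that("bin_pairs conserves totals and places cells correctly", {
  cs <- c(chr1 = 100000, chr2 = 100000)
  bt <- bin_table(cs, 10000)
  p1 <- simple_pairs("chr1", 1200, "chr1", 1800)
  cm <- bin_pairs(p1, bt)
  expect_equal(as.numeric(cm$counts[1, 1]), 1)     # both mates in bin 1
  expect_equal(matrix_total(cm), 1)

  p136 <- expand_pairs(data.table::data.table(
    read_id = "big", ordinal = 0:16,
    chrom = factor("chr1", levels = names(cs)),
    start = seq(0L, by = 5000L, length.out = 17),
    end = seq(400L, by = 5000L, length.out = 17),
    strand = "+", mapq = 60L))
  expect_equal(matrix_total(bin_pairs(p136, bt)), 136)

  set.seed(5)
  pr <- simple_pairs(sample(names(cs), 500, TRUE), sample(0:99999, 500, TRUE),
                     sample(names(cs), 500, TRUE), sample(0:99999, 500, TRUE))
  expect_equal(matrix_total(bin_pairs(pr, bt)), 500)

  expect_error(bin_pairs(simple_pairs("chr1", 100000, "chr1", 5), bt),
               "outside chromosome")
})

test_that("coarsening 50x reproduces direct binning exactly", {
  ss <- std_sim()
  sim <- ss$sim
  mono <- ingest_alignments(sim$oracle, mapq_min = 1L,
                            chrom_order = names(sim$chromsizes))
  p <- dedup_pairs(sort_pairs(expand_pairs(mono)))
  fine <- bin_pairs(p, bin_table(sim$chromsizes, 1000))
  direct <- bin_pairs(p, bin_table(sim$chromsizes, 50000))
  coarse <- coarsen_matrix(fine, 50000)
  expect_equal(matrix_total(fine), sum(!p$duplicate_flag))
  expect_equal(matrix_total(direct), sum(!p$duplicate_flag))
  expect_true(all(coarse$counts == direct$counts))
})

test_that("kr_balance handles closed-form cases", {
  # identity pattern: all weights 1
  w <- kr_balance(Matrix::Diagonal(5, x = 1))
  expect_equal(as.numeric(w), rep(1, 5), tolerance = 1e-8)
  # 2x2 closed form: [[0,2],[2,0]] -> w = 1/sqrt(2)
  A <- Matrix::Matrix(c(0, 2, 2, 0), 2, 2, sparse = TRUE)
  w2 <- kr_balance(A, mask_quantile = 0)
  expect_equal(as.numeric(w2), rep(1 / sqrt(2), 2), tolerance = 1e-6)
})

test_that("kr_balance agrees with an independent Sinkhorn oracle", {
  set.seed(23)
  for (trial in 1:3) {
    n <- 50
    A <- matrix(stats::runif(n * n, 0.1, 2), n, n)
    A <- (A + t(A)) / 2
    w <- kr_balance(A, tol = 1e-6, mask_quantile = 0)
    expect_identical(attr(w, "method"), "KR")
    rs <- as.numeric(w * (A %*% w))
    expect_lt(max(abs(rs - 1)), 1e-6)
    ws <- sinkhorn_oracle(A, tol = 1e-10)
    expect_equal(as.numeric(w), ws, tolerance = 1e-5)
  }
})

test_that("kr_balance masks empty and low-coverage bins", {
  set.seed(29)
  n <- 30
  A <- matrix(stats::runif(n * n, 0.5, 2), n, n); A <- (A + t(A)) / 2
  A[5, ] <- 0; A[, 5] <- 0            # empty bin
  w <- kr_balance(A)
  expect_true(is.na(w[5]))
  keep <- which(!is.na(w))
  rs <- (w[keep] * (A[keep, keep] %*% w[keep]))
  expect_lt(max(abs(rs - 1)), 1e-6)

  # cifi_matrix route records the normalization tag and bin weights
  cs <- c(chr1 = 100000)
  p <- simple_pairs(rep("chr1", 200),
                    sample(0:99999, 200, TRUE),
                    rep("chr1", 200), sample(0:99999, 200, TRUE),
                    levels = "chr1")
  cm <- bin_pairs(p, bin_table(cs, 10000))
  cmb <- kr_balance(cm)
  expect_s3_class(cmb, "cifi_matrix")
  expect_true(cmb$normalization %in% c("KR", "KR-sinkhorn"))
  expect_equal(length(cmb$weights), nrow(cmb$bins))
})

test_that("dump_counts is deterministic and conserves totals", {
  cs <- c(chr1 = 100000, chr2 = 100000)
  bt <- bin_table(cs, 10000)
  p <- simple_pairs(c("chr1", "chr1", "chr2"), c(100, 25000, 500),
                    c("chr1", "chr2", "chr2"), c(200, 61000, 800))
  cm <- bin_pairs(p, bt)
  one <- dump_counts(cm, "chr1:1-10000")
  expect_equal(nrow(one), 1L)
  expect_equal(one$count, 1)
  expect_equal(nrow(dump_counts(cm, "chr1:90001-100000")), 0L)
  # within-chr1 + within-chr2 + cross dumps partition the matrix total
  expect_equal(sum(dump_counts(cm, "chr1")$count) +
               sum(dump_counts(cm, "chr2")$count) +
               sum(dump_counts(cm, "chr1", "chr2")$count),
               matrix_total(cm))
})

test_that("correlate_matrices recovers known correlations", {
  cs <- c(chr1 = 1000000)
  bt <- bin_table(cs, 10000)   # 100 bins
  p <- simple_pairs(rep("chr1", 300), sample(0:999999, 300, TRUE),
                    rep("chr1", 300), sample(0:999999, 300, TRUE),
                    levels = "chr1")
  cm <- bin_pairs(p, bt)
  self <- correlate_matrices(cm, cm)
  expect_equal(self$r, 1, tolerance = 1e-12)
  expect_equal(self$r2, 1, tolerance = 1e-12)

  # planted correlation: counts whose log1p values are bivariate normal
  set.seed(31)
  rho <- 0.8
  n <- nrow(bt)
  z1 <- stats::rnorm(n, mean = 3, sd = 1)
  z2 <- rho * (z1 - 3) + sqrt(1 - rho^2) * stats::rnorm(n) + 3
  c1 <- round(expm1(z1)); c2 <- round(expm1(z2))
  mk <- function(x) {
    m <- Matrix::sparseMatrix(i = seq_len(n), j = seq_len(n), x = x,
                              dims = c(n, n))
    cifi:::new_cifi_matrix(bt, methods::as(m, "CsparseMatrix"))
  }
  out <- correlate_matrices(mk(c1), mk(c2))
  expect_lt(abs(out$r - rho), 0.05)

  # bin mask restricts the cells used
  masked <- correlate_matrices(mk(c1), mk(c2), bin_mask = 1:50)
  expect_lte(masked$n_cells, 50L)
})

test_that("matrices round-trip through triplet text", {
  dir <- withr::local_tempdir()
  cs <- c(chr1 = 100000)
  p <- simple_pairs(rep("chr1", 50), sample(0:99999, 50, TRUE),
                    rep("chr1", 50), sample(0:99999, 50, TRUE),
                    levels = "chr1")
  cm <- kr_balance(bin_pairs(p, bin_table(cs, 10000)))
  write_matrix(cm, file.path(dir, "m"))
  rt <- read_matrix(file.path(dir, "m"), cs, 10000)
  expect_true(all(rt$counts == cm$counts))
  expect_equal(rt$weights, cm$weights, tolerance = 1e-12)
  expect_equal(rt$normalization, "KR")
})
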