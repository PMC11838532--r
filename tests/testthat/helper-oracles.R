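# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (plain O(L*m) scans, brute-force enumeration,
# per-base pileups), so agreement is evidence, not tautology.

# Naive motif scan: O(L*m) substring comparison, overlapping matches included.
naive_cut_sites <- function(sequence, motif, cut_offset) {
  s <- toupper(sequence)
  L <- nchar(s)
  m <- nchar(motif)
  hits <- integer(0)
  if (L >= m) {
    for (p in seq_len(L - m + 1L)) {
      if (substring(s, p, p + m - 1L) == motif) hits <- c(hits, p - 1L + cut_offset)
    }
  }
  hits[hits > 0L & hits < L]
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Symmetric Sinkhorn iteration run to high precision; the doubly stochastic
# scaling of a symmetric positive matrix is unique, so its fixed point is an
# independent check on the Newton-based balancer.
sinkhorn_oracle <- function(A, tol = 1e-10, max_iter = 1e5) {
  x <- rep(1, nrow(A))
  for (i in seq_len(max_iter)) {
    r <- x * as.numeric(A %*% x)
    if (max(abs(r - 1)) < tol) return(x)
    x <- x / sqrt(r)
  }
  stop("sinkhorn oracle did not converge")
}

# Brute-force per-base pileup depth over [1, L].
pileup_oracle <- function(starts0, ends0, L) {
  d <- numeric(L)
  for (i in seq_along(starts0)) {
    if (ends0[i] > starts0[i]) {
      idx <- (starts0[i] + 1L):ends0[i]
      d[idx] <- d[idx] + 1
    }
  }
  d
}

# Random interval partition of n bins into k domains.
random_partition <- function(n, k) {
  cuts <- sort(sample(seq_len(n - 1L), k - 1L))
  data.table::data.table(start_bin = c(1L, cuts + 1L), end_bin = c(cuts, n))
}

# Brute-force MoC straight from the definition via bin membership labels.
moc_oracle <- function(p, q) {
  lab <- function(part) rep(seq_len(nrow(part)), part$end_bin - part$start_bin + 1L)
  lp <- lab(p); lq <- lab(q)
  if (nrow(p) == 1L && nrow(q) == 1L) return(1)
  acc <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(nrow(q))) {
    ov <- sum(lp == i & lq == j)
    if (ov > 0) acc <- acc + ov^2 / (sum(lp == i) * sum(lq == j))
  }
  (acc - 1) / (sqrt(nrow(p) * nrow(q)) - 1)
}

# Small standard simulation shared by several tests (cached per session).
std_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42L, n_chroms = 2L, chrom_lengths = 4e5,
                        n_reads = 400L, trans_fraction = 0.25)
      cache <<- list(cfg = cfg, sim = run_simulation(cfg))
    }
    cache
  }
})
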