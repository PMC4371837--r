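# Brute-force oracles, independent of the package implementations.

# O(n*m) all-pairs interval overlap under half-open arithmetic.
oracle_overlap_hits <- function(A, B) {
  hitA <- logical(nrow(A))
  hitB <- logical(nrow(B))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      if (A$chrom[i] == B$chrom[j] &&
          A$start[i] < B$end[j] && B$start[j] < A$end[i]) {
        hitA[i] <- TRUE
        hitB[j] <- TRUE
      }
    }
  }
  list(A = hitA, B = hitB)
}

# Random interval fixture on two chromosomes.
random_intervals <- function(n, max_pos = 100000, max_len = 2000) {
  chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
  start <- sample.int(max_pos, n) - 1L
  len <- sample.int(max_len, n)
  intervals(chrom, start, start + len)
}

# Exact PWM score-distribution tail by full enumeration of all 4^L
# background L-mers, with the same per-position quantization the DP
# uses: p(s) = P(sum of quantized position scores >= round(s/g)).
oracle_pwm_tail <- function(x, score, granularity = 0.01) {
  L <- x$length
  q <- round(x$scores / granularity)
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  quanta <- numeric(nrow(grid))
  weight <- numeric(nrow(grid))
  for (j in seq_len(L)) {
    quanta <- quanta + q[grid[, j], j]
    weight <- if (j == 1) x$background[grid[, 1]] else
      weight * x$background[grid[, j]]
  }
  vapply(score, function(s) sum(weight[quanta >= round(s / granularity)]),
         numeric(1))
}

# Direct evaluation of the pull-down retention rule on a count matrix.
oracle_pulldown_keep <- function(counts, bait_cols, control_cols,
                                 min_bait_detections,
                                 max_control_detections = 1,
                                 min_peptides_bait = 2,
                                 min_peptides_control = 1) {
  apply_row <- function(r) {
    bait_det <- sum(r[bait_cols] >= min_peptides_bait)
    ctrl_det <- sum(r[control_cols] >= min_peptides_control)
    bait_det >= min_bait_detections && ctrl_det <= max_control_detections
  }
  apply(counts, 1, apply_row)
}
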