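test_that("score_window matches hand arithmetic and treats N as neutral", {
  # uniform PWM: (0.25 + pc) / (1 + 4 pc) = 0.25 exactly, so every
  # window scores exactly 0 regardless of pseudocount
  u <- pwm(matrix(0.25, 4, 3))
  expect_equal(score_window(u, "ACG"), 0)

  # hand value for a 2-position consensus-style PWM
  m <- matrix(0.05, 4, 2, dimnames = list(c("A", "C", "G", "T"), NULL))
  m["A", 1] <- 0.85
  m["G", 2] <- 0.85
  x <- pwm(m)
  pc <- 1e-4
  hand <- 2 * log2(((0.85 + pc) / (1 + 4 * pc)) / 0.25)
  expect_equal(score_window(x, "AG"), hand, tolerance = 1e-12)
  mismatch <- log2(((0.85 + pc) / (1 + 4 * pc)) / 0.25) +
    log2(((0.05 + pc) / (1 + 4 * pc)) / 0.25)
  expect_equal(score_window(x, "AC"), mismatch, tolerance = 1e-12)

  # N contributes zero
  expect_equal(score_window(x, "AN"),
               log2(((0.85 + pc) / (1 + 4 * pc)) / 0.25), tolerance = 1e-12)
  expect_error(score_window(x, "ACG"), "length")
})

test_that("pwm constructor validates and subsets", {
  expect_error(pwm(matrix(0.3, 4, 2)), "sum to 1")
  expect_error(pwm(matrix(0.25, 3, 2)), "4 rows")
  x <- pwm_from_consensus("ACGTT")
  expect_equal(pwm_consensus(x), "ACGTT")
  h <- pwm_subset(x, 1:2)
  expect_equal(h$length, 2)
  expect_equal(pwm_consensus(h), "AC")
})

test_that("exact p-values match brute-force enumeration (L = 6)", {
  set.seed(42)
  raw <- matrix(stats::runif(4 * 6, 0.02, 1), 4, 6)
  probs <- sweep(raw, 2, colSums(raw), "/")
  x <- pwm(probs)
  dist <- score_distribution(x, granularity = 0.01)
  # probe the whole support plus off-grid scores
  probe <- c(dist$support, dist$support + 0.004, min(dist$support) - 1,
             max(dist$support) + 1)
  got <- pwm_pvalue(dist, probe)
  want <- oracle_pwm_tail(x, probe, granularity = 0.01)
  want <- pmax(want, .Machine$double.xmin)
  # clamping: above the max support the tail is the last grid cell
  want[probe > max(dist$support)] <-
    max(oracle_pwm_tail(x, max(dist$support), 0.01), .Machine$double.xmin)
  want[probe < min(dist$support)] <- 1
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(sum(dist$prob), 1, tolerance = 1e-12)
})

test_that("consensus p-value of a uniform-background consensus PWM is 0.25^L", {
  # only the consensus sequence attains the maximum score
  x <- pwm_from_consensus("ACGTA")
  dist <- score_distribution(x)
  s <- score_window(x, "ACGTA")
  expect_equal(pwm_pvalue(dist, s), 0.25^5, tolerance = 1e-9)
})

test_that("scan_sequence finds planted sites with exact coordinates on both strands", {
  set.seed(7)
  cons <- "TTCAGCACCACGGACAGCGCC"
  x <- pwm_from_consensus(cons)
  bg <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
              collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
  seqchr <- bg
  substr(seqchr, 51, 71) <- cons       # forward copy at 0-based 50
  substr(seqchr, 201, 221) <- rc       # reverse copy at 0-based 200
  genome <- Biostrings::DNAStringSet(c(chr1 = seqchr))
  regions <- intervals("chr1", 0L, 400L, name = "r1")
  hits <- scan_sequence(x, genome, regions)
  full <- hits[hits$motif_kind == "full", ]
  expect_true(any(full$strand == "+" & full$start == 50 & full$end == 71))
  expect_true(any(full$strand == "-" & full$start == 200 & full$end == 221))
  expect_error(scan_sequence(x, genome, intervals("chr1", 0L, 500L)),
               "outside chromosome")
  expect_error(scan_sequence(x, genome, intervals("chrX", 0L, 10L)),
               "unknown chromosome")
})

test_that("scanning is strand-symmetric under reverse complement", {
  set.seed(11)
  x <- pwm_from_consensus("TTCAGCACCACGGACAGCGCC")
  seqchr <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                  collapse = "")
  substr(seqchr, 101, 121) <- "TTCAGCACCACGGACAGCGCC"
  rcseq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seqchr)))
  g1 <- Biostrings::DNAStringSet(c(chr1 = seqchr))
  g2 <- Biostrings::DNAStringSet(c(chr1 = rcseq))
  r <- intervals("chr1", 0L, 300L, name = "r")
  h1 <- scan_sequence(x, g1, r)
  h2 <- scan_sequence(x, g2, r)
  expect_equal(nrow(h1), nrow(h2))
  expect_equal(sort(h1$score), sort(h2$score))
  # a forward hit at start s maps to a reverse hit at 300 - end
  f1 <- h1[h1$motif_kind == "full" & h1$strand == "+", ]
  f2 <- h2[h2$motif_kind == "full" & h2$strand == "-", ]
  expect_equal(sort(300 - f1$end), sort(f2$start))
})

test_that("region classification is total with the documented precedence", {
  hit <- function(kind, strand, start) {
    data.frame(region = "r", chrom = "chr1", start = start,
               end = start + 21L, strand = strand, score = 20,
               p_value = 1e-6, motif_kind = kind,
               stringsAsFactors = FALSE)
  }
  expect_equal(classify_region(NULL), "NONE")
  expect_equal(classify_region(hit("full", "+", 0)), "SINGLE_FULL")
  expect_equal(classify_region(rbind(hit("full", "+", 0),
                                     hit("full", "+", 50))),
               "MULTI_FULL_SAME_STRAND")
  # two full hits on opposite strands are not a same-strand repeat
  expect_equal(classify_region(rbind(hit("full", "+", 0),
                                     hit("full", "-", 50))),
               "SINGLE_FULL")
  # duplicate starts on one strand do not count as a repeat
  expect_equal(classify_region(rbind(hit("full", "+", 0),
                                     hit("full", "+", 0))),
               "SINGLE_FULL")
  expect_equal(classify_region(hit("left_half", "+", 0)), "HALF_ONLY")
  # full beats half regardless of order
  expect_equal(classify_region(rbind(hit("right_half", "-", 0),
                                     hit("full", "+", 40))),
               "SINGLE_FULL")
})

test_that("motif-content summary counts classes and computes the percentage", {
  cls <- data.frame(
    region = sprintf("r%d", 1:6),
    class = c("SINGLE_FULL", "SINGLE_FULL", "MULTI_FULL_SAME_STRAND",
              "HALF_ONLY", "NONE", "NONE"),
    score = c(5, 6, 12, 2, 1, 1.2), stringsAsFactors = FALSE)
  s <- summarize_motif_content(cls)
  expect_equal(unname(s$counts[["SINGLE_FULL"]]), 2)
  expect_equal(unname(s$counts[["NONE"]]), 2)
  expect_equal(s$percent_with_motif, round(100 * 4 / 6, 1))
  expect_s3_class(s$rank_test, "htest")
  expect_error(summarize_motif_content(cls[0, ]), "empty")
})

test_that("printed-ratio helper rounds to one decimal", {
  expect_equal(percent_with_motif(2064, 2136), 96.6)
  expect_equal(percent_with_motif(1, 3), 33.3)
  expect_error(percent_with_motif(0, 0), "empty")
})
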