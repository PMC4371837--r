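test_that("config merging overrides nested fields and validates", {
  cfg <- sim_config(seed = 3, chip = list(background_rate = 5),
                    genome = list(gc_fraction = 0.5))
  expect_equal(cfg$seed, 3L)
  expect_equal(cfg$chip$background_rate, 5)
  expect_equal(cfg$genome$gc_fraction, 0.5)
  # untouched siblings keep their defaults
  expect_equal(cfg$chip$bin_size, 50)
  expect_equal(cfg$motifs$n_full_single, 40)
  expect_error(sim_config(expression = list(dispersion = 0)), "dispersion")
})

test_that("simulated genome is deterministic and plants exact ground truth", {
  cfg <- sim_config(seed = 5)
  t1 <- simulate_genome(cfg)
  t2 <- simulate_genome(cfg)
  expect_identical(as.character(t1$genome), as.character(t2$genome))
  expect_identical(t1$genes, t2$genes)

  m <- cfg$motifs
  expect_equal(nrow(t1$regions), m$n_full_single + m$n_full_multi + m$n_half_only)
  expect_equal(sum(t1$region_truth$class == "SINGLE_FULL"), m$n_full_single)
  expect_equal(sum(t1$region_truth$class == "MULTI_FULL_SAME_STRAND"),
               m$n_full_multi)
  expect_equal(sum(t1$region_truth$class == "HALF_ONLY"), m$n_half_only)

  # full-consensus copies in the sequence are exactly the planted ones
  seqchr <- as.character(t1$genome[[1]])
  cons <- m$consensus
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
  count_hits <- function(pat) {
    h <- gregexpr(pat, seqchr, fixed = TRUE)[[1]]
    sum(h > 0)
  }
  expect_equal(count_hits(cons) + count_hits(rc),
               m$n_full_single + m$n_full_multi * m$multi_k)

  # targets are exactly the genes hosting a full-site region
  expect_equal(sum(t1$genes$rest_target), m$n_full_single + m$n_full_multi)
  expect_true(all(is.na(t1$genes$region_class) |
                  t1$genes$region_class != "HALF_ONLY" |
                  !t1$genes$rest_target))
  # per-gene deltas are zero outside their scope
  expect_true(all(t1$genes$delta_k4[!t1$genes$rest_target] == 0))
  expect_true(all(t1$genes$delta_k9ac[!t1$genes$rest_target] == 0))
  expect_true(all(t1$genes$delta_k9me2[t1$genes$rest_target] < 0))
})

test_that("planted motif sites scan back to their true classes", {
  truth <- simulate_genome(sim_config(seed = 21))
  x <- pwm_from_consensus(truth$config$motifs$consensus)
  # stringent thresholds: the noiseless limit of the classifier. The
  # planted exact right half (11 bases) has p = 0.25^11 ~ 2.4e-7, so
  # the half threshold must sit above that
  hits <- scan_sequence(x, truth$genome, truth$regions,
                        p_full = 1e-9, p_half = 1e-6)
  cls <- classify_regions(truth$regions, hits)
  want <- truth$region_truth$class[match(cls$region, truth$region_truth$region)]
  expect_equal(cls$class, want)
})

test_that("ChIP tracks carry the designed genotype differences", {
  truth <- simulate_genome(sim_config(seed = 8))
  wt <- simulate_chip_tracks(truth, "WT")
  ko <- simulate_chip_tracks(truth, "KO")
  ch <- truth$config$chip
  bs <- ch$bin_size
  expect_named(wt, c("REST", "H3K4me3", "H3K9ac", "H3K9me2", "H3K27me3",
                     "H3", "input"))

  # WT REST signal at single-full regions ~ fold x background; KO flat
  single <- truth$regions[truth$region_truth$class == "SINGLE_FULL", ]
  mean_in <- function(trk, iv) mean(unlist(lapply(seq_len(nrow(iv)), function(i) {
    b <- (iv$start[i] %/% bs + 1L):((iv$end[i] - 1L) %/% bs + 1L)
    trk$bins[[iv$chrom[i]]][b]
  })))
  expect_equal(mean_in(wt$REST, single),
               ch$background_rate * ch$enrichment_fold[["REST"]],
               tolerance = 0.1)
  expect_equal(mean_in(ko$REST, single), ch$background_rate, tolerance = 0.1)

  # multi-site regions are boosted above single-site ones
  multi <- truth$regions[truth$region_truth$class == "MULTI_FULL_SAME_STRAND", ]
  expect_gt(mean_in(wt$REST, multi), 1.5 * mean_in(wt$REST, single))

  # input and H3 are genotype-invariant in expectation
  expect_equal(mean(wt$input$bins$chr1), mean(ko$input$bins$chr1),
               tolerance = 0.05)
  expect_equal(mean(wt$H3$bins$chr1) / mean(wt$input$bins$chr1),
               ch$h3_fold, tolerance = 0.1)

  # determinism under the derived seeds
  expect_identical(simulate_chip_tracks(truth, "WT")$REST$bins,
                   wt$REST$bins)
})

test_that("expression counts respond to the K4 delta through beta", {
  truth <- simulate_genome(sim_config(seed = 13))
  cw <- simulate_expression_counts(truth, "WT")
  ck <- simulate_expression_counts(truth, "KO")
  expect_equal(dim(cw), c(nrow(truth$genes), truth$config$expression$n_reps))
  expect_type(cw[1, 1], "integer")
  lfc <- log_fold_change(cw, ck)
  g <- truth$genes
  up <- g$rest_target & g$k4_marked
  # genes with a planted K4 delta rise; non-targets stay near zero
  expect_gt(mean(lfc[up]), 0.5)
  expect_lt(abs(mean(lfc[!g$rest_target])), 0.3)
  expect_gt(mean(lfc[up]) - mean(lfc[!g$rest_target]), 0.5)
})

test_that("qPCR plate encodes its true fold changes recoverably", {
  cfg <- sim_config(seed = 17)
  qp <- simulate_qpcr_plate(cfg)
  expect_equal(qp$true_fold[["ref"]], 1)
  get_ct <- function(g, cond) {
    d <- qp$ct[qp$ct$gene == g & qp$ct$condition == cond, ]
    ct_set(g, cond, d$ct)
  }
  for (g in names(qp$true_fold)[-1]) {
    res <- ddct_relative_expression(get_ct(g, "test"), get_ct(g, "control"),
                                    get_ct("ref", "test"),
                                    get_ct("ref", "control"))
    expect_equal(log2(res$fold_change), log2(qp$true_fold[[g]]),
                 tolerance = 0.5)
  }
})

test_that("peptide table separates co-factors from contaminants", {
  pep <- simulate_peptide_table(sim_config(seed = 19))
  expect_equal(dim(pep$counts),
               c(30, 5))
  kept <- filter_pulldown_proteins(pep$counts, pep$bait_cols,
                                   pep$control_cols)
  sens <- mean(pep$true_retained %in% kept$protein)
  fps <- sum(!kept$protein %in% pep$true_retained)
  expect_gte(sens, 0.8)
  expect_lte(fps, 2)
})
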