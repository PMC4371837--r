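test_that("window sums and background rate match hand arithmetic", {
  expect_equal(restpoise:::window_sums(1:5, 2), c(3, 5, 7, 9))
  expect_equal(restpoise:::window_sums(1:3, 5), numeric(0))
  # constant track: median 10-bin window sum is 10c, rate c
  tr <- signal_track(list(chr1 = rep(4, 100)), 50)
  expect_equal(track_background(tr), 4)
  expect_error(track_background(signal_track(list(chr1 = rep(0, 100)), 50)),
               "empty")
})

test_that("integrate_signal matches a hand-computed partial-bin fixture", {
  tr <- signal_track(list(chr1 = c(10, 20, 30)), 10)
  iv <- intervals("chr1", 5L, 25L)
  # covered fractions 0.5, 1, 0.5 of bins with cpm 1e6 * c(10,20,30)/60
  hand <- (0.5 * 10 + 1 * 20 + 0.5 * 30) / 2 / 60 * 1e6
  expect_equal(integrate_signal(tr, iv), hand)
  # full single bin
  expect_equal(integrate_signal(tr, intervals("chr1", 10L, 20L)),
               1e6 * 20 / 60)
  expect_error(integrate_signal(tr, intervals("chr1", 0L, 40L)), "extent")
  expect_error(integrate_signal(tr, intervals("chrX", 0L, 10L)), "absent")
})

test_that("integrate_signal flags zero-normalizer intervals as NA", {
  tr <- signal_track(list(chr1 = c(10, 20)), 10)
  nz <- signal_track(list(chr1 = c(5, 0)), 10)
  expect_warning(
    v <- integrate_signal(tr, intervals("chr1", c(0L, 10L), c(10L, 20L)), nz),
    "flagged NA")
  expect_false(is.na(v[1]))
  expect_true(is.na(v[2]))
})

test_that("pearson correlation matches the closed form and rejects degeneracy", {
  x <- c(1, 2, 3); y <- c(2, 4, 7)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_correlation(x, y), hand)
  expect_error(pearson_correlation(c(1, 1, 1), y), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), "length")
})

test_that("call_domains recovers a strong planted domain and none under the null", {
  set.seed(303)
  nb <- 2000
  bg <- rep(2, nb)
  enriched <- bg
  enriched[501:540] <- 16 # 2 kb domain at 8-fold
  chip <- signal_track(list(chr1 = stats::rpois(nb, enriched)), 50)
  ctrl <- signal_track(list(chr1 = stats::rpois(nb, bg)), 50)
  doms <- call_domains(chip, ctrl)
  expect_equal(nrow(doms), 1)
  planted <- intervals("chr1", 500L * 50L, 540L * 50L)
  called <- intervals(doms$chrom, doms$start, doms$end)
  expect_true(all(restpoise:::overlap_hits_logical(called, planted)$A))
  expect_true(doms$enrichment > 2)

  # null: chip and control from the same rate, no domains
  chip0 <- signal_track(list(chr1 = stats::rpois(nb, bg)), 50)
  expect_equal(nrow(call_domains(chip0, ctrl)), 0)
  expect_error(call_domains(chip, signal_track(list(chr1 = rep(0, 10)), 50)),
               "zero library|empty")
})

test_that("domain comparison calls stable, gain and complete loss correctly", {
  set.seed(404)
  nb <- 2000
  base <- rep(2, nb)
  rate_ref <- base
  rate_ref[101:140] <- 16  # stays
  rate_ref[501:540] <- 16  # gains 4x
  rate_ref[901:940] <- 16  # lost completely
  rate_alt <- base
  rate_alt[101:140] <- 16
  rate_alt[501:540] <- 64
  ref <- signal_track(list(chr1 = stats::rpois(nb, rate_ref)), 50)
  alt <- signal_track(list(chr1 = stats::rpois(nb, rate_alt)), 50)
  in_ref <- signal_track(list(chr1 = stats::rpois(nb, base)), 50)
  in_alt <- signal_track(list(chr1 = stats::rpois(nb, base)), 50)
  domains <- data.frame(chrom = "chr1",
                        start = c(100L, 500L, 900L) * 50L,
                        end = c(140L, 540L, 940L) * 50L)
  cmp <- compare_domain_enrichment(domains, ref, alt, in_ref, in_alt)
  expect_s3_class(cmp, "domain_comparison")
  expect_equal(cmp$table$call, c("STABLE", "GAIN", "LOSS_COMPLETE"))
  expect_equal(cmp$table$log2_fold_change[2], 2, tolerance = 0.3)
  expect_equal(cmp$percent_stable, round(100 / 3, 1))

  rep2 <- fold_change_report(cmp)
  expect_equal(nrow(rep2), 2) # stable omitted
  expect_equal(rep2$change[rep2$call == "LOSS_COMPLETE"], "Loss")
  gain_str <- rep2$change[rep2$call == "GAIN"]
  expect_equal(gain_str,
               sprintf("%.1f", 2^abs(cmp$table$log2_fold_change[2])))
  expect_error(compare_domain_enrichment(domains[0, ], ref, alt), "empty")
})

test_that("identical tracks compare as fully stable with unit fold change", {
  set.seed(505)
  nb <- 1500
  rate <- rep(2, nb); rate[201:240] <- 20
  v <- stats::rpois(nb, rate)
  tr <- signal_track(list(chr1 = v), 50)
  domains <- data.frame(chrom = "chr1", start = 200L * 50L, end = 240L * 50L)
  cmp <- compare_domain_enrichment(domains, tr, tr)
  expect_equal(cmp$table$call, "STABLE")
  expect_equal(cmp$table$log2_fold_change, 0, tolerance = 1e-9)
})

test_that("swap procedure yields disjoint gains and losses", {
  cfg <- sim_config(seed = 9)
  truth <- simulate_genome(cfg)
  wt <- simulate_chip_tracks(truth, "WT")
  ko <- simulate_chip_tracks(truth, "KO")
  swap <- differential_regions_swap(ko$H3K27me3, wt$H3K27me3)
  expect_gt(nrow(swap$gains), 0)
  expect_gt(nrow(swap$losses), 0)
  hits <- restpoise:::overlap_hits_logical(
    intervals(swap$gains$chrom, swap$gains$start, swap$gains$end),
    intervals(swap$losses$chrom, swap$losses$start, swap$losses$end))
  expect_false(any(hits$A))
})
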