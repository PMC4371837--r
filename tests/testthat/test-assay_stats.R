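test_that("delta-delta Ct reproduces hand-computed fold and SD", {
  goi_test <- ct_set("goi", "test", c(24, 25, 26))      # mean 25, sd 1
  ref_test <- ct_set("ref", "test", c(20, 21, 22))      # mean 21, sd 1
  goi_control <- ct_set("goi", "control", c(26, 26, 26))
  ref_control <- ct_set("ref", "control", c(20, 20, 20))
  res <- ddct_relative_expression(goi_test, goi_control,
                                  ref_test, ref_control)
  expect_equal(res$dct_test, 4)
  expect_equal(res$dct_control, 6)
  expect_equal(res$ddct, -2)
  expect_equal(res$fold_change, 4)
  expect_equal(res$sd, 4 * log(2) * sqrt(2))
})

test_that("ddCt of identical conditions is fold 1 and SD scales with fold", {
  a <- ct_set("goi", "test", c(22.1, 22.4, 21.8))
  r <- ct_set("ref", "test", c(19.9, 20.2, 20.1))
  res <- ddct_relative_expression(a, a, r, r)
  expect_equal(res$fold_change, 1)
  expect_equal(res$ddct, 0)
  # the stated propagation formula, recomputed independently
  expect_equal(res$sd, 1 * log(2) * sqrt(sd(r$ct)^2 + sd(a$ct)^2))

  # single replicate: SD flagged NA
  one <- ct_set("goi", "test", 22)
  res1 <- ddct_relative_expression(one, a, r, r)
  expect_true(is.na(res1$sd))
  expect_error(ct_set("g", "c", c(20, NA)), "finite")
})

test_that("ChIP-qPCR enrichment follows the dilution-corrected 2^dCt form", {
  ip <- ct_set("amp", "ip", c(25, 25, 25))
  input <- ct_set("amp", "input", c(28, 28, 28))
  expect_equal(chip_qpcr_enrichment(ip, input)$enrichment, 8)
  expect_equal(chip_qpcr_enrichment(ip, input,
                                    input_dilution = 10)$enrichment, 80)
  # H3 normalization divides by the H3 pair's enrichment
  h3_ip <- ct_set("amp", "h3", c(26, 26, 26))
  res <- chip_qpcr_enrichment(ip, input, h3_ip = h3_ip, h3_input = input)
  expect_equal(res$enrichment, 8 / 4)
  expect_error(chip_qpcr_enrichment(ip, NULL), "input")
})

test_that("Welch test matches hand-computed statistic and df", {
  x <- c(1, 2, 3); y <- c(2, 4, 6, 8)
  vx <- var(x) / 3; vy <- var(y) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df_hand <- (vx + vy)^2 / (vx^2 / 2 + vy^2 / 3)
  w <- welch_t_test(x, y)
  expect_equal(w$t, t_hand)
  expect_equal(w$df, df_hand)
  expect_equal(w$p, 2 * stats::pt(-abs(t_hand), df_hand))

  # pooled variant: classic Student statistic
  sp2 <- (2 * var(x) + 3 * var(y)) / 5
  t_pool <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 4))
  expect_equal(welch_t_test(x, y, pooled = TRUE)$t, t_pool)

  # paired variant equals the one-sample test of differences
  a <- c(5, 7, 9, 11); b <- c(4, 8, 8, 12)
  wp <- welch_t_test(a, b, paired = TRUE)
  tt <- stats::t.test(a - b)
  expect_equal(wp$t, unname(tt$statistic))
  expect_equal(wp$p, tt$p.value)
})

test_that("degenerate zero-variance cases use the stated conventions", {
  expect_equal(welch_t_test(c(1, 1), c(1, 1))$p, 1)
  expect_equal(welch_t_test(c(2, 2), c(1, 1))$p, 0)
  expect_equal(welch_t_test(c(2, 2), c(1, 1))$t, Inf)
  expect_equal(welch_t_test(c(1, 1), c(3, 3))$t, -Inf)
  expect_equal(welch_t_test(c(1, 2), c(2, 3), paired = TRUE)$p, 0)
  expect_equal(welch_t_test(c(1, 2), c(1, 2), paired = TRUE)$p, 1)
  expect_error(welch_t_test(1, c(1, 2)), "length")
})

test_that("pull-down filter matches brute-force rule evaluation on a grid", {
  # every combination of peptide counts 0..3 over 2 bait + 2 controls
  grid <- as.matrix(expand.grid(b1 = 0:3, b2 = 0:3, c1 = 0:3, c2 = 0:3))
  rownames(grid) <- sprintf("p%03d", seq_len(nrow(grid)))
  for (preset in c("table-legend", "results-text")) {
    got <- filter_pulldown_proteins(grid, c("b1", "b2"), c("c1", "c2"),
                                    preset = preset)
    want <- oracle_pulldown_keep(grid, c("b1", "b2"), c("c1", "c2"),
                                 min_bait_detections = 2)
    expect_equal(sort(got$protein), sort(rownames(grid)[want]),
                 info = preset)
  }
  # custom thresholds against the oracle
  got <- filter_pulldown_proteins(grid, c("b1", "b2"), c("c1", "c2"),
                                  min_bait_detections = 1,
                                  max_control_detections = 0,
                                  min_peptides_bait = 3,
                                  min_peptides_control = 2)
  want <- oracle_pulldown_keep(grid, c("b1", "b2"), c("c1", "c2"),
                               min_bait_detections = 1,
                               max_control_detections = 0,
                               min_peptides_bait = 3,
                               min_peptides_control = 2)
  expect_equal(sort(got$protein), sort(rownames(grid)[want]))
})

test_that("pull-down presets differ only in required bait detections", {
  counts <- matrix(c(5, 5, 0, 0, 0,   # in 2 of 3 baits, clean controls
                     5, 5, 5, 1, 0),  # in all baits, 1 control
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("p_two", "p_all"),
                                   c("b1", "b2", "b3", "c1", "c2")))
  strict <- filter_pulldown_proteins(counts, 1:3, 4:5)
  loose <- filter_pulldown_proteins(counts, 1:3, 4:5,
                                    preset = "results-text")
  expect_equal(strict$protein, "p_all")
  expect_equal(sort(loose$protein), c("p_all", "p_two"))
})

test_that("pull-down retention is monotone in bait counts", {
  set.seed(909)
  base <- matrix(rpois(40 * 5, 1), 40, 5,
                 dimnames = list(sprintf("p%02d", 1:40),
                                 c("b1", "b2", "b3", "c1", "c2")))
  kept <- filter_pulldown_proteins(base, 1:3, 4:5)$protein
  boosted <- base
  boosted[, 1:3] <- boosted[, 1:3] + 2L
  kept2 <- filter_pulldown_proteins(boosted, 1:3, 4:5)$protein
  expect_true(all(kept %in% kept2))
  expect_error(filter_pulldown_proteins(base - 2L, 1:3, 4:5), "non-negative")
  expect_error(filter_pulldown_proteins(base, 1:3, 4:5,
                                        min_bait_detections = 4),
               "exceeds")
})
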