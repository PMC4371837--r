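#' Bench-assay statistics
#'
#' Delta-delta Ct relative expression with standard-deviation
#' propagation, ChIP-qPCR enrichment over input, the two-sample t test,
#' and the affinity-purification replicate filter.
#'
#' @name assay_stats
NULL

#' Replicate Ct set
#'
#' @param gene gene or amplicon label.
#' @param condition condition label.
#' @param ct numeric vector of replicate Ct values (cycles), finite and
#'   positive.
#' @return object of class `ct_set`.
#' @export
ct_set <- function(gene, condition, ct) {
  ct <- as.numeric(ct)
  stopifnot(all(is.finite(ct)), all(ct > 0))
  structure(list(gene = gene, condition = condition, ct = ct),
            class = "ct_set")
}

ct_sd <- function(x) if (length(x$ct) >= 2) stats::sd(x$ct) else NA_real_

#' Relative expression by the delta-delta Ct method
#'
#' ΔCt = mean Ct of the gene of interest minus mean Ct of the reference
#' gene, per condition; ΔΔCt = ΔCt(test) − ΔCt(control); fold change =
#' 2^(−ΔΔCt). The standard deviation of the normalized value is
#' propagated as SD = fold × ln(2) × sqrt(SD_ref² + SD_goi²), using the
#' replicate Ct standard deviations of the test condition. With fewer
#' than 2 replicates the SD is returned as NA (flagged).
#'
#' @param goi_test,goi_control `ct_set`s of the gene of interest in the
#'   test and control conditions.
#' @param ref_test,ref_control `ct_set`s of the reference gene (e.g.
#'   Gapdh).
#' @return list: fold_change, sd, ddct, dct_test, dct_control.
#' @export
ddct_relative_expression <- function(goi_test, goi_control,
                                     ref_test, ref_control) {
  dct_test <- mean(goi_test$ct) - mean(ref_test$ct)
  dct_control <- mean(goi_control$ct) - mean(ref_control$ct)
  ddct <- dct_test - dct_control
  fold <- 2^(-ddct)
  sd_goi <- ct_sd(goi_test); sd_ref <- ct_sd(ref_test)
  sd <- if (is.na(sd_goi) || is.na(sd_ref)) NA_real_ else
    fold * log(2) * sqrt(sd_ref^2 + sd_goi^2)
  list(fold_change = fold, sd = sd, ddct = ddct,
       dct_test = dct_test, dct_control = dct_control)
}

#' ChIP-qPCR enrichment relative to input
#'
#' enrichment = dilution × 2^(mean Ct_input − mean Ct_ip); divided by
#' the same quantity computed for an H3 `ct_set` pair when given
#' (H3-density normalization). SD is propagated from the IP and input
#' replicate Ct standard deviations as for the ddCt method.
#'
#' @param ip,input `ct_set`s for the immunoprecipitate and input.
#' @param h3_ip,h3_input optional `ct_set`s for the H3 normalizer.
#' @param input_dilution correction factor for input dilution
#'   (default 1).
#' @return list: enrichment, sd.
#' @export
chip_qpcr_enrichment <- function(ip, input, h3_ip = NULL, h3_input = NULL,
                                 input_dilution = 1) {
  if (is.null(input)) stop("input Ct set required")
  enr <- input_dilution * 2^(mean(input$ct) - mean(ip$ct))
  sd_ip <- ct_sd(ip); sd_in <- ct_sd(input)
  sd <- if (is.na(sd_ip) || is.na(sd_in)) NA_real_ else
    enr * log(2) * sqrt(sd_ip^2 + sd_in^2)
  if (!is.null(h3_ip)) {
    if (is.null(h3_input)) h3_input <- input
    h3 <- input_dilution * 2^(mean(h3_input$ct) - mean(h3_ip$ct))
    enr <- enr / h3
    sd <- if (is.na(sd)) NA_real_ else sd / h3
  }
  list(enrichment = enr, sd = sd)
}

#' Two-sample t test (Welch by default)
#'
#' Welch statistic with Satterthwaite degrees of freedom and a
#' two-sided p; `pooled = TRUE` gives the classic equal-variance
#' Student's test; `paired = TRUE` tests the per-element differences.
#' When both samples have zero variance and equal means the test is
#' degenerate and p = 1 is returned by convention.
#'
#' @param x,y numeric samples with >= 2 finite values each.
#' @param pooled equal-variance pooled test (default FALSE).
#' @param paired paired test (default FALSE).
#' @return list: t, df, p.
#' @export
welch_t_test <- function(x, y, pooled = FALSE, paired = FALSE) {
  stopifnot(length(x) >= 2, length(y) >= 2,
            all(is.finite(x)), all(is.finite(y)))
  if (!paired && stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = NA_real_, p = 0))
  }
  if (paired && stats::sd(x - y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = NA_real_, p = 0))
  }
  tt <- stats::t.test(x, y, var.equal = pooled, paired = paired)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Filter pull-down proteins by replicate detections
#'
#' A protein is "detected" in a sample when its unique-peptide count is
#' at least `min_peptides_bait` (bait) or `min_peptides_control`
#' (control). A protein is retained iff it is detected in at least
#' `min_bait_detections` bait samples and in at most
#' `max_control_detections` control samples. The defaults are the
#' operational rule of the purification table: detection needs >= 2
#' peptides in a bait pull-down, all bait replicates must detect it, and
#' it may be represented (>= 1 peptide) in at most one negative control.
#' The preset `"results-text"` instead requires detection in at least
#' two of the bait pull-downs.
#'
#' @param counts proteins x samples integer matrix of unique-peptide
#'   counts (rownames = proteins).
#' @param bait_cols,control_cols column names or indices of the bait and
#'   control samples.
#' @param min_bait_detections minimum bait detections (default: all bait
#'   samples).
#' @param max_control_detections maximum control detections (default 1).
#' @param min_peptides_bait peptides needed to count a bait detection
#'   (default 2).
#' @param min_peptides_control peptides that make a protein "represented"
#'   in a control (default 1).
#' @param preset "table-legend" (the defaults) or "results-text"
#'   (min_bait_detections = 2).
#' @return data.frame of retained proteins with per-sample counts and
#'   the detection tallies.
#' @export
filter_pulldown_proteins <- function(counts, bait_cols, control_cols,
                                     min_bait_detections = NULL,
                                     max_control_detections = 1,
                                     min_peptides_bait = 2,
                                     min_peptides_control = 1,
                                     preset = c("table-legend", "results-text")) {
  preset <- match.arg(preset)
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("peptide counts must be non-negative integers")
  }
  bait <- counts[, bait_cols, drop = FALSE]
  ctrl <- counts[, control_cols, drop = FALSE]
  if (ncol(bait) < 1 || ncol(ctrl) < 1) stop("need >= 1 bait and control sample")
  if (is.null(min_bait_detections)) {
    min_bait_detections <- if (preset == "results-text")
      min(2L, ncol(bait)) else ncol(bait)
  }
  if (min_bait_detections > ncol(bait)) {
    stop("min_bait_detections exceeds the number of bait samples")
  }
  bait_det <- rowSums(bait >= min_peptides_bait)
  ctrl_det <- rowSums(ctrl >= min_peptides_control)
  keep <- bait_det >= min_bait_detections & ctrl_det <= max_control_detections
  data.frame(
    protein = rownames(counts)[keep],
    counts[keep, , drop = FALSE],
    bait_detections = bait_det[keep],
    control_detections = ctrl_det[keep],
    row.names = NULL, stringsAsFactors = FALSE,
    check.names = FALSE
  )
}
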