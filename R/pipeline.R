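#' End-to-end audit pipeline
#'
#' Orchestrates the full analysis on simulated (or user-supplied)
#' inputs and emits a report shaped like the study readout: motif
#' content of bound regions, reciprocal peak/domain overlap at two
#' flanks, the domain-restricted two-genotype mark comparison with
#' concordance, promoter-class expression comparisons, the
#' mark-delta regression, and the bench-assay statistics.
#'
#' @name pipeline
NULL

#' Per-gene chromatin-mark deltas at promoters
#'
#' For each gene, the log2 ratio of the (input-normalized) mean mark
#' signal over the promoter window in the alternate versus the
#' reference genotype. Deltas can be anchored at the TSS (default) or
#' at the gene's REST-bound region.
#'
#' @param tss `interval_table` of TSS points (name = gene id).
#' @param tracks_ref,tracks_alt named lists of `signal_track`s (must
#'   contain the requested marks and, if `normalize`, "input").
#' @param marks character vector of mark names.
#' @param window promoter half-width in bases (default 500).
#' @param normalize divide each mark by the genotype's input track
#'   (default TRUE).
#' @param anchors optional `interval_table` to use instead of the
#'   promoter windows (e.g. REST-bound regions per gene).
#' @return data.frame: gene plus one delta column per mark (named
#'   d<mark>).
#' @export
promoter_mark_deltas <- function(tss, tracks_ref, tracks_alt, marks,
                                 window = 500, normalize = TRUE,
                                 anchors = NULL) {
  iv <- if (is.null(anchors)) {
    intervals(tss$chrom, pmax(0L, tss$start - as.integer(window)),
              tss$start + as.integer(window), name = tss$name)
  } else anchors
  out <- data.frame(gene = iv$name, stringsAsFactors = FALSE)
  for (mk in marks) {
    nref <- if (normalize) tracks_ref$input else NULL
    nalt <- if (normalize) tracks_alt$input else NULL
    vr <- integrate_signal(tracks_ref[[mk]], iv, nref)
    va <- integrate_signal(tracks_alt[[mk]], iv, nalt)
    out[[paste0("d", mk)]] <- log2(pmax(va, 1e-9) / pmax(vr, 1e-9))
  }
  out
}

#' Sensitivity and false-discovery rate of called vs planted intervals
#'
#' Sensitivity is the fraction of planted intervals overlapped by at
#' least one called interval; FDR is the fraction of called intervals
#' overlapping no planted one. With no planted intervals both are NA;
#' with no called intervals sensitivity is 0 and FDR NA.
#'
#' @param called,planted data.frames with chrom/start/end columns.
#' @return list: sensitivity, fdr.
#' @export
match_planted <- function(called, planted) {
  if (nrow(planted) == 0) return(list(sensitivity = NA_real_, fdr = NA_real_))
  if (nrow(called) == 0) return(list(sensitivity = 0, fdr = NA_real_))
  hits <- overlap_hits_logical(
    intervals(called$chrom, called$start, called$end),
    intervals(planted$chrom, planted$start, planted$end))
  list(sensitivity = mean(hits$B), fdr = mean(!hits$A))
}

#' Run the full audit on simulated inputs
#'
#' Simulates a genome, tracks, expression counts and bench assays under
#' `config`, runs every analysis stage, and (optionally) writes all
#' intermediate tables to `outdir`. Deterministic given the config
#' seed: two runs with the same config produce identical reports.
#'
#' @param config a `sim_config`.
#' @param outdir optional output directory for the TSV bundle and
#'   summary; created if missing.
#' @param sections character vector choosing which report sections to
#'   compute (default all): "motif", "overlap", "domains",
#'   "promoters", "expression", "assays".
#' @return list of class `audit_report`.
#' @export
run_audit <- function(config = sim_config(), outdir = NULL,
                      sections = c("motif", "overlap", "domains",
                                   "promoters", "expression", "assays")) {
  sections <- match.arg(sections, several.ok = TRUE)
  truth <- simulate_genome(config)
  tracks_wt <- simulate_chip_tracks(truth, "WT")
  tracks_ko <- simulate_chip_tracks(truth, "KO")
  report <- list(config = config)

  re1 <- pwm_from_consensus(config$motifs$consensus)

  if ("motif" %in% sections) {
    regions <- truth$regions
    regions$score <- integrate_signal(tracks_wt$REST, regions,
                                      tracks_wt$input)
    hits <- scan_sequence(re1, truth$genome, regions)
    classified <- classify_regions(regions, hits)
    classified$true_class <- truth$region_truth$class[
      match(classified$region, truth$region_truth$region)]
    summary <- summarize_motif_content(classified)
    report$motif <- list(
      hits = hits, classified = classified, summary = summary,
      accuracy = mean(classified$class == classified$true_class)
    )
  }

  rest_peaks <- call_domains(tracks_wt$REST, tracks_wt$input)
  k27_wt <- call_domains(tracks_wt$H3K27me3, tracks_wt$input)
  k4_wt <- call_domains(tracks_wt$H3K4me3, tracks_wt$input)
  as_iv <- function(d) intervals(d$chrom, d$start, d$end)

  if ("overlap" %in% sections) {
    report$overlap <- list(
      flank0 = overlap_report(as_iv(rest_peaks), as_iv(k27_wt)),
      flank1k = overlap_report(as_iv(rest_peaks), as_iv(k27_wt),
                               flank_A = 1000),
      rest_k4 = overlap_report(as_iv(rest_peaks), as_iv(k4_wt))
    )
  }

  if ("domains" %in% sections) {
    cmp <- compare_domain_enrichment(
      k27_wt, tracks_wt$H3K27me3, tracks_ko$H3K27me3,
      tracks_wt$input, tracks_ko$input)
    swap <- differential_regions_swap(tracks_ko$H3K27me3, tracks_wt$H3K27me3)
    kd <- truth$k27_domains
    gain_truth <- kd[kd$change == "gain", , drop = FALSE]
    loss_truth <- kd[kd$change == "loss", , drop = FALSE]
    report$domains <- list(
      called = k27_wt, comparison = cmp, swap = swap,
      gain_recovery = match_planted(swap$gains, gain_truth),
      loss_recovery = match_planted(swap$losses, loss_truth),
      table2 = fold_change_report(cmp)
    )
  }

  if ("promoters" %in% sections) {
    states <- classify_promoter_state(truth$tss, as_iv(k4_wt), as_iv(k27_wt))
    states$rest_target <- truth$genes$rest_target[
      match(states$gene, truth$genes$gene)]
    report$promoters <- list(
      states = states,
      table = table(target = states$rest_target, class = states$class)
    )
  }

  if ("expression" %in% sections) {
    counts_wt <- simulate_expression_counts(truth, "WT")
    counts_ko <- simulate_expression_counts(truth, "KO")
    lfc <- log_fold_change(counts_wt, counts_ko)
    # Unnormalized KO/WT ratios: the input track is genotype-invariant,
    # and dividing every mark by the same noisy input would inject
    # correlated measurement error into all regression predictors.
    deltas <- promoter_mark_deltas(
      truth$tss, tracks_wt, tracks_ko,
      marks = c("H3K4me3", "H3K9ac", "H3K9me2", "H3K27me3"),
      window = config$genes$promoter_halfwidth, normalize = FALSE)
    tgt <- truth$genes$rest_target
    # Regress over targets with a detectable H3K4me3 promoter peak;
    # elsewhere the K4 ratio is a background/background quotient whose
    # noise attenuates the coefficient.
    k4_state <- classify_promoter_state(truth$tss, as_iv(k4_wt),
                                        empty_intervals())
    sel <- tgt & k4_state$k4
    reg <- regress_mark_deltas(
      deltas[sel, c("dH3K4me3", "dH3K9ac", "dH3K9me2", "dH3K27me3")],
      lfc[sel])
    cors <- list(
      k4_vs_expr = correlate_deltas(deltas$dH3K4me3[tgt], lfc[tgt]),
      k27_vs_expr = correlate_deltas(deltas$dH3K27me3[tgt], lfc[tgt]),
      k9me2_vs_k27 = correlate_deltas(deltas$dH3K9me2[tgt],
                                      deltas$dH3K27me3[tgt])
    )
    gene_tab <- data.frame(
      gene = truth$genes$gene,
      rest_target = tgt,
      promoter_class = if (!is.null(report$promoters))
        report$promoters$states$class else NA_character_,
      log2fc = lfc, deltas[, -1],
      stringsAsFactors = FALSE)
    classes <- if (!is.null(report$promoters)) {
      data.frame(gene = gene_tab$gene, rest_target = tgt,
                 promoter_class = report$promoters$states$class,
                 stringsAsFactors = FALSE)
    } else NULL
    class_cmp <- if (!is.null(classes))
      compare_class_expression(classes, counts_wt, counts_ko) else NULL
    report$expression <- list(
      gene_table = gene_tab, regression = reg, correlations = cors,
      class_comparison = class_cmp)
  }

  if ("assays" %in% sections) {
    qp <- simulate_qpcr_plate(config)
    goi_ids <- setdiff(unique(qp$ct$gene), qp$reference)
    get_ct <- function(g, cond) {
      d <- qp$ct[qp$ct$gene == g & qp$ct$condition == cond, ]
      ct_set(g, cond, d$ct)
    }
    dd <- lapply(goi_ids, function(g) {
      res <- ddct_relative_expression(
        get_ct(g, "test"), get_ct(g, "control"),
        get_ct(qp$reference, "test"), get_ct(qp$reference, "control"))
      data.frame(gene = g, fold_change = res$fold_change, sd = res$sd,
                 true_fold = qp$true_fold[[g]], stringsAsFactors = FALSE)
    })
    pep <- simulate_peptide_table(config)
    retained <- filter_pulldown_proteins(pep$counts, pep$bait_cols,
                                         pep$control_cols)
    report$assays <- list(
      ddct = do.call(rbind, dd),
      retained = retained,
      pulldown_sensitivity = mean(pep$true_retained %in% retained$protein),
      pulldown_false_positives = sum(!retained$protein %in% pep$true_retained)
    )
  }

  class(report) <- "audit_report"
  if (!is.null(outdir)) write_audit_report(report, outdir)
  report
}

#' Write an audit report as a TSV bundle plus a text summary
#'
#' @param report an `audit_report`.
#' @param outdir output directory (created if missing).
#' @export
write_audit_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, nm) {
    utils::write.table(df, file.path(outdir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  lines <- c("audit summary", "=============")
  if (!is.null(report$motif)) {
    w(report$motif$hits, "motif_hits")
    w(report$motif$classified, "motif_classes")
    s <- report$motif$summary
    lines <- c(lines, sprintf(
      "motif: %.1f%% of %d regions carry a full or half RE1 motif; class accuracy %.3f",
      s$percent_with_motif, sum(s$counts), report$motif$accuracy))
  }
  if (!is.null(report$overlap)) {
    o0 <- report$overlap$flank0; o1 <- report$overlap$flank1k
    lines <- c(lines, sprintf(
      "overlap: REST vs H3K27me3 %.1f%%/%.1f%% at flank 0; %.1f%%/%.1f%% at 1 kb",
      o0$percent_A_hit, o0$percent_B_hit, o1$percent_A_hit, o1$percent_B_hit))
  }
  if (!is.null(report$domains)) {
    w(report$domains$comparison$table, "domain_comparison")
    w(report$domains$table2, "fold_change_calls")
    lines <- c(lines, sprintf(
      "domains: %d called; %.1f%% stable; Pearson r = %.3f",
      nrow(report$domains$comparison$table),
      report$domains$comparison$percent_stable,
      report$domains$comparison$pearson))
  }
  if (!is.null(report$promoters)) {
    w(report$promoters$states, "promoter_states")
    lines <- c(lines, paste("promoter classes:",
      paste(sprintf("%s=%d", names(table(report$promoters$states$class)),
                    table(report$promoters$states$class)), collapse = " ")))
  }
  if (!is.null(report$expression)) {
    w(report$expression$gene_table, "gene_table")
    w(report$expression$regression$coefficients, "regression")
    if (!is.null(report$expression$class_comparison)) {
      w(report$expression$class_comparison, "class_comparison")
    }
    k4 <- report$expression$regression$coefficients
    k4 <- k4[k4$term == "dH3K4me3", ]
    lines <- c(lines, sprintf(
      "expression: H3K4me3 delta coefficient %.3f (p = %.2g), model R^2 = %.3f",
      k4$estimate, k4$p, report$expression$regression$r_squared))
  }
  if (!is.null(report$assays)) {
    w(report$assays$ddct, "ddct")
    w(report$assays$retained, "pulldown_retained")
    lines <- c(lines, sprintf(
      "assays: %d proteins retained (sensitivity %.2f, %d false positives)",
      nrow(report$assays$retained), report$assays$pulldown_sensitivity,
      report$assays$pulldown_false_positives))
  }
  writeLines(lines, file.path(outdir, "summary.txt"))
  invisible(outdir)
}

#' @export
print.audit_report <- function(x, ...) {
  tmp <- tempfile()
  write_audit_report(x, tmp)
  cat(readLines(file.path(tmp, "summary.txt")), sep = "\n")
  unlink(tmp, recursive = TRUE)
  invisible(x)
}
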