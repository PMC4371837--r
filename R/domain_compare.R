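#' Enriched-domain calling and two-genotype comparison
#'
#' Defines histone-mark enrichment domains in a reference condition with
#' a sliding-window Poisson test against a library-scaled control,
#' integrates normalized signal per domain in two genotypes, calls
#' gains/losses with a treatment/control swap, and computes concordance.
#' The binary-condition discipline of the comparison: domains are defined
#' on the reference condition only, so changing the alternate track never
#' changes which domains exist.
#'
#' @name domain_compare
NULL

window_sums <- function(v, w) {
  cs <- c(0, cumsum(v))
  n <- length(v) - w + 1
  if (n < 1) return(numeric(0))
  cs[(w + 1):(w + n)] - cs[1:n]
}

#' Robust per-bin background rate of a track
#'
#' The median of 10-bin sliding-window sums divided by the window
#' width. Enriched domains occupy a minority of the genome, so the
#' median reflects the background; unlike total-count (per-million)
#' scaling it is insensitive to composition differences when one
#' condition carries large planted or biological enrichment changes.
#'
#' @param track a `signal_track`.
#' @param w window width in bins used for the median (default 10).
#' @return background rate in counts per bin.
#' @export
track_background <- function(track, w = 10) {
  sums <- unlist(lapply(track$bins, window_sums, w = w))
  if (!length(sums)) stop("track too short for background estimation")
  med <- stats::median(sums) / w
  if (med <= 0) med <- mean(unlist(track$bins))
  if (med <= 0) stop("cannot estimate background: track is empty")
  med
}

#' Call enrichment domains from a ChIP track against a control track
#'
#' Slides a window of `window_bins` bins (step one bin) along each
#' chromosome; each window's ChIP count is tested one-sided against a
#' Poisson expectation equal to the library-scaled control count (floored
#' at the control's global background rate). Window p-values are
#' Benjamini-Hochberg corrected across all windows; significant windows
#' closer than `merge_gap` bases are merged into domains, each annotated
#' with the raw p of its best window and its normalized chip/control
#' enrichment ratio.
#'
#' @param chip,control `signal_track`s with equal bin size.
#' @param window_bins window width in bins (default 10).
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param merge_gap maximum gap in bases between merged windows
#'   (default 200).
#' @param min_fold fold-enrichment floor: a window is retained only if
#'   its ChIP count also exceeds `min_fold` times its expectation
#'   (default 2). Standard peak-caller practice; without it, dense true
#'   signal relaxes the BH cutoff enough to admit weak background
#'   fluctuations as separate domains.
#' @return data.frame of domains: chrom, start, end, chip_cpm,
#'   control_cpm, enrichment, p_value.
#' @export
call_domains <- function(chip, control, window_bins = 10, alpha = 0.05,
                         merge_gap = 200, min_fold = 2) {
  stopifnot(chip$bin_size == control$bin_size)
  if (chip$library_size == 0 || control$library_size == 0) {
    stop("zero library size")
  }
  # background-rate scaling rather than total-count scaling: with few
  # large enrichment differences the totals are composition-biased
  bg_rate <- track_background(control, window_bins)
  scale <- track_background(chip, window_bins) / bg_rate
  wins <- list()
  for (chr in names(chip$bins)) {
    vc <- chip$bins[[chr]]
    vb <- if (chr %in% names(control$bins)) control$bins[[chr]] else
      numeric(length(vc))
    length(vb) <- length(vc); vb[is.na(vb)] <- 0
    sc <- window_sums(vc, window_bins)
    sb <- window_sums(vb, window_bins)
    if (!length(sc)) next
    lambda <- scale * pmax(sb, bg_rate * window_bins)
    p <- stats::ppois(sc - 1, lambda, lower.tail = FALSE)
    wins[[chr]] <- data.frame(chrom = chr, win = seq_along(sc),
                              chip = sc, lambda = lambda, p = p,
                              stringsAsFactors = FALSE)
  }
  wdf <- do.call(rbind, wins)
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      chip_cpm = numeric(), control_cpm = numeric(),
                      enrichment = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(wdf) || nrow(wdf) == 0) return(empty)
  wdf$padj <- stats::p.adjust(wdf$p, method = "BH")
  sig <- wdf[wdf$padj <= alpha & wdf$chip >= min_fold * wdf$lambda, , drop = FALSE]
  if (nrow(sig) == 0) return(empty)
  bs <- chip$bin_size
  gap_bins <- ceiling(merge_gap / bs)
  out <- list()
  for (chr in unique(sig$chrom)) {
    s <- sig[sig$chrom == chr, , drop = FALSE]
    s <- s[order(s$win), , drop = FALSE]
    # windows as bin ranges [win, win + window_bins - 1]; merge with gap
    run_start <- s$win[1]; run_end <- s$win[1] + window_bins - 1
    run_p <- s$p[1]
    flush <- function(a, b, p) {
      dom_start <- (a - 1L) * bs
      dom_end <- b * bs
      idx <- a:b
      cc <- sum(chip$bins[[chr]][idx])
      vb <- if (chr %in% names(control$bins)) control$bins[[chr]] else numeric(0)
      bb <- sum(vb[idx[idx <= length(vb)]], na.rm = TRUE)
      chip_cpm <- 1e6 * cc / chip$library_size
      ctrl_cpm <- 1e6 * bb / control$library_size
      data.frame(chrom = chr, start = dom_start, end = dom_end,
                 chip_cpm = chip_cpm, control_cpm = ctrl_cpm,
                 enrichment = chip_cpm / pmax(ctrl_cpm, 1e-9),
                 p_value = p, stringsAsFactors = FALSE)
    }
    if (nrow(s) > 1) {
      for (i in 2:nrow(s)) {
        if (s$win[i] <= run_end + gap_bins + 1) {
          run_end <- max(run_end, s$win[i] + window_bins - 1)
          run_p <- min(run_p, s$p[i])
        } else {
          out[[length(out) + 1]] <- flush(run_start, run_end, run_p)
          run_start <- s$win[i]; run_end <- s$win[i] + window_bins - 1
          run_p <- s$p[i]
        }
      }
    }
    out[[length(out) + 1]] <- flush(run_start, run_end, run_p)
  }
  res <- do.call(rbind, out)
  # domain-level confirmation: a merged domain stands only if its best
  # window survives Bonferroni across all windows, guarding against
  # isolated fluctuations that slip through the window-level BH screen
  res <- res[res$p_value <= alpha / nrow(wdf), , drop = FALSE]
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Mean library-normalized signal over intervals
#'
#' Per interval, the mean counts-per-million-per-bin over covered bins,
#' partial bins weighted by their covered fraction. With a normalizer
#' track the value is divided by the normalizer's mean over the same
#' bins; intervals where the normalizer mean is 0 get NA (flagged, not
#' dropped).
#'
#' @param track a `signal_track`.
#' @param x an `interval_table`.
#' @param normalizer optional `signal_track` (e.g. H3 or input).
#' @return numeric vector, one value per interval.
#' @export
integrate_signal <- function(track, x, normalizer = NULL) {
  bs <- track$bin_size
  one <- function(trk, chrom, start, end) {
    v <- trk$bins[[chrom]]
    if (is.null(v)) stop("interval on chromosome absent from track: ", chrom)
    if (end > length(v) * bs) stop("interval beyond track extent on ", chrom)
    b0 <- start %/% bs; b1 <- (end - 1L) %/% bs # 0-based bin range
    idx <- (b0:b1) + 1L
    frac <- pmin(end, (b0:b1 + 1) * bs) - pmax(start, (b0:b1) * bs)
    frac <- frac / bs
    cpm <- 1e6 * v[idx] / trk$library_size
    sum(frac * cpm) / sum(frac)
  }
  vals <- vapply(seq_len(nrow(x)), function(i) {
    one(track, x$chrom[i], x$start[i], x$end[i])
  }, numeric(1))
  if (!is.null(normalizer)) {
    nv <- vapply(seq_len(nrow(x)), function(i) {
      one(normalizer, x$chrom[i], x$start[i], x$end[i])
    }, numeric(1))
    vals <- ifelse(nv > 0, vals / nv, NA_real_)
    if (anyNA(vals)) {
      warning(sum(is.na(vals)), " interval(s) with zero normalizer mean flagged NA")
    }
  }
  vals
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero
#'   variance.
#' @return correlation coefficient.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: Pearson correlation undefined")
  }
  stats::cor(x, y, method = "pearson")
}

#' Compare per-domain enrichment between a reference and an alternate
#' genotype
#'
#' Domains must have been called on the reference condition. Each domain
#' gets its input-normalized enrichment in both conditions, a log2 fold
#' change, a two-sided p for the count difference (binomial split of the
#' domain's reference + alternate ChIP counts, library-scaled), and a
#' call: LOSS_COMPLETE when the alternate ChIP is not enriched over its
#' own input at `alpha` (one-sided Poisson) and signal dropped; GAIN /
#' LOSS when significant with |log2FC| >= `stable_lfc`; else STABLE.
#'
#' @param domains data.frame from [call_domains()] (or any
#'   `interval_table`-like with chrom/start/end).
#' @param track_ref,track_alt ChIP `signal_track`s.
#' @param input_ref,input_alt matched input `signal_track`s (optional;
#'   without them raw library-scaled signal is compared).
#' @param alpha significance threshold (default 0.05).
#' @param stable_lfc half-width of the stable band on log2FC
#'   (default 0.5).
#' @return list of class `domain_comparison`: `table` (per-domain
#'   data.frame with enrich_ref, enrich_alt, log2_fold_change, call,
#'   p_value), `pearson` (concordance of enrichments), `percent_stable`.
#' @export
compare_domain_enrichment <- function(domains, track_ref, track_alt,
                                      input_ref = NULL, input_alt = NULL,
                                      alpha = 0.05, stable_lfc = 0.5) {
  if (nrow(domains) == 0) stop("empty domain set")
  iv <- intervals(domains$chrom, domains$start, domains$end)
  # raw counts per domain for enrichment and the count tests
  raw_counts <- function(trk) {
    vapply(seq_len(nrow(iv)), function(i) {
      v <- trk$bins[[iv$chrom[i]]]
      b0 <- iv$start[i] %/% trk$bin_size + 1L
      b1 <- (iv$end[i] - 1L) %/% trk$bin_size + 1L
      sum(v[b0:min(b1, length(v))])
    }, numeric(1))
  }
  nbins <- (iv$end - iv$start) / track_ref$bin_size
  c_ref <- raw_counts(track_ref); c_alt <- raw_counts(track_alt)
  bg_ref <- track_background(track_ref)
  bg_alt <- track_background(track_alt)
  # fold over the track's own background; input-relative when inputs given
  enr_ref <- (c_ref / nbins) / bg_ref
  enr_alt <- (c_alt / nbins) / bg_alt
  if (!is.null(input_ref)) {
    ci <- raw_counts(input_ref) / nbins / track_background(input_ref)
    enr_ref <- ifelse(ci > 0, enr_ref / ci, NA_real_)
  }
  if (!is.null(input_alt)) {
    ci <- raw_counts(input_alt) / nbins / track_background(input_alt)
    enr_alt <- ifelse(ci > 0, enr_alt / ci, NA_real_)
  }
  pr <- bg_alt / (bg_alt + bg_ref)
  p_diff <- vapply(seq_along(c_ref), function(i) {
    n <- c_ref[i] + c_alt[i]
    if (n == 0) return(1)
    stats::binom.test(round(c_alt[i]), round(n), p = pr)$p.value
  }, numeric(1))
  lfc <- log2(pmax(enr_alt, 1e-9) / pmax(enr_ref, 1e-9))
  # is the alternate ChIP still enriched over its own input?
  alt_enriched <- rep(TRUE, nrow(iv))
  if (!is.null(input_alt)) {
    ci_alt <- raw_counts(input_alt)
    scale_alt <- bg_alt / track_background(input_alt)
    p_alt_bg <- stats::ppois(c_alt - 1, scale_alt * pmax(ci_alt, 1),
                             lower.tail = FALSE)
    alt_enriched <- p_alt_bg <= alpha
  }
  call <- ifelse(!alt_enriched & lfc < 0, "LOSS_COMPLETE",
          ifelse(p_diff <= alpha & lfc >= stable_lfc, "GAIN",
          ifelse(p_diff <= alpha & lfc <= -stable_lfc, "LOSS", "STABLE")))
  tab <- data.frame(
    chrom = iv$chrom, start = iv$start, end = iv$end,
    enrich_ref = enr_ref, enrich_alt = enr_alt,
    log2_fold_change = lfc, p_value = p_diff, call = call,
    stringsAsFactors = FALSE
  )
  r <- tryCatch(pearson_correlation(enr_ref, enr_alt), error = function(e) NA_real_)
  structure(list(
    table = tab, pearson = r,
    percent_stable = round(100 * mean(call == "STABLE"), 1)
  ), class = "domain_comparison")
}

#' @export
print.domain_comparison <- function(x, ...) {
  cat(sprintf("domain comparison: %d domains, %.1f%% stable, Pearson r = %.3f\n",
              nrow(x$table), x$percent_stable, x$pearson))
  print(table(x$table$call))
  invisible(x)
}

#' Render a domain comparison as a signed fold-change report
#'
#' Signed fold change (2^|log2FC|, negative for losses) to one decimal
#' for domains with a significant difference; complete losses are
#' rendered as the string "Loss". Stable domains are omitted.
#'
#' @param cmp a `domain_comparison`.
#' @param gene optional character vector of gene labels per domain.
#' @return data.frame: gene/locus, change.
#' @export
fold_change_report <- function(cmp, gene = NULL) {
  tab <- cmp$table
  if (is.null(gene)) gene <- sprintf("%s:%d-%d", tab$chrom, tab$start, tab$end)
  keep <- tab$call != "STABLE"
  chg <- ifelse(tab$call == "LOSS_COMPLETE", "Loss",
                sprintf("%.1f", sign(tab$log2_fold_change) *
                          2^abs(tab$log2_fold_change)))
  data.frame(gene = gene[keep], change = chg[keep],
             log2_fold_change = tab$log2_fold_change[keep],
             call = tab$call[keep], stringsAsFactors = FALSE)
}

#' Differential regions by the treatment/control swap procedure
#'
#' Gains are domains called with the treatment track as ChIP and the
#' control track as its control; the tracks are then swapped and
#' re-analyzed for losses. The two sets are disjoint by construction and
#' reported separately.
#'
#' @param track_T,track_C `signal_track`s (e.g. KO and WT ChIP).
#' @inheritParams call_domains
#' @return list with `gains` and `losses` domain data.frames.
#' @export
differential_regions_swap <- function(track_T, track_C, window_bins = 10,
                                      alpha = 0.05, merge_gap = 200,
                                      min_fold = 2) {
  list(
    gains = call_domains(track_T, track_C, window_bins, alpha, merge_gap,
                         min_fold),
    losses = call_domains(track_C, track_T, window_bins, alpha, merge_gap,
                          min_fold)
  )
}
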