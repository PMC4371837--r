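#' Interval set arithmetic and overlap statistics
#'
#' Extension, reciprocal overlap reports, TSS assignment, consensus
#' filtering against a reference peak set, and bivalent promoter
#' classification. "Overlap" throughout means at least one shared base
#' under half-open arithmetic; touching intervals do not overlap.
#'
#' @name interval_analysis
NULL

#' Extend intervals symmetrically by a flank
#'
#' start' = max(0, start - flank), end' = end + flank (clipped to the
#' chromosome length when `chrom_lengths` is given). No merging.
#'
#' @param x an `interval_table`.
#' @param flank non-negative flank in bases.
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @export
extend_intervals <- function(x, flank, chrom_lengths = NULL) {
  if (flank < 0) stop("flank must be >= 0")
  x$start <- pmax(0L, x$start - as.integer(flank))
  x$end <- x$end + as.integer(flank)
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[x$chrom]
    x$end <- as.integer(pmin(x$end, lim))
  }
  x
}

overlap_hits_logical <- function(A, B) {
  if (nrow(A) == 0 || nrow(B) == 0) {
    return(list(A = logical(nrow(A)), B = logical(nrow(B))))
  }
  grA <- intervals_to_granges(A)
  grB <- intervals_to_granges(B)
  list(
    A = IRanges::overlapsAny(grA, grB, ignore.strand = TRUE),
    B = IRanges::overlapsAny(grB, grA, ignore.strand = TRUE)
  )
}

#' Reciprocal overlap report between two interval sets
#'
#' An element is "hit" if it intersects >= 1 base of any element of the
#' other set, after extending set A by `flank_A` (and optionally B by
#' `flank_B`, default 0). Percentages are rounded to 1 decimal; empty
#' sets give 0.0.
#'
#' @param A,B `interval_table`s on the same genome.
#' @param flank_A,flank_B flanks in bases applied before overlap.
#' @return list of class `overlap_report`: n_A, n_B, n_A_hit, n_B_hit,
#'   percent_A_hit, percent_B_hit, flank_A, flank_B.
#' @export
overlap_report <- function(A, B, flank_A = 0, flank_B = 0) {
  Ax <- extend_intervals(A, flank_A)
  Bx <- extend_intervals(B, flank_B)
  hits <- overlap_hits_logical(Ax, Bx)
  n_A <- nrow(A); n_B <- nrow(B)
  n_A_hit <- sum(hits$A); n_B_hit <- sum(hits$B)
  structure(list(
    n_A = n_A, n_B = n_B, n_A_hit = n_A_hit, n_B_hit = n_B_hit,
    percent_A_hit = if (n_A) round(100 * n_A_hit / n_A, 1) else 0.0,
    percent_B_hit = if (n_B) round(100 * n_B_hit / n_B, 1) else 0.0,
    flank_A = flank_A, flank_B = flank_B
  ), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap (flank_A = %d bp): %d/%d A hit (%.1f%%), %d/%d B hit (%.1f%%)\n",
              x$flank_A, x$n_A_hit, x$n_A, x$percent_A_hit,
              x$n_B_hit, x$n_B, x$percent_B_hit))
  invisible(x)
}

#' Assign peaks to genes by TSS proximity
#'
#' A peak is assigned to every gene whose TSS point lies within
#' `max_dist` bases of the peak's nearest edge (distance 0 if the TSS
#' lies inside the peak; the `max_dist` boundary is inclusive). The
#' nearest gene per peak is flagged.
#'
#' @param peaks an `interval_table`.
#' @param tss an `interval_table` of TSS points (1-bp intervals; `name`
#'   holds the gene id).
#' @param max_dist maximum distance in bases (default 20000).
#' @return data.frame: peak, gene, distance, nearest.
#' @export
assign_to_tss <- function(peaks, tss, max_dist = 20000) {
  if (max_dist < 0) stop("max_dist must be >= 0")
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    same <- tss[tss$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(same) == 0) next
    pos <- same$start # TSS point, 0-based
    d <- ifelse(pos >= peaks$start[i] & pos < peaks$end[i], 0L,
                ifelse(pos < peaks$start[i], peaks$start[i] - pos,
                       pos - (peaks$end[i] - 1L)))
    keep <- which(d <= max_dist)
    if (!length(keep)) next
    peak_id <- if (nzchar(peaks$name[i])) peaks$name[i] else
      sprintf("%s:%d-%d", peaks$chrom[i], peaks$start[i], peaks$end[i])
    out[[length(out) + 1]] <- data.frame(
      peak = peak_id, gene = same$name[keep], distance = d[keep],
      nearest = d[keep] == min(d[keep]), stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(peak = character(), gene = character(),
                      distance = integer(), nearest = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Classify promoter chromatin state from H3K4me3 and H3K27me3 peaks
#'
#' A mark is present iff any of its peaks lies within `promoter_window`
#' bases of the TSS point (boundary inclusive). The four states of the
#' presence 2x2 are BIVALENT (both), K4_ONLY, K27_ONLY and NEITHER;
#' mutually exclusive and exhaustive.
#'
#' @param tss an `interval_table` of TSS points (name = gene).
#' @param k4_peaks,k27_peaks `interval_table`s of mark peaks.
#' @param promoter_window window half-width in bases (default 5000).
#' @return data.frame: gene, k4, k27, class.
#' @export
classify_promoter_state <- function(tss, k4_peaks, k27_peaks,
                                    promoter_window = 5000) {
  stopifnot(promoter_window > 0)
  near <- function(peaks) {
    if (nrow(peaks) == 0) return(logical(nrow(tss)))
    vapply(seq_len(nrow(tss)), function(i) {
      p <- peaks[peaks$chrom == tss$chrom[i], , drop = FALSE]
      if (nrow(p) == 0) return(FALSE)
      pos <- tss$start[i]
      d <- ifelse(pos >= p$start & pos < p$end, 0L,
                  ifelse(pos < p$start, p$start - pos, pos - (p$end - 1L)))
      any(d <= promoter_window)
    }, logical(1))
  }
  k4 <- near(k4_peaks)
  k27 <- near(k27_peaks)
  cls <- ifelse(k4 & k27, "BIVALENT",
                ifelse(k4, "K4_ONLY", ifelse(k27, "K27_ONLY", "NEITHER")))
  data.frame(gene = tss$name, k4 = k4, k27 = k27, class = cls,
             stringsAsFactors = FALSE)
}

#' Consensus filter of a peak set against a reference set
#'
#' Retains every element of A that intersects at least one element of B.
#' By default the retained interval is the union of the A element with
#' all its B partners (the retained set keeps the overlap peaks while
#' their boundaries may differ); `boundaries = "intersect"` instead
#' clips to the A/B intersection hull. Output is sorted and
#' de-duplicated; `consensus_filter(A, A)` returns A.
#'
#' @param A,B `interval_table`s.
#' @param boundaries "union" (default) or "intersect".
#' @return an `interval_table`.
#' @export
consensus_filter <- function(A, B, boundaries = c("union", "intersect")) {
  boundaries <- match.arg(boundaries)
  if (nrow(A) == 0 || nrow(B) == 0) return(empty_intervals())
  grA <- intervals_to_granges(A)
  grB <- intervals_to_granges(B)
  hits <- GenomicRanges::findOverlaps(grA, grB, ignore.strand = TRUE)
  if (length(hits) == 0) return(empty_intervals())
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  starts <- A$start[qi]; ends <- A$end[qi]
  bs <- B$start[si]; be <- B$end[si]
  if (boundaries == "union") {
    ns <- pmin(starts, bs); ne <- pmax(ends, be)
  } else {
    ns <- pmax(starts, bs); ne <- pmin(ends, be)
  }
  df <- data.frame(chrom = A$chrom[qi], start = ns, end = ne,
                   stringsAsFactors = FALSE)
  # collapse multiple partners of one A element to its overall hull
  agg_s <- tapply(df$start, qi, min)
  agg_e <- tapply(df$end, qi, max)
  uq <- as.integer(names(agg_s))
  out <- data.frame(chrom = A$chrom[uq], start = as.integer(agg_s),
                    end = as.integer(agg_e), stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  intervals(out$chrom, out$start, out$end)
}
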