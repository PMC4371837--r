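#' Position weight matrix motif scanning with exact p-values
#'
#' Scores RE1 motifs by log-odds against a background model, assigns
#' exact p-values from the discretized score distribution, scans both
#' strands of a genome, and classifies bound regions by motif content
#' (multiple same-strand full sites, single full site, half site only,
#' or none).
#'
#' @name motif_scan
NULL

#' Construct a position weight matrix
#'
#' @param probs 4 x L numeric matrix of per-position base probabilities,
#'   rows named or ordered A, C, G, T; each column must sum to 1.
#' @param background length-4 background frequencies over A, C, G, T
#'   (default uniform).
#' @param pseudocount probability mass mixed in to avoid -Inf log-odds
#'   for zero entries (default 1e-4).
#' @return object of class `pwm` with the log2-odds score matrix
#'   precomputed.
#' @export
pwm <- function(probs, background = rep(0.25, 4), pseudocount = 1e-4) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4) stop("PWM must have 4 rows (A, C, G, T)")
  if (is.null(rownames(probs))) rownames(probs) <- c("A", "C", "G", "T")
  probs <- probs[c("A", "C", "G", "T"), , drop = FALSE]
  if (any(abs(colSums(probs) - 1) > 1e-9 + 1e-6)) {
    stop("each PWM position must sum to 1")
  }
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  p <- (probs + pseudocount) / (1 + 4 * pseudocount)
  scores <- log2(p / background)
  structure(
    list(probs = probs, background = background, scores = scores,
         length = ncol(probs)),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm: length %d, consensus %s\n", x$length, pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM (highest-probability base per position)
#' @param x a `pwm`.
#' @export
pwm_consensus <- function(x) {
  paste(rownames(x$probs)[apply(x$probs, 2, which.max)], collapse = "")
}

#' Sub-PWM over a range of positions (half sites)
#' @param x a `pwm`.
#' @param positions integer vector of columns to keep.
#' @export
pwm_subset <- function(x, positions) {
  pwm(x$probs[, positions, drop = FALSE], x$background)
}

#' Build a PWM from a consensus sequence
#'
#' Each position gives probability `match_prob` to the consensus base and
#' splits the remainder evenly. Used by the simulator and tests.
#' @param consensus a DNA string.
#' @param match_prob probability of the consensus base (default 0.85).
#' @inheritParams pwm
#' @export
pwm_from_consensus <- function(consensus, match_prob = 0.85,
                               background = rep(0.25, 4)) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(all(bases %in% c("A", "C", "G", "T")))
  m <- matrix((1 - match_prob) / 3, nrow = 4, ncol = length(bases),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_along(bases)) m[bases[i], i] <- match_prob
  pwm(m, background)
}

#' Write a PWM as TSV (columns A, C, G, T; one row per position)
#' @param x a `pwm`.
#' @param path output path.
#' @export
write_pwm <- function(x, path) {
  df <- as.data.frame(t(x$probs))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

base_index <- function(chars) {
  idx <- match(chars, c("A", "C", "G", "T"))
  idx # NA for N and other ambiguity codes
}

#' Log-odds score of a single window
#'
#' score = sum_i log2(P_i(s_i) / bg(s_i)), in bits. `N` (or any
#' non-ACGT character) contributes 0 (neutral).
#'
#' @param x a `pwm`.
#' @param sequence character string of length equal to the PWM length.
#' @return numeric score in bits.
#' @export
score_window <- function(x, sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (length(chars) != x$length) {
    stop("sequence length ", length(chars), " != PWM length ", x$length)
  }
  idx <- base_index(chars)
  contrib <- x$scores[cbind(idx, seq_len(x$length))]
  sum(contrib[!is.na(idx)])
}

#' Exact discretized score distribution under the background model
#'
#' Dynamic programming convolution over positions: scores are quantized
#' to multiples of `granularity` bits and the distribution of the total
#' score of a random background L-mer is built position by position. The
#' resulting tail function gives exact p-values,
#' p(s) = P(score >= s), up to one granularity quantum.
#'
#' @param x a `pwm`.
#' @param granularity score quantum in bits (default 0.01).
#' @param max_cells guard on table size (default 1e7).
#' @return object of class `pwm_distribution` with elements `support`
#'   (score grid), `prob` and `tail` (P(score >= support)).
#' @export
score_distribution <- function(x, granularity = 0.01, max_cells = 1e7) {
  stopifnot(granularity > 0)
  q <- round(x$scores / granularity) # integer quanta, 4 x L
  lo <- sum(apply(q, 2, min))
  hi <- sum(apply(q, 2, max))
  width <- hi - lo + 1
  if (width * x$length > max_cells) {
    stop("score distribution table too large; increase granularity")
  }
  # pmf over integer offsets 0..width-1 relative to lo
  pmf <- numeric(width)
  pmf[1] <- 1
  off <- 0L
  for (j in seq_len(x$length)) {
    qj <- q[, j]
    new <- numeric(width)
    minj <- min(qj)
    for (b in 1:4) {
      shift <- qj[b] - minj
      contrib <- x$background[b] * pmf
      if (shift == 0) {
        new <- new + contrib
      } else {
        new[(shift + 1):width] <- new[(shift + 1):width] +
          contrib[1:(width - shift)]
      }
    }
    off <- off + minj
    pmf <- new
  }
  support <- (lo:hi) * granularity
  tail <- rev(cumsum(rev(pmf)))
  structure(
    list(support = support, prob = pmf, tail = tail,
         granularity = granularity),
    class = "pwm_distribution"
  )
}

#' Exact p-value of a score under a precomputed distribution
#'
#' @param dist a `pwm_distribution`.
#' @param score numeric vector of scores in bits.
#' @return P(background score >= observed), clamped to (0, 1].
#' @export
pwm_pvalue <- function(dist, score) {
  k <- round(score / dist$granularity) - round(dist$support[1] / dist$granularity) + 1
  k <- pmax(1, pmin(k, length(dist$tail)))
  p <- dist$tail[k]
  pmax(p, .Machine$double.xmin)
}

# vectorized scores of every window of a chromosome (forward strand)
scan_scores_one_strand <- function(x, seq_chars_idx) {
  L <- x$length
  n <- length(seq_chars_idx) - L + 1
  if (n < 1) return(numeric(0))
  total <- numeric(n)
  for (j in seq_len(L)) {
    idx <- seq_chars_idx[j:(j + n - 1)]
    contrib <- x$scores[cbind(idx, j)]
    contrib[is.na(idx)] <- 0
    total <- total + contrib
  }
  total
}

#' Scan genome regions for motif hits on both strands
#'
#' Scores every window of each region on both strands with the full PWM
#' and with the left- and right-half sub-PWMs, and reports hits at or
#' below the per-kind p-value thresholds. Reverse-strand hit coordinates
#' refer to the forward strand. All overlapping hits are reported.
#'
#' @param x the full-length `pwm`.
#' @param genome named `DNAStringSet` (or named character vector).
#' @param regions an `interval_table` of regions to scan.
#' @param p_full p-value threshold for full-site hits (default 1e-4).
#' @param p_half threshold for half-site hits (default 1e-3).
#' @param halves list with integer vectors `left` and `right` giving the
#'   PWM columns of the two half sites; default columns 1-9 and 11-21 of
#'   a 21-column PWM (the canonical RE1 half-site split), scaled to the
#'   PWM length if it differs.
#' @param granularity p-value discretization in bits (default 0.01).
#' @return data.frame of hits: region name, chrom, start, end, strand,
#'   score, p_value, motif_kind.
#' @export
scan_sequence <- function(x, genome, regions, p_full = 1e-4, p_half = 1e-3,
                          halves = NULL, granularity = 0.01) {
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(unlist(genome))
  }
  if (is.null(halves)) {
    if (x$length == 21) {
      halves <- list(left = 1:9, right = 11:21)
    } else {
      mid <- ceiling(x$length / 2)
      halves <- list(left = seq_len(mid - 1), right = (mid + 1):x$length)
    }
  }
  kinds <- list(
    full = list(pwm = x, thr = p_full),
    left_half = list(pwm = pwm_subset(x, halves$left), thr = p_half),
    right_half = list(pwm = pwm_subset(x, halves$right), thr = p_half)
  )
  for (k in names(kinds)) {
    kinds[[k]]$dist <- score_distribution(kinds[[k]]$pwm, granularity)
  }
  out <- list()
  for (i in seq_len(nrow(regions))) {
    chrom <- regions$chrom[i]
    if (!chrom %in% names(genome)) stop("region on unknown chromosome: ", chrom)
    chrlen <- length(genome[[chrom]])
    if (regions$end[i] > chrlen) {
      stop(sprintf("region %s:%d-%d outside chromosome (length %d)",
                   chrom, regions$start[i], regions$end[i], chrlen))
    }
    seq <- Biostrings::subseq(genome[[chrom]], regions$start[i] + 1L, regions$end[i])
    fwd <- base_index(strsplit(as.character(seq), "")[[1]])
    rev_idx <- rev(5L - fwd) # complement: A<->T (1<->4), C<->G (2<->3); NA stays NA
    reg_len <- length(fwd)
    for (k in names(kinds)) {
      kk <- kinds[[k]]
      L <- kk$pwm$length
      for (strand in c("+", "-")) {
        sc <- scan_scores_one_strand(kk$pwm, if (strand == "+") fwd else rev_idx)
        if (!length(sc)) next
        pv <- pwm_pvalue(kk$dist, sc)
        keep <- which(pv <= kk$thr)
        if (!length(keep)) next
        # map window offset to forward-strand coordinates
        offs <- keep - 1L
        if (strand == "-") offs <- reg_len - L - offs
        out[[length(out) + 1]] <- data.frame(
          region = if (nzchar(regions$name[i])) regions$name[i] else
            sprintf("%s:%d-%d", chrom, regions$start[i], regions$end[i]),
          chrom = chrom,
          start = regions$start[i] + offs,
          end = regions$start[i] + offs + L,
          strand = strand,
          score = sc[keep],
          p_value = pv[keep],
          motif_kind = k,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(region = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      p_value = numeric(), motif_kind = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Classify a region by its motif content
#'
#' MULTI_FULL_SAME_STRAND if at least two full hits (distinct start
#' positions) share a strand; else SINGLE_FULL if any full hit (two full
#' hits on opposite strands count as SINGLE_FULL, since the multi-site
#' class requires same-strand repeats); else HALF_ONLY if any half-site
#' hit; else NONE.
#'
#' @param hits data.frame of hits for one region (as from
#'   [scan_sequence()]).
#' @return one of "MULTI_FULL_SAME_STRAND", "SINGLE_FULL", "HALF_ONLY",
#'   "NONE".
#' @export
classify_region <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0) return("NONE")
  full <- hits[hits$motif_kind == "full", , drop = FALSE]
  if (nrow(full) > 0) {
    per_strand <- tapply(full$start, full$strand,
                         function(s) length(unique(s)))
    if (any(per_strand >= 2)) return("MULTI_FULL_SAME_STRAND")
    return("SINGLE_FULL")
  }
  if (any(hits$motif_kind %in% c("left_half", "right_half"))) return("HALF_ONLY")
  "NONE"
}

#' Classify every scanned region
#'
#' @param regions an `interval_table` (names used as region ids).
#' @param hits hit table from [scan_sequence()].
#' @return data.frame with region, class, n_full, n_half.
#' @export
classify_regions <- function(regions, hits) {
  ids <- ifelse(nzchar(regions$name), regions$name,
                sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end))
  cls <- character(length(ids))
  n_full <- integer(length(ids)); n_half <- integer(length(ids))
  for (i in seq_along(ids)) {
    h <- hits[hits$region == ids[i], , drop = FALSE]
    cls[i] <- classify_region(h)
    n_full[i] <- sum(h$motif_kind == "full")
    n_half[i] <- sum(h$motif_kind != "full")
  }
  data.frame(region = ids, class = cls, n_full = n_full, n_half = n_half,
             score = regions$score, stringsAsFactors = FALSE)
}

#' Summarize motif content across classified regions
#'
#' Reports per-class counts, the percentage of regions containing a full
#' or half motif (1 decimal), and -- when regions carry an enrichment
#' score -- the mean enrichment per class plus a Kruskal-Wallis rank
#' statistic for the class/enrichment association.
#'
#' @param classified data.frame from [classify_regions()] (columns
#'   `class` and optionally `score`).
#' @return list with `counts`, `percent_with_motif`, `class_means`,
#'   `rank_test` (htest or NULL).
#' @export
summarize_motif_content <- function(classified) {
  if (nrow(classified) == 0) stop("empty region set")
  lv <- c("MULTI_FULL_SAME_STRAND", "SINGLE_FULL", "HALF_ONLY", "NONE")
  counts <- table(factor(classified$class, levels = lv))
  pct <- round(100 * sum(classified$class != "NONE") / nrow(classified), 1)
  class_means <- NULL; rank_test <- NULL
  if ("score" %in% names(classified) && any(!is.na(classified$score))) {
    ok <- !is.na(classified$score)
    class_means <- tapply(classified$score[ok],
                          factor(classified$class[ok], levels = lv), mean)
    groups <- factor(classified$class[ok])
    if (nlevels(droplevels(groups)) >= 2) {
      rank_test <- stats::kruskal.test(classified$score[ok], groups)
    }
  }
  list(counts = counts, percent_with_motif = pct,
       class_means = class_means, rank_test = rank_test)
}

#' Percentage of regions with motif support from raw counts
#'
#' The printed-ratio form of the motif-content summary: given the number
#' of regions with any full or half motif and the total, returns the
#' percentage rounded to 1 decimal (2064 of 2136 gives 96.6).
#'
#' @param n_with_motif,n_total counts.
#' @export
percent_with_motif <- function(n_with_motif, n_total) {
  if (n_total <= 0) stop("empty region set")
  round(100 * n_with_motif / n_total, 1)
}
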