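#' Genomic interval and track input/output
#'
#' All coordinates inside the package are 0-based half-open (BED
#' convention); conversion to 1-based systems happens only at I/O or
#' reporting boundaries. An interval table is a plain data.frame with
#' columns `chrom`, `start`, `end`, `name`, `score`, `strand`; strand is
#' one of `"+"`, `"-"`, `"*"` (unstranded).
#'
#' @name genomic_io
NULL

#' Construct an interval table
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param name optional labels (default "").
#' @param score optional numeric scores (default NA).
#' @param strand "+", "-" or "*" (default "*"); anything else is coerced
#'   to "*".
#' @return data.frame of class `interval_table`.
#' @export
intervals <- function(chrom, start, end, name = "", score = NA_real_,
                      strand = "*") {
  n <- max(length(chrom), length(start), length(end))
  df <- data.frame(
    chrom  = rep_len(as.character(chrom), n),
    start  = as.integer(start),
    end    = as.integer(end),
    name   = rep_len(as.character(name), n),
    score  = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  df$strand[!df$strand %in% c("+", "-")] <- "*"
  validate_intervals(df)
  class(df) <- c("interval_table", "data.frame")
  df
}

validate_intervals <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(!nzchar(df$chrom))) stop("interval with empty chromosome name")
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad)) {
    stop(sprintf("invalid interval at row %d: start=%d end=%d (need 0 <= start < end)",
                 bad[1], df$start[bad[1]], df$end[bad[1]]))
  }
  invisible(df)
}

empty_intervals <- function() {
  intervals(character(), integer(), integer())
}

#' Read a BED file (3-6 columns) into an interval table
#'
#' Input order is preserved. Strand defaults to unstranded; malformed
#' lines (fewer than 3 columns, non-numeric coordinates, start >= end)
#' are rejected with their line number.
#'
#' @param path path to a BED file.
#' @return an `interval_table`.
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_intervals())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3)) {
    stop(sprintf("line %d: expected >= 3 tab-separated columns, got %d",
                 which(ncol < 3)[1], ncol[which(ncol < 3)[1]]))
  }
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  chrom <- get(1)
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop(sprintf("line %d: non-numeric coordinate", bad[1]))
  bad <- which(!(start >= 0 & start < end))
  if (length(bad)) {
    stop(sprintf("line %d: start (%d) must be < end (%d) and >= 0",
                 bad[1], start[bad[1]], end[bad[1]]))
  }
  nm <- get(4); nm[is.na(nm)] <- ""
  sc <- suppressWarnings(as.numeric(get(5)))
  st <- get(6)
  # accept both ASCII hyphen and the typographic minus for reverse strand
  st[!is.na(st) & st == "−"] <- "-"
  st[is.na(st) | !st %in% c("+", "-")] <- "*"
  intervals(chrom, start, end, nm, sc, st)
}

#' Write an interval table as BED
#'
#' Emits as many columns as are informative: 3 if no names/scores/strands
#' are set, 6 if any strand is set. `read_intervals(write_intervals(x))`
#' round-trips losslessly.
#'
#' @param x an `interval_table`.
#' @param path output path.
#' @export
write_intervals <- function(x, path) {
  validate_intervals(x)
  if (nrow(x) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  score <- ifelse(is.na(x$score), 0, x$score)
  name <- ifelse(nzchar(x$name), x$name, ".")
  has6 <- any(x$strand != "*") || any(!is.na(x$score)) || any(nzchar(x$name))
  out <- if (has6) {
    strand <- ifelse(x$strand %in% c("+", "-"), x$strand, ".")
    paste(x$chrom, x$start, x$end, name, score, strand, sep = "\t")
  } else {
    paste(x$chrom, x$start, x$end, sep = "\t")
  }
  writeLines(out, path)
  invisible(path)
}

#' Convert an interval table to GRanges (1-based closed) and back
#'
#' Used internally at the boundary to GenomicRanges set operations.
#' @param x an `interval_table`.
#' @return a `GRanges`.
#' @keywords internal
intervals_to_granges <- function(x) {
  strand <- ifelse(x$strand %in% c("+", "-"), x$strand, "*")
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

#' @rdname intervals_to_granges
#' @param gr a `GRanges`.
#' @keywords internal
granges_to_intervals <- function(gr) {
  st <- as.character(GenomicRanges::strand(gr))
  intervals(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(names(gr))) names(gr) else "",
    score = NA_real_,
    strand = st
  )
}

#' Binned coverage track
#'
#' A signal track stores per-chromosome vectors of non-negative bin
#' counts at a fixed bin width, plus the library size (total counts over
#' all bins; each bin contributes its count once, regardless of width).
#'
#' @param bins named list of non-negative numeric vectors, one per
#'   chromosome.
#' @param bin_size bin width in bases.
#' @return object of class `signal_track`.
#' @export
signal_track <- function(bins, bin_size) {
  stopifnot(is.list(bins), !is.null(names(bins)), bin_size >= 1)
  if (any(vapply(bins, function(v) any(v < 0), logical(1)))) {
    stop("signal track values must be non-negative")
  }
  structure(
    list(bins = bins, bin_size = as.integer(bin_size),
         library_size = sum(vapply(bins, sum, numeric(1)))),
    class = "signal_track"
  )
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: %d chromosome(s), bin size %d bp, library size %.0f\n",
              length(x$bins), x$bin_size, x$library_size))
  invisible(x)
}

#' Read a bedGraph file as a binned signal track
#'
#' Every record must align to the declared bin grid; overlapping records
#' and negative values are rejected. Missing bins are filled with 0.
#'
#' @param path path to a bedGraph file.
#' @param bin_size declared bin width in bases.
#' @return a `signal_track`.
#' @export
read_track <- function(path, bin_size) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "integer", "integer", "numeric"))
  if (nrow(df) == 0) stop("empty bedGraph: ", path)
  if (any(df$value < 0)) stop("negative value in bedGraph")
  if (any(df$start %% bin_size != 0 | df$end %% bin_size != 0)) {
    stop("bedGraph record not aligned to a ", bin_size, " bp bin grid")
  }
  bins <- list()
  for (chr in unique(df$chrom)) {
    d <- df[df$chrom == chr, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
      stop("overlapping bedGraph records on ", chr)
    }
    n <- max(d$end) %/% bin_size
    v <- numeric(n)
    for (i in seq_len(nrow(d))) {
      idx <- (d$start[i] %/% bin_size + 1L):(d$end[i] %/% bin_size)
      v[idx] <- d$value[i]
    }
    bins[[chr]] <- v
  }
  signal_track(bins, bin_size)
}

#' Write a signal track as bedGraph
#'
#' One record per bin; zero bins are written so the file round-trips.
#'
#' @param track a `signal_track`.
#' @param path output path.
#' @export
write_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chr in names(track$bins)) {
    v <- track$bins[[chr]]
    n <- length(v)
    starts <- (seq_len(n) - 1L) * track$bin_size
    writeLines(paste(chr, starts, starts + track$bin_size, v, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a typed TSV table
#'
#' @param path path to a tab-separated file with a header row.
#' @param schema one of "counts" (gene + numeric sample columns), "ct"
#'   (gene, condition, replicate, ct), "peptides" (protein + integer
#'   sample columns), "pwm" (columns A, C, G, T of per-position
#'   probabilities).
#' @return a typed data.frame; for schema "pwm", a `pwm` object.
#' @export
read_table_typed <- function(path, schema = c("counts", "ct", "peptides", "pwm")) {
  schema <- match.arg(schema)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  switch(schema,
    counts = {
      if (!"gene" %in% names(df)) stop("counts schema requires a 'gene' column")
      num <- setdiff(names(df), "gene")
      for (cn in num) {
        v <- suppressWarnings(as.numeric(df[[cn]]))
        if (any(is.na(v) & !is.na(df[[cn]]))) stop("non-numeric cell in column ", cn)
        df[[cn]] <- v
      }
      df
    },
    ct = {
      req <- c("gene", "condition", "replicate", "ct")
      if (!all(req %in% names(df))) {
        stop("ct schema requires columns: ", paste(req, collapse = ", "))
      }
      df$ct <- as.numeric(df$ct)
      if (any(is.na(df$ct))) stop("non-numeric Ct value")
      df
    },
    peptides = {
      if (!"protein" %in% names(df)) stop("peptides schema requires a 'protein' column")
      num <- setdiff(names(df), "protein")
      for (cn in num) {
        v <- suppressWarnings(as.numeric(df[[cn]]))
        if (any(is.na(v)) || any(v != round(v))) {
          stop("non-integer peptide count in column ", cn)
        }
        df[[cn]] <- as.integer(v)
      }
      df
    },
    pwm = {
      req <- c("A", "C", "G", "T")
      if (!all(req %in% names(df))) stop("pwm schema requires columns A, C, G, T")
      m <- as.matrix(df[, req])
      if (any(abs(rowSums(m) - 1) > 1e-6)) {
        stop("PWM row probabilities must sum to 1 (row ",
             which(abs(rowSums(m) - 1) > 1e-6)[1], ")")
      }
      pwm(t(m))
    }
  )
}

#' Read/write genome FASTA
#'
#' Thin wrappers over Biostrings for the package's toy genomes.
#' @param path FASTA path.
#' @return named `DNAStringSet`.
#' @export
read_genome <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_genome
#' @param genome a named `DNAStringSet` or named character vector.
#' @export
write_genome <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(unlist(genome))
  }
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}
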