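# Shared helpers for the numbered analysis drivers.
#
# Every driver is runnable on its own from the previous stage's
# serialized outputs:
#   Rscript analysis/01_simulate.R [--seed N] [--outdir results]
#   Rscript analysis/02_scan_motifs.R [--outdir results]
#   ...
# Stages communicate only through files under --outdir.

suppressMessages(library(restpoise))

parse_args <- function() {
  args <- commandArgs(trailingOnly = TRUE)
  get <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  list(seed = as.integer(get("--seed", "1")),
       outdir = get("--outdir", "results"))
}

stage_dir <- function(outdir, name) {
  d <- file.path(outdir, name)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

track_marks <- c("REST", "H3K4me3", "H3K9ac", "H3K9me2", "H3K27me3",
                 "H3", "input")

read_tracks <- function(dir, genotype, bin_size) {
  tr <- lapply(track_marks, function(mk) {
    read_track(file.path(dir, sprintf("%s_%s.bedGraph", mk, genotype)),
               bin_size)
  })
  names(tr) <- track_marks
  tr
}
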