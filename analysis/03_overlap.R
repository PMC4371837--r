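#!/usr/bin/env Rscript
# Stage 3: call REST peaks and H3K27me3/H3K4me3 domains in the
# wild-type condition and compute the reciprocal overlap statistics at
# zero and 1 kb flanks, plus promoter chromatin states.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))
a <- parse_args()
s1 <- file.path(a$outdir, "01_simulated")
d <- stage_dir(a$outdir, "03_overlap")

params <- utils::read.table(file.path(s1, "run_parameters.tsv"),
                            sep = "\t", row.names = 1)
bs <- params["bin_size", 1]
wt <- read_tracks(s1, "WT", bs)
tss <- read_intervals(file.path(s1, "tss.bed"))

rest <- call_domains(wt$REST, wt$input)
k27 <- call_domains(wt$H3K27me3, wt$input)
k4 <- call_domains(wt$H3K4me3, wt$input)
as_iv <- function(x) intervals(x$chrom, x$start, x$end)

write_tsv(rest, file.path(d, "rest_peaks.tsv"))
write_tsv(k27, file.path(d, "k27_domains_wt.tsv"))
write_tsv(k4, file.path(d, "k4_peaks_wt.tsv"))

o0 <- overlap_report(as_iv(rest), as_iv(k27))
o1 <- overlap_report(as_iv(rest), as_iv(k27), flank_A = 1000)
ok4 <- overlap_report(as_iv(rest), as_iv(k4))
states <- classify_promoter_state(tss, as_iv(k4), as_iv(k27))
write_tsv(states, file.path(d, "promoter_states.tsv"))
assign <- assign_to_tss(as_iv(rest), tss, max_dist = 20000)
write_tsv(assign, file.path(d, "rest_peak_tss_assignment.tsv"))

writeLines(c(
  sprintf("REST peaks\t%d", nrow(rest)),
  sprintf("K27 domains (WT)\t%d", nrow(k27)),
  sprintf("REST peaks overlapping K27, flank 0\t%.1f%%", o0$percent_A_hit),
  sprintf("K27 domains overlapping REST, flank 0\t%.1f%%", o0$percent_B_hit),
  sprintf("REST peaks overlapping K27, flank 1 kb\t%.1f%%", o1$percent_A_hit),
  sprintf("K27 domains overlapping REST, flank 1 kb\t%.1f%%", o1$percent_B_hit),
  sprintf("REST peaks overlapping K4 peaks\t%.1f%%", ok4$percent_A_hit),
  sprintf("promoter classes\t%s",
          paste(sprintf("%s=%d", names(table(states$class)),
                        table(states$class)), collapse = " "))),
  file.path(d, "summary.txt"))
cat(readLines(file.path(d, "summary.txt")), sep = "\n")
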