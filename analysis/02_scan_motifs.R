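#!/usr/bin/env Rscript
# Stage 2: scan the REST-bound regions for RE1 motifs and classify
# them by motif content, then compare against the planted truth.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))
a <- parse_args()
s1 <- file.path(a$outdir, "01_simulated")
d <- stage_dir(a$outdir, "02_motifs")

genome <- read_genome(file.path(s1, "genome.fa"))
regions <- read_intervals(file.path(s1, "rest_regions.bed"))
re1 <- read_table_typed(file.path(s1, "re1_pwm.tsv"), "pwm")
truth <- read_tsv(file.path(s1, "region_truth.tsv"))

hits <- scan_sequence(re1, genome, regions)
classified <- classify_regions(regions, hits)
classified$true_class <- truth$class[match(classified$region, truth$region)]
summary <- summarize_motif_content(classified)

write_tsv(hits, file.path(d, "motif_hits.tsv"))
write_tsv(classified, file.path(d, "region_classes.tsv"))
writeLines(c(
  sprintf("regions scanned\t%d", nrow(classified)),
  sprintf("percent with full or half RE1\t%.1f", summary$percent_with_motif),
  sprintf("class accuracy vs planted truth\t%.3f",
          mean(classified$class == classified$true_class)),
  sprintf("class counts\t%s",
          paste(sprintf("%s=%d", names(summary$counts), summary$counts),
                collapse = " "))),
  file.path(d, "summary.txt"))
cat(readLines(file.path(d, "summary.txt")), sep = "\n")
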