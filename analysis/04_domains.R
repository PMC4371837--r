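#!/usr/bin/env Rscript
# Stage 4: compare per-domain H3K27me3 enrichment between genotypes,
# run the treatment/control swap for gains and losses, and check the
# calls against the planted truth.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))
a <- parse_args()
s1 <- file.path(a$outdir, "01_simulated")
s3 <- file.path(a$outdir, "03_overlap")
d <- stage_dir(a$outdir, "04_domains")

params <- utils::read.table(file.path(s1, "run_parameters.tsv"),
                            sep = "\t", row.names = 1)
bs <- params["bin_size", 1]
wt <- read_tracks(s1, "WT", bs)
ko <- read_tracks(s1, "KO", bs)
k27_wt <- read_tsv(file.path(s3, "k27_domains_wt.tsv"))
truth <- read_tsv(file.path(s1, "k27_domain_truth.tsv"))

cmp <- compare_domain_enrichment(k27_wt, wt$H3K27me3, ko$H3K27me3,
                                 wt$input, ko$input)
swap <- differential_regions_swap(ko$H3K27me3, wt$H3K27me3)
gains_t <- truth[truth$change == "gain", ]
losses_t <- truth[truth$change == "loss", ]
gr <- match_planted(swap$gains, gains_t)
lr <- match_planted(swap$losses, losses_t)

write_tsv(cmp$table, file.path(d, "domain_comparison.tsv"))
write_tsv(fold_change_report(cmp), file.path(d, "fold_change_calls.tsv"))
write_tsv(swap$gains, file.path(d, "swap_gains.tsv"))
write_tsv(swap$losses, file.path(d, "swap_losses.tsv"))

writeLines(c(
  sprintf("domains compared\t%d", nrow(cmp$table)),
  sprintf("percent stable\t%.1f", cmp$percent_stable),
  sprintf("Pearson concordance\t%.3f", cmp$pearson),
  sprintf("swap gains called\t%d (sensitivity %.2f, FDR %s)",
          nrow(swap$gains), gr$sensitivity, format(gr$fdr)),
  sprintf("swap losses called\t%d (sensitivity %.2f, FDR %s)",
          nrow(swap$losses), lr$sensitivity, format(lr$fdr))),
  file.path(d, "summary.txt"))
cat(readLines(file.path(d, "summary.txt")), sep = "\n")
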