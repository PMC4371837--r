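#!/usr/bin/env Rscript
# Stage 6: bench-assay statistics: delta-delta Ct quantification of the
# simulated qPCR plate and replicate filtering of the pull-down
# peptide table, both checked against the planted truth.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))
a <- parse_args()
s1 <- file.path(a$outdir, "01_simulated")
d <- stage_dir(a$outdir, "06_assays")

ct <- read_table_typed(file.path(s1, "qpcr_ct.tsv"), "ct")
qtruth <- read_tsv(file.path(s1, "qpcr_truth.tsv"))
ref <- "ref"
get_ct <- function(g, cond) {
  x <- ct[ct$gene == g & ct$condition == cond, ]
  ct_set(g, cond, x$ct)
}
goi <- setdiff(unique(ct$gene), ref)
dd <- do.call(rbind, lapply(goi, function(g) {
  r <- ddct_relative_expression(get_ct(g, "test"), get_ct(g, "control"),
                                get_ct(ref, "test"), get_ct(ref, "control"))
  data.frame(gene = g, fold_change = r$fold_change, sd = r$sd,
             true_fold = qtruth$true_fold[qtruth$gene == g],
             stringsAsFactors = FALSE)
}))
write_tsv(dd, file.path(d, "ddct.tsv"))

pep <- read_table_typed(file.path(s1, "peptides.tsv"), "peptides")
m <- as.matrix(pep[, -1]); rownames(m) <- pep$protein
bait <- grep("^bait", colnames(m), value = TRUE)
ctrl <- grep("^control", colnames(m), value = TRUE)
kept <- filter_pulldown_proteins(m, bait, ctrl)
true_ret <- readLines(file.path(s1, "peptides_true_retained.txt"))
write_tsv(kept, file.path(d, "pulldown_retained.tsv"))

writeLines(c(
  sprintf("qPCR max |log2 fold error|\t%.3f",
          max(abs(log2(dd$fold_change) - log2(dd$true_fold)))),
  sprintf("pull-down proteins retained\t%d", nrow(kept)),
  sprintf("pull-down sensitivity\t%.2f",
          mean(true_ret %in% kept$protein)),
  sprintf("pull-down false positives\t%d",
          sum(!kept$protein %in% true_ret))),
  file.path(d, "summary.txt"))
cat(readLines(file.path(d, "summary.txt")), sep = "\n")
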