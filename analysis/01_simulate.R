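#!/usr/bin/env Rscript
# Stage 1: simulate the study inputs with known ground truth.
# Writes the genome (FASTA), annotations (BED), ChIP tracks (bedGraph),
# expression counts, qPCR plate and peptide table (TSV).

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))
a <- parse_args()
d <- stage_dir(a$outdir, "01_simulated")

cfg <- sim_config(seed = a$seed)
truth <- simulate_genome(cfg)

write_genome(truth$genome, file.path(d, "genome.fa"))
write_intervals(truth$tss, file.path(d, "tss.bed"))
write_intervals(truth$regions, file.path(d, "rest_regions.bed"))
write_intervals(truth$motif_sites, file.path(d, "motif_sites.bed"))
write_tsv(truth$region_truth, file.path(d, "region_truth.tsv"))
write_tsv(truth$genes, file.path(d, "gene_truth.tsv"))
write_tsv(truth$k27_domains, file.path(d, "k27_domain_truth.tsv"))

for (gt in c("WT", "KO")) {
  tracks <- simulate_chip_tracks(truth, gt)
  for (mk in names(tracks)) {
    write_track(tracks[[mk]], file.path(d, sprintf("%s_%s.bedGraph", mk, gt)))
  }
  counts <- simulate_expression_counts(truth, gt)
  write_tsv(data.frame(gene = rownames(counts), counts,
                       check.names = FALSE),
            file.path(d, sprintf("counts_%s.tsv", gt)))
}

qp <- simulate_qpcr_plate(cfg)
write_tsv(qp$ct, file.path(d, "qpcr_ct.tsv"))
write_tsv(data.frame(gene = names(qp$true_fold), true_fold = qp$true_fold),
          file.path(d, "qpcr_truth.tsv"))

pep <- simulate_peptide_table(cfg)
write_tsv(data.frame(protein = rownames(pep$counts), pep$counts,
                     check.names = FALSE),
          file.path(d, "peptides.tsv"))
writeLines(pep$true_retained, file.path(d, "peptides_true_retained.txt"))

write_pwm(pwm_from_consensus(cfg$motifs$consensus),
          file.path(d, "re1_pwm.tsv"))
writeLines(c(sprintf("seed\t%d", a$seed),
             sprintf("bin_size\t%d", cfg$chip$bin_size),
             sprintf("promoter_halfwidth\t%d", cfg$genes$promoter_halfwidth)),
           file.path(d, "run_parameters.tsv"))
cat("stage 1 written to", d, "\n")
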