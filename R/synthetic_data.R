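#' Synthetic data with known ground truth
#'
#' Generates every input the audit pipeline consumes: a small genome
#' with planted RE1 motifs (single full sites, multi-site same-strand
#' repeats, right-half-only sites), ChIP coverage tracks for REST and
#' the histone marks in two genotypes with REST-dependent mark changes,
#' negative-binomial expression counts whose de-repression is tied to
#' the H3K4me3 change, replicate qPCR Ct values, and bait/control
#' peptide tables. Every generator is deterministic under the config
#' seed and returns its ground truth alongside the data.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults describe a desk-scale mouse-ESC-like experiment: one 1-Mb
#' chromosome at 42% GC, 60 REST-bound regions (40 single full RE1, 8
#' with 3 same-strand full repeats, 12 right-half-only), 120 genes of
#' which the 48 with a full-site region at their promoter are REST
#' targets, 50-bp track bins with Poisson backgrounds, 8-fold ChIP
#' enrichment, ~30 H3K27me3 domains of which 3 gain and 3 lose 4-fold
#' in the knockout, and expression de-repression of targets equal to
#' their H3K4me3 log2 change (beta = 1) plus N(0, 0.3) noise.
#'
#' @param seed integer RNG seed.
#' @param ... named overrides of any default (nested lists merged).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    genome = list(n_chrom = 1, chrom_length = 1e6, gc_fraction = 0.42),
    motifs = list(
      consensus = "TTCAGCACCACGGACAGCGCC",
      half_left = 1:9, half_right = 11:21,
      n_full_single = 40, n_full_multi = 8, multi_k = 3,
      n_half_only = 12, region_width = 400
    ),
    genes = list(n_genes = 120, promoter_halfwidth = 500,
                 p_k4_target = 0.75, p_k4_nontarget = 0.6,
                 p_k27_target = 0.25, p_k27_nontarget = 0.3,
                 baseline_mean_range = c(50, 2000),
                 target_repression = 0.25),
    chip = list(
      bin_size = 50, background_rate = 2,
      enrichment_fold = c(REST = 8, H3K4me3 = 8, H3K9ac = 6,
                          H3K9me2 = 6, H3K27me3 = 8),
      multi_boost = 2, half_site_fold = 0.25,
      h3_fold = 2,
      n_k27_intergenic = 10, k27_domain_width = 2000,
      n_k27_gain = 3, n_k27_loss = 3, k27_change_log2fc = 2,
      rest_dependence_k27 = 1,
      delta_k4_range = c(0.5, 2), delta_k9ac_range = c(0.5, 1.5),
      delta_k9me2_range = c(0.5, 1.5)
    ),
    expression = list(beta = 1, noise_sd = 0.3, dispersion = 0.05,
                      n_reps = 2),
    qpcr = list(n_genes = 5, replicates = 3, ct_noise_sd = 0.15,
                base_ct = 22, fold_range = c(1, 8)),
    peptides = list(n_cofactors = 10, n_contaminants = 20,
                    n_bait = 3, n_control = 2,
                    p_detect_cofactor_bait = 0.95,
                    p_detect_cofactor_control = 0.05,
                    p_detect_contaminant = 0.4,
                    cofactor_peptides = 4, contaminant_peptides = 1)
  )
  over <- list(...)
  merge_rec <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(upd[[nm]]))
        merge_rec(base[[nm]], upd[[nm]]) else upd[[nm]]
    }
    base
  }
  cfg <- merge_rec(cfg, over)
  if (cfg$expression$dispersion <= 0) stop("dispersion must be > 0")
  structure(cfg, class = "sim_config")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

random_dna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Simulate a genome with planted RE1 motifs and a gene annotation
#'
#' Background sequence is i.i.d. at the configured GC fraction;
#' rejection sampling re-draws any accidental exact full-consensus
#' occurrence (either strand) outside the planted sites so the ground
#' truth is exact. Full-site regions carry one exact consensus copy
#' (random strand); multi-site regions carry `multi_k` copies on one
#' shared strand; half-only regions carry only the right half of the
#' consensus. REST target genes are the genes whose promoter hosts a
#' full-site region.
#'
#' @param config a `sim_config`.
#' @return list of class `sim_truth`: `genome` (DNAStringSet), `tss`
#'   (interval_table), `regions` (interval_table of REST-bound regions
#'   with class in name suffix), `region_truth` (data.frame region,
#'   class, strand), `motif_sites` (interval_table of planted motif
#'   copies), `genes` (data.frame of per-gene ground truth), `k27_domains`
#'   (data.frame with per-domain WT fold and gain/loss/stable label),
#'   `config`.
#' @export
simulate_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  g <- config$genome; m <- config$motifs; ge <- config$genes
  ch <- config$chip
  cons <- toupper(m$consensus)
  Lm <- nchar(cons)
  half_right_seq <- substr(cons, min(m$half_right), max(m$half_right))
  chrom <- "chr1"
  clen <- as.integer(g$chrom_length)

  n_regions <- m$n_full_single + m$n_full_multi + m$n_half_only
  n_genes <- ge$n_genes
  spacing <- clen %/% (n_genes + 1)
  if (spacing < 4 * ge$promoter_halfwidth + m$region_width + ch$k27_domain_width) {
    stop("genome too small to place the requested genes and motif regions")
  }
  tss_pos <- spacing * seq_len(n_genes) # 0-based TSS points
  gene_ids <- sprintf("gene%03d", seq_len(n_genes))

  # assign region classes to the first genes (order then shuffled)
  classes <- c(rep("SINGLE_FULL", m$n_full_single),
               rep("MULTI_FULL_SAME_STRAND", m$n_full_multi),
               rep("HALF_ONLY", m$n_half_only))
  host <- sample(n_genes, n_regions)
  region_class <- rep(NA_character_, n_genes)
  region_class[host] <- sample(classes)
  is_target <- !is.na(region_class) & region_class != "HALF_ONLY"

  # build background sequence
  seqchr <- random_dna(clen, g$gc_fraction)

  # plant motif regions upstream of their host TSS
  rw <- m$region_width
  reg_start <- integer(0); reg_end <- integer(0); reg_name <- character(0)
  reg_class <- character(0); reg_strand <- character(0)
  site_start <- integer(0); site_end <- integer(0)
  site_strand <- character(0); site_kind <- character(0); site_region <- character(0)
  for (i in which(!is.na(region_class))) {
    rs <- tss_pos[i] - ge$promoter_halfwidth - rw # region upstream of promoter edge
    re <- rs + rw
    cls <- region_class[i]
    strand <- sample(c("+", "-"), 1)
    k <- if (cls == "MULTI_FULL_SAME_STRAND") m$multi_k else 1
    planted <- if (cls == "HALF_ONLY") half_right_seq else cons
    Lp <- nchar(planted)
    gap <- (rw - k * Lp) %/% (k + 1)
    nm <- sprintf("region_%s", gene_ids[i])
    for (j in seq_len(k)) {
      s0 <- rs + j * gap + (j - 1) * Lp # 0-based start of planted copy
      ins <- if (strand == "+") planted else revcomp_chr(planted)
      substr(seqchr, s0 + 1, s0 + Lp) <- ins
      site_start <- c(site_start, s0); site_end <- c(site_end, s0 + Lp)
      site_strand <- c(site_strand, strand)
      site_kind <- c(site_kind, if (cls == "HALF_ONLY") "right_half" else "full")
      site_region <- c(site_region, nm)
    }
    reg_start <- c(reg_start, rs); reg_end <- c(reg_end, re)
    reg_name <- c(reg_name, nm); reg_class <- c(reg_class, cls)
    reg_strand <- c(reg_strand, strand)
  }

  # rejection-sample accidental full consensus outside planted sites
  protect <- logical(clen)
  full <- site_kind == "full"
  for (i in which(full)) protect[(site_start[i] + 1):site_end[i]] <- TRUE
  for (pat in c(cons, revcomp_chr(cons))) {
    repeat {
      hits <- gregexpr(pat, seqchr, fixed = TRUE)[[1]]
      hits <- hits[hits > 0]
      hits <- hits[!vapply(hits, function(h) any(protect[h:(h + Lm - 1)]), logical(1))]
      if (!length(hits)) break
      for (h in hits) substr(seqchr, h, h + Lm - 1) <- random_dna(Lm, g$gc_fraction)
    }
  }

  genome <- Biostrings::DNAStringSet(stats::setNames(seqchr, chrom))

  # per-gene ground truth
  k4 <- ifelse(is_target, stats::runif(n_genes) < ge$p_k4_target,
               stats::runif(n_genes) < ge$p_k4_nontarget)
  k27 <- ifelse(is_target, stats::runif(n_genes) < ge$p_k27_target,
                stats::runif(n_genes) < ge$p_k27_nontarget)
  lr <- log(ge$baseline_mean_range)
  baseline <- exp(stats::runif(n_genes, lr[1], lr[2]))
  baseline[is_target] <- baseline[is_target] * ge$target_repression
  dk4 <- ifelse(is_target & k4,
                stats::runif(n_genes, ch$delta_k4_range[1], ch$delta_k4_range[2]), 0)
  dk9ac <- ifelse(is_target,
                  stats::runif(n_genes, ch$delta_k9ac_range[1], ch$delta_k9ac_range[2]), 0)
  dk9me2 <- ifelse(is_target,
                   -stats::runif(n_genes, ch$delta_k9me2_range[1], ch$delta_k9me2_range[2]), 0)
  genes <- data.frame(
    gene = gene_ids, chrom = chrom, tss = tss_pos,
    rest_target = is_target, region_class = region_class,
    k4_marked = k4, k27_marked = k27,
    baseline_mean = baseline,
    delta_k4 = dk4, delta_k9ac = dk9ac, delta_k9me2 = dk9me2,
    stringsAsFactors = FALSE
  )

  # H3K27me3 domains: at promoters of k27-marked genes plus intergenic ones
  dw <- ch$k27_domain_width
  dom_center <- tss_pos[k27]
  gaps <- setdiff(seq_len(n_genes), which(k27))
  inter <- sample(gaps, min(ch$n_k27_intergenic, length(gaps)))
  dom_center <- c(dom_center, tss_pos[inter] + spacing %/% 2)
  dom_gene <- c(gene_ids[k27], rep(NA_character_, length(inter)))
  dom_start <- pmax(0L, as.integer(dom_center - dw %/% 2))
  dom_end <- dom_start + dw
  n_dom <- length(dom_start)
  wt_fold <- ch$enrichment_fold[["H3K27me3"]] * 2^stats::rnorm(n_dom, 0, 0.5)
  change <- rep("stable", n_dom)
  # gains/losses planted at domains over REST-target promoters when possible
  target_dom <- which(!is.na(dom_gene) & dom_gene %in% gene_ids[is_target])
  pool <- c(target_dom, setdiff(seq_len(n_dom), target_dom))
  pick <- pool[seq_len(min(ch$n_k27_gain + ch$n_k27_loss, n_dom))]
  change[pick[seq_len(min(ch$n_k27_gain, length(pick)))]] <- "gain"
  if (length(pick) > ch$n_k27_gain) {
    change[pick[(ch$n_k27_gain + 1):length(pick)]] <- "loss"
  }
  k27_domains <- data.frame(
    chrom = chrom, start = dom_start, end = dom_end, gene = dom_gene,
    wt_fold = wt_fold, change = change, stringsAsFactors = FALSE
  )

  tss <- intervals(chrom, tss_pos, tss_pos + 1L, name = gene_ids)
  regions <- intervals(chrom, reg_start, reg_end, name = reg_name,
                       score = NA_real_, strand = "*")
  structure(list(
    genome = genome,
    tss = tss,
    regions = regions,
    region_truth = data.frame(region = reg_name, class = reg_class,
                              strand = reg_strand, stringsAsFactors = FALSE),
    motif_sites = intervals(chrom, site_start, site_end,
                            name = site_region, strand = site_strand),
    motif_kind = site_kind,
    genes = genes,
    k27_domains = k27_domains,
    config = config
  ), class = "sim_truth")
}

add_enrichment <- function(rate, start, end, bin_size, extra_per_bin) {
  b0 <- start %/% bin_size + 1L
  b1 <- (end - 1L) %/% bin_size + 1L
  idx <- b0:min(b1, length(rate))
  rate[idx] <- rate[idx] + extra_per_bin
  rate
}

#' Simulate ChIP coverage tracks for one genotype
#'
#' Bin counts are Poisson around a flat background plus fold-enrichment
#' at the planted loci. In the knockout: REST enrichment is removed;
#' H3K4me3 and H3K9ac rise at REST-target promoters by each gene's true
#' delta; H3K9me2 falls; H3K27me3 is unchanged except at the designated
#' gain/loss domains, whose knockout enrichment is scaled by
#' 2^(+/- k27_change_log2fc x rest_dependence_k27). Input and H3 tracks
#' are genotype-invariant up to noise.
#'
#' @param truth a `sim_truth` from [simulate_genome()].
#' @param genotype "WT" or "KO".
#' @param seed optional seed override (default derived from the config
#'   seed and genotype).
#' @return named list of `signal_track`s: REST, H3K4me3, H3K9ac,
#'   H3K9me2, H3K27me3, H3, input.
#' @export
simulate_chip_tracks <- function(truth, genotype = c("WT", "KO"), seed = NULL) {
  genotype <- match.arg(genotype)
  cfg <- truth$config; ch <- cfg$chip
  if (is.null(seed)) seed <- cfg$seed + if (genotype == "WT") 104729 else 224737
  set.seed(seed)
  bs <- ch$bin_size
  clen <- Biostrings::width(truth$genome)[[1]]
  nb <- clen %/% bs
  bg <- ch$background_rate
  genes <- truth$genes
  pw <- cfg$genes$promoter_halfwidth
  ko <- genotype == "KO"

  base_rate <- function() rep(bg, nb)
  rates <- list()

  # REST: enrichment at bound regions, class-dependent height, WT only
  r <- base_rate()
  if (!ko) {
    rt <- truth$region_truth
    for (i in seq_len(nrow(truth$regions))) {
      mult <- switch(rt$class[i],
        MULTI_FULL_SAME_STRAND = ch$multi_boost * ch$enrichment_fold[["REST"]],
        SINGLE_FULL = ch$enrichment_fold[["REST"]],
        HALF_ONLY = ch$half_site_fold * ch$enrichment_fold[["REST"]])
      r <- add_enrichment(r, truth$regions$start[i], truth$regions$end[i],
                          bs, bg * (mult - 1))
    }
  }
  rates$REST <- r

  # H3K4me3 and H3K9ac at promoters; H3K9me2 at REST regions
  r4 <- base_rate(); r9ac <- base_rate(); r9me2 <- base_rate()
  f4 <- ch$enrichment_fold[["H3K4me3"]]
  f9ac <- ch$enrichment_fold[["H3K9ac"]]
  f9me2 <- ch$enrichment_fold[["H3K9me2"]]
  for (i in seq_len(nrow(genes))) {
    p0 <- max(0, genes$tss[i] - pw); p1 <- genes$tss[i] + pw
    if (genes$k4_marked[i]) {
      fold <- f4 * if (ko) 2^genes$delta_k4[i] else 1
      r4 <- add_enrichment(r4, p0, p1, bs, bg * (fold - 1))
    }
    if (genes$rest_target[i]) {
      fold <- f9ac * if (ko) 2^genes$delta_k9ac[i] else 1
      r9ac <- add_enrichment(r9ac, p0, p1, bs, bg * (fold - 1))
      fold2 <- f9me2 * if (ko) 2^genes$delta_k9me2[i] else 1
      r9me2 <- add_enrichment(r9me2, p0, p1, bs, bg * (fold2 - 1))
    }
  }
  rates$H3K4me3 <- r4; rates$H3K9ac <- r9ac; rates$H3K9me2 <- r9me2

  # H3K27me3 domains with per-domain WT fold; KO scales gains/losses
  r27 <- base_rate()
  kd <- truth$k27_domains
  eff <- ch$k27_change_log2fc * ch$rest_dependence_k27
  for (i in seq_len(nrow(kd))) {
    fold <- kd$wt_fold[i]
    if (ko && kd$change[i] == "gain") fold <- fold * 2^eff
    if (ko && kd$change[i] == "loss") fold <- fold * 2^(-eff)
    r27 <- add_enrichment(r27, kd$start[i], kd$end[i], bs, bg * (fold - 1))
  }
  rates$H3K27me3 <- r27

  rates$H3 <- rep(bg * ch$h3_fold, nb)
  rates$input <- rep(bg, nb)

  lapply(rates, function(rt) {
    signal_track(list(chr1 = stats::rpois(nb, rt)), bs)
  })
}

#' Simulate an expression count table for one genotype
#'
#' Negative-binomial counts around each gene's baseline mean; in the
#' knockout, REST-target means are multiplied by
#' 2^(beta x delta_K4 + N(0, noise_sd)), non-targets unchanged.
#'
#' @param truth a `sim_truth`.
#' @param genotype "WT" or "KO".
#' @param seed optional seed override.
#' @return genes x replicates integer matrix (rownames = gene ids).
#' @export
simulate_expression_counts <- function(truth, genotype = c("WT", "KO"),
                                       seed = NULL) {
  genotype <- match.arg(genotype)
  cfg <- truth$config; ex <- cfg$expression
  if (is.null(seed)) seed <- cfg$seed + if (genotype == "WT") 15485863 else 32452843
  set.seed(seed)
  genes <- truth$genes
  mu <- genes$baseline_mean
  if (genotype == "KO") {
    shift <- ex$beta * genes$delta_k4 +
      stats::rnorm(nrow(genes), 0, ex$noise_sd) * genes$rest_target
    mu <- mu * ifelse(genes$rest_target, 2^shift, 1)
  }
  size <- 1 / ex$dispersion
  counts <- vapply(seq_len(ex$n_reps), function(j) {
    stats::rnbinom(length(mu), mu = mu, size = size)
  }, numeric(length(mu)))
  rownames(counts) <- genes$gene
  colnames(counts) <- sprintf("%s_rep%d", genotype, seq_len(ex$n_reps))
  storage.mode(counts) <- "integer"
  counts
}

#' Simulate a qPCR plate with known fold changes
#'
#' Ct = base − log2(expression) + N(0, ct_noise); the reference gene has
#' fold change 1 between conditions by construction.
#'
#' @param config a `sim_config`.
#' @return list: `ct` data.frame (gene, condition, replicate, ct),
#'   `true_fold` named vector, `reference` the reference gene id.
#' @export
simulate_qpcr_plate <- function(config = sim_config()) {
  qp <- config$qpcr
  stopifnot(qp$replicates >= 2)
  set.seed(config$seed + 49979687)
  genes <- c("ref", sprintf("goi%d", seq_len(qp$n_genes)))
  lfr <- log2(qp$fold_range)
  folds <- c(1, 2^stats::runif(qp$n_genes, lfr[1], lfr[2]))
  names(folds) <- genes
  rows <- list()
  for (i in seq_along(genes)) {
    for (cond in c("control", "test")) {
      expr <- if (cond == "test") folds[i] else 1
      ct <- qp$base_ct - log2(expr) +
        stats::rnorm(qp$replicates, 0, qp$ct_noise_sd)
      rows[[length(rows) + 1]] <- data.frame(
        gene = genes[i], condition = cond,
        replicate = seq_len(qp$replicates), ct = ct,
        stringsAsFactors = FALSE)
    }
  }
  list(ct = do.call(rbind, rows), true_fold = folds, reference = "ref")
}

#' Simulate a pull-down peptide table with known retained set
#'
#' True co-factors are detected with high probability in the bait
#' purifications (>= 2 unique peptides when detected) and essentially
#' never in the controls; contaminants appear sporadically in both.
#'
#' @param config a `sim_config`.
#' @return list: `counts` proteins x samples matrix, `bait_cols`,
#'   `control_cols`, `true_retained` character vector of co-factor ids.
#' @export
simulate_peptide_table <- function(config = sim_config()) {
  pp <- config$peptides
  stopifnot(pp$n_bait >= 1, pp$n_control >= 1)
  set.seed(config$seed + 86028121)
  prots <- c(sprintf("cofactor%02d", seq_len(pp$n_cofactors)),
             sprintf("contam%02d", seq_len(pp$n_contaminants)))
  n <- length(prots)
  bait <- matrix(0L, n, pp$n_bait)
  ctrl <- matrix(0L, n, pp$n_control)
  for (i in seq_len(pp$n_cofactors)) {
    det <- stats::runif(pp$n_bait) < pp$p_detect_cofactor_bait
    bait[i, det] <- 2L + stats::rpois(sum(det), pp$cofactor_peptides)
    detc <- stats::runif(pp$n_control) < pp$p_detect_cofactor_control
    ctrl[i, detc] <- 1L
  }
  for (i in pp$n_cofactors + seq_len(pp$n_contaminants)) {
    det <- stats::runif(pp$n_bait) < pp$p_detect_contaminant
    bait[i, det] <- 1L + stats::rpois(sum(det), pp$contaminant_peptides)
    detc <- stats::runif(pp$n_control) < pp$p_detect_contaminant
    ctrl[i, detc] <- 1L + stats::rpois(sum(detc), pp$contaminant_peptides)
  }
  counts <- cbind(bait, ctrl)
  rownames(counts) <- prots
  colnames(counts) <- c(sprintf("bait%d", seq_len(pp$n_bait)),
                        sprintf("control%d", seq_len(pp$n_control)))
  list(counts = counts,
       bait_cols = colnames(counts)[seq_len(pp$n_bait)],
       control_cols = colnames(counts)[pp$n_bait + seq_len(pp$n_control)],
       true_retained = prots[seq_len(pp$n_cofactors)])
}
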