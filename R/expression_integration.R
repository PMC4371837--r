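#' Integration of expression changes with chromatin-mark changes
#'
#' Library-normalized fold changes, correlation of per-gene deltas,
#' multiple regression of expression changes on chromatin-mark changes,
#' and per-promoter-class de-repression comparisons.
#'
#' @name expression_integration
NULL

#' Per-gene log2 fold change from count tables
#'
#' log2((cpm_B_mean + pc) / (cpm_A_mean + pc)) with cpm = counts per
#' million of the column's library. Replaces a full NB differential
#' model with a simple normalized fold change.
#'
#' @param counts_A,counts_B numeric matrices (genes x replicates) with
#'   the same rownames (gene ids).
#' @param pseudocount added to both cpm means (default 0.5).
#' @return named numeric vector of log2 fold changes (B vs A).
#' @export
log_fold_change <- function(counts_A, counts_B, pseudocount = 0.5) {
  counts_A <- as.matrix(counts_A); counts_B <- as.matrix(counts_B)
  if (!identical(rownames(counts_A), rownames(counts_B))) {
    missing <- union(setdiff(rownames(counts_A), rownames(counts_B)),
                     setdiff(rownames(counts_B), rownames(counts_A)))
    if (length(missing)) stop("gene(s) missing in one table: ",
                              paste(utils::head(missing, 5), collapse = ", "))
    counts_B <- counts_B[rownames(counts_A), , drop = FALSE]
  }
  lib_A <- colSums(counts_A); lib_B <- colSums(counts_B)
  if (any(lib_A == 0) || any(lib_B == 0)) stop("zero library size")
  cpm_A <- rowMeans(sweep(counts_A, 2, lib_A, "/") * 1e6)
  cpm_B <- rowMeans(sweep(counts_B, 2, lib_B, "/") * 1e6)
  log2((cpm_B + pseudocount) / (cpm_A + pseudocount))
}

#' Mean log2 cpm per gene (for absolute-expression comparisons)
#' @param counts genes x replicates matrix.
#' @param pseudocount added before the log (default 0.5).
#' @export
mean_log_cpm <- function(counts, pseudocount = 0.5) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  log2(rowMeans(sweep(counts, 2, lib, "/") * 1e6) + pseudocount)
}

#' Correlate two per-gene delta vectors
#'
#' Pearson r, R-squared and the two-sided p-value from the t transform
#' of r (n - 2 degrees of freedom).
#'
#' @param x,y paired finite numeric vectors, n >= 3.
#' @return list: r, r_squared, p, n.
#' @export
correlate_deltas <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  stopifnot(length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p = ct$p.value, n = length(x))
}

#' Multiple regression of expression changes on chromatin-mark changes
#'
#' Ordinary least squares of per-gene log2 expression fold change on the
#' selected mark deltas, with intercept and per-coefficient t tests.
#'
#' @param deltas data.frame of per-gene mark deltas (columns named by
#'   mark, e.g. dK4, dK27, dK9ac, dK9me2).
#' @param log2fc numeric vector of expression log2 fold changes, same
#'   gene order.
#' @param predictors character vector of delta column names to include
#'   (default all).
#' @param standardize z-score the predictors first (default FALSE).
#' @return list of class `mark_regression`: coefficients table
#'   (estimate, std_error, t, p, ci_lo, ci_hi), r_squared, n, fit (the
#'   underlying lm).
#' @export
regress_mark_deltas <- function(deltas, log2fc, predictors = NULL,
                                standardize = FALSE) {
  if (is.null(predictors)) predictors <- names(deltas)
  X <- as.data.frame(deltas)[, predictors, drop = FALSE]
  if (standardize) X[] <- lapply(X, function(v) (v - mean(v)) / stats::sd(v))
  stopifnot(length(log2fc) == nrow(X))
  if (nrow(X) < length(predictors) + 2) stop("too few genes for regression")
  cc <- suppressWarnings(stats::cor(X))
  diag(cc) <- 0
  if (any(abs(cc) > 1 - 1e-12, na.rm = TRUE)) stop("collinear predictors")
  dat <- cbind(log2fc = log2fc, X)
  fit <- stats::lm(log2fc ~ ., data = dat)
  sm <- summary(fit)
  ci <- stats::confint(fit, level = 0.95)
  coefs <- data.frame(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, 1],
    std_error = sm$coefficients[, 2],
    t = sm$coefficients[, 3],
    p = sm$coefficients[, 4],
    ci_lo = ci[, 1], ci_hi = ci[, 2],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(coefficients = coefs, r_squared = sm$r.squared,
                 n = nrow(X), fit = fit),
            class = "mark_regression")
}

#' @export
print.mark_regression <- function(x, ...) {
  cat(sprintf("OLS of expression log2FC on mark deltas (n = %d, R^2 = %.3f)\n",
              x$n, x$r_squared))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Compare expression between conditions across promoter/target classes
#'
#' Genes are grouped by REST-target status crossed with promoter class;
#' per group, the mean log2 cpm in each condition, the within-group
#' condition difference with a two-sample test (Welch by default), and
#' the between-group contrast against the matched non-target group are
#' reported. Groups with fewer than 3 genes are reported untested.
#'
#' @param genes data.frame with columns `gene`, `rest_target` (logical),
#'   `promoter_class`.
#' @param counts_A,counts_B genes x replicates count matrices (rownames
#'   = gene ids), conditions A (e.g. WT) and B (e.g. KO).
#' @param pooled use the classic pooled-variance t test instead of
#'   Welch (default FALSE).
#' @return data.frame, one row per group: n, mean_A, mean_B, diff,
#'   t, p; plus attribute "between" with the target-vs-nontarget
#'   contrasts per promoter class.
#' @export
compare_class_expression <- function(genes, counts_A, counts_B,
                                     pooled = FALSE) {
  stopifnot(nrow(genes) > 0)
  la <- mean_log_cpm(counts_A)[genes$gene]
  lb <- mean_log_cpm(counts_B)[genes$gene]
  grp <- interaction(ifelse(genes$rest_target, "target", "nontarget"),
                     genes$promoter_class, sep = ":", drop = TRUE)
  rows <- lapply(levels(grp), function(g) {
    i <- which(grp == g)
    n <- length(i)
    if (n >= 3) {
      tt <- welch_t_test(lb[i], la[i], pooled = pooled, paired = TRUE)
      t <- tt$t; p <- tt$p
    } else {
      t <- NA_real_; p <- NA_real_
    }
    data.frame(group = g, n = n, mean_A = mean(la[i]), mean_B = mean(lb[i]),
               diff = mean(lb[i] - la[i]), t = t, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  classes <- unique(genes$promoter_class)
  btw <- lapply(classes, function(cl) {
    ti <- which(genes$rest_target & genes$promoter_class == cl)
    ni <- which(!genes$rest_target & genes$promoter_class == cl)
    if (length(ti) >= 3 && length(ni) >= 3) {
      tt <- welch_t_test(la[ti], la[ni], pooled = pooled)
      data.frame(promoter_class = cl, n_target = length(ti),
                 n_nontarget = length(ni),
                 diff = mean(la[ti]) - mean(la[ni]), t = tt$t, p = tt$p,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(promoter_class = cl, n_target = length(ti),
                 n_nontarget = length(ni),
                 diff = mean(la[ti]) - mean(la[ni]),
                 t = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
    }
  })
  attr(res, "between") <- do.call(rbind, btw)
  res
}
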