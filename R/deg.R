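#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes of the
#' ratio of the sample's count to the gene's geometric mean across
#' samples, computed over genes with non-zero counts in every sample,
#' then rescaled so the factors have geometric mean 1.
#'
#' @param counts gene-by-sample matrix of raw counts.
#' @return named numeric vector of per-sample size factors.
#' @export
sizeFactorsMOR <- function(counts) {
  counts <- as.matrix(counts)
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok))
    stop("no gene has non-zero counts in all samples; ",
         "median-of-ratios undefined (consider a pseudo-reference)")
  lg <- log(counts[ok, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- apply(lg, 2, function(col) exp(median(col - ref)))
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(counts))
}

#' Method-of-moments per-gene NB dispersion
#'
#' Within-group method of moments on normalised counts, with no
#' shrinkage.  Under `Var = mu + alpha * mu^2` the within-group variance
#' of group `g` has expectation `mu_g + alpha * mu_g^2`, so pooling over
#' groups (each weighted by its residual degrees of freedom) gives
#' `alpha = max((pooled variance - pooled mean) / pooled mean-square,
#' floor)`, where the pooled mean and mean-square average the group
#' means and squared group means with the same weights.  Using the
#' squared group means (rather than the square of the grand mean) keeps
#' the estimator unbiased for genes whose groups genuinely differ.
#'
#' @param normCounts gene-by-sample matrix of normalised counts.
#' @param groups factor of group membership (>= 2 replicates each).
#' @param floor lower bound for alpha (default `1e-8`).
#' @return numeric vector of per-gene dispersions.
#' @export
estimateDispersion <- function(normCounts, groups, floor = 1e-8) {
  normCounts <- as.matrix(normCounts)
  groups <- droplevels(as.factor(groups))
  tb <- table(groups)
  if (any(tb < 2L)) stop("every group needs >= 2 replicates")
  num <- 0; m1 <- 0; m2 <- 0; den <- 0
  for (g in levels(groups)) {
    sub <- normCounts[, groups == g, drop = FALSE]
    w <- ncol(sub) - 1L
    mu <- rowMeans(sub)
    num <- num + apply(sub, 1, var) * w
    m1 <- m1 + mu * w
    m2 <- m2 + mu^2 * w
    den <- den + w
  }
  poolVar <- num / den
  m1 <- m1 / den
  m2 <- m2 / den
  alpha <- ifelse(m2 > 0, (poolVar - m1) / m2, floor)
  pmax(alpha, floor)
}

#' Negative-binomial Wald test for drought vs control
#'
#' Per gene: group means are taken on the normalised scale with a
#' pseudo-count of 0.5; the log2 fold change is
#' `log2(mean_drought / mean_control)`; its standard error follows from
#' the delta method under `Var = mu + alpha * mu^2` with the group's
#' replicate count; the Wald statistic is referred to a t distribution
#' with the residual degrees of freedom (sum of replicates minus 2) —
#' at typical 3 + 3 designs this keeps the test calibrated where a
#' normal reference is anti-conservative.  Verdicts apply the screening
#' thresholds strictly: `up` requires `p < pThreshold` and
#' `log2fc > lfcThreshold`; `down` the mirror image.
#'
#' @param counts gene-by-sample matrix of raw counts, or a
#'   `SummarizedExperiment` with assay `counts` and `colData$group`.
#' @param groups factor with two levels; ignored when `counts` is a
#'   `SummarizedExperiment`.
#' @param numerator,denominator group labels of the contrast (positive
#'   log2 fold change = higher in `numerator`).
#' @param sizeFactors optional per-sample factors; defaults to
#'   [sizeFactorsMOR()].
#' @param alphas optional per-gene dispersions; defaults to
#'   [estimateDispersion()].
#' @param pThreshold,lfcThreshold screening thresholds used for the
#'   verdict column.
#' @return data.frame: `gene_id`, `baseMean`, `log2fc`, `se`, `stat`,
#'   `pvalue`, `verdict` (`up` / `down` / `not_significant`).
#' @export
waldTest <- function(counts, groups = NULL, numerator = "drought",
                     denominator = "control", sizeFactors = NULL,
                     alphas = NULL, pThreshold = 0.05,
                     lfcThreshold = 1) {
  if (is(counts, "SummarizedExperiment")) {
    groups <- counts$group
    counts <- SummarizedExperiment::assay(counts, "counts")
  }
  counts <- as.matrix(counts)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L)
    stop("exactly two groups required, got: ",
         paste(levels(groups), collapse = ", "))
  if (!all(c(numerator, denominator) %in% levels(groups)))
    stop("groups must contain '", numerator, "' and '", denominator, "'")
  if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMOR(counts)
  norm <- sweep(counts, 2, sizeFactors, "/")
  if (is.null(alphas)) alphas <- estimateDispersion(norm, groups)
  nD <- sum(groups == numerator)
  nC <- sum(groups == denominator)
  muD <- rowMeans(norm[, groups == numerator, drop = FALSE]) + 0.5
  muC <- rowMeans(norm[, groups == denominator, drop = FALSE]) + 0.5
  lfc <- log2(muD / muC)
  se <- sqrt(((1 / muD + alphas) / nD + (1 / muC + alphas) / nC)) /
    log(2)
  stat <- lfc / se
  pv <- 2 * pt(-abs(stat), df = nD + nC - 2L)
  verdict <- rep("not_significant", length(lfc))
  verdict[pv < pThreshold & lfc > lfcThreshold] <- "up"
  verdict[pv < pThreshold & lfc < -lfcThreshold] <- "down"
  data.frame(gene_id = rownames(counts),
             baseMean = rowMeans(norm),
             log2fc = lfc, se = se, stat = stat, pvalue = pv,
             verdict = verdict, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Screen differentially expressed genes
#'
#' Applies the screening criteria strictly (`p < pThreshold` and
#' `|log2fc| > lfcThreshold`; boundary values are excluded) and returns
#' the up- and down-regulated lists sorted by p-value, ties broken by
#' larger |log2 fold change|.
#'
#' @param results data.frame from [waldTest()].
#' @param pThreshold p-value cutoff (default 0.05).
#' @param lfcThreshold |log2 fold change| cutoff (default 1).
#' @param adjust apply Benjamini-Hochberg adjustment before screening
#'   (off by default: the screen uses raw p-values).
#' @return list with data.frames `up` and `down`.
#' @export
screenDegs <- function(results, pThreshold = 0.05, lfcThreshold = 1,
                       adjust = FALSE) {
  p <- if (adjust) p.adjust(results$pvalue, "BH") else results$pvalue
  keep <- function(side) {
    sel <- p < pThreshold & side
    df <- results[sel, , drop = FALSE]
    df <- df[order(df$pvalue, -abs(df$log2fc)), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  list(up = keep(results$log2fc > lfcThreshold),
       down = keep(results$log2fc < -lfcThreshold))
}

#' Write DE results as TSV
#'
#' @param results data.frame from [waldTest()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDeResults <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
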