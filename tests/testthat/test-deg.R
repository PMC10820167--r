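test_that("median-of-ratios size factors match closed forms", {
  set.seed(2)
  base <- matrix(rpois(200, 100), 50, 4)
  same <- cbind(base[, 1], base[, 1], base[, 1])
  expect_equal(unname(sizeFactorsMOR(same)), rep(1, 3))

  two <- cbind(s1 = base[, 1] * 2L, s2 = base[, 1] * 4L)
  sf <- sizeFactorsMOR(two)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))

  m <- base; colnames(m) <- paste0("s", 1:4)
  perm <- c(3, 1, 4, 2)
  expect_equal(sizeFactorsMOR(m[, perm]), sizeFactorsMOR(m)[perm])

  allz <- rbind(c(0L, 5L), c(4L, 0L))
  expect_error(sizeFactorsMOR(allz), "pseudo-reference")
})

test_that("size factors agree with the reference median-of-ratios oracle", {
  sim <- generateCounts(countSpec(nGenes = 500, seed = 33))
  mat <- SummarizedExperiment::assay(sim$se)
  mat[, 2] <- mat[, 2] * 3L  # introduce a depth difference
  sf <- sizeFactorsMOR(mat)
  ref <- DESeq2::estimateSizeFactorsForMatrix(mat)
  ref <- ref / exp(mean(log(ref)))  # same geometric-mean-1 convention
  expect_equal(unname(sf), unname(ref), tolerance = 1e-8)
})

test_that("normalisation honesty: rescaling one sample leaves normalised counts fixed", {
  sim <- generateCounts(countSpec(nGenes = 300, seed = 11))
  mat <- SummarizedExperiment::assay(sim$se)
  norm1 <- sweep(mat, 2, sizeFactorsMOR(mat), "/")
  mat2 <- mat; mat2[, 1] <- mat2[, 1] * 5L
  norm2 <- sweep(mat2, 2, sizeFactorsMOR(mat2), "/")
  # ratios between samples are restored up to the global rescaling
  r1 <- norm1 / norm1[, 1]
  r2 <- norm2 / norm2[, 1]
  expect_equal(r1[is.finite(r1)], r2[is.finite(r2)], tolerance = 1e-8)
})

test_that("dispersion estimation hits the floor and the simulated alpha", {
  grp <- factor(rep(c("drought", "control"), each = 3),
                levels = c("drought", "control"))
  const <- matrix(7, 10, 6)
  expect_true(all(estimateDispersion(const, grp) == 1e-8))

  set.seed(13)
  pois <- matrix(rpois(2000 * 6, 200), 2000, 6)
  aP <- estimateDispersion(pois, grp)
  expect_lt(median(aP), 0.01)

  nb <- matrix(rnbinom(2000 * 6, mu = 200, size = 10), 2000, 6)
  aN <- estimateDispersion(nb, grp)
  expect_equal(median(aN), 0.1, tolerance = 0.25)
})

test_that("Wald test symmetries and degenerate cases", {
  sim <- generateCounts(countSpec(nGenes = 300, deFraction = 0.3,
                                  seed = 17))
  se <- sim$se
  res <- waldTest(se)
  expect_true(all(res$pvalue >= 0 & res$pvalue <= 1))
  expect_true(all(res$verdict %in% c("up", "down", "not_significant")))
  expect_true(all(res$log2fc[res$verdict == "up"] > 1))
  expect_true(all(res$pvalue[res$verdict != "not_significant"] < 0.05))

  # swapping the contrast negates fold changes, preserves p-values
  swap <- waldTest(se, numerator = "control", denominator = "drought")
  expect_equal(swap$log2fc, -res$log2fc)
  expect_equal(swap$pvalue, res$pvalue)

  # identical groups: zero fold change, p = 1
  mat <- SummarizedExperiment::assay(se)
  dup <- cbind(mat[, 1:3], mat[, 1:3])
  colnames(dup) <- c(paste0("d", 1:3), paste0("c", 1:3))
  grp <- factor(rep(c("drought", "control"), each = 3),
                levels = c("drought", "control"))
  same <- waldTest(dup, grp)
  expect_true(all(same$log2fc == 0))
  expect_true(all(same$pvalue == 1))
  expect_true(all(same$verdict == "not_significant"))

  # all-zero genes never divide by zero
  mat[1, ] <- 0L
  res0 <- waldTest(mat, grp)
  expect_true(is.finite(res0$log2fc[1]) && is.finite(res0$pvalue[1]))
})

test_that("screening applies strict inequalities and the sort order", {
  res <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    baseMean = 100, log2fc = c(1.2, 1.0, -2, 1.5, 2.5),
    se = 1, stat = 1,
    pvalue = c(0.04, 0.01, 0.02, 0.05, 0.04),
    verdict = "x", stringsAsFactors = FALSE)
  out <- screenDegs(res)
  expect_equal(out$up$gene_id, c("g5", "g1"))   # g2 lfc==1, g4 p==0.05 out
  expect_equal(out$down$gene_id, "g3")

  tie <- res[res$gene_id %in% c("g1", "g5"), ]
  out2 <- screenDegs(tie)
  expect_equal(out2$up$log2fc[1], 2.5)  # tie on p -> larger |lfc| first
})
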