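test_that("proteome generation is byte-identical under a fixed seed", {
  sp <- proteomeSpec(nGenes = 50, seed = 7)
  a <- generateProteome(sp)
  b <- generateProteome(sp)
  expect_identical(a$records, b$records)
  expect_identical(a$gff, b$gff)
  expect_identical(a$truth, b$truth)
})

test_that("an all-decoy mix plants nothing and the scanner finds nothing", {
  sp <- proteomeSpec(nGenes = 40,
                     architectureMix = c(`0` = 1, `1` = 0, `2` = 0,
                                         `3` = 0, `4` = 0, `5` = 0),
                     seed = 3)
  pt <- generateProteome(sp)
  expect_true(all(pt$truth$n_repeats == 0))
  hits <- scanProteome(calibratedProfile(), pt$records)
  expect_lte(nrow(hits), 1L)  # at most a stray false positive
})

test_that("truth labels are what the classifier derives from truth intervals", {
  sp <- proteomeSpec(nGenes = 120, seed = 23)
  pt <- generateProteome(sp)
  members <- pt$truth[!is.na(pt$truth$expected_subfamily), ]
  relabel <- vapply(seq_len(nrow(members)), function(i) {
    iv <- do.call(rbind, lapply(
      strsplit(strsplit(members$intervals[i], ";")[[1]], "-"),
      as.integer))
    flags <- strsplit(members$trp_flags[i], ";")[[1]] == "1"
    assignSubfamily(iv[, 1], iv[, 2], flags, sp$spacingThreshold)
  }, character(1))
  expect_equal(relabel, members$expected_subfamily)
})

test_that("planted intervals respect spacing constraints and split flags", {
  sp <- proteomeSpec(nGenes = 150, twoRepeatGapSplit = 0.5, seed = 19)
  pt <- generateProteome(sp)
  multi <- pt$truth[pt$truth$n_repeats >= 2, ]
  for (i in seq_len(nrow(multi))) {
    iv <- do.call(rbind, lapply(
      strsplit(strsplit(multi$intervals[i], ";")[[1]], "-"), as.integer))
    gaps <- iv[-1, 1] - iv[-nrow(iv), 2] - 1L
    expect_true(all(iv[-1, 1] > iv[-nrow(iv), 2]))  # no overlap
    if (multi$n_repeats[i] == 2 && multi$split[i]) {
      expect_gt(gaps[1], sp$spacingThreshold)
    } else {
      expect_true(all(gaps >= sp$spacerRange[1] &
                      gaps <= sp$spacerRange[2]))
    }
  }
  # split genes exist at this fraction and are labelled R-R type
  split2 <- multi[multi$n_repeats == 2 & multi$split, ]
  expect_gt(nrow(split2), 0)
  expect_true(all(split2$expected_subfamily == "1R-RR" |
                  is.na(split2$expected_subfamily)))
})

test_that("count generation is reproducible and honours deFraction", {
  cs <- countSpec(nGenes = 100, seed = 5)
  a <- generateCounts(cs)
  b <- generateCounts(cs)
  expect_identical(SummarizedExperiment::assay(a$se),
                   SummarizedExperiment::assay(b$se))
  expect_identical(a$truth, b$truth)

  none <- generateCounts(countSpec(nGenes = 100, deFraction = 0, seed = 5))
  expect_true(all(none$truth$true_lfc == 0))
})

test_that("the dispersion limit recovers Poisson moments", {
  cs <- countSpec(nGenes = 400, replicates = c(50L, 50L), dispersion = 0,
                  deFraction = 0, baselineMeanlog = log(100),
                  baselineSdlog = 0.3, seed = 9)
  sim <- generateCounts(cs)
  mat <- SummarizedExperiment::assay(sim$se)
  ratio <- apply(mat, 1, var) / rowMeans(mat)
  # variance/mean ratio concentrates near 1 in the Poisson limit
  expect_equal(median(ratio), 1, tolerance = 0.1)
})

test_that("per-gene empirical means converge to specified means", {
  cs <- countSpec(nGenes = 50, replicates = c(2000L, 2000L),
                  dispersion = 0.1, deFraction = 0.3, seed = 41)
  sim <- generateCounts(cs)
  mat <- SummarizedExperiment::assay(sim$se)
  ctrl <- mat[, sim$sheet$group == "control", drop = FALSE]
  mu <- sim$truth$baseline_mean
  se <- sqrt((mu + 0.1 * mu^2) / ncol(ctrl))
  z <- abs(rowMeans(ctrl) - mu) / se
  expect_gte(mean(z <= 3), 0.95)
  drought <- mat[, sim$sheet$group == "drought", drop = FALSE]
  muD <- mu * 2^sim$truth$true_lfc
  seD <- sqrt((muD + 0.1 * muD^2) / ncol(drought))
  expect_gte(mean(abs(rowMeans(drought) - muD) / seD <= 3), 0.95)
})
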