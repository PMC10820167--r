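test_that("profile construction finds the forced tryptophan columns", {
  prof <- mybProfile()
  expect_s4_class(prof, "MybProfile")
  expect_equal(profileLength(prof), 52L)
  expect_equal(trpColumns(prof), c(9L, 28L, 47L))
  expect_true(all(diff(trpColumns(prof)) >= 15))
})

test_that("profile construction rejects degenerate alignments", {
  set.seed(2)
  aa <- setdiff(rownames(mybProfile()@scores), "X")
  rand <- vapply(1:25, function(i)
    paste(sample(aa, 52, TRUE), collapse = ""), character(1))
  expect_error(buildProfile(rand), "tryptophan-enriched")

  short <- substr(rand, 1, 40)
  expect_error(buildProfile(short), "outside")
})

test_that("column log-odds match the pseudocount formula by hand", {
  # 20 sequences; column 5 carries 18 W + 2 A; tryptophans planted at
  # 10/29/48 to satisfy the architecture constraint
  base <- strrep("A", 52)
  seqs <- vapply(1:20, function(i) {
    s <- strsplit(base, "")[[1]]
    s[c(10, 29, 48)] <- "W"
    s[5] <- if (i <= 18) "W" else "A"
    paste(s, collapse = "")
  }, character(1))
  bg <- setNames(rep(1 / 20, 20),
                 rownames(mybProfile()@scores)[1:20])
  prof <- buildProfile(seqs, pseudocount = 1, background = bg)
  handW <- log2(((18 + 1 * 0.05) / (20 + 1)) / 0.05)
  handA <- log2(((2 + 1 * 0.05) / (20 + 1)) / 0.05)
  expect_equal(unname(prof@scores["W", 5]), handW)
  expect_equal(unname(prof@scores["A", 5]), handA)
  # column 5 (90% W) may not outrank the pure-W columns
  expect_equal(sort(trpColumns(prof)), c(10L, 29L, 48L))
})

test_that("window scoring: consensus maximises, X scores zero, brute force agrees", {
  prof <- mybProfile()
  cons <- consensusSeq(prof)
  expect_equal(scoreWindow(prof, cons), maxScore(prof))
  expect_equal(scoreWindow(prof, strrep("X", 52)), 0)

  set.seed(6)
  aa <- rownames(prof@scores)[1:20]
  win <- paste(sample(aa, 52, TRUE), collapse = "")
  brute <- sum(vapply(1:52, function(j)
    prof@scores[substr(win, j, j), j], numeric(1)))
  expect_equal(scoreWindow(prof, win), brute)

  expect_error(scoreWindow(prof, win, offset = 2), "out of range")
})

test_that("E-value calibration matches the empirical null tail", {
  prof <- calibratedProfile()
  nNull <- length(prof@nullScores)
  # at the median null score the E-value over nNull windows is ~nNull/2
  med <- median(prof@nullScores)
  expect_equal(evalueOf(prof, med, nNull), nNull / 2,
               tolerance = 0.10)
  # empirical-tail agreement at probes inside the calibrated region
  for (p in c(0.10, 0.02, 0.005)) {
    s <- quantile(prof@nullScores, 1 - p)
    expect_equal(unname(evalueOf(prof, s, nNull)), p * nNull,
                 tolerance = 0.30)
  }
})

test_that("E-values are monotone and scale linearly with database size", {
  prof <- calibratedProfile()
  ss <- seq(min(prof@nullScores) - 5, max(prof@nullScores) + 40,
            length.out = 200)
  ev <- evalueOf(prof, ss, 1e4)
  expect_true(all(diff(ev) <= 1e-12))
  expect_equal(evalueOf(prof, ss, 2e4), 2 * ev, tolerance = 1e-12)
})

test_that("scanning skips short records and returns ordered, non-overlapping hits", {
  prof <- calibratedProfile()
  short <- data.frame(raw_id = "s1", clean_id = "s1", species = "x",
                      residues = strrep("A", 40),
                      stringsAsFactors = FALSE)
  expect_identical(nrow(scanProteome(prof, short)), 0L)

  pt <- generateProteome(proteomeSpec(nGenes = 60, seed = 31), prof)
  hits <- scanProteome(prof, pt$records)
  expect_true(nrow(hits) > 0)
  for (tx in unique(hits$transcript)) {
    h <- hits[hits$transcript == tx, ]
    expect_true(all(diff(h$start) > 0))
    if (nrow(h) > 1) expect_true(all(h$start[-1] > h$end[-nrow(h)]))
  }
  # deterministic: no RNG at scan time
  expect_identical(hits, scanProteome(prof, pt$records))
})

test_that("greedy overlap resolution keeps the higher-scoring window", {
  prof <- mybProfile()
  rec <- data.frame(raw_id = "T1", clean_id = "T1", species = "x",
                    residues = paste(rep(consensusSeq(prof), 2),
                                     collapse = ""),
                    stringsAsFactors = FALSE)
  rows <- data.frame(target = c("T1", "T1"), query = "q",
                     cEvalue = c(1e-10, 1e-9), score = c(30, 20),
                     hmmFrom = 1L, hmmTo = 52L,
                     envFrom = c(10L, 40L), envTo = c(61L, 91L))
  out <- hitsFromDomtblout(rows, rec, prof)
  expect_equal(nrow(out), 1L)
  expect_equal(out$score, 30)
  expect_equal(out$start, 10L)
})

test_that("scanner recovers planted repeats on noiseless proteomes", {
  prof <- calibratedProfile()
  sp <- proteomeSpec(nGenes = 120, tryptophanDropout = 0,
                     spacerRange = c(52, 80), splitGapRange = c(53, 80),
                     twoRepeatGapSplit = 0.3, seed = 13)
  pt <- generateProteome(sp, prof)
  hits <- scanProteome(prof, pt$records)
  rec <- recoveredCounts(hits, pt$truth)
  expect_gte(mean(rec == pt$truth$n_repeats), 0.99)
  # recovered envelopes sit exactly on the planted intervals
  gm <- truthGeneMap(pt)
  genes <- classifyGenes(hits, gm, pt$records)
  truthMembers <- pt$truth[!is.na(pt$truth$expected_subfamily), ]
  m <- merge(genes, truthMembers, by = "gene_id")
  expect_equal(m$intervals.x, m$intervals.y)
})

test_that("ingested domain tables reproduce the scanner's classification", {
  prof <- calibratedProfile()
  sp <- proteomeSpec(nGenes = 80, seed = 17)
  pt <- generateProteome(sp, prof)
  hits <- scanProteome(prof, pt$records)
  f <- withr::local_tempfile(fileext = ".domtblout")
  writeDomtblout(hits, f)
  ingested <- hitsFromDomtblout(readDomtblout(f), pt$records, prof)
  gm <- truthGeneMap(pt)
  direct <- classifyGenes(hits, gm, pt$records)
  viaTable <- classifyGenes(ingested, gm, pt$records)
  expect_equal(viaTable$gene_id, direct$gene_id)
  expect_equal(viaTable$subfamily, direct$subfamily)
  expect_equal(viaTable$intervals, direct$intervals)
})
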