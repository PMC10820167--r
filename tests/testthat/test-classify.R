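test_that("conserved-tryptophan rule honours the +/-1 tolerance", {
  prof <- mybProfile()
  L <- profileLength(prof)
  tc <- trpColumns(prof)
  base <- strrep("A", L)
  at <- function(pos) {
    s <- strsplit(base, "")[[1]]; s[pos] <- "W"; paste(s, collapse = "")
  }
  expect_true(hasConservedTryptophan(at(tc[1]), prof))
  expect_false(hasConservedTryptophan(base, prof))
  expect_true(hasConservedTryptophan(at(tc[2] + 1), prof))
  expect_true(hasConservedTryptophan(at(tc[2] - 1), prof))
  expect_false(hasConservedTryptophan(at(tc[2] + 2), prof))
  expect_error(hasConservedTryptophan(strrep("A", L - 1), prof),
               "length")
})

test_that("subfamily assignment follows the repeat-count and spacing rules", {
  ok <- c(TRUE, TRUE)
  # gap = start2 - end1 - 1; boundary gap 10 stays 2R, 11 demotes
  expect_equal(assignSubfamily(c(1, 63), c(52, 114), ok), "2R")
  expect_equal(assignSubfamily(c(1, 64), c(52, 115), ok), "1R-RR")
  expect_equal(assignSubfamily(1, 52, TRUE), "1R")
  mk <- function(n, gap) {
    starts <- 1 + (0:(n - 1)) * (52 + gap)
    list(s = starts, e = starts + 51)
  }
  for (n in 3:5) {
    iv <- mk(n, 5)
    expect_equal(assignSubfamily(iv$s, iv$e, rep(TRUE, n)),
                 c("3R", "4R", "5R")[n - 2])
  }
  iv <- mk(6, 5)
  expect_error(assignSubfamily(iv$s, iv$e, rep(TRUE, 6)), "review")
  expect_error(assignSubfamily(c(1, 40), c(52, 91), ok), "overlap")
  expect_error(assignSubfamily(1, 52, FALSE), "tryptophan")
})

test_that("subfamily partition is exhaustive over the gap and count grid", {
  for (gap in 0:30) {
    lab <- assignSubfamily(c(1, 52 + gap + 1), c(52, 52 + gap + 52), c(TRUE, TRUE))
    expect_equal(lab, if (gap <= 10) "2R" else "1R-RR")
  }
  for (n in 1:5) {
    starts <- 1 + (0:(n - 1)) * 60
    lab <- assignSubfamily(starts, starts + 51, rep(TRUE, n))
    expect_true(lab %in% c("1R", "1R-RR", "2R", "3R", "4R", "5R"))
  }
})

test_that("de-duplication keeps the isoform with most repeats, then longest", {
  recs <- data.frame(
    raw_id = c("G1.1", "G1.2", "G2.1", "G3.1", "G3.2"),
    clean_id = c("G1.1", "G1.2", "G2.1", "G3.1", "G3.2"),
    species = "sp",
    residues = c(strrep("A", 400), strrep("A", 300), strrep("A", 200),
                 strrep("A", 300), strrep("A", 400)),
    stringsAsFactors = FALSE)
  gm <- data.frame(transcript_id = recs$raw_id,
                   gene_id = sub("\\..*", "", recs$raw_id),
                   species = "sp", stringsAsFactors = FALSE)
  hit <- function(tx, n) data.frame(
    transcript = tx, start = 1 + (0:(n - 1)) * 60,
    end = 52 + (0:(n - 1)) * 60, score = 50, evalue = 1e-9,
    hasTrp = TRUE, stringsAsFactors = FALSE)
  hits <- rbind(hit("G1.1", 3), hit("G1.2", 2), hit("G2.1", 1),
                hit("G3.1", 2), hit("G3.2", 2))
  rep <- deduplicate(hits, gm, recs)
  expect_setequal(unique(rep$transcript), c("G1.1", "G2.1", "G3.2"))
  expect_equal(sum(rep$transcript == "G1.1"), 3L)

  orphan <- hit("G9.1", 1)
  expect_error(deduplicate(orphan, gm, recs), "G9.1")
})

test_that("genes with no conserved tryptophan anywhere are filtered out", {
  recs <- data.frame(raw_id = c("G1.1", "G2.1"), clean_id = c("G1.1", "G2.1"),
                     species = "sp",
                     residues = c(strrep("A", 200), strrep("A", 200)),
                     stringsAsFactors = FALSE)
  gm <- data.frame(transcript_id = recs$raw_id,
                   gene_id = c("G1", "G2"), species = "sp",
                   stringsAsFactors = FALSE)
  hits <- data.frame(
    transcript = c("G1.1", "G2.1"), start = 1L, end = 52L,
    score = 50, evalue = 1e-9, hasTrp = c(FALSE, TRUE),
    stringsAsFactors = FALSE)
  genes <- classifyGenes(hits, gm, recs)
  expect_equal(genes$gene_id, "G2")
})

test_that("census tabulation conserves counts and applies reporting conventions", {
  genes <- data.frame(
    gene_id = sprintf("g%d", 1:10),
    species = rep(c("spA", "spB"), each = 5),
    subfamily = c("1R", "1R-RR", "2R", "3R", "5R",
                  "2R", "2R", "4R", "5R", "1R"),
    stringsAsFactors = FALSE)
  tab <- tabulateFamily(genes)
  cc <- familyCounts(tab)
  expect_equal(unname(cc["spA", ]), c(2L, 1L, 1L, 1L))  # 1R-RR in 1R, 5R in 4R
  expect_equal(unname(cc["spB", ]), c(1L, 2L, 0L, 2L))
  expect_equal(unname(fiveRCounts(tab)), c(1L, 1L))
  expect_equal(unname(speciesTotals(tab)), c(5L, 5L))
  expect_equal(grandTotal(tab), 10L)
  expect_equal(sum(speciesTotals(tab)), grandTotal(tab))
  df <- asCensusFrame(tab)
  expect_equal(df$total, df$oneR + df$twoR + df$threeR + df$fourR + df$fiveR)
})

test_that("empty inputs give an all-zero census", {
  genes <- data.frame(gene_id = character(0), species = character(0),
                      subfamily = character(0), stringsAsFactors = FALSE)
  tab <- tabulateFamily(genes, speciesOrder = "spA")
  expect_equal(grandTotal(tab), 0L)
  expect_equal(unname(speciesTotals(tab)), 0L)
})

test_that("end-to-end labels equal generator truth on noiseless proteomes", {
  prof <- calibratedProfile()
  sp <- proteomeSpec(nGenes = 150, tryptophanDropout = 0, seed = 37)
  pt <- generateProteome(sp, prof)
  hits <- scanProteome(prof, pt$records)
  genes <- classifyGenes(hits, truthGeneMap(pt), pt$records)
  truthMembers <- pt$truth[!is.na(pt$truth$expected_subfamily), ]
  m <- merge(genes, truthMembers, by = "gene_id")
  # all recovered genes labelled exactly as the generator intended
  recovered <- m[m$n_repeats.x == m$n_repeats.y, ]
  expect_equal(recovered$subfamily,
               recovered$expected_subfamily)
  expect_gte(nrow(recovered) / nrow(truthMembers), 0.99)
})
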