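# shared fixtures, built once per test run

.cache <- new.env()

# the shipped seed profile, calibrated once (seed frozen for the suite)
calibratedProfile <- function() {
  if (is.null(.cache$prof))
    .cache$prof <- calibrateEvalue(mybProfile(), nNull = 10000L, seed = 101L)
  .cache$prof
}

# i.i.d. background records, one window each unless length given
backgroundRecords <- function(n, len = 52L, seed = 1L, profile = mybProfile()) {
  set.seed(seed)
  aa <- rownames(profile@scores)[1:20]
  data.frame(
    raw_id = sprintf("bg%05d", seq_len(n)),
    clean_id = sprintf("bg%05d", seq_len(n)),
    species = "background",
    residues = vapply(seq_len(n), function(i)
      paste(sample(aa, len, TRUE, prob = profile@background),
            collapse = ""), character(1)),
    stringsAsFactors = FALSE
  )
}

# random protein records for round-trip tests
randomRecords <- function(n, seed = 1L) {
  set.seed(seed)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  data.frame(
    raw_id = sprintf("prot%03d", seq_len(n)),
    clean_id = sprintf("prot%03d", seq_len(n)),
    species = "rand",
    residues = vapply(seq_len(n), function(i)
      paste(sample(aa, sample(60:200, 1), TRUE), collapse = ""),
      character(1)),
    stringsAsFactors = FALSE
  )
}

# per-gene recovered repeat count (max over isoforms) vs generator truth
recoveredCounts <- function(hits, truth) {
  rec <- setNames(rep(0L, nrow(truth)), truth$gene_id)
  if (nrow(hits)) {
    perTx <- table(hits$transcript)
    gene <- sub("\\.\\d+$", "", names(perTx))
    best <- tapply(as.integer(perTx), gene, max)
    rec[names(best)] <- best
  }
  rec
}

# random unrooted tree with its additive distance matrix
randomAdditiveCase <- function(ntaxa) {
  tr <- ape::unroot(ape::rtree(ntaxa, br = function(n) runif(n, 0.1, 1)))
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}
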