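#' Specification for a synthetic proteome
#'
#' Defines the planted repeat architecture of a synthetic proteome: how
#' many genes, the distribution of repeat counts per gene, inter-repeat
#' spacer lengths, the fraction of two-repeat genes whose gap exceeds
#' the 2R spacing threshold (and so are R-R-type by construction),
#' the probability that a planted repeat lacks all canonical
#' tryptophans, and the isoform count range used to exercise
#' de-duplication.
#'
#' @param nGenes number of genes.
#' @param architectureMix named probability vector over repeat counts
#'   `"0"`..`"5"`; genes drawn with 0 repeats are non-MYB decoys.
#' @param spacerRange inclusive range (aa) of inter-repeat gaps.
#' @param twoRepeatGapSplit fraction of 2-repeat genes given a gap above
#'   `spacingThreshold` (drawn from `splitGapRange`).
#' @param splitGapRange inclusive gap range for split 2-repeat genes;
#'   must lie strictly above `spacingThreshold`.
#' @param tryptophanDropout probability a planted repeat has every
#'   canonical tryptophan (and its +/-1 neighbourhood) replaced.
#' @param isoformsPerGene inclusive range of isoform counts per gene.
#' @param spacingThreshold the 2R spacing rule the truth labels use.
#' @param species species label for the generated records.
#' @param seed master RNG seed; per-gene substreams are derived from it.
#' @return a validated `proteome_spec` list.
#' @export
proteomeSpec <- function(nGenes = 200L,
                         architectureMix = c(`0` = 0.40, `1` = 0.20,
                                             `2` = 0.22, `3` = 0.08,
                                             `4` = 0.06, `5` = 0.04),
                         spacerRange = c(2L, 10L),
                         twoRepeatGapSplit = 0.3,
                         splitGapRange = c(13L, 40L),
                         tryptophanDropout = 0.05,
                         isoformsPerGene = c(1L, 2L),
                         spacingThreshold = 10L,
                         species = "Synthetica",
                         seed = 1L) {
  stopifnot(nGenes >= 1L, length(architectureMix) == 6L,
            identical(names(architectureMix), as.character(0:5)),
            all(architectureMix >= 0),
            abs(sum(architectureMix) - 1) < 1e-8,
            spacerRange[1] <= spacerRange[2], spacerRange[1] >= 0L,
            twoRepeatGapSplit >= 0, twoRepeatGapSplit <= 1,
            splitGapRange[1] > spacingThreshold,
            splitGapRange[1] <= splitGapRange[2],
            tryptophanDropout >= 0, tryptophanDropout <= 1,
            isoformsPerGene[1] >= 1L,
            isoformsPerGene[1] <= isoformsPerGene[2])
  structure(list(nGenes = as.integer(nGenes),
                 architectureMix = architectureMix,
                 spacerRange = as.integer(spacerRange),
                 twoRepeatGapSplit = twoRepeatGapSplit,
                 splitGapRange = as.integer(splitGapRange),
                 tryptophanDropout = tryptophanDropout,
                 isoformsPerGene = as.integer(isoformsPerGene),
                 spacingThreshold = as.integer(spacingThreshold),
                 species = species, seed = as.integer(seed)),
            class = "proteome_spec")
}

# per-column emission probabilities implied by the profile's log-odds
.emissionProbs <- function(profile) {
  p <- profile@background * 2^profile@scores[.AA20, , drop = FALSE]
  sweep(p, 2, colSums(p), "/")
}

# one repeat instance sampled column-by-column from the profile
.emitRepeat <- function(emis) {
  L <- ncol(emis)
  paste(vapply(seq_len(L), function(j)
    sample(.AA20, 1L, prob = emis[, j]), character(1)), collapse = "")
}

# remove every tryptophan within +/-1 of the canonical columns
.dropTryptophans <- function(rep, trpCols) {
  chars <- strsplit(rep, "")[[1]]
  pos <- unique(as.vector(outer(trpCols, -1:1, "+")))
  pos <- pos[pos >= 1L & pos <= length(chars)]
  chars[pos][chars[pos] == "W"] <- "F"
  paste(chars, collapse = "")
}

.randomBackground <- function(n, background) {
  paste(sample(.AA20, n, replace = TRUE, prob = background), collapse = "")
}

# uniform draw from an inclusive integer range (safe for width-1 ranges)
.sampleRange <- function(lo, hi, n = 1L) {
  vals <- seq.int(lo, hi)
  vals[sample.int(length(vals), n, replace = TRUE)]
}

# stable per-gene substream seeds derived from the master seed
.substreamSeeds <- function(seed, n) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a synthetic proteome with planted MYB repeats
#'
#' Each gene receives a repeat count from the architecture mix; repeats
#' are emitted column-by-column from the profile's per-column
#' distributions (so scanner sensitivity is a real measurement, not a
#' string match), separated by background spacers whose lengths respect
#' the spec, flanked by background leader/trailer segments.  Extra
#' isoforms replicate the gene with optional truncation of the last
#' repeat, to exercise de-duplication.  All randomness derives from the
#' spec seed via per-gene substreams, so the output is reproducible.
#'
#' @param spec a [proteomeSpec()].
#' @param profile a [MybProfile-class]; calibration not required.
#' @return list with elements `records` (data.frame as [readFasta()]),
#'   `gff` (character vector of GFF3 lines), and `truth` (per-gene
#'   data.frame: `gene_id`, `species`, `n_repeats`, `intervals`,
#'   `trp_flags`, `split`, `expected_subfamily` — `NA` for non-members).
#' @export
generateProteome <- function(spec, profile = mybProfile()) {
  stopifnot(inherits(spec, "proteome_spec"), is(profile, "MybProfile"))
  L <- profileLength(profile)
  emis <- .emissionProbs(profile)
  bg <- profile@background
  seeds <- .substreamSeeds(spec$seed, spec$nGenes)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  recs <- list(); gff <- c("##gff-version 3"); truth <- list()
  for (i in seq_len(spec$nGenes)) {
    set.seed(seeds[i])
    k <- sample(0:5, 1L, prob = spec$architectureMix)
    geneId <- sprintf("%s_G%04d", toupper(substr(spec$species, 1, 3)), i)
    nIso <- .sampleRange(spec$isoformsPerGene[1], spec$isoformsPerGene[2])
    split <- FALSE
    if (k == 2L && runif(1) < spec$twoRepeatGapSplit) split <- TRUE
    gaps <- if (k >= 2L) {
      g <- .sampleRange(spec$spacerRange[1], spec$spacerRange[2], k - 1L)
      if (split)
        g[1] <- .sampleRange(spec$splitGapRange[1], spec$splitGapRange[2])
      g
    } else integer(0)
    leader <- sample(10:40, 1L)
    trailer <- sample(30:80, 1L)
    reps <- character(k)
    dropped <- logical(k)
    if (k > 0L) {
      for (r in seq_len(k)) {
        reps[r] <- .emitRepeat(emis)
        dropped[r] <- runif(1) < spec$tryptophanDropout
        if (dropped[r]) reps[r] <- .dropTryptophans(reps[r],
                                                    profile@trpCols)
      }
    }
    buildSeq <- function(nRep) {
      pieces <- .randomBackground(leader, bg)
      starts <- integer(nRep); ends <- integer(nRep)
      at <- leader
      for (r in seq_len(nRep)) {
        starts[r] <- at + 1L
        ends[r] <- at + L
        pieces <- paste0(pieces, reps[r])
        at <- at + L
        if (r < nRep) {
          pieces <- paste0(pieces, .randomBackground(gaps[r], bg))
          at <- at + gaps[r]
        }
      }
      pieces <- paste0(pieces, .randomBackground(trailer, bg))
      list(seq = pieces, starts = starts, ends = ends)
    }
    if (k == 0L) {
      protLen <- sample(100:400, 1L)
      full <- list(seq = .randomBackground(protLen, bg),
                   starts = integer(0), ends = integer(0))
    } else {
      full <- buildSeq(k)
    }
    isoSeqs <- character(nIso)
    isoSeqs[1] <- full$seq
    if (nIso > 1L) {
      for (iso in 2:nIso) {
        truncate <- k >= 1L && runif(1) < 0.5
        isoSeqs[iso] <- if (truncate) buildSeq(k - 1L)$seq else full$seq
      }
    }
    txIds <- sprintf("%s.%d", geneId, seq_len(nIso))
    recs[[i]] <- data.frame(raw_id = txIds, species = spec$species,
                            residues = isoSeqs, stringsAsFactors = FALSE)
    base <- (i - 1L) * 10000L + 1L
    gff <- c(gff,
             sprintf("chr1\tmybscan\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                     base, base + 2999L, geneId),
             sprintf("chr1\tmybscan\tmRNA\t%d\t%d\t.\t+\t.\tID=%s;Parent=%s",
                     base, base + 2999L, txIds, geneId))
    flags <- if (k > 0L) vapply(seq_len(k), function(r)
      hasConservedTryptophan(reps[r], profile), logical(1)) else logical(0)
    expected <- if (k == 0L || !any(flags)) NA_character_ else
      assignSubfamily(full$starts, full$ends, flags,
                      spec$spacingThreshold)
    truth[[i]] <- data.frame(
      gene_id = geneId, species = spec$species, n_repeats = k,
      intervals = paste(sprintf("%d-%d", full$starts, full$ends),
                        collapse = ";"),
      trp_flags = paste(as.integer(flags), collapse = ";"),
      split = split, expected_subfamily = expected,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  records <- data.frame(raw_id = records$raw_id,
                        clean_id = .resolveIdCollisions(
                          simplifyId(records$raw_id)),
                        species = records$species,
                        residues = records$residues,
                        stringsAsFactors = FALSE)
  list(records = records, gff = gff, truth = do.call(rbind, truth))
}

#' Gene map implied by a generated proteome (generator truth)
#'
#' @param proteome result of [generateProteome()].
#' @return data.frame with columns `transcript_id`, `gene_id`,
#'   `species`, identical to parsing the emitted GFF.
#' @export
truthGeneMap <- function(proteome) {
  tx <- proteome$records$raw_id
  data.frame(transcript_id = tx, gene_id = sub("\\.\\d+$", "", tx),
             species = proteome$records$species, stringsAsFactors = FALSE)
}

#' Specification for a synthetic count matrix
#'
#' Negative-binomial counts with `variance = mu + alpha * mu^2`.
#' Baseline means are log-normal; a planted fraction of genes is
#' differentially expressed with log2 fold changes of magnitude drawn
#' uniformly from `lfcRange` (positive = higher under drought).
#'
#' @param nGenes number of genes.
#' @param replicates integer pair: drought and control replicate counts
#'   (default 3 + 3, the standard drought-study design).
#' @param baselineMeanlog,baselineSdlog log-normal parameters of the
#'   baseline mean.
#' @param dispersion NB dispersion alpha (0 gives Poisson counts).
#' @param deFraction fraction of genes with a planted fold change.
#' @param lfcRange inclusive magnitude range of planted log2 fold
#'   changes.
#' @param upFraction fraction of planted genes that are up-regulated.
#' @param seed master RNG seed.
#' @return a validated `count_spec` list.
#' @export
countSpec <- function(nGenes = 2000L, replicates = c(3L, 3L),
                      baselineMeanlog = log(200), baselineSdlog = 1,
                      dispersion = 0.1, deFraction = 0.1,
                      lfcRange = c(1.5, 3), upFraction = 0.5,
                      seed = 1L) {
  stopifnot(nGenes >= 1L, length(replicates) == 2L, all(replicates >= 2L),
            dispersion >= 0, deFraction >= 0, deFraction <= 1,
            lfcRange[1] <= lfcRange[2], upFraction >= 0, upFraction <= 1)
  structure(list(nGenes = as.integer(nGenes),
                 replicates = as.integer(replicates),
                 baselineMeanlog = baselineMeanlog,
                 baselineSdlog = baselineSdlog,
                 dispersion = dispersion, deFraction = deFraction,
                 lfcRange = lfcRange, upFraction = upFraction,
                 seed = as.integer(seed)),
            class = "count_spec")
}

.rnb <- function(n, mu, alpha) {
  if (alpha <= 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / alpha)
}

#' Generate a synthetic drought/control count matrix
#'
#' Drought-group means of planted genes are shifted by `2^log2fc`
#' relative to control; non-planted genes have true log2 fold change 0.
#' All randomness derives from the spec seed via per-gene substreams.
#'
#' @param spec a [countSpec()].
#' @return list with `se` (a
#'   [SummarizedExperiment::SummarizedExperiment] of raw counts with a
#'   `group` column), `sheet` (sample-sheet data.frame), and `truth`
#'   (data.frame `gene_id`, `baseline_mean`, `true_lfc`).
#' @export
generateCounts <- function(spec) {
  stopifnot(inherits(spec, "count_spec"))
  nD <- spec$replicates[1]; nC <- spec$replicates[2]
  seeds <- .substreamSeeds(spec$seed + 1L, spec$nGenes)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  mat <- matrix(0L, spec$nGenes, nD + nC)
  lfc <- numeric(spec$nGenes)
  mu0 <- numeric(spec$nGenes)
  for (i in seq_len(spec$nGenes)) {
    set.seed(seeds[i])
    mu0[i] <- exp(rnorm(1, spec$baselineMeanlog, spec$baselineSdlog))
    if (runif(1) < spec$deFraction) {
      mag <- runif(1, spec$lfcRange[1], spec$lfcRange[2])
      lfc[i] <- if (runif(1) < spec$upFraction) mag else -mag
    }
    muD <- mu0[i] * 2^lfc[i]
    mat[i, ] <- c(.rnb(nD, muD, spec$dispersion),
                  .rnb(nC, mu0[i], spec$dispersion))
  }
  storage.mode(mat) <- "integer"
  rownames(mat) <- sprintf("gene%05d", seq_len(spec$nGenes))
  colnames(mat) <- c(sprintf("drought_%d", seq_len(nD)),
                     sprintf("control_%d", seq_len(nC)))
  grp <- factor(rep(c("drought", "control"), c(nD, nC)),
                levels = c("drought", "control"))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = mat),
    colData = S4Vectors::DataFrame(group = grp, row.names = colnames(mat)))
  list(se = se,
       sheet = data.frame(sample_id = colnames(mat),
                          group = as.character(grp),
                          stringsAsFactors = FALSE),
       truth = data.frame(gene_id = rownames(mat), baseline_mean = mu0,
                          true_lfc = lfc, stringsAsFactors = FALSE))
}
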