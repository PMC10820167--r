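#' Conserved-tryptophan test for one repeat window
#'
#' A detected repeat counts as carrying a conserved tryptophan when a `W`
#' sits at one of the profile's three canonical tryptophan columns, with
#' a +/-1 column tolerance to absorb alignment jitter.
#'
#' @param window residue string of exactly the profile length.
#' @param profile a [MybProfile-class].
#' @param tolerance allowed column offset (default 1).
#' @return logical scalar.
#' @export
hasConservedTryptophan <- function(window, profile, tolerance = 1L) {
  L <- profileLength(profile)
  if (nchar(window) != L)
    stop("window length ", nchar(window), " != profile length ", L)
  pos <- unique(as.vector(outer(profile@trpCols,
                                -tolerance:tolerance, "+")))
  pos <- pos[pos >= 1L & pos <= L]
  chars <- strsplit(window, "")[[1]]
  any(chars[pos] == "W")
}

#' De-duplicate isoform hits to one representative per gene
#'
#' Maps transcripts to genes and keeps, per gene, the isoform with the
#' most passing repeats; ties are broken by the longer transcript, then
#' by the lexicographically smaller transcript id.
#'
#' @param hits hits data.frame from [scanProteome()] or
#'   [hitsFromDomtblout()].
#' @param geneMap data.frame from [readGffGeneMap()].
#' @param records proteome records (used for transcript lengths).
#' @return the subset of `hits` on representative transcripts, with
#'   `gene_id` and `species` columns added.
#' @export
deduplicate <- function(hits, geneMap, records) {
  if (nrow(hits) == 0L) {
    out <- cbind(hits, data.frame(gene_id = character(0),
                                  species = character(0)))
    return(out)
  }
  unmapped <- setdiff(unique(hits$transcript), geneMap$transcript_id)
  if (length(unmapped))
    stop("transcript(s) missing from the gene map: ",
         paste(sort(unmapped), collapse = ", "))
  lens <- setNames(nchar(records$residues), records$raw_id)
  noLen <- setdiff(unique(hits$transcript), names(lens))
  if (length(noLen))
    stop("transcript(s) missing from records: ",
         paste(sort(noLen), collapse = ", "))
  m <- match(hits$transcript, geneMap$transcript_id)
  hits$gene_id <- geneMap$gene_id[m]
  hits$species <- geneMap$species[m]
  perTx <- unique(data.frame(transcript = hits$transcript,
                             gene_id = hits$gene_id,
                             stringsAsFactors = FALSE))
  perTx$n <- as.integer(table(hits$transcript)[perTx$transcript])
  perTx$len <- lens[perTx$transcript]
  perTx <- perTx[order(perTx$gene_id, -perTx$n, -perTx$len,
                       perTx$transcript), ]
  rep <- perTx$transcript[!duplicated(perTx$gene_id)]
  out <- hits[hits$transcript %in% rep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign a subfamily label from repeat architecture
#'
#' Subfamilies follow the repeat count: 1, 3, 4 and 5 repeats map to
#' `1R`, `3R`, `4R` and `5R`.  A two-repeat protein is `2R` only when
#' its repeats are not more than `spacingThreshold` residues apart
#' (boundary included); otherwise it is demoted to the R-R type of the
#' 1R subfamily (`1R-RR`).  The gap is the number of residues strictly
#' between the two envelopes: `start(next) - end(prev) - 1`.
#'
#' @param starts,ends integer vectors of repeat envelope coordinates
#'   (1-based inclusive), sorted by start.
#' @param trpFlags logical vector, per-repeat conserved-tryptophan
#'   evidence; at least one must be `TRUE` (a protein without any is not
#'   a family member).
#' @param spacingThreshold maximum 2R inter-repeat gap in residues
#'   (default 10).
#' @return one of `"1R"`, `"1R-RR"`, `"2R"`, `"3R"`, `"4R"`, `"5R"`.
#' @examples
#' assignSubfamily(c(1, 63), c(52, 114), c(TRUE, TRUE))   # gap 10 -> "2R"
#' assignSubfamily(c(1, 64), c(52, 115), c(TRUE, TRUE))   # gap 11 -> "1R-RR"
#' @export
assignSubfamily <- function(starts, ends, trpFlags,
                            spacingThreshold = 10L) {
  n <- length(starts)
  stopifnot(length(ends) == n, length(trpFlags) == n, n >= 1L)
  if (is.unsorted(starts))
    stop("repeat intervals must be sorted by start")
  if (any(ends < starts))
    stop("interval end precedes start")
  if (n > 1L && any(starts[-1L] <= ends[-n]))
    stop("repeat intervals overlap")
  if (!any(trpFlags))
    stop("no repeat carries a conserved tryptophan; not a family member")
  if (n > 5L)
    stop(n, " repeats on one protein: flagged for manual review")
  if (n == 2L) {
    gap <- starts[2L] - ends[1L] - 1L
    return(if (gap <= spacingThreshold) "2R" else "1R-RR")
  }
  c("1R", "2R", "3R", "4R", "5R")[n]
}

#' Classify scanned hits into labelled family members
#'
#' The full identification chain: de-duplicate isoforms to genes, drop
#' genes whose every repeat lacks the conserved tryptophan, and label
#' the remainder by repeat count and spacing.
#'
#' @param hits hits data.frame from [scanProteome()] or
#'   [hitsFromDomtblout()].
#' @param geneMap data.frame from [readGffGeneMap()].
#' @param records proteome records.
#' @param spacingThreshold passed to [assignSubfamily()].
#' @return data.frame with one row per member gene: `gene_id`,
#'   `species`, `transcript` (representative isoform), `n_repeats`,
#'   `subfamily`, `intervals` (`"start-end"` semicolon-joined), and
#'   `trp_flags` (semicolon-joined 0/1).
#' @export
classifyGenes <- function(hits, geneMap, records, spacingThreshold = 10L) {
  rep <- deduplicate(hits, geneMap, records)
  if (nrow(rep) == 0L) return(.emptyGenes())
  pieces <- lapply(split(rep, rep$gene_id), function(df) {
    df <- df[order(df$start), , drop = FALSE]
    if (!any(df$hasTrp)) return(NULL)  # filter honesty
    data.frame(
      gene_id = df$gene_id[1],
      species = df$species[1],
      transcript = df$transcript[1],
      n_repeats = nrow(df),
      subfamily = assignSubfamily(df$start, df$end, df$hasTrp,
                                  spacingThreshold),
      intervals = paste(sprintf("%d-%d", df$start, df$end),
                        collapse = ";"),
      trp_flags = paste(as.integer(df$hasTrp), collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) return(.emptyGenes())
  out <- out[order(out$species, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.emptyGenes <- function() {
  data.frame(gene_id = character(0), species = character(0),
             transcript = character(0), n_repeats = integer(0),
             subfamily = character(0), intervals = character(0),
             trp_flags = character(0), stringsAsFactors = FALSE)
}

#' Tabulate the family census per species
#'
#' Counts labelled members per species and subfamily in the field's
#' reporting shape: R-R-type members are folded into the 1R column and
#' 5-repeat members are counted in the 4R column but flagged separately.
#'
#' @param genes data.frame from [classifyGenes()] (columns `species`,
#'   `subfamily`).
#' @param speciesOrder optional row order; defaults to order of first
#'   appearance.
#' @return a [FamilyCountTable-class].
#' @export
tabulateFamily <- function(genes, speciesOrder = NULL) {
  if (is.null(speciesOrder)) speciesOrder <- unique(genes$species)
  sp <- factor(genes$species, levels = speciesOrder)
  sub <- factor(genes$subfamily,
                levels = c("1R", "1R-RR", "2R", "3R", "4R", "5R"))
  if (anyNA(sub))
    stop("unknown subfamily label(s): ",
         paste(unique(genes$subfamily[is.na(sub)]), collapse = ", "))
  tab <- table(sp, sub)
  counts <- cbind(
    `1R` = tab[, "1R"] + tab[, "1R-RR"],
    `2R` = tab[, "2R"],
    `3R` = tab[, "3R"],
    `4R` = tab[, "4R"] + tab[, "5R"]
  )
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(as.character(speciesOrder),
                           c("1R", "2R", "3R", "4R"))
  new("FamilyCountTable", counts = counts,
      fiveR = setNames(as.integer(tab[, "5R"]),
                       as.character(speciesOrder)))
}

#' Write per-gene labels as TSV
#'
#' @param genes data.frame from [classifyGenes()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGeneLabels <- function(genes, path) {
  write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a family census as TSV
#'
#' @param census a [FamilyCountTable-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCensus <- function(census, path) {
  write.table(asCensusFrame(census), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Expand a published-style census table into per-gene rows
#'
#' Reads a census TSV (columns `species`, `oneR`, `twoR`, `threeR`,
#' `fourR`, `fiveR`) and expands each cell into that many synthetic
#' member rows suitable for [tabulateFamily()], so census arithmetic can
#' be exercised end-to-end.  The copy shipped in
#' `extdata/family_census_reference.tsv` transcribes a published
#' 12-species census.
#'
#' @param path census TSV; defaults to the shipped reference table.
#' @return data.frame with columns `gene_id`, `species`, `subfamily`.
#' @export
censusReferenceGenes <- function(path = system.file(
    "extdata", "family_census_reference.tsv",
    package = "mybscan", mustWork = TRUE)) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "oneR", "twoR", "threeR", "fourR", "fiveR")
  if (!all(need %in% names(tab)))
    stop("census table needs columns: ", paste(need, collapse = ", "))
  sub <- c(oneR = "1R", twoR = "2R", threeR = "3R", fourR = "4R",
           fiveR = "5R")
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    counts <- unlist(tab[i, names(sub)])
    lab <- rep(sub, counts)
    if (!length(lab)) return(NULL)
    data.frame(
      gene_id = sprintf("%s_m%03d", gsub("[^A-Za-z]", "", tab$species[i]),
                        seq_along(lab)),
      species = tab$species[i],
      subfamily = unname(lab),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
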