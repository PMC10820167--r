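#' Simplify sequence identifiers
#'
#' Downstream analysis software often rejects identifiers containing
#' special symbols such as `_`.  Each character from `stripSet` is
#' replaced by `"."` and runs of dots are collapsed, so
#' `"Traes_19F222799.7"` becomes `"Traes.19F222799.7"`.  The operation is
#' idempotent.
#'
#' @param ids character vector of raw identifiers.
#' @param stripSet characters to replace (default `"_"`).
#' @return character vector of cleaned identifiers.
#' @examples
#' simplifyId("Traes_19F222799.7")
#' simplifyId("a__b")
#' @export
simplifyId <- function(ids, stripSet = "_") {
  if (any(!nzchar(ids)))
    stop("identifiers must be non-empty")
  out <- ids
  if (length(stripSet)) {
    cls <- paste0("[", paste(vapply(stripSet, function(ch) {
      if (ch %in% c("]", "^", "-", "\\")) paste0("\\", ch) else ch
    }, character(1)), collapse = ""), "]")
    out <- gsub(cls, ".", out)
  }
  out <- gsub("\\.+", ".", out)
  if (any(!nzchar(out)))
    stop("identifier(s) empty after stripping: ",
         paste(ids[!nzchar(out)], collapse = ", "))
  out
}

# suffix 2nd, 3rd, ... occurrences of a duplicated clean id with -1, -2, ...
.resolveIdCollisions <- function(clean) {
  dup <- ave(seq_along(clean), clean, FUN = seq_along) - 1L
  ifelse(dup > 0L, paste0(clean, "-", dup), clean)
}

#' Read a protein FASTA file
#'
#' Parses a protein FASTA into one record per entry.  Residues are
#' uppercased and non-canonical letters (B, Z, J, U, O, `*`, gaps, ...)
#' are mapped to `X`.  Identifiers are simplified with [simplifyId()];
#' collisions after simplification are suffixed deterministically.
#'
#' @param path FASTA file.
#' @param species species label attached to every record.
#' @param stripSet passed to [simplifyId()].
#' @return data.frame with columns `raw_id`, `clean_id`, `species`,
#'   `residues`.  A file with zero entries yields zero rows.
#' @export
readFasta <- function(path, species = NA_character_, stripSet = "_") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- which(nzchar(trimws(lines)))
  if (length(body) && !startsWith(trimws(lines[body[1]]), ">"))
    stop(sprintf("malformed FASTA %s: line %d does not start a record",
                 path, body[1]))
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L)
    return(data.frame(raw_id = character(0), clean_id = character(0),
                      species = character(0), residues = character(0),
                      stringsAsFactors = FALSE))
  raw <- sub("\\s.*$", "", names(seqs))
  if (any(!nzchar(raw))) {
    bad <- which(!nzchar(raw))[1]
    stop(sprintf("malformed FASTA %s: empty header for entry %d", path, bad))
  }
  res <- toupper(as.character(seqs))
  res <- gsub(paste0("[^", paste(.AA20, collapse = ""), "]"), "X", res)
  if (any(!nzchar(res)))
    stop(sprintf("malformed FASTA %s: empty sequence for '%s'",
                 path, raw[!nzchar(res)][1]))
  data.frame(
    raw_id = raw,
    clean_id = .resolveIdCollisions(simplifyId(raw, stripSet)),
    species = rep(species, length(raw)),
    residues = unname(res),
    stringsAsFactors = FALSE
  )
}

#' Write records to FASTA
#'
#' @param records data.frame as returned by [readFasta()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(records, path) {
  set <- Biostrings::AAStringSet(setNames(records$residues, records$raw_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a transcript-to-gene map from a GFF3 file
#'
#' Uses the `mRNA`/`transcript` features' `ID` and `Parent` attributes.
#' Transcripts lacking a `Parent` are treated as their own gene.
#'
#' @param path GFF3 file.
#' @param species species label attached to every mapping.
#' @return data.frame with columns `transcript_id`, `gene_id`, `species`.
#' @export
readGffGeneMap <- function(path, species = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(lines) & !startsWith(lines, "#")))
    return(data.frame(transcript_id = character(0), gene_id = character(0),
                      species = character(0), stringsAsFactors = FALSE))
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% c("mRNA", "transcript")
  gr <- gr[keep]
  if (length(gr) == 0L)
    return(data.frame(transcript_id = character(0), gene_id = character(0),
                      species = character(0), stringsAsFactors = FALSE))
  tid <- as.character(gr$ID)
  parent <- vapply(seq_along(gr), function(i) {
    p <- gr$Parent[[i]]
    if (length(p) == 0L) tid[i] else {
      if (length(unique(p)) > 1L)
        stop("transcript ", tid[i], " lists multiple parents: ",
             paste(p, collapse = ", "))
      as.character(p[1])
    }
  }, character(1))
  map <- unique(data.frame(transcript_id = tid, gene_id = parent,
                           species = species, stringsAsFactors = FALSE))
  conflicted <- unique(map$transcript_id[duplicated(map$transcript_id)])
  if (length(conflicted))
    stop("transcript(s) mapped to conflicting genes: ",
         paste(conflicted, collapse = ", "))
  map
}

# domtblout column layout (HMMER 3 per-domain table):
# 1 target, 4 query, 12 c-Evalue, 14 domain score, 16-17 hmm from/to,
# 20-21 env from/to; the 23rd field onward is free-text description.
.DOMTBL_MIN_FIELDS <- 22L

#' Read a HMMER per-domain table (domtblout)
#'
#' Parses the whitespace-delimited per-domain table written by
#' `hmmsearch --domtblout`.  The envelope (`env`) coordinates are used as
#' the hit interval and the conditional E-value (`c-Evalue`) column as the
#' row's E-value.
#'
#' @param path domtblout file.
#' @return data.frame with columns `target`, `query`, `cEvalue`, `score`,
#'   `hmmFrom`, `hmmTo`, `envFrom`, `envTo`.
#' @export
readDomtblout <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  dat <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(dat) == 0L)
    return(data.frame(target = character(0), query = character(0),
                      cEvalue = numeric(0), score = numeric(0),
                      hmmFrom = integer(0), hmmTo = integer(0),
                      envFrom = integer(0), envTo = integer(0),
                      stringsAsFactors = FALSE))
  fields <- strsplit(trimws(lines[dat]), "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf < .DOMTBL_MIN_FIELDS))
    stop(sprintf("malformed domtblout %s: line %d has %d fields (expected >= %d)",
                 path, dat[which(nf < .DOMTBL_MIN_FIELDS)[1]],
                 min(nf), .DOMTBL_MIN_FIELDS))
  get <- function(k) vapply(fields, `[[`, character(1), k)
  out <- data.frame(
    target = get(1), query = get(4),
    cEvalue = as.numeric(get(12)), score = as.numeric(get(14)),
    hmmFrom = as.integer(get(16)), hmmTo = as.integer(get(17)),
    envFrom = as.integer(get(20)), envTo = as.integer(get(21)),
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$cEvalue)) || any(is.na(out$envFrom)) || any(is.na(out$envTo)))
    stop("malformed domtblout ", path, ": non-numeric coordinate or E-value")
  if (any(out$envFrom > out$envTo))
    stop("malformed domtblout ", path, ": envelope start > end")
  if (any(out$cEvalue < 0))
    stop("malformed domtblout ", path, ": negative E-value")
  out
}

#' Write domain hits in the domtblout dialect
#'
#' Emits rows readable by [readDomtblout()]; coordinates round-trip
#' exactly and scores/E-values round-trip at six significant digits.
#'
#' @param hits data.frame with columns `target` (or `transcript`),
#'   `cEvalue` (or `evalue`), `score`, `envFrom`/`envTo` (or
#'   `start`/`end`), and optionally `query`, `hmmFrom`, `hmmTo`.
#' @param path output file.
#' @param query query name used when `hits` lacks one.
#' @return `path`, invisibly.
#' @export
writeDomtblout <- function(hits, path, query = "MYB_repeat") {
  target <- if ("target" %in% names(hits)) hits$target else hits$transcript
  ev <- if ("cEvalue" %in% names(hits)) hits$cEvalue else hits$evalue
  from <- if ("envFrom" %in% names(hits)) hits$envFrom else hits$start
  to <- if ("envTo" %in% names(hits)) hits$envTo else hits$end
  qn <- if ("query" %in% names(hits)) hits$query else rep(query, nrow(hits))
  hf <- if ("hmmFrom" %in% names(hits)) hits$hmmFrom else rep(1L, nrow(hits))
  ht <- if ("hmmTo" %in% names(hits)) hits$hmmTo else hf + (to - from)
  lines <- c(
    "#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------"
  )
  if (nrow(hits)) {
    n <- nrow(hits)
    idx <- ave(seq_len(n), target, FUN = seq_along)
    tot <- ave(seq_len(n), target, FUN = length)
    lines <- c(lines, sprintf(
      "%-20s %-10s %5d %-20s %-10s %5d %9.3g %6.1f %5.1f %3d %3d %9.6g %9.6g %6.6g %5.1f %5d %5d %5d %5d %5d %5d %4.2f -",
      target, "-", to + 10L, qn, "-", ht, ev, hits$score, 0, idx, tot,
      ev, ev, hits$score, 0, hf, ht, from, to, from, to, 0.99))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a count matrix with its sample sheet
#'
#' Reads a gene-by-sample TSV of raw counts together with a two-column
#' sample sheet (`sample_id`, `group`).  Counts must be non-negative
#' integers (normalised matrices are rejected).  To be screen-eligible
#' the design must contain at least two groups with at least two
#' replicates each.
#'
#' @param countsPath TSV; first column gene id, remaining columns counts.
#' @param sheetPath TSV sample sheet with columns `sample_id`, `group`.
#' @param groups allowed group labels.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts` and a `group` column in `colData`.
#' @export
readCounts <- function(countsPath, sheetPath,
                       groups = c("drought", "control")) {
  tab <- read.delim(countsPath, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("count matrix must have a gene-id column plus at least one sample")
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab[[1]]
  if (any(is.na(mat)) || any(mat < 0) || any(mat != round(mat)))
    stop("counts must be raw non-negative integers")
  storage.mode(mat) <- "integer"
  sheet <- read.delim(sheetPath, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(sheet)))
    stop("sample sheet needs columns sample_id and group")
  missing <- setdiff(colnames(mat), sheet$sample_id)
  if (length(missing))
    stop("samples absent from sheet: ", paste(missing, collapse = ", "))
  grp <- sheet$group[match(colnames(mat), sheet$sample_id)]
  bad <- setdiff(unique(grp), groups)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  tb <- table(grp)
  if (length(tb) < 2L || any(tb < 2L))
    stop("screen-ineligible design: need >= 2 groups with >= 2 replicates ",
         "(got ", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), ")")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = mat),
    colData = S4Vectors::DataFrame(group = factor(grp, levels = groups),
                                   row.names = colnames(mat))
  )
}

#' Write a count matrix and its sample sheet
#'
#' @param se SummarizedExperiment with assay `counts` and `colData$group`.
#' @param countsPath,sheetPath output TSVs.
#' @return `countsPath`, invisibly.
#' @export
writeCounts <- function(se, countsPath, sheetPath) {
  mat <- SummarizedExperiment::assay(se, "counts")
  out <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, countsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  sheet <- data.frame(sample_id = colnames(mat),
                      group = as.character(se$group),
                      stringsAsFactors = FALSE)
  write.table(sheet, sheetPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(countsPath)
}

#' Write a tree in Newick format
#'
#' @param tree an [ape::phylo] tree; internal `node.label`s (bootstrap
#'   supports) are preserved.
#' @param path optional output file; if `NULL` the Newick string is
#'   returned.
#' @return the Newick string (invisibly when written to a file).
#' @export
writeNewick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a Newick tree
#'
#' @param path file containing one Newick tree, or a Newick string via
#'   `text`.
#' @param text optional Newick string.
#' @return an [ape::phylo] tree.
#' @export
readNewick <- function(path = NULL, text = NULL) {
  tr <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick input")
  tr
}
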