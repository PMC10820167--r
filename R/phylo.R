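#' Pairwise distance between two aligned protein sequences
#'
#' Compares only columns where both sequences are ungapped (pairwise
#' deletion).  The p-distance is mismatches over compared sites; the
#' Poisson correction is `-ln(1 - p)`.
#'
#' @param seqA,seqB aligned residue strings of equal length; `-` and `.`
#'   are gaps.
#' @param model `"poisson"` (default) or `"p"`.
#' @return numeric distance.
#' @examples
#' pairwiseDistance("ACDEFGHIKL", "ACDEFGHIAA", model = "p")   # 0.2
#' @export
pairwiseDistance <- function(seqA, seqB, model = c("poisson", "p")) {
  model <- match.arg(model)
  if (nchar(seqA) != nchar(seqB))
    stop("aligned sequences must have equal length")
  a <- strsplit(seqA, "")[[1]]
  b <- strsplit(seqB, "")[[1]]
  ok <- !(a %in% c("-", ".")) & !(b %in% c("-", "."))
  if (!any(ok))
    stop("no comparable (mutually ungapped) columns")
  p <- sum(a[ok] != b[ok]) / sum(ok)
  if (model == "p") return(p)
  if (p >= 1)
    stop("saturated pair (p >= 1); Poisson correction undefined")
  -log(1 - p)
}

#' Distance matrix over a set of aligned sequences
#'
#' @param seqs named character vector of aligned sequences.
#' @param model passed to [pairwiseDistance()].
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distanceMatrix <- function(seqs, model = c("poisson", "p")) {
  model <- match.arg(model)
  n <- length(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    D[i, j] <- D[j, i] <- pairwiseDistance(seqs[[i]], seqs[[j]], model)
  D
}

#' Neighbor-joining tree
#'
#' Canonical agglomerative neighbor joining: at each step the pair
#' minimising the Q criterion is joined, with ties broken by the
#' lexicographically smallest taxon pair (taxa are ordered
#' lexicographically on entry, so the first minimal pair in scan order
#' is the lexicographic one).  Negative branch-length estimates are
#' clamped to zero with the length moved to the sibling branch; the
#' number of clamped branches is recorded in the `"clamped"` attribute.
#' On additive distance matrices the generating topology and branch
#' lengths are recovered exactly.
#'
#' @param D symmetric distance matrix with taxon labels, or a
#'   [stats::dist].
#' @return an unrooted [ape::phylo] tree.
#' @export
neighborJoining <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  labs <- rownames(D)
  if (is.null(labs)) stop("distance matrix must carry taxon labels")
  if (any(abs(D - t(D)) > 1e-12) || any(diag(D) != 0) || any(D < 0))
    stop("distance matrix must be symmetric, non-negative, zero-diagonal")
  n <- length(labs)
  if (n < 3L) {
    warning("fewer than 3 taxa: returning degenerate tree")
    txt <- if (n == 1L) paste0("(", labs[1], ":0);")
           else sprintf("(%s:%.10g,%s:%.10g);", labs[1], D[1, 2] / 2,
                        labs[2], D[1, 2] / 2)
    return(ape::read.tree(text = txt))
  }
  ord <- order(labs)
  D <- D[ord, ord, drop = FALSE]
  node <- labs[ord]  # Newick fragment per active node
  clamped <- 0L
  fmt <- function(x) sprintf("%.15g", x)
  while (length(node) > 3L) {
    m <- length(node)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    tol <- 1e-12 * max(1, abs(qmin))
    # first minimal pair in (i < j) scan order = lexicographically
    # smallest pair under the maintained ordering
    pick <- NULL
    for (i in seq_len(m - 1L)) {
      js <- which(Q[i, (i + 1L):m] <= qmin + tol)
      if (length(js)) { pick <- c(i, i + js[1]); break }
    }
    i <- pick[1]; j <- pick[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { clamped <- clamped + 1L; lj <- D[i, j]; li <- 0 }
    if (lj < 0) { clamped <- clamped + 1L; li <- D[i, j]; lj <- 0 }
    newFrag <- sprintf("(%s:%s,%s:%s)", node[i], fmt(li), node[j], fmt(lj))
    dNew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dNew[keep]),
               c(dNew[keep], 0))
    node <- c(node[keep], newFrag)
  }
  dab <- D[1, 2]; dac <- D[1, 3]; dbc <- D[2, 3]
  la <- (dab + dac - dbc) / 2
  lb <- (dab + dbc - dac) / 2
  lc <- (dac + dbc - dab) / 2
  if (la < 0 || lb < 0 || lc < 0) {
    clamped <- clamped + sum(c(la, lb, lc) < 0)
    la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  }
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", node[1], fmt(la), node[2],
                 fmt(lb), node[3], fmt(lc))
  tr <- ape::read.tree(text = txt)
  attr(tr, "clamped") <- clamped
  tr
}

# non-trivial bipartitions of an unrooted tree as canonical keys
.bipartitions <- function(tr) {
  nt <- length(tr$tip.label)
  tipsBelow <- .tipsBelow(tr)
  internal <- setdiff(unique(tr$edge[, 2]), seq_len(nt))
  keys <- vapply(internal, function(nd) {
    side <- sort(tipsBelow[[nd - nt]])
    if (length(side) < 2L || length(side) > nt - 2L) return(NA_character_)
    all <- sort(tr$tip.label)
    if (all[1] %in% side) side <- setdiff(all, side)
    paste(sort(side), collapse = "|")
  }, character(1))
  names(keys) <- internal
  keys[!is.na(keys)]
}

# tip labels below each internal node (list indexed by node - ntip)
.tipsBelow <- function(tr) {
  nt <- length(tr$tip.label)
  nn <- tr$Nnode
  below <- vector("list", nn)
  edges <- tr$edge[order(-tr$edge[, 1]), , drop = FALSE]  # children first
  acc <- vector("list", nt + nn)
  for (t in seq_len(nt)) acc[[t]] <- tr$tip.label[t]
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1]; ch <- edges[e, 2]
    acc[[p]] <- c(acc[[p]], acc[[ch]])
  }
  for (k in seq_len(nn)) below[[k]] <- acc[[nt + k]]
  below
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree
#' for each replicate, and annotates each internal bipartition of the
#' full-data tree with the percentage of replicates containing it.
#' Supports are invariant to taxon input order because taxa are sorted
#' inside [neighborJoining()] and the resampling stream depends only on
#' the seed and the column count.
#'
#' @param seqs named character vector of aligned sequences (>= 2
#'   columns).
#' @param nReps number of bootstrap replicates (0 returns the tree
#'   without supports).
#' @param seed RNG seed for the resampling stream.
#' @param model distance model, passed to [distanceMatrix()].
#' @return the full-data [ape::phylo] tree; when `nReps > 0`,
#'   `node.label` holds integer supports in 0..100 (empty for the root).
#' @export
bootstrapSupport <- function(seqs, nReps = 1000L, seed = 1L,
                             model = c("poisson", "p")) {
  model <- match.arg(model)
  ncolA <- unique(nchar(seqs))
  if (length(ncolA) != 1L) stop("sequences must be aligned (equal length)")
  if (ncolA < 2L) stop("alignment needs at least 2 columns")
  full <- neighborJoining(distanceMatrix(seqs, model))
  if (nReps <= 0L) return(full)
  chars <- do.call(rbind, strsplit(seqs, ""))
  rownames(chars) <- names(seqs)
  keys0 <- .bipartitions(full)
  hits <- setNames(numeric(length(keys0)), unname(keys0))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  okReps <- 0L
  for (b in seq_len(nReps)) {
    cols <- sample.int(ncolA, ncolA, replace = TRUE)
    rs <- apply(chars[, cols, drop = FALSE], 1, paste, collapse = "")
    tr <- tryCatch(neighborJoining(distanceMatrix(rs, model)),
                   error = function(e) NULL)
    if (is.null(tr)) next
    okReps <- okReps + 1L
    kb <- .bipartitions(tr)
    found <- names(hits) %in% kb
    hits[found] <- hits[found] + 1
  }
  if (okReps == 0L) stop("no bootstrap replicate produced a tree")
  supp <- round(100 * hits / okReps)
  nt <- length(full$tip.label)
  lab <- rep("", full$Nnode)
  nodes <- as.integer(names(keys0))
  lab[nodes - nt] <- as.character(supp[match(unname(keys0),
                                             names(hits))])
  full$node.label <- lab
  full
}

#' Profile-anchored alignment of multi-repeat members
#'
#' Builds a deterministic alignment for tree construction: each member
#' contributes its repeat windows in order, each occupying one
#' profile-length block of columns; members with fewer repeats than the
#' deepest architecture are padded with gap blocks.  Distances computed
#' on this alignment use pairwise deletion, so padding is ignored.
#'
#' @param genes data.frame from [classifyGenes()] (typically restricted
#'   to the 3R/4R/5R subfamilies).
#' @param records proteome records holding the member transcripts.
#' @param profile the [MybProfile-class] used for scanning.
#' @return named character vector of aligned sequences (names are clean
#'   gene ids).
#' @export
repeatAlignment <- function(genes, records, profile) {
  if (nrow(genes) == 0L) stop("no genes to align")
  L <- profileLength(profile)
  res <- setNames(records$residues, records$raw_id)
  kmax <- max(genes$n_repeats)
  out <- vapply(seq_len(nrow(genes)), function(i) {
    iv <- strsplit(strsplit(genes$intervals[i], ";")[[1]], "-")
    seq <- res[[genes$transcript[i]]]
    blocks <- vapply(iv, function(se)
      substr(seq, as.integer(se[1]), as.integer(se[2])), character(1))
    paste(c(blocks, rep(strrep("-", L), kmax - length(blocks))),
          collapse = "")
  }, character(1))
  names(out) <- simplifyId(genes$gene_id)
  out
}
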