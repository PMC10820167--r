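#' Build a MYB repeat profile from a seed alignment
#'
#' Turns a gap-light alignment of repeat instances into a
#' position-specific log-odds profile.  Column frequencies receive a
#' background-proportional pseudocount,
#' `freq = (count + pseudocount * bg) / (n + pseudocount)`, and scores are
#' `log2(freq / bg)`.  Gap characters are treated as missing in the
#' column counts; `X` always scores 0.  The three canonical tryptophan
#' columns are the tryptophan-enriched columns (W frequency >=
#' `wEnrich`) with the highest W frequency, chosen greedily under the
#' constraint of being pairwise at least 15 columns apart.
#'
#' @param alignment character vector, [Biostrings::AAStringSet], or a
#'   records data.frame from [readFasta()]; all sequences must share one
#'   length in 50..53.
#' @param pseudocount pseudocount mass added per column.
#' @param background optional named background frequencies over the 20
#'   amino acids; defaults to the alignment's marginal composition
#'   (itself pseudocounted).
#' @param wEnrich minimum W column frequency for a column to count as
#'   tryptophan-enriched.
#' @return a [MybProfile-class] object (uncalibrated).
#' @export
buildProfile <- function(alignment, pseudocount = 1, background = NULL,
                         wEnrich = 0.5) {
  seqs <- if (is.data.frame(alignment)) alignment$residues
          else as.character(alignment)
  if (length(seqs) < 20L)
    stop("seed alignment needs at least 20 repeat instances")
  seqs <- toupper(seqs)
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("seed alignment sequences must have uniform length")
  if (L < 50L || L > 53L)
    stop("alignment length ", L, " outside the repeat range [50, 53]")
  chars <- matrix(unlist(strsplit(seqs, "")), nrow = length(seqs),
                  byrow = TRUE)
  chars[!(chars %in% .AA20) & chars != "-" & chars != "."] <- "X"
  counts <- apply(chars, 2, function(col)
    table(factor(col[col %in% .AA20], levels = .AA20)))
  counts <- matrix(as.numeric(counts), nrow = 20L,
                   dimnames = list(.AA20, NULL))
  if (is.null(background)) {
    marg <- rowSums(counts) + pseudocount
    background <- marg / sum(marg)
  } else {
    background <- background[.AA20]
    if (any(is.na(background)) || any(background <= 0))
      stop("background must give positive frequencies for all 20 residues")
    background <- background / sum(background)
  }
  ncol_eff <- colSums(counts)
  freq <- sweep(counts + pseudocount * background, 2,
                ncol_eff + pseudocount, "/")
  scores <- log2(freq / background)
  scores <- rbind(scores, X = 0)
  rownames(scores) <- .AAX

  wfreq <- counts["W", ] / pmax(ncol_eff, 1)
  cand <- order(wfreq, decreasing = TRUE)
  cand <- cand[wfreq[cand] >= wEnrich]
  trp <- integer(0)
  for (j in cand) {
    if (all(abs(j - trp) >= 15L)) trp <- c(trp, j)
    if (length(trp) == 3L) break
  }
  if (length(trp) < 3L)
    stop("fewer than three tryptophan-enriched columns ",
         "(>= 15 apart) in the seed alignment")
  new("MybProfile", scores = scores, background = background,
      trpCols = sort(as.integer(trp)))
}

# integer-encode a residue string against the 21-letter alphabet
.encode <- function(residues) {
  idx <- match(strsplit(residues, "")[[1]], .AAX)
  idx[is.na(idx)] <- 21L
  idx
}

# scores of every window of a single encoded sequence (vectorised over offsets)
.windowScores <- function(profile, enc) {
  L <- profileLength(profile)
  n <- length(enc) - L + 1L
  if (n < 1L) return(numeric(0))
  out <- numeric(n)
  sc <- profile@scores
  for (j in seq_len(L))
    out <- out + sc[cbind(enc[j:(j + n - 1L)], j)]
  out
}

#' Score one window of a sequence against the profile
#'
#' Sum over profile columns of the log-odds score of the observed
#' residue; `X` scores 0.
#'
#' @param profile a [MybProfile-class].
#' @param residues protein sequence (character scalar).
#' @param offset 1-based start of the window.
#' @return bit score (numeric scalar).
#' @export
scoreWindow <- function(profile, residues, offset = 1L) {
  L <- profileLength(profile)
  if (offset < 1L || offset + L - 1L > nchar(residues))
    stop("offset ", offset, " out of range for a ", L,
         "-column window on a ", nchar(residues), "-residue sequence")
  enc <- .encode(substr(residues, offset, offset + L - 1L))
  sum(profile@scores[cbind(enc, seq_len(L))])
}

#' Calibrate the profile's E-values against a null model
#'
#' Draws `nNull` i.i.d. background sequences, scores the best window of
#' each, and models the null score distribution as an empirical survival
#' function up to a tail knot (the `1 - tailFrac` quantile), continued
#' beyond the knot by a Gumbel fitted by censored maximum likelihood
#' (tail scores observed exactly, bulk scores censored at the knot) and
#' scaled to the empirical tail mass so the survival function is
#' continuous and monotone.  The E-value of a score `S` against a
#' database of `N` windows is `N * P(window score >= S)`.
#'
#' @param profile an uncalibrated [MybProfile-class].
#' @param nNull number of null sequences (>= 5000).
#' @param nullLength length of each null sequence; the default, the
#'   profile length, makes each null sequence one window.
#' @param seed RNG seed (calibration is the only stochastic step).
#' @param tailFrac fraction of null scores beyond the tail knot.
#' @return the calibrated `MybProfile`.
#' @export
calibrateEvalue <- function(profile, nNull = 10000L,
                            nullLength = profileLength(profile),
                            seed = 1L, tailFrac = 0.02) {
  stopifnot(is(profile, "MybProfile"))
  if (nNull < 5000L) stop("nNull must be at least 5000")
  L <- profileLength(profile)
  if (nullLength < L) stop("null sequences shorter than the profile")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  best <- vapply(seq_len(nNull), function(i) {
    enc <- sample.int(20L, nullLength, replace = TRUE,
                      prob = profile@background)
    max(.windowScores(profile, enc))
  }, numeric(1))
  best <- sort(best)
  tau <- unname(quantile(best, 1 - tailFrac, type = 7))
  tailScores <- best[best >= tau]
  nCens <- nNull - length(tailScores)
  nll <- function(p) {
    mu <- p[1]; beta <- exp(p[2])
    z <- (tailScores - mu) / beta
    zt <- (tau - mu) / beta
    -(-length(tailScores) * log(beta) - sum(z) - sum(exp(-z)) -
        nCens * exp(-zt))
  }
  beta0 <- sqrt(6) * sd(best) / pi
  fit <- optim(c(mean(best) - 0.5772 * beta0, log(beta0)), nll)
  beta <- exp(fit$par[2])
  if (!is.finite(beta) || beta <= 0)
    stop("degenerate Gumbel fit (non-positive scale)")
  profile@nullScores <- best
  profile@nullLength <- as.integer(nullLength)
  profile@tau <- tau
  profile@tailP <- length(tailScores) / nNull
  profile@evMu <- fit$par[1]
  profile@evBeta <- beta
  validObject(profile)
  profile
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# per-window null tail probability P(score >= s); vectorised over s
.windowTailP <- function(profile, s) {
  if (!isCalibrated(profile))
    stop("profile is not calibrated; run calibrateEvalue() first")
  ns <- profile@nullScores
  n <- length(ns)
  gumb <- function(x) -expm1(-exp(-(x - profile@evMu) / profile@evBeta))
  pTau <- gumb(profile@tau)
  p <- numeric(length(s))
  lo <- s <= profile@tau
  # empirical piece: fraction of null scores > s
  p[lo] <- 1 - findInterval(s[lo], ns) / n
  p[!lo] <- profile@tailP * gumb(s[!lo]) / pTau
  pmin(pmax(p, 0), 1)
}

#' E-value of a bit score
#'
#' @param profile a calibrated [MybProfile-class].
#' @param score bit score(s).
#' @param nWindows database size in windows.
#' @return expected number of false hits scoring at least `score` in a
#'   database of `nWindows` windows.
#' @export
evalueOf <- function(profile, score, nWindows) {
  nWindows * .windowTailP(profile, score)
}

# greedy overlap resolution: keep highest score (ties: smaller start)
.resolveOverlaps <- function(df) {
  if (nrow(df) <= 1L) return(df)
  ord <- order(-df$score, df$start)
  keep <- logical(nrow(df))
  taken_start <- integer(0)
  taken_end <- integer(0)
  for (i in ord) {
    if (!any(df$start[i] <= taken_end & df$end[i] >= taken_start)) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, df$start[i])
      taken_end <- c(taken_end, df$end[i])
    }
  }
  df[keep, , drop = FALSE]
}

#' Scan a proteome for MYB repeats
#'
#' Scores every window of every record, converts scores to E-values
#' against the scanned database size, keeps windows below the E-value
#' threshold, and resolves overlapping windows per transcript greedily by
#' descending score (ties broken by smaller start).  Scanning is
#' deterministic: all randomness lives in [calibrateEvalue()].
#'
#' @param profile a calibrated [MybProfile-class].
#' @param records data.frame from [readFasta()] or
#'   [generateProteome()].
#' @param evalueThreshold conditional E-value cutoff (default `1e-5`).
#' @param nWindows database size used for E-values; defaults to the total
#'   number of windows in `records`.
#' @return data.frame of domain hits: `transcript`, `start`, `end`
#'   (1-based inclusive envelope), `score`, `evalue`, `hasTrp` (conserved
#'   tryptophan within +/-1 of a canonical column), ordered by transcript
#'   then start.
#' @export
scanProteome <- function(profile, records, evalueThreshold = 1e-5,
                         nWindows = NULL) {
  stopifnot(is(profile, "MybProfile"))
  if (!isCalibrated(profile))
    stop("profile is not calibrated; run calibrateEvalue() first")
  L <- profileLength(profile)
  if (nrow(records) == 0L)
    return(.emptyHits())
  encs <- lapply(records$residues, .encode)
  if (is.null(nWindows))
    nWindows <- sum(pmax(lengths(encs) - L + 1L, 0L))
  hits <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    sc <- .windowScores(profile, encs[[i]])
    if (!length(sc)) next
    ev <- evalueOf(profile, sc, nWindows)
    pass <- which(ev < evalueThreshold)
    if (!length(pass)) next
    df <- data.frame(transcript = records$raw_id[i],
                     start = pass, end = pass + L - 1L,
                     score = sc[pass], evalue = ev[pass],
                     stringsAsFactors = FALSE)
    df <- .resolveOverlaps(df)
    df$hasTrp <- vapply(df$start, function(s)
      hasConservedTryptophan(substr(records$residues[i], s, s + L - 1L),
                             profile), logical(1))
    hits[[i]] <- df[order(df$start), , drop = FALSE]
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) .emptyHits() else { rownames(out) <- NULL; out }
}

.emptyHits <- function() {
  data.frame(transcript = character(0), start = integer(0),
             end = integer(0), score = numeric(0), evalue = numeric(0),
             hasTrp = logical(0), stringsAsFactors = FALSE)
}

#' Convert an ingested domtblout into scanner-compatible hits
#'
#' Allows real HMMER results to bypass the built-in scanner: rows are
#' filtered at the conditional E-value threshold, overlaps are resolved
#' with the same greedy rule, and the conserved-tryptophan flag is
#' evaluated on the envelope window, mapping canonical profile columns
#' through the row's `hmmFrom` coordinate.
#'
#' @param rows data.frame from [readDomtblout()].
#' @param records proteome records containing every target transcript.
#' @param profile a [MybProfile-class] (used for the tryptophan columns;
#'   calibration is not required).
#' @param evalueThreshold conditional E-value cutoff.
#' @param tolerance column tolerance for the tryptophan rule.
#' @return hits data.frame with the same columns as [scanProteome()].
#' @export
hitsFromDomtblout <- function(rows, records, profile,
                              evalueThreshold = 1e-5, tolerance = 1L) {
  rows <- rows[rows$cEvalue < evalueThreshold, , drop = FALSE]
  if (nrow(rows) == 0L) return(.emptyHits())
  missing <- setdiff(unique(rows$target), records$raw_id)
  if (length(missing))
    stop("domtblout targets absent from records: ",
         paste(missing, collapse = ", "))
  res <- setNames(records$residues, records$raw_id)
  out <- lapply(split(rows, rows$target), function(df) {
    d <- data.frame(transcript = df$target, start = df$envFrom,
                    end = df$envTo, score = df$score, evalue = df$cEvalue,
                    stringsAsFactors = FALSE)
    d$hmmFrom <- df$hmmFrom
    d <- .resolveOverlaps(d)
    seq <- res[[d$transcript[1]]]
    d$hasTrp <- vapply(seq_len(nrow(d)), function(i) {
      pos <- d$start[i] + (profile@trpCols - d$hmmFrom[i])
      pos <- unique(c(pos - tolerance, pos, pos + tolerance))
      pos <- pos[pos >= max(1L, d$start[i]) &
                 pos <= min(d$end[i], nchar(seq))]
      any(vapply(pos, function(p) substr(seq, p, p) == "W", logical(1)))
    }, logical(1))
    d$hmmFrom <- NULL
    d[order(d$start), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$transcript, out$start), , drop = FALSE]
}

#' The built-in MYB repeat profile
#'
#' Builds the profile from the seed alignment shipped with the package
#' (a synthetic stand-in alignment of 52-column repeat instances with the
#' canonical three-tryptophan architecture; see the package vignette).
#' The result is memoised per session.
#'
#' @param calibrate if `TRUE`, also run [calibrateEvalue()].
#' @param seed,nNull passed to [calibrateEvalue()] when calibrating.
#' @return a [MybProfile-class].
#' @export
mybProfile <- function(calibrate = FALSE, seed = 1L, nNull = 10000L) {
  if (is.null(.pkgCache$profile)) {
    path <- system.file("extdata", "myb_seed_alignment_synthetic.fasta",
                        package = "mybscan", mustWork = TRUE)
    .pkgCache$profile <- buildProfile(readFasta(path, species = "seed"))
  }
  prof <- .pkgCache$profile
  if (calibrate) prof <- calibrateEvalue(prof, nNull = nNull, seed = seed)
  prof
}

.pkgCache <- new.env(parent = emptyenv())
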