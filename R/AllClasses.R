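#' MybProfile: position-specific log-odds model of the MYB repeat
#'
#' An ungapped profile over the ~52-residue MYB repeat.  Scores are
#' log2-odds of the (pseudocounted) column frequency against a background
#' distribution; the three columns with the strongest tryptophan
#' enrichment, constrained to be at least 15 columns apart, are flagged as
#' the canonical tryptophan positions.  After [calibrateEvalue()] the
#' object also carries the null-score distribution used to convert bit
#' scores into E-values: an empirical survival function up to a tail knot,
#' continued beyond it by a censored maximum-likelihood Gumbel fit.
#'
#' @slot scores numeric matrix, 21 rows (20 amino acids plus X, which
#'   scores 0) by profile-length columns.
#' @slot background named numeric vector of 20 background frequencies.
#' @slot trpCols integer vector of the three canonical tryptophan columns.
#' @slot nullScores sorted numeric vector of null window scores (empty
#'   until calibrated).
#' @slot nullLength integer, length of the null sequences used.
#' @slot tau numeric, score knot where the empirical tail hands over to
#'   the Gumbel fit.
#' @slot tailP numeric, empirical P(score >= tau).
#' @slot evMu,evBeta numeric, location and scale of the censored Gumbel
#'   tail fit (NA until calibrated).
#'
#' @seealso [buildProfile()], [calibrateEvalue()], [scanProteome()]
#' @export
setClass("MybProfile",
  representation(
    scores = "matrix",
    background = "numeric",
    trpCols = "integer",
    nullScores = "numeric",
    nullLength = "integer",
    tau = "numeric",
    tailP = "numeric",
    evMu = "numeric",
    evBeta = "numeric"
  ),
  prototype(
    nullScores = numeric(0),
    nullLength = NA_integer_,
    tau = NA_real_,
    tailP = NA_real_,
    evMu = NA_real_,
    evBeta = NA_real_
  )
)

`%||%` <- function(a, b) if (is.null(a)) b else a

setValidity("MybProfile", function(object) {
  msg <- character(0)
  L <- ncol(object@scores)
  if (L < 50L || L > 53L)
    msg <- c(msg, sprintf("profile length %d outside [50, 53]", L))
  if (!identical(rownames(object@scores), .AAX))
    msg <- c(msg, "score rows must be the 20 amino acids plus X")
  if (any(!is.finite(object@scores)))
    msg <- c(msg, "profile scores must be finite")
  if (length(object@trpCols) != 3L)
    msg <- c(msg, "exactly three canonical tryptophan columns required")
  else if (min(diff(sort(object@trpCols))) < 15L)
    msg <- c(msg, "canonical tryptophan columns must be pairwise >= 15 apart")
  if (!is.na(object@evBeta) && object@evBeta <= 0)
    msg <- c(msg, "Gumbel scale must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn MybProfile number of profile columns
#' @param x,object a `MybProfile`
#' @export
profileLength <- function(x) ncol(x@scores)

#' @describeIn MybProfile canonical tryptophan column indices
#' @export
trpColumns <- function(x) x@trpCols

#' @describeIn MybProfile has [calibrateEvalue()] been run?
#' @export
isCalibrated <- function(x) is.finite(x@evBeta)

#' @describeIn MybProfile maximum attainable window score
#' @export
maxScore <- function(x) sum(apply(x@scores, 2, max))

#' @describeIn MybProfile consensus (per-column argmax) residue string
#' @export
consensusSeq <- function(x) {
  paste(rownames(x@scores)[apply(x@scores, 2, which.max)], collapse = "")
}

setMethod("show", "MybProfile", function(object) {
  cat(sprintf("MybProfile: %d columns, tryptophan columns %s\n",
              profileLength(object),
              paste(object@trpCols, collapse = ", ")))
  cat(sprintf("  max window score: %.1f bits\n", maxScore(object)))
  if (isCalibrated(object)) {
    cat(sprintf("  E-value calibration: %d null windows, tail knot %.2f bits (Gumbel mu=%.2f, beta=%.2f)\n",
                length(object@nullScores), object@tau, object@evMu, object@evBeta))
  } else {
    cat("  E-value calibration: none (run calibrateEvalue())\n")
  }
  invisible(object)
})

#' FamilyCountTable: per-species MYB subfamily census
#'
#' Per-species counts of family members by subfamily.  Following the
#' field's reporting convention, R-R-type members (two widely separated
#' repeats) are folded into the 1R column and the rare 5-repeat members
#' are counted inside the 4R column but flagged separately.
#'
#' @slot counts integer matrix, species rows by columns `1R`, `2R`, `3R`,
#'   `4R` (the `4R` column includes 5-repeat members).
#' @slot fiveR named integer vector, number of 5-repeat members per species.
#'
#' @seealso [tabulateFamily()]
#' @export
setClass("FamilyCountTable",
  representation(counts = "matrix", fiveR = "integer")
)

setValidity("FamilyCountTable", function(object) {
  msg <- character(0)
  if (!identical(colnames(object@counts), c("1R", "2R", "3R", "4R")))
    msg <- c(msg, "count columns must be 1R, 2R, 3R, 4R")
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    msg <- c(msg, "counts must be non-negative integers")
  rn <- rownames(object@counts)
  if (!identical(as.character(names(object@fiveR) %||% character(0)),
                 as.character(rn %||% character(0))))
    msg <- c(msg, "fiveR names must match species rows")
  if (any(object@fiveR > object@counts[, "4R"]))
    msg <- c(msg, "5R members are counted within the 4R column")
  if (length(msg)) msg else TRUE
})

#' @describeIn FamilyCountTable per-species totals (sum over subfamilies)
#' @param x,object a `FamilyCountTable`
#' @export
speciesTotals <- function(x) rowSums(x@counts)

#' @describeIn FamilyCountTable total member count over all species
#' @export
grandTotal <- function(x) sum(x@counts)

#' @describeIn FamilyCountTable per-species 5-repeat member counts
#' @export
fiveRCounts <- function(x) x@fiveR

#' @describeIn FamilyCountTable subfamily count matrix
#' @export
familyCounts <- function(x) x@counts

setMethod("show", "FamilyCountTable", function(object) {
  cc <- object@counts
  fourR <- ifelse(object@fiveR > 0,
                  ifelse(cc[, "4R"] - object@fiveR > 0,
                         sprintf("%d + %d *", cc[, "4R"] - object@fiveR, object@fiveR),
                         sprintf("%d *", object@fiveR)),
                  as.character(cc[, "4R"]))
  df <- data.frame(Total = rowSums(cc), `1R` = cc[, "1R"], `2R` = cc[, "2R"],
                   `3R` = cc[, "3R"], `4R` = fourR, check.names = FALSE,
                   row.names = rownames(cc))
  cat("FamilyCountTable (", nrow(cc), " species, grand total ",
      sum(cc), ")\n", sep = "")
  print(df)
  cat("* indicates members with 5 conserved MYB repeats\n")
  invisible(object)
})

#' Export a FamilyCountTable as a data.frame
#'
#' @param x a `FamilyCountTable`
#' @return data.frame with species, subfamily columns, 5R flag column and
#'   per-species totals.
#' @export
asCensusFrame <- function(x) {
  stopifnot(is(x, "FamilyCountTable"))
  cc <- x@counts
  data.frame(
    species = rownames(cc),
    total = unname(rowSums(cc)),
    oneR = unname(cc[, "1R"]),
    twoR = unname(cc[, "2R"]),
    threeR = unname(cc[, "3R"]),
    fourR = unname(cc[, "4R"] - x@fiveR),
    fiveR = unname(x@fiveR),
    stringsAsFactors = FALSE
  )
}
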