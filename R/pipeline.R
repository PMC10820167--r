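#' Pipeline configuration
#'
#' Collects every run-level constant of the census and screening
#' pipeline in one validated object.  Each stage takes either real
#' inputs (file paths) or a synthetic spec, never both.
#'
#' @param fasta,gff optional protein FASTA and GFF3 paths.
#' @param domtblout optional HMMER per-domain table; when given, the
#'   built-in scanner is bypassed.
#' @param counts,sampleSheet optional count-matrix and sample-sheet
#'   paths.
#' @param proteome optional [proteomeSpec()] (alternative to
#'   `fasta`/`gff`).
#' @param countsSpec optional [countSpec()] (alternative to
#'   `counts`/`sampleSheet`).
#' @param evalueThreshold conditional E-value cutoff (default `1e-5`).
#' @param spacingThreshold 2R spacing rule in residues (default 10).
#' @param pThreshold,lfcThreshold DEG screening thresholds (defaults
#'   0.05 and 1).
#' @param bootstrapReps bootstrap replicates for trees (default 1000).
#' @param seed master seed for calibration and synthetic stages.
#' @param outDir optional output directory; when set, stages write
#'   their intermediates there.
#' @return a validated `myb_pipeline_config` list.
#' @export
pipelineConfig <- function(fasta = NULL, gff = NULL, domtblout = NULL,
                           counts = NULL, sampleSheet = NULL,
                           proteome = NULL, countsSpec = NULL,
                           evalueThreshold = 1e-5,
                           spacingThreshold = 10L, pThreshold = 0.05,
                           lfcThreshold = 1, bootstrapReps = 1000L,
                           seed = 1L, outDir = NULL) {
  stopifnot(evalueThreshold > 0, spacingThreshold > 0, pThreshold > 0,
            lfcThreshold > 0, bootstrapReps >= 0)
  if (!is.null(proteome) && (!is.null(fasta) || !is.null(gff)))
    stop("give either fasta/gff paths or a proteome spec, not both")
  if (!is.null(countsSpec) && !is.null(counts))
    stop("give either a counts path or a counts spec, not both")
  if (is.null(proteome) && xor(is.null(fasta), is.null(gff)))
    stop("fasta and gff must be given together")
  if (is.null(countsSpec) && xor(is.null(counts), is.null(sampleSheet)))
    stop("counts and sampleSheet must be given together")
  structure(list(fasta = fasta, gff = gff, domtblout = domtblout,
                 counts = counts, sampleSheet = sampleSheet,
                 proteome = proteome, countsSpec = countsSpec,
                 evalueThreshold = evalueThreshold,
                 spacingThreshold = as.integer(spacingThreshold),
                 pThreshold = pThreshold, lfcThreshold = lfcThreshold,
                 bootstrapReps = as.integer(bootstrapReps),
                 seed = as.integer(seed), outDir = outDir),
            class = "myb_pipeline_config")
}

.stageLog <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the family census stage
#'
#' Scan (or ingest a domtblout), identify, de-duplicate, classify and
#' tabulate.  With `outDir` set, hits, per-gene labels and the census
#' are written as TSVs; the run is deterministic given the config, so
#' reruns reproduce the outputs byte for byte.
#'
#' @param config a [pipelineConfig()] with proteome inputs.
#' @param profile optional pre-calibrated [MybProfile-class]; by default
#'   the built-in profile is calibrated with the config seed.
#' @return list with `census` (a [FamilyCountTable-class]), `genes`
#'   (per-gene labels), and `hits`.
#' @export
runFamilyCensus <- function(config, profile = NULL) {
  stopifnot(inherits(config, "myb_pipeline_config"))
  if (is.null(config$proteome) && is.null(config$fasta))
    stop("census stage: config has neither proteome spec nor fasta/gff")
  if (is.null(profile))
    profile <- mybProfile(calibrate = is.null(config$domtblout),
                          seed = config$seed)
  if (is.null(config$proteome)) {
    records <- tryCatch(readFasta(config$fasta),
                        error = function(e)
                          stop("census stage [read_fasta]: ",
                               conditionMessage(e)))
    geneMap <- tryCatch(readGffGeneMap(config$gff),
                        error = function(e)
                          stop("census stage [read_gff]: ",
                               conditionMessage(e)))
  } else {
    prot <- generateProteome(config$proteome, profile)
    records <- prot$records
    geneMap <- truthGeneMap(prot)
  }
  .stageLog("scan", "E-value threshold %g, spacing threshold %d aa",
            config$evalueThreshold, config$spacingThreshold)
  hits <- if (is.null(config$domtblout)) {
    scanProteome(profile, records, config$evalueThreshold)
  } else {
    hitsFromDomtblout(readDomtblout(config$domtblout), records, profile,
                      config$evalueThreshold)
  }
  genes <- classifyGenes(hits, geneMap, records, config$spacingThreshold)
  census <- tabulateFamily(genes)
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    write.table(hits, file.path(config$outDir, "domain_hits.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeGeneLabels(genes, file.path(config$outDir, "gene_labels.tsv"))
    writeCensus(census, file.path(config$outDir, "family_census.tsv"))
  }
  .stageLog("census", "%d member genes across %d species",
            nrow(genes), nrow(familyCounts(census)))
  list(census = census, genes = genes, hits = hits)
}

#' Run the differential-expression screen stage
#'
#' @param config a [pipelineConfig()] with count inputs.
#' @return list with `results` (full [waldTest()] table), `up`, `down`,
#'   and `truth` (planted fold changes, synthetic runs only).
#' @export
runDegScreen <- function(config) {
  stopifnot(inherits(config, "myb_pipeline_config"))
  truth <- NULL
  if (!is.null(config$countsSpec)) {
    sim <- generateCounts(config$countsSpec)
    se <- sim$se
    truth <- sim$truth
  } else if (!is.null(config$counts)) {
    se <- readCounts(config$counts, config$sampleSheet)
  } else {
    stop("deg stage: config has neither counts path nor counts spec")
  }
  .stageLog("deg", "p < %g, |log2FC| > %g, %d x %d design",
            config$pThreshold, config$lfcThreshold,
            sum(se$group == "drought"), sum(se$group == "control"))
  results <- waldTest(se, pThreshold = config$pThreshold,
                      lfcThreshold = config$lfcThreshold)
  lists <- screenDegs(results, config$pThreshold, config$lfcThreshold)
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    writeDeResults(results, file.path(config$outDir, "de_results.tsv"))
    writeLines(lists$up$gene_id, file.path(config$outDir, "up_genes.txt"))
    writeLines(lists$down$gene_id,
               file.path(config$outDir, "down_genes.txt"))
  }
  c(list(results = results), lists, list(truth = truth))
}

#' Cross-tabulate DEG verdicts by subfamily
#'
#' Joins DE verdicts with per-gene subfamily labels and reports DEG
#' counts by direction and subfamily, plus the most significant member
#' per direction (minimum p-value, ties broken by larger |log2 fold
#' change|).
#'
#' @param results data.frame from [waldTest()].
#' @param labels data.frame with `gene_id` and `subfamily` (e.g. from
#'   [classifyGenes()]).
#' @param pThreshold,lfcThreshold screening thresholds.
#' @return list with `summary` (direction x subfamily counts) and `top`
#'   (one row per direction).
#' @export
runDegSummary <- function(results, labels, pThreshold = 0.05,
                          lfcThreshold = 1) {
  orphans <- setdiff(results$gene_id, labels$gene_id)
  if (length(orphans))
    stop("DE results without subfamily labels: ",
         paste(sort(orphans), collapse = ", "))
  lists <- screenDegs(results, pThreshold, lfcThreshold)
  sub <- setNames(labels$subfamily, labels$gene_id)
  lv <- c("1R", "1R-RR", "2R", "3R", "4R", "5R")
  rows <- lapply(c(up = "up", down = "down"), function(dir) {
    df <- lists[[dir]]
    tab <- table(factor(sub[df$gene_id], levels = lv))
    data.frame(direction = dir, subfamily = lv,
               n = as.integer(tab), stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  summary <- summary[summary$n > 0, , drop = FALSE]
  rownames(summary) <- NULL
  top <- do.call(rbind, lapply(c("up", "down"), function(dir) {
    df <- lists[[dir]]
    if (nrow(df) == 0L) return(NULL)
    best <- df[order(df$pvalue, -abs(df$log2fc)), ][1, ]
    data.frame(direction = dir, gene_id = best$gene_id,
               subfamily = unname(sub[best$gene_id]),
               log2fc = best$log2fc, pvalue = best$pvalue,
               stringsAsFactors = FALSE)
  }))
  list(summary = summary, top = top)
}
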