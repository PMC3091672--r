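#' Run the SuperSAGE analysis pipeline end-to-end
#'
#' Orchestrates the stages simulate -> extract -> detest (differential
#' expression) -> annotate -> cluster -> enrich on a synthetic experiment.
#' Each stage consumes the previous stage's artifact; requesting a stage
#' whose prerequisite is toggled off raises an error naming the missing
#' artifact.  When `outDir` is given, every artifact is also written as a TSV
#' whose header records the package version, the seed and the configuration
#' hash, so a rerun with the same configuration is byte-identical.
#'
#' @param config a \linkS4class{SimulationConfig}; its seed drives every
#'   source of randomness.
#' @param stages subset of c("simulate", "extract", "detest", "annotate",
#'   "cluster", "enrich").
#' @param outDir optional output directory for TSV artifacts.
#' @param alpha,minFold,zeroSub differential-expression parameters.
#' @param stringency annotation stringency (26 or 24).
#' @param fdr enrichment FDR threshold.
#' @param kRange,gapB clustering model-selection parameters.
#' @return a list of stage artifacts: `sim`, `reads`, `demux`, `extracted`,
#'   `librarySummary`, `de`, `annotation`, `annotationSummary`, `clusters`
#'   (lowca/h12 models + gap results + cross-tabulation), `enrichment`,
#'   and `log` (per-stage record counts).
#' @export
runPipeline <- function(config,
                        stages = c("simulate", "extract", "detest",
                                   "annotate", "cluster", "enrich"),
                        outDir = NULL, alpha = 0.05, minFold = 2,
                        zeroSub = 0.345, stringency = 26, fdr = 0.01,
                        kRange = 1:8, gapB = 50L) {
  stages <- match.arg(stages, several.ok = TRUE)
  res <- list(log = list())
  need <- function(stage, artifact, what) {
    if (is.null(artifact))
      stop("stage '", stage, "' requires the '", what,
           "' artifact; enable its stage first")
    artifact
  }
  comments <- function()
    c(paste("sagexpr", as.character(packageVersion("sagexpr"))),
      paste("seed", config@seed))
  emit <- function(df, name) {
    if (!is.null(outDir)) {
      dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
      writeTsv(as.data.frame(df), file.path(outDir, paste0(name, ".tsv")),
               comments())
    }
  }

  if ("simulate" %in% stages) {
    res$sim <- generateCountMatrix(config)
    res$reads <- generateDitagReads(config, res$sim$counts)
    res$log$simulate <- c(tags = nrow(res$sim$counts),
                          reads = nrow(res$reads$reads))
    emit(data.frame(tag = tagSequences(res$sim$counts),
                    tagCounts(res$sim$counts), check.names = FALSE),
         "counts_truth")
  }
  if ("extract" %in% stages) {
    reads <- need("extract", res$reads, "reads")
    res$demux <- demultiplexReads(reads$reads,
                                  setNames(config@linkers,
                                           config@libraryNames))
    res$extracted <- extractMonotags(res$demux, config@libraryNames)
    res$librarySummary <- summarizeLibraries(res$extracted)
    res$log$extract <- c(table(res$demux$qcStatus))
    emit(res$librarySummary, "library_summary")
    if (!is.null(outDir))
      writeTagCountMatrix(res$extracted,
                          file.path(outDir, "counts_extracted.tsv"),
                          comments())
  }
  if ("detest" %in% stages) {
    counts <- if (!is.null(res$extracted)) res$extracted else
      (if (!is.null(res$sim)) res$sim$counts else NULL)
    counts <- need("detest", counts, "counts")
    res$de <- classifyTags(counts, alpha = alpha, minFold = minFold,
                           zeroSub = zeroSub)
    res$log$detest <- c(tested = nrow(res$de),
                        retained = sum(res$de$retained))
    emit(res$de, "differential_expression")
  }
  if ("annotate" %in% stages) {
    de <- need("annotate", res$de, "differential_expression")
    sim <- need("annotate", res$sim, "simulated reference")
    ref <- generateReference(config)
    res$reference <- ref
    res$annotation <- annotateTags(de$tag[de$retained], ref,
                                   stringency = stringency)
    res$annotationSummary <- annotationSummary(res$annotation)
    res$log$annotate <- c(annotated = sum(res$annotation$status !=
                                            "unannotated"))
    emit(res$annotation, "annotation")
  }
  if ("cluster" %in% stages) {
    de <- need("cluster", res$de, "differential_expression")
    counts <- if (!is.null(res$extracted)) res$extracted else res$sim$counts
    mk <- function(an) {
      sel <- selectClusterTags(de, counts, an)
      if (nrow(sel) < 2L) return(NULL)
      prof <- normalizeProfiles(sel)
      gap <- gapStatistic(prof, kRange = kRange, B = gapB,
                          seed = config@seed + 10L)
      model <- chisqKmeans(prof, selectedK(gap), seed = config@seed + 11L)
      list(profiles = prof, gap = gap, model = model)
    }
    res$clusters <- list(lowca = mk("lowca"), h12 = mk("12h"))
    if (!is.null(res$clusters$lowca) && !is.null(res$clusters$h12)) {
      res$clusters$crossTab <- crossTabulate(res$clusters$lowca$model,
                                             res$clusters$h12$model)
      res$clusters$sizes <- summarizeClusters(
        list(res$clusters$lowca$model, res$clusters$h12$model))
    }
    res$log$cluster <- c(
      lowca = if (!is.null(res$clusters$lowca))
        length(clusterAssignments(res$clusters$lowca$model)) else 0L,
      h12 = if (!is.null(res$clusters$h12))
        length(clusterAssignments(res$clusters$h12$model)) else 0L)
    if (!is.null(res$clusters$lowca))
      emit(data.frame(tag = names(clusterAssignments(
        res$clusters$lowca$model)),
        cluster = clusterAssignments(res$clusters$lowca$model)),
        "clusters_lowca")
  }
  if ("enrich" %in% stages) {
    ann <- need("enrich", res$annotation, "annotation")
    de <- need("enrich", res$de, "differential_expression")
    counts <- if (!is.null(res$extracted)) res$extracted else res$sim$counts
    goMap <- goAnnotationMap(ann)
    bgAll <- buildBackground(goMap, counts, c("C2h", "C12h"))
    bg12 <- buildBackground(goMap, counts, "C12h")
    inBg <- function(tags, bg) intersect(tags, names(goMap))
    lowcaTags <- rownames(selectClusterTags(de, counts, "lowca"))
    h12Tags <- rownames(selectClusterTags(de, counts, "12h"))
    res$enrichment <- list(
      lowca = enrichTags(inBg(lowcaTags, bgAll), goMap, bgAll, fdr = fdr),
      h12 = enrichTags(inBg(h12Tags, bg12), goMap, bg12, fdr = fdr))
    res$log$enrich <- c(
      lowcaEnriched = sum(res$enrichment$lowca$enriched),
      h12Enriched = sum(res$enrichment$h12$enriched))
    emit(res$enrichment$lowca, "enrichment_lowca")
    emit(res$enrichment$h12, "enrichment_12h")
  }
  res
}
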