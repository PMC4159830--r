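## End-to-end trio pipeline: reads (or a simulation block) -> clean tags ->
## virtual library -> mapping -> expression -> DE -> gene action ->
## presence/PAV -> enrichment, with TSV outputs and a stderr run log.

#' Assemble and validate a pipeline configuration
#'
#' Either supply the three read files plus a reference, or a
#' \code{simulation} block (exactly one of the two).  Thresholds default to
#' the published rule (FDR <= 0.001, |log2 ratio| >= 1, presence floor 1
#' tag, 1 mismatch).
#'
#' @param reference FASTA path or \link[Biostrings]{DNAStringSet}.
#' @param geneMap gene-map TSV path or data.frame.
#' @param reads named list/vector of read files (\code{P}, \code{M},
#'   \code{F1}).
#' @param simulation list: \code{n_genes}, \code{depth}, and optionally
#'   \code{mode_proportions}, \code{tpm_range}, \code{fold_effect},
#'   \code{error_rate}, \code{antisense_fraction}, \code{frac_no_catg},
#'   \code{length_range}, \code{gc}.
#' @param annotation optional annotation TSV path or data.frame.
#' @param pav optional PAV TSV path or data.frame.
#' @param fdrThreshold,lfcThreshold,presenceMinCount,maxMismatch thresholds.
#' @param pseudoTags,lambda,adaptor3 further options.
#' @param seed integer seed driving every stochastic step.
#' @return validated config (list) for \code{\link{runPipeline}}.
#' @export
pipelineConfig <- function(reference = NULL, geneMap = NULL, reads = NULL,
                           simulation = NULL, annotation = NULL, pav = NULL,
                           fdrThreshold = 0.001, lfcThreshold = 1,
                           presenceMinCount = 1, maxMismatch = 1,
                           pseudoTags = 0.5, lambda = 0.5,
                           adaptor3 = DEFAULT_ADAPTOR3, seed = 1) {
  if (is.null(reads) == is.null(simulation)) {
    stop("supply exactly one of 'reads' and 'simulation'", call. = FALSE)
  }
  if (!is.null(reads)) {
    reads <- as.list(reads)
    if (!all(c("P", "M", "F1") %in% names(reads))) {
      stop("'reads' must name files for P, M and F1", call. = FALSE)
    }
    if (is.null(reference) || is.null(geneMap)) {
      stop("'reference' and 'geneMap' are required with real reads",
           call. = FALSE)
    }
  }
  assertScalarNumber(fdrThreshold, "fdrThreshold", 0, 1)
  assertScalarNumber(lfcThreshold, "lfcThreshold", 0, Inf)
  assertScalarNumber(presenceMinCount, "presenceMinCount", 1, Inf)
  if (!maxMismatch %in% c(0, 1)) stop("'maxMismatch' must be 0 or 1",
                                      call. = FALSE)
  list(reference = reference, geneMap = geneMap, reads = reads,
       simulation = simulation, annotation = annotation, pav = pav,
       fdrThreshold = fdrThreshold, lfcThreshold = lfcThreshold,
       presenceMinCount = presenceMinCount, maxMismatch = maxMismatch,
       pseudoTags = pseudoTags, lambda = lambda, adaptor3 = adaptor3,
       seed = as.integer(seed))
}

#' Load a pipeline configuration from a YAML file
#' @param path YAML file whose keys mirror the \code{\link{pipelineConfig}}
#'   arguments (snake_case accepted).
#' @return validated config list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  snake <- c(fdr_threshold = "fdrThreshold", lfc_threshold = "lfcThreshold",
             presence_min_count = "presenceMinCount",
             max_mismatch = "maxMismatch", pseudo_tags = "pseudoTags",
             gene_map = "geneMap")
  names(y) <- ifelse(names(y) %in% names(snake), snake[names(y)], names(y))
  do.call(pipelineConfig, y)
}

logmsg <- function(...) message("[heterosisDGE] ", ...)

#' Run the full trio analysis pipeline
#'
#' Sequences all stages and writes the result bundle as TSV files (plus a
#' stderr run log with per-stage tag accounting).  Deterministic for a
#' fixed config and seed.
#'
#' @param config from \code{\link{pipelineConfig}} or
#'   \code{\link{readPipelineConfig}}.
#' @param outDir output directory (created if missing); \code{NULL} skips
#'   file output.
#' @return (invisibly) a list: \code{expression}
#'   (\linkS4class{DgeExperiment}), \code{cleaning}, \code{mapping},
#'   \code{strand}, \code{geneAction}, \code{presence},
#'   \code{presenceSummary}, \code{pav}, \code{enrichment}, \code{truth}
#'   (simulation only).
#' @export
runPipeline <- function(config, outDir = NULL) {
  seed <- config$seed
  logmsg("seed = ", seed,
         "; thresholds: fdr <= ", config$fdrThreshold,
         ", |log2 ratio| >= ", config$lfcThreshold,
         ", presence >= ", config$presenceMinCount, " tag(s)",
         ", mismatches <= ", config$maxMismatch)
  truth <- NULL
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    logmsg("simulating ", sim$n_genes, " genes at depth ", sim$depth)
    txome <- simulateTranscriptome(
      nGenes = sim$n_genes,
      lengthRange = sim$length_range %||% c(300L, 3000L),
      gc = sim$gc %||% 0.47,
      fracNoCatg = sim$frac_no_catg %||% 0.05, seed = seed)
    truth <- assignGeneActionProfiles(
      txome$genes,
      modeProportions = unlist(sim$mode_proportions) %||%
        defaultModeProportions(),
      tpmRange = sim$tpm_range %||% c(20, 2000),
      foldEffect = sim$fold_effect %||% 4, seed = seed + 1L)
    trio <- simulateTrio(truth, txome, depth = sim$depth,
                         errorRate = sim$error_rate %||% 0.01,
                         antisenseFraction = sim$antisense_fraction %||% 0.05,
                         seed = seed + 2L, adaptor3 = config$adaptor3)
    reads <- lapply(trio, `[[`, "reads")
    reference <- txome$sequences
    geneMap <- txome$geneMap
  } else {
    reference <- if (is.character(config$reference)) {
      readReferenceFasta(config$reference)
    } else config$reference
    geneMap <- if (is.character(config$geneMap)) {
      readGeneMap(config$geneMap)
    } else config$geneMap
    reads <- lapply(config$reads, readTagReads)
  }
  cleaning <- lapply(reads, extractCleanTags, adaptor3 = config$adaptor3)
  for (l in names(cleaning)) {
    logmsg(l, ": ", rawTotal(cleaning[[l]]), " reads -> ",
           cleanTotal(cleaning[[l]]), " clean tags (",
           nTags(cleaning[[l]]), " distinct)")
  }
  lib <- buildVirtualLibrary(reference, geneMap)
  logmsg("virtual library: ", nTags(lib), " CATG+17 keys")
  mapping <- lapply(cleaning, mapTags, library = lib,
                    maxMismatch = config$maxMismatch)
  for (l in names(mapping)) {
    s <- mapping[[l]]$summary
    logmsg(l, ": mapped total ", s["all_mapped", "total"],
           " (unambiguous ", s["unambiguous", "total"],
           ", unknown ", s["unknown", "total"], ")")
  }
  se <- buildExpressionSet(mapping,
                           vapply(cleaning, cleanTotal, numeric(1)),
                           geneMap)
  strand <- lapply(mapping, function(m) strandReport(m$assignments))
  ga <- callGeneAction(se, fdrThreshold = config$fdrThreshold,
                       lfcThreshold = config$lfcThreshold,
                       pseudoTags = config$pseudoTags)
  logmsg("differential universe: ", nrow(ga$calls), " genes")
  presence <- classifyPresence(se, minCount = config$presenceMinCount)
  presSum <- presenceSummary(presence)
  pav <- NULL
  if (!is.null(config$pav)) {
    pavList <- if (is.character(config$pav)) readPavList(config$pav)
               else config$pav
    pav <- pavCrossref(presence, se, pavList, geneAction = ga$calls)
  }
  enrichment <- NULL
  if (!is.null(config$annotation)) {
    ann <- if (is.character(config$annotation)) {
      readAnnotation(config$annotation)
    } else config$annotation
    universe <- collectivelyExpressed(se, config$presenceMinCount)
    sets <- list(
      F1vP = ga$contrasts$F1vP$gene_id[ga$contrasts$F1vP$significant],
      F1vM = ga$contrasts$F1vM$gene_id[ga$contrasts$F1vM$significant])
    sets$union <- unique(c(sets$F1vP, sets$F1vM))
    enrichment <- lapply(sets, function(g) {
      if (!length(g)) return(NULL)
      enrichTerms(g, ann, universe, lambda = config$lambda)
    })
  }
  bundle <- list(expression = se, cleaning = cleaning, mapping = mapping,
                 strand = strand, geneAction = ga, presence = presence,
                 presenceSummary = presSum, pav = pav,
                 enrichment = enrichment, truth = truth)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeExpressionTable(se, file.path(outDir, "expression_table.tsv"))
    for (nm in names(ga$contrasts)) {
      writeTsv(ga$contrasts[[nm]],
               file.path(outDir, paste0("de_", nm, ".tsv")))
    }
    writeTsv(ga$calls, file.path(outDir, "gene_action_calls.tsv"))
    writeTsv(ga$summary, file.path(outDir, "gene_action_summary.tsv"))
    writeTsv(presence, file.path(outDir, "presence_calls.tsv"))
    ps <- cbind(row = rownames(presSum$table), presSum$table)
    writeTsv(ps, file.path(outDir, "presence_summary.tsv"))
    mp <- do.call(rbind, lapply(names(mapping), function(l) {
      cbind(library = l, class = rownames(mapping[[l]]$summary),
            mapping[[l]]$summary)
    }))
    writeTsv(mp, file.path(outDir, "mapping_summary.tsv"))
    sr <- do.call(rbind, lapply(names(strand), function(l) {
      data.frame(library = l, n_sense = strand[[l]]$n_sense,
                 n_antisense = strand[[l]]$n_antisense,
                 n_both = strand[[l]]$n_both, ratio = strand[[l]]$ratio)
    }))
    writeTsv(sr, file.path(outDir, "strand_report.tsv"))
    if (!is.null(truth)) writeTsv(truth, file.path(outDir, "truth.tsv"))
    if (!is.null(pav)) writeTsv(pav$report,
                                file.path(outDir, "pav_report.tsv"))
    if (!is.null(enrichment)) {
      for (nm in names(enrichment)) {
        if (!is.null(enrichment[[nm]])) {
          writeTsv(enrichment[[nm]],
                   file.path(outDir, paste0("enrichment_", nm, ".tsv")))
        }
      }
    }
    logmsg("bundle written to ", outDir)
  }
  invisible(bundle)
}
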