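#' Score recovery of injected DMRs
#'
#' Matches called DMRs to ground-truth injected intervals by >= 1-nt
#' overlap with matching context and type. Recall is the fraction of truth
#' intervals hit by at least one matching DMR; precision the fraction of
#' called DMRs hitting a truth interval. For each recovered truth interval
#' the best-overlapping DMR's start/end displacements give the boundary
#' errors.
#'
#' @param dmrs \code{GRanges} from [callDmrs()].
#' @param truth data.frame of injected intervals (from
#'   [sampleInjections()]).
#' @return list: \code{nTruth}, \code{nCalled}, \code{recall},
#'   \code{precision}, \code{meanBoundaryError}, \code{maxBoundaryError}
#'   (bp; NA when nothing is recovered).
#' @export
scoreDmrRecovery <- function(dmrs, truth) {
  nT <- nrow(truth); nC <- length(dmrs)
  if (nT == 0L)
    return(list(nTruth = 0L, nCalled = nC, recall = NA_real_,
                precision = if (nC) 0 else NA_real_,
                meanBoundaryError = NA_real_, maxBoundaryError = NA_real_))
  tg <- GenomicRanges::GRanges(truth$chrom,
                               IRanges::IRanges(truth$start, truth$end))
  mc <- S4Vectors::mcols(dmrs)
  hitT <- rep(FALSE, nT); hitC <- rep(FALSE, nC)
  errs <- c()
  for (i in seq_len(nT)) {
    cand <- which(mc$context == truth$context[i] &
                    mc$type == truth$type[i])
    if (!length(cand)) next
    ov <- GenomicRanges::findOverlaps(tg[i], dmrs[cand], minoverlap = 1L,
                                      ignore.strand = TRUE)
    j <- cand[S4Vectors::subjectHits(ov)]
    if (!length(j)) next
    hitT[i] <- TRUE; hitC[j] <- TRUE
    ovw <- GenomicRanges::width(IRanges::pintersect(
      rep(GenomicRanges::ranges(tg[i]), length(j)),
      GenomicRanges::ranges(dmrs[j])))
    best <- j[which.max(ovw)]
    errs <- c(errs,
              abs(GenomicRanges::start(dmrs[best]) - truth$start[i]),
              abs(GenomicRanges::end(dmrs[best]) - truth$end[i]))
  }
  ## called DMRs overlapping any truth interval (any context/type) are not
  ## counted as false positives of the injection experiment
  if (nC) {
    anyOv <- GenomicRanges::findOverlaps(dmrs, tg, minoverlap = 1L,
                                         ignore.strand = TRUE)
    hitC[unique(S4Vectors::queryHits(anyOv))] <- TRUE
  }
  list(nTruth = nT, nCalled = nC,
       recall = mean(hitT),
       precision = if (nC) mean(hitC) else NA_real_,
       meanBoundaryError = if (length(errs)) mean(errs) else NA_real_,
       maxBoundaryError = if (length(errs)) max(errs) else NA_real_)
}

#' Score recovery of injected differentially expressed loci
#'
#' @param calls data.frame from [callDifferential()].
#' @param truth data.frame from [simulateExpression()].
#' @return list: \code{nTruth}, \code{nCalledUp}, \code{recall} (injected
#'   loci finally called up), \code{falsePositives} (final up/down calls at
#'   non-injected loci).
#' @export
scoreDeRecovery <- function(calls, truth) {
  m <- merge(calls[, c("locus", "finalCall")], truth, by = "locus")
  de <- m$isDe
  list(nTruth = sum(de),
       nCalledUp = sum(m$finalCall == "up"),
       recall = if (any(de)) mean(m$finalCall[de] == "up") else NA_real_,
       falsePositives = sum(m$finalCall[!de] != "unchanged"))
}

#' Run the full synthetic-data analysis pipeline
#'
#' One call chains every stage of the analysis on seeded synthetic data:
#' genome generation, bisulfite simulation for wild type and mutant
#' (optionally with injected hypomethylated regions), DMR calling,
#' RNA-seq simulation (optionally with injected upregulated loci),
#' differential-expression calling with replicate intersection, the 100-kb
#' windowed log2 expression track, compartment enrichment of upregulated
#' loci, small-RNA simulation with TE metaprofiles, methylation
#' metaprofiles, hypo-DMR/upregulated-locus overlap, and truth-based
#' recovery scoring.
#'
#' Presets: \code{"null"} injects nothing (both genotypes share one
#' generative model); \code{"dmr-recovery"} injects CG hypo-DMRs;
#' \code{"de-recovery"} injects 8-fold upregulated loci; \code{"full"}
#' (default) injects both.
#'
#' @param preset One of "full", "null", "dmr-recovery", "de-recovery".
#' @param seed Integer master seed; all stages derive child seeds from it.
#' @param outDir Optional directory; when given, result tables (DMC/DMR,
#'   expression calls, windowed track, profiles, overlap and score
#'   summaries, plus ground truth) are written as TSV/BED text files.
#' @param nInjectedDmrs,nInjectedDe Injection counts (defaults 30 and 40).
#' @param genomeSpec,methylomeSpec Optional spec overrides.
#' @return A list with all intermediate and final results, including
#'   \code{dmrScore} and \code{deScore}.
#' @export
runPipeline <- function(preset = c("full", "null", "dmr-recovery",
                                   "de-recovery"),
                        seed = 1L, outDir = NULL,
                        nInjectedDmrs = 30L, nInjectedDe = 40L,
                        genomeSpec = NULL, methylomeSpec = NULL) {
  preset <- match.arg(preset)
  if (is.null(genomeSpec))
    genomeSpec <- GenomeSpec(seed = childSeed(seed, "genome"))
  if (is.null(methylomeSpec)) methylomeSpec <- MethylomeSpec()
  genome <- makeGenome(genomeSpec)

  injectDmrs <- preset %in% c("full", "dmr-recovery")
  injectDe <- preset %in% c("full", "de-recovery")
  injections <- if (injectDmrs)
    sampleInjections(genome, n = nInjectedDmrs, context = "CG",
                     type = "hypo", targetRate = 0.1,
                     seed = childSeed(seed, "inject"))
  else NULL

  wt <- simulateMethylome(genome, methylomeSpec, "WT",
                          seed = childSeed(seed, "wt"))
  mut <- simulateMethylome(genome, methylomeSpec, "mut",
                           injections = injections,
                           seed = childSeed(seed, "mut"))
  wtSm <- smoothGenotype(wt$libraries, "WT")
  mutSm <- smoothGenotype(mut$libraries, "mut")
  dmrRes <- callDmrs(wtSm, mutSm)
  dmrScore <- scoreDmrRecovery(dmrRes$dmrs, mut$truth)

  expr <- simulateExpression(genome, nDe = if (injectDe) nInjectedDe else 0,
                             seed = childSeed(seed, "de"))
  deCalls <- callDifferential(expr$counts, expr$pairs)
  deScore <- scoreDeRecovery(deCalls, expr$truth)
  track <- windowedLog2Track(expr$loci, expr$counts,
                             wtLibs = c("wt1", "wt2"),
                             mutLibs = c("mut1", "mut2"),
                             chromLengths = genome$chromLengths)
  upLoci <- expr$loci[match(deCalls$locus[deCalls$finalCall == "up"],
                            S4Vectors::mcols(expr$loci)$id)]
  enrichment <- if (length(upLoci))
    compartmentEnrichment(upLoci, expr$loci) else NULL

  srna <- simulateSrna(genome, seed = childSeed(seed, "srna"))
  tes <- genome$features[S4Vectors::mcols(genome$features)$kind == "TE"]
  teProfile24 <- scaledTeProfile(srna$coverage24, tes,
                                 flank = 500L, bodyBins = 500L)
  methProfile <- if (length(upLoci))
    methylationMetaprofile(wt$libraries[[1]], upLoci, "CG",
                           anchor = "5prime")
  else NULL
  overlap <- overlapSummary(dmrRes$dmrs, upLoci)

  res <- list(preset = preset, seed = seed, genome = genome,
              methylomeTruth = mut$truth, dmcs = dmrRes$dmcs,
              candidates = dmrRes$candidates, dmrs = dmrRes$dmrs,
              dmrScore = dmrScore, exprTruth = expr$truth,
              deCalls = deCalls, deScore = deScore,
              windowedTrack = track, enrichment = enrichment,
              srna = srna, teProfile24 = teProfile24,
              methProfile = methProfile, overlap = overlap)
  if (!is.null(outDir)) writePipelineResults(res, outDir)
  res
}

writePipelineResults <- function(res, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name)
    utils::write.table(x, file.path(outDir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  tsv(res$dmcs, "dmcs.tsv")
  writeDmrs(res$dmrs, file.path(outDir, "dmrs.bed"))
  tsv(res$methylomeTruth, "truth_dmrs.tsv")
  tsv(res$deCalls, "expression_calls.tsv")
  tsv(res$exprTruth, "truth_de.tsv")
  tsv(res$windowedTrack, "windowed_log2.tsv")
  tsv(res$overlap, "overlap_summary.tsv")
  tsv(res$teProfile24, "te_profile_24nt.tsv")
  if (!is.null(res$methProfile)) tsv(res$methProfile, "meth_profile_CG.tsv")
  if (!is.null(res$enrichment))
    tsv(as.data.frame(res$enrichment), "enrichment.tsv")
  score <- data.frame(
    metric = c("dmr_recall", "dmr_precision", "dmr_mean_boundary_error",
               "de_recall", "de_false_positives"),
    value = c(res$dmrScore$recall, res$dmrScore$precision,
              res$dmrScore$meanBoundaryError, res$deScore$recall,
              res$deScore$falsePositives))
  tsv(score, "scores.tsv")
  invisible(outDir)
}
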