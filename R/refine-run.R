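#' Configuration for the refinement pipeline
#'
#' @param minIdentity,minCoverage identity/coverage retention thresholds in
#'   percent for the one-to-one protein screen (default 80/80).
#' @param adjacency_bp adjacency window for split/merge detection.
#' @param pairWindow bp added around a lifted gene span when collecting
#'   cross-haplotype alignment candidates.
#' @param teMaxFraction TE-overlap removal threshold.
#' @param maxSmallVariant variants with REF and ALT both under this length
#'   feed the consequence engine; longer edits are treated as structural.
#' @param repairTarget which haplotype's annotation is rewritten by
#'   split/merge repair (\code{"h2"} or \code{"h1"}).
#' @return list of settings.
#' @export
refineConfig <- function(minIdentity = 80, minCoverage = 80,
                         adjacency_bp = 10000L, pairWindow = 20000L,
                         teMaxFraction = 0.30, maxSmallVariant = 50L,
                         repairTarget = "h2") {
  list(minIdentity = minIdentity, minCoverage = minCoverage,
       adjacency_bp = adjacency_bp, pairWindow = pairWindow,
       teMaxFraction = teMaxFraction, maxSmallVariant = maxSmallVariant,
       repairTarget = repairTarget)
}

peptideSet <- function(models, genome) {
  peps <- vapply(models, function(g) {
    tx <- representativeTranscript(g)
    if (nrow(tx@cds) == 0L) return(NA_character_)
    genePeptide(g, genome)
  }, character(1L))
  peps[!is.na(peps) & nzchar(peps)]
}

candidatePairs <- function(modelsH1, modelsH2, blocks, window = 20000L) {
  sp2 <- modelSpans(modelsH2)
  sp1 <- modelSpans(modelsH1)
  pairs <- list()
  addPairs <- function(models, spOther, direction, flip) {
    for (g in models) {
      lr <- tryCatch(liftInterval(seqName(g), geneSpan(g)[1L],
                                  geneSpan(g)[2L], blocks, direction),
                     error = function(e) NULL)
      if (is.null(lr) || nrow(lr$mapped) == 0L) next
      for (i in seq_len(nrow(lr$mapped))) {
        m <- lr$mapped[i, ]
        hit <- spOther$gene_id[spOther$seq_name == m$seq_name &
                               spOther$start < m$end + window &
                               m$start - window < spOther$end]
        if (length(hit))
          pairs[[length(pairs) + 1L]] <<- if (flip)
            data.frame(query_id = hit, subject_id = geneId(g),
                       stringsAsFactors = FALSE)
          else
            data.frame(query_id = geneId(g), subject_id = hit,
                       stringsAsFactors = FALSE)
      }
    }
  }
  addPairs(modelsH1, sp2, "h1to2", flip = FALSE)
  addPairs(modelsH2, sp1, "h2to1", flip = TRUE)
  if (length(pairs) == 0L)
    return(data.frame(query_id = character(), subject_id = character(),
                      stringsAsFactors = FALSE))
  out <- unique(do.call(rbind, pairs))
  out[order(out$query_id, out$subject_id), , drop = FALSE]
}

specificityReport <- function(modelsH1, modelsH2, genomeH1, genomeH2,
                              variants, blocks, hits, cfg) {
  clus <- clusterCrossHaplotype(modelsH1, modelsH2, hits,
                                cfg$minIdentity, cfg$minCoverage)
  small <- variants[nchar(variants$ref) < cfg$maxSmallVariant &
                    nchar(variants$alt) < cfg$maxSmallVariant, , drop = FALSE]
  perHap <- function(cand, models, vars, genome, hap, direction) {
    high <- callHighEffectGenes(models[cand], vars, genome)
    sv <- stats::setNames(lapply(cand, function(gid)
      svEvidenceForGene(models[[gid]], variants, blocks, hap)), cand)
    validateHapSpecific(cand, high, sv, models, blocks, direction)
  }
  h1 <- perHap(clus$candidateSpecific$h1, modelsH1, small, genomeH1,
               "h1", "h1to2")
  # only variants near the h2 candidates' counterpart loci need re-anchoring
  invSmall <- small[0L, ]
  if (length(clus$candidateSpecific$h2)) {
    nearby <- rep(FALSE, nrow(small))
    for (gid in clus$candidateSpecific$h2) {
      g <- modelsH2[[gid]]
      sp <- geneSpan(g)
      lr <- tryCatch(liftInterval(seqName(g), sp[1L], sp[2L], blocks,
                                  "h2to1"), error = function(e) NULL)
      if (is.null(lr) || nrow(lr$mapped) == 0L) next
      for (i in seq_len(nrow(lr$mapped)))
        nearby <- nearby |
          (small$seq_name == lr$mapped$seq_name[i] &
           small$pos >= lr$mapped$start[i] - 100L &
           small$pos <= lr$mapped$end[i] + 100L)
    }
    if (any(nearby))
      invSmall <- suppressMessages(invertVariants(small[nearby, , drop = FALSE],
                                                  blocks))
  }
  h2 <- perHap(clus$candidateSpecific$h2, modelsH2, invSmall, genomeH2,
               "h2", "h2to1")
  list(clusters = clus, h1 = h1, h2 = h2, hits = hits)
}

#' Run the haplotype-aware refinement pipeline
#'
#' Deterministic stage order: protein alignment across haplotypes ->
#' clustering -> haplotype-specific validation -> rescue of candidate
#' unannotated genes -> split/merge repair -> TE filter -> false-positive
#' filter. Every gene added or removed appears in the audit log with the rule
#' that fired. The haplotype-specific report is computed before and re-derived
#' after refinement on the refined annotations.
#'
#' @param bundle named list of inputs: \code{genomeH1}, \code{genomeH2}
#'   (DNAStringSet), \code{modelsH1}, \code{modelsH2} (named GeneModel
#'   lists), \code{variants}, \code{blocks}, and optional \code{teH1},
#'   \code{teH2}, \code{junctionsH1}, \code{junctionsH2}, \code{exprH1},
#'   \code{exprH2}, \code{domainsH1}, \code{domainsH2}.
#' @param config settings from \code{\link{refineConfig}}.
#' @return list of class \code{refinementResult}: refined \code{modelsH1} /
#'   \code{modelsH2}, \code{reportBefore} / \code{reportAfter} (per-haplotype
#'   specificity reports), \code{rescue} (per-direction rescue results),
#'   \code{splitMerge} (calls and repair report), \code{audit} (data.frame),
#'   and the intermediate \code{hits} and \code{clusters}.
#' @export
runRefinement <- function(bundle, config = refineConfig()) {
  cfg <- config
  m1 <- bundle$modelsH1
  m2 <- bundle$modelsH2
  audit <- list()
  note <- function(stage, action, hap, gene, rule) {
    audit[[length(audit) + 1L]] <<- data.frame(
      stage = stage, action = action, haplotype = hap, gene_id = gene,
      rule = rule, stringsAsFactors = FALSE)
  }
  nIn <- c(h1 = length(m1), h2 = length(m2))

  pep1 <- peptideSet(m1, bundle$genomeH1)
  pep2 <- peptideSet(m2, bundle$genomeH2)
  pairs <- candidatePairs(m1, m2, bundle$blocks, cfg$pairWindow)
  hits <- alignProteins(pep1, pep2, pairs, minIdentity = 0, minCoverage = 0)
  before <- specificityReport(m1, m2, bundle$genomeH1, bundle$genomeH2,
                              bundle$variants, bundle$blocks, hits, cfg)

  # rescue: unannotated candidates projected onto the opposite haplotype
  res12 <- rescueMissingGenes(before$h1$candidate_unannotated, m1, m2,
                              bundle$blocks, bundle$genomeH2, "h1to2",
                              bundle$junctionsH2, "h2")
  for (id in names(res12$rescued)) note("rescue", "added", "h2", id,
                                        "projected_from_h1")
  m2 <- c(m2, res12$rescued)
  res21 <- rescueMissingGenes(before$h2$candidate_unannotated,
                              bundle$modelsH2, m1, bundle$blocks,
                              bundle$genomeH1, "h2to1",
                              bundle$junctionsH1, "h1")
  for (id in names(res21$rescued)) note("rescue", "added", "h1", id,
                                        "projected_from_h2")
  m1 <- c(m1, res21$rescued)

  # split/merge repair (source annotation treated as reference)
  if (cfg$repairTarget == "h2") {
    calls <- detectSplitMerge(bundle$modelsH1, m2, hits, cfg$adjacency_bp,
                              bundle$junctionsH2, cfg$minIdentity)
    rep <- repairSplitMerge(calls, bundle$modelsH1, m2, bundle$blocks,
                            bundle$genomeH2, "h1to2", bundle$junctionsH2,
                            "h2")
    removedIds <- setdiff(names(m2), names(rep$targetModels))
    addedIds <- setdiff(names(rep$targetModels), names(m2))
    for (id in removedIds) note("split_merge", "removed", "h2", id,
                                "replaced_by_projection")
    for (id in addedIds) note("split_merge", "added", "h2", id,
                              "projected_from_h1")
    m2 <- rep$targetModels
  } else {
    flip <- hits
    names(flip)[match(c("query_id", "subject_id", "query_coverage_pct",
                        "subject_coverage_pct", "q_start", "q_end",
                        "s_start", "s_end"), names(flip))] <-
      c("subject_id", "query_id", "subject_coverage_pct",
        "query_coverage_pct", "s_start", "s_end", "q_start", "q_end")
    calls <- detectSplitMerge(bundle$modelsH2, m1, flip, cfg$adjacency_bp,
                              bundle$junctionsH1, cfg$minIdentity)
    rep <- repairSplitMerge(calls, bundle$modelsH2, m1, bundle$blocks,
                            bundle$genomeH1, "h2to1", bundle$junctionsH1,
                            "h1")
    removedIds <- setdiff(names(m1), names(rep$targetModels))
    addedIds <- setdiff(names(rep$targetModels), names(m1))
    for (id in removedIds) note("split_merge", "removed", "h1", id,
                                "replaced_by_projection")
    for (id in addedIds) note("split_merge", "added", "h1", id,
                              "projected_from_h2")
    m1 <- rep$targetModels
  }

  # TE filter
  teRemoved <- list(h1 = character(), h2 = character())
  if (!is.null(bundle$teH1)) {
    f <- filterTeGenes(m1, bundle$teH1, cfg$teMaxFraction)
    teRemoved$h1 <- names(f$removed)
    for (id in teRemoved$h1) note("te_filter", "removed", "h1", id,
                                  "te_overlap_gt_30pct")
    m1 <- f$kept
  }
  if (!is.null(bundle$teH2)) {
    f <- filterTeGenes(m2, bundle$teH2, cfg$teMaxFraction)
    teRemoved$h2 <- names(f$removed)
    for (id in teRemoved$h2) note("te_filter", "removed", "h2", id,
                                  "te_overlap_gt_30pct")
    m2 <- f$kept
  }

  # false-positive filter
  fp1 <- filterFalsePositives(m1, bundle$domainsH1, bundle$exprH1, hits)
  for (id in names(fp1$removed)) note("fp_filter", "removed", "h1", id,
                                      "all_four_criteria")
  m1 <- fp1$kept
  fp2 <- filterFalsePositives(m2, bundle$domainsH2, bundle$exprH2, hits)
  for (id in names(fp2$removed)) note("fp_filter", "removed", "h2", id,
                                      "all_four_criteria")
  m2 <- fp2$kept

  # re-derive the specificity report on the refined annotation
  pep1b <- peptideSet(m1, bundle$genomeH1)
  pep2b <- peptideSet(m2, bundle$genomeH2)
  pairsB <- candidatePairs(m1, m2, bundle$blocks, cfg$pairWindow)
  hitsB <- alignProteins(pep1b, pep2b, pairsB, minIdentity = 0,
                         minCoverage = 0)
  after <- specificityReport(m1, m2, bundle$genomeH1, bundle$genomeH2,
                             bundle$variants, bundle$blocks, hitsB, cfg)

  auditDf <- if (length(audit)) do.call(rbind, audit) else
    data.frame(stage = character(), action = character(),
               haplotype = character(), gene_id = character(),
               rule = character(), stringsAsFactors = FALSE)
  nOut <- c(h1 = length(m1), h2 = length(m2))
  for (hap in c("h1", "h2")) {
    added <- sum(auditDf$haplotype == hap & auditDf$action == "added")
    removed <- sum(auditDf$haplotype == hap & auditDf$action == "removed")
    stopifnot(nIn[[hap]] + added - removed == nOut[[hap]])
  }
  structure(list(modelsH1 = m1, modelsH2 = m2,
                 reportBefore = before, reportAfter = after,
                 rescue = list(h1to2 = res12, h2to1 = res21),
                 splitMerge = list(calls = calls, repair = rep$report),
                 teRemoved = teRemoved,
                 fpRemoved = list(h1 = names(fp1$removed),
                                  h2 = names(fp2$removed)),
                 hits = hits, audit = auditDf),
            class = "refinementResult")
}

#' Write refinement outputs to a directory
#'
#' Emits refined GFF3 for both haplotypes, a haplotype-specificity report TSV
#' and the audit log TSV, all deterministically ordered.
#'
#' @param result object from \code{\link{runRefinement}}.
#' @param dir output directory (created if needed).
#' @export
writeRefinement <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGff3(result$modelsH1, file.path(dir, "hap1.refined.gff3"))
  writeGff3(result$modelsH2, file.path(dir, "hap2.refined.gff3"))
  tag <- function(hap, ev) {
    if (nrow(ev) == 0L)
      return(data.frame(haplotype = character(), gene_id = character(),
                        criterion = character(), detail = character(),
                        stringsAsFactors = FALSE))
    cbind(haplotype = hap, ev)
  }
  hs <- rbind(tag("h1", result$reportAfter$h1$evidence),
              tag("h2", result$reportAfter$h2$evidence))
  write.table(hs, file.path(dir, "hapspec_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(result$audit, file.path(dir, "audit_log.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
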