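#' Validate candidate haplotype-specific genes
#'
#' Each candidate is labelled by the first satisfied criterion: (i) its locus
#' carries a HIGH-impact variant (the counterpart allele is disabled), (ii)
#' structural-variant evidence (whole-gene or majority-coding deletion, long
#' coding insertion, coding inversion), (iii) it lies in an unaligned region.
#' Candidates with none of the three are candidate unannotated genes —
#' putative annotation errors whose counterpart locus is intact — and carry
#' the counterpart locus coordinates for rescue.
#'
#' @param candidates character vector of candidate-specific gene ids.
#' @param highEffectGenes character vector of gene ids with >=1 HIGH-impact
#'   variant call (from \code{\link{callHighEffectGenes}}).
#' @param svEvidence named list of evidence records from
#'   \code{\link{svEvidenceForGene}}, one per candidate.
#' @param models named list of GeneModel (for counterpart locus lookup).
#' @param blocks synteny blocks.
#' @param direction liftover direction towards the counterpart haplotype.
#' @return list with \code{high_confidence_specific},
#'   \code{candidate_unannotated} (character vectors) and \code{evidence}
#'   (per-gene data.frame trail).
#' @export
validateHapSpecific <- function(candidates, highEffectGenes, svEvidence,
                                models, blocks,
                                direction = c("h1to2", "h2to1")) {
  direction <- match.arg(direction)
  n <- length(candidates)
  crit <- character(n)
  detail <- character(n)
  for (i in seq_len(n)) {
    gid <- candidates[i]
    sv <- svEvidence[[gid]]
    svClass <- if (is.null(sv)) "none" else sv$evidence_class
    if (gid %in% highEffectGenes) {
      crit[i] <- "high_effect"
      detail[i] <- "HIGH-impact variant on locus"
    } else if (svClass %in% c("whole_gene_deleted", "coding_majority_deleted",
                              "coding_insertion", "coding_inverted")) {
      crit[i] <- "sv"
      detail[i] <- svClass
    } else if (svClass == "unaligned_region") {
      crit[i] <- "unaligned"
      detail[i] <- "gene span in unaligned region"
    } else {
      crit[i] <- "unannotated"
      detail[i] <- "no disabling evidence; counterpart locus intact"
    }
  }
  ev <- data.frame(gene_id = candidates, criterion = crit, detail = detail,
                   stringsAsFactors = FALSE)
  list(high_confidence_specific = candidates[crit != "unannotated"],
       candidate_unannotated = candidates[crit == "unannotated"],
       evidence = ev)
}

intronsMatchHints <- function(tx, seqname, strand, hints) {
  intr <- intronTable(tx)
  if (nrow(intr) == 0L) return(TRUE)
  h <- hints[hints$seq_name == seqname & hints$strand == strand, ,
             drop = FALSE]
  all(vapply(seq_len(nrow(intr)), function(i)
    any(h$start == intr[i, 1L] + 1L & h$end == intr[i, 2L]), logical(1L)))
}

#' Rescue genes missing from the other haplotype's annotation
#'
#' Candidate unannotated genes are projected through the synteny blocks onto
#' the target haplotype. A projection is accepted only when the projected
#' splice sites are intact (GT..AG), the projected ORF is intact, the target
#' region carries no existing overlapping gene model, and — when junction
#' hints are provided — every projected intron matches a hinted junction.
#' Rejected candidates are reported, never silently dropped.
#'
#' @param candidateIds gene ids to rescue (present on the source haplotype).
#' @param sourceModels named list of GeneModel containing the candidates.
#' @param targetModels named list of GeneModel already on the target.
#' @param blocks synteny blocks.
#' @param targetGenome DNAStringSet of the target haplotype.
#' @param direction liftover direction.
#' @param junctionHints optional hinted-intron data.frame
#'   (\code{\link{readJunctions}} format, target coordinates).
#' @param targetHaplotype label for rescued models.
#' @return list with \code{rescued} (named list of GeneModel, ids suffixed
#'   \code{_rescued}) and \code{report} (per-candidate data.frame with
#'   status, reason, supported_by_junctions, peptide).
#' @export
rescueMissingGenes <- function(candidateIds, sourceModels, targetModels,
                               blocks, targetGenome,
                               direction = c("h1to2", "h2to1"),
                               junctionHints = NULL,
                               targetHaplotype = NA_character_) {
  direction <- match.arg(direction)
  tsp <- modelSpans(targetModels)
  rescued <- list()
  rows <- vector("list", length(candidateIds))
  for (i in seq_along(candidateIds)) {
    gid <- candidateIds[i]
    pr <- projectGeneModel(sourceModels[[gid]], blocks, targetGenome,
                           direction, targetHaplotype = targetHaplotype)
    status <- "rescued"
    reason <- NA_character_
    junOk <- NA
    if (!pr$success) {
      status <- "unresolved"
      reason <- paste0("projection_failed:", pr$reason)
    } else {
      m <- pr$model
      sp <- geneSpan(m)
      overl <- any(tsp$seq_name == seqName(m) & tsp$start < sp[2L] &
                   sp[1L] < tsp$end)
      if (overl) {
        status <- "unresolved"
        reason <- "target_region_annotated"
      } else if (!pr$splice_sites_intact) {
        status <- "unresolved"
        reason <- "splice_sites_broken"
      } else if (!pr$orf_intact) {
        status <- "unresolved"
        reason <- "orf_broken"
      } else if (!is.null(junctionHints)) {
        junOk <- intronsMatchHints(representativeTranscript(m), seqName(m),
                                   geneStrand(m), junctionHints)
        if (!junOk) {
          status <- "unresolved"
          reason <- "introns_not_hinted"
        }
      }
    }
    if (status == "rescued") {
      m <- pr$model
      newId <- paste0(gid, "_rescued")
      tx <- representativeTranscript(m)
      m2 <- geneModel(newId, seqName(m), geneStrand(m),
                      transcriptModel(paste0(transcriptId(tx), "_rescued"),
                                      tx@exons, tx@cds),
                      sourceHaplotype = targetHaplotype)
      rescued[[newId]] <- m2
    }
    rows[[i]] <- data.frame(
      gene_id = gid, status = status, reason = reason,
      supported_by_junctions = isTRUE(junOk),
      fraction_mapped = pr$fraction_mapped,
      peptide = if (status == "rescued") pr$peptide else NA_character_,
      stringsAsFactors = FALSE)
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), status = character(),
               reason = character(), supported_by_junctions = logical(),
               fraction_mapped = numeric(), peptide = character(),
               stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(rescued = rescued, report = report)
}

adjacentPair <- function(spans, idA, idB, adjacency_bp) {
  a <- spans[spans$gene_id == idA, ]
  b <- spans[spans$gene_id == idB, ]
  if (a$seq_name != b$seq_name) return(FALSE)
  gap <- max(a$start, b$start) - min(a$end, b$end)
  if (gap > adjacency_bp) return(FALSE)
  lo <- min(a$end, b$end)
  hi <- max(a$start, b$start)
  between <- spans$seq_name == a$seq_name & spans$start >= lo &
    spans$end <= hi & !spans$gene_id %in% c(idA, idB)
  !any(between)
}

#' Detect split and merged gene structures between haplotypes
#'
#' A gene is called split in the target haplotype when one source protein
#' aligns to two or more genomically adjacent target genes whose alignment
#' intervals tile near-disjoint parts of the source protein (<20\% pairwise
#' overlap on the source); merged is the symmetric case. Hits are used
#' unfiltered by the coverage rule, because split halves have low individual
#' coverage by nature; an identity floor still applies. Adjacency means same
#' sequence, separated by at most \code{adjacency_bp} with no intervening
#' gene.
#'
#' @param sourceModels,targetModels named lists of GeneModel.
#' @param hits unfiltered alignment hits with source genes as queries and
#'   target genes as subjects.
#' @param adjacency_bp adjacency threshold (default 10000).
#' @param junctionHints optional hinted introns on the target haplotype; a
#'   call is flagged supported when a hinted intron spans the inter-fragment
#'   gap.
#' @param minIdentity identity floor for hits considered (default 80).
#' @return data.frame of calls: pattern, source_genes, target_genes
#'   (comma-separated), adjacency_gap_bp, supported_by_junctions.
#' @export
detectSplitMerge <- function(sourceModels, targetModels, hits,
                             adjacency_bp = 10000L, junctionHints = NULL,
                             minIdentity = 80) {
  h <- hits[hits$identity_pct >= minIdentity, , drop = FALSE]
  ssp <- modelSpans(sourceModels)
  tsp <- modelSpans(targetModels)
  calls <- list()

  tileOk <- function(iv) {
    # pairwise overlap < 20% of the smaller interval, on the shared protein
    for (i in seq_len(nrow(iv) - 1L)) for (j in (i + 1L):nrow(iv)) {
      ov <- min(iv[i, 2L], iv[j, 2L]) - max(iv[i, 1L], iv[j, 1L]) + 1L
      w <- min(iv[i, 2L] - iv[i, 1L], iv[j, 2L] - iv[j, 1L]) + 1L
      if (ov > 0.2 * w) return(FALSE)
    }
    TRUE
  }
  junctionSpans <- function(gapLo, gapHi, sn) {
    if (is.null(junctionHints)) return(FALSE)
    any(junctionHints$seq_name == sn & junctionHints$start <= gapLo + 1L &
        junctionHints$end >= gapHi)
  }

  # split in target: one source gene, >=2 adjacent target genes
  for (q in unique(h$query_id)) {
    sub <- h[h$query_id == q, , drop = FALSE]
    tg <- unique(sub$subject_id)
    if (length(tg) < 2L) next
    best <- do.call(rbind, lapply(tg, function(s) {
      rows <- sub[sub$subject_id == s, , drop = FALSE]
      rows[which.max(rows$score), , drop = FALSE]
    }))
    ts <- tsp[match(tg, tsp$gene_id), ]
    ord <- order(ts$start)
    tg <- tg[ord]
    best <- best[ord, , drop = FALSE]
    ts <- ts[ord, , drop = FALSE]
    adjOk <- all(vapply(seq_len(length(tg) - 1L), function(k)
      adjacentPair(tsp, tg[k], tg[k + 1L], adjacency_bp), logical(1L))) &&
      length(unique(ts$seq_name)) == 1L
    if (!adjOk) next
    if (!tileOk(cbind(best$q_start, best$q_end))) next
    gaps <- ts$start[-1L] - ts$end[-nrow(ts)]
    supp <- any(vapply(seq_len(length(tg) - 1L), function(k)
      junctionSpans(ts$end[k], ts$start[k + 1L], ts$seq_name[1L]),
      logical(1L)))
    calls[[length(calls) + 1L]] <- data.frame(
      pattern = "split_in_target", source_genes = q,
      target_genes = paste(tg, collapse = ","),
      adjacency_gap_bp = max(gaps), supported_by_junctions = supp,
      stringsAsFactors = FALSE)
  }

  # merged in target: >=2 adjacent source genes, one target gene
  for (s in unique(h$subject_id)) {
    sub <- h[h$subject_id == s, , drop = FALSE]
    sg <- unique(sub$query_id)
    if (length(sg) < 2L) next
    best <- do.call(rbind, lapply(sg, function(q) {
      rows <- sub[sub$query_id == q, , drop = FALSE]
      rows[which.max(rows$score), , drop = FALSE]
    }))
    ss <- ssp[match(sg, ssp$gene_id), ]
    ord <- order(ss$start)
    sg <- sg[ord]
    best <- best[ord, , drop = FALSE]
    ss <- ss[ord, , drop = FALSE]
    adjOk <- all(vapply(seq_len(length(sg) - 1L), function(k)
      adjacentPair(ssp, sg[k], sg[k + 1L], adjacency_bp), logical(1L))) &&
      length(unique(ss$seq_name)) == 1L
    if (!adjOk) next
    if (!tileOk(cbind(best$s_start, best$s_end))) next
    gaps <- ss$start[-1L] - ss$end[-nrow(ss)]
    tspan <- tsp[tsp$gene_id == s, ]
    supp <- if (is.null(junctionHints)) FALSE else
      any(junctionHints$seq_name == tspan$seq_name &
          junctionHints$start >= tspan$start & junctionHints$end <= tspan$end)
    calls[[length(calls) + 1L]] <- data.frame(
      pattern = "merged_in_target", source_genes = paste(sg, collapse = ","),
      target_genes = s, adjacency_gap_bp = max(gaps),
      supported_by_junctions = supp, stringsAsFactors = FALSE)
  }
  if (length(calls) == 0L)
    return(data.frame(pattern = character(), source_genes = character(),
                      target_genes = character(), adjacency_gap_bp = integer(),
                      supported_by_junctions = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, calls)
  out[order(out$pattern, out$source_genes), , drop = FALSE]
}

#' Repair split and merged gene structures
#'
#' For a split call the source model is projected onto the target haplotype
#' to replace the fragment models; for a merged call each source model is
#' projected to replace the fused model. A replacement is accepted under the
#' same gates as rescue (intact projected splice sites and ORF, hinted
#' junctions when hints are given); otherwise the original target models are
#' kept and the call is marked unrepaired.
#'
#' @param calls data.frame from \code{\link{detectSplitMerge}}.
#' @param sourceModels,targetModels named lists of GeneModel.
#' @param blocks synteny blocks.
#' @param targetGenome DNAStringSet of the target haplotype.
#' @param direction liftover direction source -> target.
#' @param junctionHints optional hinted introns (target coordinates).
#' @param targetHaplotype label for repaired models.
#' @return list with \code{targetModels} (updated named list) and
#'   \code{report} (per-call data.frame with repaired flag and reason).
#' @export
repairSplitMerge <- function(calls, sourceModels, targetModels, blocks,
                             targetGenome, direction = c("h1to2", "h2to1"),
                             junctionHints = NULL,
                             targetHaplotype = NA_character_) {
  direction <- match.arg(direction)
  out <- targetModels
  rows <- vector("list", nrow(calls))
  for (i in seq_len(nrow(calls))) {
    srcIds <- strsplit(calls$source_genes[i], ",", fixed = TRUE)[[1L]]
    tgtIds <- strsplit(calls$target_genes[i], ",", fixed = TRUE)[[1L]]
    projections <- lapply(srcIds, function(gid)
      projectGeneModel(sourceModels[[gid]], blocks, targetGenome, direction,
                       targetHaplotype = targetHaplotype))
    gateOk <- function(pr) {
      pr$success && pr$splice_sites_intact && pr$orf_intact &&
        (is.null(junctionHints) ||
           intronsMatchHints(representativeTranscript(pr$model),
                             seqName(pr$model), geneStrand(pr$model),
                             junctionHints))
    }
    ok <- all(vapply(projections, gateOk, logical(1L)))
    if (ok) {
      out <- out[!names(out) %in% tgtIds]
      for (pr in projections) {
        m <- pr$model
        tx <- representativeTranscript(m)
        newId <- paste0(geneId(m), "_repaired")
        out[[newId]] <- geneModel(newId, seqName(m), geneStrand(m),
                                  transcriptModel(paste0(transcriptId(tx),
                                                         "_repaired"),
                                                  tx@exons, tx@cds),
                                  sourceHaplotype = targetHaplotype)
      }
    }
    rows[[i]] <- data.frame(
      pattern = calls$pattern[i], source_genes = calls$source_genes[i],
      target_genes = calls$target_genes[i], repaired = ok,
      reason = if (ok) NA_character_ else "projection_gates_failed",
      stringsAsFactors = FALSE)
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pattern = character(), source_genes = character(),
               target_genes = character(), repaired = logical(),
               reason = character(), stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(targetModels = out, report = report)
}

#' Remove transposon-related gene models
#'
#' A gene is TE-related, and removed, when annotated TE intervals cover
#' strictly more than \code{maxFraction} (default 0.30) of its span; a gene
#' at exactly the threshold is kept.
#'
#' @param models named list of GeneModel.
#' @param te TE track data.frame (seq_name, start, end 1-based incl.,
#'   te_class).
#' @param maxFraction removal threshold on the covered fraction.
#' @return list with \code{kept}, \code{removed} (named lists) and
#'   \code{fractions} (named numeric of TE-covered fractions).
#' @export
filterTeGenes <- function(models, te, maxFraction = 0.30) {
  fr <- vapply(models, function(g) {
    sp <- geneSpan(g)
    t <- te[te$seq_name == seqName(g), , drop = FALSE]
    if (nrow(t) == 0L) return(0)
    unionCoverage(sp[1L], sp[2L], t$start - 1L, t$end) / (sp[2L] - sp[1L])
  }, numeric(1L))
  rm <- fr > maxFraction
  list(kept = models[!rm], removed = models[rm], fractions = fr)
}

#' Remove putative false-positive gene models
#'
#' A gene is excluded only when it simultaneously meets all four criteria:
#' (1) mono-exonic with transcript length under 300 bp; (2) no identifiable
#' protein domain (absent from \code{domains}); (3) zero expression in every
#' sample; (4) no homology hit at or above 80\% identity and coverage. A
#' missing evidence table makes its criterion unmet, so the gene is kept.
#'
#' @param models named list of GeneModel.
#' @param domains optional character vector of gene ids with domains (or a
#'   data.frame with a gene_id column).
#' @param expression optional TPM matrix with gene ids as rownames.
#' @param homologyHits optional alignment-hit data.frame; a gene has homology
#'   support when it appears in a hit with identity >= 80 and coverage >= 80.
#' @return list with \code{kept}, \code{removed} (named lists) and
#'   \code{criteria} (logical matrix, one row per gene).
#' @export
filterFalsePositives <- function(models, domains = NULL, expression = NULL,
                                 homologyHits = NULL) {
  ids <- names(models)
  c1 <- vapply(models, function(g) {
    tx <- representativeTranscript(g)
    isMonoExonic(tx) && transcriptLength(tx) < 300L
  }, logical(1L))
  if (is.data.frame(domains)) domains <- domains$gene_id
  c2 <- if (is.null(domains)) rep(FALSE, length(ids)) else !ids %in% domains
  c3 <- if (is.null(expression)) rep(FALSE, length(ids)) else {
    vapply(ids, function(g)
      !g %in% rownames(expression) || all(expression[g, ] == 0),
      logical(1L))
  }
  c4 <- if (is.null(homologyHits)) rep(FALSE, length(ids)) else {
    strong <- filterHits(homologyHits, 80, 80)
    !ids %in% c(strong$query_id, strong$subject_id)
  }
  crit <- cbind(short_mono_exonic = c1, no_domain = c2, not_expressed = c3,
                no_homology = c4)
  rownames(crit) <- ids
  rm <- c1 & c2 & c3 & c4
  list(kept = models[!rm], removed = models[rm], criteria = crit)
}
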