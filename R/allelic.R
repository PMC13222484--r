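#' Ideal expression vectors for allelic-state classification
#'
#' Observed per-tissue expression of a gene pair is normalized to proportions
#' and assigned to the category whose ideal vector is nearest in Euclidean
#' distance: Balanced (0.5, 0.5), H1_dominant (1, 0), H2_dominant (0, 1). A
#' tissue whose summed TPM falls below \code{expression_floor} is NE (not
#' expressed) before any distance is computed. The implied decision boundary
#' is a dominant-allele proportion of 0.75 (the midpoint between 0.5 and 1).
#'
#' @param expression_floor TPM sum under which a pair is NE in a tissue.
#' @return list of class \code{idealVectors}.
#' @export
idealVectors <- function(expression_floor = 0.5) {
  stopifnot(expression_floor >= 0)
  list(Balanced = c(0.5, 0.5), H1_dominant = c(1, 0), H2_dominant = c(0, 1),
       expression_floor = expression_floor)
}

#' Classify the allelic expression state of a gene pair in one tissue
#'
#' @param tpm_h1,tpm_h2 non-negative TPM values (vectorized).
#' @param vectors from \code{\link{idealVectors}}.
#' @return character vector of states (Balanced, H1_dominant, H2_dominant,
#'   NE); ties are resolved toward Balanced.
#' @export
classifyAllelicState <- function(tpm_h1, tpm_h2, vectors = idealVectors()) {
  if (any(tpm_h1 < 0) || any(tpm_h2 < 0)) stop("TPM values must be >= 0")
  n <- max(length(tpm_h1), length(tpm_h2))
  tpm_h1 <- rep_len(tpm_h1, n)
  tpm_h2 <- rep_len(tpm_h2, n)
  tot <- tpm_h1 + tpm_h2
  out <- rep("NE", n)
  use <- tot >= vectors$expression_floor & tot > 0
  if (any(use)) {
    p1 <- tpm_h1[use] / tot[use]
    p2 <- tpm_h2[use] / tot[use]
    cats <- c("Balanced", "H1_dominant", "H2_dominant")
    d <- vapply(cats, function(cl)
      sqrt((p1 - vectors[[cl]][1L])^2 + (p2 - vectors[[cl]][2L])^2),
      numeric(length(p1)))
    d <- matrix(d, ncol = 3L)
    out[use] <- cats[max.col(-d, ties.method = "first")]
  }
  out
}

#' Tissue-specificity index (tau)
#'
#' \eqn{\tau = \sum_i (1 - x_i / x_{max}) / (n - 1)} over \code{n} tissues:
#' 0 for a uniform profile, 1 for single-tissue expression. Computed on the
#' normalized (max-scaled) profile, so it is invariant to uniform scaling.
#'
#' @param profile non-negative per-tissue expression vector, length >= 2.
#' @return tau in [0, 1]; NA for an all-zero profile.
#' @export
tauIndex <- function(profile) {
  if (length(profile) < 2L) stop("tau needs at least 2 tissues")
  if (any(profile < 0)) stop("expression values must be >= 0")
  mx <- max(profile)
  if (mx == 0) return(NA_real_)
  sum(1 - profile / mx) / (length(profile) - 1L)
}

#' Call a transcript tissue-specific
#'
#' Under the default rule a profile is tissue-specific when the ratio of its
#' highest to second-highest expression exceeds 3 (strictly); a profile whose
#' second-highest value is zero but whose maximum is positive is specific.
#' The alternative rule \code{"lowest"} uses the highest-to-lowest ratio
#' instead.
#'
#' @param profile named non-negative expression vector, length >= 2.
#' @param rule \code{"second"} (default) or \code{"lowest"}.
#' @param ratio threshold (default 3, exceeded strictly).
#' @return list with \code{is_specific} and \code{dominant_tissue} (name or
#'   index of the maximum; NA when not specific or all zero).
#' @export
tissueSpecificCall <- function(profile, rule = c("second", "lowest"),
                               ratio = 3) {
  rule <- match.arg(rule)
  if (length(profile) < 2L) stop("need at least 2 tissues")
  if (all(profile == 0))
    return(list(is_specific = FALSE, dominant_tissue = NA))
  ord <- order(profile, decreasing = TRUE)
  top1 <- profile[ord[1L]]
  denom <- if (rule == "second") profile[ord[2L]] else min(profile)
  spec <- if (denom == 0) top1 > 0 else (top1 / denom) > ratio
  dom <- if (is.null(names(profile))) ord[1L] else names(profile)[ord[1L]]
  list(is_specific = spec, dominant_tissue = if (spec) dom else NA)
}

#' Identify bi-allelic gene pairs across haplotypes
#'
#' A pair is bi-allelic when both genes belong to the same homology cluster
#' and the haplotype-1 gene's span, lifted through the synteny blocks,
#' overlaps the haplotype-2 gene's span. Among multiple candidates the pair
#' with the greatest lifted overlap is the effective allele (ties broken by
#' alignment score, then lexicographic id). For clusters of exactly two genes
#' (one per haplotype) with no lifted overlap, the pair is retained with
#' \code{anchor_type = "homology_only"}. Unpaired genes are reported
#' mono-allelic.
#'
#' @param modelsH1,modelsH2 named lists of GeneModel.
#' @param clusters result of \code{\link{clusterCrossHaplotype}}.
#' @param blocks synteny blocks.
#' @param hits optional alignment hits used for score tie-breaks.
#' @return list with \code{pairs} (data.frame gene_h1, gene_h2, anchor_type,
#'   overlap_bp) and \code{monoallelic} (list h1, h2 of id vectors).
#' @export
identifyBialleles <- function(modelsH1, modelsH2, clusters, blocks,
                              hits = NULL) {
  memb <- clusters$membership
  cand <- list()
  for (cl in unique(memb$cluster)) {
    g1 <- memb$gene_id[memb$cluster == cl & memb$haplotype == "h1"]
    g2 <- memb$gene_id[memb$cluster == cl & memb$haplotype == "h2"]
    if (length(g1) == 0L || length(g2) == 0L) next
    for (a in g1) {
      sp <- geneSpan(modelsH1[[a]])
      lr <- tryCatch(liftInterval(seqName(modelsH1[[a]]), sp[1L], sp[2L],
                                  blocks, "h1to2"), error = function(e) NULL)
      for (b in g2) {
        spb <- geneSpan(modelsH2[[b]])
        ov <- 0L
        if (!is.null(lr) && nrow(lr$mapped)) {
          m <- lr$mapped[lr$mapped$seq_name == seqName(modelsH2[[b]]), ,
                         drop = FALSE]
          if (nrow(m))
            ov <- unionCoverage(spb[1L], spb[2L], m$start, m$end)
        }
        score <- 0
        if (!is.null(hits)) {
          hrow <- hits[hits$query_id == a & hits$subject_id == b, ,
                       drop = FALSE]
          if (nrow(hrow)) score <- max(hrow$score)
        }
        anchor <- if (ov > 0L) "syntenic_anchor" else if
          (length(g1) == 1L && length(g2) == 1L) "homology_only" else NA
        if (!is.na(anchor))
          cand[[length(cand) + 1L]] <- data.frame(
            gene_h1 = a, gene_h2 = b, anchor_type = anchor,
            overlap_bp = ov, score = score, stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(cand)) do.call(rbind, cand) else
    data.frame(gene_h1 = character(), gene_h2 = character(),
               anchor_type = character(), overlap_bp = integer(),
               score = numeric(), stringsAsFactors = FALSE)
  # greedy one-to-one assignment by overlap, score, then id
  pairs <- pairs[order(-pairs$overlap_bp, -pairs$score, pairs$gene_h1,
                       pairs$gene_h2), , drop = FALSE]
  used1 <- character()
  used2 <- character()
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    if (pairs$gene_h1[i] %in% used1 || pairs$gene_h2[i] %in% used2) next
    keep[i] <- TRUE
    used1 <- c(used1, pairs$gene_h1[i])
    used2 <- c(used2, pairs$gene_h2[i])
  }
  pairs <- pairs[keep, c("gene_h1", "gene_h2", "anchor_type", "overlap_bp"),
                 drop = FALSE]
  pairs <- pairs[order(pairs$gene_h1), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       monoallelic = list(h1 = sort(setdiff(names(modelsH1), pairs$gene_h1)),
                          h2 = sort(setdiff(names(modelsH2), pairs$gene_h2))))
}

#' Annotate and classify allelic pairs across tissues
#'
#' Adds sequence identity and expression flags to bi-allelic pairs, removes
#' pairs that are never expressed or whose coding sequences are identical,
#' and classifies the per-tissue allelic state of the rest.
#'
#' @param pairs data.frame from \code{\link{identifyBialleles}}.
#' @param exprH1,exprH2 TPM matrices (genes x tissues, same tissue order).
#' @param modelsH1,modelsH2,genomeH1,genomeH2 optional; when supplied,
#'   coding-sequence identity is computed and identical pairs are dropped.
#' @param vectors from \code{\link{idealVectors}}.
#' @return list with \code{states} (pair x tissue matrix), \code{pairs}
#'   (annotated data.frame) and \code{divergent_fraction} (share of
#'   classified pairs whose state changes across tissues).
#' @export
classifyAllelicPairs <- function(pairs, exprH1, exprH2,
                                 modelsH1 = NULL, modelsH2 = NULL,
                                 genomeH1 = NULL, genomeH2 = NULL,
                                 vectors = idealVectors()) {
  tissues <- colnames(exprH1)
  stopifnot(identical(tissues, colnames(exprH2)))
  getRow <- function(m, id) if (id %in% rownames(m)) m[id, ] else
    rep(0, ncol(m))
  seqIdent <- rep(FALSE, nrow(pairs))
  if (!is.null(modelsH1) && !is.null(genomeH1)) {
    seqIdent <- vapply(seq_len(nrow(pairs)), function(i) {
      a <- modelsH1[[pairs$gene_h1[i]]]
      b <- modelsH2[[pairs$gene_h2[i]]]
      if (is.null(a) || is.null(b)) return(FALSE)
      ca <- extractCdsAndTranslate(representativeTranscript(a), genomeH1,
                                   seqName(a), geneStrand(a))$cds
      cb <- extractCdsAndTranslate(representativeTranscript(b), genomeH2,
                                   seqName(b), geneStrand(b))$cds
      identical(ca, cb)
    }, logical(1L))
  }
  e1 <- t(vapply(pairs$gene_h1, getRow, numeric(length(tissues)), m = exprH1))
  e2 <- t(vapply(pairs$gene_h2, getRow, numeric(length(tissues)), m = exprH2))
  expressed <- rowSums(e1) + rowSums(e2) > 0
  ann <- cbind(pairs, sequence_identical = seqIdent,
               expressed_any_tissue = expressed)
  use <- expressed & !seqIdent
  states <- matrix(NA_character_, sum(use), length(tissues),
                   dimnames = list(pairs$gene_h1[use], tissues))
  for (ti in seq_along(tissues))
    states[, ti] <- classifyAllelicState(e1[use, ti], e2[use, ti], vectors)
  div <- if (nrow(states)) mean(apply(states, 1L, function(s)
    length(unique(s)) > 1L)) else NA_real_
  list(states = states, pairs = ann, divergent_fraction = div)
}

#' Positional classification of candidate non-coding transcripts
#'
#' Transcripts shorter than 200 bp are rejected outright; the rest are
#' intergenic (lincRNA-eligible) only with zero overlap with any
#' protein-coding gene span, strand-agnostic — a single shared base makes
#' them overlapping.
#'
#' @param transcripts data.frame with seq_name, start, end (1-based
#'   inclusive).
#' @param codingModels named list of GeneModel.
#' @return character vector: \code{rejected_short}, \code{overlapping} or
#'   \code{intergenic}.
#' @export
classifyLncPosition <- function(transcripts, codingModels) {
  sp <- modelSpans(codingModels)
  vapply(seq_len(nrow(transcripts)), function(i) {
    len <- transcripts$end[i] - transcripts$start[i] + 1L
    if (len < 200L) return("rejected_short")
    ov <- sp$seq_name == transcripts$seq_name[i] &
      sp$start + 1L <= transcripts$end[i] & transcripts$start[i] <= sp$end
    if (any(ov)) "overlapping" else "intergenic"
  }, character(1L))
}

#' Transposon association of a transcript
#'
#' Fraction of the transcript span covered by TE intervals; associated when
#' the fraction strictly exceeds 0.5. The dominant TE class is the one
#' covering the most bases.
#'
#' @param seq_name,start,end transcript span (1-based inclusive).
#' @param te TE track data.frame.
#' @return list with \code{fraction}, \code{is_te_associated},
#'   \code{dominant_te_class}.
#' @export
teAssociation <- function(seq_name, start, end, te) {
  t <- te[te$seq_name == seq_name, , drop = FALSE]
  span <- end - start + 1L
  if (nrow(t) == 0L)
    return(list(fraction = 0, is_te_associated = FALSE,
                dominant_te_class = NA_character_))
  cov <- unionCoverage(start - 1L, end, t$start - 1L, t$end)
  perClass <- vapply(split(t, t$te_class), function(tc)
    unionCoverage(start - 1L, end, tc$start - 1L, tc$end), integer(1L))
  dom <- if (cov > 0L) names(perClass)[which.max(perClass)] else NA_character_
  list(fraction = cov / span, is_te_associated = cov / span > 0.5,
       dominant_te_class = dom)
}
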