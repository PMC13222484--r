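emptyHits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             identity_pct = numeric(), query_coverage_pct = numeric(),
             subject_coverage_pct = numeric(), score = numeric(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             stringsAsFactors = FALSE)
}

#' Local protein alignment between haplotype proteomes
#'
#' Pairwise local alignment (BLOSUM62, affine gaps) of query peptides against
#' subject peptides. Identity is matches over aligned columns x100; coverage
#' is the aligned span over the full sequence length x100, reported for each
#' side. When \code{pairs} is supplied only those query/subject combinations
#' are aligned (the synteny-derived pre-screen used by the full pipeline);
#' otherwise all-vs-all. Internal stop characters are tolerated. Empty
#' peptides are skipped with a warning.
#'
#' @param query,subject named character vectors of peptides.
#' @param pairs optional two-column data.frame/matrix of (query_id,
#'   subject_id) combinations to align.
#' @param minIdentity,minCoverage retain only hits with identity and coverage
#'   (the larger of the two sides) at or above these percentages; set both to
#'   0 to keep every hit.
#' @return data.frame of alignment hits.
#' @export
alignProteins <- function(query, subject, pairs = NULL,
                          minIdentity = 80, minCoverage = 80) {
  clean <- function(x, lab) {
    bad <- !nzchar(x) | is.na(x)
    if (any(bad))
      warning("skipping ", sum(bad), " empty ", lab, " peptide(s)")
    x[!bad]
  }
  query <- clean(query, "query")
  subject <- clean(subject, "subject")
  if (length(query) == 0L || length(subject) == 0L) return(emptyHits())
  if (is.null(pairs))
    pairs <- expand.grid(query_id = names(query), subject_id = names(subject),
                         stringsAsFactors = FALSE)
  pairs <- pairs[pairs[[1L]] %in% names(query) &
                 pairs[[2L]] %in% names(subject), , drop = FALSE]
  if (nrow(pairs) == 0L) return(emptyHits())

  qaa <- Biostrings::AAStringSet(gsub("*", "X", query, fixed = TRUE))
  saa <- Biostrings::AAStringSet(gsub("*", "X", subject, fixed = TRUE))
  mat <- "BLOSUM62"
  rows <- vector("list", nrow(pairs))
  # vectorize over queries sharing a subject
  for (sid in unique(pairs[[2L]])) {
    idx <- which(pairs[[2L]] == sid)
    qids <- pairs[[1L]][idx]
    al <- Biostrings::pairwiseAlignment(qaa[qids], saa[[sid]],
                                        type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 10, gapExtension = 0.5)
    pr <- Biostrings::pattern(al)
    sr <- Biostrings::subject(al)
    qr <- IRanges::ranges(pr)
    srg <- IRanges::ranges(sr)
    idpct <- Biostrings::pid(al, type = "PID1")
    for (k in seq_along(idx)) {
      qid <- qids[k]
      qlen <- nchar(query[[qid]])
      slen <- nchar(subject[[sid]])
      rows[[idx[k]]] <- data.frame(
        query_id = qid, subject_id = sid,
        identity_pct = idpct[k],
        query_coverage_pct = 100 * IRanges::width(qr)[k] / qlen,
        subject_coverage_pct = 100 * IRanges::width(srg)[k] / slen,
        score = Biostrings::score(al)[k],
        q_start = IRanges::start(qr)[k], q_end = IRanges::end(qr)[k],
        s_start = IRanges::start(srg)[k], s_end = IRanges::end(srg)[k],
        stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, rows)
  rownames(hits) <- NULL
  if (minIdentity > 0 || minCoverage > 0)
    hits <- filterHits(hits, minIdentity, minCoverage)
  hits
}

#' Apply the identity/coverage retention filter to alignment hits
#'
#' A hit is retained when identity and coverage are both at or above the
#' thresholds (default 80/80). Coverage for this one-to-one screen is the
#' larger of the query- and subject-side coverages; the per-side values stay
#' available for split/merge logic.
#'
#' @param hits data.frame from \code{\link{alignProteins}}.
#' @param minIdentity,minCoverage thresholds in percent.
#' @return filtered data.frame.
#' @export
filterHits <- function(hits, minIdentity = 80, minCoverage = 80) {
  keep <- hits$identity_pct >= minIdentity &
    pmax(hits$query_coverage_pct, hits$subject_coverage_pct) >= minCoverage
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

unionFind <- function(ids) {
  parent <- stats::setNames(seq_along(ids), ids)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  list(union = function(a, b) {
    ra <- find(match(a, ids))
    rb <- find(match(b, ids))
    if (ra != rb) parent[[max(ra, rb)]] <<- min(ra, rb)
  },
  components = function() {
    roots <- vapply(seq_along(ids), find, numeric(1L))
    split(ids, match(roots, sort(unique(roots))))
  })
}

#' Cluster genes across haplotypes from protein hits
#'
#' Single-linkage clustering over the graph of alignment hits that pass the
#' identity/coverage retention filter. Clusters containing genes from only
#' one haplotype are flagged as candidate haplotype-specific.
#'
#' @param modelsH1,modelsH2 named lists of GeneModel for the two haplotypes.
#' @param hits alignment hits (raw; the 80/80 filter is applied here).
#' @param minIdentity,minCoverage retention thresholds.
#' @return list with \code{membership} (data.frame gene_id, haplotype,
#'   cluster), \code{clusters} (list of id vectors) and
#'   \code{candidateSpecific} (list with \code{h1}, \code{h2} id vectors).
#' @export
clusterCrossHaplotype <- function(modelsH1, modelsH2, hits,
                                  minIdentity = 80, minCoverage = 80) {
  ids1 <- names(modelsH1)
  ids2 <- names(modelsH2)
  all <- c(ids1, ids2)
  hap <- stats::setNames(c(rep("h1", length(ids1)), rep("h2", length(ids2))),
                         all)
  uf <- unionFind(all)
  fh <- filterHits(hits, minIdentity, minCoverage)
  fh <- fh[fh$query_id %in% all & fh$subject_id %in% all, , drop = FALSE]
  for (i in seq_len(nrow(fh))) uf$union(fh$query_id[i], fh$subject_id[i])
  comps <- uf$components()
  membership <- data.frame(
    gene_id = unlist(comps, use.names = FALSE),
    haplotype = unname(hap[unlist(comps, use.names = FALSE)]),
    cluster = rep(seq_along(comps), lengths(comps)),
    stringsAsFactors = FALSE)
  membership <- membership[order(membership$cluster, membership$gene_id), ]
  rownames(membership) <- NULL
  oneHap <- vapply(comps, function(m) length(unique(hap[m])) == 1L,
                   logical(1L))
  cand <- membership$gene_id[membership$cluster %in% which(oneHap)]
  list(membership = membership, clusters = comps,
       candidateSpecific = list(
         h1 = sort(intersect(cand, ids1)),
         h2 = sort(intersect(cand, ids2))))
}
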