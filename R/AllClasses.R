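#' @import methods
#' @importFrom stats setNames rnorm runif rlnorm
#' @importFrom utils read.delim write.table head tail
NULL

#' TranscriptModel: exon/CDS structure of a single transcript
#'
#' Coordinates are stored 0-based half-open, the convention used internally
#' throughout the package; GFF3 I/O converts to and from 1-based inclusive.
#' Exons are sorted by start and non-overlapping. Every CDS segment lies
#' within an exon and carries a phase (0/1/2, number of bases to skip before
#' the first complete codon in translation order).
#'
#' @slot transcriptId character scalar, unique within an annotation set.
#' @slot exons integer matrix with columns \code{start}, \code{end}.
#' @slot cds integer matrix with columns \code{start}, \code{end}, \code{phase}.
#' @exportClass TranscriptModel
setClass("TranscriptModel",
  representation(
    transcriptId = "character",
    exons = "matrix",
    cds = "matrix"
  )
)

setValidity("TranscriptModel", function(object) {
  ex <- object@exons
  cds <- object@cds
  msgs <- character()
  if (length(object@transcriptId) != 1L || is.na(object@transcriptId) ||
      !nzchar(object@transcriptId))
    msgs <- c(msgs, "transcriptId must be a non-empty string")
  if (ncol(ex) != 2L || nrow(ex) < 1L)
    msgs <- c(msgs, "exons must be a matrix with >=1 row and 2 columns")
  else {
    if (any(ex[, 2L] <= ex[, 1L]))
      msgs <- c(msgs, "exon end must be > start (0-based half-open)")
    if (is.unsorted(ex[, 1L], strictly = TRUE) && nrow(ex) > 1L)
      msgs <- c(msgs, "exons must be sorted by start")
    if (nrow(ex) > 1L && any(ex[-1L, 1L] < ex[-nrow(ex), 2L]))
      msgs <- c(msgs, "exons must not overlap")
  }
  if (nrow(cds) > 0L) {
    if (ncol(cds) != 3L)
      msgs <- c(msgs, "cds must have 3 columns (start, end, phase)")
    else {
      if (any(cds[, 2L] <= cds[, 1L]))
        msgs <- c(msgs, "CDS end must be > start")
      if (!all(cds[, 3L] %in% 0:2))
        msgs <- c(msgs, "CDS phase must be 0, 1 or 2")
      contained <- vapply(seq_len(nrow(cds)), function(i) {
        any(ex[, 1L] <= cds[i, 1L] & cds[i, 2L] <= ex[, 2L])
      }, logical(1L))
      if (!all(contained))
        msgs <- c(msgs, "every CDS segment must be contained in an exon")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' GeneModel: a gene with one or more transcripts on a named sequence
#'
#' @slot geneId character scalar.
#' @slot seqName name of the sequence (chromosome/contig) the gene lies on.
#' @slot strand \code{"+"} or \code{"-"}; all transcripts share it.
#' @slot transcripts list of \linkS4class{TranscriptModel}.
#' @slot sourceHaplotype free-text label of the haplotype of origin.
#' @exportClass GeneModel
setClass("GeneModel",
  representation(
    geneId = "character",
    seqName = "character",
    strand = "character",
    transcripts = "list",
    sourceHaplotype = "character"
  ),
  prototype(sourceHaplotype = NA_character_)
)

setValidity("GeneModel", function(object) {
  msgs <- character()
  if (length(object@geneId) != 1L || !nzchar(object@geneId))
    msgs <- c(msgs, "geneId must be a non-empty string")
  if (!identical(length(object@strand), 1L) || !object@strand %in% c("+", "-"))
    msgs <- c(msgs, "strand must be '+' or '-'")
  if (length(object@transcripts) < 1L)
    msgs <- c(msgs, "gene must have at least one transcript")
  if (!all(vapply(object@transcripts, is, logical(1L), "TranscriptModel")))
    msgs <- c(msgs, "transcripts must all be TranscriptModel objects")
  if (length(msgs)) msgs else TRUE
})

exonMatrix <- function(exons) {
  m <- matrix(as.integer(exons), ncol = 2L,
              dimnames = list(NULL, c("start", "end")))
  m[order(m[, 1L]), , drop = FALSE]
}

cdsMatrix <- function(cds) {
  if (is.null(cds) || (is.matrix(cds) && nrow(cds) == 0L) || length(cds) == 0L)
    return(matrix(integer(), ncol = 3L,
                  dimnames = list(NULL, c("start", "end", "phase"))))
  m <- matrix(as.integer(cds), ncol = 3L,
              dimnames = list(NULL, c("start", "end", "phase")))
  m[order(m[, 1L]), , drop = FALSE]
}

#' Construct a TranscriptModel
#'
#' @param transcriptId transcript identifier.
#' @param exons two-column matrix (or coercible) of 0-based half-open exons.
#' @param cds three-column matrix of CDS segments with phase; may be empty.
#' @return a validated \linkS4class{TranscriptModel}.
#' @export
transcriptModel <- function(transcriptId, exons, cds = NULL) {
  new("TranscriptModel", transcriptId = as.character(transcriptId),
      exons = exonMatrix(exons), cds = cdsMatrix(cds))
}

#' Construct a GeneModel
#'
#' @param geneId gene identifier.
#' @param seqName sequence (chromosome) name.
#' @param strand \code{"+"} or \code{"-"}.
#' @param transcripts list of \linkS4class{TranscriptModel} (or a single one).
#' @param sourceHaplotype optional haplotype label.
#' @return a validated \linkS4class{GeneModel}.
#' @export
geneModel <- function(geneId, seqName, strand, transcripts,
                      sourceHaplotype = NA_character_) {
  if (is(transcripts, "TranscriptModel")) transcripts <- list(transcripts)
  new("GeneModel", geneId = as.character(geneId),
      seqName = as.character(seqName), strand = strand,
      transcripts = transcripts,
      sourceHaplotype = as.character(sourceHaplotype))
}

setMethod("show", "TranscriptModel", function(object) {
  n <- nrow(object@exons)
  cat("TranscriptModel", object@transcriptId, ": ", n,
      if (n == 1L) "exon" else "exons", ", CDS ",
      sum(object@cds[, 2L] - object@cds[, 1L]), " bp\n", sep = "")
})

setMethod("show", "GeneModel", function(object) {
  sp <- geneSpan(object)
  cat("GeneModel ", object@geneId, " ", object@seqName, ":",
      sp[1L] + 1L, "-", sp[2L], "(", object@strand, ") ",
      length(object@transcripts), " transcript(s)\n", sep = "")
})
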