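#' @rdname accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @rdname accessors
#' @export
setGeneric("transcriptId", function(x) standardGeneric("transcriptId"))

#' @rdname accessors
#' @export
setGeneric("seqName", function(x) standardGeneric("seqName"))

#' @rdname accessors
#' @export
setGeneric("geneStrand", function(x) standardGeneric("geneStrand"))

#' @rdname accessors
#' @export
setGeneric("transcripts", function(x) standardGeneric("transcripts"))

#' @rdname accessors
#' @export
setGeneric("exonTable", function(x) standardGeneric("exonTable"))

#' @rdname accessors
#' @export
setGeneric("cdsTable", function(x) standardGeneric("cdsTable"))

#' Accessors for gene and transcript models
#'
#' \code{geneId}, \code{seqName}, \code{geneStrand}, \code{transcripts} read
#' \linkS4class{GeneModel} slots; \code{transcriptId}, \code{exonTable},
#' \code{cdsTable} read \linkS4class{TranscriptModel} slots. Coordinates are
#' 0-based half-open.
#'
#' @param x a GeneModel or TranscriptModel.
#' @name accessors
NULL

#' @rdname accessors
setMethod("geneId", "GeneModel", function(x) x@geneId)
#' @rdname accessors
setMethod("seqName", "GeneModel", function(x) x@seqName)
#' @rdname accessors
setMethod("geneStrand", "GeneModel", function(x) x@strand)
#' @rdname accessors
setMethod("transcripts", "GeneModel", function(x) x@transcripts)
#' @rdname accessors
setMethod("transcriptId", "TranscriptModel", function(x) x@transcriptId)
#' @rdname accessors
setMethod("exonTable", "TranscriptModel", function(x) x@exons)
#' @rdname accessors
setMethod("cdsTable", "TranscriptModel", function(x) x@cds)

#' Total exon length of a transcript
#' @param tx a TranscriptModel.
#' @return integer, summed exon widths in bp.
#' @export
transcriptLength <- function(tx) sum(tx@exons[, 2L] - tx@exons[, 1L])

#' Total CDS length of a transcript
#' @param tx a TranscriptModel.
#' @return integer, summed CDS widths in bp.
#' @export
cdsLength <- function(tx) {
  if (nrow(tx@cds) == 0L) 0L else sum(tx@cds[, 2L] - tx@cds[, 1L])
}

#' Is the transcript mono-exonic?
#' @param tx a TranscriptModel.
#' @export
isMonoExonic <- function(tx) nrow(tx@exons) == 1L

#' Genomic span of a gene (0-based half-open)
#'
#' Covers all transcripts of the gene.
#' @param gene a GeneModel.
#' @return integer vector \code{c(start, end)}.
#' @export
geneSpan <- function(gene) {
  starts <- vapply(gene@transcripts, function(t) t@exons[1L, 1L], integer(1L))
  ends <- vapply(gene@transcripts, function(t) max(t@exons[, 2L]), integer(1L))
  c(min(starts), max(ends))
}

#' Representative transcript of a gene
#'
#' The longest transcript (by total exon length) represents the gene in all
#' protein-level decisions; ties are broken by lexicographic transcript id so
#' results are deterministic.
#' @param gene a GeneModel.
#' @return a TranscriptModel.
#' @export
representativeTranscript <- function(gene) {
  txs <- gene@transcripts
  if (length(txs) == 1L) return(txs[[1L]])
  lens <- vapply(txs, transcriptLength, integer(1L))
  ids <- vapply(txs, transcriptId, character(1L))
  txs[[order(-lens, ids)[1L]]]
}

#' Introns of a transcript (0-based half-open)
#' @param tx a TranscriptModel.
#' @return integer matrix with columns start, end; zero rows if mono-exonic.
#' @export
intronTable <- function(tx) {
  ex <- tx@exons
  if (nrow(ex) < 2L)
    return(matrix(integer(), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  cbind(start = ex[-nrow(ex), 2L], end = ex[-1L, 1L])
}

# named-list helpers for sets of gene models -------------------------------

modelList <- function(models) {
  stats::setNames(models, vapply(models, geneId, character(1L)))
}

#' Gene spans of a model set as a data.frame
#'
#' @param models named list of GeneModel.
#' @return data.frame with gene_id, seq_name, start, end (0-based half-open),
#'   strand.
#' @export
modelSpans <- function(models) {
  if (length(models) == 0L)
    return(data.frame(gene_id = character(), seq_name = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  sp <- t(vapply(models, geneSpan, integer(2L)))
  data.frame(
    gene_id = vapply(models, geneId, character(1L)),
    seq_name = vapply(models, seqName, character(1L)),
    start = sp[, 1L], end = sp[, 2L],
    strand = vapply(models, geneStrand, character(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
}
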