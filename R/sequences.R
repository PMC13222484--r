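#' Read a genome FASTA
#'
#' Sequences are uppercase-normalized on read; N is permitted and treated as a
#' mismatch by all downstream comparisons.
#'
#' @param path FASTA file.
#' @param haplotype optional haplotype label stored in the metadata.
#' @return a \link[Biostrings]{DNAStringSet} with unique names; the haplotype
#'   label is kept in \code{metadata(x)$haplotype}.
#' @export
readGenome <- function(path, haplotype = NA_character_) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate sequence names in ", path)
  x <- Biostrings::DNAStringSet(toupper(x))
  S4Vectors::metadata(x)$haplotype <- haplotype
  x
}

#' Write a genome FASTA
#' @param genome DNAStringSet.
#' @param path output file.
#' @export
writeGenome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

revComp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

subseqChar <- function(genome, seqname, start0, end0) {
  # 0-based half-open extraction from a DNAStringSet
  if (!seqname %in% names(genome))
    stop("sequence '", seqname, "' not found in genome")
  as.character(Biostrings::subseq(genome[[seqname]], start0 + 1L, end0))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Extract the CDS of a transcript and translate it
#'
#' Concatenates CDS segments in translation order (reverse-complemented for
#' minus-strand transcripts), honours the phase of the first segment, and
#' translates with the standard genetic code. A CDS whose length is not a
#' multiple of 3 is flagged and translated over the complete codons only.
#'
#' @param tx a \linkS4class{TranscriptModel} with a non-empty CDS.
#' @param genome DNAStringSet containing \code{seqname}.
#' @param seqname sequence the transcript lies on.
#' @param strand \code{"+"} or \code{"-"}.
#' @return list with \code{cds} (character), \code{peptide} (character, stops
#'   as \code{*}, terminal stop trimmed), and logical flags \code{has_start},
#'   \code{has_terminal_stop}, \code{internal_stop}, \code{length_ok}.
#' @export
extractCdsAndTranslate <- function(tx, genome, seqname, strand) {
  cds <- tx@cds
  if (nrow(cds) == 0L) stop("transcript ", tx@transcriptId, " has no CDS")
  segs <- lapply(seq_len(nrow(cds)), function(i)
    subseqChar(genome, seqname, cds[i, 1L], cds[i, 2L]))
  if (strand == "+") {
    s <- paste0(unlist(segs), collapse = "")
    phase <- cds[1L, 3L]
  } else {
    s <- paste0(rev(vapply(segs, revComp, character(1L))), collapse = "")
    phase <- cds[nrow(cds), 3L]
  }
  if (phase > 0L) s <- substring(s, phase + 1L)
  translateCdsString(s)
}

translateCdsString <- function(s) {
  n <- nchar(s)
  length_ok <- n %% 3L == 0L
  ncod <- n %/% 3L
  pep <- ""
  has_terminal_stop <- FALSE
  internal_stop <- FALSE
  if (ncod > 0L) {
    starts <- seq.int(1L, by = 3L, length.out = ncod)
    aa <- unname(Biostrings::GENETIC_CODE[substring(s, starts, starts + 2L)])
    aa[is.na(aa)] <- "X"  # codons containing N or other ambiguity
    pep <- paste(aa, collapse = "")
    if (aa[ncod] == "*") {
      has_terminal_stop <- TRUE
      pep <- substring(pep, 1L, ncod - 1L)
    }
    internal_stop <- grepl("*", pep, fixed = TRUE)
  }
  list(cds = s, peptide = pep,
       has_start = substring(s, 1L, 3L) == "ATG",
       has_terminal_stop = has_terminal_stop,
       internal_stop = internal_stop,
       length_ok = length_ok)
}

#' Peptide of a gene's representative transcript
#' @param gene GeneModel.
#' @param genome DNAStringSet.
#' @return character peptide (possibly containing \code{*} for internal stops).
#' @export
genePeptide <- function(gene, genome) {
  extractCdsAndTranslate(representativeTranscript(gene), genome,
                         seqName(gene), geneStrand(gene))$peptide
}

#' Apply a variant edit script to a genome
#'
#' Variants use VCF conventions: 1-based \code{pos}, indels anchored on the
#' preceding base. Records must not overlap, except that several records may
#' share one anchor position; those are composed in file order (a deletion
#' followed by an insertion at the same anchor is the encoding used for
#' inversions and translocations) before being applied. The edit is a single
#' left-to-right piecewise rebuild per sequence.
#'
#' @param genome DNAStringSet.
#' @param variants data.frame with seq_name, pos, ref, alt.
#' @return edited DNAStringSet.
#' @export
applyVariants <- function(genome, variants) {
  out <- as.list(as.character(genome))
  for (sn in unique(variants$seq_name)) {
    v <- variants[variants$seq_name == sn, , drop = FALSE]
    v <- v[order(v$pos, seq_len(nrow(v))), , drop = FALSE]
    # compose co-located records: later refs must match the running alt prefix
    eff <- list()
    i <- 1L
    while (i <= nrow(v)) {
      p <- v$pos[i]
      ref <- v$ref[i]
      alt <- v$alt[i]
      while (i < nrow(v) && v$pos[i + 1L] == p) {
        i <- i + 1L
        if (substring(alt, 1L, nchar(v$ref[i])) != v$ref[i])
          stop("co-located variant records at ", sn, ":", p,
               " do not compose")
        alt <- paste0(v$alt[i], substring(alt, nchar(v$ref[i]) + 1L))
        if (nchar(v$ref[i]) > nchar(ref)) ref <- v$ref[i]
      }
      eff[[length(eff) + 1L]] <- list(pos = p, ref = ref, alt = alt)
      i <- i + 1L
    }
    s <- out[[sn]]
    pieces <- character(2L * length(eff) + 1L)
    cur <- 1L
    for (k in seq_along(eff)) {
      e <- eff[[k]]
      if (e$pos < cur) stop("overlapping variant records at ", sn, ":", e$pos)
      if (substring(s, e$pos, e$pos + nchar(e$ref) - 1L) != e$ref)
        stop("variant REF mismatch at ", sn, ":", e$pos)
      pieces[2L * k - 1L] <- substring(s, cur, e$pos - 1L)
      pieces[2L * k] <- e$alt
      cur <- e$pos + nchar(e$ref)
    }
    pieces[2L * length(eff) + 1L] <- substring(s, cur, nchar(s))
    out[[sn]] <- paste(pieces, collapse = "")
  }
  res <- Biostrings::DNAStringSet(unlist(out))
  names(res) <- names(out)
  res
}
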