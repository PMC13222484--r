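EFFECT_SEVERITY <- c("start_lost", "stop_gained",
                     "splice_donor_lost", "splice_acceptor_lost",
                     "frameshift", "stop_lost", "inframe_indel",
                     "missense", "synonymous", "noncoding_region")

EFFECT_IMPACT <- c(start_lost = "HIGH", stop_gained = "HIGH",
                   stop_lost = "HIGH", frameshift = "HIGH",
                   splice_donor_lost = "HIGH", splice_acceptor_lost = "HIGH",
                   inframe_indel = "MODERATE", missense = "MODERATE",
                   synonymous = "LOW", noncoding_region = "MODIFIER")

#' Impact level of an effect class
#' @param effect_class character vector of effect classes.
#' @return character vector of impact levels (HIGH/MODERATE/LOW/MODIFIER).
#' @export
effectImpact <- function(effect_class) unname(EFFECT_IMPACT[effect_class])

mostSevere <- function(classes) {
  classes[which.min(match(classes, EFFECT_SEVERITY))]
}

# changed reference footprint of a variant, 0-based half-open; insertions
# have a zero-width footprint at the gap after the anchor base
variantFootprint <- function(variant) {
  p0 <- variant$pos - 1L
  nr <- nchar(variant$ref)
  na <- nchar(variant$alt)
  if (variant$var_class == "SNP") c(p0, p0 + 1L)
  else if (nr > na) c(p0 + na, p0 + nr)      # deleted bases
  else c(p0 + nr, p0 + nr)                   # insertion point
}

# map a reference footprint into CDS-relative coordinates; returns the list
# of (cds_offset_start, cds_offset_end) pieces covered, in genomic order
cdsOffsets <- function(cds, fp) {
  offs <- c(0L, cumsum(cds[, 2L] - cds[, 1L]))
  pieces <- list()
  for (i in seq_len(nrow(cds))) {
    a <- max(fp[1L], cds[i, 1L])
    z <- min(fp[2L], cds[i, 2L])
    if (a < z || (fp[1L] == fp[2L] && cds[i, 1L] < fp[1L] &&
                  fp[1L] < cds[i, 2L] && a == z && a >= cds[i, 1L] &&
                  a <= cds[i, 2L]))
      pieces[[length(pieces) + 1L]] <-
        c(offs[i] + a - cds[i, 1L], offs[i] + z - cds[i, 1L])
  }
  pieces
}

#' Classify the consequence of a variant on a transcript
#'
#' Determines the single most severe consequence by editing the coding
#' sequence in CDS coordinates and re-translating, plus splice-motif checks on
#' the first and last two bases of each intron. The severity order is
#' start_lost > stop_gained > splice > frameshift > stop_lost > inframe_indel
#' > missense > synonymous; variants outside the gene span, in intron
#' interiors or in non-coding exonic sequence are \code{noncoding_region}.
#'
#' @param gene GeneModel the variant is tested against (its representative
#'   transcript is used).
#' @param variant single-row variant data.frame (seq_name, pos, ref, alt,
#'   var_class) on the same coordinates as the gene.
#' @param genome DNAStringSet of the haplotype the coordinates refer to.
#' @return list with gene_id, transcript_id, effect_class, impact.
#' @export
classifyVariantEffect <- function(gene, variant, genome) {
  tx <- representativeTranscript(gene)
  strand <- geneStrand(gene)
  res <- function(cls) list(gene_id = geneId(gene),
                            transcript_id = transcriptId(tx),
                            effect_class = cls,
                            impact = unname(EFFECT_IMPACT[cls]))
  sp <- geneSpan(gene)
  fp <- variantFootprint(variant)
  if (variant$seq_name != seqName(gene) || fp[2L] <= sp[1L] ||
      fp[1L] >= sp[2L] || (fp[1L] == fp[2L] &&
                           (fp[1L] <= sp[1L] || fp[1L] >= sp[2L])))
    return(res("noncoding_region"))

  candidates <- character()

  # splice dinucleotides ---------------------------------------------------
  intr <- intronTable(tx)
  if (nrow(intr) > 0L) {
    for (i in seq_len(nrow(intr))) {
      don <- if (strand == "+") c(intr[i, 1L], intr[i, 1L] + 2L)
             else c(intr[i, 2L] - 2L, intr[i, 2L])
      acc <- if (strand == "+") c(intr[i, 2L] - 2L, intr[i, 2L])
             else c(intr[i, 1L], intr[i, 1L] + 2L)
      hits <- function(reg) {
        if (fp[1L] == fp[2L]) reg[1L] < fp[1L] && fp[1L] < reg[2L]
        else fp[1L] < reg[2L] && reg[1L] < fp[2L]
      }
      if (hits(don)) candidates <- c(candidates, "splice_donor_lost")
      if (hits(acc)) candidates <- c(candidates, "splice_acceptor_lost")
    }
  }

  # coding consequence via CDS-space edit ----------------------------------
  cds <- tx@cds
  inCds <- FALSE
  if (nrow(cds) > 0L) {
    pieces <- cdsOffsets(cds, fp)
    if (fp[1L] == fp[2L])  # insertion point inside a CDS segment?
      inCds <- any(cds[, 1L] < fp[1L] & fp[1L] < cds[, 2L])
    else inCds <- length(pieces) > 0L
    if (inCds) {
      orig <- extractCdsAndTranslate(tx, genome, seqName(gene), strand)
      cdsLen <- nchar(orig$cds)
      # CDS-space edit on the plus-strand concatenation, then reorient
      plusCds <- paste0(vapply(seq_len(nrow(cds)), function(i)
        subseqChar(genome, seqName(gene), cds[i, 1L], cds[i, 2L]),
        character(1L)), collapse = "")
      if (variant$var_class == "SNP") {
        off <- pieces[[1L]][1L]
        mut <- plusCds
        substring(mut, off + 1L, off + 1L) <- variant$alt
      } else if (nchar(variant$ref) > nchar(variant$alt)) {
        keep <- rep(TRUE, nchar(plusCds))
        for (p in pieces) if (p[1L] < p[2L])
          keep[(p[1L] + 1L):p[2L]] <- FALSE
        mut <- paste0(strsplit(plusCds, "")[[1L]][keep], collapse = "")
      } else {
        off <- pieces[[1L]][1L]
        insSeq <- substring(variant$alt, nchar(variant$ref) + 1L)
        mut <- paste0(substring(plusCds, 1L, off), insSeq,
                      substring(plusCds, off + 1L))
      }
      if (strand == "-") mut <- revComp(mut)
      mtr <- translateCdsString(mut)
      delta <- nchar(mut) - cdsLen
      if (orig$has_start && !mtr$has_start)
        candidates <- c(candidates, "start_lost")
      if (delta %% 3L != 0L)
        candidates <- c(candidates, "frameshift")
      # stop gain/loss and in-frame calls only apply when the frame is kept;
      # a stop is gained when the edit introduces an internal (premature)
      # stop codon the original coding sequence did not have
      if (delta %% 3L == 0L) {
        if (mtr$internal_stop && !orig$internal_stop)
          candidates <- c(candidates, "stop_gained")
        if (orig$has_terminal_stop && !mtr$has_terminal_stop &&
            !mtr$internal_stop)
          candidates <- c(candidates, "stop_lost")
        if (delta != 0L)
          candidates <- c(candidates, "inframe_indel")
      }
      if (delta == 0L && variant$var_class == "SNP") {
        candidates <- c(candidates,
                        if (identical(mtr$peptide, orig$peptide) &&
                            mtr$has_terminal_stop == orig$has_terminal_stop)
                          "synonymous" else "missense")
      }
    }
  }
  if (length(candidates) == 0L) return(res("noncoding_region"))
  res(mostSevere(candidates))
}

#' Call genes disabled by HIGH-impact variants
#'
#' A gene qualifies when at least one variant has a HIGH-impact consequence
#' (start/stop loss, premature stop, frameshift, splice-site loss) on its
#' representative transcript. Variants are tested independently.
#'
#' @param models named list of GeneModel.
#' @param variants variant data.frame on the same coordinates.
#' @param genome DNAStringSet.
#' @return character vector of gene ids.
#' @export
callHighEffectGenes <- function(models, variants, genome) {
  if (length(models) == 0L || nrow(variants) == 0L) return(character())
  sp <- modelSpans(models)
  hi <- character()
  for (sn in unique(sp$seq_name)) {
    g <- sp[sp$seq_name == sn, , drop = FALSE]
    v <- variants[variants$seq_name == sn, , drop = FALSE]
    if (nrow(v) == 0L) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(v$pos, v$pos + nchar(v$ref) - 1L),
      IRanges::IRanges(g$start + 1L, g$end))
    for (k in seq_along(ov)) {
      gid <- g$gene_id[S4Vectors::subjectHits(ov)[k]]
      if (gid %in% hi) next
      eff <- classifyVariantEffect(models[[gid]],
                                   v[S4Vectors::queryHits(ov)[k], , drop = FALSE],
                                   genome)
      if (eff$impact == "HIGH") hi <- c(hi, gid)
    }
  }
  sort(hi)
}
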