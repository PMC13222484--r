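srcCols <- function(direction) {
  if (direction == "h1to2")
    list(seq = "ref_seq", start = "ref_start", end = "ref_end",
         tseq = "qry_seq", tstart = "qry_start", tend = "qry_end")
  else
    list(seq = "qry_seq", start = "qry_start", end = "qry_end",
         tseq = "ref_seq", tstart = "ref_start", tend = "ref_end")
}

emptyMapped <- function() {
  data.frame(seq_name = character(), start = integer(), end = integer(),
             orientation = character(), block_class = character(),
             stringsAsFactors = FALSE)
}

#' Lift an interval between haplotypes through synteny blocks
#'
#' Piecewise-linear mapping within two-sided blocks (SYN, INV, TRANS, DUP).
#' INV blocks reverse coordinates (the mapped piece is flagged inverted).
#' Portions falling in NOTAL/INS/DEL records or in gaps between blocks are
#' unmapped and reduce \code{fraction_mapped}. Where a DUP block overlaps a
#' non-duplicated block on the source side, the non-DUP block takes priority,
#' so duplicated regions map to their primary copy.
#'
#' @param seqname source sequence name.
#' @param start0,end0 interval, 0-based half-open, on the source haplotype.
#' @param blocks synteny block data.frame (see \code{\link{readSynteny}}).
#' @param direction \code{"h1to2"} (ref to query) or \code{"h2to1"}.
#' @return list with \code{mapped} (data.frame of target pieces),
#'   \code{fraction_mapped}, \code{orientation_flips}, \code{blocks_crossed}.
#' @export
liftInterval <- function(seqname, start0, end0, blocks,
                         direction = c("h1to2", "h2to1")) {
  direction <- match.arg(direction)
  cl <- srcCols(direction)
  if (!seqname %in% c(blocks$ref_seq, blocks$qry_seq))
    stop("sequence '", seqname, "' not present in any synteny block")
  width <- end0 - start0
  keep <- !is.na(blocks[[cl$start]]) & !is.na(blocks[[cl$tstart]]) &
    !is.na(blocks[[cl$seq]]) & blocks[[cl$seq]] == seqname &
    blocks$class %in% c("SYN", "INV", "TRANS", "DUP") &
    (blocks[[cl$end]] - blocks[[cl$start]]) ==
      (blocks[[cl$tend]] - blocks[[cl$tstart]]) &
    blocks[[cl$start]] - 1L < end0 & start0 < blocks[[cl$end]]
  b <- blocks[which(keep), , drop = FALSE]
  b <- b[order(b$class == "DUP", b[[cl$start]]), , drop = FALSE]

  unmapped <- list(c(start0, end0))
  pieces <- list()
  crossed <- 0L
  for (i in seq_len(nrow(b))) {
    bs0 <- b[[cl$start]][i] - 1L
    be0 <- b[[cl$end]][i]
    qs <- b[[cl$tstart]][i]
    qe <- b[[cl$tend]][i]
    inv <- b$orientation[i] == "inverted"
    nxt <- list()
    used <- FALSE
    for (u in unmapped) {
      a <- max(u[1L], bs0)
      z <- min(u[2L], be0)
      if (a >= z) {
        nxt[[length(nxt) + 1L]] <- u
        next
      }
      used <- TRUE
      if (inv) {
        ts <- qe - 1L - (z - 1L - bs0)
        te <- qe - (a - bs0)
      } else {
        ts <- qs - 1L + (a - bs0)
        te <- qs - 1L + (z - bs0)
      }
      pieces[[length(pieces) + 1L]] <- data.frame(
        seq_name = b[[cl$tseq]][i], start = ts, end = te,
        orientation = if (inv) "inverted" else "same",
        block_class = b$class[i], stringsAsFactors = FALSE)
      if (u[1L] < a) nxt[[length(nxt) + 1L]] <- c(u[1L], a)
      if (z < u[2L]) nxt[[length(nxt) + 1L]] <- c(z, u[2L])
    }
    if (used) crossed <- crossed + 1L
    unmapped <- nxt
    if (length(unmapped) == 0L) break
  }
  mapped <- if (length(pieces)) do.call(rbind, pieces) else emptyMapped()
  list(mapped = mapped,
       fraction_mapped = if (width > 0L) sum(mapped$end - mapped$start) / width
                         else 0,
       orientation_flips = sum(mapped$orientation == "inverted"),
       blocks_crossed = crossed)
}

liftIntervalClean <- function(seqname, start0, end0, blocks, direction) {
  # returns a single contiguous target interval when the source maps fully
  # and contiguously with one orientation, else NULL
  lr <- liftInterval(seqname, start0, end0, blocks, direction)
  m <- lr$mapped
  if (nrow(m) == 0L || lr$fraction_mapped < 1) return(NULL)
  if (length(unique(m$seq_name)) != 1L ||
      length(unique(m$orientation)) != 1L) return(NULL)
  m <- m[order(m$start), , drop = FALSE]
  if (nrow(m) > 1L && any(m$start[-1L] != m$end[-nrow(m)])) return(NULL)
  list(seq_name = m$seq_name[1L], start = as.integer(min(m$start)),
       end = as.integer(max(m$end)),
       inverted = m$orientation[1L] == "inverted")
}

gffPhases <- function(widths) {
  # GFF3 phase of each CDS segment given widths in translation order
  cum <- c(0L, cumsum(widths))[seq_along(widths)]
  (3L - cum %% 3L) %% 3L
}

#' Project a gene model onto the other haplotype
#'
#' Each exon and CDS segment is lifted through the synteny blocks; exons that
#' do not map fully and contiguously are dropped. The projected model is
#' checked for intact splice sites (GT..AG at each projected intron, in
#' transcript orientation) and an intact ORF (ATG start, no internal stop,
#' terminal stop, length a multiple of 3).
#'
#' @param gene a \linkS4class{GeneModel} on the source haplotype.
#' @param blocks synteny blocks.
#' @param targetGenome DNAStringSet of the target haplotype.
#' @param direction \code{"h1to2"} or \code{"h2to1"}.
#' @param minFraction minimum fraction of exonic bases that must map
#'   (default 0.5); below it the projection fails and no model is emitted.
#' @param targetHaplotype label stored on the projected model.
#' @return list with \code{success}, \code{model} (GeneModel or NULL),
#'   \code{fraction_mapped}, \code{splice_sites_intact}, \code{orf_intact},
#'   \code{peptide}, \code{reason}.
#' @export
projectGeneModel <- function(gene, blocks, targetGenome,
                             direction = c("h1to2", "h2to1"),
                             minFraction = 0.5,
                             targetHaplotype = NA_character_) {
  direction <- match.arg(direction)
  tx <- representativeTranscript(gene)
  ex <- tx@exons
  fail <- function(reason, frac = 0) {
    list(success = FALSE, model = NULL, fraction_mapped = frac,
         splice_sites_intact = FALSE, orf_intact = FALSE,
         peptide = NA_character_, reason = reason)
  }
  total <- sum(ex[, 2L] - ex[, 1L])
  lifted <- vector("list", nrow(ex))
  mappedBp <- 0
  for (i in seq_len(nrow(ex))) {
    lr <- liftInterval(seqName(gene), ex[i, 1L], ex[i, 2L], blocks, direction)
    mappedBp <- mappedBp + lr$fraction_mapped * (ex[i, 2L] - ex[i, 1L])
    lifted[[i]] <- liftIntervalClean(seqName(gene), ex[i, 1L], ex[i, 2L],
                                     blocks, direction)
  }
  frac <- mappedBp / total
  if (frac < minFraction) return(fail("fraction_below_floor", frac))
  keep <- !vapply(lifted, is.null, logical(1L))
  if (!any(keep)) return(fail("no_exon_mapped", frac))
  lifted <- lifted[keep]
  seqs <- vapply(lifted, `[[`, character(1L), "seq_name")
  invs <- vapply(lifted, `[[`, logical(1L), "inverted")
  if (length(unique(seqs)) != 1L || length(unique(invs)) != 1L)
    return(fail("inconsistent_mapping", frac))
  tseq <- seqs[1L]
  tstrand <- if (invs[1L]) setdiff(c("+", "-"), geneStrand(gene)) else
    geneStrand(gene)
  exNew <- cbind(vapply(lifted, `[[`, integer(1L), "start"),
                 vapply(lifted, `[[`, integer(1L), "end"))
  exNew <- exNew[order(exNew[, 1L]), , drop = FALSE]

  cdsNew <- NULL
  if (nrow(tx@cds) > 0L) {
    lc <- lapply(seq_len(nrow(tx@cds)), function(i)
      liftIntervalClean(seqName(gene), tx@cds[i, 1L], tx@cds[i, 2L],
                        blocks, direction))
    lc <- lc[!vapply(lc, is.null, logical(1L))]
    lc <- Filter(function(p) p$seq_name == tseq &&
                   any(exNew[, 1L] <= p$start & p$end <= exNew[, 2L]), lc)
    if (length(lc) == 0L) return(fail("cds_unmapped", frac))
    cm <- cbind(vapply(lc, `[[`, integer(1L), "start"),
                vapply(lc, `[[`, integer(1L), "end"))
    cm <- cm[order(cm[, 1L]), , drop = FALSE]
    w <- cm[, 2L] - cm[, 1L]
    ph <- if (tstrand == "+") gffPhases(w) else rev(gffPhases(rev(w)))
    cdsNew <- cbind(cm, ph)
  }
  txNew <- transcriptModel(transcriptId(tx), exNew, cdsNew)
  gNew <- geneModel(geneId(gene), tseq, tstrand, txNew,
                    sourceHaplotype = targetHaplotype)

  splice_ok <- TRUE
  intr <- intronTable(txNew)
  if (nrow(intr) > 0L) {
    for (i in seq_len(nrow(intr))) {
      s <- subseqChar(targetGenome, tseq, intr[i, 1L], intr[i, 2L])
      if (tstrand == "-") s <- revComp(s)
      if (substring(s, 1L, 2L) != "GT" ||
          substring(s, nchar(s) - 1L) != "AG") {
        splice_ok <- FALSE
        break
      }
    }
  }
  orf_ok <- FALSE
  pep <- NA_character_
  if (!is.null(cdsNew)) {
    tr <- extractCdsAndTranslate(txNew, targetGenome, tseq, tstrand)
    orf_ok <- tr$has_start && tr$has_terminal_stop && !tr$internal_stop &&
      tr$length_ok
    pep <- tr$peptide
  }
  list(success = TRUE, model = gNew, fraction_mapped = frac,
       splice_sites_intact = splice_ok, orf_intact = orf_ok,
       peptide = pep, reason = NA_character_)
}

unionCoverage <- function(start0, end0, ivStart0, ivEnd0) {
  # bp of [start0,end0) covered by the union of the given intervals
  s <- pmax(ivStart0, start0)
  e <- pmin(ivEnd0, end0)
  keep <- !is.na(s) & !is.na(e) & s < e
  if (!any(keep)) return(0L)
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(s[keep] + 1L, e[keep]))))
}

#' Structural-variant evidence for a gene
#'
#' Tests a gene against structural differences (>= \code{minSvLen} bp) between
#' the haplotypes: a deletion removing the whole gene span, deletions removing
#' at least half of its coding bases, a long insertion inside a coding
#' segment, an inversion touching coding sequence, or residence in an
#' unaligned (NOTAL) region. The highest-priority satisfied class is returned.
#' For a gene on haplotype 1, "deleted" means the sequence is absent from
#' haplotype 2 (DEL records); for a haplotype-2 gene the roles of INS and DEL
#' swap. Coding overlap is computed on the union of CDS segments of the
#' representative transcript.
#'
#' @param gene GeneModel.
#' @param variants variant data.frame (haplotype-1 reference coordinates);
#'   only used for genes on haplotype 1.
#' @param blocks synteny blocks.
#' @param haplotype \code{"h1"} or \code{"h2"}: which haplotype the gene's
#'   coordinates refer to.
#' @param minSvLen minimum structural-variant length (default 50 bp).
#' @return list with \code{gene_id}, \code{evidence_class},
#'   \code{overlap_fraction}.
#' @export
svEvidenceForGene <- function(gene, variants, blocks,
                              haplotype = c("h1", "h2"), minSvLen = 50L) {
  haplotype <- match.arg(haplotype)
  sp <- geneSpan(gene)
  sn <- seqName(gene)
  tx <- representativeTranscript(gene)
  cds <- tx@cds
  cdsBp <- cdsLength(tx)
  own <- if (haplotype == "h1")
    list(seq = "ref_seq", start = "ref_start", end = "ref_end",
         del = "DEL", ins = "INS")
  else
    list(seq = "qry_seq", start = "qry_start", end = "qry_end",
         del = "INS", ins = "DEL")

  bOwn <- blocks[!is.na(blocks[[own$seq]]) & blocks[[own$seq]] == sn, ,
                 drop = FALSE]
  ownIv <- function(b) cbind(b[[own$start]] - 1L, b[[own$end]])

  # deletion events: own-side intervals whose sequence is absent opposite
  delB <- bOwn[bOwn$class == own$del &
               !is.na(bOwn[[own$start]]) &
               (bOwn[[own$end]] - bOwn[[own$start]] + 1L) >= minSvLen, ,
               drop = FALSE]
  delIv <- if (nrow(delB)) ownIv(delB) else
    matrix(integer(), ncol = 2L)
  if (haplotype == "h1" && nrow(variants)) {
    v <- variants[variants$seq_name == sn & variants$var_class == "DEL" &
                  nchar(variants$ref) - nchar(variants$alt) >= minSvLen, ,
                  drop = FALSE]
    if (nrow(v))
      delIv <- rbind(delIv, cbind(v$pos, v$pos + nchar(v$ref) - 1L))
  }

  # insertion anchors: points where a long opposite-haplotype-only sequence sits
  insB <- bOwn[bOwn$class == own$ins, , drop = FALSE]
  if (nrow(insB)) {
    othLen <- if (haplotype == "h1")
      insB$qry_end - insB$qry_start + 1L else insB$ref_end - insB$ref_start + 1L
    insPts <- insB[[own$start]][!is.na(othLen) & othLen >= minSvLen]
    insPts <- insPts[!is.na(insPts)]
  } else insPts <- integer()
  if (haplotype == "h1" && nrow(variants)) {
    v <- variants[variants$seq_name == sn & variants$var_class == "INS" &
                  nchar(variants$alt) - nchar(variants$ref) >= minSvLen, ,
                  drop = FALSE]
    insPts <- c(insPts, v$pos)
  }

  invB <- bOwn[bOwn$class == "INV" &
               (bOwn[[own$end]] - bOwn[[own$start]] + 1L) >= minSvLen, ,
               drop = FALSE]
  notB <- bOwn[bOwn$class == "NOTAL", , drop = FALSE]

  result <- function(cls, frac) list(gene_id = geneId(gene),
                                     evidence_class = cls,
                                     overlap_fraction = frac)
  if (nrow(delIv)) {
    if (any(delIv[, 1L] <= sp[1L] & sp[2L] <= delIv[, 2L]))
      return(result("whole_gene_deleted", 1))
    if (cdsBp > 0L) {
      cov <- sum(vapply(seq_len(nrow(cds)), function(i)
        unionCoverage(cds[i, 1L], cds[i, 2L], delIv[, 1L], delIv[, 2L]),
        integer(1L)))
      if (cov / cdsBp >= 0.5)
        return(result("coding_majority_deleted", cov / cdsBp))
    }
  }
  if (length(insPts) && nrow(cds)) {
    # anchor base strictly inside a CDS segment (0-based point pos-1)
    inside <- vapply(insPts, function(p)
      any(cds[, 1L] < p & p < cds[, 2L]), logical(1L))
    if (any(inside)) return(result("coding_insertion", NA_real_))
  }
  if (nrow(invB) && nrow(cds)) {
    iv <- ownIv(invB)
    ov <- sum(vapply(seq_len(nrow(cds)), function(i)
      unionCoverage(cds[i, 1L], cds[i, 2L], iv[, 1L], iv[, 2L]), integer(1L)))
    if (ov >= 1L) return(result("coding_inverted", ov / cdsBp))
  }
  if (nrow(notB)) {
    cov <- unionCoverage(sp[1L], sp[2L], notB[[own$start]] - 1L,
                         notB[[own$end]])
    if (cov == sp[2L] - sp[1L])
      return(result("unaligned_region", 1))
  }
  result("none", 0)
}

#' Re-anchor variants onto the second haplotype
#'
#' Maps variant anchor positions through the synteny blocks and swaps REF and
#' ALT so the edits are expressed with haplotype 2 as the reference. Variants
#' whose anchors do not map, or that fall in inverted blocks, are dropped with
#' a message.
#'
#' @param variants variant data.frame in haplotype-1 coordinates.
#' @param blocks synteny blocks.
#' @return variant data.frame in haplotype-2 coordinates.
#' @export
invertVariants <- function(variants, blocks) {
  rows <- vector("list", nrow(variants))
  dropped <- 0L
  for (i in seq_len(nrow(variants))) {
    p0 <- variants$pos[i] - 1L
    lr <- tryCatch(
      liftInterval(variants$seq_name[i], p0, p0 + 1L, blocks, "h1to2"),
      error = function(e) NULL)
    if (is.null(lr) || nrow(lr$mapped) != 1L ||
        lr$mapped$orientation[1L] == "inverted") {
      dropped <- dropped + 1L
      next
    }
    rows[[i]] <- data.frame(
      seq_name = lr$mapped$seq_name[1L], pos = lr$mapped$start[1L] + 1L,
      ref = variants$alt[i], alt = variants$ref[i],
      var_class = c(SNP = "SNP", INS = "DEL", DEL = "INS")[
        variants$var_class[i]],
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (dropped > 0L)
    message("invertVariants: dropped ", dropped, " unmappable variant(s)")
  if (length(rows) == 0L)
    return(variants[0L, , drop = FALSE])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
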