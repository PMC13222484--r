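# constructed loci, independent oracles and a cached fixture battery

DNA4 <- c("A", "C", "G", "T")

rseq <- function(n) paste(sample(DNA4, n, replace = TRUE), collapse = "")

revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# build a locus from explicit CDS codon string, exon widths and intron widths;
# returns genome (DNAStringSet) and a GeneModel
makeLocus <- function(cds, exonWidths, intronWidths, strand = "+",
                      flank = 60L, seqname = "chrT", geneId = "gT") {
  stopifnot(sum(exonWidths) == nchar(cds),
            length(intronWidths) == length(exonWidths) - 1L)
  pre <- character(0)
  exTx <- matrix(0L, length(exonWidths), 2L)
  cum <- 0L
  cpos <- 1L
  for (i in seq_along(exonWidths)) {
    w <- exonWidths[i]
    pre <- c(pre, substring(cds, cpos, cpos + w - 1L))
    exTx[i, ] <- c(cum, cum + w)
    cum <- cum + w
    cpos <- cpos + w
    if (i < length(exonWidths)) {
      il <- intronWidths[i]
      pre <- c(pre, paste0("GT", rseq(il - 4L), "AG"))
      cum <- cum + il
    }
  }
  locus <- paste(pre, collapse = "")
  L <- nchar(locus)
  if (strand == "-") {
    locus <- revcomp(locus)
    ex <- cbind(flank + L - exTx[, 2L], flank + L - exTx[, 1L])
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
  } else {
    ex <- cbind(flank + exTx[, 1L], flank + exTx[, 2L])
  }
  w <- ex[, 2L] - ex[, 1L]
  cum2 <- if (strand == "+") c(0L, cumsum(w))[seq_along(w)] else
    rev(c(0L, cumsum(rev(w)))[seq_along(w)])
  ph <- (3L - cum2 %% 3L) %% 3L
  g <- geneModel(geneId, seqname, strand,
                 transcriptModel(paste0(geneId, ".t1"), ex, cbind(ex, ph)))
  genome <- Biostrings::DNAStringSet(stats::setNames(
    paste0(rseq(flank), locus, rseq(flank)), seqname))
  list(genome = genome, gene = g, cds = cds)
}

# a deterministic 3-exon test gene (27 bp CDS, peptide MAWKPFDE)
standardLocus <- function(strand = "+") {
  set.seed(404)
  makeLocus("ATGGCCTGGAAACCCTTTGATGAATAG", c(9L, 9L, 9L), c(24L, 30L),
            strand = strand)
}

# random multi-exon locus for property tests (RNG state of caller is used)
randomLocus <- function(strand = sample(c("+", "-"), 1L)) {
  naa <- sample(20:60, 1L)
  cds <- paste0("ATG",
                paste(sample(setdiff(
                  as.vector(outer(as.vector(outer(DNA4, DNA4, paste0)),
                                  DNA4, paste0)),
                  c("TAA", "TAG", "TGA")), naa, replace = TRUE),
                  collapse = ""),
                sample(c("TAA", "TAG", "TGA"), 1L))
  nEx <- sample(1:4, 1L)
  w <- rep(nchar(cds) %/% nEx, nEx)
  w[nEx] <- w[nEx] + nchar(cds) %% nEx
  makeLocus(cds, w, if (nEx > 1L) sample(20:60, nEx - 1L, replace = TRUE)
            else integer(), strand = strand)
}

# independent translation oracle: Biostrings::translate on the spliced CDS
oracleTranslate <- function(gene, genome) {
  tx <- representativeTranscript(gene)
  cds <- cdsTable(tx)
  chrom <- as.character(genome)[[seqName(gene)]]
  segs <- substring(chrom, cds[, 1L] + 1L, cds[, 2L])
  s <- if (geneStrand(gene) == "+") paste(segs, collapse = "") else
    paste(rev(vapply(segs, revcomp, character(1L))), collapse = "")
  n3 <- (nchar(s) %/% 3L) * 3L
  as.character(Biostrings::translate(Biostrings::DNAString(substring(s, 1, n3)),
                                     if.fuzzy.codon = "solve",
                                     no.init.codon = TRUE))
}

# brute-force effect oracle: rebuild the mutated locus genomically, remap the
# exon/CDS boundaries, re-extract and diff peptides
oracleEffect <- function(gene, variant, genome) {
  tx <- representativeTranscript(gene)
  strand <- geneStrand(gene)
  sn <- seqName(gene)
  sp <- geneSpan(gene)
  nr <- nchar(variant$ref)
  na <- nchar(variant$alt)
  p0 <- variant$pos - 1L
  changed <- if (variant$var_class == "SNP") p0 else
    if (nr > na) seq(p0 + na, p0 + nr - 1L) else integer()  # deleted bases
  gap <- if (na > nr) p0 + nr else NA_integer_              # insertion point
  inSpan <- if (length(changed)) any(changed >= sp[1L] & changed < sp[2L])
            else (!is.na(gap) && gap > sp[1L] && gap < sp[2L])
  if (variant$seq_name != sn || !inSpan) return("noncoding_region")

  # splice rule: the variant alters the first or last 2 intron bases
  intr <- intronTable(tx)
  spliceHit <- c(donor = FALSE, acceptor = FALSE)
  for (i in seq_len(nrow(intr))) {
    don <- if (strand == "+") c(intr[i, 1L], intr[i, 1L] + 1L) else
      c(intr[i, 2L] - 1L, intr[i, 2L] - 2L)
    acc <- if (strand == "+") c(intr[i, 2L] - 2L, intr[i, 2L] - 1L) else
      c(intr[i, 1L] + 1L, intr[i, 1L])
    altered <- function(pp) {
      if (length(changed)) any(changed %in% pp) else
        (!is.na(gap) && gap == max(pp))
    }
    if (altered(don)) spliceHit["donor"] <- TRUE
    if (altered(acc)) spliceHit["acceptor"] <- TRUE
  }

  # genomic rebuild
  mutGenome <- applyVariants(genome, variant)
  delta <- na - nr
  remap <- function(x, isEnd) {
    if (nr > na) {  # deletion of [ds, de)
      ds <- p0 + na
      de <- p0 + nr
      if (x <= ds) x else if (x >= de) x + delta else ds
    } else if (na > nr) {
      if (x < gap || (isEnd && x == gap)) x else x + delta
    } else x
  }
  cds <- cdsTable(tx)
  newCds <- cbind(vapply(cds[, 1L], remap, 0L, isEnd = FALSE),
                  vapply(cds[, 2L], remap, 0L, isEnd = TRUE))
  newCds <- newCds[newCds[, 2L] > newCds[, 1L], , drop = FALSE]
  chrom <- as.character(mutGenome)[[sn]]
  extract <- function(m, chr) {
    segs <- substring(chr, m[, 1L] + 1L, m[, 2L])
    if (strand == "+") paste(segs, collapse = "") else
      paste(rev(vapply(segs, revcomp, character(1L))), collapse = "")
  }
  origChrom <- as.character(genome)[[sn]]
  origCdsSeq <- extract(cds[, 1:2, drop = FALSE], origChrom)
  mutCdsSeq <- if (nrow(newCds)) extract(newCds, chrom) else ""
  tr <- function(s) {
    n3 <- (nchar(s) %/% 3L) * 3L
    if (n3 == 0L) return("")
    as.character(Biostrings::translate(
      Biostrings::DNAString(substring(s, 1L, n3)),
      if.fuzzy.codon = "solve", no.init.codon = TRUE))
  }
  op <- tr(origCdsSeq)
  mp <- tr(mutCdsSeq)
  cdsDelta <- nchar(mutCdsSeq) - nchar(origCdsSeq)
  inCds <- if (length(changed))
    any(vapply(changed, function(x)
      any(cds[, 1L] <= x & x < cds[, 2L]), logical(1L)))
  else (!is.na(gap) && any(cds[, 1L] < gap & gap < cds[, 2L]))

  cand <- character()
  if (spliceHit["donor"]) cand <- c(cand, "splice_donor_lost")
  if (spliceHit["acceptor"]) cand <- c(cand, "splice_acceptor_lost")
  if (inCds) {
    internalStop <- function(p) grepl("*", sub("\\*$", "", p), fixed = TRUE)
    if (substring(origCdsSeq, 1L, 3L) == "ATG" &&
        substring(mutCdsSeq, 1L, 3L) != "ATG")
      cand <- c(cand, "start_lost")
    if (cdsDelta %% 3L != 0L) cand <- c(cand, "frameshift")
    if (cdsDelta %% 3L == 0L) {
      if (internalStop(mp) && !internalStop(op))
        cand <- c(cand, "stop_gained")
      opTerm <- substring(op, nchar(op)) == "*"
      mpTerm <- substring(mp, nchar(mp)) == "*"
      if (opTerm && !mpTerm && !grepl("*", sub("\\*$", "", mp), fixed = TRUE))
        cand <- c(cand, "stop_lost")
      if (cdsDelta != 0L) cand <- c(cand, "inframe_indel")
      if (cdsDelta == 0L && variant$var_class == "SNP")
        cand <- c(cand, if (identical(op, mp)) "synonymous" else "missense")
    }
  }
  if (length(cand) == 0L) return("noncoding_region")
  sev <- c("start_lost", "stop_gained", "splice_donor_lost",
           "splice_acceptor_lost", "frameshift", "stop_lost",
           "inframe_indel", "missense", "synonymous")
  cand[which.min(match(cand, sev))]
}

# random variant inside (or near) a gene span
randomVariantFor <- function(gene, genome) {
  sp <- geneSpan(gene)
  chrom <- as.character(genome)[[seqName(gene)]]
  pos <- sample(max(2L, sp[1L] - 5L):min(nchar(chrom) - 12L, sp[2L] + 5L), 1L)
  kind <- sample(c("SNP", "INS", "DEL"), 1L, prob = c(0.5, 0.25, 0.25))
  base <- substring(chrom, pos, pos)
  if (kind == "SNP") {
    data.frame(seq_name = seqName(gene), pos = pos, ref = base,
               alt = sample(setdiff(DNA4, base), 1L), var_class = "SNP",
               stringsAsFactors = FALSE)
  } else if (kind == "INS") {
    data.frame(seq_name = seqName(gene), pos = pos, ref = base,
               alt = paste0(base, rseq(sample(1:6, 1L))), var_class = "INS",
               stringsAsFactors = FALSE)
  } else {
    len <- sample(1:6, 1L)
    data.frame(seq_name = seqName(gene), pos = pos,
               ref = substring(chrom, pos, pos + len), alt = base,
               var_class = "DEL", stringsAsFactors = FALSE)
  }
}

# the default fixture battery, simulated and refined once per test run
batteryEnv <- new.env(parent = emptyenv())

getBattery <- function() {
  if (is.null(batteryEnv$sim)) {
    batteryEnv$sim <- simulateHaplotypePair(simulationConfig(seed = 20260101))
    batteryEnv$res <- runRefinement(batteryEnv$sim)
  }
  list(sim = batteryEnv$sim, res = batteryEnv$res)
}
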