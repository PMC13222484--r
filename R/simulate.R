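DNA <- c("A", "C", "G", "T")
ALL_CODONS <- as.vector(outer(as.vector(outer(DNA, DNA, paste0)), DNA, paste0))
CODING_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

randSeq <- function(n) paste(sample(DNA, n, replace = TRUE), collapse = "")

#' Configuration for the diploid fixture simulator
#'
#' Defaults describe the study conditions of the fixture battery: two 2.5 Mb
#' chromosomes, 500 protein-coding genes with 1-6 exons (GT..AG introns, ATG
#' start, terminal stop), SNP and small-indel densities of 7.6 and 2.1 per kb
#' (typical of a heterozygous diploid crop genome), a handful of structural
#' events per class, and planted annotation errors: dropped, split and merged
#' models, spurious short models, genes disabled by exactly one HIGH-impact
#' variant, and hemizygous genes removed by a whole-gene deletion.
#'
#' @param seed integer seed fixing all randomness.
#' @param n_chrom,chrom_len,n_genes genome layout.
#' @param snp_rate,indel_rate per-bp planted variant densities (SNPs avoid
#'   exons and splice dinucleotides so intact genes stay coding-identical;
#'   indels are intergenic).
#' @param sv_events data.frame with columns class
#'   (DEL/INS/INV/DUP/TRANS/NOTAL) and length: intergenic structural events.
#' @param drop_fraction,split_fraction,merge_fraction,spurious_fraction
#'   proportions of planted annotation errors.
#' @param disabled_fraction genes given one HIGH-impact variant (start loss,
#'   premature stop, frameshift or splice loss, chosen uniformly) and left
#'   unannotated on haplotype 2.
#' @param hemizygous_fraction genes whose haplotype-2 locus is deleted whole.
#' @param te_density fraction of intergenic sequence covered by TE intervals.
#' @param tissues tissue names for expression tables.
#' @param expression list: \code{category_probs} (Balanced/H1_dominant/
#'   H2_dominant/NE), \code{divergent_fraction} (expressed pairs given one
#'   switched tissue), \code{dominant_share} (expected dominant-allele
#'   proportion), \code{dispersion} (sd of the share noise), \code{floor}
#'   (TPM sum under which a tissue is not expressed).
#' @return a validated list of class \code{simulationConfig}.
#' @export
simulationConfig <- function(seed = 1L, n_chrom = 2L, chrom_len = 2500000L,
                             n_genes = 500L,
                             snp_rate = 0.0076, indel_rate = 0.0021,
                             sv_events = data.frame(
                               class = c("DEL", "INS", "INV", "DUP", "TRANS",
                                         "NOTAL", "NOTAL"),
                               length = c(3000L, 2000L, 4000L, 3000L, 3000L,
                                          5000L, 5000L)),
                             drop_fraction = 0.05, split_fraction = 0.03,
                             merge_fraction = 0.02, spurious_fraction = 0.05,
                             disabled_fraction = 0.05,
                             hemizygous_fraction = 0.02,
                             te_density = 0.2,
                             tissues = c("leaf", "root", "flower", "fruit"),
                             expression = list()) {
  expr <- utils::modifyList(list(
    category_probs = c(Balanced = 0.60, H1_dominant = 0.15,
                       H2_dominant = 0.15, NE = 0.10),
    divergent_fraction = 0.33, dominant_share = 0.92,
    dispersion = 0.02, floor = 0.5), expression)
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              chrom_len = as.integer(chrom_len), n_genes = as.integer(n_genes),
              snp_rate = snp_rate, indel_rate = indel_rate,
              sv_events = sv_events,
              drop_fraction = drop_fraction, split_fraction = split_fraction,
              merge_fraction = merge_fraction,
              spurious_fraction = spurious_fraction,
              disabled_fraction = disabled_fraction,
              hemizygous_fraction = hemizygous_fraction,
              te_density = te_density, tissues = tissues, expression = expr)
  rates <- c(cfg$snp_rate, cfg$indel_rate, cfg$te_density,
             cfg$drop_fraction, cfg$split_fraction, cfg$merge_fraction,
             cfg$spurious_fraction, cfg$disabled_fraction,
             cfg$hemizygous_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates and fractions must be in [0,1]")
  if (sum(cfg$drop_fraction, cfg$split_fraction, cfg$merge_fraction,
          cfg$disabled_fraction, cfg$hemizygous_fraction) > 1)
    stop("planted error fractions must sum to at most 1")
  if (!all(cfg$sv_events$class %in% c("DEL", "INS", "INV", "DUP", "TRANS",
                                      "NOTAL")))
    stop("unknown sv_events class")
  if (any(cfg$sv_events$length >= cfg$chrom_len))
    stop("structural event longer than a chromosome")
  structure(cfg, class = "simulationConfig")
}

# one gene template in transcript space --------------------------------------
geneTemplate <- function() {
  naa <- sample(100:400, 1L)
  cdsLen <- 3L * naa + 3L
  nEx <- sample(1:6, 1L)
  if (nEx > 1L) {
    w <- runif(nEx)
    widths <- floor(w / sum(w) * (cdsLen - 30L * nEx)) + 30L
    widths[nEx] <- cdsLen - sum(widths[-nEx])
  } else widths <- cdsLen
  introns <- if (nEx > 1L) sample(60:300, nEx - 1L, replace = TRUE)
             else integer()
  cdsSeq <- paste0("ATG",
                   paste(sample(CODING_CODONS, naa - 1L, replace = TRUE),
                         collapse = ""),
                   sample(STOP_CODONS, 1L))
  list(nEx = nEx, widths = widths, introns = introns, cdsSeq = cdsSeq,
       strand = sample(c("+", "-"), 1L),
       locusLen = cdsLen + sum(introns))
}

# pre-mRNA (5'->3') with GT..AG introns; returns locus string plus
# transcript-space exon offsets
templateLocus <- function(tpl) {
  pre <- character(2L * tpl$nEx - 1L)
  exTx <- matrix(0L, tpl$nEx, 2L)
  cum <- 0L
  cdsPos <- 1L
  for (i in seq_len(tpl$nEx)) {
    w <- tpl$widths[i]
    pre[2L * i - 1L] <- substring(tpl$cdsSeq, cdsPos, cdsPos + w - 1L)
    exTx[i, ] <- c(cum, cum + w)
    cum <- cum + w
    cdsPos <- cdsPos + w
    if (i < tpl$nEx) {
      il <- tpl$introns[i]
      pre[2L * i] <- paste0("GT", randSeq(il - 4L), "AG")
      cum <- cum + il
    }
  }
  list(seq = paste(pre, collapse = ""), exTx = exTx)
}

# genomic exon/CDS matrices for a locus starting at `start0`
templateExons <- function(tpl, exTx, start0) {
  L <- tpl$locusLen
  if (tpl$strand == "+") {
    ex <- cbind(start0 + exTx[, 1L], start0 + exTx[, 2L])
  } else {
    ex <- cbind(start0 + L - exTx[, 2L], start0 + L - exTx[, 1L])
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
  }
  wOrd <- ex[, 2L] - ex[, 1L]
  ph <- if (tpl$strand == "+") gffPhases(wOrd) else rev(gffPhases(rev(wOrd)))
  list(exons = ex, cds = cbind(ex, ph))
}

buildGeneModelAt <- function(id, seqname, tpl, exTx, start0, hap) {
  te <- templateExons(tpl, exTx, start0)
  geneModel(id, seqname, tpl$strand,
            transcriptModel(paste0(id, ".t1"), te$exons, te$cds),
            sourceHaplotype = hap)
}

# genomic 0-based positions of CDS bases in translation order
cdsPositionsTx <- function(cds, strand) {
  segs <- lapply(seq_len(nrow(cds)), function(i) cds[i, 1L]:(cds[i, 2L] - 1L))
  if (strand == "+") unlist(segs) else rev(unlist(segs))
}

complementBase <- function(b) c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]

# pick a single SNP/1-bp-del disabling a gene; returns variant row
disablingVariant <- function(gene, genome, type) {
  tx <- representativeTranscript(gene)
  strand <- geneStrand(gene)
  sn <- seqName(gene)
  pos <- cdsPositionsTx(tx@cds, strand)
  baseAt <- function(p0) subseqChar(genome, sn, p0, p0 + 1L)
  txBase <- function(p0) if (strand == "+") baseAt(p0) else
    unname(complementBase(baseAt(p0)))
  snpRow <- function(p0, altTx) {
    alt <- if (strand == "+") altTx else unname(complementBase(altTx))
    data.frame(seq_name = sn, pos = p0 + 1L, ref = baseAt(p0), alt = alt,
               var_class = "SNP", stringsAsFactors = FALSE)
  }
  if (type == "start_lost") return(snpRow(pos[1L], "C"))
  if (type == "splice_loss") {
    intr <- intronTable(tx)
    i <- sample(nrow(intr), 1L)
    p0 <- if (strand == "+") intr[i, 1L] + 1L else intr[i, 2L] - 2L
    return(snpRow(p0, "A"))  # donor GT -> GA in transcript orientation
  }
  if (type == "stop_gained") {
    naa <- length(pos) %/% 3L
    for (j in sample(5:(naa - 5L))) {
      cod <- paste0(txBase(pos[3L * j - 2L]), txBase(pos[3L * j - 1L]),
                    txBase(pos[3L * j]))
      for (s in STOP_CODONS) {
        diffAt <- which(strsplit(cod, "")[[1L]] != strsplit(s, "")[[1L]])
        if (length(diffAt) == 1L)
          return(snpRow(pos[3L * (j - 1L) + diffAt],
                        substring(s, diffAt, diffAt)))
      }
    }
    type <- "frameshift"  # unreachable in practice
  }
  # frameshift: delete one CDS base mid-gene (anchored on the previous base)
  k <- length(pos) %/% 2L
  ord <- sort(c(pos[k], pos[k] - 1L))
  p0 <- ord[1L]
  data.frame(seq_name = sn, pos = p0 + 1L,
             ref = subseqChar(genome, sn, p0, p0 + 2L),
             alt = baseAt(p0), var_class = "DEL", stringsAsFactors = FALSE)
}

freeIntervals <- function(occupied, lo, hi) {
  # occupied: 2-col 0-based matrix; returns free 0-based intervals in [lo,hi)
  if (nrow(occupied) == 0L) return(matrix(c(lo, hi), ncol = 2L))
  occ <- occupied[order(occupied[, 1L]), , drop = FALSE]
  ir <- IRanges::reduce(IRanges::IRanges(occ[, 1L] + 1L, occ[, 2L]))
  free <- IRanges::gaps(ir, start = lo + 1L, end = hi)
  cbind(IRanges::start(free) - 1L, IRanges::end(free))
}

#' Simulate a diploid haplotype pair with planted truth
#'
#' Builds haplotype 1 (random intergenic sequence plus simulated gene loci),
#' derives haplotype 2 by planting SNPs, small indels and structural events,
#' and emits annotations with planted errors, the exact variant edit script,
#' the synteny block decomposition, TE track, splice-junction hints,
#' expression tables and a truth table. Applying the emitted variants to
#' haplotype 1 reconstructs haplotype 2 exactly; the two objects are built by
#' independent routes.
#'
#' @param config from \code{\link{simulationConfig}}.
#' @return list (usable directly as a \code{\link{runRefinement}} bundle)
#'   with genomeH1/genomeH2, modelsH1/modelsH2, variants, blocks, teH1/teH2,
#'   junctionsH2, exprH1/exprH2, domainsH1/domainsH2, truth and config.
#' @export
simulateHaplotypePair <- function(config = simulationConfig()) {
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_genes
  perChrom <- diff(round(seq(0L, n, length.out = cfg$n_chrom + 1L)))
  chromOf <- rep(seq_len(cfg$n_chrom), perChrom)
  chromNames <- sprintf("chr%02d", seq_len(cfg$n_chrom))

  tpls <- replicate(n, geneTemplate(), simplify = FALSE)

  # --- statuses ------------------------------------------------------------
  status <- rep("intact", n)
  nMergePairs <- round(n * cfg$merge_fraction / 2)
  mergeFirst <- integer()
  candStarts <- which(chromOf[-n] == chromOf[-1L])
  while (length(mergeFirst) < nMergePairs && length(candStarts)) {
    pick <- sample(candStarts, 1L)
    mergeFirst <- c(mergeFirst, pick)
    candStarts <- setdiff(candStarts, c(pick - 1L, pick, pick + 1L))
  }
  mergeIdx <- sort(c(mergeFirst, mergeFirst + 1L))
  status[mergeIdx] <- "merged_hap2"
  for (i in mergeFirst) tpls[[i + 1L]]$strand <- tpls[[i]]$strand

  pool <- setdiff(seq_len(n), mergeIdx)
  multi <- pool[vapply(tpls[pool], function(t) t$nEx >= 2L, logical(1L))]
  splitIdx <- sort(sample(multi, round(n * cfg$split_fraction)))
  status[splitIdx] <- "split_hap2"
  pool <- setdiff(pool, splitIdx)
  takes <- function(k) {
    out <- sort(sample(pool, k))
    pool <<- setdiff(pool, out)
    out
  }
  dropIdx <- takes(round(n * cfg$drop_fraction))
  status[dropIdx] <- "dropped_hap2"
  disIdx <- takes(round(n * cfg$disabled_fraction))
  status[disIdx] <- "high_effect_disabled"
  hemiIdx <- takes(round(n * cfg$hemizygous_fraction))
  status[hemiIdx] <- "hemizygous_deleted"
  disType <- rep(NA_character_, n)
  for (i in disIdx) {
    ty <- sample(c("start_lost", "stop_gained", "frameshift", "splice_loss"),
                 1L)
    if (ty == "splice_loss" && tpls[[i]]$nEx < 2L) ty <- "frameshift"
    disType[i] <- ty
  }

  # --- haplotype-1 layout and sequence ------------------------------------
  geneStart0 <- integer(n)
  h1seqs <- character(cfg$n_chrom)
  exTxList <- vector("list", n)
  for (ci in seq_len(cfg$n_chrom)) {
    gidx <- which(chromOf == ci)
    nloc <- length(gidx)
    lociBp <- sum(vapply(tpls[gidx], `[[`, integer(1L), "locusLen"))
    freeBp <- cfg$chrom_len - lociBp
    nGaps <- nloc + 1L
    if (freeBp < 2000L * nGaps)
      stop("chromosome too short for the requested gene count")
    w <- runif(nGaps)
    gaps <- floor(w / sum(w) * (freeBp - 2000L * nGaps)) + 2000L
    isSecondOfPair <- gidx %in% (mergeFirst + 1L)
    gaps[which(isSecondOfPair)] <- sample(300:800, sum(isSecondOfPair),
                                          replace = TRUE)
    pieces <- character(2L * nloc + 1L)
    cur <- 0L
    for (k in seq_len(nloc)) {
      pieces[2L * k - 1L] <- randSeq(gaps[k])
      cur <- cur + gaps[k]
      gi <- gidx[k]
      loc <- templateLocus(tpls[[gi]])
      exTxList[[gi]] <- loc$exTx
      geneStart0[gi] <- cur
      pieces[2L * k] <- if (tpls[[gi]]$strand == "+") loc$seq else
        revComp(loc$seq)
      cur <- cur + tpls[[gi]]$locusLen
    }
    tailLen <- cfg$chrom_len - cur
    pieces[2L * nloc + 1L] <- randSeq(tailLen)
    h1seqs[ci] <- paste(pieces, collapse = "")
  }
  genomeH1 <- Biostrings::DNAStringSet(stats::setNames(h1seqs, chromNames))
  S4Vectors::metadata(genomeH1)$haplotype <- "hap1"

  ids1 <- sprintf("h1g%04d", seq_len(n))
  modelsH1 <- modelList(lapply(seq_len(n), function(i)
    buildGeneModelAt(ids1[i], chromNames[chromOf[i]], tpls[[i]],
                     exTxList[[i]], geneStart0[i], "h1")))

  # --- events and variants -------------------------------------------------
  geneEnd0 <- geneStart0 + vapply(tpls, `[[`, integer(1L), "locusLen")
  occupied <- lapply(seq_len(cfg$n_chrom), function(ci) {
    g <- which(chromOf == ci)
    cbind(pmax(geneStart0[g] - 200L, 0L), geneEnd0[g] + 200L)
  })
  events <- list()   # per-chrom rows: s1, e1 (1-based excl), delta, class, ...
  variants <- list()
  addOcc <- function(ci, s0, e0)
    occupied[[ci]] <<- rbind(occupied[[ci]], c(s0, e0))
  addVar <- function(sn, pos, ref, alt, cls)
    variants[[length(variants) + 1L]] <<- data.frame(
      seq_name = sn, pos = pos, ref = ref, alt = alt, var_class = cls,
      stringsAsFactors = FALSE)
  addVarBatch <- function(df)
    variants[[length(variants) + 1L]] <<- df
  addEvent <- function(ci, s1, e1, delta, class, seg1 = NA_integer_,
                       seg2 = NA_integer_, dest = NA_integer_)
    events[[length(events) + 1L]] <<- data.frame(
      chrom = ci, s1 = s1, e1 = e1, delta = delta, class = class,
      seg1 = seg1, seg2 = seg2, dest = dest, stringsAsFactors = FALSE)
  placeSegment <- function(ci, len, margin = 500L) {
    free <- freeIntervals(occupied[[ci]], 1000L, cfg$chrom_len - 1000L)
    free <- free[free[, 2L] - free[, 1L] >= len + 2L * margin, , drop = FALSE]
    if (nrow(free) == 0L) stop("no intergenic room for a ", len, " bp event")
    row <- free[sample(nrow(free), 1L), ]
    s0 <- row[1L] + margin +
      sample.int(row[2L] - row[1L] - len - 2L * margin + 1L, 1L) - 1L
    addOcc(ci, s0 - 50L, s0 + len + 50L)
    s0  # 0-based start of the segment
  }
  chromSeq <- function(ci) h1seqs[ci]
  segStr <- function(ci, s1, e1) substring(h1seqs[ci], s1, e1)

  # hemizygous genes: whole-gene deletions (flanks included)
  for (i in hemiIdx) {
    ci <- chromOf[i]
    s1 <- geneStart0[i] - 100L + 1L
    e1 <- geneEnd0[i] + 100L
    anchor <- s1 - 1L
    addVar(chromNames[ci], anchor, segStr(ci, anchor, e1), segStr(ci, anchor,
           anchor), "DEL")
    addEvent(ci, s1, e1, -(e1 - s1 + 1L), "DEL")
  }
  # configured intergenic structural events
  sv <- cfg$sv_events
  for (k in seq_len(nrow(sv))) {
    ci <- sample(cfg$n_chrom, 1L)
    len <- as.integer(sv$length[k])
    cls <- sv$class[k]
    s0 <- placeSegment(ci, len)
    s1 <- s0 + 1L
    e1 <- s0 + len
    sn <- chromNames[ci]
    if (cls == "DEL") {
      addVar(sn, s1 - 1L, segStr(ci, s1 - 1L, e1), segStr(ci, s1 - 1L, s1 - 1L),
             "DEL")
      addEvent(ci, s1, e1, -len, "DEL")
    } else if (cls == "INS") {
      ins <- randSeq(len)
      addVar(sn, s1 - 1L, segStr(ci, s1 - 1L, s1 - 1L),
             paste0(segStr(ci, s1 - 1L, s1 - 1L), ins), "INS")
      addEvent(ci, s1, s1 - 1L, len, "INS")
    } else if (cls == "INV") {
      S <- segStr(ci, s1, e1)
      a <- s1 - 1L
      ab <- segStr(ci, a, a)
      addVar(sn, a, paste0(ab, S), ab, "DEL")
      addVar(sn, a, ab, paste0(ab, revComp(S)), "INS")
      addEvent(ci, s1, e1, 0L, "INV")
    } else if (cls == "NOTAL") {
      S <- segStr(ci, s1, e1)
      a <- s1 - 1L
      ab <- segStr(ci, a, a)
      addVar(sn, a, paste0(ab, S), ab, "DEL")
      addVar(sn, a, ab, paste0(ab, randSeq(len)), "INS")
      addEvent(ci, s1, e1, 0L, "NOTAL")
    } else if (cls == "DUP") {
      S <- segStr(ci, s1, e1)
      eb <- segStr(ci, e1, e1)
      addVar(sn, e1, eb, paste0(eb, S), "INS")
      addEvent(ci, e1 + 1L, e1, len, "DUP", seg1 = s1, seg2 = e1)
    } else if (cls == "TRANS") {
      S <- segStr(ci, s1, e1)
      d0 <- placeSegment(ci, 0L, margin = 100L)
      d1 <- d0 + 1L  # insertion anchored on base d1 (1-based)
      a <- s1 - 1L
      ab <- segStr(ci, a, a)
      addVar(sn, a, paste0(ab, S), ab, "DEL")
      db <- segStr(ci, d1, d1)
      addVar(sn, d1, db, paste0(db, S), "INS")
      addEvent(ci, s1, e1, -len, "TRANS_SRC", seg1 = s1, seg2 = e1, dest = d1)
      addEvent(ci, d1 + 1L, d1, len, "TRANS_DST", dest = d1)
    }
  }

  # planted spurious model locations (kept clear of later indels and TEs)
  nSpur <- round(n * cfg$spurious_fraction)
  spurHap <- rep(c("h1", "h2"), length.out = nSpur)
  spurChrom <- integer(nSpur)
  spurStart0 <- integer(nSpur)
  spurLen <- integer(nSpur)
  for (k in seq_len(nSpur)) {
    ci <- sample(cfg$n_chrom, 1L)
    len <- sample(150:280, 1L)
    s0 <- placeSegment(ci, len, margin = 100L)
    spurChrom[k] <- ci
    spurStart0[k] <- s0
    spurLen[k] <- len
  }

  # disabling variants for high_effect_disabled genes
  for (i in disIdx) {
    v <- disablingVariant(modelsH1[[ids1[i]]], genomeH1, disType[i])
    addVar(v$seq_name, v$pos, v$ref, v$alt, v$var_class)
    ci <- chromOf[i]
    if (v$var_class == "DEL")
      addEvent(ci, v$pos + 1L, v$pos + nchar(v$ref) - 1L,
               nchar(v$alt) - nchar(v$ref), "indel")
  }

  # synonymous third-position SNPs in genes carried by both haplotypes, so
  # allelic coding sequences differ while every peptide stays identical;
  # suppressed along with all other substitutions when snp_rate is 0
  synTargets <- if (cfg$snp_rate > 0)
    which(status %in% c("intact", "dropped_hap2", "split_hap2",
                        "merged_hap2")) else integer()
  for (i in synTargets) {
    g <- modelsH1[[ids1[i]]]
    posTx <- cdsPositionsTx(representativeTranscript(g)@cds, geneStrand(g))
    naa <- length(posTx) %/% 3L
    want <- sample(2:4, 1L)
    placed <- 0L
    for (j in sample(2:(naa - 1L), min(3L * want, naa - 2L))) {
      if (placed >= want) break
      cod <- substring(tpls[[i]]$cdsSeq, 3L * j - 2L, 3L * j)
      b3 <- substring(cod, 3L, 3L)
      alts <- setdiff(DNA, b3)
      syn <- alts[Biostrings::GENETIC_CODE[paste0(substring(cod, 1L, 2L),
                                                  alts)] ==
                  Biostrings::GENETIC_CODE[cod]]
      if (length(syn) == 0L) next
      altTx <- syn[1L]
      p0 <- posTx[3L * j]
      if (geneStrand(g) == "+")
        addVar(seqName(g), p0 + 1L, b3, altTx, "SNP")
      else
        addVar(seqName(g), p0 + 1L, unname(complementBase(b3)),
               unname(complementBase(altTx)), "SNP")
      placed <- placed + 1L
    }
  }

  # --- small indels (intergenic) ------------------------------------------
  for (ci in seq_len(cfg$n_chrom)) {
    free <- freeIntervals(occupied[[ci]], 200L, cfg$chrom_len - 200L)
    free <- free[free[, 2L] - free[, 1L] > 100L, , drop = FALSE]
    freeBp <- sum(free[, 2L] - free[, 1L])
    nInd <- round(cfg$indel_rate * freeBp)
    if (nInd == 0L) next
    # candidate anchors spaced 30 bp apart so footprints stay disjoint
    cand <- sort(unlist(lapply(seq_len(nrow(free)), function(r)
      seq(free[r, 1L] + 20L, free[r, 2L] - 20L, by = 30L))))
    a1 <- sort(sample(cand, min(nInd, length(cand)))) + 1L
    len <- sample(1:10, length(a1), replace = TRUE)
    isIns <- runif(length(a1)) < 0.5
    sn <- chromNames[ci]
    anchorBase <- substring(h1seqs[ci], a1, a1)
    insSeq <- vapply(len, randSeq, character(1L))
    ref <- ifelse(isIns, anchorBase, substring(h1seqs[ci], a1, a1 + len))
    alt <- ifelse(isIns, paste0(anchorBase, insSeq), anchorBase)
    addVarBatch(data.frame(seq_name = sn, pos = a1, ref = ref, alt = alt,
                           var_class = ifelse(isIns, "INS", "DEL"),
                           stringsAsFactors = FALSE))
    for (k in seq_along(a1)) {
      if (isIns[k]) addEvent(ci, a1[k] + 1L, a1[k], len[k], "indel")
      else addEvent(ci, a1[k] + 1L, a1[k] + len[k], -len[k], "indel")
    }
  }
  eventDf <- if (length(events)) do.call(rbind, events) else
    data.frame(chrom = integer(), s1 = integer(), e1 = integer(),
               delta = integer(), class = character(), seg1 = integer(),
               seg2 = integer(), dest = integer(), stringsAsFactors = FALSE)
  eventDf <- eventDf[order(eventDf$chrom, eventDf$s1), , drop = FALSE]

  # --- SNPs ----------------------------------------------------------------
  for (ci in seq_len(cfg$n_chrom)) {
    mask <- rep(TRUE, cfg$chrom_len)
    for (i in which(chromOf == ci)) {
      tx <- representativeTranscript(modelsH1[[ids1[i]]])
      ex <- tx@exons
      for (r in seq_len(nrow(ex))) mask[(ex[r, 1L] + 1L):ex[r, 2L]] <- FALSE
      intr <- intronTable(tx)
      for (r in seq_len(nrow(intr))) {
        mask[(intr[r, 1L] + 1L):(intr[r, 1L] + 2L)] <- FALSE
        mask[(intr[r, 2L] - 1L):intr[r, 2L]] <- FALSE
      }
    }
    ev <- eventDf[eventDf$chrom == ci, , drop = FALSE]
    for (r in seq_len(nrow(ev))) {
      lo <- max(1L, ev$s1[r] - 5L)
      hi <- min(cfg$chrom_len, max(ev$s1[r], ev$e1[r]) + 5L)
      mask[lo:hi] <- FALSE
    }
    mask[1:100] <- FALSE
    mask[(cfg$chrom_len - 100L):cfg$chrom_len] <- FALSE
    allowed <- which(mask)
    nSnp <- round(cfg$snp_rate * length(allowed))
    if (nSnp == 0L) next
    at <- sort(sample(allowed, min(nSnp, length(allowed))))
    refb <- substring(h1seqs[ci], at, at)
    shift <- sample(1:3, length(at), replace = TRUE)
    altb <- DNA[(match(refb, DNA) - 1L + shift) %% 4L + 1L]
    addVarBatch(data.frame(seq_name = chromNames[ci], pos = at, ref = refb,
                           alt = altb, var_class = "SNP",
                           stringsAsFactors = FALSE))
  }

  variantDf <- if (length(variants)) do.call(rbind, variants) else
    data.frame(seq_name = character(), pos = integer(), ref = character(),
               alt = character(), var_class = character(),
               stringsAsFactors = FALSE)
  variantDf <- variantDf[order(variantDf$seq_name, variantDf$pos,
                               seq_len(nrow(variantDf))), , drop = FALSE]
  rownames(variantDf) <- NULL

  # --- haplotype-2 sequence (independent assembly) and synteny blocks ------
  h2seqs <- character(cfg$n_chrom)
  blocks <- list()
  addBlock <- function(rs, rst, ren, qs, qst, qen, cls)
    blocks[[length(blocks) + 1L]] <<- data.frame(
      ref_seq = rs, ref_start = rst, ref_end = ren, qry_seq = qs,
      qry_start = qst, qry_end = qen, class = cls, stringsAsFactors = FALSE)
  for (ci in seq_len(cfg$n_chrom)) {
    sn <- chromNames[ci]
    base <- strsplit(h1seqs[ci], "")[[1L]]
    vs <- variantDf[variantDf$seq_name == sn & variantDf$var_class == "SNP", ]
    base[vs$pos] <- vs$alt
    snpSeq <- paste(base, collapse = "")
    ev <- eventDf[eventDf$chrom == ci, , drop = FALSE]
    vIns <- variantDf[variantDf$seq_name == sn &
                      variantDf$var_class == "INS", , drop = FALSE]
    insAt <- function(pos) substring(vIns$alt[match(pos, vIns$pos)], 2L)
    cur <- 1L
    off <- 0L
    pieces <- character()
    seg <- function(s1, e1) substring(snpSeq, s1, e1)
    segRef <- function(s1, e1) substring(h1seqs[ci], s1, e1)
    for (r in seq_len(nrow(ev))) {
      if (ev$s1[r] > cur) {
        pieces <- c(pieces, seg(cur, ev$s1[r] - 1L))
        addBlock(sn, cur, ev$s1[r] - 1L, sn, cur + off, ev$s1[r] - 1L + off,
                 "SYN")
      }
      cls <- ev$class[r]
      s1 <- ev$s1[r]
      e1 <- ev$e1[r]
      if (cls == "indel") {
        if (ev$delta[r] > 0L)
          pieces <- c(pieces, insAt(s1 - 1L))
      } else if (cls == "DEL") {
        addBlock(sn, s1, e1, sn, s1 - 1L + off, s1 - 1L + off, "DEL")
      } else if (cls == "INS") {
        pieces <- c(pieces, insAt(s1 - 1L))
        addBlock(sn, s1 - 1L, s1 - 1L, sn, s1 + off, s1 - 1L + off +
                 ev$delta[r], "INS")
      } else if (cls == "INV") {
        pieces <- c(pieces, revComp(seg(s1, e1)))
        addBlock(sn, s1, e1, sn, s1 + off, e1 + off, "INV")
      } else if (cls == "NOTAL") {
        pieces <- c(pieces, insAt(s1 - 1L))
        addBlock(sn, s1, e1, NA, NA, NA, "NOTAL")
        addBlock(NA, NA, NA, sn, s1 + off, e1 + off, "NOTAL")
      } else if (cls == "DUP") {
        pieces <- c(pieces, segRef(ev$seg1[r], ev$seg2[r]))
        addBlock(sn, ev$seg1[r], ev$seg2[r], sn, ev$seg2[r] + off + 1L,
                 ev$seg2[r] + off + ev$delta[r], "DUP")
      } else if (cls == "TRANS_SRC") {
        # block emitted at the destination event where the offset is known
      } else if (cls == "TRANS_DST") {
        src <- ev[which(ev$class == "TRANS_SRC" & !is.na(ev$dest) &
                        ev$dest == ev$dest[r])[1L], ]
        pieces <- c(pieces, segRef(src$seg1, src$seg2))
        addBlock(sn, src$seg1, src$seg2, sn, ev$dest[r] + off + 1L,
                 ev$dest[r] + off + ev$delta[r], "TRANS")
      }
      off <- off + ev$delta[r]
      cur <- max(cur, e1 + 1L)
    }
    if (cur <= cfg$chrom_len) {
      pieces <- c(pieces, seg(cur, cfg$chrom_len))
      addBlock(sn, cur, cfg$chrom_len, sn, cur + off, cfg$chrom_len + off,
               "SYN")
    }
    h2seqs[ci] <- paste(pieces, collapse = "")
  }
  genomeH2 <- Biostrings::DNAStringSet(stats::setNames(h2seqs, chromNames))
  S4Vectors::metadata(genomeH2)$haplotype <- "hap2"
  blockDf <- do.call(rbind, blocks)
  blockDf$orientation <- ifelse(blockDf$class == "INV", "inverted", "same")
  rownames(blockDf) <- NULL

  # offset of a 0-based hap1 coordinate on hap2
  offset0 <- function(ci, x0) {
    ev <- eventDf[eventDf$chrom == ci, , drop = FALSE]
    sum(ev$delta[pmax(ev$s1 - 1L, ev$e1) <= x0])
  }

  # --- haplotype-2 annotation with planted errors --------------------------
  modelsH2 <- list()
  truthH2id <- rep(NA_character_, n)
  splitFragments <- function(i, id2, start2) {
    tpl <- tpls[[i]]
    exTx <- exTxList[[i]]
    te <- templateExons(tpl, exTx, start2)
    ex <- te$exons
    kEx <- nrow(ex)
    j <- sample(kEx - 1L, 1L)  # split after j-th exon in transcript order
    rowsTx <- if (tpl$strand == "+") seq_len(kEx) else rev(seq_len(kEx))
    r1 <- sort(rowsTx[seq_len(j)])
    r2 <- sort(rowsTx[(j + 1L):kEx])
    wTx <- (ex[, 2L] - ex[, 1L])[rowsTx]
    trim <- (3L - sum(wTx[seq_len(j)]) %% 3L) %% 3L
    ex2 <- ex[r2, , drop = FALSE]
    if (trim > 0L) {
      if (tpl$strand == "+") ex2[1L, 1L] <- ex2[1L, 1L] + trim
      else ex2[nrow(ex2), 2L] <- ex2[nrow(ex2), 2L] - trim
    }
    mk <- function(id, exm) {
      w <- exm[, 2L] - exm[, 1L]
      ph <- if (tpl$strand == "+") gffPhases(w) else rev(gffPhases(rev(w)))
      geneModel(id, chromNames[chromOf[i]], tpl$strand,
                transcriptModel(paste0(id, ".t1"), exm, cbind(exm, ph)),
                sourceHaplotype = "h2")
    }
    list(mk(paste0(id2, "a"), ex[r1, , drop = FALSE]),
         mk(paste0(id2, "b"), ex2))
  }
  i <- 1L
  while (i <= n) {
    ci <- chromOf[i]
    st <- status[i]
    id2 <- sprintf("h2g%04d", i)
    start2 <- geneStart0[i] + offset0(ci, geneStart0[i])
    if (st == "intact") {
      modelsH2[[id2]] <- buildGeneModelAt(id2, chromNames[ci], tpls[[i]],
                                          exTxList[[i]], start2, "h2")
      truthH2id[i] <- id2
    } else if (st == "split_hap2") {
      fr <- splitFragments(i, id2, start2)
      modelsH2[[geneId(fr[[1L]])]] <- fr[[1L]]
      modelsH2[[geneId(fr[[2L]])]] <- fr[[2L]]
      truthH2id[i] <- paste0(id2, "a,", id2, "b")
    } else if (st == "merged_hap2" && i %in% mergeFirst) {
      j <- i + 1L
      strand <- tpls[[i]]$strand
      teA <- templateExons(tpls[[i]], exTxList[[i]], start2)
      startB <- geneStart0[j] + offset0(chromOf[j], geneStart0[j])
      teB <- templateExons(tpls[[j]], exTxList[[j]], startB)
      # upstream gene in translation order loses its stop codon
      upA <- (strand == "+")
      cdsA <- teA$cds[, 1:2, drop = FALSE]
      cdsB <- teB$cds[, 1:2, drop = FALSE]
      if (upA) {
        k <- nrow(cdsA)
        cdsA[k, 2L] <- cdsA[k, 2L] - 3L
      } else {
        cdsB[1L, 1L] <- cdsB[1L, 1L] + 3L
      }
      exm <- rbind(teA$exons, teB$exons)
      cdm <- rbind(cdsA, cdsB)
      ord <- order(exm[, 1L])
      exm <- exm[ord, , drop = FALSE]
      cdm <- cdm[order(cdm[, 1L]), , drop = FALSE]
      w <- cdm[, 2L] - cdm[, 1L]
      ph <- if (strand == "+") gffPhases(w) else rev(gffPhases(rev(w)))
      fid <- paste0(id2, "m")
      modelsH2[[fid]] <- geneModel(fid, chromNames[ci], strand,
                                   transcriptModel(paste0(fid, ".t1"), exm,
                                                   cbind(cdm, ph)),
                                   sourceHaplotype = "h2")
      truthH2id[i] <- fid
      truthH2id[j] <- fid
      i <- i + 1L
    }
    # dropped_hap2 / high_effect_disabled / hemizygous_deleted: absent
    i <- i + 1L
  }
  # spurious models
  spurIds <- list(h1 = character(), h2 = character())
  for (k in seq_len(nSpur)) {
    ci <- spurChrom[k]
    hap <- spurHap[k]
    id <- sprintf("%ssp%03d", hap, k)
    s0 <- if (hap == "h1") spurStart0[k] else
      spurStart0[k] + offset0(ci, spurStart0[k])
    ex <- cbind(s0, s0 + spurLen[k])
    m <- geneModel(id, chromNames[ci], sample(c("+", "-"), 1L),
                   transcriptModel(paste0(id, ".t1"), ex, cbind(ex, 0L)),
                   sourceHaplotype = hap)
    if (hap == "h1") modelsH1[[id]] <- m else modelsH2[[id]] <- m
    spurIds[[hap]] <- c(spurIds[[hap]], id)
  }

  # --- junction hints (true hap2 intron structures) ------------------------
  jrows <- list()
  for (i in seq_len(n)) {
    if (!status[i] %in% c("intact", "dropped_hap2", "split_hap2",
                          "merged_hap2")) next
    ci <- chromOf[i]
    start2 <- geneStart0[i] + offset0(ci, geneStart0[i])
    te <- templateExons(tpls[[i]], exTxList[[i]], start2)
    tx <- transcriptModel("tmp", te$exons, te$cds)
    intr <- intronTable(tx)
    for (r in seq_len(nrow(intr)))
      jrows[[length(jrows) + 1L]] <- data.frame(
        seq_name = chromNames[ci], start = intr[r, 1L] + 1L,
        end = intr[r, 2L], strand = tpls[[i]]$strand,
        stringsAsFactors = FALSE)
  }
  junctionsH2 <- if (length(jrows)) unique(do.call(rbind, jrows)) else
    data.frame(seq_name = character(), start = integer(), end = integer(),
               strand = character(), stringsAsFactors = FALSE)

  # --- TE track ------------------------------------------------------------
  teRows <- list()
  for (ci in seq_len(cfg$n_chrom)) {
    free <- freeIntervals(occupied[[ci]], 500L, cfg$chrom_len - 500L)
    free <- free[free[, 2L] - free[, 1L] >= 800L, , drop = FALSE]
    target <- cfg$te_density * sum(free[, 2L] - free[, 1L])
    placed <- 0L
    guard <- 0L
    while (placed < target && guard < 10000L) {
      guard <- guard + 1L
      r <- sample(nrow(free), 1L)
      len <- sample(500:3000, 1L)
      room <- free[r, 2L] - free[r, 1L] - 200L
      if (room < len) next
      s0 <- free[r, 1L] + 100L + sample.int(room - len + 1L, 1L) - 1L
      teRows[[length(teRows) + 1L]] <- data.frame(
        seq_name = chromNames[ci], start = s0 + 1L, end = s0 + len,
        te_class = sample(TE_CLASSES, 1L,
                          prob = c(0.45, 0.3, 0.1, 0.15)),
        stringsAsFactors = FALSE)
      placed <- placed + len
      free[r, 1L] <- s0 + len  # crude: keep placements disjoint
    }
  }
  teH1 <- do.call(rbind, teRows)
  teH1 <- teH1[order(teH1$seq_name, teH1$start), , drop = FALSE]
  rownames(teH1) <- NULL
  teH2 <- teH1
  for (r in seq_len(nrow(teH2))) {
    ci <- match(teH2$seq_name[r], chromNames)
    d <- offset0(ci, teH2$start[r] - 1L)
    teH2$start[r] <- teH2$start[r] + d
    teH2$end[r] <- teH2$end[r] + d
  }

  # --- truth, domains, expression -----------------------------------------
  truthGenes <- data.frame(
    base_id = sprintf("g%04d", seq_len(n)), gene_h1 = ids1,
    gene_h2 = truthH2id, status = status, disabled_type = disType,
    seq_name = chromNames[chromOf], start0_h1 = geneStart0,
    end0_h1 = geneEnd0, stringsAsFactors = FALSE)
  if (nSpur > 0L)
    truthGenes <- rbind(truthGenes, data.frame(
      base_id = c(spurIds$h1, spurIds$h2),
      gene_h1 = c(spurIds$h1, rep(NA, length(spurIds$h2))),
      gene_h2 = c(rep(NA, length(spurIds$h1)), spurIds$h2),
      status = "spurious", disabled_type = NA,
      seq_name = chromNames[spurChrom[order(spurHap)]],
      start0_h1 = spurStart0[order(spurHap)],
      end0_h1 = (spurStart0 + spurLen)[order(spurHap)],
      stringsAsFactors = FALSE))
  truth <- plantExpressionTruth(truthGenes, cfg)
  exprs <- simulateExpression(truth, cfg$tissues, cfg$expression)

  list(genomeH1 = genomeH1, genomeH2 = genomeH2,
       modelsH1 = modelsH1, modelsH2 = modelsH2,
       variants = variantDf, blocks = blockDf,
       teH1 = teH1, teH2 = teH2, junctionsH2 = junctionsH2,
       exprH1 = exprs$h1, exprH2 = exprs$h2,
       domainsH1 = setdiff(names(modelsH1), spurIds$h1),
       domainsH2 = setdiff(names(modelsH2), spurIds$h2),
       truth = truth, config = cfg)
}

ALLELIC_CATEGORIES <- c("Balanced", "H1_dominant", "H2_dominant", "NE")

plantExpressionTruth <- function(truthGenes, cfg) {
  tissues <- cfg$tissues
  ec <- cfg$expression
  pairIdx <- which(truthGenes$status == "intact")
  base <- sample(ALLELIC_CATEGORIES, length(pairIdx), replace = TRUE,
                 prob = ec$category_probs[ALLELIC_CATEGORIES])
  cats <- matrix(rep(base, length(tissues)), ncol = length(tissues),
                 dimnames = list(truthGenes$base_id[pairIdx], tissues))
  divergent <- base != "NE" & runif(length(pairIdx)) < ec$divergent_fraction
  for (k in which(divergent)) {
    ti <- sample(length(tissues), 1L)
    cats[k, ti] <- sample(setdiff(ALLELIC_CATEGORIES, base[k]), 1L)
  }
  list(genes = truthGenes, categories = cats)
}

#' Draw per-tissue expression tables for planted allelic categories
#'
#' TPM pairs are drawn so the planted category is recovered by the
#' minimum-Euclidean-distance classifier at low dispersion: Balanced shares
#' near 0.5, dominant shares at or above 0.85, NE below the expression floor
#' (zero) in the planted tissue. Genes present on only one haplotype are
#' expressed there; spurious models get zero TPM everywhere.
#'
#' @param truth truth object from \code{\link{simulateHaplotypePair}} (list
#'   with \code{genes} and per-tissue \code{categories}).
#' @param tissues tissue names.
#' @param expression expression settings (see
#'   \code{\link{simulationConfig}}).
#' @return list with TPM matrices \code{h1} and \code{h2}.
#' @export
simulateExpression <- function(truth, tissues,
                               expression = simulationConfig()$expression) {
  ec <- expression
  tg <- truth$genes
  cats <- truth$categories
  ids1 <- tg$gene_h1[!is.na(tg$gene_h1)]
  ids2 <- unique(unlist(strsplit(tg$gene_h2[!is.na(tg$gene_h2)], ",")))
  h1 <- matrix(0, length(ids1), length(tissues),
               dimnames = list(ids1, tissues))
  h2 <- matrix(0, length(ids2), length(tissues),
               dimnames = list(ids2, tissues))
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  total <- function() ec$floor + rlnorm(1L, meanlog = 3, sdlog = 0.7)
  for (r in seq_len(nrow(tg))) {
    st <- tg$status[r]
    g1 <- tg$gene_h1[r]
    g2 <- tg$gene_h2[r]
    if (st == "spurious") next
    if (st == "intact") {
      for (ti in seq_along(tissues)) {
        cat <- cats[tg$base_id[r], ti]
        if (cat == "NE") next
        tt <- total()
        p1 <- switch(cat,
          Balanced = clamp(0.5 + rnorm(1L, 0, ec$dispersion), 0.35, 0.65),
          H1_dominant = clamp(ec$dominant_share + rnorm(1L, 0, ec$dispersion),
                              0.85, 1),
          H2_dominant = 1 - clamp(ec$dominant_share +
                                  rnorm(1L, 0, ec$dispersion), 0.85, 1))
        h1[g1, ti] <- round(tt * p1, 3L)
        h2[g2, ti] <- round(tt * (1 - p1), 3L)
      }
    } else if (st %in% c("dropped_hap2", "high_effect_disabled",
                         "hemizygous_deleted")) {
      for (ti in seq_along(tissues)) h1[g1, ti] <- round(total() / 2, 3L)
    } else if (st == "split_hap2") {
      frs <- strsplit(g2, ",")[[1L]]
      for (ti in seq_along(tissues)) {
        tt <- total()
        h1[g1, ti] <- round(tt / 2, 3L)
        for (f in frs) h2[f, ti] <- round(tt / (2 * length(frs)), 3L)
      }
    } else if (st == "merged_hap2") {
      for (ti in seq_along(tissues)) {
        tt <- total()
        h1[g1, ti] <- round(tt / 2, 3L)
        h2[g2, ti] <- h2[g2, ti] + round(tt / 2, 3L)
      }
    }
  }
  list(h1 = h1, h2 = h2)
}

#' Write fixture files for a simulated haplotype pair
#'
#' Emits hap1.fa, hap2.fa, hap1.gff3, hap2.gff3, variants.vcf, synteny.tsv,
#' te.bed, junctions.tsv, expr_hap1.tsv, expr_hap2.tsv and truth.tsv.
#'
#' @param sim result of \code{\link{simulateHaplotypePair}}.
#' @param dir output directory (created if needed).
#' @export
writeFixtures <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGenome(sim$genomeH1, file.path(dir, "hap1.fa"))
  writeGenome(sim$genomeH2, file.path(dir, "hap2.fa"))
  writeGff3(sim$modelsH1, file.path(dir, "hap1.gff3"))
  writeGff3(sim$modelsH2, file.path(dir, "hap2.gff3"))
  writeVariants(sim$variants, file.path(dir, "variants.vcf"))
  writeSynteny(sim$blocks, file.path(dir, "synteny.tsv"))
  writeTeTrack(sim$teH1, file.path(dir, "te.bed"))
  writeJunctions(sim$junctionsH2, file.path(dir, "junctions.tsv"))
  writeExpression(sim$exprH1, file.path(dir, "expr_hap1.tsv"))
  writeExpression(sim$exprH2, file.path(dir, "expr_hap2.tsv"))
  tg <- cbind(sim$truth$genes,
              as.data.frame(sim$truth$categories[
                match(sim$truth$genes$base_id,
                      rownames(sim$truth$categories)), , drop = FALSE],
                row.names = NULL))
  write.table(tg, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
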