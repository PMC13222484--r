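snpAt <- function(loc, pos1, alt) {
  data.frame(seq_name = "chrT", pos = pos1,
             ref = substring(as.character(loc$genome)[["chrT"]], pos1, pos1),
             alt = alt, var_class = "SNP", stringsAsFactors = FALSE)
}

test_that("canonical disruptive variants get their HIGH classes", {
  loc <- standardLocus("+")
  sp <- geneSpan(loc$gene)  # CDS starts at sp[1] (0-based), exon1 = CDS[1:9]
  cdsStart1 <- sp[1] + 1L   # 1-based position of the A of ATG

  # start codon A -> C
  e <- classifyVariantEffect(loc$gene, snpAt(loc, cdsStart1, "C"), loc$genome)
  expect_identical(e$effect_class, "start_lost")
  expect_identical(e$impact, "HIGH")

  # 1-bp insertion inside the CDS shifts the frame
  ins <- data.frame(seq_name = "chrT", pos = cdsStart1 + 4L,
                    ref = substring(as.character(loc$genome)[["chrT"]],
                                    cdsStart1 + 4L, cdsStart1 + 4L),
                    alt = paste0(substring(as.character(loc$genome)[["chrT"]],
                                           cdsStart1 + 4L, cdsStart1 + 4L),
                                 "A"),
                    var_class = "INS", stringsAsFactors = FALSE)
  e <- classifyVariantEffect(loc$gene, ins, loc$genome)
  expect_identical(e$effect_class, "frameshift")
  expect_identical(e$impact, "HIGH")

  # donor GT -> GA
  tx <- representativeTranscript(loc$gene)
  donorT1 <- intronTable(tx)[1, 1] + 2L  # 1-based position of the T of GT
  e <- classifyVariantEffect(loc$gene, snpAt(loc, donorT1, "A"), loc$genome)
  expect_identical(e$effect_class, "splice_donor_lost")
  expect_identical(e$impact, "HIGH")

  # premature stop: codon TGG (W, CDS positions 7-9) -> TGA
  e <- classifyVariantEffect(loc$gene, snpAt(loc, cdsStart1 + 8L, "A"),
                             loc$genome)
  expect_identical(e$effect_class, "stop_gained")

  # terminal stop TAG -> TAC and no downstream stop
  lastCds1 <- max(cdsTable(tx)[, 2])  # 1-based position of final G
  e <- classifyVariantEffect(loc$gene, snpAt(loc, lastCds1, "C"), loc$genome)
  expect_identical(e$effect_class, "stop_lost")
})

test_that("synonymous and in-frame changes stay below HIGH", {
  loc <- standardLocus("+")
  sp <- geneSpan(loc$gene)
  cdsStart1 <- sp[1] + 1L
  # GCC (Ala, CDS positions 4-6) -> GCA: identical peptide
  e <- classifyVariantEffect(loc$gene, snpAt(loc, cdsStart1 + 5L, "A"),
                             loc$genome)
  expect_identical(e$effect_class, "synonymous")
  expect_identical(e$impact, "LOW")
  # GCC -> GTC: missense
  e <- classifyVariantEffect(loc$gene, snpAt(loc, cdsStart1 + 4L, "T"),
                             loc$genome)
  expect_identical(e$effect_class, "missense")
  expect_identical(e$impact, "MODERATE")
  # 3-bp in-frame deletion inside exon 2 keeps the frame and the stop
  tx <- representativeTranscript(loc$gene)
  ex2 <- exonTable(tx)[2, ]
  anchor1 <- ex2[1] + 2L  # inside exon 2
  chrom <- as.character(loc$genome)[["chrT"]]
  del <- data.frame(seq_name = "chrT", pos = anchor1,
                    ref = substring(chrom, anchor1, anchor1 + 3L),
                    alt = substring(chrom, anchor1, anchor1),
                    var_class = "DEL", stringsAsFactors = FALSE)
  e <- classifyVariantEffect(loc$gene, del, loc$genome)
  expect_identical(e$effect_class, "inframe_indel")
  expect_identical(e$impact, "MODERATE")
  # intron-interior SNP is a modifier
  intr <- intronTable(tx)
  e <- classifyVariantEffect(loc$gene,
                             snpAt(loc, intr[1, 1] + 10L, "A"), loc$genome)
  expect_identical(e$effect_class, "noncoding_region")
  expect_identical(e$impact, "MODIFIER")
})

test_that("strand symmetry: the minus-strand gene gives identical classes", {
  set.seed(52)
  for (i in 1:40) {
    locP <- randomLocus("+")
    # rebuild the same CDS/structure on the minus strand
    tx <- representativeTranscript(locP$gene)
    w <- exonTable(tx)[, 2] - exonTable(tx)[, 1]
    intr <- intronTable(tx)
    set.seed(1000 + i)
    locM <- makeLocus(locP$cds, w, intr[, 2] - intr[, 1], strand = "-")
    set.seed(2000 + i)
    vP <- randomVariantFor(locP$gene, locP$genome)
    eP <- classifyVariantEffect(locP$gene, vP, locP$genome)$effect_class
    # mirror the variant onto the minus-strand locus
    spP <- geneSpan(locP$gene)
    spM <- geneSpan(locM$gene)
    chromM <- as.character(locM$genome)[["chrT"]]
    if (vP$var_class == "SNP") {
      posM <- spM[2] - (vP$pos - spP[1] - 1L)
      vM <- data.frame(seq_name = "chrT", pos = posM,
                       ref = revcomp(vP$ref), alt = revcomp(vP$alt),
                       var_class = "SNP", stringsAsFactors = FALSE)
      eM <- classifyVariantEffect(locM$gene, vM, locM$genome)$effect_class
      expect_identical(eM, eP)
    }
  }
})

test_that("rule engine matches the genomic-rebuild oracle on random cases", {
  set.seed(61)
  n <- 0
  while (n < 300) {
    loc <- randomLocus()
    for (j in 1:5) {
      v <- randomVariantFor(loc$gene, loc$genome)
      eng <- classifyVariantEffect(loc$gene, v, loc$genome)$effect_class
      ora <- oracleEffect(loc$gene, v, loc$genome)
      expect_identical(eng, ora,
                       info = sprintf("%s pos=%d ref=%s alt=%s strand=%s",
                                      v$var_class, v$pos, v$ref, v$alt,
                                      geneStrand(loc$gene)))
      n <- n + 1
    }
  }
})

test_that("HIGH-effect gene calling works at the gene level", {
  loc <- standardLocus("+")
  sp <- geneSpan(loc$gene)
  models <- list(gT = loc$gene)
  syn <- snpAt(loc, sp[1] + 6L, "A")  # synonymous only
  expect_identical(callHighEffectGenes(models, syn, loc$genome), character(0))
  dis <- snpAt(loc, sp[1] + 1L, "C")  # start lost
  expect_identical(callHighEffectGenes(models, rbind(syn, dis), loc$genome),
                   "gT")
  expect_identical(callHighEffectGenes(list(), syn, loc$genome), character(0))
})
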