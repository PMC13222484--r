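smallCfg <- function(seed = 7, ...)
  simulationConfig(seed = seed, n_chrom = 1, chrom_len = 300000L,
                   n_genes = 40, ...)

test_that("the emitted variant script reconstructs haplotype 2 exactly", {
  sim <- simulateHaplotypePair(smallCfg())
  rec <- applyVariants(sim$genomeH1, sim$variants)
  expect_identical(as.character(rec), as.character(sim$genomeH2))
})

test_that("a silent configuration yields identical haplotypes and one SYN block", {
  cfg <- simulationConfig(seed = 3, n_chrom = 1, chrom_len = 200000L,
                          n_genes = 20, snp_rate = 0, indel_rate = 0,
                          sv_events = data.frame(class = character(),
                                                 length = integer()),
                          drop_fraction = 0, split_fraction = 0,
                          merge_fraction = 0, spurious_fraction = 0,
                          disabled_fraction = 0, hemizygous_fraction = 0)
  sim <- simulateHaplotypePair(cfg)
  expect_identical(as.character(sim$genomeH1), as.character(sim$genomeH2))
  expect_equal(nrow(sim$variants), 0L)
  syn <- sim$blocks[sim$blocks$class == "SYN", ]
  expect_equal(nrow(syn), 1L)
  expect_equal(c(syn$ref_start, syn$ref_end), c(1L, 200000L))
})

test_that("same seed gives byte-identical fixtures, different seed differs", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeFixtures(simulateHaplotypePair(smallCfg(seed = 9)), d1)
  writeFixtures(simulateHaplotypePair(smallCfg(seed = 9)), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  d3 <- withr::local_tempdir()
  writeFixtures(simulateHaplotypePair(smallCfg(seed = 10)), d3)
  expect_false(identical(readLines(file.path(d1, "hap1.fa")),
                         readLines(file.path(d3, "hap1.fa"))))
})

test_that("planted truth statuses are consistent with the emitted annotations", {
  sim <- simulateHaplotypePair(smallCfg(seed = 15))
  tg <- sim$truth$genes
  # every simulated gene has exactly one status
  expect_false(any(is.na(tg$status)))
  absent <- tg$gene_h2[tg$status %in% c("dropped_hap2", "high_effect_disabled",
                                        "hemizygous_deleted")]
  expect_true(all(is.na(absent)))
  present <- unlist(strsplit(tg$gene_h2[!is.na(tg$gene_h2)], ","))
  expect_true(all(present %in% names(sim$modelsH2)))
  # hemizygous genes sit under a whole-gene deletion
  for (gid in tg$gene_h1[tg$status == "hemizygous_deleted"]) {
    ev <- svEvidenceForGene(sim$modelsH1[[gid]], sim$variants, sim$blocks,
                            "h1")
    expect_identical(ev$evidence_class, "whole_gene_deleted")
  }
  # disabled genes carry exactly one HIGH variant on their span
  small <- sim$variants[nchar(sim$variants$ref) < 50 &
                        nchar(sim$variants$alt) < 50, ]
  dis <- tg$gene_h1[tg$status == "high_effect_disabled"]
  expect_setequal(callHighEffectGenes(sim$modelsH1[dis], small, sim$genomeH1),
                  dis)
})

test_that("intact genes translate to the same peptide on both haplotypes", {
  sim <- simulateHaplotypePair(smallCfg(seed = 23))
  tg <- sim$truth$genes
  for (r in which(tg$status == "intact")) {
    expect_identical(genePeptide(sim$modelsH2[[tg$gene_h2[r]]], sim$genomeH2),
                     genePeptide(sim$modelsH1[[tg$gene_h1[r]]], sim$genomeH1))
  }
  # but coding sequences differ (planted synonymous divergence)
  ident <- vapply(which(tg$status == "intact"), function(r) {
    a <- sim$modelsH1[[tg$gene_h1[r]]]
    b <- sim$modelsH2[[tg$gene_h2[r]]]
    identical(extractCdsAndTranslate(representativeTranscript(a),
                                     sim$genomeH1, seqName(a),
                                     geneStrand(a))$cds,
              extractCdsAndTranslate(representativeTranscript(b),
                                     sim$genomeH2, seqName(b),
                                     geneStrand(b))$cds)
  }, logical(1))
  expect_false(any(ident))
})

test_that("structural synteny records correspond to planted events", {
  cfg <- smallCfg(seed = 31)
  sim <- simulateHaplotypePair(cfg)
  b <- sim$blocks
  nHemi <- sum(sim$truth$genes$status == "hemizygous_deleted")
  sv <- cfg$sv_events
  expect_equal(sum(b$class == "DEL"), nHemi + sum(sv$class == "DEL"))
  expect_equal(sum(b$class == "INS"), sum(sv$class == "INS"))
  expect_equal(sum(b$class == "INV"), sum(sv$class == "INV"))
  expect_equal(sum(b$class == "DUP"), sum(sv$class == "DUP"))
  expect_equal(sum(b$class == "TRANS"), sum(sv$class == "TRANS"))
  expect_equal(sum(b$class == "NOTAL"), 2L * sum(sv$class == "NOTAL"))
  # every NOTAL record is one-sided
  notal <- b[b$class == "NOTAL", ]
  expect_true(all(xor(is.na(notal$ref_start), is.na(notal$qry_start))))
})

test_that("expression tables follow the planted allelic categories", {
  sim <- simulateHaplotypePair(smallCfg(seed = 41))
  cats <- sim$truth$categories
  tg <- sim$truth$genes
  floorT <- sim$config$expression$floor
  for (base in rownames(cats)) {
    r <- which(tg$base_id == base)
    e1 <- sim$exprH1[tg$gene_h1[r], ]
    e2 <- sim$exprH2[tg$gene_h2[r], ]
    for (ti in seq_along(e1)) {
      cat <- cats[base, ti]
      if (cat == "NE") expect_lt(e1[ti] + e2[ti], floorT)
      else {
        p1 <- e1[ti] / (e1[ti] + e2[ti])
        switch(cat,
               Balanced = expect_true(p1 >= 0.3 && p1 <= 0.7),
               H1_dominant = expect_gte(p1, 0.85),
               H2_dominant = expect_lte(p1, 0.15))
      }
    }
  }
  # spurious models are silent everywhere
  spur <- tg$base_id[tg$status == "spurious" & !is.na(tg$gene_h1)]
  if (length(spur)) expect_true(all(sim$exprH1[spur, ] == 0))
})
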