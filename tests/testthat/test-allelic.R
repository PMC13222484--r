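test_that("allelic states follow the minimum-distance rule with an NE floor", {
  expect_identical(classifyAllelicState(50, 50), "Balanced")
  expect_identical(classifyAllelicState(0, 0), "NE")
  # (90,10): proportions (0.9,0.1); d(Balanced)=0.566 > d(H1)=0.141
  expect_identical(classifyAllelicState(90, 10), "H1_dominant")
  expect_identical(classifyAllelicState(10, 90), "H2_dominant")
  # (70,30): d(Balanced)=0.283 < d(H1)=0.424
  expect_identical(classifyAllelicState(70, 30), "Balanced")
  # decision boundary is a 0.75 share; the tie resolves toward Balanced
  expect_identical(classifyAllelicState(75, 25), "Balanced")
  expect_identical(classifyAllelicState(75.1, 24.9), "H1_dominant")
  # sums under the floor are NE
  expect_identical(classifyAllelicState(0.2, 0.1), "NE")
  expect_error(classifyAllelicState(-1, 5), ">= 0")
})

test_that("state classification is symmetric under haplotype swap", {
  set.seed(91)
  a <- runif(500, 0, 100)
  b <- runif(500, 0, 100)
  s1 <- classifyAllelicState(a, b)
  s2 <- classifyAllelicState(b, a)
  swap <- c(Balanced = "Balanced", H1_dominant = "H2_dominant",
            H2_dominant = "H1_dominant", NE = "NE")
  expect_identical(unname(swap[s1]), s2)
})

test_that("tau has its closed forms and invariances", {
  expect_equal(tauIndex(c(5, 5, 5, 5)), 0)
  expect_equal(tauIndex(c(10, 0, 0, 0)), 1)
  expect_equal(tauIndex(c(8, 4, 0, 0)), 0.8333333, tolerance = 1e-6)
  expect_true(is.na(tauIndex(c(0, 0, 0))))
  expect_error(tauIndex(5), "at least 2")
  set.seed(92)
  for (i in 1:50) {
    p <- runif(sample(3:8, 1), 0, 50)
    if (max(p) == 0) next
    # brute-force recomputation
    expect_equal(tauIndex(p), sum(1 - p / max(p)) / (length(p) - 1))
    # scale invariance
    expect_equal(tauIndex(p * 7.3), tauIndex(p))
  }
  # concentrating mass into the maximum tissue never lowers tau
  p <- c(6, 3, 2, 1)
  taus <- vapply(seq(0, 5, by = 1),
                 function(k) tauIndex(p + c(k, 0, 0, 0)), numeric(1))
  expect_false(is.unsorted(taus))
})

test_that("tissue specificity uses a strict top1/top2 ratio of 3", {
  expect_true(tissueSpecificCall(c(a = 30, b = 9, c = 1))$is_specific)   # 3.33
  expect_false(tissueSpecificCall(c(a = 30, b = 15, c = 0))$is_specific) # 2.0
  expect_false(tissueSpecificCall(c(a = 30, b = 10, c = 0))$is_specific) # 3.0
  expect_true(tissueSpecificCall(c(a = 30.1, b = 10, c = 0))$is_specific)
  z <- tissueSpecificCall(c(a = 7, b = 0, c = 0))
  expect_true(z$is_specific)  # infinite ratio
  expect_identical(z$dominant_tissue, "a")
  expect_false(tissueSpecificCall(c(a = 0, b = 0))$is_specific)
  # the alternative highest/lowest rule from the option
  expect_true(tissueSpecificCall(c(a = 10, b = 9, c = 2),
                                 rule = "lowest")$is_specific)
  expect_false(tissueSpecificCall(c(a = 10, b = 9, c = 2))$is_specific)
})

test_that("lincRNA positional rules: 200-bp floor and zero-overlap", {
  coding <- list(g = geneModel("g", "c1", "+",
                               transcriptModel("g.t1", cbind(1000L, 2000L),
                                               cbind(1000L, 2000L, 0L))))
  tx <- data.frame(seq_name = "c1",
                   start = c(100L, 100L, 1950L, 2002L, 2000L),
                   end = c(298L, 299L, 2450L, 2501L, 2200L))
  cls <- classifyLncPosition(tx, coding)
  # 199 bp rejected, 200 bp eligible; a single shared base is overlapping
  expect_identical(cls, c("rejected_short", "intergenic", "overlapping",
                          "intergenic", "overlapping"))
})

test_that("TE association is a strict 50% of the transcript span", {
  te <- function(covered, cls = "LTR")
    data.frame(seq_name = "c1", start = 1L, end = covered, te_class = cls,
               stringsAsFactors = FALSE)
  expect_false(teAssociation("c1", 1, 1000, te(500))$is_te_associated)
  a <- teAssociation("c1", 1, 1000, te(510))
  expect_true(a$is_te_associated)
  expect_equal(a$fraction, 0.51)
  expect_identical(a$dominant_te_class, "LTR")
  none <- teAssociation("c1", 1, 1000, te(0)[0, ])
  expect_equal(none$fraction, 0)
  expect_false(none$is_te_associated)
  both <- teAssociation("c1", 1, 1000,
                        rbind(te(300, "LTR"),
                              data.frame(seq_name = "c1", start = 400L,
                                         end = 800L, te_class = "TIR")))
  expect_identical(both$dominant_te_class, "TIR")
})

test_that("bi-allelic pairing picks the effective allele and is order-stable", {
  sim <- simulateHaplotypePair(simulationConfig(
    seed = 17, n_chrom = 1, chrom_len = 300000L, n_genes = 40))
  res <- runRefinement(sim)
  ba <- identifyBialleles(sim$modelsH1, sim$modelsH2,
                          res$reportBefore$clusters, sim$blocks, res$hits)
  tg <- sim$truth$genes
  intact <- tg[tg$status == "intact", ]
  got <- ba$pairs$gene_h2[match(intact$gene_h1, ba$pairs$gene_h1)]
  expect_identical(got, intact$gene_h2)
  # genes whose counterpart is deleted or disabled stay mono-allelic
  mono <- tg$gene_h1[tg$status %in% c("hemizygous_deleted",
                                      "high_effect_disabled")]
  expect_true(all(mono %in% ba$monoallelic$h1))
  # permuting the input gene order leaves the pairing unchanged
  perm <- sample(length(sim$modelsH1))
  ba2 <- identifyBialleles(sim$modelsH1[perm], sim$modelsH2,
                           res$reportBefore$clusters, sim$blocks, res$hits)
  expect_identical(ba$pairs, ba2$pairs)
})

test_that("planted allelic categories are recovered from drawn expression", {
  sim <- simulateHaplotypePair(simulationConfig(
    seed = 27, n_chrom = 1, chrom_len = 300000L, n_genes = 40))
  res <- runRefinement(sim)
  ba <- identifyBialleles(sim$modelsH1, sim$modelsH2,
                          res$reportBefore$clusters, sim$blocks, res$hits)
  cl <- classifyAllelicPairs(ba$pairs, sim$exprH1, sim$exprH2,
                             sim$modelsH1, sim$modelsH2,
                             sim$genomeH1, sim$genomeH2)
  tg <- sim$truth$genes
  base <- tg$base_id[match(rownames(cl$states), tg$gene_h1)]
  keep <- which(base %in% rownames(sim$truth$categories))
  agree <- 0L
  tot <- 0L
  for (r in keep) {
    truthRow <- sim$truth$categories[base[r], ]
    agree <- agree + sum(cl$states[r, ] == truthRow)
    tot <- tot + length(truthRow)
  }
  expect_gte(agree / tot, 0.95)
})
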