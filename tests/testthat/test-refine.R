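test_that("protein alignment reports identity and per-side coverage", {
  set.seed(81)
  p100 <- paste(sample(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")),
                       100, replace = TRUE), collapse = "")
  hits <- alignProteins(c(q = p100), c(s = p100), minIdentity = 0,
                        minCoverage = 0)
  expect_equal(hits$identity_pct, 100)
  expect_equal(hits$query_coverage_pct, 100)
  expect_equal(hits$subject_coverage_pct, 100)

  # 50-aa query matching one half of a 100-aa subject
  half <- substring(p100, 1, 50)
  hits <- alignProteins(c(q = half), c(s = p100), minIdentity = 0,
                        minCoverage = 0)
  expect_equal(hits$query_coverage_pct, 100)
  expect_equal(hits$subject_coverage_pct, 50)

  expect_warning(alignProteins(c(q = ""), c(s = p100)), "empty")
})

test_that("the retention filter is an exact 80/80 threshold", {
  h <- data.frame(query_id = c("a", "b", "c"), subject_id = "s",
                  identity_pct = c(79.9, 80.0, 95),
                  query_coverage_pct = c(100, 100, 79.9),
                  subject_coverage_pct = c(100, 100, 70),
                  score = 1, q_start = 1, q_end = 10, s_start = 1, s_end = 10,
                  stringsAsFactors = FALSE)
  kept <- filterHits(h)
  expect_identical(kept$query_id, "b")  # 79.9 identity out, 80.0 in,
                                        # max-side coverage 79.9 out
})

fakeGene <- function(id, seqname, start, width = 300L, nexon = 2L,
                     strand = "+") {
  if (nexon == 1L) ex <- cbind(start, start + width)
  else ex <- cbind(c(start, start + width + 100L),
                   c(start + width, start + 2L * width + 100L))
  geneModel(id, seqname, strand, transcriptModel(paste0(id, ".t1"), ex,
                                                 cbind(ex, 0L)))
}

test_that("clustering flags single-haplotype clusters as candidates", {
  m1 <- list(A1 = fakeGene("A1", "c1", 1000),
             A2 = fakeGene("A2", "c1", 3000),
             L1 = fakeGene("L1", "c1", 9000))
  m2 <- list(B1 = fakeGene("B1", "c1", 1000))
  hit <- function(q, s, id = 95, qc = 95, sc = 95)
    data.frame(query_id = q, subject_id = s, identity_pct = id,
               query_coverage_pct = qc, subject_coverage_pct = sc,
               score = 100, q_start = 1, q_end = 10, s_start = 1, s_end = 10,
               stringsAsFactors = FALSE)
  # tandem pair A1, A2 both hitting B1 forms one 3-gene cluster
  cl <- clusterCrossHaplotype(m1, m2, rbind(hit("A1", "B1"), hit("A2", "B1")))
  expect_equal(length(cl$clusters), 2L)
  expect_setequal(cl$clusters[[1]], c("A1", "A2", "B1"))
  expect_identical(cl$candidateSpecific$h1, "L1")
  expect_identical(cl$candidateSpecific$h2, character(0))
  # hits below threshold leave singleton candidate clusters
  cl <- clusterCrossHaplotype(m1, m2, hit("A1", "B1", id = 70))
  expect_setequal(cl$candidateSpecific$h1, c("A1", "A2", "L1"))
  expect_identical(cl$candidateSpecific$h2, "B1")
})

test_that("candidate validation partitions by the three evidence criteria", {
  cands <- c("gHigh", "gSv", "gNotal", "gPlain")
  sv <- list(
    gHigh = list(gene_id = "gHigh", evidence_class = "none",
                 overlap_fraction = 0),
    gSv = list(gene_id = "gSv", evidence_class = "whole_gene_deleted",
               overlap_fraction = 1),
    gNotal = list(gene_id = "gNotal", evidence_class = "unaligned_region",
                  overlap_fraction = 1),
    gPlain = list(gene_id = "gPlain", evidence_class = "none",
                  overlap_fraction = 0))
  rep <- validateHapSpecific(cands, "gHigh", sv, list(), data.frame())
  expect_setequal(rep$high_confidence_specific, c("gHigh", "gSv", "gNotal"))
  expect_identical(rep$candidate_unannotated, "gPlain")
  expect_identical(rep$evidence$criterion,
                   c("high_effect", "sv", "unaligned", "unannotated"))
  # the two sets partition the candidates
  expect_setequal(c(rep$high_confidence_specific, rep$candidate_unannotated),
                  cands)
})

test_that("TE filter removes genes strictly above 30% overlap", {
  g <- fakeGene("g", "c1", 1000, width = 1000, nexon = 1)  # span 1000 bp
  te <- function(covered) data.frame(seq_name = "c1", start = 1001L,
                                     end = 1000L + covered,
                                     te_class = "LTR",
                                     stringsAsFactors = FALSE)
  expect_identical(names(filterTeGenes(list(g = g), te(300))$kept), "g")
  expect_identical(names(filterTeGenes(list(g = g), te(310))$removed), "g")
  expect_identical(names(filterTeGenes(list(g = g), te(0)[0, ])$kept), "g")
})

test_that("false-positive filter needs all four criteria simultaneously", {
  short <- fakeGene("short", "c1", 1000, width = 250, nexon = 1)
  long <- fakeGene("long", "c1", 5000, width = 350, nexon = 1)
  models <- list(short = short, long = long)
  expr0 <- matrix(0, 2, 2, dimnames = list(c("short", "long"), c("a", "b")))
  noHits <- data.frame(query_id = character(), subject_id = character(),
                       identity_pct = numeric(),
                       query_coverage_pct = numeric(),
                       subject_coverage_pct = numeric(), score = numeric(),
                       stringsAsFactors = FALSE)
  f <- filterFalsePositives(models, domains = character(0),
                            expression = expr0, homologyHits = noHits)
  expect_identical(names(f$removed), "short")  # long fails criterion 1
  # expression in a single tissue rescues the gene
  expr1 <- expr0
  expr1["short", 1] <- 2
  f <- filterFalsePositives(models, character(0), expr1, noHits)
  expect_length(f$removed, 0L)
  # a domain rescues it too
  f <- filterFalsePositives(models, "short", expr0, noHits)
  expect_length(f$removed, 0L)
  # missing evidence tables keep every gene
  f <- filterFalsePositives(models)
  expect_length(f$removed, 0L)
})

test_that("split and merged structures are detected and repaired on fixtures", {
  sim <- simulateHaplotypePair(simulationConfig(
    seed = 99, n_chrom = 1, chrom_len = 400000L, n_genes = 60))
  res <- runRefinement(sim)
  tg <- sim$truth$genes
  calls <- res$splitMerge$calls
  splitSrc <- tg$gene_h1[tg$status == "split_hap2"]
  mergeFused <- unique(tg$gene_h2[tg$status == "merged_hap2"])
  expect_setequal(calls$source_genes[calls$pattern == "split_in_target"],
                  splitSrc)
  expect_setequal(calls$target_genes[calls$pattern == "merged_in_target"],
                  mergeFused)
  expect_true(all(res$splitMerge$repair$repaired))
  # repaired fragments retired, replacements present
  frags <- unlist(strsplit(tg$gene_h2[tg$status == "split_hap2"], ","))
  expect_false(any(frags %in% names(res$modelsH2)))
  # one-to-one orthologs yield no calls: fused/fragment models are the only
  # sources of split/merge patterns
  expect_equal(nrow(calls),
               length(splitSrc) + length(mergeFused))
})

test_that("refinement is a fixed point on an error-free fixture and is deterministic", {
  cfg <- simulationConfig(seed = 5, n_chrom = 1, chrom_len = 250000L,
                          n_genes = 30, drop_fraction = 0,
                          split_fraction = 0, merge_fraction = 0,
                          spurious_fraction = 0, disabled_fraction = 0,
                          hemizygous_fraction = 0)
  sim <- simulateHaplotypePair(cfg)
  res <- runRefinement(sim)
  expect_setequal(names(res$modelsH1), names(sim$modelsH1))
  expect_setequal(names(res$modelsH2), names(sim$modelsH2))
  expect_equal(nrow(res$audit), 0L)
  expect_length(res$reportBefore$h1$candidate_unannotated, 0L)
  # byte-identical outputs across two runs on identical inputs
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeRefinement(res, d1)
  writeRefinement(runRefinement(sim), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("rescue refuses candidates whose target locus is broken or occupied", {
  sim <- simulateHaplotypePair(simulationConfig(
    seed = 13, n_chrom = 1, chrom_len = 300000L, n_genes = 40))
  tg <- sim$truth$genes
  dis <- tg$gene_h1[tg$status == "high_effect_disabled"]
  # a disabled gene's haplotype-2 locus carries a HIGH variant: projecting it
  # with the rescue gates must fail the ORF or splice check for
  # frameshift/start/stop/splice damage
  out <- rescueMissingGenes(dis, sim$modelsH1, sim$modelsH2, sim$blocks,
                            sim$genomeH2, "h1to2", sim$junctionsH2, "h2")
  bad <- out$report[out$report$gene_id %in% dis, ]
  expect_true(all(bad$status == "unresolved"))
  # an intact gene present on haplotype 2 is refused: region already annotated
  intact <- tg$gene_h1[tg$status == "intact"][1]
  out2 <- rescueMissingGenes(intact, sim$modelsH1, sim$modelsH2, sim$blocks,
                             sim$genomeH2, "h1to2", NULL, "h2")
  expect_identical(out2$report$reason, "target_region_annotated")
})
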