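test_that("a tag aligning inside two genes is annotated with both superIDs", {
  ref <- toy_target()
  # tag5 has alignments inside geneY@E1 and geneZ@E1
  tags <- GenomicRanges::GRanges(c("chr1:111-135:+", "chr1:1051-1075:-"))
  names(tags) <- c("tag5", "tag5")
  ann <- annotateTags(tags, ref)
  tab <- annotationTable(ann)
  expect_setequal(unlist(tab$matchedSuper), c("geneY", "geneZ"))
  expect_true(tab$hit.multiTarget)
  expect_equal(featureTags(deriveMultiTarget(ann)), "tag5")
})

test_that("multiTarget is defined at the superID level", {
  ref <- toy_target()
  tags <- GenomicRanges::GRanges(c("chr1:111-135:+",  # geneY@E1
                                   "chr1:411-435:+",  # geneY@E2
                                   "chr1:711-735:+")) # intergenic
  names(tags) <- c("twoExons", "twoExons", "lost")
  ann <- annotateTags(tags, ref)
  tab <- annotationTable(ann)
  # two exons of one gene: not multiTarget; unmatched: retained, not MT
  expect_equal(sum(tab$hit.multiTarget), 0L)
  expect_length(featureTags(deriveMultiTarget(ann)), 0L)
  lost <- tab[tab$tag_id == "lost", ]
  expect_length(unlist(lost$matchedFull), 0L)
  # full-id granularity flags the two-exon tag instead
  expect_equal(featureTags(deriveMultiTarget(ann, level = "full")),
               "twoExons")
})

test_that("a 1-bp SNP overlap flags the tag regardless of strand", {
  ref <- toy_target()
  tags <- GenomicRanges::GRanges("chr1:111-135:+"); names(tags) <- "t1"
  snp <- exclusionFeature(
    "dbsnp", ranges = GenomicRanges::GRanges("chr1:111-111:*"))
  ann <- annotateTags(tags, ref, list(snp))
  expect_true(annotationTable(ann)$hit.dbsnp)
  # reverse-strand feature still hits: feature matching ignores strand
  snp2 <- exclusionFeature(
    "dbsnp", ranges = GenomicRanges::GRanges("chr1:135-135:-"))
  ann2 <- annotateTags(tags, ref, list(snp2))
  expect_true(annotationTable(ann2)$hit.dbsnp)
})

test_that("annotation equals one built from the all-pairs oracle", {
  set.seed(23)
  ref <- toy_target()
  tags <- random_granges(50, chroms = 1, span = 1600, max_width = 30,
                         strands = c("+", "-"), prefix = "t")
  snps <- random_granges(20, chroms = 1, span = 1600, max_width = 1,
                         strands = "*", prefix = "s")
  ann <- annotateTags(tags, ref, list(exclusionFeature("snp", snps)))
  tab <- annotationTable(ann)
  oracle_pairs <- matchAllPairsOracle(tags, targetRanges(ref), "require", 1)
  oracle_snp <- matchAllPairsOracle(tags, snps, "ignore", 1)
  for (i in seq_len(nrow(tab))) {
    expect_setequal(
      unlist(tab$matchedFull[i]),
      oracle_pairs$subject_id[oracle_pairs$query_id == tab$tag_id[i]])
    expect_equal(tab$hit.snp[i],
                 tab$tag_id[i] %in% oracle_snp$query_id)
  }
})

test_that("exclusion filtering is monotone and validates names", {
  set.seed(31)
  ref <- toy_target()
  tags <- random_granges(60, chroms = 1, span = 1600, max_width = 30,
                         strands = c("+", "-"), prefix = "t")
  snps <- random_granges(15, chroms = 1, span = 1600, max_width = 1,
                         strands = "*", prefix = "s")
  ann <- annotateTags(tags, ref, list(exclusionFeature("snp", snps)))
  s_none <- applyExclusions(ann, character())
  s_snp <- applyExclusions(ann, "snp")
  s_both <- applyExclusions(ann, c("snp", "multiTarget"))
  expect_true(all(s_both %in% s_snp))
  expect_true(all(s_snp %in% s_none))
  # empty selection keeps exactly the matched tags
  tab <- annotationTable(ann)
  expect_setequal(s_none, tab$tag_id[lengths(tab$matchedFull) > 0])
  expect_error(applyExclusions(ann, "nope"),
               "unknown exclusion feature.*available")
})

test_that("duplicate or reserved feature names are rejected", {
  ref <- toy_target()
  tags <- GenomicRanges::GRanges("chr1:111-135:+"); names(tags) <- "t1"
  f <- exclusionFeature("snp", GenomicRanges::GRanges("chr1:111-111"))
  expect_error(annotateTags(tags, ref, list(f, f)), "duplicate")
  mt <- exclusionFeature("multiTarget", GenomicRanges::GRanges("chr1:1-2"))
  expect_error(annotateTags(tags, ref, list(mt)), "derived automatically")
})

test_that("annotation and membership writers emit readable tables", {
  ref <- toy_target()
  tags <- GenomicRanges::GRanges(c("chr1:111-135:+", "chr1:1051-1075:-"))
  names(tags) <- c("tag5", "tag5")
  ann <- annotateTags(tags, ref)
  f <- withr::local_tempfile()
  writeTagAnnotation(ann, f)
  df <- utils::read.delim(f)
  expect_equal(df$tag_id, "tag5")
  expect_setequal(strsplit(df$matched_targets, ",")[[1]],
                  c("geneY@E1", "geneZ@E1"))
  g <- withr::local_tempfile()
  writeFeatureTags(deriveMultiTarget(ann), g)
  expect_equal(readLines(g), "tag5")
})
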