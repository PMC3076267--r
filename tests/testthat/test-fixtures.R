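# one small shared fixture keeps this file fast
fx_spec <- fixtureSpec(seed = 11, nGenes = 30L, readsPerSample = 3000L)

test_that("the same seed reproduces every file byte-identically", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generateFixture(fx_spec, d1)
  generateFixture(fx_spec, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 5L)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("every generated file parses cleanly through the readers", {
  d <- withr::local_tempdir()
  fx <- generateFixture(fx_spec, d)
  expect_no_warning({
    ref <- readTargetReference(fx$target)
    probes <- readBed(fx$closedBed)
    meas <- readMeasurementTable(fx$closedMeasurements)
    snps <- readBed(fx$snp)
    reads <- readBed(fx$openBeds[1])
  })
  expect_equal(length(superIDs(ref)), 30L)
  expect_setequal(rownames(meas), unique(names(probes)))
  expect_gt(length(snps), 0L)
  expect_gt(length(reads), 0L)
})

test_that("planted multiTarget tags are exactly the ones the annotator flags", {
  d <- withr::local_tempdir()
  fx <- generateFixture(fx_spec, d)
  ref <- readTargetReference(fx$target)
  for (p in c("MA", fx$openSamples[c(1, 4)])) {
    bed <- if (p == "MA") fx$closedBed else fx$openBeds[p]
    ann <- annotateTags(readBed(bed), ref)
    tab <- annotationTable(ann)
    flagged <- tab$tag_id[tab$hit.multiTarget]
    planted <- fx$multiTargetTags$tag_id[fx$multiTargetTags$platform == p]
    expect_setequal(flagged, planted)
  }
})

test_that("exclusion removes exactly the planted undesirable tags", {
  d <- withr::local_tempdir()
  fx <- generateFixture(fx_spec, d)
  ref <- readTargetReference(fx$target)
  snp <- exclusionFeature("snp", readBed(fx$snp))
  for (p in c("MA", fx$openSamples[2])) {
    bed <- if (p == "MA") fx$closedBed else fx$openBeds[p]
    ann <- annotateTags(readBed(bed), ref, list(snp))
    tab <- annotationTable(ann)
    matched <- tab$tag_id[lengths(tab$matchedFull) > 0]
    surv <- applyExclusions(ann, c("multiTarget", "snp"))
    planted <- union(
      fx$multiTargetTags$tag_id[fx$multiTargetTags$platform == p],
      fx$snpTags$tag_id[fx$snpTags$platform == p])
    expect_setequal(setdiff(matched, surv), intersect(planted, matched))
  }
})

test_that("planted fractions are near their nominal values", {
  d <- withr::local_tempdir()
  fx <- generateFixture(fx_spec, d)
  reads <- unique(names(readBed(fx$openBeds[1])))
  mt <- fx$multiTargetTags$tag_id[
    fx$multiTargetTags$platform == fx$openSamples[1]]
  expect_equal(length(mt) / length(reads), 0.1, tolerance = 0.02)
  snp <- fx$snpTags$tag_id[fx$snpTags$platform == fx$openSamples[1]]
  # SNP overlap is stochastic around the calibrated density
  expect_gt(length(snp) / length(reads), 0.03)
  expect_lt(length(snp) / length(reads), 0.25)
})

test_that("planted DE genes top the fold-change ranking on clean fixtures", {
  clean <- fixtureSpec(seed = 12, nGenes = 30L, readsPerSample = 3000L,
                       fractionMultitargetTags = 0,
                       fractionSnpTags = 0, nDeGenes = 3L)
  d <- withr::local_tempdir()
  fx <- generateFixture(clean, d)
  m <- readMeasurementTable(fx$closedMeasurements)
  r <- rankByFoldChange(m, paste0("A", 1:3), paste0("B", 1:3),
                        scale = "linear")
  top_genes <- unique(sub("^P_(G[0-9]+)_.*$", "\\1", r))
  expect_setequal(top_genes[seq_along(fx$deGenes)], fx$deGenes)
})

test_that("without planted DE the generator plants no group structure", {
  null <- fixtureSpec(seed = 13, nGenes = 30L, readsPerSample = 3000L,
                      nDeGenes = 0L, tissueEffectSd = 0)
  d <- withr::local_tempdir()
  fx <- generateFixture(null, d)
  expect_length(fx$deGenes, 0L)
  m <- readMeasurementTable(fx$closedMeasurements)
  fc <- rowMeans(log2(m[, 1:3] + 1)) - rowMeans(log2(m[, 4:6] + 1))
  # probe-level fold changes center on zero at the noise scale
  expect_lt(abs(mean(fc)), 0.1)
  expect_lt(max(abs(fc)), 1)
})

test_that("infeasible specs are rejected", {
  expect_error(fixtureSpec(nGenes = 5, nDeGenes = 10), "more DE genes")
  expect_error(fixtureSpec(fractionSnpTags = 1.5), "fractions")
  expect_error(fixtureSpec(exonsPerGene = c(4, 2)), "increasing")
})
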