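test_that("median polish handles constant and additive matrices exactly", {
  fit <- medianPolish(matrix(5, 3, 4))
  expect_equal(fit@overall, 5)
  expect_equal(fit@rowEffects, rep(0, 3))
  expect_equal(fit@colEffects, rep(0, 4))
  expect_equal(max(abs(fit@residuals)), 0)

  fit2 <- medianPolish(rbind(c(1, 2), c(3, 4)))
  expect_equal(max(abs(fit2@residuals)), 0)
  expect_equal(fit2@overall + fit2@colEffects, c(2, 3))
})

test_that("median polish agrees with the stats reference implementation", {
  set.seed(42)
  for (i in 1:30) {
    nr <- sample(2:8, 1); nc <- sample(2:6, 1)
    x <- matrix(stats::rnorm(nr * nc, sd = 2), nr, nc)
    fit <- medianPolish(x)
    ref <- stats::medpolish(x, trace.iter = FALSE)
    expect_equal(fit@overall + fit@colEffects,
                 unname(ref$overall + ref$col), tolerance = 1e-12)
    # decomposition identity
    recon <- fit@overall + outer(fit@rowEffects, fit@colEffects, "+") +
      fit@residuals
    expect_equal(max(abs(recon - x)), 0, tolerance = 1e-9)
  }
})

test_that("median polish rejects degenerate input", {
  expect_error(medianPolish(matrix(numeric(0), 0, 0)), "empty")
  expect_error(medianPolish(matrix(c(1, NA), 1, 2)), "complete")
})

test_that("one probe per target passes its log2 values straight through", {
  ref <- toy_target()
  tags <- GenomicRanges::GRanges("chr1:111-135:+"); names(tags) <- "p1"
  ann <- annotateTags(tags, ref)
  meas <- matrix(c(3, 7, 15), 1, 3,
                 dimnames = list("p1", c("s1", "s2", "s3")))
  ps <- summarizeClosed(meas, ann, "p1", logOffset = 1)
  expect_equal(summaryValues(ps)["geneY", ], log2(c(3, 7, 15) + 1),
               ignore_attr = TRUE)
})

test_that("an additive probe block recovers the column pattern", {
  ref <- toy_target()
  tags <- GenomicRanges::GRanges(rep("chr1:111-135:+", 3))
  names(tags) <- paste0("p", 1:3)
  col_pattern <- c(4, 6, 9)
  probe_offset <- c(-1, 0, 2)
  meas <- 2^outer(probe_offset, col_pattern, "+")
  dimnames(meas) <- list(paste0("p", 1:3), c("s1", "s2", "s3"))
  ann <- annotateTags(tags, ref)
  ps <- summarizeClosed(meas, ann, paste0("p", 1:3), logOffset = 0)
  v <- summaryValues(ps)["geneY", ]
  # recovered up to a shared constant
  expect_equal(diff(v), diff(col_pattern), ignore_attr = TRUE,
               tolerance = 1e-9)
})

test_that("excluding a probe changes only the targets that contained it", {
  ref <- toy_target()
  tags <- GenomicRanges::GRanges(c("chr1:111-135:+", "chr1:121-145:+",
                                   "chr1:1051-1075:-"))
  names(tags) <- c("pY1", "pY2", "pZ1")
  set.seed(5)
  meas <- matrix(2^stats::rnorm(9, 8), 3, 3,
                 dimnames = list(c("pY1", "pY2", "pZ1"),
                                 c("s1", "s2", "s3")))
  ann <- annotateTags(tags, ref)
  all_surv <- c("pY1", "pY2", "pZ1")
  a <- summaryValues(summarizeClosed(meas, ann, all_surv))
  b <- summaryValues(summarizeClosed(meas, ann, c("pY1", "pZ1")))
  expect_equal(a["geneZ", ], b["geneZ", ])
  expect_false(isTRUE(all.equal(a["geneY", ], b["geneY", ])))
})

test_that("summarizeClosed is invariant to probe row order and flags bad values", {
  ref <- toy_target()
  tags <- GenomicRanges::GRanges(c("chr1:111-135:+", "chr1:121-145:+"))
  names(tags) <- c("p1", "p2")
  meas <- matrix(c(1, 2, 3, 4), 2, 2,
                 dimnames = list(c("p1", "p2"), c("s1", "s2")))
  ann <- annotateTags(tags, ref)
  a <- summarizeClosed(meas, ann, c("p1", "p2"))
  b <- summarizeClosed(meas[2:1, ], ann, c("p1", "p2"))
  expect_equal(summaryValues(a), summaryValues(b))
  meas[1, 1] <- -1
  expect_error(summarizeClosed(meas, ann, c("p1", "p2"), logOffset = 0),
               "nonpositive.*p1")
})

test_that("RPKM closed form and conservation identity hold", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  # doubling C and N together leaves RPKM unchanged
  expect_equal(rpkm(20, 1000, 2e6), rpkm(10, 1000, 1e6))

  ref <- toy_target()
  set.seed(9)
  reads <- random_granges(200, chroms = 1, span = 1600, max_width = 25,
                          strands = c("+", "-"), prefix = "r")
  pairs <- matchIntervals(reads, targetRanges(ref))
  surv <- unique(pairs$query_id)
  ps <- summarizeOpenRpkm(pairs, surv, ref, totalMappedReads = 200,
                          platformId = "ngs")
  v <- summaryValues(ps)
  gr <- targetRanges(ref)
  merged <- GenomicRanges::reduce(S4Vectors::split(
    GenomicRanges::granges(gr), S4Vectors::mcols(gr)$superID))
  L <- sum(GenomicRanges::width(merged))[rownames(v)]
  # sum over targets of RPKM * L * N / 1e9 returns total assignments
  sup_of <- S4Vectors::mcols(gr)$superID[match(pairs$subject_id, names(gr))]
  n_assign <- nrow(unique(data.frame(pairs$query_id, sup_of)))
  expect_equal(sum(v[, 1] * L * 200 / 1e9), n_assign)
})

test_that("a read hitting one superID via several exons counts once", {
  ref <- toy_target()
  # spans the gap so it overlaps both geneY exons
  reads <- GenomicRanges::GRanges("chr1:291-410:+"); names(reads) <- "r1"
  pairs <- matchIntervals(reads, targetRanges(ref))
  expect_equal(nrow(pairs), 2L)
  ps <- summarizeOpenRpkm(pairs, "r1", ref, totalMappedReads = 10)
  expect_equal(summaryValues(ps)["geneY", 1],
               rpkm(1, 400, 10), ignore_attr = TRUE)
})
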