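# brute-force per-base oracle for open-platform coverage
per_base_counts <- function(gr, chrom, start, end) {
  bases <- numeric(end - start)
  on <- as.character(GenomicRanges::seqnames(gr)) == chrom
  for (i in which(on)) {
    s <- max(GenomicRanges::start(gr)[i] - 1L, start)
    e <- min(GenomicRanges::end(gr)[i], end)
    if (s < e) bases[(s - start + 1):(e - start)] <-
        bases[(s - start + 1):(e - start)] + 1
  }
  bases
}

expand_steps <- function(tr, start, end) {
  bases <- numeric(end - start)
  for (i in seq_len(nrow(tr)))
    bases[(tr$start[i] - start + 1):(tr$end[i] - start)] <- tr$height[i]
  bases
}

test_that("single and stacked reads produce the documented steps", {
  gr <- GenomicRanges::GRanges("chr1:101-105:+"); names(gr) <- "r1"
  tr <- coverageBedGraph(list(ngs = list(tags = gr)), "chr1", ".",
                         0, 200)$ngs
  expect_equal(tr$start, 100)
  expect_equal(tr$end, 105)
  expect_equal(tr$height, 1)

  gr2 <- GenomicRanges::GRanges(c("chr1:101-110:+", "chr1:106-115:+"))
  names(gr2) <- c("r1", "r2")
  tr2 <- coverageBedGraph(list(ngs = list(tags = gr2)), "chr1", ".",
                          0, 200)$ngs
  expect_equal(tr2$start, c(100, 105, 110))
  expect_equal(tr2$end, c(105, 110, 115))
  expect_equal(tr2$height, c(1, 2, 1))
})

test_that("empty windows and unknown chromosomes yield empty tracks", {
  gr <- GenomicRanges::GRanges("chr1:101-105:+"); names(gr) <- "r1"
  tr <- coverageBedGraph(list(ngs = list(tags = gr)), "chr1", ".",
                         500, 600)$ngs
  expect_equal(nrow(tr), 0L)
  expect_warning(
    coverageBedGraph(list(ngs = list(tags = gr)), "chrX", ".", 0, 100),
    "no tags on chromosome")
})

test_that("coverage conserves total overlap against the per-base oracle", {
  set.seed(19)
  for (i in 1:20) {
    gr <- random_granges(60, chroms = 2, span = 500, max_width = 40,
                         strands = "+", prefix = "r")
    start <- sample(0:300, 1); end <- start + sample(50:200, 1)
    tr <- coverageBedGraph(list(p = list(tags = gr)), "chr1", ".",
                           start, end)$p
    oracle <- per_base_counts(gr, "chr1", start, end)
    expect_equal(sum(tr$height * (tr$end - tr$start)), sum(oracle))
    expect_equal(expand_steps(tr, start, end), oracle)
  }
})

test_that("strand filtering counts only the requested strand", {
  gr <- GenomicRanges::GRanges(c("chr1:101-110:+", "chr1:101-110:-",
                                 "chr1:101-110:*"))
  names(gr) <- c("f", "r", "u")
  h <- function(strand)
    coverageBedGraph(list(p = list(tags = gr)), "chr1", strand,
                     90, 120)$p$height
  expect_equal(h("forward"), 2)   # + and unspecified
  expect_equal(h("backward"), 2)  # - and unspecified
  expect_equal(h("."), 3)
})

test_that("closed platforms report mean probe intensity per base", {
  gr <- GenomicRanges::GRanges(c("chr1:101-110:+", "chr1:106-115:+"))
  names(gr) <- c("p1", "p2")
  ints <- matrix(c(10, 20, 30, 50), 2, 2,
                 dimnames = list(c("p1", "p2"), c("s1", "s2")))
  tr <- coverageBedGraph(list(ma = list(tags = gr, intensities = ints)),
                         "chr1", ".", 0, 200)$ma
  # probe means are 20 and 35; overlap bases average them
  expect_equal(tr$height, c(20, 27.5, 35))
})

test_that("the bedGraph file is valid and per platform", {
  gr <- GenomicRanges::GRanges("chr1:101-105:+"); names(gr) <- "r1"
  f <- withr::local_tempfile()
  coverageBedGraph(list(a = list(tags = gr), b = list(tags = gr)),
                   "chr1", ".", 0, 200, path = f)
  lines <- readLines(f)
  expect_equal(sum(grepl("^track type=bedGraph", lines)), 2L)
  body <- lines[!grepl("^track", lines)]
  expect_true(all(lengths(strsplit(body, "\t")) == 4L))
  starts <- as.integer(vapply(strsplit(body, "\t"), `[`, "", 2))
  expect_true(!is.unsorted(starts[1:(length(starts) / 2)]))
})
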