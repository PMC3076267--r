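test_that("readBed parses both dialects into the internal convention", {
  f <- withr::local_tempfile()
  writeLines("chr1\t100\t200\ttagA\t+", f)
  gr <- readBed(f, dialect = "standard")
  expect_equal(GenomicRanges::start(gr), 101L)
  expect_equal(GenomicRanges::end(gr), 200L)
  expect_equal(names(gr), "tagA")
  expect_equal(as.character(GenomicRanges::strand(gr)), "+")

  # inclusive-end files (end = start + tag length - 1) gain one base
  writeLines("chr1\t100\t199\ttagA\t+", f)
  gr2 <- readBed(f, dialect = "closed_end")
  expect_equal(GenomicRanges::start(gr2), 101L)
  expect_equal(GenomicRanges::end(gr2), 200L)
})

test_that("6-column BED layout is auto-detected by the strand column", {
  f <- withr::local_tempfile()
  writeLines(c("chr2\t0\t50\tprobe1\t960\t-",
               "chr2\t60\t90\tprobe2\t820\t."), f)
  gr <- readBed(f)
  expect_equal(names(gr), c("probe1", "probe2"))
  expect_equal(as.character(GenomicRanges::strand(gr)), c("-", "*"))
})

test_that("comment lines are skipped and parse errors name the line", {
  f <- withr::local_tempfile()
  writeLines(c("# a comment", "track name=x", "browser position chr1",
               "chr1\t10\t20\tt1\t+"), f)
  expect_length(readBed(f), 1L)

  writeLines(c("chr1\t10\t20\tt1\t+", "chr1\tten\t20\tt2\t+"), f)
  expect_error(readBed(f), "line 2.*non-integer")
  writeLines(c("chr1\t30\t20\tt1\t+"), f)
  expect_error(readBed(f), "line 1.*invalid interval")
  writeLines(c("chr1\t10\t20\tt1\tx"), f)
  expect_error(readBed(f), "unknown strand")
})

test_that("read/write round trip is the identity in both dialects", {
  f <- withr::local_tempfile(); g <- withr::local_tempfile()
  lines <- c("chr1\t100\t200\ttagA\t+", "chr2\t0\t25\ttagB\t-",
             "chr1\t500\t501\ttagC\t.")
  for (d in c("standard", "closed_end")) {
    writeLines(lines, f)
    writeBed(readBed(f, dialect = d), g, dialect = d)
    expect_identical(readLines(g), lines)
  }
})

test_that("target references group by full id and reject malformed ids", {
  f <- withr::local_tempfile()
  writeLines(c("chr5\t100\t200\tBRCA1@Exon1\t+",
               "chr5\t300\t400\tBRCA1@Exon2\t+",
               "chr5\t100\t200\tBRCA1@Exon1\t+"), f)
  ref <- readTargetReference(f, name = "t")
  # the duplicate Exon1 line is dropped; two intervals remain
  expect_length(targetRanges(ref), 2L)
  expect_equal(superIDs(ref), "BRCA1")
  expect_setequal(names(targetRanges(ref)),
                  c("BRCA1@Exon1", "BRCA1@Exon2"))

  writeLines("chr5\t100\t200\tBRCA1\t+", f)
  expect_error(readTargetReference(f), "exactly one '@'.*BRCA1")
  writeLines("chr5\t100\t200\tBRCA1@Exon1@x\t+", f)
  expect_error(readTargetReference(f), "exactly one '@'")
})

test_that("measurement tables parse, with Windows endings equivalent", {
  f <- withr::local_tempfile()
  writeLines(c("probeID\ts1\ts2\ts3", "p1\t1.5\t2\t3", "p2\t4\t5\tNA"), f)
  m <- readMeasurementTable(f)
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(rownames(m), c("p1", "p2"))
  expect_true(is.na(m["p2", "s3"]))

  g <- withr::local_tempfile()
  writeBin(charToRaw("probeID\ts1\ts2\ts3\r\np1\t1.5\t2\t3\r\np2\t4\t5\tNA\r\n"), g)
  expect_equal(readMeasurementTable(g), m)
})

test_that("measurement tables reject degenerate input", {
  f <- withr::local_tempfile()
  writeLines("probeID\ts1\ts2", f)
  expect_error(readMeasurementTable(f), "no rows")
  writeLines(c("probeID\ts1\ts2", "p1\t1\t2", "p2\t3"), f)
  expect_error(readMeasurementTable(f), "ragged")
  writeLines(c("probeID\ts1", "p1\t1", "p1\t2"), f)
  expect_error(readMeasurementTable(f), "duplicate probe")
  writeLines(c("probeID\ts1", "p1\tabc"), f)
  expect_error(readMeasurementTable(f), "non-numeric.*p1")
})

test_that("measurement table write/read round trips including NA", {
  x <- matrix(c(1.25, NA, 3, 4), 2, 2,
              dimnames = list(c("p1", "p2"), c("a", "b")))
  f <- withr::local_tempfile()
  writeMeasurementTable(x, f, idHeader = "probeID")
  expect_equal(readMeasurementTable(f), x)
})
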