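# Shared generators for randomized interval tests.

random_granges <- function(n, chroms = 3L, span = 1000L,
                           max_width = 100L,
                           strands = c("+", "-", "*"),
                           prefix = "iv") {
  st <- sample.int(span, n, replace = TRUE)
  gr <- GenomicRanges::GRanges(
    paste0("chr", sample.int(chroms, n, replace = TRUE)),
    IRanges::IRanges(start = st,
                     width = sample.int(max_width, n, replace = TRUE)),
    strand = sample(strands, n, replace = TRUE))
  names(gr) <- paste0(prefix, seq_len(n))
  gr
}

# Small target reference: two genes, two exons each, on one chromosome.
toy_target <- function() {
  gr <- GenomicRanges::GRanges(
    rep("chr1", 4),
    IRanges::IRanges(start = c(101, 401, 1001, 1301),
                     end = c(300, 600, 1200, 1500)),
    strand = c("+", "+", "-", "-"))
  names(gr) <- c("geneY@E1", "geneY@E2", "geneZ@E1", "geneZ@E2")
  makeTargetReference(gr, name = "toy")
}

# Use an isolated system directory so build/load tests cannot collide.
with_sys_home <- function(code) {
  old <- getOption("crossExpress.home")
  options(crossExpress.home = tempfile("sys"))
  on.exit(options(crossExpress.home = old))
  force(code)
}
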