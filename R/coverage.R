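#' Per-platform coverage tracks over a genomic window, as bedGraph
#'
#' For each platform, computes base-resolution coverage over the
#' requested window and run-length encodes it into maximal constant
#' steps. Open platforms report the number of reads covering each base;
#' closed platforms report the mean, over probes covering the base, of
#' each probe's mean intensity across the platform's samples (raw-scale
#' averaging by default, switchable to log2). Zero-height runs are
#' omitted. The output file is UCSC bedGraph: one `track type=bedGraph
#' name=...` line per platform followed by `chrom start end height`
#' rows with 0-based half-open ascending coordinates.
#'
#' Only tags on the requested strand count when `strand` is `forward`
#' or `backward` (tags with unspecified strand always count); `"."`
#' disables the strand filter.
#'
#' @param platforms named list; each element a list with `tags` (named
#'   `GRanges` of alignments) and, for closed platforms, `intensities`
#'   (probe-by-sample matrix whose rownames match the tag names).
#' @param chrom chromosome of the window.
#' @param strand `"forward"`, `"backward"`, or `"."`/`"*"` for both;
#'   `"+"`/`"-"` also accepted.
#' @param start,end window in 0-based half-open coordinates,
#'   `start < end`.
#' @param path output bedGraph path, or `NULL` to skip writing.
#' @param intensityScale `"raw"` or `"log2"` averaging of closed-
#'   platform intensities.
#' @return invisibly, a named list of per-platform data.frames with
#'   columns `chrom`, `start`, `end`, `height` (0-based half-open).
#' @export
coverageBedGraph <- function(platforms, chrom, strand = ".",
                             start, end, path = NULL,
                             intensityScale = c("raw", "log2")) {
  intensityScale <- match.arg(intensityScale)
  stopifnot(start < end, start >= 0)
  strand <- switch(strand, forward = "+", backward = "-",
                   "." = "*", strand)
  if (!strand %in% c("+", "-", "*"))
    stop("strand must be forward, backward, +, -, . or *")
  tracks <- list()
  any_chrom <- FALSE
  for (id in names(platforms)) {
    p <- platforms[[id]]
    gr <- p$tags
    on_chrom <- as.character(GenomicRanges::seqnames(gr)) == chrom
    any_chrom <- any_chrom || any(on_chrom)
    keep <- on_chrom
    if (strand != "*") {
      st <- as.character(GenomicRanges::strand(gr))
      keep <- keep & (st == "*" | st == strand)
    }
    gr <- gr[keep]
    # clip to the window; coordinates below are window-relative 1-based
    s0 <- pmax(GenomicRanges::start(gr) - 1L, start)
    e0 <- pmin(GenomicRanges::end(gr), end)
    ok <- s0 < e0
    gr <- gr[ok]; s0 <- s0[ok]; e0 <- e0[ok]
    w <- as.integer(end - start)
    ir <- IRanges::IRanges(start = s0 - start + 1L, end = e0 - start)
    if (is.null(p$intensities)) {
      cov <- as.numeric(IRanges::coverage(ir, width = w))
    } else {
      probe_mean <- rowMeans(p$intensities)
      if (intensityScale == "log2") probe_mean <- log2(probe_mean + 1)
      wts <- unname(probe_mean[names(gr)])
      covW <- as.numeric(IRanges::coverage(ir, width = w, weight = wts))
      covN <- as.numeric(IRanges::coverage(ir, width = w))
      cov <- ifelse(covN > 0, covW / covN, 0)
    }
    r <- rle(cov)
    stop_at <- cumsum(r$lengths)
    step <- data.frame(chrom = chrom,
                       start = start + c(0L, stop_at[-length(stop_at)]),
                       end = start + stop_at,
                       height = r$values)
    tracks[[id]] <- step[step$height != 0, , drop = FALSE]
  }
  if (!any_chrom && length(platforms))
    warning("no tags on chromosome ", chrom, "; tracks are empty")
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    for (id in names(tracks)) {
      writeLines(sprintf("track type=bedGraph name=%s", id), con)
      tr <- tracks[[id]]
      if (nrow(tr))
        writeLines(paste(tr$chrom, tr$start, tr$end,
                         format(tr$height, trim = TRUE, digits = 10),
                         sep = "\t"), con)
    }
  }
  invisible(tracks)
}
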