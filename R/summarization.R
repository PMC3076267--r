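#' Tukey median polish
#'
#' Iteratively sweeps row medians into row effects and column medians
#' into column effects (folding medians of the effects into the overall
#' term), yielding the additive decomposition
#' `x[i, j] = overall + row[i] + col[j] + residual[i, j]`, which holds
#' exactly at every iteration. Iteration stops when the sum of absolute
#' residuals decreases by no more than `tol` times its current value,
#' or after `maxIter` full sweeps. Medians of even counts use the
#' midpoint of the middle two values.
#'
#' This is the summarization step of RMA-style probe-set analysis: run
#' on a probes-by-samples block of log2 intensities, `overall +
#' colEffects` is the per-sample summary.
#'
#' @param x numeric matrix, at least 1 x 1, no missing values.
#' @param maxIter maximum number of full sweeps (default 10).
#' @param tol relative convergence tolerance on the absolute-residual
#'   sum (default 0.01).
#' @return a [MedianPolishFit].
#' @examples
#' fit <- medianPolish(rbind(c(1, 2), c(3, 4)))
#' fit@overall + fit@colEffects   # per-column summary: 2, 3
#' @export
medianPolish <- function(x, maxIter = 10L, tol = 0.01) {
  x <- as.matrix(x)
  if (length(x) == 0L) stop("empty matrix")
  if (anyNA(x)) stop("median polish requires a complete matrix")
  nr <- nrow(x); nc <- ncol(x)
  overall <- 0
  rowEff <- numeric(nr)
  colEff <- numeric(nc)
  z <- x
  oldsum <- 0
  iter <- 0L
  converged <- FALSE
  while (iter < maxIter) {
    iter <- iter + 1L
    rdelta <- apply(z, 1L, stats::median)
    z <- z - rdelta
    rowEff <- rowEff + rdelta
    delta <- stats::median(colEff)
    colEff <- colEff - delta
    overall <- overall + delta
    cdelta <- apply(z, 2L, stats::median)
    z <- sweep(z, 2L, cdelta)
    colEff <- colEff + cdelta
    delta <- stats::median(rowEff)
    rowEff <- rowEff - delta
    overall <- overall + delta
    newsum <- sum(abs(z))
    if (newsum == 0 || abs(newsum - oldsum) < tol * newsum) {
      converged <- TRUE
      break
    }
    oldsum <- newsum
  }
  new("MedianPolishFit", overall = overall, rowEffects = rowEff,
      colEffects = colEff, residuals = z, iterations = iter,
      converged = converged)
}

#' Summarize a closed platform: probes to target-level log2 values
#'
#' For each superID, the rows of its surviving matched probes are
#' collected from the measurement table, transformed `log2(x +
#' logOffset)`, and median-polished; the reported per-sample value is
#' `overall + colEffect`. SuperIDs with no surviving probe are absent
#' from the output. The result does not depend on probe row order.
#'
#' @param measurements numeric probe-by-sample matrix (see
#'   [readMeasurementTable()]).
#' @param annotation a [TagAnnotation] built from this platform's probe
#'   alignments.
#' @param surviving character vector of surviving probe ids (from
#'   [applyExclusions()]).
#' @param logOffset nonnegative offset added before log2 (default 1).
#' @param platformId reported platform name.
#' @return a [PlatformSummary] with `kind = "closed"`, values on log2
#'   scale.
#' @export
summarizeClosed <- function(measurements, annotation, surviving,
                            logOffset = 1, platformId = "closed") {
  stopifnot(is.matrix(measurements), logOffset >= 0)
  tab <- annotationTable(annotation)
  tab <- tab[tab$tag_id %in% surviving, , drop = FALSE]
  missing <- setdiff(tab$tag_id, rownames(measurements))
  if (length(missing)) {
    warning(length(missing), " surviving tag(s) absent from the ",
            "measurement table were skipped (e.g. ", missing[1], ")")
    tab <- tab[!tab$tag_id %in% missing, , drop = FALSE]
  }
  long_tag <- rep(tab$tag_id, lengths(tab$matchedSuper))
  long_sup <- unlist(tab$matchedSuper, use.names = FALSE)
  sups <- sort(unique(long_sup))
  out <- matrix(NA_real_, nrow = length(sups), ncol = ncol(measurements),
                dimnames = list(sups, colnames(measurements)))
  tags_by_sup <- split(long_tag, factor(long_sup, sups))
  for (s in sups) {
    probes <- sort(unique(tags_by_sup[[s]]))
    block <- measurements[probes, , drop = FALSE]
    if (any(block + logOffset <= 0)) {
      bad <- probes[which(rowSums(block + logOffset <= 0) > 0)[1]]
      stop("nonpositive value under logOffset = ", logOffset,
           " at probe ", bad)
    }
    fit <- medianPolish(log2(block + logOffset))
    out[s, ] <- fit@overall + fit@colEffects
  }
  new("PlatformSummary", platformId = platformId, kind = "closed",
      values = out)
}

#' RPKM: reads per kilobase of exon model per million mapped reads
#'
#' Closed form `1e9 * C / (N * L)` for `C` reads in a target of merged
#' exon length `L` bases out of `N` mapped reads.
#'
#' @param C read count (may be a vector).
#' @param L merged exon length in bases.
#' @param N total mapped reads.
#' @return numeric RPKM value(s).
#' @examples
#' rpkm(10, 1000, 1e6)  # 10
#' @export
rpkm <- function(C, L, N) {
  stopifnot(all(L > 0), N > 0)
  1e9 * C / (N * L)
}

#' Summarize an open platform: read counts to RPKM
#'
#' Per superID: `C` is the number of distinct surviving reads matched to
#' it (a read matching one superID via several exons, or several
#' alignments, counts once), `L` the length of the union of the
#' superID's sub-intervals with overlaps merged, and the value is
#' `rpkm(C, L, totalMappedReads)`. SuperIDs with no surviving read are
#' absent from the output.
#'
#' @param pairs tag-to-target match pairs from [matchIntervals()]
#'   (`subject_id` = full target ids).
#' @param surviving character vector of surviving read ids.
#' @param target the [TargetReference] matched against.
#' @param totalMappedReads RPKM's N; conventionally the number of
#'   distinct aligned reads in the platform's input, counted before
#'   exclusion filtering.
#' @param platformId reported platform name (one open platform is one
#'   sample).
#' @param perAlignment if `TRUE`, count each (read, superID) pair once
#'   per contributing alignment-exon match instead of once per read.
#' @return a [PlatformSummary] with `kind = "open"` and a single RPKM
#'   column named `platformId`.
#' @export
summarizeOpenRpkm <- function(pairs, surviving, target, totalMappedReads,
                              platformId = "open", perAlignment = FALSE) {
  stopifnot(is(target, "TargetReference"), totalMappedReads > 0)
  gr <- targetRanges(target)
  sup_of <- S4Vectors::mcols(gr)$superID
  merged <- GenomicRanges::reduce(
    S4Vectors::split(GenomicRanges::granges(gr), sup_of))
  L <- sum(GenomicRanges::width(merged))
  if (any(L <= 0)) stop("malformed reference: superID with zero length")
  keep <- pairs$query_id %in% surviving
  sup <- sup_of[match(pairs$subject_id[keep], names(gr))]
  tag <- pairs$query_id[keep]
  if (!perAlignment && length(tag)) {
    dd <- !duplicated(paste0(tag, "\r", sup))
    tag <- tag[dd]; sup <- sup[dd]
  }
  counts <- table(factor(sup, levels = sort(unique(sup))))
  sups <- names(counts)
  vals <- matrix(rpkm(as.numeric(counts), as.numeric(L[sups]),
                      totalMappedReads),
                 ncol = 1, dimnames = list(sups, platformId))
  new("PlatformSummary", platformId = platformId, kind = "open",
      values = vals)
}

#' Write a platform summary as TSV
#'
#' @param summary a [PlatformSummary].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePlatformSummary <- function(summary, path) {
  writeMeasurementTable(summaryValues(summary), path)
}
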