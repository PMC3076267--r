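#' Overlap-join two interval sets with a sweep-line pass
#'
#' The core matching step: pairs every query interval (tag alignment)
#' with every subject interval (target sub-feature or exclusion feature)
#' that it overlaps by at least `minOverlap` bases on the same
#' chromosome. Both sets' endpoints are sorted once and a single linear
#' sweep walks the genome, keeping the currently open intervals of each
#' side in an active store; a pair is emitted when an interval opens
#' while a partner is active. Cost is O(n log n + n + k) for k
#' overlapping pairs — the quadratic all-pairs comparison is never
#' formed.
#'
#' Under half-open coordinate semantics, touching intervals (one ending
#' where the other starts) do not overlap; the sweep processes end
#' events before start events at equal positions, which makes that the
#' only consistent tie rule.
#'
#' Duplicate id pairs — a tag overlapping several exons of one full
#' target id, or via several of its alignments — are collapsed to one
#' pair.
#'
#' @param query,subject named [GenomicRanges::GRanges]; names are the
#'   ids reported in the output (and need not be unique — a tag may have
#'   several alignments).
#' @param strandPolicy `"require"`: intervals pair only when strands are
#'   equal or either is unspecified (`*`). `"ignore"`: strand plays no
#'   role.
#' @param minOverlap minimum number of shared bases (default 1).
#' @return a `data.frame` with character columns `query_id` and
#'   `subject_id`, one row per distinct pair, sorted for determinism.
#' @seealso [matchAllPairsOracle()] for the brute-force reference.
#' @examples
#' q <- GenomicRanges::GRanges("chr1:101-200:+")
#' names(q) <- "tag1"
#' s <- GenomicRanges::GRanges("chr1:151-250:+")
#' names(s) <- "G1@E1"
#' matchIntervals(q, s)
#' @export
matchIntervals <- function(query, subject,
                           strandPolicy = c("require", "ignore"),
                           minOverlap = 1L) {
  strandPolicy <- match.arg(strandPolicy)
  minOverlap <- as.integer(minOverlap)
  if (is.na(minOverlap) || minOverlap < 1L)
    stop("minOverlap must be a positive integer")
  .check_named(query, "query"); .check_named(subject, "subject")
  if (length(query) == 0L || length(subject) == 0L)
    return(.empty_pairs())
  chroms <- unique(c(as.character(GenomicRanges::seqnames(query)),
                     as.character(GenomicRanges::seqnames(subject))))
  qc <- match(as.character(GenomicRanges::seqnames(query)), chroms)
  sc <- match(as.character(GenomicRanges::seqnames(subject)), chroms)
  hits <- .sweep_match_cpp(
    GenomicRanges::start(query) - 1L, GenomicRanges::end(query),
    qc, .strand_code(query),
    GenomicRanges::start(subject) - 1L, GenomicRanges::end(subject),
    sc, .strand_code(subject),
    strandPolicy == "require", minOverlap)
  .finish_pairs(names(query)[hits[, 1]], names(subject)[hits[, 2]])
}

#' Brute-force all-pairs overlap join (test oracle)
#'
#' Definitionally correct pair set by exhaustive comparison of every
#' query against every subject — O(n^2) time, intended for small inputs
#' as an independent check on [matchIntervals()].
#'
#' @inheritParams matchIntervals
#' @return as [matchIntervals()].
#' @export
matchAllPairsOracle <- function(query, subject,
                                strandPolicy = c("require", "ignore"),
                                minOverlap = 1L) {
  strandPolicy <- match.arg(strandPolicy)
  minOverlap <- as.integer(minOverlap)
  if (is.na(minOverlap) || minOverlap < 1L)
    stop("minOverlap must be a positive integer")
  .check_named(query, "query"); .check_named(subject, "subject")
  nq <- length(query); ns <- length(subject)
  if (nq == 0L || ns == 0L) return(.empty_pairs())
  qi <- rep(seq_len(nq), times = ns)
  si <- rep(seq_len(ns), each = nq)
  ok <- as.character(GenomicRanges::seqnames(query))[qi] ==
    as.character(GenomicRanges::seqnames(subject))[si]
  ov <- pmin(GenomicRanges::end(query)[qi],
             GenomicRanges::end(subject)[si]) -
    pmax(GenomicRanges::start(query)[qi] - 1L,
         GenomicRanges::start(subject)[si] - 1L)
  ok <- ok & ov >= minOverlap
  if (strandPolicy == "require") {
    qs <- as.character(GenomicRanges::strand(query))[qi]
    ss <- as.character(GenomicRanges::strand(subject))[si]
    ok <- ok & (qs == "*" | ss == "*" | qs == ss)
  }
  .finish_pairs(names(query)[qi[ok]], names(subject)[si[ok]])
}

.strand_code <- function(gr) {
  match(as.character(GenomicRanges::strand(gr)), c("*", "+", "-")) - 1L
}

.check_named <- function(gr, what) {
  if (length(gr) > 0L && (is.null(names(gr)) || any(!nzchar(names(gr)))))
    stop(what, " intervals must carry ids as names")
}

.empty_pairs <- function() {
  data.frame(query_id = character(), subject_id = character(),
             stringsAsFactors = FALSE)
}

.finish_pairs <- function(q, s) {
  if (length(q) == 0L) return(.empty_pairs())
  keep <- !duplicated(paste0(q, "\r", s))
  q <- q[keep]; s <- s[keep]
  ord <- order(q, s)
  data.frame(query_id = q[ord], subject_id = s[ord],
             stringsAsFactors = FALSE)
}
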