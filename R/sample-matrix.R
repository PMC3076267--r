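#' Column-bind many per-sample probe tables
#'
#' Each input file is a two-column tab-separated table (probe id,
#' value), with or without a header line; Affymetrix-style text exports
#' keyed by `probeID = x-coordinate + ":" + y-coordinate` fit this
#' shape. Only probe identifiers common to all files are kept, in the
#' first file's order, with one output column per file named from the
#' file stem.
#'
#' The binding is two-pass: a first pass reads only the id column of
#' each file and maintains the running intersection, a second pass reads
#' one file at a time and fills its column. Peak memory is one file plus
#' the intersection and output — never all files at once.
#'
#' @param samplePaths ordered character vector of file paths.
#' @return numeric matrix, rows = common probes, one column per file.
#' @export
bindSamples <- function(samplePaths) {
  if (length(samplePaths) < 1L) stop("need at least one sample file")
  read_two_col <- function(path, ids_only = FALSE) {
    first <- readLines(path, n = 1L)
    f1 <- strsplit(first, "\t", fixed = TRUE)[[1]]
    has_header <- length(f1) >= 2L &&
      is.na(suppressWarnings(as.numeric(f1[2])))
    df <- utils::read.delim(path, header = has_header, sep = "\t",
                            colClasses = c("character",
                                           if (ids_only) "NULL"
                                           else "numeric"),
                            quote = "", comment.char = "",
                            check.names = FALSE)
    ids <- df[[1]]
    if (anyDuplicated(ids))
      stop("duplicate probe id '", ids[duplicated(ids)][1], "' in ", path)
    if (ids_only) ids else df
  }
  # pass 1: running intersection of probe ids, in first-file order
  common <- read_two_col(samplePaths[1], ids_only = TRUE)
  for (p in samplePaths[-1])
    common <- common[common %in% read_two_col(p, ids_only = TRUE)]
  if (length(common) == 0L) stop("no common probe identifiers")
  # pass 2: fill one column per file
  stems <- sub("\\.[^.]*$", "", basename(samplePaths))
  if (anyDuplicated(stems)) {
    dup <- duplicated(stems)
    stems[dup] <- paste0(stems[dup], ".", cumsum(dup)[dup] + 1L)
    warning("duplicate sample names resolved with numeric suffixes")
  }
  out <- matrix(NA_real_, nrow = length(common),
                ncol = length(samplePaths),
                dimnames = list(common, stems))
  for (i in seq_along(samplePaths)) {
    df <- read_two_col(samplePaths[i])
    out[, i] <- df[[2]][match(common, df[[1]])]
  }
  out
}

#' Quantile normalization
#'
#' The rank-invariant transform that gives every column an identical
#' value distribution: each column is sorted, the sorted matrix is
#' row-averaged, and each column's values are replaced by the mean at
#' their own rank. Tied values within a column receive the average of
#' their tied positions' means. Within-column rank order is preserved,
#' and in the absence of ties every column's sorted values are exactly
#' the common mean vector afterwards, making the transform idempotent.
#'
#' The rank-assignment pass is processed one column at a time in row
#' blocks of `chunkRows`, so only the per-column sorting permutation and
#' one block of values are live at once beyond the shared mean vector —
#' the pattern that keeps very wide bound matrices (hundreds of
#' samples) tractable.
#'
#' @param x numeric matrix without missing values, at least one column.
#' @param chunkRows rows materialized at a time during rank assignment
#'   (default: all rows).
#' @return normalized matrix with the dimnames of `x`.
#' @examples
#' quantileNormalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
quantileNormalize <- function(x, chunkRows = nrow(x)) {
  x <- as.matrix(x)
  if (ncol(x) < 1L) stop("need at least one column")
  if (anyNA(x))
    stop("missing values present; bind samples (bindSamples) to a ",
         "complete matrix first")
  chunkRows <- max(1L, as.integer(chunkRows))
  n <- nrow(x)
  # pass 1: per-column sort, accumulate row sums of the sorted columns
  ord <- vector("list", ncol(x))
  msum <- numeric(n)
  for (j in seq_len(ncol(x))) {
    ord[[j]] <- sort.list(x[, j], method = "radix")
    msum <- msum + x[ord[[j]], j]
  }
  m <- msum / ncol(x)
  # pass 2: map means back by each column's original ranks, chunked
  out <- matrix(NA_real_, n, ncol(x), dimnames = dimnames(x))
  for (j in seq_len(ncol(x))) {
    o <- ord[[j]]
    for (lo in seq(1L, n, by = chunkRows)) {
      hi <- min(lo + chunkRows - 1L, n)
      out[o[lo:hi], j] <- m[lo:hi]
    }
    # ties share the average of their candidate normalized values
    if (anyDuplicated(x[, j]))
      out[, j] <- stats::ave(out[, j], match(x[, j], x[, j]),
                             FUN = mean)
  }
  out
}
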