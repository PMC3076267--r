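#' Read a BED or BED-like position file
#'
#' Reads tab-separated position files into a
#' [GenomicRanges::GRanges]. Two column orders are accepted and
#' auto-detected: the 5-column `chrom/start/end/id/strand` layout emitted
#' by typical aligner post-processing, and standard 6-column BED
#' (`chrom/start/end/name/score/strand`). Detection keys on whether the
#' fifth column consists of strand symbols (`+`, `-`, `.`).
#'
#' Coordinates in the file are 0-based. Under `dialect = "standard"` the
#' end column is exclusive (UCSC BED half-open); under
#' `dialect = "closed_end"` it is inclusive, as produced by recipes that
#' compute `end = start + length(sequence) - 1` from aligner output.
#' Internally the package uses one convention everywhere: the returned
#' `GRanges` is ordinary 1-based closed Bioconductor coordinates, so a
#' file record `[100, 200)` becomes `start = 101, end = 200` and only the
#' readers and writers know about dialects.
#'
#' Comment lines starting with `#`, `track` or `browser` are skipped
#' silently. Strand symbols map `+` to forward, `-` to reverse and `.`
#' to unspecified (`*`).
#'
#' @param path path to the file.
#' @param dialect `"standard"` (half-open end, default) or
#'   `"closed_end"` (inclusive end).
#' @return a `GRanges` with names taken from the id column.
#' @seealso [writeBed()], [readTargetReference()]
#' @export
readBed <- function(path, dialect = c("standard", "closed_end")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5L))
    stop("line ", lineno[which(nf < 5L)[1]],
         ": expected at least 5 tab-separated columns")
  col <- function(k) vapply(fields, `[`, "", k)
  strand_syms <- c("+", "-", ".")
  c5 <- col(5L)
  if (all(c5 %in% strand_syms)) {
    id <- col(4L); strand_chr <- c5
  } else if (all(nf >= 6L) && all(col(6L) %in% strand_syms)) {
    id <- col(4L); strand_chr <- col(6L)
  } else {
    bad <- if (any(nf >= 6L)) col(6L)[1] else c5[1]
    stop("line ", lineno[1], ": unknown strand symbol '", bad, "'")
  }
  chrom <- col(1L)
  start0 <- suppressWarnings(as.integer(col(2L)))
  end0 <- suppressWarnings(as.integer(col(3L)))
  badc <- which(is.na(start0) | is.na(end0))
  if (length(badc))
    stop("line ", lineno[badc[1]], ": non-integer coordinate")
  if (dialect == "closed_end") end0 <- end0 + 1L
  badr <- which(start0 >= end0 | start0 < 0L)
  if (length(badr))
    stop("line ", lineno[badr[1]],
         ": invalid interval (start must be >= 0 and < end after ",
         "dialect conversion)")
  if (any(!nzchar(chrom)))
    stop("line ", lineno[which(!nzchar(chrom))[1]], ": empty chromosome")
  strand <- ifelse(strand_chr == ".", "*", strand_chr)
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start0 + 1L,
                                                end = end0),
                               strand = strand)
  names(gr) <- id
  gr
}

#' Write intervals as a 5-column BED-like file
#'
#' Inverse of [readBed()]: emits `chrom start end id strand`,
#' tab-separated, unquoted, with coordinates converted back to the
#' requested dialect. `readBed()` followed by `writeBed()` in the same
#' dialect reproduces canonical input byte-identically.
#'
#' @param gr a named `GRanges`.
#' @param path output path.
#' @param dialect as in [readBed()].
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path, dialect = c("standard", "closed_end")) {
  dialect <- match.arg(dialect)
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  if (dialect == "closed_end") end0 <- end0 - 1L
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  lines <- paste(as.character(GenomicRanges::seqnames(gr)),
                 start0, end0, names(gr), strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a target reference from a BED file
#'
#' Every id must contain exactly one `@`, splitting into
#' `superID@subID`. Lines sharing a full id are merged into one target
#' record (its intervals), with exact duplicate intervals of one id
#' dropped.
#'
#' @param path path to the target BED file.
#' @param name reference name; defaults to the file stem.
#' @param dialect coordinate dialect, as in [readBed()].
#' @return a [TargetReference].
#' @export
readTargetReference <- function(path, name = NULL,
                                dialect = c("standard", "closed_end")) {
  gr <- readBed(path, dialect = match.arg(dialect))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  makeTargetReference(gr, name = name)
}

#' Build a TargetReference from a named GRanges
#'
#' @param gr `GRanges` named with `superID@subID` identifiers.
#' @param name reference name.
#' @return a [TargetReference].
#' @export
makeTargetReference <- function(gr, name = "target") {
  ids <- names(gr)
  if (is.null(ids)) stop("target intervals must be named")
  n_at <- lengths(regmatches(ids, gregexpr("@", ids, fixed = TRUE)))
  bad <- unique(ids[n_at != 1L])
  if (length(bad))
    stop("target ids must contain exactly one '@': ",
         paste(bad, collapse = ", "))
  # drop exact duplicate (id, interval) records
  key <- paste(ids, as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr), GenomicRanges::end(gr),
               as.character(GenomicRanges::strand(gr)))
  gr <- gr[!duplicated(key)]
  ids <- names(gr)
  parts <- strsplit(ids, "@", fixed = TRUE)
  S4Vectors::mcols(gr)$superID <- vapply(parts, `[`, "", 1L)
  S4Vectors::mcols(gr)$subID <- vapply(parts, `[`, "", 2L)
  ord <- order(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr), GenomicRanges::end(gr), ids)
  new("TargetReference", name = name, ranges = gr[ord])
}

#' Read a probe-by-sample measurement table
#'
#' Tab-delimited with a header row; the first column holds probe
#' identifiers, remaining columns one sample each. Missing values are
#' the literal string `NA`. Unix and Windows line endings are accepted.
#'
#' @param path path to the table.
#' @return numeric matrix with probe rownames and sample colnames.
#' @export
readMeasurementTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  nfields <- utils::count.fields(path, sep = "\t", quote = "",
                                 comment.char = "")
  if (length(nfields) < 2L) stop("no rows in measurement table: ", path)
  if (length(unique(nfields)) != 1L)
    stop("ragged rows in measurement table (line ",
         which(nfields != nfields[1])[1], "): ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  if (nrow(df) == 0L) stop("no rows in measurement table: ", path)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate probe ids in measurement table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  badcell <- which(is.na(num) & !(vals == "NA" | vals == ""), arr.ind = TRUE)
  if (nrow(badcell))
    stop("non-numeric value '", vals[badcell[1, 1], badcell[1, 2]],
         "' at probe ", ids[badcell[1, 1]])
  dimnames(num) <- list(ids, colnames(vals))
  num
}

#' Write a measurement or combined expression table
#'
#' Tab separators, no quoting, `NA` for missing; first column is the row
#' identifier under `idHeader`.
#'
#' @param x numeric matrix with rownames and colnames.
#' @param path output path.
#' @param idHeader header for the identifier column.
#' @return `path`, invisibly.
#' @export
writeMeasurementTable <- function(x, path, idHeader = "targetID") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- idHeader
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}
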