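#' System data directory
#'
#' Built targets and exclusion features live under a system directory:
#' the `crossExpress.home` option if set, else the `CROSSEXPRESS_HOME`
#' environment variable, else a per-session directory under [tempdir()].
#'
#' @return path to the system directory (created if needed).
#' @export
systemHome <- function() {
  home <- getOption("crossExpress.home",
                    Sys.getenv("CROSSEXPRESS_HOME", ""))
  if (!nzchar(home)) home <- file.path(tempdir(), "crossExpress_sys")
  for (d in file.path(home, "sys", c("target", "feature")))
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  home
}

#' Build (register) a target reference
#'
#' Validates, sorts and stores a target BED under the system directory
#' so combine runs can refer to it by name.
#'
#' @param bedPath path to a target BED file (`superID@subID` ids).
#' @param name name to store under (default: file stem).
#' @param overwrite must be `TRUE` to replace an existing build.
#' @param dialect coordinate dialect of the input, as in [readBed()].
#' @return the stored name, invisibly.
#' @export
buildTarget <- function(bedPath, name = NULL, overwrite = FALSE,
                        dialect = "standard") {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(bedPath))
  dest <- file.path(systemHome(), "sys", "target", paste0(name, ".BED"))
  if (file.exists(dest) && !overwrite)
    stop("target '", name, "' already built; use overwrite = TRUE")
  ref <- readTargetReference(bedPath, name = name, dialect = dialect)
  writeBed(targetRanges(ref), dest, dialect = "standard")
  invisible(name)
}

#' Load a built target reference by name
#'
#' @param name a name registered with [buildTarget()].
#' @return a [TargetReference].
#' @export
loadTarget <- function(name) {
  path <- file.path(systemHome(), "sys", "target", paste0(name, ".BED"))
  if (!file.exists(path))
    stop("no built target '", name, "'; available: ",
         paste(listSystemData()$targets, collapse = ", "))
  readTargetReference(path, name = name)
}

#' Build (register) an interval exclusion feature
#'
#' As [buildTarget()] but without the `superID@subID` id constraint.
#'
#' @inheritParams buildTarget
#' @return the stored name, invisibly.
#' @export
buildExclusionFeature <- function(bedPath, name = NULL, overwrite = FALSE,
                                  dialect = "standard") {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(bedPath))
  dest <- file.path(systemHome(), "sys", "feature", paste0(name, ".BED"))
  if (file.exists(dest) && !overwrite)
    stop("exclusion feature '", name, "' already built; use overwrite = TRUE")
  gr <- readBed(bedPath, dialect = dialect)
  if (length(gr) == 0L) stop("no features in ", bedPath)
  ord <- order(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr), GenomicRanges::end(gr))
  writeBed(gr[ord], dest, dialect = "standard")
  invisible(name)
}

#' Load a built exclusion feature by name
#'
#' @param name a name registered with [buildExclusionFeature()].
#' @return an [ExclusionFeature].
#' @export
loadExclusionFeature <- function(name) {
  path <- file.path(systemHome(), "sys", "feature", paste0(name, ".BED"))
  if (!file.exists(path))
    stop("no built exclusion feature '", name, "'; available: ",
         paste(listSystemData()$features, collapse = ", "))
  exclusionFeature(name, ranges = readBed(path))
}

#' List built targets and exclusion features
#'
#' @param quiet suppress printing.
#' @return invisibly, a list with character vectors `targets` and
#'   `features`.
#' @export
listSystemData <- function(quiet = FALSE) {
  home <- systemHome()
  lst <- function(kind) sort(sub("\\.BED$", "", list.files(
    file.path(home, "sys", kind), pattern = "\\.BED$")))
  out <- list(targets = lst("target"), features = lst("feature"))
  if (!quiet) {
    cat("System data under", home, "\n")
    cat("  targets: ", paste(out$targets, collapse = ", "), "\n")
    cat("  exclusion features: ", paste(out$features, collapse = ", "),
        "\n")
  }
  invisible(out)
}

#' Configure an end-to-end combine run
#'
#' @param closedPlatforms list of closed platforms, each a list with
#'   `id`, `bed` (probe alignment BED) and `measurements` (probe-by-
#'   sample table path).
#' @param openPlatforms named character vector of open-platform BED
#'   paths; one open platform corresponds to one sample, so each
#'   contributes one output column.
#' @param targetName name of a target built with [buildTarget()].
#' @param exclusionNames exclusion features to apply; interval features
#'   must be built with [buildExclusionFeature()], and `"multiTarget"`
#'   refers to the derived cross-hybridization set.
#' @param joinMode `"intersection"` (default) or `"union"`.
#' @param projectDir output directory for the run.
#' @param strandPolicy,minOverlap,dialect matching and parsing options;
#'   see [matchIntervals()] and [readBed()].
#' @return a [CombineConfig].
#' @export
combineConfig <- function(closedPlatforms = list(),
                          openPlatforms = character(),
                          targetName, exclusionNames = character(),
                          joinMode = c("intersection", "union"),
                          projectDir,
                          strandPolicy = c("require", "ignore"),
                          minOverlap = 1L,
                          dialect = c("standard", "closed_end")) {
  if (length(openPlatforms) && is.null(names(openPlatforms)))
    names(openPlatforms) <- sub("\\.[^.]*$", "", basename(openPlatforms))
  new("CombineConfig", closedPlatforms = closedPlatforms,
      openPlatforms = openPlatforms, targetName = targetName,
      exclusionNames = exclusionNames, joinMode = match.arg(joinMode),
      projectDir = projectDir, strandPolicy = match.arg(strandPolicy),
      minOverlap = as.integer(minOverlap), dialect = match.arg(dialect))
}

#' Join per-platform summaries into one target-by-sample matrix
#'
#' Under `intersection` the output keeps superIDs present in every
#' summary; under `union` superIDs present in any, with `NA` where a
#' platform does not cover a superID. Columns are the concatenation of
#' all platforms' columns, prefixed `platformId:sample` to keep them
#' globally unique.
#'
#' @param summaries list of [PlatformSummary] objects.
#' @param mode `"intersection"` or `"union"`.
#' @return numeric matrix (superID rows, prefixed sample columns).
#' @export
joinPlatforms <- function(summaries, mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  stopifnot(length(summaries) >= 1L)
  rowsets <- lapply(summaries, superIDs)
  rows <- if (mode == "intersection") Reduce(intersect, rowsets)
          else Reduce(union, rowsets)
  rows <- sort(rows)
  if (length(rows) == 0L && mode == "intersection")
    stop("intersection join produced no common superIDs")
  cols <- lapply(summaries, function(s)
    paste0(platformId(s), ":", colnames(summaryValues(s))))
  allcols <- unlist(cols)
  if (anyDuplicated(allcols))
    stop("colliding column names after platform prefixing: ",
         paste(unique(allcols[duplicated(allcols)]), collapse = ", "))
  out <- matrix(NA_real_, length(rows), length(allcols),
                dimnames = list(rows, allcols))
  at <- 0L
  for (s in summaries) {
    v <- summaryValues(s)
    common <- intersect(rows, rownames(v))
    out[common, at + seq_len(ncol(v))] <- v[common, , drop = FALSE]
    at <- at + ncol(v)
  }
  out
}

#' Run the end-to-end combine pipeline
#'
#' For every platform: match tags to the target reference, annotate
#' (including the derived multiTarget feature), apply the selected
#' exclusions, and summarize (median polish of log2 intensities for
#' closed platforms, RPKM for open platforms). The per-platform
#' summaries are then joined into one target-by-sample matrix.
#'
#' Written into `projectDir`: `combinedExpression.txt` (TSV, first
#' column `targetID`), one `annotation_<platform>.txt` per platform,
#' `multiTarget_<platform>.txt` membership lists, per-platform summary
#' tables, and `statistics.txt`. Reruns on identical inputs reproduce
#' `combinedExpression.txt` byte-identically: there is no hidden
#' randomness anywhere in the pipeline.
#'
#' Open-platform RPKM uses as its per-million denominator the number of
#' distinct reads aligned in that platform's input, counted before
#' exclusion filtering (switchable with `rpkmPostExclusion`). Closed
#' values are written on log2 scale; RPKM is written untransformed.
#'
#' @param config a [CombineConfig].
#' @param rpkmPostExclusion count RPKM's denominator after exclusion
#'   filtering instead of before.
#' @param verbose print step-labeled progress messages.
#' @return invisibly, a list with elements `matrix` (the combined
#'   target-by-sample matrix) and `statistics` (per-platform
#'   data.frame: tags total / matched / excluded per feature /
#'   surviving, targets covered, elapsed seconds).
#' @export
runCombine <- function(config, rpkmPostExclusion = FALSE,
                       verbose = FALSE) {
  stopifnot(is(config, "CombineConfig"))
  t0 <- proc.time()[["elapsed"]]
  say <- function(...) if (verbose) message("[", ..., "]")
  if (!dir.exists(config@projectDir))
    dir.create(config@projectDir, recursive = TRUE)
  say("LOAD target ", config@targetName)
  target <- loadTarget(config@targetName)
  interval_feats <- lapply(setdiff(config@exclusionNames, "multiTarget"),
                           loadExclusionFeature)
  strandPolicy <- config@strandPolicy
  summaries <- list()
  stats <- list()

  process <- function(id, gr, kind, measurements = NULL) {
    say("MATCH/ANNOTATE platform ", id)
    ann <- annotateTags(gr, target, interval_feats,
                        strandPolicy = strandPolicy,
                        minOverlap = config@minOverlap)
    mt <- deriveMultiTarget(ann)
    writeTagAnnotation(ann, file.path(config@projectDir,
                                      paste0("annotation_", id, ".txt")))
    writeFeatureTags(mt, file.path(config@projectDir,
                                   paste0("multiTarget_", id, ".txt")))
    say("EXCLUDE [", paste(config@exclusionNames, collapse = ", "),
        "] on ", id)
    surv <- applyExclusions(ann, config@exclusionNames)
    tab <- annotationTable(ann)
    matched_ids <- tab$tag_id[lengths(tab$matchedFull) > 0L]
    say("SUMMARIZE platform ", id)
    if (kind == "closed") {
      summ <- summarizeClosed(measurements, ann, surv, platformId = id)
    } else {
      pairs <- data.frame(
        query_id = rep(tab$tag_id, lengths(tab$matchedFull)),
        subject_id = unlist(tab$matchedFull, use.names = FALSE),
        stringsAsFactors = FALSE)
      N <- if (rpkmPostExclusion) length(surv)
           else length(unique(names(gr)))
      summ <- summarizeOpenRpkm(pairs, surv, target, N, platformId = id)
    }
    writePlatformSummary(summ, file.path(config@projectDir,
                                         paste0("summary_", id, ".txt")))
    st <- data.frame(platform = id, kind = kind,
                     tags_total = length(unique(names(gr))),
                     tags_matched = length(matched_ids),
                     tags_surviving = length(surv),
                     targets_covered = length(superIDs(summ)),
                     stringsAsFactors = FALSE)
    for (f in config@exclusionNames) {
      hit <- tab[[paste0("hit.", f)]]
      st[[paste0("excluded_", f)]] <-
        sum(hit & tab$tag_id %in% matched_ids)
    }
    list(summary = summ, stats = st)
  }

  for (cp in config@closedPlatforms) {
    gr <- readBed(cp$bed, dialect = config@dialect)
    meas <- readMeasurementTable(cp$measurements)
    res <- process(cp$id, gr, "closed", meas)
    summaries[[length(summaries) + 1L]] <- res$summary
    stats[[length(stats) + 1L]] <- res$stats
  }
  for (i in seq_along(config@openPlatforms)) {
    id <- names(config@openPlatforms)[i]
    gr <- readBed(config@openPlatforms[i], dialect = config@dialect)
    res <- process(id, gr, "open")
    if (length(superIDs(res$summary)) == 0L)
      warning("platform ", id, " has no surviving tags and ",
              "contributes no rows")
    summaries[[length(summaries) + 1L]] <- res$summary
    stats[[length(stats) + 1L]] <- res$stats
  }
  say("JOIN (", config@joinMode, ")")
  combined <- joinPlatforms(summaries, mode = config@joinMode)
  writeMeasurementTable(combined,
                        file.path(config@projectDir,
                                  "combinedExpression.txt"))
  statdf <- do.call(rbind, stats)
  statdf$elapsed_seconds <- round(proc.time()[["elapsed"]] - t0, 3)
  utils::write.table(statdf,
                     file.path(config@projectDir, "statistics.txt"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say("DONE in ", statdf$elapsed_seconds[1], " s")
  invisible(list(matrix = combined, statistics = statdf))
}
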