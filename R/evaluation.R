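#' Gene coverage of a platform summary
#'
#' The number of distinct superIDs present in a summary divided by the
#' number of distinct superIDs in the reference — the fraction of the
#' transcriptome a platform still covers after filtering. Applying
#' exclusion features can only lower it.
#'
#' @param summary a [PlatformSummary] (or a combined matrix with superID
#'   rownames).
#' @param target a [TargetReference].
#' @return a proportion in `[0, 1]`.
#' @export
geneCoverage <- function(summary, target) {
  stopifnot(is(target, "TargetReference"))
  covered <- if (is(summary, "PlatformSummary")) superIDs(summary)
             else rownames(summary)
  length(unique(covered)) / length(superIDs(target))
}

#' Correspondence-at-the-top (CAT) curve
#'
#' Agreement between two ranked gene lists among their top entries: for
#' each list size `n`, the proportion `|top-n(a) intersect top-n(b)| /
#' n`. Identical rankings give 1 everywhere; rankings over disjoint
#' universes give 0.
#'
#' @param rankingA,rankingB character vectors of gene ids, best first,
#'   duplicate-free.
#' @param sizes list sizes `n`; defaults to 50 to 2000 by 50, truncated
#'   to the shorter ranking.
#' @return data.frame with columns `n` and `proportion`.
#' @export
catCurve <- function(rankingA, rankingB,
                     sizes = seq(50L, 2000L, by = 50L)) {
  if (anyDuplicated(rankingA) || anyDuplicated(rankingB))
    stop("rankings must be duplicate-free")
  maxn <- min(length(rankingA), length(rankingB))
  if (identical(sizes, seq(50L, 2000L, by = 50L)))
    sizes <- sizes[sizes <= maxn]
  if (any(sizes < 1L) || any(sizes > maxn))
    stop("sizes must be positive and no larger than the shorter ranking")
  prop <- vapply(sizes, function(n)
    length(intersect(rankingA[seq_len(n)], rankingB[seq_len(n)])) / n,
    0)
  data.frame(n = as.integer(sizes), proportion = prop)
}

.group_log2_means <- function(x, cols, scale, pseudocount) {
  v <- x[, cols, drop = FALSE]
  if (scale == "linear") v <- log2(v + pseudocount)
  rowMeans(v)
}

#' Rank genes by absolute log2 fold-change
#'
#' Per gene, log2 fold-change is `mean(group A) - mean(group B)` on
#' log2-scale values; for linear-scale values (open-platform RPKM) a
#' pseudocount is added before log2. Genes are ordered by decreasing
#' absolute fold-change, with ties broken by gene id so every ranking
#' is deterministic. Under a union join, genes with `NA` in either
#' group are dropped and the drop count reported in a message.
#'
#' @param combined numeric matrix with gene rownames (e.g. from
#'   [runCombine()]).
#' @param groupACols,groupBCols disjoint, non-empty column selections.
#' @param scale `"log2"` if the selected columns are already log2
#'   (closed platforms), `"linear"` to apply `log2(x + pseudocount)`
#'   (open-platform RPKM).
#' @param pseudocount added before log2 under `scale = "linear"`.
#' @return character vector of gene ids, strongest change first, with
#'   the fold-changes as its `log2fc` attribute.
#' @export
rankByFoldChange <- function(combined, groupACols, groupBCols,
                             scale = c("log2", "linear"),
                             pseudocount = 1) {
  scale <- match.arg(scale)
  .check_groups(combined, groupACols, groupBCols)
  cc <- stats::complete.cases(combined[, c(groupACols, groupBCols),
                                       drop = FALSE])
  if (any(!cc))
    message(sum(!cc), " gene(s) with NA in a group were dropped")
  x <- combined[cc, , drop = FALSE]
  fc <- .group_log2_means(x, groupACols, scale, pseudocount) -
    .group_log2_means(x, groupBCols, scale, pseudocount)
  ord <- order(-abs(fc), rownames(x))
  structure(rownames(x)[ord], log2fc = fc[ord])
}

#' Rank genes by FDR-adjusted q-value
#'
#' Per gene, a pooled-variance two-sample t statistic on log2 values,
#' p-values from the t distribution, Benjamini-Hochberg adjustment, and
#' ascending q-value order; ties are broken by decreasing absolute
#' fold-change, then gene id. Genes with zero within-group variance get
#' a small variance floor so the statistic stays finite (reported in a
#' message).
#'
#' @inheritParams rankByFoldChange
#' @param varFloor variance floor for degenerate genes.
#' @return character vector of gene ids, most significant first, with
#'   `qvalue` and `log2fc` attributes.
#' @export
rankByQvalue <- function(combined, groupACols, groupBCols,
                         scale = c("log2", "linear"), pseudocount = 1,
                         varFloor = 1e-8) {
  scale <- match.arg(scale)
  .check_groups(combined, groupACols, groupBCols)
  a <- combined[, groupACols, drop = FALSE]
  b <- combined[, groupBCols, drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L)
    stop("need at least 2 columns per group for a variance estimate")
  cc <- stats::complete.cases(cbind(a, b))
  if (any(!cc))
    message(sum(!cc), " gene(s) with NA in a group were dropped")
  a <- a[cc, , drop = FALSE]; b <- b[cc, , drop = FALSE]
  if (scale == "linear") {
    a <- log2(a + pseudocount); b <- log2(b + pseudocount)
  }
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  nfloor <- sum(sp2 < varFloor)
  if (nfloor)
    message(nfloor, " gene(s) hit the variance floor")
  sp2 <- pmax(sp2, varFloor)
  tstat <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * stats::pt(-abs(tstat), df = na + nb - 2)
  q <- stats::p.adjust(p, method = "BH")
  fc <- ma - mb
  ord <- order(q, -abs(fc), rownames(a))
  structure(rownames(a)[ord], qvalue = q[ord], log2fc = fc[ord])
}

#' Sample-by-sample correlation matrix
#'
#' Spearman rank correlation between the columns of a combined matrix,
#' to assess within- and cross-platform reproducibility. Constant
#' columns have no defined rank correlation and yield `NA` with a
#' warning.
#'
#' @param combined numeric matrix, at least 3 gene rows.
#' @param method currently `"spearman"`.
#' @param pairwiseComplete use pairwise-complete observations (for
#'   union-joined matrices with `NA`).
#' @return symmetric sample-by-sample matrix with unit diagonal.
#' @export
correlationMatrix <- function(combined, method = "spearman",
                              pairwiseComplete = FALSE) {
  method <- match.arg(method, "spearman")
  if (nrow(combined) < 3L) stop("need at least 3 genes")
  consts <- apply(combined, 2L, function(v)
    length(unique(v[!is.na(v)])) <= 1L)
  if (any(consts))
    warning("constant column(s): ",
            paste(colnames(combined)[consts], collapse = ", "),
            "; their correlations are NA")
  suppressWarnings(
    stats::cor(combined, method = "spearman",
               use = if (pairwiseComplete) "pairwise.complete.obs"
                     else "everything"))
}

.check_groups <- function(x, a, b) {
  cn <- colnames(x)
  a <- if (is.character(a)) a else cn[a]
  b <- if (is.character(b)) b else cn[b]
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must be non-empty")
  if (length(intersect(a, b)))
    stop("groups must be disjoint")
  if (!all(c(a, b) %in% cn))
    stop("unknown column(s): ",
         paste(setdiff(c(a, b), cn), collapse = ", "))
  invisible(NULL)
}
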