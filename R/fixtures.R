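#' Construct a fixture specification
#'
#' Defaults describe the package's reference study conditions: 100
#' non-overlapping multi-exon genes over 3 chromosomes, one closed
#' platform (8 probes per gene tiling the 3'-most exon, 3 + 3 samples,
#' log-normal intensities), 3 + 3 open platforms (~20,000 aligned
#' 25-bp reads each, negative-binomial per-gene counts, reads spread
#' across all exons), 10% of tags planted as cross-hybridizing
#' (multiTarget), 10% planted with SNP overlaps, and 10 genes with a
#' planted 2-fold-per-unit log2 group effect.
#'
#' @param seed integer seed fixing every random draw.
#' @param nGenes,exonsPerGene,chromCount genome shape.
#' @param nClosedSamplesPerGroup,nOpenSamplesPerGroup samples per group
#'   (groups are `A` and `B`, e.g. two tissues).
#' @param probesPerGene,readsPerSample platform depth.
#' @param fractionMultitargetTags,fractionSnpTags planted undesirable-
#'   tag fractions.
#' @param nDeGenes,deLog2Effect planted differential expression.
#' @param closedNoiseSd,readDispersion noise levels
#'   (`readDispersion = 0` gives Poisson counts).
#' @param platformEffectSd per-gene closed-platform tag-effect sd in
#'   log2 units (see [FixtureSpec]).
#' @param tissueEffectSd sd of the continuous per-gene group effect
#'   shared by both technologies (see [FixtureSpec]).
#' @return a [FixtureSpec].
#' @export
fixtureSpec <- function(seed = 1L, nGenes = 100L,
                        exonsPerGene = c(2L, 4L), chromCount = 3L,
                        nClosedSamplesPerGroup = 3L,
                        nOpenSamplesPerGroup = 3L,
                        probesPerGene = 8L, readsPerSample = 20000L,
                        fractionMultitargetTags = 0.1,
                        fractionSnpTags = 0.1,
                        nDeGenes = 10L, deLog2Effect = 2,
                        closedNoiseSd = 0.25, readDispersion = 0.2,
                        platformEffectSd = 1, tissueEffectSd = 1) {
  new("FixtureSpec", seed = as.integer(seed), nGenes = as.integer(nGenes),
      exonsPerGene = as.integer(exonsPerGene),
      chromCount = as.integer(chromCount),
      nClosedSamplesPerGroup = as.integer(nClosedSamplesPerGroup),
      nOpenSamplesPerGroup = as.integer(nOpenSamplesPerGroup),
      probesPerGene = as.integer(probesPerGene),
      readsPerSample = as.integer(readsPerSample),
      fractionMultitargetTags = fractionMultitargetTags,
      fractionSnpTags = fractionSnpTags, nDeGenes = as.integer(nDeGenes),
      deLog2Effect = deLog2Effect, closedNoiseSd = closedNoiseSd,
      readDispersion = readDispersion,
      platformEffectSd = platformEffectSd,
      tissueEffectSd = tissueEffectSd)
}

# Geometry constants of the toy genome. Exons are long enough to hold
# a full probe tiling; tags never span exon junctions (exon-spanning
# reads are out of scope for the matcher, so the generator never emits
# them).
.EXON_LEN <- 300L
.INTRON_LEN <- 200L
.GENE_GAP <- 1000L
.TAG_LEN <- 25L

#' Generate a synthetic cross-platform data set with planted truth
#'
#' Writes, under `dir`: `target.BED` (one line per exon,
#' `G###@E#` ids), `MA.BED` + `MA_samples.txt` (closed-platform probe
#' alignments and probe-by-sample intensities), one `NGS_<group><i>.BED`
#' per open sample, `snp.BED` (planted 1-bp SNP features), and a
#' `ground_truth/` directory with the planted differentially expressed
#' genes, per-platform multiTarget tags and per-platform SNP-overlap
#' tags.
#'
#' Planted contamination models the failure modes the exclusion
#' features target. A cross-hybridizing probe carries a second
#' alignment in a partner gene and its intensity measures the *sum* of
#' both genes' signal; a cross-hybridizing read aligns in both its
#' source gene and the partner, inflating the partner's count when
#' unfiltered. SNPs are fixed 1-bp genomic positions whose per-exon
#' density is calibrated so the expected fraction of tags overlapping
#' one equals `fractionSnpTags`; a probe overlapping a SNP hybridizes
#' unpredictably (its level is unrelated to its gene), while reads
#' overlapping a SNP are counted normally and are simply removable by
#' the `snp` filter. Genes are non-overlapping by construction, so
#' multiTarget status is exactly the planted set; SNP-overlap truth is
#' computed at generation time with an independent overlap oracle
#' (`GenomicRanges::findOverlaps`), never with the package's matcher.
#'
#' Same spec and seed reproduce every file byte-identically.
#'
#' @param spec a [FixtureSpec].
#' @param dir output directory (created if needed).
#' @return invisibly, a list: file paths (`target`, `closedBed`,
#'   `closedMeasurements`, `openBeds`, `snp`), sample grouping
#'   (`closedSamples`, `openSamples` with group attributes), and ground
#'   truth (`deGenes`, `multiTargetTags`, `snpTags` — the latter two
#'   data.frames with columns `platform`, `tag_id`).
#' @export
generateFixture <- function(spec, dir) {
  stopifnot(is(spec, "FixtureSpec"))
  validObject(spec)
  set.seed(spec@seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gt_dir <- file.path(dir, "ground_truth")
  if (!dir.exists(gt_dir)) dir.create(gt_dir)

  ng <- spec@nGenes
  gene_ids <- sprintf("G%03d", seq_len(ng))
  chrom <- paste0("chr", (seq_len(ng) - 1L) %% spec@chromCount + 1L)
  gstrand <- c("+", "-")[seq_len(ng) %% 2L + 1L]
  n_ex <- sample(seq(spec@exonsPerGene[1], spec@exonsPerGene[2]),
                 ng, replace = TRUE)

  # lay genes end to end per chromosome, 0-based exon coordinates
  exons <- vector("list", ng)
  cursor <- stats::setNames(rep(0L, spec@chromCount),
                            paste0("chr", seq_len(spec@chromCount)))
  for (g in seq_len(ng)) {
    k <- n_ex[g]
    starts <- cursor[chrom[g]] +
      (seq_len(k) - 1L) * (.EXON_LEN + .INTRON_LEN)
    exons[[g]] <- data.frame(start0 = starts, end0 = starts + .EXON_LEN)
    cursor[chrom[g]] <- starts[k] + .EXON_LEN + .GENE_GAP
  }

  target_gr <- GenomicRanges::GRanges(
    rep(chrom, n_ex),
    IRanges::IRanges(
      start = unlist(lapply(exons, `[[`, "start0")) + 1L,
      end = unlist(lapply(exons, `[[`, "end0"))),
    strand = rep(gstrand, n_ex))
  names(target_gr) <- unlist(lapply(seq_len(ng), function(g)
    paste0(gene_ids[g], "@E", seq_len(n_ex[g]))))
  target_path <- file.path(dir, "target.BED")
  writeBed(target_gr, target_path)

  gene_len <- n_ex * .EXON_LEN

  # expression program: baseline log2 means; widespread continuous
  # group (tissue) effects shared by both technologies, truncated at
  # half the spiked effect so the planted DE genes stay the extreme
  # tail; nDeGenes spiked genes with effect +/- deLog2Effect
  mu <- stats::runif(ng, 4, 10)
  de_genes <- if (spec@nDeGenes > 0L) sort(sample(gene_ids, spec@nDeGenes))
              else character()
  trunc_at <- spec@deLog2Effect / 2
  effect <- if (spec@tissueEffectSd > 0)
    stats::qnorm(stats::runif(ng,
                              stats::pnorm(-trunc_at, 0, spec@tissueEffectSd),
                              stats::pnorm(trunc_at, 0, spec@tissueEffectSd)),
                 0, spec@tissueEffectSd)
  else numeric(ng)
  is_de <- gene_ids %in% de_genes
  effect[is_de] <- spec@deLog2Effect *
    sample(c(-1, 1), sum(is_de), replace = TRUE)
  muA <- mu + effect
  muB <- mu
  partner <- vapply(seq_len(ng), function(g)
    sample(setdiff(seq_len(ng), g), 1L), 0L)
  # closed-platform tag effect: per-gene hybridization-efficiency bias,
  # shared by the gene's probes and constant across samples and groups
  tag_effect <- stats::rnorm(ng, 0, spec@platformEffectSd)

  # 3'-most exon per gene (left-most for reverse-strand genes)
  last_exon <- lapply(seq_len(ng), function(g) {
    ex <- exons[[g]]
    if (gstrand[g] == "+") ex[nrow(ex), ] else ex[1L, ]
  })

  ## ---- closed platform: probes tile the last exon -------------------
  np <- spec@probesPerGene
  probe_gene <- rep(seq_len(ng), each = np)
  probe_ids <- paste0("P_", gene_ids[probe_gene], "_",
                      rep(seq_len(np), times = ng))
  offsets <- round(seq(0, .EXON_LEN - .TAG_LEN, length.out = np))
  probe_start0 <- vapply(seq_along(probe_gene), function(i)
    last_exon[[probe_gene[i]]]$start0 +
      offsets[(i - 1L) %% np + 1L], 0)
  probe_gr <- GenomicRanges::GRanges(
    chrom[probe_gene],
    IRanges::IRanges(start = probe_start0 + 1L,
                     width = .TAG_LEN),
    strand = gstrand[probe_gene])
  names(probe_gr) <- probe_ids

  n_probes <- length(probe_ids)
  mt_probe_idx <- sort(sample(n_probes,
                              round(spec@fractionMultitargetTags *
                                      n_probes)))

  # planted SNPs: fixed 1-bp genomic positions, their per-exon density
  # calibrated so the expected fraction of 25-bp tags overlapping one
  # equals fractionSnpTags
  p_hit <- .TAG_LEN / (.EXON_LEN - .TAG_LEN + 1L)
  per_exon <- if (spec@fractionSnpTags <= 0) 0
              else log(1 - min(spec@fractionSnpTags, 0.99)) / log(1 - p_hit)
  snp_list <- list()
  for (g in seq_len(ng)) {
    ex <- exons[[g]]
    for (e in seq_len(nrow(ex))) {
      k <- floor(per_exon) +
        (stats::runif(1) < per_exon - floor(per_exon))
      if (k > 0) {
        pos0 <- ex$start0[e] + .TAG_LEN - 1L +
          sample.int(.EXON_LEN - 2L * (.TAG_LEN - 1L), k)
        snp_list[[length(snp_list) + 1L]] <-
          data.frame(chrom = chrom[g], pos0 = pos0)
      }
    }
  }
  snp_df0 <- if (length(snp_list))
    do.call(rbind, c(snp_list, list(make.row.names = FALSE)))
  snp_gr <- if (is.null(snp_df0))
    GenomicRanges::GRanges(character(),
                           IRanges::IRanges(integer(), integer()))
  else GenomicRanges::GRanges(
    snp_df0$chrom, IRanges::IRanges(start = snp_df0$pos0 + 1L,
                                    width = 1L), strand = "*")
  snp_gr <- unique(snp_gr)
  names(snp_gr) <- if (length(snp_gr)) paste0("snp", seq_along(snp_gr))
                   else character()

  # second alignments of cross-hybridizing probes, inside the partner
  # gene's last exon
  if (length(mt_probe_idx)) {
    pg <- partner[probe_gene[mt_probe_idx]]
    off2 <- floor(stats::runif(length(mt_probe_idx)) *
                    (.EXON_LEN - .TAG_LEN + 1L))
    xtra <- GenomicRanges::GRanges(
      chrom[pg],
      IRanges::IRanges(start = vapply(seq_along(pg), function(i)
        last_exon[[pg[i]]]$start0 + off2[i], 0) + 1L,
        width = .TAG_LEN),
      strand = gstrand[pg])
    names(xtra) <- probe_ids[mt_probe_idx]
    probe_aln <- c(probe_gr, xtra)
  } else {
    probe_aln <- probe_gr
  }
  closed_bed <- file.path(dir, "MA.BED")
  writeBed(probe_aln, closed_bed)
  snp_path <- file.path(dir, "snp.BED")
  writeBed(snp_gr, snp_path)

  # probes disrupted by a planted SNP (independent overlap oracle)
  snp_probe_idx <- sort(unique(S4Vectors::queryHits(
    GenomicRanges::findOverlaps(probe_gr, snp_gr,
                                ignore.strand = TRUE))))

  # intensities: normal probes follow their gene; cross-hybridizers
  # measure the sum of both genes; SNP probes hybridize unpredictably
  samplesA <- paste0("A", seq_len(spec@nClosedSamplesPerGroup))
  samplesB <- paste0("B", seq_len(spec@nClosedSamplesPerGroup))
  closed_samples <- c(samplesA, samplesB)
  base <- cbind(matrix(muA[probe_gene], n_probes, length(samplesA)),
                matrix(muB[probe_gene], n_probes, length(samplesB)))
  if (length(mt_probe_idx)) {
    pg <- partner[probe_gene[mt_probe_idx]]
    base[mt_probe_idx, ] <- cbind(
      matrix(log2(2^muA[probe_gene[mt_probe_idx]] + 2^muA[pg]),
             length(mt_probe_idx), length(samplesA)),
      matrix(log2(2^muB[probe_gene[mt_probe_idx]] + 2^muB[pg]),
             length(mt_probe_idx), length(samplesB)))
  }
  if (length(snp_probe_idx))
    base[snp_probe_idx, ] <- stats::runif(length(snp_probe_idx), 4, 10)
  base <- base + tag_effect[probe_gene]
  log2_int <- base + matrix(stats::rnorm(length(base), 0,
                                         spec@closedNoiseSd),
                            nrow = n_probes)
  intensities <- round(2^log2_int, 4)
  dimnames(intensities) <- list(probe_ids, closed_samples)
  closed_meas <- file.path(dir, "MA_samples.txt")
  writeMeasurementTable(intensities, closed_meas, idHeader = "probeID")

  ## ---- open platforms: one BED per sample ---------------------------
  open_samples <- c(paste0("NGS_A", seq_len(spec@nOpenSamplesPerGroup)),
                    paste0("NGS_B", seq_len(spec@nOpenSamplesPerGroup)))
  open_groups <- rep(c("A", "B"), each = spec@nOpenSamplesPerGroup)
  open_beds <- character(0)
  mt_truth <- list()
  snp_truth <- list()

  # flat lookup of exon starts so read placement is fully vectorized
  exon_start_flat <- unlist(lapply(exons, `[[`, "start0"))
  exon_idx0 <- cumsum(c(0L, n_ex[-ng]))

  draw_positions <- function(genes) {
    # one 25-bp alignment per entry, uniform over the gene's exons
    # (exons share one length, so exon choice is length-weighted)
    n <- length(genes)
    e <- 1L + as.integer(stats::runif(n) * n_ex[genes])
    s0 <- exon_start_flat[exon_idx0[genes] + e] +
      floor(stats::runif(n) * (.EXON_LEN - .TAG_LEN + 1L))
    GenomicRanges::GRanges(chrom[genes],
                           IRanges::IRanges(start = s0 + 1L,
                                            width = .TAG_LEN),
                           strand = gstrand[genes])
  }

  for (si in seq_along(open_samples)) {
    sname <- open_samples[si]
    m <- if (open_groups[si] == "A") muA else muB
    wgt <- 2^m * gene_len
    lambda <- spec@readsPerSample * wgt / sum(wgt)
    counts <- if (spec@readDispersion > 0)
      stats::rnbinom(ng, mu = lambda, size = 1 / spec@readDispersion)
    else stats::rpois(ng, lambda)
    src_gene <- rep(seq_len(ng), counts)
    n_reads <- length(src_gene)
    read_ids <- sprintf("R_%s_%06d", sname, seq_len(n_reads))
    mt_idx <- sort(sample(n_reads,
                          round(spec@fractionMultitargetTags * n_reads)))

    reads <- draw_positions(src_gene)
    names(reads) <- read_ids
    if (length(mt_idx)) {
      second <- draw_positions(partner[src_gene[mt_idx]])
      names(second) <- read_ids[mt_idx]
      aln <- c(reads, second)
    } else {
      aln <- reads
    }
    bed <- file.path(dir, paste0(sname, ".BED"))
    writeBed(aln, bed)
    open_beds[sname] <- bed
    mt_truth[[sname]] <- data.frame(
      platform = rep(sname, length(mt_idx)),
      tag_id = read_ids[mt_idx], stringsAsFactors = FALSE)
  }

  # ground truth: multiTarget from the planted construction (genes do
  # not overlap, so a tag is multiTarget iff its alignments were
  # planted in two distinct genes); SNP overlap via an independent
  # overlap oracle over the final SNP set
  mt_truth[["MA"]] <- data.frame(
    platform = rep("MA", length(mt_probe_idx)),
    tag_id = probe_ids[mt_probe_idx], stringsAsFactors = FALSE)
  mt_df <- do.call(rbind, c(mt_truth[c("MA", open_samples)],
                            list(make.row.names = FALSE)))

  oracle_snp <- function(tag_gr) {
    hits <- GenomicRanges::findOverlaps(tag_gr, snp_gr,
                                        ignore.strand = TRUE)
    sort(unique(names(tag_gr)[S4Vectors::queryHits(hits)]))
  }
  ma_snp <- oracle_snp(probe_aln)
  snp_truth_all <- list(data.frame(platform = rep("MA", length(ma_snp)),
                                   tag_id = ma_snp,
                                   stringsAsFactors = FALSE))
  for (sname in open_samples) {
    hits <- oracle_snp(readBed(open_beds[sname]))
    snp_truth_all[[sname]] <- data.frame(
      platform = rep(sname, length(hits)), tag_id = hits,
      stringsAsFactors = FALSE)
  }
  snp_df <- do.call(rbind, c(snp_truth_all, list(make.row.names = FALSE)))

  writeLines(de_genes, file.path(gt_dir, "de_genes.txt"))
  utils::write.table(mt_df, file.path(gt_dir, "multitarget_tags.txt"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(snp_df, file.path(gt_dir, "snp_tags.txt"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(
    target = target_path, closedBed = closed_bed,
    closedMeasurements = closed_meas, openBeds = open_beds,
    snp = snp_path, closedSamples = closed_samples,
    closedGroups = rep(c("A", "B"),
                       each = spec@nClosedSamplesPerGroup),
    openSamples = open_samples, openGroups = open_groups,
    geneIds = gene_ids, deGenes = de_genes,
    multiTargetTags = mt_df, snpTags = snp_df))
}
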