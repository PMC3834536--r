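#' Simulate the toy genome annotation and genomic-mark tracks
#'
#' Lays out protein-coding genes on a multi-chromosome toy assembly, places
#' every intronic antisense lncRNA wholly inside an intron of its host gene
#' (on the opposite strand), scatters lincRNAs over the genome, and builds
#' the genomic-mark tracks the TSS-proximity analysis consumes: CAGE-like
#' scored tags, CpG-island-like, promoter-prediction-like, Pol-II-like and
#' H3K4me3-like point marks, plus a broad H3K36me3-like track. For lncRNAs
#' in `truth$marked_tss`, each point track receives one mark whose distance
#' to the TSS is exponential with scale `mark_decay_bp`; background marks
#' are uniform over the genome. CAGE-like marks carry an RPKM score.
#'
#' Exclusion zones (1 kb upstream of each gene TSS plus a 200 bp 5'UTR
#' proxy) are returned for use when placing length-matched random controls.
#'
#' @param config a [sim_config()] object.
#' @param truth the `planted_truth` from [simulate_expression_study()].
#' @param study the matching `expression_study` (for the probe annotation).
#' @return an object of class `genomic_context`: a list with `seqlengths`,
#'   `genes`, `introns`, `lnc` (named GRanges of intronic antisense
#'   lncRNAs), `linc`, `tracks` (named list of GRanges; `cage` has an
#'   `rpkm` metadata column), and `exclusions`.
#' @export
simulate_genomic_context <- function(config, truth, study) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "planted_truth"),
            inherits(study, "expression_study"))
  set.seed(sub_seed(config$seed, 2L))

  chrom_len <- floor(config$genome_length_bp / config$n_chroms)
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  seqlens <- stats::setNames(rep(chrom_len, config$n_chroms), chroms)

  probes <- study$probes
  gene_ids <- probes$gene_id[probes$class == "protein_coding"]
  n_genes <- length(gene_ids)

  ## sequential gene layout, round-robin over chromosomes
  gene_chrom <- rep(chroms, length.out = n_genes)
  g_start <- g_end <- integer(n_genes)
  cursor <- stats::setNames(rep(10000L, config$n_chroms), chroms)
  lens <- sample(15000:40000, n_genes, replace = TRUE)
  gaps <- sample(5000:20000, n_genes, replace = TRUE)
  for (i in seq_len(n_genes)) {
    ch <- gene_chrom[i]
    g_start[i] <- cursor[ch]
    g_end[i] <- g_start[i] + lens[i] - 1L
    if (g_end[i] > chrom_len - 10000L)
      stopf("genome too small to place %d genes without overlap; increase genome_length_bp",
            n_genes)
    cursor[ch] <- g_end[i] + gaps[i]
  }
  gene_strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  genes <- GenomicRanges::GRanges(gene_chrom,
                                  IRanges::IRanges(g_start, g_end),
                                  strand = gene_strand,
                                  seqlengths = seqlens)
  names(genes) <- gene_ids

  ## one large internal intron per gene
  ioff1 <- round(0.2 * lens); ioff2 <- round(0.8 * lens)
  introns <- GenomicRanges::GRanges(gene_chrom,
                                    IRanges::IRanges(g_start + ioff1,
                                                     g_start + ioff2),
                                    strand = gene_strand,
                                    seqlengths = seqlens)
  names(introns) <- gene_ids

  ## intronic antisense lncRNAs inside the host intron, opposite strand
  as_ids <- probes$probe_id[probes$class == "intronic_antisense"]
  host <- probes$host_gene[match(as_ids, probes$probe_id)]
  hidx <- match(host, gene_ids)
  lnc_len <- sample(200:800, length(as_ids), replace = TRUE)
  int_start <- GenomicRanges::start(introns)[hidx]
  int_end <- GenomicRanges::end(introns)[hidx]
  max_off <- int_end - int_start - lnc_len + 1L
  if (any(max_off < 1))
    stopf("generation error: host intron too small for a lncRNA interval")
  l_start <- int_start + floor(stats::runif(length(as_ids)) * max_off)
  lnc <- GenomicRanges::GRanges(gene_chrom[hidx],
                                IRanges::IRanges(l_start, l_start + lnc_len - 1L),
                                strand = ifelse(gene_strand[hidx] == "+", "-", "+"),
                                seqlengths = seqlens)
  names(lnc) <- as_ids
  S4Vectors::mcols(lnc)$host_gene <- host

  ## lincRNAs scattered over the genome
  linc_ids <- probes$probe_id[probes$class == "lincRNA"]
  linc <- random_intervals(sample(300:1000, length(linc_ids), replace = TRUE),
                           seqlens, stranded = TRUE)
  names(linc) <- linc_ids

  ## mark tracks
  lnc_tss <- tss_of(lnc)
  marked <- names(lnc) %in% truth$marked_tss
  point_tracks <- list(cage = c(20L, 30L), cpg_island = c(200L, 1000L),
                       promoter_hmm = c(500L, 2000L), polii = c(100L, 300L),
                       h3k4me3 = c(500L, 1500L))
  tracks <- lapply(point_tracks, function(wr) {
    w_pl <- sample(wr[1]:wr[2], sum(marked), replace = TRUE)
    d <- stats::rexp(sum(marked), rate = 1 / config$mark_decay_bp)
    side <- sample(c(-1, 1), sum(marked), replace = TRUE)
    centre <- round(lnc_tss[marked] + side * d)
    st <- pmax(1L, centre - w_pl %/% 2L)
    planted <- GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(lnc))[marked],
      IRanges::IRanges(st, st + w_pl - 1L), seqlengths = seqlens)
    bg <- random_intervals(sample(wr[1]:wr[2], length(lnc), replace = TRUE),
                           seqlens)
    S4Vectors::mcols(planted)$planted <- rep(TRUE, length(planted))
    S4Vectors::mcols(bg)$planted <- rep(FALSE, length(bg))
    GenomicRanges::trim(c(planted, bg))
  })
  ## CAGE-like scores: planted tags well above the RPKM >= 1 filter,
  ## background tags mostly below it
  n_pl <- sum(S4Vectors::mcols(tracks$cage)$planted)
  S4Vectors::mcols(tracks$cage)$rpkm <-
    c(1 + stats::rexp(n_pl, 1 / 2),
      stats::rexp(length(tracks$cage) - n_pl, 1))

  ## broad H3K36me3-like marks over marked lncRNA bodies + background
  body_w <- sample(1000:5000, sum(marked), replace = TRUE)
  body_st <- pmax(1L, GenomicRanges::start(lnc)[marked] - body_w %/% 4L)
  broad <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(lnc))[marked],
    IRanges::IRanges(body_st, body_st + body_w - 1L), seqlengths = seqlens)
  tracks$h3k36me3 <- GenomicRanges::trim(
    c(broad, random_intervals(sample(1000:5000, length(lnc), replace = TRUE),
                              seqlens)))

  ## exclusion zones: 1 kb upstream of each gene TSS + 200 bp 5'UTR proxy
  tssg <- tss_of(genes)
  exc_start <- ifelse(gene_strand == "+", tssg - 1000L, tssg - 199L)
  exc_end <- ifelse(gene_strand == "+", tssg + 199L, tssg + 1000L)
  exclusions <- GenomicRanges::trim(GenomicRanges::GRanges(
    gene_chrom, IRanges::IRanges(pmax(1L, exc_start), exc_end),
    seqlengths = seqlens))

  structure(list(seqlengths = seqlens, genes = genes, introns = introns,
                 lnc = lnc, linc = linc, tracks = tracks,
                 exclusions = exclusions),
            class = "genomic_context")
}

# uniform random intervals of given lengths over the genome (no exclusions)
random_intervals <- function(lengths, seqlens, stranded = FALSE) {
  ch <- sample(names(seqlens), length(lengths), replace = TRUE,
               prob = seqlens / sum(seqlens))
  st <- floor(stats::runif(length(lengths)) * (seqlens[ch] - lengths)) + 1L
  GenomicRanges::GRanges(ch, IRanges::IRanges(st, st + lengths - 1L),
                         strand = if (stranded)
                           sample(c("+", "-"), length(lengths), replace = TRUE)
                         else "*",
                         seqlengths = seqlens)
}

#' @export
print.genomic_context <- function(x, ...) {
  cat("Synthetic genomic context\n")
  cat(sprintf("  genome: %d chromosomes, %.1f Mb total\n",
              length(x$seqlengths), sum(x$seqlengths) / 1e6))
  cat(sprintf("  %d genes | %d intronic antisense lncRNAs | %d lincRNAs\n",
              length(x$genes), length(x$lnc), length(x$linc)))
  cat(sprintf("  tracks: %s\n", paste(names(x$tracks), collapse = ", ")))
  invisible(x)
}
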