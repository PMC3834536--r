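#' Transcription start sites of stranded intervals
#'
#' The TSS of a plus-strand interval is its start coordinate; of a
#' minus-strand interval, its end. Unstranded intervals are an error.
#'
#' @param gr a `GRanges` with strand `+` or `-`.
#' @return named integer vector of TSS positions (1-based).
#' @export
tss_of <- function(gr) {
  std <- as.character(GenomicRanges::strand(gr))
  if (any(std == "*")) stopf("TSS undefined for unstranded intervals")
  pos <- ifelse(std == "+", GenomicRanges::start(gr), GenomicRanges::end(gr))
  stats::setNames(as.integer(pos), names(gr))
}

#' TSS positions as width-1 ranges
#'
#' @param gr a stranded `GRanges`.
#' @return a `GRanges` of width-1 intervals at the TSS of each input range.
#' @export
tss_granges <- function(gr) {
  pos <- tss_of(gr)
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                IRanges::IRanges(pos, pos),
                                strand = GenomicRanges::strand(gr),
                                seqlengths = GenomeInfoDb::seqlengths(gr))
  names(out) <- names(gr)
  out
}

#' Length-matched random control interval sets
#'
#' Draws `n_sets` sets of intervals matching the query length multiset,
#' placed uniformly over the genome outside the exclusion zones (the
#' regions near annotated gene starts that would otherwise leak known
#' promoter signal into the control).
#'
#' @param query_lengths integer vector of interval lengths (bp).
#' @param seqlengths named vector of chromosome lengths.
#' @param exclusions optional `GRanges` of zones controls must not touch.
#' @param n_sets number of control sets (default 10).
#' @param seed optional integer seed for reproducible placements.
#' @return list of `n_sets` unstranded `GRanges`.
#' @export
make_random_controls <- function(query_lengths, seqlengths, exclusions = NULL,
                                 n_sets = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genome <- GenomicRanges::GRanges(names(seqlengths),
                                   IRanges::IRanges(1L, unname(seqlengths)),
                                   seqlengths = seqlengths)
  allowed <- if (is.null(exclusions) || !length(exclusions)) genome else
    GenomicRanges::setdiff(genome, GenomicRanges::reduce(
      GenomicRanges::granges(exclusions), ignore.strand = TRUE),
      ignore.strand = TRUE)
  aw <- GenomicRanges::width(allowed)
  lapply(seq_len(n_sets), function(k) {
    st <- integer(length(query_lengths))
    ch <- character(length(query_lengths))
    for (i in seq_along(query_lengths)) {
      L <- query_lengths[i]
      ok <- which(aw >= L)
      if (!length(ok))
        stopf("placement failure: no gap outside the exclusion zones can hold a %d bp interval", L)
      slots <- aw[ok] - L + 1
      j <- ok[sample.int(length(ok), 1L, prob = slots)]
      st[i] <- GenomicRanges::start(allowed)[j] +
        floor(stats::runif(1) * (aw[j] - L + 1))
      ch[i] <- as.character(GenomicRanges::seqnames(allowed))[j]
    }
    GenomicRanges::GRanges(ch, IRanges::IRanges(st, st + query_lengths - 1L),
                           seqlengths = seqlengths)
  })
}

#' Distance from query positions to the nearest mark
#'
#' For each query (a TSS, as a width-1 range or any range whose start is
#' taken as the position), computes the unsigned genomic distance to the
#' nearest mark interval on the same chromosome (0 when the position falls
#' inside a mark; otherwise the distance to the nearest mark edge).
#' Queries with no mark within `max_dist` (or on a mark-free chromosome)
#' are excluded from the distribution and tallied separately. Distances
#' are also binned (`floor(d / bin)`, the last bin closed at `max_dist`)
#' for reporting.
#'
#' @param queries `GRanges` of query positions (e.g. from
#'   [tss_granges()]).
#' @param track `GRanges` of mark intervals; score-filtered upstream when
#'   applicable (e.g. CAGE-like tags at RPKM >= 1, see
#'   [filter_track_by_score()]).
#' @param max_dist maximum distance considered (default 10 kb).
#' @param bin histogram bin width (default 1 kb).
#' @return object of class `distance_distribution`: `distances` (named
#'   numeric, within `max_dist`), `histogram` (counts per bin),
#'   `bin_index` (0-based per retained query), `n_no_mark`, `max_dist`,
#'   `bin`.
#' @export
distance_distribution <- function(queries, track, max_dist = 10000,
                                  bin = 1000) {
  if (!length(track)) stopf("empty mark track")
  pos <- GenomicRanges::start(queries)
  track <- GenomicRanges::granges(track)
  ni <- suppressWarnings(GenomicRanges::nearest(
    queries, track, select = "arbitrary", ignore.strand = TRUE))
  d <- rep(NA_real_, length(queries))
  has <- !is.na(ni)
  if (any(has)) {
    s <- GenomicRanges::start(track)[ni[has]]
    e <- GenomicRanges::end(track)[ni[has]]
    p <- pos[has]
    d[has] <- ifelse(p >= s & p <= e, 0, pmin(abs(p - s), abs(p - e)))
  }
  keep <- !is.na(d) & d <= max_dist
  dist <- d[keep]
  names(dist) <- names(queries)[keep]
  nb <- ceiling(max_dist / bin)
  bin_index <- pmin(floor(dist / bin), nb - 1L)
  hist <- tabulate(bin_index + 1L, nbins = nb)
  names(hist) <- sprintf("[%g,%g)", bin * (seq_len(nb) - 1), bin * seq_len(nb))
  structure(list(distances = dist, histogram = hist, bin_index = bin_index,
                 n_no_mark = sum(!keep), max_dist = max_dist, bin = bin),
            class = "distance_distribution")
}

#' Drop track intervals below a score cutoff
#'
#' @param track `GRanges` with a numeric metadata column.
#' @param column metadata column name (e.g. `"rpkm"`).
#' @param min_score minimum retained score (inclusive; CAGE-like tags use
#'   RPKM >= 1).
#' @return the filtered `GRanges`.
#' @export
filter_track_by_score <- function(track, column = "rpkm", min_score = 1) {
  sc <- S4Vectors::mcols(track)[[column]]
  if (is.null(sc)) stopf("track has no '%s' score column", column)
  track[sc >= min_score]
}

#' Kolmogorov-Smirnov enrichment test against control distance sets
#'
#' Compares the query nearest-mark distance distribution with each control
#' distribution by the two-sample KS test (D = the supremum ECDF
#' difference, asymptotic p). Enrichment is claimed only when every
#' control rejects at `alpha`, so the summary reports the maximum p across
#' controls.
#'
#' @param query_dist a [distance_distribution()] (or numeric distances).
#' @param control_dists list of [distance_distribution()] objects (or
#'   numeric vectors), one per control set.
#' @param alpha per-control rejection level (default 0.05).
#' @return list of class `ks_enrichment`: `per_control` data frame
#'   (`control`, `D`, `p`), `max_p`, `all_reject`.
#' @export
ks_enrichment_test <- function(query_dist, control_dists, alpha = 0.05) {
  get_d <- function(x) if (inherits(x, "distance_distribution")) x$distances else x
  q <- get_d(query_dist)
  if (!length(q)) stopf("empty query distance distribution")
  per <- lapply(seq_along(control_dists), function(i) {
    cc <- get_d(control_dists[[i]])
    if (!length(cc)) stopf("empty control distance distribution (set %d)", i)
    kt <- suppressWarnings(stats::ks.test(q, cc))
    data.frame(control = i, D = unname(kt$statistic),
               p = kt$p.value)
  })
  per <- do.call(rbind, per)
  structure(list(per_control = per, max_p = max(per$p),
                 all_reject = all(per$p < alpha), alpha = alpha),
            class = "ks_enrichment")
}

#' @export
print.ks_enrichment <- function(x, ...) {
  cat(sprintf("KS enrichment vs %d control set(s): max p = %.3g (%s at alpha = %g)\n",
              nrow(x$per_control), x$max_p,
              if (x$all_reject) "all reject" else "not all reject", x$alpha))
  invisible(x)
}

#' Count mark intervals overlapping each query
#'
#' Overlap requires at least 1 bp of shared genomic extent (half-open
#' interval semantics when coordinates come from BED: a mark starting
#' where the query ends does not count).
#'
#' @param queries,track `GRanges` in a shared coordinate convention.
#' @return named integer vector of per-query overlap counts.
#' @export
overlap_count <- function(queries, track) {
  n <- GenomicRanges::countOverlaps(queries, track, minoverlap = 1L,
                                    ignore.strand = TRUE)
  stats::setNames(as.integer(n), names(queries))
}

#' Read / write BED intervals
#'
#' Thin wrappers over `rtracklayer` that keep the package's internal
#' 1-based closed `GRanges` convention while exchanging 0-based half-open
#' BED on disk. The BED score column (column 5) is exposed as a `score`
#' metadata column.
#'
#' @param path file path.
#' @param gr a `GRanges` to write.
#' @return `read_bed` returns a `GRanges`; `write_bed` the path,
#'   invisibly.
#' @export
read_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stopf("BED I/O needs the rtracklayer package")
  rtracklayer::import(path, format = "BED")
}

#' @rdname read_bed
#' @export
write_bed <- function(gr, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stopf("BED I/O needs the rtracklayer package")
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
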