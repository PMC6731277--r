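#' Construct a coverage track
#'
#' Per-base read coverage in RPM (reads per million mapped) for one
#' dataset, stored as one numeric vector per chromosome, together with the
#' dataset's FRiP (fraction of reads in peaks). FRiP is the per-dataset
#' scale anchor for cross-experiment rescaling: experiments with weaker
#' enrichment (lower FRiP) are scaled up to the strongest one.
#'
#' @param id Dataset identifier.
#' @param coverage Named list of non-negative numeric vectors (one per
#'   chromosome), position i = 0-based coordinate i - 1.
#' @param frip FRiP value in (0, 1\].
#' @return Object of class `coverage_track`.
#' @export
coverage_track <- function(id, coverage, frip) {
  if (!is.list(coverage) || is.null(names(coverage))) {
    stop("coverage must be a named list of per-chromosome vectors")
  }
  if (any(vapply(coverage, function(v) any(v < 0), logical(1)))) {
    stop("coverage must be non-negative")
  }
  if (length(frip) != 1L || is.na(frip) || frip <= 0 || frip > 1) {
    stop("frip must be a single value in (0, 1]")
  }
  structure(list(id = id, coverage = coverage, frip = frip),
            class = "coverage_track")
}

#' Fraction of reads in peaks (FRiP)
#'
#' Peaks are merged (overlapping/adjacent intervals unioned) before
#' counting; a read is "in peaks" when it shares at least one base with a
#' merged peak. An empty peak set gives FRiP 0.
#'
#' @param reads Data frame of read intervals (`chrom`, `start`, `end`;
#'   0-based half-open).
#' @param peaks Data frame of peak intervals, same convention.
#' @return Fraction in \[0, 1\].
#' @export
compute_frip <- function(reads, peaks) {
  if (nrow(reads) == 0L) stop("need at least one read")
  if (is.null(peaks) || nrow(peaks) == 0L) return(0)
  gr_reads <- intervals_to_granges(reads)
  gr_peaks <- GenomicRanges::reduce(intervals_to_granges(peaks),
                                    ignore.strand = TRUE)
  mean(IRanges::overlapsAny(gr_reads, gr_peaks, ignore.strand = TRUE))
}

#' Rescale coverage tracks by FRiP ratios
#'
#' Makes tracks comparable across experiments of different ChIP strength:
#' each track's coverage is multiplied by `max(FRiP) / FRiP_D`, so the
#' track with the highest FRiP is unchanged and weaker tracks are scaled
#' up. All scale factors are >= 1.
#'
#' @param tracks List of [coverage_track] objects.
#' @return List of rescaled [coverage_track] objects (same order); each
#'   carries its factor in attribute `"scale_factor"`.
#' @export
rescale_coverage <- function(tracks) {
  stopifnot(length(tracks) >= 1L,
            all(vapply(tracks, inherits, logical(1), "coverage_track")))
  frips <- vapply(tracks, `[[`, numeric(1), "frip")
  if (any(frips <= 0)) stop("all FRiP values must be > 0")
  fmax <- max(frips)
  lapply(tracks, function(tr) {
    f <- fmax / tr$frip
    out <- coverage_track(tr$id, lapply(tr$coverage, `*`, f), tr$frip)
    attr(out, "scale_factor") <- f
    out
  })
}

#' Read a bedGraph file into a coverage track
#'
#' Interval values are expanded to per-base vectors. The coverage is
#' assumed to already be in RPM; if `total_reads` is given, raw per-base
#' read counts are converted to RPM as `count * 1e6 / total_reads`.
#'
#' @param path bedGraph path.
#' @param id Dataset id, default the file name.
#' @param frip FRiP value to attach.
#' @param total_reads Optional total mapped read count for RPM conversion.
#' @return A [coverage_track].
#' @export
read_bedgraph_track <- function(path, id = basename(path), frip,
                                total_reads = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  cov <- list()
  for (chrom in unique(as.character(GenomicRanges::seqnames(gr)))) {
    sub <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
    len <- max(GenomicRanges::end(sub))
    v <- numeric(len)
    for (i in seq_along(sub)) {
      v[GenomicRanges::start(sub)[i]:GenomicRanges::end(sub)[i]] <-
        sub$score[i]
    }
    cov[[chrom]] <- v
  }
  if (!is.null(total_reads)) {
    cov <- lapply(cov, function(v) v * 1e6 / total_reads)
  }
  coverage_track(id, cov, frip)
}

#' Write a coverage track to bedGraph
#'
#' Runs of equal coverage are collapsed into intervals; zero-coverage runs
#' are omitted.
#'
#' @param track A [coverage_track].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph_track <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  rows <- list()
  for (chrom in names(track$coverage)) {
    v <- track$coverage[[chrom]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths    # 0-based
    keep <- r$values != 0
    if (any(keep)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = starts[keep], end = ends[keep],
        score = r$values[keep], stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               score = numeric())
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
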