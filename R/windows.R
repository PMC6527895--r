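# Window-based SNP density scan and candidate barcode region selection.
#
# The alignment is tiled into fixed non-overlapping windows ("bins") from
# column 0; a trailing partial window keeps its true length. Candidate
# windows must exceed a variability threshold and stay under a masked-data
# threshold; adjacent candidates merge into regions which can be refined
# with smaller sub-windows.

#' Tile an alignment into windows and count SNPs
#'
#' @param aln a `cb_aln` object.
#' @param window_size window width in columns (bp); default 500.
#' @param summary optional precomputed [classify_columns()] table.
#' @return data.frame (class `cb_windows`), one row per window: `start`,
#'   `end` (0-based half-open), `snp_count` (variable columns inside),
#'   `variability` (`snp_count / width`), `masked_fraction` (fraction of
#'   sample-by-column cells that are `N` or `-`).
#' @export
scan_windows <- function(aln, window_size = 500L, summary = NULL) {
  if (window_size < 1L) stop("domain error: window_size must be >= 1")
  if (is.null(summary)) summary <- classify_columns(aln)
  L <- ncol(aln)
  n <- nrow(aln)
  starts <- seq.int(0L, L - 1L, by = window_size)
  ends <- pmin(starts + window_size, L)
  cum_var <- cumsum(c(0L, summary$variable))
  cum_mis <- cumsum(c(0, summary$missing))
  snp <- cum_var[ends + 1L] - cum_var[starts + 1L]
  masked <- cum_mis[ends + 1L] - cum_mis[starts + 1L]
  width <- ends - starts
  out <- data.frame(
    start = starts, end = ends, snp_count = as.integer(snp),
    variability = snp / width,
    masked_fraction = masked / (n * width)
  )
  class(out) <- c("cb_windows", "data.frame")
  attr(out, "aln_name") <- aln_name(aln)
  out
}

#' Select candidate barcode windows
#'
#' Keeps windows whose variability is strictly greater than
#' `min_variability` and whose masked fraction is strictly below
#' `max_masked`. Both inequalities are strict: a 500-bp window with exactly
#' 25 SNPs (5\%) is rejected.
#'
#' @param windows a [scan_windows()] table.
#' @param min_variability minimum SNP fraction per window (default 0.05).
#' @param max_masked maximum fraction of masked cells (default 0.03).
#' @return the selected subset, same columns.
#' @export
select_candidates <- function(windows, min_variability = 0.05, max_masked = 0.03) {
  stopifnot(min_variability >= 0, min_variability <= 1,
            max_masked >= 0, max_masked <= 1)
  keep <- windows$variability > min_variability &
    windows$masked_fraction < max_masked
  out <- windows[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a barcode region
#'
#' @param name region label.
#' @param start,end 0-based half-open column interval, `end > start`.
#' @param source provenance: one of `window-merge`, `refined`,
#'   `user-supplied`.
#' @return one-row data.frame of class `cb_regions`.
#' @export
barcode_region <- function(name, start, end, source = "user-supplied") {
  stopifnot(end > start, start >= 0)
  out <- data.frame(name = name, start = as.integer(start),
                    end = as.integer(end), source = source)
  class(out) <- c("cb_regions", "data.frame")
  out
}

#' Merge adjacent candidate windows into barcode regions
#'
#' Maximal runs of windows that abut (the end of one is the start of the
#' next) become a single region, so two neighbouring 500-bp windows form a
#' 1000-bp barcode and four form a 2000-bp barcode; isolated windows become
#' regions of their own width. Names are generated from 1-based inclusive
#' coordinates.
#'
#' @param selected a [select_candidates()] table (sorted by `start`).
#' @return data.frame of class `cb_regions`: `name`, `start`, `end`,
#'   `source = "window-merge"`.
#' @export
merge_candidates <- function(selected) {
  if (nrow(selected) == 0) {
    out <- data.frame(name = character(), start = integer(),
                      end = integer(), source = character())
    class(out) <- c("cb_regions", "data.frame")
    return(out)
  }
  selected <- selected[order(selected$start), , drop = FALSE]
  run <- cumsum(c(1L, selected$start[-1L] != selected$end[-nrow(selected)]))
  starts <- tapply(selected$start, run, min)
  ends <- tapply(selected$end, run, max)
  out <- data.frame(
    name = sprintf("bar_%d_%d", starts + 1L, ends),
    start = as.integer(starts), end = as.integer(ends),
    source = "window-merge"
  )
  rownames(out) <- NULL
  class(out) <- c("cb_regions", "data.frame")
  out
}

#' Refine a barcode region with sub-windows
#'
#' Tiles the region into `subwindow`-bp sub-windows, computes per-sub-window
#' variability, and keeps the longest run of consecutive sub-windows whose
#' variability is at least `min_sub_variability`; leading and trailing
#' low-variability sub-windows are thereby trimmed. If no sub-window reaches
#' the threshold the single most variable sub-window is returned with a
#' warning.
#'
#' @param aln a `cb_aln` object.
#' @param region a one-row region (from [barcode_region()] or a row of a
#'   `cb_regions` table).
#' @param subwindow sub-window width (default 50 bp).
#' @param min_sub_variability variability threshold (default 0.02).
#' @return one-row `cb_regions` data.frame with `source = "refined"`.
#' @export
refine_region <- function(aln, region, subwindow = 50L, min_sub_variability = 0.02) {
  start <- region$start
  end <- region$end
  if (start < 0 || end > ncol(aln) || end <= start)
    stop("interval error: region outside alignment")
  if (subwindow > end - start)
    stop("domain error: subwindow larger than region")
  summary <- classify_columns(extract_region(aln, region))
  starts <- seq.int(0L, end - start - 1L, by = subwindow)
  ends <- pmin(starts + subwindow, end - start)
  cum_var <- cumsum(c(0L, summary$variable))
  variability <- (cum_var[ends + 1L] - cum_var[starts + 1L]) / (ends - starts)
  ok <- variability >= min_sub_variability
  if (!any(ok)) {
    warning("no sub-window reaches variability ", min_sub_variability,
            "; returning the single best sub-window")
    best <- which.max(variability)
    keep <- c(best, best)
  } else {
    r <- rle(ok)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    true_runs <- which(r$values)
    best <- true_runs[which.max(r$lengths[true_runs])]
    keep <- c(run_start[best], run_end[best])
  }
  barcode_region(
    name = region$name,
    start = start + starts[keep[1L]],
    end = start + ends[keep[2L]],
    source = "refined"
  )
}

#' Write regions as BED
#'
#' 0-based half-open intervals; columns chrom (the alignment name), start,
#' end, name, score. The score column carries the SNP count when an
#' alignment is supplied, else 0.
#'
#' @param regions a `cb_regions` table.
#' @param path output BED path.
#' @param aln optional alignment used to compute per-region SNP counts.
#' @param chrom chromosome/alignment label.
#' @export
write_bed <- function(regions, path, aln = NULL, chrom = NULL) {
  if (is.null(chrom))
    chrom <- if (is.null(aln)) "alignment" else aln_name(aln)
  score <- rep(0L, nrow(regions))
  if (!is.null(aln) && nrow(regions) > 0) {
    summary <- classify_columns(aln)
    cum_var <- cumsum(c(0L, summary$variable))
    score <- as.integer(cum_var[regions$end + 1L] - cum_var[regions$start + 1L])
  }
  if (nrow(regions) == 0) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end),
    name = regions$name, score = score
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read regions from BED
#'
#' @param path BED file (0-based half-open on disk).
#' @return `cb_regions` data.frame with `source = "user-supplied"`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- if (!is.null(gr$name)) gr$name else
    sprintf("bar_%d_%d", GenomicRanges::start(gr), GenomicRanges::end(gr))
  out <- data.frame(
    name = nm,
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    source = "user-supplied"
  )
  class(out) <- c("cb_regions", "data.frame")
  out
}

#' Write the window density table
#'
#' TSV with header `start_0based, end, snp_count, variability,
#' masked_fraction` — a plain-text substitute for a circular density plot.
#'
#' @param windows a [scan_windows()] table.
#' @param path output TSV path.
#' @export
write_density <- function(windows, path) {
  out <- data.frame(
    start_0based = windows$start, end = windows$end,
    snp_count = windows$snp_count,
    variability = windows$variability,
    masked_fraction = windows$masked_fraction
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
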