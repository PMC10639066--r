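#' Strand-specific single-nucleotide coverage track
#'
#' A `coverage_track` holds, for each strand, per-chromosome run-length
#' encoded vectors of 3'-end counts of engaged polymerase (one count per
#' genomic nucleotide). All coordinates exposed to users are 0-based,
#' half-open, matching BED/bedGraph conventions.
#'
#' @param plus,minus named lists (chromosome -> [S4Vectors::Rle]) of
#'   non-negative per-nucleotide counts.
#' @param sample sample label.
#' @param normalized logical; `TRUE` when values are depth-scaled floats
#'   rather than raw integer counts.
#' @return an object of class `coverage_track`.
#' @export
coverage_track <- function(plus = list(), minus = list(), sample = "",
                           normalized = FALSE) {
  for (str in list(plus, minus)) {
    for (rle in str) {
      if (!methods::is(rle, "Rle"))
        stop("coverage must be supplied as S4Vectors::Rle per chromosome")
      if (any(S4Vectors::runValue(rle) < 0))
        stop("coverage counts must be non-negative")
    }
  }
  structure(list(plus = plus, minus = minus, sample = sample,
                 normalized = normalized),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track>", if (nzchar(x$sample)) paste0(" sample: ", x$sample),
      "\n", sep = "")
  for (s in c("plus", "minus")) {
    chroms <- names(x[[s]])
    tot <- sum(vapply(x[[s]], function(r) sum(as.numeric(S4Vectors::runValue(r)) *
                                              S4Vectors::runLength(r)), 0))
    cat(sprintf("  %s strand: %d chromosome(s), total signal %.6g\n",
                if (s == "plus") "+" else "-", length(chroms), tot))
  }
  if (x$normalized) cat("  values are normalized (float)\n")
  invisible(x)
}

.strand_slot <- function(strand) {
  if (identical(strand, "+")) "plus"
  else if (identical(strand, "-")) "minus"
  else stop("strand must be '+' or '-'")
}

#' Total signal of a coverage track
#'
#' @param track a [coverage_track()].
#' @param strand optional; restrict to "+" or "-".
#' @return total summed counts.
#' @export
total_signal <- function(track, strand = NULL) {
  slots <- if (is.null(strand)) c("plus", "minus") else .strand_slot(strand)
  sum(vapply(slots, function(s) {
    sum(vapply(track[[s]], function(r)
      sum(as.numeric(S4Vectors::runValue(r)) * S4Vectors::runLength(r)), 0))
  }, 0))
}

# Build an Rle of length `len` from 0-based positions and counts.
.positions_to_rle <- function(pos, counts = NULL, len) {
  if (length(pos) == 0L) return(S4Vectors::Rle(0L, len))
  if (is.null(counts)) {            # positions may repeat; tally them
    pos <- sort(pos)
    r <- rle(pos)
    pos <- r$values; counts <- r$lengths
  } else {
    o <- order(pos); pos <- pos[o]; counts <- counts[o]
    if (anyDuplicated(pos)) {
      counts <- as.vector(tapply(counts, pos, sum))
      pos <- sort(unique(pos))
    }
  }
  if (pos[1L] < 0L || pos[length(pos)] >= len)
    stop("positions fall outside chromosome bounds")
  # interleave zero gaps with single-position runs
  gap_before <- c(pos[1L], diff(pos) - 1L)
  vals <- rbind(0, counts)
  lens <- rbind(gap_before, 1L)
  tail_gap <- len - (pos[length(pos)] + 1L)
  v <- c(as.vector(vals), 0)
  l <- c(as.vector(lens), tail_gap)
  keep <- l > 0L
  S4Vectors::Rle(v[keep], l[keep])
}

#' Build a coverage track from read positions
#'
#' @param chrom chromosome name (single chromosome).
#' @param pos_plus,pos_minus integer vectors of 0-based 3'-end positions
#'   (repeats allowed; they accumulate).
#' @param chrom_length chromosome length in nucleotides.
#' @inheritParams coverage_track
#' @return a [coverage_track()].
#' @export
track_from_positions <- function(chrom, pos_plus = integer(),
                                 pos_minus = integer(), chrom_length,
                                 sample = "") {
  plus <- stats::setNames(list(.positions_to_rle(pos_plus, len = chrom_length)),
                          chrom)
  minus <- stats::setNames(list(.positions_to_rle(pos_minus, len = chrom_length)),
                           chrom)
  coverage_track(plus = plus, minus = minus, sample = sample)
}

# Extract [start, end) (0-based half-open) from a per-chromosome Rle,
# zero-padding outside the stored bounds.
.window_rle <- function(rle, start, end) {
  n <- end - start
  if (is.null(rle) || n <= 0L) return(numeric(max(n, 0L)))
  len <- length(rle)
  lo <- max(start, 0L); hi <- min(end, len)
  out <- numeric(n)
  if (hi > lo)
    out[(lo - start + 1L):(hi - start)] <-
      as.numeric(S4Vectors::window(rle, lo + 1L, hi))
  out
}

#' Sum signal in a genomic window
#'
#' Counts are summed on the requested strand only, within the 0-based
#' half-open interval `[start, end)`. Regions with no stored signal (or an
#' empty interval) give 0.
#'
#' @param track a [coverage_track()].
#' @param chrom chromosome name.
#' @param start,end 0-based half-open bounds.
#' @param strand "+" or "-".
#' @return numeric count.
#' @export
count_window <- function(track, chrom, start, end, strand) {
  rle <- track[[.strand_slot(strand)]][[chrom]]
  if (is.null(rle) || end <= start) return(0)
  len <- length(rle)
  lo <- max(start, 0L); hi <- min(end, len)
  if (hi <= lo) return(0)
  sum(as.numeric(S4Vectors::window(rle, lo + 1L, hi)))
}

# Vectorised window sums for many intervals on one chromosome/strand.
.count_windows_vec <- function(track, chrom, starts, ends, strand) {
  rle <- track[[.strand_slot(strand)]][[chrom]]
  n <- length(starts)
  if (is.null(rle) || n == 0L) return(numeric(n))
  len <- length(rle)
  lo <- pmax(starts, 0L); hi <- pmin(ends, len)
  ok <- hi > lo
  out <- numeric(n)
  if (any(ok)) {
    v <- IRanges::Views(rle, start = lo[ok] + 1L, end = hi[ok])
    out[ok] <- IRanges::viewSums(v)
  }
  out
}

#' Extract per-nucleotide signal for a window
#'
#' @inheritParams count_window
#' @return numeric vector of length `end - start` (zero-padded outside
#'   chromosome bounds).
#' @export
window_vector <- function(track, chrom, start, end, strand) {
  .window_rle(track[[.strand_slot(strand)]][[chrom]], start, end)
}

#' Scale a coverage track
#'
#' Divides all counts by `factor` (e.g. a median-of-ratios size factor);
#' the result is flagged as normalized.
#'
#' @param track a [coverage_track()].
#' @param factor positive scalar divisor.
#' @return a normalized [coverage_track()].
#' @export
scale_track <- function(track, factor) {
  stopifnot(is.numeric(factor), length(factor) == 1L, factor > 0)
  for (s in c("plus", "minus"))
    track[[s]] <- lapply(track[[s]], function(r) r / factor)
  track$normalized <- TRUE
  track
}
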