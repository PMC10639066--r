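#' Read a BED6 gene annotation
#'
#' Coordinates are 0-based half-open. By convention the transcription start
#' site (TSS) of a plus-strand gene is `start` and its cleavage and
#' polyadenylation site (CPS) is `end - 1`; on the minus strand the two are
#' mirrored (TSS = `end - 1`, CPS = `start`).
#'
#' @param path path to a 6-column tab-separated BED file.
#' @return a data.frame with columns `chrom`, `start`, `end`, `gene_id`,
#'   `score`, `strand`, `gene_name`, `length`.
#' @export
read_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      gene_id = character(), score = numeric(),
                      strand = character(), gene_name = character(),
                      length = integer(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields))
    if (length(fields[[i]]) < 6L)
      stop(sprintf("line %d: expected 6 tab-separated BED columns", i))
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  strand <- m[, 6L]
  for (i in seq_along(lines)) {
    if (is.na(start[i]) || is.na(end[i]))
      stop(sprintf("line %d: non-integer coordinates", i))
    if (start[i] < 0L || start[i] >= end[i])
      stop(sprintf("line %d: requires 0 <= start < end", i))
    if (!strand[i] %in% c("+", "-"))
      stop(sprintf("line %d: strand must be '+' or '-', got '%s'",
                   i, strand[i]))
  }
  ids <- m[, 4L]
  dup <- which(duplicated(ids))
  if (length(dup))
    stop(sprintf("line %d: duplicate gene_id '%s'", dup[1L], ids[dup[1L]]))
  data.frame(chrom = m[, 1L], start = start, end = end, gene_id = ids,
             score = suppressWarnings(as.numeric(m[, 5L])), strand = strand,
             gene_name = ids, length = end - start, stringsAsFactors = FALSE)
}

#' Write genes as BED6
#'
#' @param genes a gene table as returned by [read_genes()].
#' @param path output path.
#' @export
write_genes <- function(genes, path) {
  score <- if ("score" %in% names(genes)) genes$score else 0
  score[is.na(score)] <- 0
  out <- sprintf("%s\t%d\t%d\t%s\t%g\t%s", genes$chrom, genes$start,
                 genes$end, genes$gene_id, score, genes$strand)
  writeLines(out, path)
  invisible(path)
}

#' TSS and CPS anchor positions
#'
#' 0-based genomic positions of the transcription start site and the
#' cleavage/polyadenylation site under the strand convention of
#' [read_genes()].
#'
#' @param genes a gene table.
#' @return integer vector, one position per gene.
#' @export
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1L)
}

#' @rdname gene_tss
#' @export
gene_cps <- function(genes) {
  ifelse(genes$strand == "+", genes$end - 1L, genes$start)
}

#' Read a bedGraph coverage file for one strand
#'
#' Intervals are 0-based half-open and must not overlap; an interval with
#' value v over `[a, b)` expands to a per-nucleotide count of v at every
#' position in the interval. Non-integer values flag the track as
#' normalized.
#'
#' @param path bedGraph path.
#' @param strand "+" or "-"; the strand this file carries.
#' @param sample sample label.
#' @param chrom_lengths optional named vector of chromosome lengths; when
#'   omitted each chromosome is sized to its last covered position.
#' @return a [coverage_track()] with signal on the requested strand.
#' @export
read_bedgraph <- function(path, strand, sample = "", chrom_lengths = NULL) {
  slot <- .strand_slot(strand)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  per_chrom <- list()
  if (length(lines)) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    for (i in seq_along(fields))
      if (length(fields[[i]]) < 4L)
        stop(sprintf("line %d: expected 4 bedGraph columns", i))
    m <- do.call(rbind, fields)
    chrom <- m[, 1L]
    start <- as.integer(m[, 2L]); end <- as.integer(m[, 3L])
    value <- as.numeric(m[, 4L])
    if (anyNA(start) || anyNA(end) || anyNA(value))
      stop("bedGraph contains non-numeric coordinates or values")
    if (any(value < 0))
      stop(sprintf("line %d: negative value", which(value < 0)[1L]))
    if (any(start < 0L | start >= end))
      stop(sprintf("line %d: requires 0 <= start < end",
                   which(start < 0L | start >= end)[1L]))
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      o <- idx[order(start[idx])]
      if (any(start[o][-1L] < end[o][-length(o)]))
        stop(sprintf("overlapping intervals on %s", ch))
      len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
        as.integer(chrom_lengths[[ch]]) else max(end[o])
      if (max(end[o]) > len)
        stop(sprintf("interval beyond declared length of %s", ch))
      s <- start[o]; e <- end[o]; v <- value[o]
      gap_before <- s - c(0L, e[-length(e)])
      runs_v <- as.vector(rbind(0, v))
      runs_l <- as.vector(rbind(gap_before, e - s))
      runs_v <- c(runs_v, 0); runs_l <- c(runs_l, len - e[length(e)])
      keep2 <- runs_l > 0L
      per_chrom[[ch]] <- S4Vectors::Rle(runs_v[keep2], runs_l[keep2])
    }
  }
  normalized <- length(lines) > 0 &&
    any(abs(as.numeric(m[, 4L]) - round(as.numeric(m[, 4L]))) > 1e-9)
  args <- list(sample = sample, normalized = normalized)
  args[[slot]] <- per_chrom
  do.call(coverage_track, args)
}

#' Write one strand of a coverage track as bedGraph
#'
#' Adjacent positions with equal counts merge into one interval; zero runs
#' are omitted.
#'
#' @param track a [coverage_track()].
#' @param path output path.
#' @param strand "+" or "-".
#' @export
write_bedgraph <- function(track, path, strand) {
  slot <- .strand_slot(strand)
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track[[slot]])) {
    rle <- track[[slot]][[ch]]
    v <- S4Vectors::runValue(rle); l <- S4Vectors::runLength(rle)
    ends <- cumsum(as.numeric(l)); starts <- ends - l
    keep <- v != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%s", ch, as.integer(starts[keep]),
                         as.integer(ends[keep]),
                         format(v[keep], trim = TRUE, scientific = FALSE)),
                 con)
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Each line holds a set name, a description, then member genes. Duplicate
#' members within a set are dropped (first occurrence kept).
#'
#' @param path GMT path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("line %d: GMT lines need >= 3 tab-separated fields", i))
    sets[[f[1L]]] <- unique(f[-(1:2)])
  }
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), ""), path)
  invisible(path)
}

#' Read a RNK ranked-score file
#'
#' Two tab-separated columns: gene and score. Duplicate genes are an error.
#'
#' @param path RNK path.
#' @return data.frame with columns `gene`, `score`.
#' @export
read_rnk <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("gene", "score"),
                         colClasses = c("character", "numeric"))
  dup <- which(duplicated(d$gene))
  if (length(dup))
    stop(sprintf("duplicate gene '%s' in RNK file", d$gene[dup[1L]]))
  d
}

#' Write a RNK ranked-score file
#'
#' @param scores named numeric vector or data.frame with `gene`, `score`.
#' @param path output path.
#' @export
write_rnk <- function(scores, path) {
  if (is.data.frame(scores)) {
    gene <- scores$gene; score <- scores$score
  } else {
    gene <- names(scores); score <- unname(scores)
  }
  writeLines(sprintf("%s\t%s", gene, format(score, trim = TRUE)), path)
  invisible(path)
}

#' Read / write a count matrix TSV
#'
#' Rows are genes, columns samples; the first column holds gene ids.
#'
#' @param path TSV path.
#' @return integer/numeric matrix with gene-id rownames.
#' @export
read_counts <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  if (any(m < 0)) stop("count matrix has negative cells")
  if (anyNA(m)) stop("count matrix has missing cells")
  m
}

#' @rdname read_counts
#' @param counts matrix with gene-id rownames.
#' @export
write_counts <- function(counts, path) {
  d <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
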