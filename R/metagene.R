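#' Average engaged-polymerase metagene profile
#'
#' Builds three panels in transcription orientation: mean density per
#' 10-nt bin from -1000 to +1000 nt around the TSS (200 bins), a gene body
#' scaled into 50 bins of 1/50 of the body length each, and 10-nt bins from
#' -1000 to +2000 nt around the CPS (300 bins). Minus-strand genes are
#' reversed so that their contribution equals that of the equivalent
#' plus-strand gene. The profile is the unweighted mean across genes; with
#' several tracks (e.g. replicates) per-track profiles are averaged.
#'
#' @param tracks a [coverage_track()] or a named list of them.
#' @param genes gene table as from [read_genes()].
#' @param sf optional named size factors (one per track); per-nucleotide
#'   densities are divided by them before averaging.
#' @param min_len minimum gene length (default 3000 nt, so the TSS and CPS
#'   panels do not swallow the body).
#' @return object of class `metagene_profile`: numeric vectors `tss` (200),
#'   `body` (50), `cps` (300), named by the bin start offset or body
#'   fraction, plus `n_genes`.
#' @export
metagene_profile <- function(tracks, genes, sf = NULL, min_len = 3000) {
  if (inherits(tracks, "coverage_track")) tracks <- list(track = tracks)
  genes <- genes[genes$length >= min_len, , drop = FALSE]
  if (!nrow(genes)) stop("no genes of length >= min_len")
  tss <- gene_tss(genes)
  cps <- gene_cps(genes)
  profiles <- lapply(seq_along(tracks), function(ti) {
    track <- tracks[[ti]]
    f <- if (!is.null(sf)) sf[[names(tracks)[ti]]] else 1
    acc_tss <- numeric(200); acc_body <- numeric(50); acc_cps <- numeric(300)
    for (g in seq_len(nrow(genes))) {
      ch <- genes$chrom[g]; str <- genes$strand[g]; L <- genes$length[g]
      # per-nt sense vector over transcription coords [lo, hi)
      sense_vec <- function(lo, hi) {
        if (str == "+") window_vector(track, ch, tss[g] + lo, tss[g] + hi, "+")
        else rev(window_vector(track, ch, tss[g] - hi + 1L, tss[g] - lo + 1L,
                               "-"))
      }
      v_tss <- sense_vec(-1000L, 1000L)
      acc_tss <- acc_tss + colMeans(matrix(v_tss, nrow = 10L)) / f
      v_body <- sense_vec(0L, L)
      cuts <- floor(seq_len(50) * L / 50)
      starts <- c(0, cuts[-50])
      acc_body <- acc_body +
        vapply(seq_len(50), function(k)
          mean(v_body[(starts[k] + 1L):cuts[k]]), 0) / f
      d_cps <- if (str == "+") cps[g] - tss[g] else tss[g] - cps[g]
      v_cps <- sense_vec(d_cps - 1000L, d_cps + 2000L)
      acc_cps <- acc_cps + colMeans(matrix(v_cps, nrow = 10L)) / f
    }
    list(tss = acc_tss / nrow(genes), body = acc_body / nrow(genes),
         cps = acc_cps / nrow(genes))
  })
  avg <- function(part) Reduce(`+`, lapply(profiles, `[[`, part)) /
    length(profiles)
  structure(list(
    tss = stats::setNames(avg("tss"), seq(-1000L, 990L, by = 10L)),
    body = stats::setNames(avg("body"), seq_len(50)),
    cps = stats::setNames(avg("cps"), seq(-1000L, 1990L, by = 10L)),
    n_genes = nrow(genes)),
    class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf(
    "<metagene_profile> %d genes; mean TSS-panel density %.4g, mean body-bin density %.4g\n",
    x$n_genes, mean(x$tss), mean(x$body)))
  invisible(x)
}

#' Plot a metagene profile
#'
#' Draws the TSS panel, the scaled body and the CPS panel side by side on a
#' shared density axis.
#'
#' @param x a `metagene_profile`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.metagene_profile <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(as.integer(names(x$tss)), x$tss, type = "l",
                 xlab = "nt from TSS", ylab = "mean density (reads/nt)",
                 main = "TSS", ...)
  graphics::plot(seq_len(50), x$body, type = "l",
                 xlab = "gene body (50 bins)", ylab = "", main = "body", ...)
  graphics::plot(as.integer(names(x$cps)), x$cps, type = "l",
                 xlab = "nt from CPS", ylab = "", main = "CPS", ...)
  invisible(x)
}
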