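#' Promoter-proximal and gene-body quantification windows
#'
#' For every gene the promoter-proximal window spans -250 to +250 nt around
#' the TSS (500 nt) and the gene-body window +250 nt from the TSS to
#' -500 nt from the cleavage/polyadenylation site, both in transcription
#' coordinates. Genomic intervals are 0-based half-open; minus-strand genes
#' get the mirror image. Genes of length <= 750 nt have no valid body
#' window and are flagged unquantifiable rather than raising an error.
#'
#' @param genes a gene table as from [read_genes()].
#' @return data.frame with `gene_id`, `chrom`, `strand`,
#'   `promoter_start/end`, `body_start/end`, `body_length`, `quantifiable`,
#'   `reason`.
#' @export
define_windows <- function(genes) {
  n <- nrow(genes)
  tss <- gene_tss(genes)
  plus <- genes$strand == "+"
  prom_start <- ifelse(plus, tss - 250L, tss - 249L)
  prom_end <- prom_start + 500L
  body_start <- ifelse(plus, genes$start + 250L, genes$start + 500L)
  body_end <- ifelse(plus, genes$end - 500L, genes$end - 250L)
  quantifiable <- genes$length > 750L
  reason <- ifelse(quantifiable, "",
                   sprintf("gene length %d <= 750 nt", genes$length))
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             strand = genes$strand,
             promoter_start = as.integer(prom_start),
             promoter_end = as.integer(prom_end),
             body_start = as.integer(body_start),
             body_end = as.integer(body_end),
             body_length = as.integer(genes$length - 750L),
             quantifiable = quantifiable, reason = reason,
             stringsAsFactors = FALSE)
}

#' Count strand-matched signal in promoter or body windows
#'
#' @param track a [coverage_track()].
#' @param windows output of [define_windows()].
#' @param region `"promoter"` or `"body"`.
#' @return numeric vector of counts, one per window row (`NA` for
#'   unquantifiable genes).
#' @export
count_windows <- function(track, windows, region = c("promoter", "body")) {
  region <- match.arg(region)
  s_col <- paste0(region, "_start"); e_col <- paste0(region, "_end")
  out <- rep(NA_real_, nrow(windows))
  for (ch in unique(windows$chrom)) {
    for (str in c("+", "-")) {
      idx <- which(windows$chrom == ch & windows$strand == str &
                     windows$quantifiable)
      if (length(idx))
        out[idx] <- .count_windows_vec(track, ch, windows[[s_col]][idx],
                                       windows[[e_col]][idx], str)
    }
  }
  out
}

#' Promoter and body count matrices for a set of samples
#'
#' @param tracks named list of [coverage_track()] (names become columns).
#' @param windows output of [define_windows()].
#' @return list with `promoter` and `body` gene x sample matrices
#'   (unquantifiable genes dropped) and the retained `windows`.
#' @export
count_matrices <- function(tracks, windows) {
  keep <- windows$quantifiable
  w <- windows[keep, , drop = FALSE]
  mk <- function(region) {
    m <- vapply(tracks, function(tr) count_windows(tr, w, region),
                numeric(nrow(w)))
    m <- matrix(m, nrow = nrow(w),
                dimnames = list(w$gene_id, names(tracks)))
    m
  }
  list(promoter = mk("promoter"), body = mk("body"), windows = w)
}

#' Identify actively transcribed genes by promoter signal
#'
#' A documented threshold rule standing in for initiation-site detection:
#' a gene is active iff its promoter counts summed over the control
#' (vehicle) replicates reach `min_total` and its body window is at least
#' `min_body_len` long.
#'
#' @param promoter_counts gene x sample promoter count matrix.
#' @param design named character vector mapping sample -> condition.
#' @param control control condition label.
#' @param min_total minimum summed promoter count (default 20).
#' @param min_body_len minimum body-window length in nt (default 500).
#' @param body_length named vector of body lengths per gene (optional; if
#'   omitted only the count rule applies).
#' @return character vector of active gene ids.
#' @export
identify_active_genes <- function(promoter_counts, design, control,
                                  min_total = 20, min_body_len = 500,
                                  body_length = NULL) {
  ctrl_samples <- names(design)[design == control]
  ctrl_samples <- intersect(ctrl_samples, colnames(promoter_counts))
  if (!length(ctrl_samples)) stop("no control samples in promoter matrix")
  tot <- rowSums(promoter_counts[, ctrl_samples, drop = FALSE])
  active <- tot >= min_total
  if (!is.null(body_length)) {
    bl <- body_length[rownames(promoter_counts)]
    active <- active & !is.na(bl) & bl >= min_body_len
  }
  rownames(promoter_counts)[active]
}

#' Pausing index
#'
#' Pol II density in the promoter-proximal window divided by Pol II density
#' across the gene body. With `pseudocount = 0` the raw density ratio is
#' returned and is invariant to rescaling both counts by a common factor;
#' genes whose body count (plus pseudocount) is zero give `NA`.
#'
#' @param promoter_count,body_count window counts (vectorised).
#' @param promoter_len,body_len window lengths (nt, > 0).
#' @param pseudocount reads added to both windows before forming densities
#'   (default 0).
#' @return numeric vector of pausing indices (`NA` where undefined).
#' @export
pausing_index <- function(promoter_count, promoter_len, body_count, body_len,
                          pseudocount = 0) {
  stopifnot(all(promoter_len > 0), all(body_len > 0), pseudocount >= 0)
  num <- (promoter_count + pseudocount) / promoter_len
  den <- (body_count + pseudocount) / body_len
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Treatment-induced change in pausing index
#'
#' `delta_pi(a, b) = a - b`: PI under treatment minus PI of the
#' time-matched vehicle control. Antisymmetric in its arguments; `NA`
#' whenever either PI is undefined.
#'
#' @param pi_treatment,pi_control pausing indices.
#' @return numeric vector of PI differences.
#' @export
delta_pi <- function(pi_treatment, pi_control) pi_treatment - pi_control

#' Per-gene pausing records across conditions
#'
#' Builds, for every gene, per-condition promoter/body counts (summed over
#' replicates), densities, pausing indices, and the PI change for each
#' requested (treatment, control) contrast.
#'
#' @param counts output of [count_matrices()].
#' @param design named character vector sample -> condition.
#' @param contrasts list of `c(treatment, control)` label pairs.
#' @param pseudocount pseudocount forwarded to [pausing_index()]
#'   (default 0.5).
#' @param genes optional restriction to these gene ids.
#' @return data.frame with one row per gene: `pi_<condition>` and
#'   `dpi_<treatment>_vs_<control>` columns.
#' @export
pausing_records <- function(counts, design, contrasts = list(),
                            pseudocount = 0.5, genes = NULL) {
  w <- counts$windows
  if (is.null(genes)) genes <- w$gene_id
  keep <- w$gene_id %in% genes
  w <- w[keep, , drop = FALSE]
  prom <- counts$promoter[keep, , drop = FALSE]
  body <- counts$body[keep, , drop = FALSE]
  conds <- unique(design[colnames(prom)])
  out <- data.frame(gene_id = w$gene_id, body_length = w$body_length,
                    stringsAsFactors = FALSE)
  for (cn in conds) {
    cols <- colnames(prom)[design[colnames(prom)] == cn]
    p <- rowSums(prom[, cols, drop = FALSE])
    b <- rowSums(body[, cols, drop = FALSE])
    out[[paste0("promoter_", cn)]] <- p
    out[[paste0("body_", cn)]] <- b
    out[[paste0("promoter_density_", cn)]] <- p / 500
    out[[paste0("body_density_", cn)]] <- b / w$body_length
    out[[paste0("pi_", cn)]] <- pausing_index(p, 500, b, w$body_length,
                                              pseudocount)
  }
  for (ct in contrasts) {
    tcol <- paste0("pi_", ct[[1L]]); ccol <- paste0("pi_", ct[[2L]])
    if (!tcol %in% names(out) || !ccol %in% names(out))
      stop(sprintf("contrast (%s vs %s) names an unknown condition",
                   ct[[1L]], ct[[2L]]))
    out[[sprintf("dpi_%s_vs_%s", ct[[1L]], ct[[2L]])]] <-
      delta_pi(out[[tcol]], out[[ccol]])
  }
  out
}
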