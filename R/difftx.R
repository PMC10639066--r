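#' Median-of-ratios size factors
#'
#' For every sample, the size factor is the median over reference genes of
#' the ratio between the sample's count and the gene's geometric mean count
#' across samples. Reference genes are those with nonzero counts in every
#' sample.
#'
#' @param counts gene x sample count matrix (>= 2 samples).
#' @param pseudocount optional count added to every cell before computing
#'   ratios (default 0); a nonzero value rescues matrices with no
#'   all-nonzero gene.
#' @return named positive numeric vector of size factors.
#' @export
size_factors <- function(counts, pseudocount = 0) {
  if (ncol(counts) < 2L) stop("size factors need >= 2 samples")
  k <- counts + pseudocount
  logk <- log(k)
  ref <- rowMeans(logk)
  keep <- is.finite(ref)
  if (!any(keep))
    stop(paste("no gene has nonzero counts in all samples;",
               "consider the pseudocount option"))
  sf <- apply(logk[keep, , drop = FALSE], 2L, function(col)
    exp(stats::median(col - ref[keep])))
  stats::setNames(sf, colnames(counts))
}

# Gene-wise method-of-moments NB dispersion plus a fitted 1/mu trend.
.dispersion_estimates <- function(q, group) {
  groups <- unique(group)
  n_tot <- 0; ss <- 0
  mu <- rowMeans(q)
  for (g in groups) {
    cols <- which(group == g)
    if (length(cols) >= 2L) {
      mg <- rowMeans(q[, cols, drop = FALSE])
      ss <- ss + rowSums((q[, cols, drop = FALSE] - mg)^2)
      n_tot <- n_tot + (length(cols) - 1L)
    }
  }
  if (n_tot == 0L)
    return(list(mom = rep(NA_real_, nrow(q)), trend = c(a0 = 0.1, a1 = 1),
                mu = mu))
  s2 <- ss / n_tot
  mom <- (s2 - mu) / mu^2
  mom[!is.finite(mom)] <- 0
  ok <- mu > 1
  if (sum(ok) >= 10L) {
    fit <- stats::lm.fit(cbind(1, 1 / mu[ok]), pmax(mom[ok], 0))
    a0 <- max(fit$coefficients[1L], 0)
    a1 <- max(fit$coefficients[2L], 0)
  } else {
    a0 <- max(mean(pmax(mom, 0), na.rm = TRUE), 1e-8); a1 <- 0
  }
  list(mom = mom, trend = c(a0 = a0, a1 = a1), mu = mu)
}

#' Negative-binomial Wald test for differential transcription
#'
#' A deliberately simple two-group NB model: counts are scaled by
#' median-of-ratios size factors; the log2 fold-change is the log2 ratio of
#' group means of normalized counts (pseudocount 0.5); its standard error
#' comes from the NB Fisher information `Var(log mu-hat) = (1/n)(1/mu +
#' alpha)`; the Wald statistic is referred to the standard normal,
#' two-sided. Gene-wise dispersions can be the fitted mean-dispersion trend
#' `a0 + a1/mu` (default), the per-gene method-of-moments estimate, or the
#' elementwise maximum of the two; all are clamped to `[1e-8, 10]`.
#'
#' @param counts gene x sample count matrix.
#' @param design named character vector sample -> condition.
#' @param treatment,control condition labels to contrast
#'   (log2FC = treatment / control).
#' @param sf optional precomputed size factors; otherwise computed from
#'   `counts`.
#' @param dispersion_mode `"trend"` (default), `"max"` or `"mom"`. With a
#'   single replicate per group only `"trend"` is valid.
#' @param pseudocount added to group means before the log-ratio
#'   (default 0.5).
#' @return data.frame of class `nb_diff`: `gene_id`, `baseMean`, `log2FC`,
#'   `se`, `stat`, `p`, `dispersion`, `allzero`.
#' @export
nb_wald_test <- function(counts, design, treatment, control, sf = NULL,
                         dispersion_mode = c("trend", "max", "mom"),
                         pseudocount = 0.5) {
  dispersion_mode <- match.arg(dispersion_mode)
  cols_t <- names(design)[design == treatment]
  cols_c <- names(design)[design == control]
  cols_t <- intersect(cols_t, colnames(counts))
  cols_c <- intersect(cols_c, colnames(counts))
  if (!length(cols_t) || !length(cols_c))
    stop("treatment and control must each have samples in the matrix")
  sub <- counts[, c(cols_c, cols_t), drop = FALSE]
  if (is.null(sf)) sf <- size_factors(sub)
  sf <- sf[colnames(sub)]
  q <- sweep(sub, 2L, sf, "/")
  nT <- length(cols_t); nC <- length(cols_c)
  if (nT < 2L && nC < 2L && dispersion_mode != "trend")
    stop("1-vs-1 designs support dispersion_mode = 'trend' only")
  group <- c(rep("C", nC), rep("T", nT))
  muT <- rowMeans(q[, group == "T", drop = FALSE])
  muC <- rowMeans(q[, group == "C", drop = FALSE])
  est <- .dispersion_estimates(q, group)
  trend_val <- est$trend["a0"] + est$trend["a1"] / pmax(est$mu, 0.5)
  disp <- switch(dispersion_mode,
                 trend = trend_val,
                 mom = ifelse(is.na(est$mom), trend_val, est$mom),
                 max = pmax(ifelse(is.na(est$mom), 0, est$mom), trend_val))
  disp <- pmin(pmax(disp, 1e-8), 10)
  log2fc <- log2((muT + pseudocount) / (muC + pseudocount))
  se <- sqrt((1 / nT) * (1 / (muT + pseudocount) + disp) +
               (1 / nC) * (1 / (muC + pseudocount) + disp)) / log(2)
  stat <- log2fc / se
  p <- 2 * stats::pnorm(-abs(stat))
  allzero <- rowSums(sub) == 0
  log2fc[allzero] <- 0; stat[allzero] <- 0; p[allzero] <- 1
  out <- data.frame(gene_id = rownames(sub),
                    baseMean = rowMeans(q), log2FC = log2fc, se = se,
                    stat = stat, p = p, dispersion = disp,
                    allzero = allzero, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "contrast") <- c(treatment = treatment, control = control)
  attr(out, "size_factors") <- sf
  class(out) <- c("nb_diff", "data.frame")
  out
}

#' @export
print.nb_diff <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat(sprintf("<nb_diff> %d genes, %s vs %s\n", nrow(x),
              ct[["treatment"]], ct[["control"]]))
  NextMethod()
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: sorted p-values are scaled by n/rank and a
#' running minimum from the largest rank downward enforces monotonicity.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

#' Classify differentially transcribed genes (engaged Pol II)
#'
#' Thresholds for gene-body engaged-polymerase counts: UP iff adjusted
#' p <= 0.05 and fold-change >= 1.25; DOWN iff adjusted p <= 0.05 and
#' fold-change <= 0.8; otherwise NS. Boundaries are inclusive.
#'
#' @param log2fc log2 fold-changes.
#' @param padj BH-adjusted p-values.
#' @return character vector in `{"UP", "DOWN", "NS"}`.
#' @export
classify_dtg <- function(log2fc, padj) {
  ifelse(padj <= 0.05 & log2fc >= log2(1.25), "UP",
         ifelse(padj <= 0.05 & log2fc <= log2(0.8), "DOWN", "NS"))
}

#' Classify differentially expressed genes (RNA abundance)
#'
#' UP iff adjusted p <= 0.001 and log2 fold-change >= 1; DOWN iff adjusted
#' p <= 0.001 and log2 fold-change <= -1; otherwise NS.
#'
#' @inheritParams classify_dtg
#' @return character vector in `{"UP", "DOWN", "NS"}`.
#' @export
classify_deg <- function(log2fc, padj) {
  ifelse(padj <= 0.001 & log2fc >= 1, "UP",
         ifelse(padj <= 0.001 & log2fc <= -1, "DOWN", "NS"))
}

#' One-call differential-transcription analysis
#'
#' Runs [nb_wald_test()], BH adjustment and the requested classification
#' rule.
#'
#' @inheritParams nb_wald_test
#' @param rule `"dtg"` (engaged Pol II thresholds), `"deg"` (RNA
#'   thresholds) or `"none"`.
#' @return an `nb_diff` data.frame with added `padj` and `class` columns.
#' @export
diff_transcription <- function(counts, design, treatment, control,
                               sf = NULL,
                               dispersion_mode = c("trend", "max", "mom"),
                               rule = c("dtg", "deg", "none"),
                               pseudocount = 0.5) {
  rule <- match.arg(rule)
  res <- nb_wald_test(counts, design, treatment, control, sf = sf,
                      dispersion_mode = dispersion_mode,
                      pseudocount = pseudocount)
  res$padj <- bh_adjust(res$p)
  res$class <- switch(rule,
                      dtg = classify_dtg(res$log2FC, res$padj),
                      deg = classify_deg(res$log2FC, res$padj),
                      none = rep(NA_character_, nrow(res)))
  res
}

#' MA table
#'
#' One row per gene: mean log2 normalized gene-body counts on x, log2
#' fold-change on y, plus the class label when present.
#'
#' @param res an `nb_diff` result (with or without `class`).
#' @return data.frame with `gene_id`, `a` (x-axis), `m` (y-axis), `class`.
#' @export
ma_table <- function(res) {
  data.frame(gene_id = res$gene_id, a = log2(res$baseMean), m = res$log2FC,
             class = if ("class" %in% names(res)) res$class
                     else NA_character_,
             stringsAsFactors = FALSE)
}

#' Boxplot summary of gene lengths by class
#'
#' Quartiles by linear interpolation (quantile type 7); whiskers reach the
#' most extreme observations within 1.5 inter-quartile ranges of the box;
#' points beyond that are listed as outliers. Empty classes are dropped.
#'
#' @param lengths numeric vector of gene lengths (nt).
#' @param class character vector of class labels, same length.
#' @return data.frame with one row per class: `class`, `n`, `q1`, `median`,
#'   `q3`, `whisker_low`, `whisker_high`, and an `outliers` list-column.
#' @export
length_summary <- function(lengths, class) {
  stopifnot(length(lengths) == length(class))
  keep <- !is.na(lengths) & !is.na(class)
  lengths <- lengths[keep]; class <- class[keep]
  classes <- unique(class)
  rows <- lapply(classes, function(cl) {
    x <- lengths[class == cl]
    if (!length(x)) return(NULL)
    qs <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- qs[3L] - qs[1L]
    lo_fence <- qs[1L] - 1.5 * iqr; hi_fence <- qs[3L] + 1.5 * iqr
    inside <- x >= lo_fence & x <= hi_fence
    data.frame(class = cl, n = length(x), q1 = qs[1L], median = qs[2L],
               q3 = qs[3L], whisker_low = min(x[inside]),
               whisker_high = max(x[inside]),
               outliers = I(list(sort(x[!inside]))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
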