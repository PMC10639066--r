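#' Build a ranked gene list
#'
#' Orders genes by decreasing score, breaking ties lexicographically by
#' gene id so the ranking is reproducible. Duplicate gene ids are an
#' error.
#'
#' @param scores numeric scores (e.g. log2 fold-changes), named by gene, or
#'   a data.frame with columns `gene` and `score` (as from [read_rnk()]).
#' @return data.frame of class `ranked_list` with columns `gene`, `score`,
#'   in ranking order.
#' @export
ranked_list <- function(scores) {
  if (is.data.frame(scores)) {
    gene <- scores$gene; score <- scores$score
  } else {
    gene <- names(scores); score <- unname(scores)
  }
  if (is.null(gene) || anyNA(gene)) stop("scores must be named by gene")
  if (anyDuplicated(gene)) stop("duplicate genes in ranked list")
  o <- order(-score, gene)
  out <- data.frame(gene = gene[o], score = score[o],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  out
}

# Core running-sum statistic on hit indicator + scores.
.es_stat <- function(score, is_hit, weight_p, return_running = FALSE) {
  N <- length(score); Nh <- sum(is_hit)
  w <- abs(score[is_hit])^weight_p
  if (sum(w) == 0) w <- rep(1, Nh)           # all-zero hit scores: flat weights
  step <- numeric(N)
  step[is_hit] <- w / sum(w)
  step[!is_hit] <- -1 / (N - Nh)
  running <- cumsum(step)
  i <- which.max(abs(running))
  es <- running[i]
  if (return_running) list(es = es, running = running) else es
}

#' Weighted running-sum enrichment score
#'
#' Walking down the ranked list, genes in the set increment the running sum
#' by `|score|^p` normalized over the set's hits, genes outside decrement
#' it by `1/(N - Nh)`; the enrichment score is the signed maximum deviation
#' from zero and lies in `[-1, 1]`.
#'
#' @param ranked a [ranked_list()].
#' @param set character vector of member genes (intersected with the
#'   ranked universe; the intersection must be non-empty and smaller than
#'   the universe).
#' @param weight_p score weight exponent (1 = the conventional weighted
#'   statistic; 0 = classic Kolmogorov-Smirnov style).
#' @param return_running also return the full running sum.
#' @return the ES, or a list `es`, `running` when `return_running`.
#' @export
enrichment_score <- function(ranked, set, weight_p = 1,
                             return_running = FALSE) {
  is_hit <- ranked$gene %in% set
  Nh <- sum(is_hit); N <- nrow(ranked)
  if (Nh < 1L) stop("gene set does not intersect the ranked universe")
  if (Nh >= N) stop("gene set covers the whole ranked universe")
  .es_stat(ranked$score, is_hit, weight_p, return_running)
}

# Null ES values for a set size: exhaustive over all size-k subsets when
# cheap enough, otherwise random subsets.
.null_es <- function(ranked, k, weight_p, nperm, exhaustive_limit) {
  N <- nrow(ranked)
  n_comb <- choose(N, k)
  if (is.finite(n_comb) && n_comb <= exhaustive_limit) {
    combs <- utils::combn(N, k)
    es <- apply(combs, 2L, function(idx) {
      hit <- logical(N); hit[idx] <- TRUE
      .es_stat(ranked$score, hit, weight_p)
    })
    list(es = es, exhaustive = TRUE)
  } else {
    es <- vapply(seq_len(nperm), function(i) {
      hit <- logical(N); hit[sample.int(N, k)] <- TRUE
      .es_stat(ranked$score, hit, weight_p)
    }, 0)
    list(es = es, exhaustive = FALSE)
  }
}

#' Preranked gene-set enrichment with permutation FDR
#'
#' For every set, a null ES distribution is built from random (or, when
#' `choose(N, k)` is small, all) same-size gene sets. NES is the ES divided
#' by the mean magnitude of the same-sign null ES values; nominal p-values
#' and FDR q-values are computed separately for positively and negatively
#' enriched sets from the sign-matched normalized null pool. Reproducible
#' given `seed`. Sets that do not intersect the universe, or swallow it,
#' are skipped with a message.
#'
#' @param ranked a [ranked_list()].
#' @param collection named list of gene sets (e.g. from [read_gmt()]).
#' @param weight_p score weight exponent (default 1).
#' @param nperm permutations per set size (default 1000, minimum 100).
#' @param seed integer seed.
#' @param exhaustive_limit enumerate all subsets when `choose(N, k)` is at
#'   most this (default 1e4).
#' @return data.frame of class `gsea_result`: `set`, `size`, `es`, `nes`,
#'   `p`, `q`, `exhaustive`.
#' @export
gsea_preranked <- function(ranked, collection, weight_p = 1, nperm = 1000,
                           seed = 1L, exhaustive_limit = 1e4) {
  if (nperm < 100) stop("nperm must be >= 100")
  set.seed(seed)
  N <- nrow(ranked)
  sizes <- vapply(collection, function(s) sum(ranked$gene %in% s), 0L)
  usable <- sizes >= 1L & sizes < N
  if (any(!usable))
    message(sprintf("skipping %d set(s) outside the ranked universe",
                    sum(!usable)))
  collection <- collection[usable]; sizes <- sizes[usable]
  if (!length(collection))
    return(structure(data.frame(set = character(), size = integer(),
                                es = numeric(), nes = numeric(),
                                p = numeric(), q = numeric(),
                                exhaustive = logical()),
                     class = c("gsea_result", "data.frame")))
  nulls <- list()
  for (k in sort(unique(sizes)))
    nulls[[as.character(k)]] <- .null_es(ranked, k, weight_p, nperm,
                                         exhaustive_limit)
  es <- vapply(collection, function(s) enrichment_score(ranked, s, weight_p),
               0)
  norm_one <- function(e, null_es) {
    mp <- mean(null_es[null_es >= 0]); mn <- mean(abs(null_es[null_es < 0]))
    ifelse(e >= 0, e / mp, e / mn)
  }
  nes <- numeric(length(es)); p <- numeric(length(es))
  null_nes_pool <- list()
  for (i in seq_along(es)) {
    ne <- nulls[[as.character(sizes[i])]]$es
    nes[i] <- norm_one(es[i], ne)
    p[i] <- if (es[i] >= 0) {
      pos <- ne[ne >= 0]
      if (length(pos)) mean(pos >= es[i]) else NA_real_
    } else {
      neg <- ne[ne < 0]
      if (length(neg)) mean(neg <= es[i]) else NA_real_
    }
    null_nes_pool[[i]] <- norm_one(ne, ne)
  }
  pool <- unlist(null_nes_pool)
  q <- vapply(seq_along(es), function(i) {
    if (is.na(nes[i])) return(NA_real_)
    if (nes[i] >= 0) {
      num <- mean(pool[pool >= 0] >= nes[i])
      den <- mean(nes[nes >= 0] >= nes[i])
    } else {
      num <- mean(pool[pool < 0] <= nes[i])
      den <- mean(nes[nes < 0] <= nes[i])
    }
    min(max(num / den, 0), 1)
  }, 0)
  out <- data.frame(set = names(collection), size = as.integer(sizes),
                    es = es, nes = nes, p = p, q = q,
                    exhaustive = vapply(as.character(sizes), function(k)
                      nulls[[k]]$exhaustive, TRUE),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("gsea_result", "data.frame")
  out
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("<gsea_result> %d set(s)\n", nrow(x)))
  NextMethod()
}
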