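#' Dose-response matrix
#'
#' Long-format replicate readouts over a two-drug titration grid. The grid
#' must contain the double-vehicle cell (dose 0 of both drugs).
#'
#' @param data data.frame with columns `dose_a`, `dose_b`, `replicate`,
#'   `value`.
#' @param kind readout kind: `"cytotoxicity"`, `"viability"`,
#'   `"apoptosis"` (raw plate signal), or `"fraction"` (already a fraction
#'   affected in `[0, 1]`).
#' @return data.frame of class `dose_matrix`.
#' @export
dose_matrix <- function(data, kind = c("cytotoxicity", "viability",
                                       "apoptosis", "fraction")) {
  kind <- match.arg(kind)
  need <- c("dose_a", "dose_b", "replicate", "value")
  if (!all(need %in% names(data)))
    stop("dose matrix needs columns dose_a, dose_b, replicate, value")
  if (!any(data$dose_a == 0 & data$dose_b == 0))
    stop("dose matrix must contain the (0, 0) vehicle cell")
  if (kind == "fraction" && any(data$value < 0 | data$value > 1))
    stop("fraction readouts must lie in [0, 1]")
  out <- data[, need]
  attr(out, "kind") <- kind
  class(out) <- c("dose_matrix", "data.frame")
  out
}

#' Normalize plate readouts to the vehicle control
#'
#' Converts raw readouts to fractions affected. Cytotoxicity/apoptosis
#' signal rises with effect: with a max-kill reference,
#' `f = (x - vehicle) / (max_signal - vehicle)`; without one the
#' documented fallback is `f = clip(x / vehicle - 1, 0, 1)`. Viability
#' falls with effect: `f = 1 - clip(x / vehicle, 0, 1)`. A `"fraction"`
#' matrix passes through unchanged.
#'
#' @param matrix a [dose_matrix()].
#' @param max_signal optional maximum-effect reference signal (same units
#'   as the readout) for rising readouts.
#' @return a [dose_matrix()] of kind `"fraction"`.
#' @export
normalize_to_vehicle <- function(matrix, max_signal = NULL) {
  kind <- attr(matrix, "kind")
  if (kind == "fraction") return(matrix)
  veh <- matrix$value[matrix$dose_a == 0 & matrix$dose_b == 0]
  vm <- mean(veh)
  if (!is.finite(vm) || vm <= 0) stop("vehicle mean must be > 0")
  x <- matrix$value
  f <- if (kind == "viability") {
    1 - pmin(pmax(x / vm, 0), 1)
  } else if (!is.null(max_signal)) {
    if (max_signal <= vm) stop("max_signal must exceed the vehicle mean")
    pmin(pmax((x - vm) / (max_signal - vm), 0), 1)
  } else {
    pmin(pmax(x / vm - 1, 0), 1)
  }
  out <- matrix
  out$value <- f
  attr(out, "kind") <- "fraction"
  out
}

#' Bliss independence expectation and excess
#'
#' Under Bliss independence two drugs act on independent targets, so the
#' expected combined fraction affected is `E = fA + fB - fA * fB`. The
#' excess `fAB - E` quantifies synergy (positive) or antagonism
#' (negative); the score is 100 times the excess.
#'
#' @param fa,fb,fab fractions affected in `[0, 1]` for drug A alone, drug
#'   B alone, and the combination (vectorised).
#' @return data.frame with `expected`, `excess`, `score`.
#' @export
bliss_excess <- function(fa, fb, fab) {
  if (any(c(fa, fb, fab) < 0 | c(fa, fb, fab) > 1))
    stop("fractions must lie in [0, 1]; clip before calling")
  expected <- fa + fb - fa * fb
  excess <- fab - expected
  data.frame(expected = expected, excess = excess, score = 100 * excess)
}

#' Bliss synergy map of a dose matrix
#'
#' Replicate readouts are averaged on the fraction scale; single-agent
#' fractions come from the dose-0 row and column; every combination cell
#' gets a Bliss expectation, excess and score (100 x excess). Swapping the
#' two drugs transposes the map.
#'
#' @param matrix a [dose_matrix()]; raw readout kinds are normalized via
#'   [normalize_to_vehicle()] first.
#' @param max_signal forwarded to [normalize_to_vehicle()].
#' @return object of class `bliss_map`: `table` (per-cell data.frame with
#'   `dose_a`, `dose_b`, `fa`, `fb`, `fab`, `expected`, `excess`,
#'   `score`), `max_pair` (highest-scoring combination) and `mean_score`.
#' @export
synergy_map <- function(matrix, max_signal = NULL) {
  fr <- normalize_to_vehicle(matrix, max_signal = max_signal)
  agg <- stats::aggregate(value ~ dose_a + dose_b, data = fr, FUN = mean)
  doses_a <- sort(unique(agg$dose_a)); doses_b <- sort(unique(agg$dose_b))
  if (!0 %in% doses_a || !0 %in% doses_b)
    stop("dose matrix must include single-agent (dose 0) row and column")
  cell <- function(a, b) {
    v <- agg$value[agg$dose_a == a & agg$dose_b == b]
    if (!length(v)) stop(sprintf("missing cell (%g, %g)", a, b))
    v
  }
  fa_by_dose <- vapply(doses_a, function(a) cell(a, 0), 0)
  fb_by_dose <- vapply(doses_b, function(b) cell(0, b), 0)
  grid <- expand.grid(dose_a = doses_a[doses_a > 0],
                      dose_b = doses_b[doses_b > 0])
  fa <- fa_by_dose[match(grid$dose_a, doses_a)]
  fb <- fb_by_dose[match(grid$dose_b, doses_b)]
  fab <- mapply(cell, grid$dose_a, grid$dose_b)
  bl <- bliss_excess(fa, fb, fab)
  tab <- cbind(grid, fa = fa, fb = fb, fab = fab, bl)
  best <- tab[which.max(tab$score), , drop = FALSE]
  structure(list(table = tab, max_pair = best,
                 mean_score = mean(tab$score)),
            class = "bliss_map")
}

#' @export
print.bliss_map <- function(x, ...) {
  cat(sprintf(
    "<bliss_map> %d combination cells; mean score %.2f; max %.2f at (%g, %g)\n",
    nrow(x$table), x$mean_score, x$max_pair$score, x$max_pair$dose_a,
    x$max_pair$dose_b))
  invisible(x)
}

#' Relative quantification by the delta-delta-Ct method
#'
#' `RQ = 2 ^ -((Ct_target,treated - Ct_ref,treated) -
#' (Ct_target,control - Ct_ref,control))`: target expression normalized to
#' a reference transcript (e.g. GAPDH) and to the vehicle-treated
#' condition.
#'
#' @param target_ct_treated,ref_ct_treated,target_ct_control,ref_ct_control
#'   cycle-threshold values (vectorised).
#' @return relative quantity (1 = no change).
#' @export
ddct <- function(target_ct_treated, ref_ct_treated, target_ct_control,
                 ref_ct_control) {
  stopifnot(all(is.finite(c(target_ct_treated, ref_ct_treated,
                            target_ct_control, ref_ct_control))))
  2^-((target_ct_treated - ref_ct_treated) -
        (target_ct_control - ref_ct_control))
}
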