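#' Treatment scenario for the nascent-transcription simulator
#'
#' A scenario multiplies the expected promoter-peak signal and the expected
#' gene-body signal of the genes it affects. Pause release (the phenotype of
#' gene-body elongation-kinase inhibition) is promoter down / body up
#' (`pause_multiplier < 1`, `body_multiplier > 1`); a pause-release block
#' (P-TEFb inhibition) is the opposite.
#'
#' @param label condition name.
#' @param affected_fraction proportion of genes carrying the effect, in
#'   `[0, 1]`. Genes are selected by thresholding one latent uniform draw
#'   per gene, so conditions with equal fractions affect the same genes and
#'   smaller fractions are nested within larger ones.
#' @param pause_multiplier,body_multiplier positive factors applied to the
#'   expected promoter-peak and gene-body signal of affected genes.
#' @return an object of class `scenario_effect`.
#' @export
scenario_effect <- function(label, affected_fraction = 0,
                            pause_multiplier = 1, body_multiplier = 1) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (affected_fraction < 0 || affected_fraction > 1)
    stop("affected_fraction must be in [0, 1]")
  if (pause_multiplier <= 0 || body_multiplier <= 0)
    stop("multipliers must be > 0")
  structure(list(label = label, affected_fraction = affected_fraction,
                 pause_multiplier = pause_multiplier,
                 body_multiplier = body_multiplier),
            class = "scenario_effect")
}

#' Configuration of the synthetic nascent-transcription experiment
#'
#' Describes the data-generating process the downstream pipeline is tested
#' against: genes placed on a synthetic chromosome, a promoter-proximal
#' paused peak 30-60 nt downstream of the TSS plus lower uniform gene-body
#' occupancy, negative-binomially dispersed replicate counts, and treatment
#' scenarios that rescale peak and body signal of an affected gene subset.
#'
#' The first condition in `conditions` is the vehicle and must have both
#' multipliers equal to 1. Defaults reflect a deeply sequenced cell-culture
#' nascent-transcription experiment: tightly concordant replicates
#' (dispersion 0.005, i.e. ~7% CV at high counts), median pausing index
#' 2.5, and 2 million gene-derived reads per sample.
#'
#' @param n_genes number of genes.
#' @param genome_length synthetic chromosome length (nt).
#' @param gene_length_law `c(meanlog, sdlog)` of the log-normal gene-length
#'   law; lengths are truncated below at `min_gene_length`.
#' @param min_gene_length hard minimum gene length (nt, >= 1250 so the
#'   quantification body window keeps >= 500 nt).
#' @param pause_offset_range inclusive integer range of the pause-peak
#'   center, in nt downstream of the TSS.
#' @param pause_width half-width of the pause peak (nt); peak positions are
#'   uniform on `offset +/- pause_width`.
#' @param expression_law `c(meanlog, sdlog)` of the log-normal gene-body
#'   density law (relative reads/nt; rescaled to `depth_per_sample`).
#' @param pi_law `c(meanlog, sdlog)` of the log-normal true pausing-index
#'   law.
#' @param dispersion negative-binomial dispersion alpha (>= 0; 0 gives
#'   Poisson counts).
#' @param depth_per_sample expected total gene-derived reads per sample,
#'   anchored on the vehicle condition.
#' @param background_rate uniform Poisson noise floor (reads/nt) applied to
#'   both strands across the whole chromosome.
#' @param n_replicates replicates per condition.
#' @param conditions list of [scenario_effect()]; first entry is vehicle.
#' @param seed integer seed; all outputs are pure functions of
#'   (config, seed).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000,
                              genome_length = 4e7,
                              gene_length_law = c(meanlog = log(4000), sdlog = 0.5),
                              min_gene_length = 1250,
                              pause_offset_range = c(30L, 60L),
                              pause_width = 25,
                              expression_law = c(meanlog = 0, sdlog = 0.5),
                              pi_law = c(meanlog = log(2.5), sdlog = 0.5),
                              dispersion = 0.005,
                              depth_per_sample = 2e6,
                              background_rate = 0.001,
                              n_replicates = 2,
                              conditions = list(scenario_effect("vehicle")),
                              seed = 1L) {
  stopifnot(n_genes >= 0, genome_length > 0, length(gene_length_law) == 2L,
            length(pause_offset_range) == 2L, pause_width >= 0,
            length(expression_law) == 2L, length(pi_law) == 2L,
            depth_per_sample >= 0, background_rate >= 0, n_replicates >= 1)
  if (min_gene_length < 1250)
    stop("min_gene_length must be >= 1250 nt (body window >= 500 nt)")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (gene_length_law[2L] < 0 || expression_law[2L] < 0 || pi_law[2L] < 0)
    stop("law sdlog parameters must be >= 0")
  if (!length(conditions) || !all(vapply(conditions, inherits, TRUE,
                                         "scenario_effect")))
    stop("conditions must be a non-empty list of scenario_effect")
  veh <- conditions[[1L]]
  if (veh$pause_multiplier != 1 || veh$body_multiplier != 1)
    stop("the first (vehicle) condition must have both multipliers = 1")
  labels <- vapply(conditions, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("condition labels must be unique")
  structure(list(n_genes = as.integer(n_genes), genome_length = genome_length,
                 gene_length_law = gene_length_law,
                 min_gene_length = as.integer(min_gene_length),
                 pause_offset_range = as.integer(pause_offset_range),
                 pause_width = as.integer(pause_width),
                 expression_law = expression_law, pi_law = pi_law,
                 dispersion = dispersion, depth_per_sample = depth_per_sample,
                 background_rate = background_rate,
                 n_replicates = as.integer(n_replicates),
                 conditions = conditions, seed = as.integer(seed)),
            class = "simulation_config")
}

.condition_labels <- function(config)
  vapply(config$conditions, `[[`, "", "label")

#' Generate a non-overlapping gene annotation
#'
#' Genes are placed on a single synthetic chromosome so that even after
#' extending every gene by 1000 nt on both sides no two genes overlap;
#' strands are assigned evenly at random. Deterministic given the config
#' seed.
#'
#' @param config a [simulation_config()].
#' @return a gene table in the layout of [read_genes()].
#' @export
generate_annotation <- function(config) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      gene_id = character(), score = numeric(),
                      strand = character(), gene_name = character(),
                      length = integer(), stringsAsFactors = FALSE)
  n <- config$n_genes
  if (n == 0L) return(empty)
  mean_len <- exp(config$gene_length_law[1L] + config$gene_length_law[2L]^2 / 2)
  if (n * mean_len > config$genome_length / 2)
    stop(sprintf(
      "genome too small: %d genes of mean length %.0f need >= %.0f nt",
      n, mean_len, 2 * n * mean_len))
  set.seed(config$seed)
  lens <- pmax(round(stats::rlnorm(n, config$gene_length_law[1L],
                                   config$gene_length_law[2L])),
               config$min_gene_length)
  pad <- 1000L
  footprint <- sum(lens + 2 * pad)
  slack <- config$genome_length - footprint
  if (slack < 0)
    stop(sprintf("genome too small to place genes: need %.0f nt, have %.0f",
                 footprint, config$genome_length))
  gaps <- diff(c(0, sort(stats::runif(n)), 1)) * slack
  starts <- pad + cumsum(gaps[seq_len(n)]) +
    cumsum(c(0, (lens + 2 * pad)[-n]))
  starts <- as.integer(round(starts))
  strand <- sample(rep(c("+", "-"), length.out = n))
  data.frame(chrom = "chrSim", start = starts, end = starts + as.integer(lens),
             gene_id = sprintf("G%05d", seq_len(n)), score = 0,
             strand = strand, gene_name = sprintf("G%05d", seq_len(n)),
             length = as.integer(lens), stringsAsFactors = FALSE)
}

#' Ground-truth occupancy parameters for a simulated experiment
#'
#' Draws per-gene body density, true pausing index and pause-peak offset,
#' and derives per-condition expected promoter-window and body counts.
#' Expected counts are scaled so the vehicle condition totals
#' `depth_per_sample` reads. True PI equals expected promoter density over
#' expected body density exactly.
#'
#' @param config a [simulation_config()].
#' @param annotation the matching [generate_annotation()] output.
#' @return a data.frame with one row per gene x condition: `gene_id`,
#'   `condition`, `affected`, `exp_promoter` (expected counts in the 500-nt
#'   promoter window), `exp_body` (expected counts in the body window),
#'   `exp_body_density` (reads/nt), `true_pi`, `true_body_fc`, plus
#'   per-gene geometry columns.
#' @export
simulation_truth <- function(config, annotation) {
  n <- nrow(annotation)
  labels <- .condition_labels(config)
  if (n == 0L)
    return(data.frame(gene_id = character(), condition = character(),
                      affected = logical(), exp_promoter = numeric(),
                      exp_body = numeric(), exp_body_density = numeric(),
                      true_pi = numeric(), true_body_fc = numeric(),
                      pause_offset = integer(), body_length = integer()))
  set.seed(config$seed + 1L)
  dens <- stats::rlnorm(n, config$expression_law[1L], config$expression_law[2L])
  pival <- stats::rlnorm(n, config$pi_law[1L], config$pi_law[2L])
  offs <- config$pause_offset_range
  pause_offset <- sample(seq(offs[1L], offs[2L]), n, replace = TRUE)
  latent <- stats::runif(n)
  body_len <- annotation$length - 750L
  base_body <- dens * body_len
  base_prom <- pival * dens * 500
  vehicle_total <- sum(base_body + base_prom)
  scale <- if (vehicle_total > 0) config$depth_per_sample / vehicle_total else 0
  out <- do.call(rbind, lapply(seq_along(labels), function(ci) {
    sc <- config$conditions[[ci]]
    affected <- latent < sc$affected_fraction
    pm <- ifelse(affected, sc$pause_multiplier, 1)
    bm <- ifelse(affected, sc$body_multiplier, 1)
    data.frame(gene_id = annotation$gene_id, condition = labels[ci],
               affected = affected,
               exp_promoter = scale * base_prom * pm,
               exp_body = scale * base_body * bm,
               exp_body_density = scale * dens * bm,
               true_pi = pival * pm / bm,
               true_body_fc = bm,
               pause_offset = pause_offset,
               body_length = body_len,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

.nb_draw <- function(n, mu, dispersion) {
  if (dispersion > 0) stats::rnbinom(n, mu = mu, size = 1 / dispersion)
  else stats::rpois(n, mu)
}

#' Simulate one strand-specific coverage track
#'
#' Region counts are drawn NB(mean, dispersion) per gene, then spread to
#' single-nucleotide positions: promoter reads uniform on the pause peak
#' (`pause_offset +/- pause_width` in transcription coordinates), body
#' reads uniform on the quantification body window (+250 to CPS-500). A
#' uniform Poisson background is laid over both strands. Deterministic
#' given (condition, replicate, config seed).
#'
#' @param annotation gene table from [generate_annotation()].
#' @param truth truth table from [simulation_truth()].
#' @param condition condition label present in `truth`.
#' @param replicate replicate index (1-based).
#' @param config the [simulation_config()].
#' @return a [coverage_track()].
#' @export
simulate_sample <- function(annotation, truth, condition, replicate, config) {
  labels <- unique(truth$condition)
  ci <- match(condition, labels)
  if (is.na(ci)) stop(sprintf("unknown condition label '%s'", condition))
  tr <- truth[truth$condition == condition, ]
  tr <- tr[match(annotation$gene_id, tr$gene_id), ]
  set.seed(config$seed + 10000L * ci + 97L * as.integer(replicate) + 2L)
  n <- nrow(annotation)
  L <- as.integer(config$genome_length)
  tss <- gene_tss(annotation)
  sgn <- ifelse(annotation$strand == "+", 1L, -1L)
  pos_list <- list(plus = integer(0), minus = integer(0))
  if (n > 0L) {
    n_prom <- .nb_draw(n, tr$exp_promoter, config$dispersion)
    n_body <- .nb_draw(n, tr$exp_body, config$dispersion)
    w <- config$pause_width
    # promoter-peak reads
    gi <- rep.int(seq_len(n), n_prom)
    d_prom <- (tr$pause_offset[gi] - w) +
      floor(stats::runif(length(gi)) * (2L * w + 1L))
    p_prom <- tss[gi] + sgn[gi] * as.integer(d_prom)
    # gene-body reads, uniform on [ +250, CPS-500 ] transcription coords
    gj <- rep.int(seq_len(n), n_body)
    d_body <- 250L + floor(stats::runif(length(gj)) * tr$body_length[gj])
    p_body <- tss[gj] + sgn[gj] * as.integer(d_body)
    pos <- c(p_prom, p_body)
    onplus <- c(sgn[gi], sgn[gj]) == 1L
    pos_list$plus <- pos[onplus]
    pos_list$minus <- pos[!onplus]
  }
  if (config$background_rate > 0) {
    for (s in c("plus", "minus")) {
      nbg <- stats::rpois(1L, config$background_rate * L)
      pos_list[[s]] <- c(pos_list[[s]],
                         as.integer(floor(stats::runif(nbg) * L)))
    }
  }
  track_from_positions("chrSim", pos_plus = pos_list$plus,
                       pos_minus = pos_list$minus, chrom_length = L,
                       sample = sprintf("%s_rep%d", condition, replicate))
}

#' Simulate a full multi-condition experiment
#'
#' @param config a [simulation_config()].
#' @return an object of class `nascent_sim`: `annotation`, `truth`,
#'   `tracks` (named list, `<condition>_rep<i>`), `samples` (sample ->
#'   condition/replicate table) and the embedded `config`.
#' @export
simulate_experiment <- function(config) {
  annotation <- generate_annotation(config)
  truth <- simulation_truth(config, annotation)
  labels <- .condition_labels(config)
  samples <- expand.grid(replicate = seq_len(config$n_replicates),
                         condition = labels, stringsAsFactors = FALSE)
  samples <- samples[, c("condition", "replicate")]
  samples$sample <- sprintf("%s_rep%d", samples$condition, samples$replicate)
  tracks <- stats::setNames(vector("list", nrow(samples)), samples$sample)
  for (i in seq_len(nrow(samples)))
    tracks[[i]] <- simulate_sample(annotation, truth, samples$condition[i],
                                   samples$replicate[i], config)
  structure(list(annotation = annotation, truth = truth, tracks = tracks,
                 samples = samples, config = config),
            class = "nascent_sim")
}

#' @export
print.nascent_sim <- function(x, ...) {
  cat(sprintf("<nascent_sim> %d genes, %d conditions x %d replicates\n",
              nrow(x$annotation), length(x$config$conditions),
              x$config$n_replicates))
  invisible(x)
}

#' Write a simulated experiment to disk
#'
#' Emits the annotation as BED6, one bedGraph per strand per sample, the
#' truth table and sample table as TSV, and the configuration as YAML.
#'
#' @param sim a `nascent_sim` from [simulate_experiment()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genes(sim$annotation, file.path(dir, "genes.bed"))
  for (s in names(sim$tracks)) {
    write_bedgraph(sim$tracks[[s]], file.path(dir, paste0(s, "_plus.bedGraph")), "+")
    write_bedgraph(sim$tracks[[s]], file.path(dir, paste0(s, "_minus.bedGraph")), "-")
  }
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$samples, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  cfg$conditions <- lapply(cfg$conditions, unclass)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Simulate a replicated dose-response matrix with planted Bliss excess
#'
#' Observed fractions are Bliss-expected effect plus a planted excess plus
#' Gaussian noise, clipped to `[0, 1]`. Single-agent fractions land in the
#' dose-0 row/column by the Bliss formula itself.
#'
#' @param single_agent list with elements `A` and `B`: named numeric
#'   vectors mapping dose (as names; must include "0" with fraction 0) to
#'   fraction affected in `[0, 1]`.
#' @param true_excess matrix (`length(A) x length(B)`) or scalar of planted
#'   excess per cell.
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param n_replicates replicate readouts per cell.
#' @param seed integer seed.
#' @return a `dose_matrix` (long data.frame: `dose_a`, `dose_b`,
#'   `replicate`, `value`, kind `"fraction"`) with the truth in
#'   `attr(, "true_excess")`.
#' @export
simulate_dose_matrix <- function(single_agent, true_excess = 0, noise_sd = 0,
                                 n_replicates = 1, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  fa <- single_agent$A; fb <- single_agent$B
  for (v in list(fa, fb)) {
    if (is.null(names(v)) || !"0" %in% names(v))
      stop("dose grids must be named and include dose 0")
    if (any(v < 0 | v > 1)) stop("single-agent fractions must be in [0, 1]")
  }
  if (fa[["0"]] != 0 || fb[["0"]] != 0)
    stop("vehicle (dose 0) single-agent fraction must be 0")
  na <- length(fa); nb <- length(fb)
  if (length(true_excess) == 1L)
    true_excess <- matrix(true_excess, na, nb)
  stopifnot(all(dim(true_excess) == c(na, nb)))
  set.seed(seed)
  rows <- expand.grid(i = seq_len(na), j = seq_len(nb),
                      replicate = seq_len(n_replicates))
  expected <- fa[rows$i] + fb[rows$j] - fa[rows$i] * fb[rows$j]
  value <- expected + true_excess[cbind(rows$i, rows$j)] +
    stats::rnorm(nrow(rows), 0, noise_sd)
  out <- data.frame(dose_a = as.numeric(names(fa))[rows$i],
                    dose_b = as.numeric(names(fb))[rows$j],
                    replicate = rows$replicate,
                    value = pmin(pmax(value, 0), 1))
  out <- dose_matrix(out, kind = "fraction")
  attr(out, "true_excess") <- true_excess
  out
}
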