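#' Configuration for an end-to-end pipeline run
#'
#' Bundles the simulation (or pre-simulated dataset), the
#' (treatment, time-matched control) contrasts, the active-gene filter and
#' classification thresholds, and optional gene sets for enrichment.
#'
#' @param simulation a [simulation_config()] or an existing `nascent_sim`.
#' @param contrasts list of `c(treatment, control)` condition-label pairs;
#'   every treatment is compared against its own time-matched control.
#' @param active_min_total minimum summed control promoter count for the
#'   active-gene filter (default 20).
#' @param min_body_len minimum body-window length (nt) for quantification
#'   (default 500).
#' @param pi_pseudocount pseudocount for pausing indices (default 0.5).
#' @param dtg_rule classification rule for differential transcription:
#'   `"dtg"`, `"deg"` or `"none"`.
#' @param dispersion_mode dispersion mode for [nb_wald_test()].
#' @param gene_sets optional named list of gene sets (or a GMT path) for
#'   preranked enrichment on the first contrast's log2 fold-changes.
#' @param gsea_nperm permutations for [gsea_preranked()].
#' @param metagene logical; compute per-condition metagene profiles.
#' @param metagene_min_len minimum gene length for the metagene panel.
#' @param seed seed for the enrichment permutations.
#' @return an object of class `run_config`.
#' @export
run_config <- function(simulation, contrasts, active_min_total = 20,
                       min_body_len = 500, pi_pseudocount = 0.5,
                       dtg_rule = c("dtg", "deg", "none"),
                       dispersion_mode = c("trend", "max", "mom"),
                       gene_sets = NULL, gsea_nperm = 1000,
                       metagene = FALSE, metagene_min_len = 3000,
                       seed = 1L) {
  dtg_rule <- match.arg(dtg_rule)
  dispersion_mode <- match.arg(dispersion_mode)
  labels <- if (inherits(simulation, "nascent_sim"))
    .condition_labels(simulation$config)
  else if (inherits(simulation, "simulation_config"))
    .condition_labels(simulation)
  else stop("simulation must be a simulation_config or nascent_sim")
  if (!length(contrasts))
    stop("at least one (treatment, control) contrast is required")
  for (ct in contrasts) {
    if (length(ct) != 2L)
      stop("each contrast must be c(treatment, control)")
    missing <- setdiff(unlist(ct), labels)
    if (length(missing))
      stop(sprintf("contrast names unknown condition '%s'", missing[1L]))
  }
  if (is.character(gene_sets) && length(gene_sets) == 1L)
    gene_sets <- read_gmt(gene_sets)
  structure(list(simulation = simulation, contrasts = contrasts,
                 active_min_total = active_min_total,
                 min_body_len = min_body_len,
                 pi_pseudocount = pi_pseudocount, dtg_rule = dtg_rule,
                 dispersion_mode = dispersion_mode, gene_sets = gene_sets,
                 gsea_nperm = gsea_nperm, metagene = metagene,
                 metagene_min_len = metagene_min_len,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full nascent-transcription analysis pipeline
#'
#' simulate (or take) tracks -> define windows -> count promoter/body
#' matrices -> median-of-ratios size factors -> active-gene filter ->
#' NB Wald differential transcription per contrast -> pausing indices and
#' PI changes -> optional metagene profiles and preranked enrichment.
#' Re-running with an identical configuration reproduces every number
#' exactly.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, all tables are written
#'   as TSV together with a machine-readable JSON run manifest.
#' @return object of class `pausekit_run`: `sim`, `windows`, `counts`,
#'   `size_factors`, `active_genes`, `diff` (named list per contrast),
#'   `pausing`, `metagene` (per condition, when requested), `gsea` (when
#'   gene sets given), `log` (per-stage gene counts).
#' @export
run_analysis <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  sim <- if (inherits(config$simulation, "nascent_sim")) config$simulation
         else simulate_experiment(config$simulation)
  control <- .condition_labels(sim$config)[1L]
  windows <- define_windows(sim$annotation)
  cm <- count_matrices(sim$tracks, windows)
  design <- stats::setNames(sim$samples$condition, sim$samples$sample)
  sf <- size_factors(cm$body + cm$promoter, pseudocount = 1)
  body_len <- stats::setNames(cm$windows$body_length, cm$windows$gene_id)
  active <- identify_active_genes(cm$promoter, design, control,
                                  min_total = config$active_min_total,
                                  min_body_len = config$min_body_len,
                                  body_length = body_len)
  diff <- list()
  for (ct in config$contrasts) {
    nm <- sprintf("%s_vs_%s", ct[[1L]], ct[[2L]])
    diff[[nm]] <- diff_transcription(
      cm$body[active, , drop = FALSE], design, ct[[1L]], ct[[2L]],
      dispersion_mode = config$dispersion_mode, rule = config$dtg_rule)
  }
  pausing <- pausing_records(cm, design, config$contrasts,
                             pseudocount = config$pi_pseudocount,
                             genes = active)
  meta <- NULL
  if (isTRUE(config$metagene)) {
    meta <- list()
    mg_genes <- sim$annotation[sim$annotation$gene_id %in% active, ,
                               drop = FALSE]
    for (cn in unique(design)) {
      trks <- sim$tracks[names(design)[design == cn]]
      meta[[cn]] <- metagene_profile(trks, mg_genes, sf = sf,
                                     min_len = config$metagene_min_len)
    }
  }
  gsea <- NULL
  if (!is.null(config$gene_sets)) {
    d1 <- diff[[1L]]
    ranking <- ranked_list(stats::setNames(d1$log2FC, d1$gene_id))
    gsea <- gsea_preranked(ranking, config$gene_sets,
                           nperm = config$gsea_nperm, seed = config$seed)
  }
  log <- data.frame(
    stage = c("annotated", "quantifiable", "active"),
    n_genes = c(nrow(sim$annotation), sum(windows$quantifiable),
                length(active)))
  run <- structure(list(sim = sim, windows = windows, counts = cm,
                        size_factors = sf, active_genes = active,
                        diff = diff, pausing = pausing, metagene = meta,
                        gsea = gsea, log = log, config = config),
                   class = "pausekit_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.pausekit_run <- function(x, ...) {
  cat("<pausekit_run>\n")
  for (i in seq_len(nrow(x$log)))
    cat(sprintf("  %-13s %d genes\n", x$log$stage[i], x$log$n_genes[i]))
  for (nm in names(x$diff)) {
    cl <- x$diff[[nm]]$class
    if (!all(is.na(cl)))
      cat(sprintf("  %s: %d UP, %d DOWN, %d NS\n", nm, sum(cl == "UP"),
                  sum(cl == "DOWN"), sum(cl == "NS")))
  }
  invisible(x)
}

.write_tsv <- function(d, path)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)

#' Write a pipeline run to disk
#'
#' Emits count matrices, per-contrast differential tables, pausing
#' records, metagene profiles and enrichment tables as TSV under
#' `out_dir`, plus a JSON manifest recording package version, seeds and
#' thresholds.
#'
#' @param run a `pausekit_run`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  for (sub in c("counts", "difftx", "pausing", "metagene", "gsea"))
    dir.create(file.path(out_dir, sub), recursive = TRUE,
               showWarnings = FALSE)
  write_counts(run$counts$promoter, file.path(out_dir, "counts",
                                              "promoter.tsv"))
  write_counts(run$counts$body, file.path(out_dir, "counts", "body.tsv"))
  for (nm in names(run$diff))
    .write_tsv(run$diff[[nm]], file.path(out_dir, "difftx",
                                         paste0(nm, ".tsv")))
  .write_tsv(run$pausing, file.path(out_dir, "pausing", "pausing.tsv"))
  if (!is.null(run$metagene))
    for (cn in names(run$metagene)) {
      mp <- run$metagene[[cn]]
      d <- rbind(data.frame(panel = "tss", bin = names(mp$tss),
                            value = unname(mp$tss)),
                 data.frame(panel = "body", bin = names(mp$body),
                            value = unname(mp$body)),
                 data.frame(panel = "cps", bin = names(mp$cps),
                            value = unname(mp$cps)))
      .write_tsv(d, file.path(out_dir, "metagene", paste0(cn, ".tsv")))
    }
  if (!is.null(run$gsea))
    .write_tsv(run$gsea, file.path(out_dir, "gsea", "enrichment.tsv"))
  cfg <- run$config
  manifest <- list(
    package = "pausekit",
    version = as.character(utils::packageVersion("pausekit")),
    seed = cfg$seed,
    simulation_seed = run$sim$config$seed,
    thresholds = list(active_min_total = cfg$active_min_total,
                      min_body_len = cfg$min_body_len,
                      pi_pseudocount = cfg$pi_pseudocount,
                      dtg_rule = cfg$dtg_rule,
                      dispersion_mode = cfg$dispersion_mode),
    contrasts = lapply(cfg$contrasts, function(ct)
      list(treatment = ct[[1L]], control = ct[[2L]])),
    stages = stats::setNames(as.list(run$log$n_genes), run$log$stage))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
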