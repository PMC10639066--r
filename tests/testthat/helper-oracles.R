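# Independent brute-force oracles, deliberately written differently from
# the package implementations they check.

# Step-up BH by direct definition: for each p_i the minimum over all
# p_j >= p_i of min(1, n * p_j / rank_j).
bh_bruteforce <- function(p) {
  n <- length(p)
  vapply(seq_len(n), function(i) {
    js <- which(p >= p[i])
    min(vapply(js, function(j) min(1, n * p[j] / sum(p <= p[j])), 0))
  }, 0)
}

# Running-sum ES by explicit walk down the list.
es_bruteforce <- function(scores, genes, set, p_w) {
  N <- length(scores)
  hits <- genes %in% set
  denom <- sum(abs(scores[hits])^p_w)
  run <- 0; best <- 0
  for (i in seq_len(N)) {
    if (hits[i]) {
      inc <- if (denom > 0) abs(scores[i])^p_w / denom else 1 / sum(hits)
      run <- run + inc
    } else {
      run <- run - 1 / (N - sum(hits))
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# A tiny deterministic single-gene track: uniform body density plus a
# promoter spike, on the requested strand.
toy_gene_track <- function(strand = "+", L = 5000L, offset = 1000L,
                           body_density = 1L, peak_pos = 40L,
                           peak_count = 0L, chrom_len = 20000L) {
  gene <- data.frame(chrom = "chr1", start = offset, end = offset + L,
                     gene_id = "G1", score = 0, strand = strand,
                     gene_name = "G1", length = L)
  tss <- if (strand == "+") offset else offset + L - 1L
  sgn <- if (strand == "+") 1L else -1L
  body <- rep(seq(offset, offset + L - 1L), body_density)
  peak <- rep(tss + sgn * peak_pos, peak_count)
  pos <- c(body, peak)
  tr <- if (strand == "+")
    track_from_positions("chr1", pos_plus = pos, chrom_length = chrom_len)
  else
    track_from_positions("chr1", pos_minus = pos, chrom_length = chrom_len)
  list(gene = gene, track = tr, tss = tss)
}

# Small two-condition pause-release simulation shared by several tests.
small_release_sim <- function(n_genes = 300, seed = 42,
                              depth = 3e5, genome = 6e6) {
  cfg <- simulation_config(
    n_genes = n_genes, genome_length = genome, depth_per_sample = depth,
    conditions = list(scenario_effect("DMSO"),
                      scenario_effect("CDK12i", affected_fraction = 0.3,
                                      pause_multiplier = 0.6,
                                      body_multiplier = 1.5)),
    seed = seed)
  simulate_experiment(cfg)
}
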