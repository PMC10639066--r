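test_that("annotation generation handles the empty case and is deterministic", {
  cfg <- simulation_config(n_genes = 0, seed = 3)
  expect_equal(nrow(generate_annotation(cfg)), 0L)
  cfg2 <- simulation_config(n_genes = 50, genome_length = 2e6,
                            depth_per_sample = 1e5, seed = 9)
  expect_identical(generate_annotation(cfg2), generate_annotation(cfg2))
})

test_that("generated genes are window-disjoint with lengths above the floor", {
  cfg <- simulation_config(n_genes = 200, genome_length = 5e6,
                           depth_per_sample = 1e5, seed = 11)
  g <- generate_annotation(cfg)
  expect_equal(nrow(g), 200L)
  expect_true(all(g$length >= 1250))
  expect_true(all(table(g$strand) >= 80))  # roughly even strands
  # brute-force pairwise overlap check after +/-1000 nt extension
  lo <- g$start - 1000L; hi <- g$end + 1000L
  disjoint <- vapply(seq_len(nrow(g) - 1L), function(i) {
    js <- (i + 1L):nrow(g)
    all(hi[i] <= lo[js] | hi[js] <= lo[i])
  }, TRUE)
  expect_true(all(disjoint))
})

test_that("a too-small genome raises a placement error naming the need", {
  expect_error(
    generate_annotation(simulation_config(n_genes = 1000,
                                          genome_length = 1e5,
                                          depth_per_sample = 1e5)),
    "genome too small")
})

test_that("truth tables are internally consistent", {
  cfg <- simulation_config(
    n_genes = 100, genome_length = 3e6, depth_per_sample = 1e5,
    conditions = list(scenario_effect("veh"),
                      scenario_effect("rel", 0.4, 0.6, 1.5)),
    seed = 5)
  ann <- generate_annotation(cfg)
  tr <- simulation_truth(cfg, ann)
  # PI recomputed from expected densities equals stored true PI
  pi_re <- (tr$exp_promoter / 500) / tr$exp_body_density
  expect_lt(max(abs(pi_re / tr$true_pi - 1)), 1e-9)
  veh <- tr[tr$condition == "veh", ]
  expect_true(all(veh$true_body_fc == 1))
  # vehicle totals match the configured depth
  expect_equal(sum(veh$exp_promoter + veh$exp_body), 1e5, tolerance = 1e-9)
  # pause release: true PI drops for affected genes only
  rel <- tr[tr$condition == "rel", ]
  expect_true(all(rel$true_pi[rel$affected] < veh$true_pi[rel$affected]))
  expect_equal(rel$true_pi[!rel$affected], veh$true_pi[!rel$affected])
})

test_that("zero depth gives an all-zero track and sampling is deterministic", {
  cfg <- simulation_config(n_genes = 20, genome_length = 1e6,
                           depth_per_sample = 0, background_rate = 0,
                           seed = 2)
  ann <- generate_annotation(cfg)
  tr <- simulation_truth(cfg, ann)
  s <- simulate_sample(ann, tr, "vehicle", 1, cfg)
  expect_equal(total_signal(s), 0)
  cfg2 <- simulation_config(n_genes = 20, genome_length = 1e6,
                            depth_per_sample = 1e4, seed = 2)
  tr2 <- simulation_truth(cfg2, ann)
  a <- simulate_sample(ann, tr2, "vehicle", 1, cfg2)
  b <- simulate_sample(ann, tr2, "vehicle", 1, cfg2)
  expect_equal(window_vector(a, "chrSim", 0, 1e6, "+"),
               window_vector(b, "chrSim", 0, 1e6, "+"))
  expect_error(simulate_sample(ann, tr2, "nosuch", 1, cfg2),
               "unknown condition")
})

test_that("promoter means track the configured pause multiplier", {
  cfg <- simulation_config(
    n_genes = 500, genome_length = 1.2e7, depth_per_sample = 1e6,
    background_rate = 0,
    conditions = list(scenario_effect("veh"),
                      scenario_effect("halved", 1, 0.5, 1)),
    seed = 8)
  sim <- simulate_experiment(cfg)
  w <- define_windows(sim$annotation)
  cm <- count_matrices(sim$tracks, w)
  pv <- cm$promoter[, "veh_rep1"]
  ph <- cm$promoter[, "halved_rep1"]
  n <- length(pv)
  se <- sqrt(stats::var(ph) / n + 0.25 * stats::var(pv) / n)
  expect_lt(abs(mean(ph) - 0.5 * mean(pv)), 3 * se)
  # moment matching against the truth expectations, both regions
  truth_v <- sim$truth[sim$truth$condition == "veh", ]
  for (m in list(cbind(obs = pv, exp = truth_v$exp_promoter),
                 cbind(obs = cm$body[, "veh_rep1"], exp = truth_v$exp_body))) {
    dif <- mean(m[, "obs"]) - mean(m[, "exp"])
    expect_lt(abs(dif), 3 * stats::sd(m[, "obs"]) / sqrt(n))
  }
})

test_that("experiments bundle the right number of tracks and truth", {
  cfg <- simulation_config(
    n_genes = 30, genome_length = 1.5e6, depth_per_sample = 2e4,
    n_replicates = 2,
    conditions = list(scenario_effect("veh"),
                      scenario_effect("trt", 0.5, 0.6, 1.5)),
    seed = 4)
  sim <- simulate_experiment(cfg)
  expect_length(sim$tracks, 4L)
  expect_setequal(sim$samples$sample,
                  c("veh_rep1", "veh_rep2", "trt_rep1", "trt_rep2"))
  # identical config reproduces identical tracks
  sim2 <- simulate_experiment(cfg)
  expect_equal(total_signal(sim$tracks[["trt_rep2"]]),
               total_signal(sim2$tracks[["trt_rep2"]]))
  # truth delta-PI is negative for affected genes under pause release
  veh <- sim$truth[sim$truth$condition == "veh", ]
  trt <- sim$truth[sim$truth$condition == "trt", ]
  dpi <- trt$true_pi - veh$true_pi
  expect_true(all(dpi[trt$affected] < 0))
  expect_true(all(dpi[!trt$affected] == 0))
})

test_that("simulated experiments round-trip to disk", {
  cfg <- simulation_config(n_genes = 10, genome_length = 6e5,
                           depth_per_sample = 5e3, seed = 6)
  sim <- simulate_experiment(cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  g <- read_genes(file.path(dir, "genes.bed"))
  expect_equal(g$start, sim$annotation$start)
  back <- read_bedgraph(file.path(dir, "vehicle_rep1_plus.bedGraph"), "+",
                        chrom_lengths = c(chrSim = 6e5))
  expect_equal(total_signal(back),
               total_signal(sim$tracks[[1]], strand = "+"))
})

test_that("dose-matrix simulation reproduces Bliss arithmetic exactly", {
  sa <- list(A = c(`0` = 0, `1` = 0.2), B = c(`0` = 0, `1` = 0.5))
  # null case: no excess, no noise
  dm0 <- simulate_dose_matrix(sa, true_excess = 0, noise_sd = 0, seed = 1)
  sm0 <- synergy_map(dm0)
  expect_equal(sm0$table$score, 0)
  # forced arithmetic: fA=0.2, fB=0.5, excess +0.12 -> observed 0.72
  ex <- matrix(0, 2, 2); ex[2, 2] <- 0.12
  dm1 <- simulate_dose_matrix(sa, ex, noise_sd = 0, seed = 1)
  expect_equal(dm1$value[dm1$dose_a == 1 & dm1$dose_b == 1], 0.72)
  expect_error(simulate_dose_matrix(sa, noise_sd = -0.1), "noise_sd")
})

test_that("planted excess is recovered within Monte-Carlo error", {
  sa <- list(A = c(`0` = 0, `1` = 0.15, `2` = 0.3),
             B = c(`0` = 0, `1` = 0.25, `2` = 0.45))
  ex <- matrix(0, 3, 3); ex[2, 3] <- 0.1
  reps <- vapply(1:30, function(s) {
    dm <- simulate_dose_matrix(sa, ex, noise_sd = 0.02, n_replicates = 3,
                               seed = s)
    sm <- synergy_map(dm)
    sm$table$excess[sm$table$dose_a == 1 & sm$table$dose_b == 2]
  }, 0)
  se <- stats::sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 0.1), 3 * se)
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(min_gene_length = 1000), "1250")
  expect_error(simulation_config(dispersion = -1), "dispersion")
  expect_error(scenario_effect("x", affected_fraction = 1.2), "affected_fraction")
  expect_error(scenario_effect("x", pause_multiplier = 0), "multipliers")
  expect_error(simulation_config(
    conditions = list(scenario_effect("v", 0.1, 2, 1))), "vehicle")
})
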