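test_that("invalid configurations are rejected with the field named", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(nb_dispersion = -1), "nb_dispersion")
  expect_error(sim_config(motif_planting_rate_dap = 1.2),
               "motif_planting_rate_dap")
  expect_error(sim_config(motif_length = 2), "motif_length")
  expect_error(sim_config(motif_length = 300, peak_width_bp = 200),
               "peak_width_bp|motif_length")
  expect_error(sim_config(n_genes = 20, n_subtypes = 4, n_marker_genes = 15),
               "n_genes")
})

test_that("identical config and seed give byte-identical outputs", {
  a <- simulate_multiome(small_config(seed = 42))
  b <- simulate_multiome(small_config(seed = 42))
  expect_identical(a$rna$values, b$rna$values)
  expect_identical(a$atac_peaks$values, b$atac_peaks$values)
  expect_identical(a$atac_tss$values, b$atac_tss$values)
  expect_identical(a$peaks, b$peaks)
  expect_identical(a$truth, b$truth)
  c <- simulate_multiome(small_config(seed = 43))
  expect_false(identical(a$rna$values, c$rna$values))
})

test_that("effect-free config plants no differences in expectation", {
  sim <- simulate_multiome(null_config(seed = 5))
  cond <- sim$truth$cells$condition
  # no planted structure recorded
  expect_true(all(vapply(sim$truth$dap_ids, length, integer(1)) ==
                    small_config()$n_dap_per_condition))  # ids still drawn...
  # ...but rates identical: per-condition peak means agree within noise
  m7 <- Matrix::colMeans(sim$atac_peaks$values[cond == "7dpi", ])
  m0 <- Matrix::colMeans(sim$atac_peaks$values[cond == "uninjured", ])
  se <- sqrt(0.5 / sum(cond == "7dpi") + 0.5 / sum(cond == "uninjured"))
  expect_lt(max(abs(m7 - m0)), 6 * se)
  # RNA: subtype means agree as well
  st <- sim$truth$cells$subtype
  g1 <- Matrix::colMeans(sim$rna$values[st == "subtype1", ])
  g2 <- Matrix::colMeans(sim$rna$values[st == "subtype2", ])
  expect_lt(max(abs(g1 - g2)), 8 * se)
})

test_that("no planted DAPs means identical peak rates across conditions", {
  sim <- simulate_multiome(small_config(seed = 8, n_dap_per_condition = 0))
  expect_true(all(vapply(sim$truth$dap_ids, length, integer(1)) == 0))
  cond <- sim$truth$cells$condition
  m7 <- Matrix::colMeans(sim$atac_peaks$values[cond == "7dpi", ])
  m0 <- Matrix::colMeans(sim$atac_peaks$values[cond == "uninjured", ])
  expect_lt(max(abs(m7 - m0)), 1)  # Poisson(0.5) noise only, n = 40/group
})

test_that("marker blocks separate subtypes at marker_fold = 8", {
  cfg <- sim_config(n_cells_per_subtype_per_condition = 67, marker_fold = 8,
                    seed = 2)
  r <- generate_rna_counts(cfg)
  st <- r$truth$cells$subtype
  wins <- unlist(lapply(names(r$truth$marker_genes), function(s) {
    own <- Matrix::colMeans(r$counts$values[st == s, r$truth$marker_genes[[s]],
                                            drop = FALSE])
    other <- Matrix::colMeans(r$counts$values[st != s, r$truth$marker_genes[[s]],
                                              drop = FALSE])
    own > other
  }))
  expect_gte(mean(wins), 0.95)
})

test_that("focal TF follows the biphasic injury pattern", {
  cfg <- small_config(seed = 3, n_cells_per_subtype_per_condition = 80,
                      tf_injury_fold = 4)
  r <- generate_rna_counts(cfg)
  cond <- r$truth$cells$condition
  tf <- r$truth$focal_tf
  m <- tapply(as.numeric(r$counts$values[, tf]), cond, mean)
  expect_gt(m[["7dpi"]], 2 * m[["uninjured"]])   # up at 7 dpi
  expect_lt(m[["2mpi"]], 1.5 * m[["uninjured"]]) # back down at 2 mpi
})

test_that("alignment between RNA and ground truth is enforced", {
  cfg <- small_config(seed = 1)
  r <- generate_rna_counts(cfg)
  truth_bad <- r$truth
  truth_bad$cells <- truth_bad$cells[-1, ]
  expect_error(generate_atac_counts(cfg, r$counts, truth_bad),
               "different cells")
})

test_that("zero coupling leaves planted TF-TSS pairs uncorrelated", {
  hits <- 0L; total <- 0L
  for (seed in 1:4) {
    cfg <- small_config(seed = seed, coupling_beta = 0,
                        n_cells_per_subtype_per_condition = 40,
                        planted_targets_per_tf = 5)
    r <- generate_rna_counts(cfg)
    a <- generate_atac_counts(cfg, r$counts, r$truth)
    n <- nrow(r$counts$values)
    for (i in seq_len(nrow(r$truth$edges))) {
      rho <- spearman(as.numeric(r$counts$values[, r$truth$edges$tf[i]]),
                      as.numeric(a$tss$values[, r$truth$edges$target[i]]))$rho
      total <- total + 1L
      if (abs(rho) <= 3 / sqrt(n)) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("strong coupling yields rho >= 0.3 for planted pairs", {
  cfg <- sim_config(n_cells_per_subtype_per_condition = 42,
                    coupling_beta = 1.5, planted_targets_per_tf = 10, seed = 6)
  r <- generate_rna_counts(cfg)
  a <- generate_atac_counts(cfg, r$counts, r$truth)
  rhos <- vapply(seq_len(nrow(r$truth$edges)), function(i) {
    spearman(as.numeric(r$counts$values[, r$truth$edges$tf[i]]),
             as.numeric(a$tss$values[, r$truth$edges$target[i]]))$rho
  }, numeric(1))
  expect_gte(mean(rhos >= 0.3), 0.95)
})

test_that("mean planted-pair rho is non-decreasing in coupling_beta", {
  mean_rho <- vapply(c(0.3, 0.8, 1.5), function(beta) {
    cfg <- small_config(seed = 9, coupling_beta = beta,
                        n_cells_per_subtype_per_condition = 40,
                        planted_targets_per_tf = 5)
    r <- generate_rna_counts(cfg)
    a <- generate_atac_counts(cfg, r$counts, r$truth)
    mean(vapply(seq_len(nrow(r$truth$edges)), function(i) {
      spearman(as.numeric(r$counts$values[, r$truth$edges$tf[i]]),
               as.numeric(a$tss$values[, r$truth$edges$target[i]]))$rho
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_rho) >= 0))
})

test_that("motif planting at rates (1, 0) is exact and exhaustive", {
  cfg <- small_config(seed = 4, motif_planting_rate_dap = 1,
                      motif_planting_rate_background = 0,
                      missing_gc_fraction = 0)
  r <- generate_rna_counts(cfg)
  s <- generate_peak_sequences(cfg, r$truth)
  daps <- unique(unlist(r$truth$dap_ids))
  consensus <- s$truth$motif$consensus
  has <- grepl(consensus, s$peaks$sequence, fixed = TRUE)
  expect_true(all(has[s$peaks$peak_id %in% daps]))
  expect_false(any(has[!(s$peaks$peak_id %in% daps)]))
  expect_setequal(s$truth$motif$positive_peak_ids, daps)
})

test_that("GC fractions follow the configured Beta distribution", {
  cfg <- sim_config(n_peaks = 2000, gc_beta_params = c(1, 1),
                    missing_gc_fraction = 0, n_dap_per_condition = 0, seed = 10)
  r <- generate_rna_counts(cfg)
  s <- generate_peak_sequences(cfg, r$truth)
  expect_lt(abs(mean(s$peaks$gc_fraction) - 0.5), 0.02)
  expect_true(all(s$peaks$gc_fraction >= 0 & s$peaks$gc_fraction <= 1))
})

test_that("planting counts fall within binomial 99% bounds", {
  cfg <- sim_config(n_peaks = 1000, n_dap_per_condition = 50,
                    motif_planting_rate_dap = 0.5,
                    motif_planting_rate_background = 0.05,
                    missing_gc_fraction = 0, seed = 12)
  r <- generate_rna_counts(cfg)
  s <- generate_peak_sequences(cfg, r$truth)
  daps <- unique(unlist(r$truth$dap_ids))  # 100 planted DAPs, 900 background
  pos <- s$truth$motif$positive_peak_ids
  n_dap_pos <- sum(pos %in% daps)
  n_bg_pos <- length(pos) - n_dap_pos
  expect_gte(n_dap_pos, qbinom(0.005, length(daps), 0.5))
  expect_lte(n_dap_pos, qbinom(0.995, length(daps), 0.5))
  expect_gte(n_bg_pos, qbinom(0.005, 1000 - length(daps), 0.05))
  expect_lte(n_bg_pos, qbinom(0.995, 1000 - length(daps), 0.05))
  # PFM consensus reproduces the planted consensus
  expect_identical(pfm_consensus(s$pfm), s$truth$motif$consensus)
})

test_that("missing-GC metadata is planted at the configured rate", {
  cfg <- sim_config(n_peaks = 1000, missing_gc_fraction = 0.02, seed = 13)
  r <- generate_rna_counts(cfg)
  s <- generate_peak_sequences(cfg, r$truth)
  n_missing <- sum(is.na(s$peaks$gc_fraction))
  expect_gte(n_missing, qbinom(0.005, 1000, 0.02))
  expect_lte(n_missing, qbinom(0.995, 1000, 0.02))
  # sequences still present for peaks with missing metadata
  expect_false(any(is.na(s$peaks$sequence)))
})
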