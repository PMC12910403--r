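# Shared fixture builders. Everything is generated in code at test time.

# A small, fast simulation design
small_config <- function(seed = 1L, ...) {
  args <- modifyList(list(
    n_cells_per_subtype_per_condition = 20L,
    n_subtypes = 2L,
    n_genes = 60L,
    n_peaks = 80L,
    n_marker_genes = 5L,
    n_dap_per_condition = 10L,
    planted_targets_per_tf = 4L,
    seed = seed
  ), list(...))
  do.call(sim_config, args)
}

# All planted effects switched off: a pure-noise null
null_config <- function(seed = 1L, ...) {
  small_config(seed = seed, marker_fold = 1, dap_fold = 1, coupling_beta = 0,
               tf_injury_fold = 1, ...)
}

# Wrap a plain matrix as a normalized count_matrix (for embedding tests)
as_norm_cm <- function(m, modality = "ATAC_PEAK", totals = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("c%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("f%03d", seq_len(ncol(m)))
  out <- count_matrix(Matrix::Matrix(m, sparse = TRUE), modality,
                      normalized = TRUE)
  if (!is.null(totals)) attr(out, "cell_totals") <- setNames(totals, rownames(m))
  out
}

# Bare embedding from a coordinate matrix
as_embedding <- function(co, dropped = integer(0)) {
  if (is.null(rownames(co))) rownames(co) <- sprintf("c%03d", seq_len(nrow(co)))
  structure(list(cell_ids = rownames(co), coordinates = co, method = "PCA",
                 singular_values = rep(1, ncol(co)),
                 components_dropped = dropped),
            class = "embedding")
}

# Adjusted Rand index between two label vectors (closed-form contingency
# formula) -- independent of any clustering implementation under test.
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Exact hypergeometric upper tail by brute-force pmf summation
hyper_tail_bruteforce <- function(q, K, N, draws) {
  ks <- q:min(K, draws)
  ks <- ks[ks >= max(0, draws - (N - K))]
  if (!length(ks)) return(0)
  sum(choose(K, ks) * choose(N - K, draws - ks)) / choose(N, draws)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
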