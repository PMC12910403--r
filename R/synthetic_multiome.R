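#' Generate synthetic single-cell RNA counts with planted structure
#'
#' Draws a cells x genes negative-binomial (Gamma-Poisson) count matrix.
#' Cells are neurons of \code{n_subtypes} subtypes at each condition (plus
#' optional non-neuronal cells); each subtype carries a disjoint block of
#' marker genes with mean multiplied by \code{marker_fold}, and the focal TF
#' follows a biphasic injury response: mean multiplied by
#' \code{tf_injury_fold} at 7 dpi, back to baseline at 2 mpi.
#'
#' The returned ground truth records every planted effect (subtype and
#' condition labels, marker blocks, TF->target couplings, DAP peak ids) so
#' downstream stages can be scored against a known answer. DAP ids and
#' regulatory edges are decided here, ahead of the ATAC generator, so both
#' generators agree on them.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return a list with elements \code{counts} (a \code{count_matrix},
#'   modality \code{"RNA"}), \code{cells} (a \code{\link{cell_table}}) and
#'   \code{truth} (a \code{ground_truth} list).
#' @export
generate_rna_counts <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(sub_seed(cfg$seed, 101L))

  gene_ids <- c(cfg$planted_tf_ids,
                sprintf("g%04d", seq_len(cfg$n_genes - length(cfg$planted_tf_ids))))
  n_tf <- length(cfg$planted_tf_ids)

  ## cell layout: subtype-major, condition-minor, then non-neurons
  grid <- expand.grid(
    subtype = sprintf("subtype%d", seq_len(cfg$n_subtypes)),
    condition = cfg$conditions,
    stringsAsFactors = FALSE
  )
  n_per <- cfg$n_cells_per_subtype_per_condition
  subtype <- rep(grid$subtype, each = n_per)
  condition <- rep(grid$condition, each = n_per)
  cell_class <- rep("Neurons", length(subtype))
  if (cfg$n_nonneuron_cells > 0) {
    subtype <- c(subtype, rep("non_neuronal", cfg$n_nonneuron_cells))
    condition <- c(condition,
                   rep(cfg$conditions, length.out = cfg$n_nonneuron_cells))
    cell_class <- c(cell_class, rep("Other", cfg$n_nonneuron_cells))
  }
  n_cells <- length(subtype)
  cells <- cell_table(
    cell_id = sprintf("cell_%05d", seq_len(n_cells)),
    cell_class = cell_class, subtype = subtype, condition = condition
  )

  ## reserve disjoint gene blocks: TFs | markers | planted targets | rest
  pool <- setdiff(gene_ids, cfg$planted_tf_ids)
  marker_genes <- vector("list", cfg$n_subtypes)
  names(marker_genes) <- sprintf("subtype%d", seq_len(cfg$n_subtypes))
  idx <- 0L
  for (s in seq_len(cfg$n_subtypes)) {
    marker_genes[[s]] <- pool[idx + seq_len(cfg$n_marker_genes)]
    idx <- idx + cfg$n_marker_genes
  }
  target_pool <- pool[-seq_len(idx)]
  edges <- data.frame(tf = character(), target = character(),
                      beta = numeric(), stringsAsFactors = FALSE)
  tidx <- 0L
  for (tf in cfg$planted_tf_ids) {
    tg <- target_pool[tidx + seq_len(cfg$planted_targets_per_tf)]
    tidx <- tidx + cfg$planted_targets_per_tf
    if (cfg$planted_targets_per_tf > 0)
      edges <- rbind(edges, data.frame(tf = tf, target = tg,
                                       beta = cfg$coupling_beta,
                                       stringsAsFactors = FALSE))
  }

  ## planted DAPs: disjoint peak-id sets per injured condition
  pk <- peak_coordinates(cfg)
  injured <- setdiff(cfg$conditions, cfg$conditions[1])
  dap_ids <- setNames(vector("list", length(injured)), injured)
  if (cfg$n_dap_per_condition > 0 && length(injured)) {
    picks <- sample(pk$peak_id, cfg$n_dap_per_condition * length(injured))
    for (i in seq_along(injured))
      dap_ids[[i]] <- picks[(i - 1) * cfg$n_dap_per_condition +
                              seq_len(cfg$n_dap_per_condition)]
  }

  ## expected-count matrix
  mu <- matrix(cfg$baseline_mean, n_cells, cfg$n_genes,
               dimnames = list(cells$cell_id, gene_ids))
  if (cfg$marker_fold > 1) {
    for (s in names(marker_genes)) {
      rows <- cells$subtype == s
      mu[rows, marker_genes[[s]]] <- cfg$baseline_mean * cfg$marker_fold
    }
  }
  focal_tf <- cfg$planted_tf_ids[1]
  tf_fold <- c("7dpi" = cfg$tf_injury_fold)  # biphasic: up then back down
  if (cfg$tf_injury_fold > 1 && "7dpi" %in% cfg$conditions) {
    rows <- cells$cell_class == "Neurons" & cells$condition == "7dpi"
    mu[rows, focal_tf] <- cfg$baseline_mean * cfg$tf_injury_fold
  }

  counts <- matrix(
    rnbinom(n_cells * cfg$n_genes, size = cfg$nb_dispersion, mu = as.vector(mu)),
    n_cells, cfg$n_genes, dimnames = dimnames(mu)
  )
  cm <- count_matrix(Matrix(counts, sparse = TRUE), "RNA")

  truth <- structure(list(
    cells = as.data.frame(cells),
    marker_genes = marker_genes,
    focal_tf = focal_tf,
    tf_condition_fold = tf_fold,
    edges = edges,
    dap_ids = dap_ids,
    motif = NULL,
    seed = cfg$seed
  ), class = "ground_truth")

  list(counts = cm, cells = cells, truth = truth)
}

#' Generate synthetic ATAC peak and TSS-window counts paired with RNA
#'
#' Draws Poisson counts for peaks and for one TSS window per gene. Planted
#' DAPs have their rate multiplied by \code{dap_fold} in their condition.
#' For each planted regulatory edge (TF, target), the target's TSS-window
#' rate in a cell is \code{baseline * exp(coupling_beta * z)} with \code{z}
#' the standardized log1p RNA count of the TF in that cell — inducing a
#' positive rank correlation between TF expression and target accessibility
#' whose strength grows with \code{coupling_beta}.
#'
#' @param cfg the \code{\link{sim_config}} used for the RNA draw.
#' @param rna the RNA \code{count_matrix} from \code{\link{generate_rna_counts}}.
#' @param truth the matching \code{ground_truth}.
#' @return list with \code{peaks} (modality \code{"ATAC_PEAK"}) and
#'   \code{tss} (modality \code{"ATAC_TSS"}) count matrices over the same
#'   cells as \code{rna}.
#' @export
generate_atac_counts <- function(cfg, rna, truth) {
  validate_sim_config(cfg)
  check_count_matrix(rna, normalized = FALSE)
  if (!identical(cell_ids(rna), truth$cells$cell_id))
    stop("RNA matrix and ground truth describe different cells")
  set.seed(sub_seed(cfg$seed, 211L))

  n_cells <- nrow(rna$values)
  condition <- truth$cells$condition
  pk <- peak_coordinates(cfg)

  ## peak counts
  rate <- matrix(cfg$baseline_mean, n_cells, cfg$n_peaks,
                 dimnames = list(cell_ids(rna), pk$peak_id))
  if (cfg$dap_fold > 1) {
    for (cond in names(truth$dap_ids)) {
      rows <- condition == cond
      rate[rows, truth$dap_ids[[cond]]] <- cfg$baseline_mean * cfg$dap_fold
    }
  }
  peak_counts <- matrix(rpois(length(rate), as.vector(rate)),
                        n_cells, cfg$n_peaks, dimnames = dimnames(rate))

  ## TSS-window counts: one window per gene, coupled for planted edges
  gene_ids <- feature_ids(rna)
  tss_rate <- matrix(cfg$baseline_mean, n_cells, length(gene_ids),
                     dimnames = list(cell_ids(rna), gene_ids))
  if (nrow(truth$edges) && cfg$coupling_beta > 0) {
    for (tf in unique(truth$edges$tf)) {
      z <- log1p(as.numeric(rna$values[, tf]))
      s <- sd(z)
      z <- if (s > 0) (z - mean(z)) / s else z * 0
      targets <- truth$edges$target[truth$edges$tf == tf]
      tss_rate[, targets] <- cfg$baseline_mean *
        exp(truth$edges$beta[truth$edges$tf == tf][1] * z)
    }
  }
  tss_counts <- matrix(rpois(length(tss_rate), as.vector(tss_rate)),
                       n_cells, length(gene_ids), dimnames = dimnames(tss_rate))

  list(
    peaks = count_matrix(Matrix(peak_counts, sparse = TRUE), "ATAC_PEAK"),
    tss = count_matrix(Matrix(tss_counts, sparse = TRUE), "ATAC_TSS")
  )
}

#' Generate peak sequences with a planted motif and its PFM
#'
#' Emits one random DNA sequence per peak with GC fraction drawn from
#' \code{Beta(gc_beta_params)}. A consensus motif of length
#' \code{motif_length} is inserted at a uniform random offset into a
#' \code{motif_planting_rate_dap} fraction of planted DAPs and a
#' \code{motif_planting_rate_background} fraction of the remaining peaks.
#' The motif is returned as a position frequency matrix built from its
#' consensus with pseudocounts; its name is the focal TF's gene symbol so
#' motif-to-gene mapping works downstream. A \code{missing_gc_fraction} of
#' peaks has GC metadata recorded as \code{NA} to exercise the missing-GC
#' exclusion rule.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param truth the \code{ground_truth} from \code{\link{generate_rna_counts}}.
#' @return list with \code{peaks} (data.frame: chrom, start, end, peak_id,
#'   gc_fraction, sequence), \code{pfm} (a \code{\link{pfm}}) and
#'   \code{truth} updated with the motif's consensus and positive peak ids.
#' @export
generate_peak_sequences <- function(cfg, truth) {
  validate_sim_config(cfg)
  set.seed(sub_seed(cfg$seed, 307L))

  pk <- peak_coordinates(cfg)
  bases <- c("A", "C", "G", "T")
  consensus <- paste(sample(bases, cfg$motif_length, replace = TRUE),
                     collapse = "")

  dap_set <- unique(unlist(truth$dap_ids, use.names = FALSE))
  is_dap <- pk$peak_id %in% dap_set
  plant <- ifelse(is_dap,
                  runif(cfg$n_peaks) < cfg$motif_planting_rate_dap,
                  runif(cfg$n_peaks) < cfg$motif_planting_rate_background)

  gc <- rbeta(cfg$n_peaks, cfg$gc_beta_params[1], cfg$gc_beta_params[2])
  w <- cfg$peak_width_bp
  seqs <- character(cfg$n_peaks)
  motif_chars <- strsplit(consensus, "")[[1]]
  for (i in seq_len(cfg$n_peaks)) {
    p <- c((1 - gc[i]) / 2, gc[i] / 2, gc[i] / 2, (1 - gc[i]) / 2)
    chars <- sample(bases, w, replace = TRUE, prob = p)
    if (plant[i]) {
      off <- sample.int(w - cfg$motif_length + 1L, 1L)
      chars[off:(off + cfg$motif_length - 1L)] <- motif_chars
    }
    seqs[i] <- paste(chars, collapse = "")
  }

  gc_realized <- vapply(seqs, gc_fraction, numeric(1), USE.NAMES = FALSE)
  if (cfg$missing_gc_fraction > 0) {
    miss <- runif(cfg$n_peaks) < cfg$missing_gc_fraction
    gc_realized[miss] <- NA_real_
  }

  peaks <- data.frame(
    chrom = pk$chrom, start = pk$start, end = pk$end, peak_id = pk$peak_id,
    gc_fraction = gc_realized, sequence = seqs, stringsAsFactors = FALSE
  )

  counts <- matrix(1, 4, cfg$motif_length, dimnames = list(bases, NULL))
  counts[cbind(match(motif_chars, bases), seq_len(cfg$motif_length))] <- 97
  motif_pfm <- pfm(motif_id = "SYN0001.1", motif_name = truth$focal_tf,
                   counts = counts)

  truth$motif <- list(
    motif_id = motif_pfm$motif_id,
    consensus = consensus,
    positive_peak_ids = pk$peak_id[plant]
  )
  list(peaks = peaks, pfm = motif_pfm, truth = truth)
}

#' Generate a full synthetic paired-multiome dataset
#'
#' Convenience wrapper running all three generators from one config.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{rna}, \code{atac_peaks}, \code{atac_tss}
#'   (\code{count_matrix} objects), \code{cells}, \code{peaks}, \code{pfm}
#'   and \code{truth}.
#' @export
simulate_multiome <- function(cfg) {
  r <- generate_rna_counts(cfg)
  a <- generate_atac_counts(cfg, r$counts, r$truth)
  s <- generate_peak_sequences(cfg, r$truth)
  list(rna = r$counts, atac_peaks = a$peaks, atac_tss = a$tss,
       cells = r$cells, peaks = s$peaks, pfm = s$pfm, truth = s$truth)
}
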