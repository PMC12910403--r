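#' Configuration for the synthetic paired-multiome generator
#'
#' Defines the simulated study design: neurons of several subtypes sampled at
#' an uninjured baseline and two post-injury timepoints, with planted
#' subtype marker genes, condition-responsive peaks (DAPs), a motif planted
#' preferentially into DAP sequences, and TF-coupled target-gene TSS
#' accessibility. The defaults mirror the design the package targets: four
#' neuron subtypes at three conditions (uninjured, 7 dpi, 2 mpi), a single
#' focal TF (\code{"Creb5"}) with biphasic expression — up at 7 dpi, back
#' down at 2 mpi — and ten planted regulatory targets.
#'
#' @param n_cells_per_subtype_per_condition cells simulated per (subtype,
#'   condition) combination.
#' @param n_subtypes number of neuron subtypes.
#' @param conditions ordered condition labels; first is the control.
#' @param n_genes,n_peaks number of RNA features / ATAC peaks.
#' @param nb_dispersion negative-binomial size parameter shared by all genes
#'   (smaller = more overdispersed).
#' @param baseline_mean baseline expected count per cell, used for both the
#'   RNA negative-binomial mean and the ATAC Poisson rate.
#' @param marker_fold fold change of subtype marker genes in their subtype
#'   (must be >= 1; 1 disables markers).
#' @param n_marker_genes marker genes per subtype (disjoint blocks).
#' @param n_dap_per_condition planted differentially accessible peaks per
#'   injured condition (disjoint between conditions).
#' @param dap_fold accessibility fold change of planted DAPs in their
#'   condition (>= 1; 1 disables).
#' @param planted_tf_ids gene ids used for planted transcription factors; the
#'   first is the focal TF.
#' @param planted_targets_per_tf number of target genes coupled to each
#'   planted TF.
#' @param coupling_beta strength of the TF -> target-TSS coupling: the TSS
#'   Poisson rate of a target is \code{baseline * exp(coupling_beta * z)}
#'   where \code{z} is the standardized log1p RNA count of its TF in the same
#'   cell. 0 disables coupling.
#' @param tf_injury_fold fold change of the focal TF at 7 dpi (back to
#'   baseline at 2 mpi); 1 disables the biphasic pattern.
#' @param motif_length length of the planted consensus motif (>= 4).
#' @param motif_planting_rate_dap,motif_planting_rate_background probability
#'   that a planted-DAP / background peak receives a motif insertion.
#' @param gc_beta_params shape parameters of the Beta distribution GC
#'   fractions are drawn from.
#' @param missing_gc_fraction fraction of peaks whose GC metadata is recorded
#'   as missing (exercises the missing-GC exclusion rule downstream).
#' @param peak_width_bp width of each simulated peak in bp.
#' @param tss_window_bp width of the TSS window each gene's accessibility is
#'   summarized over (metadata only; counts are simulated per window).
#' @param n_nonneuron_cells extra cells of class \code{"Other"} appended to
#'   the dataset, spread across conditions.
#' @param seed integer master seed; each generator derives its own sub-stream
#'   so adding one generator does not perturb the draws of another.
#'
#' @return a validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_cells_per_subtype_per_condition = 70,
                       n_subtypes = 4,
                       conditions = c("uninjured", "7dpi", "2mpi"),
                       n_genes = 400,
                       n_peaks = 800,
                       nb_dispersion = 2,
                       baseline_mean = 0.5,
                       marker_fold = 8,
                       n_marker_genes = 15,
                       n_dap_per_condition = 50,
                       dap_fold = 4,
                       planted_tf_ids = "Creb5",
                       planted_targets_per_tf = 10,
                       coupling_beta = 1.5,
                       tf_injury_fold = 4,
                       motif_length = 8,
                       motif_planting_rate_dap = 0.5,
                       motif_planting_rate_background = 0.05,
                       gc_beta_params = c(5, 5),
                       missing_gc_fraction = 0.02,
                       peak_width_bp = 200,
                       tss_window_bp = 2000,
                       n_nonneuron_cells = 0,
                       seed = 1L) {
  cfg <- list(
    n_cells_per_subtype_per_condition = n_cells_per_subtype_per_condition,
    n_subtypes = n_subtypes,
    conditions = conditions,
    n_genes = n_genes,
    n_peaks = n_peaks,
    nb_dispersion = nb_dispersion,
    baseline_mean = baseline_mean,
    marker_fold = marker_fold,
    n_marker_genes = n_marker_genes,
    n_dap_per_condition = n_dap_per_condition,
    dap_fold = dap_fold,
    planted_tf_ids = as.character(planted_tf_ids),
    planted_targets_per_tf = planted_targets_per_tf,
    coupling_beta = coupling_beta,
    tf_injury_fold = tf_injury_fold,
    motif_length = motif_length,
    motif_planting_rate_dap = motif_planting_rate_dap,
    motif_planting_rate_background = motif_planting_rate_background,
    gc_beta_params = gc_beta_params,
    missing_gc_fraction = missing_gc_fraction,
    peak_width_bp = peak_width_bp,
    tss_window_bp = tss_window_bp,
    n_nonneuron_cells = n_nonneuron_cells,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  pos_int <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1 || v != round(v))
      stop("sim_config: '", field, "' must be a positive integer")
  }
  pos_real <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0)
      stop("sim_config: '", field, "' must be a positive number")
  }
  prob <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop("sim_config: '", field, "' must be a probability in [0, 1]")
  }
  for (f in c("n_cells_per_subtype_per_condition", "n_subtypes", "n_genes",
              "n_peaks", "peak_width_bp", "tss_window_bp"))
    pos_int(f)
  for (f in c("nb_dispersion", "baseline_mean")) pos_real(f)
  for (f in c("motif_planting_rate_dap", "motif_planting_rate_background",
              "missing_gc_fraction"))
    prob(f)
  if (cfg$marker_fold < 1) stop("sim_config: 'marker_fold' must be >= 1")
  if (cfg$dap_fold < 1) stop("sim_config: 'dap_fold' must be >= 1")
  if (cfg$tf_injury_fold < 1) stop("sim_config: 'tf_injury_fold' must be >= 1")
  if (cfg$coupling_beta < 0) stop("sim_config: 'coupling_beta' must be >= 0")
  if (cfg$motif_length < 4 || cfg$motif_length != round(cfg$motif_length))
    stop("sim_config: 'motif_length' must be an integer >= 4")
  if (cfg$motif_length > cfg$peak_width_bp)
    stop("sim_config: 'motif_length' exceeds 'peak_width_bp'")
  if (length(cfg$conditions) < 1 || anyDuplicated(cfg$conditions))
    stop("sim_config: 'conditions' must be unique labels")
  if (length(cfg$gc_beta_params) != 2 || any(cfg$gc_beta_params <= 0))
    stop("sim_config: 'gc_beta_params' must be two positive shapes")
  if (cfg$n_dap_per_condition < 0 ||
      cfg$n_dap_per_condition * (length(cfg$conditions) - 1) > cfg$n_peaks)
    stop("sim_config: 'n_dap_per_condition' does not fit into 'n_peaks'")
  n_reserved <- length(cfg$planted_tf_ids) +
    cfg$n_subtypes * cfg$n_marker_genes +
    length(cfg$planted_tf_ids) * cfg$planted_targets_per_tf
  if (cfg$planted_targets_per_tf < 0 || n_reserved > cfg$n_genes)
    stop("sim_config: 'n_genes' too small for TFs + markers + planted targets")
  if (cfg$n_nonneuron_cells < 0)
    stop("sim_config: 'n_nonneuron_cells' must be >= 0")
  invisible(cfg)
}

# Derive a reproducible sub-seed per generator from the master seed so the
# generators draw from independent streams.
sub_seed <- function(seed, offset) {
  (abs(as.integer(seed)) %% 2000000L) * 1000L + as.integer(offset)
}

# Deterministic peak coordinates: peaks tiled along a synthetic chromosome.
# Needed before sequences/counts exist so ground truth can name peak ids.
peak_coordinates <- function(cfg) {
  start <- (seq_len(cfg$n_peaks) - 1L) * 1000L
  data.frame(
    chrom = "chr1",
    start = start,
    end = start + cfg$peak_width_bp,
    peak_id = sprintf("chr1:%d-%d", start, start + cfg$peak_width_bp),
    stringsAsFactors = FALSE
  )
}
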